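# Per-genome summary statistics and cross-strain repertoire comparisons.

#' AT content of a genome, in percent
#'
#' N characters are excluded from both numerator and denominator. Reported
#' rounded half-up to one decimal, matching the precision of published
#' organelle-genome tables.
#'
#' @param g A [circular_genome()] or a DNA string.
#' @return AT percentage (one decimal).
#' @export
at_content <- function(g) {
  s <- if (inherits(g, "circular_genome")) g$sequence else toupper(as.character(g))
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(s), c("A", "C", "G", "T"))
  tot <- sum(counts)
  if (tot == 0L) stop("sequence contains no unambiguous bases")
  round_half_up1(100 * (counts[["A"]] + counts[["T"]]) / tot)
}

# expand features (possibly wrap-encoded) to linear IRanges on [0, L)
.feature_ranges <- function(feats, L) {
  if (nrow(feats) == 0L) return(IRanges::IRanges())
  s <- feats$start; e <- feats$end
  wrap <- e <= s
  starts <- c(s[!wrap], s[wrap], rep(0L, sum(wrap)))
  ends <- c(e[!wrap], rep(L, sum(wrap)), e[wrap])
  IRanges::IRanges(start = starts + 1L, end = ends)  # 1-based closed for IRanges
}

#' Coding density of a genome, in percent
#'
#' Fraction of the circle covered by the union of CDS, tRNA and rRNA
#' features (overlaps counted once); repeat_region and gap features are
#' excluded. Rounded half-up to one decimal.
#'
#' @param g A [circular_genome()].
#' @return Coding percentage (one decimal).
#' @export
coding_density <- function(g) {
  f <- gene_features(g)
  if (nrow(f) == 0L) stop("no gene features annotated")
  cov <- IRanges::reduce(.feature_ranges(f, g$length))
  round_half_up1(100 * sum(IRanges::width(cov)) / g$length)
}

#' Intergenic spacers around the circle
#'
#' For consecutive gene features ordered by start, the spacer is the gap
#' (in bp) between the running maximal feature end and the next feature
#' start, clamped at zero for overlapping or nested genes; the gap spanning
#' the origin is included.
#'
#' @param g A [circular_genome()] with at least two gene features.
#' @return A data frame with columns `left`, `right`, `length`, ordered
#'   around the circle.
#' @export
intergenic_spacers <- function(g) {
  f <- gene_features(g)
  if (nrow(f) < 2L) stop("need at least two gene features")
  L <- g$length
  # linearize: wrap-encoded features extend past L
  s <- f$start
  e <- ifelse(f$end <= f$start, f$end + L, f$end)
  o <- order(s, e)
  s <- s[o]; e <- e[o]; nm <- f$name[o]
  n <- length(s)
  left <- character(0); right <- character(0); len <- integer(0)
  cur_end <- e[1L]; cur_name <- nm[1L]
  for (i in seq_len(n)[-1L]) {
    gap <- s[i] - cur_end
    left <- c(left, cur_name); right <- c(right, nm[i])
    len <- c(len, max(0L, gap))
    if (e[i] > cur_end) { cur_end <- e[i]; cur_name <- nm[i] }
  }
  # wrap gap back to the first feature (its start lifted by L)
  left <- c(left, cur_name); right <- c(right, nm[1L])
  len <- c(len, max(0L, s[1L] + L - cur_end))
  data.frame(left = left, right = right, length = len, stringsAsFactors = FALSE)
}

#' Longest intergenic spacer
#' @param g A [circular_genome()].
#' @return One-row data frame (`left`, `right`, `length`).
#' @export
longest_spacer <- function(g) {
  sp <- intergenic_spacers(g)
  sp[which.max(sp$length), , drop = FALSE]
}

#' Maximal same-strand gene runs (candidate transcription units)
#'
#' Genes are ordered by start around the circle; maximal runs of a single
#' strand are reported, merging the first and last run circularly when they
#' share a strand. Two strand blocks separated by the two repeat regions is
#' the hallmark layout of these genomes.
#'
#' @param g A [circular_genome()].
#' @return A list of character vectors of gene names, one per block, each
#'   with a `strand` attribute.
#' @export
strand_blocks <- function(g) {
  f <- gene_features(g)
  if (nrow(f) == 0L) stop("no gene features annotated")
  f <- f[order(f$start), ]
  r <- rle(f$strand)
  blocks <- split(f$name, rep(seq_along(r$lengths), r$lengths))
  strands <- r$values
  if (length(blocks) > 1L && strands[1L] == strands[length(strands)]) {
    blocks[[1L]] <- c(blocks[[length(blocks)]], blocks[[1L]])
    blocks[[length(blocks)]] <- NULL
    strands <- strands[-length(strands)]
  }
  mapply(function(b, s) { attr(b, "strand") <- s; b }, blocks, strands,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Per-genome summary statistics
#' @param g A [circular_genome()].
#' @return A list with `id`, `length`, `at_percent`, `coding_percent`,
#'   `noncoding_percent`, `longest_spacer`, `n_strand_blocks`.
#' @export
genome_summary <- function(g) {
  cp <- coding_density(g)
  list(id = g$id, length = g$length, at_percent = at_content(g),
       coding_percent = cp, noncoding_percent = round_half_up1(100 - cp),
       longest_spacer = longest_spacer(g),
       n_strand_blocks = length(strand_blocks(g)))
}

# column key for the repertoire: tRNAs are keyed by amino-acid identity so
# that anticodon variants of the same tRNA land in one column
.gene_column_key <- function(name, kind) {
  ifelse(kind == "tRNA", sub("-[ACGT]{3}(\\.[0-9]+)?$", "", name), name)
}

#' Gene repertoire matrix across genomes
#'
#' One row per genome, one column per gene (tRNA columns pooled by
#' amino-acid identity). Cells are `"1"` (present), `"0"` (absent), or
#' `"V:<anticodon>"` when a genome's tRNA carries an anticodon different
#' from the column consensus.
#'
#' @param gs A list of [circular_genome()] objects (at least two for a
#'   meaningful comparison).
#' @return A character matrix of class `repertoire_matrix`.
#' @export
repertoire_matrix <- function(gs) {
  stopifnot(length(gs) >= 1L)
  per <- lapply(gs, function(g) {
    f <- gene_features(g)
    data.frame(key = .gene_column_key(f$name, f$kind),
               anticodon = f$anticodon, kind = f$kind,
               stringsAsFactors = FALSE)
  })
  ids <- vapply(gs, function(g) g$id, character(1))
  keys <- unique(unlist(lapply(per, function(p) p$key)))
  m <- matrix("0", nrow = length(gs), ncol = length(keys),
              dimnames = list(ids, sort(keys)))
  anti <- matrix(NA_character_, nrow = length(gs), ncol = ncol(m),
                 dimnames = dimnames(m))
  for (i in seq_along(per)) {
    p <- per[[i]]
    m[i, unique(p$key)] <- "1"
    tr <- p[p$kind == "tRNA" & !is.na(p$anticodon), ]
    if (nrow(tr)) anti[i, tr$key[!duplicated(tr$key)]] <-
        tr$anticodon[!duplicated(tr$key)]
  }
  # flag anticodon variants against the column majority (ties: first seen)
  for (j in seq_len(ncol(m))) {
    a <- anti[, j]
    obs <- a[!is.na(a)]
    if (length(unique(obs)) > 1L) {
      tab <- sort(table(factor(obs, levels = unique(obs))), decreasing = TRUE)
      consensus <- names(tab)[1L]
      variant <- !is.na(a) & a != consensus
      m[variant, j] <- paste0("V:", a[variant])
    }
  }
  structure(m, class = c("repertoire_matrix", class(m)))
}

#' Core genes shared by every genome of a repertoire matrix
#'
#' Anticodon variants of the same tRNA count as present.
#'
#' @param m A [repertoire_matrix()].
#' @return Sorted character vector of column keys present in every row.
#' @export
core_genes <- function(m) {
  present <- m != "0"
  sort(colnames(m)[colSums(present) == nrow(m)])
}

#' Pairwise difference counts in a multiple alignment
#'
#' Counts, for every pair of sequences, the alignment columns where both
#' sequences carry a non-gap character and the characters differ
#' (case-insensitive). Columns with a gap in either member of the pair are
#' skipped, the convention of common alignment editors.
#'
#' @param aligned Named character vector (or `DNAStringSet`) of equal-length
#'   gapped sequences; gaps are `-` or `.`.
#' @param region Optional 1-based inclusive column interval `c(from, to)`
#'   restricting the count (e.g. the V4 or V9 subregion of an 18S alignment).
#' @return A symmetric integer matrix with zero diagonal.
#' @export
pairwise_differences <- function(aligned, region = NULL) {
  ids <- names(aligned) %||% paste0("seq", seq_along(aligned))
  seqs <- toupper(as.character(aligned))
  if (length(unique(nchar(seqs))) != 1L) stop("ragged alignment")
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  if (!is.null(region)) {
    stopifnot(length(region) == 2L, region[1L] >= 1L, region[2L] <= ncol(chars))
    chars <- chars[, region[1L]:region[2L], drop = FALSE]
  }
  n <- length(seqs)
  out <- matrix(0L, n, n, dimnames = list(ids, ids))
  gap <- chars == "-" | chars == "."
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      d <- sum(chars[i, ok] != chars[j, ok])
      out[i, j] <- d; out[j, i] <- d
    }
  }
  out
}
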