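# CircularGenome: a circular DNA molecule with annotated features and
# 0-based half-open coordinates everywhere. A feature whose end is <= its
# start encodes an interval that wraps through the origin; lengths are
# always computed modulo the genome length so features stay in one piece.

#' Construct a circular genome object
#'
#' @param id Genome identifier.
#' @param sequence DNA sequence (A/C/G/T/N; lowercase is uppercased).
#' @param features A data frame of features as returned by
#'   [empty_features()]: columns `name`, `kind` (one of CDS, tRNA, rRNA,
#'   repeat_region, gap), `start` (0-based inclusive), `end` (exclusive;
#'   `end <= start` encodes wrapping through the origin, with `end` in
#'   `(0, length]`), `strand` (`"+"`/`"-"`), `anticodon` (3-mer or `NA`).
#' @param is_circular Logical; linear contigs are accepted but wraparound
#'   extraction is refused for them.
#' @param mark_gaps If `TRUE`, runs of at least `gap_min` N characters are
#'   recorded as explicit `gap` features.
#' @param gap_min Minimum N-run length to mark as a gap.
#' @return An object of class `circular_genome`.
#' @export
circular_genome <- function(id, sequence, features = empty_features(),
                            is_circular = TRUE, mark_gaps = TRUE,
                            gap_min = 100L) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) stop("zero-length sequence")
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters other than A, C, G, T, N")
  }
  L <- nchar(sequence)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "kind", "start", "end", "strand") %in% names(features)))
  if (is.null(features$anticodon)) features$anticodon <- NA_character_
  if (nrow(features)) {
    if (any(features$start < 0 | features$start >= L)) {
      stop("feature start coordinates must lie in [0, length)")
    }
    if (any(features$end <= 0 | features$end > L)) {
      stop("feature end coordinates must lie in (0, length]")
    }
    if (!all(features$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  }
  if (mark_gaps) {
    gaps <- gregexpr(sprintf("N{%d,}", gap_min), sequence)[[1L]]
    if (gaps[1L] != -1L) {
      glen <- attr(gaps, "match.length")
      have <- features$kind == "gap"
      for (i in seq_along(gaps)) {
        s <- gaps[i] - 1L; e <- s + glen[i]
        if (!any(have & features$start == s)) {
          features <- rbind(features, data.frame(
            name = sprintf("gap_%d", i), kind = "gap", start = s, end = e,
            strand = "+", anticodon = NA_character_, stringsAsFactors = FALSE))
        }
      }
    }
  }
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  structure(list(id = id, sequence = sequence, length = L,
                 is_circular = is_circular, features = features),
            class = "circular_genome")
}

#' Empty feature table
#' @return A zero-row feature data frame with the canonical columns.
#' @export
empty_features <- function() {
  data.frame(name = character(0), kind = character(0), start = integer(0),
             end = integer(0), strand = character(0),
             anticodon = character(0), stringsAsFactors = FALSE)
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %d bp%s, %d features\n", x$id, x$length,
              if (x$is_circular) " (circular)" else " (linear)",
              nrow(x$features)))
  kinds <- table(x$features$kind)
  if (length(kinds)) {
    cat("  ", paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", "), "\n")
  }
  invisible(x)
}

# gene-like features (the annotated repertoire)
gene_features <- function(g) {
  g$features[g$features$kind %in% c("CDS", "tRNA", "rRNA"), , drop = FALSE]
}

#' Extract a subsequence from a circular genome
#'
#' Half-open extraction `[start, end)` with wraparound through the origin
#' when `end <= start`; `end == start` returns the full circle starting at
#' `start`. Strand `"-"` returns the reverse complement.
#'
#' @param g A `circular_genome`.
#' @param start 0-based inclusive start, in `[0, length)`.
#' @param end Exclusive end in `[0, length]`.
#' @param strand `"+"` or `"-"`.
#' @return A character scalar.
#' @export
subsequence <- function(g, start, end, strand = "+") {
  L <- g$length
  if (start < 0 || start >= L) stop("start out of range")
  if (end != L) end <- circ_mod(end, L)
  if (end > start) {
    s <- substr(g$sequence, start + 1L, end)
  } else {
    if (!g$is_circular) stop("wraparound extraction from a linear genome")
    s <- paste0(substr(g$sequence, start + 1L, L),
                if (end > 0L) substr(g$sequence, 1L, end) else "")
  }
  if (strand == "-") s <- revcomp(s)
  s
}

# sequence of one feature row
feature_sequence <- function(g, feat) {
  subsequence(g, feat$start, circ_mod(feat$end, g$length), feat$strand)
}

#' Reverse-complement a whole genome, remapping all features
#' @param g A `circular_genome`.
#' @return The reverse-complemented genome.
#' @export
reverse_complement_genome <- function(g) {
  L <- g$length
  f <- g$features
  if (nrow(f)) {
    new_start <- circ_mod(L - f$end, L)
    new_end <- ifelse(f$start == 0L, L, L - f$start)
    f$start <- new_start
    f$end <- new_end
    f$strand <- ifelse(f$strand == "+", "-", "+")
  }
  circular_genome(g$id, revcomp(g$sequence), f, g$is_circular, mark_gaps = FALSE)
}

#' Rotate a circular genome so a chosen start point maps to coordinate 0
#' @param g A `circular_genome`.
#' @param offset New origin (0-based coordinate of the current genome).
#' @return The rotated genome.
#' @export
rotate_genome <- function(g, offset) {
  L <- g$length
  offset <- circ_mod(offset, L)
  if (offset == 0L) return(g)
  if (!g$is_circular) stop("cannot rotate a linear genome")
  seq2 <- paste0(substr(g$sequence, offset + 1L, L),
                 substr(g$sequence, 1L, offset))
  f <- g$features
  if (nrow(f)) {
    f$start <- circ_mod(f$start - offset, L)
    e <- circ_mod(f$end - offset, L)
    f$end <- ifelse(e == 0L, L, e)
  }
  circular_genome(g$id, seq2, f, g$is_circular, mark_gaps = FALSE)
}

#' Normalize a genome to start at a named gene
#'
#' Rotates the circle so the named gene starts at coordinate 0 and is on the
#' plus strand, reverse-complementing the whole molecule when the gene lies
#' on the minus strand. The conventional anchor for these mitochondrial
#' genomes is *cox1*.
#'
#' @param g A `circular_genome`.
#' @param gene Gene name; must occur exactly once.
#' @return The rotated (and possibly reflected) genome.
#' @export
rotate_to_gene <- function(g, gene = "cox1") {
  f <- gene_features(g)
  hit <- which(f$name == gene)
  if (length(hit) == 0L) stop(sprintf("gene '%s' not found", gene))
  if (length(hit) > 1L) stop(sprintf("gene '%s' occurs %d times", gene, length(hit)))
  feat <- f[hit, ]
  if (feat$strand == "-") {
    g <- reverse_complement_genome(g)
    f <- gene_features(g)
    feat <- f[f$name == gene, ]
  }
  rotate_genome(g, feat$start)
}
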