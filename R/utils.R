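# Internal helpers shared across modules.

#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper around [Biostrings::reverseComplement()].
#' Only A, C, G, T and N are accepted.
#'
#' @param x A single DNA string.
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  chartr("ACGTNacgtn", "TGCANtgcan", paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]),
                                           collapse = ""))
}

# modular position arithmetic on the circle (always in [0, L))
circ_mod <- function(x, L) ((x %% L) + L) %% L

# span length of a half-open interval [start, end) that may wrap the origin;
# end == start is taken to mean the whole circle
span_length <- function(start, end, L) {
  len <- circ_mod(end - start, L)
  ifelse(len == 0L, L, len)
}

# round half up at one decimal (paper-style reporting; R's round() is banker's)
round_half_up1 <- function(x) floor(x * 10 + 0.5) / 10

# match +1, mismatch -1; N is penalized against everything (including N)
# so masked stretches can never contribute to an alignment
.dna_submat <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      letters5 <- c("A", "C", "G", "T", "N")
      m <- matrix(-1, 5, 5, dimnames = list(letters5, letters5))
      diag(m) <- 1
      m["N", ] <- -2; m[, "N"] <- -2
      mat <<- m
    }
    mat
  }
})

#' Percent identity between two sequences
#'
#' Edit-distance identity: `100 * (1 - d / Lmax)` with `d` the unit-cost
#' (Levenshtein) edit distance and `Lmax` the longer sequence length. Every
#' substitution and every gap position counts as one alignment column, so
#' this equals matches / alignment-columns of the optimal unit-cost global
#' alignment whenever its gaps run in one direction — the strict convention
#' fast aligners report.
#'
#' @param a,b DNA strings.
#' @return Identity in percent (numeric scalar in \[0, 100\]).
#' @export
pair_identity <- function(a, b) {
  identities_to_center(a, b)
}

# vectorized identity of many sequences against one center, same convention
identities_to_center <- function(seqs, center) {
  seqs <- toupper(as.character(seqs)); center <- toupper(as.character(center))
  lmax <- pmax(nchar(seqs), nchar(center))
  d <- as.vector(utils::adist(seqs, center))
  ifelse(lmax == 0L, 0, 100 * (1 - d / lmax))
}

# Hamming identity of equal-length strings, in percent
hamming_identity <- function(a, b) {
  va <- strsplit(a, "", fixed = TRUE)[[1L]]
  vb <- strsplit(b, "", fixed = TRUE)[[1L]]
  stopifnot(length(va) == length(vb))
  100 * sum(va == vb) / length(va)
}

# positions of all k-mers (0-based starts), named by k-mer; returns list
# kmer -> integer vector of 0-based start positions
kmer_index <- function(seq, k) {
  n <- nchar(seq)
  if (k > n) return(list())
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  keep <- !grepl("N", kmers, fixed = TRUE)
  split(starts[keep] - 1L, kmers[keep])
}

# union-find for single-linkage clustering
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[ri] <- rj
  parent
}

# single-linkage components from an edge list over n nodes
components_from_edges <- function(n, edges) {
  parent <- uf_new(n)
  if (length(edges)) {
    for (e in edges) parent <- uf_union(parent, e[1L], e[2L])
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  match(roots, unique(roots))
}

# majority-vote consensus of sequences star-aligned to a center sequence.
# Insertions relative to the center are ignored; a center column whose
# majority vote is a gap is dropped. Ties break alphabetically (gap loses).
star_consensus <- function(seqs, center) {
  seqs <- toupper(as.character(seqs)); center <- toupper(as.character(center))
  if (length(seqs) == 1L) return(seqs)
  m <- nchar(center)
  votes <- matrix(0L, nrow = 5L, ncol = m,
                  dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  cv <- strsplit(center, "", fixed = TRUE)[[1L]]
  diff <- seqs != center
  if (any(diff)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(seqs[diff]), center, type = "global",
      substitutionMatrix = .dna_submat(), gapOpening = 2, gapExtension = 1)
    pats <- strsplit(as.character(Biostrings::alignedPattern(aln)), "", fixed = TRUE)
    subs <- strsplit(as.character(Biostrings::alignedSubject(aln)), "", fixed = TRUE)
  }
  j <- 0L
  for (i in seq_along(seqs)) {
    if (diff[i]) {
      j <- j + 1L
      v <- pats[[j]][subs[[j]] != "-"]
      if (length(v) < m) v <- c(v, rep("-", m - length(v)))
      v <- v[seq_len(m)]
    } else {
      v <- cv
    }
    ok <- v %in% rownames(votes)
    idx <- cbind(match(v[ok], rownames(votes)), which(ok))
    votes[idx] <- votes[idx] + 1L
  }
  cons <- rownames(votes)[apply(votes, 2L, which.max)]
  paste(cons[cons != "-"], collapse = "")
}

# random DNA with a given GC fraction (uses the current RNG stream)
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# merge intervals (0-based half-open, linear) closer than `gap`; returns matrix
merge_intervals <- function(starts, ends, gap = 0L) {
  if (length(starts) == 0L) return(cbind(start = integer(0), end = integer(0)))
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1L]; me <- ends[1L]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= me + gap) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
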