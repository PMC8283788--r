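# Shared fixtures: small genomes built in code, and the reference planted
# architecture used by the recovery tests (two strand-segregated gene
# blocks, two repeat regions over a four-unit alphabet of 13-204 bp with
# tandem runs, mixed composite motifs and palindromic spans).

make_genome <- function(seq, feats = NULL, id = "toy") {
  if (is.null(feats)) feats <- empty_features()
  circular_genome(id, seq, feats, mark_gaps = FALSE)
}

feat_row <- function(name, kind, start, end, strand = "+", anticodon = NA) {
  data.frame(name = name, kind = kind, start = start, end = end,
             strand = strand, anticodon = anticodon, stringsAsFactors = FALSE)
}

# deterministic random DNA helper for tests
rand_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# reference architecture for planted-recovery tests: unit lengths span the
# full 13-204 bp range and every unit occurs in more than one arrangement
# context, which is what makes the decomposition identifiable
recovery_spec <- function(seed, sub_rate = 0.02, indel_rate = 0.002) {
  architecture_spec(
    genome_length_target = 7000L,
    gene_blocks = list(
      list(id = "block1", strand = "+", genes = c("cox1", "cox2")),
      list(id = "block2", strand = "-", genes = c("cob", "atp6"))),
    unit_specs = data.frame(label = c("A", "B", "C", "D"),
                            length = c(204L, 60L, 34L, 13L), gc = 0.3,
                            stringsAsFactors = FALSE),
    region_grammars = list(
      repeat1 = list(token_motif(c("B", "C", "D", "A"), 4L),
                     token_motif(c("C", "D", "A"), 3L),
                     token_motif(c("B", "C", "A"), 3L),
                     token_palindrome(c("A", "D"))),
      repeat2 = list(token_tandem("B", 20L),
                     token_motif(c("B", "C"), 4L),
                     token_palindrome(c("B", "A")))),
    sub_rate = sub_rate, indel_rate = indel_rate, seed = seed)
}

# fraction of planted copies recovered with the right label, strand, and
# boundaries within +/- tol bp, plus palindromic-arrangement detection
score_recovery <- function(seed, tol = 3L) {
  sim <- generate_genome(recovery_spec(seed))
  rec <- recover_architecture(sim$genome)
  tokens <- do.call(rbind, lapply(rec$arrangements, function(a) a$tokens))
  truth <- sim$truth$copies
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(tokens$label == truth$label[i] &
          abs(tokens$start - truth$start[i]) <= tol &
          abs(tokens$end - truth$end[i]) <= tol &
          tokens$strand == truth$strand[i])
  }, logical(1))
  pals <- do.call(rbind, lapply(rec$arrangements, detect_palindromic_arrangement))
  list(n = nrow(truth), hits = sum(hit),
       n_palindromes = if (is.null(pals)) 0L else nrow(pals))
}

# brute-force check of palindromic token runs over all sub-runs
palindrome_oracle <- function(labels, strands) {
  m <- length(labels)
  found <- list()
  for (f in seq_len(m)) {
    for (l in seq_len(m)) {
      if (l <= f || (l - f + 1L) %% 2L != 0L) next
      idx <- f:l
      ok <- all(labels[idx] == rev(labels[idx])) &&
        all(strands[idx] != rev(strands[idx]))
      if (ok) found[[length(found) + 1L]] <- c(f, l)
    }
  }
  if (length(found) == 0L) return(matrix(integer(0), ncol = 2L))
  spans <- unique(do.call(rbind, found))
  contained <- vapply(seq_len(nrow(spans)), function(i) {
    any(spans[, 1L] <= spans[i, 1L] & spans[, 2L] >= spans[i, 2L] &
          (spans[, 1L] < spans[i, 1L] | spans[, 2L] > spans[i, 2L]))
  }, logical(1))
  spans[!contained, , drop = FALSE]
}

# do two tandem call sets describe the same arrays?  Arrays must overlap
# by at least half the smaller span, have equal periods or one dividing
# the other (within the drift one period allows), and agree on the span
# within one period at each end.
same_tandem_calls <- function(a, b) {
  match_one <- function(x, tab) {
    if (nrow(tab) == 0L) return(FALSE)
    for (j in seq_len(nrow(tab))) {
      ov <- min(x$end, tab$end[j]) - max(x$start, tab$start[j])
      if (ov < 0.5 * min(x$end - x$start, tab$end[j] - tab$start[j])) next
      pr <- max(x$period, tab$period[j]) / min(x$period, tab$period[j])
      if (abs(pr - round(pr)) * min(x$period, tab$period[j]) > 3) next
      if (abs(x$start - tab$start[j]) > max(x$period, tab$period[j]) + 3) next
      if (abs(x$end - tab$end[j]) > max(x$period, tab$period[j]) + 3) next
      return(TRUE)
    }
    FALSE
  }
  all(vapply(seq_len(nrow(a)), function(i) match_one(a[i, ], b), logical(1))) &&
    all(vapply(seq_len(nrow(b)), function(i) match_one(b[i, ], a), logical(1)))
}

# random signed circular gene order as a bare data frame
random_gene_order <- function(n, id = "g") {
  df <- data.frame(name = sprintf("g%02d", seq_len(n)),
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   stringsAsFactors = FALSE)
  attr(df, "id") <- id
  df
}

# apply an inversion of positions sel (contiguous) to a signed order
invert_segment <- function(df, sel) {
  seg <- df[sel, , drop = FALSE]
  seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
  seg$strand <- ifelse(seg$strand == "+", "-", "+")
  df[sel, ] <- seg
  df
}
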