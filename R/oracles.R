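# Brute-force reference implementations used to validate the fast paths.
# These scan every placement explicitly and are intended for short inputs;
# they share no code with the seeded/extended implementations they check.

#' Brute-force tandem array scan (reference implementation)
#'
#' For every (start, period) pair, extends the array copy-by-copy while
#' each length-`period` block matches the previous block at `min_match`
#' percent Hamming identity. Maximal arrays are reported; an array whose
#' period is a multiple of a near-coincident smaller-period array is
#' dropped, so the scan reports minimal periods like the production finder.
#' Quadratic; use on short sequences only.
#'
#' @inheritParams find_tandem_repeats
#' @return Data frame with `start`, `end` (0-based half-open, linear),
#'   `period`, `copy_count`.
#' @export
tandem_scan_oracle <- function(seq, min_period = 5L, max_period = 500L,
                               min_copies = 2L, min_match = 80) {
  s <- .as_seq(seq)
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(v)
  res <- list()
  d_hi <- min(max_period, floor(n / 2))
  if (min_period > d_hi) {
    return(data.frame(start = integer(0), end = integer(0),
                      period = integer(0), copy_count = numeric(0)))
  }
  for (d in min_period:d_hi) {
    M <- c(v[seq_len(n - d)] == v[(d + 1L):n])
    S <- c(0L, cumsum(M))
    blk_ok <- function(p) {  # block [p, p+d) matches block [p+d, p+2d), 0-based p
      100 * (S[p + d + 1L] - S[p + 1L]) / d >= min_match
    }
    for (s0 in 0:(n - 2L * d)) {
      if (!blk_ok(s0)) next
      if (s0 >= d && blk_ok(s0 - d)) next  # not a maximal start
      k <- 2L
      while (s0 + (k + 1L) * d <= n && blk_ok(s0 + (k - 1L) * d)) k <- k + 1L
      if (k >= min_copies) {
        res[[length(res) + 1L]] <- c(start = s0, end = s0 + k * d,
                                     period = d, k = k)
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      period = integer(0), copy_count = numeric(0)))
  }
  df <- as.data.frame(do.call(rbind, res))
  # phase-shifted variants of one array share the period and overlap;
  # merge them into their union (the fractional-copy view of the array)
  merged <- list()
  for (d in unique(df$period)) {
    sub <- df[df$period == d, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    cur <- sub[1L, ]
    for (i in seq_len(nrow(sub))[-1L]) {
      if (sub$start[i] < cur$end) {
        cur$end <- max(cur$end, sub$end[i])
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- sub[i, ]
      }
    }
    merged[[length(merged) + 1L]] <- cur
  }
  df <- do.call(rbind, merged)
  df$k <- (df$end - df$start) / df$period
  # minimal-period reduction among near-coincident arrays
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    for (j in seq_len(nrow(df))) {
      if (i == j || !keep[i]) next
      ov <- min(df$end[i], df$end[j]) - max(df$start[i], df$start[j])
      if (ov >= 0.8 * min(df$end[i] - df$start[i], df$end[j] - df$start[j]) &&
          df$period[i] %% df$period[j] == 0L && df$period[i] > df$period[j]) {
        keep[i] <- FALSE
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  data.frame(start = df$start, end = df$end, period = df$period,
             copy_count = round(df$k, 1))
}

#' Brute-force hairpin search (reference implementation)
#'
#' Enumerates every (arm start, arm length, loop length) placement, scoring
#' stems of contiguous Watson-Crick pairs with the same integer scheme as
#' [predict_hairpin()] (G.C = 3, A.T = 2, penalty `max(0, loop - 3)`), with
#' identical tie-breaking. Cubic; use on sequences of a few dozen bp.
#'
#' @inheritParams predict_hairpin
#' @return Same structure as [predict_hairpin()], or `NULL`.
#' @export
hairpin_oracle <- function(seq, min_stem = 3L, min_loop = 3L, max_loop = 50L) {
  s <- toupper(.as_seq(seq))
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(v)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (2L * min_stem + min_loop > n) return(NULL)
  best <- NULL
  for (a in 0:(n - 1L)) {
    for (l in min_stem:floor((n - min_loop) / 2)) {
      if (a + 2L * l + min_loop > n) break
      for (g0 in min_loop:min(max_loop, n - a - 2L * l)) {
        arm1 <- v[(a + 1L):(a + l)]
        arm2 <- v[(a + l + g0 + 1L):(a + l + g0 + l)]
        paired <- rev(arm2)
        ok <- !is.na(comp[arm1]) & comp[arm1] == paired
        if (!all(ok)) next
        score <- sum(ifelse(arm1 %in% c("G", "C"), 3L, 2L)) - max(0L, g0 - 3L)
        cand <- list(stem_pairs = l, loop_len = g0,
                     arm1 = c(a, a + l), arm2 = c(a + l + g0, a + l + g0 + l),
                     score = score)
        if (is.null(best) ||
            cand$score > best$score ||
            (cand$score == best$score && cand$loop_len < best$loop_len) ||
            (cand$score == best$score && cand$loop_len == best$loop_len &&
               cand$arm1[1L] < best$arm1[1L])) {
          best <- cand
        }
      }
    }
  }
  best
}
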