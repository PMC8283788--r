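# Stem-loop (hairpin) potential and GC-skew profiles.
#
# Hairpin scoring is a deliberately simple integer scheme rather than a
# thermodynamic nearest-neighbor model: stems admit Watson-Crick pairs only
# (G.C weight 3, A.T weight 2, no wobble, no bulges or internal loops) and
# the score is the sum of pair weights minus max(0, loop_len - 3). The
# formula is exact and fully testable; it ranks hairpin potential, it does
# not estimate free energy.

.pair_weight <- function(b1, b2) {
  ifelse((b1 == "G" & b2 == "C") | (b1 == "C" & b2 == "G"), 3L,
         ifelse((b1 == "A" & b2 == "T") | (b1 == "T" & b2 == "A"), 2L, 0L))
}

#' Best hairpin of a sequence under the integer pair-weight score
#'
#' Searches all inverted-repeat geometries whose stem consists solely of
#' contiguous Watson-Crick pairs. Ties break toward the smaller loop, then
#' the leftmost arm.
#'
#' @param seq DNA string (N never pairs).
#' @param min_stem Minimum number of stem pairs.
#' @param min_loop,max_loop Loop length bounds in bp (`min_loop >= 3`).
#' @return A list (`stem_pairs`, `loop_len`, `arm1`, `arm2` as 0-based
#'   half-open intervals, `score`) or `NULL` when no qualifying hairpin
#'   exists.
#' @export
predict_hairpin <- function(seq, min_stem = 3L, min_loop = 3L, max_loop = 50L) {
  if (min_loop < 3L) stop("min_loop must be >= 3")
  s <- toupper(.as_seq(seq))
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(v)
  if (2L * min_stem + min_loop > n) return(NULL)
  best <- NULL
  better <- function(cand, best) {
    if (is.null(best)) return(TRUE)
    if (cand$score != best$score) return(cand$score > best$score)
    if (cand$loop_len != best$loop_len) return(cand$loop_len < best$loop_len)
    cand$arm1[1L] < best$arm1[1L]
  }
  # pairs (i, j) on one anti-diagonal share c = i + j (0-based)
  c_hi <- 2L * (n - 1L) - min_loop - 1L
  if (c_hi < min_loop + 1L) return(NULL)
  for (c0 in (min_loop + 1L):c_hi) {
    i_lo <- max(0L, c0 - n + 1L)
    i_hi <- floor((c0 - 1L - min_loop) / 2)  # innermost i allowed by min_loop
    i_hi_geom <- floor((c0 - 1L) / 2)
    if (i_hi < i_lo) next
    ii <- i_lo:i_hi_geom
    w <- .pair_weight(v[ii + 1L], v[c0 - ii + 1L])
    runs <- rle(w > 0L)
    pos <- cumsum(c(0L, runs$lengths))
    for (r in seq_along(runs$values)) {
      if (!runs$values[r]) next
      r_lo <- ii[pos[r] + 1L]
      r_hi <- ii[pos[r + 1L]]
      k_max <- min(r_hi, i_hi)
      k_min_loop <- ceiling((c0 - 1L - max_loop) / 2)  # loop <= max_loop
      k_lo <- max(r_lo + min_stem - 1L, k_min_loop)
      if (k_max < k_lo) next
      cw <- cumsum(.pair_weight(v[(r_lo:k_max) + 1L], v[(c0 - (r_lo:k_max)) + 1L]))
      for (k in k_lo:k_max) {
        loop <- c0 - 2L * k - 1L
        score <- cw[k - r_lo + 1L] - max(0L, loop - 3L)
        cand <- list(stem_pairs = k - r_lo + 1L, loop_len = loop,
                     arm1 = c(r_lo, k + 1L), arm2 = c(c0 - k, c0 - r_lo + 1L),
                     score = score)
        if (better(cand, best)) best <- cand
      }
    }
  }
  best
}

#' Greedy scan for multiple non-overlapping hairpins
#'
#' Repeatedly reports the best hairpin and masks its whole span (arms and
#' loop) until none remains above `min_stem`.
#'
#' @inheritParams predict_hairpin
#' @return List of hairpins, best-first (possibly empty).
#' @export
double_hairpin_scan <- function(seq, min_stem = 3L, min_loop = 3L,
                                max_loop = 50L) {
  s <- toupper(.as_seq(seq))
  out <- list()
  repeat {
    h <- predict_hairpin(s, min_stem, min_loop, max_loop)
    if (is.null(h)) break
    out[[length(out) + 1L]] <- h
    span <- h$arm2[2L] - h$arm1[1L]
    substr(s, h$arm1[1L] + 1L, h$arm2[2L]) <- strrep("N", span)
  }
  out
}

#' GC-skew profile with cumulative-skew extrema
#'
#' Windowed skew (G - C) / (G + C) with wraparound windows (0 where a
#' window has no G or C), plus the cumulative per-base skew (+1 for G, -1
#' for C) whose global minimum and maximum mark candidate replication
#' origin/terminus switch points. Also reports the window of minimum G+C
#' fraction.
#'
#' @param g A [circular_genome()] or DNA string.
#' @param window Window size in bp.
#' @param step Step between window starts in bp.
#' @return An object of class `skew_profile`: list with `window`, `step`,
#'   `positions` (0-based window starts), `values`, `cumulative` (length
#'   L + 1, starts at 0), `max_pos`, `min_pos`, `min_gc_window`
#'   (`c(start, gc_fraction)`).
#' @export
gc_skew_profile <- function(g, window = 100L, step = 10L) {
  s <- .as_seq(g)
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  L <- length(v)
  if (window < 1L || step < 1L) stop("window and step must be >= 1")
  if (window > L) stop("window exceeds genome length")
  inc <- (v == "G") - (v == "C")
  cumulative <- c(0, cumsum(inc))

  gg <- c(0, cumsum(c(v, v) == "G"))
  cc <- c(0, cumsum(c(v, v) == "C"))
  pos <- seq(0L, L - 1L, by = step)
  gw <- gg[pos + window + 1L] - gg[pos + 1L]
  cw <- cc[pos + window + 1L] - cc[pos + 1L]
  denom <- gw + cw
  vals <- ifelse(denom == 0, 0, (gw - cw) / ifelse(denom == 0, 1, denom))

  gcfrac <- denom / window
  structure(list(window = window, step = step, positions = pos, values = vals,
                 cumulative = cumulative,
                 max_pos = which.max(cumulative) - 1L,
                 min_pos = which.min(cumulative) - 1L,
                 min_gc_window = c(start = pos[which.min(gcfrac)],
                                   gc_fraction = min(gcfrac))),
            class = "skew_profile")
}

#' @export
print.skew_profile <- function(x, ...) {
  cat(sprintf("<skew_profile> window %d step %d; cumulative extrema: max @%d, min @%d\n",
              x$window, x$step, x$max_pos, x$min_pos))
  invisible(x)
}
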