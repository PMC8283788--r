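# Discovery of tandem arrays, dispersed repeat families and inverted
# repeats by exact k-mer seeding followed by explicit, deterministic
# extension. All coordinates are 0-based half-open on the input sequence;
# for circular sequences discovery runs on a virtually doubled copy and
# results are deduplicated modulo the length.

.as_seq <- function(x) {
  if (inherits(x, "circular_genome")) x$sequence else toupper(as.character(x))
}

#' Self dot-plot match points
#'
#' Position pairs of the sequence against itself that share an exact k-mer,
#' on the forward strand (`"+"`) or between the sequence and its reverse
#' complement (`"-"`). The trivial main diagonal is excluded unless
#' requested.
#'
#' @param seq DNA string or [circular_genome()].
#' @param k K-mer length (>= 2; at least 5 is sensible for real genomes).
#' @param step Subsampling step for positions considered on both axes.
#' @param include_diagonal Include main-diagonal forward points.
#' @return Data frame with 0-based columns `x`, `y` and `strand`.
#' @export
self_dotplot <- function(seq, k = 12L, step = 1L, include_diagonal = FALSE) {
  s <- .as_seq(seq)
  n <- nchar(s)
  if (k > n) stop("k exceeds sequence length")
  if (k < 2L) stop("k must be >= 2")
  pos <- seq(0L, n - k, by = step)
  km <- substring(s, pos + 1L, pos + k)
  keep <- !grepl("N", km, fixed = TRUE)
  pos <- pos[keep]; km <- km[keep]
  idx <- split(pos, km)

  xs <- integer(0); ys <- integer(0)
  for (p in idx) {
    if (length(p) < 2L && !include_diagonal) next
    grid <- expand.grid(x = p, y = p)
    if (!include_diagonal) grid <- grid[grid$x != grid$y, , drop = FALSE]
    xs <- c(xs, grid$x); ys <- c(ys, grid$y)
  }
  fwd <- data.frame(x = xs, y = ys,
                    strand = rep("+", length(xs)), stringsAsFactors = FALSE)

  r <- revcomp(s)
  posr <- seq(0L, n - k, by = step)
  kmr <- substring(r, posr + 1L, posr + k)
  keep <- !grepl("N", kmr, fixed = TRUE)
  posr <- posr[keep]; kmr <- kmr[keep]
  idxr <- split(posr, kmr)
  shared <- intersect(names(idx), names(idxr))
  xs <- integer(0); ys <- integer(0)
  for (km1 in shared) {
    pf <- idx[[km1]]
    pr <- n - idxr[[km1]] - k  # map back to forward coordinates
    grid <- expand.grid(x = pf, y = pr)
    xs <- c(xs, grid$x); ys <- c(ys, grid$y)
  }
  rev <- data.frame(x = xs, y = ys,
                    strand = rep("-", length(xs)), stringsAsFactors = FALSE)
  out <- rbind(fwd, rev)
  out[order(out$x, out$y), , drop = FALSE]
}

# --- tandem arrays -----------------------------------------------------

# step through `wv` (character vector of the sequence) with period-length
# frames, re-anchoring each frame within +/- slack to tolerate indel
# drift. A copy is accepted when its own identity reaches `floor_pid` and
# the running array-wide identity stays at or above `min_match`; this lets
# boundary copies dip below min_match individually (the way tandem-repeat
# finders count a degenerate final copy) without absorbing junk.
.ratchet <- function(wv, cons, from, min_match, floor_pid = NULL,
                     slack = 2L, backward = FALSE,
                     cum_m = 0L, cum_c = 0L) {
  d <- length(cons)
  n <- length(wv)
  floor_pid <- floor_pid %||% max(2 * min_match - 100, 50)
  starts <- integer(0); matches <- integer(0)
  p <- from
  repeat {
    best_o <- NA_integer_; best_m <- -1L
    for (o in -slack:slack) {
      s0 <- p + o
      if (s0 < 0L || s0 + d > n) next
      m <- sum(wv[(s0 + 1L):(s0 + d)] == cons)
      if (m > best_m) { best_m <- m; best_o <- o }
    }
    if (is.na(best_o)) break
    ok <- 100 * best_m / d >= min_match
    if (!ok && 100 * best_m / d >= floor_pid &&
        100 * (cum_m + best_m) / (cum_c + d) >= min_match) {
      # a genuinely degenerate copy is degenerate across its whole frame;
      # a frame half-overlapping unrelated flank matches on one side only
      s0 <- p + best_o
      half <- d %/% 2L
      m1 <- sum(wv[(s0 + 1L):(s0 + half)] == cons[seq_len(half)])
      m2 <- best_m - m1
      ok <- 100 * m1 / half >= 45 && 100 * m2 / (d - half) >= 45
    }
    if (!ok && 100 * best_m / d >= floor_pid) {
      # look one period ahead: a single degenerate interior copy should
      # not split the array when the array clearly resumes after it
      p2 <- if (backward) p + best_o - d else p + best_o + d
      m2 <- -1L
      for (o in -slack:slack) {
        s2 <- p2 + o
        if (s2 < 0L || s2 + d > n) next
        m2 <- max(m2, sum(wv[(s2 + 1L):(s2 + d)] == cons))
      }
      if (100 * m2 / d >= min_match) ok <- TRUE
    }
    if (!ok) break
    s0 <- p + best_o
    starts <- c(starts, s0); matches <- c(matches, best_m)
    cum_m <- cum_m + best_m; cum_c <- cum_c + d
    p <- if (backward) s0 - d else s0 + d
  }
  list(starts = starts, matches = matches)
}

.majority_consensus <- function(wv, starts, d) {
  mat <- vapply(starts, function(s0) wv[(s0 + 1L):(s0 + d)], character(d))
  if (d == 1L) mat <- matrix(mat, nrow = 1L)
  apply(mat, 1L, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    top <- names(tb)[tb == tb[1L]]
    sort(top)[1L]  # alphabetical tie-break
  })
}

# fractional extension of the array boundary into a partial copy
.partial_tail <- function(wv, cons, end0, min_match) {
  d <- length(cons); n <- length(wv)
  best <- 0L
  for (t in seq_len(min(d - 1L, n - end0))) {
    m <- sum(wv[(end0 + 1L):(end0 + t)] == cons[seq_len(t)])
    if (100 * m / t >= min_match) best <- t
  }
  best
}

.partial_head <- function(wv, cons, start0, min_match) {
  d <- length(cons)
  best <- 0L
  for (t in seq_len(min(d - 1L, start0))) {
    m <- sum(wv[(start0 - t + 1L):start0] == cons[(d - t + 1L):d])
    if (100 * m / t >= min_match) best <- t
  }
  best
}

#' Find tandem repeat arrays
#'
#' K-mer seeding proposes candidate periods from the spacing of identical
#' k-mers; each supported (region, period) candidate is refined by building
#' a column-majority consensus over period-length frames and extending the
#' array copy-by-copy (with a small re-anchoring slack so per-copy indels do
#' not derail the frame) while per-copy identity to the consensus stays at
#' or above `min_match`. Overlapping arrays whose periods are multiples are
#' reported at the smallest period that meets `min_match`; remaining
#' overlaps resolve to the highest-scoring array (ties: leftmost start,
#' then smallest period).
#'
#' @param seq DNA string or [circular_genome()].
#' @param min_period,max_period Period bounds in bp.
#' @param min_copies Minimum copy count (>= 2).
#' @param min_match Minimum per-copy percent identity to the consensus.
#' @param circular Treat the sequence as circular (arrays may span the
#'   origin; reported with wrap-encoded coordinates).
#' @param k Seed k-mer length.
#' @return Data frame with columns `start`, `end` (0-based half-open;
#'   `end <= start` encodes origin wrap), `period`, `copy_count`,
#'   `consensus`, `match_percent`.
#' @export
find_tandem_repeats <- function(seq, min_period = 5L, max_period = 500L,
                                min_copies = 2L, min_match = 80,
                                circular = inherits(seq, "circular_genome") && seq$is_circular,
                                k = 7L) {
  s <- .as_seq(seq)
  n <- nchar(s)
  if (min_copies < 2L) stop("min_copies must be >= 2")
  w <- if (circular && n > 1L) paste0(s, s) else s
  wv <- strsplit(w, "", fixed = TRUE)[[1L]]
  nw <- length(wv)
  k_eff <- max(2L, min(k, n - min_period))
  if (k_eff > nchar(w)) return(.empty_tandem())

  idx <- kmer_index(w, k_eff)
  cand <- list()
  for (p in idx) {
    m <- length(p)
    if (m < 2L) next
    # spacings at several lags, so that strings periodic at a divisor of
    # the true period (homopolymers, micro-repeats) still propose it
    for (lag in seq_len(min(8L, m - 1L))) {
      d <- p[-seq_len(lag)] - p[seq_len(m - lag)]
      ok <- d >= min_period & d <= max_period
      if (any(ok)) {
        cand[[length(cand) + 1L]] <- cbind(pos = p[seq_len(m - lag)][ok], d = d[ok])
      }
    }
  }
  if (length(cand) == 0L) return(.empty_tandem())
  cand <- do.call(rbind, cand)

  refine_one <- function(anchor, d) {
      if (anchor + d > nw) return(NULL)
      template <- wv[(anchor + 1L):(anchor + d)]
      st1 <- .ratchet(wv, template, anchor, min_match)$starts
      if (length(st1) < 2L) return(NULL)
      cons <- .majority_consensus(wv, st1, d)
      fw <- .ratchet(wv, cons, st1[1L], min_match)
      bw <- .ratchet(wv, cons, st1[1L] - d, min_match, backward = TRUE,
                     cum_m = sum(fw$matches), cum_c = length(fw$matches) * d)
      starts <- c(rev(bw$starts), fw$starts)
      if (length(starts) < min_copies) return(NULL)
      cons <- .majority_consensus(wv, starts, d)
      floor_pid <- max(2 * min_match - 100, 50)
      idm <- vapply(starts, function(s0)
        sum(wv[(s0 + 1L):(s0 + d)] == cons), integer(1))
      pid <- 100 * idm / d
      # trim: ends below the per-copy floor, then worse end while the
      # array-wide identity is still under min_match
      repeat {
        len <- length(starts)
        if (len == 0L) break
        if (pid[1L] < floor_pid) {
          starts <- starts[-1L]; idm <- idm[-1L]; pid <- pid[-1L]
        } else if (pid[len] < floor_pid) {
          starts <- starts[-len]; idm <- idm[-len]; pid <- pid[-len]
        } else if (100 * sum(idm) / (len * d) < min_match) {
          if (pid[1L] <= pid[len]) {
            starts <- starts[-1L]; idm <- idm[-1L]; pid <- pid[-1L]
          } else {
            starts <- starts[-len]; idm <- idm[-len]; pid <- pid[-len]
          }
        } else break
      }
      if (length(starts) < min_copies) return(NULL)
      a_start <- starts[1L]
      a_end <- starts[length(starts)] + d
      t_head <- .partial_head(wv, cons, a_start, min_match)
      a_start <- a_start - t_head
      a_end <- a_end + .partial_tail(wv, cons, a_end, min_match)
      span <- a_end - a_start
      if (t_head > 0L) {
        # phase-anchor the consensus at the array's start edge, which is a
        # true copy boundary: a copy beginning there reads the consensus
        # suffix followed by its prefix
        cons <- c(cons[(d - t_head + 1L):d], cons[seq_len(d - t_head)])
      }
      if (circular) span <- min(span, n)
      list(start = a_start, end = a_end, span = span, period = d,
           consensus = paste(cons, collapse = ""),
           match_percent = round_half_up1(100 * sum(idm) / (length(idm) * d)),
           score = span * sum(idm) / (length(idm) * d))
  }

  arrays <- list()
  for (d in sort(unique(cand[, "d"]))) {
    pos <- sort(unique(cand[cand[, "d"] == d, "pos"]))
    grp <- cumsum(c(TRUE, diff(pos) > 2L * d + k_eff))
    for (g in split(pos, grp)) {
      # one support cluster can host several distinct arrays; re-anchor
      # past each refined array until the support is exhausted
      remaining <- g
      guard <- 0L
      while (length(remaining) && guard < 8L) {
        guard <- guard + 1L
        a <- refine_one(remaining[1L], d)
        if (is.null(a)) {
          remaining <- remaining[-1L]
          next
        }
        arrays[[length(arrays) + 1L]] <- a
        remaining <- remaining[remaining >= a$end - k_eff + 1L]
      }
    }
  }
  if (length(arrays) == 0L) return(.empty_tandem())

  # canonicalize circular coordinates and deduplicate modulo length
  if (circular) {
    for (i in seq_along(arrays)) arrays[[i]]$start <- circ_mod(arrays[[i]]$start, n)
  }
  key <- vapply(arrays, function(a) sprintf("%d:%d:%d", a$start, a$span, a$period), character(1))
  arrays <- arrays[!duplicated(key)]

  # selection: smallest period among near-coincident multiples, then greedy
  ord <- order(vapply(arrays, function(a) -a$score, numeric(1)),
               vapply(arrays, function(a) a$start, numeric(1)),
               vapply(arrays, function(a) a$period, numeric(1)))
  arrays <- arrays[ord]
  accepted <- list()
  for (a in arrays) {
    sub <- FALSE
    for (j in seq_along(accepted)) {
      b <- accepted[[j]]
      ov <- .circ_overlap(a$start, a$span, b$start, b$span, n)
      if (ov >= 0.8 * min(a$span, b$span)) {
        # coincident arrays: keep the smaller period if the larger one is
        # (nearly) a multiple of it -- indel drift makes multiples inexact
        mult <- b$period / a$period
        near_multiple <- mult >= 1.5 &&
          abs(mult - round(mult)) * a$period <= 0.05 * b$period + 2
        if (a$period < b$period && near_multiple &&
            a$match_percent >= min_match && a$span >= 0.75 * b$span) {
          accepted[[j]] <- a
        }
        sub <- TRUE
        break
      }
      if (ov >= 0.5 * min(a$span, b$span)) { sub <- TRUE; break }
    }
    if (!sub) accepted[[length(accepted) + 1L]] <- a
  }

  # same-period arrays that still overlap are phase-shifted views of one
  # array (the phase can drift mid-array); merge them into their union
  merged_any <- TRUE
  while (merged_any && length(accepted) > 1L) {
    merged_any <- FALSE
    for (i in seq_along(accepted)) {
      for (j in seq_along(accepted)) {
        if (j <= i) next
        a <- accepted[[i]]; b <- accepted[[j]]
        if (a$period != b$period) next
        if (.circ_overlap(a$start, a$span, b$start, b$span, n) <= 0L) next
        lo <- min(a$start, b$start)
        hi <- max(a$start + a$span, b$start + b$span)
        a$start <- lo
        a$span <- if (circular) min(hi - lo, n) else hi - lo
        a$match_percent <- max(a$match_percent, b$match_percent)
        a$score <- a$span * a$match_percent / 100
        accepted[[i]] <- a
        accepted[[j]] <- NULL
        merged_any <- TRUE
        break
      }
      if (merged_any) break
    }
  }

  out <- do.call(rbind, lapply(accepted, function(a) {
    end <- a$start + a$span
    if (circular && end > n) end <- end - n
    data.frame(start = a$start, end = end, period = a$period,
               copy_count = round(a$span / a$period, 1),
               consensus = a$consensus, match_percent = a$match_percent,
               stringsAsFactors = FALSE)
  }))
  out <- out[out$copy_count >= min_copies, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

.empty_tandem <- function() {
  data.frame(start = integer(0), end = integer(0), period = integer(0),
             copy_count = numeric(0), consensus = character(0),
             match_percent = numeric(0), stringsAsFactors = FALSE)
}

# overlap in bp of two (possibly circular) spans
.circ_overlap <- function(s1, w1, s2, w2, L) {
  # compare on the doubled line, taking the best of the two phases
  ov <- function(a1, b1, a2, b2) max(0L, min(b1, b2) - max(a1, a2))
  max(ov(s1, s1 + w1, s2, s2 + w2),
      ov(s1 + L, s1 + L + w1, s2, s2 + w2),
      ov(s1, s1 + w1, s2 + L, s2 + L + w2))
}

# --- dispersed and inverted repeats ------------------------------------

# merge co-diagonal seed pairs into matched segment pairs
.diag_segments <- function(pairs, k, merge_gap) {
  if (nrow(pairs) == 0L) {
    return(data.frame(i1 = integer(0), i2 = integer(0),
                      j1 = integer(0), j2 = integer(0)))
  }
  out <- list()
  for (dg in unique(pairs$diag)) {
    pp <- pairs[pairs$diag == dg, , drop = FALSE]
    pp <- pp[order(pp$i), , drop = FALSE]
    grp <- cumsum(c(TRUE, diff(pp$i) > k + merge_gap))
    for (g in split(seq_len(nrow(pp)), grp)) {
      ii <- pp$i[g]; jj <- pp$j[g]
      out[[length(out) + 1L]] <- data.frame(
        i1 = min(ii), i2 = max(ii) + k, j1 = min(jj), j2 = max(jj) + k)
    }
  }
  do.call(rbind, out)
}

# local-alignment refinement of one candidate segment pair; seqs given as
# plain characters (b already reverse-complemented for inverted matches).
# Gap costs are kept stiff so alignments do not wander into unrelated
# flanking sequence.
.refine_pair <- function(sa, sb) {
  aln <- Biostrings::pairwiseAlignment(sa, sb, type = "local",
                                       substitutionMatrix = .dna_submat(),
                                       gapOpening = 4, gapExtension = 2)
  pr <- Biostrings::pattern(aln)
  sr <- Biostrings::subject(aln)
  a1 <- Biostrings::start(pr) - 1L; a2 <- Biostrings::end(pr)
  b1 <- Biostrings::start(sr) - 1L; b2 <- Biostrings::end(sr)
  cols <- max(a2 - a1, b2 - b1)
  list(a_start = a1, a_end = a2, b_start = b1, b_end = b2,
       identity = pair_identity(substr(sa, a1 + 1L, a2),
                                substr(sb, b1 + 1L, b2)),
       cols = cols)
}

# shared seed machinery: returns forward and reverse matched segment pairs
.match_segments <- function(s, k, max_occ, merge_gap) {
  n <- nchar(s)
  idx <- kmer_index(s, k)
  fw <- list()
  for (p in idx) {
    m <- length(p)
    if (m < 2L || m > max_occ) next
    grid <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    fw[[length(fw) + 1L]] <- data.frame(i = p[grid[, 1L]], j = p[grid[, 2L]])
  }
  fw <- if (length(fw)) do.call(rbind, fw) else data.frame(i = integer(0), j = integer(0))
  if (nrow(fw)) fw$diag <- fw$j - fw$i

  r <- revcomp(s)
  idxr <- kmer_index(r, k)
  shared <- intersect(names(idx), names(idxr))
  rv <- list()
  for (km in shared) {
    pf <- idx[[km]]; pr <- idxr[[km]]
    if (length(pf) > max_occ || length(pr) > max_occ) next
    grid <- expand.grid(i = pf, j = n - pr - k)
    grid <- grid[grid$i < grid$j, , drop = FALSE]  # canonical arm order
    if (nrow(grid)) rv[[length(rv) + 1L]] <- grid
  }
  rv <- if (length(rv)) do.call(rbind, rv) else data.frame(i = integer(0), j = integer(0))
  if (nrow(rv)) rv$diag <- rv$i + rv$j  # anti-diagonal is constant
  # for inverted matches, merging must track decreasing j as i increases
  seg_f <- .diag_segments(fw, k, merge_gap)
  seg_r <- .diag_segments(rv, k, merge_gap)
  list(forward = seg_f, reverse = seg_r)
}

#' Find dispersed repeat families
#'
#' Exact k-mer seeds (forward and reverse-complement) are chained along
#' diagonals into candidate matched segments, each refined to a maximal
#' local alignment; matched copies are grouped into families by
#' single-linkage through the match graph (every edge has identity at or
#' above `min_identity`). Highly abundant k-mers (above `max_occ`
#' occurrences) are skipped, as dense tandem arrays are the province of
#' [find_tandem_repeats()].
#'
#' @param seq DNA string or [circular_genome()].
#' @param min_len Minimum aligned match length in bp (>= 13, the smallest
#'   repeat-unit scale considered).
#' @param min_identity Minimum percent identity of a match and of family
#'   membership.
#' @param k Seed length; defaults to `min(13, min_len)`.
#' @param max_occ Seed occurrence cap.
#' @param merge_gap Maximum seed gap chained along one diagonal.
#' @param segs Precomputed result of the internal seed-chaining step
#'   (callers that already ran it can avoid repeating the work).
#' @param compute_consensus When `FALSE`, skip the star-consensus and
#'   per-copy identity computation (the family consensus is then the
#'   longest copy and copy identities are `NA`); useful when only copy
#'   coordinates are needed.
#' @return List of families, longest-first; each family is a list with
#'   `family` (name), `consensus`, and `copies` (data frame `start`, `end`,
#'   `strand`, `identity`).
#' @export
find_dispersed_repeats <- function(seq, min_len = 50L, min_identity = 70,
                                   k = NULL, max_occ = 60L, merge_gap = 10L,
                                   segs = NULL, compute_consensus = TRUE) {
  s <- .as_seq(seq)
  if (min_len < 13L) stop("min_len must be >= 13")
  k <- k %||% min(13L, min_len)
  if (is.null(segs)) segs <- .match_segments(s, k, max_occ, merge_gap)
  margin <- 15L
  n <- nchar(s)

  sall <- rbind(segs$forward, segs$reverse)
  if (nrow(sall) == 0L) return(list())
  strand2 <- rep(c("+", "-"), c(nrow(segs$forward), nrow(segs$reverse)))

  # refine every candidate segment pair in one batched local alignment
  a_lo <- pmax(0L, sall$i1 - margin); a_hi <- pmin(n, sall$i2 + margin)
  b_lo <- pmax(0L, sall$j1 - margin); b_hi <- pmin(n, sall$j2 + margin)
  sa <- substring(s, a_lo + 1L, a_hi)
  sb <- substring(s, b_lo + 1L, b_hi)
  rc <- strand2 == "-"
  sb[rc] <- vapply(sb[rc], revcomp, character(1), USE.NAMES = FALSE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(sa),
                                       Biostrings::DNAStringSet(sb),
                                       type = "local",
                                       substitutionMatrix = .dna_submat(),
                                       gapOpening = 4, gapExtension = 2)
  pa1 <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  pa2 <- Biostrings::end(Biostrings::pattern(aln))
  sb1 <- Biostrings::start(Biostrings::subject(aln)) - 1L
  sb2 <- Biostrings::end(Biostrings::subject(aln))
  a_start <- a_lo + pa1; a_end <- a_lo + pa2
  len_b <- b_hi - b_lo
  b_start <- ifelse(rc, b_lo + len_b - sb2, b_lo + sb1)
  b_end <- ifelse(rc, b_lo + len_b - sb1, b_lo + sb2)
  cols <- pmax(a_end - a_start, b_end - b_start)
  ident <- vapply(seq_along(sa), function(i)
    pair_identity(substr(sa[i], pa1[i] + 1L, pa2[i]),
                  substr(sb[i], sb1[i] + 1L, sb2[i])), numeric(1))
  keep <- which(cols >= min_len & ident >= min_identity)
  if (length(keep) == 0L) return(list())
  hits <- lapply(keep, function(i)
    list(a = c(a_start[i], a_end[i]), b = c(b_start[i], b_end[i]),
         strand = strand2[i], identity = ident[i]))

  # copy nodes: merge intervals that overlap reciprocally >= 50%
  iv <- do.call(rbind, lapply(hits, function(h) rbind(h$a, h$b)))
  nodes <- .merge_copy_nodes(iv)
  node_of <- function(interval) {
    mid <- (interval[1L] + interval[2L]) / 2
    which(nodes[, 1L] <= mid & nodes[, 2L] > mid)[1L]
  }
  edges <- lapply(hits, function(h) {
    e <- c(node_of(h$a), node_of(h$b))
    attr(e, "strand") <- h$strand
    e
  })
  comp <- components_from_edges(nrow(nodes), edges)

  # strand propagation within each component
  strand <- rep(NA_character_, nrow(nodes))
  for (e in edges) {
    if (is.na(strand[e[1L]]) && is.na(strand[e[2L]])) strand[e[1L]] <- "+"
    if (!is.na(strand[e[1L]]) && is.na(strand[e[2L]])) {
      strand[e[2L]] <- if (attr(e, "strand") == "+") strand[e[1L]] else
        setdiff(c("+", "-"), strand[e[1L]])
    } else if (is.na(strand[e[1L]]) && !is.na(strand[e[2L]])) {
      strand[e[1L]] <- if (attr(e, "strand") == "+") strand[e[2L]] else
        setdiff(c("+", "-"), strand[e[2L]])
    }
  }
  strand[is.na(strand)] <- "+"

  fams <- list()
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    if (length(members) < 2L) next
    cp <- data.frame(start = nodes[members, 1L], end = nodes[members, 2L],
                     strand = strand[members], stringsAsFactors = FALSE)
    cp <- cp[order(cp$start), , drop = FALSE]
    seqs <- vapply(seq_len(nrow(cp)), function(i)
      if (cp$strand[i] == "+") substr(s, cp$start[i] + 1L, cp$end[i])
      else revcomp(substr(s, cp$start[i] + 1L, cp$end[i])), character(1))
    center <- seqs[which.max(nchar(seqs))]
    if (compute_consensus) {
      cons <- star_consensus(seqs, center)
      cp$identity <- round_half_up1(identities_to_center(seqs, cons))
    } else {
      cons <- center
      cp$identity <- NA_real_
    }
    fams[[length(fams) + 1L]] <- list(consensus = cons, copies = cp,
                                      max_len = max(cp$end - cp$start))
  }
  if (length(fams) == 0L) return(list())
  fams <- fams[order(-vapply(fams, function(f) f$max_len, numeric(1)))]
  for (i in seq_along(fams)) {
    fams[[i]]$family <- sprintf("fam%d", i)
    fams[[i]]$max_len <- NULL
  }
  fams
}

.merge_copy_nodes <- function(iv) {
  o <- order(iv[, 1L], iv[, 2L])
  iv <- iv[o, , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1L]) {
    last <- out[nrow(out), ]
    ov <- min(last[2L], iv[i, 2L]) - max(last[1L], iv[i, 1L])
    w <- min(last[2L] - last[1L], iv[i, 2L] - iv[i, 1L])
    if (ov >= 0.5 * w) {
      out[nrow(out), ] <- c(min(last[1L], iv[i, 1L]), max(last[2L], iv[i, 2L]))
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

#' Find inverted repeats (potential stem-loops and region palindromes)
#'
#' Seeds between the sequence and its reverse complement are chained along
#' anti-diagonals into candidate arm pairs, refined by local alignment, and
#' filtered on arm length, arm identity and loop length. Overlapping
#' reports resolve to the longest arm.
#'
#' @param seq DNA string or [circular_genome()].
#' @param min_arm Minimum arm length in bp (also the seed length).
#' @param max_loop Maximum separation between arms (`Inf` for region-scale
#'   palindromes).
#' @param min_identity Minimum percent identity between arm 1 and the
#'   reverse complement of arm 2.
#' @return Data frame with columns `arm1_start`, `arm1_end`, `arm2_start`,
#'   `arm2_end`, `loop_len`, `arm_len`, `arm_identity`.
#' @export
find_inverted_repeats <- function(seq, min_arm = 5L, max_loop = 50L,
                                  min_identity = 80) {
  s <- .as_seq(seq)
  n <- nchar(s)
  if (min_arm < 2L) stop("min_arm must be >= 2")
  segs <- .match_segments(s, k = min_arm, max_occ = 200L, merge_gap = 10L)$reverse
  if (nrow(segs) == 0L) return(.empty_ir())
  margin <- 15L
  out <- list()
  for (i in seq_len(nrow(segs))) {
    i1 <- segs$i1[i]; i2 <- segs$i2[i]; j1 <- segs$j1[i]; j2 <- segs$j2[i]
    # arm1 = [i1, i2), arm2 = [j1, j2) with arm2 the reverse complement
    a_lo <- max(0L, i1 - margin); a_hi <- min(n, i2 + margin)
    b_lo <- max(0L, j1 - margin); b_hi <- min(n, j2 + margin)
    if (b_lo < a_hi) {  # windows meet: clamp at the palindrome centre
      centre <- (i2 + j1) %/% 2L
      a_hi <- min(a_hi, centre); b_lo <- max(b_lo, centre)
      if (a_hi - a_lo < min_arm || b_hi - b_lo < min_arm) next
    }
    sa <- substr(s, a_lo + 1L, a_hi)
    sb <- revcomp(substr(s, b_lo + 1L, b_hi))
    r <- .refine_pair(sa, sb)
    if (r$identity < min_identity || r$cols < min_arm) next
    arm1 <- c(a_lo + r$a_start, a_lo + r$a_end)
    len_b <- b_hi - b_lo
    arm2 <- c(b_lo + len_b - r$b_end, b_lo + len_b - r$b_start)
    if (arm2[1L] < arm1[1L]) { tmp <- arm1; arm1 <- arm2; arm2 <- tmp }
    loop <- arm2[1L] - arm1[2L]
    if (loop < 0L || loop > max_loop) next
    out[[length(out) + 1L]] <- data.frame(
      arm1_start = arm1[1L], arm1_end = arm1[2L],
      arm2_start = arm2[1L], arm2_end = arm2[2L],
      loop_len = loop, arm_len = arm1[2L] - arm1[1L],
      arm_identity = round_half_up1(r$identity), stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(.empty_ir())
  res <- do.call(rbind, out)
  res <- res[order(-res$arm_len, res$arm1_start), , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(res))) {
      if (j <= i || !keep[j]) next
      ov1 <- min(res$arm1_end[i], res$arm1_end[j]) - max(res$arm1_start[i], res$arm1_start[j])
      ov2 <- min(res$arm2_end[i], res$arm2_end[j]) - max(res$arm2_start[i], res$arm2_start[j])
      if (ov1 > 0L && ov2 > 0L) keep[j] <- FALSE
    }
  }
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

.empty_ir <- function() {
  data.frame(arm1_start = integer(0), arm1_end = integer(0),
             arm2_start = integer(0), arm2_end = integer(0),
             loop_len = integer(0), arm_len = integer(0),
             arm_identity = numeric(0), stringsAsFactors = FALSE)
}
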