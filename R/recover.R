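# End-to-end recovery of a repeat architecture from bare sequence.
#
# The decomposition problem is to express the repeat regions as tilings
# over a minimal alphabet of units. Discovery produces candidate repeated
# sequences at mixed granularity: tandem-array consensuses (whose periods
# may be single units like B, or whole composite motifs like B-D-E-A) and
# dispersed/inverted family copies (palindrome arms, scattered blocks).
# Candidates are then "atomized" shortest-first: a candidate that current
# atoms can tile is a composite arrangement and is dropped, while its
# uncovered remainder runs re-enter the queue as new candidates. A unit is
# identifiable exactly when it occurs in more than one arrangement
# context; a boundary that never varies carries no signal and no method
# can split it.

#' Recover repeat units and arrangements from a genome
#'
#' Runs tandem-array discovery and dispersed/inverted self-matching,
#' derives repeat regions from the merged match coverage, atomizes the
#' discovered candidate sequences into a minimal unit alphabet, and tiles
#' every region into a labelled arrangement (two passes: unit consensuses
#' are rebuilt by column majority over the first-pass copies). Unit labels
#' are A, B, C, ... by descending consensus length.
#'
#' @param g A [circular_genome()] or DNA string.
#' @param min_unit_len Smallest unit length considered, bp.
#' @param cluster_identity Percent identity for dispersed-family grouping.
#' @param tile_identity Minimum token identity when tiling regions.
#' @param min_region_len Minimum repeat-region length reported, bp.
#' @param tandem_min_match Per-copy identity floor for tandem arrays.
#' @param max_period Largest tandem period considered, bp.
#' @param atomize_identity Identity used when tiling candidates with atoms
#'   during decomposition (consensus-vs-consensus comparisons, hence
#'   stricter than `tile_identity`).
#' @return A list with `units` (label, consensus, copies from the final
#'   tiling), `arrangements` (one per region), `regions` (data frame), and
#'   `tandem_arrays` (raw [find_tandem_repeats()] table).
#' @export
recover_architecture <- function(g, min_unit_len = 13L, cluster_identity = 70,
                                 tile_identity = 70, min_region_len = 100L,
                                 tandem_min_match = 80, max_period = 350L,
                                 atomize_identity = 85) {
  if (!inherits(g, "circular_genome")) g <- circular_genome("seq", .as_seq(g))
  s <- g$sequence

  tan <- find_tandem_repeats(s, min_period = max(5L, min_unit_len - 3L),
                             max_period = max_period, min_copies = 3L,
                             min_match = tandem_min_match, circular = FALSE)
  segs <- .match_segments(s, k = min(13L, min_unit_len), max_occ = 40L,
                          merge_gap = 10L)
  seg_iv <- rbind(
    if (nrow(segs$forward)) cbind(c(segs$forward$i1, segs$forward$j1),
                                  c(segs$forward$i2, segs$forward$j2)),
    if (nrow(segs$reverse)) cbind(c(segs$reverse$i1, segs$reverse$j1),
                                  c(segs$reverse$i2, segs$reverse$j2)))
  seg_iv <- seg_iv[seg_iv[, 2L] - seg_iv[, 1L] >= max(20L, min_unit_len), ,
                   drop = FALSE]

  cov_s <- c(tan$start, seg_iv[, 1L])
  cov_e <- c(tan$end, seg_iv[, 2L])
  empty <- list(units = list(), arrangements = list(),
                regions = data.frame(start = integer(0), end = integer(0)),
                tandem_arrays = tan)
  if (length(cov_s) == 0L) return(empty)
  reg <- merge_intervals(cov_s, cov_e, gap = 50L)
  reg <- reg[reg[, 2L] - reg[, 1L] >= min_region_len, , drop = FALSE]
  regions <- data.frame(start = reg[, "start"], end = reg[, "end"])
  if (nrow(regions) == 0L) return(empty)

  peaks <- .endpoint_peaks(segs, tan, regions)

  # candidate unit sequences: tandem-array consensuses plus the longest
  # non-redundant self-match segments (palindrome arms, dispersed blocks)
  fams <- find_dispersed_repeats(s, min_len = max(20L, min_unit_len),
                                 min_identity = cluster_identity,
                                 max_occ = 40L, segs = segs,
                                 compute_consensus = FALSE)
  seg_cands <- vapply(fams, function(f) {
    i <- which.max(f$copies$end - f$copies$start)
    subsequence(g, f$copies$start[i], f$copies$end[i], f$copies$strand[i])
  }, character(1))

  # a tandem consensus has an arbitrary cyclic phase; boundary peaks
  # inside and at the edges of the array vote for the copy-boundary phase
  tan_rp <- vapply(seq_len(nrow(tan)), function(i)
    .rephase_consensus(tan$consensus[i], tan$start[i], tan$end[i],
                       tan$period[i], peaks), character(1))
  tan_cons <- tan_rp[nchar(tan_rp) >= min_unit_len]
  atz <- .atomize_candidates(tan_cons, min_unit_len, atomize_identity,
                             split_set = tan_cons, raw = seg_cands)
  if (length(atz$atoms) == 0L) return(c(empty["units"], empty["arrangements"],
                                        list(regions = regions, tandem_arrays = tan)))

  units0 <- lapply(seq_along(atz$atoms), function(i)
    list(label = sprintf("u%d", i), consensus = atz$atoms[[i]]))
  arr0 <- lapply(seq_len(nrow(regions)), function(i)
    tile_arrangement(g, regions$start[i], regions$end[i], units0, tile_identity))

  # re-fuse over-fragmented units: tokens that are (essentially) always
  # immediately adjacent in the same order are one unit, not two
  merged <- .merge_adjacent_units(g, regions, units0, arr0, tile_identity)
  units0 <- merged$units
  arr0 <- merged$arrangements

  # phase-correct tandem runs: a cyclically rotated consensus still tiles
  # the interior of a uniform array perfectly, but it leaves tell-tale
  # uncovered gaps at the run's two ends that sum to one period; shifting
  # the whole run onto its left edge restores the true copy boundaries
  arr0 <- lapply(arr0, .rephase_token_runs, L = g$length)

  # rebuild each unit's consensus by column majority over its copies,
  # snapping copy boundaries to genome-wide match-endpoint peaks first:
  # exact-seed chains between differently-arranged copies break exactly at
  # unit boundaries, so endpoint pile-ups mark the true boundary positions
  tokens0 <- do.call(rbind, lapply(arr0, function(a) a$tokens))
  units1 <- list()
  for (u in units0) {
    tk <- tokens0[tokens0$label == u$label, , drop = FALSE]
    if (nrow(tk) < 2L) next  # singletons are not repeat units
    if (nrow(tk) > 40L) tk <- tk[order(-tk$identity), ][seq_len(40L), ]
    st <- .consistent_snap(tk$start, .snap_to_peaks(tk$start, peaks,
                                                    prefer = "higher"))
    en <- .consistent_snap(tk$end, .snap_to_peaks(tk$end, peaks,
                                                  prefer = "lower"))
    if (stats::median(en - st) < 8) { st <- tk$start; en <- tk$end }
    seqs <- vapply(seq_len(nrow(tk)), function(i)
      subsequence(g, st[i], en[i], tk$strand[i]), character(1))
    center <- seqs[which.max(nchar(seqs))]
    units1[[length(units1) + 1L]] <- list(consensus = star_consensus(seqs, center))
  }
  if (length(units1) == 0L) return(c(empty["units"], empty["arrangements"],
                                     list(regions = regions, tandem_arrays = tan)))
  # dedupe rebuilt consensuses that converged to (nearly) the same unit
  dedup <- list()
  for (u in units1) {
    dup <- any(vapply(dedup, function(v)
      pair_identity(v$consensus, u$consensus) >= 90 ||
        pair_identity(v$consensus, revcomp(u$consensus)) >= 90, logical(1)))
    if (!dup) dedup[[length(dedup) + 1L]] <- u
  }
  units1 <- dedup
  for (i in seq_along(units1)) units1[[i]]$label <- sprintf("u%d", i)

  arrangements <- lapply(seq_len(nrow(regions)), function(i)
    tile_arrangement(g, regions$start[i], regions$end[i], units1, tile_identity))

  # units are labelled A, B, C, ... by descending consensus length, but
  # only after the final tiling: units without at least two tiled copies
  # are discarded (and their tokens removed) before labels are assigned
  tokens_all <- do.call(rbind, lapply(arrangements, function(a) a$tokens))
  counts <- table(tokens_all$label)
  # a real unit has at least two copies that match its consensus closely;
  # clusters whose typical copy is far from the consensus are artifacts
  # (and, worse, shift the length-ordered labels of every smaller unit)
  med_id <- vapply(units1, function(u) {
    ids <- tokens_all$identity[tokens_all$label == u$label]
    if (length(ids)) stats::median(ids) else 0
  }, numeric(1))
  keep <- vapply(units1, function(u)
    !is.na(counts[u$label]) && counts[u$label] >= 2L, logical(1)) &
    med_id >= 85
  units1 <- units1[keep]
  if (length(units1) == 0L) return(c(empty["units"], empty["arrangements"],
                                     list(regions = regions, tandem_arrays = tan)))
  ord <- order(-vapply(units1, function(u) nchar(u$consensus), integer(1)),
               vapply(units1, function(u) u$consensus, character(1)))
  units1 <- units1[ord]
  map <- stats::setNames(
    vapply(seq_along(units1), function(i)
      if (i <= 26L) LETTERS[i] else sprintf("U%d", i), character(1)),
    vapply(units1, function(u) u$label, character(1)))
  for (i in seq_along(units1)) units1[[i]]$label <- map[[units1[[i]]$label]]
  arrangements <- lapply(arrangements, function(a) {
    tk <- a$tokens[a$tokens$label %in% names(map), , drop = FALSE]
    tk$label <- unname(map[tk$label])
    rownames(tk) <- NULL
    a$tokens <- tk
    a$cover_fraction <- sum(tk$local_end - tk$local_start) / a$region_length
    a$motif_string <- paste(tk$label, collapse = "-")
    a
  })
  units <- .units_from_tokens(units1, arrangements, g)
  list(units = units, arrangements = arrangements, regions = regions,
       tandem_arrays = tan)
}

# shortest-first decomposition of candidate repeated sequences into atoms.
# Processing order matters: when a new shorter candidate turns out to be
# contained in an already-accepted atom, that atom was a composite
# accepted too early -- it is demoted back into the queue and will tile
# once the contained piece has become an atom.
.atomize_candidates <- function(cands, min_unit_len, ident,
                                split_set = cands, raw = character(0)) {
  min_keep <- max(8L, min_unit_len - 3L)
  base <- unique(toupper(cands))
  base <- base[nchar(base) >= min_keep]
  # indel-splitting only over consensus-quality candidates: pieces cut from
  # divergent raw copies tend to be chimeric
  pieces <- setdiff(.indel_split_pieces(unique(toupper(split_set)), min_keep), base)
  pieces <- pieces[nchar(pieces) >= min_keep]
  # raw genome copies (ragged chain boundaries) are second-class: they are
  # only considered once the consensus-quality candidates have established
  # the atom set, so chain debris cannot become a foundation atom
  raw <- setdiff(unique(toupper(raw)), c(base, pieces))
  raw <- raw[nchar(raw) >= min_keep]
  queue <- c(base, pieces, raw)
  cls <- rep(c(1L, 1L, 2L), c(length(base), length(pieces), length(raw)))
  pc <- rep(c(FALSE, TRUE, FALSE), c(length(base), length(pieces), length(raw)))
  atoms <- character(0)
  atom_pc <- logical(0)
  guard <- 0L
  while (length(queue) && guard < 400L) {
    guard <- guard + 1L
    i <- order(cls, nchar(queue))[1L]
    x <- queue[i]; x_cls <- cls[i]; x_pc <- pc[i]
    queue <- queue[-i]; cls <- cls[-i]; pc <- pc[-i]
    if (any(vapply(atoms, function(a)
      pair_identity(a, x) >= ident || pair_identity(a, revcomp(x)) >= ident,
      logical(1)))) next
    # cyclic phase-shifts of an existing atom are the same unit. Pieces
    # cut out of composite arrangements carry the true copy-boundary
    # phase, so a piece displaces a non-piece atom (a tandem consensus
    # whose edge-anchored phase may be off); otherwise first atom wins.
    rot <- which(vapply(atoms, function(a) {
      r <- nchar(x) / nchar(a)
      r >= 0.8 && r <= 1.25 && .contained_in(x, paste0(a, a), ident)
    }, logical(1)))
    if (length(rot)) {
      j <- rot[1L]
      if (x_pc && !atom_pc[j]) {
        atoms[j] <- x
        atom_pc[j] <- TRUE
      }
      next
    }
    contained <- vapply(atoms, function(a)
      nchar(x) < nchar(a) && .contained_in(x, a, ident), logical(1))
    if (any(contained)) {
      if (x_cls > 1L) next  # a raw partial copy of an existing atom
      # a consensus-quality piece contained in an atom means that atom
      # was a composite accepted too early: demote it for re-tiling
      queue <- c(queue, atoms[contained])
      cls <- c(cls, rep(1L, sum(contained)))
      pc <- c(pc, atom_pc[contained])
      atoms <- atoms[!contained]
      atom_pc <- atom_pc[!contained]
    }
    if (length(atoms) == 0L) { atoms <- x; atom_pc <- x_pc; next }
    gg <- circular_genome("cand", x, is_circular = FALSE, mark_gaps = FALSE)
    units <- lapply(seq_along(atoms), function(k)
      list(label = sprintf("u%d", k), consensus = atoms[[k]]))
    a <- tile_arrangement(gg, 0L, nchar(x), units, ident)
    if (nrow(a$tokens) == 0L) {
      atoms <- c(atoms, x)
      atom_pc <- c(atom_pc, x_pc)
      next
    }
    # uncovered remainder runs become new, smaller candidates
    covered <- merge_intervals(a$tokens$local_start, a$tokens$local_end)
    bounds <- c(0L, as.vector(t(covered)), nchar(x))
    run_s <- bounds[seq(1L, length(bounds), by = 2L)]
    run_e <- bounds[seq(2L, length(bounds), by = 2L)]
    keep <- run_e - run_s >= min_keep
    if (any(keep)) {
      queue <- c(queue, substring(x, run_s[keep] + 1L, run_e[keep]))
      cls <- c(cls, rep(x_cls, sum(keep)))
      pc <- c(pc, rep(x_pc || x_cls == 1L, sum(keep)))
    }
  }
  list(atoms = atoms, pieces = pieces)
}

# positions where exact-seed chain endpoints pile up (support >= 3 within
# +/- 2 bp), plus tandem-array edges and region bounds
.endpoint_peaks <- function(segs, tan, regions) {
  ep <- c(segs$forward$i1, segs$forward$i2, segs$forward$j1, segs$forward$j2,
          segs$reverse$i1, segs$reverse$i2, segs$reverse$j1, segs$reverse$j2,
          tan$start, tan$end, regions$start, regions$end)
  if (length(ep) == 0L) return(data.frame(pos = integer(0), n = integer(0)))
  ep <- sort(ep)
  grp <- cumsum(c(TRUE, diff(ep) > 2L))
  counts <- tabulate(grp)
  pos <- vapply(split(ep, grp), function(x)
    as.integer(round(stats::median(x))), integer(1))
  keep <- counts >= 3L
  out <- data.frame(pos = pos[keep], n = counts[keep])
  out[order(out$pos), , drop = FALSE]
}

# shift maximal abutting same-label token runs onto their left uncovered
# edge when the flanking gaps betray a phase error (they sum to roughly
# one token period)
.rephase_token_runs <- function(a, L) {
  tk <- a$tokens
  n <- nrow(tk)
  if (n == 0L) return(a)
  run_id <- cumsum(c(TRUE, !(tk$label[-1L] == tk$label[-n] &
                               tk$strand[-1L] == tk$strand[-n] &
                               tk$local_start[-1L] - tk$local_end[-n] <= 1L)))
  for (r in unique(run_id)) {
    idx <- which(run_id == r)
    if (length(idx) < 4L) next
    period <- stats::median(tk$local_end[idx] - tk$local_start[idx])
    prev_end <- if (idx[1L] > 1L) tk$local_end[idx[1L] - 1L] else 0L
    next_start <- if (idx[length(idx)] < n) tk$local_start[idx[length(idx)] + 1L]
    else a$region_length
    left_gap <- tk$local_start[idx[1L]] - prev_end
    right_gap <- next_start - tk$local_end[idx[length(idx)]]
    if (left_gap >= 2L && right_gap >= 0L &&
        abs(left_gap + right_gap - period) <= 6L) {
      tk$local_start[idx] <- tk$local_start[idx] - left_gap
      tk$local_end[idx] <- tk$local_end[idx] - left_gap
    }
  }
  tk$start <- circ_mod(a$region_start + tk$local_start, L)
  e <- circ_mod(a$region_start + tk$local_end, L)
  tk$end <- ifelse(e == 0L, L, e)
  a$tokens <- tk
  a
}

# rotate a tandem consensus so copies start at the phase that boundary
# peaks in and around the array support most strongly; weak or ambiguous
# support leaves the edge-anchored phase alone
.rephase_consensus <- function(cons, a_start, a_end, d, peaks) {
  inside <- peaks$pos >= a_start - 2L & peaks$pos <= a_end + 2L
  if (!any(inside)) return(cons)
  off <- (peaks$pos[inside] - a_start) %% d
  w <- peaks$n[inside]
  score <- vapply(0:(d - 1L), function(o) {
    dd <- pmin(abs(off - o), d - abs(off - o))
    sum(w[dd <= 2])
  }, numeric(1))
  o <- which.max(score) - 1L
  if (o == 0L || min(o, d - o) <= 3L) return(cons)
  paste0(substr(cons, o + 1L, d), substr(cons, 1L, o))
}

# a boundary correction is real when the copies agree on it: accept the
# snapped positions only when a modal shift is shared by at least half the
# tokens, and impute that shift for outliers
.consistent_snap <- function(orig, snapped) {
  d <- snapped - orig
  med <- as.integer(round(stats::median(d)))
  if (mean(abs(d - med) <= 3) < 0.5) return(orig)
  ifelse(abs(d - med) <= 3L, snapped, orig + med)
}

# snap each position to the best-supported peak within +/- max_shift
# (support beats proximity: mutation-offset endpoint clusters create weak
# satellite peaks a few bp from the true boundary). When the two strongest
# candidates have comparable support and lie on opposite sides, prefer the
# one inside the token (`prefer` = "higher" for starts, "lower" for ends):
# a boundary error that absorbed part of a neighbour is corrected by
# shrinking, whereas growing would swallow the neighbour whole.
.snap_to_peaks <- function(pos, peaks, max_shift = 12L,
                           prefer = c("none", "higher", "lower")) {
  prefer <- match.arg(prefer)
  if (nrow(peaks) == 0L) return(pos)
  vapply(pos, function(p) {
    cand <- which(abs(peaks$pos - p) <= max_shift)
    if (length(cand) == 0L) return(as.numeric(p))
    o <- cand[order(-peaks$n[cand], abs(peaks$pos[cand] - p))]
    best <- o[1L]
    if (length(o) >= 2L && prefer != "none") {
      n1 <- peaks$n[o[1L]]; n2 <- peaks$n[o[2L]]
      if (n2 >= 0.7 * n1 &&
          sign(peaks$pos[o[1L]] - p) != sign(peaks$pos[o[2L]] - p)) {
        pick_higher <- prefer == "higher"
        two <- c(o[1L], o[2L])
        best <- two[which((peaks$pos[two] > p) == pick_higher)][1L]
        if (is.na(best)) best <- o[1L]
      }
    }
    as.numeric(peaks$pos[best])
  }, numeric(1))
}

# Arrangement variation shows up as large indel blocks in the global
# alignment of two composite candidates (B-D-E-A vs B-D-A differ by an
# E-sized gap). Splitting both sequences at the boundaries of such blocks
# releases the elementary pieces, which then win the shortest-first
# atomization. Pieces are only taken from pairs whose aligned (non-gap)
# columns agree well, so the gaps are structural rather than noise.
.indel_split_pieces <- function(cands, min_keep, max_cands = 12L) {
  cc <- unique(cands)
  cc <- cc[order(nchar(cc))]
  if (length(cc) > max_cands) cc <- cc[seq_len(max_cands)]
  pieces <- character(0)
  for (i in seq_along(cc)) {
    for (j in seq_along(cc)) {
      if (j <= i) next
      a <- cc[i]; b <- cc[j]
      if (nchar(a) < 2L * min_keep || nchar(a) < 0.2 * nchar(b)) next
      # tandem consensuses carry arbitrary cyclic phases; rotate the
      # shorter one to its best embedding in the longer so the global
      # alignment is end-to-end and its gaps are structural
      pre <- Biostrings::pairwiseAlignment(paste0(a, a), b, type = "local",
                                           substitutionMatrix = .dna_submat(),
                                           gapOpening = 4, gapExtension = 2)
      off <- (Biostrings::start(Biostrings::pattern(pre)) - 1L) %% nchar(a)
      if (off > 0L) {
        a <- paste0(substr(a, off + 1L, nchar(a)), substr(a, 1L, off))
      }
      aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                           substitutionMatrix = .dna_submat(),
                                           gapOpening = 5, gapExtension = 0.5)
      pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "", fixed = TRUE)[[1L]]
      su <- strsplit(as.character(Biostrings::alignedSubject(aln)), "", fixed = TRUE)[[1L]]
      nong <- pa != "-" & su != "-"
      # only split cleanly aligned pairs in which the shorter candidate
      # embeds (almost) completely: a pair caught at incompatible cyclic
      # phases matches on a partial arc only and would shed chimeric
      # pieces cut at arbitrary positions
      if (sum(nong) < max(min_keep, 0.75 * nchar(a))) next
      if (sum(pa[nong] == su[nong]) / sum(nong) < 0.9) next
      runs <- rle(pa == "-" | su == "-")
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      long <- which(runs$values & runs$lengths >= min_keep)
      if (length(long) == 0L) next
      cutcols <- sort(unique(c(starts[long] - 1L, ends[long])))
      cutcols <- cutcols[cutcols > 0L]
      apos <- cumsum(pa != "-"); bpos <- cumsum(su != "-")
      cut_seq <- function(seqchr, cuts) {
        cuts <- sort(unique(c(0L, cuts, nchar(seqchr))))
        st <- cuts[-length(cuts)]; en <- cuts[-1L]
        keep <- en - st >= min_keep & (en - st) < nchar(seqchr)
        if (!any(keep)) return(character(0))
        substring(seqchr, st[keep] + 1L, en[keep])
      }
      pieces <- c(pieces, cut_seq(a, apos[cutcols]), cut_seq(b, bpos[cutcols]))
    }
  }
  unique(pieces)
}

# Iteratively merge unit pairs (X, Y) whose tokens co-occur as immediate
# neighbours in fixed order: every X is followed by Y and every Y preceded
# by X (mirrored on the minus strand), up to a small boundary allowance.
# Such pairs carry no arrangement variation and are a single unit by the
# identifiability principle; this also repairs units shattered by chimeric
# candidate pieces.
.merge_adjacent_units <- function(g, regions, units, arrangements,
                                  tile_identity, max_gap = 3L,
                                  support = 0.9, max_iter = 8L) {
  for (it in seq_len(max_iter)) {
    tok <- list()
    for (a in arrangements) {
      tk <- a$tokens
      n <- nrow(tk)
      if (n == 0L) next
      gaps <- if (n > 1L) tk$local_start[-1L] - tk$local_end[-n] else numeric(0)
      tok[[length(tok) + 1L]] <- data.frame(
        label = tk$label, strand = tk$strand,
        nl = c(tk$label[-1L], NA), ns = c(tk$strand[-1L], NA),
        ng = c(gaps, NA),
        pl = c(NA, tk$label[-n]), ps = c(NA, tk$strand[-n]),
        pg = c(NA, gaps), stringsAsFactors = FALSE)
    }
    if (length(tok) == 0L) break
    tok <- do.call(rbind, tok)
    labs <- unique(tok$label)
    if (length(labs) < 2L) break
    best <- NULL
    for (X in labs) {
      for (Y in labs) {
        if (X == Y) next
        tx <- tok[tok$label == X, , drop = FALSE]
        ty <- tok[tok$label == Y, , drop = FALSE]
        if (nrow(tx) < 2L || nrow(ty) < 2L) next
        ok_x <- ifelse(tx$strand == "+",
                       !is.na(tx$nl) & tx$nl == Y & tx$ns == "+" & tx$ng <= max_gap,
                       !is.na(tx$pl) & tx$pl == Y & tx$ps == "-" & tx$pg <= max_gap)
        ok_y <- ifelse(ty$strand == "+",
                       !is.na(ty$pl) & ty$pl == X & ty$ps == "+" & ty$pg <= max_gap,
                       !is.na(ty$nl) & ty$nl == X & ty$ns == "-" & ty$ng <= max_gap)
        sup <- min(mean(ok_x), mean(ok_y))
        if (sup >= support && (is.null(best) || sup > best$sup)) {
          best <- list(X = X, Y = Y, sup = sup)
        }
      }
    }
    if (is.null(best)) break
    cons_x <- NULL; cons_y <- NULL
    keep <- list()
    for (u in units) {
      if (u$label == best$X) cons_x <- u$consensus
      else if (u$label == best$Y) cons_y <- u$consensus
      else keep[[length(keep) + 1L]] <- u
    }
    keep[[length(keep) + 1L]] <- list(label = sprintf("m%d", it),
                                      consensus = paste0(cons_x, cons_y))
    units <- keep
    arrangements <- lapply(seq_len(nrow(regions)), function(i)
      tile_arrangement(g, regions$start[i], regions$end[i], units,
                       tile_identity))
  }
  list(units = units, arrangements = arrangements)
}

# does x (either strand) align locally into `a` over >= 90% of its length
# at roughly `ident` percent identity?
.contained_in <- function(x, a, ident) {
  for (xx in c(x, revcomp(x))) {
    aln <- Biostrings::pairwiseAlignment(xx, a, type = "local",
                                         substitutionMatrix = .dna_submat(),
                                         gapOpening = 4, gapExtension = 2)
    pr <- Biostrings::pattern(aln)
    span <- Biostrings::end(pr) - Biostrings::start(pr) + 1L
    if (span >= 0.9 * nchar(xx) &&
        Biostrings::score(aln) >= span * (2 * ident / 100 - 1) * 0.9) {
      return(TRUE)
    }
  }
  FALSE
}

# final per-unit statistics from the tiled tokens (the tokens are the
# boundary-refined copies)
.units_from_tokens <- function(units, arrangements, g) {
  tokens <- do.call(rbind, lapply(arrangements, function(a) a$tokens))
  out <- list()
  for (u in units) {
    tk <- tokens[tokens$label == u$label, , drop = FALSE]
    if (nrow(tk) == 0L) next
    cp <- data.frame(start = tk$start, end = tk$end, strand = tk$strand,
                     length = tk$local_end - tk$local_start,
                     identity = tk$identity, stringsAsFactors = FALSE)
    rownames(cp) <- NULL
    out[[length(out) + 1L]] <- list(
      label = u$label, consensus = u$consensus, copies = cp,
      length_range = range(cp$length), identity_range = range(cp$identity))
  }
  out
}
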