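# Clustering repeat copies into named units, tiling repeat regions into
# unit arrangements, and detecting palindromic arrangements of units.

# vectorized identity of a sequence set against one subject
.batch_identity <- function(seqset, seqs_chr, subject) {
  identities_to_center(seqs_chr, subject)
}

# normalize the accepted input shapes (list of families, data frame of
# copies, or bare sequences) to one copies data frame with sequences
.as_copies <- function(x, genome = NULL) {
  if (is.data.frame(x)) {
    cp <- x
    if (is.null(cp$strand)) cp$strand <- "+"
    if (is.null(cp$seq)) {
      stopifnot(!is.null(genome))
      cp$seq <- vapply(seq_len(nrow(cp)), function(i)
        subsequence(genome, cp$start[i], cp$end[i], cp$strand[i]), character(1))
    }
    return(cp)
  }
  if (is.character(x)) {
    return(data.frame(start = NA_integer_, end = NA_integer_, strand = "+",
                      seq = toupper(x), stringsAsFactors = FALSE))
  }
  if (is.list(x)) {  # families from find_dispersed_repeats
    do.call(rbind, lapply(x, function(f) {
      cp <- f$copies
      if (is.null(cp$seq)) {
        stopifnot(!is.null(genome))
        cp$seq <- vapply(seq_len(nrow(cp)), function(i)
          subsequence(genome, cp$start[i], cp$end[i], cp$strand[i]), character(1))
      }
      cp[, c("start", "end", "strand", "seq")]
    }))
  } else stop("unsupported copies input")
}

#' Cluster repeat copies into named units
#'
#' Single-linkage clustering of copies at pairwise identity at or above
#' `identity_threshold`; the per-cluster consensus is the column majority of
#' a star alignment centred on the longest member. Unit labels are assigned
#' A, B, C, ... by descending consensus length, the package's deterministic
#' labelling convention.
#'
#' @param copies A data frame of copies (`start`, `end`, `strand`, and
#'   either `seq` or a `genome` to extract from), a list of families from
#'   [find_dispersed_repeats()], or a character vector of sequences.
#' @param identity_threshold Percent identity for single linkage.
#' @param genome Optional [circular_genome()] used to extract copy
#'   sequences when they are not supplied.
#' @param both_strands When `TRUE`, copies may join a cluster in either
#'   orientation (linkage identity is the better of the forward and
#'   reverse-complement alignments) and copy strands are reported relative
#'   to the consensus, normalized so the majority of copies are `"+"`.
#' @return A list of units; each unit is a list with `label`, `consensus`,
#'   `copies` (data frame with `identity` vs the consensus), `length_range`
#'   and `identity_range`.
#' @export
cluster_into_units <- function(copies, identity_threshold = 70, genome = NULL,
                               both_strands = FALSE) {
  cp <- .as_copies(copies, genome)
  n <- nrow(cp)
  if (n == 0L) stop("need at least one copy")
  lens <- nchar(cp$seq)
  parent <- uf_new(n)
  if (n > 1L) {
    seqset <- Biostrings::DNAStringSet(cp$seq)
    for (i in seq_len(n - 1L)) {
      rest <- (i + 1L):n
      # length prefilter: identity cannot exceed 100 * shorter/longer
      cand <- rest[100 * pmin(lens[rest], lens[i]) /
                     pmax(lens[rest], lens[i]) >= identity_threshold]
      cand <- cand[vapply(cand, function(j)
        uf_find(parent, i) != uf_find(parent, j), logical(1))]
      if (length(cand) == 0L) next
      ident <- .batch_identity(seqset[cand], cp$seq[cand], cp$seq[i])
      if (both_strands) {
        ident <- pmax(ident, .batch_identity(seqset[cand], cp$seq[cand],
                                             revcomp(cp$seq[i])))
      }
      for (j in cand[ident >= identity_threshold]) {
        parent <- uf_union(parent, i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  comp <- match(roots, unique(roots))

  units <- lapply(unique(comp), function(cid) {
    idx <- which(comp == cid)
    seqs <- cp$seq[idx]
    strands <- cp$strand[idx]
    center <- seqs[which.max(nchar(seqs))]
    if (both_strands && length(idx) > 1L) {
      fwd <- identities_to_center(seqs, center)
      rev_ <- identities_to_center(vapply(seqs, revcomp, character(1),
                                          USE.NAMES = FALSE), center)
      flip <- rev_ > fwd
      seqs[flip] <- vapply(seqs[flip], revcomp, character(1), USE.NAMES = FALSE)
      strands[flip] <- ifelse(strands[flip] == "+", "-", "+")
    }
    cons <- star_consensus(seqs, center)
    if (both_strands && sum(strands == "-") > sum(strands == "+")) {
      cons <- revcomp(cons)
      seqs <- vapply(seqs, revcomp, character(1), USE.NAMES = FALSE)
      strands <- ifelse(strands == "+", "-", "+")
    }
    ident <- round_half_up1(identities_to_center(seqs, cons))
    u_cp <- cp[idx, c("start", "end"), drop = FALSE]
    u_cp$strand <- strands
    u_cp$length <- nchar(seqs)
    u_cp$identity <- ident
    rownames(u_cp) <- NULL
    list(consensus = cons, copies = u_cp,
         length_range = range(u_cp$length),
         identity_range = range(ident))
  })
  ord <- order(-vapply(units, function(u) nchar(u$consensus), integer(1)),
               vapply(units, function(u) u$consensus, character(1)))
  units <- units[ord]
  for (i in seq_along(units)) {
    units[[i]]$label <- if (i <= 26L) LETTERS[i] else sprintf("U%d", i)
  }
  units
}

#' Tabulate repeat units
#'
#' One row per unit: label, copy count, copy length range, consensus
#' (matrix) length, and identity range against the consensus, formatted the
#' way repeat-unit tables are printed in organelle-genome papers.
#'
#' @param units List of units from [cluster_into_units()].
#' @return A data frame with columns `unit`, `copies`, `length_range`,
#'   `matrix_length`, `identity_range`.
#' @export
unit_table <- function(units) {
  if (length(units) == 0L) {
    return(data.frame(unit = character(0), copies = integer(0),
                      length_range = character(0), matrix_length = integer(0),
                      identity_range = character(0), stringsAsFactors = FALSE))
  }
  fmt_range <- function(r, suffix) {
    if (r[1L] == r[2L]) paste0(r[1L], suffix)
    else paste0(r[1L], "-", r[2L], suffix)
  }
  do.call(rbind, lapply(units, function(u) {
    lr <- u$length_range %||% range(u$copies$length)
    ir <- u$identity_range %||% range(u$copies$identity)
    data.frame(unit = u$label, copies = nrow(u$copies),
               length_range = fmt_range(lr, " bp"),
               matrix_length = nchar(u$consensus),
               identity_range = fmt_range(sprintf("%.1f", ir), "%"),
               stringsAsFactors = FALSE)
  }))
}

#' Tile a repeat region with unit consensus matches
#'
#' Finds all matches of every unit consensus (both strands) within the
#' region at or above `min_identity`, then selects the maximal-scoring set
#' of non-overlapping tokens by weighted interval scheduling (score =
#' matched columns x identity). The motif string joins unit labels in
#' coordinate order.
#'
#' @param genome A [circular_genome()].
#' @param region_start,region_end Region interval (0-based half-open;
#'   `end <= start` wraps through the origin).
#' @param units List of units (see [cluster_into_units()]).
#' @param min_identity Minimum token identity in percent.
#' @param overlap_slack Adjacent tokens may overlap by up to this many bp;
#'   consensus lengths are only estimates, so hard non-overlap would drop a
#'   true abutting copy over a 1-bp conflict.
#' @return An object of class `arrangement`: list with `region_start`,
#'   `region_end`, `tokens` (data frame `label`, `strand`, `start`, `end`,
#'   `local_start`, `local_end`, `identity`), `cover_fraction`,
#'   `motif_string`.
#' @export
tile_arrangement <- function(genome, region_start, region_end, units,
                             min_identity = 70, overlap_slack = 3L) {
  stopifnot(length(units) >= 1L)
  L <- genome$length
  if (region_start < 0 || region_start >= L) stop("region outside genome")
  rseq <- subsequence(genome, region_start, region_end, "+")
  rlen <- nchar(rseq)
  subj <- Biostrings::DNAString(rseq)

  tok <- list()
  for (u in units) {
    cons <- u$consensus
    clen <- nchar(cons)
    if (clen > rlen) next
    # the match search allows floor(len * (1 - min_identity/100)) edits,
    # capped at 35: for very long units this bounds the search effort, so
    # copies of a >230 bp unit are only guaranteed to be found down to
    # ~85% identity (far below the divergence of real unit copies)
    edits <- min(35L, max(0L, floor(clen * (1 - min_identity / 100))))
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") cons else revcomp(cons)
      m <- suppressWarnings(
        Biostrings::matchPattern(pat, subj, max.mismatch = edits,
                                 with.indels = TRUE))
      if (length(m) == 0L) next
      st <- Biostrings::start(m) - 1L
      en <- Biostrings::end(m)
      hseq <- as.character(m)
      if (strand == "-") hseq <- vapply(hseq, revcomp, character(1), USE.NAMES = FALSE)
      ident <- identities_to_center(hseq, cons)
      keep <- ident >= min_identity
      if (!any(keep)) next
      tok[[length(tok) + 1L]] <- data.frame(
        label = u$label, strand = strand, local_start = st[keep],
        local_end = en[keep], identity = round_half_up1(ident[keep]),
        score = (ident[keep] / 100) * ident[keep] / 100 * clen,
        stringsAsFactors = FALSE)
    }
  }
  tokens <- if (length(tok)) do.call(rbind, tok) else
    data.frame(label = character(0), strand = character(0),
               local_start = integer(0), local_end = integer(0),
               identity = numeric(0), score = numeric(0))

  if (nrow(tokens)) {
    # weighted interval scheduling on [local_start, local_end)
    tokens <- tokens[order(tokens$local_end, tokens$local_start), , drop = FALSE]
    m <- nrow(tokens)
    p <- findInterval(tokens$local_start + overlap_slack, tokens$local_end)
    opt <- numeric(m + 1L)
    take <- logical(m)
    for (i in seq_len(m)) {
      with_i <- tokens$score[i] + opt[p[i] + 1L]
      opt[i + 1L] <- max(opt[i], with_i)
    }
    sel <- integer(0)
    i <- m
    while (i >= 1L) {
      if (tokens$score[i] + opt[p[i] + 1L] >= opt[i]) {
        sel <- c(i, sel); i <- p[i]
      } else i <- i - 1L
    }
    tokens <- tokens[sel, , drop = FALSE]
    tokens <- tokens[order(tokens$local_start), , drop = FALSE]
  }
  tokens$score <- NULL
  tokens$start <- circ_mod(region_start + tokens$local_start, L)
  e <- circ_mod(region_start + tokens$local_end, L)
  tokens$end <- ifelse(e == 0L, L, e)
  rownames(tokens) <- NULL

  structure(list(region_start = region_start, region_end = region_end,
                 region_length = rlen, tokens = tokens,
                 cover_fraction = sum(tokens$local_end - tokens$local_start) / rlen,
                 motif_string = paste(tokens$label, collapse = "-")),
            class = "arrangement")
}

#' @export
print.arrangement <- function(x, ...) {
  cat(sprintf("<arrangement> [%d,%d) %d bp, %d tokens, cover %.2f\n",
              x$region_start, x$region_end, x$region_length,
              nrow(x$tokens), x$cover_fraction))
  if (nrow(x$tokens)) cat("  ", x$motif_string, "\n")
  invisible(x)
}

#' Detect palindromic arrangements of unit tokens
#'
#' Maximal contiguous token runs whose label sequence reads identically
#' after reversing the order and flipping every strand (e.g. B+ F+ F- B-).
#' Found by expanding around every inter-token centre; spans contained in a
#' longer palindromic span are dropped.
#'
#' @param a An [tile_arrangement()] result, or its token data frame.
#' @return Data frame with `first_token`, `last_token` (1-based token
#'   indices), `n_tokens`, `motif`, `span_start`, `span_end`, `total_len`.
#' @export
detect_palindromic_arrangement <- function(a) {
  tokens <- if (inherits(a, "arrangement")) a$tokens else a
  m <- nrow(tokens)
  empty <- data.frame(first_token = integer(0), last_token = integer(0),
                      n_tokens = integer(0), motif = character(0),
                      span_start = integer(0), span_end = integer(0),
                      total_len = integer(0), stringsAsFactors = FALSE)
  if (m < 2L) return(empty)
  lab <- tokens$label; str <- tokens$strand
  res <- list()
  for (c0 in seq_len(m - 1L)) {
    t <- 0L
    while (c0 - t >= 1L && c0 + 1L + t <= m &&
           lab[c0 - t] == lab[c0 + 1L + t] &&
           str[c0 - t] != str[c0 + 1L + t]) {
      t <- t + 1L
    }
    if (t >= 1L) {
      first <- c0 - t + 1L; last <- c0 + t
      res[[length(res) + 1L]] <- c(first, last)
    }
  }
  if (length(res) == 0L) return(empty)
  spans <- unique(do.call(rbind, res))
  contained <- vapply(seq_len(nrow(spans)), function(i) {
    any(spans[, 1L] <= spans[i, 1L] & spans[, 2L] >= spans[i, 2L] &
          (spans[, 1L] < spans[i, 1L] | spans[, 2L] > spans[i, 2L]))
  }, logical(1))
  spans <- spans[!contained, , drop = FALSE]
  ls <- if ("local_start" %in% names(tokens)) tokens$local_start else tokens$start
  le <- if ("local_end" %in% names(tokens)) tokens$local_end else tokens$end
  do.call(rbind, lapply(seq_len(nrow(spans)), function(i) {
    f <- spans[i, 1L]; l <- spans[i, 2L]
    data.frame(first_token = f, last_token = l, n_tokens = l - f + 1L,
               motif = paste(lab[f:l], collapse = "-"),
               span_start = ls[f], span_end = le[l],
               total_len = le[l] - ls[f], stringsAsFactors = FALSE)
  }))
}

#' Longest tandem run of one unit in an arrangement
#'
#' Longest run of consecutive tokens with the same label and strand whose
#' inter-token genomic gap is at most `max_gap` bp.
#'
#' @param a An [tile_arrangement()] result, or its token data frame.
#' @param label Unit label.
#' @param max_gap Maximum gap between consecutive run members, in bp.
#' @return Integer run length (0 when the label is absent).
#' @export
max_tandem_run <- function(a, label, max_gap = 5L) {
  tokens <- if (inherits(a, "arrangement")) a$tokens else a
  if (nrow(tokens) == 0L) return(0L)
  ls <- if ("local_start" %in% names(tokens)) tokens$local_start else tokens$start
  le <- if ("local_end" %in% names(tokens)) tokens$local_end else tokens$end
  best <- 0L; run <- 0L
  for (i in seq_len(nrow(tokens))) {
    extend <- tokens$label[i] == label &&
      (run == 0L ||
         (tokens$label[i - 1L] == label &&
            tokens$strand[i] == tokens$strand[i - 1L] &&
            ls[i] - le[i - 1L] <= max_gap))
    run <- if (extend) run + 1L else if (tokens$label[i] == label) 1L else 0L
    best <- max(best, run)
  }
  best
}

#' Find homologs of a unit consensus in another genome
#'
#' Iteratively reports the best local alignment of the consensus (either
#' strand) against the target, masks it, and repeats. Hits qualify when
#' their identity reaches `min_identity` and they either cover at least
#' `min_cover` of the consensus or are at least `min_len` bp long (cross-
#' strain homologs are frequently truncated).
#'
#' @param consensus Unit consensus (>= 13 bp).
#' @param target A [circular_genome()] or DNA string.
#' @param min_identity Minimum percent identity.
#' @param min_cover Minimum fraction of the consensus covered.
#' @param min_len Alternative minimum hit length in bp.
#' @param max_hits Safety cap on reported copies.
#' @return Data frame of copies: `start`, `end`, `strand`, `length`,
#'   `identity`.
#' @export
find_unit_homologs <- function(consensus, target, min_identity = 80,
                               min_cover = 0.5, min_len = 50L,
                               max_hits = 500L) {
  consensus <- toupper(as.character(consensus))
  if (nchar(consensus) < 13L) stop("consensus must be >= 13 bp")
  s <- .as_seq(target)
  clen <- nchar(consensus)
  rc <- revcomp(consensus)
  out <- list()
  repeat {
    if (length(out) >= max_hits) break
    best <- NULL
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") consensus else rc
      aln <- Biostrings::pairwiseAlignment(pat, s, type = "local",
                                           substitutionMatrix = .dna_submat(),
                                           gapOpening = 2, gapExtension = 1)
      sc <- Biostrings::score(aln)
      if (is.null(best) || sc > best$sc) {
        sr <- Biostrings::subject(aln)
        pr <- Biostrings::pattern(aln)
        p1 <- Biostrings::start(pr) - 1L; p2 <- Biostrings::end(pr)
        s1 <- Biostrings::start(sr) - 1L; s2 <- Biostrings::end(sr)
        cols <- max(p2 - p1, s2 - s1)
        best <- list(sc = sc, strand = strand, start = s1, end = s2,
                     identity = pair_identity(substr(pat, p1 + 1L, p2),
                                              substr(s, s1 + 1L, s2)),
                     cols = cols)
      }
    }
    hit_len <- best$end - best$start
    ok <- best$identity >= min_identity &&
      (best$cols >= min_cover * clen || hit_len >= min_len)
    if (!ok || hit_len == 0L) break
    out[[length(out) + 1L]] <- data.frame(
      start = best$start, end = best$end, strand = best$strand,
      length = hit_len, identity = round_half_up1(best$identity),
      stringsAsFactors = FALSE)
    substr(s, best$start + 1L, best$end) <- strrep("N", hit_len)
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), length = integer(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}
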