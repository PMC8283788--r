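# Gene-order comparison between circular genomes: conserved blocks,
# inversions and translocations, all at gene-order (not nucleotide) level.

#' Signed circular gene order of a genome
#'
#' Genes (CDS/tRNA/rRNA) sorted by start around the circle with their
#' strands; duplicated gene names are disambiguated by occurrence index
#' (`.1`, `.2`, ...).
#'
#' @param g A [circular_genome()].
#' @return An object of class `gene_order`: list with `id` and a data frame
#'   `genes` (`name`, `strand`, `start`, `end`).
#' @export
gene_order <- function(g) {
  f <- gene_features(g)
  if (nrow(f) == 0L) stop("no gene features annotated")
  f <- f[order(f$start), , drop = FALSE]
  dup <- f$name %in% f$name[duplicated(f$name)]
  if (any(dup)) {
    idx <- stats::ave(seq_len(nrow(f)), f$name, FUN = seq_along)
    f$name[dup] <- sprintf("%s.%d", f$name[dup], idx[dup])
  }
  structure(list(id = g$id,
                 genes = data.frame(name = f$name, strand = f$strand,
                                    start = f$start, end = f$end,
                                    stringsAsFactors = FALSE)),
            class = "gene_order")
}

# accept either a gene_order or a raw data frame with name/strand
.as_order <- function(x) {
  if (inherits(x, "gene_order")) return(x)
  if (is.data.frame(x)) {
    return(structure(list(id = attr(x, "id") %||% "order",
                          genes = x), class = "gene_order"))
  }
  stop("expected a gene_order")
}

#' Find synteny blocks between two signed circular gene orders
#'
#' Maximal runs of genes that are contiguous in both genomes, either
#' collinear (same order, same strands) or reversed with every strand
#' flipped. Genes absent from one genome are skipped transparently; blocks
#' are labelled a, b, c, ... by position in genome `a`.
#'
#' @param a,b [gene_order()] objects (or data frames with `name`,
#'   `strand`).
#' @return A data frame of blocks: `block`, `n_genes`, `genes`
#'   (comma-separated, in `a` order), `orientation` (`"+"` collinear,
#'   `"-"` reversed in `b`), `a_pos`, `b_pos` (1-based rank of the block's
#'   first gene among shared genes).
#' @export
find_synteny_blocks <- function(a, b) {
  a <- .as_order(a); b <- .as_order(b)
  shared <- intersect(a$genes$name, b$genes$name)
  if (length(shared) == 0L) stop("genomes share no genes")
  ga <- a$genes[a$genes$name %in% shared, , drop = FALSE]
  gb <- b$genes[b$genes$name %in% shared, , drop = FALSE]
  n <- nrow(ga)
  pos_b <- match(ga$name, gb$name)
  rel <- ifelse(ga$strand == gb$strand[pos_b], 1L, -1L)

  if (n == 1L) {
    return(data.frame(block = "a", n_genes = 1L, genes = ga$name,
                      orientation = ifelse(rel == 1L, "+", "-"),
                      a_pos = 1L, b_pos = pos_b, stringsAsFactors = FALSE))
  }
  nxt <- c(2:n, 1L)
  link <- (circ_mod(pos_b[nxt] - pos_b, n) == 1L & rel == 1L & rel[nxt] == 1L) |
          (circ_mod(pos_b - pos_b[nxt], n) == 1L & rel == -1L & rel[nxt] == -1L)
  if (all(link)) {
    ori <- if (all(rel == 1L)) "+" else "-"
    return(data.frame(block = "a", n_genes = n,
                      genes = paste(ga$name, collapse = ","),
                      orientation = ori, a_pos = 1L, b_pos = min(pos_b),
                      stringsAsFactors = FALSE))
  }
  # block boundaries after every broken adjacency; start blocks at the
  # first boundary so runs wrapping the origin stay in one piece
  breaks <- which(!link)  # adjacency i -> i+1 broken
  first <- circ_mod(breaks[1L], n) + 1L
  order_idx <- circ_mod((first - 1L):(first + n - 2L), n) + 1L
  blk_id <- cumsum(c(TRUE, !link[order_idx[-n]]))
  blocks <- split(order_idx, blk_id)

  out <- do.call(rbind, lapply(blocks, function(idx) {
    ori <- if (all(rel[idx] == 1L)) "+" else "-"
    data.frame(n_genes = length(idx),
               genes = paste(ga$name[idx], collapse = ","),
               orientation = ori, a_pos = idx[1L],
               b_pos = if (ori == "+") pos_b[idx[1L]] else pos_b[idx[length(idx)]],
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$a_pos), , drop = FALSE]
  out$block <- letters[seq_len(nrow(out))]
  rownames(out) <- NULL
  out[, c("block", "n_genes", "genes", "orientation", "a_pos", "b_pos")]
}

# longest common circular subsequence of two orderings of the same labels,
# by brute force over rotations (block counts are small)
.lccs_keep <- function(ref, obs) {
  n <- length(ref)
  best <- character(0)
  lcs <- function(x, y) {
    # classic dynamic program, returns kept elements of x
    m1 <- length(x); m2 <- length(y)
    d <- matrix(0L, m1 + 1L, m2 + 1L)
    for (i in seq_len(m1)) for (j in seq_len(m2)) {
      d[i + 1L, j + 1L] <- if (x[i] == y[j]) d[i, j] + 1L else
        max(d[i, j + 1L], d[i + 1L, j])
    }
    keep <- character(0)
    i <- m1; j <- m2
    while (i > 0L && j > 0L) {
      if (x[i] == y[j]) { keep <- c(x[i], keep); i <- i - 1L; j <- j - 1L }
      else if (d[i, j + 1L] >= d[i + 1L, j]) i <- i - 1L
      else j <- j - 1L
    }
    keep
  }
  for (r in seq_len(n)) {
    rot <- obs[circ_mod((r - 1L):(r + n - 2L), n) + 1L]
    k <- lcs(ref, rot)
    if (length(k) > length(best)) best <- k
  }
  best
}

#' Classify rearrangement events from synteny blocks
#'
#' Reports one inversion event per block whose orientation differs between
#' the genomes (after normalizing a global flip), and translocation events
#' for blocks whose circular order differs (blocks outside the longest
#' common circular subsequence of block orders). The event list describes
#' the differences; it is not a minimal rearrangement scenario.
#'
#' @param blocks A block table from [find_synteny_blocks()].
#' @return A data frame of events: `type` (`"inversion"` or
#'   `"translocation"`), `block`, `detail`.
#' @export
classify_rearrangements <- function(blocks) {
  empty <- data.frame(type = character(0), block = character(0),
                      detail = character(0), stringsAsFactors = FALSE)
  if (nrow(blocks) < 2L) return(empty)
  b <- blocks
  # normalize a whole-genome flip: if most genes sit in "-" blocks, flip
  flipped <- sum(b$n_genes[b$orientation == "-"]) > sum(b$n_genes) / 2
  if (flipped) b$orientation <- ifelse(b$orientation == "+", "-", "+")
  events <- empty
  for (i in which(b$orientation == "-")) {
    events <- rbind(events, data.frame(
      type = "inversion", block = b$block[i],
      detail = sprintf("block %s (%d genes) is inverted", b$block[i], b$n_genes[i]),
      stringsAsFactors = FALSE))
  }
  ref <- b$block[order(b$a_pos)]
  obs <- b$block[order(b$b_pos)]
  if (flipped) obs <- rev(obs)
  kept <- .lccs_keep(ref, obs)
  displaced <- setdiff(ref, kept)
  for (d in displaced) {
    i_obs <- match(d, obs)
    nb_prev <- obs[circ_mod(i_obs - 2L, length(obs)) + 1L]
    nb_next <- obs[circ_mod(i_obs, length(obs)) + 1L]
    i_ref <- match(d, ref)
    old_prev <- ref[circ_mod(i_ref - 2L, length(ref)) + 1L]
    events <- rbind(events, data.frame(
      type = "translocation", block = d,
      detail = sprintf("block %s moved: now between %s and %s (was after %s)",
                       d, nb_prev, nb_next, old_prev),
      stringsAsFactors = FALSE))
  }
  events
}

#' Distance from synteny-block boundaries to repeat regions
#'
#' For each block boundary (first-gene start and last-gene end), the
#' circular distance to the nearest repeat region; boundaries within
#' `max_dist` bp are flagged, the signature of repeat-mediated
#' rearrangement.
#'
#' @param blocks Block table from [find_synteny_blocks()].
#' @param order_a The [gene_order()] of genome `a` (for coordinates).
#' @param repeat_regions Data frame with `start`, `end` (0-based half-open,
#'   possibly wrap-encoded) in genome `a` coordinates; may have zero rows.
#' @param genome_length Length of genome `a` in bp.
#' @param max_dist Flagging distance in bp.
#' @return Data frame: `block`, `boundary` (`"start"`/`"end"`),
#'   `position`, `distance` (NA when no repeat regions), `flagged`.
#' @export
repeat_adjacency_report <- function(blocks, order_a, repeat_regions,
                                    genome_length, max_dist = 500L) {
  order_a <- .as_order(order_a)
  g <- order_a$genes
  L <- genome_length
  dist_to_regions <- function(p) {
    if (is.null(repeat_regions) || nrow(repeat_regions) == 0L) return(NA_real_)
    d <- vapply(seq_len(nrow(repeat_regions)), function(i) {
      s <- repeat_regions$start[i]; e <- repeat_regions$end[i]
      w <- span_length(s, e, L)
      off <- circ_mod(p - s, L)
      if (off < w) return(0)  # inside
      min(circ_mod(s - p, L), off - w)
    }, numeric(1))
    min(d)
  }
  rows <- list()
  for (i in seq_len(nrow(blocks))) {
    genes_i <- strsplit(blocks$genes[i], ",", fixed = TRUE)[[1L]]
    first <- g[g$name == genes_i[1L], ]
    last <- g[g$name == genes_i[length(genes_i)], ]
    for (bd in list(c("start", first$start), c("end", circ_mod(last$end, L)))) {
      p <- as.numeric(bd[2L])
      d <- dist_to_regions(p)
      rows[[length(rows) + 1L]] <- data.frame(
        block = blocks$block[i], boundary = bd[1L], position = p,
        distance = d, flagged = !is.na(d) && d <= max_dist,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
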