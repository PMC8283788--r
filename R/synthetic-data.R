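# Synthetic circular genomes with planted gene layouts and repeat
# architectures, plus derived "strains". Every planted element is recorded
# in a machine-readable truth object so recovery can be scored exactly.
#
# The generator emulates the canonical layout of small haptophyte-type
# mitochondrial genomes: two strand-segregated gene blocks separated by two
# repeat regions, each repeat region realized from a grammar over a small
# alphabet of units (tandem runs, composite motifs, palindromic spans),
# with independent per-copy substitutions and single-base indels.

#' Grammar token: tandem run of one unit
#' @param unit Unit label.
#' @param n Copy count.
#' @return A token descriptor.
#' @export
token_tandem <- function(unit, n) list(type = "tandem", unit = unit, n = as.integer(n))

#' Grammar token: repeated composite motif (e.g. B-D-E-A)
#' @param units Character vector of unit labels in order.
#' @param n Number of motif repetitions.
#' @return A token descriptor.
#' @export
token_motif <- function(units, n = 1L) list(type = "motif", units = units, n = as.integer(n))

#' Grammar token: palindromic arrangement (units forward, then mirrored
#' reverse-complemented, e.g. `c("B","F")` gives B+ F+ F- B-)
#' @param units Character vector of unit labels (one half).
#' @return A token descriptor.
#' @export
token_palindrome <- function(units) list(type = "palindrome", units = units)

#' Grammar token: motif instances in shuffled order ("various arrangements")
#'
#' Realizes `n` motif instances drawn as evenly as possible from `motifs`
#' and laid out in a seeded random order, the way real repeat regions mix
#' several composite arrangements rather than repeating one block.
#'
#' @param motifs List of character vectors of unit labels.
#' @param n Total number of motif instances.
#' @return A token descriptor.
#' @export
token_mixture <- function(motifs, n) {
  list(type = "mixture", motifs = motifs, n = as.integer(n))
}

.default_pcg <- c("cox1", "cox2", "cox3", "cob", "atp6", "atp8", "atp9",
                  "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6",
                  "rps3", "rps4", "rps12", "rpl6", "rpl16")
.default_rrna <- c("rnl", "rns")
.default_trna <- c("trnA-UGC", "trnC-GCA", "trnD-GUC", "trnE-UUC", "trnF-GAA",
                   "trnG-UCC", "trnH-GUG", "trnI-GAU", "trnK-UUU", "trnL-UAA",
                   "trnL-UAG", "trnM-CAU", "trnM-CAU", "trnN-GUU", "trnP-UGG",
                   "trnQ-UUG", "trnR-ACG", "trnR-UCU", "trnS-UGA", "trnS-GCU",
                   "trnT-UGU", "trnV-UAC", "trnW-CCA", "trnY-GUA")

.default_gene_blocks <- function() {
  genes <- c(.default_pcg, .default_rrna, .default_trna)
  half <- ceiling(length(genes) / 2)
  list(list(id = "block1", strand = "+", genes = genes[seq_len(half)]),
       list(id = "block2", strand = "-", genes = genes[(half + 1L):length(genes)]))
}

.default_unit_specs <- function() {
  data.frame(label = c("A", "B", "C", "D", "E", "F"),
             length = c(162L, 46L, 63L, 33L, 13L, 204L),
             gc = 0.3, stringsAsFactors = FALSE)
}

.default_grammars <- function() {
  list(
    repeat1 = list(token_mixture(list(c("B", "D", "E", "A"),
                                      c("D", "E", "A"),
                                      c("B", "D", "A")), 24L),
                   token_palindrome(c("A", "E", "D", "B"))),
    repeat2 = list(token_tandem("B", 106L),
                   token_motif(c("B", "C"), 60L),
                   token_tandem("C", 20L),
                   token_palindrome(c("B", "F"))))
}

#' Specification of a planted genome architecture
#'
#' Defaults emulate a ~43 kb mitochondrial genome: two strand-segregated
#' gene blocks, two repeat regions built from six units of 13-204 bp
#' (tandem runs, composite motifs and palindromic spans), 2% per-copy
#' substitutions and 0.2% single-base indels.
#'
#' @param genome_length_target Approximate genome size in bp; gene lengths
#'   are scaled so the assembled genome lands near it.
#' @param gene_blocks List of blocks: each `list(id, strand, genes)`.
#' @param unit_specs Data frame with `label`, `length`, `gc`.
#' @param region_grammars Named list (region id -> list of tokens built
#'   with [token_tandem()], [token_motif()], [token_palindrome()]).
#' @param layout Segment order around the circle (ids of blocks/regions).
#' @param sub_rate,indel_rate Per-base per-copy mutation rates in [0, 0.2].
#' @param seed Mandatory integer seed.
#' @param id Genome identifier.
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(genome_length_target = 43500L,
                              gene_blocks = .default_gene_blocks(),
                              unit_specs = .default_unit_specs(),
                              region_grammars = .default_grammars(),
                              layout = NULL,
                              sub_rate = 0.02, indel_rate = 0.002,
                              seed, id = "sim1") {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(sub_rate >= 0, sub_rate <= 0.2, indel_rate >= 0, indel_rate <= 0.2)
  if (any(unit_specs$length < 13L)) stop("unit lengths must be >= 13 bp")
  if (is.null(layout)) {
    bids <- vapply(gene_blocks, function(b) b$id, character(1))
    rids <- names(region_grammars)
    layout <- character(0)
    for (i in seq_len(max(length(bids), length(rids)))) {
      if (i <= length(bids)) layout <- c(layout, bids[i])
      if (i <= length(rids)) layout <- c(layout, rids[i])
    }
  }
  structure(list(genome_length_target = as.integer(genome_length_target),
                 gene_blocks = gene_blocks, unit_specs = unit_specs,
                 region_grammars = region_grammars, layout = layout,
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 seed = as.integer(seed), id = id),
            class = "architecture_spec")
}

# total grammar length at zero divergence
.grammar_length <- function(spec) {
  ulen <- stats::setNames(spec$unit_specs$length, spec$unit_specs$label)
  tot <- 0L
  for (gr in spec$region_grammars) {
    for (tk in gr) {
      tot <- tot + switch(tk$type,
        tandem = ulen[[tk$unit]] * tk$n,
        motif = sum(ulen[tk$units]) * tk$n,
        mixture = sum(vapply(seq_along(.mixture_counts(tk)), function(m)
          sum(ulen[tk$motifs[[m]]]) * .mixture_counts(tk)[m], numeric(1))),
        palindrome = 2L * sum(ulen[tk$units]),
        stop("unknown token type: ", tk$type))
    }
  }
  tot
}

# one mutated copy of a consensus; returns list(seq, subs, ins, dels)
.mutate_copy <- function(cons, sub_rate, indel_rate) {
  v <- strsplit(cons, "", fixed = TRUE)[[1L]]
  n <- length(v)
  bases <- c("A", "C", "G", "T")
  subs <- which(stats::runif(n) < sub_rate)
  for (p in subs) v[p] <- sample(setdiff(bases, v[p]), 1L)
  ind <- which(stats::runif(n) < indel_rate)
  ins <- 0L; dels <- 0L
  if (length(ind)) {
    keep <- rep(TRUE, n)
    insert <- rep("", n)
    for (p in ind) {
      if (stats::runif(1) < 0.5) { keep[p] <- FALSE; dels <- dels + 1L }
      else { insert[p] <- sample(bases, 1L); ins <- ins + 1L }
    }
    v <- unlist(lapply(seq_len(n), function(i)
      c(if (nzchar(insert[i])) insert[i], if (keep[i]) v[i])))
  }
  list(seq = paste(v, collapse = ""), subs = length(subs), ins = ins, dels = dels)
}

# deterministic per-motif instance counts for a mixture token: n split as
# evenly as possible, remainder to the leading motifs
.mixture_counts <- function(tk) {
  k <- length(tk$motifs)
  base <- tk$n %/% k
  extra <- tk$n %% k
  base + as.integer(seq_len(k) <= extra)
}

# expand grammar tokens of one region to a flat copy plan (label, strand);
# mixture tokens consume the seeded RNG stream for their shuffle
.expand_grammar <- function(grammar) {
  lab <- character(0); str <- character(0)
  for (tk in grammar) {
    plan <- switch(tk$type,
      tandem = list(rep(tk$unit, tk$n), rep("+", tk$n)),
      motif = list(rep(tk$units, tk$n), rep("+", length(tk$units) * tk$n)),
      mixture = {
        counts <- .mixture_counts(tk)
        insts <- rep(tk$motifs, counts)
        insts <- insts[sample(length(insts))]
        labs <- unlist(insts)
        list(labs, rep("+", length(labs)))
      },
      palindrome = list(c(tk$units, rev(tk$units)),
                        c(rep("+", length(tk$units)), rep("-", length(tk$units)))))
    lab <- c(lab, plan[[1L]]); str <- c(str, plan[[2L]])
  }
  data.frame(label = lab, strand = str, stringsAsFactors = FALSE)
}

# build the persistent program (units, gene sequences, segment order) that
# realization and strain derivation share; RNG must already be seeded
.build_program <- function(spec) {
  units <- stats::setNames(
    vapply(seq_len(nrow(spec$unit_specs)), function(i)
      random_dna(spec$unit_specs$length[i], spec$unit_specs$gc[i]), character(1)),
    spec$unit_specs$label)

  rep_len <- .grammar_length(spec)
  blocks <- spec$gene_blocks
  n_genes <- sum(vapply(blocks, function(b) length(b$genes), integer(1)))
  spacer_budget <- 40L * n_genes
  coding_budget <- spec$genome_length_target - rep_len - spacer_budget
  if (coding_budget < 150L * n_genes) {
    stop("grammar exceeds genome_length_target (no room for gene blocks)")
  }

  gene_len <- function(name, budget_per_gene) {
    if (grepl("^trn", name)) return(72L)
    if (name %in% c("rnl")) return(min(2800L, budget_per_gene * 3L))
    if (name %in% c("rns")) return(min(1500L, budget_per_gene * 2L))
    len <- round(stats::runif(1, 0.6, 1.4) * budget_per_gene)
    max(150L, 3L * (len %/% 3L))
  }
  # distribute the coding budget over non-tRNA genes
  all_names <- unlist(lapply(blocks, function(b) b$genes))
  n_trna <- sum(grepl("^trn", all_names))
  per_gene <- max(150L, (coding_budget - 72L * n_trna) %/%
                    max(1L, n_genes - n_trna))

  segments <- list()
  for (b in blocks) {
    genes <- lapply(b$genes, function(nm) {
      len <- gene_len(nm, per_gene)
      list(name = nm, length = len, seq = random_dna(len, 0.32),
           strand = b$strand)
    })
    spacers <- vapply(seq_along(genes), function(i)
      random_dna(sample(20:60, 1L), 0.25), character(1))
    segments[[b$id]] <- list(type = "gene_block", id = b$id,
                             strand = b$strand, genes = genes,
                             spacers = spacers, inverted = FALSE)
  }
  for (rid in names(spec$region_grammars)) {
    segments[[rid]] <- list(type = "repeat_region", id = rid,
                            grammar = spec$region_grammars[[rid]])
  }
  list(units = units, segments = segments, layout = spec$layout,
       sub_rate = spec$sub_rate, indel_rate = spec$indel_rate, id = spec$id)
}

# realize a program into (genome, truth); RNG must already be seeded
.realize_program <- function(program, id = program$id) {
  seq_parts <- character(0)
  feats <- empty_features()
  copies <- list()
  regions <- list()
  pos <- 0L
  for (sid in program$layout) {
    seg <- program$segments[[sid]]
    if (seg$type == "gap") {
      seq_parts <- c(seq_parts, strrep("N", seg$n))
      feats <- rbind(feats, data.frame(
        name = sid, kind = "gap", start = pos, end = pos + seg$n,
        strand = "+", anticodon = NA_character_, stringsAsFactors = FALSE))
      pos <- pos + seg$n
    } else if (seg$type == "gene_block") {
      genes <- seg$genes; spacers <- seg$spacers
      if (seg$inverted) {
        genes <- rev(lapply(genes, function(g) {
          g$seq <- revcomp(g$seq)
          g$strand <- if (g$strand == "+") "-" else "+"
          g
        }))
        spacers <- rev(vapply(spacers, revcomp, character(1)))
      }
      for (i in seq_along(genes)) {
        g <- genes[[i]]
        kind <- if (grepl("^trn", g$name)) "tRNA" else
          if (grepl("^rn[sl]$", g$name)) "rRNA" else "CDS"
        anticodon <- if (kind == "tRNA") .trna_anticodon(g$name) else NA_character_
        feats <- rbind(feats, data.frame(
          name = g$name, kind = kind, start = pos, end = pos + g$length,
          strand = g$strand, anticodon = anticodon, stringsAsFactors = FALSE))
        seq_parts <- c(seq_parts, g$seq)
        pos <- pos + g$length
        seq_parts <- c(seq_parts, spacers[i])
        pos <- pos + nchar(spacers[i])
      }
    } else if (seg$type == "repeat_region") {
      plan <- .expand_grammar(seg$grammar)
      region_start <- pos
      for (i in seq_len(nrow(plan))) {
        mut <- .mutate_copy(program$units[[plan$label[i]]],
                            program$sub_rate, program$indel_rate)
        cseq <- if (plan$strand[i] == "+") mut$seq else revcomp(mut$seq)
        seq_parts <- c(seq_parts, cseq)
        copies[[length(copies) + 1L]] <- data.frame(
          region = sid, label = plan$label[i], start = pos,
          end = pos + nchar(cseq), strand = plan$strand[i],
          subs = mut$subs, ins = mut$ins, dels = mut$dels,
          stringsAsFactors = FALSE)
        pos <- pos + nchar(cseq)
      }
      feats <- rbind(feats, data.frame(
        name = sid, kind = "repeat_region", start = region_start, end = pos,
        strand = "+", anticodon = NA_character_, stringsAsFactors = FALSE))
      regions[[length(regions) + 1L]] <- data.frame(
        region = sid, start = region_start, end = pos, stringsAsFactors = FALSE)
    }
  }
  genome <- circular_genome(id, paste(seq_parts, collapse = ""), feats)
  truth <- structure(list(
    copies = if (length(copies)) do.call(rbind, copies) else NULL,
    regions = if (length(regions)) do.call(rbind, regions) else NULL,
    genes = feats[feats$kind %in% c("CDS", "tRNA", "rRNA"), , drop = FALSE],
    units = program$units,
    events = list(), program = program), class = "planted_truth")
  list(genome = genome, truth = truth)
}

#' Generate a synthetic genome with planted architecture
#'
#' @param spec An [architecture_spec()].
#' @return A list with `genome` (a [circular_genome()]) and `truth` (a
#'   `planted_truth`: per-copy records with exact coordinates and edit
#'   counts, region records, gene table, unit consensuses, applied events,
#'   and the generating program used by [derive_strain()]).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  withr::with_seed(spec$seed, {
    program <- .build_program(spec)
    .realize_program(program)
  })
}

#' Strain-derivation events
#'
#' Constructors for the event vocabulary of [derive_strain()]:
#' amplification/contraction of a unit's copy number, inversion of a gene
#' block, translocation of a block elsewhere in the layout, and masking of
#' a repeat region by a run of 1000 Ns (emulating an unresolved assembly).
#'
#' @param unit,block,region Segment/unit identifiers in the program.
#' @param factor Multiplier (amplify) or divisor (contract).
#' @param after Segment id the block is moved after.
#' @return An event descriptor.
#' @export
ev_amplify <- function(unit, factor) list(type = "amplify", unit = unit, factor = factor)

#' @rdname ev_amplify
#' @export
ev_contract <- function(unit, factor) list(type = "contract", unit = unit, factor = factor)

#' @rdname ev_amplify
#' @export
ev_invert <- function(block) list(type = "invert", block = block)

#' @rdname ev_amplify
#' @export
ev_translocate <- function(block, after) list(type = "translocate", block = block, after = after)

#' @rdname ev_amplify
#' @export
ev_mask_region <- function(region) list(type = "mask_region", region = region)

# multiply/divide copy counts of grammar tokens referencing a unit
.scale_unit <- function(grammar, unit, f) {
  found <- FALSE
  for (i in seq_along(grammar)) {
    tk <- grammar[[i]]
    hit <- switch(tk$type, tandem = tk$unit == unit,
                  motif = unit %in% tk$units,
                  mixture = any(vapply(tk$motifs, function(m) unit %in% m,
                                       logical(1))),
                  palindrome = FALSE)
    if (hit) {
      found <- TRUE
      grammar[[i]]$n <- max(1L, as.integer(round(tk$n * f)))
    }
  }
  attr(grammar, "found") <- found
  grammar
}

#' Derive a strain by applying architecture events
#'
#' Events are applied in order to the generating program of `truth`, and
#' the genome is re-realized under `seed` (unit consensuses and gene
#' sequences are inherited; per-copy mutations are redrawn, so strains
#' diverge in their repeat copies the way real strains do).
#'
#' @param g The ancestral genome (used for its id only).
#' @param truth The ancestral `planted_truth`.
#' @param events List of events built with [ev_amplify()] and friends.
#' @param seed Integer seed for the strain's own mutations.
#' @param id Identifier for the derived genome.
#' @return A list with `genome` and `truth`, as [generate_genome()].
#' @export
derive_strain <- function(g, truth, events, seed, id = paste0(g$id, "_d")) {
  program <- truth$program
  program$id <- id
  for (ev in events) {
    if (ev$type %in% c("amplify", "contract")) {
      f <- if (ev$type == "amplify") ev$factor else 1 / ev$factor
      found <- FALSE
      for (sid in names(program$segments)) {
        seg <- program$segments[[sid]]
        if (seg$type != "repeat_region") next
        gr <- .scale_unit(seg$grammar, ev$unit, f)
        if (attr(gr, "found")) found <- TRUE
        attr(gr, "found") <- NULL
        program$segments[[sid]]$grammar <- gr
      }
      if (!found) stop("unknown unit: ", ev$unit)
    } else if (ev$type == "invert") {
      seg <- program$segments[[ev$block]]
      if (is.null(seg) || seg$type != "gene_block") stop("unknown block: ", ev$block)
      program$segments[[ev$block]]$inverted <- !seg$inverted
    } else if (ev$type == "translocate") {
      if (is.null(program$segments[[ev$block]])) stop("unknown block: ", ev$block)
      lay <- setdiff(program$layout, ev$block)
      at <- match(ev$after, lay)
      if (is.na(at)) stop("unknown segment: ", ev$after)
      program$layout <- append(lay, ev$block, after = at)
    } else if (ev$type == "mask_region") {
      seg <- program$segments[[ev$region]]
      if (is.null(seg) || seg$type != "repeat_region") stop("unknown region: ", ev$region)
      program$segments[[ev$region]] <- list(type = "gap", id = ev$region, n = 1000L)
    } else stop("unknown event type: ", ev$type)
  }
  out <- withr::with_seed(as.integer(seed), .realize_program(program, id = id))
  out$truth$events <- c(truth$events, events)
  out
}

#' Generate a panel of related strains
#'
#' One ancestral genome plus `n_strains - 1` derived strains. Events per
#' strain are either supplied explicitly (a list of event lists) or drawn
#' independently from `event_menu`.
#'
#' @param spec An [architecture_spec()] for the ancestor.
#' @param n_strains Total number of strains (>= 2).
#' @param event_menu Either a list of event lists (one per derived strain)
#'   or a flat menu of candidate events to sample from; `NULL` derives
#'   identical strains.
#' @param seed Integer seed controlling strain derivation.
#' @return A list with `genomes`, `truths`, and `copy_numbers` (units x
#'   strains matrix of planted copy counts).
#' @export
strain_panel <- function(spec, n_strains, event_menu = NULL, seed) {
  stopifnot(n_strains >= 2L)
  anc <- generate_genome(spec)
  genomes <- list(anc$genome); truths <- list(anc$truth)
  # explicit when event_menu is a list of event lists (not of raw events)
  is_event <- function(x) is.list(x) && !is.null(x$type)
  explicit <- !is.null(event_menu) && length(event_menu) && !is_event(event_menu[[1L]])
  for (i in 2:n_strains) {
    evs <- if (is.null(event_menu)) list()
    else if (explicit) event_menu[[i - 1L]]
    else withr::with_seed(as.integer(seed) + 7L * i, {
      event_menu[sample(seq_along(event_menu), sample(1:2, 1L))]
    })
    d <- derive_strain(anc$genome, anc$truth, evs, seed = as.integer(seed) + i,
                       id = sprintf("%s_s%d", spec$id, i))
    genomes[[i]] <- d$genome; truths[[i]] <- d$truth
  }
  labels <- names(anc$truth$units)
  cn <- vapply(truths, function(tr) {
    if (is.null(tr$copies)) return(stats::setNames(rep(0L, length(labels)), labels))
    tab <- table(factor(tr$copies$label, levels = labels))
    stats::setNames(as.integer(tab), labels)
  }, integer(length(labels)))
  colnames(cn) <- vapply(genomes, function(g) g$id, character(1))
  list(genomes = genomes, truths = truths, copy_numbers = cn)
}

#' Read an architecture spec from a YAML or JSON file
#' @param path Path to the config file.
#' @return An [architecture_spec()].
#' @export
read_architecture_spec <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  need <- function(x, field) {
    if (is.null(x)) stop("spec file missing field: ", field)
    x
  }
  units <- do.call(rbind, lapply(need(cfg$unit_specs, "unit_specs"), function(u)
    data.frame(label = need(u$label, "unit_specs$label"),
               length = as.integer(need(u$length, "unit_specs$length")),
               gc = u$gc %||% 0.3, stringsAsFactors = FALSE)))
  grams <- lapply(need(cfg$region_grammars, "region_grammars"), function(gr)
    lapply(gr, function(tk) {
      switch(need(tk$type, "token type"),
             tandem = token_tandem(tk$unit, tk$n),
             motif = token_motif(unlist(tk$units), tk$n %||% 1L),
             mixture = token_mixture(lapply(tk$motifs, unlist), tk$n),
             palindrome = token_palindrome(unlist(tk$units)),
             stop("unknown token type: ", tk$type))
    }))
  blocks <- lapply(need(cfg$gene_blocks, "gene_blocks"), function(b)
    list(id = need(b$id, "gene_blocks$id"), strand = b$strand %||% "+",
         genes = unlist(need(b$genes, "gene_blocks$genes"))))
  architecture_spec(
    genome_length_target = as.integer(cfg$genome_length_target %||% 43500L),
    gene_blocks = blocks, unit_specs = units, region_grammars = grams,
    layout = if (!is.null(cfg$layout)) unlist(cfg$layout) else NULL,
    sub_rate = cfg$sub_rate %||% 0.02, indel_rate = cfg$indel_rate %||% 0.002,
    seed = as.integer(need(cfg$seed, "seed")), id = cfg$id %||% "sim1")
}
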