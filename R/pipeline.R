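# High-level pipelines: per-genome profiling, cross-strain comparison, and
# simulation. These orchestrate the module functions and write the
# standard report bundle (TSV/BED/JSON plus a plain-text summary and a
# manifest echoing every threshold, so runs are auditable and
# reproducible).

.run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

.read_genome_file <- function(path) {
  if (grepl("\\.(gb|gbk|gbff|genbank)$", path, ignore.case = TRUE)) {
    read_genbank(path)
  } else {
    first <- readLines(path, n = 1L, warn = FALSE)
    if (startsWith(first, ">")) read_fasta_genome(path) else read_genbank(path)
  }
}

.write_manifest <- function(dir, command, inputs, params) {
  manifest <- list(command = command, inputs = inputs, parameters = params,
                   package = "repeatarch",
                   version = as.character(utils::packageVersion("repeatarch")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Profile the repeat architecture of one genome
#'
#' Runs the full per-genome pipeline: rotation to the anchor gene, summary
#' statistics, repeat discovery and unit decomposition, arrangement tiling
#' and palindromic-arrangement detection, hairpin scoring of unit
#' consensuses, and the GC-skew profile. With `out_dir` set, writes the
#' report bundle (FASTA/BED/TSV/JSON, `summary.txt`, `manifest.json`).
#'
#' @param input Path to a GenBank/FASTA file, or a [circular_genome()].
#' @param anchor Gene whose start becomes coordinate 0 (skipped with a
#'   message when absent or when the genome has no annotations).
#' @param out_dir Optional output directory.
#' @param min_unit_len,cluster_identity,tile_identity,min_region_len
#'   Passed to [recover_architecture()].
#' @param hairpin_min_stem,hairpin_max_loop Hairpin-scan parameters.
#' @param skew_window,skew_step GC-skew parameters.
#' @return (Invisibly) a list: `genome`, `summary`, `recovery`,
#'   `palindromes`, `hairpins`, `skew`.
#' @export
profile_genome <- function(input, anchor = "cox1", out_dir = NULL,
                           min_unit_len = 13L, cluster_identity = 70,
                           tile_identity = 70, min_region_len = 100L,
                           hairpin_min_stem = 5L, hairpin_max_loop = 50L,
                           skew_window = 100L, skew_step = 10L) {
  g <- .run_stage("read", {
    if (inherits(input, "circular_genome")) input else .read_genome_file(input)
  })
  has_genes <- nrow(gene_features(g)) > 0L
  if (has_genes && anchor %in% gene_features(g)$name) {
    g <- .run_stage("rotate", rotate_to_gene(g, anchor))
  } else {
    message("anchor gene not found; analysing without rotation")
  }
  summary <- if (has_genes) .run_stage("stats", genome_summary(g)) else NULL
  rec <- .run_stage("repeat_discovery",
                    recover_architecture(g, min_unit_len = min_unit_len,
                                         cluster_identity = cluster_identity,
                                         tile_identity = tile_identity,
                                         min_region_len = min_region_len))
  palindromes <- .run_stage("palindromes",
                            lapply(rec$arrangements, detect_palindromic_arrangement))
  hairpins <- .run_stage("hairpins", lapply(rec$units, function(u)
    double_hairpin_scan(u$consensus, min_stem = hairpin_min_stem,
                        max_loop = hairpin_max_loop)))
  if (length(hairpins)) names(hairpins) <-
    vapply(rec$units, function(u) u$label, character(1))
  skew <- .run_stage("gc_skew", gc_skew_profile(g, skew_window, skew_step))

  res <- list(genome = g, summary = summary, recovery = rec,
              palindromes = palindromes, hairpins = hairpins, skew = skew)
  if (!is.null(out_dir)) {
    .run_stage("write", {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_outputs(g, rec$units, rec$arrangements, out_dir)
      utils::write.table(
        data.frame(position = skew$positions, skew = skew$values,
                   cumulative = skew$cumulative[skew$positions + 1L]),
        file.path(out_dir, "gc_skew.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      jsonlite::write_json(hairpins, file.path(out_dir, "hairpins.json"),
                           auto_unbox = TRUE, digits = NA)
      .write_manifest(out_dir, "profile",
                      if (is.character(input)) input else g$id,
                      list(anchor = anchor, min_unit_len = min_unit_len,
                           cluster_identity = cluster_identity,
                           tile_identity = tile_identity,
                           min_region_len = min_region_len,
                           hairpin_min_stem = hairpin_min_stem,
                           hairpin_max_loop = hairpin_max_loop,
                           skew_window = skew_window, skew_step = skew_step))
      writeLines(.profile_summary_text(res), file.path(out_dir, "summary.txt"))
    })
  }
  invisible(res)
}

.profile_summary_text <- function(res) {
  g <- res$genome
  out <- c(sprintf("genome %s: %d bp%s", g$id, g$length,
                   if (g$is_circular) " (circular)" else ""))
  gaps <- g$features[g$features$kind == "gap", , drop = FALSE]
  if (nrow(gaps)) out <- c(out, sprintf(
    "  unresolved gap(s): %s",
    paste(sprintf("[%d,%d)", gaps$start, gaps$end), collapse = ", ")))
  if (!is.null(res$summary)) {
    s <- res$summary
    out <- c(out,
             sprintf("  AT content: %.1f%%; coding: %.1f%%; non-coding: %.1f%%",
                     s$at_percent, s$coding_percent, s$noncoding_percent),
             sprintf("  longest spacer: %s | %s (%d bp); strand blocks: %d",
                     s$longest_spacer$left, s$longest_spacer$right,
                     s$longest_spacer$length, s$n_strand_blocks))
  }
  rec <- res$recovery
  out <- c(out, sprintf("  repeat regions: %d; repeat units: %d",
                        nrow(rec$regions), length(rec$units)))
  for (u in rec$units) {
    out <- c(out, sprintf("    unit %s: %d copies, %d-%d bp, %.1f-%.1f%% identity",
                          u$label, nrow(u$copies), u$length_range[1L],
                          u$length_range[2L], u$identity_range[1L],
                          u$identity_range[2L]))
  }
  for (i in seq_along(rec$arrangements)) {
    a <- rec$arrangements[[i]]
    pal <- res$palindromes[[i]]
    out <- c(out, sprintf("  region %d [%d,%d): cover %.2f, %d tokens, %d palindromic arrangement(s)",
                          i, a$region_start, a$region_end, a$cover_fraction,
                          nrow(a$tokens), nrow(pal)))
  }
  out <- c(out, sprintf("  cumulative GC skew: max @%d, min @%d",
                        res$skew$max_pos, res$skew$min_pos))
  out
}

#' Compare gene content, gene order and unit homologs across genomes
#'
#' Builds the repertoire matrix and core-gene set, calls synteny blocks
#' and rearrangement events of every genome against the first (the
#' reference), profiles the reference's repeat units, and searches each
#' unit's consensus in every genome ([find_unit_homologs()]), yielding the
#' cross-strain copy-number table.
#'
#' @param inputs Character vector of genome files, or a list of
#'   [circular_genome()] objects (>= 2).
#' @param anchor Rotation anchor gene.
#' @param out_dir Optional output directory for the TSV bundle.
#' @param homolog_identity,homolog_min_len [find_unit_homologs()] settings.
#' @param ... Passed to [profile_genome()] for the reference profile.
#' @return (Invisibly) a list: `repertoire`, `core_genes`, `synteny`
#'   (per non-reference genome: `blocks`, `events`), `homologs` (long data
#'   frame), `adjacency`.
#' @export
compare_genomes <- function(inputs, anchor = "cox1", out_dir = NULL,
                            homolog_identity = 80, homolog_min_len = 50L, ...) {
  if (length(inputs) < 2L) stop("need at least two genomes")
  gs <- .run_stage("read", lapply(inputs, function(x)
    if (inherits(x, "circular_genome")) x else .read_genome_file(x)))
  gs <- .run_stage("rotate", lapply(gs, function(g) {
    f <- gene_features(g)
    if (sum(f$name == anchor) == 1L) rotate_to_gene(g, anchor) else g
  }))
  rep_m <- .run_stage("repertoire", repertoire_matrix(gs))
  core <- core_genes(rep_m)

  ref <- gs[[1L]]
  ord_ref <- gene_order(ref)
  synteny <- list()
  for (i in seq_along(gs)[-1L]) {
    blocks <- .run_stage("synteny", find_synteny_blocks(ord_ref, gene_order(gs[[i]])))
    events <- .run_stage("rearrangements", classify_rearrangements(blocks))
    synteny[[gs[[i]]$id]] <- list(blocks = blocks, events = events)
  }

  prof <- .run_stage("reference_profile",
                     profile_genome(ref, anchor = anchor, ...))
  homologs <- list()
  for (u in prof$recovery$units) {
    if (nchar(u$consensus) < 13L) next
    for (g in gs) {
      hits <- .run_stage("unit_homologs",
                         find_unit_homologs(u$consensus, g,
                                            min_identity = homolog_identity,
                                            min_len = homolog_min_len))
      homologs[[length(homologs) + 1L]] <- data.frame(
        unit = u$label, genome = g$id, copies = nrow(hits),
        min_len = if (nrow(hits)) min(hits$length) else NA_integer_,
        max_len = if (nrow(hits)) max(hits$length) else NA_integer_,
        min_identity = if (nrow(hits)) min(hits$identity) else NA_real_,
        max_identity = if (nrow(hits)) max(hits$identity) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  homologs <- if (length(homologs)) do.call(rbind, homologs) else NULL

  adjacency <- lapply(synteny, function(sy)
    repeat_adjacency_report(sy$blocks, ord_ref, prof$recovery$regions,
                            ref$length))

  res <- list(repertoire = rep_m, core_genes = core, synteny = synteny,
              homologs = homologs, adjacency = adjacency,
              reference_profile = prof)
  if (!is.null(out_dir)) {
    .run_stage("write", {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(cbind(genome = rownames(rep_m), as.data.frame(unclass(rep_m))),
                         file.path(out_dir, "repertoire.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      writeLines(core, file.path(out_dir, "core_genes.txt"))
      for (id in names(synteny)) {
        utils::write.table(synteny[[id]]$blocks,
                           file.path(out_dir, sprintf("blocks_%s.tsv", id)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(synteny[[id]]$events,
                           file.path(out_dir, sprintf("events_%s.tsv", id)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      if (!is.null(homologs)) {
        utils::write.table(homologs, file.path(out_dir, "unit_homologs.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      jsonlite::write_json(adjacency, file.path(out_dir, "repeat_adjacency.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      .write_manifest(out_dir, "compare",
                      vapply(gs, function(g) g$id, character(1)),
                      list(anchor = anchor, homolog_identity = homolog_identity,
                           homolog_min_len = homolog_min_len))
    })
  }
  invisible(res)
}

#' Simulate a genome (or just write one) from an architecture spec
#'
#' @param spec An [architecture_spec()] or the path to a YAML/JSON spec
#'   file ([read_architecture_spec()]).
#' @param out_dir Output directory; writes `genome.fasta`, `genome.gb`,
#'   and `truth.json`.
#' @return (Invisibly) the list from [generate_genome()].
#' @export
simulate_genomes <- function(spec, out_dir) {
  if (is.character(spec)) spec <- .run_stage("read_spec", read_architecture_spec(spec))
  sim <- .run_stage("generate", generate_genome(spec))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(out_dir, "genome.fasta"))
  write_genbank(sim$genome, file.path(out_dir, "genome.gb"))
  truth <- sim$truth
  jsonlite::write_json(
    list(copies = truth$copies, regions = truth$regions, genes = truth$genes,
         units = as.list(truth$units), events = truth$events),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  .write_manifest(out_dir, "simulate", spec$id,
                  list(seed = spec$seed, sub_rate = spec$sub_rate,
                       indel_rate = spec$indel_rate,
                       genome_length_target = spec$genome_length_target))
  invisible(sim)
}
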