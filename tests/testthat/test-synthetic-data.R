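# The generator: planted truth correctness, determinism, mutation
# statistics, and strain derivation events.

small_spec <- function(seed, sub_rate = 0.02, indel_rate = 0) {
  architecture_spec(
    genome_length_target = 4000L,
    gene_blocks = list(
      list(id = "block1", strand = "+", genes = c("cox1", "cox2")),
      list(id = "block2", strand = "-", genes = c("cob", "atp6"))),
    unit_specs = data.frame(label = c("A", "B"), length = c(100L, 40L),
                            gc = 0.3, stringsAsFactors = FALSE),
    region_grammars = list(
      repeat1 = list(token_tandem("A", 3L), token_palindrome(c("A", "B"))),
      repeat2 = list(token_tandem("B", 8L))),
    sub_rate = sub_rate, indel_rate = indel_rate, seed = seed)
}

test_that("generation is deterministic and truth coordinates are exact", {
  sim1 <- generate_genome(small_spec(7))
  sim2 <- generate_genome(small_spec(7))
  expect_identical(sim1$genome$sequence, sim2$genome$sequence)
  expect_identical(sim1$truth$copies, sim2$truth$copies)
  # different seed differs
  expect_false(identical(sim1$genome$sequence,
                         generate_genome(small_spec(8))$genome$sequence))
  # two strand-segregated gene blocks
  expect_length(strand_blocks(sim1$genome), 2L)
  # repeat_region features match the truth regions
  rr <- sim1$genome$features[sim1$genome$features$kind == "repeat_region", ]
  expect_equal(rr$start, sim1$truth$regions$start)
  expect_equal(rr$end, sim1$truth$regions$end)
})

test_that("zero mutation rates give copies identical to the consensus", {
  sim <- generate_genome(small_spec(9, sub_rate = 0, indel_rate = 0))
  tt <- sim$truth$copies
  for (i in seq_len(nrow(tt))) {
    got <- subsequence(sim$genome, tt$start[i], tt$end[i] %% sim$genome$length,
                       tt$strand[i])
    expect_identical(got, sim$truth$units[[tt$label[i]]])
  }
  expect_true(all(tt$subs == 0L & tt$ins == 0L & tt$dels == 0L))
})

test_that("truth records the realized edit counts per copy", {
  sim <- generate_genome(small_spec(10, sub_rate = 0.05, indel_rate = 0))
  tt <- sim$truth$copies
  for (i in seq_len(nrow(tt))) {
    got <- subsequence(sim$genome, tt$start[i], tt$end[i] %% sim$genome$length,
                       tt$strand[i])
    cons <- sim$truth$units[[tt$label[i]]]
    v1 <- strsplit(got, "")[[1]]; v2 <- strsplit(cons, "")[[1]]
    expect_equal(sum(v1 != v2), tt$subs[i])
  }
})

test_that("realized substitutions follow the binomial expectation", {
  subs <- 0L; bases <- 0L
  for (sd in 1:25) {
    sim <- generate_genome(small_spec(100 + sd, sub_rate = 0.02, indel_rate = 0))
    subs <- subs + sum(sim$truth$copies$subs)
    bases <- bases + sum(sim$truth$copies$end - sim$truth$copies$start)
  }
  expect_lt(abs(subs - 0.02 * bases), 3 * sqrt(bases * 0.02 * 0.98))
})

test_that("amplification scales planted copy numbers exactly", {
  sim <- generate_genome(small_spec(11))
  d <- derive_strain(sim$genome, sim$truth, list(ev_amplify("A", 7)), seed = 99)
  # the tandem A run (3 copies) scales 7x; the palindrome A pair is fixed
  expect_equal(sum(sim$truth$copies$label == "A"), 5L)
  expect_equal(sum(d$truth$copies$label == "A"), 3L * 7L + 2L)
  expect_error(derive_strain(sim$genome, sim$truth,
                             list(ev_amplify("Z", 2)), seed = 1),
               "unknown unit")
})

test_that("inversion events round-trip through synteny detection", {
  sim <- generate_genome(small_spec(12))
  d <- derive_strain(sim$genome, sim$truth, list(ev_invert("block2")), seed = 50)
  blk <- find_synteny_blocks(gene_order(sim$genome), gene_order(d$genome))
  ev <- classify_rearrangements(blk)
  inv <- ev[ev$type == "inversion", ]
  expect_equal(nrow(inv), 1L)
  inv_genes <- strsplit(blk$genes[blk$block == inv$block], ",")[[1]]
  expect_setequal(inv_genes, c("cob", "atp6"))
})

test_that("masking a region plants a 1000-N gap feature", {
  sim <- generate_genome(small_spec(13))
  d <- derive_strain(sim$genome, sim$truth, list(ev_mask_region("repeat2")),
                     seed = 51)
  expect_true(grepl(strrep("N", 1000), d$genome$sequence, fixed = TRUE))
  gaps <- d$genome$features[d$genome$features$kind == "gap", ]
  expect_gte(nrow(gaps), 1L)
  expect_equal(gaps$end[1] - gaps$start[1], 1000L)
})

test_that("a strain panel records per-strain copy numbers and is reproducible", {
  # copy-number scenario: the ancestral 3-copy tandem amplified and
  # contracted to different degrees across strains
  menu <- list(list(), list(ev_amplify("A", 4)), list(ev_amplify("A", 2)),
               list(ev_amplify("A", 7)))
  panel <- strain_panel(small_spec(14), n_strains = 5, event_menu = menu,
                        seed = 200)
  expect_length(panel$genomes, 5L)
  base_a <- panel$copy_numbers["A", 1]
  expect_equal(unname(panel$copy_numbers["A", -1]),
               c(base_a, base_a + 3 * 3, base_a + 3, base_a + 3 * 6))
  # identical seed, identical panel
  panel2 <- strain_panel(small_spec(14), n_strains = 5, event_menu = menu,
                         seed = 200)
  expect_identical(vapply(panel$genomes, function(g) g$sequence, character(1)),
                   vapply(panel2$genomes, function(g) g$sequence, character(1)))
  # no events: strains identical to the ancestor in gene order
  p0 <- strain_panel(small_spec(15), n_strains = 2, seed = 300)
  blk <- find_synteny_blocks(gene_order(p0$genomes[[1]]),
                             gene_order(p0$genomes[[2]]))
  expect_equal(nrow(classify_rearrangements(blk)), 0L)
})

test_that("cross-strain homolog search recovers panel copy numbers", {
  menu <- list(list(ev_amplify("A", 2)), list(ev_contract("A", 3)))
  panel <- strain_panel(small_spec(16), n_strains = 3, event_menu = menu,
                        seed = 400)
  cons <- panel$truths[[1]]$units[["A"]]
  for (i in seq_along(panel$genomes)) {
    hits <- find_unit_homologs(cons, panel$genomes[[i]], min_identity = 80,
                               min_cover = 0.6)
    expect_equal(nrow(hits), unname(panel$copy_numbers["A", i]))
  }
})

test_that("an oversized grammar is rejected with a clear error", {
  expect_error(architecture_spec(seed = 1, unit_specs = data.frame(
    label = "A", length = 10L, gc = 0.3)), "unit lengths")
  spec <- small_spec(17)
  spec$genome_length_target <- 900L
  expect_error(generate_genome(spec), "exceeds genome_length_target")
})
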