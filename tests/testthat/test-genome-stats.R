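# Per-genome summary statistics and cross-genome repertoire comparisons.

test_that("AT content excludes N and rounds half-up to one decimal", {
  expect_equal(at_content("ATAT"), 100.0)
  expect_equal(at_content("ATGC"), 50.0)
  expect_equal(at_content("ATGNNN"), round(100 * 2 / 3, 1))
  expect_error(at_content("NNNN"), "no unambiguous")
})

test_that("coding density is a union over gene features", {
  g <- make_genome(strrep("A", 10), feat_row("x", "CDS", 0, 9))
  expect_equal(coding_density(g), 90.0)
  g2 <- make_genome(strrep("A", 10), rbind(feat_row("x", "CDS", 0, 5),
                                           feat_row("y", "CDS", 3, 8)))
  expect_equal(coding_density(g2), 80.0)  # union, not sum
  g3 <- make_genome(strrep("A", 10), rbind(feat_row("x", "CDS", 0, 6),
                                           feat_row("y", "rRNA", 6, 10)))
  expect_equal(coding_density(g3), 100.0)
  # repeat_region features never count as coding
  g4 <- make_genome(strrep("A", 10), rbind(feat_row("x", "CDS", 0, 5),
                                           feat_row("r", "repeat_region", 5, 10)))
  expect_equal(coding_density(g4), 50.0)
})

test_that("intergenic spacers cover the circle including the origin gap", {
  g <- make_genome(strrep("A", 30), rbind(feat_row("x", "CDS", 0, 10),
                                          feat_row("y", "CDS", 15, 20)))
  sp <- intergenic_spacers(g)
  expect_equal(sp$length, c(5L, 10L))
  expect_equal(sp$left, c("x", "y"))
  expect_equal(sp$right, c("y", "x"))
  g2 <- make_genome(strrep("A", 30), rbind(feat_row("x", "CDS", 0, 10),
                                           feat_row("y", "CDS", 10, 20)))
  expect_equal(intergenic_spacers(g2)$length, c(0L, 10L))
})

test_that("per-base oracle reproduces coding density and spacer totals", {
  set.seed(21)
  for (rep in 1:20) {
    L <- sample(60:300, 1)
    n_feat <- sample(2:6, 1)
    # non-overlapping random features
    cuts <- sort(sample(0:(L - 1), 2 * n_feat))
    feats <- do.call(rbind, lapply(seq_len(n_feat), function(i)
      feat_row(sprintf("g%d", i), "CDS", cuts[2 * i - 1], cuts[2 * i],
               sample(c("+", "-"), 1))))
    feats <- feats[feats$end > feats$start, , drop = FALSE]
    if (nrow(feats) < 2L) next
    g <- make_genome(rand_dna(L), feats)
    # oracle: classify every base
    covered <- logical(L)
    for (i in seq_len(nrow(feats))) {
      covered[(feats$start[i] + 1L):feats$end[i]] <- TRUE
    }
    expect_equal(coding_density(g), floor(100 * sum(covered) / L * 10 + 0.5) / 10)
    expect_equal(sum(intergenic_spacers(g)$length), sum(!covered))
  }
})

test_that("strand blocks merge circularly", {
  mk <- function(strands) {
    feats <- do.call(rbind, lapply(seq_along(strands), function(i)
      feat_row(sprintf("g%d", i), "CDS", (i - 1) * 10, (i - 1) * 10 + 8, strands[i])))
    make_genome(strrep("A", 10 * length(strands)), feats)
  }
  expect_length(strand_blocks(mk(c("+", "+", "-", "-"))), 2L)
  expect_length(strand_blocks(mk(c("+", "+", "+"))), 1L)
  expect_length(strand_blocks(mk(c("+", "-", "+", "-"))), 4L)
  # first and last run merge across the origin
  b <- strand_blocks(mk(c("+", "-", "-", "+")))
  expect_length(b, 2L)
  expect_setequal(b[[which(vapply(b, attr, "", which = "strand") == "+")]],
                  c("g4", "g1"))
})

test_that("repertoire matrix pools tRNA anticodon variants into one column", {
  mk <- function(id, genes, kinds, anti = NULL) {
    feats <- do.call(rbind, lapply(seq_along(genes), function(i)
      feat_row(genes[i], kinds[i], (i - 1) * 20, (i - 1) * 20 + 15, "+",
               if (!is.null(anti)) anti[i] else NA)))
    make_genome(strrep("A", 20 * length(genes)), feats, id = id)
  }
  g1 <- mk("s1", c("cox1", "trnW-TCA"), c("CDS", "tRNA"), c(NA, "TCA"))
  g2 <- mk("s2", c("cox1", "trnW-CCA", "nad1"), c("CDS", "tRNA", "CDS"),
           c(NA, "CCA", NA))
  m <- repertoire_matrix(list(g1, g2))
  expect_equal(ncol(m), 3L)  # cox1, nad1, trnW (one pooled column)
  expect_true(any(grepl("^V:", m)))
  expect_setequal(core_genes(m), c("cox1", "trnW"))
  # identical gene sets: everything core, nothing flagged absent
  m2 <- repertoire_matrix(list(g1, g1))
  expect_false(any(m2 == "0"))
})

test_that("core genes follow set semantics", {
  mk <- function(id, genes) {
    feats <- do.call(rbind, lapply(seq_along(genes), function(i)
      feat_row(genes[i], "CDS", (i - 1) * 20, (i - 1) * 20 + 15)))
    make_genome(strrep("A", 20 * length(genes)), feats, id = id)
  }
  m <- repertoire_matrix(list(mk("x", c("a", "b", "c")), mk("y", c("b", "c", "d"))))
  expect_setequal(core_genes(m), c("b", "c"))
  expect_equal(ncol(m), 4L)
  m1 <- repertoire_matrix(list(mk("x", c("a", "b"))))
  expect_setequal(core_genes(m1), c("a", "b"))
  m0 <- repertoire_matrix(list(mk("x", c("a", "b")), mk("y", c("c", "d"))))
  expect_length(core_genes(m0), 0L)
})

test_that("pairwise differences skip gap columns and form a metric-like matrix", {
  expect_equal(pairwise_differences(c(a = "ACGT", b = "ACGA"))["a", "b"], 1L)
  expect_equal(pairwise_differences(c(a = "AC-T", b = "ACGT"))["a", "b"], 0L)
  expect_error(pairwise_differences(c("ACGT", "ACG")), "ragged")
  set.seed(22)
  seqs <- vapply(1:3, function(i) {
    v <- sample(c("A", "C", "G", "T", "-"), 40, replace = TRUE)
    paste(v, collapse = "")
  }, character(1))
  names(seqs) <- c("x", "y", "z")
  m <- pairwise_differences(seqs)
  expect_true(isSymmetric(m))
  expect_equal(diag(m), c(x = 0L, y = 0L, z = 0L))
  # brute-force column scan oracle for one pair
  v1 <- strsplit(seqs[1], "")[[1]]; v2 <- strsplit(seqs[2], "")[[1]]
  ok <- v1 != "-" & v2 != "-"
  expect_equal(m["x", "y"], sum(v1[ok] != v2[ok]))
  # region restriction
  mr <- pairwise_differences(seqs, region = c(1, 10))
  ok10 <- ok[1:10]
  expect_equal(mr["x", "y"], sum(v1[1:10][ok10] != v2[1:10][ok10]))
})
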