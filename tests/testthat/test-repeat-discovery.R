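# Tandem arrays, dispersed families, inverted repeats, and the dot-plot.

test_that("self dot-plot marks forward and reverse-complement k-mer pairs", {
  d <- self_dotplot("ACGTACGT", k = 4)
  fwd <- d[d$strand == "+", ]
  expect_true(any(fwd$x == 0 & fwd$y == 4))
  expect_true(any(fwd$x == 4 & fwd$y == 0))
  expect_error(self_dotplot("ACG", k = 10), "exceeds")
  # random sequence: no off-diagonal forward points at k = 12
  set.seed(31)
  d2 <- self_dotplot(rand_dna(200), k = 12)
  expect_equal(nrow(d2[d2$strand == "+", ]), 0L)
  # planted duplicate block yields a parallel off-diagonal segment
  set.seed(32)
  blk <- rand_dna(60)
  s <- paste0(rand_dna(50), blk, rand_dna(40), blk, rand_dna(30))
  d3 <- self_dotplot(s, k = 12)
  seg <- d3[d3$strand == "+" & d3$y - d3$x == 100, ]
  expect_gte(nrow(seg), 40L)  # 60 - k + 1 minus none (exact copies)
})

test_that("tandem finder resolves period, copies and consensus on clean arrays", {
  tr <- find_tandem_repeats("ACGACGACGACG", min_period = 2, min_match = 80,
                            circular = FALSE)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$period, 3L)
  expect_equal(tr$copy_count, 4.0)
  expect_equal(tr$consensus, "ACG")
  expect_equal(tr$match_percent, 100)
})

test_that("a degenerate final copy is counted while junk is not absorbed", {
  tr <- find_tandem_repeats("AAAGAAAGAAAC", min_period = 2, min_match = 80,
                            circular = FALSE)
  expect_equal(tr$period, 4L)
  expect_equal(tr$copy_count, 3.0)
  expect_equal(tr$consensus, "AAAG")
  expect_equal(tr$match_percent, 91.7)  # 11 matches / 12 columns
})

test_that("a 106-copy array with 2% substitutions is recovered to the copy", {
  set.seed(33)
  B <- rand_dna(46, gc = 0.3)
  copies <- vapply(1:106, function(i) {
    v <- strsplit(B, "")[[1]]
    hit <- which(runif(46) < 0.02)
    for (p in hit) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    paste(v, collapse = "")
  }, character(1))
  s <- paste0(rand_dna(300, 0.3), paste(copies, collapse = ""), rand_dna(300, 0.3))
  tr <- find_tandem_repeats(s, min_period = 10, max_period = 300,
                            min_copies = 3, min_match = 80, circular = FALSE)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$period, 46L)
  expect_lte(abs(tr$copy_count - 106), 1)
  expect_equal(tr$consensus, B)
})

test_that("arrays spanning the origin of a circular sequence are found", {
  set.seed(34)
  unit <- rand_dna(20)
  arr <- strrep(unit, 6)
  # place the array across the origin: last 60 bp then first 60 bp
  s <- paste0(substr(arr, 61, 120), rand_dna(200), substr(arr, 1, 60))
  tr <- find_tandem_repeats(s, min_period = 10, max_period = 60,
                            min_copies = 3, min_match = 90, circular = TRUE)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$period, 20L)
  expect_true(tr$end <= tr$start)  # wrap-encoded
})

test_that("dispersed families report copies, strands and identities", {
  set.seed(35)
  blk <- rand_dna(203, 0.3)
  blk2 <- blk
  substr(blk2, 50, 50) <- if (substr(blk, 50, 50) == "A") "C" else "A"
  substr(blk2, 150, 150) <- if (substr(blk, 150, 150) == "G") "T" else "G"
  s <- paste0(rand_dna(400, 0.3), blk, rand_dna(350, 0.3), blk2, rand_dna(250, 0.3))
  fam <- find_dispersed_repeats(s, min_len = 50)
  expect_equal(length(fam), 1L)
  expect_equal(nrow(fam[[1]]$copies), 2L)
  # boundaries recovered to within a few bp (local alignment may pick up
  # a handful of coincidentally matching flank bases)
  expect_true(all(abs(fam[[1]]$copies$start - c(400L, 953L)) <= 5))
  expect_true(all(abs(fam[[1]]$copies$end - c(603L, 1156L)) <= 5))
  expect_true(all(fam[[1]]$copies$identity >= 98))
  # forward + reverse-complement placement gives opposite strands
  s2 <- paste0(rand_dna(300, 0.3), blk, rand_dna(300, 0.3), revcomp(blk),
               rand_dna(200, 0.3))
  fam2 <- find_dispersed_repeats(s2, min_len = 50)
  expect_equal(length(fam2), 1L)
  expect_setequal(fam2[[1]]$copies$strand, c("+", "-"))
  # nothing repeated: empty result
  set.seed(36)
  expect_length(find_dispersed_repeats(rand_dna(500), min_len = 50), 0L)
})

test_that("raising min_identity never increases reported copies", {
  set.seed(37)
  blk <- rand_dna(80, 0.3)
  mut <- function(x, k) {
    v <- strsplit(x, "")[[1]]
    for (p in sample(seq_along(v), k)) v[p] <- sample(setdiff(c("A","C","G","T"), v[p]), 1)
    paste(v, collapse = "")
  }
  s <- paste0(rand_dna(150), blk, rand_dna(120), mut(blk, 4), rand_dna(120),
              mut(blk, 16), rand_dna(100))
  n_copies <- vapply(c(70, 85, 96), function(thr) {
    fam <- find_dispersed_repeats(s, min_len = 50, min_identity = thr)
    sum(vapply(fam, function(f) nrow(f$copies), integer(1)))
  }, integer(1))
  expect_true(all(diff(n_copies) <= 0))
})

test_that("inverted repeats are located with arms, loop and identity", {
  ir <- find_inverted_repeats("GGGAAACCC", min_arm = 3, max_loop = 5)
  expect_equal(nrow(ir), 1L)
  expect_equal(ir$arm1_start, 0L); expect_equal(ir$arm1_end, 3L)
  expect_equal(ir$arm2_start, 6L); expect_equal(ir$arm2_end, 9L)
  expect_equal(ir$loop_len, 3L)
  ir2 <- find_inverted_repeats("ACGT", min_arm = 2, max_loop = 5)
  expect_equal(ir2$loop_len, 0L)
  expect_equal(ir2$arm_len, 2L)
})

test_that("a large diverged palindrome is recovered near-perfectly", {
  set.seed(38)
  arm <- rand_dna(286, 0.3)
  v <- strsplit(arm, "")[[1]]
  for (p in sample(286, 3)) v[p] <- sample(setdiff(c("A","C","G","T"), v[p]), 1)
  arm2 <- revcomp(paste(v, collapse = ""))
  s <- paste0(rand_dna(400, 0.3), arm, "A", arm2, rand_dna(400, 0.3))
  ir <- find_inverted_repeats(s, min_arm = 10, max_loop = 10, min_identity = 90)
  expect_equal(nrow(ir), 1L)
  expect_lte(abs(ir$arm1_start - 400L), 3)
  expect_lte(abs(ir$arm1_end - 686L), 3)
  expect_gte(ir$arm_identity, 98)
})

test_that("reverse-complementing the input mirrors tandem results", {
  set.seed(39)
  unit <- rand_dna(25)
  s <- paste0(rand_dna(100), strrep(unit, 5), rand_dna(80))
  n <- nchar(s)
  a <- find_tandem_repeats(s, min_period = 10, max_period = 60,
                           min_copies = 3, min_match = 90, circular = FALSE)
  b <- find_tandem_repeats(revcomp(s), min_period = 10, max_period = 60,
                           min_copies = 3, min_match = 90, circular = FALSE)
  expect_equal(nrow(a), 1L)
  expect_equal(nrow(b), 1L)
  expect_equal(b$period, a$period)
  expect_equal(b$start, n - a$end)
  expect_equal(b$end, n - a$start)
})
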