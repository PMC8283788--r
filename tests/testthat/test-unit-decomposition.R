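# Clustering into units, tiling arrangements, palindromic arrangements,
# tandem runs, and cross-genome unit homologs.

test_that("single-linkage clustering separates unrelated copies", {
  set.seed(41)
  a <- rand_dna(50)
  b <- rand_dna(50)
  units <- cluster_into_units(c(a, a, a, b), identity_threshold = 80)
  expect_length(units, 2L)
  counts <- sort(vapply(units, function(u) nrow(u$copies), integer(1)))
  expect_equal(counts, c(1L, 3L))
  # one copy: trivial unit at 100% identity
  u1 <- cluster_into_units(a)
  expect_length(u1, 1L)
  expect_equal(u1[[1]]$identity_range, c(100, 100))
  expect_equal(u1[[1]]$consensus, a)
})

test_that("cluster labels are assigned by descending consensus length", {
  set.seed(42)
  short <- rand_dna(20)
  long <- rand_dna(90)
  units <- cluster_into_units(c(short, short, long, long), identity_threshold = 80)
  expect_equal(units[[1]]$label, "A")
  expect_equal(nchar(units[[1]]$consensus), 90L)
  expect_equal(units[[2]]$label, "B")
  # permutation invariance of copy order
  units2 <- cluster_into_units(c(long, short, long, short), identity_threshold = 80)
  expect_equal(vapply(units2, function(u) u$consensus, character(1)),
               vapply(units, function(u) u$consensus, character(1)))
})

test_that("strand-aware clustering reunites reverse-complement copies", {
  set.seed(43)
  a <- rand_dna(60)
  units <- cluster_into_units(c(a, a, revcomp(a)), identity_threshold = 80,
                              both_strands = TRUE)
  expect_length(units, 1L)
  expect_equal(sort(units[[1]]$copies$strand), c("+", "+", "-"))
})

test_that("unit tables format ranges the way repeat-unit tables print", {
  units <- list(list(label = "A", consensus = strrep("A", 162),
                     copies = data.frame(start = 1:3, end = 2:4, strand = "+",
                                         length = c(161L, 165L, 167L),
                                         identity = c(94.4, 100, 97.0)),
                     length_range = c(161L, 167L),
                     identity_range = c(94.4, 100)),
                list(label = "F", consensus = strrep("C", 204),
                     copies = data.frame(start = 1, end = 2, strand = "+",
                                         length = 204L, identity = 99.0),
                     length_range = c(204L, 204L),
                     identity_range = c(99.0, 99.0)))
  tab <- unit_table(units)
  expect_equal(tab$length_range, c("161-167 bp", "204 bp"))
  expect_equal(tab$identity_range, c("94.4-100.0%", "99.0%"))
  expect_equal(tab$matrix_length, c(162L, 204L))
  expect_equal(nrow(unit_table(list())), 0L)
})

test_that("tiling a concatenation of consensuses reproduces the motif", {
  set.seed(44)
  cons <- list(B = rand_dna(46, .3), D = rand_dna(34, .3),
               E = rand_dna(13, .3), A = rand_dna(162, .3))
  units <- lapply(names(cons), function(l) list(label = l, consensus = cons[[l]]))
  g <- make_genome(paste0(cons$B, cons$D, cons$E, cons$A))
  a <- tile_arrangement(g, 0, g$length, units, min_identity = 80)
  expect_equal(a$motif_string, "B-D-E-A")
  expect_equal(a$cover_fraction, 1.0)
  # tandem of one unit
  g2 <- make_genome(strrep(cons$B, 5))
  a2 <- tile_arrangement(g2, 0, g2$length, units["B" == names(cons)], 80)
  expect_equal(a2$motif_string, "B-B-B-B-B")
})

test_that("token admission follows the identity threshold", {
  set.seed(45)
  D <- rand_dna(60, .3)
  v <- strsplit(D, "")[[1]]
  for (p in sample(60, 6)) v[p] <- sample(setdiff(c("A","C","G","T"), v[p]), 1)
  D_div <- paste(v, collapse = "")  # 10% diverged copy
  g <- make_genome(paste0(rand_dna(50), D_div, rand_dna(50)))
  units <- list(list(label = "D", consensus = D))
  hit80 <- tile_arrangement(g, 0, g$length, units, min_identity = 80)
  expect_equal(hit80$motif_string, "D")
  hit95 <- tile_arrangement(g, 0, g$length, units, min_identity = 95)
  expect_equal(nrow(hit95$tokens), 0L)
})

test_that("palindromic arrangements match a brute-force scan", {
  mk <- function(labels, strands) {
    n <- length(labels)
    data.frame(label = labels, strand = strands,
               local_start = (seq_len(n) - 1L) * 10L,
               local_end = seq_len(n) * 10L,
               start = (seq_len(n) - 1L) * 10L, end = seq_len(n) * 10L,
               identity = 100, stringsAsFactors = FALSE)
  }
  # the two canonical palindromic arrangements
  p1 <- mk(c("A","E","D","B","B","D","E","A"),
           c("+","+","+","+","-","-","-","-"))
  d1 <- detect_palindromic_arrangement(p1)
  expect_equal(nrow(d1), 1L)
  expect_equal(d1$n_tokens, 8L)
  expect_equal(d1$motif, "A-E-D-B-B-D-E-A")
  p2 <- mk(c("B","F","F","B"), c("+","+","-","-"))
  expect_equal(detect_palindromic_arrangement(p2)$n_tokens, 4L)
  # same labels but unmirrored strands: nothing
  p3 <- mk(c("B","C","B"), c("+","+","+"))
  expect_equal(nrow(detect_palindromic_arrangement(p3)), 0L)
  # randomized token runs against the oracle
  set.seed(46)
  for (rep in 1:40) {
    n <- sample(2:12, 1)
    labels <- sample(LETTERS[1:3], n, replace = TRUE)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    got <- detect_palindromic_arrangement(mk(labels, strands))
    want <- palindrome_oracle(labels, strands)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$first_token, unname(want[, 1])[order(want[, 1])])
      expect_equal(got$last_token, unname(want[, 2])[order(want[, 1])])
    }
  }
})

test_that("max tandem run respects label, strand and gap", {
  mk <- function(labels, strands, starts, ends) {
    data.frame(label = labels, strand = strands, local_start = starts,
               local_end = ends, start = starts, end = ends, identity = 100,
               stringsAsFactors = FALSE)
  }
  t1 <- mk(rep("B", 4), rep("+", 4), c(0, 10, 20, 40), c(10, 20, 30, 50))
  expect_equal(max_tandem_run(t1, "B"), 3L)  # the 10-bp gap breaks the run
  t2 <- mk(c("B", "C", "B", "C"), rep("+", 4), c(0, 10, 20, 30), c(10, 20, 30, 40))
  expect_equal(max_tandem_run(t2, "B"), 1L)
  empty_tokens <- data.frame(label = character(0), strand = character(0),
                             local_start = integer(0), local_end = integer(0),
                             start = integer(0), end = integer(0),
                             identity = numeric(0))
  expect_equal(max_tandem_run(empty_tokens, "B"), 0L)
  # strand switch breaks a run
  t3 <- mk(rep("B", 4), c("+", "+", "-", "-"), c(0, 10, 20, 30), c(10, 20, 30, 40))
  expect_equal(max_tandem_run(t3, "B"), 2L)
})

test_that("unit homolog search counts planted copies across a genome", {
  set.seed(47)
  cons <- rand_dna(100, 0.3)
  mut <- function(x, rate) {
    v <- strsplit(x, "")[[1]]
    for (p in which(runif(length(v)) < rate)) {
      v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    }
    paste(v, collapse = "")
  }
  parts <- character(0)
  for (i in 1:12) parts <- c(parts, rand_dna(120, 0.3), mut(cons, 0.05))
  g <- make_genome(paste0(paste(parts, collapse = ""), rand_dna(150, 0.3)))
  hits <- find_unit_homologs(cons, g, min_identity = 80, min_cover = 0.5)
  expect_equal(nrow(hits), 12L)
  # an unrelated genome has none
  set.seed(48)
  g2 <- make_genome(rand_dna(2000, 0.3))
  expect_equal(nrow(find_unit_homologs(cons, g2, min_identity = 80,
                                       min_len = 55)), 0L)
  # the consensus itself: one full-length perfect copy
  g3 <- make_genome(cons)
  self <- find_unit_homologs(cons, g3)
  expect_equal(nrow(self), 1L)
  expect_equal(self$identity, 100)
  expect_equal(self$length, 100L)
})
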