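# Gene orders, synteny blocks, rearrangement classification, and
# repeat-adjacency reporting.

order_df <- function(names, strands, id = "g") {
  df <- data.frame(name = names, strand = strands, stringsAsFactors = FALSE)
  attr(df, "id") <- id
  df
}

test_that("gene order sorts by position and disambiguates duplicates", {
  feats <- rbind(feat_row("b", "CDS", 50, 60),
                 feat_row("a", "CDS", 5, 15),
                 feat_row("trnM-CAU", "tRNA", 20, 28, "-", "CAT"),
                 feat_row("trnM-CAU", "tRNA", 70, 78, "+", "CAT"))
  g <- make_genome(strrep("A", 100), feats)
  o <- gene_order(g)
  expect_equal(o$genes$name, c("a", "trnM-CAU.1", "b", "trnM-CAU.2"))
  # rotation preserves the circular adjacency set (duplicate-free genome,
  # since occurrence indices of duplicated tRNAs are phase-dependent)
  feats2 <- rbind(feat_row("a", "CDS", 5, 15), feat_row("b", "CDS", 20, 28),
                  feat_row("c", "CDS", 50, 60), feat_row("d", "CDS", 70, 78))
  g2 <- make_genome(strrep("A", 100), feats2)
  adj <- function(ord) {
    n <- nrow(ord$genes)
    sort(paste(ord$genes$name, ord$genes$name[c(2:n, 1)]))
  }
  expect_equal(adj(gene_order(rotate_genome(g2, 40))), adj(gene_order(g2)))
})

test_that("identical orders give one block; inversions split with flipped strand", {
  a <- order_df(c("x", "y", "z"), c("+", "+", "+"))
  b <- find_synteny_blocks(a, a)
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_genes, 3L)
  expect_equal(b$orientation, "+")
  # y,z inverted as a pair
  b2 <- find_synteny_blocks(a, order_df(c("x", "z", "y"), c("+", "-", "-")))
  expect_equal(nrow(b2), 2L)
  x_blk <- b2[b2$genes == "x", ]
  yz_blk <- b2[b2$genes == "y,z", ]
  expect_equal(x_blk$orientation, "+")
  expect_equal(yz_blk$orientation, "-")
  expect_error(find_synteny_blocks(a, order_df(c("p", "q"), c("+", "+"))),
               "share no genes")
})

test_that("genes private to one genome are skipped transparently", {
  a <- order_df(c("x", "y", "z"), c("+", "+", "+"))
  b <- order_df(c("x", "w", "y", "z"), c("+", "+", "+", "+"))
  blk <- find_synteny_blocks(a, b)
  expect_equal(nrow(blk), 1L)  # x-y-z contiguous among shared genes
})

test_that("block layout mimicking the six-strain comparison is recovered", {
  # genome 1 regions a-b-c-d-e; genome 2 has b inverted and c moved after
  # d-e.  In a pairwise comparison d and e stay contiguous and collinear,
  # so they are reported as one block.
  genes <- lapply(letters[1:5], function(b) paste0(b, 1:3))
  a <- order_df(unlist(genes), rep("+", 15))
  b_names <- c(genes[[1]], rev(genes[[2]]), genes[[4]], genes[[5]], genes[[3]])
  b_strands <- c(rep("+", 3), rep("-", 3), rep("+", 9))
  b <- order_df(b_names, b_strands)
  blk <- find_synteny_blocks(a, b)
  expect_equal(nrow(blk), 4L)
  expect_equal(blk$genes,
               c("a1,a2,a3", "b1,b2,b3", "c1,c2,c3", "d1,d2,d3,e1,e2,e3"))
  expect_equal(blk$orientation, c("+", "-", "+", "+"))
  ev <- classify_rearrangements(blk)
  expect_equal(sum(ev$type == "inversion"), 1L)
  expect_equal(ev$block[ev$type == "inversion"], "b")
  tr <- ev[ev$type == "translocation", ]
  expect_gte(nrow(tr), 1L)
  # the displaced material involves block c and the d-e block
  expect_true(all(tr$block %in% c("c", "d")))
})

test_that("identical genomes yield no rearrangement events", {
  a <- order_df(sprintf("g%d", 1:6), rep(c("+", "-"), each = 3))
  blk <- find_synteny_blocks(a, a)
  expect_equal(nrow(classify_rearrangements(blk)), 0L)
})

test_that("planted single inversions are recovered exactly", {
  set.seed(61)
  for (rep in 1:25) {
    n <- sample(8:14, 1)
    a <- random_gene_order(n)
    len <- sample(2:(n - 2), 1)
    from <- sample(2:(n - len), 1)  # keep gene 1 outside to fix the phase
    b <- invert_segment(a, from:(from + len - 1L))
    blk <- find_synteny_blocks(a, b)
    ev <- classify_rearrangements(blk)
    inv <- ev[ev$type == "inversion", ]
    expect_equal(nrow(inv), 1L)
    inv_genes <- strsplit(blk$genes[blk$block == inv$block], ",")[[1]]
    planted <- a$name[from:(from + len - 1L)]
    # on a circle, inverting a segment equals inverting its complement
    # combined with a global flip; either description is exact
    ok <- setequal(inv_genes, planted) ||
      setequal(inv_genes, setdiff(a$name, planted))
    expect_true(ok)
    expect_equal(nrow(ev[ev$type == "translocation", ]), 0L)
  }
})

test_that("planted reciprocal translocations are recovered", {
  set.seed(62)
  for (rep in 1:25) {
    n <- sample(9:14, 1)
    a <- random_gene_order(n)
    # swap two adjacent internal segments
    l1 <- sample(1:3, 1); l2 <- sample(1:3, 1)
    from <- sample(2:(n - l1 - l2), 1)
    s1 <- from:(from + l1 - 1L)
    s2 <- (from + l1):(from + l1 + l2 - 1L)
    b <- a[c(setdiff(1:(from - 1L), 0), s2, s1,
             setdiff((from + l1 + l2):n, 0))[1:n], , drop = FALSE]
    rownames(b) <- NULL
    attr(b, "id") <- "b"
    blk <- find_synteny_blocks(a, b)
    ev <- classify_rearrangements(blk)
    expect_equal(nrow(ev[ev$type == "inversion", ]), 0L)
    tr <- ev[ev$type == "translocation", ]
    expect_gte(nrow(tr), 1L)
    swapped <- c(a$name[s1], a$name[s2])
    tr_genes <- unlist(strsplit(blk$genes[blk$block %in% tr$block], ","))
    expect_true(all(tr_genes %in% swapped))
  }
})

test_that("block boundaries near repeat regions are flagged", {
  feats <- rbind(feat_row("g1", "CDS", 100, 500),
                 feat_row("g2", "CDS", 9500, 10000),
                 feat_row("g3", "CDS", 13000, 13500))
  g <- make_genome(strrep("A", 20000), feats)
  ord <- gene_order(g)
  blocks <- data.frame(block = c("a", "b"), n_genes = c(2L, 1L),
                       genes = c("g1,g2", "g3"), orientation = "+",
                       a_pos = c(1L, 3L), b_pos = c(1L, 3L),
                       stringsAsFactors = FALSE)
  regions <- data.frame(start = 10100L, end = 12000L)
  rep_report <- repeat_adjacency_report(blocks, ord, regions, g$length)
  b_end <- rep_report[rep_report$block == "a" & rep_report$boundary == "end", ]
  expect_equal(b_end$distance, 100)
  expect_true(b_end$flagged)
  inside <- repeat_adjacency_report(blocks, ord,
                                    data.frame(start = 9000L, end = 11000L),
                                    g$length)
  expect_equal(inside$distance[inside$block == "a" & inside$boundary == "end"], 0)
  none <- repeat_adjacency_report(blocks, ord,
                                  data.frame(start = integer(0), end = integer(0)),
                                  g$length)
  expect_true(all(is.na(none$distance)))
})
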