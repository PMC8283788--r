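# GenBank/FASTA parsing, circular coordinate arithmetic and rotation.

gb_record <- function(loc_lines, seq = "ACGTACGTACGTACGTACGT", circular = TRUE) {
  lines <- c(sprintf("LOCUS       TEST %d bp    DNA     %s UNA",
                     nchar(seq), if (circular) "circular" else "linear"),
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", nchar(seq)),
             loc_lines, "ORIGIN")
  s <- tolower(seq)
  pos <- seq(1L, nchar(s), by = 60L)
  for (p in pos) lines <- c(lines, sprintf("%9d %s", p, substr(s, p, p + 59L)))
  c(lines, "//")
}

write_tmp <- function(lines) {
  f <- tempfile(fileext = ".gb")
  writeLines(lines, f)
  f
}

test_that("GenBank locations convert to 0-based half-open coordinates", {
  f <- write_tmp(gb_record(c('     CDS             5..10',
                             '                     /gene="cox1"',
                             '     tRNA            complement(3..8)',
                             '                     /gene="trnR-ACG"')))
  g <- read_genbank(f)
  cds <- g$features[g$features$kind == "CDS", ]
  expect_equal(cds$start, 4L)
  expect_equal(cds$end, 10L)
  expect_equal(cds$strand, "+")
  trna <- g$features[g$features$kind == "tRNA", ]
  expect_equal(trna$start, 2L)
  expect_equal(trna$end, 8L)
  expect_equal(trna$strand, "-")
  expect_equal(trna$anticodon, "ACG")
})

test_that("origin-spanning joins are kept as single wrap-encoded features", {
  f <- write_tmp(gb_record(c('     CDS             join(15..20,1..6)',
                             '                     /gene="wrap"')))
  g <- read_genbank(f)
  w <- g$features[g$features$name == "wrap", ]
  expect_equal(w$start, 14L)
  expect_equal(w$end, 6L)
  expect_equal(span_length <- ((w$end - w$start) %% g$length), 12L)
})

test_that("multi-record and zero-length inputs are rejected", {
  f <- write_tmp(c(gb_record(character(0)), gb_record(character(0))))
  expect_error(read_genbank(f), "multi-record")
  f2 <- write_tmp(c("LOCUS       E 0 bp DNA circular", "ORIGIN", "//"))
  expect_error(read_genbank(f2), "zero-length")
})

test_that("subsequence handles wraparound, strands and the full circle", {
  g <- make_genome("ACGTAC")
  expect_equal(subsequence(g, 4, 2), "ACAC")
  expect_equal(subsequence(g, 0, 3, "-"), "CGT")
  expect_equal(subsequence(g, 2, 2), "GTACAC")  # start==end: whole circle
  expect_equal(subsequence(g, 0, 6), "ACGTAC")
})

test_that("rotation anchors a gene at the origin and preserves content", {
  set.seed(11)
  s <- rand_dna(100)
  feats <- rbind(feat_row("cox1", "CDS", 40, 70, "+"),
                 feat_row("nad1", "CDS", 80, 95, "-"))
  g <- make_genome(s, feats)
  r <- rotate_to_gene(g, "cox1")
  f <- r$features[r$features$name == "cox1", ]
  expect_equal(f$start, 0L)
  expect_equal(f$end, 30L)
  expect_equal(f$strand, "+")
  # every gene sequence is unchanged by rotation
  for (nm in c("cox1", "nad1")) {
    before <- g$features[g$features$name == nm, ]
    after <- r$features[r$features$name == nm, ]
    expect_equal(feature_seq <- subsequence(r, after$start, after$end %% r$length, after$strand),
                 subsequence(g, before$start, before$end %% g$length, before$strand))
  }
  # idempotence
  r2 <- rotate_to_gene(r, "cox1")
  expect_identical(r2$sequence, r$sequence)
  expect_identical(r2$features, r$features)
})

test_that("rotating to a minus-strand gene reflects the molecule", {
  set.seed(12)
  g <- make_genome(rand_dna(100), feat_row("cox1", "CDS", 40, 70, "-"))
  cox1_before <- subsequence(g, 40, 70, "-")
  r <- rotate_to_gene(g, "cox1")
  f <- r$features[r$features$name == "cox1", ]
  expect_equal(f$start, 0L)
  expect_equal(f$strand, "+")
  expect_equal(subsequence(r, 0, 30, "+"), cox1_before)
  expect_error(rotate_to_gene(g, "nope"), "not found")
})

test_that("subsequences over a partition reconstruct the sequence", {
  set.seed(13)
  g <- make_genome(rand_dna(57))
  cuts <- c(0, sort(sample(1:56, 5)), 57)
  parts <- vapply(seq_len(length(cuts) - 1L), function(i)
    subsequence(g, cuts[i], cuts[i + 1L] %% 57), character(1))
  expect_equal(paste(parts, collapse = ""), g$sequence)
})

test_that("long N runs become explicit gap features", {
  g <- circular_genome("p", paste0(strrep("A", 50), strrep("N", 120), strrep("G", 50)))
  gap <- g$features[g$features$kind == "gap", ]
  expect_equal(nrow(gap), 1L)
  expect_equal(gap$start, 50L)
  expect_equal(gap$end, 170L)
  expect_error(circular_genome("bad", "ACGTRYK"), "other than")
})

test_that("FASTA and GenBank round-trips preserve the genome", {
  set.seed(14)
  g <- make_genome(rand_dna(200), rbind(
    feat_row("cox1", "CDS", 10, 100, "+"),
    feat_row("trnW-CCA", "tRNA", 120, 192, "-", "CCA")))
  ff <- tempfile(fileext = ".fasta")
  write_fasta(g, ff)
  expect_identical(read_fasta_genome(ff)$sequence, g$sequence)
  fg <- tempfile(fileext = ".gb")
  write_genbank(g, fg)
  g2 <- read_genbank(fg)
  expect_identical(g2$sequence, g$sequence)
  expect_equal(g2$features$name, g$features$name)
  expect_equal(g2$features$start, g$features$start)
  expect_equal(g2$features$end, g$features$end)
  expect_equal(g2$features$strand, g$features$strand)
})

test_that("write_outputs emits the documented bundle", {
  set.seed(15)
  g <- make_genome(rand_dna(100))
  units <- list(list(label = "A",
                     consensus = "ACGTACGTAC",
                     copies = data.frame(start = 10L, end = 20L, strand = "+",
                                         length = 10L, identity = 100)))
  dir <- tempfile()
  write_outputs(g, units, list(), dir)
  bed <- read.table(file.path(dir, "repeat_copies.bed"), sep = "\t")
  expect_equal(bed$V1, "toy")
  expect_equal(bed$V2, 10L)
  expect_equal(bed$V3, 20L)
  expect_equal(bed$V4, "A")
  expect_equal(bed$V5, 1000L)
  expect_equal(bed$V6, "+")
  tab <- read.table(file.path(dir, "unit_table.tsv"), sep = "\t", header = TRUE)
  expect_equal(tab$unit, "A")
  # empty unit set still writes a header-only table
  dir2 <- tempfile()
  write_outputs(g, list(), list(), dir2)
  tab2 <- read.table(file.path(dir2, "unit_table.tsv"), sep = "\t", header = TRUE)
  expect_equal(nrow(tab2), 0L)
})
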