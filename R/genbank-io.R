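# Reading and writing single-record GenBank flat files and FASTA.
# Only the location forms that occur in small organelle records are
# supported: `a..b`, `complement(a..b)`, and origin-spanning
# `join(a..L,1..b)` (optionally inside complement()). Coordinates are
# converted to 0-based half-open at this boundary and never leak out
# in GenBank form.

.parse_gb_location <- function(loc, L) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1L]]
    seg <- t(vapply(parts, function(p) {
      m <- as.integer(strsplit(p, "..", fixed = TRUE)[[1L]])
      if (length(m) == 1L) m <- c(m, m)
      m
    }, integer(2)))
    if (nrow(seg) == 2L && seg[1L, 2L] == L && seg[2L, 1L] == 1L) {
      # origin-spanning join -> wrap-encoded feature
      return(list(start = seg[1L, 1L] - 1L, end = seg[2L, 2L], strand = strand))
    }
    stop("unsupported join() location (only origin-spanning joins are handled): ", loc)
  }
  m <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1L]])
  if (length(m) == 1L) m <- c(m, m)
  if (anyNA(m)) stop("unparseable location: ", loc)
  list(start = m[1L] - 1L, end = m[2L], strand = strand)
}

.gb_qualifier <- function(block, name) {
  rx <- sprintf('/%s="?([^"\n]*)"?', name)
  m <- regmatches(block, regexpr(rx, block))
  if (length(m) == 0L) return(NA_character_)
  sub(rx, "\\1", m)
}

.trna_anticodon <- function(name) {
  m <- regmatches(name, regexpr("-[ACGUTacgut]{3}$", name))
  if (length(m) == 0L) return(NA_character_)
  toupper(chartr("Uu", "Tt", sub("-", "", m)))
}

#' Read a single-record GenBank flat file as a circular genome
#'
#' Captures CDS, tRNA, rRNA, repeat_region and gap features with strand,
#' converting GenBank 1-based inclusive locations to 0-based half-open.
#' Origin-spanning `join()` locations are preserved as single wrap-encoded
#' features. The sequence is uppercased; ambiguity codes other than N are
#' rejected. Runs of 100 or more Ns become explicit gap features.
#'
#' @param path Path to a GenBank flat file containing exactly one record.
#' @return A [circular_genome()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_idx <- grep("^LOCUS", lines)
  if (length(locus_idx) == 0L) stop("not a GenBank flat file (no LOCUS line)")
  if (length(locus_idx) > 1L) stop("multi-record GenBank files are not supported")
  locus <- lines[locus_idx]
  id <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1L]][1L]
  is_circular <- grepl("circular", locus, ignore.case = TRUE)

  origin_idx <- grep("^ORIGIN", lines)
  if (length(origin_idx) == 0L) stop("no ORIGIN section")
  end_idx <- grep("^//", lines)
  end_idx <- if (length(end_idx)) end_idx[1L] else length(lines) + 1L
  seq_lines <- if (end_idx - 1L >= origin_idx[1L] + 1L) {
    lines[(origin_idx[1L] + 1L):(end_idx - 1L)]
  } else character(0)
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) stop("zero-length sequence")
  L <- nchar(sequence)

  feats <- empty_features()
  feat_idx <- grep("^FEATURES", lines)
  if (length(feat_idx)) {
    fl <- lines[(feat_idx[1L] + 1L):(origin_idx[1L] - 1L)]
    is_key <- grepl("^ {1,10}\\S", fl) & !grepl("^ {12,}", fl)
    starts <- which(is_key)
    for (si in seq_along(starts)) {
      from <- starts[si]
      to <- if (si < length(starts)) starts[si + 1L] - 1L else length(fl)
      block_lines <- fl[from:to]
      key <- strsplit(trimws(block_lines[1L]), "\\s+")[[1L]]
      kind <- key[1L]
      if (!(kind %in% c("CDS", "tRNA", "rRNA", "repeat_region", "gap"))) next
      # location may continue on lines that are not qualifiers
      loc <- key[2L]
      j <- 2L
      while (j <= length(block_lines) && !grepl("^\\s*/", block_lines[j])) {
        loc <- paste0(loc, trimws(block_lines[j])); j <- j + 1L
      }
      block <- paste(block_lines, collapse = "\n")
      pos <- .parse_gb_location(loc, L)
      name <- .gb_qualifier(block, "gene")
      if (is.na(name)) name <- .gb_qualifier(block, "product")
      if (is.na(name)) name <- sprintf("%s_%d", kind, si)
      anticodon <- if (kind == "tRNA") .trna_anticodon(name) else NA_character_
      feats <- rbind(feats, data.frame(
        name = name, kind = kind, start = pos$start, end = pos$end,
        strand = pos$strand, anticodon = anticodon, stringsAsFactors = FALSE))
    }
  }
  circular_genome(id, sequence, feats, is_circular)
}

.format_gb_location <- function(start, end, strand, L) {
  loc <- if (end <= start) {
    sprintf("join(%d..%d,1..%d)", start + 1L, L, end)
  } else {
    sprintf("%d..%d", start + 1L, end)
  }
  if (strand == "-") loc <- sprintf("complement(%s)", loc)
  loc
}

#' Write a circular genome as a minimal GenBank flat file
#'
#' @param g A [circular_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s UNA",
                     g$id, g$length, if (g$is_circular) "circular" else "linear"),
             con)
  writeLines(sprintf("DEFINITION  %s.", g$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", g$length), con)
  f <- g$features
  for (i in seq_len(nrow(f))) {
    loc <- .format_gb_location(f$start[i], f$end[i], f$strand[i], g$length)
    writeLines(sprintf("     %-16s%s", f$kind[i], loc), con)
    writeLines(sprintf('                     /gene="%s"', f$name[i]), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(g$sequence)
  pos <- seq(1L, nchar(s), by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, nchar(s)))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a FASTA file as a circular genome without annotations
#' @param path Path to a FASTA file with a single sequence.
#' @param is_circular Logical, default `TRUE`.
#' @return A [circular_genome()].
#' @export
read_fasta_genome <- function(path, is_circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) stop("expected exactly one FASTA record, found ", length(ss))
  id <- strsplit(names(ss)[1L], "\\s+")[[1L]][1L]
  circular_genome(id, as.character(ss[[1L]]), is_circular = is_circular)
}

#' Write a genome as FASTA
#' @param g A [circular_genome()].
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(g, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(g$sequence)
  names(ss) <- g$id
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Write the standard analysis bundle for one genome
#'
#' Emits `sequence.fasta`, `repeat_copies.bed` (BED6, name = unit label,
#' score = identity x 10), `unit_table.tsv`, and `arrangements.json`.
#'
#' @param g A [circular_genome()].
#' @param units List of repeat units (see [cluster_into_units()]); may be empty.
#' @param arrangements List of arrangements (see [tile_arrangement()]); may be
#'   empty.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_outputs <- function(g, units = list(), arrangements = list(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(g, file.path(dir, "sequence.fasta"))

  bed <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                    name = character(0), score = integer(0), strand = character(0))
  for (u in units) {
    cp <- u$copies
    if (nrow(cp)) {
      bed <- rbind(bed, data.frame(chrom = g$id, start = cp$start, end = cp$end,
                                   name = u$label,
                                   score = as.integer(round(cp$identity * 10)),
                                   strand = cp$strand))
    }
  }
  utils::write.table(bed, file.path(dir, "repeat_copies.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  tab <- unit_table(units)
  utils::write.table(tab, file.path(dir, "unit_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  arr <- lapply(arrangements, function(a) {
    list(region = c(a$region_start, a$region_end),
         motif_string = a$motif_string,
         cover_fraction = a$cover_fraction,
         tokens = a$tokens)
  })
  jsonlite::write_json(arr, file.path(dir, "arrangements.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
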