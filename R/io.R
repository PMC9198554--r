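# iohub: minimal-subset readers/writers for the pipeline's file formats.
#
# Coordinate conventions: internal representation and BED are 0-based
# half-open; SAM, VCF and the marker map are 1-based on disk. Every writer
# has a matching reader and the pair round-trips exactly on valid data.

#' Write/read FASTA
#' @param seqs named list or character vector of sequences (or a `Genome`).
#' @param file path.
#' @rdname fasta_io
#' @export
write_fasta <- function(seqs, file) {
  if (inherits(seqs, "Genome")) seqs <- seqs$seq
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' @param set `"recipient"` or `"donor"` for the returned `Genome`.
#' @return `read_fasta` returns a `Genome`.
#' @rdname fasta_io
#' @export
read_fasta <- function(file, set = "recipient") {
  x <- Biostrings::readDNAStringSet(file)
  new_genome(setNames(as.list(as.character(x)), names(x)), set)
}

sam_flag <- function(rec) {
  f <- 0L
  f <- f + ifelse(rec$paired, 1L, 0L)
  f <- f + ifelse(rec$proper_pair & rec$paired, 2L, 0L)
  f <- f + ifelse(rec$unmapped, 4L, 0L)
  f <- f + ifelse(rec$strand == "-", 16L, 0L)
  f <- f + ifelse(rec$duplicate, 1024L, 0L)
  f <- f + ifelse(rec$supplementary, 2048L, 0L)
  f
}

#' Write/read the SAM subset used by the pipeline
#'
#' Eleven mandatory columns; QUAL is written as `*`. FLAG bits carried:
#' paired 0x1, proper pair 0x2, unmapped 0x4, reverse strand 0x10,
#' duplicate 0x400, supplementary 0x800. POS/PNEXT are 1-based on disk.
#' @param records `alignment_records`.
#' @param file path.
#' @param chrom_lengths optional named lengths for `@SQ` headers.
#' @rdname sam_io
#' @export
write_sam <- function(records, file, chrom_lengths = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  if (!is.null(chrom_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                       as.integer(chrom_lengths)), con)
  }
  if (nrow(records) > 0L) {
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t*",
                     records$read_id, sam_flag(records), records$chrom,
                     records$pos + 1L, records$mapq, records$cigar,
                     "=", ifelse(is.na(records$mate_pos), 0L,
                                 records$mate_pos + 1L),
                     records$bases)
    writeLines(lines, con)
  }
  invisible(file)
}

cigar_lengths <- function(cigar, read_id = "?") {
  cg <- parse_cigar(cigar, read_id)
  list(ref = sum(cg$len[cg$op %in% c("M", "D")]),
       query = sum(cg$len[cg$op %in% c("M", "I", "S")]))
}

#' @param chrom_lengths_check optional named lengths; records whose CIGAR
#'   consumes reference beyond the chromosome end are rejected.
#' @return `read_sam` returns `alignment_records` (0-based `pos`).
#' @rdname sam_io
#' @export
read_sam <- function(file, chrom_lengths_check = NULL) {
  lines <- readLines(file)
  body <- which(!startsWith(lines, "@"))
  out <- vector("list", length(body))
  for (k in seq_along(body)) {
    ln <- body[k]
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 11L) {
      abort_user(sprintf("malformed SAM record at line %d: %d fields", ln,
                         length(fields)))
    }
    flag <- suppressWarnings(as.integer(fields[2]))
    pos1 <- suppressWarnings(as.integer(fields[4]))
    if (is.na(flag) || is.na(pos1)) {
      abort_user(sprintf("malformed SAM record at line %d", ln))
    }
    cigar <- fields[6]
    seq <- fields[10]
    if (cigar != "*") {
      cl <- cigar_lengths(cigar, fields[1])
      if (cl$query != nchar(seq)) {
        abort_user(sprintf(
          "line %d: CIGAR %s implies %d query bases but SEQ has %d",
          ln, cigar, cl$query, nchar(seq)))
      }
      if (!is.null(chrom_lengths_check) &&
          fields[3] %in% names(chrom_lengths_check) &&
          pos1 - 1L + cl$ref > chrom_lengths_check[[fields[3]]]) {
        abort_user(sprintf("line %d: alignment overruns chromosome %s", ln,
                           fields[3]))
      }
    }
    pnext <- as.integer(fields[8])
    out[[k]] <- data.frame(
      read_id = fields[1], chrom = fields[3], pos = pos1 - 1L,
      mapq = as.integer(fields[5]),
      paired = bitwAnd(flag, 1L) > 0L,
      proper_pair = bitwAnd(flag, 2L) > 0L,
      unmapped = bitwAnd(flag, 4L) > 0L,
      supplementary = bitwAnd(flag, 2048L) > 0L,
      duplicate = bitwAnd(flag, 1024L) > 0L,
      cigar = cigar, bases = seq,
      mate_pos = if (pnext == 0L) NA_integer_ else pnext - 1L,
      strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+",
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    utils::head(data.frame(read_id = character(), chrom = character(),
                           pos = integer(), mapq = integer(), paired = logical(),
                           proper_pair = logical(), unmapped = logical(),
                           supplementary = logical(), duplicate = logical(),
                           cigar = character(), bases = character(),
                           mate_pos = integer(), strand = character(),
                           stringsAsFactors = FALSE), 0L)
  new_alignment_records(res)
}

#' Write/read the VCF subset (GT, DP, AD)
#'
#' Positions are 1-based on disk. The FILTER column carries `PASS` or the
#' suitability-filter reason code.
#' @param results `FilterResult`/`VariantCandidate` data frame (0-based
#'   `pos`; optional `status`/`reason` columns drive FILTER).
#' @param file path.
#' @rdname vcf_io
#' @export
write_vcf <- function(results, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE"), con)
  if (nrow(results) > 0L) {
    filt <- if ("status" %in% names(results)) {
      ifelse(results$status == "PASS", "PASS", results$reason)
    } else "."
    gt <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")[results$genotype]
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t%s\t.\tGT:DP:AD\t%s:%d:%d,%d",
                       results$chrom, results$pos + 1L,
                       sprintf("%s_%d", results$chrom, results$pos + 1L),
                       results$ref, results$alt, filt, gt,
                       results$DP, results$AD_ref, results$AD_alt), con)
  }
  invisible(file)
}

#' @return `read_vcf` returns a `VariantCandidate` data frame with
#'   `status`/`reason` recovered from FILTER (0-based `pos`).
#' @rdname vcf_io
#' @export
read_vcf <- function(file) {
  lines <- readLines(file)
  body <- which(!startsWith(lines, "#"))
  out <- vector("list", length(body))
  for (k in seq_along(body)) {
    ln <- body[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 10L) abort_user(sprintf("malformed VCF record at line %d", ln))
    pos1 <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos1) || pos1 < 1L) {
      abort_user(sprintf("line %d: VCF positions are 1-based; got %s", ln, f[2]))
    }
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    val <- strsplit(f[10], ":", fixed = TRUE)[[1]]
    gt <- val[match("GT", fmt)]
    dp <- as.integer(val[match("DP", fmt)])
    ad <- as.integer(strsplit(val[match("AD", fmt)], ",", fixed = TRUE)[[1]])
    out[[k]] <- data.frame(
      chrom = f[1], pos = pos1 - 1L, ref = f[4], alt = f[5],
      genotype = c("0/0" = "hom_ref", "0/1" = "het", "1/1" = "hom_alt")[gt],
      DP = dp, AD_ref = ad[1], AD_alt = ad[2],
      multiallelic = FALSE,
      status = if (f[7] %in% c(".", "PASS")) "PASS" else "FAIL",
      reason = if (f[7] %in% c(".", "PASS")) NA_character_ else f[7],
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else NULL
  if (is.null(res)) {
    res <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), genotype = character(), DP = integer(),
                      AD_ref = integer(), AD_alt = integer(),
                      multiallelic = logical(), status = character(),
                      reason = character(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Write/read BED (0-based half-open)
#' @param df data frame with `chrom, start, end` and optional `name, score`.
#' @param file path.
#' @rdname bed_io
#' @export
write_bed <- function(df, file) {
  name <- df$name %||% rep(".", nrow(df))
  score <- df$score %||% rep(0L, nrow(df))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s", df$chrom, df$start, df$end,
                     name, score), file)
  invisible(file)
}

#' @rdname bed_io
#' @export
read_bed <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  out <- lapply(seq_along(lines), function(ln) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) abort_user(sprintf("malformed BED record at line %d", ln))
    start <- as.integer(f[2]); end <- as.integer(f[3])
    if (is.na(start) || is.na(end) || end <= start || start < 0L) {
      abort_user(sprintf("line %d: BED interval must be 0-based half-open", ln))
    }
    data.frame(chrom = f[1], start = start, end = end,
               name = if (length(f) >= 4L) f[4] else ".",
               score = if (length(f) >= 5L) f[5] else "0",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out) %||%
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character(), score = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Write/read the marker map TSV
#'
#' Columns `marker_id, chrom, pos_1based, set_id, specificity`; internal
#' marker frames use 0-based `pos`.
#' @param markers marker data frame (`marker_id, chrom, pos, set_id,
#'   specificity`).
#' @param file path.
#' @rdname markermap_io
#' @export
write_marker_map <- function(markers, file) {
  df <- data.frame(marker_id = markers$marker_id, chrom = markers$chrom,
                   pos_1based = markers$pos + 1L,
                   set_id = markers$set_id %||% 4L,
                   specificity = markers$specificity %||% "nonspecific",
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname markermap_io
#' @export
read_marker_map <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  needed <- c("marker_id", "chrom", "pos_1based", "set_id", "specificity")
  if (!all(needed %in% names(df))) {
    abort_user(sprintf("marker map must have columns: %s",
                       paste(needed, collapse = ", ")))
  }
  if (any(df$pos_1based < 1L)) abort_user("marker map positions are 1-based")
  if (anyDuplicated(df$marker_id)) abort_user("duplicate marker ids")
  if (!all(df$specificity %in% c("At", "G", "nonspecific"))) {
    abort_user("specificity must be At, G or nonspecific")
  }
  data.frame(marker_id = df$marker_id, chrom = df$chrom,
             pos = df$pos_1based - 1L, set_id = df$set_id,
             specificity = df$specificity, stringsAsFactors = FALSE)
}

#' Write/read the genotype matrix CSV
#'
#' Lines x markers; values 0 (hom recipient), 1 (het), 2 (hom donor), NA
#' (no call). First column is `line_id`.
#' @param gm integer matrix with dimnames.
#' @param file path.
#' @rdname genomatrix_io
#' @export
write_genotype_matrix <- function(gm, file) {
  df <- data.frame(line_id = rownames(gm), gm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname genomatrix_io
#' @export
read_genotype_matrix <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "line_id") abort_user("first column must be line_id")
  gm <- as.matrix(df[, -1, drop = FALSE])
  mode(gm) <- "integer"
  rownames(gm) <- df$line_id
  bad <- !(gm %in% c(0L, 1L, 2L) | is.na(gm))
  if (any(bad)) abort_user("genotype values must be 0, 1, 2 or NA")
  gm
}

#' Write a pedigree TSV
#' @param lines list of `sim_line`.
#' @param file path.
#' @param parents optional data frame `line_id, mother, father`.
#' @export
write_pedigree <- function(lines, file, parents = NULL) {
  df <- data.frame(line_id = vapply(lines, `[[`, "", "line_id"),
                   generation = vapply(lines, `[[`, "", "generation"),
                   stringsAsFactors = FALSE)
  if (!is.null(parents)) df <- merge(df, parents, by = "line_id", all.x = TRUE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
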