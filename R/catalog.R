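# introgression_core: cross-line unique-segment catalog, coverage and
# summary statistics.

#' Build the unique-segment catalog from per-line homozygous segments
#'
#' Segments are equivalent iff they lie on the same recipient chromosome
#' and have exactly the same support-marker signature (the only
#' marker-resolution-faithful equivalence). Whole-chromosome classes
#' (support = every panel marker on the chromosome) are named by the donor
#' chromosome alone (e.g. `4At`); all others are named
#' `{donor chromosome}.{recipient genome letter}{ordinal}` with ordinals
#' assigned within each (donor chromosome, recipient letter) by ascending
#' outer start, ties by ascending outer end, then larger signature first.
#'
#' @param segments homozygous segments with donor chromosomes assigned
#'   ([assign_donor_chromosome()]); het rows are ignored.
#' @param markers marker data frame.
#' @param chrom_lengths named chromosome lengths.
#' @return catalog data frame: `name, donor_chrom, donor_subgenome,
#'   recipient_chrom, recipient_letter, ordinal, whole_chromosome,
#'   signature, n_members, member_lines, outer_start, outer_end,
#'   ambiguous_donor`.
#' @export
build_catalog <- function(segments, markers, chrom_lengths) {
  hom <- segments[segments$zygosity == "hom", , drop = FALSE]
  if (nrow(hom) == 0L) return(empty_catalog())
  n_panel <- table(markers$chrom)
  key <- paste(hom$chrom, hom$support, sep = "|")
  rows <- lapply(split(seq_len(nrow(hom)), key), function(ix) {
    r <- hom[ix[1], ]
    data.frame(
      donor_chrom = r$donor_chrom, donor_subgenome = r$donor_subgenome,
      recipient_chrom = r$chrom,
      recipient_letter = slot_subgenome(r$chrom),
      whole_chromosome = r$n_support == n_panel[[r$chrom]],
      signature = r$support, n_members = length(ix),
      member_lines = paste(sort(unique(hom$line_id[ix])), collapse = ","),
      outer_start = min(hom$outer_start[ix]),
      outer_end = max(hom$outer_end[ix]),
      inner_start = r$inner_start, inner_end = r$inner_end,
      n_support = r$n_support,
      ambiguous_donor = any(hom$ambiguous_donor[ix]),
      stringsAsFactors = FALSE)
  })
  cat_df <- do.call(rbind, rows)
  rownames(cat_df) <- NULL
  # name assignment
  cat_df$ordinal <- NA_integer_
  cat_df$name <- NA_character_
  whole <- cat_df$whole_chromosome
  cat_df$name[whole] <- cat_df$donor_chrom[whole]
  for (grpkey in unique(paste(cat_df$donor_chrom, cat_df$recipient_letter)[!whole])) {
    ix <- which(!whole & paste(cat_df$donor_chrom, cat_df$recipient_letter) == grpkey)
    o <- ix[order(cat_df$outer_start[ix], cat_df$outer_end[ix],
                  -cat_df$n_support[ix])]
    cat_df$ordinal[o] <- seq_along(o)
    cat_df$name[o] <- paste0(cat_df$donor_chrom[o], ".",
                             cat_df$recipient_letter[o], seq_along(o))
  }
  cat_df[order(cat_df$donor_chrom, cat_df$recipient_letter,
               ifelse(is.na(cat_df$ordinal), 0L, cat_df$ordinal)), ,
         drop = FALSE] -> cat_df
  rownames(cat_df) <- NULL
  cat_df
}

empty_catalog <- function() {
  data.frame(donor_chrom = character(), donor_subgenome = character(),
             recipient_chrom = character(), recipient_letter = character(),
             whole_chromosome = logical(), signature = character(),
             n_members = integer(), member_lines = character(),
             outer_start = integer(), outer_end = integer(),
             inner_start = integer(), inner_end = integer(),
             n_support = integer(), ambiguous_donor = logical(),
             ordinal = integer(), name = character(),
             stringsAsFactors = FALSE)
}

#' Per-donor-chromosome coverage of the introgressed genome
#'
#' Each unique segment's outer interval is projected onto fractional
#' coordinates of the recipient chromosome that carries it (interval/length
#' on `[0, 1]`); coverage of a donor chromosome is the union of its
#' segments' fractional intervals times 100. Whole-chromosome entries count
#' as full cover. The genome-wide figure is the mean over donor
#' chromosomes weighted by the length of each donor chromosome's primary
#' recipient homoeologue (A chromosomes for At, B for G).
#'
#' @param catalog a [build_catalog()] result.
#' @param chrom_lengths named recipient chromosome lengths.
#' @return data frame `donor_chrom, coverage_pct`, with attribute
#'   `genome_wide` (length-weighted mean percentage).
#' @export
coverage_stats <- function(catalog, chrom_lengths) {
  if (nrow(catalog) == 0L) {
    out <- data.frame(donor_chrom = character(), coverage_pct = numeric())
    attr(out, "genome_wide") <- NA_real_
    return(out)
  }
  donors <- sort(unique(catalog$donor_chrom))
  cov <- vapply(donors, function(dc) {
    rows <- catalog[catalog$donor_chrom == dc, , drop = FALSE]
    fs <- numeric(0); fe <- numeric(0)
    for (i in seq_len(nrow(rows))) {
      if (rows$whole_chromosome[i]) { fs <- c(fs, 0); fe <- c(fe, 1); next }
      L <- chrom_lengths[[rows$recipient_chrom[i]]]
      fs <- c(fs, rows$outer_start[i] / L)
      fe <- c(fe, min(1, rows$outer_end[i] / L))
    }
    min(1, interval_union_length(fs, fe)) * 100
  }, numeric(1))
  out <- data.frame(donor_chrom = donors, coverage_pct = unname(cov),
                    stringsAsFactors = FALSE)
  primary <- sub("At$", "A", sub("G$", "B", donors))
  w <- unlist(chrom_lengths[primary])
  attr(out, "genome_wide") <- if (length(w) == length(donors) && !anyNA(w)) {
    sum(cov * w) / sum(w)
  } else mean(cov)
  out
}

#' Summary statistics of a unique-segment catalog
#'
#' Occurrence totals weight each member line by its multiplicity (lines
#' known to share an identical genotype can be collapsed into one catalog
#' row); unique counts ignore multiplicity. Whole-chromosome substitutions
#' are tallied separately from the per-subgenome unique counts.
#'
#' @param catalog a [build_catalog()] result (or a fixture-derived catalog).
#' @param line_multiplicity optional named integer vector mapping line ids
#'   to their multiplicity (default 1).
#' @return object of class `catalog_summary`.
#' @export
summarize_catalog <- function(catalog, line_multiplicity = NULL) {
  if (nrow(catalog) == 0L) {
    return(structure(list(
      n_lines = 0L, total_occurrences = 0L,
      occurrences_by_subgenome = c(At = 0L, G = 0L),
      unique_by_subgenome = c(At = 0L, G = 0L),
      whole_chromosome = character(0),
      recipient_tallies = c(At.A = 0L, At.D = 0L, G.B = 0L, G.D = 0L),
      per_line = c(min = 0, mean = 0, max = 0)
    ), class = "catalog_summary"))
  }
  mult_of <- function(id) {
    if (is.null(line_multiplicity)) return(1L)
    m <- line_multiplicity[[id]] %||% 1L
    if (m < 1L) abort_user(sprintf("multiplicity < 1 for line %s", id))
    as.integer(m)
  }
  members <- strsplit(catalog$member_lines, ",")
  all_lines <- sort(unique(unlist(members)))
  per_line <- setNames(integer(length(all_lines)), all_lines)
  occ <- 0L
  occ_sub <- c(At = 0L, G = 0L)
  for (i in seq_len(nrow(catalog))) {
    sub <- if (grepl("At$", catalog$donor_chrom[i])) "At" else "G"
    for (id in members[[i]]) {
      m <- mult_of(id)
      occ <- occ + m
      occ_sub[sub] <- occ_sub[sub] + m
      per_line[id] <- per_line[id] + 1L
    }
  }
  # expand per-line counts by multiplicity for min/mean/max over actual lines
  expanded <- rep(per_line, vapply(names(per_line), mult_of, integer(1)))
  is_at <- grepl("At$", catalog$donor_chrom)
  whole <- catalog$whole_chromosome
  uniq <- c(At = sum(is_at & !whole), G = sum(!is_at & !whole))
  recip <- table(factor(paste0(ifelse(is_at, "At", "G"), ".",
                               catalog$recipient_letter)[!whole],
                        levels = c("At.A", "At.B", "At.D", "G.A", "G.B", "G.D")))
  structure(list(
    n_lines = length(expanded),
    total_occurrences = occ,
    occurrences_by_subgenome = occ_sub,
    unique_by_subgenome = uniq,
    whole_chromosome = catalog$donor_chrom[whole],
    recipient_tallies = as.integer(recip)[c(1, 3, 5, 6)] |>
      setNames(c("At.A", "At.D", "G.B", "G.D")),
    per_line = c(min = min(expanded), mean = mean(expanded),
                 max = max(expanded))
  ), class = "catalog_summary")
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat("Introgression catalog summary\n")
  cat(sprintf("  lines: %d, homozygous segment occurrences: %d (At %d / G %d)\n",
              x$n_lines, x$total_occurrences,
              x$occurrences_by_subgenome["At"], x$occurrences_by_subgenome["G"]))
  cat(sprintf("  unique segments: At %d + G %d (+ %d whole-chromosome: %s)\n",
              x$unique_by_subgenome["At"], x$unique_by_subgenome["G"],
              length(x$whole_chromosome),
              paste(x$whole_chromosome, collapse = ", ")))
  cat(sprintf("  recombined with D genome: At.D %d, G.D %d\n",
              x$recipient_tallies["At.D"], x$recipient_tallies["G.D"]))
  cat(sprintf("  segments per line: min %d / mean %.2f / max %d\n",
              x$per_line["min"], x$per_line["mean"], x$per_line["max"]))
  invisible(x)
}
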