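# iohub: packaged in-paper fixtures.
#
# Two tables are shipped as verbatim transcriptions: the per-chromosome
# marker-count accounting (21 wheat chromosomes x marker sets 1-4 and
# subgenome specificities) and the per-introgression-line segment catalog
# (98 rows of IL name + segment labels; one row covers two genotypically
# identical lines and carries multiplicity 2). Loaders validate the
# transcription invariants so the acceptance surface cannot silently rot.

TABLE1_PRINTED_TOTALS <- c(set1 = 250L, set2 = 30L, set3 = 51L, set4 = 149L,
                           total = 480L, at_specific = 182L,
                           g_specific = 275L, nonspecific = 23L)

SEGMENT_LABEL_RE <- "^([1-7])(At|G)(\\.([ABD])([0-9]+))?$"

#' Load a packaged in-paper fixture
#'
#' `table1` is the marker-count accounting per wheat chromosome; `table2`
#' the per-line segment catalog. Both are validated against their
#' transcription invariants at load time.
#' @param name `"table1"` or `"table2"`.
#' @param path directory holding the fixture files (defaults to the
#'   installed package's `extdata`).
#' @return a `table1_fixture` or `table2_fixture` data frame.
#' @export
load_fixture <- function(name = c("table1", "table2"), path = NULL) {
  name <- match.arg(name)
  path <- path %||% system.file("extdata", package = "introKASP")
  if (name == "table1") {
    f <- file.path(path, "table1_marker_counts.tsv")
    df <- utils::read.delim(f, stringsAsFactors = FALSE)
    if (nrow(df) != 21L) abort_user("table1 fixture must have 21 rows")
    set_sum <- df$set1 + df$set2 + df$set3 + df$set4
    if (!all(set_sum == df$total)) {
      abort_user("table1 fixture: set counts do not sum to row totals")
    }
    if (!all(df$at_specific + df$g_specific + df$nonspecific == df$total)) {
      abort_user("table1 fixture: specificity counts do not sum to row totals")
    }
    sums <- vapply(names(TABLE1_PRINTED_TOTALS), function(cl) sum(df[[cl]]),
                   integer(1))
    if (!all(sums == TABLE1_PRINTED_TOTALS)) {
      abort_user("table1 fixture: column sums do not match the printed totals row")
    }
    class(df) <- c("table1_fixture", "data.frame")
    df
  } else {
    f <- file.path(path, "table2_il_segments.tsv")
    df <- utils::read.delim(f, stringsAsFactors = FALSE)
    if (nrow(df) != 98L) abort_user("table2 fixture must have 98 rows")
    labs <- strsplit(df$segments, ",")
    if (!all(lengths(labs) == df$n_introgressions)) {
      abort_user("table2 fixture: declared count != number of segment labels")
    }
    if (!all(grepl(SEGMENT_LABEL_RE, unlist(labs)))) {
      abort_user("table2 fixture: unparseable segment label")
    }
    if (sum(df$multiplicity) != 99L) {
      abort_user("table2 fixture must expand to 99 lines")
    }
    class(df) <- c("table2_fixture", "data.frame")
    df
  }
}

# expand combined IL rows ("Tim14/29", multiplicity 2) into individual lines
expand_il_names <- function(il_name, multiplicity) {
  if (multiplicity == 1L) return(il_name)
  parts <- strsplit(il_name, "/")[[1]]
  stopifnot(length(parts) == multiplicity)
  prefix <- sub("[0-9]+$", "", parts[1])
  c(parts[1], paste0(prefix, parts[-1]))
}

#' Convert the packaged per-line segment table into a catalog
#'
#' Each distinct segment label becomes one unique-segment row; member lines
#' are the expanded IL names (combined rows become one line each, so no
#' multiplicity weighting is needed afterwards). Labels without a
#' `.{letter}{ordinal}` suffix are whole-chromosome substitutions.
#' @param fixture a `table2_fixture` from [load_fixture()].
#' @return a catalog data frame compatible with [summarize_catalog()].
#' @export
table2_to_catalog <- function(fixture) {
  stopifnot(inherits(fixture, "table2_fixture"))
  rows <- list()
  for (i in seq_len(nrow(fixture))) {
    lines <- expand_il_names(fixture$il_name[i], fixture$multiplicity[i])
    for (lab in strsplit(fixture$segments[i], ",")[[1]]) {
      rows[[length(rows) + 1L]] <- data.frame(name = lab, line_id = lines,
                                              stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, rows)
  m <- regmatches(long$name, regexec(SEGMENT_LABEL_RE, long$name))
  long$donor_chrom <- vapply(m, function(x) paste0(x[2], x[3]), character(1))
  long$recipient_letter <- vapply(m, function(x) {
    if (nzchar(x[5])) x[5] else NA_character_
  }, character(1))
  long$ordinal <- vapply(m, function(x) {
    if (nzchar(x[6])) as.integer(x[6]) else NA_integer_
  }, integer(1))
  out <- do.call(rbind, lapply(split(long, long$name), function(d) {
    data.frame(
      name = d$name[1], donor_chrom = d$donor_chrom[1],
      donor_subgenome = if (grepl("At$", d$donor_chrom[1])) "At" else "G",
      recipient_chrom = if (is.na(d$recipient_letter[1])) NA_character_ else
        paste0(substring(d$donor_chrom[1], 1, 1), d$recipient_letter[1]),
      recipient_letter = d$recipient_letter[1],
      ordinal = d$ordinal[1],
      whole_chromosome = is.na(d$recipient_letter[1]),
      signature = NA_character_,
      n_members = nrow(d),
      member_lines = paste(sort(d$line_id), collapse = ","),
      outer_start = NA_integer_, outer_end = NA_integer_,
      inner_start = NA_integer_, inner_end = NA_integer_,
      n_support = NA_integer_, ambiguous_donor = FALSE,
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Marker-panel accounting from the packaged marker-count table
#'
#' Column sums over the 21 chromosome rows: totals per marker set, overall
#' total, and subgenome-specificity totals.
#' @param fixture a `table1_fixture` from [load_fixture()].
#' @return named integer vector of column sums.
#' @export
table1_totals <- function(fixture) {
  stopifnot(inherits(fixture, "table1_fixture"))
  vapply(names(TABLE1_PRINTED_TOTALS), function(cl) sum(fixture[[cl]]),
         integer(1))
}
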