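# specificity_design: marker-panel spacing and gap-filling analytics.

#' Adjacent-gap spacing statistics of a marker panel
#'
#' `mean_gap` is the mean of adjacent inter-marker distances and `max_gap`
#' their maximum; a chromosome carrying a single marker reports the
#' chromosome length as its max gap (documented convention). Distances to
#' chromosome ends are not included in the mean.
#' @param markers marker data frame (`marker_id, chrom, pos`).
#' @param chrom_lengths named chromosome lengths.
#' @return data frame `chrom, n_markers, mean_gap, max_gap`.
#' @export
panel_spacing <- function(markers, chrom_lengths) {
  out <- lapply(unique(markers$chrom), function(ch) {
    pos <- sort(markers$pos[markers$chrom == ch])
    if (anyDuplicated(pos)) {
      abort_user(sprintf("duplicate marker positions on %s", ch))
    }
    if (length(pos) >= 2L) {
      gaps <- diff(pos)
      data.frame(chrom = ch, n_markers = length(pos), mean_gap = mean(gaps),
                 max_gap = max(gaps), stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = ch, n_markers = 1L, mean_gap = NA_real_,
                 max_gap = as.numeric(chrom_lengths[[ch]]),
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Greedy gap-filling selection of candidate SNPs
#'
#' Per chromosome: while any adjacent inter-marker gap exceeds the target
#' and at least one candidate lies strictly inside it, the widest such gap
#' (ties: smaller start) receives the candidate closest to its midpoint
#' (ties: smaller position). Deterministic; gaps that exceed the target but
#' contain no candidate are reported as unfilled.
#' @param panel existing marker data frame (`chrom, pos`).
#' @param candidates candidate data frame (`chrom, pos`); typically passed
#'   SNPs from the suitability + specificity filters.
#' @param max_gap_target gap size above which filling is attempted
#'   (default 70 Mbp, the panel's design density target).
#' @return list with `selected` (rows of `candidates`) and `unfilled`
#'   (data frame `chrom, gap_start, gap_end`).
#' @export
gap_fill_select <- function(panel, candidates, max_gap_target = 70e6) {
  sel <- integer(0)
  unfilled <- list()
  for (ch in unique(panel$chrom)) {
    pos <- sort(panel$pos[panel$chrom == ch])
    cand_ix <- which(candidates$chrom == ch)
    cand_pos <- candidates$pos[cand_ix]
    repeat {
      gaps_s <- pos[-length(pos)]; gaps_e <- pos[-1]
      w <- gaps_e - gaps_s
      open <- which(w > max_gap_target)
      fillable <- open[vapply(open, function(g) {
        any(cand_pos > gaps_s[g] & cand_pos < gaps_e[g] &
              !(cand_ix %in% sel))
      }, logical(1))]
      if (!length(fillable)) {
        for (g in open) {
          has_cand <- any(cand_pos > gaps_s[g] & cand_pos < gaps_e[g])
          if (!has_cand) {
            unfilled[[length(unfilled) + 1L]] <- data.frame(
              chrom = ch, gap_start = gaps_s[g], gap_end = gaps_e[g],
              stringsAsFactors = FALSE)
          }
        }
        break
      }
      g <- fillable[order(-w[fillable], gaps_s[fillable])][1]
      mid <- (gaps_s[g] + gaps_e[g]) / 2
      inside <- which(cand_pos > gaps_s[g] & cand_pos < gaps_e[g] &
                        !(cand_ix %in% sel))
      pick <- inside[order(abs(cand_pos[inside] - mid), cand_pos[inside])][1]
      sel <- c(sel, cand_ix[pick])
      pos <- sort(c(pos, cand_pos[pick]))
    }
  }
  list(selected = candidates[sort(sel), , drop = FALSE],
       unfilled = if (length(unfilled)) do.call(rbind, unfilled) else
         data.frame(chrom = character(), gap_start = numeric(),
                    gap_end = numeric(), stringsAsFactors = FALSE))
}
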