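# introgression_core: genotype calls -> per-line introgression segments.

#' Call genotypes from endpoint-fluorescence data (nearest centroid)
#'
#' Cluster centroids come from the control wells; each sample is assigned
#' the state of its nearest genotype centroid unless the margin between the
#' two nearest centroids is below `no_call_margin` (relative to the nearest
#' distance) or the point is nearer the no-template-control centroid, in
#' which case it is a NoCall. A desk stand-in for endpoint-genotyping
#' cluster software.
#'
#' @param points data frame with `sample_id, fam, hex, role`; roles are
#'   `sample`, `recipient_control`, `donor_control`, `het_control`, `ntc`.
#' @param no_call_margin relative margin below which a call is ambiguous.
#' @return data frame `sample_id, state` with states in
#'   HomRecipient/Het/HomDonor/NoCall.
#' @export
call_genotypes_from_fluorescence <- function(points, no_call_margin = 0.2) {
  stopifnot(all(c("sample_id", "fam", "hex", "role") %in% names(points)),
            all(is.finite(points$fam)), all(is.finite(points$hex)))
  roles <- c(recipient_control = "HomRecipient", het_control = "Het",
             donor_control = "HomDonor")
  cent <- lapply(names(roles), function(r) {
    p <- points[points$role == r, , drop = FALSE]
    if (nrow(p) == 0L) abort_user(sprintf("missing %s wells", r))
    c(fam = mean(p$fam), hex = mean(p$hex))
  })
  names(cent) <- roles
  ntc <- points[points$role == "ntc", , drop = FALSE]
  if (nrow(ntc) == 0L) abort_user("missing ntc wells")
  ntc_c <- c(fam = mean(ntc$fam), hex = mean(ntc$hex))

  samp <- points[points$role == "sample", , drop = FALSE]
  state <- character(nrow(samp))
  for (i in seq_len(nrow(samp))) {
    d <- vapply(cent, function(cc) {
      sqrt((samp$fam[i] - cc["fam"])^2 + (samp$hex[i] - cc["hex"])^2)
    }, numeric(1))
    dn <- sqrt((samp$fam[i] - ntc_c["fam"])^2 + (samp$hex[i] - ntc_c["hex"])^2)
    o <- order(d)
    d1 <- d[o[1]]; d2 <- d[o[2]]
    if (dn < d1 || (d1 > 0 && (d2 - d1) / d1 < no_call_margin) ||
        (d1 == 0 && d2 == 0)) {
      state[i] <- "NoCall"
    } else {
      state[i] <- names(d)[o[1]]
    }
  }
  data.frame(sample_id = samp$sample_id, state = state, stringsAsFactors = FALSE)
}

empty_segments <- function() {
  data.frame(line_id = character(), chrom = character(), zygosity = character(),
             inner_start = integer(), inner_end = integer(),
             outer_start = integer(), outer_end = integer(),
             bound_start = integer(), bound_end = integer(),
             n_support = integer(), support = character(),
             stringsAsFactors = FALSE)
}

# maximal runs of `target` state with optional bridging of a single NoCall
# flanked by the target state on both sides
state_runs <- function(v, target, bridge_nocall) {
  n <- length(v)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (!is.na(v[i]) && v[i] == target) {
      start <- i
      members <- i
      j <- i + 1L
      while (j <= n) {
        if (!is.na(v[j]) && v[j] == target) {
          members <- c(members, j); j <- j + 1L
        } else if (bridge_nocall && j < n && is.na(v[j]) &&
                   !is.na(v[j + 1L]) && v[j + 1L] == target) {
          j <- j + 1L  # bridge exactly one NoCall
        } else break
      }
      runs[[length(runs) + 1L]] <- members
      i <- j
    } else i <- i + 1L
  }
  runs
}

#' Call introgression segments from ordered marker genotypes
#'
#' Per chromosome, maximal runs of homozygous-donor calls become `hom`
#' segments and maximal runs of heterozygous calls become `het` segments.
#' A single NoCall flanked by the run state on both sides is bridged (when
#' `bridge_nocall`); two consecutive NoCalls, or any other state, break the
#' run. A heterozygous call always terminates a homozygous run.
#'
#' Each segment reports three nested intervals: `inner` (first to last
#' supporting marker), `outer` (extended to the midpoints towards the
#' nearest flanking markers, or to the chromosome ends when there are
#' none; used for catalog extents and coverage), and `bound` (the maximal
#' interval consistent with the flanking non-donor markers, which is
#' guaranteed to contain the true block). A chromosome whose every marker
#' supports the run is a whole-chromosome segment.
#'
#' @param calls integer matrix lines x markers (0 hom-recipient, 1 het,
#'   2 hom-donor, NA no-call) with rownames/colnames.
#' @param markers marker data frame (`marker_id, chrom, pos`), 0-based `pos`.
#' @param chrom_lengths named chromosome lengths.
#' @param min_markers drop runs supported by fewer markers (default 1:
#'   single-marker segments are retained).
#' @param bridge_nocall bridge single NoCalls inside runs.
#' @return `segments` data frame (0-based half-open intervals).
#' @export
call_segments <- function(calls, markers, chrom_lengths, min_markers = 1L,
                          bridge_nocall = TRUE) {
  stopifnot(is.matrix(calls), !is.null(rownames(calls)),
            all(colnames(calls) %in% markers$marker_id))
  out <- list()
  dropped <- 0L
  for (line_id in rownames(calls)) {
    for (ch in unique(markers$chrom)) {
      mi <- which(markers$chrom == ch)
      mi <- mi[order(markers$pos[mi])]
      ids <- markers$marker_id[mi]
      pos <- markers$pos[mi]
      v <- calls[line_id, ids]
      L <- chrom_lengths[[ch]]
      if (is.null(L)) abort_user(sprintf("no length for chromosome %s", ch))
      for (zyg in c("hom", "het")) {
        target <- if (zyg == "hom") 2L else 1L
        for (members in state_runs(v, target, bridge_nocall)) {
          if (length(members) < min_markers) { dropped <- dropped + 1L; next }
          first <- members[1]; last <- members[length(members)]
          inner_start <- pos[first]
          inner_end <- pos[last] + 1L
          outer_start <- if (first == 1L) 0L else
            as.integer(floor((pos[first - 1L] + pos[first]) / 2))
          outer_end <- if (last == length(v)) as.integer(L) else
            as.integer(ceiling((pos[last] + pos[last + 1L]) / 2))
          # maximal interval consistent with the flanking non-donor markers:
          # the true junction must lie strictly between them
          bound_start <- if (first == 1L) 0L else pos[first - 1L] + 1L
          bound_end <- if (last == length(v)) as.integer(L) else pos[last + 1L]
          out[[length(out) + 1L]] <- data.frame(
            line_id = line_id, chrom = ch, zygosity = zyg,
            inner_start = inner_start, inner_end = inner_end,
            outer_start = outer_start, outer_end = outer_end,
            bound_start = bound_start, bound_end = bound_end,
            n_support = length(members),
            support = paste(ids[members], collapse = ","),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (dropped > 0L) {
    message(sprintf("call_segments: dropped %d run(s) shorter than min_markers = %d",
                    dropped, min_markers))
  }
  if (length(out)) {
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  } else empty_segments()
}

#' Assign donor chromosomes to segments by marker-specificity vote
#'
#' The donor subgenome is the majority vote among supporting markers with a
#' subgenome-specific assay; ties or absence of specific support set
#' `ambiguous_donor` and fall back to the recipient homoeology (A -> At,
#' B -> G, D -> At). The donor chromosome label is the recipient
#' homoeologous group plus the voted subgenome (a segment on 3D with
#' G-specific support is 3G chromatin).
#' @param segments output of [call_segments()].
#' @param markers marker data frame with `marker_id` and `specificity`
#'   (`At`, `G` or `nonspecific`).
#' @return `segments` with `donor_subgenome`, `donor_chrom` and
#'   `ambiguous_donor` columns.
#' @export
assign_donor_chromosome <- function(segments, markers) {
  spec_of <- setNames(markers$specificity, markers$marker_id)
  fallback <- c(A = "At", B = "G", D = "At")
  sub <- character(nrow(segments)); amb <- logical(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    ids <- strsplit(segments$support[i], ",")[[1]]
    sp <- spec_of[ids]
    n_at <- sum(sp == "At", na.rm = TRUE)
    n_g <- sum(sp == "G", na.rm = TRUE)
    if (n_at > n_g) { sub[i] <- "At"; amb[i] <- FALSE }
    else if (n_g > n_at) { sub[i] <- "G"; amb[i] <- FALSE }
    else {
      sub[i] <- fallback[[slot_subgenome(segments$chrom[i])]]
      amb[i] <- TRUE
    }
  }
  segments$donor_subgenome <- sub
  segments$donor_chrom <- paste0(sub("[A-Za-z]+$", "", segments$chrom), sub)
  segments$ambiguous_donor <- amb
  segments
}
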