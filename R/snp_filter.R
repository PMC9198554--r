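# snp_filter: alignment-level filtering, duplicate removal, a count-based
# variant-candidate caller stand-in, and the KASP-suitability filter (core
# thresholds plus 50-bp flanking-window per-position criteria).
#
# Pipeline order is fixed: filter -> dedup -> pileup -> call -> suitability.

#' Thresholds for the KASP-suitability SNP filter
#'
#' Defaults implement the published rule set: retain homozygous SNPs with
#' read depth strictly greater than 10 and 100% of mapped reads supporting
#' the alternative allele, where every position 50 bp up- and downstream has
#' no indels, strictly more than five reads, and >= 80% of reads supporting
#' the reference allele. "Greater than" thresholds are strict; percentage
#' thresholds are inclusive.
#'
#' @param min_mapq retain alignments with MAPQ >= this (non-unique mappers
#'   have q < 10).
#' @param min_dp candidate depth must be > this.
#' @param alt_fraction required fraction of base calls supporting the alt.
#' @param flank_bp flank width on each side of the SNP.
#' @param flank_min_depth each flank position must have depth > this.
#' @param flank_ref_frac each flank position must have reference-base
#'   fraction >= this (computed over base calls; deletions excluded from the
#'   denominator unless `flank_frac_counts_dels`).
#' @param require_no_flank_indels reject any read-supported indel at a flank
#'   position.
#' @param flank_frac_counts_dels include deletion-spanning reads in the
#'   reference-fraction denominator.
#' @return object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_mapq = 10L, min_dp = 10L, alt_fraction = 1.0,
                              flank_bp = 50L, flank_min_depth = 5L,
                              flank_ref_frac = 0.80,
                              require_no_flank_indels = TRUE,
                              flank_frac_counts_dels = FALSE) {
  stopifnot(min_mapq >= 0, min_dp >= 0, alt_fraction > 0, alt_fraction <= 1,
            flank_bp >= 1, flank_min_depth >= 0,
            flank_ref_frac >= 0, flank_ref_frac <= 1)
  structure(list(min_mapq = min_mapq, min_dp = min_dp,
                 alt_fraction = alt_fraction, flank_bp = as.integer(flank_bp),
                 flank_min_depth = flank_min_depth,
                 flank_ref_frac = flank_ref_frac,
                 require_no_flank_indels = require_no_flank_indels,
                 flank_frac_counts_dels = flank_frac_counts_dels),
            class = "filter_thresholds")
}

#' Remove unusable alignments
#'
#' Retains records that are mapped, non-supplementary, properly paired and
#' have MAPQ >= `min_mapq`. Input order is preserved.
#' @param records `alignment_records`.
#' @param thresholds a [filter_thresholds()].
#' @return filtered `alignment_records`.
#' @export
filter_alignments <- function(records, thresholds = filter_thresholds()) {
  keep <- !records$unmapped & !records$supplementary &
    records$proper_pair & records$mapq >= thresholds$min_mapq
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  new_alignment_records(out)
}

#' Remove positional (PCR) duplicates
#'
#' Among records sharing (chrom, pos, strand, mate_pos) exactly one is
#' retained: the one with the lexicographically smallest read id. Input order
#' is otherwise preserved.
#' @param records `alignment_records` (already alignment-filtered).
#' @return deduplicated `alignment_records`.
#' @export
mark_duplicates <- function(records) {
  if (nrow(records) == 0L) return(records)
  key <- paste(records$chrom, records$pos, records$strand, records$mate_pos,
               sep = "\r")
  o <- order(key, records$read_id, method = "radix")
  first <- o[!duplicated(key[o])]
  out <- records[sort(first), , drop = FALSE]
  rownames(out) <- NULL
  new_alignment_records(out)
}

parse_cigar <- function(cigar, read_id = "?") {
  m <- gregexpr("\\d+[MIDS]", cigar)[[1]]
  if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(cigar)) {
    stop(sprintf("malformed CIGAR '%s' in read %s", cigar, read_id))
  }
  toks <- regmatches(cigar, gregexpr("\\d+[MIDS]", cigar))[[1]]
  list(op = substring(toks, nchar(toks), nchar(toks)),
       len = as.integer(substring(toks, 1L, nchar(toks) - 1L)))
}

#' Per-position pileup over an interval
#'
#' Walks every record's CIGAR: M bases contribute to base counts, deletions
#' increment `del_count` at every spanned position, insertions increment
#' `ins_adjacent` at the anchor position (the reference base preceding the
#' inserted sequence), and soft-clips contribute nothing. Unmapped records
#' are skipped. `depth = A + C + G + T + del_count` at every position.
#'
#' @param records `alignment_records`.
#' @param chrom chromosome to pile up.
#' @param start,end 0-based half-open interval.
#' @return data frame with one row per position in `[start, end)` and
#'   columns `chrom, pos, A, C, G, T, del_count, ins_adjacent, depth`;
#'   attributes `chrom` and `interval` record the computed window.
#' @export
compute_pileup <- function(records, chrom, start = 0L, end = NULL) {
  stopifnot(!is.null(end), end > start)
  W <- as.integer(end - start)
  sel <- records$chrom == chrom & !records$unmapped
  rec <- records[sel, , drop = FALSE]

  mpos_l <- list(); mbase_l <- list(); dpos_l <- list(); ipos_l <- list()

  if (nrow(rec) > 0L) {
    base_chars <- strsplit(rec$bases, "")
    for (i in seq_len(nrow(rec))) {
      cg <- parse_cigar(rec$cigar[i], rec$read_id[i])
      rpos <- rec$pos[i]; q <- 0L
      for (k in seq_along(cg$op)) {
        len <- cg$len[k]
        switch(cg$op[k],
               M = {
                 mpos_l[[length(mpos_l) + 1L]] <- rpos:(rpos + len - 1L)
                 mbase_l[[length(mbase_l) + 1L]] <-
                   match(base_chars[[i]][(q + 1L):(q + len)], DNA_BASES)
                 rpos <- rpos + len; q <- q + len
               },
               D = {
                 dpos_l[[length(dpos_l) + 1L]] <- rpos:(rpos + len - 1L)
                 rpos <- rpos + len
               },
               I = { ipos_l[[length(ipos_l) + 1L]] <- rpos - 1L; q <- q + len },
               S = { q <- q + len })
      }
    }
  }
  mpos <- unlist(mpos_l) %||% integer(0)
  mbase_id <- unlist(mbase_l) %||% integer(0)
  dpos <- unlist(dpos_l) %||% integer(0)
  ipos <- unlist(ipos_l) %||% integer(0)
  if (is.null(mpos)) mpos <- integer(0)
  if (is.null(mbase_id)) mbase_id <- integer(0)
  if (is.null(dpos)) dpos <- integer(0)
  if (is.null(ipos)) ipos <- integer(0)

  inw <- function(p) p >= start & p < end
  base_mat <- matrix(0L, nrow = W, ncol = 4L, dimnames = list(NULL, DNA_BASES))
  ok <- inw(mpos) & !is.na(mbase_id)
  if (any(ok)) {
    idx <- (mbase_id[ok] - 1L) * W + (mpos[ok] - start + 1L)
    tab <- tabulate(idx, nbins = 4L * W)
    base_mat[] <- tab
  }
  del_count <- tabulate(dpos[inw(dpos)] - start + 1L, nbins = W)
  ins_adj <- tabulate(ipos[inw(ipos)] - start + 1L, nbins = W)

  out <- data.frame(chrom = chrom, pos = start:(end - 1L),
                    A = base_mat[, "A"], C = base_mat[, "C"],
                    G = base_mat[, "G"], T = base_mat[, "T"],
                    del_count = del_count, ins_adjacent = ins_adj,
                    stringsAsFactors = FALSE)
  out$depth <- out$A + out$C + out$G + out$T + out$del_count
  attr(out, "chrom") <- chrom
  attr(out, "interval") <- c(start, end)
  out
}

#' Call variant candidates from a pileup (count-based stand-in)
#'
#' A candidate is emitted at every position where a single non-reference base
#' is supported by at least two reads. Positions where two or more distinct
#' non-reference bases each have two or more supporting reads are emitted
#' with `multiallelic = TRUE` and must be excluded downstream. Genotype is
#' `hom_alt` when the alternative fraction among base calls is exactly 1,
#' otherwise `het`; homozygous-reference calls are never emitted.
#'
#' @param pileup output of [compute_pileup()].
#' @param reference recipient `Genome`.
#' @return data frame of `VariantCandidate`s (`chrom, pos, ref, alt,
#'   genotype, DP, AD_ref, AD_alt, multiallelic`), 0-based positions.
#' @export
call_candidates <- function(pileup, reference) {
  chrom <- attr(pileup, "chrom")
  stopifnot(chrom %in% names(reference$seq))
  refseq <- reference$seq[[chrom]]
  refbase <- strsplit(substring(refseq, pileup$pos[1] + 1L,
                                pileup$pos[nrow(pileup)] + 1L), "")[[1]]
  counts <- as.matrix(pileup[, DNA_BASES])
  ref_idx <- match(refbase, DNA_BASES)
  ref_count <- counts[cbind(seq_len(nrow(counts)), ref_idx)]
  nonref <- counts
  nonref[cbind(seq_len(nrow(counts)), ref_idx)] <- -1L
  alt_count <- apply(nonref, 1L, max)
  alt_idx <- max.col(nonref, ties.method = "first")
  second <- apply(nonref, 1L, function(x) sort(x, decreasing = TRUE)[2])
  is_cand <- alt_count >= 2L
  if (!any(is_cand)) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), genotype = character(), DP = integer(),
                      AD_ref = integer(), AD_alt = integer(),
                      multiallelic = logical(), stringsAsFactors = FALSE))
  }
  i <- which(is_cand)
  basecalls <- rowSums(counts)[i]
  altfrac <- alt_count[i] / basecalls
  data.frame(
    chrom = chrom, pos = pileup$pos[i], ref = refbase[i],
    alt = DNA_BASES[alt_idx[i]],
    genotype = ifelse(altfrac == 1, "hom_alt", "het"),
    DP = pileup$depth[i],
    AD_ref = ref_count[i], AD_alt = alt_count[i],
    multiallelic = second[i] >= 2L,
    stringsAsFactors = FALSE)
}

#' KASP-suitability filter for SNP candidates
#'
#' Rules are applied in a fixed, documented order; the first violated rule
#' is the single FAIL reason:
#' \enumerate{
#'   \item genotype is `hom_alt` (else `NOT_HOMOZYGOUS`),
#'   \item `DP > min_dp` (else `LOW_DEPTH`; "greater than 10" is strict),
#'   \item alternative fraction among base calls is 1.0 (else `IMPURE_ALT`),
#'   \item the site is at least `flank_bp` from both chromosome ends
#'     (else `EDGE_OF_CHROM`),
#'   \item every flank position (SNP excluded): no read-supported indel
#'     (else `FLANK_INDEL`), depth > `flank_min_depth` (else
#'     `LOW_FLANK_DEPTH`), reference-base fraction >= `flank_ref_frac`
#'     (else `FLANK_POLYMORPHIC`). Flank rules are evaluated rule-major
#'     (indels at all positions, then depth, then fraction).
#' }
#'
#' @param candidates `VariantCandidate` data frame (single chromosome,
#'   no multiallelic rows).
#' @param pileup pileup covering every candidate's flank window.
#' @param thresholds a [filter_thresholds()].
#' @param chrom_length length of the chromosome.
#' @param reference recipient `Genome` (for flank reference bases).
#' @return `FilterResult` data frame: the candidate columns plus `status`
#'   (PASS/FAIL) and `reason` (NA for PASS).
#' @export
kasp_suitability_filter <- function(candidates, pileup, thresholds,
                                    chrom_length, reference) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  if (nrow(candidates) > 0L) {
    stopifnot(all(!candidates$multiallelic))
    stopifnot(all(candidates$chrom == attr(pileup, "chrom")))
  }
  fb <- thresholds$flank_bp
  iv <- attr(pileup, "interval")
  chrom <- attr(pileup, "chrom")
  refseq <- reference$seq[[chrom]]

  counts <- as.matrix(pileup[, DNA_BASES])
  basecalls <- rowSums(counts)
  refbase_all <- strsplit(substring(refseq, iv[1] + 1L, iv[2]), "")[[1]]
  ref_idx <- match(refbase_all, DNA_BASES)
  refn <- counts[cbind(seq_len(nrow(counts)), ref_idx)]
  denom <- if (thresholds$flank_frac_counts_dels) {
    basecalls + pileup$del_count
  } else basecalls
  ref_frac <- ifelse(denom > 0, refn / denom, 1)

  status <- character(nrow(candidates))
  reason <- rep(NA_character_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cd <- candidates[i, ]
    fail <- function(r) { status[i] <<- "FAIL"; reason[i] <<- r }
    if (cd$genotype != "hom_alt") { fail("NOT_HOMOZYGOUS"); next }
    if (!(cd$DP > thresholds$min_dp)) { fail("LOW_DEPTH"); next }
    if ((cd$AD_alt / cd$DP) < thresholds$alt_fraction) { fail("IMPURE_ALT"); next }
    if (cd$pos < fb || cd$pos > chrom_length - fb - 1L) { fail("EDGE_OF_CHROM"); next }
    lo <- cd$pos - fb; hi <- cd$pos + fb
    if (lo < iv[1] || hi >= iv[2]) {
      stop(sprintf("pileup does not cover flank window [%d, %d] of %s:%d",
                   lo, hi, cd$chrom, cd$pos))
    }
    w <- (lo - iv[1] + 1L):(hi - iv[1] + 1L)
    w <- setdiff(w, cd$pos - iv[1] + 1L)  # SNP position itself excluded
    if (thresholds$require_no_flank_indels &&
        any(pileup$del_count[w] > 0L | pileup$ins_adjacent[w] > 0L)) {
      fail("FLANK_INDEL"); next
    }
    if (any(pileup$depth[w] <= thresholds$flank_min_depth)) {
      fail("LOW_FLANK_DEPTH"); next
    }
    if (any(ref_frac[w] < thresholds$flank_ref_frac)) {
      fail("FLANK_POLYMORPHIC"); next
    }
    status[i] <- "PASS"
  }
  out <- candidates
  out$status <- status
  out$reason <- reason
  out
}

#' Run the fixed SNP-discovery chain on one chromosome's alignments
#'
#' Convenience wrapper enforcing the pipeline order filter -> dedup ->
#' pileup -> call -> suitability.
#' @param records `alignment_records` for one target chromosome.
#' @param reference recipient `Genome`.
#' @param chrom chromosome name.
#' @param thresholds a [filter_thresholds()].
#' @return list with `pileup`, `candidates` and `results` (FilterResult).
#' @export
discover_snps <- function(records, reference, chrom,
                          thresholds = filter_thresholds()) {
  L <- nchar(reference$seq[[chrom]])
  flt <- mark_duplicates(filter_alignments(records, thresholds))
  pu <- compute_pileup(flt, chrom, 0L, L)
  cands <- call_candidates(pu, reference)
  cands <- cands[!cands$multiallelic, , drop = FALSE]
  res <- kasp_suitability_filter(cands, pu, thresholds, L, reference)
  list(pileup = pu, candidates = cands, results = res)
}
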