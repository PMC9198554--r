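# specificity_design: chromosome-specificity screening of SNP flanking
# contexts via an exact-seed + local-alignment extension search (desk-scale
# stand-in for a nucleotide homology search), and simplified allele-specific
# assay design.

#' Parameters for the local homology search
#'
#' Seed length 16 guarantees sensitivity at the decision boundary: a 101-mer
#' copy with at most 3 mismatches always contains an exact run of at least
#' ceiling((101 - 3) / 4) = 25 >= 16 bases by pigeonhole.
#'
#' @param seed_len exact seed length.
#' @param min_identity_report report hits with identity >= this.
#' @param min_hit_len minimum aligned columns for a reportable hit
#'   (61 = 60% of the 101-bp query, rounded up).
#' @param off_target_identity identity at or above which a non-self hit
#'   disqualifies the SNP.
#' @return object of class `search_params`.
#' @export
search_params <- function(seed_len = 16L, min_identity_report = 0.90,
                          min_hit_len = 61L, off_target_identity = 0.97) {
  stopifnot(seed_len >= 4, seed_len <= min_hit_len,
            min_identity_report > 0, min_identity_report <= 1,
            off_target_identity > 0, off_target_identity <= 1)
  structure(list(seed_len = as.integer(seed_len),
                 min_identity_report = min_identity_report,
                 min_hit_len = as.integer(min_hit_len),
                 off_target_identity = off_target_identity),
            class = "search_params")
}

#' Extract the 101-bp flanking context of a SNP
#'
#' The query is built from the recipient reference with the reference base at
#' the centre (index 50, 0-based): flank extraction happens on the assembly,
#' not on the donor allele.
#' @param variant one `VariantCandidate` row (or any list with `chrom`,
#'   `pos`, `ref`, `alt`).
#' @param reference recipient `Genome`.
#' @param flank_bp flank width.
#' @return object of class `flank_context` with `snp_id`, `chrom`, `pos`,
#'   `query`, `alleles` and `self_locus`.
#' @export
extract_flank_context <- function(variant, reference, flank_bp = 50L) {
  chrom <- variant$chrom
  pos <- variant$pos
  L <- nchar(reference$seq[[chrom]])
  if (pos < flank_bp || pos > L - flank_bp - 1L) {
    abort_user(sprintf("EDGE: site %s:%d is closer than %d bp to a chromosome end",
                       chrom, pos, flank_bp))
  }
  query <- substring(reference$seq[[chrom]], pos - flank_bp + 1L,
                     pos + flank_bp + 1L)
  stopifnot(nchar(query) == 2L * flank_bp + 1L)
  structure(list(
    snp_id = sprintf("%s_%d", chrom, pos + 1L),
    chrom = chrom, pos = pos, query = query,
    alleles = c(ref = variant$ref, alt = variant$alt),
    self_locus = c(start = pos - flank_bp, end = pos + flank_bp + 1L)
  ), class = "flank_context")
}

# Identity and span of a local alignment: matches / aligned columns, where
# aligned columns include gap columns.
aln_stats <- function(aln) {
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  ind <- Biostrings::nindel(aln)
  gaps <- sum(Biostrings::insertion(ind)[, "WidthSum"]) +
    sum(Biostrings::deletion(ind)[, "WidthSum"])
  cols <- nm + nmm + gaps
  list(identity = if (cols > 0) nm / cols else 0, aligned_len = cols)
}

local_align <- function(query, subject) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 1, gapExtension = 1)
}

#' Build an exact k-mer index of a genome for [local_search()]
#'
#' One environment per chromosome mapping every `seed_len`-mer to its
#' 1-based start positions. Building the index once and passing it to
#' repeated [local_search()] calls makes batch specificity screening fast.
#' @param reference `Genome`.
#' @param seed_len k-mer length (must match the search's `seed_len`).
#' @return object of class `search_index`.
#' @export
build_search_index <- function(reference, seed_len = 16L) {
  idx <- lapply(reference$seq, function(s) {
    n <- nchar(s) - seed_len + 1L
    if (n < 1L) return(new.env(parent = emptyenv()))
    kmers <- substring(s, seq_len(n), seq_len(n) + seed_len - 1L)
    list2env(split(seq_len(n), kmers), parent = emptyenv())
  })
  structure(list(index = idx, seed_len = as.integer(seed_len)),
            class = "search_index")
}

#' Seed-and-extend local homology search
#'
#' Every locus sharing an exact `seed_len`-mer with the query (either strand)
#' is extended with a local alignment (match +1, mismatch -1, gap open -2
#' including the first gap base, extend -1). Hits with identity >=
#' `min_identity_report` over >= `min_hit_len` aligned columns are reported,
#' merged per locus, and sorted by identity (descending), then chromosome
#' and start.
#'
#' @param query query sequence (the 101-bp flank context, or a primer).
#' @param reference `Genome` to search.
#' @param params a [search_params()].
#' @param query_id id copied onto hits.
#' @param index optional prebuilt [build_search_index()] (built on the fly
#'   otherwise).
#' @return data frame of hits: `query_id, chrom, start, end, strand,
#'   identity, aligned_len` (0-based half-open reference coordinates).
#' @export
local_search <- function(query, reference, params = search_params(),
                         query_id = "query", index = NULL) {
  qlen <- nchar(query)
  stopifnot(qlen >= params$seed_len)
  if (is.null(index)) {
    index <- build_search_index(reference, params$seed_len)
  } else {
    stopifnot(inherits(index, "search_index"),
              index$seed_len == params$seed_len)
  }
  hits <- list()
  pad <- 20L
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else revcomp(query)
    k <- params$seed_len
    starts <- seq_len(qlen - k + 1L)
    seeds <- substring(q, starts, starts + k - 1L)
    keep <- !duplicated(seeds)
    seeds <- seeds[keep]; qstarts <- starts[keep]
    for (chrom in names(reference$seq)) {
      e <- index$index[[chrom]]
      L <- nchar(reference$seq[[chrom]])
      proj <- integer(0)
      for (si in seq_along(seeds)) {
        st <- get0(seeds[si], envir = e, inherits = FALSE)
        if (!is.null(st)) proj <- c(proj, st - qstarts[si])  # projected locus start (1-based)
      }
      if (!length(proj)) next
      proj <- sort(unique(proj))
      # cluster projected starts within half a query length
      grp <- cumsum(c(TRUE, diff(proj) > qlen %/% 2L))
      for (g in unique(grp)) {
        p0 <- min(proj[grp == g]); p1 <- max(proj[grp == g])
        ws <- max(1L, p0 - pad); we <- min(L, p1 + qlen - 1L + pad)
        aln <- local_align(q, substring(reference$seq[[chrom]], ws, we))
        st <- aln_stats(aln)
        if (st$identity >= params$min_identity_report &&
            st$aligned_len >= params$min_hit_len) {
          sstart <- ws + BiocGenerics::start(Biostrings::subject(aln)) - 2L  # 0-based
          send <- ws + BiocGenerics::end(Biostrings::subject(aln)) - 1L     # half-open
          hits[[length(hits) + 1L]] <- data.frame(
            query_id = query_id, chrom = chrom, start = sstart, end = send,
            strand = strand, identity = st$identity,
            aligned_len = st$aligned_len, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(query_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      identity = numeric(), aligned_len = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  # merge hits landing on the same locus (overlapping intervals on a
  # chromosome, either strand): keep the best identity per locus cluster
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  cluster <- integer(nrow(out))
  cid <- 0L; last_end <- -1L; last_chrom <- ""
  for (i in seq_len(nrow(out))) {
    if (!(out$chrom[i] == last_chrom && out$start[i] < last_end)) {
      cid <- cid + 1L
      last_chrom <- out$chrom[i]; last_end <- out$end[i]
    } else {
      last_end <- max(last_end, out$end[i])
    }
    cluster[i] <- cid
  }
  best <- unlist(lapply(split(seq_len(nrow(out)), cluster), function(ix) {
    ix[order(-out$identity[ix], -out$aligned_len[ix], out$start[ix])][1]
  }), use.names = FALSE)
  out <- out[sort(best), , drop = FALSE]
  out <- out[order(-out$identity, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chromosome-specificity filter for a SNP context
#'
#' The hit overlapping the extraction locus on the same chromosome is the
#' required self-hit (its absence signals a heavily duplicated or mutated
#' context: `NONUNIQUE_CONTEXT`). The SNP passes iff no other hit reaches
#' `off_target_identity`.
#' @param context a [extract_flank_context()] result.
#' @param hits data frame from [local_search()] on the full recipient genome.
#' @param params a [search_params()].
#' @return list with `status` (PASS/FAIL), `reason` (NA, `OFF_TARGET` or
#'   `NONUNIQUE_CONTEXT`) and `off_target` (the offending hits, if any).
#' @export
chromosome_specificity_filter <- function(context, hits,
                                          params = search_params()) {
  is_self <- hits$chrom == context$chrom &
    hits$start < context$self_locus["end"] &
    hits$end > context$self_locus["start"]
  if (!any(is_self)) {
    return(list(status = "FAIL", reason = "NONUNIQUE_CONTEXT",
                off_target = hits))
  }
  off <- hits[!is_self & hits$identity >= params$off_target_identity, ,
              drop = FALSE]
  if (nrow(off) > 0L) {
    list(status = "FAIL", reason = "OFF_TARGET", off_target = off)
  } else {
    list(status = "PASS", reason = NA_character_,
         off_target = off)
  }
}

#' Screen a set of passed SNPs for chromosome specificity
#'
#' Batch wrapper: builds the k-mer index once, then runs
#' [extract_flank_context()], [local_search()] and
#' [chromosome_specificity_filter()] for every row.
#' @param snps `VariantCandidate`/`FilterResult` rows (suitability PASSes).
#' @param reference recipient `Genome`.
#' @param params a [search_params()].
#' @param flank_bp flank width for context extraction.
#' @return `snps` with `spec_status` and `spec_reason` columns, plus a
#'   `hits` attribute (all reported hits).
#' @export
screen_specificity <- function(snps, reference, params = search_params(),
                               flank_bp = 50L) {
  index <- build_search_index(reference, params$seed_len)
  status <- character(nrow(snps))
  reason <- rep(NA_character_, nrow(snps))
  hit_rows <- vector("list", nrow(snps))
  for (i in seq_len(nrow(snps))) {
    ctx <- extract_flank_context(snps[i, ], reference, flank_bp)
    hits <- local_search(ctx$query, reference, params, ctx$snp_id, index)
    hit_rows[[i]] <- hits
    sf <- chromosome_specificity_filter(ctx, hits, params)
    status[i] <- sf$status
    reason[i] <- sf$reason
  }
  snps$spec_status <- status
  snps$spec_reason <- reason
  attr(snps, "hits") <- do.call(rbind, hit_rows)
  attr(snps, "index") <- index
  snps
}

#' Wallace-rule melting temperature
#'
#' `Tm = 2 * (A + T) + 4 * (G + C)`, the standard quick estimate for short
#' oligos.
#' @param seq primer sequence.
#' @return numeric Tm in degrees Celsius.
#' @export
wallace_tm <- function(seq) {
  b <- strsplit(toupper(seq), "")[[1]]
  2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
}

grow_primer_5prime <- function(refseq, end_pos, tm_range, len_range) {
  # plus-strand primer with fixed 3' end at end_pos (0-based, inclusive)
  for (len in len_range[1]:len_range[2]) {
    start <- end_pos - len + 1L
    if (start < 0L) break
    p <- substring(refseq, start + 1L, end_pos + 1L)
    tm <- wallace_tm(p)
    if (tm >= tm_range[1] && tm <= tm_range[2]) {
      return(list(seq = p, start = start, tm = tm))
    }
  }
  NULL
}

#' Design a KASP assay for a SNP
#'
#' Two allele-specific primers on the plus strand end 3' at the SNP and are
#' identical except for their terminal base (one per allele); primer length
#' grows from 18 until the Wallace Tm falls in `[58, 62]` (or length 30 is
#' reached, in which case design fails). The common primer is taken on the
#' reverse strand 3'-ward of the SNP, subject to the same Tm window and a
#' product length in `[40, 120]` bp. `specific` is TRUE iff a homology
#' search of each primer's genomic footprint finds no non-self locus at
#' >= `off_target_identity` (the unique-region contract of the assay
#' designer).
#'
#' @param context a [extract_flank_context()].
#' @param reference recipient `Genome`.
#' @param params a [search_params()].
#' @param tm_range acceptable Wallace Tm window.
#' @param primer_len_range allele/common primer length bounds.
#' @param product_range PCR product length bounds.
#' @param index optional prebuilt [build_search_index()] for the uniqueness
#'   check.
#' @return object of class `kasp_assay`, or `NULL` with a warning when no
#'   primer satisfies the constraints.
#' @export
design_assay <- function(context, reference, params = search_params(),
                         tm_range = c(58, 62), primer_len_range = c(18L, 30L),
                         product_range = c(40L, 120L), index = NULL) {
  chrom <- context$chrom; pos <- context$pos
  refseq <- reference$seq[[chrom]]
  ap <- grow_primer_5prime(refseq, pos, tm_range, primer_len_range)
  if (is.null(ap)) {
    warning("no allele primer satisfies Tm/length constraints")
    return(NULL)
  }
  stem <- substring(ap$seq, 1L, nchar(ap$seq) - 1L)
  allele_ref <- paste0(stem, context$alleles["ref"])
  allele_alt <- paste0(stem, context$alleles["alt"])

  common <- NULL
  for (e in (pos + primer_len_range[1] + 1L):(ap$start + product_range[2] - 1L)) {
    if (e > nchar(refseq) - 1L) break
    product_len <- e - ap$start + 1L
    if (product_len < product_range[1]) next
    if (product_len > product_range[2]) break
    for (len in primer_len_range[1]:primer_len_range[2]) {
      cstart <- e - len + 1L
      if (cstart <= pos) break  # common primer must not cover the SNP
      win <- substring(refseq, cstart + 1L, e + 1L)
      tm <- wallace_tm(win)
      if (tm >= tm_range[1] && tm <= tm_range[2]) {
        common <- list(seq = revcomp(win), start = cstart, end = e,
                       tm = tm, product_len = product_len)
        break
      }
    }
    if (!is.null(common)) break
  }
  if (is.null(common)) {
    warning("no common primer satisfies Tm/product constraints")
    return(NULL)
  }

  # uniqueness contract: each primer footprint must be unique in the genome
  specific <- TRUE
  for (footprint in list(
    list(seq = substring(refseq, ap$start + 1L, pos + 1L),
         locus = c(ap$start, pos + 1L)),
    list(seq = substring(refseq, common$start + 1L, common$end + 1L),
         locus = c(common$start, common$end + 1L)))) {
    plen <- nchar(footprint$seq)
    sl <- min(params$seed_len, plen)
    pp <- search_params(seed_len = sl,
                        min_identity_report = params$off_target_identity,
                        min_hit_len = max(sl, ceiling(0.6 * plen)),
                        off_target_identity = params$off_target_identity)
    h <- local_search(footprint$seq, reference, pp, query_id = context$snp_id,
                      index = if (!is.null(index) &&
                                  index$seed_len == pp$seed_len) index)
    self <- h$chrom == chrom & h$start < footprint$locus[2] &
      h$end > footprint$locus[1]
    if (any(!self & h$identity >= params$off_target_identity)) {
      specific <- FALSE
      break
    }
  }

  structure(list(
    snp_id = context$snp_id,
    allele_primers = c(ref = allele_ref, alt = allele_alt),
    common_primer = unname(common$seq),
    product_len = common$product_len,
    tm_estimates = c(allele = ap$tm, common = common$tm),
    specific = specific
  ), class = "kasp_assay")
}
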