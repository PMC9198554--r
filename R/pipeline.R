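# iohub: umbrella pipeline wiring the stages together.
#
# Fixed stage order: simulate -> filter-snps -> screen-specificity ->
# design-kasp -> genotype (breeding simulation) -> call-segments ->
# summarize. Every stage logs its input/output counts and effective
# thresholds so filter attrition is auditable.

#' Default pipeline configuration
#'
#' A nested list mirroring the stages; values can be overridden via
#' `modifyList()` semantics in [run_pipeline()] or a YAML file on the
#' command line. Unknown keys are rejected.
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "introkasp_run",
    genome = list(groups = 2L, chrom_length_bp = 20000L,
                  divergence = c(At = 0.005, G = 0.0075),
                  indel_rate = 2e-4, repeat_fraction = 0.05,
                  flank_poly_events = 2L, low_depth_events = 0L),
    reads = list(coverage = 20, read_len = 250L, frag_mean = 600L,
                 error_rate = 0, junk_frac = 0.02),
    thresholds = list(min_mapq = 10L, min_dp = 10L, alt_fraction = 1.0,
                      flank_bp = 50L, flank_min_depth = 5L,
                      flank_ref_frac = 0.80),
    search = list(seed_len = 16L, min_identity_report = 0.90,
                  min_hit_len = 61L, off_target_identity = 0.97),
    scheme = list(pairing_prob = c("At-A" = 0.70, "G-B" = 0.30,
                                   "At-D" = 0.02, "G-D" = 0.10),
                  second_crossover_prob = 0,
                  transmission_bias = numeric(0)),
    breeding = list(n_backcross = 2L, n_self = 3L, family_size = 8L,
                    n_families = 12L),
    segments = list(min_markers = 1L, bridge_nocall = TRUE),
    design = list(max_assays = 25L)
  )
}

merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  unknown <- setdiff(names(override), names(base))
  if (length(unknown)) {
    abort_user(sprintf("unknown configuration key(s): %s",
                       paste(unknown, collapse = ", ")))
  }
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]])) {
      merge_config(base[[k]], override[[k]])
    } else override[[k]]
  }
  base
}

#' Read a pipeline configuration file (YAML)
#' @param file YAML path; keys must match [default_config()].
#' @return merged configuration list.
#' @export
read_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  if (!is.null(cfg$genome$divergence)) {
    cfg$genome$divergence <- unlist(cfg$genome$divergence)
  }
  if (!is.null(cfg$scheme$pairing_prob)) {
    cfg$scheme$pairing_prob <- unlist(cfg$scheme$pairing_prob)
  }
  if (!is.null(cfg$scheme$transmission_bias)) {
    cfg$scheme$transmission_bias <- unlist(cfg$scheme$transmission_bias)
  }
  merge_config(default_config(), cfg)
}

log_stage <- function(log, stage, ...) {
  entry <- list(stage = stage, ...)
  log[[length(log) + 1L]] <- entry
  message(sprintf("[%s] %s", stage,
                  paste(names(entry)[-1], unlist(entry[-1]), sep = "=",
                        collapse = " ")))
  log
}

#' Run the full pipeline on synthetic data
#'
#' @param config configuration list (see [default_config()]); partial lists
#'   are merged over the defaults.
#' @return invisibly, a list with the run artifacts (genomes, truth,
#'   filter results, markers, lines, segments, catalog, summary, log);
#'   files are written under `config$out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- merge_config(default_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  seed <- cfg$seed

  # --- simulate -------------------------------------------------------
  spec <- do.call(genome_spec, cfg$genome)
  gn <- make_genomes(spec, seed)
  donor <- attach_recipient(gn$donor, gn$recipient)
  lens <- genome_lengths(gn$recipient)
  write_fasta(gn$recipient, file.path(cfg$out_dir, "recipient.fa"))
  write_fasta(gn$donor, file.path(cfg$out_dir, "donor.fa"))
  utils::write.table(gn$truth, file.path(cfg$out_dir, "truth_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  reads <- do.call(simulate_reads,
                   c(list(genome = donor), cfg$reads, list(seed = seed)))
  write_sam(reads, file.path(cfg$out_dir, "reads.sam"), lens)
  log <- log_stage(log, "simulate", chromosomes = length(lens),
                   truth_variants = nrow(gn$truth), reads = nrow(reads))

  # --- filter-snps ----------------------------------------------------
  thr <- do.call(filter_thresholds, cfg$thresholds)
  target_chroms <- sort(unique(donor$target))
  results <- list(); pileups <- list()
  for (ch in target_chroms) {
    d <- discover_snps(reads, gn$recipient, ch, thr)
    results[[ch]] <- d$results
    pileups[[ch]] <- d$pileup
  }
  res <- do.call(rbind, results)
  rownames(res) <- NULL
  write_vcf(res, file.path(cfg$out_dir, "candidates.vcf"))
  utils::write.table(res, file.path(cfg$out_dir, "filter_audit.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  passed <- res[res$status == "PASS", , drop = FALSE]
  log <- log_stage(log, "filter-snps", candidates = nrow(res),
                   passed = nrow(passed), min_dp = thr$min_dp,
                   flank_min_depth = thr$flank_min_depth)

  # --- screen-specificity ---------------------------------------------
  sp <- do.call(search_params, cfg$search)
  passed <- screen_specificity(passed, gn$recipient, sp, thr$flank_bp)
  search_idx <- attr(passed, "index")
  hits_all <- attr(passed, "hits")
  if (!is.null(hits_all)) {
    utils::write.table(hits_all, file.path(cfg$out_dir, "specificity_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  specific <- passed[passed$spec_status == "PASS", , drop = FALSE]
  write_vcf(specific, file.path(cfg$out_dir, "chromosome_specific.vcf"))
  log <- log_stage(log, "screen-specificity", screened = nrow(passed),
                   chromosome_specific = nrow(specific),
                   off_target_identity = sp$off_target_identity)

  # --- design-kasp ----------------------------------------------------
  n_design <- min(nrow(specific), cfg$design$max_assays)
  assays <- list()
  for (i in seq_len(n_design)) {
    ctx <- extract_flank_context(specific[i, ], gn$recipient, thr$flank_bp)
    a <- tryCatch(design_assay(ctx, gn$recipient, sp, index = search_idx),
                  warning = function(w) NULL)
    if (!is.null(a)) assays[[length(assays) + 1L]] <- a
  }
  assay_df <- do.call(rbind, lapply(assays, function(a) {
    data.frame(snp_id = a$snp_id, allele_primer_ref = a$allele_primers["ref"],
               allele_primer_alt = a$allele_primers["alt"],
               common_primer = a$common_primer, product_len = a$product_len,
               tm_allele = a$tm_estimates["allele"],
               tm_common = a$tm_estimates["common"],
               specific = a$specific, stringsAsFactors = FALSE)
  }))
  if (!is.null(assay_df)) {
    utils::write.table(assay_df, file.path(cfg$out_dir, "kasp_assays.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  log <- log_stage(log, "design-kasp", attempted = n_design,
                   designed = length(assays))

  # --- marker panel ---------------------------------------------------
  sub_of <- c(A = "At", B = "G", D = "nonspecific")
  markers <- data.frame(
    marker_id = sprintf("WRC%04d", seq_len(nrow(specific))),
    chrom = specific$chrom, pos = specific$pos, set_id = 4L,
    specificity = unname(sub_of[slot_subgenome(specific$chrom)]),
    stringsAsFactors = FALSE)
  markers <- markers[order(markers$chrom, markers$pos), , drop = FALSE]
  markers$marker_id <- sprintf("WRC%04d", seq_len(nrow(markers)))
  write_marker_map(markers, file.path(cfg$out_dir, "marker_map.tsv"))
  spacing <- panel_spacing(markers, lens)
  utils::write.table(spacing, file.path(cfg$out_dir, "panel_spacing.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log <- log_stage(log, "panel", markers = nrow(markers))

  # --- breeding simulation -> genotypes -------------------------------
  scheme <- do.call(cross_scheme, c(cfg$scheme, list(seed = seed)))
  recurrent <- recipient_line(gn$recipient)
  f1 <- f1_line(gn$recipient, gn$donor)
  ils <- list()
  founders <- cross(f1, recurrent, cfg$breeding$n_families, scheme)
  for (fi in seq_along(founders)) {
    ln <- founders[[fi]]
    ln$line_id <- sprintf("fam%02d", fi)
    for (b in seq_len(cfg$breeding$n_backcross - 1L)) {
      off <- cross(ln, recurrent, cfg$breeding$family_size, scheme)
      keep <- Filter(function(o) nrow(line_true_segments(o)) > 0L, off)
      if (!length(keep)) break
      ln <- keep[[1]]
    }
    for (s in seq_len(cfg$breeding$n_self)) {
      off <- cross(ln, ln, cfg$breeding$family_size, scheme)
      segs <- lapply(off, line_true_segments)
      n_donor <- vapply(segs, nrow, integer(1))
      if (all(n_donor == 0L)) { ln <- NULL; break }
      hom_ok <- vapply(seq_along(off), function(k) {
        d <- segs[[k]]
        nrow(d) > 0L && all(table(paste(d$chrom, d$start, d$end, d$src)) == 2L)
      }, logical(1))
      ln <- if (any(hom_ok)) off[[which(hom_ok)[1]]] else
        off[[which(n_donor > 0L)[1]]]
      if (any(hom_ok)) break
    }
    if (!is.null(ln)) {
      d <- line_true_segments(ln)
      if (nrow(d) > 0L && all(table(paste(d$chrom, d$start, d$end, d$src)) == 2L)) {
        ln$line_id <- sprintf("IL%02d", length(ils) + 1L)
        ils[[length(ils) + 1L]] <- ln
      }
    }
  }
  log <- log_stage(log, "genotype", families = cfg$breeding$n_families,
                   homozygous_ILs = length(ils))
  if (!length(ils)) abort_user("breeding simulation produced no homozygous ILs")
  gm <- genotype_truth(ils, markers)
  write_genotype_matrix(gm, file.path(cfg$out_dir, "genotypes.csv"))
  write_pedigree(ils, file.path(cfg$out_dir, "pedigree.tsv"))

  # --- call-segments / summarize --------------------------------------
  segs <- call_segments(gm, markers, lens,
                        min_markers = cfg$segments$min_markers,
                        bridge_nocall = cfg$segments$bridge_nocall)
  segs <- assign_donor_chromosome(segs, markers)
  catalog <- build_catalog(segs, markers, lens)
  cov <- coverage_stats(catalog, as.list(lens))
  summ <- summarize_catalog(catalog)
  hom <- segs[segs$zygosity == "hom", , drop = FALSE]
  if (nrow(hom) > 0L) {
    name_of <- setNames(catalog$name, paste(catalog$recipient_chrom,
                                            catalog$signature, sep = "|"))
    write_bed(data.frame(chrom = hom$chrom, start = hom$outer_start,
                         end = hom$outer_end,
                         name = unname(name_of[paste(hom$chrom, hom$support,
                                                     sep = "|")]),
                         score = hom$n_support, stringsAsFactors = FALSE),
              file.path(cfg$out_dir, "segments.bed"))
  }
  utils::write.table(catalog, file.path(cfg$out_dir, "catalog.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary_out <- list(
    n_lines = summ$n_lines,
    total_occurrences = summ$total_occurrences,
    occurrences_by_subgenome = as.list(summ$occurrences_by_subgenome),
    unique_by_subgenome = as.list(summ$unique_by_subgenome),
    whole_chromosome = summ$whole_chromosome,
    recipient_tallies = as.list(summ$recipient_tallies),
    per_line = as.list(summ$per_line),
    coverage = stats::setNames(as.list(cov$coverage_pct), cov$donor_chrom),
    coverage_genome_wide = attr(cov, "genome_wide"))
  jsonlite::write_json(summary_out, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log <- log_stage(log, "summarize", segments = nrow(hom),
                   unique_segments = nrow(catalog))
  jsonlite::write_json(log, file.path(cfg$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(genomes = gn, truth = gn$truth, results = res,
                 passed = passed, markers = markers, lines = ils,
                 genotypes = gm, segments = segs, catalog = catalog,
                 coverage = cov, summary = summ, log = log))
}
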