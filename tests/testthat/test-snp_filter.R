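# snp_filter: alignment filtering, dedup, pileup, caller, suitability.

test_that("filter_alignments applies the MAPQ and flag rules at the boundary", {
  recs <- as_records(
    rec_row("a", "1A", 100L, "ACGT", mapq = 9L),
    rec_row("b", "1A", 100L, "ACGT", mapq = 10L),
    rec_row("c", "1A", 100L, "ACGT", unmapped = TRUE),
    rec_row("d", "1A", 100L, "ACGT", supplementary = TRUE),
    rec_row("e", "1A", 100L, "ACGT", proper_pair = FALSE),
    rec_row("f", "1A", 200L, "ACGT", mapq = 60L))
  out <- filter_alignments(recs, filter_thresholds())
  expect_identical(out$read_id, c("b", "f"))  # order preserved
})

test_that("mark_duplicates keeps one record per positional key", {
  recs <- as_records(
    rec_row("r2", "1A", 100L, "ACGT", mate_pos = 500L),
    rec_row("r1", "1A", 100L, "ACGT", mate_pos = 500L),
    rec_row("r3", "1A", 100L, "ACGT", mate_pos = 500L),
    rec_row("r4", "1A", 100L, "ACGT", mate_pos = 600L),
    rec_row("r5", "1A", 100L, "ACGT", mate_pos = 500L, strand = "-"))
  out <- mark_duplicates(recs)
  # smallest read_id wins the three-way tie; different mate_pos and strand
  # are distinct keys
  expect_setequal(out$read_id, c("r1", "r4", "r5"))
})

test_that("compute_pileup walks CIGARs correctly", {
  recs <- do.call(as_records, lapply(1:12, function(i) {
    rec_row(paste0("r", i), "c", 10L, "GGGG")
  }))
  pu <- compute_pileup(recs, "c", 0L, 30L)
  expect_equal(pu$depth[pu$pos == 11], 12)
  expect_equal(pu$G[pu$pos == 11], 12)
  expect_equal(sum(pu$del_count), 0)

  # a deletion spanning p contributes to del_count and to depth
  recs2 <- as_records(
    rec_row("d1", "c", 10L, "AAAACCCC", cigar = "4M2D4M"),
    rec_row("d2", "c", 12L, "TTTT"),
    rec_row("i1", "c", 10L, "AAAAGGCCCC", cigar = "5M2I3M"))
  pu2 <- compute_pileup(recs2, "c", 0L, 30L)
  expect_equal(pu2$del_count[pu2$pos == 14], 1)
  expect_equal(pu2$del_count[pu2$pos == 15], 1)
  expect_equal(pu2$ins_adjacent[pu2$pos == 14], 1)
  # conservation: base counts + deletions = depth at every position
  expect_true(all(pu2$A + pu2$C + pu2$G + pu2$T + pu2$del_count == pu2$depth))
  expect_error(compute_pileup(as_records(rec_row("x", "c", 1L, "AC",
                                                 cigar = "2Q")),
                              "c", 0L, 10L), "malformed CIGAR")
})

test_that("compute_pileup matches a naive per-read oracle on random data", {
  set.seed(31)
  rows <- lapply(1:60, function(i) {
    pos <- sample(0:400, 1)
    type <- sample(c("M", "D", "I", "S"), 1, prob = c(0.55, 0.15, 0.15, 0.15))
    if (type == "M") {
      n <- sample(10:40, 1)
      rec_row(paste0("r", i), "c", pos, random_seq(n))
    } else if (type == "D") {
      rec_row(paste0("r", i), "c", pos, random_seq(20),
              cigar = sprintf("10M%dD10M", sample(1:5, 1)))
    } else if (type == "I") {
      k <- sample(1:4, 1)
      rec_row(paste0("r", i), "c", pos, random_seq(20 + k),
              cigar = sprintf("10M%dI10M", k))
    } else {
      rec_row(paste0("r", i), "c", pos, random_seq(25), cigar = "5S15M5S")
    }
  })
  recs <- do.call(as_records, rows)
  pu <- compute_pileup(recs, "c", 0L, 460L)
  orc <- oracle_pileup(recs, "c", 0L, 460L)
  expect_equal(pu$A, orc$A)
  expect_equal(pu$C, orc$C)
  expect_equal(pu$G, orc$G)
  expect_equal(pu$T, orc$T)
  expect_equal(pu$del_count, orc$del_count)
  expect_equal(pu$ins_adjacent, orc$ins_adjacent)
  expect_equal(pu$depth, orc$depth)
})

# a pileup with uniform depth and a single-SNP column, built by hand
flat_pileup <- function(L, depth, ref = "A", snp_pos, alt = "G", alt_n,
                        ref_at_snp = 0L) {
  df <- data.frame(chrom = "c", pos = 0:(L - 1L), A = 0L, C = 0L, G = 0L,
                   T = 0L, del_count = 0L, ins_adjacent = 0L,
                   stringsAsFactors = FALSE)
  df[[ref]] <- depth
  df[[ref]][df$pos == snp_pos] <- ref_at_snp
  df[[alt]][df$pos == snp_pos] <- alt_n
  df$depth <- df$A + df$C + df$G + df$T + df$del_count
  attr(df, "chrom") <- "c"
  attr(df, "interval") <- c(0L, L)
  df
}

ref_genome_c <- function(L) toy_genome(c(c = paste(rep("A", L), collapse = "")))

test_that("call_candidates implements the count-based stand-in", {
  g <- ref_genome_c(200L)
  pu <- flat_pileup(200L, 15L, snp_pos = 100L, alt_n = 15L)
  cc <- call_candidates(pu, g)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$genotype, "hom_alt")
  expect_equal(cc$DP, 15L)
  expect_equal(c(cc$AD_ref, cc$AD_alt), c(0L, 15L))
  # all-reference column: no candidate
  expect_equal(nrow(call_candidates(flat_pileup(200L, 15L, snp_pos = 100L,
                                                alt_n = 0L, ref_at_snp = 15L),
                                    g)), 0L)
  # 7 alt / 8 ref -> het
  het <- call_candidates(flat_pileup(200L, 15L, snp_pos = 100L, alt_n = 7L,
                                     ref_at_snp = 8L), g)
  expect_equal(het$genotype, "het")
  expect_equal(c(het$AD_ref, het$AD_alt), c(8L, 7L))
  # two non-reference alleles with >= 2 reads each -> multiallelic
  pu3 <- flat_pileup(200L, 15L, snp_pos = 100L, alt_n = 8L, ref_at_snp = 0L)
  pu3$C[pu3$pos == 100L] <- 7L
  ma <- call_candidates(pu3, g)
  expect_true(ma$multiallelic)
})

suit <- function(pu, cand, thr = filter_thresholds(), L = 200L) {
  kasp_suitability_filter(cand, pu, thr, L, ref_genome_c(L))
}

cand_at <- function(pos, DP, alt_n, genotype = "hom_alt", ref_n = 0L) {
  data.frame(chrom = "c", pos = pos, ref = "A", alt = "G",
             genotype = genotype, DP = DP, AD_ref = ref_n, AD_alt = alt_n,
             multiallelic = FALSE, stringsAsFactors = FALSE)
}

test_that("suitability thresholds are strict exactly as documented", {
  # DP 15, clean flanks -> PASS
  pu <- flat_pileup(200L, 15L, snp_pos = 100L, alt_n = 15L)
  expect_equal(suit(pu, cand_at(100L, 15L, 15L))$status, "PASS")
  # DP 10 (10/10 alt) -> LOW_DEPTH ("greater than 10" is strict)
  pu10 <- flat_pileup(200L, 15L, snp_pos = 100L, alt_n = 10L)
  r <- suit(pu10, cand_at(100L, 10L, 10L))
  expect_equal(r$reason, "LOW_DEPTH")
  # heterozygous candidate
  expect_equal(suit(pu, cand_at(100L, 15L, 7L, genotype = "het",
                                ref_n = 8L))$reason, "NOT_HOMOZYGOUS")
  # impure alt (14/15)
  expect_equal(suit(pu, cand_at(100L, 15L, 14L, ref_n = 1L))$reason,
               "IMPURE_ALT")
  # one flank position at depth exactly 5 -> LOW_FLANK_DEPTH (strict)
  pu5 <- flat_pileup(200L, 15L, snp_pos = 100L, alt_n = 15L)
  pu5$A[pu5$pos == 90L] <- 5L
  pu5$depth <- pu5$A + pu5$C + pu5$G + pu5$T + pu5$del_count
  expect_equal(suit(pu5, cand_at(100L, 15L, 15L))$reason, "LOW_FLANK_DEPTH")
  # depth exactly 6 passes
  pu6 <- flat_pileup(200L, 15L, snp_pos = 100L, alt_n = 15L)
  pu6$A[pu6$pos == 90L] <- 6L
  pu6$depth <- pu6$A + pu6$C + pu6$G + pu6$T + pu6$del_count
  expect_equal(suit(pu6, cand_at(100L, 15L, 15L))$status, "PASS")
  # flank ref fraction 0.79 fails, 0.80 passes
  pu79 <- flat_pileup(200L, 100L, snp_pos = 100L, alt_n = 100L)
  pu79$A[pu79$pos == 60L] <- 79L; pu79$C[pu79$pos == 60L] <- 21L
  pu79$depth <- pu79$A + pu79$C + pu79$G + pu79$T + pu79$del_count
  expect_equal(suit(pu79, cand_at(100L, 100L, 100L))$reason,
               "FLANK_POLYMORPHIC")
  pu80 <- flat_pileup(200L, 100L, snp_pos = 100L, alt_n = 100L)
  pu80$A[pu80$pos == 60L] <- 80L; pu80$C[pu80$pos == 60L] <- 20L
  pu80$depth <- pu80$A + pu80$C + pu80$G + pu80$T + pu80$del_count
  expect_equal(suit(pu80, cand_at(100L, 100L, 100L))$status, "PASS")
  # one read with an insertion in the flank -> FLANK_INDEL
  pui <- flat_pileup(200L, 15L, snp_pos = 100L, alt_n = 15L)
  pui$ins_adjacent[pui$pos == 120L] <- 1L
  expect_equal(suit(pui, cand_at(100L, 15L, 15L))$reason, "FLANK_INDEL")
  # FLANK_INDEL outranks the depth/fraction flank rules (rule-major order)
  pui$A[pui$pos == 90L] <- 2L
  pui$depth <- pui$A + pui$C + pui$G + pui$T + pui$del_count
  expect_equal(suit(pui, cand_at(100L, 15L, 15L))$reason, "FLANK_INDEL")
  # sites too close to a chromosome end
  expect_equal(suit(pu, cand_at(30L, 15L, 15L))$reason, "EDGE_OF_CHROM")
  expect_equal(suit(pu, cand_at(160L, 15L, 15L))$reason, "EDGE_OF_CHROM")
  # missing pileup coverage is an error, not a FAIL
  punar <- flat_pileup(200L, 15L, snp_pos = 100L, alt_n = 15L)
  attr(punar, "interval") <- c(60L, 140L)
  expect_error(suit(punar[punar$pos >= 60 & punar$pos < 140, ],
                    cand_at(100L, 15L, 15L)), "does not cover")
})

test_that("tightening thresholds never grows the PASS set", {
  gn <- make_genomes(genome_spec(groups = 1, chrom_length_bp = 8000,
                                 divergence = 0.004), seed = 13)
  donor <- attach_recipient(gn$donor, gn$recipient)
  reads <- simulate_reads(donor, coverage = 9, seed = 13, error_rate = 0.002)
  base_thr <- filter_thresholds(min_dp = 6L, flank_min_depth = 2L)
  pass_set <- function(thr) {
    res <- do.call(rbind, lapply(c("1A", "1B"), function(ch) {
      discover_snps(reads, gn$recipient, ch, thr)$results
    }))
    paste(res$chrom, res$pos)[res$status == "PASS"]
  }
  base <- pass_set(base_thr)
  expect_gt(length(base), 0L)
  tighter <- list(
    filter_thresholds(min_dp = 8L, flank_min_depth = 2L),
    filter_thresholds(min_dp = 6L, flank_min_depth = 4L),
    filter_thresholds(min_dp = 6L, flank_min_depth = 2L,
                      flank_ref_frac = 0.95))
  for (thr in tighter) {
    expect_true(all(pass_set(thr) %in% base))
  }
})
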