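# introgression_core: fluorescence calling, segment calling, catalog,
# coverage, summaries.

test_that("fluorescence calls use nearest centroid with a margin", {
  ctl <- data.frame(
    sample_id = c("w", "h", "d", "n"),
    fam = c(0.1, 1.0, 2.0, 0.05), hex = c(2.0, 1.0, 0.1, 0.05),
    role = c("recipient_control", "het_control", "donor_control", "ntc"))
  samples <- data.frame(
    sample_id = c("s_w", "s_d", "s_mid", "s_ntc"),
    fam = c(0.1, 2.0, 0.55, 0.05), hex = c(2.0, 0.1, 1.5, 0.05),
    role = "sample")
  calls <- call_genotypes_from_fluorescence(rbind(ctl, samples))
  expect_equal(calls$state[calls$sample_id == "s_w"], "HomRecipient")
  expect_equal(calls$state[calls$sample_id == "s_d"], "HomDonor")
  expect_equal(calls$state[calls$sample_id == "s_mid"], "NoCall")
  expect_equal(calls$state[calls$sample_id == "s_ntc"], "NoCall")
  expect_error(call_genotypes_from_fluorescence(samples), "control")
})

# shared toy panel: one chromosome, six markers at known positions
toy_markers <- data.frame(
  marker_id = paste0("m", 1:6), chrom = "2A",
  pos = c(1000L, 3000L, 5000L, 7000L, 9000L, 11000L),
  set_id = 1L, specificity = "At", stringsAsFactors = FALSE)
toy_lens <- c(`2A` = 12000L)

calls_mat <- function(v, line = "L1") {
  m <- matrix(v, nrow = 1, dimnames = list(line, toy_markers$marker_id))
  m
}

test_that("call_segments applies the boundary conventions", {
  # W W D D D W
  segs <- call_segments(calls_mat(c(0L, 0L, 2L, 2L, 2L, 0L)), toy_markers,
                        toy_lens)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$zygosity, "hom")
  expect_equal(c(segs$inner_start, segs$inner_end), c(5000L, 9001L))
  expect_equal(c(segs$outer_start, segs$outer_end), c(4000L, 10000L))
  expect_equal(segs$support, "m3,m4,m5")

  # donor at every marker: outer spans the whole chromosome
  whole <- call_segments(calls_mat(rep(2L, 6)), toy_markers, toy_lens)
  expect_equal(c(whole$outer_start, whole$outer_end), c(0L, 12000L))

  # D NoCall D bridges to a single two-marker segment
  br <- call_segments(calls_mat(c(2L, NA, 2L, 0L, 0L, 0L)), toy_markers,
                      toy_lens)
  expect_equal(nrow(br), 1L)
  expect_equal(br$support, "m1,m3")
  # two consecutive NoCalls break the run
  br2 <- call_segments(calls_mat(c(2L, NA, NA, 2L, 0L, 0L)), toy_markers,
                       toy_lens)
  expect_equal(nrow(br2), 2L)
  # bridging can be disabled
  br3 <- call_segments(calls_mat(c(2L, NA, 2L, 0L, 0L, 0L)), toy_markers,
                       toy_lens, bridge_nocall = FALSE)
  expect_equal(nrow(br3), 2L)

  # a het call breaks a hom run and opens a het segment
  mix <- call_segments(calls_mat(c(2L, 2L, 1L, 2L, 0L, 0L)), toy_markers,
                       toy_lens)
  expect_equal(sort(mix$zygosity), c("het", "hom", "hom"))

  # min_markers drops short runs with a note
  expect_message(
    short <- call_segments(calls_mat(c(2L, 0L, 0L, 2L, 2L, 0L)), toy_markers,
                           toy_lens, min_markers = 2L),
    "dropped")
  expect_equal(nrow(short), 1L)
})

test_that("donor chromosomes are assigned by specificity vote", {
  mk <- data.frame(marker_id = paste0("m", 1:4), chrom = "3D",
                   pos = c(100L, 200L, 300L, 400L), set_id = 1L,
                   specificity = c("G", "G", "At", "nonspecific"),
                   stringsAsFactors = FALSE)
  seg <- data.frame(line_id = "L", chrom = "3D", zygosity = "hom",
                    inner_start = 100L, inner_end = 201L, outer_start = 0L,
                    outer_end = 250L, n_support = 2L, support = "m1,m2",
                    stringsAsFactors = FALSE)
  out <- assign_donor_chromosome(seg, mk)
  expect_equal(out$donor_chrom, "3G")
  expect_false(out$ambiguous_donor)
  # tie -> ambiguous, fallback from recipient homoeology
  seg2 <- seg; seg2$support <- "m2,m3"; seg2$n_support <- 2L
  out2 <- assign_donor_chromosome(seg2, mk)
  expect_true(out2$ambiguous_donor)
  expect_equal(out2$donor_chrom, "3At")
  # 2A segment with At support
  mk3 <- data.frame(marker_id = "a", chrom = "2A", pos = 5L, set_id = 1L,
                    specificity = "At", stringsAsFactors = FALSE)
  seg3 <- seg; seg3$chrom <- "2A"; seg3$support <- "a"
  expect_equal(assign_donor_chromosome(seg3, mk3)$donor_chrom, "2At")
})

test_that("build_catalog groups by signature and names deterministically", {
  gm <- rbind(calls_mat(c(0L, 2L, 2L, 0L, 0L, 0L), "L1"),
              calls_mat(c(0L, 2L, 2L, 0L, 0L, 0L), "L2"),
              calls_mat(c(0L, 2L, 2L, 2L, 0L, 0L), "L3"),   # nested superset
              calls_mat(rep(2L, 6), "L4"))                  # whole chromosome
  segs <- assign_donor_chromosome(
    call_segments(gm, toy_markers, toy_lens), toy_markers)
  cat_df <- build_catalog(segs, toy_markers, toy_lens)
  expect_equal(nrow(cat_df), 3L)
  shared <- cat_df[cat_df$signature == "m2,m3", ]
  expect_equal(shared$n_members, 2L)
  expect_equal(shared$member_lines, "L1,L2")
  expect_equal(shared$name, "2At.A1")
  expect_equal(cat_df$name[cat_df$signature == "m2,m3,m4"], "2At.A2")
  expect_equal(cat_df$name[cat_df$whole_chromosome], "2At")
})

empty_catalog_for_test <- function() {
  introKASP::build_catalog(
    data.frame(line_id = character(), chrom = character(),
               zygosity = character(), inner_start = integer(),
               inner_end = integer(), outer_start = integer(),
               outer_end = integer(), n_support = integer(),
               support = character(), stringsAsFactors = FALSE),
    toy_markers, toy_lens)
}

test_that("coverage union arithmetic matches the documented examples", {
  mk_cat <- function(intervals, whole = FALSE) {
    do.call(rbind, lapply(seq_along(intervals), function(i) {
      data.frame(name = paste0("s", i), donor_chrom = "1At",
                 donor_subgenome = "At", recipient_chrom = "1A",
                 recipient_letter = "A", ordinal = i,
                 whole_chromosome = whole, signature = NA,
                 n_members = 1L, member_lines = paste0("L", i),
                 outer_start = intervals[[i]][1], outer_end = intervals[[i]][2],
                 inner_start = NA, inner_end = NA, n_support = 1L,
                 ambiguous_donor = FALSE, stringsAsFactors = FALSE)
    }))
  }
  lens <- list(`1A` = 100L)
  expect_equal(coverage_stats(mk_cat(list(c(0L, 100L))), lens)$coverage_pct, 100)
  expect_equal(coverage_stats(mk_cat(list(c(0L, 60L), c(40L, 100L))),
                              lens)$coverage_pct, 100)
  expect_equal(coverage_stats(mk_cat(list(c(0L, 40L), c(60L, 100L))),
                              lens)$coverage_pct, 80)
  # random catalogs vs the per-base boolean oracle
  set.seed(77)
  for (k in 1:10) {
    n <- sample(1:6, 1)
    iv <- lapply(seq_len(n), function(i) {
      s <- sample(0:90, 1); c(s, s + sample(5:(100 - s), 1))
    })
    cc <- mk_cat(iv)
    expect_equal(coverage_stats(cc, lens)$coverage_pct,
                 unname(oracle_coverage(cc, lens)), tolerance = 1e-9)
  }
  # monotonicity: adding a segment never decreases coverage
  c1 <- mk_cat(list(c(10L, 30L)))
  c2 <- mk_cat(list(c(10L, 30L), c(50L, 60L)))
  expect_gte(coverage_stats(c2, lens)$coverage_pct,
             coverage_stats(c1, lens)$coverage_pct)
})

test_that("summarize_catalog totals, tallies and per-line statistics", {
  empty <- summarize_catalog(empty_catalog_for_test())
  expect_equal(empty$total_occurrences, 0L)
  one <- data.frame(name = "1At.A1", donor_chrom = "1At",
                    donor_subgenome = "At", recipient_chrom = "1A",
                    recipient_letter = "A", ordinal = 1L,
                    whole_chromosome = FALSE, signature = "m1",
                    n_members = 1L, member_lines = "L1", outer_start = 0L,
                    outer_end = 10L, inner_start = 0L, inner_end = 10L,
                    n_support = 1L, ambiguous_donor = FALSE,
                    stringsAsFactors = FALSE)
  s1 <- summarize_catalog(one)
  expect_equal(s1$total_occurrences, 1L)
  expect_equal(unname(s1$unique_by_subgenome), c(1L, 0L))
  expect_equal(unname(s1$per_line), c(1, 1, 1))
  # multiplicity weights occurrences but not unique counts
  s2 <- summarize_catalog(one, line_multiplicity = c(L1 = 3L))
  expect_equal(s2$total_occurrences, 3L)
  expect_equal(unname(s2$unique_by_subgenome), c(1L, 0L))
  expect_equal(s2$n_lines, 3L)
  expect_error(summarize_catalog(one, line_multiplicity = c(L1 = 0L)),
               "multiplicity")
})

test_that("segment caller brackets the simulated truth (inner/truth/outer)", {
  gn <- make_genomes(genome_spec(groups = 2, chrom_length_bp = 20000,
                                 divergence = 0.001), seed = 17)
  lens <- genome_lengths(gn$recipient)
  markers <- panel_for(lens, spacing = 800L)
  set.seed(17)
  lines <- lapply(1:20, function(i) {
    ln <- recipient_line(gn$recipient, sprintf("IL%02d", i))
    slot <- sample(c("1A", "2A", "1B", "2B"), 1)
    src <- paste0(sub("[AB]$", "", slot),
                  if (grepl("A$", slot)) "At" else "G")
    s <- sample(0:15000, 1); e <- s + sample(2000:5000, 1)
    blk <- list(src = c(slot, src, slot),
                start = c(0L, as.integer(s), as.integer(min(e, 20000L))),
                end = c(as.integer(s), as.integer(min(e, 20000L)), 20000L))
    if (s == 0L) blk <- lapply(blk, function(x) x[-1])
    if (min(e, 20000L) == 20000L) blk <- lapply(blk, function(x) x[-length(x)])
    ln$mosaic[[slot]] <- list(blk, blk)
    attr(ln, "truth") <- data.frame(chrom = slot, start = s,
                                    end = min(e, 20000), stringsAsFactors = FALSE)
    ln
  })
  gm <- genotype_truth(lines, markers)
  segs <- call_segments(gm, markers, lens)
  for (ln in lines) {
    tr <- attr(ln, "truth")
    mine <- segs[segs$line_id == ln$line_id, ]
    n_markers_in <- sum(markers$chrom == tr$chrom & markers$pos >= tr$start &
                          markers$pos < tr$end)
    if (n_markers_in >= 1L) {
      expect_equal(nrow(mine), 1L)
      expect_true(mine$inner_start >= tr$start && mine$inner_end <= tr$end)
      expect_true(mine$bound_start <= tr$start && mine$bound_end >= tr$end)
      expect_equal(mine$chrom, tr$chrom)
    } else {
      expect_equal(nrow(mine), 0L)
    }
  }
  # no segments on chromosomes without donor chromatin
  expect_true(all(segs$chrom %in% vapply(lines, function(l)
    attr(l, "truth")$chrom, "")))
})
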