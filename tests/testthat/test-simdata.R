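# simdata: genomes, planted variants, reads, breeding.

test_that("zero divergence gives identical donor and empty truth", {
  gn <- make_genomes(genome_spec(groups = 1, chrom_length_bp = 2000,
                                 divergence = 0), seed = 3)
  expect_identical(gn$donor$seq[["1At"]], gn$recipient$seq[["1A"]])
  expect_identical(gn$donor$seq[["1G"]], gn$recipient$seq[["1B"]])
  expect_equal(nrow(gn$truth), 0L)
})

test_that("truth variants are recoverable by diffing the emitted sequences", {
  # pure-substitution genome: position-wise comparison is the oracle
  gn <- make_genomes(genome_spec(groups = 2, chrom_length_bp = 20000,
                                 divergence = 0.005), seed = 7)
  for (dchrom in names(gn$donor$seq)) {
    rchrom <- gn$donor$target[[dchrom]]
    d <- strsplit(gn$donor$seq[[dchrom]], "")[[1]]
    r <- strsplit(gn$recipient$seq[[rchrom]], "")[[1]]
    expect_equal(length(d), length(r))
    diffs <- which(d != r) - 1L
    tr <- gn$truth[gn$truth$chrom == rchrom, ]
    expect_identical(sort(diffs), sort(tr$pos))
    # ~100 per donor chromosome at 0.005 x 20 kb
    expect_equal(nrow(tr), 100L, tolerance = 0.15)
    expect_true(all(tr$ref != tr$alt))
  }
})

test_that("REPEAT_REGION contexts match a second locus at >= 97% identity", {
  gn <- make_genomes(genome_spec(groups = 1, chrom_length_bp = 6000,
                                 divergence = 0.004, repeat_fraction = 0.1),
                     seed = 11)
  reps <- gn$truth[gn$truth$planted_class == "REPEAT_REGION", ]
  expect_gt(nrow(reps), 0L)
  for (i in seq_len(nrow(reps))) {
    q <- substring(gn$recipient$seq[[reps$chrom[i]]],
                   reps$pos[i] - 50 + 1, reps$pos[i] + 50 + 1)
    hits <- oracle_sw_scan(q, gn$recipient, min_identity = 0.97, min_len = 61)
    self <- hits$chrom == reps$chrom[i] &
      hits$start < reps$pos[i] + 51 & hits$end > reps$pos[i] - 50
    expect_gte(sum(!self), 1L)
  }
})

test_that("simulate_reads pair count follows the coverage arithmetic", {
  g <- toy_genome(c(chr1 = random_seq(100000)))
  reads <- simulate_reads(g, coverage = 5, read_len = 250, frag_mean = 600,
                          seed = 1)
  expect_equal(nrow(reads), 2000L)  # 1,000 pairs
  expect_error(simulate_reads(g, coverage = 0), "coverage")
  expect_error(simulate_reads(g, coverage = 5, read_len = 700,
                              frag_mean = 600), "read_len")
})

test_that("error-free donor reads show 100% alt at planted SNPs", {
  gn <- make_genomes(genome_spec(groups = 1, chrom_length_bp = 6000,
                                 divergence = 0.003), seed = 5)
  donor <- attach_recipient(gn$donor, gn$recipient)
  reads <- simulate_reads(donor, coverage = 12, error_rate = 0, seed = 5)
  tr <- gn$truth[gn$truth$chrom == "1A", ]
  pu <- compute_pileup(reads, "1A", 0L, 6000L)
  for (i in seq_len(nrow(tr))) {
    row <- pu[pu$pos == tr$pos[i], ]
    expect_gt(row$depth, 0)
    expect_equal(row[[tr$alt[i]]], row$depth)
  }
})

test_that("read simulation is deterministic per seed", {
  g <- toy_genome(c(chr1 = random_seq(20000)))
  r1 <- simulate_reads(g, coverage = 3, seed = 42, junk_frac = 0.1,
                       error_rate = 0.01)
  r2 <- simulate_reads(g, coverage = 3, seed = 42, junk_frac = 0.1,
                       error_rate = 0.01)
  expect_identical(r1, r2)
  r3 <- simulate_reads(g, coverage = 3, seed = 43)
  expect_false(identical(r1, r3))
})

test_that("gametes from a pure recipient are single recipient blocks", {
  gn <- make_genomes(genome_spec(groups = 1, chrom_length_bp = 2000,
                                 divergence = 0.002), seed = 2)
  p <- recipient_line(gn$recipient)
  set.seed(1)
  g <- make_gamete(p, cross_scheme())
  for (slot in names(g)) {
    expect_equal(length(g[[slot]]$src), 1L)
    expect_equal(g[[slot]]$src, slot)
  }
})

test_that("pairing probability zero transmits parental chromosomes intact", {
  gn <- make_genomes(genome_spec(groups = 1, chrom_length_bp = 2000,
                                 divergence = 0.002), seed = 2)
  f1 <- f1_line(gn$recipient, gn$donor)
  sch <- cross_scheme(pairing_prob = c("At-A" = 0, "G-B" = 0, "At-D" = 0,
                                       "G-D" = 0))
  set.seed(9)
  for (k in 1:20) {
    g <- make_gamete(f1, sch)
    for (slot in names(g)) expect_equal(length(g[[slot]]$src), 1L)
  }
})

test_that("offspring mosaics tile the chromosome after every meiosis", {
  gn <- make_genomes(genome_spec(groups = 2, chrom_length_bp = 5000,
                                 divergence = 0.002), seed = 4)
  lens <- genome_lengths(gn$recipient)
  f1 <- f1_line(gn$recipient, gn$donor)
  off <- cross(f1, recipient_line(gn$recipient), 30, cross_scheme(seed = 4))
  for (o in off) expect_true(validate_mosaic(o, lens))
  self_off <- cross(off[[1]], off[[1]], 10, cross_scheme(seed = 5))
  for (o in self_off) expect_true(validate_mosaic(o, lens))
  expect_equal(off[[1]]$generation, "BC1")
  expect_equal(self_off[[1]]$generation, "BC1F1")
})

test_that("transmission bias raises het frequency of the biased chromosome", {
  gn <- make_genomes(genome_spec(groups = 2, chrom_length_bp = 5000,
                                 divergence = 0.002), seed = 4)
  f1 <- f1_line(gn$recipient, gn$donor)
  rec <- recipient_line(gn$recipient)
  # a small marker battery per chromosome so a carried segment is always seen
  markers <- do.call(rbind, lapply(c("1B", "2B"), function(ch) {
    data.frame(marker_id = sprintf("%s_%d", ch, 1:9), chrom = ch,
               pos = as.integer(seq(250, 4750, length.out = 9)), set_id = 1L,
               specificity = "G", stringsAsFactors = FALSE)
  }))
  sch <- cross_scheme(transmission_bias = c("2G" = 1.5), seed = 10)
  off <- cross(f1, rec, 1000, sch)
  gm <- genotype_truth(off, markers)
  n_biased <- sum(rowSums(gm[, markers$chrom == "2B"] >= 1L) > 0L)
  n_plain <- sum(rowSums(gm[, markers$chrom == "1B"] >= 1L) > 0L)
  # one-sided binomial comparison at alpha = 0.01
  pv <- stats::prop.test(c(n_biased, n_plain), c(1000, 1000),
                         alternative = "greater")$p.value
  expect_lt(pv, 0.01)
})

test_that("genotype_truth reads block structure exactly", {
  gn <- make_genomes(genome_spec(groups = 1, chrom_length_bp = 20000,
                                 divergence = 0.001), seed = 6)
  lens <- genome_lengths(gn$recipient)
  line <- recipient_line(gn$recipient, "L1")
  # plant a homozygous donor block [10 kb, 15 kb) on 1A
  blk <- list(src = c("1A", "1At", "1A"),
              start = c(0L, 10000L, 15000L), end = c(10000L, 15000L, 20000L))
  line$mosaic[["1A"]] <- list(blk, blk)
  markers <- panel_for(lens, spacing = 1000L)
  gm <- genotype_truth(list(line), markers)
  on_1a <- markers$chrom == "1A"
  inside <- on_1a & markers$pos >= 10000 & markers$pos < 15000
  expect_true(all(gm[1, markers$marker_id[inside]] == 2L))
  expect_true(all(gm[1, markers$marker_id[!inside]] == 0L))
  # F1: everything over donor-carrying slots is het
  f1 <- f1_line(gn$recipient, gn$donor)
  gmf <- genotype_truth(list(f1), markers)
  ab <- markers$chrom %in% c("1A", "1B")
  expect_true(all(gmf[1, markers$marker_id[ab]] == 1L))
  expect_error(genotype_truth(list(line),
                              data.frame(marker_id = "x", chrom = "9Z",
                                         pos = 1L)), "unknown chromosome")
})

test_that("select_plants partitions a family by the documented rules", {
  gn <- make_genomes(genome_spec(groups = 2, chrom_length_bp = 20000,
                                 divergence = 0.001), seed = 6)
  lens <- genome_lengths(gn$recipient)
  markers <- panel_for(lens, spacing = 1000L)
  mk_line <- function(id, blocks_hom, blocks_het) {
    ln <- recipient_line(gn$recipient, id)
    for (b in blocks_hom) {
      blk <- list(src = c(b$slot, b$src, b$slot),
                  start = c(0L, b$s, b$e), end = c(b$s, b$e, lens[[b$slot]]))
      ln$mosaic[[b$slot]] <- list(blk, blk)
    }
    for (b in blocks_het) {
      blk <- list(src = c(b$slot, b$src, b$slot),
                  start = c(0L, b$s, b$e), end = c(b$s, b$e, lens[[b$slot]]))
      ln$mosaic[[b$slot]] <- list(blk, ln$mosaic[[b$slot]][[2]])
    }
    ln
  }
  hom_il <- mk_line("hom", list(list(slot = "1A", src = "1At", s = 2000L,
                                     e = 8000L)), list())
  pure <- recipient_line(gn$recipient, "pure")
  busy <- mk_line("busy",
                  list(list(slot = "1A", src = "1At", s = 2000L, e = 8000L),
                       list(slot = "2A", src = "2At", s = 1000L, e = 9000L),
                       list(slot = "1B", src = "1G", s = 3000L, e = 7000L)),
                  list(list(slot = "2B", src = "2G", s = 2000L, e = 9000L)))
  few <- mk_line("few", list(),
                 list(list(slot = "1A", src = "1At", s = 2000L, e = 8000L)))
  fam <- list(hom_il, pure, busy, few)
  gm <- genotype_truth(fam, markers)
  sel <- select_plants(fam, gm, markers)
  expect_equal(sel$homozygous_ILs, "hom")
  expect_equal(sel$discard, "pure")
  expect_equal(sel$to_backcross, "busy")
  expect_equal(sel$to_self, "few")
  expect_error(select_plants(fam, gm, markers, rules = list(bogus = 1)),
               "unknown selection rule")
})
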