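# simdata: toy polyploid genomes with planted, class-labelled variants.
#
# The recipient emulates a hexaploid wheat-like genome (subgenomes A, B, D);
# the donor emulates a tetraploid wild relative (subgenomes At, G) whose
# chromosomes are mutated copies of their recipient homoeologues (At from A,
# G from B). Every deliberate donor-vs-recipient difference is recorded as a
# TruthVariant with a planted filter class, so downstream filters can be
# scored against known truth.

#' Specification of a synthetic recipient/donor genome pair
#'
#' @param groups number of homoeologous groups (chromosome groups); the full
#'   wheat complement is 7, desk-scale runs typically use 2.
#' @param chrom_length_bp chromosome length in bp (all chromosomes equal).
#' @param divergence substitution rate per homoeologous pair. Either a single
#'   rate for both pairs or a named vector `c(At = ..., G = ...)`. The default
#'   makes A-At closer than B-G, mirroring the relative relatedness of the
#'   two subgenome pairs.
#' @param indel_rate rate of small donor indels; each planted indel is
#'   accompanied by a SNP within 50 bp labelled `NEAR_INDEL`.
#' @param repeat_fraction fraction of each recipient A/B chromosome duplicated
#'   onto another chromosome at >= 97% identity (off-target traps). Some SNPs
#'   are planted inside these regions and labelled `REPEAT_REGION`.
#' @param flank_poly_events number of planted close SNP pairs (< 50 bp apart)
#'   per donor chromosome; both members are labelled `FLANK_POLYMORPHIC`.
#' @param low_depth_events number of planted SNPs per donor chromosome inside
#'   regions that [simulate_reads()] under-samples; labelled
#'   `LOW_DEPTH_REGION`.
#' @param translocations optional list of donor rearrangements, each a list
#'   with `src`, `src_start`, `src_end` (0-based half-open) and `dest`.
#'   Default off.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(groups = 7L,
                        chrom_length_bp = 20000L,
                        divergence = c(At = 0.005, G = 0.0075),
                        indel_rate = 0,
                        repeat_fraction = 0,
                        flank_poly_events = 0L,
                        low_depth_events = 0L,
                        translocations = list()) {
  if (length(divergence) == 1L && is.null(names(divergence))) {
    divergence <- c(At = unname(divergence), G = unname(divergence))
  }
  stopifnot(
    groups >= 1, chrom_length_bp > 0,
    all(divergence >= 0), all(divergence < 1),
    indel_rate >= 0, repeat_fraction >= 0, repeat_fraction < 1,
    all(c("At", "G") %in% names(divergence))
  )
  for (tr in translocations) {
    stopifnot(all(c("src", "src_start", "src_end", "dest") %in% names(tr)),
              tr$src_start >= 0, tr$src_end <= chrom_length_bp,
              tr$src_end > tr$src_start)
  }
  structure(list(
    groups = as.integer(groups),
    chrom_length_bp = as.integer(chrom_length_bp),
    recipient_subgenomes = c("A", "B", "D"),
    donor_subgenomes = c(At = "A", G = "B"),
    divergence = divergence,
    indel_rate = indel_rate,
    repeat_fraction = repeat_fraction,
    flank_poly_events = as.integer(flank_poly_events),
    low_depth_events = as.integer(low_depth_events),
    translocations = translocations
  ), class = "genome_spec")
}

new_genome <- function(seqs, set, edits = NULL, target = NULL,
                       repeats = NULL, low_depth = NULL) {
  stopifnot(is.list(seqs), !is.null(names(seqs)))
  structure(list(
    seq = seqs,
    set = set,
    # per-chromosome edit tables (donor-vs-recipient ops in recipient coords)
    edits = edits %||% setNames(vector("list", length(seqs)), names(seqs)),
    # donor chrom -> recipient homoeologue it aligns to
    target = target %||% setNames(names(seqs), names(seqs)),
    repeats = repeats %||% list(),
    low_depth = low_depth %||% list()
  ), class = "Genome")
}

#' Chromosome lengths of a Genome
#' @param genome a `Genome` object.
#' @return named integer vector of sequence lengths.
#' @export
genome_lengths <- function(genome) {
  stopifnot(inherits(genome, "Genome"))
  vapply(genome$seq, nchar, integer(1))
}

#' @export
print.Genome <- function(x, ...) {
  cat(sprintf("<Genome: %s set, %d chromosomes, %s bp total>\n",
              x$set, length(x$seq), format(sum(genome_lengths(x)), big.mark = ",")))
  invisible(x)
}

empty_truth <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), planted_class = character(),
             stringsAsFactors = FALSE)
}

in_intervals <- function(pos, iv, pad = 0L) {
  # iv: matrix with columns start, end (0-based half-open) or NULL
  if (is.null(iv) || nrow(iv) == 0L) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(iv))) {
    out <- out | (pos >= iv[i, 1] - pad & pos < iv[i, 2] + pad)
  }
  out
}

# Sample up to n positions in [lo, hi], keeping a minimum pairwise distance
# from already-taken positions and staying outside forbidden intervals.
# Rejection sampling, deterministic per RNG state; may return fewer than n
# when the space is saturated.
sample_spaced <- function(n, lo, hi, min_dist, avoid = integer(0),
                          forbid = NULL, forbid_pad = 0L) {
  if (n <= 0L || hi < lo) return(integer(0))
  taken <- as.integer(avoid)
  out <- integer(0)
  tries <- 0L
  while (length(out) < n && tries < (n + 10L) * 200L) {
    p <- sample.int(hi - lo + 1L, 1L) + lo - 1L
    ok <- (length(taken) == 0L || min(abs(taken - p)) >= min_dist) &&
      !in_intervals(p, forbid, forbid_pad)
    if (ok) {
      out <- c(out, p)
      taken <- c(taken, p)
    }
    tries <- tries + 1L
  }
  sort(out)
}

mutate_base <- function(base) {
  vapply(base, function(b) sample(setdiff(DNA_BASES, b), 1L),
         character(1), USE.NAMES = FALSE)
}

#' Generate a recipient/donor genome pair with planted truth variants
#'
#' Donor chromosomes are mutated copies of their recipient homoeologues at the
#' configured divergence. Planted classes:
#' \describe{
#'   \item{CLEAN}{isolated substitution, >= 101 bp from any other edit,
#'     >= 60 bp from chromosome ends and outside duplicated regions, so its
#'     KASP context is unconfounded by construction.}
#'   \item{NEAR_INDEL}{substitution with a planted donor indel within 50 bp.}
#'   \item{FLANK_POLYMORPHIC}{member of a close pair of substitutions
#'     (< 50 bp apart).}
#'   \item{REPEAT_REGION}{substitution whose 101-bp recipient context is
#'     duplicated elsewhere in the recipient at >= 97% identity.}
#'   \item{LOW_DEPTH_REGION}{substitution inside a region that
#'     [simulate_reads()] under-samples.}
#' }
#' @param spec a [genome_spec()].
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return list with elements `recipient`, `donor` (Genome objects) and
#'   `truth` (data frame of TruthVariants with 0-based positions).
#' @export
make_genomes <- function(spec, seed) {
  stopifnot(inherits(spec, "genome_spec"))
  L <- spec$chrom_length_bp
  if (L < 101L) abort_user("chromosome too short for flank structure (< 101 bp)")
  with_seed(child_seed(seed, "make_genomes"), {
    rec_chroms <- as.vector(outer(seq_len(spec$groups),
                                  spec$recipient_subgenomes, paste0))
    rec_seq <- setNames(lapply(rec_chroms, function(ch) random_dna(L)), rec_chroms)

    # Planted variants keep clear of chromosome ends: sequencing coverage
    # ramps over roughly a fragment length at each end, and a KASP-suitable
    # site needs full-depth flanks. The margin scales down for very short
    # test chromosomes.
    margin <- as.integer(max(60L, min(700L, L %/% 10L)))

    # Off-target traps: copy a block from each A/B chromosome onto the tail of
    # another chromosome (next group, same subgenome; or the D homoeologue
    # when there is a single group), lightly mutated so 101-mer identity stays
    # >= 97%. Both the source and the copy are recorded so that other planted
    # classes can stay clear of duplicated sequence.
    repeats <- list()
    if (spec$repeat_fraction > 0) {
      rep_len <- max(202L, as.integer(round(spec$repeat_fraction * L)))
      if (2L * rep_len + 2L * margin + 2L >= L) {
        abort_user("repeat_fraction too large for chromosome length")
      }
      for (sub in c("A", "B")) {
        for (g in seq_len(spec$groups)) {
          src <- paste0(g, sub)
          dest <- if (spec$groups > 1L) {
            paste0(g %% spec$groups + 1L, sub)
          } else paste0(g, "D")
          src_start <- sample.int(L - 2L * rep_len - 2L * margin, 1L) + margin
          block <- substring(rec_seq[[src]], src_start + 1L, src_start + rep_len)
          bl <- strsplit(block, "")[[1]]
          nmut <- max(1L, round(rep_len * 0.005))
          at <- sample.int(rep_len, nmut)
          bl[at] <- mutate_base(bl[at])
          # park the copy at the destination tail; with a single group both
          # subgenomes copy into the D homoeologue, so stack the two blocks
          dest_start <- if (spec$groups == 1L && sub == "B") {
            L - 2L * rep_len
          } else L - rep_len
          s <- strsplit(rec_seq[[dest]], "")[[1]]
          s[(dest_start + 1L):(dest_start + rep_len)] <- bl
          rec_seq[[dest]] <- paste(s, collapse = "")
          repeats[[src]] <- rbind(repeats[[src]],
                                  cbind(start = src_start, end = src_start + rep_len,
                                        plantable = 1L))
          repeats[[dest]] <- rbind(repeats[[dest]],
                                   cbind(start = dest_start, end = L, plantable = 0L))
        }
      }
    }
    recipient <- new_genome(rec_seq, "recipient", repeats = repeats)

    donor_seq <- list(); donor_edits <- list(); donor_target <- character(0)
    low_depth <- list()
    truth <- empty_truth()

    for (dsub in names(spec$donor_subgenomes)) {
      rsub <- spec$donor_subgenomes[[dsub]]
      div <- spec$divergence[[dsub]]
      for (g in seq_len(spec$groups)) {
        rchrom <- paste0(g, rsub)
        dchrom <- paste0(g, dsub)
        rseq <- rec_seq[[rchrom]]
        rs <- strsplit(rseq, "")[[1]]
        edits <- data.frame(pos = integer(), ref = character(), alt = character(),
                            type = character(), stringsAsFactors = FALSE)
        n_total <- round(L * div)
        if (n_total > 0) {
          lo <- margin; hi <- L - margin - 1L
          placed <- integer(0)
          rep_iv <- repeats[[rchrom]]

          add_snp <- function(pos, class) {
            ref <- rs[pos + 1L]
            alt <- mutate_base(ref)
            edits <<- rbind(edits, data.frame(pos = pos, ref = ref, alt = alt,
                                              type = "snp", stringsAsFactors = FALSE))
            truth <<- rbind(truth, data.frame(chrom = rchrom, pos = pos, ref = ref,
                                              alt = alt, planted_class = class,
                                              stringsAsFactors = FALSE))
            placed <<- c(placed, pos)
          }

          # special classes first, then CLEAN fills the rest of the budget
          n_ni <- min(round(L * spec$indel_rate), n_total %/% 4L)
          n_fp <- spec$flank_poly_events
          n_ld <- spec$low_depth_events
          n_rep <- if (!is.null(rep_iv) && any(rep_iv[, "plantable"] == 1L)) {
            min(3L, max(1L, n_total %/% 20L))
          } else 0L

          anchors <- sample_spaced(n_ni + n_fp + n_ld, lo, hi, 300L,
                                   forbid = rep_iv, forbid_pad = 110L)
          idx <- 0L
          take <- function(k) {
            if (k == 0L || idx >= length(anchors)) return(integer(0))
            sel <- anchors[(idx + 1L):min(idx + k, length(anchors))]
            idx <<- idx + length(sel)
            sel
          }
          for (p in take(n_ni)) {
            add_snp(p, "NEAR_INDEL")
            off <- sample(c(-1L, 1L), 1L) * sample(5:45, 1L)
            ipos <- p + off
            if (sample(c(TRUE, FALSE), 1L)) {
              edits <- rbind(edits, data.frame(pos = ipos, ref = "",
                                               alt = random_dna(sample(1:3, 1L)),
                                               type = "ins", stringsAsFactors = FALSE))
            } else {
              dlen <- sample(1:3, 1L)
              edits <- rbind(edits, data.frame(
                pos = ipos, ref = substring(rseq, ipos + 1L, ipos + dlen),
                alt = "", type = "del", stringsAsFactors = FALSE))
            }
          }
          for (p in take(n_fp)) {
            add_snp(p, "FLANK_POLYMORPHIC")
            add_snp(p + sample(10:40, 1L), "FLANK_POLYMORPHIC")
          }
          for (p in take(n_ld)) {
            add_snp(p, "LOW_DEPTH_REGION")
            low_depth[[rchrom]] <- rbind(low_depth[[rchrom]],
                                         cbind(start = max(0L, p - 100L),
                                               end = min(L, p + 101L)))
          }
          if (n_rep > 0L) {
            plantable <- rep_iv[rep_iv[, "plantable"] == 1L, , drop = FALSE]
            rp <- sample_spaced(n_rep, plantable[1, "start"] + 60L,
                                plantable[1, "end"] - 61L, 101L,
                                avoid = c(placed, edits$pos[edits$type != "snp"]))
            for (p in rp) add_snp(p, "REPEAT_REGION")
          }
          n_clean <- max(0L, n_total - sum(edits$type == "snp"))
          avoid <- c(placed, edits$pos[edits$type != "snp"])
          # CLEAN sites keep clear of duplicated regions and of low-depth
          # zones (which depress flanking depth up to a read length away)
          forbid <- rbind(rep_iv[, 1:2, drop = FALSE],
                          if (!is.null(low_depth[[rchrom]])) {
                            cbind(low_depth[[rchrom]][, "start"] - 300L,
                                  low_depth[[rchrom]][, "end"] + 300L)
                          })
          for (p in sample_spaced(n_clean, lo, hi, 101L, avoid,
                                  forbid = forbid, forbid_pad = 110L)) {
            add_snp(p, "CLEAN")
          }
        }
        edits <- edits[order(edits$pos), , drop = FALSE]
        rownames(edits) <- NULL
        donor_seq[[dchrom]] <- apply_edits(rseq, edits)
        donor_edits[[dchrom]] <- edits
        donor_target[dchrom] <- rchrom
      }
    }

    donor <- new_genome(donor_seq, "donor", edits = donor_edits,
                        target = donor_target, low_depth = low_depth)
    donor <- apply_translocations(donor, spec$translocations)
    truth <- truth[order(truth$chrom, truth$pos), , drop = FALSE]
    rownames(truth) <- NULL
    list(recipient = recipient, donor = donor, truth = truth)
  })
}

# Build the donor sequence by applying an ordered edit table (recipient
# coordinates) to the recipient homoeologue.
apply_edits <- function(rseq, edits) {
  if (nrow(edits) == 0L) return(rseq)
  parts <- character(0)
  cursor <- 0L  # 0-based position of next unconsumed recipient base
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    if (e$pos < cursor) next  # overlapping edits: first wins
    parts <- c(parts, substring(rseq, cursor + 1L, e$pos))
    if (e$type == "snp") {
      parts <- c(parts, e$alt); cursor <- e$pos + 1L
    } else if (e$type == "ins") {
      parts <- c(parts, substring(rseq, e$pos + 1L, e$pos + 1L), e$alt)
      cursor <- e$pos + 1L
    } else {  # del
      cursor <- e$pos + nchar(e$ref)
    }
  }
  parts <- c(parts, substring(rseq, cursor + 1L, nchar(rseq)))
  paste(parts, collapse = "")
}

# Reciprocal tail swap between two donor chromosomes. Sequence-level only:
# read simulation and the breeding model keep working from the per-chromosome
# edit tables, which are unaffected; a flag records that the donor karyotype
# is rearranged (the breeding simulator refuses such donors, see vignette).
apply_translocations <- function(donor, translocations) {
  for (tr in translocations) {
    stopifnot(tr$src %in% names(donor$seq), tr$dest %in% names(donor$seq))
    src_seq <- donor$seq[[tr$src]]
    stopifnot(tr$src_end <= nchar(src_seq))
    block <- substring(src_seq, tr$src_start + 1L, tr$src_end)
    dest_seq <- donor$seq[[tr$dest]]
    keep <- nchar(dest_seq) - nchar(block)
    tail_block <- substring(dest_seq, keep + 1L, nchar(dest_seq))
    donor$seq[[tr$dest]] <- paste0(substring(dest_seq, 1L, keep), block)
    donor$seq[[tr$src]] <- paste0(
      substring(src_seq, 1L, tr$src_start),
      tail_block,
      substring(src_seq, tr$src_end + 1L, nchar(src_seq)))
    attr(donor, "translocated") <- TRUE
  }
  donor
}
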