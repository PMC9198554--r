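# simdata: pre-aligned paired-end read simulation.
#
# Reads are emitted already placed at their true coordinates on the recipient
# reference (read mapping is deliberately not re-implemented: the downstream
# filters act on alignments, not on a mapper). A donor Genome carries its
# edit table versus each recipient homoeologue, so a simulated donor read is
# the recipient sequence with the donor's substitutions/indels applied, and
# its CIGAR encodes the indels.

new_alignment_records <- function(df) {
  needed <- c("read_id", "chrom", "pos", "mapq", "paired", "proper_pair",
              "unmapped", "supplementary", "duplicate", "cigar", "bases",
              "mate_pos", "strand")
  stopifnot(all(needed %in% names(df)))
  structure(df[, needed, drop = FALSE],
            class = c("alignment_records", "data.frame"))
}

# Walk the recipient reference from 0-based position `s`, applying donor
# edits, until n_bases donor bases are collected (or the chromosome ends).
# Returns parallel vectors: ref_pos (0-based recipient position per emitted
# base, NA for inserted bases) and base.
walk_fragment <- function(rs, edits, s, n_bases) {
  L <- length(rs)
  ref_pos <- integer(0); base <- character(0)
  cursor <- s
  es <- edits[edits$pos >= s, , drop = FALSE]
  ei <- 1L
  while (length(base) < n_bases && cursor < L) {
    need <- n_bases - length(base)
    e <- if (ei <= nrow(es)) es[ei, ] else NULL
    if (is.null(e) || e$pos >= cursor + need) {
      run <- cursor:(min(cursor + need, L) - 1L)
      ref_pos <- c(ref_pos, run); base <- c(base, rs[run + 1L])
      cursor <- cursor + length(run)
    } else {
      if (e$pos > cursor) {
        run <- cursor:(e$pos - 1L)
        ref_pos <- c(ref_pos, run); base <- c(base, rs[run + 1L])
        cursor <- e$pos
      }
      if (e$type == "snp") {
        ref_pos <- c(ref_pos, e$pos); base <- c(base, e$alt)
        cursor <- e$pos + 1L
      } else if (e$type == "ins") {
        ins <- strsplit(e$alt, "")[[1]]
        ref_pos <- c(ref_pos, e$pos, rep(NA_integer_, length(ins)))
        base <- c(base, rs[e$pos + 1L], ins)
        cursor <- e$pos + 1L
      } else {  # del: skip deleted reference bases
        cursor <- e$pos + nchar(e$ref)
      }
      ei <- ei + 1L
    }
  }
  n <- min(length(base), n_bases)
  list(ref_pos = ref_pos[seq_len(n)], base = base[seq_len(n)])
}

# CIGAR (M/I/D) and leftmost position from a per-base ref_pos vector.
cigar_from_refpos <- function(ref_pos) {
  stopifnot(length(ref_pos) > 0L, !is.na(ref_pos[1]))
  n <- length(ref_pos)
  # fast path: gapless read
  if (!anyNA(ref_pos) && ref_pos[n] - ref_pos[1] == n - 1L) {
    return(list(pos = ref_pos[1], cigar = paste0(n, "M")))
  }
  ops <- character(0); lens <- integer(0)
  push <- function(op, len) {
    if (len == 0L) return()
    k <- length(ops)
    if (k > 0L && ops[k] == op) lens[k] <<- lens[k] + len
    else { ops <<- c(ops, op); lens <<- c(lens, len) }
  }
  push("M", 1L)
  last_ref <- ref_pos[1]
  for (i in 2:n) {
    if (is.na(ref_pos[i])) push("I", 1L)
    else {
      gap <- ref_pos[i] - last_ref
      if (gap > 1L) push("D", gap - 1L)
      push("M", 1L)
      last_ref <- ref_pos[i]
    }
  }
  list(pos = ref_pos[1], cigar = paste0(lens, ops, collapse = ""))
}

#' Simulate pre-aligned paired-end reads from a genome
#'
#' Pair count is `round(coverage * total_length / (2 * read_len))`, allocated
#' to chromosomes proportionally to length. Fragments have fixed length
#' `frag_mean`; read 1 is the first `read_len` bases of the fragment (forward
#' strand), read 2 the last `read_len` bases (reverse strand, bases stored in
#' reference-forward orientation as in SAM). Donor genomes yield reads
#' against their recipient homoeologue with the donor edits applied.
#'
#' @param genome a `Genome` (recipient or donor).
#' @param coverage target mean coverage (must be > 0).
#' @param read_len read length in bp.
#' @param frag_mean fragment length in bp (`read_len <= frag_mean`).
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed.
#' @param junk_frac fraction of pairs carrying a defect that the alignment
#'   filters must remove: MAPQ < 10, unmapped, supplementary, improper pair,
#'   or a positional duplicate of the preceding pair.
#' @return an `alignment_records` data frame (0-based `pos`).
#' @export
simulate_reads <- function(genome, coverage, read_len = 250L,
                           frag_mean = 600L, error_rate = 0, seed = 1L,
                           junk_frac = 0) {
  stopifnot(inherits(genome, "Genome"))
  if (coverage <= 0) abort_user("coverage must be > 0")
  lens <- genome_lengths(genome)
  if (read_len > frag_mean || any(frag_mean > lens)) {
    abort_user("need read_len <= frag_mean <= chromosome length")
  }
  total_len <- sum(lens)
  n_pairs <- round(coverage * total_len / (2 * read_len))
  # deterministic largest-remainder allocation across chromosomes
  exact <- n_pairs * lens / total_len
  alloc <- floor(exact)
  rem <- n_pairs - sum(alloc)
  if (rem > 0) {
    o <- order(exact - alloc, decreasing = TRUE)
    alloc[o[seq_len(rem)]] <- alloc[o[seq_len(rem)]] + 1L
  }

  with_seed(child_seed(seed, "simulate_reads"), {
    rows <- vector("list", length(lens))
    for (ci in seq_along(lens)) {
      chrom <- names(lens)[ci]
      target <- genome$target[[chrom]]
      edits <- genome$edits[[chrom]] %||%
        data.frame(pos = integer(), ref = character(), alt = character(),
                   type = character(), stringsAsFactors = FALSE)
      # walking happens on the recipient homoeologue's coordinates; for a
      # recipient genome target == chrom and the edit table is empty
      rs_string <- if (genome$set == "donor") {
        attr(genome, "recipient_seq")[[target]] %||% NULL
      } else genome$seq[[chrom]]
      if (is.null(rs_string)) {
        # donor sequence was built from recipient + edits; reverse the snps
        # to recover the recipient locally is wasteful, so donors are
        # expected to be paired with their recipient via attach_recipient()
        abort_user("donor genome lacks recipient sequences; call attach_recipient()")
      }
      rs <- strsplit(rs_string, "")[[1]]
      Lr <- length(rs)
      n_c <- alloc[ci]
      if (n_c == 0L) next
      # stratified fragment placement: evenly spaced starts with uniform
      # jitter of half a stride, emulating the near-uniform coverage of a
      # PCR-free library while keeping local depth close to its target
      span <- max(1L, Lr - frag_mean + 1L)
      stride <- span / n_c
      grid <- (seq_len(n_c) - 0.5) * stride
      starts <- as.integer(pmax(0, pmin(span - 1L,
                                        round(grid + stats::runif(n_c, -stride / 2,
                                                                  stride / 2)))))
      junk <- if (junk_frac > 0) runif(n_c) < junk_frac else rep(FALSE, n_c)
      junk_kind <- sample(c("mapq", "unmapped", "supplementary", "improper", "dup"),
                          n_c, replace = TRUE)
      out <- vector("list", n_c)
      for (i in seq_len(n_c)) {
        s <- starts[i]
        if (junk[i] && junk_kind[i] == "dup" && i > 1L) s <- starts[i - 1L]
        fr <- walk_fragment(rs, edits, s, frag_mean)
        nfr <- length(fr$base)
        if (nfr < read_len) next
        idx1 <- seq_len(read_len)
        idx2 <- (nfr - read_len + 1L):nfr
        r1 <- cigar_from_refpos(fr$ref_pos[idx1])
        r2 <- cigar_from_refpos(fr$ref_pos[idx2])
        b1 <- fr$base[idx1]; b2 <- fr$base[idx2]
        if (error_rate > 0) {
          e1 <- runif(read_len) < error_rate
          e2 <- runif(read_len) < error_rate
          if (any(e1)) b1[e1] <- mutate_base(b1[e1])
          if (any(e2)) b2[e2] <- mutate_base(b2[e2])
        }
        mapq <- c(60L, 60L)
        unmapped <- c(FALSE, FALSE); suppl <- c(FALSE, FALSE)
        proper <- c(TRUE, TRUE)
        if (junk[i]) {
          switch(junk_kind[i],
                 mapq = { mapq <- c(sample(0:9, 1L), 60L) },
                 unmapped = { unmapped[1] <- TRUE },
                 supplementary = { suppl[1] <- TRUE },
                 improper = { proper <- c(FALSE, FALSE) },
                 dup = NULL)
        }
        rid <- sprintf("%s_p%06d", chrom, i)
        out[[i]] <- data.frame(
          read_id = rid, chrom = target,
          pos = c(r1$pos, r2$pos), mapq = mapq,
          paired = TRUE, proper_pair = proper, unmapped = unmapped,
          supplementary = suppl, duplicate = FALSE,
          cigar = c(r1$cigar, r2$cigar),
          bases = c(paste(b1, collapse = ""), paste(b2, collapse = "")),
          mate_pos = c(r2$pos, r1$pos), strand = c("+", "-"),
          stringsAsFactors = FALSE)
      }
      rows[[ci]] <- do.call(rbind, out)
    }
    rec <- do.call(rbind, rows)
    rownames(rec) <- NULL
    # under-sample reads overlapping declared low-depth regions
    if (length(genome$low_depth) > 0L && nrow(rec) > 0L) {
      keep <- rep(TRUE, nrow(rec))
      for (ch in names(genome$low_depth)) {
        iv <- genome$low_depth[[ch]]
        span <- rec$pos + read_len + 10L  # conservative reference span
        for (k in seq_len(nrow(iv))) {
          hit <- rec$chrom == ch & rec$pos < iv[k, "end"] & span > iv[k, "start"]
          keep[hit] <- keep[hit] & (runif(sum(hit)) < 0.15)
        }
      }
      rec <- rec[keep, , drop = FALSE]
      rownames(rec) <- NULL
    }
    new_alignment_records(rec)
  })
}

#' Attach recipient sequences to a donor genome for read simulation
#'
#' [simulate_reads()] walks donor edits along the recipient homoeologue, so a
#' donor `Genome` needs access to the recipient sequences.
#' @param donor donor `Genome`.
#' @param recipient recipient `Genome`.
#' @return the donor with recipient sequences attached.
#' @export
attach_recipient <- function(donor, recipient) {
  stopifnot(inherits(donor, "Genome"), inherits(recipient, "Genome"),
            donor$set == "donor", recipient$set == "recipient")
  attr(donor, "recipient_seq") <- recipient$seq
  donor
}
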