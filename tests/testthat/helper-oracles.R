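# Shared builders and independent oracles. Oracles deliberately avoid the
# code paths they check: the pileup oracle walks reads one base at a time,
# the homology oracle scans every reference window, and the coverage oracle
# fills a per-base boolean array.

rec_row <- function(read_id, chrom, pos, bases, cigar = NULL, mapq = 60L,
                    paired = TRUE, proper_pair = TRUE, unmapped = FALSE,
                    supplementary = FALSE, duplicate = FALSE,
                    mate_pos = NA_integer_, strand = "+") {
  data.frame(read_id = read_id, chrom = chrom, pos = pos, mapq = mapq,
             paired = paired, proper_pair = proper_pair, unmapped = unmapped,
             supplementary = supplementary, duplicate = duplicate,
             cigar = cigar %||% paste0(nchar(bases), "M"), bases = bases,
             mate_pos = mate_pos, strand = strand, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_records <- function(...) {
  df <- do.call(rbind, list(...))
  structure(df, class = c("alignment_records", "data.frame"))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

toy_genome <- function(seqs, set = "recipient") {
  g <- structure(list(seq = as.list(seqs), set = set,
                      edits = setNames(vector("list", length(seqs)), names(seqs)),
                      target = setNames(names(seqs), names(seqs)),
                      repeats = list(), low_depth = list()),
                 class = "Genome")
  g
}

# --- naive pileup oracle: per read, per base, no vectorisation ----------
oracle_pileup <- function(records, chrom, start, end) {
  W <- end - start
  A <- C <- G <- T <- del <- ins <- rep(0L, W)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$chrom != chrom || r$unmapped) next
    toks <- regmatches(r$cigar, gregexpr("[0-9]+[MIDS]", r$cigar))[[1]]
    rpos <- r$pos; q <- 0L
    bases <- strsplit(r$bases, "")[[1]]
    for (tk in toks) {
      len <- as.integer(sub("[MIDS]", "", tk))
      op <- sub("[0-9]+", "", tk)
      if (op == "M") {
        for (j in seq_len(len)) {
          p <- rpos + j - 1L
          if (p >= start && p < end) {
            b <- bases[q + j]
            k <- p - start + 1L
            if (b == "A") A[k] <- A[k] + 1L
            if (b == "C") C[k] <- C[k] + 1L
            if (b == "G") G[k] <- G[k] + 1L
            if (b == "T") T[k] <- T[k] + 1L
          }
        }
        rpos <- rpos + len; q <- q + len
      } else if (op == "D") {
        for (j in seq_len(len)) {
          p <- rpos + j - 1L
          if (p >= start && p < end) del[p - start + 1L] <- del[p - start + 1L] + 1L
        }
        rpos <- rpos + len
      } else if (op == "I") {
        p <- rpos - 1L
        if (p >= start && p < end) ins[p - start + 1L] <- ins[p - start + 1L] + 1L
        q <- q + len
      } else if (op == "S") {
        q <- q + len
      }
    }
  }
  data.frame(chrom = chrom, pos = start:(end - 1L), A = A, C = C, G = G, T = T,
             del_count = del, ins_adjacent = ins,
             depth = A + C + G + T + del, stringsAsFactors = FALSE)
}

# --- brute-force homology oracle: full local-SW scan of every window ----
# Windows of `win` bases advanced by `step` guarantee every alignment of up
# to ~(win - step) columns is fully contained in some window. All windows of
# a chromosome/strand are aligned in a single vectorised pairwiseAlignment
# call; overlapping reports of one locus are merged keeping the
# highest-scoring (i.e. fullest) alignment.
oracle_sw_scan <- function(query, genome, min_identity = 0.97,
                           min_len = 61L, win = 160L, step = 50L) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = TRUE)
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(query)))
    qd <- Biostrings::DNAString(q)
    for (chrom in names(genome$seq)) {
      s <- genome$seq[[chrom]]
      L <- nchar(s)
      starts <- unique(c(seq(1L, max(1L, L - win + 1L), by = step),
                         max(1L, L - win + 1L)))
      windows <- Biostrings::DNAStringSet(substring(s, starts,
                                                    pmin(L, starts + win - 1L)))
      aln <- Biostrings::pairwiseAlignment(
        windows, qd, type = "local",
        substitutionMatrix = submat, gapOpening = 1, gapExtension = 1)
      nm <- Biostrings::nmatch(aln); nmm <- Biostrings::nmismatch(aln)
      ind <- Biostrings::nindel(aln)
      gaps <- Biostrings::insertion(ind)[, "WidthSum"] +
        Biostrings::deletion(ind)[, "WidthSum"]
      cols <- nm + nmm + gaps
      sc <- BiocGenerics::score(aln)
      ok <- which(cols >= min_len & nm / cols >= min_identity)
      for (i in ok) {
        # pattern side = the window (reference); map back to the chromosome
        pr <- Biostrings::pattern(aln)[i]
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom,
          start = starts[i] + BiocGenerics::start(pr) - 2L,
          end = starts[i] + BiocGenerics::end(pr) - 1L,
          strand = strand, identity = nm[i] / cols[i], score = sc[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), identity = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, hits)
  # merge overlapping reports of the same locus: keep the best-scoring one
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  grp <- integer(nrow(df)); gid <- 0L; last_chrom <- ""; last_end <- -1L
  for (i in seq_len(nrow(df))) {
    if (!(df$chrom[i] == last_chrom && df$start[i] < last_end)) {
      gid <- gid + 1L; last_chrom <- df$chrom[i]; last_end <- df$end[i]
    } else last_end <- max(last_end, df$end[i])
    grp[i] <- gid
  }
  best <- vapply(split(seq_len(nrow(df)), grp), function(ix) {
    ix[order(-df$score[ix], -df$identity[ix])][1]
  }, integer(1))
  res <- df[sort(best), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# --- per-base boolean coverage oracle -----------------------------------
# Exact for catalogs whose donor chromosomes each map to a single recipient
# chromosome (one boolean cell per reference base).
oracle_coverage <- function(catalog, chrom_lengths) {
  donors <- sort(unique(catalog$donor_chrom))
  vapply(donors, function(dc) {
    rows <- catalog[catalog$donor_chrom == dc, , drop = FALSE]
    stopifnot(length(unique(rows$recipient_chrom)) == 1L)
    L <- chrom_lengths[[rows$recipient_chrom[1]]]
    covered <- rep(FALSE, L)
    for (i in seq_len(nrow(rows))) {
      if (isTRUE(rows$whole_chromosome[i])) { covered[] <- TRUE; next }
      covered[(rows$outer_start[i] + 1L):rows$outer_end[i]] <- TRUE
    }
    mean(covered) * 100
  }, numeric(1))
}

# small deterministic marker panel over a genome
panel_for <- function(lens, spacing = 500L) {
  rows <- list()
  i <- 0L
  for (ch in names(lens)) {
    pos <- seq(spacing %/% 2L, lens[[ch]] - 1L, by = spacing)
    sub <- sub("^[0-9]+", "", ch)
    spec <- c(A = "At", B = "G", D = "nonspecific")[[sub]]
    for (p in pos) {
      i <- i + 1L
      rows[[i]] <- data.frame(marker_id = sprintf("M%04d", i), chrom = ch,
                              pos = p, set_id = 1L, specificity = spec,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
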