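# simdata: backcross/self breeding-scheme simulation.
#
# A line is a mosaic: for each recipient chromosome slot, two homologous
# copies, each an ordered run of blocks (source chromosome, 0-based
# half-open interval) tiling [0, length). The F1 carries one recipient and
# one donor copy per A/B slot (donor At pairs into the A slot, G into B);
# D slots start pure recipient. Homoeologous pairing probabilities control
# whether a donor-carrying bivalent recombines at meiosis.

new_blocks <- function(src, start, end) {
  list(src = as.character(src), start = as.integer(start), end = as.integer(end))
}

merge_blocks <- function(b) {
  n <- length(b$src)
  if (n <= 1L) return(b)
  keep <- c(TRUE, b$src[-1] != b$src[-n])
  idx <- which(keep)
  end_idx <- c(idx[-1] - 1L, n)
  new_blocks(b$src[idx], b$start[idx], b$end[end_idx])
}

blocks_valid <- function(b, len) {
  n <- length(b$src)
  n >= 1L && b$start[1] == 0L && b$end[n] == len &&
    all(b$end > b$start) &&
    (n == 1L || all(b$start[-1] == b$end[-n]))
}

#' Validate a line's chromosome mosaic
#'
#' Asserts that every chromosome copy's blocks are sorted, non-overlapping
#' and tile `[0, length)` exactly.
#' @param line a `sim_line`.
#' @param chrom_lengths named lengths of the recipient chromosomes.
#' @return TRUE invisibly; errors otherwise.
#' @export
validate_mosaic <- function(line, chrom_lengths) {
  for (slot in names(line$mosaic)) {
    for (ci in 1:2) {
      if (!blocks_valid(line$mosaic[[slot]][[ci]], chrom_lengths[[slot]])) {
        stop(sprintf("invalid mosaic: line %s slot %s copy %d",
                     line$line_id, slot, ci))
      }
    }
  }
  invisible(TRUE)
}

new_sim_line <- function(line_id, generation, mosaic) {
  structure(list(line_id = line_id, generation = generation, mosaic = mosaic),
            class = "sim_line")
}

#' @export
print.sim_line <- function(x, ...) {
  nd <- sum(vapply(x$mosaic, function(s) {
    sum(vapply(1:2, function(i) sum(grepl("(At|G)$", s[[i]]$src)), numeric(1)))
  }, numeric(1)))
  cat(sprintf("<sim_line %s (%s): %d slots, %d donor blocks>\n",
              x$line_id, x$generation, length(x$mosaic), nd))
  invisible(x)
}

#' Pure recipient (recurrent parent) line
#' @param recipient recipient `Genome`.
#' @param line_id id for the line.
#' @return a `sim_line`.
#' @export
recipient_line <- function(recipient, line_id = "recurrent") {
  lens <- genome_lengths(recipient)
  mosaic <- lapply(names(lens), function(ch) {
    b <- new_blocks(ch, 0L, lens[[ch]])
    list(b, b)
  })
  names(mosaic) <- names(lens)
  new_sim_line(line_id, "P", mosaic)
}

#' F1 hybrid line (recipient x donor)
#'
#' Each A slot carries one recipient copy and the donor At homoeologue, each
#' B slot one recipient copy and the donor G homoeologue; D slots are pure
#' recipient. Donor chromosomes are laid onto the recipient slot's
#' coordinates (equal lengths in the simulator).
#' @param recipient recipient `Genome`.
#' @param donor donor `Genome`.
#' @param line_id id for the line.
#' @return a `sim_line`.
#' @export
f1_line <- function(recipient, donor, line_id = "F1") {
  if (isTRUE(attr(donor, "translocated"))) {
    abort_user("breeding simulation does not support translocated donor karyotypes")
  }
  lens <- genome_lengths(recipient)
  donor_for_slot <- setNames(names(donor$target), donor$target)
  mosaic <- lapply(names(lens), function(ch) {
    rec <- new_blocks(ch, 0L, lens[[ch]])
    if (ch %in% names(donor_for_slot)) {
      list(rec, new_blocks(donor_for_slot[[ch]], 0L, lens[[ch]]))
    } else list(rec, rec)
  })
  names(mosaic) <- names(lens)
  new_sim_line(line_id, "F1", mosaic)
}

#' Crossing-scheme configuration
#'
#' @param pairing_prob named homoeologous pairing probabilities for
#'   donor-carrying bivalents, keyed `"<donor subgenome>-<slot subgenome>"`.
#'   Defaults: At-A 0.70 and G-B 0.30 (the reported pairing frequencies of
#'   the two subgenome pairs); At-D 0.02 and G-D 0.10 are tunable stand-ins
#'   chosen so D-genome recombinants arise at roughly the observed
#'   proportions.
#' @param second_crossover_prob probability of a second crossover on a
#'   paired bivalent (default 0: exactly one crossover, uniform position).
#' @param transmission_bias named per-donor-chromosome gamete transmission
#'   multipliers (e.g. `c("2G" = 1.5)`); applied by rejection sampling.
#' @param selection_rules declarative selection thresholds for
#'   [select_plants()].
#' @param seed integer seed used by [cross()].
#' @return object of class `cross_scheme`.
#' @export
cross_scheme <- function(pairing_prob = c("At-A" = 0.70, "G-B" = 0.30,
                                          "At-D" = 0.02, "G-D" = 0.10),
                         second_crossover_prob = 0,
                         transmission_bias = numeric(0),
                         selection_rules = list(min_other_segments = 2L,
                                                max_self_segments = 2L),
                         seed = 1L) {
  stopifnot(all(pairing_prob >= 0), all(pairing_prob <= 1),
            second_crossover_prob >= 0, second_crossover_prob <= 1,
            all(transmission_bias > 0))
  known <- c("min_other_segments", "max_self_segments")
  if (!all(names(selection_rules) %in% known)) {
    abort_user(sprintf("unknown selection rule(s): %s",
                       paste(setdiff(names(selection_rules), known), collapse = ", ")))
  }
  structure(list(pairing_prob = pairing_prob,
                 second_crossover_prob = second_crossover_prob,
                 transmission_bias = transmission_bias,
                 selection_rules = selection_rules,
                 seed = seed),
            class = "cross_scheme")
}

slot_subgenome <- function(slot) sub("^[0-9]+", "", slot)
donor_subgenome_of_src <- function(src) {
  ifelse(grepl("At$", src), "At", ifelse(grepl("G$", src), "G", NA_character_))
}
has_donor <- function(b) any(grepl("(At|G)$", b$src))

# split a block run at position x: return [0,x) part and [x,L) part
split_blocks <- function(b, x) {
  left <- new_blocks(character(0), integer(0), integer(0))
  right <- left
  for (i in seq_along(b$src)) {
    s <- b$start[i]; e <- b$end[i]
    if (e <= x) {
      left$src <- c(left$src, b$src[i]); left$start <- c(left$start, s)
      left$end <- c(left$end, e)
    } else if (s >= x) {
      right$src <- c(right$src, b$src[i]); right$start <- c(right$start, s)
      right$end <- c(right$end, e)
    } else {
      left$src <- c(left$src, b$src[i]); left$start <- c(left$start, s)
      left$end <- c(left$end, x)
      right$src <- c(right$src, b$src[i]); right$start <- c(right$start, x)
      right$end <- c(right$end, e)
    }
  }
  list(left = left, right = right)
}

recombine <- function(c1, c2, xs) {
  # alternate source copy at each crossover point
  xs <- sort(xs)
  cur <- c1; other <- c2
  for (x in xs) {
    sp_cur <- split_blocks(cur, x)
    sp_oth <- split_blocks(other, x)
    new_cur <- new_blocks(c(sp_cur$left$src, sp_oth$right$src),
                          c(sp_cur$left$start, sp_oth$right$start),
                          c(sp_cur$left$end, sp_oth$right$end))
    other <- new_blocks(c(sp_oth$left$src, sp_cur$right$src),
                        c(sp_oth$left$start, sp_cur$right$start),
                        c(sp_oth$left$end, sp_cur$right$end))
    cur <- new_cur
  }
  merge_blocks(cur)
}

#' Draw one gamete from a line
#'
#' For each chromosome slot: if either copy carries donor chromatin the
#' bivalent pairs with the configured homoeologous pairing probability; a
#' paired bivalent undergoes one crossover at a uniform position (optionally
#' a second) and transmits a recombinant product, so the gamete junction
#' frequency equals the pairing probability (two-strand simplification; see
#' vignette). An unpaired bivalent (or a pure-recipient slot, which always
#' pairs) transmits one copy unchanged. Transmission bias is applied by the
#' caller ([cross()]) via rejection sampling over whole gametes.
#'
#' Uses the current RNG state; seed via [cross()] or `set.seed()`.
#'
#' @param line a `sim_line`.
#' @param scheme a [cross_scheme()].
#' @return named list of block runs, one per slot (haploid mosaic).
#' @export
make_gamete <- function(line, scheme) {
  out <- vector("list", length(line$mosaic))
  names(out) <- names(line$mosaic)
  for (slot in names(line$mosaic)) {
    c1 <- line$mosaic[[slot]][[1]]
    c2 <- line$mosaic[[slot]][[2]]
    L <- max(c1$end)
    donor_subs <- unique(stats::na.omit(donor_subgenome_of_src(c(c1$src, c2$src))))
    p_pair <- if (length(donor_subs) == 0L) 1.0 else {
      keys <- paste0(donor_subs, "-", slot_subgenome(slot))
      max(scheme$pairing_prob[keys], na.rm = TRUE)
    }
    if (stats::runif(1) < p_pair) {
      xs <- sample.int(L - 1L, 1L)
      if (scheme$second_crossover_prob > 0 &&
          stats::runif(1) < scheme$second_crossover_prob) {
        xs <- c(xs, sample.int(L - 1L, 1L))
      }
      if (stats::runif(1) < 0.5) {
        out[[slot]] <- recombine(c1, c2, xs)
      } else {
        out[[slot]] <- recombine(c2, c1, xs)
      }
    } else {
      out[[slot]] <- if (stats::runif(1) < 0.5) c1 else c2
    }
  }
  out
}

gamete_weight <- function(gamete, bias) {
  if (length(bias) == 0L) return(1)
  srcs <- unique(unlist(lapply(gamete, `[[`, "src")))
  w <- 1
  for (ch in intersect(names(bias), srcs)) w <- w * bias[[ch]]
  w
}

draw_gamete <- function(line, scheme) {
  bias <- scheme$transmission_bias
  if (length(bias) == 0L) return(make_gamete(line, scheme))
  wmax <- prod(pmax(bias, 1))
  repeat {
    g <- make_gamete(line, scheme)
    if (stats::runif(1) < gamete_weight(g, bias) / wmax) return(g)
  }
}

advance_generation <- function(label, type) {
  bc <- if (grepl("BC[0-9]+", label)) {
    as.integer(sub(".*BC([0-9]+).*", "\\1", label))
  } else 0L
  fs <- if (grepl("F[0-9]+$", label)) {
    as.integer(sub(".*F([0-9]+)$", "\\1", label))
  } else 0L
  if (type == "BC") {
    paste0("BC", bc + 1L)
  } else {
    paste0(if (bc > 0L) paste0("BC", bc) else "", "F", fs + 1L)
  }
}

#' Cross two lines (backcross or self)
#'
#' Each offspring receives one gamete from each parent. The generation label
#' advances to `BC(n+1)` when one parent is a pure recipient, and to the
#' next selfing generation when mother and father are the same line.
#' @param mother,father `sim_line` parents.
#' @param n_offspring number of offspring (>= 1).
#' @param scheme a [cross_scheme()]; its seed drives the meioses.
#' @return list of `sim_line` offspring.
#' @export
cross <- function(mother, father, n_offspring, scheme) {
  stopifnot(n_offspring >= 1)
  selfing <- identical(mother$line_id, father$line_id)
  mother_pure <- !any(vapply(mother$mosaic, function(s) {
    has_donor(s[[1]]) || has_donor(s[[2]])
  }, logical(1)))
  father_pure <- !any(vapply(father$mosaic, function(s) {
    has_donor(s[[1]]) || has_donor(s[[2]])
  }, logical(1)))
  type <- if (selfing) "self" else if (mother_pure || father_pure) "BC" else "cross"
  base <- if (selfing || !mother_pure) mother$generation else father$generation
  label <- if (type == "cross") paste0(base, "x") else advance_generation(base, type)
  with_seed(child_seed(scheme$seed, paste0("cross_", mother$line_id, "_",
                                           father$line_id)), {
    lapply(seq_len(n_offspring), function(i) {
      gm <- draw_gamete(mother, scheme)
      gf <- draw_gamete(father, scheme)
      mosaic <- lapply(names(gm), function(slot) list(gm[[slot]], gf[[slot]]))
      names(mosaic) <- names(gm)
      new_sim_line(sprintf("%s.%d", mother$line_id, i), label, mosaic)
    })
  })
}

#' Noise-free genotyping of simulated lines (truth oracle)
#'
#' The call at a marker is HomDonor (2) when both copies carry a donor block
#' over the position, Het (1) when exactly one does, HomRecipient (0)
#' otherwise. Subgenome-specific markers only see donor chromatin of their
#' subgenome; nonspecific markers see either.
#' @param lines list of `sim_line`.
#' @param markers marker data frame (`marker_id, chrom, pos, specificity`),
#'   0-based positions.
#' @return integer matrix lines x markers (dimnames set).
#' @export
genotype_truth <- function(lines, markers) {
  stopifnot(all(c("marker_id", "chrom", "pos") %in% names(markers)))
  spec <- markers$specificity %||% rep("nonspecific", nrow(markers))
  gm <- matrix(0L, nrow = length(lines), ncol = nrow(markers),
               dimnames = list(vapply(lines, `[[`, "", "line_id"),
                               markers$marker_id))
  for (li in seq_along(lines)) {
    line <- lines[[li]]
    for (mi in seq_len(nrow(markers))) {
      slot <- markers$chrom[mi]
      if (!slot %in% names(line$mosaic)) {
        stop(sprintf("marker %s on unknown chromosome %s",
                     markers$marker_id[mi], slot))
      }
      pos <- markers$pos[mi]
      n_donor <- 0L
      for (ci in 1:2) {
        b <- line$mosaic[[slot]][[ci]]
        k <- which(b$start <= pos & b$end > pos)
        if (length(k) == 1L) {
          dsub <- donor_subgenome_of_src(b$src[k])
          hit <- !is.na(dsub) &&
            (spec[mi] == "nonspecific" || spec[mi] == dsub)
          if (hit) n_donor <- n_donor + 1L
        }
      }
      gm[li, mi] <- n_donor
    }
  }
  gm
}

# donor segments of a line as (slot, zygosity) runs, from the mosaic itself
line_true_segments <- function(line) {
  out <- list()
  for (slot in names(line$mosaic)) {
    for (ci in 1:2) {
      b <- line$mosaic[[slot]][[ci]]
      for (k in which(grepl("(At|G)$", b$src))) {
        out[[length(out) + 1L]] <- data.frame(
          line_id = line$line_id, chrom = slot, copy = ci,
          src = b$src[k], start = b$start[k], end = b$end[k],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(line_id = character(), chrom = character(), copy = integer(),
               src = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
}

#' Partition a genotyped family for the next breeding round
#'
#' Plants whose every donor segment is homozygous become homozygous
#' introgression lines; plants with heterozygous segments go to backcrossing
#' when they still carry more than `min_other_segments` other donor
#' segments, otherwise to self-fertilisation; plants with no donor
#' chromatin are discarded.
#' @param family list of `sim_line`.
#' @param genotypes integer matrix from [genotype_truth()] (or called data).
#' @param markers marker data frame matching the genotype columns.
#' @param rules selection rules (see [cross_scheme()]).
#' @return list of four character vectors of line ids: `to_backcross`,
#'   `to_self`, `homozygous_ILs`, `discard`.
#' @export
select_plants <- function(family, genotypes,
                          markers, rules = list(min_other_segments = 2L,
                                                max_self_segments = 2L)) {
  known <- c("min_other_segments", "max_self_segments")
  if (!all(names(rules) %in% known)) {
    abort_user(sprintf("unknown selection rule(s): %s",
                       paste(setdiff(names(rules), known), collapse = ", ")))
  }
  min_other <- rules$min_other_segments %||% 2L
  out <- list(to_backcross = character(0), to_self = character(0),
              homozygous_ILs = character(0), discard = character(0))
  ids <- vapply(family, `[[`, "", "line_id")
  stopifnot(all(ids %in% rownames(genotypes)))
  for (line in family) {
    g <- genotypes[line$line_id, ]
    segs <- genotype_runs(g, markers)
    if (nrow(segs) == 0L) {
      out$discard <- c(out$discard, line$line_id)
    } else if (all(segs$zygosity == "hom")) {
      out$homozygous_ILs <- c(out$homozygous_ILs, line$line_id)
    } else if (nrow(segs) - 1L >= min_other) {
      out$to_backcross <- c(out$to_backcross, line$line_id)
    } else {
      out$to_self <- c(out$to_self, line$line_id)
    }
  }
  out
}

# maximal runs of a constant donor state (1 = het, 2 = hom) along each
# chromosome of a single line's genotype vector
genotype_runs <- function(g, markers) {
  res <- list()
  for (ch in unique(markers$chrom)) {
    mi <- which(markers$chrom == ch)
    mi <- mi[order(markers$pos[mi])]
    v <- g[mi]
    r <- rle(ifelse(is.na(v), -1L, v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values %in% c(1L, 2L))) {
      res[[length(res) + 1L]] <- data.frame(
        chrom = ch,
        zygosity = if (r$values[k] == 2L) "hom" else "het",
        n_markers = r$lengths[k],
        first_pos = markers$pos[mi[starts[k]]],
        last_pos = markers$pos[mi[ends[k]]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(), zygosity = character(),
               n_markers = integer(), first_pos = integer(),
               last_pos = integer(), stringsAsFactors = FALSE)
}
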