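# Synthetic reference data with known ground truth. Every seed-match site
# in the generated 3'-UTRs is implanted deliberately (accidental catalog
# seed matches are mutated away), so the provenance of every site is known:
# "functional" sites carry AU-enriched flanks, extended tRF complementarity
# (lower duplex MFE) and an elevated position-8 match rate relative to
# implanted background sites, by configurable effect sizes.

#' Synthetic study configuration
#'
#' Defaults describe the emulated study: a catalog of 6 tRFs with
#' tRF-subclass lengths (tRF-3: 18/22 nt; tRF-5: 15/22/31 nt), 100
#' transcripts with 400-800 nt 3'-UTRs at background GC 50%, 50 functional
#' (positive) sites on 50 transcripts, and 400 background sites implanted
#' on the remaining transcripts. Effect sizes: positives' flanks are drawn
#' at 70% AU (background 50%), tRF positions 9-14 find perfect upstream
#' complements in 70% of positives (extended complementarity, lowering the
#' duplex MFE), and the position-8 match rate is 60% in positives versus
#' the 25% base-composition expectation in the background.
#'
#' @param n_transcripts Number of transcripts.
#' @param n_positive Number of implanted functional sites (one per
#'   transcript).
#' @param n_background Number of implanted background sites (on
#'   transcripts without functional sites).
#' @param utr_min,utr_max 3'-UTR length range (nt).
#' @param utr5_len,cds_len Fixed 5'-UTR and CDS lengths (nt).
#' @param gc_background Background GC fraction for i.i.d. sequence.
#' @param au_flank_pos AU fraction of positive-site flanks.
#' @param ext_compl_rate Fraction of positives with a perfect upstream
#'   complement of tRF positions 9-14.
#' @param pos8_rate Position-8 match rate among positives.
#' @param n_trf3,n_trf5 Catalog sizes per tRF class.
#' @param reads_per_pair Chimeric reads generated per positive pair.
#' @param n_decoy_reads Reads containing no catalog tRF.
#' @param tag_lambda Poisson mean of per-transcript 3P-seq tag counts.
#' @param cons_high,cons_low Beta parameters (shape1, shape2) of the
#'   conservation score at functional sites and elsewhere.
#' @param seed RNG seed.
#' @return Config list.
#' @export
synthetic_config <- function(n_transcripts = 100L, n_positive = 50L,
                             n_background = 400L,
                             utr_min = 400L, utr_max = 800L,
                             utr5_len = 80L, cds_len = 240L,
                             gc_background = 0.5,
                             au_flank_pos = 0.70, ext_compl_rate = 0.70,
                             pos8_rate = 0.60,
                             n_trf3 = 4L, n_trf5 = 2L,
                             reads_per_pair = 1L, n_decoy_reads = 10L,
                             tag_lambda = 50,
                             cons_high = c(8, 2), cons_low = c(2, 8),
                             seed = 1L) {
  stopifnot(n_positive >= 1L, n_positive <= n_transcripts,
            n_background >= 1L, utr_min >= 100L, utr_max >= utr_min,
            gc_background > 0, gc_background < 1,
            au_flank_pos >= 0, au_flank_pos <= 1,
            ext_compl_rate >= 0, ext_compl_rate <= 1,
            pos8_rate >= 0, pos8_rate <= 1,
            n_trf3 + n_trf5 >= 1L)
  as.list(environment())
}

rand_seq <- function(n, gc = 0.5) {
  if (n == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(RNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

rand_au_seq <- function(n, au = 0.5) {
  if (n == 0L) return("")
  p <- c(A = au / 2, C = (1 - au) / 2, G = (1 - au) / 2, U = au / 2)
  paste(sample(RNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

complement_base <- function(b) chartr("ACGU", "UGCA", b)

splice_in <- function(s, start0, piece) {
  # overwrite s at 0-based offset start0 with piece
  paste0(substr(s, 1L, start0),
         piece,
         substring(s, start0 + nchar(piece) + 1L))
}

# mutate away accidental occurrences of any motif, preserving protected
# intervals (0-based half-open matrix with columns start, end)
scrub_motifs <- function(utr, motifs, protected) {
  inside_protected <- function(pos0) {
    any(pos0 >= protected[, 1L] & pos0 < protected[, 2L])
  }
  is_implanted <- function(st) {
    any(st == protected[, 1L] & (st + 6L) == protected[, 2L])
  }
  for (iter in 1:25) {
    dirty <- FALSE
    for (m in motifs) {
      for (st in find_motif(utr, m)) {
        if (is_implanted(st)) next
        # rotate one base of the occurrence that no implant owns
        span <- st:(st + 5L)
        cand <- span[!vapply(span, inside_protected, logical(1L))]
        if (length(cand) == 0L) next
        pos <- cand[[(st %% length(cand)) + 1L]]
        old <- substr(utr, pos + 1L, pos + 1L)
        new <- RNA_BASES[(match(old, RNA_BASES) %% 4L) + 1L]
        utr <- splice_in(utr, pos, new)
        dirty <- TRUE
      }
    }
    if (!dirty) return(utr)
  }
  utr
}

#' Generate the synthetic reference set
#'
#' Builds the tRF catalog, the transcript set with implanted functional
#' and background seed-match sites, per-transcript 3P-seq tag counts, and
#' the ground-truth tables. Deterministic per \code{cfg$seed}. Every site
#' found by \code{\link{scan_seed_matches}} on the output is an implanted
#' site.
#'
#' @param cfg \code{\link{synthetic_config}} list.
#' @return List: \code{trfs}, \code{transcripts}, \code{tag_counts}
#'   (named vector), \code{truth} (list with \code{positives},
#'   \code{background} site tables and \code{informative_features}).
#' @export
generate_reference <- function(cfg = synthetic_config()) {
  with_seed(cfg$seed, {
    # catalog: subclass lengths per class
    len3 <- c(18L, 22L)
    len5 <- c(15L, 22L, 31L)
    n_trf <- cfg$n_trf3 + cfg$n_trf5
    lens <- c(len3[((seq_len(cfg$n_trf3) - 1L) %% 2L) + 1L],
              len5[((seq_len(cfg$n_trf5) - 1L) %% 3L) + 1L])
    cls <- c(rep("tRF-3", cfg$n_trf3), rep("tRF-5", cfg$n_trf5))
    repeat {
      seqs <- vapply(lens, rand_seq, character(1L), gc = cfg$gc_background)
      if (!anyDuplicated(substr(seqs, 2L, 7L))) break  # distinct seeds
    }
    ids <- sprintf("%s-%03d", ifelse(cls == "tRF-3", "tRF-3", "tRF-5"),
                   seq_len(n_trf))
    trfs <- trf_catalog(ids, seqs, cls)

    utr_len <- sample(cfg$utr_min:cfg$utr_max, cfg$n_transcripts,
                      replace = TRUE)
    utr5 <- vapply(rep(cfg$utr5_len, cfg$n_transcripts), rand_seq,
                   character(1L), gc = cfg$gc_background)
    cds <- vapply(rep(cfg$cds_len, cfg$n_transcripts), rand_seq,
                  character(1L), gc = cfg$gc_background)
    utr3 <- vapply(utr_len, rand_seq, character(1L), gc = cfg$gc_background)
    tx_ids <- sprintf("NM_%06d", seq_len(cfg$n_transcripts))

    pos_tx <- seq_len(cfg$n_positive)
    bg_tx <- setdiff(seq_len(cfg$n_transcripts), pos_tx)

    positives <- vector("list", cfg$n_positive)
    for (i in pos_tx) {
      ti <- sample.int(n_trf, 1L)
      trf <- trfs[ti, ]
      n <- nchar(utr3[i])
      start <- sample(60:(n - 40L), 1L)
      site <- reverse_complement(trf$seed)
      u <- utr3[i]
      # AU-enriched flanks: [start-35, start-7) and [end, end+15)
      u <- splice_in(u, start - 35L,
                     rand_au_seq(28L, cfg$au_flank_pos))
      u <- splice_in(u, start + 6L, rand_au_seq(15L, cfg$au_flank_pos))
      # extended complementarity: rc of tRF positions 9-14 at
      # [start-7, start-1)
      if (runif(1L) < cfg$ext_compl_rate) {
        ext <- reverse_complement(substr(trf$sequence, 9L, 14L))
        u <- splice_in(u, start - 7L, ext)
      }
      # position 8: the base immediately 5' of the site
      p8 <- substr(trf$sequence, 8L, 8L)
      b <- if (runif(1L) < cfg$pos8_rate) complement_base(p8) else {
        sample(setdiff(RNA_BASES, complement_base(p8)), 1L)
      }
      u <- splice_in(u, start - 1L, b)
      u <- splice_in(u, start, site)
      utr3[i] <- u
      positives[[i]] <- data.frame(trf_id = trf$trf_id,
                                   transcript_id = tx_ids[i],
                                   start = start, end = start + 6L,
                                   stringsAsFactors = FALSE)
    }
    positives <- do.call(rbind, positives)

    # background sites: implanted without any context effect
    per_tx <- ceiling(cfg$n_background / length(bg_tx))
    background <- list()
    made <- 0L
    for (i in bg_tx) {
      if (made >= cfg$n_background) break
      n <- nchar(utr3[i])
      k <- min(per_tx, cfg$n_background - made)
      slots <- seq.int(60L, n - 46L, by = 60L)
      k <- min(k, length(slots))
      starts <- sort(sample(slots, k)) + sample(0:40, k, replace = TRUE)
      for (start in starts) {
        ti <- sample.int(n_trf, 1L)
        trf <- trfs[ti, ]
        utr3[i] <- splice_in(utr3[i], start, reverse_complement(trf$seed))
        background[[length(background) + 1L]] <-
          data.frame(trf_id = trf$trf_id, transcript_id = tx_ids[i],
                     start = start, end = start + 6L,
                     stringsAsFactors = FALSE)
        made <- made + 1L
      }
    }
    background <- do.call(rbind, background)

    # remove accidental seed matches so implants are the only sites
    motifs <- vapply(trfs$seed, reverse_complement, character(1L))
    all_sites <- rbind(positives, background)
    for (i in seq_len(cfg$n_transcripts)) {
      own <- all_sites[all_sites$transcript_id == tx_ids[i], , drop = FALSE]
      prot <- cbind(own$start, own$end)
      if (nrow(own) == 0L) prot <- matrix(integer(0), ncol = 2L)
      utr3[i] <- scrub_motifs(utr3[i], motifs, prot)
    }

    transcripts <- data.frame(
      transcript_id = tx_ids,
      gene_symbol = sprintf("GENE%03d", seq_len(cfg$n_transcripts)),
      utr5 = utr5, cds = cds, utr3 = utr3, stringsAsFactors = FALSE)
    tag_counts <- setNames(rpois(cfg$n_transcripts, cfg$tag_lambda), tx_ids)

    list(trfs = trfs, transcripts = transcripts, tag_counts = tag_counts,
         truth = list(
           positives = positives, background = background,
           informative_features = list(
             duplex = c("duplex_mfe", "duplex_paired",
                        "duplex_paired_nonseed"),
             pos8 = "pos8_match",
             flank_au = c("sau_up35", "sau_up25ex10", "sau_down15",
                          "gc_up35", "gc_up25ex10", "gc_down15"))))
  })
}

#' Generate chimeric reads for the implanted positive pairs
#'
#' Each positive pair yields \code{reads_per_pair} reads formed by
#' concatenating the full tRF sequence with a UTR fragment containing the
#' implanted site (orientation randomized), plus decoy reads containing no
#' catalog tRF. Deterministic per \code{cfg$seed}.
#'
#' @param ref \code{\link{generate_reference}} output.
#' @param cfg The same config.
#' @return Named character vector of reads.
#' @export
generate_chimeric_reads <- function(ref, cfg = synthetic_config()) {
  with_seed(cfg$seed + 1L, {
    truth <- ref$truth$positives
    reads <- character(0)
    for (i in seq_len(nrow(truth))) {
      trf <- ref$trfs[ref$trfs$trf_id == truth$trf_id[i], ]
      tx <- ref$transcripts[
        ref$transcripts$transcript_id == truth$transcript_id[i], ]
      n <- nchar(tx$utr3)
      fs <- max(0L, truth$start[i] - 12L)
      fe <- min(n, truth$end[i] + 12L)
      frag <- seq_window(tx$utr3, fs, fe)
      for (r in seq_len(cfg$reads_per_pair)) {
        read <- if (runif(1L) < 0.5) paste0(trf$sequence, frag) else {
          paste0(frag, trf$sequence)
        }
        reads[sprintf("read_%04d_%d", i, r)] <- read
      }
    }
    for (d in seq_len(cfg$n_decoy_reads)) {
      repeat {
        dec <- rand_seq(40L, cfg$gc_background)
        hit <- any(vapply(ref$trfs$sequence, function(s) {
          grepl(s, dec, fixed = TRUE)
        }, logical(1L)))
        if (!hit) break
      }
      reads[sprintf("decoy_%04d", d)] <- dec
    }
    reads
  })
}

#' Generate a per-base conservation track
#'
#' Positions inside implanted functional sites draw scores from the high
#' Beta mode, everything else (including background sites) from the low
#' mode. Deterministic per \code{cfg$seed}.
#'
#' @param ref \code{\link{generate_reference}} output.
#' @param cfg The same config.
#' @return Named list of per-base score vectors over each 3'-UTR.
#' @export
generate_conservation_track <- function(ref, cfg = synthetic_config()) {
  with_seed(cfg$seed + 2L, {
    track <- list()
    for (i in seq_len(nrow(ref$transcripts))) {
      id <- ref$transcripts$transcript_id[i]
      n <- nchar(ref$transcripts$utr3[i])
      sc <- rbeta(n, cfg$cons_low[1L], cfg$cons_low[2L])
      own <- ref$truth$positives[ref$truth$positives$transcript_id == id, ,
                                 drop = FALSE]
      for (j in seq_len(nrow(own))) {
        idx <- (own$start[j] + 1L):own$end[j]
        sc[idx] <- rbeta(length(idx), cfg$cons_high[1L], cfg$cons_high[2L])
      }
      track[[id]] <- round(sc, 3)
    }
    track
  })
}

#' Write a score track as fixedStep wiggle
#'
#' One fixedStep block per sequence, start=1, step=1; NA positions split
#' blocks.
#'
#' @param track Named list of per-base score vectors.
#' @param path Output path.
#' @export
write_score_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(track)) {
    sc <- track[[id]]
    runs <- rle(!is.na(sc))
    pos <- 1L
    for (r in seq_along(runs$lengths)) {
      len <- runs$lengths[r]
      if (runs$values[r]) {
        writeLines(sprintf("fixedStep chrom=%s start=%d step=1", id, pos),
                   con)
        writeLines(format(sc[pos:(pos + len - 1L)], trim = TRUE,
                          scientific = FALSE), con)
      }
      pos <- pos + len
    }
  }
  invisible(path)
}

#' Write 3P-seq tag counts as TSV
#'
#' @param tag_counts Named vector (transcript_id -> tags).
#' @param path Output path.
#' @export
write_tag_counts <- function(tag_counts, path) {
  write.table(data.frame(transcript_id = names(tag_counts),
                         tag_count = as.integer(tag_counts)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
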