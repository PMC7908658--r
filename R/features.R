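# Per-site feature roster: sequence context of the seed match, transcript
# properties, tRF properties, and duplex/accessibility thermodynamics.
# Feature extraction is a pure function of (tRF, transcript, site); missing
# values (empty windows or regions) are NA here and imputed downstream with
# training-partition medians only.

#' Distance-weighted AU content of a flanking window
#'
#' Sites in locally AU-rich (weakly structured) context are more effective;
#' the score weights each A or U by the inverse of its distance to the seed
#' match: S = sum over positions d of 1/d for bases in {A, U}, with the
#' window listed nearest-first (d = 1 is the base adjacent to the site).
#' \code{exclude_first = 10} skips the 10 bases immediately next to the
#' site, used for the upstream score that avoids the region where the tRF
#' 3' end itself tends to pair.
#'
#' @param window Residue string, nearest base first; may be empty.
#' @param exclude_first Number of nearest positions to skip (0 or 10).
#' @return Dimensionless score >= 0.
#' @export
#' @examples
#' flank_au_score("AU")  # 1/1 + 1/2 = 1.5
flank_au_score <- function(window, exclude_first = 0L) {
  n <- nchar(window)
  if (n == 0L) return(0)
  v <- strsplit(window, "", fixed = TRUE)[[1L]]
  d <- seq_len(n)
  keep <- d > exclude_first & (v == "A" | v == "U")
  sum(1 / d[keep])
}

DINUCS <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                          paste0))

#' Base, dinucleotide and GC composition of a window
#'
#' Fractions are over the effective window length (N excluded from all
#' denominators; dinucleotides containing N are dropped). An empty window
#' yields all-NA composition for downstream imputation.
#'
#' @param window Residue string, possibly empty.
#' @return List: \code{base} (named length-4 fractions), \code{dinuc}
#'   (named length-16 fractions), \code{gc} (percentage).
#' @export
window_composition <- function(window) {
  v <- strsplit(window, "", fixed = TRUE)[[1L]]
  v_eff <- v[v != "N"]
  if (length(v_eff) == 0L) {
    return(list(base = setNames(rep(NA_real_, 4L), RNA_BASES),
                dinuc = setNames(rep(NA_real_, 16L), DINUCS),
                gc = NA_real_))
  }
  base <- vapply(RNA_BASES, function(b) mean(v_eff == b), numeric(1L))
  if (length(v) >= 2L) {
    di <- paste0(v[-length(v)], v[-1L])
    di <- di[!grepl("N", di, fixed = TRUE)]
  } else {
    di <- character(0)
  }
  if (length(di) == 0L) {
    dinuc <- setNames(rep(NA_real_, 16L), DINUCS)
  } else {
    dinuc <- vapply(DINUCS, function(d) mean(di == d), numeric(1L))
  }
  list(base = base, dinuc = dinuc,
       gc = 100 * mean(v_eff == "G" | v_eff == "C"))
}

base_indicators <- function(b, prefix) {
  out <- setNames(as.numeric(RNA_BASES == b), paste0(prefix, "_", RNA_BASES))
  out
}

comp_features <- function(window, prefix) {
  wc <- window_composition(window)
  c(setNames(wc$base, paste0("comp_", prefix, "_", RNA_BASES)),
    setNames(wc$dinuc, paste0("dinuc_", prefix, "_", DINUCS)))
}

gc_or_na <- function(s) {
  if (nchar(gsub("N", "", s)) == 0L) return(NA_real_)
  gc_percent(s)
}

#' Site-sequence features of one seed-match site
#'
#' Seed-type indicators (position 8 match, position 1 match, position 1 A),
#' identity indicators of the two bases on each side of the site, GC
#' percentage and distance-weighted AU score of the 35-nt upstream window,
#' of the same window excluding the 10 nt immediately upstream, and of the
#' 15-nt downstream window, base/dinucleotide composition of the 35-up and
#' 15-down windows, and the distances to the UTR ends. Windows truncated at
#' UTR boundaries are used as-is.
#'
#' @param trf One-row tRF catalog slice.
#' @param utr3 UTR residue string.
#' @param start,end Site interval, 0-based half-open.
#' @return Named numeric vector.
#' @export
site_features <- function(trf, utr3, start, end) {
  n <- nchar(utr3)
  if (start < 0L || end > n) stop("site outside UTR")
  flags <- classify_site_type(trf, utr3, start)
  w <- window_extract(utr3, start, end, up = 35L, down = 15L)
  up35 <- w$upstream
  down15 <- w$downstream
  # 25-nt window ending 10 nt before the site: drop the last 10 of up35
  up25ex10 <- if (nchar(up35) > 10L) {
    substr(up35, 1L, nchar(up35) - 10L)
  } else ""
  # nearest-first orderings for the AU score
  up35_nf <- reverse_string(up35)
  out <- c(
    pos8_match = as.numeric(flags$pos8_match),
    pos1_match = as.numeric(flags$pos1_match),
    pos1A = as.numeric(flags$pos1A),
    base_indicators(char_at(utr3, start - 1L), "up1"),
    base_indicators(char_at(utr3, start - 2L), "up2"),
    base_indicators(char_at(utr3, end), "down1"),
    base_indicators(char_at(utr3, end + 1L), "down2"),
    gc_up35 = if (nchar(up35)) gc_or_na(up35) else NA_real_,
    gc_up25ex10 = if (nchar(up25ex10)) gc_or_na(up25ex10) else NA_real_,
    gc_down15 = if (nchar(down15)) gc_or_na(down15) else NA_real_,
    sau_up35 = flank_au_score(up35_nf, 0L),
    sau_up25ex10 = flank_au_score(up35_nf, 10L),
    sau_down15 = flank_au_score(down15, 0L),
    comp_features(up35, "up35"),
    comp_features(down15, "down15"),
    dist5 = start,
    dist3 = n - end,
    dist_nearest = min(start, n - end)
  )
  out
}

reverse_string <- function(s) {
  if (nchar(s) < 2L) return(s)
  paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
}

char_at <- function(s, pos0) {
  if (pos0 < 0L || pos0 >= nchar(s)) return("")
  substr(s, pos0 + 1L, pos0 + 1L)
}

seed_match_frequency <- function(region, motif) {
  n <- nchar(region)
  if (n == 0L) return(NA_real_)
  1000 * length(find_motif(region, motif)) / n
}

#' Transcript-level features for one tRF
#'
#' Region lengths and GC percentages, seed-match frequency per 1000 nt of
#' each region (frequency rather than raw count, since region length is a
#' feature of its own), and base/dinucleotide composition of the 3'-UTR.
#' Empty regions yield NA.
#'
#' @param trf One-row tRF catalog slice.
#' @param transcript One-row transcript slice.
#' @return Named numeric vector.
#' @export
transcript_features <- function(trf, transcript) {
  motif <- reverse_complement(trf$seed)
  u3 <- transcript$utr3
  u5 <- transcript$utr5
  cds <- transcript$cds
  c(
    len_utr3 = nchar(u3),
    gc_utr3 = if (nchar(u3)) gc_or_na(u3) else NA_real_,
    seedfreq_utr3 = seed_match_frequency(u3, motif),
    comp_features(u3, "utr3"),
    len_cds = if (nchar(cds)) nchar(cds) else NA_real_,
    gc_cds = if (nchar(cds)) gc_or_na(cds) else NA_real_,
    seedfreq_cds = seed_match_frequency(cds, motif),
    len_utr5 = if (nchar(u5)) nchar(u5) else NA_real_,
    gc_utr5 = if (nchar(u5)) gc_or_na(u5) else NA_real_,
    seedfreq_utr5 = seed_match_frequency(u5, motif)
  )
}

#' tRF-level features
#'
#' Catalog length, GC of the whole tRF and of its seed, and target-site
#' abundance (TA): the total count of the seed's complementary 6-mer over
#' all provided 3'-UTRs and, when a genome sequence set is supplied, over
#' the genome. High TA dilutes repression.
#'
#' @param trf One-row tRF catalog slice.
#' @param transcripts Transcript data.frame.
#' @param genome Optional named character vector of genomic sequences;
#'   absent -> \code{ta_genome} is NA.
#' @return Named numeric vector.
#' @export
trf_features <- function(trf, transcripts, genome = NULL) {
  motif <- reverse_complement(trf$seed)
  ta3 <- sum(vapply(transcripts$utr3,
                    function(u) length(find_motif(u, motif)), integer(1L)))
  tag <- if (is.null(genome)) NA_real_ else {
    sum(vapply(genome, function(g) length(find_motif(g, motif)), integer(1L)))
  }
  c(
    trf_length = nchar(trf$sequence),
    trf_gc = gc_percent(trf$sequence),
    seed_gc = gc_percent(trf$seed),
    ta_utr3 = ta3,
    ta_genome = tag
  )
}

#' Duplex and accessibility features for one site
#'
#' The duplex is formed between the full tRF and the target region around
#' the site (25 nt upstream + site + 5 nt downstream; the tRF 3' portion
#' pairs upstream of the seed match on an antiparallel duplex). Reports the
#' duplex MFE, the number of paired tRF positions, the number paired
#' outside the seed (positions 2-7), and the accessibility of the site in
#' its local fold.
#'
#' @param trf One-row tRF catalog slice.
#' @param utr3 UTR residue string.
#' @param start,end Site interval.
#' @param model Energy model.
#' @return Named numeric vector.
#' @export
thermo_features <- function(trf, utr3, start, end, model = energy_model()) {
  n <- nchar(utr3)
  rs <- max(0L, start - 25L)
  re <- min(n, end + 5L)
  region <- seq_window(utr3, rs, re)
  dup <- duplex_mfe(trf$sequence, region, model)
  nonseed <- sum(dup$pairing_map$trf_pos < 2L | dup$pairing_map$trf_pos > 7L)
  acc <- accessibility_features(utr3, start, end, model)
  c(
    duplex_mfe = dup$mfe,
    duplex_paired = dup$paired_count,
    duplex_paired_nonseed = nonseed,
    exposed_at_site = acc$exposed_at_site,
    exposed_flanks = acc$exposed_flanks,
    opening_energy = acc$opening_energy
  )
}

#' The active feature registry
#'
#' Ordered roster of feature names with their family, matching the four
#' feature categories: site sequence context, transcript, tRF, and
#' duplex/accessibility thermodynamics. The roster is derived from a probe
#' extraction, so it always agrees with what the providers emit.
#'
#' @param include_thermo Include the thermodynamics family (default TRUE).
#' @return data.frame with columns \code{name}, \code{family}.
#' @export
feature_registry <- function(include_thermo = TRUE) {
  trf <- trf_catalog("probe", "ACGUACGUACGUACGUAC", "tRF-3")[1L, ]
  tx <- data.frame(transcript_id = "probe_tx", gene_symbol = "P",
                   utr5 = "ACGU", cds = "AUGUAA",
                   utr3 = strrep("ACGU", 30L), stringsAsFactors = FALSE)
  sf <- site_features(trf, tx$utr3, 40L, 46L)
  tf <- transcript_features(trf, tx[1L, ])
  rf <- trf_features(trf, tx)
  reg <- data.frame(
    name = c(names(sf), names(tf), names(rf)),
    family = c(rep("site_sequence", length(sf)),
               rep("transcript", length(tf)),
               rep("trf", length(rf))),
    stringsAsFactors = FALSE
  )
  if (include_thermo) {
    th <- c("duplex_mfe", "duplex_paired", "duplex_paired_nonseed",
            "exposed_at_site", "exposed_flanks", "opening_energy")
    reg <- rbind(reg, data.frame(name = th, family = "duplex_thermo"))
  }
  stopifnot(!anyDuplicated(reg$name))
  reg
}

REGISTRY_VERSION <- "trftargets-registry-1"

#' Assemble the site-by-feature matrix for a set of interaction pairs
#'
#' One row per pair, columns in registry order. Missing values are left as
#' NA (imputation with training-partition medians happens at model fitting,
#' never here, so no information leaks across folds). Deterministic given
#' its inputs.
#'
#' @param pairs Site data.frame (\code{trf_id}, \code{transcript_id},
#'   \code{start}, \code{end}).
#' @param trfs tRF catalog.
#' @param transcripts Transcript data.frame.
#' @param model Energy model for the thermo family.
#' @param genome Optional genome sequence set for target abundance.
#' @param include_thermo Compute the thermodynamics family (default TRUE).
#' @return List: \code{matrix} (numeric, rownames = pair keys),
#'   \code{registry}, \code{registry_version}, \code{pairs} (rows kept).
#' @export
assemble_feature_matrix <- function(pairs, trfs, transcripts,
                                    model = energy_model(), genome = NULL,
                                    include_thermo = TRUE) {
  reg <- feature_registry(include_thermo)
  # tRF and per-(trf, transcript) features are shared across sites: cache
  trf_cache <- new.env(parent = emptyenv())
  tx_cache <- new.env(parent = emptyenv())
  mat <- matrix(NA_real_, nrow = nrow(pairs), ncol = nrow(reg),
                dimnames = list(NULL, reg$name))
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    trf <- trfs[trfs$trf_id == pairs$trf_id[i], , drop = FALSE]
    tx <- transcripts[transcripts$transcript_id == pairs$transcript_id[i], ,
                      drop = FALSE]
    if (nrow(trf) != 1L || nrow(tx) != 1L) {
      warning("dropping pair with unknown tRF or transcript: ",
              pairs$trf_id[i], " / ", pairs$transcript_id[i])
      next
    }
    row <- tryCatch({
      sf <- site_features(trf, tx$utr3, pairs$start[i], pairs$end[i])
      key_t <- trf$trf_id
      if (is.null(trf_cache[[key_t]])) {
        trf_cache[[key_t]] <- trf_features(trf, transcripts, genome)
      }
      key_x <- paste0(trf$trf_id, "\r", tx$transcript_id)
      if (is.null(tx_cache[[key_x]])) {
        tx_cache[[key_x]] <- transcript_features(trf, tx)
      }
      v <- c(sf, tx_cache[[key_x]], trf_cache[[key_t]])
      if (include_thermo) {
        v <- c(v, thermo_features(trf, tx$utr3, pairs$start[i],
                                  pairs$end[i], model))
      }
      v
    }, error = function(e) {
      warning("dropping pair ", pairs$trf_id[i], "/",
              pairs$transcript_id[i], ": ", conditionMessage(e))
      NULL
    })
    if (is.null(row)) next
    mat[i, ] <- row[reg$name]
    keep[i] <- TRUE
  }
  list(matrix = mat[keep, , drop = FALSE],
       registry = reg,
       registry_version = REGISTRY_VERSION,
       pairs = pairs[keep, , drop = FALSE])
}

#' Write a feature matrix and its registry as TSV
#'
#' @param fm Result of \code{\link{assemble_feature_matrix}}.
#' @param matrix_path,registry_path Output paths.
#' @export
write_feature_matrix <- function(fm, matrix_path, registry_path) {
  out <- cbind(fm$pairs[, c("trf_id", "transcript_id", "start", "end")],
               as.data.frame(fm$matrix))
  write.table(out, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(fm$registry, registry_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(NULL)
}
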