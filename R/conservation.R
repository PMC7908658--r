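# Conservation-based independent predictor. Per-base scores in [0, 1]
# (phastCons-style) are consumed from a fixedStep wiggle or bedGraph track
# expressed in transcript 3'-UTR coordinates; genome-to-transcript
# projection is out of scope.

#' Load a per-base score track
#'
#' Parses a fixedStep wiggle or bedGraph file (format by extension or the
#' \code{format} argument) into dense per-sequence score arrays. Positions
#' without a score are NA (missing). Scores outside \[0, 1\] and
#' overlapping blocks are errors.
#'
#' @param path Track file.
#' @param seq_lengths Named integer vector: sequence id -> length. Track
#'   ids must be a subset of these names.
#' @param format \code{"auto"} (default), \code{"wig"} or
#'   \code{"bedGraph"}.
#' @return Named list of numeric vectors (one per sequence, NA = missing).
#' @export
load_score_track <- function(path, seq_lengths,
                             format = c("auto", "wig", "bedGraph")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(bedgraph|bg)$", tolower(path))) "bedGraph"
              else "wig"
  }
  gr <- rtracklayer::import(path, format = format)
  ids <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(ids), names(seq_lengths))
  if (length(unknown) > 0L) {
    stop("track sequence ids not in the sequence set: ",
         paste(head(unknown, 5L), collapse = ", "))
  }
  score <- gr$score
  if (any(score < 0 | score > 1)) {
    bad <- which(score < 0 | score > 1)[1L]
    stop(sprintf("score %g outside [0,1] in block %d of %s",
                 score[bad], bad, path))
  }
  track <- lapply(seq_lengths, function(n) rep(NA_real_, n))
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  for (i in seq_along(gr)) {
    id <- ids[i]
    if (en[i] > seq_lengths[[id]]) {
      stop("track block ", i, " extends past the end of ", id)
    }
    span <- st[i]:en[i]
    if (any(!is.na(track[[id]][span]))) {
      stop("overlapping track blocks on ", id, " near position ", st[i])
    }
    track[[id]][span] <- score[i]
  }
  track
}

mean_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) NA_real_ else mean(x)
}

#' Conservation summary of one seed-match site
#'
#' Mean score over the seed region, the 35-nt upstream and 15-nt
#' downstream windows (truncated at the UTR ends), and the whole UTR,
#' with the fraction of each window covered by scores. A window with zero
#' coverage is NA.
#'
#' @param track Score track list from \code{\link{load_score_track}}.
#' @param utr_id Sequence id in the track.
#' @param start,end Site interval, 0-based half-open on the UTR.
#' @return List: \code{mean_seed}, \code{mean_up35}, \code{mean_down15},
#'   \code{mean_utr}, and coverage fractions \code{cov_seed},
#'   \code{cov_up35}, \code{cov_down15}, \code{cov_utr}.
#' @export
site_conservation <- function(track, utr_id, start, end) {
  sc <- track[[utr_id]]
  if (is.null(sc)) stop("no track for sequence: ", utr_id)
  n <- length(sc)
  stopifnot(start >= 0L, end > start, end <= n)
  seed <- sc[(start + 1L):end]
  up <- if (start > 0L) sc[(max(0L, start - 35L) + 1L):start] else numeric(0)
  down <- if (end < n) sc[(end + 1L):min(n, end + 15L)] else numeric(0)
  cov <- function(x) if (length(x) == 0L) 0 else mean(!is.na(x))
  list(mean_seed = mean_or_na(seed),
       mean_up35 = mean_or_na(up),
       mean_down15 = mean_or_na(down),
       mean_utr = mean_or_na(sc),
       cov_seed = cov(seed), cov_up35 = cov(up),
       cov_down15 = cov(down), cov_utr = cov(sc))
}

#' Conservation-based site prediction
#'
#' A site is predicted as a target when its seed-region mean conservation
#' score reaches the cutoff (boundary inclusive, default 0.5). Sites
#' without seed coverage are NA (excluded).
#'
#' @param mean_seed Numeric vector of seed-region mean scores (NA allowed).
#' @param cutoff Score threshold (default 0.5).
#' @return Logical vector (NA where the score is missing).
#' @export
conservation_predict <- function(mean_seed, cutoff = 0.5) {
  ifelse(is.na(mean_seed), NA, mean_seed >= cutoff)
}

#' Conservation summaries for a site table
#'
#' @param track Score track.
#' @param sites Site data.frame (\code{transcript_id}, \code{start},
#'   \code{end}).
#' @param cutoff Prediction cutoff on the seed mean.
#' @return \code{sites} with conservation means, coverages and a
#'   \code{conserved} prediction column.
#' @export
conservation_table <- function(track, sites, cutoff = 0.5) {
  res <- lapply(seq_len(nrow(sites)), function(i) {
    sc <- site_conservation(track, sites$transcript_id[i],
                            sites$start[i], sites$end[i])
    as.data.frame(sc)
  })
  out <- cbind(sites, do.call(rbind, res))
  out$conserved <- conservation_predict(out$mean_seed, cutoff)
  out
}
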