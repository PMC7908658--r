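# Decomposition of AGO chimeric reads (CLASH / CLEAR-CLIP) into a catalog
# tRF and a 3'-UTR target fragment. Matching is exact: no mismatches or
# bulges are allowed, so a read is decomposed only when a full catalog tRF
# sequence is its exact prefix or suffix.

#' Collapse exact duplicate reads
#'
#' Optional PCR-duplicate handling for pre-trimmed reads: identical residue
#' strings collapse to the first read id carrying them.
#'
#' @param reads Named character vector of residue strings.
#' @return De-duplicated named character vector.
#' @export
collapse_duplicates <- function(reads) {
  reads[!duplicated(unname(reads))]
}

#' Decompose one chimeric read against a tRF catalog
#'
#' Finds the longest exact match of a full catalog tRF sequence at either
#' read end (prefix = \code{trf_first}, suffix = \code{trf_last}); the rest
#' of the read is the target fragment and must be at least 6 nt. When
#' distinct tRF sequences of equal (maximal) length match at both ends the
#' read is rejected as ambiguous.
#'
#' @param read_id Read identifier.
#' @param residues Canonical read string (length >= 20).
#' @param trfs tRF catalog data.frame.
#' @return On success a list with \code{read_id}, \code{trf_id},
#'   \code{trf_start}, \code{trf_end} (interval on the read),
#'   \code{target_fragment}, \code{orientation}; on rejection a list with
#'   \code{read_id} and \code{reason} in \code{no_trf_match},
#'   \code{fragment_too_short}, \code{ambiguous}.
#' @export
decompose_read <- function(read_id, residues, trfs) {
  stopifnot(nrow(trfs) > 0L)
  n <- nchar(residues)
  len <- nchar(trfs$sequence)
  pref <- which(len < n & substring(residues, 1L, len) == trfs$sequence)
  suff <- which(len < n &
                  substring(residues, n - len + 1L, n) == trfs$sequence)
  best_len <- max(c(0L, len[pref], len[suff]))
  if (best_len == 0L) {
    return(list(read_id = read_id, reason = "no_trf_match"))
  }
  pref <- pref[len[pref] == best_len]
  suff <- suff[len[suff] == best_len]
  cand_seq <- unique(trfs$sequence[c(pref, suff)])
  if (length(cand_seq) > 1L || length(pref) > 1L || length(suff) > 1L) {
    return(list(read_id = read_id, reason = "ambiguous"))
  }
  # identical sequence at both ends: take the 5' (prefix) placement
  if (length(pref) == 1L) {
    i <- pref[1L]
    frag <- substring(residues, best_len + 1L, n)
    span <- c(0L, best_len)
    orient <- "trf_first"
  } else {
    i <- suff[1L]
    frag <- substr(residues, 1L, n - best_len)
    span <- c(n - best_len, n)
    orient <- "trf_last"
  }
  if (nchar(frag) < 6L) {
    return(list(read_id = read_id, reason = "fragment_too_short"))
  }
  list(read_id = read_id, trf_id = trfs$trf_id[i],
       trf_start = span[1L], trf_end = span[2L],
       target_fragment = frag, orientation = orient)
}

#' Decompose a set of reads
#'
#' @param reads Named character vector of read strings.
#' @param trfs tRF catalog.
#' @return List with \code{decompositions} (list of successful
#'   decompositions) and \code{rejections} (data.frame read_id, reason).
#' @export
decompose_reads <- function(reads, trfs) {
  dec <- vector("list", length(reads))
  rej_id <- character(0)
  rej_why <- character(0)
  k <- 0L
  for (i in seq_along(reads)) {
    d <- decompose_read(names(reads)[i], reads[[i]], trfs)
    if (is.null(d$reason)) {
      k <- k + 1L
      dec[[k]] <- d
    } else {
      rej_id <- c(rej_id, d$read_id)
      rej_why <- c(rej_why, d$reason)
    }
  }
  list(decompositions = dec[seq_len(k)],
       rejections = data.frame(read_id = rej_id, reason = rej_why,
                               stringsAsFactors = FALSE))
}

#' Map a target fragment to 3'-UTRs by exact search
#'
#' All exact occurrences of the fragment in any transcript 3'-UTR are
#' returned; fragments hitting more than one UTR are flagged multi-mapping.
#' A fragment mapping nowhere yields zero rows (such pairs are discarded,
#' reason code \code{unmapped} at the caller).
#'
#' @param fragment Residue string, length >= 6.
#' @param transcripts Transcript data.frame.
#' @return data.frame \code{transcript_id}, \code{frag_start},
#'   \code{frag_end} (0-based half-open on the UTR), \code{multi_mapping}.
#' @export
map_target_fragment <- function(fragment, transcripts) {
  stopifnot(nchar(fragment) >= 6L)
  hits <- lapply(seq_len(nrow(transcripts)), function(j) {
    st <- find_motif(transcripts$utr3[j], fragment)
    if (length(st) == 0L) return(NULL)
    data.frame(transcript_id = transcripts$transcript_id[j],
               frag_start = st, frag_end = st + nchar(fragment),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, hits)
  if (is.null(res)) {
    res <- data.frame(transcript_id = character(0), frag_start = integer(0),
                      frag_end = integer(0), stringsAsFactors = FALSE)
  }
  res$multi_mapping <- rep(length(unique(res$transcript_id)) > 1L, nrow(res))
  res
}

#' Build positive interaction pairs from decomposed reads
#'
#' For each decomposition the target fragment is exactly mapped to the
#' 3'-UTRs; a pair is kept only when the mapped fragment interval contains
#' a perfect Watson-Crick seed match (reverse complement of tRF positions
#' 2-7) of the read's tRF. Identical (trf, transcript, site) triples from
#' different reads are de-duplicated.
#'
#' @param decompositions List from \code{\link{decompose_reads}}.
#' @param transcripts Transcript data.frame.
#' @param trfs tRF catalog.
#' @param drop_multi Drop fragments mapping to more than one UTR
#'   (default FALSE: all hits retained, flagged).
#' @return Site data.frame (as \code{\link{scan_seed_matches}}) with
#'   \code{label = "positive"} and \code{source = "chimera"}.
#' @export
build_interaction_pairs <- function(decompositions, transcripts, trfs,
                                    drop_multi = FALSE) {
  rows <- list()
  for (d in decompositions) {
    trf <- trfs[trfs$trf_id == d$trf_id, , drop = FALSE]
    if (nrow(trf) != 1L) stop("unknown tRF id in decomposition: ", d$trf_id)
    hits <- map_target_fragment(d$target_fragment, transcripts)
    if (nrow(hits) == 0L) next
    if (drop_multi && any(hits$multi_mapping)) next
    for (h in seq_len(nrow(hits))) {
      tx <- transcripts[transcripts$transcript_id == hits$transcript_id[h], ]
      sites <- scan_seed_matches(trf, tx$utr3, tx$transcript_id)
      if (nrow(sites) == 0L) next
      # seed match must lie inside the mapped fragment interval (strict)
      inside <- sites$start >= hits$frag_start[h] &
        sites$end <= hits$frag_end[h]
      rows[[length(rows) + 1L]] <- sites[inside, , drop = FALSE]
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0L) {
    res <- empty_sites()
    res$label <- character(0)
    res$source <- character(0)
    return(res)
  }
  res <- res[!duplicated(res[, c("trf_id", "transcript_id", "start")]), ,
             drop = FALSE]
  res$label <- "positive"
  res$source <- "chimera"
  rownames(res) <- NULL
  res
}
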