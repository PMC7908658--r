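# Sequence and coordinate primitives. All sequences are held as plain
# character strings over the RNA alphabet {A,C,G,U} (plus N); all intervals
# are 0-based half-open on the sequence's own 5'->3' orientation.

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a raw nucleotide string to the canonical RNA alphabet
#'
#' Uppercases, maps T to U, and rejects any character outside
#' \code{A,C,G,T,U,N} (either case). \code{N} is retained: composition
#' denominators exclude it and seed matches may not overlap it.
#'
#' @param raw Non-empty character scalar.
#' @return Canonical residue string over \code{{A,C,G,U,N}}.
#' @export
#' @examples
#' normalize_sequence("tGca")  # "UGCA"
normalize_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (is.na(raw) || nchar(raw) == 0L) {
    stop("sequence is empty")
  }
  up <- chartr("T", "U", toupper(raw))
  bad <- regexpr("[^ACGUN]", up)
  if (bad > 0L) {
    stop(sprintf("invalid character '%s' at position %d",
                 substr(up, bad, bad), bad))
  }
  up
}

#' Reverse complement of an RNA string
#'
#' Antiparallel Watson-Crick complement (A-U, C-G); N maps to N.
#' Involution: \code{reverse_complement(reverse_complement(x)) == x}.
#'
#' @param s Canonical residue string.
#' @return Residue string of the same length.
#' @export
reverse_complement <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  comp <- chartr("ACGUN", "UGCAN", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' GC percentage of a residue string
#'
#' 100 * (G + C) / effective length, where the effective length excludes N.
#'
#' @param s Residue string, at least one non-N base.
#' @return Percentage in \[0, 100\].
#' @export
gc_percent <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  eff <- sum(v != "N")
  if (eff == 0L) {
    stop("GC percentage undefined: no non-N bases")
  }
  100 * sum(v == "G" | v == "C") / eff
}

# substring by 0-based half-open interval; returns "" for empty interval
seq_window <- function(s, start, end) {
  if (end <= start) return("")
  substr(s, start + 1L, end)
}

#' Extract flanking windows around a site
#'
#' Returns \code{up} nucleotides ending immediately 5' of the site and
#' \code{down} nucleotides starting immediately 3' of it, truncating at the
#' sequence boundaries. Truncation is legal and flagged, never an error:
#' sites near a UTR edge keep their (shorter) windows.
#'
#' @param seq Residue string.
#' @param start,end Site interval, 0-based half-open.
#' @param up,down Window lengths in nt.
#' @return List with \code{upstream}, \code{downstream} (strings, possibly
#'   empty) and \code{truncated_up}, \code{truncated_down} flags.
#' @export
window_extract <- function(seq, start, end, up, down) {
  n <- nchar(seq)
  stopifnot(start >= 0L, end > start, end <= n)
  us <- max(0L, start - up)
  de <- min(n, end + down)
  list(upstream = seq_window(seq, us, start),
       downstream = seq_window(seq, end, de),
       truncated_up = (start - up) < 0L,
       truncated_down = (end + down) > n)
}

#' Read a FASTA file into a named vector of canonical RNA strings
#'
#' Sequence ids are taken from the header up to the first whitespace and
#' must be unique. Sequences are normalized to the RNA alphabet (T -> U).
#'
#' @param path FASTA file path.
#' @return Named character vector of residue strings, input order preserved.
#' @export
load_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop("no records in FASTA: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate FASTA ids: ", paste(dup, collapse = ", "))
  }
  raw <- as.character(set)
  if (any(nchar(raw) == 0L)) {
    stop("empty sequence for id: ", ids[which(nchar(raw) == 0L)[1L]])
  }
  out <- vapply(raw, normalize_sequence, character(1L), USE.NAMES = FALSE)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of residue strings.
#' @param path Output path.
#' @param alphabet \code{"rna"} (default, as stored) or \code{"dna"}
#'   (U written back as T).
#' @export
write_fasta <- function(seqs, path, alphabet = c("rna", "dna")) {
  alphabet <- match.arg(alphabet)
  out <- seqs
  if (alphabet == "dna") out <- chartr("U", "T", out)
  set <- Biostrings::BStringSet(out)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, format = "fasta")
  invisible(path)
}

#' Read chimeric reads from FASTA or FASTQ
#'
#' Format is chosen by extension (\code{.fq}/\code{.fastq} -> FASTQ,
#' otherwise FASTA). Reads are normalized to the RNA alphabet.
#'
#' @param path Read file.
#' @return Named character vector of residue strings.
#' @export
load_reads <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  set <- Biostrings::readBStringSet(path, format = fmt)
  ids <- sub("\\s.*$", "", names(set))
  out <- vapply(as.character(set), normalize_sequence, character(1L),
                USE.NAMES = FALSE)
  names(out) <- ids
  out
}

#' Load a transcript set from FASTA plus a region table
#'
#' The FASTA holds one full transcript sequence per record
#' (5'-UTR + CDS + 3'-UTR concatenated); the region table is a TSV with
#' columns \code{transcript_id}, \code{gene_symbol}, \code{utr5_len},
#' \code{cds_len}, \code{utr3_len}. The three lengths must sum to the
#' FASTA sequence length.
#'
#' @param fasta_path Transcript FASTA.
#' @param region_path Region table TSV (header required).
#' @return A data.frame with columns \code{transcript_id},
#'   \code{gene_symbol}, \code{utr5}, \code{cds}, \code{utr3}
#'   (residue strings, possibly empty except \code{utr3}).
#' @export
load_transcripts <- function(fasta_path, region_path) {
  seqs <- load_fasta(fasta_path)
  reg <- read.delim(region_path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene_symbol", "utr5_len", "cds_len", "utr3_len")
  miss <- setdiff(need, names(reg))
  if (length(miss) > 0L) {
    stop("region table missing columns: ", paste(miss, collapse = ", "))
  }
  unknown <- setdiff(reg$transcript_id, names(seqs))
  if (length(unknown) > 0L) {
    stop("region table ids absent from FASTA: ",
         paste(head(unknown, 5L), collapse = ", "))
  }
  reg <- reg[match(names(seqs), reg$transcript_id), , drop = FALSE]
  if (anyNA(reg$transcript_id)) {
    stop("FASTA ids absent from region table")
  }
  tot <- reg$utr5_len + reg$cds_len + reg$utr3_len
  bad <- which(tot != nchar(seqs))
  if (length(bad) > 0L) {
    stop(sprintf("region lengths (%d) disagree with sequence length (%d) for %s",
                 tot[bad[1L]], nchar(seqs[bad[1L]]), reg$transcript_id[bad[1L]]))
  }
  data.frame(
    transcript_id = reg$transcript_id,
    gene_symbol = reg$gene_symbol,
    utr5 = substr(seqs, 1L, reg$utr5_len),
    cds = substr(seqs, reg$utr5_len + 1L, reg$utr5_len + reg$cds_len),
    utr3 = substr(seqs, reg$utr5_len + reg$cds_len + 1L, nchar(seqs)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write a transcript table back to FASTA + region TSV
#'
#' Inverse of \code{\link{load_transcripts}}.
#'
#' @param transcripts Transcript data.frame.
#' @param fasta_path,region_path Output paths.
#' @export
write_transcripts <- function(transcripts, fasta_path, region_path) {
  full <- paste0(transcripts$utr5, transcripts$cds, transcripts$utr3)
  names(full) <- transcripts$transcript_id
  write_fasta(full, fasta_path)
  reg <- data.frame(
    transcript_id = transcripts$transcript_id,
    gene_symbol = transcripts$gene_symbol,
    utr5_len = nchar(transcripts$utr5),
    cds_len = nchar(transcripts$cds),
    utr3_len = nchar(transcripts$utr3)
  )
  write.table(reg, region_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

# subclass lengths observed for human tRF series: tRF-3a 18 nt, tRF-3b 22 nt,
# tRF-5a 15 nt, tRF-5b 22 nt, tRF-5c 31 nt
trf_length_subclass <- function(trf_class, len) {
  if (trf_class == "tRF-3") {
    if (len == 18L) return("3a")
    if (len == 22L) return("3b")
  } else if (trf_class == "tRF-5") {
    if (len == 15L) return("5a")
    if (len == 22L) return("5b")
    if (len == 31L) return("5c")
  }
  "other"
}

#' Build a tRF catalog table
#'
#' @param ids Character vector of tRF ids.
#' @param sequences Residue strings, each at least 8 nt (the seed occupies
#'   positions 2-7 and position 8 must exist).
#' @param trf_class \code{"tRF-3"} or \code{"tRF-5"} per entry (recycled).
#' @return A data.frame with columns \code{trf_id}, \code{sequence},
#'   \code{trf_class}, \code{length_subclass}, \code{seed} (positions 2-7).
#' @export
trf_catalog <- function(ids, sequences, trf_class) {
  stopifnot(length(ids) == length(sequences))
  trf_class <- rep_len(trf_class, length(ids))
  stopifnot(all(trf_class %in% c("tRF-3", "tRF-5")))
  sequences <- vapply(sequences, normalize_sequence, character(1L),
                      USE.NAMES = FALSE)
  if (any(nchar(sequences) < 8L)) {
    stop("tRF sequences must be at least 8 nt (positions 1-8 must exist)")
  }
  if (anyDuplicated(ids)) stop("duplicate tRF ids")
  data.frame(
    trf_id = as.character(ids),
    sequence = sequences,
    trf_class = trf_class,
    length_subclass = mapply(trf_length_subclass, trf_class, nchar(sequences),
                             USE.NAMES = FALSE),
    seed = substr(sequences, 2L, 7L),
    stringsAsFactors = FALSE
  )
}

#' Load a tRF catalog from FASTA
#'
#' The tRF class is parsed from the record id or description: any record
#' whose header contains \code{tRF-3} (or \code{trf-3}, \code{tRF3}) is
#' tRF-3, likewise tRF-5. tRF-3 sequences are stored with their 3'-CCA
#' terminus, as mature catalog entries carry it.
#'
#' @param path FASTA path.
#' @return tRF catalog data.frame (see \code{\link{trf_catalog}}).
#' @export
load_trf_catalog <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  cls <- ifelse(grepl("tRF-?3", headers, ignore.case = TRUE), "tRF-3",
         ifelse(grepl("tRF-?5", headers, ignore.case = TRUE), "tRF-5", NA))
  if (anyNA(cls)) {
    stop("cannot infer tRF class (tRF-3/tRF-5) from header: ",
         headers[which(is.na(cls))[1L]])
  }
  trf_catalog(ids, as.character(set), cls)
}

# Watson-Crick complementarity test for single bases (no wobble)
wc_complement <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
  (a == "C" & b == "G") | (a == "G" & b == "C")
}
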