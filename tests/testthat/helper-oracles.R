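# Independent brute-force oracles used to verify the dynamic programs and
# scanners. These deliberately share no code with the package internals:
# duplexes and folds are scored by exhaustive enumeration over explicit
# pair sets with a face-based energy definition.

PAIR_OK <- c("AU", "UA", "CG", "GC", "GU", "UG")

pair_class <- function(x, y) {
  p <- paste0(x, y)
  if (p %in% c("CG", "GC")) return(0L)
  if (p %in% c("AU", "UA")) return(1L)
  if (p %in% c("GU", "UG")) return(2L)
  -1L
}

stack_e <- function(model, p, q) {
  if (p == 2L || q == 2L) return(model$stack_gu)
  c(model$stack_gc, model$stack_mixed, model$stack_au)[(p == 1L) + (q == 1L) + 1L]
}

# exhaustive minimum over all antiparallel non-crossing inter-strand
# matchings; ties resolved toward more pairs (as the implementation does)
oracle_duplex <- function(a, b, model) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  n <- length(av)
  m <- length(bv)
  env <- new.env()
  env$e <- 0
  env$c <- 0L
  rec <- function(i, lasti, lastj, lastp, e, cnt) {
    if (e < env$e || (e == env$e && cnt > env$c)) {
      env$e <- e
      env$c <- cnt
    }
    if (i > n) return(invisible())
    rec(i + 1L, lasti, lastj, lastp, e, cnt)
    jmax <- if (is.na(lastj)) m else lastj - 1L
    for (j in seq_len(jmax)) {
      p <- pair_class(av[i], bv[j])
      if (p < 0L) next
      add <- if (is.na(lasti)) 0 else if (i == lasti + 1L && j == lastj - 1L) {
        stack_e(model, lastp, p)
      } else model$loop_penalty
      rec(i + 1L, i, j, p, e + add, cnt + 1L)
    }
  }
  rec(1L, NA, NA, NA, 0, 0L)
  list(mfe = env$e, paired_count = env$c)
}

# enumerate all valid secondary structures (non-crossing, hairpin >= 3,
# optional blocked positions) as lists of pair matrices
enumerate_structures <- function(v, model, blocked = integer(0)) {
  n <- length(v)
  memo <- new.env()
  # structures over positions i..j as list of k x 2 matrices
  gen <- function(i, j) {
    if (j - i < 0L) return(list(matrix(integer(0), ncol = 2L)))
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- gen(i + 1L, j)  # i unpaired
    if (!(i %in% blocked) && i + model$min_hairpin + 1L <= j) {
      for (k in (i + model$min_hairpin + 1L):j) {
        if (k %in% blocked) next
        if (pair_class(v[i], v[k]) < 0L) next
        inner <- gen(i + 1L, k - 1L)
        outer_ <- gen(k + 1L, j)
        for (a in inner) for (b in outer_) {
          out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
        }
      }
    }
    memo[[key]] <- out
    out
  }
  if (n < 2L) return(list(matrix(integer(0), ncol = 2L)))
  gen(1L, n)
}

# face-based score: stack if the single directly-nested pair is (i+1, j-1),
# hairpin (no nested pair) free, any other loop one flat penalty
score_structure <- function(v, pairs, model) {
  if (nrow(pairs) == 0L) return(0)
  e <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]
    j <- pairs[r, 2L]
    inside <- pairs[pairs[, 1L] > i & pairs[, 2L] < j, , drop = FALSE]
    if (nrow(inside) == 0L) next  # hairpin face, free
    # direct children: pairs inside not enclosed by another inside pair
    encl <- vapply(seq_len(nrow(inside)), function(r2) {
      any(inside[, 1L] < inside[r2, 1L] & inside[, 2L] > inside[r2, 2L])
    }, logical(1L))
    ch <- inside[!encl, , drop = FALSE]
    if (nrow(ch) == 1L && ch[1L, 1L] == i + 1L && ch[1L, 2L] == j - 1L) {
      e <- e + stack_e(model,
                       pair_class(v[i], v[j]),
                       pair_class(v[i + 1L], v[j - 1L]))
    } else {
      e <- e + model$loop_penalty
    }
  }
  e
}

oracle_fold <- function(s, model, blocked = integer(0)) {
  v <- strsplit(s, "")[[1L]]
  structs <- enumerate_structures(v, model, blocked)
  best_e <- 0
  best_np <- 0L
  for (p in structs) {
    e <- score_structure(v, p, model)
    if (e < best_e || (e == best_e && nrow(p) < best_np)) {
      best_e <- e
      best_np <- nrow(p)
    }
  }
  list(energy = best_e, n_pairs = best_np)
}

# naive O(n*m) sliding-window scan for a motif (overlaps allowed)
oracle_scan <- function(s, motif) {
  n <- nchar(s)
  k <- nchar(motif)
  hits <- integer(0)
  if (n < k) return(hits)
  for (i in 0:(n - k)) {
    if (substr(s, i + 1L, i + k) == motif) hits <- c(hits, i)
  }
  hits
}

random_rna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# small fixed transcript/catalog fixture used across files
tiny_fixture <- function() {
  trfs <- trf_catalog(
    c("trf_a", "trf_b"),
    c("UGGUUCGAGUCCAAUUCG",          # seed GGUUCG -> match CGAACC
      "ACCCGGAUACGUAGGAUCGAAUCGAU"), # seed CCCGGA -> match UCCGGG
    c("tRF-3", "tRF-5"))
  transcripts <- data.frame(
    transcript_id = c("NM_000001", "NM_000002", "NM_000003"),
    gene_symbol = c("G1", "G2", "G3"),
    utr5 = c("ACGUACGU", "", "GGGG"),
    cds = c("AUGGCCUAA", "AUGUAA", "AUGAAAUAA"),
    utr3 = c(paste0(strrep("AGCU", 10), "CGAACC", strrep("UUAC", 10)),
             paste0(strrep("CAGU", 8), "UCCGGG", strrep("GAUC", 8)),
             strrep("ACGG", 15)),
    stringsAsFactors = FALSE)
  list(trfs = trfs, transcripts = transcripts)
}
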