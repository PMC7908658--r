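# Duplex stability and target-site accessibility. The default backend is a
# small self-contained stacking energy model whose dynamic programs are
# exactly testable against exhaustive enumeration; an adapter to the
# ViennaRNA command-line programs (RNAduplex / RNAfold) is provided for
# production parity.

#' Bundled RNA energy model
#'
#' Stacking energies per adjacent base-pair step, classified by the pairs
#' involved: both Watson-Crick G:C type, one A:U, both A:U, or any step
#' touching a G:U wobble. A flat penalty is charged per internal loop,
#' bulge or multiloop event; hairpin loops and exterior bases are free;
#' hairpins need at least \code{min_hairpin} unpaired bases. Units kcal/mol.
#'
#' @param stack_gc,stack_mixed,stack_au,stack_gu Stack energies (<= 0).
#' @param loop_penalty Penalty per loop event (>= 0).
#' @param min_hairpin Minimum hairpin loop size in nt.
#' @return A list usable as the \code{model} argument of the thermo
#'   functions.
#' @export
energy_model <- function(stack_gc = -3.0, stack_mixed = -2.0,
                         stack_au = -1.0, stack_gu = -0.5,
                         loop_penalty = 4.0, min_hairpin = 3L) {
  stopifnot(stack_gc <= 0, stack_mixed <= 0, stack_au <= 0, stack_gu <= 0,
            loop_penalty >= 0, min_hairpin >= 0)
  list(stack_gc = stack_gc, stack_mixed = stack_mixed, stack_au = stack_au,
       stack_gu = stack_gu, loop_penalty = loop_penalty,
       min_hairpin = as.integer(min_hairpin))
}

#' Load an energy model from a TSV of (key, value) rows
#'
#' @param path TSV with columns \code{key}, \code{value}.
#' @return Energy model list.
#' @export
load_energy_model <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  args <- as.list(setNames(tab$value, tab$key))
  do.call(energy_model, args)
}

#' Minimum free energy of an intermolecular tRF:target duplex
#'
#' Global minimum over all non-crossing antiparallel inter-strand pairings
#' (intramolecular pairing disallowed) of the sum of stack energies plus
#' one loop penalty per interior loop/bulge between consecutive pairs.
#' The empty pairing (0 kcal/mol) is always admissible, so the MFE is
#' never positive. Ties are broken toward more paired bases, then by a
#' fixed deterministic traceback.
#'
#' @param trf,target Residue strings (5'->3').
#' @param model Energy model (default \code{\link{energy_model}()}).
#' @return List: \code{mfe} (kcal/mol, <= 0), \code{paired_count} (tRF
#'   positions paired), \code{pairing_map} (data.frame of 1-based
#'   \code{trf_pos}, \code{target_pos}).
#' @export
#' @examples
#' duplex_mfe("GGGG", "CCCC")$mfe  # -9: three stacked G:C steps
duplex_mfe <- function(trf, target, model = energy_model()) {
  stopifnot(nchar(trf) >= 1L, nchar(target) >= 1L)
  r <- .duplex_mfe_cpp(trf, target, model)
  list(mfe = r$mfe, paired_count = r$paired_count,
       pairing_map = data.frame(trf_pos = r$trf_pos,
                                target_pos = r$target_pos))
}

#' Minimum-energy local secondary structure of a window
#'
#' Intramolecular fold without pseudoknots under the bundled model;
#' optionally a contiguous interval is forced unpaired (used for opening
#' energies). Among minimum-energy structures the one with fewest pairs is
#' returned, so isolated energy-neutral pairs never appear.
#'
#' @param window Residue string (length >= 6).
#' @param model Energy model.
#' @param forced_unpaired Optional 0-based half-open interval
#'   \code{c(start, end)} whose bases may not pair.
#' @return List: \code{structure} (dot-bracket string), \code{energy}
#'   (kcal/mol), \code{n_pairs}.
#' @export
local_fold <- function(window, model = energy_model(),
                       forced_unpaired = NULL) {
  if (nchar(window) < 6L) stop("fold window shorter than 6 nt")
  blocked <- integer(0)
  if (!is.null(forced_unpaired)) {
    stopifnot(length(forced_unpaired) == 2L,
              forced_unpaired[1L] < forced_unpaired[2L])
    blocked <- seq.int(forced_unpaired[1L] + 1L, forced_unpaired[2L])
  }
  .local_fold_cpp(window, model, as.integer(blocked))
}

#' Accessibility of a seed-match site in its local structural context
#'
#' Folds the window of 40 nt upstream + site + 40 nt downstream (truncated
#' at the UTR ends). Reports how many site bases and how many bases in the
#' +/-10 nt flanks are unpaired in the local MFE structure, and the opening
#' energy: the energy cost of forcing the site single-stranded
#' (constrained MFE minus unconstrained MFE, always >= 0).
#'
#' @param utr3 UTR residue string.
#' @param start,end Site interval, 0-based half-open.
#' @param model Energy model.
#' @param flank Fold window size on each side (default 40 nt).
#' @return List: \code{exposed_at_site} (0..site length),
#'   \code{exposed_flanks} (unpaired bases within +/-10 nt),
#'   \code{opening_energy} (kcal/mol, >= 0).
#' @export
accessibility_features <- function(utr3, start, end,
                                   model = energy_model(), flank = 40L) {
  n <- nchar(utr3)
  stopifnot(start >= 0L, end > start, end <= n)
  ws <- max(0L, start - flank)
  we <- min(n, end + flank)
  window <- seq_window(utr3, ws, we)
  site_rel <- c(start - ws, end - ws)  # 0-based within window
  free <- local_fold(window, model)
  cons <- local_fold(window, model, forced_unpaired = site_rel)
  dots <- strsplit(free$structure, "", fixed = TRUE)[[1L]] == "."
  site_idx <- seq.int(site_rel[1L] + 1L, site_rel[2L])
  fl_idx <- setdiff(seq.int(max(1L, site_rel[1L] - 9L),
                            min(nchar(window), site_rel[2L] + 10L)),
                    site_idx)
  opening <- cons$energy - free$energy
  list(exposed_at_site = sum(dots[site_idx]),
       exposed_flanks = sum(dots[fl_idx]),
       opening_energy = max(0, opening))
}

# --- ViennaRNA adapter -------------------------------------------------------

#' Duplex MFE via the ViennaRNA RNAduplex program
#'
#' External backend for production use; requires \code{RNAduplex} on the
#' PATH. Only the MFE and the paired span are parsed.
#'
#' @param trf,target Residue strings.
#' @return List with \code{mfe} (kcal/mol).
#' @export
duplex_mfe_vienna <- function(trf, target) {
  if (Sys.which("RNAduplex") == "") stop("RNAduplex not found on PATH")
  out <- system2("RNAduplex", input = c(trf, target), stdout = TRUE,
                 stderr = FALSE)
  m <- regmatches(out[1L], regexpr("\\(\\s*-?[0-9.]+\\s*\\)$", out[1L]))
  if (length(m) == 0L) stop("unparseable RNAduplex output: ", out[1L])
  list(mfe = as.numeric(gsub("[()\\s]", "", m, perl = TRUE)))
}

#' Local fold via the ViennaRNA RNAfold program
#'
#' @param window Residue string.
#' @return List with \code{structure}, \code{energy}.
#' @export
local_fold_vienna <- function(window) {
  if (Sys.which("RNAfold") == "") stop("RNAfold not found on PATH")
  out <- system2("RNAfold", args = "--noPS", input = window, stdout = TRUE,
                 stderr = FALSE)
  line <- out[2L]
  db <- sub("\\s.*$", "", line)
  m <- regmatches(line, regexpr("-?[0-9.]+(?=\\s*\\)$)", line, perl = TRUE))
  list(structure = db, energy = as.numeric(m))
}
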