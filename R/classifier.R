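# SVM site classifier with genetic-algorithm feature selection under
# fivefold cross-validation, transcript-level noisy-OR aggregation, and
# evaluation metrics.

# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# rank-based AUC of scores for binary labels (1 = positive)
fast_auc <- function(scores, labels) {
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sample the negative training set from the background
#'
#' Negatives are drawn from background sites on well-expressed 3'-UTR
#' isoforms: background pairs are ranked by their host transcript's 3P-seq
#' tag count, restricted to the top pool (twice the requested number,
#' extended through ties at the boundary), and the requested number
#' (ratio x positives) is sampled uniformly without replacement.
#'
#' @param background Background site data.frame.
#' @param tag_counts Named numeric vector: transcript_id -> 3P-seq tags
#'   (missing transcripts count 0).
#' @param n_positives Number of positive pairs.
#' @param ratio Negatives per positive (default 5).
#' @param seed RNG seed.
#' @return Sampled rows of \code{background}.
#' @export
sample_negatives <- function(background, tag_counts, n_positives,
                             ratio = 5L, seed = 1L) {
  n <- ratio * n_positives
  tags <- tag_counts[background$transcript_id]
  tags[is.na(tags)] <- 0
  if (nrow(background) <= n) {
    warning("background smaller than requested negatives; taking all")
    out <- background
    out$label <- "negative"
    return(out)
  }
  ord <- order(-tags, seq_len(nrow(background)))
  pool_n <- min(nrow(background), 2L * n)
  # extend the pool through ties at the tag-count boundary
  cut_tag <- tags[ord[pool_n]]
  while (pool_n < nrow(background) && tags[ord[pool_n + 1L]] == cut_tag) {
    pool_n <- pool_n + 1L
  }
  pool <- ord[seq_len(pool_n)]
  sel <- with_seed(seed, sample(pool, n))
  out <- background[sort(sel), , drop = FALSE]
  out$label <- "negative"
  rownames(out) <- NULL
  out
}

#' Stratified fold assignment for cross-validation
#'
#' Rows are shuffled within each label stratum and dealt cyclically onto
#' the folds, always filling the currently smallest folds first, so fold
#' sizes differ by at most one and each label's per-fold counts differ by
#' at most one. Deterministic per seed.
#'
#' @param labels Vector of row labels (any type).
#' @param k Number of folds (default 5).
#' @param seed RNG seed.
#' @return Integer vector of fold ids in 1..k, one per row.
#' @export
make_folds <- function(labels, k = 5L, seed = 1L) {
  n <- length(labels)
  stopifnot(n >= k)
  fold <- integer(n)
  counts <- integer(k)
  with_seed(seed, {
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      idx <- idx[sample.int(length(idx))]
      ordk <- order(counts, seq_len(k))
      f <- ordk[((seq_along(idx) - 1L) %% k) + 1L]
      fold[idx] <- f
      counts <- counts + tabulate(f, k)
    }
  })
  fold
}

# median-impute and z-scale test rows using parameters fitted on train rows
fit_preproc <- function(xtr) {
  med <- apply(xtr, 2L, median, na.rm = TRUE)
  med[is.na(med)] <- 0  # all-NA training column
  for (j in seq_len(ncol(xtr))) {
    xtr[is.na(xtr[, j]), j] <- med[j]
  }
  ctr <- colMeans(xtr)
  scl <- apply(xtr, 2L, sd)
  scl[scl == 0 | is.na(scl)] <- 1
  list(median = med, center = ctr, scale = scl,
       xtr = sweep(sweep(xtr, 2L, ctr), 2L, scl, "/"))
}

apply_preproc <- function(x, pp) {
  for (j in seq_len(ncol(x))) {
    x[is.na(x[, j]), j] <- pp$median[j]
  }
  sweep(sweep(x, 2L, pp$center), 2L, pp$scale, "/")
}

# decision-value scores of an SVM on test rows, oriented so that larger
# means more positive-like (orientation fixed on the *training* rows)
svm_fold_scores <- function(xtr, ytr, xte, cost, gamma) {
  fit <- e1071::svm(xtr, factor(ytr, levels = c(0L, 1L)), kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
  dtr <- attr(predict(fit, xtr, decision.values = TRUE), "decision.values")[, 1L]
  flip <- mean(dtr[ytr == 1L]) < mean(dtr[ytr == 0L])
  dte <- attr(predict(fit, xte, decision.values = TRUE), "decision.values")[, 1L]
  if (flip) -dte else dte
}

# mean held-out AUC of an RBF SVM over the folds for one feature mask
cv_mask_fitness <- function(x, y, folds, mask, cost = 1, gamma = NULL) {
  cols <- which(mask)
  if (length(cols) == 0L) return(0)
  g <- if (is.null(gamma)) 1 / length(cols) else gamma
  aucs <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    pp <- fit_preproc(x[tr, cols, drop = FALSE])
    xte <- apply_preproc(x[!tr, cols, drop = FALSE], pp)
    sc <- svm_fold_scores(pp$xtr, y[tr], xte, cost, g)
    fast_auc(sc, y[!tr])
  }, numeric(1L))
  mean(aucs, na.rm = TRUE)
}

#' Genetic-algorithm configuration
#'
#' Defaults mirror the published training setup: 10,000 iterations
#' (generations) with crossover and mutation probabilities of 10% and 30%.
#' The canonical GA internals are a population of 50 bitmasks, tournament
#' selection (size 3), single-elite survival, uniform crossover applied
#' with probability \code{crossover_prob}, and per-bit flips at
#' \code{mutation_prob}. Scale \code{generations} down for small studies.
#'
#' @param generations Number of GA generations.
#' @param crossover_prob Probability a selected pair is recombined.
#' @param mutation_prob Per-bit flip probability.
#' @param population Population size.
#' @param tournament Tournament size.
#' @param elitism Number of elites copied unchanged.
#' @param seed RNG seed.
#' @return Config list.
#' @export
ga_config <- function(generations = 10000L, crossover_prob = 0.10,
                      mutation_prob = 0.30, population = 50L,
                      tournament = 3L, elitism = 1L, seed = 1L) {
  stopifnot(crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            population >= 2L, generations >= 1L)
  list(generations = as.integer(generations),
       crossover_prob = crossover_prob, mutation_prob = mutation_prob,
       population = as.integer(population),
       tournament = as.integer(tournament),
       elitism = as.integer(elitism), seed = as.integer(seed))
}

#' Select features with a genetic algorithm
#'
#' Evolves a population of feature bitmasks; the fitness of a mask is the
#' mean held-out AUC of an RBF SVM over the supplied cross-validation
#' folds. All-zero candidates are repaired by switching one random bit on.
#' Fitness values are cached per mask, and the best mask ever seen is
#' returned (elitism makes the best fitness non-decreasing).
#'
#' @param x Feature matrix (may contain NA; imputation is per fold).
#' @param y Binary labels (1 positive, 0 negative).
#' @param folds Fold assignment from \code{\link{make_folds}}.
#' @param cfg \code{\link{ga_config}} list.
#' @param cost,gamma SVM hyperparameters used inside the fitness
#'   (\code{gamma = NULL} means 1 / n selected features).
#' @return List: \code{mask} (named logical), \code{fitness} (its mean
#'   held-out AUC), \code{history} (best fitness per generation).
#' @export
ga_select_features <- function(x, y, folds, cfg = ga_config(),
                               cost = 1, gamma = NULL) {
  p <- ncol(x)
  stopifnot(p >= 1L, length(unique(y)) == 2L)
  if (p == 1L) {
    m <- setNames(TRUE, colnames(x))
    return(list(mask = m,
                fitness = cv_mask_fitness(x, y, folds, m, cost, gamma),
                history = numeric(0)))
  }
  cache <- new.env(parent = emptyenv())
  evals <- function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    v <- cv_mask_fitness(x, y, folds, mask, cost, gamma)
    cache[[key]] <- v
    v
  }
  repair <- function(mask) {
    if (!any(mask)) mask[sample.int(p, 1L)] <- TRUE
    mask
  }
  with_seed(cfg$seed, {
    pop <- lapply(seq_len(cfg$population),
                  function(i) repair(runif(p) < 0.5))
    fit <- vapply(pop, evals, numeric(1L))
    history <- numeric(cfg$generations)
    for (g in seq_len(cfg$generations)) {
      ord <- order(-fit)
      newpop <- pop[ord[seq_len(cfg$elitism)]]
      while (length(newpop) < cfg$population) {
        pick <- function() {
          cand <- sample.int(cfg$population, cfg$tournament)
          cand[which.max(fit[cand])]
        }
        p1 <- pop[[pick()]]
        p2 <- pop[[pick()]]
        if (runif(1L) < cfg$crossover_prob) {
          take <- runif(p) < 0.5
          c1 <- ifelse(take, p1, p2)
          c2 <- ifelse(take, p2, p1)
        } else {
          c1 <- p1
          c2 <- p2
        }
        for (child in list(c1, c2)) {
          flip <- runif(p) < cfg$mutation_prob
          child <- xor(child, flip)
          newpop[[length(newpop) + 1L]] <- repair(child)
          if (length(newpop) == cfg$population) break
        }
      }
      pop <- newpop
      fit <- vapply(pop, evals, numeric(1L))
      history[g] <- max(fit)
    }
  })
  best <- ls(cache)
  vals <- vapply(best, function(k) cache[[k]], numeric(1L))
  key <- best[which.max(vals)]
  mask <- strsplit(key, "", fixed = TRUE)[[1L]] == "1"
  names(mask) <- colnames(x)
  list(mask = mask, fitness = max(vals), history = history)
}

#' Train the fivefold cross-validated SVM site classifier
#'
#' Per fold: missing values are imputed with the training-fold column
#' medians, features are centered and scaled on the training fold only,
#' and an RBF SVM with probability calibration is fitted. Held-out
#' probabilities are recorded for every row (each row is tested exactly
#' once); prediction averages the five fold models.
#'
#' @param x Feature matrix.
#' @param y Binary labels (1 positive, 0 negative).
#' @param mask Named logical feature mask (default: all features).
#' @param folds Fold assignment (default: \code{\link{make_folds}} with
#'   \code{seed}).
#' @param seed Seed for the default fold assignment.
#' @param cost,gamma SVM hyperparameters (\code{gamma = NULL}: 1 / n
#'   selected features).
#' @param tune Grid-search \code{cost} and \code{gamma} on the training
#'   folds (coarse grid over \code{2^(-3..7)} and \code{2^(-7..3)}) before
#'   the final per-fold fits.
#' @return Object of class \code{trf_svm_model}: per-fold models with
#'   preprocessing parameters, the mask, held-out probabilities, and
#'   per-fold train/test AUC.
#' @export
train_cv_svm <- function(x, y, mask = NULL, folds = NULL, seed = 1L,
                         cost = 1, gamma = NULL, tune = FALSE) {
  stopifnot(all(y %in% c(0L, 1L)), length(y) == nrow(x))
  if (is.null(mask)) mask <- setNames(rep(TRUE, ncol(x)), colnames(x))
  stopifnot(any(mask))
  if (is.null(folds)) folds <- make_folds(y, 5L, seed)
  cols <- which(mask)
  g <- if (is.null(gamma)) 1 / length(cols) else gamma
  if (tune) {
    grid <- expand.grid(cost = 2^seq(-3, 7, by = 2),
                        gamma = 2^seq(-7, 3, by = 2))
    fitn <- vapply(seq_len(nrow(grid)), function(i) {
      cv_mask_fitness(x, y, folds, mask, grid$cost[i], grid$gamma[i])
    }, numeric(1L))
    cost <- grid$cost[which.max(fitn)]
    g <- grid$gamma[which.max(fitn)]
  }
  kf <- sort(unique(folds))
  heldout <- rep(NA_real_, nrow(x))
  fold_models <- vector("list", length(kf))
  auc_train <- auc_test <- numeric(length(kf))
  for (f in kf) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) {
      stop("degenerate single-class fold; use stratified folds")
    }
    pp <- fit_preproc(x[tr, cols, drop = FALSE])
    xte <- apply_preproc(x[!tr, cols, drop = FALSE], pp)
    fit <- with_seed(seed + f, e1071::svm(
      pp$xtr, factor(y[tr], levels = c(0L, 1L)), kernel = "radial",
      cost = cost, gamma = g, probability = TRUE, scale = FALSE))
    ptr <- attr(predict(fit, pp$xtr, probability = TRUE),
                "probabilities")[, "1"]
    pte <- attr(predict(fit, xte, probability = TRUE),
                "probabilities")[, "1"]
    heldout[!tr] <- pte
    auc_train[f] <- fast_auc(ptr, y[tr])
    auc_test[f] <- fast_auc(pte, y[!tr])
    fold_models[[f]] <- list(svm = fit, preproc = pp[c("median", "center",
                                                       "scale")])
  }
  structure(list(
    selected_mask = mask, fold_models = fold_models,
    fold_assignment = folds, heldout = heldout,
    auc_train = auc_train, auc_test = auc_test,
    cost = cost, gamma = g,
    feature_names = colnames(x)[cols],
    registry_version = REGISTRY_VERSION
  ), class = "trf_svm_model")
}

#' @export
print.trf_svm_model <- function(x, ...) {
  cat("Fivefold SVM site classifier\n")
  cat(sprintf("  features selected: %d / %d\n", sum(x$selected_mask),
              length(x$selected_mask)))
  cat(sprintf("  held-out AUC per fold: %s (mean %.3f)\n",
              paste(sprintf("%.3f", x$auc_test), collapse = " "),
              mean(x$auc_test)))
  invisible(x)
}

#' Save / load a trained model archive
#'
#' @param model \code{trf_svm_model} object.
#' @param path Archive path (RDS).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trf_svm_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "trf_svm_model")) stop("not a trftargets model: ", path)
  if (!identical(model$registry_version, REGISTRY_VERSION)) {
    stop("model registry version ", model$registry_version,
         " does not match installed registry ", REGISTRY_VERSION)
  }
  model
}

#' Per-site positive probability
#'
#' The mean of the five calibrated fold-model probabilities for each row
#' of the feature matrix.
#'
#' @param model \code{trf_svm_model}.
#' @param x Feature matrix covering the masked feature columns.
#' @return Numeric vector of site probabilities in \[0, 1\].
#' @export
predict_site <- function(model, x) {
  cols <- model$feature_names
  miss <- setdiff(cols, colnames(x))
  if (length(miss) > 0L) {
    stop("feature matrix lacks masked features: ",
         paste(head(miss, 5L), collapse = ", "))
  }
  xs <- x[, cols, drop = FALSE]
  probs <- vapply(model$fold_models, function(fm) {
    xi <- apply_preproc(xs, fm$preproc)
    attr(predict(fm$svm, xi, probability = TRUE), "probabilities")[, "1"]
  }, numeric(nrow(xs)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  rowMeans(probs)
}

#' Combine site probabilities into a transcript-level prediction
#'
#' Sites are assumed to act independently, so the probability that at
#' least one site is functional is the noisy-OR
#' P = 1 - prod(1 - p_i). A transcript is called a target when P > 0.5
#' (strictly).
#'
#' @param p_sites Numeric vector of per-site probabilities (length >= 1).
#' @return List: \code{n}, \code{P}, \code{is_target}.
#' @export
#' @examples
#' aggregate_transcript(c(0.5, 0.5))  # P = 0.75, target
aggregate_transcript <- function(p_sites) {
  stopifnot(length(p_sites) >= 1L, all(p_sites >= 0 & p_sites <= 1))
  P <- 1 - prod(1 - p_sites)
  list(n = length(p_sites), P = P, is_target = P > 0.5)
}

#' Transcript predictions for a scored site table
#'
#' @param pairs Site data.frame with \code{trf_id}, \code{transcript_id}.
#' @param p_sites Per-site probabilities aligned with \code{pairs}.
#' @return data.frame \code{trf_id}, \code{transcript_id}, \code{n_sites},
#'   \code{P}, \code{is_target}, one row per (tRF, transcript).
#' @export
predict_transcripts <- function(pairs, p_sites) {
  stopifnot(nrow(pairs) == length(p_sites))
  key <- paste(pairs$trf_id, pairs$transcript_id, sep = "\r")
  out <- lapply(split(seq_along(key), key), function(idx) {
    agg <- aggregate_transcript(p_sites[idx])
    data.frame(trf_id = pairs$trf_id[idx[1L]],
               transcript_id = pairs$transcript_id[idx[1L]],
               n_sites = agg$n, P = agg$P, is_target = agg$is_target,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(-res$P), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity = TP / (TP + FN), specificity = TN / (TN + FP), and the
#' Matthews correlation coefficient
#' (TP * TN - FP * FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), in \[-1, 1\].
#' A metric whose denominator vanishes is NA (flagged undefined), never an
#' error.
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return List: \code{sensitivity}, \code{specificity}, \code{mcc}.
#' @export
evaluate_confusion <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den)
  } else NA_real_
  list(sensitivity = sens, specificity = spec, mcc = mcc)
}

#' Compare feature distributions between positives and background
#'
#' Two-sided two-sample Student's t-test (pooled variance) per feature,
#' producing a table of group means and P-values in registry (category)
#' order. Features with zero pooled variance or fewer than two values in
#' either group get NA.
#'
#' @param pos_matrix,bg_matrix Feature matrices with identical columns.
#' @param registry Feature registry (default: active registry).
#' @return data.frame \code{feature}, \code{family}, \code{mean_pos},
#'   \code{mean_bg}, \code{t}, \code{p_value}.
#' @export
compare_feature_distributions <- function(pos_matrix, bg_matrix,
                                          registry = feature_registry()) {
  registry <- registry[registry$name %in% colnames(pos_matrix), ,
                       drop = FALSE]
  rows <- lapply(seq_len(nrow(registry)), function(i) {
    f <- registry$name[i]
    a <- pos_matrix[, f]
    b <- bg_matrix[, f]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    tt <- if (length(a) >= 2L && length(b) >= 2L &&
              (var(a) > 0 || var(b) > 0)) {
      t.test(a, b, var.equal = TRUE)
    } else NULL
    data.frame(feature = f, family = registry$family[i],
               mean_pos = if (length(a)) mean(a) else NA_real_,
               mean_bg = if (length(b)) mean(b) else NA_real_,
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p_value = if (is.null(tt)) NA_real_ else tt$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
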