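make_toy_data <- function(n_per_class = 60, n_noise = 9, effect = 2,
                          seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  y <- rep(c(1L, 0L), each = n_per_class)
  x <- matrix(rnorm(n * (n_noise + 1)), n,
              dimnames = list(NULL, c("informative",
                                      paste0("noise", seq_len(n_noise)))))
  x[, "informative"] <- x[, "informative"] + effect * y
  list(x = x, y = y)
}

test_that("negative sampling draws from the top 3P-seq pool, deterministically", {
  set.seed(91)
  bg <- data.frame(trf_id = "t",
                   transcript_id = paste0("NM_", 1:1000),
                   start = 10, end = 16, stringsAsFactors = FALSE)
  tags <- setNames(rpois(1000, 30), bg$transcript_id)
  neg <- sample_negatives(bg, tags, n_positives = 20, ratio = 5, seed = 3)
  expect_equal(nrow(neg), 100)
  expect_true(all(neg$label == "negative"))
  neg2 <- sample_negatives(bg, tags, n_positives = 20, ratio = 5, seed = 3)
  expect_identical(neg, neg2)
  # top-pool rule pushes the sampled tag counts above the background median
  expect_gte(median(tags[neg$transcript_id]), median(tags))
  # background smaller than request: take all with a warning
  expect_warning(
    small <- sample_negatives(bg[1:30, ], tags, n_positives = 20, ratio = 5),
    "taking all")
  expect_equal(nrow(small), 30)
})

test_that("fold assignment is stratified, balanced and exhaustive", {
  y <- rep(c(1L, 0L), c(547, 2000))
  f <- make_folds(y, 5, seed = 2)
  expect_equal(sort(as.integer(table(f)), decreasing = TRUE),
               c(510L, 510L, 509L, 509L, 509L))
  expect_equal(length(f), 2547)
  expect_true(all(f %in% 1:5))
  # label balance within one item per fold
  pos_per_fold <- table(f[y == 1L])
  expect_lte(diff(range(pos_per_fold)), 1)
  expect_identical(make_folds(y, 5, seed = 2), f)
})

test_that("cross-validated SVM separates separable data and records held-out rows", {
  d <- make_toy_data(effect = 4, seed = 5)
  folds <- make_folds(d$y, 5, seed = 5)
  m <- train_cv_svm(d$x, d$y, folds = folds, seed = 5)
  expect_gte(mean(m$auc_test), 0.99)
  expect_false(anyNA(m$heldout))  # every row tested exactly once
  expect_true(all(m$heldout >= 0 & m$heldout <= 1))
})

test_that("label permutation drives the held-out AUC to chance", {
  d <- make_toy_data(effect = 4, seed = 6)
  aucs <- vapply(1:10, function(s) {
    set.seed(s)
    yp <- sample(d$y)
    m <- train_cv_svm(d$x, yp, folds = make_folds(yp, 5, s), seed = s)
    mean(m$auc_test)
  }, numeric(1))
  expect_gte(mean(aucs), 0.40)
  expect_lte(mean(aucs), 0.60)
})

test_that("test-fold rows never influence the preprocessing parameters", {
  d <- make_toy_data(seed = 7)
  folds <- make_folds(d$y, 5, seed = 7)
  m1 <- train_cv_svm(d$x, d$y, folds = folds, seed = 7)
  # corrupt the test rows of fold 1 grossly; fold-1 model must not change
  x2 <- d$x
  x2[folds == 1, ] <- x2[folds == 1, ] + 1000
  m2 <- train_cv_svm(x2, d$y, folds = folds, seed = 7)
  expect_identical(m1$fold_models[[1]]$preproc,
                   m2$fold_models[[1]]$preproc)
})

test_that("GA selection finds an implanted informative feature", {
  hits <- vapply(1:6, function(s) {
    d <- make_toy_data(n_per_class = 40, n_noise = 9, effect = 2, seed = s)
    folds <- make_folds(d$y, 3, seed = s)
    ga <- ga_select_features(d$x, d$y, folds,
                             ga_config(generations = 6, population = 16,
                                       seed = s))
    ga$mask[["informative"]]
  }, logical(1))
  expect_gte(sum(hits), 5)
})

test_that("GA degenerate and monotone contracts hold", {
  d <- make_toy_data(n_per_class = 30, seed = 9)
  folds <- make_folds(d$y, 3, seed = 9)
  # single-feature input returns that feature
  x1 <- d$x[, "informative", drop = FALSE]
  ga1 <- ga_select_features(x1, d$y, folds, ga_config(generations = 2))
  expect_true(ga1$mask[["informative"]])
  # returned mask at least as fit as the all-ones mask
  ga <- ga_select_features(d$x, d$y, folds,
                           ga_config(generations = 4, population = 12,
                                     seed = 9))
  all_ones <- setNames(rep(TRUE, ncol(d$x)), colnames(d$x))
  f_all <- trftargets:::cv_mask_fitness(d$x, d$y, folds, all_ones)
  expect_gte(ga$fitness, f_all)
})

test_that("site probabilities average the five folds and stay in range", {
  d <- make_toy_data(effect = 3, seed = 11)
  m <- train_cv_svm(d$x, d$y, seed = 11)
  p <- predict_site(m, d$x)
  expect_true(all(p >= 0 & p <= 1))
  # per-fold probabilities bracket the mean
  per_fold <- sapply(m$fold_models, function(fm) {
    xi <- trftargets:::apply_preproc(d$x[, m$feature_names, drop = FALSE],
                                     fm$preproc)
    attr(predict(fm$svm, xi, probability = TRUE), "probabilities")[, "1"]
  })
  expect_true(all(p >= apply(per_fold, 1, min) - 1e-12))
  expect_true(all(p <= apply(per_fold, 1, max) + 1e-12))
  expect_gte(trftargets:::fast_auc(p, d$y), 0.95)
  # identical inputs give identical probabilities
  expect_identical(p, predict_site(m, d$x))
})

test_that("model archive round-trips and checks the registry version", {
  d <- make_toy_data(seed = 13)
  m <- train_cv_svm(d$x, d$y, seed = 13)
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(predict_site(m, d$x), predict_site(m2, d$x))
  bad <- m
  bad$registry_version <- "other-registry"
  saveRDS(bad, f)
  expect_error(load_model(f), "registry version")
})

test_that("noisy-OR aggregation is monotone and matches direct evaluation", {
  expect_equal(aggregate_transcript(0.5)$P, 0.5)
  expect_false(aggregate_transcript(0.5)$is_target)  # strict > 0.5
  a <- aggregate_transcript(c(0.5, 0.5))
  expect_equal(a$P, 0.75)
  expect_true(a$is_target)
  expect_equal(aggregate_transcript(c(0.9, 0.2))$P, 0.92)
  # adding a site never decreases P
  set.seed(15)
  for (i in 1:20) {
    p <- runif(sample(1:6, 1))
    P1 <- aggregate_transcript(p)$P
    P2 <- aggregate_transcript(c(p, runif(1)))$P
    expect_gte(P2, P1)
    expect_gte(P1, max(p))
    expect_lte(P2, 1)
  }
  expect_error(aggregate_transcript(numeric(0)))
})

test_that("confusion metrics match the closed-form definitions", {
  m <- evaluate_confusion(5, 5, 0, 0)
  expect_equal(unlist(m), c(sensitivity = 1, specificity = 1, mcc = 1))
  m2 <- evaluate_confusion(tp = 2, tn = 3, fp = 1, fn = 4)
  expect_equal(m2$mcc, 2 / sqrt(504))
  expect_equal(m2$sensitivity, 2 / 6)
  expect_equal(m2$specificity, 3 / 4)
  # degenerate all-positive calls: specificity 0, MCC undefined
  m3 <- evaluate_confusion(tp = 5, tn = 0, fp = 5, fn = 0)
  expect_equal(m3$specificity, 0)
  expect_true(is.na(m3$mcc))
})

test_that("feature comparison reproduces the pooled-variance t-test", {
  x <- matrix(c(1, 2, 3, 4), ncol = 1, dimnames = list(NULL, "pos8_match"))
  yv <- matrix(c(3, 4, 5, 6), ncol = 1, dimnames = list(NULL, "pos8_match"))
  tab <- compare_feature_distributions(x, yv)
  expect_equal(tab$t, -2.19089, tolerance = 1e-5)
  expect_equal(tab$mean_pos, 2.5)
  # identical groups: t = 0, p ~ 1
  tab2 <- compare_feature_distributions(x, x)
  expect_equal(tab2$t, 0)
  expect_equal(tab2$p_value, 1)
})

test_that("internal AUC agrees with the pROC reference", {
  set.seed(17)
  y <- rbinom(200, 1, 0.4)
  s <- rnorm(200) + y
  a1 <- trftargets:::fast_auc(s, y)
  a2 <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                       direction = "<")))
  expect_equal(a1, a2, tolerance = 1e-12)
})
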