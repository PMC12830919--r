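eye_df <- function(n_single, n_double = 0, labels = NULL) {
  pid <- c(sprintf("S%03d", seq_len(n_single)),
           rep(sprintf("D%03d", seq_len(n_double)), each = 2))
  if (is.null(labels))
    labels <- rep(c("healthy", "glaucoma"), length.out = n_single + n_double)
  lab <- c(labels[seq_len(n_single)],
           rep(labels[n_single + seq_len(n_double)], each = 2))
  data.frame(patient_id = pid, label = lab)
}

test_that("grouped split: exact proportions, grouping, determinism", {
  df <- eye_df(100)
  sp <- grouped_split(df, seed = 3)
  sizes <- tapply(sp$n_eyes, sp$set, sum)
  expect_equal(as.vector(sizes[c("train", "validation", "test")]),
               c(60, 20, 20))
  expect_identical(grouped_split(df, seed = 3), sp)
  expect_false(identical(grouped_split(df, seed = 4)$set, sp$set))

  df2 <- eye_df(40, n_double = 30)
  sp2 <- grouped_split(df2, seed = 1)
  # every eye of a patient shares its patient's set, by construction:
  # one row per patient with its full eye count
  expect_identical(sort(unique(df2$patient_id)), sort(sp2$patient_id))
  expect_false(any(duplicated(sp2$patient_id)))
  # both classes present in every set
  expect_true(all(table(sp2$set, sp2$label) > 0))
})

test_that("grouped split errors on impossible cohorts", {
  expect_error(grouped_split(eye_df(4)), "3 patients")
})

test_that("grouped folds balance eyes and never split patients", {
  df <- eye_df(40, n_double = 20)
  sp <- grouped_split(df, seed = 2)
  nontest <- sp[sp$set != "test", ]
  folds <- grouped_folds(nontest, k = 10, seed = 7)
  expect_length(folds, nrow(nontest))
  eyes_per_fold <- tapply(nontest$n_eyes, folds[nontest$patient_id], sum)
  expect_lte(max(eyes_per_fold) - min(eyes_per_fold), 3)
  expect_identical(folds, grouped_folds(nontest, k = 10, seed = 7))
})

test_that("auroc matches the brute-force pair oracle, including ties", {
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), positive = 1), 0.75)
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1), positive = 1), 1.0)
  expect_equal(auroc(rep(1, 10), rep(c(0, 1), 5), positive = 1), 0.5)
  for (s in 1:100) {
    set.seed(s)
    n <- sample(6:30, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    pos <- runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    expect_equal(auroc(scores, pos), auroc_oracle(scores, pos),
                 tolerance = 1e-12)
  }
  expect_error(auroc(1:3, c(1, 1, 1), positive = 1), "both classes")
})

test_that("auroc is invariant under strictly increasing transforms", {
  set.seed(6)
  scores <- rnorm(40)
  pos <- runif(40) < 0.4
  a0 <- auroc(scores, pos)
  expect_equal(auroc(exp(scores), pos), a0)
  expect_equal(auroc(3 * scores - 7, pos), a0)
  expect_equal(auroc(rank(scores), pos), a0)
})

test_that("classification metrics follow the confusion-matrix formulas", {
  truth <- c(rep(TRUE, 4), rep(FALSE, 6))
  pred <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  m <- classification_metrics(pred, truth)   # TP=3 FN=1 TN=4 FP=2
  expect_equal(unname(m["sensitivity"]), 0.75)
  expect_equal(unname(m["specificity"]), 2 / 3)
  expect_equal(unname(m["f1"]), 6 / 9)
  perfect <- classification_metrics(truth, truth)
  expect_equal(unname(perfect), c(1, 1, 1))
  all_pos <- classification_metrics(rep(TRUE, 10), truth)
  expect_equal(unname(all_pos["sensitivity"]), 1)
  expect_equal(unname(all_pos["specificity"]), 0)
  expect_error(classification_metrics(pred, rep(TRUE, 10)), "both classes")
})

test_that("cross-validation selects the separating feature set", {
  set.seed(20)
  n <- 60
  y <- rep(c("glaucoma", "healthy"), n / 2)
  x <- cbind(sep = ifelse(y == "glaucoma", 1, -1) * (1 + runif(n)),
             noise = rnorm(n))
  folds <- rep(1:5, length.out = n)
  res <- cross_validate_method(x, y, folds, compact_svm_grid())
  expect_s3_class(res, "cv_result")
  expect_equal(unname(res$mean["auroc"]), 1.0)
  expect_true(all(res$fold_metrics$auroc == 1))
})

test_that("a single-config grid is selected as-is and test metrics appear", {
  set.seed(21)
  n <- 40
  y <- rep(c("glaucoma", "healthy"), n / 2)
  x <- matrix(rnorm(2 * n), n, 2) + ifelse(y == "glaucoma", 1.5, 0)
  grid <- list(svm_config("linear", C = 1))
  res <- cross_validate_method(x[1:30, ], y[1:30], rep(1:3, 10), grid,
                               test_x = x[31:40, ], test_y = y[31:40])
  expect_identical(res$config, grid[[1]])
  expect_length(res$grid_mean_val_auroc, 1L)
  expect_true(all(res$test >= 0 & res$test <= 1))
})

test_that("label-permuted features give chance-level validation AUROC", {
  set.seed(22)
  aucs <- numeric(20)
  for (s in 1:20) {
    set.seed(400 + s)
    n <- 50
    x <- matrix(rnorm(4 * n), n, 4)
    y <- sample(rep(c("glaucoma", "healthy"), n / 2))   # no signal
    folds <- sample(rep(1:5, length.out = n))
    res <- cross_validate_method(x, y, folds,
                                 list(svm_config("linear", C = 1),
                                      svm_config("rbf", C = 1)))
    aucs[s] <- res$mean["auroc"]
  }
  expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs))
})

test_that("single-class folds are rejected with a clear message", {
  x <- matrix(rnorm(20), 10, 2)
  y <- rep(c("glaucoma", "healthy"), each = 5)
  folds <- rep(1:2, each = 5)        # fold 1 all glaucoma
  expect_error(cross_validate_method(x, y, folds,
                                     list(svm_config("linear"))),
               "single class")
})

test_that("the full experiment is leakage-free and reproducible", {
  cfg <- test_cohort_config(n_patients = 30, seed = 19)
  coh <- generate_cohort(cfg)
  feats <- cohort_features(coh)
  grid <- list(svm_config("linear", C = 1), svm_config("rbf", C = 1))
  ex1 <- run_full_experiment(coh, features = feats, grid = grid, k = 5,
                             seed = 2)
  ex2 <- run_full_experiment(coh, features = feats, grid = grid, k = 5,
                             seed = 2)
  expect_identical(results_table(ex1), results_table(ex2))
  expect_identical(ex1$manifest, ex2$manifest)
  expect_named(ex1$results, names(feats$methods))

  # no patient spans sets; no test patient appears in any fold
  sp <- ex1$split
  expect_false(any(duplicated(sp$patient_id)))
  test_pats <- sp$patient_id[sp$set == "test"]
  expect_length(intersect(names(ex1$folds), test_pats), 0L)
  # folds cover exactly the non-test patients
  expect_setequal(names(ex1$folds), sp$patient_id[sp$set != "test"])

  # ANOVA and pairwise table share the six methods
  expect_equal(ex1$pairwise$n_pairs, 15)
  expect_equal(nrow(ex1$pairwise$pairs), 15)

  # results CSVs and manifest are bit-identical across reruns
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_results_csv(ex1, d1)
  write_results_csv(ex2, d2)
  for (f in c("metrics.csv", "pairwise.csv", "manifest.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})
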