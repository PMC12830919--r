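#' Patient-grouped train/validation/test split
#'
#' Assigns whole patients (never single eyes) to the train, validation and
#' test sets, stratified by diagnosis at the patient level, targeting the
#' given eye-count proportions. Assignment is a greedy largest-deficit fill
#' over randomly ordered patients within each class, which reproduces exact
#' proportions whenever the cohort allows them.
#'
#' @param eyes an `octa_cohort` or a data.frame with columns `patient_id` and
#'   `label` (one row per eye).
#' @param ratios named numeric `c(train, validation, test)` summing to 1.
#' @param seed RNG seed for the patient shuffling.
#' @return a `split_assignment`: data.frame with one row per patient
#'   (`patient_id`, `label`, `n_eyes`, `set`) plus attribute `seed`.
#' @export
grouped_split <- function(eyes, ratios = c(train = 0.6, validation = 0.2,
                                           test = 0.2), seed = 1L) {
  df <- if (inherits(eyes, "octa_cohort")) cohort_table(eyes) else eyes
  stopifnot(all(c("patient_id", "label") %in% names(df)))
  if (abs(sum(ratios) - 1) > 1e-8 || length(ratios) != 3L)
    stop("`ratios` must be three proportions summing to 1", call. = FALSE)
  sets <- c("train", "validation", "test")
  pat <- stats::aggregate(list(n_eyes = df$patient_id),
                          by = list(patient_id = df$patient_id,
                                    label = df$label), FUN = length)
  for (lb in unique(pat$label))
    if (sum(pat$label == lb) < 3L)
      stop("need at least 3 patients per class", call. = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)

  pat$set <- NA_character_
  for (lb in sort(unique(pat$label))) {
    idx <- which(pat$label == lb)
    idx <- idx[sample.int(length(idx))]
    deficit <- ratios * sum(pat$n_eyes[idx])
    names(deficit) <- sets
    for (i in idx) {
      s <- sets[which.max(deficit)]      # ties resolve train > validation > test
      pat$set[i] <- s
      deficit[s] <- deficit[s] - pat$n_eyes[i]
    }
  }
  for (s in sets) {
    if (length(unique(pat$label[pat$set == s])) < 2L)
      stop(sprintf("cohort too small: set '%s' lacks one class", s),
           call. = FALSE)
  }
  structure(pat, class = c("split_assignment", "data.frame"), seed = seed)
}

#' Patient-grouped, class-stratified k folds
#'
#' Deals randomly ordered patients of each class onto the fold with the
#' fewest eyes so far, keeping folds balanced in size and class mix while
#' never splitting a patient.
#'
#' @param patients data.frame with `patient_id`, `label`, `n_eyes` (e.g. the
#'   non-test rows of a [grouped_split()]).
#' @param k number of folds.
#' @param seed RNG seed.
#' @return named integer vector: fold id per patient.
#' @export
grouped_folds <- function(patients, k = 10L, seed = 1L) {
  stopifnot(k >= 2L, all(c("patient_id", "n_eyes", "label") %in% names(patients)))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)
  fold <- integer(nrow(patients))
  load <- numeric(k)
  for (lb in sort(unique(patients$label))) {
    idx <- which(patients$label == lb)
    idx <- idx[sample.int(length(idx))]
    for (i in idx) {
      f <- which.min(load)
      fold[i] <- f
      load[f] <- load[f] + patients$n_eyes[i]
    }
  }
  stats::setNames(fold, patients$patient_id)
}

as_positive <- function(labels, positive = "glaucoma") {
  if (is.logical(labels)) labels
  else if (is.numeric(labels)) labels == 1
  else as.character(labels) == positive
}

#' Area under the ROC curve (rank / Mann-Whitney formulation)
#'
#' The probability that a randomly chosen positive outranks a randomly chosen
#' negative, with ties counted one half.
#'
#' @param scores numeric decision values (larger = more positive).
#' @param labels logical, 0/1, or labels where `positive` marks the positive
#'   class.
#' @param positive positive-class label (default `"glaucoma"`).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels, positive = "glaucoma") {
  pos <- as_positive(labels, positive)
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L)
    stop("AUROC undefined: both classes must be present", call. = FALSE)
  if (anyNA(scores)) stop("scores contain NA", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Sensitivity, specificity and F1 of hard predictions
#'
#' Glaucoma (the positive class) drives sensitivity;
#' `F1 = 2 TP / (2 TP + FP + FN)`.
#'
#' @param predicted predicted labels (logical or labels; see `positive`).
#' @param truth true labels; both classes must be present.
#' @param positive positive-class label.
#' @return named numeric: `sensitivity`, `specificity`, `f1`.
#' @export
classification_metrics <- function(predicted, truth, positive = "glaucoma") {
  p <- as_positive(predicted, positive)
  t <- as_positive(truth, positive)
  if (!any(t) || all(t))
    stop("both classes must be present in `truth`", call. = FALSE)
  tp <- sum(p & t); fn <- sum(!p & t)
  tn <- sum(!p & !t); fp <- sum(p & !t)
  c(sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    f1 = 2 * tp / (2 * tp + fp + fn))
}

# z-scoring with training statistics only (constant features left unscaled)
scale_params <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(center = mu, scale = sd)
}
apply_scale <- function(x, sp) sweep(sweep(x, 2, sp$center), 2, sp$scale, "/")

#' Cross-validated SVM model selection for one method
#'
#' For each candidate configuration, trains on all folds but one and scores
#' the held-out validation fold by AUROC; the configuration with the highest
#' mean validation AUROC is selected (ties resolve to the earliest grid
#' entry), refit on all non-test data, and evaluated once on the test set
#' when one is provided. Per-fold AUROC, sensitivity, specificity and F1 of
#' the winning configuration (hard labels at the SVM's native `f(x) > 0`
#' boundary) populate the result. Features are z-scored with training-fold
#' statistics only.
#'
#' @param x numeric feature matrix of the non-test eyes.
#' @param y their labels (logical or labels; positive = glaucoma).
#' @param folds integer fold id per row of `x` (patient-grouped; see
#'   [grouped_folds()]).
#' @param grid list of [svm_config()] candidates.
#' @param test_x,test_y optional held-out test set.
#' @param standardize z-score features per training fold (default TRUE).
#' @param positive positive-class label.
#' @return a `cv_result`: winning config, per-fold metrics, their mean/sd,
#'   per-config mean validation AUROC, and test metrics when applicable.
#' @export
cross_validate_method <- function(x, y, folds, grid, test_x = NULL,
                                  test_y = NULL, standardize = TRUE,
                                  positive = "glaucoma") {
  x <- as.matrix(x)
  pos <- as_positive(y, positive)
  folds <- as.integer(folds)
  stopifnot(length(pos) == nrow(x), length(folds) == nrow(x), length(grid) >= 1L)
  fold_ids <- sort(unique(folds))
  k <- length(fold_ids)
  if (k < 2L) stop("need at least 2 folds", call. = FALSE)
  for (f in fold_ids) {
    if (length(unique(pos[folds == f])) < 2L)
      stop(sprintf(paste0("fold %d has a single class; the cohort is too ",
                          "small or imbalanced for %d-fold stratified CV"),
                   f, k), call. = FALSE)
  }

  val_auc <- matrix(NA_real_, length(grid), k)
  models <- vector("list", k)   # per-fold models of each config, transient
  for (ci in seq_along(grid)) {
    cfg <- grid[[ci]]
    for (fi in seq_len(k)) {
      f <- fold_ids[fi]
      tr <- folds != f
      sp <- if (standardize) scale_params(x[tr, , drop = FALSE])
            else list(center = rep(0, ncol(x)), scale = rep(1, ncol(x)))
      xtr <- apply_scale(x[tr, , drop = FALSE], sp)
      m <- svm_fit(xtr, pos[tr], cfg)
      sc <- svm_decision(m, apply_scale(x[!tr, , drop = FALSE], sp))
      val_auc[ci, fi] <- auroc(sc, pos[!tr], positive = TRUE)
    }
  }
  mean_auc <- rowMeans(val_auc)
  best <- which.max(mean_auc)            # first maximum on ties
  cfg <- grid[[best]]

  fold_metrics <- data.frame(fold = fold_ids, auroc = NA_real_,
                             sensitivity = NA_real_, specificity = NA_real_,
                             f1 = NA_real_)
  for (fi in seq_len(k)) {
    f <- fold_ids[fi]
    tr <- folds != f
    sp <- if (standardize) scale_params(x[tr, , drop = FALSE])
          else list(center = rep(0, ncol(x)), scale = rep(1, ncol(x)))
    m <- svm_fit(apply_scale(x[tr, , drop = FALSE], sp), pos[tr], cfg)
    sc <- svm_decision(m, apply_scale(x[!tr, , drop = FALSE], sp))
    fold_metrics$auroc[fi] <- auroc(sc, pos[!tr], positive = TRUE)
    cm <- classification_metrics(sc > 0, pos[!tr], positive = TRUE)
    fold_metrics[fi, c("sensitivity", "specificity", "f1")] <- cm
  }

  test <- NULL
  if (!is.null(test_x)) {
    test_pos <- as_positive(test_y, positive)
    sp <- if (standardize) scale_params(x) else
      list(center = rep(0, ncol(x)), scale = rep(1, ncol(x)))
    m <- svm_fit(apply_scale(x, sp), pos, cfg)
    sc <- svm_decision(m, apply_scale(as.matrix(test_x), sp))
    test <- c(auroc = auroc(sc, test_pos, positive = TRUE),
              classification_metrics(sc > 0, test_pos, positive = TRUE))
  }

  metric_cols <- c("auroc", "sensitivity", "specificity", "f1")
  structure(
    list(config = cfg,
         fold_metrics = fold_metrics,
         mean = vapply(fold_metrics[metric_cols], mean, numeric(1)),
         sd = vapply(fold_metrics[metric_cols], stats::sd, numeric(1)),
         grid_mean_val_auroc = mean_auc,
         test = test, k = k),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s\n", format(x$config)))
  cat(sprintf("  AUROC %.3f +/- %.3f  sens %.3f  spec %.3f  F1 %.3f (%d folds)\n",
              x$mean["auroc"], x$sd["auroc"], x$mean["sensitivity"],
              x$mean["specificity"], x$mean["f1"], x$k))
  if (!is.null(x$test))
    cat(sprintf("  test: AUROC %.3f  sens %.3f  spec %.3f  F1 %.3f\n",
                x$test["auroc"], x$test["sensitivity"], x$test["specificity"],
                x$test["f1"]))
  invisible(x)
}

#' Per-method VD feature matrices for a whole cohort
#'
#' Runs the extraction chain once per (eye, plexus) and assembles, for each
#' of the six methods (plexus x zone), the eyes-by-regions VD matrix.
#'
#' @param cohort an `octa_cohort`.
#' @param layout a `region_layout` (default: built from the cohort geometry).
#' @param params [vesselness_params()].
#' @param n_bins Otsu histogram bins.
#' @return list with `methods` (named list of feature matrices), `table`
#'   (the eye-level cohort table), and `layout`.
#' @export
cohort_features <- function(cohort, layout = NULL,
                            params = vesselness_params(), n_bins = 256L) {
  stopifnot(inherits(cohort, "octa_cohort"))
  if (is.null(layout)) layout <- make_region_layout(cohort[[1]]$images[[1]])
  tab <- cohort_table(cohort)
  plexuses <- names(cohort[[1]]$images)
  method_ids <- as.vector(outer(plexuses, c("parafoveal", "perifoveal"),
                                paste, sep = "."))
  feats <- lapply(stats::setNames(method_ids, method_ids), function(m) NULL)
  for (i in seq_along(cohort)) {
    fv <- extract_features(cohort[[i]], layout, params, n_bins)
    for (m in names(fv)) feats[[m]] <- rbind(feats[[m]], fv[[m]]$values)
  }
  for (m in names(feats)) rownames(feats[[m]]) <- paste(tab$patient_id, tab$eye)
  list(methods = feats, table = tab, layout = layout)
}

# structural no-leakage guard, executed on every experiment run
assert_no_leakage <- function(split, folds, eye_table) {
  if (any(duplicated(split$patient_id)))
    stop("internal leakage check failed: patient assigned to several sets",
         call. = FALSE)
  if (!all(eye_table$patient_id %in% split$patient_id))
    stop("internal leakage check failed: unassigned patient", call. = FALSE)
  test_p <- split$patient_id[split$set == "test"]
  if (length(intersect(names(folds), test_p)) > 0L)
    stop("internal leakage check failed: test patient appears in CV folds",
         call. = FALSE)
  invisible(TRUE)
}

#' Run the full six-method VD experiment
#'
#' Holds out a patient-grouped, class-stratified test set (default 20% of
#' eyes), builds one k-fold patient-grouped partition of the remaining eyes
#' (per fold: ~60% of all eyes train, ~20% validate), and runs SVM model
#' selection for each of the six methods `{SVP, ICP, DCP} x {parafoveal,
#' perifoveal}` on the identical split and folds, so that per-fold AUROCs are
#' comparable across methods. Finishes with a one-way ANOVA over the six
#' per-fold AUROC groups and Bonferroni-corrected pairwise comparisons.
#'
#' @param cohort an `octa_cohort` (each eye must carry all three plexuses).
#' @param layout optional `region_layout`.
#' @param params [vesselness_params()].
#' @param grid list of [svm_config()] candidates
#'   (default [default_svm_grid()]).
#' @param k number of cross-validation folds (default 10).
#' @param ratios train/validation/test eye proportions.
#' @param seed seed driving the split and fold shuffles.
#' @param features optional precomputed [cohort_features()] result (skips
#'   image processing).
#' @return a `vd_experiment`: per-method `cv_result`s, the ANOVA, the
#'   Bonferroni pairwise table, the split, folds, and a run manifest.
#' @export
run_full_experiment <- function(cohort, layout = NULL,
                                params = vesselness_params(),
                                grid = default_svm_grid(), k = 10L,
                                ratios = c(train = 0.6, validation = 0.2,
                                           test = 0.2),
                                seed = 1L, features = NULL) {
  if (is.null(features)) features <- cohort_features(cohort, layout, params)
  tab <- features$table
  split <- grouped_split(tab, ratios = ratios, seed = seed)
  pat_set <- stats::setNames(split$set, split$patient_id)
  eye_set <- pat_set[tab$patient_id]
  nontest_pat <- split[split$set != "test", , drop = FALSE]
  folds_by_pat <- grouped_folds(nontest_pat, k = k, seed = seed + 1L)
  assert_no_leakage(split, folds_by_pat, tab)

  nontest_rows <- eye_set != "test"
  test_rows <- !nontest_rows
  fold_per_eye <- folds_by_pat[tab$patient_id[nontest_rows]]
  y <- tab$label

  results <- list()
  for (m in names(features$methods)) {
    x <- features$methods[[m]]
    results[[m]] <- cross_validate_method(
      x[nontest_rows, , drop = FALSE], y[nontest_rows], fold_per_eye, grid,
      test_x = x[test_rows, , drop = FALSE], test_y = y[test_rows])
  }

  auc_groups <- lapply(results, function(r) r$fold_metrics$auroc)
  anova <- one_way_anova(auc_groups)
  pairwise <- posthoc_bonferroni(auc_groups)

  manifest <- list(
    seed = as.integer(seed), k = as.integer(k), ratios = as.list(ratios),
    n_eyes = nrow(tab), n_patients = length(unique(tab$patient_id)),
    n_grid = length(grid),
    vesselness = list(scales_px = params$scales_px, beta = params$beta,
                      c = if (identical(params$c, "auto")) "auto" else params$c),
    selected = lapply(results, function(r) format(r$config)),
    mean_cv_auroc = lapply(results, function(r) unname(r$mean["auroc"])))

  structure(list(results = results, anova = anova, pairwise = pairwise,
                 split = split, folds = folds_by_pat, manifest = manifest),
            class = "vd_experiment")
}

#' Summarize a VD experiment as a metrics table
#'
#' One row per method with the mean and standard deviation of the per-fold
#' AUROC, sensitivity, specificity and F1 of the selected configuration.
#'
#' @param experiment a `vd_experiment`.
#' @return data.frame.
#' @export
results_table <- function(experiment) {
  stopifnot(inherits(experiment, "vd_experiment"))
  rows <- lapply(names(experiment$results), function(m) {
    r <- experiment$results[[m]]
    data.frame(method = m,
               auroc_mean = r$mean["auroc"], auroc_sd = r$sd["auroc"],
               sensitivity_mean = r$mean["sensitivity"],
               sensitivity_sd = r$sd["sensitivity"],
               specificity_mean = r$mean["specificity"],
               specificity_sd = r$sd["specificity"],
               f1_mean = r$mean["f1"], f1_sd = r$sd["f1"],
               config = format(r$config), row.names = NULL)
  })
  do.call(rbind, rows)
}

#' @export
print.vd_experiment <- function(x, ...) {
  cat("<vd_experiment>\n")
  tab <- results_table(x)
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-16s AUROC %.3f +/- %.3f  [%s]\n", tab$method[i],
                tab$auroc_mean[i], tab$auroc_sd[i], tab$config[i]))
  cat(sprintf("  ANOVA: F = %.3f, p = %.4g\n", x$anova$F, x$anova$p))
  invisible(x)
}
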