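#' One SVM hyperparameter configuration
#'
#' @param kernel one of `"linear"`, `"polynomial"`, `"rbf"`, `"sigmoid"`.
#' @param C positive regularization strength (soft-margin box constraint).
#' @param degree polynomial degree (>= 2; polynomial kernel only).
#' @param gamma kernel coefficient: a positive number or `"scale"` for the
#'   `1 / (p * var(x))` heuristic computed on the training matrix.
#' @param coef0 independent term of the polynomial/sigmoid kernels.
#' @return object of class `svm_config`.
#' @export
svm_config <- function(kernel = c("linear", "polynomial", "rbf", "sigmoid"),
                       C = 1, degree = 3L, gamma = "scale", coef0 = 0) {
  kernel <- match.arg(kernel)
  if (!is.numeric(C) || length(C) != 1L || C <= 0)
    stop("`C` must be positive", call. = FALSE)
  if (kernel == "polynomial" && (!is.numeric(degree) || degree < 2))
    stop("`degree` must be >= 2 for the polynomial kernel", call. = FALSE)
  if (!(identical(gamma, "scale") ||
        (is.numeric(gamma) && length(gamma) == 1L && gamma > 0)))
    stop("`gamma` must be \"scale\" or positive", call. = FALSE)
  structure(list(kernel = kernel, C = C, degree = as.integer(degree),
                 gamma = gamma, coef0 = coef0),
            class = "svm_config")
}

#' @export
format.svm_config <- function(x, ...) {
  extra <- switch(x$kernel,
    linear = "",
    polynomial = sprintf(", degree=%d, gamma=%s, coef0=%g", x$degree,
                         if (identical(x$gamma, "scale")) "scale" else format(x$gamma),
                         x$coef0),
    sprintf(", gamma=%s, coef0=%g",
            if (identical(x$gamma, "scale")) "scale" else format(x$gamma),
            x$coef0))
  sprintf("svm(kernel=%s, C=%g%s)", x$kernel, x$C, extra)
}

#' @export
print.svm_config <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

kernel_matrix <- function(x1, x2, config, gamma_value) {
  g <- gamma_value
  switch(config$kernel,
    linear = x1 %*% t(x2),
    polynomial = (g * (x1 %*% t(x2)) + config$coef0)^config$degree,
    rbf = {
      d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * (x1 %*% t(x2))
      exp(-g * pmax(d2, 0))
    },
    sigmoid = tanh(g * (x1 %*% t(x2)) + config$coef0))
}

#' Fit a soft-margin kernel SVM
#'
#' Solves the SVM dual with a deterministic SMO solver. Intended for the
#' small per-fold problems of the VD experiment; the full kernel matrix is
#' formed in memory.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y labels in `{-1, +1}` (numeric), or a logical vector
#'   (`TRUE` = positive class).
#' @param config an [svm_config()].
#' @param class_weights optional named numeric `c(positive = , negative = )`
#'   multipliers on `C` per class.
#' @return an `svm_model` with dual coefficients, bias, and the training data
#'   needed for kernel evaluation.
#' @export
svm_fit <- function(x, y, config, class_weights = NULL) {
  stopifnot(inherits(config, "svm_config"))
  x <- as.matrix(x)
  if (is.logical(y)) y <- ifelse(y, 1, -1)
  if (!all(y %in% c(-1, 1))) stop("`y` must be +/-1 or logical", call. = FALSE)
  if (length(unique(y)) < 2L) stop("training data has a single class", call. = FALSE)
  gamma_value <- if (identical(config$gamma, "scale")) {
    v <- stats::var(as.vector(x))
    if (!is.finite(v) || v <= 0) v <- 1
    1 / (ncol(x) * v)
  } else config$gamma
  Cvec <- rep(config$C, nrow(x))
  if (!is.null(class_weights)) {
    Cvec[y > 0] <- Cvec[y > 0] * class_weights[["positive"]]
    Cvec[y < 0] <- Cvec[y < 0] * class_weights[["negative"]]
  }
  K <- kernel_matrix(x, x, config, gamma_value)
  sol <- smo_solve(K, y, Cvec)
  structure(list(alpha = sol$alpha, b = sol$b, x = x, y = y,
                 config = config, gamma_value = gamma_value,
                 converged = sol$converged),
            class = "svm_model")
}

#' SVM decision values
#'
#' `f(x) = sum_i alpha_i y_i K(x_i, x) + b`; the native decision boundary is
#' `f(x) > 0`.
#'
#' @param model an `svm_model`.
#' @param newx numeric matrix of samples to score.
#' @return numeric vector of decision values.
#' @export
svm_decision <- function(model, newx) {
  stopifnot(inherits(model, "svm_model"))
  newx <- as.matrix(newx)
  K <- kernel_matrix(newx, model$x, model$config, model$gamma_value)
  drop(K %*% (model$alpha * model$y) + model$b)
}

#' Default SVM hyperparameter grid
#'
#' All four kernels with log-spaced regularization `10^-2 ... 10^3`,
#' polynomial degrees 2-4 with `coef0 = 1`, and the `"scale"` kernel
#' coefficient heuristic. 36 configurations.
#'
#' @param C_values regularization values to cross.
#' @return list of [svm_config()] objects.
#' @export
default_svm_grid <- function(C_values = 10^(-2:3)) {
  grid <- list()
  for (C in C_values) grid <- c(grid, list(svm_config("linear", C = C)))
  for (C in C_values) grid <- c(grid, list(svm_config("rbf", C = C)))
  for (d in 2:4) for (C in C_values)
    grid <- c(grid, list(svm_config("polynomial", C = C, degree = d, coef0 = 1)))
  for (C in C_values) grid <- c(grid, list(svm_config("sigmoid", C = C, coef0 = 0)))
  grid
}

#' Compact SVM grid (one configuration per kernel family x three C values)
#'
#' A 12-configuration grid covering all four kernels, used where runtime
#' matters more than an exhaustive search (tests, demos).
#'
#' @return list of [svm_config()] objects.
#' @export
compact_svm_grid <- function() {
  grid <- list()
  for (C in c(0.1, 1, 10)) {
    grid <- c(grid,
              list(svm_config("linear", C = C),
                   svm_config("rbf", C = C),
                   svm_config("polynomial", C = C, degree = 2L, coef0 = 1),
                   svm_config("sigmoid", C = C, coef0 = 0)))
  }
  grid
}
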