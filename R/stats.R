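#' One-way ANOVA over k groups
#'
#' Classic fixed-effects decomposition: `F = MS_between / MS_within` on
#' `(k - 1, N - k)` degrees of freedom, p-value from the upper tail of the F
#' distribution. Zero within-group variance with unequal means yields
#' `F = Inf, p = 0`; fully identical values are an error (F undefined).
#'
#' @param groups list of k >= 2 numeric vectors, each with >= 2 values.
#' @return an `anova_result`: `F`, `p`, `df` (numerator, denominator),
#'   `ms_within`, per-group `means` and sizes `ns`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least 2 values", call. = FALSE)
  vals <- unlist(groups, use.names = FALSE)
  if (anyNA(vals) || !all(is.finite(vals)))
    stop("groups must be finite", call. = FALSE)
  ns <- vapply(groups, length, integer(1))
  k <- length(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  grand <- mean(vals)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- k - 1L
  dfw <- N - k
  if (ssw == 0) {
    if (ssb == 0)
      stop("all values identical: F undefined", call. = FALSE)
    return(structure(list(F = Inf, p = 0, df = c(dfb, dfw),
                          ms_within = 0, means = means, ns = ns),
                     class = "anova_result"))
  }
  Fstat <- (ssb / dfb) / (ssw / dfw)
  p <- stats::pf(Fstat, dfb, dfw, lower.tail = FALSE)
  structure(list(F = Fstat, p = p, df = c(dfb, dfw),
                 ms_within = ssw / dfw, means = means, ns = ns),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.4f, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}

#' Bonferroni-corrected post-hoc pairwise comparisons
#'
#' Each unordered pair of groups is tested with the pooled-error t statistic
#' `t = (m_i - m_j) / sqrt(MS_within * (1/n_i + 1/n_j))` on `N - k` degrees
#' of freedom (the SPSS post-hoc convention); the two-sided p-value is
#' multiplied by the number of pairs `k (k - 1) / 2` and capped at 1.
#'
#' @param groups list of named numeric vectors (as for [one_way_anova()]).
#' @param alpha family-wise significance level for the flags (default 0.05).
#' @return a `pairwise_table`: data.frame of all pairs with raw and adjusted
#'   p-values and significance flags, a symmetric matrix `p_adj_matrix`, and
#'   the overall ANOVA result.
#' @export
posthoc_bonferroni <- function(groups, alpha = 0.05) {
  an <- one_way_anova(groups)
  k <- length(groups)
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("group", seq_len(k))
  m <- k * (k - 1L) / 2L
  dfw <- an$df[2]
  rows <- list()
  pmat <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      diff <- an$means[i] - an$means[j]
      se <- sqrt(an$ms_within * (1 / an$ns[i] + 1 / an$ns[j]))
      if (se == 0) {
        p_raw <- if (diff == 0) 1 else 0
        tstat <- if (diff == 0) 0 else sign(diff) * Inf
      } else {
        tstat <- diff / se
        p_raw <- 2 * stats::pt(-abs(tstat), dfw)
      }
      p_adj <- min(1, p_raw * m)
      pmat[i, j] <- p_adj
      pmat[j, i] <- p_adj
      rows[[length(rows) + 1L]] <- data.frame(
        method_i = nms[i], method_j = nms[j], diff = diff, t = tstat,
        p_raw = p_raw, p_adj = p_adj, significant = p_adj < alpha,
        row.names = NULL)
    }
  }
  structure(list(pairs = do.call(rbind, rows), p_adj_matrix = pmat,
                 anova = an, alpha = alpha, n_pairs = m),
            class = "pairwise_table")
}

#' Format a pairwise table as an upper-triangular text block
#'
#' @param x a `pairwise_table`.
#' @param ... unused.
#' @return character vector of lines (invisibly printed by
#'   [print.pairwise_table()]).
#' @export
format.pairwise_table <- function(x, ...) {
  nms <- rownames(x$p_adj_matrix)
  k <- length(nms)
  wid <- max(nchar(nms), 8L)
  fmt_cell <- function(p, sig) {
    if (is.na(p)) return(formatC("", width = wid))
    s <- if (p < 0.001) "<0.001" else sprintf("%.3f", p)
    if (isTRUE(sig)) s <- paste0(s, "*")
    formatC(s, width = wid)
  }
  header <- paste(c(formatC("", width = wid),
                    vapply(nms, formatC, "", width = wid)), collapse = " ")
  lines <- header
  for (i in seq_len(k)) {
    cells <- vapply(seq_len(k), function(j) {
      if (j <= i) formatC("", width = wid)
      else fmt_cell(x$p_adj_matrix[i, j], x$p_adj_matrix[i, j] < x$alpha)
    }, "")
    lines <- c(lines, paste(c(formatC(nms[i], width = wid), cells),
                            collapse = " "))
  }
  c(lines, sprintf("* adjusted p < %.2f (Bonferroni over %d pairs)",
                   x$alpha, x$n_pairs))
}

#' @export
print.pairwise_table <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}
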