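#' Group summaries of per-subject metrics
#'
#' Mean and SD per group and metric, in the column layout of the in vivo
#' flux table (Ala/Pyr, Lac/Pyr, kPA, kPL when present).
#'
#' @param metrics Data frame with a `group` column and one numeric column
#'   per metric.
#' @param group_order Optional character vector fixing the row order.
#' @return Data frame with columns `group`, `metric`, `n`, `mean`, `sd`
#'   (class `group_summary`). Groups with a single subject get `sd = NA`
#'   with a warning.
#' @export
summarize_groups <- function(metrics, group_order = NULL) {
  stopifnot(is.data.frame(metrics), "group" %in% names(metrics))
  mcols <- names(metrics)[vapply(metrics, is.numeric, TRUE)]
  groups <- if (is.null(group_order)) unique(metrics$group) else group_order
  out <- list()
  for (g in groups) {
    sub <- metrics[metrics$group == g, , drop = FALSE]
    if (nrow(sub) < 2)
      warning(sprintf("group '%s' has n < 2; SD not estimable", g))
    for (m in mcols) {
      v <- sub[[m]][is.finite(sub[[m]])]
      out[[length(out) + 1]] <- data.frame(
        group = g, metric = m, n = length(v), mean = mean(v),
        sd = if (length(v) >= 2) stats::sd(v) else NA_real_)
    }
  }
  structure(do.call(rbind, out), class = c("group_summary", "data.frame"))
}

#' Welch two-sample t-test
#'
#' Unequal-variance two-sample comparison:
#' \deqn{t = \frac{\bar x - \bar y}{\sqrt{s_x^2/n_x + s_y^2/n_y}}}
#' with Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#' When both samples have zero variance and equal means, `t = 0, p = 1`
#' by convention.
#'
#' @param x,y Numeric samples, each of length >= 2 with finite values.
#' @param labels Length-2 character vector naming the two groups.
#' @param metric Metric name carried into the result.
#' @return Object of class `welch_test`: list with `metric`, `groups`,
#'   `t`, `df`, `p`, `significant` (at 0.05), `mean_x`, `mean_y`.
#' @examples
#' welch_ttest(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
welch_ttest <- function(x, y, labels = c("x", "y"), metric = NA_character_) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs at least 2 finite values")
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    if (mean(x) == mean(y)) {
      t <- 0; p <- 1; df <- nx + ny - 2
    } else {
      t <- sign(mean(x) - mean(y)) * Inf; p <- 0; df <- nx + ny - 2
    }
  } else {
    t <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(metric = metric, groups = labels, t = t, df = df, p = p,
                 significant = is.finite(p) && p < 0.05,
                 mean_x = mean(x), mean_y = mean(y)),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch t-test%s: %s vs %s, t = %.4g, df = %.3g, p = %.4g%s\n",
              if (is.na(x$metric)) "" else paste0(" [", x$metric, "]"),
              x$groups[1], x$groups[2], x$t, x$df, x$p,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Check monotone ordering of group means
#'
#' For each metric, tests whether the group means are strictly monotone in
#' the declared direction along the declared group ordering (ties fail).
#'
#' @param summaries A `group_summary` from [summarize_groups()].
#' @param group_order Character vector declaring the progression order.
#' @param directions Named character vector, one entry per metric to
#'   check, values `"increasing"` or `"decreasing"`.
#' @return Data frame: `metric`, `direction`, `monotone` (logical),
#'   `means` (comma-separated group means in order).
#' @export
trend_check <- function(summaries, group_order, directions) {
  stopifnot(inherits(summaries, "group_summary"))
  if (length(group_order) < 2) stop("need >= 2 ordered groups")
  if (is.null(names(directions)))
    stop("directions must be a named vector (metric -> direction)")
  out <- lapply(names(directions), function(m) {
    dir <- match.arg(directions[[m]], c("increasing", "decreasing"))
    means <- vapply(group_order, function(g) {
      v <- summaries$mean[summaries$group == g & summaries$metric == m]
      if (length(v) != 1) stop(sprintf(
        "metric '%s' missing for group '%s'", m, g))
      v
    }, 0)
    d <- diff(means)
    mono <- if (dir == "increasing") all(d > 0) else all(d < 0)
    data.frame(metric = m, direction = dir, monotone = mono,
               means = paste(signif(means, 4), collapse = ", "))
  })
  do.call(rbind, out)
}
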