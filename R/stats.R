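#' Holm-Sidak step-down adjustment
#'
#' Orders the raw p-values ascending and sets
#' `adjusted_i = max_{j <= i} (1 - (1 - p_j)^(m - j + 1))`, monotonized and
#' capped at 1, returned in the original order. With a single comparison the
#' adjustment is the identity.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
holm_sidak <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  step <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(step), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# one two-group test; degenerate constant-equal groups get p = 1
two_group_test <- function(a, b, method) {
  if (method == "t") {
    res <- tryCatch(stats::t.test(a, b, var.equal = FALSE),
                    error = function(e) NULL)
    if (is.null(res))  # both groups essentially constant
      return(list(statistic = 0, p = 1, degenerate = TRUE))
    list(statistic = unname(res$statistic), p = res$p.value,
         degenerate = FALSE)
  } else {
    res <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    list(statistic = unname(res$statistic), p = res$p.value,
         degenerate = FALSE)
  }
}

#' Group comparisons with the study's statistical battery
#'
#' Pairwise designs use an unpaired two-tailed Welch t-test or Mann-Whitney
#' test with optional Holm-Sidak multiple-comparison adjustment across all
#' pairs. The many-vs-control design runs a one-way ANOVA followed by Dunnett
#' contrasts against the control (first) group. Analytic p-values only.
#'
#' @param samples Named list of numeric vectors (>= 2 observations each), or
#'   a data frame with columns `value` and `group`.
#' @param design `"pairwise"` (all pairs) or `"many-vs-control"`.
#' @param method `"t"`, `"mann-whitney"`, or `"anova-dunnett"` (implies
#'   many-vs-control).
#' @param adjustment `"holm-sidak"` or `"none"` (pairwise designs; Dunnett
#'   contrasts carry their own single-step adjustment).
#' @param control Name of the control group (default: first).
#' @return Data frame of class `group_comparison`: `group1`, `group2`,
#'   `statistic`, `raw_p`, `adjusted_p`, `method`, `adjustment`, `n1`, `n2`,
#'   `degenerate`.
#' @export
compare_groups <- function(samples,
                           design = c("pairwise", "many-vs-control"),
                           method = c("t", "mann-whitney", "anova-dunnett"),
                           adjustment = c("holm-sidak", "none"),
                           control = NULL) {
  design <- match.arg(design)
  method <- tryCatch(match.arg(method), error = function(e)
    stop("unknown method; options: t, mann-whitney, anova-dunnett"))
  adjustment <- match.arg(adjustment)
  if (is.data.frame(samples))
    samples <- split(samples$value, samples$group)
  if (is.null(names(samples)))
    names(samples) <- paste0("group", seq_along(samples))
  if (any(lengths(samples) < 2)) stop("need >= 2 observations per group")
  if (method == "anova-dunnett") design <- "many-vs-control"
  if (is.null(control)) control <- names(samples)[1]

  if (method == "anova-dunnett") {
    df <- data.frame(value = unlist(samples),
                     group = factor(rep(names(samples), lengths(samples)),
                                    levels = c(control,
                                               setdiff(names(samples),
                                                       control))))
    fit <- stats::aov(value ~ group, data = df)
    glht <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
    adj <- summary(glht)
    raw <- summary(glht, test = multcomp::univariate())
    others <- setdiff(names(samples), control)
    out <- data.frame(group1 = others, group2 = control,
                      statistic = unname(adj$test$tstat),
                      raw_p = unname(raw$test$pvalues),
                      adjusted_p = unname(as.vector(adj$test$pvalues)),
                      method = method, adjustment = "dunnett",
                      n1 = lengths(samples)[others],
                      n2 = length(samples[[control]]),
                      degenerate = FALSE)
  } else {
    pairs <- if (design == "pairwise")
      utils::combn(names(samples), 2, simplify = FALSE)
    else lapply(setdiff(names(samples), control), function(g)
      c(g, control))
    rows <- lapply(pairs, function(pr) {
      tst <- two_group_test(samples[[pr[1]]], samples[[pr[2]]], method)
      data.frame(group1 = pr[1], group2 = pr[2], statistic = tst$statistic,
                 raw_p = tst$p, adjusted_p = NA_real_, method = method,
                 adjustment = adjustment, n1 = length(samples[[pr[1]]]),
                 n2 = length(samples[[pr[2]]]), degenerate = tst$degenerate)
    })
    out <- do.call(rbind, rows)
    out$adjusted_p <- if (adjustment == "holm-sidak") holm_sidak(out$raw_p)
    else out$raw_p
  }
  rownames(out) <- NULL
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group comparisons (%s, %s adjustment)\n",
              x$method[1], x$adjustment[1]))
  print.data.frame(x, digits = 4)
  invisible(x)
}
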