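# Inferential layer: Welch's one-way ANOVA (base oneway.test), Dunnett's T3
# post hoc over the studentized maximum modulus (SMM) distribution, weighted
# one-way ANOVA with Tukey-adjusted weighted marginal means (lm + emmeans),
# and Pearson correlation / simple linear regression.

.as_groups <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("label", "value") %in% names(groups)))
      stop("data-frame input needs columns 'label' and 'value'")
    groups <- split(groups$value, groups$label)
  }
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  lapply(groups, as.numeric)
}

#' Welch's heteroscedasticity-robust one-way ANOVA
#'
#' Tests equality of group means without assuming equal variances. The W
#' statistic follows an F distribution with numerator df \eqn{k - 1} and a
#' Welch-Satterthwaite denominator df. Computed via
#' [stats::oneway.test()] with `var.equal = FALSE`.
#'
#' @param groups Named list of numeric vectors (one per group, each n >= 2),
#'   or a data frame with columns `label`, `value`.
#' @return An object of class `"welch_anova"`: `w_statistic`, `df_num`,
#'   `df_den`, `p_value`, `group_stats`, `degenerate` flag.
#' @examples
#' welch_anova(list(a = c(1, 2, 3), b = c(2, 3, 4)))  # W = 1.5
#' @export
welch_anova <- function(groups) {
  g <- .as_groups(groups)
  ns <- lengths(g)
  if (any(ns < 2L)) stop("each group needs at least 2 observations")
  vars <- vapply(g, stats::var, numeric(1))
  means <- vapply(g, mean, numeric(1))
  gs <- data.frame(label = names(g), n = ns, mean = means, sd = sqrt(vars),
                   row.names = NULL)
  degenerate <- FALSE
  if (all(vars == 0)) {
    if (diff(range(means)) == 0) {
      w <- 0; p <- 1; dfn <- length(g) - 1; dfd <- Inf
    } else {
      w <- Inf; p <- 0; dfn <- length(g) - 1; dfd <- NA_real_
      degenerate <- TRUE
      warning("all groups have zero variance but unequal means; test degenerate")
    }
  } else {
    y <- unlist(g, use.names = FALSE)
    f <- factor(rep(names(g), ns), levels = names(g))
    ht <- stats::oneway.test(y ~ f, var.equal = FALSE)
    w <- unname(ht$statistic); dfn <- unname(ht$parameter[1])
    dfd <- unname(ht$parameter[2]); p <- ht$p.value
  }
  structure(list(w_statistic = w, df_num = dfn, df_den = dfd, p_value = p,
                 group_stats = gs, degenerate = degenerate),
            class = "welch_anova")
}

.stars <- function(p) {
  if (is.na(p)) return("")
  if (p <= 1e-4) "****" else if (p <= 1e-3) "***"
  else if (p <= 0.01) "**" else if (p <= 0.05) "*" else "ns"
}

#' @export
print.welch_anova <- function(x, digits = 4, ...) {
  cat(sprintf("Welch's one-way ANOVA: W(%g, %s) = %s, p = %s %s\n",
              x$df_num, format(x$df_den, digits = digits),
              format(x$w_statistic, digits = digits),
              format.pval(x$p_value, digits = digits), .stars(x$p_value)))
  print(x$group_stats, digits = digits)
  invisible(x)
}

# Studentized maximum modulus distribution -----------------------------------
# M = max_i |Z_i| / S with Z_i iid N(0,1) (i = 1..m) and S = sqrt(X/df),
# X ~ chi^2_df independent. P(M <= q) = E[(2 Phi(qS) - 1)^m], evaluated by
# quadrature over the density of S.

#' Studentized maximum modulus distribution
#'
#' CDF and quantile of the maximum of `m` independent absolute standard
#' normals studentized by a common chi-based scale with `df` degrees of
#' freedom — the reference distribution of Dunnett's T3 procedure.
#'
#' @param q Quantile (>= 0).
#' @param p Probability.
#' @param m Number of comparisons (>= 1).
#' @param df Degrees of freedom (> 0; `Inf` gives the max-modulus of normals).
#' @return `psmm`: probability; `qsmm`: quantile.
#' @export
psmm <- function(q, m, df) {
  if (m < 1) stop("'m' must be >= 1")
  if (df <= 0) stop("'df' must be positive")
  vapply(q, function(qq) {
    if (qq <= 0) return(0)
    if (!is.finite(df)) return((2 * stats::pnorm(qq) - 1)^m)
    f <- function(s) (2 * stats::pnorm(qq * s) - 1)^m *
      2 * df * s * stats::dchisq(df * s^2, df)
    stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value
  }, numeric(1))
}

#' @rdname psmm
#' @export
qsmm <- function(p, m, df) {
  if (p <= 0 || p >= 1) stop("'p' must lie in (0, 1)")
  stats::uniroot(function(q) psmm(q, m, df) - p, c(1e-6, 100),
                 tol = 1e-8, extendInt = "upX")$root
}

#' Dunnett's T3 post hoc test
#'
#' Pairwise comparisons after a Welch-type one-way analysis for unequal
#' variances: each pair gets a Welch t statistic with its own
#' Welch-Satterthwaite df, and the adjusted p-value is the tail probability
#' of the studentized maximum modulus distribution with `m` = the number of
#' comparisons performed. With a single comparison this reduces to the
#' two-sided Welch t-test.
#'
#' @param groups As in [welch_anova()].
#' @param reference Optional group label: compare every other group against
#'   this reference only. Default: all pairwise comparisons.
#' @return Data frame of class `"dunnett_t3"` with columns `pair`,
#'   `mean_diff`, `t`, `df`, `p_unadjusted`, `p_adjusted`.
#' @export
dunnett_t3 <- function(groups, reference = NULL) {
  g <- .as_groups(groups)
  if (any(lengths(g) < 2L)) stop("each group needs at least 2 observations")
  labs <- names(g)
  if (!is.null(reference)) {
    if (!reference %in% labs) stop("'reference' is not a group label")
    pairs <- cbind(setdiff(labs, reference), reference)
  } else {
    pairs <- t(utils::combn(labs, 2))
  }
  m <- nrow(pairs)
  if (m == 0L) stop("no comparisons to perform")
  out <- do.call(rbind, lapply(seq_len(m), function(i) {
    a <- g[[pairs[i, 1]]]; b <- g[[pairs[i, 2]]]
    va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
    se <- sqrt(va + vb)
    tt <- (mean(a) - mean(b)) / se
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    data.frame(pair = paste(pairs[i, 1], "-", pairs[i, 2]),
               mean_diff = mean(a) - mean(b), t = tt, df = df,
               p_unadjusted = 2 * stats::pt(-abs(tt), df))
  }))
  out$p_adjusted <- vapply(seq_len(m), function(i)
    1 - psmm(abs(out$t[i]), m, out$df[i]), numeric(1))
  out$p_adjusted <- pmin(out$p_adjusted, 1)
  class(out) <- c("dunnett_t3", "data.frame")
  out
}

#' @export
print.dunnett_t3 <- function(x, digits = 4, ...) {
  cat(sprintf("Dunnett's T3 post hoc test (%d comparisons)\n", nrow(x)))
  y <- as.data.frame(x)
  y$signif <- vapply(y$p_adjusted, .stars, character(1))
  print(y, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Weighted one-way ANOVA with Tukey-adjusted weighted marginal means
#'
#' Weighted least-squares F test for a difference among group means, with
#' observation weights (e.g. tissue cores per array when each array mean is
#' one data point), followed by pairwise comparisons of the weighted marginal
#' means with the Tukey studentized-range adjustment (via
#' [emmeans::emmeans()]). With all weights equal this is the ordinary
#' one-way ANOVA.
#'
#' @param values Numeric response vector.
#' @param labels Group labels (coerced to factor).
#' @param weights Positive observation weights.
#' @return List of class `"weighted_anova"`: `f_statistic`, `df_num`,
#'   `df_den`, `p_value`, `posthoc` (data frame of Tukey-adjusted pairwise
#'   contrasts), `emmeans` (weighted marginal means), `model`.
#' @export
weighted_one_way_anova <- function(values, labels, weights) {
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive and finite")
  d <- data.frame(y = as.numeric(values), g = factor(labels), w = as.numeric(weights))
  if (nlevels(d$g) < 2L) stop("need at least 2 groups")
  fit <- stats::lm(y ~ g, data = d, weights = w)
  an <- stats::anova(fit)
  em <- emmeans::emmeans(fit, "g")
  ph <- as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = "tukey"))
  structure(list(f_statistic = an[["F value"]][1],
                 df_num = an$Df[1], df_den = an$Df[2],
                 p_value = an[["Pr(>F)"]][1],
                 posthoc = ph, emmeans = as.data.frame(em), model = fit),
            class = "weighted_anova")
}

#' @export
print.weighted_anova <- function(x, digits = 4, ...) {
  cat(sprintf("Weighted one-way ANOVA: F(%d, %d) = %s, p = %s %s\n",
              x$df_num, x$df_den, format(x$f_statistic, digits = digits),
              format.pval(x$p_value, digits = digits), .stars(x$p_value)))
  cat("Weighted marginal means:\n")
  print(x$emmeans, digits = digits)
  cat("Tukey-adjusted pairwise comparisons:\n")
  print(x$posthoc, digits = digits)
  invisible(x)
}

#' Pearson correlation with simple linear regression
#'
#' Pearson r with the two-sided t test (\eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}},
#' df = n - 2) and the ordinary least-squares line.
#'
#' @param x,y Numeric vectors of equal length (n >= 3, neither constant).
#' @return List of class `"pearson_fit"`: `r`, `r_squared`, `p_value`, `n`,
#'   `slope`, `intercept`.
#' @examples
#' set.seed(1)
#' x <- rnorm(45); y <- 0.4 * x + rnorm(45)
#' pearson(x, y)
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  ols <- stats::lm(y ~ x)
  structure(list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
                 p_value = ct$p.value, n = length(x),
                 slope = unname(stats::coef(ols)[2]),
                 intercept = unname(stats::coef(ols)[1])),
            class = "pearson_fit")
}

#' @export
print.pearson_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Pearson correlation: r = %s, r^2 = %s, p = %s %s (n = %d)\n",
              format(x$r, digits = digits), format(x$r_squared, digits = digits),
              format.pval(x$p_value, digits = digits), .stars(x$p_value), x$n))
  cat(sprintf("OLS line: y = %s + %s x\n", format(x$intercept, digits = digits),
              format(x$slope, digits = digits)))
  invisible(x)
}
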