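#' Fisher's exact test for a periodic component in a short series
#'
#' Computes periodogram ordinates at the Fourier frequencies k/n,
#' k = 1..floor((n-1)/2), after mean removal, and tests the share of total
#' spectral power carried by the largest ordinate, g = max I / sum I. The
#' p-value uses the exact null distribution
#' \deqn{P(G > g) = \sum_{j=1}^{\lfloor 1/g \rfloor} (-1)^{j-1}
#'   \binom{m}{j} (1 - j g)^{m-1},}
#' appropriate for short series where the exponential approximation is poor.
#'
#' @param series Numeric vector, length at least 6, not constant. Missing
#'   values must be handled by the caller.
#' @return A list of class `fisher_g` with `g`, `p`, `n`, `m` (number of
#'   ordinates) and `peak_frequency` (cycles per observation).
#' @examples
#' fishers_g_test(sin(2 * pi * (1:30) * 5 / 30) + rnorm(30, 0, 0.1))
#' @export
fishers_g_test <- function(series) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 6) stop("series too short for a periodicity test (n < 6)")
  if (stats::sd(series) == 0) stop("constant series: periodicity undefined")
  m <- (n - 1) %/% 2
  xc <- series - mean(series)
  I <- (Mod(stats::fft(xc))^2 / n)[2:(m + 1)]
  g <- max(I) / sum(I)
  j <- seq_len(floor(1 / g))
  keep <- 1 - j * g > 0
  j <- j[keep]
  terms <- exp(lchoose(m, j) + (m - 1) * log1p(-j * g))
  p <- sum((-1)^(j - 1) * terms)
  structure(list(g = g, p = min(max(p, 0), 1), n = n, m = m,
                 peak_frequency = which.max(I) / n),
            class = "fisher_g")
}

#' @export
print.fisher_g <- function(x, ...) {
  cat(sprintf("Fisher's g test: g = %.4f (m = %d ordinates, n = %d), p = %.4g\n",
              x$g, x$m, x$n, x$p))
  cat(sprintf("  peak frequency %.4f cycles/obs (period %.1f obs)\n",
              x$peak_frequency, 1 / x$peak_frequency))
  invisible(x)
}

#' Pairwise two-sample Kolmogorov-Smirnov tests with Bonferroni correction
#'
#' All unordered pairs of groups are compared with the two-sample KS
#' statistic (asymptotic p-values); raw p-values are multiplied by the number
#' of comparisons and capped at 1. Groups with fewer than `min_n`
#' observations are excluded with a warning.
#'
#' @param data A data frame.
#' @param value,group Column names (strings) of the numeric values and group
#'   labels.
#' @param alpha Family-wise significance level carried into the result.
#' @param alternative Passed to [stats::ks.test()] (`"two.sided"` default).
#' @param min_n Minimum group size.
#' @return A list of class `ks_pairwise`: `groups`, symmetric matrices `D`,
#'   `p_raw`, `p_adjusted`, `n_comparisons`, `alpha`, and a long `table`
#'   tibble (one row per pair).
#' @export
ks_pairwise <- function(data, value, group, alpha = 0.05,
                        alternative = "two.sided", min_n = 5) {
  v <- data[[value]]; gl <- as.character(data[[group]])
  sizes <- table(gl)
  small <- names(sizes)[sizes < min_n]
  if (length(small) > 0) {
    warning("excluding group(s) with fewer than ", min_n, " observations: ",
            paste(small, collapse = ", "))
    keep <- !gl %in% small
    v <- v[keep]; gl <- gl[keep]
  }
  groups <- sort(unique(gl))
  if (length(groups) < 2) stop("need at least two groups of sufficient size")
  k <- length(groups)
  D <- p_raw <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  diag(D) <- 0; diag(p_raw) <- 1
  pairs <- utils::combn(k, 2)
  n_comp <- ncol(pairs)
  rows <- vector("list", n_comp)
  for (c in seq_len(n_comp)) {
    i <- pairs[1, c]; j <- pairs[2, c]
    kt <- suppressWarnings(stats::ks.test(v[gl == groups[i]],
                                          v[gl == groups[j]],
                                          alternative = alternative))
    D[i, j] <- D[j, i] <- unname(kt$statistic)
    p_raw[i, j] <- p_raw[j, i] <- kt$p.value
    rows[[c]] <- tibble::tibble(group1 = groups[i], group2 = groups[j],
                                D = unname(kt$statistic), p_raw = kt$p.value)
  }
  p_adj <- p_raw * n_comp
  p_adj[p_adj > 1] <- 1
  diag(p_adj) <- 1
  table <- dplyr::bind_rows(rows) |>
    dplyr::mutate(p_adjusted = pmin(1, .data$p_raw * n_comp),
                  significant = .data$p_adjusted < alpha)
  structure(list(groups = groups, D = D, p_raw = p_raw, p_adjusted = p_adj,
                 n_comparisons = n_comp, alpha = alpha, table = table),
            class = "ks_pairwise")
}

#' @export
print.ks_pairwise <- function(x, ...) {
  cat(sprintf("Pairwise KS tests, %d groups, %d comparisons (Bonferroni), alpha = %g\n",
              length(x$groups), x$n_comparisons, x$alpha))
  print(x$table)
  invisible(x)
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' Product-moment correlation with the two-sided t-test p-value and the 95%
#' interval `tanh(atanh(r) +/- 1.96/sqrt(n - 3))`.
#'
#' @param x,y Paired numeric vectors, n >= 4, finite, non-constant.
#' @return A list of class `pearson_ci` with `r`, `p`, `ci_low`, `ci_high`,
#'   `n`.
#' @export
pearson_ci <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = 0.95)
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
                 n = length(x)),
            class = "pearson_ci")
}

#' @export
print.pearson_ci <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d), p = %.3g, 95%% CI [%.3f, %.3f]\n",
              x$r, x$n, x$p, x$ci_low, x$ci_high))
  invisible(x)
}

#' Gaussian random-intercept mixed model
#'
#' Fits `y = intercept + slope * x + u_group + e` with `u ~ N(0, s_u^2)` by
#' REML (lme4), the standard treatment for unbalanced longitudinal data with
#' repeated measures per individual. With a single group the random intercept
#' is unidentifiable and the model collapses to ordinary least squares,
#' flagged in the result; a singular fit (`s_u^2 -> 0`) is allowed and
#' flagged.
#'
#' @param y,x Numeric response and covariate.
#' @param group Grouping labels (one level per individual).
#' @return A list of class `ri_model`: `intercept_est`, `intercept_se`,
#'   `slope_est`, `slope_se`, `random_intercept_variance`,
#'   `residual_variance`, `n_obs`, `n_groups`, `singular`, `collapsed_to_ols`
#'   and the underlying `fit`.
#' @export
random_intercept_model <- function(y, x, group) {
  ok <- is.finite(y) & is.finite(x) & !is.na(group)
  y <- y[ok]; x <- x[ok]; group <- factor(group[ok])
  if (length(y) <= 4) stop("too few observations")
  if (stats::sd(x) == 0) stop("constant covariate: slope unidentifiable")
  n_groups <- nlevels(group)
  if (n_groups < 2) {
    fit <- stats::lm(y ~ x)
    cf <- summary(fit)$coefficients
    return(structure(list(
      intercept_est = cf[1, 1], intercept_se = cf[1, 2],
      slope_est = cf[2, 1], slope_se = cf[2, 2],
      random_intercept_variance = 0,
      residual_variance = summary(fit)$sigma^2,
      n_obs = length(y), n_groups = n_groups,
      singular = TRUE, collapsed_to_ols = TRUE, fit = fit
    ), class = "ri_model"))
  }
  dat <- data.frame(y = y, x = x, group = group)
  fit <- lme4::lmer(y ~ x + (1 | group), data = dat, REML = TRUE)
  cf <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    intercept_est = cf["(Intercept)", "Estimate"],
    intercept_se = cf["(Intercept)", "Std. Error"],
    slope_est = cf["x", "Estimate"], slope_se = cf["x", "Std. Error"],
    random_intercept_variance = vc$vcov[vc$grp == "group"],
    residual_variance = vc$vcov[vc$grp == "Residual"],
    n_obs = length(y), n_groups = n_groups,
    singular = lme4::isSingular(fit), collapsed_to_ols = FALSE, fit = fit
  ), class = "ri_model")
}

#' @export
print.ri_model <- function(x, ...) {
  cat(sprintf("Random-intercept model (%d obs, %d groups%s)\n", x$n_obs,
              x$n_groups,
              if (x$collapsed_to_ols) "; collapsed to OLS"
              else if (x$singular) "; singular fit" else ""))
  cat(sprintf("  intercept %.3f +/- %.3f; slope %.3f +/- %.3f\n",
              x$intercept_est, x$intercept_se, x$slope_est, x$slope_se))
  cat(sprintf("  var(random intercept) %.4g, var(residual) %.4g\n",
              x$random_intercept_variance, x$residual_variance))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.fisher_g <- function(x, ...) {
  tibble::tibble(statistic = x$g, p.value = x$p, n = x$n, m = x$m,
                 peak_frequency = x$peak_frequency)
}

#' @export
tidy.ks_pairwise <- function(x, ...) x$table

#' @export
tidy.pearson_ci <- function(x, ...) {
  tibble::tibble(estimate = x$r, p.value = x$p, conf.low = x$ci_low,
                 conf.high = x$ci_high, n = x$n)
}

#' @export
tidy.ri_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "x"),
    estimate = c(x$intercept_est, x$slope_est),
    std.error = c(x$intercept_se, x$slope_se)
  )
}

#' @export
glance.ri_model <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_groups = x$n_groups,
                 random_intercept_variance = x$random_intercept_variance,
                 residual_variance = x$residual_variance,
                 singular = x$singular)
}
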