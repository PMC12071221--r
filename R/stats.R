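#' Kruskal-Wallis test across groups
#'
#' Rank-based one-way comparison of two or more groups, using mid-ranks for
#' ties, the tie-corrected H statistic and an upper-tail chi-square p-value
#' with `groups - 1` degrees of freedom.
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return List of class `kw_result`: `H`, `df`, `p`, `group_sizes`.
#' @examples
#' reg <- load_station_table()
#' kruskal_wallis(split(reg$density, reg$area))$p  # area density difference
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups)
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1L) {
    return(structure(list(H = 0, df = length(groups) - 1L, p = 1,
                          group_sizes = lengths(groups)), class = "kw_result"))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(pooled, g)
  structure(list(
    H = unname(kt$statistic),
    df = unname(kt$parameter),
    p = kt$p.value,
    group_sizes = lengths(groups)
  ), class = "kw_result")
}

#' Dunn post hoc comparisons with Bonferroni adjustment
#'
#' Pairwise z statistics from group mean ranks,
#' `z = (R_i - R_j) / sqrt(V * (1/n_i + 1/n_j))` with tie-corrected variance
#' `V = N(N+1)/12 - sum(t^3 - t) / (12 (N - 1))`, two-sided normal p-values
#' and Bonferroni adjustment over all `g(g-1)/2` pairs.
#'
#' @param groups Named (or unnamed) list of numeric vectors as in
#'   [kruskal_wallis()].
#' @return data.frame of class `dunn_result`: `group_a`, `group_b`, `z`,
#'   `p_raw`, `p_adj`.
#' @export
dunn_bonferroni <- function(groups) {
  check_groups(groups)
  if (is.null(names(groups))) names(groups) <- as.character(seq_along(groups))
  pooled <- unlist(groups, use.names = FALSE)
  r <- rank(pooled)
  g <- rep(names(groups), lengths(groups))
  N <- length(pooled)
  mean_rank <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  V <- N * (N + 1) / 12 - tie_term

  pairs <- utils::combn(names(groups), 2L)
  m <- ncol(pairs)
  res <- data.frame(
    group_a = pairs[1L, ], group_b = pairs[2L, ],
    z = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
    stringsAsFactors = FALSE
  )
  for (j in seq_len(m)) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    se <- sqrt(V * (1 / n[[a]] + 1 / n[[b]]))
    z <- if (se == 0) 0 else (mean_rank[[a]] - mean_rank[[b]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    res$z[j] <- z
    res$p_raw[j] <- p
    res$p_adj[j] <- min(1, p * m)
  }
  class(res) <- c("dunn_result", "data.frame")
  res
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("at least two groups are required")
  }
  if (any(lengths(groups) == 0L)) stop("every group must contain at least one value")
  if (sum(lengths(groups)) < 3L) stop("at least three observations are required")
  invisible(groups)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rho is the Pearson correlation of mid-ranks (equivalent to
#' `1 - 6 sum(d^2) / (n (n^2 - 1))` when there are no ties); the two-sided
#' p-value uses `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @return List of class `spearman_result`: `rho`, `n`, `p`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("at least three pairs are required")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("rank correlation is undefined for a constant sequence")
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  structure(list(rho = rho, n = n, p = p), class = "spearman_result")
}

#' Simple linear regression with Durbin-Watson diagnostics
#'
#' Ordinary least squares of `y` on `x` with R-squared, adjusted R-squared
#' `1 - (1 - R^2)(n - 1)/(n - 2)`, the slope's two-sided p-value, the
#' Durbin-Watson statistic `sum(diff(e)^2) / sum(e^2)` and its p-value from
#' the exact small-sample null distribution (via \pkg{lmtest}).
#'
#' @param x,y Numeric vectors, n >= 3; `x` must not be constant.
#' @param dw_alternative Alternative for the Durbin-Watson test:
#'   `"two.sided"` (default), `"greater"` (positive autocorrelation) or
#'   `"less"`.
#' @return List of class `ols_diagnostics`: `slope`, `intercept`,
#'   `r_squared`, `adj_r_squared`, `p_slope`, `dw_stat`, `dw_p`, `n`,
#'   `residuals`.
#' @export
ols_with_durbin_watson <- function(x, y, dw_alternative = "two.sided") {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("at least three observations are required")
  if (length(unique(x)) == 1L) stop("x is constant; slope is undefined")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  e <- stats::residuals(fit)
  dw <- sum(diff(e)^2) / sum(e^2)
  dw_p <- tryCatch(
    lmtest::dwtest(fit, alternative = dw_alternative)$p.value,
    error = function(cond) NA_real_
  )
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = s$r.squared,
    adj_r_squared = 1 - (1 - s$r.squared) * (n - 1) / (n - 2),
    p_slope = unname(s$coefficients[2L, 4L]),
    dw_stat = dw,
    dw_p = unname(dw_p),
    n = n,
    residuals = unname(e)
  ), class = "ols_diagnostics")
}
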