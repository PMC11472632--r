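#' Nonparametric test result
#'
#' Lightweight container for the nonparametric tests of the cohort
#' statistics battery.
#'
#' @param statistic Test statistic.
#' @param p_value p value in `(0, 1]`.
#' @param method Test name.
#' @param n Integer vector of group sizes.
#' @param exact Logical, exact enumeration (`TRUE`) or asymptotic
#'   approximation (`FALSE`).
#' @return A list of class `"test_result"`.
#' @export
test_result <- function(statistic, p_value, method, n, exact = NA) {
  p_value <- min(max(p_value, .Machine$double.xmin), 1)
  structure(list(statistic = unname(statistic), p_value = p_value,
                 method = method, n = as.integer(n), exact = exact),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.6g, p = %.4g (n = %s%s)\n", x$method,
              x$statistic, x$p_value, paste(x$n, collapse = "/"),
              if (isTRUE(x$exact)) ", exact" else ""))
  invisible(x)
}

# U statistic via mid-ranks (ties allowed): U = R_x - n(n+1)/2
u_statistic <- function(rank_sum_x, n_x) rank_sum_x - n_x * (n_x + 1) / 2

#' Mann-Whitney U test (unpaired rank-sum)
#'
#' For small samples (`min(n, m) <= exact_max`, default 8) the exact
#' permutation distribution of U is enumerated over all group assignments
#' of the combined sample - ties included, via mid-ranks - and the
#' two-sided p value is the probability of a U at least as far from its
#' null mean `nm/2` as observed.  For larger samples the tie-corrected
#' normal approximation with continuity correction is used.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (referring to the distribution of `x`).
#' @param exact_max Largest `min(n, m)` for which enumeration is used.
#' @return A [test_result()] with `statistic` = U of `x`.
#' @export
mann_whitney_u <- function(x, y, alternative = c("two.sided", "less",
                                                 "greater"),
                           exact_max = 8) {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n <- length(x); m <- length(y)
  if (n < 1 || m < 1) stop("both samples must be nonempty", call. = FALSE)
  comb <- c(x, y)
  r <- rank(comb)
  u_obs <- u_statistic(sum(r[seq_len(n)]), n)
  mu <- n * m / 2
  if (min(n, m) <= exact_max) {
    idx <- utils::combn(n + m, n)
    u_all <- u_statistic(colSums(matrix(r[idx], nrow = n)), n)
    p <- switch(alternative,
      two.sided = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9),
      greater   = mean(u_all >= u_obs - 1e-9),
      less      = mean(u_all <= u_obs + 1e-9))
    return(test_result(u_obs, p, "Mann-Whitney U", c(n, m), exact = TRUE))
  }
  nties <- table(r)
  sigma2 <- n * m / 12 *
    ((n + m + 1) - sum(nties^3 - nties) / ((n + m) * (n + m - 1)))
  z_num <- u_obs - mu
  cc <- switch(alternative, two.sided = sign(z_num) * 0.5, greater = 0.5,
               less = -0.5)
  z <- (z_num - cc) / sqrt(sigma2)
  p <- switch(alternative,
    two.sided = 2 * stats::pnorm(-abs(z)),
    greater   = stats::pnorm(z, lower.tail = FALSE),
    less      = stats::pnorm(z))
  test_result(u_obs, min(p, 1), "Mann-Whitney U", c(n, m), exact = FALSE)
}

#' Wilcoxon signed-rank test (paired or one-sample)
#'
#' Wraps `stats::wilcox.test`: paired when `y` is supplied, one-sample
#' against `mu` otherwise.
#'
#' @param x Numeric sample.
#' @param y Optional paired sample.
#' @param mu Null location for the one-sample form (default 0).
#' @param ... Passed to `stats::wilcox.test`.
#' @return A [test_result()].
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, mu = 0, ...) {
  wt <- if (is.null(y))
    suppressWarnings(stats::wilcox.test(x, mu = mu, ...))
  else
    suppressWarnings(stats::wilcox.test(x, y, paired = TRUE, ...))
  method <- if (is.null(y)) "one-sample Wilcoxon" else
    "Wilcoxon matched-pairs signed rank"
  test_result(wt$statistic, wt$p.value, method,
              if (is.null(y)) length(x) else c(length(x), length(y)),
              exact = !grepl("correction", wt$method))
}

#' Kruskal-Wallis rank test across independent groups
#'
#' Wraps `stats::kruskal.test` (tie-corrected chi-square approximation).
#'
#' @param groups List of numeric samples.
#' @return A [test_result()].
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (length(unique(unlist(groups))) == 1)  # all values identical
    return(test_result(0, 1, "Kruskal-Wallis",
                       lengths(groups), exact = FALSE))
  kt <- stats::kruskal.test(groups)
  test_result(kt$statistic, kt$p.value, "Kruskal-Wallis", lengths(groups),
              exact = FALSE)
}

#' Friedman rank test across related samples (blocks)
#'
#' Wraps `stats::friedman.test` on a blocks-by-treatments matrix.
#'
#' @param blocks Numeric matrix, one row per block (e.g. cell), one column
#'   per treatment.
#' @return A [test_result()].
#' @export
friedman_blocks <- function(blocks) {
  blocks <- as.matrix(blocks)
  if (length(unique(as.numeric(blocks))) == 1)
    return(test_result(0, 1, "Friedman", nrow(blocks), exact = FALSE))
  ft <- stats::friedman.test(blocks)
  test_result(ft$statistic, ft$p.value, "Friedman", nrow(blocks),
              exact = FALSE)
}

#' Dunn's multiple-comparison post hoc test
#'
#' Pairwise z statistics on mean ranks of the pooled sample with tie
#' correction,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))`,
#' `T = sum(t^3 - t) / (12 (N - 1))`, with the multiplicity adjustment
#' applied across all pairs (Bonferroni by default).
#'
#' @param groups Named list of numeric samples (>= 2 groups).
#' @param adjust `"bonferroni"` (default), `"holm"` or `"none"`.
#' @return data.frame with one row per pair: `group1`, `group2`, `z`,
#'   `p_raw`, `p_adj`, `n1`, `n2`.
#' @export
dunns_posthoc <- function(groups, adjust = c("bonferroni", "holm", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  comb <- unlist(groups, use.names = FALSE)
  gl <- rep(names(groups), lengths(groups))
  N <- length(comb)
  r <- rank(comb)
  rbar <- tapply(r, gl, mean)
  nn <- tapply(r, gl, length)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / nn[[i]] + 1 / nn[[j]]))
    z <- if (se == 0) 0 else (rbar[[i]] - rbar[[j]]) / se
    c(z = z, p_raw = 2 * stats::pnorm(-abs(z)), n1 = nn[[i]], n2 = nn[[j]])
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = res["z", ], p_raw = pmin(res["p_raw", ], 1),
                    n1 = as.integer(res["n1", ]),
                    n2 = as.integer(res["n2", ]))
  out$p_adj <- stats::p.adjust(out$p_raw, method = adjust)
  out
}

#' Cohort summary (median, quartiles, SD, n)
#'
#' The summary convention of the cohort tables: boxplot statistics (median
#' and interquartile range) plus `median +/- SD`.
#'
#' @param x Numeric sample.
#' @return A list of class `"cohort_summary"`: `median`, `q1`, `q3`, `sd`,
#'   `n`.
#' @export
cohort_summary <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("empty sample", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(median = q[2], q1 = q[1], q3 = q[3],
                 sd = if (length(x) > 1) stats::sd(x) else NaN,
                 n = length(x)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("median %.4g +/- SD %.4g (IQR %.4g..%.4g, n = %d)\n",
              x$median, x$sd, x$q1, x$q3, x$n))
  invisible(x)
}

#' Per-cell activation factors between trans- and cis-state currents
#'
#' The activation factor of a cell is the ratio of its maximal
#' cis-induced to its trans-state current density magnitude.  Cells whose
#' trans-state density is (near) zero are excluded with a warning.
#'
#' @param trans_cds,cis_cds Paired per-cell current densities (pA/pF).
#' @param min_denom Magnitude below which a trans density counts as zero.
#' @return List with `factors` (per-cell ratios, `NA` for excluded cells)
#'   and `summary` (a [cohort_summary()] over the included cells).
#' @export
activation_factor <- function(trans_cds, cis_cds, min_denom = 1e-9) {
  stopifnot(length(trans_cds) == length(cis_cds))
  bad <- abs(trans_cds) <= min_denom
  if (any(bad))
    warning(sum(bad), " cell(s) excluded: trans current density near zero")
  factors <- ifelse(bad, NA_real_, abs(cis_cds) / abs(trans_cds))
  list(factors = factors, summary = cohort_summary(factors[!bad]))
}

#' Coefficient of determination between kinetics and current amplitude
#'
#' Ordinary least-squares R-squared of current density on the half-life
#' constant, used to check that kinetics do not merely track current
#' amplitude.
#'
#' @param taus Per-cell half-life constants.
#' @param current_densities Per-cell current densities.
#' @return R-squared in `[0, 1]`.
#' @export
correlate_kinetics_amplitude <- function(taus, current_densities) {
  stopifnot(length(taus) == length(current_densities))
  if (length(taus) < 3) stop("need at least 3 cells", call. = FALSE)
  if (stats::var(taus) == 0)
    stop("constant half-life vector: R-squared undefined", call. = FALSE)
  summary(stats::lm(current_densities ~ taus))$r.squared
}
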