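#' Cubic smoothing-spline fit of a current-density-voltage relation
#'
#' Fits a cubic smoothing spline (penalized least squares) to the I-V
#' relation.  The smoothing parameter is chosen by generalized
#' cross-validation by default; a fixed `spar` or `lambda` can (and, when
#' comparing groups, should) be supplied so every cell in a comparison is
#' smoothed identically.
#'
#' @param iv An [iv_curve()] with at least 10 grid points.
#' @param spar Fixed smoothing parameter in `smooth.spline`'s `spar`
#'   parameterization (optional).
#' @param lambda Fixed penalty `lambda` (optional, overrides `spar`).
#' @return A list of class `"smoothed_iv"`: `voltage_mV`, `density_pA_pF`
#'   (smoothed, on the source grid), `fit` (the `smooth.spline` object),
#'   `residual_sse`, `lambda`, `source`.
#' @export
smooth_iv <- function(iv, spar = NULL, lambda = NULL) {
  stopifnot(inherits(iv, "iv_curve"))
  if (length(iv$voltage_mV) < 10)
    stop("need at least 10 voltage grid points", call. = FALSE)
  if (diff(range(iv$voltage_mV)) == 0)
    stop("degenerate I-V: constant voltage", call. = FALSE)
  args <- list(x = iv$voltage_mV, y = iv$density_pA_pF, keep.data = FALSE)
  if (!is.null(lambda)) args$lambda <- lambda
  else if (!is.null(spar)) args$spar <- spar
  else args$cv <- FALSE  # generalized cross-validation
  fit <- do.call(stats::smooth.spline, args)
  sm <- stats::predict(fit, iv$voltage_mV)$y
  structure(list(voltage_mV = iv$voltage_mV, density_pA_pF = sm,
                 fit = fit, residual_sse = sum((sm - iv$density_pA_pF)^2),
                 lambda = fit$lambda, source = iv),
            class = "smoothed_iv")
}

branch_anchors <- function(voltage_mV, density) {
  neg <- voltage_mV < 0
  pos <- voltage_mV > 0
  if (!any(neg) || !any(pos))
    stop("I-V must cover both negative and positive potentials", call. = FALSE)
  list(neg = neg, pos = pos,
       anchor_neg = density[which.min(voltage_mV)],
       anchor_pos = density[which.max(voltage_mV)])
}

#' Branch-wise percent normalization of a smoothed I-V relation
#'
#' The inward branch (V < 0) is scaled so the smoothed density at the most
#' negative grid voltage maps to -100%, the outward branch (V > 0) so the
#' most positive grid voltage maps to +100%; the reversal potential (0 mV)
#' maps to 0% by construction of the densities.  The two branches are
#' anchored independently, so rectification ratios are deliberately
#' discarded and only curve *shape* remains.
#'
#' @param smoothed A [smooth_iv()] result.
#' @return A list of class `"normalized_iv"`: `voltage_mV`, `norm_pct`,
#'   `branch` (`"inward"`/`"outward"`/`"reversal"`), `scale_neg`,
#'   `scale_pos`, `fit`.
#' @export
normalize_iv <- function(smoothed) {
  stopifnot(inherits(smoothed, "smoothed_iv"))
  v <- smoothed$voltage_mV
  dens <- smoothed$density_pA_pF
  an <- branch_anchors(v, dens)
  tiny <- 1e-6 * max(abs(dens), .Machine$double.eps)
  if (abs(an$anchor_neg) <= tiny || abs(an$anchor_pos) <= tiny)
    stop("no current at an anchor potential; cannot normalize", call. = FALSE)
  scale_neg <- 100 / abs(an$anchor_neg)
  scale_pos <- 100 / abs(an$anchor_pos)
  norm <- ifelse(an$neg, dens * scale_neg,
                 ifelse(an$pos, dens * scale_pos, 0))
  branch <- ifelse(an$neg, "inward", ifelse(an$pos, "outward", "reversal"))
  structure(list(voltage_mV = v, norm_pct = norm, branch = branch,
                 scale_neg = scale_neg, scale_pos = scale_pos,
                 fit = smoothed$fit),
            class = "normalized_iv")
}

#' Normalized slope conductance of a normalized I-V relation
#'
#' The slope conductance is the voltage derivative of the normalized
#' current density, evaluated analytically from the smoothing spline, and
#' rescaled per branch so the branch mean is 1 - a dimensionless "Norm.
#' G_slope" whose deviations from 1 localise where the I-V shape bends.
#' The derivative at the reversal potential is excluded (the branch anchors
#' make it degenerate) and the outermost grid point of each branch carries
#' the flag `"endpoint"` (one-sided derivative support).
#'
#' @param normalized A [normalize_iv()] result.
#' @param cell_id,group Optional labels stored on the curve.
#' @return A list of class `"nsc_curve"`: `voltage_mV`, `nsc`, `branch`,
#'   `endpoint` (logical), `branch_mean_neg`, `branch_mean_pos`,
#'   `cell_id`, `group`.
#' @export
compute_nsc <- function(normalized, cell_id = NA_character_,
                        group = NA_character_) {
  stopifnot(inherits(normalized, "normalized_iv"))
  keep <- normalized$branch != "reversal"
  v <- normalized$voltage_mV[keep]
  branch <- normalized$branch[keep]
  deriv <- stats::predict(normalized$fit, v, deriv = 1)$y
  scale <- ifelse(branch == "inward", normalized$scale_neg,
                  normalized$scale_pos)
  slope <- deriv * scale  # d(norm_pct)/dV
  nsc <- slope
  mean_neg <- mean(slope[branch == "inward"])
  mean_pos <- mean(slope[branch == "outward"])
  if (mean_neg == 0 || mean_pos == 0)
    stop("zero mean slope on a branch; cannot rescale", call. = FALSE)
  nsc[branch == "inward"] <- slope[branch == "inward"] / mean_neg
  nsc[branch == "outward"] <- slope[branch == "outward"] / mean_pos
  endpoint <- v == min(v) | v == max(v)
  structure(list(voltage_mV = v, nsc = nsc, branch = branch,
                 endpoint = endpoint, branch_mean_neg = mean_neg,
                 branch_mean_pos = mean_pos, cell_id = cell_id,
                 group = group),
            class = "nsc_curve")
}

#' Full NSC pipeline for one I-V curve
#'
#' Convenience wrapper: [smooth_iv()] then [normalize_iv()] then
#' [compute_nsc()].
#'
#' @inheritParams smooth_iv
#' @inheritParams compute_nsc
#' @return An `"nsc_curve"`.
#' @export
nsc_from_iv <- function(iv, spar = NULL, lambda = NULL,
                        cell_id = NA_character_, group = NA_character_) {
  compute_nsc(normalize_iv(smooth_iv(iv, spar = spar, lambda = lambda)),
              cell_id = cell_id, group = group)
}

#' Per-voltage nonparametric comparison of NSC curves between groups
#'
#' At each grid voltage the per-cell NSC values are compared across groups:
#' two groups with the Mann-Whitney U test ([mann_whitney_u()]), three or
#' more with the Kruskal-Wallis rank test.  p values are reported pointwise
#' per voltage without across-voltage multiplicity adjustment (a Holm
#' option exists, default off).
#'
#' @param curves List of `"nsc_curve"` objects, all on the same voltage
#'   grid.
#' @param groups Group label per curve (defaults to each curve's own
#'   `group` field).
#' @param adjust `"none"` (default) or `"holm"` across voltages.
#' @return data.frame with columns `voltage_mV`, `branch`, `p_value`,
#'   `test`, plus one `n_<group>` column per group.
#' @export
compare_nsc <- function(curves, groups = NULL, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (is.null(groups))
    groups <- vapply(curves, function(cv) cv$group, character(1))
  groups <- as.character(groups)
  if (length(unique(groups)) < 2)
    stop("need at least 2 groups", call. = FALSE)
  tab <- table(groups)
  if (any(tab < 3)) stop("every group needs at least 3 cells", call. = FALSE)
  grid <- curves[[1]]$voltage_mV
  for (cv in curves)
    if (!isTRUE(all.equal(cv$voltage_mV, grid)))
      stop("all NSC curves must share one voltage grid", call. = FALSE)
  k <- length(unique(groups))
  test_name <- if (k == 2) "Mann-Whitney U" else "Kruskal-Wallis"
  p <- vapply(seq_along(grid), function(i) {
    vals <- vapply(curves, function(cv) cv$nsc[i], numeric(1))
    if (k == 2) {
      g <- unique(groups)
      mann_whitney_u(vals[groups == g[1]], vals[groups == g[2]])$p_value
    } else {
      kruskal_wallis(split(vals, groups))$p_value
    }
  }, numeric(1))
  if (adjust == "holm") p <- stats::p.adjust(p, "holm")
  out <- data.frame(voltage_mV = grid, branch = curves[[1]]$branch,
                    p_value = p, test = test_name)
  for (g in names(tab)) out[[paste0("n_", g)]] <- as.integer(tab[[g]])
  out
}
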