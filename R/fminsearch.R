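#' Nelder-Mead simplex minimisation (fminsearch-style)
#'
#' Unconstrained Nelder-Mead simplex search with the standard Lagarias et
#' al. (1998) coefficients (reflection 1, expansion 2, contraction 0.5,
#' shrink 0.5) and the joint termination rule of the classic `fminsearch`
#' routine: the search stops successfully only when the simplex satisfies
#' *both* the parameter tolerance (`tol_x`, max coordinate spread relative
#' to the best vertex) and the objective tolerance (`tol_fun`, max objective
#' spread relative to the best vertex); otherwise it runs until the
#' function-evaluation or iteration cap is hit, in which case the best point
#' found is returned with `converged = FALSE`.
#'
#' The initial simplex perturbs each coordinate of `x0` by 5% (or by
#' 0.00025 where the coordinate is zero), as in the reference routine.
#'
#' @param fn Objective function of a numeric vector.
#' @param x0 Numeric start vector.
#' @param max_fun_evals,max_iter Caps on function evaluations / iterations.
#' @param tol_x,tol_fun Termination tolerances (both must be met).
#' @return List with `par`, `value`, `n_evals`, `n_iter`, `converged`.
#' @export
fminsearch_nm <- function(fn, x0, max_fun_evals = 5000, max_iter = 10000,
                          tol_x = 1e-10, tol_fun = 1e-6) {
  stopifnot(tol_x > 0, tol_fun > 0, max_fun_evals >= 1, max_iter >= 1)
  n <- length(x0)
  rho <- 1; chi <- 2; psi <- 0.5; sigma <- 0.5
  usual_delta <- 0.05; zero_term_delta <- 0.00025

  v <- matrix(0, n, n + 1)
  v[, 1] <- x0
  for (j in seq_len(n)) {
    y <- x0
    y[j] <- if (y[j] != 0) (1 + usual_delta) * y[j] else zero_term_delta
    v[, j + 1] <- y
  }
  safe_fn <- function(x) {
    val <- suppressWarnings(fn(x))
    if (!is.finite(val)) Inf else val
  }
  fv <- apply(v, 2, safe_fn)
  n_evals <- n + 1
  o <- order(fv); v <- v[, o, drop = FALSE]; fv <- fv[o]

  n_iter <- 0
  converged <- FALSE
  while (TRUE) {
    if (max(abs(fv[-1] - fv[1])) <= tol_fun &&
        max(abs(v[, -1, drop = FALSE] - v[, 1])) <= tol_x) {
      converged <- TRUE
      break
    }
    if (n_evals >= max_fun_evals || n_iter >= max_iter) break
    n_iter <- n_iter + 1

    xbar <- rowMeans(v[, seq_len(n), drop = FALSE])
    xr <- (1 + rho) * xbar - rho * v[, n + 1]
    fr <- safe_fn(xr); n_evals <- n_evals + 1

    if (fr < fv[1]) {
      xe <- (1 + rho * chi) * xbar - rho * chi * v[, n + 1]
      fe <- safe_fn(xe); n_evals <- n_evals + 1
      if (fe < fr) { v[, n + 1] <- xe; fv[n + 1] <- fe }
      else         { v[, n + 1] <- xr; fv[n + 1] <- fr }
    } else if (fr < fv[n]) {
      v[, n + 1] <- xr; fv[n + 1] <- fr
    } else if (fr < fv[n + 1]) {
      # outside contraction
      xc <- (1 + psi * rho) * xbar - psi * rho * v[, n + 1]
      fc <- safe_fn(xc); n_evals <- n_evals + 1
      if (fc <= fr) { v[, n + 1] <- xc; fv[n + 1] <- fc }
      else {
        for (j in 2:(n + 1)) {
          v[, j] <- v[, 1] + sigma * (v[, j] - v[, 1])
          fv[j] <- safe_fn(v[, j])
        }
        n_evals <- n_evals + n
      }
    } else {
      # inside contraction
      xcc <- (1 - psi) * xbar + psi * v[, n + 1]
      fcc <- safe_fn(xcc); n_evals <- n_evals + 1
      if (fcc < fv[n + 1]) { v[, n + 1] <- xcc; fv[n + 1] <- fcc }
      else {
        for (j in 2:(n + 1)) {
          v[, j] <- v[, 1] + sigma * (v[, j] - v[, 1])
          fv[j] <- safe_fn(v[, j])
        }
        n_evals <- n_evals + n
      }
    }
    o <- order(fv); v <- v[, o, drop = FALSE]; fv <- fv[o]
  }
  list(par = v[, 1], value = fv[1], n_evals = n_evals, n_iter = n_iter,
       converged = converged)
}
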