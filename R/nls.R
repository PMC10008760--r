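#' Default parameter bounds for NLS fitting
#'
#' Reasonably conservative lower and upper limits for each kinetic parameter,
#' used both to constrain the bounded least-squares optimiser and as the box
#' within which multi-start points are drawn. All bounds are overridable via
#' the `bounds` argument of [fit_nls()].
#'
#' @param model_id One of `"2tc"`, `"1tc"`, `"srtm"`.
#' @return A list with numeric vectors `lower` and `upper`, named by
#'   parameter.
#' @export
default_pk_bounds <- function(model_id = c("2tc", "1tc", "srtm")) {
  model_id <- match.arg(model_id)
  switch(model_id,
    "2tc" = list(lower = c(K1 = 1e-4, VND = 1e-3, BPP = 1e-3, k4 = 1e-4),
                 upper = c(K1 = 2, VND = 10, BPP = 20, k4 = 1)),
    "1tc" = list(lower = c(K1 = 1e-4, VT = 1e-2),
                 upper = c(K1 = 2, VT = 50)),
    "srtm" = list(lower = c(R1 = 0.1, k2prime = 1e-3, BPND = 1e-3),
                  upper = c(R1 = 3, k2prime = 1, BPND = 20)))
}

pk_constructor <- function(model_id) {
  switch(model_id, "2tc" = function(p) pk_2tc(p[1], p[2], p[3], p[4]),
         "1tc" = function(p) pk_1tc(p[1], p[2]),
         "srtm" = function(p) pk_srtm(p[1], p[2], p[3]))
}

#' Weighted multi-start nonlinear least squares fit of a kinetic model
#'
#' Fits a kinetic model directly in its compound parameterisation (e.g. `VND`
#' and `BPP` rather than `k2` and `k3` for the 2TC), which keeps combined
#' parameters biologically consistent and eases subsequent prior definition.
#' Optimisation is bounded Levenberg-Marquardt on the log-parameter scale
#' (so positivity is automatic), minimising the weighted residual sum of
#' squares. Multiple starting points guard against local minima: the first
#' start is the geometric midpoint of the bounds and the remainder are drawn
#' by Latin-hypercube sampling within the (log) bounds; the best converged
#' start by objective value wins, ties broken by the lower start index.
#'
#' @param x The measured [tac()].
#' @param model_id `"2tc"`, `"1tc"` or `"srtm"`.
#' @param input An [aif()] (2TC/1TC) or reference-region [tac()] (SRTM).
#' @param starts Either an integer number of starts (default 5) or a matrix
#'   of natural-scale start points (one row per start, columns named by
#'   parameter). Start points drawn internally use the current RNG state;
#'   seed the session for reproducibility.
#' @param bounds List with `lower`/`upper` named vectors on the natural
#'   scale; defaults to [default_pk_bounds()].
#' @param weights Optional weights overriding those in `x`.
#' @return An object of class `nls_fit`: a list with `estimates` (log-scale,
#'   named `log<param>`), `par` (natural scale), `rss` (weighted), `converged`,
#'   `start_index`, `fitted` (predicted frame values), `vcov` (Gauss-Newton
#'   approximation on the log scale), `cond_number`, `ill_conditioned`, and
#'   `at_bound` flags.
#' @export
fit_nls <- function(x, model_id = c("2tc", "1tc", "srtm"), input,
                    starts = 5, bounds = NULL, weights = NULL) {
  model_id <- match.arg(model_id)
  if (!inherits(x, "tac")) validation_error("x must be a tac")
  bounds <- bounds %||% default_pk_bounds(model_id)
  pnames <- names(bounds$lower)
  make <- pk_constructor(model_id)
  w <- weights %||% x$weights
  lo <- log(bounds$lower); hi <- log(bounds$upper)
  if (any(hi <= lo)) validation_error("upper bounds must exceed lower bounds")

  predict_fun <- function(logp) {
    p <- make(exp(logp))
    simulate_tac(p, input, x$schedule)$values
  }
  resid_fun <- function(logp) sqrt(w) * (x$values - predict_fun(logp))

  if (is.matrix(starts)) {
    start_mat <- log(starts[, pnames, drop = FALSE])
  } else {
    n_starts <- as.integer(starts)
    if (n_starts < 1) validation_error("at least one start point is required")
    start_mat <- matrix((lo + hi) / 2, nrow = 1)
    if (n_starts > 1) {
      u <- lhs::randomLHS(n_starts - 1, length(pnames))
      start_mat <- rbind(start_mat,
                         sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`))
    }
    colnames(start_mat) <- pnames
  }

  best <- NULL
  any_converged <- FALSE
  for (s in seq_len(nrow(start_mat))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start_mat[s, ], lower = lo, upper = hi,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    # minpack info 1-3: ftol/ptol satisfied; 4: gradient orthogonality
    # (also returned for exactly zero residuals) -- all indicate a minimum
    conv <- fit$info %in% 1:4
    any_converged <- any_converged || conv
    obj <- fit$deviance
    if (is.null(best) || obj < best$obj - 1e-12) {
      best <- list(fit = fit, obj = obj, idx = s, conv = conv)
    }
  }
  if (is.null(best))
    validation_error("all NLS starts failed")

  logp <- coef(best$fit)
  names(logp) <- pnames
  fitted <- predict_fun(logp)
  at_bound <- (logp - lo < 1e-6) | (hi - logp < 1e-6)

  # Gauss-Newton variance-covariance at the optimum: sigma^2 (J' W J)^-1
  J <- num_jacobian(predict_fun, logp)
  n <- length(x$values); p <- length(logp)
  sigma2 <- best$obj / max(n - p, 1)
  JtWJ <- t(J) %*% (w * J)
  vc <- tryCatch(sigma2 * solve(JtWJ), error = function(e) {
    matrix(Inf, p, p, dimnames = list(pnames, pnames))
  })
  dimnames(vc) <- list(pnames, pnames)
  kappa <- condition_number(JtWJ)

  out <- list(model_id = model_id,
              estimates = setNames(logp, paste0("log", pnames)),
              par = exp(logp),
              rss = best$obj,
              converged = best$conv && any_converged,
              start_index = best$idx,
              fitted = fitted,
              vcov = vc,
              cond_number = kappa,
              ill_conditioned = is_ill_conditioned(kappa),
              at_bound = at_bound)
  class(out) <- "nls_fit"
  out
}

#' @export
print.nls_fit <- function(x, ...) {
  cat(sprintf("<nls_fit %s> rss %.4g, converged %s, cond %.3g%s\n",
              x$model_id, x$rss, x$converged, x$cond_number,
              if (x$ill_conditioned) " (ill-conditioned)" else ""))
  print(round(x$par, 5))
  invisible(x)
}

# central-difference Jacobian of fun (vector-valued) at p
num_jacobian <- function(fun, p, eps = 1e-6) {
  f0 <- fun(p)
  J <- matrix(0, length(f0), length(p))
  for (i in seq_along(p)) {
    h <- eps * max(abs(p[i]), 1)
    pp <- p; pp[i] <- p[i] + h
    pm <- p; pm[i] <- p[i] - h
    J[, i] <- (fun(pp) - fun(pm)) / (2 * h)
  }
  J
}

#' Condition number of a matrix after unit-norm column rescaling
#'
#' Identifiability diagnostic for NLS fits: the ratio of the largest to the
#' smallest eigenvalue magnitude of the matrix after rescaling each column to
#' unit Euclidean norm. Rescaling removes arbitrary parameter scaling, so any
#' diagonal matrix has condition number 1. Values above `1e6` indicate severe
#' ill-conditioning (high sensitivity of the fit to small data perturbations).
#'
#' @param m A square, finite numeric matrix.
#' @return The condition number (`>= 1`); `Inf` if the rescaled matrix is
#'   singular.
#' @examples
#' condition_number(diag(3))          # 1
#' condition_number(matrix(c(1, .8, .8, 1), 2))  # (1 + .8)/(1 - .8) = 9
#' @export
condition_number <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    validation_error("m must be a square matrix")
  if (any(!is.finite(m))) return(Inf)
  norms <- sqrt(colSums(m^2))
  if (any(norms == 0)) return(Inf)
  ms <- sweep(m, 2, norms, `/`)
  ev <- Mod(eigen(ms, only.values = TRUE)$values)
  if (min(ev) <= .Machine$double.eps * max(ev) * nrow(m)) return(Inf)
  max(ev) / min(ev)
}

#' @rdname condition_number
#' @param kappa A condition number.
#' @param threshold Flagging threshold (default `1e6`).
#' @export
is_ill_conditioned <- function(kappa, threshold = 1e6) {
  !is.finite(kappa) || kappa > threshold
}
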