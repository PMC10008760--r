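#' Build a PuMBA model from a specification and a parameter table
#'
#' Assembles the joint multivariate hierarchical multifactor model over all
#' `m` PK parameters,
#' \deqn{\theta_{i,j,k} = \alpha_i + X_{i,j}^T \beta_i + \tau_{i,j} +
#'   \upsilon_{i,k} + \epsilon_{i,j,k},}
#' where subject deviations \eqn{\tau_j}, pooled region deviations
#' \eqn{\upsilon_k} and residuals \eqn{\epsilon_{j,k}} are each
#' `m`-dimensional multivariate normal draws, and parameters flagged as
#' region-fixed (binding and delivery by default) receive per-region offsets
#' with the first region (alphabetically) as reference instead of pooled
#' deviations. The model is compiled to code for the Gibbs-sampling backend
#' (JAGS); covariance priors are parameterised through the half-normal SD
#' scale and LKJ correlation shape in the spec, mapped to a calibrated
#' inverse-Wishart form (see the methods vignette).
#'
#' Rows with missing parameter values are dropped listwise per
#' (subject, region) cell with a warning.
#'
#' @param spec A [pumba_spec()].
#' @param table Data frame with columns `subject`, `region`, one `log<param>`
#'   column per parameter (natural-log scale), and any covariates used in the
#'   spec formulas.
#' @return An object of class `pumba_model` (the model handle): JAGS code,
#'   prepared data, monitor list and label maps, ready for [fit_pumba()].
#' @export
build_pumba <- function(spec, table) {
  if (!inherits(spec, "pumba_spec"))
    validation_error("spec must be a pumba_spec")
  table <- as.data.frame(table)
  pars <- spec$parameters
  m <- length(pars)
  ycols <- paste0("log", pars)
  need <- c("subject", "region", ycols)
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    validation_error("table lacks column(s): %s",
                     paste(missing_cols, collapse = ", "))
  for (f in spec$formulas) {
    vars <- all.vars(f)
    if (length(setdiff(vars, names(table))))
      validation_error("covariate(s) not in table: %s",
                       paste(setdiff(vars, names(table)), collapse = ", "))
  }

  ok <- complete.cases(table[, ycols, drop = FALSE])
  if (!all(ok)) {
    warning(sprintf("dropping %d incomplete (subject, region) cells",
                    sum(!ok)))
    table <- table[ok, , drop = FALSE]
  }
  if (any(!is.finite(as.matrix(table[, ycols]))))
    validation_error("parameter columns must be finite")

  subjects <- sort(unique(as.character(table$subject)))
  regions <- sort(unique(as.character(table$region)))
  J <- length(subjects); K <- length(regions)
  if (J < 2 || K < 2)
    validation_error("need at least 2 subjects and 2 regions (got %d, %d)",
                     J, K)
  pooled <- pars[!spec$region_fixed[pars]]
  if (m >= 2 && length(pooled) && (J < 4 || K < 3))
    validation_error(
      "pooled region deviations need >= 4 subjects and >= 3 regions to be identifiable from the residual term")

  N <- nrow(table)
  y <- as.matrix(table[, ycols, drop = FALSE])
  subj <- match(as.character(table$subject), subjects)
  reg <- match(as.character(table$region), regions)
  pr <- spec$priors

  # per-parameter covariate designs (intercept handled by alpha)
  X <- vector("list", m)
  xnames <- vector("list", m)
  for (i in seq_len(m)) {
    f <- spec$formulas[[pars[i]]]
    if (is.null(f)) { xnames[[i]] <- character(0); next }
    mm <- model.matrix(f, table)
    mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
    if (ncol(mm) == 0) { xnames[[i]] <- character(0); next }
    if (qr(mm)$rank < ncol(mm))
      validation_error("rank-deficient design for parameter %s", pars[i])
    X[[i]] <- mm
    xnames[[i]] <- colnames(mm)
  }

  code <- jags_code(spec, m, length(pooled), xnames)
  data <- list(N = N, y = if (m == 1) as.vector(y) else y, reg = reg, K = K)
  if (spec$pool_subjects) data$subj <- subj
  if (m >= 2) {
    data$M <- m
    data$zero_m <- rep(0, m)
    iw <- iw_hyper(m, pr$lkj_eta, pr$sd_scale)
    data$Se <- iw$S; data$nu_e <- iw$nu
    if (spec$pool_subjects) { data$Ss <- iw$S; data$nu_s <- iw$nu }
  }
  if (spec$pool_subjects && m >= 2) data$J <- J
  if (spec$pool_subjects && m == 1) data$J <- J
  P <- length(pooled)
  if (P >= 2) {
    iwr <- iw_hyper(P, pr$lkj_eta, pr$sd_scale)
    data$Sr <- iwr$S; data$nu_r <- iwr$nu
    data$zero_p <- rep(0, P)
  }
  data$prior_alpha_mean <- unname(pr$intercept_mean[pars])
  data$prior_alpha_prec <- 1 / pr$intercept_sd^2
  if (any(lengths(xnames) > 0)) data$prior_beta_prec <- 1 / pr$beta_sd^2
  if (any(spec$region_fixed)) data$prior_rfe_prec <- 1 / pr$region_fe_sd^2
  if (m == 1 || P == 1) data$prior_sd_scale <- pr$sd_scale
  for (i in seq_len(m)) if (!is.null(X[[i]])) {
    data[[paste0("X_", i)]] <- X[[i]]
    data[[paste0("P_", i)]] <- ncol(X[[i]])
  }

  monitors <- c("alpha")
  for (i in seq_len(m)) if (length(xnames[[i]]))
    monitors <- c(monitors, paste0("beta_", i))
  for (i in seq_len(m)) if (spec$region_fixed[pars[i]])
    monitors <- c(monitors, paste0("rfe_", i))
  if (m >= 2) monitors <- c(monitors, "Omega_e") else
    monitors <- c(monitors, "sd_e1")
  if (spec$pool_subjects)
    monitors <- c(monitors, if (m >= 2) "Omega_s" else "sd_s1")
  if (P >= 2) monitors <- c(monitors, "Omega_r")
  if (P == 1) monitors <- c(monitors, "sd_r1")

  structure(list(code = code, data = data, monitors = monitors,
                 parameters = pars, xnames = xnames,
                 pooled = pooled, regions = regions, subjects = subjects,
                 spec = spec),
            class = "pumba_model")
}

#' @export
print.pumba_model <- function(x, ...) {
  cat(sprintf("<pumba_model> %d parameters, %d subjects x %d regions (%d cells)\n",
              length(x$parameters), length(x$subjects), length(x$regions),
              x$data$N))
  invisible(x)
}

# Inverse-Wishart hyperparameters matching the requested correlation shape
# and SD scale: nu = 2*eta + 2*d - 3 makes the implied marginal correlation
# density proportional to (1 - r^2)^(eta - 1 + (d - 2)/2), the LKJ(eta)
# marginal; the scale matrix is chosen so the prior mean variance (where
# defined) equals sd_scale^2.
iw_hyper <- function(d, eta, sd_scale) {
  nu <- 2 * eta + 2 * d - 3
  fac <- max(nu - d - 1, 1)
  list(S = diag(sd_scale^2 * fac, d), nu = nu)
}

jags_code <- function(spec, m, P, xnames) {
  pars <- spec$parameters
  mu_lines <- character(m)
  pooled_pos <- 0L
  for (i in seq_len(m)) {
    terms <- sprintf("alpha[%d]", i)
    if (length(xnames[[i]]))
      terms <- c(terms, sprintf("inprod(X_%d[c, 1:P_%d], beta_%d[1:P_%d])",
                                i, i, i, i))
    if (spec$pool_subjects)
      terms <- c(terms,
                 if (m >= 2) sprintf("tau[subj[c], %d]", i) else "tau[subj[c]]")
    if (spec$region_fixed[pars[i]]) {
      terms <- c(terms, sprintf("rfe_%d[reg[c]]", i))
    } else {
      pooled_pos <- pooled_pos + 1L
      terms <- c(terms, if (P >= 2) sprintf("ups[reg[c], %d]", pooled_pos)
                 else "ups1[reg[c]]")
    }
    lhs <- if (m >= 2) sprintf("mu[c, %d]", i) else "mu[c]"
    mu_lines[i] <- sprintf("    %s <- %s", lhs, paste(terms, collapse = " + "))
  }
  lik <- if (m >= 2)
    "    y[c, 1:M] ~ dmnorm(mu[c, 1:M], Omega_e[1:M, 1:M])"
  else
    "    y[c] ~ dnorm(mu[c], pow(sd_e1, -2))"

  blocks <- c("model {", "  for (c in 1:N) {", lik, mu_lines, "  }")

  if (spec$pool_subjects) {
    blocks <- c(blocks, if (m >= 2) c(
      "  for (j in 1:J) { tau[j, 1:M] ~ dmnorm(zero_m[1:M], Omega_s[1:M, 1:M]) }",
      "  Omega_s ~ dwish(Ss[1:M, 1:M], nu_s)")
      else c(
        "  for (j in 1:J) { tau[j] ~ dnorm(0, pow(sd_s1, -2)) }",
        "  sd_s1 ~ dnorm(0, pow(prior_sd_scale, -2)) T(0, )"))
  }
  if (P >= 2) {
    blocks <- c(blocks,
      sprintf("  for (k in 1:K) { ups[k, 1:%d] ~ dmnorm(zero_p[1:%d], Omega_r[1:%d, 1:%d]) }",
              P, P, P, P),
      sprintf("  Omega_r ~ dwish(Sr[1:%d, 1:%d], nu_r)", P, P))
  } else if (P == 1) {
    blocks <- c(blocks,
      "  for (k in 1:K) { ups1[k] ~ dnorm(0, pow(sd_r1, -2)) }",
      "  sd_r1 ~ dnorm(0, pow(prior_sd_scale, -2)) T(0, )")
  }
  for (i in seq_len(m)) {
    if (spec$region_fixed[pars[i]])
      blocks <- c(blocks, sprintf("  rfe_%d[1] <- 0", i),
        sprintf("  for (k in 2:K) { rfe_%d[k] ~ dnorm(0, prior_rfe_prec) }", i))
    if (length(xnames[[i]]))
      blocks <- c(blocks,
        sprintf("  for (p in 1:P_%d) { beta_%d[p] ~ dnorm(0, prior_beta_prec) }",
                i, i))
  }
  blocks <- c(blocks,
    sprintf("  for (i in 1:%d) { alpha[i] ~ dnorm(prior_alpha_mean[i], prior_alpha_prec) }",
            m))
  if (m >= 2) blocks <- c(blocks,
    "  Omega_e ~ dwish(Se[1:M, 1:M], nu_e)")
  else blocks <- c(blocks,
    "  sd_e1 ~ dnorm(0, pow(prior_sd_scale, -2)) T(0, )")
  paste(c(blocks, "}"), collapse = "\n")
}

#' Fit a PuMBA model by MCMC
#'
#' Runs the Gibbs-sampling backend on a compiled [build_pumba()] handle and
#' returns posterior summaries for the intercepts, covariate effects
#' (including the group difference), region effects, and the standard
#' deviations and correlations of every multivariate-normal hierarchy.
#' Results are deterministic given `seed`, `chains` and the iteration
#' settings.
#'
#' @param model A `pumba_model` handle.
#' @param chains Number of chains (default 4).
#' @param warmup Iterations discarded per chain (split between sampler
#'   adaptation and burn-in; default 1000).
#' @param sampling Retained iterations per chain (default 1000).
#' @param seed Integer seed; per-chain RNG seeds are derived from it.
#' @param rhat_threshold Convergence flag threshold on split-R-hat
#'   (default 1.01).
#' @param quiet Suppress backend progress output.
#' @return An object of class `pumba_fit` with elements `summary` (a tibble
#'   with columns `quantity`, `mean`, `sd`, `q2.5`, `q97.5`, `rhat`, `ess`),
#'   `converged`, `max_rhat` and `meta`. Divergence counts are an
#'   HMC-specific diagnostic and are reported as `NA` by this backend.
#' @export
fit_pumba <- function(model, chains = 4, warmup = 1000, sampling = 1000,
                      seed = 1, rhat_threshold = 1.01, quiet = TRUE) {
  if (!inherits(model, "pumba_model"))
    validation_error("model must come from build_pumba()")
  if (sampling < 2) validation_error("sampling iterations must be >= 2")
  adapt <- max(100L, as.integer(warmup) %/% 2L)
  burn <- max(as.integer(warmup) - adapt, 0L)
  inits <- lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (as.integer(seed) + ch * 1000003L) %% 2147483646L + 1L))
  jm <- rjags::jags.model(textConnection(model$code), data = model$data,
                          inits = inits, n.chains = chains, n.adapt = adapt,
                          quiet = quiet)
  if (burn > 0) update(jm, burn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, variable.names = model$monitors,
                              n.iter = sampling, progress.bar = "none")
  summ <- summarise_draws(samp, model)
  max_rhat <- suppressWarnings(max(summ$rhat, na.rm = TRUE))
  structure(list(summary = summ,
                 converged = is.finite(max_rhat) && max_rhat <= rhat_threshold,
                 max_rhat = max_rhat,
                 parameters = model$parameters,
                 binding = model$spec$binding,
                 meta = list(chains = chains, warmup = warmup,
                             sampling = sampling, seed = seed,
                             backend = sprintf("rjags %s (Gibbs)",
                                               utils::packageVersion("rjags")),
                             divergences = NA_integer_)),
            class = "pumba_fit")
}

#' @export
print.pumba_fit <- function(x, ...) {
  cat(sprintf("<pumba_fit> %d quantities; max R-hat %.3f (%s)\n",
              nrow(x$summary), x$max_rhat,
              if (x$converged) "converged" else "NOT converged"))
  print(x$summary, n = 20)
  invisible(x)
}

# -- posterior post-processing ------------------------------------------------

# split-R-hat over a list of per-chain draws for one scalar quantity
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

summarise_draws <- function(samp, model) {
  pars <- model$parameters
  m <- length(pars)
  # rename raw columns to quantity labels; NULL label drops the column
  label_of <- function(nm) {
    if (grepl("^alpha\\[", nm)) {
      i <- as.integer(sub("^alpha\\[(\\d+)\\]$", "\\1", nm))
      return(sprintf("alpha[%s]", pars[i]))
    }
    if (grepl("^beta_", nm)) {
      # single-element vector nodes are reported without an index
      i <- as.integer(sub("^beta_(\\d+).*$", "\\1", nm))
      p <- if (grepl("\\[", nm))
        as.integer(sub(".*\\[(\\d+)\\]$", "\\1", nm)) else 1L
      return(sprintf("beta[%s:%s]", pars[i], model$xnames[[i]][p]))
    }
    if (grepl("^rfe_", nm)) {
      i <- as.integer(sub("^rfe_(\\d+).*$", "\\1", nm))
      k <- if (grepl("\\[", nm))
        as.integer(sub(".*\\[(\\d+)\\]$", "\\1", nm)) else 1L
      if (k == 1) return(NULL)  # reference region, structurally zero
      return(sprintf("rfe[%s:%s]", pars[i], model$regions[k]))
    }
    if (nm == "sd_e1") return(sprintf("sd_resid[%s]", pars[1]))
    if (nm == "sd_s1") return(sprintf("sd_subject[%s]", pars[1]))
    if (nm == "sd_r1") return(sprintf("sd_region[%s]", model$pooled[1]))
    NULL
  }

  mats <- lapply(samp, as.matrix)
  cn <- colnames(mats[[1]])
  out <- list()
  add_quantity <- function(label, chains) {
    x <- unlist(chains)
    out[[length(out) + 1]] <<- tibble::tibble(
      quantity = label, mean = mean(x), sd = sd(x),
      q2.5 = unname(quantile(x, 0.025)), q97.5 = unname(quantile(x, 0.975)),
      rhat = split_rhat(chains),
      ess = tryCatch(sum(vapply(chains, function(v)
        coda::effectiveSize(coda::mcmc(v)), numeric(1))),
        error = function(e) NA_real_))
  }

  for (nm in cn) {
    lab <- label_of(nm)
    if (is.null(lab)) next
    add_quantity(lab, lapply(mats, function(mm) mm[, nm]))
  }

  # hierarchy covariance draws -> SD and correlation summaries
  add_cov_block <- function(prefix, dim, names, tag) {
    idx <- outer(seq_len(dim), seq_len(dim),
                 function(i, j) sprintf("%s[%d,%d]", prefix, i, j))
    if (!all(idx %in% cn)) return(invisible(NULL))
    per_chain <- lapply(mats, function(mm) {
      ndraw <- nrow(mm)
      sds <- matrix(0, ndraw, dim)
      cors <- matrix(0, ndraw, dim * (dim - 1) / 2)
      for (d in seq_len(ndraw)) {
        Om <- matrix(mm[d, idx], dim, dim)
        Sg <- tryCatch(solve(Om), error = function(e) diag(NA_real_, dim))
        sds[d, ] <- sqrt(diag(Sg))
        R <- stats::cov2cor(Sg)
        cors[d, ] <- R[lower.tri(R)]
      }
      list(sds = sds, cors = cors)
    })
    for (i in seq_len(dim))
      add_quantity(sprintf("sd_%s[%s]", tag, names[i]),
                   lapply(per_chain, function(pc) pc$sds[, i]))
    pair <- which(lower.tri(diag(dim)), arr.ind = TRUE)
    for (q in seq_len(nrow(pair)))
      add_quantity(sprintf("cor_%s[%s,%s]", tag,
                           names[pair[q, 2]], names[pair[q, 1]]),
                   lapply(per_chain, function(pc) pc$cors[, q]))
  }
  if (m >= 2) add_cov_block("Omega_e", m, pars, "resid")
  if (m >= 2 && model$spec$pool_subjects)
    add_cov_block("Omega_s", m, pars, "subject")
  if (length(model$pooled) >= 2)
    add_cov_block("Omega_r", length(model$pooled), model$pooled, "region")

  do.call(rbind, out)
}

#' Extract the estimated group difference from a fitted model
#'
#' Pulls the posterior summary of the group coefficient for the requested
#' parameter: the log-scale group difference, its posterior SD (reported as
#' the standard error of the estimate), and the equal-tailed 95% credible
#' interval.
#'
#' @param fit A `pumba_fit`.
#' @param parameter Parameter name (defaults to the spec's binding parameter).
#' @return A list with `estimate`, `se`, `ci_low`, `ci_high` and
#'   `percent` (the estimate converted via [percent_difference()]).
#' @export
extract_group_difference <- function(fit, parameter = NULL) {
  if (!inherits(fit, "pumba_fit"))
    validation_error("fit must be a pumba_fit")
  parameter <- parameter %||% fit$binding
  if (is.null(parameter))
    validation_error("no parameter given and the spec declares no binding parameter")
  rows <- grep(sprintf("^beta\\[%s:group", parameter), fit$summary$quantity)
  if (length(rows) != 1)
    validation_error("parameter %s has no (unique) group coefficient",
                     parameter)
  s <- fit$summary[rows, ]
  list(estimate = s$mean, se = s$sd, ci_low = s$q2.5, ci_high = s$q97.5,
       percent = percent_difference(s$mean))
}

#' Convert a log-scale difference to a percent difference
#'
#' A difference of `d` on the natural-log scale corresponds to a
#' \eqn{100 (e^d - 1)} percent difference on the original scale; e.g.
#' `d = 0.1` is a 10.5% group difference and `d = 0.182` is 20%.
#'
#' @param d Log-scale difference(s).
#' @return Percent difference(s).
#' @export
percent_difference <- function(d) 100 * (exp(d) - 1)
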