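#' Specification of a PuMBA hierarchical model
#'
#' Declares which PK parameters enter the joint model, the covariate formula
#' for each, which parameters receive pooled region deviations versus
#' per-region fixed effects, and the priors. The binding and blood-delivery
#' parameters default to per-region fixed effects: regional differences in
#' delivery and binding are too heterogeneous for a common distribution,
#' whereas the remaining parameters are pooled across regions.
#'
#' The parameter columns of the data table must be named `log<parameter>`
#' (e.g. `logBPP`) and hold natural-log-scale values.
#'
#' @param parameters Character vector of PK parameter names (length `m >= 1`).
#' @param formulas Named list of right-hand-side formulas, one entry per
#'   parameter that has covariates (e.g. `list(BPP = ~ group)`); parameters
#'   without an entry get an intercept-only design.
#' @param region_fixed Named logical vector: `TRUE` for per-region fixed
#'   effects, `FALSE` for pooled multivariate-normal region deviations.
#'   Missing entries default per `binding`/`delivery` to `TRUE` and otherwise
#'   to `FALSE`.
#' @param binding,delivery Names of the binding and blood-delivery parameters.
#' @param priors A `pumba_priors` object from [default_priors()].
#' @param pool_subjects Logical; `FALSE` drops the subject hierarchy entirely
#'   (mainly useful for degenerate single-parameter checks).
#' @return An object of class `pumba_spec`.
#' @examples
#' pr <- default_priors(c(K1 = 0.35, VND = 1.4, BPP = 1.5, k4 = 0.06))
#' spec <- pumba_spec(c("K1", "VND", "BPP", "k4"),
#'                    formulas = list(BPP = ~ group),
#'                    binding = "BPP", delivery = "K1", priors = pr)
#' @export
pumba_spec <- function(parameters, formulas = list(), region_fixed = NULL,
                       binding = NULL, delivery = NULL, priors,
                       pool_subjects = TRUE) {
  if (length(parameters) < 1) validation_error("at least one parameter")
  if (anyDuplicated(parameters)) validation_error("duplicate parameter names")
  if (!inherits(priors, "pumba_priors"))
    validation_error("priors must come from default_priors()")
  missing_prior <- setdiff(parameters, names(priors$intercept_mean))
  if (length(missing_prior))
    validation_error("no prior central value for parameter(s): %s",
                     paste(missing_prior, collapse = ", "))
  bad <- setdiff(names(formulas), parameters)
  if (length(bad))
    validation_error("formula given for unknown parameter(s): %s",
                     paste(bad, collapse = ", "))
  rf <- setNames(rep(FALSE, length(parameters)), parameters)
  rf[intersect(c(binding, delivery), parameters)] <- TRUE
  if (!is.null(region_fixed)) {
    bad <- setdiff(names(region_fixed), parameters)
    if (length(bad))
      validation_error("region_fixed names unknown: %s",
                       paste(bad, collapse = ", "))
    rf[names(region_fixed)] <- region_fixed
  }
  structure(list(parameters = parameters,
                 formulas = formulas,
                 region_fixed = rf,
                 binding = binding,
                 delivery = delivery,
                 priors = priors,
                 pool_subjects = isTRUE(pool_subjects)),
            class = "pumba_spec")
}

#' @export
print.pumba_spec <- function(x, ...) {
  cat(sprintf("<pumba_spec> %d parameters: %s\n", length(x$parameters),
              paste(x$parameters, collapse = ", ")))
  cat("  region fixed effects:",
      paste(names(x$region_fixed)[x$region_fixed], collapse = ", "), "\n")
  for (p in names(x$formulas))
    cat(sprintf("  %s: %s\n", p, deparse(x$formulas[[p]])))
  invisible(x)
}

#' Read or write a model specification as YAML
#'
#' Serialises a [pumba_spec()] (including priors) to a YAML file and back.
#' Formulas are stored as Wilkinson-style strings.
#'
#' @param spec A `pumba_spec`.
#' @param path File path.
#' @return `write_spec_yaml` returns `path` invisibly; `read_spec_yaml`
#'   returns a `pumba_spec`.
#' @export
write_spec_yaml <- function(spec, path) {
  pr <- spec$priors
  obj <- list(
    parameters = spec$parameters,
    formulas = lapply(spec$formulas, function(f) deparse(f)),
    region_fixed = as.list(spec$region_fixed),
    binding = spec$binding,
    delivery = spec$delivery,
    pool_subjects = spec$pool_subjects,
    priors = list(central_values = as.list(exp(pr$intercept_mean)),
                  intercept_sd = pr$intercept_sd, beta_sd = pr$beta_sd,
                  sd_scale = pr$sd_scale, lkj_eta = pr$lkj_eta,
                  region_fe_sd = pr$region_fe_sd))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_spec_yaml
#' @export
read_spec_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  pr <- do.call(default_priors,
                c(list(central_values = unlist(obj$priors$central_values)),
                  obj$priors[c("intercept_sd", "beta_sd", "sd_scale",
                               "lkj_eta", "region_fe_sd")]))
  pumba_spec(parameters = unlist(obj$parameters),
             formulas = lapply(obj$formulas, function(s) stats::as.formula(s)),
             region_fixed = unlist(obj$region_fixed),
             binding = obj$binding, delivery = obj$delivery,
             priors = pr, pool_subjects = obj$pool_subjects)
}
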