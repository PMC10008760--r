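#' Linear mixed-effects comparator analysis
#'
#' The conventional univariate reference analysis: a linear mixed-effects
#' model on the natural-log binding parameter across all regions, with group
#' and region as fixed effects and subject as the only random effect
#' (random intercept), fitted by REML. Inference on the group coefficient is
#' by Wald 95% confidence interval.
#'
#' @param table Parameter table with columns `subject`, `region`, `group`
#'   (factor, reference level first) and `log<binding_parameter>`.
#' @param binding_parameter Name of the binding parameter (e.g. `"BPP"`).
#' @return A one-row tibble of class `univariate_result` with columns
#'   `method`, `region` (`"all"`), `estimate`, `se`, `ci_low`, `ci_high`,
#'   `p_value`, `singular`.
#' @export
fit_lme <- function(table, binding_parameter) {
  table <- as.data.frame(table)
  ycol <- paste0("log", binding_parameter)
  if (!ycol %in% names(table))
    validation_error("table lacks column %s", ycol)
  if (!all(c("subject", "region", "group") %in% names(table)))
    validation_error("table needs subject, region and group columns")
  table$group <- as.factor(table$group)
  if (nlevels(table$group) != 2)
    validation_error("group must have exactly two levels")
  table$.y <- table[[ycol]]
  multi_region <- length(unique(table$region)) > 1
  form <- if (multi_region) .y ~ group + region + (1 | subject)
          else .y ~ group + (1 | subject)
  fit <- tryCatch(suppressMessages(lme4::lmer(form, data = table,
                                              REML = TRUE)),
                  error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate subject grouping (e.g. one observation per subject):
    # the mixed model collapses to its fixed-effect part
    warning("subject random effect is degenerate; reporting the fixed-effects fit")
    fit <- if (multi_region) stats::lm(.y ~ group + region, data = table)
           else stats::lm(.y ~ group, data = table)
    singular <- TRUE
  } else {
    singular <- lme4::isSingular(fit)
    if (singular)
      warning("singular random-effect fit; Wald inference reported anyway")
  }
  co <- summary(fit)$coefficients
  row <- grep("^group", rownames(co))[1]
  est <- co[row, "Estimate"]; se <- co[row, "Std. Error"]
  z <- qnorm(0.975)
  res <- tibble::tibble(method = "lme", region = "all",
                        estimate = est, se = se,
                        ci_low = est - z * se, ci_high = est + z * se,
                        p_value = 2 * pnorm(-abs(est / se)),
                        singular = singular)
  class(res) <- c("univariate_result", class(res))
  res
}

#' Per-region Welch t-test comparator analysis
#'
#' Welch two-sample t-tests on the natural-log binding parameter, one per
#' region, comparing the second group level against the first (so the
#' estimate is `mean(group 2) - mean(group 1)` on the log scale, matching the
#' sign convention of the group coefficients elsewhere). Regions with fewer
#' than two subjects in either group are skipped with a warning.
#'
#' @inheritParams fit_lme
#' @return A tibble of class `univariate_result`, one row per region.
#' @export
ttest_by_region <- function(table, binding_parameter) {
  table <- as.data.frame(table)
  ycol <- paste0("log", binding_parameter)
  if (!ycol %in% names(table))
    validation_error("table lacks column %s", ycol)
  table$group <- as.factor(table$group)
  if (nlevels(table$group) != 2)
    validation_error("group must have exactly two levels")
  g2 <- levels(table$group)[2]
  rows <- lapply(sort(unique(as.character(table$region))), function(r) {
    d <- table[table$region == r, ]
    x <- d[[ycol]][d$group == g2]
    y <- d[[ycol]][d$group != g2]
    if (length(x) < 2 || length(y) < 2) {
      warning(sprintf("region %s has < 2 subjects in a group; skipped", r))
      return(NULL)
    }
    tt <- t.test(x, y)
    tibble::tibble(method = "ttest", region = r,
                   estimate = unname(tt$estimate[1] - tt$estimate[2]),
                   se = unname(tt$stderr),
                   ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
                   p_value = tt$p.value, singular = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) validation_error("no region had enough data for a t-test")
  class(res) <- c("univariate_result", class(res))
  res
}
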