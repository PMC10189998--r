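#' Test group-wise residual means against zero
#'
#' Sensitivity analysis of the fitted allometric-thermal model: do the
#' residuals of any species (or habitat-preference) group deviate
#' systematically from zero, which would indicate group-specific responses
#' the mass-and-temperature model misses?
#'
#' Fits the zero-intercept linear model `residual ~ 0 + group`, so each
#' coefficient is literally that group's mean residual, tested against zero
#' by a two-sided t-test with the pooled residual variance. No multiplicity
#' adjustment is applied to the reported `p_value`; a Bonferroni-adjusted
#' column is included for transparency.
#'
#' @param residual_table Data.frame from [residual_table()] (needs a
#'   `residual` column and the grouping column).
#' @param grouping Name of the grouping column, e.g. `"species"` or
#'   `"habitat_group"`.
#' @param coding `"means"` (default; zero-intercept, coefficients are group
#'   means) or `"treatment"` (standard intercept coding, coefficients are
#'   contrasts against the first group).
#' @return Data.frame with one row per group: `grouping`, `group`, `n`,
#'   `mean_residual`, `std_error`, `t_stat`, `p_value`, `p_bonferroni`.
#'   Groups with a single observation are reported with NA standard error and
#'   p-value (with a warning).
#' @export
group_residual_test <- function(residual_table, grouping = "species",
                                coding = c("means", "treatment")) {
  coding <- match.arg(coding)
  if (!grouping %in% names(residual_table)) {
    stop("residual table has no column '", grouping, "'")
  }
  if (!"residual" %in% names(residual_table)) {
    stop("residual table has no 'residual' column")
  }
  tab <- residual_table[is.finite(residual_table$residual), , drop = FALSE]
  if (nrow(tab) == 0) stop("residual table is empty")
  g <- factor(tab[[grouping]])
  fit <- if (coding == "means") {
    stats::lm(tab$residual ~ 0 + g)
  } else {
    stats::lm(tab$residual ~ g)
  }
  sm <- summary(fit)$coefficients
  counts <- table(g)
  lev <- levels(g)
  # map coefficient rows back to group labels
  rowname_for <- if (coding == "means") paste0("g", lev) else
    c("(Intercept)", paste0("g", lev[-1]))
  out <- data.frame(
    grouping = grouping,
    group = lev,
    n = as.integer(counts[lev]),
    mean_residual = NA_real_,
    std_error = NA_real_,
    t_stat = NA_real_,
    p_value = NA_real_,
    stringsAsFactors = FALSE
  )
  idx <- match(rowname_for, rownames(sm))
  out$mean_residual <- sm[idx, "Estimate"]
  out$std_error <- sm[idx, "Std. Error"]
  out$t_stat <- sm[idx, "t value"]
  out$p_value <- sm[idx, "Pr(>|t|)"]
  if (coding == "means") {
    singletons <- out$n == 1
    if (any(singletons)) {
      warning("group(s) with a single observation reported without SE/p: ",
              paste(out$group[singletons], collapse = ", "))
      out$std_error[singletons] <- NA_real_
      out$t_stat[singletons] <- NA_real_
      out$p_value[singletons] <- NA_real_
    }
  }
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  rownames(out) <- NULL
  out
}
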