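#' Two-step MR mediation analysis
#'
#' The mediation machinery decomposes the total causal effect of an exposure
#' on an outcome (`beta1`, log-odds scale for binary outcomes) into the part
#' transmitted through a mediator and the remainder:
#'
#' * step 1 — `beta1`: univariable IVW of the outcome on the exposure's
#'   instruments, and `beta2`: univariable IVW of the *mediator* on the same
#'   instruments;
#' * step 2 — `beta3`: the mediator's coefficient from a multivariable IVW of
#'   the outcome on mediator and exposure jointly, using the mediator's
#'   instruments (the mediator's effect adjusted for the exposure);
#' * decomposition — indirect = `beta2 * beta3`, direct = `beta1 - beta2*beta3`,
#'   proportion mediated = 100 * indirect / beta1.
#'
#' @name mediation
NULL

#' Total effect of exposure on outcome
#'
#' Univariable IVW (`model = "auto"`: multiplicative random effects when
#' Cochran's Q is significant) on instruments selected for the exposure.
#'
#' @param h a [harmonized_set] of exposure instruments against the outcome.
#' @return An `mr_result` (beta1).
#' @export
mr_total_effect <- function(h) mr_ivw(h, model = "auto")

#' Effect of exposure on mediator
#'
#' Univariable IVW of the mediator on the exposure's instruments.
#'
#' @param h a [harmonized_set] of exposure instruments against the mediator
#'   (the mediator panel plays the outcome role).
#' @return An `mr_result` (beta2).
#' @export
mr_exposure_to_mediator <- function(h) mr_ivw(h, model = "auto")

#' Effect of mediator on outcome adjusted for exposure
#'
#' The mediator's coefficient from a K = 2 multivariable IVW: the outcome
#' regressed jointly on the mediator's and the exposure's SNP effects over
#' the mediator's instruments.
#'
#' @param h a [harmonized_set] whose `gamma` column holds the *mediator's*
#'   SNP effects and whose single `mediators` entry holds the exposure's
#'   (i.e. build it with `harmonize(mediator_panel, outcome_panel,
#'   mediators = list(exposure = exposure_panel))`).
#' @return An `mr_result` (beta3): the first (mediator) coefficient.
#' @export
mr_mediator_to_outcome_adjusted <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  if (is.null(h$mediators) || length(h$mediators) != 1) {
    validation_error("expected exactly one adjustment column (the exposure)")
  }
  fit <- mr_mvmr(h)
  fit[[1]]  # design column 1 = h$gamma = the mediator's effects
}

#' Mediation decomposition
#'
#' Combines the three path estimates into direct and indirect effects and
#' the proportion mediated. By construction `direct + indirect == beta1`
#' exactly. When `beta1 == 0` the proportion is undefined (returned as `NA`
#' with `proportion_defined = FALSE`); proportions outside \[0, 100\]%
#' (inconsistent mediation, i.e. indirect and total effects of opposite sign
#' or indirect exceeding total) are reported as computed and flagged via
#' `consistent = FALSE`, never truncated.
#'
#' @param beta1 total effect of exposure on outcome.
#' @param beta2 effect of exposure on mediator.
#' @param beta3 effect of mediator on outcome adjusted for exposure.
#' @param component_results optional named list of the underlying
#'   `mr_result`s (`beta1`, `beta2`, `beta3`).
#' @param exposure,mediator,outcome optional trait labels.
#' @return An object of class `mediation_result` with fields `beta1`,
#'   `beta2`, `beta3`, `direct`, `indirect`, `proportion_mediated` (percent),
#'   `proportion_defined`, `consistent`, `component_results`.
#' @examples
#' # a worked decomposition: total -2.304 with indirect -0.274
#' decompose_mediation(-2.304, 1, -0.274)
#' @export
decompose_mediation <- function(beta1, beta2, beta3, component_results = NULL,
                                exposure = NA_character_, mediator = NA_character_,
                                outcome = NA_character_) {
  stopifnot(is.numeric(beta1), is.numeric(beta2), is.numeric(beta3))
  indirect <- beta2 * beta3
  direct <- beta1 - indirect
  defined <- beta1 != 0
  proportion <- if (defined) 100 * indirect / beta1 else NA_real_
  structure(
    list(
      beta1 = beta1, beta2 = beta2, beta3 = beta3,
      direct = direct, indirect = indirect,
      proportion_mediated = proportion,
      proportion_defined = defined,
      consistent = isTRUE(defined && proportion >= 0 && proportion <= 100),
      component_results = component_results,
      exposure = exposure, mediator = mediator, outcome = outcome
    ),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, digits = 4, ...) {
  cat("<mediation_result>\n")
  if (!is.na(x$exposure)) {
    cat(sprintf("  %s -> %s via %s\n", x$exposure, x$outcome, x$mediator))
  }
  cat(sprintf("  total %s = direct %s + indirect %s\n",
              format(x$beta1, digits = digits), format(x$direct, digits = digits),
              format(x$indirect, digits = digits)))
  if (x$proportion_defined) {
    cat(sprintf("  proportion mediated: %.2f%%%s\n", x$proportion_mediated,
                if (x$consistent) "" else " (inconsistent mediation)"))
  } else {
    cat("  proportion mediated undefined (total effect is zero)\n")
  }
  invisible(x)
}

#' @export
coef.mediation_result <- function(object, ...) {
  c(beta1 = object$beta1, beta2 = object$beta2, beta3 = object$beta3,
    direct = object$direct, indirect = object$indirect)
}

# Instrument set for the multivariable step: union of each trait's selected
# instruments, restricted to SNPs present in every contributing panel
# (complete case).
mvmr_instrument_union <- function(selected_panels, all_panels) {
  ids <- unique(unlist(lapply(selected_panels, function(p) p$snp_id)))
  present <- Reduce(intersect, lapply(all_panels, `[[`, "snp_id"))
  ids[ids %in% present]
}

#' Run the full two-step mediation analysis
#'
#' Orchestrates instrument selection for the exposure and the mediator
#' separately, the three path estimations, and the decomposition:
#' exposure instruments (after confounder exclusion) give `beta1` against
#' the outcome and `beta2` against the mediator; the union of the mediator's
#' and exposure's instruments (complete-case across panels) feeds the
#' multivariable step for `beta3`. Instrument counts per step are recorded
#' in the result's `log`.
#'
#' @param exposure,mediator,outcome `summary_panel` objects.
#' @param ld an [ld_info] covering all candidate instruments.
#' @param catalog a [confounder_catalog].
#' @param config an [iv_config].
#' @param palindromic_eaf_window passed to [harmonize()].
#' @return A `mediation_result`; `$log` holds per-step instrument counts and
#'   audits.
#' @export
run_mediation <- function(exposure, mediator, outcome, ld, catalog,
                          config = iv_config(),
                          palindromic_eaf_window = c(0.42, 0.58)) {
  step <- function(label, expr) {
    tryCatch(expr, mrmediate_error = function(e) {
      mrm_error(sprintf("mediation step '%s' failed: %s", label,
                        conditionMessage(e)), class(e)[1])
    })
  }
  sel_exp <- step("select exposure instruments",
                  select_instruments(exposure, ld, catalog, config))
  sel_med <- step("select mediator instruments",
                  select_instruments(mediator, ld, catalog, config))

  h1 <- step("harmonize exposure vs outcome",
             harmonize(sel_exp$panel, outcome,
                       palindromic_eaf_window = palindromic_eaf_window))
  b1 <- step("total effect (beta1)", mr_total_effect(h1))

  h2 <- step("harmonize exposure vs mediator",
             harmonize(sel_exp$panel, mediator,
                       palindromic_eaf_window = palindromic_eaf_window))
  b2 <- step("exposure on mediator (beta2)", mr_exposure_to_mediator(h2))

  union_ids <- mvmr_instrument_union(
    list(sel_med$panel, sel_exp$panel),
    list(mediator, exposure, outcome)
  )
  if (length(union_ids) == 0) {
    empty_instrument_error("mediation step 'multivariable instruments': no union instruments present in all panels")
  }
  med_sub <- panel_subset(mediator, union_ids)
  h3 <- step("harmonize mediator + exposure vs outcome",
             harmonize(med_sub, outcome,
                       mediators = list(exposure = panel_subset(exposure, union_ids)),
                       palindromic_eaf_window = palindromic_eaf_window))
  b3 <- step("mediator on outcome adjusted (beta3)",
             mr_mediator_to_outcome_adjusted(h3))

  res <- decompose_mediation(
    b1$estimate, b2$estimate, b3$estimate,
    component_results = list(beta1 = b1, beta2 = b2, beta3 = b3),
    exposure = trait_name(exposure), mediator = trait_name(mediator),
    outcome = trait_name(outcome)
  )
  res$log <- list(
    exposure_audit = sel_exp$audit, mediator_audit = sel_med$audit,
    n_snp_beta1 = b1$n_snp, n_snp_beta2 = b2$n_snp, n_snp_beta3 = b3$n_snp
  )
  res
}

#' Bootstrap interval for the proportion mediated
#'
#' Optional parametric bootstrap: the three path estimates are redrawn from
#' normal distributions centred at their point estimates with their standard
#' errors, and the decomposition recomputed. Off by default because the
#' primary report is the point decomposition.
#'
#' @param result a `mediation_result` with `component_results` present.
#' @param n_boot replicates (default 1000).
#' @param seed RNG seed.
#' @param level interval coverage (default 0.95).
#' @return Named numeric: `low`, `high` percent bounds for the proportion
#'   mediated.
#' @export
mediation_proportion_ci <- function(result, n_boot = 1000, seed = 1, level = 0.95) {
  stopifnot(inherits(result, "mediation_result"))
  cr <- result$component_results
  if (is.null(cr)) validation_error("component_results required for the bootstrap")
  props <- with_seed(seed, {
    b1 <- stats::rnorm(n_boot, cr$beta1$estimate, cr$beta1$se)
    b2 <- stats::rnorm(n_boot, cr$beta2$estimate, cr$beta2$se)
    b3 <- stats::rnorm(n_boot, cr$beta3$estimate, cr$beta3$se)
    100 * (b2 * b3) / b1
  })
  qs <- stats::quantile(props, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  c(low = qs[1], high = qs[2])
}
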