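#' Effect-scale transforms
#'
#' `beta_to_or()` maps a log-odds effect to an odds ratio (`exp(beta)`);
#' `or_to_beta()` is its inverse. Both are vectorized.
#'
#' @param beta log-odds effect(s).
#' @param or odds ratio(s), > 0.
#' @return Numeric vector.
#' @examples
#' beta_to_or(0.392)  # 1.480 to 3 dp
#' @export
beta_to_or <- function(beta) exp(beta)

#' @rdname beta_to_or
#' @export
or_to_beta <- function(or) {
  if (any(or <= 0)) validation_error("odds ratios must be > 0")
  log(or)
}

#' 95% confidence bounds on the beta and odds-ratio scales
#'
#' Normal-theory bounds `beta +/- 1.959964 se`, with the odds-ratio bounds
#' obtained by exponentiation (so the OR interval is exactly the exp of the
#' beta interval).
#'
#' @param beta point estimate (log-odds scale).
#' @param se standard error, > 0.
#' @return A named list: `beta_low`, `beta_high`, `or_low`, `or_high`.
#' @examples
#' ci_from_beta_se(0.392, (0.515 - 0.269) / (2 * qnorm(0.975)))
#' @export
ci_from_beta_se <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) validation_error("se must be > 0")
  low <- beta - Z975 * se
  high <- beta + Z975 * se
  list(beta_low = low, beta_high = high,
       or_low = exp(low), or_high = exp(high))
}

#' Family-wise significance labeling
#'
#' Bonferroni-style labeling for a family of `family_size` outcomes tested
#' at family-wise level `alpha`: an association is `significant` when
#' `p < alpha/family_size` (strict), `suggestive` when
#' `alpha/family_size <= p < alpha`, and `null` otherwise. With the default
#' family of nine outcomes at alpha 0.05 the Bonferroni threshold is
#' 0.05/9 = 0.0056 (4 dp). (Some reports quote the suggestive band loosely
#' as "p > 0.005"; this implementation uses the exact threshold
#' `alpha/family_size` as the band's lower edge, so the boundary p lands in
#' `suggestive`.)
#'
#' @param family_size number of outcomes in the tested family (>= 1).
#' @param alpha family-wise error level in (0, 1).
#' @return `significance_config()` returns a config object;
#'   `bonferroni_threshold()` the computed per-test threshold;
#'   `classify_significance()` a character vector of labels.
#' @export
significance_config <- function(family_size = 9, alpha = 0.05) {
  if (!is_count(family_size) || family_size < 1) {
    validation_error("family_size must be a positive count")
  }
  if (!(alpha > 0 && alpha < 1)) validation_error("alpha must lie in (0, 1)")
  structure(list(family_size = as.integer(family_size), alpha = alpha),
            class = "significance_config")
}

#' @rdname significance_config
#' @param config a `significance_config`.
#' @export
bonferroni_threshold <- function(config = significance_config()) {
  config$alpha / config$family_size
}

#' @rdname significance_config
#' @param pval p-value(s) in (0, 1].
#' @export
classify_significance <- function(pval, config = significance_config()) {
  if (any(!is.finite(pval)) || any(pval <= 0) || any(pval > 1)) {
    validation_error("pval must lie in (0, 1]")
  }
  thr <- bonferroni_threshold(config)
  ifelse(pval < thr, "significant",
         ifelse(pval < config$alpha, "suggestive", "null"))
}

round_sig <- function(p, digits = 3) signif(p, digits)

#' Forest-style results table
#'
#' Flattens a collection of `mr_result` and/or `mediation_result` objects
#' into one deterministic delimited-ready table: one row per
#' exposure-outcome-method combination, ordered by (exposure, outcome,
#' method) regardless of input order. MR rows carry estimate/OR/CI/p/label,
#' instrument count, heterogeneity and the model note; mediation rows
#' additionally carry total/direct/indirect effects and the proportion
#' mediated. Estimates and ORs are rounded to 3 decimals, proportions to 2,
#' p-values to 3 significant figures (full precision lives in the JSON
#' serializers).
#'
#' @param results a list of `mr_result`/`mediation_result` objects.
#' @param config a [significance_config] for the labels.
#' @return A data.frame; zero rows (with a warning) for empty input.
#' @export
forest_table <- function(results, config = significance_config()) {
  cols <- c("exposure", "outcome", "method", "n_snp", "estimate", "or",
            "ci_low", "ci_high", "or_low", "or_high", "pval", "label",
            "q_stat", "q_pval", "model_note",
            "total", "direct", "indirect", "proportion_mediated")
  if (inherits(results, c("mr_result", "mediation_result"))) results <- list(results)
  if (length(results) == 0) {
    warning("empty result collection: empty report")
    out <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)), cols))
    return(out)
  }
  rows <- lapply(results, function(r) {
    if (inherits(r, "mr_result")) {
      data.frame(
        exposure = r$exposure %||% NA_character_, outcome = r$outcome,
        method = r$method, n_snp = r$n_snp,
        estimate = round(r$estimate, 3), or = round(exp(r$estimate), 3),
        ci_low = round(r$ci_low, 3), ci_high = round(r$ci_high, 3),
        or_low = round(exp(r$ci_low), 3), or_high = round(exp(r$ci_high), 3),
        pval = round_sig(r$pval), label = classify_significance(min(max(r$pval, 1e-300), 1), config),
        q_stat = round(r$q_stat, 3), q_pval = round_sig(r$q_pval),
        model_note = r$model_note,
        total = NA_real_, direct = NA_real_, indirect = NA_real_,
        proportion_mediated = NA_real_, stringsAsFactors = FALSE
      )
    } else if (inherits(r, "mediation_result")) {
      b1 <- r$component_results$beta1
      data.frame(
        exposure = r$exposure, outcome = r$outcome,
        method = sprintf("mediation[%s]", r$mediator),
        n_snp = if (is.null(b1)) NA_integer_ else b1$n_snp,
        estimate = round(r$beta1, 3), or = round(exp(r$beta1), 3),
        ci_low = NA_real_, ci_high = NA_real_, or_low = NA_real_,
        or_high = NA_real_,
        pval = if (is.null(b1)) NA_real_ else round_sig(b1$pval),
        label = if (is.null(b1)) NA_character_ else {
          classify_significance(min(max(b1$pval, 1e-300), 1), config)
        },
        q_stat = NA_real_, q_pval = NA_real_, model_note = NA_character_,
        total = round(r$beta1, 3), direct = round(r$direct, 3),
        indirect = round(r$indirect, 3),
        proportion_mediated = round(r$proportion_mediated, 2),
        stringsAsFactors = FALSE
      )
    } else {
      validation_error("forest_table accepts mr_result and mediation_result objects")
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$exposure, out$outcome, out$method, method = "radix",
                   na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a forest table as a tab-separated report
#'
#' @param results passed to [forest_table()].
#' @param path output file path.
#' @param config a [significance_config].
#' @return Invisibly, `path`.
#' @export
write_forest_table <- function(results, path, config = significance_config()) {
  tab <- forest_table(results, config)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
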