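#' @title MR result objects
#' @description Every estimator returns an `mr_result`: the causal estimate
#' (per unit exposure, on the outcome scale — log-odds for binary outcomes),
#' its standard error, 95% confidence bounds, two-sided p-value, Cochran's Q
#' heterogeneity diagnostics, and (for MR-Egger) the intercept test for
#' directional pleiotropy.
#' @param method estimator label.
#' @param n_snp number of instruments J.
#' @param estimate,se point estimate and standard error.
#' @param pval two-sided p-value.
#' @param q_stat,q_df,q_pval heterogeneity statistic, df, p (NA when J
#'   precludes them).
#' @param egger_intercept,egger_intercept_se,egger_intercept_pval MR-Egger
#'   intercept fields (NA unless `method = "egger"`).
#' @param model_note free-text note recording e.g. the fixed- vs
#'   multiplicative-random-effects choice and why.
#' @param data optional list of the harmonized arrays used (kept for
#'   `plot()`/`residuals()`).
#' @param exposure,outcome optional trait labels for reporting.
#' @return An object of class `mr_result`.
#' @keywords internal
new_mr_result <- function(method, n_snp, estimate, se, pval,
                          q_stat = NA_real_, q_df = NA_real_, q_pval = NA_real_,
                          egger_intercept = NA_real_,
                          egger_intercept_se = NA_real_,
                          egger_intercept_pval = NA_real_,
                          model_note = NA_character_, data = NULL,
                          exposure = NA_character_, outcome = NA_character_) {
  structure(
    list(
      method = method, n_snp = n_snp,
      estimate = estimate, se = se,
      ci_low = estimate - Z975 * se, ci_high = estimate + Z975 * se,
      pval = pval,
      q_stat = q_stat, q_df = q_df, q_pval = q_pval,
      egger_intercept = egger_intercept,
      egger_intercept_se = egger_intercept_se,
      egger_intercept_pval = egger_intercept_pval,
      model_note = model_note, data = data,
      exposure = exposure, outcome = outcome
    ),
    class = "mr_result"
  )
}

#' @export
print.mr_result <- function(x, digits = 4, ...) {
  cat(sprintf("<mr_result> method: %s, instruments: %d\n", x$method, x$n_snp))
  cat(sprintf("  estimate %s (se %s), 95%% CI [%s, %s], p = %s\n",
              format(x$estimate, digits = digits), format(x$se, digits = digits),
              format(x$ci_low, digits = digits), format(x$ci_high, digits = digits),
              format(x$pval, digits = 3)))
  if (!is.na(x$q_stat)) {
    cat(sprintf("  Cochran's Q = %s on %d df, p = %s\n",
                format(x$q_stat, digits = digits), x$q_df,
                format(x$q_pval, digits = 3)))
  }
  if (identical(x$method, "egger")) {
    cat(sprintf("  Egger intercept %s (se %s), p = %s\n",
                format(x$egger_intercept, digits = digits),
                format(x$egger_intercept_se, digits = digits),
                format(x$egger_intercept_pval, digits = 3)))
  }
  if (!is.na(x$model_note)) cat("  note:", x$model_note, "\n")
  invisible(x)
}

#' @export
coef.mr_result <- function(object, ...) {
  stats::setNames(object$estimate, object$method)
}

#' @export
confint.mr_result <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(c(object$estimate - z * object$se, object$estimate + z * object$se),
              nrow = 1,
              dimnames = list(object$method,
                              sprintf("%g %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)))
  m
}

#' @export
summary.mr_result <- function(object, ...) {
  out <- data.frame(
    method = object$method, n_snp = object$n_snp,
    estimate = object$estimate, se = object$se,
    ci_low = object$ci_low, ci_high = object$ci_high,
    or = exp(object$estimate), or_low = exp(object$ci_low),
    or_high = exp(object$ci_high), pval = object$pval,
    q_stat = object$q_stat, q_df = object$q_df, q_pval = object$q_pval,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' @export
residuals.mr_result <- function(object, ...) {
  d <- object$data
  if (is.null(d)) return(NULL)
  fitted <- object$estimate * d$gamma +
    if (is.na(object$egger_intercept)) 0 else object$egger_intercept
  stats::setNames(d$Gamma - fitted, d$snp_ids)
}

#' @export
plot.mr_result <- function(x, ...) {
  d <- x$data
  if (is.null(d)) stop("no per-SNP data stored in this result")
  graphics::plot(d$gamma, d$Gamma,
                 xlab = "SNP-exposure effect", ylab = "SNP-outcome effect",
                 main = sprintf("%s estimate = %.3f", x$method, x$estimate), ...)
  graphics::segments(d$gamma, d$Gamma - Z975 * d$se_Gamma,
                     d$gamma, d$Gamma + Z975 * d$se_Gamma, col = "grey60")
  intercept <- if (is.na(x$egger_intercept)) 0 else x$egger_intercept
  graphics::abline(a = intercept, b = x$estimate, col = "firebrick")
  invisible(x)
}

#' Wald ratio for a single instrument
#'
#' The per-SNP causal estimate: the SNP-outcome effect divided by the
#' SNP-exposure effect, with the first-order standard error
#' `se_Gamma / |gamma|` (which ignores uncertainty in `gamma`; the
#' no-measurement-error assumption standard in summary-data MR).
#'
#' @param gamma,se_gamma SNP-exposure effect and SE (`gamma` must be nonzero).
#' @param Gamma,se_Gamma SNP-outcome effect and SE.
#' @return An [new_mr_result()] with `method = "wald"`.
#' @examples
#' wald_ratio(0.1, 0.005, 0.05, 0.01)  # estimate 0.5, se 0.1
#' @export
wald_ratio <- function(gamma, se_gamma, Gamma, se_Gamma) {
  if (gamma == 0) {
    mrm_error("Wald ratio undefined for gamma = 0", "mrmediate_undefined_ratio")
  }
  if (se_Gamma <= 0) validation_error("se_Gamma must be > 0")
  est <- Gamma / gamma
  se <- se_Gamma / abs(gamma)
  new_mr_result(
    method = "wald", n_snp = 1L, estimate = est, se = se,
    pval = 2 * stats::pnorm(-abs(est / se))
  )
}

ivw_theta <- function(gamma, Gamma, w) {
  sum(w * gamma * Gamma) / sum(w * gamma^2)
}

#' Inverse-variance-weighted estimator
#'
#' The primary two-sample MR estimator: a weighted regression of SNP-outcome
#' effects on SNP-exposure effects through the origin, with weights
#' `1/se_Gamma^2` — equivalently the inverse-variance meta-analysis of the
#' per-SNP Wald ratios. `model = "fe"` uses the fixed-effect standard error
#' `(sum w gamma^2)^(-1/2)`; `model = "mre"` (multiplicative random effects)
#' inflates it by `max(1, sqrt(Q/(J-1)))` to absorb heterogeneity.
#' `model = "auto"` follows the convention of switching to multiplicative
#' random effects exactly when Cochran's Q is significant at p < 0.05, and
#' records the choice in `model_note`.
#'
#' @param h a [harmonized_set] (J >= 1; J >= 2 for `"mre"`).
#' @param model `"auto"`, `"fe"` or `"mre"`.
#' @return An `mr_result` with method `"ivw_fe"` or `"ivw_mre"`.
#' @export
mr_ivw <- function(h, model = c("auto", "fe", "mre")) {
  model <- match.arg(model)
  stopifnot(inherits(h, "harmonized_set"))
  J <- length(h$snp_ids)
  if (J == 0) empty_instrument_error("IVW requires at least one instrument")
  if (J < 2 && model == "mre") {
    insufficient_instruments_error(2, J, "multiplicative random effects IVW")
  }
  w <- 1 / h$se_Gamma^2
  theta <- ivw_theta(h$gamma, h$Gamma, w)
  se_fe <- sqrt(1 / sum(w * h$gamma^2))
  Q <- sum(w * (h$Gamma - theta * h$gamma)^2)
  if (J >= 2) {
    q_df <- J - 1
    q_pval <- stats::pchisq(Q, df = q_df, lower.tail = FALSE)
  } else {
    q_df <- NA_real_
    q_pval <- NA_real_
  }
  use_mre <- switch(model,
    fe = FALSE,
    mre = TRUE,
    auto = isTRUE(q_pval < 0.05)
  )
  note <- switch(model,
    fe = "fixed effects (requested)",
    mre = "multiplicative random effects (requested)",
    auto = if (use_mre) {
      sprintf("multiplicative random effects (Q p = %.3g < 0.05)", q_pval)
    } else if (J >= 2) {
      sprintf("fixed effects (Q p = %.3g >= 0.05)", q_pval)
    } else {
      "fixed effects (single instrument)"
    }
  )
  se <- if (use_mre) se_fe * max(1, sqrt(Q / (J - 1))) else se_fe
  new_mr_result(
    method = if (use_mre) "ivw_mre" else "ivw_fe",
    n_snp = J, estimate = theta, se = se,
    pval = 2 * stats::pnorm(-abs(theta / se)),
    q_stat = if (J >= 2) Q else NA_real_, q_df = q_df, q_pval = q_pval,
    model_note = note,
    data = h[c("snp_ids", "gamma", "se_gamma", "Gamma", "se_Gamma")]
  )
}

#' Cochran's Q heterogeneity test
#'
#' Q = sum of `w_j (Gamma_j - theta * gamma_j)^2` with IVW weights
#' `w_j = 1/se_Gamma_j^2`, referred to a chi-square with J - 1 degrees of
#' freedom. Q is zero exactly when all per-SNP Wald ratios agree.
#'
#' @param h a [harmonized_set] with J >= 2.
#' @param theta the causal estimate around which to measure dispersion
#'   (defaults to the IVW estimate of `h`).
#' @return A list with `q`, `df`, `pval`.
#' @export
cochran_q <- function(h, theta = NULL) {
  stopifnot(inherits(h, "harmonized_set"))
  J <- length(h$snp_ids)
  if (J < 2) insufficient_instruments_error(2, J, "Cochran's Q")
  w <- 1 / h$se_Gamma^2
  if (is.null(theta)) theta <- ivw_theta(h$gamma, h$Gamma, w)
  q <- sum(w * (h$Gamma - theta * h$gamma)^2)
  list(q = q, df = J - 1, pval = stats::pchisq(q, df = J - 1, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted least squares of SNP-outcome effects on SNP-exposure effects
#' *with* an intercept, after orienting every pair so the exposure effect is
#' non-negative (flipping both signs where needed — the fit is invariant to
#' the original orientation). The slope estimates the causal effect under
#' the weaker InSIDE assumption; a non-zero intercept indicates directional
#' pleiotropy. Both standard errors are inflated by
#' `max(1, sqrt(RSS_w/(J-2)))` and p-values use a t reference with J - 2 df.
#'
#' @param h a [harmonized_set] with J >= 3.
#' @return An `mr_result` with method `"egger"` and the intercept fields set.
#' @export
mr_egger <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  J <- length(h$snp_ids)
  if (J < 3) insufficient_instruments_error(3, J, "MR-Egger")
  s <- ifelse(h$gamma < 0, -1, 1)
  x <- s * h$gamma
  y <- s * h$Gamma
  w <- 1 / h$se_Gamma^2
  X <- cbind(intercept = 1, slope = x)
  XtWX <- crossprod(X, w * X)
  if (abs(det(XtWX)) < .Machine$double.eps * max(abs(XtWX))^2) {
    mrm_error("degenerate design in MR-Egger (constant exposure effects?)",
              "mrmediate_collinearity")
  }
  cov_unscaled <- solve(XtWX)
  betas <- drop(cov_unscaled %*% crossprod(X, w * y))
  rss_w <- sum(w * (y - drop(X %*% betas))^2)
  scale <- max(1, sqrt(rss_w / (J - 2)))
  ses <- sqrt(diag(cov_unscaled)) * scale
  tvals <- betas / ses
  pvals <- 2 * stats::pt(-abs(tvals), df = J - 2)
  new_mr_result(
    method = "egger", n_snp = J,
    estimate = betas[["slope"]], se = ses[["slope"]], pval = pvals[["slope"]],
    q_stat = rss_w, q_df = J - 2,
    q_pval = stats::pchisq(rss_w, df = J - 2, lower.tail = FALSE),
    egger_intercept = betas[["intercept"]],
    egger_intercept_se = ses[["intercept"]],
    egger_intercept_pval = pvals[["intercept"]],
    data = list(snp_ids = h$snp_ids, gamma = x, se_gamma = h$se_gamma,
                Gamma = y, se_Gamma = h$se_Gamma)
  )
}

weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  stats::approx(p, theta, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median estimator
#'
#' The weighted median of the per-SNP Wald ratios, with inverse-variance
#' weights `(se_Gamma/|gamma|)^(-2)`: consistent as long as instruments
#' carrying at least half of the total weight are valid. The point estimate
#' interpolates the ratio against the cumulative weight midpoints at 0.5;
#' the standard error is the standard deviation of the estimate over seeded
#' parametric-bootstrap replicates (exposure and outcome effects resampled
#' from normal distributions centred at the observed values).
#'
#' @param h a [harmonized_set] with J >= 3 and no zero exposure effects.
#' @param n_boot bootstrap replicates for the SE (default 1000).
#' @param seed RNG seed for the bootstrap (recorded in `model_note`).
#' @return An `mr_result` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1) {
  stopifnot(inherits(h, "harmonized_set"))
  J <- length(h$snp_ids)
  if (J < 3) insufficient_instruments_error(3, J, "weighted median")
  if (any(h$gamma == 0)) {
    mrm_error("weighted median undefined with zero exposure effects",
              "mrmediate_undefined_ratio")
  }
  theta_j <- h$Gamma / h$gamma
  w <- (h$se_Gamma / abs(h$gamma))^-2
  est <- weighted_median_point(theta_j, w)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      g <- stats::rnorm(J, h$gamma, h$se_gamma)
      G <- stats::rnorm(J, h$Gamma, h$se_Gamma)
      g[g == 0] <- .Machine$double.eps
      weighted_median_point(G / g, (h$se_Gamma / abs(g))^-2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  new_mr_result(
    method = "weighted_median", n_snp = J, estimate = est, se = se,
    pval = 2 * stats::pnorm(-abs(est / se)),
    model_note = sprintf("bootstrap SE, n_boot = %d, seed = %d", n_boot, seed),
    data = h[c("snp_ids", "gamma", "se_gamma", "Gamma", "se_Gamma")]
  )
}

#' MR-PRESSO outlier detection and correction
#'
#' Residual-sum-of-squares outlier search for pleiotropic instruments. For
#' each SNP the IVW slope is recomputed leaving that SNP out; its weighted
#' squared residual about that leave-one-out slope contributes to the
#' observed global statistic. The null distribution comes from `n_sim`
#' parametric simulations (outcome effects redrawn about the leave-one-out
#' fitted values with their observed SEs, statistic recomputed in full).
#' Empirical p-values use the add-one rule `(1 + b)/(1 + n_sim)` so they are
#' never zero; per-SNP outliers are flagged at the Bonferroni-adjusted level
#' `outlier_alpha / J` and the corrected IVW estimate refits without them.
#'
#' @param h a [harmonized_set] with J >= 4.
#' @param n_sim number of null simulations (default 1000).
#' @param seed RNG seed (recorded in the result).
#' @param outlier_alpha family-wise level for outlier flagging (default 0.05).
#' @return An object of class `mr_presso_result`: `global_rss_obs`,
#'   `global_pval`, `outlier_snp_ids`, `outlier_pvals` (all SNPs' empirical
#'   p-values), `corrected` (IVW after outlier removal), `raw` (IVW on all
#'   instruments), `n_sim`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, seed = 1, outlier_alpha = 0.05) {
  stopifnot(inherits(h, "harmonized_set"))
  J <- length(h$snp_ids)
  if (J < 4) insufficient_instruments_error(4, J, "MR-PRESSO")
  g <- h$gamma
  G <- h$Gamma
  seG <- h$se_Gamma
  w <- 1 / seG^2
  sxy <- sum(w * g * G)
  sxx <- sum(w * g^2)
  theta_loo <- (sxy - w * g * G) / (sxx - w * g^2)
  rss_obs_j <- w * (G - theta_loo * g)^2
  global_obs <- sum(rss_obs_j)

  sims <- with_seed(seed, {
    # n_sim x J draws about the leave-one-out fitted values; column j of the
    # rep(..., each = n_sim) matrices is constant at the j-th SNP's value
    wg <- w * g
    Gs <- matrix(stats::rnorm(n_sim * J, mean = rep(theta_loo * g, each = n_sim),
                              sd = rep(seG, each = n_sim)), nrow = n_sim)
    sxy_s <- drop(Gs %*% wg)                                    # length n_sim
    theta_loo_s <- (sxy_s - Gs * rep(wg, each = n_sim)) /
      rep(sxx - wg * g, each = n_sim)                           # n_sim x J
    resid <- Gs - theta_loo_s * rep(g, each = n_sim)
    rss_s <- resid^2 * rep(w, each = n_sim)                     # n_sim x J
    list(global = rowSums(rss_s), per_snp = rss_s)
  })
  global_pval <- (1 + sum(sims$global >= global_obs)) / (n_sim + 1)
  per_snp_pvals <- vapply(seq_len(J), function(j) {
    (1 + sum(sims$per_snp[, j] >= rss_obs_j[j])) / (n_sim + 1)
  }, numeric(1))
  flagged <- which(per_snp_pvals < outlier_alpha / J)
  corrected <- if (length(flagged) && length(flagged) < J) {
    keep <- setdiff(seq_len(J), flagged)
    mr_ivw(harmonized_set(h$snp_ids[keep], g[keep], h$se_gamma[keep],
                          G[keep], seG[keep]), model = "auto")
  } else {
    mr_ivw(h, model = "auto")
  }
  structure(
    list(
      global_rss_obs = global_obs, global_pval = global_pval,
      outlier_snp_ids = h$snp_ids[flagged],
      outlier_pvals = stats::setNames(per_snp_pvals, h$snp_ids),
      corrected = corrected, raw = mr_ivw(h, model = "auto"),
      n_sim = n_sim, seed = seed, outlier_alpha = outlier_alpha
    ),
    class = "mr_presso_result"
  )
}

#' @export
print.mr_presso_result <- function(x, ...) {
  cat(sprintf("<mr_presso_result> global RSS = %.4g, global p = %.4g (n_sim = %d, seed = %d)\n",
              x$global_rss_obs, x$global_pval, x$n_sim, x$seed))
  if (length(x$outlier_snp_ids)) {
    cat("  outliers:", paste(x$outlier_snp_ids, collapse = ", "), "\n")
  } else {
    cat("  no outliers flagged\n")
  }
  cat("  corrected "); print(x$corrected, ...)
  invisible(x)
}

#' Multivariable IVW regression
#'
#' Weighted least squares of the SNP-outcome effects on K exposure/mediator
#' effect columns jointly, with no intercept and weights `1/se_Gamma^2`.
#' Each coefficient is the direct effect of its exposure conditional on the
#' others. Per-coefficient standard errors are inflated by
#' `max(1, sqrt(RSS_w/(J-K)))`; p-values use the standard normal.
#'
#' @param h a [harmonized_set] whose `mediators` field supplies the
#'   additional effect columns (design = exposure `gamma` plus each mediator
#'   beta column), **or** a plain numeric matrix of K columns when `Gamma`
#'   and `se_Gamma` are given.
#' @param Gamma,se_Gamma outcome effects and SEs (only when `h` is a matrix).
#' @return A named list of `mr_result` objects (method `"mvmr_ivw"`), one
#'   per design column, each with `q_df = J - K`; of class `mr_mvmr_result`.
#' @export
mr_mvmr <- function(h, Gamma = NULL, se_Gamma = NULL) {
  if (inherits(h, "harmonized_set")) {
    if (is.null(h$mediators) || length(h$mediators) < 1) {
      validation_error("multivariable IVW needs at least one mediator column in h")
    }
    X <- cbind(exposure = h$gamma,
               do.call(cbind, lapply(h$mediators, `[[`, "beta")))
    colnames(X) <- make.unique(c("exposure", names(h$mediators)))
    Gamma <- h$Gamma
    se_Gamma <- h$se_Gamma
  } else {
    X <- as.matrix(h)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    stopifnot(!is.null(Gamma), !is.null(se_Gamma))
  }
  J <- nrow(X)
  K <- ncol(X)
  if (K < 2) validation_error("multivariable IVW needs K >= 2 columns")
  if (J <= K) {
    mrm_error(sprintf("under-identified: J = %d instruments for K = %d exposures", J, K),
              "mrmediate_underidentified")
  }
  if (any(se_Gamma <= 0)) validation_error("se_Gamma must be > 0")
  w <- 1 / se_Gamma^2
  # identically-zero columns carry no information and are excluded from the
  # solve (their coefficients are reported NA); any remaining rank deficiency
  # is a genuine collinearity error
  zero_col <- colSums(abs(X)) == 0
  Xa <- X[, !zero_col, drop = FALSE]
  if (ncol(Xa) == 0 || qr(sqrt(w) * Xa)$rank < ncol(Xa)) {
    mrm_error("rank-deficient multivariable design (collinear columns)",
              "mrmediate_collinearity")
  }
  XtWX <- crossprod(Xa, w * Xa)
  cov_unscaled <- solve(XtWX)
  betas_a <- drop(cov_unscaled %*% crossprod(Xa, w * Gamma))
  names(betas_a) <- colnames(Xa)
  rss_w <- sum(w * (Gamma - drop(Xa %*% betas_a))^2)
  q_df <- J - ncol(Xa)
  scale <- max(1, sqrt(rss_w / q_df))
  ses_a <- sqrt(diag(cov_unscaled)) * scale
  names(ses_a) <- colnames(Xa)
  q_pval <- stats::pchisq(rss_w, df = q_df, lower.tail = FALSE)
  out <- lapply(colnames(X), function(nm) {
    if (zero_col[[nm]]) {
      return(new_mr_result(
        method = "mvmr_ivw", n_snp = J, estimate = NA_real_, se = NA_real_,
        pval = NA_real_, q_stat = rss_w, q_df = q_df, q_pval = q_pval,
        model_note = sprintf("'%s' aliased (all-zero effect column)", nm)
      ))
    }
    b <- betas_a[[nm]]
    s <- ses_a[[nm]]
    new_mr_result(
      method = "mvmr_ivw", n_snp = J, estimate = b, se = s,
      pval = 2 * stats::pnorm(-abs(b / s)),
      q_stat = rss_w, q_df = q_df, q_pval = q_pval,
      model_note = sprintf("coefficient for '%s' adjusted for %s", nm,
                           paste(setdiff(colnames(X), nm), collapse = ", "))
    )
  })
  names(out) <- colnames(X)
  structure(out, class = "mr_mvmr_result")
}

#' @export
print.mr_mvmr_result <- function(x, ...) {
  cat(sprintf("<mr_mvmr_result> %d exposures, %d instruments\n",
              length(x), x[[1]]$n_snp))
  for (nm in names(x)) {
    r <- x[[nm]]
    cat(sprintf("  %-12s %8.4f (se %.4f), p = %.3g\n", nm, r$estimate, r$se, r$pval))
  }
  invisible(x)
}

#' Serialize MR results
#'
#' `mr_result_json()` renders one or more results as a JSON array of records
#' (method, n_snp, estimate, se, ci, pval, heterogeneity and intercept
#' fields); `mr_result_table()` flattens them to a data.frame, one row per
#' result.
#'
#' @param results an `mr_result` or a list of them.
#' @param path optional file to write the JSON to.
#' @return JSON string (invisibly, if written to `path`) or a data.frame.
#' @export
mr_result_json <- function(results, path = NULL) {
  txt <- jsonlite::toJSON(mr_result_table(results), digits = NA, na = "null",
                          auto_unbox = FALSE, dataframe = "rows")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname mr_result_json
#' @export
mr_result_table <- function(results) {
  if (inherits(results, "mr_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    data.frame(
      exposure = r$exposure, outcome = r$outcome, method = r$method,
      n_snp = r$n_snp, estimate = r$estimate, se = r$se,
      ci_low = r$ci_low, ci_high = r$ci_high, pval = r$pval,
      q_stat = r$q_stat, q_df = r$q_df, q_pval = r$q_pval,
      egger_intercept = r$egger_intercept,
      egger_intercept_se = r$egger_intercept_se,
      egger_intercept_pval = r$egger_intercept_pval,
      model_note = r$model_note, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
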