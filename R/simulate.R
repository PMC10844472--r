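#' Generating parameters for synthetic GWAS summary statistics
#'
#' Encodes the causal diagram the mediation analysis assumes: every SNP has
#' a direct effect `gamma_j` on the exposure; the mediator responds to the
#' exposure with slope `tau` and carries SNP-specific genetic effects of its
#' own (`mediator_effect_sd`); the outcome (binary, log-odds scale) receives
#' `theta_direct` per unit exposure, `beta3` per unit mediator, and — for a
#' fraction `prop_invalid` of instruments — a direct pleiotropic effect
#' drawn from Normal(`pleiotropy_mean`, `pleiotropy_sd`^2). The implied
#' total exposure-outcome effect is `theta_direct + tau * beta3`.
#'
#' Observed effects add sampling noise with standard errors from the
#' large-sample approximation `se ~ 1/sqrt(2 maf (1-maf) n v)`, `v = 1` for
#' continuous traits and `v = cf (1-cf)` for a binary outcome with case
#' fraction `cf`.
#'
#' @param n_snp number of SNPs J.
#' @param maf_range minor-allele-frequency range, a sub-interval of (0, 0.5].
#' @param theta_direct direct exposure-outcome effect (log-odds per unit).
#' @param tau exposure-mediator effect.
#' @param beta3 mediator-outcome effect (log-odds per unit).
#' @param pleiotropy_mean,pleiotropy_sd distribution of direct SNP-outcome
#'   effects for invalid instruments (mean 0 = balanced, nonzero =
#'   directional).
#' @param prop_invalid fraction of instruments carrying pleiotropy, in \[0,1\].
#' @param mediator_effect_sd SD of SNP-specific mediator effects (makes the
#'   mediator's genetic signal distinguishable from `tau * gamma_j`).
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes.
#' @param outcome_case_fraction case fraction of the binary outcome GWAS.
#' @param seed RNG seed; identical seeds give identical panels.
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(n_snp = 50, maf_range = c(0.1, 0.4),
                             theta_direct = 0, tau = 0, beta3 = 0,
                             pleiotropy_mean = 0, pleiotropy_sd = 0,
                             prop_invalid = 0, mediator_effect_sd = 0.03,
                             n_exposure = 350000, n_mediator = 300000,
                             n_outcome = 200000, outcome_case_fraction = 0.25,
                             seed = 1) {
  if (!is_count(n_snp) || n_snp < 1) validation_error("n_snp must be a positive count")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    validation_error("maf_range must be within (0, 0.5]")
  }
  if (prop_invalid < 0 || prop_invalid > 1) validation_error("prop_invalid must lie in [0, 1]")
  for (n in c(n_exposure, n_mediator, n_outcome)) {
    if (!(n > 0)) validation_error("sample sizes must be > 0")
  }
  if (outcome_case_fraction <= 0 || outcome_case_fraction >= 1) {
    validation_error("outcome_case_fraction must lie in (0, 1)")
  }
  if (pleiotropy_sd < 0 || mediator_effect_sd < 0) {
    validation_error("standard deviations must be >= 0")
  }
  structure(
    list(n_snp = as.integer(n_snp), maf_range = maf_range,
         theta_direct = theta_direct, tau = tau, beta3 = beta3,
         pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
         prop_invalid = prop_invalid, mediator_effect_sd = mediator_effect_sd,
         n_exposure = n_exposure, n_mediator = n_mediator,
         n_outcome = n_outcome, outcome_case_fraction = outcome_case_fraction,
         seed = as.integer(seed)),
    class = "simulation_truth"
  )
}

# exposure-effect magnitudes: uniform on this range so that at the default
# sample sizes every true instrument clears genome-wide significance
GAMMA_MAG_RANGE <- c(0.03, 0.08)

# non-palindromic allele pairs used for simulated variants
ALLELE_PAIRS <- rbind(
  c("A", "G"), c("G", "A"), c("A", "C"), c("C", "A"),
  c("T", "G"), c("G", "T"), c("T", "C"), c("C", "T")
)

se_approx <- function(maf, n, v = 1) 1 / sqrt(2 * maf * (1 - maf) * n * v)

two_sided_p <- function(beta, se) {
  pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300)
}

#' Simulate exposure, mediator and outcome summary panels
#'
#' Draws one synthetic three-trait GWAS summary dataset under a
#' [simulation_truth]: per-SNP true effects following the encoded causal
#' structure, observed effects with sampling noise, per-SNP standard errors
#' from sample size and allele frequency, and two-sided normal p-values.
#' Variants are placed more than one clumping window apart (25 Mb spacing on
#' chromosomes 1-22), so the default instruments are mutually unlinked; LD
#' structure for clumping tests is built with dedicated fixtures instead.
#'
#' @param truth a [simulation_truth].
#' @param confounder_snp_ids optional SNP ids to mark in the returned
#'   catalog as strongly associated (p = 1e-9) with a confounder trait.
#' @return A list: `exposure`, `mediator`, `outcome` (summary panels), `ld`
#'   (an [ld_info] with no linked pairs), `catalog` (a
#'   [confounder_catalog]), `truth`, and `latent` (the per-SNP true effects:
#'   `gamma`, `mediator_beta`, `Gamma`, `invalid_ids`, `maf`).
#' @export
simulate_panels <- function(truth, confounder_snp_ids = character(0)) {
  stopifnot(inherits(truth, "simulation_truth"))
  J <- truth$n_snp
  with_seed(truth$seed, {
    maf <- stats::runif(J, truth$maf_range[1], truth$maf_range[2])
    # effect alleles oriented to the exposure-increasing allele, as an
    # exposure GWAS reports its lead variants; directional pleiotropy is
    # defined relative to this orientation
    gamma_true <- stats::runif(J, GAMMA_MAG_RANGE[1], GAMMA_MAG_RANGE[2])
    delta <- if (truth$mediator_effect_sd > 0) {
      stats::rnorm(J, 0, truth$mediator_effect_sd)
    } else {
      numeric(J)
    }
    m_true <- truth$tau * gamma_true + delta
    n_invalid <- round(truth$prop_invalid * J)
    invalid <- if (n_invalid > 0) sample.int(J, n_invalid) else integer(0)
    alpha <- numeric(J)
    if (n_invalid > 0) {
      alpha[invalid] <- stats::rnorm(n_invalid, truth$pleiotropy_mean,
                                     truth$pleiotropy_sd)
    }
    Gamma_true <- truth$theta_direct * gamma_true + truth$beta3 * m_true + alpha

    se_exp <- se_approx(maf, truth$n_exposure)
    se_med <- se_approx(maf, truth$n_mediator)
    cf <- truth$outcome_case_fraction
    se_out <- se_approx(maf, truth$n_outcome, cf * (1 - cf))

    beta_exp <- stats::rnorm(J, gamma_true, se_exp)
    beta_med <- stats::rnorm(J, m_true, se_med)
    beta_out <- stats::rnorm(J, Gamma_true, se_out)

    snp_id <- sprintf("rs%05d", seq_len(J))
    chrom <- as.character(((seq_len(J) - 1) %% 22) + 1)
    pos <- 1e6 + ((seq_len(J) - 1) %/% 22) * 2.5e7
    pair <- ALLELE_PAIRS[sample.int(nrow(ALLELE_PAIRS), J, replace = TRUE), ,
                         drop = FALSE]

    base <- data.frame(
      snp_id = snp_id, chrom = chrom, pos = pos,
      effect_allele = pair[, 1], other_allele = pair[, 2],
      eaf = maf, stringsAsFactors = FALSE
    )
    mk <- function(beta, se, n, name, type) {
      rec <- base
      rec$beta <- beta
      rec$se <- se
      rec$pval <- two_sided_p(beta, se)
      rec$n <- n
      summary_panel(rec, name, type)
    }
    catalog_df <- if (length(confounder_snp_ids)) {
      data.frame(snp_id = confounder_snp_ids, trait = "confounder",
                 pval = 1e-9, stringsAsFactors = FALSE)
    } else {
      data.frame(snp_id = character(), trait = character(), pval = numeric())
    }
    list(
      exposure = mk(beta_exp, se_exp, truth$n_exposure, "exposure", "continuous"),
      mediator = mk(beta_med, se_med, truth$n_mediator, "mediator", "continuous"),
      outcome = mk(beta_out, se_out, truth$n_outcome, "outcome", "binary"),
      ld = ld_info(base[c("snp_id", "chrom", "pos")]),
      catalog = confounder_catalog(catalog_df),
      truth = truth,
      latent = list(gamma = gamma_true, mediator_beta = m_true,
                    Gamma = Gamma_true, invalid_ids = snp_id[invalid],
                    maf = maf)
    )
  })
}

#' Plant outlier instruments in a simulated dataset
#'
#' Displaces `k` randomly chosen outcome betas by `displacement` times their
#' standard error (recomputing those rows' p-values), to exercise outlier
#' detection.
#'
#' @param sim the list returned by [simulate_panels()].
#' @param k number of outliers to plant (must be < J).
#' @param displacement shift in units of the outcome SE.
#' @param seed RNG seed for choosing which SNPs to displace.
#' @return A list: `sim` (with the modified outcome panel) and `planted_ids`.
#' @export
plant_outliers <- function(sim, k, displacement, seed = 1) {
  J <- nrow(sim$outcome)
  if (!is_count(k)) validation_error("k must be a non-negative count")
  if (k >= J) validation_error("k must be smaller than the number of SNPs")
  if (k == 0) return(list(sim = sim, planted_ids = character(0)))
  idx <- with_seed(seed, sample.int(J, k))
  out <- as.data.frame(sim$outcome)
  out$beta[idx] <- out$beta[idx] + displacement * out$se[idx]
  out$pval[idx] <- two_sided_p(out$beta[idx], out$se[idx])
  sim$outcome <- summary_panel(out, trait_name(sim$outcome), trait_type(sim$outcome))
  list(sim = sim, planted_ids = sim$outcome$snp_id[sort(idx)])
}

#' Harmonized set straight from a simulated dataset
#'
#' Convenience for estimator-level studies: builds the [harmonized_set] of
#' all simulated SNPs against the outcome (or the mediator), skipping
#' selection. Valid because simulated panels share allele coding by
#' construction.
#'
#' @param sim the list returned by [simulate_panels()].
#' @param outcome `"outcome"` or `"mediator"`: which panel plays the outcome
#'   role.
#' @return A [harmonized_set].
#' @export
sim_harmonized <- function(sim, outcome = c("outcome", "mediator")) {
  outcome <- match.arg(outcome)
  out <- sim[[outcome]]
  harmonized_set(sim$exposure$snp_id, sim$exposure$beta, sim$exposure$se,
                 out$beta, out$se)
}

#' Serialize simulation truth as JSON
#'
#' @param truth a [simulation_truth].
#' @param path optional output file.
#' @return The JSON string (invisibly when written to `path`).
#' @export
truth_json <- function(truth, path = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  txt <- jsonlite::toJSON(unclass(truth), digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
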