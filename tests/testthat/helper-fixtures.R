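# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# Quick panel: defaults give valid, mutually distant, non-palindromic SNPs.
make_panel <- function(n = 3, snp_id = sprintf("rs%03d", seq_len(n)),
                       chrom = rep("1", n),
                       pos = seq(1e6, by = 2e7, length.out = n),
                       effect_allele = rep("A", n), other_allele = rep("G", n),
                       eaf = rep(0.3, n), beta = rep(0.05, n),
                       se = rep(0.005, n), pval = rep(1e-10, n),
                       n_samples = rep(1e5, n),
                       trait = "exposure", type = "continuous") {
  summary_panel(
    data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
               effect_allele = effect_allele, other_allele = other_allele,
               eaf = eaf, beta = beta, se = se, pval = pval, n = n_samples,
               stringsAsFactors = FALSE),
    trait, type
  )
}

# Harmonized set with explicit arrays (defaults: exact proportional effects).
make_hset <- function(gamma, Gamma, se_Gamma, se_gamma = rep(1e-4, length(gamma)),
                      ids = sprintf("rs%03d", seq_along(gamma)), ...) {
  harmonized_set(ids, gamma, se_gamma, Gamma, se_Gamma, ...)
}

# Direct draw of a harmonized set under a linear model with optional
# per-SNP pleiotropy: Gamma_true = theta * gamma + alpha. Exposure effects
# positive (oriented), observed with sampling noise.
draw_hset <- function(J, theta, se_gamma = 0.003, se_Gamma = 0.008,
                      alpha = numeric(J)) {
  gamma <- stats::runif(J, 0.03, 0.08)
  g_obs <- stats::rnorm(J, gamma, se_gamma)
  G_obs <- stats::rnorm(J, theta * gamma + alpha, se_Gamma)
  make_hset(g_obs, G_obs, rep(se_Gamma, J), se_gamma = rep(se_gamma, J))
}

expect_mrm_error <- function(expr, class) {
  expect_error(expr, class = class)
}
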