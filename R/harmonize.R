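#' Allele-aligned multi-trait effect sets
#'
#' A harmonized set holds, for an ordered set of SNPs shared across traits,
#' the per-SNP effects on the exposure (`gamma`), on the outcome (`Gamma`)
#' and optionally on one or more mediators, all expressed for the *same*
#' effect allele (the exposure panel's). This is the input container for
#' every MR estimator in the package.
#'
#' @param snp_ids character vector of SNP identifiers (unique).
#' @param gamma,se_gamma numeric vectors: SNP-exposure effects and SEs.
#' @param Gamma,se_Gamma numeric vectors: SNP-outcome effects and SEs
#'   (log-odds scale for binary outcomes).
#' @param mediators optional named list; each element a list with numeric
#'   `beta` and `se` vectors aligned to `snp_ids`.
#' @param provenance optional data.frame of per-SNP harmonization flags.
#' @return An object of class `harmonized_set`.
#' @export
harmonized_set <- function(snp_ids, gamma, se_gamma, Gamma, se_Gamma,
                           mediators = NULL, provenance = NULL) {
  J <- length(snp_ids)
  if (J < 1) empty_instrument_error("harmonized set must contain at least one SNP")
  lens <- c(length(gamma), length(se_gamma), length(Gamma), length(se_Gamma))
  if (any(lens != J)) validation_error("all effect/SE vectors must have length equal to snp_ids")
  if (anyDuplicated(snp_ids)) validation_error("snp_ids must be unique")
  if (any(!is.finite(se_gamma)) || any(se_gamma <= 0)) validation_error("se_gamma must be > 0")
  if (any(!is.finite(se_Gamma)) || any(se_Gamma <= 0)) validation_error("se_Gamma must be > 0")
  if (!is.null(mediators)) {
    if (is.null(names(mediators)) || any(names(mediators) == "")) {
      validation_error("mediators must be a named list")
    }
    for (nm in names(mediators)) {
      m <- mediators[[nm]]
      if (length(m$beta) != J || length(m$se) != J) {
        validation_error(sprintf("mediator '%s' arrays must have length %d", nm, J))
      }
      if (any(!is.finite(m$se)) || any(m$se <= 0)) {
        validation_error(sprintf("mediator '%s' SEs must be > 0", nm))
      }
    }
  }
  structure(
    list(
      snp_ids = as.character(snp_ids),
      gamma = as.numeric(gamma), se_gamma = as.numeric(se_gamma),
      Gamma = as.numeric(Gamma), se_Gamma = as.numeric(se_Gamma),
      mediators = mediators, provenance = provenance
    ),
    class = "harmonized_set"
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %d SNP(s), %d mediator column(s)\n",
              length(x$snp_ids), length(x$mediators)))
  if (!is.null(x$provenance)) {
    tab <- table(x$provenance$flag)
    cat("provenance:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.harmonized_set <- function(x) length(x$snp_ids)

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) COMPLEMENT[a1] == a2

# Alignment of one panel's rows to the exposure's allele coding.
# Returns action per row: unchanged | allele_flipped | eaf_inferred |
# dropped_palindromic | dropped_mismatch. eaf_inferred marks palindromic SNPs
# whose orientation was resolved by allele-frequency comparison (the flip, if
# any, is applied).
align_to_exposure <- function(exp_ea, exp_oa, exp_eaf, pan_ea, pan_oa, pan_eaf,
                              window) {
  n <- length(exp_ea)
  action <- character(n)
  flip <- logical(n)
  pal <- is_palindromic(exp_ea, exp_oa)

  for (i in seq_len(n)) {
    ea <- pan_ea[i]; oa <- pan_oa[i]
    same_pair <- (ea == exp_ea[i] && oa == exp_oa[i])
    swap_pair <- (ea == exp_oa[i] && oa == exp_ea[i])
    if (pal[i]) {
      # same variant iff the panel's alleles are the same palindromic pair;
      # strand is unknowable from labels, so orientation comes from EAF
      if (!(same_pair || swap_pair)) { action[i] <- "dropped_mismatch"; next }
      e1 <- exp_eaf[i]; e2 <- pan_eaf[i]
      ambiguous <- is.na(e1) || is.na(e2) ||
        (e1 >= window[1] && e1 <= window[2]) ||
        (e2 >= window[1] && e2 <= window[2])
      if (ambiguous) { action[i] <- "dropped_palindromic"; next }
      flip[i] <- (e1 - 0.5) * (e2 - 0.5) < 0
      action[i] <- "eaf_inferred"
    } else {
      cea <- COMPLEMENT[ea]; coa <- COMPLEMENT[oa]
      if (same_pair || (cea == exp_ea[i] && coa == exp_oa[i])) {
        action[i] <- "unchanged"
      } else if (swap_pair || (cea == exp_oa[i] && coa == exp_ea[i])) {
        action[i] <- "allele_flipped"; flip[i] <- TRUE
      } else {
        action[i] <- "dropped_mismatch"
      }
    }
  }
  list(action = action, flip = flip)
}

#' Harmonize summary panels to a common effect allele
#'
#' Aligns the outcome panel (and any mediator panels) to the exposure panel's
#' effect-allele coding over the SNPs shared by all panels. Where a panel
#' reports the swapped allele pair, its beta sign is flipped and its EAF
#' replaced by 1 - EAF. Strand flips (complement-base matches) are attempted
#' before declaring alleles irreconcilable. Palindromic SNPs (A/T or C/G) are
#' oriented by comparing effect-allele frequencies when both traits' EAFs lie
#' outside `palindromic_eaf_window`; otherwise they are dropped and flagged
#' `dropped_palindromic`. SNPs with irreconcilable alleles are dropped and
#' flagged `dropped_mismatch`. A missing EAF drops a palindromic SNP
#' (conservative) but a non-palindromic SNP is aligned by allele labels alone.
#'
#' @param exposure,outcome `summary_panel` objects.
#' @param mediators optional named list of `summary_panel` objects (names
#'   default to their trait names).
#' @param palindromic_eaf_window numeric length-2: EAFs inside this closed
#'   interval are considered too close to 0.5 to resolve strand.
#' @return A [harmonized_set]; its `provenance` field is a data.frame
#'   (`snp_id`, `flag`) over all shared SNPs, and the per-panel detail table
#'   is attached as attribute `"report"` (`snp_id`, `panel`, `action`).
#' @export
harmonize <- function(exposure, outcome, mediators = NULL,
                      palindromic_eaf_window = c(0.42, 0.58)) {
  stopifnot(inherits(exposure, "summary_panel"), inherits(outcome, "summary_panel"))
  if (!is.null(mediators)) {
    if (is.null(names(mediators))) {
      names(mediators) <- vapply(mediators, trait_name, character(1))
    }
  }
  panels <- c(list(outcome = outcome), mediators)
  shared <- Reduce(intersect, c(list(exposure$snp_id), lapply(panels, `[[`, "snp_id")))
  if (length(shared) == 0) {
    mrm_error("no SNPs shared across the panels", "mrmediate_empty_intersection")
  }
  exp_rows <- as.data.frame(panel_subset(exposure, shared))

  report <- list()
  aligned <- list()
  for (nm in names(panels)) {
    pan_rows <- as.data.frame(panel_subset(panels[[nm]], shared))
    al <- align_to_exposure(
      exp_rows$effect_allele, exp_rows$other_allele, exp_rows$eaf,
      pan_rows$effect_allele, pan_rows$other_allele, pan_rows$eaf,
      palindromic_eaf_window
    )
    beta <- ifelse(al$flip, -pan_rows$beta, pan_rows$beta)
    aligned[[nm]] <- list(beta = beta, se = pan_rows$se, action = al$action)
    report[[nm]] <- data.frame(snp_id = shared, panel = nm, action = al$action,
                               stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, report)
  rownames(report) <- NULL

  # per-SNP flag: any drop wins, then eaf_inferred, then allele_flipped
  rank <- c(unchanged = 1, allele_flipped = 2, eaf_inferred = 3,
            dropped_palindromic = 4, dropped_mismatch = 5)
  flag <- vapply(shared, function(s) {
    acts <- report$action[report$snp_id == s]
    acts[which.max(rank[acts])]
  }, character(1))
  keep <- !startsWith(flag, "dropped")
  if (!any(keep)) {
    empty_instrument_error("all shared SNPs were dropped during harmonization")
  }

  med_cols <- NULL
  if (!is.null(mediators)) {
    med_cols <- lapply(names(mediators), function(nm) {
      list(beta = aligned[[nm]]$beta[keep], se = aligned[[nm]]$se[keep])
    })
    names(med_cols) <- names(mediators)
  }
  h <- harmonized_set(
    snp_ids = shared[keep],
    gamma = exp_rows$beta[keep], se_gamma = exp_rows$se[keep],
    Gamma = aligned$outcome$beta[keep], se_Gamma = aligned$outcome$se[keep],
    mediators = med_cols,
    provenance = data.frame(snp_id = shared, flag = unname(flag),
                            stringsAsFactors = FALSE)
  )
  attr(h, "report") <- report
  h
}
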