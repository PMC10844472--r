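#' Linkage-disequilibrium reference for clumping
#'
#' Holds SNP genomic positions and a sparse symmetric map of pairwise r2
#' values. Pairs absent from the map are treated as unlinked (r2 = 0);
#' r2 of a SNP with itself is implicitly 1.
#'
#' @param positions data.frame with columns `snp_id`, `chrom`, `pos`.
#' @param r2 data.frame with columns `snp_a`, `snp_b`, `r2` (values in
#'   \[0, 1\]); may have zero rows.
#' @return An object of class `ld_info`.
#' @export
ld_info <- function(positions, r2 = data.frame(snp_a = character(), snp_b = character(),
                                               r2 = numeric())) {
  stopifnot(is.data.frame(positions),
            all(c("snp_id", "chrom", "pos") %in% names(positions)))
  stopifnot(is.data.frame(r2), all(c("snp_a", "snp_b", "r2") %in% names(r2)))
  if (nrow(r2) && (any(r2$r2 < 0) || any(r2$r2 > 1))) {
    validation_error("r2 values must lie in [0, 1]")
  }
  if (anyDuplicated(positions$snp_id)) validation_error("duplicated snp_id in positions")
  key <- character(0)
  val <- numeric(0)
  if (nrow(r2)) {
    a <- as.character(r2$snp_a); b <- as.character(r2$snp_b)
    lo <- pmin(a, b); hi <- pmax(a, b)
    key <- paste(lo, hi, sep = "\r")
    val <- r2$r2
    keep <- !duplicated(key)
    key <- key[keep]; val <- val[keep]
  }
  lookup <- stats::setNames(val, key)
  structure(
    list(positions = positions[c("snp_id", "chrom", "pos")], r2 = lookup),
    class = "ld_info"
  )
}

get_r2 <- function(ld, a, b) {
  if (a == b) return(1)
  key <- paste(min(a, b), max(a, b), sep = "\r")
  v <- ld$r2[key]
  if (is.na(v)) 0 else unname(v)
}

#' Catalog of SNP-confounder associations
#'
#' A local stand-in for a phenotype-association lookup service: a table of
#' known associations between candidate instruments and confounding traits
#' (e.g. hypertension, BMI, smoking). SNPs absent from the catalog are
#' treated as unassociated with any confounder.
#'
#' @param associations data.frame with columns `snp_id`, `trait`, `pval`
#'   (p-values in (0, 1\]); may have zero rows.
#' @return An object of class `confounder_catalog`.
#' @export
confounder_catalog <- function(associations = data.frame(snp_id = character(),
                                                         trait = character(),
                                                         pval = numeric())) {
  stopifnot(is.data.frame(associations),
            all(c("snp_id", "trait", "pval") %in% names(associations)))
  if (nrow(associations) &&
      (any(associations$pval <= 0) || any(associations$pval > 1))) {
    validation_error("catalog pvals must lie in (0, 1]")
  }
  structure(list(associations = associations), class = "confounder_catalog")
}

#' Instrument-selection configuration
#'
#' Thresholds for the four-stage instrument screen: genome-wide significance,
#' LD clumping, confounder exclusion and instrument strength.
#'
#' @param p_threshold genome-wide significance threshold (default 5e-8,
#'   strict `<`).
#' @param clump_r2 r2 above or at which a SNP is clumped away (default 0.001).
#' @param clump_window_kb clumping window half-width in kilobases
#'   (default 10000).
#' @param f_min minimum per-SNP F statistic; instruments must have F strictly
#'   greater than this (default 10).
#' @param confounder_p threshold below which a catalog association marks a
#'   SNP as confounder-linked (default 5e-8).
#' @return An object of class `iv_config`.
#' @export
iv_config <- function(p_threshold = 5e-8, clump_r2 = 0.001,
                      clump_window_kb = 10000, f_min = 10,
                      confounder_p = 5e-8) {
  if (!(p_threshold >= 0) || !(confounder_p > 0)) {
    validation_error("thresholds must be positive")
  }
  if (!(clump_r2 > 0 && clump_r2 < 1)) validation_error("clump_r2 must lie in (0, 1)")
  if (!(clump_window_kb > 0) || !(f_min > 0)) validation_error("thresholds must be positive")
  structure(
    list(p_threshold = p_threshold, clump_r2 = clump_r2,
         clump_window_kb = clump_window_kb, f_min = f_min,
         confounder_p = confounder_p),
    class = "iv_config"
  )
}

#' Genome-wide significance filter
#'
#' Retains exactly the records with `pval < p_threshold` (strict inequality).
#'
#' @param panel a `summary_panel`.
#' @param p_threshold significance threshold (default 5e-8).
#' @return The filtered `summary_panel` (possibly empty).
#' @export
filter_genomewide <- function(panel, p_threshold = 5e-8) {
  stopifnot(inherits(panel, "summary_panel"))
  panel_subset(panel, which(panel$pval < p_threshold))
}

#' Greedy LD clumping
#'
#' Repeatedly takes the remaining SNP with the smallest p-value as an index
#' SNP, then removes all remaining SNPs on the same chromosome within
#' `window_kb` kilobases of it whose r2 with it is at or above `r2_max`
#' (both conditions required). Ties on p-value are broken by smaller genomic
#' coordinate, then lexicographic `snp_id`, so the result is deterministic
#' and independent of input order.
#'
#' @param panel a `summary_panel`; every SNP must appear in `ld`'s positions.
#' @param ld an [ld_info].
#' @param r2_max clumping r2 threshold (default 0.001).
#' @param window_kb window half-width in kilobases (default 10000).
#' @return The `summary_panel` of index SNPs, payloads intact.
#' @export
clump_greedy <- function(panel, ld, r2_max = 0.001, window_kb = 10000) {
  stopifnot(inherits(panel, "summary_panel"), inherits(ld, "ld_info"))
  if (nrow(panel) == 0) return(panel)
  posmap <- ld$positions
  idx <- match(panel$snp_id, posmap$snp_id)
  if (anyNA(idx)) {
    config_error(paste0("SNP(s) missing from LD positions: ",
                        paste(panel$snp_id[is.na(idx)], collapse = ", ")))
  }
  chrom <- posmap$chrom[idx]
  pos <- posmap$pos[idx]
  ord <- order(panel$pval, pos, panel$snp_id)
  remaining <- ord
  kept <- integer(0)
  win <- window_kb * 1000
  while (length(remaining)) {
    i <- remaining[1]
    kept <- c(kept, i)
    remaining <- remaining[-1]
    if (length(remaining)) {
      prune <- vapply(remaining, function(j) {
        chrom[j] == chrom[i] &&
          abs(pos[j] - pos[i]) <= win &&
          get_r2(ld, panel$snp_id[i], panel$snp_id[j]) >= r2_max
      }, logical(1))
      remaining <- remaining[!prune]
    }
  }
  panel_subset(panel, sort(kept))
}

#' Exclude SNPs associated with confounders
#'
#' Removes records whose catalog entry contains any confounder association
#' with `pval < confounder_p`. SNPs absent from the catalog are retained.
#'
#' @param panel a `summary_panel`.
#' @param catalog a [confounder_catalog].
#' @param confounder_p exclusion threshold (default 5e-8).
#' @return A list: `panel` (the retained records) and `report`, a data.frame
#'   (`snp_id`, `trait`, `pval`) with one row per excluding association.
#' @export
exclude_confounder_snps <- function(panel, catalog, confounder_p = 5e-8) {
  stopifnot(inherits(panel, "summary_panel"), inherits(catalog, "confounder_catalog"))
  assoc <- catalog$associations
  hits <- assoc[assoc$snp_id %in% panel$snp_id & assoc$pval < confounder_p, ,
                drop = FALSE]
  rownames(hits) <- NULL
  keep <- !(panel$snp_id %in% hits$snp_id)
  list(panel = panel_subset(panel, which(keep)),
       report = hits[c("snp_id", "trait", "pval")])
}

#' Per-SNP instrument-strength F statistic
#'
#' The summary-data approximation F = (beta / se)^2, i.e. the squared
#' z-score. F > 10 is the conventional weak-instrument screen.
#'
#' @param beta,se numeric vectors (or a `summary_panel` passed as `beta`).
#' @return Numeric vector of F statistics.
#' @examples
#' per_snp_f(0.02, 0.002)  # 100
#' @export
per_snp_f <- function(beta, se = NULL) {
  if (inherits(beta, "summary_panel")) {
    se <- beta$se
    beta <- beta$beta
  }
  (beta / se)^2
}

#' Select instrumental variables
#'
#' The full four-stage screen, applied in order: genome-wide significance
#' (`pval < p_threshold`), greedy LD clumping, confounder exclusion, and the
#' instrument-strength screen (F > `f_min`, strict). The audit trail records
#' the count entering the pipeline and the count surviving each stage.
#'
#' @param panel a `summary_panel` for the exposure.
#' @param ld an [ld_info] covering the panel's SNPs.
#' @param catalog a [confounder_catalog].
#' @param config an [iv_config].
#' @return A list: `panel` (the selected instruments), `audit` (named integer
#'   vector: input, genomewide, clumped, confounder_screened, f_screened) and
#'   `exclusions` (the confounder report).
#' @export
select_instruments <- function(panel, ld, catalog, config = iv_config()) {
  stopifnot(inherits(config, "iv_config"))
  audit <- c(input = nrow(panel))
  p1 <- filter_genomewide(panel, config$p_threshold)
  audit["genomewide"] <- nrow(p1)
  if (nrow(p1) == 0) {
    empty_instrument_error("no SNPs pass the genome-wide significance filter")
  }
  p2 <- clump_greedy(p1, ld, config$clump_r2, config$clump_window_kb)
  audit["clumped"] <- nrow(p2)
  ex <- exclude_confounder_snps(p2, catalog, config$confounder_p)
  p3 <- ex$panel
  audit["confounder_screened"] <- nrow(p3)
  keep <- per_snp_f(p3) > config$f_min
  p4 <- panel_subset(p3, which(keep))
  audit["f_screened"] <- nrow(p4)
  if (nrow(p4) == 0) {
    empty_instrument_error("no instruments survive selection")
  }
  list(panel = p4, audit = audit, exclusions = ex$report)
}

#' Read LD reference files
#'
#' `read_ld_info` reads a positions table (`snp_id`, `chrom`, `pos`) and an
#' optional r2 triples table (`snp_a`, `snp_b`, `r2`), both tab-separated
#' with headers. `read_confounder_catalog` reads association triples
#' (`snp_id`, `trait`, `pval`).
#'
#' @param positions_path,r2_path,path file paths of tab-separated tables.
#' @return An [ld_info] or [confounder_catalog].
#' @export
read_ld_info <- function(positions_path, r2_path = NULL) {
  pos <- utils::read.delim(positions_path, stringsAsFactors = FALSE)
  r2 <- if (is.null(r2_path)) {
    data.frame(snp_a = character(), snp_b = character(), r2 = numeric())
  } else {
    utils::read.delim(r2_path, stringsAsFactors = FALSE)
  }
  ld_info(pos, r2)
}

#' @rdname read_ld_info
#' @export
read_confounder_catalog <- function(path) {
  confounder_catalog(utils::read.delim(path, stringsAsFactors = FALSE))
}
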