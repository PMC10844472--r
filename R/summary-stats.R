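#' GWAS summary-statistic panels
#'
#' A summary panel holds one trait's per-SNP association statistics: the
#' additive per-allele effect (`beta`, on the log-odds scale for binary
#' traits), its standard error, p-value, allele coding and study sample size.
#' Panels are plain data frames carrying the trait name and type as
#' attributes, so every data.frame idiom keeps working.
#'
#' Canonical columns, in order: `snp_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`. Missing effect-allele
#' frequencies are `NA`.
#'
#' @param records data.frame with the canonical columns.
#' @param trait_name character scalar naming the trait.
#' @param trait_type `"continuous"` or `"binary"` (binary betas are log-odds).
#' @return An object of class `summary_panel` (a validated data.frame).
#' @examples
#' rec <- data.frame(
#'   snp_id = "rs1", chrom = "1", pos = 1000L,
#'   effect_allele = "A", other_allele = "G",
#'   eaf = 0.3, beta = 0.05, se = 0.01, pval = 5e-7, n = 10000
#' )
#' summary_panel(rec, "example trait", "continuous")
#' @export
summary_panel <- function(records, trait_name, trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  if (!is.data.frame(records)) validation_error("records must be a data.frame")
  missing_cols <- setdiff(panel_columns(), names(records))
  if (length(missing_cols)) {
    format_error(paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")))
  }
  records <- records[panel_columns()]
  records$snp_id <- as.character(records$snp_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  validate_panel_records(records)
  structure(
    records,
    trait_name = trait_name,
    trait_type = trait_type,
    class = c("summary_panel", "data.frame")
  )
}

panel_columns <- function() {
  c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
    "eaf", "beta", "se", "pval", "n")
}

validate_panel_records <- function(records) {
  bad <- function(rows, what) {
    if (any(rows)) {
      validation_error(sprintf(
        "%s at row(s): %s", what, paste(which(rows), collapse = ", ")
      ))
    }
  }
  dup <- duplicated(records$snp_id)
  if (any(dup)) {
    validation_error(paste0(
      "duplicated snp_id: ", paste(unique(records$snp_id[dup]), collapse = ", ")
    ))
  }
  nt <- c("A", "C", "G", "T")
  bad(!(records$effect_allele %in% nt), "effect_allele not a single nucleotide")
  bad(!(records$other_allele %in% nt), "other_allele not a single nucleotide")
  bad(records$effect_allele == records$other_allele, "effect_allele equals other_allele")
  bad(!is.finite(records$se) | records$se <= 0, "se must be > 0")
  bad(!is.finite(records$pval) | records$pval <= 0 | records$pval > 1,
      "pval must lie in (0, 1]")
  with_eaf <- !is.na(records$eaf)
  bad(with_eaf & (records$eaf < 0 | records$eaf > 1), "eaf must lie in [0, 1]")
  bad(!is.finite(records$beta), "beta must be finite")
  bad(!is.finite(records$n) | records$n <= 0, "n must be > 0")
  invisible(records)
}

#' @export
print.summary_panel <- function(x, ...) {
  cat(sprintf(
    "<summary_panel> %s (%s), %d SNP(s)\n",
    attr(x, "trait_name"), attr(x, "trait_type"), nrow(x)
  ))
  print(as.data.frame(utils::head(x, 10)), ...)
  if (nrow(x) > 10) cat(sprintf("... %d more row(s)\n", nrow(x) - 10))
  invisible(x)
}

#' Trait metadata accessors
#' @param panel a `summary_panel`.
#' @return `trait_name()`/`trait_type()` return the corresponding attribute.
#' @export
trait_name <- function(panel) attr(panel, "trait_name")

#' @rdname trait_name
#' @export
trait_type <- function(panel) attr(panel, "trait_type")

# Subset a panel by row index or snp_id, keeping class and attributes.
panel_subset <- function(panel, idx) {
  if (is.character(idx)) idx <- match(idx, panel$snp_id)
  out <- as.data.frame(panel)[idx, , drop = FALSE]
  rownames(out) <- NULL
  summary_panel(out, attr(panel, "trait_name"), attr(panel, "trait_type"))
}

#' Read a tab-separated GWAS summary-statistics table
#'
#' Reads a delimited table with a header row into a validated
#' [summary_panel]. Column names in the file may differ from the canonical
#' vocabulary; `column_map` translates them (names are the canonical columns,
#' values the file's column names). Rows violating the panel invariants
#' (non-positive standard errors, p-values outside (0,1], duplicate SNP ids,
#' malformed alleles) are rejected with row-indexed diagnostics rather than
#' silently dropped.
#'
#' @param path file path of a tab-separated table with header.
#' @param trait_name,trait_type trait metadata, see [summary_panel].
#' @param column_map optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(snp_id = "SNP", pval = "P")`.
#' @return A `summary_panel`.
#' @seealso [write_summary_tsv()]
#' @export
read_summary_tsv <- function(path, trait_name, trait_type = c("continuous", "binary"),
                             column_map = NULL) {
  trait_type <- match.arg(trait_type)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", na.strings = "NA",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src)) {
      format_error(paste0(
        "column_map refers to column(s) absent from the file: ",
        paste(missing_src, collapse = ", ")
      ))
    }
    for (canon in names(column_map)) {
      names(raw)[names(raw) == column_map[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(panel_columns(), names(raw))
  if (length(missing_cols)) {
    format_error(paste0(
      "file lacks mandatory column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  summary_panel(raw[panel_columns()], trait_name, trait_type)
}

#' Write a summary panel as a tab-separated table
#'
#' Emits the canonical column order (`snp_id, chrom, pos, effect_allele,
#' other_allele, eaf, beta, se, pval, n`), `NA` for missing values, full
#' double precision (round-trips through [read_summary_tsv()] to at least
#' 15 significant digits).
#'
#' @param panel a `summary_panel`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_summary_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "summary_panel"))
  out <- as.data.frame(panel)[panel_columns()]
  for (col in c("eaf", "beta", "se", "pval")) {
    out[[col]] <- vapply(out[[col]], function(v) {
      if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = TRUE)
    }, character(1))
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) mrm_error(conditionMessage(ok), "mrmediate_io_error")
  invisible(path)
}
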