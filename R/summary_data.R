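#' Construct a two-sample summary-data MR dataset
#'
#' Bundles per-SNP summary statistics from two independent GWAS: the
#' SNP-exposure association estimates (`gamma_hat`, standard error `se_x`)
#' and the SNP-outcome association estimates (`Gamma_hat`, standard error
#' `se_y`). Standard errors are treated as fixed and known, and SNPs are
#' assumed independent (LD-clumped) and allele-harmonized upstream.
#'
#' @param snp_id Character vector of unique SNP identifiers.
#' @param gamma_hat Numeric vector of SNP-exposure effect estimates.
#' @param se_x Numeric vector of standard errors of `gamma_hat` (> 0).
#' @param Gamma_hat Numeric vector of SNP-outcome effect estimates.
#' @param se_y Numeric vector of standard errors of `Gamma_hat` (> 0).
#'
#' @return An object of class `mr_summary`: a data frame with the five
#'   columns above, one row per SNP.
#' @examples
#' d <- mr_dataset(c("rs1", "rs2"), c(0.5, 0.7), c(0.05, 0.06),
#'                 c(0.02, 0.05), c(0.04, 0.04))
#' f_statistics(d)
#' @export
mr_dataset <- function(snp_id, gamma_hat, se_x, Gamma_hat, se_y) {
  d <- data.frame(
    snp_id = as.character(snp_id),
    gamma_hat = as.numeric(gamma_hat),
    se_x = as.numeric(se_x),
    Gamma_hat = as.numeric(Gamma_hat),
    se_y = as.numeric(se_y),
    stringsAsFactors = FALSE
  )
  class(d) <- c("mr_summary", "data.frame")
  validate_mr_dataset(d)
}

#' Validate a summary-data MR dataset
#'
#' Checks the invariants of an [mr_dataset()]: equal lengths, finite values,
#' strictly positive standard errors and unique SNP identifiers. Missing
#' values are rejected rather than imputed; the summary-data model has no
#' missing-data mechanism.
#'
#' @param data An `mr_summary` object or a data frame with the same columns.
#' @return The validated `mr_summary` object (invisibly classed).
#' @export
validate_mr_dataset <- function(data) {
  req <- c("snp_id", "gamma_hat", "se_x", "Gamma_hat", "se_y")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) < 1L) stop("dataset must contain at least one SNP", call. = FALSE)
  num <- c("gamma_hat", "se_x", "Gamma_hat", "se_y")
  for (col in num) {
    x <- data[[col]]
    if (!is.numeric(x)) stop("column '", col, "' is not numeric", call. = FALSE)
    if (anyNA(x) || any(!is.finite(x))) {
      bad <- which(!is.finite(x))[1L]
      stop("non-finite value in column '", col, "' for SNP ",
           data$snp_id[bad], call. = FALSE)
    }
  }
  for (col in c("se_x", "se_y")) {
    bad <- which(data[[col]] <= 0)
    if (length(bad) > 0) {
      stop("non-positive ", col, " for SNP ", data$snp_id[bad[1L]],
           call. = FALSE)
    }
  }
  dup <- duplicated(data$snp_id)
  if (any(dup)) {
    stop("duplicated SNP id: ", data$snp_id[which(dup)[1L]], call. = FALSE)
  }
  if (!inherits(data, "mr_summary")) class(data) <- c("mr_summary", "data.frame")
  data
}

# Recognized header dialects, tried in order when no column_map is given.
# Dialect 1 is the package default; dialect 2 is the TwoSampleMR convention
# (harmonized ".exposure"/".outcome" suffixes); dialect 3 is GWAS-SSF-like.
default_column_maps <- function() {
  list(
    c(snp_id = "SNP", gamma_hat = "beta_exposure", se_x = "se_exposure",
      Gamma_hat = "beta_outcome", se_y = "se_outcome"),
    c(snp_id = "SNP", gamma_hat = "beta.exposure", se_x = "se.exposure",
      Gamma_hat = "beta.outcome", se_y = "se.outcome"),
    c(snp_id = "rsid", gamma_hat = "beta_exposure", se_x = "standard_error_exposure",
      Gamma_hat = "beta_outcome", se_y = "standard_error_outcome")
  )
}

#' Read a two-sample summary table from a delimited text file
#'
#' Reads a tab- or comma-separated text file with a header and returns a
#' validated [mr_dataset()]. Row order is preserved. Extra columns (effect
#' alleles, p-values, ...) are ignored; effects are assumed to be
#' pre-harmonized.
#'
#' @param path Path to the delimited file (UTF-8, header required).
#' @param column_map Optional named character vector mapping the internal
#'   names `snp_id`, `gamma_hat`, `se_x`, `Gamma_hat`, `se_y` to the file's
#'   column names. When `NULL`, the default dialects (`SNP`/`beta_exposure`/
#'   `se_exposure`/`beta_outcome`/`se_outcome`, the TwoSampleMR dotted form,
#'   and a GWAS-SSF-like form) are tried in turn.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return An `mr_summary` dataset.
#' @seealso [write_summary_table()]
#' @export
read_summary_table <- function(path, column_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header_line <- readLines(path, n = 1L)
  if (is.null(sep)) {
    sep <- if (grepl("\t", header_line)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", fileEncoding = "UTF-8")
  maps <- if (is.null(column_map)) default_column_maps() else list(column_map)
  chosen <- NULL
  for (m in maps) {
    if (all(m %in% names(raw))) { chosen <- m; break }
  }
  if (is.null(chosen)) {
    m <- maps[[1L]]
    missing_cols <- setdiff(unname(m), names(raw))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  num_fields <- c("gamma_hat", "se_x", "Gamma_hat", "se_y")
  out <- list(snp_id = raw[[chosen[["snp_id"]]]])
  for (f in num_fields) {
    txt <- raw[[chosen[[f]]]]
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(val) & !is.na(txt))
    if (length(bad) > 0) {
      stop("could not parse column '", chosen[[f]], "' as numeric at row ",
           bad[1L], " ('", txt[bad[1L]], "')", call. = FALSE)
    }
    out[[f]] <- val
  }
  mr_dataset(out$snp_id, out$gamma_hat, out$se_x, out$Gamma_hat, out$se_y)
}

#' Write a summary-data MR dataset to a TSV file
#'
#' Emits the default header dialect (`SNP`, `beta_exposure`, `se_exposure`,
#' `beta_outcome`, `se_outcome`) with full double precision, so that
#' `read_summary_table(write_summary_table(d, f))` round-trips values to at
#' least 15 significant digits.
#'
#' @param data An `mr_summary` dataset.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(data, path) {
  data <- validate_mr_dataset(data)
  out <- data.frame(
    SNP = data$snp_id,
    beta_exposure = format(data$gamma_hat, digits = 17, trim = TRUE, scientific = NA),
    se_exposure = format(data$se_x, digits = 17, trim = TRUE, scientific = NA),
    beta_outcome = format(data$Gamma_hat, digits = 17, trim = TRUE, scientific = NA),
    se_outcome = format(data$se_y, digits = 17, trim = TRUE, scientific = NA),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-SNP instrument-strength F-statistics
#'
#' The strength of instrument j is measured by `F_j = (gamma_hat_j / se_x_j)^2`;
#' the mean F over instruments summarizes overall strength (a mean F near 10
#' is conventionally "weak", near 100 "strong").
#'
#' @param data An `mr_summary` dataset.
#' @return A list with `F` (per-SNP values, named by SNP id) and `mean_F`.
#' @export
f_statistics <- function(data) {
  data <- validate_mr_dataset(data)
  f <- (data$gamma_hat / data$se_x)^2
  names(f) <- data$snp_id
  list(F = f, mean_F = mean(f))
}

#' Filter instruments by F-statistic
#'
#' Keeps SNPs with `F_j > threshold`, preserving row order. Weak-instrument
#' pre-filtering of this kind is common when instruments are chosen from an
#' external discovery study (three-sample design).
#'
#' @param data An `mr_summary` dataset.
#' @param threshold Non-negative F cutoff; SNPs with F strictly above it are
#'   retained.
#' @return The filtered `mr_summary` dataset (possibly empty, with a warning).
#' @export
filter_by_f <- function(data, threshold) {
  data <- validate_mr_dataset(data)
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  keep <- f_statistics(data)$F > threshold
  out <- data[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning("no SNPs exceed the F threshold of ", threshold, call. = FALSE)
    class(out) <- c("mr_summary", "data.frame")
    return(out)
  }
  validate_mr_dataset(out)
}

#' @export
print.mr_summary <- function(x, ...) {
  cat("Two-sample summary MR dataset: ", nrow(x), " SNPs\n", sep = "")
  cat("  mean F-statistic: ", format(mean((x$gamma_hat / x$se_x)^2), digits = 4),
      "\n", sep = "")
  NextMethod()
}
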