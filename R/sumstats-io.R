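# Reading, harmonizing and quality-filtering per-sex GWAS summary
# statistics, plus the results writer/reader used by the pipeline.
#
# Input files are Neale-style TSV (optionally gzipped) with one row per
# variant. Column names are mapped through an explicit user-supplied map
# (see neale_column_map()); there is deliberately no auto-detection.

#' Default logical-column mapping for Neale-style sex-stratified exports
#'
#' Maps the logical columns the reader needs onto physical column names.
#' Either `major`/`minor` or a single `alleles` column ("MAJ/MIN") may be
#' provided; at least one of `se`, `p` must be present alongside `beta`.
#'
#' @param ... Name-value overrides, e.g. `p = "pval_col"`.
#' @return Named list mapping logical names to column names.
#' @export
neale_column_map <- function(...) {
  map <- list(
    variant = "variant", chr = "chr", pos = "pos",
    major = "major", minor = "minor", alleles = NULL,
    info = "info", n = "n", maf = "maf",
    beta = "beta", se = "se", p = "pval"
  )
  dots <- list(...)
  map[names(dots)] <- dots
  map
}

chr_to_int <- function(chr) {
  chr <- toupper(as.character(chr))
  chr[chr %in% c("X", "23")] <- "23"
  out <- suppressWarnings(as.integer(chr))
  out
}

#' Read one sex stratum of GWAS summary statistics
#'
#' Reads a TSV/TSV.GZ of per-variant summary statistics, standardizes the
#' columns, and fills in the Wald z and two-sided p from whichever of
#' (beta, se) or (beta, p) the file provides. When both `se` and `p` are
#' present and disagree by more than 1% on the z scale, `se` wins and a
#' warning is issued (printed p columns are often rounded). Minor-allele
#' frequencies are stored as `min(f, 1 - f)`. The X chromosome is coded 23
#' and processed like any autosome.
#'
#' @param path Path to the summary-statistic file.
#' @param column_map Logical-to-physical column mapping; see
#'   [neale_column_map()].
#' @param group Stratum label, `"female"` or `"male"`.
#' @param strict If `TRUE` (default) unparseable numeric cells or invalid
#'   rows abort with the offending line numbers; if `FALSE` such rows are
#'   dropped with a warning.
#' @return A data frame with columns `variant`, `chr`, `pos`, `major`,
#'   `minor`, `info`, `n`, `maf`, `beta`, `se`, `z`, `p`, `neglog10p`,
#'   `group`.
#' @export
read_sumstats <- function(path, column_map = neale_column_map(),
                          group = c("female", "male"), strict = TRUE) {
  group <- match.arg(group)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character", data.table = FALSE)

  has <- function(key) !is.null(column_map[[key]]) && column_map[[key]] %in% names(raw)
  need <- c("variant", "chr", "pos", "info", "n", "maf", "beta")
  for (key in need) {
    if (is.null(column_map[[key]])) {
      stop("column_map does not map required logical column `", key, "`",
           call. = FALSE)
    }
    if (!column_map[[key]] %in% names(raw)) {
      stop("mapped column `", column_map[[key]], "` (for `", key,
           "`) not present in ", path, call. = FALSE)
    }
  }
  if (!has("se") && !has("p")) {
    stop("at least one of `se`, `p` must be mapped and present alongside `beta`",
         call. = FALSE)
  }
  if (!(has("major") && has("minor")) && !has("alleles")) {
    stop("either `major`/`minor` or an `alleles` column must be mapped",
         call. = FALSE)
  }

  col <- function(key) raw[[column_map[[key]]]]
  num <- function(key) suppressWarnings(as.numeric(col(key)))

  out <- data.frame(
    variant = col("variant"),
    chr = chr_to_int(col("chr")),
    pos = num("pos"),
    stringsAsFactors = FALSE
  )
  if (has("major") && has("minor")) {
    out$major <- toupper(col("major"))
    out$minor <- toupper(col("minor"))
  } else {
    parts <- strsplit(toupper(col("alleles")), "\\s*/\\s*")
    out$major <- vapply(parts, `[`, character(1), 1L)
    out$minor <- vapply(parts, function(x) if (length(x) >= 2) x[2] else NA_character_, character(1))
  }
  out$info <- num("info")
  out$n <- num("n")
  out$maf <- num("maf")
  out$beta <- num("beta")
  out$se <- if (has("se")) num("se") else NA_real_
  out$p <- if (has("p")) num("p") else NA_real_

  numeric_cols <- c("pos", "info", "n", "maf", "beta",
                    if (has("se")) "se", if (has("p")) "p")
  bad_parse <- Reduce(`|`, lapply(numeric_cols, function(cn) is.na(out[[cn]])))
  invalid <- !bad_parse & (
    out$pos < 1 | is.na(out$chr) |
      out$info < 0 | out$info > 1 |
      is.na(out$major) | is.na(out$minor) |
      nchar(out$major) == 0 | nchar(out$minor) == 0 |
      out$major == out$minor |
      (!is.na(out$p) & (out$p <= 0 | out$p > 1))
  )
  bad <- which(bad_parse | invalid)
  if (length(bad)) {
    msg <- paste0("unparseable or invalid row(s) at data line(s): ",
                  paste(utils::head(bad, 10L), collapse = ", "))
    if (strict) stop(msg, " in ", path, call. = FALSE)
    warning(msg, "; dropped", call. = FALSE)
    out <- out[-bad, , drop = FALSE]
  }

  out$maf <- pmin(out$maf, 1 - out$maf)

  # Fill z / p / se from what is available. z comes from beta/se when se is
  # present (se wins over a rounded p column, with a warning when they
  # disagree by >1% on the z scale); a p column, when present, is kept
  # verbatim so the file round-trips exactly.
  z_se <- ifelse(!is.na(out$se) & out$se > 0, out$beta / out$se, NA_real_)
  z_p <- rep(NA_real_, nrow(out))
  okp <- !is.na(out$p) & out$p < 1 & out$beta != 0
  if (any(okp)) z_p[okp] <- z_from_p_sign(out$p[okp], sign(out$beta[okp]))
  both <- !is.na(z_se) & !is.na(z_p)
  if (any(both)) {
    rel <- abs(z_se[both] - z_p[both]) / pmax(1, abs(z_se[both]))
    if (any(rel > 0.01)) {
      warning(sum(rel > 0.01), " row(s) with se- and p-derived z disagreeing ",
              "by >1%; using se", call. = FALSE)
    }
  }
  out$z <- ifelse(!is.na(z_se), z_se, z_p)
  out$z[is.na(out$z)] <- 0 # beta == 0 with no usable se
  derive_se <- (is.na(out$se) | out$se <= 0) & !is.na(z_p) & z_p != 0
  out$se[derive_se] <- abs(out$beta[derive_se]) / abs(z_p[derive_se])
  pp <- p_from_z(out$z)
  fill_p <- is.na(out$p)
  out$p[fill_p] <- pp$p[fill_p]
  out$neglog10p <- ifelse(fill_p, pp$neglog10p, -log10(out$p))
  out$group <- rep(group, nrow(out))
  out
}

qc_report <- function(n_input, n_kept, n_dropped_maf = 0L,
                      n_dropped_info = 0L, n_dropped_unmatched = 0L) {
  stopifnot(n_input == n_kept + n_dropped_maf + n_dropped_info + n_dropped_unmatched)
  structure(list(n_input = n_input, n_kept = n_kept,
                 n_dropped_maf = n_dropped_maf,
                 n_dropped_info = n_dropped_info,
                 n_dropped_unmatched = n_dropped_unmatched),
            class = "sexmeta_qc")
}

#' @export
print.sexmeta_qc <- function(x, ...) {
  cat(sprintf("variant QC: %d in, %d kept (%d dropped: %d MAF, %d INFO, %d unmatched)\n",
              x$n_input, x$n_kept,
              x$n_input - x$n_kept, x$n_dropped_maf, x$n_dropped_info,
              x$n_dropped_unmatched))
  invisible(x)
}

same_allele_pair <- function(a1, a2, b1, b2) {
  (a1 == b1 & a2 == b2) | (a1 == b2 & a2 == b1)
}

#' Pair the female and male summary-statistic tables per variant
#'
#' Joins the two strata on variant id + position, re-orienting the male
#' record to the female file's minor allele when the major/minor coding is
#' swapped (beta sign flipped; MAF is stored as `min(f, 1 - f)` so its
#' value is orientation-invariant). Variants present in only one file, or
#' with conflicting positions or incompatible allele sets, are dropped and
#' counted as unmatched.
#'
#' @param female,male Data frames from [read_sumstats()].
#' @param drop_ambiguous Drop strand-ambiguous (A/T, C/G) SNPs. Default
#'   `FALSE`: both strata are assumed to come from one imputation panel, so
#'   id matching is safe.
#' @return A list with `pairs` (one row per shared variant, per-sex columns
#'   suffixed `_F`/`_M`, pooled `maf_all`) and `qc` (a QC report counting
#'   unmatched records).
#' @export
harmonize_groups <- function(female, male, drop_ambiguous = FALSE) {
  if (drop_ambiguous) {
    amb <- function(d) (d$major == "A" & d$minor == "T") |
      (d$major == "T" & d$minor == "A") |
      (d$major == "C" & d$minor == "G") |
      (d$major == "G" & d$minor == "C")
    female <- female[!amb(female), , drop = FALSE]
    male <- male[!amb(male), , drop = FALSE]
  }
  n_input <- length(unique(c(female$variant, male$variant)))
  shared <- intersect(female$variant, male$variant)
  f <- female[match(shared, female$variant), , drop = FALSE]
  m <- male[match(shared, male$variant), , drop = FALSE]

  pos_ok <- f$pos == m$pos & f$chr == m$chr
  alleles_ok <- same_allele_pair(f$major, f$minor, m$major, m$minor)
  keep <- pos_ok & alleles_ok
  if (any(!keep)) {
    message(sum(!keep), " shared variant id(s) dropped: conflicting position ",
            "or incompatible alleles")
  }
  f <- f[keep, , drop = FALSE]
  m <- m[keep, , drop = FALSE]

  flipped <- f$major == m$minor & f$minor == m$major
  m$beta[flipped] <- -m$beta[flipped]
  m$z[flipped] <- -m$z[flipped]
  # MAF already stored as min(f, 1-f): numerically unchanged by a flip.

  pairs <- data.frame(
    variant = f$variant, chr = f$chr, pos = f$pos,
    major = f$major, minor = f$minor, info = f$info,
    n_F = f$n, maf_F = f$maf, beta_F = f$beta, se_F = f$se,
    z_F = f$z, p_F = f$p, neglog10_p_F = f$neglog10p,
    n_M = m$n, maf_M = m$maf, beta_M = m$beta, se_M = m$se,
    z_M = m$z, p_M = m$p, neglog10_p_M = m$neglog10p,
    stringsAsFactors = FALSE
  )
  pairs$maf_all <- (pairs$n_F * pairs$maf_F + pairs$n_M * pairs$maf_M) /
    (pairs$n_F + pairs$n_M)
  qc <- qc_report(n_input = n_input, n_kept = nrow(pairs),
                  n_dropped_unmatched = n_input - nrow(pairs))
  list(pairs = pairs, qc = qc)
}

#' Variant-level quality control on harmonized pairs
#'
#' Keeps variants with trait-specific MAF strictly above `maf_min` in
#' both sexes and imputation INFO strictly above `info_min`. Defaults
#' follow common practice for sex-stratified biobank analyses
#' (MAF > 0.01 in each sex, INFO > 0.8). The MAF condition is checked
#' first for drop accounting; the filter is idempotent.
#'
#' @param pairs Data frame from [harmonize_groups()].
#' @param maf_min,info_min Strict lower thresholds.
#' @return A list with the filtered `pairs` and a `qc` report.
#' @export
apply_variant_qc <- function(pairs, maf_min = 0.01, info_min = 0.8) {
  fail_maf <- !(pairs$maf_F > maf_min & pairs$maf_M > maf_min)
  fail_info <- !fail_maf & !(pairs$info > info_min)
  keep <- !fail_maf & !fail_info
  qc <- qc_report(n_input = nrow(pairs), n_kept = sum(keep),
                  n_dropped_maf = sum(fail_maf),
                  n_dropped_info = sum(fail_info))
  list(pairs = pairs[keep, , drop = FALSE], qc = qc)
}

RESULT_COLUMNS <- c("variant", "chr", "pos", "major", "minor", "info",
                    "maf_F", "maf_M", "beta_F", "se_F", "p_F",
                    "beta_M", "se_M", "p_M",
                    "z_diff", "p_diff", "z_metaL", "p_metaL",
                    "chi2_metaQ", "p_metaQ", "neglog10_p_metaQ")

#' Write a results table to TSV
#'
#' Writes the fixed result column order with p-values in scientific
#' notation (6 significant digits, so a write/read round trip preserves
#' all numeric fields to better than 1e-6 relative) plus the
#' `neglog10_p_metaQ` column. An optional `# `-prefixed comment line
#' (e.g. version + configuration hash) is placed above the header.
#'
#' @param results Data frame containing at least the standard result
#'   columns; extra columns are appended after the standard ones.
#' @param path Output path.
#' @param comment Optional single-line comment written as `# <comment>`.
#' @export
write_results <- function(results, path, comment = NULL) {
  results <- as.data.frame(results)
  missing_cols <- setdiff(RESULT_COLUMNS, names(results))
  for (cn in missing_cols) results[[cn]] <- NA_real_
  extra <- setdiff(names(results), RESULT_COLUMNS)
  extra <- extra[!extra %in% c("z_F", "z_M", "n_F", "n_M", "neglog10_p_F",
                               "neglog10_p_M", "neglog10_p_diff",
                               "neglog10_p_metaL", "maf_all", "group")]
  out <- results[, c(RESULT_COLUMNS, extra), drop = FALSE]
  fmt_p <- function(x) ifelse(is.na(x), "NA", sprintf("%.6E", x))
  fmt_g <- function(x) ifelse(is.na(x), "NA", sprintf("%.10g", x))
  for (cn in names(out)) {
    if (grepl("^p_", cn)) {
      out[[cn]] <- fmt_p(out[[cn]])
    } else if (is.numeric(out[[cn]])) {
      out[[cn]] <- fmt_g(out[[cn]])
    }
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out)) {
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  }
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' Skips leading `#` comment lines and restores numeric types.
#' @param path Path to a results TSV.
#' @export
read_results <- function(path) {
  d <- utils::read.delim(path, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  d$chr <- chr_to_int(d$chr)
  d
}
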