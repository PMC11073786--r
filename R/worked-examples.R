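# Packaged worked examples: two small lead-SNP tables from a published
# sex-stratified UK Biobank analysis, shipped as plain-text fixtures.
# "testosterone": 12 novel loci whose lead SNPs are significant only under
# the omnibus quadratic meta-analysis; "urate": 19 SNPs near SLC2A9 with
# genome-wide significant effects in opposite directions between sexes.

WORKED_EXAMPLE_N <- list(
  testosterone = c(n_F = 154364, n_M = 157738),
  urate = c(n_F = 184755, n_M = 159081)
)

#' Load a packaged worked-example lead-SNP table
#'
#' @param name `"testosterone"` (12 omnibus-unique novel loci) or
#'   `"urate"` (19 SNPs with opposite-direction effects).
#' @return A data frame with the printed per-sex summary statistics
#'   (`beta_F`, `beta_M`, `p_F`, `p_M`) and the printed sex-combined
#'   p-values (`p_diff`, `p_metaL`, `p_metaQ`); per-sex sample sizes are
#'   attached as columns `n_F`, `n_M`.
#' @export
worked_example <- function(name = c("testosterone", "urate")) {
  name <- match.arg(name)
  file <- c(testosterone = "testosterone_novel_loci.tsv",
            urate = "urate_sexdivergent_snps.tsv")[[name]]
  path <- system.file("extdata", file, package = "sexmeta", mustWork = TRUE)
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  d$n_F <- WORKED_EXAMPLE_N[[name]][["n_F"]]
  d$n_M <- WORKED_EXAMPLE_N[[name]][["n_M"]]
  d
}

#' Write a worked example as a pair of per-sex summary-statistic files
#'
#' Splits a worked-example table into two Neale-style per-sex TSVs
#' (columns: variant, chr, pos, major, minor, info, n, maf, beta, pval)
#' suitable for [read_sumstats()] and the [cmd_meta()] pipeline. Standard
#' errors are back-derived from beta and p on read.
#'
#' @param name Worked example name (see [worked_example()]).
#' @param dir Output directory (created if needed).
#' @return Named character vector with the `female` and `male` paths.
#' @export
worked_example_sumstats <- function(name = c("testosterone", "urate"),
                                    dir = tempfile("sumstats")) {
  name <- match.arg(name)
  d <- worked_example(name)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(female = file.path(dir, paste0(name, "_female.tsv")),
             male = file.path(dir, paste0(name, "_male.tsv")))
  for (sex in c("female", "male")) {
    sfx <- if (sex == "female") "F" else "M"
    out <- data.frame(
      variant = d$variant, chr = d$chr, pos = d$pos,
      major = d$major, minor = d$minor, info = d$info,
      n = d[[paste0("n_", sfx)]],
      maf = d[[paste0("maf_", sfx)]],
      beta = d[[paste0("beta_", sfx)]],
      pval = d[[paste0("p_", sfx)]],
      stringsAsFactors = FALSE
    )
    data.table::fwrite(out, paths[[sex]], sep = "\t", quote = FALSE)
  }
  paths
}
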