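# End-to-end orchestration of the stages: meta (read -> harmonize -> QC ->
# tests -> write), report (filter -> clump -> merge -> flag -> compare),
# power (Monte-Carlo study), simulate (cohort / summary output). A thin
# command-line wrapper over these functions ships in inst/cli/sexmeta.R.

#' Assemble a pipeline run configuration
#'
#' Thresholds default to the standard values: genome-wide alpha 5e-8,
#' per-sex MAF > 0.01, INFO > 0.8, clump window 10 Mb with r^2 > 0.01,
#' locus merge distance 250 kb.
#'
#' @param female,male Paths to the per-sex summary-statistic files.
#' @param out_dir Output directory.
#' @param column_map Column mapping for [read_sumstats()].
#' @param alpha_gw Genome-wide significance threshold.
#' @param maf_min,info_min Variant QC thresholds.
#' @param clump_window_bp,clump_r2_min,merge_bp Post-GWAS thresholds.
#' @param ld LD provider for the report stage.
#' @param seed Integer seed; required by any stochastic stage.
#' @param strict Strict parsing flag for [read_sumstats()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(female = NULL, male = NULL, out_dir = tempfile("sexmeta"),
                       column_map = neale_column_map(),
                       alpha_gw = 5e-8, maf_min = 0.01, info_min = 0.8,
                       clump_window_bp = 1e7, clump_r2_min = 0.01,
                       merge_bp = 250000, ld = NULL, seed = NULL,
                       strict = TRUE) {
  stopifnot(alpha_gw > 0, alpha_gw < 1, maf_min >= 0, maf_min < 0.5,
            info_min >= 0, info_min <= 1, clump_window_bp > 0,
            clump_r2_min >= 0, clump_r2_min <= 1, merge_bp >= 0)
  structure(list(female = female, male = male, out_dir = out_dir,
                 column_map = column_map, alpha_gw = alpha_gw,
                 maf_min = maf_min, info_min = info_min,
                 clump_window_bp = clump_window_bp,
                 clump_r2_min = clump_r2_min, merge_bp = merge_bp,
                 ld = ld, seed = seed, strict = strict),
            class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the [run_config()] arguments (scalar fields
#' only; an LD provider must be attached in R).
#' @param path YAML file path.
#' @param ... Overrides applied after the file is read.
#' @export
load_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  vals <- vals[names(vals) %in% names(formals(run_config))]
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

# FNV-1a over the deparsed scalar config, for reproducible output headers
config_hash <- function(config) {
  scal <- config[!vapply(config, is.function, logical(1))]
  scal$ld <- if (is.null(config$ld)) "none" else class(config$ld)[1]
  bytes <- utf8ToInt(paste(deparse(scal), collapse = ""))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

output_comment <- function(config) {
  ver <- as.character(utils::packageVersion("sexmeta"))
  sprintf("sexmeta %s config=%s", ver, config_hash(config))
}

#' Run the meta-analysis stage of the pipeline
#'
#' Reads both per-sex summary files, harmonizes and QC-filters the pairs,
#' applies the three sex-combined tests and writes the results TSV
#' (`meta_results.tsv` under `out_dir`). Per-stage variant counts are
#' logged via `message()`.
#'
#' @param config A [run_config()] with `female` and `male` paths set.
#' @return Invisibly, a list with `results`, `qc` (harmonization + QC
#'   reports) and the output `path`.
#' @export
cmd_meta <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$female) || is.null(config$male)) {
    stop("config must set both `female` and `male` input paths", call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- read_sumstats(config$female, config$column_map, "female",
                     strict = config$strict)
  m <- read_sumstats(config$male, config$column_map, "male",
                     strict = config$strict)
  message("read: ", nrow(f), " female, ", nrow(m), " male records")
  h <- harmonize_groups(f, m)
  message(capture_qc(h$qc))
  q <- apply_variant_qc(h$pairs, config$maf_min, config$info_min)
  message(capture_qc(q$qc))
  results <- run_all_tests(q$pairs)
  if (nrow(results) == 0) warning("no variants passed harmonization + QC",
                                  call. = FALSE)
  path <- file.path(config$out_dir, "meta_results.tsv")
  write_results(results, path, comment = output_comment(config))
  invisible(list(results = results, qc = list(harmonize = h$qc, variant = q$qc),
                 path = path))
}

capture_qc <- function(qc) {
  paste(utils::capture.output(print(qc)), collapse = "\n")
}

#' Run the Monte-Carlo type-I error / power stage
#'
#' @param config A [run_config()]; `seed` must be set (stochastic stage).
#' @param scenarios Scenario list (default [scenario_grid()]).
#' @param n_reps Replicates per scenario.
#' @param alpha Test level.
#' @return Invisibly, a list with the rejection `table`, the method
#'   `comparison` and the output `path` (`rejection_rates.tsv`).
#' @export
cmd_power <- function(config, scenarios = scenario_grid(), n_reps = 2000,
                      alpha = 0.05) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$seed)) {
    stop("a seed is required to run the stochastic power stage", call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- estimate_rejection_rates(scenarios, n_reps = n_reps, alpha = alpha,
                                  seed = config$seed)
  cmp <- compare_methods(tab)
  path <- file.path(config$out_dir, "rejection_rates.tsv")
  con <- file(path, "wt")
  writeLines(paste0("# ", output_comment(config)), con)
  close(con)
  data.table::fwrite(tab, path, sep = "\t", quote = FALSE, append = TRUE,
                     col.names = TRUE)
  invisible(list(table = tab, comparison = cmp, path = path))
}

#' Run the post-GWAS report stage
#'
#' Filters the meta-analysis results to genome-wide significance, clumps
#' them into independent variants, merges those into risk loci, flags
#' variants with significant opposite-direction effects, and tabulates
#' per-method unique hits. Writes `loci.tsv` and `opposite_direction.tsv`
#' under `out_dir`.
#'
#' @param config A [run_config()] with an `ld` provider set.
#' @param results Optional results data frame; defaults to reading
#'   `meta_results.tsv` from `out_dir`.
#' @return Invisibly, a list with `significant`, `independent`, `loci`,
#'   `opposite`, `unique_hits` and the output paths.
#' @export
cmd_report <- function(config, results = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(results)) {
    path <- file.path(config$out_dir, "meta_results.tsv")
    if (!file.exists(path)) {
      stop("no `results` given and ", path, " not found; run cmd_meta() first",
           call. = FALSE)
    }
    results <- read_results(path)
  }
  if (is.null(config$ld)) {
    stop("config must carry an `ld` provider for clumping", call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sig <- filter_genome_wide(results, config$alpha_gw)
  message(nrow(sig), " of ", nrow(results), " variants genome-wide significant")
  indep <- clump(sig, config$ld, config$clump_window_bp, config$clump_r2_min)
  loci <- merge_loci(indep, config$merge_bp)
  opp <- flag_opposite_direction(results, config$alpha_gw)
  uh <- method_unique_hits(results, config$alpha_gw)
  loci_path <- file.path(config$out_dir, "loci.tsv")
  opp_path <- file.path(config$out_dir, "opposite_direction.tsv")
  con <- file(loci_path, "wt")
  writeLines(paste0("# ", output_comment(config)), con)
  close(con)
  data.table::fwrite(loci, loci_path, sep = "\t", quote = FALSE, append = TRUE,
                     col.names = TRUE)
  write_results(opp, opp_path, comment = output_comment(config))
  invisible(list(significant = sig, independent = indep, loci = loci,
                 opposite = opp, unique_hits = uh,
                 paths = c(loci = loci_path, opposite = opp_path)))
}

#' Simulate and write a cohort or a paired summary-statistic table
#'
#' @param config A [run_config()]; `seed` must be set.
#' @param sc A [scenario()].
#' @param what `"cohort"` (individual-level TSV: id, y, sex, genotype,
#'   covariates) or `"sumstats"` (paired summary records).
#' @param n_reps Replicates for `what = "sumstats"`.
#' @return Invisibly, the output path.
#' @export
cmd_simulate <- function(config, sc, what = c("cohort", "sumstats"),
                         n_reps = 1) {
  stopifnot(inherits(config, "run_config"), inherits(sc, "sexmeta_scenario"))
  what <- match.arg(what)
  if (is.null(config$seed)) {
    stop("a seed is required to run the stochastic simulate stage", call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (what == "cohort") {
    coh <- simulate_cohort(sc, seed = config$seed)
    d <- data.frame(id = coh$ids, y = coh$y, sex = coh$s, genotype = coh$g)
    if (!is.null(coh$X)) d <- cbind(d, as.data.frame(coh$X))
    path <- file.path(config$out_dir, "cohort.tsv")
  } else {
    d <- simulate_sumstats(sc, n_reps = n_reps, seed = config$seed)
    path <- file.path(config$out_dir, "sumstats_pairs.tsv")
  }
  data.table::fwrite(d, path, sep = "\t", quote = FALSE)
  invisible(path)
}
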