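# Monte-Carlo type-I error and power estimation for the five association
# tests, with a closed-form noncentral oracle for validation.

METHODS <- c("T_Female", "T_Male", "T_Diff", "T_1_metaL", "T_2_metaQ")

reject_matrix <- function(sims, alpha) {
  thr <- -log10(alpha)
  d <- test_diff(sims$beta_F, sims$se_F, sims$beta_M, sims$se_M)
  l <- test_meta_linear(sims$z_F, sims$se_F, sims$z_M, sims$se_M)
  q <- test_meta_quadratic(sims$z_F, sims$z_M)
  cbind(
    T_Female = sims$neglog10_p_F > thr,
    T_Male = sims$neglog10_p_M > thr,
    T_Diff = d$neglog10p > thr,
    T_1_metaL = l$neglog10p > thr,
    T_2_metaQ = q$neglog10p > thr
  )
}

#' Monte-Carlo rejection rates for the five tests across scenarios
#'
#' For each scenario, simulates `n_reps` paired per-sex summary records and
#' records the proportion of replicates in which each of the five tests
#' (female-only, male-only, effect-difference, linear meta-analysis,
#' omnibus quadratic meta-analysis) rejects at level `alpha`. Under a null
#' scenario the rejection rate estimates the type-I error; otherwise the
#' power. The default engine draws summary statistics directly
#' ([simulate_sumstats()]); `engine = "cohort"` runs the full
#' individual-level path ([simulate_cohort()] + [stratified_gwas()]) for
#' end-to-end validation at reduced replicate counts.
#'
#' @param scenarios Named list of [scenario()] objects (default
#'   [scenario_grid()]).
#' @param n_reps Replicates per scenario (>= 100).
#' @param alpha Test level in (0, 1).
#' @param seed Integer seed; scenario i uses substream
#'   `derive_seed(seed, i)`.
#' @param engine `"summary"` or `"cohort"`.
#' @return A data frame with one row per (scenario, method): `rejection`,
#'   `n_reps`, `alpha`, and the binomial Monte-Carlo standard error
#'   `mc_se = sqrt(r (1 - r) / n_reps)`.
#' @export
estimate_rejection_rates <- function(scenarios = scenario_grid(),
                                     n_reps = 2000, alpha = 0.05, seed = 1,
                                     engine = c("summary", "cohort")) {
  engine <- match.arg(engine)
  stopifnot(n_reps >= 100, alpha > 0, alpha < 1)
  if (is.null(names(scenarios))) {
    names(scenarios) <- paste0("scenario_", seq_along(scenarios))
  }
  out <- vector("list", length(scenarios))
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    if (engine == "summary") {
      sims <- simulate_sumstats(sc, n_reps = n_reps,
                                seed = derive_seed(seed, i))
    } else {
      set.seed(derive_seed(seed, i))
      rows <- vector("list", n_reps)
      for (r in seq_len(n_reps)) {
        strat <- stratified_gwas(simulate_cohort(sc))
        rows[[r]] <- data.frame(
          beta_F = strat$beta[1], se_F = strat$se[1], z_F = strat$z[1],
          neglog10_p_F = strat$neglog10p[1],
          beta_M = strat$beta[2], se_M = strat$se[2], z_M = strat$z[2],
          neglog10_p_M = strat$neglog10p[2]
        )
      }
      sims <- do.call(rbind, rows)
    }
    rej <- colMeans(reject_matrix(sims, alpha))
    out[[i]] <- data.frame(
      scenario = names(scenarios)[i], method = METHODS,
      rejection = as.numeric(rej), n_reps = n_reps, alpha = alpha,
      mc_se = sqrt(pmax(rej * (1 - rej), 0) / n_reps),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  do.call(rbind, out)
}

#' Closed-form asymptotic power of the five tests
#'
#' Per-sex noncentrality is `ncp_s = beta_s / v_s` with
#' `v_s^2 = sigma_s^2 / (2 maf (1 - maf) n_s)`. The 1-df tests have power
#' `P(|Z + ncp| > z_{alpha/2})`; the omnibus quadratic test has power given
#' by the noncentral chi-square (2 df) upper tail at noncentrality
#' `ncp_F^2 + ncp_M^2`. Used as the independent oracle for the Monte-Carlo
#' estimates.
#'
#' @param sc A [scenario()].
#' @param alpha Test level.
#' @return A data frame with `method` and `power`.
#' @export
analytic_power <- function(sc, alpha = 0.05) {
  stopifnot(inherits(sc, "sexmeta_scenario"))
  vF <- sc$sigma_F / sqrt(2 * sc$maf * (1 - sc$maf) * sc$n_F)
  vM <- sc$sigma_M / sqrt(2 * sc$maf * (1 - sc$maf) * sc$n_M)
  ncF <- sc$beta_F / vF
  ncM <- sc$beta_M / vM
  zc <- stats::qnorm(1 - alpha / 2)
  pow1 <- function(nc) stats::pnorm(-zc - nc) + stats::pnorm(nc - zc)
  ncD <- (sc$beta_F - sc$beta_M) / sqrt(vF^2 + vM^2)
  ncL <- ((1 / vF) * ncF + (1 / vM) * ncM) / sqrt(1 / vF^2 + 1 / vM^2)
  powQ <- stats::pchisq(stats::qchisq(1 - alpha, df = 2), df = 2,
                        ncp = ncF^2 + ncM^2, lower.tail = FALSE)
  data.frame(method = METHODS,
             power = c(pow1(ncF), pow1(ncM), pow1(ncD), pow1(ncL), powQ),
             stringsAsFactors = FALSE)
}

#' Rank methods by power and report the omnibus test's deficit
#'
#' For each scenario in a rejection table, ranks the methods by rejection
#' rate and reports how far the omnibus quadratic meta-analysis falls
#' short of the best method -- the quantity behind the robustness claim
#' that the joint test is either the most powerful or loses only a small
#' margin to the scenario-specific oracle.
#'
#' @param table Output of [estimate_rejection_rates()] covering at least
#'   two methods.
#' @return A data frame with one row per scenario: `best_method`,
#'   `best_power`, `power_metaQ`, `deficit_metaQ`, `rank_metaQ`.
#' @export
compare_methods <- function(table) {
  if (length(unique(table$method)) < 2) {
    stop("`table` must cover at least two methods", call. = FALSE)
  }
  out <- lapply(split(table, table$scenario), function(d) {
    d <- d[order(-d$rejection, d$method), ]
    q <- d[d$method == "T_2_metaQ", ]
    data.frame(
      scenario = d$scenario[1],
      best_method = d$method[1], best_power = d$rejection[1],
      power_metaQ = if (nrow(q)) q$rejection else NA_real_,
      deficit_metaQ = if (nrow(q)) d$rejection[1] - q$rejection else NA_real_,
      rank_metaQ = if (nrow(q)) match("T_2_metaQ", d$method) else NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[match(unique(table$scenario), out$scenario), , drop = FALSE]
}
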