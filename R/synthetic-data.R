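# Generators for cohorts and summary statistics with sex-specific genetic
# effects, phenotype means and residual variances, plus the rank-based
# inverse normal transform utility. All randomness flows through explicit
# integer seeds; replicate r of scenario s draws from the documented
# substream derive_seed(seed, index).

#' Deterministic seed substream
#'
#' Maps a user seed and a stream index to an integer below 2^31, so that
#' each scenario/replicate gets an independent, reproducible stream.
#' @param seed Base integer seed.
#' @param index Non-negative stream index.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 +
                as.numeric(index) * 8191 + 1) %% 2147483629)
}

#' Define a generative scenario for one variant
#'
#' A scenario bundles the per-sex sample sizes, the minor-allele frequency,
#' the true per-allele effects, the sex-specific phenotype means and
#' residual standard deviations, and optional nuisance covariates.
#'
#' @param n_F,n_M Per-sex sample sizes (>= 0).
#' @param maf Minor-allele frequency in (0, 0.5].
#' @param beta_F,beta_M True additive effects, phenotype units per minor
#'   allele.
#' @param mu_F,mu_M Sex-specific phenotype means.
#' @param sigma_F,sigma_M Sex-specific residual SDs (> 0).
#' @param covariates Optional named list; each element a list with
#'   `effect` (scalar) and `sample` (function of n returning draws).
#' @param name Optional label.
#' @return An object of class `sexmeta_scenario`.
#' @export
scenario <- function(n_F = 2000, n_M = 2000, maf = 0.3,
                     beta_F = 0, beta_M = 0,
                     mu_F = 0, mu_M = 1,
                     sigma_F = 1, sigma_M = 1,
                     covariates = NULL, name = NULL) {
  stopifnot(n_F >= 0, n_M >= 0, maf > 0, maf <= 0.5,
            sigma_F > 0, sigma_M > 0)
  if (!is.null(covariates)) {
    ok <- all(vapply(covariates, function(cv) {
      is.list(cv) && is.numeric(cv$effect) && is.function(cv$sample)
    }, logical(1)))
    if (!ok) stop("each covariate needs an `effect` and a `sample` function",
                  call. = FALSE)
  }
  structure(list(n_F = n_F, n_M = n_M, maf = maf,
                 beta_F = beta_F, beta_M = beta_M,
                 mu_F = mu_F, mu_M = mu_M,
                 sigma_F = sigma_F, sigma_M = sigma_M,
                 covariates = covariates, name = name),
            class = "sexmeta_scenario")
}

#' @export
print.sexmeta_scenario <- function(x, ...) {
  cat(sprintf("scenario%s: n=(%d F, %d M), maf=%.3g, beta=(%.3g, %.3g), mu=(%.3g, %.3g), sigma=(%.3g, %.3g)\n",
              if (is.null(x$name)) "" else paste0(" `", x$name, "`"),
              x$n_F, x$n_M, x$maf, x$beta_F, x$beta_M,
              x$mu_F, x$mu_M, x$sigma_F, x$sigma_M))
  invisible(x)
}

#' Draw genotypes under Hardy-Weinberg equilibrium
#'
#' i.i.d. minor-allele counts with P(0) = (1-maf)^2, P(1) = 2 maf (1-maf),
#' P(2) = maf^2.
#'
#' @param n Number of individuals.
#' @param maf Minor-allele frequency in (0, 0.5].
#' @param seed Optional integer seed (set when given).
#' @export
simulate_genotypes <- function(n, maf, seed = NULL) {
  if (!is.numeric(maf) || maf <= 0 || maf > 0.5) {
    stop("`maf` must lie in (0, 0.5]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sample(0:2, n, replace = TRUE,
         prob = c((1 - maf)^2, 2 * maf * (1 - maf), maf^2))
}

#' Construct a cohort object from raw vectors
#'
#' @param y Phenotype vector.
#' @param g Genotype vector in \{0,1,2\}.
#' @param s Sex indicator (0 = female, 1 = male).
#' @param X Optional covariate matrix.
#' @param ids Optional row labels.
#' @export
as_cohort <- function(y, g = NULL, s = NULL, X = NULL, ids = NULL) {
  if (is.list(y) && !is.data.frame(y)) {
    if (inherits(y, "sexmeta_cohort")) return(y)
    g <- y$g; s <- y$s; X <- y$X; ids <- y$ids; y <- y$y
  }
  n <- length(y)
  stopifnot(length(g) == n, length(s) == n)
  if (any(!g %in% c(0, 1, 2))) stop("`g` must contain only 0/1/2", call. = FALSE)
  if (any(!s %in% c(0, 1))) stop("`s` must contain only 0/1", call. = FALSE)
  if (anyNA(y) || anyNA(g) || anyNA(s) || (!is.null(X) && anyNA(X))) {
    stop("cohort contains missing values", call. = FALSE)
  }
  if (is.null(ids)) ids <- paste0("id", seq_len(n))
  structure(list(y = as.numeric(y), g = as.numeric(g), s = as.numeric(s),
                 X = X, ids = ids),
            class = "sexmeta_cohort")
}

#' Simulate an individual-level cohort from a scenario
#'
#' Phenotypes follow `y = mu_s + beta_s * g + X b_X + e`, with
#' `e ~ N(0, sigma_s^2)` depending on sex. Rows are shuffled so that sex
#' is not confounded with row order. Deterministic given `seed`.
#'
#' @param sc A [scenario()].
#' @param seed Integer seed.
#' @return A `sexmeta_cohort` (see [as_cohort()]).
#' @export
simulate_cohort <- function(sc, seed = NULL) {
  stopifnot(inherits(sc, "sexmeta_scenario"))
  if (!is.null(seed)) set.seed(seed)
  n <- sc$n_F + sc$n_M
  s <- c(rep(0, sc$n_F), rep(1, sc$n_M))
  g <- simulate_genotypes(n, sc$maf)
  mu <- ifelse(s == 0, sc$mu_F, sc$mu_M)
  beta <- ifelse(s == 0, sc$beta_F, sc$beta_M)
  sig <- ifelse(s == 0, sc$sigma_F, sc$sigma_M)
  y <- mu + beta * g + stats::rnorm(n, 0, sig)
  X <- NULL
  if (!is.null(sc$covariates)) {
    X <- sapply(sc$covariates, function(cv) cv$sample(n))
    X <- matrix(X, nrow = n, dimnames = list(NULL, names(sc$covariates)))
    eff <- vapply(sc$covariates, function(cv) cv$effect, numeric(1))
    y <- y + as.numeric(X %*% eff)
  }
  ord <- sample.int(n)
  as_cohort(y = y[ord], g = g[ord], s = s[ord],
            X = if (is.null(X)) NULL else X[ord, , drop = FALSE])
}

#' Simulate per-sex summary statistics directly (summary-level shortcut)
#'
#' Draws `beta_hat_s ~ N(beta_s, v_s^2)` with the asymptotic sampling
#' variance `v_s^2 = sigma_s^2 / (2 maf (1 - maf) n_s)` and reports
#' `se = v_s`, so `z_s = beta_hat_s / v_s` is exactly normal with
#' noncentrality `beta_s / v_s`. Asymptotically matches
#' [simulate_cohort()] followed by [stratified_gwas()], at a tiny fraction
#' of the cost; this is the default engine of the power study.
#'
#' @param sc A [scenario()] with `n_F`, `n_M >= 30`.
#' @param n_reps Number of replicate records to draw.
#' @param seed Optional integer seed.
#' @return A data frame of `n_reps` paired records with columns `variant`,
#'   `maf_F`, `maf_M`, `beta_F`, `se_F`, `z_F`, `p_F`, and the male
#'   counterparts.
#' @export
simulate_sumstats <- function(sc, n_reps = 1, seed = NULL) {
  stopifnot(inherits(sc, "sexmeta_scenario"))
  if (sc$n_F < 30 || sc$n_M < 30) {
    stop("summary-level simulation needs n_F, n_M >= 30", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  vF <- sc$sigma_F / sqrt(2 * sc$maf * (1 - sc$maf) * sc$n_F)
  vM <- sc$sigma_M / sqrt(2 * sc$maf * (1 - sc$maf) * sc$n_M)
  bF <- stats::rnorm(n_reps, sc$beta_F, vF)
  bM <- stats::rnorm(n_reps, sc$beta_M, vM)
  zF <- bF / vF
  zM <- bM / vM
  pF <- p_from_z(zF)
  pM <- p_from_z(zM)
  data.frame(
    variant = paste0("sim_", seq_len(n_reps)),
    maf_F = sc$maf, maf_M = sc$maf,
    n_F = sc$n_F, n_M = sc$n_M,
    beta_F = bF, se_F = vF, z_F = zF, p_F = pF$p, neglog10_p_F = pF$neglog10p,
    beta_M = bM, se_M = vM, z_M = zM, p_M = pM$p, neglog10_p_M = pM$neglog10p,
    stringsAsFactors = FALSE
  )
}

#' Preset scenario grid spanning the heterogeneity configurations
#'
#' Returns the six named configurations the power study runs over: no
#' effect, homogeneous effect, effect exclusive to one sex (both ways),
#' equal-magnitude opposite directions, and same-direction magnitude
#' difference. Effect sizes default to values giving mid-range (~0.6-0.9)
#' per-sex power at alpha = 0.05 with the default n = 2000 per sex and
#' maf = 0.3, keeping method comparisons discriminative at desk scale.
#'
#' @param n_F,n_M,maf,sigma_F,sigma_M Shared scenario parameters.
#' @param effect,effect_small Effect sizes used by the presets: `effect`
#'   for one-sex-only (0.11) and opposite directions (0.10), and
#'   `effect_small` (0.08) for the homogeneous preset.
#' @return Named list of [scenario()] objects.
#' @export
scenario_grid <- function(n_F = 2000, n_M = 2000, maf = 0.3,
                          sigma_F = 1, sigma_M = 1,
                          effect = 0.11, effect_small = 0.08) {
  base <- function(bF, bM, nm) {
    scenario(n_F = n_F, n_M = n_M, maf = maf,
             beta_F = bF, beta_M = bM,
             mu_F = 0, mu_M = 1, sigma_F = sigma_F, sigma_M = sigma_M,
             name = nm)
  }
  list(
    null = base(0, 0, "null"),
    homogeneous = base(effect_small, effect_small, "homogeneous"),
    female_only = base(effect, 0, "female_only"),
    male_only = base(0, effect, "male_only"),
    opposite_equal = base(-0.10, 0.10, "opposite_equal"),
    magnitude_diff = base(0.12, 0.04, "magnitude_diff")
  )
}

#' Rank-based inverse normal transformation (IRNT)
#'
#' Maps `y` to `qnorm((rank - offset) / (n - 2*offset + 1))` with average
#' ranks for ties; the default offset 0.5 gives the (r - 0.5)/n variant.
#' `mode = "per_group"` transforms within each group separately (as done
#' in sex-specific phenotype pipelines), which centres every group at zero
#' and therefore makes stratified and pooled response scales inconsistent
#' -- the reason raw-phenotype analyses are preferred for meta/mega
#' equivalence.
#'
#' @param y Numeric vector (not all equal).
#' @param groups Group labels, required for `mode = "per_group"`.
#' @param mode `"pooled"` or `"per_group"`.
#' @param offset Rank offset c in (r - c) / (n - 2c + 1).
#' @export
apply_irnt <- function(y, groups = NULL, mode = c("pooled", "per_group"),
                       offset = 0.5) {
  mode <- match.arg(mode)
  if (length(y) == 0) stop("`y` is empty", call. = FALSE)
  irnt1 <- function(v) {
    if (length(unique(v)) < 2) {
      stop("all values equal; ranks are degenerate", call. = FALSE)
    }
    r <- rank(v, ties.method = "average")
    stats::qnorm((r - offset) / (length(v) - 2 * offset + 1))
  }
  if (mode == "pooled") return(irnt1(y))
  if (is.null(groups)) stop("`groups` required for per-group IRNT", call. = FALSE)
  out <- numeric(length(y))
  for (gr in unique(groups)) {
    idx <- groups == gr
    out[idx] <- irnt1(y[idx])
  }
  out
}
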