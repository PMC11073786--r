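# Core sex-combined association statistics.
#
# Everything here is a pure, vectorized function over per-sex effect
# estimates (beta), standard errors (se), Wald z-statistics and two-sided
# p-values. Tail probabilities are always computed in log space so that the
# -log10(p) surface stays finite and accurate out to |z| well beyond 40
# (p below the smallest positive double); the `p` fields may underflow to 0
# in double precision but the paired `neglog10p` fields never do.

LOG10 <- log(10)

#' Wald z-statistic from an effect estimate and its standard error
#'
#' @param beta Additive effect per copy of the minor allele.
#' @param se Standard error of `beta`; must be strictly positive.
#' @return `beta / se`, vectorized.
#' @examples
#' z_from_beta_se(1, 0.5)
#' @export
z_from_beta_se <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("`se` must be strictly positive and finite", call. = FALSE)
  }
  beta / se
}

#' Two-sided normal p-value from a z-statistic
#'
#' Computes `p = 2 * pnorm(-|z|)` together with `-log10(p)` evaluated via
#' the log survival function, so the -log10 value is finite and accurate
#' even when `p` itself underflows (|z| > ~38).
#'
#' @param z Wald statistic(s); must be finite.
#' @return A list with components `p` and `neglog10p`.
#' @export
p_from_z <- function(z) {
  if (any(!is.finite(z))) stop("`z` must be finite", call. = FALSE)
  logp <- log(2) + stats::pnorm(-abs(z), log.p = TRUE)
  list(p = exp(logp), neglog10p = -logp / LOG10)
}

#' Signed z-statistic from a two-sided p-value
#'
#' Inverts [p_from_z()]: `|z| = qnorm(1 - p/2)` computed on the log scale,
#' with the sign of the effect applied. Exact inverse to within 1e-6
#' relative for p down to 1e-300.
#'
#' @param p Two-sided p-value(s) in (0, 1].
#' @param sign Effect sign(s), one of -1, 0, +1 (any negative/positive
#'   number is reduced to its sign).
#' @export
z_from_p_sign <- function(p, sign) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("`p` must lie in (0, 1]", call. = FALSE)
  }
  absz <- -stats::qnorm(log(p) - log(2), log.p = TRUE)
  # qnorm(log(1/2), log.p = TRUE) is exactly 0 at p = 1
  base::sign(sign) * absz
}

#' Standard error back-derived from an effect estimate and its p-value
#'
#' Reconstructs `se = |beta| / |z(p)|`, as needed when a summary file (or a
#' printed table) carries beta and p but no standard error.
#'
#' @param beta Nonzero effect estimate.
#' @param p Two-sided p-value in (0, 1).
#' @export
se_from_beta_p <- function(beta, p) {
  if (any(beta == 0)) stop("`beta` must be nonzero to back-derive `se`", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("`p` must lie strictly in (0, 1) to back-derive `se`", call. = FALSE)
  }
  abs(beta) / abs(z_from_p_sign(p, 1))
}

#' Interaction-only test for a sex difference in genetic effect
#'
#' Tests H0: beta_F = beta_M with the effect-difference Wald statistic
#' `z = (beta_F - beta_M) / sqrt(se_F^2 + se_M^2)`, standard normal under
#' the null of no difference.
#'
#' @param beta_F,se_F Female effect estimate and standard error.
#' @param beta_M,se_M Male effect estimate and standard error.
#' @return A list with `z`, `p`, `neglog10p`.
#' @export
test_diff <- function(beta_F, se_F, beta_M, se_M) {
  if (any(se_F <= 0) || any(se_M <= 0)) {
    stop("standard errors must be strictly positive", call. = FALSE)
  }
  z <- (beta_F - beta_M) / sqrt(se_F^2 + se_M^2)
  c(list(z = z), p_from_z(z))
}

#' Traditional fixed-effect (linear) meta-analysis of two sex strata
#'
#' Combines the per-sex z-statistics with inverse-variance weights:
#' `z = ((1/v_F) z_F + (1/v_M) z_M) / sqrt(1/v_F^2 + 1/v_M^2)`, where
#' v_F, v_M are the per-sex standard errors. This equals the usual
#' inverse-variance-weighted fixed-effect meta-analysis z and is standard
#' normal under the null of no association. Powerful when effects are
#' homogeneous; collapses to zero when effects are equal and opposite.
#'
#' @param z_F,z_M Per-sex Wald statistics.
#' @param se_F,se_M Per-sex standard errors (weights).
#' @return A list with `z`, `p`, `neglog10p`.
#' @export
test_meta_linear <- function(z_F, se_F, z_M, se_M) {
  if (any(se_F <= 0) || any(se_M <= 0)) {
    stop("standard errors must be strictly positive", call. = FALSE)
  }
  z <- ((1 / se_F) * z_F + (1 / se_M) * z_M) / sqrt(1 / se_F^2 + 1 / se_M^2)
  c(list(z = z), p_from_z(z))
}

#' Omnibus quadratic meta-analysis (2-df joint main + interaction test)
#'
#' Sums the squared per-sex z-statistics, `chi2 = z_F^2 + z_M^2`, which is
#' chi-square with 2 df under the null of no association in either sex.
#' Because the combination is quadratic, the test is direction-agnostic:
#' it retains power when the two sexes have opposite effect directions,
#' where the linear meta-analysis loses all power. The upper tail of the
#' 2-df chi-square has the closed form `p = exp(-chi2/2)`, evaluated in
#' log space.
#'
#' @param z_F,z_M Per-sex Wald statistics; must be finite.
#' @return A list with `chi2`, `p`, `neglog10p`.
#' @export
test_meta_quadratic <- function(z_F, z_M) {
  if (any(!is.finite(z_F)) || any(!is.finite(z_M))) {
    stop("z-statistics must be finite", call. = FALSE)
  }
  chi2 <- z_F^2 + z_M^2
  list(chi2 = chi2, p = exp(-chi2 / 2), neglog10p = chi2 / (2 * LOG10))
}

#' Apply all three sex-combined tests to paired per-sex summary statistics
#'
#' Takes a data frame of harmonized pairs (one row per variant with columns
#' `beta_F`, `se_F`, `beta_M`, `se_M`; `z_F`/`z_M` are recomputed from
#' beta/se when absent) and appends the effect-difference, linear
#' meta-analysis, and omnibus quadratic meta-analysis statistics with their
#' p-values and -log10 p-values.
#'
#' @param pairs Data frame of paired per-sex summary statistics.
#' @return `pairs` with columns `z_diff`, `p_diff`, `neglog10_p_diff`,
#'   `z_metaL`, `p_metaL`, `neglog10_p_metaL`, `chi2_metaQ`, `p_metaQ`,
#'   `neglog10_p_metaQ` appended.
#' @export
run_all_tests <- function(pairs) {
  pairs <- as.data.frame(pairs)
  need <- c("beta_F", "se_F", "beta_M", "se_M")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) {
    stop("`pairs` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(pairs) == 0) {
    extra <- c("z_diff", "p_diff", "neglog10_p_diff", "z_metaL", "p_metaL",
               "neglog10_p_metaL", "chi2_metaQ", "p_metaQ", "neglog10_p_metaQ")
    for (cn in extra) pairs[[cn]] <- numeric(0)
    return(pairs)
  }
  bad <- which(!is.finite(pairs$se_F) | pairs$se_F <= 0 |
                 !is.finite(pairs$se_M) | pairs$se_M <= 0)
  if (length(bad)) {
    ids <- if (!is.null(pairs$variant)) pairs$variant[bad] else bad
    stop("non-positive standard error for variant(s): ",
         paste(utils::head(ids, 5L), collapse = ", "), call. = FALSE)
  }
  if (is.null(pairs$z_F)) pairs$z_F <- z_from_beta_se(pairs$beta_F, pairs$se_F)
  if (is.null(pairs$z_M)) pairs$z_M <- z_from_beta_se(pairs$beta_M, pairs$se_M)

  d <- test_diff(pairs$beta_F, pairs$se_F, pairs$beta_M, pairs$se_M)
  l <- test_meta_linear(pairs$z_F, pairs$se_F, pairs$z_M, pairs$se_M)
  q <- test_meta_quadratic(pairs$z_F, pairs$z_M)

  pairs$z_diff <- d$z
  pairs$p_diff <- d$p
  pairs$neglog10_p_diff <- d$neglog10p
  pairs$z_metaL <- l$z
  pairs$p_metaL <- l$p
  pairs$neglog10_p_metaL <- l$neglog10p
  pairs$chi2_metaQ <- q$chi2
  pairs$p_metaQ <- q$p
  pairs$neglog10_p_metaQ <- q$neglog10p
  pairs
}
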