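# Post-GWAS stage: genome-wide significance filtering, greedy LD clumping,
# single-linkage locus merging, opposite-direction flagging and per-method
# unique-hit comparison. LD is consumed through an abstract provider so
# that either a dense r^2 matrix fixture or a synthetic block generator
# can back it; reference-panel handling is out of scope.

#' LD provider backed by a dense r-squared matrix
#'
#' @param mat Square numeric matrix of pairwise r^2 values with variant
#'   ids as dimnames; must be symmetric with unit diagonal and entries in
#'   \[0, 1\].
#' @return An object usable with [ld_r2()].
#' @export
ld_matrix_provider <- function(mat) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("LD matrix needs variant ids as dimnames", call. = FALSE)
  }
  if (!isTRUE(all.equal(mat, t(mat), tolerance = 1e-8))) {
    stop("LD matrix must be symmetric", call. = FALSE)
  }
  if (any(mat < 0 | mat > 1)) stop("r^2 values must lie in [0, 1]", call. = FALSE)
  if (any(abs(diag(mat) - 1) > 1e-8)) {
    stop("LD matrix diagonal must be 1", call. = FALSE)
  }
  structure(list(mat = mat), class = c("ld_matrix", "ld_provider"))
}

#' LD provider from disjoint blocks of variants
#'
#' Variants inside the same block share `r2_within`; all other pairs have
#' `r2_between` (default 0, i.e. independent blocks).
#'
#' @param blocks List of character vectors of variant ids.
#' @param r2_within,r2_between r^2 inside vs across blocks.
#' @export
ld_block_provider <- function(blocks, r2_within = 1, r2_between = 0) {
  stopifnot(r2_within >= 0, r2_within <= 1, r2_between >= 0, r2_between <= 1)
  ids <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(ids)) stop("blocks must be disjoint", call. = FALSE)
  block_of <- rep(seq_along(blocks), lengths(blocks))
  names(block_of) <- ids
  structure(list(block_of = block_of, r2_within = r2_within,
                 r2_between = r2_between),
            class = c("ld_blocks", "ld_provider"))
}

#' Pairwise r-squared lookup
#'
#' @param ld An LD provider.
#' @param a Single variant id.
#' @param b Vector of variant ids.
#' @return Numeric vector of r^2(a, b).
#' @export
ld_r2 <- function(ld, a, b) UseMethod("ld_r2")

#' @export
ld_r2.ld_matrix <- function(ld, a, b) {
  ids <- rownames(ld$mat)
  missing <- setdiff(c(a, b), ids)
  if (length(missing)) {
    stop("LD lookup failed for pair (", a, ", ", paste(missing, collapse = ","),
         "): id(s) not in matrix", call. = FALSE)
  }
  unname(ld$mat[a, b])
}

#' @export
ld_r2.ld_blocks <- function(ld, a, b) {
  ba <- ld$block_of[a]
  bb <- ld$block_of[b]
  out <- ifelse(!is.na(bb) & !is.na(ba) & bb == ba, ld$r2_within, ld$r2_between)
  out[a == b] <- 1
  unname(out)
}

neglog10_col <- function(results, method) {
  nl <- sub("^p_", "neglog10_p_", method)
  if (nl %in% names(results)) return(results[[nl]])
  -log10(results[[method]])
}

#' Keep genome-wide significant records
#'
#' Strict threshold `p < alpha` (default 5e-8), compared on the -log10
#' scale so that p-values below double underflow still filter correctly.
#'
#' @param results Results data frame (from [run_all_tests()] or
#'   [read_results()]).
#' @param alpha Significance threshold.
#' @param method p-value column to filter on (default the omnibus test).
#' @export
filter_genome_wide <- function(results, alpha = 5e-8, method = "p_metaQ") {
  keep <- neglog10_col(results, method) > -log10(alpha)
  results[which(keep), , drop = FALSE]
}

#' Greedy LD clumping of significant variants
#'
#' Repeatedly takes the remaining record with the smallest p-value as an
#' index variant and absorbs all remaining records on the same chromosome
#' within `window_bp` of it and with r^2 strictly greater than `r2_min`.
#' Defaults follow standard practice (10 Mb window, r^2 > 0.01). Ties in p
#' are broken canonically by (chromosome, position, id), so the output is
#' invariant to input row order.
#'
#' @param records Significant records with `variant`, `chr`, `pos` and the
#'   p-value column.
#' @param ld An LD provider ([ld_matrix_provider()] /
#'   [ld_block_provider()]).
#' @param window_bp Physical window around the index variant.
#' @param r2_min Strict r^2 threshold for absorption.
#' @param method p-value column to rank on.
#' @return The independent index records, with `n_clumped` (clump size
#'   including the index) and `clump_members` (comma-joined ids) appended.
#' @export
clump <- function(records, ld, window_bp = 1e7, r2_min = 0.01,
                  method = "p_metaQ") {
  if (nrow(records) == 0) {
    records$n_clumped <- integer(0)
    records$clump_members <- character(0)
    return(records)
  }
  nl <- neglog10_col(records, method)
  ord <- order(-nl, records$chr, records$pos, records$variant)
  records <- records[ord, , drop = FALSE]
  remaining <- rep(TRUE, nrow(records))
  keep_idx <- integer(0)
  n_clumped <- integer(0)
  members <- character(0)
  while (any(remaining)) {
    i <- which(remaining)[1]
    remaining[i] <- FALSE
    cand <- which(remaining &
                    records$chr == records$chr[i] &
                    abs(records$pos - records$pos[i]) <= window_bp)
    absorbed <- integer(0)
    if (length(cand)) {
      r2 <- ld_r2(ld, records$variant[i], records$variant[cand])
      absorbed <- cand[r2 > r2_min]
      remaining[absorbed] <- FALSE
    }
    keep_idx <- c(keep_idx, i)
    n_clumped <- c(n_clumped, 1L + length(absorbed))
    members <- c(members, paste(records$variant[c(i, absorbed)], collapse = ","))
  }
  out <- records[keep_idx, , drop = FALSE]
  out$n_clumped <- n_clumped
  out$clump_members <- members
  rownames(out) <- NULL
  out
}

#' Merge independent variants into risk loci
#'
#' Single-linkage merge of clumped index variants on the same chromosome
#' whose positions lie within `merge_bp` of each other (chains merge
#' transitively). Each locus is represented by its lead variant, the
#' member with the smallest p-value; the span covers all member positions.
#'
#' @param indep Clumped records (from [clump()]).
#' @param merge_bp Merge distance in bp (default 250 kb).
#' @param method p-value column defining the lead.
#' @return A data frame with one row per locus: `locus_id`, `chr`,
#'   `start`, `end`, `lead`, `lead_neglog10p`, `n_members`, `members`.
#' @export
merge_loci <- function(indep, merge_bp = 250000, method = "p_metaQ") {
  if (nrow(indep) == 0) {
    return(data.frame(locus_id = integer(0), chr = integer(0),
                      start = numeric(0), end = numeric(0),
                      lead = character(0), lead_neglog10p = numeric(0),
                      n_members = integer(0), members = character(0),
                      stringsAsFactors = FALSE))
  }
  nl <- neglog10_col(indep, method)
  ord <- order(indep$chr, indep$pos, indep$variant)
  indep <- indep[ord, , drop = FALSE]
  nl <- nl[ord]
  # single-linkage in 1-D: a new locus starts when the gap to the previous
  # variant on the same chromosome exceeds merge_bp
  new_locus <- c(TRUE, diff(indep$pos) > merge_bp | diff(indep$chr) != 0)
  locus <- cumsum(new_locus)
  out <- lapply(split(seq_len(nrow(indep)), locus), function(idx) {
    lead <- idx[which.max(nl[idx])]
    data.frame(
      chr = indep$chr[lead],
      start = min(indep$pos[idx]), end = max(indep$pos[idx]),
      lead = indep$variant[lead], lead_neglog10p = nl[lead],
      n_members = length(idx),
      members = paste(indep$variant[idx], collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out <- cbind(locus_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Flag variants with significant opposite-direction effects in the sexes
#'
#' Keeps variants whose per-sex p-values are both below `alpha` and whose
#' per-sex effect estimates are nonzero with opposite signs -- the
#' sex-divergent signature that the linear meta-analysis is structurally
#' blind to.
#'
#' @param results Results with `p_F`, `p_M`, `beta_F`, `beta_M`.
#' @param alpha Per-sex significance threshold (default genome-wide 5e-8).
#' @export
flag_opposite_direction <- function(results, alpha = 5e-8) {
  thr <- -log10(alpha)
  keep <- neglog10_col(results, "p_F") > thr &
    neglog10_col(results, "p_M") > thr &
    results$beta_F != 0 & results$beta_M != 0 &
    sign(results$beta_F) != sign(results$beta_M)
  results[which(keep), , drop = FALSE]
}

#' Per-method unique and pairwise missed significant variants
#'
#' For every method, reports the variants significant by that method and
#' by no other, plus, for every ordered pair of methods, the variants
#' significant by the first but not the second.
#'
#' @param results Results carrying all five p-value columns (`p_F`, `p_M`,
#'   `p_diff`, `p_metaL`, `p_metaQ`).
#' @param alpha Significance threshold.
#' @return A list with `unique` (named list of variant id vectors) and
#'   `pairwise` (nested list: `pairwise[[m1]][[m2]]` = ids significant by
#'   m1 but not m2).
#' @export
method_unique_hits <- function(results, alpha = 5e-8) {
  cols <- c(T_Female = "p_F", T_Male = "p_M", T_Diff = "p_diff",
            T_1_metaL = "p_metaL", T_2_metaQ = "p_metaQ")
  thr <- -log10(alpha)
  sig <- sapply(cols, function(cn) neglog10_col(results, cn) > thr)
  sig <- matrix(sig, nrow = nrow(results), dimnames = list(NULL, names(cols)))
  uniq <- lapply(seq_along(cols), function(j) {
    results$variant[sig[, j] & rowSums(sig[, -j, drop = FALSE]) == 0]
  })
  names(uniq) <- names(cols)
  pairwise <- lapply(names(cols), function(m1) {
    out <- lapply(setdiff(names(cols), m1), function(m2) {
      results$variant[sig[, m1] & !sig[, m2]]
    })
    names(out) <- setdiff(names(cols), m1)
    out
  })
  names(pairwise) <- names(cols)
  list(unique = uniq, pairwise = pairwise)
}
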