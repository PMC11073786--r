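# Reading, harmonization, QC and result round-tripping.

test_that("reader fills z and p from beta/se or beta/p", {
  path <- write_sumstat_file(data.frame(beta = c(-3.837, 0), se = c(0.2372, 1)))
  d <- read_sumstats(path, group = "female")
  expect_equal(d$z[1], -16.17622260, tolerance = 1e-7)
  expect_equal(d$p[1], 7.42e-59, tolerance = 1e-2)
  expect_equal(d$z[2], 0)
  expect_equal(d$p[2], 1)

  # p-only file: se back-derived, sign from beta
  rows <- data.frame(variant = "rs4308991", beta = -0.007, p = 2.01e-3)
  path2 <- tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(variant = rows$variant, chr = 1, pos = 100, major = "T",
               minor = "A", info = 0.987, n = 154364, maf = 0.398,
               beta = rows$beta, pval = rows$p),
    path2, sep = "\t", quote = FALSE, row.names = FALSE)
  d2 <- read_sumstats(path2, group = "female")
  expect_equal(d2$z, -3.0888, tolerance = 1e-4)
  expect_equal(d2$p, 2.01e-3) # printed p kept verbatim
  expect_equal(d2$se, abs(d2$beta / d2$z), tolerance = 1e-10)
})

test_that("reader errors name missing columns and bad rows; strict flag works", {
  path <- write_sumstat_file(data.frame(beta = 0.1))
  expect_error(read_sumstats(path, neale_column_map(chr = "CHROM"), "female"),
               "CHROM")
  lines <- readLines(path)
  lines[2] <- sub("0\\.99", "not_a_number", lines[2])
  bad <- tempfile(fileext = ".tsv")
  writeLines(lines, bad)
  expect_error(read_sumstats(bad, group = "female"), "line")
  expect_warning(d <- read_sumstats(bad, group = "female", strict = FALSE),
                 "dropped")
  expect_equal(nrow(d), 0)
})

test_that("se wins over a disagreeing p column, with a warning", {
  path <- write_sumstat_file(data.frame(beta = 2, se = 1))
  # p implies z = 3, se implies z = 2
  raw <- utils::read.delim(path)
  raw$pval <- 2 * pnorm(-3)
  utils::write.table(raw, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(d <- read_sumstats(path, group = "male"), "using se")
  expect_equal(d$z, 2)
})

test_that("X chromosome is coded 23 and flows through the autosomal path", {
  path <- write_sumstat_file(data.frame(chr = "X", beta = -0.021))
  d <- read_sumstats(path, group = "female")
  expect_identical(d$chr, 23L)
})

test_that("harmonization pairs shared variants and re-orients flipped alleles", {
  f <- read_sumstats(write_sumstat_file(data.frame(
    variant = c("a", "b", "c", "fonly"), major = "G", minor = "A",
    maf = 0.4, beta = 0.5, pos = c(100, 200, 300, 400))), group = "female")
  m <- read_sumstats(write_sumstat_file(data.frame(
    variant = c("a", "b", "c", "monly1", "monly2"),
    major = c("G", "A", "G", "G", "G"), minor = c("A", "G", "A", "A", "A"),
    maf = 0.4, beta = 0.5, pos = c(100, 200, 300, 500, 600))), group = "male")
  h <- harmonize_groups(f, m)
  expect_equal(nrow(h$pairs), 3)
  expect_equal(h$qc$n_dropped_unmatched, 3)
  expect_equal(h$qc$n_input, 6)
  # variant b was flipped: beta sign reversed, MAF still the minor frequency
  expect_equal(h$pairs$beta_M[h$pairs$variant == "b"], -0.5)
  expect_equal(h$pairs$maf_M[h$pairs$variant == "b"], 0.4)
  expect_equal(h$pairs$beta_M[h$pairs$variant == "a"], 0.5)
})

test_that("conflicting positions or incompatible alleles count as unmatched", {
  f <- read_sumstats(write_sumstat_file(data.frame(
    variant = c("a", "b"), pos = c(100, 200), major = "G", minor = "A")),
    group = "female")
  m <- read_sumstats(write_sumstat_file(data.frame(
    variant = c("a", "b"), pos = c(100, 999), major = c("C", "G"),
    minor = c("T", "A"))), group = "male")
  h <- suppressMessages(harmonize_groups(f, m))
  expect_equal(nrow(h$pairs), 0)
  expect_equal(h$qc$n_dropped_unmatched, 2)
})

test_that("variant QC applies strict per-sex MAF and INFO thresholds", {
  pairs <- data.frame(
    variant = c("lowmafF", "lowinfo", "keep", "edge_maf", "edge_info"),
    maf_F = c(0.005, 0.3, 0.3, 0.01, 0.3),
    maf_M = c(0.02, 0.3, 0.3, 0.3, 0.3),
    info = c(0.99, 0.79, 0.9, 0.9, 0.8)
  )
  q <- apply_variant_qc(pairs)
  expect_identical(q$pairs$variant, "keep")
  expect_equal(q$qc$n_dropped_maf, 2) # 0.005 and the boundary 0.01
  expect_equal(q$qc$n_dropped_info, 2) # 0.79 and the boundary 0.8
  # idempotent
  q2 <- apply_variant_qc(q$pairs)
  expect_identical(q2$pairs, q$pairs)
  expect_equal(q2$qc$n_kept, q2$qc$n_input)
})

test_that("all printed lead SNPs pass the default QC", {
  for (nm in c("testosterone", "urate")) {
    d <- worked_example(nm)
    q <- apply_variant_qc(d)
    expect_equal(nrow(q$pairs), nrow(d))
  }
})

test_that("write/read round trip preserves numeric fields to 1e-6 relative", {
  paths <- worked_example_sumstats("urate")
  f <- read_sumstats(paths["female"], group = "female")
  m <- read_sumstats(paths["male"], group = "male")
  res <- run_all_tests(harmonize_groups(f, m)$pairs)
  out <- tempfile(fileext = ".tsv")
  write_results(res, out, comment = "round-trip fixture")
  back <- read_results(out)
  for (cn in c("pos", "info", "maf_F", "maf_M", "beta_F", "se_F", "p_F",
               "beta_M", "se_M", "p_M", "z_diff", "p_diff", "z_metaL",
               "p_metaL", "chi2_metaQ", "neglog10_p_metaQ")) {
    expect_equal(back[[cn]], res[[cn]], tolerance = 1e-6, label = cn)
  }
  # empty result set: header-only file
  empty <- tempfile(fileext = ".tsv")
  write_results(res[0, ], empty)
  expect_equal(length(readLines(empty)), 1L)
  expect_equal(nrow(read_results(empty)), 0L)
})

test_that("downstream statistics are invariant to allele orientation of one file", {
  paths <- worked_example_sumstats("urate")
  f <- read_sumstats(paths["female"], group = "female")
  m <- read_sumstats(paths["male"], group = "male")
  straight <- run_all_tests(harmonize_groups(f, m)$pairs)

  # flip every male record: swap alleles, negate beta
  raw <- utils::read.delim(paths["male"])
  tmp <- raw$major; raw$major <- raw$minor; raw$minor <- tmp
  raw$beta <- -raw$beta
  flipped_path <- tempfile(fileext = ".tsv")
  utils::write.table(raw, flipped_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  m2 <- read_sumstats(flipped_path, group = "male")
  flipped <- run_all_tests(harmonize_groups(f, m2)$pairs)

  expect_equal(flipped$chi2_metaQ, straight$chi2_metaQ, tolerance = 1e-12)
  expect_equal(flipped$z_diff, straight$z_diff, tolerance = 1e-12)
  expect_equal(flipped$z_metaL, straight$z_metaL, tolerance = 1e-12)
})
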