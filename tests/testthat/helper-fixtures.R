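# Shared test fixtures and independent oracles, all built in code.

TEST_SEED <- 1234L

# write a minimal Neale-style per-sex sumstat TSV; fields beyond `rows`
# columns get sensible defaults
write_sumstat_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  defaults <- data.frame(
    variant = paste0("rs", seq_len(nrow(rows))),
    chr = 1L, pos = seq_len(nrow(rows)) * 1000L,
    major = "A", minor = "G", info = 0.99, n = 1000L,
    maf = 0.25, beta = 0.1, se = 0.05,
    stringsAsFactors = FALSE
  )
  for (cn in names(rows)) defaults[[cn]] <- rows[[cn]]
  utils::write.table(defaults, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# independent greedy-clumping oracle: plain data-frame walk, re-deriving
# the absorption rule from scratch (sort by p, repeat-take-head, absorb by
# explicit distance/r2 scan)
clump_oracle <- function(records, ld, window_bp, r2_min, method = "p_metaQ") {
  nl <- -log10(records[[method]])
  if (paste0("neglog10_", method) %in% names(records)) {
    nl <- records[[paste0("neglog10_", method)]]
  }
  d <- records[order(-nl, records$chr, records$pos, records$variant), ]
  leads <- character(0)
  while (nrow(d) > 0) {
    lead <- d[1, ]
    leads <- c(leads, lead$variant)
    d <- d[-1, , drop = FALSE]
    if (nrow(d) == 0) break
    drop <- logical(nrow(d))
    for (j in seq_len(nrow(d))) {
      if (d$chr[j] == lead$chr && abs(d$pos[j] - lead$pos) <= window_bp &&
            ld_r2(ld, lead$variant, d$variant[j]) > r2_min) {
        drop[j] <- TRUE
      }
    }
    d <- d[!drop, , drop = FALSE]
  }
  leads
}

# random block-LD clumping instance: n variants on 1-2 chromosomes,
# block structure with high within-block r2
random_clump_instance <- function(n = 50) {
  chr <- sample(1:2, n, replace = TRUE)
  pos <- sample.int(3e7, n)
  p <- 10^(-runif(n, 8, 60))
  ids <- paste0("v", seq_len(n))
  n_blocks <- sample(3:8, 1)
  block_id <- sample.int(n_blocks, n, replace = TRUE)
  blocks <- split(ids, block_id)
  list(
    records = data.frame(variant = ids, chr = chr, pos = pos, p_metaQ = p,
                         stringsAsFactors = FALSE),
    ld = ld_block_provider(blocks, r2_within = 0.95, r2_between = 0.001)
  )
}
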