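# Small in-code fixtures shared across test files.

# A RegionStats built directly from vectors.
toyStats <- function(ids = paste0("v", 1:5),
                     pos = seq(100, 500, by = 100),
                     beta = c(0.1, -0.2, 0.3, 0.05, 0),
                     se = rep(0.1, 5),
                     maf = rep(0.3, 5),
                     n = 100L, chrom = "chr1", trait = "geneA",
                     ref = "A", alt = "G") {
  regionStats(
    traitId = trait,
    variants = data.frame(id = ids, chrom = chrom, pos = pos,
                          ref = ref, alt = alt,
                          stringsAsFactors = FALSE),
    beta = beta, se = se, maf = maf, n = n
  )
}

# Simulate one locus + single-causal trait pair and return everything a
# fine-mapping / colocalization test needs.
simPair <- function(seed, m = 60L, nExp = 500L, nOut = 500L, rho = 0.9,
                    blockSize = 10L, causalIdx = 25L, veExp = 0.1,
                    veOut = 0.1, causalIdxOut = causalIdx) {
  cfg <- locusConfig(m = m, nExp = nExp, nOut = nOut, rho = rho,
                     blockSize = blockSize)
  loc <- simulateLocus(cfg, seed = seed)
  arch <- causalArchitecture(
    if (veExp > 0) data.frame(idx = causalIdx, ve = veExp) else NULL,
    if (veOut > 0) data.frame(idx = causalIdxOut, ve = veOut) else NULL
  )
  tr <- simulateTraits(loc$dosExp, loc$dosOut, arch, seed = seed + 1L)
  list(
    loc = loc,
    exp = marginalSumstats(loc$dosExp, tr$yExp, loc$variants, "geneA"),
    out = marginalSumstats(loc$dosOut, tr$yOut, loc$variants, "protA"),
    causalId = loc$variants$id[causalIdx],
    causalIdOut = loc$variants$id[causalIdxOut]
  )
}

# Write a well-formed summary-statistics TSV; returns the path.
writeToyTsv <- function(path, df = NULL) {
  if (is.null(df)) {
    df <- data.frame(
      molecular_trait_id = "geneA",
      variant = paste0("v", 1:5), chromosome = "chr1",
      position = seq(100, 500, 100), ref = "A", alt = "G",
      beta = c(0.1, -0.2, 0.3, 0.05, 0.01), se = rep(0.1, 5),
      maf = c(0.1, 0.2, 0.3, 0.4, 0.5), an = 200L
    )
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
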