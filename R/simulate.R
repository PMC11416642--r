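#' Locus simulation configuration
#'
#' Study conditions for one synthetic cis-locus: a shared haplotype pool
#' with block LD structure, a small exposure cohort (eQTL-scale) and a large
#' outcome cohort (pQTL-scale) of disjoint individuals drawn from it.
#'
#' @param m variant count (>= 2).
#' @param nExp exposure cohort size; eQTL datasets run ~100-700 and the
#'   default matches the well-powered end of that range, where secondary
#'   signals are detectable at all.
#' @param nOut outcome cohort size (plasma pQTL scale, ~3,000).
#' @param rho within-block adjacent-haplotype copy probability in [0, 1).
#' @param blockSize variants per LD block.
#' @param mafRange allele-frequency bounds (lo, hi), 0.01 <= lo < hi <= 0.5.
#' @return list of class \code{LocusConfig}.
#' @export
locusConfig <- function(m = 200L, nExp = 500L, nOut = 3000L, rho = 0.9,
                        blockSize = 20L, mafRange = c(0.05, 0.5)) {
  stopifnot(m >= 2, rho >= 0, rho < 1,
            mafRange[1] >= 0.01, mafRange[1] < mafRange[2],
            mafRange[2] <= 0.5)
  structure(list(m = as.integer(m), nExp = as.integer(nExp),
                 nOut = as.integer(nOut), rho = rho,
                 blockSize = as.integer(blockSize), mafRange = mafRange),
            class = "LocusConfig")
}

#' Causal architecture of a simulated trait pair
#'
#' Causal variants are parameterized by the fraction of phenotypic variance
#' they explain (not raw effect size), so power is comparable across allele
#' frequencies. Shared causals use the identical variant index in both
#' traits; \code{sign} sets the direction of each true effect.
#'
#' @param expCausals data.frame with columns \code{idx} (variant index),
#'   \code{ve} (variance explained, in (0, 0.5]) and optionally \code{sign}.
#' @param outCausals same for the outcome trait.
#' @param label scenario tag (e.g. "H0".."H4", "multi").
#' @return list of class \code{CausalArchitecture}.
#' @export
causalArchitecture <- function(expCausals = NULL, outCausals = NULL,
                               label = "custom") {
  norm <- function(df) {
    if (is.null(df) || nrow(df) == 0) {
      return(data.frame(idx = integer(), ve = numeric(), sign = numeric()))
    }
    if (is.null(df$sign)) df$sign <- 1
    stopifnot(all(df$ve > 0), all(df$ve <= 0.5), sum(df$ve) < 1)
    df
  }
  structure(list(exp = norm(expCausals), out = norm(outCausals),
                 label = label),
            class = "CausalArchitecture")
}

#' Simulate a cis-locus: haplotypes, cohort dosages, and realized LD
#'
#' Haplotypes are built by a first-order copy process: within an LD block
#' each variant copies the previous variant's allele on the same haplotype
#' with probability \code{rho}, otherwise draws fresh from the block's
#' allele frequency (one frequency per block, so marginal frequencies are
#' preserved exactly). Diploid dosages are sums of two haplotypes; the
#' exposure and outcome cohorts are disjoint individuals from the same
#' pool. The LD matrix is the empirical dosage correlation of the pooled
#' cohorts with unit diagonal. Monomorphic variants are redrawn once; a
#' variant still monomorphic afterwards is an error.
#'
#' @param config a \code{\link{locusConfig}}.
#' @param seed integer seed; the locus is a pure function of
#'   (config, seed).
#' @param chrom chromosome label for the variant table.
#' @param posStart position of the first variant (bp).
#' @param posStep spacing between adjacent variants (bp).
#' @return list with \code{dosExp} (nExp x m), \code{dosOut} (nOut x m),
#'   \code{ld} (m x m), \code{freq} (block design frequencies),
#'   \code{variants} (data.frame id/chrom/pos/ref/alt).
#' @export
simulateLocus <- function(config, seed = 1L, chrom = "chr1",
                          posStart = 1e6, posStep = 2000) {
  set.seed(seed)
  m <- config$m
  nHap <- 2L * (config$nExp + config$nOut)
  block <- ((seq_len(m) - 1L) %/% config$blockSize) + 1L
  blockFreq <- runif(max(block), config$mafRange[1], config$mafRange[2])
  freq <- blockFreq[block]

  H <- matrix(0L, nHap, m)
  for (j in seq_len(m)) {
    fresh <- rbinom(nHap, 1L, freq[j])
    if (j > 1L && block[j] == block[j - 1L]) {
      copy <- runif(nHap) < config$rho
      H[, j] <- ifelse(copy, H[, j - 1L], fresh)
    } else {
      H[, j] <- fresh
    }
  }

  mono <- which(apply(H, 2, function(x) all(x == x[1])))
  if (length(mono)) {
    for (j in mono) H[, j] <- rbinom(nHap, 1L, freq[j])
    still <- vapply(mono, function(j) all(H[, j] == H[1, j]), logical(1))
    if (any(still)) {
      stop("simulateLocus: variant(s) monomorphic after resampling: ",
           paste(mono[still], collapse = ", "))
    }
  }

  iExp <- seq_len(2L * config$nExp)
  iOut <- 2L * config$nExp + seq_len(2L * config$nOut)
  dosExp <- H[iExp[c(TRUE, FALSE)], ] + H[iExp[c(FALSE, TRUE)], ]
  dosOut <- H[iOut[c(TRUE, FALSE)], ] + H[iOut[c(FALSE, TRUE)], ]

  ld <- stats::cor(rbind(dosExp, dosOut))
  diag(ld) <- 1

  variants <- data.frame(
    id = sprintf("%s_v%03d", chrom, seq_len(m)),
    chrom = chrom,
    pos = as.integer(posStart + (seq_len(m) - 1L) * posStep),
    ref = "A", alt = "G", stringsAsFactors = FALSE
  )
  list(dosExp = dosExp, dosOut = dosOut, ld = ld, freq = freq,
       variants = variants)
}

#' Simulate exposure and outcome phenotypes on given dosages
#'
#' Each phenotype is \code{sum_c beta_c g_c + eps} with standard normal
#' noise and \code{beta_c} scaled against the realized dosage variance so
#' that causal variant c explains its configured fraction of the total
#' phenotypic variance. The outcome phenotype is additionally passed through
#' the rank-based inverse normal transformation, emulating protein
#' abundance processing.
#'
#' @param dosExp,dosOut dosage matrices from \code{\link{simulateLocus}}.
#' @param arch a \code{\link{causalArchitecture}}.
#' @param seed integer seed.
#' @return list with \code{yExp}, \code{yOut} and the true per-variant
#'   effect vectors \code{betaExp}, \code{betaOut}.
#' @export
simulateTraits <- function(dosExp, dosOut, arch, seed = 1L) {
  set.seed(seed)
  build <- function(dos, causals) {
    n <- nrow(dos)
    beta <- numeric(ncol(dos))
    if (nrow(causals) > 0) {
      veTot <- sum(causals$ve)
      if (veTot >= 1) stop("simulateTraits: total variance explained >= 1")
      for (i in seq_len(nrow(causals))) {
        g <- dos[, causals$idx[i]]
        sg <- stats::sd(g)
        if (sg == 0) stop("simulateTraits: causal variant is monomorphic")
        beta[causals$idx[i]] <- causals$sign[i] *
          sqrt(causals$ve[i] / (1 - veTot)) / sg
      }
    }
    list(y = as.numeric(dos %*% beta) + rnorm(n), beta = beta)
  }
  e <- build(dosExp, arch$exp)
  o <- build(dosOut, arch$out)
  list(yExp = e$y, yOut = rankInverseNormal(o$y),
       betaExp = e$beta, betaOut = o$beta)
}

#' Per-variant marginal association statistics by simple linear regression
#'
#' Ordinary least squares of the phenotype on each variant's dosage:
#' \code{beta = Sxy/Sxx}, residual-based standard error with n - 2 degrees
#' of freedom, folded sample allele frequency. Zero-variance dosages are
#' flagged with missing beta/se.
#'
#' @param dosages n x m dosage matrix.
#' @param y phenotype vector of length n.
#' @param variants variant table (id/chrom/pos/ref/alt) with m rows.
#' @param traitId,datasetId identifiers for the resulting object.
#' @return a \linkS4class{RegionStats}.
#' @export
marginalSumstats <- function(dosages, y, variants, traitId,
                             datasetId = "synthetic") {
  n <- nrow(dosages)
  if (length(y) != n) {
    stop("marginalSumstats: phenotype length must equal cohort size")
  }
  xc <- sweep(dosages, 2, colMeans(dosages))
  yc <- y - mean(y)
  Sxx <- colSums(xc^2)
  Sxy <- as.numeric(crossprod(xc, yc))
  Syy <- sum(yc^2)
  beta <- Sxy / Sxx
  rss <- Syy - beta * Sxy
  se <- sqrt(pmax(rss, 0) / (n - 2) / Sxx)
  zeroVar <- Sxx == 0
  if (any(zeroVar)) {
    warning(sum(zeroVar), " zero-variance dosage column(s) flagged")
    beta[zeroVar] <- NA_real_
    se[zeroVar] <- NA_real_
  }
  f <- colMeans(dosages) / 2
  maf <- pmin(f, 1 - f)
  maf[zeroVar] <- NA_real_
  regionStats(traitId = traitId, variants = variants, beta = beta, se = se,
              maf = maf, n = n, datasetId = datasetId)
}

#' Simulate a benchmark catalog of paired protein/gene cis-loci
#'
#' One locus per synthetic protein. Each locus carries
#' \code{genesPerLocus} protein-coding genes at distinct TSS offsets; the
#' coding gene always shares the protein's primary causal variant (which
#' lies inside the coding gene's body). With probability
#' \code{pleiotropyRate} each neighbor gene is co-regulated by that same
#' primary causal variant (horizontal pleiotropy — the confound that
#' produces false-positive colocalizations); otherwise the neighbor gets
#' its own, conditionally distinct causal variant. With probability
#' \code{multiSignalRate} the protein and its coding gene share a second,
#' conditionally distinct causal variant (neighbors never share the second
#' signal). Every sharing is recorded in the truth table.
#'
#' Default variance-explained values are calibration choices emulating
#' typical cis-QTL effect sizes: primary eQTL 10%, secondary eQTL 8%,
#' primary pQTL 4%, secondary pQTL 2.5%, with secondary signals weaker than
#' primary ones on both traits.
#'
#' @param nProteins number of protein loci.
#' @param genesPerLocus candidate genes per locus.
#' @param pleiotropyRate probability a neighbor gene shares the primary
#'   causal variant.
#' @param multiSignalRate probability of a second shared causal signal.
#' @param config a \code{\link{locusConfig}}.
#' @param seed master seed; each locus derives its own stream.
#' @param veExp,veExpSecondary,veOut,veOutSecondary,veNeighbor variance
#'   explained by the respective causal effects.
#' @return a \linkS4class{SyntheticCatalog}.
#' @export
simulateBenchmarkCatalog <- function(nProteins = 50L, genesPerLocus = 3L,
                                     pleiotropyRate = 0.3,
                                     multiSignalRate = 0.5,
                                     config = locusConfig(), seed = 1L,
                                     veExp = 0.10, veExpSecondary = 0.08,
                                     veOut = 0.04, veOutSecondary = 0.025,
                                     veNeighbor = 0.10) {
  stopifnot(pleiotropyRate >= 0, pleiotropyRate <= 1,
            multiSignalRate >= 0, multiSignalRate <= 1,
            genesPerLocus >= 1)
  m <- config$m
  idxPrimary <- max(1L, round(m * 0.40))
  idxSecondary <- min(m, round(m * 0.70))
  posStep <- 2000

  allGenes <- list()
  proteins <- data.frame(protein_id = character(), gene_id = character(),
                         stringsAsFactors = FALSE)
  loci <- list()
  truthRows <- list()

  for (i in seq_len(nProteins)) {
    chrom <- sprintf("chr%d", i)
    loc <- simulateLocus(config, seed = deriveSeed(seed, 3L * i),
                         chrom = chrom, posStart = 1e6, posStep = posStep)
    set.seed(deriveSeed(seed, 3L * i + 1L))
    pos <- loc$variants$pos
    posPrimary <- pos[idxPrimary]

    pid <- sprintf("P%03d", i)
    codingId <- sprintf("GENE%03d_1", i)
    geneIds <- sprintf("GENE%03d_%d", i, seq_len(genesPerLocus))

    # coding gene body contains the primary causal variant
    starts <- ends <- integer(genesPerLocus)
    starts[1] <- posPrimary - 15000L
    ends[1] <- posPrimary + 15000L
    if (genesPerLocus > 1) {
      offs <- rep(c(-1, 1), length.out = genesPerLocus - 1) *
        (60000L + 60000L * ((seq_len(genesPerLocus - 1) - 1) %/% 2))
      for (g in 2:genesPerLocus) {
        starts[g] <- starts[1] + offs[g - 1]
        ends[g] <- starts[g] + 30000L
      }
    }
    genes <- geneAnnotation(geneIds, chrom, starts, ends, strand = "+",
                            gene_type = "protein_coding")

    multi <- runif(1) < multiSignalRate
    pleio <- runif(genesPerLocus) < pleiotropyRate
    pleio[1] <- TRUE   # the coding gene always shares the primary causal

    outCausals <- data.frame(idx = idxPrimary, ve = veOut)
    if (multi) {
      outCausals <- rbind(outCausals,
                          data.frame(idx = idxSecondary,
                                     ve = veOutSecondary))
    }

    exposures <- list()
    for (g in seq_len(genesPerLocus)) {
      if (g == 1L) {
        expCausals <- data.frame(idx = idxPrimary, ve = veExp)
        if (multi) {
          expCausals <- rbind(expCausals,
                              data.frame(idx = idxSecondary,
                                         ve = veExpSecondary))
        }
      } else if (pleio[g]) {
        expCausals <- data.frame(idx = idxPrimary, ve = veNeighbor)
      } else {
        # own, conditionally distinct causal outside the shared causals'
        # LD blocks (falling back to any other index on tiny loci)
        blockId <- ((seq_len(m) - 1L) %/% config$blockSize) + 1L
        forbidden <- blockId %in% blockId[c(idxPrimary, idxSecondary)]
        candidates <- which(!forbidden)
        if (length(candidates) == 0L) {
          candidates <- setdiff(seq_len(m), c(idxPrimary, idxSecondary))
        }
        own <- candidates[1L + ((g * 7L) %% length(candidates))]
        expCausals <- data.frame(idx = own, ve = veNeighbor)
      }
      tr <- simulateTraits(loc$dosExp, loc$dosOut,
                           causalArchitecture(expCausals, outCausals),
                           seed = deriveSeed(seed, 1000L * i + g))
      exposures[[geneIds[g]]] <- marginalSumstats(
        loc$dosExp, tr$yExp, loc$variants, traitId = geneIds[g],
        datasetId = "eqtl_sim"
      )
      shared <- intersect(expCausals$idx, outCausals$idx)
      for (sIdx in shared) {
        truthRows[[length(truthRows) + 1L]] <- data.frame(
          protein_id = pid, gene_id = geneIds[g],
          variant_id = loc$variants$id[sIdx],
          exp_signal = match(sIdx, expCausals$idx),
          out_signal = match(sIdx, outCausals$idx),
          slope_sign = 1,
          coding = g == 1L, stringsAsFactors = FALSE
        )
      }
    }
    # outcome phenotype: simulate once with the protein's own architecture
    trOut <- simulateTraits(loc$dosExp, loc$dosOut,
                            causalArchitecture(NULL, outCausals),
                            seed = deriveSeed(seed, 1000L * i))
    outcome <- marginalSumstats(loc$dosOut, trOut$yOut, loc$variants,
                                traitId = pid, datasetId = "pqtl_sim")

    allGenes[[i]] <- genes
    proteins <- rbind(proteins,
                      data.frame(protein_id = pid, gene_id = codingId,
                                 stringsAsFactors = FALSE))
    loci[[pid]] <- list(outcome = outcome, exposures = exposures,
                        ld = loc$ld, genes = genes,
                        nSignalsOut = nrow(outCausals))
  }

  truth <- if (length(truthRows)) {
    do.call(rbind, truthRows)
  } else {
    data.frame(protein_id = character(), gene_id = character(),
               variant_id = character(), exp_signal = integer(),
               out_signal = integer(), slope_sign = numeric(),
               coding = logical(), stringsAsFactors = FALSE)
  }
  new("SyntheticCatalog",
      genes = do.call(c, allGenes), proteins = proteins, loci = loci,
      truth = truth,
      config = list(locus = config, nProteins = nProteins,
                    genesPerLocus = genesPerLocus,
                    pleiotropyRate = pleiotropyRate,
                    multiSignalRate = multiSignalRate, seed = seed))
}
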