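#' Colocalization priors
#'
#' Standard per-variant prior probabilities of association: \code{p1} and
#' \code{p2} for association with each single trait (1e-4) and \code{p12}
#' for association with both (5e-6). \code{W} is the prior effect variance
#' used by the approximate Bayes factors.
#'
#' @param p1,p2 per-variant prior probability of association with trait 1 /
#'   trait 2.
#' @param p12 per-variant prior probability of association with both.
#' @param W prior effect-size variance for the approximate Bayes factors.
#' @return list of class \code{ColocPriors}.
#' @export
colocPriors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 5e-6, W = 0.0225) {
  stopifnot(p12 > 0, p12 <= min(p1, p2), p1 + p2 + p12 < 1, W > 0)
  structure(list(p1 = p1, p2 = p2, p12 = p12, W = W),
            class = "ColocPriors")
}

# Shared enumeration core: given per-variant log Bayes factors for two
# traits over the same variant set, compute PP0..PP4.
colocEnumerate <- function(lbfA, lbfB, priors, method, traitPair,
                           signalPair, pp4Threshold) {
  M <- length(lbfA)
  if (length(lbfB) != M) {
    stop("colocalization: Bayes-factor rows have mismatched length")
  }
  if (M < 2L) {
    stop("colocalization: need at least 2 shared variants")
  }
  L1 <- logSumExp(lbfA)
  L2 <- logSumExp(lbfB)
  L12 <- logSumExp(lbfA + lbfB)
  if (L12 > L1 + L2 + 1e-6) {
    stop("colocalization: internal inconsistency, sum of joint BFs ",
         "exceeds product of marginal sums")
  }
  S <- c(
    0,
    log(priors$p1) + L1,
    log(priors$p2) + L2,
    log(priors$p1) + log(priors$p2) + logDiffExp(L1 + L2, L12, tol = 1e-6),
    log(priors$p12) + L12
  )
  pp <- setNames(softmax(S), paste0("PP", 0:4))
  new("ColocResult", method = method, traitPair = traitPair,
      signalPair = as.integer(signalPair), pp = pp, clpp = NA_real_,
      significant = unname(pp["PP4"] > pp4Threshold))
}

#' Enumeration colocalization over marginal summary statistics
#'
#' Computes per-variant Wakefield approximate Bayes factors for each trait
#' from the harmonized marginal statistics, then enumerates the five
#' hypotheses (no association, trait-1 only, trait-2 only, two distinct
#' causal variants, one shared causal variant) assuming at most one causal
#' variant per trait. Significance is declared when PP4 exceeds
#' \code{pp4Threshold} (default 0.8).
#'
#' @param a,b \linkS4class{RegionStats} for the two traits; they are
#'   harmonized to shared effect alleles internally.
#' @param priors a \code{\link{colocPriors}}.
#' @param pp4Threshold significance threshold on PP4.
#' @return a \linkS4class{ColocResult} with method \code{"abf"}.
#' @export
colocAbf <- function(a, b, priors = colocPriors(), pp4Threshold = 0.8) {
  h <- harmonizePair(a, b)
  lbfA <- wakefieldLabf(h$beta_a, h$se_a, priors$W)
  lbfB <- wakefieldLabf(h$beta_b, h$se_b, priors$W)
  colocEnumerate(lbfA, lbfB, priors, "abf",
                 c(traitId(a), traitId(b)), c(NA_integer_, NA_integer_),
                 pp4Threshold)
}

#' Per-signal Bayes-factor colocalization
#'
#' The same five-hypothesis enumeration as \code{\link{colocAbf}}, but fed
#' one fine-mapped signal's log-Bayes-factor row per trait instead of
#' marginal statistics, so every (exposure signal, outcome signal) pair can
#' be tested separately. Rows must be aligned to the same harmonized variant
#' set.
#'
#' @param lbfA,lbfB per-variant natural-log Bayes factors for one exposure
#'   signal and one outcome signal.
#' @param priors a \code{\link{colocPriors}} (the same priors as for the
#'   marginal enumeration; no per-signal rescaling).
#' @param signalPair integer(2): (exposure signal index, outcome signal
#'   index).
#' @param traitPair character(2) trait ids.
#' @param pp4Threshold significance threshold on PP4.
#' @return a \linkS4class{ColocResult} with method \code{"bf_bf"}.
#' @export
colocBfBf <- function(lbfA, lbfB, priors = colocPriors(),
                      signalPair = c(NA_integer_, NA_integer_),
                      traitPair = c("exposure", "outcome"),
                      pp4Threshold = 0.8) {
  colocEnumerate(as.numeric(lbfA), as.numeric(lbfB), priors, "bf_bf",
                 traitPair, signalPair, pp4Threshold)
}

#' Credible-set colocalization posterior probability (CLPP)
#'
#' Multiplies the two traits' per-signal posterior inclusion probabilities
#' variant by variant and sums the products over the exposure trait's
#' credible set. Variants absent from either trait contribute zero.
#' Significance is declared when the value exceeds \code{clppThreshold}
#' (default 0.1).
#'
#' @param alphaA named per-variant inclusion probabilities of the exposure
#'   signal (names are variant ids).
#' @param alphaB same for the outcome signal.
#' @param csA exposure-trait credible set (a list with \code{variantIds}),
#'   or a character vector of variant ids.
#' @param signalPair,traitPair identifiers carried into the result.
#' @param clppThreshold significance threshold.
#' @return a \linkS4class{ColocResult} with method \code{"clpp"}.
#' @export
clpp <- function(alphaA, alphaB, csA,
                 signalPair = c(NA_integer_, NA_integer_),
                 traitPair = c("exposure", "outcome"),
                 clppThreshold = 0.1) {
  ids <- if (is.list(csA)) csA$variantIds else as.character(csA)
  pA <- alphaA[match(ids, names(alphaA))]
  pB <- alphaB[match(ids, names(alphaB))]
  pA[is.na(pA)] <- 0
  pB[is.na(pB)] <- 0
  val <- sum(pA * pB)
  new("ColocResult", method = "clpp",
      traitPair = traitPair, signalPair = as.integer(signalPair),
      pp = rep(NA_real_, 5), clpp = val,
      significant = val > clppThreshold)
}

#' Should a trait pair be skipped for insufficient cis-window overlap?
#'
#' A (gene, protein) pair is skipped when more than 90% of the outcome
#' region's variants fall outside the exposure gene's cis-window.
#'
#' @param outcomeStats \linkS4class{RegionStats} of the outcome trait.
#' @param gene length-1 GRanges of the exposure gene.
#' @param minFraction minimum fraction of outcome variants that must fall
#'   inside the window (default 0.1).
#' @return logical(1): TRUE if the pair should be skipped.
#' @export
skipPair <- function(outcomeStats, gene, minFraction = 0.1) {
  w <- cisWindowBounds(gene)
  v <- variants(outcomeStats)
  inside <- v$chrom == as.character(GenomicRanges::seqnames(gene)) &
    v$pos >= w$lo & v$pos <= w$hi
  mean(inside) < minFraction
}
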