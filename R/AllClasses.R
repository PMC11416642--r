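#' @import methods
#' @importFrom stats qnorm dnorm pnorm rnorm rbinom runif integrate uniroot
#'   setNames var sd cor quantile approx median
NULL

#' RegionStats: per-variant association summary statistics for one trait
#'
#' Marginal (or conditional) association results for a single molecular
#' trait — a gene's expression or a protein's abundance — across the variants
#' of one cis-region. Mirrors the per-variant columns of standard QTL
#' summary-statistic exports: effect size on the alt-allele dosage scale, its
#' standard error, the folded minor-allele frequency, and the cohort size.
#'
#' @slot traitId character(1), molecular trait identifier.
#' @slot datasetId character(1), dataset/cohort identifier.
#' @slot variants data.frame with columns \code{id}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt} (1-based positions).
#' @slot beta numeric, per-variant effect estimates.
#' @slot se numeric, per-variant standard errors (> 0).
#' @slot maf numeric, folded minor-allele frequencies in (0, 0.5].
#' @slot n integer(1), sample size.
#'
#' @export
setClass("RegionStats",
  representation(
    traitId = "character",
    datasetId = "character",
    variants = "data.frame",
    beta = "numeric",
    se = "numeric",
    maf = "numeric",
    n = "integer"
  )
)

setValidity("RegionStats", function(object) {
  v <- object@variants
  m <- nrow(v)
  msg <- character()
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(v))) {
    return(paste("variants must have columns:", paste(need, collapse = ", ")))
  }
  if (length(object@beta) != m || length(object@se) != m ||
      length(object@maf) != m) {
    msg <- c(msg, "beta, se, maf must match the number of variants")
  }
  if (anyDuplicated(v$id)) msg <- c(msg, "variant ids must be unique")
  if (m > 0 && any(v$pos < 1)) msg <- c(msg, "positions must be >= 1")
  if (m > 0 && any(v$ref == v$alt)) msg <- c(msg, "ref and alt must differ")
  if (any(object@se <= 0, na.rm = TRUE)) msg <- c(msg, "se must be > 0")
  if (any(object@maf <= 0 | object@maf > 0.5, na.rm = TRUE)) {
    msg <- c(msg, "maf must lie in (0, 0.5]")
  }
  if (length(object@n) != 1L || object@n < 1L) {
    msg <- c(msg, "n must be a single positive integer")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' FineMapFit: sum-of-single-effects fine-mapping result
#'
#' @slot alpha L x M matrix of per-signal posterior inclusion probabilities;
#'   each row sums to 1.
#' @slot lbf L x M matrix of per-signal, per-variant natural-log Bayes
#'   factors.
#' @slot mu L x M matrix of per-signal posterior mean effects (z-score
#'   scale), conditional on inclusion.
#' @slot pip length-M posterior inclusion probabilities,
#'   \code{1 - prod_l (1 - alpha[l, ])}.
#' @slot credibleSets list of purity-filtered credible sets, each a list with
#'   elements \code{csIndex}, \code{variantIds}, \code{alphaMass},
#'   \code{purity}, \code{leadVariant}, \code{effectRow}.
#' @slot variantIds character, column identity of the matrices.
#' @slot converged logical(1).
#' @slot niter integer(1).
#'
#' @export
setClass("FineMapFit",
  representation(
    alpha = "matrix",
    lbf = "matrix",
    mu = "matrix",
    pip = "numeric",
    credibleSets = "list",
    variantIds = "character",
    converged = "logical",
    niter = "integer"
  )
)

setValidity("FineMapFit", function(object) {
  msg <- character()
  if (ncol(object@alpha) != length(object@variantIds)) {
    msg <- c(msg, "alpha columns must match variantIds")
  }
  if (!all(dim(object@alpha) == dim(object@lbf))) {
    msg <- c(msg, "alpha and lbf must share dimensions")
  }
  if (length(object@mu) > 0 &&
      !all(dim(object@alpha) == dim(object@mu))) {
    msg <- c(msg, "alpha and mu must share dimensions")
  }
  if (nrow(object@alpha) > 0) {
    rs <- rowSums(object@alpha)
    if (any(abs(rs - 1) > 1e-8)) msg <- c(msg, "alpha rows must sum to 1")
  }
  pipChk <- 1 - apply(1 - object@alpha, 2, prod)
  if (length(object@pip) != length(object@variantIds) ||
      any(abs(object@pip - pipChk) > 1e-8)) {
    msg <- c(msg, "pip must equal 1 - prod_l (1 - alpha)")
  }
  if (any(object@pip < -1e-12 | object@pip > 1 + 1e-12)) {
    msg <- c(msg, "pip must lie in [0, 1]")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' ColocResult: colocalization evidence for one trait pair / signal pair
#'
#' For the enumeration methods, \code{pp} holds the posterior probabilities
#' of the five sharing hypotheses (no association; trait-1 only; trait-2
#' only; two distinct causal variants; one shared causal variant). For the
#' credible-set product method only \code{clpp} is populated.
#'
#' @slot method one of \code{"abf"}, \code{"bf_bf"}, \code{"clpp"}.
#' @slot traitPair character(2): exposure trait id, outcome trait id.
#' @slot signalPair integer(2) signal (credible set) indices, NA when not
#'   applicable.
#' @slot pp named numeric(5) \code{PP0..PP4} or NA for clpp.
#' @slot clpp numeric(1) in [0, 1] or NA for the enumeration methods.
#' @slot significant logical(1).
#'
#' @export
setClass("ColocResult",
  representation(
    method = "character",
    traitPair = "character",
    signalPair = "integer",
    pp = "numeric",
    clpp = "numeric",
    significant = "logical"
  )
)

setValidity("ColocResult", function(object) {
  msg <- character()
  if (!object@method %in% c("abf", "bf_bf", "clpp")) {
    msg <- c(msg, "method must be abf, bf_bf or clpp")
  }
  if (object@method %in% c("abf", "bf_bf")) {
    if (length(object@pp) != 5L || abs(sum(object@pp) - 1) > 1e-8 ||
        any(object@pp < -1e-12 | object@pp > 1 + 1e-12)) {
      msg <- c(msg, "pp must be 5 probabilities summing to 1")
    }
  } else {
    if (is.na(object@clpp) || object@clpp < -1e-12 ||
        object@clpp > 1 + 1e-9) {
      msg <- c(msg, "clpp must lie in [0, 1]")
    }
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' MREstimate: a cis-Mendelian-randomization causal-slope estimate
#'
#' @slot method one of \code{"ivw"}, \code{"ivw_delta"},
#'   \code{"ivw_delta_random"}, \code{"raps"}, \code{"locus_spread"}.
#' @slot alphaHat causal slope (outcome units per exposure unit).
#' @slot interval numeric(2) lower/upper bound at the stated level.
#' @slot level interval level (default 0.80).
#' @slot dispersion overdispersion variance or allelic-spread scale; NA for
#'   plain fixed-effect IVW.
#' @slot k number of instruments used.
#' @slot significant logical(1): TRUE iff 0 lies outside the interval.
#'
#' @export
setClass("MREstimate",
  representation(
    method = "character",
    alphaHat = "numeric",
    interval = "numeric",
    level = "numeric",
    dispersion = "numeric",
    k = "integer",
    significant = "logical"
  )
)

setValidity("MREstimate", function(object) {
  msg <- character()
  if (length(object@interval) != 2L ||
      object@interval[1] > object@alphaHat + 1e-9 ||
      object@interval[2] < object@alphaHat - 1e-9) {
    msg <- c(msg, "interval must bracket alphaHat")
  }
  sig <- !(object@interval[1] <= 0 && object@interval[2] >= 0)
  if (!identical(sig, object@significant)) {
    msg <- c(msg, "significant must equal (0 outside interval)")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' SyntheticCatalog: a simulated benchmark of paired cis-loci
#'
#' One locus per synthetic protein, each carrying the protein's outcome
#' trait, several candidate genes measured in a smaller exposure cohort, the
#' realized LD matrix, and ground-truth signal-sharing labels.
#'
#' @slot genes GRanges of all gene annotations (mcols: \code{gene_id},
#'   \code{gene_type}, \code{protein_coding}).
#' @slot proteins data.frame with \code{protein_id} and the coding
#'   \code{gene_id} (the truth map).
#' @slot loci named list (by protein id), each a list with elements
#'   \code{outcome} (RegionStats), \code{exposures} (named list of
#'   RegionStats per gene), \code{ld} (matrix), \code{truth} (data.frame of
#'   sharing labels), \code{genes} (GRanges subset).
#' @slot truth data.frame with one row per (protein, gene, causal variant)
#'   sharing record: protein_id, gene_id, variant_id, signal rank on each
#'   trait, true slope sign.
#' @slot config list, the generator configuration used.
#'
#' @export
setClass("SyntheticCatalog",
  representation(
    genes = "ANY",
    proteins = "data.frame",
    loci = "list",
    truth = "data.frame",
    config = "list"
  )
)

setValidity("SyntheticCatalog", function(object) {
  msg <- character()
  if (!all(c("protein_id", "gene_id") %in% names(object@proteins))) {
    msg <- c(msg, "proteins needs protein_id and gene_id columns")
  }
  if (anyDuplicated(object@proteins$protein_id)) {
    msg <- c(msg, "each protein must map to exactly one coding gene")
  }
  gid <- object@genes$gene_id
  if (!all(object@proteins$gene_id %in% gid)) {
    msg <- c(msg, "every coding gene must be present in genes")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
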