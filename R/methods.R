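#' Construct a RegionStats object
#'
#' @param traitId,datasetId identifiers.
#' @param variants data.frame with columns id, chrom, pos, ref, alt.
#' @param beta,se,maf per-variant numeric vectors; maf is folded to the
#'   minor allele automatically.
#' @param n sample size.
#' @return a validated \linkS4class{RegionStats}.
#' @export
regionStats <- function(traitId, variants, beta, se, maf, n,
                        datasetId = "synthetic") {
  new("RegionStats",
    traitId = as.character(traitId),
    datasetId = as.character(datasetId),
    variants = as.data.frame(variants, stringsAsFactors = FALSE),
    beta = as.numeric(beta),
    se = as.numeric(se),
    maf = pmin(as.numeric(maf), 1 - as.numeric(maf)),
    n = as.integer(n)
  )
}

#' Accessors for RegionStats
#'
#' @param x a \linkS4class{RegionStats}.
#' @name RegionStats-accessors
NULL

#' @rdname RegionStats-accessors
#' @export
setMethod("traitId", "RegionStats", function(x) x@traitId)

#' @rdname RegionStats-accessors
#' @export
setMethod("datasetId", "RegionStats", function(x) x@datasetId)

#' @rdname RegionStats-accessors
#' @export
setMethod("variants", "RegionStats", function(x) x@variants)

#' @rdname RegionStats-accessors
#' @export
setMethod("variantIds", "RegionStats", function(x) x@variants$id)

#' @rdname RegionStats-accessors
#' @export
setMethod("effectSizes", "RegionStats", function(x) {
  setNames(x@beta, x@variants$id)
})

#' @rdname RegionStats-accessors
#' @export
setMethod("standardErrors", "RegionStats", function(x) {
  setNames(x@se, x@variants$id)
})

#' @rdname RegionStats-accessors
#' @export
setMethod("minorAlleleFreqs", "RegionStats", function(x) {
  setNames(x@maf, x@variants$id)
})

#' @rdname RegionStats-accessors
#' @export
setMethod("sampleSize", "RegionStats", function(x) x@n)

#' @rdname RegionStats-accessors
#' @export
setMethod("zScores", "RegionStats", function(x) {
  setNames(x@beta / x@se, x@variants$id)
})

#' @rdname RegionStats-accessors
#' @export
setMethod("length", "RegionStats", function(x) nrow(x@variants))

#' Subset a RegionStats by variant index or id
#'
#' @param x a RegionStats.
#' @param i integer, logical or character index over variants.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "RegionStats", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@variants$id)
  new("RegionStats",
    traitId = x@traitId, datasetId = x@datasetId,
    variants = x@variants[i, , drop = FALSE],
    beta = x@beta[i], se = x@se[i], maf = x@maf[i], n = x@n
  )
})

setMethod("show", "RegionStats", function(object) {
  cat("RegionStats for trait", object@traitId,
      "(dataset", paste0(object@datasetId, ")"), "\n")
  cat(" ", nrow(object@variants), "variants on chromosome",
      unique(object@variants$chrom), "| n =", object@n, "\n")
  if (nrow(object@variants) > 0) {
    z <- object@beta / object@se
    cat("  max |z| =", format(max(abs(z)), digits = 4), "at",
        object@variants$id[which.max(abs(z))], "\n")
  }
})

#' Accessors for FineMapFit
#'
#' @param x a \linkS4class{FineMapFit}.
#' @param ... passed on (\code{firstOnly} for \code{credibleSets}).
#' @name FineMapFit-accessors
NULL

#' @rdname FineMapFit-accessors
#' @export
setMethod("signalAlpha", "FineMapFit", function(x) x@alpha)

#' @rdname FineMapFit-accessors
#' @export
setMethod("signalLbf", "FineMapFit", function(x) x@lbf)

#' @rdname FineMapFit-accessors
#' @export
setMethod("signalMu", "FineMapFit", function(x) x@mu)

#' @rdname FineMapFit-accessors
#' @export
setMethod("pip", "FineMapFit", function(x) {
  setNames(x@pip, x@variantIds)
})

#' @rdname FineMapFit-accessors
#' @export
setMethod("credibleSets", "FineMapFit", function(x, ...) {
  extractCredibleSets(x, ...)
})

setMethod("show", "FineMapFit", function(object) {
  cat("FineMapFit:", nrow(object@alpha), "single effects over",
      length(object@variantIds), "variants\n")
  cat(" ", length(object@credibleSets), "purity-filtered credible set(s);",
      if (object@converged) "converged" else "NOT converged",
      "in", object@niter, "iterations\n")
  for (cs in object@credibleSets) {
    cat(sprintf("  CS%d: %d variant(s), mass %.3f, purity %.3f, lead %s\n",
                cs$csIndex, length(cs$variantIds), cs$alphaMass, cs$purity,
                cs$leadVariant))
  }
})

#' Accessors for ColocResult
#'
#' @param x a \linkS4class{ColocResult}.
#' @name ColocResult-accessors
NULL

#' @rdname ColocResult-accessors
#' @export
setMethod("posteriorProbs", "ColocResult", function(x) x@pp)

#' @rdname ColocResult-accessors
#' @export
setMethod("clppValue", "ColocResult", function(x) x@clpp)

#' @rdname ColocResult-accessors
#' @export
setMethod("isSignificant", "ColocResult", function(x) x@significant)

setMethod("show", "ColocResult", function(object) {
  cat("ColocResult [", object@method, "] ", object@traitPair[1], " vs ",
      object@traitPair[2], "\n", sep = "")
  if (!all(is.na(object@signalPair))) {
    cat("  signal pair:", object@signalPair[1], "/", object@signalPair[2], "\n")
  }
  if (object@method == "clpp") {
    cat(sprintf("  CLPP = %.4f (%ssignificant)\n", object@clpp,
                if (object@significant) "" else "not "))
  } else {
    cat("  ", paste(sprintf("PP%d=%.3f", 0:4, object@pp), collapse = " "),
        "\n")
    cat(sprintf("  %ssignificant\n",
                if (object@significant) "" else "not "))
  }
})

#' Accessors for MREstimate
#'
#' @param x an \linkS4class{MREstimate}.
#' @name MREstimate-accessors
NULL

#' @rdname MREstimate-accessors
#' @export
setMethod("causalSlope", "MREstimate", function(x) x@alphaHat)

#' @rdname MREstimate-accessors
#' @export
setMethod("slopeInterval", "MREstimate", function(x) x@interval)

#' @rdname MREstimate-accessors
#' @export
setMethod("dispersion", "MREstimate", function(x) x@dispersion)

#' @rdname MREstimate-accessors
#' @export
setMethod("isSignificant", "MREstimate", function(x) x@significant)

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s], k = %d instruments\n", object@method,
              object@k))
  cat(sprintf("  slope %.4f, %d%% interval [%.4f, %.4f]%s\n",
              object@alphaHat, round(100 * object@level),
              object@interval[1], object@interval[2],
              if (object@significant) " *" else ""))
  if (!is.na(object@dispersion)) {
    cat(sprintf("  dispersion %.4f\n", object@dispersion))
  }
})

setMethod("show", "SyntheticCatalog", function(object) {
  cat("SyntheticCatalog:", nrow(object@proteins), "proteins,",
      length(object@genes), "genes\n")
  cat("  truth records:", nrow(object@truth), "\n")
})
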