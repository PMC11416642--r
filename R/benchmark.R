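#' Distance from a variant to a gene body
#'
#' Zero when the position falls inside the closed interval
#' [start, end]; otherwise the distance to the nearer gene edge. Variants on
#' a different chromosome are at infinite distance.
#'
#' @param pos variant position (bp, 1-based).
#' @param chrom variant chromosome.
#' @param gene length-1 GRanges from \code{\link{geneAnnotation}}.
#' @return distance in bp (possibly \code{Inf}).
#' @export
distanceToGene <- function(pos, chrom, gene) {
  stopifnot(length(gene) == 1L)
  if (as.character(GenomicRanges::seqnames(gene)) != chrom) return(Inf)
  s <- GenomicRanges::start(gene)
  e <- GenomicRanges::end(gene)
  if (pos >= s && pos <= e) return(0)
  min(abs(pos - s), abs(pos - e))
}

#' Closest protein-coding gene(s) to a lead variant
#'
#' Ranks genes by gene-body distance (\code{mode = "gene_body"}) or by
#' distance to the strand-aware TSS (\code{mode = "tss"}). All genes tied at
#' the minimum distance are returned.
#'
#' @param pos,chrom lead-variant coordinates.
#' @param genes GRanges of candidate annotations; restricted internally to
#'   protein-coding entries.
#' @param mode \code{"gene_body"} or \code{"tss"}.
#' @return character vector of gene ids (all ties).
#' @export
closestGenes <- function(pos, chrom, genes, mode = c("gene_body", "tss")) {
  mode <- match.arg(mode)
  genes <- genes[genes$protein_coding]
  if (length(genes) == 0L) stop("closestGenes: no protein-coding genes")
  d <- if (mode == "tss") {
    ifelse(as.character(GenomicRanges::seqnames(genes)) == chrom,
           abs(pos - tssPositions(genes)), Inf)
  } else {
    vapply(seq_along(genes),
           function(i) distanceToGene(pos, chrom, genes[i]), numeric(1))
  }
  genes$gene_id[d == min(d)]
}

#' Precision/recall report from prediction counts
#'
#' Precision is computed over unique (protein, gene) pairs; recall over the
#' tested proteins (those with at least one purity-filtered credible set),
#' so \code{tp + fn = tested}. Percentages are rounded half-up to one
#' decimal.
#'
#' @param method method label.
#' @param tp,fp true/false positive pair counts.
#' @param tested number of tested proteins (recall denominator).
#' @return list of class \code{BenchmarkReport} with counts, ratios and
#'   one-decimal percentage fields.
#' @export
benchmarkReport <- function(method, tp, fp, tested) {
  fn <- tested - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tested > 0) tp / tested else NA_real_
  structure(list(
    method = method, tp = tp, fp = fp, fn = fn, tested = tested,
    precision = precision, recall = recall,
    precisionPct = if (is.na(precision)) NA_real_ else
      roundHalfUp(100 * precision, 1),
    recallPct = if (is.na(recall)) NA_real_ else
      roundHalfUp(100 * recall, 1)
  ), class = "BenchmarkReport")
}

#' @export
print.BenchmarkReport <- function(x, ...) {
  cat(sprintf("%s: TP=%d FP=%d FN=%d | precision %s%% recall %s%%\n",
              x$method, x$tp, x$fp, x$fn,
              format(x$precisionPct), format(x$recallPct)))
  invisible(x)
}

#' Score a method's predictions against the coding-gene truth
#'
#' A predicted (protein, gene) pair is a true positive iff the gene codes
#' for the protein; any other predicted pair is a false positive. A tested
#' protein with no true-positive prediction is a false negative. Predicted
#' pairs are deduplicated before counting (pooling across datasets);
#' \code{restriction = "first_signal_only"} keeps predictions from the
#' first outcome signal, and \code{"by_cs_index"} returns one report per
#' outcome credible-set rank.
#'
#' @param predictions data.frame with columns \code{protein_id},
#'   \code{gene_id} and optionally \code{out_signal}.
#' @param truth data.frame mapping \code{protein_id} to the coding
#'   \code{gene_id} (one row per protein).
#' @param testedProteins character vector of proteins with >= 1
#'   purity-filtered credible set.
#' @param method method label for the report.
#' @param restriction \code{"all"}, \code{"first_signal_only"} or
#'   \code{"by_cs_index"}.
#' @return a \code{\link{benchmarkReport}} (or a list of them for
#'   \code{"by_cs_index"}).
#' @export
scoreMethod <- function(predictions, truth, testedProteins,
                        method = "method",
                        restriction = c("all", "first_signal_only",
                                        "by_cs_index")) {
  restriction <- match.arg(restriction)
  if (nrow(predictions) > 0 &&
      !all(predictions$protein_id %in% testedProteins)) {
    stop("scoreMethod: prediction for an untested protein")
  }
  if (restriction == "first_signal_only" && nrow(predictions) > 0) {
    keep <- is.na(predictions$out_signal) | predictions$out_signal == 1L
    predictions <- predictions[keep, , drop = FALSE]
  }
  if (restriction == "by_cs_index") {
    strata <- sort(unique(predictions$out_signal))
    reports <- lapply(strata, function(s) {
      scoreMethod(predictions[predictions$out_signal == s, , drop = FALSE],
                  truth, testedProteins,
                  method = paste0(method, "_cs", s), restriction = "all")
    })
    names(reports) <- paste0("cs", strata)
    return(reports)
  }
  codingOf <- setNames(truth$gene_id, truth$protein_id)
  pairs <- unique(predictions[, c("protein_id", "gene_id"), drop = FALSE])
  isTp <- pairs$gene_id == codingOf[pairs$protein_id]
  tp <- sum(isTp)
  fp <- sum(!isTp)
  benchmarkReport(method, tp, fp, length(testedProteins))
}

#' Direction-of-effect concordance of MR slopes
#'
#' Fraction of true-positive and of false-positive gene-protein-dataset
#' triplets whose fitted MR slope is positive (a variant that increases
#' gene expression should increase the protein's abundance for genuinely
#' causal pairs). Slopes exactly zero count as non-positive.
#'
#' @param estimates data.frame with columns \code{alphaHat} and \code{label}
#'   ("TP" or "FP"), one row per triplet.
#' @return list with positive counts, totals and one-decimal percentages
#'   per label.
#' @export
signConcordance <- function(estimates) {
  out <- list()
  for (lab in c("TP", "FP")) {
    e <- estimates[estimates$label == lab, , drop = FALSE]
    pos <- sum(e$alphaHat > 0)
    out[[lab]] <- list(
      positive = pos, total = nrow(e),
      fraction = if (nrow(e)) pos / nrow(e) else NA_real_,
      pct = if (nrow(e)) roundHalfUp(100 * pos / nrow(e), 1) else NA_real_
    )
  }
  out
}

# Evaluate every (exposure credible set, outcome credible set) pair of a
# harmonized trait pair with the per-signal enumeration method.
bfbfAllPairs <- function(fitExp, fitOut, harmonized, priors, traitPair,
                         pp4Threshold = 0.8) {
  csE <- extractCredibleSets(fitExp)
  csO <- extractCredibleSets(fitOut)
  rows <- list()
  idxE <- match(harmonized$id, fitExp@variantIds)
  idxO <- match(harmonized$id, fitOut@variantIds)
  for (ce in csE) {
    for (co in csO) {
      res <- colocBfBf(signalLbf(fitExp)[ce$effectRow, idxE],
                       signalLbf(fitOut)[co$effectRow, idxO],
                       priors, signalPair = c(ce$csIndex, co$csIndex),
                       traitPair = traitPair, pp4Threshold = pp4Threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        pairExp = ce$csIndex, pairOut = co$csIndex,
        pp4 = unname(posteriorProbs(res)["PP4"]),
        significant = isSignificant(res)
      )
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(pairExp = integer(), pairOut = integer(), pp4 = numeric(),
               significant = logical())
}

#' Run the full benchmark pipeline on a synthetic catalog
#'
#' For every protein locus: fine-map the protein (the tested universe is
#' proteins with at least one purity-filtered credible set); predict with
#' the closest-gene baseline (gene-body and TSS modes) from the first
#' credible set's lead variant; fine-map each candidate gene and run the
#' three colocalization methods; retain gene-protein pairs with two or more
#' distinct-signal colocalizations and feed them to the five MR estimators;
#' finally score every method against the coding-gene truth.
#'
#' Single-signal comparisons (abf, bf_bf, clpp) are restricted to the first
#' outcome signal; the multi-signal + MR route uses all signal pairs.
#' Outcome traits carrying a TRUE \code{complex} flag in the catalog's
#' protein table are excluded from the analysis universe, and only
#' protein-coding exposure genes are considered.
#'
#' @param catalog a \linkS4class{SyntheticCatalog}.
#' @param fmConfigExp,fmConfigOut fine-mapping configurations for exposure
#'   and outcome traits.
#' @param priors a \code{\link{colocPriors}}.
#' @param pp4Threshold,clppThreshold significance thresholds.
#' @param mrLevel MR interval level.
#' @param mrMethods character vector of MR estimators to run.
#' @return list with \code{reports} (named list of
#'   \code{\link{benchmarkReport}}s), \code{mr} (per-triplet MR slopes with
#'   TP/FP labels), \code{predictions} (per-method prediction tables),
#'   \code{testedProteins}.
#' @export
runEndToEnd <- function(catalog,
                        fmConfigExp = fineMapConfig(L = 5L),
                        fmConfigOut = fineMapConfig(L = 5L),
                        priors = colocPriors(),
                        pp4Threshold = 0.8, clppThreshold = 0.1,
                        mrLevel = 0.8,
                        mrMethods = c("ivw", "ivw_delta",
                                      "ivw_delta_random", "raps",
                                      "locus_spread")) {
  truth <- catalog@proteins
  tested <- character()
  pred <- list(closest_gene = list(), closest_tss = list(), abf = list(),
               bf_bf = list(), clpp = list(), multi_coloc = list())
  mrPred <- setNames(vector("list", length(mrMethods)), mrMethods)
  mrRows <- list()

  # analysis-universe filter: outcome traits flagged as protein complexes
  # are excluded (their abundance can reflect any constituent gene)
  complexFlag <- catalog@proteins$complex
  excluded <- if (is.null(complexFlag)) character() else
    catalog@proteins$protein_id[complexFlag %in% TRUE]

  for (pid in names(catalog@loci)) {
    if (pid %in% excluded) next
    locus <- catalog@loci[[pid]]
    out <- locus$outcome
    fitOut <- tryCatch(susieRss(out, locus$ld, fmConfigOut),
                       error = function(e) NULL)
    if (is.null(fitOut)) next
    csOut <- extractCredibleSets(fitOut)
    if (length(csOut) == 0L) next
    tested <- c(tested, pid)

    # closest-gene baseline from the first signal's lead variant
    lead <- csOut[[1]]$leadVariant
    vv <- variants(out)
    leadPos <- vv$pos[match(lead, vv$id)]
    leadChrom <- vv$chrom[match(lead, vv$id)]
    for (mode in c("gene_body", "tss")) {
      ids <- closestGenes(leadPos, leadChrom, locus$genes, mode)
      key <- if (mode == "gene_body") "closest_gene" else "closest_tss"
      pred[[key]][[length(pred[[key]]) + 1L]] <- data.frame(
        protein_id = pid, gene_id = ids, out_signal = 1L,
        stringsAsFactors = FALSE
      )
    }

    for (gid in names(locus$exposures)) {
      gene <- locus$genes[locus$genes$gene_id == gid]
      if (!gene$protein_coding || skipPair(out, gene)) next
      exp <- locus$exposures[[gid]]
      h <- tryCatch(harmonizePair(exp, out), error = function(e) NULL)
      if (is.null(h) || nrow(h) < 2L) next
      fitExp <- tryCatch(susieRss(exp, locus$ld, fmConfigExp),
                         error = function(e) NULL)
      if (is.null(fitExp)) next

      resAbf <- tryCatch(colocAbf(exp, out, priors, pp4Threshold),
                         error = function(e) NULL)
      if (!is.null(resAbf) && isSignificant(resAbf)) {
        pred$abf[[length(pred$abf) + 1L]] <- data.frame(
          protein_id = pid, gene_id = gid, out_signal = 1L,
          stringsAsFactors = FALSE
        )
      }

      bfbf <- bfbfAllPairs(fitExp, fitOut, h, priors, c(gid, pid),
                           pp4Threshold)
      sig <- bfbf[bfbf$significant, , drop = FALSE]
      if (any(sig$pairOut == 1L)) {
        pred$bf_bf[[length(pred$bf_bf) + 1L]] <- data.frame(
          protein_id = pid, gene_id = gid, out_signal = 1L,
          stringsAsFactors = FALSE
        )
      }

      # CLPP: each exposure credible set against the first outcome signal
      csExp <- extractCredibleSets(fitExp)
      if (length(csExp) > 0L && length(csOut) > 0L) {
        idxE <- match(h$id, fitExp@variantIds)
        idxO <- match(h$id, fitOut@variantIds)
        aO <- setNames(signalAlpha(fitOut)[csOut[[1]]$effectRow, idxO],
                       h$id)
        clppSig <- FALSE
        for (ce in csExp) {
          aE <- setNames(signalAlpha(fitExp)[ce$effectRow, idxE], h$id)
          r <- clpp(aE, aO, ce, signalPair = c(ce$csIndex, 1L),
                    traitPair = c(gid, pid),
                    clppThreshold = clppThreshold)
          if (isSignificant(r)) clppSig <- TRUE
        }
        if (clppSig) {
          pred$clpp[[length(pred$clpp) + 1L]] <- data.frame(
            protein_id = pid, gene_id = gid, out_signal = 1L,
            stringsAsFactors = FALSE
          )
        }
      }

      # multi-signal route: >= 2 distinct-signal colocalizations + MR
      input <- tryCatch(buildMrInput(bfbf, fitExp, fitOut, h),
                        error = function(e) NULL)
      if (!is.null(input)) {
        pred$multi_coloc[[length(pred$multi_coloc) + 1L]] <- data.frame(
          protein_id = pid, gene_id = gid, out_signal = NA_integer_,
          stringsAsFactors = FALSE
        )
        label <- if (gid == truth$gene_id[truth$protein_id == pid]) {
          "TP"
        } else {
          "FP"
        }
        for (mm in mrMethods) {
          est <- tryCatch(mrFit(input, mm, mrLevel),
                          error = function(e) NULL)
          if (is.null(est)) next
          mrRows[[length(mrRows) + 1L]] <- data.frame(
            method = mm, protein_id = pid, gene_id = gid,
            dataset_id = datasetId(exp), k = est@k,
            alphaHat = causalSlope(est), lo = slopeInterval(est)[1],
            hi = slopeInterval(est)[2],
            significant = isSignificant(est), label = label,
            stringsAsFactors = FALSE
          )
          if (isSignificant(est)) {
            mrPred[[mm]][[length(mrPred[[mm]]) + 1L]] <- data.frame(
              protein_id = pid, gene_id = gid, out_signal = NA_integer_,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }

  collect <- function(lst) {
    if (length(lst)) do.call(rbind, lst) else
      data.frame(protein_id = character(), gene_id = character(),
                 out_signal = integer(), stringsAsFactors = FALSE)
  }
  predictions <- lapply(pred, collect)
  for (mm in mrMethods) {
    predictions[[paste0("mr_", mm)]] <- collect(mrPred[[mm]])
  }
  reports <- lapply(names(predictions), function(nm) {
    scoreMethod(predictions[[nm]], truth, tested, method = nm)
  })
  names(reports) <- names(predictions)
  mr <- if (length(mrRows)) do.call(rbind, mrRows) else
    data.frame(method = character(), protein_id = character(),
               gene_id = character(), dataset_id = character(),
               k = integer(), alphaHat = numeric(), lo = numeric(),
               hi = numeric(), significant = logical(),
               label = character(), stringsAsFactors = FALSE)
  list(reports = reports, mr = mr, predictions = predictions,
       testedProteins = tested)
}
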