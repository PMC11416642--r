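#' Fine-mapping configuration
#'
#' Defaults follow the published conventions of the sum-of-single-effects
#' method for quantitative traits: up to 10 signals, 95% credible sets,
#' purity threshold 0.5 on the minimum absolute pairwise LD correlation, and
#' a prior effect-size standard deviation of 0.15 (W = 0.0225) suitable for
#' inverse-normal-transformed phenotypes.
#'
#' @param L maximum number of single effects.
#' @param coverage credible-set posterior mass.
#' @param purityMin minimum absolute pairwise correlation within a set.
#' @param maxIter iteration cap for the IBSS loop.
#' @param tol convergence tolerance on the fitted single-effect means.
#' @param W prior effect-size variance.
#' @param ridge diagonal regularization added to the LD matrix when it fails
#'   the positive-semi-definiteness check.
#' @param estimateResidual if TRUE, the residual variance of the z-score
#'   model is re-estimated each iteration instead of being fixed at 1 (the
#'   appropriate value for standardized, inverse-normal traits).
#' @return list of class \code{FineMapConfig}.
#' @export
fineMapConfig <- function(L = 10L, coverage = 0.95, purityMin = 0.5,
                          maxIter = 200L, tol = 1e-4, W = 0.0225,
                          ridge = 1e-6, estimateResidual = FALSE) {
  stopifnot(L >= 1, coverage > 0, coverage < 1,
            purityMin >= 0, purityMin <= 1, W > 0)
  structure(list(L = as.integer(L), coverage = coverage,
                 purityMin = purityMin, maxIter = as.integer(maxIter),
                 tol = tol, W = W, ridge = ridge,
                 estimateResidual = isTRUE(estimateResidual)),
            class = "FineMapConfig")
}

#' Wakefield log approximate Bayes factor
#'
#' For an effect estimate \code{beta} with standard error \code{se} and a
#' normal prior with variance \code{W} on the true effect, the approximate
#' Bayes factor against the null is \code{lABF = 0.5 * (log(1 - r) +
#' r * z^2)} with \code{r = W / (W + se^2)} and \code{z = beta / se}.
#' Applied row-wise to all-but-one conditional statistics this yields
#' per-signal LABF rows usable wherever fine-mapping LBF rows are expected.
#'
#' @param beta effect estimates.
#' @param se standard errors (> 0).
#' @param W prior effect variance (>= 0; 0 gives lABF = 0 everywhere).
#' @return numeric vector of natural-log approximate Bayes factors.
#' @export
wakefieldLabf <- function(beta, se, W = 0.0225) {
  if (any(!is.finite(beta)) || any(!is.finite(se)) || !is.finite(W)) {
    stop("wakefieldLabf: inputs must be finite")
  }
  if (any(se <= 0)) stop("wakefieldLabf: se must be > 0")
  if (W < 0) stop("wakefieldLabf: W must be >= 0")
  r <- W / (W + se^2)
  z <- beta / se
  0.5 * (log1p(-r) + r * z^2)
}

# Minimum absolute pairwise correlation within a variant set ("purity").
# For large sets a fixed subsample of 100 pairs is examined.
csPurity <- function(idx, R, maxPairs = 100L) {
  if (length(idx) <= 1L) return(1)
  pairs <- utils::combn(idx, 2L)
  if (ncol(pairs) > maxPairs) {
    # deterministic subsample: evenly spaced pairs
    sel <- unique(round(seq(1, ncol(pairs), length.out = maxPairs)))
    pairs <- pairs[, sel, drop = FALSE]
  }
  min(abs(R[cbind(pairs[1, ], pairs[2, ])]))
}

#' Sum-of-single-effects fine-mapping from summary statistics
#'
#' Iterative Bayesian stepwise selection on z-scores: each of L single
#' effects is fit as a Bayesian single-effect regression on the residualized
#' z-vector (\code{alpha} proportional to \code{exp(lbf)}), cycling until
#' the expected single-effect contributions stabilize. Per signal, a
#' credible set is the smallest prefix of variants (by descending alpha)
#' holding at least \code{coverage} posterior mass; sets whose minimum
#' absolute pairwise LD correlation falls below \code{purityMin} are
#' discarded, and survivors are re-indexed in order of decreasing maximum
#' single-effect log Bayes factor.
#'
#' The per-variant prior effect variance \code{W} is interpreted on the
#' effect-size scale of the trait, so with a single effect (L = 1) the
#' inclusion probabilities equal the softmax of
#' \code{wakefieldLabf(beta, se, W)} exactly.
#'
#' @param stats a \linkS4class{RegionStats}.
#' @param R LD correlation matrix (symmetric, unit diagonal) matching the
#'   variant order of \code{stats}.
#' @param config a \code{\link{fineMapConfig}}.
#' @return a \linkS4class{FineMapFit}.
#' @export
susieRss <- function(stats, R, config = fineMapConfig()) {
  M <- length(stats)
  if (!is.matrix(R) || nrow(R) != M || ncol(R) != M) {
    stop("susieRss: R must be an M x M matrix matching stats")
  }
  if (max(abs(R - t(R))) > 1e-8 || max(abs(diag(R) - 1)) > 1e-8) {
    stop("susieRss: R must be symmetric with unit diagonal")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6) {
    R <- R + diag(config$ridge, M)
    R <- R / sqrt(diag(R) %o% diag(R))
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-6) {
      stop("susieRss: LD matrix is not positive semi-definite; ",
           "consider stronger ridge regularization")
    }
  }

  z <- as.numeric(zScores(stats))
  se <- stats@se
  w <- config$W / se^2        # prior variance on the z-score scale
  L <- config$L

  B <- matrix(0, L, M)        # expected single-effect contributions
  alpha <- matrix(1 / M, L, M)
  lbf <- matrix(0, L, M)
  mu <- matrix(0, L, M)
  sigma2 <- 1                 # residual variance; 1 for standardized traits
  converged <- FALSE
  iter <- 0L
  total <- colSums(B)
  for (iter in seq_len(config$maxIter)) {
    maxDelta <- 0
    shrink <- w / (sigma2 + w)
    for (l in seq_len(L)) {
      resid <- z - as.numeric(R %*% (total - B[l, ]))
      lbf_l <- 0.5 * (log1p(-shrink) + resid^2 * shrink / sigma2)
      alpha_l <- softmax(lbf_l)
      mu_l <- shrink * resid
      newB <- alpha_l * mu_l
      maxDelta <- max(maxDelta, max(abs(newB - B[l, ])))
      total <- total - B[l, ] + newB
      B[l, ] <- newB
      alpha[l, ] <- alpha_l
      lbf[l, ] <- lbf_l
      mu[l, ] <- mu_l
    }
    if (config$estimateResidual) {
      # expected residual sum of squares: the naive squared residual plus
      # the posterior variance of each single effect (without this term
      # sigma2 is biased down and phantom signals appear under the null)
      shrinkCur <- w / (sigma2 + w)
      d <- colSums(R^2)
      erss <- sum((z - as.numeric(R %*% total))^2)
      for (l in seq_len(L)) {
        m2 <- alpha[l, ] * (mu[l, ]^2 + shrinkCur * sigma2)
        erss <- erss + sum(m2 * d) - sum(as.numeric(R %*% B[l, ])^2)
      }
      sigma2 <- max(1e-4, erss / M)
    }
    if (maxDelta < config$tol) {
      converged <- TRUE
      break
    }
  }

  pipVec <- 1 - apply(1 - alpha, 2, prod)
  ids <- variantIds(stats)
  colnames(alpha) <- ids
  colnames(lbf) <- ids
  colnames(mu) <- ids

  # credible sets per signal, purity-filtered, re-indexed by max lbf
  pos <- variants(stats)$pos
  sets <- list()
  for (l in seq_len(L)) {
    ord <- order(alpha[l, ], decreasing = TRUE)
    mass <- cumsum(alpha[l, ord])
    size <- which(mass >= config$coverage)[1]
    if (is.na(size)) next
    idx <- ord[seq_len(size)]
    purity <- csPurity(idx, R)
    if (purity < config$purityMin) next
    lead <- idx[order(-abs(z[idx]), pos[idx], ids[idx])][1]
    sets[[length(sets) + 1L]] <- list(
      variantIds = ids[idx], alphaMass = mass[size], purity = purity,
      leadVariant = ids[lead], effectRow = l, maxLbf = max(lbf[l, ])
    )
  }
  if (length(sets) > 1L) {
    # drop duplicate sets from effects that converged to the same signal
    keyOf <- vapply(sets, function(s) paste(sort(s$variantIds),
                                            collapse = ","), character(1))
    sets <- sets[!duplicated(keyOf)]
    sets <- sets[order(-vapply(sets, `[[`, numeric(1), "maxLbf"))]
  }
  for (k in seq_along(sets)) sets[[k]]$csIndex <- k

  new("FineMapFit", alpha = alpha, lbf = lbf, mu = mu, pip = pipVec,
      credibleSets = sets, variantIds = ids, converged = converged,
      niter = iter)
}

#' Extract purity-filtered credible sets from a fit
#'
#' @param result a \linkS4class{FineMapFit}.
#' @param firstOnly if TRUE, return only the top-ranked set (csIndex 1), the
#'   restriction used when comparing multi-signal methods against
#'   single-signal ones.
#' @return list of credible sets (possibly empty).
#' @export
extractCredibleSets <- function(result, firstOnly = FALSE) {
  cs <- result@credibleSets
  if (firstOnly && length(cs) > 0L) cs <- cs[1]
  cs
}
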