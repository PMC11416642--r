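#' Instrument table for cis-Mendelian randomization
#'
#' One row per colocalizing signal pair: the exposure and outcome effect
#' estimates (and standard errors) of the chosen instrument variant, plus
#' the pair of signal indices it came from. All estimators require k >= 2
#' instruments except the plain fixed-effect ratio special case (k = 1).
#'
#' @param bx,seBx exposure effects and standard errors.
#' @param by,seBy outcome effects and standard errors.
#' @param pairExp,pairOut exposure / outcome signal (credible-set) indices;
#'   must be distinct on both coordinates.
#' @param variant instrument variant ids.
#' @return data.frame of class \code{MRInput}.
#' @export
mrInput <- function(bx, seBx, by, seBy,
                    pairExp = seq_along(bx), pairOut = seq_along(bx),
                    variant = paste0("v", seq_along(bx))) {
  stopifnot(length(bx) == length(by), length(seBx) == length(bx),
            length(seBy) == length(bx))
  if (any(seBx <= 0) || any(seBy <= 0)) {
    stop("mrInput: standard errors must be > 0")
  }
  if (anyDuplicated(pairExp) || anyDuplicated(pairOut)) {
    stop("mrInput: signal indices must be distinct on both coordinates")
  }
  structure(
    data.frame(bx = bx, seBx = seBx, by = by, seBy = seBy,
               pairExp = pairExp, pairOut = pairOut, variant = variant,
               stringsAsFactors = FALSE),
    class = c("MRInput", "data.frame")
  )
}

# 80% normal quantile used for all confidence intervals (level -> quantile)
mrQuantile <- function(level) qnorm(0.5 + level / 2)

mrEstimate <- function(method, alphaHat, se = NULL, interval = NULL,
                       level = 0.8, dispersion = NA_real_, k) {
  if (is.null(interval)) {
    q <- mrQuantile(level)
    interval <- c(alphaHat - q * se, alphaHat + q * se)
  }
  new("MREstimate", method = method, alphaHat = alphaHat,
      interval = interval, level = level, dispersion = dispersion,
      k = as.integer(k),
      significant = !(interval[1] <= 0 && interval[2] >= 0))
}

#' Inverse-variance-weighted Mendelian randomization
#'
#' Per-instrument ratio estimates \code{theta_j = by_j / bx_j} are combined
#' with inverse-variance weights. First-order weights use
#' \code{v_j = seBy_j^2 / bx_j^2}; delta weights add the exposure's sampling
#' error, \code{v_j = seBy_j^2 / bx_j^2 + by_j^2 seBx_j^2 / bx_j^4}. Under
#' the multiplicative random-effects model the standard error is inflated by
#' \code{max(1, sqrt(Q / (k - 1)))} where Q is Cochran's heterogeneity
#' statistic, modeling overdispersion heterogeneity between instruments
#' (never deflated below the fixed-effect value).
#'
#' @param input an \code{\link{mrInput}}.
#' @param weighting \code{"first_order"} or \code{"delta"}.
#' @param model \code{"fixed"} or \code{"random"}.
#' @param level interval level (default 0.80).
#' @return an \linkS4class{MREstimate}.
#' @export
mrIvw <- function(input, weighting = c("first_order", "delta"),
                  model = c("fixed", "random"), level = 0.8) {
  weighting <- match.arg(weighting)
  model <- match.arg(model)
  keep <- input$bx != 0
  if (any(!keep)) {
    warning(sum(!keep), " instrument(s) with zero exposure effect rejected")
    input <- input[keep, , drop = FALSE]
  }
  k <- nrow(input)
  if (k == 0L) stop("mrIvw: no usable instruments")
  if (k == 1L) {
    if (model == "random" || weighting == "delta") {
      stop("mrIvw: a single instrument supports only the fixed ",
           "first-order ratio estimate")
    }
    ratio <- input$by / input$bx
    se <- input$seBy / abs(input$bx)
    return(mrEstimate("ivw", ratio, se = se, level = level, k = 1L))
  }
  theta <- input$by / input$bx
  v <- input$seBy^2 / input$bx^2
  if (weighting == "delta") {
    v <- v + input$by^2 * input$seBx^2 / input$bx^4
  }
  wts <- 1 / v
  alphaHat <- sum(theta * wts) / sum(wts)
  seFixed <- sqrt(1 / sum(wts))
  Q <- sum((theta - alphaHat)^2 / v)
  method <- if (weighting == "first_order") "ivw" else "ivw_delta"
  if (model == "random") {
    infl <- max(1, sqrt(Q / (k - 1)))
    return(mrEstimate("ivw_delta_random", alphaHat, se = seFixed * infl,
                      level = level, dispersion = Q / (k - 1), k = k))
  }
  mrEstimate(method, alphaHat, se = seFixed, level = level, k = k)
}

# Tukey biweight score and its derivative (tuning constant c)
tukeyPsi <- function(t, cc = 4.685) {
  ifelse(abs(t) < cc, t * (1 - (t / cc)^2)^2, 0)
}
tukeyPsiDeriv <- function(t, cc = 4.685) {
  u <- (t / cc)^2
  ifelse(abs(t) < cc, (1 - u) * (1 - 5 * u), 0)
}

# E[t * psi(t)] under t ~ N(0,1); the null expectation calibrating the
# overdispersion moment equation.
tukeyDelta <- function(cc = 4.685) {
  integrate(function(t) t * tukeyPsi(t, cc) * dnorm(t), -cc, cc,
            rel.tol = 1e-10)$value
}

#' Robust adjusted profile score Mendelian randomization
#'
#' Solves the robust adjusted profile score equations for the causal slope
#' and an additive overdispersion variance tau^2: standardized residuals
#' \code{t_j = (by_j - alpha * bx_j) / sqrt(seBy_j^2 + alpha^2 seBx_j^2 +
#' tau^2)} enter a Tukey-biweight score equation for alpha, while tau^2
#' solves the companion moment equation calibrated so the weighted squared
#' residuals match their null expectation. Outlying instruments are
#' downweighted smoothly to zero. Standard errors come from a numerical
#' sandwich estimate.
#'
#' @param input an \code{\link{mrInput}} with k >= 2.
#' @param level interval level.
#' @param cc Tukey biweight tuning constant (default 4.685).
#' @param maxIter iteration cap for the alternating root finder.
#' @return an \linkS4class{MREstimate} with \code{dispersion} = tau^2.
#' @export
mrRaps <- function(input, level = 0.8, cc = 4.685, maxIter = 100L) {
  k <- nrow(input)
  if (k < 2L) stop("mrRaps: at least 2 instruments required")
  bx <- input$bx; seBx <- input$seBx
  by <- input$by; seBy <- input$seBy
  delta0 <- tukeyDelta(cc)

  tfun <- function(alpha, tau2) {
    (by - alpha * bx) / sqrt(seBy^2 + alpha^2 * seBx^2 + tau2)
  }
  dtda <- function(alpha, tau2) {
    s2 <- seBy^2 + alpha^2 * seBx^2 + tau2
    s <- sqrt(s2)
    -bx / s - (by - alpha * bx) * alpha * seBx^2 / (s2 * s)
  }
  f1 <- function(alpha, tau2) {
    sum(tukeyPsi(tfun(alpha, tau2), cc) * dtda(alpha, tau2))
  }
  f2 <- function(tau2, alpha) {
    t <- tfun(alpha, tau2)
    sum(t * tukeyPsi(t, cc) - delta0)
  }
  # The Tukey score redescends to zero far from the truth, so the alpha
  # equation is solved by IRLS from a consistent start (weights
  # psi(t)/t), then polished by a local root search on the exact score.
  rootAlpha <- function(tau2, center) {
    alpha <- center
    for (i in 1:200) {
      s2 <- seBy^2 + alpha^2 * seBx^2 + tau2
      t <- (by - alpha * bx) / sqrt(s2)
      wR <- ifelse(abs(t) < cc, (1 - (t / cc)^2)^2, 0)
      denom <- sum(wR * bx^2 / s2)
      if (denom <= 0) break   # all instruments downweighted to zero
      alphaNew <- sum(wR * bx * by / s2) / denom
      if (abs(alphaNew - alpha) < 1e-12) {
        alpha <- alphaNew
        break
      }
      alpha <- alphaNew
    }
    step <- max(1e-4, 0.5 * sqrt(mean(seBy^2 + tau2)) / mean(abs(bx)))
    lo <- alpha - step; hi <- alpha + step
    flo <- f1(lo, tau2); fhi <- f1(hi, tau2)
    if (is.finite(flo) && is.finite(fhi) && flo * fhi <= 0) {
      return(uniroot(f1, c(lo, hi), tau2 = tau2, tol = 1e-10)$root)
    }
    alpha
  }

  start <- tryCatch(
    causalSlope(mrIvw(input, weighting = "delta", model = "fixed")),
    error = function(e) stats::median(by / bx)
  )
  alpha <- start
  tau2 <- 0
  for (it in seq_len(maxIter)) {
    alphaNew <- rootAlpha(tau2, alpha)
    # moment equation: near its root f2 crosses + -> -; when residuals are
    # grossly overdispersed the redescending score drives f2 < 0 at BOTH
    # extremes, so scan a grid up to a moment-based ceiling for the upper
    # crossing instead of assuming monotonicity from zero.
    hi <- 4 * (stats::var(by - alphaNew * bx) + max(seBy^2)) + 1e-8
    grid <- c(0, exp(seq(log(hi * 1e-6), log(hi), length.out = 60L)))
    fg <- vapply(grid, f2, numeric(1), alpha = alphaNew)
    posIdx <- which(fg > 0)
    tau2New <- 0
    if (length(posIdx)) {
      iPos <- max(posIdx)
      if (iPos < length(grid)) {
        tau2New <- uniroot(f2, c(grid[iPos], grid[iPos + 1L]),
                           alpha = alphaNew, tol = 1e-10)$root
      } else {
        tau2New <- grid[iPos]
      }
    }
    if (abs(alphaNew - alpha) < 1e-8 && abs(tau2New - tau2) < 1e-8) {
      alpha <- alphaNew; tau2 <- tau2New
      break
    }
    alpha <- alphaNew
    tau2 <- tau2New
  }

  # numerical sandwich variance for alpha from the joint system
  t <- tfun(alpha, tau2)
  g1 <- tukeyPsi(t, cc) * dtda(alpha, tau2)
  g2 <- t * tukeyPsi(t, cc) - delta0
  eps <- 1e-6 * max(1, abs(alpha))
  epsT <- 1e-6 * max(1, tau2)
  G <- matrix(c(
    (f1(alpha + eps, tau2) - f1(alpha - eps, tau2)) / (2 * eps),
    (f1(alpha, tau2 + epsT) - f1(alpha, max(0, tau2 - epsT))) /
      (epsT + min(epsT, tau2)),
    (f2(tau2, alpha + eps) - f2(tau2, alpha - eps)) / (2 * eps),
    (f2(tau2 + epsT, alpha) - f2(max(0, tau2 - epsT), alpha)) /
      (epsT + min(epsT, tau2))
  ), 2, 2, byrow = TRUE)
  Omega <- rbind(c(sum(g1^2), sum(g1 * g2)),
                 c(sum(g1 * g2), sum(g2^2)))
  seAlpha <- tryCatch({
    Ginv <- solve(G)
    V <- Ginv %*% Omega %*% t(Ginv)
    sqrt(max(V[1, 1], 0))
  }, error = function(e) {
    d1 <- (f1(alpha + eps, tau2) - f1(alpha - eps, tau2)) / (2 * eps)
    sqrt(sum(g1^2)) / abs(d1)
  })
  if (!is.finite(seAlpha) || seAlpha <= 0) {
    stop("mrRaps: estimation failed (degenerate sandwich variance), ",
         "last iterate alpha = ", signif(alpha, 4))
  }
  mrEstimate("raps", alpha, se = seAlpha, level = level,
             dispersion = tau2, k = k)
}

#' Hierarchical allelic-spread Mendelian randomization
#'
#' Fits the hierarchical model in which each instrument has its own slope
#' \code{alpha_j ~ N(alpha, tau^2)} (tau is the allelic spread) and
#' \code{by_j ~ N(alpha_j * bx_j, seBy_j^2)} with the exposure effects fixed
#' at their observed values. Marginalizing the per-instrument slopes gives
#' \code{by_j ~ N(alpha * bx_j, seBy_j^2 + tau^2 * bx_j^2)}. With
#' weakly-informative priors (alpha ~ N(0, 10^2), tau ~ half-N(0, 5^2)) the
#' posterior is evaluated on a deterministic adaptive grid over
#' (alpha, tau) and summarized by the posterior median and the central
#' credible interval; no stochastic sampler is involved, so results are
#' exactly reproducible. Discordant instruments inflate tau and widen the
#' interval toward zero rather than producing spuriously precise estimates.
#'
#' @param input an \code{\link{mrInput}} with k >= 2.
#' @param level credible-interval level (default 0.80).
#' @param gridN grid resolution per dimension.
#' @return an \linkS4class{MREstimate} with \code{dispersion} = posterior
#'   median of tau.
#' @export
mrLocusSpread <- function(input, level = 0.8, gridN = 201L) {
  k <- nrow(input)
  if (k < 2L) stop("mrLocusSpread: at least 2 instruments required")
  bx <- input$bx; by <- input$by; seBy <- input$seBy

  theta <- by / bx
  seTheta <- seBy / abs(bx)
  center <- sum(theta / seTheta^2) / sum(1 / seTheta^2)
  spread <- sqrt(sum((theta - center)^2) / max(1, k - 1))
  halfA <- max(10 * sqrt(1 / sum(1 / seTheta^2)), 3 * spread,
               2 * max(seTheta), abs(center), 0.5)
  tauHi <- max(3 * spread, 3 * max(seTheta), 0.5)

  logPost <- function(aGrid, tauGrid) {
    lp <- matrix(0, length(aGrid), length(tauGrid))
    for (j in seq_len(k)) {
      sd_j <- sqrt(outer(rep(seBy[j]^2, length(aGrid)),
                         tauGrid^2 * bx[j]^2, "+"))
      lp <- lp + dnorm(by[j], outer(aGrid * bx[j], rep(1, length(tauGrid))),
                       sd_j, log = TRUE)
    }
    lp + dnorm(aGrid, 0, 10, log = TRUE) +
      rep(dnorm(tauGrid, 0, 5, log = TRUE), each = length(aGrid))
  }

  summarize <- function(aGrid, tauGrid) {
    lp <- logPost(aGrid, tauGrid)
    w <- exp(lp - max(lp))
    # trapezoidal marginalization over tau
    dt <- diff(tauGrid)
    margA <- as.numeric(
      (w[, -1, drop = FALSE] + w[, -ncol(w), drop = FALSE]) %*% (dt / 2)
    )
    da <- diff(aGrid)
    Z <- sum((margA[-1] + margA[-length(margA)]) * da / 2)
    cdf <- cumsum(c(0, (margA[-1] + margA[-length(margA)]) * da / 2)) / Z
    qA <- function(p) approx(cdf, aGrid, xout = p, ties = "ordered")$y
    margT <- as.numeric(
      (da / 2) %*% (w[-1, , drop = FALSE] + w[-nrow(w), , drop = FALSE])
    )
    Zt <- sum((margT[-1] + margT[-length(margT)]) * dt / 2)
    cdfT <- cumsum(c(0, (margT[-1] + margT[-length(margT)]) * dt / 2)) / Zt
    qT <- function(p) approx(cdfT, tauGrid, xout = p, ties = "ordered")$y
    list(qA = qA, qT = qT)
  }

  aGrid <- seq(center - halfA, center + halfA, length.out = gridN)
  tauGrid <- seq(0, tauHi, length.out = max(81L, gridN %/% 2))
  s <- summarize(aGrid, tauGrid)
  # refine once around the bulk of the posterior
  lo999 <- s$qA(0.001); hi999 <- s$qA(0.999)
  pad <- 0.2 * (hi999 - lo999)
  aGrid <- seq(lo999 - pad, hi999 + pad, length.out = gridN)
  s <- summarize(aGrid, tauGrid)

  alphaHat <- s$qA(0.5)
  lohi <- c(s$qA(0.5 - level / 2), s$qA(0.5 + level / 2))
  tauMed <- s$qT(0.5)
  if (any(!is.finite(c(alphaHat, lohi)))) {
    stop("mrLocusSpread: posterior grid evaluation failed")
  }
  mrEstimate("locus_spread", alphaHat, interval = lohi, level = level,
             dispersion = tauMed, k = k)
}

#' Run one of the five MR estimators by name
#'
#' @param input an \code{\link{mrInput}}.
#' @param method one of \code{"ivw"}, \code{"ivw_delta"},
#'   \code{"ivw_delta_random"}, \code{"raps"}, \code{"locus_spread"}.
#' @param level interval level.
#' @return an \linkS4class{MREstimate}.
#' @export
mrFit <- function(input, method = c("ivw", "ivw_delta", "ivw_delta_random",
                                    "raps", "locus_spread"), level = 0.8) {
  method <- match.arg(method)
  switch(method,
    ivw = mrIvw(input, "first_order", "fixed", level),
    ivw_delta = mrIvw(input, "delta", "fixed", level),
    ivw_delta_random = mrIvw(input, "delta", "random", level),
    raps = mrRaps(input, level),
    locus_spread = mrLocusSpread(input, level)
  )
}

#' Build an MR instrument table from per-signal colocalization results
#'
#' Keeps a (gene, protein, dataset) triplet only when it has two or more
#' significant per-signal colocalizations whose exposure signal indices are
#' mutually distinct and whose outcome signal indices are mutually distinct
#' (signal pairs are taken greedily by decreasing PP4). For each retained
#' pair the instrument variant is the shared variant maximizing the product
#' of the two signals' inclusion probabilities, and its marginal effects on
#' both traits are read from the harmonized statistics.
#'
#' @param bfbfResults data.frame with columns \code{pairExp},
#'   \code{pairOut}, \code{pp4}, \code{significant} — one row per evaluated
#'   signal pair.
#' @param fitExp,fitOut \linkS4class{FineMapFit}s of exposure and outcome.
#' @param harmonized harmonized variant table from
#'   \code{\link{harmonizePair}} (exposure = a, outcome = b).
#' @return an \code{\link{mrInput}} or NULL when fewer than 2 eligible
#'   pairs exist.
#' @export
buildMrInput <- function(bfbfResults, fitExp, fitOut, harmonized) {
  sig <- bfbfResults[bfbfResults$significant, , drop = FALSE]
  if (nrow(sig) < 2L) return(NULL)
  sig <- sig[order(-sig$pp4), , drop = FALSE]
  chosen <- sig[0, ]
  for (i in seq_len(nrow(sig))) {
    if (!(sig$pairExp[i] %in% chosen$pairExp) &&
        !(sig$pairOut[i] %in% chosen$pairOut)) {
      chosen <- rbind(chosen, sig[i, ])
    }
  }
  if (nrow(chosen) < 2L) return(NULL)

  ids <- harmonized$id
  csExp <- extractCredibleSets(fitExp)
  csOut <- extractCredibleSets(fitOut)
  rowOf <- function(cs, k) cs[[which(vapply(cs, `[[`, integer(1),
                                            "csIndex") == k)]]$effectRow
  bx <- seBx <- by <- seBy <- numeric(nrow(chosen))
  vids <- character(nrow(chosen))
  for (i in seq_len(nrow(chosen))) {
    ae <- signalAlpha(fitExp)[rowOf(csExp, chosen$pairExp[i]),
                              match(ids, colnames(signalAlpha(fitExp)))]
    ao <- signalAlpha(fitOut)[rowOf(csOut, chosen$pairOut[i]),
                              match(ids, colnames(signalAlpha(fitOut)))]
    ae[is.na(ae)] <- 0
    ao[is.na(ao)] <- 0
    prod <- ae * ao
    if (max(prod) <= 0) {
      stop("buildMrInput: significant signal pair with disjoint support")
    }
    j <- which.max(prod)
    vids[i] <- ids[j]
    bx[i] <- harmonized$beta_a[j]; seBx[i] <- harmonized$se_a[j]
    by[i] <- harmonized$beta_b[j]; seBy[i] <- harmonized$se_b[j]
  }
  mrInput(bx, seBx, by, seBy, pairExp = chosen$pairExp,
          pairOut = chosen$pairOut, variant = vids)
}
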