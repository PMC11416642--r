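test_that("IVW reproduces hand-computed weighted means and Q inflation", {
  # both ratios equal 2 -> slope exactly 2
  inp <- mrInput(bx = c(0.5, 0.25), seBx = c(1e-6, 1e-6),
                 by = c(1.0, 0.5), seBy = c(0.1, 0.1))
  expect_equal(causalSlope(mrIvw(inp, "first_order", "fixed")), 2,
               tolerance = 1e-12)

  # bx=(1,1,1), by=(0,2,4), seBy=1: alpha=2, SE_fixed=3^(-1/2), Q=8,
  # SE_random = 2 * SE_fixed
  inp2 <- mrInput(bx = rep(1, 3), seBx = rep(1e-9, 3),
                  by = c(0, 2, 4), seBy = rep(1, 3))
  ef <- mrIvw(inp2, "first_order", "fixed")
  er <- mrIvw(inp2, "first_order", "random")
  q <- qnorm(0.9)
  expect_equal(causalSlope(ef), 2, tolerance = 1e-12)
  expect_equal(diff(slopeInterval(ef)) / (2 * q), 1 / sqrt(3),
               tolerance = 1e-9)
  expect_equal(diff(slopeInterval(er)) / (2 * q), 2 / sqrt(3),
               tolerance = 1e-9)
  expect_equal(dispersion(er), 4, tolerance = 1e-9)  # Q/(k-1)
})

test_that("the 80% interval uses the 1.2816 normal quantile", {
  inp <- mrInput(bx = rep(1, 3), seBx = rep(1e-9, 3),
                 by = c(0, 2, 4), seBy = rep(1, 3))
  ef <- mrIvw(inp, "first_order", "fixed")
  expect_equal(slopeInterval(ef)[2] - causalSlope(ef),
               1.281552 / sqrt(3), tolerance = 1e-6)
})

test_that("a single instrument returns the fixed first-order ratio", {
  inp <- mrInput(bx = 0.5, seBx = 0.1, by = 1, seBy = 0.2)
  e <- mrIvw(inp, "first_order", "fixed")
  expect_equal(causalSlope(e), 2)
  expect_equal(slopeInterval(e)[2] - causalSlope(e),
               qnorm(0.9) * 0.2 / 0.5, tolerance = 1e-9)
  expect_error(mrIvw(inp, "delta", "fixed"), "single instrument")
})

test_that("delta weights are never smaller than first-order weights", {
  set.seed(11)
  inp <- mrInput(bx = rnorm(6, 0.5, 0.1), seBx = rep(0.1, 6),
                 by = rnorm(6, 0.25, 0.05), seBy = rep(0.05, 6))
  ef <- mrIvw(inp, "first_order", "fixed")
  ed <- mrIvw(inp, "delta", "fixed")
  expect_gte(diff(slopeInterval(ed)), diff(slopeInterval(ef)) - 1e-12)
})

test_that("random-effects SE is never below the fixed-effect SE", {
  set.seed(12)
  for (rep in 1:20) {
    k <- sample(2:8, 1)
    inp <- mrInput(bx = rnorm(k, 0.5, 0.2), seBx = rep(0.05, k),
                   by = rnorm(k, 0.2, 0.3), seBy = runif(k, 0.02, 0.2))
    ed <- mrIvw(inp, "delta", "fixed")
    er <- mrIvw(inp, "delta", "random")
    expect_gte(diff(slopeInterval(er)), diff(slopeInterval(ed)) - 1e-12)
  }
})

test_that("instruments with zero exposure effect are rejected", {
  inp <- mrInput(bx = c(0, 0.5, 0.4), seBx = rep(0.05, 3),
                 by = c(0.1, 0.25, 0.2), seBy = rep(0.05, 3))
  expect_warning(e <- mrIvw(inp, "first_order", "fixed"),
                 "zero exposure effect")
  expect_equal(e@k, 2L)
})

test_that("all five estimators are scale-equivariant in the outcome", {
  set.seed(13)
  k <- 6
  bx <- rnorm(k, 0.6, 0.1)
  by <- 0.5 * bx + rnorm(k, 0, 0.03)
  inp1 <- mrInput(bx, rep(0.05, k), by, rep(0.03, k))
  cc <- 3.7
  inp2 <- mrInput(bx, rep(0.05, k), cc * by, cc * rep(0.03, k))
  for (m in c("ivw", "ivw_delta", "ivw_delta_random", "raps")) {
    e1 <- mrFit(inp1, m); e2 <- mrFit(inp2, m)
    expect_equal(causalSlope(e2), cc * causalSlope(e1), tolerance = 1e-6)
    expect_equal(slopeInterval(e2), cc * slopeInterval(e1),
                 tolerance = 1e-6)
  }
  # grid posterior with weak priors: equivariant to within grid resolution
  e1 <- mrFit(inp1, "locus_spread"); e2 <- mrFit(inp2, "locus_spread")
  expect_equal(causalSlope(e2), cc * causalSlope(e1), tolerance = 1e-2)
  expect_equal(slopeInterval(e2), cc * slopeInterval(e1), tolerance = 5e-2)
})

test_that("RAPS agrees with delta-weighted IVW absent violations", {
  set.seed(14)
  diffs <- vapply(1:25, function(s) {
    k <- 10
    bx <- rnorm(k, 0.6, 0.15)
    by <- 0.5 * bx + rnorm(k, 0, 0.02)
    inp <- mrInput(bx, rep(0.03, k), by, rep(0.02, k))
    causalSlope(mrRaps(inp)) -
      causalSlope(mrIvw(inp, "delta", "fixed"))
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.05)
})

test_that("RAPS downweights a gross outlier that inflates plain IVW", {
  set.seed(15)
  wins <- vapply(1:20, function(s) {
    k <- 10
    bx <- rep(1, k + 1)
    by <- c(rnorm(k, 0, 0.1), 10)   # one gross outlier ratio of 10
    inp <- mrInput(bx, rep(0.01, k + 1), by, rep(0.1, k + 1))
    abs(causalSlope(mrRaps(inp))) <
      abs(causalSlope(mrIvw(inp, "first_order", "fixed")))
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("RAPS recovers injected overdispersion at k = 50", {
  set.seed(16)
  tau2s <- vapply(1:15, function(s) {
    k <- 50
    bx <- rnorm(k, 1, 0.2)
    by <- 0.5 * bx + rnorm(k, 0, sqrt(0.2)) + rnorm(k, 0, 0.05)
    dispersion(mrRaps(mrInput(bx, rep(0.02, k), by, rep(0.05, k))))
  }, numeric(1))
  expect_lt(abs(median(tau2s) - 0.2) / 0.2, 0.5)
  # and stays near zero without injected overdispersion
  set.seed(17)
  tau2s0 <- vapply(1:10, function(s) {
    k <- 50
    bx <- rnorm(k, 1, 0.2)
    by <- 0.5 * bx + rnorm(k, 0, 0.05)
    dispersion(mrRaps(mrInput(bx, rep(0.02, k), by, rep(0.05, k))))
  }, numeric(1))
  expect_lt(median(tau2s0), 0.05)
})

test_that("the allelic-spread model concentrates on concordant ratios", {
  inp <- mrInput(bx = c(0.5, 0.4), seBx = c(0.02, 0.02),
                 by = c(1.0, 0.8), seBy = c(0.02, 0.02))
  e <- mrLocusSpread(inp)
  ci <- slopeInterval(e)
  expect_true(ci[1] <= 2 && ci[2] >= 2)
  expect_true(isSignificant(e))
})

test_that("discordant instruments widen the interval to include zero", {
  inp <- mrInput(bx = c(0.5, 0.5), seBx = c(0.02, 0.02),
                 by = c(1.0, -0.6), seBy = c(0.02, 0.02))
  e <- mrLocusSpread(inp)
  expect_false(isSignificant(e))
  expect_gt(dispersion(e), 0.5)   # wide allelic spread
  # the same locus looks highly significant to plain IVW
  eIvw <- mrIvw(inp, "first_order", "fixed")
  expect_true(isSignificant(eIvw))
})

test_that("an all-null outcome yields a near-symmetric interval", {
  inp <- mrInput(bx = c(0.5, 0.4, 0.6), seBx = rep(0.02, 3),
                 by = c(0, 0, 0), seBy = rep(0.05, 3))
  e <- mrLocusSpread(inp)
  expect_lt(abs(causalSlope(e)), 0.05)
  expect_lt(abs(sum(slopeInterval(e))), 0.1)
  expect_false(isSignificant(e))
})

test_that("fixed IVW over-rejects a heterogeneous null vs random effects", {
  set.seed(18)
  sigF <- sigR <- logical(200)
  for (i in 1:200) {
    k <- 3
    slopes <- rnorm(k, 0, 1)       # per-instrument slopes, true mean 0
    bx <- rnorm(k, 0.6, 0.1)
    by <- slopes * bx + rnorm(k, 0, 0.02)
    inp <- mrInput(bx, rep(0.03, k), by, rep(0.02, k))
    sigF[i] <- isSignificant(mrIvw(inp, "delta", "fixed"))
    sigR[i] <- isSignificant(mrIvw(inp, "delta", "random"))
  }
  expect_gt(mean(sigF), mean(sigR))
})

test_that("fixed IVW significance is calibrated under a homogeneous null", {
  set.seed(19)
  sig <- vapply(1:400, function(i) {
    k <- 4
    bx <- rnorm(k, 0.6, 0.1)
    by <- rnorm(k, 0, 0.02)       # true slope zero, exact SEs
    isSignificant(mrIvw(mrInput(bx, rep(1e-9, k), by, rep(0.02, k)),
                        "first_order", "fixed"))
  }, logical(1))
  expect_lt(abs(mean(sig) - 0.2), 0.06)
})

test_that("instrument tables enforce distinctness and positive SEs", {
  expect_error(mrInput(bx = c(1, 1), seBx = c(0.1, 0.1), by = c(1, 1),
                       seBy = c(0.1, 0.1), pairExp = c(1, 1),
                       pairOut = c(1, 2)), "distinct")
  expect_error(mrInput(bx = 1, seBx = 0, by = 1, seBy = 0.1), "standard")
})

test_that("MR input assembly enforces the multiplicity and distinctness rules", {
  mkFit <- function(alphaRows, csIdx) {
    a <- do.call(rbind, alphaRows)
    colnames(a) <- paste0("v", seq_len(ncol(a)))
    sets <- lapply(seq_along(csIdx), function(i) {
      ord <- order(a[i, ], decreasing = TRUE)
      list(variantIds = colnames(a)[ord[1]], alphaMass = max(a[i, ]),
           purity = 1, leadVariant = colnames(a)[ord[1]],
           effectRow = i, maxLbf = 10, csIndex = csIdx[i])
    })
    new("FineMapFit", alpha = a, lbf = a, pip = 1 - apply(1 - a, 2, prod),
        credibleSets = sets, variantIds = colnames(a), converged = TRUE,
        niter = 1L)
  }
  h <- data.frame(id = paste0("v", 1:4),
                  beta_a = c(0.5, 0.4, 0.3, 0.2), se_a = rep(0.05, 4),
                  beta_b = c(0.25, 0.2, 0.15, 0.1), se_b = rep(0.02, 4))
  e1 <- c(0.97, 0.01, 0.01, 0.01)
  e2 <- c(0.01, 0.97, 0.01, 0.01)
  fitE <- mkFit(list(e1, e2), 1:2)
  fitO <- mkFit(list(e1, e2), 1:2)

  # two significant pairs with distinct indices on both sides -> k = 2
  bfbf <- data.frame(pairExp = c(1, 2), pairOut = c(1, 2),
                     pp4 = c(0.99, 0.95), significant = c(TRUE, TRUE))
  inp <- buildMrInput(bfbf, fitE, fitO, h)
  expect_s3_class(inp, "MRInput")
  expect_equal(nrow(inp), 2L)
  expect_equal(inp$variant, c("v1", "v2"))
  expect_equal(inp$bx, c(0.5, 0.4))

  # only one significant pair -> below the multiplicity threshold
  bfbf1 <- data.frame(pairExp = 1, pairOut = 1, pp4 = 0.99,
                      significant = TRUE)
  expect_null(buildMrInput(bfbf1, fitE, fitO, h))

  # same exposure signal used twice -> distinctness rule rejects
  bfbf2 <- data.frame(pairExp = c(1, 1), pairOut = c(1, 2),
                      pp4 = c(0.99, 0.95), significant = c(TRUE, TRUE))
  expect_null(buildMrInput(bfbf2, fitE, fitO, h))

  # non-significant rows never contribute
  bfbf3 <- data.frame(pairExp = c(1, 2), pairOut = c(1, 2),
                      pp4 = c(0.99, 0.5), significant = c(TRUE, FALSE))
  expect_null(buildMrInput(bfbf3, fitE, fitO, h))
})
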