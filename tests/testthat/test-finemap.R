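test_that("Wakefield lABF matches the closed form and its limits", {
  # beta=0.1, se=0.05, W=0.0225: r=0.9, lABF = 0.5*(ln 0.1 + 3.6)
  expect_equal(wakefieldLabf(0.1, 0.05, 0.0225),
               0.5 * (log(0.1) + 0.9 * 4), tolerance = 1e-12)
  expect_equal(round(wakefieldLabf(0.1, 0.05, 0.0225), 5), 0.64871)
  # z = 0: negative lABF
  expect_lt(wakefieldLabf(0, 0.05, 0.0225), 0)
  expect_equal(wakefieldLabf(0, 0.05, 0.0225),
               0.5 * log(1 - 0.9), tolerance = 1e-12)
  # W -> 0 gives lABF -> 0
  expect_equal(wakefieldLabf(c(0.1, -0.5), c(0.05, 0.1), 0), c(0, 0))
  expect_error(wakefieldLabf(Inf, 0.05), "finite")
  expect_error(wakefieldLabf(0.1, -0.05), "se")
})

test_that("lABF increases strictly in z^2 for fixed se and W", {
  z <- c(0, 0.5, 1, 2, 4, 8)
  l <- wakefieldLabf(z * 0.1, rep(0.1, 6), 0.0225)
  expect_true(all(diff(l) > 0))
})

test_that("alpha rows sum to one and pip matches its identity on every fit", {
  for (s in 1:3) {
    p <- simPair(seed = 700 + s)
    fit <- susieRss(p$exp, p$loc$ld, fineMapConfig(L = 5L))
    a <- signalAlpha(fit)
    expect_equal(rowSums(a), rep(1, nrow(a)), tolerance = 1e-8)
    expect_equal(unname(pip(fit)), unname(1 - apply(1 - a, 2, prod)),
                 tolerance = 1e-8)
    expect_true(all(pip(fit) >= 0 & pip(fit) <= 1))
  }
})

test_that("with L = 1 the fit reduces to the softmax of Wakefield lABFs", {
  p <- simPair(seed = 710)
  W <- 0.0225
  fit <- susieRss(p$exp, p$loc$ld, fineMapConfig(L = 1L, W = W))
  labf <- wakefieldLabf(p$exp@beta, p$exp@se, W)
  expect_equal(unname(signalAlpha(fit)[1, ]),
               exp(labf - max(labf)) / sum(exp(labf - max(labf))),
               tolerance = 1e-6)
  expect_equal(unname(signalLbf(fit)[1, ]), labf, tolerance = 1e-6)
})

test_that("pure-noise regions yield no credible sets", {
  empty <- vapply(1:20, function(s) {
    p <- simPair(seed = 720 + s, m = 50L, nExp = 500L, nOut = 100L,
                 veExp = 0, veOut = 0)
    fit <- susieRss(p$exp, p$loc$ld, fineMapConfig(L = 5L))
    length(extractCredibleSets(fit)) == 0L
  }, logical(1))
  expect_gte(mean(empty), 0.95)
})

test_that("a strong single causal lands in the single credible set", {
  hits <- vapply(1:25, function(s) {
    p <- simPair(seed = 740 + s, m = 60L, nExp = 500L, nOut = 100L,
                 veExp = 0.1, veOut = 0)
    fit <- susieRss(p$exp, p$loc$ld, fineMapConfig(L = 5L))
    cs <- extractCredibleSets(fit)
    length(cs) >= 1L && p$causalId %in% cs[[1]]$variantIds
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("two causals in different blocks give two purity-filtered sets", {
  hits <- vapply(1:15, function(s) {
    cfg <- locusConfig(m = 60L, nExp = 800L, nOut = 100L, rho = 0.9,
                       blockSize = 10L)
    loc <- simulateLocus(cfg, seed = 760 + s)
    arch <- causalArchitecture(
      data.frame(idx = c(15, 45), ve = c(0.12, 0.1)), NULL
    )
    tr <- simulateTraits(loc$dosExp, loc$dosOut, arch, seed = 860 + s)
    ss <- marginalSumstats(loc$dosExp, tr$yExp, loc$variants, "g")
    fit <- susieRss(ss, loc$ld, fineMapConfig(L = 5L))
    cs <- extractCredibleSets(fit)
    members <- unlist(lapply(cs, `[[`, "variantIds"))
    length(cs) == 2L && all(loc$variants$id[c(15, 45)] %in% members)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("credible sets respect coverage, purity and lead-variant rules", {
  p <- simPair(seed = 780)
  cfg <- fineMapConfig(L = 5L, coverage = 0.95, purityMin = 0.5)
  fit <- susieRss(p$exp, p$loc$ld, cfg)
  for (cs in extractCredibleSets(fit)) {
    expect_gte(cs$alphaMass, 0.95)
    expect_gte(cs$purity, 0.5)
    expect_true(cs$leadVariant %in% cs$variantIds)
    # lead variant has the max |z| among members
    z <- abs(zScores(p$exp)[cs$variantIds])
    expect_equal(unname(z[cs$leadVariant]), max(z))
  }
})

test_that("firstOnly restriction returns only the top-ranked set", {
  cfg <- locusConfig(m = 60L, nExp = 800L, nOut = 100L, blockSize = 10L)
  loc <- simulateLocus(cfg, seed = 790)
  arch <- causalArchitecture(
    data.frame(idx = c(15, 45), ve = c(0.15, 0.08)), NULL
  )
  tr <- simulateTraits(loc$dosExp, loc$dosOut, arch, seed = 791)
  ss <- marginalSumstats(loc$dosExp, tr$yExp, loc$variants, "g")
  fit <- susieRss(ss, loc$ld, fineMapConfig(L = 5L))
  all <- extractCredibleSets(fit)
  expect_gte(length(all), 2L)
  first <- extractCredibleSets(fit, firstOnly = TRUE)
  expect_length(first, 1L)
  expect_equal(first[[1]]$csIndex, 1L)
  # sets are ranked by decreasing max single-effect lbf
  maxes <- vapply(all, `[[`, numeric(1), "maxLbf")
  expect_true(all(diff(maxes) <= 1e-9))
})

test_that("lead-variant ties break by lower position", {
  # two variants in perfect LD carry identical z; lower position must win
  v <- data.frame(id = c("b", "a"), chrom = "chr1", pos = c(200, 100),
                  ref = "A", alt = "G", stringsAsFactors = FALSE)
  ss <- regionStats("g", v, beta = c(0.5, 0.5), se = c(0.1, 0.1),
                    maf = c(0.3, 0.3), n = 100L)
  R <- matrix(c(1, 1, 1, 1), 2, 2)
  fit <- susieRss(ss, R, fineMapConfig(L = 1L))
  cs <- extractCredibleSets(fit)
  expect_length(cs, 1L)
  expect_equal(cs[[1]]$leadVariant, "a")
})

test_that("removing the fitted effects leaves no residual credible sets", {
  p <- simPair(seed = 797, m = 50L, nExp = 800L, nOut = 100L, veExp = 0.15)
  cfg <- fineMapConfig(L = 5L)
  fit <- susieRss(p$exp, p$loc$ld, cfg)
  expect_gte(length(extractCredibleSets(fit)), 1L)
  # subtract the fitted single-effect contributions from z and refit:
  # the residual carries no further signal
  b <- colSums(signalAlpha(fit) * signalMu(fit))
  zRes <- as.numeric(zScores(p$exp)) - as.numeric(p$loc$ld %*% b)
  resid <- p$exp
  resid@beta <- zRes * p$exp@se
  fit2 <- susieRss(resid, p$loc$ld, cfg)
  expect_length(extractCredibleSets(fit2), 0L)
})

test_that("residual-variance estimation is a working config switch", {
  p <- simPair(seed = 798, m = 40L, nExp = 500L, nOut = 100L, veExp = 0.1,
               causalIdx = 20L)
  fit <- susieRss(p$exp, p$loc$ld,
                  fineMapConfig(L = 5L, estimateResidual = TRUE))
  cs <- extractCredibleSets(fit)
  expect_gte(length(cs), 1L)
  expect_true(p$causalId %in% cs[[1]]$variantIds)
  # under the null the estimated residual variance changes nothing
  pNull <- simPair(seed = 799, m = 40L, nExp = 500L, nOut = 100L,
                   veExp = 0, veOut = 0, causalIdx = 20L)
  fitN <- susieRss(pNull$exp, pNull$loc$ld,
                   fineMapConfig(L = 5L, estimateResidual = TRUE))
  expect_length(extractCredibleSets(fitN), 0L)
})

test_that("an asymmetric or non-unit-diagonal LD matrix is rejected", {
  p <- simPair(seed = 795, m = 20L, nExp = 100L, nOut = 100L,
               causalIdx = 10L)
  badR <- p$loc$ld
  badR[1, 2] <- badR[1, 2] + 0.5
  expect_error(susieRss(p$exp, badR, fineMapConfig()), "symmetric")
  badD <- p$loc$ld
  diag(badD) <- 2
  expect_error(susieRss(p$exp, badD, fineMapConfig()), "diagonal")
})
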