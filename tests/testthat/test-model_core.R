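cst <- modelConstants()   # d = -8.67, nu = log2(100)

test_that("expression probabilities follow the inverse logit", {
  expect_equal(expressionProb(0), 0.5)
  expect_equal(expressionProb(2.94), 0.95, tolerance = 1e-3)
  expect_equal(expressionProb(1.3, 0), expressionProb(1.3))
  # saturates smoothly, no overflow
  expect_equal(expressionProb(800), 1)
  expect_gt(expressionProb(-800), 0 - 1e-300)
})

test_that("truncation mass matches quadrature and its limits", {
  expect_equal(truncnormMass(0, 1, -Inf, Inf), 1)
  # symmetric window around the mean
  expect_equal(truncnormMass(0, 2, -3, 3), pnorm(1.5) - pnorm(-1.5))
  # quadrature oracle on the working window
  m <- truncnormMass(-5, 0.7, cst@d, cst@nu)
  expect_equal(m, quadTruncMass(-5, 0.7, cst@d, cst@nu), tolerance = 1e-8)
  # far-out mean floors instead of hitting zero
  expect_gt(truncnormMass(500, 0.1, cst@d, cst@nu), 0)
  expect_true(is.finite(truncnormMass(500, 0.1, cst@d, cst@nu, log = TRUE)))
})

test_that("single-observation log likelihood covers both branches", {
  # rho = 0 and missing: mixture collapses to certain non-expression
  expect_equal(spotObsLogLik(NA, -5, 0.7, 0, cst), 0)
  # rho = 1, full support, peak of a normal with sd 1/sqrt(2*pi) is 1
  free <- modelConstants(d = -1e6, nu = log2(100))
  expect_equal(spotObsLogLik(-3, -3, 1 / sqrt(2 * pi), 1, free), 0,
               tolerance = 1e-9)
  # observed branch equals the composite with the quadrature-oracle mass
  lam <- quadTruncMass(-5, 0.7, cst@d, cst@nu)
  expect_equal(spotObsLogLik(-5, -5, 0.7, 0.8, cst),
               log(0.8) + log(dnorm(0) / (0.7 * lam)), tolerance = 1e-8)
  # censored branch
  expect_equal(spotObsLogLik(NA, -5, 0.7, 0.8, cst),
               log(0.2 + 0.8 * pnorm((cst@d + 5) / 0.7)))
  # a value above nu violates the data invariant
  expect_error(spotObsLogLik(7, -5, 0.7, 0.8, cst), "nu")
})

test_that("observed branch integrates to rho; total mass is 1 + rho*Phi", {
  for (par in list(c(-5, 0.7, 0.8), c(-8, 1.5, 0.3), c(-6, 0.4, 0.99))) {
    mu <- par[1]; sig <- par[2]; rho <- par[3]
    obsMass <- integrate(function(c)
      exp(spotObsLogLik(c, mu, sig, rho, cst)), cst@d, cst@nu,
      rel.tol = 1e-10)$value
    expect_equal(obsMass, rho, tolerance = 1e-7)
    missMass <- exp(spotObsLogLik(NA, mu, sig, rho, cst))
    # the below-detection expressed mass appears in both branches, exactly
    expect_equal(obsMass + missMass,
                 1 + rho * pnorm((cst@d - mu) / sig), tolerance = 1e-7)
  }
  # far above detection the total is 1 to numerical precision
  expect_equal(
    integrate(function(c) exp(spotObsLogLik(c, -3, 0.5, 0.7, cst)),
              cst@d, cst@nu, rel.tol = 1e-10)$value +
      exp(spotObsLogLik(NA, -3, 0.5, 0.7, cst)),
    1, tolerance = 1e-7)
})

test_that("spot likelihood sums per-gel terms with the right group params", {
  v <- c(-5.1, NA, -4.2, -4.6)
  gr <- c("control", "control", "case", "case")
  mu <- -5; delta <- 0.6; kappa <- 1.2; tau <- -0.4; sig <- 0.7
  p0 <- expressionProb(kappa); p1 <- expressionProb(kappa, tau)
  byTerm <- spotObsLogLik(v[1], mu, sig, p0, cst) +
    spotObsLogLik(NA, mu, sig, p0, cst) +
    spotObsLogLik(v[3], mu + delta, sig, p1, cst) +
    spotObsLogLik(v[4], mu + delta, sig, p1, cst)
  expect_equal(spotLogLik(v, gr, mu, delta, kappa, tau, sig, cst), byTerm)

  # delta = tau = 0: swapping group labels leaves the likelihood unchanged
  gr2 <- c("case", "case", "control", "control")
  expect_equal(spotLogLik(v, gr, mu, 0, kappa, 0, sig, cst),
               spotLogLik(v, gr2, mu, 0, kappa, 0, sig, cst))

  # nearly-zero expression probability and all-missing row: product of ones
  expect_equal(spotLogLik(rep(NA_real_, 4), gr, mu, delta, -40, 0, sig, cst),
               0, tolerance = 1e-12)
})

test_that("asymmetric Laplace density behaves and normalizes", {
  expect_equal(exp(modLaplaceLogPdf(0, 1, 0.5)), 0.5)
  expect_equal(modLaplaceLogPdf(-0.1, 2, 1), -Inf)
  expect_equal(modLaplaceLogPdf(0.1, 2, 0), -Inf)
  tot <- integrate(function(x) exp(modLaplaceLogPdf(x, 0.66, 0.3)),
                   -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(tot, 1, tolerance = 1e-7)
  # the two tails carry phi and 1 - phi
  up <- integrate(function(x) exp(modLaplaceLogPdf(x, 0.66, 0.3)),
                  0, Inf, rel.tol = 1e-10)$value
  expect_equal(up, 0.3, tolerance = 1e-7)
})

test_that("global layer and prior match component-wise oracles", {
  loc <- toyLocals(); gl <- toyGlobals()
  byComp <- sum(dnorm(loc@mu, gl@muG, gl@sigmaG, log = TRUE)) +
    sum(ifelse(loc@delta < 0,
               log(1 - gl@phiDelta) + log(gl@lambdaDelta) +
                 gl@lambdaDelta * loc@delta,
               log(gl@phiDelta) + log(gl@lambdaDelta) -
                 gl@lambdaDelta * loc@delta)) +
    sum(dnorm(loc@kappa, gl@muKappa, gl@sigmaKappa, log = TRUE)) +
    sum(dnorm(loc@tau, gl@muTau, gl@sigmaTau, log = TRUE))
  expect_equal(globalLayerLogLik(loc, gl), byComp, tolerance = 1e-12)

  # symmetry of the kappa term around mu_kappa
  locA <- localParams(loc@mu, loc@delta, rep(gl@muKappa + 0.7, 5), loc@tau)
  locB <- localParams(loc@mu, loc@delta, rep(gl@muKappa - 0.7, 5), loc@tau)
  expect_equal(globalLayerLogLik(locA, gl), globalLayerLogLik(locB, gl))

  # prior: support boundaries and the component-wise oracle
  asList <- function(g, ...) {
    out <- setNames(lapply(slotNames(g), function(s) slot(g, s)),
                    slotNames(g))
    mod <- list(...)
    out[names(mod)] <- mod
    out
  }
  expect_equal(globalLogPrior(asList(gl, psi = 2.5)), -Inf)
  expect_equal(globalLogPrior(asList(gl, phiDelta = 0)), -Inf)
  expect_equal(globalLogPrior(asList(gl, phiDelta = 1)), -Inf)
  ig <- function(v) 0.001 * log(0.001) - lgamma(0.001) - 1.001 * log(v) -
    0.001 / v
  oracle <- dnorm(gl@muG, -3, 5, log = TRUE) +
    ig(gl@sigmaG^2) + log(2 * gl@sigmaG) - log(1.999) +
    dexp(gl@lambdaDelta, 1, log = TRUE) +
    dbeta(gl@phiDelta, 2, 2, log = TRUE) +
    dnorm(gl@muKappa, 0, 3, log = TRUE) +
    ig(gl@sigmaKappa^2) + log(2 * gl@sigmaKappa) +
    dnorm(gl@muTau, 0, 3, log = TRUE) +
    ig(gl@sigmaTau^2) + log(2 * gl@sigmaTau)
  expect_equal(globalLogPrior(gl), oracle, tolerance = 1e-12)
})

test_that("every prior component integrates to one", {
  sdPrior <- function(s) exp(0.001 * log(0.001) - lgamma(0.001) -
    1.001 * log(s^2) - 0.001 / s^2) * 2 * s
  # the inverse-gamma(0.001, 0.001) in sd coordinates is heavy-tailed;
  # integrate the variance-scale density, which is the defining form
  igVar <- function(v) exp(0.001 * log(0.001) - lgamma(0.001) -
    1.001 * log(v) - 0.001 / v)
  expect_equal(integrate(function(x) dnorm(x, -3, 5), -Inf, Inf)$value, 1,
               tolerance = 1e-6)
  # quadrature on this very heavy-tailed density is only good to ~1e-3
  expect_equal(integrate(igVar, 0, Inf, rel.tol = 1e-10)$value, 1,
               tolerance = 2e-3)
  # and the sd-scale version agrees with the variance-scale one on a window
  expect_equal(integrate(sdPrior, 0.05, 50, rel.tol = 1e-10)$value,
               integrate(igVar, 0.05^2, 2500, rel.tol = 1e-10)$value,
               tolerance = 1e-8)
  expect_equal(integrate(function(x) dbeta(x, 2, 2), 0, 1)$value, 1,
               tolerance = 1e-8)
  expect_equal(integrate(function(x) dexp(x, 1), 0, Inf)$value, 1,
               tolerance = 1e-8)
  expect_equal(integrate(function(x) dunif(x, 0.001, 2), 0.001, 2)$value, 1,
               tolerance = 1e-6)
})

test_that("joint posterior is deterministic and shift-structured", {
  gm <- toyGelMatrix(); loc <- toyLocals(); gl <- toyGlobals()
  a <- jointLogPosterior(gm, loc, gl, cst)
  b <- jointLogPosterior(gm, loc, gl, cst)
  expect_identical(a, b)
  expect_true(is.finite(a))

  # shifting data, spot means and the global mean together changes only the
  # constants-window terms and the mu_g prior, by a computable amount
  free <- modelConstants(d = -1e5, nu = 1e5)
  shift <- 0.8
  gmS <- gelMatrix(intensityMatrix(gm) + shift, gelGroups(gm))
  locS <- localParams(loc@mu + shift, loc@delta, loc@kappa, loc@tau)
  glS <- globalParams(gl@muG + shift, gl@sigmaG, gl@psi, gl@lambdaDelta,
                      gl@phiDelta, gl@muKappa, gl@sigmaKappa, gl@muTau,
                      gl@sigmaTau)
  dPrior <- dnorm(gl@muG + shift, -3, 5, log = TRUE) -
    dnorm(gl@muG, -3, 5, log = TRUE)
  expect_equal(jointLogPosterior(gmS, locS, glS, free),
               jointLogPosterior(gm, loc, gl, free) + dPrior,
               tolerance = 1e-9)
})

test_that("joint posterior matches the scalar reference to 1e-10", {
  gm <- toyGelMatrix(); loc <- toyLocals(); gl <- toyGlobals()
  ref <- refJointLogPosterior(
    intensityMatrix(gm), as.character(gelGroups(gm)),
    loc@mu, loc@delta, loc@kappa, loc@tau,
    list(muG = gl@muG, sigmaG = gl@sigmaG, psi = gl@psi,
         lambdaDelta = gl@lambdaDelta, phiDelta = gl@phiDelta,
         muKappa = gl@muKappa, sigmaKappa = gl@sigmaKappa,
         muTau = gl@muTau, sigmaTau = gl@sigmaTau),
    cst@d, cst@nu)
  expect_equal(jointLogPosterior(gm, loc, gl, cst), ref, tolerance = 1e-10)
})
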