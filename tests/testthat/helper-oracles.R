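# Independent reference implementations used as oracles.  These are written
# as naive scalar loops / quadrature, deliberately sharing no code with the
# package internals.

# normal mass on [d, nu] by adaptive quadrature
quadTruncMass <- function(mu, sigma, d, nu) {
  integrate(function(y) dnorm(y, mu, sigma), d, nu,
            rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# one observation's likelihood, scalar, following the two-branch mixture
refObsLik <- function(c, mu, sigma, rho, d, nu) {
  if (is.na(c) || c < d) {
    (1 - rho) + rho * pnorm((d - mu) / sigma)
  } else {
    lam <- pnorm((nu - mu) / sigma) - pnorm((d - mu) / sigma)
    rho * dnorm((c - mu) / sigma) / (sigma * lam)
  }
}

# full joint log posterior, scalar loops throughout
refJointLogPosterior <- function(values, groups, mu, delta, kappa, tau,
                                 gl, d, nu) {
  sigS <- gl$psi * gl$sigmaG
  ll <- 0
  for (s in seq_len(nrow(values))) {
    p0 <- exp(kappa[s]) / (1 + exp(kappa[s]))
    p1 <- exp(kappa[s] + tau[s]) / (1 + exp(kappa[s] + tau[s]))
    for (g in seq_len(ncol(values))) {
      if (groups[g] == "control")
        ll <- ll + log(refObsLik(values[s, g], mu[s], sigS, p0, d, nu))
      else
        ll <- ll + log(refObsLik(values[s, g], mu[s] + delta[s], sigS, p1,
                                 d, nu))
    }
  }
  gll <- 0
  for (s in seq_len(nrow(values))) {
    gll <- gll + dnorm(mu[s], gl$muG, gl$sigmaG, log = TRUE)
    gll <- gll + if (delta[s] < 0)
      log(1 - gl$phiDelta) + log(gl$lambdaDelta) + gl$lambdaDelta * delta[s]
    else
      log(gl$phiDelta) + log(gl$lambdaDelta) - gl$lambdaDelta * delta[s]
    gll <- gll + dnorm(kappa[s], gl$muKappa, gl$sigmaKappa, log = TRUE)
    gll <- gll + dnorm(tau[s], gl$muTau, gl$sigmaTau, log = TRUE)
  }
  igLog <- function(v) 0.001 * log(0.001) - lgamma(0.001) -
    1.001 * log(v) - 0.001 / v
  pr <- dnorm(gl$muG, -3, 5, log = TRUE) +
    igLog(gl$sigmaG^2) + log(2 * gl$sigmaG) +
    dunif(gl$psi, 0.001, 2, log = TRUE) +
    dexp(gl$lambdaDelta, 1, log = TRUE) +
    dbeta(gl$phiDelta, 2, 2, log = TRUE) +
    dnorm(gl$muKappa, 0, 3, log = TRUE) +
    igLog(gl$sigmaKappa^2) + log(2 * gl$sigmaKappa) +
    dnorm(gl$muTau, 0, 3, log = TRUE) +
    igLog(gl$sigmaTau^2) + log(2 * gl$sigmaTau)
  ll + gll + pr
}

# exhaustive shortest-window HPD scan
bruteHpd <- function(x, mass = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1L)) {
    lo <- x[i]; hi <- x[i + m - 1L]
    if (hi - lo < best[2] - best[1]) best <- c(lo, hi)
  }
  best
}

# a small deterministic 5-spot x 4-gel fixture with missing cells
toyGelMatrix <- function() {
  v <- matrix(c(
    -5.0, -4.6,   NA, -4.1,
    -6.2,   NA, -6.8, -7.0,
      NA,   NA, -3.2, -3.0,
    -4.9, -5.1, -5.0, -5.2,
    -8.0, -7.5,   NA,   NA), nrow = 5, byrow = TRUE)
  gelMatrix(v, groups = c("control", "control", "case", "case"))
}

toyLocals <- function() {
  localParams(mu = c(-5, -6.5, -3.5, -5, -7.6),
              delta = c(0.4, -0.3, 0.2, -0.1, 0.5),
              kappa = c(1, 0.5, -0.2, 2, 0.3),
              tau = c(0.2, -0.5, 1.2, 0, -0.8))
}

toyGlobals <- function() {
  globalParams(muG = -5.2, sigmaG = 1.1, psi = 0.65, lambdaDelta = 0.6,
               phiDelta = 0.55, muKappa = 0.9, sigmaKappa = 1.05,
               muTau = -0.1, sigmaTau = 1.9)
}

# extract a LocalParams/GlobalParams pair from one trace row
stateFromTraceRow <- function(trace, i) {
  sm <- traceSamples(trace)
  ids <- traceSpotIds(trace)
  row <- sm[i, ]
  list(
    local = localParams(mu = unname(row[paste0("mu.", ids)]),
                        delta = unname(row[paste0("delta.", ids)]),
                        kappa = unname(row[paste0("kappa.", ids)]),
                        tau = unname(row[paste0("tau.", ids)])),
    global = globalParams(row[["mu_g"]], row[["sigma_g"]], row[["psi"]],
                          row[["lambda_delta"]], row[["phi_delta"]],
                          row[["mu_kappa"]], row[["sigma_kappa"]],
                          row[["mu_tau"]], row[["sigma_tau"]]),
    logpost = row[["logpost"]])
}

# assemble a ChainTrace by hand from per-spot delta/tau samples
makeTrace <- function(deltaList, tauList, nGlobalsVal = 1) {
  n <- length(deltaList[[1L]])
  ids <- names(deltaList)
  globals <- matrix(nGlobalsVal, n, 12,
                    dimnames = list(NULL, c("mu_g", "sigma_g", "psi",
                      "lambda_delta", "phi_delta", "mu_kappa", "sigma_kappa",
                      "mu_tau", "sigma_tau", "alpha_mu", "alpha_kappa",
                      "alpha_tau")))
  loc <- cbind(
    matrix(0, n, length(ids), dimnames = list(NULL, paste0("mu.", ids))),
    do.call(cbind, setNames(deltaList, paste0("delta.", ids))),
    matrix(0, n, length(ids), dimnames = list(NULL, paste0("kappa.", ids))),
    do.call(cbind, setNames(tauList, paste0("tau.", ids))))
  sm <- cbind(globals, loc, logpost = rep(0, n))
  rownames(sm) <- seq_len(n)
  new("ChainTrace", samples = sm, thin = 1L, burninFrac = 0,
      iterations = as.integer(n), seed = 0L, spotIds = ids,
      acceptance = numeric(0), proposalSd = numeric(0))
}
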