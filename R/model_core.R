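# Log-space density layer of the two-level model.  The spot likelihood is a
# left-censored mixture: a missing cell is either a non-expressed protein
# (probability 1 - rho) or an expressed one censored below the limit of
# detection d; an observed cell follows a normal truncated to [d, nu].

.LOG_FLOOR <- -1e308   # stands in for -Inf only at the MH comparison point

#' Expression probability from logit-scale propensities
#'
#' \eqn{p_0 = \mathrm{logit}^{-1}(\kappa)} for the control group and
#' \eqn{p_1 = \mathrm{logit}^{-1}(\kappa + \tau)} for the case group.
#'
#' @param kappa logit-scale control propensity (vectorized).
#' @param tau optional logit-scale case-minus-control difference; 0 if omitted.
#' @return Probabilities in (0, 1); numerically stable for large |kappa|.
#' @examples
#' expressionProb(0)        # 0.5
#' expressionProb(2.94)     # ~0.95
#' @export
expressionProb <- function(kappa, tau = 0) plogis(kappa + tau)

#' Probability mass of a normal on the detection window [d, nu]
#'
#' The scaling factor \eqn{\lambda = \Phi((\nu-\mu)/\sigma) -
#' \Phi((d-\mu)/\sigma)} that makes the truncated observed-intensity density
#' integrate to one.  Computed in the better tail to avoid cancellation; a
#' mass underflowing to zero is floored at \code{1e-300} (the log-domain
#' floor) rather than allowed to reach an exact zero divisor.
#'
#' @param mu,sigma normal mean and sd (vectorized; \code{sigma > 0}).
#' @param d,nu window bounds, \code{d < nu} (may be infinite).
#' @param log return the log mass.
#' @return The mass (or log mass) in (0, 1].
#' @export
truncnormMass <- function(mu, sigma, d, nu, log = FALSE) {
  stopifnot(all(sigma > 0), d < nu)
  a <- (d - mu) / sigma
  b <- (nu - mu) / sigma
  m <- ifelse(a > 0,
    pnorm(a, lower.tail = FALSE) - pnorm(b, lower.tail = FALSE),
    pnorm(b) - pnorm(a))
  m <- pmax(m, 1e-300)
  if (log) base::log(m) else m
}

#' Log likelihood of one observation under the censored mixture
#'
#' Missing (or below-detection) cells contribute
#' \eqn{\log[(1-\rho) + \rho\,\Phi((d-\mu)/\sigma)]}; an observed intensity
#' \eqn{c \in [d, \nu]} contributes
#' \eqn{\log\rho + \log\phi((c-\mu)/\sigma) - \log\sigma - \log\lambda}
#' with \eqn{\lambda} from [truncnormMass()].  The censored-branch mass uses
#' the untruncated lower tail \eqn{\Phi((d-\mu)/\sigma)}, exactly as the
#' model defines it.
#'
#' @param c observed intensity or \code{NA} for missing (vectorized).
#' @param mu,sigma group mean and common spot sd.
#' @param rho expression probability for the observation's group.
#' @param constants a \linkS4class{ModelConstants}.
#' @return Log density/mass per observation.
#' @export
spotObsLogLik <- function(c, mu, sigma, rho, constants = modelConstants()) {
  d <- constants@d; nu <- constants@nu
  stopifnot(all(sigma > 0), all(rho >= 0 & rho <= 1))
  if (any(!is.na(c) & c > nu + 1e-9))
    stop("observed intensity above the maximum expression value nu")
  n <- max(length(c), length(mu), length(sigma), length(rho))
  c <- rep_len(c, n); mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n); rho <- rep_len(rho, n)
  out <- numeric(n)
  cens <- is.na(c) | c < d
  if (any(cens)) {
    pc <- pnorm((d - mu[cens]) / sigma[cens])
    out[cens] <- log((1 - rho[cens]) + rho[cens] * pc)
  }
  if (any(!cens)) {
    i <- !cens
    out[i] <- log(rho[i]) +
      dnorm(c[i], mu[i], sigma[i], log = TRUE) -
      truncnormMass(mu[i], sigma[i], d, nu, log = TRUE)
  }
  out
}

#' Local-layer log likelihood of one spot across all gels
#'
#' Control gels use \eqn{(\mu_s, p_0)}, case gels
#' \eqn{(\mu_s + \delta_s, p_1)}.
#'
#' @param values numeric vector of intensities for one spot (NA = missing).
#' @param groups group factor/character aligned with \code{values}.
#' @param mu,delta,kappa,tau the spot's local parameters.
#' @param sigmaS common spot sd (\eqn{\psi\sigma_g} under the global model).
#' @param constants a \linkS4class{ModelConstants}.
#' @return The spot's log likelihood (a scalar).
#' @export
spotLogLik <- function(values, groups, mu, delta, kappa, tau, sigmaS,
                       constants = modelConstants()) {
  groups <- as.character(groups)
  stopifnot(all(groups %in% c("control", "case")))
  ctrl <- groups == "control"
  p0 <- expressionProb(kappa)
  p1 <- expressionProb(kappa, tau)
  sum(spotObsLogLik(values[ctrl], mu, sigmaS, p0, constants)) +
    sum(spotObsLogLik(values[!ctrl], mu + delta, sigmaS, p1, constants))
}

#' Asymmetric (weighted) Laplace log density for intensity differences
#'
#' Two exponential tails with rate \eqn{\lambda_\delta} glued at zero, the
#' positive side carrying weight \eqn{\phi_\delta} (the proportion of
#' up-regulated proteins) and the negative side \eqn{1-\phi_\delta}.
#'
#' @param delta case-minus-control mean difference (vectorized).
#' @param lambdaDelta rate, > 0.
#' @param phiDelta up-regulated proportion in [0, 1]; a boundary value puts
#'   zero mass on one side (log density \code{-Inf} there).
#' @return Log density.
#' @examples
#' exp(modLaplaceLogPdf(0, 1, 0.5))  # 0.5 = lambda/2 at the peak
#' @export
modLaplaceLogPdf <- function(delta, lambdaDelta, phiDelta) {
  stopifnot(lambdaDelta > 0, phiDelta >= 0, phiDelta <= 1)
  ifelse(delta < 0,
    log(1 - phiDelta) + log(lambdaDelta) + lambdaDelta * delta,
    log(phiDelta) + log(lambdaDelta) - lambdaDelta * delta)
}

#' Global-layer log likelihood of the local parameters
#'
#' Sums, over spots, the normal law of the spot means, the asymmetric
#' Laplace law of the intensity differences, and the normal laws of the
#' expression-propensity parameters.
#'
#' @param local a \linkS4class{LocalParams}.
#' @param global a \linkS4class{GlobalParams}.
#' @return Scalar log likelihood.
#' @export
globalLayerLogLik <- function(local, global) {
  sum(dnorm(local@mu, global@muG, global@sigmaG, log = TRUE)) +
    sum(modLaplaceLogPdf(local@delta, global@lambdaDelta, global@phiDelta)) +
    sum(dnorm(local@kappa, global@muKappa, global@sigmaKappa, log = TRUE)) +
    sum(dnorm(local@tau, global@muTau, global@sigmaTau, log = TRUE))
}

# inverse-gamma log density
.invGammaLogPdf <- function(x, shape, rate) {
  ifelse(x > 0,
    shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x,
    -Inf)
}

#' Log prior density of the global parameters
#'
#' Normal(-3, 5) on \eqn{\mu_g}; inverse-gamma(0.001, 0.001) on the
#' variances \eqn{\sigma_g^2, \sigma_\kappa^2, \sigma_\tau^2} (evaluated as
#' densities in the standard deviations, i.e. including the
#' \eqn{2\sigma} change-of-variables factor); Uniform(0.001, 2) on
#' \eqn{\psi}; Exponential(1) on \eqn{\lambda_\delta}; Beta(2, 2) on
#' \eqn{\phi_\delta}; Normal(0, 3) on \eqn{\mu_\kappa} and \eqn{\mu_\tau}.
#' Returns \code{-Inf} outside any support.
#'
#' @param global a \linkS4class{GlobalParams}, or a named list with the same
#'   elements (to allow out-of-support values to be scored).
#' @return Scalar log prior density.
#' @export
globalLogPrior <- function(global) {
  g <- if (is(global, "GlobalParams"))
    setNames(lapply(slotNames(global), function(s) slot(global, s)),
             slotNames(global))
  else global
  sdPrior <- function(s) {
    if (!is.finite(s) || s <= 0) return(-Inf)
    .invGammaLogPdf(s^2, 0.001, 0.001) + log(2 * s)
  }
  dnorm(g$muG, -3, 5, log = TRUE) +
    sdPrior(g$sigmaG) +
    dunif(g$psi, 0.001, 2, log = TRUE) +
    dexp(g$lambdaDelta, 1, log = TRUE) +
    dbeta(g$phiDelta, 2, 2, log = TRUE) +
    dnorm(g$muKappa, 0, 3, log = TRUE) +
    sdPrior(g$sigmaKappa) +
    dnorm(g$muTau, 0, 3, log = TRUE) +
    sdPrior(g$sigmaTau)
}

#' Unnormalized joint log posterior
#'
#' Local-layer likelihood over all spots (with
#' \eqn{\sigma_s = \psi\sigma_g}) plus the global-layer likelihood of the
#' local parameters plus the global prior.
#'
#' @param x a \linkS4class{GelMatrix}.
#' @param local a \linkS4class{LocalParams} with one entry per spot of \code{x}.
#' @param global a \linkS4class{GlobalParams}.
#' @param constants a \linkS4class{ModelConstants}.
#' @return Scalar unnormalized log posterior; \code{-Inf} out of support.
#' @export
jointLogPosterior <- function(x, local, global,
                              constants = modelConstants()) {
  stopifnot(is(x, "GelMatrix"), is(local, "LocalParams"),
            is(global, "GlobalParams"))
  v <- intensityMatrix(x)
  if (nrow(v) != length(local@mu))
    stop("local parameters must have one entry per spot")
  groups <- gelGroups(x)
  sigmaS <- global@psi * global@sigmaG
  ll <- 0
  for (s in seq_len(nrow(v)))
    ll <- ll + spotLogLik(v[s, ], groups, local@mu[s], local@delta[s],
                          local@kappa[s], local@tau[s], sigmaS, constants)
  ll + globalLayerLogLik(local, global) + globalLogPrior(global)
}
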