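#' @import methods
#' @importFrom stats dnorm pnorm qnorm dbeta dexp dunif runif rnorm sd var
#'   plogis qlogis optim pchisq acf density integrate setNames
#' @importFrom utils read.delim write.table
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @useDynLib BayesPAGE, .registration = TRUE
NULL

#' Model constants: limit of detection and maximum expression value
#'
#' Intensities are log2 relative percentage volumes, so a spot can never
#' exceed \eqn{\nu = \log_2(100) \approx 6.64} (a spot cannot carry more than
#' 100\% of a gel's volume).  Observations below the limit of detection
#' \eqn{d} are indistinguishable from non-expression and are recorded as
#' missing.
#'
#' @slot d numeric(1), limit of detection on the log2 percent-volume scale.
#' @slot nu numeric(1), maximum expression value, default \code{log2(100)}.
#' @exportClass ModelConstants
setClass("ModelConstants",
  representation(d = "numeric", nu = "numeric"),
  prototype(d = -8.67, nu = log2(100))
)

setValidity("ModelConstants", function(object) {
  if (length(object@d) != 1L || length(object@nu) != 1L)
    return("d and nu must be scalars")
  if (!is.finite(object@d) || !is.finite(object@nu))
    return("d and nu must be finite")
  if (object@d >= object@nu)
    return("the limit of detection d must be below the maximum value nu")
  TRUE
})

#' @rdname ModelConstants-class
#' @param d limit of detection (log2 percent volume).
#' @param nu maximum expression value (log2 percent volume).
#' @return A \code{ModelConstants} object.
#' @examples
#' modelConstants()             # d = -8.67, nu = log2(100)
#' modelConstants(d = -10)
#' @export
modelConstants <- function(d = -8.67, nu = log2(100)) {
  new("ModelConstants", d = d, nu = nu)
}

#' Spot-intensity matrix for a case-control 2D PAGE experiment
#'
#' A \code{GelMatrix} is a \linkS4class{SummarizedExperiment} holding one
#' assay \code{"exprs"}: spots (rows) by gels (columns) of log2 relative
#' percentage volumes, with \code{NA} marking missing spots (non-expressed,
#' unmatched, or censored below the limit of detection).  Each gel carries a
#' group label, \code{"control"} or \code{"case"}, in
#' \code{colData(x)$group}.
#'
#' @seealso [gelMatrix()], [readIntensityTable()], [toRelativeLog2()]
#' @exportClass GelMatrix
setClass("GelMatrix", contains = "SummarizedExperiment")

setValidity("GelMatrix", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!("exprs" %in% a))
    return("GelMatrix must contain an assay named 'exprs'")
  v <- SummarizedExperiment::assay(object, "exprs")
  if (!is.numeric(v))
    return("assay 'exprs' must be numeric")
  if (any(v > log2(100) + 1e-9, na.rm = TRUE))
    return("relative percentage volumes cannot exceed log2(100) on the log2 scale")
  cd <- SummarizedExperiment::colData(object)
  if (!("group" %in% colnames(cd)))
    return("colData must contain a 'group' column")
  g <- as.character(cd$group)
  if (!all(g %in% c("control", "case")))
    return("group labels must be 'control' or 'case'")
  if (!all(c("control", "case") %in% g))
    return("need at least one control gel and one case gel")
  if (anyDuplicated(rownames(object)))
    return("duplicate spot ids")
  if (anyDuplicated(colnames(object)))
    return("duplicate gel ids")
  TRUE
})

#' Global-layer parameters of the hierarchical model
#'
#' The nine parameters tying the per-spot (local) parameters together:
#' spot means \eqn{\mu_s \sim N(\mu_g, \sigma_g)}; a common spot standard
#' deviation \eqn{\sigma_s = \psi\,\sigma_g}; case-control intensity
#' differences \eqn{\delta_s} following an asymmetric (weighted) Laplace law
#' with rate \eqn{\lambda_\delta} and up-regulated proportion
#' \eqn{\phi_\delta}; logit-scale expression propensities
#' \eqn{\kappa_s \sim N(\mu_\kappa, \sigma_\kappa)} and their case-control
#' differences \eqn{\tau_s \sim N(\mu_\tau, \sigma_\tau)}.
#'
#' @slot muG,sigmaG mean and sd of the spot means.
#' @slot psi spot-sd scalar in \eqn{[0.001, 2]}.
#' @slot lambdaDelta,phiDelta asymmetric Laplace rate (> 0) and up-weight in (0,1).
#' @slot muKappa,sigmaKappa mean/sd of \eqn{\kappa_s}.
#' @slot muTau,sigmaTau mean/sd of \eqn{\tau_s}.
#' @exportClass GlobalParams
setClass("GlobalParams",
  representation(
    muG = "numeric", sigmaG = "numeric", psi = "numeric",
    lambdaDelta = "numeric", phiDelta = "numeric",
    muKappa = "numeric", sigmaKappa = "numeric",
    muTau = "numeric", sigmaTau = "numeric"
  )
)

setValidity("GlobalParams", function(object) {
  sc <- vapply(slotNames(object), function(s) length(slot(object, s)) == 1L,
    logical(1))
  if (!all(sc)) return("all slots must be scalars")
  if (!all(vapply(slotNames(object), function(s) is.finite(slot(object, s)),
    logical(1)))) return("all parameters must be finite")
  if (object@sigmaG <= 0) return("sigmaG must be > 0")
  if (object@psi < 0.001 || object@psi > 2) return("psi must lie in [0.001, 2]")
  if (object@lambdaDelta <= 0) return("lambdaDelta must be > 0")
  if (object@phiDelta <= 0 || object@phiDelta >= 1)
    return("phiDelta must lie in (0, 1)")
  if (object@sigmaKappa <= 0) return("sigmaKappa must be > 0")
  if (object@sigmaTau <= 0) return("sigmaTau must be > 0")
  TRUE
})

#' @rdname GlobalParams-class
#' @param muG,sigmaG,psi,lambdaDelta,phiDelta,muKappa,sigmaKappa,muTau,sigmaTau
#'   see the class slots.
#' @return A validated \code{GlobalParams} object.
#' @export
globalParams <- function(muG, sigmaG, psi, lambdaDelta, phiDelta,
                         muKappa, sigmaKappa, muTau, sigmaTau) {
  new("GlobalParams",
    muG = muG, sigmaG = sigmaG, psi = psi,
    lambdaDelta = lambdaDelta, phiDelta = phiDelta,
    muKappa = muKappa, sigmaKappa = sigmaKappa,
    muTau = muTau, sigmaTau = sigmaTau)
}

#' Local-layer parameters: one quadruple per spot
#'
#' @slot mu control-group mean intensities \eqn{\mu_s}.
#' @slot delta case-minus-control mean differences \eqn{\delta_s}.
#' @slot kappa logit-scale control expression propensities \eqn{\kappa_s}.
#' @slot tau logit-scale case-minus-control propensity differences \eqn{\tau_s}.
#' @exportClass LocalParams
setClass("LocalParams",
  representation(mu = "numeric", delta = "numeric",
                 kappa = "numeric", tau = "numeric")
)

setValidity("LocalParams", function(object) {
  n <- length(object@mu)
  if (length(object@delta) != n || length(object@kappa) != n ||
      length(object@tau) != n)
    return("mu, delta, kappa, tau must have equal length")
  if (!all(is.finite(object@mu), is.finite(object@delta),
           is.finite(object@kappa), is.finite(object@tau)))
    return("all local parameters must be finite")
  TRUE
})

#' @rdname LocalParams-class
#' @param mu,delta,kappa,tau equal-length numeric vectors, one entry per spot.
#' @return A validated \code{LocalParams} object.
#' @export
localParams <- function(mu, delta, kappa, tau) {
  new("LocalParams", mu = mu, delta = delta, kappa = kappa, tau = tau)
}

#' Thinned post-burn-in MCMC trace
#'
#' Rows are recorded states (every \code{thin}-th iteration, after discarding
#' the burn-in fraction); columns are the nine global parameters on the
#' natural scale, the three expansion multipliers, the four local parameters
#' for every spot, and the unnormalized log posterior.  Row names are the
#' iteration ("state") indices.
#'
#' @slot samples numeric matrix of recorded states.
#' @slot thin thinning interval (iterations between recorded states).
#' @slot burninFrac fraction of iterations discarded as burn-in.
#' @slot iterations total chain length.
#' @slot seed RNG seed used for the run.
#' @slot spotIds spot identifiers, in matrix order.
#' @slot acceptance post-burn-in acceptance rate per update block.
#' @slot tunedAcceptance windowed acceptance rate per block at the moment
#'   adaptation froze (end of burn-in) — what the tuning rule directly
#'   controls.
#' @slot proposalSd final (frozen) proposal standard deviation per block.
#' @exportClass ChainTrace
setClass("ChainTrace",
  representation(
    samples = "matrix", thin = "integer", burninFrac = "numeric",
    iterations = "integer", seed = "integer", spotIds = "character",
    acceptance = "numeric", tunedAcceptance = "numeric",
    proposalSd = "numeric"
  )
)

setValidity("ChainTrace", function(object) {
  if (!is.numeric(object@samples)) return("samples must be numeric")
  if (is.null(colnames(object@samples))) return("samples must have column names")
  if (!("logpost" %in% colnames(object@samples)))
    return("samples must contain a 'logpost' column")
  lp <- object@samples[, "logpost"]
  if (nrow(object@samples) > 0L && !all(is.finite(lp)))
    return("log posterior must be finite in every stored row")
  TRUE
})

#' Simulation scenario for synthetic case-control gel data
#'
#' Distributional laws are lists with a \code{kind} element:
#' \code{list(kind = "normal", mean=, sd=)},
#' \code{list(kind = "uniform", min=, max=)},
#' \code{list(kind = "normalmix", mean = c(,), sd = c(,))} (assigned
#' half/half deterministically), \code{list(kind = "fixed", value=)}, or for
#' the intensity difference \code{list(kind = "modlaplace", lambda=, phi=)}.
#'
#' @slot S number of spots.
#' @slot nControl,nCase gels per group.
#' @slot muG,sigmaG law of the spot means.
#' @slot sigmaS common per-spot intensity sd.
#' @slot deltaLaw,kappaLaw,tauLaw laws for the per-spot effect parameters.
#' @slot d,nu detection limit and maximum value (log2 percent volume).
#' @slot name scenario label.
#' @exportClass SimulationScenario
setClass("SimulationScenario",
  representation(
    S = "integer", nControl = "integer", nCase = "integer",
    muG = "numeric", sigmaG = "numeric", sigmaS = "numeric",
    deltaLaw = "list", kappaLaw = "list", tauLaw = "list",
    d = "numeric", nu = "numeric", name = "character"
  )
)

setValidity("SimulationScenario", function(object) {
  if (object@S < 1L) return("S must be >= 1")
  if (object@nControl < 2L || object@nCase < 2L)
    return("need at least 2 gels per group")
  if (object@sigmaG <= 0 || object@sigmaS <= 0)
    return("scale parameters must be > 0")
  if (object@d >= object@nu) return("d must be < nu")
  for (lw in list(object@deltaLaw, object@kappaLaw, object@tauLaw))
    if (is.null(lw$kind)) return("each law needs a 'kind'")
  TRUE
})

#' Synthetic dataset with known truth
#'
#' @slot gelMatrix the simulated \linkS4class{GelMatrix}.
#' @slot truth data.frame with one row per spot: the true local parameters
#'   and a \code{true_de} flag (nonzero \eqn{\delta_s} or \eqn{\tau_s}).
#' @slot expressed logical spots-by-gels matrix: was the protein expressed.
#' @slot censored logical matrix: expressed but simulated below the limit of
#'   detection (hence missing).
#' @slot scenario the generating \linkS4class{SimulationScenario}.
#' @exportClass SimulatedDataset
setClass("SimulatedDataset",
  representation(
    gelMatrix = "GelMatrix", truth = "data.frame",
    expressed = "matrix", censored = "matrix",
    scenario = "SimulationScenario"
  )
)

setValidity("SimulatedDataset", function(object) {
  S <- nrow(object@gelMatrix)
  G <- ncol(object@gelMatrix)
  if (nrow(object@truth) != S) return("truth must have one row per spot")
  if (!identical(dim(object@expressed), c(S, G)) ||
      !identical(dim(object@censored), c(S, G)))
    return("indicator matrices must match the gel matrix dimensions")
  miss <- is.na(SummarizedExperiment::assay(object@gelMatrix, "exprs"))
  ok <- miss == (!object@expressed | object@censored)
  if (!all(ok))
    return("every missing cell must be explained by non-expression or censoring")
  if (any(object@censored & !object@expressed))
    return("a censored cell must be an expressed cell")
  TRUE
})
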