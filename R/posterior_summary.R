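# HPD intervals, ESS, the three-scenario DE classification, and
# global-parameter summaries.

#' Highest posterior density interval (contiguous, shortest-window)
#'
#' Among all windows of \code{ceiling(mass * n)} consecutive order
#' statistics, the shortest one; ties resolved towards the lowest lower
#' bound.  This is the exact contiguous HPD for unimodal marginals, which is
#' how the per-parameter posteriors behave here.
#'
#' @param samples numeric vector of at least 20 posterior draws.
#' @param mass interval mass, default 0.95.
#' @return \code{c(lower, upper)}.
#' @examples
#' hpdInterval(rnorm(1e4))  # about (-1.96, 1.96)
#' @export
hpdInterval <- function(samples, mass = 0.95) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 20L) stop("need at least 20 samples for an HPD interval")
  stopifnot(mass > 0, mass <= 1)
  x <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1L], x[n]))
  w <- x[(m):n] - x[seq_len(n - m + 1L)]
  i <- which.min(w)  # which.min takes the first (lowest lower bound) on ties
  c(x[i], x[i + m - 1L])
}

#' Effective sample size by initial positive-sequence truncation
#'
#' \eqn{n / (1 + 2\sum_k \hat\rho_k)} with empirical autocorrelations summed
#' until the first non-positive estimate, capped at \eqn{n}.  A
#' zero-variance (constant) chain is returned as ESS = n with a
#' \code{constant} attribute set.
#'
#' @param samples numeric vector of at least 10 draws.
#' @return Scalar ESS, with attribute \code{constant}.
#' @export
essChain <- function(samples) {
  n <- length(samples)
  if (n < 10L) stop("need at least 10 samples for an ESS estimate")
  if (var(samples) == 0) {
    return(structure(as.numeric(n), constant = TRUE))
  }
  rho <- acf(samples, lag.max = n - 2L, plot = FALSE,
             demean = TRUE)$acf[-1L]
  pos <- which(rho <= 0)
  if (length(pos) > 0L) rho <- rho[seq_len(pos[1L] - 1L)]
  ess <- n / (1 + 2 * sum(rho))
  structure(min(max(ess, 1), n), constant = FALSE)
}

.paramCols <- function(trace, prefix) {
  paste0(prefix, ".", trace@spotIds)
}

#' Classify spots as differentially expressed from a chain trace
#'
#' A spot is flagged under three scenarios: (1) the 95\% HPD of its
#' intensity difference \eqn{\delta_s} excludes zero
#' (\code{de_intensity}; its sign gives the direction), (2) the 95\% HPD of
#' its expression-propensity difference \eqn{\tau_s} excludes zero
#' (\code{de_probability}), or (3) both.  \code{de} is the union.
#'
#' @param trace a \linkS4class{ChainTrace} with post-burn-in samples.
#' @param mass HPD mass, default 0.95.
#' @return A data.frame with one row per spot: posterior means, HPD bounds,
#'   the three flags, and \code{direction} in \code{up/down/none}.
#' @export
classifySpots <- function(trace, mass = 0.95) {
  stopifnot(is(trace, "ChainTrace"))
  sm <- trace@samples
  ids <- trace@spotIds
  out <- lapply(seq_along(ids), function(i) {
    dcol <- sm[, paste0("delta.", ids[i])]
    tcol <- sm[, paste0("tau.", ids[i])]
    dh <- hpdInterval(dcol, mass)
    th <- hpdInterval(tcol, mass)
    deI <- dh[1L] > 0 || dh[2L] < 0
    deP <- th[1L] > 0 || th[2L] < 0
    data.frame(
      spot_id = ids[i],
      delta_mean = mean(dcol), delta_hpd_lo = dh[1L], delta_hpd_hi = dh[2L],
      tau_mean = mean(tcol), tau_hpd_lo = th[1L], tau_hpd_hi = th[2L],
      de_intensity = deI, de_probability = deP, de = deI || deP,
      direction = if (!deI) "none" else if (dh[1L] > 0) "up" else "down",
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.globalNames <- c("mu_g", "sigma_g", "psi", "lambda_delta", "phi_delta",
                  "mu_kappa", "sigma_kappa", "mu_tau", "sigma_tau")

#' Summarize the global parameters of a chain
#'
#' Posterior mean, 95\% HPD and ESS per global parameter, in the layout of
#' the usual recovered-parameter tables.
#'
#' @param trace a \linkS4class{ChainTrace}.
#' @param mass HPD mass.
#' @return data.frame with columns \code{parameter, mean, hpd_lo, hpd_hi,
#'   ess, constant}.
#' @export
summarizeGlobals <- function(trace, mass = 0.95) {
  stopifnot(is(trace, "ChainTrace"))
  sm <- trace@samples
  rows <- lapply(.globalNames, function(p) {
    x <- sm[, p]
    h <- hpdInterval(x, mass)
    e <- essChain(x)
    data.frame(parameter = p, mean = mean(x), hpd_lo = h[1L], hpd_hi = h[2L],
               ess = as.numeric(e), constant = isTRUE(attr(e, "constant")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# log prior density curve of one global parameter over a grid
.priorCurve <- function(param, grid) {
  switch(param,
    mu_g = dnorm(grid, -3, 5),
    sigma_g = ,
    sigma_kappa = ,
    sigma_tau = ifelse(grid > 0,
      exp(.invGammaLogPdf(grid^2, 0.001, 0.001)) * 2 * grid, 0),
    psi = dunif(grid, 0.001, 2),
    lambda_delta = dexp(grid, 1),
    phi_delta = dbeta(grid, 2, 2),
    mu_kappa = ,
    mu_tau = dnorm(grid, 0, 3),
    stop("unknown global parameter: ", param))
}

#' Export prior and posterior density curves for the global parameters
#'
#' For each global parameter, a kernel-density estimate of the marginal
#' posterior and the prior density evaluated over a shared grid — the
#' plot-ready table behind the usual posterior-vs-prior figures.
#'
#' @param trace a \linkS4class{ChainTrace}.
#' @param nGrid grid points per parameter.
#' @return data.frame with columns \code{parameter, grid, prior, posterior}.
#' @export
densityExport <- function(trace, nGrid = 256L) {
  stopifnot(is(trace, "ChainTrace"))
  sm <- trace@samples
  rows <- lapply(.globalNames, function(p) {
    x <- sm[, p]
    if (var(x) == 0) {
      grid <- seq(x[1L] - 1, x[1L] + 1, length.out = nGrid)
      post <- as.numeric(grid == x[1L])
    } else {
      kd <- density(x, n = nGrid)
      grid <- kd$x
      post <- kd$y
    }
    data.frame(parameter = p, grid = grid, prior = .priorCurve(p, grid),
               posterior = post, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Count differential-expression classifications
#'
#' Marginal counts of the three scenarios plus direction, and (optionally) a
#' Venn-style breakdown against a second method's significant spot set, e.g.
#' the LRT baseline.
#'
#' @param classification output of [classifySpots()].
#' @param otherSpots optional character vector of spot ids flagged by a
#'   second method.
#' @return A list with \code{total_de, by_intensity, by_probability, both,
#'   up, down} and, when \code{otherSpots} is given, \code{overlap,
#'   only_this, only_other}.
#' @export
countClassifications <- function(classification, otherSpots = NULL) {
  cl <- classification
  out <- list(
    total_de = sum(cl$de),
    by_intensity = sum(cl$de_intensity),
    by_probability = sum(cl$de_probability),
    both = sum(cl$de_intensity & cl$de_probability),
    up = sum(cl$direction == "up"),
    down = sum(cl$direction == "down"))
  if (!is.null(otherSpots)) {
    mine <- cl$spot_id[cl$de]
    out$overlap <- length(intersect(mine, otherSpots))
    out$only_this <- length(setdiff(mine, otherSpots))
    out$only_other <- length(setdiff(otherSpots, mine))
  }
  out
}
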