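# Univariate baseline: per-spot maximum likelihood under the same censored
# mixture, with a free per-spot sd (the key contrast with the global model's
# shared psi*sigma_g), and a 2-df likelihood ratio test of delta = tau = 0.

# per-group sufficient statistics of one spot row: with the common-sd normal
# the likelihood depends on the data only through counts, sums and sums of
# squares, making each optimizer evaluation O(1) in the number of gels
.spotStats <- function(values, groups, constants) {
  obs <- !is.na(values) & values >= constants@d
  st <- function(sel) {
    x <- values[sel & obs]
    c(n = length(x), sum = sum(x), ss = sum(x^2), miss = sum(sel & !obs))
  }
  list(ctrl = st(groups == "control"), case = st(groups == "case"))
}

.groupLL <- function(st, mu, sigma, rho, d, nu) {
  out <- 0
  if (st[["miss"]] > 0) {
    mass <- (1 - rho) + rho * pnorm((d - mu) / sigma)
    out <- st[["miss"]] * log(max(mass, 1e-300))
  }
  if (st[["n"]] > 0) {
    out <- out + st[["n"]] * (log(rho) - log(sigma) - 0.5 * log(2 * pi) -
        truncnormMass(mu, sigma, d, nu, log = TRUE)) -
      (st[["ss"]] - 2 * mu * st[["sum"]] + st[["n"]] * mu^2) / (2 * sigma^2)
  }
  out
}

.spotLLfast <- function(stats, mu, delta, kappa, tau, sigma, constants) {
  .groupLL(stats$ctrl, mu, sigma, expressionProb(kappa),
           constants@d, constants@nu) +
    .groupLL(stats$case, mu + delta, sigma, expressionProb(kappa, tau),
             constants@d, constants@nu)
}

.negLogLik <- function(par, stats, constants, null) {
  if (null) {
    mu <- par[1L]; kappa <- par[2L]; sigma <- exp(par[3L])
    delta <- 0; tau <- 0
  } else {
    mu <- par[1L]; delta <- par[2L]; kappa <- par[3L]; tau <- par[4L]
    sigma <- exp(par[5L])
  }
  ll <- .spotLLfast(stats, mu, delta, kappa, tau, sigma, constants)
  if (!is.finite(ll)) return(1e12)
  -ll
}

#' Maximum-likelihood fit of the censored mixture to a single spot
#'
#' Maximizes the spot likelihood over \eqn{(\mu_s, \delta_s, \kappa_s,
#' \tau_s, \sigma_s)} (full model) or with \eqn{\delta_s = \tau_s = 0}
#' constrained (null model).  \eqn{\kappa, \tau} are box-constrained to
#' \eqn{|\cdot| \le 10} — beyond that, expression probabilities are
#' indistinguishable from 0/1 and the likelihood surface is flat.
#' Optimization is multi-start (a moment-based start plus fixed
#' perturbations of it), keeping the best optimum.  A spot with no observed
#' value in either group is degenerate: the likelihood is maximized on the
#' never-expressed boundary \eqn{p \to 0} with log likelihood 0.
#'
#' @param values intensity vector for one spot (NA = missing).
#' @param groups aligned control/case labels.
#' @param constants a \linkS4class{ModelConstants}.
#' @param null fit the constrained null model?
#' @param extraStarts optional list of additional start vectors on the
#'   optimizer scale (\code{c(mu, delta, kappa, tau, log sigma)} for the full
#'   model, \code{c(mu, kappa, log sigma)} for the null); used to seed one
#'   model's search with the other's optimum so that nested fits explore the
#'   same likelihood modes.
#' @return List with \code{par} (named mu, delta, kappa, tau, sigma),
#'   \code{loglik}, and \code{neverExpressed}.
#' @export
fitUnivariateSpot <- function(values, groups, constants = modelConstants(),
                              null = FALSE, extraStarts = list()) {
  groups <- as.character(groups)
  obs <- !is.na(values) & values >= constants@d
  if (!any(obs)) {
    return(list(par = c(mu = constants@d, delta = 0, kappa = -10, tau = 0,
                        sigma = 1),
                loglik = 0, neverExpressed = TRUE))
  }
  ctrl <- groups == "control"
  m0 <- mean(values[obs & ctrl])
  m1 <- mean(values[obs & !ctrl])
  if (!is.finite(m0)) m0 <- mean(values[obs])
  if (!is.finite(m1)) m1 <- mean(values[obs])
  s0 <- sd(values[obs])
  if (!is.finite(s0) || s0 < 0.05) s0 <- 0.5
  f0 <- max(min(mean(obs[ctrl]), 0.99), 0.01)
  f1 <- max(min(mean(obs[!ctrl]), 0.99), 0.01)
  k0 <- max(min(qlogis(f0), 5), -5)
  t0 <- max(min(qlogis(f1) - qlogis(f0), 5), -5)

  if (null) {
    base <- c(mean(values[obs]), max(min(qlogis(mean(obs)), 5), -5), log(s0))
    starts <- c(list(base,
                     base + c(0.5, 1, 0.3), base - c(0.5, 1, 0.3),
                     base + c(-1, 2, -0.5), base + c(1, -2, 0.5),
                     # censoring-heavy mode: everything expressed, mean below
                     # the detection limit with a wide sd
                     c(constants@d - 1.5, 3, log(1.5)),
                     c(constants@d - 3, 5, log(3))),
                extraStarts)
    lower <- c(-Inf, -10, log(0.01))
    upper <- c(Inf, 10, log(10))
  } else {
    base <- c(m0, m1 - m0, k0, t0, log(s0))
    starts <- c(list(base,
                     base + c(0.5, -0.5, 1, 1, 0.3),
                     base - c(0.5, -0.5, 1, 1, 0.3),
                     base + c(-1, 1, -2, 2, -0.5),
                     base + c(1, -1, 2, -2, 0.5),
                     c(constants@d - 1.5, 0, 3, 0, log(1.5)),
                     c(constants@d - 3, 0, 5, 0, log(3))),
                extraStarts)
    lower <- c(-Inf, -Inf, -10, -10, log(0.01))
    upper <- c(Inf, Inf, 10, 10, log(10))
  }
  stats <- .spotStats(values, groups, constants)
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower + 1e-6), upper - 1e-6)
    fit <- tryCatch(
      optim(st, .negLogLik, stats = stats, constants = constants,
            null = null, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  p <- best$par
  par <- if (null)
    c(mu = p[1L], delta = 0, kappa = p[2L], tau = 0, sigma = exp(p[3L]))
  else
    c(mu = p[1L], delta = p[2L], kappa = p[3L], tau = p[4L],
      sigma = exp(p[5L]))
  list(par = par, loglik = -best$value, neverExpressed = FALSE)
}

#' Likelihood ratio test for differential expression, per spot
#'
#' For each spot, \eqn{2(\ell_{full} - \ell_{null})} is referred to a
#' chi-squared distribution with 2 degrees of freedom (the null constrains
#' \eqn{\delta_s} and \eqn{\tau_s}); a spot is significant at
#' \code{p < alpha}.  Never-expressed spots are flagged non-significant.
#'
#' @param x a \linkS4class{GelMatrix}.
#' @param alpha significance level, default 0.05.
#' @param constants a \linkS4class{ModelConstants}.
#' @return data.frame with \code{spot_id, loglik_full, loglik_null,
#'   statistic, p_value, significant, never_expressed}.
#' @export
lrtClassify <- function(x, alpha = 0.05, constants = modelConstants()) {
  stopifnot(is(x, "GelMatrix"))
  v <- intensityMatrix(x)
  groups <- gelGroups(x)
  rows <- lapply(seq_len(nrow(v)), function(s) {
    nullf <- fitUnivariateSpot(v[s, ], groups, constants, null = TRUE)
    # seed the full fit with the null optimum (guarantees nesting), then
    # re-check the null with the full optimum projected onto delta = tau = 0,
    # so both fits settle in the same likelihood mode family
    np <- nullf$par
    full <- fitUnivariateSpot(
      v[s, ], groups, constants, null = FALSE,
      extraStarts = list(c(np["mu"], 0, np["kappa"], 0, log(np["sigma"]))))
    fp <- full$par
    null2 <- fitUnivariateSpot(
      v[s, ], groups, constants, null = TRUE,
      extraStarts = list(
        c(fp["mu"], fp["kappa"], log(fp["sigma"])),
        c(fp["mu"] + fp["delta"], fp["kappa"] + fp["tau"],
          log(fp["sigma"]))))
    if (null2$loglik > nullf$loglik) nullf <- null2
    stat <- max(0, 2 * (full$loglik - nullf$loglik))
    p <- pchisq(stat, df = 2, lower.tail = FALSE)
    data.frame(spot_id = spotIds(x)[s],
               loglik_full = full$loglik, loglik_null = nullf$loglik,
               statistic = stat, p_value = p,
               significant = (p < alpha) && !full$neverExpressed,
               never_expressed = full$neverExpressed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
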