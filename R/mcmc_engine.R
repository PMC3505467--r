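# R-facing layer over the compiled adaptive block-updating MH sampler, plus
# the small reusable MH primitives (proposals, acceptance, scale adaptation)
# that the tests exercise directly.

#' Adapt a proposal standard deviation towards a target acceptance rate
#'
#' \eqn{\sigma_{new} = \sigma_{cur}\,\Phi^{-1}(\rho_{opt}/2) /
#' \Phi^{-1}(\rho_{cur}/2)}: acceptance above target inflates the scale,
#' below target shrinks it.
#'
#' @param sdCur current proposal sd.
#' @param rhoCur observed acceptance rate in (0, 1); clamp it away from the
#'   boundaries before calling (the sampler uses 1/window).
#' @param rhoOpt target acceptance rate (0.44 for one-parameter blocks,
#'   0.234 for multi-parameter blocks).
#' @return The new proposal sd.
#' @export
adaptSd <- function(sdCur, rhoCur, rhoOpt) {
  stopifnot(rhoCur > 0, rhoCur < 1, rhoOpt > 0, rhoOpt < 1)
  sdCur * qnorm(rhoOpt / 2) / qnorm(rhoCur / 2)
}

#' Metropolis-Hastings accept/reject decision
#'
#' Accepts with probability \eqn{\min(1, \exp(\Delta + h))} where
#' \eqn{\Delta} is the candidate-minus-current log posterior difference and
#' \eqn{h} the log Hastings correction; one uniform draw per call.
#'
#' @param logPostCur,logPostCand current and candidate log posteriors.
#' @param logHastings log proposal-density correction (0 for symmetric kernels).
#' @return \code{TRUE} to accept. A candidate at \code{-Inf} is always
#'   rejected.
#' @export
mhAccept <- function(logPostCur, logPostCand, logHastings = 0) {
  stopifnot(is.finite(logPostCur))
  delta <- logPostCand - logPostCur + logHastings
  log(runif(1)) < delta
}

#' Random-walk proposal kernels with their log Hastings corrections
#'
#' \code{proposeNormal} is the symmetric kernel (correction 0).
#' \code{proposeTruncNormal} draws from a normal truncated to
#' \code{[lower, upper]} via the inverse CDF and returns the exact
#' renormalization correction \eqn{\log Z(cur) - \log Z(cand)}.
#' \code{proposeLogitNormal} walks on the logit scale for a (0,1)-bounded
#' parameter and returns the Jacobian correction.
#'
#' @param cur current value.
#' @param sd proposal scale.
#' @param lower,upper truncation bounds (may be infinite).
#' @return \code{list(value =, logHastings =)}.
#' @name proposals
NULL

#' @rdname proposals
#' @export
proposeNormal <- function(cur, sd) {
  list(value = cur + sd * rnorm(1), logHastings = 0)
}

#' @rdname proposals
#' @export
proposeTruncNormal <- function(cur, sd, lower = -Inf, upper = Inf) {
  pa <- pnorm(lower, cur, sd)
  pb <- pnorm(upper, cur, sd)
  m <- max(pb - pa, 1e-300)
  u <- min(max(pa + runif(1) * (pb - pa), 1e-300), 1 - 1e-16)
  x <- min(max(qnorm(u, cur, sd), lower), upper)
  mNew <- max(pnorm(upper, x, sd) - pnorm(lower, x, sd), 1e-300)
  list(value = x, logHastings = log(m) - log(mNew))
}

#' @rdname proposals
#' @export
proposeLogitNormal <- function(cur, sd) {
  stopifnot(cur > 0, cur < 1)
  x <- plogis(qlogis(cur) + sd * rnorm(1))
  list(value = x,
       logHastings = log(x) + log1p(-x) - log(cur) - log1p(-cur))
}

# spec'd initialization: observed spot means, moment-matched globals
.initState <- function(x, constants) {
  v <- intensityMatrix(x)
  groups <- gelGroups(x)
  S <- nrow(v); G <- ncol(v)
  obs <- !is.na(v) & v >= constants@d
  mu0 <- rowMeans(ifelse(obs, v, NA), na.rm = TRUE)
  mu0[!is.finite(mu0)] <- -3
  fr <- rowMeans(obs)
  kap0 <- pmin(pmax(qlogis(pmin(pmax(fr, 1e-3), 1 - 1e-3)), -2.94), 2.94)
  muG0 <- mean(mu0)
  sigG0 <- max(sd(mu0), 0.1)
  if (!is.finite(sigG0)) sigG0 <- 1
  spotVar <- apply(ifelse(obs, v, NA), 1L, var, na.rm = TRUE)
  pooled <- sqrt(mean(spotVar, na.rm = TRUE))
  if (!is.finite(pooled) || pooled <= 0) pooled <- 0.5 * sigG0
  list(mu = mu0, delta = rep(0, S), kappa = kap0, tau = rep(0, S),
       muG = muG0, sigmaG = sigG0,
       psi = min(max(pooled / sigG0, 0.05), 1.95),
       lambdaDelta = 1, phiDelta = 0.5,
       muKappa = mean(kap0), sigmaKappa = max(sd(kap0), 0.1),
       muTau = 0, sigmaTau = 1)
}

.traceColNames <- function(ids) {
  c("mu_g", "sigma_g", "psi", "lambda_delta", "phi_delta",
    "mu_kappa", "sigma_kappa", "mu_tau", "sigma_tau",
    "alpha_mu", "alpha_kappa", "alpha_tau",
    paste0("mu.", ids), paste0("delta.", ids),
    paste0("kappa.", ids), paste0("tau.", ids), "logpost")
}

.blockNames <- c("muG_sigmaG", "alpha_mu", "lambda_phi", "psi",
                 "muKappa_sigmaKappa", "alpha_kappa", "muTau_sigmaTau",
                 "alpha_tau", "local_mu_delta", "local_kappa_tau")

#' Run the adaptive block-updating MH sampler
#'
#' Each iteration updates the eight global blocks (two-parameter
#' mean/scale blocks, the scalar expansion multipliers, \eqn{\psi}, and the
#' Laplace pair) followed by the two local blocks
#' \eqn{(\mu_s, \delta_s)} and \eqn{(\kappa_s, \tau_s)} of every spot, in a
#' fixed spot order.  Proposal scales are tuned every 500 iterations during
#' burn-in (acceptance averaged over a 3000-iteration window) and frozen
#' afterwards, so the post-burn-in chain is a fixed-kernel MH sampler.
#' Every \code{thin}-th state is recorded on the natural scale; rows falling
#' inside the burn-in fraction are discarded.
#'
#' @param x a \linkS4class{GelMatrix}.
#' @param iterations total chain length.
#' @param thin record every \code{thin}-th state.
#' @param burninFrac fraction of iterations discarded (and during which
#'   proposal scales adapt).
#' @param seed RNG seed; identical seed, config and data give bit-identical
#'   traces.
#' @param constants a \linkS4class{ModelConstants}.
#' @param expand use parameter expansion (redundant multiplicative
#'   \eqn{\alpha} linking each mean/variance pair, uniform(0.01, 10) prior);
#'   \code{FALSE} gives the plain five-block sampler with all
#'   \eqn{\alpha = 1}.
#' @param rhoOptSingle,rhoOptBlock target acceptance rates for one- and
#'   multi-parameter blocks.
#' @param init optional named list of initial values (as produced
#'   internally); defaults to moment-based initialization from the data.
#' @param sdInit initial proposal sd for every block.
#' @return A \linkS4class{ChainTrace}.
#' @examples
#' sim <- simulateGels(simPreset("sim1", S = 5L), seed = 1)
#' tr <- runChain(simGelMatrix(sim), iterations = 2000, thin = 20, seed = 1)
#' tr
#' @export
runChain <- function(x, iterations, thin = 1000L, burninFrac = 0.1,
                     seed = 1L, constants = modelConstants(),
                     expand = TRUE, rhoOptSingle = 0.44,
                     rhoOptBlock = 0.234, init = NULL, sdInit = 0.5) {
  stopifnot(is(x, "GelMatrix"), iterations >= thin, thin >= 1,
            burninFrac >= 0, burninFrac < 1)
  if (any(intensityMatrix(x) > constants@nu + 1e-9, na.rm = TRUE))
    stop("observed intensity above nu")
  if (is.null(init)) init <- .initState(x, constants)
  groups <- as.integer(gelGroups(x) == "case")
  set.seed(as.integer(seed))
  res <- .run_sampler_cpp(intensityMatrix(x), groups, constants@d,
                          constants@nu, as.integer(iterations),
                          as.integer(thin), burninFrac, init, expand,
                          rhoOptSingle, rhoOptBlock, 500L, 3000L, sdInit)
  keep <- res$state > res$burnIters
  samples <- res$samples[keep, , drop = FALSE]
  colnames(samples) <- .traceColNames(spotIds(x))
  rownames(samples) <- res$state[keep]
  new("ChainTrace", samples = samples, thin = as.integer(thin),
      burninFrac = burninFrac, iterations = as.integer(iterations),
      seed = as.integer(seed), spotIds = spotIds(x),
      acceptance = setNames(res$acceptance, .blockNames),
      tunedAcceptance = setNames(res$tunedAcceptance, .blockNames),
      proposalSd = setNames(res$proposalSd, .blockNames))
}

#' Map expansion (primed) parameters to the natural scale
#'
#' Parameter expansion links each mean/variance pair through a redundant
#' multiplier: \eqn{\mu = \alpha\,\mu'}, \eqn{\sigma^2 = \alpha^2\sigma'^2}.
#' Different \eqn{(\alpha, \mu', \sigma'^2)} triples mapping to the same
#' natural pair are equivalent by construction, which is what lets the
#' sampler sidestep the sticky region near zero variance.
#'
#' @param alpha expansion multiplier in [0.01, 10].
#' @param muPrime primed mean.
#' @param sigma2Prime primed variance (> 0).
#' @return Named vector \code{c(mu =, sigma2 =)} on the natural scale.
#' @examples
#' expansionToNatural(2, -2.5, 0.25)  # same natural pair as (1, -5, 1)
#' expansionToNatural(1, -5, 1)
#' @export
expansionToNatural <- function(alpha, muPrime, sigma2Prime) {
  stopifnot(alpha >= 0.01, alpha <= 10, sigma2Prime > 0)
  c(mu = alpha * muPrime, sigma2 = alpha^2 * sigma2Prime)
}

#' Adaptive random-walk MH on a standard normal target
#'
#' A test hook: the same tuning schedule as the full sampler (update every
#' 500 iterations, acceptance averaged over 3000, target 0.44) applied to a
#' one-dimensional N(0, 1) target.  Long-run mean/variance near 0/1 is a
#' detailed-balance smoke test, and comparing \code{adapt = TRUE} against a
#' frozen-kernel run checks that freezing adaptation after burn-in preserves
#' the stationary distribution.
#'
#' @param iterations chain length.
#' @param seed RNG seed.
#' @param sdInit initial proposal sd.
#' @param adapt tune the proposal sd during the first \code{burninFrac}?
#' @param burninFrac fraction treated as burn-in (discarded).
#' @return List with \code{samples} (post-burn-in draws), \code{acceptance},
#'   and the final \code{proposalSd}.
#' @export
mhNormalTarget <- function(iterations, seed = 1L, sdInit = 0.5,
                           adapt = TRUE, burninFrac = 0.1) {
  set.seed(as.integer(seed))
  burn <- floor(burninFrac * iterations)
  x <- 0
  lp <- dnorm(x, log = TRUE)
  sdCur <- sdInit
  out <- numeric(iterations - burn)
  accWin <- integer(0)
  nAccPost <- 0L
  for (t in seq_len(iterations)) {
    cand <- x + sdCur * rnorm(1)
    lpCand <- dnorm(cand, log = TRUE)
    acc <- log(runif(1)) < (lpCand - lp)
    if (acc) { x <- cand; lp <- lpCand }
    accWin <- c(accWin, as.integer(acc))
    if (length(accWin) > 3000L) accWin <- accWin[-1L]
    if (adapt && t <= burn && t %% 500L == 0L) {
      n <- length(accWin)
      rho <- min(max(mean(accWin), 1 / n), 1 - 1 / n)
      sdCur <- min(max(adaptSd(sdCur, rho, 0.44), 1e-8), 1e8)
    }
    if (t > burn) {
      out[t - burn] <- x
      nAccPost <- nAccPost + as.integer(acc)
    }
  }
  list(samples = out, acceptance = nAccPost / (iterations - burn),
       proposalSd = sdCur)
}

#' Write / read a ChainTrace as a tab-delimited trace log
#'
#' The format is the conventional MCMC trace layout readable by standard
#' trace viewers: \code{#}-prefixed comment header, then a header row with a
#' leading \code{state} column followed by one column per parameter and the
#' log posterior.
#'
#' @param trace a \linkS4class{ChainTrace}.
#' @param path output (input) file path.
#' @return \code{writeTrace}: invisibly, \code{path}; \code{readTrace}: a
#'   \linkS4class{ChainTrace} (acceptance diagnostics are not round-tripped).
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "ChainTrace"), nrow(trace@samples) > 0L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# BayesPAGE MCMC trace",
               sprintf("# iterations=%d thin=%d burninFrac=%g seed=%d",
                       trace@iterations, trace@thin, trace@burninFrac,
                       trace@seed),
               sprintf("# spots=%s", paste(trace@spotIds, collapse = ","))),
             con)
  fmt <- matrix(sprintf("%.17g", trace@samples), nrow = nrow(trace@samples))
  df <- data.frame(state = rownames(trace@samples), fmt, check.names = FALSE)
  colnames(df) <- c("state", colnames(trace@samples))
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  meta <- c(iterations = NA, thin = NA, burninFrac = NA, seed = NA)
  m <- regmatches(hdr, regexec(
    "iterations=(\\d+) thin=(\\d+) burninFrac=([0-9.eE+-]+) seed=(-?\\d+)", hdr))
  for (mm in m) if (length(mm) == 5L)
    meta[] <- as.numeric(mm[-1L])
  spots <- character(0)
  sp <- regmatches(hdr, regexec("^# spots=(.*)$", hdr))
  for (mm in sp) if (length(mm) == 2L)
    spots <- strsplit(mm[2L], ",", fixed = TRUE)[[1L]]
  body <- lines[!startsWith(lines, "#")]
  tab <- read.delim(text = body, sep = "\t", check.names = FALSE)
  samples <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(samples) <- tab[[1L]]
  new("ChainTrace", samples = samples, thin = as.integer(meta["thin"]),
      burninFrac = as.numeric(meta["burninFrac"]),
      iterations = as.integer(meta["iterations"]),
      seed = as.integer(meta["seed"]), spotIds = spots,
      acceptance = numeric(0), proposalSd = numeric(0))
}
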