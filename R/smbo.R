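# Sequential model-based optimization: Gaussian-process surrogate with a
# Matern-5/2 ARD kernel on the unit cube, expected-improvement acquisition,
# and the relative-deviation convergence diagnostic.

.spaceToUnit <- function(space, L) {
  # L: data.frame/matrix of parameter values (columns in space order)
  ps <- space@params
  U <- matrix(0, nrow(L), length(ps))
  for (d in seq_along(ps)) {
    p <- ps[[d]]
    x <- L[[p$name]]
    U[, d] <- if (p$prior == "log-uniform")
      (log(x) - log(p$lower)) / (log(p$upper) - log(p$lower))
    else (x - p$lower) / (p$upper - p$lower)
  }
  U
}

.unitToLambda <- function(space, u) {
  # u: numeric vector in [0,1]^d -> named list, integers rounded + clamped
  ps <- space@params
  out <- list()
  for (d in seq_along(ps)) {
    p <- ps[[d]]
    x <- if (p$prior == "log-uniform")
      exp(log(p$lower) + u[d] * (log(p$upper) - log(p$lower)))
    else p$lower + u[d] * (p$upper - p$lower)
    if (p$integer) x <- min(max(round(x), ceiling(p$lower)), floor(p$upper))
    out[[p$name]] <- x
  }
  out
}

#' Draw hyperparameter configurations from the prior
#'
#' Uniform priors are sampled directly; log-uniform priors via
#' \eqn{\exp(U(\log a, \log b))}. Integer parameters are rounded to the
#' nearest integer and clamped to the bounds.
#'
#' @param space a \linkS4class{SearchSpace}.
#' @param seed integer seed (same seed, same draws).
#' @param n number of configurations (>= 1).
#' @return data.frame with one column per parameter and n rows.
#' @export
samplePrior <- function(space, seed = 0L, n = 1L) {
  stopifnot(n >= 1L)
  validObject(space)
  .withSeed(seed, {
    cols <- lapply(space@params, function(p) {
      x <- if (p$prior == "log-uniform")
        exp(runif(n, log(p$lower), log(p$upper)))
      else runif(n, p$lower, p$upper)
      if (p$integer) x <- pmin(pmax(round(x), ceiling(p$lower)),
                               floor(p$upper))
      x
    })
    as.data.frame(setNames(cols, paramNames(space)))
  })
}

.matern52 <- function(U1, U2, ell, s2) {
  D2 <- matrix(0, nrow(U1), nrow(U2))
  for (d in seq_along(ell)) {
    dd <- outer(U1[, d], U2[, d], "-") / ell[d]
    D2 <- D2 + dd * dd
  }
  r <- sqrt(pmax(D2, 0)) * sqrt(5)
  s2 * (1 + r + r^2 / 3) * exp(-r)
}

.gpNll <- function(theta, U, y) {
  d <- ncol(U)
  ell <- exp(theta[seq_len(d)])
  s2 <- exp(theta[d + 1L])
  noise <- exp(theta[d + 2L])
  K <- .matern52(U, U, ell, s2) + diag(noise + 1e-6, nrow(U))
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  as.numeric(0.5 * crossprod(y, alpha) + sum(log(diag(ch))) +
               0.5 * length(y) * log(2 * pi))
}

.gpFit <- function(U, y) {
  mu <- mean(y)
  sc <- sd(y)
  if (!is.finite(sc) || sc == 0) sc <- 1
  ys <- (y - mu) / sc
  d <- ncol(U)
  lower <- c(rep(log(0.03), d), log(0.05), log(1e-6))
  upper <- c(rep(log(30), d), log(20), log(1))
  best <- NULL
  for (l0 in c(0.3, 1)) {
    th0 <- c(rep(log(l0), d), log(1), log(1e-4))
    fit <- tryCatch(
      optim(th0, .gpNll, U = U, y = ys, method = "L-BFGS-B",
            lower = lower, upper = upper, control = list(maxit = 60)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  theta <- if (is.null(best)) c(rep(log(0.3), d), log(1), log(1e-4))
           else best$par
  ell <- exp(theta[seq_len(d)])
  s2 <- exp(theta[d + 1L])
  noise <- exp(theta[d + 2L])
  K <- .matern52(U, U, ell, s2) + diag(noise + 1e-6, nrow(U))
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  list(U = U, chol = ch, alpha = alpha, ell = ell, s2 = s2, noise = noise,
       yMean = mu, yScale = sc)
}

.gpPredict <- function(fit, Unew) {
  Ks <- .matern52(Unew, fit$U, fit$ell, fit$s2)
  mu <- as.numeric(Ks %*% fit$alpha)
  V <- forwardsolve(t(fit$chol), t(Ks))
  v <- pmax(fit$s2 - colSums(V^2), 0)
  list(mean = mu * fit$yScale + fit$yMean, sd = sqrt(v) * fit$yScale)
}

#' Fit the Gaussian-process surrogate to evaluated trials
#'
#' Maps parameters to the unit cube (log scale for log-uniform priors) and
#' fits a GP with Matern-5/2 ARD kernel; kernel scales and the observation
#' noise are chosen by marginal-likelihood maximization. Duplicate
#' configurations with conflicting objectives are absorbed by the noise
#' term.
#'
#' @param trials data.frame of evaluated configurations with an
#'   \code{objective} column (and optionally \code{failed}), or an
#'   \linkS4class{HPOHistory}.
#' @param space the \linkS4class{SearchSpace}.
#' @return A surrogate object with a \code{$posterior(lambda)} function
#'   returning \code{list(mean, sd)} for a data.frame of configurations.
#' @export
fitSurrogate <- function(trials, space) {
  if (is(trials, "HPOHistory")) trials <- trials@trials
  if (!is.null(trials$failed)) trials <- trials[!trials$failed, , drop = FALSE]
  if (nrow(trials) < 2L) stop("need at least 2 trials", call. = FALSE)
  U <- .spaceToUnit(space, trials)
  fit <- .gpFit(U, trials$objective)
  structure(list(
    fit = fit, space = space,
    posterior = function(lambda) {
      Unew <- if (is.matrix(lambda)) lambda else .spaceToUnit(space, lambda)
      .gpPredict(fit, Unew)
    }), class = "gpSurrogate")
}

#' Expected improvement
#'
#' Closed form of \eqn{E[\max(z - \Psi^*, 0)]} for a Gaussian posterior
#' \eqn{z \sim N(\mu, \sigma^2)}:
#' \eqn{(\mu - \Psi^*)\Phi(u) + \sigma\phi(u)} with
#' \eqn{u = (\mu - \Psi^*)/\sigma}; for \eqn{\sigma = 0} it degenerates to
#' \eqn{\max(\mu - \Psi^*, 0)}.
#'
#' @param mu posterior mean(s).
#' @param sigma posterior standard deviation(s), >= 0.
#' @param best incumbent objective \eqn{\Psi^*}.
#' @return Non-negative expected improvement, vectorized over mu/sigma.
#' @export
expectedImprovement <- function(mu, sigma, best) {
  stopifnot(all(sigma >= 0))
  out <- pmax(mu - best, 0)
  pos <- sigma > 0
  if (any(pos)) {
    u <- (mu[pos] - best) / sigma[pos]
    out[pos] <- (mu[pos] - best) * pnorm(u) + sigma[pos] * dnorm(u)
  }
  pmax(out, 0)
}

#' Propose the next configuration by maximizing expected improvement
#'
#' Fits the surrogate to the history, evaluates EI on a seeded random
#' candidate set in the unit cube, and locally refines the best candidate
#' with box-constrained optimization. Deterministic given (history, seed).
#'
#' @param history an \linkS4class{HPOHistory} or trials data.frame.
#' @param space the \linkS4class{SearchSpace}.
#' @param seed integer seed for the candidate set.
#' @param candidateCount number of random candidates.
#' @return A named list, the proposed configuration (within bounds,
#'   integer-feasible).
#' @export
proposeNext <- function(history, space, seed = 0L, candidateCount = 512L) {
  trialsDf <- if (is(history, "HPOHistory")) history@trials else history
  ok <- if (is.null(trialsDf$failed)) rep(TRUE, nrow(trialsDf))
        else !trialsDf$failed
  sur <- fitSurrogate(trialsDf, space)
  best <- max(trialsDf$objective[ok])
  d <- length(space@params)
  Ucand <- .withSeed(seed, matrix(runif(candidateCount * d), ncol = d))
  post <- .gpPredict(sur$fit, Ucand)
  ei <- expectedImprovement(post$mean, post$sd, best)
  u0 <- Ucand[which.max(ei), ]
  negEI <- function(u) {
    p <- .gpPredict(sur$fit, matrix(u, nrow = 1))
    -expectedImprovement(p$mean, p$sd, best)
  }
  ref <- tryCatch(
    optim(u0, negEI, method = "L-BFGS-B", lower = rep(0, d),
          upper = rep(1, d), control = list(maxit = 50)),
    error = function(e) list(par = u0, value = -max(ei)))
  u <- if (-ref$value >= max(ei)) ref$par else u0
  .unitToLambda(space, u)
}

#' Run sequential model-based optimization
#'
#' Evaluates \code{nInit} prior draws, then repeatedly fits the GP
#' surrogate and evaluates the EI-maximizing proposal, for \code{nIter}
#' evaluations in total (the default mirrors a 50-iteration budget).
#' Objective failures (errors or non-finite values) are recorded as failed
#' trials, excluded from the surrogate, and the loop continues.
#'
#' @param objective function(named list) -> numeric validation metric to
#'   maximize.
#' @param space a \linkS4class{SearchSpace}.
#' @param nIter total number of evaluations (>= nInit).
#' @param nInit prior draws before the surrogate is first fitted (>= 2).
#' @param seed integer seed; the run is reproducible from it for a
#'   deterministic objective.
#' @param metricName label of the optimized metric.
#' @return An \linkS4class{HPOHistory} of length \code{nIter}.
#' @export
runSMBO <- function(objective, space, nIter = 50L, nInit = 5L, seed = 0L,
                    metricName = "SSIM") {
  stopifnot(nInit >= 2L, nIter >= nInit)
  validObject(space)
  nms <- paramNames(space)
  init <- samplePrior(space, .childSeed(seed, "init"), nInit)
  trialsDf <- NULL
  evalOne <- function(lambda, i) {
    val <- tryCatch(objective(lambda), error = function(e) NA_real_)
    failed <- !is.finite(val)
    row <- as.data.frame(lambda)
    row$iteration <- i
    row$objective <- if (failed) NA_real_ else val
    row$failed <- failed
    row
  }
  for (i in seq_len(nInit))
    trialsDf <- rbind(trialsDf, evalOne(as.list(init[i, , drop = FALSE]), i))
  for (i in seq(nInit + 1L, length.out = nIter - nInit)) {
    okn <- sum(!trialsDf$failed)
    lambda <- if (okn >= 2L)
      proposeNext(trialsDf, space, .childSeed(seed, paste0("prop-", i)))
    else as.list(samplePrior(space, .childSeed(seed, paste0("rand-", i)), 1L))
    trialsDf <- rbind(trialsDf, evalOne(lambda, i))
  }
  ok <- !trialsDf$failed
  if (!any(ok)) stop("all trials failed", call. = FALSE)
  bi <- which(ok)[which.max(trialsDf$objective[ok])]
  new("HPOHistory",
      trials = trialsDf[, c("iteration", "objective", "failed", nms)],
      space = space,
      bestLambda = as.list(trialsDf[bi, nms, drop = FALSE]),
      bestObjective = trialsDf$objective[bi], metricName = metricName,
      seed = as.integer(seed))
}

#' Relative deviation from the best setting
#'
#' \eqn{RelDev_i = 1 - \max_{j \le i} M_j / \max_j M_j}: how far the best
#' objective found up to iteration i falls short of the best over the whole
#' run. Non-increasing; the final element is 0.
#'
#' @param history an \linkS4class{HPOHistory} or numeric vector of
#'   per-iteration objectives.
#' @return Numeric vector of relative deviations.
#' @export
relDev <- function(history) {
  m <- if (is(history, "HPOHistory")) {
    x <- history@trials$objective
    x[history@trials$failed] <- NA_real_
    x
  } else as.numeric(history)
  if (!length(m)) stop("empty history", call. = FALSE)
  run <- cummax(ifelse(is.na(m), -Inf, m))
  gmax <- max(run)
  if (!(gmax > 0)) stop("global best objective must be positive",
                        call. = FALSE)
  pmin(1, 1 - run / gmax)
}

#' Retrain a method with multiple random seeds
#'
#' Runs \code{trainFn(lambda, seed)} for seeds 0..nSeeds-1 and keeps each
#' per-seed output for downstream spread and significance analysis.
#' Per-seed failures are reported, not swallowed.
#'
#' @param trainFn function(lambda, seed) -> fitted state / metrics.
#' @param lambda the selected hyperparameter configuration (named list).
#' @param nSeeds number of retraining seeds (default 10).
#' @return Named list ("seed0", "seed1", ...) of outputs, order-stable;
#'   failed seeds hold a \code{list(error = <message>)}.
#' @export
retrainWithSeeds <- function(trainFn, lambda, nSeeds = 10L) {
  stopifnot(nSeeds >= 1L)
  out <- lapply(seq_len(nSeeds) - 1L, function(s) {
    tryCatch(trainFn(lambda, s), error = function(e) {
      warning(sprintf("retraining seed %d failed: %s", s, conditionMessage(e)),
              call. = FALSE)
      list(error = conditionMessage(e))
    })
  })
  names(out) <- paste0("seed", seq_len(nSeeds) - 1L)
  out
}
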