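## Ensemble construction: scoring, coarse filtering, local optimization,
## strict filtering, de-duplication.

#' Score a matrix of models against a scenario's target profile
#'
#' @param scenario a \code{\linkS4class{Scenario}}.
#' @param params matrix of parameter vectors (rows), columns named after
#'   \code{\link{parameterNames}(scenario)}.
#' @return numeric vector of mean-squared-error scores.
#' @export
scoreModels <- function(scenario, params) {
  engine <- .scenarioEngine(scenario)
  target <- targetProfile(scenario)
  apply(params, 1, function(p)
    sseScore(.predictProfileEngine(engine, p), target))
}

#' Coarse filtering of sampled models
#'
#' Retains exactly the models whose goodness-of-fit score against the
#' scenario's target is below the threshold \code{tau1} (the modest
#' pre-optimization threshold of the pipeline).
#'
#' @param params matrix of parameter vectors.
#' @param scenario a \code{\linkS4class{Scenario}}.
#' @param tau1 positive score threshold.
#' @param sse optional precomputed scores (avoids rescoring).
#' @return list with elements \code{params} (retained rows) and \code{sse}.
#' @export
coarseFilter <- function(params, scenario, tau1, sse = NULL) {
  stopifnot(tau1 > 0)
  if (is.null(sse)) sse <- scoreModels(scenario, params)
  keep <- which(sse < tau1)
  list(params = params[keep, , drop = FALSE], sse = sse[keep])
}

## bounded objective on [0,1]^D unit-cube coordinates (declared scales):
## out-of-box proposals are clamped and smoothly penalized
.makeObjective <- function(engine, target, space, penalty = 10) {
  lo <- .toScale(space@lower, space@scale)
  hi <- .toScale(space@upper, space@scale)
  width <- hi - lo
  nms <- space@parameters
  function(t) {
    tc <- pmin(pmax(t, 0), 1)
    x <- .fromScale(lo + tc * width, space@scale)
    names(x) <- nms
    val <- sseScore(.predictProfileEngine(engine, x), target)
    val + penalty * sum((t - tc)^2)
  }
}

.toUnit <- function(x, space) {
  lo <- .toScale(space@lower, space@scale)
  hi <- .toScale(space@upper, space@scale)
  (.toScale(x, space@scale) - lo) / (hi - lo)
}

.fromUnit <- function(t, space) {
  lo <- .toScale(space@lower, space@scale)
  hi <- .toScale(space@upper, space@scale)
  x <- .fromScale(lo + pmin(pmax(t, 0), 1) * (hi - lo), space@scale)
  names(x) <- space@parameters
  x
}

#' Locally optimize a model's fit
#'
#' Derivative-free Nelder-Mead descent of the goodness-of-fit score, run on
#' unit-cube coordinates (log dimensions optimized in log space), with the
#' result clamped to the declared bounds and optional restarts.  The returned
#' model never scores worse than the seed.
#'
#' @param params named numeric seed parameter vector inside the space.
#' @param scenario a \code{\linkS4class{Scenario}}.
#' @param space a \code{\linkS4class{ParameterSpace}}.
#' @param maxit Nelder-Mead iteration cap per start (default 400).
#' @param restarts number of restarts from the incumbent (default 1).
#' @param reltol relative convergence tolerance (default 1e-10).
#' @return list with the optimized \code{params} and its \code{sse}.
#' @export
localOptimize <- function(params, scenario, space, maxit = 400,
                          restarts = 1, reltol = 1e-10) {
  engine <- .scenarioEngine(scenario)
  .localOptimizeEngine(params, engine, targetProfile(scenario), space,
                       maxit, restarts, reltol)
}

.localOptimizeEngine <- function(params, engine, target, space, maxit = 400,
                                 restarts = 1, reltol = 1e-10) {
  obj <- .makeObjective(engine, target, space)
  t0 <- .toUnit(params[space@parameters], space)
  f0 <- obj(t0)
  if (!is.finite(f0))
    stop("non-finite objective at seed model; offending parameters: ",
         paste(space@parameters[!is.finite(t0)], collapse = ", "))
  best <- t0
  bestVal <- f0
  for (r in seq_len(restarts + 1)) {
    fit <- if (length(t0) == 1L)
      optim(best, obj, method = "Brent", lower = 0, upper = 1,
            control = list(maxit = maxit)) else
      optim(best, obj, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = reltol))
    if (fit$value < bestVal) {
      best <- fit$par
      bestVal <- fit$value
    }
  }
  out <- .fromUnit(best, space)
  sse <- sseScore(.predictProfileEngine(engine, out), target)
  seedSse <- sseScore(.predictProfileEngine(engine,
                                            params[space@parameters]),
                      target)
  if (sse > seedSse) {
    out <- params[space@parameters]
    sse <- seedSse
  }
  list(params = out, sse = sse)
}

## greedy de-duplication on min-max scaled coordinates: models closer than
## `radius` in max-norm are duplicates; the better-scoring one is kept
.dedupModels <- function(params, sse, radius) {
  n <- nrow(params)
  if (n <= 1L) return(seq_len(n))
  rng <- apply(params, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  scaled <- sweep(sweep(params, 2, rng[1, ]), 2, span, "/")
  ord <- order(sse)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep)) {
      d <- abs(scaled[keep, , drop = FALSE] -
               matrix(scaled[i, ], length(keep), ncol(scaled), byrow = TRUE))
      if (min(apply(d, 1, max)) < radius) next
    }
    keep <- c(keep, i)
  }
  sort(keep)
}

#' Build a wild-type ensemble of fit models
#'
#' Composes the full construction pipeline: stratified uniform sampling of
#' the parameter space, coarse filtering at \code{tau1}, local optimization
#' of every retained model, strict filtering at \code{tau2}, and
#' de-duplication.  Scoring is streamed in chunks so large sampling plans do
#' not require holding all predictions in memory.
#'
#' @param scenario a \code{\linkS4class{Scenario}}.
#' @param space a \code{\linkS4class{ParameterSpace}} (default
#'   \code{\link{defaultParameterSpace}(scenario)}).
#' @param samplesPerCell stratified samples per half-range cell.
#' @param seed integer seed governing all sampling.
#' @param tau1 coarse (pre-optimization) score threshold, default 0.10.
#' @param tau2 strict (post-optimization) threshold, default 0.05; must not
#'   exceed \code{tau1}.
#' @param dedupRadius max-norm radius on min-max-scaled coordinates below
#'   which two models are considered duplicates (default 1e-3).
#' @param maxModels sampling budget guard (see
#'   \code{\link{sampleParameterGrid}}).
#' @param maxOptimize cap on the number of coarse-filtered models passed to
#'   local optimization (the best-scoring ones are kept); default unlimited.
#' @param maxit,restarts optimizer settings per model.
#' @param chunkSize scoring chunk size (default 4000).
#' @return an \code{\linkS4class{Ensemble}} with provenance recorded.
#' @examples
#' \donttest{
#' sc <- makeToyScenario(1)
#' ens <- buildEnsemble(sc, samplesPerCell = 50, seed = 1)
#' ens
#' }
#' @export
buildEnsemble <- function(scenario, space = defaultParameterSpace(scenario),
                          samplesPerCell, seed, tau1 = 0.10, tau2 = 0.05,
                          dedupRadius = 1e-3, maxModels = 2e6,
                          maxOptimize = Inf, maxit = 400, restarts = 1,
                          chunkSize = 4000) {
  stopifnot(tau2 <= tau1, tau1 > 0, tau2 > 0)
  samples <- sampleParameterGrid(space, samplesPerCell, seed, maxModels)
  engine <- .scenarioEngine(scenario)
  target <- targetProfile(scenario)
  n <- nrow(samples)
  sse <- numeric(n)
  for (from in seq(1, n, by = chunkSize)) {
    to <- min(from + chunkSize - 1L, n)
    sse[from:to] <- apply(samples[from:to, , drop = FALSE], 1, function(p)
      sseScore(.predictProfileEngine(engine, p), target))
  }
  coarse <- which(sse < tau1)
  nCoarse <- length(coarse)
  if (nCoarse > maxOptimize)
    coarse <- coarse[order(sse[coarse])[seq_len(maxOptimize)]]
  optParams <- matrix(NA_real_, length(coarse), nparameters(space),
                      dimnames = list(NULL, space@parameters))
  optSse <- numeric(length(coarse))
  for (k in seq_along(coarse)) {
    res <- .localOptimizeEngine(samples[coarse[k], ], engine, target, space,
                                maxit = maxit, restarts = restarts)
    optParams[k, ] <- res$params
    optSse[k] <- res$sse
  }
  strict <- which(optSse < tau2)
  if (!length(strict))
    stop("no model passed the strict threshold tau2 = ", tau2,
         "; consider relaxing tau2/tau1 or increasing samplesPerCell")
  optParams <- optParams[strict, , drop = FALSE]
  optSse <- optSse[strict]
  keep <- .dedupModels(optParams, optSse, dedupRadius)
  new("Ensemble", space = space,
      params = optParams[keep, , drop = FALSE], sse = optSse[keep],
      provenance = list(seed = as.integer(seed), tau1 = tau1, tau2 = tau2,
                        samplesPerCell = samplesPerCell,
                        dedupRadius = dedupRadius, nSampled = n,
                        nCoarse = nCoarse, nOptimized = length(coarse),
                        nStrict = length(strict), nFinal = length(keep)))
}
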