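## Shared fixtures and independent oracles.  Expensive objects are built
## lazily and memoized so only the tests that need them pay for them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

fixtureToy <- function() fixture("toy", makeToyScenario(1))

fixtureTwoRep <- function() fixture("tworep", makeTwoRepressorScenario(1))

## desk-scale ensemble + clustering for the mechanistically ambiguous
## scenario; used by the experiment-evaluation and acceptance tests
fixtureTwoRepEnsemble <- function()
  fixture("tworepEnsemble",
          buildEnsemble(fixtureTwoRep(), samplesPerCell = 100, seed = 7,
                        maxOptimize = 300))

fixtureTwoRepClustered <- function()
  fixture("tworepClustered", clusterModels(fixtureTwoRepEnsemble()))

## ---- independent oracles -------------------------------------------------

## Brute-force configuration-sum expression: enumerates every subset of
## non-overlapping sites, with adjacency cooperativity, entirely
## independently of the package's dynamic program.
bruteForceExpression <- function(scenario, params, bin,
                                 sites = siteTable(scenario)) {
  n <- nrow(sites)
  ord <- order(sites$start, sites$end)
  sites <- sites[ord, , drop = FALSE]
  tfs <- setNames(scenario@tfs, tfNames(scenario))
  q <- numeric(n)
  al <- numeric(n)
  for (i in seq_len(n)) {
    tf <- tfs[[sites$tf[i]]]
    qq <- params[[paste0("K_", tf@name)]] * tf@concentration[bin] *
      sites$rel_affinity[i]
    if (length(tf@attenuationMask) && tf@attenuationMask[bin])
      qq <- qq * params[[paste0("atten_", tf@name)]]
    q[i] <- qq
    al[i] <- params[[paste0("alpha_", tf@name)]]
  }
  pairs <- scenario@coopPairs
  coopW <- function(cfg) {
    w <- 1
    if (length(cfg) > 1) for (k in 2:length(cfg)) {
      j <- cfg[k - 1]; i <- cfg[k]
      gap <- sites$start[i] - sites$end[j] - 1
      if (gap > scenario@coopRange) next
      for (r in seq_len(nrow(pairs))) {
        tfpair <- sort(c(pairs$tf1[r], pairs$tf2[r]))
        if (identical(sort(c(sites$tf[j], sites$tf[i])), tfpair))
          w <- w * params[[paste0("coop_", pairs$tf1[r], "_",
                                  pairs$tf2[r])]]
      }
    }
    w
  }
  zOff <- 0
  zOn <- 0
  for (m in 0:(2^n - 1)) {
    cfg <- which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
    if (length(cfg) > 1) {
      s <- sites[cfg, , drop = FALSE]
      if (any(s$start[-1] <= s$end[-length(cfg)])) next
    }
    W <- prod(q[cfg]) * coopW(cfg)
    zOff <- zOff + W
    zOn <- zOn + W * prod(al[cfg])
  }
  qb <- params[["q_btm"]]
  qb * zOn / (qb * zOn + zOff)
}

## hand-coded multivariate normal density (oracle for mixture evaluations)
oracleDmvnorm <- function(x, mu, S) {
  d <- length(mu)
  diff <- as.numeric(x - mu)
  exp(-0.5 * drop(diff %*% solve(S, diff))) /
    sqrt((2 * pi)^d * det(S))
}

## Eq.-1 style mixture density evaluated by explicit loops
oracleMixtureDensity <- function(x, means, labels, covs) {
  live <- sort(unique(labels))
  N <- length(live)
  total <- 0
  for (g in live) {
    idx <- which(labels == g)
    contrib <- mean(vapply(idx, function(i)
      oracleDmvnorm(x, means[i, ], covs[[g]]), 0))
    total <- total + contrib / N
  }
  total
}

## construct a ClusteredEnsemble directly from scaled coordinates, labels,
## and covariances (models' natural-scale params are the scaled coordinates
## themselves, over a unit-box linear space)
makeClusteredFixture <- function(scaled, labels, covs, sse = NULL) {
  scaled <- as.matrix(scaled)
  D <- ncol(scaled)
  nms <- paste0("d", seq_len(D))
  colnames(scaled) <- nms
  space <- ParameterSpace(nms, rep(-0.001, D), rep(1.001, D),
                          rep("linear", D))
  if (is.null(sse)) sse <- rep(0, nrow(scaled))
  ens <- new("Ensemble", space = space, params = scaled, sse = sse,
             provenance = list())
  new("ClusteredEnsemble", ensemble = ens, scaled = scaled,
      scaling = list(min = rep(0, D), max = rep(1, D)),
      labels = as.integer(labels), covariances = covs)
}

## scaled max-norm distance of every ensemble member to a reference model,
## on the parameter space's unit-cube (declared-scale) coordinates
unitDistancesTo <- function(ensemble, reference) {
  space <- ensemble@space
  toUnit <- function(x) {
    lo <- ifelse(space@scale == "log", log(space@lower), space@lower)
    hi <- ifelse(space@scale == "log", log(space@upper), space@upper)
    (ifelse(space@scale == "log", log(x), x) - lo) / (hi - lo)
  }
  un <- t(apply(modelMatrix(ensemble), 1, toUnit))
  ut <- toUnit(reference[space@parameters])
  apply(abs(sweep(un, 2, ut)), 1, max)
}
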