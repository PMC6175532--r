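## Cluster-balanced probability distribution over a model ensemble:
## min-max scaling, Gaussian-mixture clustering, the mixture density, the
## discrete model probabilities, and entropy.

#' Min-max scale an ensemble's parameter matrix
#'
#' Maps every dimension affinely to [0, 1] using the ensemble's own minimum
#' and maximum, placing all parameters on a common scale before clustering.
#' Degenerate dimensions (min = max) map to 0 and cannot be inverted; all
#' others invert exactly from the returned scaling record.
#'
#' @param x an \code{\linkS4class{Ensemble}} or numeric matrix.
#' @return list with \code{scaled} (matrix in [0, 1]), \code{min}, and
#'   \code{max} per dimension.
#' @export
minMaxScale <- function(x) {
  m <- if (is(x, "Ensemble")) modelMatrix(x) else as.matrix(x)
  mins <- apply(m, 2, min)
  maxs <- apply(m, 2, max)
  span <- maxs - mins
  scaled <- sweep(m, 2, mins)
  nz <- span > 0
  scaled[, nz] <- sweep(scaled[, nz, drop = FALSE], 2, span[nz], "/")
  scaled[, !nz] <- 0
  list(scaled = scaled, min = mins, max = maxs)
}

#' Invert min-max scaling
#'
#' @param scaled matrix of scaled coordinates.
#' @param scaling scaling record from \code{\link{minMaxScale}}.
#' @return matrix on the natural scale (degenerate dimensions restored to
#'   their constant value).
#' @export
minMaxInvert <- function(scaled, scaling) {
  out <- sweep(scaled, 2, scaling$max - scaling$min, "*")
  sweep(out, 2, scaling$min, "+")
}

#' Cluster an ensemble with a Gaussian mixture model
#'
#' Fits Gaussian mixtures to the min-max-scaled parameter vectors over a
#' range of component counts and covariance structures, selects the best
#' model by BIC (via \code{mclust::Mclust}), assigns each model to its
#' maximum-responsibility component, and stores one regularized covariance
#' matrix per cluster.
#'
#' @param ensemble an \code{\linkS4class{Ensemble}}.
#' @param G integer vector of component counts to consider (default 1:20,
#'   clamped to the number of models).
#' @param modelNames optional mclust covariance-structure set (default:
#'   mclust's own default search over spherical/diagonal/full families).
#' @param epsilon ridge added to each covariance diagonal before use
#'   (default 1e-6 on the scaled space).
#' @return a \code{\linkS4class{ClusteredEnsemble}}.
#' @export
clusterModels <- function(ensemble, G = 1:20, modelNames = NULL,
                          epsilon = 1e-6) {
  stopifnot(nmodels(ensemble) >= 1)
  sc <- minMaxScale(ensemble)
  m <- sc$scaled
  D <- ncol(m)
  M <- nrow(m)
  if (M < 2L || max(apply(m, 2, function(v) diff(range(v)))) == 0) {
    ## degenerate: a single point mass
    labels <- rep(1L, M)
    covs <- list(diag(epsilon, D))
  } else {
    G <- G[G <= M]
    fit <- Mclust(m, G = G, modelNames = modelNames,
                          verbose = FALSE)
    if (is.null(fit)) stop("mclust failed to fit any mixture model")
    labels <- as.integer(fit$classification)
    covs <- .mclustCovariances(fit, D)
  }
  covs <- lapply(covs, function(S) {
    S <- (S + t(S)) / 2 + diag(epsilon, D)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch))
      stop("singular cluster covariance after regularization")
    S
  })
  new("ClusteredEnsemble", ensemble = ensemble, scaled = m,
      scaling = sc[c("min", "max")], labels = labels, covariances = covs)
}

## extract per-component DxD covariance matrices from an Mclust fit
.mclustCovariances <- function(fit, D) {
  G <- fit$G
  v <- fit$parameters$variance
  if (!is.null(v$sigma)) {
    sig <- v$sigma
    if (length(dim(sig)) == 3L)
      return(lapply(seq_len(G), function(g) sig[, , g]))
    return(lapply(seq_len(G), function(g) as.matrix(sig)))
  }
  if (!is.null(v$sigmasq)) {
    s2 <- rep(v$sigmasq, length.out = G)
    return(lapply(seq_len(G), function(g) diag(s2[g], D)))
  }
  stop("cannot extract covariance matrices from mclust fit")
}

## log multivariate normal densities of `points` (P x D) against `means`
## (n x D) under shared covariance `S`; returns P x n matrix of log densities
.logMvnCross <- function(points, means, S) {
  R <- chol(S)
  zP <- points %*% backsolve(R, diag(nrow(R)))
  zM <- means %*% backsolve(R, diag(nrow(R)))
  d2 <- outer(rowSums(zP^2), rowSums(zM^2), "+") - 2 * tcrossprod(zP, zM)
  d2[d2 < 0] <- 0
  logConst <- -0.5 * ncol(points) * log(2 * pi) - sum(log(diag(R)))
  logConst - d2 / 2
}

## Evaluate the cluster-balanced mixture density at `points` for the
## distribution restricted to the models indexed by `keep` (the full
## ensemble when keep covers all models).  Surviving clusters get uniform
## weight 1/N'; within a cluster the n'_C survivor-centered Gaussians (with
## the cluster's original covariance) get weight 1/n'_C each.
.mixtureDensityAt <- function(clustered, points, keep = NULL) {
  if (is.null(keep)) keep <- seq_len(nrow(clustered@scaled))
  labs <- clustered@labels[keep]
  live <- sort(unique(labs))
  N <- length(live)
  dens <- numeric(nrow(points))
  for (g in live) {
    means <- clustered@scaled[keep[labs == g], , drop = FALSE]
    ld <- .logMvnCross(points, means, clustered@covariances[[g]])
    dens <- dens + (1 / N) * rowMeans(exp(ld))
  }
  dens
}

#' Evaluate the probability density over model space
#'
#' The distribution over models theta is a uniform mixture over clusters, in
#' which cluster C (of n_C models) is itself a uniform mixture of n_C
#' Gaussians centered at its member models with the cluster's shared
#' covariance:
#' \deqn{P(\theta) = \frac{1}{N}\sum_{C=1}^{N}\frac{1}{n_C}
#'   \sum_{i=1}^{n_C} \mathcal{N}(\theta;\mu_{iC},\Sigma_C)}
#' evaluated on the min-max-scaled coordinates.
#'
#' @param clustered a \code{\linkS4class{ClusteredEnsemble}}.
#' @param theta numeric vector (length D) or matrix (rows = points) of
#'   scaled coordinates.
#' @return nonnegative density value(s).
#' @export
mixtureDensity <- function(clustered, theta) {
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  if (ncol(theta) != ncol(clustered@scaled))
    stop("theta dimension must match the ensemble's parameter count")
  .mixtureDensityAt(clustered, theta)
}

## discrete probabilities for the models indexed by `keep`: p_iC is
## proportional to the full mixture density at the model's location, with the
## per-cluster constant chosen so each surviving cluster's mass is 1/N'
.discreteProbs <- function(clustered, keep = NULL) {
  if (is.null(keep)) keep <- seq_len(nrow(clustered@scaled))
  dens <- .mixtureDensityAt(clustered,
                            clustered@scaled[keep, , drop = FALSE], keep)
  labs <- clustered@labels[keep]
  live <- sort(unique(labs))
  N <- length(live)
  p <- numeric(length(keep))
  for (g in live) {
    idx <- labs == g
    tot <- sum(dens[idx])
    if (tot <= 0)
      stop("all model densities in cluster ", g,
           " are numerically zero; cannot normalize")
    p[idx] <- dens[idx] / tot / N
  }
  p
}

#' Discrete model probabilities under the cluster-balanced distribution
#'
#' Each model's probability is proportional to the continuous mixture density
#' at its location (with contributions from all Gaussians of the full
#' mixture, not only its own cluster's), normalized per cluster so that every
#' cluster carries total mass 1/N.
#'
#' @param clustered a \code{\linkS4class{ClusteredEnsemble}}.
#' @return numeric vector of probabilities, one per model, summing to 1.
#' @export
discreteProbabilities <- function(clustered) .discreteProbs(clustered)

#' Entropy of a discrete distribution over models
#'
#' Shannon entropy with base-10 logarithm, \eqn{H = -\sum p \log_{10} p},
#' with the convention 0 log 0 = 0.  H is 0 iff a single model carries all
#' mass; for a single cluster of n equally probable models H = log10(n).
#'
#' @param p numeric probability vector (or a
#'   \code{\linkS4class{FilteredEnsemble}}, whose stored entropy is
#'   returned).
#' @return nonnegative entropy in base-10 units.
#' @export
entropyOf <- function(p) {
  if (is(p, "FilteredEnsemble")) return(p@entropy)
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-6)
  nz <- p > 0
  -sum(p[nz] * log10(p[nz]))
}

## build a FilteredEnsemble (distribution) over the models indexed by `keep`
.makeDistribution <- function(clustered, keep, label) {
  keep <- sort(as.integer(keep))
  p <- .discreteProbs(clustered, keep)
  new("FilteredEnsemble", clustered = clustered, keep = keep,
      probabilities = p, entropy = entropyOf(p), label = label)
}

#' Restrict the distribution to a subset of models
#'
#' Rebuilds the cluster-balanced distribution over the given surviving
#' models using the update rules applied after an experiment: original
#' cluster assignments and covariances are retained, clusters left empty are
#' dropped, surviving clusters are re-equalized to weight 1/N', and each
#' cluster's Gaussians are re-centered on its survivors.  This is the
#' distribution-side of \code{\link{filterEnsemble}}, exposed for direct
#' use.
#'
#' @param clustered a \code{\linkS4class{ClusteredEnsemble}}.
#' @param keep integer indices of surviving models.
#' @param label distribution label.
#' @return a \code{\linkS4class{FilteredEnsemble}}.
#' @export
restrictEnsemble <- function(clustered, keep, label = "restricted")
  .makeDistribution(clustered, keep, label)

#' Distribution over the full (wild-type) ensemble
#'
#' Convenience wrapper building the unfiltered cluster-balanced distribution:
#' discrete probabilities and entropy over all models of the clustered
#' ensemble.
#'
#' @param clustered a \code{\linkS4class{ClusteredEnsemble}}.
#' @param label distribution label (default "wild-type").
#' @return a \code{\linkS4class{FilteredEnsemble}} with every model kept.
#' @export
ensembleDistribution <- function(clustered, label = "wild-type")
  .makeDistribution(clustered, seq_len(nrow(clustered@scaled)), label)
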