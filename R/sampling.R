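## Parameter-space declaration and stratified uniform sampling.

#' Default parameter space for a scenario
#'
#' Builds bounds and scales for every free parameter: binding constants
#' \code{K} on a log scale, activator potencies \code{alpha > 1} on a linear
#' scale, repressor potencies \code{alpha <= 1} on a log scale, cooperativity
#' weights linear, the basal weight \code{q_btm} on a log scale, and
#' attenuation factors linear in (0, 1].
#'
#' @param scenario a \code{\linkS4class{Scenario}}.
#' @param kRange,actRange,repRange,coopRange,qbtmRange,attenRange length-2
#'   numeric bounds for the respective parameter groups.
#' @return a \code{\linkS4class{ParameterSpace}} covering
#'   \code{\link{parameterNames}(scenario)}.
#' @export
defaultParameterSpace <- function(scenario,
                                  kRange = c(0.01, 100),
                                  actRange = c(1, 50),
                                  repRange = c(0.001, 1),
                                  coopRange = c(1, 20),
                                  qbtmRange = c(1e-4, 1),
                                  attenRange = c(0.01, 1)) {
  nms <- parameterNames(scenario)
  roles <- setNames(vapply(scenario@tfs, function(tf) tf@role, ""),
                    tfNames(scenario))
  lower <- upper <- numeric(length(nms))
  scale <- character(length(nms))
  for (i in seq_along(nms)) {
    nm <- nms[i]
    if (startsWith(nm, "K_")) {
      rng <- kRange; sc <- "log"
    } else if (startsWith(nm, "alpha_")) {
      tf <- sub("^alpha_", "", nm)
      if (roles[[tf]] == "activator") { rng <- actRange; sc <- "linear" }
      else { rng <- repRange; sc <- "log" }
    } else if (startsWith(nm, "coop_")) {
      rng <- coopRange; sc <- "linear"
    } else if (nm == "q_btm") {
      rng <- qbtmRange; sc <- "log"
    } else {                             # atten_*
      rng <- attenRange; sc <- "linear"
    }
    lower[i] <- rng[1]; upper[i] <- rng[2]; scale[i] <- sc
  }
  ParameterSpace(nms, lower, upper, scale)
}

.toScale <- function(x, scale) ifelse(scale == "log", log(x), x)
.fromScale <- function(x, scale) ifelse(scale == "log", exp(x), x)

## matrix versions (columns = dimensions)
.toScaleMat <- function(m, scale) {
  for (j in which(scale == "log")) m[, j] <- log(m[, j])
  m
}
.fromScaleMat <- function(m, scale) {
  for (j in which(scale == "log")) m[, j] <- exp(m[, j])
  m
}

#' Size of a stratified sampling plan
#'
#' The sampling scheme splits every dimension's range into two halves on its
#' declared scale and draws the same number of points uniformly in each of
#' the \code{2^D} cells.  This function computes the total number of models
#' the plan generates without materializing any samples; for the 13-parameter
#' configuration with 1000 samples per cell it is 2^13 x 1000 = 8,192,000.
#'
#' @param space a \code{\linkS4class{ParameterSpace}}.
#' @param samplesPerCell number of points per half-range cell.
#' @return total sample count as a double (may exceed integer range).
#' @export
gridSampleCount <- function(space, samplesPerCell) {
  stopifnot(samplesPerCell >= 1)
  2^nparameters(space) * as.numeric(samplesPerCell)
}

#' Stratified uniform sampling of parameter space
#'
#' Divides each dimension's range into two halves (on the declared log or
#' linear scale) and samples \code{samplesPerCell} points uniformly within
#' every cell of the resulting \code{2^D} grid, so that every corner region
#' of the space is represented.  Reproducible given \code{seed}.
#'
#' @param space a \code{\linkS4class{ParameterSpace}}.
#' @param samplesPerCell points drawn per cell (>= 1).
#' @param seed integer seed.
#' @param maxModels refuse plans whose total exceeds this budget (default
#'   2e6); reduce \code{samplesPerCell} or the dimensionality for larger
#'   plans, or raise the budget explicitly.
#' @return matrix of \code{2^D * samplesPerCell} rows (parameter vectors on
#'   the natural scale), columns named after the space's parameters.
#' @export
sampleParameterGrid <- function(space, samplesPerCell, seed,
                                maxModels = 2e6) {
  total <- gridSampleCount(space, samplesPerCell)
  if (total > maxModels)
    stop("sampling plan of ", format(total, big.mark = ","),
         " models exceeds the budget of ", format(maxModels, big.mark = ","),
         "; reduce samplesPerCell or dimensionality, or raise maxModels")
  D <- nparameters(space)
  lo <- .toScale(space@lower, space@scale)
  hi <- .toScale(space@upper, space@scale)
  mid <- (lo + hi) / 2
  cells <- as.matrix(expand.grid(rep(list(0:1), D)))[, seq_len(D),
                                                     drop = FALSE]
  set.seed(as.integer(seed))
  total <- as.integer(total)
  u <- matrix(runif(total * D), total, D)
  cellIdx <- rep(seq_len(nrow(cells)), each = samplesPerCell)
  half <- cells[cellIdx, , drop = FALSE]
  cellLo <- sweep(half, 2, mid - lo, "*")
  cellLo <- sweep(cellLo, 2, lo, "+")
  width <- matrix((hi - lo) / 2, total, D, byrow = TRUE)
  x <- cellLo + u * width
  x <- .fromScaleMat(x, space@scale)
  colnames(x) <- space@parameters
  x
}
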