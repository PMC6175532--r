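## Thermodynamic sequence-to-expression model: site annotation, the
## configuration-sum readout, and goodness-of-fit scoring.

.BASES <- c("A", "C", "G", "T")

## integer encoding of a DNA sequence; N and other ambiguity codes -> NA
.encodeSequence <- function(sequence) {
  chars <- strsplit(as.character(sequence), "")[[1]]
  bad <- !chars %in% c(.BASES, "N")
  if (any(bad))
    stop("invalid sequence character(s): ",
         paste(unique(chars[bad]), collapse = ", "))
  match(chars, .BASES)
}

#' Annotate motif matches on both strands of a sequence
#'
#' Scores every window of the sequence (and its reverse complement) against
#' the motif's log-likelihood ratio (LLR, natural log) relative to the
#' background composition, and returns the windows scoring at least
#' \code{llrFraction} times the maximal attainable score.  The relative
#' affinity of a site is \code{exp(llr - llr_max)}, the ratio of its
#' statistical weight to that of the optimal site.
#'
#' @param sequence character or \code{DNAString}; letters A, C, G, T, N.
#'   Windows containing N are skipped.
#' @param motif a \code{\linkS4class{Motif}}.
#' @param llrFraction keep windows with LLR >= \code{llrFraction * llr_max};
#'   must be in (0, 1].
#' @return data.frame with columns \code{tf}, \code{start}, \code{end}
#'   (1-based, closed interval on the forward strand), \code{strand}
#'   (\code{"+"}/\code{"-"}), \code{llr}, and \code{rel_affinity}, sorted by
#'   \code{start}.
#' @examples
#' m <- Motif("ac", rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)), pseudocount = 0.01)
#' scanSites("ACGT", m, 0.9)
#' @export
scanSites <- function(sequence, motif, llrFraction = 0.5) {
  stopifnot(is(motif, "Motif"))
  if (llrFraction <= 0 || llrFraction > 1)
    stop("llrFraction must be in (0, 1]")
  enc <- .encodeSequence(sequence)
  L <- motifLength(motif)
  n <- length(enc) - L + 1L
  empty <- data.frame(tf = character(), start = integer(), end = integer(),
                      strand = character(), llr = numeric(),
                      rel_affinity = numeric())
  if (n < 1L) return(empty)
  S <- log(motif@matrix / rep(motif@background, each = L))
  llrMax <- sum(apply(S, 1, max))
  ## reverse-complement score matrix: scoring the forward bases with Src
  ## equals scoring the reverse complement of the window with S
  Src <- S[L:1, 4:1, drop = FALSE]
  scoreStrand <- function(mat) {
    sc <- numeric(n)
    for (i in seq_len(L)) {
      col <- mat[i, ][enc[i:(i + n - 1L)]]
      sc <- sc + col        # NA from N propagates
    }
    sc
  }
  fwd <- scoreStrand(S)
  rev <- scoreStrand(Src)
  thr <- llrFraction * llrMax
  hits <- function(sc, strand) {
    keep <- which(!is.na(sc) & sc >= thr)
    if (!length(keep)) return(empty)
    data.frame(tf = motif@name, start = keep, end = keep + L - 1L,
               strand = strand, llr = sc[keep],
               rel_affinity = exp(sc[keep] - llrMax))
  }
  out <- rbind(hits(fwd, "+"), hits(rev, "-"))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## scan all TF motifs of a scenario; one row per (TF, window, strand) match
annotateScenarioSites <- function(scenario) {
  res <- lapply(scenario@tfs, function(tf)
    scanSites(scenario@sequence, tf@motif, scenario@siteThreshold))
  for (i in seq_along(res)) if (nrow(res[[i]]))
    res[[i]]$tf <- scenario@tfs[[i]]@name
  out <- do.call(rbind, res)
  if (is.null(out) || !nrow(out)) return(
    data.frame(tf = character(), start = integer(), end = integer(),
               strand = character(), llr = numeric(),
               rel_affinity = numeric()))
  out <- out[order(out$start, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Names of the free parameters of a scenario's model
#'
#' The model has one binding parameter \code{K_<tf>} and one potency
#' \code{alpha_<tf>} per TF, one cooperativity weight \code{coop_<a>_<b>} per
#' declared pair, the basal-machinery weight \code{q_btm}, and one
#' \code{atten_<tf>} per TF carrying an attenuation mask.  The dimensionality
#' is therefore 2 #TF + #pairs + 1 + #attenuated (13 for the ind
#' configuration: five TFs, one cooperativity, one attenuation).
#'
#' @param scenario a \code{\linkS4class{Scenario}}.
#' @return character vector of parameter names in canonical order.
#' @export
parameterNames <- function(scenario) {
  nm <- tfNames(scenario)
  atten <- nm[vapply(scenario@tfs,
                     function(tf) length(tf@attenuationMask) > 0, NA)]
  coop <- character(0)
  if (nrow(scenario@coopPairs))
    coop <- paste0("coop_", scenario@coopPairs$tf1, "_",
                   scenario@coopPairs$tf2)
  c(paste0("K_", nm), paste0("alpha_", nm), coop, "q_btm",
    if (length(atten)) paste0("atten_", atten))
}

## Precompute everything about a scenario that does not depend on parameters:
## site geometry, relative affinities, per-bin concentration rows, the
## adjacency-compatible predecessor lists, and cooperativity pair slots.
.scenarioEngine <- function(scenario, sites = siteTable(scenario)) {
  B <- nbins(scenario)
  nS <- nrow(sites)
  tfIdx <- match(sites$tf, tfNames(scenario))
  if (nS && anyNA(tfIdx)) stop("site table references unknown TFs")
  conc <- do.call(rbind, lapply(scenario@tfs, function(tf) tf@concentration))
  attenOf <- vapply(scenario@tfs,
                    function(tf) length(tf@attenuationMask) > 0, NA)
  masks <- lapply(scenario@tfs, function(tf) tf@attenuationMask)
  ## base[i, b] = rel_affinity_i * conc_tf(i)[b]
  base <- if (nS) sites$rel_affinity * conc[tfIdx, , drop = FALSE] else
    matrix(0, 0, B)
  ## cooperativity: pairIdx[j, i] > 0 when sites j < i (sorted by start) are
  ## non-overlapping, within range, and their TFs form a declared pair
  ord <- if (nS) order(sites$start, sites$end) else integer(0)
  sites <- sites[ord, , drop = FALSE]
  tfIdx <- tfIdx[ord]
  base <- base[ord, , drop = FALSE]
  coopName <- matrix("", nS, nS)
  compat <- matrix(FALSE, nS, nS)
  if (nS > 1) {
    pairKey <- character(0)
    if (nrow(scenario@coopPairs))
      pairKey <- c(paste(scenario@coopPairs$tf1, scenario@coopPairs$tf2),
                   paste(scenario@coopPairs$tf2, scenario@coopPairs$tf1))
    pairLab <- c(paste0("coop_", scenario@coopPairs$tf1, "_",
                        scenario@coopPairs$tf2),
                 paste0("coop_", scenario@coopPairs$tf1, "_",
                        scenario@coopPairs$tf2))
    names(pairLab) <- pairKey
    nmv <- tfNames(scenario)
    for (i in 2:nS) for (j in 1:(i - 1L)) {
      if (sites$end[j] < sites$start[i]) {
        compat[j, i] <- TRUE
        gap <- sites$start[i] - sites$end[j] - 1L
        key <- paste(nmv[tfIdx[j]], nmv[tfIdx[i]])
        if (gap <= scenario@coopRange && key %in% pairKey)
          coopName[j, i] <- pairLab[[key]]
      }
    }
  }
  list(B = B, nS = nS, sites = sites, tfIdx = tfIdx, base = base,
       attenOf = attenOf, masks = masks, compat = compat,
       coopName = coopName, tfNames = tfNames(scenario),
       roles = vapply(scenario@tfs, function(tf) tf@role, ""))
}

## per-site, per-bin statistical weights q_i(b) for one parameter vector
.siteWeights <- function(engine, params) {
  if (!engine$nS) return(matrix(0, 0, engine$B))
  K <- params[paste0("K_", engine$tfNames[engine$tfIdx])]
  q <- K * engine$base
  for (i in seq_len(engine$nS)) {
    t <- engine$tfIdx[i]
    if (engine$attenOf[t]) {
      att <- params[[paste0("atten_", engine$tfNames[t])]]
      q[i, engine$masks[[t]]] <- q[i, engine$masks[[t]]] * att
    }
  }
  q
}

## Configuration sum over all subsets of mutually compatible (non-overlapping)
## sites, with adjacency cooperativity, computed by dynamic programming
## jointly over all bins.  q is nS x B; w[j, i] is the pairwise weight for
## adjacent bound sites j then i (1 when not cooperating).
.configSum <- function(q, compat, w) {
  nS <- nrow(q)
  B <- ncol(q)
  if (!nS) return(rep(1, B))
  Zlast <- matrix(0, nS, B)
  for (i in seq_len(nS)) {
    acc <- rep(1, B)
    js <- which(compat[, i])
    for (j in js) acc <- acc + Zlast[j, ] * w[j, i]
    Zlast[i, ] <- q[i, ] * acc
  }
  1 + colSums(Zlast)
}

.checkParams <- function(params, needed) {
  if (is.null(names(params))) stop("parameter vector must be named")
  missing <- setdiff(needed, names(params))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  if (any(!is.finite(params[needed])) || any(params[needed] <= 0))
    stop("all parameters must be finite and strictly positive")
}

#' Predict the expression profile of a scenario under one model
#'
#' Implements the configuration-sum thermodynamic readout.  In bin b each
#' annotated site i of TF t carries weight
#' \code{q_i(b) = K_t * c_t(b) * rel_affinity_i * atten_t(b)}; a
#' configuration c of mutually compatible (non-overlapping) bound sites has
#' weight \code{W(c) = prod q_i * prod w} over adjacent cooperating pairs;
#' \code{Z_off = sum W(c)}, \code{Z_on = q_btm * sum W(c) * prod alpha_i},
#' and the predicted expression is \code{Z_on / (Z_on + Z_off)}.  The sums
#' run over all configurations (the empty one included, with weight 1) and
#' are computed by dynamic programming over sites sorted by position.
#'
#' @param scenario a \code{\linkS4class{Scenario}}.
#' @param params named numeric parameter vector covering
#'   \code{\link{parameterNames}(scenario)}; all entries strictly positive.
#' @param sites optional replacement site table (used for site-mutagenesis
#'   perturbations); defaults to the scenario's annotated sites.
#' @return numeric vector of predicted expression per bin, values in [0, 1].
#' @examples
#' sc <- makeToyScenario(1)
#' pred <- predictProfile(sc, groundTruth(sc))
#' range(pred)
#' @export
predictProfile <- function(scenario, params, sites = NULL) {
  engine <- if (is.null(sites)) .scenarioEngine(scenario) else
    .scenarioEngine(scenario, sites)
  .predictProfileEngine(engine, params)
}

.predictProfileEngine <- function(engine, params) {
  siteTFs <- unique(engine$tfNames[engine$tfIdx])
  attenTFs <- intersect(siteTFs, engine$tfNames[engine$attenOf])
  needed <- c("q_btm",
              if (length(siteTFs)) c(paste0("K_", siteTFs),
                                     paste0("alpha_", siteTFs)),
              unique(engine$coopName[engine$coopName != ""]),
              if (length(attenTFs)) paste0("atten_", attenTFs))
  .checkParams(params, needed)
  q <- .siteWeights(engine, params)
  nS <- engine$nS
  w <- matrix(1, nS, nS)
  if (nS) {
    hasCoop <- engine$coopName != ""
    if (any(hasCoop)) w[hasCoop] <- params[engine$coopName[hasCoop]]
  }
  zOff <- .configSum(q, engine$compat, w)
  alpha <- params[paste0("alpha_", engine$tfNames[engine$tfIdx])]
  zOnSum <- .configSum(q * alpha, engine$compat, w)
  qbtm <- params[["q_btm"]]
  zOn <- qbtm * zOnSum
  zOn / (zOn + zOff)
}

#' @describeIn predictProfile predicted expression in a single bin.
#' @param bin 1-based bin index.
#' @export
predictExpression <- function(scenario, params, bin, sites = NULL) {
  if (bin < 1 || bin > nbins(scenario)) stop("bin out of range")
  predictProfile(scenario, params, sites)[bin]
}

#' Goodness of fit between two expression profiles
#'
#' Mean of squared per-bin differences, so that thresholds quoted as
#' percentages of the [0, 1] expression scale ("SSE below 10\%") read
#' directly as 0.10.
#'
#' @param predicted,observed numeric profiles of equal length.
#' @return nonnegative scalar; 0 iff the profiles are identical.
#' @export
sseScore <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("profiles must have equal length")
  mean((predicted - observed)^2)
}
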