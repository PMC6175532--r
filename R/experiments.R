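## Perturbation experiments: perturbation operators, consistency criteria,
## ensemble filtering with the distribution update rules, information gain,
## and the derived reports.

#' Perturbation descriptors
#'
#' Constructors for the three supported perturbation operators.
#' \code{tfKnockout} zeroes the concentration profile of every TF whose
#' underlying protein matches (so a factor modeled with split
#' activator/repressor roles is knocked out as one protein).
#' \code{siteMutagenesis} removes annotated binding site(s) of a TF, either
#' the strongest \code{k} (ranked by relative affinity, i.e. site weight at
#' reference concentration 1) or explicitly listed start positions.
#' \code{variantEnhancer} replaces the enhancer sequence and re-annotates all
#' sites.
#'
#' @param protein protein name to knock out.
#' @return a perturbation descriptor list for
#'   \code{\link{PerturbationExperiment}}.
#' @export
tfKnockout <- function(protein)
  list(type = "knockout", protein = as.character(protein))

#' @rdname tfKnockout
#' @param tf TF whose sites are mutated.
#' @param strongest number of strongest sites to remove (ignored when
#'   \code{positions} is given).
#' @param positions optional explicit site start positions to remove.
#' @export
siteMutagenesis <- function(tf, strongest = 1, positions = NULL)
  list(type = "site_mutagenesis", tf = as.character(tf),
       strongest = strongest, positions = positions)

#' @rdname tfKnockout
#' @param sequence replacement enhancer sequence.
#' @export
variantEnhancer <- function(sequence)
  list(type = "variant_enhancer", sequence = as.character(sequence))

#' Consistency criteria
#'
#' Constructors for the machine-checkable criteria that decide whether a
#' model's perturbed prediction is consistent with an experiment's observed
#' outcome.  \code{criterionUnchanged}: the prediction matches the wild-type
#' profile (score < threshold).  \code{criterionProfileMatch}: the prediction
#' matches a given target profile.  \code{criterionPeakFraction}: the ratio
#' of predicted peak to wild-type peak falls in a window (e.g. [0.35, 0.65]
#' encodes "peak reduces to about half").  \code{criterionBoundaryShift}:
#' the half-maximum boundary crossing on the stated side moves by at least
#' \code{minBins} bins in the stated direction (encodes "expression expands
#' dorsally/ventrally").  \code{criterionAbolished}: predicted peak at or
#' below a low ceiling.
#'
#' @param threshold mean-squared-error threshold.
#' @return a criterion descriptor list for
#'   \code{\link{PerturbationExperiment}}.
#' @export
criterionUnchanged <- function(threshold = 0.05)
  list(kind = "unchanged", threshold = threshold)

#' @rdname criterionUnchanged
#' @param target numeric profile the prediction must match.
#' @export
criterionProfileMatch <- function(target, threshold = 0.05)
  list(kind = "profile_match", target = as.numeric(target),
       threshold = threshold)

#' @rdname criterionUnchanged
#' @param lo,hi window bounds for the peak ratio.
#' @export
criterionPeakFraction <- function(lo, hi) {
  stopifnot(lo <= hi)
  list(kind = "peak_fraction", lo = lo, hi = hi)
}

#' @rdname criterionUnchanged
#' @param side \code{"dorsal"} (toward bin B) or \code{"ventral"} (toward
#'   bin 1).
#' @param minBins minimum boundary displacement in bins.
#' @export
criterionBoundaryShift <- function(side = c("dorsal", "ventral"),
                                   minBins = 2) {
  side <- match.arg(side)
  stopifnot(minBins > 0)
  list(kind = "boundary_shift", side = side, minBins = minBins)
}

#' @rdname criterionUnchanged
#' @param maxLevel expression ceiling for an abolished pattern.
#' @export
criterionAbolished <- function(maxLevel = 0.1)
  list(kind = "abolished", maxLevel = maxLevel)

#' @rdname criterionUnchanged
#' @export
criterionAcceptAll <- function() list(kind = "accept_all")

#' Apply a perturbation to a scenario
#'
#' Returns a modified copy of the scenario: a knockout zeroes the matching
#' protein's concentration profile(s); site mutagenesis removes the selected
#' annotated site(s); a variant enhancer replaces the sequence and
#' re-annotates sites at the scenario's threshold.  The input scenario is
#' untouched.
#'
#' @param scenario a \code{\linkS4class{Scenario}}.
#' @param perturbation descriptor from \code{\link{tfKnockout}},
#'   \code{\link{siteMutagenesis}}, or \code{\link{variantEnhancer}}.
#' @return the perturbed \code{\linkS4class{Scenario}}.
#' @export
applyPerturbation <- function(scenario, perturbation) {
  type <- perturbation$type
  if (is.null(type)) stop("perturbation must have a type")
  if (type == "none") return(scenario)
  if (type == "knockout") {
    hit <- vapply(scenario@tfs,
                  function(tf) tf@protein == perturbation$protein, NA)
    if (!any(hit)) stop("no TF with protein '", perturbation$protein, "'")
    for (i in which(hit))
      scenario@tfs[[i]]@concentration[] <- 0
    return(scenario)
  }
  if (type == "site_mutagenesis") {
    sites <- scenario@sites
    mine <- which(sites$tf == perturbation$tf)
    if (!length(mine))
      stop("no annotated site for TF '", perturbation$tf, "'")
    if (!is.null(perturbation$positions)) {
      drop <- mine[sites$start[mine] %in% perturbation$positions]
      if (length(drop) < length(perturbation$positions))
        stop("some requested site positions do not match annotated sites")
    } else {
      k <- min(perturbation$strongest, length(mine))
      drop <- mine[order(-sites$rel_affinity[mine])[seq_len(k)]]
    }
    scenario@sites <- sites[-drop, , drop = FALSE]
    return(scenario)
  }
  if (type == "variant_enhancer") {
    scenario@sequence <- DNAString(toupper(perturbation$sequence))
    scenario@sites <- annotateScenarioSites(scenario)
    return(scenario)
  }
  stop("unknown perturbation type: ", type)
}

## outermost crossing of half the profile's maximum on the stated side,
## with linear interpolation between bins; returns a fractional bin index
.halfMaxCrossing <- function(profile, side) {
  level <- max(profile) / 2
  B <- length(profile)
  above <- profile >= level
  if (!any(above)) return(NA_real_)
  if (side == "dorsal") {
    i <- max(which(above))
    if (i == B) return(as.numeric(B))
    ## descend from bin i to i+1 through `level`
    i + (profile[i] - level) / (profile[i] - profile[i + 1])
  } else {
    i <- min(which(above))
    if (i == 1L) return(1)
    i - (profile[i] - level) / (profile[i] - profile[i - 1])
  }
}

#' Test a prediction against a consistency criterion
#'
#' @param prediction predicted expression profile under the perturbation.
#' @param wildType the wild-type (observed) expression profile.
#' @param criterion a criterion descriptor (see
#'   \code{\link{criterionUnchanged}}).
#' @return logical: is the prediction consistent with the experiment?
#' @export
isConsistent <- function(prediction, wildType, criterion) {
  if (length(prediction) != length(wildType))
    stop("profiles must have equal length")
  kind <- criterion$kind
  if (kind == "accept_all") return(TRUE)
  if (kind == "unchanged")
    return(sseScore(prediction, wildType) < criterion$threshold)
  if (kind == "profile_match")
    return(sseScore(prediction, criterion$target) < criterion$threshold)
  if (kind == "peak_fraction") {
    if (diff(range(wildType)) == 0)
      stop("peak fraction undefined for a flat wild-type profile")
    frac <- max(prediction) / max(wildType)
    return(frac >= criterion$lo && frac <= criterion$hi)
  }
  if (kind == "abolished")
    return(max(prediction) <= criterion$maxLevel)
  if (kind == "boundary_shift") {
    cw <- .halfMaxCrossing(wildType, criterion$side)
    cp <- .halfMaxCrossing(prediction, criterion$side)
    if (is.na(cw) || is.na(cp)) return(FALSE)
    shift <- if (criterion$side == "dorsal") cp - cw else cw - cp
    return(shift >= criterion$minBins)
  }
  stop("unknown criterion kind: ", kind)
}

## candidate survivor indices of a parent (full clustered ensemble or an
## already-filtered ensemble)
.parentKeep <- function(parent) {
  if (is(parent, "FilteredEnsemble")) return(parent@keep)
  if (is(parent, "ClusteredEnsemble"))
    return(seq_len(nrow(parent@scaled)))
  stop("parent must be a ClusteredEnsemble or FilteredEnsemble")
}

.parentClustered <- function(parent)
  if (is(parent, "FilteredEnsemble")) parent@clustered else parent

#' Filter an ensemble by consistency with an experiment
#'
#' Evaluates every candidate model of the parent under the experiment's
#' perturbed scenario, keeps the models whose predictions satisfy the
#' consistency criterion, and rebuilds the probability distribution by (a)
#' retaining the original cluster assignments and cluster covariance
#' matrices, (b) removing clusters left empty and re-equalizing the weights
#' of the surviving N' clusters to 1/N' each, and (c) re-centering each
#' surviving cluster's Gaussian mixture on its surviving models only.
#' Discrete probabilities and entropy are recomputed for the new
#' distribution.
#'
#' @param parent a \code{\linkS4class{ClusteredEnsemble}} or a
#'   \code{\linkS4class{FilteredEnsemble}} (for sequential filtering).
#' @param experiment a \code{\linkS4class{PerturbationExperiment}}.
#' @param scenario the wild-type \code{\linkS4class{Scenario}}.
#' @return a \code{\linkS4class{FilteredEnsemble}}.
#' @export
filterEnsemble <- function(parent, experiment, scenario) {
  clustered <- .parentClustered(parent)
  cand <- .parentKeep(parent)
  perturbed <- applyPerturbation(scenario, experiment@perturbation)
  engine <- .scenarioEngine(perturbed, siteTable(perturbed))
  wt <- targetProfile(scenario)
  params <- modelMatrix(clustered@ensemble)
  ok <- vapply(cand, function(i) {
    pred <- .predictProfileEngine(engine, params[i, ])
    isConsistent(pred, wt, experiment@criterion)
  }, NA)
  if (!any(ok))
    stop("experiment '", experiment@name,
         "' refutes the entire ensemble: no model is consistent")
  .makeDistribution(clustered, cand[ok], experiment@name)
}

#' Information gain of an experiment
#'
#' The difference between the entropy of the distribution over the parent
#' ensemble and that over the ensemble filtered by the experiment, both in
#' base-10 units.  Reported signed: nothing in the construction forbids a
#' negative value.
#'
#' @param hParent entropy of the parent distribution (or a
#'   \code{\linkS4class{FilteredEnsemble}}).
#' @param hFiltered entropy of the filtered distribution (or a
#'   \code{\linkS4class{FilteredEnsemble}}).
#' @return \code{hParent - hFiltered}.
#' @examples
#' informationGain(3.55, 2.91)
#' @export
informationGain <- function(hParent, hFiltered) {
  h1 <- if (is(hParent, "FilteredEnsemble")) hParent@entropy else hParent
  h2 <- if (is(hFiltered, "FilteredEnsemble")) hFiltered@entropy else
    hFiltered
  h1 - h2
}

#' Cluster-survival table across experiments
#'
#' One row per ensemble (the parent first), with per-cluster survivor
#' counts, the total, the entropy, and the information gain relative to the
#' parent -- the layout used to compare how experiments prune mechanistic
#' hypotheses.
#'
#' @param parent the parent \code{\linkS4class{FilteredEnsemble}} (typically
#'   \code{\link{ensembleDistribution}} of the wild-type ensemble).
#' @param ... filtered \code{\linkS4class{FilteredEnsemble}}s sharing the
#'   parent's clustered ensemble.
#' @return data.frame with columns \code{ensemble}, \code{cluster_1} ..
#'   \code{cluster_G}, \code{total}, \code{entropy},
#'   \code{information_gain}.
#' @export
clusterSurvivalTable <- function(parent, ...) {
  filtered <- list(...)
  if (length(filtered) == 1L && is.list(filtered[[1]]) &&
      !is(filtered[[1]], "FilteredEnsemble"))
    filtered <- filtered[[1]]
  all <- c(list(parent), filtered)
  for (fe in all)
    if (!identical(fe@clustered, parent@clustered))
      stop("all filtered ensembles must share the parent's clustering")
  G <- nclusters(parent@clustered)
  rows <- lapply(all, function(fe) {
    counts <- clusterCounts(fe)
    data.frame(ensemble = fe@label,
               as.list(setNames(counts, paste0("cluster_", seq_len(G)))),
               total = sum(counts), entropy = fe@entropy,
               information_gain = informationGain(parent, fe))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sequential information-gain matrix
#'
#' Entry (i, j) is the information gain of experiment j when performed after
#' experiment i: entropy(filtered by i) - entropy(filtered by i then j),
#' with the same distribution update rules applied at each stage.  Diagonal
#' entries are 0 because refiltering with the same deterministic criterion
#' removes nothing.  Entries where the intermediate ensemble is empty are
#' \code{NA}.
#'
#' @param experiments list of
#'   \code{\linkS4class{PerturbationExperiment}}s.
#' @param parent a \code{\linkS4class{ClusteredEnsemble}} or
#'   \code{\linkS4class{FilteredEnsemble}}.
#' @param scenario the wild-type \code{\linkS4class{Scenario}}.
#' @return numeric matrix with experiment names on both dimensions.
#' @export
sequentialGainMatrix <- function(experiments, parent, scenario) {
  n <- length(experiments)
  nms <- vapply(experiments, function(e) e@name, "")
  out <- matrix(NA_real_, n, n, dimnames = list(first = nms, second = nms))
  for (i in seq_len(n)) {
    fi <- tryCatch(filterEnsemble(parent, experiments[[i]], scenario),
                   error = function(e) NULL)
    if (is.null(fi)) next
    for (j in seq_len(n)) {
      fij <- tryCatch(filterEnsemble(fi, experiments[[j]], scenario),
                      error = function(e) NULL)
      if (!is.null(fij)) out[i, j] <- informationGain(fi, fij)
    }
  }
  out
}

#' Probability-weighted aggregate prediction of an ensemble
#'
#' Per-bin mean and variance of the member models' predicted profiles,
#' weighted by the distribution's discrete probabilities.  The variance
#' quantifies the ensemble's uncertainty about the prediction.
#'
#' @param distribution a \code{\linkS4class{FilteredEnsemble}}.
#' @param scenario the \code{\linkS4class{Scenario}} to predict (perturbed
#'   or wild-type).
#' @return list with numeric vectors \code{mean} and \code{variance}.
#' @export
aggregatePrediction <- function(distribution, scenario) {
  clustered <- distribution@clustered
  engine <- .scenarioEngine(scenario, siteTable(scenario))
  params <- modelMatrix(clustered@ensemble)
  preds <- t(vapply(distribution@keep, function(i)
    .predictProfileEngine(engine, params[i, ]),
    numeric(nbins(scenario))))
  p <- distribution@probabilities
  mu <- colSums(preds * p)
  v <- colSums(sweep(preds, 2, mu)^2 * p)
  list(mean = mu, variance = v)
}

#' Cross-experiment interpretation report
#'
#' Compares how the parent ensemble and the ensemble filtered by experiment
#' A predict the outcome of experiment B's perturbation -- the device used
#' to articulate *what* was learned from A.  Returns both aggregate
#' predictions and the per-bin variance reduction.
#'
#' @param experimentA,experimentB
#'   \code{\linkS4class{PerturbationExperiment}}s.
#' @param parent a \code{\linkS4class{ClusteredEnsemble}} or
#'   \code{\linkS4class{FilteredEnsemble}}.
#' @param scenario the wild-type \code{\linkS4class{Scenario}}.
#' @return list with \code{parent} and \code{filtered} aggregate predictions
#'   (each mean + variance) and \code{varianceReduction} per bin.
#' @export
crossPredict <- function(experimentA, experimentB, parent, scenario) {
  clustered <- .parentClustered(parent)
  parentDist <- if (is(parent, "FilteredEnsemble")) parent else
    ensembleDistribution(clustered)
  filtered <- filterEnsemble(parent, experimentA, scenario)
  scenB <- applyPerturbation(scenario, experimentB@perturbation)
  aggP <- aggregatePrediction(parentDist, scenB)
  aggF <- aggregatePrediction(filtered, scenB)
  list(parent = aggP, filtered = aggF,
       varianceReduction = aggP$variance - aggF$variance)
}

#' Select a synthetic true model jointly consistent with experiments
#'
#' Successively filters the parent ensemble by each experiment's criterion,
#' skipping (and reporting) any experiment that would refute every remaining
#' model, and returns the best-fitting surviving model.  This mirrors the
#' search for a single ensemble member that reproduces the known outcomes of
#' as many perturbation experiments as possible.
#'
#' @param parent a \code{\linkS4class{ClusteredEnsemble}} or
#'   \code{\linkS4class{FilteredEnsemble}}.
#' @param experiments list of
#'   \code{\linkS4class{PerturbationExperiment}}s.
#' @param scenario the wild-type \code{\linkS4class{Scenario}}.
#' @return list with \code{params} (named vector of the selected model),
#'   \code{index} (its row in the ensemble), \code{sse},
#'   \code{satisfied} and \code{unsatisfied} experiment names.
#' @export
selectSyntheticTrueModel <- function(parent, experiments, scenario) {
  stopifnot(length(experiments) >= 1)
  clustered <- .parentClustered(parent)
  current <- if (is(parent, "FilteredEnsemble")) parent else
    ensembleDistribution(clustered)
  satisfied <- character(0)
  unsatisfied <- character(0)
  for (e in experiments) {
    nxt <- tryCatch(filterEnsemble(current, e, scenario),
                    error = function(err) NULL)
    if (is.null(nxt)) unsatisfied <- c(unsatisfied, e@name)
    else {
      current <- nxt
      satisfied <- c(satisfied, e@name)
    }
  }
  sse <- sseScores(clustered@ensemble)[current@keep]
  best <- current@keep[which.min(sse)]
  list(params = modelMatrix(clustered@ensemble)[best, ], index = best,
       sse = min(sse), satisfied = satisfied, unsatisfied = unsatisfied)
}
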