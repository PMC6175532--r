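#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet writeXStringSet reverseComplement
#' @importFrom mclust Mclust mclustBIC
#' @importFrom stats optim runif rnorm setNames var
#' @importFrom utils read.table write.table head
NULL

#' Position weight matrix for a transcription factor
#'
#' A \code{Motif} holds an L x 4 matrix of per-position base frequencies
#' (columns A, C, G, T) together with the background base composition against
#' which log-likelihood-ratio (LLR) site scores are computed.  Count matrices
#' are converted to frequencies with a pseudocount at construction.
#'
#' @slot name identifier of the motif (usually the TF name).
#' @slot matrix L x 4 numeric matrix of base frequencies; every row sums to 1.
#' @slot background length-4 numeric vector of background base frequencies,
#'   summing to 1, all entries positive.
#' @aliases Motif-class
#' @exportClass Motif
setClass("Motif",
  representation(name = "character", matrix = "matrix", background = "numeric"))

setValidity("Motif", function(object) {
  m <- object@matrix
  if (nrow(m) < 1L || ncol(m) != 4L)
    return("motif matrix must have >= 1 row and exactly 4 columns (A,C,G,T)")
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-6))
    return("motif matrix rows must be nonnegative and sum to 1")
  bg <- object@background
  if (length(bg) != 4L || any(bg <= 0) || abs(sum(bg) - 1) > 1e-6)
    return("background must be 4 positive frequencies summing to 1")
  TRUE
})

#' Construct a Motif from a count or frequency matrix
#'
#' @param name motif identifier.
#' @param counts L x 4 numeric matrix of base counts or frequencies, columns
#'   in order A, C, G, T.
#' @param pseudocount small positive value added to every cell before row
#'   normalization.  For matrices that are already normalized frequencies, use
#'   \code{pseudocount = 0} (rows are then re-normalized only if needed).
#' @param background length-4 background base frequencies (A, C, G, T).
#' @return a \code{\linkS4class{Motif}}.
#' @examples
#' m <- Motif("toy", rbind(c(10, 0, 0, 0), c(0, 10, 0, 0)), pseudocount = 1)
#' motifLength(m)
#' @export
Motif <- function(name, counts, pseudocount = 0.5,
                  background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L)
    stop("motif matrix must have 4 columns (A,C,G,T)")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("motif matrix entries must be finite and nonnegative")
  if (any(rowSums(counts) == 0) && pseudocount <= 0)
    stop("motif has an all-zero row and pseudocount is not positive")
  freq <- counts + pseudocount
  freq <- freq / rowSums(freq)
  dimnames(freq) <- list(NULL, c("A", "C", "G", "T"))
  new("Motif", name = as.character(name), matrix = freq,
      background = as.numeric(background))
}

#' @describeIn Motif length (number of positions) of the motif.
#' @param x,object a \code{Motif}.
#' @export
motifLength <- function(x) nrow(x@matrix)

setMethod("show", "Motif", function(object) {
  cons <- paste(c("A", "C", "G", "T")[apply(object@matrix, 1, which.max)],
                collapse = "")
  cat("Motif '", object@name, "': ", motifLength(object),
      " bp, consensus ", cons, "\n", sep = "")
})

#' Transcription factor specification
#'
#' Bundles a TF's regulatory role, its spatial concentration profile along the
#' binned axis (scaled to [0, 1]), its binding motif, and an optional
#' attenuation mask marking bins in which its site weights are multiplied by a
#' free attenuation parameter (the mechanism used for CIC, whose repression is
#' relieved by locally activated ERK in the neuroectoderm).
#'
#' @slot name TF identifier used in parameter names and site annotations.
#' @slot protein name of the underlying protein; two TFSpec entries may share
#'   a protein when a single factor is modeled with two roles (the Su(H)
#'   activator/repressor split).  Knockouts act at the protein level.
#' @slot role \code{"activator"} or \code{"repressor"}.
#' @slot concentration numeric vector of per-bin concentrations in [0, 1].
#' @slot motif a \code{\linkS4class{Motif}}.
#' @slot attenuationMask logical vector (length = bins) flagging bins where
#'   the TF's attenuation parameter applies; \code{logical(0)} when the TF has
#'   no attenuation parameter.
#' @aliases TFSpec-class
#' @exportClass TFSpec
setClass("TFSpec",
  representation(name = "character", protein = "character", role = "character",
                 concentration = "numeric", motif = "Motif",
                 attenuationMask = "logical"))

setValidity("TFSpec", function(object) {
  if (!object@role %in% c("activator", "repressor"))
    return("role must be 'activator' or 'repressor'")
  cc <- object@concentration
  if (any(!is.finite(cc)) || any(cc < 0) || any(cc > 1))
    return("concentration values must lie in [0, 1]")
  if (length(object@attenuationMask) &&
      length(object@attenuationMask) != length(cc))
    return("attenuationMask length must match concentration length")
  TRUE
})

#' Construct a TFSpec
#'
#' @param name TF identifier.
#' @param role \code{"activator"} or \code{"repressor"}.
#' @param concentration per-bin concentration profile in [0, 1].
#' @param motif a \code{\linkS4class{Motif}}.
#' @param protein underlying protein name (defaults to \code{name}).
#' @param attenuationMask optional logical per-bin mask of attenuated bins.
#' @return a \code{\linkS4class{TFSpec}}.
#' @export
TFSpec <- function(name, role, concentration, motif, protein = name,
                   attenuationMask = logical(0)) {
  new("TFSpec", name = as.character(name), protein = as.character(protein),
      role = role, concentration = as.numeric(concentration), motif = motif,
      attenuationMask = as.logical(attenuationMask))
}

setMethod("show", "TFSpec", function(object) {
  cat("TFSpec '", object@name, "' (", object@role, ", protein ",
      object@protein, "), ", length(object@concentration), " bins",
      if (length(object@attenuationMask)) ", attenuated" else "", "\n",
      sep = "")
})

#' Regulatory scenario: enhancer, TFs, and target expression
#'
#' A \code{Scenario} is the complete input to the thermodynamic model: an
#' enhancer sequence, the set of relevant TFs (roles, concentration profiles,
#' motifs), declared cooperativity pairs, the annotated binding sites, and the
#' target expression profile along the binned spatial axis.  Synthetic
#' scenarios may also carry a planted ground-truth parameter vector whose
#' prediction equals the target by construction.
#'
#' @slot name scenario label.
#' @slot sequence enhancer sequence as a \code{DNAString}.
#' @slot tfs list of \code{\linkS4class{TFSpec}}.
#' @slot target numeric target expression profile, values in [0, 1].
#' @slot coopPairs data.frame with columns \code{tf1}, \code{tf2} declaring
#'   cooperativity parameters between bound site pairs of these TFs.
#' @slot coopRange maximum gap (bp) between site footprints for a
#'   cooperativity weight to apply.
#' @slot siteThreshold LLR fraction threshold used to annotate sites.
#' @slot sites data.frame of annotated sites (tf, start, end, strand, llr,
#'   rel_affinity), as returned by \code{\link{scanSites}}.
#' @slot groundTruth named numeric parameter vector, or \code{numeric(0)}.
#' @slot seed integer seed the scenario was generated from (NA for data read
#'   from files).
#' @aliases Scenario-class
#' @exportClass Scenario
setClass("Scenario",
  representation(name = "character", sequence = "DNAString", tfs = "list",
                 target = "numeric", coopPairs = "data.frame",
                 coopRange = "numeric", siteThreshold = "numeric",
                 sites = "data.frame", groundTruth = "numeric",
                 seed = "integer"))

setValidity("Scenario", function(object) {
  B <- length(object@target)
  if (B < 2L) return("target profile must have at least 2 bins")
  if (any(object@target < -1e-9) || any(object@target > 1 + 1e-9))
    return("target values must lie in [0, 1]")
  for (tf in object@tfs) {
    if (!is(tf, "TFSpec")) return("tfs must be a list of TFSpec objects")
    if (length(tf@concentration) != B)
      return("all TF concentration profiles must have the same length as the target")
  }
  nm <- vapply(object@tfs, function(tf) tf@name, "")
  if (anyDuplicated(nm)) return("TF names must be unique")
  if (nrow(object@coopPairs)) {
    if (!all(c("tf1", "tf2") %in% names(object@coopPairs)))
      return("coopPairs needs columns tf1, tf2")
    if (!all(unlist(object@coopPairs[c("tf1", "tf2")]) %in% nm))
      return("coopPairs reference unknown TFs")
  }
  TRUE
})

#' Construct a Scenario
#'
#' Annotates binding sites for every TF motif on both strands of the enhancer
#' at the given LLR fraction threshold and stores them with the scenario.
#'
#' @param name scenario label.
#' @param sequence enhancer sequence (character or \code{DNAString}).
#' @param tfs list of \code{\linkS4class{TFSpec}}.
#' @param target numeric target expression profile in [0, 1].
#' @param coopPairs data.frame with columns \code{tf1}, \code{tf2};
#'   default none.
#' @param coopRange maximum footprint gap (bp) for cooperativity (default 50).
#' @param siteThreshold LLR fraction threshold for site annotation
#'   (default 0.5).
#' @param groundTruth optional named parameter vector.
#' @param seed integer seed recorded for provenance.
#' @return a \code{\linkS4class{Scenario}} with sites annotated.
#' @export
Scenario <- function(name, sequence, tfs, target,
                     coopPairs = data.frame(tf1 = character(),
                                            tf2 = character()),
                     coopRange = 50, siteThreshold = 0.5,
                     groundTruth = numeric(0), seed = NA_integer_) {
  if (!is(sequence, "DNAString")) sequence <- DNAString(toupper(sequence))
  obj <- new("Scenario", name = as.character(name), sequence = sequence,
             tfs = tfs, target = as.numeric(target),
             coopPairs = coopPairs, coopRange = as.numeric(coopRange),
             siteThreshold = as.numeric(siteThreshold),
             sites = data.frame(), groundTruth = groundTruth,
             seed = as.integer(seed))
  obj@sites <- annotateScenarioSites(obj)
  obj
}

#' @describeIn Scenario number of spatial bins.
#' @export
nbins <- function(x) length(x@target)

#' @describeIn Scenario the target expression profile.
#' @export
targetProfile <- function(x) x@target

#' @describeIn Scenario names of the TFs in the scenario.
#' @export
tfNames <- function(x) vapply(x@tfs, function(tf) tf@name, "")

#' @describeIn Scenario the annotated binding-site table.
#' @export
siteTable <- function(x) x@sites

#' @describeIn Scenario the planted ground-truth parameters (or
#'   \code{numeric(0)} if none).
#' @export
groundTruth <- function(x) x@groundTruth

setMethod("show", "Scenario", function(object) {
  cat("Scenario '", object@name, "': ", length(object@sequence),
      " bp enhancer, ", length(object@tfs), " TFs, ", nbins(object),
      " bins, ", nrow(object@sites), " annotated sites",
      if (length(object@groundTruth)) ", ground truth planted" else "",
      "\n", sep = "")
  roles <- vapply(object@tfs, function(tf) tf@role, "")
  cat("  activators: ", paste(tfNames(object)[roles == "activator"],
                              collapse = ", "), "\n", sep = "")
  cat("  repressors: ", paste(tfNames(object)[roles == "repressor"],
                              collapse = ", "), "\n", sep = "")
})

#' Parameter space declaration
#'
#' Names, bounds, and sampling scale (log or linear) for every free parameter
#' of the thermodynamic model.  K parameters, repressor potencies, and the
#' basal-machinery weight are conventionally sampled on a log scale; activator
#' potencies, cooperativity weights, and attenuation factors on a linear
#' scale.
#'
#' @slot parameters character vector of parameter names.
#' @slot lower,upper numeric bounds (natural scale), \code{lower < upper}.
#' @slot scale character vector, each \code{"log"} or \code{"linear"}.
#' @aliases ParameterSpace-class
#' @exportClass ParameterSpace
setClass("ParameterSpace",
  representation(parameters = "character", lower = "numeric",
                 upper = "numeric", scale = "character"))

setValidity("ParameterSpace", function(object) {
  D <- length(object@parameters)
  if (length(object@lower) != D || length(object@upper) != D ||
      length(object@scale) != D)
    return("parameters, lower, upper, scale must have equal length")
  if (any(object@lower >= object@upper))
    return("every lower bound must be < its upper bound")
  if (!all(object@scale %in% c("log", "linear")))
    return("scale entries must be 'log' or 'linear'")
  if (any(object@scale == "log" & object@lower <= 0))
    return("log-scaled dimensions must have positive bounds")
  TRUE
})

#' Construct a ParameterSpace
#'
#' @param parameters parameter names.
#' @param lower,upper numeric bounds on the natural scale.
#' @param scale per-dimension sampling scale, \code{"log"} or
#'   \code{"linear"}.
#' @return a \code{\linkS4class{ParameterSpace}}.
#' @export
ParameterSpace <- function(parameters, lower, upper, scale) {
  new("ParameterSpace", parameters = as.character(parameters),
      lower = as.numeric(lower), upper = as.numeric(upper),
      scale = as.character(scale))
}

#' @describeIn ParameterSpace number of dimensions.
#' @param x a \code{ParameterSpace}.
#' @export
nparameters <- function(x) length(x@parameters)

setMethod("show", "ParameterSpace", function(object) {
  cat("ParameterSpace with", nparameters(object), "dimensions\n")
  print(data.frame(parameter = object@parameters, lower = object@lower,
                   upper = object@upper, scale = object@scale),
        row.names = FALSE)
})

#' Ensemble of fit thermodynamic models
#'
#' The set of parameter vectors retained after sampling, coarse filtering,
#' local optimization, strict filtering, and de-duplication, together with
#' their goodness-of-fit scores and run provenance.
#'
#' @slot space the \code{\linkS4class{ParameterSpace}} sampled.
#' @slot params M x D matrix of parameter vectors on the natural scale
#'   (columns named after the space's parameters).
#' @slot sse numeric vector of mean-squared-error scores, one per model.
#' @slot provenance list of run settings (seed, thresholds, counts).
#' @aliases Ensemble-class
#' @exportClass Ensemble
setClass("Ensemble",
  representation(space = "ParameterSpace", params = "matrix",
                 sse = "numeric", provenance = "list"))

setValidity("Ensemble", function(object) {
  if (nrow(object@params) != length(object@sse))
    return("one sse score per model row is required")
  if (ncol(object@params) != nparameters(object@space))
    return("parameter matrix columns must match the parameter space")
  if (any(object@sse < 0)) return("sse scores must be nonnegative")
  TRUE
})

#' @describeIn Ensemble number of models.
#' @param x an \code{Ensemble}.
#' @export
nmodels <- function(x) nrow(x@params)

#' @describeIn Ensemble matrix of model parameter vectors (natural scale).
#' @export
modelMatrix <- function(x) x@params

#' @describeIn Ensemble per-model goodness-of-fit scores.
#' @export
sseScores <- function(x) x@sse

setMethod("show", "Ensemble", function(object) {
  cat("Ensemble of ", nmodels(object), " models in ",
      nparameters(object@space), " dimensions (sse range ",
      if (nmodels(object)) paste0(signif(min(object@sse), 3), " - ",
                                  signif(max(object@sse), 3)) else "-",
      ")\n", sep = "")
})

#' Clustered ensemble
#'
#' An \code{\linkS4class{Ensemble}} after min-max scaling and Gaussian-mixture
#' clustering: scaled coordinates, cluster labels, and one regularized
#' covariance matrix per cluster.  This is the object over which the
#' cluster-balanced probability distribution is defined.
#'
#' @slot ensemble the parent \code{\linkS4class{Ensemble}}.
#' @slot scaled M x D matrix of min-max-scaled parameter vectors in [0, 1].
#' @slot scaling list with \code{min} and \code{max} per dimension, allowing
#'   inversion of non-degenerate dimensions.
#' @slot labels integer cluster label per model (1..G).
#' @slot covariances list of G symmetric positive-definite D x D matrices.
#' @aliases ClusteredEnsemble-class
#' @exportClass ClusteredEnsemble
setClass("ClusteredEnsemble",
  representation(ensemble = "Ensemble", scaled = "matrix", scaling = "list",
                 labels = "integer", covariances = "list"))

setValidity("ClusteredEnsemble", function(object) {
  M <- nrow(object@scaled)
  if (length(object@labels) != M)
    return("one cluster label per model is required")
  G <- length(object@covariances)
  if (G < 1L || !all(object@labels %in% seq_len(G)))
    return("labels must index the covariance list")
  if (any(tabulate(object@labels, G) == 0L))
    return("every cluster must contain at least one model")
  if (any(object@scaled < -1e-9) || any(object@scaled > 1 + 1e-9))
    return("scaled coordinates must lie in [0, 1]")
  TRUE
})

#' @describeIn ClusteredEnsemble cluster label per model.
#' @param x a \code{ClusteredEnsemble}.
#' @export
clusterLabels <- function(x) x@labels

#' @describeIn ClusteredEnsemble number of clusters.
#' @export
nclusters <- function(x) length(x@covariances)

#' @describeIn ClusteredEnsemble list of per-cluster covariance matrices.
#' @export
clusterCovariances <- function(x) x@covariances

setMethod("show", "ClusteredEnsemble", function(object) {
  sizes <- tabulate(object@labels, nclusters(object))
  cat("ClusteredEnsemble: ", nrow(object@scaled), " models in ",
      nclusters(object), " clusters (sizes ", paste(sizes, collapse = ", "),
      ")\n", sep = "")
})

#' Probability distribution over a (possibly filtered) ensemble
#'
#' Represents the discrete cluster-balanced distribution over a subset of a
#' clustered ensemble's models: the surviving model indices, their discrete
#' probabilities (summing to 1/N' within each surviving cluster), and the
#' resulting entropy.  The unfiltered (wild-type) distribution is the special
#' case where every model survives.
#'
#' @slot clustered the parent \code{\linkS4class{ClusteredEnsemble}}.
#' @slot keep integer indices of surviving models (into the parent).
#' @slot probabilities discrete probability per surviving model; sums to 1.
#' @slot entropy Shannon entropy (base-10 logarithm) of the probabilities.
#' @slot label name of the experiment the ensemble was filtered by
#'   ("wild-type" for the unfiltered distribution).
#' @aliases FilteredEnsemble-class
#' @exportClass FilteredEnsemble
setClass("FilteredEnsemble",
  representation(clustered = "ClusteredEnsemble", keep = "integer",
                 probabilities = "numeric", entropy = "numeric",
                 label = "character"))

setValidity("FilteredEnsemble", function(object) {
  if (!length(object@keep)) return("a filtered ensemble cannot be empty")
  M <- nrow(object@clustered@scaled)
  if (any(object@keep < 1L) || any(object@keep > M) ||
      anyDuplicated(object@keep))
    return("keep must be unique indices into the parent ensemble")
  if (length(object@probabilities) != length(object@keep))
    return("one probability per surviving model is required")
  if (abs(sum(object@probabilities) - 1) > 1e-8)
    return("probabilities must sum to 1")
  if (any(object@probabilities <= 0))
    return("all probabilities must be positive")
  TRUE
})

#' @describeIn FilteredEnsemble indices of surviving models.
#' @param x a \code{FilteredEnsemble}.
#' @export
survivingModels <- function(x) x@keep

#' @describeIn FilteredEnsemble discrete model probabilities.
#' @export
modelProbabilities <- function(x) x@probabilities

#' @describeIn FilteredEnsemble entropy (base-10) of the distribution.
#' @export
ensembleEntropy <- function(x) x@entropy

#' @describeIn FilteredEnsemble per-cluster survivor counts, indexed by the
#'   parent's cluster ids (zeros for refuted clusters).
#' @export
clusterCounts <- function(x)
  tabulate(x@clustered@labels[x@keep], nclusters(x@clustered))

setMethod("show", "FilteredEnsemble", function(object) {
  cat("FilteredEnsemble '", object@label, "': ", length(object@keep), "/",
      nrow(object@clustered@scaled), " models, ",
      sum(clusterCounts(object) > 0), "/", nclusters(object@clustered),
      " clusters, entropy ", round(object@entropy, 3), "\n", sep = "")
})

#' Perturbation experiment
#'
#' A perturbation operator (TF knockout, site mutagenesis, or variant
#' enhancer) paired with a machine-checkable consistency criterion against
#' which every ensemble model's perturbed prediction is judged.
#'
#' @slot name experiment label.
#' @slot perturbation list with element \code{type} (one of
#'   \code{"knockout"}, \code{"site_mutagenesis"}, \code{"variant_enhancer"})
#'   plus type-specific fields; see \code{\link{tfKnockout}},
#'   \code{\link{siteMutagenesis}}, \code{\link{variantEnhancer}}.
#' @slot criterion list with element \code{kind} (one of \code{"unchanged"},
#'   \code{"profile_match"}, \code{"peak_fraction"}, \code{"boundary_shift"},
#'   \code{"abolished"}) plus kind-specific fields; see
#'   \code{\link{criterionUnchanged}} and friends.
#' @aliases PerturbationExperiment-class
#' @exportClass PerturbationExperiment
setClass("PerturbationExperiment",
  representation(name = "character", perturbation = "list",
                 criterion = "list"))

setValidity("PerturbationExperiment", function(object) {
  if (!identical(length(object@name), 1L)) return("name must be a string")
  ptype <- object@perturbation$type
  if (is.null(ptype) ||
      !ptype %in% c("knockout", "site_mutagenesis", "variant_enhancer",
                    "none"))
    return("unknown perturbation type")
  kind <- object@criterion$kind
  if (is.null(kind) ||
      !kind %in% c("unchanged", "profile_match", "peak_fraction",
                   "boundary_shift", "abolished", "accept_all"))
    return("unknown criterion kind")
  TRUE
})

#' Construct a PerturbationExperiment
#'
#' @param name experiment label.
#' @param perturbation a perturbation descriptor, e.g.
#'   \code{\link{tfKnockout}("SNA")}.
#' @param criterion a consistency criterion, e.g.
#'   \code{\link{criterionUnchanged}(0.05)}.
#' @return a \code{\linkS4class{PerturbationExperiment}}.
#' @export
PerturbationExperiment <- function(name, perturbation, criterion) {
  new("PerturbationExperiment", name = as.character(name),
      perturbation = perturbation, criterion = criterion)
}

setMethod("show", "PerturbationExperiment", function(object) {
  cat("PerturbationExperiment '", object@name, "': ",
      object@perturbation$type, " / criterion ", object@criterion$kind,
      "\n", sep = "")
})
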