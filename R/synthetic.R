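## Synthetic regulatory scenarios: TF concentration profiles, motifs,
## enhancers with planted binding sites, and complete ind-like / sim-like /
## toy scenarios with planted ground-truth parameters.

#' Generate a TF concentration profile
#'
#' Samples a named curve at B equally spaced bins along the spatial axis
#' (bin 1 = ventral end) and clips it to [0, 1].
#'
#' @param shape one of \code{"sigmoid"} (logistic in the bin index;
#'   negative \code{slope} gives a ventrally-high, dorsally-decreasing
#'   profile), \code{"gaussian"}, \code{"uniform"}, or \code{"complement"}
#'   (1 - profile).
#' @param B number of bins (>= 2).
#' @param midpoint,slope sigmoid parameters: half-maximum bin and width;
#'   \code{slope < 0} makes the profile decrease with bin index.
#' @param center,sd Gaussian parameters.
#' @param level uniform level.
#' @param profile profile to complement.
#' @param height peak height of sigmoid/gaussian shapes (default 1).
#' @return numeric vector of length B with values in [0, 1].
#' @examples
#' makeTFProfile("sigmoid", 50, midpoint = 18.5, slope = -0.8)[17:21]
#' @export
makeTFProfile <- function(shape = c("sigmoid", "gaussian", "uniform",
                                    "complement"),
                          B = 50, midpoint = B / 2, slope = 1,
                          center = B / 2, sd = B / 10, level = 1,
                          profile = NULL, height = 1) {
  shape <- match.arg(shape)
  stopifnot(B >= 2)
  x <- seq_len(B)
  out <- switch(shape,
    sigmoid = {
      if (slope == 0) stop("sigmoid slope must be nonzero")
      height / (1 + exp(-(x - midpoint) / slope))
    },
    gaussian = {
      if (sd <= 0) stop("gaussian sd must be positive")
      height * exp(-(x - center)^2 / (2 * sd^2))
    },
    uniform = rep(level, B),
    complement = {
      if (is.null(profile) || length(profile) != B)
        stop("complement requires a length-B profile")
      1 - profile
    })
  pmin(pmax(out, 0), 1)
}

## synthetic motif: designated consensus base gets `major` frequency, a
## designated second base `second`, the rest share the remainder equally
.syntheticMotif <- function(name, consensus, major = 0.7, second = 0.15) {
  bases <- strsplit(consensus, "")[[1]]
  stopifnot(all(bases %in% .BASES))
  L <- length(bases)
  m <- matrix((1 - major - second) / 2, L, 4,
              dimnames = list(NULL, .BASES))
  for (i in seq_len(L)) {
    ci <- match(bases[i], .BASES)
    m[i, ci] <- major
    m[i, if (ci == 4L) 1L else ci + 1L] <- second
  }
  Motif(name, m, pseudocount = 0)
}

## site instance of a given strength tier: 0 (strong), 1 (medium), or
## 2 (weak) positions deviated from the consensus to the second-best base
.siteInstance <- function(motif, tier = c("strong", "medium", "weak")) {
  tier <- match.arg(tier)
  ndev <- c(strong = 0L, medium = 1L, weak = 2L)[[tier]]
  cons <- apply(motif@matrix, 1, which.max)
  inst <- cons
  if (ndev > 0) for (i in seq_len(ndev)) {
    ord <- order(motif@matrix[i, ], decreasing = TRUE)
    inst[i] <- ord[2]
  }
  paste(.BASES[inst], collapse = "")
}

#' Generate an enhancer with planted binding sites
#'
#' Draws a background sequence i.i.d. from the background base composition
#' and overwrites it with motif instances at the planned positions.  Site
#' strength tiers plant the consensus ("strong") or instances with one
#' ("medium") or two ("weak") positions changed to the second-best base, so
#' that within a TF the planted "strong" site always has the maximal
#' relative affinity.
#'
#' @param motifs named list of \code{\linkS4class{Motif}}s.
#' @param sitePlan data.frame with columns \code{tf}, \code{position}
#'   (1-based start), \code{tier} (\code{"strong"}, \code{"medium"},
#'   \code{"weak"}).  Planted sites must not overlap.
#' @param length enhancer length in bp.
#' @param background length-4 base composition (default uniform).
#' @param seed integer seed.
#' @return list with \code{sequence} (a \code{DNAString}) and
#'   \code{plannedSites} (the plan plus each site's \code{end} and planted
#'   instance).
#' @export
makeEnhancer <- function(motifs, sitePlan, length, background = rep(0.25, 4),
                         seed = 1) {
  stopifnot(is.data.frame(sitePlan),
            all(c("tf", "position", "tier") %in% names(sitePlan)))
  set.seed(as.integer(seed))
  seq <- sample(.BASES, length, replace = TRUE, prob = background)
  if (nrow(sitePlan)) {
    Ls <- vapply(as.character(sitePlan$tf),
                 function(tf) motifLength(motifs[[tf]]), 1L)
    starts <- sitePlan$position
    ends <- starts + Ls - 1L
    if (any(ends > length) || any(starts < 1))
      stop("planted site does not fit in the enhancer")
    ord <- order(starts)
    if (any(starts[ord][-1] <= ends[ord][-nrow(sitePlan)]))
      stop("planted sites overlap")
    inst <- character(nrow(sitePlan))
    for (k in seq_len(nrow(sitePlan))) {
      inst[k] <- .siteInstance(motifs[[as.character(sitePlan$tf[k])]],
                               as.character(sitePlan$tier[k]))
      seq[starts[k]:ends[k]] <- strsplit(inst[k], "")[[1]]
    }
    sitePlan$end <- ends
    sitePlan$instance <- inst
  }
  list(sequence = DNAString(paste(seq, collapse = "")),
       plannedSites = sitePlan)
}

## shared motif catalogue, flavored after the D/V patterning factors
.dvMotifs <- function() {
  list(DLA = .syntheticMotif("DLA", "GGGAAAAC"),
       ZLU = .syntheticMotif("ZLU", "CAGGTAGC"),
       TWA = .syntheticMotif("TWA", "CACATGTT"),
       SNR = .syntheticMotif("SNR", "CACCTGTT"),
       VNR = .syntheticMotif("VNR", "CAAGTGGC"),
       CIR = .syntheticMotif("CIR", "TGAATGAA"),
       SUH = .syntheticMotif("SUH", "CGTGGGAA"))
}

#' Synthetic ind-like regulatory scenario
#'
#' A 50-bin dorso-ventral axis scenario emulating the structure of the ind
#' system: a ventrally graded activator (DL-like), a uniform activator
#' (ZLD-like) cooperating with it, a mesodermal repressor (SNA-like), a
#' ventral-neuroectoderm repressor (VND-like), and a uniform repressor
#' (CIC-like) whose effect is attenuated over the neuroectodermal bins by a
#' free attenuation parameter.  A 13-parameter ground truth is planted and
#' the target profile is its own prediction, peaked at bin 25 with support
#' confined to bins 22-28.
#'
#' @param seed integer seed for the background sequence.
#' @return a \code{\linkS4class{Scenario}} with \code{groundTruth} set.
#' @examples
#' sc <- makeIndLikeScenario(1)
#' which.max(targetProfile(sc))
#' @export
makeIndLikeScenario <- function(seed = 1) {
  B <- 50
  motifs <- .dvMotifs()
  conc <- list(
    DLA = makeTFProfile("sigmoid", B, midpoint = 26, slope = -2),
    ZLU = makeTFProfile("uniform", B, level = 1),
    SNR = makeTFProfile("sigmoid", B, midpoint = 18.5, slope = -0.8),
    VNR = makeTFProfile("sigmoid", B, midpoint = 21, slope = -0.8),
    CIR = makeTFProfile("uniform", B, level = 1))
  attenMask <- seq_len(B) >= 20 & seq_len(B) <= 28
  plan <- data.frame(
    tf = c("DLA", "ZLU", "DLA", "SNR", "VNR", "DLA", "CIR", "ZLU",
           "SNR", "VNR", "CIR"),
    position = c(50, 61, 120, 150, 180, 210, 240, 280, 320, 380, 440),
    tier = c("strong", "strong", "medium", "strong", "strong", "medium",
             "strong", "medium", "medium", "medium", "medium"))
  enh <- makeEnhancer(motifs, plan, length = 600, seed = seed)
  truth <- c(K_DLA = 3, K_ZLU = 1.5, K_SNR = 30, K_VNR = 25, K_CIR = 25,
             alpha_DLA = 8, alpha_ZLU = 3, alpha_SNR = 0.002,
             alpha_VNR = 0.01, alpha_CIR = 0.002,
             coop_DLA_ZLU = 5, q_btm = 0.01, atten_CIR = 0.02)
  tfs <- list(
    TFSpec("DLA", "activator", conc$DLA, motifs$DLA),
    TFSpec("ZLU", "activator", conc$ZLU, motifs$ZLU),
    TFSpec("SNR", "repressor", conc$SNR, motifs$SNR),
    TFSpec("VNR", "repressor", conc$VNR, motifs$VNR),
    TFSpec("CIR", "repressor", conc$CIR, motifs$CIR,
           attenuationMask = attenMask))
  sc <- Scenario("ind-like", enh$sequence, tfs, target = rep(0, B),
                 coopPairs = data.frame(tf1 = "DLA", tf2 = "ZLU"),
                 coopRange = 50, siteThreshold = 0.7, groundTruth = truth,
                 seed = as.integer(seed))
  sc@target <- predictProfile(sc, truth)
  validObject(sc)
  sc
}

#' Synthetic sim-like regulatory scenario
#'
#' A 25-bin scenario (the ventral half of the axis) emulating the structure
#' of the sim system: activators DL-like and TWI-like, the mesodermal
#' repressor SNA-like, and a uniformly expressed factor (Su(H)-like) split
#' into two complementary role profiles -- an activator profile covering the
#' SNA domain extended into the mesectoderm and a repressor profile equal to
#' its complement -- because the model does not allow a single TF to switch
#' roles along the axis.  The target is a narrow Gaussian peaked at bin 12,
#' where the mesodermal repressor falls from high to low.
#'
#' @param seed integer seed for the background sequence.
#' @return a \code{\linkS4class{Scenario}} (no planted ground truth; the
#'   target is specified directly).
#' @export
makeSimLikeScenario <- function(seed = 1) {
  B <- 25
  motifs <- .dvMotifs()
  suhAct <- makeTFProfile("sigmoid", B, midpoint = 13, slope = -0.6)
  conc <- list(
    DLA = makeTFProfile("sigmoid", B, midpoint = 20, slope = -3),
    TWA = makeTFProfile("sigmoid", B, midpoint = 16, slope = -2.5),
    SNR = makeTFProfile("sigmoid", B, midpoint = 11.5, slope = -0.6),
    SUA = suhAct,
    SUR = makeTFProfile("complement", B, profile = suhAct))
  plan <- data.frame(
    tf = c("DLA", "TWA", "SNR", "SUH", "DLA", "SNR", "TWA", "SUH"),
    position = c(40, 60, 90, 120, 160, 200, 250, 300),
    tier = c("strong", "strong", "strong", "strong", "medium", "medium",
             "medium", "medium"))
  enh <- makeEnhancer(motifs, plan, length = 400, seed = seed)
  target <- makeTFProfile("gaussian", B, center = 12, sd = 1.5)
  tfs <- list(
    TFSpec("DLA", "activator", conc$DLA, motifs$DLA),
    TFSpec("TWA", "activator", conc$TWA, motifs$TWA),
    TFSpec("SNR", "repressor", conc$SNR, motifs$SNR),
    TFSpec("SUA", "activator", conc$SUA, motifs$SUH, protein = "SUH"),
    TFSpec("SUR", "repressor", conc$SUR, motifs$SUH, protein = "SUH"))
  Scenario("sim-like", enh$sequence, tfs, target = target,
           coopRange = 50, siteThreshold = 0.7, seed = as.integer(seed))
}

#' Reduced-dimension desk-scale scenario
#'
#' A two-TF reduction of the ind-like setting on the same 50-bin axis (one
#' ventrally graded activator, one mesodermal repressor; no cooperativity or
#' attenuation), giving a 5-dimensional parameter space in which the full
#' sample-optimize-filter-cluster-evaluate pipeline runs in seconds.  A
#' ground truth is planted and the target is its prediction.
#'
#' @param seed integer seed for the background sequence.
#' @return a \code{\linkS4class{Scenario}} with \code{groundTruth} set.
#' @export
makeToyScenario <- function(seed = 1) {
  B <- 50
  motifs <- .dvMotifs()
  conc <- list(
    ACT = makeTFProfile("sigmoid", B, midpoint = 32, slope = -4),
    REP = makeTFProfile("sigmoid", B, midpoint = 18.5, slope = -0.8))
  plan <- data.frame(
    tf = c("ACT", "REP", "ACT", "REP"),
    position = c(40, 100, 160, 230),
    tier = c("strong", "strong", "medium", "medium"))
  enh <- makeEnhancer(list(ACT = motifs$DLA, REP = motifs$SNR), plan,
                      length = 400, seed = seed)
  truth <- c(K_ACT = 3, K_REP = 20, alpha_ACT = 30, alpha_REP = 0.005,
             q_btm = 0.01)
  tfs <- list(
    TFSpec("ACT", "activator", conc$ACT, motifs$DLA),
    TFSpec("REP", "repressor", conc$REP, motifs$SNR))
  sc <- Scenario("toy", enh$sequence, tfs, target = rep(0, B),
                 siteThreshold = 0.7, groundTruth = truth,
                 seed = as.integer(seed))
  sc@target <- predictProfile(sc, truth)
  validObject(sc)
  sc
}

#' Desk-scale scenario with planted mechanistic ambiguity
#'
#' A three-TF reduction of the ind-like setting built so that the wild-type
#' data cannot distinguish two repressor mechanisms: one activator with a
#' dorsally declining gradient and two repressors whose expression domains
#' are nested (one falling off at bin 18.5, the other at bin 21).  The
#' planted truth uses both repressors, but models using either repressor
#' alone fit the wild-type target within the strict threshold, so the fitted
#' ensemble splits into mechanistic clusters that knockout experiments can
#' discriminate -- the situation in which information gain is nontrivial.
#'
#' @param seed integer seed for the background sequence.
#' @return a \code{\linkS4class{Scenario}} with \code{groundTruth} set
#'   (7 free parameters).
#' @export
makeTwoRepressorScenario <- function(seed = 1) {
  B <- 50
  motifs <- .dvMotifs()
  conc <- list(
    ACT = makeTFProfile("sigmoid", B, midpoint = 32, slope = -4),
    RPA = makeTFProfile("sigmoid", B, midpoint = 18.5, slope = -0.8),
    RPB = makeTFProfile("sigmoid", B, midpoint = 21, slope = -1.2))
  plan <- data.frame(
    tf = c("ACT", "RPA", "RPB", "ACT", "RPA", "RPB"),
    position = c(40, 90, 140, 190, 240, 300),
    tier = c("strong", "strong", "strong", "medium", "medium", "medium"))
  enh <- makeEnhancer(list(ACT = motifs$DLA, RPA = motifs$SNR,
                           RPB = motifs$VNR), plan,
                      length = 450, seed = seed)
  truth <- c(K_ACT = 3, K_RPA = 20, K_RPB = 20, alpha_ACT = 30,
             alpha_RPA = 0.005, alpha_RPB = 0.005, q_btm = 0.01)
  tfs <- list(
    TFSpec("ACT", "activator", conc$ACT, motifs$DLA),
    TFSpec("RPA", "repressor", conc$RPA, motifs$SNR),
    TFSpec("RPB", "repressor", conc$RPB, motifs$VNR))
  sc <- Scenario("two-repressor", enh$sequence, tfs, target = rep(0, B),
                 siteThreshold = 0.7, groundTruth = truth,
                 seed = as.integer(seed))
  sc@target <- predictProfile(sc, truth)
  validObject(sc)
  sc
}

#' In-silico experiment set from a planted ground truth
#'
#' For every TF of a scenario with a planted ground truth, emits a knockout
#' experiment and a strongest-site-mutagenesis experiment whose consistency
#' criterion is a profile match against the ground truth's own prediction
#' under that perturbation -- the synthetic-true-model device for evaluating
#' experiments in a setting where the answer is known.  A TF without
#' annotated sites gets no mutagenesis experiment (with a warning).
#'
#' @param scenario a \code{\linkS4class{Scenario}} with \code{groundTruth}.
#' @param threshold profile-match score threshold (default 0.05, the strict
#'   ensemble threshold).
#' @return list of \code{\linkS4class{PerturbationExperiment}}s (2 per TF
#'   with sites; e.g. 10 for the five-TF ind-like scenario).
#' @export
makeInsilicoExperimentSet <- function(scenario, threshold = 0.05) {
  truth <- groundTruth(scenario)
  if (!length(truth))
    stop("scenario has no planted ground truth")
  out <- list()
  for (tf in scenario@tfs) {
    ko <- tfKnockout(tf@protein)
    koScen <- applyPerturbation(scenario, ko)
    out[[paste0(tf@name, " KO")]] <- PerturbationExperiment(
      paste0(tf@name, " KO"), ko,
      criterionProfileMatch(predictProfile(koScen, truth), threshold))
    if (!any(siteTable(scenario)$tf == tf@name)) {
      warning("TF ", tf@name,
              " has no annotated site; mutagenesis experiment omitted")
      next
    }
    mut <- siteMutagenesis(tf@name, strongest = 1)
    mutScen <- applyPerturbation(scenario, mut)
    out[[paste0(tf@name, " site mut.")]] <- PerturbationExperiment(
      paste0(tf@name, " site mut."), mut,
      criterionProfileMatch(predictProfile(mutScen, truth), threshold))
  }
  unname(out)
}
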