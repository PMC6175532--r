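test_that("perturbations modify scenarios as declared and leave the original intact", {
  sc <- fixtureTwoRep()
  truth <- groundTruth(sc)
  ## knockout zeroes the concentration profile
  ko <- applyPerturbation(sc, tfKnockout("RPA"))
  expect_true(all(ko@tfs[[2]]@concentration == 0))
  expect_false(all(sc@tfs[[2]]@concentration == 0))
  expect_error(applyPerturbation(sc, tfKnockout("NOPE")), "no TF")
  ## split-role protein: both derived profiles are zeroed together
  sim <- makeSimLikeScenario(1)
  koSuh <- applyPerturbation(sim, tfKnockout("SUH"))
  roles <- vapply(koSuh@tfs, function(tf) tf@protein, "")
  for (i in which(roles == "SUH"))
    expect_true(all(koSuh@tfs[[i]]@concentration == 0))
  ## strongest-site selection agrees with an exhaustive argmax
  st <- siteTable(sc)
  mut <- applyPerturbation(sc, siteMutagenesis("ACT", strongest = 1))
  removed <- setdiff(st$start[st$tf == "ACT"],
                     siteTable(mut)$start[siteTable(mut)$tf == "ACT"])
  best <- st$start[st$tf == "ACT"][which.max(st$rel_affinity[st$tf == "ACT"])]
  expect_identical(removed, best)
  expect_error(applyPerturbation(sc, siteMutagenesis("ACT",
                                                     positions = 99999)),
               "positions")
  ## a knockout of a potency-neutral TF changes nothing
  neutral <- truth
  neutral[["alpha_RPB"]] <- 1
  koB <- applyPerturbation(sc, tfKnockout("RPB"))
  expect_equal(predictProfile(koB, neutral), predictProfile(sc, neutral),
               tolerance = 1e-12)
  ## removing the only sites of the only TF reduces to the basal profile
  m <- Motif("x", matrix(c(0.97, 0.01, 0.01, 0.01), 1, 4), pseudocount = 0)
  solo <- Scenario("solo", "AAAA", list(
    TFSpec("X", "activator", rep(1, 6), m)), target = rep(0, 6))
  gone <- applyPerturbation(solo, siteMutagenesis("X",
    strongest = nrow(siteTable(solo))))
  pars <- c(K_X = 2, alpha_X = 9, q_btm = 0.2)
  expect_equal(predictProfile(gone, pars), rep(0.2 / 1.2, 6))
  ## variant enhancer re-annotates sites on the new sequence (G carries no
  ## match for the A-favoring motif on either strand)
  var <- applyPerturbation(solo, variantEnhancer("GGGG"))
  expect_identical(nrow(siteTable(var)), 0L)
})

test_that("consistency criteria implement their windows and boundary rules", {
  wt <- makeTFProfile("gaussian", 50, center = 25, sd = 3, height = 0.8)
  expect_true(isConsistent(wt, wt, criterionUnchanged(0.001)))
  expect_false(isConsistent(wt * 0.4, wt, criterionUnchanged(0.001)))
  ## halved peak falls in the [0.35, 0.65] window
  expect_true(isConsistent(wt * 0.5, wt, criterionPeakFraction(0.35, 0.65)))
  expect_false(isConsistent(wt, wt, criterionPeakFraction(0.35, 0.65)))
  expect_error(isConsistent(wt, rep(0.2, 50),
                            criterionPeakFraction(0.35, 0.65)), "flat")
  ## a 3-bin dorsal shift of the half-maximum crossing
  shifted <- makeTFProfile("gaussian", 50, center = 28, sd = 3,
                           height = 0.8)
  expect_true(isConsistent(shifted, wt,
                           criterionBoundaryShift("dorsal", 2)))
  expect_false(isConsistent(wt, shifted,
                            criterionBoundaryShift("dorsal", 2)))
  expect_true(isConsistent(makeTFProfile("gaussian", 50, center = 21,
                                         sd = 3, height = 0.8), wt,
                           criterionBoundaryShift("ventral", 2)))
  expect_true(isConsistent(rep(0.01, 50), wt, criterionAbolished(0.1)))
  expect_false(isConsistent(wt, wt, criterionAbolished(0.1)))
  expect_true(isConsistent(wt, wt,
                           criterionProfileMatch(wt, 0.001)))
  expect_error(isConsistent(wt[-1], wt, criterionUnchanged(0.1)), "length")
})

test_that("filtering applies the update rules: labels kept, empty clusters dropped, weights re-equalized", {
  ## construct a two-mechanism ensemble over the toy scenario directly:
  ## cluster 1 holds near-truth models, cluster 2 holds basal-only models
  sc <- fixtureToy()
  truth <- groundTruth(sc)
  nms <- names(truth)
  jit <- function(f) {x <- truth * f; x}
  good <- rbind(jit(1), jit(1.01), jit(0.99))
  flat <- truth
  flat[["alpha_ACT"]] <- 1          # potency-neutral activator: basal output
  flats <- rbind(flat, flat * c(1.05, 1, 1, 1, 1))
  params <- rbind(good, flats)
  colnames(params) <- nms
  space <- defaultParameterSpace(sc)
  ens <- new("Ensemble", space = space, params = params,
             sse = scoreModels(sc, params), provenance = list())
  scd <- minMaxScale(ens)
  cl <- new("ClusteredEnsemble", ensemble = ens, scaled = scd$scaled,
            scaling = scd[c("min", "max")],
            labels = c(1L, 1L, 1L, 2L, 2L),
            covariances = list(diag(0.05, 5), diag(0.05, 5)))
  wt <- ensembleDistribution(cl)
  expect_equal(sum(modelProbabilities(wt)[1:3]), 0.5, tolerance = 1e-10)
  ## an accept-all filter reproduces the parent distribution
  acceptAll <- PerturbationExperiment("null", tfKnockout("REP"),
                                      criterionAcceptAll())
  feAll <- filterEnsemble(cl, acceptAll, sc)
  expect_identical(survivingModels(feAll), 1:5)
  expect_equal(informationGain(wt, feAll), 0)
  ## a wild-type match criterion kills the basal cluster entirely
  match <- PerturbationExperiment("wt-match", list(type = "none"),
                                  criterionProfileMatch(targetProfile(sc),
                                                        0.05))
  fe <- filterEnsemble(cl, match, sc)
  expect_identical(survivingModels(fe), 1:3)
  expect_equal(clusterCounts(fe), c(3L, 0L))
  expect_equal(sum(modelProbabilities(fe)), 1, tolerance = 1e-10)
  ## the surviving cluster's weight becomes 1 and entropy drops
  expect_lt(ensembleEntropy(fe), ensembleEntropy(wt))
  ## survivors' consistency re-verified by independent re-prediction
  for (i in survivingModels(fe))
    expect_true(isConsistent(predictProfile(sc, params[i, ]),
                             targetProfile(sc), match@criterion))
  ## a criterion nothing satisfies refutes the whole ensemble
  impossible <- PerturbationExperiment("impossible", list(type = "none"),
                                       criterionAbolished(1e-9))
  expect_error(filterEnsemble(cl, impossible, sc), "refutes")
  ## filtering is idempotent for deterministic criteria
  fe2 <- filterEnsemble(fe, match, sc)
  expect_identical(survivingModels(fe2), survivingModels(fe))
  expect_equal(ensembleEntropy(fe2), ensembleEntropy(fe), tolerance = 1e-12)
})

test_that("information gain is the entropy difference, reported signed", {
  expect_equal(informationGain(3.55, 2.91), 0.64)
  expect_equal(informationGain(2, 2), 0)
  expect_equal(informationGain(1.5, 2.0), -0.5)
})

test_that("the cluster-survival table mirrors per-cluster bookkeeping", {
  cl <- fixtureTwoRepClustered()
  sc <- fixtureTwoRep()
  wt <- ensembleDistribution(cl)
  exps <- makeInsilicoExperimentSet(sc)
  filtered <- lapply(exps[c(3, 5)], function(e) filterEnsemble(cl, e, sc))
  tab <- clusterSurvivalTable(wt, filtered)
  G <- nclusters(cl)
  countCols <- paste0("cluster_", seq_len(G))
  expect_identical(tab$ensemble[1], "wild-type")
  expect_equal(tab$information_gain[1], 0)
  ## row totals equal the sum of their cluster counts
  expect_equal(tab$total, rowSums(tab[countCols]))
  expect_identical(tab$total[1], nmodels(fixtureTwoRepEnsemble()))
  expect_equal(tab$information_gain,
               tab$entropy[1] - tab$entropy, tolerance = 1e-12)
})

test_that("aggregate predictions are probability-weighted with convex means", {
  ## two single-model clusters predicting different constant levels
  basal <- Scenario("basal", "ACGTACGT", list(), target = rep(0.5, 10))
  space <- ParameterSpace("q_btm", 1e-4, 10, "log")
  params <- matrix(c(0.25, 4), 2, 1, dimnames = list(NULL, "q_btm"))
  ens <- new("Ensemble", space = space, params = params, sse = c(0, 0),
             provenance = list())
  scd <- minMaxScale(ens)
  cl <- new("ClusteredEnsemble", ensemble = ens, scaled = scd$scaled,
            scaling = scd[c("min", "max")], labels = 1:2,
            covariances = list(diag(0.1, 1), diag(0.1, 1)))
  agg <- aggregatePrediction(ensembleDistribution(cl), basal)
  expect_equal(agg$mean, rep((0.2 + 0.8) / 2, 10), tolerance = 1e-12)
  expect_equal(agg$variance, rep(0.09, 10), tolerance = 1e-12)
  ## all models identical: zero variance, mean equals the prediction
  ens2 <- new("Ensemble", space = space,
              params = matrix(1, 2, 1, dimnames = list(NULL, "q_btm")),
              sse = c(0, 0), provenance = list())
  scd2 <- minMaxScale(ens2)
  cl2 <- new("ClusteredEnsemble", ensemble = ens2, scaled = scd2$scaled,
             scaling = scd2[c("min", "max")], labels = c(1L, 1L),
             covariances = list(diag(0.1, 1)))
  agg2 <- aggregatePrediction(ensembleDistribution(cl2), basal)
  expect_equal(agg2$mean, rep(0.5, 10))
  expect_equal(agg2$variance, rep(0, 10))
  ## convexity on the fitted two-repressor ensemble
  cl3 <- fixtureTwoRepClustered()
  sc3 <- fixtureTwoRep()
  agg3 <- aggregatePrediction(ensembleDistribution(cl3), sc3)
  preds <- t(apply(modelMatrix(fixtureTwoRepEnsemble()), 1, function(p)
    predictProfile(sc3, p)))
  expect_true(all(agg3$mean >= apply(preds, 2, min) - 1e-12))
  expect_true(all(agg3$mean <= apply(preds, 2, max) + 1e-12))
})

test_that("sequential gains telescope and cross-prediction reduces variance", {
  sc <- fixtureTwoRep()
  cl <- fixtureTwoRepClustered()
  wt <- ensembleDistribution(cl)
  exps <- makeInsilicoExperimentSet(sc)
  rpaKO <- exps[[3]]
  rpbKO <- exps[[5]]
  ## telescoping: gain(i) + gain(j after i) equals the total joint gain
  fi <- filterEnsemble(cl, rpaKO, sc)
  fij <- filterEnsemble(fi, rpbKO, sc)
  expect_equal(informationGain(wt, fi) + informationGain(fi, fij),
               informationGain(wt, fij), tolerance = 1e-12)
  ## diagonal of the sequential matrix is zero
  m <- sequentialGainMatrix(list(rpaKO, rpbKO), cl, sc)
  expect_equal(unname(diag(m)), c(0, 0), tolerance = 1e-12)
  ## cross-prediction: an accept-all first experiment changes nothing
  acceptAll <- PerturbationExperiment("null", list(type = "none"),
                                      criterionAcceptAll())
  cp0 <- crossPredict(acceptAll, rpbKO, cl, sc)
  expect_equal(cp0$parent$mean, cp0$filtered$mean, tolerance = 1e-12)
})

test_that("cross-prediction resolves a two-mechanism ensemble's disagreement", {
  ## two planted mechanisms over the toy scenario: a cluster of near-truth
  ## models and a cluster of basal-only models that happen to be tolerated
  ## only by lax criteria
  sc <- fixtureToy()
  truth <- groundTruth(sc)
  flat <- truth
  flat[["alpha_ACT"]] <- 1
  params <- rbind(truth, truth * 1.01, truth * 0.99,
                  flat, flat * c(1.05, 1, 1, 1, 1))
  colnames(params) <- names(truth)
  space <- defaultParameterSpace(sc)
  ens <- new("Ensemble", space = space, params = params,
             sse = scoreModels(sc, params), provenance = list())
  scd <- minMaxScale(ens)
  cl <- new("ClusteredEnsemble", ensemble = ens, scaled = scd$scaled,
            scaling = scd[c("min", "max")],
            labels = c(1L, 1L, 1L, 2L, 2L),
            covariances = list(diag(0.05, 5), diag(0.05, 5)))
  ## experiment A: consistency with the wild-type pattern itself;
  ## experiment B: the activator-site mutagenesis the clusters disagree on
  a <- PerturbationExperiment("wt-match", list(type = "none"),
                              criterionProfileMatch(targetProfile(sc),
                                                    0.05))
  b <- PerturbationExperiment("ACT mut", siteMutagenesis("ACT", 1),
                              criterionAcceptAll())
  cp <- crossPredict(a, b, cl, sc)
  ## filtering by A removed the basal mechanism: predictions for B tighten
  ## at every bin and the means move
  expect_true(all(cp$varianceReduction >= -1e-12))
  expect_gt(max(abs(cp$parent$mean - cp$filtered$mean)), 0.01)
})

test_that("synthetic-true-model selection reports unsatisfiable criteria", {
  sc <- fixtureToy()
  cl <- clusterModels(buildEnsemble(sc, samplesPerCell = 100, seed = 3,
                                    maxOptimize = 60))
  ## a single accept-all experiment returns the best-fitting model
  acceptAll <- PerturbationExperiment("null", list(type = "none"),
                                      criterionAcceptAll())
  sel <- selectSyntheticTrueModel(cl, list(acceptAll), sc)
  expect_identical(sel$index,
                   which.min(sseScores(cl@ensemble)))
  expect_identical(sel$satisfied, "null")
  ## criteria generated from the planted truth select the truth's
  ## neighborhood
  exps <- makeInsilicoExperimentSet(sc)
  sel2 <- selectSyntheticTrueModel(cl, exps, sc)
  d <- unitDistancesTo(cl@ensemble, groundTruth(sc))
  expect_lt(d[sel2$index], 0.05)
  expect_identical(length(sel2$unsatisfied), 0L)
  ## two mutually exclusive criteria: exactly one flagged unsatisfied
  hi <- PerturbationExperiment("peak-high", list(type = "none"),
                               criterionPeakFraction(0.9, 1.1))
  lo <- PerturbationExperiment("peak-low", list(type = "none"),
                               criterionPeakFraction(0.0, 0.2))
  sel3 <- selectSyntheticTrueModel(cl, list(hi, lo), sc)
  expect_identical(sel3$satisfied, "peak-high")
  expect_identical(sel3$unsatisfied, "peak-low")
})
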