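## Readers and writers: FASTA, motif matrices, profile TSVs, scenario
## bundles, ensemble TSVs with provenance sidecars, experiment configs.

#' Read and write FASTA sequence files
#'
#' Thin wrappers over Biostrings with the package's conventions: sequences
#' are uppercased on input and names are preserved.
#'
#' @param path file path.
#' @return \code{readFasta}: a named \code{DNAStringSet} (empty for an empty
#'   file).
#' @export
readFasta <- function(path) {
  if (file.size(path) == 0) return(DNAStringSet())
  seqs <- readDNAStringSet(path)
  DNAStringSet(toupper(seqs))
}

#' @rdname readFasta
#' @param sequences named character vector, \code{DNAString}, or
#'   \code{DNAStringSet}.
#' @export
writeFasta <- function(sequences, path) {
  if (is(sequences, "DNAString"))
    sequences <- DNAStringSet(list(sequence = sequences))
  if (!is(sequences, "DNAStringSet"))
    sequences <- DNAStringSet(vapply(sequences, as.character, ""))
  writeXStringSet(sequences, path)
  invisible(path)
}

#' Read a motif matrix file
#'
#' Parses a 4-column count or frequency matrix (columns A, C, G, T; one row
#' per motif position).  Lines starting with \code{>} or \code{#} carry the
#' motif name; an optional header row naming the bases is accepted.  Counts
#' are normalized to frequencies with the pseudocount.
#'
#' @param path file path.
#' @param name motif name (default: from the file's header line, else the
#'   file name).
#' @param pseudocount added to every cell before normalization (default 0.5;
#'   use 0 for already-normalized matrices).
#' @param background length-4 background frequencies.
#' @return a \code{\linkS4class{Motif}}.
#' @export
readMotif <- function(path, name = NULL, pseudocount = 0.5,
                      background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^[>#]", lines)
  if (is.null(name)) {
    name <- if (any(hdr)) sub("^[>#]\\s*", "", lines[which(hdr)[1]]) else
      sub("\\.[^.]*$", "", basename(path))
  }
  body <- lines[!hdr]
  ## drop an A C G T header row if present
  if (length(body) && grepl("^[ \t]*A[ \t]+C[ \t]+G[ \t]+T[ \t]*$",
                            toupper(body[1])))
    body <- body[-1]
  if (!length(body)) stop("motif file has no matrix rows: ", path)
  rows <- lapply(seq_along(body), function(i) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(body[i]),
                                                 "[ \t,]+")[[1]]))
    if (length(vals) != 4L || anyNA(vals))
      stop("motif file ", path, ": line ", i,
           " is not a numeric 4-column row")
    vals
  })
  Motif(name, do.call(rbind, rows), pseudocount = pseudocount,
        background = background)
}

#' @rdname readMotif
#' @param motif a \code{\linkS4class{Motif}} to write (frequencies, with a
#'   \code{#}-prefixed name line).
#' @export
writeMotif <- function(motif, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# ", motif@name), "A\tC\tG\tT"), con)
  write.table(format(motif@matrix, digits = 15), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write per-bin profile tables
#'
#' Profiles are exchanged as TSV with a header row: column \code{bin}
#' (1-based, 1..B, complete and ordered) followed by one column per named
#' profile.  All values must lie in [0, 1]; a violation is reported with its
#' row and column.
#'
#' @param path file path.
#' @param B expected number of bins (default: taken from the file).
#' @return \code{readProfiles}: named list of numeric vectors of length B.
#' @export
readProfiles <- function(path, B = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (!"bin" %in% names(tab)) stop("profile table needs a 'bin' column")
  if (is.null(B)) B <- nrow(tab)
  if (nrow(tab) != B || !identical(as.integer(tab$bin), seq_len(B)))
    stop("profile table must have bins 1..", B, " in order")
  out <- list()
  for (cn in setdiff(names(tab), "bin")) {
    v <- tab[[cn]]
    bad <- which(!is.finite(v) | v < 0 | v > 1)
    if (length(bad))
      stop("profile value out of [0,1] at row ", bad[1], ", column '", cn,
           "' (", v[bad[1]], ")")
    out[[cn]] <- as.numeric(v)
  }
  out
}

#' @rdname readProfiles
#' @param profiles named list of numeric per-bin vectors (equal lengths).
#' @export
writeProfiles <- function(profiles, path) {
  B <- unique(vapply(profiles, length, 1L))
  if (length(B) != 1L) stop("all profiles must have the same length")
  tab <- data.frame(bin = seq_len(B), profiles, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write and read scenario bundles
#'
#' A scenario is stored as a directory: \code{sequence.fasta},
#' \code{motifs/<tf>.txt}, \code{profiles.tsv} (TF concentrations plus the
#' \code{target} column), and \code{manifest.yaml} (roles, proteins,
#' attenuation masks, cooperativity, thresholds, seed, and any planted
#' ground truth).  \code{readScenario} reconstructs the scenario, including
#' re-annotation of binding sites.
#'
#' @param scenario a \code{\linkS4class{Scenario}}.
#' @param dir bundle directory (created if needed).
#' @return the directory (\code{writeScenario}) or a
#'   \code{\linkS4class{Scenario}} (\code{readScenario}).
#' @export
writeScenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "motifs"), showWarnings = FALSE)
  writeFasta(setNames(as.character(scenario@sequence), scenario@name),
             file.path(dir, "sequence.fasta"))
  profs <- lapply(scenario@tfs, function(tf) tf@concentration)
  names(profs) <- tfNames(scenario)
  profs$target <- targetProfile(scenario)
  writeProfiles(profs, file.path(dir, "profiles.tsv"))
  for (tf in scenario@tfs)
    writeMotif(tf@motif, file.path(dir, "motifs", paste0(tf@name, ".txt")))
  manifest <- list(
    name = scenario@name,
    bins = nbins(scenario),
    coopRange = scenario@coopRange,
    siteThreshold = scenario@siteThreshold,
    seed = if (is.na(scenario@seed)) NULL else scenario@seed,
    coopPairs = if (nrow(scenario@coopPairs))
      lapply(seq_len(nrow(scenario@coopPairs)), function(i)
        list(tf1 = scenario@coopPairs$tf1[i],
             tf2 = scenario@coopPairs$tf2[i])) else list(),
    tfs = lapply(scenario@tfs, function(tf) list(
      name = tf@name, protein = tf@protein, role = tf@role,
      attenuatedBins = if (length(tf@attenuationMask))
        which(tf@attenuationMask) else NULL)),
    groundTruth = if (length(scenario@groundTruth))
      as.list(scenario@groundTruth) else NULL)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname writeScenario
#' @export
readScenario <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  seqs <- readFasta(file.path(dir, "sequence.fasta"))
  profs <- readProfiles(file.path(dir, "profiles.tsv"), man$bins)
  B <- man$bins
  tfs <- lapply(man$tfs, function(m) {
    motif <- readMotif(file.path(dir, "motifs", paste0(m$name, ".txt")),
                       name = m$name, pseudocount = 0)
    mask <- logical(0)
    if (!is.null(m$attenuatedBins)) {
      mask <- rep(FALSE, B)
      mask[unlist(m$attenuatedBins)] <- TRUE
    }
    TFSpec(m$name, m$role, profs[[m$name]], motif, protein = m$protein,
           attenuationMask = mask)
  })
  coop <- if (length(man$coopPairs))
    data.frame(tf1 = vapply(man$coopPairs, `[[`, "", "tf1"),
               tf2 = vapply(man$coopPairs, `[[`, "", "tf2")) else
    data.frame(tf1 = character(), tf2 = character())
  gt <- if (!is.null(man$groundTruth)) unlist(man$groundTruth) else
    numeric(0)
  Scenario(man$name, seqs[[1]], tfs, profs$target, coopPairs = coop,
           coopRange = man$coopRange, siteThreshold = man$siteThreshold,
           groundTruth = gt,
           seed = if (is.null(man$seed)) NA_integer_ else man$seed)
}

#' Write and read ensembles
#'
#' The ensemble is stored as a TSV (one row per model: parameters on the
#' natural scale plus the \code{sse} column) with a YAML provenance sidecar
#' (\code{<path>.yaml}) recording the parameter space and run settings, so
#' the ensemble reconstructs exactly.
#'
#' @param ensemble an \code{\linkS4class{Ensemble}}.
#' @param path TSV file path.
#' @return the path (\code{writeEnsemble}) or an
#'   \code{\linkS4class{Ensemble}} (\code{readEnsemble}).
#' @export
writeEnsemble <- function(ensemble, path) {
  tab <- data.frame(modelMatrix(ensemble), sse = sseScores(ensemble),
                    check.names = FALSE)
  write.table(format(tab, digits = 17), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  space <- ensemble@space
  side <- list(
    space = list(parameters = space@parameters,
                 lower = space@lower, upper = space@upper,
                 scale = space@scale),
    provenance = ensemble@provenance)
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname writeEnsemble
#' @export
readEnsemble <- function(path) {
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  space <- ParameterSpace(unlist(side$space$parameters),
                          unlist(side$space$lower),
                          unlist(side$space$upper),
                          unlist(side$space$scale))
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  params <- as.matrix(tab[, space@parameters, drop = FALSE])
  new("Ensemble", space = space, params = params,
      sse = as.numeric(tab$sse), provenance = side$provenance)
}

#' Read experiment definitions from a config file
#'
#' The YAML config holds a list under \code{experiments}, each entry with
#' \code{name}, a \code{perturbation} block (\code{type} plus fields), and a
#' \code{criterion} block (\code{kind} plus fields).  A profile-match
#' criterion may give \code{target: truth}, meaning the scenario ground
#' truth's own prediction under the experiment's perturbation.
#'
#' @param path YAML file path.
#' @param scenario the \code{\linkS4class{Scenario}} experiments refer to
#'   (needed for \code{target: truth} criteria).
#' @return list of \code{\linkS4class{PerturbationExperiment}}s.
#' @export
readExperiments <- function(path, scenario = NULL) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$experiments)) stop("config has no 'experiments' list")
  lapply(cfg$experiments, function(e) {
    pert <- e$perturbation
    crit <- e$criterion
    if (identical(crit$kind, "profile_match") &&
        identical(crit$target, "truth")) {
      if (is.null(scenario) || !length(groundTruth(scenario)))
        stop("experiment '", e$name,
             "' needs a scenario with a planted ground truth")
      pscen <- applyPerturbation(scenario, pert)
      crit$target <- predictProfile(pscen, groundTruth(scenario))
    } else if (!is.null(crit$target)) {
      crit$target <- as.numeric(unlist(crit$target))
    }
    PerturbationExperiment(e$name, pert, crit)
  })
}
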