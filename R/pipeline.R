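# End-to-end orchestration: build or load a double layer, relax the flat
# reference, enumerate torsion axes, generate twisted conformations, account
# for broken hydrogen bonds, relax flat-to-twisted pathways and report
# barriers and near-axis contacts.

#' Parse an axis specification string
#'
#' Accepts \code{"G25:psi"}, \code{"25:psi"}, \code{"D23:phi"} and similar.
#'
#' @param spec character vector of axis specifications.
#' @return data.frame with columns \code{residue}, \code{kind}.
#' @export
parseAxisSpec <- function(spec) {
  m <- regmatches(spec, regexec("^([A-Za-z]?)([0-9]+):(psi|phi)$", spec))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) stop("malformed axis spec: ", paste(spec[bad], collapse = ", "))
  data.frame(residue = vapply(m, function(x) as.integer(x[3L]), 0L),
             kind = vapply(m, `[`, "", 4L), stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Exactly one input source must be given: a structure file (\code{input}) or
#' builder parameters (\code{builder}).
#'
#' @param input path to a PDB file holding the flat dimer, or \code{NULL}.
#' @param builder a \code{\link{builderParams}} object, or \code{NULL}.
#' @param axes character vector of axis specs (see \code{\link{parseAxisSpec}}).
#' @param criteria a \code{\link{hbCriteria}} object.
#' @param energy an \code{\link{energyParams}} object.
#' @param nImages images per pathway.
#' @param springK band spring constant.
#' @param climbing climbing-image flag.
#' @param relaxFlat iterations used to relax the flat reference (0 to skip,
#'   e.g. for an already-optimised input structure).
#' @param relaxTwist iterations for twisted-candidate relaxation.
#' @param nebIter iterations for path relaxation.
#' @param nebTol force tolerance for path relaxation, surrogate unit per
#'   Angstrom.
#' @param outDir output directory for reports (\code{NULL}: nothing written).
#' @param seed integer seed fixing all stochastic steps.
#' @return a configuration list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(input = NULL, builder = NULL,
                           axes = c("G25:psi", "S26:phi"),
                           criteria = hbCriteria(), energy = energyParams(),
                           nImages = 8L, springK = 1.0, climbing = FALSE,
                           relaxFlat = 2000L, relaxTwist = 600L,
                           nebIter = 500L, nebTol = 0.05,
                           outDir = NULL, seed = 1L) {
  if (is.null(input) == is.null(builder))
    stop("exactly one input source (input file or builder params) is required")
  if (!is.null(builder)) stopifnot(inherits(builder, "BuilderParams"))
  structure(list(input = input, builder = builder, axes = axes,
                 criteria = criteria, energy = energy,
                 nImages = as.integer(nImages), springK = springK,
                 climbing = climbing, relaxFlat = as.integer(relaxFlat),
                 relaxTwist = as.integer(relaxTwist),
                 nebIter = as.integer(nebIter), nebTol = nebTol,
                 outDir = outDir, seed = as.integer(seed)),
            class = "PipelineConfig")
}

## read a yaml pipeline configuration file (axis specs, criteria, energy
## overrides, builder parameters)
#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys: \code{input}, \code{builder} (a mapping of
#' \code{\link{builderParams}} arguments), \code{axes}, \code{criteria}
#' (\code{maxDistance}, \code{minAngle}), \code{energy} (scalar
#' \code{\link{energyParams}} arguments), and any remaining
#' \code{\link{pipelineConfig}} argument.
#'
#' @param path YAML file.
#' @return a \code{"PipelineConfig"} object.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$builder)) args$builder <- do.call(builderParams, y$builder)
  if (!is.null(y$input)) args$input <- y$input
  if (!is.null(y$axes)) args$axes <- unlist(y$axes)
  if (!is.null(y$criteria)) args$criteria <- do.call(hbCriteria, y$criteria)
  if (!is.null(y$energy)) args$energy <- do.call(energyParams, y$energy)
  for (k in intersect(names(y), c("nImages", "springK", "climbing",
                                  "relaxFlat", "relaxTwist", "nebIter",
                                  "nebTol", "outDir", "seed")))
    args[[k]] <- y[[k]]
  do.call(pipelineConfig, args)
}

#' Run the full torsional-interconversion pipeline
#'
#' Builds or loads the flat double layer, relaxes it under the surrogate
#' energy, and for every requested axis: generates the optimised twisted
#' conformation, compiles the broken/formed hydrogen-bond ledger, relaxes the
#' flat-to-twisted pathway with the nudged elastic band, and extracts
#' activation barriers and near-axis contact distances. Deterministic under a
#' fixed configuration and seed.
#'
#' @param config a \code{\link{pipelineConfig}} object.
#' @param verbose print progress to stderr.
#' @return a list of class \code{"RunReport"}: \code{flat} (structure),
#'   \code{flatSummary}, \code{axes} (per-axis records), \code{config}.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (verbose) message(...)
  set.seed(config$seed)
  stage <- function(label, axisLab, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s'%s failed: %s", label,
                   if (nzchar(axisLab)) paste0(" [", axisLab, "]") else "",
                   conditionMessage(e)), call. = FALSE))
  }
  s0 <- stage("input", "", {
    if (!is.null(config$input)) readStructure(config$input, format = "pdb")
    else buildParallelDimer(config$builder)
  })
  if (nMonomers(s0) != 2L) stop("pipeline stage 'input' failed: need a dimer")
  s0 <- assignLayers(s0)
  say("relaxing the flat reference ...")
  flat <- if (config$relaxFlat > 0L) {
    stage("relax-flat", "", minimizeStructure(
      s0, config$energy, maxIter = config$relaxFlat, tol = config$nebTol)
    )$structure
  } else s0
  flatHB <- detectHBonds(flat, config$criteria)
  eFlat <- surrogateEnergy(flat, config$energy, reference = flat)
  flatSummary <- list(
    nAtoms = nAtoms(flat),
    interHB = sum(flatHB$scope == "intermolecular"),
    interMainchainHB = sum(flatHB$scope == "intermolecular" &
                             flatHB$class == "mainchain"),
    interlayerDistance = interlayerDistance(flat),
    energy = eFlat)
  axspec <- parseAxisSpec(config$axes)
  records <- vector("list", nrow(axspec))
  for (k in seq_len(nrow(axspec))) {
    lab <- sprintf("%d:%s", axspec$residue[k], axspec$kind[k])
    say("axis ", lab, " ...")
    ax <- stage("axis", lab,
                .makeAxis(flat, axspec$residue[k], axspec$kind[k]))
    tw <- stage("twist", lab,
                generateTwisted(flat, ax, params = config$energy,
                                maxIter = config$relaxTwist))
    ledger <- stage("hb-ledger", lab,
                    deltaHB(flat, tw@structure, config$criteria))
    path <- stage("interpolate", lab,
                  interpolatePath(flat, tw@structure, ax,
                                  nImages = config$nImages))
    rp <- stage("neb", lab,
                nebRelax(path, config$energy, springK = config$springK,
                         climbing = config$climbing, tol = config$nebTol,
                         maxIter = config$nebIter))
    bar <- barrierReport(rp)
    contacts <- stage("contacts", lab,
                      contactTable(rp, ax, bar$topIndex,
                                   length(rp@images)))
    records[[k]] <- list(
      axis = lab, residue = axspec$residue[k], kind = axspec$kind[k],
      appliedAngle = tw@appliedAngle,
      deltaNHB = ledger$deltaNHB,
      brokenHB = nrow(ledger$broken), formedHB = nrow(ledger$formed),
      endothermicEnergy = bar$endothermicEnergy,
      barrierTwistedToFlat = bar$barrierTwistedToFlat,
      barrierFlatToTwisted = bar$barrierFlatToTwisted,
      pathEnergies = rp@energies - rp@energies[1L],
      nebConverged = rp@converged,
      contacts = contacts,
      ledger = ledger,
      path = rp)
  }
  report <- structure(list(flat = flat, flatSummary = flatSummary,
                           axes = records, config = config),
                      class = "RunReport")
  if (!is.null(config$outDir)) writeRunReport(report, config$outDir)
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport:", length(x$axes), "axes on a", x$flatSummary$nAtoms,
      "atom dimer\n")
  cat(sprintf("  flat: %d intermolecular HBs (%d mainchain), interlayer %.3f A\n",
              x$flatSummary$interHB, x$flatSummary$interMainchainHB,
              x$flatSummary$interlayerDistance))
  for (r in x$axes)
    cat(sprintf("  %-8s dNHB %d endo %8.3f barrier(t->f) %8.3f\n",
                r$axis, r$deltaNHB, r$endothermicEnergy,
                r$barrierTwistedToFlat))
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits \code{report.json} (summary and per-axis scalars), tidy CSV tables
#' (\code{hbonds.csv}, \code{ledger.csv}, \code{contacts.csv},
#' \code{profile_<axis>.csv}) and each relaxed pathway as a multi-model PDB.
#'
#' @param report a \code{"RunReport"}.
#' @param dir output directory (created if absent).
#' @return invisibly, \code{dir}.
#' @export
writeRunReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  flatHB <- detectHBonds(report$flat, report$config$criteria)
  utils::write.csv(flatHB, file.path(dir, "hbonds.csv"), row.names = FALSE)
  led <- do.call(rbind, lapply(report$axes, function(r) {
    b <- r$ledger$broken; f <- r$ledger$formed
    rbind(
      if (nrow(b)) cbind(axis = r$axis, change = "broken", b),
      if (nrow(f)) cbind(axis = r$axis, change = "formed", f))
  }))
  if (!is.null(led))
    utils::write.csv(led, file.path(dir, "ledger.csv"), row.names = FALSE)
  cons <- do.call(rbind, lapply(report$axes, function(r)
    cbind(axis = r$axis, as.data.frame(r$contacts))))
  utils::write.csv(cons, file.path(dir, "contacts.csv"), row.names = FALSE)
  for (r in report$axes) {
    tag <- gsub(":", "_", r$axis)
    utils::write.csv(
      data.frame(image = seq_along(r$pathEnergies),
                 relativeEnergy = r$pathEnergies),
      file.path(dir, sprintf("profile_%s.csv", tag)), row.names = FALSE)
    writePath(r$path, file.path(dir, sprintf("path_%s.pdb", tag)),
              format = "pdb")
  }
  scalars <- list(
    flat = report$flatSummary[c("nAtoms", "interHB", "interMainchainHB",
                                "interlayerDistance", "energy")],
    axes = lapply(report$axes, function(r)
      r[c("axis", "appliedAngle", "deltaNHB", "endothermicEnergy",
          "barrierTwistedToFlat", "barrierFlatToTwisted", "nebConverged")]))
  jsonlite::write_json(scalars, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Analyse a stored pathway ensemble
#'
#' For a conformational pathway (for example a deposited minimum-energy-path
#' ensemble, or one produced by \code{\link{nebRelax}}), computes per-image
#' intermolecular mainchain hydrogen-bond counts and the near-axis contact
#' distances of every image.
#'
#' @param pathFiles path accepted by \code{\link{readPath}}, or a list of
#'   \linkS4class{PeptideStructure}.
#' @param axisSpec single axis specification string (e.g. \code{"G25:psi"}).
#' @param criteria a \code{\link{hbCriteria}} object.
#' @param outFile optional CSV output path.
#' @return data.frame with one row per image: \code{image},
#'   \code{interMainchainHB}, \code{interHB}, \code{intraHB},
#'   \code{minContact} (Angstrom, near-axis class).
#' @export
analyzeDepositedPath <- function(pathFiles, axisSpec, criteria = hbCriteria(),
                                 outFile = NULL) {
  imgs <- if (is.list(pathFiles) && is(pathFiles[[1L]], "PeptideStructure"))
    pathFiles else readPath(pathFiles)
  imgs <- lapply(imgs, function(s)
    if (nMonomers(s) == 2L && !any(!is.na(s@atoms$layer))) assignLayers(s)
    else s)
  spec <- parseAxisSpec(axisSpec)
  ax <- .makeAxis(imgs[[1L]], spec$residue[1L], spec$kind[1L])
  rows <- lapply(seq_along(imgs), function(k) {
    hb <- detectHBonds(imgs[[k]], criteria)
    ct <- contactTable(imgs, ax, k, k)
    data.frame(image = k,
               interMainchainHB = sum(hb$scope == "intermolecular" &
                                        hb$class == "mainchain"),
               interHB = sum(hb$scope == "intermolecular"),
               intraHB = sum(hb$scope == "intramolecular"),
               minContact = min(ct$barrierTop))
  })
  out <- do.call(rbind, rows)
  if (!is.null(outFile))
    utils::write.csv(out, outFile, row.names = FALSE)
  out
}
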