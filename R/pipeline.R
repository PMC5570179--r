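# End-to-end orchestration: binding-site resolution -> residue mapping ->
# superposition -> RMSD statistics -> clustering -> per-member pocket
# detection -> frequency / transient / sub-pocket analysis -> optional
# conservation, with CSV/DX/JSON artifacts and a run log.

.defaultConfig <- function() {
  list(
    reference = NULL, ensemble = NULL, ligand = NULL, center = NULL,
    site = list(radius = 5),
    mapping = list(minIdentity = 0.2),
    metric = "backbone",
    cluster = list(method = "single_linkage", threshold = 3, seed = 17L,
                   maxK = NULL),
    pocket = list(spacing = 1, probeRadius = 1.4, minBuried = 5L,
                  scanDepth = 10, contactDistance = 4, margin = 2),
    transient = list(thresholds = c(0.25, 0.5), conservedFraction = 0.9,
                     minSubpocketPoints = 5L, includeReference = FALSE),
    msa = NULL, offTarget = NULL, mapConservation = TRUE,
    seed = 17L, outDir = NULL)
}

.mergeConfig <- function(user) {
  cfg <- .defaultConfig()
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      for (k2 in names(user[[k]])) cfg[[k]][[k2]] <- user[[k]][[k2]]
    } else cfg[[k]] <- user[[k]]
  }
  cfg
}

.writeCsv <- function(x, dir, name) {
  utils::write.csv(x, file.path(dir, name), row.names = FALSE)
}

#' Run the full transient-pocket analysis pipeline
#'
#' Executes binding-site resolution, residue mapping, superposition, RMSD
#' statistics, clustering, per-member pocket detection, transient-region /
#' sub-pocket analysis and (when an MSA is supplied) conservation scoring,
#' writing CSV, OpenDX and JSON artifacts plus a run log to the output
#' directory. All defaults follow the standard workflow: site radius 5 A,
#' single-linkage clustering at 3 A, grid spacing 1 A, probe 1.4 A,
#' occurrence thresholds 25% and 50%.
#'
#' @param config a configuration list or the path of a JSON configuration
#'   file. Recognized top-level entries: \code{reference} (PDB path or
#'   ProteinStructure), \code{ensemble} (vector of PDB paths, one
#'   multi-model PDB path, or a StructureEnsemble), \code{ligand} (PDB
#'   path or structure) or \code{center} (3-vector), \code{site$radius},
#'   \code{mapping$minIdentity}, \code{metric} ("backbone" or
#'   "sidechain_center"), \code{cluster$method/threshold/seed},
#'   \code{pocket$spacing/probeRadius/minBuried/scanDepth/contactDistance/
#'   margin}, \code{transient$thresholds/conservedFraction/
#'   minSubpocketPoints/includeReference}, \code{msa} (FASTA path or
#'   AAStringSet), \code{offTarget} (sequence id), \code{seed},
#'   \code{outDir}.
#' @return invisibly, a list with the main in-memory results (site,
#'   superposition, stats, clustering, pockets, transients, conservation)
#'   and \code{outDir}.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- .mergeConfig(config)
  outDir <- cfg$outDir
  if (is.null(outDir)) stop("config$outDir is required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(outDir, "run.log")
  log <- function(...) cat(sprintf(...), "\n", sep = "", file = logFile, append = TRUE)
  cat("", file = logFile)
  log("TransPocket %s | seed %d", as.character(utils::packageVersion("TransPocket")),
      as.integer(cfg$seed))
  log("parameters: %s", jsonlite::toJSON(cfg[c("site", "mapping", "metric",
                                               "cluster", "pocket", "transient")],
                                         auto_unbox = TRUE))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log("stage '%s' FAILED: %s", name, conditionMessage(e))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  set.seed(as.integer(cfg$seed))

  ens <- stage("input", {
    if (is(cfg$ensemble, "StructureEnsemble")) cfg$ensemble
    else {
      ref <- if (is(cfg$reference, "ProteinStructure")) cfg$reference
             else readPdb(cfg$reference, "first")[[1]]
      mems <- if (length(cfg$ensemble) == 1L && !is(cfg$ensemble, "ProteinStructure"))
        readPdb(cfg$ensemble, "all")
      else unlist(lapply(cfg$ensemble, function(p) readPdb(p, "first")), recursive = FALSE)
      StructureEnsemble(ref, mems)
    }
  })
  log("ensemble: %d members, reference '%s'", nMembers(ens),
      referenceStructure(ens)@id)

  site <- stage("binding_site", {
    if (!is.null(cfg$ligand)) {
      lig <- if (is(cfg$ligand, "ProteinStructure")) cfg$ligand
             else readPdb(cfg$ligand, "first")[[1]]
      defineSiteFromLigand(referenceStructure(ens), lig, cfg$site$radius)
    } else if (!is.null(cfg$center)) {
      defineSiteFromPoint(referenceStructure(ens), as.numeric(cfg$center),
                          cfg$site$radius)
    } else stop("either ligand or center must be given")
  })
  log("site: %d residues within %.1f A", nrow(siteResidues(site)), siteRadius(site))

  sup <- stage("superpose", superposeEnsemble(ens, site, cfg$mapping$minIdentity))
  stats <- stage("rmsd_stats", rmsdStats(sup, site, cfg$metric))
  .writeCsv(data.frame(member = rownames(stats$matrix),
                       round(stats$matrix, 6), check.names = FALSE),
            outDir, "rmsd_matrix.csv")
  .writeCsv(data.frame(member = names(stats$perMemberMean),
                       mean_rmsd = round(stats$perMemberMean, 6),
                       fit_rmsd = round(sup$fitRmsd, 6)),
            outDir, "per_member_mean.csv")
  .writeCsv(data.frame(residue = names(stats$perResidueMax),
                       max_rmsd = round(stats$perResidueMax, 6)),
            outDir, "per_residue_max.csv")
  writePdb(c(list(referenceStructure(sup$ensemble)), members(sup$ensemble)),
           file.path(outDir, "superposed.pdb"))

  clustering <- stage("cluster", {
    if (cfg$cluster$method == "single_linkage") {
      singleLinkageCluster(stats$matrix, cfg$cluster$threshold)
    } else {
      feat <- sideChainCenterFeatures(sup, site)
      kmeansThresholdCluster(feat, cfg$cluster$threshold,
                             seed = cfg$cluster$seed,
                             maxK = if (is.null(cfg$cluster$maxK)) nrow(feat)
                                    else cfg$cluster$maxK)
    }
  })
  log("clustering (%s, %.2f A): %d clusters", clustering@method,
      clustering@threshold, nClusters(clustering))
  .writeCsv(data.frame(member = sup$ensemble@labels,
                       label = clusterLabels(clustering),
                       is_representative = seq_len(nMembers(ens)) %in%
                         representatives(clustering)),
            outDir, "clusters.csv")
  .writeCsv(clusterReport(clustering, round(stats$perResidue, 6),
                          sup$ensemble@labels),
            outDir, "cluster_report.csv")

  pockets <- stage("pocket", {
    grid <- buildPocketGrid(site, cfg$pocket$margin, cfg$pocket$spacing)
    det <- function(s) detectPocket(s, grid, site, cfg$pocket$probeRadius,
                                    cfg$pocket$minBuried, cfg$pocket$scanDepth)
    list(grid = grid, reference = det(referenceStructure(sup$ensemble)),
         members = lapply(members(sup$ensemble), det))
  })
  statsList <- stage("pocket_stats", {
    ps <- function(p, s) pocketStats(p, s, cfg$pocket$contactDistance,
                                     cfg$pocket$probeRadius)
    list(reference = ps(pockets$reference, referenceStructure(sup$ensemble)),
         members = Map(ps, pockets$members, members(sup$ensemble)))
  })
  .writeCsv(do.call(rbind, lapply(c(list(statsList$reference), statsList$members),
    function(s) data.frame(structure = s@structureId, volume = s@volume,
                           surface_area = s@surfaceArea,
                           n_lining = length(s@liningResidues),
                           t(s@propertyCounts)))),
    outDir, "pocket_stats.csv")
  .writeCsv(liningResidueComparison(statsList$members, statsList$reference),
            outDir, "lining_residues.csv")

  transients <- stage("transient", {
    pocketSet <- pockets$members
    if (isTRUE(cfg$transient$includeReference))
      pocketSet <- c(list(pockets$reference), pocketSet)
    freq <- frequencyGrid(pocketSet)
    writeDxGrid(freq, file.path(outDir, "frequency.dx"))
    regions <- list(); subTab <- NULL; openTab <- NULL
    for (thr in cfg$transient$thresholds) {
      tr <- transientRegions(freq, pockets$reference, thr,
                             cfg$transient$conservedFraction)
      tag <- sprintf("%d", round(thr * 100))
      writeDxGrid(tr$appearing, file.path(outDir, sprintf("appearing_%s.dx", tag)))
      writeDxGrid(tr$disappearing,
                  file.path(outDir, sprintf("disappearing_%s.dx", tag)))
      for (regionName in c("appearing", "disappearing")) {
        sp <- splitSubpockets(tr[[regionName]], cfg$transient$minSubpocketPoints)
        tab <- subPocketTable(sp)
        if (nrow(tab)) {
          tab <- cbind(region = regionName, threshold = thr, tab,
                       volume = tab$size * freq@spacing^3)
          subTab <- rbind(subTab, tab)
          for (lb in tab$label) {
            os <- openingSeries(sp, lb, pockets$members)
            openTab <- rbind(openTab, data.frame(
              region = regionName, threshold = thr, subpocket = lb,
              member = sup$ensemble@labels, opening_fraction = os,
              open_volume = os * sum(gridValues(sp@grid) == lb) * freq@spacing^3))
          }
        }
      }
      regions[[tag]] <- tr
    }
    writeDxGrid(regions[[1]]$conserved, file.path(outDir, "conserved.dx"))
    if (is.null(subTab))
      subTab <- data.frame(region = character(0), threshold = numeric(0),
                           label = integer(0), size = integer(0),
                           cx = numeric(0), cy = numeric(0), cz = numeric(0),
                           volume = numeric(0))
    if (is.null(openTab))
      openTab <- data.frame(region = character(0), threshold = numeric(0),
                            subpocket = integer(0), member = character(0),
                            opening_fraction = numeric(0), open_volume = numeric(0))
    .writeCsv(subTab, outDir, "subpockets.csv")
    .writeCsv(openTab, outDir, "opening_series.csv")
    list(frequency = freq, regions = regions, subpockets = subTab,
         opening = openTab)
  })

  conservation <- NULL
  if (!is.null(cfg$msa)) conservation <- stage("conservation", {
    msa <- if (is.character(cfg$msa)) readMsaFasta(cfg$msa) else cfg$msa
    prof <- conservationProfile(msa)
    diffProf <- NULL
    if (!is.null(cfg$offTarget)) {
      if (!cfg$offTarget %in% names(msa))
        stop("off-target id '", cfg$offTarget, "' not in MSA")
      on <- msa[setdiff(names(msa), cfg$offTarget)]
      diffProf <- differentialConservation(on, as.character(msa[[cfg$offTarget]]))
    }
    mapped <- prof
    if (isTRUE(cfg$mapConservation)) {
      mapped <- tryCatch(
        mapScoresToStructure(prof, msa, referenceStructure(sup$ensemble)),
        error = function(e) { log("conservation mapping skipped: %s",
                                  conditionMessage(e)); prof })
      if (length(residueScores(mapped)))
        writePdb(referenceStructure(sup$ensemble),
                 file.path(outDir, "conservation_bfactor.pdb"),
                 bfactor = residueScores(mapped))
    }
    tab <- data.frame(column = seq_along(rawScores(prof)),
                      raw = rawScores(prof), rescaled = rescaledScores(prof))
    if (!is.null(diffProf)) {
      tab$raw_differential <- rawScores(diffProf)
      tab$rescaled_differential <- rescaledScores(diffProf)
    }
    .writeCsv(tab, outDir, "conservation.csv")
    list(profile = mapped, differential = diffProf)
  })

  result <- list(site = site, superposed = sup, stats = stats,
                 clustering = clustering, pockets = pockets,
                 pocketStats = statsList, transients = transients,
                 conservation = conservation, outDir = outDir)
  summary <- summarizeRun(outDir)
  log("done: %d clusters, reference pocket volume %.1f A^3",
      summary$cluster_count, statsList$reference@volume)
  invisible(result)
}

#' Summarize a pipeline run directory as JSON
#'
#' Collects cluster count and representatives, per-member pocket volumes,
#' the sub-pocket table and (when present) the top differential
#' conservation columns from the CSV artifacts of
#' \code{\link{runPipeline}}, and writes \code{summary.json} in the run
#' directory.
#'
#' @param dir a run directory.
#' @return the summary list, invisibly written to summary.json.
#' @export
summarizeRun <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), check.names = FALSE)
  clusters <- rd("clusters.csv")
  pstats <- rd("pocket_stats.csv")
  sub <- rd("subpockets.csv")
  out <- list(
    cluster_count = length(unique(clusters$label)),
    representatives = clusters$member[clusters$is_representative],
    pocket_volume = stats::setNames(as.list(pstats$volume), pstats$structure),
    subpockets = sub)
  if (file.exists(file.path(dir, "conservation.csv"))) {
    cons <- rd("conservation.csv")
    if ("rescaled_differential" %in% names(cons)) {
      ord <- order(-cons$rescaled_differential)
      out$top_differential_columns <- cons$column[utils::head(ord, 10)]
    }
  }
  jsonlite::write_json(out, file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out)
}

#' Crystal-structure ensemble analysis from PDB files
#'
#' The workflow used for analysing the binding-site variability of a
#' protein across its deposited crystal structures: every input entry is
#' split into single protein chains (HETATM dropped), unwanted chains are
#' excluded, the binding site is defined around a ligand extracted from
#' the reference entry, all chains are mapped and superposed onto the
#' reference, and the site conformations are clustered with threshold
#' k-means on side-chain geometric centres.
#'
#' @param pdbPaths paths of the multi-chain PDB entries.
#' @param referencePath path of the reference entry (single chain used).
#' @param ligandPath path of the ligand PDB defining the site.
#' @param radius site radius, Angstrom (default 5).
#' @param clusterThreshold k-means threshold, Angstrom (default 1.5).
#' @param excludeChains chain ids (as "<entry>_<chain>") to discard, e.g.
#'   chains with many missing site residues.
#' @param seed clustering seed (default 17).
#' @param minIdentity mapping identity floor (default 0.2).
#' @return list with \code{chainCount} (realized number of analysed
#'   chains), \code{clustering}, \code{stats}, \code{superposed},
#'   \code{site}.
#' @export
runPdbEnsembleAnalysis <- function(pdbPaths, referencePath, ligandPath,
                                   radius = 5, clusterThreshold = 1.5,
                                   excludeChains = character(0), seed = 17L,
                                   minIdentity = 0.2) {
  chains <- unlist(lapply(pdbPaths, function(p)
    splitChains(readPdb(p, "first")[[1]])), recursive = FALSE)
  keep <- !vapply(chains, function(s) s@id %in% excludeChains, logical(1))
  chains <- chains[keep]
  message("realized chain count: ", length(chains))
  ref <- splitChains(readPdb(referencePath, "first")[[1]])[[1]]
  lig <- readPdb(ligandPath, "first")[[1]]
  site <- defineSiteFromLigand(ref, lig, radius)
  ens <- StructureEnsemble(ref, chains)
  sup <- superposeEnsemble(ens, site, minIdentity)
  feat <- sideChainCenterFeatures(sup, site)
  clustering <- kmeansThresholdCluster(feat, clusterThreshold, seed = seed)
  stats <- rmsdStats(sup, site, "sidechain_center")
  list(chainCount = length(chains), clustering = clustering, stats = stats,
       superposed = sup, site = site)
}
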