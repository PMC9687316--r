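#' Pipeline run configuration
#'
#' Assembles the configuration for [runPipeline()] with the standard
#' thresholds: confidence cutoff 90 (strict `>`), fragment merge gap 15
#' residues, cluster cutoff 0.3 nm, interfacial-contact threshold 5.5
#' Angstrom, hydrogen-bond cutoff 3.5 Angstrom, hydrophobic-contact cutoff
#' 4.0 Angstrom, minimum peptide length 8, temperature 298.15 K, and the
#' bundled DNA-binding site ranges. Every input is optional; stages without
#' input are skipped and recorded as such.
#'
#' @param structures named character vector/list of PDB paths (or
#'   [ProteinStructure-class] objects) for the fragment stage.
#' @param ensemble multi-model PDB path or [PoseEnsemble-class] for the
#'   clustering stage.
#' @param scores path to a per-pose score TSV (`pose_id`, `score`, optional
#'   grouping columns) for the score summary.
#' @param complex PDB path or [ProteinStructure-class] of the docked
#'   complex for the interface stage.
#' @param receptorChains,ligandChains chain-id sets of the complex.
#' @param residueLists character paths (or pre-read lists) of interfacial
#'   residue-list files for the peptide stage, fragment-1 complexes first.
#' @param interfaceResidues optional TSV (`peptide`, `pose`, `fragment`,
#'   `residues`) of receptor-side interface residues for overlap scoring.
#' @param trajectory multi-model PDB path or [Trajectory-class] for the
#'   trajectory stage.
#' @param dt trajectory frame interval, ps.
#' @param confidenceThreshold,mergeGap fragment-extraction parameters.
#' @param clusterCutoff GROMOS cutoff, nm.
#' @param contactThreshold interfacial-contact threshold, Angstrom.
#' @param hbondMax,hydrophobicMax trajectory contact cutoffs, Angstrom.
#' @param minPeptideLength minimum stretch span for peptide candidates.
#' @param dnaSites `data.frame` with `fragment`, `start`, `end`.
#' @param temperature K, for the affinity/Kd conversion.
#' @param seed integer seed recorded in provenance and set before the run.
#' @param outDir optional output directory; when given, every stage writes
#'   its files there.
#' @return a `boomdock_config` list.
#' @export
boomdockConfig <- function(structures = NULL, ensemble = NULL, scores = NULL,
                           complex = NULL, receptorChains = "A",
                           ligandChains = "B", residueLists = NULL,
                           interfaceResidues = NULL, trajectory = NULL,
                           dt = 2, confidenceThreshold = 90, mergeGap = 15,
                           clusterCutoff = 0.3, contactThreshold = 5.5,
                           hbondMax = 3.5, hydrophobicMax = 4.0,
                           minPeptideLength = 8,
                           dnaSites = dnaBindingSites(),
                           temperature = 298.15, seed = 1, outDir = NULL) {
  cfg <- list(structures = structures, ensemble = ensemble, scores = scores,
              complex = complex, receptorChains = receptorChains,
              ligandChains = ligandChains, residueLists = residueLists,
              interfaceResidues = interfaceResidues,
              trajectory = trajectory, dt = dt,
              confidenceThreshold = confidenceThreshold,
              mergeGap = mergeGap, clusterCutoff = clusterCutoff,
              contactThreshold = contactThreshold, hbondMax = hbondMax,
              hydrophobicMax = hydrophobicMax,
              minPeptideLength = minPeptideLength, dnaSites = dnaSites,
              temperature = temperature, seed = seed, outDir = outDir)
  class(cfg) <- "boomdock_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Returns findings (character vector), not exceptions; an empty vector
#' means the configuration is valid. Checked: positive thresholds, disjoint
#' non-empty chain sets, well-formed DNA-binding ranges, positive peptide
#' length and temperature.
#'
#' @param config a [boomdockConfig()] list.
#' @return character vector of findings, possibly empty.
#' @export
validateConfig <- function(config) {
  findings <- character(0)
  pos <- c("confidenceThreshold", "clusterCutoff", "contactThreshold",
           "hbondMax", "hydrophobicMax", "temperature", "dt")
  for (f in pos)
    if (!is.numeric(config[[f]]) || length(config[[f]]) != 1L ||
        !is.finite(config[[f]]) || config[[f]] <= 0)
      findings <- c(findings, paste0(f, " must be a positive number"))
  if (!is.numeric(config$mergeGap) || config$mergeGap < 0)
    findings <- c(findings, "mergeGap must be >= 0")
  if (!is.numeric(config$minPeptideLength) || config$minPeptideLength < 1)
    findings <- c(findings, "minPeptideLength must be >= 1")
  if (length(intersect(config$receptorChains, config$ligandChains)))
    findings <- c(findings, "chain sets overlap")
  if (!length(config$receptorChains) || !length(config$ligandChains))
    findings <- c(findings, "chain sets must be non-empty")
  ds <- config$dnaSites
  if (!is.null(ds)) {
    if (!is.data.frame(ds) || !all(c("start", "end") %in% names(ds)))
      findings <- c(findings, "dnaSites must have start and end columns")
    else if (any(ds$start > ds$end))
      findings <- c(findings, "dnaSites contains a range with start > end")
  }
  findings
}

#' Run the post-docking analysis pipeline
#'
#' Executes, in order and each only when its input is present: fragment
#' extraction from confidence-scored structures; pose clustering with
#' representative selection; docked-score summarization; interface
#' characterization (dSASA, contacts, affinity, Kd); peptide candidate
#' design from interfacial residue lists; DNA-binding-site overlap scoring;
#' and trajectory metrics (RMSD, RMSF, hydrogen bonds, hydrophobic
#' contacts). Skipped stages are recorded. A stage error aborts the run
#' naming the stage and input. With `outDir` set, each stage writes its
#' table/JSON/FASTA/PDB outputs there; re-running an identical
#' configuration on identical inputs reproduces the outputs byte for byte.
#'
#' @param config a [boomdockConfig()] list.
#' @return a `RunReport` list: `tables` (per-stage outputs), `skipped`,
#'   `notes`, `provenance`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "boomdock_config"))
  findings <- validateConfig(config)
  if (length(findings))
    stop("invalid configuration:\n  - ",
         paste(findings, collapse = "\n  - "))
  set.seed(config$seed)
  out_dir <- config$outDir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  report <- list(tables = list(), skipped = character(0),
                 notes = character(0),
                 provenance = list(
                   package = "boomdock",
                   version = as.character(utils::packageVersion("boomdock")),
                   seed = config$seed,
                   thresholds = config[c("confidenceThreshold", "mergeGap",
                                         "clusterCutoff", "contactThreshold",
                                         "hbondMax", "hydrophobicMax",
                                         "minPeptideLength",
                                         "temperature")]))
  stage <- function(name, input_id, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed for %s: %s", name, input_id,
                   conditionMessage(e)), call. = FALSE))
  }
  as_structure <- function(x, id) if (is(x, "ProteinStructure")) x else
    readStructure(x, id = id)

  # --- fragments -----------------------------------------------------------
  if (!is.null(config$structures)) {
    frag_rows <- list()
    all_frags <- list()
    for (nm in names(config$structures)) {
      stage("fragments", nm, {
        s <- as_structure(config$structures[[nm]], nm)
        fr <- extractConfidentFragments(s, config$confidenceThreshold,
                                        config$mergeGap)
        all_frags[[nm]] <- fr
        for (f in fr)
          frag_rows[[length(frag_rows) + 1L]] <- data.frame(
            structure = nm, fragment = f$fragment_id, chain = f$chain,
            runs = paste(vapply(f$runs, function(r)
              paste(r, collapse = "-"), character(1)), collapse = ","),
            n_residues = sum(vapply(f$runs, function(r)
              r[2] - r[1] + 1L, integer(1))),
            stringsAsFactors = FALSE)
      })
    }
    report$tables$fragments <- if (length(frag_rows))
      do.call(rbind, frag_rows) else data.frame()
    if (!is.null(out_dir))
      for (nm in names(all_frags))
        writeFragments(all_frags[[nm]],
                       file.path(out_dir, paste0(nm, "_fragments.json")))
  } else report$skipped <- c(report$skipped, "fragments")

  # --- clustering ----------------------------------------------------------
  ens <- NULL
  if (!is.null(config$ensemble)) {
    stage("cluster", "ensemble", {
      ens <- if (is(config$ensemble, "PoseEnsemble")) config$ensemble else
        readEnsemble(config$ensemble)
      m <- pairwiseRMSD(ens)
      cl <- gromosCluster(m, config$clusterCutoff)
      rep_idx <- representative(cl, quiet = TRUE)
      sizes <- clusterSizes(cl)
      report$tables$clusters <- data.frame(
        cluster = seq_along(sizes), size = sizes,
        center = vapply(cl@clusters, `[[`, integer(1), "center"))
      report$tables$representative <- data.frame(
        complex = structureId(ens), pose = rep_idx,
        tie = length(cl@ties) > 0 &&
          any(vapply(cl@ties, function(t) 1 %in% t, logical(1))))
      if (!is.null(out_dir)) {
        payload <- list(cutoff = cl@cutoff,
                        clusters = lapply(cl@clusters, function(x)
                          list(center = x$center, members = x$members,
                               size = length(x$members))),
                        ties = cl@ties)
        writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                    pretty = TRUE),
                   file.path(out_dir, "clusters.json"))
        topo <- ens@topology
        topo@atoms[, c("x", "y", "z")] <- ens@coords[, , rep_idx]
        writePDB(topo, file.path(out_dir, "representative.pdb"))
      }
    })
  } else report$skipped <- c(report$skipped, "cluster")

  # --- docked-score summary ------------------------------------------------
  if (!is.null(config$scores)) {
    stage("scores", config$scores, {
      df <- if (is.data.frame(config$scores)) config$scores else
        readScoreTable(config$scores)
      if ("receptor" %in% names(df)) {
        agg <- do.call(rbind, lapply(split(df, df$receptor), function(g)
          data.frame(receptor = g$receptor[1], n = nrow(g),
                     average = summarizeScores(g$score)$report)))
        rownames(agg) <- NULL
      } else {
        agg <- data.frame(receptor = "all", n = nrow(df),
                          average = summarizeScores(df$score)$report)
      }
      report$tables$score_summary <- agg
      if (!is.null(out_dir))
        utils::write.table(agg, file.path(out_dir, "score_summary.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    })
  } else report$skipped <- c(report$skipped, "scores")

  # --- interface -----------------------------------------------------------
  iface <- NULL
  if (!is.null(config$complex)) {
    stage("interface", "complex", {
      cx <- as_structure(config$complex, "complex")
      model <- defaultAffinityModel()
      model$temperature <- config$temperature
      iface <- interfaceReport(cx, config$receptorChains,
                                config$ligandChains,
                                threshold = config$contactThreshold,
                                model = model)
      files <- if (is.null(out_dir)) list(NULL, NULL) else
        list(file.path(out_dir, "interface.json"),
             file.path(out_dir, "interface.tsv"))
      report$tables$interface <- writeInterfaceReport(
        iface, json = files[[1]], tsv = files[[2]])$table
    })
  } else report$skipped <- c(report$skipped, "interface")

  # --- peptide design ------------------------------------------------------
  peptides <- NULL
  if (!is.null(config$residueLists)) {
    stage("peptides", "residue lists", {
      lists <- list()
      for (p in config$residueLists)
        lists <- c(lists, if (is.character(p)) readResidueLists(p)
                   else list(p))
      peptides <- selectPeptides(lists, config$minPeptideLength)
      report$tables$peptides <- peptides
      if (!nrow(peptides))
        report$notes <- c(report$notes,
                           sprintf("0 candidates at minimum length %d",
                                   config$minPeptideLength))
      if (!is.null(out_dir) && nrow(peptides))
        peptidesToFasta(peptides, file.path(out_dir, "peptides.fasta"))
    })
  } else report$skipped <- c(report$skipped, "peptides")

  # --- DNA-binding overlap -------------------------------------------------
  if (!is.null(config$interfaceResidues) || !is.null(iface)) {
    stage("overlap", "interface residues", {
      rows <- list()
      sites <- config$dnaSites
      if (!is.null(config$interfaceResidues)) {
        df <- if (is.data.frame(config$interfaceResidues))
          config$interfaceResidues else
          utils::read.delim(config$interfaceResidues,
                            stringsAsFactors = FALSE)
        for (i in seq_len(nrow(df))) {
          res <- parseResidueTokens(df$residues[i])$resno
          site <- sites[match(df$fragment[i], sites$fragment), ]
          if (is.na(site$start[1]))
            stop("unknown fragment id: ", df$fragment[i])
          sc <- overlapScore(res, site)
          rows[[length(rows) + 1L]] <- data.frame(
            peptide = df$peptide[i], pose = df$pose[i],
            fragment = df$fragment[i], site = paste0(site$start, "-",
                                                     site$end),
            count = sc$count,
            residues = paste(sc$residues, collapse = ","),
            stringsAsFactors = FALSE)
        }
      } else {
        res <- iface@deltaSASA
        res <- res[res$interface & res$side == "receptor", "resno"]
        for (i in seq_len(nrow(sites))) {
          sc <- overlapScore(res, sites[i, ])
          rows[[length(rows) + 1L]] <- data.frame(
            peptide = structureId_or(iface@id), pose = NA,
            fragment = sites$fragment[i],
            site = paste0(sites$start[i], "-", sites$end[i]),
            count = sc$count,
            residues = paste(sc$residues, collapse = ","),
            stringsAsFactors = FALSE)
        }
      }
      report$tables$overlap <- do.call(rbind, rows)
      if (!is.null(out_dir))
        utils::write.table(report$tables$overlap,
                           file.path(out_dir, "overlap.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    })
  } else report$skipped <- c(report$skipped, "overlap")

  # --- trajectory metrics --------------------------------------------------
  if (!is.null(config$trajectory)) {
    stage("trajectory", "trajectory", {
      traj <- if (is(config$trajectory, "Trajectory")) config$trajectory
        else asTrajectory(config$trajectory, dt = config$dt)
      two_sided <- all(c(config$receptorChains, config$ligandChains) %in%
                         chainIds(traj@topology))
      fit_sel <- if (two_sided) config$receptorChains else NULL
      mea_sel <- if (two_sided) config$ligandChains else NULL
      report$tables$rmsd <- rmsdSeries(traj, fitSelection = fit_sel,
                                        measureSelection = mea_sel)
      report$tables$rmsf <- rmsfProfile(traj)
      frame1 <- traj@topology
      if (two_sided) {
        report$tables$hbonds <- hydrogenBonds(
          frame1, config$receptorChains, config$ligandChains,
          config$hbondMax)
        report$tables$hydrophobic <- hydrophobicContacts(
          frame1, config$receptorChains, config$ligandChains,
          config$hydrophobicMax)
      }
      if (!is.null(out_dir)) {
        utils::write.table(report$tables$rmsd,
                           file.path(out_dir, "rmsd.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(report$tables$rmsf,
                           file.path(out_dir, "rmsf.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    })
  } else report$skipped <- c(report$skipped, "trajectory")

  class(report) <- "RunReport"
  if (!is.null(out_dir)) {
    js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", pretty = TRUE, force = TRUE)
    writeLines(js, file.path(out_dir, "report.json"))
  }
  report
}

structureId_or <- function(x) if (nzchar(x)) x else "complex"

#' @export
print.RunReport <- function(x, ...) {
  cat("boomdock RunReport\n")
  cat("  stages run:   ", paste(names(x$tables), collapse = ", "), "\n")
  if (length(x$skipped))
    cat("  stages skipped:", paste(x$skipped, collapse = ", "), "\n")
  for (note in x$notes) cat("  note:", note, "\n")
  invisible(x)
}
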