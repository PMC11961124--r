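#' Validate a run configuration
#'
#' @param config named list or path to a YAML/JSON config file. Recognized
#'   keys: `structure` (path), `chain`, `holo` (path), `holo_chain`,
#'   `ligand` ("chain:resno:resname"), `pocket_cutoff`, `trajectory` (path),
#'   `trajectory_total_time`, `motif`, `core`, `chromatogram` (path),
#'   `n_peaks`, `peak_centers`, `peak_labels`, `standards` (path to CSV
#'   Ve,mass), `titration` (list A412, path_length, protein_conc, epsilon),
#'   `assay` (list dA340_per_min, epsilon_NADPH, path_length, assay_volume,
#'   enzyme_mass), `sasa` (list probe_radius, n_points), `redox` (cutoff
#'   overrides), `assembly_threshold`, `seed`, `output_dir`.
#' @return the validated config list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  known <- c("structure", "chain", "holo", "holo_chain", "ligand",
             "pocket_cutoff", "trajectory", "trajectory_total_time", "motif",
             "core", "chromatogram", "n_peaks", "peak_centers", "peak_labels",
             "standards", "titration", "assay", "sasa", "redox",
             "assembly_threshold", "seed", "output_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in c("structure", "holo", "trajectory", "chromatogram", "standards")) {
    if (!is.null(config[[k]]) && !file.exists(config[[k]]))
      stop("config path does not exist: ", k, " = ", config[[k]])
  }
  if (is.null(config$seed)) config$seed <- 1L
  config
}

.stage <- function(name, enabled, fun) {
  if (!enabled) return(list(status = "skipped"))
  tryCatch(c(list(status = "ok"), fun()),
           error = function(e) list(status = "error", message = conditionMessage(e)))
}

#' Run the full structure-to-report pipeline
#'
#' Executes every stage whose inputs are present in the config — structure
#' census, per-chain superpositions, solvent accessibility, cysteine redox
#' report, pocket mapping, interfaces/assemblies, SEC calibration and
#' deconvolution, trajectory analytics, titration and activity arithmetic —
#' and writes a JSON report (plus per-stage tables) under `output_dir`.
#' Identical config and seed give an identical report; stage failures are
#' isolated and reported while the remaining stages still run.
#'
#' @param config see [validate_config()].
#' @return the report list, invisibly; JSON at
#'   `file.path(output_dir, "report.json")` when `output_dir` is set.
#' @export
run_report <- function(config) {
  config <- validate_config(config)
  report <- list(parameters = config[setdiff(names(config), "output_dir")])
  s <- NULL
  if (!is.null(config$structure)) s <- parse_structure(config$structure)

  report$census <- .stage("census", !is.null(s), function() {
    cen <- structure_census(s)
    cen$residues_per_chain <- as.list(cen$residues_per_chain)
    cen
  })

  report$superposition <- .stage("superposition",
                                 !is.null(s) && structure_census(s)$n_chains >= 2, function() {
    ch <- structure_census(s)$chain_ids
    ref <- ch[1]
    out <- lapply(ch[-1], function(c2) {
      sp <- superpose_chains(s, c2, s, ref, trim = list())
      list(moving = c2, fixed = ref, rmsd = sp$rmsd, rmsd_all = sp$rmsd_all,
           n_atoms = sp$n_atoms, retained_fraction = sp$retained_fraction)
    })
    list(reference_chain = ref, pairs = out)
  })

  sasa_par <- config$sasa
  tab <- NULL
  report$sasa <- .stage("sasa", !is.null(s), function() {
    tab <<- shrake_rupley(s,
                          probe_radius = if (is.null(sasa_par$probe_radius)) 1.4 else sasa_par$probe_radius,
                          n_points = if (is.null(sasa_par$n_points)) 960 else sasa_par$n_points)
    list(probe_radius = tab$probe_radius, n_points = tab$n_points,
         total_asa = sum(tab$atoms$asa))
  })

  report$redox <- .stage("redox", !is.null(s) && !is.null(tab), function() {
    rx <- config$redox
    rep_ <- cysteine_report(
      s, tab, chain = config$chain,
      bond_cutoff = if (is.null(rx$bond_cutoff)) 2.3 else rx$bond_cutoff,
      direct_exchange_cutoff = if (is.null(rx$direct_exchange_cutoff)) 5.0 else rx$direct_exchange_cutoff,
      rearrangement_cutoff = if (is.null(rx$rearrangement_cutoff)) 11.0 else rx$rearrangement_cutoff)
    list(summary = rep_$summary, cysteines = rep_$cysteines,
         disulfides = rep_$disulfides)
  })

  report$titration <- .stage("titration", !is.null(config$titration), function() {
    ti <- config$titration
    thiols <- dtnb_stoichiometry(ti$A412,
                                 path_length = if (is.null(ti$path_length)) 1 else ti$path_length,
                                 protein_conc = ti$protein_conc,
                                 epsilon = if (is.null(ti$epsilon)) 14.15 else ti$epsilon)
    out <- list(thiols_per_monomer = thiols)
    if (report$redox$status == "ok" && !is.null(ti$sd)) {
      rep_ <- structure(list(summary = report$redox$summary), class = "CysteineReport")
      out$reconciliation <- reconcile_titration(rep_, thiols, ti$sd)
    }
    out
  })

  report$activity <- .stage("activity", !is.null(config$assay), function() {
    a <- config$assay
    list(specific_activity = specific_activity(
      a$dA340_per_min,
      epsilon_NADPH = if (is.null(a$epsilon_NADPH)) 6.22 else a$epsilon_NADPH,
      path_length = if (is.null(a$path_length)) 1 else a$path_length,
      assay_volume = a$assay_volume, enzyme_mass = a$enzyme_mass))
  })

  report$pocket <- .stage("pocket",
                          !is.null(s) && !is.null(config$holo) && !is.null(config$ligand),
                          function() {
    holo <- parse_structure(config$holo)
    pm <- map_pocket_from_holo(
      s, if (is.null(config$chain)) structure_census(s)$chain_ids[1] else config$chain,
      holo, if (is.null(config$holo_chain)) structure_census(holo)$chain_ids[1] else config$holo_chain,
      config$ligand,
      cutoff = if (is.null(config$pocket_cutoff)) 4.0 else config$pocket_cutoff)
    list(residues = pm$residues, cutoff = pm$cutoff,
         superposition_rmsd = pm$superposition$rmsd)
  })

  report$assembly <- .stage("assembly",
                            !is.null(s) && structure_census(s)$n_chains >= 2, function() {
    ag <- detect_assemblies(s, threshold = if (is.null(config$assembly_threshold)) 500
                            else config$assembly_threshold,
                            n_points = if (is.null(sasa_par$n_points)) 960 else sasa_par$n_points)
    list(edges = ag$edges,
         components = lapply(seq_along(ag$components), function(k)
           list(label = ag$labels[k], chains = ag$components[[k]])),
         threshold = ag$threshold)
  })

  report$sec <- .stage("sec", !is.null(config$chromatogram), function() {
    chrom <- parse_chromatogram(config$chromatogram)
    out <- list()
    curve <- NULL
    if (!is.null(config$standards)) {
      std <- read.table(config$standards, header = TRUE, sep = ",")
      curve <- sec_calibrate(std)
      out$calibration <- list(slope = curve$slope, intercept = curve$intercept,
                              r_squared = curve$r_squared, on = curve$on)
    }
    if (!is.null(config$n_peaks)) {
      centers <- config$peak_centers
      if (is.null(centers))
        centers <- seq(min(chrom$volume), max(chrom$volume),
                       length.out = config$n_peaks + 2)[2:(config$n_peaks + 1)]
      pm <- deconvolve(chrom, config$n_peaks, centers)
      out$peaks <- pm$peaks
      out$converged <- pm$converged
      if (!is.null(curve)) out$apparent_mass <- as.numeric(apparent_mass(curve, pm$peaks$center))
      labels <- config$peak_labels
      if (is.null(labels)) labels <- paste0("species", seq_len(config$n_peaks))
      out$repartition <- as.data.frame(repartition(pm, labels))
    }
    out
  })

  report$trajectory <- .stage("trajectory", !is.null(config$trajectory), function() {
    tr <- parse_trajectory(config$trajectory,
                           total_time = config$trajectory_total_time)
    motif <- config$motif
    if (is.null(motif)) stop("trajectory stage requires 'motif' residue numbers")
    motif <- .parse_range(motif)
    core <- if (is.null(config$core)) {
      resnos <- sort(unique(tr$topology$atoms$resno[!tr$topology$atoms$solvent]))
      setdiff(resnos, motif)
    } else .parse_range(config$core)
    al <- core_superpose(tr, core_resno = core)
    ser <- residue_rmsd_series(al, motif)
    cp <- detect_transitions(ser)
    blk_window <- c(max(al$times) - 0.15 * diff(range(al$times)), max(al$times))
    blk <- block_representative(al, blk_window)
    list(n_frames = length(tr$frames),
         core_rmsd_mean = mean(attr(al, "core_rmsd")),
         motif = motif,
         rmsf = as.list(rmsf(al, motif)),
         events = cp$events,
         per_residue_transitions = cp$per_residue,
         block = list(window = blk$window, medoid_frame = blk$medoid_frame,
                      medoid_time = blk$medoid_time,
                      mean_pairwise_rmsd = blk$mean_pairwise_rmsd))
  })

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", null = "null")
    writeLines(.report_text(report), file.path(config$output_dir, "report.txt"))
  }
  invisible(report)
}

.parse_range <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  parts <- strsplit(as.character(x), "-", fixed = TRUE)[[1]]
  seq(as.integer(parts[1]), as.integer(parts[2]))
}

.report_text <- function(report) {
  ln <- c("redoxstruct pipeline report", "===========================")
  for (st in setdiff(names(report), "parameters")) {
    sec <- report[[st]]
    ln <- c(ln, paste0("[", st, "] status: ", sec$status))
    if (identical(sec$status, "ok")) {
      flat <- unlist(sec[setdiff(names(sec), "status")])
      if (length(flat) > 0)
        ln <- c(ln, paste0("  ", names(flat), " = ",
                           vapply(flat, function(v) format(v, digits = 10), character(1))))
    } else if (identical(sec$status, "error")) {
      ln <- c(ln, paste0("  ", sec$message))
    }
  }
  ln
}
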