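# Orchestration: a single resolved configuration drives the stage chain
# simulate -> assign -> calibrate -> anneal -> refine -> analyze, each stage
# reading its inputs from the run directory (or from the in-memory results
# of the previous stage) and writing its outputs plus a manifest entry.

#' Default pipeline configuration
#'
#' All tunable parameters of every stage with their defaults; any subset can
#' be overridden through \code{...} or by loading a YAML file with
#' [load_pipeline_config()].  The configuration is validated before any
#' stage runs and a fully resolved copy is written into the run directory,
#' so a run can be reproduced exactly.
#'
#' @param ... named overrides of the defaults.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    outdir = "incellfold_run",
    seed = 1L,
    stages = c("simulate", "assign", "calibrate", "anneal", "refine",
               "analyze"),
    # simulate
    preset = "hairpin12",
    noe_sigma = 0.1,
    degeneracy_fraction = 0,
    r_max = 5.5,
    # assign
    tol_h = 0.04, tol_heavy = 0.4, min_support = 1,
    # inputs when the simulate stage is disabled
    peak_files = NULL, shift_file = NULL, upl_file = NULL, aco_file = NULL,
    sequence = NULL,
    # calibrate
    target_median = 4.0, d_min = 2.4, d_max = 6.0,
    # anneal
    n_starts = 20, n_steps = 5000,
    # refine
    replicas = 4, t_min = 300, t_max = 400, rexmc_steps = 2e5,
    exchange_every = 100, gibbs_every = 10, stride = 100, burn = NULL,
    # analyze
    subsample_fraction = 0.2)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown pipeline config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$stages) >= 1)
  bad <- setdiff(cfg$stages, c("simulate", "assign", "calibrate", "anneal",
                               "refine", "analyze"))
  if (length(bad)) stop("unknown pipeline stages: ", paste(bad, collapse = ", "))
  if (cfg$tol_h <= 0 || cfg$tol_heavy <= 0)
    stop("chemical-shift matching tolerances must be positive")
  if (cfg$d_min >= cfg$d_max) stop("d_min must be below d_max")
  if (cfg$replicas < 1 || cfg$t_min <= 0 || cfg$t_max < cfg$t_min)
    stop("invalid replica ladder specification")
  if (cfg$subsample_fraction <= 0 || cfg$subsample_fraction > 1)
    stop("subsample_fraction must be in (0, 1]")
  if (is.null(cfg$burn)) cfg$burn <- floor(cfg$rexmc_steps / 5)
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file of configuration overrides.
#' @export
load_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the structure-determination pipeline
#'
#' Executes the enabled stages in order.  Every stage writes its outputs
#' under \code{cfg$outdir}; a resolved configuration copy
#' (\code{config.yaml}) and a manifest of produced files are saved.
#' Re-running with the same resolved configuration is deterministic.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  cfg <- validate_pipeline_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_out <- cfg
  cfg_out$stages <- as.list(cfg$stages)
  yaml::write_yaml(cfg_out, file.path(cfg$outdir, "config.yaml"))
  manifest <- character(0)
  note <- function(f) manifest <<- c(manifest, f)
  res <- list()
  stage_on <- function(s) s %in% cfg$stages

  if (stage_on("simulate")) {
    spectra <- list(
      noesy_spec("noesyN", C = 64 * 4^6, sigma = cfg$noe_sigma, class = "N"),
      noesy_spec("noesyC", C = 40 * 4^6, sigma = cfg$noe_sigma, class = "C"))
    sc <- make_scenario(cfg$preset, seed = cfg$seed, spectra = spectra,
                        degeneracy_fraction = cfg$degeneracy_fraction,
                        r_max = cfg$r_max)
    res$scenario <- sc
    res$sequence <- sc$conformer$sequence
    res$shifts <- sc$shifts
    res$peaks <- sc$peaks
    write_shift_list(sc$shifts, file.path(cfg$outdir, "shifts.prot"))
    note("shifts.prot")
    for (id in names(sc$peaks)) {
      write_peak_list(sc$peaks[[id]], file.path(cfg$outdir,
                                                paste0(id, ".peaks")))
      note(paste0(id, ".peaks"))
    }
    write_pdb_model(sc$structure, file.path(cfg$outdir, "reference.pdb"))
    note("reference.pdb")
  } else {
    if (is.null(cfg$shift_file) || is.null(cfg$peak_files))
      stop("stage 'assign' requires shift_file and peak_files when the ",
           "simulate stage is disabled")
    res$shifts <- read_shift_list(cfg$shift_file)
    res$peaks <- lapply(cfg$peak_files, read_peak_list)
    names(res$peaks) <- vapply(res$peaks,
                               function(p) p$spectrum_id[1], character(1))
    res$sequence <- cfg$sequence
  }

  if (stage_on("assign")) {
    res$candidates <- lapply(res$peaks, function(p) {
      network_filter(match_assignments(p, res$shifts, tol_H = cfg$tol_h,
                                       tol_heavy = cfg$tol_heavy),
                     min_support = cfg$min_support)
    })
  }

  if (stage_on("calibrate")) {
    if (is.null(res$candidates)) stop("stage 'calibrate' needs 'assign'")
    sets <- list()
    offset <- 0L
    for (id in names(res$candidates)) {
      model <- auto_calibrate(res$peaks[[id]]$intensity, spectrum_id = id,
                              target_median = cfg$target_median,
                              d_min = cfg$d_min, d_max = cfg$d_max)
      rs <- calibrate(res$candidates[[id]], model)
      if (nrow(rs)) rs$group <- rs$group + offset
      offset <- offset + length(unique(rs$group))
      sets[[id]] <- rs
    }
    res$restraints <- do.call(rbind, unname(sets))
    class(res$restraints) <- c("restraint_set", "data.frame")
    write_upl(res$restraints, file.path(cfg$outdir, "restraints.upl"))
    note("restraints.upl")
  } else if (!is.null(cfg$upl_file)) {
    res$restraints <- read_upl(cfg$upl_file)
  }

  res$aco <- if (!is.null(cfg$aco_file)) read_aco(cfg$aco_file) else NULL

  if (stage_on("anneal")) {
    if (is.null(res$restraints)) stop("stage 'anneal' needs restraints")
    if (is.null(res$sequence)) stop("stage 'anneal' needs a sequence")
    ann <- run_annealing(res$sequence, res$restraints,
                         anneal_config(n_starts = cfg$n_starts,
                                       n_steps = cfg$n_steps,
                                       seed = cfg$seed),
                         aco = res$aco)
    res$annealed <- ann
    res$seed_conformer <- select_seed(ann)
    utils::write.table(
      data.frame(rank = seq_along(ann),
                 target = vapply(ann, `[[`, numeric(1), "target")),
      file.path(cfg$outdir, "anneal_targets.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    note("anneal_targets.tsv")
    write_pdb_model(build_coordinates(res$seed_conformer),
                    file.path(cfg$outdir, "seed.pdb"))
    note("seed.pdb")
  }

  if (stage_on("refine")) {
    if (is.null(res$seed_conformer)) stop("stage 'refine' needs 'anneal'")
    rc <- rexmc_config(n_steps = cfg$rexmc_steps,
                       ladder = build_ladder(cfg$replicas, cfg$t_min,
                                             cfg$t_max),
                       exchange_every = cfg$exchange_every,
                       gibbs_every = cfg$gibbs_every, stride = cfg$stride,
                       burn = if (is.null(cfg$burn))
                         floor(cfg$rexmc_steps / 5) else cfg$burn,
                       seed = cfg$seed)
    tr <- run_rexmc(res$seed_conformer, res$restraints, rc,
                    hyper = cybay_hyper(mu0 = NA))
    res$trace <- tr
    res$ensemble <- burn_and_thin(tr)
    utils::write.table(tr$log, file.path(cfg$outdir, "trace.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    note("trace.tsv")
    structs <- ensemble_structures(res$ensemble)
    res$structures <- structs
    write_pdb_model(structs, file.path(cfg$outdir, "ensemble.pdb"))
    note("ensemble.pdb")
  }

  if (stage_on("analyze")) {
    if (is.null(res$ensemble)) stop("stage 'analyze' needs 'refine'")
    structs <- res$structures
    ms <- map_state(res$ensemble)
    map_struct <- build_coordinates(torsion_conformer(res$sequence,
                                                      ms$angles))
    write_pdb_model(map_struct, file.path(cfg$outdir, "map.pdb"))
    note("map.pdb")
    report <- list(
      n_conformers = length(structs),
      rmsd_to_mean = rmsd_to_mean(structs),
      map_log_posterior = ms$log_posterior)
    prr <- per_residue_rmsd(structs, map_struct, "backbone")
    prs <- per_residue_rmsd(structs, map_struct, "sidechain")
    prr$sidechain_rmsd <- prs$rmsd
    prr$sidechain_sd <- prs$sd
    utils::write.table(prr, file.path(cfg$outdir, "per_residue_rmsd.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    note("per_residue_rmsd.tsv")
    pca <- pca_ensemble(structs)
    utils::write.table(
      data.frame(member = seq_len(nrow(pca$projections)),
                 PC1 = pca$projections[, 1],
                 PC2 = pca$projections[, 2]),
      file.path(cfg$outdir, "pca_projections.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    note("pca_projections.tsv")
    disp <- subsample(res$ensemble, cfg$subsample_fraction,
                      seed = cfg$seed)
    write_pdb_model(ensemble_structures(disp),
                    file.path(cfg$outdir, "ensemble_display.pdb"))
    note("ensemble_display.pdb")
    report$pc1_variance_fraction <- pca$variance_fraction[1]
    res$report <- report
    jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    note("report.json")
  }

  writeLines(manifest, file.path(cfg$outdir, "MANIFEST"))
  res$manifest <- manifest
  res$config <- cfg
  invisible(res)
}
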