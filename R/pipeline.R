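## Pipeline configuration, demo data generation, and report bundles tying
## the analysis stages together.

#' Pipeline configuration with the protocol defaults
#'
#' Every tunable of the analysis pipeline, with the umbrella/WHAM/SASA
#' protocol constants as defaults: 5 degree window spacing (72 windows),
#' k = 2000 kcal/(mol rad^2), 720 bins, tolerance 1e-6, 4 error blocks,
#' 300 K, open/closed SASA threshold 0.001 nm^2.
#'
#' @param structure path to a PDB file, or a `dna_structure`, or NULL to
#'   build the bundled example system.
#' @param windows_dir directory of umbrella-window series (optional).
#' @param analyses character vector among `"steps"`, `"regions"`,
#'   `"grooves"`, `"overlaps"`, `"bends"`, `"variability"`, `"pca"`,
#'   `"pmf"`.
#' @param output_dir where to write the report bundle.
#' @param with_tfo annotate/build the triplex variant of the example system.
#' @param window_spacing,umbrella_k,n_bins,wham_tolerance,n_blocks,temperature
#'   umbrella/WHAM protocol settings.
#' @param sasa_threshold,sasa_radii,sasa_probe open/closed definition.
#' @param minor_offset,major_offset groove-width cross-strand offsets.
#' @param seed RNG seed for any synthetic stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(structure = NULL, windows_dir = NULL,
                            analyses = c("steps", "regions", "grooves"),
                            output_dir = "stepflip_out", with_tfo = FALSE,
                            window_spacing = 5, umbrella_k = 2000,
                            n_bins = 720, wham_tolerance = 1e-6,
                            n_blocks = 4, temperature = 300,
                            sasa_threshold = 0.001,
                            sasa_radii = default_sasa_radii(),
                            sasa_probe = 0, minor_offset = -2,
                            major_offset = 2, seed = 1) {
  structure(list(structure = structure, windows_dir = windows_dir,
                 analyses = analyses, output_dir = output_dir,
                 with_tfo = with_tfo, window_spacing = window_spacing,
                 umbrella_k = umbrella_k, n_bins = n_bins,
                 wham_tolerance = wham_tolerance, n_blocks = n_blocks,
                 temperature = temperature, sasa_threshold = sasa_threshold,
                 sasa_radii = sasa_radii, sasa_probe = sasa_probe,
                 minor_offset = minor_offset, major_offset = major_offset,
                 seed = seed),
            class = "pipeline_config")
}

#' Default synthetic double-well flipping surface
#'
#' A periodic two-state surface with the closed well at 0 degrees, the open
#' well at 180 degrees, an opening free energy `dg` and an additional
#' barrier `b`: `W(x) = b/2 (1 - cos 2x) + dg/2 (1 - cos x)`.
#'
#' @param dg open-minus-closed free energy, kcal/mol (default 3).
#' @param b symmetric barrier component, kcal/mol (default 4).
#' @return function of angle (degrees) returning kcal/mol.
#' @export
double_well_pmf <- function(dg = 3, b = 4) {
  force(dg); force(b)
  function(x) b / 2 * (1 - cos(2 * x * DEG2RAD)) +
    dg / 2 * (1 - cos(x * DEG2RAD))
}

#' Example-system step-parameter targets
#'
#' Canonical B parameters throughout for the duplex; for the triplex, the
#' homo-purine region uses the TFO-bound values (twist 33.1 deg, roll 5.6
#' deg, rise 3.30 A, slide -1.5 A) while the flanking duplex regions stay
#' canonical B.
#'
#' @param sysdef a `system_definition`.
#' @param bound use the TFO-bound homo-purine parameters.
#' @return (n-1) x 6 step-parameter matrix.
#' @export
example_step_targets <- function(sysdef, bound = FALSE) {
  n <- sysdef$n_bp
  par <- matrix(rep(canonical_step_parameters("B"), each = n - 1),
                nrow = n - 1, dimnames = list(NULL, .step_par_names))
  if (bound && !is.null(sysdef$regions$homo_purine)) {
    r <- sysdef$regions$homo_purine
    steps <- seq(r[1], r[2] - 1)
    par[steps, "twist"] <- 33.1
    par[steps, "roll"] <- 5.6
    par[steps, "rise"] <- 3.30
    par[steps, "slide"] <- -1.5
  }
  par
}

#' Per-step Gaussian covariance emulating sequence-dependent deformability
#'
#' Diagonal step-parameter covariances scaled by step class: pyrimidine-
#' purine (YR) steps are most deformable, purine-purine (RR) intermediate,
#' purine-pyrimidine (RY) most rigid.
#'
#' @param sequence leading-strand sequence.
#' @param base_sd baseline SDs for (shift, slide, rise, tilt, roll, twist):
#'   defaults (0.4 A, 0.35 A, 0.25 A, 3 deg, 4 deg, 4 deg).
#' @param class_scale named scaling factors for YR/RR/RY/YY.
#' @return list of per-step 6x6 covariance matrices.
#' @export
deformability_covariances <- function(sequence,
                                      base_sd = c(shift = 0.4, slide = 0.35,
                                                  rise = 0.25, tilt = 3,
                                                  roll = 4, twist = 4),
                                      class_scale = c(YR = 1.5, RR = 1.0,
                                                      RY = 0.6, YY = 1.0)) {
  bases <- seq_letters(sequence)
  n <- length(bases)
  lapply(seq_len(n - 1), function(s) {
    cl <- paste0(ifelse(is_purine(bases[s]), "R", "Y"),
                 ifelse(is_purine(bases[s + 1]), "R", "Y"))
    diag((base_sd * class_scale[[cl]])^2)
  })
}

#' Generate the demo dataset
#'
#' Writes the bundled example system as PDB fixtures (duplex and triplex),
#' a Gaussian step-parameter ensemble, and synthetic umbrella windows drawn
#' from the default double-well surface.  Byte-identical for a fixed seed.
#'
#' @param dir output directory.
#' @param seed RNG seed.
#' @param n_ensemble_frames frames in the Gaussian ensemble (default 200).
#' @param n_window_samples samples per umbrella window (default 2000).
#' @return invisible list of the generated objects and paths.
#' @export
generate_demo <- function(dir, seed = 1, n_ensemble_frames = 200,
                          n_window_samples = 2000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sysd <- purine_triplex_system()
  seqs <- paste(sysd$duplex_seq, collapse = "")
  duplex <- rebuild_helix(seqs, example_step_targets(sysd, bound = FALSE))
  tri_core <- rebuild_helix(seqs, example_step_targets(sysd, bound = TRUE))
  triplex <- build_triplex(tri_core, paste(sysd$tfo_seq, collapse = ""),
                           sysd$tfo_target)
  write_structure(duplex, file.path(dir, "duplex.pdb"))
  write_structure(triplex, file.path(dir, "triplex.pdb"))
  spec <- ensemble_spec(seqs, canonical_step_parameters("B"),
                        deformability_covariances(seqs),
                        n_frames = n_ensemble_frames, seed = seed)
  ens <- sample_step_ensemble(spec)
  write_structure(ens, file.path(dir, "ensemble.pdb"))
  ssp <- sampler_spec(double_well_pmf(), schedule_windows(), k = 2000,
                      n_samples = n_window_samples, seed = seed + 1)
  win <- sample_biased_windows(ssp, thin = 2)
  write_windows(win, file.path(dir, "windows"))
  invisible(list(duplex = duplex, triplex = triplex, ensemble = ens,
                 windows = win, dir = dir))
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in dependency order and writes CSV/JSON
#' outputs plus a run manifest (package version, seed, config echo,
#' per-stage status and output hashes).
#'
#' @param config a [pipeline_config()].
#' @return invisible list with the manifest and the stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (is.character(config$structure) && !file.exists(config$structure))
    stop("input structure not found: ", config$structure)
  if (!is.null(config$windows_dir) && !dir.exists(config$windows_dir))
    stop("windows directory not found: ", config$windows_dir)
  manifest <- list(package = "stepflip",
                   version = as.character(utils::packageVersion("stepflip")),
                   seed = config$seed,
                   config = config[setdiff(names(config), "structure")],
                   stages = list(), warnings = list())
  results <- list()
  sysd <- purine_triplex_system(with_tfo = config$with_tfo)
  st <- if (is.null(config$structure)) {
    base <- rebuild_helix(paste(sysd$duplex_seq, collapse = ""),
                          example_step_targets(sysd, bound = config$with_tfo))
    if (config$with_tfo)
      build_triplex(base, paste(sysd$tfo_seq, collapse = ""),
                    sysd$tfo_target)
    else base
  } else if (inherits(config$structure, "dna_structure")) {
    config$structure
  } else read_structure(config$structure)
  ann <- annotate_system(st, sysd)
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) e),
      warning = function(w) {
        manifest$warnings[[length(manifest$warnings) + 1]] <<-
          paste0(name, ": ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    ok <- !inherits(res, "error")
    manifest$stages[[name]] <<- list(
      status = if (ok) "ok" else "failed",
      message = if (ok) "" else conditionMessage(res),
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
    if (!ok) stop("stage '", name, "' failed: ", conditionMessage(res))
    res
  }
  need_steps <- any(c("steps", "regions", "variability") %in% config$analyses)
  if (need_steps) {
    tab <- run_stage("steps", function() step_table(st, ann))
    results$steps <- tab
    utils::write.csv(tab, file.path(out, "steps.csv"), row.names = FALSE)
  }
  if ("regions" %in% config$analyses) {
    rs <- run_stage("regions", function() region_statistics(results$steps))
    results$regions <- rs
    utils::write.csv(rs, file.path(out, "regions.csv"), row.names = FALSE)
  }
  if ("variability" %in% config$analyses) {
    vs <- run_stage("variability",
                    function() variability_summary(results$steps))
    results$variability <- vs
    utils::write.csv(vs, file.path(out, "variability.csv"), row.names = FALSE)
  }
  if ("grooves" %in% config$analyses) {
    gw <- run_stage("grooves", function()
      groove_widths(st, ann, config$minor_offset, config$major_offset))
    results$grooves <- gw
    utils::write.csv(gw, file.path(out, "grooves.csv"), row.names = FALSE)
  }
  if ("overlaps" %in% config$analyses) {
    ov <- run_stage("overlaps", function() {
      t(vapply(seq_len(ann$n_bp - 1), function(s)
        overlap_areas(st, ann, s), c(endocyclic = 0, exocyclic = 0)))
    })
    ov <- data.frame(step = seq_len(ann$n_bp - 1), ov)
    results$overlaps <- ov
    utils::write.csv(ov, file.path(out, "overlaps.csv"), row.names = FALSE)
  }
  if ("bends" %in% config$analyses) {
    ba <- run_stage("bends", function() bend_angles(st, ann))
    results$bends <- ba
    utils::write.csv(ba, file.path(out, "bend_angles.csv"), row.names = FALSE)
  }
  if ("pca" %in% config$analyses) {
    pr <- run_stage("pca", function() {
      fit <- if (!is.null(sysd$regions$homo_purine))
        seq(sysd$regions$homo_purine[1], sysd$regions$homo_purine[2])
      else unique(st$atoms$resno)
      fit <- c(fit, 2 * ann$n_bp + 1 - fit)
      pca_ensemble(st, fit_resno = fit)
    })
    results$pca <- pr
    utils::write.csv(data.frame(mode = seq_along(pr$eigenvalues),
                                eigenvalue = pr$eigenvalues,
                                fraction = pr$fractions),
                     file.path(out, "pca_eigenvalues.csv"),
                     row.names = FALSE)
  }
  if ("pmf" %in% config$analyses) {
    pm <- run_stage("pmf", function() {
      if (is.null(config$windows_dir))
        stop("pmf analysis requested without windows_dir")
      win <- read_windows(config$windows_dir)
      prof <- pmf_error(win, n_blocks = config$n_blocks,
                        n_bins = config$n_bins,
                        tolerance = config$wham_tolerance,
                        temperature = config$temperature)
      closed <- abs(prof$x) <= 90  # fixed angular cut fallback partition
      list(profile = prof,
           dg_open = delta_g_open(prof, closed),
           barrier = barrier(prof))
    })
    results$pmf <- pm
    utils::write.csv(data.frame(x = pm$profile$x, W = pm$profile$W,
                                error = pm$profile$error),
                     file.path(out, "pmf.csv"), row.names = FALSE)
    jsonlite::write_json(list(dg_open = pm$dg_open,
                              barrier = pm$barrier),
                         file.path(out, "pmf_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  files <- setdiff(list.files(out), "manifest.json")
  manifest$outputs <- as.list(tools::md5sum(file.path(out, sort(files))))
  names(manifest$outputs) <- sort(files)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, results = results))
}
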