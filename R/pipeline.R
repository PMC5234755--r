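#' Run the full simulation/reconstruction pipeline
#'
#' phantom -> simulate (expected counts) -> noise -> reconstruct -> analyze,
#' writing every stage artifact plus a manifest to `out_dir`. Stages are
#' resumable: an artifact is regenerated only if missing or if the manifest
#' records a different config hash or seed. All randomness flows from the
#' single `seed`.
#'
#' @param cfg A `run_config` (path or list, see [read_config()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Root integer seed for the Poisson noise stage.
#' @param resume Reuse existing artifacts when the manifest matches.
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the artifact paths and the resolution
#'   report (when the phantom has a descriptor).
#' @export
run_pipeline <- function(cfg, out_dir, seed = 1, resume = TRUE,
                         verbose = FALSE) {
  cfg <- read_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (resume && file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else list()
  fresh <- !identical(manifest$config_hash, hash) ||
    !identical(as.integer(manifest$seed), as.integer(seed))
  paths <- list(phantom = file.path(out_dir, "phantom.nii.gz"),
                descriptor = file.path(out_dir, "phantom.json"),
                expected = file.path(out_dir, "expected.tif"),
                observed = file.path(out_dir, "observed.tif"),
                recon = file.path(out_dir, "recon.nii.gz"),
                loglik = file.path(out_dir, "loglik.csv"),
                report = file.path(out_dir, "report.json"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, out_files, fn) {
    if (!fresh && all(file.exists(unlist(out_files)))) {
      say("[%s] reusing existing artifact", name)
      return(invisible(NULL))
    }
    say("[%s] running", name)
    tryCatch(fn(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  model <- config_model(cfg)
  sim <- cfg$simulation
  exposure <- if (is.null(sim$exposure)) 60 else sim$exposure
  calibration <- if (is.null(sim$calibration)) 1 else sim$calibration

  truth <- NULL
  stage("phantom", paths$phantom, function() {
    truth <<- config_phantom(cfg)
    write_volume(truth, paths$phantom)
    if (!is.null(attr(truth, "descriptor")))
      write_descriptor(truth, paths$descriptor)
  })
  if (is.null(truth)) truth <- config_phantom(cfg)

  stage("simulate", paths$expected, function() {
    expected <- forward_project(truth, model, exposure, calibration)
    if (!is.null(sim$counts_per_frame))
      expected <- calibrate_counts(expected, sim$counts_per_frame)
    write_projections(expected, paths$expected)
  })

  stage("noise", paths$observed, function() {
    expected <- read_projections(paths$expected)
    write_projections(add_poisson_noise(expected, seed), paths$observed)
  })

  stage("recon", paths$recon, function() {
    observed <- read_projections(paths$observed)
    grid <- volume_image(array(0, dim(truth$values)), truth$voxel_size,
                         truth$origin)
    st <- config_recon_settings(cfg)
    rec <- osem_reconstruct(observed, model, grid, st, verbose = verbose)
    write_volume(rec, paths$recon)
    ll <- attr(rec, "loglik")
    if (!is.null(ll))
      utils::write.csv(data.frame(iteration = seq_along(ll), loglik = ll),
                       paths$loglik, row.names = FALSE)
  })

  report <- NULL
  if (file.exists(paths$descriptor)) {
    stage("analyze", paths$report, function() {
      rec <- read_volume(paths$recon)
      desc <- read_descriptor(paths$descriptor)
      an <- cfg$analysis
      report <<- limiting_resolution(
        rec, desc,
        criterion = if (is.null(an$criterion)) 0.735 else an$criterion,
        axial_fraction = if (is.null(an$axial_fraction)) 1 / 3
                         else an$axial_fraction)
      write_report(report, paths$report)
    })
    if (is.null(report) && file.exists(paths$report))
      report <- jsonlite::read_json(paths$report, simplifyVector = TRUE)
  }

  jsonlite::write_json(list(package_version = as.character(
                              utils::packageVersion("pinspect")),
                            config_hash = hash, seed = as.integer(seed),
                            fingerprint = model_fingerprint(model),
                            created = format(Sys.time(), tz = "UTC"),
                            artifacts = paths),
                       manifest_path, auto_unbox = TRUE)
  invisible(list(paths = paths, report = report, manifest = manifest_path))
}
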