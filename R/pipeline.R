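# One entry point wiring the pipeline:
# synth -> exclude -> decompose -> transform -> ladder,
# with config validation, logging and provenance in every output.

#' Validate and normalize a run configuration
#'
#' A run configuration is a named list (or a JSON file holding one).
#' Recognized keys and defaults:
#' \describe{
#'   \item{seed}{master RNG seed (default 1)}
#'   \item{outdir}{output directory (required)}
#'   \item{n_molecules, n_frames}{fixture size (512 / 24)}
#'   \item{q_min, q_max, dq}{reciprocal grid (0.5 / required / 0.01)}
#'   \item{r_max, dr}{real-space grid (20 / 0.01)}
#'   \item{radii_set}{\code{"ff"} or \code{"bondi"}}
#'   \item{solute}{fixture name (\code{"rubpy3cl2"})}
#'   \item{granularity, placement, criterion}{droplet options}
#'   \item{mode, bin_width}{intensity evaluation options}
#'   \item{window}{transform window function}
#' }
#' Validation happens before any computation; \code{q_max} has no default
#' and must be supplied, since every transform output depends on it.
#'
#' @param config named list or path to a JSON file
#' @return validated config (class \code{run_config})
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  defaults <- list(seed = 1L, n_molecules = 512L, n_frames = 24L,
                   q_min = 0.5, dq = 0.01, r_max = 20, dr = 0.01,
                   radii_set = "ff", solute = "rubpy3cl2",
                   granularity = "atom",
                   placement = "center_random_rotation",
                   criterion = "solute_radius",
                   mode = "histogram", bin_width = 0.01,
                   window = "none")
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (is.null(config$outdir)) stop("config error: 'outdir' is required")
  if (is.null(config$q_max))
    stop("config error: 'q_max' is required (the transform window is an ",
         "explicit analysis parameter)")
  with(config, {
    if (q_min < 0 || q_max <= q_min || dq <= 0) stop("config error: bad Q grid")
    if (r_max <= 0 || dr <= 0) stop("config error: bad r grid")
  })
  if (!config$radii_set %in% c("ff", "bondi"))
    stop("config error: radii_set must be 'ff' or 'bondi'")
  class(config) <- c("run_config", "list")
  config
}

.log_stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf("[solvscat %s] %s",
                              format(Sys.time(), "%H:%M:%S"),
                              sprintf(fmt, ...)))
}

#' Run the full differential-scattering pipeline
#'
#' Generates the matched A/B fixture, labels the excluded-solvent droplet,
#' decomposes the differential structure function, transforms everything to
#' real space and scores the model ladder.  All outputs (curve files per
#' component in Q and r space, droplet statistics, the ladder and a
#' manifest with parameters and checksums) are written under
#' \code{config$outdir}.  Reruns with the same config are bit-identical.
#'
#' @param config a [run_config()] (or list/path accepted by it)
#' @param quiet suppress stage logging
#' @return (invisibly) a list with the decompositions, ladder and manifest
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- run_config(config)
  t0 <- Sys.time()
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  radii <- vdw_radii(cfg$radii_set)
  q <- seq(cfg$q_min, cfg$q_max, by = cfg$dq)

  .log_stage(quiet, "synth: %d molecules, %d frames, seed %d",
             cfg$n_molecules, cfg$n_frames, cfg$seed)
  fix <- make_reference_fixture(seed = cfg$seed,
                                n_molecules = cfg$n_molecules,
                                n_frames = cfg$n_frames,
                                solute_name = cfg$solute, radii = radii)
  .log_stage(quiet, "exclude: <N_x> = %.1f atoms (heuristic %.1f)",
             fix$droplet$mean_n_x, fix$spec$n_x)
  .log_stage(quiet, "decompose: %d Q points, mode %s", length(q), cfg$mode)
  dec_q <- decompose_dF(fix$a, fix$b, fix$droplet, q = q, mode = cfg$mode,
                        bin_width = cfg$bin_width)
  spec <- transform_spec(cfg$q_min, cfg$q_max, cfg$r_max, cfg$dr,
                         window = cfg$window)
  .log_stage(quiet, "transform: Q_max = %g, %d r points", cfg$q_max,
             length(spec$r))
  dec_r <- transform_decomposition(dec_q, spec)
  ladder <- model_ladder(dec_r)

  files <- character(0)
  put_curve <- function(curve, name) {
    p <- file.path(cfg$outdir, name)
    write_curve(curve, p)
    files <<- c(files, p)
  }
  for (nm in names(dec_q$components))
    put_curve(dec_q$components[[nm]], sprintf("dF_%s.fq", nm))
  put_curve(dec_q$total, "dF_total.fq")
  for (nm in names(dec_r$components))
    put_curve(dec_r$components[[nm]], sprintf("dG_%s.gr", nm))
  put_curve(dec_r$total, "dG_total.gr")

  stats <- droplet_statistics(fix$droplet, n_x_ref = fix$spec$n_x)
  report <- list(
    closure = list(q_space = dec_q$closure_residual,
                   r_space = dec_r$closure_residual,
                   dvv_partition = dec_q$closure_dvv),
    droplet = list(mean = stats$mean, var = stats$var,
                   consistency_ratio = stats$consistency_ratio),
    excluded_volume = list(v_vdw = fix$spec$v_vdw, n_x = fix$spec$n_x,
                           nu = fix$spec$nu, radii_set = cfg$radii_set))
  p <- file.path(cfg$outdir, "closure_report.json")
  jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA)
  files <- c(files, p)
  p <- file.path(cfg$outdir, "ladder.json")
  jsonlite::write_json(as.list(as.data.frame(ladder)), p,
                       auto_unbox = FALSE, digits = NA)
  files <- c(files, p)
  p <- file.path(cfg$outdir, "ladder.md")
  writeLines(c("| model | r2 | R (%) | Rw (%) |", "|---|---|---|---|",
               sprintf("| %s | %.3f | %.1f | %.1f |", ladder$model,
                       ladder$r2, ladder$r_factor, ladder$r_factor_l2)), p)
  files <- c(files, p)

  manifest <- list(package = "solvscat", version = .pkg_version(),
                   config = unclass(cfg),
                   files = lapply(files, function(f)
                     list(path = basename(f),
                          md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log_stage(quiet, "done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  invisible(list(fixture = fix, decomposition_q = dec_q,
                 decomposition_r = dec_r, ladder = ladder,
                 report = report, manifest = manifest))
}
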