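# Orchestration: unit conversion, one-call analysis, report aggregation.

#' Convert between k_BT and joules
#'
#' Multiplies/divides by \eqn{k_B T} with
#' \eqn{k_B = 1.380649\times10^{-23}} J/K. The round trip is exact to
#' floating-point precision.
#'
#' @param value modulus in k_BT (or J for the inverse).
#' @param temperature absolute temperature (K), > 0.
#' @return converted value.
#' @export
kbt_to_joule <- function(value, temperature) {
  if (any(temperature <= 0)) {
    stop_memflex("temperature must be positive", class = "memflex_param_error")
  }
  value * .kB * temperature
}

#' @rdname kbt_to_joule
#' @export
joule_to_kbt <- function(value, temperature) {
  if (any(temperature <= 0)) {
    stop_memflex("temperature must be positive", class = "memflex_param_error")
  }
  value / (.kB * temperature)
}

default_config <- function() {
  list(
    methods = c("q4", "bwdcf", "rsf"),
    n_max = 5, q_window = 5, include_tension = FALSE,
    n_bw = 3, bw_backend = "direct",
    rsf_cutoff = 1.2, rsf_patch_radius = 1.5, rsf_bins = 101,
    rsf_convention = "difference",
    density_bin_width = 0.05,
    msd = FALSE, msd_fit_window = c(0.1, 0.5),
    keep_going = FALSE
  )
}

#' Run the full membrane analysis
#'
#' Executes the selected bending-modulus estimators plus geometry (and
#' optionally lateral diffusion) on one trajectory with a shared leaflet
#' assignment, echoing every default actually used into the report.
#'
#' @param config named list or path to a JSON config file. Recognized
#'   fields: `trajectory` (dialect stem or GRO path; optional when `traj` is
#'   given), `methods` (subset of `"q4"`, `"bwdcf"`, `"rsf"`), estimator
#'   settings (see [default_config()] source), `msd` (logical), `out_dir`.
#' @param traj optionally, an in-memory [trajectory()] (overrides
#'   `config$trajectory`).
#' @return object of class `analysis_report`: named `estimates` (each a
#'   [modulus_estimate()] with k_BT and J values), `geometry`, `diffusion`
#'   (when requested), the `D_B`/APL ratio, the echoed config and package
#'   version. Written as JSON (plus CSV curves) under `out_dir` when set.
#' @export
run_analysis <- function(config = list(), traj = NULL) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(traj)) {
    if (is.null(cfg$trajectory)) {
      stop_memflex("config names no trajectory and none was supplied",
        class = "memflex_config_error")
    }
    if (!file.exists(cfg$trajectory) &&
        !file.exists(paste0(cfg$trajectory, ".json"))) {
      stop_memflex("trajectory '%s' not found", cfg$trajectory,
        class = "memflex_config_error")
    }
    traj <- read_trajectory(cfg$trajectory)
  }
  bad <- setdiff(cfg$methods, c("q4", "bwdcf", "rsf"))
  if (length(bad)) {
    stop_memflex("unknown method(s): %s", paste(bad, collapse = ", "),
      class = "memflex_config_error")
  }
  assignment <- assign_leaflets(traj)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      msg <- sprintf("stage '%s' failed: %s", name, conditionMessage(e))
      if (isTRUE(cfg$keep_going)) {
        warning(msg, call. = FALSE)
        NULL
      } else stop_memflex("%s", msg, class = "memflex_stage_error")
    })
  }
  estimates <- list()
  if ("q4" %in% cfg$methods) {
    estimates$q4 <- run_stage("q4", {
      spec <- average_spectrum(traj, assignment, n_max = cfg$n_max)
      fit_q4(spec, q_window = cfg$q_window,
        include_tension = isTRUE(cfg$include_tension))
    })
  }
  if ("bwdcf" %in% cfg$methods) {
    estimates$bwdcf <- run_stage("bwdcf",
      estimate_bwdcf(traj, assignment, n_bw = cfg$n_bw, n_max = cfg$n_max,
        q_window = cfg$q_window, backend = cfg$bw_backend,
        bin_width = cfg$density_bin_width))
  }
  if ("rsf" %in% cfg$methods) {
    estimates$rsf <- run_stage("rsf",
      estimate_rsf(traj, assignment, cutoff = cfg$rsf_cutoff,
        patch_radius = cfg$rsf_patch_radius, bins = cfg$rsf_bins,
        convention = cfg$rsf_convention))
  }
  geometry <- run_stage("geometry", membrane_geometry(traj, assignment))
  diffusion <- NULL
  if (isTRUE(cfg$msd)) {
    diffusion <- run_stage("diffusion", {
      tr <- if (traj$com_removed) traj else remove_com_motion(traj)
      diffusion_coefficient(lateral_msd(tr), fit_window = cfg$msd_fit_window)
    })
  }
  report <- structure(
    list(
      estimates = estimates,
      geometry = geometry,
      diffusion = diffusion,
      thickness_apl_ratio = if (!is.null(geometry)) geometry$D_B / geometry$APL,
      temperature = traj$temperature,
      species = unique(traj$frames[[1]]$meta$species),
      provenance = traj$provenance[setdiff(names(traj$provenance), "ground_truth")],
      seed = traj$provenance$ground_truth$seed %||% traj$provenance$params$seed,
      config = cfg,
      version = as.character(packageVersion("memflex"))
    ),
    class = "analysis_report"
  )
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  for (nm in names(x$estimates)) {
    e <- x$estimates[[nm]]
    if (!is.null(e)) cat(sprintf("  %-6s kappa_b = %.4g k_BT (%.3g J)\n",
      nm, e$kappa, e$kappa_J))
  }
  if (!is.null(x$geometry)) {
    cat(sprintf("  D_B = %.4g nm, APL = %.4g nm^2, D_B/APL = %.4g nm^-1\n",
      x$geometry$D_B, x$geometry$APL, x$thickness_apl_ratio))
  }
  if (!is.null(x$diffusion)) {
    cat(sprintf("  D = %.4g nm^2/ps\n", x$diffusion$D))
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ser <- report
  ser$estimates <- lapply(report$estimates, function(e) {
    e$gamma_curve <- NULL
    unclass(e)
  })
  ser$geometry <- if (!is.null(report$geometry)) {
    g <- unclass(report$geometry)
    g$D_B_per_frame <- NULL
    g$APL_per_frame <- NULL
    g
  }
  ser$diffusion <- if (!is.null(report$diffusion)) unclass(report$diffusion)
  jsonlite::write_json(ser, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  if (!is.null(report$geometry)) {
    data.table::fwrite(
      data.frame(frame = seq_along(report$geometry$D_B_per_frame),
        D_B = report$geometry$D_B_per_frame,
        APL = report$geometry$APL_per_frame),
      file.path(out_dir, "geometry_series.csv"))
  }
  gc <- report$estimates$bwdcf$gamma_curve
  if (!is.null(gc)) {
    data.table::fwrite(gc$shells, file.path(out_dir, "gamma_cu.csv"))
  }
  invisible(out_dir)
}

#' Aggregate modulus estimates across reports
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' per-method bending moduli, grouped by a report field (e.g. a headgroup
#' tag stored in `species`).
#'
#' @param reports list of [run_analysis()] reports.
#' @param group_by name of the report field to group on (scalar per report),
#'   default `"species"`.
#' @return data.frame with `group`, `method`, `mean`, `sd`, `n`; groups with
#'   a single report get `sd = 0` and are flagged `single = TRUE`.
#' @export
aggregate_reports <- function(reports, group_by = "species") {
  if (length(reports) == 0) {
    stop_memflex("no reports to aggregate", class = "memflex_empty_error")
  }
  rows <- do.call(rbind, lapply(reports, function(r) {
    g <- r[[group_by]]
    if (is.null(g)) g <- r$config[[group_by]]
    if (is.null(g)) stop_memflex("report lacks grouping field '%s'", group_by,
      class = "memflex_config_error")
    do.call(rbind, lapply(names(r$estimates), function(m) {
      if (is.null(r$estimates[[m]])) return(NULL)
      data.frame(group = as.character(g)[1], method = m,
        kappa = r$estimates[[m]]$kappa, stringsAsFactors = FALSE)
    }))
  }))
  out <- do.call(rbind, lapply(split(rows, list(rows$group, rows$method),
      drop = TRUE), function(d) {
    data.frame(
      group = d$group[1], method = d$method[1],
      mean = mean(d$kappa),
      sd = if (nrow(d) > 1) sd(d$kappa) else 0,
      n = nrow(d), single = nrow(d) == 1,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out[order(out$group, out$method), ]
}
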