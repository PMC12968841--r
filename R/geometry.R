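# Membrane geometry observables: bilayer thickness, area per lipid, leaflet
# density profiles with Gaussian fitting, lateral MSD and diffusion.

#' Bilayer (Luzzati-style) thickness
#'
#' \eqn{D_B} is the frame-averaged difference between the mean head-bead z of
#' the top and bottom leaflets.
#'
#' @param traj a [trajectory()].
#' @param assignment a [assign_leaflets()] result.
#' @return list with `value` (nm) and `per_frame` series.
#' @export
bilayer_thickness <- function(traj, assignment) {
  f1 <- traj$frames[[1]]
  top <- leaflet_heads(f1, assignment, "top")
  bot <- leaflet_heads(f1, assignment, "bottom")
  if (length(top) == 0 || length(bot) == 0) {
    stop_memflex("degenerate bilayer: empty leaflet", class = "memflex_degenerate_error")
  }
  per <- vapply(traj$frames, function(f) {
    mean(f$positions[top, 3]) - mean(f$positions[bot, 3])
  }, numeric(1))
  list(value = mean(per), per_frame = per)
}

#' Area per lipid
#'
#' The lateral cell area divided by the number of lipids in a monolayer,
#' averaged over the two leaflets (for a symmetric bilayer with `n` lipids in
#' total this equals the textbook \eqn{\frac12 l_{cell}^2 / n_{lipids}} with
#' the bilayer count in the denominator read as per-leaflet pairs).
#'
#' @param x a [bead_frame()] or [trajectory()].
#' @param assignment a [assign_leaflets()] result.
#' @param ... unused.
#' @return for a frame, the APL (nm^2); for a trajectory, list with `value`
#'   and `per_frame`.
#' @export
area_per_lipid <- function(x, assignment, ...) UseMethod("area_per_lipid")

#' @rdname area_per_lipid
#' @export
area_per_lipid.bead_frame <- function(x, assignment, ...) {
  assert_square_box(x$box)
  n_top <- sum(assignment$leaflet == "top")
  n_bot <- sum(assignment$leaflet == "bottom")
  if (n_top == 0 || n_bot == 0) {
    stop_memflex("degenerate bilayer: empty leaflet", class = "memflex_degenerate_error")
  }
  a <- x$box[1] * x$box[2]
  mean(c(a / n_top, a / n_bot))
}

#' @rdname area_per_lipid
#' @export
area_per_lipid.md_trajectory <- function(x, assignment, ...) {
  per <- vapply(x$frames, area_per_lipid, numeric(1), assignment = assignment)
  list(value = mean(per), per_frame = per)
}

#' Summarize membrane geometry
#'
#' @inheritParams bilayer_thickness
#' @return list of class `geometry_result` with `D_B`, `APL`, per-frame
#'   series, `l_cell` and per-leaflet lipid counts.
#' @export
membrane_geometry <- function(traj, assignment) {
  th <- bilayer_thickness(traj, assignment)
  ap <- area_per_lipid(traj, assignment)
  structure(
    list(
      D_B = th$value, APL = ap$value,
      D_B_per_frame = th$per_frame, APL_per_frame = ap$per_frame,
      l_cell = traj$frames[[1]]$box[1],
      n_top = sum(assignment$leaflet == "top"),
      n_bottom = sum(assignment$leaflet == "bottom")
    ),
    class = "geometry_result"
  )
}

#' @export
print.geometry_result <- function(x, ...) {
  cat(sprintf("<geometry_result> D_B = %.4g nm, APL = %.4g nm^2 (l_cell = %.4g nm, %d/%d lipids)\n",
    x$D_B, x$APL, x$l_cell, x$n_top, x$n_bottom))
  invisible(x)
}

#' Leaflet number-density profile
#'
#' Histogram of head-bead z relative to the per-frame midplane, normalized by
#' lateral area, bin width and frame count, i.e. an estimate of
#' \eqn{\rho(z) = \langle \frac{1}{A_o}\sum_i \delta(z - z_i)\rangle} in
#' nm^-3; its integral over z equals \eqn{n_{leaflet}/A_o} (nm^-2).
#'
#' @param traj a [trajectory()].
#' @param assignment a [assign_leaflets()] result.
#' @param leaflet `"top"` or `"bottom"`.
#' @param bin_width histogram bin (nm).
#' @param range optional `c(lo, hi)` (nm, midplane-relative); defaults to the
#'   data range padded by one bin.
#' @return object of class `density_profile` with columns `z` (bin centers)
#'   and `rho`.
#' @export
density_profile <- function(traj, assignment, leaflet = "top",
                            bin_width = 0.05, range = NULL) {
  if (bin_width <= 0) {
    stop_memflex("bin_width must be > 0", class = "memflex_config_error")
  }
  idx <- leaflet_heads(traj$frames[[1]], assignment, leaflet)
  if (length(idx) == 0) {
    stop_memflex("empty leaflet '%s'", leaflet, class = "memflex_degenerate_error")
  }
  z <- unlist(lapply(seq_along(traj$frames), function(i) {
    traj$frames[[i]]$positions[idx, 3] - assignment$midplane[
      min(i, length(assignment$midplane))]
  }))
  if (is.null(range)) range <- c(min(z) - bin_width, max(z) + bin_width)
  breaks <- seq(range[1], range[2] + bin_width, by = bin_width)
  counts <- tabulate(findInterval(z, breaks, rightmost.closed = TRUE),
    nbins = length(breaks) - 1)
  A_o <- traj$frames[[1]]$box[1] * traj$frames[[1]]$box[2]
  structure(
    list(
      z = breaks[-length(breaks)] + bin_width / 2,
      rho = counts / (A_o * bin_width * n_frames(traj)),
      bin_width = bin_width, A_o = A_o, n_leaflet = length(idx),
      n_frames = n_frames(traj), leaflet = leaflet
    ),
    class = "density_profile"
  )
}

#' Fit the Gaussian leaflet density model
#'
#' Least-squares fit of
#' \eqn{\rho(z) = \rho_o \exp(-(z \mp d/2)^2 / 2a) / \sqrt{2\pi a}}
#' to a leaflet [density_profile()]. `rho_o` is the 2D density (nm^-2), `d`
#' the membrane thickness parameter (nm) and `a` the mean-square interface
#' width (nm^2).
#'
#' @param profile a [density_profile()].
#' @param leaflet_sign `+1` for the top leaflet (center `+d/2`), `-1` for the
#'   bottom; defaults to the profile's leaflet.
#' @return object of class `density_model` with fields `rho_o`, `d`, `a`,
#'   `sign` and `resid_norm`.
#' @export
fit_density_gaussian <- function(profile, leaflet_sign = NULL) {
  if (is.null(leaflet_sign)) {
    leaflet_sign <- if (identical(profile$leaflet, "bottom")) -1 else 1
  }
  occ <- profile$rho > 0
  if (sum(occ) < 5) {
    stop_memflex("density profile has %d occupied bins (need >= 5) for a Gaussian fit",
      sum(occ), class = "memflex_fit_error")
  }
  z <- profile$z
  rho <- profile$rho
  w <- rho / sum(rho)
  mu0 <- sum(w * z)
  a0 <- max(sum(w * (z - mu0)^2), 1e-6)
  r0 <- sum(rho) * profile$bin_width
  fit <- tryCatch(
    # scaleOffset makes the convergence test sound on (near-)zero-residual
    # profiles, e.g. histograms evaluated from the model itself
    nls(rho ~ ro * exp(-(z - mu)^2 / (2 * av)) / sqrt(2 * pi * av),
      start = list(ro = r0, mu = mu0, av = a0),
      control = list(maxiter = 200, scaleOffset = 1, warnOnly = FALSE)),
    error = function(e) {
      stop_memflex("Gaussian density fit did not converge: %s", conditionMessage(e),
        class = "memflex_fit_error")
    }
  )
  p <- coef(fit)
  structure(
    list(
      rho_o = unname(p["ro"]), d = unname(2 * abs(p["mu"])),
      a = unname(p["av"]), sign = leaflet_sign,
      resid_norm = sqrt(sum(stats::resid(fit)^2))
    ),
    class = "density_model"
  )
}

#' @export
print.density_model <- function(x, ...) {
  cat(sprintf("<density_model> rho_o = %.4g nm^-2, d = %.4g nm, a = %.4g nm^2 (center %+.3g nm)\n",
    x$rho_o, x$d, x$a, x$sign * x$d / 2))
  invisible(x)
}

#' Lateral mean-squared displacement
#'
#' MSD of lipid head beads in x-y, averaged over lipids and all time origins.
#' Coordinates are unwrapped internally by accumulating minimum-image
#' frame-to-frame displacements, so jumps across the periodic boundary do not
#' corrupt the statistics (valid while per-frame steps stay below half the
#' box).
#'
#' @param traj a [trajectory()]; should have lateral COM motion removed
#'   ([remove_com_motion()]), a warning is emitted otherwise.
#' @param max_lag largest lag, in frames; default half the trajectory.
#' @return data.frame of class `msd_series` with `lag` (ps) and `msd` (nm^2);
#'   `MSD(0) = 0` by construction.
#' @export
lateral_msd <- function(traj, max_lag = NULL) {
  nf <- n_frames(traj)
  if (nf < 2) {
    stop_memflex("need at least 2 frames for an MSD", class = "memflex_empty_error")
  }
  if (!isTRUE(traj$com_removed)) {
    warning("trajectory is not flagged com_removed; MSD may contain drift",
      call. = FALSE)
  }
  if (is.null(max_lag)) max_lag <- max(1L, nf %/% 2L)
  max_lag <- min(max_lag, nf - 1L)
  idx <- head_table(traj$frames[[1]])
  box <- traj$frames[[1]]$box
  n <- length(idx)
  X <- matrix(0, nf, n); Y <- matrix(0, nf, n)
  X[1, ] <- traj$frames[[1]]$positions[idx, 1]
  Y[1, ] <- traj$frames[[1]]$positions[idx, 2]
  for (i in 2:nf) {
    dx <- min_image(traj$frames[[i]]$positions[idx, 1] -
                    traj$frames[[i - 1]]$positions[idx, 1], box[1])
    dy <- min_image(traj$frames[[i]]$positions[idx, 2] -
                    traj$frames[[i - 1]]$positions[idx, 2], box[2])
    X[i, ] <- X[i - 1, ] + dx
    Y[i, ] <- Y[i - 1, ] + dy
  }
  grp <- if (n >= 8) sort(rep_len(1:8, n)) else rep(1L, n)
  G <- max(grp)
  msd <- numeric(max_lag + 1L)
  msd_g <- matrix(0, max_lag + 1L, G)
  for (lag in seq_len(max_lag)) {
    o <- seq_len(nf - lag)
    sq <- (X[o + lag, , drop = FALSE] - X[o, , drop = FALSE])^2 +
          (Y[o + lag, , drop = FALSE] - Y[o, , drop = FALSE])^2
    msd[lag + 1L] <- mean(sq)
    msd_g[lag + 1L, ] <- vapply(seq_len(G), function(g)
      mean(sq[, grp == g, drop = FALSE]), numeric(1))
  }
  out <- structure(
    data.frame(lag = (0:max_lag) * traj$dt, msd = msd),
    class = c("msd_series", "data.frame")
  )
  # per-lipid-group curves: independent walkers give independent estimates,
  # used for a resampling standard error of the diffusion coefficient
  attr(out, "msd_groups") <- msd_g
  out
}

#' Lateral diffusion coefficient from an MSD series
#'
#' Linear least squares on the chosen lag window; for two-dimensional
#' diffusion the slope equals \eqn{4D}, so `D = slope / 4`.
#'
#' @param msd a [lateral_msd()] result.
#' @param fit_window fraction `c(lo, hi)` of the maximum lag to fit over
#'   (default 10--50%), or absolute lags (ps) if any value exceeds 1.
#' @return list of class `diffusion_result`: `D` (nm^2/ps), `D_cm2_s`,
#'   `D_se` (standard error over independent lipid groups), `slope`,
#'   `slope_se`, `r_squared`, `window` and a `ballistic` flag set
#'   when the linear model fits poorly (R^2 of the windowed fit on the
#'   log-log slope far from 1).
#' @export
diffusion_coefficient <- function(msd, fit_window = c(0.1, 0.5)) {
  lmax <- max(msd$lag)
  win <- if (any(fit_window > 1)) fit_window else fit_window * lmax
  sel <- msd$lag >= win[1] & msd$lag <= win[2] & msd$lag > 0
  if (sum(sel) < 2) {
    stop_memflex("fit window [%g, %g] ps contains %d points", win[1], win[2],
      sum(sel), class = "memflex_config_error")
  }
  fit <- lm(msd ~ lag, data = msd[sel, ])
  slope <- unname(coef(fit)[2])
  if (slope < 0) {
    warning("negative MSD slope; D reported with its sign", call. = FALSE)
  }
  # standard error from independent lipid groups (time-correlated MSD points
  # make the OLS slope error an underestimate)
  D_se <- NA_real_
  mg <- attr(msd, "msd_groups")
  if (!is.null(mg) && ncol(mg) >= 4) {
    Dg <- vapply(seq_len(ncol(mg)), function(g) {
      unname(coef(lm(mg[sel, g] ~ msd$lag[sel]))[2]) / 4
    }, numeric(1))
    D_se <- sd(Dg) / sqrt(length(Dg))
  }
  # ballistic diagnostic: slope of log(MSD) vs log(lag) ~ 2 indicates x = vt
  pos <- sel & msd$msd > 0
  alpha <- if (sum(pos) >= 2) {
    unname(coef(lm(log(msd$msd[pos]) ~ log(msd$lag[pos])))[2])
  } else NA_real_
  structure(
    list(
      D = slope / 4, D_cm2_s = slope / 4 * 1e-2,
      D_se = D_se,
      slope = slope,
      slope_se = suppressWarnings(summary(fit))$coefficients[2, 2],
      r_squared = suppressWarnings(summary(fit))$r.squared,
      window = win, msd_exponent = alpha,
      ballistic = is.finite(alpha) && alpha > 1.5
    ),
    class = "diffusion_result"
  )
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf("<diffusion_result> D = %.4g nm^2/ps (%.4g cm^2/s), slope exponent %.2f%s\n",
    x$D, x$D_cm2_s, x$msd_exponent,
    if (x$ballistic) " [non-diffusive]" else ""))
  invisible(x)
}
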