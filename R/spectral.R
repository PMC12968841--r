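# Undulation spectrum on the periodic box and the q^-4 bending-modulus fit.
#
# Fourier convention (shared with the synthetic generator): the mid-surface
# height field is h(x) = sum_q h_q exp(i q.x) over the discrete lattice
# q = 2*pi*(n_x, n_y)/L, and modes are estimated from bead samples by the
# direct nonuniform sum h_q = (1/N) sum_j z_j exp(-i q.x_j). Under this
# convention equipartition of the Helfrich Hamiltonian reads
#   <|h_q|^2> = k_B T / (A (tau q^2 + kappa_b q^4)),   A = l_cell^2,
# which is the identity both the estimator and the generator use. Moduli are
# handled in k_BT units (k_B T == 1) throughout.

#' Discrete q-vector lattice of the periodic box
#'
#' All integer `(n_x, n_y)` with `0 < n_x^2 + n_y^2 <= n_max^2`.
#'
#' @param L lateral box length (nm).
#' @param n_max mode cutoff: modes with `|n| <= n_max` are kept.
#' @param half keep one representative of each `(q, -q)` pair
#'   (`n_x > 0` or (`n_x = 0` and `n_y > 0`)).
#' @return data.frame with `nx`, `ny`, `qx`, `qy`, `q` and integer `shell`
#'   (`nx^2 + ny^2`).
#' @export
q_lattice <- function(L, n_max, half = TRUE) {
  stopifnot(n_max >= 1)
  g <- expand.grid(nx = -n_max:n_max, ny = -n_max:n_max)
  g <- g[g$nx^2 + g$ny^2 > 0 & g$nx^2 + g$ny^2 <= n_max^2, ]
  if (half) g <- g[g$nx > 0 | (g$nx == 0 & g$ny > 0), ]
  g$qx <- 2 * pi * g$nx / L
  g$qy <- 2 * pi * g$ny / L
  g$q <- sqrt(g$qx^2 + g$qy^2)
  g$shell <- g$nx^2 + g$ny^2
  g[order(g$shell, g$nx, g$ny), ]
}

# Mid-surface heights: head-bead z minus the per-leaflet mean, both leaflets
# pooled. Removing each leaflet's own mean strips the +-d/2 offsets so the
# pooled field carries undulation only. Returns list(z, xy).
midsurface_heights <- function(frame, assignment) {
  top <- leaflet_heads(frame, assignment, "top")
  bot <- leaflet_heads(frame, assignment, "bottom")
  zt <- frame$positions[top, 3]
  zb <- frame$positions[bot, 3]
  list(
    z = c(zt - mean(zt), zb - mean(zb)),
    xy = frame$positions[c(top, bot), 1:2, drop = FALSE]
  )
}

# Direct nonuniform Fourier sum: (1/N) sum_j z_j exp(-i q.x_j) for the rows
# of lattice `lat`. Returns complex vector.
mode_sum <- function(xy, z, lat) {
  ph <- xy %*% rbind(lat$qx, lat$qy) # N x nq
  (colSums(z * cos(ph)) - 1i * colSums(z * sin(ph))) / length(z)
}

#' Per-frame undulation modes
#'
#' Computes \eqn{h(q) = (1/N)\sum_j z_j e^{-i q\cdot r_j}} over all head
#' beads of both leaflets (per-leaflet mean z removed) for every lattice
#' vector with `0 < |n| <= n_max`. The returned table covers the full
#' lattice; Hermitian symmetry `h(-q) = conj(h(q))` holds by construction.
#'
#' @param frame a [bead_frame()].
#' @param assignment a [assign_leaflets()] result.
#' @param n_max mode cutoff.
#' @return data.frame of class `height_modes`: lattice columns plus `re`,
#'   `im`, `power` (`|h|^2`).
#' @export
height_modes <- function(frame, assignment, n_max = 5) {
  assert_square_box(frame$box)
  lat <- q_lattice(frame$box[1], n_max, half = TRUE)
  hs <- midsurface_heights(frame, assignment)
  hq <- mode_sum(hs$xy, hs$z, lat)
  full <- rbind(
    cbind(lat, re = Re(hq), im = Im(hq)),
    cbind(transform(lat, nx = -nx, ny = -ny, qx = -qx, qy = -qy),
      re = Re(hq), im = -Im(hq))
  )
  full$power <- full$re^2 + full$im^2
  structure(full[order(full$shell, full$nx, full$ny), ],
    class = c("height_modes", "data.frame"))
}

#' Ensemble-averaged undulation spectrum
#'
#' \eqn{\langle|h(q)|^2\rangle} averaged over frames, with a shell average
#' over lattice vectors of equal `|q|`.
#'
#' @param traj a [trajectory()].
#' @param assignment a [assign_leaflets()] result.
#' @param n_max mode cutoff.
#' @param estimator `"ls"` (default) estimates the per-frame mode
#'   coefficients by linear least squares on the band-limited Fourier
#'   design (intercept + cos/sin columns per half-lattice mode). This
#'   removes inter-mode leakage of the nonuniform bead sampling exactly and
#'   subtracts the white-noise power bias of the interface jitter using the
#'   regression residual variance, so the per-mode variance is unbiased
#'   irrespective of the lateral point statistics. `"direct"` is the plain
#'   nonuniform Fourier sum of [height_modes()], whose upper shells sit on
#'   an incoherent sampling floor of order \eqn{(a + Var\,h)/N}.
#' @return object of class `height_spectrum`: per-mode table `modes`
#'   (half lattice, `S = <|h|^2>`), shell table `shells` (`q`, `S`,
#'   `n_modes`), per-frame power matrix `frame_power` (frames x modes,
#'   kept for convergence analyses), projected area `A` and `temperature`.
#' @export
average_spectrum <- function(traj, assignment, n_max = 5,
                             estimator = c("ls", "direct")) {
  estimator <- match.arg(estimator)
  f1 <- traj$frames[[1]]
  assert_square_box(f1$box)
  lat <- q_lattice(f1$box[1], n_max, half = TRUE)
  Q <- rbind(lat$qx, lat$qy)
  M <- nrow(lat)
  pw <- matrix(0, n_frames(traj), M)
  for (i in seq_len(n_frames(traj))) {
    hs <- midsurface_heights(traj$frames[[i]], assignment)
    N <- length(hs$z)
    ph <- hs$xy %*% Q
    if (estimator == "ls" && N > 2 * M + 2) {
      # z_j = b0 + sum_q (c_q cos + s_q sin)(q.x_j) + eps;  h_q = (c - i s)/2
      W <- cbind(1, cos(ph), sin(ph))
      G <- crossprod(W)
      Gi <- tryCatch(solve(G), error = function(e) NULL)
      if (!is.null(Gi)) {
        Wz <- crossprod(W, hs$z)
        beta <- Gi %*% Wz
        s2 <- max(0, (sum(hs$z^2) - sum(beta * Wz)) / (N - ncol(W)))
        ic <- 2:(M + 1)
        is_ <- (M + 2):(2 * M + 1)
        pw[i, ] <- (beta[ic]^2 + beta[is_]^2 -
          s2 * (diag(Gi)[ic] + diag(Gi)[is_])) / 4
        next
      }
    }
    re <- colSums(hs$z * cos(ph)) / N
    im <- colSums(hs$z * sin(ph)) / N
    pw[i, ] <- re^2 + im^2
  }
  modes <- cbind(lat, S = colMeans(pw))
  spectrum_from_modes(modes, pw, A = f1$box[1] * f1$box[2],
    temperature = traj$temperature)
}

spectrum_from_modes <- function(modes, frame_power, A, temperature) {
  sh <- split(seq_len(nrow(modes)), modes$shell)
  shells <- data.frame(
    shell = as.integer(names(sh)),
    q = vapply(sh, function(i) modes$q[i[1]], numeric(1)),
    S = vapply(sh, function(i) mean(modes$S[i]), numeric(1)),
    n_modes = vapply(sh, length, integer(1))
  )
  shells <- shells[order(shells$shell), ]
  rownames(shells) <- NULL
  structure(
    list(modes = modes, shells = shells, frame_power = frame_power,
      A = A, temperature = temperature),
    class = "height_spectrum"
  )
}

#' @export
print.height_spectrum <- function(x, ...) {
  cat(sprintf("<height_spectrum> %d modes in %d shells, %d frames, A = %.4g nm^2\n",
    nrow(x$modes), nrow(x$shells), nrow(x$frame_power), x$A))
  invisible(x)
}

#' Fit the bending modulus from the undulation spectrum
#'
#' Default (`include_tension = FALSE`): the log-log slope of the
#' shell-averaged spectrum over the fit window is reported as a diagnostic
#' (expected near -4) and \eqn{\kappa_b} is the mean of
#' \eqn{k_BT/(A\,S(q)\,q^4)} over the window's modes. With
#' `include_tension = TRUE`, \eqn{k_BT/(A\,S(q)\,q^2)} is regressed linearly
#' on \eqn{q^2}, giving intercept \eqn{\tau} and slope \eqn{\kappa_b}
#' (an exact linearization of the full spectrum model).
#'
#' @param spectrum a [average_spectrum()] result.
#' @param q_window number of lowest shells to fit (default 5), or a numeric
#'   `c(qmin, qmax)` range in nm^-1.
#' @param include_tension also estimate the tension \eqn{\tau}.
#' @param slope_tol warn when the log-log slope deviates from -4 by more.
#' @return object of class `modulus_estimate` with `kappa` (k_BT),
#'   `kappa_J`, `se`, `tau` (k_BT/nm^2, tension fit only), `slope`,
#'   `slope_se` and window bookkeeping.
#' @export
fit_q4 <- function(spectrum, q_window = 5, include_tension = FALSE,
                   slope_tol = 0.5) {
  sh <- spectrum$shells
  sel_sh <- if (length(q_window) == 1) {
    sh$shell %in% head(sh$shell, q_window)
  } else {
    sh$q >= q_window[1] & sh$q <= q_window[2]
  }
  if (sum(sel_sh) < 3) {
    stop_memflex("fit window contains %d shells (need >= 3)", sum(sel_sh),
      class = "memflex_config_error")
  }
  win <- sh[sel_sh, ]
  if (any(win$S <= 0)) {
    warning(sprintf("dropping %d shell(s) with non-positive spectrum from the fit window",
      sum(win$S <= 0)), call. = FALSE)
    win <- win[win$S > 0, ]
    if (nrow(win) < 3) {
      stop_memflex("fewer than 3 positive shells remain in the fit window",
        class = "memflex_config_error")
    }
  }
  A <- spectrum$A
  ll <- lm(log(S) ~ log(q), data = win)
  slope <- unname(coef(ll)[2])
  slope_se <- suppressWarnings(summary(ll))$coefficients[2, 2]
  warn <- character()
  if (!include_tension && abs(slope + 4) > slope_tol) {
    warn <- sprintf("log-log slope %.2f deviates from -4 by more than %.2f", slope, slope_tol)
    warning(warn, call. = FALSE)
  }
  md <- spectrum$modes[spectrum$modes$shell %in% win$shell, ]
  if (include_tension) {
    y <- 1 / (A * win$S * win$q^2) # = tau + kappa q^2 in k_BT units
    # equal relative errors in S give var(y) ~ y^2 / n_modes (delta method)
    fit <- lm(y ~ I(win$q^2), weights = win$n_modes / y^2)
    kappa <- unname(coef(fit)[2])
    tau <- unname(coef(fit)[1])
    se <- suppressWarnings(summary(fit))$coefficients[2, 2]
    tau_se <- suppressWarnings(summary(fit))$coefficients[1, 2]
  } else {
    kv <- 1 / (A * md$S * md$q^4)
    kappa <- mean(kv)
    se <- sd(kv) / sqrt(length(kv))
    tau <- NULL
    tau_se <- NULL
  }
  modulus_estimate(
    method = "q4", kappa = kappa, se = se,
    temperature = spectrum$temperature,
    tau = tau, tau_se = tau_se, slope = slope, slope_se = slope_se,
    window = list(shells = win$shell, q = range(win$q), n_modes = sum(win$n_modes)),
    warnings = warn
  )
}

#' Bending-modulus convergence over simulation time
#'
#' Recomputes the estimate on the frame prefix `[1, t]` for each checkpoint.
#' For `method = "q4"` the per-frame mode powers are accumulated once, so
#' the series costs no more than a single full analysis.
#'
#' @param traj a [trajectory()].
#' @param assignment a [assign_leaflets()] result.
#' @param checkpoints frame indices (last one typically `n_frames`).
#' @param method `"q4"` or a `function(traj_prefix, assignment)` returning a
#'   `modulus_estimate`.
#' @param ... passed to [fit_q4()] for the q4 method.
#' @return data.frame with `frame`, `time` (ps) and `kappa` (k_BT).
#' @export
convergence_series <- function(traj, assignment, checkpoints,
                               method = "q4", ...) {
  checkpoints <- sort(unique(as.integer(checkpoints)))
  if (any(checkpoints < 2) || any(checkpoints > n_frames(traj))) {
    stop_memflex("checkpoints must lie in [2, n_frames]", class = "memflex_config_error")
  }
  if (identical(method, "q4")) {
    spec <- average_spectrum(traj, assignment, ...)
    kap <- vapply(checkpoints, function(tt) {
      m <- spec$modes
      m$S <- colMeans(spec$frame_power[seq_len(tt), , drop = FALSE])
      sub <- spectrum_from_modes(m, spec$frame_power[seq_len(tt), , drop = FALSE],
        A = spec$A, temperature = spec$temperature)
      suppressWarnings(fit_q4(sub)$kappa)
    }, numeric(1))
  } else {
    kap <- vapply(checkpoints, function(tt) {
      sub <- traj
      sub$frames <- traj$frames[seq_len(tt)]
      method(sub, assignment)$kappa
    }, numeric(1))
  }
  data.frame(frame = checkpoints, time = checkpoints * traj$dt, kappa = kap)
}

#' Construct a modulus estimate record
#'
#' Container shared by the three estimators; `kappa` is the bilayer bending
#' modulus in k_BT, `kappa_J` its joule value at `temperature`.
#'
#' @param method `"q4"`, `"bwdcf"` or `"rsf"`.
#' @param kappa bending modulus (k_BT).
#' @param se standard error (k_BT).
#' @param temperature K.
#' @param ... extra fields stored verbatim (`tau`, `slope`, diagnostics...).
#' @return object of class `modulus_estimate`.
#' @export
modulus_estimate <- function(method, kappa, se = NA_real_, temperature = 310, ...) {
  structure(
    c(list(method = method, kappa = kappa, se = se,
           kappa_J = kbt_to_joule(kappa, temperature),
           temperature = temperature), list(...)),
    class = "modulus_estimate"
  )
}

#' @export
print.modulus_estimate <- function(x, ...) {
  cat(sprintf("<modulus_estimate> %s: kappa_b = %.4g k_BT (%.3g J at %g K)%s\n",
    x$method, x$kappa, x$kappa_J, x$temperature,
    if (is.finite(x$se)) sprintf(", se %.2g", x$se) else ""))
  if (!is.null(x$tau)) cat(sprintf("  tau = %.4g k_BT/nm^2\n", x$tau))
  if (!is.null(x$slope)) cat(sprintf("  log-log slope %.3f\n", x$slope))
  invisible(x)
}
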