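# Synthetic equilibrium membrane ensembles with known ground truth.
#
# Frames are independent equilibrium samples (not time-correlated dynamics):
# estimator correctness depends only on the equilibrium distribution of
# heights, densities and splay. The only Markovian ingredient is the lateral
# random walk that emulates diffusion.

#' Parameters of the synthetic membrane ensemble
#'
#' Defaults describe the desk-scale stand-in for a coarse-grained 40 x 40 nm
#' bilayer patch: 1024 lipids per leaflet, kappa = 30 k_BT, zero tension,
#' thickness d = 4 nm, interface width a = 0.09 nm^2, T = 310 K, 1 ns frame
#' spacing and a lateral diffusion constant of 5e-6 nm^2/ps.
#'
#' @param L lateral box length (nm).
#' @param n_lipids_leaflet lipids per leaflet (square-lattice placement).
#' @param kappa ground-truth bending modulus (k_BT).
#' @param tau ground-truth tension (k_BT/nm^2).
#' @param d membrane thickness parameter (nm): leaflet head planes at +-d/2.
#' @param a mean-square interface width (nm^2): head z jitter about the
#'   undulating surface.
#' @param tilt_sd pointwise per-axis standard deviation (radians, small
#'   angle) of the smooth lipid tilt field (geometric mode). Tilt is a
#'   band-limited Gaussian random field (wavelengths 4--8 nm) rather than
#'   per-lipid white noise, so the pairwise splay of neighboring lipids is
#'   Gaussian and independent of the pair distance, as the Boltzmann splay
#'   model assumes. The implied splay variance is
#'   \eqn{V_t = \frac{1}{2}\,tilt\_sd^2\,\langle q^2\rangle_{band}}, giving
#'   a monolayer splay modulus \eqn{K_c = 1/(V_t A_l)}; both are recorded
#'   in the ground truth. The default `NULL` derives the amplitude from the
#'   bending modulus so that \eqn{K_c = \kappa/2}, i.e. the splay
#'   statistics are elastically consistent with the undulation spectrum and
#'   all three estimators target the same \eqn{\kappa}.
#' @param splay_mode `"geometric"` (directors follow sampled surface normals
#'   plus tilt noise) or `"direct"` (flat dimer lattice whose pair splay is
#'   drawn exactly from the Boltzmann distribution of `K_c`, `A_l`).
#' @param K_c,A_l direct-mode monolayer splay modulus (k_BT) and lipid area
#'   (nm^2).
#' @param D lateral diffusion constant (nm^2/ps); per-frame Gaussian step
#'   variance is `2 * D * dt` per axis.
#' @param temperature K.
#' @param n_frames number of stored frames.
#' @param n_max undulation mode cutoff (`|n| <= n_max`).
#' @param dt frame spacing (ps).
#' @param Lz box height (nm); membrane is centered at `Lz/2`.
#' @param tail_length head-to-terminal-tail distance along the director (nm).
#' @param seed RNG seed recorded in the provenance.
#' @return validated list of class `synth_params`.
#' @export
synth_params <- function(L = 40, n_lipids_leaflet = 1024, kappa = 30, tau = 0,
                         d = 4, a = 0.09, tilt_sd = NULL,
                         splay_mode = c("geometric", "direct"),
                         K_c = 12, A_l = 0.65, D = 5e-6,
                         temperature = 310, n_frames = 500, n_max = 5,
                         dt = 1000, Lz = 20, tail_length = 1.5, seed = 1) {
  splay_mode <- match.arg(splay_mode)
  stopifnot(L > 0, kappa > 0, n_lipids_leaflet >= 4, n_max >= 1,
    d > 0, a > 0, n_frames >= 1, dt > 0, D >= 0, temperature > 0,
    K_c > 0, A_l > 0)
  if (is.null(tilt_sd) && splay_mode == "geometric") {
    # amplitude such that the implied monolayer splay modulus is kappa/2
    V_t <- 2 / (kappa * L^2 / n_lipids_leaflet)
    tilt_sd <- sqrt(2 * V_t / mean(tilt_band(L)$q^2))
  }
  structure(
    list(L = L, n_lipids_leaflet = n_lipids_leaflet, kappa = kappa, tau = tau,
      d = d, a = a, tilt_sd = tilt_sd, splay_mode = splay_mode,
      K_c = K_c, A_l = A_l, D = D, temperature = temperature,
      n_frames = n_frames, n_max = n_max, dt = dt, Lz = Lz,
      tail_length = tail_length, seed = seed),
    class = "synth_params"
  )
}

# Per-mode variance of the Helfrich ensemble under the shared convention.
mode_variance <- function(params, lat) {
  1 / (params$L^2 * (params$tau * lat$q^2 + params$kappa * lat$q^4))
}

#' Sample one realization of the undulation height field
#'
#' Draws independent complex Gaussian modes on the half lattice with
#' \eqn{\langle|h_q|^2\rangle = k_BT/(A(\tau q^2+\kappa q^4))}, completes
#' them Hermitianly, and returns evaluators for the real field and its
#' lateral gradient at arbitrary points.
#'
#' @param params a [synth_params()].
#' @return list with the half `lattice`, complex `alpha` (one per half-lattice
#'   mode), `h(xy)` and `grad(xy)` evaluators, and `var_spatial`, the exact
#'   ensemble-expected spatial variance \eqn{\sum_q \langle|h_q|^2\rangle}.
#' @export
sample_height_field <- function(params) {
  lat <- q_lattice(params$L, params$n_max, half = TRUE)
  s2 <- mode_variance(params, lat)
  alpha <- complex(
    real = rnorm(nrow(lat), sd = sqrt(s2 / 2)),
    imaginary = rnorm(nrow(lat), sd = sqrt(s2 / 2))
  )
  Q <- rbind(lat$qx, lat$qy)
  a_re <- Re(alpha); a_im <- Im(alpha)
  h <- function(xy) {
    ph <- xy %*% Q
    2 * (cos(ph) %*% a_re - sin(ph) %*% a_im)[, 1]
  }
  grad <- function(xy) {
    ph <- xy %*% Q
    cp <- cos(ph); sp <- sin(ph)
    # d/dx sum 2(Re a cos - Im a sin) = sum 2(-Re a qx sin - Im a qx cos)
    hx <- (-2) * (sp %*% (a_re * lat$qx) + cp %*% (a_im * lat$qx))[, 1]
    hy <- (-2) * (sp %*% (a_re * lat$qy) + cp %*% (a_im * lat$qy))[, 1]
    cbind(hx, hy)
  }
  list(lattice = lat, alpha = alpha, h = h, grad = grad,
    var_spatial = 2 * sum(s2))
}

# Lattice band used for the smooth tilt field: wavelengths 4--8 nm, i.e.
# |q| in [2*pi/8, 2*pi/4] nm^-1, independent of the box size.
tilt_band <- function(L) {
  n_hi <- floor(L / 4)
  lat <- q_lattice(L, max(n_hi, 1), half = TRUE)
  band <- lat[lat$q >= 2 * pi / 8 & lat$q <= 2 * pi / 4, ]
  if (nrow(band) == 0) {
    stop_memflex("box too small (L = %g nm) to host the 4-8 nm tilt band", L,
      class = "memflex_param_error")
  }
  band
}

# One realization of a band-limited scalar Gaussian field with pointwise
# variance `var_point`, returned as an evaluator over lateral positions.
sample_scalar_field <- function(band, var_point) {
  s2 <- rep(var_point / (2 * nrow(band)), nrow(band)) # full-lattice share
  beta <- complex(
    real = rnorm(nrow(band), sd = sqrt(s2 / 2)),
    imaginary = rnorm(nrow(band), sd = sqrt(s2 / 2))
  )
  Q <- rbind(band$qx, band$qy)
  br <- Re(beta); bi <- Im(beta)
  function(xy) {
    ph <- xy %*% Q
    2 * (cos(ph) %*% br - sin(ph) %*% bi)[, 1]
  }
}

# Small-separation splay variance implied by the tilt field:
# (1/2) * sum_fulllattice sigma_q^2 q^2 = (tilt_sd^2 / 2) <q^2>_band.
tilt_splay_variance <- function(params) {
  band <- tilt_band(params$L)
  params$tilt_sd^2 / 2 * mean(band$q^2)
}

# Jittered square lattice of n points in an L x L box.
jittered_lattice <- function(n, L) {
  m <- ceiling(sqrt(n))
  sp <- L / m
  g <- expand.grid(ix = 0:(m - 1), iy = 0:(m - 1))[seq_len(n), ]
  cbind(
    (g$ix + 0.5) * sp + runif(n, -0.25, 0.25) * sp,
    (g$iy + 0.5) * sp + runif(n, -0.25, 0.25) * sp
  )
}

#' Generate a synthetic membrane trajectory with known ground truth
#'
#' Each frame is an independent equilibrium sample: a fresh undulation field
#' (per [sample_height_field()]), head beads at `z = Lz/2 +- d/2 + h(x,y) +
#' N(0, a)`, and one terminal tail bead per lipid placed `tail_length` along
#' the (noisy) director toward the midplane. Lateral positions start on
#' jittered per-leaflet lattices and follow a wrapped 2D Gaussian walk with
#' step variance `2 D dt` per axis. In `"direct"` splay mode the membrane is
#' flat and lipids sit in isolated dimers whose pair splay is drawn exactly
#' from `N(0, k_BT/(K_c A_l))`.
#'
#' @param params a [synth_params()].
#' @return a [trajectory()] whose provenance records the parameters and the
#'   ground truth (`kappa`, `tau`, `d`, `a`, `D`, expected spatial height
#'   variance, true leaflet labels, seed).
#' @export
generate_trajectory <- function(params) {
  set.seed(params$seed)
  if (params$splay_mode == "direct") return(generate_direct_dimers(params))
  npl <- params$n_lipids_leaflet
  z0 <- params$Lz / 2
  xy <- list(top = jittered_lattice(npl, params$L),
             bottom = jittered_lattice(npl, params$L))
  step_sd <- sqrt(2 * params$D * params$dt)
  meta <- data.frame(
    lipid_id = rep(1:(2 * npl), each = 2),
    species = "SYNT",
    role = rep(c("head", "tail_terminal"), 2 * npl),
    stringsAsFactors = FALSE
  )
  # mode bookkeeping shared by every frame
  lat <- q_lattice(params$L, params$n_max, half = TRUE)
  s2 <- mode_variance(params, lat)
  Qh <- rbind(lat$qx, lat$qy)
  band <- tilt_band(params$L)
  Qt <- rbind(band$qx, band$qy)
  t2 <- params$tilt_sd^2 / (2 * nrow(band))
  frames <- vector("list", params$n_frames)
  for (f in seq_len(params$n_frames)) {
    if (f > 1 && step_sd > 0) {
      for (side in c("top", "bottom")) {
        st <- matrix(rnorm(2 * npl, sd = step_sd), ncol = 2)
        xy[[side]] <- xy[[side]] + st
        xy[[side]][, 1] <- xy[[side]][, 1] %% params$L
        xy[[side]][, 2] <- xy[[side]][, 2] %% params$L
      }
    }
    # fresh undulation field: h(x) = sum_q 2(Re a cos(qx) - Im a sin(qx))
    a_re <- rnorm(nrow(lat), sd = sqrt(s2 / 2))
    a_im <- rnorm(nrow(lat), sd = sqrt(s2 / 2))
    pos <- matrix(0, 4 * npl, 3)
    for (side in c("top", "bottom")) {
      sgn <- if (side == "top") 1 else -1
      X <- xy[[side]]
      ph <- X %*% Qh
      cp <- cos(ph); sp <- sin(ph)
      h <- 2 * (cp %*% a_re - sp %*% a_im)[, 1]
      hx <- (-2) * (sp %*% (a_re * lat$qx) + cp %*% (a_im * lat$qx))[, 1]
      hy <- (-2) * (sp %*% (a_re * lat$qy) + cp %*% (a_im * lat$qy))[, 1]
      zhead <- z0 + sgn * params$d / 2 + h + rnorm(npl, sd = sqrt(params$a))
      # smooth per-leaflet tilt fields u, v on the 4-8 nm band
      b_re <- matrix(rnorm(2 * nrow(band), sd = sqrt(t2 / 2)), ncol = 2)
      b_im <- matrix(rnorm(2 * nrow(band), sd = sqrt(t2 / 2)), ncol = 2)
      pht <- X %*% Qt
      uv <- 2 * (cos(pht) %*% b_re - sin(pht) %*% b_im)
      # director lateral components = outward-normal lateral components plus
      # the tilt field, exactly (z chosen for unit norm), so pairwise splay
      # differences are linear in the tilt field
      grad_norm <- sqrt(1 + hx^2 + hy^2)
      nlat <- cbind(-sgn * hx / grad_norm + uv[, 1],
                    -sgn * hy / grad_norm + uv[, 2])
      lat2 <- pmin(rowSums(nlat^2), 0.99)
      nvec <- cbind(nlat, sgn * sqrt(1 - lat2))
      head_xyz <- cbind(X[, 1], X[, 2], zhead)
      tail_xyz <- head_xyz - params$tail_length * nvec
      rows0 <- if (side == "top") 0L else 2L * npl
      pos[rows0 + seq(1, 2 * npl, by = 2), ] <- head_xyz
      pos[rows0 + seq(2, 2 * npl, by = 2), ] <- tail_xyz
    }
    frames[[f]] <- bead_frame(pos, c(params$L, params$L, params$Lz),
      time = (f - 1) * params$dt, meta = meta, validate = f == 1)
  }
  var_sp <- 2 * sum(s2) * params$n_frames
  trajectory(frames,
    temperature = params$temperature, dt = params$dt,
    provenance = list(
      origin = "synthetic", params = unclass(params),
      ground_truth = list(
        kappa = params$kappa, tau = params$tau, d = params$d, a = params$a,
        D = params$D, var_spatial_h = var_sp / params$n_frames,
        splay_var = tilt_splay_variance(params),
        A_l = params$L^2 / npl,
        K_c = 1 / (tilt_splay_variance(params) * params$L^2 / npl),
        leaflet = setNames(rep(c("top", "bottom"), each = npl), 1:(2 * npl)),
        seed = params$seed
      )
    )
  )
}

# Direct splay mode: flat membrane, isolated lipid dimers, per-pair splay
# drawn exactly from the Boltzmann distribution. Dimer sites are spaced so a
# 1.2 nm neighbor cutoff sees only intra-dimer pairs.
generate_direct_dimers <- function(params) {
  npl <- params$n_lipids_leaflet
  if (npl %% 2 != 0) {
    stop_memflex("direct splay mode needs an even n_lipids_leaflet",
      class = "memflex_param_error")
  }
  n_dim <- npl / 2
  m <- ceiling(sqrt(n_dim))
  spacing <- params$L / m
  h0 <- 0.8 # intra-dimer separation (nm)
  if (spacing < 2 * 1.2 + h0) {
    stop_memflex(
      "lattice cannot host %d lipids/leaflet as isolated dimers in L = %g nm",
      npl, params$L, class = "memflex_param_error")
  }
  g <- expand.grid(ix = 0:(m - 1), iy = 0:(m - 1))[seq_len(n_dim), ]
  centers <- cbind((g$ix + 0.5) * spacing, (g$iy + 0.5) * spacing)
  z0 <- params$Lz / 2
  sd_S <- sqrt(1 / (params$K_c * params$A_l))
  meta <- data.frame(
    lipid_id = rep(1:(2 * npl), each = 2),
    species = "SYNT",
    role = rep(c("head", "tail_terminal"), 2 * npl),
    stringsAsFactors = FALSE
  )
  frames <- vector("list", params$n_frames)
  for (f in seq_len(params$n_frames)) {
    pos <- matrix(0, 8 * n_dim * 2 / 2, 3) # 2 lipids x 2 beads x 2 leaflets per dimer
    row <- 0
    for (side in c(1, -1)) {
      S <- rnorm(n_dim, sd = sd_S)
      delta <- asin(pmax(-0.99, pmin(0.99, S * h0 / 2)))
      for (k in seq_len(n_dim)) {
        for (j in c(-1, 1)) { # lipid A (-) then B (+) along x
          hx <- centers[k, 1] + j * h0 / 2
          hy <- centers[k, 2]
          hz <- z0 + side * params$d / 2 + rnorm(1, sd = sqrt(params$a))
          nv <- c(j * sin(delta[k]), 0, side * cos(delta[k]))
          tailp <- c(hx, hy, hz) - params$tail_length * nv
          pos[row + 1, ] <- c(hx, hy, hz)
          pos[row + 2, ] <- tailp
          row <- row + 2
        }
      }
    }
    frames[[f]] <- bead_frame(pos, c(params$L, params$L, params$Lz),
      time = (f - 1) * params$dt, meta = meta, validate = f == 1)
  }
  trajectory(frames,
    temperature = params$temperature, dt = params$dt,
    provenance = list(
      origin = "synthetic", params = unclass(params),
      ground_truth = list(
        kappa = 2 * params$K_c, K_c = params$K_c, A_l = params$A_l,
        splay_var = 1 / (params$K_c * params$A_l),
        d = params$d, a = params$a, seed = params$seed,
        leaflet = setNames(rep(c("top", "bottom"), each = npl), 1:(2 * npl))
      )
    )
  )
}

#' Draw i.i.d. splay samples from the Boltzmann distribution
#'
#' \eqn{S_t \sim N(0, k_BT/(K_c A_l))} in nm^-1 (k_BT = 1 reduced units).
#'
#' @param K_c monolayer splay modulus (k_BT).
#' @param A_l lipid area (nm^2).
#' @param n number of samples.
#' @param seed optional RNG seed.
#' @return numeric vector of splay samples.
#' @export
generate_splay_samples <- function(K_c, A_l, n, seed = NULL) {
  if (K_c <= 0) stop_memflex("K_c must be > 0", class = "memflex_param_error")
  stopifnot(A_l > 0, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  rnorm(n, sd = sqrt(1 / (K_c * A_l)))
}
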