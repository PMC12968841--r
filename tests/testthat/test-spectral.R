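test_that("height modes vanish for flat membranes and obey the shift theorem", {
  fr <- make_bilayer_frame(n_per_leaflet = 64, L = 10)
  asg <- assign_leaflets(fr)
  hm <- height_modes(fr, asg, n_max = 3)
  expect_true(all(abs(hm$re) < 1e-12 & abs(hm$im) < 1e-12))

  # cosine field on a dense uniform lattice: |h| = a/2 at (±1, 0), ~0 elsewhere
  amp <- 0.3
  fr2 <- make_field_frame(function(x, y) amp * cos(2 * pi * x / 10), m = 16)
  asg2 <- assign_leaflets(fr2)
  hm2 <- height_modes(fr2, asg2, n_max = 3)
  at <- hm2[hm2$ny == 0 & abs(hm2$nx) == 1, ]
  expect_equal(sqrt(at$power), rep(amp / 2, 2), tolerance = 1e-10)
  expect_lt(max(hm2$power[!(hm2$ny == 0 & abs(hm2$nx) == 1)]), 1e-20)

  # Hermitian symmetry h(-q) = conj(h(q))
  key <- paste(hm2$nx, hm2$ny)
  mirror <- match(paste(-hm2$nx, -hm2$ny), key)
  expect_equal(hm2$re, hm2$re[mirror])
  expect_equal(hm2$im, -hm2$im[mirror])

  # lateral translation changes phases only
  fr3 <- fr2
  fr3$positions[, 1] <- (fr3$positions[, 1] + 2.13) %% 10
  hm3 <- height_modes(fr3, asg2, n_max = 3)
  expect_equal(hm3$power, hm2$power, tolerance = 1e-12)
})

test_that("Parseval holds to 1e-10 on lattice-sampled band-limited fields", {
  set.seed(99)
  L <- 10
  lat <- q_lattice(L, 3, half = TRUE)
  cf <- rnorm(nrow(lat), sd = 0.1)
  sf <- rnorm(nrow(lat), sd = 0.1)
  field <- function(x, y) {
    z <- 0
    for (k in seq_len(nrow(lat))) {
      z <- z + 2 * (cf[k] * cos(lat$qx[k] * x + lat$qy[k] * y) -
                    sf[k] * sin(lat$qx[k] * x + lat$qy[k] * y))
    }
    z
  }
  fr <- make_field_frame(field, m = 16, L = L)
  hm <- height_modes(fr, assign_leaflets(fr), n_max = 3)
  # spatial variance of the gridded field (q = 0 component is zero)
  g <- expand.grid(x = 0:15 * L / 16, y = 0:15 * L / 16)
  zv <- field(g$x, g$y)
  expect_lt(abs(sum(hm$power) - mean(zv^2)), 1e-10)
})

test_that("ensemble averaging and spectrum bookkeeping are consistent", {
  w <- small_world()
  sp <- average_spectrum(w$traj, w$assignment, n_max = 3)
  expect_equal(nrow(sp$frame_power), 120)
  expect_equal(sp$A, 400)
  # identical frames -> ensemble spectrum equals the single-frame spectrum
  tr1 <- w$traj
  tr1$frames <- rep(tr1$frames[1], 4)
  for (i in 1:4) tr1$frames[[i]]$time <- i
  sp1 <- average_spectrum(tr1, w$assignment, n_max = 3)
  expect_equal(sp1$modes$S, sp1$frame_power[1, ], tolerance = 1e-12,
    ignore_attr = TRUE)
})

test_that("fit_q4 inverts noiseless spectra exactly", {
  L <- 40; A <- L^2; kappa <- 20
  lat <- q_lattice(L, 5, half = TRUE)
  modes <- cbind(lat, S = 1 / (A * kappa * lat$q^4))
  sp <- memflex:::spectrum_from_modes(modes,
    matrix(modes$S, 2, nrow(modes), byrow = TRUE), A = A, temperature = 310)
  est <- fit_q4(sp)
  expect_equal(est$kappa, 20, tolerance = 1e-12)
  expect_equal(est$slope, -4, tolerance = 1e-10)
  expect_equal(est$kappa_J, kbt_to_joule(20, 310))

  # tension-inclusive fit recovers (kappa, tau) exactly from the full model
  tau <- 5
  modes2 <- cbind(lat, S = 1 / (A * (tau * lat$q^2 + kappa * lat$q^4)))
  sp2 <- memflex:::spectrum_from_modes(modes2,
    matrix(modes2$S, 2, nrow(modes2), byrow = TRUE), A = A, temperature = 310)
  est2 <- fit_q4(sp2, include_tension = TRUE)
  expect_equal(est2$kappa, kappa, tolerance = 1e-9)
  expect_equal(est2$tau, tau, tolerance = 1e-9)

  expect_error(fit_q4(sp, q_window = 2), class = "memflex_config_error")
})

test_that("generator/estimator convention round trip recovers kappa (master test)", {
  w <- small_world()
  est <- fit_q4(average_spectrum(w$traj, w$assignment, n_max = 5))
  expect_rel(est$kappa, 30, 0.10)
  expect_lt(abs(est$slope + 4), 0.3)

  # spectrum invariant under lipid relabeling
  fr <- w$traj$frames[[1]]
  perm <- sample(nrow(fr$positions))
  fr2 <- bead_frame(fr$positions[perm, ], fr$box, meta = fr$meta[perm, ])
  hm_a <- height_modes(fr, w$assignment, 2)
  hm_b <- height_modes(fr2, assign_leaflets(fr2), 2)
  expect_equal(hm_b$power, hm_a$power, tolerance = 1e-10)
})

test_that("tension-inclusive fits separate kappa and tau on synthetic data", {
  kappa <- 30
  tau <- kappa * (2 * pi * sqrt(8) / 40)^2 # tau q^2 ~ kappa q^4 at the window edge
  p <- synth_params(L = 40, n_lipids_leaflet = 400, kappa = kappa, tau = tau,
    n_frames = 500, seed = 31)
  tr <- generate_trajectory(p)
  asg <- suppressWarnings(assign_leaflets(tr))
  sp <- average_spectrum(tr, asg)
  est <- fit_q4(sp, include_tension = TRUE)
  expect_rel(est$kappa, kappa, 0.15)
  expect_rel(est$tau, tau, 0.15)
  # neglecting the tension adds tau/q^2 >= 0 to every per-mode inversion, so
  # the pure q^-4 fit over the same band is biased high — directionally
  est0 <- suppressWarnings(fit_q4(sp, include_tension = FALSE))
  expect_gt(est0$kappa, est$kappa)
  expect_gt(est0$kappa, kappa)
})

test_that("convergence series ends at the full-trajectory estimate", {
  w <- small_world()
  cs <- convergence_series(w$traj, w$assignment, checkpoints = c(40, 80, 120))
  full <- fit_q4(average_spectrum(w$traj, w$assignment))
  expect_equal(cs$kappa[3], full$kappa, tolerance = 1e-12)
  expect_equal(cs$time, c(40, 80, 120) * w$traj$dt)
  # single checkpoint equals the plain estimate
  one <- convergence_series(w$traj, w$assignment, checkpoints = 120)
  expect_equal(one$kappa, full$kappa, tolerance = 1e-12)
  expect_error(convergence_series(w$traj, w$assignment, checkpoints = 1000),
    class = "memflex_config_error")
})
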