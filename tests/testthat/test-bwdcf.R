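model_fixture <- function(rho_o = 1.5, d = 4, a = 0.09, sign = 1) {
  structure(list(rho_o = rho_o, d = d, a = a, sign = sign),
    class = "density_model")
}

test_that("Gaussian density derivatives match finite differences and closed forms", {
  m <- model_fixture()
  d1 <- gaussian_density_derivatives(m, 1)
  expect_equal(d1(m$d / 2), 0) # extremum at the center
  d2 <- gaussian_density_derivatives(m, 2)
  expect_equal(d2(m$d / 2), -m$rho_o / (m$a * sqrt(2 * pi * m$a)),
    tolerance = 1e-12)

  # n-th derivative vs central finite differences of the density itself
  rho <- memflex:::gaussian_deriv_fun(m, 0)
  z <- seq(-m$d, m$d, length.out = 41)
  h <- 1e-4
  for (n in 1:4) {
    dn <- gaussian_density_derivatives(m, n)
    # finite-difference the (n-1)-th analytic derivative once
    prev <- if (n == 1) rho else gaussian_density_derivatives(m, n - 1)
    fd <- (prev(z + h) - prev(z - h)) / (2 * h)
    expect_equal(dn(z), fd, tolerance = 1e-6)
  }
  expect_error(gaussian_density_derivatives(m, 0), class = "memflex_config_error")
})

test_that("A matrix has parity zeros, closed-form entries and bilinear scaling", {
  m <- model_fixture(rho_o = 1.5, a = 0.09)
  Am <- bw_matrix_A(m, n_bw = 4)
  for (n in 1:4) for (k in 1:4) {
    if ((n + k) %% 2 == 1) expect_identical(Am$A[n, k], 0)
  }
  expect_equal(Am$A[1, 1], m$rho_o^2 / (4 * sqrt(pi) * m$a^1.5),
    tolerance = 1e-8)
  expect_equal(Am$A %*% Am$A_inv, diag(4), tolerance = 1e-8,
    ignore_attr = TRUE)

  Am2 <- bw_matrix_A(model_fixture(rho_o = 3, a = 0.09), n_bw = 4)
  expect_equal(Am2$A, 4 * Am$A, tolerance = 1e-10)

  expect_error(bw_matrix_A(m, n_bw = 6, cond_limit = 10),
    class = "memflex_conditioning_error")
})

test_that("B matrix reproduces the two-bead hand computation", {
  # one lipid per leaflet at lateral separation dx
  L <- 10; d <- 4; dx <- 1.5
  pos <- rbind(
    c(1.0, 5, 10 + d / 2), c(1.0, 5, 10 + d / 2 - 1.5),
    c(1.0 + dx, 5, 10 - d / 2), c(1.0 + dx, 5, 10 - d / 2 + 1.5))
  meta <- data.frame(lipid_id = c(1, 1, 2, 2), species = "SYNT",
    role = rep(c("head", "tail_terminal"), 2), stringsAsFactors = FALSE)
  fr <- bead_frame(pos, c(L, L, 20), meta = meta)
  tr <- trajectory(list(fr))
  asg <- assign_leaflets(fr)
  m <- model_fixture(rho_o = 0.02, d = 4.4, a = 0.2)
  qt <- q_lattice(L, 2, half = TRUE)[1:3, ]
  Bm <- bw_matrix_B(tr, asg, m, q_table = qt, n_bw = 2)
  mid <- asg$midplane[1]
  z1 <- pos[1, 3] - mid
  z2 <- pos[3, 3] - mid
  for (k in 1:3) {
    dphi <- qt$qx[k] * (pos[1, 1] - pos[3, 1]) + qt$qy[k] * (pos[1, 2] - pos[3, 2])
    for (n in 1:2) for (mm in 1:2) {
      mt <- m; mt$sign <- 1
      mb <- m; mb$sign <- -1
      expected <- gaussian_density_derivatives(mt, n)(z1) * cos(dphi) *
        gaussian_density_derivatives(mb, mm)(z2) / L^2
      expect_equal(Bm$B[n, mm, k], expected, tolerance = 1e-12)
    }
  }
  # non-commensurate q is rejected
  bad <- qt; bad$qx <- bad$qx * 1.01
  expect_error(bw_matrix_B(tr, asg, m, q_table = bad, n_bw = 2),
    class = "memflex_config_error")
})

test_that("statistically independent leaflets give B(q) ~ 0", {
  set.seed(5)
  n <- 200; L <- 20
  meta <- data.frame(lipid_id = rep(1:(2 * n), each = 2), species = "SYNT",
    role = rep(c("head", "tail_terminal"), 2 * n), stringsAsFactors = FALSE)
  make <- function(i) {
    pos <- NULL
    for (side in c(1, -1)) {
      xy <- cbind(runif(n, 0, L), runif(n, 0, L))
      zh <- 10 + side * 2 + rnorm(n, sd = 0.3)
      blk <- matrix(0, 2 * n, 3)
      blk[seq(1, 2 * n, 2), ] <- cbind(xy, zh)
      blk[seq(2, 2 * n, 2), ] <- cbind(xy, zh - side * 1.5)
      pos <- rbind(pos, blk)
    }
    bead_frame(pos, c(L, L, 20), time = i, meta = meta, validate = i == 0)
  }
  frames <- lapply(0:39, make)
  tr <- trajectory(frames)
  asg <- assign_leaflets(tr)
  m <- model_fixture(rho_o = n / L^2, a = 0.09)
  Bm <- bw_matrix_B(tr, asg, m, q_table = 2, n_bw = 1, n_blocks = 40)
  # per-frame B11 values average to zero within 4 SE at every q
  for (k in seq_len(dim(Bm$B)[3])) {
    per <- Bm$B_blocks[1, 1, k, ]
    expect_lt(abs(mean(per)), 4 * sd(per) / sqrt(length(per)) + 1e-12)
  }
})

test_that("the two B-matrix backends agree within binning tolerance", {
  p <- synth_params(L = 20, n_lipids_leaflet = 144, kappa = 25, n_frames = 30,
    seed = 17)
  tr <- generate_trajectory(p)
  asg <- suppressWarnings(assign_leaflets(tr))
  prof <- density_profile(tr, asg, "top")
  m <- fit_density_gaussian(prof)
  qt <- q_lattice(20, 2, half = TRUE)
  Bd <- bw_matrix_B(tr, asg, m, q_table = qt, n_bw = 3, backend = "direct")
  Bb <- bw_matrix_B(tr, asg, m, q_table = qt, n_bw = 3, backend = "binned",
    z_bins = 200)
  # entrywise agreement on the physical scale of each entry (parity-odd
  # entries average to zero; their own maximum is a noise scale)
  sc_diag <- vapply(1:3, function(n) max(abs(Bd$B[n, n, ])), numeric(1))
  for (n in 1:3) for (k in 1:3) {
    sc <- sqrt(sc_diag[n] * sc_diag[k])
    expect_lt(max(abs(Bd$B[n, k, ] - Bb$B[n, k, ])) / sc, 0.02)
  }
  expect_equal(dim(Bb$G), c(200, 200, nrow(qt)))
})

test_that("gamma_cu matches the 1x1 algebra and drops bad shells", {
  m <- model_fixture(rho_o = 0.5, a = 0.12)
  Am <- bw_matrix_A(m, 1)
  qt <- q_lattice(20, 2, half = TRUE)
  B11 <- 0.02 * (1 + seq_len(nrow(qt)))
  Bm <- structure(list(B = array(B11, c(1, 1, nrow(qt))), q_table = qt,
    A_o = 400, n_bw = 1, n_frames = 1, backend = "direct"),
    class = "bw_matrix_B")
  gc_ <- gamma_cu(Am, Bm)
  # per-shell: gamma = A11^2 / (q^2 * mean B11)
  for (i in seq_len(nrow(gc_$shells))) {
    sh <- gc_$shells$shell[i]
    expect_equal(gc_$shells$gamma[i],
      Am$A[1, 1]^2 / (gc_$shells$q[i]^2 * mean(B11[qt$shell == sh])),
      tolerance = 1e-10)
  }
  # non-positive structure factor is dropped with a warning
  Bm$B[1, 1, 1:2] <- -1
  expect_warning(gc2 <- gamma_cu(Am, Bm), "non-positive")
  expect_false(1 %in% gc2$shells$shell)
})

test_that("quadratic gamma fits are exact on exact curves", {
  qt <- q_lattice(40, 3, half = TRUE)
  shells <- data.frame(shell = unique(qt$shell))
  shells$q <- sqrt(shells$shell) * 2 * pi / 40
  shells$S1 <- 1 # unused by the fit
  shells$n_modes <- 2
  shells$gamma <- 0.5 + 25 * shells$q^2
  curve <- structure(list(points = NULL, shells = shells), class = "gamma_curve")
  est <- fit_gamma_quadratic(curve, q_window = 3)
  expect_equal(est$kappa, 25, tolerance = 1e-10)
  expect_equal(est$gamma_o, 0.5, tolerance = 1e-10)
  est5 <- fit_gamma_quadratic(curve, q_window = 5)
  expect_equal(est5$kappa, 25, tolerance = 1e-10)
  expect_error(fit_gamma_quadratic(curve, q_window = 2),
    class = "memflex_config_error")
})

test_that("BW-DCF recovers the generator's bending modulus end to end", {
  p <- synth_params(L = 20, n_lipids_leaflet = 256, kappa = 25, n_frames = 250,
    seed = 23)
  tr <- generate_trajectory(p)
  asg <- suppressWarnings(assign_leaflets(tr))
  est <- estimate_bwdcf(tr, asg)
  expect_rel(est$kappa, 25, 0.30)
  # cross-method consistency with the undulation spectrum on the same frames
  q4 <- fit_q4(average_spectrum(tr, asg))
  expect_lt(abs(est$kappa - q4$kappa), 3 * (est$se + q4$se))
})
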