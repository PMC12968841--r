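test_that("directors point from tail ends to heads, outward per leaflet", {
  fr <- make_bilayer_frame(n_per_leaflet = 4, d = 4, tail_len = 2)
  asg <- assign_leaflets(fr)
  dir <- compute_directors(fr, asg)
  expect_equal(dir$nz[dir$leaflet == "top"], rep(1, 4))
  expect_equal(dir$nz[dir$leaflet == "bottom"], rep(-1, 4))
  expect_equal(sqrt(dir$nx^2 + dir$ny^2 + dir$nz^2), rep(1, 8),
    tolerance = 1e-10)

  # prescribed tilt angle is recovered exactly
  theta <- 0.3
  fr2 <- fr
  hrow <- which(fr2$meta$lipid_id == 1 & fr2$meta$role == "head")
  trow <- which(fr2$meta$lipid_id == 1 & fr2$meta$role == "tail_terminal")
  fr2$positions[trow, ] <- fr2$positions[hrow, ] -
    2 * c(sin(theta), 0, cos(theta))
  dir2 <- compute_directors(fr2, asg)
  expect_equal(acos(dir2$nz[1]), theta, tolerance = 1e-10)

  # zero-length director
  fr3 <- fr
  fr3$positions[trow, ] <- fr3$positions[hrow, ]
  expect_error(compute_directors(fr3, asg), class = "memflex_degenerate_error")
})

test_that("local normals recover flat and tilted planes", {
  fr <- make_bilayer_frame(n_per_leaflet = 25, L = 5, d = 4)
  asg <- assign_leaflets(fr)
  nor <- local_normals(fr, asg, patch_radius = 1.5)
  expect_equal(nor$Nz[asg$leaflet == "top"], rep(1, 25), tolerance = 1e-12)
  expect_equal(nor$Nz[asg$leaflet == "bottom"], rep(-1, 25), tolerance = 1e-12)

  # leaflet on the plane z = x tan(alpha), lipids clustered away from the
  # periodic seam so the plane is single-valued over every patch
  alpha <- 0.25
  fr2 <- make_bilayer_frame(n_per_leaflet = 25, L = 40, d = 8)
  sel <- fr2$meta$role == "head" | fr2$meta$role == "tail_terminal"
  fr2$positions[, 1:2] <- fr2$positions[, 1:2] / 8 # cluster into 5x5 nm
  fr2$positions[, 3] <- fr2$positions[, 3] +
    fr2$positions[, 1] * tan(alpha)
  asg2 <- assign_leaflets(fr2)
  nor2 <- local_normals(fr2, asg2, patch_radius = 1.5)
  expected <- c(-sin(alpha), 0, cos(alpha))
  top <- which(asg2$leaflet == "top")
  for (k in head(top, 3)) {
    expect_equal(c(nor2$Nx[k], nor2$Ny[k], nor2$Nz[k]), expected,
      tolerance = 1e-8)
  }

  # isolated lipids fall back to the global leaflet normal with a warning
  fr3 <- make_bilayer_frame(n_per_leaflet = 4, L = 40)
  expect_warning(nor3 <- local_normals(fr3, assign_leaflets(fr3), 1.5),
    "global leaflet normal")
  expect_equal(nor3$Nz, c(1, 1, 1, 1, -1, -1, -1, -1))
})

test_that("neighbor pairs respect cutoff, lattice counts and periodicity", {
  # two lipids 0.5 nm apart
  fr <- make_bilayer_frame(n_per_leaflet = 2, L = 4)
  fr$positions[, 1] <- c(1, 1, 1.5, 1.5, 1, 1, 1.5, 1.5)
  fr$positions[, 2] <- 2
  asg <- assign_leaflets(fr)
  pr <- neighbor_pairs(fr, asg, cutoff = 1.2)
  expect_equal(nrow(pr), 2) # one pair per leaflet
  expect_equal(pr$dist, c(0.5, 0.5))

  # 5x5 periodic lattice, spacing 0.8, cutoff 1.0: every lipid has exactly 4
  fr2 <- make_bilayer_frame(n_per_leaflet = 25, L = 4)
  asg2 <- assign_leaflets(fr2)
  pr2 <- neighbor_pairs(fr2, asg2, cutoff = 1.0)
  counts <- table(c(pr2$i, pr2$j))
  expect_true(all(counts == 4))
  expect_equal(nrow(pr2), 2 * 25 * 4 / 2)

  # wrapped pair across the boundary
  fr3 <- make_bilayer_frame(n_per_leaflet = 2, L = 10)
  fr3$positions[, 1] <- c(0.2, 0.2, 9.9, 9.9, 0.2, 0.2, 9.9, 9.9)
  fr3$positions[, 2] <- 5
  pr3 <- neighbor_pairs(fr3, assign_leaflets(fr3), cutoff = 1.2)
  expect_equal(nrow(pr3), 2)
  expect_equal(pr3$dist, c(0.3, 0.3), tolerance = 1e-12)
})

test_that("pair splay matches hand trigonometry and symmetry properties", {
  N <- c(0, 0, 1)
  # identical directors -> zero splay
  expect_equal(pair_splay(c(0.1, 0, 0.99), c(0.1, 0, 0.99), N, N, c(1, 0)), 0)
  # symmetric +-delta tilt about a shared normal: S = 2 sin(delta) / h
  delta <- 0.1
  nA <- c(-sin(delta), 0, cos(delta))
  nB <- c(sin(delta), 0, cos(delta))
  expect_equal(pair_splay(nA, nB, N, N, c(1, 0)), 2 * sin(delta),
    tolerance = 1e-10)
  expect_equal(round(pair_splay(nA, nB, N, N, c(1, 0)), 5), 0.19967)
  # swapping the lipids leaves S unchanged
  expect_equal(pair_splay(nB, nA, N, N, c(-1, 0)),
    pair_splay(nA, nB, N, N, c(1, 0)))
  # flat leaflet, directors equal to the normal -> 0 for any separation
  expect_equal(pair_splay(N, N, N, N, c(0.37, 0.11)), 0)
  # sum convention assembles the normal increments with opposite sign
  NB <- c(0.05, 0, sqrt(1 - 0.05^2))
  s_diff <- pair_splay(nA, nB, N, NB, c(1, 0))
  s_sum <- pair_splay(nA, nB, N, NB, c(1, 0), convention = "sum")
  expect_equal(s_sum - s_diff, 2 * 0.05)
  expect_error(pair_splay(nA, nB, N, N, c(0, 0)),
    class = "memflex_degenerate_error")
})

test_that("splay is invariant under in-plane rigid rotation of the frame", {
  p <- synth_params(L = 20, n_lipids_leaflet = 64, kappa = 25, n_frames = 1,
    seed = 13)
  tr <- generate_trajectory(p)
  fr <- tr$frames[[1]]
  asg <- assign_leaflets(fr)
  s0 <- suppressWarnings(splay_samples(fr, asg, patch_radius = 2.8))
  # rotate 90 degrees about the box center (maps the periodic cell onto itself)
  R <- matrix(c(0, -1, 1, 0), 2)
  fr2 <- fr
  fr2$positions[, 1:2] <- sweep(fr$positions[, 1:2], 2, c(10, 10)) %*% t(R) +
    matrix(c(10, 10), nrow(fr$positions), 2, byrow = TRUE)
  fr2 <- bead_frame(fr2$positions, fr2$box, meta = fr2$meta)
  s1 <- suppressWarnings(splay_samples(fr2, assign_leaflets(fr2), patch_radius = 2.8))
  expect_equal(sort(s1$S), sort(s0$S), tolerance = 1e-8)
})

test_that("Boltzmann inversion recovers K_c from direct splay samples", {
  S <- generate_splay_samples(K_c = 12, A_l = 0.65, n = 1e5, seed = 99)
  d <- splay_distribution(S, A_l = 0.65)
  expect_equal(sum(d$P) * d$bin_width, 1, tolerance = 1e-12)
  est <- fit_splay_modulus(d)
  expect_rel(est$K_c_monolayer, 12, 0.05)
  # bilayer modulus is exactly twice the monolayer value
  expect_identical(est$kappa, 2 * est$K_c_monolayer)
  # agreement with the variance-inversion oracle
  expect_rel(est$K_c_monolayer, 1 / (0.65 * var(S)), 0.03)

  expect_error(splay_distribution(rep(0, 100), 0.65), class = "memflex_fit_error")
  expect_error(generate_splay_samples(K_c = -1, A_l = 0.65, n = 10),
    class = "memflex_param_error")
})

test_that("pair-modulus combination follows the harmonic pair weighting", {
  expect_equal(combine_pair_moduli(c(a = 10), c(20)), 20)
  expect_equal(combine_pair_moduli(c(3, 7), c(15, 15)), 15)
  # phi11=100 chi11=10, phi12=50 chi12=20 -> K_c = 150/(100/10+50/20) = 12
  expect_equal(combine_pair_moduli(c(100, 50), c(10, 20)), 12)
  # bounds property on random inputs
  set.seed(2)
  for (i in 1:20) {
    phi <- runif(4, 1, 100)
    chi <- runif(4, 5, 40)
    K <- combine_pair_moduli(phi, chi)
    expect_gte(K, min(chi))
    expect_lte(K, max(chi))
  }
  expect_error(combine_pair_moduli(c(1, 1), c(10, 0)),
    class = "memflex_param_error")
})

test_that("RSF end-to-end recovery on geometric synthetic membranes", {
  p <- synth_params(L = 20, n_lipids_leaflet = 256, kappa = 25, n_frames = 25,
    seed = 6)
  tr <- generate_trajectory(p)
  asg <- suppressWarnings(assign_leaflets(tr))
  gt <- tr$provenance$ground_truth
  # wide normal patches: with a = 0.09 nm^2 interface jitter, plane-fit
  # slope noise at the spec's 1.5 nm patch dominates the splay signal
  est <- suppressWarnings(estimate_rsf(tr, asg, patch_radius = 2.8))
  expect_rel(est$K_c_monolayer, gt$K_c, 0.10)
  expect_rel(est$kappa, 25, 0.15) # generator ties K_c to kappa/2
  # quadratic fit consistent with variance inversion on the same samples
  samp <- suppressWarnings(splay_samples(tr, asg, patch_radius = 2.8))
  expect_rel(est$K_c_monolayer, 1 / (est$A_l * var(samp$S)), 0.05)
})

test_that("direct dimer mode realizes the prescribed Boltzmann splay", {
  p <- synth_params(L = 40, n_lipids_leaflet = 128, splay_mode = "direct",
    K_c = 12, A_l = 0.65, n_frames = 50, seed = 9)
  tr <- generate_trajectory(p)
  asg <- assign_leaflets(tr)
  est <- suppressWarnings(estimate_rsf(tr, asg, A_l = 0.65))
  expect_rel(est$K_c_monolayer, 12, 0.10)
  expect_identical(est$kappa, 2 * est$K_c_monolayer)
})

test_that("multi-species trajectories combine per-pair moduli", {
  p <- synth_params(L = 20, n_lipids_leaflet = 256, kappa = 25, n_frames = 10,
    seed = 14)
  tr <- generate_trajectory(p)
  # tag half the lipids as a second species
  for (i in seq_along(tr$frames)) {
    tr$frames[[i]]$meta$species <-
      ifelse(tr$frames[[i]]$meta$lipid_id %% 2 == 0, "DOPC", "POPC")
  }
  asg <- suppressWarnings(assign_leaflets(tr))
  est <- suppressWarnings(estimate_rsf(tr, asg, patch_radius = 2.8))
  expect_equal(nrow(est$pair_moduli), 3)
  expect_setequal(est$pair_moduli$pair, c("DOPC:DOPC", "DOPC:POPC", "POPC:POPC"))
  expect_gte(est$K_c_monolayer, min(est$pair_moduli$chi))
  expect_lte(est$K_c_monolayer, max(est$pair_moduli$chi))
})
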