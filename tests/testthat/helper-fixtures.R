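# Shared fixture builders. Everything is generated in code; no data files.

# A hand-built bilayer frame: heads at z0 +- d/2 (+ optional per-lipid head
# z offsets), tails tail_len below/above the head along z. Lipids are laid
# out on a jittered-free square lattice per leaflet.
make_bilayer_frame <- function(n_per_leaflet = 4, L = 10, Lz = 20, d = 4,
                               z_offsets = NULL, tail_len = 1.5,
                               species = "SYNT", time = 0) {
  m <- ceiling(sqrt(n_per_leaflet))
  g <- expand.grid(ix = 0:(m - 1), iy = 0:(m - 1))[seq_len(n_per_leaflet), ]
  xy <- cbind((g$ix + 0.5) * L / m, (g$iy + 0.5) * L / m)
  if (is.null(z_offsets)) z_offsets <- numeric(2 * n_per_leaflet)
  pos <- NULL
  for (side in c(1, -1)) {
    off <- z_offsets[if (side == 1) seq_len(n_per_leaflet) else
      n_per_leaflet + seq_len(n_per_leaflet)]
    zh <- Lz / 2 + side * d / 2 + off
    heads <- cbind(xy, zh)
    tails <- cbind(xy, zh - side * tail_len)
    block <- matrix(0, 2 * n_per_leaflet, 3)
    block[seq(1, 2 * n_per_leaflet, 2), ] <- heads
    block[seq(2, 2 * n_per_leaflet, 2), ] <- tails
    pos <- rbind(pos, block)
  }
  n <- 2 * n_per_leaflet
  meta <- data.frame(
    lipid_id = rep(seq_len(n), each = 2),
    species = species,
    role = rep(c("head", "tail_terminal"), n),
    stringsAsFactors = FALSE
  )
  bead_frame(pos, c(L, L, Lz), time = time, meta = meta)
}

# Frame whose pooled head field follows z(x, y) on dense uniform lattices
# (identical field on both leaflets), for spectral oracles.
make_field_frame <- function(field_fun, m = 16, L = 10, Lz = 20, d = 4) {
  g <- expand.grid(ix = 0:(m - 1), iy = 0:(m - 1))
  xy <- cbind(g$ix * L / m, g$iy * L / m)
  z <- field_fun(xy[, 1], xy[, 2])
  n <- nrow(xy)
  pos <- NULL
  for (side in c(1, -1)) {
    zh <- Lz / 2 + side * d / 2 + z
    block <- matrix(0, 2 * n, 3)
    block[seq(1, 2 * n, 2), ] <- cbind(xy, zh)
    block[seq(2, 2 * n, 2), ] <- cbind(xy, zh - side * 1.5)
    pos <- rbind(pos, block)
  }
  meta <- data.frame(
    lipid_id = rep(seq_len(2 * n), each = 2),
    species = "SYNT",
    role = rep(c("head", "tail_terminal"), 2 * n),
    stringsAsFactors = FALSE
  )
  bead_frame(pos, c(L, L, Lz), meta = meta)
}

# Small synthetic ensembles used by several files (cached per session).
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- synth_params(L = 20, n_lipids_leaflet = 256, kappa = 30,
        n_frames = 120, seed = 421)
      tr <- generate_trajectory(p)
      cache <<- list(params = p, traj = tr,
        assignment = suppressWarnings(assign_leaflets(tr)))
    }
    cache
  }
})

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol * abs(expected))
}
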