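# Real-space splay fluctuation estimator: lipid directors, local interface
# normals, neighbor pairs, pairwise splay, Boltzmann inversion.

#' Lipid tilt directors
#'
#' The director is the unit vector from the centroid of a lipid's terminal
#' tail beads to its head bead, flipped if necessary so it points away from
#' the bilayer midplane (top-leaflet directors have positive z against the
#' outward normal, bottom negative).
#'
#' @param frame a [bead_frame()].
#' @param assignment a [assign_leaflets()] result.
#' @return data.frame of class `lipid_directors`: `lipid_id`, `species`,
#'   `leaflet`, head position `px`, `py`, director `nx`, `ny`, `nz`.
#' @export
compute_directors <- function(frame, assignment) {
  meta <- frame$meta
  hidx <- head_table(frame)
  ids <- sort(unique(meta$lipid_id))
  tails <- split(which(meta$role == "tail_terminal"), meta$lipid_id[meta$role == "tail_terminal"])
  tails <- tails[as.character(ids)]
  tc <- t(vapply(tails, function(i) {
    colMeans(frame$positions[i, , drop = FALSE])
  }, numeric(3)))
  hp <- frame$positions[hidx, , drop = FALSE]
  # head and tail may sit in different periodic images; take the minimum image
  d <- hp - tc
  d[, 1] <- min_image(d[, 1], frame$box[1])
  d[, 2] <- min_image(d[, 2], frame$box[2])
  d[, 3] <- min_image(d[, 3], frame$box[3])
  nrm <- sqrt(rowSums(d^2))
  if (any(nrm < 1e-12)) {
    stop_memflex("degenerate lipid: zero-length director for lipid %s",
      ids[which(nrm < 1e-12)[1]], class = "memflex_degenerate_error")
  }
  n <- d / nrm
  leaf <- assignment$leaflet[as.character(ids)]
  flip <- ifelse(leaf == "top", 1, -1) * n[, 3] < 0
  n[flip, ] <- -n[flip, ]
  structure(
    data.frame(
      lipid_id = ids,
      species = meta$species[hidx],
      leaflet = unname(leaf),
      px = hp[, 1], py = hp[, 2],
      nx = n[, 1], ny = n[, 2], nz = n[, 3],
      stringsAsFactors = FALSE
    ),
    class = c("lipid_directors", "data.frame")
  )
}

#' Local interface normals
#'
#' For each lipid, a least-squares plane is fitted to the same-leaflet head
#' beads within `patch_radius` (minimum-image lateral metric, the lipid
#' itself included); the plane normal is oriented away from the midplane.
#' Lipids with fewer than 3 patch members (or a degenerate patch) fall back
#' to the global leaflet normal `(0, 0, +-1)` with a single warning.
#'
#' @param frame a [bead_frame()].
#' @param assignment a [assign_leaflets()] result.
#' @param patch_radius nm.
#' @return data.frame with `lipid_id`, `Nx`, `Ny`, `Nz`.
#' @export
local_normals <- function(frame, assignment, patch_radius = 1.5) {
  ids <- sort(unique(frame$meta$lipid_id))
  out <- matrix(0, length(ids), 3)
  fell_back <- 0L
  for (leaf in c("top", "bottom")) {
    idx <- leaflet_heads(frame, assignment, leaf)
    rows <- which(assignment$leaflet[as.character(ids)] == leaf)
    P <- frame$positions[idx, , drop = FALSE]
    sgn <- if (leaf == "top") 1 else -1
    for (k in seq_along(rows)) {
      dx <- min_image(P[, 1] - P[k, 1], frame$box[1])
      dy <- min_image(P[, 2] - P[k, 2], frame$box[2])
      inp <- which(dx * dx + dy * dy <= patch_radius^2)
      N <- c(0, 0, sgn)
      if (length(inp) >= 3) {
        X <- cbind(1, dx[inp], dy[inp])
        M <- crossprod(X)
        if (abs(det(M)) > 1e-12) {
          ab <- solve(M, crossprod(X, P[inp, 3]))
          N <- c(-ab[2], -ab[3], 1) * sgn
          N <- N / sqrt(sum(N^2))
        } else fell_back <- fell_back + 1L
      } else fell_back <- fell_back + 1L
      out[rows[k], ] <- N
    }
  }
  if (fell_back > 0) {
    warning(sprintf("%d lipid(s) lacked >= 3 patch neighbors; global leaflet normal used",
      fell_back), call. = FALSE)
  }
  data.frame(lipid_id = ids, Nx = out[, 1], Ny = out[, 2], Nz = out[, 3])
}

#' Same-leaflet neighbor pairs
#'
#' Unordered head-bead pairs with minimum-image lateral separation at most
#' `cutoff`, each pair listed once.
#'
#' @param frame a [bead_frame()].
#' @param assignment a [assign_leaflets()] result.
#' @param cutoff nm.
#' @return data.frame with `i`, `j` (lipid ids, `i < j` by id order),
#'   `dx`, `dy` (minimum-image separation j - i) and `dist`.
#' @export
neighbor_pairs <- function(frame, assignment, cutoff = 1.2) {
  stopifnot(cutoff > 0)
  res <- list()
  for (leaf in c("top", "bottom")) {
    idx <- leaflet_heads(frame, assignment, leaf)
    ids <- sort(unique(frame$meta$lipid_id))
    ids <- ids[assignment$leaflet[as.character(ids)] == leaf]
    P <- frame$positions[idx, 1:2, drop = FALSE]
    n <- nrow(P)
    if (n < 2) next
    dx <- min_image(outer(P[, 1], P[, 1], `-`), frame$box[1])
    dy <- min_image(outer(P[, 2], P[, 2], `-`), frame$box[2])
    d2 <- dx * dx + dy * dy
    sel <- which(upper.tri(d2) & d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(sel) == 0) next
    res[[leaf]] <- data.frame(
      i = ids[sel[, 1]], j = ids[sel[, 2]],
      dx = dx[sel] * -1, dy = dy[sel] * -1, # j - i
      dist = sqrt(d2[sel]), leaflet = leaf,
      stringsAsFactors = FALSE
    )
  }
  if (length(res) == 0) {
    return(data.frame(i = integer(), j = integer(), dx = numeric(),
      dy = numeric(), dist = numeric(), leaflet = character()))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pairwise splay of two lipids
#'
#' Two-point finite-difference projection along the pair separation:
#' \deqn{S_t = \frac{(n_B - n_A)\cdot e_1 - (N_B - N_A)\cdot e_1}{h}}
#' with \eqn{e_1} the unit lateral separation vector and `h` the lateral
#' distance. Directors and normals enter through their lateral components
#' (the fields are two-dimensional). `convention = "sum"` selects the
#' literal printed finite-difference assembly in which the director and
#' normal increments add instead of subtract.
#'
#' @param n_a,n_b director 3-vectors of lipids A and B.
#' @param N_a,N_b local interface normal 3-vectors.
#' @param sep lateral separation vector B - A (length-2, minimum image).
#' @param convention `"difference"` (consistent with the splay free energy,
#'   default) or `"sum"`.
#' @return splay `S_t` in nm^-1.
#' @export
pair_splay <- function(n_a, n_b, N_a, N_b, sep,
                       convention = c("difference", "sum")) {
  convention <- match.arg(convention)
  h <- sqrt(sum(sep^2))
  if (h < 1e-6) {
    stop_memflex("coincident pair: lateral separation below 1e-6 nm",
      class = "memflex_degenerate_error")
  }
  e <- sep / h
  dn <- (n_b[1:2] - n_a[1:2]) %*% e
  dN <- (N_b[1:2] - N_a[1:2]) %*% e
  as.numeric(if (convention == "difference") (dn - dN) / h else (dn + dN) / h)
}

#' Collect splay samples from a frame or trajectory
#'
#' Runs [compute_directors()], [local_normals()] and [neighbor_pairs()] and
#' evaluates the pairwise splay for every neighbor pair.
#'
#' @param x a [bead_frame()] or [trajectory()].
#' @param assignment a [assign_leaflets()] result.
#' @param cutoff neighbor cutoff (nm).
#' @param patch_radius plane-fit patch radius (nm).
#' @param convention see [pair_splay()].
#' @param ... unused.
#' @return data.frame with `S` (nm^-1), `species_i`, `species_j`, `pair`
#'   (canonical species-pair tag) and `dist`.
#' @export
splay_samples <- function(x, assignment, cutoff = 1.2, patch_radius = 1.5,
                          convention = "difference", ...) {
  UseMethod("splay_samples")
}

#' @rdname splay_samples
#' @export
splay_samples.bead_frame <- function(x, assignment, cutoff = 1.2,
                                     patch_radius = 1.5,
                                     convention = "difference", ...) {
  dir <- compute_directors(x, assignment)
  nor <- local_normals(x, assignment, patch_radius)
  pairs <- neighbor_pairs(x, assignment, cutoff)
  if (nrow(pairs) == 0) {
    return(data.frame(S = numeric(), species_i = character(),
      species_j = character(), pair = character(), dist = numeric()))
  }
  key <- match(pairs$i, dir$lipid_id)
  kej <- match(pairs$j, dir$lipid_id)
  h <- pairs$dist
  ex <- pairs$dx / h
  ey <- pairs$dy / h
  dnx <- dir$nx[kej] - dir$nx[key]
  dny <- dir$ny[kej] - dir$ny[key]
  dNx <- nor$Nx[kej] - nor$Nx[key]
  dNy <- nor$Ny[kej] - nor$Ny[key]
  sgn <- if (identical(convention, "sum")) 1 else -1
  S <- ((dnx * ex + dny * ey) + sgn * (dNx * ex + dNy * ey)) / h
  spi <- dir$species[key]
  spj <- dir$species[kej]
  data.frame(
    S = S, species_i = spi, species_j = spj,
    pair = paste(pmin(spi, spj), pmax(spi, spj), sep = ":"),
    dist = h, stringsAsFactors = FALSE
  )
}

#' @rdname splay_samples
#' @export
splay_samples.md_trajectory <- function(x, assignment, cutoff = 1.2,
                                        patch_radius = 1.5,
                                        convention = "difference", ...) {
  out <- lapply(x$frames, splay_samples, assignment = assignment,
    cutoff = cutoff, patch_radius = patch_radius, convention = convention)
  do.call(rbind, out)
}

#' Histogram of splay samples with the Boltzmann energy curve
#'
#' `P(S_t)` is the density-normalized histogram (`sum(P) * bin = 1`); the
#' energy curve is \eqn{-(2 k_BT / A_l)\ln P(S_t)} in k_BT units. Bins with
#' fewer than `min_count` samples are excluded from the fit window.
#'
#' @param S numeric splay samples (nm^-1) or a [splay_samples()] table.
#' @param A_l lipid area (nm^2).
#' @param bins number of bins (default 101 over mean +- 4 SD).
#' @param min_count fit-window occupancy threshold.
#' @return object of class `splay_distribution`.
#' @export
splay_distribution <- function(S, A_l, bins = 101, min_count = 10) {
  if (is.data.frame(S)) S <- S$S
  if (length(S) == 0 || all(S == S[1])) {
    stop_memflex("degenerate splay sample set (empty or constant)",
      class = "memflex_fit_error")
  }
  ctr <- mean(S); sdv <- sd(S)
  breaks <- seq(ctr - 4 * sdv, ctr + 4 * sdv, length.out = bins + 1)
  keep <- S >= breaks[1] & S <= breaks[length(breaks)]
  counts <- tabulate(findInterval(S[keep], breaks, rightmost.closed = TRUE),
    nbins = bins)
  bw <- breaks[2] - breaks[1]
  P <- counts / (sum(counts) * bw)
  mids <- breaks[-1] - bw / 2
  occupied <- counts >= min_count
  structure(
    list(
      mids = mids, counts = counts, P = P, bin_width = bw,
      A_l = A_l, n = length(S),
      energy = ifelse(P > 0, -(2 / A_l) * log(P), NA_real_),
      fit_window = occupied
    ),
    class = "splay_distribution"
  )
}

#' @export
print.splay_distribution <- function(x, ...) {
  cat(sprintf("<splay_distribution> %d samples in %d bins (%d in fit window), A_l = %.3g nm^2\n",
    x$n, length(x$mids), sum(x$fit_window), x$A_l))
  invisible(x)
}

#' Boltzmann inversion of the splay distribution
#'
#' Quadratic least squares of the energy curve
#' \eqn{-(2k_BT/A_l)\ln P(S_t) = c_0 + c_1 S_t + K_c S_t^2} over the
#' occupied fit window (the intercept absorbs the normalization constant,
#' the linear term any residual asymmetry). The monolayer splay modulus is
#' the quadratic coefficient; the bilayer bending modulus is exactly twice
#' it.
#'
#' @param dist a [splay_distribution()].
#' @param temperature K.
#' @return a [modulus_estimate()] with `kappa = 2 K_c` (bilayer),
#'   `K_c_monolayer` and the fit standard errors.
#' @export
fit_splay_modulus <- function(dist, temperature = 310) {
  sel <- dist$fit_window & is.finite(dist$energy)
  if (sum(sel) < 5) {
    stop_memflex("splay histogram has %d usable bins (need >= 5)", sum(sel),
      class = "memflex_fit_error")
  }
  df <- data.frame(S = dist$mids[sel], E = dist$energy[sel],
    w = dist$counts[sel])
  fit <- lm(E ~ S + I(S^2), data = df, weights = df$w)
  Kc <- unname(coef(fit)[3])
  if (!is.finite(Kc) || Kc <= 0) {
    stop_memflex("non-positive curvature in the splay energy fit (K_c = %.3g)",
      Kc, class = "memflex_fit_error")
  }
  se <- suppressWarnings(summary(fit))$coefficients[3, 2]
  modulus_estimate(
    method = "rsf", kappa = 2 * Kc, se = 2 * se, temperature = temperature,
    K_c_monolayer = Kc, K_c_se = se,
    variance_oracle_K_c = 1 / (dist$A_l * weighted_var(dist))
  )
}

# sample variance implied by the histogram (moment route used as the
# internal cross-check of the Boltzmann inversion)
weighted_var <- function(dist) {
  w <- dist$counts / sum(dist$counts)
  m <- sum(w * dist$mids)
  sum(w * (dist$mids - m)^2)
}

#' Combine per-species-pair splay moduli
#'
#' Pair-count-weighted harmonic-style combination
#' \eqn{1/K_c = \frac{1}{\phi_{total}} \sum_{ij} \phi_{ij}/\chi_{ij}}.
#'
#' @param phi named numeric vector of pair counts \eqn{\phi_{ij}}.
#' @param chi numeric vector of pair splay moduli \eqn{\chi_{ij}} (k_BT),
#'   same order/names.
#' @return combined monolayer splay modulus `K_c` (k_BT); always lies
#'   between `min(chi)` and `max(chi)`.
#' @export
combine_pair_moduli <- function(phi, chi) {
  stopifnot(length(phi) == length(chi), all(phi >= 0), sum(phi) > 0)
  if (any(chi <= 0)) {
    stop_memflex("all pair moduli must be positive", class = "memflex_param_error")
  }
  sum(phi) / sum(phi / chi)
}

#' One-call RSF bending-modulus estimate
#'
#' Collects splay samples over the trajectory; with a single species (or
#' `per_species = FALSE`) all pairs are pooled into one Boltzmann inversion,
#' otherwise each species pair is inverted separately and combined with
#' [combine_pair_moduli()]. `A_l` defaults to the trajectory's
#' [area_per_lipid()].
#'
#' @param traj a [trajectory()].
#' @param assignment a [assign_leaflets()] result.
#' @param cutoff,patch_radius,convention see [splay_samples()].
#' @param A_l lipid area (nm^2), computed from the trajectory when `NULL`.
#' @param bins histogram bins.
#' @param per_species fit per species pair before combining.
#' @return a [modulus_estimate()] (bilayer `kappa = 2 K_c`); the pooled
#'   sample count and per-pair table are attached.
#' @export
estimate_rsf <- function(traj, assignment, cutoff = 1.2, patch_radius = 1.5,
                         convention = "difference", A_l = NULL, bins = 101,
                         per_species = TRUE) {
  if (is.null(A_l)) A_l <- area_per_lipid(traj, assignment)$value
  samp <- splay_samples(traj, assignment, cutoff = cutoff,
    patch_radius = patch_radius, convention = convention)
  if (nrow(samp) == 0) {
    stop_memflex("no neighbor pairs found (cutoff %.3g nm)", cutoff,
      class = "memflex_empty_error")
  }
  pairs <- table(samp$pair)
  if (!per_species || length(pairs) == 1) {
    est <- fit_splay_modulus(splay_distribution(samp$S, A_l, bins),
      temperature = traj$temperature)
    est$n_samples <- nrow(samp)
    est$A_l <- A_l
    return(est)
  }
  chi <- vapply(names(pairs), function(p) {
    fit_splay_modulus(splay_distribution(samp$S[samp$pair == p], A_l, bins),
      temperature = traj$temperature)$K_c_monolayer
  }, numeric(1))
  Kc <- combine_pair_moduli(as.numeric(pairs), chi)
  est <- modulus_estimate(method = "rsf", kappa = 2 * Kc,
    temperature = traj$temperature, K_c_monolayer = Kc)
  est$pair_moduli <- data.frame(pair = names(pairs),
    phi = as.numeric(pairs), chi = chi, row.names = NULL)
  est$n_samples <- nrow(samp)
  est$A_l <- A_l
  est
}
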