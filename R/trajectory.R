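#' Construct a single bead frame
#'
#' A frame holds wrapped bead positions, the periodic box and per-bead
#' metadata (lipid id, species tag and bead role). Roles follow the
#' coarse-grained bilayer convention: one `"head"` bead per lipid marks the
#' water-membrane interface, `"tail_terminal"` beads mark chain ends used for
#' tilt directors, everything else is `"other"`.
#'
#' @param positions numeric N x 3 matrix of bead coordinates (nm). Wrapped
#'   into `[0, L)` per axis on construction.
#' @param box numeric length-3 box vector `(L_x, L_y, L_z)` (nm).
#' @param time frame time (ps).
#' @param meta data.frame with columns `lipid_id` (integer), `species`
#'   (character) and `role` (one of `"head"`, `"tail"`, `"tail_terminal"`,
#'   `"other"`), one row per bead.
#' @param validate check invariants (every lipid has exactly one head and at
#'   least one terminal tail bead). Skipped internally for generated frames.
#' @return object of class `bead_frame`.
#' @export
bead_frame <- function(positions, box, time = 0, meta, validate = TRUE) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  dimnames(positions) <- NULL
  box <- as.numeric(box)
  stopifnot(ncol(positions) == 3, length(box) == 3, all(box > 0))
  if (nrow(meta) != nrow(positions)) {
    stop_memflex("meta has %d rows for %d beads", nrow(meta), nrow(positions),
      class = "memflex_meta_error")
  }
  fr <- structure(
    list(
      positions = wrap_positions(positions, box),
      box = box, time = as.numeric(time), meta = meta
    ),
    class = "bead_frame"
  )
  if (validate) validate_frame(fr)
  fr
}

validate_frame <- function(frame) {
  meta <- frame$meta
  heads <- tapply(meta$role == "head", meta$lipid_id, sum)
  if (any(heads != 1)) {
    bad <- names(heads)[heads != 1][1]
    stop_memflex("lipid %s has %d head beads under the selector (need exactly 1)",
      bad, heads[[bad]], class = "memflex_selector_error")
  }
  tails <- tapply(meta$role == "tail_terminal", meta$lipid_id, sum)
  if (any(tails < 1)) {
    bad <- names(tails)[tails < 1][1]
    stop_memflex("lipid %s has no tail_terminal bead under the selector",
      bad, class = "memflex_selector_error")
  }
  invisible(frame)
}

#' Construct a trajectory from a list of frames
#'
#' @param frames list of [bead_frame()] objects with identical bead count and
#'   ordering.
#' @param temperature simulation temperature (K).
#' @param dt time between stored frames (ps).
#' @param provenance list describing the origin; `origin` is `"real"` or
#'   `"synthetic"`, synthetic trajectories carry generator parameters and the
#'   ground-truth record.
#' @return object of class `md_trajectory`.
#' @export
trajectory <- function(frames, temperature = 310, dt = NULL,
                       provenance = list(origin = "real")) {
  if (length(frames) == 0) {
    stop_memflex("trajectory has no frames", class = "memflex_empty_error")
  }
  n <- vapply(frames, function(f) nrow(f$positions), integer(1))
  if (length(unique(n)) != 1) {
    stop_memflex("bead count varies across frames", class = "memflex_frame_error")
  }
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop_memflex("frame times are not strictly increasing", class = "memflex_frame_error")
  }
  if (is.null(dt)) dt <- if (length(times) > 1) times[2] - times[1] else 1
  structure(
    list(
      frames = frames, temperature = temperature, dt = dt,
      provenance = provenance, com_removed = isTRUE(provenance$com_removed)
    ),
    class = "md_trajectory"
  )
}

#' @export
print.md_trajectory <- function(x, ...) {
  f1 <- x$frames[[1]]
  cat(sprintf(
    "<md_trajectory> %d frames, %d beads, %d lipids\n  box %.3g x %.3g x %.3g nm, T = %g K, dt = %g ps, origin: %s%s\n",
    length(x$frames), nrow(f1$positions), length(unique(f1$meta$lipid_id)),
    f1$box[1], f1$box[2], f1$box[3], x$temperature, x$dt,
    x$provenance$origin %||% "real",
    if (x$com_removed) " (COM removed)" else ""
  ))
  invisible(x)
}

#' @export
print.bead_frame <- function(x, ...) {
  cat(sprintf("<bead_frame> %d beads, box %.3g x %.3g x %.3g nm, t = %g ps\n",
    nrow(x$positions), x$box[1], x$box[2], x$box[3], x$time))
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

head_indices <- function(frame) which(frame$meta$role == "head")

# Head-bead rows ordered by lipid_id (one per lipid).
head_table <- function(frame) {
  idx <- head_indices(frame)
  idx[order(frame$meta$lipid_id[idx])]
}

#' Assign lipids to leaflets
#'
#' The membrane midplane is the mean z of all head beads; a lipid belongs to
#' the top leaflet iff its head bead lies above the midplane. For a
#' trajectory the assignment is computed on the first frame and held fixed
#' (head-group flip-flop is not modeled); if a head later crosses the
#' instantaneous midplane by more than `flip_tol` a warning is emitted.
#'
#' @param x a [bead_frame()] or [trajectory()].
#' @param flip_tol distance (nm) beyond the midplane a head may stray before
#'   it counts as crossed in a frame; defaults to a quarter of the apparent
#'   bilayer thickness. A flip-flop warning is emitted for lipids crossed in
#'   the majority of frames (transient undulation bumps are not flips).
#' @param local_refine refine the global-midplane rule by comparing each
#'   head to the mean z of laterally nearby heads (default `TRUE`). With
#'   undulation amplitudes approaching d/2 the global rule mislabels lipids
#'   riding extreme bumps; the local reference tracks the membrane height.
#' @param ... unused.
#' @return object of class `leaflet_assignment`: per-lipid labels
#'   (`"top"`/`"bottom"` named by lipid id), per-frame midplane z (nm), and
#'   the head selector used.
#' @export
assign_leaflets <- function(x, ...) UseMethod("assign_leaflets")

#' @rdname assign_leaflets
#' @export
assign_leaflets.bead_frame <- function(x, local_refine = TRUE, ...) {
  idx <- head_table(x)
  if (length(idx) < 2) {
    stop_memflex("need at least 2 lipids to assign leaflets",
      class = "memflex_degenerate_error")
  }
  z <- x$positions[idx, 3]
  mid <- mean(z)
  lab <- ifelse(z > mid, "top", "bottom")
  if (local_refine && length(idx) >= 16) {
    # compare each head to the mean z of heads within a few lattice
    # spacings (both leaflets pooled approximates the local mid-surface)
    r2 <- 9 * x$box[1] * x$box[2] / (length(idx) / 2)
    P <- x$positions[idx, , drop = FALSE]
    for (k in seq_along(idx)) {
      dx <- min_image(P[, 1] - P[k, 1], x$box[1])
      dy <- min_image(P[, 2] - P[k, 2], x$box[2])
      nb <- dx * dx + dy * dy <= r2
      if (sum(nb) >= 8) lab[k] <- if (z[k] > mean(z[nb])) "top" else "bottom"
    }
  }
  if (length(unique(lab)) < 2) {
    stop_memflex("degenerate bilayer: all head beads on one side of the midplane",
      class = "memflex_degenerate_error")
  }
  structure(
    list(
      leaflet = setNames(lab, sort(unique(x$meta$lipid_id))),
      midplane = mid, head_selector = "role == 'head'"
    ),
    class = "leaflet_assignment"
  )
}

#' @rdname assign_leaflets
#' @export
assign_leaflets.md_trajectory <- function(x, flip_tol = NULL,
                                          local_refine = TRUE, ...) {
  asg <- assign_leaflets(x$frames[[1]], local_refine = local_refine)
  idx <- head_table(x$frames[[1]])
  mids <- vapply(x$frames, function(f) mean(f$positions[idx, 3]), numeric(1))
  asg$midplane <- mids
  dhalf <- abs(diff(vapply(split(
    x$frames[[1]]$positions[idx, 3], asg$leaflet), mean, numeric(1)))) / 2
  if (is.null(flip_tol)) flip_tol <- dhalf / 2 # d/4
  top <- asg$leaflet == "top"
  crossed <- numeric(length(idx))
  for (i in seq_along(x$frames)) {
    z <- x$frames[[i]]$positions[idx, 3] - mids[i]
    crossed <- crossed + (ifelse(top, -z, z) > flip_tol)
  }
  persistent <- sum(crossed > length(x$frames) / 2)
  if (persistent > 0) {
    warning(sprintf(
      "%d lipid(s) sit > %.3g nm beyond the instantaneous midplane in most frames; flip-flop is not modeled",
      persistent, flip_tol), call. = FALSE)
  }
  asg
}

#' @export
print.leaflet_assignment <- function(x, ...) {
  cat(sprintf("<leaflet_assignment> %d top / %d bottom lipids, midplane z ~ %.3g nm\n",
    sum(x$leaflet == "top"), sum(x$leaflet == "bottom"), mean(x$midplane)))
  invisible(x)
}

# Indices (into frame rows) of head beads in a given leaflet, ordered by lipid id.
leaflet_heads <- function(frame, assignment, leaflet) {
  idx <- head_table(frame)
  idx[assignment$leaflet[as.character(sort(unique(frame$meta$lipid_id)))] == leaflet]
}

#' Remove lateral center-of-mass motion
#'
#' Subtracts the accumulated lateral center-of-mass drift (z is untouched)
#' so that every frame's lateral centroid coincides with the first frame's.
#' The drift is accumulated from per-frame mean minimum-image displacements,
#' not from the wrapped centroid directly: with periodic coordinates the
#' naive mean jumps every time a bead crosses the boundary, which would
#' inject spurious common motion into diffusion estimates. Idempotent;
#' preserves all pairwise lateral distances.
#'
#' @param traj a [trajectory()].
#' @return the trajectory with lateral COM motion removed and flagged
#'   `com_removed`.
#' @export
remove_com_motion <- function(traj) {
  box <- traj$frames[[1]]$box
  prev <- traj$frames[[1]]$positions[, 1:2, drop = FALSE]
  drift <- c(0, 0)
  for (i in seq_along(traj$frames)) {
    cur <- traj$frames[[i]]$positions[, 1:2, drop = FALSE]
    if (i > 1) {
      drift <- drift + c(
        mean(min_image(cur[, 1] - prev[, 1], box[1])),
        mean(min_image(cur[, 2] - prev[, 2], box[2])))
    }
    prev <- cur
    traj$frames[[i]]$positions[, 1] <- cur[, 1] - drift[1]
    traj$frames[[i]]$positions[, 2] <- cur[, 2] - drift[2]
  }
  traj$com_removed <- TRUE
  traj$provenance$com_removed <- TRUE
  traj
}
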