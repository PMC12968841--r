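# Internal geometry helpers shared across modules.

# Wrap coordinates into [0, L) per axis. `x` is an N x 3 matrix, `box` a
# length-3 vector.
wrap_positions <- function(x, box) {
  for (k in 1:3) x[, k] <- x[, k] - box[k] * floor(x[, k] / box[k])
  x
}

# Minimum-image difference a - b along one periodic axis.
min_image <- function(d, L) d - L * round(d / L)

# Lateral (x, y) minimum-image displacement matrix rows a - b.
min_image_xy <- function(d, box) {
  d[, 1] <- min_image(d[, 1], box[1])
  d[, 2] <- min_image(d[, 2], box[2])
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_memflex <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "memflex_error")))
}

assert_square_box <- function(box) {
  if (!isTRUE(all.equal(box[1], box[2], tolerance = 1e-9))) {
    stop_memflex(
      "square lateral cell required (L_x = %.6g, L_y = %.6g nm)",
      box[1], box[2],
      class = "memflex_box_error"
    )
  }
  invisible(box)
}
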