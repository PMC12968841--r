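# Trajectory input/output.
#
# Two on-disk forms are supported:
#  * GRO coordinate files (fixed-width GROMACS format), including
#    multi-frame "trajectory" GRO files produced by trjconv;
#  * the package's plain-text dialect: <stem>.csv holding the long position
#    table (frame, time, bead, lipid_id, species, role, x, y, z) and
#    <stem>.json holding box vectors, temperature, dt and provenance.

#' Default bead selectors
#'
#' Maps species tags to the bead names defining the head (interface) bead and
#' the terminal tail beads. The default covers common MARTINI lipids: the
#' phosphate bead `PO4` is the head, and tail beads whose names match
#' `C<k><chain>`/`D<k><chain>` with the largest `k` per chain are terminal.
#' Species not listed fall back to `.default`; set `.default = NULL` to make
#' unknown species an error.
#'
#' @param ... named per-species overrides, each a
#'   `list(head = <names>, tail_terminal = <names or NULL>)`. `NULL`
#'   `tail_terminal` means "detect by chain-end pattern".
#' @return named list of selectors.
#' @export
default_selectors <- function(...) {
  over <- list(...)
  base <- list(.default = list(head = "PO4", tail_terminal = NULL))
  base[names(over)] <- over
  base
}

solvent_species <- c("W", "WF", "PW", "ION", "NA+", "CL-", "NA", "CL")

# Assign roles from atom/residue names using the selectors.
assign_roles <- function(atom, species, selectors) {
  role <- rep("other", length(atom))
  for (sp in unique(species)) {
    sel <- selectors[[sp]] %||% selectors$.default
    if (is.null(sel)) {
      stop_memflex("unknown species tag '%s' and no .default selector", sp,
        class = "memflex_selector_error")
    }
    rows <- which(species == sp)
    role[rows][atom[rows] %in% sel$head] <- "head"
    if (!is.null(sel$tail_terminal)) {
      role[rows][atom[rows] %in% sel$tail_terminal] <- "tail_terminal"
    } else {
      # chain-end detection: tail beads C1A..C5B / D3A ... -> largest index per chain
      m <- regmatches(atom[rows], regexec("^[CD]([0-9]+)([A-D])$", atom[rows]))
      num <- vapply(m, function(g) if (length(g)) as.integer(g[2]) else NA_integer_, integer(1))
      chain <- vapply(m, function(g) if (length(g)) g[3] else NA_character_, character(1))
      for (ch in unique(chain[!is.na(chain)])) {
        in_ch <- !is.na(chain) & chain == ch
        role[rows][in_ch & num == max(num[in_ch])] <- "tail_terminal"
      }
    }
  }
  role
}

parse_gro_block <- function(lines, selectors, drop_species) {
  natoms <- as.integer(trimws(lines[2]))
  atoms <- lines[3:(2 + natoms)]
  boxline <- as.numeric(strsplit(trimws(lines[3 + natoms]), "\\s+")[[1]])
  resid <- as.integer(substr(atoms, 1, 5))
  resname <- trimws(substr(atoms, 6, 10))
  atname <- trimws(substr(atoms, 11, 15))
  x <- as.numeric(substr(atoms, 21, 28))
  y <- as.numeric(substr(atoms, 29, 36))
  z <- as.numeric(substr(atoms, 37, 44))
  keep <- !(resname %in% drop_species)
  tmatch <- regmatches(lines[1], regexec("t=\\s*([0-9.eE+-]+)", lines[1]))[[1]]
  list(
    time = if (length(tmatch) == 2) as.numeric(tmatch[2]) else NA_real_,
    positions = cbind(x, y, z)[keep, , drop = FALSE],
    box = boxline[1:3],
    lipid_id = resid[keep], species = resname[keep], atom = atname[keep]
  )
}

#' Read a trajectory from disk
#'
#' Accepts either a GRO coordinate file (optionally with a multi-frame GRO
#' trajectory file alongside) or the stem of the package's plain-text dialect
#' (`<stem>.csv` + `<stem>.json`, as written by [write_trajectory()]).
#'
#' @param coordinate_path path to a `.gro` file or a dialect stem/`.csv`.
#' @param trajectory_path optional multi-frame `.gro` trajectory whose frames
#'   replace the single coordinate frame.
#' @param selectors bead selectors, see [default_selectors()].
#' @param temperature temperature metadata (K); dialect files carry their own.
#' @param dt frame spacing (ps) used when frames carry no time stamps.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(coordinate_path, trajectory_path = NULL,
                            selectors = default_selectors(),
                            temperature = 310, dt = 1) {
  stem <- sub("\\.(csv|json)$", "", coordinate_path)
  if (file.exists(paste0(stem, ".json")) && !grepl("\\.gro$", coordinate_path)) {
    return(read_trajectory_dialect(stem))
  }
  if (!file.exists(coordinate_path)) {
    stop_memflex("coordinate file '%s' does not exist", coordinate_path,
      class = "memflex_io_error")
  }
  path <- trajectory_path %||% coordinate_path
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) ) { i <- i + 1; next }
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1])))
    if (is.na(natoms)) stop_memflex("malformed GRO block at line %d", i,
      class = "memflex_io_error")
    blk <- parse_gro_block(lines[i:(i + 2 + natoms)], selectors, solvent_species)
    role <- assign_roles(blk$atom, blk$species, selectors)
    meta <- data.frame(
      lipid_id = blk$lipid_id, species = blk$species, role = role,
      stringsAsFactors = FALSE
    )
    tm <- if (is.na(blk$time)) (length(frames)) * dt else blk$time
    frames[[length(frames) + 1]] <-
      bead_frame(blk$positions, blk$box, time = tm, meta = meta)
    i <- i + 3 + natoms
  }
  if (length(frames) == 0) {
    stop_memflex("no frames found in '%s'", path, class = "memflex_empty_error")
  }
  trajectory(frames, temperature = temperature, dt = dt,
    provenance = list(origin = "real", source = path))
}

#' Write a frame as a GRO file
#'
#' @param frame a [bead_frame()].
#' @param path output path.
#' @param title header line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(frame, path, title = "memflex frame") {
  meta <- frame$meta
  n <- nrow(frame$positions)
  atom <- ifelse(meta$role == "head", "PO4",
    ifelse(meta$role == "tail_terminal", "C4A", "GL1"))
  lines <- c(
    sprintf("%s, t= %.3f", title, frame$time),
    sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
      meta$lipid_id %% 100000L, substr(meta$species, 1, 5), atom,
      seq_len(n) %% 100000L,
      frame$positions[, 1], frame$positions[, 2], frame$positions[, 3]),
    sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2], frame$box[3])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a trajectory in the plain-text dialect
#'
#' Produces `<stem>.csv` (long position table, full double precision, so the
#' round trip through [read_trajectory()] is bitwise exact) and
#' `<stem>.json` (box, times, temperature, dt, provenance).
#'
#' @param traj a [trajectory()].
#' @param stem output path stem (no extension).
#' @return `stem`, invisibly.
#' @export
write_trajectory <- function(traj, stem) {
  f1 <- traj$frames[[1]]
  nb <- nrow(f1$positions)
  pos <- do.call(rbind, lapply(traj$frames, `[[`, "positions"))
  dt_tab <- data.table::data.table(
    frame = rep(seq_along(traj$frames), each = nb),
    bead = rep(seq_len(nb), n_frames(traj)),
    lipid_id = rep(f1$meta$lipid_id, n_frames(traj)),
    species = rep(f1$meta$species, n_frames(traj)),
    role = rep(f1$meta$role, n_frames(traj)),
    # %.17g guarantees a bitwise-exact numeric round trip through fread
    x = sprintf("%.17g", pos[, 1]), y = sprintf("%.17g", pos[, 2]),
    z = sprintf("%.17g", pos[, 3])
  )
  data.table::fwrite(dt_tab, paste0(stem, ".csv"))
  prov <- traj$provenance
  prov$params$splay_mode <- unclass(prov$params$splay_mode)
  jsonlite::write_json(
    list(
      format = "memflex-trajectory", version = 1L,
      temperature = traj$temperature, dt = traj$dt,
      com_removed = traj$com_removed,
      times = vapply(traj$frames, `[[`, numeric(1), "time"),
      box = do.call(rbind, lapply(traj$frames, `[[`, "box")),
      provenance = prov
    ),
    paste0(stem, ".json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(stem)
}

read_trajectory_dialect <- function(stem) {
  hdr <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  tab <- data.table::fread(paste0(stem, ".csv"))
  box <- matrix(as.numeric(hdr$box), ncol = 3)
  frames <- lapply(seq_along(hdr$times), function(i) {
    sub <- tab[tab$frame == i, ]
    bead_frame(
      cbind(sub$x, sub$y, sub$z), box[i, ], time = hdr$times[i],
      meta = data.frame(lipid_id = sub$lipid_id, species = sub$species,
        role = sub$role, stringsAsFactors = FALSE),
      validate = i == 1
    )
  })
  prov <- as.list(hdr$provenance %||% list(origin = "real"))
  prov$com_removed <- isTRUE(hdr$com_removed)
  trajectory(frames, temperature = hdr$temperature, dt = hdr$dt,
    provenance = prov)
}
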