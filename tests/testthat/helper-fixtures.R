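# Fixture builders shared across test files. All tracks are built in code;
# nothing is read from disk unless a test writes it first.

# A minimal straight track moving along +x at `speed_mm_frame` per frame.
make_straight_track <- function(n = 50, speed_mm_frame = 0.3, fps = 10,
                                L = 4, id = "t1", y0 = 10) {
  x <- 5 + speed_mm_frame * (0:(n - 1))
  fr <- tibble::tibble(frame = 0:(n - 1), x_mm = x, y_mm = y0)
  for (k in 0:4) {
    # head at +L/2 along x, tail at -L/2
    fr[[paste0("spine", k, "_x_mm")]] <- x + (2 - k) / 4 * L
    fr[[paste0("spine", k, "_y_mm")]] <- y0
  }
  fr$bending_deg <- 180
  fr$area_mm2 <- 2.4
  fr$spine_len_mm <- L
  larva_track(fr, id, fps)
}

# A track with prescribed per-frame positions and bending deviations.
make_track_from <- function(x, y, dev = NULL, fps = 10, L = 4, id = "t1") {
  n <- length(x)
  dev <- dev %||% rep(0, n)
  fr <- tibble::tibble(frame = 0:(n - 1), x_mm = x, y_mm = y)
  for (k in 0:4) {
    # straight spine placeholder; bending encoded via bending_deg
    fr[[paste0("spine", k, "_x_mm")]] <- x + (2 - k) / 4 * L
    fr[[paste0("spine", k, "_y_mm")]] <- y
  }
  fr$bending_deg <- 180 - dev
  fr$area_mm2 <- 2.4
  fr$spine_len_mm <- L
  larva_track(fr, id, fps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Section with n_ind individually wrapped axons, fascicle sizes given by
# `fascicles` (all wrapped), and n_naked axons in one unwrapped unit.
make_section <- function(n_ind, fascicles = integer(0), n_naked = 0,
                         area = 0.1, id = "n1") {
  units <- tibble::tibble(unit_id = character(), wrapped = logical())
  axons <- tibble::tibble(axon_id = character(), area_um2 = numeric(),
                          unit_id = character())
  add <- function(uid, n_ax, wrapped) {
    units <<- rbind(units, tibble::tibble(unit_id = uid, wrapped = wrapped))
    if (n_ax > 0) {
      axons <<- rbind(axons, tibble::tibble(
        axon_id = paste0(uid, "_", seq_len(n_ax)),
        area_um2 = area, unit_id = uid))
    }
  }
  for (i in seq_len(n_ind)) add(paste0("ind", i), 1L, TRUE)
  for (i in seq_along(fascicles)) add(paste0("fas", i), fascicles[i], TRUE)
  if (n_naked > 0) add("naked", n_naked, FALSE)
  nerve_section(id, axons, units)
}

# Exact set comparison of bout tables (kind/start/end, per larva).
bout_key <- function(b) {
  if (nrow(b) == 0L) return(character(0))
  id <- if ("larva_id" %in% names(b)) b$larva_id else ""
  sort(paste(id, b$kind, b$start_frame, b$end_frame))
}
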