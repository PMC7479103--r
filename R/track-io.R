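#' Write tracks in the long tracker CSV dialect
#'
#' One row per (larva_id, frame); columns `larva_id, frame, x_mm, y_mm,
#' spine<k>_x_mm, spine<k>_y_mm, ..., bending_deg, area_mm2, spine_len_mm`
#' in this fixed order. Numbers are serialized with 6 significant digits.
#' A JSON sidecar `<path>.json` records fps and the spine point count.
#'
#' @param tracks list of [larva_track()] objects.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  if (length(tracks) == 0L) {
    readr::write_lines(paste(c("larva_id", "frame", "x_mm", "y_mm",
                               spine_col_names(5L), "bending_deg",
                               "area_mm2", "spine_len_mm"), collapse = ","),
                       path)
    return(invisible(path))
  }
  K <- track_n_spine(tracks[[1]])
  tab <- tracks_to_table(tracks)
  cols <- c("larva_id", "frame", "x_mm", "y_mm", spine_col_names(K),
            "bending_deg", "area_mm2", "spine_len_mm")
  tab <- tab[, cols]
  num <- vapply(tab, is.numeric, logical(1)) & names(tab) != "frame"
  tab[num] <- lapply(tab[num], function(x) signif(x, 6))
  readr::write_csv(tab, path)
  jsonlite::write_json(
    list(fps = tracks[[1]]$fps, n_spine_points = K,
         n_larvae = length(tracks)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read tracks from the long tracker CSV dialect
#'
#' @param path CSV path written by [write_tracks()] (or by a compatible
#'   tracker export). `fps` is read from the `<path>.json` sidecar unless
#'   given.
#' @param fps frames per second; overrides the sidecar.
#' @return a list of [larva_track()] objects, one per larva id.
#' @export
read_tracks <- function(path, fps = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  expected_fixed <- c("larva_id", "frame", "x_mm", "y_mm", "bending_deg",
                      "area_mm2", "spine_len_mm")
  spine_like <- grepl("^spine[0-9]+_[xy]_mm$", names(tab))
  unknown <- setdiff(names(tab)[!spine_like], expected_fixed)
  if (length(unknown) > 0L) {
    stop("unknown column(s) in track file: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing_cols <- setdiff(expected_fixed, names(tab))
  if (length(missing_cols) > 0L) {
    stop("track file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab[, c("larva_id", "frame")])) {
    stop("duplicated (larva_id, frame) rows", call. = FALSE)
  }
  if (is.null(fps)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      fps <- jsonlite::read_json(sidecar)$fps
    } else {
      stop("`fps` not given and no sidecar found at ", sidecar, call. = FALSE)
    }
  }
  ids <- unique(tab$larva_id)
  lapply(stats::setNames(ids, ids), function(id) {
    fr <- tab[tab$larva_id == id, setdiff(names(tab), "larva_id"),
              drop = FALSE]
    fr <- fr[order(fr$frame), , drop = FALSE]
    larva_track(fr, id, fps)
  })
}

#' Write a dual recording to disk
#'
#' Two two-column CSVs (`time_s`, `volts`), one per electrode, plus a JSON
#' sidecar with the sampling rate, electrode distance, and the
#' ground-truth spike table when present.
#'
#' @param rec a `dual_recording`.
#' @param stem path stem; files become `<stem>_e1.csv`, `<stem>_e2.csv`,
#'   `<stem>.json`.
#' @return the stem, invisibly.
#' @export
write_recording <- function(rec, stem) {
  t <- (seq_along(rec$trace1_volts) - 1) / rec$sampling_hz
  readr::write_csv(tibble::tibble(time_s = t, volts = rec$trace1_volts),
                   paste0(stem, "_e1.csv"))
  readr::write_csv(tibble::tibble(time_s = t, volts = rec$trace2_volts),
                   paste0(stem, "_e2.csv"))
  meta <- list(sampling_hz = rec$sampling_hz,
               electrode_distance_mm = rec$electrode_distance_mm)
  if (!is.null(rec$truth)) meta$truth <- rec$truth
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' Read a dual recording written by [write_recording()]
#'
#' @param stem path stem.
#' @return a `dual_recording` list.
#' @export
read_recording <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  e1 <- readr::read_csv(paste0(stem, "_e1.csv"), show_col_types = FALSE,
                        progress = FALSE)
  e2 <- readr::read_csv(paste0(stem, "_e2.csv"), show_col_types = FALSE,
                        progress = FALSE)
  structure(
    list(trace1_volts = e1$volts, trace2_volts = e2$volts,
         sampling_hz = meta$sampling_hz,
         electrode_distance_mm = meta$electrode_distance_mm,
         truth = if (!is.null(meta$truth)) tibble::as_tibble(meta$truth)),
    class = "dual_recording"
  )
}

#' Write nerve sections in the morpho CSV dialect
#'
#' `<stem>_axons.csv` (nerve_id, axon_id, area_um2, unit_id) and
#' `<stem>_units.csv` (nerve_id, unit_id, wrapped).
#'
#' @param sections list of [nerve_section()] objects.
#' @param stem path stem.
#' @return the stem, invisibly.
#' @export
write_sections <- function(sections, stem) {
  axons <- purrr::map_dfr(sections, function(s) {
    dplyr::bind_cols(tibble::tibble(nerve_id = s$nerve_id), s$axons)
  })
  units <- purrr::map_dfr(sections, function(s) {
    dplyr::bind_cols(tibble::tibble(nerve_id = s$nerve_id), s$units)
  })
  readr::write_csv(axons, paste0(stem, "_axons.csv"))
  readr::write_csv(units, paste0(stem, "_units.csv"))
  invisible(stem)
}

#' Read nerve sections from the morpho CSV dialect
#'
#' @param stem path stem used by [write_sections()].
#' @return a list of [nerve_section()] objects.
#' @export
read_sections <- function(stem) {
  axons <- readr::read_csv(paste0(stem, "_axons.csv"),
                           show_col_types = FALSE, progress = FALSE)
  units <- readr::read_csv(paste0(stem, "_units.csv"),
                           show_col_types = FALSE, progress = FALSE)
  ids <- unique(axons$nerve_id)
  lapply(stats::setNames(ids, ids), function(id) {
    nerve_section(id,
                  axons[axons$nerve_id == id, -1, drop = FALSE],
                  units[units$nerve_id == id, -1, drop = FALSE])
  })
}
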