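#' Nerve cross-section annotation
#'
#' Container for one electron-microscopy nerve cross-section: per-axon
#' areas with wrapping-unit membership, plus the wrapped flag per unit. A
#' wrapping unit is either a single individually wrapped axon, a wrapped
#' fascicle holding several axons, or the "naked" remainder (wrapped =
#' FALSE) of axons not enclosed by any glial process.
#'
#' @param nerve_id identifier.
#' @param axons data frame with columns `axon_id`, `area_um2`, `unit_id`.
#' @param units data frame with columns `unit_id`, `wrapped` (logical).
#' @return an object of class `nerve_section`.
#' @export
nerve_section <- function(nerve_id, axons, units) {
  axons <- tibble::as_tibble(axons)
  units <- tibble::as_tibble(units)
  stopifnot(all(c("axon_id", "area_um2", "unit_id") %in% names(axons)),
            all(c("unit_id", "wrapped") %in% names(units)))
  if (nrow(axons) < 1L) stop("a nerve section needs >= 1 axon", call. = FALSE)
  if (any(axons$area_um2 <= 0)) stop("axon areas must be positive",
                                     call. = FALSE)
  if (!all(axons$unit_id %in% units$unit_id)) {
    stop("every axon must reference an existing wrapping unit", call. = FALSE)
  }
  structure(list(nerve_id = as.character(nerve_id), axons = axons,
                 units = units),
            class = "nerve_section")
}

#' @export
print.nerve_section <- function(x, ...) {
  cat(sprintf("<nerve_section> %s: %d axons in %d units (w_i = %.2f)\n",
              x$nerve_id, nrow(x$axons), nrow(x$units), wrapping_index(x)))
  invisible(x)
}

#' Circular-equivalent axon radius from cross-section area
#'
#' r = sqrt(area / pi): the radius of the circle with the measured area,
#' which is robust against fixation-induced shape distortion.
#'
#' @param area_um2 axon cross-section area(s) in square micrometres.
#' @return radius in micrometres.
#' @export
radius_from_area <- function(area_um2) {
  if (any(!is.finite(area_um2)) || any(area_um2 <= 0)) {
    stop("areas must be positive", call. = FALSE)
  }
  sqrt(area_um2 / pi)
}

#' Wrapping index of a nerve section
#'
#' 100 x (number of wrapped units, i.e. individually wrapped axons plus
#' wrapped fascicles) / (total number of axons). An index of 100 means
#' every single axon is individually wrapped; grouping axons into shared
#' fascicles lowers the index. Units flagged as not wrapped (the naked
#' remainder) do not count toward the numerator.
#'
#' @param section a [nerve_section()].
#' @return wrapping index in (0, 100].
#' @export
wrapping_index <- function(section) {
  n_axons <- nrow(section$axons)
  if (n_axons == 0L) stop("zero axons", call. = FALSE)
  occupied <- unique(section$axons$unit_id)
  wrapped_units <- section$units$unit_id[section$units$wrapped]
  100 * sum(wrapped_units %in% occupied) / n_axons
}

#' Filter nerves by axon count
#'
#' Retains sections whose axon count lies in [lo, hi] (inclusive); the
#' published criterion excludes nerves with fewer than 76 or more than 82
#' axons from statistics.
#'
#' @param sections list of [nerve_section()] objects.
#' @param lo,hi inclusive axon-count bounds.
#' @return a list with `retained` (list of sections) and `excluded`
#'   (tibble `nerve_id`, `n_axons`, `reason`).
#' @export
filter_nerves <- function(sections, lo = 76L, hi = 82L) {
  n_ax <- vapply(sections, function(s) nrow(s$axons), integer(1))
  keep <- n_ax >= lo & n_ax <= hi
  excluded <- tibble::tibble(
    nerve_id = vapply(sections[!keep], `[[`, character(1), "nerve_id"),
    n_axons = n_ax[!keep],
    reason = ifelse(n_ax[!keep] < lo, sprintf("fewer than %d axons", lo),
                    sprintf("more than %d axons", hi))
  )
  list(retained = sections[keep], excluded = excluded)
}

#' Axon size histogram
#'
#' Counts axon areas in half-open bins [k*w, (k+1)*w).
#'
#' @param areas_um2 axon areas.
#' @param bin_width_um2 bin width in the same units (default 0.04 um^2).
#' @return a list of class `size_histogram` with `bin_width`, `breaks`,
#'   `counts`, `n_axons`.
#' @export
size_histogram <- function(areas_um2, bin_width_um2 = 0.04) {
  assert_positive(bin_width_um2, "bin_width_um2")
  if (any(areas_um2 <= 0)) stop("areas must be positive", call. = FALSE)
  k <- floor(areas_um2 / bin_width_um2)
  kmax <- max(k)
  counts <- tabulate(k + 1L, nbins = kmax + 1L)
  structure(
    list(bin_width = bin_width_um2,
         breaks = (0:(kmax + 1L)) * bin_width_um2,
         counts = counts,
         n_axons = length(areas_um2)),
    class = "size_histogram"
  )
}

#' Per-bin relative change between two size histograms
#'
#' (n_treatment - n_control) / n_control per bin; bins with an empty
#' control count are flagged undefined (NA).
#'
#' @param hist_control,hist_treat `size_histogram` objects with the same
#'   bin width.
#' @return a tibble with `bin_lo`, `bin_hi`, `n_control`, `n_treat`,
#'   `relative_change`, `defined`.
#' @export
relative_change <- function(hist_control, hist_treat) {
  if (abs(hist_control$bin_width - hist_treat$bin_width) > 1e-12) {
    stop("histograms have different bin widths", call. = FALSE)
  }
  nb <- max(length(hist_control$counts), length(hist_treat$counts))
  nc <- c(hist_control$counts, rep(0L, nb - length(hist_control$counts)))
  nt <- c(hist_treat$counts, rep(0L, nb - length(hist_treat$counts)))
  w <- hist_control$bin_width
  tibble::tibble(
    bin_lo = (0:(nb - 1L)) * w,
    bin_hi = (1:nb) * w,
    n_control = nc,
    n_treat = nt,
    relative_change = ifelse(nc > 0L, (nt - nc) / nc, NA_real_),
    defined = nc > 0L
  )
}

#' Pooled radius summary over retained nerves
#'
#' Mean circular-equivalent radius pooled over all axons of all sections
#' (axon-level, not nerve-level, averaging).
#'
#' @param sections list of [nerve_section()] objects.
#' @return a tibble with `mean_radius_um`, `median_radius_um`, `n_axons`,
#'   `n_nerves`.
#' @export
summarize_radii <- function(sections) {
  if (length(sections) == 0L) stop("no nerve sections", call. = FALSE)
  areas <- unlist(lapply(sections, function(s) s$axons$area_um2))
  r <- radius_from_area(areas)
  tibble::tibble(mean_radius_um = mean(r),
                 median_radius_um = stats::median(r),
                 n_axons = length(r),
                 n_nerves = length(sections))
}
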