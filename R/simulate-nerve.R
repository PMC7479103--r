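#' Configuration for the nerve cross-section simulator
#'
#' Defaults emulate a control abdominal nerve: about 80 axons whose
#' circular-equivalent radii follow a lognormal distribution with median
#' 0.194 um, organized into a few wrapped fascicles plus a fraction of
#' individually wrapped axons (the remainder stays in a single naked,
#' unwrapped unit).
#'
#' @param n_axons number of axons.
#' @param radius_log_mean_um meanlog of the lognormal radius model, i.e.
#'   log of the median radius in um.
#' @param radius_log_sd_um sdlog of the lognormal radius model.
#' @param n_fascicles number of multi-axon wrapped fascicles.
#' @param frac_individually_wrapped fraction of axons wrapped alone.
#' @param seed integer seed.
#' @return a list of class `nerve_config`.
#' @export
nerve_config <- function(n_axons = 80L,
                         radius_log_mean_um = log(0.194),
                         radius_log_sd_um = 0.5,
                         n_fascicles = 3L,
                         frac_individually_wrapped = 0.1,
                         seed = 1L) {
  if (n_axons < 1L) stop("`n_axons` must be >= 1", call. = FALSE)
  if (frac_individually_wrapped < 0 || frac_individually_wrapped > 1) {
    stop("`frac_individually_wrapped` must lie in [0, 1]", call. = FALSE)
  }
  if (n_fascicles < 0L) stop("`n_fascicles` must be >= 0", call. = FALSE)
  structure(
    list(n_axons = as.integer(n_axons),
         radius_log_mean_um = radius_log_mean_um,
         radius_log_sd_um = radius_log_sd_um,
         n_fascicles = as.integer(n_fascicles),
         frac_individually_wrapped = frac_individually_wrapped,
         seed = as.integer(seed)),
    class = "nerve_config"
  )
}

#' Simulate a nerve cross-section annotation
#'
#' Draws per-axon areas from the lognormal radius model (area = pi r^2)
#' and assigns axons to wrapping units: `round(frac * n)` axons get their
#' own wrapped unit, the rest are split uniformly among `n_fascicles`
#' wrapped fascicles, and any axons left over (when `n_fascicles` is 0)
#' fall into one naked unwrapped unit. The ground-truth wrapping index is
#' returned alongside.
#'
#' @param config a [nerve_config()].
#' @param nerve_id identifier for the section.
#' @return a list of class `nerve_sim` with `section` (a
#'   [nerve_section()]) and `true_wrapping_index`.
#' @export
simulate_nerve <- function(config, nerve_id = "nerve1") {
  if (!inherits(config, "nerve_config")) {
    stop("`config` must be a nerve_config", call. = FALSE)
  }
  n <- config$n_axons
  if (config$n_fascicles > n) {
    stop("more fascicles than axons", call. = FALSE)
  }
  withr::local_seed(config$seed)
  r <- stats::rlnorm(n, config$radius_log_mean_um, config$radius_log_sd_um)
  areas <- pi * r^2

  n_ind <- round(config$frac_individually_wrapped * n)
  n_ind <- min(n_ind, n - config$n_fascicles)  # fascicles need >= 1 axon each
  ids <- sample.int(n)   # random assignment order
  unit_of <- character(n)
  units <- tibble::tibble(unit_id = character(), wrapped = logical())
  pos <- 1L
  if (n_ind > 0L) {
    for (k in seq_len(n_ind)) {
      uid <- sprintf("ind%03d", k)
      unit_of[ids[pos]] <- uid
      units <- dplyr::bind_rows(units, tibble::tibble(unit_id = uid,
                                                      wrapped = TRUE))
      pos <- pos + 1L
    }
  }
  remaining <- if (pos <= n) ids[pos:n] else integer(0)
  n_rem <- length(remaining)
  if (config$n_fascicles > 0L && pos <= n) {
    fas <- rep(seq_len(config$n_fascicles), length.out = n_rem)
    fas <- sample(fas)
    for (k in seq_len(config$n_fascicles)) {
      uid <- sprintf("fas%03d", k)
      unit_of[remaining[fas == k]] <- uid
      units <- dplyr::bind_rows(units, tibble::tibble(unit_id = uid,
                                                      wrapped = TRUE))
    }
  } else if (pos <= n) {
    unit_of[remaining] <- "naked"
    units <- dplyr::bind_rows(units, tibble::tibble(unit_id = "naked",
                                                    wrapped = FALSE))
  }

  axons <- tibble::tibble(axon_id = sprintf("ax%04d", seq_len(n)),
                          area_um2 = areas,
                          unit_id = unit_of)
  section <- nerve_section(nerve_id, axons, units)
  # ground truth straight from the construction, independent of the
  # wrapping_index() estimator
  n_fas_used <- if (config$n_fascicles > 0L && n_rem > 0L) {
    min(config$n_fascicles, n_rem)
  } else 0L
  structure(list(section = section,
                 true_wrapping_index = 100 * (n_ind + n_fas_used) / n,
                 config = config),
            class = "nerve_sim")
}
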