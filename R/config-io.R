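#' Read a generator configuration from a flat key-value file
#'
#' Configurations are stored as flat YAML: a `kind` field selecting the
#' generator (`"locomotion"`, `"ephys"` or `"nerve"`) and the remaining
#' keys passed straight to the matching constructor
#' ([locomotion_config()], [ephys_config()], [nerve_config()]), so every
#' invariant check of the constructor applies to file input too. The
#' nested `bout_rates` / `bout_duration_frames` maps become named
#' vectors.
#'
#' @param path YAML file.
#' @return a config object of the kind named in the file.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  kind <- raw$kind %||% stop("config file needs a `kind` field",
                             call. = FALSE)
  raw$kind <- NULL
  for (nm in c("bout_rates", "bout_duration_frames")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  ctor <- switch(kind,
                 locomotion = locomotion_config,
                 ephys = ephys_config,
                 nerve = nerve_config,
                 stop("unknown config kind: ", kind, call. = FALSE))
  do.call(ctor, raw)
}

#' Write a generator configuration as a flat key-value file
#'
#' @param config a `locomotion_config`, `ephys_config` or `nerve_config`.
#' @param path output YAML file.
#' @return the path, invisibly.
#' @export
write_config <- function(config, path) {
  kind <- switch(class(config)[1],
                 locomotion_config = "locomotion",
                 ephys_config = "ephys",
                 nerve_config = "nerve",
                 stop("not a generator config", call. = FALSE))
  x <- unclass(config)
  x <- c(list(kind = kind), x)
  for (nm in c("bout_rates", "bout_duration_frames")) {
    if (!is.null(x[[nm]])) x[[nm]] <- as.list(x[[nm]])
  }
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}
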