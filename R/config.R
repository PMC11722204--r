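# Run configuration shared by the command-line entry point: palette,
# connectivity, consensus defaults, Dice policy and the hypertrabeculation
# threshold, serialized as JSON so every run is reproducible from its
# config + seeds.

#' Default run configuration
#'
#' @return A named list: `palette` (hex colors, see [default_palette()]),
#'   `connectivity` (blob adjacency), `consensus_n` / `consensus_m`
#'   (ensemble size and agreement threshold), `dice_empty_policy`,
#'   `vt_threshold` (hypertrabeculation criterion, percent) and `seed`.
#' @export
default_run_config <- function() {
  pal <- default_palette()
  list(
    palette = list(class_rgb = as.list(pal$class_rgb),
                   diff_rgb = as.list(pal$diff_rgb),
                   no_diff = pal$no_diff),
    connectivity = 4L,
    consensus_n = 4L,
    consensus_m = 3L,
    dice_empty_policy = "exclude",
    vt_threshold = 27.4,
    seed = 1L
  )
}

#' Write a run configuration as JSON
#'
#' @param config A configuration list (see [default_run_config()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read and validate a run configuration
#'
#' Every field is checked against the preconditions of the module that
#' consumes it (palette distinctness, `m > n/2`, threshold range, ...).
#'
#' @param path JSON path written by [write_run_config()].
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  base <- default_run_config()
  for (nm in names(base)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- base[[nm]]
  }
  # constructors carry the validation
  default_palette(class_rgb = unlist(cfg$palette$class_rgb),
                  diff_rgb = unlist(cfg$palette$diff_rgb),
                  no_diff = cfg$palette$no_diff)
  if (!(cfg$connectivity %in% c(4L, 8L))) stop("connectivity must be 4 or 8")
  if (cfg$consensus_m <= cfg$consensus_n / 2 ||
        cfg$consensus_m > cfg$consensus_n) {
    stop("consensus_m must satisfy n/2 < m <= n")
  }
  if (!(cfg$dice_empty_policy %in% c("exclude", "one"))) {
    stop("dice_empty_policy must be 'exclude' or 'one'")
  }
  if (cfg$vt_threshold <= 0 || cfg$vt_threshold >= 100) {
    stop("vt_threshold must be strictly between 0 and 100")
  }
  cfg
}

#' Palette object from a run configuration
#'
#' @param config A configuration list (see [read_run_config()]).
#' @return A [default_palette()] object.
#' @export
config_palette <- function(config) {
  default_palette(class_rgb = unlist(config$palette$class_rgb),
                  diff_rgb = unlist(config$palette$diff_rgb),
                  no_diff = config$palette$no_diff)
}
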