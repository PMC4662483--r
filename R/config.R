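#' Load and validate a batch run configuration
#'
#' The configuration is YAML (JSON, being a subset, is accepted too):
#' \preformatted{
#' pairs:
#'   - id: pair1            # optional, defaults to pair<k>
#'     treated_t0: t_0h.tif
#'     treated_t1: t_24h.tif
#'     control_t0: c_0h.tif
#'     control_t1: c_24h.tif
#' n_lines: 5               # optional, default 5
#' window: 15               # optional, default 15
#' min_wound_area_frac: 0.02
#' scale_um_per_px: 1.3     # optional; omit for pixel units
#' output_dir: results      # optional, default "woundquant_out"
#' seed: 1                  # optional, default 1
#' overlay: false           # optional QC overlays
#' }
#' Unknown keys are rejected (typos should fail loudly, not be ignored) and
#' all referenced image paths must exist at load time.
#'
#' @param path Path to the YAML/JSON configuration file.
#' @return A validated list of class `run_config` with defaults filled in.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")

  allowed <- c("pairs", "n_lines", "window", "min_wound_area_frac",
               "scale_um_per_px", "output_dir", "seed", "overlay")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$pairs) || length(cfg$pairs) == 0L)
    stop("config must list at least one image pair under 'pairs'")

  defaults <- list(n_lines = 5L, window = 15L, min_wound_area_frac = 0.02,
                   scale_um_per_px = NULL, output_dir = "woundquant_out",
                   seed = 1L, overlay = FALSE)
  cfg <- modifyList(defaults, cfg)
  cfg$n_lines <- as.integer(cfg$n_lines)
  if (is.na(cfg$n_lines) || cfg$n_lines < 1L)
    stop("n_lines must be >= 1")
  if (!is.null(cfg$scale_um_per_px) && cfg$scale_um_per_px <= 0)
    stop("scale_um_per_px must be > 0")

  roles <- c("treated_t0", "treated_t1", "control_t0", "control_t1")
  cfg$pairs <- lapply(seq_along(cfg$pairs), function(k) {
    p <- cfg$pairs[[k]]
    unknown <- setdiff(names(p), c("id", roles))
    if (length(unknown))
      stop("pair ", k, ": unknown key(s): ", paste(unknown, collapse = ", "))
    missing <- setdiff(roles, names(p))
    if (length(missing))
      stop("pair ", k, ": missing image path(s): ",
           paste(missing, collapse = ", "))
    for (r in roles) {
      if (!file.exists(p[[r]]))
        stop("pair ", k, " (", r, "): image file not found: ", p[[r]])
    }
    if (is.null(p$id)) p$id <- paste0("pair", k)
    p
  })
  structure(cfg, class = "run_config")
}
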