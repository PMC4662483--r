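# Fixed output schemas (versioned; tests assert these headers exactly).
LINE_CSV_COLUMNS <- c("image", "condition", "timepoint", "n_lines",
                      "line_index", "position_px", "width_px", "width_um",
                      "flag_closed", "mean_width_px")
SUMMARY_CSV_COLUMNS <- c("pair_id", "treated_t0", "treated_t1", "control_t0",
                         "control_t1", "A", "B", "a", "b", "closure_treated",
                         "closure_control", "relative_migration_pct",
                         "status", "message")

#' Run a configured batch of scratch-assay pairs
#'
#' For each treated/control pair the four images are quantified with
#' [quantify_image()], the relative migration distance is computed from the
#' per-image mean widths, and results are written as one summary CSV
#' (`summary.csv`, one row per pair), one line-level CSV (`lines.csv`,
#' `4 * n_lines` rows per pair), one JSON result per image under `json/`,
#' optional QC overlays under `qc/`, and a plain-text run log. Per-image
#' failures are recorded as flagged rows and the batch continues; re-running
#' an identical configuration reproduces byte-identical CSVs (timestamps are
#' confined to the log).
#'
#' @param cfg A `run_config` from [load_config()], or a path to one.
#' @return Invisibly, a list with `summary` and `lines` data.frames, the
#'   `output_dir`, and `ok` (`TRUE` when every pair succeeded).
#' @export
run_batch <- function(cfg) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "json"), showWarnings = FALSE)
  if (isTRUE(cfg$overlay)) dir.create(file.path(out, "qc"),
                                      showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  logf <- function(...) cat(sprintf("[%s] ", format(Sys.time())),
                            sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("woundquant %s batch run", as.character(packageVersion("woundquant")))
  logf("n_lines=%d window=%d min_wound_area_frac=%g seed=%d overlay=%s",
       cfg$n_lines, cfg$window, cfg$min_wound_area_frac, cfg$seed,
       cfg$overlay)

  roles <- c("treated_t0", "treated_t1", "control_t0", "control_t1")
  role_meta <- list(treated_t0 = c("treated", "t0"),
                    treated_t1 = c("treated", "t1"),
                    control_t0 = c("control", "t0"),
                    control_t1 = c("control", "t1"))
  summary_rows <- list()
  line_rows <- list()

  for (p in cfg$pairs) {
    profiles <- list()
    err <- NULL
    for (r in roles) {
      prof <- tryCatch({
        mg <- read_micrograph(p[[r]], scale = cfg$scale_um_per_px,
                              condition = role_meta[[r]][1],
                              timepoint = role_meta[[r]][2])
        quantify_image(mg, n_lines = cfg$n_lines, window = cfg$window,
                       min_wound_area_frac = cfg$min_wound_area_frac)
      }, error = function(e) e)
      if (inherits(prof, "error")) {
        err <- sprintf("%s: %s", r, conditionMessage(prof))
        logf("pair %s FAILED at %s: %s", p$id, r, conditionMessage(prof))
        break
      }
      profiles[[r]] <- prof
      logf("pair %s %s: mean width %.3f px (%d/%d lines closed)", p$id, r,
           prof$mean_width_px, sum(prof$lines$flag_closed), prof$n_lines)
      ln <- prof$lines
      line_rows[[length(line_rows) + 1L]] <- data.frame(
        image = p[[r]], condition = role_meta[[r]][1],
        timepoint = role_meta[[r]][2], n_lines = prof$n_lines,
        line_index = ln$index, position_px = ln$position_px,
        width_px = ln$width_px, width_um = ln$width_um,
        flag_closed = ln$flag_closed, mean_width_px = prof$mean_width_px)
      jsonlite::write_json(
        list(image = p[[r]], pair_id = p$id,
             condition = role_meta[[r]][1], timepoint = role_meta[[r]][2],
             mean_width_px = prof$mean_width_px,
             mean_width_um = prof$mean_width_um,
             lines = prof$lines[, c("index", "position_px", "width_px",
                                    "width_um", "flag_closed")]),
        file.path(out, "json", paste0(p$id, "_", r, ".json")),
        auto_unbox = TRUE, digits = NA, na = "null")
      if (isTRUE(cfg$overlay)) {
        ov_path <- file.path(out, "qc", paste0(p$id, "_", r, ".png"))
        tryCatch(render_overlay(read_micrograph(p[[r]]), prof, ov_path),
                 error = function(e) logf("overlay failed for %s: %s",
                                          p[[r]], conditionMessage(e)))
      }
    }

    if (is.null(err)) {
      mig <- tryCatch(
        withCallingHandlers(
          migration_result(profiles$treated_t0, profiles$treated_t1,
                           profiles$control_t0, profiles$control_t1),
          warning = function(w) {
            logf("pair %s warning: %s", p$id, conditionMessage(w))
            invokeRestart("muffleWarning")
          }),
        error = function(e) e)
      if (inherits(mig, "error")) {
        err <- conditionMessage(mig)
        logf("pair %s migration FAILED: %s", p$id, err)
      }
    }
    mw <- function(r) if (!is.null(profiles[[r]]))
      profiles[[r]]$mean_width_px else NA_real_
    ok <- is.null(err)
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      pair_id = p$id, treated_t0 = p$treated_t0, treated_t1 = p$treated_t1,
      control_t0 = p$control_t0, control_t1 = p$control_t1,
      A = mw("treated_t0"), B = mw("treated_t1"),
      a = mw("control_t0"), b = mw("control_t1"),
      closure_treated = if (ok) mig$closure_treated else NA_real_,
      closure_control = if (ok) mig$closure_control else NA_real_,
      relative_migration_pct = if (ok) mig$relative_migration_pct else
        NA_real_,
      status = if (ok) "ok" else "error",
      message = if (ok) "" else err)
  }

  summary_df <- do.call(rbind, summary_rows)[, SUMMARY_CSV_COLUMNS]
  lines_df <- if (length(line_rows))
    do.call(rbind, line_rows)[, LINE_CSV_COLUMNS]
  else
    as.data.frame(stats::setNames(rep(list(logical(0)),
                                      length(LINE_CSV_COLUMNS)),
                                  LINE_CSV_COLUMNS))
  write.csv(summary_df, file.path(out, "summary.csv"), row.names = FALSE)
  write.csv(lines_df, file.path(out, "lines.csv"), row.names = FALSE)
  all_ok <- all(summary_df$status == "ok")
  logf("batch complete: %d/%d pairs ok", sum(summary_df$status == "ok"),
       nrow(summary_df))
  invisible(list(summary = summary_df, lines = lines_df,
                 output_dir = out, ok = all_ok))
}

#' Render a QC overlay of contours and measurement lines
#'
#' Draws the two boundary contours (red/blue) and the measurement lines
#' (green) over the grayscale image and writes a PNG.
#'
#' @param img A [micrograph] or matrix.
#' @param profile A `width_profile` from [quantify_image()] (its `contour`
#'   attribute supplies the boundary traces).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
render_overlay <- function(img, profile, path) {
  px <- as_micrograph(img)$pixels
  px <- pmin(pmax(px, 0), 1)
  h <- nrow(px); w <- ncol(px)
  rgb <- array(rep(px, 3L), dim = c(h, w, 3L))
  paint <- function(rows, cols, col3) {
    rows <- round(rows); cols <- round(cols)
    keep <- rows >= 1 & rows <= h & cols >= 1 & cols <= w
    idx <- cbind(rows[keep], cols[keep])
    for (ch in 1:3) rgb[cbind(idx, ch)] <<- col3[ch]
  }
  contour <- attr(profile, "contour")
  if (!is.null(contour)) {
    paint(contour$side_a[, "row"], contour$side_a[, "col"], c(1, 0.2, 0.2))
    paint(contour$side_b[, "row"], contour$side_b[, "col"], c(0.2, 0.4, 1))
  }
  ln <- profile$lines
  for (i in seq_len(nrow(ln))) {
    if (ln$flag_closed[i] || is.na(ln$a_row[i])) next
    tt <- seq(0, 1, length.out = 2L * ceiling(ln$width_px[i]) + 2L)
    paint(ln$a_row[i] + tt * (ln$b_row[i] - ln$a_row[i]),
          ln$a_col[i] + tt * (ln$b_col[i] - ln$a_col[i]), c(0.1, 0.9, 0.1))
  }
  png::writePNG(rgb, path)
  invisible(path)
}
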