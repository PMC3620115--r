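# Result serialization: CSV matrices for 2D maps, long-format CSV for the
# absorption voxel grid, JSON metadata (seed, config hash, totals by
# channel), a JSON-lines run log, and 16-bit PNG previews with a linear
# scaling recorded in a sidecar JSON. All text output uses '.' decimals
# and no locale dependence.

#' Write a transport result to a directory
#'
#' @param result an `mc_result`.
#' @param dir output directory (created if needed).
#' @param config optional `simulation_config` whose hash is stamped into
#'   the metadata and every CSV header.
#' @param png write 16-bit PNG previews of the face grids.
#' @return the directory, invisibly.
#' @export
write_result <- function(result, dir, config = NULL, png = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hash <- if (!is.null(config)) config_hash(config) else NA_character_
  meta <- list(seed = result$controls$seed,
               n_photons = result$controls$n_photons,
               mode = result$controls$mode,
               config_hash = hash,
               gate_edges_ps = result$gate_edges,
               units = list(length = "mm", time = "ps",
                            weight = "source power units"),
               totals = result$totals)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  hdr <- sprintf("# config_hash=%s units=weight", hash)
  face_names <- c("x-", "x+", "y-", "y+", "z-", "z+")
  for (band in names(result$tri_exit)) {
    if (!is.null(result$face_grid)) {
      for (f in 1:6) {
        p <- file.path(dir, sprintf("face_%s_%s.csv",
                                    sub("[+]", "p", sub("-", "m", face_names[f])),
                                    band))
        writeLines(hdr, p)
        suppressWarnings(utils::write.table(
          result$face_grid[[band]][, , f], p, append = TRUE, sep = ",",
          row.names = FALSE, col.names = FALSE))
        if (png) write_png_preview(result$face_grid[[band]][, , f],
                                   sub("\\.csv$", ".png", p))
      }
    }
    utils::write.csv(
      data.frame(triangle = seq_along(result$tri_exit[[band]]),
                 weight = result$tri_exit[[band]]),
      file.path(dir, sprintf("tri_exit_%s.csv", band)), row.names = FALSE)
    if (!is.null(result$absorption)) {
      a <- result$absorption[[band]]
      idx <- which(a > 0)
      ijk <- arrayInd(idx, dim(a))
      utils::write.csv(
        data.frame(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3], weight = a[idx]),
        file.path(dir, sprintf("absorption_%s.csv", band)), row.names = FALSE)
    }
    if (!is.null(result$exit_time)) {
      ng <- length(result$exit_time[[band]])
      utils::write.csv(
        data.frame(gate = c(seq_len(ng - 1), NA),
                   start_ps = c(result$gate_edges[-length(result$gate_edges)], NA),
                   exited = result$exit_time[[band]],
                   absorbed = result$absorbed_time[[band]]),
        file.path(dir, sprintf("time_gates_%s.csv", band)), row.names = FALSE)
    }
  }
  if (nrow(result$exit_log))
    utils::write.csv(as.data.frame(result$exit_log),
                     file.path(dir, "exit_log.csv"), row.names = FALSE)
  log_line(file.path(dir, "run_log.jsonl"),
           list(event = "write_result", seed = result$controls$seed,
                config_hash = hash,
                launched = result$totals$launched,
                exited = sum(result$totals$exited),
                deposited = sum(result$totals$deposited)))
  invisible(dir)
}

#' Write a 16-bit PNG preview of a matrix
#'
#' Linear scaling to the full 16-bit range; the scale (min, max) is
#' recorded in a sidecar `<path>.json`.
#'
#' @param m numeric matrix.
#' @param path output path ending in `.png`.
#' @export
write_png_preview <- function(m, path) {
  m <- as.matrix(m)
  lo <- min(m); hi <- max(m)
  scl <- if (hi > lo) (m - lo) / (hi - lo) else m * 0
  png::writePNG(scl, path, dpi = NULL)
  jsonlite::write_json(list(min = lo, max = hi, encoding = "linear-16bit"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Append a JSON line to a run log
#'
#' @param path log file path.
#' @param record named list; a timestamp is added.
#' @export
log_line <- function(path, record) {
  record$time <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  cat(jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA), "\n",
      file = path, append = TRUE, sep = "")
  invisible(path)
}

#' Read back a face-grid CSV written by [write_result()]
#'
#' @param path CSV path.
#' @return numeric matrix (the comment header is skipped).
#' @export
read_result_matrix <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", comment.char = "#",
                              header = FALSE))
}

#' Write a detector image as CSV (+ optional PNG preview)
#'
#' @param image a `detector_image`.
#' @param path CSV output path.
#' @param png also write a 16-bit PNG preview next to it.
#' @export
write_detector_image <- function(image, path, png = TRUE) {
  suppressWarnings(utils::write.table(unclass(image), path, sep = ",",
                                      row.names = FALSE, col.names = FALSE))
  if (png) write_png_preview(unclass(image), sub("\\.csv$", ".png", path))
  invisible(path)
}
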