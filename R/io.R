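# File formats: frame stacks (multi-page TIFF / PNG sequence), CSV tables,
# JSON/YAML configuration, and JSON sidecars carrying provenance.

#' Read a JSON or YAML run configuration
#'
#' Recognised blocks: `spring`, `geometry`, `optics`, `protocol`, each
#' passed as arguments to the corresponding constructor; missing blocks
#' fall back to the defaults.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A list with elements `spring`, `geom`, `optics`, `protocol` and
#'   the raw config under `$raw`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  build <- function(ctor, block) do.call(ctor, as.list(raw[[block]] %||%
                                                        list()))
  list(spring = build(spring_model, "spring"),
       geom = build(contact_geometry, "geometry"),
       optics = build(optics_model, "optics"),
       protocol = build(protocol_config, "protocol"),
       raw = raw)
}

# md5 of the canonical JSON serialization of a config-ish list.
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

# Sidecar JSON recording provenance next to an artifact.
write_sidecar <- function(path, seed = NULL, config = NULL, extra = list()) {
  meta <- c(list(
    package = "pinholebp",
    version = as.character(packageVersion("pinholebp")),
    seed = seed,
    config_hash = if (!is.null(config)) config_hash(config)), extra)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(paste0(path, ".json"))
}

#' Write a session's frame stack to disk
#'
#' Multi-page TIFF (`format = "tiff"`) or a numbered PNG sequence, plus a
#' JSON sidecar with the ground truth, seed and configuration echo.
#'
#' @param recording A frame-mode `session_recording`.
#' @param path Output path: a `.tif` file for TIFF, a directory for PNG.
#' @param format `"tiff"` or `"png"`.
#' @return The sidecar path, invisibly.
#' @export
write_session_frames <- function(recording, path,
                                 format = c("tiff", "png")) {
  format <- match.arg(format)
  stopifnot(inherits(recording, "session_recording"))
  if (recording$mode != "frames") stop("recording has no frames",
                                       call. = FALSE)
  imgs <- lapply(recording$frames, function(f) f / 255)
  if (format == "tiff") {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the tiff package is required", call. = FALSE)
    }
    tiff::writeTIFF(imgs, path, bits.per.sample = 8L)
    base <- path
  } else {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("the png package is required", call. = FALSE)
    }
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(imgs)) {
      png::writePNG(imgs[[i]], file.path(path,
                                         sprintf("frame_%05d.png", i)))
    }
    base <- file.path(path, "stack")
  }
  s <- recording$subject
  invisible(write_sidecar(base, seed = recording$seed,
    config = recording[c("optics", "spring", "geom", "protocol")],
    extra = list(mode = recording$mode, frame_rate = recording$frame_rate,
                 n_frames = length(imgs), frame_level = recording$frame_level,
                 ground_truth = list(sbp_true = s$sbp_true,
                                     dbp_true = s$dbp_true,
                                     mbp_true = s$mbp_true,
                                     heart_rate = s$heart_rate))))
}

#' Read a frame stack from a multi-page TIFF or a PNG directory
#'
#' @param path `.tif` file or a directory of `frame_*.png`.
#' @return List of integer matrices (grey levels 0--255).
#' @export
read_frame_stack <- function(path) {
  to_int <- function(img) {
    if (length(dim(img)) == 3) img <- img[, , 1]
    matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "^frame_.*\\.png$",
                             full.names = TRUE))
    if (length(files) == 0) stop("no frame_*.png in ", path, call. = FALSE)
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("the png package is required", call. = FALSE)
    }
    return(lapply(files, function(f) to_int(png::readPNG(f))))
  }
  if (!file.exists(path)) stop("no such frame stack: ", path, call. = FALSE)
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the tiff package is required", call. = FALSE)
  }
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(imgs)) imgs <- list(imgs)
  lapply(imgs, to_int)
}

#' Write a data frame as CSV with a provenance sidecar
#'
#' Comma-separated, dot decimal, header row, UTF-8; a `<path>.json` sidecar
#' records package version, seed and config hash.
#'
#' @param df Data frame.
#' @param path Output CSV path.
#' @param seed,config Provenance recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_csv_sidecar <- function(df, path, seed = NULL, config = NULL) {
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  write_sidecar(path, seed = seed, config = config,
                extra = list(rows = nrow(df)))
  invisible(path)
}

#' Write / read an oscillogram CSV
#'
#' @param osc An `oscillogram`.
#' @param path CSV path.
#' @param ... Passed to [write_csv_sidecar()].
#' @return `path` (write) or the `oscillogram` (read).
#' @export
write_oscillogram_csv <- function(osc, path, ...) {
  stopifnot(inherits(osc, "oscillogram"))
  df <- as.data.frame(osc)
  df$normalized <- isTRUE(attr(osc, "normalized"))
  write_csv_sidecar(df, path, ...)
}

#' @rdname write_oscillogram_csv
#' @export
read_oscillogram_csv <- function(path) {
  df <- read.csv(path)
  normalized <- isTRUE(all(df$normalized))
  n_raw <- nrow(df) + if (normalized) 2L else 0L
  df$normalized <- NULL
  structure(df, n_raw = n_raw, normalized = normalized,
            class = c("oscillogram", "data.frame"))
}

#' Serialize a trained model to JSON
#'
#' @param model A `bp_model` from [train_bp_model()].
#' @param path Output `.json` path.
#' @return `path` (write) or the `bp_model` (read).
#' @export
write_bp_model <- function(model, path) {
  stopifnot(inherits(model, "bp_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bp_model
#' @export
read_bp_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(raw, class = "bp_model")
}
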