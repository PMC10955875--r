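# Container formats, configuration files and run manifests.
#
# Channel data and frame stacks are stored in a single self-describing
# binary container: an 8-byte magic, a length-prefixed JSON header
# (type, dimensions, geometry, acquisition metadata) and a little-endian
# float32 payload.  The round trip is lossless for float32 payloads.
# Images travel as 32-bit float TIFF rescaled to [0, 1] with a JSON
# sidecar holding the affine scale and the pixel size.

CONTAINER_MAGIC <- "EATLAB01"

write_container_raw <- function(path, header, payload) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(CONTAINER_MAGIC), con)
  hdr <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA))
  writeBin(length(hdr), con, size = 4, endian = "little")
  writeBin(hdr, con)
  writeBin(as.numeric(payload), con, size = 4, endian = "little")
  invisible(path)
}

read_container_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8))
  if (!identical(magic, CONTAINER_MAGIC)) {
    stop("not an eatlab container (bad magic): ", path, call. = FALSE)
  }
  nh <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (length(nh) != 1 || is.na(nh) || nh <= 0) {
    stop("truncated container header: ", path, call. = FALSE)
  }
  hdr_raw <- readBin(con, "raw", nh)
  if (length(hdr_raw) < nh) stop("truncated container header: ", path, call. = FALSE)
  header <- jsonlite::fromJSON(rawToChar(hdr_raw))
  n <- prod(header$dims)
  payload <- readBin(con, "numeric", n, size = 4, endian = "little")
  if (length(payload) < n) {
    stop(sprintf("truncated container payload in %s: expected %d values, got %d",
                 path, n, length(payload)), call. = FALSE)
  }
  list(header = header, payload = payload)
}

# Strip S3 classes so provenance objects (responses, geometries) serialize
# as plain JSON lists.
sanitize_meta <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), sanitize_meta)
  } else if (is.object(x)) {
    unclass(x)
  } else {
    x
  }
}

require_fields <- function(header, fields, path) {
  missing <- setdiff(fields, names(header))
  if (length(missing)) {
    stop("container ", path, " is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Write channel data to the eatlab container format
#'
#' @param data an [channel_data()]
#' @param path output file path
#' @param manifest optional [run_manifest()] written as a `.manifest.json`
#'   sidecar
#' @return `path`, invisibly
#' @export
write_channel_data <- function(data, path, manifest = NULL) {
  stopifnot(inherits(data, "eat_channel_data"))
  geo <- data$geometry
  header <- list(
    type = "channel_data",
    dims = dim(data$traces),
    sampling_rate = data$sampling_rate,
    t0 = data$t0,
    geometry = list(
      n_elements = geo$n_elements, ring_radius = geo$ring_radius,
      element_angles = geo$element_angles,
      sampling_rate = geo$sampling_rate, n_samples = geo$n_samples
    ),
    meta = sanitize_meta(data$meta)
  )
  write_container_raw(path, header, data$traces)
  if (!is.null(manifest)) write_manifest(manifest, paste0(path, ".manifest.json"))
  invisible(path)
}

#' Write a frame stack to the eatlab container format
#'
#' @param stack an [frame_stack()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "eat_frame_stack"))
  header <- list(
    type = "frame_stack",
    dims = dim(stack$frames),
    frame_interval = stack$frame_interval,
    sampling_rate = stack$sampling_rate,
    meta = sanitize_meta(stack$meta)
  )
  write_container_raw(path, header, stack$frames)
  invisible(path)
}

#' Read an eatlab container
#'
#' Dispatches on the container's `type` field and returns the matching
#' object ([channel_data()] or [frame_stack()]).  Fails with a message
#' naming the offending field on schema mismatch or truncation.
#'
#' @param path container file path
#' @return an `eat_channel_data` or `eat_frame_stack`
#' @export
read_container <- function(path) {
  rc <- read_container_raw(path)
  h <- rc$header
  require_fields(h, c("type", "dims"), path)
  if (h$type == "channel_data") {
    require_fields(h, c("sampling_rate", "t0", "geometry"), path)
    g <- h$geometry
    require_fields(g, c("n_elements", "ring_radius", "element_angles",
                        "sampling_rate", "n_samples"), path)
    geo <- ring_array(g$n_elements, g$ring_radius, g$sampling_rate,
                      n_samples = g$n_samples,
                      element_angles = g$element_angles)
    channel_data(matrix(rc$payload, h$dims[1], h$dims[2]),
                 h$sampling_rate, geo, t0 = h$t0,
                 meta = as.list(h$meta))
  } else if (h$type == "frame_stack") {
    require_fields(h, c("frame_interval"), path)
    frame_stack(array(rc$payload, h$dims), h$frame_interval,
                if (is.null(h$sampling_rate)) NA_real_ else h$sampling_rate,
                meta = as.list(h$meta))
  } else {
    stop("unknown container type '", h$type, "' in ", path, call. = FALSE)
  }
}

#' Export / import a single trace as CSV
#'
#' Two columns, `time` (s) and `pressure` (Pa).  On import the sampling
#' rate is inferred from the time column (or declared explicitly).
#'
#' @param trace numeric vector
#' @param sampling_rate Hz
#' @param path CSV path
#' @param t0 time of the first sample, seconds
#' @return `path` invisibly (write); list with `trace`, `sampling_rate`,
#'   `t0` (read)
#' @export
write_trace_csv <- function(trace, sampling_rate, path, t0 = 0) {
  tt <- t0 + (seq_along(trace) - 1) / sampling_rate
  utils::write.csv(data.frame(time = tt, pressure = trace), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param declared_rate optional sampling rate overriding the inferred one
#' @export
read_trace_csv <- function(path, declared_rate = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("time", "pressure") %in% names(df))) {
    stop("trace CSV must have 'time' and 'pressure' columns", call. = FALSE)
  }
  fs <- if (!is.null(declared_rate)) declared_rate else {
    1 / median(diff(df$time))
  }
  list(trace = df$pressure, sampling_rate = fs, t0 = df$time[1])
}

#' Export a reconstructed image (or map) as 32-bit float TIFF
#'
#' The pixel array is affinely rescaled to [0, 1] for storage; the scale,
#' offset and pixel size are recorded in a `.json` sidecar so
#' [read_image_tiff()] restores the original values exactly (to float32
#' precision).
#'
#' @param image an [recon_image()] or a plain matrix
#' @param path output `.tif` path
#' @param pixel_size pixel pitch in metres (taken from the image if given)
#' @return `path`, invisibly
#' @export
write_image_tiff <- function(image, path, pixel_size = NULL) {
  if (inherits(image, "eat_image")) {
    pixels <- image$pixels
    pixel_size <- image$grid$pixel_size
  } else {
    pixels <- as.matrix(image)
  }
  lo <- min(pixels); hi <- max(pixels)
  scaled <- if (hi > lo) (pixels - lo) / (hi - lo) else pixels * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  sidecar <- list(pixel_size = pixel_size, offset = lo, scale = hi - lo,
                  nx = nrow(pixels), ny = ncol(pixels))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_image_tiff
#' @return list with `pixels` matrix and `pixel_size` (read)
#' @export
read_image_tiff <- function(path) {
  scaled <- tiff::readTIFF(path)
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::fromJSON(sidecar_path)
    list(pixels = scaled * sc$scale + sc$offset, pixel_size = sc$pixel_size)
  } else {
    list(pixels = scaled, pixel_size = NULL)
  }
}

#' Write a multi-page float TIFF video of reconstructed frames
#'
#' @param images list of [recon_image()] with a common grid and joint
#'   normalization (pixel values in [0, 1])
#' @param path output `.tif` path
#' @param frame_interval seconds between frames (recorded in the sidecar)
#' @return `path`, invisibly
#' @export
write_video_tiff <- function(images, path, frame_interval) {
  pages <- lapply(images, function(im) {
    px <- if (inherits(im, "eat_image")) im$pixels else as.matrix(im)
    pmin(pmax(px, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(
    list(n_frames = length(pages), frame_interval = frame_interval,
         pixel_size = if (inherits(images[[1]], "eat_image"))
           images[[1]]$grid$pixel_size else NULL),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a phantom / experiment configuration file
#'
#' Plain YAML with optional sections `medium` (grid_shape, pixel_size and
#' property values), `electrodes` (centers, radius, mode, voltage),
#' `pulse` (amplitude, width, rise_time, rep_rate) and `array`
#' (n_elements, ring_radius, sampling_rate, n_samples).  Returns the
#' constructed package objects alongside the raw list.
#'
#' @param path YAML file path
#' @return list with any of `medium`, `electrodes`, `pulse`, `geometry`,
#'   plus `raw` (the parsed YAML)
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list(raw = cfg)
  if (!is.null(cfg$medium)) {
    m <- cfg$medium
    args <- m[intersect(names(m), c("sigma", "beta", "kappa", "rho", "c_v", "v_s"))]
    out$medium <- do.call(medium, c(
      list(grid_shape = unlist(m$grid_shape), pixel_size = m$pixel_size), args
    ))
  }
  if (!is.null(cfg$electrodes)) {
    e <- cfg$electrodes
    out$electrodes <- electrode_pair(
      matrix(unlist(e$centers), 2, 2, byrow = TRUE),
      radius = e$radius, mode = e$mode,
      voltage = if (is.null(e$voltage)) 0 else e$voltage
    )
  }
  if (!is.null(cfg$pulse)) {
    p <- cfg$pulse
    out$pulse <- pulse_waveform(
      amplitude = p$amplitude,
      width = if (is.null(p$width)) 100e-9 else p$width,
      rise_time = if (is.null(p$rise_time)) 15e-9 else p$rise_time,
      rep_rate = if (is.null(p$rep_rate)) 1000 else p$rep_rate
    )
  }
  if (!is.null(cfg$array)) {
    a <- cfg$array
    out$geometry <- ring_array(
      n_elements = if (is.null(a$n_elements)) 128 else a$n_elements,
      ring_radius = if (is.null(a$ring_radius)) 0.05 else a$ring_radius,
      sampling_rate = if (is.null(a$sampling_rate)) 40e6 else a$sampling_rate,
      n_samples = a$n_samples
    )
  }
  out
}

#' Run manifest
#'
#' Snapshot of everything needed to re-execute a run: configuration,
#' seed, package version, input/output paths and a timestamp.
#'
#' @param config configuration list or [experiment_config()]
#' @param seed integer seed
#' @param inputs,outputs character vectors of paths
#' @return an object of class `eat_manifest`
#' @export
run_manifest <- function(config, seed, inputs = character(), outputs = character()) {
  structure(
    list(
      config = unclass(config), seed = seed,
      version = as.character(utils::packageVersion("eatlab")),
      inputs = inputs, outputs = outputs,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    class = "eat_manifest"
  )
}

#' @rdname run_manifest
#' @param manifest an `eat_manifest`
#' @param path output JSON path
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "eat_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write any supported object to the eatlab container format
#'
#' Dispatches on class: [channel_data()] and [frame_stack()] objects go to
#' their respective writers.
#'
#' @param data an `eat_channel_data` or `eat_frame_stack`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_container <- function(data, path) {
  if (inherits(data, "eat_channel_data")) {
    write_channel_data(data, path)
  } else if (inherits(data, "eat_frame_stack")) {
    write_frame_stack(data, path)
  } else {
    stop("no container writer for class ", paste(class(data), collapse = "/"),
         call. = FALSE)
  }
}
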