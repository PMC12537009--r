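# Plain-text and TIFF input/output. Sweeps and capacitance tracks travel as
# CSV; movies and stacks as multi-page TIFF with a YAML sidecar carrying the
# acquisition metadata (frame interval, pixel/voxel size, intensity scale).
# TIFF/YAML support uses the optional 'tiff' and 'yaml' packages.

need_pkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    stop(sprintf("package '%s' is required for this I/O function", pkg),
         call. = FALSE)
  }
}

#' Write / read a current sweep as CSV
#'
#' Columns `time`, `voltage`, `current` and (uncorrected sweeps) one
#' `leak_<i>` column per p/4 companion.
#'
#' @param sweep A `current_sweep`.
#' @param path Output CSV path.
#' @return `write_sweep_csv()`: the path, invisibly. `read_sweep_csv()`:
#'   a `current_sweep` (without protocol metadata; analysis functions that
#'   need segment timing require the in-memory object).
#' @export
write_sweep_csv <- function(sweep, path) {
  d <- data.frame(time = sweep$time, voltage = sweep$voltage,
                  current = sweep$current)
  if (!is.null(sweep$leak_sweeps)) {
    leak <- as.data.frame(sweep$leak_sweeps)
    names(leak) <- paste0("leak_", seq_len(ncol(leak)))
    d <- cbind(d, leak)
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  d <- utils::read.csv(path)
  leak_cols <- grep("^leak_", names(d))
  structure(list(time = d$time, voltage = d$voltage, current = d$current,
                 leak_sweeps = if (length(leak_cols)) as.matrix(d[leak_cols]) else NULL,
                 protocol = NULL, meta = list()),
            class = "current_sweep")
}

#' Write / read a hotspot movie as multi-page TIFF + YAML sidecar
#'
#' Frames are stored as 32-bit grayscale pages scaled to \[0, 1\]; the scale
#' factor, frame interval, per-frame command voltages, LJP, baseline count
#' and ramp timing go to the YAML sidecar so the movie round-trips exactly.
#'
#' @param movie A `hotspot_movie`.
#' @param path TIFF path.
#' @param sidecar YAML sidecar path (default `<path>.yml`).
#' @return The TIFF path, invisibly (`write`), or a `hotspot_movie`
#'   (`read`).
#' @export
write_movie_tiff <- function(movie, path, sidecar = paste0(path, ".yml")) {
  need_pkg("tiff"); need_pkg("yaml")
  lo <- min(movie$frames); hi <- max(movie$frames)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(movie$frames)[3]), function(f) {
    t((movie$frames[, , f] - lo) / scale)  # TIFF pages are row-major
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(offset = lo, scale = scale,
               frame_interval = movie$frame_interval,
               pixel_size = movie$pixel_size, n_baseline = movie$n_baseline,
               ljp = movie$ljp, time = movie$time, v_cmd = movie$v_cmd,
               ramp_onset = movie$ramp_onset,
               ramp_duration = movie$ramp_duration)
  yaml::write_yaml(meta, sidecar)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, sidecar = paste0(path, ".yml")) {
  need_pkg("tiff"); need_pkg("yaml")
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- yaml::read_yaml(sidecar)
  frames <- array(0, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) {
    frames[, , f] <- t(pages[[f]]) * meta$scale + meta$offset
  }
  structure(list(frames = frames, time = as.numeric(meta$time),
                 v_cmd = as.numeric(meta$v_cmd),
                 n_baseline = meta$n_baseline,
                 frame_interval = meta$frame_interval,
                 pixel_size = meta$pixel_size, ramp = NULL,
                 ramp_onset = meta$ramp_onset,
                 ramp_duration = meta$ramp_duration, ljp = meta$ljp),
            class = "hotspot_movie")
}

#' Write a two-channel puncta stack as TIFF files + YAML sidecar
#'
#' Channels are written as separate multi-page (z) TIFFs; voxel size and
#' intensity scaling go to the sidecar.
#'
#' @param stack A `puncta_stack`.
#' @param path_a,path_b Per-channel TIFF paths.
#' @param sidecar YAML sidecar path.
#' @return Invisibly, the sidecar path.
#' @export
write_puncta_tiff <- function(stack, path_a, path_b,
                              sidecar = paste0(path_a, ".yml")) {
  need_pkg("tiff"); need_pkg("yaml")
  wr <- function(arr, path) {
    lo <- min(arr); hi <- max(arr)
    scale <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(dim(arr)[3]), function(z) t((arr[, , z] - lo) / scale))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    c(offset = lo, scale = scale)
  }
  sa <- wr(stack$channel_a, path_a)
  sb <- wr(stack$channel_b, path_b)
  yaml::write_yaml(list(voxel_size = stack$voxel_size,
                        channel_a = as.list(sa), channel_b = as.list(sb)),
                   sidecar)
  invisible(sidecar)
}

#' @rdname write_puncta_tiff
#' @export
read_puncta_tiff <- function(path_a, path_b, sidecar = paste0(path_a, ".yml")) {
  need_pkg("tiff"); need_pkg("yaml")
  meta <- yaml::read_yaml(sidecar)
  rd <- function(path, sc) {
    pages <- tiff::readTIFF(path, all = TRUE)
    arr <- array(0, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
    for (z in seq_along(pages)) arr[, , z] <- t(pages[[z]]) * sc$scale + sc$offset
    arr
  }
  structure(list(channel_a = rd(path_a, meta$channel_a),
                 channel_b = rd(path_b, meta$channel_b),
                 voxel_size = as.numeric(meta$voxel_size),
                 truth = NULL),
            class = "puncta_stack")
}
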