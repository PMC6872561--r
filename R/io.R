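#' Read and write hyperspectral cubes
#'
#' The on-disk container is a multi-page TIFF (one page per Raman channel)
#' with two plain-text sidecars next to it: `<stem>.wn.csv` holding the
#' wavenumber axis (columns `channel`, `wavenumber_cm1`) and
#' `<stem>.meta.json` holding acquisition metadata plus the affine scale
#' used to map intensities into the TIFF's [0, 1] 32-bit range. Round trips
#' are lossless to the declared precision (about 1e-9 of the data range).
#'
#' @param cube a [hyper_cube()].
#' @param path TIFF file path (`.tif`/`.tiff`).
#' @param force overwrite an existing file set (default `FALSE`; writing
#'   onto an existing path without `force` is an error).
#' @return `read_cube` returns a validated `hyper_cube`; `write_cube`
#'   returns `path` invisibly.
#' @export
write_cube <- function(cube, path, force = FALSE) {
  stopifnot(inherits(cube, "hyper_cube"))
  side <- cube_sidecars(path)
  if (!force && any(file.exists(c(path, side$wn, side$meta))))
    stop("output exists (use force = TRUE to overwrite): ", path)
  d <- dim(cube$data)
  lo <- min(cube$data)
  scale <- max(max(cube$data) - lo, .Machine$double.eps)
  pages <- lapply(seq_len(d[3]), function(k)
    (cube$data[, , k, drop = TRUE] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  compression = "deflate", reduce = FALSE)
  write.csv(data.frame(channel = seq_len(d[3]),
                       wavenumber_cm1 = cube$axis$wavenumbers),
            side$wn, row.names = FALSE)
  meta <- list(pixel_pitch_nm = cube$pixel_pitch_nm,
               dwell_us = cube$dwell_us,
               resolution_fwhm = cube$axis$resolution_fwhm,
               frame_index = cube$frame_index,
               intensity_offset = lo, intensity_scale = scale)
  jsonlite::write_json(meta, side$meta, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

cube_sidecars <- function(path) {
  stem <- tools::file_path_sans_ext(path)
  list(wn = paste0(stem, ".wn.csv"), meta = paste0(stem, ".meta.json"))
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("cube file not found: ", path)
  side <- cube_sidecars(path)
  if (!file.exists(side$wn))
    stop("missing wavenumber sidecar: ", side$wn)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  wn <- read.csv(side$wn)
  if (!("wavenumber_cm1" %in% names(wn)))
    stop("wavenumber sidecar lacks a 'wavenumber_cm1' column: ", side$wn)
  if (nrow(wn) != length(pages))
    stop("wavenumber sidecar has ", nrow(wn), " rows for ", length(pages),
         " TIFF pages")
  meta <- list(pixel_pitch_nm = 150, dwell_us = 10, resolution_fwhm = NA,
               frame_index = NULL, intensity_offset = 0, intensity_scale = 1)
  if (file.exists(side$meta)) {
    got <- jsonlite::read_json(side$meta, simplifyVector = TRUE)
    meta[names(got)] <- got
  }
  d1 <- dim(pages[[1]])
  data <- array(0, dim = c(d1[1], d1[2], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # tolerate grayscale+alpha
    data[, , k] <- pg * meta$intensity_scale + meta$intensity_offset
  }
  wavenumbers <- as.numeric(wn$wavenumber_cm1)
  if (anyNA(wavenumbers)) stop("non-numeric wavenumbers in sidecar")
  axis <- spectral_axis(wavenumbers, resolution_fwhm = meta$resolution_fwhm)
  if (length(wavenumbers) > 1L && wavenumbers[1] > wavenumbers[2])
    data <- data[, , rev(seq_len(dim(data)[3])), drop = FALSE]
  hyper_cube(data, axis, pixel_pitch_nm = meta$pixel_pitch_nm,
             dwell_us = meta$dwell_us,
             frame_index = if (is.null(meta$frame_index) ||
                               all(is.na(meta$frame_index))) NULL else
               meta$frame_index)
}

#' Read and write time-lapse stacks
#'
#' A stack is written as one cube file per frame, `<stem>_f###.tif`, each
#' carrying its `frame_index` in the metadata sidecar; frames are re-read
#' in frame order.
#'
#' @param frames list of [hyper_cube()] frames.
#' @param stem path stem (without extension).
#' @param force overwrite existing files.
#' @return `read_cube_stack` returns a list of cubes ordered by frame.
#' @export
write_cube_stack <- function(frames, stem, force = FALSE) {
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    fr$frame_index <- i
    write_cube(fr, sprintf("%s_f%03d.tif", stem, i), force = force)
  }
  invisible(stem)
}

#' @rdname write_cube_stack
#' @export
read_cube_stack <- function(stem) {
  paths <- Sys.glob(sprintf("%s_f*.tif", stem))
  if (length(paths) == 0L) stop("no stack frames found for stem: ", stem)
  frames <- lapply(sort(paths), read_cube)
  ord <- order(vapply(frames, function(f)
    if (is.null(f$frame_index)) NA_integer_ else f$frame_index, 1L))
  frames[ord]
}

#' Read and write single spectra as two-column CSV
#'
#' Format: one header line, then `wavenumber_cm1, intensity` rows.
#'
#' @param spec a [spectrum()].
#' @param path CSV file path.
#' @param resolution_fwhm optional instrument line width recorded on the
#'   axis when reading (metadata only).
#' @return `read_spectrum_csv` returns a [spectrum()].
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  write.csv(data.frame(wavenumber_cm1 = spec$axis$wavenumbers,
                       intensity = spec$intensity),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path, resolution_fwhm = NA_real_) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  df <- read.csv(path)
  if (nrow(df) == 0L) stop("empty spectrum file: ", path)
  if (ncol(df) < 2L) stop("expected two columns (wavenumber_cm1, intensity)")
  wn <- suppressWarnings(as.numeric(df[[1]]))
  y <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(wn) || anyNA(y)) stop("non-numeric rows in spectrum CSV: ", path)
  if (length(wn) > 1L && all(diff(wn) < 0)) {
    # spectral_axis flips and warns; flip intensities to match
    y <- rev(y)
  }
  spectrum(y, spectral_axis(wn, resolution_fwhm = resolution_fwhm))
}

#' Read and write event tables as JSON
#'
#' @param table an `event_table` (see [select_events()]).
#' @param path JSON file path.
#' @return `read_event_table` returns an `event_table` data frame.
#' @export
write_event_table <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  jsonlite::write_json(as.data.frame(unclass(table)), path,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("event table not found: ", path)
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  df <- as.data.frame(df)
  class(df) <- c("event_table", "data.frame")
  df
}
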