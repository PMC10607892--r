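# Frame-stack reading and ROI extraction.
#
# Stacks are per-frame still images (16-bit TIFF or PNG), one file per frame
# and band, described by a JSON manifest or discovered by filename pattern.
# ROI coordinates are 0-based with half-open extents
# [x0, x0 + width) x [y0, y0 + height).

#' Rectangular region of interest
#'
#' @param name label (`"face"`, `"patch"` or custom).
#' @param x0,y0 top-left pixel, 0-based.
#' @param width,height extent in pixels, >= 1. The ROI covers the half-open
#'   rectangle `[x0, x0 + width) x [y0, y0 + height)`.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(name, x0, y0, width, height) {
  stopifnot_scalar_number(x0, "x0", min = 0)
  stopifnot_scalar_number(y0, "y0", min = 0)
  stopifnot_scalar_number(width, "width", min = 1)
  stopifnot_scalar_number(height, "height", min = 1)
  structure(list(name = as.character(name), x0 = as.integer(x0),
                 y0 = as.integer(y0), width = as.integer(width),
                 height = as.integer(height)),
            class = "roi_spec")
}

read_image_counts <- function(path, max_value) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = {
      if (!requireNamespace("png", quietly = TRUE)) {
        stop("reading PNG frames requires the 'png' package", call. = FALSE)
      }
      png::readPNG(path)
    },
    stop(sprintf("unsupported frame format '%s' (%s)", ext, path),
         call. = FALSE))
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # first channel if multi
  img * max_value
}

#' Open a two-band frame stack
#'
#' Reads a JSON manifest (as written by [synthesize_frames]) or scans a
#' directory for `*_band<ID>.tif` / `.png` files in lexicographic order, and
#' returns a lazy handle; pixels are read frame by frame during extraction,
#' so arbitrarily long stacks fit in memory.
#'
#' @param source path to a `manifest.json` or to a stack directory.
#' @param bands the two band ids to select (default: the manifest's bands).
#' @return An object of class `frame_stack` with fields `dir`, `files`
#'   (named list per band), `band_ids`, `frame_rate`, `max_value`,
#'   `n_frames`, `dim` (rows, cols of the first frame) and optional `rois`,
#'   `reference`.
#' @export
read_frame_stack <- function(source, bands = NULL) {
  if (dir.exists(source) && file.exists(file.path(source, "manifest.json"))) {
    source <- file.path(source, "manifest.json")
  }
  if (!file.exists(source)) {
    stop(sprintf("frame stack source '%s' does not exist", source),
         call. = FALSE)
  }
  if (dir.exists(source)) {
    dir <- source
    all_files <- sort(list.files(dir, pattern = "\\.(tif|tiff|png)$",
                                 ignore.case = TRUE))
    if (is.null(bands)) {
      stop("`bands` must be given when no manifest is present", call. = FALSE)
    }
    files <- lapply(bands, function(b) {
      f <- all_files[grepl(sprintf("band%s\\.", b), all_files)]
      if (!length(f)) {
        stop(sprintf("no frames found for band '%s' in %s", b, dir),
             call. = FALSE)
      }
      f
    })
    names(files) <- bands
    meta <- list(frame_rate = NA_real_, max_value = 65535, rois = NULL,
                 reference = NULL)
  } else {
    manifest <- jsonlite::read_json(source, simplifyVector = TRUE)
    dir <- dirname(source)
    if (is.null(bands)) bands <- manifest$band_ids
    missing <- setdiff(bands, manifest$band_ids)
    if (length(missing)) {
      stop(sprintf("band(s) %s not present in manifest (has: %s)",
                   paste(missing, collapse = ", "),
                   paste(manifest$band_ids, collapse = ", ")), call. = FALSE)
    }
    files <- manifest$frames[as.character(bands)]
    meta <- list(frame_rate = manifest$frame_rate %||% NA_real_,
                 max_value = manifest$max_value %||% 65535,
                 rois = manifest$rois, reference = manifest$reference)
  }
  if (length(bands) != 2L) {
    stop("exactly two bands must be selected", call. = FALSE)
  }
  n_frames <- unique(lengths(files))
  if (length(n_frames) != 1L) {
    stop("bands have differing frame counts", call. = FALSE)
  }
  first <- file.path(dir, files[[1L]][1L])
  if (!file.exists(first)) {
    stop(sprintf("unreadable frame: %s", first), call. = FALSE)
  }
  img <- read_image_counts(first, meta$max_value)
  structure(list(dir = dir, files = files, band_ids = as.character(bands),
                 frame_rate = meta$frame_rate, max_value = meta$max_value,
                 n_frames = n_frames, dim = dim(img), rois = meta$rois,
                 reference = meta$reference),
            class = "frame_stack")
}

#' Per-frame ROI mean of a frame stack
#'
#' For each frame and band, the arithmetic mean of the pixel values inside
#' the half-open ROI rectangle. Frame dimensions are checked against the
#' first frame; a mismatch is reported with the offending file name.
#'
#' @param stack a `frame_stack`.
#' @param roi a [roi_spec] fully inside the frame.
#' @param frame_rate frame rate for the resulting series; defaults to the
#'   stack's manifest value.
#' @return A [band_series] of ROI means.
#' @export
extract_roi_mean <- function(stack, roi, frame_rate = NULL) {
  stopifnot(inherits(stack, "frame_stack"), inherits(roi, "roi_spec"))
  frame_rate <- frame_rate %||% stack$frame_rate
  if (!is.finite(frame_rate)) {
    stop("frame rate unknown: pass `frame_rate` explicitly", call. = FALSE)
  }
  if (roi$x0 + roi$width > stack$dim[2L] ||
      roi$y0 + roi$height > stack$dim[1L]) {
    stop(sprintf("ROI '%s' (%d+%d x %d+%d) exceeds frame dimensions %d x %d",
                 roi$name, roi$x0, roi$width, roi$y0, roi$height,
                 stack$dim[2L], stack$dim[1L]), call. = FALSE)
  }
  rows <- roi$y0 + seq_len(roi$height)
  cols <- roi$x0 + seq_len(roi$width)
  means <- matrix(NA_real_, stack$n_frames, 2L)
  for (b in 1:2) {
    for (i in seq_len(stack$n_frames)) {
      path <- file.path(stack$dir, stack$files[[b]][i])
      if (!file.exists(path)) {
        stop(sprintf("unreadable frame: %s", path), call. = FALSE)
      }
      img <- read_image_counts(path, stack$max_value)
      if (!identical(dim(img), stack$dim)) {
        stop(sprintf("frame %s has dimensions %s, expected %s",
                     stack$files[[b]][i], paste(dim(img), collapse = "x"),
                     paste(stack$dim, collapse = "x")), call. = FALSE)
      }
      means[i, b] <- mean(img[rows, cols])
    }
  }
  band_series(means, frame_rate, band_ids = stack$band_ids,
              max_value = stack$max_value)
}

#' Area-weighted combination of several ROI mean series
#'
#' Combines per-frame means of multiple (disjoint) ROIs — e.g. nose and both
#' cheeks — into a single series, weighting each ROI by its pixel area, so
#' the result equals the mean over the union of the regions.
#'
#' @param series_list list of [band_series], one per ROI.
#' @param rois list of the matching [roi_spec]s.
#' @return A [band_series].
#' @export
combine_roi_means <- function(series_list, rois) {
  stopifnot(length(series_list) == length(rois), length(rois) >= 1L)
  areas <- vapply(rois, function(r) as.numeric(r$width * r$height), numeric(1))
  acc <- 0
  for (i in seq_along(series_list)) {
    acc <- acc + areas[i] * unclass(series_list[[i]])
  }
  proto <- series_list[[1L]]
  band_series(acc / sum(areas), attr(proto, "frame_rate"),
              band_ids = attr(proto, "band_ids"),
              max_value = attr(proto, "max_value"))
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frames x 2 bands (%s), %d x %d px @ %s fps in %s\n",
              x$n_frames, paste(x$band_ids, collapse = ", "),
              x$dim[1L], x$dim[2L],
              if (is.finite(x$frame_rate)) sprintf("%.6g", x$frame_rate) else "?",
              x$dir))
  invisible(x)
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec> '%s' [%d, %d) x [%d, %d)\n", x$name,
              x$x0, x$x0 + x$width, x$y0, x$y0 + x$height))
  invisible(x)
}
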