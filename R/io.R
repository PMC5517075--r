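#' Write / read multi-channel TIFF images
#'
#' Channels (and z-planes) are stored as TIFF pages at 16 or 8 bit; channel
#' names, pixel size and the z-plane count go to a small JSON sidecar
#' (`<image>.json`) so that a write/read round trip preserves pixels exactly
#' and metadata to full precision. When the sidecar is missing, `read_image()`
#' falls back to `default_pixel_size_um` with a warning.
#'
#' @param img An [mc_image()].
#' @param path Path of the `.tif` file.
#' @param bit_depth Bits per sample used on disk (8 or 16).
#' @return `write_image()` returns `path` invisibly; `read_image()` returns
#'   an [mc_image()].
#' @examples
#' f <- tempfile(fileext = ".tif")
#' img <- mc_image(array(sample(0:255, 64, TRUE), c(8, 8, 1)))
#' write_image(img, f)
#' identical(read_image(f)$pixels, img$pixels)
#' @export
write_image <- function(img, path, bit_depth = 16) {
  stopifnot(inherits(img, "mc_image"))
  top <- 2^bit_depth - 1
  px <- img$pixels
  if (max(px) > top) {
    stop(sprintf("image intensities exceed %d-bit range", bit_depth), call. = FALSE)
  }
  d <- dim(px)
  nz <- if (length(d) == 4L) d[4] else 1L
  pages <- list()
  for (z in seq_len(nz)) {
    for (ch in seq_len(d[3])) {
      plane <- if (length(d) == 4L) px[, , ch, z] else px[, , ch]
      pages[[length(pages) + 1L]] <- round(plane) / top
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bit_depth)
  meta <- list(schema = "tubemorph-image/1", channel_names = img$channel_names,
               pixel_size_um = img$pixel_size_um, n_z = nz, bit_depth = bit_depth)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image
#' @param default_pixel_size_um Pixel size assumed when no sidecar metadata is
#'   found alongside the TIFF.
#' @export
read_image <- function(path, default_pixel_size_um = 0.1) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop(sprintf("cannot read TIFF '%s': %s",
                                                     path, conditionMessage(e)),
                                             call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- sidecar_path(path)
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    ch_names <- meta$channel_names
    psz <- meta$pixel_size_um
    nz <- meta$n_z
    bit_depth <- meta$bit_depth
  } else {
    warning(sprintf("no metadata sidecar for '%s'; assuming %g um/px, one z-plane",
                    path, default_pixel_size_um))
    ch_names <- NULL
    psz <- default_pixel_size_um
    nz <- 1L
    bit_depth <- 16L
  }
  nch <- length(pages) / nz
  if (nch != round(nch)) stop("TIFF page count inconsistent with metadata", call. = FALSE)
  nch <- as.integer(nch)
  top <- 2^bit_depth - 1
  d1 <- dim(pages[[1]])
  px <- array(0, c(d1[1], d1[2], nch, nz))
  k <- 0L
  for (z in seq_len(nz)) {
    for (ch in seq_len(nch)) {
      k <- k + 1L
      px[, , ch, z] <- round(pages[[k]] * top)
    }
  }
  if (nz == 1L) px <- array(px, c(d1[1], d1[2], nch))
  mc_image(px, ch_names, psz)
}

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Write / read ROI collections as JSON
#'
#' ROIs use a small versioned JSON schema (`tubemorph-roi/1`): a list of
#' records with a `type` of `"polyline"`, `"polygon"` or `"landmarks"`, a
#' `name`, the coordinate list, and `width_px` for polylines. Unknown extra
#' fields in a record are preserved on read.
#'
#' @param rois A list of ROI objects (see [roi_polyline()]).
#' @param path Path of the JSON file.
#' @return `write_rois()` returns `path` invisibly; `read_rois()` returns a
#'   list of ROI objects.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_rois(list(roi_polyline(cbind(0:1, 0:1))), f)
#' read_rois(f)
#' @export
write_rois <- function(rois, path) {
  recs <- lapply(rois, function(r) {
    if (inherits(r, "roi_polyline")) {
      list(type = "polyline", name = r$name, width_px = r$width_px,
           points = unname(apply(r$points, 1, as.list)))
    } else if (inherits(r, "roi_polygon")) {
      list(type = "polygon", name = r$name,
           points = unname(apply(r$vertices, 1, as.list)))
    } else if (inherits(r, "roi_landmarks")) {
      list(type = "landmarks", name = r$name,
           points = unname(apply(r$points, 1, as.list)))
    } else {
      stop("unsupported ROI object", call. = FALSE)
    }
  })
  jsonlite::write_json(list(schema = "tubemorph-roi/1", rois = recs), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  doc <- jsonlite::read_json(path)
  recs <- if (!is.null(doc$rois)) doc$rois else doc
  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    if (is.null(r$type)) {
      stop(sprintf("ROI record %d has no 'type' field", i), call. = FALSE)
    }
    pts <- tryCatch(
      do.call(rbind, lapply(r$points, function(p) as.numeric(unlist(p)[1:2]))),
      error = function(e) NULL)
    if (is.null(pts)) {
      stop(sprintf("ROI record %d ('%s'): malformed coordinates", i, r$type),
           call. = FALSE)
    }
    roi <- switch(r$type,
      polyline = roi_polyline(pts, name = r$name %||% "polyline",
                              width_px = r$width_px %||% 1),
      polygon = roi_polygon(pts, name = r$name %||% "polygon"),
      landmarks = roi_landmarks(pts, name = r$name %||% "landmarks"),
      stop(sprintf("ROI record %d: unknown type '%s'", i, r$type), call. = FALSE)
    )
    extra <- setdiff(names(r), c("type", "name", "points", "width_px"))
    if (length(extra)) roi$extra <- r[extra]
    out[[i]] <- roi
  }
  out
}

#' Write / read phantom ground truth as JSON
#'
#' Ground-truth records produced by the phantom generators serialize to a JSON
#' sidecar (`tubemorph-truth/1` schema) and read back with tables restored as
#' tibbles and coordinate lists as matrices, so truth can accompany an image
#' on disk and round-trip losslessly to numeric precision.
#'
#' @param truth A `ground_truth` object from a generator.
#' @param path Path of the JSON file.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns a `ground_truth` object.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  payload <- list(schema = "tubemorph-truth/1", kind = truth$kind,
                  fields = unclass(truth))
  payload$fields$kind <- NULL
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  fields <- lapply(doc$fields, function(f) {
    if (is.data.frame(f)) tibble::as_tibble(f) else f
  })
  # coordinate blocks come back as plain matrices already (simplifyVector)
  structure(c(list(kind = doc$kind), fields), class = "ground_truth")
}

new_ground_truth <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> kind: %s; fields: %s\n", x$kind,
              paste(setdiff(names(x), "kind"), collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
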