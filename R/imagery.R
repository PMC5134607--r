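# Image loading, ROI polygons/masks, and chromatic-coordinate extraction.
#
# Conventions (fixed package-wide):
#  * pixel coordinates are 0-based (row, col), origin at the top-left;
#  * a pixel belongs to a polygon when its centre lies inside or on the
#    boundary;
#  * timestamps are naive local camera time parsed from the filename.

#' List and timestamp a directory of camera frames
#'
#' Parses acquisition times out of image filenames and returns an index of
#' decodable frames sorted by time. Files whose names do not parse under the
#' supplied pattern are skipped (counted, not fatal).
#'
#' @param paths Character vector of image file paths (JPEG or PNG), or a
#'   single directory that will be listed.
#' @param timestamp_pattern A [strptime()] format matched against the
#'   filename without directory or extension, e.g. `"site_%Y_%m_%d_%H%M"`.
#' @return A tibble with columns `path`, `source_id` (filename stem), `time`
#'   (POSIXct) and `doy` (fractional day of year), sorted by `time`. The
#'   number of unparseable files is attached as attribute `n_skipped`.
#' @export
load_image_series <- function(paths, timestamp_pattern = "site_%Y_%m_%d_%H%M") {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(jpe?g|png)$", ignore.case = TRUE,
                        full.names = TRUE)
  }
  if (length(paths) == 0) {
    abort("no image files found: empty input")
  }
  stem <- sub("\\.[A-Za-z]+$", "", basename(paths))
  time <- as.POSIXct(strptime(stem, timestamp_pattern, tz = "UTC"))
  bad <- is.na(time)
  if (any(bad)) {
    warn(sprintf("%d file(s) with unparseable timestamps skipped", sum(bad)))
  }
  out <- tibble::tibble(
    path = paths[!bad],
    source_id = stem[!bad],
    time = time[!bad],
    doy = fractional_doy(time[!bad])
  )
  out <- dplyr::arrange(out, .data$time)
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Read one camera frame as 8-bit digital numbers
#'
#' @param path Path to a JPEG or PNG image with 3 colour channels.
#' @param time Optional POSIXct acquisition time to attach.
#' @return A `pheno_frame`: list with `pixels` (H x W x 3 integer array of
#'   digital numbers 0--255), `time`, and `source_id`.
#' @export
read_frame <- function(path, time = NULL) {
  ext <- tolower(sub(".*\\.", "", path))
  arr <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    abort(sprintf("unsupported image format: '%s'", ext))
  )
  if (length(dim(arr)) == 2) {
    abort(sprintf("image '%s' is single-channel; 3 channels required", basename(path)))
  }
  if (dim(arr)[3] > 3) arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
  dn <- array(as.integer(round(arr * 255)), dim = dim(arr))
  structure(
    list(pixels = dn, time = time,
         source_id = sub("\\.[A-Za-z]+$", "", basename(path))),
    class = "pheno_frame"
  )
}

# --- polygons ---------------------------------------------------------------

# Vectorised even-odd (crossing number) point-in-polygon with boundary
# inclusion: a point on an edge (within eps) counts as inside.
point_in_polygon <- function(py, px, vy, vx, eps = 1e-9) {
  n <- length(vy)
  inside <- rep(FALSE, length(py))
  on_edge <- rep(FALSE, length(py))
  j <- n
  for (i in seq_len(n)) {
    yi <- vy[i]; xi <- vx[i]; yj <- vy[j]; xj <- vx[j]
    # boundary test: point within eps of segment (i, j)
    dy <- yj - yi; dx <- xj - xi
    len2 <- dy^2 + dx^2
    if (len2 > 0) {
      t <- pmin(1, pmax(0, ((py - yi) * dy + (px - xi) * dx) / len2))
      d2 <- (py - (yi + t * dy))^2 + (px - (xi + t * dx))^2
      on_edge <- on_edge | d2 <= eps
    } else {
      on_edge <- on_edge | ((py - yi)^2 + (px - xi)^2 <= eps)
    }
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

polygon_area <- function(vy, vx) {
  n <- length(vy)
  j <- c(n, seq_len(n - 1))
  abs(sum(vx[j] * vy - vx * vy[j])) / 2
}

#' Rasterise a polygon region of interest
#'
#' Builds the boolean pixel mask of a polygon ROI. A pixel is in the mask when
#' its centre -- the integer (row, col) coordinate itself, 0-based from the
#' top-left -- is inside the polygon or on its boundary.
#'
#' @param vertices A 2-column matrix or data frame of polygon vertices as
#'   (row, col), 0-based, in drawing order; at least 3 vertices.
#' @param image_height,image_width Frame dimensions in pixels.
#' @param name ROI name.
#' @return A `pheno_roi`: list with `name`, `vertices` (matrix), and `mask`
#'   (`image_height` x `image_width` logical).
#' @export
build_roi_mask <- function(vertices, image_height, image_width, name = "roi") {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3) abort("a polygon ROI needs at least 3 vertices")
  storage.mode(vertices) <- "double"
  vy <- vertices[, 1]; vx <- vertices[, 2]
  if (any(vy < 0 | vy > image_height - 1 | vx < 0 | vx > image_width - 1)) {
    abort("ROI vertices fall outside the image bounds")
  }
  if (polygon_area(vy, vx) <= 0) {
    abort(sprintf("degenerate (zero-area) polygon for ROI '%s'", name))
  }
  grid <- expand.grid(row = 0:(image_height - 1), col = 0:(image_width - 1))
  inside <- point_in_polygon(grid$row, grid$col, vy, vx)
  mask <- matrix(FALSE, image_height, image_width)
  mask[cbind(grid$row + 1, grid$col + 1)] <- inside
  if (!any(mask)) abort(sprintf("ROI '%s' covers no pixel centres", name))
  colnames(vertices) <- c("row", "col")
  structure(list(name = name, vertices = vertices, mask = mask),
            class = "pheno_roi")
}

#' @export
print.pheno_roi <- function(x, ...) {
  cat(sprintf("<pheno_roi '%s': %d vertices, %d pixels in a %d x %d mask>\n",
              x$name, nrow(x$vertices), sum(x$mask),
              nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

#' Write / read ROI vertex files
#'
#' Plain-text ROI format: one block per ROI, a `name: <name>` header followed
#' by one `row,col` vertex per line; blocks separated by blank lines.
#' Coordinates round-trip bit-exactly.
#'
#' @param rois A `pheno_roi` or list of them.
#' @param path File path.
#' @return `write_roi()` returns `path` invisibly; `read_roi()` returns a
#'   named list of vertex matrices (rebuild masks with [build_roi_mask()]).
#' @export
write_roi <- function(rois, path) {
  if (inherits(rois, "pheno_roi")) rois <- list(rois)
  blocks <- purrr::map_chr(rois, function(r) {
    paste(c(paste0("name: ", r$name),
            sprintf("%.17g,%.17g", r$vertices[, 1], r$vertices[, 2])),
          collapse = "\n")
  })
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  lines <- readLines(path)
  starts <- grep("^name:", lines)
  if (length(starts) == 0) abort(sprintf("no 'name:' header found in '%s'", path))
  ends <- c(starts[-1] - 1, length(lines))
  out <- purrr::map2(starts, ends, function(s, e) {
    body <- lines[(s + 1):e]
    body <- body[nzchar(trimws(body))]
    parts <- do.call(rbind, strsplit(body, ","))
    m <- cbind(row = as.numeric(parts[, 1]), col = as.numeric(parts[, 2]))
    m
  })
  names(out) <- trimws(sub("^name:", "", lines[starts]))
  out
}

# --- chromatic coordinates --------------------------------------------------

#' Chromatic coordinates of one frame within an ROI
#'
#' Computes green/red/blue chromatic coordinates, each channel's digital
#' number divided by the sum of the three channels (GCC = G / (R + G + B)),
#' over the pixels of an ROI. Pixels with R + G + B = 0 carry no chromatic
#' information and are excluded and counted.
#'
#' @param frame A `pheno_frame` from [read_frame()].
#' @param roi A `pheno_roi`.
#' @param scope `"roi-average"` (one triple for the ROI) or `"per-pixel"`
#'   (one triple per masked pixel).
#' @param average For roi-average scope: `"ratio-of-means"` (default;
#'   chromatic coordinates of the per-channel mean digital numbers, robust to
#'   dark pixels) or `"mean-of-ratios"` (mean of per-pixel coordinates).
#' @return A tibble. For roi-average: one row with `gcc`, `rcc`, `bcc`,
#'   `n_pixels` (pixels used) and `n_zero` (excluded zero-sum pixels); all
#'   columns `NA` (missing sample) if every pixel is zero. For per-pixel: one
#'   row per usable pixel with 0-based `row`, `col` and the coordinates.
#' @export
extract_chromatic <- function(frame, roi,
                              scope = c("roi-average", "per-pixel"),
                              average = c("ratio-of-means", "mean-of-ratios")) {
  scope <- match.arg(scope)
  average <- match.arg(average)
  px <- frame$pixels
  if (nrow(roi$mask) != dim(px)[1] || ncol(roi$mask) != dim(px)[2]) {
    abort("ROI mask dimensions do not match the frame")
  }
  idx <- which(roi$mask, arr.ind = TRUE)
  r <- as.numeric(px[cbind(idx, 1L)])
  g <- as.numeric(px[cbind(idx, 2L)])
  b <- as.numeric(px[cbind(idx, 3L)])
  s <- r + g + b
  zero <- s == 0
  n_zero <- sum(zero)
  if (n_zero > 0) {
    inform(sprintf("frame %s: %d zero-DN pixel(s) excluded",
                   frame$source_id %||% "?", n_zero))
  }
  if (scope == "per-pixel") {
    keep <- !zero
    return(tibble::tibble(
      row = idx[keep, 1] - 1L, col = idx[keep, 2] - 1L,
      gcc = g[keep] / s[keep], rcc = r[keep] / s[keep], bcc = b[keep] / s[keep]
    ))
  }
  if (all(zero)) {
    return(tibble::tibble(gcc = NA_real_, rcc = NA_real_, bcc = NA_real_,
                          n_pixels = 0L, n_zero = n_zero))
  }
  if (average == "ratio-of-means") {
    mr <- mean(r[!zero]); mg <- mean(g[!zero]); mb <- mean(b[!zero])
    ms <- mr + mg + mb
    trip <- c(mg, mr, mb) / ms
  } else {
    trip <- c(mean(g[!zero] / s[!zero]), mean(r[!zero] / s[!zero]),
              mean(b[!zero] / s[!zero]))
  }
  tibble::tibble(gcc = trip[1], rcc = trip[2], bcc = trip[3],
                 n_pixels = sum(!zero), n_zero = n_zero)
}

#' Extract an ROI-averaged chromatic time series from an image index
#'
#' Maps [read_frame()] + [extract_chromatic()] over the frames of
#' [load_image_series()]. Undecodable frames are skipped and counted.
#'
#' @param images Tibble from [load_image_series()].
#' @param roi A `pheno_roi`.
#' @inheritParams extract_chromatic
#' @return A sub-daily chromatic series tibble with columns `time`, `doy`,
#'   `roi`, `gcc`, `rcc`, `bcc`, `n_pixels`; attribute `n_unreadable` counts
#'   skipped frames. Attribute `aggregation` is `"sub-daily"`.
#' @export
extract_series <- function(images, roi,
                           average = c("ratio-of-means", "mean-of-ratios")) {
  average <- match.arg(average)
  rows <- purrr::pmap(list(images$path, images$time, images$doy),
    function(path, time, doy) {
      fr <- tryCatch(read_frame(path, time), error = function(e) NULL)
      if (is.null(fr)) return(NULL)
      cc <- extract_chromatic(fr, roi, scope = "roi-average", average = average)
      dplyr::bind_cols(tibble::tibble(time = time, doy = doy, roi = roi$name), cc)
    })
  n_bad <- sum(purrr::map_lgl(rows, is.null))
  if (n_bad > 0) warn(sprintf("%d unreadable frame(s) skipped", n_bad))
  out <- dplyr::bind_rows(rows)
  out <- dplyr::select(out, -dplyr::any_of("n_zero"))
  out <- dplyr::filter(out, !is.na(.data$gcc))
  attr(out, "n_unreadable") <- n_bad
  attr(out, "aggregation") <- "sub-daily"
  out
}
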