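#' Binarize a frame by Otsu thresholding
#'
#' The frame is converted to grayscale by fixed luma weights and split at
#' the Otsu threshold. By default the fly-polarity side is darker than
#' background (dark fly on a light slide); set `polarity = "light"` for
#' inverted footage.
#'
#' @param frame `h x w` matrix or `h x w x 3` array (0--255), or a
#'   [strif_frames()] video (its first frame is used).
#' @param polarity which side of the threshold is foreground.
#' @return Logical `h x w` mask. A zero-variance frame yields an empty mask
#'   with a warning.
#' @export
binarize <- function(frame, polarity = c("dark", "light")) {
  polarity <- match.arg(polarity)
  if (inherits(frame, "strif_frames")) frame <- get_frame(frame, 1L)
  g <- to_gray(frame) / 255
  if (sd(g) == 0) {
    warning("uniform frame: no contrast, returning empty mask")
    return(matrix(FALSE, nrow(g), ncol(g)))
  }
  th <- EBImage::otsu(EBImage::Image(g), range = c(0, 1))
  if (polarity == "dark") g < th else g > th
}

#' Morphologically clean a binary mask
#'
#' Opening followed by closing with a disc structuring element, removing
#' sub-kernel specks and filling sub-kernel holes.
#'
#' @param mask logical matrix.
#' @param kernel_radius radius of the disc kernel in pixels.
#' @return Logical matrix of the same shape.
#' @export
clean_mask <- function(mask, kernel_radius = 1) {
  stopifnot(is.matrix(mask))
  kern <- EBImage::makeBrush(2L * as.integer(kernel_radius) + 1L, shape = "disc")
  m <- EBImage::Image(mask * 1)
  m <- EBImage::closing(EBImage::opening(m, kern), kern)
  EBImage::imageData(m) > 0.5
}

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so
# labels touching diagonally are merged via union-find.
label_components8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  k <- max(lab)
  if (k <= 1) return(lab)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  h <- nrow(lab); w <- ncol(lab)
  for (shift in list(c(1, 1), c(1, -1))) {
    a <- lab[seq_len(h - 1), if (shift[2] > 0) seq_len(w - 1) else 2:w]
    b <- lab[2:h, if (shift[2] > 0) 2:w else seq_len(w - 1)]
    touch <- which(a > 0 & b > 0 & a != b)
    for (i in touch) {
      ra <- find(a[i]); rb <- find(b[i])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(k), find, 0L)
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Detect restrained flies in a frame
#'
#' Binarizes the frame, cleans the mask, labels 8-connected components,
#' filters them to `[min_area, max_area]` and assigns fly ids in raster
#' order of centroids (top-to-bottom, then left-to-right). Each fly gets a
#' fixed square ROI centred on its centroid with side
#' `roi_scale * max(blob height, blob width)` (odd-rounded); `roi_scale = 1`
#' is the tight blob square, the default 2 leaves margin for limb and
#' body excursions during flailing (the cleaned blob is slightly eroded
#' by morphological opening, so the doubled side stays below the minimum
#' fly separation and ROIs remain disjoint). ROIs are clipped to frame bounds,
#' preserving side length by shifting where possible.
#'
#' @param frame frame matrix/array or [strif_frames()] video (first frame).
#' @param min_area,max_area component area bounds in pixels.
#' @param n_expected expected number of flies; a mismatch flags the result.
#' @param kernel_radius morphological cleaning radius.
#' @param polarity foreground polarity, see [binarize()].
#' @param roi_scale ROI side as a multiple of the max blob dimension.
#' @return A `fly_detections` data frame with columns `fly_id`,
#'   `centroid_row`, `centroid_col`, `area`, `height`, `width`, `roi_top`,
#'   `roi_left`, `roi_side` and attribute `flagged` (count mismatch or
#'   clipped ROI).
#' @export
detect_flies <- function(frame, min_area = 30, max_area = 2000,
                         n_expected = 6, kernel_radius = 1,
                         polarity = "dark", roi_scale = 2) {
  stopifnot(is_count(n_expected))
  if (inherits(frame, "strif_frames")) frame <- get_frame(frame, 1L)
  mask <- clean_mask(binarize(frame, polarity), kernel_radius)
  lab <- label_components8(mask)
  k <- max(lab)
  if (k == 0) stop_param("detection failure: no components in mask")
  idx <- which(lab > 0)
  labs <- lab[idx]
  rows <- (idx - 1) %% nrow(lab) + 1
  cols <- (idx - 1) %/% nrow(lab) + 1
  stats <- data.frame(
    label = seq_len(k),
    area = as.vector(tabulate(labs, k)),
    centroid_row = as.vector(tapply(rows, labs, mean)),
    centroid_col = as.vector(tapply(cols, labs, mean)),
    height = as.vector(tapply(rows, labs, function(r) diff(range(r)) + 1)),
    width = as.vector(tapply(cols, labs, function(c) diff(range(c)) + 1)))
  stats <- stats[stats$area >= min_area & stats$area <= max_area, ]
  if (nrow(stats) == 0)
    stop_param("detection failure: no components within [%g, %g] px",
               min_area, max_area)
  # raster order: group near-equal centroid rows (within a blob height)
  # into arena rows, then sort left-to-right within each
  ord <- order(stats$centroid_row)
  sr <- stats$centroid_row[ord]
  grp <- cumsum(c(1, diff(sr) > max(stats$height)))
  stats <- stats[ord, ][order(grp, stats$centroid_col[ord]), ]
  stats$fly_id <- seq_len(nrow(stats))
  h <- nrow(mask); w <- ncol(mask)
  clipped <- FALSE
  roi <- t(vapply(seq_len(nrow(stats)), function(i) {
    side <- max(stats$height[i], stats$width[i]) * roi_scale
    side <- 2L * floor(side / 2) + 1L  # odd, so the centre pixel is central
    side <- min(side, h, w)
    top <- round(stats$centroid_row[i]) - (side - 1L) %/% 2L
    left <- round(stats$centroid_col[i]) - (side - 1L) %/% 2L
    # shift inside the frame, preserving side length
    if (top < 1L || left < 1L || top + side - 1L > h || left + side - 1L > w)
      clipped <<- TRUE
    top <- min(max(top, 1L), h - side + 1L)
    left <- min(max(left, 1L), w - side + 1L)
    c(top, left, side)
  }, numeric(3)))
  out <- data.frame(fly_id = stats$fly_id,
                    centroid_row = stats$centroid_row,
                    centroid_col = stats$centroid_col,
                    area = stats$area, height = stats$height,
                    width = stats$width,
                    roi_top = as.integer(roi[, 1]),
                    roi_left = as.integer(roi[, 2]),
                    roi_side = as.integer(roi[, 3]))
  rownames(out) <- NULL
  structure(out, flagged = (nrow(out) != n_expected) || clipped,
            n_expected = n_expected,
            class = c("fly_detections", "data.frame"))
}

#' Export detections to CSV
#'
#' Columns are joinable with a genotype metadata table by arena position
#' (`fly_id` follows raster order of the arena).
#'
#' @param detections a `fly_detections` data frame.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_detections <- function(detections, path) {
  write.csv(as.data.frame(detections), path, row.names = FALSE)
  invisible(path)
}

# ROI of one fly as a list(top, left, side)
detection_roi <- function(detections, fly) {
  i <- match(fly, detections$fly_id)
  list(top = detections$roi_top[i], left = detections$roi_left[i],
       side = detections$roi_side[i])
}
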