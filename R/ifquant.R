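#' Generate a synthetic multi-channel embryo image with truth masks
#'
#' Places `n_nuclei` non-overlapping disk-shaped nuclei on a dark
#' background. The DAPI channel carries the nuclear stain used for
#' segmentation; the remaining channels (e.g. an EED-like or H3K27me3-like
#' signal) have per-nucleus intensities given by `nucleus_intensity`.
#' Gaussian noise of standard deviation `noise_sd` is added everywhere.
#' A nucleus-free rectangle is reserved in the top-left corner as the
#' background region for intensity correction. Intensities are arbitrary
#' units in [0, 1] so images round-trip through 16-bit TIFF.
#'
#' @param n_nuclei number of nuclei.
#' @param nucleus_intensity named numeric, one entry per channel (must
#'   include `dapi`): intensity inside nuclei.
#' @param background_level intensity outside nuclei (all channels).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed; the image is reproducible given it.
#' @param dim image height and width in pixels.
#' @param radius nucleus radius in pixels.
#' @return List: `image` (array height x width x channel, dimnames on
#'   channel), `truth_masks` (integer label matrix), `background_region`
#'   (list x0, x1, y0, y1, inclusive pixel bounds).
#' @export
make_synthetic_embryo_image <- function(n_nuclei,
                                        nucleus_intensity = c(dapi = 0.8,
                                                              signal = 0.5),
                                        background_level = 0.05,
                                        noise_sd = 0.01, seed = 1,
                                        dim = c(192L, 192L), radius = 14L) {
  stopifnot(n_nuclei >= 1, "dapi" %in% names(nucleus_intensity),
            all(nucleus_intensity > 0), background_level >= 0,
            noise_sd >= 0)
  set.seed(seed)
  h <- dim[1]; w <- dim[2]
  bg <- list(x0 = 1L, x1 = max(8L, w %/% 8L), y0 = 1L, y1 = max(8L, h %/% 8L))

  centers <- matrix(numeric(0), ncol = 2)
  attempts <- 0L
  while (nrow(centers) < n_nuclei) {
    attempts <- attempts + 1L
    if (attempts > 5000L)
      stop("cannot place ", n_nuclei, " non-overlapping nuclei in a ",
           h, "x", w, " frame")
    cx <- runif(1, radius + 1, w - radius)
    cy <- runif(1, radius + 1, h - radius)
    # keep out of the reserved background rectangle
    if (cx - radius <= bg$x1 + 2 && cy - radius <= bg$y1 + 2) next
    if (nrow(centers) > 0 &&
        any((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2 <
              (2 * radius + 2)^2)) next
    centers <- rbind(centers, c(cx, cy))
  }

  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  labels <- matrix(0L, h, w)
  for (i in seq_len(n_nuclei)) {
    inside <- (xs - centers[i, 1])^2 + (ys - centers[i, 2])^2 <= radius^2
    labels[inside] <- i
  }

  channels <- names(nucleus_intensity)
  img <- array(0, dim = c(h, w, length(channels)),
               dimnames = list(NULL, NULL, channels))
  for (ch in channels) {
    plane <- matrix(background_level, h, w)
    plane[labels > 0L] <- nucleus_intensity[[ch]]
    if (noise_sd > 0) plane <- plane + rnorm(h * w, 0, noise_sd)
    img[, , ch] <- pmin(pmax(plane, 0), 1)
  }
  list(image = img, truth_masks = labels, background_region = bg)
}

#' Segment nuclei from a DAPI channel
#'
#' Thresholds the DAPI image (Otsu's method by default, matching a
#' parameter-free "Threshold" step), binarizes, and labels connected
#' components; each component becomes one region of interest. Touching
#' nuclei merge into a single ROI — a documented limitation of
#' threshold-based nucleus counting.
#'
#' @param dapi numeric matrix in [0, 1].
#' @param threshold `"otsu"` or a numeric cutoff.
#' @param min_pixels components smaller than this are dropped as specks.
#' @return Integer label matrix (0 = background); attribute `n_rois`
#'   carries the component count. A blank image yields zero ROIs with a
#'   warning.
#' @export
segment_nuclei <- function(dapi, threshold = "otsu", min_pixels = 9L) {
  stopifnot(is.matrix(dapi))
  thr <- if (identical(threshold, "otsu"))
    EBImage::otsu(EBImage::Image(dapi), range = c(0, 1)) else
    as.numeric(threshold)
  binary <- dapi > thr
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(binary)))
  labels <- matrix(as.integer(labels), nrow = nrow(dapi))
  sizes <- tabulate(labels)
  keep <- which(sizes >= min_pixels)
  relabel <- integer(max(labels, 1L))
  relabel[keep] <- seq_along(keep)
  labels[labels > 0L] <- relabel[labels[labels > 0L]]
  if (max(labels) == 0L) warning("no nuclei found above threshold")
  attr(labels, "n_rois") <- max(labels)
  labels
}

#' Measure background-corrected nuclear intensities
#'
#' For each channel, computes the mean intensity of every labeled nucleus
#' ROI, subtracts the mean of the non-nuclear background region, and
#' averages nuclei to a per-embryo mean. The background region must be
#' disjoint from all nuclei.
#'
#' @param image array height x width x channel (channel dimnames) or a
#'   single matrix.
#' @param labels integer label matrix from [segment_nuclei()].
#' @param background_region list (x0, x1, y0, y1) inclusive pixel bounds,
#'   or a logical matrix mask.
#' @param embryo_id sample label carried into the output.
#' @return List: `nuclei` (data.frame embryo_id, nucleus_id, channel,
#'   raw_mean, background_mean, corrected_mean), `embryo_means` (named
#'   per-channel means over nuclei), `n_nuclei`.
#' @export
measure_embryo <- function(image, labels, background_region,
                           embryo_id = "embryo") {
  if (is.matrix(image))
    image <- array(image, dim = c(dim(image), 1L),
                   dimnames = list(NULL, NULL, "signal"))
  channels <- dimnames(image)[[3]]
  if (is.null(channels)) channels <- sprintf("ch%d", seq_len(dim(image)[3]))
  bg_mask <- if (is.matrix(background_region)) background_region else {
    m <- matrix(FALSE, nrow(labels), ncol(labels))
    m[background_region$y0:background_region$y1,
      background_region$x0:background_region$x1] <- TRUE
    m
  }
  if (any(labels[bg_mask] > 0L))
    stop("background region overlaps a nucleus ROI")
  n_nuclei <- max(labels)
  rows <- list()
  for (k in seq_along(channels)) {
    plane <- image[, , k]
    bg_mean <- mean(plane[bg_mask])
    for (i in seq_len(n_nuclei)) {
      raw <- mean(plane[labels == i])
      rows[[length(rows) + 1L]] <- data.frame(
        embryo_id = embryo_id, nucleus_id = i, channel = channels[k],
        raw_mean = raw, background_mean = bg_mean,
        corrected_mean = raw - bg_mean, stringsAsFactors = FALSE)
    }
  }
  nuclei <- if (length(rows)) do.call(rbind, rows) else
    data.frame(embryo_id = character(0), nucleus_id = integer(0),
               channel = character(0), raw_mean = numeric(0),
               background_mean = numeric(0), corrected_mean = numeric(0))
  embryo_means <- vapply(channels, function(ch)
    mean(nuclei$corrected_mean[nuclei$channel == ch]), numeric(1))
  list(nuclei = nuclei, embryo_means = embryo_means, n_nuclei = n_nuclei)
}

#' Bin an embryo into a developmental stage by cell count
#'
#' Stage bins: 2-3 cells = ~2-cell, 4-5 = ~4-cell, 6-10 = ~8-cell,
#' 14-19 = ~16-cell. Counts outside every bin (1, 11-13, 20+) are
#' "unstaged" rather than forced into a nearest bin.
#'
#' @param n_cells positive integer cell count.
#' @return One of `"~2-cell"`, `"~4-cell"`, `"~8-cell"`, `"~16-cell"`,
#'   `"unstaged"`.
#' @export
stage_embryo <- function(n_cells) {
  stopifnot(length(n_cells) == 1L, n_cells >= 1)
  if (n_cells >= 2 && n_cells <= 3) "~2-cell"
  else if (n_cells >= 4 && n_cells <= 5) "~4-cell"
  else if (n_cells >= 6 && n_cells <= 10) "~8-cell"
  else if (n_cells >= 14 && n_cells <= 19) "~16-cell"
  else "unstaged"
}

#' Write / read a multi-channel image as 16-bit TIFF
#'
#' One directory (page) per channel; channel names are preserved in the
#' page order given by `channel_order` on read.
#'
#' @param image array height x width x channel with values in [0, 1].
#' @param path file path.
#' @param channel_order channel names assumed on read.
#' @return `write_image_tiff`: the path, invisibly; `read_image_tiff`:
#'   the image array.
#' @export
write_image_tiff <- function(image, path) {
  planes <- lapply(seq_len(dim(image)[3]), function(k) image[, , k])
  tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, channel_order = c("dapi", "signal")) {
  planes <- tiff::readTIFF(path, all = TRUE)
  stopifnot(length(planes) == length(channel_order))
  img <- array(0, dim = c(dim(planes[[1]]), length(planes)),
               dimnames = list(NULL, NULL, channel_order))
  for (k in seq_along(planes)) img[, , k] <- planes[[k]]
  img
}
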