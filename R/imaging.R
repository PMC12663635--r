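#' Histogram-mode background estimation
#'
#' The background level of a channel is the most populated bin of its
#' intensity histogram, computed over an optional demarcated region. For
#' integer-valued data the bin width defaults to one grey level; for float
#' data, to 256 bins over the observed range.
#'
#' @param image Numeric matrix.
#' @param region Optional logical mask restricting the histogram.
#' @param bin_width Optional bin width override.
#' @return The background level (centre of the modal bin).
#' @export
estimate_background <- function(image, region = NULL, bin_width = NULL) {
  v <- if (is.null(region)) as.numeric(image) else {
    stopifnot(any(region))
    as.numeric(image[region])
  }
  integerish <- all(v == round(v))
  if (is.null(bin_width))
    bin_width <- if (integerish) 1 else diff(range(v)) / 256
  if (bin_width <= 0) return(v[1])   # constant float image
  bins <- floor((v - min(v)) / bin_width)
  tab <- table(bins)
  modal <- as.numeric(names(tab)[which.max(tab)])
  min(v) + (modal + if (integerish && bin_width == 1) 0 else 0.5) * bin_width
}

#' Subtract a background level, clamping at zero
#'
#' @param image Numeric matrix.
#' @param level Background level, e.g. from [estimate_background()].
#' @export
subtract_background <- function(image, level) pmax(image - level, 0)

disc_brush <- function(radius) {
  EBImage::makeBrush(2 * floor(radius) + 1, shape = "disc")
}

#' White top-hat haze correction
#'
#' Subtracts the morphological opening with a disc structuring element,
#' removing structures wider than the disc (smooth haze, gradients) while
#' preserving puncta narrower than it.
#'
#' @param image Numeric matrix.
#' @param radius Disc radius in pixels; must exceed the punctum radius.
#' @export
tophat_correct <- function(image, radius = 8) {
  stopifnot(radius >= 1)
  mx <- max(image)
  if (mx == 0) return(image)
  out <- EBImage::whiteTopHat(image / mx, disc_brush(radius)) * mx
  matrix(pmax(as.numeric(out), 0), nrow(image), ncol(image))
}

#' Segment the nucleus of a single-cell crop
#'
#' Adaptive (moving-average) thresholding of the nuclear channel, followed
#' by hole filling and selection of the largest connected component — one
#' dominant nucleus per crop is assumed.
#'
#' @param nuclear_channel Numeric matrix.
#' @param window Half-width of the moving-average threshold window, pixels;
#'   default a quarter of the image side, so a nucleus filling much of the
#'   crop is still resolved against its surroundings.
#' @param offset Threshold offset as a fraction of the channel's dynamic
#'   range, default 0.05.
#' @return Logical nuclear mask.
#' @export
segment_nucleus <- function(nuclear_channel, window = NULL, offset = 0.05) {
  img <- nuclear_channel
  rng <- range(img)
  if (diff(rng) == 0) stop("no foreground component", call. = FALSE)
  norm <- (img - rng[1]) / diff(rng)
  if (is.null(window)) window <- floor(min(dim(img)) / 4)
  window <- min(window, floor((min(dim(img)) - 2) / 2))
  mask <- EBImage::thresh(norm, w = window, h = window, offset = offset)
  mask <- EBImage::fillHull(mask)
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n == 0) stop("no foreground component", call. = FALSE)
  sizes <- tabulate(lab[lab > 0], nbins = n)
  matrix(lab == which.max(sizes), nrow(img), ncol(img))
}

#' Perinuclear ring fraction of a lysosome channel
#'
#' The nuclear mask is dilated by `ring_width` pixels with a disc element
#' and the original mask subtracted, leaving a ring around the nucleus; the
#' measurement is the fraction of the whole-frame (one cell per crop)
#' integrated intensity that falls inside the ring.
#'
#' @param nuclear_mask Logical matrix.
#' @param lysosome_channel Numeric matrix of the same shape (background-
#'   corrected).
#' @param ring_width Ring width in pixels, default 30.
#' @param cell_id Identifier carried into the result.
#' @return A `ring_measurement` list: `cell_id`, `ring_mask`,
#'   `integrated_ring`, `integrated_total`, `fraction`, and `truncated`
#'   (TRUE when the ring is cut by the frame edge).
#' @export
ring_fraction <- function(nuclear_mask, lysosome_channel, ring_width = 30,
                          cell_id = "cell") {
  stopifnot(identical(dim(nuclear_mask), dim(lysosome_channel)))
  mask <- nuclear_mask > 0
  dil <- EBImage::dilate(matrix(as.numeric(mask), nrow(mask)),
                         disc_brush(ring_width)) > 0
  ring <- dil & !mask
  border <- c(dil[1, ], dil[nrow(dil), ], dil[, 1], dil[, ncol(dil)])
  truncated <- any(border)
  if (truncated)
    warning("ring truncated by the frame edge for ", cell_id, call. = FALSE)
  tot <- sum(lysosome_channel)
  rng <- sum(lysosome_channel[ring])
  structure(list(cell_id = cell_id, ring_mask = ring,
                 nuclear_mask = mask, ring_width = ring_width,
                 integrated_ring = rng, integrated_total = tot,
                 fraction = if (tot > 0) rng / tot else 0,
                 truncated = truncated),
            class = "ring_measurement")
}

#' @export
print.ring_measurement <- function(x, ...) {
  cat(sprintf("ring_measurement %s: fraction %.3f (ring %g of total %g)%s\n",
              x$cell_id, x$fraction, x$integrated_ring, x$integrated_total,
              if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

#' Full per-cell lysosome-positioning measurement
#'
#' Runs the complete procedure on a two-channel single-cell crop:
#' histogram-mode background subtraction per channel, optional white
#' top-hat haze correction of the lysosome channel, adaptive nuclear
#' segmentation, and the dilated-ring intensity fraction.
#'
#' @param nuclear_channel,lysosome_channel Numeric matrices.
#' @param ring_width Ring width, default 30 px.
#' @param tophat_radius Disc radius for the top-hat step; `NULL` skips it.
#' @param cell_id Identifier carried through.
#' @param ... Passed to [segment_nucleus()].
#' @return A `ring_measurement` (see [ring_fraction()]).
#' @export
measure_cell <- function(nuclear_channel, lysosome_channel, ring_width = 30,
                         tophat_radius = 8, cell_id = "cell", ...) {
  nuc <- subtract_background(nuclear_channel,
                             estimate_background(nuclear_channel))
  lys <- subtract_background(lysosome_channel,
                             estimate_background(lysosome_channel))
  if (!is.null(tophat_radius)) lys <- tophat_correct(lys, tophat_radius)
  mask <- segment_nucleus(nuc, ...)
  ring_fraction(mask, lys, ring_width, cell_id)
}

#' Per-cell integrated PLA signal
#'
#' Thresholds the amplified proximity-ligation channel (Otsu by default on
#' the background-subtracted image) and sums the above-threshold intensity
#' within each cell mask — the per-cell readout plotted in PLA
#' quantifications.
#'
#' @param pla_channel Numeric matrix.
#' @param cell_masks Named list of logical masks, one per cell; default one
#'   cell covering the whole frame.
#' @param threshold `"otsu"` or a numeric level; `"none"` sums everything.
#' @return data.frame with `cell_id` and `integrated_signal`.
#' @export
pla_quantify <- function(pla_channel, cell_masks = NULL,
                         threshold = "otsu") {
  if (is.null(cell_masks))
    cell_masks <- list(cell1 = matrix(TRUE, nrow(pla_channel),
                                      ncol(pla_channel)))
  if (is.null(names(cell_masks)))
    names(cell_masks) <- sprintf("cell%d", seq_along(cell_masks))
  mx <- max(pla_channel)
  thr <- if (identical(threshold, "none")) -Inf
         else if (is.numeric(threshold)) threshold
         else if (mx > 0) EBImage::otsu(EBImage::Image(pla_channel / mx)) * mx
         else Inf
  sig <- vapply(cell_masks, function(m) {
    v <- pla_channel[m]
    sum(v[v >= thr])
  }, 0)
  data.frame(cell_id = names(cell_masks), integrated_signal = unname(sig),
             stringsAsFactors = FALSE)
}

#' Maximum-intensity projection of an image stack
#'
#' Inputs to the ring measurement are assumed to be projected planes; this
#' helper collapses a Z-stack (3D array) by pixelwise maximum.
#'
#' @param stack 3D numeric array (x, y, z).
#' @export
max_project <- function(stack) {
  stopifnot(length(dim(stack)) == 3)
  apply(stack, c(1, 2), max)
}

#' Read / write multi-channel TIFF images
#'
#' Thin wrappers over EBImage for 16-bit TIFF input and output of the
#' microscopy channels this package quantifies.
#'
#' @param path TIFF path.
#' @return `read_channel_tiff()`: a numeric matrix (single plane) or 3D
#'   array on the original 16-bit scale.
#' @export
read_channel_tiff <- function(path) {
  img <- EBImage::readImage(path)
  EBImage::imageData(img) * 65535
}

#' @rdname read_channel_tiff
#' @param image Numeric matrix on the 16-bit scale (0-65535).
#' @export
write_channel_tiff <- function(image, path) {
  EBImage::writeImage(EBImage::Image(image / 65535), path, type = "tiff",
                      bits.per.sample = 16L)
  invisible(path)
}
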