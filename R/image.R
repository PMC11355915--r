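#' Greyscale image objects
#'
#' A greyscale image is a two-dimensional field of intensities `z(i, j)` on an
#' `N x M` pixel lattice, stored as a plain numeric matrix with a
#' `transform` attribute recording which intensity transform has been
#' applied: `"raw"` (as read), `"unit"` (min-max rescaled to \[0, 1\]) or
#' `"z"` (globally standardised).
#'
#' @param values Numeric matrix of finite pixel intensities.
#' @param transform One of `"raw"`, `"unit"`, `"z"`.
#' @return A `greyscale_image`: a numeric matrix with class and `transform`
#'   attributes.
#' @examples
#' img <- greyscale_image(matrix(runif(64), 8, 8))
#' attr(img, "transform")
#' @export
greyscale_image <- function(values, transform = c("raw", "unit", "z")) {
  transform <- match.arg(transform)
  if (!is.matrix(values) || !is.numeric(values))
    abort("`values` must be a numeric matrix.")
  if (nrow(values) < 1L || ncol(values) < 1L)
    abort("image must have at least one row and one column.")
  if (!all(is.finite(values)))
    abort("all pixel values must be finite.")
  structure(values, class = c("greyscale_image", class(matrix())),
            transform = transform)
}

as_greyscale <- function(x) {
  if (inherits(x, "greyscale_image")) return(x)
  greyscale_image(as.matrix(x))
}

#' @export
print.greyscale_image <- function(x, ...) {
  cat(sprintf("<greyscale_image> %d x %d, transform = %s, range [%.4g, %.4g]\n",
              nrow(x), ncol(x), attr(x, "transform"), min(x), max(x)))
  invisible(x)
}

#' Convert an RGB array to a greyscale image
#'
#' Collapses a 3-channel image to a single luminance channel with fixed
#' channel weights. The default weights are the Rec.601 luma coefficients
#' (0.299, 0.587, 0.114), the common convention for greyscale conversion of
#' colour fundus photographs.
#'
#' @param rgb Numeric array `N x M x 3` (or an `N x M` matrix, returned
#'   unchanged as a greyscale image), values in \[0, 1\] or \[0, 255\].
#' @param weights Length-3 non-negative channel weights; rescaled to sum to 1.
#' @return A [greyscale_image()] with `transform = "raw"`.
#' @examples
#' arr <- array(runif(2 * 2 * 3), dim = c(2, 2, 3))
#' to_greyscale(arr)
#' @export
to_greyscale <- function(rgb, weights = c(0.299, 0.587, 0.114)) {
  if (is.matrix(rgb)) return(greyscale_image(rgb))
  if (!is.array(rgb) || length(dim(rgb)) != 3L)
    abort("`rgb` must be an N x M x 3 array or an N x M matrix.")
  d <- dim(rgb)
  if (d[3] < 3L)
    abort(sprintf("expected 3 channels, got %d.", d[3]))
  if (length(weights) != 3L || any(weights < 0) || sum(weights) <= 0)
    abort("`weights` must be 3 non-negative numbers with a positive sum.")
  w <- weights / sum(weights)
  g <- w[1] * rgb[, , 1] + w[2] * rgb[, , 2] + w[3] * rgb[, , 3]
  greyscale_image(matrix(g, d[1], d[2]))
}

#' Intensity transforms
#'
#' `unit_transform()` rescales intensities affinely to \[0, 1\]
#' (min to 0, max to 1); `z_transform()` standardises them to mean 0 and
#' standard deviation 1 over all pixels. A constant image maps to all zeros
#' under both conventions (with a warning for the z-transform, where the
#' standard deviation is undefined).
#'
#' @param img A [greyscale_image()] or numeric matrix.
#' @return A [greyscale_image()] tagged `"unit"` or `"z"`.
#' @examples
#' unit_transform(matrix(c(2, 4, 6, 4), 2, 2))
#' @export
unit_transform <- function(img) {
  img <- as_greyscale(img)
  rng <- range(img)
  vals <- if (rng[1] == rng[2]) {
    matrix(0, nrow(img), ncol(img))
  } else {
    (unclass(img) - rng[1]) / (rng[2] - rng[1])
  }
  greyscale_image(vals, transform = "unit")
}

#' @rdname unit_transform
#' @export
z_transform <- function(img) {
  img <- as_greyscale(img)
  s <- sd(img)
  vals <- if (s == 0 || !is.finite(s)) {
    warn("constant image: z-transform returns all zeros.")
    matrix(0, nrow(img), ncol(img))
  } else {
    (unclass(img) - mean(img)) / s
  }
  greyscale_image(vals, transform = "z")
}

apply_transform <- function(img, transform = c("unit", "z", "raw")) {
  transform <- match.arg(transform)
  switch(transform,
         unit = unit_transform(img),
         z = z_transform(img),
         raw = as_greyscale(img))
}

#' Read an image file as a greyscale image
#'
#' Reads PNG or TIFF (8- or 16-bit, greyscale or RGB); colour images are
#' collapsed with [to_greyscale()]. An alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @inheritParams to_greyscale
#' @return A [greyscale_image()].
#' @export
read_image <- function(path, weights = c(0.299, 0.587, 0.114)) {
  if (!file.exists(path))
    abort(sprintf("cannot read image: '%s' does not exist.", path))
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path),
              abort(sprintf("unsupported image format '.%s' (PNG/TIFF only): %s",
                            ext, path)))
  if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[3] >= 3L) x <- to_greyscale(x[, , 1:3, drop = FALSE], weights)
    else x <- greyscale_image(x[, , 1])
  } else {
    x <- greyscale_image(as.matrix(x))
  }
  x
}

#' Write a greyscale image to PNG
#'
#' Intensities are clipped to \[0, 1\] before writing.
#'
#' @param img A [greyscale_image()] or matrix.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- as_greyscale(img)
  m <- pmin(pmax(unclass(img), 0), 1)
  png::writePNG(m, target = path)
  invisible(path)
}
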