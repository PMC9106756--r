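# Core image container and low-level grid operations.
#
# Images are plain numeric matrices (rows = image rows, columns = image
# columns) with intensities in [0, 1], carrying the S3 class
# "intensity_image".  All point coordinates exposed by the package are
# 0-based (row, col) with pixel centers at integer positions, so the value
# "at" point (r, c) is values[r + 1, c + 1].

#' Create an intensity image
#'
#' Wraps a numeric matrix as an `intensity_image`, rescaling to \[0, 1\] if
#' requested. Integer-valued inputs (e.g. raw 8/16-bit pixel data) are divided
#' by the maximum representable value inferred from the data range.
#'
#' @param values Numeric matrix of pixel intensities.
#' @param normalize If `TRUE` (default), min-max rescale to \[0, 1\] unless the
#'   data already lie in that range.
#' @return An `intensity_image`: a numeric matrix in \[0, 1\].
#' @export
as_intensity_image <- function(values, normalize = TRUE) {
  if (inherits(values, "intensity_image")) return(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (any(!is.finite(values)))
    stop("image contains non-finite values")
  v <- values
  if (normalize) {
    rng <- range(v)
    if (rng[1] < 0 || rng[2] > 1) {
      if (diff(rng) == 0) {
        v[] <- 0
      } else {
        v <- (v - rng[1]) / diff(rng)
      }
    }
  } else if (min(v) < 0 || max(v) > 1) {
    stop("intensities outside [0, 1]; use normalize = TRUE")
  }
  structure(v, class = c("intensity_image", class(matrix())))
}

#' Read a grayscale PNG or TIFF image
#'
#' Reads an 8- or 16-bit PNG/TIFF, averages channels if the file is not
#' single-channel, and normalizes intensities to \[0, 1\].
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return An [as_intensity_image()] matrix.
#' @export
read_ir_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(arr)) == 3L) arr <- apply(arr[, , 1:min(3L, dim(arr)[3]), drop = FALSE], c(1, 2), mean)
  as_intensity_image(arr)
}

#' Write an image as 8-bit grayscale PNG
#'
#' @param image Intensity image (values clipped to \[0, 1\]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ir_image <- function(image, path) {
  v <- pmin(pmax(unclass(image), 0), 1)
  png::writePNG(v, target = path, dpi = NULL)
  invisible(path)
}

# --- separable filtering with symmetric-reflect boundaries ------------------

# symmetric (half-sample) reflection indices for length n, pad r
reflect_index <- function(n, r) {
  idx <- seq(1 - r, n + r)
  # fold into [1, n] by repeated reflection about half-sample boundaries
  period <- 2L * n
  idx <- ((idx - 1L) %% period + period) %% period + 1L
  idx[idx > n] <- period - idx[idx > n] + 1L
  idx
}

# 1-D correlation along rows (dim = 1) or columns (dim = 2),
# out(i) = sum_t k[t] * x(i + t - center), reflect boundary.
filter_dim <- function(x, k, dim = 1L) {
  r <- (length(k) - 1L) %/% 2L
  n <- dim(x)[dim]
  idx <- reflect_index(n, r)
  out <- matrix(0, nrow(x), ncol(x))
  for (t in seq_along(k)) {
    if (k[t] == 0) next
    sel <- idx[seq_len(n) + (t - 1L)]
    out <- out + k[t] * (if (dim == 1L) x[sel, , drop = FALSE] else x[, sel, drop = FALSE])
  }
  out
}

gaussian_kernel1d <- function(sigma, radius = max(1L, ceiling(4 * sigma))) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing with reflected boundaries
#'
#' Separable Gaussian filter (kernel truncated at 4 sigma), using symmetric
#' half-sample reflection at the image borders.
#'
#' @param image Numeric matrix.
#' @param sigma Standard deviation in pixels (`sigma <= 0` returns the input).
#' @return Smoothed matrix of the same dimensions.
#' @export
gaussian_smooth <- function(image, sigma) {
  if (sigma <= 0) return(unclass(image))
  k <- gaussian_kernel1d(sigma)
  filter_dim(filter_dim(unclass(image), k, 1L), k, 2L)
}

# central first/second differences with reflect boundaries;
# "x" is the column direction, "y" the row direction.
deriv_x  <- function(img) filter_dim(img, c(-0.5, 0, 0.5), 2L)
deriv_y  <- function(img) filter_dim(img, c(-0.5, 0, 0.5), 1L)
deriv_xx <- function(img) filter_dim(img, c(1, -2, 1), 2L)
deriv_yy <- function(img) filter_dim(img, c(1, -2, 1), 1L)
deriv_xy <- function(img) deriv_x(deriv_y(img))

# --- bilinear sampling and resizing ----------------------------------------

#' Bilinear sampling at fractional coordinates
#'
#' Samples `image` at 0-based coordinates (`y` = row, `x` = col) with bilinear
#' interpolation; coordinates outside the frame are clamped to the nearest
#' edge pixel (nearest-edge extension).
#'
#' @param image Numeric matrix.
#' @param x,y Numeric vectors/matrices of equal shape, 0-based column and row
#'   coordinates.
#' @return Sampled values, same shape as `x`.
#' @export
bilinear_sample <- function(image, x, y) {
  img <- unclass(image)
  h <- nrow(img); w <- ncol(img)
  xs <- pmin(pmax(as.vector(x), 0), w - 1)
  ys <- pmin(pmax(as.vector(y), 0), h - 1)
  x0 <- floor(xs); y0 <- floor(ys)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- xs - x0; fy <- ys - y0
  # convert to 1-based linear indices
  i00 <- (x0) * h + y0 + 1
  i01 <- (x1) * h + y0 + 1
  i10 <- (x0) * h + y1 + 1
  i11 <- (x1) * h + y1 + 1
  v <- (1 - fy) * ((1 - fx) * img[i00] + fx * img[i01]) +
       fy       * ((1 - fx) * img[i10] + fx * img[i11])
  if (is.matrix(x)) dim(v) <- dim(x)
  v
}

# resize by bilinear interpolation with pixel-center alignment
resize_bilinear <- function(image, new_h, new_w) {
  h <- nrow(image); w <- ncol(image)
  ys <- ((seq_len(new_h) - 0.5) * h / new_h) - 0.5
  xs <- ((seq_len(new_w) - 0.5) * w / new_w) - 0.5
  X <- matrix(xs, new_h, new_w, byrow = TRUE)
  Y <- matrix(ys, new_h, new_w)
  out <- bilinear_sample(image, X, Y)
  dim(out) <- c(new_h, new_w)
  out
}

# 8-connected component labels of a logical matrix (igraph backend);
# returns an integer matrix, 0 = background.
label8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, h, w)
  if (length(idx) == 0) return(lab)
  r <- ((idx - 1L) %% h) + 1L
  c <- ((idx - 1L) %/% h) + 1L
  pos <- match(idx, idx)
  # edges to 4 "forward" neighbors (E, SE, S, SW) to avoid duplicates
  edges <- list()
  lin <- function(r, c) (c - 1L) * h + r
  shifts <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  map <- integer(h * w); map[idx] <- seq_along(idx)
  for (s in shifts) {
    rn <- r + s[1]; cn <- c + s[2]
    ok <- rn >= 1L & rn <= h & cn >= 1L & cn <= w
    ni <- lin(rn[ok], cn[ok])
    has <- map[ni] > 0L
    edges[[length(edges) + 1L]] <- rbind(seq_along(idx)[ok][has], map[ni[has]])
  }
  e <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(e)) g <- igraph::add_edges(g, as.integer(e))
  comp <- igraph::components(g)$membership
  lab[idx] <- comp[seq_along(idx)]
  lab
}

# restore-on-exit seeded RNG scope
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}
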