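# Feature-quality and registration-quality metrics.
#
# H_uni = <r> / r_ran is a spatial-entropy uniformity score: the mean
# nearest-neighbor distance of the detected points divided by the expected
# nearest-neighbor distance 0.5 * sqrt(I_pixels / n) of the same number of
# uniformly random points (higher = more uniform).  H_spa = <r> / A_per,
# with A_per = n / I_pixels features per pixel, scores sparsity (lower =
# denser coverage).  Registration quality uses mutual information on the
# joint intensity histogram and Canny edge-overlap overlays.

#' Spatial uniformity and sparsity of a feature set
#'
#' Computes the mean nearest-neighbor distance `<r>` (Euclidean, continuous
#' pixel coordinates, exact ties permitted), the random-expectation distance
#' `r_ran = 0.5 * sqrt(I_pixels / n)`, the per-pixel feature density
#' `A_per = n / I_pixels`, and the derived scores `h_uni = <r> / r_ran` and
#' `h_spa = <r> / A_per`.
#'
#' @param points A `feature_set`, or a data frame with `row`, `col`.
#' @param image_shape `c(height, width)`; defaults to the feature set's own
#'   shape.
#' @return A `feature_quality` list: `n`, `mean_nn`, `r_ran`, `a_per`,
#'   `h_uni`, `h_spa`.
#' @export
feature_quality <- function(points, image_shape = NULL) {
  if (inherits(points, "feature_set")) {
    if (is.null(image_shape)) image_shape <- points$shape
    points <- points$points
  }
  if (is.null(image_shape)) stop("image_shape is required")
  n <- nrow(points)
  if (n < 2) stop("feature quality requires at least 2 points")
  d <- as.matrix(dist(cbind(points$row, points$col)))
  diag(d) <- Inf
  mean_nn <- mean(apply(d, 1, min))
  i_pixels <- prod(image_shape)
  r_ran <- 0.5 * sqrt(i_pixels / n)
  a_per <- n / i_pixels
  structure(list(n = n, mean_nn = mean_nn, r_ran = r_ran, a_per = a_per,
                 h_uni = mean_nn / r_ran, h_spa = mean_nn / a_per),
            class = "feature_quality")
}

#' Precision of a matched pair set against ground truth
#'
#' A pair (p_src, p_tgt) is counted correct when its target point is
#' consistent with the ground-truth field at that location:
#' `|| p_tgt + w_true(p_tgt) - p_src || <= tol` (the field uses the backward
#' convention `target(x) = source(x + w(x))`, evaluated bilinearly).
#' An empty pair set gives `NA` with a warning, never 0 or 1.
#'
#' @param pairs A `control_point_set` (its inliers are scored) or a data
#'   frame with `row_src`, `col_src`, `row_tgt`, `col_tgt`.
#' @param truth A `synthetic_case` or a field list (`u`, `v`).
#' @param tol Tolerance in pixels (default 3).
#' @return Precision in \[0, 1\], or `NA` for an empty pair set.
#' @export
match_precision <- function(pairs, truth, tol = 3) {
  if (inherits(pairs, "control_point_set")) pairs <- pairs$inliers
  field <- if (inherits(truth, "synthetic_case")) truth$true_field else truth
  if (nrow(pairs) == 0) {
    warning("empty pair set: precision is undefined")
    return(NA_real_)
  }
  wv <- eval_field(field, cbind(pairs$row_tgt, pairs$col_tgt))
  err <- sqrt((pairs$row_tgt + wv[, "v"] - pairs$row_src)^2 +
              (pairs$col_tgt + wv[, "u"] - pairs$col_src)^2)
  mean(err <= tol)
}

#' Mutual information of two images
#'
#' `MI = H(A) + H(B) - H(A, B)` in nats, from the joint histogram of the two
#' images over `n_bins` equal-width intensity bins on \[0, 1\].
#'
#' @param img_a,img_b Intensity images of equal shape.
#' @param n_bins Number of histogram bins per image (>= 2, default 64).
#' @return Mutual information in nats.
#' @export
mutual_information <- function(img_a, img_b, n_bins = 64L) {
  a <- unclass(img_a); b <- unclass(img_b)
  if (!all(dim(a) == dim(b))) stop("images must have the same shape")
  if (n_bins < 2) stop("n_bins must be >= 2")
  ia <- pmin(floor(as.vector(a) * n_bins), n_bins - 1L)
  ib <- pmin(floor(as.vector(b) * n_bins), n_bins - 1L)
  joint <- matrix(tabulate(ia * n_bins + ib + 1L, nbins = n_bins^2),
                  n_bins, n_bins)
  p <- joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  ent(px) + ent(py) - ent(p)
}

#' Canny edge detector
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and hysteresis thresholding: the high
#' threshold is derived from the gradient-magnitude histogram by Otsu's
#' method, the low threshold is `low_frac` times the high one, and weak
#' edges are kept only in 8-connected components containing a strong edge.
#'
#' @param image Intensity image.
#' @param sigma Smoothing scale (default 1.5).
#' @param low_frac Low/high threshold ratio (default 0.4).
#' @return Logical edge matrix.
#' @export
canny_edges <- function(image, sigma = 1.5, low_frac = 0.4) {
  img <- gaussian_smooth(unclass(image), sigma)
  # Sobel
  kx <- c(1, 2, 1); kd <- c(-1, 0, 1)
  gx <- filter_dim(filter_dim(img, kx, 1L), kd, 2L)
  gy <- filter_dim(filter_dim(img, kx, 2L), kd, 1L)
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) return(matrix(FALSE, nrow(img), ncol(img)))
  # non-maximum suppression over 4 quantized directions
  ang <- atan2(gy, gx) %% pi
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4
  n <- neighbor_stack(mag)
  nmax <- matrix(0, nrow(img), ncol(img))
  nmax[sector == 0] <- pmax(n$p4, n$p8)[sector == 0]  # horizontal gradient
  nmax[sector == 1] <- pmax(n$p5, n$p9)[sector == 1]
  nmax[sector == 2] <- pmax(n$p2, n$p6)[sector == 2]  # vertical gradient
  nmax[sector == 3] <- pmax(n$p3, n$p7)[sector == 3]
  thin <- mag >= nmax & mag > 0
  high <- EBImage::otsu(mag / max(mag)) * max(mag)
  low <- low_frac * high
  strong <- thin & mag >= high
  weak <- thin & mag >= low
  if (!any(strong)) return(strong)
  lab <- label8(weak)
  keep_ids <- unique(lab[strong])
  weak & matrix(lab %in% keep_ids, nrow(lab), ncol(lab))
}

#' Edge-agreement overlay of a registered pair
#'
#' Canny edges of both images are rendered into an RGB image: pixels where
#' both edge maps fire are green, warped-source-only edges white,
#' target-only edges red, background black.
#'
#' @param target,warped_src Intensity images of equal shape.
#' @param sigma,low_frac Canny parameters (see [canny_edges()]).
#' @return `height x width x 3` RGB array in \[0, 1\], with the edge maps
#'   attached as attribute `"edges"`.
#' @export
canny_overlay <- function(target, warped_src, sigma = 1.5, low_frac = 0.4) {
  if (!all(dim(unclass(target)) == dim(unclass(warped_src))))
    stop("images must have the same shape")
  e_t <- canny_edges(target, sigma, low_frac)
  e_s <- canny_edges(warped_src, sigma, low_frac)
  both <- e_t & e_s
  only_s <- e_s & !e_t
  only_t <- e_t & !e_s
  rgb <- array(0, c(nrow(e_t), ncol(e_t), 3))
  rgb[, , 1][only_t] <- 1                       # red: target only
  rgb[, , 2][both] <- 1                         # green: overlap
  rgb[, , 1][only_s] <- 1; rgb[, , 2][only_s] <- 1; rgb[, , 3][only_s] <- 1
  attr(rgb, "edges") <- list(target = e_t, warped_src = e_s)
  rgb
}

#' Fraction of edge pixels in agreement
#'
#' Green fraction of a [canny_overlay()]: overlapping edge pixels divided by
#' all edge pixels of either map.
#'
#' @param overlay Result of [canny_overlay()].
#' @return Fraction in \[0, 1\] (`NA` if neither image has edges).
#' @export
edge_agreement <- function(overlay) {
  e <- attr(overlay, "edges")
  tot <- sum(e$target | e$warped_src)
  if (tot == 0) return(NA_real_)
  sum(e$target & e$warped_src) / tot
}
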