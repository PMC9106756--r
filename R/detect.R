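# Feature detection in hot and cold patterns.
#
# Infrared images are split into a bright, vessel-dominated "hot pattern"
# and dark flat "cold pattern" regions by the sign of the dominant Hessian
# eigenvalue at scale sigma.  Three feature classes are extracted:
#   W - branch points of the skeletonized hot pattern (vascular intersections)
#   B - branch points of the skeletonized cold pattern (flat-region grid
#       intersections)
#   C - Harris corners restricted to the hot pattern.

#' Per-pixel eigenvalues of the Gaussian-smoothed Hessian
#'
#' Smooths the image at scale `sigma` (symmetric-reflect boundaries), forms
#' the Hessian from central finite differences, and returns its eigenvalues
#' per pixel via the closed form `(tr +/- sqrt(tr^2 - 4 det)) / 2`.
#' `lambda1` holds the eigenvalue of smaller absolute value, `lambda2` the
#' dominant (larger-absolute-value) one; when the absolute values tie,
#' `lambda2` is the algebraically larger eigenvalue.
#'
#' @param image An intensity image (finite values).
#' @param sigma Gaussian scale in pixels (> 0, default 2).
#' @return An `eigen_field`: list with matrices `lambda1`, `lambda2` and the
#'   scale `sigma`.
#' @export
hessian_eigen <- function(image, sigma = 2) {
  img <- unclass(image)
  if (any(!is.finite(img))) stop("image contains non-finite values")
  if (sigma <= 0) stop("sigma must be > 0")
  g <- gaussian_smooth(img, sigma)
  hxx <- deriv_xx(g); hyy <- deriv_yy(g); hxy <- deriv_xy(g)
  tr <- hxx + hyy
  dt <- hxx * hyy - hxy^2
  disc <- sqrt(pmax(tr^2 - 4 * dt, 0))
  e_lo <- (tr - disc) / 2   # algebraically smaller
  e_hi <- (tr + disc) / 2   # algebraically larger
  hi_dominant <- abs(e_hi) >= abs(e_lo)
  lambda2 <- ifelse(hi_dominant, e_hi, e_lo)
  lambda1 <- ifelse(hi_dominant, e_lo, e_hi)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, sigma = sigma),
            class = "eigen_field")
}

#' Separate hot and cold patterns by dominant-eigenvalue sign
#'
#' A pixel is hot when its dominant Hessian eigenvalue is negative (bright
#' ridge/blob) and cold when positive (dark valley/blob). Magnitudes below a
#' relative noise floor `tau_rel * max(|lambda2|)` are assigned to neither
#' mask, as are exact zeros, so the masks are always disjoint.
#'
#' @param eig An `eigen_field` from [hessian_eigen()].
#' @param tau_rel Relative noise floor (default `1e-6`, effectively off for
#'   clean images).
#' @return A `pattern_masks` list with logical matrices `hot` and `cold`.
#' @export
binarize_patterns <- function(eig, tau_rel = 1e-6) {
  lam <- eig$lambda2
  floor_abs <- tau_rel * max(abs(lam))
  hot <- lam < -floor_abs
  cold <- lam > floor_abs
  structure(list(hot = hot, cold = cold), class = "pattern_masks")
}

# 8-neighborhood values as a list of shifted matrices, clockwise from N:
# p2=N, p3=NE, p4=E, p5=SE, p6=S, p7=SW, p8=W, p9=NW  (Zhang-Suen numbering)
neighbor_stack <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(0L, h + 2, w + 2)
  p[2:(h + 1), 2:(w + 1)] <- m
  at <- function(dr, dc) p[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  list(p2 = at(-1, 0), p3 = at(-1, 1), p4 = at(0, 1), p5 = at(1, 1),
       p6 = at(1, 0), p7 = at(1, -1), p8 = at(0, -1), p9 = at(-1, -1))
}

#' Morphological thinning to a one-pixel skeleton
#'
#' Iterative two-subpass thinning (Zhang-Suen deletion rules) producing an
#' 8-connected, one-pixel-wide skeleton that preserves the topology of each
#' connected component. Already-thin lines are returned unchanged.
#'
#' @param mask Logical (or 0/1) matrix.
#' @return Logical matrix of the same size.
#' @export
skeletonize_mask <- function(mask) {
  m <- matrix(as.integer(as.logical(mask)), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      n <- neighbor_stack(m)
      B <- n$p2 + n$p3 + n$p4 + n$p5 + n$p6 + n$p7 + n$p8 + n$p9
      seqn <- list(n$p2, n$p3, n$p4, n$p5, n$p6, n$p7, n$p8, n$p9, n$p2)
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) A <- A + (seqn[[i]] == 0L & seqn[[i + 1]] == 1L)
      if (pass == 1) {
        cond <- m == 1L & B >= 2 & B <= 6 & A == 1 &
          (n$p2 * n$p4 * n$p6 == 0L) & (n$p4 * n$p6 * n$p8 == 0L)
      } else {
        cond <- m == 1L & B >= 2 & B <= 6 & A == 1 &
          (n$p2 * n$p4 * n$p8 == 0L) & (n$p2 * n$p6 * n$p8 == 0L)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

#' Branch points of a skeleton
#'
#' A skeleton pixel is a branch pixel when at least three distinct skeleton
#' branches meet there, measured by the crossing number (number of 0-to-1
#' transitions around its 8-neighborhood). Adjacent branch pixels
#' (8-connected clusters, as produced by thinning at junctions) are merged to
#' their centroid, rounded to the nearest pixel.
#'
#' @param skeleton Logical matrix (one-pixel-wide skeleton).
#' @param klass Feature class label to assign (`"W"` or `"B"`).
#' @return Data frame of feature points (`row`, `col`, `klass`; 0-based).
#' @export
detect_intersections <- function(skeleton, klass = "B") {
  m <- matrix(as.integer(as.logical(skeleton)), nrow(skeleton), ncol(skeleton))
  if (!any(m == 1L)) return(feature_points(numeric(0), numeric(0), character(0)))
  n <- neighbor_stack(m)
  seqn <- list(n$p2, n$p3, n$p4, n$p5, n$p6, n$p7, n$p8, n$p9, n$p2)
  A <- matrix(0L, nrow(m), ncol(m))
  for (i in 1:8) A <- A + (seqn[[i]] == 0L & seqn[[i + 1]] == 1L)
  branch <- m == 1L & A >= 3
  if (!any(branch)) return(feature_points(numeric(0), numeric(0), character(0)))
  lab <- label8(branch)
  ids <- sort(unique(lab[lab > 0]))
  rows <- cols <- numeric(length(ids))
  for (i in seq_along(ids)) {
    idx <- which(lab == ids[i])
    rows[i] <- round(mean((idx - 1) %% nrow(m)))       # 0-based row
    cols[i] <- round(mean((idx - 1) %/% nrow(m)))      # 0-based col
  }
  feature_points(rows, cols, rep(klass, length(ids)))
}

#' Harris corner detection within a mask
#'
#' Standard Harris response `R = det(M) - k * trace(M)^2` on the Gaussian-
#' windowed structure tensor of image gradients. Local maxima with
#' `R >= rel_threshold * max(R within mask)` are kept and non-maximum
#' suppressed greedily within `nms_radius`.
#'
#' @param image Intensity image.
#' @param mask Logical matrix restricting where corners may fire (an empty
#'   mask yields an empty result).
#' @param k Harris sensitivity (in \[0.02, 0.15\], default 0.04).
#' @param rel_threshold Response threshold as a fraction of the masked
#'   maximum (default 0.01).
#' @param nms_radius Non-maximum-suppression radius in pixels (default 5).
#' @param sigma_d,sigma_i Derivative and integration scales in pixels.
#' @return Data frame of `C` feature points (`row`, `col`, `klass`; 0-based).
#' @export
harris_corners <- function(image, mask = NULL, k = 0.04, rel_threshold = 0.01,
                           nms_radius = 5, sigma_d = 1, sigma_i = 2) {
  if (k < 0.02 || k > 0.15) stop("k must be in [0.02, 0.15]")
  if (rel_threshold <= 0 || rel_threshold >= 1)
    stop("rel_threshold must be in (0, 1)")
  img <- unclass(image)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  if (!any(mask)) return(feature_points(numeric(0), numeric(0), character(0)))
  g <- gaussian_smooth(img, sigma_d)
  ix <- deriv_x(g); iy <- deriv_y(g)
  a <- gaussian_smooth(ix * ix, sigma_i)
  b <- gaussian_smooth(ix * iy, sigma_i)
  c2 <- gaussian_smooth(iy * iy, sigma_i)
  resp <- (a * c2 - b^2) - k * (a + c2)^2
  rmax <- max(resp[mask])
  if (rmax <= 0) return(feature_points(numeric(0), numeric(0), character(0)))
  cand <- which(mask & resp >= rel_threshold * rmax)
  if (!length(cand)) return(feature_points(numeric(0), numeric(0), character(0)))
  # 3x3 local maxima
  n <- neighbor_stack(resp)
  locmax <- resp >= pmax(n$p2, n$p3, n$p4, n$p5, n$p6, n$p7, n$p8, n$p9)
  cand <- cand[locmax[cand]]
  if (!length(cand)) return(feature_points(numeric(0), numeric(0), character(0)))
  ord <- order(resp[cand], decreasing = TRUE)
  cand <- cand[ord]
  rows <- (cand - 1) %% nrow(img)
  cols <- (cand - 1) %/% nrow(img)
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    if (i == 1) { keep[1] <- TRUE; next }
    d2 <- (rows[keep & seq_along(cand) < i] - rows[i])^2 +
          (cols[keep & seq_along(cand) < i] - cols[i])^2
    keep[i] <- all(d2 > nms_radius^2)
  }
  feature_points(rows[keep], cols[keep], rep("C", sum(keep)))
}

# constructor for the points data frame used across modules
feature_points <- function(row, col, klass) {
  structure(data.frame(row = as.numeric(row), col = as.numeric(col),
                       klass = as.character(klass),
                       stringsAsFactors = FALSE),
            class = c("feature_points", "data.frame"))
}

#' Default detection parameters
#'
#' @return Named list: Hessian scale `sigma`, eigenvalue noise floor
#'   `tau_rel`, Harris parameters, and the per-class duplicate `merge_radius`.
#' @export
detect_params <- function() {
  list(sigma = 2, tau_rel = 1e-6,
       harris_k = 0.04, harris_rel_threshold = 0.01, harris_nms_radius = 5,
       merge_radius = 3)
}

# greedy per-class deduplication: keep first point, drop later points
# within merge_radius of a kept one
dedupe_points <- function(pts, merge_radius) {
  if (nrow(pts) <= 1) return(pts)
  keep <- rep(TRUE, nrow(pts))
  for (kl in unique(pts$klass)) {
    idx <- which(pts$klass == kl)
    for (i in seq_along(idx)) {
      if (!keep[idx[i]]) next
      if (i == length(idx)) break
      later <- idx[(i + 1):length(idx)]
      later <- later[keep[later]]
      if (!length(later)) next
      d2 <- (pts$row[later] - pts$row[idx[i]])^2 +
            (pts$col[later] - pts$col[idx[i]])^2
      keep[later[d2 <= merge_radius^2]] <- FALSE
    }
  }
  pts[keep, , drop = FALSE]
}

#' Detect W, B and C feature points
#'
#' Full detection pipeline: Hessian eigen-analysis at scale `sigma`, hot/cold
#' binarization, skeletonization of both masks, branch-point extraction
#' (W from the hot skeleton, B from the cold skeleton) and Harris corners
#' restricted to the hot mask (C). Points of the same class closer than
#' `merge_radius` are deduplicated.
#'
#' @param image Intensity image.
#' @param params Parameter list as from [detect_params()].
#' @return A `feature_set`: list with `points` (data frame `row`, `col`,
#'   `klass`, 0-based) and `shape = c(height, width)`; intermediate masks and
#'   skeletons are attached as attribute `"layers"`.
#' @export
detect_features <- function(image, params = detect_params()) {
  img <- unclass(image)
  eig <- hessian_eigen(img, params$sigma)
  masks <- binarize_patterns(eig, params$tau_rel)
  sk_hot <- skeletonize_mask(masks$hot)
  sk_cold <- skeletonize_mask(masks$cold)
  w_pts <- detect_intersections(sk_hot, klass = "W")
  b_pts <- detect_intersections(sk_cold, klass = "B")
  c_pts <- harris_corners(img, mask = masks$hot, k = params$harris_k,
                          rel_threshold = params$harris_rel_threshold,
                          nms_radius = params$harris_nms_radius)
  pts <- rbind(w_pts, b_pts, c_pts)
  pts <- unique(pts)
  pts <- dedupe_points(pts, params$merge_radius)
  rownames(pts) <- NULL
  out <- structure(list(points = pts, shape = dim(img)),
                   class = "feature_set")
  attr(out, "layers") <- list(hot = masks$hot, cold = masks$cold,
                              skeleton_hot = sk_hot, skeleton_cold = sk_cold)
  out
}

#' Write a feature set as CSV
#'
#' @param features A `feature_set`.
#' @param path Output CSV path (columns `row`, `col`, `klass`).
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features$points, path, row.names = FALSE)
  invisible(path)
}
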