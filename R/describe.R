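# Shape-context descriptors and chi-square descriptor costs.
#
# Each feature point is described by a log-polar occupancy histogram of the
# positions of the *other points of the same class* relative to it, and
# descriptors are compared per class with the chi-square cost
# D = 1/2 * sum_k (h2(k) - h1(k))^2 / (h2(k) + h1(k)).

#' Default shape-context parameters
#'
#' `r_inner`/`r_outer` of `NULL` mean "derive from the point set": 0.125x and
#' 2x the mean pairwise distance of the image's points.
#'
#' @return Named list: `n_r`, `n_theta`, `r_inner`, `r_outer`.
#' @export
sc_params <- function() {
  list(n_r = 5L, n_theta = 12L, r_inner = NULL, r_outer = NULL)
}

# default radial scale from a point set (>= 2 points)
sc_radial_scale <- function(pts) {
  if (nrow(pts) < 2) return(c(r_inner = 1, r_outer = 16))
  md <- mean(dist(as.matrix(pts[, c("row", "col")])))
  c(r_inner = 0.125 * md, r_outer = 2 * md)
}

#' Shape-context descriptor of one feature point
#'
#' Log-polar histogram of all other points in `all_points` relative to
#' `center`: `n_r` radial bins uniform in `log(r)` between `r_inner` and
#' `r_outer` (points nearer than `r_inner` fall into the first radial bin;
#' points beyond `r_outer` are dropped), and `n_theta` angular bins uniform
#' on \[0, 2*pi) with the angle measured from the +col axis rotating toward
#' -row (upward on screen). Bins are flattened radial-major: bin index
#' `k = (i_r - 1) * n_theta + i_theta`.
#'
#' @param all_points Data frame with `row`, `col` (same-class points,
#'   including the center).
#' @param center Either a row index into `all_points` or a list/data frame
#'   row with `row`, `col`; must be present in `all_points`.
#' @param n_r,n_theta Bin counts (>= 1).
#' @param r_inner,r_outer Radial annulus in pixels (0 < r_inner < r_outer);
#'   `NULL` derives both from the point set via the mean pairwise distance.
#' @return An `sc_descriptor`: list with `counts` (length `n_r * n_theta`),
#'   `point`, and the bin geometry.
#' @export
shape_context <- function(all_points, center, n_r = 5L, n_theta = 12L,
                          r_inner = NULL, r_outer = NULL) {
  if (n_r < 1 || n_theta < 1) stop("n_r and n_theta must be >= 1")
  pts <- as.data.frame(all_points)
  if (is.numeric(center) && length(center) == 1) {
    ci <- as.integer(center)
    if (ci < 1 || ci > nrow(pts)) stop("center index out of range")
  } else {
    ci <- which(pts$row == center$row & pts$col == center$col)[1]
    if (is.na(ci)) stop("center point is not in `all_points`")
  }
  if (is.null(r_inner) || is.null(r_outer)) {
    sc <- sc_radial_scale(pts)
    if (is.null(r_inner)) r_inner <- sc["r_inner"]
    if (is.null(r_outer)) r_outer <- sc["r_outer"]
  }
  r_inner <- as.numeric(r_inner); r_outer <- as.numeric(r_outer)
  if (!(r_inner > 0 && r_outer > r_inner))
    stop("need 0 < r_inner < r_outer")
  K <- n_r * n_theta
  counts <- integer(K)
  if (nrow(pts) > 1) {
    dr <- pts$row[-ci] - pts$row[ci]
    dc <- pts$col[-ci] - pts$col[ci]
    r <- sqrt(dr^2 + dc^2)
    keep <- r <= r_outer & r > 0
    if (any(keep)) {
      r <- r[keep]; dr <- dr[keep]; dc <- dc[keep]
      edges <- exp(seq(log(r_inner), log(r_outer), length.out = n_r + 1))
      ir <- findInterval(r, edges, rightmost.closed = TRUE)
      ir[ir < 1] <- 1L          # nearer than r_inner -> first radial bin
      ir[ir > n_r] <- n_r
      th <- atan2(-dr, dc) %% (2 * pi)
      it <- floor(th / (2 * pi / n_theta)) + 1L
      it[it > n_theta] <- n_theta
      k <- (ir - 1L) * n_theta + it
      tab <- tabulate(k, nbins = K)
      counts <- tab
    }
  }
  structure(list(counts = counts,
                 point = pts[ci, , drop = FALSE],
                 K = K, n_r = n_r, n_theta = n_theta,
                 r_inner = r_inner, r_outer = r_outer),
            class = "sc_descriptor")
}

#' Chi-square cost between two shape-context descriptors
#'
#' `D = 1/2 * sum_k (h2(k) - h1(k))^2 / (h2(k) + h1(k))`, with 0/0 terms
#' contributing 0. Symmetric, non-negative, and 0 iff the histograms are
#' identical.
#'
#' @param h1,h2 `sc_descriptor` objects (or bare count vectors) with equal
#'   bin counts.
#' @return Scalar cost.
#' @export
sc_cost <- function(h1, h2) {
  c1 <- if (is.list(h1)) h1$counts else h1
  c2 <- if (is.list(h2)) h2$counts else h2
  if (length(c1) != length(c2))
    stop("descriptors have different numbers of bins")
  den <- c1 + c2
  nz <- den > 0
  0.5 * sum((c2[nz] - c1[nz])^2 / den[nz])
}

# all descriptors for one class of one image; returns K x n count matrix
sc_descriptor_matrix <- function(pts, n_r, n_theta, r_inner, r_outer) {
  n <- nrow(pts)
  K <- n_r * n_theta
  if (n == 0) return(matrix(0L, K, 0))
  out <- matrix(0L, K, n)
  for (i in seq_len(n)) {
    out[, i] <- shape_context(pts, i, n_r, n_theta, r_inner, r_outer)$counts
  }
  out
}

#' Per-class chi-square cost matrices between two feature sets
#'
#' Builds shape-context descriptors per class (W, B, C) in both images and
#' returns, for each class, the chi-square cost matrix with rows indexing
#' target-image descriptors and columns source-image descriptors. A class
#' empty in either image yields a 0 x 0 matrix. Radial scales default to
#' 0.125x / 2x the mean pairwise distance of each image's own point set.
#'
#' @param features_tgt,features_src `feature_set` objects (target and source).
#' @param params Parameter list as from [sc_params()].
#' @return A `cost_matrices` list: per class, a list with `costs`,
#'   `tgt_points`, `src_points`, and the descriptor count matrices
#'   `tgt_desc`, `src_desc`.
#' @export
cost_matrices <- function(features_tgt, features_src, params = sc_params()) {
  out <- list()
  for (kl in c("W", "B", "C")) {
    pt <- features_tgt$points[features_tgt$points$klass == kl, , drop = FALSE]
    ps <- features_src$points[features_src$points$klass == kl, , drop = FALSE]
    if (nrow(pt) == 0 || nrow(ps) == 0) {
      out[[kl]] <- list(costs = matrix(numeric(0), nrow(pt), 0)[, 0, drop = FALSE],
                        tgt_points = pt, src_points = ps,
                        tgt_desc = NULL, src_desc = NULL)
      out[[kl]]$costs <- matrix(numeric(0), 0, 0)
      next
    }
    st <- if (is.null(params$r_inner) || is.null(params$r_outer))
      sc_radial_scale(pt) else c(r_inner = params$r_inner, r_outer = params$r_outer)
    ss <- if (is.null(params$r_inner) || is.null(params$r_outer))
      sc_radial_scale(ps) else c(r_inner = params$r_inner, r_outer = params$r_outer)
    dt <- sc_descriptor_matrix(pt, params$n_r, params$n_theta, st[1], st[2])
    ds <- sc_descriptor_matrix(ps, params$n_r, params$n_theta, ss[1], ss[2])
    costs <- matrix(0, ncol(dt), ncol(ds))
    for (i in seq_len(ncol(dt))) {
      for (j in seq_len(ncol(ds))) {
        costs[i, j] <- sc_cost(dt[, i], ds[, j])
      }
    }
    out[[kl]] <- list(costs = costs, tgt_points = pt, src_points = ps,
                      tgt_desc = dt, src_desc = ds)
  }
  structure(out, class = "cost_matrices")
}
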