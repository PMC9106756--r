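# Two-stage iterative feature matching.
#
# Initial correspondences come from mutual minima of the per-class
# shape-context cost matrices.  Stage one removes incoherent pairs by
# iteratively fitting a thin-plate spline to the current inliers (with an
# annealed smoothing weight) and deleting pairs with large residuals; stage
# two re-admits unmatched points whose displacement is consistent with the
# inliers' mean displacement and with the fitted spline.  The two stages
# alternate until the control-point set is stable.  Removed pairs are
# recorded in a registry and never re-admitted.

#' Mutual-minimum initial matching
#'
#' Accepts pair `(i, j)` iff column `j` is the minimum of row `i` AND row `i`
#' is the minimum of column `j` of the cost matrix (rows = target
#' descriptors, cols = source descriptors). Ties are broken toward the
#' smaller index, giving at most one match per point.
#'
#' @param cost Numeric cost matrix (finite entries).
#' @return Two-column integer matrix (`tgt`, `src`) of accepted index pairs
#'   with a `"cost"` attribute; zero rows when the matrix is empty.
#' @export
initial_match <- function(cost) {
  if (length(cost) == 0 || nrow(cost) == 0 || ncol(cost) == 0)
    return(structure(cbind(tgt = integer(0), src = integer(0)),
                     cost = numeric(0)))
  if (any(!is.finite(cost))) stop("cost matrix must be finite")
  row_min <- apply(cost, 1, which.min)   # first index on ties
  col_min <- apply(cost, 2, which.min)
  acc <- which(col_min[row_min] == seq_len(nrow(cost)))
  m <- cbind(tgt = acc, src = as.integer(row_min[acc]))
  structure(m, cost = cost[m])
}

# thin-plate spline kernel U(r) = r^2 log(r), 0 at r = 0
tps_kernel <- function(r) {
  out <- r
  nz <- r > 0
  out[nz] <- r[nz]^2 * log(r[nz])
  out[!nz] <- 0
  out
}

#' Fit a thin-plate spline mapping source points to target points
#'
#' Minimizes the sum of squared residuals at the control points plus
#' `lambda_reg` times the bending energy. With `lambda_reg = 0` the spline
#' interpolates the control points exactly; with three non-collinear points
#' it reduces to the affine interpolant. Kernel weights satisfy the standard
#' side conditions (orthogonal to `[1, x, y]`).
#'
#' @param pairs Data frame with `row_src`, `col_src`, `row_tgt`, `col_tgt`
#'   (0-based pixel coordinates).
#' @param lambda_reg Smoothing regularizer (>= 0).
#' @return A `tps_model` with `control_points`, `kernel_weights` (n x 2),
#'   `affine` (3 x 2: intercept, col, row coefficients per output) and
#'   `lambda_reg`.
#' @export
tps_fit <- function(pairs, lambda_reg = 0) {
  pairs <- as.data.frame(pairs)
  n <- nrow(pairs)
  if (n < 3) stop("need at least 3 control points")
  if (lambda_reg < 0) stop("lambda_reg must be >= 0")
  src <- cbind(pairs$row_src, pairs$col_src)
  tgt <- cbind(pairs$row_tgt, pairs$col_tgt)
  P <- cbind(1, src)
  if (qr(P)$rank < 3)
    stop("degenerate control-point configuration (collinear points)")
  K <- tps_kernel(as.matrix(dist(src)))
  A <- rbind(cbind(K + diag(lambda_reg, n), P),
             cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(tgt, matrix(0, 3, 2))
  sol <- tryCatch(solve(A, rhs),
                  error = function(e) stop("TPS system is singular: ",
                                           conditionMessage(e)))
  structure(list(control_points = src,
                 kernel_weights = sol[seq_len(n), , drop = FALSE],
                 affine = sol[n + 1:3, , drop = FALSE],
                 lambda_reg = lambda_reg),
            class = "tps_model")
}

#' Evaluate a fitted thin-plate spline
#'
#' @param model A `tps_model` from [tps_fit()].
#' @param pts Two-column matrix of 0-based (row, col) query points.
#' @return Two-column matrix of mapped (row, col) points.
#' @export
tps_predict <- function(model, pts) {
  pts <- rbind(pts)
  d <- sqrt(outer(pts[, 1], model$control_points[, 1], "-")^2 +
            outer(pts[, 2], model$control_points[, 2], "-")^2)
  U <- tps_kernel(d)
  cbind(1, pts) %*% model$affine + U %*% model$kernel_weights
}

tps_residuals <- function(model, pairs) {
  pred <- tps_predict(model, cbind(pairs$row_src, pairs$col_src))
  sqrt((pred[, 1] - pairs$row_tgt)^2 + (pred[, 2] - pairs$col_tgt)^2)
}

#' Default matching parameters
#'
#' Stage-one removal: the spline smoothing weight is annealed as
#' `lambda0 * anneal^t` over at most `max_passes` passes, and a pair is
#' removed when its residual exceeds
#' `max(theta_min, resid_factor * median residual)`. Stage-two addition
#' accepts a candidate whose displacement norm is within `tau_add` px of the
#' inlier mean and whose spline prediction error is within `tau_tps` px.
#'
#' @return Named list of parameters.
#' @export
match_params <- function() {
  list(lambda0 = 1000, anneal = 0.5, max_passes = 8L,
       resid_factor = 2.5, theta_min = 2,
       tau_add = 3, tau_tps = 5,
       max_outer_iters = 10L)
}

#' Stage one: coherence-based mismatch removal
#'
#' Annealed backward elimination. At each pass `t` a thin-plate spline with
#' smoothing weight `lambda0 * anneal^t` is fitted to the current inliers;
#' while any residual `r_i = ||T(p_src_i) - p_tgt_i||` exceeds
#' `theta_t = max(theta_min, resid_factor * median(r))`, the single worst
#' pair is removed and the spline refitted at the same weight, so one
#' incoherent pair cannot drag its neighbors' residuals over the threshold
#' (leverage contamination). Stops when a pass removes nothing or
#' `max_passes` is reached. Deterministic.
#'
#' @param pairs Data frame of candidate pairs (needs `row_src`, `col_src`,
#'   `row_tgt`, `col_tgt`; >= 4 rows).
#' @param params Parameter list as from [match_params()].
#' @return List with `inliers`, `removed` (possibly 0-row), `model` (the last
#'   fitted spline) and `n_passes`.
#' @export
mrcsm_remove <- function(pairs, params = match_params()) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) < 4)
    stop("mismatch removal needs at least 4 pairs")
  inl <- pairs
  removed <- pairs[0, , drop = FALSE]
  model <- NULL
  pass <- 0L
  repeat {
    lambda_t <- params$lambda0 * params$anneal^pass
    removed_this_pass <- 0L
    repeat {
      model <- tps_fit(inl, lambda_reg = lambda_t)
      r <- tps_residuals(model, inl)
      theta <- max(params$theta_min, params$resid_factor * median(r))
      if (!any(r > theta)) break
      worst <- which.max(r)
      removed <- rbind(removed, inl[worst, , drop = FALSE])
      inl <- inl[-worst, , drop = FALSE]
      removed_this_pass <- removed_this_pass + 1L
      if (nrow(inl) < 4)
        stop("fewer than 4 coherent pairs survive mismatch removal; ",
             "registration cannot proceed")
    }
    pass <- pass + 1L
    if (removed_this_pass == 0L || pass >= params$max_passes) break
  }
  list(inliers = inl, removed = removed, model = model, n_passes = pass)
}

pair_key <- function(p) paste(p$klass, p$src_idx, p$tgt_idx, sep = ":")

# assemble the pooled pair data frame from per-class index matches
pairs_from_matches <- function(costs, matches_by_class) {
  out <- NULL
  for (kl in names(matches_by_class)) {
    m <- matches_by_class[[kl]]
    if (is.null(m) || nrow(m) == 0) next
    cm <- costs[[kl]]
    df <- data.frame(
      row_src = cm$src_points$row[m[, "src"]],
      col_src = cm$src_points$col[m[, "src"]],
      row_tgt = cm$tgt_points$row[m[, "tgt"]],
      col_tgt = cm$tgt_points$col[m[, "tgt"]],
      klass = kl,
      cost = cm$costs[m],
      src_idx = m[, "src"], tgt_idx = m[, "tgt"],
      stringsAsFactors = FALSE)
    out <- rbind(out, df)
  }
  if (is.null(out))
    out <- data.frame(row_src = numeric(0), col_src = numeric(0),
                      row_tgt = numeric(0), col_tgt = numeric(0),
                      klass = character(0), cost = numeric(0),
                      src_idx = integer(0), tgt_idx = integer(0))
  out
}

#' Stage two: add coherent pairs among unmatched points
#'
#' Computes the inlier mean displacement magnitude
#' `d_bar = (1/K) * sum_k ||p_tgt_k - p_src_k||` (K = number of inliers).
#' A same-class pair (s, t) of unmatched points is a candidate iff
#' `| ||t - s|| - d_bar | <= tau_add` and the stage-one spline predicts
#' `||T(s) - t|| <= tau_tps`. Pairs present in the removed registry are
#' excluded. Candidates are admitted greedily by ascending shape-context
#' cost, each source and target point used at most once.
#'
#' @param inliers Pooled inlier pair data frame (>= 4 rows).
#' @param removed_keys Character keys (`klass:src:tgt`) of registry pairs.
#' @param costs `cost_matrices` object.
#' @param model Stage-one `tps_model`.
#' @param params Parameter list as from [match_params()].
#' @return Data frame of added pairs (possibly 0-row), same columns as
#'   `inliers`.
#' @export
add_pairs <- function(inliers, removed_keys, costs, model,
                      params = match_params()) {
  stopifnot(nrow(inliers) >= 4)
  d_bar <- mean(sqrt((inliers$row_tgt - inliers$row_src)^2 +
                     (inliers$col_tgt - inliers$col_src)^2))
  cand <- NULL
  for (kl in names(costs)) {
    cm <- costs[[kl]]
    if (length(cm$costs) == 0) next
    used_src <- inliers$src_idx[inliers$klass == kl]
    used_tgt <- inliers$tgt_idx[inliers$klass == kl]
    free_src <- setdiff(seq_len(nrow(cm$src_points)), used_src)
    free_tgt <- setdiff(seq_len(nrow(cm$tgt_points)), used_tgt)
    if (!length(free_src) || !length(free_tgt)) next
    ps <- cm$src_points[free_src, , drop = FALSE]
    pt <- cm$tgt_points[free_tgt, , drop = FALSE]
    pred <- tps_predict(model, cbind(ps$row, ps$col))
    for (a in seq_along(free_src)) {
      disp <- sqrt((pt$row - ps$row[a])^2 + (pt$col - ps$col[a])^2)
      tps_err <- sqrt((pt$row - pred[a, 1])^2 + (pt$col - pred[a, 2])^2)
      ok <- abs(disp - d_bar) <= params$tau_add & tps_err <= params$tau_tps
      if (!any(ok)) next
      keys <- paste(kl, free_src[a], free_tgt[ok], sep = ":")
      ok[ok] <- !(keys %in% removed_keys)
      if (!any(ok)) next
      sel <- which(ok)
      cc <- cm$costs[free_tgt[sel], free_src[a]]
      # per-source best candidate by SC cost
      best <- sel[which.min(cc)]
      cand <- rbind(cand, data.frame(
        row_src = ps$row[a], col_src = ps$col[a],
        row_tgt = pt$row[best], col_tgt = pt$col[best],
        klass = kl, cost = min(cc),
        src_idx = free_src[a], tgt_idx = free_tgt[best],
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(cand)) return(inliers[0, , drop = FALSE])
  # greedy one-to-one by ascending SC cost
  cand <- cand[order(cand$cost), , drop = FALSE]
  used_t <- character(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    tk <- paste(cand$klass[i], cand$tgt_idx[i])
    if (!(tk %in% used_t)) {
      keep[i] <- TRUE
      used_t <- c(used_t, tk)
    }
  }
  cand[keep, , drop = FALSE]
}

#' Alternate mismatch removal and pair addition to a stable control-point set
#'
#' Starts from per-class mutual-minimum matches of the cost matrices, then
#' alternates stage-one removal ([mrcsm_remove()]) and stage-two addition
#' ([add_pairs()]) on the pooled pair set until a full pass changes nothing
#' or `max_outer_iters` is reached. The removed registry grows monotonically
#' and removed pairs are never re-admitted.
#'
#' @param features_tgt,features_src `feature_set` objects (unused beyond
#'   documentation of provenance; geometry is taken from `costs`).
#' @param costs `cost_matrices` from [cost_matrices()].
#' @param params Parameter list as from [match_params()].
#' @return A `control_point_set`: list with `inliers`, `removed`,
#'   `n_iterations`, `stable`, and the final `model`.
#' @export
iterate_matching <- function(features_tgt, features_src, costs,
                             params = match_params()) {
  matches <- lapply(costs, function(cm) initial_match(cm$costs))
  pairs <- pairs_from_matches(costs, matches)
  if (nrow(pairs) == 0)
    stop("no initial matches in any feature class")
  refine_matches(pairs, costs, params)
}

#' Refine an initial pooled pair set (removal/addition loop)
#'
#' The iterative core of [iterate_matching()], exposed so that a caller can
#' supply its own initial pair set (e.g. with known injected mismatches).
#'
#' @inheritParams iterate_matching
#' @param pairs Pooled initial pair data frame as built from per-class
#'   matches (columns `row_src`, `col_src`, `row_tgt`, `col_tgt`, `klass`,
#'   `cost`, `src_idx`, `tgt_idx`).
#' @return A `control_point_set` (see [iterate_matching()]).
#' @export
refine_matches <- function(pairs, costs, params = match_params()) {
  removed <- pairs[0, , drop = FALSE]
  inl <- pairs
  stable <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    before <- sort(pair_key(inl))
    st1 <- mrcsm_remove(inl, params)
    removed <- rbind(removed, st1$removed)
    inl <- st1$inliers
    added <- add_pairs(inl, pair_key(removed), costs, st1$model, params)
    inl <- rbind(inl, added)
    after <- sort(pair_key(inl))
    if (identical(before, after)) {
      stable <- TRUE
      break
    }
    if (iter >= params$max_outer_iters) break
  }
  structure(list(inliers = inl, removed = removed,
                 n_iterations = iter, stable = stable,
                 model = st1$model),
            class = "control_point_set")
}

#' Write a control-point set as CSV
#'
#' Columns: `x_src,y_src,x_tgt,y_tgt,klass,cost,status` with x = col,
#' y = row (0-based); `status` is `"inlier"` or `"removed"`.
#'
#' @param cps A `control_point_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_control_points <- function(cps, path) {
  fmt <- function(df, status) {
    if (nrow(df) == 0) return(NULL)
    data.frame(x_src = df$col_src, y_src = df$row_src,
               x_tgt = df$col_tgt, y_tgt = df$row_tgt,
               klass = df$klass, cost = df$cost, status = status)
  }
  out <- rbind(fmt(cps$inliers, "inlier"), fmt(cps$removed, "removed"))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
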