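# Match-constrained large-displacement optical flow.
#
# The dense displacement field w = (u, v) minimizes
#   E(w) = E_color + gamma * E_gradient + alpha * E_smooth + beta * E_match
# where E_color and E_gradient penalize intensity and gradient-constancy
# residuals between src(x) and tgt(x + w(x)) under the robust penalty
# Psi(s^2) = sqrt(s^2 + 1e-6), E_smooth penalizes the field gradient, and
# E_match anchors w at sparse matched points with a quadratic penalty.
# The energy is minimized by nested fixed-point iterations (linearization
# about the current field with frozen robust weights) whose inner linear
# systems are solved by point-coupled SOR, inside a coarse-to-fine Gaussian
# pyramid: the field at scale s initializes scale s-1 after bilinear
# upsampling and division by the scale factor eta.
#
# Fields use the backward convention: warping samples the image at
# x + w(x), so tgt(x + w(x)) is compared against src(x) on the src grid.

PSI_EPS <- 1e-6

psi_robust <- function(s2) sqrt(s2 + PSI_EPS)

#' Default flow solver parameters
#'
#' `alpha` weighs smoothness, `beta` the match constraints, `gamma` gradient
#' constancy (defaults 50, 10000, 20). `eta` is the pyramid scale factor,
#' `epsilon_stop` the SOR mean-squared-increment stopping threshold,
#' `omega_sor` the relaxation factor.
#'
#' @return Named list of solver parameters.
#' @export
ldof_params <- function() {
  list(alpha = 50, beta = 10000, gamma = 20,
       eta = 0.8, min_level_size = 20L,
       epsilon_stop = 1e-4, omega_sor = 1.85,
       max_fixed_point = 5L, max_sor = 200L)
}

# rasterize match anchors onto the src grid: beta at rounded (row, col),
# target displacement (du, dv); coincident anchors are averaged
match_maps <- function(matches, h, w, beta) {
  bm <- matrix(0, h, w); mu <- matrix(0, h, w); mv <- matrix(0, h, w)
  cnt <- matrix(0L, h, w)
  if (!is.null(matches) && nrow(matches) > 0) {
    r <- pmin(pmax(round(matches$row_src), 0), h - 1) + 1
    c <- pmin(pmax(round(matches$col_src), 0), w - 1) + 1
    for (i in seq_along(r)) {
      mu[r[i], c[i]] <- mu[r[i], c[i]] + (matches$col_tgt[i] - matches$col_src[i])
      mv[r[i], c[i]] <- mv[r[i], c[i]] + (matches$row_tgt[i] - matches$row_src[i])
      cnt[r[i], c[i]] <- cnt[r[i], c[i]] + 1L
    }
    nz <- cnt > 0
    mu[nz] <- mu[nz] / cnt[nz]
    mv[nz] <- mv[nz] / cnt[nz]
    bm[nz] <- beta
  }
  list(beta_map = bm, mu = mu, mv = mv)
}

#' Evaluate the four-term flow energy
#'
#' Components are sums over pixels of the robust penalty minus its value at
#' zero residual, so an exact solution scores 0 in every term; the constant
#' `I_pixels * Psi(0)` is reported separately as `psi_floor`.
#' `e_match` is the plain (non-robust) sum of squared differences between
#' `w` at each match anchor and the match displacement.
#'
#' @param w Displacement field: list with matrices `u` (col) and `v` (row).
#' @param src,tgt Intensity images of equal shape.
#' @param matches Data frame with `row_src`, `col_src`, `row_tgt`, `col_tgt`
#'   (anchors live on the `src` grid), or `NULL`.
#' @param params Parameter list as from [ldof_params()].
#' @return An `energy_breakdown`: list with `e_color`, `e_gradient`,
#'   `e_smooth`, `e_match`, `e_total` and `psi_floor`.
#' @export
ldof_energy <- function(w, src, tgt, matches = NULL, params = ldof_params()) {
  src <- unclass(src); tgt <- unclass(tgt)
  if (!all(dim(src) == dim(tgt)) || !all(dim(src) == dim(w$u)))
    stop("image and field shapes must match")
  h <- nrow(src); wd <- ncol(src)
  floor0 <- psi_robust(0)
  tw <- warp_bilinear(tgt, w$u, w$v)
  e_color <- sum(psi_robust((tw - src)^2) - floor0)
  gx_t <- deriv_x(tgt); gy_t <- deriv_y(tgt)
  gxw <- warp_bilinear(gx_t, w$u, w$v)
  gyw <- warp_bilinear(gy_t, w$u, w$v)
  e_gradient <- sum(psi_robust((gxw - deriv_x(src))^2 +
                               (gyw - deriv_y(src))^2) - floor0)
  e_smooth <- sum(psi_robust(deriv_x(w$u)^2 + deriv_y(w$u)^2 +
                             deriv_x(w$v)^2 + deriv_y(w$v)^2) - floor0)
  e_match <- 0
  if (!is.null(matches) && nrow(matches) > 0) {
    r <- pmin(pmax(round(matches$row_src), 0), h - 1) + 1
    c <- pmin(pmax(round(matches$col_src), 0), wd - 1) + 1
    idx <- cbind(r, c)
    e_match <- sum((w$u[idx] - (matches$col_tgt - matches$col_src))^2 +
                   (w$v[idx] - (matches$row_tgt - matches$row_src))^2)
  }
  e_total <- e_color + params$gamma * e_gradient +
    params$alpha * e_smooth + params$beta * e_match
  structure(list(e_color = e_color, e_gradient = e_gradient,
                 e_smooth = e_smooth, e_match = e_match,
                 e_total = e_total,
                 psi_floor = h * wd * floor0),
            class = "energy_breakdown")
}

#' Solve the flow at a single pyramid level
#'
#' Runs up to `max_fixed_point` outer linearizations about the current field
#' (warped images and robust weights frozen per pass); each linear system is
#' solved by point-coupled SOR with stopping rule
#' `(1/N) sum((du_k+1 - du_k)^2 + (dv_k+1 - dv_k)^2) < epsilon_stop`.
#' After each pass `w <- w + dw`, with step halving if the energy would
#' increase, so the energy trace is non-increasing. Aborts with a diagnostic
#' if the SOR error grows over 10 consecutive sweeps.
#'
#' @param src_s,tgt_s Images at this scale.
#' @param w_init Initial field (list `u`, `v`) or `NULL` for zero.
#' @param matches_s Matches rescaled to this level (or `NULL`).
#' @param params Parameter list as from [ldof_params()].
#' @return Displacement field (list `u`, `v`) with attributes `"sor_log"`
#'   (data frame: pass, n_sweeps, final_error, converged) and
#'   `"energy_trace"` (e_total per accepted pass, leading with the initial
#'   energy).
#' @export
solve_level <- function(src_s, tgt_s, w_init = NULL, matches_s = NULL,
                        params = ldof_params()) {
  src_s <- unclass(src_s); tgt_s <- unclass(tgt_s)
  h <- nrow(src_s); ww <- ncol(src_s)
  w <- if (is.null(w_init)) list(u = matrix(0, h, ww), v = matrix(0, h, ww))
       else w_init
  mm <- match_maps(matches_s, h, ww, params$beta)
  gx_t <- deriv_x(tgt_s); gy_t <- deriv_y(tgt_s)
  gxx_t <- deriv_xx(tgt_s); gxy_t <- deriv_xy(tgt_s); gyy_t <- deriv_yy(tgt_s)
  gx_s <- deriv_x(src_s); gy_s <- deriv_y(src_s)

  energy <- ldof_energy(w, src_s, tgt_s, matches_s, params)$e_total
  trace <- energy
  log <- NULL
  for (pass in seq_len(params$max_fixed_point)) {
    tw <- warp_bilinear(tgt_s, w$u, w$v)
    Ix <- warp_bilinear(gx_t, w$u, w$v)
    Iy <- warp_bilinear(gy_t, w$u, w$v)
    Ixx <- warp_bilinear(gxx_t, w$u, w$v)
    Ixy <- warp_bilinear(gxy_t, w$u, w$v)
    Iyy <- warp_bilinear(gyy_t, w$u, w$v)
    Iz <- tw - src_s
    Ixz <- Ix - gx_s
    Iyz <- Iy - gy_s
    wd <- 1 / (2 * sqrt(Iz^2 + PSI_EPS))
    wg <- 1 / (2 * sqrt(Ixz^2 + Iyz^2 + PSI_EPS))
    psi_s <- 1 / (2 * sqrt(deriv_x(w$u)^2 + deriv_y(w$u)^2 +
                           deriv_x(w$v)^2 + deriv_y(w$v)^2 + PSI_EPS))
    sol <- sor_solve(wd, wg, Ix, Iy, Iz, Ixx, Ixy, Iyy, Ixz, Iyz, psi_s,
                     w$u, w$v, mm$beta_map, mm$mu, mm$mv,
                     params$alpha, params$gamma, params$omega_sor,
                     params$epsilon_stop, params$max_sor)
    if (sol$diverged)
      stop("SOR iteration diverged (error grew over 10 consecutive sweeps)")
    log <- rbind(log, data.frame(pass = pass, n_sweeps = sol$n_sweeps,
                                 final_error = sol$final_error,
                                 converged = sol$final_error < params$epsilon_stop))
    # accept the step only if the energy does not increase (step halving)
    step <- 1
    accepted <- FALSE
    for (try in 1:7) {
      w_new <- list(u = w$u + step * sol$du, v = w$v + step * sol$dv)
      e_new <- ldof_energy(w_new, src_s, tgt_s, matches_s, params)$e_total
      if (e_new <= energy * (1 + 1e-12) + 1e-12) {
        w <- w_new; energy <- e_new; accepted <- TRUE
        break
      }
      step <- step / 2
    }
    trace <- c(trace, energy)
    if (!accepted) break
    if (max(abs(sol$du), abs(sol$dv)) * step < 1e-4) break
  }
  attr(w, "sor_log") <- log
  attr(w, "energy_trace") <- trace
  w
}

#' Estimate the dense displacement field (coarse-to-fine)
#'
#' Builds a Gaussian-prefiltered pyramid with scale factor `eta` down to
#' `min_level_size`, solves the coarsest level from a zero field, and
#' propagates the solution downward: the field is bilinearly resampled to
#' the finer grid and divided by the scale factor (`u^{s-1}(x) = u^s(eta x)
#' / eta`, likewise `v`). Match anchors are rescaled per level.
#'
#' @param src,tgt Intensity images of equal shape; the solved field `w`
#'   satisfies `tgt(x + w(x)) ~ src(x)` on the `src` grid.
#' @param matches Data frame with `row_src`, `col_src`, `row_tgt`,
#'   `col_tgt` (anchors on the `src` grid), a `control_point_set` (its
#'   inliers are used), or `NULL`.
#' @param params Parameter list as from [ldof_params()].
#' @return A `displacement_field`: list with matrices `u`, `v` and
#'   attribute `"levels"` holding the per-level solver logs.
#' @export
estimate_flow <- function(src, tgt, matches = NULL, params = ldof_params()) {
  src <- unclass(src); tgt <- unclass(tgt)
  if (!all(dim(src) == dim(tgt))) stop("images must have the same shape")
  if (inherits(matches, "control_point_set")) matches <- matches$inliers
  h <- nrow(src); w <- ncol(src)

  # pyramid dimensions, finest first
  dims <- list(c(h, w))
  repeat {
    nxt <- round(dims[[length(dims)]] * params$eta)
    if (min(nxt) < params$min_level_size) break
    dims[[length(dims) + 1]] <- nxt
  }
  sigma_pyr <- 0.5 * sqrt(1 / params$eta^2 - 1)
  pyr_src <- list(src); pyr_tgt <- list(tgt)
  for (k in seq_along(dims)[-1]) {
    pyr_src[[k]] <- resize_bilinear(gaussian_smooth(pyr_src[[k - 1]], sigma_pyr),
                                    dims[[k]][1], dims[[k]][2])
    pyr_tgt[[k]] <- resize_bilinear(gaussian_smooth(pyr_tgt[[k - 1]], sigma_pyr),
                                    dims[[k]][1], dims[[k]][2])
  }

  wfield <- NULL
  level_logs <- list()
  for (k in rev(seq_along(dims))) {
    dk <- dims[[k]]
    sr <- dk[1] / h; sc <- dk[2] / w
    m_k <- NULL
    if (!is.null(matches) && nrow(matches) > 0) {
      m_k <- data.frame(row_src = matches$row_src * sr,
                        col_src = matches$col_src * sc,
                        row_tgt = matches$row_tgt * sr,
                        col_tgt = matches$col_tgt * sc)
    }
    if (is.null(wfield)) {
      w_init <- NULL
    } else {
      prev <- dims[[k + 1]]
      w_init <- list(
        u = resize_bilinear(wfield$u, dk[1], dk[2]) * (dk[2] / prev[2]),
        v = resize_bilinear(wfield$v, dk[1], dk[2]) * (dk[1] / prev[1]))
    }
    wfield <- solve_level(pyr_src[[k]], pyr_tgt[[k]], w_init, m_k, params)
    level_logs[[length(level_logs) + 1]] <-
      list(dims = dk, sor_log = attr(wfield, "sor_log"),
           energy_trace = attr(wfield, "energy_trace"))
  }
  out <- list(u = wfield$u, v = wfield$v)
  attr(out, "levels") <- level_logs
  class(out) <- "displacement_field"
  out
}

#' Warp an image by a displacement field
#'
#' Backward warp `out(x) = image(x + w(x))` with bilinear interpolation,
#' nearest-edge extension outside the frame, and output clipped to \[0, 1\].
#'
#' @param image Intensity image.
#' @param w Displacement field (list `u`, `v` of matching shape).
#' @return Warped `intensity_image`.
#' @export
warp_image <- function(image, w) {
  img <- unclass(image)
  if (!all(dim(img) == dim(w$u))) stop("image and field shapes must match")
  out <- warp_bilinear(img, w$u, w$v)
  as_intensity_image(pmin(pmax(out, 0), 1), normalize = FALSE)
}

#' Write / read a displacement field
#'
#' `write_field()` stores the field as `<path>.bin` (two float32 planes, u
#' then v, column-major) plus `<path>.json` (shape and the backward-warp
#' convention); `read_field()` restores it.
#'
#' @param w Displacement field.
#' @param path Path prefix (no extension).
#' @return `write_field()`: `path`, invisibly. `read_field()`: the field.
#' @export
write_field <- function(w, path) {
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(w$u), con, size = 4)
  writeBin(as.numeric(w$v), con, size = 4)
  jsonlite::write_json(list(height = nrow(w$u), width = ncol(w$u),
                            planes = c("u", "v"), dtype = "float32",
                            order = "column-major", convention = "backward"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- hdr$height * hdr$width
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  u <- matrix(readBin(con, "numeric", n, size = 4), hdr$height, hdr$width)
  v <- matrix(readBin(con, "numeric", n, size = 4), hdr$height, hdr$width)
  structure(list(u = u, v = v), class = "displacement_field")
}
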