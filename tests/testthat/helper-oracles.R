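# Independent brute-force oracles used across the suite.  These deliberately
# re-derive quantities by the most literal route available (per-pixel loops,
# exhaustive scans, LAPACK eigendecompositions) so they share no code path
# with the vectorized implementations they check.

# smoothed random test image
random_smooth_image <- function(h, w, sigma = 3, seed = 1) {
  set.seed(seed)
  img <- gaussian_smooth(matrix(runif(h * w), h, w), sigma)
  (img - min(img)) / (max(img) - min(img))
}

# per-pixel LAPACK eigenvalues of the finite-difference Hessian of the
# smoothed image, interior pixels only, ordered by absolute value
oracle_hessian_eigen <- function(image, sigma) {
  g <- gaussian_smooth(unclass(image), sigma)
  h <- nrow(g); w <- ncol(g)
  lam1 <- lam2 <- matrix(NA_real_, h, w)
  for (i in 2:(h - 1)) {
    for (j in 2:(w - 1)) {
      hxx <- g[i, j + 1] - 2 * g[i, j] + g[i, j - 1]
      hyy <- g[i + 1, j] - 2 * g[i, j] + g[i - 1, j]
      hxy <- (g[i + 1, j + 1] - g[i + 1, j - 1] -
              g[i - 1, j + 1] + g[i - 1, j - 1]) / 4
      ev <- eigen(matrix(c(hxx, hxy, hxy, hyy), 2, 2),
                  symmetric = TRUE, only.values = TRUE)$values
      ord <- order(abs(ev))
      lam1[i, j] <- ev[ord[1]]
      lam2[i, j] <- ev[ord[2]]
    }
  }
  list(lambda1 = lam1, lambda2 = lam2)
}

# literal per-point log-polar binning
oracle_shape_context <- function(pts, ci, n_r, n_theta, r_inner, r_outer) {
  counts <- integer(n_r * n_theta)
  edges <- exp(seq(log(r_inner), log(r_outer), length.out = n_r + 1))
  for (i in seq_len(nrow(pts))) {
    if (i == ci) next
    dr <- pts$row[i] - pts$row[ci]
    dc <- pts$col[i] - pts$col[ci]
    r <- sqrt(dr^2 + dc^2)
    if (r == 0 || r > r_outer) next
    ir <- 1L
    while (ir < n_r && r > edges[ir + 1]) ir <- ir + 1L
    th <- atan2(-dr, dc)
    if (th < 0) th <- th + 2 * pi
    it <- min(floor(th / (2 * pi / n_theta)) + 1, n_theta)
    k <- (ir - 1L) * n_theta + it
    counts[k] <- counts[k] + 1L
  }
  counts
}

# exhaustive mutual-minimum scan with the smaller-index tie rule
oracle_mutual_minimum <- function(cost) {
  out <- NULL
  for (i in seq_len(nrow(cost))) {
    for (j in seq_len(ncol(cost))) {
      row_ok <- cost[i, j] <= min(cost[i, ]) &&
        j == which(cost[i, ] == min(cost[i, ]))[1]
      col_ok <- cost[i, j] <= min(cost[, j]) &&
        i == which(cost[, j] == min(cost[, j]))[1]
      if (row_ok && col_ok) out <- rbind(out, c(tgt = i, src = j))
    }
  }
  if (is.null(out)) cbind(tgt = integer(0), src = integer(0)) else out
}

# double-loop two-subpass thinning (hit-or-miss deletion masks)
oracle_thin <- function(mask) {
  m <- matrix(as.integer(as.logical(mask)), nrow(mask), ncol(mask))
  h <- nrow(m); w <- ncol(m)
  val <- function(mm, i, j) if (i < 1 || i > h || j < 1 || j > w) 0L else mm[i, j]
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      del <- NULL
      for (i in seq_len(h)) for (j in seq_len(w)) {
        if (m[i, j] == 0L) next
        p <- c(val(m, i - 1, j), val(m, i - 1, j + 1), val(m, i, j + 1),
               val(m, i + 1, j + 1), val(m, i + 1, j), val(m, i + 1, j - 1),
               val(m, i, j - 1), val(m, i - 1, j - 1))
        B <- sum(p)
        A <- sum(p == 0 & c(p[-1], p[1]) == 1)
        if (B < 2 || B > 6 || A != 1) next
        if (pass == 1) {
          if (p[1] * p[3] * p[5] != 0 || p[3] * p[5] * p[7] != 0) next
        } else {
          if (p[1] * p[3] * p[7] != 0 || p[1] * p[5] * p[7] != 0) next
        }
        del <- rbind(del, c(i, j))
      }
      if (!is.null(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# naive per-pixel bilinear backward warp with edge clamping
oracle_warp <- function(img, u, v) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    x <- min(max(j - 1 + u[i, j], 0), w - 1)
    y <- min(max(i - 1 + v[i, j], 0), h - 1)
    x0 <- floor(x); y0 <- floor(y)
    x1 <- min(x0 + 1, w - 1); y1 <- min(y0 + 1, h - 1)
    fx <- x - x0; fy <- y - y0
    out[i, j] <- (1 - fy) * ((1 - fx) * img[y0 + 1, x0 + 1] + fx * img[y0 + 1, x1 + 1]) +
                 fy * ((1 - fx) * img[y1 + 1, x0 + 1] + fx * img[y1 + 1, x1 + 1])
  }
  out
}

# straightforward-summation energy oracle (shares only the formulas)
oracle_energy <- function(w, src, tgt, matches, params) {
  psi <- function(s2) sqrt(s2 + 1e-6)
  f0 <- psi(0)
  h <- nrow(src); wd <- ncol(src)
  dx <- function(m) {
    out <- m
    for (i in seq_len(h)) for (j in seq_len(wd))
      out[i, j] <- (m[i, min(j + 1, wd)] - m[i, max(j - 1, 1)]) / 2
    out
  }
  # note: thermreg uses symmetric-reflect boundaries for central differences;
  # at the border the reflected neighbor equals the edge pixel, which this
  # clamped formulation reproduces exactly
  dy <- function(m) {
    out <- m
    for (i in seq_len(h)) for (j in seq_len(wd))
      out[i, j] <- (m[min(i + 1, h), j] - m[max(i - 1, 1), j]) / 2
    out
  }
  tw <- oracle_warp(tgt, w$u, w$v)
  e_color <- sum(psi((tw - src)^2) - f0)
  gxw <- oracle_warp(dx(tgt), w$u, w$v)
  gyw <- oracle_warp(dy(tgt), w$u, w$v)
  e_grad <- sum(psi((gxw - dx(src))^2 + (gyw - dy(src))^2) - f0)
  e_smooth <- sum(psi(dx(w$u)^2 + dy(w$u)^2 + dx(w$v)^2 + dy(w$v)^2) - f0)
  e_match <- 0
  if (!is.null(matches) && nrow(matches) > 0) {
    for (i in seq_len(nrow(matches))) {
      r <- round(matches$row_src[i]) + 1
      c <- round(matches$col_src[i]) + 1
      e_match <- e_match +
        (w$u[r, c] - (matches$col_tgt[i] - matches$col_src[i]))^2 +
        (w$v[r, c] - (matches$row_tgt[i] - matches$row_src[i]))^2
    }
  }
  e_color + params$gamma * e_grad + params$alpha * e_smooth +
    params$beta * e_match
}

# single pure-R lexicographic Gauss-Seidel/SOR sweep of the linearized flow
# system (reference for the compiled solver)
oracle_sor_sweep <- function(wd, wg, Ix, Iy, Iz, Ixx, Ixy, Iyy, Ixz, Iyz,
                             psi_s, u, v, beta_map, mu, mv,
                             alpha, gamma, omega, du, dv) {
  h <- nrow(wd); w <- ncol(wd)
  for (j in seq_len(w)) for (i in seq_len(h)) {
    sum_s <- sum_u <- sum_v <- 0
    for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
      if (nb[1] < 1 || nb[1] > h || nb[2] < 1 || nb[2] > w) next
      s <- 0.5 * (psi_s[i, j] + psi_s[nb[1], nb[2]])
      sum_s <- sum_s + s
      sum_u <- sum_u + s * (u[nb[1], nb[2]] - u[i, j] + du[nb[1], nb[2]])
      sum_v <- sum_v + s * (v[nb[1], nb[2]] - v[i, j] + dv[nb[1], nb[2]])
    }
    d <- wd[i, j]; g <- gamma * wg[i, j]; b <- beta_map[i, j]
    A11 <- d * Ix[i, j]^2 + g * (Ixx[i, j]^2 + Ixy[i, j]^2) + b + alpha * sum_s
    A22 <- d * Iy[i, j]^2 + g * (Ixy[i, j]^2 + Iyy[i, j]^2) + b + alpha * sum_s
    A12 <- d * Ix[i, j] * Iy[i, j] + g * Ixy[i, j] * (Ixx[i, j] + Iyy[i, j])
    b1 <- -d * Ix[i, j] * Iz[i, j] -
      g * (Ixx[i, j] * Ixz[i, j] + Ixy[i, j] * Iyz[i, j]) +
      b * (mu[i, j] - u[i, j]) + alpha * sum_u
    b2 <- -d * Iy[i, j] * Iz[i, j] -
      g * (Ixy[i, j] * Ixz[i, j] + Iyy[i, j] * Iyz[i, j]) +
      b * (mv[i, j] - v[i, j]) + alpha * sum_v
    det <- max(A11 * A22 - A12^2, 1e-12)
    du[i, j] <- (1 - omega) * du[i, j] + omega * (A22 * b1 - A12 * b2) / det
    dv[i, j] <- (1 - omega) * dv[i, j] + omega * (A11 * b2 - A12 * b1) / det
  }
  # constant-mode (coarse-grid) correction: Galerkin projection of the
  # residual onto globally constant increments
  G11 <- G12 <- G22 <- R1 <- R2 <- 0
  for (j in seq_len(w)) for (i in seq_len(h)) {
    sum_s <- sum_u <- sum_v <- 0
    for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
      if (nb[1] < 1 || nb[1] > h || nb[2] < 1 || nb[2] > w) next
      s <- 0.5 * (psi_s[i, j] + psi_s[nb[1], nb[2]])
      sum_s <- sum_s + s
      sum_u <- sum_u + s * (u[nb[1], nb[2]] - u[i, j] + du[nb[1], nb[2]])
      sum_v <- sum_v + s * (v[nb[1], nb[2]] - v[i, j] + dv[nb[1], nb[2]])
    }
    d <- wd[i, j]; g <- gamma * wg[i, j]; b <- beta_map[i, j]
    a11 <- d * Ix[i, j]^2 + g * (Ixx[i, j]^2 + Ixy[i, j]^2) + b
    a22 <- d * Iy[i, j]^2 + g * (Ixy[i, j]^2 + Iyy[i, j]^2) + b
    a12 <- d * Ix[i, j] * Iy[i, j] + g * Ixy[i, j] * (Ixx[i, j] + Iyy[i, j])
    c1 <- -d * Ix[i, j] * Iz[i, j] -
      g * (Ixx[i, j] * Ixz[i, j] + Ixy[i, j] * Iyz[i, j]) +
      b * (mu[i, j] - u[i, j])
    c2 <- -d * Iy[i, j] * Iz[i, j] -
      g * (Ixy[i, j] * Ixz[i, j] + Iyy[i, j] * Iyz[i, j]) +
      b * (mv[i, j] - v[i, j])
    R1 <- R1 + c1 + alpha * sum_u - (a11 + alpha * sum_s) * du[i, j] -
      a12 * dv[i, j]
    R2 <- R2 + c2 + alpha * sum_v - (a22 + alpha * sum_s) * dv[i, j] -
      a12 * du[i, j]
    G11 <- G11 + a11; G12 <- G12 + a12; G22 <- G22 + a22
  }
  detG <- G11 * G22 - G12^2
  if (detG > 1e-10 && G11 + G22 > 1e-10) {
    du <- du + (G22 * R1 - G12 * R2) / detG
    dv <- dv + (G11 * R2 - G12 * R1) / detG
  }
  list(du = du, dv = dv)
}
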