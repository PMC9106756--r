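# synthetic crossing-ridge image: two perpendicular Gaussian ridges
ridge_cross <- function(h = 64, w = 64, amp = 0.4, sv = 2) {
  R <- matrix(seq_len(h) - 1, h, w)
  C <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  r0 <- (h - 1) / 2; c0 <- (w - 1) / 2
  0.4 + amp * pmax(exp(-(R - r0)^2 / (2 * sv^2)),
                   exp(-(C - c0)^2 / (2 * sv^2)))
}

test_that("Hessian eigenvalues vanish on a constant image", {
  eig <- hessian_eigen(matrix(0.5, 40, 40), sigma = 2)
  expect_equal(max(abs(eig$lambda1)), 0, tolerance = 1e-14)
  expect_equal(max(abs(eig$lambda2)), 0, tolerance = 1e-14)
})

test_that("a bright blob has a negative dominant eigenvalue at its center", {
  h <- w <- 41
  R <- matrix(seq_len(h) - 1, h, w)
  C <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  img <- 0.3 + 0.5 * exp(-((R - 20)^2 + (C - 20)^2) / (2 * 4^2))
  eig <- hessian_eigen(img, sigma = 2)
  expect_lt(eig$lambda2[21, 21], 0)
  expect_lt(eig$lambda1[21, 21], 0)
  # dark blob: positive
  eig2 <- hessian_eigen(1 - img, sigma = 2)
  expect_gt(eig2$lambda2[21, 21], 0)
})

test_that("negating the image swaps hot and cold masks exactly", {
  img <- random_smooth_image(48, 56, sigma = 3, seed = 12)
  m1 <- binarize_patterns(hessian_eigen(img, 2))
  m2 <- binarize_patterns(hessian_eigen(1 - img, 2))
  expect_identical(m1$hot, m2$cold)
  expect_identical(m1$cold, m2$hot)
  expect_false(any(m1$hot & m1$cold))
})

test_that("binarization respects the sign convention on a hand-built field", {
  eig <- list(lambda1 = matrix(c(1, -1, 0, 0.5), 2, 2),
              lambda2 = matrix(c(-5, 5, 0, 2), 2, 2), sigma = 2)
  class(eig) <- "eigen_field"
  m <- binarize_patterns(eig, tau_rel = 1e-6)
  expect_identical(m$hot, matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  expect_identical(m$cold, matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2))
})

test_that("thinning matches the double-loop reference and is idempotent", {
  set.seed(31)
  for (rep in 1:3) {
    mask <- matrix(FALSE, 18, 22)
    # random thick blob
    r0 <- sample(5:12, 1); c0 <- sample(6:15, 1)
    R <- matrix(seq_len(18), 18, 22)
    C <- matrix(seq_len(22), 18, 22, byrow = TRUE)
    mask[(R - r0)^2 + (C - c0)^2 < sample(9:25, 1)] <- TRUE
    mask[r0, ] <- TRUE
    got <- skeletonize_mask(mask)
    ref <- oracle_thin(mask)
    expect_identical(got, ref)
    expect_identical(skeletonize_mask(got), got)
  }
})

test_that("thinning preserves the component count of a thick plus shape", {
  mask <- matrix(FALSE, 31, 31)
  mask[14:18, 4:28] <- TRUE
  mask[4:28, 14:18] <- TRUE
  sk <- skeletonize_mask(mask)
  expect_equal(max(thermreg:::label8(sk)), max(thermreg:::label8(mask)))
  # one-pixel wide: no 2x2 block fully set
  blk <- sk[-1, -1] & sk[-nrow(sk), -1] & sk[-1, -ncol(sk)] &
    sk[-nrow(sk), -ncol(sk)]
  expect_false(any(blk))
})

test_that("branch points: a plus has one, a line none", {
  plus <- matrix(FALSE, 21, 21)
  plus[11, 3:19] <- TRUE
  plus[3:19, 11] <- TRUE
  p <- detect_intersections(plus, "W")
  expect_equal(nrow(p), 1)
  expect_equal(c(p$row, p$col), c(10, 10))
  line <- matrix(FALSE, 21, 21)
  line[11, 3:19] <- TRUE
  expect_equal(nrow(detect_intersections(line, "W")), 0)
  expect_equal(nrow(detect_intersections(matrix(FALSE, 5, 5), "W")), 0)
})

test_that("a grid of lines yields one branch point per crossing", {
  grid <- matrix(FALSE, 40, 40)
  for (g in c(10, 20, 30)) {
    grid[g, 4:36] <- TRUE
    grid[4:36, g] <- TRUE
  }
  p <- detect_intersections(grid, "B")
  expect_equal(nrow(p), 9)
  truth <- expand.grid(row = c(9, 19, 29), col = c(9, 19, 29))
  for (i in seq_len(9)) {
    d <- sqrt((truth$row - p$row[i])^2 + (truth$col - p$col[i])^2)
    expect_lte(min(d), 1)
  }
})

test_that("Harris finds the corners of a bright square and respects masks", {
  img <- matrix(0.2, 64, 64)
  img[20:44, 20:44] <- 0.9
  img <- gaussian_smooth(img, 1)
  p <- harris_corners(img)
  expect_equal(nrow(p), 4)
  truth <- expand.grid(row = c(19, 43), col = c(19, 43))
  for (i in 1:4) {
    d <- sqrt((truth$row - p$row[i])^2 + (truth$col - p$col[i])^2)
    expect_lte(min(d), 2.5)
  }
  # restrict to the left half: only the two left corners remain
  mask <- matrix(FALSE, 64, 64); mask[, 1:32] <- TRUE
  pl <- harris_corners(img, mask)
  expect_equal(nrow(pl), 2)
  expect_true(all(pl$col < 32))
  expect_equal(nrow(harris_corners(matrix(0.5, 32, 32))), 0)
  expect_error(harris_corners(img, k = 0.5), "k must be")
})

test_that("detection on a crossing-ridge image finds the crossing", {
  img <- ridge_cross()
  f <- detect_features(img)
  w_pts <- f$points[f$points$klass == "W", ]
  expect_gte(nrow(w_pts), 1)
  d <- sqrt((w_pts$row - 31.5)^2 + (w_pts$col - 31.5)^2)
  expect_lt(min(d), 3)
})

test_that("a blob's internal grid is recovered as B points on the lattice", {
  spec <- phantom_spec(height = 96, width = 96, n_vessel_segments = 0,
                       n_cold_blobs = 1, cold_blob_radius_range = c(26, 28),
                       cold_grid_spacing = 9, noise_sd = 0,
                       background_smoothness = 15, seed = 9L)
  img <- generate_phantom(spec)
  lattice <- attr(img, "truth")$lattice
  expect_gte(nrow(lattice), 9)
  f <- detect_features(img)
  b_pts <- f$points[f$points$klass == "B", ]
  expect_gte(nrow(b_pts), 9)
  # core lattice points (at least one grid cell away from the blob rim,
  # where the rim ring does not perturb the skeleton) are each recovered
  blob <- attr(img, "truth")$blobs
  dc <- sqrt((lattice$row - blob$row)^2 + (lattice$col - blob$col)^2)
  core <- lattice[dc <= blob$radius - spec$cold_grid_spacing, ]
  expect_gte(nrow(core), 9)
  covered <- vapply(seq_len(nrow(core)), function(i) {
    min(sqrt((b_pts$row - core$row[i])^2 +
             (b_pts$col - core$col[i])^2)) <= 2
  }, logical(1))
  expect_true(all(covered))
})

test_that("feature classes live in their own masks", {
  p <- phantom_preset("I", height = 128, width = 160, seed = 15L)
  img <- generate_phantom(p$spec)
  f <- detect_features(img)
  layers <- attr(f, "layers")
  pts <- f$points
  expect_true(all(c("W", "B", "C") %in% pts$klass))
  for (i in which(pts$klass == "C")) {
    expect_true(layers$hot[pts$row[i] + 1, pts$col[i] + 1])
  }
  # points are deduplicated within classes
  for (kl in unique(pts$klass)) {
    sub <- pts[pts$klass == kl, ]
    if (nrow(sub) > 1) {
      d <- as.matrix(dist(cbind(sub$row, sub$col)))
      diag(d) <- Inf
      expect_gt(min(d), 0)
    }
  }
})
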