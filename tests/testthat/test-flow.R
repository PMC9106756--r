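zero_field <- function(h, w) list(u = matrix(0, h, w), v = matrix(0, h, w))

test_that("warping matches the per-pixel bilinear oracle", {
  img <- random_smooth_image(20, 26, sigma = 2, seed = 51)
  set.seed(52)
  u <- matrix(runif(20 * 26, -3, 3), 20, 26)
  v <- matrix(runif(20 * 26, -3, 3), 20, 26)
  got <- unclass(warp_image(as_intensity_image(img, normalize = FALSE),
                            list(u = u, v = v)))
  ref <- oracle_warp(img, u, v)
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("integer translations shift the image exactly in the interior", {
  img <- random_smooth_image(30, 30, sigma = 2, seed = 53)
  w <- list(u = matrix(2, 30, 30), v = matrix(-3, 30, 30))
  out <- unclass(warp_image(as_intensity_image(img, normalize = FALSE), w))
  expect_equal(out[5:26, 3:27], img[2:23, 5:29], tolerance = 1e-12)
})

test_that("the energy of a perfect alignment is zero in every term", {
  img <- random_smooth_image(24, 24, sigma = 2, seed = 54)
  e <- ldof_energy(zero_field(24, 24), img, img)
  expect_equal(e$e_color, 0, tolerance = 1e-10)
  expect_equal(e$e_gradient, 0, tolerance = 1e-10)
  expect_equal(e$e_smooth, 0, tolerance = 1e-10)
  expect_equal(e$e_match, 0)
  expect_equal(e$e_total, 0, tolerance = 1e-8)
  expect_equal(e$psi_floor, 24 * 24 * sqrt(1e-6))
})

test_that("the match term is the quadratic anchor penalty", {
  img <- random_smooth_image(20, 20, sigma = 2, seed = 55)
  m <- data.frame(row_src = 10, col_src = 10, row_tgt = 14, col_tgt = 13)
  e <- ldof_energy(zero_field(20, 20), img, img, m)
  expect_equal(e$e_match, 3^2 + 4^2)
  expect_equal(e$e_total - ldof_energy(zero_field(20, 20), img, img)$e_total,
               ldof_params()$beta * 25, tolerance = 1e-9)
})

test_that("the energy matches the straightforward-summation oracle", {
  set.seed(56)
  src <- random_smooth_image(16, 18, sigma = 1.5, seed = 57)
  tgt <- random_smooth_image(16, 18, sigma = 1.5, seed = 58)
  w <- list(u = matrix(rnorm(16 * 18, 0, 1), 16, 18),
            v = matrix(rnorm(16 * 18, 0, 1), 16, 18))
  m <- data.frame(row_src = c(5, 9), col_src = c(6, 12),
                  row_tgt = c(6.2, 8.1), col_tgt = c(7.4, 13.3))
  p <- ldof_params()
  got <- ldof_energy(w, src, tgt, m, p)$e_total
  ref <- oracle_energy(w, src, tgt, m, p)
  expect_equal(got, ref, tolerance = 1e-8)
})

test_that("one compiled SOR sweep equals the pure-R reference sweep", {
  set.seed(59)
  h <- 9; w <- 11
  rm_ <- function(lo, hi) matrix(runif(h * w, lo, hi), h, w)
  args <- list(wd = rm_(0.1, 5), wg = rm_(0.1, 5),
               Ix = rm_(-1, 1), Iy = rm_(-1, 1), Iz = rm_(-1, 1),
               Ixx = rm_(-1, 1), Ixy = rm_(-1, 1), Iyy = rm_(-1, 1),
               Ixz = rm_(-1, 1), Iyz = rm_(-1, 1),
               psi_s = rm_(0.1, 5),
               u = rm_(-2, 2), v = rm_(-2, 2),
               beta_map = matrix(0, h, w), mu = matrix(0, h, w),
               mv = matrix(0, h, w))
  args$beta_map[4, 6] <- 100; args$mu[4, 6] <- 2; args$mv[4, 6] <- -1
  alpha <- 50; gamma <- 20; omega <- 1.85
  got <- thermreg:::sor_solve(args$wd, args$wg, args$Ix, args$Iy, args$Iz,
                              args$Ixx, args$Ixy, args$Iyy, args$Ixz,
                              args$Iyz, args$psi_s, args$u, args$v,
                              args$beta_map, args$mu, args$mv,
                              alpha, gamma, omega,
                              eps_stop = 0, max_sor = 1L)
  ref <- oracle_sor_sweep(args$wd, args$wg, args$Ix, args$Iy, args$Iz,
                          args$Ixx, args$Ixy, args$Iyy, args$Ixz, args$Iyz,
                          args$psi_s, args$u, args$v,
                          args$beta_map, args$mu, args$mv,
                          alpha, gamma, omega,
                          du = matrix(0, h, w), dv = matrix(0, h, w))
  expect_equal(got$du, ref$du, tolerance = 1e-10)
  expect_equal(got$dv, ref$dv, tolerance = 1e-10)
  # the logged stopping error follows Eq. (15): mean squared increment change
  expect_equal(got$final_error,
               mean(ref$du^2 + ref$dv^2), tolerance = 1e-10)
  expect_equal(got$n_sweeps, 1L)
})

test_that("identical images give a (near-)zero field", {
  img <- random_smooth_image(40, 48, sigma = 3, seed = 60)
  w <- estimate_flow(img, img)
  expect_lt(max(abs(w$u)), 1e-2)
  expect_lt(max(abs(w$v)), 1e-2)
})

test_that("a one-pixel shift is recovered at a single level", {
  img <- random_smooth_image(48, 48, sigma = 3, seed = 61)
  # shifted = img warped by (1, 0); solving with shifted as the source
  # recovers w = (1, 0) under the tgt(x + w) ~ src(x) convention
  shifted <- oracle_warp(img, matrix(1, 48, 48), matrix(0, 48, 48))
  w <- solve_level(shifted, img, NULL, NULL)
  inner <- w$u[10:39, 10:39]
  expect_lt(mean(abs(inner - 1)), 0.25)
  expect_lt(mean(abs(w$v[10:39, 10:39])), 0.2)
})

test_that("the per-pass energy trace is non-increasing", {
  img <- random_smooth_image(40, 40, sigma = 3, seed = 62)
  shifted <- oracle_warp(img, matrix(1.5, 40, 40), matrix(-1, 40, 40))
  w <- solve_level(img, shifted, NULL, NULL)
  tr <- attr(w, "energy_trace")
  expect_gte(length(tr), 2)
  expect_true(all(diff(tr) <= 1e-8))
  log <- attr(w, "sor_log")
  expect_true(all(c("pass", "n_sweeps", "final_error", "converged")
                  %in% names(log)))
  expect_true(all(log$final_error[log$converged] <
                    ldof_params()$epsilon_stop))
})

test_that("match anchors pull the field toward the matched displacement", {
  img <- random_smooth_image(40, 40, sigma = 3, seed = 63)
  # flat source/target pair: data terms carry no information in the middle
  m <- data.frame(row_src = 20, col_src = 20, row_tgt = 26, col_tgt = 20)
  p <- ldof_params()
  w_with <- solve_level(img, img, NULL, m, p)
  expect_gt(w_with$v[21, 21], 1)
  p0 <- p; p0$beta <- 0
  w_without <- solve_level(img, img, NULL, m, p0)
  expect_lt(abs(w_without$v[21, 21]), 0.05)
})

test_that("field serialization round-trips", {
  set.seed(64)
  w <- list(u = matrix(rnorm(30), 5, 6), v = matrix(rnorm(30), 5, 6))
  pre <- file.path(tempdir(), "fld")
  write_field(w, pre)
  back <- read_field(pre)
  expect_equal(back$u, w$u, tolerance = 1e-6)
  expect_equal(back$v, w$v, tolerance = 1e-6)
  hdr <- jsonlite::read_json(paste0(pre, ".json"))
  expect_identical(hdr$convention, "backward")
  unlink(paste0(pre, c(".bin", ".json")))
})
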