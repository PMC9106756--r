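empty_costs <- structure(list(), class = "cost_matrices")

test_that("mutual-minimum matching on hand-built matrices", {
  m <- initial_match(matrix(c(0, 5, 5, 0), 2, 2, byrow = TRUE))
  expect_equal(unname(m[, "tgt"]), c(1L, 2L))
  expect_equal(unname(m[, "src"]), c(1L, 2L))
  # row 2's minimum is column 1, but column 1 prefers row 1 -> only (1,1)
  # survives mutually... here both diagonal entries are mutual minima
  m2 <- initial_match(matrix(c(1, 2, 1.5, 1.2), 2, 2, byrow = TRUE))
  expect_equal(unname(m2[, "tgt"]), c(1L, 2L))
  expect_equal(unname(m2[, "src"]), c(1L, 2L))
  # one source dominating two targets yields a single match
  m3 <- initial_match(matrix(c(1, 10, 2, 10), 2, 2, byrow = TRUE))
  expect_equal(nrow(m3), 1)
  expect_equal(unname(m3[1, ]), c(1L, 1L))
  expect_equal(nrow(initial_match(matrix(numeric(0), 0, 0))), 0)
  expect_error(initial_match(matrix(c(1, Inf, 2, 3), 2, 2)), "finite")
})

test_that("ties break toward the smaller index", {
  cost <- matrix(1, 3, 3)
  m <- initial_match(cost)
  expect_equal(nrow(m), 1)
  expect_equal(unname(m[1, ]), c(1L, 1L))
})

test_that("mutual-minimum matching agrees with the exhaustive oracle", {
  set.seed(63)
  for (rep in 1:25) {
    nr <- sample(1:12, 1); nc <- sample(1:12, 1)
    cost <- matrix(sample(1:6, nr * nc, replace = TRUE) +
                     round(runif(nr * nc), 1), nr, nc)
    got <- initial_match(cost)
    ref <- oracle_mutual_minimum(cost)
    got <- got[order(got[, "tgt"]), , drop = FALSE]
    ref <- ref[order(ref[, "tgt"]), , drop = FALSE]
    expect_equal(unname(got[, 1:2, drop = FALSE]),
                 unname(ref[, 1:2, drop = FALSE]))
  }
})

test_that("TPS interpolates exactly with zero regularization", {
  set.seed(3)
  n <- 12
  pr <- data.frame(row_src = runif(n, 0, 100), col_src = runif(n, 0, 100))
  pr$row_tgt <- pr$row_src + 3 + 0.05 * pr$col_src + sin(pr$row_src / 20)
  pr$col_tgt <- pr$col_src - 2 + 0.04 * pr$row_src
  model <- tps_fit(pr, lambda_reg = 0)
  r <- thermreg:::tps_residuals(model, pr)
  expect_lt(max(r), 1e-6)
  # side conditions: kernel weights orthogonal to [1, row, col]
  P <- cbind(1, model$control_points)
  expect_lt(max(abs(t(P) %*% model$kernel_weights)), 1e-6)
})

test_that("TPS reproduces an affine map exactly away from the knots", {
  set.seed(8)
  n <- 10
  pr <- data.frame(row_src = runif(n, 0, 80), col_src = runif(n, 0, 80))
  pr$row_tgt <- 2 + 1.1 * pr$row_src + 0.2 * pr$col_src
  pr$col_tgt <- -1 + 0.95 * pr$col_src - 0.1 * pr$row_src
  model <- tps_fit(pr)
  q <- cbind(runif(50, 0, 80), runif(50, 0, 80))
  pred <- tps_predict(model, q)
  truth <- cbind(2 + 1.1 * q[, 1] + 0.2 * q[, 2],
                 -1 + 0.95 * q[, 2] - 0.1 * q[, 1])
  expect_lt(max(abs(pred - truth)), 1e-5)
})

test_that("TPS rejects degenerate configurations", {
  col3 <- data.frame(row_src = c(1, 2, 3), col_src = c(1, 2, 3),
                     row_tgt = c(1, 2, 3), col_tgt = c(2, 3, 4))
  expect_error(tps_fit(col3), "collinear")
  expect_error(tps_fit(col3[1:2, ]), "at least 3")
  expect_error(tps_fit(data.frame(row_src = c(1, 2, 3, 4),
                                  col_src = c(1, 5, 2, 7),
                                  row_tgt = 1:4, col_tgt = 1:4),
                       lambda_reg = -1), "lambda_reg")
})

test_that("mismatch removal keeps coherent sets intact", {
  prob <- make_pair_problem(seed = 101, n = 30, n_outliers = 0)
  res <- mrcsm_remove(prob$pairs)
  expect_equal(nrow(res$removed), 0)
  expect_equal(nrow(res$inliers), 30)
})

test_that("mismatch removal deletes gross outliers exactly", {
  prob <- make_pair_problem(seed = 202, n = 30, n_outliers = 3,
                            outlier_shift = 30)
  res <- mrcsm_remove(prob$pairs)
  expect_setequal(res$removed$src_idx, prob$pairs$src_idx[prob$is_outlier])
  expect_equal(nrow(res$inliers), 27)
})

test_that("mismatch removal refuses tiny or degenerate inputs", {
  prob <- make_pair_problem(seed = 7, n = 3)
  expect_error(mrcsm_remove(prob$pairs), "at least 4")
  # at exactly 4 pairs the relative threshold cannot single out a worst
  # member (the residual is spread by leverage), so the set survives intact
  junk <- data.frame(row_src = c(10, 10, 90, 50), col_src = c(10, 90, 50, 40),
                     row_tgt = c(10, 10, 90, 500),
                     col_tgt = c(10, 90, 50, 700),
                     klass = "W", cost = 0, src_idx = 1:4, tgt_idx = 1:4)
  res <- mrcsm_remove(junk)
  expect_equal(nrow(res$inliers), 4)
})

test_that("stage two adds a coherent unmatched pair and honors the registry", {
  # inliers: pure +5 column shift on a grid
  g <- expand.grid(row = c(20, 40, 60, 80), col = c(20, 40, 60))
  inl <- data.frame(row_src = g$row, col_src = g$col,
                    row_tgt = g$row, col_tgt = g$col + 5,
                    klass = "W", cost = 0,
                    src_idx = seq_len(nrow(g)), tgt_idx = seq_len(nrow(g)))
  model <- tps_fit(inl)
  # one extra source point with two candidate targets: one coherent (+5),
  # one far off
  cm <- list(W = list(
    costs = rbind(matrix(5, nrow(g), nrow(g) + 1),
                  c(rep(5, nrow(g)), 0.1),
                  c(rep(5, nrow(g)), 0.2)),
    src_points = data.frame(row = c(g$row, 50), col = c(g$col, 50),
                            klass = "W"),
    tgt_points = data.frame(row = c(g$row, 50, 50),
                            col = c(g$col + 5, 55, 90), klass = "W")))
  class(cm) <- "cost_matrices"
  added <- add_pairs(inl, character(0), cm, model)
  expect_equal(nrow(added), 1)
  expect_equal(added$src_idx, nrow(g) + 1)
  expect_equal(added$tgt_idx, nrow(g) + 1)
  expect_equal(added$col_tgt, 55)
  # the same pair in the removed registry is never re-admitted
  key <- paste("W", nrow(g) + 1, nrow(g) + 1, sep = ":")
  added2 <- add_pairs(inl, key, cm, model)
  expect_equal(nrow(added2), 0)
})

test_that("the mean displacement screen is computed per Eq. (6)", {
  g <- expand.grid(row = c(20, 40, 60), col = c(20, 40, 60))
  # zero displacement inliers -> d_bar = 0; a +5 candidate fails the screen
  inl <- data.frame(row_src = g$row, col_src = g$col,
                    row_tgt = g$row, col_tgt = g$col,
                    klass = "W", cost = 0,
                    src_idx = seq_len(nrow(g)), tgt_idx = seq_len(nrow(g)))
  model <- tps_fit(inl)
  cm <- list(W = list(
    costs = rbind(matrix(5, nrow(g), nrow(g) + 1),
                  c(rep(5, nrow(g)), 0.1)),
    src_points = data.frame(row = c(g$row, 45), col = c(g$col, 45),
                            klass = "W"),
    tgt_points = data.frame(row = c(g$row, 45), col = c(g$col, 50),
                            klass = "W")))
  class(cm) <- "cost_matrices"
  expect_equal(nrow(add_pairs(inl, character(0), cm, model)), 0)
})

test_that("refinement removes injected mismatches and re-adds the truth", {
  spec <- phantom_spec(height = 192, width = 240, seed = 31L)
  case <- make_case(spec, deformation_spec("translation", magnitude = 8,
                                           seed = 32L))
  prob <- make_injected_problem(case, frac = 0.1, seed = 33)
  res <- refine_matches(prob$pairs, prob$costs)
  expect_s3_class(res, "control_point_set")
  expect_true(res$stable)
  expect_lte(res$n_iterations, match_params()$max_outer_iters)
  prec <- match_precision(res, case, tol = 3)
  expect_gte(prec, 0.95)
  # removed registry holds the corrupted assignments
  expect_gte(nrow(res$removed), 1)
})

test_that("iterate_matching is stable and exact on identical feature sets", {
  set.seed(9)
  pts <- data.frame(row = runif(25, 10, 110), col = runif(25, 10, 110),
                    klass = "W")
  fs <- structure(list(points = pts, shape = c(128, 128)),
                  class = "feature_set")
  cm <- cost_matrices(fs, fs)
  res <- iterate_matching(fs, fs, cm)
  expect_true(res$stable)
  expect_equal(nrow(res$removed), 0)
  expect_equal(res$inliers$row_src, res$inliers$row_tgt)
  expect_equal(res$inliers$col_src, res$inliers$col_tgt)
})
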