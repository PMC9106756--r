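# Shared builders for synthetic matching problems.

# coherent pair set from a known smooth map, with optional gross outliers
make_pair_problem <- function(seed, n = 30, n_outliers = 0,
                              h = 200, w = 250, outlier_shift = 25) {
  set.seed(seed)
  row_src <- runif(n, 10, h - 10)
  col_src <- runif(n, 10, w - 10)
  # smooth map: mild affine plus a low-frequency sine
  row_tgt <- row_src + 4 + 0.01 * (col_src - w / 2) +
    1.5 * sin(2 * pi * col_src / w)
  col_tgt <- col_src - 3 + 0.01 * (row_src - h / 2) +
    1.5 * cos(2 * pi * row_src / h)
  pairs <- data.frame(row_src = row_src, col_src = col_src,
                      row_tgt = row_tgt, col_tgt = col_tgt,
                      klass = "W", cost = 0,
                      src_idx = seq_len(n), tgt_idx = seq_len(n))
  is_outlier <- rep(FALSE, n)
  if (n_outliers > 0) {
    bad <- sample(n, n_outliers)
    ang <- runif(n_outliers, 0, 2 * pi)
    mag <- runif(n_outliers, outlier_shift, 2 * outlier_shift)
    pairs$row_tgt[bad] <- pairs$row_tgt[bad] + mag * sin(ang)
    pairs$col_tgt[bad] <- pairs$col_tgt[bad] + mag * cos(ang)
    is_outlier[bad] <- TRUE
  }
  list(pairs = pairs, is_outlier = is_outlier)
}

# matching problem on a synthetic case: feature sets are the ground-truth
# correspondences with sub-pixel jitter; the initial pair set is the correct
# assignment with a fraction of targets swapped (injected mismatches)
make_injected_problem <- function(case, frac = 0.1, jitter_sd = 0.3,
                                  seed = 1) {
  set.seed(seed)
  tp <- case$true_pairs
  n <- nrow(tp)
  src <- data.frame(row = tp$row_src + rnorm(n, 0, jitter_sd),
                    col = tp$col_src + rnorm(n, 0, jitter_sd),
                    klass = "W")
  tgt <- data.frame(row = tp$row_tgt + rnorm(n, 0, jitter_sd),
                    col = tp$col_tgt + rnorm(n, 0, jitter_sd),
                    klass = "W")
  f_src <- structure(list(points = src, shape = dim(unclass(case$source))),
                     class = "feature_set")
  f_tgt <- structure(list(points = tgt, shape = dim(unclass(case$target))),
                     class = "feature_set")
  costs <- cost_matrices(f_tgt, f_src)
  tgt_idx <- seq_len(n)
  n_bad <- max(1L, round(frac * n))
  bad <- sample(n, n_bad)
  # swap each corrupted assignment with a distant partner
  for (b in bad) {
    far <- which(abs(seq_len(n) - b) > n / 4)
    tgt_idx[b] <- sample(far, 1)
  }
  pairs <- data.frame(
    row_src = src$row, col_src = src$col,
    row_tgt = tgt$row[tgt_idx], col_tgt = tgt$col[tgt_idx],
    klass = "W",
    cost = costs$W$costs[cbind(tgt_idx, seq_len(n))],
    src_idx = seq_len(n), tgt_idx = tgt_idx)
  list(pairs = pairs, costs = costs, corrupted = bad)
}
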