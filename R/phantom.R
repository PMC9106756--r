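# Synthetic thermal phantom generator.
#
# Emulates the structure of infrared breast images: a smooth low-contrast
# background, a bright vessel-like ridge network (the "hot pattern"), and
# dark flat blobs carrying a faint internal valley grid (the "cold pattern",
# i.e. flat regions that still contain weak structure).  Every case carries a
# ground-truth dense displacement field and exact point correspondences so
# each pipeline stage can be validated without patient data.

#' Phantom specification
#'
#' @param height,width Image dimensions in pixels (>= 64).
#' @param n_vessel_segments Number of vessel polylines crossing the frame.
#' @param vessel_width Full width of the Gaussian ridge profile in pixels
#'   (profile sigma is `vessel_width / 2`).
#' @param n_cold_blobs Number of dark flat blobs.
#' @param cold_blob_radius_range Length-2 vector, blob radius range (pixels).
#' @param cold_grid_spacing Spacing of the faint valley grid inside blobs.
#' @param background_smoothness Gaussian sigma (pixels) of the smooth
#'   background field.
#' @param noise_sd Additive Gaussian noise standard deviation (intensity
#'   fraction, >= 0).
#' @param seed Integer seed; identical spec + seed gives a bit-identical
#'   phantom.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(height = 256, width = 320,
                         n_vessel_segments = 8, vessel_width = 4,
                         n_cold_blobs = 6, cold_blob_radius_range = c(22, 30),
                         cold_grid_spacing = 8, background_smoothness = 30,
                         noise_sd = 0.005, seed = 1L) {
  spec <- list(height = as.integer(height), width = as.integer(width),
               n_vessel_segments = as.integer(n_vessel_segments),
               vessel_width = vessel_width,
               n_cold_blobs = as.integer(n_cold_blobs),
               cold_blob_radius_range = as.numeric(cold_blob_radius_range),
               cold_grid_spacing = cold_grid_spacing,
               background_smoothness = background_smoothness,
               noise_sd = noise_sd, seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  if (spec$height < 64 || spec$width < 64)
    stop("phantom dimensions must be at least 64 x 64")
  if (spec$n_vessel_segments < 0 || spec$n_cold_blobs < 0)
    stop("structure counts must be non-negative")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(spec$cold_blob_radius_range) != 2 ||
      any(spec$cold_blob_radius_range <= 0))
    stop("cold_blob_radius_range must be two positive values")
  invisible(spec)
}

#' Deformation specification
#'
#' Describes the ground-truth warp applied to a phantom: the dense field `w`
#' is defined on the target grid with the backward convention
#' `target(x) = source(x + w(x))`.
#'
#' @param kind One of `"translation"`, `"affine"`, `"tps_warp"`.
#' @param magnitude Maximum displacement norm in pixels (>= 0); the rendered
#'   field is scaled so its maximum vector norm equals `magnitude`.
#' @param n_warp_knots Number of warp knots (`tps_warp` only, >= 3).
#' @param intensity_gain Multiplicative intensity factor applied to the target.
#' @param intensity_offset Additive intensity fraction applied to the target.
#' @param seed Integer seed for the random deformation draw.
#' @return A `deformation_spec` list.
#' @export
deformation_spec <- function(kind = c("translation", "affine", "tps_warp"),
                             magnitude = 5, n_warp_knots = 6,
                             intensity_gain = 1, intensity_offset = 0,
                             seed = 1L) {
  kind <- match.arg(kind)
  if (magnitude < 0) stop("magnitude must be >= 0")
  if (kind == "tps_warp" && n_warp_knots < 3)
    stop("tps_warp requires n_warp_knots >= 3")
  structure(list(kind = kind, magnitude = magnitude,
                 n_warp_knots = as.integer(n_warp_knots),
                 intensity_gain = intensity_gain,
                 intensity_offset = intensity_offset,
                 seed = as.integer(seed)),
            class = "deformation_spec")
}

# distance from every pixel to segment (r1,c1)-(r2,c2); 0-based pixel coords
segment_distance <- function(h, w, r1, c1, r2, c2) {
  R <- matrix(seq_len(h) - 1, h, w)
  C <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  dr <- r2 - r1; dc <- c2 - c1
  len2 <- dr^2 + dc^2
  if (len2 == 0) return(sqrt((R - r1)^2 + (C - c1)^2))
  t <- ((R - r1) * dr + (C - c1) * dc) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((R - (r1 + t * dr))^2 + (C - (c1 + t * dc))^2)
}

# intersection point of two segments, or NULL
segment_intersection <- function(a, b) {
  # a, b: c(r1, c1, r2, c2)
  p <- a[1:2]; r <- a[3:4] - a[1:2]
  q <- b[1:2]; s <- b[3:4] - b[1:2]
  den <- r[1] * s[2] - r[2] * s[1]
  if (abs(den) < 1e-12) return(NULL)
  qp <- q - p
  t <- (qp[1] * s[2] - qp[2] * s[1]) / den
  u <- (qp[1] * r[2] - qp[2] * r[1]) / den
  if (t < 0 || t > 1 || u < 0 || u > 1) return(NULL)
  p + t * r
}

# random point on the image border (0-based coords)
border_point <- function(h, w) {
  side <- sample.int(4L, 1L)
  switch(side,
    c(0, runif(1, 0, w - 1)),
    c(h - 1, runif(1, 0, w - 1)),
    c(runif(1, 0, h - 1), 0),
    c(runif(1, 0, h - 1), w - 1))
}

# deterministic noiseless render + structural ground truth
render_phantom <- function(spec) {
  h <- spec$height; w <- spec$width
  with_seed(spec$seed, {
    # smooth background in [0.35, 0.55]
    bg <- gaussian_smooth(matrix(rnorm(h * w), h, w), spec$background_smoothness)
    amp <- max(abs(bg))
    if (amp > 0) bg <- bg / amp
    img <- 0.45 + 0.1 * bg

    # vessels: border-to-border polylines with a jittered midpoint
    vessels <- list()
    ridge <- matrix(0, h, w)
    sv <- spec$vessel_width / 2
    if (spec$n_vessel_segments > 0) {
      for (i in seq_len(spec$n_vessel_segments)) {
        p1 <- border_point(h, w); p2 <- border_point(h, w)
        while (sum((p1 - p2)^2) < (min(h, w) / 2)^2) p2 <- border_point(h, w)
        mid <- (p1 + p2) / 2 + rnorm(2, 0, min(h, w) / 12)
        mid <- pmin(pmax(mid, 0), c(h - 1, w - 1))
        vessels[[i]] <- rbind(p1, mid, p2)
        d1 <- segment_distance(h, w, p1[1], p1[2], mid[1], mid[2])
        d2 <- segment_distance(h, w, mid[1], mid[2], p2[1], p2[2])
        d <- pmin(d1, d2)
        ridge <- pmax(ridge, 0.35 * exp(-d^2 / (2 * sv^2)))
      }
    }
    img <- img + ridge

    # vessel crossing points (ground-truth W-like structure)
    crossings <- NULL
    if (length(vessels) >= 2) {
      segs <- do.call(rbind, lapply(vessels, function(v)
        rbind(c(v[1, ], v[2, ]), c(v[2, ], v[3, ]))))
      seg_of <- rep(seq_along(vessels), each = 2)
      pts <- list()
      n <- nrow(segs)
      for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
        if (seg_of[i] == seg_of[j]) next
        p <- segment_intersection(segs[i, ], segs[j, ])
        if (!is.null(p) && p[1] > 3 && p[1] < h - 4 && p[2] > 3 && p[2] < w - 4)
          pts[[length(pts) + 1]] <- p
      }
      if (length(pts))
        crossings <- do.call(rbind, pts)
    }

    # cold blobs: flat dark disks with a faint internal valley grid
    blobs <- NULL
    lattice <- NULL
    if (spec$n_cold_blobs > 0) {
      rr <- spec$cold_blob_radius_range
      centers <- matrix(numeric(0), 0, 3)
      tries <- 0
      while (nrow(centers) < spec$n_cold_blobs && tries < 500) {
        tries <- tries + 1
        rad <- runif(1, rr[1], rr[2])
        cen <- c(runif(1, rad + 4, h - 1 - rad - 4),
                 runif(1, rad + 4, w - 1 - rad - 4))
        ok <- TRUE
        if (nrow(centers) > 0) {
          sep <- sqrt((centers[, 1] - cen[1])^2 + (centers[, 2] - cen[2])^2)
          ok <- all(sep > centers[, 3] + rad + 6)
        }
        if (ok) centers <- rbind(centers, c(cen, rad))
      }
      if (nrow(centers) < spec$n_cold_blobs)
        stop("could not place ", spec$n_cold_blobs,
             " non-overlapping cold blobs; reduce count or radius")
      R <- matrix(seq_len(h) - 1, h, w)
      C <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
      lat <- list()
      for (b in seq_len(nrow(centers))) {
        cen <- centers[b, 1:2]; rad <- centers[b, 3]
        d <- sqrt((R - cen[1])^2 + (C - cen[2])^2)
        # smooth-edged disk profile (2 px transition)
        prof <- pmin(pmax((rad - d) / 2, 0), 1)
        img <- img - 0.3 * prof
        # internal valley grid aligned to the blob center
        sp <- spec$cold_grid_spacing
        inner <- rad - 4
        if (inner > sp / 2) {
          ks <- seq(-floor(inner / sp), floor(inner / sp))
          rows_g <- cen[1] + ks * sp
          cols_g <- cen[2] + ks * sp
          dr <- do.call(pmin, lapply(rows_g, function(g) abs(R - g)))
          dc <- do.call(pmin, lapply(cols_g, function(g) abs(C - g)))
          dg <- pmin(dr, dc)
          fade <- pmin(pmax((inner - d) / 2, 0), 1)
          img <- img - 0.1 * exp(-dg^2 / 2) * fade
          for (gr in rows_g) for (gc in cols_g) {
            if (sqrt((gr - cen[1])^2 + (gc - cen[2])^2) <= inner - 1)
              lat[[length(lat) + 1]] <- c(gr, gc, b)
          }
        }
      }
      blobs <- data.frame(row = centers[, 1], col = centers[, 2],
                          radius = centers[, 3])
      if (length(lat)) {
        lattice <- as.data.frame(do.call(rbind, lat))
        names(lattice) <- c("row", "col", "blob")
      }
    }

    img <- pmin(pmax(img, 0), 1)
    list(image = img,
         truth = list(vessels = vessels, crossings = crossings,
                      blobs = blobs, lattice = lattice))
  })
}

#' Generate a synthetic infrared-like phantom image
#'
#' Renders a smooth background, a bright vessel ridge network, and dark flat
#' blobs with a faint internal valley grid, then adds Gaussian noise. The
#' result is deterministic for a given spec (including its seed). Structural
#' ground truth (vessel polylines and crossings, blob geometry, grid lattice
#' points) is attached as attribute `"truth"` in 0-based (row, col)
#' coordinates.
#'
#' @param spec A [phantom_spec()].
#' @return An `intensity_image` with a `"truth"` attribute.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  ren <- render_phantom(spec)
  img <- ren$image
  if (spec$noise_sd > 0) {
    img <- with_seed(spec$seed + 7919L, {
      pmin(pmax(img + matrix(rnorm(length(img), 0, spec$noise_sd),
                             nrow(img), ncol(img)), 0), 1)
    })
  }
  out <- as_intensity_image(img, normalize = FALSE)
  attr(out, "truth") <- ren$truth
  out
}

# build the ground-truth backward field (u = col, v = row displacement)
# on the target grid; max vector norm scaled to exactly `magnitude`
build_true_field <- function(deform, h, w) {
  with_seed(deform$seed + 104729L, {
    if (deform$magnitude == 0) {
      return(list(u = matrix(0, h, w), v = matrix(0, h, w)))
    }
    if (deform$kind == "translation") {
      th <- runif(1, 0, 2 * pi)
      u <- matrix(deform$magnitude * cos(th), h, w)
      v <- matrix(deform$magnitude * sin(th), h, w)
      return(list(u = u, v = v))
    }
    R <- matrix(seq_len(h) - 1, h, w)
    C <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
    if (deform$kind == "affine") {
      M <- matrix(runif(4, -1, 1), 2, 2) * 0.02
      t0 <- runif(2, -1, 1)
      u <- M[1, 1] * (C - w / 2) + M[1, 2] * (R - h / 2) + t0[1]
      v <- M[2, 1] * (C - w / 2) + M[2, 2] * (R - h / 2) + t0[2]
    } else { # tps_warp
      k <- deform$n_warp_knots
      kr <- runif(k, 0.1 * h, 0.9 * h)
      kc <- runif(k, 0.1 * w, 0.9 * w)
      du <- rnorm(k); dv <- rnorm(k)
      src <- cbind(row = kr, col = kc)
      mu <- tps_fit(data.frame(row_src = kr, col_src = kc,
                               row_tgt = kr + dv, col_tgt = kc + du),
                    lambda_reg = 0)
      pred <- tps_predict(mu, cbind(as.vector(R), as.vector(C)))
      v <- matrix(pred[, 1] - as.vector(R), h, w)
      u <- matrix(pred[, 2] - as.vector(C), h, w)
    }
    nrm <- sqrt(u^2 + v^2)
    s <- deform$magnitude / max(nrm)
    list(u = u * s, v = v * s)
  })
}

# evaluate field bilinearly at 0-based points (row, col); pts = 2-col matrix
eval_field <- function(field, pts) {
  cbind(v = bilinear_sample(field$v, pts[, 2], pts[, 1]),
        u = bilinear_sample(field$u, pts[, 2], pts[, 1]))
}

#' Build a synthetic registration case with ground truth
#'
#' Renders a source phantom, warps it by a ground-truth backward field
#' (`target(x) = source(x + w(x))`, bilinear sampling), applies a global
#' intensity gain/offset, and adds independent noise to both images.
#' Ground-truth correspondences are sampled on image structure (vessel
#' crossings and cold-grid lattice points) by inverting the field with
#' fixed-point iteration; each retained pair is consistent with the field to
#' better than 0.5 px.
#'
#' The case is labelled TYPE I-IV by crossing displacement magnitude
#' (large: `magnitude >= 8` px) with cold-blob area fraction
#' (many flat regions: fraction >= 0.15).
#'
#' @param spec A [phantom_spec()].
#' @param deform A [deformation_spec()].
#' @return A `synthetic_case`: list with `source`, `target`, `true_field`
#'   (list `u`, `v`), `true_pairs` (data frame `row_src`, `col_src`,
#'   `row_tgt`, `col_tgt`), `type_label`, plus noiseless renders and the
#'   input specs.
#' @export
make_case <- function(spec, deform) {
  validate_phantom_spec(spec)
  h <- spec$height; w <- spec$width
  ren <- render_phantom(spec)
  S0 <- ren$image
  field <- build_true_field(deform, h, w)

  # reject warps that push too much content out of frame
  R <- matrix(seq_len(h) - 1, h, w)
  C <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  xs <- C + field$u; ys <- R + field$v
  out_frac <- mean(xs < 0 | xs > w - 1 | ys < 0 | ys > h - 1)
  if (out_frac > 0.2)
    stop(sprintf("deformation pushes %.0f%% of the content outside the frame",
                 100 * out_frac))

  target0 <- bilinear_sample(S0, xs, ys)
  dim(target0) <- c(h, w)
  target_noiseless <- pmin(pmax(deform$intensity_gain * target0 +
                                deform$intensity_offset, 0), 1)

  add_noise <- function(img, seed_shift) {
    if (spec$noise_sd <= 0) return(img)
    with_seed(spec$seed + seed_shift, {
      pmin(pmax(img + matrix(rnorm(h * w, 0, spec$noise_sd), h, w), 0), 1)
    })
  }
  source_img <- add_noise(S0, 7919L)
  target_img <- add_noise(target_noiseless, 6007L)

  # structure points in the source image
  pts <- NULL
  if (!is.null(ren$truth$crossings)) pts <- ren$truth$crossings
  if (!is.null(ren$truth$lattice))
    pts <- rbind(pts, as.matrix(ren$truth$lattice[, c("row", "col")]))
  true_pairs <- NULL
  if (!is.null(pts) && nrow(pts) > 0) {
    pairs <- matrix(NA_real_, nrow(pts), 4)
    for (i in seq_len(nrow(pts))) {
      p <- pts[i, 1:2]
      x <- p
      for (it in 1:80) {
        wv <- eval_field(field, rbind(x))
        xn <- c(p[1] - wv[1, "v"], p[2] - wv[1, "u"])
        if (max(abs(xn - x)) < 1e-4) { x <- xn; break }
        x <- xn
      }
      if (x[1] < 0 || x[1] > h - 1 || x[2] < 0 || x[2] > w - 1) next
      wv <- eval_field(field, rbind(x))
      err <- sqrt((x[1] + wv[1, "v"] - p[1])^2 + (x[2] + wv[1, "u"] - p[2])^2)
      if (err < 0.5) pairs[i, ] <- c(p[1], p[2], x[1], x[2])
    }
    pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
    true_pairs <- as.data.frame(pairs)
    names(true_pairs) <- c("row_src", "col_src", "row_tgt", "col_tgt")
  }

  blob_frac <- if (is.null(ren$truth$blobs)) 0 else
    sum(pi * ren$truth$blobs$radius^2) / (h * w)
  large <- deform$magnitude >= 8
  many <- blob_frac >= 0.15
  type_label <- if (large && many) "I" else if (!large && !many) "II"
    else if (!large && many) "III" else "IV"

  structure(list(source = as_intensity_image(source_img, normalize = FALSE),
                 target = as_intensity_image(target_img, normalize = FALSE),
                 true_field = field,
                 true_pairs = true_pairs,
                 type_label = type_label,
                 source_noiseless = S0,
                 target_noiseless = target_noiseless,
                 truth = ren$truth,
                 cold_area_fraction = blob_frac,
                 spec = spec, deform = deform),
            class = "synthetic_case")
}

#' Preset phantom cases for the four registration regimes
#'
#' TYPE I: large displacement, many flat regions; TYPE II: small
#' displacement, few flat regions; TYPE III: small displacement, many flat
#' regions; TYPE IV: large displacement, few flat regions. "Large" means a
#' 12 px maximum displacement (threshold 8 px), "small" 4 px; "many" means a
#' cold-blob area fraction of about 16% (threshold 15%), "few" about 3%.
#' Blob radii scale with image size so the area fraction is preserved.
#'
#' @param type `"I"`, `"II"`, `"III"` or `"IV"`.
#' @param height,width Image dimensions.
#' @param seed Integer seed.
#' @return List with elements `spec` and `deform`, ready for [make_case()].
#' @export
phantom_preset <- function(type = c("I", "II", "III", "IV"),
                           height = 256, width = 320, seed = 1L) {
  type <- match.arg(type)
  scale <- sqrt(height * width)
  many <- type %in% c("I", "III")
  large <- type %in% c("I", "IV")
  spec <- phantom_spec(
    height = height, width = width,
    n_vessel_segments = 8, vessel_width = 4,
    n_cold_blobs = if (many) 6 else 2,
    cold_blob_radius_range = if (many) round(c(0.085, 0.100) * scale)
                             else      round(c(0.050, 0.060) * scale),
    cold_grid_spacing = max(6, round(0.028 * scale)),
    background_smoothness = 0.1 * scale,
    noise_sd = 0.005, seed = seed)
  deform <- deformation_spec(
    kind = "tps_warp", magnitude = if (large) 12 else 4,
    n_warp_knots = 6, intensity_gain = 1.03, intensity_offset = 0.01,
    seed = seed + 13L)
  list(spec = spec, deform = deform, type = type)
}

#' Write a synthetic case to disk
#'
#' Writes PNG image pairs, a JSON sidecar with the specs and type
#' label, the ground-truth field as a two-plane 32-bit float binary with JSON
#' header, and the true pairs as CSV (`x_src,y_src,x_tgt,y_tgt`; x = col,
#' y = row, 0-based).
#'
#' @param case A `synthetic_case`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ir_image(case$source, file.path(dir, "source.png"))
  write_ir_image(case$target, file.path(dir, "target.png"))
  jsonlite::write_json(
    list(type_label = case$type_label,
         cold_area_fraction = case$cold_area_fraction,
         spec = unclass(case$spec), deform = unclass(case$deform)),
    file.path(dir, "case.json"), auto_unbox = TRUE, digits = NA)
  write_field(case$true_field, file.path(dir, "true_field"))
  if (!is.null(case$true_pairs)) {
    tp <- data.frame(x_src = case$true_pairs$col_src,
                     y_src = case$true_pairs$row_src,
                     x_tgt = case$true_pairs$col_tgt,
                     y_tgt = case$true_pairs$row_tgt)
    utils::write.csv(tp, file.path(dir, "true_pairs.csv"), row.names = FALSE)
  }
  invisible(dir)
}
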