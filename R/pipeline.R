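# End-to-end orchestration: load pair -> detect -> describe -> match ->
# flow -> warp -> metrics, plus phantom batch evaluation.

#' Default pipeline configuration
#'
#' Collects every stage's tunables in one nested, serializable list:
#' `detect` ([detect_params()]), `sc` ([sc_params()]), `match`
#' ([match_params()]), `flow` ([ldof_params()]), and `metrics` (mutual
#' information bins, Canny settings, precision tolerance).
#'
#' @param seed Integer seed recorded with the config.
#' @return A `pipeline_config` list.
#' @export
default_config <- function(seed = 1L) {
  structure(list(detect = detect_params(),
                 sc = sc_params(),
                 match = match_params(),
                 flow = ldof_params(),
                 metrics = list(mi_bins = 64L, canny_sigma = 1.5,
                                canny_low_frac = 0.4, precision_tol = 3),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration (YAML)
#'
#' `write_config()` serializes a config; `read_config()` restores it,
#' rejecting unknown keys at the top and stage level.
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `write_config()`: `path`, invisibly; `read_config()`: the config.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ref <- default_config()
  bad <- setdiff(names(raw), names(ref))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (sec in names(raw)) {
    if (is.list(ref[[sec]])) {
      badk <- setdiff(names(raw[[sec]]), names(ref[[sec]]))
      if (length(badk))
        stop("unknown keys in config section '", sec, "': ",
             paste(badk, collapse = ", "))
      for (k in names(raw[[sec]])) ref[[sec]][[k]] <- raw[[sec]][[k]]
    } else if (!is.null(raw[[sec]])) {
      ref[[sec]] <- raw[[sec]]
    }
  }
  # NULL radial scales ("derive from data") survive YAML round trips as absent
  for (k in c("r_inner", "r_outer"))
    if (is.null(raw$sc[[k]])) ref$sc[k] <- list(NULL)
  ref
}

# swap pair roles so flow anchors live on the target grid with
# displacements pointing into the source image
swap_pairs <- function(pairs) {
  data.frame(row_src = pairs$row_tgt, col_src = pairs$col_tgt,
             row_tgt = pairs$row_src, col_tgt = pairs$col_src)
}

#' Register a source image onto a target image
#'
#' Full pipeline: feature detection in both images, per-class shape-context
#' cost matrices, two-stage iterative matching, match-constrained
#' large-displacement optical flow, backward warping of the source onto the
#' target grid, and quality metrics. The estimated field `w` lives on the
#' target grid with `source(x + w(x)) ~ target(x)`, the same convention as
#' the phantom ground-truth field.
#'
#' @param source,target Intensity images (or paths readable by
#'   [read_ir_image()]); `source` is the moving image.
#' @param config A `pipeline_config`.
#' @param truth Optional `synthetic_case` for ground-truth scoring
#'   (precision, endpoint error).
#' @return A `run_record`: list with `features_src`, `features_tgt`,
#'   `matches` (`control_point_set`), `field`, `warped`, `report`
#'   (mi_before/mi_after in nats, edge agreement, optional precision and
#'   endpoint error), `counts`, `timings` (seconds per stage) and the config.
#' @export
run_register <- function(source, target, config = default_config(),
                         truth = NULL) {
  if (is.character(source)) source <- read_ir_image(source)
  if (is.character(target)) target <- read_ir_image(target)
  source <- as_intensity_image(unclass(source), normalize = FALSE)
  target <- as_intensity_image(unclass(target), normalize = FALSE)
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()

  t0 <- tic()
  f_src <- detect_features(source, config$detect)
  f_tgt <- detect_features(target, config$detect)
  timings["detect"] <- tic() - t0

  t0 <- tic()
  costs <- cost_matrices(f_tgt, f_src, config$sc)
  timings["describe"] <- tic() - t0

  t0 <- tic()
  matches <- iterate_matching(f_tgt, f_src, costs, config$match)
  timings["match"] <- tic() - t0

  # flow on the target grid: anchors at target points, displacement
  # pointing into the source image
  t0 <- tic()
  field <- estimate_flow(target, source, swap_pairs(matches$inliers),
                         config$flow)
  timings["flow"] <- tic() - t0

  t0 <- tic()
  warped <- warp_image(source, field)
  mi_before <- mutual_information(source, target, config$metrics$mi_bins)
  mi_after <- mutual_information(warped, target, config$metrics$mi_bins)
  overlay <- canny_overlay(target, warped, config$metrics$canny_sigma,
                           config$metrics$canny_low_frac)
  report <- list(mi_before = mi_before, mi_after = mi_after,
                 mi_units = "nats",
                 edge_agreement = edge_agreement(overlay),
                 n_pairs = nrow(matches$inliers))
  if (!is.null(truth)) {
    report$precision <- match_precision(matches, truth,
                                        config$metrics$precision_tol)
    report$mean_epe <- mean_endpoint_error(field, truth$true_field)
  }
  timings["metrics"] <- tic() - t0

  counts <- list(
    features_src = table(factor(f_src$points$klass, c("W", "B", "C"))),
    features_tgt = table(factor(f_tgt$points$klass, c("W", "B", "C"))),
    inliers = nrow(matches$inliers), removed = nrow(matches$removed),
    outer_iterations = matches$n_iterations, stable = matches$stable)

  structure(list(features_src = f_src, features_tgt = f_tgt,
                 matches = matches, field = field, warped = warped,
                 overlay = overlay, report = report, counts = counts,
                 timings = timings, config = config),
            class = "run_record")
}

#' Mean endpoint error between two displacement fields
#'
#' Mean Euclidean norm of the vector difference, evaluated over the interior
#' of the frame (a `margin_frac` border is excluded on each side).
#'
#' @param field,truth_field Displacement fields (lists `u`, `v`).
#' @param margin_frac Border fraction excluded per side (default 0.1).
#' @return Mean endpoint error in pixels.
#' @export
mean_endpoint_error <- function(field, truth_field, margin_frac = 0.1) {
  h <- nrow(field$u); w <- ncol(field$u)
  mr <- max(1L, round(margin_frac * h)); mc <- max(1L, round(margin_frac * w))
  ri <- (mr + 1):(h - mr); ci <- (mc + 1):(w - mc)
  mean(sqrt((field$u[ri, ci] - truth_field$u[ri, ci])^2 +
            (field$v[ri, ci] - truth_field$v[ri, ci])^2))
}

#' Batch evaluation on phantom presets
#'
#' Generates `n_per_type` synthetic cases for each requested TYPE preset,
#' registers each with [run_register()], and aggregates precision, mean
#' endpoint error, H_uni, H_spa and MI gain as mean and sd per type.
#' Deterministic for a given seed; individual case failures are logged and
#' the batch continues.
#'
#' @param types Subset of `c("I","II","III","IV")`.
#' @param n_per_type Cases per type.
#' @param seed Integer base seed.
#' @param config A `pipeline_config`.
#' @param height,width Phantom dimensions.
#' @return A `batch_report`: list with per-case results (`cases` data frame)
#'   and per-type `summary` (mean/sd columns), plus the failure count.
#' @export
run_phantom_batch <- function(types = c("I", "II", "III", "IV"),
                              n_per_type = 2, seed = 1L,
                              config = default_config(),
                              height = 256, width = 320) {
  rows <- list()
  failures <- 0L
  for (ty in types) {
    for (i in seq_len(n_per_type)) {
      case_seed <- seed + 1000L * match(ty, c("I", "II", "III", "IV")) + i
      res <- tryCatch({
        preset <- phantom_preset(ty, height, width, seed = case_seed)
        case <- make_case(preset$spec, preset$deform)
        rec <- run_register(case$source, case$target, config, truth = case)
        fq <- feature_quality(rec$features_src)
        data.frame(type = ty, seed = case_seed,
                   n_features = fq$n, h_uni = fq$h_uni, h_spa = fq$h_spa,
                   n_pairs = rec$report$n_pairs,
                   precision = rec$report$precision,
                   mean_epe = rec$report$mean_epe,
                   mi_gain = rec$report$mi_after - rec$report$mi_before,
                   edge_agreement = rec$report$edge_agreement)
      }, error = function(e) {
        message("case ", ty, "/", i, " failed: ", conditionMessage(e))
        NULL
      })
      if (is.null(res)) failures <- failures + 1L else
        rows[[length(rows) + 1L]] <- res
    }
  }
  cases <- do.call(rbind, rows)
  summary <- NULL
  if (!is.null(cases)) {
    agg <- function(v) c(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0)
    summary <- do.call(rbind, lapply(split(cases, cases$type), function(d) {
      data.frame(type = d$type[1], n = nrow(d),
                 t(c(precision = agg(d$precision),
                     mean_epe = agg(d$mean_epe),
                     h_uni = agg(d$h_uni), h_spa = agg(d$h_spa),
                     mi_gain = agg(d$mi_gain))))
    }))
    rownames(summary) <- NULL
  }
  structure(list(cases = cases, summary = summary, failures = failures,
                 seed = seed),
            class = "batch_report")
}

#' @export
print.run_record <- function(x, ...) {
  cat("Registration run\n")
  cat("  features (src):", paste(names(x$counts$features_src),
                                 x$counts$features_src, collapse = "  "), "\n")
  cat("  features (tgt):", paste(names(x$counts$features_tgt),
                                 x$counts$features_tgt, collapse = "  "), "\n")
  cat(sprintf("  control points: %d inliers, %d removed, %d outer iteration(s), stable: %s\n",
              x$counts$inliers, x$counts$removed,
              x$counts$outer_iterations, x$counts$stable))
  cat(sprintf("  MI before: %.4f nats   MI after: %.4f nats\n",
              x$report$mi_before, x$report$mi_after))
  cat(sprintf("  edge agreement: %.3f\n", x$report$edge_agreement))
  if (!is.null(x$report$precision))
    cat(sprintf("  precision: %.3f   mean EPE: %.3f px\n",
                x$report$precision, x$report$mean_epe))
  invisible(x)
}

#' Write the artifacts of a registration run
#'
#' Writes the warped image and overlay as PNG, the field (binary + JSON
#' header), the control points as CSV, and the report/counts as JSON.
#'
#' @param record A `run_record`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_record <- function(record, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ir_image(record$warped, file.path(dir, "warped.png"))
  png::writePNG(record$overlay, file.path(dir, "overlay.png"))
  write_field(record$field, file.path(dir, "field"))
  write_control_points(record$matches, file.path(dir, "control_points.csv"))
  jsonlite::write_json(
    list(report = record$report,
         counts = lapply(record$counts, function(x)
           if (inherits(x, "table")) as.list(x) else x),
         timings = as.list(record$timings)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
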