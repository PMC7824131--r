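# End-to-end orchestration: preprocessing, cross-validation, evaluation.

#' Pipeline run settings
#'
#' @param crop_half_width half-width of the head crop in voxels (default 40,
#'   i.e. an 80-voxel cube).
#' @param angle_baseline inclusion limit (degrees) on both labelling angles.
#' @param folds number of cross-validation folds.
#' @param rng_seed master seed for fold assignment and training.
#' @param seed_config an [seed_cascade_config()] for stage 1 (side must
#'   equal `2 * crop_half_width` when phantoms are already cropped).
#' @param gan_config an [generator_config()] for stage 2.
#' @param gan_weights an [loss_weights()].
#' @param gan_epochs,gan_lr stage-2 training schedule.
#' @param semi_automatic use annotated seed points instead of the stage-1
#'   cascade at test time (the semi-automatic arm).
#' @param fit_threshold `"adaptive"` (half the soft mask's peak value) or a
#'   fixed numeric threshold for plane fitting.
#' @return `msp_run_config` list.
#' @export
run_config <- function(crop_half_width = 40L, angle_baseline = 30,
                       folds = 5L, rng_seed = 1L,
                       seed_config = NULL, gan_config = NULL,
                       gan_weights = loss_weights(),
                       gan_epochs = 30L, gan_lr = 1e-4,
                       semi_automatic = FALSE, fit_threshold = "adaptive") {
  side <- 2L * as.integer(crop_half_width)
  if (is.null(seed_config)) seed_config <- seed_cascade_config(side = side)
  if (is.null(gan_config)) gan_config <- generator_config(side = side)
  structure(list(crop_half_width = as.integer(crop_half_width),
                 angle_baseline = angle_baseline, folds = as.integer(folds),
                 rng_seed = as.integer(rng_seed), seed_config = seed_config,
                 gan_config = gan_config, gan_weights = gan_weights,
                 gan_epochs = as.integer(gan_epochs), gan_lr = gan_lr,
                 semi_automatic = semi_automatic,
                 fit_threshold = fit_threshold),
            class = "msp_run_config")
}

#' Case-record table for a phantom dataset
#'
#' @param samples list of `msp_phantom` samples.
#' @return Tibble with one row per case: `id`, `theta_axi`, `theta_cor`,
#'   `head_side`, `status` (`"included"` initially) and `fold` (`NA`).
#' @export
case_records <- function(samples) {
  tibble::tibble(
    id = seq_along(samples),
    theta_axi = vapply(samples, `[[`, numeric(1), "theta_axi"),
    theta_cor = vapply(samples, `[[`, numeric(1), "theta_cor"),
    head_side = vapply(samples, `[[`, character(1), "head_side"),
    status = "included",
    fold = NA_integer_
  )
}

#' Exclude cases whose labelling angles exceed the baseline
#'
#' Inclusive boundary: a case at exactly the baseline is kept.
#'
#' @param records case-record tibble (or a single list with `theta_axi`,
#'   `theta_cor`).
#' @param baseline angle limit in degrees.
#' @return The records with `status` set to
#'   `"excluded:angle-out-of-range"` where either angle exceeds the
#'   baseline.
#' @export
filter_by_angle <- function(records, baseline = 30) {
  if (!is.data.frame(records)) {
    bad <- abs(records$theta_axi) > baseline | abs(records$theta_cor) > baseline
    records$status <- if (bad) "excluded:angle-out-of-range" else "included"
    return(records)
  }
  dplyr::mutate(records, status = ifelse(
    abs(.data$theta_axi) > baseline | abs(.data$theta_cor) > baseline,
    "excluded:angle-out-of-range", .data$status))
}

#' Align head orientation by horizontal flipping
#'
#' Volumes whose head faces the right half of the horizontal in-plane axis
#' (axis 2) are mirrored so all heads face left; ground-truth plane and seed
#' are transformed consistently.  Left-side volumes pass through unchanged.
#'
#' @param sample an `msp_phantom`, or a plain 3D array.
#' @param head_side for plain arrays: `"left"`, `"right"` or `NA` (unknown
#'   side passes through with a warning).
#' @return Same type as the input, aligned to `head_side = "left"`.
#' @export
align_flip <- function(sample, head_side = NULL) {
  flip_y <- function(v) v[, dim(v)[2]:1, , drop = FALSE]
  if (inherits(sample, "msp_phantom")) {
    if (sample$head_side != "right") return(sample)
    ny <- dim(sample$volume)[2]
    p <- sample$gt_plane
    sample$volume <- flip_y(sample$volume)
    sample$head_label <- flip_y(sample$head_label)
    sample$gt_mask <- flip_y(sample$gt_mask)
    sample$gt_plane <- normalize_plane(c(p[["a"]], -p[["b"]], p[["c"]],
                                         p[["d"]] + p[["b"]] * (ny - 1)))
    sample$gt_seed[2] <- (ny - 1) - sample$gt_seed[2]
    ang <- angles_from_plane(sample$gt_plane)
    sample$theta_axi <- unname(ang["theta_axi"])
    sample$theta_cor <- unname(ang["theta_cor"])
    bb <- sample$head_bbox
    sample$head_bbox["lo", 2] <- (ny - 1) - bb["hi", 2]
    sample$head_bbox["hi", 2] <- (ny - 1) - bb["lo", 2]
    sample$head_side <- "left"
    return(sample)
  }
  if (is.null(head_side) || is.na(head_side)) {
    warning("unknown head side; volume passed through unflipped", call. = FALSE)
    return(sample)
  }
  if (head_side == "right") flip_y(sample) else sample
}

#' Crop a cube around a seed point
#'
#' Extracts the cube `[seed - hw, seed + hw)` per axis around the rounded
#' (half-up) seed, zero-padding outside the source volume so the output is
#' always exactly `2 hw` per side.
#'
#' @param volume 3D array.
#' @param seed length-3 seed point (0-based voxel coordinates, may be
#'   continuous).
#' @param half_width crop half-width in voxels.
#' @return Cropped array with attribute `offset` (the 0-based source
#'   coordinate of the cube's first voxel).
#' @export
crop_cube <- function(volume, seed, half_width = 40L) {
  dims <- dim(volume)
  seed <- as.numeric(seed)
  if (any(seed < 0) || any(seed > dims - 1))
    stop("seed point lies outside the volume", call. = FALSE)
  ctr <- round_half_up(seed)
  hw <- as.integer(half_width)
  side <- 2L * hw
  lo <- ctr - hw                       # 0-based inclusive start
  out <- array(0, rep(side, 3L))
  src_lo <- pmax(lo, 0L); src_hi <- pmin(lo + side - 1L, dims - 1L)
  if (all(src_lo <= src_hi)) {
    dst_lo <- src_lo - lo
    out[(dst_lo[1] + 1L):(dst_lo[1] + 1L + src_hi[1] - src_lo[1]),
        (dst_lo[2] + 1L):(dst_lo[2] + 1L + src_hi[2] - src_lo[2]),
        (dst_lo[3] + 1L):(dst_lo[3] + 1L + src_hi[3] - src_lo[3])] <-
      volume[(src_lo[1] + 1L):(src_hi[1] + 1L),
             (src_lo[2] + 1L):(src_hi[2] + 1L),
             (src_lo[3] + 1L):(src_hi[3] + 1L)]
  }
  attr(out, "offset") <- lo
  out
}

# express a full-volume plane in crop coordinates (0-based crop frame)
plane_to_crop <- function(plane, offset) {
  p <- as_plane(plane)
  normalize_plane(c(p[1:3], p[[4]] + sum(p[1:3] * offset)))
}

# choose the fitting threshold for a soft mask: half the peak value, so the
# fit uses the most confident voxels whatever the mask's absolute scale
resolve_fit_threshold <- function(mask, fit_threshold) {
  if (is.numeric(fit_threshold)) return(fit_threshold)
  max(1e-6, max(mask) / 2)
}

#' Detect the MSP of one (cropped) volume with trained models
#'
#' Runs the full stage-1 + stage-2 chain: seed detection (unless a seed is
#' supplied), crop, mask prediction, total-least-squares plane fit, and
#' optional 2D MSP extraction.
#'
#' @param volume 3D array (full volume; cropping happens around the seed).
#' @param seed_models `msp_seed_models` (may be `NULL` when `seed_point`
#'   is given — the semi-automatic arm).
#' @param gan trained `msp_gan`.
#' @param config an [run_config()].
#' @param seed_point optional annotated seed (semi-automatic mode).
#' @return List: `seed` (used seed point), `plane` (in full-volume
#'   coordinates), `plane_crop` (in crop coordinates), `mask` (soft mask),
#'   `offset` (crop offset), `msp_image` (extracted 2D MSP).
#' @export
detect_msp <- function(volume, seed_models, gan, config = run_config(),
                       seed_point = NULL) {
  sd <- if (is.null(seed_point)) detect_seed(volume, seed_models)
        else as.numeric(seed_point)
  crop <- crop_cube(volume, sd, config$crop_half_width)
  m <- predict_mask(gan, crop)
  thr <- resolve_fit_threshold(m, config$fit_threshold)
  pl_crop <- fit_plane_from_mask(m, thr)
  off <- attr(crop, "offset")
  pl_full <- normalize_plane(c(pl_crop[1:3],
                               pl_crop[[4]] - sum(pl_crop[1:3] * off)))
  img <- extract_msp_image(crop, pl_crop)
  list(seed = sd, plane = pl_full, plane_crop = pl_crop, mask = m,
       offset = off, msp_image = img)
}

#' Five-fold cross-validation of the full pipeline on phantoms
#'
#' Splits the included cases into near-equal folds (seeded), trains both
#' stages on each training split, runs seed detection, cropping, mask
#' prediction and plane fitting on the test split, and aggregates the four
#' pair metrics per fold and overall, with a one-way ANOVA of each metric
#' across folds.
#'
#' @param samples list of `msp_phantom` samples (equal cube extents; the
#'   crop half-width should be half the extent so crops stay in-volume).
#' @param config an [run_config()].
#' @param verbose print per-fold progress.
#' @return `msp_crossval` object: `cases` tibble (per-case metrics, seed
#'   errors, fold), `fold_summary`, `anova` (metric ~ fold p-values),
#'   `records` (case records with fold assignment), `summary` (cohort
#'   summary incl. threshold fractions).
#' @export
run_cross_validation <- function(samples, config = run_config(),
                                 verbose = FALSE) {
  rec <- filter_by_angle(case_records(samples), config$angle_baseline)
  keep <- which(rec$status == "included")
  if (length(keep) < config$folds)
    stop("fewer included cases than folds", call. = FALSE)
  samples <- lapply(samples, align_flip)
  fold_of <- local_seed(config$rng_seed,
                        sample(rep_len(seq_len(config$folds), length(keep))))
  rec$fold[keep] <- fold_of
  all_cases <- list()
  for (f in seq_len(config$folds)) {
    tr_id <- keep[fold_of != f]
    te_id <- keep[fold_of == f]
    if (length(te_id) == 0L) stop("fold with no test cases", call. = FALSE)
    if (verbose) message(sprintf("fold %d: %d train / %d test",
                                 f, length(tr_id), length(te_id)))
    fseed <- config$rng_seed + 1000L * f
    seed_models <- if (config$semi_automatic) NULL
      else train_seed_networks(samples[tr_id], config$seed_config,
                               seed = fseed)
    crops <- lapply(samples[tr_id], function(s)
      crop_cube(s$volume, s$gt_seed, config$crop_half_width))
    masks <- Map(function(s, cr) {
      rasterize_plane(plane_to_crop(s$gt_plane, attr(cr, "offset")),
                      dim(cr), 0.5)
    }, samples[tr_id], crops)
    gan <- train_gan(crops, masks, config = config$gan_config,
                     weights = config$gan_weights,
                     epochs = config$gan_epochs, lr = config$gan_lr,
                     seed = fseed + 1L)
    ctr <- rep(config$crop_half_width - 0.5, 3L)
    for (i in te_id) {
      s <- samples[[i]]
      res <- tryCatch(
        detect_msp(s$volume, seed_models, gan, config,
                   seed_point = if (config$semi_automatic) s$gt_seed else NULL),
        error = function(e) e)
      if (inherits(res, "error")) {
        all_cases[[length(all_cases) + 1L]] <- tibble::tibble(
          id = i, fold = f, ok = FALSE, seed_error = NA_real_,
          theta = NA_real_, dist = NA_real_, dyaw = NA_real_,
          droll = NA_real_)
        next
      }
      gt_crop <- plane_to_crop(s$gt_plane, res$offset)
      pm <- plane_pair_metrics(recenter_plane(res$plane_crop, ctr),
                               recenter_plane(gt_crop, ctr))
      all_cases[[length(all_cases) + 1L]] <- tibble::tibble(
        id = i, fold = f, ok = TRUE,
        seed_error = sqrt(sum((res$seed - s$gt_seed)^2)), pm)
    }
  }
  cases <- dplyr::bind_rows(all_cases)
  okc <- dplyr::filter(cases, .data$ok)
  fold_summary <- dplyr::summarise(
    dplyr::group_by(okc, .data$fold),
    n = dplyr::n(), mean_theta = mean(.data$theta),
    mean_dist = mean(.data$dist), mean_dyaw = mean(.data$dyaw),
    mean_droll = mean(.data$droll),
    median_theta = stats::median(.data$theta), .groups = "drop")
  anova_p <- vapply(c("theta", "dist", "dyaw", "droll"), function(mt) {
    if (length(unique(okc$fold)) < 2L) return(NA_real_)
    fit <- stats::aov(stats::reformulate("factor(fold)", mt), data = okc)
    summary(fit)[[1]][["Pr(>F)"]][1]
  }, numeric(1))
  summary <- tibble::tibble(
    n = nrow(okc), failed = sum(!cases$ok),
    median_theta = stats::median(okc$theta),
    mean_theta = mean(okc$theta), mean_dist = mean(okc$dist),
    mean_dyaw = mean(okc$dyaw), mean_droll = mean(okc$droll),
    median_seed_error = stats::median(okc$seed_error, na.rm = TRUE),
    frac_dist_below = mean(okc$dist < 0.05),
    frac_angle_below = mean(okc$theta < 1))
  structure(list(cases = cases, fold_summary = fold_summary,
                 anova = anova_p, records = rec, summary = summary,
                 config = config),
            class = "msp_crossval")
}

#' @export
print.msp_crossval <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cross-validation> %d cases (%d failed), %d folds\n",
              s$n + s$failed, s$failed, x$config$folds))
  cat(sprintf("  median included angle %.3f deg; mean %.3f deg\n",
              s$median_theta, s$mean_theta))
  cat(sprintf("  mean coeff distance %.4f; yaw %.3f deg; roll %.3f deg\n",
              s$mean_dist, s$mean_dyaw, s$mean_droll))
  cat(sprintf("  ANOVA across folds (p): theta %.3f dist %.3f yaw %.3f roll %.3f\n",
              x$anova["theta"], x$anova["dist"], x$anova["dyaw"],
              x$anova["droll"]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.msp_crossval <- function(x, ...) x$cases

#' @exportS3Method generics::glance
glance.msp_crossval <- function(x, ...) x$summary
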