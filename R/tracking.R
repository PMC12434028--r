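# Simplified probabilistic streamline tracker over phantom orientation
# fields. Two modes mirror the two tractography stages of the pipeline:
# classification-targets mode (each seed voxel is tracked separately and
# streamlines are credited to the first target mask they touch) and
# streamline mode (region-to-region counting with waypoint/avoid masks,
# normalized by seed volume).

#' Tracking parameters
#'
#' Defaults follow the probabilistic tractography settings of the pipeline:
#' curvature threshold 0.2 (minimum cosine between successive unit steps),
#' 0.5 mm steps, 2,000 steps per sample, 5,000 streamlines per seed voxel.
#'
#' @param curvature_threshold minimum dot product between successive unit
#'   step directions, in `[-1, 1]`.
#' @param step_length_mm step length (> 0).
#' @param max_steps maximum steps per streamline (>= 1).
#' @param samples_per_seed_voxel streamlines launched per seed voxel (>= 1).
#' @param rng_seed integer seed; identical seeds give identical counts.
#' @param curvature_retries bounded redraws after a curvature violation.
#' @param symmetrize antipodal symmetrization: flip a drawn direction when
#'   the flip better satisfies curvature (orientation fields are
#'   sign-ambiguous). Disable for strictly directed fields.
#' @return a `tracking_params` list.
#' @export
tracking_params <- function(curvature_threshold = 0.2,
                            step_length_mm = 0.5,
                            max_steps = 2000L,
                            samples_per_seed_voxel = 5000L,
                            rng_seed = 1L,
                            curvature_retries = 1L,
                            symmetrize = TRUE) {
  stopifnot(curvature_threshold >= -1, curvature_threshold <= 1,
            step_length_mm > 0, max_steps >= 1L,
            samples_per_seed_voxel >= 1L, curvature_retries >= 0L)
  structure(list(curvature_threshold = curvature_threshold,
                 step_length_mm = step_length_mm,
                 max_steps = as.integer(max_steps),
                 samples_per_seed_voxel = as.integer(samples_per_seed_voxel),
                 rng_seed = as.integer(rng_seed),
                 curvature_retries = as.integer(curvature_retries),
                 symmetrize = isTRUE(symmetrize)),
            class = "tracking_params")
}

#' Tracking domain: an orientation field on a grid
#'
#' @param grid a [voxel_grid()].
#' @param weights V x K per-voxel mixture weights over attractor points
#'   (rows of zeros mark voxels where the field is undefined).
#' @param centers K x 3 attractor coordinates (0-based voxel units).
#' @return a `tracking_domain` list.
#' @export
tracking_domain <- function(grid, weights, centers) {
  stopifnot(inherits(grid, "voxel_grid"),
            nrow(weights) == prod(grid$dim), ncol(weights) == nrow(centers),
            ncol(centers) == 3)
  structure(list(grid = grid, weights = weights, centers = centers),
            class = "tracking_domain")
}

#' Tracking domain of a phantom subject
#'
#' @param phantom a `phantom_subject`.
#' @return a `tracking_domain` built from [orientation_weights()].
#' @export
phantom_domain <- function(phantom) {
  tracking_domain(phantom$grid, orientation_weights(phantom),
                  attractor_points(phantom))
}

as_flat <- function(mask) which(mask)

check_masks_3d <- function(grid, ...) {
  for (m in list(...)) {
    if (is.null(m)) next
    stopifnot(is.logical(m), identical(dim(m), as.integer(grid$dim)))
  }
}

#' Classification-targets tractography
#'
#' Launches `samples_per_seed_voxel` streamlines from a uniformly jittered
#' position inside every seed voxel. Each streamline repeatedly samples a
#' direction from the local orientation-field mixture, takes a fixed-length
#' step, and terminates on entering a target mask (credited to that target,
#' first-touch wins), entering the exclusion mask, violating curvature,
#' exiting the defined field, or exhausting `max_steps` (all discarded).
#'
#' @param domain a [tracking_domain()].
#' @param seed_mask logical array of seed voxels (field must be defined
#'   there).
#' @param target_masks named list of disjoint logical arrays.
#' @param exclusion_mask optional logical array of discard voxels.
#' @param params a [tracking_params()].
#' @return a `streamline_counts` object: per-seed-voxel counts per target,
#'   launched counts, and per-run normalized region totals
#'   (count / seed-mask volume in mm^3).
#' @export
track_classification <- function(domain, seed_mask, target_masks,
                                 exclusion_mask = NULL,
                                 params = tracking_params()) {
  grid <- domain$grid
  check_masks_3d(grid, seed_mask, exclusion_mask)
  if (!sum(seed_mask)) stop("empty seed mask")
  if (is.null(names(target_masks)) || any(!nzchar(names(target_masks))))
    stop("target_masks must be a named list")
  target_id <- integer(prod(grid$dim))
  for (t in seq_along(target_masks)) {
    tm <- target_masks[[t]]
    check_masks_3d(grid, tm)
    f <- as_flat(tm)
    if (any(target_id[f] > 0)) stop("target masks must be disjoint")
    target_id[f] <- t
  }
  seeds <- as_flat(seed_mask)
  if (any(target_id[seeds] > 0)) stop("targets must be disjoint from seeds")
  avoid <- if (is.null(exclusion_mask)) logical(prod(grid$dim))
           else as.logical(exclusion_mask)
  if (any(avoid & target_id > 0))
    stop("target masks must not overlap the exclusion mask")
  defined <- rowSums(domain$weights) > 0
  if (any(!defined[seeds]))
    stop("seed voxels must lie where the orientation field is defined")

  set.seed(params$rng_seed)
  res <- track_cpp(grid$dim, domain$weights, domain$centers,
                   seeds - 1L, target_id, length(target_masks),
                   avoid, defined, logical(prod(grid$dim)), FALSE,
                   params$samples_per_seed_voxel, params$max_steps,
                   params$step_length_mm / grid$voxel_mm,
                   params$curvature_threshold, params$curvature_retries,
                   params$symmetrize)
  counts <- res$counts
  colnames(counts) <- names(target_masks)
  seed_vol <- sum(seed_mask) * voxel_volume(grid)
  structure(list(counts = counts, launched = res$launched,
                 seed_flat = seeds, seed_mask = seed_mask, grid = grid,
                 normalized_totals = colSums(counts) / seed_vol,
                 params = params),
            class = "streamline_counts")
}

#' @export
print.streamline_counts <- function(x, ...) {
  cat(sprintf("<streamline_counts: %d seed voxels x %d targets, %d/voxel>\n",
              nrow(x$counts), ncol(x$counts), x$params$samples_per_seed_voxel))
  print(round(x$normalized_totals, 3))
  invisible(x)
}

#' Region-to-region streamline tractography with waypoint/avoid masks
#'
#' Counts streamlines launched from the whole seed region that reach the
#' target region (passing through the waypoint mask first, when one is
#' given) and never touch the avoid mask. The count is normalized by the
#' seed-mask volume in mm^3 to make differently sized seed regions
#' comparable; both A-to-B and B-to-A runs are just argument swaps.
#'
#' @param domain a [tracking_domain()].
#' @param seed_region,target_region logical arrays (disjoint).
#' @param waypoint_mask optional must-pass mask.
#' @param avoid_mask optional discard mask; all four masks must be mutually
#'   disjoint.
#' @param params a [tracking_params()].
#' @return list with `count`, `normalized` (count per mm^3 of seed),
#'   `launched`, and `seed_volume_mm3`.
#' @export
track_streamline_mode <- function(domain, seed_region, target_region,
                                  waypoint_mask = NULL, avoid_mask = NULL,
                                  params = tracking_params()) {
  grid <- domain$grid
  check_masks_3d(grid, seed_region, target_region, waypoint_mask, avoid_mask)
  if (!sum(seed_region)) stop("empty seed mask")
  masks <- Filter(Negate(is.null),
                  list(seed_region, target_region, waypoint_mask, avoid_mask))
  overlap <- Reduce(`+`, lapply(masks, as.integer))
  if (any(overlap > 1)) stop("seed, target, waypoint and avoid masks must be mutually disjoint")
  V <- prod(grid$dim)
  target_id <- integer(V)
  target_id[as_flat(target_region)] <- 1L
  avoid <- if (is.null(avoid_mask)) logical(V) else as.logical(avoid_mask)
  waypoint <- if (is.null(waypoint_mask)) logical(V)
              else as.logical(waypoint_mask)
  defined <- rowSums(domain$weights) > 0
  seeds <- as_flat(seed_region)
  if (any(!defined[seeds]))
    stop("seed voxels must lie where the orientation field is defined")

  set.seed(params$rng_seed)
  res <- track_cpp(grid$dim, domain$weights, domain$centers,
                   seeds - 1L, target_id, 1L, avoid, defined,
                   waypoint, !is.null(waypoint_mask),
                   params$samples_per_seed_voxel, params$max_steps,
                   params$step_length_mm / grid$voxel_mm,
                   params$curvature_threshold, params$curvature_retries,
                   params$symmetrize)
  count <- sum(res$counts[, 1])
  seed_vol <- length(seeds) * voxel_volume(grid)
  list(count = count, normalized = count / seed_vol,
       launched = sum(res$launched), seed_volume_mm3 = seed_vol)
}
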