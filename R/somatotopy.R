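# N-1 leave-one-bait-out somatotopy: re-parcellate with nine bait regions,
# difference against the full parcellation to get per-region influence maps,
# derive ten disjoint similar-size somatotopic zones, and summarize each
# zone's compartment content as a signed normalized volume ratio.

#' N-1 parcellation probability maps
#'
#' Identical pipeline to the full parcellation (per-hemisphere
#' classification-targets tractography with contra-hemispheric exclusion)
#' but with one named bait region removed from its composite target; the
#' per-hemisphere seed streams are the same as the full parcellation's so
#' the two maps are comparable.
#'
#' @param phantom a `phantom_subject`.
#' @param leave_out bait region name.
#' @param params a [tracking_params()].
#' @param min_total_count classification floor.
#' @return a `probability_maps` object.
#' @export
n_minus_one_parcellation <- function(phantom, leave_out,
                                     params = tracking_params(),
                                     min_total_count = 10L) {
  composite <- bait_composites(phantom, leave_out = leave_out)
  domain <- phantom_domain(phantom)
  striatal <- striatal_mask_of(phantom$nuclei)
  hemi <- hemisphere_masks(phantom$grid)
  counts <- vector("list", 2)
  for (h in 1:2) {
    hm <- if (h == 1) hemi$left else hemi$right
    pars_h <- params
    pars_h$rng_seed <- spawn_seed(params$rng_seed, h)
    counts[[h]] <- track_classification(
      domain, seed_mask = striatal & hm,
      target_masks = list(matrix = composite$matrix & hm,
                          striosome = composite$striosome & hm),
      exclusion_mask = !hm, params = pars_h)
  }
  compute_bias_probabilities(counts, striatal, min_total_count)
}

# ratio maps robust to sub-floor voxels (used for influence differencing)
soft_p_matrix <- function(prob) {
  tot <- prob$matrix_counts + prob$striosome_counts
  p <- array(0.5, prob$grid$dim)
  f <- which(tot > 0)
  p[f] <- prob$matrix_counts[f] / tot[f]
  p
}

#' Influence map of one bait region
#'
#' The signed voxelwise difference, on the matrix-map convention, between
#' the full parcellation and the N-1 parcellation with the region left out:
#' `full p_matrix - N-1 p_matrix`. Defined on the full parcellation's
#' seeded voxels (NA elsewhere); near zero wherever the left-out region
#' contributed nothing.
#'
#' @param full full-parcellation `probability_maps`.
#' @param n1 the N-1 `probability_maps`.
#' @return 3D numeric array.
#' @export
influence_map <- function(full, n1) {
  stopifnot(inherits(full, "probability_maps"),
            inherits(n1, "probability_maps"))
  infl <- array(NA_real_, full$grid$dim)
  f <- which(full$seeded_mask)
  p1 <- soft_p_matrix(n1)
  infl[f] <- full$p_matrix[f] - p1[f]
  infl
}

#' Derive disjoint somatotopic zones from influence maps
#'
#' Each voxel with at least one absolute influence reaching that map's floor
#' is assigned to the region of maximal absolute influence (which guarantees
#' disjoint zones; ties break by the fixed region order of the input list);
#' each zone is then truncated to its top-influence voxels so that the
#' largest:smallest zone size ratio does not exceed `size_bound`.
#'
#' @param influence_maps named list of ten influence arrays on a common
#'   grid.
#' @param floor minimum absolute influence per map; defaults to each map's
#'   95th percentile of absolute influence.
#' @param size_bound maximum allowed largest:smallest zone size ratio.
#' @return a `somatotopic_zone_set`: named list of zone masks plus sizes.
#' @export
derive_zones <- function(influence_maps, floor = NULL, size_bound = 4) {
  regions <- names(influence_maps)
  stopifnot(!is.null(regions), all(nzchar(regions)))
  d <- dim(influence_maps[[1]])
  A <- vapply(influence_maps, function(m) abs(as.vector(m)),
              numeric(prod(d)))
  A[is.na(A)] <- 0
  floors <- if (is.null(floor)) {
    vapply(seq_along(regions), function(j) {
      v <- A[, j][A[, j] > 0]
      if (!length(v)) 0 else unname(quantile(v, 0.95))
    }, numeric(1))
  } else rep_len(floor, length(regions))
  above <- sweep(A, 2, floors, `>=`) & A > 0
  for (j in seq_along(regions)) {
    if (!any(above[, j]))
      stop("no voxels above the influence floor for region: ", regions[j])
  }
  eligible <- which(rowSums(above) > 0)
  win <- max.col(A[eligible, , drop = FALSE], ties.method = "first")
  zones <- lapply(seq_along(regions), function(j) {
    z <- array(FALSE, d)
    z[eligible[win == j]] <- TRUE
    z
  })
  names(zones) <- regions
  sizes <- vapply(zones, sum, integer(1))
  cap <- as.integer(size_bound * min(sizes))   # truncation cap
  for (j in seq_along(zones)) {
    if (sizes[j] > cap) {
      f <- which(zones[[j]])
      keep <- f[order(-A[f, j], f)][seq_len(cap)]
      z <- array(FALSE, d); z[keep] <- TRUE
      zones[[j]] <- z
      sizes[j] <- cap
    }
  }
  structure(list(zones = zones, sizes = sizes, floors = floors,
                 size_bound = size_bound),
            class = "somatotopic_zone_set")
}

#' @export
print.somatotopic_zone_set <- function(x, ...) {
  cat("<somatotopic_zone_set>\n")
  print(x$sizes)
  invisible(x)
}

#' Signed normalized compartment volume ratio within a zone
#'
#' `(Vdom - Vnon) / (Vdom + Vnon)` where `Vdom` is the compartment-like
#' volume (at the parcellation's bias threshold) of the zone's dominant
#' compartment and `Vnon` the other's. Undefined (NA) when both volumes are
#' zero — never reported as 0.
#'
#' @param parc a `compartment_parcellation`.
#' @param zone_mask logical array, subset of the striatal mask.
#' @param dominant `"matrix"` or `"striosome"`.
#' @return a `zone_ratio` list: `dominant`, `v_dom`, `v_non`, `value`.
#' @export
zone_ratio_statistic <- function(parc, zone_mask, dominant) {
  dominant <- match.arg(dominant, c("matrix", "striosome"))
  if (any(zone_mask & !parc$striatal_mask))
    stop("zone must lie inside the striatal mask")
  vv <- voxel_volume(parc$grid)
  vm <- sum(zone_mask & parc_mask(parc, "matrix_like")) * vv
  vs <- sum(zone_mask & parc_mask(parc, "striosome_like")) * vv
  v_dom <- if (dominant == "matrix") vm else vs
  v_non <- if (dominant == "matrix") vs else vm
  value <- if (v_dom + v_non > 0) (v_dom - v_non) / (v_dom + v_non)
           else NA_real_
  structure(list(dominant = dominant, v_dom = v_dom, v_non = v_non,
                 value = value), class = "zone_ratio")
}

#' Somatotopic zones of one subject
#'
#' Runs the full parcellation plus the ten N-1 rounds, builds the influence
#' maps, and derives the zone set.
#'
#' @param phantom a `phantom_subject`.
#' @param params a [tracking_params()].
#' @param min_total_count classification floor.
#' @param floor,size_bound passed to [derive_zones()].
#' @return list with `zones` (a `somatotopic_zone_set`), `influence`
#'   (named list of arrays) and `full` (the full `probability_maps`).
#' @export
subject_zones <- function(phantom, params = tracking_params(),
                          min_total_count = 10L, floor = NULL,
                          size_bound = 4) {
  full <- n_minus_one_parcellation_full(phantom, params, min_total_count)
  influence <- lapply(BAIT_REGIONS, function(r) {
    n1 <- n_minus_one_parcellation(phantom, r, params, min_total_count)
    influence_map(full, n1)
  })
  names(influence) <- BAIT_REGIONS
  zones <- derive_zones(influence, floor = floor, size_bound = size_bound)
  list(zones = zones, influence = influence, full = full)
}

# the "full" round shares the N-1 plumbing (no region left out)
n_minus_one_parcellation_full <- function(phantom, params, min_total_count) {
  n_minus_one_parcellation(phantom, leave_out = NULL, params = params,
                           min_total_count = min_total_count)
}

#' Per-zone compartment ratio report
#'
#' @param parc a `compartment_parcellation`.
#' @param zone_set a `somatotopic_zone_set`.
#' @param affinity named affinity map (region -> dominant compartment),
#'   e.g. `phantom$bait_atlas$affinity`.
#' @return data.frame (zone, dominant, v_dom, v_non, ratio).
#' @export
zone_report <- function(parc, zone_set, affinity) {
  rows <- lapply(names(zone_set$zones), function(r) {
    zr <- zone_ratio_statistic(parc, zone_set$zones[[r]], affinity[[r]])
    data.frame(zone = r, dominant = zr$dominant, v_dom = zr$v_dom,
               v_non = zr$v_non, ratio = zr$value)
  })
  do.call(rbind, rows)
}
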