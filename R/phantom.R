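# Synthetic striatum phantoms.
#
# A phantom is a voxel grid carrying: caudate/putamen nucleus labels (mirror
# symmetric across the mid-sagittal plane), a ground-truth compartment label
# (matrix or striosome) on every striatal voxel, a per-voxel fiber orientation
# field wired toward ten extra-striatal "bait" regions, a tensor-eigenvalue
# field for radial diffusivity, and subject covariates. Striosomes are grown
# as thin separated random-walk tubules (the histological picture: separated
# islands embedded in a contiguous matrix), with a rostro-ventral location
# bias and a hard cap on tubule cross-sectional diameter.

MATRIX_REGIONS <- c("ifg_pars_opercularis", "primary_motor",
                    "supplementary_motor", "primary_somatosensory",
                    "superior_parietal")
STRIOSOME_REGIONS <- c("posterior_orbitofrontal", "anterior_insula",
                       "basolateral_amygdala", "basal_operculum",
                       "posterior_temporal_fusiform")
BAIT_REGIONS <- c(MATRIX_REGIONS, STRIOSOME_REGIONS)
BAIT_AFFINITY <- setNames(rep(c("matrix", "striosome"), each = 5),
                          BAIT_REGIONS)
# each affinity lists its regions in somatotopic (caudal -> rostral) band order
BAIT_BAND <- setNames(rep(1:5, 2), BAIT_REGIONS)

#' Phantom configuration
#'
#' Defaults define the package's reference striatum phantom: a 1 mm isotropic
#' grid whose two nuclei per hemisphere hold roughly 3,000 striatal voxels in
#' total, a 15% striosome volume target, a 1.25 mm cap on striosome tubule
#' diameter, and an orientation field that routes 85% of each voxel's
#' streamline probability toward bait regions of its own compartment's
#' affinity (leakage 0.15 toward the opposite affinity), concentrated on the
#' bait region of its somatotopic band.
#'
#' @param dim grid size (voxels per axis, all >= 20).
#' @param voxel_mm isotropic voxel size in mm, in (0.5, 3.0).
#' @param striosome_fraction target striosome fraction of striatal volume,
#'   in (0.05, 0.4).
#' @param striosome_diameter_cap_mm maximum tubule cross-sectional diameter.
#' @param n_tubules minimum striosome tubules per hemisphere (>= 3).
#' @param leakage orientation-field probability routed to the opposite
#'   affinity's bait regions.
#' @param zone_weight share of each affinity's probability concentrated on
#'   the bait region of the voxel's own somatotopic band.
#' @param rostroventral_bias strength of the rostral(+y)/ventral(-z) seeding
#'   bias for striosome tubules (log-linear in normalized position).
#' @param etiv_mm3 intracranial-volume analog in mm^3.
#' @param rd_eigenvalues baseline tensor eigenvalues (mm^2/s), descending.
#' @param rd_noise relative jitter applied to the eigenvalue field.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(dim = c(40, 48, 40),
                           voxel_mm = 1,
                           striosome_fraction = 0.15,
                           striosome_diameter_cap_mm = 1.25,
                           n_tubules = 5,
                           leakage = 0.15,
                           zone_weight = 0.6,
                           rostroventral_bias = 4,
                           etiv_mm3 = 1.438e6,
                           rd_eigenvalues = c(1.0e-3, 6e-4, 5e-4),
                           rd_noise = 0.05) {
  cfg <- list(dim = as.integer(dim), voxel_mm = voxel_mm,
              striosome_fraction = striosome_fraction,
              striosome_diameter_cap_mm = striosome_diameter_cap_mm,
              n_tubules = as.integer(n_tubules), leakage = leakage,
              zone_weight = zone_weight,
              rostroventral_bias = rostroventral_bias,
              etiv_mm3 = etiv_mm3, rd_eigenvalues = rd_eigenvalues,
              rd_noise = rd_noise)
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (any(cfg$dim < 20L))
    stop("grid dimensions must be at least 20 voxels per axis")
  if (cfg$voxel_mm <= 0.5 || cfg$voxel_mm >= 3.0)
    stop("voxel size must lie in (0.5, 3.0) mm")
  if (cfg$striosome_fraction <= 0.05 || cfg$striosome_fraction >= 0.4)
    stop("striosome target fraction must lie in (0.05, 0.4)")
  if (cfg$voxel_mm > cfg$striosome_diameter_cap_mm)
    stop("infeasible geometry: striosome target fraction unreachable under ",
         "the diameter cap (voxel edge ", cfg$voxel_mm,
         " mm exceeds the cap ", cfg$striosome_diameter_cap_mm, " mm)")
  if (cfg$leakage < 0 || cfg$leakage >= 0.5)
    stop("leakage must lie in [0, 0.5)")
  if (cfg$n_tubules < 3L) stop("n_tubules must be at least 3 per hemisphere")
  if (any(diff(cfg$rd_eigenvalues) > 0) || any(cfg$rd_eigenvalues < 0))
    stop("rd_eigenvalues must satisfy lambda1 >= lambda2 >= lambda3 >= 0")
  invisible(cfg)
}

# ellipsoid nucleus mask in voxel index space
ellipsoid_mask <- function(dim, center, semi) {
  ii <- slice.index(array(0L, dim), 1)
  jj <- slice.index(array(0L, dim), 2)
  kk <- slice.index(array(0L, dim), 3)
  ((ii - center[1]) / semi[1])^2 + ((jj - center[2]) / semi[2])^2 +
    ((kk - center[3]) / semi[3])^2 <= 1
}

# nucleus geometry scales with the grid so non-default dims stay usable
phantom_geometry <- function(cfg) {
  d <- cfg$dim
  sc <- d / c(40, 48, 40)
  r_caud_center <- c(26.5, 29, 24) * sc
  r_caud_semi <- c(3.5, 10, 5) * sc
  r_put_center <- c(33, 23, 18) * sc
  r_put_semi <- c(4.5, 9, 5) * sc
  caud_r <- ellipsoid_mask(d, r_caud_center, r_caud_semi)
  put_r <- ellipsoid_mask(d, r_put_center, r_put_semi)
  if (any(caud_r & put_r)) {           # carve the overlap into the caudate
    put_r[caud_r] <- FALSE
  }
  caud_l <- mirror_x(caud_r)
  put_l <- mirror_x(put_r)
  nuclei <- array(0L, d)
  nuclei[caud_l] <- 1L; nuclei[caud_r] <- 2L
  nuclei[put_l] <- 3L; nuclei[put_r] <- 4L
  # bait slabs hug the striatum (1-voxel gap): matrix-favoring regions form
  # a dorsal slab, striosome-favoring regions a ventral slab, each divided
  # into somatotopic y-bands. The two composite routes are antipodal, so
  # antipodal symmetrization in the tracker preserves a streamline's initial
  # (seed-drawn) direction while it traverses tissue wired the other way.
  zs <- range(mask_indices(nuclei > 0L)[, 3])
  matrix_slab_z <- seq(zs[2] + 2L, min(zs[2] + 5L, d[3]))
  strio_slab_z <- seq(max(zs[1] - 5L, 1L), zs[1] - 2L)
  list(nuclei = nuclei, matrix_slab_z = matrix_slab_z,
       strio_slab_z = strio_slab_z)
}

NUCLEUS_LABELS <- c(`caudate-L` = 1L, `caudate-R` = 2L,
                    `putamen-L` = 3L, `putamen-R` = 4L)

striatal_mask_of <- function(nuclei) nuclei > 0L

# somatotopic band cut points from striatal y-quantiles (5 similar-count bands)
band_cuts <- function(nuclei, dim) {
  ys <- mask_indices(striatal_mask_of(nuclei))[, 2]
  round(unname(quantile(ys, probs = c(0.2, 0.4, 0.6, 0.8))))
}

band_of_y <- function(y, cuts) findInterval(y, cuts,
                                            left.open = TRUE) + 1L

# bait region block masks: each somatotopic y-band of the dorsal slab is
# split into a matrix-favoring stripe (lower-y half) and a striosome-favoring
# stripe (upper-y half); stripes tile the slab with no gaps
build_bait_masks <- function(cfg, geom, cuts) {
  d <- cfg$dim
  edges <- c(0L, cuts, d[2])          # outer bands extend to catch drift
  jj <- slice.index(array(0L, d), 2)
  kk <- slice.index(array(0L, d), 3)
  masks <- vector("list", 10)
  names(masks) <- BAIT_REGIONS
  for (r in BAIT_REGIONS) {
    b <- BAIT_BAND[[r]]
    zr <- if (BAIT_AFFINITY[[r]] == "matrix") geom$matrix_slab_z
          else geom$strio_slab_z
    masks[[r]] <- jj > edges[b] & jj <= edges[b + 1] &
      kk >= zr[1] & kk <= zr[length(zr)]
  }
  masks
}

# ---- striosome tubule growth ----------------------------------------------
# Unbranched 6-connected random-walk chains, forbidden from coming within the
# 26-neighbourhood of any other striosome voxel except the chain's own last
# two voxels. This keeps every tubule one voxel thick (no fully-striosome
# 2x2 in-plane block can form), hence cross-sectional diameter = voxel edge
# <= the configured cap, and keeps tubules 26-separated so each is its own
# connected component ("islands").

neighbours6 <- function(v, d) {
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  nb <- sweep(offs, 2, v, `+`)
  nb[nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
       nb[, 3] >= 1 & nb[, 3] <= d[3], , drop = FALSE]
}

neighbours26_flat <- function(v, d) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  nb <- sweep(g, 2, v, `+`)
  nb <- nb[nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
             nb[, 3] >= 1 & nb[, 3] <= d[3], , drop = FALSE]
  nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
}

grow_striosome_hemi <- function(striatum_hemi, nuclei, cfg) {
  d <- dim(striatum_hemi)
  target <- round(cfg$striosome_fraction * sum(striatum_hemi))
  strio <- array(FALSE, d)
  idx_all <- mask_indices(striatum_hemi)
  flat_all <- which(striatum_hemi)
  # rostro-ventral bias normalized within each voxel's nucleus of origin,
  # so both caudate and putamen tubules sit rostral/ventral within their
  # own nucleus
  nuc_of <- nuclei[flat_all]
  ynorm <- znorm <- numeric(length(flat_all))
  for (lab in unique(nuc_of)) {
    in_n <- nuc_of == lab
    yr_n <- range(idx_all[in_n, 2]); zr_n <- range(idx_all[in_n, 3])
    ynorm[in_n] <- (idx_all[in_n, 2] - yr_n[1]) / max(1, diff(yr_n))
    znorm[in_n] <- (idx_all[in_n, 3] - zr_n[1]) / max(1, diff(zr_n))
  }
  yr <- range(idx_all[, 2]); zr <- range(idx_all[, 3])
  norm_w <- exp(cfg$rostroventral_bias * (ynorm - znorm))
  seed_w <- norm_w
  max_len <- max(8L, ceiling(target / cfg$n_tubules))
  placed <- 0L
  chains <- 0L
  attempts <- 0L
  max_attempts <- 400L
  while (placed < target) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("infeasible geometry: striosome target fraction unreachable ",
           "under the diameter cap (tubule packing exhausted at ",
           sprintf("%.1f%% of striatal volume", 100 * placed /
                     sum(striatum_hemi)), ")")
    free <- !strio[flat_all]
    # candidate starts: free striatal voxels with no striosome 26-neighbour
    cand <- which(free)
    if (!length(cand)) break
    start_row <- cand[sample.int(length(cand), 1, prob = seed_w[cand])]
    v <- idx_all[start_row, ]
    if (any(strio[neighbours26_flat(v, d)])) next
    chain <- matrix(v, nrow = 1)
    strio[v[1], v[2], v[3]] <- TRUE
    len <- 1L
    while (len < max_len && (placed + len < target || len < 3L)) {
      head_v <- chain[nrow(chain), ]
      prev_v <- if (nrow(chain) > 1) chain[nrow(chain) - 1, ] else head_v
      nb <- neighbours6(head_v, d)
      ok <- logical(nrow(nb))
      for (i in seq_len(nrow(nb))) {
        c_v <- nb[i, ]
        if (!striatum_hemi[c_v[1], c_v[2], c_v[3]] ||
            strio[c_v[1], c_v[2], c_v[3]]) next
        nbf <- neighbours26_flat(c_v, d)
        touching <- nbf[strio[nbf]]
        allowed <- c(head_v[1] + d[1] * (head_v[2] - 1) +
                       d[1] * d[2] * (head_v[3] - 1),
                     prev_v[1] + d[1] * (prev_v[2] - 1) +
                       d[1] * d[2] * (prev_v[3] - 1))
        ok[i] <- all(touching %in% allowed)
      }
      if (!any(ok)) break
      ok_rows <- which(ok)
      wk <- exp(cfg$rostroventral_bias *
                  ((nb[ok_rows, 2] - yr[1]) / max(1, diff(yr)) -
                   (nb[ok_rows, 3] - zr[1]) / max(1, diff(zr))))
      pick <- nb[ok_rows[sample.int(length(ok_rows), 1, prob = wk)], ]
      strio[pick[1], pick[2], pick[3]] <- TRUE
      chain <- rbind(chain, pick)
      len <- len + 1L
    }
    if (len < 3L) {                      # too short to be a tubule: retract
      for (i in seq_len(nrow(chain)))
        strio[chain[i, 1], chain[i, 2], chain[i, 3]] <- FALSE
      next
    }
    placed <- placed + len
    chains <- chains + 1L
  }
  if (chains < cfg$n_tubules && placed >= target) {
    # enough volume but too few islands: retry is handled by caller via error
    stop("infeasible geometry: fewer than ", cfg$n_tubules,
         " striosome tubules fit under the diameter cap")
  }
  strio
}

# ---- orientation field -----------------------------------------------------
# Attractor layout: columns 1..10 = left-hemisphere halves of the ten bait
# regions, 11..20 = right halves, 21/22 = left/right striatal centroids
# (used only by extra-striatal voxels so that bait-seeded streamlines can
# find their way into the striatum). All coordinates 0-based voxel units.

attractor_points <- function(phantom) {
  d <- phantom$grid$dim
  hemi <- hemisphere_masks(phantom$grid)
  centers <- matrix(NA_real_, 22, 3)
  for (h in 1:2) {
    hm <- if (h == 1) hemi$left else hemi$right
    sm_h <- striatal_mask_of(phantom$nuclei) & hm
    sijk <- mask_indices(sm_h)
    x_center <- mean(sijk[, 1]) - 1
    d3 <- phantom$grid$dim[3]
    for (j in seq_along(BAIT_REGIONS)) {
      r <- BAIT_REGIONS[j]
      b <- BAIT_BAND[[r]]
      # attractors sit far beyond their slab on a vertical axis through the
      # band's striatal footprint: all drawn directions are near-vertical
      # (dorsal for matrix-favoring, ventral for striosome-favoring), so a
      # streamline's destination composite is fixed by its seed-voxel draw
      # and its landing band tracks its own y-column (gentle pull toward
      # the band centre); the slab masks capture it on entry
      in_band <- band_of_y(sijk[, 2], phantom$band_cuts) == b
      y_center <- (if (any(in_band)) mean(sijk[in_band, 2])
                   else mean(sijk[, 2])) - 1
      z_far <- if (BAIT_AFFINITY[[r]] == "matrix") d3 + 15 else -16
      centers[(h - 1) * 10 + j, ] <- c(x_center, y_center, z_far)
    }
    sm <- striatal_mask_of(phantom$nuclei) & hm
    centers[20 + h, ] <- colMeans(mask_indices(sm)) - 1
  }
  centers
}

# per-voxel mixture weights for one compartment identity
compartment_mixture <- function(compartment, band, leakage, zone_weight) {
  w <- numeric(10)
  own <- which(BAIT_AFFINITY == compartment)
  opp <- setdiff(1:10, own)
  own_zone <- own[BAIT_BAND[own] == band]
  opp_zone <- opp[BAIT_BAND[opp] == band]
  w[own_zone] <- (1 - leakage) * zone_weight
  w[setdiff(own, own_zone)] <- (1 - leakage) * (1 - zone_weight) / 4
  w[opp_zone] <- leakage * zone_weight
  w[setdiff(opp, opp_zone)] <- leakage * (1 - zone_weight) / 4
  w
}

#' Orientation-field mixture weights for a phantom subject
#'
#' Builds the V x 22 matrix of per-voxel categorical weights over the
#' attractor set (10 bait-region halves per hemisphere + the two striatal
#' centroids). Striatal voxels route `1 - leakage` of their probability
#' toward bait regions of their ground-truth compartment's affinity
#' (concentrated on their somatotopic band's region by `zone_weight`), and
#' `leakage` toward the opposite affinity. Extra-striatal voxels split
#' between their hemisphere's striatal centroid and bait regions.
#' Any per-voxel overrides injected by the cohort simulator (bias flips,
#' indeterminate voxels) are applied last.
#'
#' @param phantom a `phantom_subject`.
#' @return numeric matrix, one row per grid voxel (column-major order).
#' @export
orientation_weights <- function(phantom) {
  d <- phantom$grid$dim
  V <- prod(d)
  cfg <- phantom$params
  W <- matrix(0, V, 22)
  hemi <- hemisphere_masks(phantom$grid)
  striatal <- striatal_mask_of(phantom$nuclei)
  jj <- slice.index(array(0L, d), 2)
  bands <- band_of_y(jj, phantom$band_cuts)

  # striatal voxels: compartment wiring on ipsilateral attractors
  for (h in 1:2) {
    hm <- if (h == 1) hemi$left else hemi$right
    off <- (h - 1) * 10
    for (comp in c("matrix", "striosome")) {
      gt_val <- if (comp == "matrix") 1L else 2L
      for (b in 1:5) {
        sel <- which(striatal & hm & phantom$gt_compartment == gt_val &
                       bands == b)
        if (!length(sel)) next
        mix <- compartment_mixture(comp, b, cfg$leakage, cfg$zone_weight)
        W[sel, off + (1:10)] <- matrix(mix, length(sel), 10, byrow = TRUE)
      }
    }
    # extra-striatal: toward the bait attractors only, which keeps
    # transiting streamlines on near-vertical headings (no transverse
    # component that could U-turn or strand them); bait-slab voxels
    # additionally pull toward the striatal centroid so that bait-seeded
    # streamlines (inverse tractography) find their way into the striatum
    in_bait <- Reduce(`|`, phantom$bait_atlas$regions)
    sel <- which(!striatal & hm & !in_bait)
    W[sel, off + (1:10)] <- 0.1
    selb <- which(!striatal & hm & in_bait)
    W[selb, off + (1:10)] <- 0.05
    W[selb, 20 + h] <- 0.5
  }

  # cohort-injected overrides: list(idx = flat voxel indices, type)
  for (ov in phantom$weight_overrides) {
    idx <- ov$idx
    hemi_of <- ifelse(((idx - 1) %% d[1]) + 1 <= d[1] / 2, 1L, 2L)
    for (h in 1:2) {
      sel <- idx[hemi_of == h]
      if (!length(sel)) next
      off <- (h - 1) * 10
      b_sel <- bands[sel]
      for (b in unique(b_sel)) {
        rows <- sel[b_sel == b]
        mix <- switch(ov$type,
          flip_to_striosome = compartment_mixture("striosome", b,
                                                  cfg$leakage,
                                                  cfg$zone_weight),
          flip_to_matrix = compartment_mixture("matrix", b, cfg$leakage,
                                               cfg$zone_weight),
          indeterminate = compartment_mixture("matrix", b, 0.5,
                                              cfg$zone_weight),
          stop("unknown override type: ", ov$type))
        W[rows, off + (1:10)] <- matrix(mix, length(rows), 10, byrow = TRUE)
        W[rows, 21:22] <- 0
      }
    }
  }
  W
}

#' Orientation field at one voxel as (direction, weight) pairs
#'
#' @param phantom a `phantom_subject`.
#' @param voxel integer vector of length 3 (1-based array index).
#' @return data.frame with unit direction components and weights (rows with
#'   zero weight dropped); weights sum to 1.
#' @export
orientation_field_at <- function(phantom, voxel) {
  d <- phantom$grid$dim
  flat <- voxel[1] + d[1] * (voxel[2] - 1) + d[1] * d[2] * (voxel[3] - 1)
  W <- orientation_weights(phantom)
  centers <- attractor_points(phantom)
  w <- W[flat, ]
  keep <- which(w > 0)
  dirs <- sweep(centers[keep, , drop = FALSE], 2, voxel - 1, `-`)
  nrm <- sqrt(rowSums(dirs^2))
  dirs <- dirs / nrm
  att_names <- c(paste0(BAIT_REGIONS, "-L"), paste0(BAIT_REGIONS, "-R"),
                 "striatum-L", "striatum-R")
  data.frame(attractor = att_names[keep], dx = dirs[, 1], dy = dirs[, 2],
             dz = dirs[, 3], weight = w[keep] / sum(w[keep]),
             row.names = NULL)
}

# ---- phantom assembly ------------------------------------------------------

#' Build one synthetic striatum phantom subject
#'
#' @param params a [phantom_config()].
#' @param rng_seed integer seed; identical seeds give bit-identical phantoms.
#' @param subject_id identifier string.
#' @param group `"HC"` or `"MDD"` (covariate only; effects are injected by
#'   [simulate_cohort()]).
#' @return a `phantom_subject` object.
#' @export
build_phantom <- function(params = phantom_config(), rng_seed = 1L,
                          subject_id = "phantom", group = "HC") {
  validate_phantom_config(params)
  set.seed(rng_seed)
  geom <- phantom_geometry(params)
  d <- params$dim
  grid <- voxel_grid(d, params$voxel_mm)
  striatal <- striatal_mask_of(geom$nuclei)
  hemi <- hemisphere_masks(grid)

  strio <- array(FALSE, d)
  for (h in 1:2) {
    hm <- if (h == 1) hemi$left else hemi$right
    strio <- strio | grow_striosome_hemi(striatal & hm, geom$nuclei, params)
  }
  gt <- array(0L, d)
  gt[striatal] <- 1L
  gt[strio] <- 2L

  cuts <- band_cuts(geom$nuclei, d)
  bait_masks <- build_bait_masks(params, geom, cuts)
  gt_zone <- lapply(BAIT_REGIONS, function(r) {
    gt_val <- if (BAIT_AFFINITY[[r]] == "matrix") 1L else 2L
    jj <- slice.index(array(0L, d), 2)
    gt == gt_val & band_of_y(jj, cuts) == BAIT_BAND[[r]]
  })
  names(gt_zone) <- BAIT_REGIONS

  lam <- params$rd_eigenvalues
  n_striatal <- sum(striatal)
  rd_field <- array(0, c(d, 3))
  noise <- matrix(1 + params$rd_noise * (2 * runif(n_striatal * 3) - 1),
                  n_striatal, 3)
  vals <- sweep(noise, 2, lam, `*`)
  vals <- t(apply(vals, 1, sort, decreasing = TRUE))
  for (k in 1:3) {
    slab <- array(0, d)
    slab[striatal] <- vals[, k]
    rd_field[, , , k] <- slab
  }

  phantom <- structure(list(
    subject_id = subject_id,
    grid = grid,
    nuclei = geom$nuclei,
    gt_compartment = gt,
    band_cuts = cuts,
    bait_atlas = list(regions = bait_masks, affinity = BAIT_AFFINITY,
                      band = BAIT_BAND, gt_zone = gt_zone),
    rd_field = rd_field,
    etiv = params$etiv_mm3,
    group = group,
    severity_score = NA_real_,
    severity_scale = NA_character_,
    scanner_id = "scannerA",
    study_id = "studyA",
    age = 25,
    weight_overrides = list(),
    params = params,
    rng_seed = as.integer(rng_seed)
  ), class = "phantom_subject")
  validate_phantom(phantom)
  phantom
}

#' @export
print.phantom_subject <- function(x, ...) {
  ns <- sum(striatal_mask_of(x$nuclei))
  fr <- sum(x$gt_compartment == 2L) / ns
  cat(sprintf(
    "<phantom_subject %s: %s, %d striatal voxels, striosome %.1f%%, %s>\n",
    x$subject_id, x$group, ns, 100 * fr,
    paste(x$grid$dim, collapse = "x")))
  invisible(x)
}

# invariant checks used at build time and by tests
validate_phantom <- function(p) {
  striatal <- striatal_mask_of(p$nuclei)
  gt_on <- p$gt_compartment != 0L
  if (!identical(unname(which(gt_on)), unname(which(striatal))))
    stop("gt_compartment must be defined exactly on striatal voxels")
  frac <- sum(p$gt_compartment == 2L) / sum(striatal)
  if (abs(frac - p$params$striosome_fraction) > 0.02)
    stop("striosome fraction out of tolerance: ", round(frac, 3))
  if (striosome_max_width_mm(p) > p$params$striosome_diameter_cap_mm + 1e-9)
    stop("striosome diameter cap violated")
  rl <- p$nuclei[rev(seq_len(dim(p$nuclei)[1])), , ]
  swap <- rl
  swap[rl == 1L] <- 2L; swap[rl == 2L] <- 1L
  swap[rl == 3L] <- 4L; swap[rl == 4L] <- 3L
  if (!identical(swap, p$nuclei))
    stop("nucleus geometry must be mirror-symmetric")
  invisible(p)
}

# Inscribed tubule width: the cap is respected iff no 2x2 in-plane block of
# voxels is fully striosome, i.e. tubules are at most one voxel wide.
striosome_max_width_mm <- function(p) {
  s <- p$gt_compartment == 2L
  d <- dim(s)
  two_by_two <- function(a, ax1, ax2) {
    idx1 <- seq_len(d[ax1] - 1); idx2 <- seq_len(d[ax2] - 1)
    sh <- function(o1, o2) {
      ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      ix[[ax1]] <- idx1 + o1; ix[[ax2]] <- idx2 + o2
      a[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
    }
    any(sh(0, 0) & sh(1, 0) & sh(0, 1) & sh(1, 1))
  }
  thick <- two_by_two(s, 1, 2) || two_by_two(s, 1, 3) || two_by_two(s, 2, 3)
  if (thick) 2 * p$grid$voxel_mm else p$grid$voxel_mm
}

# ---- severity binning ------------------------------------------------------

#' Depression severity category from a scale score
#'
#' Bins a severity score into `Mild`, `Moderate`, `Severe` or `VerySevere`
#' using the scale-specific tables (Hamilton Depression Rating Scale, the
#' RCADS depression subscale, or Achenbach depression T-scores). Bins are
#' half-open, with a boundary shared between two printed bins resolved to the
#' upper bin; scores below the lowest bin return `BelowThreshold`.
#'
#' @param scale one of `"Hamilton"`, `"RCADS"`, `"Achenbach"`.
#' @param score finite numeric score.
#' @return character category.
#' @export
severity_to_category <- function(scale, score) {
  if (length(scale) != 1L || !scale %in% c("Hamilton", "RCADS", "Achenbach"))
    stop("unknown severity scale: ", paste(scale, collapse = ", "))
  if (!is.numeric(score) || !is.finite(score))
    stop("score must be finite")
  lower <- switch(scale,
                  Hamilton = c(8, 14, 19, 23),
                  RCADS = c(18, 21, 24, 27),
                  Achenbach = c(70, 78, 85, 92))
  cats <- c("BelowThreshold", "Mild", "Moderate", "Severe", "VerySevere")
  cats[findInterval(score, lower) + 1L]
}

severity_category_index <- function(category) {
  match(category, c("BelowThreshold", "Mild", "Moderate", "Severe",
                    "VerySevere")) - 1L
}
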