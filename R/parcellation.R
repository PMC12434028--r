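# From streamline counts to compartment-like maps and derived measures:
# voxelwise connection probabilities, the matrix-like / striosome-like /
# indeterminate / unseeded classification, compartment volumes (raw and
# intracranial-volume normalized), high-bias equal-volume masks, largest
# clusters, centroid-relative locations and radial diffusivity.

PARC_LABELS <- c(outside = 0L, matrix_like = 1L, striosome_like = 2L,
                 indeterminate = 3L, unseeded = 4L)

#' Voxelwise compartment-bias probabilities from streamline counts
#'
#' For every striatal voxel whose combined matrix + striosome target count
#' reaches `min_total_count`, the matrix-like probability is the matrix
#' count divided by the summed count (so the two maps sum to one exactly);
#' voxels below the floor are marked unseeded.
#'
#' @param counts a `streamline_counts` (or list of them, e.g. one per
#'   hemisphere) with targets named `"matrix"` and `"striosome"`.
#' @param striatal_mask logical array of striatal voxels.
#' @param min_total_count classification floor (total streamlines needed for
#'   a voxel to be classifiable).
#' @return a `probability_maps` object with `p_matrix`, `p_striosome`
#'   (NA off the seeded mask), `seeded_mask`, and the counts.
#' @export
compute_bias_probabilities <- function(counts, striatal_mask,
                                       min_total_count = 10L) {
  if (inherits(counts, "streamline_counts")) counts <- list(counts)
  grid <- counts[[1]]$grid
  stopifnot(identical(dim(striatal_mask), as.integer(grid$dim)))
  V <- prod(grid$dim)
  cm <- numeric(V); cs <- numeric(V)
  for (sc in counts) {
    stopifnot(inherits(sc, "streamline_counts"),
              all(c("matrix", "striosome") %in% colnames(sc$counts)))
    if (any(sc$counts < 0)) stop("negative streamline counts")
    cm[sc$seed_flat] <- cm[sc$seed_flat] + sc$counts[, "matrix"]
    cs[sc$seed_flat] <- cs[sc$seed_flat] + sc$counts[, "striosome"]
  }
  if (any(cm < 0) || any(cs < 0)) stop("negative streamline counts")
  tot <- cm + cs
  seeded <- array(FALSE, grid$dim)
  seeded[striatal_mask & array(tot >= min_total_count, grid$dim)] <- TRUE
  p_matrix <- array(NA_real_, grid$dim)
  p_striosome <- array(NA_real_, grid$dim)
  f <- which(seeded)
  p_matrix[f] <- cm[f] / tot[f]
  p_striosome[f] <- cs[f] / tot[f]
  structure(list(p_matrix = p_matrix, p_striosome = p_striosome,
                 seeded_mask = seeded, striatal_mask = striatal_mask,
                 matrix_counts = array(cm, grid$dim),
                 striosome_counts = array(cs, grid$dim),
                 min_total_count = as.integer(min_total_count), grid = grid),
            class = "probability_maps")
}

#' @export
print.probability_maps <- function(x, ...) {
  cat(sprintf("<probability_maps: %d/%d striatal voxels seeded (floor %d)>\n",
              sum(x$seeded_mask), sum(x$striatal_mask), x$min_total_count))
  invisible(x)
}

#' Classify striatal voxels from bias probabilities
#'
#' A voxel is matrix-like iff its matrix probability reaches the bias
#' threshold (default P >= 0.55), striosome-like iff the striosome
#' probability does, indeterminate in the band between (default
#' P in \[0.45, 0.55)); unseeded voxels pass through.
#'
#' @param prob a [compute_bias_probabilities()] result.
#' @param bias_threshold inclusive threshold, in (0.5, 1].
#' @param indeterminate_band lower/upper bounds of the indeterminate band
#'   (upper must equal `bias_threshold`).
#' @return a `compartment_parcellation` object with an integer label grid.
#' @export
classify_voxels <- function(prob, bias_threshold = 0.55,
                            indeterminate_band = c(0.45, 0.55)) {
  stopifnot(inherits(prob, "probability_maps"))
  if (bias_threshold <= 0.5 || bias_threshold > 1)
    stop("bias_threshold must lie in (0.5, 1]")
  labels <- array(PARC_LABELS[["outside"]], prob$grid$dim)
  labels[prob$striatal_mask] <- PARC_LABELS[["unseeded"]]
  f <- which(prob$seeded_mask)
  pm <- prob$p_matrix[f]
  lab <- ifelse(pm >= bias_threshold, PARC_LABELS[["matrix_like"]],
         ifelse(1 - pm >= bias_threshold, PARC_LABELS[["striosome_like"]],
                PARC_LABELS[["indeterminate"]]))
  labels[f] <- lab
  structure(list(labels = labels, bias_threshold = bias_threshold,
                 indeterminate_band = c(1 - bias_threshold, bias_threshold),
                 striatal_mask = prob$striatal_mask, grid = prob$grid),
            class = "compartment_parcellation")
}

#' @export
print.compartment_parcellation <- function(x, ...) {
  tab <- parcellation_table(x)
  cat(sprintf("<compartment_parcellation (P >= %.2f)>\n", x$bias_threshold))
  print(tab)
  invisible(x)
}

#' Label counts of a parcellation
#'
#' @param parc a `compartment_parcellation`.
#' @return named integer vector over the four striatal label classes.
#' @export
parcellation_table <- function(parc) {
  lab <- parc$labels[parc$striatal_mask]
  vapply(c("matrix_like", "striosome_like", "indeterminate", "unseeded"),
         function(n) sum(lab == PARC_LABELS[[n]]), integer(1))
}

parc_mask <- function(parc, class) {
  parc$labels == PARC_LABELS[[class]]
}

#' Per-nucleus compartment volumes, raw and normalized
#'
#' Raw volume is voxel count times voxel volume; normalized volume is the
#' plain ratio raw / eTIV (the intracranial-volume analog).
#'
#' @param parc a `compartment_parcellation`.
#' @param nuclei integer nucleus label grid (as in a `phantom_subject`).
#' @param etiv intracranial volume in mm^3 (> 0).
#' @return data.frame with one row per nucleus x label class.
#' @export
compartment_volumes <- function(parc, nuclei, etiv) {
  stopifnot(identical(dim(nuclei), dim(parc$labels)))
  if (!is.numeric(etiv) || etiv <= 0) stop("etiv must be positive")
  vv <- voxel_volume(parc$grid)
  nuc_groups <- list(caudate = c(1L, 2L), putamen = c(3L, 4L))
  classes <- c("matrix_like", "striosome_like", "indeterminate", "unseeded")
  rows <- list()
  for (nn in names(nuc_groups)) {
    in_nuc <- nuclei %in% nuc_groups[[nn]]
    for (cl in classes) {
      n <- sum(in_nuc & parc_mask(parc, cl))
      rows[[length(rows) + 1]] <- data.frame(
        nucleus = nn, compartment = cl, n_voxels = n,
        volume_mm3 = n * vv, normalized_volume = n * vv / etiv)
    }
    n <- sum(in_nuc)
    rows[[length(rows) + 1]] <- data.frame(
      nucleus = nn, compartment = "total", n_voxels = n,
      volume_mm3 = n * vv, normalized_volume = n * vv / etiv)
  }
  do.call(rbind, rows)
}

#' High-bias equal-volume compartment masks
#'
#' Selects, for each compartment, its most-biased voxels (bias strictly
#' above 0.5) up to `target_fraction` of the striatal volume; if one
#' compartment has fewer eligible voxels, the larger selection is truncated
#' (lowest-bias voxels removed) so the two masks always have equal volume.
#' Ties at the selection boundary break deterministically by (bias
#' descending, flat voxel index ascending).
#'
#' @param prob a `probability_maps`.
#' @param striatal_mask logical array (defaults to the one in `prob`).
#' @param target_fraction per-mask size target as a fraction of striatal
#'   volume, in (0, 0.5].
#' @return a `high_bias_masks` object with `matrix_mask` and
#'   `striosome_mask`.
#' @export
build_high_bias_masks <- function(prob, striatal_mask = prob$striatal_mask,
                                  target_fraction = 0.13) {
  stopifnot(inherits(prob, "probability_maps"))
  if (target_fraction <= 0 || target_fraction > 0.5)
    stop("target_fraction must lie in (0, 0.5]")
  n_target <- floor(target_fraction * sum(striatal_mask))
  pick <- function(p_map) {
    f <- which(prob$seeded_mask & striatal_mask & !is.na(p_map) & p_map > 0.5)
    f[order(-p_map[f], f)][seq_len(min(n_target, length(f)))]
  }
  fm <- pick(prob$p_matrix)
  fs <- pick(prob$p_striosome)
  n <- min(length(fm), length(fs))
  fm <- fm[seq_len(n)]; fs <- fs[seq_len(n)]
  mm <- array(FALSE, prob$grid$dim); mm[fm] <- TRUE
  sm <- array(FALSE, prob$grid$dim); sm[fs] <- TRUE
  structure(list(matrix_mask = mm, striosome_mask = sm,
                 target_fraction = target_fraction, n_each = n,
                 grid = prob$grid),
            class = "high_bias_masks")
}

#' @export
print.high_bias_masks <- function(x, ...) {
  cat(sprintf("<high_bias_masks: %d voxels each (target %.0f%% of striatum)>\n",
              x$n_each, 100 * x$target_fraction))
  invisible(x)
}

#' Volume of the largest connected cluster in a mask
#'
#' @param mask logical 3D array.
#' @param grid the [voxel_grid()] the mask lives on.
#' @param connectivity 6, 18 or 26 (default 26, the clustering convention
#'   used throughout the pipeline).
#' @return volume in mm^3 (0 for an empty mask).
#' @export
largest_cluster_volume <- function(mask, grid, connectivity = 26) {
  if (!any(mask)) return(0)
  sizes <- component_sizes(label_components(mask, connectivity))
  max(sizes) * voxel_volume(grid)
}

#' Mean voxel location relative to the nucleus centroid
#'
#' @param mask logical array, subset of `nucleus_mask`.
#' @param nucleus_mask logical array of the nucleus of origin.
#' @param grid the [voxel_grid()].
#' @return named numeric offset vector (mm); +y is rostral, -z is ventral.
#' @export
centroid_relative_locations <- function(mask, nucleus_mask, grid) {
  if (!any(mask)) stop("empty mask")
  if (any(mask & !nucleus_mask)) stop("mask must lie inside nucleus_mask")
  centroid <- colMeans(voxel_to_world(grid, mask_indices(nucleus_mask)))
  offs <- colMeans(voxel_to_world(grid, mask_indices(mask))) - centroid
  setNames(offs, c("x_mm", "y_mm_rostral", "z_mm_dorsal"))
}

#' Mean high-bias voxel location relative to each voxel's nucleus of origin
#'
#' Each mask voxel's offset is taken relative to the centroid of the
#' nucleus-hemisphere it belongs to (caudate or putamen, left or right),
#' then averaged over the mask; this isolates within-nucleus location bias
#' from between-nucleus position differences.
#'
#' @param mask logical array of striatal voxels.
#' @param nuclei integer nucleus label grid.
#' @param grid the [voxel_grid()].
#' @return named numeric offset vector (mm); +y is rostral, -z is ventral.
#' @export
nucleus_origin_offsets <- function(mask, nuclei, grid) {
  if (!any(mask)) stop("empty mask")
  offs <- matrix(NA_real_, 0, 3)
  for (lab in 1:4) {
    nm <- nuclei == lab
    m <- mask & nm
    if (!any(m)) next
    centroid <- colMeans(voxel_to_world(grid, mask_indices(nm)))
    offs <- rbind(offs, sweep(voxel_to_world(grid, mask_indices(m)), 2,
                              centroid))
  }
  setNames(colMeans(offs), c("x_mm", "y_mm_rostral", "z_mm_dorsal"))
}

#' Mean radial diffusivity over a mask
#'
#' Radial diffusivity at a voxel is the mean of the second and third tensor
#' eigenvalues.
#'
#' @param rd_field 4D array `dim x 3` of eigenvalue triples (descending).
#' @param mask logical array of voxels to average.
#' @return mean RD in mm^2/s.
#' @export
radial_diffusivity <- function(rd_field, mask) {
  stopifnot(length(dim(rd_field)) == 4L, dim(rd_field)[4] == 3L)
  f <- which(mask)
  if (!length(f)) stop("empty mask")
  V <- prod(dim(rd_field)[1:3])
  l1 <- rd_field[f]; l2 <- rd_field[f + V]; l3 <- rd_field[f + 2 * V]
  if (any(l1 < l2 - 1e-12) || any(l2 < l3 - 1e-12) || any(l3 < 0))
    stop("unordered eigenvalue triples")
  mean((l2 + l3) / 2)
}

# ---- per-subject parcellation pipeline -------------------------------------

#' Parcellate one phantom subject
#'
#' Runs the full per-subject pipeline: per-hemisphere classification-targets
#' tractography (seeding every striatal voxel, with the composite
#' matrix-favoring and striosome-favoring bait masks as targets and a
#' contra-hemispheric exclusion mask), bias probabilities, voxel
#' classification, high-bias masks and the per-subject measures table.
#'
#' @param phantom a `phantom_subject`.
#' @param params a [tracking_params()]; the per-hemisphere seed streams are
#'   spawned deterministically from `params$rng_seed`.
#' @param min_total_count classification floor.
#' @param bias_threshold classification threshold (P >= 0.55 by default).
#' @param target_fraction high-bias mask size target.
#' @return a `subject_parcellation` list: `prob`, `parcellation`,
#'   `high_bias`, `measures` (data.frame), and the inputs used.
#' @export
parcellate_subject <- function(phantom, params = tracking_params(),
                               min_total_count = 10L,
                               bias_threshold = 0.55,
                               target_fraction = 0.13) {
  domain <- phantom_domain(phantom)
  striatal <- striatal_mask_of(phantom$nuclei)
  hemi <- hemisphere_masks(phantom$grid)
  composite <- bait_composites(phantom)
  counts <- vector("list", 2)
  for (h in 1:2) {
    hm <- if (h == 1) hemi$left else hemi$right
    contra <- !hm
    pars_h <- params
    pars_h$rng_seed <- spawn_seed(params$rng_seed, h)
    counts[[h]] <- track_classification(
      domain, seed_mask = striatal & hm,
      target_masks = list(matrix = composite$matrix & hm,
                          striosome = composite$striosome & hm),
      exclusion_mask = contra, params = pars_h)
  }
  prob <- compute_bias_probabilities(counts, striatal, min_total_count)
  parc <- classify_voxels(prob, bias_threshold)
  hb <- build_high_bias_masks(prob, striatal, target_fraction)
  measures <- subject_measures(phantom, parc, hb)
  structure(list(subject_id = phantom$subject_id, prob = prob,
                 parcellation = parc, high_bias = hb, measures = measures,
                 counts = counts, params = params),
            class = "subject_parcellation")
}

#' Composite bait masks of a phantom
#'
#' @param phantom a `phantom_subject`.
#' @param leave_out optional region name excluded from its composite.
#' @return list with logical `matrix` and `striosome` composite masks.
#' @export
bait_composites <- function(phantom, leave_out = NULL) {
  atlas <- phantom$bait_atlas
  if (!is.null(leave_out) && !leave_out %in% names(atlas$regions))
    stop("unknown bait region: ", leave_out)
  comb <- function(comp) {
    nm <- names(atlas$affinity)[atlas$affinity == comp]
    nm <- setdiff(nm, leave_out)
    Reduce(`|`, atlas$regions[nm])
  }
  list(matrix = comb("matrix"), striosome = comb("striosome"))
}

#' Per-subject measures table
#'
#' One row per nucleus x measure: total and compartment-like volumes (raw
#' and eTIV-normalized), largest-cluster volumes, high-bias centroid
#' offsets, and radial diffusivity of nuclei and high-bias masks.
#'
#' @param phantom a `phantom_subject`.
#' @param parc its `compartment_parcellation`.
#' @param high_bias its `high_bias_masks`.
#' @return data.frame in long format (`subject_id`, `measure`, `value`).
#' @export
subject_measures <- function(phantom, parc, high_bias) {
  grid <- phantom$grid
  vols <- compartment_volumes(parc, phantom$nuclei, phantom$etiv)
  rows <- data.frame(measure = paste(vols$nucleus, vols$compartment,
                                     "volume_mm3", sep = "."),
                     value = vols$volume_mm3)
  rows <- rbind(rows,
                data.frame(measure = paste(vols$nucleus, vols$compartment,
                                           "normalized_volume", sep = "."),
                           value = vols$normalized_volume))
  for (cl in c("matrix_like", "striosome_like")) {
    rows <- rbind(rows, data.frame(
      measure = paste0(cl, ".largest_cluster_mm3"),
      value = largest_cluster_volume(parc_mask(parc, cl), grid)))
  }
  striatal <- striatal_mask_of(phantom$nuclei)
  for (cl in c("matrix", "striosome")) {
    hb <- high_bias[[paste0(cl, "_mask")]]
    if (any(hb)) {
      off <- nucleus_origin_offsets(hb, phantom$nuclei, grid)
      rows <- rbind(rows, data.frame(
        measure = paste0("high_bias_", cl, c(".x_mm", ".y_mm", ".z_mm")),
        value = unname(off)))
      rows <- rbind(rows, data.frame(
        measure = paste0("high_bias_", cl, ".rd"),
        value = radial_diffusivity(phantom$rd_field, hb)))
    }
  }
  for (nn in list(c("caudate", 1, 2), c("putamen", 3, 4))) {
    m <- phantom$nuclei %in% as.integer(nn[2:3])
    dim(m) <- grid$dim
    rows <- rbind(rows, data.frame(
      measure = paste0(nn[1], ".rd"),
      value = radial_diffusivity(phantom$rd_field, m)))
  }
  rows <- rbind(rows, data.frame(measure = "etiv_mm3", value = phantom$etiv))
  data.frame(subject_id = phantom$subject_id, rows, row.names = NULL)
}
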