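# Stage runners binding the modules into the end-to-end workflow:
# phantom/cohort generation -> per-subject parcellation -> cohort-level
# statistics. Each stage writes its outputs (NIfTI volumes + delimited
# tables) plus a run log, and is byte-reproducible from config + seed.

#' Generate and write a phantom cohort
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return the `phantom_cohort`, invisibly.
#' @export
run_phantom_stage <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  params <- config_phantom_params(cfg)
  spec <- do.call(cohort_spec,
                  utils::modifyList(cfg$cohort,
                                    list(rng_seed = spawn_seed(cfg$seed, 10))))
  cohort <- simulate_cohort(spec, params)
  base <- cohort$base
  grid <- base$grid
  write_nifti_volume(base$nuclei, grid, file.path(out_dir, "nuclei.nii"))
  write_nifti_volume(base$gt_compartment, grid,
                     file.path(out_dir, "gt_compartment.nii"))
  write_nifti_volume(base$rd_field, grid, file.path(out_dir, "rd.nii"))
  atlas_vol <- array(0L, grid$dim)
  for (j in seq_along(base$bait_atlas$regions))
    atlas_vol[base$bait_atlas$regions[[j]]] <- j
  write_nifti_volume(atlas_vol, grid, file.path(out_dir, "bait_atlas.nii"))
  write_tsv(data.frame(label = seq_along(base$bait_atlas$regions),
                       region = names(base$bait_atlas$regions),
                       affinity = unname(base$bait_atlas$affinity)),
            file.path(out_dir, "bait_legend.tsv"))
  for (s in cohort$subjects) {
    sd <- file.path(out_dir, s$subject_id)
    dir.create(sd, showWarnings = FALSE)
    write_nifti_volume(s$nuclei, grid, file.path(sd, "nuclei.nii"))
    write_nifti_volume(s$gt_compartment, grid,
                       file.path(sd, "gt_compartment.nii"))
  }
  write_tsv(cohort$manifest, file.path(out_dir, "manifest.tsv"))
  write_run_config(cfg, file.path(out_dir, "config.yaml"))
  write_run_log(out_dir, "phantom", cfg, cfg$seed,
                list(n_subjects = length(cohort$subjects)))
  invisible(cohort)
}

#' Parcellate one subject and write its maps and measures
#'
#' @param phantom a `phantom_subject`.
#' @param cfg a [run_config()].
#' @param out_dir output directory.
#' @return the `subject_parcellation`, invisibly.
#' @export
run_parcellation_stage <- function(phantom, cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  params <- config_tracking_params(cfg, spawn_seed(cfg$seed, 20))
  sp <- parcellate_subject(phantom, params,
                           min_total_count = cfg$parcellation$min_total_count,
                           bias_threshold = cfg$parcellation$bias_threshold,
                           target_fraction = cfg$parcellation$target_fraction)
  grid <- phantom$grid
  zero_na <- function(a) { a[is.na(a)] <- 0; a }
  write_nifti_volume(zero_na(sp$prob$p_matrix), grid,
                     file.path(out_dir, "p_matrix.nii"))
  write_nifti_volume(zero_na(sp$prob$p_striosome), grid,
                     file.path(out_dir, "p_striosome.nii"))
  write_nifti_volume(sp$parcellation$labels, grid,
                     file.path(out_dir, "labels.nii"))
  write_nifti_volume(sp$high_bias$matrix_mask, grid,
                     file.path(out_dir, "high_bias_matrix.nii"))
  write_nifti_volume(sp$high_bias$striosome_mask, grid,
                     file.path(out_dir, "high_bias_striosome.nii"))
  write_nifti_volume(striatal_mask_of(phantom$nuclei), grid,
                     file.path(out_dir, "striatal_mask.nii"))
  write_tsv(sp$measures, file.path(out_dir, "measures.tsv"))
  write_run_log(out_dir, "parcellate", cfg, params$rng_seed,
                list(subject_id = phantom$subject_id))
  invisible(sp)
}

#' Somatotopic-zone stage: N-1 parcellations and the zone report
#'
#' Runs the ten leave-one-bait-out parcellations for one subject, derives
#' the somatotopic zones, and writes them as a single integer-labelled
#' NIfTI with a legend table plus the per-zone compartment volume-ratio
#' report.
#'
#' @param phantom a `phantom_subject`.
#' @param cfg a [run_config()].
#' @param out_dir output directory.
#' @return list with `zones` and `report`, invisibly.
#' @export
run_zones_stage <- function(phantom, cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  params <- config_tracking_params(cfg, spawn_seed(cfg$seed, 20))
  sz <- subject_zones(phantom, params,
                      min_total_count = cfg$parcellation$min_total_count,
                      floor = cfg$zones$floor,
                      size_bound = cfg$zones$size_bound)
  parc <- classify_voxels(sz$full, cfg$parcellation$bias_threshold)
  report <- zone_report(parc, sz$zones, phantom$bait_atlas$affinity)
  zone_vol <- array(0L, phantom$grid$dim)
  for (j in seq_along(sz$zones$zones)) zone_vol[sz$zones$zones[[j]]] <- j
  write_nifti_volume(zone_vol, phantom$grid, file.path(out_dir, "zones.nii"))
  write_tsv(data.frame(label = seq_along(sz$zones$zones),
                       zone = names(sz$zones$zones),
                       dominant = unname(phantom$bait_atlas$affinity),
                       n_voxels = unname(sz$zones$sizes)),
            file.path(out_dir, "zone_legend.tsv"))
  write_tsv(report, file.path(out_dir, "zone_ratios.tsv"))
  write_run_log(out_dir, "zones", cfg, params$rng_seed,
                list(subject_id = phantom$subject_id))
  invisible(list(zones = sz$zones, report = report))
}

#' Cohort-level analysis: group statistics and permutation inference
#'
#' Parcellates every subject, runs the covariate-adjusted group comparisons
#' within the pre-declared test families (Benjamini-Hochberg corrected),
#' the voxelwise permutation test of the matrix-like probability maps
#' (hemispheres combined), and the severity association within the MDD
#' subset; writes a summary report.
#'
#' @param cohort a `phantom_cohort` from [simulate_cohort()] or
#'   [run_phantom_stage()].
#' @param cfg a [run_config()].
#' @param out_dir output directory.
#' @return list with `measures`, `group_stats`, `permutation`, `severity`,
#'   invisibly.
#' @export
run_cohort_stage <- function(cohort, cfg, out_dir) {
  stopifnot(inherits(cohort, "phantom_cohort"), inherits(cfg, "run_config"))
  manifest <- cohort$manifest
  if (is.null(manifest) || !nrow(manifest)) stop("empty manifest")
  if (any(table(manifest$group) < 2L) ||
      length(unique(manifest$group)) < 2L)
    stop("need at least 2 subjects per group")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)

  params <- config_tracking_params(cfg, spawn_seed(cfg$seed, 20))
  striatal <- striatal_mask_of(cohort$base$nuclei)
  f <- which(striatal)
  measures <- list()
  maps <- matrix(NA_real_, length(cohort$subjects), length(f))
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    sp <- parcellate_subject(s, params,
                             min_total_count =
                               cfg$parcellation$min_total_count,
                             bias_threshold = cfg$parcellation$bias_threshold,
                             target_fraction =
                               cfg$parcellation$target_fraction)
    measures[[i]] <- sp$measures
    pm <- soft_p_matrix(sp$prob)      # hemispheres combined in one map
    maps[i, ] <- pm[f]
  }
  measures <- do.call(rbind, measures)
  write_tsv(measures, file.path(out_dir, "measures.tsv"))

  fams <- mdd_test_families()
  stats_rows <- list()
  for (fam in names(fams)) {
    outs <- intersect(fams[[fam]], unique(measures$measure))
    if (!length(outs)) next
    if (fam == "severity_caudate") {
      res <- lapply(outs, function(o)
        severity_association(measures, manifest, o))
      p <- vapply(res, `[[`, numeric(1), "p")
      adj <- bh_adjust(p, fam)
      stats_rows[[fam]] <- data.frame(
        family = fam, outcome = outs,
        statistic = vapply(res, `[[`, numeric(1), "t"),
        effect = vapply(res, `[[`, numeric(1), "slope"),
        p = p, bh_adjusted = adj$bh_adjusted, discovery = adj$discovery)
    } else {
      res <- lapply(outs, function(o) group_compare(measures, manifest, o))
      p <- vapply(res, `[[`, numeric(1), "p")
      adj <- bh_adjust(p, fam)
      stats_rows[[fam]] <- data.frame(
        family = fam, outcome = outs,
        statistic = vapply(res, `[[`, numeric(1), "f"),
        effect = vapply(res, `[[`, numeric(1), "percent_difference"),
        p = p, bh_adjusted = adj$bh_adjusted, discovery = adj$discovery)
    }
  }
  group_stats <- do.call(rbind, c(stats_rows, list(make.row.names = FALSE)))
  write_tsv(group_stats, file.path(out_dir, "group_stats.tsv"))

  design <- manifest[, c("group", "study_id", "scanner_id", "age")]
  perm <- permutation_test(
    maps, striatal, cohort$base$grid, design, contrast = "group",
    covariates = c("study_id", "scanner_id", "age"),
    n_perm = cfg$inference$n_perm,
    variance_smoothing_mm = cfg$inference$variance_smoothing_mm,
    tfce = config_tfce_params(cfg), alpha = cfg$inference$alpha,
    rng_seed = spawn_seed(cfg$seed, 30))
  pmap <- perm$p_corrected
  pmap[is.na(pmap)] <- 1
  write_nifti_volume(pmap, cohort$base$grid,
                     file.path(out_dir, "p_corrected.nii"))
  if (nrow(perm$clusters))
    write_tsv(perm$clusters, file.path(out_dir, "clusters.tsv"))

  write_run_log(out_dir, "cohort", cfg, cfg$seed,
                list(n_subjects = nrow(manifest),
                     n_discoveries = sum(group_stats$discovery)))
  invisible(list(measures = measures, group_stats = group_stats,
                 permutation = perm, manifest = manifest))
}
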