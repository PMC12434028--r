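# Format plumbing: NIfTI volumes (RAS axis order with an explicit affine),
# delimited tables, the YAML run configuration, and machine-readable run
# logs with parameter echo, seeds and input checksums.

#' Write a volume as NIfTI
#'
#' Volumes are written uncompressed in right-anterior-superior axis order
#' with the grid's affine in both qform and sform, so that a fixed config +
#' seed reproduces output files byte-for-byte.
#'
#' @param vol 3D or 4D numeric/integer/logical array.
#' @param grid the [voxel_grid()] it lives on.
#' @param path output path (`.nii`).
#' @return the path, invisibly.
#' @export
write_nifti_volume <- function(vol, grid, path) {
  storage.mode(vol) <- if (is.integer(vol) || is.logical(vol)) "integer"
                       else "double"
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(grid$voxel_mm, 3)
  RNifti::qform(img) <- structure(grid$affine, code = 2L)
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume written by this package
#'
#' @param path `.nii` / `.nii.gz` path.
#' @return list with `data` (array) and `grid` (a [voxel_grid()]).
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  vx <- abs(aff[1, 1])
  grid <- voxel_grid(dim(img)[1:3], vx, origin = aff[1:3, 4])
  list(data = array(as.numeric(img), dim(img)), grid = grid)
}

#' Run configuration
#'
#' Collects every stage's parameters plus the global seed into one nested
#' list that round-trips losslessly through its YAML file representation.
#'
#' @param phantom named list of [phantom_config()] arguments.
#' @param cohort named list of [cohort_spec()] arguments.
#' @param tracking named list of [tracking_params()] arguments.
#' @param parcellation `min_total_count`, `bias_threshold`,
#'   `target_fraction`.
#' @param zones `size_bound` and optional `floor`.
#' @param inference `n_perm`, `variance_smoothing_mm`, `alpha`, TFCE
#'   settings.
#' @param seed global seed; per-stage substreams are spawned from it.
#' @return a `run_config` list.
#' @export
run_config <- function(phantom = list(), cohort = list(),
                       tracking = list(), parcellation = list(),
                       zones = list(), inference = list(), seed = 1L) {
  cfg <- list(
    phantom = utils::modifyList(unclass(phantom_config()), phantom),
    cohort = cohort,
    tracking = utils::modifyList(
      unclass(tracking_params())[c("curvature_threshold", "step_length_mm",
                                   "max_steps", "samples_per_seed_voxel",
                                   "curvature_retries", "symmetrize")],
      tracking),
    parcellation = utils::modifyList(
      list(min_total_count = 10L, bias_threshold = 0.55,
           target_fraction = 0.13), parcellation),
    zones = utils::modifyList(list(size_bound = 4), zones),
    inference = utils::modifyList(
      list(n_perm = 5000L, variance_smoothing_mm = 2, alpha = 0.05,
           height_exponent = 2, extent_exponent = 0.5, n_steps = 100L,
           connectivity = 26L), inference),
    seed = as.integer(seed))
  required <- c("dim", "voxel_mm", "striosome_fraction")
  missing <- setdiff(required, names(cfg$phantom))
  if (length(missing))
    stop("run_config is missing required phantom field(s): ",
         paste(missing, collapse = ", "))
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[c("phantom", "cohort", "tracking", "parcellation",
                            "zones", "inference", "seed")])
}

config_phantom_params <- function(cfg) {
  do.call(phantom_config, cfg$phantom)
}

config_tracking_params <- function(cfg, rng_seed) {
  do.call(tracking_params, c(cfg$tracking, list(rng_seed = rng_seed)))
}

config_tfce_params <- function(cfg) {
  tfce_params(height_exponent = cfg$inference$height_exponent,
              extent_exponent = cfg$inference$extent_exponent,
              n_steps = cfg$inference$n_steps,
              connectivity = cfg$inference$connectivity)
}

# run log: versions, seeds, parameters, output inventory with checksums
write_run_log <- function(out_dir, stage, cfg, seed, extra = list()) {
  files <- setdiff(list.files(out_dir, recursive = TRUE, full.names = TRUE),
                   file.path(out_dir, "run_log.json"))
  sums <- tools::md5sum(files)
  log <- c(list(stage = stage,
                package_version = as.character(packageVersion("striatparc")),
                r_version = paste(R.version$major, R.version$minor,
                                  sep = "."),
                seed = seed,
                config = unclass(cfg),
                files = as.list(setNames(unname(sums),
                                         basename(names(sums))))),
           extra)
  writeLines(jsonlite::toJSON(log, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(out_dir, "run_log.json"))
  invisible(log)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Probability maps from externally supplied NIfTI files
#'
#' Accepts voxelwise matrix-like / striosome-like probability maps in the
#' package's layout (NA or both-zero outside the seeded mask) and wraps
#' them as a `probability_maps` object so every downstream stage
#' (classification, volumes, high-bias masks, zones) applies unchanged.
#'
#' @param p_matrix_path,p_striosome_path NIfTI paths.
#' @param striatal_mask_path NIfTI path of the striatal mask (nonzero =
#'   striatal).
#' @return a `probability_maps` object.
#' @export
probability_maps_from_files <- function(p_matrix_path, p_striosome_path,
                                        striatal_mask_path) {
  pm <- read_nifti_volume(p_matrix_path)
  ps <- read_nifti_volume(p_striosome_path)
  sm <- read_nifti_volume(striatal_mask_path)
  if (!identical(dim(pm$data), dim(ps$data)) ||
      !identical(dim(pm$data), dim(sm$data)))
    stop("grid mismatch between probability and mask files")
  striatal <- sm$data != 0
  tot <- pm$data + ps$data
  seeded <- striatal & is.finite(tot) & tot > 0
  p_matrix <- array(NA_real_, dim(pm$data))
  p_striosome <- array(NA_real_, dim(pm$data))
  f <- which(seeded)
  p_matrix[f] <- pm$data[f] / tot[f]
  p_striosome[f] <- ps$data[f] / tot[f]
  scale <- 1e4                    # pseudo-counts for influence differencing
  structure(list(p_matrix = p_matrix, p_striosome = p_striosome,
                 seeded_mask = seeded, striatal_mask = striatal,
                 matrix_counts = array(ifelse(is.na(p_matrix), 0,
                                              p_matrix) * scale,
                                       dim(pm$data)),
                 striosome_counts = array(ifelse(is.na(p_striosome), 0,
                                                 p_striosome) * scale,
                                          dim(pm$data)),
                 min_total_count = 1L, grid = pm$grid),
            class = "probability_maps")
}
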