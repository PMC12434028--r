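# Simulated MDD / healthy-control cohorts around a base phantom.
#
# Healthy controls are jittered copies of the base phantom (lognormal noise
# on eTIV and nucleus volume, realized as mirror-paired boundary
# erosion/dilation so hemispheric geometry stays symmetric). MDD subjects
# additionally receive (a) a putamen volume scaling and (b) a
# connectivity-bias shift: a fixed rostral-putamen set of matrix ground-truth
# voxels whose orientation-field bias is flipped toward striosome-favoring
# bait regions (or pushed into the indeterminate band), applied per subject
# with a membership probability. A severity gradient flips caudate
# striosome-bias voxels toward matrix bias in proportion to the subject's
# severity category.

#' Cohort specification
#'
#' Effect defaults are the generator's study conditions: an MDD putamen
#' matrix-like volume shift of -8.2% and striosome-like shift of +15%
#' (connectivity-bias flips), a putamen volume scale of 0.917 (raw volume
#' 8.3% smaller), an eTIV scale of 0.960, and a caudate severity gradient
#' that flips 10% of caudate striosome-bias voxels toward matrix bias per
#' severity category step.
#'
#' @param n_mdd number of MDD subjects (>= 1).
#' @param match_ratio healthy controls generated per MDD subject.
#' @param n_hc total controls; must equal `n_mdd * match_ratio` (defaulted).
#' @param effects list with `putamen_matrix` and `putamen_striosome`
#'   multiplicative compartment-like volume shifts for the MDD group.
#' @param severity_gradient caudate striosome-to-matrix flip fraction per
#'   severity category step.
#' @param hemispheric_asymmetry optional additional right-caudate
#'   striosome-to-matrix flip fraction in MDD.
#' @param putamen_scale MDD putamen volume factor.
#' @param mdd_etiv_scale MDD eTIV factor.
#' @param jitter_sigma lognormal sigma of subject-level eTIV / nucleus
#'   volume jitter.
#' @param membership_prob per-subject probability that an effect voxel is
#'   shifted.
#' @param severity_scale severity scale used for MDD scores.
#' @param rng_seed integer seed; identical seeds give identical cohorts.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_mdd = 20L, match_ratio = 1L, n_hc = NULL,
                        effects = list(putamen_matrix = -0.082,
                                       putamen_striosome = 0.15),
                        severity_gradient = 0.10,
                        hemispheric_asymmetry = 0,
                        putamen_scale = 0.917,
                        mdd_etiv_scale = 0.960,
                        jitter_sigma = 0.03,
                        membership_prob = 0.9,
                        severity_scale = "Hamilton",
                        rng_seed = 1L) {
  n_mdd <- as.integer(n_mdd); match_ratio <- as.integer(match_ratio)
  if (is.null(n_hc)) n_hc <- n_mdd * match_ratio
  n_hc <- as.integer(n_hc)
  if (n_mdd < 1L || n_hc < 1L) stop("subject counts must be >= 1")
  if (n_hc != n_mdd * match_ratio)
    stop("n_hc must equal n_mdd * match_ratio")
  if (!all(is.finite(unlist(effects)))) stop("effects must be finite")
  structure(list(n_mdd = n_mdd, n_hc = n_hc, match_ratio = match_ratio,
                 effects = effects, severity_gradient = severity_gradient,
                 hemispheric_asymmetry = hemispheric_asymmetry,
                 putamen_scale = putamen_scale,
                 mdd_etiv_scale = mdd_etiv_scale,
                 jitter_sigma = jitter_sigma,
                 membership_prob = membership_prob,
                 severity_scale = severity_scale,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

shift3 <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(FALSE, d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  fx <- sx - dx; fy <- sy - dy; fz <- sz - dz
  okx <- fx >= 1 & fx <= d[1]; oky <- fy >= 1 & fy <= d[2]
  okz <- fz >= 1 & fz <= d[3]
  out[sx[okx], sy[oky], sz[okz]] <- a[fx[okx], fy[oky], fz[okz]]
  out
}

has_outside_neighbour <- function(mask) {
  outside <- !mask
  touch <- array(FALSE, dim(mask))
  for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                 c(0,0,1), c(0,0,-1))) {
    touch <- touch | shift3(outside, o[1], o[2], o[3])
  }
  # voxels on the grid edge also border the outside
  d <- dim(mask)
  touch[c(1, d[1]), , ] <- TRUE
  touch[, c(1, d[2]), ] <- TRUE
  touch[, , c(1, d[3])] <- TRUE
  mask & touch
}

adjacent_background <- function(mask, background) {
  touch <- array(FALSE, dim(mask))
  for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                 c(0,0,1), c(0,0,-1))) {
    touch <- touch | shift3(mask, o[1], o[2], o[3])
  }
  background & touch
}

mirror_flat <- function(flat, d) {
  i <- ((flat - 1) %% d[1]) + 1
  rest <- (flat - 1) %/% d[1]
  (d[1] + 1 - i) + d[1] * rest
}

# mirror-paired boundary erosion (delta < 0) or dilation (delta > 0) of one
# nucleus, operating on the right-hemisphere half and mirroring to the left
adjust_nucleus_volume <- function(nuclei, gt, right_label, left_label,
                                  delta_per_hemi) {
  d <- dim(nuclei)
  done <- 0L
  guard <- 0L
  while (done < abs(delta_per_hemi) && guard < 50L) {
    guard <- guard + 1L
    right <- nuclei == right_label
    if (delta_per_hemi < 0) {
      cand <- which(has_outside_neighbour(right))
    } else {
      cand <- which(adjacent_background(right, nuclei == 0L))
      cand <- cand[((cand - 1) %% d[1]) + 1 > d[1] / 2]
    }
    if (!length(cand)) break
    take <- cand[sample.int(length(cand),
                            min(length(cand), abs(delta_per_hemi) - done))]
    pair <- c(take, mirror_flat(take, d))
    if (delta_per_hemi < 0) {
      nuclei[pair] <- 0L
      gt[pair] <- 0L
    } else {
      nuclei[take] <- right_label
      nuclei[mirror_flat(take, d)] <- left_label
      gt[pair] <- 1L                      # new tissue defaults to matrix
    }
    done <- done + length(take)
  }
  list(nuclei = nuclei, gt = gt)
}

make_rd_field <- function(striatal, lam, noise_level) {
  d <- dim(striatal)
  n <- sum(striatal)
  noise <- matrix(1 + noise_level * (2 * runif(n * 3) - 1), n, 3)
  vals <- sweep(noise, 2, lam, `*`)
  vals <- t(apply(vals, 1, sort, decreasing = TRUE))
  rd <- array(0, c(d, 3))
  for (k in 1:3) {
    slab <- array(0, d)
    slab[striatal] <- vals[, k]
    rd[, , , k] <- slab
  }
  rd
}

# rostral-first ordering (y descending, then flat index) of gt voxels
ranked_gt_voxels <- function(phantom, nucleus_labels, gt_value,
                             right_only = FALSE) {
  d <- phantom$grid$dim
  sel <- which(phantom$nuclei %in% nucleus_labels &
                 phantom$gt_compartment == gt_value)
  if (right_only) sel <- sel[((sel - 1) %% d[1]) + 1 > d[1] / 2]
  y <- ((sel - 1) %/% d[1]) %% d[2] + 1
  sel[order(-y, sel)]
}

#' Simulate an MDD / healthy-control phantom cohort
#'
#' @param spec a [cohort_spec()].
#' @param params a [phantom_config()] for the shared base phantom.
#' @return a `phantom_cohort`: `subjects` (list of `phantom_subject`),
#'   `manifest` (data.frame), `base` phantom, and `injected` ground-truth
#'   effect masks (`putamen`, `caudate`).
#' @export
simulate_cohort <- function(spec, params = phantom_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  base <- build_phantom(params, rng_seed = spawn_seed(spec$rng_seed, 0),
                        subject_id = "base")
  set.seed(spawn_seed(spec$rng_seed, 1))
  d <- params$dim

  # fixed effect voxel sets, rostral putamen / rostral caudate
  n_s_put <- sum(base$nuclei %in% c(3L, 4L) & base$gt_compartment == 2L)
  n_m_put <- sum(base$nuclei %in% c(3L, 4L) & base$gt_compartment == 1L)
  mp <- max(spec$membership_prob, 1e-9)
  n_flip <- round(abs(spec$effects$putamen_striosome) * n_s_put / mp)
  n_indet <- max(0, round(abs(spec$effects$putamen_matrix) * n_m_put / mp) -
                   n_flip)
  put_matrix_ranked <- ranked_gt_voxels(base, c(3L, 4L), 1L)
  flip_set <- put_matrix_ranked[seq_len(min(n_flip, length(put_matrix_ranked)))]
  indet_set <- put_matrix_ranked[seq_len(min(n_flip + n_indet,
                                             length(put_matrix_ranked)))]
  indet_set <- setdiff(indet_set, flip_set)
  caud_strio_ranked <- ranked_gt_voxels(base, c(1L, 2L), 2L)
  caud_strio_right <- ranked_gt_voxels(base, c(1L, 2L), 2L, right_only = TRUE)

  injected_put <- array(FALSE, d); injected_put[c(flip_set, indet_set)] <- TRUE
  injected_caud <- array(FALSE, d)
  injected_caud[caud_strio_ranked] <- TRUE

  subjects <- list()
  manifest <- list()
  studies <- c("studyA", "studyB")
  scanners <- c("scanner1", "scanner2")
  sev_min <- c(Hamilton = 8, RCADS = 18, Achenbach = 70)[[spec$severity_scale]]
  sev_max <- c(Hamilton = 30, RCADS = 30, Achenbach = 100)[[spec$severity_scale]]

  make_subject <- function(id, group, study, scanner, age, severity) {
    p <- base
    p$subject_id <- id
    p$group <- group
    p$study_id <- study
    p$scanner_id <- scanner
    p$age <- age
    etiv_f <- rlnorm(1, 0, spec$jitter_sigma)
    if (group == "MDD") etiv_f <- etiv_f * spec$mdd_etiv_scale
    p$etiv <- params$etiv_mm3 * etiv_f
    for (nuc in list(list(right = 2L, left = 1L, scale = 1),
                     list(right = 4L, left = 3L,
                          scale = if (group == "MDD") spec$putamen_scale
                                  else 1))) {
      f <- rlnorm(1, 0, spec$jitter_sigma) * nuc$scale
      n_hemi <- sum(p$nuclei == nuc$right)
      delta <- round(n_hemi * (f - 1))
      adj <- adjust_nucleus_volume(p$nuclei, p$gt_compartment, nuc$right,
                                   nuc$left, delta)
      p$nuclei <- adj$nuclei
      p$gt_compartment <- adj$gt
    }
    overrides <- list()
    striatal_now <- which(striatal_mask_of(p$nuclei))
    if (group == "MDD") {
      keep <- function(set) {
        set <- intersect(set, striatal_now)
        set[runif(length(set)) < spec$membership_prob]
      }
      fs <- keep(flip_set)
      is_ <- keep(indet_set)
      if (length(fs))
        overrides[[length(overrides) + 1]] <-
          list(idx = fs, type = "flip_to_striosome")
      if (length(is_))
        overrides[[length(overrides) + 1]] <-
          list(idx = is_, type = "indeterminate")
      p$severity_score <- severity
      p$severity_scale <- spec$severity_scale
      cat_idx <- severity_category_index(
        severity_to_category(spec$severity_scale, severity))
      n_sev <- round(spec$severity_gradient * max(0, cat_idx - 1) *
                       length(caud_strio_ranked))
      sev_set <- intersect(caud_strio_ranked[seq_len(min(n_sev,
                             length(caud_strio_ranked)))], striatal_now)
      if (length(sev_set))
        overrides[[length(overrides) + 1]] <-
          list(idx = sev_set, type = "flip_to_matrix")
      if (spec$hemispheric_asymmetry > 0) {
        n_asym <- round(spec$hemispheric_asymmetry * length(caud_strio_right))
        asym_set <- intersect(caud_strio_right[seq_len(n_asym)], striatal_now)
        if (length(asym_set))
          overrides[[length(overrides) + 1]] <-
            list(idx = asym_set, type = "flip_to_matrix")
      }
    }
    p$weight_overrides <- overrides
    p$rd_field <- make_rd_field(striatal_mask_of(p$nuclei),
                                params$rd_eigenvalues, params$rd_noise)
    p
  }

  k <- 0L
  for (i in seq_len(spec$n_mdd)) {
    study <- studies[(i - 1) %% length(studies) + 1]
    scanner <- sample(scanners, 1)
    age <- round(runif(1, 18, 45))
    severity <- sample(seq(sev_min, sev_max), 1)
    k <- k + 1L
    id <- sprintf("S%03d", k)
    subjects[[id]] <- make_subject(id, "MDD", study, scanner, age, severity)
    manifest[[id]] <- data.frame(subject_id = id, group = "MDD",
                                 severity_scale = spec$severity_scale,
                                 severity_score = severity,
                                 severity_category = severity_to_category(
                                   spec$severity_scale, severity),
                                 etiv = subjects[[id]]$etiv,
                                 scanner_id = scanner, study_id = study,
                                 age = age, matched_to = NA_character_)
    for (j in seq_len(spec$match_ratio)) {
      k <- k + 1L
      hid <- sprintf("S%03d", k)
      hage <- age + round(rnorm(1, 0, 1.5))
      subjects[[hid]] <- make_subject(hid, "HC", study, scanner, hage,
                                      NA_real_)
      manifest[[hid]] <- data.frame(subject_id = hid, group = "HC",
                                    severity_scale = NA_character_,
                                    severity_score = NA_real_,
                                    severity_category = NA_character_,
                                    etiv = subjects[[hid]]$etiv,
                                    scanner_id = scanner, study_id = study,
                                    age = hage, matched_to = id)
    }
  }
  structure(list(subjects = subjects,
                 manifest = do.call(rbind, c(manifest,
                                             list(make.row.names = FALSE))),
                 base = base,
                 injected = list(putamen = injected_put,
                                 caudate = injected_caud),
                 spec = spec, params = params),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort: %d MDD + %d HC on a %s grid>\n",
              x$spec$n_mdd, x$spec$n_hc,
              paste(x$params$dim, collapse = "x")))
  invisible(x)
}
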