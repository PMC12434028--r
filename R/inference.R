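# Group-level statistics: covariate-adjusted ANOVAs with Benjamini-Hochberg
# family correction, and voxelwise permutation inference with Freedman-Lane
# covariate residualization, Gaussian variance smoothing and threshold-free
# cluster enhancement, FWE-corrected by the max-statistic null distribution.

#' Covariate-adjusted group comparison of one measure
#'
#' Linear-model F-test of the group indicator adjusting for covariates of no
#' interest; reports the effect direction and the percent difference of the
#' covariate-adjusted group means.
#'
#' @param measures long measures table (`subject_id`, `measure`, `value`),
#'   e.g. rows of [subject_measures()].
#' @param manifest cohort manifest with `subject_id`, `group`, and the
#'   covariate columns.
#' @param outcome measure name to test.
#' @param covariates covariate column names (categorical ones are expanded
#'   to indicators).
#' @return list: `f`, `p`, `df`, `percent_difference` (MDD vs HC, of
#'   adjusted means), `direction`, `adjusted_means`, `n`.
#' @export
group_compare <- function(measures, manifest, outcome,
                          covariates = c("study_id", "scanner_id", "age")) {
  dat <- merge(measures[measures$measure == outcome,
                        c("subject_id", "value")],
               manifest, by = "subject_id")
  if (!nrow(dat)) stop("outcome not found in measures: ", outcome)
  dat$group <- factor(dat$group)
  if (nlevels(dat$group) != 2L || any(table(dat$group) < 2L))
    stop("need at least 2 subjects in each of two groups")
  covariates <- covariates[vapply(covariates, function(cv)
    length(unique(dat[[cv]])) > 1L, logical(1))]
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  full_fml <- stats::as.formula(paste("value ~ group +", rhs))
  red_fml <- stats::as.formula(paste("value ~", rhs))
  mm <- model.matrix(full_fml, dat)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  full <- lm(full_fml, dat)
  if (sd(stats::residuals(full)) < .Machine$double.eps^0.5 &&
      sd(dat$value) < .Machine$double.eps^0.5)
    stop("outcome is constant across subjects (zero residual variance)")
  red <- lm(red_fml, dat)
  an <- anova(red, full)
  f <- an$F[2]; p <- an$`Pr(>F)`[2]
  # adjusted means: average prediction over all subjects with group forced
  adj <- vapply(levels(dat$group), function(g) {
    nd <- dat; nd$group <- factor(g, levels = levels(dat$group))
    mean(stats::predict(full, newdata = nd))
  }, numeric(1))
  ref <- if ("HC" %in% names(adj)) "HC" else names(adj)[1]
  other <- setdiff(names(adj), ref)[1]
  pct <- 100 * (adj[[other]] - adj[[ref]]) / adj[[ref]]
  list(outcome = outcome, f = f, p = p,
       df = c(an$Df[2], an$Res.Df[2]),
       percent_difference = pct,
       direction = if (pct < 0) "lower" else if (pct > 0) "higher" else "equal",
       adjusted_means = adj, n = nrow(dat))
}

#' Severity association of a measure within the MDD subset
#'
#' @inheritParams group_compare
#' @return list with `slope`, `t`, `p`, `n`.
#' @export
severity_association <- function(measures, manifest, outcome,
                                 covariates = c("study_id", "scanner_id",
                                                "age")) {
  mdd <- manifest[manifest$group == "MDD" &
                    is.finite(manifest$severity_score), ]
  dat <- merge(measures[measures$measure == outcome,
                        c("subject_id", "value")], mdd, by = "subject_id")
  if (nrow(dat) < 4L) stop("need at least 4 MDD subjects with severity")
  covariates <- covariates[vapply(covariates, function(cv)
    length(unique(dat[[cv]])) > 1L, logical(1))]
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  fit <- lm(stats::as.formula(paste("value ~ severity_score +", rhs)), dat)
  co <- summary(fit)$coefficients["severity_score", ]
  list(outcome = outcome, slope = unname(co[1]), t = unname(co[3]),
       p = unname(co[4]), n = nrow(dat))
}

#' Benjamini-Hochberg adjustment within a named test family
#'
#' Step-up Benjamini-Hochberg on the raw p-values of one pre-declared
#' family, with discovery flags at q = 0.05.
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @param family family label carried into the output.
#' @param q discovery threshold on adjusted values.
#' @return data.frame (`family`, `p`, `bh_adjusted`, `discovery`).
#' @export
bh_adjust <- function(p_values, family = "family", q = 0.05) {
  if (!length(p_values)) stop("empty test family")
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  adj <- p.adjust(p_values, method = "BH")
  data.frame(family = family, p = p_values, bh_adjusted = adj,
             discovery = adj <= q)
}

# the pre-declared test families for the cohort-level report
mdd_test_families <- function() {
  list(
    nuclei_size = c("caudate.total.normalized_volume",
                    "putamen.total.normalized_volume"),
    nuclei_rd = c("caudate.rd", "putamen.rd"),
    compartment_volumes = c("caudate.matrix_like.normalized_volume",
                            "caudate.striosome_like.normalized_volume",
                            "putamen.matrix_like.normalized_volume",
                            "putamen.striosome_like.normalized_volume"),
    high_bias_rd = c("high_bias_matrix.rd", "high_bias_striosome.rd"),
    severity_caudate = c("caudate.matrix_like.normalized_volume",
                         "caudate.striosome_like.normalized_volume")
  )
}

# ---- TFCE ------------------------------------------------------------------

#' TFCE parameters
#'
#' @param height_exponent H (default 2).
#' @param extent_exponent E (default 0.5).
#' @param dh integration step; default: statistic range / `n_steps`.
#' @param n_steps integration steps used when `dh` is NULL.
#' @param connectivity cluster connectivity (6, 18, 26).
#' @return a `tfce_params` list.
#' @export
tfce_params <- function(height_exponent = 2, extent_exponent = 0.5,
                        dh = NULL, n_steps = 100L, connectivity = 26) {
  stopifnot(height_exponent >= 0, extent_exponent >= 0,
            is.null(dh) || dh > 0, n_steps >= 1)
  structure(list(H = height_exponent, E = extent_exponent, dh = dh,
                 n_steps = as.integer(n_steps),
                 connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

mask_adjacency <- function(dim, mask_flat, connectivity) {
  mask_adjacency_cpp(as.integer(dim), as.integer(mask_flat - 1L),
                     as.integer(connectivity))
}

tfce_signed_vec <- function(stat, adj, params) {
  out <- numeric(length(stat))
  for (sgn in c(1, -1)) {
    s <- sgn * stat
    s[s < 0] <- 0
    mx <- max(s)
    if (mx <= 0) next
    dh <- params$dh %||% (mx / params$n_steps)
    out <- out + sgn * tfce_masked_cpp(s, adj$ptr, adj$idx,
                                       params$E, params$H, dh)
  }
  out
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' Per voxel, numerically integrates `extent(h)^E * h^H dh` over thresholds
#' h from 0 to the voxel's statistic, where `extent(h)` is the size (voxel
#' count) of the connected component containing the voxel at threshold h.
#' Negative statistics are handled by enhancing the negated map separately
#' (the result keeps their sign).
#'
#' @param stat_map 3D numeric array (finite on the mask).
#' @param mask logical array.
#' @param params a [tfce_params()].
#' @return 3D array of enhanced values (0 off the mask).
#' @export
tfce <- function(stat_map, mask, params = tfce_params()) {
  stopifnot(identical(dim(stat_map), dim(mask)))
  f <- which(mask)
  if (any(!is.finite(stat_map[f]))) stop("non-finite statistic values")
  adj <- mask_adjacency(dim(mask), f, params$connectivity)
  out <- array(0, dim(mask))
  out[f] <- tfce_signed_vec(stat_map[f], adj, params)
  out
}

# ---- permutation inference -------------------------------------------------

# Gaussian smoothing operator over mask voxels (rows normalized); sigma mm
smoothing_operator <- function(coords, sigma_mm, cutoff = 3) {
  if (sigma_mm <= 0) return(NULL)
  n <- nrow(coords)
  d2 <- as.matrix(stats::dist(coords))^2
  W <- exp(-d2 / (2 * sigma_mm^2))
  W[d2 > (cutoff * sigma_mm)^2] <- 0
  W / rowSums(W)
}

#' Enumerate all distinct two-group label permutations
#'
#' Returns a permutation matrix (one row permutation per distinct
#' assignment of the group labels), suitable for the `perms` argument of
#' [permutation_test()]; the first row is the identity.
#'
#' @param group two-level factor or character vector.
#' @return integer matrix, `choose(n, n_A)` rows by `n` columns.
#' @export
all_group_permutations <- function(group) {
  group <- factor(group)
  stopifnot(nlevels(group) == 2L)
  n <- length(group)
  pos_a <- which(group == levels(group)[1])
  combos <- utils::combn(n, length(pos_a))
  pos_b <- setdiff(seq_len(n), pos_a)
  perms <- t(apply(combos, 2, function(s) {
    p <- integer(n)
    p[pos_a] <- s
    p[pos_b] <- setdiff(seq_len(n), s)
    p
  }))
  first <- which(apply(perms, 1, function(p) all(p == seq_len(n))))
  perms[c(first, setdiff(seq_len(nrow(perms)), first)), , drop = FALSE]
}

#' Voxelwise permutation inference with variance smoothing and TFCE
#'
#' Nuisance covariates are removed by Freedman-Lane residualization (the
#' reduced-model residuals are permuted and the reduced fit added back);
#' each permutation's voxelwise t-map uses a Gaussian-smoothed variance
#' image, is TFCE-enhanced, and contributes its maximum |enhanced| value to
#' the null distribution. The FWE-corrected p at a voxel is the fraction of
#' permutations (the identity included) whose maximum reaches that voxel's
#' observed enhanced value.
#'
#' @param maps n x V matrix of subject map values over the mask voxels.
#' @param mask logical 3D array with V TRUE voxels.
#' @param grid the [voxel_grid()] of the mask.
#' @param design data.frame with the contrast column and covariates, rows
#'   aligned with `maps`.
#' @param contrast name of the two-level group column tested.
#' @param covariates covariate column names (may be empty).
#' @param n_perm number of permutations (identity included).
#' @param perms optional explicit permutation matrix (rows = permutations),
#'   e.g. from [all_group_permutations()]; overrides `n_perm`.
#' @param variance_smoothing_mm Gaussian sigma (mm) for the variance image;
#'   0 disables smoothing.
#' @param tfce a [tfce_params()].
#' @param alpha significance level for cluster descriptors.
#' @param rng_seed integer seed.
#' @return a `permutation_result`: `p_corrected` (3D array, NA off mask),
#'   `t_observed`, `enhanced_observed`, `max_null`, `clusters`, `n_perm`.
#' @export
permutation_test <- function(maps, mask, grid, design, contrast = "group",
                             covariates = character(),
                             n_perm = 5000L, perms = NULL,
                             variance_smoothing_mm = 2,
                             tfce = tfce_params(), alpha = 0.05,
                             rng_seed = 1L) {
  stopifnot(is.matrix(maps), sum(mask) == ncol(maps))
  n <- nrow(maps)
  # below 8 subjects only an explicit (e.g. exhaustive) permutation set is
  # accepted: random subsets of so few permutations are meaningless
  if (n < 8L && is.null(perms)) stop("need at least 8 subjects")
  g <- factor(design[[contrast]])
  if (nlevels(g) != 2L)
    stop("contrast is not estimable: ", contrast,
         " must have exactly 2 levels")
  covariates <- covariates[vapply(covariates, function(cv)
    length(unique(design[[cv]])) > 1L, logical(1))]
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  Z <- model.matrix(stats::as.formula(paste("~", rhs)), design)
  x <- as.numeric(g == levels(g)[2])
  M <- cbind(Z, contrast = x)
  if (qr(M)$rank < ncol(M))
    stop("contrast is not estimable after covariate expansion")

  # Freedman-Lane: reduced-model fit and residuals
  qz <- qr(Z)
  fitted_red <- qr.fitted(qz, maps)
  resid_red <- maps - fitted_red

  if (is.null(perms)) {
    if (n_perm < 100L)
      warning("n_perm < 100: corrected p-values are coarse")
    set.seed(rng_seed)
    perms <- rbind(seq_len(n),
                   t(replicate(n_perm - 1L, sample.int(n))))
  }
  n_perm <- nrow(perms)

  MtM_inv <- solve(crossprod(M))
  proj <- MtM_inv %*% t(M)                  # p x n coefficient extractor
  cvec <- proj[ncol(M), ]                   # contrast coefficient row
  gxx <- MtM_inv[ncol(M), ncol(M)]
  hat <- M %*% proj
  dof <- n - ncol(M)

  f <- which(mask)
  coords <- voxel_to_world(grid, mask_indices(mask))
  W <- smoothing_operator(coords, variance_smoothing_mm)
  adj <- mask_adjacency(dim(mask), f, tfce$connectivity)

  t_of <- function(Y) {
    beta <- drop(cvec %*% Y)
    res <- Y - hat %*% Y
    s2 <- colSums(res^2) / dof
    if (!is.null(W)) s2 <- drop(W %*% s2)
    beta / sqrt(pmax(gxx * s2, .Machine$double.eps))
  }

  max_null <- numeric(n_perm)
  enh_obs <- NULL
  t_obs <- NULL
  for (j in seq_len(n_perm)) {
    Yj <- fitted_red + resid_red[perms[j, ], , drop = FALSE]
    tj <- t_of(Yj)
    ej <- tfce_signed_vec(tj, adj, tfce)
    if (j == 1L) { t_obs <- tj; enh_obs <- ej }
    max_null[j] <- max(abs(ej))
  }
  p_vec <- vapply(abs(enh_obs), function(e)
    mean(max_null >= e - 1e-12), numeric(1))
  p_map <- array(NA_real_, dim(mask))
  p_map[f] <- p_vec
  t_map <- array(NA_real_, dim(mask))
  t_map[f] <- t_obs
  e_map <- array(NA_real_, dim(mask))
  e_map[f] <- enh_obs
  clusters <- cluster_descriptors(p_map, alpha, grid,
                                  connectivity = tfce$connectivity,
                                  sign_map = e_map)
  structure(list(p_corrected = p_map, t_observed = t_map,
                 enhanced_observed = e_map, max_null = max_null,
                 clusters = clusters, n_perm = n_perm, alpha = alpha,
                 contrast = contrast),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  nsig <- sum(x$p_corrected <= x$alpha, na.rm = TRUE)
  cat(sprintf("<permutation_result: %d permutations, %d voxels p < %.2f>\n",
              x$n_perm, nsig, x$alpha))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Significant-cluster descriptors of a corrected p-map
#'
#' Connected components of `p <= alpha` (the exact-calibration convention for discrete permutation p-values), each with its center of gravity in
#' world mm and its volume in mm^3, sorted by volume descending.
#'
#' @param p_map 3D array of corrected p-values (NA outside the mask).
#' @param alpha significance level.
#' @param grid the [voxel_grid()].
#' @param connectivity cluster connectivity.
#' @param sign_map optional statistic map used to report each cluster's
#'   effect direction.
#' @return data.frame (`cluster`, `n_voxels`, `volume_mm3`, `cog_x/y/z_mm`,
#'   `direction`); zero rows when nothing is significant.
#' @export
cluster_descriptors <- function(p_map, alpha, grid, connectivity = 26,
                                sign_map = NULL) {
  sig <- !is.na(p_map) & p_map <= alpha
  empty <- data.frame(cluster = integer(), n_voxels = integer(),
                      volume_mm3 = numeric(), cog_x_mm = numeric(),
                      cog_y_mm = numeric(), cog_z_mm = numeric(),
                      direction = character())
  if (!any(sig)) return(empty)
  lab <- label_components(sig, connectivity)
  ids <- sort(unique(lab[lab > 0]))
  rows <- lapply(ids, function(i) {
    m <- lab == i
    cog <- colMeans(voxel_to_world(grid, mask_indices(m)))
    dir <- if (is.null(sign_map)) NA_character_
           else if (mean(sign_map[m]) > 0) "positive" else "negative"
    data.frame(cluster = i, n_voxels = sum(m),
               volume_mm3 = sum(m) * voxel_volume(grid),
               cog_x_mm = cog[1], cog_y_mm = cog[2], cog_z_mm = cog[3],
               direction = dir)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$volume_mm3), , drop = FALSE]
  out$cluster <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
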