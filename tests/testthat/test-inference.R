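# Group statistics, BH correction, TFCE, permutation inference and
# cluster descriptors.

make_measures <- function(values, ids) {
  data.frame(subject_id = ids, measure = "vol", value = values)
}

make_manifest <- function(ids, group, age = NULL, study = "studyA",
                          scanner = "scanner1") {
  data.frame(subject_id = ids, group = group,
             age = age %||% rep(30, length(ids)),
             study_id = study, scanner_id = scanner,
             severity_score = NA_real_)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("group comparison: null, signal, and degenerate inputs", {
  ids <- sprintf("S%02d", 1:12)
  grp <- rep(c("HC", "MDD"), each = 6)
  vals <- rep(c(10, 11, 12, 10, 11, 12), 2)      # identical groups
  gc <- group_compare(make_measures(vals, ids), make_manifest(ids, grp),
                      "vol", covariates = character())
  expect_equal(gc$percent_difference, 0)
  expect_gt(gc$p, 0.99)
  # injected 20% reduction is recovered in sign and size
  set.seed(1)
  vals2 <- c(rnorm(6, 100, 2), rnorm(6, 80, 2))
  gc2 <- group_compare(make_measures(vals2, ids), make_manifest(ids, grp),
                       "vol", covariates = character())
  expect_identical(gc2$direction, "lower")
  expect_lt(gc2$p, 0.01)
  expect_lt(abs(gc2$percent_difference + 20), 5)
  # constant outcome -> zero residual variance
  expect_error(group_compare(make_measures(rep(5, 12), ids),
                             make_manifest(ids, grp), "vol",
                             covariates = character()),
               "constant")
  # collinear covariates named in the failure
  man <- make_manifest(ids, grp)
  man$age <- 1:12
  man$age2 <- man$age * 2
  expect_error(group_compare(make_measures(vals2, ids), man, "vol",
                             covariates = c("age", "age2")),
               "collinear.*age2")
  expect_error(group_compare(make_measures(vals2[1:3], ids[1:3]),
                             make_manifest(ids[1:3], c("HC", "HC", "MDD")),
                             "vol"), "2 subjects")
})

test_that("covariate adjustment removes a confounded group difference", {
  set.seed(2)
  ids <- sprintf("S%02d", 1:40)
  grp <- rep(c("HC", "MDD"), each = 20)
  age <- c(rnorm(20, 30, 3), rnorm(20, 50, 3))   # group confounded with age
  vals <- 100 - 0.8 * age + rnorm(40, 0, 1)      # pure age effect
  man <- make_manifest(ids, grp, age = age)
  unadj <- group_compare(make_measures(vals, ids), man, "vol",
                         covariates = character())
  adj <- group_compare(make_measures(vals, ids), man, "vol",
                       covariates = "age")
  expect_lt(unadj$p, 1e-6)
  expect_gt(adj$p, 0.01)
})

test_that("BH step-up matches hand-computed adjustments", {
  expect_equal(bh_adjust(0.3)$bh_adjusted, 0.3)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03))$bh_adjusted,
               c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.05, 0.5))$bh_adjusted, c(0.10, 0.50))
  # monotone in raw rank order and idempotent on sorted adjusted values
  set.seed(4)
  p <- sort(runif(20))
  adj <- bh_adjust(p)$bh_adjusted
  expect_true(all(diff(adj) >= 0))
  expect_equal(bh_adjust(adj)$bh_adjusted >= adj, rep(TRUE, 20))
  expect_error(bh_adjust(numeric(0)), "empty")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("TFCE: degenerate maps, toy oracle, monotonicity, sign", {
  d <- c(9, 3, 3)
  mask <- array(FALSE, d); mask[1:9, 2, 2] <- TRUE
  zero <- array(0, d)
  expect_true(all(tfce(zero, mask) == 0))
  # uniform map over a connected mask -> constant enhancement
  uni <- zero; uni[mask] <- 2
  e_uni <- tfce(uni, mask)
  expect_equal(length(unique(round(e_uni[mask], 10))), 1L)
  # 3-voxel toy map against the brute-force threshold-sum oracle
  toy <- zero; toy[4:6, 2, 2] <- c(1, 2, 1)
  pars <- tfce_params(dh = 0.01)
  e <- tfce(toy, mask, pars)
  stat_line <- toy[1:9, 2, 2]
  oracle <- oracle_tfce(stat_line, line_neighbours(9), E = 0.5, H = 2,
                        dh = 0.01)
  expect_lt(max(abs(e[1:9, 2, 2] - oracle)), 5e-4)
  expect_equal(round(e[5, 2, 2], 3), round(oracle[5], 3))
  # pointwise dominance is preserved
  lo <- zero; lo[mask] <- runif(9)
  hi <- lo + 0.5 * (lo > 0)
  expect_true(all(tfce(hi, mask, pars) >= tfce(lo, mask, pars) - 1e-12))
  # negative statistics: enhanced separately with sign kept
  expect_equal(tfce(-toy, mask, pars), -tfce(toy, mask, pars))
  bad <- zero; bad[2, 2, 2] <- NA
  expect_error(tfce(bad, mask), "finite")
})

test_that("exhaustive permutation matches an independent enumeration", {
  # n = 7 (3 vs 4) on a 1D mask: all 35 relabelings enumerable
  d <- c(8, 3, 3)
  mask <- array(FALSE, d); mask[1:8, 2, 2] <- TRUE
  grid <- voxel_grid(d, 1)
  n <- 7
  g <- c("A", "A", "A", "B", "B", "B", "B")
  set.seed(11)
  maps <- matrix(rnorm(n * 8), n, 8)
  maps[g == "B", 3:5] <- maps[g == "B", 3:5] + 1.5
  perms <- all_group_permutations(g)
  expect_identical(nrow(perms), 35L)
  expect_identical(perms[1, ], 1:7)
  pars <- tfce_params(dh = 0.05)
  pt <- permutation_test(maps, mask, grid, data.frame(group = g),
                         perms = perms, variance_smoothing_mm = 0,
                         tfce = pars, rng_seed = 1)
  # oracle: plain two-sample t per voxel, brute-force TFCE, max-stat rank
  oracle_stats <- apply(perms, 1, function(pm) {
    Y <- maps[pm, , drop = FALSE]
    tv <- vapply(1:8, function(v) {
      a <- Y[g == "A", v]; b <- Y[g == "B", v]
      sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                   (n - 2))
      (mean(b) - mean(a)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
    }, numeric(1))
    e <- numeric(8)
    for (sgn in c(1, -1)) {
      s <- pmax(sgn * tv, 0)
      if (max(s) > 0)
        e <- e + sgn * oracle_tfce(s, line_neighbours(8), 0.5, 2, 0.05)
    }
    e
  })                                        # 8 x 35
  e_obs <- oracle_stats[, 1]
  max_null <- apply(abs(oracle_stats), 2, max)
  p_oracle <- vapply(abs(e_obs), function(x)
    mean(max_null >= x - 1e-12), numeric(1))
  expect_equal(unname(pt$p_corrected[1:8, 2, 2]), p_oracle,
               tolerance = 1e-10)
})

test_that("corrected p respects the permutation rank bound", {
  sg <- small_mask_grid(c(6, 6, 6))
  n <- 10
  set.seed(5)
  maps <- matrix(rnorm(n * sum(sg$mask)), n)
  maps[6:10, ] <- maps[6:10, ] + 3          # gross effect
  g <- rep(c("A", "B"), each = 5)
  pt <- suppressWarnings(
    permutation_test(maps, sg$mask, sg$grid, data.frame(group = g),
                     n_perm = 50, rng_seed = 2))
  expect_gte(min(pt$p_corrected, na.rm = TRUE), 1 / 50)
  pt2 <- suppressWarnings(
    permutation_test(maps, sg$mask, sg$grid, data.frame(group = g),
                     n_perm = 50, rng_seed = 2))
  expect_identical(pt$p_corrected, pt2$p_corrected)
  expect_error(permutation_test(maps[1:6, ], sg$mask, sg$grid,
                                data.frame(group = g[1:6]), n_perm = 50),
               "8 subjects")
  expect_error(permutation_test(maps, sg$mask, sg$grid,
                                data.frame(group = rep("A", n)),
                                n_perm = 50), "estimable")
  expect_warning(permutation_test(maps, sg$mask, sg$grid,
                                  data.frame(group = g), n_perm = 50,
                                  rng_seed = 2),
                 "coarse")
})

test_that("cluster descriptors report COG and volume, largest first", {
  d <- c(10, 10, 10)
  grid <- voxel_grid(d, 2)
  p_map <- array(NA_real_, d)
  p_map[2:9, 2:9, 2:9] <- 0.5
  expect_identical(nrow(cluster_descriptors(p_map, 0.05, grid)), 0L)
  # one significant voxel: COG at its world position, volume = voxel volume
  p_map[4, 5, 6] <- 0.01
  cd <- cluster_descriptors(p_map, 0.05, grid)
  expect_identical(nrow(cd), 1L)
  expect_equal(cd$volume_mm3, 8)
  world <- voxel_to_world(grid, matrix(c(4, 5, 6), 1))
  expect_equal(c(cd$cog_x_mm, cd$cog_y_mm, cd$cog_z_mm), as.vector(world))
  # two separated clusters sorted by volume
  p_map[7:8, 8, 8] <- 0.01
  cd2 <- cluster_descriptors(p_map, 0.05, grid)
  expect_identical(nrow(cd2), 2L)
  expect_identical(cd2$n_voxels, c(2L, 1L))
})
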