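# Streamline tracker: forced geometries, termination rules, conservation,
# determinism, seed-volume normalization, and the Markov-chain absorption
# oracle on a 1D chain field.

test_that("a field pointing straight into a target credits every sample", {
  cd <- corridor_domain()
  seed <- chain_mask(cd$grid, 3)
  targets <- list(A = chain_mask(cd$grid, 10), B = chain_mask(cd$grid, 1))
  counts <- track_classification(cd$domain, seed, targets,
                                 params = tracking_params(
                                   samples_per_seed_voxel = 500,
                                   step_length_mm = 1, rng_seed = 1))
  expect_identical(unname(counts$counts[1, "A"]), 500L)
  expect_identical(unname(counts$counts[1, "B"]), 0L)
})

test_that("a forced successive-step cosine below threshold kills streams", {
  # voxel 1 points +x; all voxels beyond point at ~84 degrees to +x
  # (cos ~ 0.1 < 0.2): with symmetrization off every streamline dies
  grid <- voxel_grid(c(30, 30, 30), 1)
  V <- prod(grid$dim)
  weights <- matrix(0, V, 2)
  centers <- rbind(c(1000, 15, 15), c(5 + 0.1 * 985, 1000, 15))
  flat <- function(x, y, z) x + 30 * (y - 1) + 900 * (z - 1)
  weights[flat(4, 15, 15), 1] <- 1
  for (x in 5:30) for (y in 1:30) weights[flat(x, y, 15), 2] <- 1
  dom <- tracking_domain(grid, weights, centers)
  seed <- array(FALSE, grid$dim); seed[4, 15, 15] <- TRUE
  target <- array(FALSE, grid$dim); target[, 28, ] <- TRUE
  counts <- track_classification(dom, seed, list(T = target),
                                 params = tracking_params(
                                   samples_per_seed_voxel = 200,
                                   step_length_mm = 1, symmetrize = FALSE,
                                   rng_seed = 2))
  expect_identical(sum(counts$counts), 0L)
  # the same geometry passes once the curvature threshold drops below 0.1
  counts2 <- track_classification(dom, seed, list(T = target),
                                  params = tracking_params(
                                    curvature_threshold = 0.05,
                                    samples_per_seed_voxel = 200,
                                    step_length_mm = 1, symmetrize = FALSE,
                                    rng_seed = 2))
  expect_gt(sum(counts2$counts), 0L)
})

test_that("targets beyond max_steps x step_length are unreachable", {
  cd <- corridor_domain()
  seed <- chain_mask(cd$grid, 3)
  targets <- list(A = chain_mask(cd$grid, 15))
  counts <- track_classification(cd$domain, seed, targets,
                                 params = tracking_params(
                                   max_steps = 5, step_length_mm = 1,
                                   samples_per_seed_voxel = 100,
                                   rng_seed = 1))
  expect_identical(sum(counts$counts), 0L)
})

test_that("counts are conserved, deterministic, and seed-sensitive", {
  p <- default_phantom()
  dom <- phantom_domain(p)
  striatal <- p$nuclei > 0L
  hemi_r <- slice.index(striatal, 1) > dim(striatal)[1] / 2
  comp <- bait_composites(p)
  seeds <- striatal & hemi_r
  seeds[, , seq_len(15)] <- FALSE          # a few hundred voxels suffice
  pars <- tracking_params(samples_per_seed_voxel = 50, rng_seed = 21)
  run <- function(pr) track_classification(
    dom, seeds, list(matrix = comp$matrix & hemi_r,
                     striosome = comp$striosome & hemi_r),
    exclusion_mask = !hemi_r, params = pr)
  a <- run(pars)
  expect_true(all(rowSums(a$counts) <= a$launched))
  expect_true(all(a$counts >= 0))
  b <- run(pars)
  expect_identical(a$counts, b$counts)
  c <- run(tracking_params(samples_per_seed_voxel = 50, rng_seed = 22))
  expect_false(identical(a$counts, c$counts))
})

test_that("tracker errors on empty seeds and mask conflicts", {
  cd <- corridor_domain()
  empty <- array(FALSE, cd$grid$dim)
  target <- chain_mask(cd$grid, 10)
  expect_error(track_classification(cd$domain, empty, list(A = target)),
               "empty seed")
  expect_error(track_classification(cd$domain, chain_mask(cd$grid, 3),
                                    list(A = target),
                                    exclusion_mask = target),
               "overlap")
  expect_error(track_classification(cd$domain, target, list(A = target)),
               "disjoint")
})

test_that("streamline-mode counts are seed-volume normalized", {
  # two identical, independent corridors: doubling the seed region doubles
  # the raw count but leaves the normalized count unchanged
  grid <- voxel_grid(c(20, 21, 21), 1)
  V <- prod(grid$dim)
  weights <- matrix(0, V, 2)
  centers <- rbind(c(1000, 8, 10), c(1000, 12, 10))   # one per corridor
  flat <- function(x, y, z) x + 20 * (y - 1) + 20 * 21 * (z - 1)
  for (x in 1:20) weights[flat(x, 9, 11), 1] <- 1
  for (x in 1:20) weights[flat(x, 13, 11), 2] <- 1
  dom <- tracking_domain(grid, weights, centers)
  seed1 <- array(FALSE, grid$dim); seed1[3, 9, 11] <- TRUE
  seed2 <- seed1; seed2[3, 13, 11] <- TRUE
  target <- array(FALSE, grid$dim); target[15, c(9, 13), 11] <- TRUE
  pars <- tracking_params(samples_per_seed_voxel = 400, step_length_mm = 1,
                          rng_seed = 5)
  r1 <- track_streamline_mode(dom, seed1, target, params = pars)
  r2 <- track_streamline_mode(dom, seed2, target, params = pars)
  expect_identical(r2$count, 2L * r1$count)
  expect_equal(r2$normalized, r1$normalized)
})

test_that("an avoid mask across the only corridor blocks everything", {
  cd <- corridor_domain()
  seed <- chain_mask(cd$grid, 3)
  target <- chain_mask(cd$grid, 15)
  avoid <- chain_mask(cd$grid, 9)
  r <- track_streamline_mode(cd$domain, seed, target, avoid_mask = avoid,
                             params = tracking_params(
                               samples_per_seed_voxel = 200,
                               step_length_mm = 1, rng_seed = 3))
  expect_identical(r$count, 0L)
  expect_identical(r$normalized, 0)
})

test_that("enlarging a target does not decrease its expected count", {
  p <- default_phantom()
  dom <- phantom_domain(p)
  striatal <- p$nuclei > 0L
  hemi_r <- slice.index(striatal, 1) > dim(striatal)[1] / 2
  comp <- bait_composites(p)
  big <- comp$matrix & hemi_r
  small <- big & slice.index(big, 2) <= p$band_cuts[3]  # bands 1-3 only
  seeds <- striatal & hemi_r & p$gt_compartment == 1L
  totals <- vapply(1:5, function(s) {
    pars <- tracking_params(samples_per_seed_voxel = 20, rng_seed = 100 + s)
    c(sum(track_classification(dom, seeds, list(m = small),
                               exclusion_mask = !hemi_r,
                               params = pars)$counts),
      sum(track_classification(dom, seeds, list(m = big),
                               exclusion_mask = !hemi_r,
                               params = pars)$counts))
  }, numeric(2))
  expect_gte(mean(totals[2, ]), mean(totals[1, ]))
})

test_that("1D chain absorption matches the Markov closed form", {
  # biased +/-1 random walk on a chain, absorbing targets at both ends;
  # symmetrization off and curvature threshold -1 so reversals are free
  n <- 15
  cd <- corridor_domain(n, w_right = 0.6, w_left = 0.4)
  seed_x <- 8
  seed <- chain_mask(cd$grid, seed_x)
  targets <- list(right = chain_mask(cd$grid, n - 1),
                  left = chain_mask(cd$grid, 2))
  samples <- 4000
  counts <- track_classification(cd$domain, seed, targets,
                                 params = tracking_params(
                                   curvature_threshold = -1,
                                   symmetrize = FALSE,
                                   step_length_mm = 1,
                                   samples_per_seed_voxel = samples,
                                   rng_seed = 17))
  reached <- sum(counts$counts)
  expect_gt(reached, 0.95 * samples)       # nothing else can kill the walk
  # absorbing barriers at x = 2 and x = n-1: k interior steps to the left
  # barrier, N total gap
  k <- seed_x - 2
  N <- (n - 1) - 2
  p_right <- oracle_absorption_right(k, N, 0.6)
  phat <- counts$counts[1, "right"] / reached
  se <- sqrt(p_right * (1 - p_right) / reached)
  expect_lt(abs(phat - p_right), 3 * se)
})
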