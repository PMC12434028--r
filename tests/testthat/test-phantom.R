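# Phantom generator: geometry invariants, striosome topology and location,
# determinism, severity binning.

test_that("identical seeds produce bit-identical phantoms", {
  a <- build_phantom(rng_seed = 5)
  b <- build_phantom(rng_seed = 5)
  expect_identical(a$nuclei, b$nuclei)
  expect_identical(a$gt_compartment, b$gt_compartment)
  expect_identical(a$rd_field, b$rd_field)
  c <- build_phantom(rng_seed = 6)
  expect_false(identical(a$gt_compartment, c$gt_compartment))
})

test_that("ground-truth invariants hold across seeds", {
  for (seed in 1:10) {
    p <- build_phantom(rng_seed = seed)
    striatal <- p$nuclei > 0L
    # compartment labels partition the striatum
    expect_identical(which(p$gt_compartment != 0L), which(striatal))
    # striosome abundance within +/- 2 percentage points of 15%
    frac <- sum(p$gt_compartment == 2L) / sum(striatal)
    expect_lt(abs(frac - 0.15), 0.02)
  }
})

test_that("striosomes form separated thin tubules, matrix is contiguous", {
  p <- default_phantom()
  s <- p$gt_compartment == 2L
  m <- p$gt_compartment == 1L
  hemi <- slice.index(s, 1) <= dim(s)[1] / 2
  for (hm in list(hemi, !hemi)) {
    lab <- label_components(s & hm, 26)
    expect_gte(max(lab), 3)                    # >= 3 islands per hemisphere
  }
  # largest matrix component dwarfs largest striosome component
  expect_gt(max(table(label_components(m, 26)[m])),
            max(table(label_components(s, 26)[s])))
  # thickness <= 1 voxel: no fully-striosome 2x2 in-plane block anywhere
  # (independent check of the diameter cap: width 1 mm <= 1.25 mm)
  block <- function(a, ax1, ax2) {
    d <- dim(a)
    ix <- function(o1, o2) {
      sl <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      sl[[ax1]] <- seq_len(d[ax1] - 1) + o1
      sl[[ax2]] <- seq_len(d[ax2] - 1) + o2
      a[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
    }
    any(ix(0, 0) & ix(1, 0) & ix(0, 1) & ix(1, 1))
  }
  expect_false(block(s, 1, 2) || block(s, 1, 3) || block(s, 2, 3))
})

test_that("striosomes sit rostral and ventral of matrix within nuclei", {
  for (seed in 1:3) {
    p <- build_phantom(rng_seed = seed)
    off_s <- nucleus_origin_offsets(p$gt_compartment == 2L, p$nuclei, p$grid)
    off_m <- nucleus_origin_offsets(p$gt_compartment == 1L, p$nuclei, p$grid)
    expect_gt(off_s[["y_mm_rostral"]], off_m[["y_mm_rostral"]])
    expect_lt(off_s[["z_mm_dorsal"]], off_m[["z_mm_dorsal"]])
  }
})

test_that("nucleus geometry is mirror-symmetric across the midline", {
  p <- default_phantom()
  flipped <- p$nuclei[rev(seq_len(dim(p$nuclei)[1])), , ]
  swap <- flipped
  swap[flipped == 1L] <- 2L; swap[flipped == 2L] <- 1L
  swap[flipped == 3L] <- 4L; swap[flipped == 4L] <- 3L
  expect_identical(swap, p$nuclei)
})

test_that("bait atlas has 5+5 disjoint regions and disjoint gt zones", {
  p <- default_phantom()
  atlas <- p$bait_atlas
  expect_identical(sum(atlas$affinity == "matrix"), 5L)
  expect_identical(sum(atlas$affinity == "striosome"), 5L)
  striatal <- p$nuclei > 0L
  overlap <- Reduce(`+`, lapply(atlas$regions, as.integer))
  expect_true(all(overlap <= 1))                      # regions disjoint
  expect_false(any(overlap > 0 & striatal))           # and off-striatum
  zoverlap <- Reduce(`+`, lapply(atlas$gt_zone, as.integer))
  expect_true(all(zoverlap <= 1))                     # zones disjoint
})

test_that("zero leakage wires a striosome voxel only to striosome baits", {
  p <- build_phantom(phantom_config(leakage = 0), rng_seed = 2)
  v <- which(p$gt_compartment == 2L, arr.ind = TRUE)[1, ]
  field <- orientation_field_at(p, as.integer(v))
  strio_names <- names(p$bait_atlas$affinity)[p$bait_atlas$affinity ==
                                                "striosome"]
  expect_true(all(sub("-[LR]$", "", field$attractor) %in% strio_names))
  expect_equal(sum(field$weight), 1)
})

test_that("invalid configurations are rejected with explicit errors", {
  expect_error(phantom_config(dim = c(16, 48, 40)), "20 voxels")
  expect_error(phantom_config(voxel_mm = 3.5), "voxel size")
  expect_error(phantom_config(striosome_fraction = 0.5), "fraction")
  # voxel too coarse to honour the tubule diameter cap
  expect_error(phantom_config(voxel_mm = 1.5,
                              striosome_diameter_cap_mm = 1.25),
               "diameter cap")
})

test_that("severity categories follow the three scale tables", {
  expect_identical(severity_to_category("Hamilton", 15), "Moderate")
  expect_identical(severity_to_category("RCADS", 19), "Mild")
  expect_identical(severity_to_category("Achenbach", 95), "VerySevere")
  # bin edges: half-open, shared boundaries resolve to the upper bin
  expect_identical(severity_to_category("Hamilton", 8), "Mild")
  expect_identical(severity_to_category("Hamilton", 13), "Mild")
  expect_identical(severity_to_category("Hamilton", 14), "Moderate")
  expect_identical(severity_to_category("Hamilton", 22), "Severe")
  expect_identical(severity_to_category("Hamilton", 23), "VerySevere")
  expect_identical(severity_to_category("Hamilton", 7), "BelowThreshold")
  expect_identical(severity_to_category("RCADS", 27), "VerySevere")
  expect_identical(severity_to_category("Achenbach", 85), "Severe")
  expect_identical(severity_to_category("Achenbach", 69), "BelowThreshold")
  expect_error(severity_to_category("PHQ9", 10), "unknown severity scale")
  expect_error(severity_to_category("Hamilton", NA_real_), "finite")
})
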