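# Probability maps, classification, volumes, high-bias masks, clusters,
# locations and radial diffusivity.

test_that("bias probabilities are count ratios with a classification floor", {
  grid <- voxel_grid(c(20, 20, 20), 1)
  striatal <- array(FALSE, grid$dim); striatal[5:7, 5, 5] <- TRUE
  cm <- array(0, grid$dim); cs <- array(0, grid$dim)
  cm[5, 5, 5] <- 990; cs[5, 5, 5] <- 10
  cm[6, 5, 5] <- 0;   cs[6, 5, 5] <- 0
  cm[7, 5, 5] <- 55;  cs[7, 5, 5] <- 45
  prob <- synthetic_prob(cm, cs, striatal, grid)
  expect_equal(prob$p_matrix[5, 5, 5], 0.99)
  expect_false(prob$seeded_mask[6, 5, 5])          # 0 + 0 -> unseeded
  expect_equal(prob$p_matrix[7, 5, 5], 0.55)
  expect_equal(prob$p_striosome[7, 5, 5], 0.45)
  f <- which(prob$seeded_mask)
  expect_true(all(abs(prob$p_matrix[f] + prob$p_striosome[f] - 1) < 1e-9))
  cm[5, 5, 5] <- -1
  expect_error(synthetic_prob(cm, cs, striatal, grid), "negative")
})

test_that("voxel classification follows the bias threshold and band", {
  grid <- voxel_grid(c(20, 20, 20), 1)
  striatal <- array(FALSE, grid$dim); striatal[5:8, 5, 5] <- TRUE
  cm <- array(0, grid$dim); cs <- array(0, grid$dim)
  cm[5, 5, 5] <- 55; cs[5, 5, 5] <- 45    # exactly at threshold
  cm[6, 5, 5] <- 50; cs[6, 5, 5] <- 50    # indeterminate
  cm[7, 5, 5] <- 30; cs[7, 5, 5] <- 70    # striosome-like
  prob <- synthetic_prob(cm, cs, striatal, grid)
  parc <- classify_voxels(prob)
  expect_identical(parc$labels[5, 5, 5], 1L)       # matrix-like at P = 0.55
  expect_identical(parc$labels[6, 5, 5], 3L)       # indeterminate at P = 0.5
  expect_identical(parc$labels[7, 5, 5], 2L)       # complement >= 0.55
  expect_identical(parc$labels[8, 5, 5], 4L)       # unseeded passthrough
  expect_error(classify_voxels(prob, bias_threshold = 0.5), "0.5")
  expect_error(classify_voxels(prob, bias_threshold = 1.2), "0.5")
})

test_that("swapping the probability maps swaps the labels exactly", {
  sp <- default_parcellation()
  prob <- sp$prob
  swapped <- prob
  swapped$p_matrix <- prob$p_striosome
  swapped$p_striosome <- prob$p_matrix
  a <- classify_voxels(prob)$labels
  b <- classify_voxels(swapped)$labels
  expect_identical(b == 1L, a == 2L)
  expect_identical(b == 2L, a == 1L)
  expect_identical(b == 3L, a == 3L)
})

test_that("labels partition the striatal mask exactly", {
  sp <- default_parcellation()
  tab <- parcellation_table(sp$parcellation)
  expect_identical(sum(tab), sum(sp$parcellation$striatal_mask))
  expect_identical(sum(sp$parcellation$labels != 0L),
                   sum(sp$parcellation$striatal_mask))
})

test_that("compartment volumes are voxel counts times voxel volume / eTIV", {
  grid <- voxel_grid(c(20, 20, 20), 1)
  nuclei <- array(0L, grid$dim)
  nuclei[3:12, 3:12, 3] <- 4L              # 100 putamen voxels of 1 mm^3
  striatal <- nuclei > 0L
  cm <- array(0, grid$dim); cm[striatal] <- 100
  cs <- array(0, grid$dim)
  prob <- synthetic_prob(cm, cs, striatal, grid)
  parc <- classify_voxels(prob)
  vols <- compartment_volumes(parc, nuclei, etiv = 1e6)
  pm <- vols[vols$nucleus == "putamen" & vols$compartment == "matrix_like", ]
  expect_equal(pm$volume_mm3, 100)
  expect_equal(pm$normalized_volume, 1e-4)
  ps <- vols[vols$nucleus == "putamen" &
               vols$compartment == "striosome_like", ]
  expect_equal(ps$volume_mm3, 0)
  expect_error(compartment_volumes(parc, nuclei, etiv = 0), "positive")
})

test_that("printed group means reproduce the reported volume contrasts", {
  expect_equal(round(percent_smaller(3857, 4207), 1), 8.3)
  expect_equal(round(fold_difference(571, 162), 1), 3.5)
})

test_that("high-bias masks are equal volume with deterministic ties", {
  grid <- voxel_grid(c(20, 20, 20), 1)
  striatal <- array(FALSE, grid$dim)
  striatal[1:10, 1:10, 1:10] <- TRUE       # 1000 striatal voxels
  set.seed(8)
  cm <- array(0, grid$dim)
  cm[striatal] <- sample(c(200, 800), 1000, replace = TRUE)
  cs <- array(0, grid$dim); cs[striatal] <- 1000 - cm[striatal]
  prob <- synthetic_prob(cm, cs, striatal, grid)
  hb <- build_high_bias_masks(prob, striatal)
  expect_identical(sum(hb$matrix_mask), 130L)      # floor(0.13 x 1000)
  expect_identical(sum(hb$striosome_mask), 130L)
  expect_false(any(hb$matrix_mask & hb$striosome_mask))
  # all biases tie: selection must be the lowest flat indices
  elig <- which(prob$p_matrix > 0.5 & striatal)
  expect_identical(which(hb$matrix_mask), sort(elig)[1:130])

  # striosome-poor fixture: only 90 eligible -> both truncated to 90
  cm2 <- array(0, grid$dim); cm2[striatal] <- 800
  cs2 <- cm2 * 0; cs2[striatal] <- 200
  poor <- which(striatal)[1:90]
  cm2[poor] <- 200; cs2[poor] <- 800
  prob2 <- synthetic_prob(cm2, cs2, striatal, grid)
  hb2 <- build_high_bias_masks(prob2, striatal)
  expect_identical(sum(hb2$matrix_mask), 90L)
  expect_identical(sum(hb2$striosome_mask), 90L)
  expect_error(build_high_bias_masks(prob, striatal, target_fraction = 0.6),
               "target_fraction")
})

test_that("largest cluster volume respects the connectivity choice", {
  grid <- voxel_grid(c(20, 20, 20), 1.5)
  m <- array(FALSE, grid$dim)
  m[5, 5, 5] <- TRUE
  expect_equal(largest_cluster_volume(m, grid), 1.5^3)
  # two voxels sharing only a corner
  m[6, 6, 6] <- TRUE
  expect_equal(largest_cluster_volume(m, grid, 26), 2 * 1.5^3)
  expect_equal(largest_cluster_volume(m, grid, 6), 1.5^3)
  expect_equal(largest_cluster_volume(m, grid, 18), 1.5^3)
  # edge-sharing pair: 18- and 26-connected, not 6-connected
  m2 <- array(FALSE, grid$dim)
  m2[5, 5, 5] <- TRUE; m2[6, 6, 5] <- TRUE
  expect_equal(largest_cluster_volume(m2, grid, 18), 2 * 1.5^3)
  expect_equal(largest_cluster_volume(m2, grid, 6), 1.5^3)
  expect_equal(largest_cluster_volume(array(FALSE, grid$dim), grid), 0)
})

test_that("component labelling agrees with an igraph oracle", {
  skip_if_not_installed("igraph")
  set.seed(3)
  d <- c(12, 12, 12)
  m <- array(runif(prod(d)) < 0.25, d)
  for (conn in c(6, 18, 26)) {
    lab <- label_components(m, conn)
    idx <- which(m, arr.ind = TRUE)
    n <- nrow(idx)
    edges <- NULL
    for (i in seq_len(n - 1)) {
      dd <- abs(sweep(idx[(i + 1):n, , drop = FALSE], 2, idx[i, ]))
      adj <- apply(dd, 1, max) <= 1
      manh <- rowSums(dd)
      adj <- adj & switch(as.character(conn), "6" = manh <= 1,
                          "18" = manh <= 2, "26" = TRUE)
      if (any(adj)) edges <- rbind(edges, cbind(i, i + which(adj)))
    }
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
    oracle_n <- igraph::count_components(g)
    expect_identical(max(lab), as.integer(oracle_n))
  }
})

test_that("centroid-relative locations behave as mean offsets", {
  grid <- voxel_grid(c(20, 20, 20), 1)
  nucleus <- array(FALSE, grid$dim); nucleus[5:9, 5:9, 5:9] <- TRUE
  expect_equal(unname(centroid_relative_locations(nucleus, nucleus, grid)),
               c(0, 0, 0))
  pair <- array(FALSE, grid$dim); pair[7, c(5, 9), 7] <- TRUE
  off <- centroid_relative_locations(pair, nucleus, grid)
  expect_equal(unname(off[["y_mm_rostral"]]), 0)
  expect_error(centroid_relative_locations(array(FALSE, grid$dim), nucleus,
                                           grid), "empty")
  outside <- array(FALSE, grid$dim); outside[1, 1, 1] <- TRUE
  expect_error(centroid_relative_locations(outside, nucleus, grid),
               "inside")
})

test_that("radial diffusivity averages the minor eigenvalues", {
  d <- c(4, 4, 4)
  rd <- array(0, c(d, 3))
  mask <- array(FALSE, d); mask[1, 1, 1] <- TRUE; mask[2, 1, 1] <- TRUE
  rd[1, 1, 1, ] <- c(7e-4, 7e-4, 7e-4)
  rd[2, 1, 1, ] <- c(1.5e-3, 5e-4, 3e-4)
  m1 <- array(FALSE, d); m1[1, 1, 1] <- TRUE
  m2 <- array(FALSE, d); m2[2, 1, 1] <- TRUE
  expect_equal(radial_diffusivity(rd, m1), 7e-4)
  expect_equal(radial_diffusivity(rd, m2), 4e-4)
  rd[2, 1, 1, ] <- c(1.5e-3, 0, 0)
  expect_equal(radial_diffusivity(rd, m2), 0)
  rd[2, 1, 1, ] <- c(3e-4, 5e-4, 1.5e-3)   # unordered triple
  expect_error(radial_diffusivity(rd, m2), "unordered")
})

test_that("threshold sweep: striosome-like fraction falls monotonically", {
  sp <- default_parcellation()
  fr <- vapply(c(0.55, 0.7, 0.87), function(th) {
    parc <- classify_voxels(sp$prob, th)
    tab <- parcellation_table(parc)
    tab[["striosome_like"]] / sum(tab)
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
})
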