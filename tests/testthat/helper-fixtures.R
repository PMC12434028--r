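# Shared fixtures, built lazily and cached for the whole test run.
# Problem sizes are scaled down (reduced sample counts, smaller grids) so
# the full suite stays fast; the phantom itself is the package default.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

default_phantom <- function() {
  fixture("phantom", function() build_phantom(rng_seed = 1))
}

default_parcellation <- function() {
  fixture("parcellation", function() {
    parcellate_subject(default_phantom(),
                       tracking_params(samples_per_seed_voxel = 500,
                                       rng_seed = 7))
  })
}

# small grid + mask for inference tests
small_mask_grid <- function(dim = c(8, 8, 8), voxel_mm = 2) {
  grid <- voxel_grid(dim, voxel_mm)
  mask <- array(FALSE, dim)
  mask[2:(dim[1] - 1), 2:(dim[2] - 1), 2:(dim[3] - 1)] <- TRUE
  list(grid = grid, mask = mask)
}

# synthetic probability_maps object from explicit count arrays
synthetic_prob <- function(matrix_counts, striosome_counts, striatal_mask,
                           grid, min_total_count = 10L) {
  sc <- structure(list(
    counts = cbind(matrix = matrix_counts[striatal_mask],
                   striosome = striosome_counts[striatal_mask]),
    launched = rep(sum(matrix_counts + striosome_counts), sum(striatal_mask)),
    seed_flat = which(striatal_mask), seed_mask = striatal_mask,
    grid = grid, normalized_totals = c(matrix = 0, striosome = 0),
    params = tracking_params()), class = "streamline_counts")
  compute_bias_probabilities(sc, striatal_mask, min_total_count)
}

# a straight corridor along +x at (y, z) = (11, 11): per-voxel mixture over
# two attractors far right / far left, so steps are exactly +/- 1 voxel
corridor_domain <- function(n = 20, w_right = 1, w_left = 0) {
  grid <- voxel_grid(c(n, 21, 21), 1)
  V <- prod(grid$dim)
  weights <- matrix(0, V, 2)
  centers <- rbind(c(1000, 10, 10), c(-1000, 10, 10))
  idx <- sapply(seq_len(n), function(x) x + n * 10 + n * 21 * 10)
  weights[idx, 1] <- w_right
  weights[idx, 2] <- w_left
  list(domain = tracking_domain(grid, weights, centers), grid = grid,
       chain_flat = idx)
}

chain_mask <- function(grid, xs) {
  m <- array(FALSE, grid$dim)
  m[xs, 11, 11] <- TRUE
  m
}

# --- independent oracles (deliberately simple, no package internals) -------

# brute-force TFCE on a vector of mask voxels with an explicit neighbour
# function; extent via repeated flood fill
oracle_tfce <- function(stat, neighbours, E, H, dh) {
  out <- numeric(length(stat))
  hmax <- max(stat)
  if (hmax <= 0) return(out)
  hs <- dh * seq_len(floor(hmax / dh + 1e-9))
  for (h in hs) {
    on <- which(stat >= h - 1e-9 * dh)
    if (!length(on)) break
    comp <- rep(NA_integer_, length(stat))
    cid <- 0L
    for (s in on) {
      if (!is.na(comp[s])) next
      cid <- cid + 1L
      queue <- s
      comp[s] <- cid
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        for (nb in neighbours(v)) {
          if (nb %in% on && is.na(comp[nb])) {
            comp[nb] <- cid
            queue <- c(queue, nb)
          }
        }
      }
    }
    sizes <- table(comp[on])
    out[on] <- out[on] + as.numeric(sizes[as.character(comp[on])])^E *
      h^H * dh
  }
  out
}

line_neighbours <- function(n) {
  function(v) c(if (v > 1) v - 1, if (v < n) v + 1)
}

# gambler's-ruin absorption probability: biased +1/-1 walk starting at k of
# {0, ..., N}, absorbing at both ends, p = P(step +1)
oracle_absorption_right <- function(k, N, p) {
  if (p == 0.5) return(k / N)
  r <- (1 - p) / p
  (1 - r^k) / (1 - r^N)
}
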