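# Geometry oracles shared by the packing and acceptance tests.

lattice_coords <- function(n, a) {
  g <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  as.matrix(g) * a
}

lattice_interior <- function(n) {
  g <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  g$x > 1 & g$x < n & g$y > 1 & g$y < n & g$z > 1 & g$z < n
}

# Monte-Carlo Voronoi volumes: uniform points in a box, assigned to the
# nearest centre; cell volume = box volume * hit fraction.
mc_voronoi <- function(coords, lo, hi, n_pts = 2e5, seed = 42) {
  set.seed(seed)
  pts <- cbind(runif(n_pts, lo[1], hi[1]), runif(n_pts, lo[2], hi[2]),
               runif(n_pts, lo[3], hi[3]))
  counts <- integer(nrow(coords))
  for (start in seq(1, n_pts, by = 20000)) {
    block <- pts[start:min(start + 19999, n_pts), , drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(coords^2), "+") -
      2 * block %*% t(coords)
    nn <- max.col(-d2)
    counts <- counts + tabulate(nn, nbins = nrow(coords))
  }
  vol_box <- prod(hi - lo)
  list(volume = counts / n_pts * vol_box,
       se = sqrt(counts) / n_pts * vol_box)
}
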