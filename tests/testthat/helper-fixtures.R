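# Programmatic fixtures shared across test files.

draw_disk <- function(m, ctr, r) {
  nr <- nrow(m)
  idx <- seq_along(m)
  rr <- (idx - 1) %% nr + 1
  cc <- (idx - 1) %/% nr + 1
  m | matrix((rr - ctr[1])^2 + (cc - ctr[2])^2 <= r^2, nr)
}

# two abutting r=12 nuclei plus a small boundary bump, with a membrane wall
# between the main pair: distance-transform thresholding finds 3 seeds, of
# which the bump seed is spurious
three_seed_cluster <- function() {
  nr <- 80; nc <- 110
  m <- matrix(FALSE, nr, nc)
  c1 <- c(40, 35); c2 <- c(40, 35 + 1.6 * 12)
  m <- draw_disk(m, c1, 12)
  m <- draw_disk(m, c2, 12)
  m <- draw_disk(m, c(40 - 15, 35), 4)     # spurious bump
  idx <- which(m)
  rr <- (idx - 1) %% nr + 1
  cc <- (idx - 1) %/% nr + 1
  d1 <- sqrt((rr - c1[1])^2 + (cc - c1[2])^2)
  d2 <- sqrt((rr - c2[1])^2 + (cc - c2[2])^2)
  wall <- matrix(FALSE, nr, nc)
  wall[idx[abs(d1 - d2) <= 1]] <- TRUE
  list(mask = m, wall = wall, centers = rbind(c1, c2))
}

small_bundle <- function(seed = 1L, n_cells = 10L, size = 200L, ...) {
  generate_tissue(fixture_spec(size = c(size, size),
                               n_cells = as.integer(n_cells),
                               seed = as.integer(seed), ...))
}

# tiny label map from a list of pixel-index vectors
label_map <- function(nr, nc, objects) {
  m <- matrix(0L, nr, nc)
  for (k in seq_along(objects)) m[objects[[k]]] <- k
  m
}
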