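# Synthetic two-channel tissue images with exact instance ground truth.
# The generator emulates the content the segmentation pipeline targets:
# convex-to-mildly-nonconvex nuclei with radial intensity falloff, membrane
# rings (complete, partial, weak or absent), touching nucleus clusters that
# share membrane walls, heterogeneous per-cell intensities, and additive
# Gaussian noise.

#' Specification of a synthetic tissue fixture
#'
#' @param size Image size `c(rows, cols)` in pixels.
#' @param n_cells Number of nucleated cells.
#' @param radius_range Nucleus radius range in pixels (min 3).
#' @param eccentricity_range Axis-ratio range for single-cell nuclei
#'   (touching-cluster members are circular so that the shared-wall ground
#'   truth stays exact).
#' @param frac_pairs Fraction of nuclei placed in touching pairs.
#' @param frac_triples Fraction of nuclei placed in touching triples.
#' @param pair_distance_factor Range of centre distance, as a multiple of
#'   the nucleus radius, between touching cluster members.
#' @param cell_scale Cell radius as a multiple of its nucleus radius.
#' @param membrane_width Membrane ring width in pixels.
#' @param membrane_completeness Fraction of each ring's angular extent that
#'   is actually drawn (one random arc is deleted).
#' @param frac_membrane_free Fraction of cells drawn without any membrane
#'   ring.
#' @param frac_nucleus_free Number of additional membrane-ring-only cells
#'   (no nucleus), as a fraction of `n_cells`; these rings are complete.
#' @param intensity_jitter Amplitude of per-pixel multiplicative intensity
#'   jitter inside nuclei and rings.
#' @param noise_sd Standard deviation of additive Gaussian background noise
#'   on the normalized `[0, 1]` scale (values clipped to the range). The
#'   default emulates camera read noise of min-max normalized 16-bit
#'   fluorescence acquisitions, where background fluctuations sit well
#'   below 1% of the dynamic range.
#' @param seed RNG seed; fixes all randomness of the bundle.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(size = c(512L, 512L), n_cells = 60L,
                         radius_range = c(7, 12),
                         eccentricity_range = c(1, 1.5),
                         frac_pairs = 0.2, frac_triples = 0,
                         pair_distance_factor = c(1.5, 1.8),
                         cell_scale = 1.5, membrane_width = 3L,
                         membrane_completeness = 0.9,
                         frac_membrane_free = 0.1,
                         frac_nucleus_free = 0.05,
                         intensity_jitter = 0.1, noise_sd = 0.002,
                         seed = 0L) {
  stopifnot(length(size) == 2, all(size >= 32), n_cells >= 1,
            radius_range[1] >= 3, radius_range[2] >= radius_range[1],
            eccentricity_range[1] >= 1,
            frac_pairs >= 0, frac_pairs <= 1,
            frac_triples >= 0, frac_triples <= 1,
            frac_pairs + frac_triples <= 1,
            all(pair_distance_factor > 1), cell_scale > 1,
            membrane_width >= 1,
            membrane_completeness > 0, membrane_completeness <= 1,
            frac_membrane_free >= 0, frac_membrane_free <= 1,
            frac_nucleus_free >= 0, frac_nucleus_free <= 1,
            intensity_jitter >= 0, noise_sd >= 0)
  structure(as.list(environment()), class = "fixture_spec")
}

# squared normalized elliptical radius of grid points around a centre
ellipse_rho <- function(rows, cols, center, a, b, theta) {
  dr <- outer(rows - center[1], rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - center[2])
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  sqrt((u / a)^2 + (v / b)^2)
}

# one cluster of k equal circular nuclei with centres `centers` (k x 2);
# paints nuclei/cells/membranes into the environment matrices of `env`
paint_cluster <- function(env, centers, r, ecc, theta, ids, spec,
                          membrane_free, ring_complete) {
  k <- nrow(centers)
  a <- r; b <- r / ecc
  Rcell <- spec$cell_scale * r + spec$membrane_width + 2
  r0 <- max(1L, floor(min(centers[, 1]) - Rcell))
  r1 <- min(nrow(env$I1), ceiling(max(centers[, 1]) + Rcell))
  c0 <- max(1L, floor(min(centers[, 2]) - Rcell))
  c1 <- min(ncol(env$I1), ceiling(max(centers[, 2]) + Rcell))
  rows <- r0:r1; cols <- c0:c1
  rho <- array(0, c(length(rows), length(cols), k))
  for (j in seq_len(k))
    rho[, , j] <- ellipse_rho(rows, cols, centers[j, ], a, b, theta)
  nearest <- apply(rho, c(1, 2), which.min)
  rho_min <- apply(rho, c(1, 2), min)
  nuc_of <- ifelse(rho_min <= 1, nearest, 0L)
  cell_of <- ifelse(rho_min <= spec$cell_scale, nearest, 0L)
  # nucleus intensity: radial Gaussian falloff, per-cell peak
  peaks <- runif(k, 0.7, 0.95)
  mem_int <- runif(k, 0.5, 0.9)
  arc0 <- runif(k, -pi, pi)
  jit <- function(n) 1 + spec$intensity_jitter * runif(n, -0.5, 0.5)
  for (j in seq_len(k)) {
    sel_n <- nuc_of == j
    env$gt_n[rows, cols][sel_n] <- ids[j]
    env$I1[rows, cols][sel_n] <-
      pmax(env$I1[rows, cols][sel_n],
           peaks[j] * exp(-0.5 * (rho_min[sel_n] / 0.6)^2) *
             jit(sum(sel_n)))
    sel_c <- cell_of == j
    env$gt_c[rows, cols][sel_c] <- ids[j]
    if (!membrane_free[j]) {
      # ring: cell pixels within membrane_width of the cell edge or of the
      # shared wall with another member
      edge <- sel_c & rho[, , j] > (spec$cell_scale - spec$membrane_width / r)
      if (k > 1) {
        for (l in seq_len(k)[-j]) {
          wall <- sel_c & (rho[, , l] - rho[, , j]) * r <= spec$membrane_width
          edge <- edge | wall
        }
      }
      if (ring_complete[j] < 1) {
        ang <- atan2(outer(rows - centers[j, 1], rep(1, length(cols))),
                     outer(rep(1, length(rows)), cols - centers[j, 2]))
        gap <- (ang - arc0[j]) %% (2 * pi) >
          ring_complete[j] * 2 * pi
        # never delete shared walls, only the outer arc
        outer_only <- edge & gap
        if (k > 1)
          for (l in seq_len(k)[-j])
            outer_only <- outer_only &
              !((rho[, , l] - rho[, , j]) * r <= spec$membrane_width)
        edge <- edge & !outer_only
      }
      env$I2[rows, cols][edge] <-
        pmax(env$I2[rows, cols][edge], mem_int[j] * jit(sum(edge)))
      env$ring_px[ids[j]] <- sum(edge)
    } else {
      env$ring_px[ids[j]] <- 0L
    }
  }
  invisible(NULL)
}

#' Generate a synthetic tissue image with exact ground truth
#'
#' Places nucleated cells (singles plus touching pairs/triples that share
#' membrane walls) and optional nucleus-free membrane rings on a noisy
#' background, and returns the two-channel image together with exact
#' nucleus and cell instance ground truth. Identical specs (same seed)
#' produce identical bundles.
#'
#' @param spec A [fixture_spec()].
#' @return A `fixture_bundle`: list with `image` ([two_channel_image()]),
#'   `gt_nuclei`, `gt_cells` (integer label matrices), `info` (per-cell
#'   bookkeeping data.frame with membrane/ring metadata) and `spec`.
#' @export
generate_tissue <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  restore <- .Random.seed_exists()
  on.exit(restore())
  set.seed(spec$seed)
  nr <- spec$size[1]; nc <- spec$size[2]
  n <- spec$n_cells
  n_pairs <- floor(spec$frac_pairs * n / 2)
  n_triples <- floor(spec$frac_triples * n / 3)
  n_single <- n - 2L * n_pairs - 3L * n_triples
  n_rings <- round(spec$frac_nucleus_free * n)
  # units: each cluster/single/ring is placed with a bounding radius
  units <- list()
  for (i in seq_len(n_single)) units <- c(units, list(list(k = 1L)))
  for (i in seq_len(n_pairs)) units <- c(units, list(list(k = 2L)))
  for (i in seq_len(n_triples)) units <- c(units, list(list(k = 3L)))
  for (i in seq_len(n_rings)) units <- c(units, list(list(k = 0L)))
  # membrane-free assignment over nucleated cells
  n_mfree <- round(spec$frac_membrane_free * n)
  mfree_ids <- if (n_mfree > 0) sort(sample.int(n, n_mfree)) else integer(0)
  env <- new.env()
  env$I1 <- matrix(0, nr, nc); env$I2 <- matrix(0, nr, nc)
  env$gt_n <- matrix(0L, nr, nc); env$gt_c <- matrix(0L, nr, nc)
  env$ring_px <- integer(n + n_rings)
  placed <- matrix(numeric(0), 0, 3)  # center r, c, bounding radius
  next_id <- 0L
  info <- NULL
  for (u in units) {
    k <- u$k
    r <- runif(1, spec$radius_range[1], spec$radius_range[2])
    ecc <- if (k == 1) runif(1, spec$eccentricity_range[1],
                             spec$eccentricity_range[2]) else 1
    theta <- runif(1, 0, pi)
    fac <- runif(1, spec$pair_distance_factor[1],
                 spec$pair_distance_factor[2])
    d <- fac * r
    span <- if (k >= 2) (k - 1) * d / 2 else 0
    Rb <- spec$cell_scale * r + spec$membrane_width + span + 2
    ok <- FALSE
    for (try in seq_len(400L)) {
      ctr <- c(runif(1, Rb + 1, nr - Rb), runif(1, Rb + 1, nc - Rb))
      if (nrow(placed) == 0 ||
          all(sqrt((placed[, 1] - ctr[1])^2 + (placed[, 2] - ctr[2])^2) >=
              placed[, 3] + Rb + 2)) { ok <- TRUE; break }
    }
    if (!ok)
      stop("placement failed: cell density too high for image size ",
           nr, "x", nc, " with ", n, " cells")
    placed <- rbind(placed, c(ctr, Rb))
    if (k == 0L) {
      # nucleus-free membrane ring (complete), no nucleus label
      next_id <- next_id + 1L
      id <- next_id
      paint_ring_only(env, ctr, r, spec, id)
      info <- rbind(info, data.frame(
        id = id, kind = "ring_only", center_row = ctr[1],
        center_col = ctr[2], radius = r, membrane_free = FALSE,
        in_cluster = 0L))
    } else {
      dirv <- c(cos(theta), sin(theta))
      offs <- (seq_len(k) - (k + 1) / 2) * d
      centers <- cbind(ctr[1] + offs * dirv[1], ctr[2] + offs * dirv[2])
      ids <- next_id + seq_len(k)
      next_id <- next_id + k
      mf <- ids %in% mfree_ids
      comp <- rep(spec$membrane_completeness, k)
      paint_cluster(env, centers, r, ecc, theta, ids, spec, mf, comp)
      info <- rbind(info, data.frame(
        id = ids, kind = if (k == 1) "single" else paste0("cluster", k),
        center_row = centers[, 1], center_col = centers[, 2], radius = r,
        membrane_free = mf, in_cluster = if (k > 1) 1L else 0L))
    }
  }
  info$ring_px <- env$ring_px[info$id]
  I1 <- pmin(pmax(env$I1 + rnorm(nr * nc, 0, spec$noise_sd), 0), 1)
  I2 <- pmin(pmax(env$I2 + rnorm(nr * nc, 0, spec$noise_sd), 0), 1)
  structure(list(
    image = two_channel_image(I1, I2, normalize = FALSE),
    gt_nuclei = env$gt_n, gt_cells = env$gt_c,
    info = info, spec = spec), class = "fixture_bundle")
}

# complete membrane ring with empty interior (a cell without a nucleus)
paint_ring_only <- function(env, center, r, spec, id) {
  Rc <- spec$cell_scale * r
  r0 <- max(1L, floor(center[1] - Rc - 2))
  r1 <- min(nrow(env$I1), ceiling(center[1] + Rc + 2))
  c0 <- max(1L, floor(center[2] - Rc - 2))
  c1 <- min(ncol(env$I1), ceiling(center[2] + Rc + 2))
  rows <- r0:r1; cols <- c0:c1
  rho <- ellipse_rho(rows, cols, center, Rc, Rc, 0)
  cellm <- rho <= 1
  ring <- cellm & rho > 1 - spec$membrane_width / Rc
  env$gt_c[rows, cols][cellm] <- id
  mem_int <- runif(1, 0.6, 0.9)
  env$I2[rows, cols][ring] <- pmax(env$I2[rows, cols][ring],
                                   mem_int * (1 + spec$intensity_jitter *
                                                runif(sum(ring), -0.5, 0.5)))
  env$ring_px[id] <- sum(ring)
  invisible(NULL)
}

#' Generate a single touching-nucleus cluster fixture
#'
#' A row of `k` equal circular nuclei whose centres are
#' `center_distance_factor * radius` apart (fused for factors below 2),
#' with an optional membrane wall along the shared interfaces. Used to
#' exercise the cluster-splitting machinery on controlled geometry.
#'
#' @param k Number of nuclei (2 or 3).
#' @param radius Nucleus radius in pixels.
#' @param center_distance_factor Centre distance as a multiple of `radius`.
#' @param seed RNG seed.
#' @param membrane_wall Draw a 2-pixel membrane wall between adjacent
#'   nuclei.
#' @return A `fixture_bundle` with additional elements `nucleus_mask`
#'   (logical union of the nuclei) and `wall_mask` (logical membrane wall).
#' @export
generate_cluster <- function(k = 2L, radius = 10, center_distance_factor = 1.6,
                             seed = 0L, membrane_wall = TRUE) {
  stopifnot(k %in% c(2L, 3L), radius >= 3, center_distance_factor > 0)
  restore <- .Random.seed_exists()
  on.exit(restore())
  set.seed(seed)
  d <- center_distance_factor * radius
  margin <- ceiling(2 * radius) + 6
  nrr <- 2L * margin
  ncc <- as.integer(ceiling((k - 1) * d) + 2L * margin)
  ctr_r <- margin
  offs <- (seq_len(k) - (k + 1) / 2) * d
  centers <- cbind(rep(ctr_r, k), ncc / 2 + offs)
  rows <- seq_len(nrr); cols <- seq_len(ncc)
  rho <- array(0, c(nrr, ncc, k))
  dist_c <- array(0, c(nrr, ncc, k))
  for (j in seq_len(k)) {
    dist_c[, , j] <- sqrt(outer((rows - centers[j, 1])^2, rep(1, ncc)) +
                            outer(rep(1, nrr), (cols - centers[j, 2])^2))
    rho[, , j] <- dist_c[, , j] / radius
  }
  rho_min <- apply(rho, c(1, 2), min)
  nearest <- apply(rho, c(1, 2), which.min)
  gt_n <- matrix(0L, nrr, ncc)
  gt_n[rho_min <= 1] <- nearest[rho_min <= 1]
  nucleus_mask <- gt_n > 0
  wall <- matrix(FALSE, nrr, ncc)
  if (membrane_wall && k >= 2) {
    for (j in seq_len(k - 1)) {
      band <- abs(dist_c[, , j] - dist_c[, , j + 1]) <= 1
      wall <- wall | (band & dilate_disk(nucleus_mask, 1L))
    }
  }
  peak <- runif(k, 0.75, 0.95)
  I1 <- matrix(0, nrr, ncc)
  for (j in seq_len(k)) {
    sel <- gt_n == j
    I1[sel] <- peak[j] * exp(-0.5 * (rho_min[sel] / 0.6)^2)
  }
  I2 <- matrix(0, nrr, ncc)
  I2[wall] <- 0.8
  I1 <- pmin(pmax(I1 + rnorm(nrr * ncc, 0, 0.02), 0), 1)
  I2 <- pmin(pmax(I2 + rnorm(nrr * ncc, 0, 0.02), 0), 1)
  gt_c <- gt_n   # cluster fixtures carry no cytoplasm beyond the nuclei
  structure(list(
    image = two_channel_image(I1, I2, normalize = FALSE),
    gt_nuclei = gt_n, gt_cells = gt_c,
    nucleus_mask = nucleus_mask, wall_mask = wall,
    info = data.frame(id = seq_len(k), center_row = centers[, 1],
                      center_col = centers[, 2], radius = radius),
    spec = list(k = k, radius = radius,
                center_distance_factor = center_distance_factor,
                seed = seed, membrane_wall = membrane_wall)),
    class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("fixture_bundle: %d x %d px, %d nuclei, %d cells\n",
              nrow(x$gt_nuclei), ncol(x$gt_nuclei),
              length(unique(x$gt_nuclei[x$gt_nuclei > 0])),
              length(unique(x$gt_cells[x$gt_cells > 0]))))
  invisible(x)
}
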