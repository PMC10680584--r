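# Stage 3: parse the nucleus semantic mask into individual nuclei via
# convexity analysis, the perturbed watershed (PW) and virtual cuts (VC).

#' Steepest concave point of a connected component
#'
#' The boundary pixel with the largest Euclidean deviation from the convex
#' hull of the component, and that deviation (the concavity depth). Convex
#' shapes have depth at most about half a pixel (pixelization). Components
#' with fewer than 3 pixels get depth 0.
#'
#' @param mask Logical matrix holding one connected component.
#' @return List with `location` (row, col), `depth` (pixels) and `normal`
#'   (unit vector perpendicular to the hull edge spanning the concavity,
#'   pointing into the component).
#' @export
steepest_concave_point <- function(mask) {
  idx <- which(mask)
  if (length(idx) < 3)
    return(list(location = c((idx[1] - 1) %% nrow(mask) + 1,
                             (idx[1] - 1) %/% nrow(mask) + 1),
                depth = 0, normal = c(0, 0)))
  bnd <- which(boundary_pixels(mask))
  r <- (bnd - 1) %% nrow(mask) + 1
  c <- (bnd - 1) %/% nrow(mask) + 1
  P <- cbind(r, c)
  h <- chull(c, r)               # hull vertex indices
  if (length(h) < 3)             # collinear boundary: convex
    return(list(location = as.numeric(P[1, ]), depth = 0, normal = c(0, 0)))
  H <- P[h, , drop = FALSE]
  dp <- dist_to_polygon(P, H)
  k <- which.max(dp$dist)
  if (length(k) > 1) k <- k[1]
  a <- H[dp$edge[k], ]
  b <- H[if (dp$edge[k] == nrow(H)) 1L else dp$edge[k] + 1L, ]
  ab <- b - a
  nrm <- c(-ab[2], ab[1])
  len <- sqrt(sum(nrm^2))
  nrm <- if (len > 0) nrm / len else c(0, 0)
  # orient the normal to point from the hull edge towards the SCP (interior)
  if (sum(nrm * (P[k, ] - a)) < 0) nrm <- -nrm
  list(location = as.numeric(P[k, ]), depth = dp$dist[k], normal = nrm)
}

#' Convexity analysis of nucleus-mask components
#'
#' Classifies each connected component of the semantic nucleus mask:
#' components with area at most `a0` are discarded; components whose
#' steepest-concave-point depth exceeds `d0` are nucleus clusters (`"NC"`)
#' to be split; the rest are nucleus candidates, and candidates with area
#' below `sc_area_factor` times the median candidate area are flagged as
#' small components (`"SC"`).
#'
#' @param Mnuc Logical nucleus semantic mask.
#' @param params An [unseg_params()] object.
#' @return A data.frame with columns `id`, `area`, `scp_depth`,
#'   `class` (one of `"discarded"`, `"nucleus"`, `"NC"`, `"SC"`), plus the
#'   label matrix as attribute `"labels"`.
#' @export
convexity_analysis <- function(Mnuc, params = unseg_params()) {
  lab <- cc_label(Mnuc, 8L)
  n <- max(lab)
  if (n == 0) {
    df <- data.frame(id = integer(), area = integer(), scp_depth = numeric(),
                     class = character())
    attr(df, "labels") <- lab
    return(df)
  }
  area <- tabulate(lab[lab > 0], nbins = n)
  depth <- numeric(n)
  cls <- character(n)
  for (i in seq_len(n)) {
    if (area[i] <= params$a0) { cls[i] <- "discarded"; next }
    bb <- mask_bbox(lab == i, pad = 1L)
    m <- lab[bb$r0:bb$r1, bb$c0:bb$c1] == i
    depth[i] <- steepest_concave_point(m)$depth
    cls[i] <- if (depth[i] > params$d0) "NC" else "nucleus"
  }
  cand <- which(cls == "nucleus")
  if (length(cand) > 1) {
    med <- median(area[cand])
    cls[cand[area[cand] < params$sc_area_factor * med]] <- "SC"
  }
  df <- data.frame(id = seq_len(n), area = area, scp_depth = depth, class = cls)
  attr(df, "labels") <- lab
  df
}

# seed per labelled region at the DT argmax; ties broken by smallest
# (row, col) lexicographically. Returns n x 2 matrix of (row, col).
seed_argmax <- function(DT, regs, n) {
  idx <- which(regs > 0)
  r <- (idx - 1) %% nrow(DT) + 1
  c <- (idx - 1) %/% nrow(DT) + 1
  l <- regs[idx]
  o <- order(l, -DT[idx], r, c)
  first <- o[!duplicated(l[o])]
  m <- matrix(0L, n, 2)
  m[l[first], ] <- cbind(r[first], c[first])
  m
}

# core of the perturbed watershed, operating on (cropped) matrices
pw_core <- function(mask, membrane, params) {
  cut <- if (is.null(membrane)) mask else mask & !membrane
  if (!any(cut)) {
    warning("membrane cuts removed the whole component; using the uncut mask")
    cut <- mask
  }
  DT <- distmap_euclid(cut)
  d_avr <- mean(DT[DT > 0])
  s <- floor(d_avr)
  regs <- cc_label(DT >= d_avr, 8L)
  n <- max(regs)
  if (n <= 1 || s < 1)
    return(list(masks = list(mask), n_initial = max(1L, n),
                n_final = 1L, d_avr = d_avr))
  seeds_rc <- seed_argmax(DT, regs, n)
  seedmat <- matrix(0L, nrow(mask), ncol(mask))
  seedmat[seeds_rc] <- seq_len(n)
  prio <- -DT
  unstable <- rep(FALSE, n)
  shifts <- rbind(c(0L, -s), c(0L, s), c(-s, 0L), c(s, 0L))
  for (k in 1:4) {
    sh <- sweep(seeds_rc, 2, shifts[k, ], "+")
    inb <- sh[, 1] >= 1 & sh[, 1] <= nrow(mask) &
      sh[, 2] >= 1 & sh[, 2] <= ncol(mask)
    inmask <- inb
    inmask[inb] <- cut[sh[inb, , drop = FALSE]]
    unstable <- unstable | !inmask       # seed pushed off the mask collapses
    ok <- which(inmask)
    if (!length(ok)) next
    sm <- matrix(0L, nrow(mask), ncol(mask))
    sm[sh[ok, , drop = FALSE]] <- ok
    labk <- seeded_flood_cpp(prio, sm, cut)
    areas <- tabulate(labk[labk > 0], nbins = n)
    unstable[ok] <- unstable[ok] | areas[ok] <= params$collapse_area
  }
  surv <- which(!unstable)
  if (!length(surv))
    return(list(masks = list(mask), n_initial = n, n_final = 1L, d_avr = d_avr))
  sm <- matrix(0L, nrow(mask), ncol(mask))
  sm[seeds_rc[surv, , drop = FALSE]] <- seq_along(surv)
  fin <- seeded_flood_cpp(prio, sm, cut)
  if (any(mask & !cut)) {
    # membrane-cut pixels rejoin the nearest (geodesic BFS) final region so
    # the sub-masks partition the original component
    fin <- seeded_flood_cpp(matrix(0, nrow(mask), ncol(mask)), fin, mask)
  }
  masks <- lapply(seq_along(surv), function(l) fin == l)
  masks <- masks[vapply(masks, any, logical(1))]
  list(masks = masks, n_initial = n, n_final = length(masks), d_avr = d_avr)
}

#' Perturbed watershed
#'
#' Splits a non-convex component (a putative nucleus cluster) into
#' sub-regions by marker-controlled watershed on the negated distance
#' transform, with a stability test: all seeds are shifted simultaneously by
#' plus/minus `floor(d_avr)` pixels horizontally and vertically (`d_avr` is
#' the mean non-zero distance-transform value), and any seed whose region
#' collapses to at most `collapse_area` pixels in any shift (or whose
#' shifted position leaves the mask) is spurious and removed. The final
#' watershed runs on the unperturbed distance transform with the surviving
#' seeds. Optional membrane evidence first cuts the mask; cut pixels are
#' reassigned to the nearest final sub-region so the output partitions the
#' input. The routine is agnostic to the imaging modality: it applies to any
#' binary mask plus optional cut mask.
#'
#' @param nc_mask Logical matrix holding one connected component.
#' @param membrane_local Optional logical matrix of cut evidence (e.g. the
#'   local membrane semantic mask), same shape.
#' @param params An [unseg_params()] object.
#' @return List of logical sub-region masks (same shape as `nc_mask`)
#'   partitioning it, with attributes `n_initial` (seed count before
#'   perturbation) and `d_avr`.
#' @export
perturbed_watershed <- function(nc_mask, membrane_local = NULL,
                                params = unseg_params()) {
  stopifnot(any(nc_mask))
  bb <- mask_bbox(nc_mask, pad = 2L)
  m <- nc_mask[bb$r0:bb$r1, bb$c0:bb$c1]
  mem <- if (is.null(membrane_local)) NULL else
    membrane_local[bb$r0:bb$r1, bb$c0:bb$c1]
  res <- pw_core(m, mem, params)
  out <- lapply(res$masks, function(sub) {
    full <- matrix(FALSE, nrow(nc_mask), ncol(nc_mask))
    full[bb$r0:bb$r1, bb$c0:bb$c1] <- sub
    full
  })
  stopifnot(length(out) <= res$n_initial)   # PW can only remove seeds
  attr(out, "n_initial") <- res$n_initial
  attr(out, "d_avr") <- res$d_avr
  out
}

# rasterize a straight line through point p (row, col) along unit direction
# v, both ways, until leaving the mask; supercover stepping (half-pixel
# increments) so the cut blocks 8-connectivity
trace_cut_line <- function(mask, p, v) {
  nr <- nrow(mask); nc <- ncol(mask)
  pix <- integer(0)
  for (sgn in c(1, -1)) {
    t <- 0
    repeat {
      rr <- round(p[1] + sgn * t * v[1])
      cc <- round(p[2] + sgn * t * v[2])
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) break
      if (!mask[rr, cc] && t > 1) break
      pix <- c(pix, (cc - 1L) * nr + rr)
      t <- t + 0.5
    }
  }
  unique(pix)
}

# core of virtual cuts on a cropped mask; returns list of 2 masks or NULL
vc_core <- function(mask, params) {
  scp <- steepest_concave_point(mask)
  if (scp$depth <= 1)   # sub-pixel deviation: convex up to pixelization
    stop("virtual cuts requires a non-convex component")
  if (sum(scp$normal^2) == 0) return(NULL)
  cutpix <- trace_cut_line(mask, scp$location, scp$normal)
  cutmask <- mask
  cutmask[cutpix] <- FALSE
  comps <- cc_label(cutmask, 8L)
  ncomp <- max(comps)
  if (ncomp < 2) return(NULL)
  areas <- tabulate(comps[comps > 0], nbins = ncomp)
  top2 <- order(areas, decreasing = TRUE)[1:2]
  if (min(areas[top2]) < 1) return(NULL)
  DTcut <- distmap_euclid(cutmask)
  sel <- matrix(0L, nrow(mask), ncol(mask))
  sel[comps == top2[1]] <- 1L
  sel[comps == top2[2]] <- 2L
  seeds_rc <- seed_argmax(DTcut, sel, 2L)
  DT <- distmap_euclid(mask)
  sm <- matrix(0L, nrow(mask), ncol(mask))
  sm[seeds_rc] <- 1:2
  fin <- seeded_flood_cpp(-DT, sm, mask)
  out <- list(fin == 1L, fin == 2L)
  if (!any(out[[1]]) || !any(out[[2]])) return(NULL)
  out
}

#' Virtual cuts
#'
#' Fallback splitter for a non-convex component that the perturbed watershed
#' left whole (typically when no membrane evidence cuts the cluster and the
#' distance-transform threshold yields a single seed). A virtual cut line is
#' drawn through the steepest concave point, perpendicular to the convex-hull
#' chord spanning the concavity; the two virtual sub-regions it creates
#' contribute one watershed seed each (their internal distance-transform
#' maxima), and the actual watershed then runs on the *uncut* mask with
#' those two seeds.
#'
#' @param nc_mask Logical matrix holding one non-convex connected component.
#' @param params An [unseg_params()] object.
#' @return List of two logical sub-region masks, or `NULL` when the cut
#'   fails to split the component (degenerate geometry).
#' @export
virtual_cuts <- function(nc_mask, params = unseg_params()) {
  stopifnot(any(nc_mask))
  bb <- mask_bbox(nc_mask, pad = 2L)
  m <- nc_mask[bb$r0:bb$r1, bb$c0:bb$c1]
  res <- vc_core(m, params)
  if (is.null(res)) return(NULL)
  lapply(res, function(sub) {
    full <- matrix(FALSE, nrow(nc_mask), ncol(nc_mask))
    full[bb$r0:bb$r1, bb$c0:bb$c1] <- sub
    full
  })
}

# recursive splitting of one component (cropped); returns list of local
# pixel-index vectors (within the crop) accepted as nucleus candidates
split_component <- function(mask, membrane, params, depth) {
  area <- sum(mask)
  if (area <= params$a0) return(list())
  scp_depth <- steepest_concave_point(mask)$depth
  if (scp_depth <= params$d0 || depth >= params$max_recursion)
    return(list(which(mask)))
  subs <- pw_core(mask, membrane, params)$masks
  if (length(subs) == 1) {
    vc <- tryCatch(vc_core(mask, params), error = function(e) NULL)
    if (!is.null(vc)) subs <- vc
  }
  if (length(subs) == 1) return(list(which(mask)))
  out <- list()
  for (sub in subs) {
    if (sum(sub) >= area) {      # no strict decrease: accept to terminate
      out <- c(out, list(which(sub)))
    } else {
      out <- c(out, split_component(sub, membrane, params, depth + 1L))
    }
  }
  out
}

# morphological boundary smoothing (closing then opening) of one instance;
# returns the smoothed local mask, or NULL when smoothing degenerates
smooth_instance <- function(mask, r) {
  if (r < 1) return(mask)
  sm <- erode_disk(dilate_disk(mask, r), r)   # closing
  sm <- dilate_disk(erode_disk(sm, r), r)     # opening
  if (!any(sm)) return(NULL)
  if (max(cc_label(sm, 8L)) > 1) return(NULL) # smoothing must not split
  sm
}

#' Segment nuclei from semantic label maps
#'
#' Orchestrates Stage 3: connected components of the global nucleus class
#' undergo convexity analysis; nucleus clusters are split recursively by the
#' perturbed watershed (with cuts from the local membrane class) and, when
#' that fails, by virtual cuts; small components are kept only when
#' isolated; and each final instance gets morphological boundary smoothing,
#' with overlaps resolved by distance competition. Labels are assigned
#' 1..N in raster order.
#'
#' @param Mg Integer global semantic label map (0/1/2).
#' @param Ml Integer local semantic label map (0/1/2).
#' @param params An [unseg_params()] object.
#' @return Integer nucleus instance label matrix.
#' @export
segment_nuclei <- function(Mg, Ml, params = unseg_params()) {
  nr <- nrow(Mg); nc <- ncol(Mg)
  Mnuc <- Mg == 1L
  Mcell_l <- Ml == 2L
  out <- matrix(0L, nr, nc)
  if (!any(Mnuc)) return(out)
  lab <- cc_label(Mnuc, 8L)
  n <- max(lab)
  areas <- tabulate(lab[lab > 0], nbins = n)
  cand <- list()    # global pixel-index vectors
  for (i in seq_len(n)) {
    if (areas[i] <= params$a0) next
    bb <- mask_bbox(lab == i, pad = 2L)
    m <- lab[bb$r0:bb$r1, bb$c0:bb$c1] == i
    mem <- Mcell_l[bb$r0:bb$r1, bb$c0:bb$c1]
    pieces <- split_component(m, mem, params, 0L)
    for (p in pieces) {
      loc <- matrix(FALSE, nrow(m), ncol(m)); loc[p] <- TRUE
      cand <- c(cand, list(local_to_global(loc, bb, nr)))
    }
  }
  if (!length(cand)) return(out)
  carea <- vapply(cand, length, integer(1))
  keep_area <- carea > params$a0
  cand <- cand[keep_area]; carea <- carea[keep_area]
  if (!length(cand)) return(out)
  # small-component handling: small candidates are kept only when isolated
  med <- median(carea)
  is_sc <- carea < params$sc_area_factor * med
  accepted <- matrix(0L, nr, nc)
  for (j in which(!is_sc)) accepted[cand[[j]]] <- j
  keep <- rep(TRUE, length(cand))
  for (j in which(is_sc)) {
    m <- matrix(FALSE, nr, nc); m[cand[[j]]] <- TRUE
    halo <- dilate_disk(m, params$sc_isolation_px)
    if (any(accepted[halo] != 0L & accepted[halo] != j)) keep[j] <- FALSE
  }
  cand <- cand[keep]
  # boundary smoothing with distance competition for contested pixels
  final <- matrix(0L, nr, nc)
  orig_of <- vector("list", length(cand))
  for (j in seq_along(cand)) final[cand[[j]]] <- j
  if (params$smoothing_radius >= 1) {
    added_px <- integer(0); added_j <- integer(0)
    for (j in seq_along(cand)) {
      m <- matrix(FALSE, nr, nc); m[cand[[j]]] <- TRUE
      bb <- mask_bbox(m, pad = params$smoothing_radius + 1L)
      loc <- m[bb$r0:bb$r1, bb$c0:bb$c1]
      sm <- smooth_instance(loc, params$smoothing_radius)
      if (is.null(sm)) next
      final[local_to_global(loc & !sm, bb, nr)] <- 0L     # opening removals
      add <- local_to_global(sm & !loc, bb, nr)
      added_px <- c(added_px, add)
      added_j <- c(added_j, rep.int(j, length(add)))
    }
    # closing additions: pixels still free go to their claimant; pixels
    # claimed by several smoothed instances go to the nearest original one
    if (length(added_px)) {
      free <- final[added_px] == 0L
      added_px <- added_px[free]; added_j <- added_j[free]
      ndup <- !(duplicated(added_px) | duplicated(added_px, fromLast = TRUE))
      final[added_px[ndup]] <- added_j[ndup]
      for (px in unique(added_px[!ndup])) {
        js <- added_j[added_px == px]
        pr <- (px - 1) %% nr + 1; pc <- (px - 1) %/% nr + 1
        dbest <- Inf; jbest <- js[1]
        for (j in js) {
          q <- cand[[j]]
          dj <- min(((q - 1) %% nr + 1 - pr)^2 + ((q - 1) %/% nr + 1 - pc)^2)
          if (dj < dbest) { dbest <- dj; jbest <- j }
        }
        final[px] <- jbest
      }
    }
  }
  # enforce 8-connectivity per id (smoothing interactions can strand pixels)
  final <- enforce_connected(final)
  relabel_raster(final)
}

# keep only the largest 8-connected piece of each instance
enforce_connected <- function(lab) {
  ids <- unique(lab[lab > 0])
  for (i in ids) {
    m <- lab == i
    cc <- cc_label(m, 8L)
    k <- max(cc)
    if (k > 1) {
      a <- tabulate(cc[cc > 0], nbins = k)
      main <- which.max(a)
      lab[m & cc != main] <- 0L
    }
  }
  lab
}
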