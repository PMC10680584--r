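# Stage 4: segment cells by expanding each nucleus to its membrane, with a
# dilation fallback for nuclei lacking membrane support, plus detection of
# membrane-delimited cells that contain no nucleus.

#' Expand nuclei to cells
#'
#' Each cell is initialized as its nucleus and grown outward by multi-source
#' shortest-path (geodesic) competition: the cost of entering a pixel is its
#' step length times `1 + membrane_cost_beta * P2g`, so growth is cheap
#' through membrane-free tissue and expensive across membrane evidence, and
#' competing cells meet along membrane walls. Growth stops at a geodesic
#' budget of `u0`, which for nuclei without nearby membrane reduces to the
#' morphological `u0`-dilation (clipped against neighbours). For
#' membrane-supported nuclei (at least `membrane_support_frac` of the
#' 10-degree angular sectors around the nucleus contain membrane evidence
#' within `u0 + 2` pixels of its boundary), the membrane wall adjacent to
#' the claimed territory is attached to the cell, so the cell boundary
#' coincides with the far side of its membrane.
#'
#' @param nuclei Integer nucleus instance label matrix.
#' @param Mcell_g Logical global membrane mask.
#' @param P2g Posterior membrane probability matrix.
#' @param params An [unseg_params()] object.
#' @return Integer cell label matrix (same ids as `nuclei`), with a
#'   data.frame attribute `"records"` holding `cell_id`, `nucleus_id`,
#'   `origin` (`"expanded"` or `"dilated_fallback"`).
#' @export
expand_nuclei_to_cells <- function(nuclei, Mcell_g, P2g,
                                   params = unseg_params()) {
  nr <- nrow(nuclei); nc <- ncol(nuclei)
  ids <- sort(unique(nuclei[nuclei > 0]))
  cells <- matrix(0L, nr, nc)
  rec <- data.frame(cell_id = integer(), nucleus_id = integer(),
                    origin = character())
  if (!length(ids)) {
    attr(cells, "records") <- rec
    return(cells)
  }
  nucbin <- nuclei > 0
  domain <- dilate_disk(nucbin, params$u0)
  w <- 1 + params$membrane_cost_beta * P2g
  gf <- geodesic_flood_cpp(w, nuclei, domain)
  origin <- character(length(ids))
  for (k in seq_along(ids)) {
    i <- ids[k]
    m <- nuclei == i
    bb <- mask_bbox(m, pad = params$u0 + 3L)
    loc_n <- m[bb$r0:bb$r1, bb$c0:bb$c1]
    loc_lab <- gf$labels[bb$r0:bb$r1, bb$c0:bb$c1] == i
    loc_cost <- gf$cost[bb$r0:bb$r1, bb$c0:bb$c1]
    loc_mem <- Mcell_g[bb$r0:bb$r1, bb$c0:bb$c1]
    support <- membrane_angular_support(loc_n, loc_mem, params$u0 + 2L)
    if (support >= params$membrane_support_frac) {
      core <- (loc_lab & loc_cost <= params$u0 & !loc_mem) | loc_n
      # attach the adjacent membrane wall (restricted to own territory)
      seeds2 <- matrix(0L, nrow(loc_n), ncol(loc_n)); seeds2[core] <- 1L
      zero <- matrix(0, nrow(loc_n), ncol(loc_n))
      cell_loc <- seeded_flood_cpp(zero, seeds2,
                                   core | (loc_lab & loc_mem)) > 0
      origin[k] <- "expanded"
    } else {
      cell_loc <- (loc_lab & dilate_disk(loc_n, params$u0)) | loc_n
      origin[k] <- "dilated_fallback"
    }
    cells[local_to_global(cell_loc, bb, nr)] <- i
  }
  # territory competition guarantees disjointness; nuclei stay put
  cells[nucbin] <- nuclei[nucbin]
  attr(cells, "records") <- data.frame(cell_id = ids, nucleus_id = ids,
                                       origin = origin)
  cells
}

# fraction of 10-degree angular sectors around the nucleus centroid whose
# annulus (between the nucleus boundary and its r-dilation) contains
# membrane evidence
membrane_angular_support <- function(nuc, mem, r, n_sectors = 36L) {
  ann <- dilate_disk(nuc, r) & !nuc & mem
  if (!any(ann)) return(0)
  idx <- which(nuc)
  cr <- mean((idx - 1) %% nrow(nuc) + 1)
  cc <- mean((idx - 1) %/% nrow(nuc) + 1)
  aidx <- which(ann)
  ang <- atan2((aidx - 1) %% nrow(nuc) + 1 - cr,
               (aidx - 1) %/% nrow(nuc) + 1 - cc)
  sect <- floor((ang + pi) / (2 * pi) * n_sectors) %% n_sectors
  length(unique(sect)) / n_sectors
}

#' Detect nucleus-free cells from the membrane mask
#'
#' A tissue section can contain a cell membrane contour without its nucleus.
#' The skeleton of the global membrane mask reduces every membrane band to a
#' one-pixel centreline whose closed loops are cell membrane contours: a
#' skeleton component that is a single closed contour has Euler number 0
#' (it encloses exactly one hole), and a network component encloses one hole
#' per delimited cell. Each enclosed hole, filled and joined with its
#' adjacent membrane band, is a candidate cell; it is emitted when its area
#' exceeds half the mean nucleus area and its overlap with already-segmented
#' cells stays below `nucleus_free_overlap` of its area.
#'
#' @param Mcell_g Logical global membrane mask.
#' @param existing_cells Integer cell label matrix from
#'   [expand_nuclei_to_cells()].
#' @param mean_nucleus_area Mean nucleus area in pixels (use
#'   `params$default_nucleus_area` when no nuclei exist).
#' @param params An [unseg_params()] object.
#' @return List of logical masks, one per nucleus-free cell.
#' @export
detect_nucleus_free_cells <- function(Mcell_g, existing_cells,
                                      mean_nucleus_area,
                                      params = unseg_params()) {
  stopifnot(mean_nucleus_area > 0)
  out <- list()
  if (!any(Mcell_g)) return(out)
  skel <- skeletonize(Mcell_g)
  if (!any(skel)) return(out)
  lab <- cc_label(skel, 8L)
  n <- max(lab)
  cands <- list(); careas <- numeric(0)
  for (i in seq_len(n)) {
    m <- lab == i
    bb <- mask_bbox(m, pad = 4L)
    loc <- m[bb$r0:bb$r1, bb$c0:bb$c1]
    filled <- as.matrix(EBImage::fillHull(
      matrix(as.numeric(loc), nrow(loc)))) > 0
    holes <- filled & !loc
    if (!any(holes)) next                    # open arcs enclose nothing
    hl <- cc_label(holes, 4L)
    mem_loc <- Mcell_g[bb$r0:bb$r1, bb$c0:bb$c1]
    for (h in seq_len(max(hl))) {
      hole <- hl == h
      cand <- hole | (dilate_disk(hole, 3L) & mem_loc)
      ca <- sum(cand)
      if (ca <= mean_nucleus_area / 2) next
      cands[[length(cands) + 1L]] <- list(bb = bb, m = cand)
      careas <- c(careas, ca)
    }
  }
  if (!length(cands)) return(out)
  taken <- existing_cells > 0
  for (i in order(careas)) {                 # inner contours first
    f <- cands[[i]]
    full <- matrix(FALSE, nrow(Mcell_g), ncol(Mcell_g))
    full[f$bb$r0:f$bb$r1, f$bb$c0:f$bb$c1] <- f$m
    ov <- sum(full & taken) / sum(full)
    if (ov >= params$nucleus_free_overlap) next
    out[[length(out) + 1L]] <- full
    taken <- taken | full
  }
  out
}

#' Segment cells
#'
#' Stage-4 orchestration: expands every nucleus to its cell, adds
#' nucleus-free membrane-delimited cells, and relabels the union 1..N in
#' raster order. Nucleus-free cells only occupy pixels not already claimed
#' by nucleated cells, so cells stay pairwise disjoint and every nucleus
#' lies inside exactly one cell.
#'
#' @param nuclei Integer nucleus instance label matrix.
#' @param Mg Integer global semantic label map (0/1/2).
#' @param P2g Posterior membrane probability matrix.
#' @param params An [unseg_params()] object.
#' @return Integer cell label matrix with a data.frame attribute
#'   `"records"` (`cell_id`, `nucleus_id` with 0 for nucleus-free cells,
#'   `origin`).
#' @export
segment_cells <- function(nuclei, Mg, P2g, params = unseg_params()) {
  Mcell_g <- Mg == 2L
  cells <- expand_nuclei_to_cells(nuclei, Mcell_g, P2g, params)
  rec <- attr(cells, "records")
  n_areas <- tabulate(nuclei[nuclei > 0])
  mean_area <- if (any(n_areas > 0)) mean(n_areas[n_areas > 0]) else
    params$default_nucleus_area
  extra <- detect_nucleus_free_cells(Mcell_g, cells, mean_area, params)
  next_id <- if (nrow(rec)) max(rec$cell_id) else 0L
  for (m in extra) {
    next_id <- next_id + 1L
    cells[m & cells == 0L] <- next_id
    rec <- rbind(rec, data.frame(cell_id = next_id, nucleus_id = 0L,
                                 origin = "membrane_only"))
  }
  out <- relabel_raster(cells)
  # remap record ids after relabelling
  if (nrow(rec)) {
    old_ids <- unique(cells[cells > 0])    # raster order, matches relabel
    map <- match(rec$cell_id, old_ids)
    rec$cell_id <- map
    rec <- rec[!is.na(rec$cell_id), , drop = FALSE]
    rec <- rec[order(rec$cell_id), , drop = FALSE]
    rownames(rec) <- NULL
  }
  attr(out, "records") <- rec
  out
}
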