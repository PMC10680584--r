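# Small geometry / morphology utilities shared by the instance-parsing
# stages. All masks are logical matrices indexed (row, col).

#' Label connected components
#'
#' Components are numbered 1..N in raster order of their first pixel.
#'
#' @param mask Logical matrix.
#' @param conn Connectivity, 4 or 8 (default 8).
#' @return Integer label matrix.
#' @export
cc_label <- function(mask, conn = 8L) {
  cc_label_cpp(mask, as.integer(conn))
}

# Euclidean distance transform (distance of foreground pixels to the
# nearest background pixel). Foreground touching no background (all-ones
# mask) gets distances from EBImage's border convention.
distmap_euclid <- function(mask) {
  if (!any(mask)) return(matrix(0, nrow(mask), ncol(mask)))
  as.matrix(EBImage::distmap(matrix(as.numeric(mask), nrow(mask))))
}

disk_brush <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, "disc")

dilate_disk <- function(mask, r) {
  if (r < 1) return(mask)
  as.matrix(EBImage::dilate(matrix(as.numeric(mask), nrow(mask)), disk_brush(r))) > 0
}

erode_disk <- function(mask, r) {
  if (r < 1) return(mask)
  as.matrix(EBImage::erode(matrix(as.numeric(mask), nrow(mask)), disk_brush(r))) > 0
}

# bounding box of TRUE pixels, padded and clipped to the matrix
mask_bbox <- function(mask, pad = 1L) {
  idx <- which(mask)
  r <- (idx - 1L) %% nrow(mask) + 1L
  c <- (idx - 1L) %/% nrow(mask) + 1L
  list(r0 = max(1L, min(r) - pad), r1 = min(nrow(mask), max(r) + pad),
       c0 = max(1L, min(c) - pad), c1 = min(ncol(mask), max(c) + pad))
}

# convert local (cropped) TRUE pixels back to global linear indices
local_to_global <- function(local_mask, bb, nr_global) {
  idx <- which(local_mask)
  r <- (idx - 1L) %% nrow(local_mask) + bb$r0
  c <- (idx - 1L) %/% nrow(local_mask) + bb$c0
  (c - 1L) * nr_global + r
}

# boundary pixels: foreground with a 4-neighbour outside the mask (image
# border counts as outside)
boundary_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  inner <- p[2:(nr + 1L), 2:(nc + 1L)]
  full4 <- p[1:nr, 2:(nc + 1L)] & p[3:(nr + 2L), 2:(nc + 1L)] &
    p[2:(nr + 1L), 1:nc] & p[2:(nr + 1L), 3:(nc + 2L)]
  inner & !full4
}

# min distance from each point (rows of P, (r,c)) to the polygon through
# hull vertices H (closed); returns list(dist, edge) with the nearest edge
# index per point
dist_to_polygon <- function(P, H) {
  n <- nrow(H)
  d <- rep(Inf, nrow(P)); e <- rep(1L, nrow(P))
  for (k in seq_len(n)) {
    a <- H[k, ]; b <- H[if (k == n) 1L else k + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      dk <- sqrt((P[, 1] - a[1])^2 + (P[, 2] - a[2])^2)
    } else {
      t <- ((P[, 1] - a[1]) * ab[1] + (P[, 2] - a[2]) * ab[2]) / len2
      t <- pmin(pmax(t, 0), 1)
      dk <- sqrt((P[, 1] - (a[1] + t * ab[1]))^2 +
                 (P[, 2] - (a[2] + t * ab[2]))^2)
    }
    upd <- dk < d
    d[upd] <- dk[upd]; e[upd] <- k
  }
  list(dist = d, edge = e)
}

# count holes of a single-component mask: connected components (4-conn) of
# the filled interior minus the mask
count_holes <- function(mask, hole_conn = 4L) {
  filled <- as.matrix(EBImage::fillHull(matrix(as.numeric(mask), nrow(mask)))) > 0
  holes <- filled & !mask
  if (!any(holes)) return(list(n = 0L, filled = filled))
  list(n = max(cc_label(holes, hole_conn)), filled = filled)
}

#' Skeletonize a binary mask
#'
#' Topological thinning (Zhang-Suen) to a one-pixel-wide, 8-connected
#' skeleton.
#'
#' @param mask Logical matrix.
#' @return Logical matrix.
#' @export
skeletonize <- function(mask) {
  skeletonize_cpp(mask)
}

#' Euler number of a binary region
#'
#' Computed as (number of 8-connected components) minus (number of
#' 4-connected holes). A single closed contour enclosing one hole has Euler
#' number 0.
#'
#' @param mask Logical matrix.
#' @return Integer.
#' @export
euler_number <- function(mask) {
  if (!any(mask)) return(0L)
  ncomp <- max(cc_label(mask, 8L))
  filled <- as.matrix(EBImage::fillHull(matrix(as.numeric(mask), nrow(mask)))) > 0
  holes <- filled & !mask
  nholes <- if (any(holes)) max(cc_label(holes, 4L)) else 0L
  as.integer(ncomp - nholes)
}
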