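#' Two-channel image container
#'
#' Pairs a nucleus-marker channel and a cell-membrane-marker channel defined
#' over the same pixel lattice. Channels are stored as numeric matrices in
#' `[0, 1]`, indexed `(row, col)` with the origin at the top-left.
#'
#' @param I1 Numeric matrix, nucleus channel.
#' @param I2 Numeric matrix, membrane channel, same dimensions as `I1`.
#' @param pixel_pitch Optional micrometers-per-pixel metadata.
#' @param normalize If `TRUE` (default), each channel is independently
#'   min-max normalized to `[0, 1]`; a constant channel maps to all zeros.
#' @return An object of class `two_channel_image` with elements `I1`, `I2`,
#'   `pixel_pitch`.
#' @export
two_channel_image <- function(I1, I2, pixel_pitch = NA_real_, normalize = TRUE) {
  I1 <- as.matrix(I1); I2 <- as.matrix(I2)
  if (!identical(dim(I1), dim(I2)))
    stop("channel shapes differ: ", paste(dim(I1), collapse = "x"), " vs ",
         paste(dim(I2), collapse = "x"))
  if (anyNA(I1) || anyNA(I2)) stop("channels must not contain missing values")
  if (normalize) {
    I1 <- normalize_channel(I1)
    I2 <- normalize_channel(I2)
  } else if (min(I1) < 0 || max(I1) > 1 || min(I2) < 0 || max(I2) > 1) {
    stop("channels must lie in [0,1] when normalize = FALSE")
  }
  structure(list(I1 = I1, I2 = I2, pixel_pitch = pixel_pitch),
            class = "two_channel_image")
}

#' @export
print.two_channel_image <- function(x, ...) {
  cat(sprintf("two_channel_image: %d x %d px, pixel pitch %s um/px\n",
              nrow(x$I1), ncol(x$I1),
              ifelse(is.na(x$pixel_pitch), "unknown", format(x$pixel_pitch))))
  invisible(x)
}

#' Min-max normalize one channel to [0, 1]
#'
#' A constant channel maps to all zeros so the pipeline stays total on
#' degenerate input. Normalizing an already-normalized channel is a no-op.
#'
#' @param I Numeric matrix.
#' @return Numeric matrix in `[0, 1]`.
#' @export
normalize_channel <- function(I) {
  rng <- range(I)
  if (rng[2] <= rng[1]) return(matrix(0, nrow(I), ncol(I)))
  (I - rng[1]) / (rng[2] - rng[1])
}

#' Load a two-channel image from TIFF file(s)
#'
#' Accepts either a single multi-plane TIFF (with `nucleus_index` and
#' `membrane_index` selecting 0-based planes) or a character vector of two
#' single-plane TIFFs, in which case the indices select within that pair.
#' Each channel is independently min-max normalized to `[0, 1]`.
#'
#' @param path_or_paths One multi-plane TIFF path, or two single-plane paths.
#' @param nucleus_index 0-based plane index of the nucleus channel.
#' @param membrane_index 0-based plane index of the membrane channel.
#' @param pixel_pitch Optional micrometers-per-pixel metadata.
#' @return A [two_channel_image()].
#' @export
load_two_channel_image <- function(path_or_paths, nucleus_index = 0L,
                                   membrane_index = 1L, pixel_pitch = NA_real_) {
  for (p in path_or_paths)
    if (!file.exists(p)) stop("file not found: ", p)
  planes <- list()
  for (p in path_or_paths) {
    img <- tiff::readTIFF(p, all = TRUE)
    if (!is.list(img)) img <- list(img)
    for (pl in img) {
      if (length(dim(pl)) == 3) {          # collapse RGB-style planes
        pl <- pl[, , 1]
      }
      planes[[length(planes) + 1L]] <- pl
    }
  }
  idx <- c(nucleus_index, membrane_index) + 1L
  if (any(idx < 1L) || any(idx > length(planes)))
    stop("channel index out of range: file provides ", length(planes), " plane(s)")
  I1 <- planes[[idx[1]]]; I2 <- planes[[idx[2]]]
  if (!identical(dim(I1), dim(I2)))
    stop("selected planes have mismatched shapes")
  two_channel_image(I1, I2, pixel_pitch = pixel_pitch, normalize = TRUE)
}

#' Write a label image as TIFF
#'
#' Labels up to 65535 are written as 16-bit; larger ids promote the file to
#' 32-bit float samples with a warning. Reading back with
#' [read_label_tiff()] reproduces the label matrix exactly.
#'
#' @param labels Integer matrix of non-negative object ids (0 = background).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  labels <- as.matrix(labels)
  mx <- max(labels)
  if (mx > 65535) {
    warning("label ids exceed 65535; writing 32-bit TIFF")
    tiff::writeTIFF(labels / (2^32 - 1), path, bits.per.sample = 32)
  } else {
    tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16)
  }
  invisible(path)
}

#' Read a label image written by [write_label_tiff()]
#'
#' @param path TIFF path.
#' @return Integer matrix of object ids.
#' @export
read_label_tiff <- function(path) {
  x <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(x)) == 3) x <- x[, , 1]
  if (is.double(x) && max(abs(x - round(x))) > 0) {
    # 16-bit files read with as.is give integers; float files give the ids
    x <- round(x)
  }
  storage.mode(x) <- "integer"
  x
}

#' Build the object table for a pair of label maps
#'
#' One row per object: id, kind (`"nucleus"` or `"cell"`), area, centroid
#' (0-based row/col), and the matched id in the other map (the cell
#' containing a nucleus, or the nucleus inside a cell; 0 when none).
#'
#' @param nuclei,cells Integer label matrices of identical shape.
#' @return A data.frame.
#' @export
object_table <- function(nuclei, cells) {
  stopifnot(identical(dim(nuclei), dim(cells)))
  row_of <- function(lab, kind, other) {
    ids <- sort(unique(lab[lab > 0]))
    if (!length(ids))
      return(data.frame(id = integer(), kind = character(),
                        area_px = integer(), centroid_row = numeric(),
                        centroid_col = numeric(), match_id = integer()))
    idx <- which(lab > 0)
    rr <- (idx - 1) %% nrow(lab)          # 0-based coordinates
    cc <- (idx - 1) %/% nrow(lab)
    l <- lab[idx]
    area <- as.integer(tapply(l, l, length)[as.character(ids)])
    crow <- as.numeric(tapply(rr, l, mean)[as.character(ids)])
    ccol <- as.numeric(tapply(cc, l, mean)[as.character(ids)])
    # majority-vote match with the other map
    o <- other[idx]
    match_id <- vapply(ids, function(i) {
      ov <- o[l == i]
      ov <- ov[ov > 0]
      if (!length(ov)) return(0L)
      tab <- table(ov)
      as.integer(names(tab)[which.max(tab)])
    }, integer(1))
    data.frame(id = ids, kind = kind, area_px = area,
               centroid_row = crow, centroid_col = ccol, match_id = match_id)
  }
  rbind(row_of(nuclei, "nucleus", cells), row_of(cells, "cell", nuclei))
}

#' Write segmentation outputs
#'
#' Writes `nuclei.tif` and `cells.tif` (16-bit label TIFFs, or 32-bit when
#' ids exceed 65535) plus `objects.csv`, the object table of
#' [object_table()], into `out_dir`.
#'
#' @param nuclei,cells Integer label matrices of identical shape.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the files written, invisibly.
#' @export
write_outputs <- function(nuclei, cells, out_dir) {
  stopifnot(identical(dim(nuclei), dim(cells)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fn <- file.path(out_dir, "nuclei.tif")
  fc <- file.path(out_dir, "cells.tif")
  ft <- file.path(out_dir, "objects.csv")
  write_label_tiff(nuclei, fn)
  write_label_tiff(cells, fc)
  write.csv(object_table(nuclei, cells), ft, row.names = FALSE)
  invisible(c(nuclei = fn, cells = fc, table = ft))
}

#' Relabel objects 1..N in raster order of first pixel
#'
#' @param lab Integer label matrix.
#' @return Integer label matrix with contiguous ids assigned in column-major
#'   raster order of each object's first pixel.
#' @export
relabel_raster <- function(lab) {
  ids <- unique(lab[lab > 0])   # unique() follows storage (raster) order
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- match(lab, ids)
  keep <- !is.na(pos) & lab > 0
  out[keep] <- pos[keep]
  out
}
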