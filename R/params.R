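#' Algorithm parameters
#'
#' Bundles every tunable constant of the segmentation pipeline, with the
#' defaults used throughout. The two primary parameters users typically
#' adjust are `a0` (minimal component area) and `d0` (concavity depth
#' threshold separating single nuclei from nucleus clusters).
#'
#' @param sigma Standard deviation, in pixels, of the Gaussian filter used
#'   before the three-class Otsu foreground estimate.
#' @param t0 Ratio threshold of the local mean suppression filter (LMSF):
#'   a pixel is zeroed when its intensity falls below `t0` times its local
#'   window mean. Must lie in (0, 1).
#' @param n0_list Integer vector of LMSF window half-widths; each scale is an
#'   independent pass over the original image and a pixel zeroed at any scale
#'   is background in the global mask.
#' @param p1,p2 Prior-probability refinement thresholds for the nucleus and
#'   membrane channels: global-mask pixels with a-priori probability below
#'   `p_i` are reassigned to background.
#' @param k0 Smoothing scale of the gradient adaptive smoothing (GAS) kernel.
#' @param r0 Disk radius, in pixels, of the local Otsu neighbourhood.
#' @param a0 Minimal area, in pixels, for a component to be considered a
#'   nucleus (or nucleus cluster).
#' @param d0 Concavity depth threshold, in pixels: components whose steepest
#'   concave point is deeper than `d0` are treated as nucleus clusters.
#' @param u0 Fallback dilation radius, in pixels (valid 1-10), used to build a
#'   cell for nuclei without membrane support, and the expansion budget for
#'   membrane-constrained growth.
#' @param labeling_mode Either `"argmax"` (default, deterministic) or
#'   `"kmeans"` for turning posterior probability pairs into semantic labels.
#' @param collapse_area Area, in pixels, at or below which a watershed region
#'   is considered collapsed to a point object during seed perturbation.
#' @param smoothing_radius Disk radius of the morphological boundary
#'   smoothing (closing then opening) applied to final nucleus instances.
#' @param max_recursion Recursion cap for cluster splitting.
#' @param sc_area_factor Nucleus candidates with area below
#'   `sc_area_factor` times the median candidate area enter the
#'   small-component (SC) list.
#' @param sc_isolation_px An SC is "isolated" (and kept) when its dilation by
#'   this many pixels touches no other accepted nucleus.
#' @param membrane_support_frac Minimum fraction of 10-degree angular
#'   sectors around a nucleus whose annulus (out to `u0 + 2` pixels from
#'   the nucleus boundary) contains membrane evidence for the nucleus to be
#'   expanded to the membrane (otherwise the dilation fallback is used).
#' @param membrane_cost_beta Cost multiplier for crossing membrane evidence
#'   during cell expansion: the geodesic step weight is
#'   `1 + membrane_cost_beta * P2g`.
#' @param nucleus_free_overlap Maximum fraction of a candidate nucleus-free
#'   cell's area that may overlap already-segmented cells.
#' @param default_nucleus_area Mean nucleus area, in pixels, assumed when no
#'   nuclei were segmented (used by nucleus-free cell detection).
#' @param rng_seed Seed used by the k-means labeling mode.
#'
#' @return An object of class `unseg_params` (a validated named list).
#' @export
#' @examples
#' p <- unseg_params(a0 = 30)
#' p$a0
unseg_params <- function(sigma = 3, t0 = 0.5, n0_list = c(5L, 10L, 20L, 40L),
                         p1 = 0.01, p2 = 0.01, k0 = 1, r0 = 5L, a0 = 20L,
                         d0 = 4, u0 = 9L, labeling_mode = c("argmax", "kmeans"),
                         collapse_area = 4L, smoothing_radius = 1L,
                         max_recursion = 10L, sc_area_factor = 0.5,
                         sc_isolation_px = 2L, membrane_support_frac = 0.25,
                         membrane_cost_beta = 20,
                         nucleus_free_overlap = 0.1,
                         default_nucleus_area = 300,
                         rng_seed = 1L) {
  labeling_mode <- match.arg(labeling_mode)
  stopifnot(
    sigma > 0, t0 > 0, t0 < 1,
    length(n0_list) >= 1, all(n0_list >= 1),
    p1 >= 0, p1 < 1, p2 >= 0, p2 < 1,
    k0 > 0, r0 >= 1, a0 >= 1, d0 >= 0,
    u0 >= 1, u0 <= 10,
    collapse_area >= 1, smoothing_radius >= 0, max_recursion >= 1,
    sc_area_factor >= 0, sc_isolation_px >= 1,
    membrane_support_frac >= 0, membrane_support_frac <= 1,
    membrane_cost_beta >= 0,
    nucleus_free_overlap >= 0, nucleus_free_overlap <= 1,
    default_nucleus_area > 0
  )
  p <- list(
    sigma = sigma, t0 = t0, n0_list = as.integer(n0_list),
    p1 = p1, p2 = p2, k0 = k0, r0 = as.integer(r0), a0 = as.integer(a0),
    d0 = d0, u0 = as.integer(u0), labeling_mode = labeling_mode,
    collapse_area = as.integer(collapse_area),
    smoothing_radius = as.integer(smoothing_radius),
    max_recursion = as.integer(max_recursion),
    sc_area_factor = sc_area_factor,
    sc_isolation_px = as.integer(sc_isolation_px),
    membrane_support_frac = membrane_support_frac,
    membrane_cost_beta = membrane_cost_beta,
    nucleus_free_overlap = nucleus_free_overlap,
    default_nucleus_area = default_nucleus_area,
    rng_seed = as.integer(rng_seed)
  )
  class(p) <- "unseg_params"
  p
}

#' @export
print.unseg_params <- function(x, ...) {
  cat("unseg_params:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

#' Read parameters from a plain-text key-value config file
#'
#' The file contains `key = value` lines mirroring the [unseg_params()]
#' argument names exactly; `n0_list` takes comma-separated values. Blank
#' lines and lines starting with `#` are ignored.
#'
#' @param path Path to the config file.
#' @return An `unseg_params` object.
#' @export
read_unseg_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    args[[key]] <- if (key == "labeling_mode") val else
      as.numeric(strsplit(val, ",")[[1]])
  }
  unknown <- setdiff(names(args), names(formals(unseg_params)))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(unseg_params, args)
}
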