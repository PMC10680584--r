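# End-to-end orchestration of the four processing stages, with invariant
# checks, a run manifest, and the runtime scaling probe.

# Stage 1+2 for one image: per-channel priors/masks, likelihood, posterior
# fields, semantic label maps. Degenerate channels (constant, or empty
# initial foreground) yield all-zero fields so the pipeline stays total.
semantic_stage <- function(image, params = unseg_params(), verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  chan <- list(image$I1, image$I2)
  p_min <- c(params$p1, params$p2)
  Pe <- Mgc <- Mlc <- vector("list", 2)
  for (i in 1:2) {
    I <- chan[[i]]
    fg <- if (max(I) > min(I)) initial_foreground(I, params$sigma) else
      matrix(FALSE, nrow(I), ncol(I))
    if (!any(fg)) {
      say("channel ", i, ": no foreground; treating channel as empty")
      Pe[[i]] <- matrix(0, nrow(I), ncol(I))
      Mgc[[i]] <- Mlc[[i]] <- matrix(FALSE, nrow(I), ncol(I))
      next
    }
    Pe[[i]] <- apriori_probability(I, fg)
    Mgc[[i]] <- global_mask(I, Pe[[i]], params$t0, params$n0_list, p_min[i])
    Ig <- gas(I, params$k0)
    Mlc[[i]] <- local_mask(Ig, params$r0, Mgc[[i]])
    say("channel ", i, ": global mask ", sum(Mgc[[i]]), " px, local mask ",
        sum(Mlc[[i]]), " px")
  }
  L <- suppressWarnings(
    contrast_likelihood(image, Mlc[[1]], Mlc[[2]], Mgc[[1]], Mgc[[2]]))
  P1s <- saturate_prior(Pe[[1]], Mlc[[1]])
  P2s <- saturate_prior(Pe[[2]], Mlc[[2]])
  pg <- posterior_global(P1s, P2s, L)
  pl <- posterior_local(Pe[[1]], Pe[[2]], Mlc[[1]], Mlc[[2]])
  Mg <- semantic_labels(pg$P1g, pg$P2g, params$labeling_mode, params$rng_seed)
  Ml <- semantic_labels(pl$P1l, pl$P2l, params$labeling_mode, params$rng_seed)
  list(P1e = Pe[[1]], P2e = Pe[[2]], M1g = Mgc[[1]], M2g = Mgc[[2]],
       M1l = Mlc[[1]], M2l = Mlc[[2]], L = L,
       P1g = pg$P1g, P2g = pg$P2g, P1l = pl$P1l, P2l = pl$P2l,
       Mg = Mg, Ml = Ml)
}

#' Run the full segmentation pipeline
#'
#' Executes the four stages in order: per-channel a-priori probabilities and
#' global/local masks; contrast likelihood and posterior semantic label
#' maps; nucleus instance parsing; membrane-constrained cell expansion.
#' Core invariants are asserted on every run: probability fields in
#' `[0, 1]`, posterior exclusivity (`P1g * P2g = 0` everywhere), pairwise
#' disjoint instances, and every nucleus contained in exactly one cell.
#'
#' @param image A [two_channel_image()].
#' @param params An [unseg_params()] object.
#' @param dump_dir Optional directory for intermediate-field TIFFs.
#' @param verbose Emit per-stage progress messages.
#' @return List with `nuclei`, `cells` (integer label matrices), `records`
#'   (nucleus-cell correspondence data.frame), `semantic` (the Stage-1/2
#'   fields) and `manifest` (parameters, counts, stage timings, version).
#' @export
run_unseg <- function(image, params = unseg_params(), dump_dir = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(image, "two_channel_image"))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  sem <- semantic_stage(image, params, verbose)
  timings["semantic"] <- tic() - t0
  stopifnot(all(sem$P1g >= 0 & sem$P1g <= 1), all(sem$P2g >= 0 & sem$P2g <= 1))
  stopifnot(all(sem$P1g * sem$P2g == 0))
  t0 <- tic()
  nuclei <- segment_nuclei(sem$Mg, sem$Ml, params)
  timings["nuclei"] <- tic() - t0
  t0 <- tic()
  cells <- segment_cells(nuclei, sem$Mg, sem$P2g, params)
  timings["cells"] <- tic() - t0
  records <- attr(cells, "records")
  # headline consistency guarantee: every nucleus inside exactly one cell
  nuc_px <- nuclei > 0
  if (any(nuc_px)) {
    stopifnot(all(cells[nuc_px] > 0))
    cross <- table(nuclei[nuc_px], cells[nuc_px])
    stopifnot(all(rowSums(cross > 0) == 1))
  }
  if (!is.null(dump_dir)) {
    dir.create(dump_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("P1e", "P2e", "L", "P1g", "P2g")) {
      v <- sem[[nm]]
      tiff::writeTIFF((v - min(v)) / max(1e-12, diff(range(v))),
                      file.path(dump_dir, paste0(nm, ".tif")),
                      bits.per.sample = 16)
    }
    for (nm in c("M1g", "M2g", "M1l", "M2l", "Mg", "Ml"))
      write_label_tiff(matrix(as.integer(sem[[nm]]), nrow(sem[[nm]])),
                       file.path(dump_dir, paste0(nm, ".tif")))
  }
  manifest <- list(
    version = as.character(utils::packageVersion("unseg")),
    params = unclass(params),
    image_size = dim(image$I1),
    n_nuclei = length(unique(nuclei[nuclei > 0])),
    n_cells = length(unique(cells[cells > 0])),
    stage_seconds = timings)
  if (verbose)
    message("segmented ", manifest$n_nuclei, " nuclei and ",
            manifest$n_cells, " cells")
  list(nuclei = nuclei, cells = cells, records = records,
       semantic = sem, manifest = manifest)
}

#' Runtime scaling probe
#'
#' Runs the full pipeline on uniformly populated synthetic fixtures of
#' increasing cell count (constant cell density, so image area grows with
#' the count) and summarizes how wall-clock runtime relates to the number
#' of segmented cells by the R-squared of a least-squares line. Only the
#' relative trend is meaningful.
#'
#' @param sizes Integer vector of cell counts (at least 3).
#' @param px_per_cell Image area per cell, in pixels (constant density).
#' @param params An [unseg_params()] object.
#' @param seed Seed offset for the fixtures.
#' @return Data.frame with `n_cells_requested`, `n_cells_segmented`,
#'   `runtime_seconds`, plus attribute `"r_squared"`.
#' @export
runtime_scaling_probe <- function(sizes = c(50L, 100L, 200L, 400L),
                                  px_per_cell = 4400,
                                  params = unseg_params(), seed = 0L) {
  stopifnot(length(sizes) >= 3)
  out <- data.frame(n_cells_requested = integer(),
                    n_cells_segmented = integer(),
                    runtime_seconds = numeric())
  for (n in sizes) {
    side <- as.integer(ceiling(sqrt(n * px_per_cell)))
    spec <- fixture_spec(size = c(side, side), n_cells = as.integer(n),
                         seed = as.integer(seed))
    bundle <- generate_tissue(spec)
    t0 <- proc.time()[["elapsed"]]
    res <- run_unseg(bundle$image, params)
    dt <- proc.time()[["elapsed"]] - t0
    out <- rbind(out, data.frame(n_cells_requested = n,
                                 n_cells_segmented = res$manifest$n_cells,
                                 runtime_seconds = dt))
  }
  fit <- stats::lm(runtime_seconds ~ n_cells_segmented, data = out)
  attr(out, "r_squared") <- summary(fit)$r.squared
  out
}
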