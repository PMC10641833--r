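# Area per lipid, phosphorus-phosphorus bilayer thickness, and the
# surface-unevenness statistic.

#' Area per lipid series
#'
#' Per-frame area per lipid `APL = Lx * Ly / n_per_leaflet`, with an
#' autocorrelation-corrected standard error on the mean.
#'
#' @param traj `mm_trajectory`.
#' @param n_per_leaflet number of lipids in one leaflet.
#' @return An `mm_area_series`: list with `apl` (per frame, A^2), `mean`,
#'   `se`, `n_eff`, `n_frames`, `n_per_leaflet`.
#' @export
area_per_lipid <- function(traj, n_per_leaflet) {
  stopifnot(n_per_leaflet > 0)
  apl <- traj$box[, 1] * traj$box[, 2] / n_per_leaflet
  ss <- series_se(apl)
  structure(list(apl = apl, mean = mean(apl), se = ss$se, n_eff = ss$n_eff,
                 n_frames = length(apl), n_per_leaflet = n_per_leaflet),
            class = "mm_area_series")
}

#' @export
print.mm_area_series <- function(x, ...) {
  cat("<mm_area_series> APL = ", format(x$mean, digits = 5), " +/- ",
      format(x$se, digits = 3), " A^2 over ", x$n_frames, " frames\n", sep = "")
  invisible(x)
}

#' Bilayer thickness series
#'
#' Per-frame phosphorus-phosphorus thickness: mean HEAD_P z of the upper
#' leaflet minus mean HEAD_P z of the lower leaflet.
#'
#' @param traj `mm_trajectory`.
#' @param assignment `mm_leaflets` from [assign_leaflets()].
#' @return An `mm_thickness_series`: list with `thickness` (per frame, A),
#'   `mean`, `se`, `n_eff`.
#' @export
bilayer_thickness <- function(traj, assignment) {
  top <- traj$topology
  hp <- atom_indices(top, role = "HEAD_P")
  lids <- top$atoms$lipid_id[hp]
  up <- hp[assignment$labels[as.character(lids)] == "upper"]
  lo <- hp[assignment$labels[as.character(lids)] == "lower"]
  if (!length(up) || !length(lo)) stop("empty leaflet in assignment")
  zs <- traj$coords[, 3, , drop = FALSE]
  th <- apply(zs, 3, function(z) mean(z[up, 1]) - mean(z[lo, 1]))
  ss <- series_se(th)
  structure(list(thickness = th, mean = mean(th), se = ss$se, n_eff = ss$n_eff),
            class = "mm_thickness_series")
}

#' @export
print.mm_thickness_series <- function(x, ...) {
  cat("<mm_thickness_series> thickness = ", format(x$mean, digits = 5),
      " +/- ", format(x$se, digits = 3), " A\n", sep = "")
  invisible(x)
}

#' Surface-unevenness statistic
#'
#' At `n_frames` randomly sampled frames, the per-leaflet mean HEAD_P z is
#' computed; each phosphorus's deviation from its own frame-and-leaflet mean
#' is pooled per leaflet over all sampled frames; the statistic is
#' `U = sd_upper + sd_lower`, the sum of the two pooled standard deviations
#' (angstrom). Larger U means a broader vertical phosphorus distribution and
#' hence a more uneven leaflet surface. For headgroup z-scatter that is
#' Gaussian with standard deviation sigma per leaflet, U converges to
#' 2*sigma (up to the 1 - 1/n_lipids finite-sample factor from per-frame
#' centering).
#'
#' `mode = "frame_means"` gives the literal alternative reading in which the
#' standard deviation is taken over the sampled per-frame leaflet means
#' themselves; it measures frame-to-frame breathing of each leaflet plane
#' rather than surface roughness, and is provided for comparison only.
#'
#' @param traj `mm_trajectory`.
#' @param assignment `mm_leaflets`.
#' @param n_frames number of frames to sample without replacement
#'   (default 500); reduced to the trajectory length with a warning when the
#'   trajectory is shorter.
#' @param seed integer seed for the frame sampling; recorded in the result.
#' @param mode `"pooled"` (default) or `"frame_means"`, see Details.
#' @return An `mm_unevenness`: list with `U`, `sd_upper`, `sd_lower` (A),
#'   `n_frames_sampled`, `rng_seed`, `mode`.
#' @export
surface_unevenness <- function(traj, assignment, n_frames = 500, seed = 1,
                               mode = c("pooled", "frame_means")) {
  mode <- match.arg(mode)
  if (n_frames <= 1) stop("n_frames must be > 1")
  nf <- n_frames(traj)
  if (n_frames > nf) {
    warning("trajectory has only ", nf, " frames; sampling all of them")
    n_frames <- nf
  }
  idx <- if (n_frames == nf) seq_len(nf) else {
    rng <- local({
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(seed)
      s <- sample.int(nf, n_frames)
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      s
    })
    rng
  }
  top <- traj$topology
  hp <- atom_indices(top, role = "HEAD_P")
  lids <- as.character(top$atoms$lipid_id[hp])
  sds <- numeric(2); names(sds) <- c("upper", "lower")
  for (lf in c("upper", "lower")) {
    sel <- hp[assignment$labels[lids] == lf]
    if (!length(sel)) stop("empty leaflet in assignment")
    if (mode == "pooled") {
      dev <- unlist(lapply(idx, function(k) {
        z <- traj$coords[sel, 3, k]
        z - mean(z)
      }))
      sds[lf] <- stats::sd(dev)
    } else {
      m <- vapply(idx, function(k) mean(traj$coords[sel, 3, k]), numeric(1))
      sds[lf] <- stats::sd(m)
    }
  }
  structure(list(U = sum(sds), sd_upper = sds[["upper"]],
                 sd_lower = sds[["lower"]], n_frames_sampled = length(idx),
                 rng_seed = seed, mode = mode),
            class = "mm_unevenness")
}

#' @export
print.mm_unevenness <- function(x, ...) {
  cat("<mm_unevenness> U = ", format(x$U, digits = 4), " A (upper ",
      format(x$sd_upper, digits = 4), " + lower ",
      format(x$sd_lower, digits = 4), "; ", x$n_frames_sampled,
      " frames, mode ", x$mode, ")\n", sep = "")
  invisible(x)
}
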