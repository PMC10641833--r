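# Acyl-tail order parameters, relative-order profiles, and terminal-methyl
# z-distributions.
#
# The order parameter at interior carbon i is S_C = <(3 cos^2 theta_i - 1)/2>
# where theta_i is the angle between the bilayer normal (z) and the vector
# joining the heavy atoms i-1 and i+1 of the same tail. This is the
# carbon-skeleton estimator (no hydrogens are used), so the first and last
# carbons of a tail carry no value.

#' Per-carbon tail order-parameter profile
#'
#' @param traj `mm_trajectory`.
#' @param species lipid species label.
#' @param tail `"SN1"` or `"SN2"`.
#' @return An `mm_order_profile`: data.frame with columns `species`, `tail`,
#'   `carbon` (interior index `2..n-1`), `S` (order parameter), `se`
#'   (autocorrelation-corrected SE of the frame means) and attribute
#'   `n_frames`.
#' @details S ranges over [-0.5, 1]: 1 for a chord exactly along z, 0 for an
#'   isotropic orientation distribution, -0.5 for chords lying in the
#'   membrane plane. Averaging is over lipids within each frame, then the SE
#'   is taken over the per-frame means via [stationary_se()].
#' @export
order_parameter_profile <- function(traj, species, tail = c("SN1", "SN2")) {
  tail <- match.arg(tail)
  top <- traj$topology
  idx <- atom_indices(top, species = species, tail = tail)
  if (!length(idx)) stop("no atoms for species '", species, "' tail ", tail)
  a <- top$atoms[idx, ]
  n_c <- max(a$tail_pos)
  if (n_c < 3) stop("tail too short for order parameters")
  lip <- sort(unique(a$lipid_id))
  # [lipid x carbon] index matrix into coords
  im <- matrix(NA_integer_, length(lip), n_c)
  for (r in seq_len(nrow(a))) {
    im[match(a$lipid_id[r], lip), a$tail_pos[r]] <- a$atom[r]
  }
  if (anyNA(im)) stop("incomplete tail atoms for species '", species, "'")
  interior <- 2:(n_c - 1)
  nf <- n_frames(traj)
  frame_means <- matrix(NA_real_, nf, length(interior))
  for (k in seq_len(nf)) {
    xyz <- traj$coords[, , k, drop = TRUE]
    prev <- im[, interior - 1L, drop = FALSE]
    nxt <- im[, interior + 1L, drop = FALSE]
    dx <- xyz[nxt, 1] - xyz[prev, 1]
    dy <- xyz[nxt, 2] - xyz[prev, 2]
    dz <- xyz[nxt, 3] - xyz[prev, 3]
    c2 <- dz^2 / (dx^2 + dy^2 + dz^2)
    p2 <- matrix((3 * c2 - 1) / 2, nrow(im), length(interior))
    frame_means[k, ] <- colMeans(p2)
  }
  S <- colMeans(frame_means)
  se <- vapply(seq_along(interior), function(j) series_se(frame_means[, j])$se,
               numeric(1))
  out <- data.frame(species = species, tail = tail, carbon = interior,
                    S = S, se = se, stringsAsFactors = FALSE)
  attr(out, "n_frames") <- nf
  class(out) <- c("mm_order_profile", "data.frame")
  out
}

#' Relative-order profile of a mixed versus a pure bilayer
#'
#' Each interior carbon's order parameter in the mixed system is divided by
#' its counterpart in the pure reference system and multiplied by the carbon
#' index, so a mixed system identical to the pure one falls on the diagonal
#' `value = carbon`.
#'
#' @param mixed,pure `mm_order_profile` objects on the same species, tail
#'   and carbon grid.
#' @return data.frame with columns `carbon`, `ratio` (`S_mix/S_pure`) and
#'   `value` (`ratio * carbon`). Carbons where the pure profile is exactly
#'   zero are dropped with a warning.
#' @export
relative_order_profile <- function(mixed, pure) {
  if (!identical(mixed$tail[1], pure$tail[1])) stop("tail mismatch")
  if (!identical(mixed$carbon, pure$carbon)) stop("carbon grids differ")
  ok <- pure$S != 0
  if (!all(ok)) {
    warning("pure-profile S = 0 at carbon(s) ",
            paste(mixed$carbon[!ok], collapse = ", "),
            "; relative order undefined there, dropped")
  }
  data.frame(carbon = mixed$carbon[ok],
             ratio = mixed$S[ok] / pure$S[ok],
             value = mixed$S[ok] / pure$S[ok] * mixed$carbon[ok])
}

#' Terminal-methyl z-distribution
#'
#' Density-normalized histograms of terminal-methyl (TMG) z positions
#' relative to the per-frame bilayer midplane (mean HEAD_P z of that frame),
#' separately per leaflet and combined. Using the per-frame midplane removes
#' box drift along z.
#'
#' @param traj `mm_trajectory`.
#' @param assignment `mm_leaflets` (leaflet membership of each lipid).
#' @param species lipid species label.
#' @param bin_width histogram bin width in angstrom (default 1).
#' @return An `mm_zhist`: list with `breaks`, `mids` (A, midplane-relative),
#'   `density_upper`, `density_lower`, `density_both` (each integrating
#'   to 1), `bin_width`, and the raw relative z values in `z` (list per
#'   curve).
#' @export
tmg_distribution <- function(traj, assignment, species, bin_width = 1.0) {
  stopifnot(bin_width > 0)
  top <- traj$topology
  tmg <- atom_indices(top, species = species, role = "TMG")
  if (!length(tmg)) stop("species '", species, "' has no TMG-tagged atoms")
  hp <- atom_indices(top, role = "HEAD_P")
  tmg_lip <- as.character(top$atoms$lipid_id[tmg])
  lab <- assignment$labels[tmg_lip]
  nf <- n_frames(traj)
  rel <- matrix(NA_real_, length(tmg), nf)
  for (k in seq_len(nf)) {
    zc <- mean(traj$coords[hp, 3, k])
    rel[, k] <- traj$coords[tmg, 3, k] - zc
  }
  z_up <- as.vector(rel[lab == "upper", , drop = FALSE])
  z_lo <- as.vector(rel[lab == "lower", , drop = FALSE])
  z_all <- c(z_up, z_lo)
  rng <- range(z_all)
  breaks <- seq(floor(rng[1] / bin_width) * bin_width,
                ceiling(rng[2] / bin_width) * bin_width + bin_width / 2,
                by = bin_width)
  hfun <- function(z) {
    if (!length(z)) return(rep(0, length(breaks) - 1))
    graphics::hist(z, breaks = breaks, plot = FALSE)$density
  }
  structure(list(
    breaks = breaks, mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
    density_upper = hfun(z_up), density_lower = hfun(z_lo),
    density_both = hfun(z_all), bin_width = bin_width,
    z = list(upper = z_up, lower = z_lo)
  ), class = "mm_zhist")
}

#' @export
print.mm_zhist <- function(x, ...) {
  cat("<mm_zhist> ", length(x$mids), " bins of ", x$bin_width,
      " A; mean z upper ", format(mean(x$z$upper), digits = 4),
      ", lower ", format(mean(x$z$lower), digits = 4), " A\n", sep = "")
  invisible(x)
}
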