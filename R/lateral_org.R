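# Lateral organization: periodic 2D Voronoi tessellation of headgroup
# positions, per-lipid cell areas, mixed-contact fraction, and
# neighbor-composition tables.

# Clip a convex polygon (matrix [n x 2]) with the half-plane
# { p : (p - m) . nrm <= 0 }  (Sutherland-Hodgman against one edge).
clip_halfplane <- function(poly, m, nrm) {
  s <- (poly[, 1] - m[1]) * nrm[1] + (poly[, 2] - m[2]) * nrm[2]
  n <- nrow(poly)
  inside <- s <= 0
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  out <- matrix(NA_real_, n + 4, 2)
  cnt <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) {
      cnt <- cnt + 1L; out[cnt, ] <- poly[i, ]
    }
    if (inside[i] != inside[j]) {
      t_ <- s[i] / (s[i] - s[j])
      cnt <- cnt + 1L
      out[cnt, ] <- poly[i, ] + t_ * (poly[j, ] - poly[i, ])
    }
  }
  out[seq_len(cnt), , drop = FALSE]
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Periodic Voronoi cell areas of one leaflet
#'
#' Tessellates the HEAD_P (x, y) positions of one leaflet under periodic
#' boundary conditions: seeds are tiled into the 8 surrounding images, each
#' central seed's cell is cut by half-plane clipping against its neighbors
#' (nearest first, stopping once no remaining image can intersect the cell),
#' and the polygon area is returned per lipid. Cell areas partition the
#' leaflet: their sum equals Lx*Ly to within 1e-6 relative.
#'
#' @param frame `mm_frame`.
#' @param topology matching `mm_topology`.
#' @param assignment `mm_leaflets`.
#' @param leaflet `"upper"` or `"lower"`.
#' @return An `mm_voronoi`: data.frame with columns `lipid_id`, `species`,
#'   `x`, `y` (seed, A, wrapped into the box) and `area` (A^2); attributes
#'   `box` and `leaflet`.
#' @export
voronoi_areas <- function(frame, topology, assignment,
                          leaflet = c("upper", "lower")) {
  leaflet <- match.arg(leaflet)
  hp <- atom_indices(topology, role = "HEAD_P")
  lids <- topology$atoms$lipid_id[hp]
  sel <- assignment$labels[as.character(lids)] == leaflet
  hp <- hp[sel]; lids <- lids[sel]
  if (length(hp) < 3) stop("need >= 3 seeds in the leaflet")
  Lx <- frame$box[1]; Ly <- frame$box[2]
  sx <- frame$coords[hp, 1] %% Lx
  sy <- frame$coords[hp, 2] %% Ly
  n <- length(sx)
  # coincident-seed guard (minimum-image)
  dxm <- outer(sx, sx, "-"); dxm <- dxm - Lx * round(dxm / Lx)
  dym <- outer(sy, sy, "-"); dym <- dym - Ly * round(dym / Ly)
  d2 <- dxm^2 + dym^2; diag(d2) <- Inf
  if (any(d2 < 1e-12)) {
    w <- which(d2 < 1e-12, arr.ind = TRUE)[1, ]
    stop("coincident seeds: lipids ", lids[w[1]], " and ", lids[w[2]])
  }
  ox <- rep(c(-1, 0, 1), each = 3) * Lx
  oy <- rep(c(-1, 0, 1), times = 3) * Ly
  ax <- as.vector(outer(sx, ox, "+"))
  ay <- as.vector(outer(sy, oy, "+"))
  big <- max(Lx, Ly) * 2
  areas <- numeric(n)
  for (i in seq_len(n)) {
    px <- sx[i]; py <- sy[i]
    poly <- cbind(px + c(-big, big, big, -big), py + c(-big, -big, big, big))
    d2i <- (ax - px)^2 + (ay - py)^2
    ord <- order(d2i)
    for (jj in ord) {
      dj2 <- d2i[jj]
      if (dj2 < 1e-12) next  # the seed itself (central copy)
      # max distance from seed to current cell vertices
      r2 <- max((poly[, 1] - px)^2 + (poly[, 2] - py)^2)
      if (dj2 > 4 * r2) break  # bisector cannot cut the cell
      m <- c((ax[jj] + px) / 2, (ay[jj] + py) / 2)
      nrm <- c(ax[jj] - px, ay[jj] - py)
      poly <- clip_halfplane(poly, m, nrm)
      if (nrow(poly) < 3) break
    }
    areas[i] <- polygon_area(poly)
  }
  out <- data.frame(lipid_id = lids,
                    species = topology$lipids$species[match(lids, topology$lipids$lipid_id)],
                    x = sx, y = sy, area = areas, stringsAsFactors = FALSE)
  attr(out, "box") <- frame$box
  attr(out, "leaflet") <- leaflet
  class(out) <- c("mm_voronoi", "data.frame")
  out
}

# Minimum-image pair distances (squared) between two coordinate matrices
# under an orthorhombic box; returns an [n1 x n2] matrix.
min_image_dist2 <- function(a, b, box) {
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in seq_len(ncol(a))) {
    d <- outer(a[, k], b[, k], "-")
    d <- d - box[k] * round(d / box[k])
    d2 <- d2 + d^2
  }
  d2
}

#' Mixed-contact fraction
#'
#' Counts unordered same-leaflet contact pairs per frame (two lipids are in
#' contact when the 3D minimum-image distance between their reference beads
#' is at most `cutoff`), splits them into like (AA, BB) and unlike (AB)
#' species pairs, and reports the mixed fraction
#' `f_mix = C_AB / (C_AA + C_AB + C_BB)` averaged over frames with an
#' autocorrelation-corrected SE. `denominator = "unlike_over_like"` instead
#' reports `C_AB / (C_AA + C_BB)` (alternative convention).
#'
#' @param traj `mm_trajectory`.
#' @param assignment `mm_leaflets`.
#' @param cutoff contact distance in angstrom (default 11, i.e. 1.1 nm).
#' @param role reference bead role (default `"HEAD_P"`, the phosphate).
#' @param same_leaflet_only restrict pairs to the same leaflet (default
#'   `TRUE`).
#' @param denominator `"all"` (default) or `"unlike_over_like"`.
#' @return An `mm_contacts`: list with mean counts `C_AA`, `C_AB`, `C_BB`
#'   (per frame), `f_mix`, `se`, per-frame series `f_mix_frames`, `cutoff`
#'   and `n_frames`.
#' @export
mixed_contacts <- function(traj, assignment, cutoff = 11.0, role = "HEAD_P",
                           same_leaflet_only = TRUE,
                           denominator = c("all", "unlike_over_like")) {
  denominator <- match.arg(denominator)
  if (cutoff <= 0) stop("cutoff must be positive")
  top <- traj$topology
  idx <- atom_indices(top, role = role)
  lids <- top$atoms$lipid_id[idx]
  sp <- top$lipids$species[match(lids, top$lipids$lipid_id)]
  spl <- unique(sp)
  if (length(spl) > 2) stop("mixed_contacts handles at most 2 species")
  lab <- assignment$labels[as.character(lids)]
  nf <- n_frames(traj)
  cAA <- cAB <- cBB <- numeric(nf)
  for (k in seq_len(nf)) {
    xyz <- traj$coords[idx, , k, drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    groups <- if (same_leaflet_only) c("upper", "lower") else "all"
    for (g in groups) {
      gi <- if (g == "all") seq_along(idx) else which(lab == g)
      if (length(gi) < 2) next
      d2 <- min_image_dist2(xyz[gi, , drop = FALSE], xyz[gi, , drop = FALSE],
                            traj$box[k, ])
      inc <- d2 <= cutoff^2
      inc[lower.tri(inc, diag = TRUE)] <- FALSE
      if (!any(inc)) next
      pr <- which(inc, arr.ind = TRUE)
      sa <- sp[gi][pr[, 1]]; sb <- sp[gi][pr[, 2]]
      mixed <- sa != sb
      like_a <- !mixed & sa == spl[1]
      cAB[k] <- cAB[k] + sum(mixed)
      cAA[k] <- cAA[k] + sum(like_a)
      cBB[k] <- cBB[k] + sum(!mixed & !like_a)
    }
  }
  denom <- if (denominator == "all") cAA + cAB + cBB else cAA + cBB
  fk <- ifelse(denom > 0, cAB / denom, 0)
  ss <- series_se(fk)
  structure(list(C_AA = mean(cAA), C_AB = mean(cAB), C_BB = mean(cBB),
                 f_mix = mean(fk), se = ss$se, f_mix_frames = fk,
                 cutoff = cutoff, n_frames = nf, species = spl,
                 denominator = denominator),
            class = "mm_contacts")
}

#' @export
print.mm_contacts <- function(x, ...) {
  cat("<mm_contacts> f_mix = ", format(x$f_mix, digits = 4), " +/- ",
      format(x$se, digits = 3), " (cutoff ", x$cutoff, " A, ",
      x$n_frames, " frames)\n", sep = "")
  invisible(x)
}

#' Neighbor-composition table
#'
#' For each center species, the mean number of same-leaflet neighbors of
#' each species (two lipids are neighbors when the 3D minimum-image distance
#' between their reference beads, by default the first tail bead, is at most
#' `cutoff`), averaged over frames, with SEs over per-frame means and
#' percentage shares per center species.
#'
#' @param traj `mm_trajectory`.
#' @param assignment `mm_leaflets`.
#' @param cutoff neighbor distance in angstrom (default 15, i.e. 1.5 nm).
#' @param role reference bead role (default `"FIRST_TAIL_BEAD"`).
#' @return An `mm_neighbors`: data.frame with columns `center_species`,
#'   `neighbor_species`, `mean_count`, `se` and `percent` (shares sum to 100
#'   within each center species).
#' @export
neighbor_composition <- function(traj, assignment, cutoff = 15.0,
                                 role = "FIRST_TAIL_BEAD") {
  if (cutoff <= 0) stop("cutoff must be positive")
  top <- traj$topology
  idx <- atom_indices(top, role = role)
  lids <- top$atoms$lipid_id[idx]
  if (length(unique(lids)) != nrow(top$lipids)) {
    stop("role '", role, "' is not tagged for every lipid")
  }
  sp <- top$lipids$species[match(lids, top$lipids$lipid_id)]
  spl <- sort(unique(sp))
  lab <- assignment$labels[as.character(lids)]
  nf <- n_frames(traj)
  # per-frame mean count [center species x neighbor species]
  per_frame <- array(NA_real_, c(length(spl), length(spl), nf),
                     dimnames = list(spl, spl, NULL))
  for (k in seq_len(nf)) {
    xyz <- traj$coords[idx, , k, drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    counts <- matrix(0, length(idx), length(spl), dimnames = list(NULL, spl))
    for (g in c("upper", "lower")) {
      gi <- which(lab == g)
      if (length(gi) < 2) next
      d2 <- min_image_dist2(xyz[gi, , drop = FALSE], xyz[gi, , drop = FALSE],
                            traj$box[k, ])
      inc <- d2 <= cutoff^2
      diag(inc) <- FALSE
      for (s in spl) counts[gi, s] <- rowSums(inc[, sp[gi] == s, drop = FALSE])
    }
    for (cs in spl) {
      per_frame[cs, , k] <- colMeans(counts[sp == cs, , drop = FALSE])
    }
  }
  rows <- list()
  for (cs in spl) {
    mc <- apply(per_frame[cs, , , drop = FALSE], 2, mean)
    ses <- vapply(spl, function(ns) series_se(per_frame[cs, ns, ])$se,
                  numeric(1))
    rows[[cs]] <- data.frame(center_species = cs, neighbor_species = spl,
                             mean_count = as.numeric(mc), se = ses,
                             percent = neighbor_shares(as.numeric(mc)),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mm_neighbors", "data.frame")
  out
}

#' Percentage shares from mean neighbor counts
#'
#' Converts mean neighbor counts around one center species into percentage
#' shares of the total neighborhood, e.g. counts `c(6.73, 3.26)` give
#' `c(67.4, 32.6)` percent.
#'
#' @param counts numeric vector of mean neighbor counts.
#' @return Numeric vector of percentages summing to 100.
#' @export
neighbor_shares <- function(counts) {
  stopifnot(all(counts >= 0), sum(counts) > 0)
  100 * counts / sum(counts)
}

#' Voronoi cell-area distribution per species
#'
#' Pools Voronoi maps (typically one per frame and leaflet) and summarizes
#' the per-species cell-area distribution: histogram, median and quartiles.
#'
#' @param maps list of `mm_voronoi` objects (or a single one).
#' @param bins number of histogram bins (default 30) spanning the pooled
#'   area range.
#' @return List with `quartiles` (data.frame: species, q25, median, q75, n)
#'   and `histograms` (per species: breaks, mids, density).
#' @export
voronoi_area_distribution <- function(maps, bins = 30) {
  if (inherits(maps, "mm_voronoi")) maps <- list(maps)
  if (!length(maps)) stop("need >= 1 Voronoi map")
  areas <- unlist(lapply(maps, function(m) m$area))
  species <- unlist(lapply(maps, function(m) m$species))
  rng <- range(areas)
  breaks <- if (diff(rng) == 0) c(rng[1] - 0.5, rng[1] + 0.5)
            else seq(rng[1], rng[2], length.out = bins + 1)
  spl <- sort(unique(species))
  hists <- lapply(spl, function(s) {
    a <- areas[species == s]
    h <- graphics::hist(a, breaks = breaks, plot = FALSE)
    list(breaks = h$breaks, mids = h$mids, density = h$density)
  })
  names(hists) <- spl
  q <- t(vapply(spl, function(s) {
    stats::quantile(areas[species == s], c(0.25, 0.5, 0.75))
  }, numeric(3)))
  quart <- data.frame(species = spl, q25 = q[, 1], median = q[, 2],
                      q75 = q[, 3],
                      n = as.integer(table(species)[spl]),
                      stringsAsFactors = FALSE)
  rownames(quart) <- NULL
  list(quartiles = quart, histograms = hists)
}
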