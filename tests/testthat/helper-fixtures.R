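# Shared in-code fixtures and independent oracles.

# Minimal topology: n lipids, each one P head plus (optionally) two tails of
# tail_len members.
toy_topology <- function(n_lipids, tail_len = 0, species = rep("DOPC", n_lipids)) {
  rows <- lapply(seq_len(n_lipids), function(l) {
    if (tail_len == 0) {
      data.frame(lipid_id = l, species = species[l], name = "P", head = TRUE,
                 tail = NA, tail_pos = NA, tmg = FALSE, first_tail_bead = TRUE)
    } else {
      data.frame(
        lipid_id = l, species = species[l],
        name = c("P", paste0("C3", seq_len(tail_len)), paste0("C2", seq_len(tail_len))),
        head = c(TRUE, rep(FALSE, 2 * tail_len)),
        tail = c(NA, rep("SN1", tail_len), rep("SN2", tail_len)),
        tail_pos = c(NA, seq_len(tail_len), seq_len(tail_len)),
        tmg = c(FALSE, seq_len(tail_len) == tail_len, seq_len(tail_len) == tail_len),
        first_tail_bead = c(FALSE, seq_len(tail_len) == 1, rep(FALSE, tail_len))
      )
    }
  })
  mm_topology(do.call(rbind, rows))
}

# Trajectory with explicit per-frame coordinate matrices.
toy_trajectory <- function(topology, frames, box = c(80, 80, 100), dt = 1) {
  nf <- length(frames)
  coords <- array(NA_real_, c(nrow(topology$atoms), 3, nf))
  for (k in seq_len(nf)) coords[, , k] <- frames[[k]]
  mm_trajectory(topology, coords,
                matrix(rep(box, each = nf), nf, 3), (seq_len(nf) - 1) * dt)
}

# Flat two-leaflet frame: n heads per leaflet at z = +/- h/2 (+ scatter),
# positions on a grid.
flat_frame <- function(n_per_leaflet, h = 40, box = c(80, 80, 100),
                       z_jitter = 0) {
  m <- ceiling(sqrt(n_per_leaflet))
  g <- (expand.grid(x = seq_len(m), y = seq_len(m)) - 0.5)
  g <- g[seq_len(n_per_leaflet), ] * (box[1] / m)
  up <- cbind(g$x, g$y, h / 2 + stats::rnorm(n_per_leaflet, 0, z_jitter))
  lo <- cbind(g$x, g$y, -h / 2 + stats::rnorm(n_per_leaflet, 0, z_jitter))
  rbind(up, lo)
}

# CHARMM-style DOPC GRO writer (programmatic fixture).
write_test_gro <- function(path, n_frames = 1, drop_P_for_lipid = integer()) {
  con <- file(path, "w")
  on.exit(close(con))
  base_names <- c("P", paste0("C2", 1:18), paste0("C3", 1:18), "C1", "C2", "C3")
  for (f in seq_len(n_frames)) {
    writeLines("generated test bilayer", con)
    nmat <- sum(vapply(1:2, function(l) {
      length(base_names) - (l %in% drop_P_for_lipid)
    }, numeric(1)))
    writeLines(sprintf("%d", nmat), con)
    cnt <- 0
    for (l in 1:2) {
      nm <- base_names
      if (l %in% drop_P_for_lipid) nm <- nm[nm != "P"]
      for (a in seq_along(nm)) {
        cnt <- cnt + 1
        writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", l, "DOPC", nm[a],
                           cnt, 0.1 * a + f, 0.2 * l,
                           ifelse(l == 1, 2.0, -2.0)), con)
      }
    }
    writeLines("  8.00000  8.00000 10.00000", con)
  }
  path
}

# O(T^2) brute-force MSD oracle over all particles and overlapping origins.
msd_brute <- function(x, y, kmax) {
  T_ <- nrow(x)
  vapply(0:kmax, function(k) {
    if (k == 0) return(0)
    d <- 0; cnt <- 0
    for (t0 in seq_len(T_ - k)) {
      d <- d + sum((x[t0 + k, ] - x[t0, ])^2 + (y[t0 + k, ] - y[t0, ])^2)
      cnt <- cnt + ncol(x)
    }
    d / cnt
  }, numeric(1))
}

# O(N^2) brute-force same-leaflet contact oracle (3D minimum image).
contacts_brute <- function(xyz, box, species, leaflet, cutoff) {
  n <- nrow(xyz)
  cAA <- cAB <- cBB <- 0
  spl <- unique(species)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (leaflet[i] != leaflet[j]) next
    d <- xyz[i, ] - xyz[j, ]
    d <- d - box * round(d / box)
    if (sum(d^2) <= cutoff^2) {
      if (species[i] != species[j]) cAB <- cAB + 1
      else if (species[i] == spl[1]) cAA <- cAA + 1
      else cBB <- cBB + 1
    }
  }
  c(AA = cAA, AB = cAB, BB = cBB)
}

# Pixel-raster oracle for periodic Voronoi cell areas: assign every pixel
# center to its minimum-image nearest seed and count.
voronoi_raster_oracle <- function(sx, sy, L, npix = 2000) {
  n <- length(sx)
  px <- (rep(seq_len(npix), times = npix) - 0.5) * L / npix
  py <- (rep(seq_len(npix), each = npix) - 0.5) * L / npix
  best <- rep(Inf, npix * npix)
  idx <- integer(npix * npix)
  for (i in seq_len(n)) {
    dx <- px - sx[i]; dx <- dx - L * round(dx / L)
    dy <- py - sy[i]; dy <- dy - L * round(dy / L)
    d2 <- dx * dx + dy * dy
    upd <- d2 < best
    best[upd] <- d2[upd]
    idx[upd] <- i
  }
  tabulate(idx, n) * (L / npix)^2
}
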