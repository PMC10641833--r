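# Synthetic bilayer trajectories with fully known ground truth.
#
# The generated world is a stylized planar two-leaflet bilayer: headgroup
# phosphorus z-positions scatter as Normal(+/- h/2, sigma_z); acyl tails are
# rigid straight chains whose orientation is drawn per lipid, tail and frame
# from a two-component mixture (probability w: exactly z-aligned; 1 - w:
# isotropic), so every carbon-skeleton chord shares the chain axis and the
# ground-truth order parameter is exactly w at every interior carbon;
# terminal-methyl z-positions are Normal around a fixed offset from the
# midplane; lateral positions perform 2D Brownian motion with periodic
# wrapping (the true unwrapped tracks are stored); species labels are laid
# out randomly or as a grown cluster. The generator is deterministic under
# its seed.

#' Parameterization of a synthetic bilayer
#'
#' Defaults emulate the all-atom-scale systems the analysis pipeline
#' targets: 100 lipids per leaflet on an ~8 x 8 nm box at an area per lipid
#' of 68 A^2, phosphorus-phosphorus thickness 38 A with 2 A headgroup
#' z-scatter, 18-carbon tails, terminal methyls 3 A past the midplane with
#' 2 A spread, lateral diffusivity 100e-9 cm^2/s sampled every 100 ps, and
#' a 75:25 binary composition. `preset = "cg_large"` switches to the
#' coarse-grained-like scale (1520 lipids per leaflet, ~30 x 30 nm box,
#' 4-bead tails).
#'
#' @param n_per_leaflet lipids per leaflet.
#' @param A0 area per lipid at zero tension, A^2 (sets Lx = Ly).
#' @param Lz box height, A.
#' @param h target phosphorus-phosphorus thickness, A.
#' @param sigma_z headgroup z-scatter (per-leaflet SD), A.
#' @param tail_length carbons (or beads) per tail.
#' @param order_w ground-truth order parameter (mixture alignment weight),
#'   in [0, 1].
#' @param tmg_offset distance from the head plane to the mean TMG position,
#'   A; the mean TMG z is `-(h/2 - tmg_offset)` for the upper leaflet (i.e.
#'   3 A past the midplane with the defaults).
#' @param tmg_sd TMG z spread, A.
#' @param D_true lateral diffusion coefficient, 1e-9 cm^2/s.
#' @param dt frame spacing, ps.
#' @param n_frames frames to generate.
#' @param K_A_true area compressibility modulus of the stated world, mN/m.
#' @param tension_list imposed surface tensions, mN/m.
#' @param ar1_tau autocorrelation time of area fluctuations, frames.
#' @param species labels of the two species (first = primary).
#' @param species_fraction fraction of the primary species.
#' @param layout `"random"` or `"clustered"`.
#' @param seed integer RNG seed.
#' @param preset `"aa_dopc"` (default) or `"cg_large"`.
#' @return A `mm_synthetic_spec` list of the resolved parameters.
#' @export
synthetic_spec <- function(n_per_leaflet = 100, A0 = 68, Lz = 100,
                           h = 38, sigma_z = 2, tail_length = 18,
                           order_w = 0.6, tmg_offset = 16, tmg_sd = 2,
                           D_true = 100, dt = 100, n_frames = 100,
                           K_A_true = 245, tension_list = c(-7, 0, 7, 15),
                           ar1_tau = 20,
                           species = c("DOPC", "DHPC"),
                           species_fraction = 0.75,
                           layout = c("random", "clustered"),
                           seed = 42, preset = c("aa_dopc", "cg_large")) {
  layout <- match.arg(layout)
  preset <- match.arg(preset)
  if (preset == "cg_large") {
    if (missing(n_per_leaflet)) n_per_leaflet <- 1520
    if (missing(A0)) A0 <- 59
    if (missing(tail_length)) tail_length <- 4
    if (missing(h)) h <- 40
    if (missing(species)) species <- c("DOPC", "DPPC")
  }
  stopifnot(n_per_leaflet >= 2, A0 > 0, Lz > 0, h > 0, sigma_z >= 0,
            tail_length >= 3, order_w >= 0, order_w <= 1, tmg_sd >= 0,
            D_true >= 0, dt > 0, n_frames >= 1, K_A_true > 0,
            species_fraction >= 0, species_fraction <= 1,
            length(species) == 2)
  L <- sqrt(n_per_leaflet * A0)
  structure(list(
    n_per_leaflet = n_per_leaflet, box = c(L, L, Lz), A0 = A0, h = h,
    sigma_z = sigma_z, tail_length = tail_length, order_w = order_w,
    tmg_offset = tmg_offset, tmg_sd = tmg_sd, D_true = D_true, dt = dt,
    n_frames = n_frames, K_A_true = K_A_true, tension_list = tension_list,
    ar1_tau = ar1_tau, species = species,
    species_fraction = species_fraction, layout = layout, seed = seed,
    preset = preset
  ), class = "mm_synthetic_spec")
}

# jittered square lattice of n sites in an L x L box
lattice_sites <- function(n, L, jitter_frac = 0.25) {
  m <- ceiling(sqrt(n))
  sp <- L / m
  gx <- (rep(seq_len(m), each = m) - 0.5) * sp
  gy <- (rep(seq_len(m), times = m) - 0.5) * sp
  keep <- seq_len(n)
  cbind(gx[keep] + stats::runif(n, -jitter_frac, jitter_frac) * sp,
        gy[keep] + stats::runif(n, -jitter_frac, jitter_frac) * sp)
}

# species labels: primary fraction x; clustered = seed-and-grow of the
# secondary species from one random start, adding the nearest unassigned
# lipid (minimum image) to the cluster until the target count is reached.
species_labels <- function(pos, L, x, layout, species) {
  n <- nrow(pos)
  n_b <- round((1 - x) * n)
  lab <- rep(species[1], n)
  if (n_b == 0) return(lab)
  if (layout == "random") {
    lab[sample.int(n, n_b)] <- species[2]
    return(lab)
  }
  start <- sample.int(n, 1)
  in_cluster <- rep(FALSE, n)
  in_cluster[start] <- TRUE
  dx <- pos[, 1] - pos[start, 1]; dx <- dx - L * round(dx / L)
  dy <- pos[, 2] - pos[start, 2]; dy <- dy - L * round(dy / L)
  mind <- dx^2 + dy^2
  mind[start] <- Inf
  while (sum(in_cluster) < n_b) {
    nxt <- which.min(mind)
    in_cluster[nxt] <- TRUE
    mind[nxt] <- Inf
    dx <- pos[, 1] - pos[nxt, 1]; dx <- dx - L * round(dx / L)
    dy <- pos[, 2] - pos[nxt, 2]; dy <- dy - L * round(dy / L)
    d2 <- dx^2 + dy^2
    upd <- !in_cluster & d2 < mind
    mind[upd] <- d2[upd]
  }
  lab[in_cluster] <- species[2]
  lab
}

random_unit_sphere <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Generate a synthetic bilayer trajectory with known ground truth
#'
#' See [synthetic_spec()] for the stated world. Every generated trajectory
#' satisfies the topology and trajectory invariants of the analysis modules,
#' and the returned ground-truth record contains everything needed to score
#' them: leaflet labels, species labels, the true (unwrapped) lateral
#' tracks, and the generative parameter values.
#'
#' @param spec `mm_synthetic_spec`.
#' @return List with `trajectory` (`mm_trajectory`) and `truth` (list:
#'   `leaflet` named character vector per lipid id, `species`, `tracks_x`,
#'   `tracks_y` true unwrapped `[n_frames x n_lipids]` matrices, `S_C`
#'   (= `order_w`), `tmg_mean_upper`, `tmg_mean_lower`, `tmg_sd`, `D_true`,
#'   `spec`).
#' @export
make_bilayer <- function(spec) {
  stopifnot(inherits(spec, "mm_synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_per_leaflet
  L <- spec$box[1]
  n_c <- spec$tail_length
  if (n > (floor(L / 2))^2) stop("lattice too dense for n_per_leaflet in box")
  nlip <- 2L * n
  # topology: per lipid 1 head + 2 tails of n_c members
  per <- 1L + 2L * n_c
  atoms <- data.frame(
    lipid_id = rep(seq_len(nlip), each = per),
    species = NA_character_,
    name = rep(c("P", paste0("C3", seq_len(n_c)), paste0("C2", seq_len(n_c))), nlip),
    head = rep(c(TRUE, rep(FALSE, 2L * n_c)), nlip),
    tail = rep(c(NA, rep("SN1", n_c), rep("SN2", n_c)), nlip),
    tail_pos = rep(c(NA, seq_len(n_c), seq_len(n_c)), nlip),
    tmg = rep(c(FALSE, seq_len(n_c) == n_c, seq_len(n_c) == n_c), nlip),
    first_tail_bead = rep(c(FALSE, seq_len(n_c) == 1L, rep(FALSE, n_c)), nlip),
    stringsAsFactors = FALSE
  )
  pos_u <- lattice_sites(n, L)
  pos_l <- lattice_sites(n, L)
  lab_u <- species_labels(pos_u, L, spec$species_fraction, spec$layout, spec$species)
  lab_l <- species_labels(pos_l, L, spec$species_fraction, spec$layout, spec$species)
  species_by_lipid <- c(lab_u, lab_l)
  leaflet_by_lipid <- rep(c("upper", "lower"), each = n)
  atoms$species <- rep(species_by_lipid, each = per)
  top <- mm_topology(atoms)

  nf <- spec$n_frames
  # Brownian lateral tracks for all lipids (head reference points)
  sd_step <- sqrt(2 * spec$D_true / mm_units()[["A2_per_ps_to_1e9_cm2_per_s"]] * spec$dt)
  start_xy <- rbind(pos_u, pos_l)
  tr_x <- matrix(0, nf, nlip); tr_y <- matrix(0, nf, nlip)
  tr_x[1, ] <- start_xy[, 1]; tr_y[1, ] <- start_xy[, 2]
  if (nf > 1 && sd_step > 0) {
    step_x <- matrix(stats::rnorm((nf - 1) * nlip, 0, sd_step), nf - 1, nlip)
    step_y <- matrix(stats::rnorm((nf - 1) * nlip, 0, sd_step), nf - 1, nlip)
    tr_x[-1, ] <- tr_x[rep(1, nf - 1), ] + apply(step_x, 2, cumsum)
    tr_y[-1, ] <- tr_y[rep(1, nf - 1), ] + apply(step_y, 2, cumsum)
  } else if (nf > 1) {
    tr_x[-1, ] <- tr_x[rep(1, nf - 1), ]
    tr_y[-1, ] <- tr_y[rep(1, nf - 1), ]
  }

  b <- 1.25  # chain bond projection per carbon, A
  sgn <- ifelse(leaflet_by_lipid == "upper", 1, -1)  # head side
  tmg_mean <- -sgn * (spec$h / 2 - spec$tmg_offset)
  head_rows <- which(atoms$head)
  sn1_rows <- matrix(which(!is.na(atoms$tail) & atoms$tail == "SN1"), nrow = n_c)
  sn2_rows <- matrix(which(!is.na(atoms$tail) & atoms$tail == "SN2"), nrow = n_c)
  # columns of sn*_rows are lipids (atom table is lipid-major); rows are pos

  coords <- array(0, c(nrow(atoms), 3, nf))
  for (k in seq_len(nf)) {
    hx <- tr_x[k, ] %% L
    hy <- tr_y[k, ] %% L
    hz <- sgn * spec$h / 2 + stats::rnorm(nlip, 0, spec$sigma_z)
    coords[head_rows, 1, k] <- hx
    coords[head_rows, 2, k] <- hy
    coords[head_rows, 3, k] <- hz
    for (tl in 1:2) {
      rows <- if (tl == 1) sn1_rows else sn2_rows
      aligned <- stats::runif(nlip) < spec$order_w
      u <- random_unit_sphere(nlip)
      u[aligned, ] <- 0
      u[aligned, 3] <- -sgn[aligned]  # aligned chains point toward midplane
      ztm <- stats::rnorm(nlip, tmg_mean, spec$tmg_sd)
      # atom at position i sits (n_c - i) * b back along the axis from TMG
      back <- (n_c - seq_len(n_c)) * b  # length n_c
      # [pos x lipid] coordinates
      cx <- matrix(hx, n_c, nlip, byrow = TRUE) -
        outer(back, u[, 1])
      cy <- matrix(hy, n_c, nlip, byrow = TRUE) -
        outer(back, u[, 2])
      cz <- matrix(ztm, n_c, nlip, byrow = TRUE) -
        outer(back, u[, 3])
      coords[rows, 1, k] <- cx
      coords[rows, 2, k] <- cy
      coords[rows, 3, k] <- cz
    }
  }
  traj <- mm_trajectory(top, coords,
                        matrix(rep(spec$box, each = nf), nf, 3),
                        (seq_len(nf) - 1) * spec$dt)
  truth <- list(
    leaflet = stats::setNames(leaflet_by_lipid, seq_len(nlip)),
    species = stats::setNames(species_by_lipid, seq_len(nlip)),
    tracks_x = tr_x, tracks_y = tr_y,
    S_C = spec$order_w,
    tmg_mean_upper = -(spec$h / 2 - spec$tmg_offset),
    tmg_mean_lower = +(spec$h / 2 - spec$tmg_offset),
    tmg_sd = spec$tmg_sd, D_true = spec$D_true, spec = spec
  )
  list(trajectory = traj, truth = truth)
}

#' Generate wrapped + true 2D Brownian tracks
#'
#' Light-weight generator for diffusion-estimator tests: pure 2D Brownian
#' motion with per-axis step variance `2 D dt`, periodically wrapped into
#' the box, with the true unwrapped tracks returned alongside.
#'
#' @param n_particles number of particles.
#' @param n_steps number of frames.
#' @param D diffusion coefficient, 1e-9 cm^2/s.
#' @param dt frame spacing, ps.
#' @param box lateral box lengths `(Lx, Ly)`, A.
#' @param seed integer seed.
#' @return List with `wrapped` and `true`, both `mm_tracks`.
#' @export
make_brownian_tracks <- function(n_particles, n_steps, D, dt,
                                 box = c(80, 80), seed = 1) {
  set.seed(seed)
  sd_step <- sqrt(2 * D / mm_units()[["A2_per_ps_to_1e9_cm2_per_s"]] * dt)
  x0 <- stats::runif(n_particles, 0, box[1])
  y0 <- stats::runif(n_particles, 0, box[2])
  x <- rbind(x0, matrix(stats::rnorm((n_steps - 1) * n_particles, 0, sd_step),
                        n_steps - 1, n_particles))
  y <- rbind(y0, matrix(stats::rnorm((n_steps - 1) * n_particles, 0, sd_step),
                        n_steps - 1, n_particles))
  x <- apply(x, 2, cumsum)
  y <- apply(y, 2, cumsum)
  true <- mm_tracks(x, y, dt)
  wrapped <- mm_tracks(x %% box[1], y %% box[2], dt)
  list(wrapped = wrapped, true = true)
}

#' Generate a synthetic surface-tension series of APL streams
#'
#' For each imposed tension, the area-per-lipid stream is a stationary AR(1)
#' process around the mean `A0 * (1 + gamma / K_A_true)` implied by the
#' linear tension-strain relation, with autocorrelation time `ar1_tau`
#' frames and stationary standard deviation `noise_sd`.
#'
#' @param K_A_true true area compressibility modulus, mN/m (> 0).
#' @param A0 tensionless area per lipid, A^2.
#' @param tensions imposed tensions, mN/m; must contain 0.
#' @param n_samples samples per stream.
#' @param ar1_tau AR(1) autocorrelation time in frames (0 = i.i.d.).
#' @param noise_sd stationary SD of each stream, A^2.
#' @param seed integer seed.
#' @return List with `streams` (named list of numeric vectors) and `points`
#'   (data.frame `gamma`, `apl_mean`, `apl_se`, `n_eff` ready for
#'   [fit_area_compressibility()]).
#' @export
make_tension_series <- function(K_A_true, A0, tensions = c(-7, 0, 7, 15),
                                n_samples = 3500, ar1_tau = 20,
                                noise_sd = 1.0, seed = 1) {
  if (K_A_true <= 0) stop("K_A_true must be positive")
  if (!any(tensions == 0)) stop("tensions must include 0")
  set.seed(seed)
  phi <- if (ar1_tau > 0) exp(-1 / ar1_tau) else 0
  streams <- list()
  pts <- data.frame(gamma = tensions, apl_mean = NA_real_, apl_se = NA_real_,
                    n_eff = NA_real_)
  for (i in seq_along(tensions)) {
    mu <- A0 * (1 + tensions[i] / K_A_true)
    if (noise_sd == 0) {
      s <- rep(mu, n_samples)
    } else {
      innov_sd <- noise_sd * sqrt(1 - phi^2)
      e <- stats::rnorm(n_samples, 0, innov_sd)
      s <- numeric(n_samples)
      s[1] <- mu + stats::rnorm(1, 0, noise_sd)
      for (t_ in 2:n_samples) s[t_] <- mu + phi * (s[t_ - 1] - mu) + e[t_]
    }
    streams[[as.character(tensions[i])]] <- s
    ss <- stationary_se(s)
    pts$apl_mean[i] <- ss$mean
    pts$apl_se[i] <- ss$se
    pts$n_eff[i] <- ss$n_eff
  }
  list(streams = streams, points = pts)
}

#' Generate a synthetic pressure-tensor record stream
#'
#' The normal pressure is fixed at 1 bar; the lateral components are drawn
#' i.i.d. Gaussian around the value implied by the target surface tension,
#' so the per-record tension has mean `gamma_true`.
#'
#' @param gamma_true target mean surface tension, mN/m.
#' @param Lz box height, A (> 0).
#' @param n number of records.
#' @param noise_sd_bar SD of each lateral pressure component, bar.
#' @param seed integer seed.
#' @param dt record spacing, ps.
#' @return data.frame with columns `time_ps`, `Pxx_bar`, `Pyy_bar`,
#'   `Pzz_bar`, `Lz_A`.
#' @export
make_pressure_stream <- function(gamma_true, Lz, n = 1000, noise_sd_bar = 50,
                                 seed = 1, dt = 1) {
  if (Lz <= 0) stop("Lz must be positive")
  set.seed(seed)
  k <- mm_units()[["bar_A_to_mN_per_m"]]
  p_lat <- 1 - gamma_true / (k * Lz)
  data.frame(
    time_ps = (seq_len(n) - 1) * dt,
    Pxx_bar = stats::rnorm(n, p_lat, noise_sd_bar),
    Pyy_bar = stats::rnorm(n, p_lat, noise_sd_bar),
    Pzz_bar = rep(1, n),
    Lz_A = rep(Lz, n)
  )
}
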