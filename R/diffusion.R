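# Lateral diffusion: periodic unwrapping, MSD with overlapping time origins,
# D from the Einstein relation MSD = 4 D t, and a Kolmogorov-Smirnov check
# for anomalous (non-Gaussian) diffusion.

#' Unwrap lateral (x-y) tracks across periodic boundaries
#'
#' Frame-to-frame coordinate increments are minimum-imaged per axis and
#' accumulated into continuous tracks. By default the selection centroid's
#' displacement is subtracted per frame to remove collective lateral drift.
#'
#' @param traj `mm_trajectory`.
#' @param species optional species label restricting the selection.
#' @param role atom role used as the reference point (default `"HEAD_P"`,
#'   i.e. the phosphorus atoms).
#' @param remove_drift subtract the per-frame centroid displacement of the
#'   selection (default `TRUE`).
#' @return An `mm_tracks`: list with `x`, `y` (`[n_frames x n_particles]`
#'   matrices, A), `times` (ps), `dt` (median frame spacing, ps) and
#'   `selection` descriptor.
#' @details A single-axis increment whose magnitude exceeds 45% of the box
#'   length is flagged with a warning naming the frame: displacements that
#'   close to half the box cannot be unwrapped unambiguously (possible
#'   undersampling).
#' @export
unwrap_xy <- function(traj, species = NULL, role = "HEAD_P",
                      remove_drift = TRUE) {
  idx <- atom_indices(traj$topology, species = species, role = role)
  if (!length(idx)) stop("empty selection")
  nf <- n_frames(traj)
  if (nf < 2) stop("need >= 2 frames to unwrap")
  x <- t(traj$coords[idx, 1, , drop = TRUE])
  y <- t(traj$coords[idx, 2, , drop = TRUE])
  if (length(idx) == 1L) { x <- matrix(x, ncol = 1); y <- matrix(y, ncol = 1) }
  for (k in 2:nf) {
    Lx <- traj$box[k, 1]; Ly <- traj$box[k, 2]
    ddx <- x[k, ] - x[k - 1, ]
    ddy <- y[k, ] - y[k - 1, ]
    ddx <- ddx - Lx * round(ddx / Lx)
    ddy <- ddy - Ly * round(ddy / Ly)
    if (any(abs(ddx) > 0.45 * Lx) || any(abs(ddy) > 0.45 * Ly)) {
      warning("frame ", k, ": lateral jump close to half the box; ",
              "possible undersampling, unwrapping may be ambiguous")
    }
    x[k, ] <- x[k - 1, ] + ddx
    y[k, ] <- y[k - 1, ] + ddy
  }
  if (remove_drift) {
    x <- x - (rowMeans(x) - mean(x[1, ]))
    y <- y - (rowMeans(y) - mean(y[1, ]))
  }
  dt <- if (nf > 1) stats::median(diff(traj$times)) else 1
  structure(list(x = x, y = y, times = traj$times, dt = dt,
                 selection = list(species = species, role = role,
                                  drift_removed = remove_drift)),
            class = "mm_tracks")
}

#' Construct tracks directly from coordinate matrices
#'
#' Convenience constructor for already-continuous tracks (e.g. the ground
#' truth stored by the synthetic generator).
#'
#' @param x,y `[n_frames x n_particles]` matrices, A.
#' @param dt frame spacing, ps.
#' @return `mm_tracks`.
#' @export
mm_tracks <- function(x, y, dt) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(all(dim(x) == dim(y)), dt > 0)
  structure(list(x = x, y = y, times = (seq_len(nrow(x)) - 1) * dt, dt = dt,
                 selection = list(species = NULL, role = "direct",
                                  drift_removed = FALSE)),
            class = "mm_tracks")
}

# FFT-based MSD for one coordinate matrix [T x N]: per lag k (0..T-1),
# sum over particles and overlapping origins of (x_{t+k} - x_t)^2, via the
# standard S1 - 2 S2 decomposition. S2 (the autocorrelation) comes from one
# zero-padded mvfft over all particles; S1 from prefix-sum identities.
msd_fft_1d <- function(m) {
  T_ <- nrow(m); N <- ncol(m)
  nfft <- stats::nextn(2 * T_, 2)
  pad <- rbind(m, matrix(0, nfft - T_, N))
  f <- stats::mvfft(pad)
  ac <- Re(stats::mvfft(f * Conj(f), inverse = TRUE))[seq_len(T_), , drop = FALSE] / nfft
  sq <- m^2
  cs <- apply(sq, 2, cumsum)                 # sum_{j <= k} x_j^2
  csr <- apply(sq[T_:1, , drop = FALSE], 2, cumsum)  # from the tail
  tot <- matrix(cs[T_, ], T_, N, byrow = TRUE)
  # S1[k+1] = 2*sum(sq) - sum(first k) - sum(last k)
  lead <- rbind(0, cs[-T_, , drop = FALSE])
  tail_ <- rbind(0, csr[-T_, , drop = FALSE])
  s1 <- 2 * tot - lead - tail_
  counts <- T_ - (0:(T_ - 1))
  list(sum_over_particles = rowSums(s1 - 2 * ac), counts = counts * N)
}

#' Mean squared lateral displacement
#'
#' MSD over all particles and all overlapping time origins (stride 1):
#' `MSD(k dt) = < |r(t + k dt) - r(t)|^2 >` for the x-y displacement. The
#' implementation uses the standard FFT decomposition; an O(T^2) brute force
#' gives identical values on small inputs.
#'
#' @param tracks `mm_tracks` (continuous, unwrapped).
#' @param max_lag maximum lag in ps (default: half the track span). Truncated
#'   with a warning if it reaches the span.
#' @return An `mm_msd`: data.frame with columns `lag_ps`, `msd` (A^2) and
#'   `count` (displacement pairs contributing), plus attribute `dt`.
#' @export
msd <- function(tracks, max_lag = NULL) {
  T_ <- nrow(tracks$x)
  if (T_ < 2) stop("need >= 2 frames")
  span <- (T_ - 1) * tracks$dt
  if (is.null(max_lag)) max_lag <- span / 2
  if (max_lag >= span + tracks$dt / 2) {
    warning("max_lag >= trajectory span; truncating to span")
    max_lag <- span
  }
  kmax <- min(T_ - 1, floor(max_lag / tracks$dt + 1e-9))
  rx <- msd_fft_1d(tracks$x)
  ry <- msd_fft_1d(tracks$y)
  msd_val <- (rx$sum_over_particles + ry$sum_over_particles) / rx$counts
  lags <- 0:kmax
  out <- data.frame(lag_ps = lags * tracks$dt,
                    msd = pmax(msd_val[lags + 1], 0),
                    count = rx$counts[lags + 1])
  attr(out, "dt") <- tracks$dt
  class(out) <- c("mm_msd", "data.frame")
  out
}

#' Fit the lateral diffusion coefficient from an MSD curve
#'
#' Ordinary least squares of MSD versus lag time over a fit window; the 2D
#' Einstein relation gives `D = slope / 4`, converted from A^2/ps to
#' 1e-9 cm^2/s (1 A^2/ps = 1e5 in those units).
#'
#' @param curve `mm_msd`.
#' @param window numeric `(t_min, t_max)` in ps; default is 10%..50% of the
#'   largest lag in the curve.
#' @return An `mm_diffusion`: list with `D`, `se` (1e-9 cm^2/s), `window`,
#'   `intercept` (A^2), `slope_A2_per_ps`, `n_lags` and `negative_slope`
#'   flag (D is reported as max(D, 0) with the flag set when the raw slope
#'   is negative).
#' @export
fit_diffusion <- function(curve, window = NULL) {
  lmax <- max(curve$lag_ps)
  if (is.null(window)) window <- c(0.1, 0.5) * lmax
  sel <- curve$lag_ps >= window[1] & curve$lag_ps <= window[2] & curve$lag_ps > 0
  if (sum(sel) < 5) stop("fewer than 5 lags in the fit window")
  fit <- stats::lm(msd ~ lag_ps, data = curve[sel, ])
  slope <- stats::coef(fit)[["lag_ps"]]
  slope_se <- suppressWarnings(summary(fit))$coefficients["lag_ps", "Std. Error"]
  k <- mm_units()[["A2_per_ps_to_1e9_cm2_per_s"]]
  D <- slope / 4 * k
  structure(list(D = max(D, 0), se = slope_se / 4 * k, window = window,
                 intercept = stats::coef(fit)[["(Intercept)"]],
                 slope_A2_per_ps = slope, n_lags = sum(sel),
                 negative_slope = slope < 0),
            class = "mm_diffusion")
}

#' @export
print.mm_diffusion <- function(x, ...) {
  cat("<mm_diffusion> D = ", format(x$D, digits = 4), " +/- ",
      format(x$se, digits = 3), " x 1e-9 cm^2/s (window ",
      format(x$window[1]), "..", format(x$window[2]), " ps)\n", sep = "")
  invisible(x)
}

#' Kolmogorov-Smirnov check for anomalous diffusion
#'
#' Pools the x and y displacement increments at one lag and tests them,
#' two-sided, against a zero-mean Gaussian whose variance is estimated from
#' the same increments. Normal diffusion gives Gaussian increments; heavy
#' tails or other non-Gaussian structure (anomalous diffusion) drives the
#' p-value down. Estimating the variance from the tested sample makes the
#' test mildly conservative.
#'
#' Increments are taken at non-overlapping windows (stride = lag):
#' overlapping windows share steps and are autocorrelated, which would
#' invalidate the i.i.d. assumption of the KS test and inflate its
#' false-positive rate severalfold. Because the reference variance is
#' estimated from the tested sample itself, the textbook KS p-value is
#' conservative (Lilliefors effect); the reported p is therefore calibrated
#' by parametric bootstrap -- `n_boot` Gaussian samples of the same size,
#' each with its variance re-estimated -- which restores the nominal level.
#' `n_boot = 0` returns the uncalibrated (conservative) p.
#'
#' @param tracks `mm_tracks`.
#' @param lag lag in ps (rounded to a whole number of frames, >= 1).
#' @param n_boot bootstrap replicates for the calibrated p (default 199).
#' @return List with `statistic` (KS D), `p`, `n_increments`, `lag_frames`.
#' @export
anomaly_test <- function(tracks, lag, n_boot = 199) {
  kf <- max(1L, round(lag / tracks$dt))
  T_ <- nrow(tracks$x)
  if (kf >= T_) stop("lag exceeds track length")
  orig <- seq(1L, T_ - kf, by = kf)
  inc <- c(tracks$x[orig + kf, ] - tracks$x[orig, ],
           tracks$y[orig + kf, ] - tracks$y[orig, ])
  if (length(inc) < 100) stop("need >= 100 increments at this lag")
  s <- sqrt(mean(inc^2))
  if (s == 0) stop("degenerate (constant) increments; KS test undefined")
  ks_stat <- function(x, sd_) {
    n <- length(x)
    u <- stats::pnorm(sort(x), 0, sd_)
    max(seq_len(n) / n - u, u - (seq_len(n) - 1) / n)
  }
  D <- ks_stat(inc, s)
  if (n_boot > 0) {
    n <- length(inc)
    ge <- 0L
    for (b in seq_len(n_boot)) {
      z <- stats::rnorm(n, 0, s)
      if (ks_stat(z, sqrt(mean(z^2))) >= D) ge <- ge + 1L
    }
    p <- (1 + ge) / (n_boot + 1)
  } else {
    p <- suppressWarnings(stats::ks.test(inc, "pnorm", mean = 0, sd = s))$p.value
  }
  list(statistic = D, p = p, n_increments = length(inc), lag_frames = kf)
}
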