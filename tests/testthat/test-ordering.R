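# A trajectory whose tails are straight chains along a fixed unit vector u.
chain_traj <- function(u, n_lipids = 4, tail_len = 6, n_frames = 2) {
  top <- toy_topology(n_lipids, tail_len = tail_len)
  b <- 1.25
  frames <- lapply(seq_len(n_frames), function(k) {
    m <- matrix(NA_real_, nrow(top$atoms), 3)
    for (l in seq_len(n_lipids)) {
      base <- c(5 * l, 5 * l, ifelse(l %% 2 == 0, 20, -20))
      rows <- which(top$atoms$lipid_id == l)
      m[rows[1], ] <- base
      chain <- t(vapply(seq_len(tail_len), function(i) base + (i - 1) * b * u,
                        numeric(3)))
      m[rows[2:(1 + tail_len)], ] <- chain
      m[rows[(2 + tail_len):(1 + 2 * tail_len)], ] <- chain
    }
    m
  })
  toy_trajectory(top, frames)
}

test_that("order parameters hit the closed-form extremes", {
  # all-trans chain exactly parallel to z -> S = 1 at every interior carbon
  tz <- chain_traj(c(0, 0, 1))
  pz <- order_parameter_profile(tz, "DOPC", "SN1")
  expect_equal(pz$carbon, 2:5)
  expect_equal(pz$S, rep(1, 4))
  # chain axis in the x-y plane -> S = -0.5
  txy <- chain_traj(c(1 / sqrt(2), 1 / sqrt(2), 0))
  expect_equal(order_parameter_profile(txy, "DOPC", "SN2")$S, rep(-0.5, 4))
  expect_error(order_parameter_profile(tz, "NOPE", "SN1"), "no atoms")
})

test_that("mixture generator closure: S_C = w at every interior carbon", {
  for (w in c(0, 0.6, 1.0)) {
    spec <- synthetic_spec(n_per_leaflet = 50, order_w = w, tail_length = 10,
                           n_frames = 60, seed = round(100 * w) + 1)
    bl <- make_bilayer(spec)
    p <- order_parameter_profile(bl$trajectory, "DOPC", "SN1")
    # w = 1 is exact (every chain aligned); w < 1 has sampling noise
    tol <- if (w == 1) 1e-9 else 0.03
    expect_lt(max(abs(p$S - w)), tol + 1e-12)
    expect_true(all(p$S >= -0.5 - 1e-9 & p$S <= 1 + 1e-9))
  }
})

test_that("S_C is invariant under rotation about z and z-translation", {
  spec <- synthetic_spec(n_per_leaflet = 30, order_w = 0.4, tail_length = 8,
                         n_frames = 10, seed = 21)
  bl <- make_bilayer(spec)
  p0 <- order_parameter_profile(bl$trajectory, "DOPC", "SN1")
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  tr <- bl$trajectory
  for (k in seq_len(n_frames(tr))) {
    tr$coords[, , k] <- tr$coords[, , k] %*% t(R)
  }
  tr$coords[, 3, ] <- tr$coords[, 3, ] + 4.2
  p1 <- order_parameter_profile(tr, "DOPC", "SN1")
  expect_equal(p1$S, p0$S, tolerance = 1e-10)
})

test_that("relative order profiles reduce to the carbon-index diagonal", {
  spec <- synthetic_spec(n_per_leaflet = 20, order_w = 0.5, tail_length = 8,
                         n_frames = 5, seed = 31)
  p <- order_parameter_profile(make_bilayer(spec)$trajectory, "DOPC", "SN1")
  d <- relative_order_profile(p, p)
  expect_equal(d$value, d$carbon)
  expect_equal(d$carbon, 2:7)

  p90 <- p; p90$S <- 0.9 * p90$S
  expect_equal(relative_order_profile(p90, p)$value, 0.9 * p$carbon)

  # hand-computed ratio grid from two generator runs
  spec2 <- synthetic_spec(n_per_leaflet = 20, order_w = 0.6, tail_length = 8,
                          n_frames = 5, seed = 32)
  p2 <- order_parameter_profile(make_bilayer(spec2)$trajectory, "DOPC", "SN1")
  r <- relative_order_profile(p2, p)
  expect_equal(r$value, p2$S / p$S * p$carbon)

  pz <- p; pz$S[2] <- 0
  expect_warning(out <- relative_order_profile(p, pz), "S = 0")
  expect_false(3 %in% out$carbon)
})

test_that("TMG distributions recover the generator and conserve mass", {
  spec <- synthetic_spec(n_per_leaflet = 100, h = 38, tmg_offset = 16,
                         tmg_sd = 2, tail_length = 6, n_frames = 50, seed = 41)
  bl <- make_bilayer(spec)
  asg <- assign_leaflets(get_frame(bl$trajectory, 1), bl$trajectory$topology)
  h <- tmg_distribution(bl$trajectory, asg, "DOPC", bin_width = 1)
  # upper-leaflet TMGs sit below the midplane at -(h/2 - offset) = -3
  n_up <- length(h$z$upper)
  expect_lt(abs(mean(h$z$upper) - (-3)), 3 * 2 / sqrt(n_up / 10))
  expect_lt(abs(mean(h$z$lower) - 3), 0.5)
  expect_lt(abs(sd(h$z$upper) - 2) / 2, 0.10)
  # densities integrate to 1
  for (d in list(h$density_upper, h$density_lower, h$density_both)) {
    expect_equal(sum(d) * h$bin_width, 1, tolerance = 1e-9)
  }
  h2 <- tmg_distribution(bl$trajectory, asg, "DOPC", bin_width = 2)
  expect_equal(sum(h2$density_both) * 2, 1, tolerance = 1e-9)
  # mirror symmetry of the combined histogram for a z-symmetric world
  mid <- h$mids
  sym_err <- vapply(seq_along(mid), function(i) {
    j <- which.min(abs(mid + mid[i]))
    abs(h$density_both[i] - h$density_both[j])
  }, numeric(1))
  expect_lt(mean(sym_err), 0.02)
  expect_error(tmg_distribution(bl$trajectory, asg, "NOPE"), "TMG")
})
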