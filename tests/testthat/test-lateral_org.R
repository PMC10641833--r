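# Frame with explicit upper-leaflet head positions (plus a 4-seed lower
# leaflet so assignment is valid).
seeds_frame <- function(xy, L, species = rep("DOPC", nrow(xy) + 4)) {
  n <- nrow(xy)
  top <- toy_topology(n + 4, species = species)
  lower <- cbind(c(5, 50, 5, 50), c(5, 5, 50, 50), -20)
  fr <- mm_frame(rbind(cbind(xy, 20), lower), c(L, L, 60))
  list(top = top, fr = fr, asg = assign_leaflets(fr, top))
}

test_that("Voronoi areas: lattice symmetry, conservation, raster oracle", {
  # perfect square lattice -> every cell = L^2 / N
  L <- 60; m <- 5
  g <- as.matrix(expand.grid(x = (seq_len(m) - 0.5) * L / m,
                             y = (seq_len(m) - 0.5) * L / m))
  sf <- seeds_frame(g, L)
  vm <- voronoi_areas(sf$fr, sf$top, sf$asg, "upper")
  expect_equal(vm$area, rep(L^2 / 25, 25), tolerance = 1e-9)

  # uniform random seeds: area conservation and positivity
  set.seed(17)
  xy <- cbind(runif(50, 0, L), runif(50, 0, L))
  sf2 <- seeds_frame(xy, L)
  vm2 <- voronoi_areas(sf2$fr, sf2$top, sf2$asg, "upper")
  expect_lt(abs(sum(vm2$area) - L^2) / L^2, 1e-6)
  expect_true(all(vm2$area > 0))

  # raster-oracle agreement on a physically plausible 50-seed leaflet
  # (generator headgroups; uniform draws can produce near-coincident seeds
  # whose sliver cells no pixel raster resolves)
  spec <- synthetic_spec(n_per_leaflet = 50, tail_length = 4, n_frames = 1,
                         seed = 19)
  bl <- make_bilayer(spec)
  asg <- assign_leaflets(get_frame(bl$trajectory, 1), bl$trajectory$topology)
  vg <- voronoi_areas(get_frame(bl$trajectory, 1), bl$trajectory$topology,
                      asg, "upper")
  Lg <- bl$trajectory$box[1, 1]
  oracle <- voronoi_raster_oracle(vg$x, vg$y, Lg, npix = 2000)
  expect_lt(max(abs(oracle - vg$area) / vg$area), 0.005)

  # coincident seeds are rejected with lipid ids
  xy3 <- rbind(c(10, 10), c(10, 10), c(30, 30))
  sf3 <- seeds_frame(xy3, L)
  expect_error(voronoi_areas(sf3$fr, sf3$top, sf3$asg, "upper"),
               "coincident seeds")
})

test_that("mixed contacts match enumeration and binomial expectations", {
  # single species -> f_mix = 0
  set.seed(2)
  xy <- cbind(runif(20, 0, 60), runif(20, 0, 60))
  sf <- seeds_frame(xy, 60)
  tr <- toy_trajectory(sf$top, list(sf$fr$coords), box = c(60, 60, 60))
  expect_equal(mixed_contacts(tr, sf$asg, cutoff = 11)$f_mix, 0)

  # 50:50 checkerboard, cutoff covering only the 4 nearest neighbors
  L <- 80; m <- 8; a <- L / m
  g <- expand.grid(i = 0:(m - 1), j = 0:(m - 1))
  xy2 <- cbind((g$i + 0.5) * a, (g$j + 0.5) * a)
  spc <- ifelse((g$i + g$j) %% 2 == 0, "DOPC", "DHPC")
  sf2 <- seeds_frame(xy2, L, species = c(spc, rep("DOPC", 4)))
  tr2 <- toy_trajectory(sf2$top, list(sf2$fr$coords), box = c(L, L, 60))
  mc <- mixed_contacts(tr2, sf2$asg, cutoff = a * 1.05)
  expect_equal(mc$f_mix, 1.0)
  expect_equal(mc$C_AA + mc$C_BB, 0)

  # random 75:25 labels on the lattice -> E[f_mix] = 2 * 0.75 * 0.25
  set.seed(31)
  fr_vals <- replicate(40, {
    lab <- sample(c(rep("DOPC", 48), rep("DHPC", 16)))
    sfr <- seeds_frame(xy2, L, species = c(lab, rep("DOPC", 4)))
    trr <- toy_trajectory(sfr$top, list(sfr$fr$coords), box = c(L, L, 60))
    mixed_contacts(trr, sfr$asg, cutoff = a * 1.05)$f_mix
  })
  se <- sd(fr_vals) / sqrt(length(fr_vals))
  expect_lt(abs(mean(fr_vals) - 0.375), 3 * se)

  # exact equality with the brute-force O(N^2) oracle
  set.seed(7)
  n <- 60
  xyr <- cbind(runif(n, 0, 60), runif(n, 0, 60))
  labr <- sample(c("DOPC", "DHPC"), n, replace = TRUE, prob = c(0.7, 0.3))
  sfr <- seeds_frame(xyr, 60, species = c(labr, rep("DOPC", 4)))
  trr <- toy_trajectory(sfr$top, list(sfr$fr$coords), box = c(60, 60, 60))
  mcr <- mixed_contacts(trr, sfr$asg, cutoff = 11)
  hp <- atom_indices(sfr$top, role = "HEAD_P")
  oracle <- contacts_brute(sfr$fr$coords[hp, ], c(60, 60, 60),
                           sfr$top$lipids$species,
                           sfr$asg$labels[as.character(sfr$top$lipids$lipid_id)],
                           cutoff = 11)
  expect_equal(mcr$C_AB, unname(oracle["AB"]))
  expect_equal(mcr$C_AA + mcr$C_BB, unname(oracle["AA"] + oracle["BB"]))

  # A<->B relabeling leaves f_mix unchanged
  lab_sw <- ifelse(labr == "DOPC", "DHPC", "DOPC")
  sfs <- seeds_frame(xyr, 60, species = c(lab_sw, rep("DHPC", 4)))
  trs <- toy_trajectory(sfs$top, list(sfs$fr$coords), box = c(60, 60, 60))
  expect_equal(mixed_contacts(trs, sfs$asg, cutoff = 11)$f_mix, mcr$f_mix)
  expect_error(mixed_contacts(trr, sfr$asg, cutoff = -1), "positive")
})

test_that("clustered layouts mix less than random ones", {
  f_of <- function(layout, s) {
    spec <- synthetic_spec(n_per_leaflet = 64, species_fraction = 0.75,
                           layout = layout, D_true = 0, tail_length = 4,
                           n_frames = 1, seed = s)
    bl <- make_bilayer(spec)
    asg <- assign_leaflets(get_frame(bl$trajectory, 1), bl$trajectory$topology)
    mixed_contacts(bl$trajectory, asg, cutoff = 11)$f_mix
  }
  diffs <- vapply(1:20, function(s) f_of("clustered", s) < f_of("random", s),
                  logical(1))
  # sign test: P(all-but-<=2 of 20) under p = 0.5 is << 0.01
  expect_gte(sum(diffs), 17)
})

test_that("neighbor composition matches hand enumeration and Table arithmetic", {
  # 10-lipid toy layout, hand-enumerable
  xy <- cbind(c(5, 15, 25, 35, 45, 5, 15, 25, 35, 45),
              c(5, 5, 5, 5, 5, 15, 15, 15, 15, 15))
  lab <- c("DOPC", "DOPC", "DHPC", "DOPC", "DHPC",
           "DOPC", "DHPC", "DOPC", "DOPC", "DOPC")
  sf <- seeds_frame(xy, 60, species = c(lab, rep("DOPC", 4)))
  tr <- toy_trajectory(sf$top, list(sf$fr$coords), box = c(60, 60, 60))
  nc <- neighbor_composition(tr, sf$asg, cutoff = 12, role = "FIRST_TAIL_BEAD")
  # brute-force oracle on the same layout (first tail bead == head position
  # for the single-atom toy lipids)
  hp <- atom_indices(sf$top, role = "FIRST_TAIL_BEAD")
  xyz <- sf$fr$coords[hp, ]
  lfl <- sf$asg$labels[as.character(sf$top$lipids$lipid_id)]
  spc <- sf$top$lipids$species
  cnt <- matrix(0, length(hp), 2, dimnames = list(NULL, c("DHPC", "DOPC")))
  for (i in seq_along(hp)) for (j in seq_along(hp)) {
    if (i == j || lfl[i] != lfl[j]) next
    d <- xyz[i, ] - xyz[j, ]; d <- d - c(60, 60, 60) * round(d / c(60, 60, 60))
    if (sum(d^2) <= 144) cnt[i, spc[j]] <- cnt[i, spc[j]] + 1
  }
  for (cs in c("DOPC", "DHPC")) for (ns in c("DOPC", "DHPC")) {
    expect_equal(nc$mean_count[nc$center_species == cs & nc$neighbor_species == ns],
                 mean(cnt[spc == cs, ns]))
  }
  # percentage shares sum to 100 per center species
  for (cs in c("DOPC", "DHPC")) {
    expect_equal(sum(nc$percent[nc$center_species == cs]), 100)
  }

  # printed-counts arithmetic: 6.73/3.26 -> 67.4% / 32.6%
  sh <- neighbor_shares(c(6.73, 3.26))
  expect_equal(round(sh, 1), c(67.4, 32.6))

  # pure system -> 100% same species
  sfp <- seeds_frame(xy, 60)
  trp <- toy_trajectory(sfp$top, list(sfp$fr$coords), box = c(60, 60, 60))
  ncp <- neighbor_composition(trp, sfp$asg, cutoff = 12)
  expect_equal(ncp$percent, 100)
})

test_that("Voronoi area distributions: degenerate lattice and invariances", {
  L <- 60; m <- 5
  g <- as.matrix(expand.grid(x = (seq_len(m) - 0.5) * L / m,
                             y = (seq_len(m) - 0.5) * L / m))
  sf <- seeds_frame(g, L)
  vm <- voronoi_areas(sf$fr, sf$top, sf$asg, "upper")
  d <- voronoi_area_distribution(vm)
  expect_equal(unname(unlist(d$quartiles[1, c("q25", "median", "q75")])),
               rep(L^2 / 25, 3), tolerance = 1e-9)

  # two species with identical spatial statistics -> matching quartiles
  set.seed(4)
  xy <- cbind(runif(80, 0, L), runif(80, 0, L))
  lab <- rep(c("DOPC", "DHPC"), 40)
  sf2 <- seeds_frame(xy, L, species = c(lab, rep("DOPC", 4)))
  vm2 <- voronoi_areas(sf2$fr, sf2$top, sf2$asg, "upper")
  d2 <- voronoi_area_distribution(vm2)
  expect_lt(abs(d2$quartiles$median[1] - d2$quartiles$median[2]),
            0.5 * mean(d2$quartiles$median))

  # rigid shift of all seeds leaves the areas unchanged
  xy3 <- (xy + 13.7) %% L
  sf3 <- seeds_frame(xy3, L, species = c(lab, rep("DOPC", 4)))
  vm3 <- voronoi_areas(sf3$fr, sf3$top, sf3$asg, "upper")
  expect_equal(sort(vm3$area), sort(vm2$area), tolerance = 1e-6)
})
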