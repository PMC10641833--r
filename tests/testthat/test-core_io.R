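test_that("topology invariants are enforced", {
  top <- toy_topology(4, tail_len = 7)
  expect_s3_class(top, "mm_topology")
  expect_equal(nrow(top$lipids), 4)
  expect_equal(sum(top$atoms$tail == "SN1", na.rm = TRUE), 4 * 7)
  expect_equal(sum(top$atoms$tmg), 8)

  # lipid without a head
  bad <- top$atoms
  bad$head[bad$lipid_id == 2 & bad$head] <- FALSE
  expect_error(mm_topology(bad), "exactly one HEAD_P.*2")
  # tail too short
  expect_error(toy_topology(2, tail_len = 2), "fewer than 3")
  # TMG not last
  bad2 <- toy_topology(2, tail_len = 5)$atoms
  i_last <- which(bad2$lipid_id == 1 & bad2$tail == "SN1" & bad2$tail_pos == 5)
  i_mid <- which(bad2$lipid_id == 1 & bad2$tail == "SN1" & bad2$tail_pos == 3)
  bad2$tmg[i_last] <- FALSE; bad2$tmg[i_mid] <- TRUE
  expect_error(mm_topology(bad2), "TMG")
})

test_that("GRO topology parsing tags CHARMM DOPC roles, matching MDAnalysis", {
  gro <- write_test_gro(tempfile(fileext = ".gro"), n_frames = 2)
  top <- load_topology(gro, "gro")
  expect_equal(nrow(top$lipids), 2)
  for (tl in c("SN1", "SN2")) {
    expect_equal(sum(top$atoms$tail == tl & top$atoms$lipid_id == 1, na.rm = TRUE), 18)
  }
  expect_setequal(unique(top$atoms$name[top$atoms$tmg]), c("C218", "C318"))
  # glycerol carbons retained but untagged
  expect_true(all(is.na(top$atoms$tail[top$atoms$name %in% c("C1", "C2", "C3")])))

  # independent reference reader agreement on atom counts and P selection
  py <- sprintf(
    "import MDAnalysis as mda\nu = mda.Universe(%s)\nprint(len(u.atoms), len(u.select_atoms('name P')))",
    deparse(gro))
  sf <- tempfile(fileext = ".py"); writeLines(py, sf)
  out <- system2("python", sf, stdout = TRUE, stderr = FALSE)
  ref <- as.integer(strsplit(tail(out, 1), " ")[[1]])
  expect_equal(nrow(top$atoms), ref[1])
  expect_equal(sum(top$atoms$head), ref[2])
})

test_that("PDB lipid lacking a P atom raises an error naming the lipid", {
  pdb <- tempfile(fileext = ".pdb")
  lines <- c("CRYST1   80.000   80.000  100.000  90.00  90.00  90.00 P 1")
  mk <- function(serial, name, resid, z) {
    sprintf("ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00",
            serial, name, "DHPC", resid, 1.0, 2.0, z)
  }
  nm <- c("P", paste0("C2", 1:7), paste0("C3", 1:7))
  s <- 0; out <- lines
  for (r in 1:2) for (a in nm) {
    if (r == 2 && a == "P") next  # second lipid misses its phosphorus
    s <- s + 1
    out <- c(out, mk(s, a, r, ifelse(r == 1, 20, -20)))
  }
  writeLines(c(out, "END"), pdb)
  expect_error(load_topology(pdb, "pdb", role_map = list(
    DHPC = list(head = "^P$", sn1 = "^C3([0-9]+)$", sn2 = "^C2([0-9]+)$")
  )), "HEAD_P.*2")
})

test_that("fixture round-trips coordinates to 1e-6 A", {
  spec <- synthetic_spec(n_per_leaflet = 6, tail_length = 4, n_frames = 3,
                         seed = 5)
  bl <- make_bilayer(spec)
  f <- tempfile(fileext = ".txt")
  write_fixture(bl$trajectory, f)
  top2 <- load_topology(f, "fixture")
  tr2 <- load_trajectory(top2, f, "fixture")
  expect_lt(max(abs(tr2$coords - bl$trajectory$coords)), 1e-6)
  expect_equal(tr2$times, bl$trajectory$times)
  expect_equal(top2$atoms$tail, bl$trajectory$topology$atoms$tail)
  # truncated file -> error, no partial trajectory
  lines <- readLines(f)
  writeLines(lines[1:(length(lines) - 5)], f)
  expect_error(load_trajectory(top2, f, "fixture"), "truncated")
})

test_that("trajectory loading converts nm sources to A and checks counts", {
  gro <- write_test_gro(tempfile(fileext = ".gro"), n_frames = 2)
  top <- load_topology(gro, "gro")
  tr <- load_trajectory(top, gro, "gro")
  expect_equal(n_frames(tr), 2)
  # second atom written at x = 0.1*2 + 1 = 1.2 nm -> 12 A
  expect_equal(tr$coords[2, 1, 1], 12, tolerance = 1e-8)
  expect_false(is.unsorted(tr$times))
  # atom-count mismatch reports both counts
  spec <- synthetic_spec(n_per_leaflet = 4, tail_length = 4, n_frames = 1, seed = 1)
  other <- make_bilayer(spec)$trajectory
  f <- tempfile(fileext = ".txt")
  write_fixture(other, f)
  expect_error(load_trajectory(top, f, "fixture"), "atom-count mismatch")
})

test_that("XTC and DCD dialects agree with the GRO source", {
  gro <- write_test_gro(tempfile(fileext = ".gro"))
  top <- load_topology(gro, "gro")
  tg <- load_trajectory(top, gro, "gro")
  py <- sprintf(paste0(
    "import MDAnalysis as mda\nu = mda.Universe(%s)\n",
    "import warnings; warnings.filterwarnings('ignore')\n",
    "w = mda.Writer(%s, len(u.atoms)); w.write(u.atoms); w.close()\n",
    "w = mda.Writer(%s, len(u.atoms)); w.write(u.atoms); w.close()\n"),
    deparse(gro), deparse(xtc <- tempfile(fileext = ".xtc")),
    deparse(dcd <- tempfile(fileext = ".dcd")))
  sf <- tempfile(fileext = ".py"); writeLines(py, sf)
  expect_equal(system2("python", sf, stdout = FALSE, stderr = FALSE), 0L)
  tx <- load_trajectory(top, xtc, "xtc")
  expect_lt(max(abs(tx$coords[, , 1] - tg$coords[, , 1])), 1e-2)  # float32
  td <- load_trajectory(top, dcd, "dcd")
  expect_lt(max(abs(td$coords[, , 1] - tg$coords[, , 1])), 1e-4)
  expect_equal(td$box[1, ], c(80, 80, 100))
})

test_that("leaflet assignment splits by midplane and matches generator truth", {
  top <- toy_topology(2)
  fr <- mm_frame(rbind(c(0, 0, 10), c(0, 0, -10)), c(80, 80, 100))
  a <- assign_leaflets(fr, top)
  expect_equal(a$z_center, 0)
  expect_equal(unname(a$labels), c("upper", "lower"))
  # degenerate monolayer
  fr2 <- mm_frame(rbind(c(0, 0, 10), c(0, 0, 10)), c(80, 80, 100))
  expect_error(assign_leaflets(fr2, top), "degenerate")

  spec <- synthetic_spec(n_per_leaflet = 50, sigma_z = 2, h = 38,
                         tail_length = 4, n_frames = 1, seed = 3)
  bl <- make_bilayer(spec)
  a2 <- assign_leaflets(get_frame(bl$trajectory, 1), bl$trajectory$topology)
  expect_equal(unname(a2$labels[names(bl$truth$leaflet)]),
               unname(bl$truth$leaflet))
  # invariance under rigid z-translation
  tr <- bl$trajectory
  tr$coords[, 3, ] <- tr$coords[, 3, ] + 17.3
  a3 <- assign_leaflets(get_frame(tr, 1), tr$topology)
  expect_equal(a3$labels, a2$labels)
  expect_equal(a3$z_center, a2$z_center + 17.3, tolerance = 1e-10)
})
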