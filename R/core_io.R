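# Domain containers and I/O.
#
# A topology is a flat atom table plus a lipid table; roles are tagged per
# atom (HEAD_P, TAIL_SN1/TAIL_SN2 with a 1-based position counted from the
# glycerol end, TMG, FIRST_TAIL_BEAD). A trajectory stores coordinates as a
# dense [n_atoms x 3 x n_frames] array in angstrom with per-frame
# orthorhombic boxes; z is the bilayer normal.

#' Construct a bilayer topology
#'
#' Builds the topology container from a per-atom table. Most users will not
#' call this directly but obtain topologies from [load_topology()] or
#' [make_bilayer()].
#'
#' @param atoms data.frame with one row per atom, columns `lipid_id`
#'   (integer), `species` (character), `name` (character atom name), `head`
#'   (logical: phosphorus/PO4 reference atom), `tail` (character `"SN1"`,
#'   `"SN2"` or `NA`), `tail_pos` (integer position along the tail counted
#'   from the glycerol end, `NA` for non-tail atoms), `tmg` (logical:
#'   terminal methyl of a tail), `first_tail_bead` (logical: CG GL1
#'   equivalent; optional, defaults to all `FALSE`).
#' @return An object of class `mm_topology` with elements `atoms` (the
#'   validated table, plus an `atom` index column) and `lipids`
#'   (`lipid_id`, `species`).
#' @details Invariants enforced: unique lipid ids; exactly one `head` atom
#'   per lipid; every tagged tail has at least 3 members with contiguous
#'   positions 1..n; the TMG of a tail is its last member.
#' @export
mm_topology <- function(atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  req <- c("lipid_id", "species", "name", "head", "tail", "tail_pos", "tmg")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$first_tail_bead)) atoms$first_tail_bead <- FALSE
  atoms$atom <- seq_len(nrow(atoms))
  atoms$lipid_id <- as.integer(atoms$lipid_id)

  lip_ids <- unique(atoms$lipid_id)
  lipids <- data.frame(
    lipid_id = lip_ids,
    species = atoms$species[match(lip_ids, atoms$lipid_id)],
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(lipids$lipid_id)) stop("duplicate lipid ids")

  nh <- tapply(atoms$head, atoms$lipid_id, sum)
  bad <- names(nh)[nh != 1L]
  if (length(bad)) {
    stop("lipid(s) without exactly one HEAD_P atom: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  for (tl in c("SN1", "SN2")) {
    sel <- !is.na(atoms$tail) & atoms$tail == tl
    if (!any(sel)) next
    for (lid in unique(atoms$lipid_id[sel])) {
      pos <- sort(atoms$tail_pos[sel & atoms$lipid_id == lid])
      n <- length(pos)
      if (n < 3L) stop("tail ", tl, " of lipid ", lid, " has fewer than 3 members")
      if (!identical(as.integer(pos), seq_len(n))) {
        stop("tail ", tl, " of lipid ", lid, " has non-contiguous positions")
      }
      last <- atoms$atom[sel & atoms$lipid_id == lid & atoms$tail_pos == n]
      if (!atoms$tmg[last]) stop("TMG of lipid ", lid, " tail ", tl,
                                 " is not the last tail member")
    }
  }
  structure(list(atoms = atoms, lipids = lipids), class = "mm_topology")
}

#' @export
print.mm_topology <- function(x, ...) {
  cat("<mm_topology> ", nrow(x$lipids), " lipids (",
      paste(sprintf("%s:%d", names(table(x$lipids$species)),
                    as.integer(table(x$lipids$species))), collapse = ", "),
      "), ", nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Select atom indices by species and role
#'
#' @param topology an `mm_topology`.
#' @param species optional character vector of species labels; `NULL` keeps
#'   all species.
#' @param role one of `"HEAD_P"`, `"TMG"`, `"FIRST_TAIL_BEAD"`, `"TAIL"` or
#'   `NULL` (all atoms).
#' @param tail for `role = "TAIL"`, optionally `"SN1"` or `"SN2"`.
#' @return Integer vector of atom indices (rows of `topology$atoms`),
#'   ordered by lipid then tail position.
#' @export
atom_indices <- function(topology, species = NULL, role = NULL, tail = NULL) {
  a <- topology$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(species)) keep <- keep & a$species %in% species
  if (!is.null(role)) {
    keep <- keep & switch(role,
      HEAD_P = a$head,
      TMG = a$tmg,
      FIRST_TAIL_BEAD = a$first_tail_bead,
      TAIL = !is.na(a$tail),
      stop("unknown role: ", role)
    )
  }
  if (!is.null(tail)) keep <- keep & !is.na(a$tail) & a$tail == tail
  a$atom[keep]
}

#' Construct a single coordinate frame
#'
#' @param coords numeric matrix `[n_atoms x 3]`, angstrom.
#' @param box numeric length-3 `(Lx, Ly, Lz)`, angstrom, orthorhombic.
#' @param time time in ps.
#' @return `mm_frame` object.
#' @export
mm_frame <- function(coords, box, time = 0) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, all(box > 0), length(box) == 3)
  structure(list(coords = coords, box = as.numeric(box), time = as.numeric(time)),
            class = "mm_frame")
}

#' Construct a trajectory
#'
#' @param topology an `mm_topology`; coordinate count per frame must equal
#'   its atom count.
#' @param coords numeric array `[n_atoms x 3 x n_frames]`, angstrom.
#' @param box numeric matrix `[n_frames x 3]` of box lengths, angstrom.
#' @param times numeric vector of frame times in ps, non-decreasing.
#' @return `mm_trajectory` object.
#' @export
mm_trajectory <- function(topology, coords, box, times) {
  stopifnot(inherits(topology, "mm_topology"))
  d <- dim(coords)
  if (length(d) != 3 || d[2] != 3) stop("coords must be [n_atoms x 3 x n_frames]")
  if (d[1] != nrow(topology$atoms)) {
    stop("atom-count mismatch: topology has ", nrow(topology$atoms),
         " atoms, coordinates have ", d[1])
  }
  box <- matrix(box, ncol = 3)
  if (nrow(box) != d[3]) stop("box rows must equal frame count")
  if (any(box <= 0)) stop("box lengths must be positive")
  if (length(times) != d[3]) stop("times length must equal frame count")
  if (d[3] < 1) stop("trajectory needs >= 1 frame")
  if (is.unsorted(times)) stop("frame times must be non-decreasing")
  structure(list(topology = topology, coords = coords, box = box,
                 times = as.numeric(times)),
            class = "mm_trajectory")
}

#' @export
print.mm_trajectory <- function(x, ...) {
  cat("<mm_trajectory> ", dim(x$coords)[3], " frames, ",
      dim(x$coords)[1], " atoms, t = ", x$times[1], "..",
      x$times[length(x$times)], " ps\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `mm_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame of a trajectory
#' @param traj an `mm_trajectory`.
#' @param i frame index (1-based).
#' @return `mm_frame`.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  mm_frame(traj$coords[, , i, drop = TRUE], traj$box[i, ], traj$times[i])
}

# ---------------------------------------------------------------------------
# Role mapping: species -> atom-name patterns

#' Default species-to-role mapping
#'
#' Atom-name conventions for the six all-atom phosphatidylcholines handled by
#' default (DOPC, DPMPC, DHPC, DDPC, DLPC, DMPC; CHARMM-style names: `P` for
#' the phosphorus, chain carbons `C2i` for the sn-2 and `C3i` for the sn-1
#' tail) and for Martini-style coarse-grained lipids (`PO4` head bead, `GL1`
#' first tail bead, tail beads `C1A`/`D2A`/... for chain A and `...B` for
#' chain B). Unknown species must be supplied an entry of the same shape.
#'
#' @return Named list; each element has fields `head` (regex), `sn1`, `sn2`
#'   (regexes with one capture group giving the position index), and
#'   optionally `first_tail_bead` (regex).
#' @export
default_role_map <- function() {
  aa <- list(head = "^P$", sn1 = "^C3([0-9]{1,2})$", sn2 = "^C2([0-9]{1,2})$")
  cg <- list(head = "^PO4$", sn1 = "^[CD]([0-9])A$", sn2 = "^[CD]([0-9])B$",
             first_tail_bead = "^GL1$")
  out <- list()
  for (s in c("DOPC", "DPMPC", "DHPC", "DDPC", "DLPC", "DMPC")) out[[s]] <- aa
  for (s in c("DPPC", "DTPC")) out[[s]] <- cg
  out$.martini <- cg
  out$.allatom <- aa
  out
}

# Tag roles on a raw atom table (lipid_id, species, name) using a role map.
# Atoms that match no pattern are retained untagged.
apply_role_map <- function(raw, role_map) {
  n <- nrow(raw)
  raw$head <- FALSE
  raw$tail <- NA_character_
  raw$tail_pos <- NA_integer_
  raw$tmg <- FALSE
  raw$first_tail_bead <- FALSE
  for (sp in unique(raw$species)) {
    rm_sp <- role_map[[sp]]
    if (is.null(rm_sp)) {
      stop("no role mapping for species '", sp,
           "'; supply one via the role_map argument")
    }
    sel <- which(raw$species == sp)
    nm <- raw$name[sel]
    raw$head[sel][grepl(rm_sp$head, nm)] <- TRUE
    for (tl in c("sn1", "sn2")) {
      hit <- grepl(rm_sp[[tl]], nm)
      if (any(hit)) {
        pos <- as.integer(sub(rm_sp[[tl]], "\\1", nm[hit]))
        raw$tail[sel][hit] <- toupper(tl)
        raw$tail_pos[sel][hit] <- pos
      }
    }
    if (!is.null(rm_sp$first_tail_bead)) {
      raw$first_tail_bead[sel][grepl(rm_sp$first_tail_bead, nm)] <- TRUE
    }
  }
  # TMG = last member of each tagged tail
  for (lid in unique(raw$lipid_id)) {
    for (tl in c("SN1", "SN2")) {
      idx <- which(raw$lipid_id == lid & !is.na(raw$tail) & raw$tail == tl)
      if (length(idx)) {
        # renumber positions contiguously in case names skip indices
        o <- order(raw$tail_pos[idx])
        raw$tail_pos[idx[o]] <- seq_along(idx)
        raw$tmg[idx[o][length(idx)]] <- TRUE
      }
    }
  }
  # all-atom lipids: first sn1 carbon doubles as the first tail bead
  ftb_missing <- !tapply(raw$first_tail_bead, raw$lipid_id, any)
  if (any(ftb_missing)) {
    idx <- which(!is.na(raw$tail) & raw$tail == "SN1" & raw$tail_pos == 1L &
                   raw$lipid_id %in% as.integer(names(ftb_missing)[ftb_missing]))
    raw$first_tail_bead[idx] <- TRUE
  }
  bad <- tapply(raw$head, raw$lipid_id, sum)
  nohead <- names(bad)[bad == 0L]
  if (length(nohead)) {
    stop("missing HEAD_P atom for lipid(s): ",
         paste(utils::head(nohead, 5), collapse = ", "))
  }
  raw
}

# ---------------------------------------------------------------------------
# GRO / PDB parsing

parse_gro_frames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (i + 1L > length(lines)) break
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms)) stop("malformed GRO file at line ", i + 1L)
    if (i + 1L + natoms + 1L > length(lines)) {
      stop("truncated GRO file: frame starting at line ", i, " is incomplete")
    }
    atom_lines <- lines[(i + 2L):(i + 1L + natoms)]
    box_line <- lines[i + 2L + natoms]
    frames[[length(frames) + 1L]] <- list(atoms = atom_lines, box = box_line)
    i <- i + 3L + natoms
  }
  if (!length(frames)) stop("no frames found in GRO file")
  frames
}

gro_frame_atoms <- function(atom_lines) {
  data.frame(
    resid = as.integer(substr(atom_lines, 1, 5)),
    resname = trimws(substr(atom_lines, 6, 10)),
    name = trimws(substr(atom_lines, 11, 15)),
    x = as.numeric(substr(atom_lines, 21, 28)),
    y = as.numeric(substr(atom_lines, 29, 36)),
    z = as.numeric(substr(atom_lines, 37, 44)),
    stringsAsFactors = FALSE
  )
}

gro_box <- function(box_line) {
  v <- as.numeric(strsplit(trimws(box_line), "\\s+")[[1]])
  if (length(v) > 3 && any(abs(v[4:length(v)]) > 1e-9)) {
    stop("triclinic GRO box not supported")
  }
  v[1:3]
}

parse_pdb_frames <- function(path) {
  lines <- readLines(path)
  cryst <- grep("^CRYST1", lines, value = TRUE)
  box <- if (length(cryst)) {
    c(as.numeric(substr(cryst[1], 7, 15)),
      as.numeric(substr(cryst[1], 16, 24)),
      as.numeric(substr(cryst[1], 25, 33)))
  } else NULL
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  is_model_end <- grepl("^(ENDMDL|END( |$))", lines)
  frames <- list()
  cur <- character()
  for (i in seq_along(lines)) {
    if (is_atom[i]) cur <- c(cur, lines[i])
    if (is_model_end[i] && length(cur)) {
      frames[[length(frames) + 1L]] <- cur
      cur <- character()
    }
  }
  if (length(cur)) frames[[length(frames) + 1L]] <- cur
  if (!length(frames)) stop("no ATOM records found in PDB file")
  list(frames = frames, box = box)
}

pdb_frame_atoms <- function(atom_lines) {
  data.frame(
    resid = as.integer(substr(atom_lines, 23, 26)),
    resname = trimws(substr(atom_lines, 18, 21)),
    name = trimws(substr(atom_lines, 13, 16)),
    x = as.numeric(substr(atom_lines, 31, 38)),
    y = as.numeric(substr(atom_lines, 39, 46)),
    z = as.numeric(substr(atom_lines, 47, 54)),
    stringsAsFactors = FALSE
  )
}

# Assign consecutive lipid ids from residue numbers (which may wrap) by
# breaking whenever resid or resname changes.
lipid_ids_from_residues <- function(resid, resname) {
  brk <- c(TRUE, resid[-1] != resid[-length(resid)] |
             resname[-1] != resname[-length(resname)])
  cumsum(brk)
}

#' Load a bilayer topology from file
#'
#' Reads atom identities from a GRO, PDB or memmech fixture file and tags
#' roles (HEAD_P, TAIL_SN1/SN2, TMG, FIRST_TAIL_BEAD) using a species-to-name
#' mapping. Residues whose name is not in `only_species` (when given) or that
#' look like solvent (`W`, `TIP3`, `SOL`, `NA`, `CL`, `ION`) are dropped.
#'
#' @param path file path.
#' @param dialect `"gro"`, `"pdb"` or `"fixture"`.
#' @param role_map species-to-pattern mapping, see [default_role_map()].
#' @param only_species optional character vector restricting which residue
#'   names are treated as lipids.
#' @return `mm_topology`. The `atoms` table carries a `source_row` column
#'   mapping back to the atom order of the source file, used by
#'   [load_trajectory()] to subset coordinates.
#' @export
load_topology <- function(path, dialect = c("fixture", "gro", "pdb"),
                          role_map = default_role_map(),
                          only_species = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "fixture") return(read_fixture(path)$topology)
  raw <- switch(dialect,
    gro = gro_frame_atoms(parse_gro_frames(path)[[1]]$atoms),
    pdb = pdb_frame_atoms(parse_pdb_frames(path)$frames[[1]])
  )
  raw$source_row <- seq_len(nrow(raw))
  solvent <- c("W", "TIP3", "SOL", "NA", "CL", "ION", "WF")
  keep <- if (is.null(only_species)) !(raw$resname %in% solvent)
          else raw$resname %in% only_species
  raw <- raw[keep, , drop = FALSE]
  if (!nrow(raw)) stop("no lipid atoms found in ", path)
  tab <- data.frame(
    lipid_id = lipid_ids_from_residues(raw$resid, raw$resname),
    species = raw$resname, name = raw$name,
    source_row = raw$source_row, stringsAsFactors = FALSE
  )
  tab <- apply_role_map(tab, role_map)
  mm_topology(tab)
}

#' Load a trajectory from file
#'
#' Coordinates are converted to angstrom regardless of the source unit
#' (GRO/XTC store nm). When the topology was read from a GRO/PDB file
#' containing non-lipid atoms, the stored `source_row` mapping subsets each
#' frame to the topology's atoms.
#'
#' @param topology `mm_topology` the coordinates belong to.
#' @param path file path.
#' @param dialect `"fixture"`, `"dcd"`, `"xtc"` or `"gro"` (multi-frame GRO).
#' @param dt frame spacing in ps, used when the file does not store times
#'   (GRO) or stores them in native units that cannot be trusted (DCD
#'   without a sensible header); default 1 ps.
#' @return `mm_trajectory`.
#' @details XTC is a compressed binary format; it is read through the
#'   MDAnalysis Python library (`python` must be on the PATH), used here
#'   purely as an infrastructure decoder. GRO, PDB, DCD and the fixture
#'   format are parsed natively.
#' @export
load_trajectory <- function(topology, path,
                            dialect = c("fixture", "dcd", "xtc", "gro"),
                            dt = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "fixture") {
    fx <- read_fixture(path)
    if (nrow(fx$topology$atoms) != nrow(topology$atoms)) {
      stop("atom-count mismatch: topology has ", nrow(topology$atoms),
           ", fixture has ", nrow(fx$topology$atoms))
    }
    return(mm_trajectory(topology, fx$coords, fx$box, fx$times))
  }
  src_rows <- topology$atoms$source_row
  n_top <- nrow(topology$atoms)
  if (dialect == "gro") {
    frames <- parse_gro_frames(path)
    nat <- length(frames[[1]]$atoms)
    check_atom_count(n_top, nat, src_rows)
    nf <- length(frames)
    coords <- array(NA_real_, c(n_top, 3, nf))
    box <- matrix(NA_real_, nf, 3)
    for (k in seq_len(nf)) {
      a <- gro_frame_atoms(frames[[k]]$atoms)
      xyz <- as.matrix(a[, c("x", "y", "z")]) * 10  # nm -> A
      coords[, , k] <- if (is.null(src_rows)) xyz else xyz[src_rows, , drop = FALSE]
      box[k, ] <- gro_box(frames[[k]]$box) * 10
    }
    if (is.null(dt)) dt <- 1
    return(mm_trajectory(topology, coords, box, (seq_len(nf) - 1) * dt))
  }
  if (dialect == "dcd") {
    d <- read_dcd(path)
    check_atom_count(n_top, dim(d$coords)[1], src_rows)
    coords <- if (is.null(src_rows)) d$coords else d$coords[src_rows, , , drop = FALSE]
    times <- if (!is.null(dt)) (seq_len(dim(coords)[3]) - 1) * dt else d$times
    return(mm_trajectory(topology, coords, d$box, times))
  }
  # xtc via MDAnalysis
  d <- read_xtc_via_python(path)
  check_atom_count(n_top, dim(d$coords)[1], src_rows)
  coords <- if (is.null(src_rows)) d$coords else d$coords[src_rows, , , drop = FALSE]
  times <- if (!is.null(dt)) (seq_len(dim(coords)[3]) - 1) * dt else d$times
  mm_trajectory(topology, coords, d$box, times)
}

check_atom_count <- function(n_top, n_file, src_rows) {
  if (is.null(src_rows)) {
    if (n_file != n_top) {
      stop("atom-count mismatch: topology has ", n_top,
           " atoms, trajectory frames have ", n_file)
    }
  } else if (n_file < max(src_rows)) {
    stop("atom-count mismatch: topology refers to source atom ", max(src_rows),
         " but trajectory frames have only ", n_file)
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# DCD (CHARMM/NAMD) binary reader

read_dcd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  m1 <- readBin(con, "integer", 1, 4, endian = endian)
  if (!identical(m1, 84L)) {
    endian <- "big"
    seek(con, 0)
    m1 <- readBin(con, "integer", 1, 4, endian = endian)
    if (!identical(m1, 84L)) stop("not a DCD file (bad header marker)")
  }
  magic <- rawToChar(readBin(con, "raw", 4))
  if (magic != "CORD") stop("not a coordinate DCD file")
  icntrl_head <- readBin(con, "integer", 9, 4, endian = endian)
  delta <- readBin(con, "numeric", 1, 4, endian = endian)
  icntrl_tail <- readBin(con, "integer", 10, 4, endian = endian)
  readBin(con, "integer", 1, 4, endian = endian)  # closing marker
  nsavc <- icntrl_head[3]
  has_cell <- icntrl_tail[1] != 0L
  # title block
  nt_marker <- readBin(con, "integer", 1, 4, endian = endian)
  ntitle <- readBin(con, "integer", 1, 4, endian = endian)
  if (ntitle > 0) readBin(con, "raw", 80L * ntitle)
  readBin(con, "integer", 1, 4, endian = endian)
  # natoms block
  readBin(con, "integer", 1, 4, endian = endian)
  natoms <- readBin(con, "integer", 1, 4, endian = endian)
  readBin(con, "integer", 1, 4, endian = endian)
  if (is.na(natoms) || natoms <= 0) stop("bad atom count in DCD header")

  frames <- list(); boxes <- list()
  repeat {
    mk <- readBin(con, "integer", 1, 4, endian = endian)
    if (!length(mk)) break
    if (has_cell && mk == 48L) {
      cell <- readBin(con, "numeric", 6, 8, endian = endian)
      readBin(con, "integer", 1, 4, endian = endian)
      mk <- readBin(con, "integer", 1, 4, endian = endian)
      if (!length(mk)) stop("truncated DCD file (frame header after cell)")
    } else {
      cell <- NULL
    }
    if (mk != 4L * natoms) stop("truncated or corrupt DCD frame block")
    x <- readBin(con, "numeric", natoms, 4, endian = endian)
    readBin(con, "integer", 1, 4, endian = endian)
    readBin(con, "integer", 1, 4, endian = endian)
    y <- readBin(con, "numeric", natoms, 4, endian = endian)
    readBin(con, "integer", 1, 4, endian = endian)
    readBin(con, "integer", 1, 4, endian = endian)
    z <- readBin(con, "numeric", natoms, 4, endian = endian)
    readBin(con, "integer", 1, 4, endian = endian)
    if (length(z) < natoms) stop("truncated DCD file mid-frame")
    frames[[length(frames) + 1L]] <- cbind(x, y, z)
    boxes[[length(boxes) + 1L]] <-
      if (is.null(cell)) c(NA, NA, NA) else cell[c(1, 3, 6)]
  }
  if (!length(frames)) stop("DCD file contains no frames")
  nf <- length(frames)
  coords <- array(unlist(frames), c(natoms, 3, nf))
  box <- do.call(rbind, boxes)
  if (anyNA(box)) box[] <- 1  # no cell info; callers must not rely on box
  akma_ps <- 0.04888821
  dt_ps <- if (!is.na(delta) && delta > 0 && nsavc > 0) delta * nsavc * akma_ps else 1
  list(coords = coords, box = box, times = (seq_len(nf) - 1) * dt_ps)
}

# ---------------------------------------------------------------------------
# XTC via MDAnalysis (python) -- infrastructure decoder only

read_xtc_via_python <- function(path) {
  out <- tempfile(fileext = ".txt")
  on.exit(unlink(out))
  script <- sprintf(
    'import sys\nfrom MDAnalysis.coordinates.XTC import XTCReader\nr = XTCReader(%s)\nwith open(%s, "w") as f:\n    for ts in r:\n        d = ts.dimensions\n        f.write("F %%r %%r %%r %%r\\n" %% (float(ts.time), float(d[0]), float(d[1]), float(d[2])))\n        for row in ts.positions:\n            f.write("%%r %%r %%r\\n" %% (float(row[0]), float(row[1]), float(row[2])))\n',
    deparse(path), deparse(out))
  sf <- tempfile(fileext = ".py")
  on.exit(unlink(sf), add = TRUE)
  writeLines(script, sf)
  status <- system2("python", sf, stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("failed to read XTC file ", path,
                        " (python/MDAnalysis decoder returned status ", status, ")")
  lines <- readLines(out)
  hdr <- grep("^F ", lines)
  if (!length(hdr)) stop("XTC file ", path, " contains no frames")
  nat <- if (length(hdr) > 1) hdr[2] - hdr[1] - 1L else length(lines) - 1L
  nf <- length(hdr)
  coords <- array(NA_real_, c(nat, 3, nf))
  box <- matrix(NA_real_, nf, 3)
  times <- numeric(nf)
  for (k in seq_len(nf)) {
    h <- as.numeric(strsplit(lines[hdr[k]], " ")[[1]][-1])
    times[k] <- h[1]; box[k, ] <- h[2:4]
    blk <- lines[(hdr[k] + 1L):(hdr[k] + nat)]
    coords[, , k] <- matrix(as.numeric(unlist(strsplit(blk, " "))),
                            ncol = 3, byrow = TRUE)
  }
  list(coords = coords, box = box, times = times)  # MDAnalysis returns A, ps
}

# ---------------------------------------------------------------------------
# Fixture format: plain-text, language-neutral.
#   line 1: "#MEMMECH fixture 1"
#   line 2: one-line JSON header (units, n_atoms, n_frames, lipid/atom table)
#   then per frame: "#FRAME <time_ps> <Lx> <Ly> <Lz>" + n_atoms lines "x y z"

#' Write a trajectory to the portable fixture format
#'
#' One JSON header line (topology, roles, units, frame count) followed by a
#' delimited numeric block per frame. Round-trips coordinates to better than
#' 1e-6 A.
#'
#' @param traj `mm_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(traj, path) {
  a <- traj$topology$atoms
  header <- list(
    format = "memmech-fixture", version = 1L,
    units = list(length = "angstrom", time = "ps"),
    n_atoms = nrow(a), n_frames = n_frames(traj),
    atoms = list(lipid_id = a$lipid_id, species = a$species, name = a$name,
                 head = a$head, tail = ifelse(is.na(a$tail), "", a$tail),
                 tail_pos = ifelse(is.na(a$tail_pos), -1L, a$tail_pos),
                 tmg = a$tmg, first_tail_bead = a$first_tail_bead)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#MEMMECH fixture 1", con)
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), con)
  nf <- n_frames(traj)
  for (k in seq_len(nf)) {
    writeLines(sprintf("#FRAME %.10g %.10g %.10g %.10g", traj$times[k],
                       traj$box[k, 1], traj$box[k, 2], traj$box[k, 3]), con)
    xyz <- traj$coords[, , k, drop = TRUE]
    writeLines(sprintf("%.10g %.10g %.10g", xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

read_fixture <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || !startsWith(lines[1], "#MEMMECH fixture")) {
    stop("not a memmech fixture file: ", path)
  }
  header <- jsonlite::fromJSON(lines[2])
  nat <- header$n_atoms; nf <- header$n_frames
  at <- header$atoms
  atoms <- data.frame(
    lipid_id = at$lipid_id, species = at$species, name = at$name,
    head = at$head, tail = ifelse(at$tail == "", NA_character_, at$tail),
    tail_pos = ifelse(at$tail_pos < 0, NA_integer_, at$tail_pos),
    tmg = at$tmg, first_tail_bead = at$first_tail_bead,
    stringsAsFactors = FALSE
  )
  topology <- mm_topology(atoms)
  coords <- array(NA_real_, c(nat, 3, nf))
  box <- matrix(NA_real_, nf, 3)
  times <- numeric(nf)
  pos <- 3L
  for (k in seq_len(nf)) {
    if (pos > length(lines) || !startsWith(lines[pos], "#FRAME")) {
      stop("truncated fixture file: expected frame ", k, " at line ", pos)
    }
    h <- as.numeric(strsplit(lines[pos], " ")[[1]][-1])
    times[k] <- h[1]; box[k, ] <- h[2:4]
    if (pos + nat > length(lines)) stop("truncated fixture file in frame ", k)
    blk <- lines[(pos + 1L):(pos + nat)]
    coords[, , k] <- matrix(as.numeric(unlist(strsplit(blk, " ", fixed = TRUE))),
                            ncol = 3, byrow = TRUE)
    pos <- pos + nat + 1L
  }
  if (anyNA(coords)) stop("fixture file contains unparseable coordinates")
  list(topology = topology, coords = coords, box = box, times = times)
}

# ---------------------------------------------------------------------------
# Leaflet assignment

#' Assign lipids to bilayer leaflets
#'
#' The bilayer midplane is the unweighted mean z of all HEAD_P atoms; a lipid
#' belongs to the upper leaflet iff its HEAD_P z exceeds the midplane.
#'
#' @param frame `mm_frame` to assign from (typically the first frame; lipid
#'   flip-flop is not modeled, so a single reference assignment is normally
#'   reused across a trajectory).
#' @param topology matching `mm_topology`.
#' @return An `mm_leaflets` object: list with `labels` (character vector
#'   `"upper"`/`"lower"` named by lipid id), `z_center` (A) and `lipid_id`.
#' @export
assign_leaflets <- function(frame, topology) {
  if (nrow(topology$lipids) < 2) stop("need >= 2 lipids to assign leaflets")
  hp <- atom_indices(topology, role = "HEAD_P")
  hp_lipid <- topology$atoms$lipid_id[hp]
  z <- frame$coords[hp, 3]
  z_center <- mean(z)
  lab <- ifelse(z > z_center, "upper", "lower")
  if (!any(lab == "upper") || !any(lab == "lower")) {
    stop("degenerate monolayer: all HEAD_P atoms on one side of the midplane")
  }
  names(lab) <- hp_lipid
  structure(list(labels = lab, z_center = z_center, lipid_id = hp_lipid),
            class = "mm_leaflets")
}

#' @export
print.mm_leaflets <- function(x, ...) {
  cat("<mm_leaflets> upper ", sum(x$labels == "upper"), " / lower ",
      sum(x$labels == "lower"), ", midplane z = ",
      format(x$z_center, digits = 5), " A\n", sep = "")
  invisible(x)
}

# Lipid ids of one leaflet
leaflet_lipids <- function(assignment, leaflet) {
  assignment$lipid_id[assignment$labels == leaflet]
}
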