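#' Physical constants for cell-wall analyses
#'
#' Bundles the constants used throughout the package: the gas constant in
#' kcal/(mol K), the analysis temperature, the molecular weight and density of
#' water, Avogadro's number, and the exact unit factor converting diffusion
#' coefficients from the internal Angstrom^2/ns scale to cm^2/s.
#'
#' @param temperature simulation temperature in Kelvin.
#' @param rho_water liquid water density in g/cm^3 used for constant-volume
#'   water-removal bookkeeping.
#' @return a list with elements `R`, `temperature`, `RT`, `mw_water`,
#'   `rho_water`, `n_avogadro`, and `a2ns_to_cm2s`.
#' @export
#' @examples
#' wall_constants()$RT  # kcal/mol at 300 K
wall_constants <- function(temperature = 300, rho_water = 0.997) {
  stopifnot(temperature > 0, rho_water > 0)
  R <- 1.987204e-3  # kcal mol^-1 K^-1
  list(
    R = R,
    temperature = temperature,
    RT = R * temperature,
    mw_water = 18.02,        # g/mol
    rho_water = rho_water,   # g/cm^3
    n_avogadro = 6.02214e23, # mol^-1
    a2ns_to_cm2s = 1e-7      # 1 A^2/ns = 1e-7 cm^2/s, exact
  )
}

.components <- c("cellulose", "hemicellulose", "lignin", "water", "ion")
.groups <- c("hydroxyl", "carboxyl", "acetyl", "none")

#' Construct an annotated structure model
#'
#' An atom table bound to a total system charge. Atoms carry a component label
#' (cellulose, hemicellulose, lignin, water, ion) and a functional-group label
#' (hydroxyl, carboxyl, acetyl, none). Functional groups may only occur on
#' hemicellulose or lignin atoms: cellulose is too densely packed to be
#' acetylated and is never labelled. The `site_head` flag marks one atom per
#' functional-group instance (the hydroxyl oxygen, the carboxyl carbon, the
#' acetyl carbonyl carbon) so that group abundances count chemical instances,
#' not atoms.
#'
#' @param atoms data.frame with columns `elety` (atom name), `element`, `mass`
#'   (g/mol), `component`, `group`, `resid` (integer residue id), and
#'   optionally `site_head` (logical).
#' @param charge total system charge in elementary charges.
#' @return an object of class `wall_structure`.
#' @export
wall_structure <- function(atoms, charge = 0) {
  atoms <- as.data.frame(atoms)
  req <- c("elety", "element", "mass", "component", "group", "resid")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$site_head)) atoms$site_head <- FALSE
  if (!all(atoms$component %in% .components))
    stop("unknown component label(s): ",
         paste(unique(setdiff(atoms$component, .components)), collapse = ", "))
  if (!all(atoms$group %in% .groups))
    stop("unknown functional-group label(s): ",
         paste(unique(setdiff(atoms$group, .groups)), collapse = ", "))
  bad <- atoms$group != "none" & !(atoms$component %in% c("hemicellulose", "lignin"))
  if (any(bad))
    stop("functional-group labels are only valid on hemicellulose/lignin atoms")
  if (!all(is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("all atomic masses must be finite and > 0")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, charge = charge), class = "wall_structure")
}

#' @export
print.wall_structure <- function(x, ...) {
  cat("wall_structure:", nrow(x$atoms), "atoms, total charge", x$charge, "e\n")
  cat("  components:", paste(sprintf("%s=%d", names(table(x$atoms$component)),
                                     table(x$atoms$component)), collapse = " "), "\n")
  grp <- x$atoms$group[x$atoms$group != "none" & x$atoms$site_head]
  if (length(grp))
    cat("  functional-group instances:",
        paste(sprintf("%s=%d", names(table(grp)), table(grp)), collapse = " "), "\n")
  invisible(x)
}

#' Number of atoms in a structure or trajectory
#' @param x a `wall_structure` or `wall_trajectory`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "wall_trajectory")) x <- x$structure
  nrow(x$atoms)
}

#' Construct a trajectory bound to a structure
#'
#' Frames of periodic orthorhombic-box coordinates. Coordinates are in
#' Angstrom, times in ns; the box may change frame to frame (the source data
#' use semi-isotropic pressure coupling). The equilibration cutoff marks the
#' initial portion that all summary analyses discard (50 ns in the source
#' study).
#'
#' @param struct a [wall_structure()].
#' @param xyz numeric array of dimension (n_atoms, 3, n_frames), or a list of
#'   n_atoms x 3 matrices.
#' @param box n_frames x 3 matrix of box lengths (Lx, Ly, Lz) in Angstrom, or a
#'   length-3 vector recycled to all frames.
#' @param dt frame interval in ns.
#' @param equilibration equilibration cutoff in ns (frames with time strictly
#'   below it are excluded from summary statistics).
#' @param wrapped logical, whether coordinates are wrapped into the box.
#' @return object of class `wall_trajectory`.
#' @export
wall_trajectory <- function(struct, xyz, box, dt, equilibration = 0,
                            wrapped = TRUE) {
  stopifnot(inherits(struct, "wall_structure"), dt > 0, equilibration >= 0)
  if (is.list(xyz)) {
    xyz <- array(unlist(xyz), dim = c(nrow(xyz[[1]]), 3, length(xyz)))
  }
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[2] == 3)
  if (dim(xyz)[1] != nrow(struct$atoms))
    stop("coordinate array does not match the structure's atom count")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  nf <- dim(xyz)[3]
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  box <- as.matrix(box)
  if (nrow(box) == 1 && nf > 1) box <- box[rep(1, nf), , drop = FALSE]
  stopifnot(nrow(box) == nf, ncol(box) == 3, all(box > 0))
  structure(list(structure = struct, xyz = xyz, box = box, dt = dt,
                 equilibration = equilibration, wrapped = wrapped),
            class = "wall_trajectory")
}

#' @export
print.wall_trajectory <- function(x, ...) {
  cat("wall_trajectory:", dim(x$xyz)[3], "frames x", dim(x$xyz)[1],
      "atoms, dt =", x$dt, "ns",
      if (x$wrapped) "(wrapped)" else "(unwrapped)", "\n")
  cat("  box (frame 1):", paste(round(x$box[1, ], 2), collapse = " x "),
      "A; equilibration cutoff", x$equilibration, "ns\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `wall_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$xyz)[3]

#' Frame times in ns
#' @param traj a `wall_trajectory`.
#' @return numeric vector, frame i at time (i-1)*dt.
#' @export
frame_times <- function(traj) (seq_len(n_frames(traj)) - 1) * traj$dt

#' Indices of post-equilibration frames
#' @param traj a `wall_trajectory`.
#' @return integer vector of frames with time >= the equilibration cutoff.
#' @export
production_frames <- function(traj) {
  which(frame_times(traj) >= traj$equilibration)
}

#' Select atoms by annotation
#'
#' @param x a `wall_structure` or `wall_trajectory`.
#' @param component optional component label(s) to keep.
#' @param group optional functional-group label(s) to keep.
#' @param element optional element symbol(s) to keep.
#' @param site_head if TRUE keep only the head atom of each functional-group
#'   instance.
#' @return integer vector of atom indices (1-based).
#' @export
atom_select <- function(x, component = NULL, group = NULL, element = NULL,
                        site_head = FALSE) {
  if (inherits(x, "wall_trajectory")) x <- x$structure
  a <- x$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(component)) keep <- keep & a$component %in% component
  if (!is.null(group)) keep <- keep & a$group %in% group
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (site_head) keep <- keep & a$site_head
  which(keep)
}

#' Count functional-group instances
#'
#' Abundance is the number of chemical group instances (one per `site_head`
#' atom), not the number of atoms carrying the label; it is the denominator
#' normalising contact scores and integrated RDFs into per-site interaction
#' probabilities.
#'
#' @param x a `wall_structure` or `wall_trajectory`.
#' @param group functional-group label.
#' @return integer count.
#' @export
group_abundance <- function(x, group) {
  length(atom_select(x, group = group, site_head = TRUE))
}

# ---- periodic geometry -----------------------------------------------------

#' Minimum-image displacement between two points
#'
#' Displacement from `a` to `b` under orthorhombic periodic boundary
#' conditions; each component lies in [-L/2, L/2) and its norm is the minimum
#' distance over all periodic images. Antisymmetric in its arguments.
#'
#' @param a,b numeric length-3 vectors or n x 3 matrices (Angstrom).
#' @param box length-3 vector of box lengths (Angstrom).
#' @return displacement of the same shape as the inputs.
#' @export
#' @examples
#' minimum_image_displacement(c(9.9, 0, 0), c(0.1, 0, 0), c(10, 10, 10))
minimum_image_displacement <- function(a, b, box) {
  stopifnot(all(box > 0))
  d <- b - a
  if (is.matrix(d)) {
    bm <- matrix(box, nrow = nrow(d), ncol = 3, byrow = TRUE)
    d - bm * floor(d / bm + 0.5)
  } else {
    d - box * floor(d / box + 0.5)
  }
}

# Coordinates of one frame as an n_atoms x 3 matrix (guards against R's
# dimension dropping when the system has a single atom).
frame_coords <- function(traj, f) {
  matrix(traj$xyz[, , f], ncol = 3)
}

# Chunked minimum-image distance matrix between coordinate sets A (n x 3) and
# B (m x 3). Returns an n x m matrix. Chunking bounds peak memory at roughly
# chunk * m doubles.
min_image_distances <- function(A, B, box, chunk = 512L) {
  A <- matrix(A, ncol = 3); B <- matrix(B, ncol = 3)
  n <- nrow(A); m <- nrow(B)
  out <- matrix(NA_real_, n, m)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- 0
    for (k in 1:3) {
      dx <- outer(A[s:e, k], B[, k], "-")
      dx <- dx - box[k] * floor(dx / box[k] + 0.5)
      d2 <- d2 + dx * dx
    }
    out[s:e, ] <- sqrt(d2)
  }
  out
}

#' Periodic neighbour pairs within a cutoff
#'
#' Exact minimum-image pair search between two atom groups in one frame.
#' Self-pairs (the same atom appearing in both groups) are excluded, and when
#' the groups overlap each unordered pair is reported once.
#'
#' @param coords n_atoms x 3 coordinate matrix for one frame (Angstrom).
#' @param box length-3 box vector.
#' @param ia,ib integer atom indices of the two groups.
#' @param cutoff distance cutoff in Angstrom. If it exceeds half the shortest
#'   box length a warning is issued (beyond-nearest-image contacts cannot be
#'   represented); the nearest-image result is still returned.
#' @return data.frame with columns `i`, `j` (atom indices), `distance`.
#' @export
periodic_neighbor_pairs <- function(coords, box, ia, ib, cutoff) {
  stopifnot(cutoff > 0, all(box > 0))
  if (cutoff > min(box) / 2)
    warning("cutoff exceeds half the minimum box length; ",
            "only nearest-image contacts are reported")
  if (length(ia) == 0 || length(ib) == 0)
    return(data.frame(i = integer(), j = integer(), distance = numeric()))
  D <- min_image_distances(coords[ia, , drop = FALSE],
                           coords[ib, , drop = FALSE], box)
  hit <- which(D <= cutoff, arr.ind = TRUE)
  i <- ia[hit[, 1]]; j <- ib[hit[, 2]]
  keep <- i != j
  # deduplicate unordered pairs where both atoms belong to both groups
  both <- keep & (i %in% ib) & (j %in% ia)
  keep <- keep & (!both | i < j)
  data.frame(i = i[keep], j = j[keep],
             distance = D[hit][keep])
}

# ---- file I/O --------------------------------------------------------------

#' Default annotation rules for topology loading
#'
#' Rule-driven mapping from residue and atom names to component and
#' functional-group labels, so archive files and synthetic fixtures load
#' through one path. `components` maps residue-name regular expressions to
#' component labels; `groups` is a data.frame of (residue regex, atom-name
#' regex, group label, head flag) applied to hemicellulose/lignin atoms.
#'
#' @param required character vector of component labels that must match at
#'   least one atom (e.g. `"ion"`); violation is an error at load time.
#' @return a list with elements `components`, `groups`, `required`.
#' @export
default_annotation_rules <- function(required = character()) {
  list(
    components = c(
      "^(WAT|TIP3?|HOH|SPC)$" = "water",
      "^(SOD|NA\\+?|FE3?\\+?|FE|ION)$" = "ion",
      "^(CEL|BGLC)$" = "cellulose",
      "^(HEM|XYL[SP]?)$" = "hemicellulose",
      "^LIG" = "lignin"
    ),
    groups = data.frame(
      resname = ".*",
      elety = c("^OH", "^HO", "^CX$", "^OX", "^CA$", "^OA$", "^CME$", "^HM"),
      group = c("hydroxyl", "hydroxyl", "carboxyl", "carboxyl",
                "acetyl", "acetyl", "acetyl", "acetyl"),
      head = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
      stringsAsFactors = FALSE
    ),
    required = required
  )
}

.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     NA. = 22.990, P = 30.974, S = 32.06, FE = 55.845)

guess_element <- function(elety) {
  e <- toupper(sub("^[0-9]*", "", elety))
  two <- substr(e, 1, 2)
  one <- substr(e, 1, 1)
  out <- ifelse(two %in% c("FE", "NA") & !grepl("^NA[A-Z]", e), two, one)
  out[e == "SOD"] <- "NA"  # CHARMM-style sodium
  ifelse(out == "NA", "NA.", out)
}

#' Load an annotated structure from a topology file
#'
#' Reads a PDB file via bio3d and applies annotation rules mapping residue and
#' atom names to component/functional-group labels. Atoms whose residue name
#' matches no component rule get component `water` only if named like water;
#' otherwise loading fails so that silent mislabelling cannot occur.
#'
#' @param file path to a PDB topology file.
#' @param rules annotation rules, see [default_annotation_rules()].
#' @return a [wall_structure()] plus attribute `xyz` holding the file's
#'   coordinates (n_atoms x 3).
#' @export
load_structure <- function(file, rules = default_annotation_rules()) {
  pdb <- bio3d::read.pdb(file)
  a <- pdb$atom
  comp <- rep(NA_character_, nrow(a))
  for (pat in names(rules$components)) {
    hit <- grepl(pat, a$resid)  # bio3d calls the residue name 'resid'
    comp[is.na(comp) & hit] <- rules$components[[pat]]
  }
  if (any(is.na(comp)))
    stop("unmatched residue names: ",
         paste(unique(a$resid[is.na(comp)]), collapse = ", "))
  grp <- rep("none", nrow(a))
  head <- rep(FALSE, nrow(a))
  on_poly <- comp %in% c("hemicellulose", "lignin")
  for (r in seq_len(nrow(rules$groups))) {
    hit <- on_poly & grepl(rules$groups$resname[r], a$resid) &
      grepl(rules$groups$elety[r], a$elety)
    grp[hit] <- rules$groups$group[r]
    head[hit] <- head[hit] | rules$groups$head[r]
  }
  elem <- guess_element(a$elety)
  mass <- .element_masses[elem]
  if (any(is.na(mass)))
    stop("cannot assign masses for elements: ",
         paste(unique(elem[is.na(mass)]), collapse = ", "))
  for (need in rules$required) {
    if (!any(comp == need))
      stop("annotation rules matched zero atoms for required group '",
           need, "'")
  }
  st <- wall_structure(
    data.frame(elety = a$elety, element = elem, mass = unname(mass),
               component = comp, group = grp, resid = a$resno,
               site_head = head, stringsAsFactors = FALSE),
    charge = 0)
  attr(st, "xyz") <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  st
}

#' Write a structure (with one coordinate frame) to PDB
#'
#' @param struct a [wall_structure()].
#' @param coords n_atoms x 3 coordinate matrix.
#' @param file output path.
#' @param resname_map named character vector mapping component labels to
#'   4-character residue names understood by [default_annotation_rules()].
#' @return `file`, invisibly.
#' @export
write_structure_pdb <- function(struct, coords, file,
                                resname_map = c(cellulose = "CEL",
                                                hemicellulose = "HEM",
                                                lignin = "LIG",
                                                water = "WAT", ion = "ION")) {
  a <- struct$atoms
  bio3d::write.pdb(file = file,
                   xyz = as.vector(t(coords)),
                   resno = a$resid,
                   resid = unname(resname_map[a$component]),
                   elety = a$elety)
  invisible(file)
}

#' Write a trajectory to a plain-text fixture file
#'
#' Long-format CSV with one row per atom per frame plus the frame box, read
#' back by [read_trajectory_csv()]. Intended for small synthetic fixtures;
#' binary DCD input for real archives is read with [load_trajectory()].
#'
#' @param traj a [wall_trajectory()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_trajectory_csv <- function(traj, file) {
  nf <- n_frames(traj); na <- n_atoms(traj)
  dt_tab <- data.table::data.table(
    frame = rep(seq_len(nf), each = na),
    atom = rep(seq_len(na), nf),
    x = as.vector(traj$xyz[, 1, ]),
    y = as.vector(traj$xyz[, 2, ]),
    z = as.vector(traj$xyz[, 3, ]),
    lx = rep(traj$box[, 1], each = na),
    ly = rep(traj$box[, 2], each = na),
    lz = rep(traj$box[, 3], each = na))
  data.table::fwrite(dt_tab, file)
  invisible(file)
}

#' Read a trajectory fixture written by [write_trajectory_csv()]
#'
#' @param file CSV path.
#' @param struct the [wall_structure()] the coordinates belong to.
#' @param dt frame interval in ns.
#' @param equilibration equilibration cutoff in ns.
#' @return a [wall_trajectory()].
#' @export
read_trajectory_csv <- function(file, struct, dt, equilibration = 0) {
  d <- data.table::fread(file)
  nf <- max(d$frame); na <- max(d$atom)
  d <- d[order(d$frame, d$atom), ]
  xyz <- array(NA_real_, dim = c(na, 3, nf))
  xyz[, 1, ] <- d$x; xyz[, 2, ] <- d$y; xyz[, 3, ] <- d$z
  box <- as.matrix(d[d$atom == 1, c("lx", "ly", "lz")])
  wall_trajectory(struct, xyz, box, dt = dt, equilibration = equilibration)
}

#' Load a trajectory from a topology plus coordinate file
#'
#' Supports binary DCD coordinate files (via bio3d) against a PDB topology, or
#' the package's CSV fixture format. Triclinic boxes are rejected: the cell
#' wall systems are orthorhombic and the periodic geometry here assumes it.
#'
#' @param topology PDB topology path.
#' @param coordinates DCD or CSV trajectory path.
#' @param dt frame interval in ns (required; DCD headers do not carry reliable
#'   physical time).
#' @param equilibration equilibration cutoff in ns.
#' @param box box lengths (length-3 vector or n_frames x 3 matrix) when the
#'   coordinate file carries none.
#' @param rules annotation rules for the topology.
#' @return a [wall_trajectory()].
#' @export
load_trajectory <- function(topology, coordinates, dt, equilibration = 50,
                            box = NULL, rules = default_annotation_rules()) {
  struct <- load_structure(topology, rules)
  if (grepl("\\.csv$", coordinates, ignore.case = TRUE))
    return(read_trajectory_csv(coordinates, struct, dt, equilibration))
  trj <- bio3d::read.dcd(coordinates, verbose = FALSE, cell = is.null(box))
  if (is.null(box)) {
    cell <- trj
    trj <- bio3d::read.dcd(coordinates, verbose = FALSE)
    if (any(abs(cell[, 4:6] - 90) > 1e-6))
      stop("triclinic boxes are not supported (orthorhombic systems only)")
    box <- cell[, 1:3, drop = FALSE]
  }
  nf <- nrow(trj)
  xyz <- array(NA_real_, dim = c(ncol(trj) / 3, 3, nf))
  for (f in seq_len(nf)) xyz[, , f] <- matrix(trj[f, ], ncol = 3, byrow = TRUE)
  wall_trajectory(struct, xyz, box, dt = dt, equilibration = equilibration)
}
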