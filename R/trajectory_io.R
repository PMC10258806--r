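#' Atom roles recognised by the toolkit
#'
#' Role labels partition a metalloporphyrin + water system into the
#' selections the analyses operate on: the metal centre, the four pyrrole
#' nitrogens, the alpha/beta/meso ring carbons, ring hydrogens, water
#' oxygens and hydrogens, and a catch-all `other`.
#' @export
ATOM_ROLES <- c("metal", "ring_N", "ring_C_alpha", "ring_C_beta",
                "ring_C_meso", "ring_H", "water_O", "water_H", "other")

#' Construct a topology
#'
#' A topology records, per atom: element, name, role (one of [ATOM_ROLES]),
#' van der Waals radius (angstrom), polarity class
#' (`hydrophobic`/`hydrophilic`) and, for water hydrogens, the row index of
#' the parent oxygen.  Torsion quadruples (ordered 4-tuples of atom indices,
#' labelled `proper` or `improper`) drive the torsional-flexibility
#' analysis.
#'
#' @param atoms data.frame with columns `element`, `name`; optional `role`,
#'   `vdw_radius`, `polarity_class`, `water_parent`, `resid`, `resno`.
#' @param torsions list of `list(ids =, label =, name =)` entries;
#'   `ids` are 1-based atom row indices.
#' @return object of class `topology`
#' @export
topology <- function(atoms, torsions = list()) {
  stopifnot(is.data.frame(atoms), all(c("element", "name") %in% names(atoms)))
  n <- nrow(atoms)
  if (is.null(atoms$role)) atoms$role <- rep("other", n)
  if (is.null(atoms$vdw_radius)) atoms$vdw_radius <- bondi_radius(atoms$element)
  if (is.null(atoms$polarity_class))
    atoms$polarity_class <- ifelse(atoms$element %in% c("N", "O"),
                                   "hydrophilic", "hydrophobic")
  if (is.null(atoms$water_parent)) atoms$water_parent <- rep(NA_integer_, n)
  bad <- !atoms$role %in% ATOM_ROLES
  if (any(bad)) stop("unknown role(s): ", paste(unique(atoms$role[bad]), collapse = ", "))
  structure(list(atoms = atoms, torsions = torsions), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  tab <- table(x$atoms$role)
  cat("<topology> ", nrow(x$atoms), " atoms (",
      paste(names(tab), tab, sep = ":", collapse = ", "), "); ",
      length(x$torsions), " torsion quadruple(s)\n", sep = "")
  invisible(x)
}

#' Validate metalloporphyrin topology invariants
#'
#' Checks that a role-assigned topology describes a metalloporphyrin:
#' exactly one `metal`, exactly four `ring_N`, every `water_H` mapped to a
#' parent `water_O`, all radii positive.
#' @param top topology
#' @return `top`, invisibly; errors otherwise
#' @export
validate_macrocycle <- function(top) {
  a <- top$atoms
  n_metal <- sum(a$role == "metal")
  n_ringN <- sum(a$role == "ring_N")
  if (n_metal != 1L)
    stop("role assignment: expected exactly 1 metal atom, found ", n_metal)
  if (n_ringN != 4L)
    stop("role assignment: expected exactly 4 ring_N atoms, found ", n_ringN)
  wh <- which(a$role == "water_H")
  orphan <- wh[is.na(a$water_parent[wh]) | a$role[a$water_parent[wh]] != "water_O"]
  if (length(orphan))
    stop("water_H atoms without a parent water_O: ", paste(orphan, collapse = ", "))
  if (any(!is.finite(a$vdw_radius)) || any(a$vdw_radius <= 0))
    stop("all van der Waals radii must be positive")
  invisible(top)
}

#' Construct a trajectory
#'
#' @param coords numeric array `n_frames x n_atoms x 3`, angstrom.
#' @param dt time between stored frames, ps.
#' @param box_length cubic periodic box edge, angstrom, or `NULL` for a
#'   non-periodic system.
#' @param velocities optional array like `coords`, angstrom/ps.
#' @param topology optional [topology()] describing the atoms.
#' @return object of class `trajectory`
#' @export
trajectory <- function(coords, dt, box_length = NULL, velocities = NULL,
                       topology = NULL) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("dt must be a positive scalar (ps)")
  if (!is.null(box_length) && (!is.numeric(box_length) || box_length <= 0))
    stop("box_length must be positive (angstrom) or NULL")
  if (!is.null(velocities) && !identical(dim(velocities), dim(coords)))
    stop("velocities must match coordinate dimensions")
  if (!is.null(topology) && nrow(topology$atoms) != dim(coords)[2])
    stop("topology atom count (", nrow(topology$atoms),
         ") does not match trajectory (", dim(coords)[2], ")")
  structure(list(coords = coords, velocities = velocities, dt = dt,
                 box_length = box_length, topology = topology),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("<trajectory> ", d[1], " frames x ", d[2], " atoms; dt = ", x$dt, " ps",
      if (!is.null(x$box_length)) paste0("; cubic box ", x$box_length, " A"),
      if (!is.null(x$velocities)) "; velocities stored",
      "\n", sep = "")
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj trajectory
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

#' Extract one frame as an `n_atoms x 3` matrix
#' @param traj trajectory
#' @param i frame index (1-based)
#' @export
frame_coords <- function(traj, i) {
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(traj$coords)[2:3]
  m
}

#' Resolve an atom selection to 1-based indices
#'
#' Selections throughout the package are either a character vector of role
#' labels or a vector of 1-based atom indices.
#' @param top topology (may be `NULL` only for index selections)
#' @param sel roles or indices
#' @return integer vector of atom indices
#' @export
resolve_selection <- function(top, sel) {
  if (is.numeric(sel)) {
    idx <- as.integer(sel)
    if (any(idx < 1L)) stop("atom indices are 1-based and must be >= 1")
    return(idx)
  }
  if (is.character(sel)) {
    if (is.null(top)) stop("role-based selection requires a topology")
    bad <- setdiff(sel, ATOM_ROLES)
    if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
    idx <- which(top$atoms$role %in% sel)
    if (!length(idx)) stop("empty selection: no atoms with role ",
                           paste(sel, collapse = "/"))
    return(idx)
  }
  stop("selection must be a character vector of roles or numeric indices")
}

## ---------------------------------------------------------------- XYZ I/O

#' Read a multi-frame XYZ trajectory
#'
#' Parses the plain multi-frame XYZ format (atom-count line, comment line,
#' then `element x y z` records, repeated per frame).  Coordinates are taken
#' to be in angstrom.
#'
#' @param path file path
#' @param dt time between stored frames, ps
#' @param box_length cubic box edge (angstrom) or `NULL` for non-periodic
#' @return [trajectory()] whose topology holds the elements (roles unset)
#' @export
read_xyz_trajectory <- function(path, dt = 1, box_length = NULL) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))] # drop trailing blanks
  if (!length(lines)) stop("malformed XYZ file: ", path, " is empty")
  pos <- 1L
  frames <- list()
  elements <- NULL
  while (pos <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat <= 0)
      stop("malformed XYZ file: invalid atom count at line ", pos)
    if (pos + 1L + nat > length(lines))
      stop("malformed XYZ file: truncated frame starting at line ", pos)
    rec <- lines[(pos + 2L):(pos + 1L + nat)]
    parts <- strsplit(trimws(rec), "\\s+")
    nf <- lengths(parts)
    if (any(nf < 4L))
      stop("parse error at line ", pos + 1L + which(nf < 4L)[1],
           ": expected 'element x y z'")
    el <- vapply(parts, `[[`, "", 1L)
    xyz <- matrix(suppressWarnings(as.numeric(
      unlist(lapply(parts, function(p) p[2:4])))), ncol = 3L, byrow = TRUE)
    if (anyNA(xyz))
      stop("parse error at line ",
           pos + 1L + which(rowSums(is.na(xyz)) > 0)[1],
           ": non-numeric coordinate")
    if (is.null(elements)) {
      elements <- el
    } else if (length(el) != length(elements)) {
      stop("malformed XYZ file: frame ", length(frames) + 1L, " has ",
           length(el), " atoms but frame 1 has ", length(elements))
    }
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + nat
  }
  nfr <- length(frames)
  nat <- length(elements)
  coords <- array(NA_real_, c(nfr, nat, 3L))
  for (i in seq_len(nfr)) coords[i, , ] <- frames[[i]]
  top <- topology(data.frame(element = elements, name = elements,
                             stringsAsFactors = FALSE))
  trajectory(coords, dt = dt, box_length = box_length, topology = top)
}

#' Write a trajectory as multi-frame XYZ
#'
#' Coordinates are written with 5 decimal places, so a write/read round trip
#' preserves them to better than 1e-4 angstrom.
#' @param traj trajectory
#' @param path output path
#' @param comment per-frame comment prefix
#' @export
write_xyz_trajectory <- function(traj, path, comment = "frame") {
  el <- if (!is.null(traj$topology)) traj$topology$atoms$element
        else rep("X", n_atoms(traj))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, i)
    writeLines(c(as.character(length(el)), paste(comment, i)), con)
    writeLines(sprintf("%-3s %12.5f %12.5f %12.5f",
                       el, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

## ---------------------------------------------------------------- PDB I/O

#' Read a single-model PDB file as a topology
#'
#' Elements come from the element column when present, with a fallback
#' heuristic on the atom name (leading alphabetic characters, two-letter
#' symbols recognised for common metals).  Roles are left unset; use
#' [assign_roles()].  The single-model coordinates are kept in the returned
#' topology (`$coords`) so that connectivity-based role rules can use them.
#'
#' @param path PDB file path
#' @return [topology()] with an extra `coords` matrix field
#' @export
read_pdb_topology <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("cannot read PDB topology: ", path, " is missing or empty")
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file ", path,
                                           ": ", conditionMessage(e)))
  a <- pdb$atom
  if (!nrow(a)) stop("PDB file ", path, " contains no ATOM/HETATM records")
  el <- trimws(as.character(a$elesy))
  miss <- is.na(el) | el == ""
  if (any(miss)) el[miss] <- element_from_name(a$elety[miss], a$eleno[miss])
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
  atoms <- data.frame(element = el, name = trimws(a$elety),
                      resid = trimws(a$resid), resno = a$resno,
                      stringsAsFactors = FALSE)
  top <- topology(atoms)
  top$coords <- cbind(a$x, a$y, a$z)
  top
}

# Atom-name -> element heuristic for PDB records lacking an element column.
element_from_name <- function(names, records) {
  two <- c("CO", "FE", "MG", "ZN", "NI", "MN", "CU", "NA", "CL", "BR", "CA")
  out <- character(length(names))
  for (i in seq_along(names)) {
    nm <- toupper(gsub("[^A-Za-z].*$", "", trimws(names[i])))
    if (!nzchar(nm))
      stop("cannot determine element for PDB record ", records[i],
           " (atom name '", names[i], "')")
    out[i] <- if (nm %in% two) nm else substr(nm, 1, 1)
  }
  out
}

## ------------------------------------------------------------ role rules

#' Default role-assignment rules for porphyrin + water systems
#'
#' An ordered list of rules; each rule matches on element and/or atom-name
#' regex and/or residue-name regex.  The first matching rule wins; unmatched
#' atoms get role `other`.
#' @export
default_role_rules <- function() {
  list(
    list(role = "metal",   element = c("Co", "Fe", "Mg", "Zn", "Ni", "Mn", "Cu")),
    list(role = "water_O", element = "O", resid_regex = "^(HOH|WAT|SOL|TIP.?|SPC)$"),
    list(role = "water_H", element = "H", resid_regex = "^(HOH|WAT|SOL|TIP.?|SPC)$"),
    list(role = "water_O", element = "O", name_regex = "^OW"),
    list(role = "water_H", element = "H", name_regex = "^HW"),
    list(role = "ring_N",  element = "N", name_regex = "^N[1-4ABCD]?$"),
    list(role = "ring_C_alpha", element = "C", name_regex = "^CA[0-9]*$"),
    list(role = "ring_C_beta",  element = "C", name_regex = "^CB[0-9]*$"),
    list(role = "ring_C_meso",  element = "C", name_regex = "^CM[0-9]*$"),
    list(role = "ring_H",  element = "H", name_regex = "^H[BM][0-9]*$")
  )
}

#' Assign roles to a topology
#'
#' Applies ordered matching rules (see [default_role_rules()]), maps water
#' hydrogens to their parent oxygen (same residue number when available,
#' otherwise nearest oxygen within 1.25 angstrom using the topology's
#' coordinates), assigns polarity classes, and — in macrocycle mode —
#' enforces the metalloporphyrin invariants (1 metal, 4 ring_N).
#'
#' Polarity defaults: N, O, metal and water atoms hydrophilic; C and ring H
#' hydrophobic.
#'
#' @param top topology from [read_pdb_topology()] or [topology()]
#' @param rules list of rules; see [default_role_rules()]
#' @param macrocycle enforce metalloporphyrin invariants (default TRUE)
#' @return topology with roles, polarity classes and water parents set
#' @export
assign_roles <- function(top, rules = default_role_rules(), macrocycle = TRUE) {
  a <- top$atoms
  role <- rep("other", nrow(a))
  for (rule in rules) {
    cand <- rep(TRUE, nrow(a))
    if (!is.null(rule$element)) cand <- cand & a$element %in% rule$element
    if (!is.null(rule$name_regex)) cand <- cand & grepl(rule$name_regex, a$name)
    if (!is.null(rule$resid_regex)) {
      cand <- if (is.null(a$resid)) cand & FALSE
              else cand & grepl(rule$resid_regex, a$resid)
    }
    role[cand & role == "other"] <- rule$role
  }
  a$role <- role
  # parent oxygen for each water hydrogen
  a$water_parent <- rep(NA_integer_, nrow(a))
  wh <- which(role == "water_H"); wo <- which(role == "water_O")
  if (length(wh)) {
    if (!is.null(a$resno)) {
      omap <- wo[match(a$resno[wh], a$resno[wo])]
      a$water_parent[wh] <- omap
    }
    need <- wh[is.na(a$water_parent[wh])]
    if (length(need) && !is.null(top$coords)) {
      for (h in need) {
        d <- sqrt(rowSums((top$coords[wo, , drop = FALSE] -
                           matrix(top$coords[h, ], length(wo), 3, byrow = TRUE))^2))
        j <- which.min(d)
        if (d[j] <= 1.25) a$water_parent[h] <- wo[j]
      }
    }
  }
  a$polarity_class <- ifelse(a$element %in% c("N", "O") | role == "metal" |
                               role %in% c("water_O", "water_H"),
                             "hydrophilic", "hydrophobic")
  out <- top
  out$atoms <- a
  if (macrocycle) validate_macrocycle(out)
  out
}

## --------------------------------------------------- periodic primitives

#' Minimum-image displacement in a cubic periodic box
#'
#' Returns `b - a` mapped so every component lies in `[-box/2, +box/2)`;
#' a component exactly on the boundary resolves to the negative image.
#' The result is the displacement of minimum norm over all periodic images.
#'
#' @param a,b positions: length-3 vectors or `n x 3` matrices
#' @param box_length cubic box edge, angstrom
#' @return displacement(s), same shape as the inputs
#' @export
minimum_image_displacement <- function(a, b, box_length) {
  if (!is.numeric(box_length) || length(box_length) != 1L || box_length <= 0)
    stop("box_length must be a positive scalar")
  d <- b - a
  d - box_length * floor(d / box_length + 0.5)
}

#' Minimum-image distance(s) between a point and a set of points
#' @param x length-3 position
#' @param pts `n x 3` matrix
#' @param box_length box edge or `NULL` (plain Euclidean)
#' @return numeric vector of distances
#' @export
min_image_distance <- function(x, pts, box_length = NULL) {
  pts <- matrix(pts, ncol = 3L)
  d <- sweep(pts, 2L, as.numeric(x))
  if (!is.null(box_length))
    d <- d - box_length * floor(d / box_length + 0.5)
  sqrt(rowSums(d * d))
}

#' Wrap coordinates into the primary box [0, L)
#' @param traj trajectory with a box
#' @return trajectory with wrapped coordinates
#' @export
wrap_coordinates <- function(traj) {
  if (is.null(traj$box_length)) stop("trajectory is non-periodic")
  traj$coords <- traj$coords - traj$box_length * floor(traj$coords / traj$box_length)
  traj
}
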