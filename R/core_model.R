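# Domain containers and structure I/O.
#
# A conformational ensemble is stored column-wise: one shared atom table
# (the topology) plus one n_atoms x 3 coordinate matrix per frame. This makes
# the shared-topology invariant structural: atom i of residue j is the same
# atom in every frame by construction.

# ---- protein residue templates -----------------------------------------

# Formal-charge and aromatic-ring templates for standard residues at neutral
# pH. Charged-group atoms are tagged with the sign of their group so that
# charge-contact detection can test "opposite formal charges" at atom level;
# His is treated as neutral and aromatic (5-membered ring).
.PROTEIN_CHARGE_TEMPLATES <- list(
  ASP = c(OD1 = -1L, OD2 = -1L),
  GLU = c(OE1 = -1L, OE2 = -1L),
  LYS = c(NZ = 1L),
  ARG = c(NH1 = 1L, NH2 = 1L, NE = 1L)
)

.PROTEIN_RING_TEMPLATES <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2"))
)

protein_formal_charge <- function(res_name, atom_name) {
  tmpl <- .PROTEIN_CHARGE_TEMPLATES[[toupper(res_name)]]
  if (is.null(tmpl)) return(0L)
  ch <- tmpl[toupper(atom_name)]
  if (is.na(ch)) 0L else unname(ch)
}

# ---- constructors -------------------------------------------------------

#' Build an atom table for a conformational ensemble
#'
#' @param res_index integer, 1-based contiguous residue index per atom.
#' @param pdb_number author residue number per atom (display only).
#' @param res_name three-letter residue code per atom.
#' @param atom_name atom name per atom (Cα must be named "CA").
#' @param element element symbol per atom; guessed from `atom_name` if NULL.
#' @param formal_charge integer formal charge per atom; protein templates
#'   applied if NULL.
#' @return data.frame with columns res_index, pdb_number, res_name,
#'   atom_name, element, mass, formal_charge, is_heavy.
#' @export
atom_table <- function(res_index, pdb_number, res_name, atom_name,
                       element = NULL, formal_charge = NULL) {
  if (is.null(element)) element <- guess_element(atom_name)
  element <- toupper(element)
  if (is.null(formal_charge)) {
    formal_charge <- mapply(protein_formal_charge, res_name, atom_name)
  }
  data.frame(
    res_index = as.integer(res_index),
    pdb_number = as.integer(pdb_number),
    res_name = toupper(res_name),
    atom_name = toupper(atom_name),
    element = element,
    mass = element_mass(element),
    formal_charge = as.integer(formal_charge),
    is_heavy = element != "H",
    stringsAsFactors = FALSE
  )
}

#' Construct a conformational ensemble
#'
#' @param atoms atom table (see [atom_table()]), shared by all frames.
#' @param coords list of n_atoms x 3 coordinate matrices (Å), one per frame.
#' @param frame_ids unique frame identifiers; defaults to 1..n.
#' @param source_tag free-text provenance tag (`apo`, `holo:<ligand>`,
#'   `synthetic`).
#' @return object of class `conf_ensemble`.
#' @export
conformation_ensemble <- function(atoms, coords, frame_ids = NULL,
                                  source_tag = "synthetic") {
  if (length(coords) == 0) stop("ensemble must contain at least one frame")
  if (is.null(frame_ids)) frame_ids <- seq_along(coords)
  if (anyDuplicated(frame_ids)) stop("frame_ids must be unique")
  coords <- lapply(coords, function(x) {
    x <- matrix(as.numeric(x), ncol = 3)
    if (nrow(x) != nrow(atoms))
      stop("coordinate rows do not match the atom table")
    if (!all(is.finite(x))) stop("non-finite coordinates")
    dimnames(x) <- NULL
    x
  })
  ri <- atoms$res_index
  if (any(diff(unique(ri)) != 1L) || unique(ri)[1] != 1L)
    stop("res_index must be 1-based and contiguous")
  structure(
    list(atoms = atoms, coords = coords,
         frame_ids = frame_ids, source_tag = source_tag),
    class = "conf_ensemble"
  )
}

#' @export
print.conf_ensemble <- function(x, ...) {
  cat(sprintf("<conf_ensemble> %d frames, %d residues, %d atoms [%s]\n",
              n_frames(x), n_residues(x), nrow(x$atoms), x$source_tag))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens a `conf_ensemble`.
#' @export
n_frames <- function(ens) length(ens$coords)

#' Number of residues in an ensemble or conformation
#' @param x a `conf_ensemble` or `conformation`.
#' @export
n_residues <- function(x) max(x$atoms$res_index)

#' Extract one conformation (frame) from an ensemble
#'
#' @param ens a `conf_ensemble`.
#' @param i frame position (1..n_frames).
#' @return object of class `conformation`: the shared atom table plus that
#'   frame's coordinates and frame_id.
#' @export
get_conformation <- function(ens, i) {
  if (i < 1 || i > n_frames(ens)) stop("frame index out of range")
  structure(list(atoms = ens$atoms, coords = ens$coords[[i]],
                 frame_id = ens$frame_ids[[i]]),
            class = "conformation")
}

# Row indices of a residue's atoms.
residue_atom_rows <- function(conf, residue_index) {
  if (residue_index < 1 || residue_index > n_residues(conf))
    stop("residue index ", residue_index, " out of range")
  which(conf$atoms$res_index == residue_index)
}

# Row indices of Cα atoms, in residue order; errors if any residue lacks one.
ca_rows <- function(x, require_all = TRUE) {
  idx <- which(x$atoms$atom_name == "CA")
  if (require_all && length(idx) != n_residues(x))
    stop("not every residue has a CA atom")
  idx[order(x$atoms$res_index[idx])]
}

#' Construct a ligand model
#'
#' @param atoms data.frame with columns name, element, formal_charge (mass and
#'   is_heavy derived if absent).
#' @param coords n_atoms x 3 matrix (Å), reference conformer.
#' @param bonds data.frame with columns i, j, order (order 4 = aromatic).
#' @param aromatic_rings list of integer vectors of atom positions.
#' @param donors 2-column integer matrix of (heavy donor, hydrogen) pairs.
#' @param acceptors integer vector of heavy acceptor positions.
#' @param rotatable_bonds count of rotatable single bonds.
#' @param net_charge declared net formal charge.
#' @param name ligand tag.
#' @return object of class `ligand_model`.
#' @export
ligand_model <- function(atoms, coords, bonds,
                         aromatic_rings = list(),
                         donors = matrix(integer(), ncol = 2),
                         acceptors = integer(),
                         rotatable_bonds = 0L,
                         net_charge = sum(atoms$formal_charge),
                         name = "ligand") {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (nrow(coords) != nrow(atoms)) stop("coords/atoms length mismatch")
  atoms$element <- toupper(atoms$element)
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  atoms$is_heavy <- atoms$element != "H"
  atoms$formal_charge <- as.integer(atoms$formal_charge)
  if (sum(atoms$formal_charge) != net_charge)
    stop("formal charges sum to ", sum(atoms$formal_charge),
         ", not the declared net charge ", net_charge)
  for (ring in aromatic_rings) {
    if (length(ring) < 5) stop("aromatic ring with fewer than 5 atoms")
    if (any(!atoms$is_heavy[ring])) stop("aromatic ring containing hydrogen")
  }
  donors <- matrix(as.integer(donors), ncol = 2)
  if (nrow(donors) > 0) {
    ok <- atoms$element[donors[, 1]] %in% c("N", "O", "S") &
      atoms$element[donors[, 2]] == "H"
    if (!all(ok)) stop("donors must pair an N/O/S heavy atom with an H")
  }
  structure(
    list(atoms = atoms, coords = coords, bonds = bonds,
         aromatic_rings = aromatic_rings, donors = donors,
         acceptors = as.integer(acceptors),
         rotatable_bonds = as.integer(rotatable_bonds),
         net_charge = as.integer(net_charge), name = name),
    class = "ligand_model"
  )
}

#' @export
print.ligand_model <- function(x, ...) {
  cat(sprintf(
    "<ligand_model> %s: %d atoms (%d heavy), net charge %+d, %d aromatic ring(s), %d donor(s), %d acceptor(s)\n",
    x$name, nrow(x$atoms), sum(x$atoms$is_heavy), x$net_charge,
    length(x$aromatic_rings), nrow(x$donors), length(x$acceptors)))
  invisible(x)
}

# Heavy-atom coordinate helper.
heavy_coords <- function(obj, coords = NULL) {
  cc <- if (is.null(coords)) obj$coords else coords
  cc[obj$atoms$is_heavy, , drop = FALSE]
}

#' Construct a docked pose
#'
#' @param ligand_coords n_atoms x 3 matrix in the ligand's atom order (Å).
#' @param raw_score backend score.
#' @param frame_id originating conformation.
#' @param origin_residue residue index whose box produced the pose (NA in
#'   whole-conformation mode).
#' @return object of class `pose`.
#' @export
pose <- function(ligand_coords, raw_score, frame_id, origin_residue = NA_integer_) {
  structure(list(ligand_coords = matrix(as.numeric(ligand_coords), ncol = 3),
                 raw_score = as.numeric(raw_score),
                 frame_id = frame_id,
                 origin_residue = as.integer(origin_residue)),
            class = "pose")
}

# Validating constructor for a docked ensemble; checks the one-pose-per-frame
# and selected-is-optimal invariants.
docked_ensemble <- function(ensemble, ligand, selected, candidates,
                            backend_tag, polarity, failed_frames = integer()) {
  stopifnot(polarity %in% c("lower_is_better", "higher_is_better"))
  kept <- setdiff(seq_len(n_frames(ensemble)), failed_frames)
  if (length(selected) != length(kept))
    stop("exactly one selected pose required per (non-failed) frame")
  sgn <- if (polarity == "lower_is_better") 1 else -1
  for (k in seq_along(kept)) {
    cand_scores <- vapply(candidates[[kept[k]]], function(p) p$raw_score, 0)
    if (length(cand_scores) &&
        sgn * selected[[k]]$raw_score > min(sgn * cand_scores) + 1e-9)
      stop("selected pose is not optimal among candidates for frame ",
           ensemble$frame_ids[[kept[k]]])
  }
  structure(
    list(ensemble = ensemble, ligand = ligand, selected = selected,
         candidates = candidates, backend_tag = backend_tag,
         polarity = polarity, failed_frames = as.integer(failed_frames)),
    class = "docked_ensemble"
  )
}

#' @export
print.docked_ensemble <- function(x, ...) {
  cat(sprintf("<docked_ensemble> %s (%s): %d selected poses / %d frames\n",
              x$backend_tag, x$polarity, length(x$selected),
              n_frames(x$ensemble)))
  invisible(x)
}

#' Selected raw scores of a docked ensemble
#' @param de a `docked_ensemble`.
#' @return numeric vector, one score per selected pose.
#' @export
selected_scores <- function(de) vapply(de$selected, function(p) p$raw_score, 0)

# ---- multi-model PDB I/O -----------------------------------------------

# Pre-scan MODEL/ENDMDL blocks: returns per-model atom counts so a topology
# mismatch can be reported naming the offending model.
scan_pdb_models <- function(lines) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0) {
    return(list(n_models = 1L, counts = sum(is_atom)))
  }
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts))
    stop("unbalanced MODEL/ENDMDL records")
  counts <- mapply(function(s, e) sum(is_atom[s:e]), model_starts, model_ends)
  list(n_models = length(model_starts), counts = counts)
}

#' Read a conformational ensemble from a multi-model PDB file
#'
#' One conformation per MODEL block; all models must share an identical atom
#' ordering (the shared topology). Author residue numbers are preserved as
#' `pdb_number`; internal residue indices are 1-based and contiguous.
#' Alternate location A is kept (others dropped with a warning); insertion
#' codes are rejected.
#'
#' @param path PDB file with MODEL/ENDMDL blocks (a single-model file yields a
#'   one-frame ensemble).
#' @param source_tag provenance tag stored on the ensemble.
#' @return a `conf_ensemble`.
#' @export
read_ensemble <- function(path, source_tag = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^(ATOM  |HETATM)", lines))) stop("no atoms in ", path)
  scan <- scan_pdb_models(lines)
  if (length(unique(scan$counts)) > 1) {
    bad <- which(scan$counts != scan$counts[1])[1]
    stop(sprintf(
      "topology mismatch: model %d has %d atoms, model 1 has %d",
      bad, scan$counts[bad], scan$counts[1]))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes are not supported")
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " alternate-location atoms (keeping altloc A)")
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  keep_xyz <- rep(keep, each = 3)
  at <- at[keep, , drop = FALSE]
  xyz <- xyz[, keep_xyz, drop = FALSE]

  res_key <- paste(at$chain, at$resno, sep = "_")
  res_index <- match(res_key, unique(res_key))
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem) | elem == ""))
    elem <- guess_element(at$elety)
  else elem <- ifelse(is.na(elem) | elem == "", guess_element(at$elety), elem)
  atoms <- atom_table(res_index, at$resno, at$resid, at$elety, element = elem)
  coords <- lapply(seq_len(nrow(xyz)), function(m) {
    matrix(xyz[m, ], ncol = 3, byrow = TRUE)
  })
  conformation_ensemble(atoms, coords,
                        frame_ids = seq_len(nrow(xyz)),
                        source_tag = source_tag)
}

#' Write a conformational ensemble as a multi-model PDB file
#'
#' @param ens a `conf_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  xyz <- do.call(rbind, lapply(ens$coords, function(m) as.vector(t(m))))
  a <- ens$atoms
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = a$pdb_number, resid = a$res_name,
                   elety = a$atom_name, chain = "A",
                   elesy = a$element)
  invisible(path)
}

#' Write a docked ensemble: poses PDB plus a score table
#'
#' Writes `<prefix>.pdb` (protein + ligand per MODEL, one model per selected
#' pose) and `<prefix>_scores.tsv` (frame_id, origin_residue, raw_score, with
#' a header line).
#'
#' @param de a `docked_ensemble`.
#' @param prefix output path prefix.
#' @return named character vector of the two files written, invisibly.
#' @export
write_docked_ensemble <- function(de, prefix) {
  if (length(de$selected) == 0) stop("empty docked ensemble")
  ens <- de$ensemble
  lig <- de$ligand
  kept <- setdiff(seq_len(n_frames(ens)), de$failed_frames)
  pa <- ens$atoms
  lig_resno <- max(pa$pdb_number) + 1L
  a_res <- c(pa$pdb_number, rep(lig_resno, nrow(lig$atoms)))
  a_resid <- c(pa$res_name, rep("LIG", nrow(lig$atoms)))
  a_name <- c(pa$atom_name, lig$atoms$name)
  a_elem <- c(pa$element, lig$atoms$element)
  xyz <- do.call(rbind, lapply(seq_along(kept), function(k) {
    m <- rbind(ens$coords[[kept[k]]], de$selected[[k]]$ligand_coords)
    as.vector(t(m))
  }))
  pdb_path <- paste0(prefix, ".pdb")
  bio3d::write.pdb(file = pdb_path, xyz = xyz, resno = a_res, resid = a_resid,
                   elety = a_name, chain = "A", elesy = a_elem)
  tab <- data.frame(
    frame_id = vapply(de$selected, function(p) as.integer(p$frame_id), 0L),
    origin_residue = vapply(de$selected, function(p) p$origin_residue, 0L),
    raw_score = vapply(de$selected, function(p) p$raw_score, 0)
  )
  tsv_path <- paste0(prefix, "_scores.tsv")
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(pdb = pdb_path, scores = tsv_path))
}

# ---- ligand I/O ---------------------------------------------------------

# Extract M CHG formal charges from the raw text of one SDF record.
parse_sdf_charges <- function(sdf_lines, n_atoms) {
  charges <- integer(n_atoms)
  chg_lines <- grep("^M  CHG", sdf_lines, value = TRUE)
  for (ln in chg_lines) {
    fields <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
    n <- fields[1]
    for (k in seq_len(n)) {
      charges[fields[2 * k]] <- fields[2 * k + 1]
    }
  }
  if (length(chg_lines) == 0) {
    # fall back to atom-block charge codes (MDL: 1=+3 .. 3=+1, 5=-1 .. 7=-3)
    code_map <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
    counts <- as.integer(strsplit(trimws(substr(sdf_lines[4], 1, 6)), "\\s+")[[1]])[1]
    for (i in seq_len(min(counts, n_atoms))) {
      code <- suppressWarnings(as.integer(substr(sdf_lines[4 + i], 37, 39)))
      if (!is.na(code) && as.character(code) %in% names(code_map))
        charges[i] <- code_map[[as.character(code)]]
    }
  }
  charges
}

read_ligand_sdf <- function(path, name) {
  sdfset <- ChemmineR::read.SDFset(path)
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n_atoms <- nrow(ab)
  elements <- toupper(sub("_.*$", "", rownames(ab)))
  coords <- unname(ab[, 1:3, drop = FALSE])
  bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  charges <- parse_sdf_charges(readLines(path, warn = FALSE), n_atoms)

  # aromatic rings: rings (ChemmineR perception) whose bonds are all SDF
  # bond type 4
  arom_bonds <- bonds[bonds$order == 4L, , drop = FALSE]
  bond_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  arom_keys <- bond_key(arom_bonds$i, arom_bonds$j)
  rings_raw <- tryCatch(
    ChemmineR::rings(sdf, type = "all", arom = FALSE),
    error = function(e) list()
  )
  if (!is.null(rings_raw$RINGS)) rings_raw <- rings_raw$RINGS
  aromatic_rings <- list()
  for (ring in rings_raw) {
    idx <- as.integer(sub("^.*_", "", ring))
    edges <- bond_key(idx, c(idx[-1], idx[1]))
    if (length(idx) >= 5 && all(edges %in% arom_keys))
      aromatic_rings <- c(aromatic_rings, list(idx))
  }

  build_ligand(elements, coords, bonds, charges, aromatic_rings, name)
}

# Minimal ligand-from-PDB reader: atoms from the coordinate records, bonds
# inferred from covalent distances. No aromaticity information is available
# in PDB, so aromatic rings are left empty with a warning.
read_ligand_pdb <- function(path, name) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  elements <- toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                             guess_element(at$elety), at$elesy))
  coords <- as.matrix(at[, c("x", "y", "z")])
  d <- cross_dist(coords, coords)
  cutoff <- outer(ifelse(elements == "H", 0.4, 0.9),
                  ifelse(elements == "H", 0.4, 0.9), "+")
  bonded <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  bonds <- data.frame(i = bonded[, 1], j = bonded[, 2], order = 1L)
  warning("PDB ligand input carries no aromaticity; aromatic rings left empty ",
          "(prefer SDF V2000)")
  build_ligand(elements, coords, bonds, integer(length(elements)),
               list(), name)
}

# Assemble a ligand_model from parsed pieces: donors, acceptors, rotatable
# bonds derived here from the connection table.
build_ligand <- function(elements, coords, bonds, charges, aromatic_rings,
                         name) {
  n <- length(elements)
  atoms <- data.frame(
    name = paste0(elements, seq_len(n)),
    element = elements,
    formal_charge = as.integer(charges),
    stringsAsFactors = FALSE
  )
  nbrs <- lapply(seq_len(n), function(i) {
    c(bonds$j[bonds$i == i], bonds$i[bonds$j == i])
  })
  is_h <- elements == "H"
  if (!any(is_h))
    warning("ligand has no explicit hydrogens; donor list will be empty")
  donors <- matrix(integer(), ncol = 2)
  for (h in which(is_h)) {
    heavy <- nbrs[[h]]
    heavy <- heavy[elements[heavy] %in% c("N", "O", "S")]
    if (length(heavy)) donors <- rbind(donors, c(heavy[1], h))
  }
  acceptors <- which(elements %in% c("N", "O", "S"))
  ring_atoms <- unique(unlist(aromatic_rings))
  heavy_deg <- vapply(nbrs, function(v) sum(!is_h[v]), 0L)
  rot <- sum(bonds$order == 1L &
               !is_h[bonds$i] & !is_h[bonds$j] &
               heavy_deg[bonds$i] >= 2 & heavy_deg[bonds$j] >= 2 &
               !(bonds$i %in% ring_atoms & bonds$j %in% ring_atoms))
  ligand_model(atoms, coords, bonds, aromatic_rings, donors, acceptors,
               rotatable_bonds = rot, net_charge = sum(charges), name = name)
}

#' Read a ligand structure
#'
#' SDF (V2000, with explicit hydrogens and `M CHG` formal charges) is the
#' preferred input; a basic PDB reader (distance-inferred bonds, no
#' aromaticity) is provided as a fallback. MOL2 is not supported: convert to
#' SDF first (e.g. with Open Babel).
#'
#' @param path ligand file (.sdf/.mol or .pdb).
#' @param name ligand tag; defaults to the file stem.
#' @return a `ligand_model` with bonds, formal charges, aromatic rings,
#'   hydrogen-bond donors/acceptors and a rotatable-bond count.
#' @export
read_ligand <- function(path, name = sub("\\.[^.]+$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(sub("^.*\\.", "", path))
  switch(ext,
    sdf = ,
    mol = read_ligand_sdf(path, name),
    pdb = read_ligand_pdb(path, name),
    mol2 = stop("MOL2 is not supported; convert to SDF (V2000) first"),
    stop("unrecognized ligand format: .", ext)
  )
}

#' Write a ligand model as an SDF (V2000) file
#'
#' @param ligand a `ligand_model`.
#' @param path output file.
#' @param coords optional replacement coordinates (e.g. a docked pose).
#' @return `path`, invisibly.
#' @export
write_ligand_sdf <- function(ligand, path, coords = NULL) {
  if (is.null(coords)) coords <- ligand$coords
  n <- nrow(ligand$atoms)
  nb <- nrow(ligand$bonds)
  lines <- c(
    ligand$name, "  idpdock", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            coords[, 1], coords[, 2], coords[, 3], ligand$atoms$element),
    sprintf("%3d%3d%3d  0", ligand$bonds$i, ligand$bonds$j,
            ligand$bonds$order)
  )
  chg <- which(ligand$atoms$formal_charge != 0)
  if (length(chg)) {
    lines <- c(lines, paste0(
      sprintf("M  CHG%3d", length(chg)),
      paste0(sprintf("%4d%4d", chg, ligand$atoms$formal_charge[chg]),
             collapse = "")))
  }
  writeLines(c(lines, "M  END", "$$$$"), path)
  invisible(path)
}
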