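# Docking backend contract.
#
# Every backend maps (conformation, ligand, box?, n_poses, seed) to a list of
# scored poses under a declared score polarity. The built-in mock backend is
# a deterministic rigid-ligand grid search whose output can be checked
# exactly against brute-force enumeration; external engines (AutoDock
# Vina-style grid engines, DiffDock-style whole-conformation engines) are
# driven through thin subprocess adapters behind the same contract.

#' Declare a docking backend
#'
#' @param name backend tag.
#' @param polarity `"lower_is_better"` (physics-style energies) or
#'   `"higher_is_better"` (confidence scores).
#' @param mode `"boxed"` (requires a search box per call) or
#'   `"whole_conformation"`.
#' @param parameters named list of engine settings (grid spacing, binary
#'   path, exhaustiveness, ...).
#' @return object of class `backend_spec`.
#' @export
backend_spec <- function(name, polarity, mode, parameters = list()) {
  polarity <- match.arg(polarity, c("lower_is_better", "higher_is_better"))
  mode <- match.arg(mode, c("boxed", "whole_conformation"))
  structure(list(name = name, polarity = polarity, mode = mode,
                 parameters = parameters),
            class = "backend_spec")
}

#' The deterministic mock grid backend
#'
#' Rigid-ligand translational grid search with a simple pairwise clash +
#' attraction score (see [mock_grid_dock()]); exact, deterministic, and
#' checkable against independent enumeration. Supports both boxed and
#' whole-conformation calls.
#'
#' @param grid_spacing grid spacing g in Å (> 0).
#' @return a `backend_spec` named `"mock_grid"`, lower_is_better.
#' @export
mock_backend <- function(grid_spacing = 1.0) {
  if (grid_spacing <= 0) stop("grid spacing must be > 0")
  backend_spec("mock_grid", "lower_is_better", "boxed",
               parameters = list(grid_spacing = grid_spacing))
}

# Pairwise score term of the mock backend: hard clash inside 2 Å, Gaussian
# attraction well centered at 3.5 Å, zero beyond 8 Å.
mock_pair_term <- function(d) {
  ifelse(d > 8, 0, ifelse(d < 2, 1000, -exp(-(d - 3.5)^2 / 2)))
}

# Grid centroid positions filling a box at spacing g, in lexicographic
# (x, y, z) order. Points are cell centers: lo + (k - 1/2) g, k = 1..floor(edge/g).
mock_grid_points <- function(box, g) {
  n <- floor(box$edge / g + 1e-9)
  if (n < 1) stop("empty grid: box edge ", box$edge, " < spacing ", g)
  ax <- function(c0) c0 - box$edge / 2 + (seq_len(n) - 0.5) * g
  pts <- expand.grid(z = ax(box$center[3]), y = ax(box$center[2]),
                     x = ax(box$center[1]))
  as.matrix(pts[, c("x", "y", "z")])  # x varies slowest: lexicographic
}

#' Dock with the deterministic mock grid backend
#'
#' The ligand is kept rigid in its input conformer (no rotation or torsion
#' sampling) and translated so its centroid visits every point of a regular
#' grid of spacing `g` filling the box. Each placement is scored as the sum
#' over all ligand-heavy / protein-heavy atom pairs within 8 Å of
#' `+1000` (clash) for pair distances below 2 Å and
#' `-exp(-(d - 3.5)^2 / 2)` otherwise. Poses are returned sorted by
#' ascending score (lower is better); ties are broken by grid-point
#' lexicographic order.
#'
#' @param conf a `conformation` (the receptor frame).
#' @param ligand a `ligand_model`.
#' @param box a `search_box`.
#' @param n_poses number of poses to return (top of the sorted grid).
#' @param grid_spacing grid spacing g (Å).
#' @return list of `pose` objects, scores in `raw_score`, sorted ascending.
#' @export
mock_grid_dock <- function(conf, ligand, box, n_poses = 1,
                           grid_spacing = 1.0) {
  if (n_poses < 1) stop("n_poses must be >= 1")
  G <- mock_grid_points(box, grid_spacing)
  scores <- mock_grid_scores(conf, ligand, G)
  ord <- order(scores)  # stable: ties keep lexicographic grid order
  top <- ord[seq_len(min(n_poses, length(ord)))]
  lig_centroid <- colMeans(ligand$coords)
  offsets <- sweep(ligand$coords, 2, lig_centroid)
  lapply(top, function(k) {
    pose(sweep(offsets, 2, G[k, ], "+"), scores[k], conf$frame_id)
  })
}

# Scores of every grid placement (vectorized over grid points).
mock_grid_scores <- function(conf, ligand, G) {
  P <- heavy_coords(conf)
  lig_centroid <- colMeans(ligand$coords)
  L <- sweep(heavy_coords(ligand), 2, lig_centroid)  # heavy offsets
  if (nrow(P) == 0) return(numeric(nrow(G)))
  scores <- numeric(nrow(G))
  for (a in seq_len(nrow(L))) {
    pos <- sweep(G, 2, L[a, ], "+")
    d <- cross_dist(pos, P)
    scores <- scores + rowSums(mock_pair_term(d))
  }
  scores
}

# Whole-conformation box for the mock backend: cube covering the protein
# bounding box with a 2 Rg margin on every side.
whole_conformation_box <- function(conf, ligand_rg) {
  P <- conf$coords
  lo <- apply(P, 2, min); hi <- apply(P, 2, max)
  search_box((lo + hi) / 2, max(hi - lo) + 4 * ligand_rg)
}

#' Dispatch one docking call through a backend spec
#'
#' @param spec a `backend_spec`.
#' @param conf a `conformation`.
#' @param ligand a `ligand_model`.
#' @param box a `search_box` (required for boxed backends; for the mock
#'   backend in whole-conformation use, defaults to the protein bounding box
#'   plus a 2 Rg margin).
#' @param n_poses poses requested.
#' @param seed integer seed forwarded to stochastic engines (the mock
#'   backend is deterministic and ignores it).
#' @return list of `pose` objects sorted best-first under the declared
#'   polarity.
#' @export
backend_dock <- function(spec, conf, ligand, box = NULL, n_poses = 1,
                         seed = 1L) {
  if (spec$name == "mock_grid") {
    if (is.null(box))
      box <- whole_conformation_box(conf, radius_of_gyration(ligand))
    g <- spec$parameters$grid_spacing
    if (is.null(g)) g <- 1.0
    return(mock_grid_dock(conf, ligand, box, n_poses, g))
  }
  external_dock(spec, conf, ligand, box, n_poses, seed)
}

# ---- external engine adapter -------------------------------------------

#' Build the command line for a boxed grid engine
#'
#' @param spec a `backend_spec` whose parameters include `binary`.
#' @param receptor,ligand,out file paths handed to the engine.
#' @param box a `search_box`.
#' @param n_poses poses requested (engine `--num_modes`).
#' @param seed engine seed.
#' @return character vector: binary followed by its arguments.
#' @export
grid_engine_command <- function(spec, receptor, ligand, out, box,
                                n_poses = 9, seed = 1L) {
  extra <- spec$parameters$extra_args
  c(spec$parameters$binary,
    "--receptor", receptor, "--ligand", ligand, "--out", out,
    "--center_x", sprintf("%.3f", box$center[1]),
    "--center_y", sprintf("%.3f", box$center[2]),
    "--center_z", sprintf("%.3f", box$center[3]),
    "--size_x", sprintf("%.3f", box$edge),
    "--size_y", sprintf("%.3f", box$edge),
    "--size_z", sprintf("%.3f", box$edge),
    "--num_modes", as.character(n_poses),
    "--seed", as.character(seed),
    if (!is.null(extra)) as.character(extra))
}

#' Parse a Vina-style result table from engine output
#'
#' Reads the `mode | affinity | ...` table printed by grid engines and
#' returns the per-mode scores in order.
#'
#' @param lines captured engine stdout.
#' @return numeric vector of scores (kcal/mol, lower is better).
#' @export
parse_grid_engine_scores <- function(lines) {
  body <- grep("^\\s*\\d+\\s+-?\\d+\\.\\d+", lines, value = TRUE)
  if (length(body) == 0) stop("no score table found in engine output:\n",
                              paste(utils::tail(lines, 5), collapse = "\n"))
  vapply(strsplit(trimws(body), "\\s+"),
         function(f) as.numeric(f[2]), 0)
}

#' Run an external docking engine behind the backend contract
#'
#' Writes receptor and ligand in the engine's input format (PDBQT for grid
#' engines, via Open Babel), invokes the engine binary, and parses poses and
#' scores back under the declared polarity. DiffDock-style engines report a
#' confidence where higher is better; that polarity is declared on the spec
#' so all downstream selection logic is polarity-driven.
#'
#' @inheritParams backend_dock
#' @return list of `pose` objects.
#' @export
external_dock <- function(spec, conf, ligand, box = NULL, n_poses = 9,
                          seed = 1L) {
  bin <- spec$parameters$binary
  if (is.null(bin) || Sys.which(bin) == "") {
    stop(structure(class = c("backend_unavailable", "error", "condition"),
                   list(message = paste0("backend unavailable: engine binary '",
                                         if (is.null(bin)) "<unset>" else bin,
                                         "' not found"),
                        call = NULL)))
  }
  if (spec$mode == "boxed" && is.null(box))
    stop("boxed backend requires a search box")
  work <- tempfile("dock_")
  dir.create(work)
  rec <- file.path(work, "receptor.pdbqt")
  lig <- file.path(work, "ligand.pdbqt")
  out <- file.path(work, "out.pdbqt")
  write_receptor_pdbqt(conf, rec)
  write_ligand_pdbqt(ligand, lig)
  cmd <- grid_engine_command(spec, rec, lig, out, box, n_poses, seed)
  log <- suppressWarnings(system2(cmd[1], cmd[-1], stdout = TRUE,
                                  stderr = TRUE))
  scores <- tryCatch(parse_grid_engine_scores(log), error = function(e) {
    stop("engine output parse failure: ", conditionMessage(e),
         "\n--- engine log ---\n", paste(log, collapse = "\n"))
  })
  pose_coords <- parse_pdbqt_poses(readLines(out, warn = FALSE))
  n <- min(length(scores), length(pose_coords), n_poses)
  lapply(seq_len(n), function(k) {
    pose(pose_coords[[k]], scores[k], conf$frame_id)
  })
}

# Rigid receptor PDBQT: ATOM records with zeroed partial charges and element
# AD types; sufficient for rigid-side-chain grid docking.
write_receptor_pdbqt <- function(conf, path) {
  a <- conf$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00    %6.3f %-2s",
    seq_len(nrow(a)), substr(a$atom_name, 1, 4), substr(a$res_name, 1, 3),
    a$pdb_number, conf$coords[, 1], conf$coords[, 2], conf$coords[, 3],
    0, a$element)
  writeLines(c(lines, "TER"), path)
  invisible(path)
}

# Ligand PDBQT through Open Babel; keeps the torsion tree construction in an
# established tool rather than reimplementing it.
write_ligand_pdbqt <- function(ligand, path) {
  sdf <- tempfile(fileext = ".sdf")
  write_ligand_sdf(ligand, sdf)
  if (Sys.which("obabel") == "")
    stop("obabel not available to prepare ligand PDBQT")
  system2("obabel", c(sdf, "-O", path, "--partialcharge", "gasteiger"),
          stdout = FALSE, stderr = FALSE)
  if (!file.exists(path)) stop("obabel failed to write ", path)
  invisible(path)
}

#' Parse pose coordinate blocks from a multi-model PDBQT file
#'
#' @param lines PDBQT text.
#' @return list of n_atoms x 3 matrices, one per MODEL.
#' @export
parse_pdbqt_poses <- function(lines) {
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0) { starts <- 1; ends <- length(lines) }
  lapply(seq_along(starts), function(k) {
    blk <- lines[starts[k]:ends[k]]
    at <- grep("^(ATOM|HETATM)", blk, value = TRUE)
    matrix(c(as.numeric(substr(at, 31, 38)),
             as.numeric(substr(at, 39, 46)),
             as.numeric(substr(at, 47, 54))), ncol = 3)
  })
}
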