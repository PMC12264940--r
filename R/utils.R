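# Shared small helpers: element masses, geometry primitives, seed derivation.

.ELEMENT_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  B = 10.81, SE = 78.971
)

#' Atomic mass for an element symbol
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of atomic masses (u).
#' @keywords internal
element_mass <- function(element) {
  m <- .ELEMENT_MASSES[toupper(element)]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

# Infer an element symbol from a PDB atom name ("CA" -> C, "OD1" -> O,
# "1HB" -> H). Two-letter elements relevant here: CL, BR, SE.
guess_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  ifelse(two %in% c("CL", "BR", "SE") , two,
         ifelse(one %in% names(.ELEMENT_MASSES), one, nm))
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

# Interior angle (degrees) at vertex b of the triangle a-b-c.
angle_deg <- function(a, b, c) {
  u <- a - b; v <- c - b
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu < 1e-9 || nv < 1e-9) stop("coincident points: angle undefined")
  cosang <- sum(u * v) / (nu * nv)
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# Angle (degrees) between two vectors, in [0, 180].
vec_angle_deg <- function(u, v) {
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# All pairwise Euclidean distances between rows of X (n x 3) and Y (m x 3).
cross_dist <- function(X, Y) {
  X <- matrix(X, ncol = 3); Y <- matrix(Y, ncol = 3)
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  sqrt(pmax(d2, 0))
}

# Mass-weighted center of a coordinate matrix.
center_of_mass <- function(coords, mass) {
  coords <- matrix(coords, ncol = 3)
  if (sum(mass) <= 0) stop("zero total mass")
  colSums(coords * mass) / sum(mass)
}

# Deterministic per-frame seeds derived from one master seed, keyed by frame
# position so serial and parallel schedules agree. Kept below 2^31.
derive_seeds <- function(master_seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

# Uniform random rotation matrix (from QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
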