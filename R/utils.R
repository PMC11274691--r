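# Shared constants and small numerical helpers.

# Atomic masses (Da) of the heavy elements found in protein + GSH-like ligands.
.element_masses <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06)

# Three-letter -> one-letter amino-acid codes.
.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
.aa_letters <- sort(unname(.aa3to1))

# gamma heavy atom defining chi1 (N-CA-CB-X), per residue type.
.chi1_gamma_atom <- c(
  ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG",
  GLU = "CG", HIS = "CG", ILE = "CG1", LEU = "CG", LYS = "CG",
  MET = "CG", PHE = "CG", PRO = "CG", SER = "OG", THR = "OG1",
  TRP = "CG", TYR = "CG", VAL = "CG1"
)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's random state
#' afterwards, so generators are pure functions of their arguments.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

vnorm <- function(v) sqrt(sum(v^2))

# Planar angle at b (degrees), from three points.
point_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu == 0 || nv == 0) stop("coincident points in angle computation")
  deg(acos(max(-1, min(1, sum(u * v) / (nu * nv)))))
}

# Signed dihedral (degrees, IUPAC convention, in (-180, 180]) from four points.
point_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / vnorm(b2)
  x <- sum(n1 * n2)
  y <- -sum(m1 * n2)
  ang <- deg(atan2(y, x))
  if (ang <= -180) ang + 360 else ang
}

# Wrap an angle difference to [0, 180] (circular absolute difference).
wrap_angle_diff <- function(delta) {
  d <- abs(((delta + 180) %% 360) - 180)
  d
}

# Random proper rotation matrix (uses current RNG state).
random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
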