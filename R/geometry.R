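# Conformation comparison: rigid-body superposition and RMSD, per-residue
# Calpha deviation, coarse-grained backbone angles (theta, gamma), chi1
# side-chain distances, radius of gyration and Calpha-only secondary
# structure.

#' Kabsch least-squares superposition
#'
#' Optimal proper rigid transform mapping point set `P` onto `Q`
#' (singular-value decomposition of the cross-covariance, reflection
#' corrected).
#'
#' @param P,Q n x 3 matrices of matched coordinates (n >= 3, non-collinear).
#' @return list with `rotation` (3 x 3, det +1), `translation` (the transform
#'   is `x' = rotation %*% (x - centroid_P) + centroid_Q`; `translation` is the
#'   net shift `centroid_Q - rotation %*% centroid_P`), `rmsd` (Angstrom, after
#'   the transform) and `n_atoms_used`.
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) stop("point sets differ in size")
  if (nrow(P) < 3) stop("need at least 3 matched points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv_p <- svd(Pc)$d
  if (sv_p[2] < 1e-8 * max(sv_p[1], 1))
    stop("matched points are collinear; superposition is degenerate")
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Pr <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Pr - Qc)^2)))
  list(rotation = R, translation = as.numeric(cq - R %*% cp),
       rmsd = rmsd, n_atoms_used = nrow(P))
}

#' @rdname kabsch_superpose
#' @param X coordinates to transform.
#' @param sup a superposition from `kabsch_superpose`.
#' @export
apply_superposition <- function(X, sup) {
  sweep(as.matrix(X) %*% t(sup$rotation), 2, sup$translation, `+`)
}

# Match the Calpha atoms of one chain of each model through the alignment:
# columns that are non-gap in both rows, restricted to residues that actually
# carry a Calpha. Chain residue count must equal the ungapped row length.
matched_calpha <- function(modelA, modelB, aln, idA, idB,
                           chainA = NULL, chainB = NULL) {
  one <- function(model, id, chain) {
    chain <- chain %||% model$residues$chain[1]
    res <- model$residues[model$residues$chain == chain, ]
    nseq <- sum(aln$mat[id, ] != "-")
    if (nrow(res) != nseq)
      stop("chain ", chain, " has ", nrow(res), " residues but alignment row '",
           id, "' has ", nseq, " ungapped positions")
    cols <- map_position(aln, id, seq_len(nrow(res)))
    ca <- calpha_coords(model, chain)
    keep <- res$res_index %in% as.integer(rownames(ca))
    xyz <- matrix(NA_real_, nrow(res), 3)
    xyz[keep, ] <- ca[match(res$res_index[keep], as.integer(rownames(ca))), ]
    list(cols = cols, xyz = xyz)
  }
  a <- one(modelA, idA, chainA); b <- one(modelB, idB, chainB)
  common <- intersect(a$cols, b$cols)
  ia <- match(common, a$cols); ib <- match(common, b$cols)
  ok <- !is.na(a$xyz[ia, 1]) & !is.na(b$xyz[ib, 1])
  list(cols = common[ok], P = a$xyz[ia[ok], , drop = FALSE],
       Q = b$xyz[ib[ok], , drop = FALSE])
}

#' Global Calpha RMSD between two aligned structures
#'
#' Kabsch superposition restricted to the Calpha atoms at alignment columns
#' that are non-gap in both sequences.
#'
#' @param modelA,modelB [structure_model]s.
#' @param aln an [aligned_set] containing both sequences.
#' @param idA,idB alignment row ids of the two structures.
#' @param chainA,chainB chains to compare (default: first chain of each).
#' @return list with `rmsd` (Angstrom), `n_common` (matched Calpha count) and
#'   the `superposition`.
#' @export
rmsd_common_calpha <- function(modelA, modelB, aln, idA, idB,
                               chainA = NULL, chainB = NULL) {
  m <- matched_calpha(modelA, modelB, aln, idA, idB, chainA, chainB)
  if (length(m$cols) < 3) stop("fewer than 3 common aligned Calpha positions")
  sup <- kabsch_superpose(m$P, m$Q)
  list(rmsd = sup$rmsd, n_common = length(m$cols), superposition = sup)
}

#' Per-residue Calpha deviation between two aligned structures
#'
#' Distance between matched Calpha positions after global superposition, one
#' value per doubly-non-gap MSA number.
#'
#' @inheritParams rmsd_common_calpha
#' @param superpose logical; set `FALSE` when the two models are already in a
#'   common global frame.
#' @return named numeric vector (names = MSA numbers) of distances in
#'   Angstrom; gap columns are absent.
#' @export
local_ca_deviation <- function(modelA, modelB, aln, idA, idB,
                               chainA = NULL, chainB = NULL,
                               superpose = TRUE) {
  m <- matched_calpha(modelA, modelB, aln, idA, idB, chainA, chainB)
  if (length(m$cols) < 3) stop("fewer than 3 common aligned Calpha positions")
  Pr <- if (superpose) {
    sup <- kabsch_superpose(m$P, m$Q)
    apply_superposition(m$P, sup)
  } else m$P
  d <- sqrt(rowSums((Pr - m$Q)^2))
  names(d) <- m$cols
  d
}

#' Coarse-grained backbone angles of a Calpha trace
#'
#' The virtual bond angle `theta_n` (at Calpha n, from Calpha n-1, n, n+1;
#' defined for n = 2..N-1) and the virtual torsion `gamma_n` (from Calpha
#' n-1..n+2, IUPAC sign, defined for n = 2..N-2). They are the discrete local
#' curvature and torsion of the backbone; an N-residue chain contributes
#' N-3 complete (theta, gamma) pairs.
#'
#' @param ca n x 3 matrix of consecutive Calpha coordinates (n >= 4).
#' @return list of class `cga` with `theta` (named by residue index, degrees in
#'   (0, 180]), `gamma` (degrees in (-180, 180]) and `n_residues`.
#' @export
coarse_grained_angles <- function(ca) {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  if (n < 4) stop("need at least 4 consecutive Calpha atoms")
  bond <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
  if (any(bond < 1e-6)) stop("coincident consecutive Calpha atoms")
  theta <- vapply(2:(n - 1), function(i)
    point_angle(ca[i - 1, ], ca[i, ], ca[i + 1, ]), numeric(1))
  names(theta) <- 2:(n - 1)
  gamma <- vapply(2:(n - 2), function(i)
    point_dihedral(ca[i - 1, ], ca[i, ], ca[i + 1, ], ca[i + 2, ]), numeric(1))
  names(gamma) <- 2:(n - 2)
  structure(list(theta = theta, gamma = gamma, n_residues = n), class = "cga")
}

#' Circular deviation between two coarse-grained angle sets
#'
#' Per matched residue, the circular absolute differences of theta and gamma
#' (each wrapped to [0, 180] degrees) and a combined unitless score
#' `max(|dtheta|, |dgamma|) / 180` in [0, 1].
#'
#' @param cgaA,cgaB `cga` objects from [coarse_grained_angles()]; matched on
#'   their residue-index names.
#' @return data.frame with `residue`, `dtheta`, `dgamma`, `score`.
#' @export
cga_deviation <- function(cgaA, cgaB) {
  rt <- intersect(names(cgaA$theta), names(cgaB$theta))
  rg <- intersect(names(cgaA$gamma), names(cgaB$gamma))
  res <- sort(as.integer(union(rt, rg)))
  dth <- dg <- rep(NA_real_, length(res))
  names(dth) <- names(dg) <- res
  dth[as.character(intersect(res, as.integer(rt)))] <-
    wrap_angle_diff(cgaA$theta[rt] - cgaB$theta[rt])
  dg[as.character(intersect(res, as.integer(rg)))] <-
    wrap_angle_diff(cgaA$gamma[rg] - cgaB$gamma[rg])
  score <- pmax(dth, dg, na.rm = TRUE) / 180
  data.frame(residue = res, dtheta = unname(dth), dgamma = unname(dg),
             score = unname(score))
}

#' chi1 side-chain dihedrals of one chain
#'
#' First side-chain dihedral N-CA-CB-Xgamma per residue; undefined (`NA`) for
#' Gly and Ala and wherever a defining atom is missing.
#'
#' @param model a [structure_model].
#' @param chain chain id (default: first chain).
#' @return named numeric vector (names = residue index within the chain, i.e.
#'   sequence position) of chi1 in degrees.
#' @export
chi1_profile <- function(model, chain = NULL) {
  chain <- chain %||% model$residues$chain[1]
  res <- model$residues[model$residues$chain == chain, ]
  a <- model$atoms[model$atoms$chain == chain, ]
  out <- rep(NA_real_, nrow(res))
  names(out) <- seq_len(nrow(res))
  for (i in seq_len(nrow(res))) {
    g <- .chi1_gamma_atom[res$resid[i]]
    if (is.na(g)) next
    at <- a[a$res_index == res$res_index[i], ]
    need <- c("N", "CA", "CB", unname(g))
    hit <- match(need, at$elety)
    if (anyNA(hit)) next
    p <- as.matrix(at[hit, c("x", "y", "z")])
    out[i] <- point_dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
  }
  out
}

#' chi1 rotamer distance between two aligned structures
#'
#' `d = (1 - cos(delta chi1)) / 2`: 0 for identical rotamers, 1 for a 180-degree
#' flip. Residues where chi1 is undefined on either side are `NA`, never 0.
#'
#' @inheritParams rmsd_common_calpha
#' @return named numeric vector over doubly-non-gap MSA numbers, values in
#'   [0, 1].
#' @export
chi1_distance <- function(modelA, modelB, aln, idA, idB,
                          chainA = NULL, chainB = NULL) {
  chainA <- chainA %||% modelA$residues$chain[1]
  chainB <- chainB %||% modelB$residues$chain[1]
  chiA <- chi1_profile(modelA, chainA)
  chiB <- chi1_profile(modelB, chainB)
  colsA <- map_position(aln, idA, seq_along(chiA))
  colsB <- map_position(aln, idB, seq_along(chiB))
  common <- intersect(colsA, colsB)
  dA <- chiA[match(common, colsA)]
  dB <- chiB[match(common, colsB)]
  d <- (1 - cos(rad(dA - dB))) / 2
  names(d) <- common
  d
}

#' Mass-weighted radius of gyration
#'
#' RMS distance of the protein heavy atoms from their center of mass.
#'
#' @param model a [structure_model].
#' @return radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(model) {
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  w <- a$mass / sum(a$mass)
  com <- colSums(xyz * w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, com)^2)))
}

#' Calpha-only secondary structure from coarse-grained angles
#'
#' Assigns H (helix), E (strand) or C (coil) per residue from the (theta,
#' gamma) trace alone: helix where theta and gamma fall in the canonical
#' helical box over runs of at least `min_helix` residues, strand where they
#' fall in the extended box over runs of at least `min_strand`. The angular
#' boxes approximate canonical Calpha-trace geometry and are configurable.
#'
#' @param cga a `cga` object from [coarse_grained_angles()].
#' @param helix_theta,helix_gamma,strand_theta,strand_gamma_abs numeric
#'   length-2 inclusive ranges in degrees (`strand_gamma_abs` applies to
#'   `|gamma|`).
#' @param min_helix,min_strand minimum run lengths.
#' @return character vector of per-residue labels, length `cga$n_residues`;
#'   termini without angles are C.
#' @export
assign_secondary_structure <- function(cga,
                                       helix_theta = c(80, 105),
                                       helix_gamma = c(30, 70),
                                       strand_theta = c(100, 155),
                                       strand_gamma_abs = c(140, 180),
                                       min_helix = 4, min_strand = 3) {
  n <- cga$n_residues
  in_box <- function(x, r) !is.na(x) & x >= r[1] & x <= r[2]
  th <- ga <- rep(NA_real_, n)
  th[as.integer(names(cga$theta))] <- cga$theta
  ga[as.integer(names(cga$gamma))] <- cga$gamma
  helix_ok <- in_box(th, helix_theta) & in_box(ga, helix_gamma)
  strand_ok <- in_box(th, strand_theta) & in_box(abs(ga), strand_gamma_abs)
  lab <- rep("C", n)
  mark_runs <- function(ok, min_len, code) {
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths >= min_len))
      lab[starts[k]:ends[k]] <<- code
  }
  mark_runs(strand_ok, min_strand, "E")
  mark_runs(helix_ok, min_helix, "H")
  lab
}
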