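# Parameter-free anisotropic network model (pfANM).
#
# Every protein heavy atom is a node; every node pair is connected by a spring
# whose stiffness decays with distance, Gamma_ij = gamma / Rij^2 (no cutoff:
# this is what makes the model parameter-free). Normal modes come from the
# eigendecomposition of the mass-weighted Hessian,
#     Hhat_ij^{ab} = H_ij^{ab} / sqrt(mi mj),
#     H_ij^{ab} = -(Rij^a Rij^b / Rij^2) Gamma_ij,   H_ii = -sum_{j!=i} H_ij,
# and per-atom thermal B-factors from the 3N-6 internal modes,
#     B_i = (8 pi^2 / 3) (kB T / m_i) sum_k |e_k,i|^2 / omega_k^2.
# With gamma left at its default the absolute scale of B is arbitrary;
# correlations with experimental profiles are scale-invariant, and a
# least-squares calibration of gamma against an experimental profile is
# available.

#' Elastic network of a heavy-atom model
#'
#' @param model a [structure_model], or a list/data.frame with `x`,`y`,`z` and
#'   `mass` columns (then `atoms` is ignored).
#' @param gamma overall spring stiffness scale (arbitrary units, default 1).
#' @param atoms `"heavy"` (all protein heavy atoms) or `"calpha"`.
#' @return An `elastic_network`: list with `xyz` (N x 3), `mass` (Da),
#'   `gamma`, and `res_index` (per node, when built from a model).
#' @export
elastic_network <- function(model, gamma = 1, atoms = c("heavy", "calpha")) {
  atoms <- match.arg(atoms)
  if (inherits(model, "structure_model")) {
    a <- model$atoms
    if (atoms == "calpha") a <- a[a$elety == "CA", ]
    xyz <- as.matrix(a[, c("x", "y", "z")])
    mass <- a$mass
    res_index <- a$res_index
  } else {
    xyz <- as.matrix(model[, c("x", "y", "z")])
    mass <- model$mass %||% rep(12.011, nrow(xyz))
    res_index <- model$res_index %||% seq_len(nrow(xyz))
  }
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  structure(list(xyz = xyz, mass = mass, gamma = gamma,
                 res_index = res_index),
            class = "elastic_network")
}

#' Mass-weighted Hessian of a parameter-free elastic network
#'
#' Assembles the 3N x 3N mass-weighted Hessian with all-pairs springs
#' `Gamma_ij = gamma / Rij^2`. Super-element off-diagonals are
#' `-(R^a R^b / R^2) Gamma_ij`; diagonal super-elements enforce translational
#' invariance; the matrix is then divided element-wise by `sqrt(mi mj)`.
#'
#' @param network an [elastic_network()].
#' @return symmetric 3N x 3N numeric matrix.
#' @export
build_hessian <- function(network) {
  xyz <- network$xyz
  n <- nrow(xyz)
  if (n < 2) stop("need at least 2 nodes")
  dx <- outer(xyz[, 1], xyz[, 1], `-`)
  dy <- outer(xyz[, 2], xyz[, 2], `-`)
  dz <- outer(xyz[, 3], xyz[, 3], `-`)
  r2 <- dx^2 + dy^2 + dz^2
  if (any(r2[upper.tri(r2)] < 1e-12)) stop("coincident nodes in the network")
  diag(r2) <- Inf
  # -(R^a R^b / R^2) * gamma / R^2
  f <- -network$gamma / r2^2
  H <- matrix(0, 3 * n, 3 * n)
  ia <- list(seq(1, 3 * n, 3), seq(2, 3 * n, 3), seq(3, 3 * n, 3))
  dd <- list(dx, dy, dz)
  for (a in 1:3) for (b in 1:3) {
    blk <- f * dd[[a]] * dd[[b]]
    diag(blk) <- 0
    diag(blk) <- -rowSums(blk)
    H[ia[[a]], ia[[b]]] <- blk
  }
  sm <- rep(sqrt(network$mass), each = 3)
  H / tcrossprod(sm)
}

#' Normal modes of a mass-weighted Hessian
#'
#' Full symmetric eigendecomposition; eigenvalues below `tol` times the
#' largest are classified as rigid-body modes. A 3-D non-collinear network has
#' exactly 6 of them (5 for a collinear network, the documented degenerate
#' case); more indicate a disconnected or degenerate network.
#'
#' @param hessian symmetric matrix from [build_hessian()].
#' @param tol relative zero threshold for rigid-body classification.
#' @return A `normal_modes` object: list with `values` (eigenvalues
#'   `omega_k^2`, ascending), `vectors` (orthonormal columns), `rigid`
#'   (indices of rigid-body modes) and `internal` (the remaining mode
#'   indices).
#' @export
normal_modes <- function(hessian, tol = 1e-8) {
  if (max(abs(hessian - t(hessian))) > 1e-9 * max(abs(hessian)))
    stop("hessian is not symmetric")
  e <- eigen((hessian + t(hessian)) / 2, symmetric = TRUE)
  values <- rev(e$values)
  vectors <- e$vectors[, rev(seq_len(ncol(e$vectors))), drop = FALSE]
  rigid <- which(abs(values) < tol * max(abs(values)))
  if (length(rigid) > 6)
    stop("disconnected or degenerate network: ", length(rigid),
         " near-zero modes")
  internal <- setdiff(seq_along(values), rigid)
  if (any(values[internal] <= 0))
    stop("negative internal eigenvalue: input is not a stable network")
  structure(list(values = values, vectors = vectors, rigid = rigid,
                 internal = internal), class = "normal_modes")
}

#' Thermal B-factors from normal modes
#'
#' Per-atom mean-square displacement converted to a crystallographic B-factor:
#' `B_i = (8 pi^2 / 3) (kB T / m_i) sum_k |e_k,i|^2 / omega_k^2`, summed over
#' the internal (non-rigid-body) modes. Absolute values are defined up to the
#' global spring scale gamma unless `calibrate` is supplied.
#'
#' @param modes a `normal_modes` object.
#' @param masses per-node masses (Da).
#' @param T temperature in Kelvin (default 300).
#' @param kB Boltzmann constant in the model's energy units (default 1: B in
#'   arbitrary units up to the gamma scale).
#' @param calibrate optional experimental per-atom (or per-residue, matching
#'   `res_index` aggregation downstream) profile; when given, the returned
#'   profile is rescaled by least squares through the origin onto it.
#' @param res_index optional per-node residue indices; when given, a
#'   per-residue profile (mean over each residue's atoms) is returned in
#'   `residue_b`.
#' @return list with `atom_b` (per node), and `residue_b` (named by residue
#'   index) when `res_index` is given.
#' @export
thermal_bfactors <- function(modes, masses, T = 300, kB = 1,
                             calibrate = NULL, res_index = NULL) {
  idx <- modes$internal
  if (any(modes$values[idx] <= 0)) stop("zero eigenvalue in the internal set")
  v2 <- modes$vectors[, idx, drop = FALSE]^2
  inv_w2 <- 1 / modes$values[idx]
  per_coord <- drop(v2 %*% inv_w2)
  n <- length(per_coord) / 3
  per_atom <- per_coord[seq(1, 3 * n, 3)] + per_coord[seq(2, 3 * n, 3)] +
    per_coord[seq(3, 3 * n, 3)]
  b <- (8 * pi^2 / 3) * (kB * T / masses) * per_atom
  if (!is.null(calibrate)) {
    ok <- is.finite(calibrate)
    scale <- sum(calibrate[ok] * b[ok]) / sum(b[ok]^2)
    b <- b * scale
  }
  out <- list(atom_b = b)
  if (!is.null(res_index)) {
    out$residue_b <- tapply(b, res_index, mean)
    out$residue_b <- stats::setNames(as.numeric(out$residue_b),
                                     names(out$residue_b))
  }
  out
}

#' Fit a parameter-free ANM to a structure
#'
#' Convenience wrapper: builds the all-pairs elastic network, assembles and
#' diagonalizes the mass-weighted Hessian and computes per-atom and
#' per-residue thermal B-factors.
#'
#' @inheritParams elastic_network
#' @param T temperature in Kelvin.
#' @param experimental optional per-residue experimental B profile (named by
#'   residue index) used for least-squares calibration of the overall scale.
#' @return A `pfanm` object: list with the `network`, `modes`, `atom_b`,
#'   `residue_b` (named by residue index) and `residues` (residue table when
#'   fitted to a `structure_model`).
#' @export
pfanm <- function(model, gamma = 1, atoms = c("heavy", "calpha"), T = 300,
                  experimental = NULL) {
  net <- elastic_network(model, gamma = gamma, atoms = atoms)
  modes <- normal_modes(build_hessian(net))
  bf <- thermal_bfactors(modes, net$mass, T = T, res_index = net$res_index)
  if (!is.null(experimental)) {
    exp_atom <- experimental[as.character(net$res_index)]
    ok <- is.finite(exp_atom)
    scale <- sum(exp_atom[ok] * bf$atom_b[ok]) / sum(bf$atom_b[ok]^2)
    bf$atom_b <- bf$atom_b * scale
    bf$residue_b <- bf$residue_b * scale
  }
  structure(list(network = net, modes = modes, atom_b = bf$atom_b,
                 residue_b = bf$residue_b,
                 residues = if (inherits(model, "structure_model"))
                   model$residues else NULL,
                 T = T, gamma = gamma),
            class = "pfanm")
}

#' @export
print.pfanm <- function(x, ...) {
  n <- nrow(x$network$xyz)
  cat("pfanm: all-pairs elastic network,", n, "heavy-atom nodes,",
      length(x$modes$internal), "internal modes (",
      length(x$modes$rigid), "rigid-body )\n")
  cat("  per-residue B-factor range:",
      sprintf("%.3g - %.3g", min(x$residue_b), max(x$residue_b)),
      "(arbitrary units unless calibrated)\n")
  invisible(x)
}

#' @export
summary.pfanm <- function(object, ...) {
  v <- object$modes$values[object$modes$internal]
  out <- list(n_nodes = nrow(object$network$xyz),
              n_internal = length(object$modes$internal),
              n_rigid = length(object$modes$rigid),
              lowest_frequencies = sqrt(utils::head(v, 6)),
              residue_b = summary(object$residue_b))
  class(out) <- "summary.pfanm"
  out
}

#' @export
print.summary.pfanm <- function(x, ...) {
  cat("pfANM with", x$n_nodes, "nodes:", x$n_internal, "internal modes,",
      x$n_rigid, "rigid-body modes\n")
  cat("lowest internal frequencies (sqrt eigenvalue):",
      paste(sprintf("%.4g", x$lowest_frequencies), collapse = ", "), "\n")
  cat("per-residue B-factors:\n")
  print(x$residue_b)
  invisible(x)
}

#' @export
predict.pfanm <- function(object, ...) object$residue_b

#' @export
plot.pfanm <- function(x, ...) {
  ri <- as.integer(names(x$residue_b))
  graphics::plot(ri, x$residue_b, type = "l", xlab = "residue index",
                 ylab = "predicted B-factor", ...)
  invisible(x)
}

#' Pearson correlation between predicted and experimental B-factors
#'
#' Per-residue pairing; residues missing on either side are excluded and their
#' count reported. Undefined when either profile has zero variance.
#'
#' @param predicted named numeric (per-residue predicted B), or a `pfanm`
#'   object.
#' @param experimental named numeric per-residue experimental B.
#' @return list with `rho`, `n_used`, `n_dropped`.
#' @export
bfactor_correlation <- function(predicted, experimental) {
  if (inherits(predicted, "pfanm")) predicted <- predicted$residue_b
  keys <- union(names(predicted), names(experimental))
  p <- predicted[keys]; e <- experimental[keys]
  ok <- is.finite(p) & is.finite(e)
  if (sum(ok) < 3) stop("fewer than 3 residues common to both profiles")
  if (stats::sd(p[ok]) == 0 || stats::sd(e[ok]) == 0) {
    warning("zero variance: correlation undefined")
    return(list(rho = NA_real_, n_used = sum(ok), n_dropped = sum(!ok)))
  }
  list(rho = stats::cor(p[ok], e[ok]), n_used = sum(ok),
       n_dropped = sum(!ok))
}
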