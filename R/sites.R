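# Contact-based site identification: residue contact maps at a heavy-atom
# distance threshold, dimerization-interface (DI) and cofactor binding-site
# (GS) residue sets, single-linkage ligand clustering, and Shrake-Rupley
# solvent accessibility for buried interface areas.

# van der Waals radii (Angstrom) used for solvent accessibility.
default_vdw_radii <- function() c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# All atom index pairs (i < j) closer than `cutoff`, via cell-list binning;
# results are identical to the all-pairs double loop.
neighbor_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), 0, 2))
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  groups <- split(seq_len(n), key)
  coord <- do.call(rbind, strsplit(names(groups), " "))
  coord <- matrix(as.integer(coord), ncol = 3)
  keymap <- seq_along(groups)
  names(keymap) <- names(groups)
  # half-space of 13 forward neighbor offsets + the cell itself
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
               (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] >= 0), , drop = FALSE]
  out <- vector("list", length(groups) * nrow(offs))
  k <- 0L
  c2 <- cutoff^2
  for (g in seq_along(groups)) {
    ia <- groups[[g]]
    for (o in seq_len(nrow(offs))) {
      nb_key <- paste(coord[g, 1] + offs[o, 1], coord[g, 2] + offs[o, 2],
                      coord[g, 3] + offs[o, 3])
      h <- keymap[nb_key]
      if (is.na(h)) next
      ib <- groups[[h]]
      if (g == h) {
        if (length(ia) < 2) next
        pr <- t(utils::combn(ia, 2))
      } else {
        pr <- cbind(rep(ia, each = length(ib)), rep(ib, length(ia)))
      }
      d2 <- rowSums((xyz[pr[, 1], , drop = FALSE] -
                     xyz[pr[, 2], , drop = FALSE])^2)
      pr <- pr[d2 < c2, , drop = FALSE]
      if (nrow(pr)) {
        k <- k + 1L
        out[[k]] <- pr
      }
    }
  }
  if (k == 0L) return(matrix(integer(0), 0, 2))
  pr <- do.call(rbind, out[seq_len(k)])
  cbind(pmin(pr[, 1], pr[, 2]), pmax(pr[, 1], pr[, 2]))
}

#' Residue-residue contact map
#'
#' Two residues are in contact when any heavy atom of one lies within
#' `threshold` of any heavy atom of the other (strictly smaller). Ligand
#' copies can be included as additional "residues" identified by their
#' `lig_id`.
#'
#' @param model a [structure_model].
#' @param threshold heavy-atom distance threshold in Angstrom (default 4.0).
#' @param include_ligands logical; add ligand copies as extra nodes.
#' @return A `residue_contact_map`: list with `pairs` (two-column matrix of
#'   node indices, i < j), `n_atom_pairs` (contacting atom pairs per residue
#'   pair), `nodes` (node table: `node`, `chain`, `resno`, `ins`, `resid`,
#'   `kind` protein/ligand, `lig_id`) and `threshold`.
#' @export
residue_contact_map <- function(model, threshold = 4.0,
                                include_ligands = FALSE) {
  stopifnot(threshold > 0)
  a <- model$atoms
  nodes <- cbind(model$residues, kind = "protein", lig_id = NA_character_)
  node_of_atom <- a$res_index
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (include_ligands && nrow(model$ligands)) {
    l <- model$ligands
    lig_ids <- unique(l$lig_id)
    lig_nodes <- l[!duplicated(l$lig_id), c("chain", "resno", "ins", "resid")]
    lig_nodes <- cbind(res_index = nrow(nodes) + seq_along(lig_ids), lig_nodes,
                       kind = "ligand", lig_id = lig_ids)
    names(lig_nodes)[1] <- "res_index"
    nodes <- rbind(nodes, lig_nodes)
    node_of_atom <- c(node_of_atom, nrow(model$residues) + match(l$lig_id, lig_ids))
    xyz <- rbind(xyz, as.matrix(l[, c("x", "y", "z")]))
  }
  ap <- neighbor_pairs(xyz, threshold)
  ri <- node_of_atom[ap[, 1]]
  rj <- node_of_atom[ap[, 2]]
  keep <- ri != rj
  pi_ <- pmin(ri[keep], rj[keep]); pj <- pmax(ri[keep], rj[keep])
  tab <- table(paste(pi_, pj))
  if (length(tab)) {
    pr <- do.call(rbind, strsplit(names(tab), " "))
    pairs <- matrix(as.integer(pr), ncol = 2)
    o <- order(pairs[, 1], pairs[, 2])
    pairs <- pairs[o, , drop = FALSE]
    counts <- as.integer(tab)[o]
  } else {
    pairs <- matrix(integer(0), 0, 2)
    counts <- integer(0)
  }
  names(nodes)[names(nodes) == "res_index"] <- "node"
  rownames(nodes) <- NULL
  structure(list(pairs = pairs, n_atom_pairs = counts, nodes = nodes,
                 threshold = threshold),
            class = "residue_contact_map")
}

#' @export
print.residue_contact_map <- function(x, ...) {
  cat("residue_contact_map:", nrow(x$nodes), "nodes,", nrow(x$pairs),
      "contacts at <", x$threshold, "A\n")
  invisible(x)
}

#' Dimerization-interface residues of a homodimer
#'
#' Residues of each chain with at least one heavy-atom contact (< `threshold`)
#' to the partner chain. When an alignment row is supplied, residue positions
#' are also reported as MSA numbers.
#'
#' @param model a [structure_model] with exactly two protein chains.
#' @param threshold contact distance in Angstrom.
#' @param aln,row_id optional [aligned_set] and row id for MSA numbering.
#' @param his_positive charge convention flag (see [formal_charge()]).
#' @return An `interface_result`: list with `residues` (data.frame: chain,
#'   resno, resid, seq_pos, msa_number), `n_di` (count per chain), `charge`
#'   (formal charge of the interface residues per chain) and `msa_numbers`
#'   (union over chains, sorted).
#' @export
interface_residues <- function(model, threshold = 4.0, aln = NULL,
                               row_id = NULL, his_positive = FALSE) {
  chains <- model_chains(model)
  if (length(chains) != 2)
    stop("interface analysis needs exactly two protein chains, found ",
         length(chains))
  cm <- residue_contact_map(model, threshold)
  nd <- cm$nodes
  cross <- nd$chain[cm$pairs[, 1]] != nd$chain[cm$pairs[, 2]]
  di_nodes <- sort(unique(as.vector(cm$pairs[cross, , drop = FALSE])))
  res <- nd[nd$node %in% di_nodes, c("chain", "resno", "ins", "resid")]
  seq_pos <- vapply(di_nodes, function(i)
    sum(nd$chain[seq_len(i)] == nd$chain[i]), integer(1))
  res$seq_pos <- seq_pos
  res$msa_number <- if (!is.null(aln) && !is.null(row_id))
    map_position(aln, row_id, res$seq_pos) else rep(NA_integer_, nrow(res))
  rownames(res) <- NULL
  chg <- function(d) formal_charge(paste(.aa3to1[d$resid], collapse = ""),
                                   his_positive)
  structure(list(
    residues = res,
    n_di = vapply(chains, function(ch) sum(res$chain == ch), integer(1)),
    charge = vapply(chains, function(ch) chg(res[res$chain == ch, ]),
                    integer(1)),
    msa_numbers = sort(unique(res$msa_number[!is.na(res$msa_number)])),
    threshold = threshold), class = "interface_result")
}

# Distance between two ligand copies: mean distance between atoms shared by
# name; centroid distance when no atom names are shared.
ligand_pair_distance <- function(la, lb) {
  shared <- intersect(la$elety, lb$elety)
  if (length(shared)) {
    pa <- as.matrix(la[match(shared, la$elety), c("x", "y", "z")])
    pb <- as.matrix(lb[match(shared, lb$elety), c("x", "y", "z")])
    mean(sqrt(rowSums((pa - pb)^2)))
  } else {
    vnorm(colMeans(as.matrix(la[, c("x", "y", "z")])) -
          colMeans(as.matrix(lb[, c("x", "y", "z")])))
  }
}

#' Single-linkage clustering of ligand copies
#'
#' Groups transplanted ligand copies into binding positions: single-linkage
#' clusters cut at `threshold`, so any two clusters are separated by more than
#' `threshold` under the ligand metric (mean distance over atoms shared by
#' name, centroid distance otherwise).
#'
#' @param model a [structure_model] with ligand copies (or a ligand
#'   data.frame in the same layout).
#' @param threshold cluster distance threshold in Angstrom (default 2.0).
#' @return A `ligand_cluster_set`: list with `membership` (named by `lig_id`),
#'   `clusters` (list of `lig_id` vectors), `sizes`, `centroids` (one row per
#'   cluster) and `threshold`.
#' @export
cluster_ligands <- function(model, threshold = 2.0) {
  lig <- if (inherits(model, "structure_model")) model$ligands else model
  if (!nrow(lig)) stop("no ligand copies to cluster")
  ids <- unique(lig$lig_id)
  copies <- lapply(ids, function(id) lig[lig$lig_id == id, ])
  k <- length(ids)
  if (k == 1) {
    membership <- stats::setNames(1L, ids)
  } else {
    d <- matrix(0, k, k)
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
      d[i, j] <- d[j, i] <- ligand_pair_distance(copies[[i]], copies[[j]])
    hc <- stats::hclust(stats::as.dist(d), method = "single")
    membership <- stats::cutree(hc, h = threshold)
    names(membership) <- ids
  }
  nclus <- max(membership)
  clusters <- split(ids, membership)
  centroids <- t(vapply(seq_len(nclus), function(cl) {
    sub <- lig[lig$lig_id %in% clusters[[cl]], ]
    colMeans(as.matrix(sub[, c("x", "y", "z")]))
  }, numeric(3)))
  structure(list(membership = membership, clusters = unname(clusters),
                 sizes = unname(lengths(clusters)), centroids = centroids,
                 threshold = threshold), class = "ligand_cluster_set")
}

#' @export
print.ligand_cluster_set <- function(x, ...) {
  cat("ligand_cluster_set:", length(x$clusters), "cluster(s) of sizes",
      paste(x$sizes, collapse = ", "), "at threshold", x$threshold, "A\n")
  invisible(x)
}

#' Cofactor binding-site residues
#'
#' Union over the cluster's ligand copies of the protein residues with at
#' least one heavy atom within `threshold` of a ligand atom.
#'
#' @param model a [structure_model].
#' @param cluster either a `ligand_cluster_set` plus `which_cluster`, or a
#'   character vector of `lig_id`s.
#' @param which_cluster cluster index when `cluster` is a cluster set.
#' @param threshold contact distance in Angstrom (default 4.0).
#' @inheritParams interface_residues
#' @return A `binding_site_result`: list with `residues` (chain, resno, resid,
#'   seq_pos, msa_number), `n_gs` (count), `charge` and `msa_numbers`.
#' @export
binding_site_residues <- function(model, cluster, which_cluster = 1,
                                  threshold = 4.0, aln = NULL, row_id = NULL,
                                  his_positive = FALSE) {
  lig_ids <- if (inherits(cluster, "ligand_cluster_set"))
    cluster$clusters[[which_cluster]] else as.character(cluster)
  if (!length(lig_ids)) stop("empty ligand cluster")
  lig <- model$ligands[model$ligands$lig_id %in% lig_ids, ]
  if (!nrow(lig)) stop("ligand ids not present in the model")
  a <- model$atoms
  xyz <- rbind(as.matrix(a[, c("x", "y", "z")]),
               as.matrix(lig[, c("x", "y", "z")]))
  np <- nrow(a)
  ap <- neighbor_pairs(xyz, threshold)
  cross <- xor(ap[, 1] <= np, ap[, 2] <= np)
  prot_atoms <- pmin(ap[cross, 1], ap[cross, 2])
  hit <- sort(unique(a$res_index[prot_atoms]))
  if (!length(hit))
    warning("no protein residue within ", threshold, " A of the ligand cluster")
  res <- model$residues[model$residues$res_index %in% hit,
                        c("chain", "resno", "ins", "resid")]
  res$seq_pos <- vapply(hit, function(i) {
    r <- model$residues
    sum(r$chain[seq_len(match(i, r$res_index))] == r$chain[match(i, r$res_index)])
  }, integer(1))
  res$msa_number <- if (!is.null(aln) && !is.null(row_id))
    map_position(aln, row_id, res$seq_pos) else rep(NA_integer_, nrow(res))
  rownames(res) <- NULL
  structure(list(
    residues = res, n_gs = nrow(res),
    charge = formal_charge(paste(.aa3to1[res$resid], collapse = ""),
                           his_positive),
    msa_numbers = sort(unique(res$msa_number[!is.na(res$msa_number)])),
    threshold = threshold), class = "binding_site_result")
}

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by point sampling: `n_points` quasi-uniform points on each
#' atom's solvent-expanded sphere (vdW radius + probe), counting the fraction
#' not buried inside any neighbour's expanded sphere.
#'
#' @param model a [structure_model] (protein atoms only are used), or an atom
#'   data.frame with x, y, z, element columns.
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sampling points per atom (default 960).
#' @param radii named vdW radii per element.
#' @param chains optional chain subset.
#' @return numeric vector of per-atom areas in Angstrom^2.
#' @export
shrake_rupley_sasa <- function(model, probe = 1.4, n_points = 960,
                               radii = default_vdw_radii(), chains = NULL) {
  a <- if (inherits(model, "structure_model")) model$atoms else model
  if (!is.null(chains)) a <- a[a$chain %in% chains, ]
  n <- nrow(a)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  r <- unname(radii[a$element]) + probe
  if (anyNA(r)) stop("missing vdW radius for element(s): ",
                     paste(unique(a$element[is.na(r)]), collapse = ", "))
  pts <- sphere_points(n_points)
  nb <- neighbor_pairs(xyz, 2 * (max(r)))
  nb_list <- vector("list", n)
  if (nrow(nb)) {
    nb_all <- rbind(nb, nb[, 2:1])
    # keep only genuinely overlapping expanded spheres
    d <- sqrt(rowSums((xyz[nb_all[, 1], , drop = FALSE] -
                       xyz[nb_all[, 2], , drop = FALSE])^2))
    nb_all <- nb_all[d < r[nb_all[, 1]] + r[nb_all[, 2]], , drop = FALSE]
    nb_list <- split(nb_all[, 2], factor(nb_all[, 1], levels = seq_len(n)))
  }
  area <- numeric(n)
  for (i in seq_len(n)) {
    surf <- sweep(pts * r[i], 2, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in nb_list[[i]]) {
      if (!any(free)) break
      d2 <- rowSums(sweep(surf[free, , drop = FALSE], 2, xyz[j, ])^2)
      free[free] <- d2 >= r[j]^2
    }
    area[i] <- 4 * pi * r[i]^2 * sum(free) / n_points
  }
  area
}

#' Buried interface area of a dimer
#'
#' Half the solvent-accessible surface area lost upon dimer formation:
#' `(SASA(A) + SASA(B) - SASA(AB)) / 2`.
#'
#' @param model a [structure_model] with exactly two protein chains.
#' @inheritParams shrake_rupley_sasa
#' @return buried area in Angstrom^2 (non-negative up to sampling error).
#' @export
buried_interface_area <- function(model, probe = 1.4, n_points = 960,
                                  radii = default_vdw_radii()) {
  chains <- model_chains(model)
  if (length(chains) != 2)
    stop("buried interface area needs exactly two protein chains")
  s_ab <- sum(shrake_rupley_sasa(model, probe, n_points, radii))
  s_a <- sum(shrake_rupley_sasa(model, probe, n_points, radii, chains = chains[1]))
  s_b <- sum(shrake_rupley_sasa(model, probe, n_points, radii, chains = chains[2]))
  (s_a + s_b - s_ab) / 2
}
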