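# Inter-site communication pathways: residue-interaction graph of a homodimer
# with one cofactor bound (holo monomer A, apo monomer B), and enumeration of
# all minimum-length paths between the two binding sites.

#' Residue-interaction graph for pathway analysis
#'
#' Nodes are the residues of both chains plus one ligand node for the bound
#' (holo) cofactor cluster of monomer A; edges connect residues in heavy-atom
#' contact (< `threshold`) and the ligand node to the residues it touches.
#' The source set is the residues contacting the bound ligand; the target set
#' is the apo binding site of monomer B, identified from its own ligand
#' cluster before that cluster is removed.
#'
#' @param model a [structure_model] with two protein chains and ligand copies.
#' @param holo_cluster,apo_cluster `lig_id` vectors (or a
#'   `ligand_cluster_set` index pair via `clusters`) for the bound and the
#'   removed cofactor cluster.
#' @param clusters optionally a [cluster_ligands()] result; then
#'   `holo_cluster`/`apo_cluster` are cluster indices.
#' @param threshold contact distance in Angstrom.
#' @return A `residue_graph`: list with `graph` (igraph, undirected, unit
#'   weights), `sources`, `targets` (node name vectors), and `nodes` (node
#'   table with chain/resno/resid/seq_pos).
#' @export
build_residue_graph <- function(model, holo_cluster, apo_cluster,
                                clusters = NULL, threshold = 4.0) {
  if (!is.null(clusters)) {
    holo_cluster <- clusters$clusters[[holo_cluster]]
    apo_cluster <- clusters$clusters[[apo_cluster]]
  }
  if (!length(holo_cluster)) stop("no source set: empty holo ligand cluster")
  gs_a <- binding_site_residues(model, holo_cluster, threshold = threshold)
  gs_b <- binding_site_residues(model, apo_cluster, threshold = threshold)
  if (!nrow(gs_a$residues)) stop("no source set: bound ligand touches no residue")
  cm <- residue_contact_map(model, threshold)
  nd <- cm$nodes
  node_name <- paste0(nd$chain, nd$resno, ifelse(nd$ins == "", "", nd$ins))
  seq_pos <- ave(seq_len(nrow(nd)), nd$chain, FUN = seq_along)
  edges <- cbind(node_name[cm$pairs[, 1]], node_name[cm$pairs[, 2]])
  lig_edges <- cbind("LIG", name_of(gs_a$residues))
  g <- igraph::graph_from_edgelist(rbind(edges, lig_edges), directed = FALSE)
  g <- igraph::add_vertices(g, sum(!(node_name %in% igraph::V(g)$name)),
                            name = node_name[!(node_name %in% igraph::V(g)$name)])
  nodes <- cbind(nd[, c("chain", "resno", "ins", "resid")],
                 name = node_name, seq_pos = seq_pos)
  structure(list(graph = g,
                 sources = name_of(gs_a$residues),
                 targets = name_of(gs_b$residues),
                 nodes = nodes),
            class = "residue_graph")
}

name_of <- function(res) paste0(res$chain, res$resno,
                                ifelse(res$ins == "", "", res$ins))

#' Enumerate all minimum-length paths between two residue sets
#'
#' Unit edge weights, so path "length" is the residue count of the path. All
#' paths achieving the global minimum length from any source to any target are
#' enumerated (via the shortest-path predecessor structure); a source that is
#' itself a target yields a length-1 path.
#'
#' @param rg a `residue_graph`, or an igraph (then give `sources`/`targets`).
#' @param sources,targets node name vectors (defaults taken from `rg`).
#' @param weighted logical; use inter-residue distance weights stored in the
#'   `weight` edge attribute instead of unit weights.
#' @return A `pathway_result`: list with `paths` (list of node-name vectors),
#'   `length` (number of residues in each minimal path; `NA` when no path
#'   exists), `reachable`, and `visits` (named per-node visit counts over all
#'   minimal paths, ligand node excluded).
#' @export
shortest_site_paths <- function(rg, sources = NULL, targets = NULL,
                                weighted = FALSE) {
  g <- if (inherits(rg, "residue_graph")) rg$graph else rg
  sources <- sources %||% rg$sources
  targets <- targets %||% rg$targets
  if (!length(sources) || !length(targets))
    stop("empty source or target set")
  sources <- intersect(sources, igraph::V(g)$name)
  targets <- intersect(targets, igraph::V(g)$name)
  w <- if (weighted) igraph::E(g)$weight else rep(1, igraph::ecount(g))
  common <- intersect(sources, targets)
  if (length(common)) {
    paths <- as.list(common)
    return(finish_pathways(paths, 1))
  }
  dmat <- igraph::distances(g, v = sources, to = targets, weights = w)
  if (!is.finite(min(dmat))) {
    return(structure(list(paths = list(), length = NA_real_,
                          reachable = FALSE, visits = numeric(0)),
                     class = "pathway_result"))
  }
  best <- min(dmat)
  paths <- list()
  for (s in sources[apply(dmat, 1, min) == best]) {
    to <- targets[dmat[s, ] == best]
    asp <- igraph::all_shortest_paths(g, from = s, to = to, weights = w)
    for (p in asp$vpaths)
      paths[[length(paths) + 1L]] <- igraph::V(g)$name[as.integer(p)]
  }
  # de-duplicate (a path can be found from several sources only if identical
  # endpoints; protect anyway)
  paths <- unique(paths)
  finish_pathways(paths, best + 1)
}

finish_pathways <- function(paths, nresidues) {
  visits <- table(unlist(paths))
  visits <- visits[names(visits) != "LIG"]
  structure(list(paths = paths, length = nresidues, reachable = TRUE,
                 visits = stats::setNames(as.numeric(visits), names(visits))),
            class = "pathway_result")
}

#' @export
print.pathway_result <- function(x, ...) {
  if (!x$reachable) cat("pathway_result: target unreachable\n")
  else cat("pathway_result:", length(x$paths), "minimal path(s) of",
           x$length, "residues\n")
  invisible(x)
}

#' Aggregate pathway statistics over a structure set
#'
#' Per-MSA-number visit counts (N_path), per-structure mean path length and
#' the most visited MSA number(s).
#'
#' @param results named list of `pathway_result`s (one per structure).
#' @param graphs matching list of `residue_graph`s (for node -> sequence
#'   position lookup).
#' @param aln an [aligned_set]; `row_ids` names one alignment row per
#'   structure.
#' @param row_ids character vector of alignment ids, parallel to `results`.
#' @return list with `n_path` (named numeric over MSA numbers: number of
#'   structures whose minimal pathways visit that column), `mean_length`
#'   (per structure), and `most_visited` (MSA number(s) with maximal N_path;
#'   ties reported as a set).
#' @export
pathway_stats <- function(results, graphs, aln, row_ids) {
  n_path <- numeric(aln$ncols)
  mean_length <- stats::setNames(numeric(length(results)),
                                 names(results) %||% row_ids)
  for (k in seq_along(results)) {
    pr <- results[[k]]
    mean_length[k] <- pr$length
    if (!pr$reachable || !length(pr$visits)) next
    nodes <- graphs[[k]]$nodes
    pos <- nodes$seq_pos[match(names(pr$visits), nodes$name)]
    cols <- map_position(aln, row_ids[k], pos)
    n_path[unique(cols)] <- n_path[unique(cols)] + 1
  }
  mx <- max(n_path)
  list(n_path = n_path, mean_length = mean_length,
       most_visited = if (mx > 0) which(n_path == mx) else integer(0))
}
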