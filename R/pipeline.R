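# Orchestration: run the whole analysis over a set of homodimer structures
# sharing one alignment, and aggregate every per-residue quantity onto MSA
# numbers.

#' Analysis configuration
#'
#' All tunables of the pipeline in one place.
#'
#' @param contact_threshold heavy-atom contact distance, Angstrom.
#' @param ligand_threshold single-linkage ligand cluster cut, Angstrom.
#' @param probe SASA probe radius, Angstrom.
#' @param sasa_points SASA sampling points per atom.
#' @param his_positive charge convention: count His as +1.
#' @param gamma,T ANM spring scale and temperature (K).
#' @param anm_atoms `"heavy"` or `"calpha"` ANM nodes.
#' @param path_weighted distance-weighted pathway lengths instead of residue
#'   counts.
#' @param compute_sasa logical; buried interface areas are comparatively slow.
#' @param seed integer seed recorded in the report.
#' @return a `gstome_config` list.
#' @export
gstome_config <- function(contact_threshold = 4.0, ligand_threshold = 2.0,
                          probe = 1.4, sasa_points = 960,
                          his_positive = FALSE, gamma = 1, T = 300,
                          anm_atoms = "heavy", path_weighted = FALSE,
                          compute_sasa = FALSE, seed = 1) {
  stopifnot(contact_threshold > 0, ligand_threshold > 0, probe > 0)
  structure(list(contact_threshold = contact_threshold,
                 ligand_threshold = ligand_threshold, probe = probe,
                 sasa_points = sasa_points, his_positive = his_positive,
                 gamma = gamma, T = T, anm_atoms = anm_atoms,
                 path_weighted = path_weighted, compute_sasa = compute_sasa,
                 seed = seed), class = "gstome_config")
}

#' Scatter homodimer per-residue values onto MSA numbers
#'
#' Averages the two monomers' values position-wise (a homodimer yields one
#' profile per sequence), then maps sequence positions to alignment columns.
#'
#' @param values_by_chain list of one or two numeric vectors (one value per
#'   residue of each chain, in chain order).
#' @param aln an [aligned_set].
#' @param row_id alignment row of this structure.
#' @param average logical; set `FALSE` to keep chains separate (rows of a
#'   matrix).
#' @return numeric vector over MSA numbers (`NA` at this row's gap columns),
#'   or a 2-row matrix when `average = FALSE`.
#' @export
monomer_to_msa_profile <- function(values_by_chain, aln, row_id,
                                   average = TRUE) {
  if (is.numeric(values_by_chain)) values_by_chain <- list(values_by_chain)
  nseq <- sum(aln$mat[row_id, ] != "-")
  for (v in values_by_chain)
    if (length(v) != nseq)
      stop("chain has ", length(v), " values but alignment row '", row_id,
           "' has ", nseq, " ungapped positions")
  cols <- map_position(aln, row_id, seq_len(nseq))
  out <- matrix(NA_real_, length(values_by_chain), aln$ncols)
  for (k in seq_along(values_by_chain)) out[k, cols] <- values_by_chain[[k]]
  if (average) colMeans(out) else out
}

#' Per-structure correlation with the family-average profile
#'
#' Pearson correlation, per structure, between its per-MSA-number profile and
#' the across-structure mean profile, over the columns where both are defined.
#'
#' @param profile_matrix structures x MSA-numbers matrix (NA at gaps).
#' @param mean_profile optional precomputed mean; default: column means over
#'   the matrix.
#' @return named numeric vector of correlations (NA where undefined).
#' @export
profile_correlation <- function(profile_matrix, mean_profile = NULL) {
  mean_profile <- mean_profile %||% colMeans(profile_matrix, na.rm = TRUE)
  apply(profile_matrix, 1, function(p) {
    ok <- is.finite(p) & is.finite(mean_profile)
    if (sum(ok) < 3 || stats::sd(p[ok]) == 0 || stats::sd(mean_profile[ok]) == 0)
      return(NA_real_)
    stats::cor(p[ok], mean_profile[ok])
  })
}

#' Run the full family analysis
#'
#' For every structure: secondary structure, radius of gyration, interface
#' (DI) residues, ligand clusters and binding-site (GS) residues,
#' inter-site communication pathways, and pfANM B-factors; everything is
#' aggregated per MSA number across the set (occupancies N_DI / N_GS /
#' N_path, mean and SD B-factor, amino-acid occurrence), alongside the
#' pairwise identity and RMSD matrices and per-structure correlations with
#' the family-average flexibility profile.
#'
#' @param structures named list of [structure_model]s, or a directory of
#'   `.pdb` files (file base names must match alignment ids).
#' @param alignment an [aligned_set] or a path to an aligned FASTA file.
#' @param config a [gstome_config()].
#' @param out_dir optional directory; when given, TSV tables and a JSON
#'   manifest are written there.
#' @return a `gstome_report`: list with `per_structure` (per-id results),
#'   `profile` (data.frame per MSA number: occurrence, gap count, N_DI, N_GS,
#'   N_path, mean_b, sd_b), `b_matrix`, `rmsd_matrix`, `identity_matrix`,
#'   `profile_rho`, `errors` and `config`.
#' @export
run_gstome <- function(structures, alignment, config = gstome_config(),
                       out_dir = NULL) {
  if (is.character(structures)) {
    files <- list.files(structures, pattern = "\\.pdb$", full.names = TRUE)
    ids <- sub("\\.pdb$", "", basename(files))
    structures <- stats::setNames(lapply(files, read_structure), ids)
  }
  aln <- if (inherits(alignment, "aligned_set")) alignment
         else read_alignment(alignment)
  ids <- names(structures)
  missing <- setdiff(ids, aln$ids)
  if (length(missing))
    stop("structures with no alignment row: ", paste(missing, collapse = ", "))

  ncol_ <- aln$ncols
  n_di <- n_gs <- n_path <- numeric(ncol_)
  b_matrix <- matrix(NA_real_, length(ids), ncol_, dimnames = list(ids, NULL))
  per_structure <- list()
  errors <- list()

  for (id in ids) {
    res <- tryCatch({
      model <- structures[[id]]
      chains <- model_chains(model)
      if (length(chains) != 2)
        stop("expected a homodimer with two chains, found ", length(chains))
      ss <- lapply(chains, function(ch) {
        ca <- calpha_coords(model, ch)
        assign_secondary_structure(coarse_grained_angles(ca))
      })
      rg <- radius_of_gyration(model)
      di <- interface_residues(model, config$contact_threshold, aln, id,
                               config$his_positive)
      clus <- if (nrow(model$ligands))
        cluster_ligands(model, config$ligand_threshold) else NULL
      gs <- path_res <- rgph <- NULL
      if (!is.null(clus) && length(clus$clusters) >= 2) {
        chain_of <- vapply(clus$clusters, function(cl)
          model$ligands$chain[match(cl[1], model$ligands$lig_id)],
          character(1))
        holo <- which(chain_of == chains[1])[1]
        apo <- which(chain_of == chains[2])[1]
        gs <- binding_site_residues(model, clus, holo,
                                    config$contact_threshold, aln, id,
                                    config$his_positive)
        rgph <- build_residue_graph(model, holo, apo, clusters = clus,
                                    threshold = config$contact_threshold)
        path_res <- shortest_site_paths(rgph,
                                        weighted = config$path_weighted)
      } else if (!is.null(clus)) {
        gs <- binding_site_residues(model, clus, 1, config$contact_threshold,
                                    aln, id, config$his_positive)
      }
      fit <- pfanm(model, gamma = config$gamma, atoms = config$anm_atoms,
                   T = config$T)
      b_by_chain <- lapply(chains, function(ch) {
        ri <- model$residues$res_index[model$residues$chain == ch]
        unname(fit$residue_b[as.character(ri)])
      })
      b_profile <- monomer_to_msa_profile(b_by_chain, aln, id)
      bia <- if (config$compute_sasa)
        buried_interface_area(model, config$probe, config$sasa_points)
      else NA_real_
      list(id = id, ss = ss, rg = rg, di = di, clusters = clus, gs = gs,
           graph = rgph, pathways = path_res, anm = fit,
           b_profile = b_profile, buried_area = bia)
    }, error = function(e) structure(conditionMessage(e), class = "try-error"))
    if (inherits(res, "try-error")) {
      errors[[id]] <- as.character(res)
      next
    }
    per_structure[[id]] <- res
    n_di[res$di$msa_numbers] <- n_di[res$di$msa_numbers] + 1
    if (!is.null(res$gs))
      n_gs[res$gs$msa_numbers] <- n_gs[res$gs$msa_numbers] + 1
    if (!is.null(res$pathways) && res$pathways$reachable) {
      nodes <- res$graph$nodes
      pos <- nodes$seq_pos[match(names(res$pathways$visits), nodes$name)]
      cols <- unique(map_position(aln, id, pos))
      n_path[cols] <- n_path[cols] + 1
    }
    b_matrix[id, ] <- res$b_profile
  }

  ok_ids <- names(per_structure)
  occurrence <- colSums(aln$mat[ok_ids, , drop = FALSE] != "-")
  gaps <- length(ok_ids) - occurrence
  profile <- data.frame(msa_number = seq_len(ncol_),
                        occurrence = occurrence, gaps = gaps,
                        n_di = n_di, n_gs = n_gs, n_path = n_path,
                        mean_b = colMeans(b_matrix[ok_ids, , drop = FALSE],
                                          na.rm = TRUE),
                        sd_b = apply(b_matrix[ok_ids, , drop = FALSE], 2,
                                     stats::sd, na.rm = TRUE))
  rmsd_matrix <- matrix(NA_real_, length(ok_ids), length(ok_ids),
                        dimnames = list(ok_ids, ok_ids))
  diag(rmsd_matrix) <- 0
  if (length(ok_ids) > 1) {
    for (i in seq_len(length(ok_ids) - 1)) for (j in seq(i + 1, length(ok_ids))) {
      a <- ok_ids[i]; b <- ok_ids[j]
      r <- tryCatch(rmsd_common_calpha(structures[[a]], structures[[b]],
                                       aln, a, b)$rmsd,
                    error = function(e) NA_real_)
      rmsd_matrix[a, b] <- rmsd_matrix[b, a] <- r
    }
  }
  idm <- identity_matrix(aln)
  rho <- profile_correlation(b_matrix[ok_ids, , drop = FALSE])
  report <- structure(list(per_structure = per_structure, profile = profile,
                           b_matrix = b_matrix, rmsd_matrix = rmsd_matrix,
                           identity_matrix = idm, profile_rho = rho,
                           errors = errors, config = config),
                      class = "gstome_report")
  if (!is.null(out_dir)) write_gstome_report(report, out_dir)
  report
}

#' @export
print.gstome_report <- function(x, ...) {
  cat("gstome_report:", length(x$per_structure), "structures analyzed")
  if (length(x$errors)) cat(",", length(x$errors), "failed")
  cat("\n  alignment columns:", nrow(x$profile), "\n")
  mv <- which(x$profile$n_path == max(x$profile$n_path))
  if (max(x$profile$n_path) > 0)
    cat("  most visited pathway column(s):", paste(mv, collapse = ", "), "\n")
  invisible(x)
}

#' Write the report bundle as TSV tables plus a JSON manifest
#'
#' @param report a `gstome_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_gstome_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) utils::write.table(d, file.path(out_dir, f), sep = "\t",
                                         quote = FALSE, row.names = FALSE)
  w(report$profile, "profile.tsv")
  wm <- function(m, f) utils::write.table(cbind(id = rownames(m), round(m, 4)),
                                          file.path(out_dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wm(report$rmsd_matrix, "rmsd_matrix.tsv")
  wm(report$identity_matrix, "identity_matrix.tsv")
  per <- data.frame(
    id = names(report$per_structure),
    rg = vapply(report$per_structure, function(s) s$rg, numeric(1)),
    n_di = vapply(report$per_structure, function(s) sum(s$di$n_di), numeric(1)),
    n_gs = vapply(report$per_structure, function(s)
      if (is.null(s$gs)) NA_real_ else s$gs$n_gs, numeric(1)),
    path_length = vapply(report$per_structure, function(s)
      if (is.null(s$pathways)) NA_real_ else s$pathways$length, numeric(1)),
    buried_area = vapply(report$per_structure, function(s) s$buried_area,
                         numeric(1)),
    profile_rho = report$profile_rho[names(report$per_structure)])
  w(per, "per_structure.tsv")
  manifest <- list(config = unclass(report$config),
                   n_structures = length(report$per_structure),
                   errors = report$errors)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
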