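# Deterministic seeded generators for every fixture the tests need. They
# emulate the geometric/statistical shape of the study inputs (predicted
# homodimers with a planned interface, transplanted ligand ensembles,
# alignments with controlled conservation), not protein energetics. Each
# generator returns the object plus a `ledger` holding the planted ground
# truth, and is a pure function of its arguments and seed.

# Assemble a structure_model from a residue-level specification.
build_model <- function(chain, resno, resid, elety, xyz, b = NULL,
                        ligands = NULL) {
  element <- infer_element(elety)
  atoms <- data.frame(chain = chain, resno = resno, ins = "", resid = resid,
                      elety = elety, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      occ = 1, b = b %||% rep(0, length(chain)),
                      element = element,
                      mass = unname(.element_masses[element]),
                      stringsAsFactors = FALSE)
  rkey <- paste(atoms$chain, atoms$resno, atoms$ins, sep = "\r")
  atoms$res_index <- match(rkey, unique(rkey))
  residues <- atoms[!duplicated(atoms$res_index),
                    c("res_index", "chain", "resno", "ins", "resid")]
  rownames(residues) <- NULL
  if (is.null(ligands)) {
    ligands <- atoms[0, ]
    ligands$lig_id <- character(0)
    ligands$res_index <- NULL
  }
  structure(list(atoms = atoms, ligands = ligands, residues = residues),
            class = "structure_model")
}

build_ligand_table <- function(chain, resno, resid, elety, xyz, b = 0) {
  element <- infer_element(elety)
  out <- data.frame(chain = chain, resno = resno, ins = "", resid = resid,
                    elety = elety, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    occ = 1, b = b, element = element,
                    mass = unname(.element_masses[element]),
                    stringsAsFactors = FALSE)
  out$lig_id <- paste(out$chain, out$resno, out$ins, out$resid, sep = ":")
  out
}

#' Ideal single-chain Calpha traces
#'
#' Helix: canonical Calpha helix (rise 1.5 A per residue, 100 degrees per
#' residue, radius 2.3 A). Strand: extended zigzag trace. Coil: bounded
#' self-avoiding random walk with 3.8 A steps never placing consecutive
#' Calpha closer than 3 A. Each residue is an Ala with a stub Cbeta.
#'
#' @param kind `"helix"`, `"strand"` or `"coil"`.
#' @param n number of residues (>= 5).
#' @param seed integer seed (used by the coil walk).
#' @param plddt optional per-residue confidence plan written to the B column
#'   (recycled); default 90.
#' @return list with `model` (a [structure_model]) and `ledger` (seed, planned
#'   atom count, planned confidence).
#' @export
make_ideal_chain <- function(kind = c("helix", "strand", "coil"), n, seed = 1,
                             plddt = 90) {
  kind <- match.arg(kind)
  if (n < 5) stop("n must be at least 5")
  ca <- with_seed(seed, switch(kind,
    helix = {
      i <- seq_len(n)
      cbind(2.3 * cos(rad(100) * i), 2.3 * sin(rad(100) * i), 1.5 * i)
    },
    strand = {
      i <- seq_len(n)
      cbind(3.3 * i, 0.8 * (-1)^i, 0)
    },
    coil = {
      pts <- matrix(0, n, 3)
      for (i in 2:n) {
        repeat {
          step <- stats::rnorm(3)
          cand <- pts[i - 1, ] + 3.8 * step / vnorm(step)
          d <- sqrt(rowSums(sweep(pts[seq_len(i - 1), , drop = FALSE], 2,
                                  cand)^2))
          if (all(d >= 3.0) && all(abs(cand) < 50)) break
        }
        pts[i, ] <- cand
      }
      pts
    }))
  # stub side chains: Cbeta offset perpendicular-ish to the trace
  cb <- ca + 1.5 * t(vapply(seq_len(n), function(i) {
    ref <- if (i < n) ca[i + 1, ] - ca[i, ] else ca[i, ] - ca[i - 1, ]
    v <- c(ref[2], -ref[1], 0.5)
    v / vnorm(v)
  }, numeric(3)))
  xyz <- cbind(as.vector(rbind(ca[, 1], cb[, 1])),
               as.vector(rbind(ca[, 2], cb[, 2])),
               as.vector(rbind(ca[, 3], cb[, 3])))
  plddt_plan <- rep_len(plddt, n)
  model <- build_model(chain = rep("A", 2 * n),
                       resno = rep(seq_len(n), each = 2),
                       resid = rep("ALA", 2 * n),
                       elety = rep(c("CA", "CB"), n),
                       xyz = xyz,
                       b = rep(plddt_plan, each = 2))
  list(model = model,
       ledger = list(seed = seed, kind = kind, n_residues = n,
                     n_atoms = 2 * n, plddt = plddt_plan))
}

#' Toy homodimer with a planned interface, pockets and corridor
#'
#' Two single-atom-per-residue chains related by a two-fold axis along x.
#' Exactly `interface_size` central residues per chain sit within 4 A of their
#' mirror partner (all other inter-chain distances exceed the threshold), so
#' the interface, the contact corridor between the two pockets and the
#' minimal pathway length are all known by construction. Ligand copies are
#' jittered by less than 0.5 A around each pocket centroid so they form one
#' single-linkage cluster per pocket at the 2.0 A threshold.
#'
#' @param n_per_chain residues per chain.
#' @param interface_size number of interface residues per chain
#'   (< `n_per_chain`).
#' @param ligand_copies_per_pocket ligand copies per pocket (2 pockets).
#' @param seed integer seed for the jitter.
#' @param pocket_residue sequence position of the residue each pocket centroid
#'   sits next to (default 2).
#' @return list with `model` and `ledger` (interface residues per chain,
#'   pocket residue sets, ligand cluster assignment, designed minimal pathway
#'   length in residues, atom counts).
#' @export
make_toy_dimer <- function(n_per_chain = 12, interface_size = 4,
                           ligand_copies_per_pocket = 9, seed = 1,
                           pocket_residue = 2) {
  if (interface_size >= n_per_chain)
    stop("interface_size must be smaller than n_per_chain")
  n <- n_per_chain
  i0 <- floor((n - interface_size) / 2) + 1
  iface <- seq(i0, i0 + interface_size - 1)
  if (pocket_residue %in% iface || pocket_residue > n)
    stop("infeasible geometry: pocket residue inside the interface block")
  # distance of each chain to the two-fold axis: 1.75 A at the interface
  # block (partner distance 3.5 < 4), ramped by 1 A per residue away from it
  # (so consecutive residues stay in heavy-atom contact: sqrt(3.8^2+1) < 4)
  # and capped at 3.75 A (partner distance 7.5 > 4 everywhere else)
  dist_to_block <- vapply(seq_len(n), function(i) min(abs(i - iface)),
                          numeric(1))
  dy <- pmin(1.75 + dist_to_block, 3.75)
  # small z zigzag keeps the structure non-planar (a coplanar all-pairs
  # elastic network is degenerate) without changing any planned contact
  zz <- 0.3 * (-1)^seq_len(n)
  xa <- cbind(3.8 * seq_len(n), dy, zz)
  xb <- cbind(3.8 * seq_len(n), -dy, zz)         # two-fold axis along x
  # pockets: 3.5 A outward of the pocket residue, so only that residue is
  # within the 4.0 A contact threshold of the ligand copies
  pocket_a <- xa[pocket_residue, ] + c(0, 3.5, 0)
  pocket_b <- xb[pocket_residue, ] + c(0, -3.5, 0)
  lig_atoms <- c("N1", "C2", "O3")
  lig_off <- rbind(c(0.4, 0, 0), c(-0.4, 0, 0), c(0, 0.4, 0))
  mk_pocket <- function(center, chain) {
    do.call(rbind, lapply(seq_len(ligand_copies_per_pocket), function(k) {
      jit <- matrix(stats::runif(9, -0.25, 0.25), 3, 3)
      build_ligand_table(chain = rep(chain, 3), resno = rep(200 + k, 3),
                         resid = rep("GSH", 3), elety = lig_atoms,
                         xyz = sweep(lig_off + jit, 2, center, `+`))
    }))
  }
  ligands <- with_seed(seed, rbind(mk_pocket(pocket_a, "A"),
                                   mk_pocket(pocket_b, "B")))
  model <- build_model(chain = rep(c("A", "B"), each = n),
                       resno = rep(seq_len(n), 2),
                       resid = rep("GLY", 2 * n),
                       elety = rep("CA", 2 * n),
                       xyz = rbind(xa, xb),
                       b = rep(85, 2 * n),
                       ligands = ligands)
  # designed minimal pathway: pocket residue -> nearest interface residue on
  # chain A -> its mirror on B -> back to the pocket residue of B
  cross_at <- iface[which.min(abs(iface - pocket_residue))]
  path_len <- 2 * abs(pocket_residue - cross_at) + 2
  list(model = model,
       ledger = list(seed = seed, n_per_chain = n,
                     interface_residues = iface,
                     interface_size = interface_size,
                     pocket_residue = pocket_residue,
                     ligand_copies_per_pocket = ligand_copies_per_pocket,
                     n_clusters = 2,
                     n_protein_atoms = 2 * n,
                     n_ligand_atoms = 2 * 3 * ligand_copies_per_pocket,
                     corridor_length = path_len))
}

#' Synthetic alignment with planted conservation, gaps and charges
#'
#' Random alignment in which exactly `invariant_columns` are 100% conserved,
#' the requested gap blocks are placed, and (optionally) each row's formal
#' charge under the default convention equals `charge_plan`.
#'
#' @param n_rows number of sequences (default 36).
#' @param length alignment length (columns).
#' @param invariant_columns MSA numbers planted as fully conserved.
#' @param gap_blocks list of `list(rows =, cols =)` gap plans.
#' @param charge_plan optional integer vector (length `n_rows`) of target
#'   formal charges.
#' @param seed integer seed.
#' @return list with `aln` (an [aligned_set]), `fasta` (text lines) and
#'   `ledger`.
#' @export
make_synthetic_msa <- function(n_rows = 36, length = 60,
                               invariant_columns = integer(0),
                               gap_blocks = list(), charge_plan = NULL,
                               seed = 1) {
  if (any(invariant_columns > length) ||
      any(unlist(lapply(gap_blocks, `[[`, "cols")) > length))
    stop("plan does not fit in the alignment length")
  gap_cols <- unique(unlist(lapply(gap_blocks, `[[`, "cols")))
  if (any(invariant_columns %in% gap_cols))
    stop("contradictory plan: invariant column inside a gap block")
  neutral <- setdiff(.aa_letters, c("K", "R", "D", "E", "H"))
  mat <- with_seed(seed, {
    m <- matrix(sample(neutral, n_rows * length, replace = TRUE),
                n_rows, length)
    for (j in invariant_columns) m[, j] <- sample(.aa_letters, 1)
    for (blk in gap_blocks) m[blk$rows, blk$cols] <- "-"
    # break accidental full conservation outside the plan
    for (j in setdiff(seq_len(length), c(invariant_columns, gap_cols))) {
      if (stats::var(match(m[, j], .aa_letters)) == 0)
        m[sample(n_rows, 1), j] <- sample(setdiff(neutral, m[1, j]), 1)
    }
    if (!is.null(charge_plan)) {
      stopifnot(length(charge_plan) == n_rows)
      free <- setdiff(seq_len(length), c(invariant_columns, gap_cols))
      for (r in seq_len(n_rows)) {
        cur <- formal_charge(paste(m[r, ], collapse = ""))
        slots <- free[m[r, free] %in% neutral]
        need <- charge_plan[r] - cur
        if (abs(need) > base::length(slots))
          stop("contradictory plan: not enough free columns for charge ",
               charge_plan[r], " in row ", r)
        if (need != 0) {
          pick <- slots[seq_len(abs(need))]
          m[r, pick] <- if (need > 0) "K" else "D"
        }
      }
    }
    m
  })
  rownames(mat) <- sprintf("SYN%02d", seq_len(n_rows))
  seqs <- apply(mat, 1, paste, collapse = "")
  aln <- aligned_set(seqs)
  planted <- sort(invariant_columns)
  actual <- fully_conserved_columns(aln)
  if (!identical(as.integer(actual), as.integer(planted)))
    stop("internal generator error: conservation plan not realized")
  fasta <- as.vector(rbind(paste0(">", names(seqs)), unname(seqs)))
  list(aln = aln, fasta = fasta,
       ledger = list(seed = seed, n_rows = n_rows, ncols = length,
                     invariant_columns = planted, gap_blocks = gap_blocks,
                     charge_plan = charge_plan))
}

#' Two-domain dumbbell for flexibility sanity checks
#'
#' Two dense atom clusters joined by a thin sparse linker: the linker must be
#' softer (larger predicted B) than the domain cores under any sensible
#' elastic network.
#'
#' @param n_core atoms per core (>= 4).
#' @param n_linker linker atoms (>= 4).
#' @param seed integer seed.
#' @return list with `model` and `ledger` (atom class assignment).
#' @export
make_flexible_dumbbell <- function(n_core = 20, n_linker = 6, seed = 1) {
  if (n_core < 4 || n_linker < 4) stop("sizes must be at least 4")
  span <- 3.8 * (n_linker + 1)
  xyz <- with_seed(seed, {
    core <- function(center) sweep(matrix(stats::rnorm(3 * n_core, sd = 1.6),
                                          n_core, 3), 2, center, `+`)
    link <- cbind(seq(-span / 2 + 3.8, span / 2 - 3.8, length.out = n_linker),
                  0, 0)
    rbind(core(c(-span / 2 - 2, 0, 0)), link, core(c(span / 2 + 2, 0, 0)))
  })
  n <- nrow(xyz)
  model <- build_model(chain = rep("A", n), resno = seq_len(n),
                       resid = rep("GLY", n), elety = rep("CA", n), xyz = xyz)
  list(model = model,
       ledger = list(seed = seed,
                     core_atoms = c(seq_len(n_core),
                                    n_core + n_linker + seq_len(n_core)),
                     linker_atoms = n_core + seq_len(n_linker)))
}
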