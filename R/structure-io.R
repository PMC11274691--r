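# Structure input/output: heavy-atom models from PDB text.
#
# A `structure_model` is the container the whole pipeline operates on:
# protein chains reduced to heavy atoms (N, C, O, S), waters and hydrogens
# removed, GSH-like hetero residues kept aside as ligand copies. The
# temperature-factor column carries either an experimental B-factor (Angstrom^2)
# or, for predicted models, the per-residue pLDDT confidence (0-100).

# Hetero residue codes retained as ligand copies by default (GSH and common
# GSH-like analogues as ligand-transplant tools emit them).
default_ligand_codes <- function() c("GSH", "GTX", "GSF", "GTS", "GDS", "GTT")

.water_codes <- c("HOH", "WAT", "DOD", "H2O", "SOL")

# Best-effort element from a PDB atom name when the element column is absent.
infer_element <- function(elety) {
  nm <- gsub("[0-9']", "", toupper(trimws(elety)))
  el <- substr(nm, 1, 1)
  two <- substr(nm, 1, 2)
  el[two %in% c("SE", "FE", "ZN", "MG", "MN", "NA", "CL", "CA")] <-
    two[two %in% c("SE", "FE", "ZN", "MG", "MN", "NA", "CL", "CA")]
  # Disambiguate: a leading CA in a protein atom name is a calcium only for ions;
  # atom names CA/CB/CG/etc are carbons. Treat any name present in proteins as C.
  el[substr(nm, 1, 1) == "C"] <- "C"
  el[substr(nm, 1, 1) == "N"] <- "N"
  el[substr(nm, 1, 1) == "O"] <- "O"
  el[substr(nm, 1, 1) == "S" & two != "SE"] <- "S"
  el
}

#' Parse a PDB structure into a heavy-atom model
#'
#' Reads ATOM/HETATM records and returns a [structure_model]: protein chains
#' filtered to heavy atoms (N, C, O, S), hydrogens and waters removed, the
#' first-listed alternate conformer retained, and GSH-like hetero residues
#' routed to a separate ligand table. Other hetero residues (ions, glycans)
#' are discarded.
#'
#' @param pdb_text character scalar or vector with PDB-format text.
#' @param ligand_codes three-letter hetero codes retained as ligand copies.
#' @return A `structure_model`: list with `atoms` (protein heavy atoms:
#'   chain, resno, ins, resid, elety, x, y, z, occ, b, element, mass,
#'   res_index), `ligands` (same columns plus `lig_id`, one id per hetero
#'   residue copy), and `residues` (one row per protein residue in file order).
#' @examples
#' txt <- c("ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00 10.00           C",
#'          "END")
#' m <- parse_structure(txt)
#' nrow(m$atoms)
#' @export
parse_structure <- function(pdb_text, ligand_codes = default_ligand_codes()) {
  lines <- unlist(strsplit(paste(pdb_text, collapse = "\n"), "\n", fixed = TRUE))
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") | substr(lines, 1, 4) == "ATOM"
  idx <- which(is_atom)
  if (length(idx)) {
    coords <- cbind(substr(lines[idx], 31, 38),
                    substr(lines[idx], 39, 46),
                    substr(lines[idx], 47, 54))
    bad <- which(apply(coords, 1, function(r)
      any(is.na(suppressWarnings(as.numeric(trimws(r)))))))
    if (length(bad))
      stop("malformed coordinate fields at line ", idx[bad[1]])
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- tryCatch(bio3d::read.pdb(tf, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) stop("PDB parse error: ", conditionMessage(e)))
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$element <- ifelse(is.na(at$elesy) | at$elesy == "", infer_element(at$elety),
                       toupper(at$elesy))
  # hydrogens / deuterium out
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  # waters out
  at <- at[!(at$resid %in% .water_codes), , drop = FALSE]
  # alternate locations: keep the first listed conformer of each atom
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "\r")
  at <- at[!duplicated(key), , drop = FALSE]

  is_lig <- at$type == "HETATM" & at$resid %in% ligand_codes
  is_prot <- at$type == "ATOM" & at$element %in% c("C", "N", "O", "S")

  prot <- at[is_prot, , drop = FALSE]
  lig <- at[is_lig, , drop = FALSE]
  if (nrow(prot) == 0L && nrow(lig) == 0L) stop("empty model")

  mk <- function(d) {
    data.frame(chain = d$chain, resno = d$resno, ins = d$insert,
               resid = d$resid, elety = d$elety,
               x = d$x, y = d$y, z = d$z,
               occ = ifelse(is.na(d$o), 1, d$o), b = ifelse(is.na(d$b), 0, d$b),
               element = d$element,
               mass = unname(.element_masses[d$element]),
               stringsAsFactors = FALSE)
  }
  atoms <- mk(prot)
  if (nrow(atoms)) {
    rkey <- paste(atoms$chain, atoms$resno, atoms$ins, sep = "\r")
    atoms$res_index <- match(rkey, unique(rkey))
    residues <- atoms[!duplicated(atoms$res_index),
                      c("res_index", "chain", "resno", "ins", "resid")]
    rownames(residues) <- NULL
  } else {
    stop("empty model")
  }
  ligands <- mk(lig)
  if (nrow(ligands)) {
    ligands$lig_id <- paste(ligands$chain, ligands$resno, ligands$ins,
                            ligands$resid, sep = ":")
  } else {
    ligands$lig_id <- character(0)
  }
  rownames(atoms) <- NULL
  rownames(ligands) <- NULL
  structure(list(atoms = atoms, ligands = ligands, residues = residues),
            class = "structure_model")
}

#' @rdname parse_structure
#' @param path path to a PDB file.
#' @export
read_structure <- function(path, ligand_codes = default_ligand_codes()) {
  parse_structure(readLines(path, warn = FALSE), ligand_codes = ligand_codes)
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat("structure_model:", length(ch), "chain(s) [", paste(ch, collapse = ", "),
      "], ", nrow(x$residues), "residues,", nrow(x$atoms), "heavy atoms")
  if (nrow(x$ligands))
    cat(",", length(unique(x$ligands$lig_id)), "ligand copies")
  cat("\n")
  invisible(x)
}

#' Write a heavy-atom model as PDB text
#'
#' Emits standards-conformant fixed-column ATOM records (and HETATM records for
#' ligand copies), preserving chain identifiers and residue numbering.
#'
#' @param model a [structure_model].
#' @param path optional file path; when given the text is also written there.
#' @return PDB text as a character vector of lines (invisibly when `path` is
#'   given).
#' @export
write_structure <- function(model, path = NULL) {
  stopifnot(inherits(model, "structure_model"))
  if (length(unique(c(model$atoms$chain, model$ligands$chain))) > 62)
    stop("more than 62 chains: PDB chain identifier space exhausted")
  fmt <- function(d, type, offset = 0L) {
    if (!nrow(d)) return(character(0))
    name4 <- ifelse(nchar(d$elety) >= 4, substr(d$elety, 1, 4),
                    sprintf(" %-3s", d$elety))
    sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, offset + seq_len(nrow(d)), name4, "", d$resid, d$chain,
            d$resno, ifelse(d$ins == "", " ", d$ins), d$x, d$y, d$z, d$occ,
            d$b, d$element)
  }
  out <- c(fmt(model$atoms, "ATOM"),
           fmt(model$ligands, "HETATM", nrow(model$atoms)), "END")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Per-residue model confidence (pLDDT)
#'
#' For predicted structures the temperature-factor column stores the
#' per-residue pLDDT confidence (0-100), identical for all atoms of a residue;
#' it is read from each residue's Calpha record. Residues without a Calpha are
#' reported as `NA` rather than interpolated.
#'
#' @param model a [structure_model].
#' @return data.frame with one row per protein residue: `chain`, `resno`,
#'   `resid`, `plddt`.
#' @export
extract_confidence <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  res <- model$residues
  ca <- model$atoms[model$atoms$elety == "CA", ]
  res$plddt <- ca$b[match(res$res_index, ca$res_index)]
  res[c("chain", "resno", "resid", "plddt")]
}

#' Calpha coordinates of one chain
#'
#' @param model a [structure_model].
#' @param chain chain identifier; default: the first chain.
#' @return numeric matrix (n residues x 3) of Calpha coordinates, with the
#'   residue indices as rownames; residues lacking a Calpha are dropped.
#' @export
calpha_coords <- function(model, chain = NULL) {
  a <- model$atoms
  chain <- chain %||% a$chain[1]
  ca <- a[a$chain == chain & a$elety == "CA", ]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$res_index
  m
}

#' One-letter sequence of a chain
#'
#' @inheritParams calpha_coords
#' @return character scalar; unknown residue names become `X`.
#' @export
chain_sequence <- function(model, chain = NULL) {
  r <- model$residues
  chain <- chain %||% r$chain[1]
  r <- r[r$chain == chain, ]
  paste(ifelse(r$resid %in% names(.aa3to1), .aa3to1[r$resid], "X"),
        collapse = "")
}

#' Chain identifiers of the protein part of a model
#'
#' @param model a [structure_model].
#' @return character vector of chain ids in file order.
#' @export
model_chains <- function(model) unique(model$residues$chain)
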