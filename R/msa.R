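# Alignment-indexed sequence analytics.
#
# Every residue in the family is addressed by its "MSA number": the 1-based
# column of the multiple sequence alignment. Conservation, gaps, charges and
# the per-row position mapping defined here are the coordinate system the
# structural modules aggregate onto.

#' Read an aligned FASTA file into an aligned_set
#'
#' @param input path to an aligned FASTA file, or the FASTA text itself
#'   (anything containing a newline or starting with `>` is treated as text).
#' @param class_labels optional named character vector of family-class labels,
#'   named by sequence id.
#' @return An `aligned_set`: list with `ids`, `seqs` (named aligned strings),
#'   `mat` (character matrix, rows = sequences, columns = MSA numbers),
#'   `ncols`, and optional `class_labels`.
#' @export
read_alignment <- function(input, class_labels = NULL) {
  if (length(input) > 1 || grepl("\n", input[1]) || startsWith(input[1], ">")) {
    tf <- tempfile(fileext = ".fasta")
    on.exit(unlink(tf))
    writeLines(unlist(strsplit(paste(input, collapse = "\n"), "\n")), tf)
    input <- tf
  }
  ss <- Biostrings::readBStringSet(input)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicated sequence ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  aligned_set(seqs, class_labels = class_labels)
}

#' @rdname read_alignment
#' @param seqs named character vector of aligned rows (equal lengths, amino
#'   acid letters and `-`).
#' @export
aligned_set <- function(seqs, class_labels = NULL) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1)
    stop("ragged alignment: row lengths ", paste(unique(widths), collapse = ", "))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  ok <- mat %in% c(.aa_letters, "-")
  if (!all(ok)) {
    bad <- which(!matrix(ok, nrow(mat)), arr.ind = TRUE)[1, ]
    stop("non-amino-acid letter '", mat[bad[1], bad[2]], "' in row ",
         rownames(mat)[bad[1]], ", column ", bad[2])
  }
  if (!is.null(class_labels)) class_labels <- class_labels[rownames(mat)]
  structure(list(ids = rownames(mat), seqs = seqs, mat = mat,
                 ncols = ncol(mat), class_labels = class_labels),
            class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  cat("aligned_set:", length(x$ids), "sequences x", x$ncols, "columns\n")
  invisible(x)
}

#' Per-column conservation profile of an alignment
#'
#' For every MSA number, the frequency of each amino acid among the rows, in
#' percent of the total number of rows (so gaps count against conservation);
#' a column is fully conserved only when one amino acid occupies it in every
#' row.
#'
#' @param aln an [aligned_set].
#' @return list with `freq` (20 x ncol matrix, percent of rows), `gaps`
#'   (per-column gap counts), `majority` (most frequent amino acid per column,
#'   `NA` for all-gap columns), `score` (its percentage), and `nrows`.
#' @export
conservation_profile <- function(aln) {
  m <- aln$mat
  n <- nrow(m)
  counts <- vapply(seq_len(ncol(m)), function(j)
    tabulate(match(m[, j], .aa_letters), nbins = length(.aa_letters)),
    integer(length(.aa_letters)))
  rownames(counts) <- .aa_letters
  freq <- 100 * counts / n
  gaps <- colSums(m == "-")
  top <- apply(counts, 2, which.max)
  majority <- ifelse(colSums(counts) > 0, .aa_letters[top], NA_character_)
  score <- vapply(seq_len(ncol(m)), function(j) freq[top[j], j], numeric(1))
  score[is.na(majority)] <- NA_real_
  list(freq = freq, gaps = unname(gaps), majority = majority,
       score = score, nrows = n)
}

#' Fully conserved MSA numbers
#'
#' Columns where one amino acid is present in every row of the alignment.
#'
#' @param aln an [aligned_set].
#' @return ascending integer vector of MSA numbers.
#' @export
fully_conserved_columns <- function(aln) {
  p <- conservation_profile(aln)
  which(!is.na(p$score) & p$score >= 100 - 1e-9)
}

#' Gap profile of an alignment
#'
#' @param aln an [aligned_set].
#' @return list with `by_column` (gap count per MSA number) and `by_row`
#'   (total gaps per sequence, named).
#' @export
gap_profile <- function(aln) {
  list(by_column = unname(colSums(aln$mat == "-")),
       by_row = rowSums(aln$mat == "-"))
}

#' Pairwise sequence identity of two aligned rows
#'
#' Exact-match identity in percent. The default denominator is the number of
#' columns where at least one of the two rows is non-gap, so insertions and
#' deletions reduce identity; alternatives are the ungapped length of the
#' shorter sequence or the full alignment length.
#'
#' @param rowA,rowB aligned strings of equal length.
#' @param denominator one of `"pair_coverage"`, `"shorter"`, `"alignment"`.
#' @return identity in percent.
#' @export
pairwise_identity <- function(rowA, rowB,
                              denominator = c("pair_coverage", "shorter",
                                              "alignment")) {
  denominator <- match.arg(denominator)
  a <- strsplit(rowA, "")[[1]]
  b <- strsplit(rowB, "")[[1]]
  if (length(a) != length(b)) stop("rows have unequal lengths")
  ga <- a == "-"; gb <- b == "-"
  if (all(ga) && all(gb)) stop("both rows are all-gap")
  matches <- sum(a == b & !ga & !gb)
  den <- switch(denominator,
                pair_coverage = sum(!(ga & gb)),
                shorter = min(sum(!ga), sum(!gb)),
                alignment = length(a))
  100 * matches / den
}

#' Pairwise identity matrix of an alignment
#'
#' @param aln an [aligned_set].
#' @param denominator passed to [pairwise_identity()].
#' @return symmetric matrix of identities in percent, 100 on the diagonal.
#' @export
identity_matrix <- function(aln, denominator = "pair_coverage") {
  n <- length(aln$ids)
  m <- matrix(100, n, n, dimnames = list(aln$ids, aln$ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        m[i, j] <- m[j, i] <-
          pairwise_identity(aln$seqs[i], aln$seqs[j], denominator)
      }
    }
  }
  m
}

#' Class-block average identities
#'
#' Mean pairwise identity for every pair of family classes, excluding the
#' diagonal self-comparisons.
#'
#' @param mat identity matrix from [identity_matrix()].
#' @param labels character vector of class labels, named by sequence id (or in
#'   matrix order).
#' @return symmetric matrix of mean identities per class pair.
#' @export
class_average_identity <- function(mat, labels) {
  if (!is.null(names(labels))) labels <- labels[rownames(mat)]
  if (anyNA(labels)) stop("unknown class label for: ",
                          paste(rownames(mat)[is.na(labels)], collapse = ", "))
  cls <- sort(unique(labels))
  out <- matrix(NA_real_, length(cls), length(cls), dimnames = list(cls, cls))
  for (a in cls) for (b in cls) {
    block <- mat[labels == a, labels == b, drop = FALSE]
    if (a == b) {
      vals <- block[upper.tri(block)]
      out[a, b] <- if (length(vals)) mean(vals) else NA_real_
    } else out[a, b] <- mean(block)
  }
  out
}

#' Formal charge of a sequence
#'
#' count(Lys, Arg) - count(Asp, Glu); histidine counts +1 only when
#' `his_positive = TRUE`.
#'
#' @param seq amino-acid string (gaps ignored).
#' @param his_positive logical; count His as +1.
#' @return integer net charge.
#' @export
formal_charge <- function(seq, his_positive = FALSE) {
  a <- strsplit(gsub("-", "", seq), "")[[1]]
  pos <- sum(a %in% c("K", "R")) + if (his_positive) sum(a == "H") else 0L
  neg <- sum(a %in% c("D", "E"))
  as.integer(pos - neg)
}

#' Per-column charge of one alignment row
#'
#' @param aln an [aligned_set].
#' @param row_id sequence id.
#' @inheritParams formal_charge
#' @return integer vector over MSA numbers: +1/-1/0, `NA` at gap columns.
#' @export
charge_by_msa <- function(aln, row_id, his_positive = FALSE) {
  a <- aln$mat[row_id, ]
  ch <- integer(length(a))
  ch[a %in% c("K", "R")] <- 1L
  if (his_positive) ch[a == "H"] <- 1L
  ch[a %in% c("D", "E")] <- -1L
  ch[a == "-"] <- NA_integer_
  ch
}

#' Map sequence positions to MSA numbers (and back)
#'
#' `map_position` maps 1-based positions in the ungapped sequence of one row
#' to MSA numbers; `msa_to_position` is the inverse and returns `NA` for gap
#' columns of that row.
#'
#' @param aln an [aligned_set].
#' @param row_id sequence id.
#' @param seq_index positions in the ungapped sequence.
#' @return integer vector of MSA numbers (or sequence positions for the
#'   inverse; `NA` marks a gap column).
#' @export
map_position <- function(aln, row_id, seq_index) {
  cols <- which(aln$mat[row_id, ] != "-")
  if (any(seq_index < 1 | seq_index > length(cols)))
    stop("seq_index outside the ungapped sequence (length ", length(cols), ")")
  cols[seq_index]
}

#' @rdname map_position
#' @param msa_number MSA numbers (alignment columns).
#' @export
msa_to_position <- function(aln, row_id, msa_number) {
  row <- aln$mat[row_id, ]
  if (any(msa_number < 1 | msa_number > length(row)))
    stop("msa_number outside the alignment (ncols ", length(row), ")")
  pos <- cumsum(row != "-")
  out <- pos[msa_number]
  out[row[msa_number] == "-"] <- NA_integer_
  as.integer(out)
}
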