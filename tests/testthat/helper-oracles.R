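# Independent brute-force oracles used across the suite. These deliberately
# take the slow, obvious route so they share no code path with the package.

# All residue pairs in contact, by the O(n^2) double loop over atoms.
brute_force_contacts <- function(model, threshold) {
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n_res <- max(a$res_index)
  hits <- matrix(FALSE, n_res, n_res)
  for (i in seq_len(nrow(a) - 1)) {
    for (j in seq(i + 1, nrow(a))) {
      if (a$res_index[i] == a$res_index[j]) next
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < threshold) {
        hits[a$res_index[i], a$res_index[j]] <- TRUE
        hits[a$res_index[j], a$res_index[i]] <- TRUE
      }
    }
  }
  which(hits & upper.tri(hits), arr.ind = TRUE)
}

# All simple paths of exactly the minimal source->target length, by exhaustive
# depth-first enumeration on an adjacency list.
brute_force_min_paths <- function(adj, sources, targets) {
  best <- Inf
  found <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v %in% targets) {
      if (length(path) < best) {
        best <<- length(path)
        found <<- list(path)
      } else if (length(path) == best) {
        found[[length(found) + 1]] <<- path
      }
      return()
    }
    if (length(path) >= best) return()
    for (w in adj[[v]]) if (!(w %in% path)) walk(c(path, w))
  }
  for (s in sources) walk(s)
  list(length = if (is.finite(best)) best else NA_real_, paths = found)
}

# Angle at b from pairwise distances only (law of cosines): an oracle for the
# coarse-grained bond angle that never touches vector algebra.
angle_from_distances <- function(a, b, c) {
  ab <- sqrt(sum((a - b)^2)); cb <- sqrt(sum((c - b)^2))
  ac <- sqrt(sum((a - c)^2))
  acos((ab^2 + cb^2 - ac^2) / (2 * ab * cb)) * 180 / pi
}

# Mean-square fluctuation per atom from the Moore-Penrose pseudo-inverse of
# the mass-weighted Hessian: trace of each atom's 3x3 diagonal block.
pinv_msf <- function(hessian) {
  p <- MASS::ginv(hessian)
  n <- nrow(hessian) / 3
  vapply(seq_len(n), function(i) {
    k <- (3 * (i - 1) + 1):(3 * i)
    sum(diag(p[k, k, drop = FALSE]))
  }, numeric(1))
}

# A seeded random rigid motion applied to a structure_model.
rigid_move <- function(model, seed = 99) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  R <- {
    m <- matrix(rnorm(9), 3, 3)
    q <- qr.Q(qr(m))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  }
  shift <- runif(3, -20, 20)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  move <- function(d) {
    xyz <- as.matrix(d[, c("x", "y", "z")]) %*% t(R)
    d$x <- xyz[, 1] + shift[1]
    d$y <- xyz[, 2] + shift[2]
    d$z <- xyz[, 3] + shift[3]
    d
  }
  model$atoms <- move(model$atoms)
  if (nrow(model$ligands)) model$ligands <- move(model$ligands)
  model
}
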