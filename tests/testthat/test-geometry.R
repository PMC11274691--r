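test_that("Kabsch superposition recovers rigid motion exactly", {
  set.seed(42)
  P <- matrix(rnorm(30, sd = 8), 10, 3)
  expect_equal(kabsch_superpose(P, P)$rmsd, 0, tolerance = 1e-10)
  R <- {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  }
  Q <- P %*% t(R) + matrix(rep(c(3, -5, 11), each = 10), 10, 3)
  s <- kabsch_superpose(P, Q)
  expect_lt(s$rmsd, 1e-8)
  expect_equal(det(s$rotation), 1, tolerance = 1e-10)
  expect_equal(apply_superposition(P, s), Q, tolerance = 1e-8)
  expect_error(kabsch_superpose(P[1:2, ], Q[1:2, ]), "3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("Kabsch RMSD is the rigid-transform optimum", {
  set.seed(7)
  P <- matrix(rnorm(24, sd = 5), 8, 3)
  Q <- P + matrix(rnorm(24, sd = 0.8), 8, 3)
  best <- kabsch_superpose(P, Q)$rmsd
  # independent cross-check against bio3d's least-squares fit
  ref <- bio3d::rmsd(as.vector(t(Q)), as.vector(t(P)), fit = TRUE)
  expect_equal(best, ref, tolerance = 1e-3)
  # a randomized oracle never beats it
  for (k in 1:25) {
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    t0 <- rnorm(3)
    cand <- sqrt(mean(rowSums((sweep(P %*% t(R), 2, -t0) - Q)^2)))
    expect_gte(cand + 1e-10, best)
  }
})

test_that("alignment-matched RMSD uses doubly-non-gap columns only", {
  fx <- make_ideal_chain("coil", 12, seed = 6)
  aln <- aligned_set(c(a = "ACDEFGHIKLMN", b = "ACDEFGHIKLMN",
                       c = "ACDEF---KLMN"))
  expect_equal(rmsd_common_calpha(fx$model, fx$model, aln, "a", "b")$rmsd, 0,
               tolerance = 1e-10)
  short <- fx$model
  keep <- short$residues$res_index[-(6:8)]
  short$atoms <- short$atoms[short$atoms$res_index %in% keep, ]
  short$atoms$res_index <- match(short$atoms$res_index, keep)
  short$residues <- short$atoms[!duplicated(short$atoms$res_index),
                                c("res_index", "chain", "resno", "ins", "resid")]
  r <- rmsd_common_calpha(fx$model, short, aln, "a", "c")
  expect_equal(r$n_common, 9)  # columns non-gap in both rows
  # hinge fixture: rotate the tail of a copy by a known transform
  hinged <- fx$model
  xyz <- as.matrix(hinged$atoms[, c("x", "y", "z")])
  tail_idx <- hinged$atoms$res_index > 6
  Rz <- matrix(c(cos(0.5), sin(0.5), 0, -sin(0.5), cos(0.5), 0, 0, 0, 1), 3, 3)
  pivot <- xyz[which(tail_idx)[1], ]
  xyz[tail_idx, ] <- sweep(sweep(xyz[tail_idx, ], 2, pivot) %*% t(Rz), 2,
                           pivot, `+`)
  hinged$atoms[, c("x", "y", "z")] <- xyz
  got <- rmsd_common_calpha(fx$model, hinged, aln, "a", "b")$rmsd
  # oracle: bio3d least-squares fit on the same matched coordinates
  P <- calpha_coords(fx$model); Q <- calpha_coords(hinged)
  ref <- bio3d::rmsd(as.vector(t(P)), as.vector(t(Q)), fit = TRUE)
  expect_equal(got, ref, tolerance = 1e-3)
})

test_that("local Calpha deviation reads planted displacements", {
  fx <- make_ideal_chain("helix", 10, seed = 3)
  aln <- aligned_set(c(a = "ACDEFGHIKL", b = "ACDEFGHIKL"))
  d0 <- local_ca_deviation(fx$model, fx$model, aln, "a", "b")
  expect_equal(unname(d0), rep(0, 10), tolerance = 1e-10)
  moved <- fx$model
  i <- with(moved$atoms, which(res_index == 5 & elety == "CA"))
  moved$atoms$y[i] <- moved$atoms$y[i] + 2.5
  d <- local_ca_deviation(fx$model, moved, aln, "a", "b", superpose = FALSE)
  expect_equal(unname(d["5"]), 2.5, tolerance = 1e-12)
  expect_equal(unname(d[-5]), rep(0, 9), tolerance = 1e-12)
  # co-rotating both structures leaves superposed deviations unchanged
  d1 <- local_ca_deviation(fx$model, moved, aln, "a", "b")
  d2 <- local_ca_deviation(rigid_move(fx$model), rigid_move(moved),
                           aln, "a", "b")
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("coarse-grained angles match independent geometric oracles", {
  line <- cbind(3.8 * (1:5), 0, 0)
  expect_equal(unname(coarse_grained_angles(line)$theta), rep(180, 3))
  zig <- cbind(3.3 * (1:6), 0.8 * (-1)^(1:6), 0)       # planar trans zigzag
  expect_equal(abs(unname(coarse_grained_angles(zig)$gamma)), rep(180, 3),
               tolerance = 1e-9)
  h <- make_ideal_chain("helix", 20, seed = 1)
  ca <- calpha_coords(h$model)
  cga <- coarse_grained_angles(ca)
  # theta oracle: law of cosines from pairwise distances only
  for (i in 2:19)
    expect_equal(unname(cga$theta[as.character(i)]),
                 angle_from_distances(ca[i - 1, ], ca[i, ], ca[i + 1, ]),
                 tolerance = 1e-9)
  # gamma oracle: bio3d torsion
  tor <- bio3d::torsion.xyz(as.vector(t(ca)), atm.inc = 1)
  expect_equal(unname(cga$gamma), tor[!is.na(tor)], tolerance = 1e-6)
  expect_equal(mean(cga$theta), 91, tolerance = 0.02)
  expect_equal(mean(cga$gamma), 50, tolerance = 0.02)
  # an N-residue chain carries N-3 complete (theta, gamma) pairs
  expect_length(cga$gamma, 20 - 3)
  expect_error(coarse_grained_angles(ca[1:3, ]), "at least 4")
  expect_error(coarse_grained_angles(rbind(ca[1, ], ca[1, ], ca[2:3, ])),
               "coincident")
})

test_that("CGA deviation wraps circularly and scores the planted flip", {
  h <- make_ideal_chain("helix", 12, seed = 2)
  ca <- calpha_coords(h$model)
  a <- coarse_grained_angles(ca)
  d0 <- cga_deviation(a, a)
  expect_equal(d0$score, rep(0, nrow(d0)))
  b <- a
  b$gamma["6"] <- b$gamma["6"] + 360
  expect_equal(cga_deviation(a, b)$score, rep(0, nrow(d0)), tolerance = 1e-12)
  b <- a
  b$gamma["6"] <- b$gamma["6"] - 30
  dd <- cga_deviation(a, b)
  expect_equal(dd$score[dd$residue == 6], 30 / 180, tolerance = 1e-12)
  expect_equal(sum(dd$score), 30 / 180, tolerance = 1e-12)
})

test_that("chi1 distance hits its endpoints and flags missing atoms", {
  mk <- function(chi_deg) {
    xyz <- rbind(c(0, 1.4, 1.0),                   # N
                 c(0, 0, 0),                       # CA
                 c(0, 0, 1.53),                    # CB (z axis)
                 c(sin(rad(0)), 0, 2.3))           # placeholder
    xyz[4, ] <- c(1.4 * cos(rad(chi_deg + 90)), 1.4 * sin(rad(chi_deg + 90)), 2.3)
    build <- data.frame(chain = "A", resno = 1, ins = "", resid = "SER",
                        elety = c("N", "CA", "CB", "OG"),
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        occ = 1, b = 0, element = c("N", "C", "C", "O"),
                        mass = 12, res_index = 1)
    structure(list(atoms = build,
                   ligands = cbind(build[0, ], lig_id = character(0)),
                   residues = build[1, c("res_index", "chain", "resno", "ins",
                                         "resid")]),
              class = "structure_model")
  }
  rad <- function(d) d * pi / 180
  aln <- aligned_set(c(a = "S", b = "S"))
  d <- function(delta)
    unname(chi1_distance(mk(0), mk(delta), aln, "a", "b"))
  expect_equal(d(0), 0, tolerance = 1e-12)
  expect_equal(d(90), 0.5, tolerance = 1e-9)
  expect_equal(d(180), 1, tolerance = 1e-12)
  noside <- mk(0)
  noside$atoms <- noside$atoms[noside$atoms$elety != "OG", ]
  expect_true(is.na(chi1_distance(noside, mk(0), aln, "a", "b")))
})

test_that("chi1 and CGA are invariant under rigid motion", {
  fx <- make_ideal_chain("coil", 10, seed = 12)
  moved <- rigid_move(fx$model)
  a <- coarse_grained_angles(calpha_coords(fx$model))
  b <- coarse_grained_angles(calpha_coords(moved))
  expect_equal(a$theta, b$theta, tolerance = 1e-8)
  expect_equal(a$gamma, b$gamma, tolerance = 1e-8)
})

test_that("radius of gyration obeys closed forms", {
  one <- make_ideal_chain("helix", 5, seed = 1)$model
  one$atoms <- one$atoms[1, ]
  one$residues <- one$residues[1, ]
  expect_equal(radius_of_gyration(one), 0)
  two <- one
  two$atoms <- rbind(two$atoms, two$atoms)
  two$atoms$x <- c(0, 6)
  expect_equal(radius_of_gyration(two), 3)
  # uniform ball of radius R: Rg -> R sqrt(3/5)
  set.seed(10)
  n <- 40000
  pts <- matrix(runif(3 * n * 3, -1, 1), ncol = 3)
  pts <- pts[rowSums(pts^2) <= 1, ][seq_len(n), ] * 9
  ball <- list(atoms = data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                                  mass = 12))
  class(ball) <- "structure_model"
  expect_equal(radius_of_gyration(ball), 9 * sqrt(3 / 5), tolerance = 0.01)
})

test_that("secondary structure assignment labels ideal traces", {
  h <- make_ideal_chain("helix", 14, seed = 1)
  ss_h <- assign_secondary_structure(coarse_grained_angles(calpha_coords(h$model)))
  expect_true(all(ss_h[3:11] == "H"))
  expect_true(all(ss_h[c(1, 14)] == "C"))
  s <- make_ideal_chain("strand", 12, seed = 1)
  ss_s <- assign_secondary_structure(coarse_grained_angles(calpha_coords(s$model)))
  expect_true(all(ss_s[3:9] == "E"))
  expect_false(any(ss_s == "H"))
  # assignment is a pure function of the angles
  cga <- coarse_grained_angles(calpha_coords(h$model))
  expect_identical(assign_secondary_structure(cga),
                   assign_secondary_structure(cga))
})
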