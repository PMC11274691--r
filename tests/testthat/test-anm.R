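triangle_network <- function(gamma = 1) {
  elastic_network(data.frame(x = c(0, 2, 1), y = c(0, 0, sqrt(3)), z = c(0, 0, 0),
                             mass = c(12, 14, 16)), gamma = gamma)
}

test_that("the mass-weighted Hessian has the defining structure", {
  fx <- make_flexible_dumbbell(n_core = 8, n_linker = 4, seed = 2)
  H <- build_hessian(elastic_network(fx$model))
  expect_lt(max(abs(H - t(H))), 1e-12)
  # mass-weighted translation vectors span part of the null space
  m <- elastic_network(fx$model)$mass
  for (axis in 1:3) {
    t_vec <- rep(0, 3 * length(m))
    t_vec[seq(axis, by = 3, length.out = length(m))] <- sqrt(m)
    expect_lt(max(abs(H %*% t_vec)), 1e-9 * max(abs(H)))
  }
  expect_error(build_hessian(elastic_network(
    data.frame(x = c(0, 0), y = c(0, 0), z = c(0, 0), mass = c(1, 1)))),
    "coincident")
})

test_that("a 3-node triangle matches element-wise symbolic assembly", {
  net <- triangle_network()
  H <- build_hessian(net)
  # independent assembly: explicit loops straight from the definition
  n <- 3
  xyz <- net$xyz; m <- net$mass
  Ho <- matrix(0, 9, 9)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    rij <- xyz[j, ] - xyz[i, ]
    r2 <- sum(rij^2)
    gam <- net$gamma / r2
    blk <- -outer(rij, rij) / r2 * gam
    Ho[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)] <- blk
    Ho[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)] <-
      Ho[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)] - blk
  }
  for (i in 1:n) for (j in 1:n)
    Ho[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)] <-
      Ho[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)] / sqrt(m[i] * m[j])
  expect_equal(H, Ho, tolerance = 1e-12)
})

test_that("the diatomic network reproduces its closed-form eigenvalue", {
  r <- 1.5; m1 <- 12; m2 <- 16
  net <- elastic_network(data.frame(x = c(0, r), y = 0, z = 0,
                                    mass = c(m1, m2)))
  nm <- normal_modes(build_hessian(net))
  expect_length(nm$rigid, 5)  # linear molecule: 5 rigid-body modes
  expect_length(nm$internal, 1)
  gam <- 1 / r^2
  expect_equal(nm$values[nm$internal], gam * (1 / m1 + 1 / m2),
               tolerance = 1e-12)
})

test_that("mode counting and orthonormality hold for 3-D networks", {
  tet <- elastic_network(data.frame(
    x = c(1, -1, -1, 1), y = c(1, -1, 1, -1), z = c(1, 1, -1, -1),
    mass = rep(12, 4)))
  nm <- normal_modes(build_hessian(tet))
  expect_length(nm$rigid, 6)
  expect_length(nm$internal, 3 * 4 - 6)
  expect_true(all(nm$values[nm$internal] > 0))
  V <- nm$vectors
  expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-10)
  # a coplanar network has a vanishing out-of-plane block: more than 6
  # near-zero modes must be reported as degenerate
  flat <- elastic_network(data.frame(x = c(0, 2, 1, 3), y = c(0, 0, 2, 2),
                                     z = 0, mass = rep(12, 4)))
  expect_error(normal_modes(build_hessian(flat)), "degenerate")
})

test_that("thermal B-factors obey positivity, symmetry and the gamma scale law", {
  tet <- data.frame(x = c(1, -1, -1, 1), y = c(1, -1, 1, -1),
                    z = c(1, 1, -1, -1), mass = rep(12, 4))
  fit1 <- {
    net <- elastic_network(tet, gamma = 1)
    nm <- normal_modes(build_hessian(net))
    thermal_bfactors(nm, net$mass)$atom_b
  }
  expect_true(all(fit1 > 0))
  # equal-mass symmetric tetrahedron: all four atoms equivalent
  expect_equal(fit1, rep(fit1[1], 4), tolerance = 1e-9)
  fit2 <- {
    net <- elastic_network(tet, gamma = 2)
    nm <- normal_modes(build_hessian(net))
    thermal_bfactors(nm, net$mass)$atom_b
  }
  expect_equal(fit2, fit1 / 2, tolerance = 1e-9)
})

test_that("predicted B-factors are invariant under rigid motion", {
  fx <- make_flexible_dumbbell(n_core = 8, n_linker = 4, seed = 6)
  b1 <- pfanm(fx$model)$atom_b
  b2 <- pfanm(rigid_move(fx$model))$atom_b
  expect_equal(b2, b1, tolerance = 1e-8)
})

test_that("the linker of a dumbbell is softer than its cores", {
  fx <- make_flexible_dumbbell(n_core = 16, n_linker = 5, seed = 1)
  fit <- pfanm(fx$model)
  expect_gt(mean(fit$atom_b[fx$ledger$linker_atoms]),
            mean(fit$atom_b[fx$ledger$core_atoms]))
})

test_that("mode-sum fluctuations equal the pseudo-inverse oracle", {
  fx <- make_flexible_dumbbell(n_core = 6, n_linker = 4, seed = 3)
  net <- elastic_network(fx$model)
  H <- build_hessian(net)
  nm <- normal_modes(H)
  b <- thermal_bfactors(nm, net$mass)$atom_b
  msf <- pinv_msf(H)  # tr of each atom's 3x3 block of the pseudo-inverse
  oracle_b <- (8 * pi^2 / 3) * (300 / net$mass) * msf
  expect_equal(b, oracle_b, tolerance = 1e-6)
})

test_that("B-factor correlations behave at the endpoints", {
  prof <- stats::setNames(c(5, 9, 14, 7, 11), as.character(1:5))
  expect_equal(bfactor_correlation(prof, prof)$rho, 1)
  expect_equal(bfactor_correlation(prof, -prof)$rho, -1)
  flat <- stats::setNames(rep(3, 5), as.character(1:5))
  expect_warning(r <- bfactor_correlation(prof, flat), "zero variance")
  expect_true(is.na(r$rho))
  # missing residues are dropped and reported
  short <- prof[1:4]
  r2 <- bfactor_correlation(prof, short)
  expect_equal(r2$n_used, 4)
  expect_equal(r2$n_dropped, 1)
  expect_error(bfactor_correlation(prof[1:2], prof[1:2]), "fewer than 3")
  # correlation is invariant under the gamma scale
  expect_equal(bfactor_correlation(prof * 2, prof)$rho, 1)
})
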