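two_atom_model <- function(d) {
  at <- data.frame(chain = "A", resno = 1:2, ins = "", resid = "GLY",
                   elety = "CA", x = c(0, d), y = 0, z = 0, occ = 1, b = 0,
                   element = "C", mass = 12.011, res_index = 1:2)
  structure(list(atoms = at, ligands = cbind(at[0, -13], lig_id = character(0)),
                 residues = at[, c("res_index", "chain", "resno", "ins",
                                   "resid")]),
            class = "structure_model")
}

test_that("the contact threshold is a strict 4.0 A heavy-atom rule", {
  expect_equal(nrow(residue_contact_map(two_atom_model(3.9))$pairs), 1)
  expect_equal(nrow(residue_contact_map(two_atom_model(4.1))$pairs), 0)
  expect_equal(nrow(residue_contact_map(two_atom_model(4.0))$pairs), 0)
})

test_that("neighbor-search contact maps equal the all-pairs oracle", {
  fx <- make_ideal_chain("coil", 50, seed = 17)
  cm <- residue_contact_map(fx$model, 4.0)
  oracle <- brute_force_contacts(fx$model, 4.0)
  oracle <- oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE]
  expect_equal(unname(cm$pairs), unname(cbind(oracle[, 1], oracle[, 2])))
  # and at a larger cutoff
  cm8 <- residue_contact_map(fx$model, 8.0)
  o8 <- brute_force_contacts(fx$model, 8.0)
  expect_equal(nrow(cm8$pairs), nrow(o8))
})

test_that("planted dimer interfaces are recovered exactly", {
  fx <- make_toy_dimer(n_per_chain = 14, interface_size = 6, seed = 5)
  di <- interface_residues(fx$model)
  for (ch in c("A", "B"))
    expect_equal(di$residues$seq_pos[di$residues$chain == ch],
                 fx$ledger$interface_residues)
  expect_equal(unname(di$n_di), c(6L, 6L))
  # rigid motion of the whole dimer changes nothing
  di2 <- interface_residues(rigid_move(fx$model))
  expect_equal(di2$residues, di$residues)
  # chains far apart: no interface
  apart <- fx$model
  b <- apart$atoms$chain == "B"
  apart$atoms$y[b] <- apart$atoms$y[b] - 50
  expect_equal(sum(interface_residues(apart)$n_di), 0)
  mono <- fx$model
  mono$atoms <- mono$atoms[!b, ]
  mono$residues <- mono$residues[mono$residues$chain == "A", ]
  expect_error(interface_residues(mono), "two protein chains")
})

test_that("ligand clustering reproduces the two-pockets-by-nine design", {
  fx <- make_toy_dimer(ligand_copies_per_pocket = 9, seed = 9)
  cl <- cluster_ligands(fx$model, 2.0)
  expect_length(cl$clusters, 2)
  expect_equal(unname(cl$sizes), c(9L, 9L))
  # one copy: singleton
  one <- fx$model
  one$ligands <- one$ligands[one$ligands$lig_id == one$ligands$lig_id[1], ]
  expect_equal(cluster_ligands(one)$sizes, 1L)
})

test_that("single-linkage semantics chain copies and are monotone in the cut", {
  # copies on a line spaced 1.9 A: one chain-linked cluster at 2.0
  lig <- do.call(rbind, lapply(1:5, function(k)
    data.frame(chain = "L", resno = k, ins = "", resid = "GSH", elety = "C1",
               x = 1.9 * k, y = 0, z = 0, occ = 1, b = 0, element = "C",
               mass = 12.011, lig_id = paste0("L", k))))
  expect_length(cluster_ligands(lig, 2.0)$clusters, 1)
  expect_length(cluster_ligands(lig, 1.5)$clusters, 5)
  fx <- make_toy_dimer(seed = 4)
  ncl <- vapply(c(0.3, 1, 2, 5, 30), function(th)
    length(cluster_ligands(fx$model, th)$clusters), numeric(1))
  expect_true(all(diff(ncl) <= 0))
})

test_that("binding sites are unions of residues contacting cluster members", {
  # a ligand atom 3 A from exactly 4 residues of a square
  at <- data.frame(chain = "A", resno = 1:4, ins = "", resid = "GLY",
                   elety = "CA",
                   x = c(2, -2, 0, 0), y = c(0, 0, 2, -2), z = 0,
                   occ = 1, b = 0, element = "C", mass = 12.011,
                   res_index = 1:4)
  lig1 <- data.frame(chain = "L", resno = 1, ins = "", resid = "GSH",
                     elety = "C1", x = 0, y = 0, z = sqrt(9 - 4), occ = 1,
                     b = 0, element = "C", mass = 12.011, lig_id = "L:1")
  m <- structure(list(atoms = at, ligands = lig1,
                      residues = at[, c("res_index", "chain", "resno", "ins",
                                        "resid")]),
                 class = "structure_model")
  gs <- binding_site_residues(m, "L:1")
  expect_equal(gs$n_gs, 4)
  # far ligand: empty site with a warning
  m2 <- m
  m2$ligands$z <- 50
  expect_warning(gs2 <- binding_site_residues(m2, "L:1"), "no protein residue")
  expect_equal(gs2$n_gs, 0)
  # two members touching different residues: union
  lig2 <- lig1
  lig2$lig_id <- "L:2"; lig2$resno <- 2
  lig2$x <- 5  # within 4.0 of residue 1 only (distance 3 + something)
  lig2$z <- 0
  m3 <- m
  m3$ligands <- rbind(lig1, lig2)
  gs3 <- binding_site_residues(m3, c("L:1", "L:2"))
  expect_equal(gs3$n_gs, 4)
  expect_setequal(gs3$residues$resno, 1:4)
  expect_error(binding_site_residues(m3, character(0)), "empty ligand cluster")
})

test_that("Shrake-Rupley areas match sphere closed forms", {
  iso <- data.frame(x = 0, y = 0, z = 0, element = "C", chain = "A")
  a <- shrake_rupley_sasa(iso)
  expect_equal(a, 4 * pi * (1.70 + 1.4)^2, tolerance = 0.01)
  # one sphere strictly containing another: the small one is fully buried,
  # the big one untouched
  pair <- data.frame(x = c(0, 0), y = 0, z = 0, element = c("S", "O"),
                     chain = "A")
  ap <- shrake_rupley_sasa(pair)
  expect_equal(ap[2], 0)
  expect_equal(ap[1], 4 * pi * (1.80 + 1.4)^2, tolerance = 0.01)
  # two atoms at partial overlap: spherical-cap closed form for each
  d <- 1.7
  r <- 1.70 + 1.4
  cap_exposed <- 4 * pi * r^2 - 2 * pi * r * (r - d / 2)  # cut at the midplane
  two <- data.frame(x = c(0, d), y = 0, z = 0, element = "C", chain = "A")
  a2 <- shrake_rupley_sasa(two)
  expect_equal(a2[1], cap_exposed, tolerance = 0.02)
  expect_equal(a2[2], cap_exposed, tolerance = 0.02)
  # together they expose one full sphere plus the band the caps leave over
  expect_lt(sum(a2), 2 * a)
})

test_that("buried interface area is symmetric, non-negative and zero when apart", {
  fx <- make_toy_dimer(n_per_chain = 8, interface_size = 2, seed = 2)
  apart <- fx$model
  b <- apart$atoms$chain == "B"
  apart$atoms$y[b] <- apart$atoms$y[b] - 50
  expect_equal(buried_interface_area(apart, n_points = 240), 0,
               tolerance = 1e-9)
  area <- buried_interface_area(fx$model, n_points = 240)
  expect_gte(area, 0)
  swapped <- fx$model
  swapped$atoms$chain <- ifelse(swapped$atoms$chain == "A", "B", "A")
  expect_equal(buried_interface_area(swapped, n_points = 240), area,
               tolerance = 1e-9)
})
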