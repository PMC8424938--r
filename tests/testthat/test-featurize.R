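# Featurization tests run against the Open Babel backend; flag
# expectations for amide/aromatic/hydrophobic probes were cross-checked
# against an independent SMARTS evaluation (RDKit) when the rules were
# frozen.

test_that("every heavy atom gets exactly 18 channels with a valid one-hot", {
  tp <- cached_toy(n_residues = 10, seed = 5)
  ft <- featurize_structure(tp$structure)
  expect_equal(nrow(ft), sum(tp$structure$atoms$is_heavy))
  fmat <- as.matrix(ft[, paste0("f", 1:18)])
  expect_equal(ncol(fmat), 18)
  onehot <- fmat[, 1:9]
  expect_true(all(rowSums(onehot) <= 1))
  # C/N/O/S atoms all belong to the class table -> exactly one hot
  expect_true(all(rowSums(onehot) == 1))
  expect_true(all(fmat[, 14:18] %in% c(0, 1)))
  expect_true(all(fmat[, 10] %in% 0:3))
  expect_true(all(is.finite(fmat[, 13])))
})

test_that("aromatic ring atoms carry aromatic, ring and sp2 channels", {
  tp <- cached_toy(n_residues = 10, seed = 4)  # sequence ESSDSLTFSE
  ft <- featurize_structure(tp$structure)
  ring <- ft[ft$residue_name == "PHE" &
    ft$atom_name %in% c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"), ]
  expect_true(all(ring$f15 == 1))  # aromatic
  expect_true(all(ring$f18 == 1))  # ring
  expect_true(all(ring$f10 == 2))  # sp2
  non_ring <- ft[ft$atom_name %in% c("CA", "CB"), ]
  expect_true(all(non_ring$f15 == 0))
  expect_true(all(non_ring$f18 == 0))
})

test_that("donor/acceptor/hydrophobic flags follow amide chemistry", {
  tp <- cached_toy(n_residues = 10, seed = 5)
  ctx <- molecule_context(tp$structure)
  ft <- featurize_structure(ctx)
  bbN <- ft[ft$atom_name == "N", ]
  bbO <- ft[ft$atom_name == "O", ]
  # backbone amide N-H donates, never accepts; carbonyl O accepts
  expect_true(all(bbN$f17[-1] == 1))
  expect_true(all(bbN$f16 == 0))
  expect_true(all(bbO$f16 == 1))
  expect_true(all(bbO$f17 == 0))
  # sp3 carbon with only C/H neighbors is hydrophobic (e.g. LEU CD1)
  cd <- ft[ft$atom_name %in% c("CD1", "CD2") & ft$residue_name == "LEU", ]
  if (nrow(cd) > 0) expect_true(all(cd$f14 == 1))
  # smarts_flags agrees with the featurized columns
  fl <- smarts_flags(ctx, which(ctx$atoms$is_heavy))
  expect_equal(unname(fl[, "donor"]), unname(ft$f17 == 1))
  expect_error(smarts_flags(ctx, nrow(ctx$atoms) + 1),
    class = "pocketgrid_domain_error")
})

test_that("features are invariant under rigid-body motion", {
  tp <- cached_toy(n_residues = 8, seed = 7)
  f1 <- featurize_structure(tp$structure)
  s2 <- tp$structure
  # rotate 90 degrees about z then translate
  xy <- cbind(s2$atoms$x, s2$atoms$y)
  s2$atoms$x <- -xy[, 2] + 12
  s2$atoms$y <- xy[, 1] - 5
  s2$atoms$z <- s2$atoms$z + 30
  f2 <- featurize_structure(s2)
  cols <- paste0("f", 1:18)
  expect_equal(as.matrix(f1[, cols]), as.matrix(f2[, cols]),
    tolerance = 1e-8)
})

test_that("metal atoms map to the metal class channel", {
  onehot <- pocketgrid:::element_class_onehot(c("Zn", "Fe", "C", "Se", "Cl"))
  expect_equal(onehot[1, 9], 1)  # Zn -> metal
  expect_equal(onehot[2, 9], 1)  # Fe -> metal
  expect_equal(onehot[3, 2], 1)  # C
  expect_equal(onehot[4, 7], 1)  # Se
  expect_equal(onehot[5, 8], 1)  # Cl -> halogen
  expect_true(all(rowSums(onehot) == 1))
})
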