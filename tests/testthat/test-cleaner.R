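test_that("kmers enumerates consecutive substrings with stride 1", {
  expect_equal(kmers("ACDEFG"), c("ACD", "CDE", "DEF", "EFG"))
  expect_equal(kmers("ACD"), "ACD")
  expect_error(kmers("AC"), class = "pocketgrid_domain_error")
  # count property across lengths
  set.seed(4)
  for (n in c(3, 7, 50, 211, 500)) {
    s <- paste(sample(names(pocketgrid:::AA_SIDE_SMILES), n,
      replace = TRUE), collapse = "")
    expect_length(kmers(s), n - 2)
  }
})

test_that("tripeptide molecules fingerprint to 167-bit MACCS keys", {
  fp <- fingerprint_matrix("ACDEFGHIKL")
  expect_equal(dim(fp), c(8L, 167L))
  expect_true(all(fp %in% c(0L, 1L)))
  # determinism
  expect_identical(
    unclass(fingerprint_matrix("GGAKL")), unclass(fingerprint_matrix("GGAKL"))
  )
  expect_error(fingerprint_matrix("GGX"), class = "pocketgrid_domain_error")
})

test_that("GGG MACCS row matches an independent file-based computation", {
  row <- fingerprint_matrix("GGG")[1, ]
  keys_pkg <- which(row == 1) - 1L  # column k+1 holds key k
  keys_cli <- obabel_maccs_keys(peptide_smiles("GGG"))
  expect_setequal(keys_pkg, keys_cli)
})

test_that("pooled Tanimoto follows set arithmetic", {
  a <- matrix(0L, 2, 167)
  b <- matrix(0L, 2, 167)
  a[1, c(5, 10)] <- 1L
  b[1, c(10, 20)] <- 1L
  expect_equal(tanimoto_equal(a, a), 1)
  expect_equal(tanimoto_equal(a, b), 1 / 3)
  expect_equal(tanimoto_equal(matrix(0L, 3, 167), matrix(0L, 3, 167)), 1)
  disj <- matrix(0L, 2, 167)
  disj[1, c(30, 40)] <- 1L
  expect_equal(tanimoto_equal(a, disj), 0)
  expect_error(tanimoto_equal(a, matrix(0L, 3, 167)),
    class = "pocketgrid_domain_error")
})

test_that("sliding Tanimoto equals the exhaustive window oracle", {
  set.seed(99)
  for (i in 1:60) {
    n1 <- sample(1:20, 1)
    n2 <- sample(1:20, 1)
    a1 <- random_bit_matrix(n1)
    a2 <- random_bit_matrix(n2)
    expect_equal(sliding_tanimoto(a1, a2), oracle_sliding_tanimoto(a1, a2))
    expect_equal(sliding_tanimoto(a1, a2), sliding_tanimoto(a2, a1))
    expect_equal(sliding_tanimoto(a1, a1), 1)
  }
  # a contiguous row-slice scores a perfect window
  a <- random_bit_matrix(12)
  expect_equal(sliding_tanimoto(a, a[4:9, , drop = FALSE]), 1)
})

test_that("clustering groups by accession and rejects unmapped ids", {
  structures <- tibble::tibble(
    structure_id = c("a", "b", "c"),
    sequence = c("GGG", "GGA", "AAA")
  )
  mapping <- tibble::tibble(
    structure_id = c("a", "b", "c"),
    uniprot_id = c("U1", "U1", "U2")
  )
  cl <- cluster_by_uniprot(structures, mapping)
  expect_equal(sort(table(cl$uniprot_id), decreasing = TRUE),
    sort(table(c("U1", "U1", "U2")), decreasing = TRUE))
  expect_error(
    cluster_by_uniprot(structures, mapping[1:2, ]),
    class = "pocketgrid_domain_error"
  )
})

test_that("representative selection takes the longest sequence, ties by id", {
  members <- tibble::tibble(
    structure_id = c("c", "a", "b"),
    sequence = c(strrep("G", 50), strrep("G", 80), strrep("G", 80))
  )
  rep1 <- select_representative(members)
  expect_equal(rep1$structure_id, "a")
  # order independence
  rep2 <- select_representative(members[c(3, 1, 2), ])
  expect_equal(rep2$structure_id, "a")
  single <- select_representative(members[1, ])
  expect_equal(single$mean_tanimoto, 1)
  expect_false(single$below_threshold)
})

test_that("dissimilar cluster members trip the similarity warning", {
  members <- tibble::tibble(
    structure_id = c("x", "y"),
    sequence = c("GGGGGGGGGG", "FKFKFKFKFK")
  )
  res <- select_representative(members, similarity_threshold = 0.8)
  expect_lt(res$mean_tanimoto, 0.8)
  expect_true(res$below_threshold)
})

test_that("site distance filter drops strictly beyond the cutoff", {
  tp <- cached_toy(n_residues = 8, seed = 6)
  ctr <- structure_center(tp$structure)
  at70 <- site_coords(matrix(ctr + c(70, 0, 0), ncol = 3))
  at71 <- site_coords(matrix(ctr + c(71, 0, 0), ncol = 3))
  at0 <- site_coords(matrix(ctr, ncol = 3))
  expect_equal(filter_distant_site(tp$structure, at70), "keep")
  expect_equal(filter_distant_site(tp$structure, at71), "drop")
  expect_equal(filter_distant_site(tp$structure, at0), "keep")
})

test_that("chain retention keeps exactly the contacting chains", {
  tp <- cached_toy(n_residues = 10, n_chains = 2, seed = 4)
  kept <- retain_site_chains(tp$structure, tp$site)
  expect_equal(unique(kept$atoms$chain_id), "A")
  # a site point between the chains within cutoff of both keeps both
  a_atom <- tp$structure$atoms[tp$structure$atoms$chain_id == "A", ][1, ]
  b_atom <- tp$structure$atoms[tp$structure$atoms$chain_id == "B", ][1, ]
  both <- site_coords(rbind(
    c(a_atom$x, a_atom$y, a_atom$z), c(b_atom$x, b_atom$y, b_atom$z)
  ))
  expect_setequal(
    unique(retain_site_chains(tp$structure, both)$atoms$chain_id),
    c("A", "B")
  )
  far <- site_coords(matrix(c(500, 500, 500), ncol = 3))
  expect_error(retain_site_chains(tp$structure, far),
    class = "pocketgrid_no_contact_error")
})

test_that("run_cleaning dispositions partition the batch", {
  b <- make_cleaning_batch(seed = 2)
  res <- run_cleaning(b$batch, b$mapping)
  expect_setequal(res$report$structure_id, b$batch$structure_id)
  expect_false(any(is.na(res$report$disposition)))
  expect_equal(sort(names(res$retained)),
    sort(res$report$structure_id[res$report$disposition == "kept"]))
  # empty input
  empty <- run_cleaning(b$batch[0, ], b$mapping)
  expect_equal(nrow(empty$report), 0)
})

test_that("the row-mean Tanimoto variant brackets sensibly", {
  set.seed(5)
  a <- random_bit_matrix(6)
  b <- random_bit_matrix(6)
  expect_equal(tanimoto_equal(a, a, method = "rowmean"), 1)
  rm_val <- tanimoto_equal(a, b, method = "rowmean")
  # independent computation: mean of per-row Jaccard indices
  per_row <- vapply(1:6, function(r) {
    x <- a[r, ] == 1
    y <- b[r, ] == 1
    sum(x & y) / sum(x | y)
  }, 1.0)
  expect_equal(rm_val, mean(per_row))
  expect_equal(sliding_tanimoto(a, b[1:4, ], method = "rowmean"),
    max(vapply(0:2, function(off) {
      mean(vapply(1:4, function(r) {
        x <- b[r, ] == 1
        y <- a[off + r, ] == 1
        u <- sum(x | y)
        if (u == 0) 1 else sum(x & y) / u
      }, 1.0))
    }, 1.0)))
})
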