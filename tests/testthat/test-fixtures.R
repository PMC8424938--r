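test_that("toy proteins are bit-reproducible given the seed", {
  t1 <- make_toy_protein(fixture_config(n_residues = 9, seed = 12))
  t2 <- make_toy_protein(fixture_config(n_residues = 9, seed = 12))
  expect_identical(t1$structure$atoms, t2$structure$atoms)
  expect_identical(t1$site, t2$site)
  t3 <- make_toy_protein(fixture_config(n_residues = 9, seed = 13))
  expect_false(identical(t1$structure$atoms, t3$structure$atoms))
})

test_that("toy proteins carry their own ground truth", {
  tp <- make_toy_protein(fixture_config(n_residues = 20, n_chains = 2,
    seed = 3))
  expect_equal(nchar(tp$meta$sequences[["A"]]), 20)
  expect_equal(n_residues(tp$structure), 40)
  expect_equal(
    unname(tp$meta$structure_center),
    unname(structure_center(tp$structure))
  )
  # constructed contact geometry: the site touches chain A only
  kept <- retain_site_chains(tp$structure, tp$site)
  expect_equal(unique(kept$atoms$chain_id), tp$meta$site_chain)
  # site centroid near the recorded pocket center
  expect_lt(
    dcc(colMeans(pocketgrid:::points_matrix(tp$site)), tp$meta$site_center),
    2
  )
})

test_that("cleaning batches encode one case per disposition branch", {
  b <- make_cleaning_batch(seed = 1)
  expect_setequal(
    unique(b$expected$disposition),
    c("kept", "deduplicated", "dropped_distance", "dropped_parse")
  )
  # the duplicate pair is highly similar: one terminal residue apart
  s2 <- read_structure(b$batch$structure_path[2])
  s3 <- read_structure(b$batch$structure_path[3])
  fp2 <- fingerprint_matrix(paste(protein_sequences(s2), collapse = ""))
  fp3 <- fingerprint_matrix(paste(protein_sequences(s3), collapse = ""))
  expect_gt(sliding_tanimoto(fp2, fp3), 0.8)
  # the distant-site member really is beyond 70 A
  s4 <- read_structure(b$batch$structure_path[4])
  site4 <- read_site(b$batch$site_path[4])
  d <- sqrt(rowSums(sweep(pocketgrid:::points_matrix(site4), 2,
    structure_center(s4))^2))
  expect_gt(max(d), 70)
})

test_that("probability grids honor their blob and noise construction", {
  pg1 <- make_probability_grid(
    tibble::tibble(cx = 10, cy = 10, cz = 10, radius = 2),
    noise_level = 0.2, seed = 5
  )
  pg2 <- make_probability_grid(
    tibble::tibble(cx = 10, cy = 10, cz = 10, radius = 2),
    noise_level = 0.2, seed = 5
  )
  expect_identical(pg1$prob, pg2$prob)
  # noise-only grid stays below threshold everywhere
  pg0 <- make_probability_grid(
    tibble::tibble(cx = integer(), cy = integer(), cz = integer(),
      radius = numeric()),
    noise_level = 0.4, seed = 2
  )
  expect_lt(max(pg0$prob), 0.5)
  expect_length(extract_pockets(pg0$prob, grid_spec()), 0)
  # overlapping blobs merge into one expected component
  pgm <- make_probability_grid(
    tibble::tibble(cx = c(15, 17), cy = c(15, 15), cz = c(15, 15),
      radius = c(3, 3)),
    noise_level = 0, seed = 3
  )
  expect_length(pgm$expected, 1)
})

test_that("fixture datasets land on disk with a mapping table", {
  dir <- withr::local_tempdir()
  files <- write_fixture_dataset(dir, seed = 2, n_structures = 2)
  expect_true(all(file.exists(files$structure_path)))
  expect_true(all(file.exists(files$site_path)))
  expect_true(file.exists(file.path(dir, "mapping.tsv")))
  mp <- readr::read_tsv(file.path(dir, "mapping.tsv"),
    show_col_types = FALSE)
  expect_equal(nrow(mp), 2)
})
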