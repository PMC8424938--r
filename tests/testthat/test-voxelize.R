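test_that("grid_spec defaults give the production 36-voxel cube", {
  spec <- grid_spec()
  expect_equal(spec$side, 36L)
  expect_error(grid_spec(resolution = 0), class = "pocketgrid_domain_error")
})

test_that("voxel assignment matches the index formula and drops outsiders", {
  spec <- grid_spec(center = c(0, 0, 0))
  ft <- tibble::tibble(x = c(0, 100), y = c(0, 0), z = c(0, 0))
  for (i in 1:18) ft[[paste0("f", i)]] <- 1
  fg <- voxelize_atoms(ft, spec)
  nz <- which(fg$tensor[, , , 1] != 0, arr.ind = TRUE)
  expect_equal(unname(nz[1, ]), c(18L, 18L, 18L))  # 0-based index 17
  expect_equal(fg$dropped, 1L)
  # additivity: two identical atoms double every channel
  ft2 <- ft[c(1, 1), ]
  fg2 <- voxelize_atoms(ft2, spec)
  expect_equal(fg2$tensor[18, 18, 18, ], 2 * fg$tensor[18, 18, 18, ])
})

test_that("voxelize_atoms is equivariant under joint translation", {
  set.seed(20)
  pts <- matrix(runif(60, -30, 30), ncol = 3)
  ft <- tibble::as_tibble(as.data.frame(pts))
  names(ft) <- c("x", "y", "z")
  for (i in 1:18) ft[[paste0("f", i)]] <- runif(20)
  t_vec <- c(5.3, -2.2, 9.9)
  fg1 <- voxelize_atoms(ft, grid_spec(center = c(0, 0, 0)))
  ft2 <- ft
  ft2$x <- ft2$x + t_vec[1]
  ft2$y <- ft2$y + t_vec[2]
  ft2$z <- ft2$z + t_vec[3]
  fg2 <- voxelize_atoms(ft2, grid_spec(center = t_vec))
  expect_equal(fg1$tensor, fg2$tensor)
})

test_that("site masks are binary occupancy, idempotent over repeats", {
  spec <- grid_spec(center = c(0, 0, 0))
  pts <- matrix(rep(c(0.1, 0.2, 0.3), 10), ncol = 3, byrow = TRUE)
  m <- voxelize_site(pts, spec)
  expect_equal(sum(m$tensor), 1)
  expect_true(all(m$tensor %in% c(0, 1)))
  far <- matrix(c(500, 500, 500), ncol = 3)
  expect_equal(sum(voxelize_site(far, spec)$tensor), 0)
})

test_that("voxel assignment agrees with brute-force nearest-voxel mapping", {
  set.seed(7)
  spec <- grid_spec(center = c(1.5, -2, 3))
  pts <- matrix(runif(3000, -45, 45), ncol = 3)
  pts <- sweep(pts, 2, spec$center, "+")
  got <- pocketgrid:::voxel_index(pts, spec)
  want <- oracle_voxel_index(pts, spec)
  # rows fully inside for the oracle
  both_na <- is.na(got[, 1]) & is.na(want[, 1])
  expect_equal(is.na(got[, 1]), is.na(want[, 1]))
  expect_equal(got[!both_na, ], want[!both_na, ], ignore_attr = TRUE)
})

test_that("extract_pockets partitions super-threshold voxels", {
  spec <- grid_spec()
  pg <- make_probability_grid(
    tibble::tibble(cx = c(8, 20, 30), cy = c(8, 20, 8),
      cz = c(8, 20, 30), radius = c(2, 3, 2)),
    noise_level = 0.3, seed = 9
  )
  pk <- extract_pockets(pg$prob, spec, threshold = 0.5)
  all_flat <- sort(unlist(lapply(pk, function(p) p$flat)))
  expect_equal(all_flat, which(pg$prob > 0.5))
  expect_equal(sum(duplicated(all_flat)), 0)
  # sorted by decreasing mean probability
  mp <- vapply(pk, function(p) p$mean_prob, 1.0)
  expect_equal(mp, sort(mp, decreasing = TRUE))
  # center equals the mean of member voxel Cartesian centers
  vc <- pocketgrid:::voxel_center(pk[[1]]$voxels, spec)
  expect_equal(unname(pk[[1]]$center), unname(colMeans(vc)))
  expect_error(extract_pockets(pg$prob, spec, threshold = 1.2),
    class = "pocketgrid_domain_error")
  expect_length(extract_pockets(array(0, dim = c(36, 36, 36)), spec), 0)
})

test_that("single hot voxel yields one single-voxel pocket at its center", {
  spec <- grid_spec(center = c(0, 0, 0))
  prob <- array(0, dim = rep(36, 3))
  prob[10, 20, 30] <- 0.9
  pk <- extract_pockets(prob, spec)
  expect_length(pk, 1)
  expect_equal(pk[[1]]$n_voxels, 1L)
  expect_equal(
    unname(pk[[1]]$center),
    unname(as.vector(pocketgrid:::voxel_center(
      matrix(c(10, 20, 30), ncol = 3), spec
    )))
  )
})
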