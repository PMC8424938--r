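test_that("dcc is the Euclidean center distance", {
  expect_equal(dcc(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dcc(c(0, 0, 0), c(3, 4, 0)), 5)
})

test_that("success rate counts missing predictions in the denominator", {
  recs <- tibble::tibble(dcc = c(2, 5, 3, NA))
  expect_equal(success_rate(recs), 0.5)
  expect_equal(success_rate(tibble::tibble(dcc = c(4, 4))), 1)
  expect_error(success_rate(tibble::tibble(dcc = numeric())),
    class = "pocketgrid_domain_error")
  # random fixture equals the trivial count oracle
  set.seed(31)
  d <- ifelse(runif(100) < 0.2, NA, runif(100, 0, 10))
  recs <- tibble::tibble(dcc = d)
  expect_equal(success_rate(recs),
    sum(!is.na(d) & d <= 4) / 100)
})

test_that("dvo and pli follow brute-force set arithmetic", {
  side <- 36
  mk <- function(flat) {
    a <- array(0, dim = rep(side, 3))
    a[flat] <- 1
    a
  }
  a <- mk(1:60)
  b <- mk(41:80)
  expect_equal(dvo(a, b), 20 / 80)
  expect_equal(dvo(a, a), 1)
  expect_equal(dvo(a, mk(100:110)), 0)
  expect_equal(pli(mk(1:10), mk(4:100)), 0.7)
  expect_equal(pli(mk(1:10), mk(1:50)), 1)
  expect_equal(pli(mk(1:10), mk(90:95)), 0)
  expect_error(dvo(mk(integer(0)), mk(integer(0))),
    class = "pocketgrid_domain_error")
  expect_error(pli(mk(integer(0)), a), class = "pocketgrid_domain_error")
  # random sets vs independent set arithmetic; dvo symmetric
  set.seed(8)
  for (i in 1:20) {
    s1 <- sample(side^3, 200)
    s2 <- sample(side^3, 150)
    expect_equal(dvo(mk(s1), mk(s2)),
      length(intersect(s1, s2)) / length(union(s1, s2)))
    expect_equal(dvo(mk(s1), mk(s2)), dvo(mk(s2), mk(s1)))
    expect_equal(pli(mk(s1), mk(s2)),
      length(intersect(s1, s2)) / length(s1))
  }
})

test_that("evaluate_structure classifies FN / TP / FP correctly", {
  spec <- grid_spec(center = c(0, 0, 0))
  site <- site_coords(matrix(c(0, 0, 0), ncol = 3))
  # FN: no pockets
  fn <- evaluate_structure(list(), site, spec)
  expect_equal(fn$class, "FN")
  expect_true(is.na(fn$dcc))
  expect_true(is.na(fn$dvo))
  # TP: single-voxel pocket at the site voxel
  prob <- array(0, dim = rep(36, 3))
  prob[18, 18, 18] <- 0.95
  tp <- evaluate_structure(extract_pockets(prob, spec), site, spec)
  expect_equal(tp$class, "TP")
  expect_lte(tp$dcc, 4)
  expect_equal(tp$dvo, 1)
  # FP: pocket far away
  prob2 <- array(0, dim = rep(36, 3))
  prob2[2, 2, 2] <- 0.95
  fp <- evaluate_structure(extract_pockets(prob2, spec), site, spec)
  expect_equal(fp$class, "FP")
  expect_true(is.na(fp$dvo))
})

test_that("min-dcc pairing picks the nearest pocket, top-ranked the first", {
  spec <- grid_spec(center = c(0, 0, 0))
  site <- site_coords(matrix(c(0, 0, 0), ncol = 3))
  prob <- array(0, dim = rep(36, 3))
  prob[18, 18, 18] <- 0.6   # near, lower confidence
  prob[28, 28, 28] <- 0.99  # far, ranked first
  pockets <- extract_pockets(prob, spec)
  expect_equal(pockets[[1]]$mean_prob, 0.99)
  r_min <- evaluate_structure(pockets, site, spec, policy = "min_dcc")
  expect_equal(r_min$class, "TP")
  r_top <- evaluate_structure(pockets, site, spec, policy = "top_ranked")
  expect_equal(r_top$class, "FP")
  # exhaustive pairing cross-check: min over all pockets
  d_all <- vapply(pockets, function(p) dcc(p$center, c(0, 0, 0)), 1.0)
  expect_equal(r_min$dcc, min(d_all))
})

test_that("pli lands in the TP record when ligand coordinates are given", {
  spec <- grid_spec(center = c(0, 0, 0))
  site <- site_coords(matrix(c(0.5, 0.5, 0.5), ncol = 3))
  lig <- site_coords(matrix(c(0.5, 0.5, 0.5, 30, 30, 30),
    ncol = 3, byrow = TRUE))
  prob <- array(0, dim = rep(36, 3))
  prob[18, 18, 18] <- 0.95
  rec <- evaluate_structure(extract_pockets(prob, spec), site, spec,
    ligand = lig)
  expect_equal(rec$class, "TP")
  expect_equal(rec$pli, 0.5)  # one of two ligand voxels inside
})

test_that("summaries aggregate counts and means over TP records only", {
  recs <- tibble::tibble(
    structure_id = letters[1:5],
    class = c("TP", "TP", "FP", "FN", "TP"),
    dcc = c(1, 2, 9, NA, 3),
    dvo = c(0.5, 0.7, NA, NA, 0.9),
    pli = c(1, 0.8, NA, NA, 0.6)
  )
  s <- summarize_eval(recs)
  expect_equal(c(s$tp, s$fp, s$fn), c(3, 1, 1))
  expect_equal(s$f1, 2 * 3 / (2 * 3 + 1 + 1))
  expect_equal(s$mean_dvo, mean(c(0.5, 0.7, 0.9)))
  expect_equal(s$mean_pli, mean(c(1, 0.8, 0.6)))
  expect_equal(s$success_rate, 3 / 5)
  # degenerate: no TP at all
  expect_equal(f1_score(0, 0, 5), 0)
})
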