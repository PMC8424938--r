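# shared test fixtures and independent oracles

toy_cache <- new.env(parent = emptyenv())

cached_toy <- function(n_residues = 10, n_chains = 1, seed = 1) {
  key <- paste("toy", n_residues, n_chains, seed, sep = "_")
  if (is.null(toy_cache[[key]])) {
    toy_cache[[key]] <- make_toy_protein(fixture_config(
      n_residues = n_residues, n_chains = n_chains, seed = seed
    ))
  }
  toy_cache[[key]]
}

# brute-force nearest-voxel assignment: per axis, the index of the closest
# voxel center, NA when the point is outside the box
oracle_voxel_index <- function(pts, spec) {
  centers <- spec$center[1] - spec$max_dist +
    (seq_len(spec$side) - 0.5) * spec$resolution
  # per-axis centers share spacing; build one axis then offset
  axis_centers <- function(dim) {
    spec$center[dim] - spec$max_dist +
      (seq_len(spec$side) - 0.5) * spec$resolution
  }
  t(apply(pts, 1, function(p) {
    idx <- integer(3)
    for (d in 1:3) {
      ac <- axis_centers(d)
      i <- which.min(abs(ac - p[d]))
      lo <- spec$center[d] - spec$max_dist
      hi <- lo + spec$side * spec$resolution
      if (p[d] < lo || p[d] >= hi) i <- NA_integer_
      idx[d] <- i
    }
    # a point outside along any axis falls outside the box entirely
    if (anyNA(idx)) idx[] <- NA_integer_
    idx
  }))
}

# independent stack-based flood fill over a binary array, 26-connectivity
oracle_flood_fill <- function(binary, side) {
  lab <- array(0L, dim = rep(side, 3))
  cur <- 0L
  on <- which(binary > 0, arr.ind = TRUE)
  onset <- array(FALSE, dim = rep(side, 3))
  onset[on] <- TRUE
  for (r in seq_len(nrow(on))) {
    p <- on[r, ]
    if (lab[p[1], p[2], p[3]] != 0L) next
    cur <- cur + 1L
    stack <- list(p)
    lab[p[1], p[2], p[3]] <- cur
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        q <- v + c(dx, dy, dz)
        if (any(q < 1) || any(q > side)) next
        if (onset[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- cur
          stack[[length(stack) + 1]] <- q
        }
      }
    }
  }
  lab
}

# brute-force maximum windowed Tanimoto over all alignments
oracle_sliding_tanimoto <- function(a1, a2) {
  jac <- function(x, y) {
    x <- as.logical(x)
    y <- as.logical(y)
    u <- sum(x | y)
    if (u == 0) return(1)
    sum(x & y) / u
  }
  if (nrow(a1) == nrow(a2)) return(jac(a1, a2))
  s <- if (nrow(a1) < nrow(a2)) a1 else a2
  l <- if (nrow(a1) < nrow(a2)) a2 else a1
  w <- nrow(s)
  best <- -Inf
  for (off in 0:(nrow(l) - w)) {
    best <- max(best, jac(s, l[off + seq_len(w), , drop = FALSE]))
  }
  best
}

# decode an obabel `-ofpt -xfMACCS` hex dump into MACCS key numbers
obabel_maccs_keys <- function(smiles) {
  out <- system2("obabel", c(shQuote(paste0("-:", smiles)), "-ofpt",
    "-xfMACCS"), stdout = TRUE, stderr = FALSE)
  hexlines <- grep("^[0-9a-f]{8}( [0-9a-f]{8})*[[:space:]]*$", out,
    value = TRUE)
  words <- unlist(strsplit(paste(hexlines, collapse = " "), "[[:space:]]+"))
  words <- words[nzchar(words)]
  keys <- integer(0)
  nw <- length(words)
  for (w in seq_along(words)) {
    v <- strtoi(substring(words[w], 1:8, 1:8), base = 16L)
    for (d in 1:8) for (b in 0:3) {
      if (bitwAnd(v[d], bitwShiftL(1L, 3L - b)) != 0) {
        pos_msb <- (d - 1L) * 4L + b
        bit <- (nw - w) * 32L + (31L - pos_msb)
        keys <- c(keys, bit + 1L)
      }
    }
  }
  sort(keys)
}

random_bit_matrix <- function(nrow, ncol = 167, density = 0.15) {
  matrix(as.integer(runif(nrow * ncol) < density), nrow = nrow)
}
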