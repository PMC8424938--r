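# Fixed-size voxel grids: the 36x36x36 box placed at the protein center,
# 18-channel feature accumulation, binary site masks, and extraction of
# discrete pockets from probability grids by 26-connected labeling.

#' Grid specification for voxelization
#'
#' A cube of `side = floor(2 * max_dist / resolution) + 1` voxels per axis is
#' placed at `center`, spanning `max_dist` Angstroms in each direction. The
#' defaults (35 A, 2 A/voxel) give the production 36-voxel side: a ~70 A
#' total extent matching the distance filter used during data cleaning.
#'
#' @param center Numeric 3-vector, Angstroms.
#' @param max_dist Half-extent of the cube in Angstroms (default 35).
#' @param resolution Voxel edge length in Angstroms (default 2).
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(center = c(0, 0, 0), max_dist = 35, resolution = 2) {
  stopifnot(length(center) == 3, all(is.finite(center)))
  if (resolution <= 0) {
    abort("resolution must be > 0", class = "pocketgrid_domain_error")
  }
  if (max_dist <= 0) {
    abort("max_dist must be > 0", class = "pocketgrid_domain_error")
  }
  structure(
    list(
      center = as.numeric(center), max_dist = max_dist,
      resolution = resolution,
      side = as.integer(floor(2 * max_dist / resolution) + 1)
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> side %d, %.3g A/voxel, center (%.2f, %.2f, %.2f)\n",
    x$side, x$resolution, x$center[1], x$center[2], x$center[3]
  ))
  invisible(x)
}

# 1-based voxel indices for an n x 3 coordinate matrix; rows outside the box
# get NA. Formula: i0 = floor((x - center + max_dist) / resolution) (0-based),
# kept iff i0 in [0, side - 1].
voxel_index <- function(coords, spec) {
  coords <- as.matrix(coords)
  off <- sweep(coords, 2, spec$center - spec$max_dist)
  idx0 <- floor(off / spec$resolution)
  out <- idx0 < 0 | idx0 > (spec$side - 1)
  idx <- idx0 + 1
  idx[rowSums(out) > 0, ] <- NA_real_
  storage.mode(idx) <- "integer"
  idx
}

# Cartesian centers of 1-based voxel indices
voxel_center <- function(idx, spec) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(
    (idx - 1) * spec$resolution + spec$resolution / 2,
    2, spec$center - spec$max_dist, FUN = "+"
  )
}

new_feature_grid <- function(tensor, spec, dropped = 0L) {
  structure(
    list(spec = spec, tensor = tensor, dropped = dropped),
    class = "feature_grid"
  )
}

new_site_mask <- function(tensor, spec) {
  structure(list(spec = spec, tensor = tensor), class = "site_mask")
}

#' Voxelize featurized atoms onto a feature grid
#'
#' Each atom inside the box adds its 18-channel feature vector to the voxel
#' containing it (channel-wise sum, so the operation is additive over atom
#' sets); atoms outside are dropped and counted in the result's `dropped`
#' field.
#'
#' @param featurized A tibble from [featurize_structure()]: columns x, y, z
#'   and f1..f18.
#' @param spec A [grid_spec()].
#' @return A `feature_grid` with a `side^3 x 18` tensor
#'   (`array(side, side, side, 18)`).
#' @export
voxelize_atoms <- function(featurized, spec = grid_spec()) {
  side <- spec$side
  nc <- length(grep("^f[0-9]+$", names(featurized)))
  stopifnot(nc == 18)
  tensor <- array(0, dim = c(side, side, side, 18))
  if (nrow(featurized) == 0) return(new_feature_grid(tensor, spec))
  idx <- voxel_index(featurized[, c("x", "y", "z")], spec)
  keep <- !is.na(idx[, 1])
  dropped <- sum(!keep)
  feats <- as.matrix(featurized[keep, paste0("f", 1:18)])
  idx <- idx[keep, , drop = FALSE]
  if (nrow(idx) > 0) {
    flat <- idx[, 1] + (idx[, 2] - 1L) * side + (idx[, 3] - 1L) * side^2
    for (ch in 1:18) {
      acc <- rowsum(feats[, ch], group = flat)
      pos <- as.integer(rownames(acc)) + (ch - 1L) * side^3
      tensor[pos] <- tensor[pos] + acc[, 1]
    }
  }
  new_feature_grid(tensor, spec, dropped = as.integer(dropped))
}

#' Voxelize site points into a binary occupancy mask
#'
#' A voxel is 1 iff at least one site point falls inside it. An optional
#' dilation radius (in voxels, Chebyshev metric) grows the occupied set,
#' for users who prefer a padded label over raw occupancy.
#'
#' @param site A `site_coords` tibble (or matrix of points).
#' @param spec A [grid_spec()].
#' @param dilate Non-negative integer dilation radius in voxels (default 0).
#' @return A `site_mask` whose tensor is a `side^3` 0/1 array.
#' @export
voxelize_site <- function(site, spec = grid_spec(), dilate = 0L) {
  if (!inherits(site, "site_coords")) site <- site_coords(site)
  side <- spec$side
  tensor <- array(0, dim = c(side, side, side))
  idx <- voxel_index(points_matrix(site), spec)
  idx <- idx[!is.na(idx[, 1]), , drop = FALSE]
  if (nrow(idx) > 0) tensor[idx] <- 1
  if (dilate > 0 && nrow(idx) > 0) {
    r <- -dilate:dilate
    shifts <- expand.grid(dx = r, dy = r, dz = r)
    for (k in seq_len(nrow(shifts))) {
      sh <- idx
      sh[, 1] <- sh[, 1] + shifts$dx[k]
      sh[, 2] <- sh[, 2] + shifts$dy[k]
      sh[, 3] <- sh[, 3] + shifts$dz[k]
      ok <- rowSums(sh < 1 | sh > side) == 0
      if (any(ok)) tensor[sh[ok, , drop = FALSE]] <- 1
    }
  }
  new_site_mask(tensor, spec)
}

#' Extract discrete pockets from a voxel probability grid
#'
#' Binarizes the grid at `threshold`, labels 26-connected components, drops
#' components smaller than `min_voxels`, and returns the surviving pockets
#' sorted by decreasing mean probability. An empty result is the
#' "no prediction" case and is scored as a false negative downstream.
#'
#' @param prob `side^3` numeric array with values in \[0, 1\].
#' @param spec A [grid_spec()].
#' @param threshold Binarization threshold in (0, 1), default 0.5.
#' @param min_voxels Minimum component size kept, default 1.
#' @return A list of `pocket_prediction` objects (possibly empty), each with
#'   `voxels` (n x 3 integer matrix of 1-based indices), `center` (Cartesian
#'   mean of voxel centers), and `mean_prob`.
#' @export
extract_pockets <- function(prob, spec = grid_spec(), threshold = 0.5,
                            min_voxels = 1L) {
  if (threshold <= 0 || threshold >= 1) {
    abort("threshold must lie in (0, 1)", class = "pocketgrid_domain_error")
  }
  side <- spec$side
  stopifnot(length(prob) == side^3)
  prob <- array(prob, dim = c(side, side, side))
  on <- which(prob > threshold)
  if (length(on) == 0) return(list())
  comp <- label_components_26(on, side)
  pockets <- lapply(split(on, comp), function(flat) {
    idx <- cbind(
      (flat - 1L) %% side + 1L,
      ((flat - 1L) %/% side) %% side + 1L,
      (flat - 1L) %/% (side^2) + 1L
    )
    p <- mean(prob[flat])
    structure(
      list(
        voxels = idx, flat = flat,
        center = colMeans(voxel_center(idx, spec)),
        mean_prob = p, n_voxels = nrow(idx)
      ),
      class = "pocket_prediction"
    )
  })
  pockets <- pockets[vapply(pockets, function(p) p$n_voxels, 1L) >=
    min_voxels]
  pockets <- pockets[order(
    -vapply(pockets, function(p) p$mean_prob, 1.0)
  )]
  names(pockets) <- NULL
  pockets
}

# 26-connected component labels for flat 1-based voxel indices `on` in a
# side^3 grid; returns an integer label per element of `on`.
label_components_26 <- function(on, side) {
  n <- length(on)
  pos <- match(seq_len(side^3), on)  # flat -> index into `on`, NA if off
  lab <- integer(n)
  cur <- 0L
  ix <- (on - 1L) %% side + 1L
  iy <- ((on - 1L) %/% side) %% side + 1L
  iz <- (on - 1L) %/% (side^2) + 1L
  r <- -1:1
  nb <- as.matrix(expand.grid(dx = r, dy = r, dz = r))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  queue <- integer(n)
  for (s in seq_len(n)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue[1] <- s
    qhead <- 1L
    qtail <- 1L
    lab[s] <- cur
    while (qhead <= qtail) {
      v <- queue[qhead]
      qhead <- qhead + 1L
      nx <- ix[v] + nb[, 1]
      ny <- iy[v] + nb[, 2]
      nz <- iz[v] + nb[, 3]
      ok <- nx >= 1 & nx <= side & ny >= 1 & ny <= side & nz >= 1 & nz <= side
      f <- nx[ok] + (ny[ok] - 1L) * side + (nz[ok] - 1L) * side^2
      hit <- pos[f]
      hit <- hit[!is.na(hit)]
      hit <- hit[lab[hit] == 0L]
      if (length(hit)) {
        lab[hit] <- cur
        queue[qtail + seq_along(hit)] <- hit
        qtail <- qtail + length(hit)
      }
    }
  }
  lab
}

#' @export
print.pocket_prediction <- function(x, ...) {
  cat(sprintf(
    "<pocket_prediction> %d voxels, mean prob %.3f, center (%.2f, %.2f, %.2f)\n",
    x$n_voxels, x$mean_prob, x$center[1], x$center[2], x$center[3]
  ))
  invisible(x)
}

#' Tidy a list of pocket predictions into one row per pocket
#' @param x List of `pocket_prediction`s as returned by [extract_pockets()].
#' @param ... Unused.
#' @return Tibble with rank, n_voxels, mean_prob and center coordinates.
#' @export
tidy.pocket_prediction <- function(x, ...) {
  tibble::tibble(
    n_voxels = x$n_voxels, mean_prob = x$mean_prob,
    cx = x$center[1], cy = x$center[2], cz = x$center[3]
  )
}

#' Summarise pockets extracted from one probability grid
#' @param pockets List of `pocket_prediction`s.
#' @return Tibble, one row per pocket, ranked by mean probability.
#' @export
pockets_table <- function(pockets) {
  if (length(pockets) == 0) {
    return(tibble::tibble(
      rank = integer(), n_voxels = integer(), mean_prob = numeric(),
      cx = numeric(), cy = numeric(), cz = numeric()
    ))
  }
  dplyr::bind_rows(lapply(pockets, tidy.pocket_prediction), .id = "rank") |>
    dplyr::mutate(rank = as.integer(.data$rank))
}
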