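# Deterministic synthetic fixtures: toy helical proteins with chemically
# sane residue topology, binding-site / ligand point clouds, cleaning
# batches exercising every disposition branch, and probability grids with
# known pocket memberships. Every generator is a pure function of its
# seed/config and ships its own ground truth.

ring_coords <- function(center, normal = c(0, 0, 1), radius = 1.39, n = 6) {
  normal <- normal / sqrt(sum(normal^2))
  ref <- if (abs(normal[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * normal) * normal
  u <- u / sqrt(sum(u^2))
  v <- c(
    normal[2] * u[3] - normal[3] * u[2],
    normal[3] * u[1] - normal[1] * u[3],
    normal[1] * u[2] - normal[2] * u[1]
  )
  ang <- 2 * pi * (0:(n - 1)) / n
  t(vapply(ang, function(a) {
    center + radius * (cos(a) * u + sin(a) * v)
  }, numeric(3)))
}

# one template per residue: local coordinates around CA at the origin,
# intra-residue bonds with TRIPOS orders
residue_template <- function(code) {
  bb <- tibble::tibble(
    atom_name = c("N", "CA", "C", "O"),
    element = c("N", "C", "C", "O"),
    x = c(-1.46, 0, 0.76, 0.60),
    y = c(0, 0, 1.22, 2.42),
    z = c(0, 0, 0, 0.10)
  )
  bb_bonds <- tibble::tibble(
    from = c("N", "CA", "C"), to = c("CA", "C", "O"),
    type = c("1", "1", "2")
  )
  cb <- tibble::tibble(
    atom_name = "CB", element = "C", x = 0.53, y = -0.77, z = 1.21
  )
  side <- switch(code,
    G = list(atoms = NULL, bonds = NULL),
    A = list(atoms = cb, bonds = tibble::tibble(
      from = "CA", to = "CB", type = "1"
    )),
    S = list(
      atoms = dplyr::bind_rows(cb, tibble::tibble(
        atom_name = "OG", element = "O", x = 0.0, y = -1.75, z = 2.15
      )),
      bonds = tibble::tibble(
        from = c("CA", "CB"), to = c("CB", "OG"), type = c("1", "1")
      )
    ),
    V = list(
      atoms = dplyr::bind_rows(cb, tibble::tibble(
        atom_name = c("CG1", "CG2"), element = "C",
        x = c(0.0, 1.95), y = c(-1.80, -0.35), z = c(2.05, 1.85)
      )),
      bonds = tibble::tibble(
        from = c("CA", "CB", "CB"), to = c("CB", "CG1", "CG2"),
        type = "1"
      )
    ),
    T = list(
      atoms = dplyr::bind_rows(cb, tibble::tibble(
        atom_name = c("OG1", "CG2"), element = c("O", "C"),
        x = c(0.0, 1.95), y = c(-1.80, -0.35), z = c(2.05, 1.85)
      )),
      bonds = tibble::tibble(
        from = c("CA", "CB", "CB"), to = c("CB", "OG1", "CG2"),
        type = "1"
      )
    ),
    L = list(
      atoms = dplyr::bind_rows(cb, tibble::tibble(
        atom_name = c("CG", "CD1", "CD2"), element = "C",
        x = c(0.0, -0.10, 1.25), y = c(-1.70, -3.20, -1.35),
        z = c(2.10, 2.05, 3.05)
      )),
      bonds = tibble::tibble(
        from = c("CA", "CB", "CG", "CG"), to = c("CB", "CG", "CD1", "CD2"),
        type = "1"
      )
    ),
    D = list(
      atoms = dplyr::bind_rows(cb, tibble::tibble(
        atom_name = c("CG", "OD1", "OD2"), element = c("C", "O", "O"),
        x = c(0.0, -1.05, 1.15), y = c(-1.70, -2.40, -2.25),
        z = c(2.10, 2.30, 2.25)
      )),
      bonds = tibble::tibble(
        from = c("CA", "CB", "CG", "CG"), to = c("CB", "CG", "OD1", "OD2"),
        type = c("1", "1", "2", "1")
      )
    ),
    E = list(
      atoms = dplyr::bind_rows(cb, tibble::tibble(
        atom_name = c("CG", "CD", "OE1", "OE2"),
        element = c("C", "C", "O", "O"),
        x = c(0.0, 0.60, 0.0, 1.80), y = c(-1.70, -2.90, -4.00, -2.95),
        z = c(2.10, 2.90, 3.05, 3.40)
      )),
      bonds = tibble::tibble(
        from = c("CA", "CB", "CG", "CD", "CD"),
        to = c("CB", "CG", "CD", "OE1", "OE2"),
        type = c("1", "1", "1", "2", "1")
      )
    ),
    K = list(
      atoms = dplyr::bind_rows(cb, tibble::tibble(
        atom_name = c("CG", "CD", "CE", "NZ"),
        element = c("C", "C", "C", "N"),
        x = c(0.0, 0.60, 0.10, 0.70), y = c(-1.70, -2.90, -4.20, -5.35),
        z = c(2.10, 2.90, 3.30, 4.00)
      )),
      bonds = tibble::tibble(
        from = c("CA", "CB", "CG", "CD", "CE"),
        to = c("CB", "CG", "CD", "CE", "NZ"),
        type = "1"
      )
    ),
    F = {
      rc <- ring_coords(c(0.0, -2.55, 2.95), normal = c(1, 0.3, 0.4))
      ring <- tibble::tibble(
        atom_name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
        element = "C", x = rc[, 1], y = rc[, 2], z = rc[, 3]
      )
      list(
        atoms = dplyr::bind_rows(cb, ring),
        bonds = tibble::tibble(
          from = c("CA", "CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
          to = c("CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2", "CG"),
          type = c("1", "1", "ar", "ar", "ar", "ar", "ar", "ar")
        )
      )
    },
    abort(paste0("no template for residue code ", code))
  )
  name3 <- c(
    G = "GLY", A = "ALA", S = "SER", V = "VAL", T = "THR", L = "LEU",
    D = "ASP", E = "GLU", K = "LYS", F = "PHE"
  )[[code]]
  atoms <- dplyr::bind_rows(bb, side$atoms)
  atoms$residue_name <- name3
  list(atoms = atoms, bonds = dplyr::bind_rows(bb_bonds, side$bonds))
}

FIXTURE_ALPHABET <- c("G", "A", "S", "V", "T", "L", "D", "E", "K", "F")

#' Fixture generator configuration
#' @param n_residues Residues per chain.
#' @param n_chains Number of chains (chains beyond the first are placed
#'   ~40 A away so they never contact the site).
#' @param site_radius Radius of the binding-site point cloud in Angstroms.
#' @param seed RNG seed.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_residues = 20L, n_chains = 1L,
                           site_radius = 3, seed = 1L) {
  stopifnot(n_residues >= 3, n_chains >= 1, site_radius > 0)
  structure(
    list(
      n_residues = as.integer(n_residues), n_chains = as.integer(n_chains),
      site_radius = site_radius, seed = as.integer(seed)
    ),
    class = "fixture_config"
  )
}

build_chain_atoms <- function(sequence, chain_id, origin) {
  codes <- strsplit(sequence, "")[[1]]
  rows <- list()
  bonds <- list()
  offset <- 0L
  prev_c <- NA_integer_
  for (i in seq_along(codes)) {
    tpl <- residue_template(codes[i])
    # helix-like placement: CA along a coiled path
    theta <- (i - 1) * 100 * pi / 180
    ca <- origin + c(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * (i - 1))
    at <- tpl$atoms
    at$x <- at$x + ca[1]
    at$y <- at$y + ca[2]
    at$z <- at$z + ca[3]
    at$chain_id <- chain_id
    at$residue_index <- i
    at$atom_id <- offset + seq_len(nrow(at))
    rows[[i]] <- at
    b <- tpl$bonds
    b$from_id <- at$atom_id[match(b$from, at$atom_name)]
    b$to_id <- at$atom_id[match(b$to, at$atom_name)]
    bonds[[length(bonds) + 1]] <- b[, c("from_id", "to_id", "type")]
    if (!is.na(prev_c)) {
      bonds[[length(bonds) + 1]] <- tibble::tibble(
        from_id = prev_c, to_id = at$atom_id[at$atom_name == "N"],
        type = "am"
      )
    }
    prev_c <- at$atom_id[at$atom_name == "C"]
    offset <- offset + nrow(at)
  }
  list(
    atoms = dplyr::bind_rows(rows),
    bonds = dplyr::bind_rows(bonds)
  )
}

#' Generate a toy protein with binding site and ligand
#'
#' Emits a helix-like multi-chain structure built from residue templates
#' with real amino-acid topology (so featurization operates on sane
#' chemistry), a binding-site point cloud hugging a chosen residue of
#' chain A, a smaller ligand cloud inside it, and ground-truth metadata
#' (sequence, true centers, contact chain).
#'
#' @param config A [fixture_config()].
#' @return List: `structure` (`protein_structure`), `site` (`site_coords`),
#'   `ligand` (`site_coords`), `meta` (list with `sequences`,
#'   `site_chain`, `site_center`, `structure_center`).
#' @export
make_toy_protein <- function(config = fixture_config()) {
  set.seed(config$seed)
  chains <- LETTERS[seq_len(config$n_chains)]
  all_atoms <- list()
  all_bonds <- list()
  seqs <- character(config$n_chains)
  offset <- 0L
  for (ci in seq_along(chains)) {
    sequence <- paste(
      sample(FIXTURE_ALPHABET, config$n_residues, replace = TRUE),
      collapse = ""
    )
    seqs[ci] <- sequence
    origin <- c(40 * (ci - 1), 0, 0)
    built <- build_chain_atoms(sequence, chains[ci], origin)
    built$atoms$atom_id <- built$atoms$atom_id + offset
    built$bonds$from_id <- built$bonds$from_id + offset
    built$bonds$to_id <- built$bonds$to_id + offset
    all_atoms[[ci]] <- built$atoms
    all_bonds[[ci]] <- built$bonds
    offset <- offset + nrow(built$atoms)
  }
  atoms <- dplyr::bind_rows(all_atoms)
  atoms$atom_type <- NA_character_
  atoms$charge <- 0
  atoms$is_heavy <- TRUE
  atoms <- atoms[, c(
    "atom_id", "atom_name", "element", "x", "y", "z", "atom_type",
    "chain_id", "residue_name", "residue_index", "charge", "is_heavy"
  )]
  bonds <- dplyr::bind_rows(all_bonds)
  names(bonds) <- c("from", "to", "type")
  id <- sprintf("toy%04d", config$seed %% 10000)
  structure <- new_protein_structure(id, atoms, bonds)
  names(seqs) <- chains

  # binding site: cloud around a mid-chain CA of chain A, nudged outward
  mid <- ceiling(config$n_residues / 2)
  anchor <- atoms[atoms$chain_id == "A" & atoms$residue_index == mid &
    atoms$atom_name == "CA", ]
  pocket_center <- c(anchor$x, anchor$y, anchor$z) + c(2.5, 0, 0)
  n_pts <- 30L
  u <- matrix(rnorm(3 * n_pts), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  rad <- config$site_radius * runif(n_pts)^(1 / 3)
  pts <- sweep(u * rad, 2, pocket_center, "+")
  site <- site_coords(pts)
  lig_pts <- sweep(u[1:10, ] * rad[1:10] * 0.5, 2, pocket_center, "+")
  ligand <- site_coords(lig_pts)
  list(
    structure = structure, site = site, ligand = ligand,
    meta = list(
      sequences = seqs, site_chain = "A", site_center = pocket_center,
      structure_center = structure_center(structure)
    )
  )
}

#' Generate a cleaning batch with known dispositions
#'
#' Writes a batch of toy structure/site mol2 files to `dir`, including one
#' unparseable structure (truncated ATOM section), one same-UniProt
#' duplicate pair with near-identical sequences (same helix with one extra
#' terminal residue), and one structure whose site sits ~80 A from the
#' protein center. The expected disposition of every member is returned
#' alongside the batch.
#'
#' @param seed RNG seed.
#' @param dir Output directory (created if needed).
#' @return List: `batch` (tibble for [run_cleaning()]), `mapping`,
#'   `expected` (tibble structure_id/disposition), `mapping_path`.
#' @export
make_cleaning_batch <- function(seed = 1L, dir = tempfile("cleanbatch")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pair <- function(tp, id) {
    sp <- file.path(dir, paste0(id, ".mol2"))
    tp$structure$id <- id
    write_structure_mol2(tp$structure, sp)
    stp <- file.path(dir, paste0(id, "_site.mol2"))
    write_points_mol2(points_matrix(tp$site), stp, name = paste0(id, "_site"))
    c(structure = sp, site = stp)
  }
  # s1: valid singleton
  p1 <- write_pair(make_toy_protein(fixture_config(
    n_residues = 12, seed = seed
  )), "s1")
  # s2/s3: same-uniprot duplicates; s2 one residue longer -> representative
  base <- make_toy_protein(fixture_config(n_residues = 15, seed = seed + 1))
  seq2 <- paste0(base$meta$sequences[["A"]], "A")
  tp2 <- base
  b2 <- build_chain_atoms(seq2, "A", c(0, 0, 0))
  b2$atoms$atom_type <- NA_character_
  b2$atoms$charge <- 0
  b2$atoms$is_heavy <- TRUE
  names(b2$bonds) <- c("from", "to", "type")
  tp2$structure <- new_protein_structure("s2", b2$atoms, b2$bonds)
  p2 <- write_pair(tp2, "s2")
  p3 <- write_pair(base, "s3")
  # s4: distant site (80 A from the center)
  tp4 <- make_toy_protein(fixture_config(n_residues = 12, seed = seed + 2))
  ctr <- structure_center(tp4$structure)
  far <- sweep(matrix(rnorm(12), ncol = 3), 2, ctr + c(80, 0, 0), "+")
  tp4$site <- site_coords(far)
  p4 <- write_pair(tp4, "s4")
  # s5: truncated mol2 (header declares more atoms than present)
  tp5 <- make_toy_protein(fixture_config(n_residues = 10, seed = seed + 3))
  p5s <- file.path(dir, "s5.mol2")
  tp5$structure$id <- "s5"
  write_structure_mol2(tp5$structure, p5s)
  lines <- readLines(p5s)
  atom_beg <- grep("^@<TRIPOS>ATOM", lines)
  writeLines(lines[seq_len(atom_beg + 5)], p5s)
  p5t <- file.path(dir, "s5_site.mol2")
  write_points_mol2(points_matrix(tp5$site), p5t)
  # s6: valid singleton
  p6 <- write_pair(make_toy_protein(fixture_config(
    n_residues = 14, seed = seed + 4
  )), "s6")

  batch <- tibble::tibble(
    structure_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
    structure_path = c(p1["structure"], p2["structure"], p3["structure"],
      p4["structure"], p5s, p6["structure"]),
    site_path = c(p1["site"], p2["site"], p3["site"], p4["site"], p5t,
      p6["site"])
  )
  mapping <- tibble::tibble(
    structure_id = batch$structure_id,
    uniprot_id = c("U1", "U2", "U2", "U4", "U5", "U6")
  )
  mapping_path <- file.path(dir, "mapping.tsv")
  readr::write_tsv(mapping, mapping_path)
  expected <- tibble::tibble(
    structure_id = batch$structure_id,
    disposition = c("kept", "kept", "deduplicated", "dropped_distance",
      "dropped_parse", "kept")
  )
  list(
    batch = batch, mapping = mapping, expected = expected,
    mapping_path = mapping_path, dir = dir
  )
}

#' Generate a probability grid with known pocket memberships
#'
#' Places Gaussian blobs at the requested voxel centers over sub-threshold
#' uniform noise. The expected 26-connected components are derived from the
#' construction: each blob's super-threshold region, merged when regions
#' touch.
#'
#' @param pocket_specs Tibble/data frame with columns `cx, cy, cz` (1-based
#'   voxel indices), `radius` (voxels), and optionally `peak`
#'   (default 0.95).
#' @param noise_level Upper bound of the uniform background noise; clamped
#'   below `threshold`.
#' @param seed RNG seed.
#' @param spec A [grid_spec()].
#' @param threshold Threshold the expectation is built for (default 0.5).
#' @return List: `prob` (side^3 array), `expected` (list of integer vectors
#'   of flat voxel indices, one per expected pocket).
#' @export
make_probability_grid <- function(pocket_specs, noise_level = 0.2,
                                  seed = 1L, spec = grid_spec(),
                                  threshold = 0.5) {
  set.seed(seed)
  side <- spec$side
  noise_cap <- min(noise_level, threshold - 0.05)
  prob <- array(runif(side^3, 0, max(noise_cap, 0)), dim = rep(side, 3))
  pocket_specs <- tibble::as_tibble(pocket_specs)
  if (!"peak" %in% names(pocket_specs)) pocket_specs$peak <- 0.95
  coords <- expand.grid(x = 1:side, y = 1:side, z = 1:side)
  blob_sets <- list()
  for (i in seq_len(nrow(pocket_specs))) {
    ps <- pocket_specs[i, ]
    d2 <- (coords$x - ps$cx)^2 + (coords$y - ps$cy)^2 + (coords$z - ps$cz)^2
    field <- ps$peak * exp(-d2 / (2 * (ps$radius / 1.5)^2))
    prob <- pmax(prob, array(field, dim = rep(side, 3)))
    blob_sets[[i]] <- which(field > threshold)
  }
  # merge blobs whose super-threshold regions are 26-connected
  merged <- as.list(seq_along(blob_sets))
  if (length(blob_sets) > 1) {
    touching <- function(a, b) {
      ax <- (a - 1) %% side
      ay <- ((a - 1) %/% side) %% side
      az <- (a - 1) %/% side^2
      bx <- (b - 1) %% side
      by <- ((b - 1) %/% side) %% side
      bz <- (b - 1) %/% side^2
      for (i in seq_along(a)) {
        if (any(abs(ax[i] - bx) <= 1 & abs(ay[i] - by) <= 1 &
          abs(az[i] - bz) <= 1)) {
          return(TRUE)
        }
      }
      FALSE
    }
    g <- igraph::make_empty_graph(length(blob_sets), directed = FALSE)
    for (i in seq_along(blob_sets)) {
      for (j in seq_len(i - 1)) {
        if (touching(blob_sets[[i]], blob_sets[[j]])) {
          g <- igraph::add_edges(g, c(i, j))
        }
      }
    }
    comp <- igraph::components(g)$membership
    merged <- lapply(unique(comp), function(k) {
      sort(unique(unlist(blob_sets[comp == k])))
    })
  } else {
    merged <- lapply(blob_sets, sort)
  }
  merged <- merged[vapply(merged, length, 1L) > 0]
  list(prob = prob, expected = merged)
}

#' Write a complete toy dataset to disk
#'
#' Emits mol2 structures/sites/ligands and the UniProt mapping TSV for a
#' small deterministic dataset, ready for the command-line pipeline.
#'
#' @param dir Output directory.
#' @param seed RNG seed.
#' @param n_structures Number of toy proteins.
#' @return Invisibly, a tibble describing the written files.
#' @export
write_fixture_dataset <- function(dir, seed = 1L, n_structures = 3L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_len(n_structures)) {
    tp <- make_toy_protein(fixture_config(
      n_residues = 12 + i, seed = seed + i - 1
    ))
    id <- sprintf("toy%02d", i)
    tp$structure$id <- id
    sp <- file.path(dir, paste0(id, ".mol2"))
    write_structure_mol2(tp$structure, sp)
    st <- file.path(dir, paste0(id, "_site.mol2"))
    write_points_mol2(points_matrix(tp$site), st)
    lg <- file.path(dir, paste0(id, "_ligand.mol2"))
    write_points_mol2(points_matrix(tp$ligand), lg)
    rows[[i]] <- tibble::tibble(
      structure_id = id, structure_path = sp, site_path = st,
      ligand_path = lg, uniprot_id = sprintf("U%02d", i)
    )
  }
  files <- dplyr::bind_rows(rows)
  readr::write_tsv(
    files[, c("structure_id", "uniprot_id")],
    file.path(dir, "mapping.tsv")
  )
  invisible(files)
}
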