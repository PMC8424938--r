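# 18-channel atomic featurization. Chemical perception (atom typing,
# explicit hydrogens, Gasteiger partial charges, bond orders) is delegated
# to Open Babel; the pharmacophore-style flags are evaluated in R on the
# perceived molecular graph. Channel layout (frozen contract):
#   f1..f9  one-hot atom class: B, C, N, O, P, S, Se, halogen, metal
#   f10     hybridization (1, 2, or 3; 0 when undetermined)
#   f11     heavy-atom neighbor count
#   f12     heteroatom (non C/H) neighbor count
#   f13     Gasteiger partial charge (e)
#   f14..f18 binary flags: hydrophobic, aromatic, acceptor, donor, ring

HALOGENS <- c("F", "Cl", "Br", "I")

FEATURE_CHANNELS <- c(
  "class_B", "class_C", "class_N", "class_O", "class_P", "class_S",
  "class_Se", "class_halogen", "class_metal", "hybridization",
  "heavy_neighbors", "hetero_neighbors", "partial_charge",
  "hydrophobic", "aromatic", "acceptor", "donor", "ring"
)

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (p == "") {
    abort("Open Babel ('obabel') not found on PATH; required for featurization",
      class = "pocketgrid_backend_error"
    )
  }
  p
}

run_obabel <- function(args) {
  out <- suppressWarnings(
    system2(obabel_path(), args, stdout = TRUE, stderr = TRUE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    abort(paste0("obabel failed: ", paste(out, collapse = "\n")),
      class = "pocketgrid_backend_error"
    )
  }
  invisible(out)
}

#' Build the annotated molecule context used by featurization
#'
#' Writes the structure out, lets Open Babel add explicit hydrogens, assign
#' TRIPOS atom types and Gasteiger partial charges, and perceive bonds
#' (for PDB-derived structures without a bond table), then reads the result
#' back and attaches the bond graph.
#'
#' @param structure A `protein_structure`.
#' @return A `molecule_context`: list with `atoms` (tibble incl. perceived
#'   atom types and charges), `bonds`, and the igraph `graph`.
#' @export
molecule_context <- function(structure) {
  tmp_out <- tempfile(fileext = ".mol2")
  on.exit(unlink(tmp_out), add = TRUE)
  if (!is.null(structure$bonds) && nrow(structure$bonds) > 0) {
    tmp_in <- tempfile(fileext = ".mol2")
    on.exit(unlink(tmp_in), add = TRUE)
    write_structure_mol2(structure, tmp_in)
    infmt <- "-imol2"
  } else {
    tmp_in <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp_in), add = TRUE)
    write_structure_pdb(structure, tmp_in)
    infmt <- "-ipdb"
  }
  res <- tryCatch(
    run_obabel(c(
      infmt, tmp_in, "-omol2", "-O", tmp_out, "-h",
      "--partialcharge", "gasteiger"
    )),
    error = function(e) e
  )
  if (inherits(res, "error") || !file.exists(tmp_out)) {
    abort(
      sprintf("sanitization of structure '%s' failed: %s", structure$id,
        if (inherits(res, "error")) conditionMessage(res) else "no output"),
      class = "pocketgrid_backend_error"
    )
  }
  mol <- read_structure(tmp_out, format = "mol2", id = structure$id)
  at <- mol$atoms
  n_heavy_in <- sum(structure$atoms$is_heavy)
  n_heavy_out <- sum(at$is_heavy)
  if (n_heavy_out != n_heavy_in) {
    abort(
      sprintf(
        "sanitization of structure '%s' changed the heavy atom count (%d -> %d)",
        structure$id, n_heavy_in, n_heavy_out
      ),
      class = "pocketgrid_backend_error"
    )
  }
  bad <- !is.finite(at$charge)
  if (any(bad)) {
    warn(sprintf(
      "structure '%s': %d non-finite partial charges clamped to 0",
      structure$id, sum(bad)
    ))
    at$charge[bad] <- 0
  }
  g <- igraph::make_empty_graph(n = nrow(at), directed = FALSE)
  bonds <- mol$bonds
  if (!is.null(bonds) && nrow(bonds) > 0) {
    g <- igraph::add_edges(g, rbind(bonds$from, bonds$to))
  }
  structure(
    list(id = structure$id, atoms = at, bonds = bonds, graph = g),
    class = "molecule_context"
  )
}

hybridization_from_type <- function(atom_type, element) {
  suffix <- ifelse(grepl("\\.", atom_type),
    sub("^[^.]*\\.", "", atom_type), ""
  )
  h <- rep(0, length(atom_type))
  h[suffix == "1"] <- 1
  h[suffix %in% c("2", "ar", "am", "pl3", "cat", "co2")] <- 2
  h[suffix %in% c("3", "4", "t3h", "o", "o2", "th")] <- 3
  # bare types (ions, metals, unparameterized) stay 0
  h
}

ring_membership <- function(ctx) {
  n <- nrow(ctx$atoms)
  in_ring <- rep(FALSE, n)
  if (igraph::ecount(ctx$graph) == 0) return(in_ring)
  br <- igraph::bridges(ctx$graph)
  ring_edges <- setdiff(seq_len(igraph::ecount(ctx$graph)), br)
  if (length(ring_edges) > 0) {
    ends <- igraph::ends(ctx$graph, ring_edges)
    in_ring[unique(as.vector(ends))] <- TRUE
  }
  in_ring
}

#' Pharmacophore-style flags for one atom in a molecule context
#'
#' Evaluates membership of the five flag classes on the whole-molecule
#' graph: hydrophobic (carbon whose neighbors are all carbon or hydrogen),
#' aromatic (perceived aromatic atom type), acceptor (oxygen, or nitrogen
#' with a free lone pair: no attached hydrogen, not amide, at most two
#' heavy neighbors), donor (N/O/S with at least one attached hydrogen),
#' and ring (atom on any cycle of the bond graph).
#'
#' @param ctx A `molecule_context`.
#' @param atom_index Index into `ctx$atoms` (may be a vector).
#' @return Logical matrix with columns hydrophobic, aromatic, acceptor,
#'   donor, ring; one row per requested atom.
#' @export
smarts_flags <- function(ctx, atom_index) {
  stopifnot(inherits(ctx, "molecule_context"))
  n <- nrow(ctx$atoms)
  if (any(atom_index < 1 | atom_index > n)) {
    abort("atom_index out of range", class = "pocketgrid_domain_error")
  }
  ann <- context_annotations(ctx)
  ann[atom_index, c("hydrophobic", "aromatic", "acceptor", "donor", "ring"),
    drop = FALSE
  ] == 1
}

# full per-atom annotation matrix; cached on the context via attribute-free
# recompute (cheap relative to the obabel call)
context_annotations <- function(ctx) {
  at <- ctx$atoms
  n <- nrow(at)
  el <- at$element
  adj <- igraph::as_adj_list(ctx$graph)
  nb_el <- lapply(adj, function(v) el[as.integer(v)])
  n_h <- vapply(nb_el, function(e) sum(e == "H"), 1L)
  heavy_nb <- vapply(nb_el, function(e) sum(e != "H"), 1L)
  hetero_nb <- vapply(nb_el, function(e) sum(!e %in% c("C", "H")), 1L)
  arom <- grepl("\\.ar$", at$atom_type)
  amide_n <- grepl("^N\\.am$", at$atom_type)
  in_ring <- ring_membership(ctx)
  hydrophobic <- el == "C" &
    vapply(nb_el, function(e) all(e %in% c("C", "H")), TRUE)
  donor <- el %in% c("N", "O", "S") & n_h > 0
  acceptor <- (el == "O") |
    (el == "N" & n_h == 0 & !amide_n & heavy_nb <= 2)
  m <- cbind(
    hydrophobic = hydrophobic, aromatic = arom, acceptor = acceptor,
    donor = donor, ring = in_ring, n_h = n_h, heavy_neighbors = heavy_nb,
    hetero_neighbors = hetero_nb
  )
  m
}

element_class_onehot <- function(el) {
  classes <- c("B", "C", "N", "O", "P", "S", "Se")
  m <- matrix(0, nrow = length(el), ncol = 9)
  for (i in seq_along(classes)) m[el == classes[i], i] <- 1
  m[el %in% HALOGENS, 8] <- 1
  m[toupper(el) %in% METALS, 9] <- 1
  m
}

#' Featurize every heavy atom of a structure
#'
#' One 18-channel feature vector per heavy atom (hydrogens contribute to
#' their heavy neighbors' donor flags and charges but are never featurized
#' themselves). All channels are coordinate-free, so the features are
#' invariant under rigid-body motion of the structure.
#'
#' @param structure A `protein_structure`, or a prebuilt
#'   [molecule_context()].
#' @return Tibble with atom metadata, coordinates, and columns f1..f18.
#' @export
featurize_structure <- function(structure) {
  ctx <- if (inherits(structure, "molecule_context")) {
    structure
  } else {
    molecule_context(structure)
  }
  at <- ctx$atoms
  ann <- context_annotations(ctx)
  heavy <- which(at$is_heavy)
  onehot <- element_class_onehot(at$element[heavy])
  feats <- cbind(
    onehot,
    hybridization_from_type(at$atom_type[heavy], at$element[heavy]),
    ann[heavy, "heavy_neighbors"],
    ann[heavy, "hetero_neighbors"],
    at$charge[heavy],
    ann[heavy, "hydrophobic"],
    ann[heavy, "aromatic"],
    ann[heavy, "acceptor"],
    ann[heavy, "donor"],
    ann[heavy, "ring"]
  )
  colnames(feats) <- paste0("f", 1:18)
  out <- tibble::as_tibble(cbind(
    at[heavy, c("atom_id", "atom_name", "element", "chain_id",
      "residue_name", "residue_index", "x", "y", "z")],
    tibble::as_tibble(feats)
  ))
  attr(out, "channels") <- FEATURE_CHANNELS
  out
}

write_structure_pdb <- function(structure, path) {
  at <- structure$atoms
  xyz <- as.numeric(t(cbind(at$x, at$y, at$z)))
  bio3d::write.pdb(
    file = path, xyz = xyz, type = "ATOM",
    resno = at$residue_index, resid = at$residue_name,
    eleno = at$atom_id, elety = at$atom_name, chain = at$chain_id,
    elesy = at$element
  )
  invisible(path)
}
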