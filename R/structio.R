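# Structure I/O: TRIPOS mol2 + PDB reading, mol2 writing, sequences, centers.
# Parsing is delegated to bio3d; this layer normalizes both formats into one
# tidy atom table and validates what the parsers let through.

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

METALS <- c(
  "LI", "NA", "K", "RB", "CS", "BE", "MG", "CA", "SR", "BA", "AL",
  "MN", "FE", "CO", "NI", "CU", "ZN", "CD", "HG", "CR", "MO", "W",
  "V", "TI", "AG", "AU", "PT", "PD", "RU", "RH", "IR", "OS", "PB",
  "SN", "GA", "IN", "TL", "BI", "SB"
)

parse_error <- function(msg, path = NULL, line = NULL) {
  abort(
    paste0(
      "Failed to parse structure",
      if (!is.null(path)) paste0(" '", path, "'"),
      if (!is.null(line)) paste0(" (near line ", line, ")"),
      ": ", msg
    ),
    class = "pocketgrid_parse_error", path = path, line = line
  )
}

new_protein_structure <- function(id, atoms, bonds = NULL) {
  stopifnot(is.data.frame(atoms))
  atoms <- tibble::as_tibble(atoms)
  structure(
    list(id = id, atoms = atoms, bonds = bonds),
    class = "protein_structure"
  )
}

#' @export
print.protein_structure <- function(x, ...) {
  sq <- protein_sequences(x)
  cat(
    "<protein_structure> ", x$id, ": ", nrow(x$atoms), " atoms, ",
    length(sq), " chain(s), ", sum(nchar(sq)), " residues\n",
    sep = ""
  )
  invisible(x)
}

element_from_type <- function(atom_type, atom_name) {
  el <- sub("\\..*$", "", atom_type)
  bad <- is.na(el) | el == "" | el == "Du" | el == "Any"
  if (any(bad)) {
    guess <- sub("[^A-Za-z].*$", "", atom_name[bad])
    guess <- sub("^([A-Z][a-z]?).*$", "\\1", guess)
    el[bad] <- guess
  }
  # normalise case: "CL"/"cl" -> "Cl"
  paste0(
    toupper(substr(el, 1, 1)),
    tolower(substr(el, 2, nchar(el)))
  )
}

# chain map from the raw @<TRIPOS>SUBSTRUCTURE section (bio3d drops it on
# some files); returns named vector subst_id -> chain or NULL
mol2_chain_map <- function(lines) {
  beg <- grep("^@<TRIPOS>SUBSTRUCTURE", lines)
  if (length(beg) == 0) return(NULL)
  beg <- beg[1] + 1
  end <- grep("^@<TRIPOS>", lines)
  end <- end[end >= beg]
  end <- if (length(end)) min(end) - 1 else length(lines)
  if (end < beg) return(NULL)
  rows <- lines[beg:end]
  rows <- rows[nzchar(trimws(rows))]
  if (!length(rows)) return(NULL)
  tok <- strsplit(trimws(rows), "\\s+")
  ids <- vapply(tok, function(t) t[1], "")
  chains <- vapply(tok, function(t) {
    ch <- if (length(t) >= 6) t[6] else NA_character_
    if (is.na(ch) || ch %in% c("****", "*")) NA_character_ else ch
  }, "")
  setNames(chains, ids)
}

read_mol2_structure <- function(path, id) {
  m <- tryCatch(
    suppressWarnings(bio3d::read.mol2(path)),
    error = function(e) parse_error(conditionMessage(e), path)
  )
  at <- m$atom
  if (is.null(at) || nrow(at) == 0) parse_error("no atoms found", path)
  declared <- suppressWarnings(as.integer(m$info[1]))
  if (!is.na(declared) && declared != nrow(at)) {
    parse_error(
      sprintf(
        "ATOM section has %d records but the header declares %d",
        nrow(at), declared
      ),
      path
    )
  }
  if (!all(is.finite(at$x) & is.finite(at$y) & is.finite(at$z))) {
    parse_error("non-finite atom coordinates", path)
  }
  chain_map <- mol2_chain_map(readLines(path, warn = FALSE))
  chain <- if (!is.null(chain_map)) {
    unname(chain_map[as.character(at$resno)])
  } else {
    rep(NA_character_, nrow(at))
  }
  chain[is.na(chain)] <- "A"
  el <- element_from_type(at$elety, at$elena)
  res_name <- toupper(sub("[0-9'].*$", "", at$resid))
  res_name[res_name == ""] <- "UNK"
  bonds <- NULL
  if (!is.null(m$bond) && nrow(m$bond) > 0) {
    bonds <- tibble::tibble(
      from = as.integer(m$bond$origin),
      to = as.integer(m$bond$target),
      type = as.character(m$bond$type)
    )
  }
  atoms <- tibble::tibble(
    atom_id = as.integer(at$eleno),
    atom_name = as.character(at$elena),
    element = el,
    x = at$x, y = at$y, z = at$z,
    atom_type = as.character(at$elety),
    chain_id = chain,
    residue_name = res_name,
    residue_index = as.integer(at$resno),
    charge = ifelse(is.na(at$charge), 0, at$charge),
    is_heavy = toupper(el) != "H"
  )
  new_protein_structure(id, atoms, bonds)
}

read_pdb_structure <- function(path, id) {
  p <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path)),
    error = function(e) parse_error(conditionMessage(e), path)
  )
  at <- p$atom
  if (is.null(at) || nrow(at) == 0) parse_error("no atoms found", path)
  el <- at$elesy
  miss <- is.na(el) | el == ""
  el[miss] <- sub("^([A-Za-z]).*$", "\\1", at$elety[miss])
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  atoms <- tibble::tibble(
    atom_id = as.integer(at$eleno),
    atom_name = as.character(at$elety),
    element = el,
    x = at$x, y = at$y, z = at$z,
    atom_type = NA_character_,
    chain_id = chain,
    residue_name = toupper(as.character(at$resid)),
    residue_index = as.integer(at$resno),
    charge = 0,
    is_heavy = toupper(el) != "H"
  )
  new_protein_structure(id, atoms, bonds = NULL)
}

#' Read a protein structure from mol2 or PDB
#'
#' Parses a TRIPOS mol2 or PDB file into a `protein_structure`: a tidy atom
#' table (one row per atom, with element, coordinates, chain, residue and
#' partial charge where the file carries one) plus the bond table for mol2
#' input. Hydrogens are retained but flagged `is_heavy = FALSE`.
#'
#' @param path Path to the structure file.
#' @param format `"pdb"` or `"mol2"`; defaults to the file extension.
#' @param id Structure identifier; defaults to the file base name.
#' @return A `protein_structure` object. Its `atoms` element is a tibble.
#' @export
read_structure <- function(path, format = c("auto", "mol2", "pdb"),
                           id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "pocketgrid_io_error")
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "auto") {
    ext <- tolower(sub("^.*\\.", "", path))
    format <- if (ext == "pdb") "pdb" else "mol2"
  }
  switch(format,
    mol2 = read_mol2_structure(path, id),
    pdb = read_pdb_structure(path, id)
  )
}

#' Per-chain amino-acid sequences of a structure
#'
#' Residues are ordered by residue index within each chain; standard 3-letter
#' codes map to 1-letter codes and anything else (hetero residues, modified
#' amino acids) maps to `"X"`.
#'
#' @param structure A `protein_structure`.
#' @return Named character vector, one sequence per chain.
#' @export
protein_sequences <- function(structure) {
  at <- structure$atoms
  res <- dplyr::distinct(
    at, .data$chain_id, .data$residue_index, .data$residue_name
  )
  res <- dplyr::arrange(res, .data$chain_id, .data$residue_index)
  sp <- split(res, res$chain_id)
  vapply(sp, function(d) {
    aa <- AA3TO1[d$residue_name]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, "")
}

#' Number of residues across all retained chains
#' @param structure A `protein_structure`.
#' @return Integer residue count.
#' @export
n_residues <- function(structure) {
  sum(nchar(protein_sequences(structure)))
}

#' Geometric center of a structure
#'
#' Unweighted arithmetic mean of the heavy-atom coordinates, the reference
#' point at which the voxel grid is placed and from which the binding-site
#' distance filter measures.
#'
#' @param structure A `protein_structure` with at least one heavy atom.
#' @return Numeric 3-vector (x, y, z) in Angstroms.
#' @export
structure_center <- function(structure) {
  at <- dplyr::filter(structure$atoms, .data$is_heavy)
  if (nrow(at) == 0) {
    abort("structure has no heavy atoms", class = "pocketgrid_domain_error")
  }
  c(x = mean(at$x), y = mean(at$y), z = mean(at$z))
}

new_site_coords <- function(points) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("x", "y", "z") %in% names(points)))
  if (nrow(points) == 0) {
    abort("site has no points", class = "pocketgrid_domain_error")
  }
  if (!all(is.finite(points$x) & is.finite(points$y) & is.finite(points$z))) {
    abort("site coordinates must be finite",
      class = "pocketgrid_domain_error"
    )
  }
  structure(points, class = c("site_coords", class(tibble::tibble())))
}

#' Read binding-site or ligand coordinates from a mol2 file
#'
#' All atom positions in the file become site points; chemistry is ignored.
#'
#' @param path Path to a mol2 file with at least one atom record.
#' @return A `site_coords` tibble with columns x, y, z (Angstroms).
#' @export
read_site <- function(path) {
  s <- read_structure(path, format = "mol2")
  new_site_coords(s$atoms[, c("x", "y", "z")])
}

#' Construct site coordinates from a matrix or data frame
#' @param points Matrix or data frame with 3 columns (x, y, z).
#' @return A `site_coords` tibble.
#' @export
site_coords <- function(points) {
  if (is.matrix(points)) {
    points <- tibble::tibble(
      x = points[, 1], y = points[, 2], z = points[, 3]
    )
  }
  new_site_coords(points)
}

points_matrix <- function(site) {
  cbind(x = site$x, y = site$y, z = site$z)
}

fmt_mol2_num <- function(v) formatC(v, format = "f", digits = 4)

#' Write a point cloud as a TRIPOS mol2 file
#'
#' One dummy atom (`Du`) per point, coordinates at 4 decimals; the standard
#' vehicle for exporting predicted pocket voxel centers so they can be
#' overlaid on the protein in a molecular viewer.
#'
#' @param points A `site_coords` tibble, matrix, or data frame of x/y/z.
#' @param path Output path.
#' @param name Molecule name written to the header.
#' @return Invisibly, `path`.
#' @export
write_points_mol2 <- function(points, path, name = "pocket") {
  if (is.matrix(points) || !inherits(points, "site_coords")) {
    points <- site_coords(points)
  }
  n <- nrow(points)
  lines <- c(
    "@<TRIPOS>MOLECULE", name,
    sprintf("%5d %5d %5d %5d %5d", n, 0L, 1L, 0L, 0L),
    "SMALL", "NO_CHARGES", "", "@<TRIPOS>ATOM",
    sprintf(
      "%7d %-8s %10s %10s %10s %-5s %5d %-8s %10s",
      seq_len(n), paste0("DU", seq_len(n)),
      fmt_mol2_num(points$x), fmt_mol2_num(points$y), fmt_mol2_num(points$z),
      "Du", 1L, "PKT1", "0.0000"
    ),
    "@<TRIPOS>SUBSTRUCTURE",
    sprintf("%6d %-8s %6d %-8s %6d %-2s", 1L, "PKT1", 1L, "GROUP", 1L, "A")
  )
  tryCatch(
    writeLines(lines, path),
    error = function(e) {
      abort(paste0("Cannot write mol2 to '", path, "': ",
        conditionMessage(e)), class = "pocketgrid_io_error")
    }
  )
  invisible(path)
}

mol2_type_for <- function(element, atom_type) {
  ifelse(!is.na(atom_type) & atom_type != "", atom_type, element)
}

#' Write a protein structure as a TRIPOS mol2 file
#'
#' Atoms keep their stored mol2 atom types when present (element symbol
#' otherwise), bonds are written when the structure carries a bond table,
#' and chain assignment is preserved through the SUBSTRUCTURE section.
#'
#' @param structure A `protein_structure`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_structure_mol2 <- function(structure, path) {
  at <- structure$atoms
  n <- nrow(at)
  res_key <- paste(at$chain_id, at$residue_index, sep = "|")
  subst <- dplyr::distinct(
    at, .data$chain_id, .data$residue_index, .data$residue_name
  )
  subst_key <- paste(subst$chain_id, subst$residue_index, sep = "|")
  subst_id <- match(res_key, subst_key)
  res_label <- paste0(subst$residue_name, subst$residue_index)
  nb <- if (is.null(structure$bonds)) 0L else nrow(structure$bonds)
  lines <- c(
    "@<TRIPOS>MOLECULE", structure$id,
    sprintf("%5d %5d %5d %5d %5d", n, nb, nrow(subst), 0L, 0L),
    "PROTEIN", "USER_CHARGES", "", "@<TRIPOS>ATOM",
    sprintf(
      "%7d %-8s %10s %10s %10s %-6s %5d %-9s %10s",
      seq_len(n), at$atom_name,
      fmt_mol2_num(at$x), fmt_mol2_num(at$y), fmt_mol2_num(at$z),
      mol2_type_for(at$element, at$atom_type),
      subst_id, res_label[subst_id], fmt_mol2_num(at$charge)
    )
  )
  if (nb > 0) {
    b <- structure$bonds
    lines <- c(
      lines, "@<TRIPOS>BOND",
      sprintf("%6d %5d %5d %4s", seq_len(nb), b$from, b$to, b$type)
    )
  }
  lines <- c(
    lines, "@<TRIPOS>SUBSTRUCTURE",
    sprintf(
      "%6d %-9s %6d %-8s %6d %-2s",
      seq_len(nrow(subst)), res_label,
      match(subst_key, res_key), "RESIDUE", 1L, subst$chain_id
    )
  )
  writeLines(lines, path)
  invisible(path)
}
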