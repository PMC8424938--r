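# Structural-similarity data cleaning: k-mer MACCS fingerprints, pooled and
# sliding-window Tanimoto similarity, UniProt clustering with
# longest-sequence representatives, binding-site chain retention, and the
# 70 A site-distance filter, composed into one batch pipeline.

# Side-chain SMILES fragments attached to the alpha carbon. Tripeptides are
# built with neutral free termini (N-terminal NH2, C-terminal COOH), no
# stereochemistry: MACCS keys are substructure patterns and do not see
# chirality.
AA_SIDE_SMILES <- c(
  A = "C", R = "CCCNC(N)=N", N = "CC(N)=O", D = "CC(O)=O", C = "CS",
  Q = "CCC(N)=O", E = "CCC(O)=O", G = "", H = "Cc1c[nH]cn1", I = "C(C)CC",
  L = "CC(C)C", K = "CCCCN", M = "CCSC", F = "Cc1ccccc1", P = NA,
  S = "CO", T = "C(O)C", W = "Cc1c[nH]c2ccccc12", Y = "Cc1ccc(O)cc1",
  V = "C(C)C"
)

#' Consecutive k-mers of a sequence
#'
#' All substrings of length `k` at stride 1; a length-N sequence yields
#' N - k + 1 of them.
#'
#' @param sequence Amino-acid string of length at least `k`.
#' @param k Substring length (default 3).
#' @return Character vector of k-mers in sequence order.
#' @export
kmers <- function(sequence, k = 3L) {
  n <- nchar(sequence)
  if (n < k) {
    abort(
      sprintf("sequence of length %d is shorter than k = %d", n, k),
      class = "pocketgrid_domain_error"
    )
  }
  vapply(seq_len(n - k + 1), function(i) substr(sequence, i, i + k - 1), "")
}

#' SMILES of a tripeptide (or longer peptide) from 1-letter codes
#'
#' Each residue becomes one backbone unit N-CA(side chain)-C(=O); proline
#' closes its pyrrolidine ring onto the backbone nitrogen. Termini are left
#' neutral (NH2 / COOH).
#'
#' @param peptide 1-letter amino-acid string.
#' @return A SMILES string.
#' @export
peptide_smiles <- function(peptide) {
  aas <- strsplit(peptide, "")[[1]]
  units <- vapply(aas, function(a) {
    if (a == "P") return("N9CCCC9C(=O)")
    side <- AA_SIDE_SMILES[a]
    if (is.na(side) || !a %in% names(AA_SIDE_SMILES)) {
      abort(
        sprintf("residue '%s' in k-mer '%s' cannot be mapped to a molecule",
          a, peptide),
        class = "pocketgrid_domain_error"
      )
    }
    if (side == "") "NCC(=O)" else paste0("NC(", side, ")C(=O)")
  }, "")
  paste0(paste(units, collapse = ""), "O")
}

# package-level cache: 3-mer -> 167-bit row
.fp_cache <- new.env(parent = emptyenv())

maccs_bits_for_kmers <- function(kms) {
  miss <- kms[!vapply(kms, exists, TRUE, envir = .fp_cache)]
  miss <- unique(miss)
  if (length(miss) > 0) {
    smis <- vapply(miss, peptide_smiles, "")
    mols <- ChemmineOB::forEachMol(
      "SMILES", paste(smis, collapse = "\n"), identity
    )
    fp <- ChemmineOB::fingerprint_OB(mols, "MACCS")
    if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1)
    if (nrow(fp) != length(miss)) {
      abort("fingerprint backend returned an unexpected number of molecules",
        class = "pocketgrid_backend_error"
      )
    }
    for (i in seq_along(miss)) {
      # OpenBabel sets key b at column b of its 256-wide block; keep the
      # standard 167-slot layout (slot 1 = unused key 0, slots 2:167 =
      # keys 1:166).
      row <- c(0L, as.integer(fp[i, 1:166]))
      assign(miss[i], row, envir = .fp_cache)
    }
  }
  do.call(rbind, lapply(kms, get, envir = .fp_cache))
}

#' k-mer MACCS fingerprint matrix of a protein sequence
#'
#' Every 3-mer of the sequence is embodied as a tripeptide molecule and
#' fingerprinted with 167-bit MACCS keys, giving an (N - 2) x 167 bit
#' matrix whose row r is the key of 3-mer r.
#'
#' @param sequence Amino-acid string, length >= 3.
#' @param k k-mer length (default 3).
#' @return A `fingerprint_matrix`: 0/1 integer matrix with one row per k-mer
#'   and 167 columns.
#' @export
fingerprint_matrix <- function(sequence, k = 3L) {
  kms <- kmers(sequence, k)
  bits <- maccs_bits_for_kmers(kms)
  rownames(bits) <- NULL
  structure(bits, class = c("fingerprint_matrix", "matrix", "array"))
}

#' Tanimoto similarity of two equal-length fingerprint matrices
#'
#' By default the matrices are pooled row-aligned into one long bit vector
#' each and the Tanimoto (Jaccard) index of the on-bit sets is returned
#' (`method = "pooled"`, the pipeline's reading). `method = "rowmean"`
#' instead averages the per-row (per-k-mer) Tanimoto indices, a variant
#' kept for sensitivity checks. Two all-zero vectors are identical objects
#' and score 1 under either method.
#'
#' @param a1,a2 Bit matrices with equal row counts.
#' @param method `"pooled"` (default) or `"rowmean"`.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto_equal <- function(a1, a2, method = c("pooled", "rowmean")) {
  method <- match.arg(method)
  if (nrow(a1) != nrow(a2)) {
    abort("fingerprint matrices differ in length; use sliding_tanimoto()",
      class = "pocketgrid_domain_error"
    )
  }
  jac <- function(x, y) {
    u <- sum(x | y)
    if (u == 0) return(1)
    sum(x & y) / u
  }
  if (method == "pooled") {
    return(jac(as.logical(a1), as.logical(a2)))
  }
  mean(vapply(seq_len(nrow(a1)), function(r) {
    jac(as.logical(a1[r, ]), as.logical(a2[r, ]))
  }, 1.0))
}

#' Sliding-window maximum Tanimoto similarity
#'
#' Equal-length inputs reduce to [tanimoto_equal()]. Otherwise a window of
#' the shorter matrix's row count slides along the longer one at stride 1
#' and the maximum windowed Tanimoto index is returned.
#'
#' @param a1,a2 Non-empty bit matrices (rows = k-mers, columns = key bits).
#' @param method Passed to [tanimoto_equal()].
#' @return Similarity in \[0, 1\].
#' @export
sliding_tanimoto <- function(a1, a2, method = c("pooled", "rowmean")) {
  method <- match.arg(method)
  if (nrow(a1) == 0 || nrow(a2) == 0) {
    abort("fingerprint matrices must be non-empty",
      class = "pocketgrid_domain_error"
    )
  }
  if (nrow(a1) == nrow(a2)) return(tanimoto_equal(a1, a2, method))
  if (nrow(a1) < nrow(a2)) {
    short <- a1
    long <- a2
  } else {
    short <- a2
    long <- a1
  }
  w <- nrow(short)
  best <- 0
  for (s in 0:(nrow(long) - w)) {
    best <- max(best, tanimoto_equal(short, long[s + seq_len(w), ,
      drop = FALSE
    ], method))
  }
  best
}

#' Group structures into clusters by UniProt accession
#'
#' @param structures Tibble with columns `structure_id` and `sequence`.
#' @param mapping Tibble with columns `structure_id` and `uniprot_id`; every
#'   structure must be mapped.
#' @return Tibble of cluster members: uniprot_id, structure_id, sequence.
#' @export
cluster_by_uniprot <- function(structures, mapping) {
  miss <- setdiff(structures$structure_id, mapping$structure_id)
  if (length(miss) > 0) {
    abort(
      paste0("structures missing from the UniProt mapping: ",
        paste(miss, collapse = ", ")),
      class = "pocketgrid_domain_error"
    )
  }
  dplyr::inner_join(structures, mapping, by = "structure_id") |>
    dplyr::select("uniprot_id", "structure_id", "sequence") |>
    dplyr::arrange(.data$uniprot_id, .data$structure_id)
}

#' Select the representative structure of one cluster
#'
#' The member with the longest sequence wins; ties break to the
#' lexicographically smallest structure id. The cluster's mean pairwise
#' sliding Tanimoto similarity is reported along with a warning flag when
#' it falls below `similarity_threshold` (singletons score 1).
#'
#' @param members Tibble with columns `structure_id` and `sequence`.
#' @param similarity_threshold Mean-similarity warning cutoff (default 0.8).
#' @return One-row tibble: structure_id, n_members, mean_tanimoto,
#'   below_threshold.
#' @export
select_representative <- function(members, similarity_threshold = 0.8) {
  stopifnot(nrow(members) >= 1)
  ord <- order(-nchar(members$sequence), members$structure_id)
  rep_id <- members$structure_id[ord[1]]
  n <- nrow(members)
  if (n == 1) {
    mean_tan <- 1
  } else {
    fps <- lapply(members$sequence, fingerprint_matrix)
    pairs <- utils::combn(n, 2)
    sims <- apply(pairs, 2, function(p) {
      sliding_tanimoto(fps[[p[1]]], fps[[p[2]]])
    })
    mean_tan <- mean(sims)
  }
  tibble::tibble(
    structure_id = rep_id, n_members = n, mean_tanimoto = mean_tan,
    below_threshold = mean_tan < similarity_threshold
  )
}

#' Keep / drop decision for the binding-site distance filter
#'
#' A structure is dropped when any site point lies strictly farther than
#' `max_site_dist` from the protein center: such a site cannot be
#' represented inside the voxel box.
#'
#' @param structure A `protein_structure`.
#' @param site A `site_coords` tibble.
#' @param max_site_dist Distance cutoff in Angstroms (default 70).
#' @return `"keep"` or `"drop"`.
#' @export
filter_distant_site <- function(structure, site, max_site_dist = 70) {
  ctr <- structure_center(structure)
  d <- sqrt(rowSums(sweep(points_matrix(site), 2, ctr)^2))
  if (any(d > max_site_dist)) "drop" else "keep"
}

#' Retain only the chains in contact with the binding site
#'
#' Keeps chains having at least one heavy atom within `contact_cutoff` of
#' any site point — the automated stand-in for the manual retain-the-chain
#' inspection step. Structures with no contacting chain raise a structured
#' error so they can be flagged for review rather than silently dropped.
#'
#' @param structure A `protein_structure`.
#' @param site A `site_coords` tibble.
#' @param contact_cutoff Contact distance in Angstroms (default 4).
#' @return A `protein_structure` containing only the contacting chains.
#' @export
retain_site_chains <- function(structure, site, contact_cutoff = 4) {
  at <- dplyr::filter(structure$atoms, .data$is_heavy)
  pts <- points_matrix(site)
  keep_chain <- vapply(split(at, at$chain_id), function(d) {
    m <- cbind(d$x, d$y, d$z)
    # min distance chain <-> site
    for (i in seq_len(nrow(pts))) {
      dd <- sqrt(rowSums(sweep(m, 2, pts[i, ])^2))
      if (any(dd <= contact_cutoff)) return(TRUE)
    }
    FALSE
  }, TRUE)
  chains <- names(keep_chain)[keep_chain]
  if (length(chains) == 0) {
    abort(
      sprintf(
        "structure '%s': no chain within %.1f A of the site; flagged for manual review",
        structure$id, contact_cutoff
      ),
      class = "pocketgrid_no_contact_error"
    )
  }
  atoms <- dplyr::filter(structure$atoms, .data$chain_id %in% chains)
  bonds <- structure$bonds
  if (!is.null(bonds)) {
    keep_atom <- structure$atoms$chain_id %in% chains
    new_id <- cumsum(keep_atom)
    bonds <- dplyr::filter(bonds, keep_atom[.data$from] & keep_atom[.data$to])
    bonds$from <- new_id[bonds$from]
    bonds$to <- new_id[bonds$to]
  }
  atoms$atom_id <- seq_len(nrow(atoms))
  new_protein_structure(structure$id, atoms, bonds)
}

#' Run the full data-cleaning pipeline on a batch
#'
#' Applies, in order: parse-failure removal, UniProt clustering,
#' longest-sequence representative selection (other members are marked
#' `deduplicated`), site-chain retention, and the site-distance filter.
#' Per-structure failures are recorded, never aborting the batch.
#'
#' @param batch Tibble with columns `structure_id`, `structure_path`,
#'   `site_path`.
#' @param mapping Tibble with columns `structure_id`, `uniprot_id`.
#' @param similarity_threshold Cluster mean-similarity warning cutoff.
#' @param max_site_dist Site-distance cutoff in Angstroms (default 70).
#' @param contact_cutoff Chain-contact cutoff in Angstroms (default 4).
#' @return A list with `report` (tibble: structure_id, disposition, uniprot_id,
#'   flagged, note — dispositions partition the batch), `clusters` (tibble
#'   from [select_representative()] per cluster), and `retained` (named list
#'   of cleaned `protein_structure` objects).
#' @export
run_cleaning <- function(batch, mapping, similarity_threshold = 0.8,
                         max_site_dist = 70, contact_cutoff = 4) {
  report <- tibble::tibble(
    structure_id = character(), disposition = character(),
    uniprot_id = character(), flagged = logical(), note = character()
  )
  if (nrow(batch) == 0) {
    return(list(report = report, clusters = tibble::tibble(),
      retained = list()))
  }
  disposition <- setNames(rep(NA_character_, nrow(batch)),
    batch$structure_id)
  flagged <- setNames(rep(FALSE, nrow(batch)), batch$structure_id)
  note <- setNames(rep(NA_character_, nrow(batch)), batch$structure_id)

  structures <- list()
  sites <- list()
  for (i in seq_len(nrow(batch))) {
    id <- batch$structure_id[i]
    res <- tryCatch(
      {
        s <- read_structure(batch$structure_path[i])
        s$id <- id
        list(structure = s, site = read_site(batch$site_path[i]))
      },
      error = function(e) e
    )
    if (inherits(res, "error")) {
      disposition[id] <- "dropped_parse"
      note[id] <- conditionMessage(res)
    } else {
      structures[[id]] <- res$structure
      sites[[id]] <- res$site
    }
  }

  seq_tbl <- tibble::tibble(
    structure_id = names(structures),
    sequence = vapply(structures, function(s) {
      paste(protein_sequences(s), collapse = "")
    }, "")
  )
  clusters_tbl <- tibble::tibble()
  if (nrow(seq_tbl) > 0) {
    clustered <- cluster_by_uniprot(seq_tbl, mapping)
    clusters_tbl <- clustered |>
      dplyr::group_by(.data$uniprot_id) |>
      dplyr::group_modify(~ select_representative(.x,
        similarity_threshold)) |>
      dplyr::ungroup()
    for (uid in unique(clustered$uniprot_id)) {
      members <- clustered$structure_id[clustered$uniprot_id == uid]
      rep_id <- clusters_tbl$structure_id[clusters_tbl$uniprot_id == uid]
      for (m in members) {
        if (m != rep_id) {
          disposition[m] <- "deduplicated"
          note[m] <- paste0("cluster ", uid, " represented by ", rep_id)
        }
      }
    }
    uid_of <- setNames(clustered$uniprot_id, clustered$structure_id)
  } else {
    uid_of <- character()
  }

  retained <- list()
  for (id in names(structures)) {
    if (!is.na(disposition[id])) next
    s <- structures[[id]]
    st <- sites[[id]]
    s2 <- tryCatch(
      retain_site_chains(s, st, contact_cutoff),
      pocketgrid_no_contact_error = function(e) e
    )
    if (inherits(s2, "error")) {
      flagged[id] <- TRUE
      note[id] <- conditionMessage(s2)
      s2 <- s
    }
    if (filter_distant_site(s2, st, max_site_dist) == "drop") {
      disposition[id] <- "dropped_distance"
      note[id] <- sprintf("site beyond %.0f A of the protein center",
        max_site_dist)
      next
    }
    disposition[id] <- "kept"
    retained[[id]] <- s2
  }

  report <- tibble::tibble(
    structure_id = batch$structure_id,
    disposition = unname(disposition[batch$structure_id]),
    uniprot_id = unname(uid_of[batch$structure_id]),
    flagged = unname(flagged[batch$structure_id]),
    note = unname(note[batch$structure_id])
  )
  list(report = report, clusters = clusters_tbl, retained = retained)
}
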