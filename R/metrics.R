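# Evaluation suite: DCC, success rate, DVO, PLI, and the TP/FP/FN -> F1
# protocol. One actual site per structure; a structure with no extracted
# pocket is a false negative, a nearest pocket within 4 A of the site
# center is a true positive, anything else a false positive.

#' Distance between predicted and actual site centers (DCC)
#' @param pred_center,actual_center Numeric 3-vectors, Angstroms.
#' @return Euclidean distance in Angstroms.
#' @export
dcc <- function(pred_center, actual_center) {
  stopifnot(
    length(pred_center) == 3, length(actual_center) == 3,
    all(is.finite(pred_center)), all(is.finite(actual_center))
  )
  sqrt(sum((as.numeric(pred_center) - as.numeric(actual_center))^2))
}

#' Success rate: fraction of sites with DCC at or under a threshold
#'
#' Records without any prediction (DCC `NA`) count in the denominator and
#' never in the numerator.
#'
#' @param records Tibble of evaluation records with a `dcc` column
#'   (`NA` = no prediction).
#' @param threshold DCC cutoff in Angstroms (default 4).
#' @return Fraction in \[0, 1\].
#' @export
success_rate <- function(records, threshold = 4) {
  if (nrow(records) == 0) {
    abort("no evaluation records", class = "pocketgrid_domain_error")
  }
  mean(!is.na(records$dcc) & records$dcc <= threshold)
}

as_voxel_flat <- function(x) {
  if (inherits(x, "pocket_prediction")) return(x$flat)
  if (inherits(x, "site_mask")) return(which(x$tensor > 0))
  if (is.array(x) || is.numeric(x)) return(which(x > 0))
  abort("expected a pocket_prediction, site_mask, or 0/1 array",
    class = "pocketgrid_domain_error"
  )
}

#' Discretized volume overlap (DVO)
#'
#' Jaccard overlap of two voxel sets on a common grid: intersection over
#' union of occupied voxels.
#'
#' @param pred,actual `pocket_prediction`, `site_mask`, or 0/1 arrays over
#'   the same grid.
#' @return Overlap in \[0, 1\].
#' @export
dvo <- function(pred, actual) {
  a <- as_voxel_flat(pred)
  b <- as_voxel_flat(actual)
  if (length(a) == 0 && length(b) == 0) {
    abort("both voxel sets are empty", class = "pocketgrid_domain_error")
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Proportion of ligand inside the predicted site (PLI)
#'
#' Fraction of ligand voxels contained in the predicted pocket's voxel set.
#' Unlike DVO this is asymmetric: it does not penalize a pocket for being
#' larger than the ligand.
#'
#' @param ligand Non-empty ligand voxel set (`site_mask` or 0/1 array).
#' @param pred Predicted voxel set (`pocket_prediction`, `site_mask`, array).
#' @return Fraction in \[0, 1\].
#' @export
pli <- function(ligand, pred) {
  l <- as_voxel_flat(ligand)
  if (length(l) == 0) {
    abort("ligand voxel set is empty", class = "pocketgrid_domain_error")
  }
  p <- as_voxel_flat(pred)
  length(intersect(l, p)) / length(l)
}

#' Evaluate the predicted pockets of one structure against its actual site
#'
#' Pairs the actual site with the pocket minimizing DCC (`policy = "min_dcc"`)
#' or with the top-ranked pocket only (`policy = "top_ranked"`). No pockets
#' is a false negative; a paired DCC within `threshold` is a true positive
#' (with DVO against the voxelized site and, when ligand coordinates are
#' given, PLI against the voxelized ligand); otherwise a false positive.
#'
#' @param pockets List from [extract_pockets()].
#' @param actual_site `site_coords` of the actual binding site.
#' @param spec The [grid_spec()] both grids live on.
#' @param ligand Optional `site_coords` of the ligand (for PLI).
#' @param threshold DCC cutoff in Angstroms (default 4).
#' @param policy `"min_dcc"` or `"top_ranked"`.
#' @param structure_id Identifier copied into the record.
#' @return One-row tibble: structure_id, class, dcc, dvo, pli, n_pockets.
#' @export
evaluate_structure <- function(pockets, actual_site, spec = grid_spec(),
                               ligand = NULL, threshold = 4,
                               policy = c("min_dcc", "top_ranked"),
                               structure_id = NA_character_) {
  policy <- match.arg(policy)
  rec <- tibble::tibble(
    structure_id = structure_id, class = "FN", dcc = NA_real_,
    dvo = NA_real_, pli = NA_real_, n_pockets = length(pockets)
  )
  if (length(pockets) == 0) return(rec)
  actual_center <- colMeans(points_matrix(actual_site))
  if (policy == "top_ranked") pockets <- pockets[1]
  d <- vapply(pockets, function(p) dcc(p$center, actual_center), 1.0)
  best <- which.min(d)
  rec$dcc <- d[best]
  if (rec$dcc <= threshold) {
    rec$class <- "TP"
    site_mask <- voxelize_site(actual_site, spec)
    rec$dvo <- dvo(pockets[[best]], site_mask)
    if (!is.null(ligand)) {
      lig_mask <- voxelize_site(ligand, spec)
      if (sum(lig_mask$tensor) > 0) {
        rec$pli <- pli(lig_mask, pockets[[best]])
      }
    }
  } else {
    rec$class <- "FP"
  }
  rec
}

#' Summarise evaluation records into TP/FP/FN counts, F1 and means
#'
#' F1 = 2TP / (2TP + FP + FN); there are no true negatives because every
#' structure has a site. Mean DVO and PLI are taken over true positives only.
#'
#' @param records Tibble of records from [evaluate_structure()], or any
#'   tibble with columns class (TP/FP/FN), dcc, and optionally dvo, pli.
#' @param threshold DCC cutoff for the success rate (default 4).
#' @return One-row tibble: tp, fp, fn, f1, success_rate, mean_dvo, mean_pli.
#' @export
summarize_eval <- function(records, threshold = 4) {
  if (nrow(records) == 0) {
    abort("no evaluation records", class = "pocketgrid_domain_error")
  }
  tp <- sum(records$class == "TP")
  fp <- sum(records$class == "FP")
  fn <- sum(records$class == "FN")
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    f1 = f1_score(tp, fp, fn),
    success_rate = success_rate(records, threshold),
    mean_dvo = if ("dvo" %in% names(records) && tp > 0) {
      mean(records$dvo[records$class == "TP"], na.rm = TRUE)
    } else {
      NA_real_
    },
    mean_pli = if ("pli" %in% names(records) && tp > 0) {
      mean(records$pli[records$class == "TP"], na.rm = TRUE)
    } else {
      NA_real_
    }
  )
}

#' F1 score from TP/FP/FN counts
#' @param tp,fp,fn Non-negative integer counts.
#' @return 2TP / (2TP + FP + FN), or 0 when the denominator is 0.
#' @export
f1_score <- function(tp, fp, fn) {
  den <- 2 * tp + fp + fn
  ifelse(den > 0, 2 * tp / den, 0)
}
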