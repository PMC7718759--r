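#' Flag small colonies on the untreated plate
#'
#' Strains whose colony size on the no-drug plate is below a fraction
#' (default 5%) of the plate-average colony size are excluded from fitness
#' analysis: they are dead or too slow-growing for a ratio to mean anything.
#' The comparison is a strict less-than, so a strain at exactly the cutoff
#' is retained. The plate average is taken over non-missing strains.
#'
#' @param control_sizes data.frame from [collapse_quadruplicates()] for the
#'   no-drug plate.
#' @param small_frac Fraction of the plate mean under which a strain is
#'   excluded. Default 0.05.
#' @return Character vector of excluded strain ids.
#' @export
filter_small_colonies <- function(control_sizes, small_frac = 0.05) {
  if (nrow(control_sizes) == 0L)
    stop("filter_small_colonies: empty plate", call. = FALSE)
  plate_mean <- mean(control_sizes$size)
  control_sizes$strain_id[control_sizes$size < small_frac * plate_mean]
}

#' Per-strain fitness from paired drug / no-drug plates
#'
#' Fitness W of a strain is the ratio of its (collapsed) colony size on the
#' drug plate to its size on the no-drug plate. Small-colony exclusions are
#' applied first; strains present in only one condition are excluded as
#' missing.
#'
#' @param control,drug data.frames from [collapse_quadruplicates()].
#' @param small_frac Passed to [filter_small_colonies()].
#' @return data.frame with columns `strain_id`, `control_size`, `drug_size`,
#'   `fitness_W`, `is_border`, `excluded`, `exclusion_reason`
#'   (small_colony / missing / none).
#' @export
compute_fitness <- function(control, drug, small_frac = 0.05) {
  small <- filter_small_colonies(control, small_frac)
  all_ids <- union(control$strain_id, drug$strain_id)
  ci <- match(all_ids, control$strain_id)
  di <- match(all_ids, drug$strain_id)
  rec <- data.frame(
    strain_id = all_ids,
    control_size = control$size[ci],
    drug_size = drug$size[di],
    is_border = control$is_border[ci],
    stringsAsFactors = FALSE)
  rec$is_border[is.na(rec$is_border)] <- drug$is_border[di][is.na(rec$is_border)]
  rec$exclusion_reason <- "none"
  rec$exclusion_reason[is.na(rec$control_size) | is.na(rec$drug_size)] <- "missing"
  rec$exclusion_reason[rec$strain_id %in% small] <- "small_colony"
  rec$excluded <- rec$exclusion_reason != "none"
  rec$fitness_W <- ifelse(rec$excluded, NA_real_,
                          rec$drug_size / rec$control_size)
  rec
}

#' Per-plate Z-score normalization of fitness
#'
#' Z-scores the fitness ratios of retained strains so that, per plate, the
#' mean is 0 and the SD is 1. Excluded strains never contribute to the plate
#' mean/SD; border strains are excluded from the mean/SD by default (edge
#' effect) but still receive a z-score on the plate's scale.
#'
#' @param records data.frame from [compute_fitness()].
#' @param include_border Include border strains in the plate mean/SD.
#'   Default FALSE.
#' @param ddof Passed to [zscore()]; default 1 (sample SD).
#' @return `records` with a `z_score` column (NA for excluded strains). On a
#'   degenerate plate (zero spread) every record is flagged
#'   `exclusion_reason = "degenerate_plate"` and a warning is raised.
#' @export
normalize_plate <- function(records, include_border = FALSE, ddof = 1) {
  records$z_score <- NA_real_
  use <- !records$excluded & (include_border | !records$is_border)
  if (sum(use) < 2L)
    stop("normalize_plate: fewer than 2 retained strains", call. = FALSE)
  z <- tryCatch(zscore(records$fitness_W[use], ddof = ddof),
                chemscreen_degenerate = function(e) NULL)
  if (is.null(z)) {
    records$excluded <- TRUE
    records$exclusion_reason <- "degenerate_plate"
    warning("normalize_plate: degenerate plate (zero fitness spread); ",
            "all records excluded", call. = FALSE)
    return(records)
  }
  m <- mean(records$fitness_W[use])
  s <- sqrt(sum((records$fitness_W[use] - m)^2) / (sum(use) - ddof))
  records$z_score <- (records$fitness_W - m) / s
  records$z_score[records$excluded] <- NA_real_
  records
}

#' Group allele Z-scores into per-gene calls
#'
#' Alleles of the same gene (e.g. several temperature-sensitive alleles of
#' an essential gene) are grouped and one Z-score reported per gene, by
#' default the mean of the allele Z-scores. Genes score a positive
#' chemical-genetic interaction at `grouped_z >= z_pos` and a negative one
#' at `grouped_z <= z_neg`.
#'
#' @param records Normalized records ([normalize_plate()]), possibly
#'   concatenated across plates.
#' @param annotations data.frame mapping `strain_id` to `gene` (see
#'   [read_annotations()]); strains without annotation fall back to their
#'   own id as gene, with a warning.
#' @param group_fun `"mean"` (default) or `"min"`.
#' @param z_pos,z_neg Call thresholds; defaults +3 and -1.5.
#' @return data.frame with `gene`, `grouped_z`, `n_alleles`,
#'   `member_alleles` (comma-separated), `call` (positive/negative/none).
#' @export
group_alleles <- function(records, annotations = NULL,
                          group_fun = c("mean", "min"),
                          z_pos = 3, z_neg = -1.5) {
  group_fun <- match.arg(group_fun)
  f <- if (group_fun == "mean") mean else min
  keep <- !records$excluded & !records$is_border & !is.na(records$z_score)
  rec <- records[keep, , drop = FALSE]
  if (is.null(annotations)) {
    gene <- rec$strain_id
  } else {
    gene <- annotations$gene[match(rec$strain_id, annotations$strain_id)]
    if (anyNA(gene)) {
      warning("group_alleles: ", sum(is.na(gene)),
              " unannotated strain(s); using strain id as gene",
              call. = FALSE)
      gene[is.na(gene)] <- rec$strain_id[is.na(gene)]
    }
  }
  gz <- tapply(rec$z_score, gene, f)
  members <- tapply(rec$strain_id, gene, paste, collapse = ",")
  n <- tapply(rec$strain_id, gene, length)
  out <- data.frame(gene = names(gz), grouped_z = as.numeric(gz),
                    n_alleles = as.integer(n),
                    member_alleles = as.character(members),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$call <- "none"
  out$call[out$grouped_z >= z_pos] <- "positive"
  out$call[out$grouped_z <= z_neg] <- "negative"
  out
}

#' Arrayed colony screen: fitness, normalization and hit calling
#'
#' Runs the full solid-medium screen analysis on one or more paired
#' drug / no-drug plates: quadruplicate collapse, small-colony filtering,
#' fitness ratios, per-plate Z-normalization, allele grouping and hit
#' calling.
#'
#' @param control,drug A `plate_grid` or list of `plate_grid`s; pairs are
#'   matched by `plate_id`.
#' @param annotations Optional annotation data.frame ([read_annotations()]).
#' @param z_pos,z_neg Call thresholds (defaults +3 / -1.5).
#' @param small_frac Small-colony exclusion fraction (default 0.05).
#' @param summary_fun Quadruplicate summary, `"mean"` or `"median"`.
#' @param group_fun Allele grouping statistic, `"mean"` or `"min"`.
#' @param include_border Include border strains in plate statistics.
#' @return An object of class `colony_screen`: list with `records` (one row
#'   per strain x plate, with W, Z and exclusion status), `hits` (per-gene
#'   grouped calls), and `params`.
#' @examples
#' sim <- simulate_colony_screen(list(n_strains = 200, n_plates = 1), seed = 1)
#' scr <- colony_screen(sim$control, sim$drug)
#' summary(scr)
#' @export
colony_screen <- function(control, drug, annotations = NULL,
                          z_pos = 3, z_neg = -1.5, small_frac = 0.05,
                          summary_fun = "mean", group_fun = "mean",
                          include_border = FALSE) {
  if (inherits(control, "plate_grid")) control <- list(control)
  if (inherits(drug, "plate_grid")) drug <- list(drug)
  cid <- vapply(control, `[[`, "", "plate_id")
  did <- vapply(drug, `[[`, "", "plate_id")
  if (!setequal(cid, did))
    stop("colony_screen: control and drug plate ids do not match",
         call. = FALSE)
  drug <- drug[match(cid, did)]
  recs <- vector("list", length(control))
  for (i in seq_along(control)) {
    ctab <- collapse_quadruplicates(control[[i]], summary_fun)
    dtab <- collapse_quadruplicates(drug[[i]], summary_fun)
    r <- compute_fitness(ctab, dtab, small_frac)
    r <- normalize_plate(r, include_border = include_border)
    r$plate_id <- control[[i]]$plate_id
    recs[[i]] <- r
  }
  records <- do.call(rbind, recs)
  hits <- group_alleles(records, annotations, group_fun, z_pos, z_neg)
  structure(list(records = records, hits = hits,
                 params = list(z_pos = z_pos, z_neg = z_neg,
                               small_frac = small_frac,
                               summary_fun = summary_fun,
                               group_fun = group_fun,
                               include_border = include_border)),
            class = "colony_screen")
}

#' @export
print.colony_screen <- function(x, ...) {
  cat(sprintf("Colony screen: %d strain records on %d plate pair(s)\n",
              nrow(x$records), length(unique(x$records$plate_id))))
  cat(sprintf("  excluded: %d (%s)\n", sum(x$records$excluded),
              paste(names(table(x$records$exclusion_reason[x$records$excluded])),
                    collapse = ", ")))
  cat(sprintf("  hits: %d positive (Z >= %g), %d negative (Z <= %g) of %d genes\n",
              sum(x$hits$call == "positive"), x$params$z_pos,
              sum(x$hits$call == "negative"), x$params$z_neg, nrow(x$hits)))
  invisible(x)
}

#' @export
summary.colony_screen <- function(object, ...) {
  print(object)
  keep <- !object$records$excluded & !object$records$is_border
  z <- object$records$z_score[keep]
  cat(sprintf("  retained Z: mean %.3g, sd %.3g, range [%.3g, %.3g]\n",
              mean(z, na.rm = TRUE), stats::sd(z, na.rm = TRUE),
              min(z, na.rm = TRUE), max(z, na.rm = TRUE)))
  invisible(object)
}

#' Write colony-screen outputs to TSV
#'
#' @param x A `colony_screen` object.
#' @param fitness_path,hits_path Output paths (either may be NULL to skip).
#' @export
write_colony_screen <- function(x, fitness_path = NULL, hits_path = NULL) {
  if (!is.null(fitness_path)) {
    cols <- c("plate_id", "strain_id", "control_size", "drug_size",
              "fitness_W", "z_score", "is_border", "excluded",
              "exclusion_reason")
    utils::write.table(x$records[cols], fitness_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(hits_path))
    utils::write.table(x$hits, hits_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(x)
}
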