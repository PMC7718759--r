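#' Per-replicate AUC ratio with / without drug
#'
#' For overexpression suppression analysis the per-strain statistic is the
#' ratio of the growth-curve AUC in drug medium to the AUC in plain medium,
#' paired by replicate index.
#'
#' @param auc_drug,auc_plain Numeric vectors of AUCs, paired by position
#'   (replicate index), at least 3 replicates each.
#' @return Numeric vector of per-replicate ratios.
#' @export
auc_ratio <- function(auc_drug, auc_plain) {
  if (length(auc_drug) != length(auc_plain))
    stop("auc_ratio: replicate counts differ", call. = FALSE)
  if (length(auc_drug) < 3L)
    stop("auc_ratio: need >= 3 paired replicates", call. = FALSE)
  if (any(auc_plain <= 0))
    stop("auc_ratio: zero or negative plain-medium AUC", call. = FALSE)
  auc_drug / auc_plain
}

#' Flag a growth cost of overexpression in plain medium
#'
#' Some overexpressed genes reduce growth even without drug; a strain is
#' flagged when its mean plain-medium AUC falls below `cost_frac`
#' (default 80%) of the control's.
#'
#' @param strain_plain_auc,control_plain_auc Numeric vectors of plain-medium
#'   AUC replicates.
#' @param cost_frac Fraction of the control mean below which the flag is
#'   set. Default 0.8.
#' @return Logical flag.
#' @export
flag_growth_cost <- function(strain_plain_auc, control_plain_auc,
                             cost_frac = 0.8) {
  mean(strain_plain_auc) < cost_frac * mean(control_plain_auc)
}

#' Call suppressors against the empty-vector control
#'
#' A gene suppresses drug toxicity when overexpressed if its drug/plain AUC
#' ratio is at least `fold_thresh` times (default twofold) the control
#' strain's and the Welch test of its replicate ratios against the
#' control's, Benjamini-Hochberg corrected across the gene family, gives
#' `p_adj <= alpha`.
#'
#' @param strain_ratios Named list: per gene, the numeric vector of
#'   replicate AUC ratios ([auc_ratio()]).
#' @param control_ratio Numeric vector of the control strain's replicate
#'   ratios.
#' @param fold_thresh Fold-change gate (default 2).
#' @param alpha Corrected p-value gate (default 0.05).
#' @return data.frame with `gene`, `mean_ratio`, `fold_vs_control`,
#'   `p_value`, `p_adj`, `suppressor`.
#' @export
call_suppressors <- function(strain_ratios, control_ratio,
                             fold_thresh = 2, alpha = 0.05) {
  if (missing(control_ratio) || length(control_ratio) < 2L)
    stop("call_suppressors: control ratios missing", call. = FALSE)
  genes <- names(strain_ratios)
  if (is.null(genes))
    stop("call_suppressors: strain_ratios must be a named list",
         call. = FALSE)
  mr <- vapply(strain_ratios, mean, 0)
  ctrl <- mean(control_ratio)
  p <- vapply(strain_ratios, function(r)
    tryCatch(welch_t_test(r, control_ratio)$p_value,
             error = function(e) 1), 0)
  padj <- bh_adjust(p)
  out <- data.frame(gene = genes, mean_ratio = unname(mr),
                    fold_vs_control = unname(mr / ctrl),
                    p_value = unname(p), p_adj = padj,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$suppressor <- out$fold_vs_control >= fold_thresh & out$p_adj <= alpha
  out
}

#' Overexpression suppression screen from growth curves
#'
#' End-to-end suppression analysis: per-replicate drug/plain AUC ratios for
#' every overexpression strain and the empty-vector control, fold change
#' versus control, Welch + BH calling, and the plain-medium growth-cost
#' flag.
#'
#' @param curves A `growth_curves` object whose `map` has a `vector` column
#'   (gene name, or the control label for the empty plasmid) and paired
#'   drug / plain conditions per replicate.
#' @param control_vector Label of the empty-plasmid control in the `vector`
#'   column (default `"empty"`).
#' @param fold_thresh,alpha Calling gates (defaults 2 and 0.05).
#' @param cost_frac Growth-cost threshold (default 0.8).
#' @param fitted_auc Use fitted-model AUC. Default FALSE.
#' @return Object of class `suppression_screen`: list with `calls`
#'   (per-gene data.frame incl. `growth_cost`), `control_ratio`
#'   (replicates), and `params`.
#' @export
suppression_screen <- function(curves, control_vector = "empty",
                               fold_thresh = 2, alpha = 0.05,
                               cost_frac = 0.8, fitted_auc = FALSE) {
  tab <- curve_auc(curves, fitted = fitted_auc)
  if (!"vector" %in% names(tab))
    stop("suppression_screen: curve map needs a `vector` column",
         call. = FALSE)
  if (!control_vector %in% tab$vector)
    stop("suppression_screen: control vector '", control_vector,
         "' not found", call. = FALSE)

  ratios_of <- function(v) {
    d <- tab[tab$vector == v & tab$drug != "none", ]
    pl <- tab[tab$vector == v & tab$drug == "none", ]
    common <- sort(intersect(d$replicate, pl$replicate))
    list(ratio = auc_ratio(d$auc[match(common, d$replicate)],
                           pl$auc[match(common, pl$replicate)]),
         plain = pl$auc[match(common, pl$replicate)])
  }
  ctrl <- ratios_of(control_vector)
  genes <- setdiff(unique(tab$vector), control_vector)
  rs <- lapply(genes, ratios_of)
  names(rs) <- genes
  calls <- call_suppressors(lapply(rs, `[[`, "ratio"), ctrl$ratio,
                            fold_thresh, alpha)
  calls$growth_cost <- vapply(genes, function(g)
    flag_growth_cost(rs[[g]]$plain, ctrl$plain, cost_frac), TRUE)
  structure(list(calls = calls, control_ratio = ctrl$ratio,
                 params = list(control_vector = control_vector,
                               fold_thresh = fold_thresh, alpha = alpha,
                               cost_frac = cost_frac)),
            class = "suppression_screen")
}

#' @export
print.suppression_screen <- function(x, ...) {
  cat(sprintf(
    "Suppression screen: %d genes vs control (mean drug/plain ratio %.3f)\n",
    nrow(x$calls), mean(x$control_ratio)))
  cat(sprintf("  suppressors (fold >= %g, p_adj <= %g): %d\n",
              x$params$fold_thresh, x$params$alpha,
              sum(x$calls$suppressor)))
  invisible(x)
}

#' @export
summary.suppression_screen <- function(object, ...) {
  print(object)
  s <- object$calls[object$calls$suppressor, ]
  if (nrow(s)) {
    s <- s[order(-s$fold_vs_control), ]
    cat("  top suppressors:\n")
    for (i in seq_len(min(5, nrow(s))))
      cat(sprintf("    %s  fold = %.2f, p_adj = %.3g%s\n", s$gene[i],
                  s$fold_vs_control[i], s$p_adj[i],
                  if (s$growth_cost[i]) " (growth cost)" else ""))
  }
  invisible(object)
}

#' Write suppression calls to TSV
#'
#' @param x A `suppression_screen` object.
#' @param path Output path.
#' @export
write_suppressors <- function(x, path) {
  utils::write.table(x$calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}
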