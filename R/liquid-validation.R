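#' Multiplicative interaction score
#'
#' Under the multiplicative model the expected fitness of a mutant in drug
#' is the product of the wild type's drug fitness (W_i) and the mutant's
#' no-drug fitness (W_j); the interaction score is the deviation of the
#' observed double fitness from that expectation:
#' `eps = W_ij - W_i * W_j`. Negative scores mean drug sensitivity beyond
#' the multiplicative expectation; positive scores mean suppression.
#'
#' @param W_i Wild-type fitness in drug.
#' @param W_j Mutant fitness in plain medium.
#' @param W_ij Mutant fitness in drug.
#' @return The interaction score(s), vectorized.
#' @examples
#' interaction_score(0.6, 1.0, 0.3)  # -0.30
#' @export
interaction_score <- function(W_i, W_j, W_ij) {
  if (any(c(W_i, W_j, W_ij) < 0, na.rm = TRUE))
    stop("interaction_score: fitness values must be >= 0", call. = FALSE)
  W_ij - W_i * W_j
}

#' Call chemical-genetic interactions from replicated growth curves
#'
#' Full liquid-medium validation: per-replicate AUC fitness (normalized to
#' the wild type in plain medium of the same experiment and replicate),
#' multiplicative interaction scores, a Welch test of observed double
#' fitness against the replicate-wise expected products, and the
#' two-experiment intersection rule. A strain is called negative only if in
#' BOTH experiments its mean score is below `neg_thresh` with Welch
#' p <= `alpha`; positive symmetrically above `pos_thresh`.
#'
#' @param curves A `growth_curves` object with at least 2 experiments and
#'   biological replicates per experiment (typically 3), containing the
#'   wild-type strain in both plain and drug medium.
#' @param wt_strain Identifier of the wild-type reference strain.
#' @param drug Name of the drug condition to score; default: the single
#'   non-`"none"` drug present.
#' @param neg_thresh,pos_thresh Score thresholds (defaults -0.1 / +0.1,
#'   strict inequalities).
#' @param alpha Welch p-value cutoff per experiment (default 0.05).
#' @param fitted_auc Use fitted-model AUC instead of empirical trapezoid.
#' @return Object of class `interaction_calls`: list with `per_experiment`
#'   (strain x experiment rows: W_ij, expected, eps, p, call), `combined`
#'   (strain rows with `combined_call`), and `params`.
#' @export
call_interactions <- function(curves, wt_strain, drug = NULL,
                              neg_thresh = -0.1, pos_thresh = 0.1,
                              alpha = 0.05, fitted_auc = FALSE) {
  tab <- curve_auc(curves, fitted = fitted_auc)
  drugs <- setdiff(unique(tab$drug), "none")
  if (is.null(drug)) {
    if (length(drugs) != 1L)
      stop("call_interactions: specify `drug` (found: ",
           paste(drugs, collapse = ", "), ")", call. = FALSE)
    drug <- drugs
  }
  if (!wt_strain %in% tab$strain)
    stop("call_interactions: wild-type strain not in curves", call. = FALSE)

  per <- list()
  for (ex in sort(unique(tab$experiment))) {
    sub <- tab[tab$experiment == ex, , drop = FALSE]
    wt_plain <- sub[sub$strain == wt_strain & sub$drug == "none", ]
    wt_drug <- sub[sub$strain == wt_strain & sub$drug == drug, ]
    if (nrow(wt_plain) == 0L || nrow(wt_drug) == 0L)
      stop("call_interactions: wild type missing in experiment ", ex,
           call. = FALSE)
    # per-replicate pairing: replicate k of every curve is normalized by the
    # wild-type plain-medium AUC of replicate k, so W_j(wt) is exactly 1
    ref <- wt_plain$auc[order(wt_plain$replicate)]
    reps <- sort(wt_plain$replicate)
    ref_of <- function(r) ref[match(r, reps)]
    W_i <- curve_fitness(wt_drug$auc, ref_of(wt_drug$replicate))
    names(W_i) <- wt_drug$replicate
    for (st in unique(sub$strain)) {
      mut_plain <- sub[sub$strain == st & sub$drug == "none", ]
      mut_drug <- sub[sub$strain == st & sub$drug == drug, ]
      common <- sort(Reduce(intersect, list(
        mut_plain$replicate, mut_drug$replicate, wt_drug$replicate)))
      if (length(common) < 2L) {
        per[[length(per) + 1L]] <- data.frame(
          strain = st, drug = drug, experiment = ex, n_replicates =
            length(common), W_ij = NA_real_, expected = NA_real_,
          eps = NA_real_, p_value = NA_real_, call = "uncallable",
          stringsAsFactors = FALSE)
        next
      }
      wj <- curve_fitness(mut_plain$auc[match(common, mut_plain$replicate)],
                          ref_of(common))
      wij <- curve_fitness(mut_drug$auc[match(common, mut_drug$replicate)],
                           ref_of(common))
      wi <- W_i[match(common, as.numeric(names(W_i)))]
      expd <- wi * wj
      eps_k <- interaction_score(wi, wj, wij)
      p <- if (st == wt_strain) 1 else
        tryCatch(welch_t_test(wij, expd)$p_value, error = function(e) 1)
      me <- mean(eps_k)
      cl <- "none"
      if (me < neg_thresh && p <= alpha) cl <- "negative"
      if (me > pos_thresh && p <= alpha) cl <- "positive"
      per[[length(per) + 1L]] <- data.frame(
        strain = st, drug = drug, experiment = ex,
        n_replicates = length(common), W_ij = mean(wij),
        expected = mean(expd), eps = me, p_value = p, call = cl,
        stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, per)

  comb <- do.call(rbind, lapply(split(per, per$strain), function(d) {
    cc <- if (any(d$call == "uncallable")) "uncallable"
    else if (all(d$call == "negative")) "negative"
    else if (all(d$call == "positive")) "positive"
    else "none"
    data.frame(strain = d$strain[1], drug = d$drug[1],
               n_experiments = nrow(d), mean_eps = mean(d$eps),
               combined_call = cc, stringsAsFactors = FALSE)
  }))
  rownames(comb) <- NULL
  structure(list(per_experiment = per, combined = comb,
                 params = list(wt_strain = wt_strain, drug = drug,
                               neg_thresh = neg_thresh,
                               pos_thresh = pos_thresh, alpha = alpha)),
            class = "interaction_calls")
}

#' @export
print.interaction_calls <- function(x, ...) {
  tb <- table(x$combined$combined_call)
  cat(sprintf("Interaction calls (%s): %d strains over %d experiment(s)\n",
              x$params$drug, nrow(x$combined),
              max(x$per_experiment$experiment)))
  cat(sprintf("  negative %d | positive %d | none %d | uncallable %d\n",
              sum(x$combined$combined_call == "negative"),
              sum(x$combined$combined_call == "positive"),
              sum(x$combined$combined_call == "none"),
              sum(x$combined$combined_call == "uncallable")))
  invisible(x)
}

#' @export
summary.interaction_calls <- function(object, ...) {
  print(object)
  neg <- object$combined[object$combined$combined_call == "negative", ]
  if (nrow(neg)) {
    neg <- neg[order(neg$mean_eps), ]
    cat("  strongest negative interactions:\n")
    for (i in seq_len(min(5, nrow(neg))))
      cat(sprintf("    %s  eps = %.3f\n", neg$strain[i], neg$mean_eps[i]))
  }
  invisible(object)
}

#' Write interaction calls to TSV
#'
#' @param x An `interaction_calls` object.
#' @param path Output path for the per-experiment table; the combined call
#'   is merged in.
#' @export
write_interactions <- function(x, path) {
  out <- merge(x$per_experiment,
               x$combined[c("strain", "combined_call")], by = "strain")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Choose a working dose from a dose-response table
#'
#' Picks the dose whose wild-type fitness is closest to the target drop
#' (e.g. `target_drop = 0.4` selects the dose that reduces wild-type
#' fitness by about 40%). Ties go to the smaller dose.
#'
#' @param dose_response Named numeric vector or list: names are doses
#'   (ug/mL), values wild-type fitness.
#' @param target_drop Target fractional fitness drop, default 0.4.
#' @return The selected dose (numeric).
#' @examples
#' select_dose(c("1" = 0.9, "10" = 0.62, "30" = 0.41), 0.4)  # 10
#' @export
select_dose <- function(dose_response, target_drop = 0.4) {
  v <- unlist(dose_response)
  if (length(v) == 0L)
    stop("select_dose: empty dose-response map", call. = FALSE)
  doses <- as.numeric(names(v))
  if (anyNA(doses))
    stop("select_dose: dose names must be numeric", call. = FALSE)
  dev <- abs(v - (1 - target_drop))
  cand <- doses[dev == min(dev)]
  min(cand)
}
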