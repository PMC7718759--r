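#' Control-strain normalization of an SGA plate
#'
#' Divides each array strain's quadruplicate colony mean by the plate-wide
#' mean of the embedded control strain's colonies (the his3-delta filler
#' that surrounds each array position to buffer nutrient effects), yielding
#' per-strain normalized fitness with the control at exactly 1.
#'
#' @param grid A `plate_grid` of the selected double mutants.
#' @param control_strain Identifier of the embedded control strain.
#' @return data.frame with `strain_id`, `fitness` (control-normalized),
#'   `n_colonies`.
#' @export
normalize_sga_plate <- function(grid, control_strain) {
  tab <- collapse_quadruplicates(grid)
  w <- grid$wells
  ctrl_sizes <- w$colony_size[w$strain_id == control_strain]
  if (length(ctrl_sizes) == 0L)
    stop("normalize_sga_plate: no colonies of control strain '",
         control_strain, "'", call. = FALSE)
  ctrl_mean <- mean(ctrl_sizes)
  if (ctrl_mean <= 0)
    stop("normalize_sga_plate: control colonies have zero mean size",
         call. = FALSE)
  data.frame(strain_id = tab$strain_id, fitness = tab$size / ctrl_mean,
             n_colonies = tab$n_colonies, stringsAsFactors = FALSE)
}

#' Score one array allele against the control query
#'
#' The SGA score of an array allele is the deviation of its double-mutant
#' fitness (allele x mistranslating-tRNA query) from the multiplicative
#' expectation: mean fitness under the control query scaled by the query
#' strain's own single-mutant fitness Q. The p-value is a Welch test of the
#' double-mutant replicates against the Q-scaled control-query replicates.
#'
#' @param double_fitness Replicate normalized fitness under the
#'   mistranslating query (>= 3 replicates).
#' @param reference_fitness Replicate normalized fitness under the control
#'   (wild-type tRNA) query.
#' @param Q Query single-mutant fitness (default 0.8: the mistranslating
#'   tRNA alone costs ~20% growth).
#' @return List with `score` (= mean(double) - Q * mean(reference)) and
#'   `p_value` (uncorrected).
#' @export
sga_score <- function(double_fitness, reference_fitness, Q = 0.8) {
  if (length(double_fitness) < 2L || length(reference_fitness) < 2L)
    stop("sga_score: need >= 2 replicates in each query", call. = FALSE)
  score <- mean(double_fitness) - Q * mean(reference_fitness)
  p <- tryCatch(welch_t_test(double_fitness, Q * reference_fitness)$p_value,
                error = function(e) 1)
  list(score = score, p_value = p)
}

#' Score a synthetic genetic array against a control query
#'
#' Simplified SGA analysis of double mutants: each array plate (one per
#' randomized array, typically 3) is control-strain normalized, the
#' per-array fitness values form the biological replicates, and each allele
#' is scored against the control-query arrays under the multiplicative
#' expectation with query fitness `Q`. Welch p-values are BH-corrected
#' across the array; alleles with `score <= score_thresh` and
#' `p_adj <= alpha` are called synthetic (negative).
#'
#' @param query_plates List of `plate_grid`s mated to the mistranslating
#'   query (one per array).
#' @param control_plates List of `plate_grid`s mated to the control query.
#' @param control_strain Embedded control strain id used for plate
#'   normalization.
#' @param Q Query single-mutant fitness (default 0.8).
#' @param score_thresh,alpha Calling gates (defaults -0.1 and 0.05).
#' @return Object of class `sga_screen`: list with `calls` (per-allele
#'   data.frame: normalized_double_fitness, reference_fitness, sga_score,
#'   p_adj, call) and `params`.
#' @export
sga_screen <- function(query_plates, control_plates, control_strain,
                       Q = 0.8, score_thresh = -0.1, alpha = 0.05) {
  if (inherits(query_plates, "plate_grid")) query_plates <- list(query_plates)
  if (inherits(control_plates, "plate_grid"))
    control_plates <- list(control_plates)
  qf <- lapply(query_plates, normalize_sga_plate, control_strain)
  cf <- lapply(control_plates, normalize_sga_plate, control_strain)
  alleles <- setdiff(Reduce(union, lapply(qf, `[[`, "strain_id")),
                     control_strain)
  rows <- lapply(alleles, function(a) {
    dv <- unlist(lapply(qf, function(d) d$fitness[d$strain_id == a]))
    rv <- unlist(lapply(cf, function(d) d$fitness[d$strain_id == a]))
    if (length(dv) < 2L || length(rv) < 2L)
      return(data.frame(array_allele = a,
                        normalized_double_fitness = mean(dv),
                        reference_fitness = mean(rv), sga_score = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    s <- sga_score(dv, rv, Q)
    data.frame(array_allele = a, normalized_double_fitness = mean(dv),
               reference_fitness = mean(rv), sga_score = s$score,
               p_value = s$p_value, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  calls$p_adj <- bh_adjust(calls$p_value)
  calls$call <- ifelse(!is.na(calls$sga_score) &
                         calls$sga_score <= score_thresh &
                         !is.na(calls$p_adj) & calls$p_adj <= alpha,
                       "negative", "none")
  calls$call[is.na(calls$sga_score)] <- "uncallable"
  structure(list(calls = calls,
                 params = list(control_strain = control_strain, Q = Q,
                               score_thresh = score_thresh, alpha = alpha)),
            class = "sga_screen")
}

#' @export
print.sga_screen <- function(x, ...) {
  cat(sprintf("SGA screen: %d array alleles (Q = %g)\n", nrow(x$calls),
              x$params$Q))
  cat(sprintf("  negative (score <= %g, p_adj <= %g): %d\n",
              x$params$score_thresh, x$params$alpha,
              sum(x$calls$call == "negative")))
  invisible(x)
}

#' @export
summary.sga_screen <- function(object, ...) {
  print(object)
  n <- object$calls[object$calls$call == "negative", ]
  if (nrow(n)) {
    n <- n[order(n$sga_score), ]
    cat("  strongest synthetic interactions:\n")
    for (i in seq_len(min(5, nrow(n))))
      cat(sprintf("    %s  score = %.3f, p_adj = %.3g\n",
                  n$array_allele[i], n$sga_score[i], n$p_adj[i]))
  }
  invisible(object)
}

#' Write SGA calls to TSV
#'
#' @param x An `sga_screen` object.
#' @param path Output path.
#' @export
write_sga <- function(x, path) {
  utils::write.table(x$calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}
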