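#' Read a microplate-reader export with a well map
#'
#' Parses the wide CSV a plate reader emits (a `time` column in hours plus
#' one OD600 column per well) together with a tab-separated well map
#' assigning each well a strain, condition and replicate. Every data column
#' must be mapped; ragged rows are an error.
#'
#' @param path CSV path: first column `time` (hours), remaining columns one
#'   per well.
#' @param map_path TSV path with columns `well`, `strain`, `drug` (empty or
#'   `none` for plain medium), `concentration`, `replicate`, `experiment`,
#'   and optionally `vector` (overexpression screens).
#' @param subtract_t0 Subtract each curve's first OD reading and floor at 0
#'   (per-curve blank). Default TRUE.
#' @return A `growth_curves` object: list with `times` (hours), `od`
#'   (matrix, one row per curve), and `map` (data.frame of curve metadata,
#'   rows aligned with `od`).
#' @export
read_plate_reader <- function(path, map_path, subtract_t0 = TRUE) {
  raw <- utils::read.csv(path, check.names = FALSE)
  if (names(raw)[1] != "time")
    stop("read_plate_reader: first CSV column must be 'time'", call. = FALSE)
  if (anyNA(raw))
    stop("read_plate_reader: ragged/missing values in CSV", call. = FALSE)
  times <- as.numeric(raw$time)
  if (any(diff(times) <= 0))
    stop("read_plate_reader: times must be strictly increasing",
         call. = FALSE)
  map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  need <- c("well", "strain", "drug", "concentration", "replicate",
            "experiment")
  miss <- setdiff(need, names(map))
  if (length(miss))
    stop("read_plate_reader: well map missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  wells <- setdiff(names(raw), "time")
  unmapped <- setdiff(wells, map$well)
  if (length(unmapped))
    stop("read_plate_reader: unmapped wells: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  map <- map[match(wells, map$well), , drop = FALSE]
  od <- t(as.matrix(raw[wells]))
  if (subtract_t0) {
    od <- od - od[, 1]
    od[od < 0] <- 0
  }
  map$drug[is.na(map$drug) | map$drug == ""] <- "none"
  dimnames(od) <- NULL
  rownames(map) <- NULL
  growth_curves(times, od, map)
}

#' Construct a growth-curve set
#'
#' @param times Shared time grid (hours), strictly increasing.
#' @param od Matrix of OD600 readings, one row per curve.
#' @param map data.frame of per-curve metadata (same row count as `od`),
#'   with at least `strain`, `drug`, `replicate`, `experiment`.
#' @return A `growth_curves` object.
#' @export
growth_curves <- function(times, od, map) {
  od <- as.matrix(od)
  stopifnot(length(times) == ncol(od), nrow(map) == nrow(od))
  if (any(diff(times) <= 0))
    stop("growth_curves: times must be strictly increasing", call. = FALSE)
  structure(list(times = as.numeric(times), od = od,
                 map = as.data.frame(map)),
            class = "growth_curves")
}

#' @export
print.growth_curves <- function(x, ...) {
  cat(sprintf(
    "Growth curves: %d wells x %d timepoints over %.3g h (%d strains)\n",
    nrow(x$od), ncol(x$od), max(x$times) - min(x$times),
    length(unique(x$map$strain))))
  invisible(x)
}

#' Empirical AUC for every curve in a set
#'
#' @param curves A `growth_curves` object.
#' @param fitted Use the closed-form AUC of a logistic fit instead of the
#'   trapezoid on raw OD. Default FALSE (empirical).
#' @return The `map` data.frame with an added `auc` column.
#' @export
curve_auc <- function(curves, fitted = FALSE) {
  out <- curves$map
  if (fitted) {
    out$auc <- apply(curves$od, 1, function(y) {
      f <- fit_logistic(curves$times, y)
      if (f$converged) f$auc_fitted else f$auc_empirical
    })
  } else {
    out$auc <- apply(curves$od, 1, function(y)
      trapezoid_auc(curves$times, y))
  }
  out
}

#' AUC-based fitness relative to a reference
#'
#' Growth-curve fitness is the AUC divided by a reference AUC (the
#' wild-type strain in plain medium from the same experiment), so the
#' wild type in plain medium has fitness 1.
#'
#' @param auc Numeric vector of AUC values.
#' @param reference_auc Positive scalar or vector recycled against `auc`.
#' @return Fitness values `auc / reference_auc`.
#' @export
curve_fitness <- function(auc, reference_auc) {
  if (any(!is.finite(reference_auc)) || any(reference_auc <= 0))
    stop("curve_fitness: reference AUC must be positive", call. = FALSE)
  auc / reference_auc
}
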