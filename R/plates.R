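#' Read an arrayed colony-size table
#'
#' Ingests the tab-separated colony tables emitted by colony-quantification
#' tools (one row per colony position) into a validated plate grid. Expected
#' columns: `plate`, `row`, `col`, `strain`, `size`. Rows (1-based) and
#' columns must lie inside the stated grid; duplicated positions are an
#' error. The outermost ring of positions is flagged `is_border` (classic
#' plate edge effect) unless the file carries its own `is_border` column.
#'
#' @param path Path to a TSV file.
#' @param n_rows,n_cols Grid dimensions; the default 32 x 48 is the 1536
#'   colony format.
#' @param condition Optional list describing the plate condition, e.g.
#'   `list(drug = "AZC", concentration = 30)`; `NULL` means no drug.
#' @return A `plate_grid` object: list with `plate_id`, `condition`,
#'   `n_rows`, `n_cols` and `wells` (data.frame: row, col, strain_id,
#'   colony_size, is_border).
#' @export
read_plate_table <- function(path, n_rows = 32, n_cols = 48,
                             condition = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("plate", "row", "col", "strain", "size")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("read_plate_table: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(tab$row) | !is.finite(tab$col) |
                 !is.finite(tab$size) | tab$size < 0 |
                 tab$row < 1 | tab$row > n_rows |
                 tab$col < 1 | tab$col > n_cols)
  if (length(bad))
    stop("read_plate_table: malformed rows (1-based, excluding header): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  if (length(unique(tab$plate)) != 1L)
    stop("read_plate_table: file must contain exactly one plate id",
         call. = FALSE)
  wells <- data.frame(
    row = as.integer(tab$row), col = as.integer(tab$col),
    strain_id = as.character(tab$strain),
    colony_size = as.numeric(tab$size),
    stringsAsFactors = FALSE)
  if ("is_border" %in% names(tab)) {
    wells$is_border <- as.logical(tab$is_border)
  } else {
    wells$is_border <- wells$row == 1L | wells$row == n_rows |
      wells$col == 1L | wells$col == n_cols
  }
  if (anyDuplicated(wells[c("row", "col")]))
    stop("read_plate_table: duplicate (row, col) positions", call. = FALSE)
  plate_grid(plate_id = as.character(tab$plate[1]), condition = condition,
             n_rows = n_rows, n_cols = n_cols, wells = wells)
}

#' Construct a plate grid
#'
#' @param plate_id Plate identifier.
#' @param condition `NULL` (no drug) or `list(drug =, concentration =)`.
#' @param n_rows,n_cols Grid dimensions.
#' @param wells data.frame with columns row, col, strain_id, colony_size and
#'   optionally is_border.
#' @return A `plate_grid` object.
#' @export
plate_grid <- function(plate_id, condition = NULL, n_rows = 32, n_cols = 48,
                       wells) {
  stopifnot(is.data.frame(wells),
            all(c("row", "col", "strain_id", "colony_size") %in% names(wells)))
  if (!"is_border" %in% names(wells))
    wells$is_border <- wells$row == 1L | wells$row == n_rows |
      wells$col == 1L | wells$col == n_cols
  if (anyDuplicated(wells[c("row", "col")]))
    stop("plate_grid: duplicate (row, col) positions", call. = FALSE)
  if (any(wells$colony_size < 0))
    stop("plate_grid: colony sizes must be >= 0", call. = FALSE)
  structure(list(plate_id = plate_id, condition = condition,
                 n_rows = n_rows, n_cols = n_cols, wells = wells),
            class = "plate_grid")
}

#' @export
print.plate_grid <- function(x, ...) {
  cond <- if (is.null(x$condition)) "no drug" else
    sprintf("%s %g ug/mL", x$condition$drug, x$condition$concentration)
  cat(sprintf("Plate %s (%d x %d, %d colonies, %s)\n", x$plate_id,
              x$n_rows, x$n_cols, nrow(x$wells), cond))
  invisible(x)
}

#' Write a plate grid back to TSV
#'
#' @param grid A `plate_grid`.
#' @param path Output path.
#' @export
write_plate_table <- function(grid, path) {
  w <- grid$wells
  out <- data.frame(plate = grid$plate_id, row = w$row, col = w$col,
                    strain = w$strain_id, size = w$colony_size,
                    is_border = w$is_border)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse quadruplicate colonies to per-strain sizes
#'
#' Strains are arrayed in quadruplicate (2x2 blocks); this summarizes the
#' available replicate colonies of each strain into one size. Missing
#' colonies simply reduce the replicate count; a strain with zero colonies
#' yields a missing record downstream.
#'
#' @param grid A `plate_grid`.
#' @param summary_fun `"mean"` (default) or `"median"`.
#' @return data.frame with columns `strain_id`, `size`, `n_colonies`,
#'   `is_border` (TRUE when more than half of the strain's colonies sit on
#'   the border ring).
#' @export
collapse_quadruplicates <- function(grid, summary_fun = c("mean", "median")) {
  summary_fun <- match.arg(summary_fun)
  f <- if (summary_fun == "mean") mean else stats::median
  w <- grid$wells
  sizes <- tapply(w$colony_size, w$strain_id, f)
  ncol_ <- tapply(w$colony_size, w$strain_id, length)
  bord <- tapply(w$is_border, w$strain_id, function(b) mean(b) > 0.5)
  data.frame(strain_id = names(sizes), size = as.numeric(sizes),
             n_colonies = as.integer(ncol_), is_border = as.logical(bord),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a strain annotation table
#'
#' TSV with columns `strain`, `gene`, `allele`, `collection`
#' (deletion / temperature_sensitive), `essential` (logical), and optional
#' `category`.
#'
#' @param path Path to TSV.
#' @return data.frame of annotations keyed by `strain_id`.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "gene", "allele", "collection", "essential")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("read_annotations: missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  data.frame(strain_id = as.character(tab$strain), gene = tab$gene,
             allele = tab$allele, collection = tab$collection,
             essential = as.logical(tab$essential),
             category = if ("category" %in% names(tab)) tab$category
                        else NA_character_,
             stringsAsFactors = FALSE)
}
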