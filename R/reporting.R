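#' Round half away from zero
#'
#' Integer-percent rounding used in overlap summaries (0.5 rounds up, the
#' convention of printed screen overlap percentages), unlike base R's
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @return Rounded values.
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Overlap structure of named gene sets
#'
#' Exact per-set sizes and pairwise / full intersection counts for 2 or
#' more named sets (e.g. the negative interactors of several amino acid
#' analogs, as a Venn diagram would display them).
#'
#' @param sets Named list of character vectors.
#' @return Object of class `overlap_summary`: list with `set_names`,
#'   `sizes`, `pairwise` (data.frame set_a, set_b, intersection),
#'   `full_intersection` (count of genes in every set), `union_size`, and
#'   `members` (genes of the full intersection).
#' @examples
#' overlap(list(A = c("g1", "g2"), B = "g2", C = "g2"))
#' @export
overlap <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("overlap: sets must be named", call. = FALSE)
  sets <- lapply(sets, unique)
  nm <- names(sets)
  sizes <- vapply(sets, length, 0L)
  pw <- NULL
  if (length(sets) >= 2L) {
    cmb <- utils::combn(nm, 2)
    pw <- data.frame(set_a = cmb[1, ], set_b = cmb[2, ],
                     intersection = apply(cmb, 2, function(p)
                       length(intersect(sets[[p[1]]], sets[[p[2]]]))),
                     stringsAsFactors = FALSE)
  }
  common <- Reduce(intersect, sets)
  structure(list(set_names = nm, sizes = sizes, pairwise = pw,
                 full_intersection = length(common),
                 union_size = length(Reduce(union, sets)),
                 members = sort(common)),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("Gene-set overlap:\n")
  for (nm in x$set_names)
    cat(sprintf("  %s: %d genes\n", nm, x$sizes[[nm]]))
  if (!is.null(x$pairwise))
    for (i in seq_len(nrow(x$pairwise)))
      cat(sprintf("  %s & %s: %d\n", x$pairwise$set_a[i],
                  x$pairwise$set_b[i], x$pairwise$intersection[i]))
  if (length(x$set_names) > 2L)
    cat(sprintf("  all %d sets: %d\n", length(x$set_names),
                x$full_intersection))
  cat(sprintf("  union: %d\n", x$union_size))
  invisible(x)
}

#' Per-category overlap percentages
#'
#' For each functional category, the percentage of hit genes in that
#' category that also appear in a reference gene set, rounded half-up to
#' integer percent (the convention of printed overlap figures such as
#' "67% overlap").
#'
#' @param hits data.frame with columns `gene` and `category`.
#' @param reference_set Character vector of genes.
#' @return data.frame with `category`, `n_hits`, `n_shared`, `percent`.
#'   Genes without a category are omitted with a warning.
#' @export
category_overlap <- function(hits, reference_set) {
  stopifnot(all(c("gene", "category") %in% names(hits)))
  drop <- is.na(hits$category) | hits$category == ""
  if (any(drop)) {
    warning("category_overlap: ", sum(drop),
            " gene(s) without category omitted", call. = FALSE)
    hits <- hits[!drop, , drop = FALSE]
  }
  out <- do.call(rbind, lapply(split(hits$gene, hits$category), function(g) {
    g <- unique(g)
    data.frame(n_hits = length(g),
               n_shared = length(intersect(g, reference_set)))
  }))
  data.frame(category = rownames(out), n_hits = out$n_hits,
             n_shared = out$n_shared,
             percent = round_half_up(100 * out$n_shared / out$n_hits),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Default column manifest for supplement-style tables
#'
#' Maps the logical tables of a published screen's supplementary files to
#' file names and column names. Adjust entries to match the downloaded
#' files; ingestion fails loudly on missing columns rather than guessing.
#'
#' @return Nested list: one entry per logical table with `file` and a
#'   `columns` name map.
#' @export
supplement_manifest <- function() {
  list(
    screen = list(file = "screen_zscores.tsv",
                  columns = c(gene = "gene", z = "z_score")),
    validation = list(file = "validation_calls.tsv",
                      columns = c(gene = "gene", call = "call")),
    analogs = list(file = "analog_calls.tsv",
                   columns = c(gene = "gene", drug = "drug", call = "call")),
    sga = list(file = "sga_calls.tsv",
               columns = c(allele = "allele", call = "call")),
    suppression = list(file = "suppression.tsv",
                       columns = c(gene = "gene", ratio = "mean_ratio",
                                   suppressor = "suppressor")))
}

#' Recompute printed screen counts from supplementary tables
#'
#' Reads screen supplements (downloaded once from the publisher's archive)
#' through a column manifest and recomputes the headline counts: screen
#' positives (Z >= 3) and negatives (Z <= -1.5), a spotlight gene's
#' Z-score, validated negative/positive interaction counts, per-analog
#' negative counts and their triple overlap, SGA synthetic calls, the
#' suppressor count, and the control AUC ratio. Each computed value is
#' reported next to the expected printed value with a discrepancy flag;
#' the function never silently passes.
#'
#' @param dir Directory holding the supplement-derived TSV files named in
#'   the manifest. Missing files are skipped with a warning (their rows are
#'   omitted).
#' @param manifest Manifest as from [supplement_manifest()].
#' @param expected Named numeric vector of printed values to compare
#'   against; entries default to NA (no comparison) when not given.
#' @param spotlight_gene Optional gene whose screen Z-score is reported.
#' @param control_gene Label of the control row in the suppression table
#'   (default `"control"`).
#' @return data.frame of class `supplement_report` with `metric`,
#'   `computed`, `expected`, `match` (NA when no expectation was supplied).
#' @export
reproduce_from_supplements <- function(dir, manifest = supplement_manifest(),
                                       expected = numeric(),
                                       spotlight_gene = NULL,
                                       control_gene = "control") {
  read_tab <- function(entry) {
    path <- file.path(dir, entry$file)
    if (!file.exists(path)) {
      warning("reproduce_from_supplements: missing file ", entry$file,
              call. = FALSE)
      return(NULL)
    }
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    miss <- setdiff(unname(entry$columns), names(tab))
    if (length(miss))
      stop("reproduce_from_supplements: ", entry$file,
           " lacks expected columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    stats::setNames(tab[unname(entry$columns)], names(entry$columns))
  }
  rows <- list()
  add <- function(metric, computed) {
    exp_v <- if (metric %in% names(expected)) expected[[metric]] else NA_real_
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, computed = computed, expected = exp_v,
      match = if (is.na(exp_v)) NA else isTRUE(all.equal(
        computed, exp_v, tolerance = 0.05)),
      stringsAsFactors = FALSE)
  }

  scr <- read_tab(manifest$screen)
  if (!is.null(scr)) {
    add("screen_positive_genes", sum(scr$z >= 3, na.rm = TRUE))
    add("screen_negative_genes", sum(scr$z <= -1.5, na.rm = TRUE))
    if (!is.null(spotlight_gene))
      add(paste0("screen_z_", spotlight_gene),
          scr$z[match(spotlight_gene, scr$gene)])
  }
  val <- read_tab(manifest$validation)
  if (!is.null(val)) {
    add("validated_negative", sum(val$call == "negative"))
    add("validated_positive", sum(val$call == "positive"))
  }
  ana <- read_tab(manifest$analogs)
  if (!is.null(ana)) {
    neg <- ana[ana$call == "negative", ]
    for (d in sort(unique(neg$drug)))
      add(paste0("analog_negative_", d), sum(neg$drug == d))
    if (length(unique(neg$drug)) >= 2L)
      add("analog_overlap_all",
          overlap(split(neg$gene, neg$drug))$full_intersection)
  }
  sga <- read_tab(manifest$sga)
  if (!is.null(sga)) {
    add("sga_negative", sum(sga$call == "negative"))
    add("sga_total", nrow(sga))
  }
  sup <- read_tab(manifest$suppression)
  if (!is.null(sup)) {
    ctrl <- sup$ratio[match(control_gene, sup$gene)]
    if (!is.na(ctrl)) add("control_auc_ratio_percent", 100 * ctrl)
    add("suppressor_count",
        sum(sup$suppressor[sup$gene != control_gene] %in%
              c(TRUE, "TRUE", "true", 1)))
    add("suppression_total", sum(sup$gene != control_gene))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("supplement_report", class(out))
  out
}

#' @export
print.supplement_report <- function(x, ...) {
  cat("Recomputed counts vs printed values:\n")
  for (i in seq_len(nrow(x))) {
    flag <- if (is.na(x$match[i])) "" else
      if (x$match[i]) "  [ok]" else "  [DISCREPANCY]"
    exp_s <- if (is.na(x$expected[i])) "" else
      sprintf(" (printed %.4g)", x$expected[i])
    cat(sprintf("  %-28s %.4g%s%s\n", x$metric[i], x$computed[i],
                exp_s, flag))
  }
  invisible(x)
}

#' Histogram of screen Z-scores
#'
#' Distribution of per-strain Z-score normalized fitness, with the calling
#' thresholds marked.
#'
#' @param screen A `colony_screen` object.
#' @param ... Passed to [graphics::hist()].
#' @export
plot_z_distribution <- function(screen, ...) {
  keep <- !screen$records$excluded & !screen$records$is_border
  z <- screen$records$z_score[keep]
  graphics::hist(z, breaks = 60, main = "Z-score normalized fitness",
                 xlab = "Z-score", ...)
  graphics::abline(v = c(screen$params$z_neg, screen$params$z_pos),
                   lty = 2, col = "firebrick")
  invisible(screen)
}
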