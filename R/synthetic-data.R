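#' Deterministic substream seed
#'
#' Fans a single global seed out to per-plate / per-curve substreams by a
#' counter scheme: `(seed * 1000003 + index) mod 2147483629`. Regeneration
#' from the same (seed, index) is bit-identical.
#'
#' @param seed Integer master seed.
#' @param index Non-negative integer substream counter.
#' @return An integer seed below 2^31.
#' @export
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483629 * 1000003 + index) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a paired-plate colony screen with known truth
#'
#' Generates paired no-drug / drug `plate_grid`s emulating an arrayed
#' chemical-genetic screen: strains in quadruplicate 2x2 blocks, a
#' multiplicative per-plate effect per condition, lognormal per-colony
#' noise, a small fraction of dead (small-colony) strains, and planted
#' sensitive / resistant strains with known effect sizes.
#'
#' Colony size = plate_effect x base_size x strain_vigor x drug_multiplier
#' x lognormal noise. Null strains share the plate-wide drug multiplier
#' exactly (their fitness spread is measurement noise only); planted
#' strains have the multiplier shifted by `effect_sd_units x interaction_sd`
#' fitness units.
#'
#' @param config List of generator settings (all optional):
#'   `n_strains` (4000), `n_rows`/`n_cols` (32 x 48, i.e. 1536 format),
#'   `base_size` (500 units), `vigor_sdlog` (0.2; strain-level growth vigor,
#'   common to both conditions so it cancels in the ratio),
#'   `drug_effect` (0.6; the drug dose costs ~40% fitness),
#'   `plate_effect_sd` (0.1, lognormal sdlog per plate x condition),
#'   `colony_noise_cv` (0.05, lognormal sdlog per colony),
#'   `dead_frac` (0.005), `sensitive_frac` (0.02), `resistant_frac` (0.005),
#'   `sensitive_effect` (-3) and `resistant_effect` (+4) in units of
#'   `interaction_sd` (0.1), `drug` ("AZC"), `concentration` (30).
#' @param seed Integer master seed.
#' @return List with `control` (list of `plate_grid`), `drug` (ditto,
#'   matched plate ids) and `truth` (data.frame: strain_id, plate_id,
#'   class, vigor, drug_multiplier, is_dead, effect_sd_units, seed).
#' @export
simulate_colony_screen <- function(config = list(), seed) {
  cfg <- utils::modifyList(list(
    n_strains = 4000, n_rows = 32, n_cols = 48, base_size = 500,
    vigor_sdlog = 0.2, drug_effect = 0.6, plate_effect_sd = 0.1,
    colony_noise_cv = 0.05, dead_frac = 0.005, sensitive_frac = 0.02,
    resistant_frac = 0.005, sensitive_effect = -3, resistant_effect = 4,
    interaction_sd = 0.1, drug = "AZC", concentration = 30,
    n_plates = NULL), config)
  if (cfg$n_rows %% 2L || cfg$n_cols %% 2L)
    stop("simulate_colony_screen: grid dimensions must be even (2x2 blocks)",
         call. = FALSE)
  per_plate <- (cfg$n_rows / 2) * (cfg$n_cols / 2)
  n_plates <- cfg$n_plates %||% ceiling(cfg$n_strains / per_plate)
  if (n_plates * per_plate < cfg$n_strains)
    stop("simulate_colony_screen: n_plates too small for n_strains",
         call. = FALSE)

  set.seed(substream_seed(seed, 0L))
  ids <- sprintf("strain%04d", seq_len(cfg$n_strains))
  cls <- sample(c("dead", "sensitive", "resistant", "null"),
                cfg$n_strains, replace = TRUE,
                prob = c(cfg$dead_frac, cfg$sensitive_frac,
                         cfg$resistant_frac,
                         1 - cfg$dead_frac - cfg$sensitive_frac -
                           cfg$resistant_frac))
  effect_units <- ifelse(cls == "sensitive", cfg$sensitive_effect,
                         ifelse(cls == "resistant", cfg$resistant_effect, 0))
  mult <- pmax(cfg$drug_effect + effect_units * cfg$interaction_sd, 0.01)
  vigor <- exp(stats::rnorm(cfg$n_strains, 0, cfg$vigor_sdlog))
  vigor[cls == "dead"] <- 0.01
  plate_of <- rep(seq_len(n_plates), each = per_plate)[seq_len(cfg$n_strains)]
  ord <- sample.int(cfg$n_strains)  # shuffle strains across plates

  assigned <- ids[ord]
  truth <- data.frame(strain_id = assigned,
                      plate_id = sprintf("P%02d", plate_of),
                      class = cls[ord], vigor = vigor[ord],
                      drug_multiplier = mult[ord],
                      is_dead = cls[ord] == "dead",
                      effect_sd_units = effect_units[ord],
                      seed = seed, stringsAsFactors = FALSE)

  block_rows <- rep(seq_len(cfg$n_rows / 2), each = cfg$n_cols / 2)
  block_cols <- rep(seq_len(cfg$n_cols / 2), times = cfg$n_rows / 2)
  control <- vector("list", n_plates)
  drugp <- vector("list", n_plates)
  for (p in seq_len(n_plates)) {
    set.seed(substream_seed(seed, p))
    pe_c <- exp(stats::rnorm(1, 0, cfg$plate_effect_sd))
    pe_d <- exp(stats::rnorm(1, 0, cfg$plate_effect_sd))
    on_plate <- which(truth$plate_id == sprintf("P%02d", p))
    nb <- length(on_plate)
    br <- block_rows[seq_len(nb)]; bc <- block_cols[seq_len(nb)]
    mk <- function(plate_effect, with_drug) {
      expect <- cfg$base_size * plate_effect * truth$vigor[on_plate] *
        (if (with_drug) truth$drug_multiplier[on_plate] else 1)
      rows <- c(2 * br - 1, 2 * br - 1, 2 * br, 2 * br)
      cols <- c(2 * bc - 1, 2 * bc, 2 * bc - 1, 2 * bc)
      sz <- rep(expect, 4) *
        exp(stats::rnorm(4 * nb, 0, cfg$colony_noise_cv))
      data.frame(row = rows, col = cols,
                 strain_id = rep(truth$strain_id[on_plate], 4),
                 colony_size = sz, stringsAsFactors = FALSE)
    }
    wc <- mk(pe_c, FALSE)
    wd <- mk(pe_d, TRUE)
    control[[p]] <- plate_grid(sprintf("P%02d", p), NULL,
                               cfg$n_rows, cfg$n_cols, wc)
    drugp[[p]] <- plate_grid(sprintf("P%02d", p),
                             list(drug = cfg$drug,
                                  concentration = cfg$concentration),
                             cfg$n_rows, cfg$n_cols, wd)
  }
  list(control = control, drug = drugp, truth = truth)
}

#' Simulate replicated growth curves with planted interactions
#'
#' Generates logistic OD600 curves (N0 = 0.1, 15-min sampling over 24 h by
#' default) for a wild type and a set of mutants in paired plain / drug
#' media, across biological replicates and independent experiments, with
#' planted multiplicative-model interaction scores. The growth rate of each
#' curve is solved (monotone bisection on the trapezoid AUC of the sampled
#' grid) so that the noiseless fitness ratios reproduce the planted scores
#' exactly; replicate noise is applied to the target fitness (biological
#' variability) and to the OD readings (measurement noise).
#'
#' @param config List of settings (all optional): `n_strains` (200 mutants),
#'   `planted_frac` (0.5) with `planted_eps` (-0.3), or an explicit `eps`
#'   vector (length `n_strains`); `wt_drug_fitness` (0.6, i.e. W_i: the
#'   drug costs the wild type ~40%), `mutant_fitness_range` (c(0.8, 1.0)
#'   for W_j), `n_replicates` (3), `n_experiments` (2),
#'   `fitness_noise_sd` (0.05), `od_noise_sd` (0.003), `K` (1.4),
#'   `r` (0.5 per hour), `N0` (0.1), `t_end` (24 h), `dt` (0.25 h),
#'   `drug` ("AZC"), `concentration` (10), `wt_strain` ("WT").
#' @param seed Integer master seed.
#' @return List with `curves` (a `growth_curves` object) and `truth`
#'   (data.frame: strain, W_j, eps, planted, seed).
#' @export
simulate_growth_curves <- function(config = list(), seed) {
  cfg <- utils::modifyList(list(
    n_strains = 200, planted_frac = 0.5, planted_eps = -0.3, eps = NULL,
    wt_drug_fitness = 0.6, mutant_fitness_range = c(0.8, 1.0),
    n_replicates = 3, n_experiments = 2, fitness_noise_sd = 0.05,
    od_noise_sd = 0.003, K = 1.4, r = 0.5, N0 = 0.1, t_end = 24, dt = 0.25,
    drug = "AZC", concentration = 10, wt_strain = "WT"), config)
  times <- seq(0, cfg$t_end, by = cfg$dt)

  set.seed(substream_seed(seed, 0L))
  strains <- sprintf("mut%03d", seq_len(cfg$n_strains))
  if (is.null(cfg$eps)) {
    planted <- stats::runif(cfg$n_strains) < cfg$planted_frac
    eps <- ifelse(planted, cfg$planted_eps, 0)
  } else {
    eps <- rep_len(cfg$eps, cfg$n_strains)
    planted <- eps != 0
  }
  W_j <- stats::runif(cfg$n_strains, cfg$mutant_fitness_range[1],
                      cfg$mutant_fitness_range[2])
  truth <- data.frame(strain = strains, W_j = W_j, eps = eps,
                      planted = planted, seed = seed,
                      stringsAsFactors = FALSE)

  ref_auc <- trapezoid_auc(times, logistic_od(times, cfg$K, cfg$r, cfg$N0))
  g <- function(r) trapezoid_auc(times, logistic_od(times, cfg$K, r, cfg$N0))
  auc_lo <- g(1e-4); auc_hi <- g(10)
  solve_r <- function(target_auc) {
    target <- min(max(target_auc, auc_lo * 1.001), auc_hi * 0.999)
    stats::uniroot(function(r) g(r) - target, c(1e-4, 10), tol = 1e-12)$root
  }

  meta <- list(); odl <- list(); k <- 0L
  emit <- function(strain, drug, conc, replicate, experiment, W_target,
                   vec = NA_character_) {
    k <<- k + 1L
    r_fit <- solve_r(W_target * ref_auc)
    od <- logistic_od(times, cfg$K, r_fit, cfg$N0) +
      stats::rnorm(length(times), 0, cfg$od_noise_sd)
    od[od < 0] <- 0
    meta[[k]] <<- data.frame(well = sprintf("W%04d", k), strain = strain,
                             drug = drug, concentration = conc,
                             replicate = replicate, experiment = experiment,
                             vector = vec, stringsAsFactors = FALSE)
    odl[[k]] <<- od
  }

  for (ex in seq_len(cfg$n_experiments)) {
    set.seed(substream_seed(seed, 1000L + ex))
    for (rep_i in seq_len(cfg$n_replicates)) {
      fn <- function(mu) max(mu + stats::rnorm(1, 0, cfg$fitness_noise_sd),
                             0.05)
      # the wild-type plain-medium reference anchors the fitness scale:
      # realized at its nominal value so the stated fitness noise is the
      # noise of the normalized fitness values, not noise-on-noise
      emit(cfg$wt_strain, "none", 0, rep_i, ex, 1)
      emit(cfg$wt_strain, cfg$drug, cfg$concentration, rep_i, ex,
           fn(cfg$wt_drug_fitness))
      for (s in seq_len(cfg$n_strains)) {
        emit(strains[s], "none", 0, rep_i, ex, fn(W_j[s]))
        emit(strains[s], cfg$drug, cfg$concentration, rep_i, ex,
             fn(cfg$wt_drug_fitness * W_j[s] + eps[s]))
      }
    }
  }
  curves <- growth_curves(times, do.call(rbind, odl),
                          do.call(rbind, meta))
  list(curves = curves, truth = truth)
}

#' Simulate an overexpression suppression experiment
#'
#' Generates paired drug / plain growth curves for overexpression strains
#' and an empty-vector control. The control's drug/plain AUC ratio is
#' centred on `control_ratio`; planted suppressors multiply that ratio by
#' `suppression_fold`; planted growth-cost genes grow at `cost_fitness` of
#' the control in plain medium. Replicate variability is lognormal on the
#' drug-medium target (CV `ratio_cv`).
#'
#' @param config List of settings (all optional): `n_genes` (53),
#'   `control_ratio` (0.183), `ratio_cv` (0.10), `suppressor_genes`
#'   (character vector, default none) with `suppression_fold` (3),
#'   `cost_genes` (default none) with `cost_fitness` (0.7), curve
#'   parameters as in [simulate_growth_curves()], `n_replicates` (3),
#'   `drug` ("AZC"), `concentration` (10).
#' @param seed Integer master seed.
#' @return List with `curves` (a `growth_curves` object whose map carries a
#'   `vector` column, control = `"empty"`) and `truth`.
#' @export
simulate_suppression <- function(config = list(), seed) {
  cfg <- utils::modifyList(list(
    n_genes = 53, control_ratio = 0.183, ratio_cv = 0.10,
    suppressor_genes = character(), suppression_fold = 3,
    cost_genes = character(), cost_fitness = 0.7,
    n_replicates = 3, od_noise_sd = 0.003, K = 1.4, r = 0.5, N0 = 0.1,
    t_end = 24, dt = 0.25, drug = "AZC", concentration = 10), config)
  times <- seq(0, cfg$t_end, by = cfg$dt)
  genes <- if (cfg$n_genes > 0) sprintf("GENE%02d", seq_len(cfg$n_genes))
           else character()
  genes <- union(genes, union(cfg$suppressor_genes, cfg$cost_genes))
  truth <- data.frame(
    gene = genes,
    suppression_fold = ifelse(genes %in% cfg$suppressor_genes,
                              cfg$suppression_fold, 1),
    growth_cost = genes %in% cfg$cost_genes, seed = seed,
    stringsAsFactors = FALSE)

  ref_auc <- trapezoid_auc(times, logistic_od(times, cfg$K, cfg$r, cfg$N0))
  g <- function(r) trapezoid_auc(times, logistic_od(times, cfg$K, r, cfg$N0))
  auc_lo <- g(1e-4); auc_hi <- g(10)
  solve_r <- function(target_auc) {
    target <- min(max(target_auc, auc_lo * 1.001), auc_hi * 0.999)
    stats::uniroot(function(r) g(r) - target, c(1e-4, 10), tol = 1e-12)$root
  }
  meta <- list(); odl <- list(); k <- 0L
  emit <- function(vec, drug, conc, replicate, W_target) {
    k <<- k + 1L
    od <- logistic_od(times, cfg$K, solve_r(W_target * ref_auc), cfg$N0) +
      stats::rnorm(length(times), 0, cfg$od_noise_sd)
    od[od < 0] <- 0
    meta[[k]] <<- data.frame(well = sprintf("W%04d", k), strain = vec,
                             drug = drug, concentration = conc,
                             replicate = replicate, experiment = 1L,
                             vector = vec, stringsAsFactors = FALSE)
    odl[[k]] <<- od
  }
  all_vec <- c("empty", genes)
  for (i in seq_along(all_vec)) {
    v <- all_vec[i]
    set.seed(substream_seed(seed, i))
    plain_f <- if (v %in% cfg$cost_genes) cfg$cost_fitness else 1
    ratio <- cfg$control_ratio *
      (if (v %in% cfg$suppressor_genes) cfg$suppression_fold else 1)
    for (rep_i in seq_len(cfg$n_replicates)) {
      noise <- exp(stats::rnorm(1, 0, cfg$ratio_cv))
      emit(v, "none", 0, rep_i, plain_f)
      emit(v, cfg$drug, cfg$concentration, rep_i, plain_f * ratio * noise)
    }
  }
  list(curves = growth_curves(times, do.call(rbind, odl),
                              do.call(rbind, meta)),
       truth = truth)
}

#' Simulate a synthetic genetic array with a control query
#'
#' Builds paired plate sets (mistranslating-tRNA query vs wild-type-tRNA
#' control query) for a set of array alleles, each in quadruplicate on
#' every array, with allele positions randomized per array and the
#' remaining positions (including the whole border) filled with the
#' embedded control strain. On the normalized scale the query-plate double
#' fitness of an array allele is `array_fitness x Q x (1 + planted
#' deviation)`; the control strain anchors the plate scale at 1 on both
#' queries.
#'
#' @param config List of settings (all optional): `n_alleles` (72),
#'   `n_arrays` (3), `Q` (0.8), `array_fitness_range` (c(0.8, 1.0)),
#'   `deviations` (named numeric vector of planted deviations, default
#'   none), `colony_noise_cv` (0.05), `base_size` (500),
#'   `n_rows`/`n_cols` (32 x 48), `control_strain` ("his3d"),
#'   `layout_master` (seed for the position-randomization substream;
#'   defaults to `seed`, settable separately to re-randomize the layout
#'   while holding the biology fixed).
#' @param seed Integer master seed.
#' @return List with `query_plates`, `control_plates` (lists of
#'   `plate_grid`, one per array) and `truth` (allele, array_fitness,
#'   deviation, seed).
#' @export
simulate_sga_array <- function(config = list(), seed) {
  cfg <- utils::modifyList(list(
    n_alleles = 72, n_arrays = 3, Q = 0.8,
    array_fitness_range = c(0.8, 1.0), deviations = NULL,
    colony_noise_cv = 0.05, base_size = 500, n_rows = 32, n_cols = 48,
    control_strain = "his3d", layout_master = NULL), config)
  layout_master <- cfg$layout_master %||% seed
  nb <- (cfg$n_rows / 2) * (cfg$n_cols / 2)
  if (cfg$n_alleles > nb - 4)
    stop("simulate_sga_array: too many alleles for the grid", call. = FALSE)
  set.seed(substream_seed(seed, 0L))
  alleles <- sprintf("allele%03d", seq_len(cfg$n_alleles))
  af <- stats::runif(cfg$n_alleles, cfg$array_fitness_range[1],
                     cfg$array_fitness_range[2])
  names(af) <- alleles
  dev <- stats::setNames(rep(0, cfg$n_alleles), alleles)
  if (!is.null(cfg$deviations))
    dev[names(cfg$deviations)] <- cfg$deviations
  truth <- data.frame(allele = alleles, array_fitness = unname(af),
                      deviation = unname(dev), seed = seed,
                      stringsAsFactors = FALSE)

  block_rows <- rep(seq_len(cfg$n_rows / 2), each = cfg$n_cols / 2)
  block_cols <- rep(seq_len(cfg$n_cols / 2), times = cfg$n_rows / 2)
  interior <- which(block_rows > 1 & block_rows < cfg$n_rows / 2 &
                      block_cols > 1 & block_cols < cfg$n_cols / 2)
  mk_plate <- function(array_i, is_query) {
    # layout substream shared by the two queries of the same array
    set.seed(substream_seed(layout_master, 100L + array_i))
    pos <- sample(interior, cfg$n_alleles)
    strain_at <- rep(cfg$control_strain, nb)
    strain_at[pos] <- alleles
    fitness_at <- rep(1, nb)
    fitness_at[pos] <- if (is_query) af * cfg$Q * (1 + dev) else af
    set.seed(substream_seed(seed, 200L + 2L * array_i + is_query))
    rows <- c(2 * block_rows - 1, 2 * block_rows - 1,
              2 * block_rows, 2 * block_rows)
    cols <- c(2 * block_cols - 1, 2 * block_cols,
              2 * block_cols - 1, 2 * block_cols)
    sz <- rep(cfg$base_size * fitness_at, 4) *
      exp(stats::rnorm(4 * nb, 0, cfg$colony_noise_cv))
    plate_grid(sprintf("%s%d", if (is_query) "Q" else "C", array_i),
               condition = NULL, cfg$n_rows, cfg$n_cols,
               data.frame(row = rows, col = cols,
                          strain_id = rep(strain_at, 4), colony_size = sz,
                          stringsAsFactors = FALSE))
  }
  list(query_plates = lapply(seq_len(cfg$n_arrays), mk_plate, TRUE),
       control_plates = lapply(seq_len(cfg$n_arrays), mk_plate, FALSE),
       truth = truth)
}

#' Write a growth-curve set to plate-reader CSV + well-map TSV
#'
#' Emits the same dialect [read_plate_reader()] ingests, for round-trip
#' testing and interoperability.
#'
#' @param curves A `growth_curves` object.
#' @param csv_path,map_path Output paths.
#' @export
write_growth_curves <- function(curves, csv_path, map_path) {
  wide <- data.frame(time = curves$times)
  od <- t(curves$od)
  colnames(od) <- curves$map$well
  utils::write.csv(cbind(wide, od), csv_path, row.names = FALSE)
  utils::write.table(curves$map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(csv_path)
}
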