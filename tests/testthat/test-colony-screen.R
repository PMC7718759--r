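test_that("plate tables round-trip through TSV with validation", {
  p <- toy_plate(c(s1 = 100, s2 = 80, s3 = 120, s4 = 60))
  tsv <- tempfile(fileext = ".tsv")
  write_plate_table(p, tsv)
  p2 <- read_plate_table(tsv, n_rows = 4, n_cols = 4)
  expect_equal(p2$wells$colony_size, p$wells$colony_size)
  expect_equal(sort(unique(p2$wells$strain_id)), c("s1", "s2", "s3", "s4"))

  # duplicate positions rejected
  tab <- read.delim(tsv)
  tab <- rbind(tab, tab[1, ])
  tsv2 <- tempfile(fileext = ".tsv")
  write.table(tab, tsv2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_plate_table(tsv2, 4, 4), "duplicate")

  # missing column rejected with its name
  write.table(tab[setdiff(names(tab), "size")], tsv2, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_plate_table(tsv2, 4, 4), "size")

  # full 1536 synthetic plate: 1536 wells, 384 strains in quadruplicate
  sim <- simulate_colony_screen(list(n_strains = 384, n_plates = 1), seed = 2)
  tsv3 <- tempfile(fileext = ".tsv")
  write_plate_table(sim$control[[1]], tsv3)
  g <- read_plate_table(tsv3)
  expect_equal(nrow(g$wells), 1536)
  expect_equal(length(unique(g$wells$strain_id)), 384)
  expect_true(all(table(g$wells$strain_id) == 4))
})

test_that("quadruplicate collapse averages available colonies", {
  p <- toy_plate(c(a = 100, b = 100))
  expect_equal(collapse_quadruplicates(p)$size, c(100, 100))

  # two of four colonies missing: mean of the available pair
  w <- p$wells[p$wells$strain_id == "a", ][1:2, ]
  w$colony_size <- c(80, 120)
  p2 <- plate_grid("P1", NULL, 4, 4, rbind(w, p$wells[p$wells$strain_id == "b", ]))
  tab <- collapse_quadruplicates(p2)
  expect_equal(tab$size[tab$strain_id == "a"], 100)
  expect_equal(tab$n_colonies[tab$strain_id == "a"], 2L)

  # matches a brute-force per-strain mean on a full synthetic plate
  sim <- simulate_colony_screen(list(n_strains = 384, n_plates = 1), seed = 3)
  g <- sim$control[[1]]
  tab <- collapse_quadruplicates(g)
  oracle <- sapply(split(g$wells$colony_size, g$wells$strain_id), mean)
  expect_equal(tab$size, unname(oracle[tab$strain_id]))

  med <- collapse_quadruplicates(g, "median")
  om <- sapply(split(g$wells$colony_size, g$wells$strain_id), median)
  expect_equal(med$size, unname(om[med$strain_id]))
})

test_that("small-colony filtering applies a strict 5% rule and finds planted dead strains", {
  tab <- data.frame(strain_id = c("a", "b", "c"), size = c(191, 4, 105),
                    n_colonies = 4L, is_border = FALSE)
  expect_equal(filter_small_colonies(tab), "b")  # plate mean 100, 4 < 5
  tab$size <- c(190, 5, 105)  # plate mean 100, strain at exactly 5 retained
  expect_equal(length(filter_small_colonies(tab)), 0L)
  expect_error(filter_small_colonies(tab[0, ]), "empty")

  sim <- simulate_colony_screen(list(n_strains = 2000, dead_frac = 0.005),
                                seed = 4)
  scr <- colony_screen(sim$control, sim$drug)
  dead_true <- sim$truth$strain_id[sim$truth$is_dead]
  dead_called <- scr$records$strain_id[
    scr$records$exclusion_reason == "small_colony"]
  expect_setequal(dead_called, dead_true)
})

test_that("fitness ratios and exclusions follow the drug/control contract", {
  ctl <- data.frame(strain_id = c("a", "b", "c"), size = c(100, 100, 90),
                    n_colonies = 4L, is_border = FALSE)
  drg <- data.frame(strain_id = c("a", "b"), size = c(60, 0),
                    n_colonies = 4L, is_border = FALSE)
  rec <- compute_fitness(ctl, drg)
  expect_equal(rec$fitness_W[rec$strain_id == "a"], 0.6)
  expect_equal(rec$fitness_W[rec$strain_id == "b"], 0)
  expect_equal(rec$exclusion_reason[rec$strain_id == "c"], "missing")

  sim <- simulate_colony_screen(list(n_strains = 384, n_plates = 1), seed = 5)
  ctab <- collapse_quadruplicates(sim$control[[1]])
  dtab <- collapse_quadruplicates(sim$drug[[1]])
  rec <- compute_fitness(ctab, dtab)
  keep <- !rec$excluded
  oracle <- dtab$size[match(rec$strain_id, dtab$strain_id)] /
    ctab$size[match(rec$strain_id, ctab$strain_id)]
  expect_equal(rec$fitness_W[keep], oracle[keep])
})

test_that("per-plate Z-normalization yields mean 0 / sd 1 and flags degenerate plates", {
  rec <- data.frame(strain_id = letters[1:3], control_size = 100,
                    drug_size = c(50, 100, 150),
                    fitness_W = c(0.5, 1.0, 1.5), is_border = FALSE,
                    excluded = FALSE, exclusion_reason = "none")
  out <- normalize_plate(rec)
  expect_equal(out$z_score, c(-1, 0, 1))

  # excluded strains get no z and do not shift the plate statistics
  rec2 <- rbind(rec, data.frame(strain_id = "dead", control_size = 2,
                                drug_size = 1, fitness_W = NA_real_,
                                is_border = FALSE, excluded = TRUE,
                                exclusion_reason = "small_colony"))
  out2 <- normalize_plate(rec2)
  expect_equal(out2$z_score[1:3], c(-1, 0, 1))
  expect_true(is.na(out2$z_score[4]))

  rec$fitness_W <- rep(0.7, 3)
  expect_warning(out3 <- normalize_plate(rec), "degenerate")
  expect_true(all(out3$excluded))
  expect_true(all(out3$exclusion_reason == "degenerate_plate"))
})

test_that("allele grouping and thresholds call hits per gene", {
  rec <- data.frame(strain_id = c("ts1", "ts2", "d1", "d2"),
                    control_size = 100, drug_size = 100,
                    fitness_W = 1, is_border = FALSE, excluded = FALSE,
                    exclusion_reason = "none",
                    z_score = c(-2, -1, 3, -1.49))
  ann <- data.frame(strain_id = c("ts1", "ts2", "d1", "d2"),
                    gene = c("ESS1", "ESS1", "GENE1", "GENE2"),
                    allele = c("ess1-1", "ess1-2", "gene1d", "gene2d"),
                    collection = c("temperature_sensitive",
                                   "temperature_sensitive", "deletion",
                                   "deletion"),
                    essential = c(TRUE, TRUE, FALSE, FALSE),
                    category = NA_character_)
  hits <- group_alleles(rec, ann)
  expect_equal(hits$grouped_z[hits$gene == "ESS1"], -1.5)
  expect_equal(hits$call[hits$gene == "ESS1"], "negative")   # <= -1.5
  expect_equal(hits$call[hits$gene == "GENE1"], "positive")  # >= 3
  expect_equal(hits$call[hits$gene == "GENE2"], "none")      # -1.49 boundary
  expect_equal(hits$n_alleles[hits$gene == "ESS1"], 2L)

  hmin <- group_alleles(rec, ann, group_fun = "min")
  expect_equal(hmin$grouped_z[hmin$gene == "ESS1"], -2)

  expect_warning(group_alleles(rec, ann[-3, ]), "unannotated")
})

test_that("lowering a strain's drug colony size never moves its call toward positive", {
  sim <- simulate_colony_screen(list(n_strains = 384, n_plates = 1), seed = 6)
  scr <- colony_screen(sim$control, sim$drug)
  target <- scr$records$strain_id[!scr$records$excluded &
                                    !scr$records$is_border][10]
  z0 <- scr$records$z_score[scr$records$strain_id == target]
  for (f in c(0.8, 0.5, 0.2)) {
    d <- sim$drug[[1]]
    hit <- d$wells$strain_id == target
    d$wells$colony_size[hit] <- d$wells$colony_size[hit] * f
    scr2 <- colony_screen(sim$control[[1]], d)
    z1 <- scr2$records$z_score[scr2$records$strain_id == target]
    expect_lt(z1, z0)
  }
})

test_that("the screen is deterministic and Z removes per-plate effects", {
  s1 <- simulate_colony_screen(list(n_strains = 500, n_plates = 2), seed = 9)
  s2 <- simulate_colony_screen(list(n_strains = 500, n_plates = 2), seed = 9)
  expect_identical(s1, s2)
  r1 <- colony_screen(s1$control, s1$drug)
  r2 <- colony_screen(s2$control, s2$drug)
  expect_identical(r1$records, r2$records)

  # per-plate z statistics are exactly normalized despite plate effects
  for (p in unique(r1$records$plate_id)) {
    keep <- r1$records$plate_id == p & !r1$records$excluded &
      !r1$records$is_border
    expect_equal(mean(r1$records$z_score[keep]), 0, tolerance = 1e-12)
    expect_equal(sd(r1$records$z_score[keep]), 1, tolerance = 1e-12)
  }
})

test_that("screen outputs write to TSV", {
  sim <- simulate_colony_screen(list(n_strains = 100, n_plates = 1), seed = 12)
  scr <- colony_screen(sim$control, sim$drug)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_colony_screen(scr, f1, f2)
  fit <- read.delim(f1); hits <- read.delim(f2)
  expect_equal(nrow(fit), nrow(scr$records))
  expect_equal(nrow(hits), nrow(scr$hits))
})
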