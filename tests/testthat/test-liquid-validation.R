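test_that("plate-reader CSVs round-trip with the well map", {
  map <- data.frame(well = c("A1", "A2", "A3"), strain = c("WT", "WT", "m1"),
                    drug = c("none", "AZC", "AZC"), concentration = c(0, 10, 10),
                    replicate = 1L, experiment = 1L)
  times <- seq(0, 24, by = 0.25)  # 97 points
  od <- rbind(logistic_od(times, 1.4, 0.5, 0.1),
              logistic_od(times, 1.4, 0.3, 0.1),
              logistic_od(times, 1.4, 0.2, 0.1))
  gc <- growth_curves(times, od, map)
  csv <- tempfile(fileext = ".csv"); tsv <- tempfile(fileext = ".tsv")
  write_growth_curves(gc, csv, tsv)
  back <- read_plate_reader(csv, tsv, subtract_t0 = FALSE)
  expect_equal(ncol(back$od), 97)
  expect_equal(nrow(back$od), 3)
  expect_equal(back$od, gc$od, tolerance = 1e-12)
  expect_equal(back$map$strain, map$strain)

  # unmapped well is an error
  write.table(map[-1, ], tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_plate_reader(csv, tsv), "unmapped")
})

test_that("t0 subtraction floors curves at zero", {
  map <- data.frame(well = "A1", strain = "WT", drug = "none",
                    concentration = 0, replicate = 1L, experiment = 1L)
  times <- seq(0, 24, by = 0.25)
  gc <- growth_curves(times, matrix(0.1 + logistic_od(times, 1, 0.4, 0.05),
                                    nrow = 1), map)
  csv <- tempfile(fileext = ".csv"); tsv <- tempfile(fileext = ".tsv")
  write_growth_curves(gc, csv, tsv)
  back <- read_plate_reader(csv, tsv)
  expect_equal(back$od[1, 1], 0)
  expect_true(all(back$od >= 0))
})

test_that("curve fitness is the AUC ratio to the reference", {
  expect_equal(curve_fitness(6, 12), 0.5)
  expect_equal(curve_fitness(c(6, 12, 24), 12), c(0.5, 1, 2))
  expect_error(curve_fitness(6, 0), "positive")

  # wild-type plain-medium replicates against their own mean sit near 1
  sim <- simulate_growth_curves(list(n_strains = 2), seed = 21)
  tab <- curve_auc(sim$curves)
  wtp <- tab$auc[tab$strain == "WT" & tab$drug == "none"]
  expect_equal(curve_fitness(wtp, mean(wtp)), rep(1, length(wtp)),
               tolerance = 0.01)
})

test_that("interaction_score implements the multiplicative model", {
  expect_equal(interaction_score(0.6, 0.9, 0.54), 0)
  expect_equal(interaction_score(0.6, 1.0, 0.3), -0.30)
  expect_equal(interaction_score(0.6, 0.8, 0.70), 0.22)
  expect_error(interaction_score(-0.1, 1, 1), ">= 0")
})

test_that("interaction calling enforces thresholds and the two-experiment rule", {
  # constant-OD curves: fitness levels are exact by construction
  mk_map <- function(strain, drug, rep, exp)
    data.frame(well = paste0("w", seq_along(strain)), strain = strain,
               drug = drug, concentration = ifelse(drug == "none", 0, 10),
               replicate = rep, experiment = exp)
  strains <- c("WT", "WT", "neg", "neg", "border", "border", "onesided",
               "onesided")
  drugs <- rep(c("none", "AZC"), 4)
  maps <- list(); lv <- list()
  for (e in 1:2) for (r in 1:3) {
    jit <- 0.005 * r  # small replicate spread so Welch has variance
    # W_i = 0.6; neg: W_ij = 0.6 - 0.3; border: eps = -0.09 (under threshold);
    # onesided: eps = -0.25 in experiment 1 only
    eps_one <- if (e == 1) -0.25 else 0.02
    m <- mk_map(strains, drugs, r, e)
    m$well <- sprintf("w%d_%d_%d", seq_len(nrow(m)), r, e)
    maps[[length(maps) + 1]] <- m
    lv[[length(lv) + 1]] <- c(1, 0.6 + jit,
                              1, 0.6 - 0.3 + jit,
                              1, 0.6 - 0.09 + jit,
                              1, 0.6 + eps_one + jit)
  }
  map <- do.call(rbind, maps)
  gc <- const_curves(map, unlist(lv))
  calls <- call_interactions(gc, "WT")
  cc <- calls$combined
  expect_equal(cc$combined_call[cc$strain == "neg"], "negative")
  expect_equal(cc$combined_call[cc$strain == "border"], "none")
  expect_equal(cc$combined_call[cc$strain == "onesided"], "none")

  # wild-type self-interaction is exactly zero
  pe <- calls$per_experiment
  expect_identical(pe$eps[pe$strain == "WT"], c(0, 0))

  # epsilon is invariant under a common rescaling of every AUC
  gc2 <- growth_curves(gc$times, gc$od * 3.7, gc$map)
  calls2 <- call_interactions(gc2, "WT")
  expect_equal(calls2$per_experiment$eps, pe$eps, tolerance = 1e-12)
  expect_identical(calls2$combined$combined_call, cc$combined_call)

  # a strain measured in fewer than 2 replicates is uncallable
  drop <- gc$map$strain == "neg" & gc$map$replicate > 1 & gc$map$drug != "none"
  gc3 <- growth_curves(gc$times, gc$od[!drop, ], gc$map[!drop, ])
  calls3 <- call_interactions(gc3, "WT")
  expect_equal(calls3$combined$combined_call[calls3$combined$strain == "neg"],
               "uncallable")
})

test_that("positive interactions are called symmetrically", {
  maps <- list(); lv <- list()
  for (e in 1:2) for (r in 1:3) {
    m <- data.frame(well = sprintf("w%d_%d_%d", 1:4, r, e),
                    strain = c("WT", "WT", "sup", "sup"),
                    drug = c("none", "AZC", "none", "AZC"),
                    concentration = c(0, 10, 0, 10), replicate = r,
                    experiment = e)
    maps[[length(maps) + 1]] <- m
    lv[[length(lv) + 1]] <- c(1, 0.6 + 0.004 * r, 1, 0.85 + 0.004 * r)
  }
  gc <- const_curves(do.call(rbind, maps), unlist(lv))
  cc <- call_interactions(gc, "WT")$combined
  expect_equal(cc$combined_call[cc$strain == "sup"], "positive")
})

test_that("select_dose picks the dose nearest the target fitness drop", {
  expect_equal(select_dose(c("1" = 0.9, "10" = 0.62, "30" = 0.41), 0.4), 10)
  expect_equal(select_dose(c("7.5" = 0.60), 0.4), 7.5)
  expect_equal(select_dose(c("5" = 0.55, "20" = 0.65), 0.4), 5)  # tie: smaller
  expect_error(select_dose(numeric(0)), "empty")
})
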