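test_that("overlap counts match brute-force enumeration", {
  ov <- overlap(list(A = c("g1", "g2"), B = "g2", C = "g2"))
  expect_equal(ov$full_intersection, 1)
  expect_equal(ov$pairwise$intersection, c(1, 1, 1))

  ov0 <- overlap(list(A = c("a", "b"), B = c("c"), C = c("d", "e")))
  expect_equal(ov0$full_intersection, 0)
  expect_true(all(ov0$pairwise$intersection == 0))
  expect_error(overlap(list(c("a"), B = "b")), "named")

  set.seed(71)
  for (i in 1:25) {
    sets <- lapply(1:3, function(j) sample(letters, sample(3:15, 1)))
    names(sets) <- c("x", "y", "z")
    ov <- overlap(sets)
    oracle <- overlap_oracle(sets)
    expect_equal(ov$full_intersection, oracle$full)
    expect_equal(ov$union_size, oracle$union)
    # inclusion-exclusion consistency
    ie <- sum(ov$sizes) - sum(ov$pairwise$intersection) +
      ov$full_intersection
    expect_equal(ov$union_size, ie)
  }
})

test_that("category overlap percentages round half-up", {
  expect_equal(round_half_up(c(66.5, 66.4, -0.2)), c(67, 66, 0))
  hits <- data.frame(gene = c("a", "b", "c", "d"),
                     category = c("sorting", "sorting", "sorting", "rna"))
  out <- category_overlap(hits, reference_set = c("a", "b", "x"))
  expect_equal(out$percent[out$category == "sorting"], 67)  # 2 of 3
  expect_equal(out$percent[out$category == "rna"], 0)
  expect_warning(
    category_overlap(rbind(hits, data.frame(gene = "e", category = NA)),
                     c("a")), "without category")

  set.seed(72)
  for (i in 1:10) {
    h <- data.frame(gene = sample(letters, 10),
                    category = sample(c("c1", "c2"), 10, replace = TRUE))
    ref <- sample(letters, 8)
    out <- category_overlap(h, ref)
    for (k in seq_len(nrow(out))) {
      g <- unique(h$gene[h$category == out$category[k]])
      expect_equal(out$n_shared[k], sum(g %in% ref))
    }
  }
})

test_that("supplement-style tables are recomputed through the manifest with discrepancy flags", {
  # synthetic stand-in supplement tables with known counts
  dir <- tempfile(); dir.create(dir)
  man <- supplement_manifest()
  set.seed(73)
  z <- c(runif(30, -1, 1), c(3.2, 4.1), c(-1.6, -2.0, -3.5))
  genes <- sprintf("g%02d", seq_along(z))
  write.table(data.frame(gene = genes, z_score = z),
              file.path(dir, man$screen$file), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(gene = genes[1:10],
                         call = c(rep("negative", 6), rep("positive", 2),
                                  rep("none", 2))),
              file.path(dir, man$validation$file), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene = rep(genes[1:4], 2),
                         drug = rep(c("canavanine", "thialysine"), each = 4),
                         call = c("negative", "negative", "none", "negative",
                                  "negative", "none", "none", "negative")),
              file.path(dir, man$analogs$file), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(allele = genes[1:8],
                         call = c(rep("negative", 3), rep("none", 5))),
              file.path(dir, man$sga$file), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(gene = c("control", genes[1:5]),
                         mean_ratio = c(0.183, 0.6, 0.5, 0.2, 0.19, 0.21),
                         suppressor = c(FALSE, TRUE, TRUE, FALSE, FALSE,
                                        FALSE)),
              file.path(dir, man$suppression$file), sep = "\t",
              quote = FALSE, row.names = FALSE)

  rep <- reproduce_from_supplements(
    dir, expected = c(screen_positive_genes = 2, screen_negative_genes = 3,
                      validated_negative = 6, suppressor_count = 7),
    spotlight_gene = "g35")
  get <- function(m) rep$computed[rep$metric == m]
  expect_equal(get("screen_positive_genes"), 2)
  expect_equal(get("screen_negative_genes"), 3)
  expect_equal(get("screen_z_g35"), -3.5)
  expect_equal(get("validated_negative"), 6)
  expect_equal(get("validated_positive"), 2)
  expect_equal(get("analog_negative_canavanine"), 3)
  expect_equal(get("analog_negative_thialysine"), 2)
  expect_equal(get("analog_overlap_all"), 2)  # g01, g04 negative in both
  expect_equal(get("sga_negative"), 3)
  expect_equal(get("control_auc_ratio_percent"), 18.3)
  expect_equal(get("suppressor_count"), 2)

  # a planted discrepancy is flagged, matching values pass
  expect_true(rep$match[rep$metric == "screen_positive_genes"])
  expect_false(rep$match[rep$metric == "suppressor_count"])  # printed 7 != 2
  expect_true(is.na(rep$match[rep$metric == "sga_negative"]))

  # missing file is a loud warning, wrong columns a loud error
  file.remove(file.path(dir, man$sga$file))
  expect_warning(reproduce_from_supplements(dir), "missing file")
  bad <- man
  bad$screen$columns <- c(gene = "gene", z = "zz")
  expect_error(suppressWarnings(reproduce_from_supplements(dir, bad)),
               "lacks expected columns")
})

test_that("screen hits flow into overlap summaries", {
  sets <- list(azc = c("g1", "g2", "g3", "g4"),
               canavanine = c("g2", "g3", "g9"),
               thialysine = c("g3", "g4"))
  ov <- overlap(sets)
  expect_equal(ov$full_intersection, 1)
  expect_equal(ov$members, "g3")
  expect_output(print(ov), "azc: 4 genes")
})
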