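test_that("score filtering is inclusive at the cutoffs and order-preserving", {
  rec <- tibble::tibble(
    protein = "P", site = "1", glycan = "H5N2", sample = "T01",
    abundance = 1,
    ms1_score = c(3.0, 10, 2.9, 5),
    ms2_score = c(5.0, 4.9, 10, 8)
  )
  kept <- filter_by_scores(rec)
  expect_equal(kept$ms1_score, c(3.0, 5))  # boundary record kept; order kept
  expect_error(filter_by_scores(dplyr::mutate(rec, ms2_score = NA)),
               "record 1 has a missing ms2_score")
  expect_error(filter_by_scores(dplyr::select(rec, -ms1_score)),
               "lack a 'ms1_score'")
})

test_that("score filtering matches a brute-force loop on random records", {
  withr::local_seed(7)
  rec <- tibble::tibble(
    protein = "P", site = "1", glycan = "H5N2", sample = "T01", abundance = 1,
    ms1_score = runif(100, 0, 6), ms2_score = runif(100, 0, 10)
  )
  kept <- filter_by_scores(rec)
  want <- 0L
  for (i in 1:100) {
    if (rec$ms1_score[i] >= 3 && rec$ms2_score[i] >= 5) want <- want + 1L
  }
  expect_equal(nrow(kept), want)
  # idempotence
  expect_identical(filter_by_scores(kept), kept)
})

test_that("merging sums within-sample duplicates and keeps absences missing", {
  m <- merge_glyco_samples(tiny_records(), tiny_sample_sheet())
  expect_s3_class(m, "glyco_matrix")
  # P1/100/H5N2 appears twice in T01 (2 + 3) and once in A01
  row1 <- m[m$protein == "P1", ]
  expect_equal(row1$T01, 5)
  expect_equal(row1$A01, 4)
  expect_true(is.na(row1$T02))
  expect_true(is.na(row1$A02))
  # ambiguous site renders sorted and is a single feature
  expect_true("197/553" %in% m$site)
  expect_false("553/197" %in% m$site)
  expect_equal(sum(m$site == "197/553"), 1L)
  expect_equal(nrow(m), 3L)
})

test_that("merging rejects samples missing from or duplicated in the sheet", {
  bad_sheet <- tiny_sample_sheet()
  bad_sheet$sample[2] <- "T01" # same sample twice (hence in two groups)
  bad_sheet$group[2] <- "adjacent"
  expect_error(merge_glyco_samples(tiny_records(), bad_sheet),
               "more than once")
  expect_error(
    merge_glyco_samples(dplyr::mutate(tiny_records(), sample = "Tx"),
                        tiny_sample_sheet()),
    "missing from the sample sheet"
  )
})

test_that("merged row count equals the set union of per-sample keys", {
  withr::local_seed(11)
  sheet <- tiny_sample_sheet()
  pool <- glycan_composition_pool()
  recs <- purrr::map(sheet$sample, function(s) {
    n <- sample(5:20, 1)
    tibble::tibble(
      protein = sample(paste0("P", 1:10), n, replace = TRUE),
      site = as.character(sample(c(50, 100, 200), n, replace = TRUE)),
      glycan = sample(pool, n, replace = TRUE),
      sample = s, abundance = rlnorm(n),
      ms1_score = 4, ms2_score = 6
    )
  }) |> purrr::list_rbind()
  m <- merge_glyco_samples(recs, sheet)
  keys <- unique(paste(recs$protein, recs$site, recs$glycan))
  expect_equal(nrow(m), length(keys))
})

test_that("presence filter keeps >=5-in-one-group rows and matches a loop", {
  withr::local_seed(3)
  sheet <- tibble::tibble(
    sample = c(sprintf("T%02d", 1:12), sprintf("A%02d", 1:12)),
    group = rep(c("tumor", "adjacent"), each = 12)
  )
  n <- 200
  vals <- matrix(ifelse(runif(n * 24) < 0.3, rlnorm(n * 24), NA), n, 24)
  m <- tibble::tibble(protein = paste0("P", 1:n), site = "1", glycan = "H5N2")
  for (j in 1:24) m[[sheet$sample[j]]] <- vals[, j]
  m <- glycodiff:::new_glyco_matrix(m, sheet)
  kept <- presence_filter(m, 5)
  expect_equal(nrow(kept), sum(presence_oracle(m, 5)))
  # idempotence and boundary behavior
  expect_equal(nrow(presence_filter(kept, 5)), nrow(kept))
  expect_error(presence_filter(m, 13), "exceeds both group sizes")
  # explicit boundary rows: 5 tumor / 0 adjacent kept, 4 / 4 dropped
  boundary <- tibble::tibble(protein = c("B1", "B2"), site = "1",
                             glycan = "H5N2")
  for (j in 1:24) {
    boundary[[sheet$sample[j]]] <- c(
      if (j <= 5) 1 else NA,            # 5 tumor only
      if (j %in% c(1:4, 13:16)) 1 else NA # 4 + 4
    )
  }
  mb <- glycodiff:::new_glyco_matrix(boundary, sheet)
  expect_equal(presence_filter(mb, 5)$protein, "B1")
})

test_that("filter ordering: score-then-presence is the stricter composition", {
  sim <- simulate_glyco_dataset(seed = 19, n_glycoproteins = 40)
  key_of <- function(m) paste(m$protein, m$site, m$glycan)
  # canonical order: drop sub-threshold records, then require presence
  a <- sim$records |> filter_by_scores() |>
    merge_glyco_samples(sim$sample_sheet) |> presence_filter()
  # reversed order: presence counts inflated by sub-threshold records
  pre <- merge_glyco_samples(sim$records, sim$sample_sheet) |> presence_filter()
  b <- sim$records |> filter_by_scores() |> merge_glyco_samples(sim$sample_sheet)
  b <- b[key_of(b) %in% key_of(pre), ]
  expect_true(all(key_of(a) %in% key_of(b)))
  # with no sub-threshold records the two orders coincide exactly
  clean <- dplyr::mutate(sim$records, ms1_score = 10, ms2_score = 10)
  a2 <- clean |> filter_by_scores() |>
    merge_glyco_samples(sim$sample_sheet) |> presence_filter()
  b2 <- merge_glyco_samples(clean, sim$sample_sheet) |> presence_filter()
  expect_identical(key_of(a2), key_of(b2))
})

test_that("singleton statistics match a hand count", {
  m <- merge_glyco_samples(tiny_records(), tiny_sample_sheet())
  st <- singleton_stats(m)
  # P1/100 has 2 samples, P2 ambiguous has 2, P2/40 has 1 -> 1 of 3
  expect_equal(st$n_glycopeptides, 3L)
  expect_equal(st$n_singletons, 1L)
  expect_equal(st$fraction, 1 / 3)
  rec <- tiny_records()
  one_each <- rec[!duplicated(paste(rec$protein, render_site_oracle(rec$site),
                                    rec$glycan)), ]
  expect_equal(
    singleton_stats(merge_glyco_samples(one_each, tiny_sample_sheet()))$fraction,
    1
  )
})

test_that("adaptive test picks the right branch and handles degeneracy", {
  x <- c(1.2, 2.3, 3.1, 4.5, 5.0)
  res <- adaptive_test(x, x, log_transform = FALSE)
  expect_equal(res$test_used, "student")
  expect_equal(res$p, 1)
  expect_equal(res$statistic, 0)
  expect_error(adaptive_test(c(1, 2), c(1, 2, 3), log_transform = FALSE),
               "at least 3 observations")
  expect_error(adaptive_test(c(-1, 2, 3), c(1, 2, 3)), "positive abundances")
  # constant data: degenerate but defined
  res0 <- adaptive_test(rep(2, 4), rep(2, 5), log_transform = FALSE)
  expect_equal(res0$p, 1)
})

test_that("heavy-tailed data route to Wilcoxon in the majority of draws", {
  withr::local_seed(5)
  used <- replicate(200, {
    adaptive_test(rlnorm(15, sdlog = 2), rlnorm(15, sdlog = 2),
                  log_transform = FALSE)$test_used
  })
  expect_gt(mean(used == "wilcoxon"), 0.5)
})

test_that("unequal variances under normality route to Welch", {
  withr::local_seed(8)
  used <- replicate(200, {
    adaptive_test(rnorm(20, sd = 1), rnorm(20, sd = 6),
                  log_transform = FALSE)$test_used
  })
  expect_gt(mean(used == "welch"), 0.5)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  withr::local_seed(21)
  for (rep in 1:10) {
    p <- runif(sample(5:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, NA)), "0, 1")
})

test_that("differential testing reports means, fold-changes and BH q", {
  withr::local_seed(13)
  sim <- simulate_glyco_dataset(seed = 13, n_glycoproteins = 50,
                                glyco_effect_fraction = 0.1)
  m <- sim$records |> filter_by_scores() |>
    merge_glyco_samples(sim$sample_sheet) |> presence_filter()
  res <- diff_glycopeptides(m)
  expect_equal(nrow(res), nrow(m))
  tested <- !is.na(res$p)
  expect_equal(res$q[tested], bh_oracle(res$p[tested]))
  expect_true(all(res$test_used[tested] %in% c("student", "welch", "wilcoxon")))
  # fold-change is the ratio of group means of observed values
  i <- which(tested)[1]
  vals <- glycodiff:::glyco_values(m)[i, ]
  sheet <- glyco_samples(m)
  expect_equal(
    res$fold_change[i],
    mean(vals[sheet$sample[sheet$group == "tumor"]], na.rm = TRUE) /
      mean(vals[sheet$sample[sheet$group == "adjacent"]], na.rm = TRUE)
  )
})

test_that("per-sample overall metrics equal a loop recomputation", {
  withr::local_seed(17)
  sim <- simulate_glyco_dataset(seed = 17, n_glycoproteins = 30)
  m <- merge_glyco_samples(sim$records, sim$sample_sheet)
  met <- sample_glyco_metrics(m)
  sheet <- glyco_samples(m)
  expect_equal(nrow(met), nrow(sheet))
  ann <- glycan_metrics(m$glycan)
  for (s in sample(sheet$sample, 4)) {
    ab <- glycodiff:::glyco_values(m)[, s]
    ok <- !is.na(ab) & ab > 0
    want <- weighted_metrics_oracle(ann[ok, ], ab[ok])
    row <- met[met$sample == s, ]
    expect_equal(row$sialylation, unname(want["sialylation"]), tolerance = 1e-12)
    expect_equal(row$galactosylation, unname(want["galactosylation"]),
                 tolerance = 1e-12)
    expect_equal(row$fucosylation, unname(want["fucosylation"]),
                 tolerance = 1e-12)
  }
  # identical columns give identical metric triples
  m2 <- m
  m2[[sheet$sample[2]]] <- m2[[sheet$sample[1]]]
  met2 <- sample_glyco_metrics(m2)
  expect_equal(unlist(met2[1, 3:5]), unlist(met2[2, 3:5]))
  cmp <- compare_glyco_metrics(met)
  expect_equal(nrow(cmp), 3L)
  expect_true(all(cmp$q >= cmp$p))
})

test_that("an empty sample is flagged rather than scored", {
  rec <- tiny_records()[tiny_records()$sample != "T02", ]
  m <- merge_glyco_samples(rec, tiny_sample_sheet())
  met <- sample_glyco_metrics(m)
  expect_true(met$empty[met$sample == "T02"])
  expect_true(is.na(met$sialylation[met$sample == "T02"]))
})

test_that("fold-change overlay attributes changes by protein agreement", {
  glyco <- tibble::tibble(
    protein = c("PA", "PB", "PC"), site = "1", glycan = "H5N4S1",
    n_tumor = 6, n_adjacent = 6, mean_tumor = c(4, 0.2, 8),
    mean_adjacent = 1, fold_change = c(4, 0.2, 8),
    test_used = "student", statistic = 1, p = 0.001, q = 0.004
  )
  prot <- tibble::tibble(protein = c("PA", "PB"), fold_change = c(4, 1))
  ov <- fold_change_overlay(glyco, prot)
  expect_equal(ov$attribution[ov$protein == "PA"], "expression-driven")
  # protein flat while the glycoform collapses: glycosylation event
  expect_equal(ov$attribution[ov$protein == "PB"], "glycosylation-driven")
  expect_equal(ov$attribution[ov$protein == "PC"], "unattributed")
  expect_true(is.na(ov$protein_fold_change[ov$protein == "PC"]))
  # opposite directions are glycosylation-driven too
  prot2 <- tibble::tibble(protein = "PA", log2_fc = -2)
  expect_equal(fold_change_overlay(glyco[1, ], prot2)$attribution,
               "glycosylation-driven")
  # non-significant glycopeptides never enter the overlay
  expect_equal(nrow(fold_change_overlay(dplyr::mutate(glyco, q = 0.5), prot)),
               0L)
})
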