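test_that("protein-group filtering drops decoys and enforces 2/3 presence", {
  sheet <- make_sheet()
  withr::local_seed(1)
  n <- 150
  tab <- tibble::tibble(
    protein = paste0("P", 1:n), gene = paste0("G", 1:n),
    reverse = rep(c(TRUE, FALSE), c(10, n - 10)),
    contaminant = c(rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, n - 20))
  )
  for (s in sheet$sample) {
    tab[[s]] <- ifelse(runif(n) < 0.7, rlnorm(n, 17), NA)
  }
  kept <- filter_protein_groups(tab, sheet)
  expect_false(any(kept$reverse | kept$contaminant))
  # loop oracle: >= ceil(2/3 * 12) = 8 observed in one of the groups
  vals <- as.matrix(tab[sheet$sample])
  keep_want <- logical(n)
  for (i in 1:n) {
    nt <- sum(!is.na(vals[i, 1:12]))
    na_ <- sum(!is.na(vals[i, 13:24]))
    keep_want[i] <- !tab$reverse[i] && !tab$contaminant[i] &&
      (nt >= 8 || na_ >= 8)
  }
  expect_equal(kept$protein, tab$protein[keep_want])
  # boundary: complete in one group only is kept; contaminants never are
  b <- tab[1:2, ]
  b$protein <- c("B1", "B2")
  b$reverse <- FALSE
  b$contaminant <- c(FALSE, TRUE)
  for (j in seq_len(nrow(sheet))) {
    b[[sheet$sample[j]]] <- if (j <= 8) c(1, 1) else c(NA, NA)
  }
  expect_equal(filter_protein_groups(b, sheet)$protein, "B1")
})

test_that("left-censored imputation fills the left tail reproducibly", {
  sheet <- make_sheet()
  withr::local_seed(2)
  n <- 600
  complete <- tibble::tibble(protein = paste0("P", 1:n))
  for (s in sheet$sample) complete[[s]] <- rnorm(n, 25, 2)
  # no missing values: returned unchanged
  expect_identical(impute_left_censored(complete, sheet, seed = 1), complete)
  # plant censoring below a known per-sample threshold
  censored <- complete
  for (s in sheet$sample) {
    cut <- quantile(censored[[s]], 0.2)
    censored[[s]][censored[[s]] < cut] <- NA
  }
  imp1 <- impute_left_censored(censored, sheet, seed = 99)
  imp2 <- impute_left_censored(censored, sheet, seed = 99)
  expect_identical(imp1, imp2)
  imp3 <- impute_left_censored(censored, sheet, seed = 100)
  expect_false(identical(imp1, imp3))
  # observed cells are untouched
  for (s in sheet$sample) {
    obs <- !is.na(censored[[s]])
    expect_identical(imp1[[s]][obs], censored[[s]][obs])
  }
  # imputed draws sit in the left tail: below the observed minimum + 1 sd
  below <- vapply(sheet$sample, function(s) {
    miss <- is.na(censored[[s]])
    lim <- min(censored[[s]], na.rm = TRUE) + sd(censored[[s]], na.rm = TRUE)
    mean(imp1[[s]][miss] < lim)
  }, double(1))
  expect_gte(mean(below), 0.95)
  # too few observations to fit
  tiny <- tibble::tibble(protein = c("a", "b", "c"))
  for (s in sheet$sample) tiny[[s]] <- c(1, NA, NA)
  expect_error(impute_left_censored(tiny, sheet), "observed values")
})

test_that("moderated t reduces to the classical t when the prior is off", {
  sheet <- make_sheet(6)
  withr::local_seed(3)
  n <- 80
  tab <- tibble::tibble(protein = paste0("P", 1:n))
  for (s in sheet$sample) tab[[s]] <- rnorm(n, 20, 1)
  fit0 <- fit_moderated_t(tab, sheet, d0 = 0)
  r0 <- tidy(fit0)
  for (i in c(1, 17, 42)) {
    x <- as.numeric(tab[i, sheet$sample[sheet$group == "tumor"]])
    y <- as.numeric(tab[i, sheet$sample[sheet$group == "adjacent"]])
    expect_equal(r0$t_mod[i], classical_t_oracle(x, y), tolerance = 1e-9)
    expect_equal(r0$p[i], t.test(x, y, var.equal = TRUE)$p.value,
                 tolerance = 1e-9)
  }
  expect_equal(r0$s2_post, r0$s2)
  expect_equal(unique(r0$df_total), length(sheet$sample) - 2)
  # complete shrinkage: every posterior variance equals the prior
  fit_inf <- fit_moderated_t(tab, sheet, d0 = Inf)
  r_inf <- tidy(fit_inf)
  expect_equal(r_inf$s2_post, rep(fit_inf$s0_sq, n))
})

test_that("posterior variances interpolate between s2 and the prior", {
  sheet <- make_sheet(8)
  withr::local_seed(4)
  n <- 300
  tab <- tibble::tibble(protein = paste0("P", 1:n))
  sigma <- 0.5 * sqrt(4 / rchisq(n, 4))
  for (s in sheet$sample) tab[[s]] <- rnorm(n, 20, sigma)
  fit <- fit_moderated_t(tab, sheet)
  r <- tidy(fit)
  expect_true(fit$d0 > 0)
  lo <- pmin(r$s2, fit$s0_sq) - 1e-12
  hi <- pmax(r$s2, fit$s0_sq) + 1e-12
  expect_true(all(r$s2_post >= lo & r$s2_post <= hi))
  expect_equal(unique(r$df_total), fit$d0 + unique(r$df_residual))
  expect_equal(r$q, bh_oracle(r$p))
})

test_that("moderated t agrees with an independent empirical-Bayes fit", {
  skip_if_not_installed("limma")
  sheet <- make_sheet()
  withr::local_seed(5)
  n <- 400
  tab <- tibble::tibble(protein = paste0("P", 1:n))
  sigma <- 0.4 * sqrt(5 / rchisq(n, 5))
  fc <- ifelse(runif(n) < 0.1, 2, 0)
  for (j in seq_len(nrow(sheet))) {
    tab[[sheet$sample[j]]] <- rnorm(n, 20 + fc * (sheet$group[j] == "tumor"),
                                    sigma)
  }
  fit <- fit_moderated_t(tab, sheet)
  x <- as.matrix(tab[sheet$sample])
  design <- cbind(1, sheet$group == "tumor")
  lfit <- limma::eBayes(limma::lmFit(x, design))
  expect_equal(fit$d0, unname(lfit$df.prior), tolerance = 1e-8)
  expect_equal(fit$s0_sq, unname(lfit$s2.prior), tolerance = 1e-8)
  expect_equal(tidy(fit)$t_mod, unname(lfit$t[, 2]), tolerance = 1e-8)
  expect_equal(tidy(fit)$p, unname(lfit$p.value[, 2]), tolerance = 1e-8)
})

test_that("null p-values are approximately uniform", {
  sheet <- make_sheet()
  withr::local_seed(6)
  n <- 2000
  tab <- tibble::tibble(protein = paste0("P", 1:n))
  sigma <- 0.4 * sqrt(5 / rchisq(n, 5))
  for (s in sheet$sample) tab[[s]] <- rnorm(n, 20, sigma)
  fit <- fit_moderated_t(tab, sheet)
  ks <- suppressWarnings(ks.test(tidy(fit)$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate variance input raises, zero rows are offset", {
  sheet <- make_sheet(3)
  tab <- tibble::tibble(protein = c("a", "b"))
  for (s in sheet$sample) tab[[s]] <- c(1, 2)
  expect_error(fit_moderated_t(tab, sheet), "zero variance")
  tab2 <- tab
  tab2[[sheet$sample[1]]] <- c(1, 2.5) # one protein with spread
  fit <- fit_moderated_t(tab2, sheet)
  expect_true(all(is.finite(tidy(fit)$s2_post)))
})

test_that("planted effects are detected with high sensitivity and tidiers work", {
  sim <- simulate_protein_dataset(seed = 7, n_proteins = 1000)
  fit <- sim$table |>
    filter_protein_groups(sim$sample_sheet) |>
    log2_intensities(sim$sample_sheet) |>
    impute_left_censored(sim$sample_sheet, seed = 8) |>
    fit_moderated_t(sim$sample_sheet)
  joined <- dplyr::inner_join(tidy(fit), sim$truth, by = "protein")
  sens <- mean(joined$q[joined$de] < 0.05)
  expect_gt(sens, 0.8)
  g <- glance(fit)
  expect_equal(g$n_significant, sum(tidy(fit)$q < 0.05))
  expect_equal(g$n_up + g$n_down, g$n_significant)
  # planted log2 fold-changes are recovered without systematic bias
  med_err <- median(abs(joined$log2_fc.x - joined$log2_fc.y)[joined$de])
  expect_lt(med_err, 0.5)
})
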