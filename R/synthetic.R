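#' Curated pool of plausible N-glycan compositions
#'
#' A hand-curated list of roughly forty compositions spanning the
#' high-mannose series (H5N2 to H9N2), paucimannose, hybrid and complex
#' types with and without fucose (F0/1) and with up to two sialic acids,
#' mirroring the compositions that dominate human tissue glycoproteomics.
#'
#' @return Character vector of canonical composition strings.
#' @export
glycan_composition_pool <- function() {
  pool <- c(
    paste0("H", 5:9, "N2"),                    # high-mannose series
    "H3N2", "H4N2", "F1H3N2", "F1H4N2",        # paucimannose
    "H5N3", "H6N3", "H5N3S1", "F1H5N3",        # hybrid
    # complex: bi- to tetra-antennary, galactosylated/sialylated/fucosylated
    "H3N4", "H4N4", "H5N4", "H5N4S1", "H5N4S2",
    "F1H3N4", "F1H4N4", "F1H5N4", "F1H5N4S1", "F1H5N4S2",
    "H4N3", "F1H4N3", "H6N5", "H6N5S1", "H6N5S2",
    "F1H6N5", "F1H6N5S1", "F1H6N5S2", "H7N6", "H7N6S1",
    "H7N6S2", "F1H7N6", "F1H7N6S1", "H4N5", "F1H4N5",
    "H5N5", "F1H5N5", "H5N5S1", "H6N4", "F1H6N4S1"
  )
  glycan_parse(pool)$glycan
}

default_sample_sheet <- function(n_per_group) {
  tibble::tibble(
    sample = c(sprintf("T%02d", seq_len(n_per_group)),
               sprintf("A%02d", seq_len(n_per_group))),
    group = rep(c("tumor", "adjacent"), each = n_per_group)
  )
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop("`", name, "` must be a single fraction in [0, 1]")
  }
  x
}

n_planted <- function(fraction, n, name) {
  k <- round(fraction * n)
  if (fraction > 0 && k < 1) {
    stop("infeasible configuration: ", name, " = ", fraction,
         " plants fewer than one feature among ", n)
  }
  k
}

#' Simulate a protein-group quantification dataset with known truth
#'
#' Generates a label-free protein intensity table emulating MaxQuant
#' `proteinGroups` output for a two-group tissue cohort. Log2 intensities
#' are Gaussian around protein-specific baselines with protein-specific
#' residual variances drawn from a scaled inverse chi-squared prior (so
#' the empirical-Bayes variance moderation has a true prior to recover).
#' A chosen fraction of proteins carries a planted group shift of
#' `de_log2fc` (random sign). Missingness is left-censored: within each
#' sample, values below that sample's `censoring_quantile` quantile are
#' deleted. Reverse and contaminant decoy rows are appended.
#'
#' @param n_per_group samples per group (default 12, the study cohort size).
#' @param n_proteins number of genuine protein groups (default 2000).
#' @param de_fraction fraction of proteins with a planted effect
#'   (default 0.1).
#' @param de_log2fc absolute planted log2 fold-change (default 2).
#' @param baseline_mean,baseline_sd mean and sd of protein log2 baselines
#'   (defaults 25 and 2, typical of LFQ intensities).
#' @param sigma0,df0 scale and degrees of freedom of the residual-sd prior
#'   (defaults 0.4 and 5): per-protein variance is
#'   `sigma0^2 * df0 / rchisq(df0)`.
#' @param censoring_quantile per-sample left-censoring quantile
#'   (default 0.15).
#' @param n_reverse,n_contaminant decoy rows appended (defaults 25 each).
#' @param seed optional integer for reproducibility.
#' @return A list: `table` (tibble: `protein`, `gene`, `reverse`,
#'   `contaminant`, raw intensity per sample with `NA` missing), `truth`
#'   (tibble: `protein`, `de`, `log2_fc`), `sample_sheet`.
#' @export
simulate_protein_dataset <- function(n_per_group = 12L, n_proteins = 2000L,
                                     de_fraction = 0.1, de_log2fc = 2,
                                     baseline_mean = 25, baseline_sd = 2,
                                     sigma0 = 0.4, df0 = 5,
                                     censoring_quantile = 0.15,
                                     n_reverse = 25L, n_contaminant = 25L,
                                     seed = NULL) {
  check_fraction(de_fraction, "de_fraction")
  check_fraction(censoring_quantile, "censoring_quantile")
  stopifnot(n_per_group >= 2L, n_proteins >= 1L)
  gen <- function() {
    sheet <- default_sample_sheet(n_per_group)
    k <- n_planted(de_fraction, n_proteins, "de_fraction")
    proteins <- sprintf("PROT%04d", seq_len(n_proteins))
    genes <- sprintf("GENE%04d", seq_len(n_proteins))
    de_idx <- sample.int(n_proteins, k)
    log2_fc <- rep(0, n_proteins)
    log2_fc[de_idx] <- sample(c(-1, 1), k, replace = TRUE) * de_log2fc
    baseline <- stats::rnorm(n_proteins, baseline_mean, baseline_sd)
    sigma <- sigma0 * sqrt(df0 / stats::rchisq(n_proteins, df = df0))
    is_tumor <- sheet$group == "tumor"
    x <- baseline +
      outer(log2_fc, as.numeric(is_tumor)) +
      matrix(stats::rnorm(n_proteins * nrow(sheet), sd = sigma),
             nrow = n_proteins)
    # per-sample left censoring at the sample's lower quantile
    for (j in seq_len(ncol(x))) {
      cut <- stats::quantile(x[, j], censoring_quantile, names = FALSE)
      x[x[, j] < cut, j] <- NA_real_
    }
    tab <- tibble::tibble(
      protein = proteins, gene = genes,
      reverse = FALSE, contaminant = FALSE
    )
    for (j in seq_len(nrow(sheet))) tab[[sheet$sample[j]]] <- 2^x[, j]
    n_decoy <- n_reverse + n_contaminant
    if (n_decoy > 0) {
      decoy <- tibble::tibble(
        protein = c(sprintf("REV__PROT%04d", seq_len(n_reverse)),
                    sprintf("CON__PROT%04d", seq_len(n_contaminant))),
        gene = NA_character_,
        reverse = rep(c(TRUE, FALSE), c(n_reverse, n_contaminant)),
        contaminant = rep(c(FALSE, TRUE), c(n_reverse, n_contaminant))
      )
      dx <- matrix(2^stats::rnorm(n_decoy * nrow(sheet), baseline_mean,
                                  baseline_sd),
                   nrow = n_decoy)
      for (j in seq_len(nrow(sheet))) decoy[[sheet$sample[j]]] <- dx[, j]
      tab <- dplyr::bind_rows(tab, decoy)
    }
    list(
      table = tab,
      truth = tibble::tibble(protein = proteins, de = log2_fc != 0,
                             log2_fc = log2_fc),
      sample_sheet = sheet
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate site-specific glycopeptide quantification tables with known truth
#'
#' Generates per-sample glycopeptide records emulating merged
#' GlycReSoft-style output for a two-group cohort: glycoproteins carry one
#' to three glycosites (occasionally an ambiguous `"x/y"` site), each
#' bearing one to four glycoforms drawn from [glycan_composition_pool()].
#' The observation mask reproduces the sparsity of real site-specific
#' data: a `singleton_inflation` fraction of glycopeptides is observed in
#' exactly one sample, the remainder with a low glycopeptide-specific
#' detection probability. Two kinds of effects are planted: glycosylation
#' driven (one glycoform shifted `glyco_fold`-fold while its protein stays
#' flat) and expression driven (every glycoform of a protein shifted
#' coherently, matching a planted protein-level effect). Planted
#' glycopeptides are made reliably detectable so they survive the presence
#' filter. A `decoy_fraction` of records receives sub-threshold MS1/MS2
#' scores.
#'
#' @param n_per_group samples per group (default 12).
#' @param n_glycoproteins number of glycoproteins (default 365, the study
#'   scale; the implied glycopeptide count is about 1600).
#' @param singleton_inflation target fraction of glycopeptides observed in
#'   exactly one sample (default 0.68).
#' @param detect_shape1,detect_shape2 Beta parameters of the per-feature
#'   detection probability for non-singleton glycopeptides (default
#'   Beta(1, 4)).
#' @param glyco_effect_fraction fraction of glycopeptides with planted
#'   effects (default 0.03), split evenly between glycosylation-driven and
#'   expression-driven.
#' @param glyco_fold absolute planted fold-change (default 4).
#' @param baseline_mean,baseline_sd,noise_sd log2 abundance model
#'   (defaults 20, 2, 0.8).
#' @param decoy_fraction fraction of records with sub-threshold scores
#'   (default 0.1).
#' @param ambiguous_site_prob probability a glycosite is an ambiguous pair
#'   (default 0.05).
#' @param seed optional integer for reproducibility.
#' @return A list: `records` (long tibble: `protein`, `site`, `glycan`,
#'   `sample`, `group`, `abundance`, `ms1_score`, `ms2_score`), `truth`
#'   (per glycopeptide: `protein`, `site`, `glycan`, `effect`, `fold`,
#'   `attribution` in `"none"`/`"glycosylation"`/`"expression"`),
#'   `protein_truth` (per glycoprotein planted `log2_fc`), `sample_sheet`.
#' @export
simulate_glyco_dataset <- function(n_per_group = 12L, n_glycoproteins = 365L,
                                   singleton_inflation = 0.68,
                                   detect_shape1 = 1, detect_shape2 = 4,
                                   glyco_effect_fraction = 0.03,
                                   glyco_fold = 4,
                                   baseline_mean = 20, baseline_sd = 2,
                                   noise_sd = 0.8,
                                   decoy_fraction = 0.1,
                                   ambiguous_site_prob = 0.05,
                                   seed = NULL) {
  check_fraction(singleton_inflation, "singleton_inflation")
  check_fraction(glyco_effect_fraction, "glyco_effect_fraction")
  check_fraction(decoy_fraction, "decoy_fraction")
  stopifnot(n_per_group >= 2L, n_glycoproteins >= 1L, glyco_fold > 0)
  gen <- function() {
    sheet <- default_sample_sheet(n_per_group)
    n_samples <- nrow(sheet)
    pool <- glycan_composition_pool()
    proteins <- sprintf("GPROT%04d", seq_len(n_glycoproteins))
    features <- purrr::map(seq_len(n_glycoproteins), function(i) {
      n_sites <- sample(1:3, 1)
      pos <- sort(sample(30:900, n_sites + 2L))
      sites <- vapply(seq_len(n_sites), function(s) {
        if (stats::runif(1) < ambiguous_site_prob) {
          paste(sort(pos[c(s, s + 2L)]), collapse = "/")
        } else {
          as.character(pos[s])
        }
      }, character(1))
      purrr::map(sites, function(site) {
        n_forms <- sample(1:4, 1, prob = c(0.35, 0.3, 0.2, 0.15))
        tibble::tibble(protein = proteins[i], site = site,
                       glycan = sample(pool, n_forms))
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
    features <- dplyr::distinct(features, .data$protein, .data$site,
                                .data$glycan)
    n_feat <- nrow(features)

    # planted effects: half glycosylation-driven, half expression-driven
    k <- n_planted(glyco_effect_fraction, n_feat, "glyco_effect_fraction")
    k_gly <- ceiling(k / 2)
    k_exp <- k - k_gly
    attribution <- rep("none", n_feat)
    fold <- rep(1, n_feat)
    idx_gly <- sample.int(n_feat, k_gly)
    attribution[idx_gly] <- "glycosylation"
    fold[idx_gly] <- ifelse(stats::runif(k_gly) < 0.5, glyco_fold,
                            1 / glyco_fold)
    protein_log2fc <- stats::setNames(rep(0, n_glycoproteins), proteins)
    if (k_exp > 0) {
      free <- setdiff(unique(features$protein), features$protein[idx_gly])
      exp_prot <- sample(free, min(k_exp, length(free)))
      exp_fc <- ifelse(stats::runif(length(exp_prot)) < 0.5,
                       glyco_fold, 1 / glyco_fold)
      protein_log2fc[exp_prot] <- log2(exp_fc)
      hit <- features$protein %in% exp_prot
      attribution[hit] <- "expression"
      fold[hit] <- exp_fc[match(features$protein[hit], exp_prot)]
    }

    # observation mask: singletons vs Beta-distributed detection probability;
    # planted features are made reliably detectable
    planted <- attribution != "none"
    # planted features are never singletons; rescale so the overall singleton
    # fraction still targets `singleton_inflation`
    p_singleton <- min(1, singleton_inflation / max(1 - mean(planted), 1e-9))
    singleton <- !planted & stats::runif(n_feat) < p_singleton
    p_detect <- stats::rbeta(n_feat, detect_shape1, detect_shape2)
    p_detect[planted] <- 0.85
    mask <- matrix(FALSE, n_feat, n_samples)
    for (i in seq_len(n_feat)) {
      if (singleton[i]) {
        mask[i, sample.int(n_samples, 1)] <- TRUE
      } else {
        obs <- stats::runif(n_samples) < p_detect[i]
        if (sum(obs) < 2L) obs[sample.int(n_samples, 2)] <- TRUE
        mask[i, ] <- obs
      }
    }

    baseline <- stats::rnorm(n_feat, baseline_mean, baseline_sd)
    is_tumor <- sheet$group == "tumor"
    recs <- purrr::map(seq_len(n_feat), function(i) {
      cols <- which(mask[i, ])
      x <- baseline[i] + log2(fold[i]) * is_tumor[cols] +
        stats::rnorm(length(cols), sd = noise_sd)
      tibble::tibble(
        protein = features$protein[i], site = features$site[i],
        glycan = features$glycan[i],
        sample = sheet$sample[cols], group = sheet$group[cols],
        abundance = 2^x
      )
    }) |> purrr::list_rbind()
    n_rec <- nrow(recs)
    decoy <- stats::runif(n_rec) < decoy_fraction
    recs$ms1_score <- ifelse(decoy, stats::runif(n_rec, 0, 2.9),
                             3 + stats::rexp(n_rec, rate = 1 / 3))
    recs$ms2_score <- ifelse(decoy, stats::runif(n_rec, 0, 4.9),
                             5 + stats::rexp(n_rec, rate = 1 / 5))
    list(
      records = recs,
      truth = dplyr::mutate(features, effect = planted, fold = fold,
                            attribution = attribution),
      protein_truth = tibble::tibble(protein = proteins,
                                     log2_fc = unname(protein_log2fc)),
      sample_sheet = sheet
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a coherent proteomics + glycoproteomics study
#'
#' Couples [simulate_glyco_dataset()] and [simulate_protein_dataset()] so
#' the two arms describe the same samples: the glycoproteins appear in the
#' protein table with planted protein effects matching the glycopeptide
#' truth — expression-driven glycopeptides sit on proteins that are
#' genuinely differentially expressed, glycosylation-driven ones on flat
#' proteins. This is the end-to-end fixture for testing fold-change
#' attribution.
#'
#' @param n_per_group samples per group (default 12).
#' @param n_background_proteins non-glycosylated proteins added to the
#'   protein table (default 1500).
#' @param seed optional integer seed.
#' @param ... passed to [simulate_glyco_dataset()].
#' @return A list: `glyco` (as from [simulate_glyco_dataset()]), `protein`
#'   (as from [simulate_protein_dataset()] but with the glycoproteins
#'   included and their planted effects aligned), `sample_sheet`.
#' @export
simulate_study <- function(n_per_group = 12L, n_background_proteins = 1500L,
                           seed = NULL, ...) {
  gen <- function() {
    glyco <- simulate_glyco_dataset(n_per_group = n_per_group, ...)
    prot <- simulate_protein_dataset(
      n_per_group = n_per_group,
      n_proteins = n_background_proteins, seed = NULL
    )
    sheet <- glyco$sample_sheet
    gp <- glyco$protein_truth
    baseline <- stats::rnorm(nrow(gp), 25, 2)
    sigma <- 0.4 * sqrt(5 / stats::rchisq(nrow(gp), df = 5))
    is_tumor <- sheet$group == "tumor"
    x <- baseline + outer(gp$log2_fc, as.numeric(is_tumor)) +
      matrix(stats::rnorm(nrow(gp) * nrow(sheet), sd = sigma), nrow = nrow(gp))
    gtab <- tibble::tibble(protein = gp$protein, gene = gp$protein,
                           reverse = FALSE, contaminant = FALSE)
    for (j in seq_len(nrow(sheet))) gtab[[sheet$sample[j]]] <- 2^x[, j]
    prot$table <- dplyr::bind_rows(gtab, prot$table)
    prot$truth <- dplyr::bind_rows(
      tibble::tibble(protein = gp$protein, de = gp$log2_fc != 0,
                     log2_fc = gp$log2_fc),
      prot$truth
    )
    list(glyco = glyco, protein = prot, sample_sheet = sheet)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Write a simulated study to disk in the pipelines' input dialects
#'
#' Writes one glycopeptide CSV per sample, a MaxQuant-style
#' `proteinGroups.txt`, the shared sample sheet, and the ground-truth
#' tables.
#'
#' @param sim output of [simulate_study()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(all(c("glyco", "protein", "sample_sheet") %in% names(sim)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sheet <- sim$sample_sheet
  readr::write_tsv(sheet, file.path(dir, "samplesheet.tsv"))
  for (s in sheet$sample) {
    recs <- dplyr::filter(sim$glyco$records, .data$sample == s)
    readr::write_csv(
      dplyr::select(recs, dplyr::all_of(c("protein", "site", "glycan",
                                          "abundance", "ms1_score",
                                          "ms2_score"))),
      file.path(dir, paste0(s, ".csv"))
    )
  }
  # MaxQuant proteinGroups dialect
  tab <- sim$protein$table
  mq <- tibble::tibble(
    `Majority protein IDs` = tab$protein,
    `Gene names` = tab$gene,
    Reverse = ifelse(tab$reverse, "+", ""),
    `Potential contaminant` = ifelse(tab$contaminant, "+", "")
  )
  for (s in sheet$sample) {
    v <- tab[[s]]
    v[is.na(v)] <- 0 # MaxQuant writes 0 for missing
    mq[[paste0("LFQ intensity ", s)]] <- v
  }
  readr::write_tsv(mq, file.path(dir, "proteinGroups.txt"))
  readr::write_tsv(sim$glyco$truth, file.path(dir, "glyco_truth.tsv"))
  readr::write_tsv(sim$protein$truth, file.path(dir, "protein_truth.tsv"))
  invisible(dir)
}
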