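#' @keywords internal
check_sample_sheet <- function(sample_sheet) {
  stopifnot(is.data.frame(sample_sheet),
            all(c("sample", "group") %in% names(sample_sheet)))
  if (anyDuplicated(sample_sheet$sample)) {
    dup <- sample_sheet$sample[duplicated(sample_sheet$sample)][1]
    stop("sample '", dup, "' appears more than once in the sample sheet")
  }
  bad <- setdiff(unique(sample_sheet$group), c("tumor", "adjacent"))
  if (length(bad)) {
    stop("unknown group label '", bad[1], "'; expected 'tumor' or 'adjacent'")
  }
  tibble::as_tibble(sample_sheet[c("sample", "group")])
}

# Canonical rendering of a (possibly ambiguous) glycosite: "553/197" -> "197/553".
render_site <- function(site) {
  vapply(as.character(site), function(s) {
    parts <- stringr::str_split_1(s, "/")
    nums <- suppressWarnings(as.integer(parts))
    if (anyNA(nums) || any(nums < 1L)) {
      stop("invalid glycosite '", s, "': sites are 1-based residue positions",
           call. = FALSE)
    }
    paste(sort(unique(nums)), collapse = "/")
  }, character(1), USE.NAMES = FALSE)
}

#' Filter glycopeptide records by identification scores
#'
#' Keeps records whose MS1 and MS2 identification scores both reach their
#' minimum acceptable values (inclusive). The defaults, MS1 >= 3.0 and
#' MS2 >= 5.0, are the conventional confidence cutoffs for
#' GlycReSoft-style output.
#'
#' @param records a data frame of glycopeptide records with numeric columns
#'   `ms1_score` and `ms2_score`.
#' @param ms1_min,ms2_min score cutoffs, inclusive.
#' @return The surviving records, input order preserved.
#' @export
filter_by_scores <- function(records, ms1_min = 3.0, ms2_min = 5.0) {
  stopifnot(is.data.frame(records))
  for (col in c("ms1_score", "ms2_score")) {
    if (!col %in% names(records)) stop("records lack a '", col, "' column")
    if (anyNA(records[[col]])) {
      i <- which(is.na(records[[col]]))[1]
      stop("record ", i, " has a missing ", col)
    }
  }
  dplyr::filter(records, .data$ms1_score >= ms1_min, .data$ms2_score >= ms2_min)
}

#' Merge per-sample glycopeptide tables into an abundance matrix
#'
#' Combines records from all samples into one matrix-shaped tibble with a
#' row per distinct glycopeptide — a (protein, glycosite, glycan
#' composition) triple — and a column per sample. Duplicate observations of
#' the same glycopeptide within one sample are summed; a glycopeptide not
#' observed in a sample is missing (`NA`), which is distinct from zero.
#' Ambiguous glycosites such as `"197/553"` are kept as a single feature
#' under their sorted rendering. Glycan strings are canonicalized via
#' [glycan_parse()].
#'
#' @param records a data frame with columns `protein`, `site`, `glycan`,
#'   `sample`, `abundance` (and optionally scores); typically the
#'   concatenation of per-sample tables read with [read_glyco_table()].
#' @param sample_sheet a data frame mapping `sample` to `group`
#'   (`"tumor"`/`"adjacent"`). Every record's sample must appear exactly
#'   once; a sample cannot belong to two groups.
#' @return A `glyco_matrix`: a tibble with columns `protein`, `site`,
#'   `glycan` followed by one abundance column per sample, carrying the
#'   sample sheet as attribute `"samples"`.
#' @export
merge_glyco_samples <- function(records, sample_sheet) {
  stopifnot(is.data.frame(records),
            all(c("protein", "site", "glycan", "sample", "abundance") %in%
                  names(records)))
  sample_sheet <- check_sample_sheet(sample_sheet)
  unknown <- setdiff(unique(records$sample), sample_sheet$sample)
  if (length(unknown)) {
    stop("sample '", unknown[1], "' is missing from the sample sheet")
  }
  if (any(records$abundance < 0, na.rm = TRUE)) stop("abundances must be >= 0")
  wide <- records |>
    dplyr::mutate(
      site = render_site(.data$site),
      glycan = glycan_parse(.data$glycan)$glycan
    ) |>
    dplyr::summarise(
      abundance = sum(.data$abundance),
      .by = c("protein", "site", "glycan", "sample")
    ) |>
    tidyr::pivot_wider(names_from = "sample", values_from = "abundance") |>
    dplyr::arrange(.data$protein, .data$site, .data$glycan)
  # carry empty columns for samples with no records so group sizes stay honest
  for (s in setdiff(sample_sheet$sample, names(wide))) wide[[s]] <- NA_real_
  wide <- wide[c("protein", "site", "glycan", sample_sheet$sample)]
  new_glyco_matrix(wide, sample_sheet)
}

new_glyco_matrix <- function(data, sample_sheet) {
  structure(data, samples = sample_sheet,
            class = c("glyco_matrix", class(tibble::tibble())))
}

#' @export
print.glyco_matrix <- function(x, ...) {
  sheet <- attr(x, "samples")
  cat("# glyco_matrix: ", nrow(x), " glycopeptides x ", nrow(sheet),
      " samples (", sum(sheet$group == "tumor"), " tumor, ",
      sum(sheet$group == "adjacent"), " adjacent)\n", sep = "")
  NextMethod()
}

#' Sample annotation of a glycopeptide matrix
#' @param m a `glyco_matrix`.
#' @return The sample sheet tibble (`sample`, `group`) stored on the matrix.
#' @export
glyco_samples <- function(m) {
  stopifnot(inherits(m, "glyco_matrix"))
  attr(m, "samples")
}

# numeric abundance matrix (features x samples) of a glyco_matrix
glyco_values <- function(m) {
  sheet <- glyco_samples(m)
  as.matrix(as.data.frame(m)[, sheet$sample, drop = FALSE])
}

#' Presence filter for glycopeptides
#'
#' Keeps glycopeptides found in at least `min_per_group` samples in at
#' least one of the two groups, discarding sporadically observed features
#' before statistical comparison.
#'
#' @param m a `glyco_matrix` from [merge_glyco_samples()].
#' @param min_per_group minimum number of samples with an observation
#'   required within a single group (default 5).
#' @return The filtered `glyco_matrix`.
#' @export
presence_filter <- function(m, min_per_group = 5L) {
  sheet <- glyco_samples(m)
  sizes <- table(sheet$group)
  if (min_per_group > max(sizes)) {
    stop("min_per_group (", min_per_group, ") exceeds both group sizes")
  }
  vals <- glyco_values(m)
  n_tum <- rowSums(!is.na(vals[, sheet$sample[sheet$group == "tumor"], drop = FALSE]))
  n_adj <- rowSums(!is.na(vals[, sheet$sample[sheet$group == "adjacent"], drop = FALSE]))
  keep <- n_tum >= min_per_group | n_adj >= min_per_group
  new_glyco_matrix(m[keep, , drop = FALSE], sheet)
}

#' Singleton glycopeptide statistics
#'
#' Counts the glycopeptides observed in exactly one sample across the whole
#' cohort — the sporadic identifications that motivate stringent presence
#' filtering.
#'
#' @param m a `glyco_matrix`.
#' @return A one-row tibble: `n_glycopeptides`, `n_singletons`, `fraction`.
#' @export
singleton_stats <- function(m) {
  stopifnot(inherits(m, "glyco_matrix"), nrow(m) > 0L)
  n_obs <- rowSums(!is.na(glyco_values(m)))
  tibble::tibble(
    n_glycopeptides = nrow(m),
    n_singletons = sum(n_obs == 1L),
    fraction = sum(n_obs == 1L) / nrow(m)
  )
}

#' Glycopeptide and glycoprotein counts
#'
#' @param m a `glyco_matrix`.
#' @return A one-row tibble: `n_glycopeptides` (distinct protein/site/glycan
#'   triples) and `n_glycoproteins` (distinct protein accessions).
#' @export
glyco_counts <- function(m) {
  stopifnot(inherits(m, "glyco_matrix"))
  tibble::tibble(
    n_glycopeptides = nrow(m),
    n_glycoproteins = dplyr::n_distinct(m$protein)
  )
}

#' Adaptive two-sample test
#'
#' Compares two groups of abundances with a test chosen by normality and
#' variance pre-tests: if the Shapiro-Wilk test does not reject normality
#' in either group (p >= `alpha_pre` in both), homogeneity of variance is
#' checked with the Brown-Forsythe (median-centered Levene) test — Student's
#' t when variances look equal, Welch's t otherwise; if normality is
#' rejected in either group, the Wilcoxon rank-sum test is used (exact p
#' for small untied samples, normal approximation with continuity
#' correction otherwise).
#'
#' @param x,y numeric abundance vectors for the two groups, each of length
#'   >= 3 (the Shapiro-Wilk test is undefined below that).
#' @param alpha_pre significance level of the Shapiro and Levene gates.
#' @param log_transform log2-transform the data before the normality gate
#'   and the parametric tests (default `TRUE`; abundances must then be
#'   positive). The Wilcoxon branch is invariant to this.
#' @param levene_center centering for the Levene gate: `"median"`
#'   (Brown-Forsythe, default) or `"mean"`.
#' @return A one-row tibble: `test_used` (`"student"`, `"welch"` or
#'   `"wilcoxon"`), `statistic`, `p`.
#' @export
adaptive_test <- function(x, y, alpha_pre = 0.05, log_transform = TRUE,
                          levene_center = c("median", "mean")) {
  levene_center <- match.arg(levene_center)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 3L || length(y) < 3L) {
    stop("adaptive_test needs at least 3 observations per group ",
         "(got ", length(x), " and ", length(y), ")")
  }
  if (log_transform) {
    if (any(c(x, y) <= 0)) stop("log transform requires positive abundances")
    x <- log2(x)
    y <- log2(y)
  }
  shapiro_p <- function(v) {
    if (stats::sd(v) == 0) return(1) # degenerate: constant group, nothing to reject
    stats::shapiro.test(v)$p.value
  }
  result <- function(test_used, statistic, p) {
    tibble::tibble(test_used = test_used, statistic = unname(statistic),
                   p = unname(p))
  }
  if (stats::sd(c(x, y)) == 0) return(result("student", 0, 1))
  if (shapiro_p(x) >= alpha_pre && shapiro_p(y) >= alpha_pre) {
    grp <- factor(rep(c("x", "y"), c(length(x), length(y))))
    lev <- car::leveneTest(c(x, y), grp, center = levene_center)
    if (lev[1, "Pr(>F)"] >= alpha_pre) {
      tt <- stats::t.test(x, y, var.equal = TRUE)
      result("student", tt$statistic, tt$p.value)
    } else {
      tt <- stats::t.test(x, y, var.equal = FALSE)
      result("welch", tt$statistic, tt$p.value)
    }
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
    result("wilcoxon", wt$statistic, wt$p.value)
  }
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a thin validating wrapper
#' around [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in input order, monotone in p-rank, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential glycopeptide abundance between tumor and adjacent groups
#'
#' Runs the adaptive two-sample test on every glycopeptide with enough
#' observations in both groups, computes tumor/adjacent fold-changes as the
#' ratio of group means of the observed abundances (no imputation on the
#' glycopeptide side — missingness here reflects sporadic identification),
#' and controls the FDR across the tested features with Benjamini-Hochberg.
#'
#' @param m a `glyco_matrix`, normally after [presence_filter()].
#' @param alpha_pre,log_transform,levene_center passed to [adaptive_test()].
#' @param min_n minimum observations per group to attempt a test (>= 3);
#'   glycopeptides below it are reported with `NA` test results and are not
#'   counted in the FDR adjustment.
#' @return A tibble with one row per glycopeptide: `protein`, `site`,
#'   `glycan`, `n_tumor`, `n_adjacent`, `mean_tumor`, `mean_adjacent`,
#'   `fold_change` (tumor/adjacent), `test_used`, `statistic`, `p`, `q`.
#' @export
diff_glycopeptides <- function(m, alpha_pre = 0.05, log_transform = TRUE,
                               levene_center = "median", min_n = 3L) {
  stopifnot(inherits(m, "glyco_matrix"))
  if (min_n < 3L) stop("min_n must be at least 3")
  sheet <- glyco_samples(m)
  vals <- glyco_values(m)
  tum <- vals[, sheet$sample[sheet$group == "tumor"], drop = FALSE]
  adj <- vals[, sheet$sample[sheet$group == "adjacent"], drop = FALSE]
  per_row <- function(i) {
    x <- tum[i, ][!is.na(tum[i, ])]
    y <- adj[i, ][!is.na(adj[i, ])]
    base <- tibble::tibble(
      n_tumor = length(x), n_adjacent = length(y),
      mean_tumor = if (length(x)) mean(x) else NA_real_,
      mean_adjacent = if (length(y)) mean(y) else NA_real_
    )
    test <- if (length(x) >= min_n && length(y) >= min_n) {
      adaptive_test(x, y, alpha_pre = alpha_pre, log_transform = log_transform,
                    levene_center = levene_center)
    } else {
      tibble::tibble(test_used = NA_character_, statistic = NA_real_, p = NA_real_)
    }
    dplyr::bind_cols(base, test)
  }
  stats_tbl <- purrr::map(seq_len(nrow(m)), per_row) |> purrr::list_rbind()
  out <- dplyr::bind_cols(
    tibble::as_tibble(as.data.frame(m)[c("protein", "site", "glycan")]),
    stats_tbl
  )
  out$fold_change <- out$mean_tumor / out$mean_adjacent
  out$q <- NA_real_
  tested <- !is.na(out$p)
  out$q[tested] <- bh_adjust(out$p[tested])
  dplyr::relocate(out, "fold_change", .after = "mean_adjacent")
}

#' Per-sample overall glycosylation metrics
#'
#' Applies the abundance-weighted overall metrics within each sample column
#' of a glycopeptide matrix, over the glycopeptides observed in that
#' sample. Samples with no observations get `NA` metrics and are flagged.
#'
#' @param m a `glyco_matrix`.
#' @param rules a [glycan_rules()] object for classification.
#' @param weighting passed to [weighted_glycan_metrics()].
#' @return A tibble with one row per sample: `sample`, `group`,
#'   `sialylation`, `galactosylation`, `fucosylation`, `n_glycopeptides`,
#'   `empty` (no observations).
#' @export
sample_glyco_metrics <- function(m, rules = glycan_rules(),
                                 weighting = c("proportion", "antenna")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(m, "glyco_matrix"))
  sheet <- glyco_samples(m)
  ann <- glycan_metrics(glycan_parse(m$glycan), rules)
  vals <- glyco_values(m)
  purrr::pmap(sheet, function(sample, group) {
    ab <- vals[, sample]
    ok <- !is.na(ab) & ab > 0
    if (!any(ok)) {
      return(tibble::tibble(
        sample = sample, group = group, sialylation = NA_real_,
        galactosylation = NA_real_, fucosylation = NA_real_,
        n_glycopeptides = 0L, empty = TRUE
      ))
    }
    met <- weighted_glycan_metrics(
      dplyr::mutate(ann[ok, ], abundance = ab[ok]),
      weighting = weighting
    )
    tibble::tibble(
      sample = sample, group = group,
      sialylation = met$sialylation, galactosylation = met$galactosylation,
      fucosylation = met$fucosylation, n_glycopeptides = met$n, empty = FALSE
    )
  }) |> purrr::list_rbind()
}

#' Group comparison of overall glycosylation metrics
#'
#' Tests each overall metric (sialylation, galactosylation, fucosylation)
#' for a tumor-vs-adjacent difference with the adaptive two-sample test and
#' adjusts across the three metrics with Benjamini-Hochberg.
#'
#' @param metrics output of [sample_glyco_metrics()].
#' @param alpha_pre passed to [adaptive_test()].
#' @return A tibble with one row per metric: `metric`, group means,
#'   `test_used`, `statistic`, `p`, `q`.
#' @export
compare_glyco_metrics <- function(metrics, alpha_pre = 0.05) {
  stopifnot(all(c("group", "sialylation", "galactosylation", "fucosylation")
                %in% names(metrics)))
  one <- function(metric) {
    v <- metrics[[metric]]
    x <- v[metrics$group == "tumor" & !is.na(v)]
    y <- v[metrics$group == "adjacent" & !is.na(v)]
    res <- adaptive_test(x, y, alpha_pre = alpha_pre, log_transform = FALSE)
    tibble::tibble(
      metric = metric, mean_tumor = mean(x), mean_adjacent = mean(y),
      test_used = res$test_used, statistic = res$statistic, p = res$p
    )
  }
  out <- purrr::map(c("sialylation", "galactosylation", "fucosylation"), one) |>
    purrr::list_rbind()
  out$q <- bh_adjust(out$p)
  out
}

#' Overlay glycopeptide fold-changes with protein fold-changes
#'
#' Joins significant glycopeptide changes with the fold-changes of their
#' parent glycoproteins from the proteomics arm, and attributes each
#' glycopeptide change: `"expression-driven"` when protein and glycopeptide
#' move in the same direction and the protein change is itself substantial,
#' `"glycosylation-driven"` when the protein change is absent or opposite
#' (the glycoform must have shifted relative to its carrier), and
#' `"unattributed"` when the protein was not quantified. Fold-changes are
#' tumor/adjacent ratios; 1 is the no-change threshold separating
#' under- from overexpression.
#'
#' @param glyco_results output of [diff_glycopeptides()].
#' @param protein_fc a data frame with columns `protein` and either
#'   `fold_change` (ratio) or `log2_fc`; e.g. `tidy()` of a
#'   [fit_moderated_t()] object.
#' @param q_max glycopeptide significance cutoff on the BH q-value
#'   (default 0.05).
#' @param null_fold protein fold-changes within \[1/null_fold, null_fold\]
#'   count as "absent" for attribution (default 1.5).
#' @return A tibble of class `glyco_overlay`, one row per significant
#'   glycopeptide: identification columns, group means, `fold_change`,
#'   `protein_fold_change`, `q`, `attribution`.
#' @export
fold_change_overlay <- function(glyco_results, protein_fc, q_max = 0.05,
                                null_fold = 1.5) {
  stopifnot(is.data.frame(glyco_results), is.data.frame(protein_fc),
            "protein" %in% names(protein_fc))
  if (!"fold_change" %in% names(protein_fc)) {
    if (!"log2_fc" %in% names(protein_fc)) {
      stop("protein_fc needs a 'fold_change' or 'log2_fc' column")
    }
    protein_fc$fold_change <- 2^protein_fc$log2_fc
  }
  prot <- dplyr::distinct(
    tibble::as_tibble(protein_fc)[c("protein", "fold_change")],
    .data$protein, .keep_all = TRUE
  )
  sig <- dplyr::filter(glyco_results, !is.na(.data$q), .data$q < q_max)
  out <- sig |>
    dplyr::left_join(
      dplyr::rename(prot, protein_fold_change = "fold_change"),
      by = "protein"
    ) |>
    dplyr::mutate(
      attribution = dplyr::case_when(
        is.na(.data$protein_fold_change) ~ "unattributed",
        # opposite direction, or protein essentially unchanged
        log2(.data$fold_change) * log2(.data$protein_fold_change) < 0 |
          abs(log2(.data$protein_fold_change)) < log2(null_fold) ~
          "glycosylation-driven",
        .default = "expression-driven"
      )
    ) |>
    dplyr::select(dplyr::all_of(c(
      "protein", "site", "glycan", "n_tumor", "n_adjacent", "mean_tumor",
      "mean_adjacent", "fold_change", "protein_fold_change", "q", "attribution"
    )))
  class(out) <- c("glyco_overlay", class(out))
  out
}
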