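#' Filter a protein-group table
#'
#' Drops decoy (Reverse) and Contaminant protein groups, then applies a
#' presence filter: a protein is kept when it was quantified in at least
#' `min_fraction` of the samples of either group (with 12 samples per group
#' and the default 2/3, that is at least 8 of 12 tumor or 8 of 12 adjacent
#' samples).
#'
#' @param data a protein-group tibble with columns `protein`, logical
#'   `reverse` and `contaminant`, and one intensity column per sample
#'   (`NA` = not quantified; never zero).
#' @param sample_sheet tibble mapping `sample` to `group`.
#' @param min_fraction minimum non-missing fraction within a group
#'   (default 2/3); the per-group threshold is `ceiling(min_fraction * n)`
#'   samples.
#' @return The filtered tibble, decoy/contaminant columns retained.
#' @export
filter_protein_groups <- function(data, sample_sheet, min_fraction = 2 / 3) {
  sample_sheet <- check_sample_sheet(sample_sheet)
  stopifnot(all(c("protein", "reverse", "contaminant") %in% names(data)),
            all(sample_sheet$sample %in% names(data)))
  vals <- as.matrix(data[, sample_sheet$sample, drop = FALSE])
  keep_flags <- !data$reverse & !data$contaminant
  need <- function(group) {
    cols <- sample_sheet$sample[sample_sheet$group == group]
    n_obs <- rowSums(!is.na(vals[, cols, drop = FALSE]))
    n_obs >= ceiling(min_fraction * length(cols))
  }
  dplyr::filter(data, keep_flags & (need("tumor") | need("adjacent")))
}

#' Left-censored missing-value imputation (QRILC-style)
#'
#' Intensities missing from label-free proteomics are predominantly
#' left-censored: the analyte fell below the detection limit of that run.
#' This imputation works sample by sample on log-scale intensities. For
#' each sample it fits a normal distribution to the observed values by
#' quantile matching — the observed values are treated as the upper
#' `(1 - f)` quantiles of a complete distribution, where `f` is the
#' missing fraction, and mean and standard deviation come from a least
#' squares fit of the observed order statistics against the corresponding
#' standard-normal quantiles. Missing cells are then drawn from the left
#' tail of the fitted distribution, truncated above at its `q_cens`
#' quantile, so imputed values land below essentially everything observed.
#'
#' @param data a tibble with a `protein` column and one numeric log-scale
#'   intensity column per sample listed in `sample_sheet` (any other
#'   columns are carried through unchanged).
#' @param sample_sheet tibble mapping `sample` to `group`; names the
#'   intensity columns.
#' @param q_cens quantile of the fitted distribution bounding the imputed
#'   draws from above (default 0.01).
#' @param seed optional integer; when given, draws are reproducible and the
#'   caller's RNG state is untouched.
#' @return `data` with every `NA` intensity replaced by an imputed draw;
#'   observed cells are returned bit-identical.
#' @export
impute_left_censored <- function(data, sample_sheet, q_cens = 0.01, seed = NULL) {
  sample_sheet <- check_sample_sheet(sample_sheet)
  stopifnot(all(sample_sheet$sample %in% names(data)),
            q_cens > 0, q_cens < 1)
  draw_all <- function() {
    for (s in sample_sheet$sample) {
      v <- data[[s]]
      miss <- is.na(v)
      if (!any(miss)) next
      obs <- v[!miss]
      if (length(obs) < 3L) {
        stop("sample '", s, "' has only ", length(obs),
             " observed values; cannot fit a censored-normal model")
      }
      f <- mean(miss)
      th <- stats::qnorm(f + (1 - f) * stats::ppoints(length(obs)))
      fit <- stats::lm.fit(cbind(1, th), sort(obs))
      mu <- fit$coefficients[[1]]
      sd_hat <- fit$coefficients[[2]]
      if (!is.finite(sd_hat) || sd_hat <= 0) sd_hat <- stats::sd(obs)
      # inverse-CDF draw from N(mu, sd) truncated above at its q_cens quantile
      u <- stats::runif(sum(miss)) * q_cens
      data[[s]][miss] <- mu + sd_hat * stats::qnorm(u)
    }
    data
  }
  if (is.null(seed)) draw_all() else withr::with_seed(seed, draw_all())
}

# Newton inversion of the trigamma function (for the variance-prior fit).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderated t-tests for two-group intensity data
#'
#' Fits the standard hierarchical model for feature-wise variances: each
#' protein's sample variance \eqn{s^2} (pooled across the two groups, with
#' \eqn{d} residual degrees of freedom) is shrunk towards a prior
#' \eqn{s_0^2} carrying \eqn{d_0} prior degrees of freedom,
#' \deqn{s^2_{post} = (d_0 s_0^2 + d s^2) / (d_0 + d),}
#' and the moderated t-statistic
#' \eqn{t = \Delta / (s_{post}\sqrt{1/n_1 + 1/n_2})} is referred to a
#' t-distribution on \eqn{d_0 + d} degrees of freedom. The prior
#' \eqn{(d_0, s_0^2)} is estimated by closed-form moment matching of
#' \eqn{\log s^2} to a scaled log-F distribution (mean via digamma, spread
#' via trigamma inversion). Zero sample variances are offset by the
#' smallest positive variance before fitting.
#'
#' @param data a complete (imputed) tibble with a `protein` column,
#'   optionally `gene`, and one log2-intensity column per sample.
#' @param sample_sheet tibble mapping `sample` to `group`.
#' @param d0,s0_sq optional prior overrides. `d0 = 0` reduces to the
#'   ordinary pooled two-sample t-test; `d0 = Inf` shrinks every variance
#'   completely to `s0_sq` (estimated from the data unless supplied).
#' @return An object of class `moderated_fit`. Use [generics::tidy()] for
#'   the per-protein table (`protein`, `gene`, `log2_fc`, `s2`, `s2_post`,
#'   `t_mod`, `df_residual`, `df_prior`, `df_total`, `p`, `q`) and
#'   [generics::glance()] for the fit-level summary.
#' @export
fit_moderated_t <- function(data, sample_sheet, d0 = NULL, s0_sq = NULL) {
  sample_sheet <- check_sample_sheet(sample_sheet)
  stopifnot("protein" %in% names(data),
            all(sample_sheet$sample %in% names(data)))
  tum_cols <- sample_sheet$sample[sample_sheet$group == "tumor"]
  adj_cols <- sample_sheet$sample[sample_sheet$group == "adjacent"]
  n1 <- length(tum_cols)
  n2 <- length(adj_cols)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  xt <- as.matrix(data[, tum_cols, drop = FALSE])
  xa <- as.matrix(data[, adj_cols, drop = FALSE])
  if (anyNA(xt) || anyNA(xa)) {
    stop("intensity matrix has missing values; impute before testing")
  }
  mt <- rowMeans(xt)
  ma <- rowMeans(xa)
  df_res <- n1 + n2 - 2
  s2 <- (rowSums((xt - mt)^2) + rowSums((xa - ma)^2)) / df_res
  if (all(s2 == 0)) stop("all proteins have zero variance; prior not estimable")
  s2_fit <- s2
  s2_fit[s2_fit == 0] <- min(s2_fit[s2_fit > 0])
  z <- log(s2_fit)
  # moment matching: E log s2 and Var log s2 under s2 ~ s0^2 F(d, d0)
  evar <- stats::var(z) - trigamma(df_res / 2)
  if (is.null(d0)) {
    d0 <- if (evar > 0) 2 * trigamma_inverse(evar) else Inf
  }
  if (is.null(s0_sq)) {
    offset <- if (is.finite(d0) && d0 > 0) digamma(d0 / 2) - log(d0 / 2) else 0
    s0_sq <- exp(mean(z) - digamma(df_res / 2) + log(df_res / 2) + offset)
  }
  s2_post <- if (is.infinite(d0)) {
    rep(s0_sq, length(s2))
  } else if (d0 == 0) {
    s2 # no prior information: ordinary pooled variances
  } else {
    (d0 * s0_sq + df_res * s2) / (d0 + df_res)
  }
  df_total <- d0 + df_res
  log2_fc <- mt - ma
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- log2_fc / se
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  results <- tibble::tibble(
    protein = data$protein,
    gene = if ("gene" %in% names(data)) data$gene else NA_character_,
    log2_fc = log2_fc,
    fold_change = 2^log2_fc,
    s2 = s2,
    s2_post = s2_post,
    t_mod = t_mod,
    df_residual = df_res,
    df_prior = d0,
    df_total = df_total,
    p = p,
    q = bh_adjust(p)
  )
  structure(
    list(results = results, d0 = d0, s0_sq = s0_sq,
         n_tumor = n1, n_adjacent = n2),
    class = "moderated_fit"
  )
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat("Moderated t fit: ", nrow(x$results), " proteins, ",
      x$n_tumor, " tumor vs ", x$n_adjacent, " adjacent samples\n",
      "  prior df d0 = ", format(x$d0, digits = 4),
      ", prior variance s0^2 = ", format(x$s0_sq, digits = 4), "\n",
      "  q < 0.05: ", sum(x$results$q < 0.05), " proteins\n", sep = "")
  invisible(x)
}
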