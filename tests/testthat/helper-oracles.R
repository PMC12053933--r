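# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# step-up BH by direct enumeration of the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- prev
  }
  q
}

# per-row presence count by explicit loops over a wide matrix tibble
presence_oracle <- function(m, min_per_group) {
  sheet <- glyco_samples(m)
  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    counts <- c(tumor = 0L, adjacent = 0L)
    for (j in seq_len(nrow(sheet))) {
      if (!is.na(m[[sheet$sample[j]]][i])) {
        counts[sheet$group[j]] <- counts[sheet$group[j]] + 1L
      }
    }
    keep[i] <- any(counts >= min_per_group)
  }
  keep
}

# naive loop recomputation of abundance-weighted overall metrics
weighted_metrics_oracle <- function(metrics, abundance) {
  acc <- function(metric_vals) {
    num <- 0
    den <- 0
    for (i in seq_along(metric_vals)) {
      if (!is.na(metric_vals[i]) && abundance[i] > 0) {
        num <- num + abundance[i] * metric_vals[i]
        den <- den + abundance[i]
      }
    }
    if (den == 0) NA_real_ else num / den
  }
  c(
    sialylation = acc(metrics$sialylation),
    galactosylation = acc(metrics$galactosylation),
    fucosylation = sum(abundance * as.numeric(metrics$fucosylated)) /
      sum(abundance)
  )
}

# two-sample pooled-variance t by hand
classical_t_oracle <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# independent canonicalization of (possibly ambiguous) glycosites
render_site_oracle <- function(site) {
  vapply(strsplit(as.character(site), "/", fixed = TRUE), function(parts) {
    paste(sort(as.integer(parts)), collapse = "/")
  }, character(1))
}

make_sheet <- function(n = 12) {
  tibble::tibble(
    sample = c(sprintf("T%02d", 1:n), sprintf("A%02d", 1:n)),
    group = rep(c("tumor", "adjacent"), each = n)
  )
}

# small fixture: a hand-written record set over 4 samples
tiny_sample_sheet <- function() {
  tibble::tibble(
    sample = c("T01", "T02", "A01", "A02"),
    group = c("tumor", "tumor", "adjacent", "adjacent")
  )
}

tiny_records <- function() {
  tibble::tibble(
    protein = c("P1", "P1", "P1", "P2", "P2", "P2"),
    site = c("100", "100", "100", "197/553", "553/197", "40"),
    glycan = c("H5N2", "H5N2", "H5N2", "F1H5N4S1", "F1H5N4S1", "H5N4"),
    sample = c("T01", "T01", "A01", "T01", "T02", "A02"),
    abundance = c(2, 3, 4, 10, 20, 5),
    ms1_score = c(5, 5, 5, 5, 5, 5),
    ms2_score = c(6, 6, 6, 6, 6, 6)
  )
}
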