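#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a moderated-t fit
#'
#' @param x a `moderated_fit` from [fit_moderated_t()].
#' @param ... unused.
#' @return The per-protein results tibble.
#' @export
tidy.moderated_fit <- function(x, ...) {
  x$results
}

#' One-row summary of a moderated-t fit
#'
#' @param x a `moderated_fit`.
#' @param alpha significance threshold for the discovery count
#'   (default 0.05).
#' @param ... unused.
#' @return A one-row tibble: `n_proteins`, `n_tumor`, `n_adjacent`,
#'   `df_prior`, `s0_sq`, `n_significant`, `n_up`, `n_down`.
#' @export
glance.moderated_fit <- function(x, alpha = 0.05, ...) {
  r <- x$results
  sig <- r$q < alpha
  tibble::tibble(
    n_proteins = nrow(r),
    n_tumor = x$n_tumor,
    n_adjacent = x$n_adjacent,
    df_prior = x$d0,
    s0_sq = x$s0_sq,
    n_significant = sum(sig),
    n_up = sum(sig & r$log2_fc > 0),
    n_down = sum(sig & r$log2_fc < 0)
  )
}
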