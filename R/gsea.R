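#' Read gene sets in GMT format
#'
#' One set per tab-separated line: set id, description, then member genes.
#'
#' @param path path to a `.gmt` file.
#' @return A named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(stringr::str_trim(lines))]
  fields <- stringr::str_split(lines, "\t")
  short <- lengths(fields) < 3L
  if (any(short)) {
    stop("GMT line ", which(short)[1], " has fewer than 3 fields")
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) {
    stop("duplicated gene-set id: ", names(sets)[duplicated(names(sets))][1])
  }
  sets
}

# weighted Kolmogorov-Smirnov running-sum enrichment score for one set,
# given the ranked |stat|^weight values and a logical membership vector
ks_enrichment_score <- function(weights_ranked, member) {
  n <- length(member)
  n_hit <- sum(member)
  hit_w <- weights_ranked * member
  denom_hit <- sum(hit_w)
  if (denom_hit == 0) { # all member stats are exactly zero: fall back to counts
    hit_w <- as.numeric(member)
    denom_hit <- n_hit
  }
  running <- cumsum(hit_w / denom_hit - (!member) / (n - n_hit))
  running[which.max(abs(running))]
}

#' Preranked gene set enrichment analysis
#'
#' Computes, for each gene set, the weighted Kolmogorov-Smirnov running-sum
#' enrichment score (ES) on the ranking of genes by a per-gene statistic
#' (here typically the moderated t-statistic, so that positive ES/NES means
#' the set concentrates among tumor-overexpressed proteins and negative
#' among underexpressed ones). Significance comes from gene-label
#' permutations: random sets of the same size drawn from the ranked
#' universe. The normalized enrichment score (NES) divides ES by the mean
#' |ES| of the sign-matched permutations, and the permutation p-value
#' counts sign-matched permutations at least as extreme. Ties in the
#' ranking are broken by gene id, so results do not depend on input order.
#'
#' @param data a data frame with columns `gene` (unique ids) and `stat`,
#'   or a named numeric vector of statistics.
#' @param sets a named list of character vectors ([read_gmt()]).
#' @param weight exponent on |stat| in the running sum (default 1).
#' @param nperm number of gene-label permutations (default 1000).
#' @param min_size sets with fewer ranked members are skipped (default 10);
#'   sets covering the whole universe are degenerate and also skipped.
#' @param seed optional integer for reproducible permutations.
#' @return A tibble with one row per scored set: `set_id`, `set_size`
#'   (after intersection with the universe), `es`, `nes`, `p`, `q` (BH over
#'   scored sets).
#' @export
preranked_gsea <- function(data, sets, weight = 1, nperm = 1000L,
                           min_size = 10L, seed = NULL) {
  if (is.numeric(data) && !is.null(names(data))) {
    data <- tibble::tibble(gene = names(data), stat = unname(data))
  }
  stopifnot(is.data.frame(data), all(c("gene", "stat") %in% names(data)),
            is.list(sets), !is.null(names(sets)))
  if (anyDuplicated(data$gene)) {
    stop("ranking has duplicated gene id: ",
         data$gene[duplicated(data$gene)][1])
  }
  ord <- order(-data$stat, data$gene)
  genes <- data$gene[ord]
  w <- abs(data$stat[ord])^weight
  n <- length(genes)
  sizes <- integer(0)
  score_set <- function(set) {
    member <- genes %in% set
    k <- sum(member)
    if (k == 0L) {
      warning("gene set has no genes in the ranking; skipped")
      return(NULL)
    }
    if (k < min_size || k >= n) return(NULL)
    list(size = k, es = ks_enrichment_score(w, member))
  }
  run <- function() {
    scored <- purrr::map(sets, score_set)
    keep <- !vapply(scored, is.null, logical(1))
    scored <- scored[keep]
    if (!length(scored)) {
      return(tibble::tibble(set_id = character(), set_size = integer(),
                            es = double(), nes = double(),
                            p = double(), q = double()))
    }
    sizes <- vapply(scored, `[[`, integer(1), "size")
    es <- vapply(scored, `[[`, double(1), "es")
    # one permutation null per distinct set size
    perm_by_size <- lapply(unique(sizes), function(k) {
      vapply(seq_len(nperm), function(i) {
        member <- logical(n)
        member[sample.int(n, k)] <- TRUE
        ks_enrichment_score(w, member)
      }, double(1))
    })
    names(perm_by_size) <- as.character(unique(sizes))
    nes <- double(length(es))
    p <- double(length(es))
    for (i in seq_along(es)) {
      null_es <- perm_by_size[[as.character(sizes[i])]]
      same_sign <- null_es[sign(null_es) == sign(es[i])]
      if (length(same_sign) == 0L) {
        nes[i] <- sign(es[i]) * Inf
        p[i] <- 1 / (nperm + 1)
      } else {
        nes[i] <- es[i] / mean(abs(same_sign))
        p[i] <- (1 + sum(abs(same_sign) >= abs(es[i]))) / (1 + length(same_sign))
      }
    }
    tibble::tibble(
      set_id = names(scored), set_size = unname(sizes), es = unname(es),
      nes = unname(nes), p = unname(p), q = bh_adjust(unname(p))
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
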