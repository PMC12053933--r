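#' Parse N-glycan composition strings
#'
#' Glycan compositions are written in the compact F/H/N/S nomenclature:
#' counts of fucose (F), hexose (H; mannose or galactose), N-acetylhexosamine
#' (N; GlcNAc or GalNAc) and sialic acid (S), e.g. `"F1H5N4S1"`. Letters may
#' appear in any order but at most once each; an absent letter means a count
#' of zero. Topology is not encoded: the composition alone does not
#' distinguish core from antennal fucose, nor bisecting GlcNAc.
#'
#' @param x character vector of composition strings.
#' @return A tibble with one row per input: `glycan` (the canonical
#'   rendering, letters in F,H,N,S order with zero counts omitted) and
#'   integer columns `fucose`, `hexose`, `hexnac`, `sialic`.
#' @details The total residue count must not exceed 26, the upper bound of
#'   the biosynthetically feasible human N-glycan search space used at
#'   identification time.
#' @examples
#' glycan_parse(c("F1H5N4S1", "H5N2"))
#' @export
glycan_parse <- function(x) {
  if (!is.character(x)) stop("`x` must be a character vector of composition strings")
  parsed <- lapply(x, parse_one_glycan)
  out <- dplyr::bind_rows(parsed)
  out$glycan <- glycan_format(out)
  dplyr::relocate(out, "glycan")
}

parse_one_glycan <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    stop("empty glycan composition string", call. = FALSE)
  }
  tokens <- stringr::str_match_all(s, "([A-Za-z]+)([0-9]*)")[[1]]
  # validate full coverage: re-assembling the tokens must give back s
  if (paste0(tokens[, 1], collapse = "") != s) {
    stop("malformed glycan composition '", s, "'", call. = FALSE)
  }
  letters <- tokens[, 2]
  counts <- tokens[, 3]
  bad <- !letters %in% c("F", "H", "N", "S")
  if (any(bad)) {
    stop("unknown residue letter '", letters[bad][1], "' in glycan '", s, "'",
         call. = FALSE)
  }
  if (anyDuplicated(letters)) {
    dup <- letters[duplicated(letters)][1]
    stop("repeated residue letter '", dup, "' in glycan '", s, "'", call. = FALSE)
  }
  if (any(!nzchar(counts))) {
    miss <- letters[!nzchar(counts)][1]
    stop("missing count after '", miss, "' in glycan '", s, "'", call. = FALSE)
  }
  n <- stats::setNames(as.integer(counts), letters)
  get <- function(l) if (l %in% names(n)) n[[l]] else 0L
  res <- tibble::tibble(
    fucose = get("F"), hexose = get("H"), hexnac = get("N"), sialic = get("S")
  )
  total <- res$fucose + res$hexose + res$hexnac + res$sialic
  if (total > 26L) {
    stop("glycan '", s, "' has ", total,
         " monosaccharides; the search space is limited to at most 26",
         call. = FALSE)
  }
  res
}

#' Render glycan compositions in canonical form
#'
#' @param counts a data frame with columns `fucose`, `hexose`, `hexnac`,
#'   `sialic` (as produced by [glycan_parse()]).
#' @return Character vector of canonical composition strings: letters in
#'   F,H,N,S order, zero counts omitted.
#' @export
glycan_format <- function(counts) {
  stopifnot(all(c("fucose", "hexose", "hexnac", "sialic") %in% names(counts)))
  piece <- function(letter, k) ifelse(k > 0, paste0(letter, k), "")
  paste0(
    piece("F", counts$fucose), piece("H", counts$hexose),
    piece("N", counts$hexnac), piece("S", counts$sialic)
  )
}

#' Classification rule table for glycan compositions
#'
#' Composition-only classification into high-mannose, paucimannose, hybrid
#' and complex types. The defaults encode the standard heuristics: two
#' HexNAc (the chitobiose core only) with five or more hexoses is
#' high-mannose, with four or fewer paucimannose; three HexNAc with five or
#' more hexoses is hybrid (one antennal GlcNAc plus retained mannose arms);
#' any other composition with three or more HexNAc is complex; fewer than
#' two HexNAc cannot form the core and is unclassified.
#'
#' @param high_mannose_min_hex minimum hexose count for high-mannose (default 5).
#' @param hybrid_hexnac exact HexNAc count for the hybrid rule (default 3).
#' @param hybrid_min_hex minimum hexose count for the hybrid rule (default 5).
#' @param complex_min_hexnac minimum HexNAc count for complex (default 3).
#' @return A named list of thresholds with class `"glycan_rules"`.
#' @seealso [read_glycan_rules()] to load thresholds from a plain-text file.
#' @export
glycan_rules <- function(high_mannose_min_hex = 5L, hybrid_hexnac = 3L,
                         hybrid_min_hex = 5L, complex_min_hexnac = 3L) {
  structure(
    list(
      high_mannose_min_hex = as.integer(high_mannose_min_hex),
      hybrid_hexnac = as.integer(hybrid_hexnac),
      hybrid_min_hex = as.integer(hybrid_min_hex),
      complex_min_hexnac = as.integer(complex_min_hexnac)
    ),
    class = "glycan_rules"
  )
}

#' Read a glycan classification rule table from a text file
#'
#' The file holds `key = value` pairs, one per line, with the keys of
#' [glycan_rules()]; `#` starts a comment. Missing keys keep their defaults.
#'
#' @param path path to the rule file.
#' @return A `"glycan_rules"` object.
#' @export
read_glycan_rules <- function(path) {
  lines <- readr::read_lines(path)
  lines <- stringr::str_trim(stringr::str_remove(lines, "#.*$"))
  lines <- lines[nzchar(lines)]
  kv <- stringr::str_match(lines, "^([A-Za-z_]+)\\s*=\\s*([0-9]+)$")
  if (anyNA(kv[, 1])) {
    stop("malformed rule line: '", lines[is.na(kv[, 1])][1], "'")
  }
  args <- stats::setNames(as.list(as.integer(kv[, 3])), kv[, 2])
  known <- names(formals(glycan_rules))
  unknown <- setdiff(names(args), known)
  if (length(unknown)) stop("unknown rule key: ", unknown[1])
  do.call(glycan_rules, args)
}

#' Classify glycan compositions
#'
#' Assigns exactly one of `high_mannose`, `paucimannose`, `hybrid`,
#' `complex` or `unclassified` to each composition, using a configurable
#' composition-only rule table (see [glycan_rules()]).
#'
#' @param counts a data frame with columns `fucose`, `hexose`, `hexnac`,
#'   `sialic`, or a character vector of composition strings.
#' @param rules a [glycan_rules()] object.
#' @return Character vector of class labels, one per composition.
#' @examples
#' glycan_classify(c("H5N2", "F1H5N4S1"))
#' @export
glycan_classify <- function(counts, rules = glycan_rules()) {
  if (is.character(counts)) counts <- glycan_parse(counts)
  stopifnot(inherits(rules, "glycan_rules"))
  h <- counts$hexose
  n <- counts$hexnac
  dplyr::case_when(
    n < 2L ~ "unclassified",
    n == 2L & h >= rules$high_mannose_min_hex ~ "high_mannose",
    n == 2L ~ "paucimannose",
    n == rules$hybrid_hexnac & h >= rules$hybrid_min_hex ~ "hybrid",
    n >= rules$complex_min_hexnac ~ "complex",
    .default = "unclassified"
  )
}

#' Count the antennae of a glycan composition
#'
#' For complex and hybrid glycans every HexNAc beyond the two core GlcNAcs
#' is counted as initiating an antenna (bisecting GlcNAc cannot be
#' distinguished from composition alone and is counted as antennal).
#' High-mannose, paucimannose and unclassified compositions have zero
#' antennae by definition.
#'
#' @inheritParams glycan_classify
#' @param class optional precomputed class labels; computed from `rules`
#'   when omitted.
#' @return Integer vector of antenna counts.
#' @export
glycan_antennae <- function(counts, class = NULL, rules = glycan_rules()) {
  if (is.character(counts)) counts <- glycan_parse(counts)
  if (is.null(class)) class <- glycan_classify(counts, rules)
  ifelse(class %in% c("complex", "hybrid"), pmax(counts$hexnac - 2L, 0L), 0L)
}

#' Per-glycan derivatization metrics
#'
#' Computes, for each composition, the antenna count and three
#' microheterogeneity metrics: sialylation (the proportion of sialylated
#' antennae), galactosylation (the proportion of galactosylated antennae)
#' and a fucosylation indicator (any fucose present). Antennal galactoses
#' are counted as hexoses beyond the three core mannoses, capped at the
#' antenna count; sialic acids are likewise capped. Sialylation and
#' galactosylation are undefined (`NA`) for glycans without antennae —
#' a proportion of antennae has no meaning when there are none.
#'
#' @inheritParams glycan_classify
#' @return A tibble with one row per composition: `glycan`, the four residue
#'   counts, `class`, `antennae`, `sialylation`, `galactosylation`,
#'   `fucosylated`.
#' @examples
#' glycan_metrics("H5N4S1") # biantennary, one sialylated antenna: 0.5
#' @export
glycan_metrics <- function(counts, rules = glycan_rules()) {
  if (is.character(counts)) counts <- glycan_parse(counts)
  cls <- glycan_classify(counts, rules)
  a <- glycan_antennae(counts, cls)
  gal <- pmin(pmax(counts$hexose - 3L, 0L), a)
  sia <- pmin(counts$sialic, a)
  tibble::tibble(
    glycan = glycan_format(counts),
    fucose = counts$fucose, hexose = counts$hexose,
    hexnac = counts$hexnac, sialic = counts$sialic,
    class = cls,
    antennae = a,
    sialylation = ifelse(a > 0L, sia / a, NA_real_),
    galactosylation = ifelse(a > 0L, gal / a, NA_real_),
    fucosylated = counts$fucose >= 1L
  )
}

#' Abundance-weighted overall glycosylation metrics
#'
#' Aggregates per-glycopeptide metrics into overall sialylation,
#' galactosylation and fucosylation, weighting each glycopeptide by its
#' expression so that abundant glycoforms dominate the tissue-level value.
#' For sialylation and galactosylation the average runs over the
#' glycopeptides where the metric is defined (those with at least one
#' antenna); fucosylation averages the 0/1 fucose indicator over all
#' glycopeptides. A metric whose defined set is empty is returned as `NA`.
#'
#' @param data a data frame with columns `sialylation`, `galactosylation`,
#'   `fucosylated` (as from [glycan_metrics()]) and an abundance column.
#' @param abundance name of the abundance column (default `"abundance"`).
#' @param weighting `"proportion"` (default) weights each glycopeptide's
#'   metric by its abundance; `"antenna"` additionally weights by the
#'   antenna count, i.e. averages over antennae rather than glycopeptides
#'   (requires an `antennae` column).
#' @return A one-row tibble: `sialylation`, `galactosylation`,
#'   `fucosylation`, `n` (rows used), `total_abundance`.
#' @export
weighted_glycan_metrics <- function(data, abundance = "abundance",
                                    weighting = c("proportion", "antenna")) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("sialylation", "galactosylation", "fucosylated") %in% names(data)))
  if (!abundance %in% names(data)) {
    stop("abundance column '", abundance, "' not found")
  }
  w <- data[[abundance]]
  if (nrow(data) == 0L || any(is.na(w)) || any(w < 0)) {
    stop("abundances must be present and non-negative")
  }
  if (sum(w) <= 0) stop("all abundances are zero; weighted metrics undefined")
  wmean <- function(metric, weights) {
    ok <- !is.na(metric) & weights > 0
    if (!any(ok)) return(NA_real_)
    sum(weights[ok] * metric[ok]) / sum(weights[ok])
  }
  wa <- if (weighting == "antenna") {
    stopifnot("antennae" %in% names(data))
    w * data$antennae
  } else {
    w
  }
  tibble::tibble(
    sialylation = wmean(data$sialylation, wa),
    galactosylation = wmean(data$galactosylation, wa),
    fucosylation = wmean(as.numeric(data$fucosylated), w),
    n = nrow(data),
    total_abundance = sum(w)
  )
}
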