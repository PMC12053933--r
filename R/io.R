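delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a sample sheet
#'
#' @param path delimited text (CSV or TSV) with columns `sample`, `group`
#'   (`"tumor"` / `"adjacent"`).
#' @return A validated tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_delim(path, delim = delim_for(path),
                             show_col_types = FALSE)
  check_sample_sheet(sheet)
}

#' Read a per-sample glycopeptide quantification table
#'
#' Reads one GlycReSoft-style identification/quantification table. Required
#' columns: `protein`, `site`, `glycan` (F/H/N/S composition string),
#' `abundance`, `ms1_score`, `ms2_score`.
#'
#' @param path delimited text file (CSV or TSV).
#' @param sample sample id to attach to every record (defaults to the file
#'   name without extension when the table has no `sample` column).
#' @return A tibble of glycopeptide records with a `sample` column.
#' @export
read_glyco_table <- function(path, sample = NULL) {
  tab <- readr::read_delim(path, delim = delim_for(path),
                           show_col_types = FALSE)
  # sites may be ambiguous ("197/553"): always a character column
  if ("site" %in% names(tab)) tab$site <- as.character(tab$site)
  required <- c("protein", "site", "glycan", "abundance",
                "ms1_score", "ms2_score")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("'", path, "' lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"sample" %in% names(tab)) {
    if (is.null(sample)) {
      sample <- sub("\\.[^.]*$", "", basename(path))
    }
    tab$sample <- sample
  }
  tibble::as_tibble(tab)
}

#' Read a protein-group quantification table
#'
#' Accepts either the MaxQuant `proteinGroups.txt` dialect — columns
#' `Majority protein IDs`, `Gene names`, per-sample `LFQ intensity <sample>`,
#' with `Reverse` and `Potential contaminant` flagged by `"+"`, and `0`
#' meaning not quantified — or a generic dialect with columns `protein`,
#' optional `gene`, logical `reverse`/`contaminant`, and one intensity
#' column per sample (`NA` = missing).
#'
#' @param path tab-separated protein-group file.
#' @param sample_sheet tibble mapping `sample` to `group`; used to locate
#'   the intensity columns.
#' @return A tibble with columns `protein`, `gene`, `reverse`,
#'   `contaminant`, then one raw-intensity column per sample with `NA` for
#'   missing values.
#' @export
read_protein_groups <- function(path, sample_sheet) {
  sample_sheet <- check_sample_sheet(sample_sheet)
  tab <- readr::read_delim(path, delim = "\t", show_col_types = FALSE,
                           name_repair = "minimal")
  if ("Majority protein IDs" %in% names(tab)) {
    lfq <- paste0("LFQ intensity ", sample_sheet$sample)
    missing_cols <- setdiff(lfq, names(tab))
    if (length(missing_cols)) {
      stop("'", path, "' lacks intensity column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    plus <- function(col) {
      if (!col %in% names(tab)) return(rep(FALSE, nrow(tab)))
      !is.na(tab[[col]]) & tab[[col]] == "+"
    }
    out <- tibble::tibble(
      # first accession of the group is the representative
      protein = stringr::str_split_i(tab[["Majority protein IDs"]], ";", 1),
      gene = if ("Gene names" %in% names(tab)) {
        stringr::str_split_i(tab[["Gene names"]], ";", 1)
      } else {
        NA_character_
      },
      reverse = plus("Reverse"),
      contaminant = plus("Potential contaminant")
    )
    for (i in seq_along(lfq)) {
      v <- as.numeric(tab[[lfq[i]]])
      v[v == 0] <- NA_real_ # MaxQuant writes 0 for "not quantified"
      out[[sample_sheet$sample[i]]] <- v
    }
    out
  } else {
    required <- c("protein", sample_sheet$sample)
    missing_cols <- setdiff(required, names(tab))
    if (length(missing_cols)) {
      stop("'", path, "' lacks required column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    if (!"gene" %in% names(tab)) tab$gene <- NA_character_
    for (flag in c("reverse", "contaminant")) {
      tab[[flag]] <- if (flag %in% names(tab)) as.logical(tab[[flag]]) else FALSE
    }
    tibble::as_tibble(tab[c("protein", "gene", "reverse", "contaminant",
                            sample_sheet$sample)])
  }
}

#' Log2-transform the intensity columns of a protein table
#'
#' @param data a protein tibble as from [read_protein_groups()].
#' @param sample_sheet tibble naming the intensity columns.
#' @return `data` with intensity columns replaced by their log2.
#' @export
log2_intensities <- function(data, sample_sheet) {
  sample_sheet <- check_sample_sheet(sample_sheet)
  for (s in sample_sheet$sample) {
    v <- data[[s]]
    if (any(v <= 0, na.rm = TRUE)) {
      stop("sample '", s, "' has non-positive intensities; ",
           "missing values must be NA, not 0")
    }
    data[[s]] <- log2(v)
  }
  data
}

#' Write a glycopeptide matrix and sample sheet to TSV
#'
#' @param m a `glyco_matrix`.
#' @param path output TSV for the matrix.
#' @param samples_path optional TSV for the sample sheet.
#' @return `m`, invisibly.
#' @export
write_glyco_matrix <- function(m, path, samples_path = NULL) {
  stopifnot(inherits(m, "glyco_matrix"))
  readr::write_tsv(tibble::as_tibble(as.data.frame(m)), path)
  if (!is.null(samples_path)) readr::write_tsv(glyco_samples(m), samples_path)
  invisible(m)
}
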