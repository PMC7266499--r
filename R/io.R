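#' Read a wide protein intensity matrix
#'
#' Expects a header line, protein identifiers in the first column, an
#' optional gene-name column (named `gene_name`, `gene_names` or `gene`,
#' case-insensitive), and one column per sample. Cells matching
#' `missing_tokens` become `NA`. By default an intensity of exactly 0 is
#' treated as missing too, following the DIA reporting convention in which a
#' protein is either quantified (positive intensity) or absent.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"csv"`.
#' @param missing_tokens Character vector of cell values to read as missing.
#' @param zero_as_missing Treat numeric 0 as missing (default `TRUE`).
#' @return An [intensity_tbl()] on the linear scale.
#' @export
read_intensity_matrix <- function(path, dialect = c("tsv", "csv"),
                                  missing_tokens = c("", "NA", "NaN"),
                                  zero_as_missing = TRUE) {
  dialect <- match.arg(dialect)
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                na = character(), progress = FALSE)
  if (ncol(raw) < 2) stop("intensity matrix needs id + sample columns", call. = FALSE)
  names(raw)[1] <- "protein_id"
  gene_col <- which(tolower(names(raw)) %in% c("gene_name", "gene_names", "gene"))
  gene <- if (length(gene_col)) raw[[gene_col[1]]] else ""
  value_cols <- setdiff(seq_along(raw), c(1L, gene_col))
  ids <- raw$protein_id
  if (anyDuplicated(ids)) {
    stop("duplicate protein id in ", path, ": ", ids[duplicated(ids)][1],
         call. = FALSE)
  }
  vals <- vapply(value_cols, function(j) {
    cell <- raw[[j]]
    cell[cell %in% missing_tokens] <- NA_character_
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric cell '%s' at row %d, column '%s'",
                   cell[bad[1]], bad[1], names(raw)[j]), call. = FALSE)
    }
    num
  }, numeric(nrow(raw)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(raw))
  colnames(vals) <- names(raw)[value_cols]
  if (zero_as_missing) vals[!is.na(vals) & vals == 0] <- NA_real_
  intensity_tbl(tibble::tibble(protein_id = ids, gene_name = gene),
                vals, scale = "linear")
}

meta_numeric_cols <- c("age", "t_tau", "p_tau181", "ab42", "ab40", "mmse")

#' Read per-sample clinical and technical metadata
#'
#' Recognised columns: `sample_id`, `cohort`, `group_label`, `plate_id`,
#' `prep_day`, `age`, `sex`, `t_tau`, `p_tau181`, `ab42`, `ab40`, `mmse`,
#' `control_override`. Concentrations are in ng/l. Unknown columns are
#' dropped with a warning; missing clinical values stay `NA`.
#'
#' @inheritParams read_intensity_matrix
#' @return A tibble with one row per sample.
#' @export
read_sample_metadata <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                na = c("", "NA"), progress = FALSE)
  known <- c("sample_id", "cohort", "group_label", "plate_id", "prep_day",
             "age", "sex", "t_tau", "p_tau181", "ab42", "ab40", "mmse",
             "control_override")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    warning("ignoring unknown metadata column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
    raw <- raw[intersect(names(raw), known)]
  }
  if (!"sample_id" %in% names(raw) || anyNA(raw$sample_id)) {
    stop("sample_id column absent or has missing entries", call. = FALSE)
  }
  if (anyDuplicated(raw$sample_id)) {
    stop("duplicated sample_id: ",
         raw$sample_id[duplicated(raw$sample_id)][1], call. = FALSE)
  }
  for (col in intersect(meta_numeric_cols, names(raw))) {
    raw[[col]] <- as.numeric(raw[[col]])
  }
  if ("control_override" %in% names(raw)) {
    raw$control_override <- tolower(raw$control_override) %in%
      c("true", "t", "1", "yes")
  } else {
    raw$control_override <- FALSE
  }
  if ("sex" %in% names(raw)) {
    raw$sex <- tolower(raw$sex)
    bad <- !is.na(raw$sex) & !raw$sex %in% c("male", "female")
    if (any(bad)) {
      stop("sex must be male/female, got: ", raw$sex[which(bad)[1]],
           call. = FALSE)
    }
  }
  validate_sample_meta(raw)
  raw
}

validate_sample_meta <- function(meta) {
  for (col in intersect(c("t_tau", "p_tau181", "ab42", "ab40"), names(meta))) {
    if (any(meta[[col]] < 0, na.rm = TRUE)) {
      stop(col, " concentrations must be >= 0", call. = FALSE)
    }
  }
  if ("mmse" %in% names(meta) &&
      any(meta$mmse < 0 | meta$mmse > 30, na.rm = TRUE)) {
    stop("mmse must be in [0, 30]", call. = FALSE)
  }
  if ("age" %in% names(meta) && any(meta$age < 0, na.rm = TRUE)) {
    stop("age must be >= 0", call. = FALSE)
  }
  invisible(meta)
}

#' Read a gene-set catalog in GMT format
#'
#' Each line is `term<TAB>description<TAB>member1<TAB>member2...`. Members
#' are deduplicated; terms left without members are dropped with a warning.
#' Term categories (GOBP/GOCC/Keyword/other) may be encoded as a prefix in
#' the description; they are kept verbatim.
#'
#' @param path GMT file path.
#' @return A tibble with columns `term_id`, `description`, `members`
#'   (list-column of character vectors) and `n_members`.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble::tibble(term_id = character(), description = character(),
                          members = list(), n_members = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short)) {
    stop("GMT line ", short[1], " has fewer than 3 tab-separated fields",
         call. = FALSE)
  }
  out <- tibble::tibble(
    term_id = vapply(parts, `[[`, "", 1),
    description = vapply(parts, `[[`, "", 2),
    members = lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  )
  empty <- lengths(out$members) == 0
  if (any(empty)) {
    warning("dropping ", sum(empty), " GMT term(s) with no members",
            call. = FALSE)
    out <- out[!empty, ]
  }
  out$n_members <- lengths(out$members)
  out
}

#' Write a result table to TSV/CSV
#'
#' Deterministic column order (as given), missing values serialized as empty
#' strings, and numbers kept at full precision (readr writes >= 15
#' significant digits), so a write/read round trip preserves q-values to
#' well below 1e-9.
#'
#' @param rows A data frame of results.
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `rows`, invisibly.
#' @export
write_result_table <- function(rows, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  rows <- tibble::as_tibble(rows)
  writer <- if (dialect == "tsv") readr::write_tsv else readr::write_csv
  writer(rows, path, na = "", progress = FALSE)
  invisible(rows)
}

#' Write an intensity matrix as wide TSV/CSV
#'
#' Inverse of [read_intensity_matrix()]: missing values become empty cells.
#' readr serializes doubles with shortest round-trippable representation, so
#' a write/read cycle reproduces present values bit-identically.
#'
#' @param x An [intensity_tbl()].
#' @inheritParams write_result_table
#' @return `x`, invisibly.
#' @export
write_intensity_matrix <- function(x, path, dialect = c("tsv", "csv")) {
  write_result_table(tibble::as_tibble(x), path, dialect)
  invisible(x)
}
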