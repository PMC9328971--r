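#' Read a genes-by-samples expression table
#'
#' Reads a tab-separated expression table (first column gene id, header row
#' of sample ids, non-negative linear-scale values). Duplicate gene rows are
#' collapsed by their mean, with a warning listing the affected ids;
#' duplicate sample columns are an error.
#'
#' @param path Path to the TSV file.
#' @param sample_sheet Optional path to a two-column TSV (`sample_id`,
#'   `condition`) assigning tumor/normal labels, or a data frame with those
#'   columns.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, sample_sheet = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        na = character(), name_repair = "minimal")
  if (ncol(df) < 2) abort("expression table needs a gene column plus >= 1 sample.")
  gene_col <- names(df)[1]
  sample_cols <- names(df)[-1]
  if (anyDuplicated(sample_cols)) {
    abort(paste0("duplicate sample id(s) in header: ",
                 paste(unique(sample_cols[duplicated(sample_cols)]), collapse = ", ")))
  }
  for (cn in sample_cols) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num))
      if (length(bad) > 0) {
        abort(sprintf("non-numeric expression value '%s' at gene '%s', sample '%s'",
                      v[bad[1]], as.character(df[[gene_col]][bad[1]]), cn))
      }
      df[[cn]] <- num
    }
  }
  genes <- as.character(df[[gene_col]])
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warn(paste0("collapsing ", length(dup), " duplicated gene id(s) by mean: ",
                paste(head(dup, 5), collapse = ", ")))
    df <- df |>
      dplyr::group_by(.data[[gene_col]]) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(sample_cols), mean),
                       .groups = "drop") |>
      dplyr::arrange(match(.data[[gene_col]], unique(genes)))
    genes <- as.character(df[[gene_col]])
  }
  values <- as.matrix(df[sample_cols])
  rownames(values) <- genes
  condition <- NULL
  if (!is.null(sample_sheet)) {
    ss <- if (is.data.frame(sample_sheet)) sample_sheet
          else readr::read_tsv(sample_sheet, show_col_types = FALSE, progress = FALSE)
    for (col in c("sample_id", "condition")) {
      if (!col %in% names(ss)) abort(paste0("sample sheet lacks column '", col, "'"))
    }
    condition <- setNames(as.character(ss$condition), as.character(ss$sample_id))
  }
  expr_matrix(values, condition = condition)
}

#' Read gene biotypes from a GTF file
#'
#' Extracts a `gene_id -> biotype` mapping from the `gene` feature lines of
#' a GTF annotation. Both the Ensembl `gene_biotype` and the GENCODE
#' `gene_type` attribute keys are accepted; a `gene_name` attribute, when
#' present, is carried along as the symbol. Genes without a biotype
#' attribute are skipped with a warning. Feature coordinates are never used
#' downstream and are discarded.
#'
#' @param path Path to a GTF file.
#' @return A tibble with columns `gene_id`, `biotype`, `symbol`.
#' @export
read_gtf_biotypes <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, integer(1)) == 9L
  fields <- fields[ok]
  feature <- vapply(fields, `[[`, character(1), 3L)
  genes <- fields[feature == "gene"]
  if (length(genes) == 0) abort("no `gene` features found in GTF.")
  attr_value <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0(key, ' "([^"]*)"'), attrs))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, character(1))
  }
  attrs <- vapply(genes, `[[`, character(1), 9L)
  gene_id <- attr_value(attrs, "gene_id")
  biotype <- attr_value(attrs, "gene_biotype")
  alt <- attr_value(attrs, "gene_type")
  biotype <- dplyr::coalesce(biotype, alt)
  symbol <- attr_value(attrs, "gene_name")
  if (anyNA(gene_id)) abort("GTF `gene` feature without a gene_id attribute.")
  drop <- is.na(biotype)
  if (any(drop)) {
    warn(paste0(sum(drop), " gene(s) lack a biotype attribute and were skipped: ",
                paste(head(gene_id[drop], 5), collapse = ", ")))
  }
  out <- tibble(gene_id = gene_id[!drop], biotype = biotype[!drop],
                symbol = symbol[!drop])
  dup <- duplicated(out$gene_id)
  if (any(dup)) out <- out[!dup, ]
  out
}

#' Read a clinical table
#'
#' Reads a tab-separated clinical table and applies the standard validity
#' filter: rows with missing or non-positive follow-up time, or a missing
#' event status, are dropped and counted; duplicated sample ids keep the
#' first occurrence. The drop counts are attached as the `dropped`
#' attribute and reported via a message.
#'
#' @param path Path to the TSV file, or a data frame.
#' @param required Columns that must be present.
#' @return A tibble with one row per retained sample; `time` in days,
#'   `event` in `{0,1}`.
#' @export
read_clinical <- function(path,
                          required = c("sample_id", "time", "event")) {
  df <- if (is.data.frame(path)) tibble::as_tibble(path)
        else readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (col in required) {
    if (!col %in% names(df)) abort(paste0("clinical table lacks required column '", col, "'"))
  }
  n0 <- nrow(df)
  dup <- duplicated(df$sample_id)
  n_dup <- sum(dup)
  if (n_dup > 0) {
    warn(paste0("dropping ", n_dup, " duplicated sample row(s), keeping first."))
    df <- df[!dup, ]
  }
  keep <- !is.na(df$time) & df$time > 0 & !is.na(df$event) & df$event %in% c(0, 1)
  n_invalid <- sum(!keep)
  if (n_invalid > 0) {
    inform(paste0("dropping ", n_invalid,
                  " sample(s) with missing/zero follow-up or unknown status."))
  }
  df <- df[keep, ]
  df$time <- as.numeric(df$time)
  df$event <- as.integer(df$event)
  attr(df, "dropped") <- c(duplicates = n_dup, invalid = n_invalid)
  df
}

#' Read a one-symbol-per-line gene list
#'
#' @param path Path to a text file with one gene symbol/id per line.
#' @param name Name for the resulting set (default: file base name).
#' @return A `gene_set`: list with `name` and unique, non-empty `members`.
#' @export
read_gene_list <- function(path, name = NULL) {
  members <- readr::read_lines(path, progress = FALSE)
  members <- trimws(members)
  members <- members[nzchar(members) & !startsWith(members, "#")]
  gene_set(name %||% sub("\\.[^.]*$", "", basename(path)), members)
}

#' Construct a named gene set
#' @param name Set name.
#' @param members Character vector of gene ids/symbols (deduplicated).
#' @return A `gene_set` object.
#' @export
gene_set <- function(name, members) {
  members <- unique(as.character(members))
  if (length(members) == 0) abort("gene set must have >= 1 member.")
  structure(list(name = name, members = members), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d members\n", x$name, length(x$members)))
  invisible(x)
}

#' Extract survival data from a clinical table
#'
#' @param clinical A clinical tibble with `sample_id`, `time`, `event`.
#' @return A tibble with columns `sample_id`, `time`, `event`.
#' @export
survival_data <- function(clinical) {
  for (col in c("sample_id", "time", "event")) {
    if (!col %in% names(clinical)) abort(paste0("missing column '", col, "'"))
  }
  if (any(clinical$time <= 0)) abort("survival times must be > 0.")
  if (!all(clinical$event %in% c(0, 1))) abort("event must be 0/1.")
  tibble(sample_id = as.character(clinical$sample_id),
         time = as.numeric(clinical$time),
         event = as.integer(clinical$event))
}

#' Write a pipeline object to a tab-separated file
#'
#' Every tabular result round-trips losslessly through TSV with a
#' deterministic column order. `expr_matrix` and `pair_matrix` objects are
#' written wide (genes/pairs in rows) and can be re-read with
#' [read_expression()] / [read_pair_matrix()].
#'
#' @param obj A tibble/data frame, `expr_matrix`, or `pair_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(obj, path) UseMethod("write_table")

#' @export
write_table.data.frame <- function(obj, path) {
  readr::write_tsv(obj, path, progress = FALSE)
  invisible(path)
}

#' @export
write_table.expr_matrix <- function(obj, path) {
  df <- tibble::as_tibble(obj$values, rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @export
write_table.pair_matrix <- function(obj, path) {
  df <- tibble::as_tibble(obj$indicators, rownames = "pair_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @export
write_table.signature_model <- function(obj, path) {
  readr::write_tsv(tidy(obj), path, progress = FALSE)
  invisible(path)
}

#' Re-read a pair indicator matrix written by [write_table()]
#'
#' @param path Path to the TSV (row ids `GENEA|GENEB`).
#' @return A `pair_matrix`.
#' @export
read_pair_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ind <- as.matrix(df[-1])
  rownames(ind) <- df[[1]]
  storage.mode(ind) <- "integer"
  new_pair_matrix(ind)
}
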