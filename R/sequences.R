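# Measurement-sequence lists and filename-based sample categorisation.

#' Read a measurement-sequence CSV
#'
#' Reads a sequence list naming the data files of one or more
#' measurement sequences in injection order. The required column is
#' `file`; optional columns are `sequence` (sequence label; default one
#' sequence per CSV, named after the CSV file) and `acquisition_time`
#' (ISO-8601 timestamp). Entries keep file order; `order_index` is
#' assigned 1-based per sequence. Multiple CSVs can be read and
#' row-bound to form a multi-sequence campaign.
#'
#' @param path Path to the CSV file.
#' @param delimiter Field delimiter, default `","`.
#' @param base_dir Directory against which relative file paths are
#'   resolved; defaults to the CSV's directory.
#' @return A data.frame with columns `file_path`, `sequence_id`,
#'   `order_index`, `acquisition_time`, `file_exists`.
#' @export
read_sequence_csv <- function(path, delimiter = ",", base_dir = dirname(path)) {
  if (!file.exists(path)) stop(sprintf("sequence CSV not found: %s", path), call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE, comment.char = "",
                           strip.white = TRUE)
  if (!"file" %in% names(tab))
    stop(sprintf("sequence CSV %s lacks required column 'file' (found: %s)",
                 path, paste(names(tab), collapse = ", ")), call. = FALSE)
  seq_id <- if ("sequence" %in% names(tab)) as.character(tab$sequence)
            else rep(tools::file_path_sans_ext(basename(path)), nrow(tab))
  acq <- if ("acquisition_time" %in% names(tab)) as.character(tab$acquisition_time)
         else rep(NA_character_, nrow(tab))
  fp <- as.character(tab$file)
  rel <- !grepl("^(/|[A-Za-z]:)", fp)
  fp[rel] <- file.path(base_dir, fp[rel])
  if (anyDuplicated(fp))
    warning(sprintf("sequence CSV %s lists duplicate file paths; kept as-is", path),
            call. = FALSE)
  order_index <- stats::ave(seq_along(fp), seq_id, FUN = seq_along)
  data.frame(file_path = fp, sequence_id = seq_id,
             order_index = as.integer(order_index),
             acquisition_time = acq,
             file_exists = file.exists(fp),
             stringsAsFactors = FALSE)
}

#' Group sequence entries into sample-type categories
#'
#' The category of a file is its filename prefix up to the first
#' occurrence of `separator` (e.g. `"QCstd_01.mzXML"` with separator
#' `"_"` belongs to category `"QCstd"`). Filenames lacking the separator
#' fall back to the full stem, with a warning. The result is a
#' partition: every entry belongs to exactly one category.
#'
#' @param entries Data.frame from [read_sequence_csv()].
#' @param separator Single separator character, default `"_"`.
#' @return `entries` with an added `category` column; category sizes are
#'   attached as attribute `"category_sizes"`.
#' @export
categorize_samples <- function(entries, separator = "_") {
  stopifnot(is.character(separator), nzchar(separator))
  stem <- tools::file_path_sans_ext(basename(entries$file_path))
  has_sep <- grepl(separator, stem, fixed = TRUE)
  if (any(!has_sep))
    warning(sprintf("%d filename(s) lack separator '%s'; using full stem as category: %s",
                    sum(!has_sep), separator,
                    paste(utils::head(stem[!has_sep], 5), collapse = ", ")),
            call. = FALSE)
  cat_name <- stem
  cat_name[has_sep] <- vapply(strsplit(stem[has_sep], separator, fixed = TRUE),
                              `[[`, character(1), 1L)
  entries$category <- cat_name
  attr(entries, "category_sizes") <- table(cat_name)
  entries
}
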