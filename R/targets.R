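# Target-feature tables: the analytes and ion species to screen for.

#' Read a target-feature table
#'
#' Reads a delimited table of target features. Expected columns:
#' `name`, `formula`, `target_mz`, `ion`, `expected_tR_min`, `group`
#' (`formula` or `target_mz` may be empty, not both; `group` is
#' optional and links ion species of the same metabolite). The
#' delimiter is sniffed from the extension: tab for `.tsv`/`.txt`,
#' comma otherwise. Expected retention times are given in minutes
#' (chromatographic convention) and converted to seconds internally.
#'
#' When a formula is given, the theoretical m/z is computed from the
#' formula and ion species; if `target_mz` is also given the two must
#' agree within 0.001 Da.
#'
#' @param path Path to a CSV/TSV target table.
#' @return A data.frame with columns `name`, `formula`, `ion`,
#'   `theoretical_mz`, `expected_rt_s`, `group`, `n_carbon`,
#'   `theoretical_ria`.
#' @export
read_targets <- function(path) {
  if (!file.exists(path)) stop(sprintf("target table not found: %s", path), call. = FALSE)
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                           comment.char = "", strip.white = TRUE,
                           colClasses = "character")
  need <- c("name", "ion", "expected_tR_min")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L)
    stop(sprintf("target table %s lacks column(s): %s (found: %s)", path,
                 paste(miss, collapse = ", "), paste(names(tab), collapse = ", ")),
         call. = FALSE)
  if (!"formula" %in% names(tab)) tab$formula <- ""
  if (!"target_mz" %in% names(tab)) tab$target_mz <- ""
  if (!"group" %in% names(tab)) tab$group <- ""

  out <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    has_formula <- nzchar(trimws(row$formula))
    stated_mz <- suppressWarnings(as.numeric(row$target_mz))
    has_mz <- is.finite(stated_mz)
    if (!has_formula && !has_mz)
      stop(sprintf("target '%s' (row %d): neither formula nor target_mz given",
                   row$name, i), call. = FALSE)
    ion <- ion_species(trimws(row$ion))
    n_carbon <- NA_integer_
    ria <- NA_real_
    if (has_formula) {
      f <- parse_formula(trimws(row$formula))
      theo <- adduct_mz(monoisotopic_mass(f), ion)
      if (has_mz && abs(theo - stated_mz) > 0.001)
        stop(sprintf("target '%s' (row %d): stated target_mz %.4f disagrees with %.4f computed from formula %s %s",
                     row$name, i, stated_mz, theo, row$formula, row$ion), call. = FALSE)
      if ("C" %in% names(f)) {
        n_carbon <- unclass(f)[["C"]]
        ria <- theoretical_ria(f)
      }
    } else {
      theo <- stated_mz
    }
    rt_min <- suppressWarnings(as.numeric(row$expected_tR_min))
    if (!is.finite(rt_min) || rt_min < 0)
      stop(sprintf("target '%s' (row %d): invalid expected_tR_min '%s'",
                   row$name, i, row$expected_tR_min), call. = FALSE)
    data.frame(name = row$name,
               formula = if (has_formula) trimws(row$formula) else NA_character_,
               ion = ion$label, theoretical_mz = theo,
               expected_rt_s = rt_min * 60,
               group = if (nzchar(trimws(row$group))) trimws(row$group) else row$name,
               n_carbon = n_carbon, theoretical_ria = ria,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (anyDuplicated(paste(res$name, res$ion)) > 0L)
    warning("duplicate (name, ion) rows in target table", call. = FALSE)
  stopifnot(all(res$theoretical_mz > 0))
  res
}
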