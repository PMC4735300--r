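#' Parse a compound table
#'
#' Reads a delimited text file of compounds into a compound table. The file
#' must carry a header with at least `id` and `smiles` columns; the optional
#' columns `name`, `activity` (spikes/s increase above spontaneous firing),
#' `active_label` (`active`/`inactive`/`unknown`) and `kinetics_label`
#' (`transient`/`prolonged`/`unknown`) are mapped when present. Row order is
#' preserved.
#'
#' @param path Path to a delimited text file. Comma-separated by default;
#'   tab-separated files are detected from the header line (or force with
#'   `sep`).
#' @param sep Field separator; `NULL` (default) autodetects "," vs tab.
#' @return A `data.frame` with columns `id`, `smiles`, `name`, `activity`,
#'   `active_label`, `kinetics_label` (missing optional columns filled with
#'   `NA`), one row per compound in file order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,smiles,activity,active_label",
#'              "ea,CCOC(C)=O,60,active",
#'              "clb,Clc1ccccc1,0,inactive"), f)
#' parse_compounds(f)
#' @export
parse_compounds <- function(path, sep = NULL) {
  if (!file.exists(path)) stopf("compound file not found: %s", path)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   comment.char = "#", quote = "\"", check.names = TRUE)
  need <- c("id", "smiles")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("compound table lacks required column(s): %s",
                          paste(miss, collapse = ", "))
  df$id <- as.character(df$id)
  df$smiles <- as.character(df$smiles)
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup)) stopf("duplicate compound id(s): %s",
                         paste(dup, collapse = ", "))
  bad <- which(is.na(df$smiles) | !nzchar(trimws(df$smiles)))
  if (length(bad)) stopf("missing smiles at data row(s): %s",
                         paste(bad, collapse = ", "))
  out <- data.frame(
    id = df$id,
    smiles = df$smiles,
    name = if ("name" %in% names(df)) as.character(df$name) else NA_character_,
    activity = if ("activity" %in% names(df)) as.numeric(df$activity) else NA_real_,
    active_label = if ("active_label" %in% names(df))
      as.character(df$active_label) else NA_character_,
    kinetics_label = if ("kinetics_label" %in% names(df))
      as.character(df$kinetics_label) else NA_character_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write a compound table
#'
#' Inverse of [parse_compounds()]: writes the standard compound columns as
#' delimited text.
#'
#' @param compounds Compound `data.frame` (as from [parse_compounds()] or the
#'   generators).
#' @param path Output file path.
#' @param sep Field separator (default ",").
#' @return `path`, invisibly.
#' @export
write_compounds <- function(compounds, path, sep = ",") {
  keep <- intersect(c("id", "smiles", "name", "activity", "active_label",
                      "kinetics_label"), names(compounds))
  write.table(compounds[, keep, drop = FALSE], path, sep = sep,
              row.names = FALSE, quote = FALSE)
  invisible(path)
}
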