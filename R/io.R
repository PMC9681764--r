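#' Read a sensor logger export
#'
#' Parses a delimited logger export into the sensor-series tibble used
#' throughout the package. Timestamps must parse as ISO-8601 (a logger
#' export without an offset is interpreted in `tz`, which is never guessed);
#' rows with unparseable timestamps are rejected with their line numbers.
#' RH readings outside [0, 100] are clipped with a warning.
#'
#' @param path File path.
#' @param col_map Named character vector mapping the canonical column names
#'   (`timestamp`, `temp_c`, `rh_pct`, `par_umol`) to the file's column
#'   names.
#' @param tz Timezone applied to offset-less timestamps.
#' @param site,position,replicate Labels for the series; columns of the same
#'   name in the file take precedence.
#' @param delim Field delimiter (default comma).
#'
#' @return A sensor-series tibble.
#' @export
read_sensor_csv <- function(path,
                            col_map = c(timestamp = "timestamp",
                                        temp_c = "temp_c",
                                        rh_pct = "rh_pct",
                                        par_umol = "par_umol"),
                            tz = "UTC",
                            site = "site1", position = "air",
                            replicate = "r1", delim = ",") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  missing_cols <- setdiff(col_map, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("column(s) not found in %s: %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  ts <- suppressWarnings(
    readr::parse_datetime(raw[[col_map[["timestamp"]]]],
                          locale = readr::locale(tz = tz))
  )
  bad <- which(is.na(ts))
  if (length(bad) == nrow(raw) || nrow(raw) == 0) {
    abort(sprintf("no parseable rows in %s", path))
  }
  if (length(bad) > 0) {
    warn(sprintf("rejected %d row(s) with unparseable timestamps (lines %s)",
                 length(bad),
                 paste(head(bad + 1L, 10), collapse = ", ")))
  }
  num <- function(col) suppressWarnings(as.numeric(raw[[col_map[[col]]]]))
  rh <- num("rh_pct")
  out_of_range <- sum(rh < 0 | rh > 100, na.rm = TRUE)
  if (out_of_range > 0) {
    warn(sprintf("clipped %d RH reading(s) to [0, 100]", out_of_range))
    rh <- pmin(pmax(rh, 0), 100)
  }
  tibble(
    site = if ("site" %in% names(raw)) raw$site else site,
    position = if ("position" %in% names(raw)) raw$position else position,
    replicate = if ("replicate" %in% names(raw)) raw$replicate else replicate,
    timestamp = ts,
    temp_c = num("temp_c"),
    rh_pct = rh,
    par_umol = num("par_umol")
  ) |>
    filter(!is.na(.data$timestamp))
}

#' Write a sensor series in the canonical dialect
#'
#' Comma-separated with header, timestamps as ISO-8601 UTC
#' (`YYYY-MM-DDTHH:MM:SSZ`). Reading the file back with
#' [read_sensor_csv()] and writing it again is byte-identical.
#'
#' @param series A sensor-series tibble.
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(series, path) {
  out <- series |>
    mutate(timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                              tz = "UTC")) |>
    select(any_of(c("site", "position", "replicate", "timestamp",
                    "temp_c", "rh_pct", "par_umol")))
  readr::write_csv(out, path)
  invisible(path)
}

#' Read predicted protein sequences from FASTA
#'
#' Sequences are upper-cased; the FASTA description (text after the first
#' space) is preserved; ids of the form `<contig>_<orf>` yield the parent
#' contig id. Empty records are an error.
#'
#' @param path FASTA file path.
#'
#' @return A tibble: `id`, `description`, `contig`, `sequence`, `weight`
#'   (1 for every record; join abundance weights afterwards).
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) abort(sprintf("no FASTA records in %s", path))
  seqs <- toupper(as.character(aa))
  empty <- which(nchar(seqs) == 0)
  if (length(empty) > 0) {
    abort(sprintf("empty FASTA record(s) at index %s",
                  paste(empty, collapse = ", ")))
  }
  header <- names(aa)
  id <- sub("\\s.*$", "", header)
  desc <- ifelse(grepl("\\s", header), sub("^\\S+\\s+", "", header), "")
  tibble(
    id = id,
    description = desc,
    contig = sub("_[^_]+$", "", id),
    sequence = unname(seqs),
    weight = 1
  )
}

#' Write protein records as FASTA
#'
#' @param proteins Tibble with `id`, `sequence` and optional `description`.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#'
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60) {
  aa <- Biostrings::AAStringSet(proteins$sequence)
  desc <- proteins$description %||% rep("", nrow(proteins))
  names(aa) <- ifelse(nzchar(desc),
                      paste(proteins$id, desc), proteins$id)
  Biostrings::writeXStringSet(aa, path, width = width)
  invisible(path)
}

#' Read a wide feature-by-sample abundance TSV into long form
#'
#' @param path TSV with a `feature` first column and one column per sample.
#' @param sites Optional named vector mapping sample ids to site labels.
#'
#' @return Long tibble: `feature`, `sample`, `abundance` (+ `site` when
#'   `sites` is given).
#' @export
read_abundance_tsv <- function(path, sites = NULL) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  names(wide)[1] <- "feature"
  long <- tidyr::pivot_longer(wide, -"feature",
                              names_to = "sample", values_to = "abundance")
  if (!is.null(sites)) long$site <- unname(sites[long$sample])
  long
}

#' Write a long abundance table as a wide feature-by-sample TSV
#'
#' @param table Long abundance tibble.
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(table, path) {
  table |>
    select("feature", "sample", "abundance") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "abundance",
                       values_fill = 0) |>
    readr::write_tsv(path)
  invisible(path)
}
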