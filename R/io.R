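#' Read a BS/oxBS count table
#'
#' Reads the long TSV dialect consumed by the methylome stage: header
#' columns `chrom`, `pos`, `strand`, `condition`, `replicate`, `assay`
#' (`BS`/`oxBS`), `meth`, `total`. Malformed rows (meth > total, negative
#' counts, bad assay labels) are dropped and reported via a warning and the
#' `rejected` attribute, so one bad row does not poison a run.
#'
#' @param path Path to a TSV file with the required header.
#' @return A tibble of typed records; attribute `rejected` holds the dropped
#'   rows with a `reason` column.
#' @export
read_counts_table <- function(path) {
  req <- c("chrom", "pos", "strand", "condition", "replicate", "assay",
           "meth", "total")
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  if (nrow(tbl) == 0L && ncol(tbl) == 0L) {
    abort("empty count table: no header found")
  }
  missing_cols <- setdiff(req, names(tbl))
  if (length(missing_cols)) {
    abort(paste0("count table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in c("chrom", "strand", "condition", "assay")) {
    tbl[[col]] <- as.character(tbl[[col]])
  }
  bad <- dplyr::case_when(
    !tbl$assay %in% c("BS", "oxBS") ~ "assay not BS/oxBS",
    is.na(tbl$meth) | is.na(tbl$total) ~ "missing counts",
    tbl$meth < 0 | tbl$total < 0 ~ "negative counts",
    tbl$meth > tbl$total ~ "meth > total",
    .default = NA_character_
  )
  rejected <- tbl[!is.na(bad), ]
  if (nrow(rejected)) {
    rejected$reason <- bad[!is.na(bad)]
    warn(sprintf("dropped %d malformed row(s); see attr(, 'rejected')",
                 nrow(rejected)))
  }
  out <- tbl[is.na(bad), ] |>
    dplyr::mutate(pos = as.integer(.data$pos),
                  replicate = as.integer(.data$replicate),
                  meth = as.integer(.data$meth),
                  total = as.integer(.data$total))
  attr(out, "rejected") <- rejected
  out
}

#' Read a BED3/BED4 interval track
#'
#' 0-based half-open intervals, tab-separated, no header; a fourth column is
#' taken as the interval label. Rows with `start >= end` or negative starts
#' are rejected with a warning. Output is sorted by chromosome and start;
#' overlapping intervals are allowed.
#'
#' @param path Path to a BED file.
#' @return A tibble `chrom`, `start`, `end` and, when present, `label`;
#'   attribute `rejected` holds dropped rows.
#' @export
read_bed <- function(path) {
  tbl <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         comment = "#")
  if (ncol(tbl) < 3L) abort("BED needs at least 3 columns")
  names(tbl)[1:3] <- c("chrom", "start", "end")
  if (ncol(tbl) >= 4L) names(tbl)[4] <- "label"
  tbl <- tbl[, intersect(c("chrom", "start", "end", "label"), names(tbl))]
  bad <- tbl$start >= tbl$end | tbl$start < 0
  rejected <- tbl[bad, ]
  if (nrow(rejected)) {
    warn(sprintf("dropped %d invalid interval(s) (start >= end or negative)",
                 nrow(rejected)))
  }
  out <- tbl[!bad, ] |>
    dplyr::mutate(start = as.integer(.data$start),
                  end = as.integer(.data$end)) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end)
  attr(out, "rejected") <- rejected
  out
}

fmt9 <- function(x) {
  if (is.numeric(x) && !is.integer(x)) {
    formatC(x, digits = 9, format = "g")
  } else {
    x
  }
}

write_table9 <- function(df, path) {
  out <- dplyr::mutate(as_tibble(df), dplyr::across(dplyr::everything(), fmt9))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write pipeline tables as deterministic TSV
#'
#' Writers with a fixed column order and 9-significant-digit float
#' formatting, so that writing the same object twice yields byte-identical
#' files and a write/read round trip preserves values to well under 1e-9
#' relative.
#'
#' @param tc A `no_timecourse` (or `activity_timecourse`).
#' @param dmps A [call_dmps()] result (annotated or not).
#' @param summary A [summarize_by_annotation()] table.
#' @param objects Any data frame (generic writer).
#' @param path Output file path.
#' @return The path, invisibly.
#' @name writers
NULL

#' @rdname writers
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(is.data.frame(tc))
  write_table9(tc, path)
}

#' @rdname writers
#' @export
write_dmps <- function(dmps, path) {
  stopifnot(is.data.frame(dmps))
  write_table9(dmps, path)
}

#' @rdname writers
#' @export
write_summary <- function(summary, path) {
  stopifnot(is.data.frame(summary))
  write_table9(summary, path)
}
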