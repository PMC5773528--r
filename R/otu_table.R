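#' Construct an OTU abundance time-series table
#'
#' The central container of the package: a non-negative OTU-by-sample matrix
#' together with the sampling day of every column. Several columns may share a
#' day (replicates); [average_replicates()] collapses them to one column per
#' day. Relative-abundance tables carry the `is_relative` flag and must have
#' every day-column summing to 1.
#'
#' @param values numeric matrix, rows = OTUs, columns = samples; all entries
#'   must be non-negative and finite.
#' @param otu_ids character vector of unique OTU identifiers (defaults to the
#'   rownames of `values`).
#' @param sample_days integer vector, one day index per column (ordinal day of
#'   year in the original study design); repeated values mark replicates.
#' @param is_relative logical; if `TRUE`, every day-column must sum to 1
#'   within `1e-9` and all-zero columns are rejected.
#'
#' @return an object of class `otu_table`: a list with elements `values`,
#'   `otu_ids`, `sample_days`, `is_relative`.
#' @export
otu_table <- function(values, otu_ids = rownames(values), sample_days,
                      is_relative = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(otu_ids)) otu_ids <- paste0("OTU", seq_len(nrow(values)))
  otu_ids <- as.character(otu_ids)
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU ids: ", paste(unique(otu_ids[duplicated(otu_ids)]),
                                      collapse = ", "))
  if (length(otu_ids) != nrow(values))
    stop("otu_ids length does not match number of rows")
  sample_days <- as.integer(sample_days)
  if (length(sample_days) != ncol(values))
    stop("sample_days length does not match number of columns")
  if (anyNA(values) || any(!is.finite(values)))
    stop("values must be finite and non-missing")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance at OTU '%s', column %d",
                 otu_ids[bad[1L]], bad[2L]))
  }
  if (is.unsorted(sample_days))
    stop("sample_days must be non-decreasing (time-ordered columns)")
  if (is_relative) {
    cs <- colSums(values)
    if (any(abs(cs - 1) > 1e-9))
      stop("relative-abundance columns must sum to 1 (day ",
           sample_days[which.max(abs(cs - 1))], " does not)")
  }
  rownames(values) <- otu_ids
  structure(list(values = values, otu_ids = otu_ids,
                 sample_days = sample_days, is_relative = is_relative),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples over %d days%s\n",
              nrow(x$values), ncol(x$values), length(unique(x$sample_days)),
              if (x$is_relative) " (relative abundances)" else " (counts)"))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$values)

#' Read an OTU table from a tab-delimited file
#'
#' Expects a header row of sample labels and a first column of OTU ids (or the
#' transpose, per `orientation`). The sampling day of each column is taken
#' from the first run of digits in its label, so labels such as `d247_r1`,
#' `247.2` or plain `247` all map to day 247.
#'
#' @param path file path of a TSV (tab-delimited, '.' decimal).
#' @param orientation `"otus_in_rows"` (default) or `"otus_in_columns"`.
#' @param is_relative passed to [otu_table()].
#' @return an [otu_table()].
#' @export
read_otu_table <- function(path, orientation = c("otus_in_rows",
                                                 "otus_in_columns"),
                           is_relative = FALSE) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (orientation == "otus_in_columns") m <- t(m)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) &
                   !is.na(m), arr.ind = TRUE)
    if (length(bad)) {
      stop(sprintf("non-numeric cell at row '%s', column '%s'",
                   rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
    }
    storage.mode(m) <- "double"
  }
  days <- parse_day_labels(colnames(m))
  o <- order(days)
  otu_table(m[, o, drop = FALSE], rownames(m), days[o],
            is_relative = is_relative)
}

parse_day_labels <- function(labels) {
  day <- suppressWarnings(as.integer(sub("^[^0-9]*([0-9]+).*$", "\\1",
                                         labels)))
  if (anyNA(day))
    stop("cannot parse a day index from sample label(s): ",
         paste(labels[is.na(day)], collapse = ", "))
  day
}

#' Write an OTU table to a tab-delimited file
#'
#' Columns are labelled `d<day>` (with `.r<k>` suffixes for replicates) so a
#' round trip through [read_otu_table()] restores the day map.
#'
#' @param table an [otu_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  labs <- paste0("d", table$sample_days)
  if (anyDuplicated(table$sample_days)) {
    rep_idx <- stats::ave(seq_along(table$sample_days), table$sample_days,
                          FUN = seq_along)
    labs <- paste0(labs, ".r", rep_idx)
  }
  df <- data.frame(otu_id = table$otu_ids, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("otu_id", labs)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average replicate samples taken on the same day
#'
#' Collapses the table to one column per day; each cell is the arithmetic mean
#' of that day's replicate cells. Singleton days pass through unchanged.
#' Averaging is done on whatever scale the table is on; the default pipeline
#' averages counts before normalising (which weights replicates by sequencing
#' depth), but the function applies equally to relative abundances if the
#' alternative order is preferred.
#'
#' @param table an [otu_table()].
#' @return an [otu_table()] with strictly increasing, unique `sample_days`.
#' @export
average_replicates <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  days <- sort(unique(table$sample_days))
  if (length(days) == ncol(table$values)) return(table)
  v <- vapply(days, function(d) {
    cols <- table$sample_days == d
    rowMeans(table$values[, cols, drop = FALSE])
  }, numeric(nrow(table$values)))
  v <- matrix(v, nrow = nrow(table$values),
              dimnames = list(table$otu_ids, NULL))
  otu_table(v, table$otu_ids, days, is_relative = table$is_relative)
}

#' Convert counts to relative abundances
#'
#' Divides every day-column by its sum. Idempotent on tables that are already
#' relative.
#'
#' @param table an [otu_table()].
#' @return an [otu_table()] with `is_relative = TRUE`.
#' @export
to_relative_abundance <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  cs <- colSums(table$values)
  if (any(cs == 0))
    stop("all-zero column(s) on day(s): ",
         paste(table$sample_days[cs == 0], collapse = ", "))
  v <- sweep(table$values, 2L, cs, "/")
  otu_table(v, table$otu_ids, table$sample_days, is_relative = TRUE)
}

#' Keep OTUs that recur on more than `min_days` distinct days
#'
#' Presence means strictly positive abundance. With the default
#' `min_days = 10` an OTU must be present on at least 11 distinct days to be
#' kept (strict inequality, "more than 10 days").
#'
#' The result is always flagged as counts-like (`is_relative = FALSE`)
#' because dropping rows breaks the unit-sum closure; renormalise with
#' [to_relative_abundance()] afterwards if needed.
#'
#' @param table a day-averaged [otu_table()].
#' @param min_days integer threshold (default 10).
#' @return the filtered [otu_table()].
#' @export
filter_recurrent <- function(table, min_days = 10) {
  stopifnot(inherits(table, "otu_table"))
  days <- table$sample_days
  present_days <- apply(table$values > 0, 1L, function(p)
    length(unique(days[p])))
  keep <- present_days > min_days
  otu_table(table$values[keep, , drop = FALSE], table$otu_ids[keep],
            table$sample_days, is_relative = FALSE)
}

#' Read an environmental metadata table
#'
#' TSV with a `day` column of day indices and one column per environmental
#' variable; missing values are encoded as `NA` and are never imputed.
#'
#' @param path file path.
#' @return a data.frame with integer `day` first, numeric variables after.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, na.strings = "NA",
                          stringsAsFactors = FALSE)
  if (!"day" %in% names(df)) stop("metadata table must have a 'day' column")
  df$day <- as.integer(df$day)
  if (anyDuplicated(df$day)) stop("duplicate day indices in metadata")
  df[order(df$day), , drop = FALSE]
}
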