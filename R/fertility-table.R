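#' Per-offspring fertility table keyed by clutch size
#'
#' The engine of every F2 computation in the package: for each clutch size
#' `k` (number of offspring developing in one host egg), `f(k)` is the
#' expected lifetime egg complement of a single female offspring from a
#' clutch of that size. Because gregarious larvae share one host's
#' resources, offspring from larger clutches emerge smaller, and in
#' proovigenic species body size maps linearly onto the fixed egg
#' complement, so `f(k)` typically decreases with `k`.
#'
#' @param f Numeric vector of per-offspring fertilities (eggs); element `k`
#'   is the value for clutch size `k`, so clutch sizes are the contiguous
#'   range `1..length(f)`. All values must be non-negative. `NA` entries are
#'   only permitted when `incomplete = TRUE` (tables recovered from data in
#'   which some clutch size yielded no female offspring).
#' @param mean_females_per_host Optional numeric vector of the same length:
#'   expected number of female offspring per host at each clutch size, each
#'   within `[0, k]`.
#' @param incomplete Allow `NA` fertility entries (flagged on the result).
#'
#' @return An object of class `fertility_table`: a list with elements
#'   `max_clutch`, `f` (named numeric), `mean_females_per_host` (or `NULL`),
#'   `non_increasing` (is `f` non-increasing over its defined entries?) and
#'   `complete`.
#' @seealso [default_fertility_table()], [per_host_f2()], [cohort_f2()]
#' @export
#' @examples
#' fertility_table(c(19.3, 13.8, 11.2, 10.0))
fertility_table <- function(f, mean_females_per_host = NULL, incomplete = FALSE) {
  if (!is.numeric(f) || length(f) < 1L) {
    stop_clutchfit("`f` must be a non-empty numeric vector of per-offspring fertilities",
                   "clutchfit_invalid_input")
  }
  max_clutch <- length(f)
  if (max_clutch > MAX_CLUTCH_ABS) {
    stop_clutchfit(
      sprintf("clutch sizes beyond %d are not representable (got table up to %d)",
              MAX_CLUTCH_ABS, max_clutch),
      "clutchfit_invalid_input"
    )
  }
  f <- as.numeric(f)
  if (anyNA(f) && !incomplete) {
    stop_clutchfit("fertility values must not be missing (use `incomplete = TRUE` for partially observed tables)",
                   "clutchfit_invalid_input")
  }
  if (any(!is.na(f) & (!is.finite(f) | f < 0))) {
    stop_clutchfit("per-offspring fertility must be finite and non-negative",
                   "clutchfit_invalid_input")
  }
  names(f) <- as.character(seq_len(max_clutch))
  if (!is.null(mean_females_per_host)) {
    mf <- as.numeric(mean_females_per_host)
    if (length(mf) != max_clutch) {
      stop_clutchfit("`mean_females_per_host` must have one entry per clutch size",
                     "clutchfit_invalid_input")
    }
    k <- seq_len(max_clutch)
    bad <- !is.na(mf) & (mf < 0 | mf > k)
    if (any(bad)) {
      stop_clutchfit(
        sprintf("mean females per host must lie in [0, k]; violated at clutch size(s) %s",
                paste(k[bad], collapse = ", ")),
        "clutchfit_invalid_input"
      )
    }
    names(mf) <- names(f)
    mean_females_per_host <- mf
  }
  defined <- f[!is.na(f)]
  structure(
    list(
      max_clutch = as.integer(max_clutch),
      f = f,
      mean_females_per_host = mean_females_per_host,
      non_increasing = length(defined) < 2L || all(diff(defined) <= 0),
      complete = !anyNA(f)
    ),
    class = "fertility_table"
  )
}

#' The packaged default fertility table for *Anaphes flavipes*
#'
#' Measured per-offspring fertilities by clutch size: 19.3, 13.8, 11.2 and
#' 10.0 eggs for clutch sizes 1-4. Larger clutches (5-7) are representable
#' as compositions but carry no default fertility value; evaluating F2 on
#' them requires a user-supplied extended table.
#'
#' @return A [fertility_table] with `max_clutch = 4`.
#' @export
#' @examples
#' default_fertility_table()
default_fertility_table <- function() {
  fertility_table(c(19.3, 13.8, 11.2, 10.0))
}

# Look up f(k); errors rather than extrapolating.
fertility_of <- function(table, clutch_size) {
  stopifnot(inherits(table, "fertility_table"))
  k <- check_count(clutch_size, "clutch_size", min = 1L)
  if (k > table$max_clutch || is.na(table$f[[k]])) {
    stop_clutchfit(
      sprintf("no fertility value for clutch size %d (table covers 1..%d%s); supply an extended table",
              k, table$max_clutch,
              if (table$complete) "" else ", with gaps"),
      "clutchfit_missing_fertility"
    )
  }
  table$f[[k]]
}

#' @export
print.fertility_table <- function(x, ...) {
  cat(sprintf("<fertility_table> clutch sizes 1..%d%s\n", x$max_clutch,
              if (x$non_increasing) " (non-increasing)" else ""))
  df <- data.frame(
    clutch_size = seq_len(x$max_clutch),
    per_offspring_fertility = unname(x$f)
  )
  if (!is.null(x$mean_females_per_host)) {
    df$mean_females_per_host <- unname(x$mean_females_per_host)
  }
  print(df, row.names = FALSE)
  invisible(x)
}

#' Read and write fertility tables
#'
#' Tables serialise to a small CSV (columns `clutch_size`,
#' `per_offspring_fertility` and optionally `mean_females_per_host`) or to
#' JSON. The format is inferred from the file extension unless given.
#'
#' @param table A [fertility_table].
#' @param path File path ending in `.csv` or `.json`.
#' @param format `"csv"` or `"json"`; default inferred from `path`.
#' @return `write_fertility_table()` returns `path` invisibly;
#'   `read_fertility_table()` returns a [fertility_table].
#' @export
write_fertility_table <- function(table, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(table, "fertility_table"))
  format <- resolve_format(match.arg(format), path)
  df <- data.frame(
    clutch_size = seq_len(table$max_clutch),
    per_offspring_fertility = unname(table$f)
  )
  if (!is.null(table$mean_females_per_host)) {
    df$mean_females_per_host <- unname(table$mean_females_per_host)
  }
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "columns", digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_fertility_table
#' @export
read_fertility_table <- function(path, format = c("auto", "csv", "json")) {
  format <- resolve_format(match.arg(format), path)
  df <- if (format == "csv") {
    utils::read.csv(path)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
  req <- c("clutch_size", "per_offspring_fertility")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop_clutchfit(
      sprintf("%s: missing column(s) %s", basename(path),
              paste(missing_cols, collapse = ", ")),
      "clutchfit_validation"
    )
  }
  df <- df[order(df$clutch_size), , drop = FALSE]
  if (!identical(as.integer(df$clutch_size), seq_len(nrow(df)))) {
    stop_clutchfit(
      sprintf("%s: clutch_size must be the contiguous range 1..K", basename(path)),
      "clutchfit_validation"
    )
  }
  fertility_table(
    df$per_offspring_fertility,
    mean_females_per_host = if ("mean_females_per_host" %in% names(df)) {
      df$mean_females_per_host
    },
    incomplete = anyNA(df$per_offspring_fertility)
  )
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "json")) return(ext)
  stop_clutchfit(
    sprintf("cannot infer format from extension '%s'; pass `format`", ext),
    "clutchfit_invalid_input"
  )
}
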