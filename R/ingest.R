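#' Missing-value coding policy
#'
#' Defines which cell contents are treated as missing when a response table
#' is read. The built-in codes are the empty string, `"NA"` and `"N/A"`;
#' up to three additional custom codes may be supplied (e.g. `"-99"`,
#' `"-777"`), mirroring common survey-software conventions.
#'
#' Codes are compared against whole cells after trimming surrounding
#' whitespace, case-sensitively: `"na"` is *not* missing under the default
#' policy, and `"nap"` never matches `"NA"`.
#'
#' @param custom character vector of at most 3 additional missing codes.
#' @return An object of class `na_policy`.
#' @examples
#' na_policy()
#' na_policy(custom = "-99")
#' @export
na_policy <- function(custom = character()) {
  custom <- as.character(custom)
  if (length(custom) > 3) {
    stop("at most 3 custom missing codes are supported, got ",
         length(custom), call. = FALSE)
  }
  if (anyNA(custom)) stop("custom missing codes must not be NA", call. = FALSE)
  structure(
    list(builtin = c("", "NA", "N/A"), custom = custom),
    class = "na_policy"
  )
}

#' @export
print.na_policy <- function(x, ...) {
  cat("Missing-value policy\n")
  cat("  builtin:", paste(dQuote(x$builtin, q = FALSE), collapse = ", "), "\n")
  if (length(x$custom)) {
    cat("  custom: ", paste(dQuote(x$custom, q = FALSE), collapse = ", "), "\n")
  }
  invisible(x)
}

# Apply an na_policy to a character vector: exact full-cell match after
# trimming surrounding whitespace. Returns the vector with matches set to NA.
recode_missing <- function(x, policy) {
  stopifnot(inherits(policy, "na_policy"))
  codes <- c(policy$builtin, policy$custom)
  trimmed <- trimws(x)
  x[!is.na(trimmed) & trimmed %in% codes] <- NA_character_
  x
}

#' Read a delimited response table
#'
#' Reads a wide-format delimited text file (one row per participant, one
#' column per item plus a condition column) into a character data frame,
#' recoding missing values according to a [na_policy()]. All cells are kept
#' as strings; response content is never interpreted numerically because only
#' the pattern of answered versus missing cells matters for dropout analysis.
#'
#' A header row is required. Files are read as UTF-8 and a leading byte-order
#' mark is tolerated (web-exported CSVs commonly carry one).
#'
#' @param path path to the delimited file.
#' @param sep field separator: `","` (default), `";"` or `"\t"`.
#' @param quote quoting character: `"\""` (default), `"'"` or `""` for none.
#' @param na a [na_policy()] describing missing-value codes.
#' @return A data frame of character columns; cells matching a missing code
#'   are `NA`.
#' @seealso [select_columns()] to bind condition and item columns.
#' @export
read_response_table <- function(path, sep = ",", quote = "\"",
                                na = na_policy()) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    stop("cannot read file: ", path, call. = FALSE)
  }
  if (!sep %in% c(",", ";", "\t")) {
    stop("separator must be one of ',', ';' or tab", call. = FALSE)
  }
  if (!quote %in% c("\"", "'", "")) {
    stop("quote character must be double, single, or none (\"\")",
         call. = FALSE)
  }
  stopifnot(inherits(na, "na_policy"))

  fields <- utils::count.fields(path, sep = sep, quote = quote,
                                blank.lines.skip = TRUE)
  fields <- fields[!is.na(fields)]
  if (length(fields) > 1 && length(unique(fields)) > 1) {
    bad <- which(fields != fields[1])[1]
    stop("ragged input: line ", bad, " has ", fields[bad],
         " fields, header has ", fields[1], call. = FALSE)
  }

  raw <- utils::read.table(
    path, header = TRUE, sep = sep, quote = quote,
    colClasses = "character", check.names = FALSE,
    na.strings = character(), fileEncoding = "UTF-8-BOM",
    comment.char = "", stringsAsFactors = FALSE
  )
  if (anyDuplicated(names(raw))) {
    stop("duplicate column names in header: ",
         paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "),
         call. = FALSE)
  }
  raw[] <- lapply(raw, recode_missing, policy = na)
  raw
}

#' Bind condition and item columns into a response table
#'
#' Selects the condition column and the item columns, in the order the items
#' were presented during the study, and validates the result. The supplied
#' item order is authoritative — it need not follow the file's column order,
#' because every downstream quantity (dropout index, curves, tests) is
#' defined relative to presentation order.
#'
#' Rows whose condition cell is missing are dropped with a warning: the
#' condition drives every grouping, so such rows cannot be analyzed.
#'
#' @param raw a data frame as returned by [read_response_table()].
#' @param condition name of the column coding experimental condition.
#' @param items character vector of item column names, in presentation order.
#' @return A `response_table`: a data frame holding the condition column and
#'   the item columns, with attributes `condition` (column name) and `items`
#'   (ordered item names).
#' @export
select_columns <- function(raw, condition, items) {
  stopifnot(is.data.frame(raw))
  if (length(items) == 0) stop("item selection is empty", call. = FALSE)
  if (anyDuplicated(items)) {
    stop("duplicate item columns: ",
         paste(unique(items[duplicated(items)]), collapse = ", "),
         call. = FALSE)
  }
  if (condition %in% items) {
    stop("condition column ", sQuote(condition),
         " must not be among the items", call. = FALSE)
  }
  unknown <- setdiff(c(condition, items), names(raw))
  if (length(unknown)) {
    hints <- vapply(unknown, function(u) {
      near <- agrep(u, names(raw), max.distance = 0.25, value = TRUE)
      if (length(near)) paste0(" (did you mean ",
                               paste(sQuote(near[1:min(3, length(near))]),
                                     collapse = ", "), "?)")
      else ""
    }, character(1))
    stop("unknown column(s): ",
         paste0(sQuote(unknown), hints, collapse = "; "), call. = FALSE)
  }

  out <- raw[, c(condition, items), drop = FALSE]
  miss_cond <- is.na(out[[condition]])
  if (any(miss_cond)) {
    warning(sum(miss_cond),
            " row(s) dropped because the condition cell is missing",
            call. = FALSE)
    out <- out[!miss_cond, , drop = FALSE]
  }
  if (nrow(out) == 0) stop("no rows with a non-missing condition", call. = FALSE)
  rownames(out) <- NULL
  new_response_table(out, condition = condition, items = items)
}

new_response_table <- function(df, condition, items) {
  structure(df,
            condition = condition,
            items = items,
            class = c("response_table", "data.frame"))
}

#' Validate a response table
#'
#' Checks the structural invariants: a non-empty, duplicate-free ordered item
#' list, all named columns present, and a non-missing condition label on
#' every row.
#'
#' @param rt a `response_table`.
#' @return `rt`, invisibly, if valid; otherwise an error.
#' @export
validate_response_table <- function(rt) {
  if (!inherits(rt, "response_table")) {
    stop("not a response_table; see select_columns()", call. = FALSE)
  }
  items <- attr(rt, "items")
  cond <- attr(rt, "condition")
  if (is.null(items) || length(items) == 0) stop("empty item list", call. = FALSE)
  if (anyDuplicated(items)) stop("duplicate items", call. = FALSE)
  if (is.null(cond) || !cond %in% names(rt)) {
    stop("condition column ", sQuote(cond), " not present", call. = FALSE)
  }
  if (!all(items %in% names(rt))) stop("item columns missing", call. = FALSE)
  if (anyNA(rt[[cond]])) stop("missing condition labels present", call. = FALSE)
  invisible(rt)
}

#' @export
print.response_table <- function(x, ...) {
  items <- attr(x, "items")
  cat("Response table: ", nrow(x), " participants, ",
      length(items), " items, condition column ",
      sQuote(attr(x, "condition")), "\n", sep = "")
  cat("Conditions:",
      paste(names(table(x[[attr(x, "condition")]])), collapse = ", "), "\n")
  NextMethod()
}

#' Write a response table back to delimited text
#'
#' Inverse of [read_response_table()] + [select_columns()]: writes the
#' condition and item columns with a header row; missing cells are written
#' as the empty string, which the default [na_policy()] reads back as
#' missing.
#'
#' @param rt a `response_table`.
#' @param path output file path.
#' @param sep field separator.
#' @param quote logical, quote fields.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(rt, path, sep = ",", quote = TRUE) {
  validate_response_table(rt)
  utils::write.table(as.data.frame(rt), path, sep = sep, quote = quote,
                     na = "", row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

item_cols <- function(rt) attr(rt, "items")
condition_col <- function(rt) attr(rt, "condition")
condition_labels <- function(rt) {
  sort(unique(as.character(rt[[attr(rt, "condition")]])))
}
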