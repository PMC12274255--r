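#' Add the per-participant dropout index
#'
#' The dropout index `do_idx` is the 1-based position, within the selected
#' items, of the last answered item: `K` (the item count) for completers and
#' 0 for participants who answered nothing. Only *trailing* missingness
#' counts as dropout — a skipped item followed by later responses
#' (intermittent missing) does not move the index, so the rule is immune to
#' single or repeated skips mid-study.
#'
#' @param rt a `response_table` from [select_columns()] (or any data frame
#'   carrying the `condition`/`items` attributes).
#' @return An `indexed_table`: the input with an integer `do_idx` column
#'   appended. Participants with `do_idx < K` are dropouts; `do_idx == K`
#'   marks completers.
#' @examples
#' rt <- demo_like()
#' it <- add_dropout_idx(rt)
#' table(it$do_idx == length(attr(it, "items")))  # completers
#' @export
add_dropout_idx <- function(rt) {
  validate_response_table(rt)
  items <- item_cols(rt)
  answered <- !is.na(as.matrix(rt[, items, drop = FALSE]))
  # last TRUE per row; 0 when none
  do_idx <- apply(answered, 1L, function(r) {
    w <- which(r)
    if (length(w)) w[length(w)] else 0L
  })
  out <- rt
  out$do_idx <- as.integer(do_idx)
  n0 <- sum(do_idx == 0L)
  if (n0 > 0) {
    message(n0, " participant(s) answered no items (do_idx = 0); ",
            "they are retained and counted as dropped from question 1 on")
  }
  class(out) <- c("indexed_table", class(rt))
  out
}

validate_indexed_table <- function(it) {
  if (!inherits(it, "indexed_table") || is.null(it$do_idx)) {
    stop("input must carry a do_idx column; run add_dropout_idx() first",
         call. = FALSE)
  }
  K <- length(item_cols(it))
  if (any(it$do_idx < 0 | it$do_idx > K)) {
    stop("do_idx out of range [0, ", K, "]", call. = FALSE)
  }
  invisible(it)
}

#' Per-condition dropout statistics
#'
#' For every question position `q` in `1..K` and every condition (plus a
#' pooled `"total"` pseudo-condition), tabulates the cumulative dropout count
#' `cs`, the condition's starting sample size `N`, the number of remaining
#' participants, and percent remaining. A participant with dropout index `d`
#' counts as dropped at questions `q > d` — i.e. the dropout is attributed to
#' the first *unanswered* question, so the participant still appears in the
#' curve at the last item they answered. Completers (`do_idx == K`) never
#' enter `cs`. Consequently, when every participant answers the first item,
#' percent remaining at question 1 is 100 for every condition, and with `K`
#' items a curve has at most `K - 1` visible dropout steps.
#'
#' @param it an `indexed_table` from [add_dropout_idx()].
#' @param by_condition if `TRUE` (default) produce per-condition rows as well
#'   as `"total"`; if `FALSE`, only the pooled `"total"` rows.
#' @return A data frame (class `dropout_stats`) with columns `question`,
#'   `condition`, `cs`, `N`, `remaining`, `pct_remaining`.
#' @examples
#' stats <- compute_stats(add_dropout_idx(demo_like()))
#' head(stats)
#' @export
compute_stats <- function(it, by_condition = TRUE) {
  validate_indexed_table(it)
  K <- length(item_cols(it))
  cond <- as.character(it[[condition_col(it)]])
  groups <- list(total = rep(TRUE, nrow(it)))
  if (by_condition) {
    for (lv in sort(unique(cond))) groups[[lv]] <- cond == lv
  }
  res <- lapply(names(groups), function(g) {
    sel <- groups[[g]]
    if (!any(sel)) {
      warning("condition ", sQuote(g), " is empty; omitted", call. = FALSE)
      return(NULL)
    }
    d <- it$do_idx[sel]
    N <- length(d)
    q <- seq_len(K)
    # dropped at q: do_idx < q and not a completer
    cs <- vapply(q, function(qq) sum(d < qq & d < K), integer(1))
    data.frame(question = q, condition = g, cs = cs, N = N,
               remaining = N - cs, pct_remaining = 100 * (N - cs) / N,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  # conditions first (alphabetically), pooled total last
  out <- out[order(out$condition == "total", out$condition, out$question), ]
  rownames(out) <- NULL
  structure(out, n_items = K, class = c("dropout_stats", "data.frame"))
}

#' @export
print.dropout_stats <- function(x, ...) {
  conds <- setdiff(unique(x$condition), "total")
  cat("Dropout statistics: ", attr(x, "n_items"), " questions, ",
      length(conds), " condition(s) + total\n", sep = "")
  NextMethod()
}

#' Write dropout statistics as tidy CSV
#'
#' @param stats a `dropout_stats` data frame from [compute_stats()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stats <- function(stats, path) {
  stopifnot(inherits(stats, "dropout_stats"))
  utils::write.csv(as.data.frame(stats), path, row.names = FALSE)
  invisible(path)
}
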