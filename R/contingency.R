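#' Dropped-vs-remaining crosstab at a question
#'
#' Builds the condition-by-status contingency table at question `q`: a
#' participant counts as *dropped* if their dropout index is below `q` (and
#' they are not a completer), and as *remaining* otherwise — the same
#' attribution rule as [compute_stats()], so the column sums agree with the
#' pooled dropout statistics at `q`.
#'
#' @param it an `indexed_table` from [add_dropout_idx()].
#' @param q question index in `1..K`; defaults to `K`, i.e. overall dropout
#'   (differences between conditions in reaching the end of the study).
#' @return An integer matrix (conditions x `dropped`/`remaining`) with
#'   attribute `question`.
#' @export
crosstab_at <- function(it, q = NULL) {
  validate_indexed_table(it)
  K <- length(item_cols(it))
  if (is.null(q)) q <- K
  if (length(q) != 1 || is.na(q) || q < 1 || q > K) {
    stop("question index must lie in 1..", K, call. = FALSE)
  }
  cond <- as.character(it[[condition_col(it)]])
  levs <- sort(unique(cond))
  if (length(levs) < 2) {
    stop("only one condition present; use the total dropout curve instead",
         call. = FALSE)
  }
  dropped <- vapply(levs, function(lv) {
    d <- it$do_idx[cond == lv]
    sum(d < q & d < K)
  }, integer(1))
  n <- as.integer(table(factor(cond, levels = levs)))
  tab <- cbind(dropped = dropped, remaining = n - dropped)
  rownames(tab) <- levs
  attr(tab, "question") <- as.integer(q)
  tab
}

#' Chi-square test of dropout differences between conditions
#'
#' Pearson chi-square (no continuity correction at any table size, so the
#' 2x2 and k x 2 cases share one formula) on a dropped-vs-remaining table.
#' A degenerate margin — nobody dropped, or everybody dropped — carries no
#' information about condition differences; the statistic is then reported
#' as 0 with a warning.
#'
#' @param tab a crosstab from [crosstab_at()] (conditions x
#'   `dropped`/`remaining`).
#' @return A list of class `do_chisq`: `statistic`, `df`, `p.value`, `N`,
#'   `table`, `question`.
#' @examples
#' it <- add_dropout_idx(demo_like())
#' chisq_dropout(crosstab_at(it))
#' @export
chisq_dropout <- function(tab) {
  stopifnot(is.matrix(tab), ncol(tab) == 2)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("crosstab cells must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(tab) == 0)) {
    stop("every condition must have at least one participant", call. = FALSE)
  }
  df <- (nrow(tab) - 1L) * 1L
  if (any(colSums(tab) == 0)) {
    warning("degenerate margin: no participant (or every participant) ",
            "dropped; chi-square reported as 0", call. = FALSE)
    stat <- 0
    p <- 1
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    stat <- unname(ct$statistic)
    p <- unname(ct$p.value)
  }
  structure(
    list(statistic = stat, df = df, p.value = p, N = sum(tab),
         table = tab, question = attr(tab, "question")),
    class = "do_chisq"
  )
}

#' @export
print.do_chisq <- function(x, ...) {
  if (!is.null(x$question)) {
    cat("Dropout contingency at question", x$question, "\n")
  }
  print(x$table)
  cat(sprintf("\nchi-squared(%d, N = %d) = %.3f, p = %.4g\n",
              x$df, x$N, x$statistic, x$p.value))
  invisible(x)
}

#' All-pairs odds-ratio matrix of dropout between conditions
#'
#' `OR[i, j]` is the odds of having dropped in condition `i` relative to
#' condition `j`: `(dropped_i * remaining_j) / (remaining_i * dropped_j)`.
#' The matrix has a unit diagonal and is reciprocal
#' (`OR[i, j] * OR[j, i] = 1`). When a pair of rows contains a zero cell,
#' the Haldane-Anscombe correction adds 0.5 to all four cells of that 2x2
#' subtable only, keeping the estimate finite.
#'
#' @param tab a crosstab from [crosstab_at()].
#' @return A square numeric matrix of class `odds_ratio_matrix`.
#' @export
odds_ratio_matrix <- function(tab) {
  stopifnot(is.matrix(tab), ncol(tab) == 2, nrow(tab) >= 2)
  k <- nrow(tab)
  or <- diag(1, k)
  dimnames(or) <- list(rownames(tab), rownames(tab))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      cells <- c(tab[i, 1], tab[i, 2], tab[j, 1], tab[j, 2])
      if (any(cells == 0)) cells <- cells + 0.5
      or[i, j] <- (cells[1] * cells[4]) / (cells[2] * cells[3])
      or[j, i] <- 1 / or[i, j]
    }
  }
  structure(or, question = attr(tab, "question"),
            class = c("odds_ratio_matrix", "matrix", "array"))
}

#' @export
print.odds_ratio_matrix <- function(x, digits = 3, ...) {
  cat("Odds-ratio condition matrix (row vs column odds of dropout)\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Plain-text statistical copy for a contingency analysis
#'
#' Formats the chi-square result and odds-ratio matrix the way they would be
#' reported in a results section.
#'
#' @param chisq a `do_chisq` result.
#' @param or an `odds_ratio_matrix` (optional).
#' @return A character scalar.
#' @export
contingency_copy <- function(chisq, or = NULL) {
  stopifnot(inherits(chisq, "do_chisq"))
  txt <- sprintf("chi-squared(%d, N = %d) = %.3f, p = %.4g",
                 chisq$df, chisq$N, chisq$statistic, chisq$p.value)
  if (!is.null(or)) {
    m <- utils::capture.output(print(or))
    txt <- paste(c(txt, "", m), collapse = "\n")
  }
  txt
}
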