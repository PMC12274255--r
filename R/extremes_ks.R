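#' Most extreme conditions by percent remaining
#'
#' Identifies the conditions with the least and the most participants
#' remaining at question `q` (percent relative to each condition's own
#' sample size), excluding the pooled `"total"` rows. On a tie the
#' lexicographically first label wins, with a warning.
#'
#' @param stats a `dropout_stats` table from [compute_stats()].
#' @param q question index used to rank conditions; defaults to the final
#'   question, i.e. end-of-study retention.
#' @return A named character vector `c(lo = ..., hi = ...)` with attribute
#'   `question`.
#' @export
find_extremes <- function(stats, q = NULL) {
  stopifnot(inherits(stats, "dropout_stats"))
  K <- attr(stats, "n_items")
  if (is.null(q)) q <- K
  if (length(q) != 1 || is.na(q) || q < 1 || q > K) {
    stop("question index must lie in 1..", K, call. = FALSE)
  }
  rows <- stats[stats$question == q & stats$condition != "total", ,
                drop = FALSE]
  if (nrow(rows) < 2) {
    stop("need at least 2 conditions to find extremes", call. = FALSE)
  }
  rows <- rows[order(rows$condition), , drop = FALSE]
  pct <- rows$pct_remaining
  if (length(unique(pct)) == 1) {
    warning("all conditions tie on percent remaining at question ", q,
            "; picking the first two labels", call. = FALSE)
    lo <- rows$condition[1]
    hi <- rows$condition[2]
  } else {
    lo <- rows$condition[which.min(pct)]
    hi <- rows$condition[which.max(pct)]
    if (sum(pct == min(pct)) > 1 || sum(pct == max(pct)) > 1) {
      warning("tie among extreme conditions at question ", q,
              "; lexicographically first label used", call. = FALSE)
    }
  }
  structure(c(lo = lo, hi = hi), question = as.integer(q))
}

#' Kolmogorov-Smirnov comparison of two conditions' dropout times
#'
#' Two-sample KS test on the empirical distributions of the dropout index in
#' the two named conditions (typically the extremes from [find_extremes()]).
#' `D` is the largest vertical gap between the two empirical CDFs; under the
#' dropout attribution rule it equals the largest gap between the two
#' dropout curves, in proportion terms. The p-value is the asymptotic
#' Kolmogorov approximation with effective size `n1 * n2 / (n1 + n2)`.
#' Item positions are heavily tied discrete times, for which the asymptotic
#' p-value is approximate; the result carries this caveat and the print
#' method repeats it.
#'
#' @param it an `indexed_table` from [add_dropout_idx()].
#' @param cond_lo,cond_hi condition labels to compare.
#' @param q question index the extremes were evaluated at (annotation only).
#' @return A list of class `ks_result`: `D`, `p.value`, `cond_lo`,
#'   `cond_hi`, `n_lo`, `n_hi`, `at_question`, `caveat`.
#' @examples
#' it <- add_dropout_idx(demo_like())
#' ext <- find_extremes(compute_stats(it))
#' ks_dropout(it, ext["lo"], ext["hi"])
#' @export
ks_dropout <- function(it, cond_lo, cond_hi, q = NULL) {
  validate_indexed_table(it)
  cond <- as.character(it[[condition_col(it)]])
  cond_lo <- as.character(cond_lo)
  cond_hi <- as.character(cond_hi)
  for (cc in c(cond_lo, cond_hi)) {
    if (!cc %in% cond) stop("unknown condition: ", sQuote(cc), call. = FALSE)
  }
  x <- it$do_idx[cond == cond_lo]
  y <- it$do_idx[cond == cond_hi]
  if (length(x) < 2 || length(y) < 2) {
    stop("each compared condition needs at least 2 participants",
         call. = FALSE)
  }
  # sup over the pooled support of |F_lo - F_hi|
  support <- sort(unique(c(x, y)))
  D <- max(abs(stats::ecdf(x)(support) - stats::ecdf(y)(support)))
  n_eff <- length(x) * length(y) / (length(x) + length(y))
  p <- ks_pvalue_asymptotic(sqrt(n_eff) * D)
  structure(
    list(D = D, p.value = p, cond_lo = cond_lo, cond_hi = cond_hi,
         n_lo = length(x), n_hi = length(y),
         at_question = if (is.null(q)) NA_integer_ else as.integer(q),
         caveat = paste("discrete-time caveat: dropout indices are heavily",
                        "tied; the asymptotic p-value is approximate")),
    class = "ks_result"
  )
}

# Survival function of the Kolmogorov distribution,
# Q(lambda) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2).
ks_pvalue_asymptotic <- function(lambda, terms = 100) {
  if (lambda <= 0) return(1)
  k <- seq_len(terms)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' @export
print.ks_result <- function(x, ...) {
  cat(ks_copy(x), "\n")
  cat("note:", x$caveat, "\n")
  invisible(x)
}

#' Plain-text statistical copy for a KS comparison
#'
#' @param x a `ks_result`.
#' @return A character scalar.
#' @export
ks_copy <- function(x) {
  stopifnot(inherits(x, "ks_result"))
  at <- if (is.na(x$at_question)) "" else
    sprintf(" at question %d", x$at_question)
  sprintf("KS D = %.3f, p = %.4g, comparing %s (n = %d) vs %s (n = %d)%s",
          x$D, x$p.value, x$cond_lo, x$n_lo, x$cond_hi, x$n_hi, at)
}
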