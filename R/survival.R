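#' Recast dropout indices as survival records
#'
#' Dropout maps naturally onto discrete-time survival: the event is dropping
#' out, the event time is the dropout index, and completers are censored at
#' `K` — their (hypothetical) dropout time is only known to exceed the study
#' length. Participants who answered nothing (`do_idx = 0`) enter at time
#' 0.5 as events, so they precede all item times without colliding with an
#' item position.
#'
#' @param it an `indexed_table` from [add_dropout_idx()].
#' @return A data frame with columns `time`, `event` (1 = dropout,
#'   0 = censored completer) and `condition`.
#' @export
to_surv <- function(it) {
  validate_indexed_table(it)
  K <- length(item_cols(it))
  time <- as.numeric(it$do_idx)
  time[time == 0] <- 0.5
  data.frame(
    time = time,
    event = as.integer(it$do_idx < K),
    condition = as.character(it[[condition_col(it)]]),
    stringsAsFactors = FALSE
  )
}

as_surv_records <- function(x) {
  if (inherits(x, "indexed_table")) return(to_surv(x))
  stopifnot(is.data.frame(x),
            all(c("time", "event", "condition") %in% names(x)))
  x
}

#' Kaplan-Meier retention curves per condition
#'
#' Product-limit estimate of the retention function S(t) for each condition,
#' with Greenwood variance and log-scale 95% confidence limits clipped to
#' [0, 1]. Tied event times (unavoidable on discrete item positions) are
#' handled by the standard aggregated `1 - d/n` step. The estimation is
#' delegated to [survival::survfit()]; this wrapper fixes the conventions
#' and returns one tidy table for all conditions.
#'
#' @param x an `indexed_table`, or a data frame of survival records from
#'   [to_surv()].
#' @param conf.level confidence level for the limits (default 0.95).
#' @return A data frame of class `km_curve` with columns `condition`,
#'   `time`, `n_risk`, `n_event`, `n_censor`, `S`, `var_S`, `ci_lo`, `ci_hi`.
#' @examples
#' km <- km_fit(add_dropout_idx(demo_like()))
#' head(km)
#' @export
km_fit <- function(x, conf.level = 0.95) {
  rec <- as_surv_records(x)
  if (all(rec$event == 0)) {
    warning("all records censored: retention is flat at 1", call. = FALSE)
  }
  out <- do.call(rbind, lapply(sort(unique(rec$condition)), function(cc) {
    r <- rec[rec$condition == cc, , drop = FALSE]
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = r,
                             conf.type = "log", conf.int = conf.level)
    s <- summary(fit, censored = TRUE)
    data.frame(
      condition = cc,
      time = s$time,
      n_risk = s$n.risk,
      n_event = s$n.event,
      n_censor = s$n.censor,
      S = s$surv,
      var_S = s$std.err^2,  # summary() reports the SE of S itself
      ci_lo = pmin(pmax(ifelse(is.na(s$lower), 0, s$lower), 0), 1),
      ci_hi = pmin(pmax(ifelse(is.na(s$upper), 1, s$upper), 0), 1),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  structure(out, conf.level = conf.level,
            class = c("km_curve", "data.frame"))
}

#' Write Kaplan-Meier curves as CSV
#'
#' @param km a `km_curve` from [km_fit()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_km <- function(km, path) {
  stopifnot(inherits(km, "km_curve"))
  utils::write.csv(as.data.frame(km), path, row.names = FALSE)
  invisible(path)
}

#' G-rho family (weighted log-rank) test of retention differences
#'
#' Tests whether the dropout processes differ between conditions using the
#' Fleming-Harrington G-rho family: each distinct event time contributes its
#' observed-minus-expected events per group, weighted by
#' `S_pooled(t-)^rho`, the left-continuous Kaplan-Meier estimate of the
#' pooled sample. `rho = 0` (default) is the standard log-rank test, equally
#' sensitive across the study; `rho = 1` is a Peto-Peto-type test that
#' up-weights early dropout. The statistic is the quadratic form of the
#' weighted (O - E) vector with the hypergeometric covariance, with
#' `groups - 1` degrees of freedom.
#'
#' @param x an `indexed_table` or a data frame of survival records.
#' @param rho non-negative weighting exponent.
#' @return A list of class `grho_result`: `rho`, `statistic`, `df`,
#'   `p.value`, and per-group `n`, `observed`, `expected`.
#' @examples
#' grho_test(add_dropout_idx(demo_like()), rho = 0)
#' @export
grho_test <- function(x, rho = 0) {
  rec <- as_surv_records(x)
  if (length(rho) != 1 || is.na(rho) || rho < 0) {
    stop("rho must be a single non-negative number", call. = FALSE)
  }
  grp <- factor(rec$condition)
  levs <- levels(grp)
  if (length(levs) < 2) stop("need at least 2 conditions", call. = FALSE)
  if (sum(rec$event) == 0) {
    stop("no dropout events to compare", call. = FALSE)
  }

  times <- sort(unique(rec$time[rec$event == 1]))
  g <- length(levs)
  U <- numeric(g)
  V <- matrix(0, g, g)
  observed <- expected <- numeric(g)
  S_pooled <- 1
  for (tt in times) {
    at_risk <- rec$time >= tt
    n <- sum(at_risk)
    d <- sum(rec$time == tt & rec$event == 1)
    n_g <- vapply(levs, function(l) sum(at_risk & grp == l), numeric(1))
    d_g <- vapply(levs, function(l)
      sum(rec$time == tt & rec$event == 1 & grp == l), numeric(1))
    w <- S_pooled^rho
    e_g <- d * n_g / n
    U <- U + w * (d_g - e_g)
    observed <- observed + d_g
    expected <- expected + e_g
    if (n > 1) {
      p <- n_g / n
      V <- V + w^2 * d * (n - d) / (n - 1) * (diag(p) - tcrossprod(p))
    }
    S_pooled <- S_pooled * (1 - d / n)
  }
  # drop one group: V is singular by construction (rows sum to 0)
  keep <- seq_len(g - 1)
  Vk <- V[keep, keep, drop = FALSE]
  stat <- tryCatch(
    drop(t(U[keep]) %*% solve(Vk, U[keep])),
    error = function(e) {
      # collapse to generalized inverse if a group contributed no variance
      drop(t(U[keep]) %*% ginv_svd(Vk) %*% U[keep])
    }
  )
  df <- g - 1L
  structure(
    list(rho = rho, statistic = stat, df = df,
         p.value = stats::pchisq(stat, df, lower.tail = FALSE),
         n = as.integer(table(grp)), conditions = levs,
         observed = stats::setNames(observed, levs),
         expected = stats::setNames(expected, levs)),
    class = "grho_result"
  )
}

# Moore-Penrose inverse via SVD, for the degenerate case where a group
# contributes no variance and the drop-one covariance block is singular.
ginv_svd <- function(m, tol = sqrt(.Machine$double.eps)) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.grho_result <- function(x, ...) {
  cat(sprintf("G-rho family test of retention differences (rho = %g)\n",
              x$rho))
  tab <- data.frame(N = x$n, Observed = round(x$observed, 2),
                    Expected = round(x$expected, 2))
  rownames(tab) <- x$conditions
  print(tab)
  cat(sprintf("\nchi-squared = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}

#' Plain-text statistical copy for a G-rho test
#'
#' @param x a `grho_result`.
#' @return A character scalar suitable for a results section.
#' @export
grho_copy <- function(x) {
  stopifnot(inherits(x, "grho_result"))
  lab <- if (x$rho == 0) "log-rank" else sprintf("G-rho (rho = %g)", x$rho)
  sprintf("%s chi-squared(%d, N = %d) = %.3f, p = %.4g",
          lab, x$df, sum(x$n), x$statistic, x$p.value)
}
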