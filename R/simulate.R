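#' Design for a simulated dropout study
#'
#' Describes a discrete-time dropout process: after answering item `j`
#' (`j = 1 .. K-1`), a still-active participant in condition `c` drops out
#' with hazard `hazard[[c]][j]`; otherwise they answer item `j + 1`.
#' Everyone answers the first item, matching the convention that retention
#' at the first selected item is the 100% baseline. Answered items may
#' additionally be blanked *intermittently* with probability `skip_prob` —
#' except the final answered item, so the intended dropout index is
#' preserved exactly and simulated ground truth stays checkable.
#'
#' @param n_per_condition named integer vector: participants per condition
#'   label.
#' @param n_items number of items `K`.
#' @param hazard either a single numeric vector of length `K - 1` (shared by
#'   all conditions) or a named list of such vectors, one per condition;
#'   values in [0, 1].
#' @param skip_prob probability in [0, 1) that an answered, non-final item
#'   is left blank.
#' @param seed integer seed making [simulate_responses()] deterministic.
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(n_per_condition, n_items, hazard,
                       skip_prob = 0, seed = 1L) {
  if (is.null(names(n_per_condition)) || any(names(n_per_condition) == "")) {
    stop("n_per_condition must be a named vector of condition sizes",
         call. = FALSE)
  }
  if (any(n_per_condition < 1)) {
    stop("every condition needs at least one participant", call. = FALSE)
  }
  stopifnot(n_items >= 2)
  conds <- names(n_per_condition)
  if (!is.list(hazard)) hazard <- stats::setNames(
    rep(list(as.numeric(hazard)), length(conds)), conds)
  if (!all(conds %in% names(hazard))) {
    stop("hazard must be named for every condition", call. = FALSE)
  }
  for (cc in conds) {
    h <- hazard[[cc]]
    if (length(h) != n_items - 1 || any(h < 0 | h > 1)) {
      stop("hazard for condition ", sQuote(cc), " must have length ",
           n_items - 1, " with values in [0, 1]", call. = FALSE)
    }
  }
  if (skip_prob < 0 || skip_prob >= 1) {
    stop("skip_prob must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(n_per_condition = n_per_condition, n_items = as.integer(n_items),
         hazard = hazard[conds], skip_prob = skip_prob,
         seed = as.integer(seed)),
    class = "sim_design"
  )
}

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Simulate a wide-format response table
#'
#' Draws each participant's dropout position from the design's discrete
#' hazard (or completion, with probability `prod(1 - hazard)`), fills the
#' answered cells with integer response tokens, and independently blanks
#' non-final answered cells with the design's `skip_prob` to emulate
#' intermittent item skipping. Deterministic given the design seed.
#'
#' @param design a [sim_design()].
#' @return A `response_table` with columns `condition`, `q1 .. qK`.
#' @examples
#' d <- sim_design(c(a = 20, b = 20), n_items = 10, hazard = rep(0.05, 9),
#'                 seed = 7)
#' rt <- simulate_responses(d)
#' table(add_dropout_idx(rt)$do_idx)
#' @export
simulate_responses <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  K <- design$n_items
  conds <- names(design$n_per_condition)
  with_seed(design$seed, {
    rows <- lapply(conds, function(cc) {
      n <- design$n_per_condition[[cc]]
      h <- design$hazard[[cc]]
      # drop after item j with prob h[j], conditional on surviving past j-1
      u <- matrix(stats::runif(n * (K - 1)), nrow = n)
      drops <- u < matrix(h, nrow = n, ncol = K - 1, byrow = TRUE)
      do_idx <- apply(drops, 1L, function(r) {
        w <- which(r)
        if (length(w)) w[1] else K
      })
      vals <- matrix(NA_character_, nrow = n, ncol = K)
      for (i in seq_len(n)) {
        idx <- seq_len(do_idx[i])
        vals[i, idx] <- as.character(sample.int(5L, do_idx[i],
                                                replace = TRUE))
        if (design$skip_prob > 0 && do_idx[i] > 1) {
          skippable <- idx[-length(idx)]  # never the final answered item
          blank <- skippable[stats::runif(length(skippable)) <
                               design$skip_prob]
          vals[i, blank] <- NA_character_
        }
      }
      cbind(data.frame(condition = rep(cc, n), stringsAsFactors = FALSE),
            as.data.frame(vals, stringsAsFactors = FALSE))
    })
    out <- do.call(rbind, rows)
    items <- paste0("q", seq_len(K))
    names(out) <- c("condition", items)
    rownames(out) <- NULL
    new_response_table(out, condition = "condition", items = items)
  })
}

#' Demo-style response table
#'
#' A fixed-seed synthetic table shaped like a four-arm online experiment:
#' conditions `11`, `12`, `21`, `22` over 52 questions, 180 participants per
#' condition, with distinct hazard profiles per condition (an early-dropout
#' burst over the first items, then condition-specific flat attrition) and
#' occasional intermittent skips. Repeated calls return byte-identical
#' tables.
#'
#' @return A `response_table`.
#' @export
demo_like <- function() {
  K <- 52
  base <- c(rep(0.03, 5), rep(0.008, K - 6))  # early burst, then trickle
  mult <- c("11" = 0.5, "12" = 1, "21" = 1.6, "22" = 2.4)
  hz <- lapply(mult, function(m) pmin(base * m, 1))
  d <- sim_design(
    n_per_condition = c("11" = 180, "12" = 180, "21" = 180, "22" = 180),
    n_items = K, hazard = hz, skip_prob = 0.02, seed = 20260401L
  )
  simulate_responses(d)
}

#' Stress-test response table
#'
#' A fixed-seed table with the shape of a large online experiment: 1000
#' participants, 100 item columns, two conditions (500 each) with mildly
#' different flat hazards.
#'
#' @return A `response_table`.
#' @export
stress_like <- function() {
  K <- 100
  hz <- list(A = rep(0.006, K - 1), B = rep(0.009, K - 1))
  d <- sim_design(n_per_condition = c(A = 500, B = 500), n_items = K,
                  hazard = hz, skip_prob = 0.01, seed = 73L)
  simulate_responses(d)
}
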