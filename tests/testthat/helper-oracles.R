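# Independent brute-force oracles. These deliberately use naive loops and
# textbook formulas, not the package's vectorized code paths.

# Build an indexed_table directly from dropout indices (one item block per
# participant, answered up to do_idx, with optional intermittent holes).
table_from_idx <- function(do_idx, cond, K, intermittent = FALSE) {
  n <- length(do_idx)
  vals <- matrix(NA_character_, n, K)
  for (i in seq_len(n)) {
    if (do_idx[i] >= 1) {
      vals[i, seq_len(do_idx[i])] <- "1"
      if (intermittent && do_idx[i] > 2) {
        hole <- sample(seq_len(do_idx[i] - 1), 1)
        vals[i, hole] <- NA_character_
      }
    }
  }
  df <- cbind(data.frame(condition = cond, stringsAsFactors = FALSE),
              as.data.frame(vals, stringsAsFactors = FALSE))
  items <- paste0("q", seq_len(K))
  names(df) <- c("condition", items)
  rt <- structure(df, condition = "condition", items = items,
                  class = c("response_table", "data.frame"))
  add_dropout_idx(rt)
}

random_indexed_table <- function(n = 30, K = 6, n_cond = 2,
                                 p_zero = 0.05) {
  cond <- sample(LETTERS[seq_len(n_cond)], n, replace = TRUE)
  # ensure each condition occupied
  cond[seq_len(n_cond)] <- LETTERS[seq_len(n_cond)]
  do_idx <- sample(0:K, n, replace = TRUE,
                   prob = c(p_zero, rep((1 - p_zero) / K, K)))
  table_from_idx(do_idx, cond, K, intermittent = TRUE)
}

# Triple loop over (condition, question, participant).
oracle_stats <- function(do_idx, cond, K) {
  groups <- c(list(total = rep(TRUE, length(do_idx))),
              lapply(sort(unique(cond)), function(l) cond == l))
  names(groups) <- c("total", sort(unique(cond)))
  out <- list()
  for (g in names(groups)) {
    d <- do_idx[groups[[g]]]
    N <- length(d)
    for (q in seq_len(K)) {
      cs <- 0
      for (x in d) if (x < q && x < K) cs <- cs + 1
      out[[length(out) + 1]] <- data.frame(
        question = q, condition = g, cs = cs, N = N,
        remaining = N - cs, pct_remaining = 100 * (N - cs) / N)
    }
  }
  do.call(rbind, out)
}

# Direct sum of (O - E)^2 / E.
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Textbook product-limit loop for a single group.
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  S <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    n <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / n)
    S[i] <- s
  }
  data.frame(time = ut, S = S)
}

# Greenwood variance at each event time, same loop style.
oracle_greenwood <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  km <- oracle_km(time, event)
  acc <- 0
  v <- numeric(length(ut))
  for (i in seq_along(ut)) {
    n <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    acc <- acc + d / (n * (n - d))
    v[i] <- km$S[i]^2 * acc
  }
  v
}

# Two-group weighted log-rank via explicit per-time hypergeometric sums,
# variance written in the 2x2 form d*nA*nB*(n-d) / (n^2*(n-1)).
oracle_grho_2g <- function(time, event, grp, rho = 0) {
  levs <- sort(unique(grp))
  stopifnot(length(levs) == 2)
  ut <- sort(unique(time[event == 1]))
  U <- 0; V <- 0; S <- 1
  for (tt in ut) {
    w <- S^rho
    n <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    nA <- sum(time >= tt & grp == levs[1])
    dA <- sum(time == tt & event == 1 & grp == levs[1])
    U <- U + w * (dA - d * nA / n)
    if (n > 1) V <- V + w^2 * d * nA * (n - nA) * (n - d) / (n^2 * (n - 1))
    S <- S * (1 - d / n)
  }
  U^2 / V
}

# Max ECDF gap by explicit counting over the pooled support.
oracle_ks_D <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  D <- 0
  for (g in grid) {
    D <- max(D, abs(mean(x <= g) - mean(y <= g)))
  }
  D
}
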