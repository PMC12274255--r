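test_that("to_surv codes completers as censored and shifts zero indices", {
  suppressMessages(
    it <- table_from_idx(c(3, 2, 0), c("A", "A", "A"), K = 3)
  )
  rec <- to_surv(it)
  expect_equal(rec$time, c(3, 2, 0.5))
  expect_equal(rec$event, c(0L, 1L, 1L))
})

test_that("km_fit reproduces the hand product-limit computation", {
  it <- table_from_idx(c(1, 2, 2, 3, 3), rep("A", 5), K = 3)
  km <- km_fit(it)
  s_at <- function(t) km$S[km$time == t]
  expect_equal(s_at(1), 0.8)
  expect_equal(s_at(2), 0.4)
  expect_equal(s_at(3), 0.4)  # completers censored at K
  expect_equal(km$n_censor[km$time == 3], 2)
})

test_that("km_fit edge cases: no events, instant total dropout", {
  it <- table_from_idx(c(3, 3, 3), rep("A", 3), K = 3)
  expect_warning(km <- km_fit(it), "censored")
  expect_true(all(km$S == 1))

  all1 <- table_from_idx(c(1, 1, 1, 1), rep("A", 4), K = 3)
  km1 <- km_fit(all1)
  expect_equal(km1$S[km1$time == 1], 0)
})

test_that("km_fit matches loop oracles for S and Greenwood variance", {
  set.seed(31)
  for (i in 1:30) {
    suppressMessages(it <- random_indexed_table(n = 40, K = 6, n_cond = 1))
    rec <- to_surv(it)
    km <- km_fit(it)
    ev <- km[km$n_event > 0, ]
    orc <- oracle_km(rec$time, rec$event)
    expect_equal(ev$S, orc$S, tolerance = 1e-12)
    expect_equal(ev$var_S, oracle_greenwood(rec$time, rec$event),
                 tolerance = 1e-10)
    expect_true(all(km$var_S >= 0))
    expect_true(all(km$ci_lo >= 0 & km$ci_hi <= 1 & km$ci_lo <= km$ci_hi))
    expect_true(all(diff(km$S) <= 1e-12))
  }
})

test_that("retention S(q-1) equals the share with do_idx >= q", {
  set.seed(13)
  for (i in 1:20) {
    it <- table_from_idx(sample(1:5, 30, replace = TRUE),
                         rep("A", 30), K = 5)
    km <- km_fit(it)
    N <- nrow(it)
    for (q in 2:5) {
      s_prev <- km$S[km$time == q - 1]
      if (length(s_prev)) {
        expect_equal(s_prev, sum(it$do_idx >= q) / N, tolerance = 1e-12)
      }
    }
  }
})

test_that("grho_test reproduces the hand log-rank case", {
  it <- table_from_idx(c(1, 1, 2, 2, 3, 3),
                       c("A", "A", "A", "B", "B", "B"), K = 3)
  res <- grho_test(it, rho = 0)
  expect_equal(res$statistic, 3.462, tolerance = 1e-3)
  expect_identical(res$df, 1L)
  expect_equal(unname(res$observed["A"]), 3)
  expect_equal(unname(res$expected["A"]), 1.5)
})

test_that("grho_test degenerate inputs", {
  same <- table_from_idx(c(1, 2, 3, 1, 2, 3),
                         c("A", "A", "A", "B", "B", "B"), K = 3)
  expect_equal(grho_test(same)$statistic, 0, tolerance = 1e-12)

  none <- table_from_idx(c(3, 3, 3, 3), c("A", "A", "B", "B"), K = 3)
  expect_error(grho_test(none), "no dropout events")
  expect_error(grho_test(same, rho = -1), "non-negative")
})

test_that("grho matches the brute-force hypergeometric oracle and survdiff", {
  set.seed(21)
  for (i in 1:100) {
    suppressMessages(it <- random_indexed_table(n = 30, K = 5, n_cond = 2))
    rec <- to_surv(it)
    if (sum(rec$event) == 0) next
    for (rho in c(0, 1)) {
      mine <- grho_test(it, rho = rho)$statistic
      expect_equal(mine, oracle_grho_2g(rec$time, rec$event, rec$condition,
                                        rho = rho),
                   tolerance = 1e-9)
      sd <- survival::survdiff(
        survival::Surv(time, event) ~ condition, data = rec, rho = rho)
      expect_equal(mine, unname(sd$chisq), tolerance = 1e-9)
    }
  }
})

test_that("multi-group grho agrees with survdiff", {
  set.seed(8)
  for (i in 1:20) {
    suppressMessages(it <- random_indexed_table(n = 60, K = 6, n_cond = 4))
    rec <- to_surv(it)
    if (sum(rec$event) == 0) next
    res <- grho_test(it, rho = 0)
    sd <- survival::survdiff(survival::Surv(time, event) ~ condition,
                             data = rec, rho = 0)
    expect_equal(res$statistic, unname(sd$chisq), tolerance = 1e-9)
    expect_identical(res$df, 3L)
  }
})

test_that("one common event time reduces the log-rank to the 2x2 chi-square", {
  set.seed(55)
  for (i in 1:20) {
    nA <- sample(5:15, 1); nB <- sample(5:15, 1)
    dA <- sample(1:(nA - 1), 1); dB <- sample(1:(nB - 1), 1)
    K <- 4
    it <- table_from_idx(
      c(rep(2, dA), rep(K, nA - dA), rep(2, dB), rep(K, nB - dB)),
      c(rep("A", nA), rep("B", nB)), K = K)
    tab <- cbind(dropped = c(dA, dB), remaining = c(nA - dA, nB - dB))
    rownames(tab) <- c("A", "B")
    # z^2 form without the finite-population (n-1) factor
    chi <- chisq_dropout(tab)$statistic
    lr <- grho_test(it, rho = 0)$statistic
    n <- nA + nB
    expect_equal(lr * n / (n - 1), chi, tolerance = 1e-9)
  }
})

test_that("permutation null of the log-rank covers the analytic p-value", {
  set.seed(2024)
  it <- table_from_idx(sample(1:8, 80, replace = TRUE),
                       rep(c("A", "B"), 40), K = 8)
  obs <- grho_test(it)$statistic
  p_analytic <- grho_test(it)$p.value
  B <- 1000
  rec <- to_surv(it)
  stats_perm <- replicate(B, {
    rec$condition <- sample(rec$condition)
    grho_test(rec)$statistic
  })
  p_emp <- mean(stats_perm >= obs)
  se <- sqrt(p_emp * (1 - p_emp) / B)
  expect_lt(abs(p_emp - p_analytic), 3 * se + 0.02)
})
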