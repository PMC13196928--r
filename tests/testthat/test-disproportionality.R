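# independent scalar formulas, coded separately from the vectorized implementation
oracle_ror <- function(a, b, c, d, z = 1.96) {
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(est, exp(log(est) - z * se), exp(log(est) + z * se))
}
oracle_prr <- function(a, b, c, d, z = 1.96) {
  est <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  c(est, exp(log(est) - z * se), exp(log(est) + z * se))
}

test_that("contingency cells enumerate cases and partition the case set", {
  cases <- make_cases(
    drug_sets = list("D", "D", character(), character()),
    reac_sets = list("E", character(), "E", character())
  )
  t1 <- build_contingency(cases, "D", "E")
  expect_equal(unlist(t1[c("a", "b", "c", "d")], use.names = FALSE),
               c(1L, 1L, 1L, 1L))

  # repeated mentions contribute once; cells always sum to N
  cases2 <- make_cases(
    drug_sets = list(c("D", "D"), "X", "D"),
    reac_sets = list(c("E"), "E", character())
  )
  t2 <- build_contingency(cases2, "D", "E")
  expect_equal(t2$a, 1L)
  expect_equal(t2$a + t2$b + t2$c + t2$d, nrow(cases2))
})

test_that("ROR and PRR reproduce hand-derived values", {
  r <- ror_estimate(10, 90, 100, 9900)
  expect_equal(c(r$ror, r$ror_low, r$ror_high), oracle_ror(10, 90, 100, 9900),
               tolerance = 1e-12)
  expect_equal(r$ror, 11)
  expect_equal(round(r$ror_low, 2), 5.56)
  expect_equal(round(r$ror_high, 2), 21.76)
  expect_false(r$corrected)

  p <- prr_estimate(10, 90, 100, 9900)
  expect_equal(p$prr, 10)

  sym <- ror_estimate(5, 5, 5, 5)
  expect_equal(sym$ror, 1)
  expect_lt(sym$ror_low, 1)
  expect_gt(sym$ror_high, 1)
  expect_equal(prr_estimate(5, 5, 5, 5)$prr, 1)
})

test_that("doubling all cells keeps the estimate and narrows the CI", {
  r1 <- ror_estimate(10, 90, 100, 9900)
  r2 <- ror_estimate(20, 180, 200, 19800)
  expect_equal(r1$ror, r2$ror)
  expect_lt(r1$ror_low, r2$ror_low)
  expect_gt(r1$ror_high, r2$ror_high)
})

test_that("estimates match the oracle on the exhaustive small-cell grid", {
  grid <- expand.grid(a = 1:6, b = 1:6, c = 1:6, d = 1:6)
  r <- ror_estimate(grid$a, grid$b, grid$c, grid$d)
  p <- prr_estimate(grid$a, grid$b, grid$c, grid$d)
  for (i in seq_len(nrow(grid))) {
    o <- oracle_ror(grid$a[i], grid$b[i], grid$c[i], grid$d[i])
    expect_equal(c(r$ror[i], r$ror_low[i], r$ror_high[i]), o, tolerance = 1e-12)
    op <- oracle_prr(grid$a[i], grid$b[i], grid$c[i], grid$d[i])
    expect_equal(c(p$prr[i], p$prr_low[i], p$prr_high[i]), op, tolerance = 1e-12)
  }
})

test_that("chi-squared with Yates correction agrees with chisq.test", {
  expect_equal(chi2_yates(50, 50, 50, 50), 0)
  set.seed(7)
  for (i in 1:60) {
    cells <- sample.int(400, 4)
    ours <- chi2_yates(cells[1], cells[2], cells[3], cells[4])
    ref <- suppressWarnings(
      stats::chisq.test(matrix(cells, 2, byrow = TRUE), correct = TRUE)
    )$statistic
    expect_equal(ours, unname(ref), tolerance = 1e-12)
    # invariance under transposition (swap rows with columns)
    expect_equal(chi2_yates(cells[1], cells[3], cells[2], cells[4]), ours)
  }
  expect_gt(chi2_yates(20, 80, 100, 9800), 100)
  expect_error(chi2_yates(0, 0, 5, 5), class = "pvsignal_estimate_error")
})

test_that("ROR and PRR are concordant and |log ROR| >= |log PRR|", {
  set.seed(11)
  for (i in 1:200) {
    cells <- sample.int(500, 4, replace = TRUE)
    r <- ror_estimate(cells[1], cells[2], cells[3], cells[4])$ror
    p <- prr_estimate(cells[1], cells[2], cells[3], cells[4])$prr
    expect_equal(sign(r - 1), sign(p - 1), tolerance = 1e-12)
    expect_gte(abs(log(r)) - abs(log(p)), -1e-12)
    # algebraic identity ror/prr = (1 + a/b) / (1 + c/d)
    expect_equal(r / p,
                 (1 + cells[1] / cells[2]) / (1 + cells[3] / cells[4]),
                 tolerance = 1e-12)
  }
})

test_that("increasing a (holding b, c, d) strictly increases ROR and PRR", {
  a <- 1:30
  r <- ror_estimate(a, 50, 40, 900)$ror
  p <- prr_estimate(a, 50, 40, 900)$prr
  expect_true(all(diff(r) > 0))
  expect_true(all(diff(p) > 0))
})

test_that("zero cells get the Haldane-Anscombe correction only when needed", {
  r <- ror_estimate(0, 10, 10, 100)
  expect_true(r$corrected)
  expect_true(is.finite(r$ror) && r$ror > 0)
  expect_false(ror_estimate(1, 10, 10, 100)$corrected)
  expect_error(ror_estimate(0, 10, 10, 100, correction = FALSE),
               class = "pvsignal_estimate_error")
})

test_that("signal flags implement the ROR and PRR criteria", {
  stats <- tibble::tibble(
    a = c(1465, 100, 100, 2),
    ror_low = c(7.92, 0.94, 1.17, 9),
    prr = c(8.8, 1.1, 2.5, 9),
    chi2 = c(500, 1, 10, 9)
  )
  expect_equal(flag_signal(stats), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(flag_signal(stats, signal_criteria("prr")),
               c(TRUE, FALSE, TRUE, FALSE))
  # rows without a count (published interval fixtures) use the CI rule alone
  expect_true(flag_signal(tibble::tibble(a = NA, ror_low = 1.2)))
})

test_that("the Woolf 95% CI covers a known odds ratio at its nominal rate", {
  set.seed(2024)
  rho <- 3
  p0 <- 0.05
  p1 <- plogis(log(p0 / (1 - p0)) + log(rho))
  n1 <- 500; n0 <- 5000
  reps <- 10000
  a <- rbinom(reps, n1, p1); b <- n1 - a
  c <- rbinom(reps, n0, p0); d <- n0 - c
  ci <- ror_estimate(a, b, c, d)
  coverage <- mean(ci$ror_low <= rho & rho <= ci$ror_high)
  expect_gt(coverage, 0.93)
  expect_lt(coverage, 0.97)
})

test_that("compute_signals matches per-pair contingency construction", {
  set.seed(5)
  all_drugs <- paste0("D", 1:4)
  all_events <- paste0("E", 1:3)
  drug_sets <- replicate(60, sample(all_drugs, sample.int(3, 1)), simplify = FALSE)
  reac_sets <- replicate(60, sample(all_events, sample.int(2, 1)), simplify = FALSE)
  cases <- make_cases(drug_sets, reac_sets)
  sig <- compute_signals(cases, drugs = all_drugs, events = all_events)
  expect_equal(nrow(sig), 12L)
  expect_true(all(sig$a + sig$b + sig$c + sig$d == nrow(cases)))
  for (i in sample.int(nrow(sig), 5)) {
    ct <- build_contingency(cases, sig$drug[i], sig$event[i])
    expect_equal(sig$a[i], ct$a)
    expect_equal(sig$b[i], ct$b)
    expect_equal(sig$c[i], ct$c)
    expect_equal(sig$d[i], ct$d)
  }
})

test_that("a panel drug absent from the data yields degenerate flagged stats", {
  cases <- make_cases(list("D"), list("E"))
  sig <- compute_signals(cases, drugs = c("D", "GHOSTINIB"), events = "E")
  ghost <- sig[sig$drug == "GHOSTINIB", ]
  expect_equal(ghost$a + ghost$b, 0L)
  expect_true(ghost$corrected)
  expect_false(ghost$signal)
})
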