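test_that("paired t statistic matches the closed form", {
  # paired differences 0.40, 0.50, 0.30, 0.45, 0.35:
  # mean 0.40, sd 0.0790569, t = 0.40 / (0.0790569/sqrt(5)) = 11.3137
  d <- c(0.40, 0.50, 0.30, 0.45, 0.35)
  normal <- c(0.10, 0.12, 0.20, 0.15, 0.25)
  beta <- rbind(cg1 = c(normal, normal + d))
  colnames(beta) <- toy_sheet(5)$sample_id
  res <- test_probes(beta, toy_sheet(5))
  expect_equal(res$statistic, 11.3137, tolerance = 1e-4)
  expect_equal(res$delta_beta, 0.40)
  expect_equal(res$p, 2 * pt(-11.3137, df = 4), tolerance = 1e-4)
})

test_that("probe tests agree with stats::t.test probe by probe", {
  set.seed(21)
  n <- 4
  beta <- matrix(runif(12 * 2 * n, 0.05, 0.95), nrow = 12,
                 dimnames = list(sprintf("cg%02d", 1:12),
                                 toy_sheet(n)$sample_id))
  sheet <- toy_sheet(n)
  for (method in c("paired", "welch")) {
    res <- test_probes(beta, sheet, method = method)
    for (i in 1:12) {
      ref <- t.test(beta[i, (n + 1):(2 * n)], beta[i, 1:n],
                    paired = method == "paired")
      expect_equal(res$statistic[i], unname(ref$statistic),
                   tolerance = 1e-12)
      expect_equal(res$p[i], ref$p.value, tolerance = 1e-12)
    }
  }
  # M-value scale still reports means and deltas on the beta scale
  resm <- test_probes(beta, sheet, scale = "mvalue")
  expected_delta <- rowMeans(beta[, (n + 1):(2 * n)]) - rowMeans(beta[, 1:n])
  expect_equal(resm$delta_beta, unname(expected_delta))
})

test_that("degenerate probes are handled per policy", {
  sheet <- toy_sheet(3)
  base <- c(0.25, 0.5, 0.75)
  beta <- rbind(flat = c(base, base),             # tumor == normal
                shift = c(base, base + 0.125))    # exactly constant shift
  colnames(beta) <- sheet$sample_id
  res <- suppressMessages(test_probes(beta, sheet))
  expect_equal(res$statistic[res$probe_id == "flat"], 0)
  expect_equal(res$delta_beta[res$probe_id == "flat"], 0)
  expect_equal(res$p[res$probe_id == "flat"], 1)
  expect_true(is.infinite(res$statistic[res$probe_id == "shift"]))
  expect_gt(res$p[res$probe_id == "shift"], 0)
  expect_lt(res$p[res$probe_id == "shift"], 1e-100)
})

test_that("probes with missing values are excluded with a message", {
  sheet <- toy_sheet(3)
  beta <- matrix(runif(18), nrow = 3,
                 dimnames = list(c("cg1", "cg2", "cg3"), sheet$sample_id))
  beta["cg2", "T01"] <- NA
  expect_message(res <- test_probes(beta, sheet), "1 probe")
  expect_identical(res$probe_id, c("cg1", "cg3"))
})

test_that("fewer than two complete pairs is rejected", {
  sheet <- toy_sheet(2)[c(1, 3), ]
  beta <- matrix(runif(4), nrow = 2,
                 dimnames = list(c("cg1", "cg2"),
                                 c("N01", "T01")))
  expect_error(test_probes(beta, sheet), "pair")
})

test_that("BH adjustment matches worked example and brute-force oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(adjust_bh(0.5), 0.5)
  expect_error(adjust_bh(c(0.1, 1.2)), "outside")
  set.seed(31)
  for (i in 1:200) {
    p <- round(runif(sample(1:8, 1)), 3)
    expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
  }
  # exhaustive over permutations of a tied p-list
  base <- c(0.01, 0.01, 0.2, 0.04, 0.9)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  for (p in perms(base)) expect_equal(adjust_bh(p), bh_oracle(p))
})

test_that("row z-scores normalize and handle degenerate rows", {
  expect_equal(unname(zscore_rows(rbind(c(0.1, 0.2, 0.3)))[1, ]),
               c(-1, 0, 1))
  expect_message(z <- zscore_rows(rbind(a = c(0.5, 0.5, 0.5),
                                        b = c(0.2, 0.8, 0.5))),
                 "constant")
  expect_equal(unname(z["a", ]), c(0, 0, 0))
  expect_error(zscore_rows(matrix(0.5, nrow = 2, ncol = 1)), "2 samples")
  set.seed(5)
  m <- matrix(runif(50), nrow = 5)
  z <- zscore_rows(m)
  expect_equal(rowMeans(z), rep(0, 5), tolerance = 1e-9)
  expect_equal(apply(z, 1, sd), rep(1, 5), tolerance = 1e-9)
})

test_that("significance filter applies the q threshold", {
  res <- toy_results(c("a", "b", "c"), 0.2, q = c(0.005, 0.02, 0.009))
  kept <- suppressMessages(filter_significant(res, alpha = 0.01))
  expect_identical(kept$probe_id, c("a", "c"))
  expect_true(all(kept$significant))
  all_kept <- suppressMessages(filter_significant(res, alpha = 1))
  expect_equal(nrow(all_kept), 3)
})

test_that("planted island effect is fully recovered on a small cohort", {
  # programmed +0.45 effect, precision 100, 5 pairs, small background
  co <- small_cohort(seed = 1, n_background = 10, noise_precision = 100)
  res <- test_probes(co$beta, co$sheet)
  b_probes <- co$manifest$probe_id[co$manifest$gene == "CLDN10B-like"]
  expect_true(all(res$q[res$probe_id %in% b_probes] < 0.01))
  # independent re-implementation: per-probe t.test + stats::p.adjust
  pref <- vapply(seq_len(nrow(co$beta)), function(i)
    t.test(co$beta[i, 6:10], co$beta[i, 1:5], paired = TRUE)$p.value,
    numeric(1))
  qref <- p.adjust(pref, "BH")
  expect_equal(res$q, qref, tolerance = 1e-10)
})
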