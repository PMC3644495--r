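test_that("percentage change normalisation follows the control baseline", {
  expect_equal(pct_change(10, 15), 50)
  expect_equal(pct_change(7, 7), 0)
  expect_true(is.na(pct_change(0, 5)))
  expect_equal(pct_change(c(10, 0, 20), c(5, 5, 30)), c(-50, NA, 50))
  # swapping drug/control flips the sign of the change direction
  for (s in 1:20) {
    set.seed(s)
    a <- runif(1, 1, 10); b <- runif(1, 1, 10)
    expect_equal(sign(pct_change(a, b)), -sign(pct_change(b, a)))
  }
})

test_that("histogram change applies the per-bin contract", {
  h <- function(counts) data.frame(bin_start = seq_along(counts) - 1,
                                   bin_end = seq_along(counts),
                                   count = counts)
  out <- histogram_change(h(c(10, 20)), h(c(5, 30)))
  expect_equal(out$pct_change, c(-50, 50))
  expect_equal(histogram_change(h(c(3, 3)), h(c(3, 3)))$pct_change, c(0, 0))
  expect_true(is.na(histogram_change(h(c(0, 1)), h(c(4, 1)))$pct_change[1]))
  expect_error(histogram_change(h(c(1, 2)), h(c(1, 2, 3))), "edges")
})

test_that("signed-rank worked case: n = 6 all-positive differences", {
  t <- wilcoxon_signed_rank(rep(0, 6), 1:6)
  expect_equal(t$p_value, 2 / 64)
  expect_equal(t$statistic, 21)
  expect_equal(t$alpha, 0.0125)        # 0.05 / 4
  expect_false(t$significant)          # 0.03125 > 0.0125
  expect_identical(t$method, "exact")
})

test_that("signed-rank p equals exhaustive sign enumeration for n <= 12", {
  for (s in 1:40) {
    set.seed(100 + s)
    n <- sample(3:12, 1)
    d <- round(rnorm(n, sample(c(-1, 0.2, 1), 1), 1), 2)
    d[d == 0] <- 0.11
    t <- wilcoxon_signed_rank(rep(0, n), d)
    expect_equal(t$p_value, oracle_signed_rank_p(d),
                 info = paste("seed", s))
  }
})

test_that("signed-rank agrees with wilcox.test where both are exact", {
  for (s in 1:20) {
    set.seed(200 + s)
    n <- sample(6:15, 1)
    a <- rnorm(n); b <- a + rnorm(n, 0.3)
    if (anyDuplicated(abs(b - a)) || any(b == a)) next
    expect_equal(wilcoxon_signed_rank(a, b)$p_value,
                 stats::wilcox.test(b, a, paired = TRUE,
                                    exact = TRUE)$p.value)
  }
  # large-n path against the normal approximation in wilcox.test
  set.seed(5)
  a <- rnorm(40); b <- a + rnorm(40, 0.2)
  expect_equal(wilcoxon_signed_rank(a, b)$p_value,
               stats::wilcox.test(b, a, paired = TRUE, exact = FALSE,
                                  correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("degenerate and zero-difference handling", {
  t <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_true(t$degenerate)
  expect_equal(t$p_value, 1)
  expect_false(t$significant)
  # zeros are dropped before ranking
  t2 <- wilcoxon_signed_rank(c(0, 0, 0, 0, 0, 0, 0), c(0, 1, 2, 3, 4, 5, 6))
  expect_equal(t2$n, 6L)
  expect_equal(t2$p_value, 2 / 64)
})

test_that("profile ANOVA recovers hand-computed sums of squares", {
  # 2 conditions x 2 bins x 2 cultures, values chosen for exact arithmetic:
  # control: bin1 (1, 3), bin2 (5, 7); drug: bin1 (2, 4), bin2 (10, 12)
  pc <- list(fake_profile(c(0, 1), c(1, 5)), fake_profile(c(0, 1), c(3, 7)))
  pd <- list(fake_profile(c(0, 1), c(2, 10)), fake_profile(c(0, 1), c(4, 12)))
  out <- profile_anova(pc, pd)
  # hand-worked: grand mean 5.5; condition means 4 and 7 -> SS_cond = 18;
  # bin means 2.5 and 8.5 -> SS_bin = 72; cell deviations from additivity
  # all +/-1 -> SS_int = 8; within-cell SS = 2 per cell -> SS_err = 8 on
  # 4 df
  f <- function(term) out$F[out$term == term]
  expect_equal(f("condition"), (18 / 1) / (8 / 4))
  expect_equal(f("bin"), (72 / 1) / (8 / 4))
  expect_equal(f("condition:bin"), (8 / 1) / (8 / 4))
  expect_equal(out$df, c(1, 1, 1))
})

test_that("profile ANOVA flags an additive condition offset, not interaction", {
  set.seed(7)
  offs <- 0:9
  base <- sin(offs / 3) + 2
  pc <- lapply(1:4, function(i) fake_profile(offs, base + rnorm(10, 0, 0.05)))
  pd <- lapply(1:4, function(i) fake_profile(offs, base + 1 + rnorm(10, 0, 0.05)))
  out <- profile_anova(pc, pd)
  expect_true(out$significant[out$term == "condition"])
  expect_false(out$significant[out$term == "condition:bin"])
  # identical groups: condition effect vanishes
  out0 <- profile_anova(pc, pc)
  expect_gt(out0$p[out0$term == "condition"], 0.9)
})

test_that("profile ANOVA validates its inputs", {
  p <- fake_profile(0:3, 1:4)
  expect_error(profile_anova(list(p), list(p, p)), ">= 2 cultures")
  expect_error(profile_anova(list(p, p),
                             list(fake_profile(0:4, 1:5),
                                  fake_profile(0:4, 1:5))),
               "binned differently")
})

test_that("compare_conditions calls directions per measure", {
  mk <- function(id, ibi) fake_measure_set(id, c(ibi = ibi, sib = 60,
                                                 g_spikes = 140))
  control <- lapply(1:6, function(i) mk(paste0("c", i), 5 + i / 10))
  # IBI x1.5 in drug, others identical
  drug <- lapply(1:6, function(i) fake_measure_set(
    paste0("c", i), c(ibi = (5 + i / 10) * 1.5, sib = 60, g_spikes = 140)))
  cmp <- compare_conditions(control, drug,
                            measures = c("ibi", "sib", "g_spikes"))
  tab <- cmp$table
  expect_equal(tab$direction[tab$measure == "ibi"], "increase")
  expect_equal(tab$direction[tab$measure == "sib"], "none")
  expect_equal(tab$direction[tab$measure == "g_spikes"], "none")
  expect_equal(tab$median_pct_change[tab$measure == "ibi"], 50)
  expect_equal(tab$alpha, rep(0.0125, 3))
  # n = 6 can never clear the family-wise threshold exactly
  expect_false(any(tab$significant))

  # identical conditions: everything "none"
  cmp0 <- compare_conditions(control, control,
                             measures = c("ibi", "sib", "g_spikes"))
  expect_true(all(cmp0$table$direction == "none"))
})

test_that("compare_conditions rejects unpaired cultures", {
  a <- list(fake_measure_set("c1", c(ibi = 5)),
            fake_measure_set("c2", c(ibi = 5)))
  b <- list(fake_measure_set("c1", c(ibi = 5)),
            fake_measure_set("c3", c(ibi = 5)))
  expect_error(compare_conditions(a, b, measures = "ibi"), "c2")
})

test_that("null data keeps the family-wise false-positive rate at bay", {
  # 500 label-shuffled null experiments on measure-set level data
  set.seed(31)
  n_rep <- 500
  sig <- 0L; dir_calls <- 0L
  for (r in seq_len(n_rep)) {
    vals <- matrix(rlnorm(12, 1, 0.3), ncol = 2)
    control <- lapply(1:6, function(i)
      fake_measure_set(paste0("c", i), c(m = vals[i, 1])))
    drug <- lapply(1:6, function(i)
      fake_measure_set(paste0("c", i), c(m = vals[i, 2])))
    tab <- compare_conditions(control, drug, measures = "m")$table
    sig <- sig + tab$significant
    dir_calls <- dir_calls + (tab$direction != "none")
  }
  # family-wise calls: rate must not exceed alpha (+3 binomial SD)
  expect_lte(sig / n_rep, 0.0125 + 3 * sqrt(0.0125 * 0.9875 / n_rep))
  # marker-level calls happen at the exact null rate 2/64
  expect_lt(abs(dir_calls / n_rep - 2 / 64),
            3 * sqrt((2 / 64) * (62 / 64) / n_rep) + 1e-9)
})

test_that("paired t-test wraps the standard paired comparison", {
  set.seed(3)
  a <- rnorm(8); b <- a + 1 + rnorm(8, 0, 0.1)
  out <- paired_t_test(a, b)
  ref <- t.test(b, a, paired = TRUE)
  expect_equal(out$p_value, ref$p.value)
  expect_true(out$significant)
  expect_equal(out$mean_difference, unname(ref$estimate))
})
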