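test_that("jaccard counts intersection over union on aligned lists", {
  universe <- paste0("v", 1:6)
  x <- universe %in% c("v1", "v2", "v3")
  y <- universe %in% c("v2", "v3", "v4")
  expect_equal(jaccard(x, y), 0.5)
  expect_equal(jaccard(x, x), 1)
  expect_equal(jaccard(x, universe %in% c("v4", "v5")), 0)
  expect_warning(j <- jaccard(logical(6), logical(6)), "empty")
  expect_equal(j, 1)
  expect_error(jaccard(c(TRUE, FALSE), TRUE), "length")
})

test_that("exact JTC p equals exhaustive enumeration on the worked example", {
  # universe 6, lists of 3 and 3, intersection 2: 380/400 placements give
  # J <= 2/4 (frozen from the enumeration oracle)
  x <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  y <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  res <- jtc_pvalue(x, y, method = "exact")
  expect_equal(res$jaccard, 0.5)
  expect_equal(res$p_value, 0.95)
  expect_equal(oracle_jtc_p(6, 3, 3, 2), 0.95)
})

test_that("exact JTC p matches brute-force enumeration on random small instances", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    k1 <- sample(0:n, 1); k2 <- sample(0:n, 1)
    x <- seq_len(n) %in% sample(n, k1)
    y <- seq_len(n) %in% sample(n, k2)
    res <- suppressWarnings(jtc_pvalue(x, y, method = "exact"))
    expect_equal(res$p_value, oracle_jtc_p(n, k1, k2, sum(x & y)),
                 tolerance = 1e-12)
  }
})

test_that("identical lists sit at the similarity boundary with p = 1", {
  x <- seq_len(30) %in% sample(30, 12)
  res <- jtc_pvalue(x, x, method = "exact")
  expect_equal(res$jaccard, 1)
  expect_equal(res$p_value, 1)
})

test_that("monte-carlo JTC is seeded-deterministic and close to exact", {
  set.seed(32)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    x <- seq_len(n) %in% sample(n, sample(2:(n - 2), 1))
    y <- seq_len(n) %in% sample(n, sample(2:(n - 2), 1))
    ex <- jtc_pvalue(x, y, method = "exact")$p_value
    mc1 <- jtc_pvalue(x, y, method = "monte-carlo", n_null = 2000, seed = 99)
    mc2 <- jtc_pvalue(x, y, method = "monte-carlo", n_null = 2000, seed = 99)
    expect_identical(mc1$p_value, mc2$p_value)
    se <- sqrt(ex * (1 - ex) / 2000) + 1 / 2000
    expect_lt(abs(mc1$p_value - ex), 3 * se + 1e-9)
  }
  expect_error(jtc_pvalue(c(TRUE, FALSE), c(FALSE, TRUE),
                          method = "monte-carlo", n_null = 50), "100")
})

test_that("two-sided JTC alternative doubles the smaller tail, capped at 1", {
  x <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  y <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  one <- jtc_pvalue(x, y, method = "exact")$p_value
  two <- jtc_pvalue(x, y, method = "exact", alternative = "two.sided")$p_value
  expect_lte(two, 1)
  expect_gte(two, min(one, 1 - one))
})

test_that("ENFC evaluates the normalized log fold change and its contracts", {
  r <- enfc(2, 0.2, 1, 0.1)
  expect_equal(r$fold_change, 2)
  expect_equal(r$enfc, log(2) / sqrt(0.01 + 0.01), tolerance = 1e-12)
  expect_equal(r$enfc, 4.901291, tolerance = 1e-6)

  expect_equal(enfc(3, 0.5, 3, 0.4)$enfc, 0)
  expect_false(enfc(2, 0, 1, 0)$calculable)
  expect_false(enfc(0, 0.1, 1, 0.1)$calculable)

  # antisymmetry under swapping groups; sign follows ln FC
  a <- enfc(2, 0.2, 1, 0.1); b <- enfc(1, 0.1, 2, 0.2)
  expect_equal(a$enfc, -b$enfc, tolerance = 1e-12)
  expect_gt(a$enfc, 0)
})

test_that("enfc_table flags incalculable records instead of dropping them", {
  vals <- cbind("PC(34:2)" = c(2, 2.2, 1.8, 1, 1.1, 0.9),
                "TG(48:1)" = c(0, 0, 0, 1, 1.2, 0.8))
  ids <- paste0("s", 1:6)
  tab <- toy_table(vals, ids)
  des <- study_design(ids, rep(c("F", "M"), each = 3), rep("liver", 6))
  et <- enfc_table(tab, des, c("F", "M"))
  expect_true(et$calculable[et$variable == "PC(34:2)"])
  expect_false(et$calculable[et$variable == "TG(48:1)"])
  expect_equal(et$fold_change[et$variable == "PC(34:2)"], 2, tolerance = 1e-12)
})

test_that("CV summary computes per-variable and mean CV with scale invariance", {
  vals <- cbind(a = c(1, 2, 3, 5, 5, 5), b = c(2, 4, 6, 1, 2, 3))
  pheno <- rep(c("F", "M"), each = 3)
  s <- cv_summary(vals, pheno)
  pv <- s$per_variable
  expect_equal(pv$cv_pct[pv$variable == "a" & pv$phenotype == "F"], 50)
  expect_equal(pv$cv_pct[pv$variable == "a" & pv$phenotype == "M"], 0)
  expect_equal(unname(s$mean_cv["F"]), mean(c(50, 50)))
  s2 <- cv_summary(vals * 7, pheno)
  expect_equal(s2$per_variable$cv_pct, pv$cv_pct)
  # mean CV of two variables with CVs 10% and 30% is 20%
  v <- cbind(a = c(10, 9, 11) , b = c(10, 7, 13))
  v <- rbind(v, v)
  cv <- cv_summary(v, rep(c("F", "M"), each = 3))
  expect_equal(unname(cv$mean_cv["F"]),
               mean(100 * apply(v[1:3, ], 2, sd) / colMeans(v[1:3, ])))
})

test_that("between-phenotype mean difference summary matches direct arithmetic", {
  vals <- cbind(a = c(10, 10, 10, 12, 12, 12))
  s <- cv_summary(vals, rep(c("F", "M"), each = 3))
  expect_equal(s$mean_between_diff_pct, 100 * 2 / 11, tolerance = 1e-12)
})

test_that("group test matches the exact rank-sum oracle and handles ties", {
  x <- 1:8; y <- 11:18
  p <- group_test(x, y)$p_value
  expect_equal(p, 2 / choose(16, 8), tolerance = 1e-12)
  expect_equal(p, oracle_ranksum_p(x, y), tolerance = 1e-12)

  expect_warning(res <- group_test(rep(1, 5), rep(1, 5)), "tied")
  expect_equal(res$p_value, 1)
  expect_error(group_test(1:2, 1:5), ">= 3")

  set.seed(33)
  for (rep in 1:10) {
    x <- runif(sample(3:6, 1)); y <- runif(sample(3:6, 1))
    expect_equal(group_test(x, y)$p_value, oracle_ranksum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("significance tiers follow the composition-plot convention", {
  expect_identical(p_tier(c(0.5, 0.09, 0.03, 0.005, 5e-4, 5e-5)),
                   c("", "*", "+", "**", "***", "****"))
  expect_true(is.na(p_tier(NA_real_)))
})

test_that("p-value floor and display convention", {
  expect_equal(p_floor(1e-20), 2.2e-16)
  expect_identical(format_pvalue(1e-20), "<2.2e-16")
  expect_identical(format_pvalue(0.0312), "0.0312")
})
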