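test_that("age correlation handles exact, null, and degenerate inputs", {
  ages <- c(6, 10, 15, 22, 30, 41)
  out <- correlate_with_age(ages, ages)
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_lt(out$p, 1e-10)
  # permuted linear relation: |r| within the 95% null band for n
  set.seed(81)
  n <- 30
  a <- runif(n, 6, 44)
  v <- 2 * sample(a) + rnorm(n)
  null_band <- qnorm(0.975) / sqrt(n - 3)        # Fisher-z approximation
  expect_lt(abs(correlate_with_age(v, a)$r), tanh(null_band) + 0.15)
  expect_error(correlate_with_age(rep(1, 5), 1:5), "zero variance")
  expect_error(correlate_with_age(1:2, 1:2), "at least 3")
})

test_that("BH rejection matches the brute-force definition", {
  p <- c(0.001, 0.02, 0.04, 0.9)
  q <- 0.05
  m <- length(p)
  # brute force: sort, find largest i with p_(i) <= i q / m, reject 1..i
  o <- order(p)
  passing <- which(p[o] <= seq_len(m) * q / m)
  reject_oracle <- logical(m)
  if (length(passing))
    reject_oracle[o[seq_len(max(passing))]] <- TRUE
  # drive the module surface: a fixture pair whose p equals each family
  # member in turn, flag compared against the oracle rejection set
  set.seed(80)
  for (i in seq_len(m)) {
    fake_p <- p[i]
    # build values whose Pearson p is exactly fake_p via the t quantile
    n <- 10
    tcrit <- qt(fake_p / 2, df = n - 2, lower.tail = FALSE)
    r <- tcrit / sqrt(n - 2 + tcrit^2)
    ages <- scale(1:n)[, 1]
    values <- r * ages + sqrt(1 - r^2) * scale(resid(lm(rnorm(n) ~ ages)))[, 1]
    out <- correlate_with_age(values, ages, fdr_q = q,
                              family = replace(p, i, cor.test(values, ages)$p.value))
    expect_identical(out$fdr_flag, reject_oracle[i])
  }
})

test_that("the FDR flag agrees with p.adjust for a planted family", {
  set.seed(82)
  ages <- runif(24, 6, 44)
  isc <- 2 - 0.03 * ages + rnorm(24, sd = 0.2)
  p_main <- correlate_with_age(isc, ages)$p
  fam <- c(p_main, 0.2, 0.8)
  out <- correlate_with_age(isc, ages, fdr_q = 0.05, family = fam)
  expect_identical(out$fdr_flag,
                   p.adjust(fam, "BH")[1] <= 0.05)
  expect_error(correlate_with_age(isc, ages, family = c(0.5, 0.9)),
               "not in the supplied family")
})

test_that("median split honors the boundary policy", {
  tab <- data.frame(subject_id = letters[1:10], age = 1:10)
  out <- median_split(tab)
  expect_equal(as.character(out$age_group),
               rep(c("young", "old"), each = 5))
  fixed <- data.frame(subject_id = letters[1:5],
                      age = c(6, 10, 14, 15, 20))
  out2 <- median_split(fixed, boundary = 14)
  expect_equal(as.character(out2$age_group),
               c("young", "young", "young", "old", "old"))
  same <- data.frame(subject_id = c("a", "b"), age = c(9, 9))
  expect_warning(out3 <- median_split(same), "one side")
  expect_true(all(out3$age_group == "young"))
})

test_that("one-way reduction satisfies F = t^2", {
  set.seed(83)
  v <- c(rnorm(12), rnorm(15, 1))
  g <- rep(c("a", "b"), c(12, 15))
  out <- two_way_anova(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(out$F_a, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(out$p_a, tt$p.value, tolerance = 1e-9)
})

test_that("balanced 2x2 ANOVA matches hand-computed sums of squares", {
  # 4 cells x 3 values, additive model
  v <- c(1, 2, 3,   4, 5, 6,   2, 3, 4,   7, 8, 9)
  a <- rep(c("a1", "a2"), each = 6)
  b <- rep(rep(c("b1", "b2"), each = 3), 2)
  out <- two_way_anova(v, a, b)
  # balanced design: SS_A = sum_i n_i (mean_i - grand)^2, etc.
  grand <- mean(v)
  ss_a <- sum(tapply(v, a, length) * (tapply(v, a, mean) - grand)^2)
  ss_b <- sum(tapply(v, b, length) * (tapply(v, b, mean) - grand)^2)
  fitted <- ave(v, a) + ave(v, b) - grand
  ss_res <- sum((v - fitted)^2)
  df_res <- 12 - 3
  expect_equal(out$F_a, (ss_a / 1) / (ss_res / df_res), tolerance = 1e-9)
  expect_equal(out$F_b, (ss_b / 1) / (ss_res / df_res), tolerance = 1e-9)
  expect_equal(out$df_resid, df_res)
  # cell (a1, b2) unobserved: error names the offending cell
  expect_error(two_way_anova(c(1, 2, 3, 4, 5, 6),
                             rep(c("a1", "a2"), each = 3),
                             c("b1", "b1", "b1", "b1", "b2", "b2")),
               "empty cell.*a1:b2")
})

test_that("null p-values are calibrated for unbalanced Type II ANOVA", {
  set.seed(84)
  reps <- 200
  p_b <- vapply(seq_len(reps), function(i) {
    a <- sample(rep(c("a1", "a2"), c(18, 22)))
    b <- sample(rep(c("b1", "b2", "b3"), c(10, 14, 16)))
    v <- rnorm(40) + (a == "a2") * 1.5      # main effect of a only
    two_way_anova(v, a, b)$p_b
  }, numeric(1))
  expect_gt(ks.test(p_b, "punif")$p.value, 0.01)
  emp <- mean(p_b <= 0.05)
  expect_gte(emp, 0.02); expect_lte(emp, 0.09)
})

test_that("Tukey with two groups reduces to the pooled t-test", {
  set.seed(85)
  v <- c(rnorm(10), rnorm(14, 0.8))
  g <- rep(c("x", "y"), c(10, 14))
  hsd <- tukey_hsd(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(hsd$p_adj, tt$p.value, tolerance = 1e-6)
})

test_that("Tukey separates a strongly shifted group and not equal means", {
  set.seed(86)
  v <- c(rnorm(20), rnorm(20), rnorm(20, 10))
  g <- rep(c("a", "b", "c"), each = 20)
  hsd <- tukey_hsd(v, g)
  with_c <- grepl("c", hsd$comparison)
  expect_true(all(hsd$p_adj[with_c] < 1e-6))
  expect_gt(hsd$p_adj[!with_c], 0.05)
  same <- c(rep(1:5, 3))
  hsd2 <- tukey_hsd(same, rep(c("a", "b", "c"), each = 5))
  expect_true(all(hsd2$p_adj >= 0.99))
  expect_warning(tukey_hsd(c(v, 1), c(g, "lonely")), "size-1")
})

test_that("SSVEP residualization is an exact OLS projection", {
  ids <- sprintf("S%02d", 1:10)
  ssvep <- data.frame(subject_id = ids, band_power = seq(1, 5.5, 0.5))
  exact <- data.frame(subject_id = ids,
                      isc = 2 * ssvep$band_power + 5)
  out <- residualize_isc(exact, ssvep)
  expect_lt(max(abs(out$residual)), 1e-10)
  # constant SSVEP: residual is the mean-removed ISC
  const <- data.frame(subject_id = ids, band_power = rep(2, 10))
  set.seed(87)
  isc <- data.frame(subject_id = ids, isc = rnorm(10))
  out2 <- residualize_isc(isc, const)
  expect_equal(out2$residual, isc$isc - mean(isc$isc), tolerance = 1e-10)
  # noisy relation: residual orthogonal to the regressor, mean zero
  noisy <- data.frame(subject_id = ids,
                      isc = 1.5 * ssvep$band_power + rnorm(10))
  out3 <- residualize_isc(noisy, ssvep)
  expect_lt(abs(sum(out3$residual * out3$band_power)),
            1e-8 * sqrt(sum(out3$residual^2) * sum(out3$band_power^2)))
  expect_lt(abs(mean(out3$residual)), 1e-10)
  expect_error(residualize_isc(isc[1:2, ], ssvep), "at least 3")
})

test_that("null Pearson type-I error is calibrated at alpha = 0.05", {
  set.seed(88)
  reps <- 200
  p <- vapply(seq_len(reps), function(i)
    correlate_with_age(rnorm(20), runif(20, 6, 44))$p, numeric(1))
  emp <- mean(p <= 0.05)
  expect_gte(emp, 0.02); expect_lte(emp, 0.09)
})
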