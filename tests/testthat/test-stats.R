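test_that("sample summaries use the n-1 SD and SD/sqrt(n) SEM", {
  s <- summarize_sample(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$sem, 0.5773503, tolerance = 1e-6)
  s1 <- summarize_sample(5)
  expect_equal(s1$mean, 5)
  expect_true(is.na(s1$sd) && is.na(s1$sem))
  expect_equal(summarize_sample(rep(2, 10))$sd, 0)
  expect_error(summarize_sample(numeric()), "empty")
})

test_that("Jarque-Bera statistic matches an independent moments oracle", {
  jb_oracle <- function(x) {
    n <- length(x)
    s <- e1071::skewness(x, type = 1)
    k <- e1071::kurtosis(x, type = 1) + 3
    n / 6 * (s^2 + (k - 3)^2 / 4)
  }
  set.seed(10)
  for (i in 1:20) {
    x <- switch(1 + i %% 3, rnorm(30), rexp(25), rt(40, df = 3))
    expect_equal(jarque_bera(x)$statistic, jb_oracle(x), tolerance = 1e-10)
  }
  expect_error(jarque_bera(c(1, 2)), "at least 3")
})

test_that("test selection follows the normality/variance gates", {
  set.seed(1)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(select_two_sample_test(x, y)$test, "student_t")
  # heavy-tailed sample fails the Jarque-Bera gate
  set.seed(2)
  h <- rt(60, df = 1.5)
  expect_equal(select_two_sample_test(h, rnorm(60))$test, "mann_whitney")
  # grossly unequal variances fail the F gate even for normal data
  set.seed(3)
  expect_equal(select_two_sample_test(rnorm(60), rnorm(60, sd = 5))$test,
               "mann_whitney")
  expect_error(select_two_sample_test(1:2, 1:5), "at least 3")
})

test_that("gate decision matches a brute-force rule oracle on seeded pairs", {
  oracle <- function(x, y, alpha = 0.05) {
    jb_p <- function(z) {
      n <- length(z); m <- z - mean(z)
      s <- mean(m^3) / mean(m^2)^1.5
      k <- mean(m^4) / mean(m^2)^2
      pchisq(n / 6 * (s^2 + (k - 3)^2 / 4), 2, lower.tail = FALSE)
    }
    ok <- jb_p(x) > alpha && jb_p(y) > alpha && var.test(x, y)$p.value > alpha
    if (ok) "student_t" else "mann_whitney"
  }
  set.seed(77)
  for (i in 1:200) {
    x <- switch(1 + i %% 4, rnorm(15), rexp(12), rnorm(20, sd = 3), rt(15, 2))
    y <- switch(1 + (i + 1) %% 4, rnorm(15), rexp(12), rnorm(20, sd = 3), rt(15, 2))
    expect_identical(select_two_sample_test(x, y)$test, oracle(x, y))
  }
})

test_that("gate decision is invariant to order and common rescaling", {
  set.seed(8)
  for (i in 1:25) {
    x <- rnorm(20, sd = sample(c(1, 4), 1)); y <- rexp(18)
    d1 <- select_two_sample_test(x, y)
    expect_identical(d1$test, select_two_sample_test(3.7 * x, 3.7 * y)$test)
    d2 <- select_two_sample_test(y, x)
    expect_identical(d1$test, d2$test)
  }
})

test_that("gated comparison behaves correctly under null and shift", {
  # identical samples: Mann-Whitney p of 1
  x <- c(1.2, 3.4, 2.2, 5.1, 0.7, 2.9)
  cmp <- run_two_sample(x, x)
  expect_gte(cmp$p, 0.99)
  # null calibration: nominal 5% type-I
  set.seed(20)
  p_null <- vapply(1:400, function(i)
    run_two_sample(rnorm(15), rnorm(15))$p, numeric(1))
  expect_gte(mean(p_null > 0.05), 0.90)
  # power: a 2 SD shift at n = 20 is detected almost always
  set.seed(21)
  p_shift <- vapply(1:100, function(i)
    run_two_sample(rnorm(20), rnorm(20, mean = 2))$p, numeric(1))
  expect_gte(mean(p_shift < 0.01), 0.95)
  # decision recorded matches the standalone gate
  set.seed(22)
  a <- rexp(15); b <- rnorm(15)
  expect_identical(run_two_sample(a, b)$test_used,
                   select_two_sample_test(a, b)$test)
})

test_that("exact and approximate Mann-Whitney agree for small tie-free n", {
  set.seed(30)
  n_checked <- 0L
  for (i in 1:30) {
    # grossly unequal variances force the Mann-Whitney branch while the
    # samples stay tie-free, so the exact distribution is used
    x <- rnorm(8); y <- rnorm(8, 0.5, 8)
    cmp <- run_two_sample(x, y)
    if (cmp$test_used != "mann_whitney") next
    n_checked <- n_checked + 1L
    # independent continuity-corrected normal oracle on the U statistic
    u <- sum(outer(x, y, ">"))
    mu <- 64 / 2; sg <- sqrt(8 * 8 * 17 / 12)
    p_approx <- 2 * pnorm(-(abs(u - mu) - 0.5) / sg)
    expect_lt(abs(cmp$p - min(1, p_approx)), 0.012)
  }
  expect_gt(n_checked, 10L)
})

test_that("Kruskal-Wallis H matches a direct rank-computation oracle", {
  h_oracle <- function(groups) {
    v <- unlist(groups); g <- rep(seq_along(groups), lengths(groups))
    N <- length(v); r <- rank(v)
    h <- 12 / (N * (N + 1)) *
      sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
    ties <- table(v)
    h / (1 - sum(ties^3 - ties) / (N^3 - N))
  }
  set.seed(40)
  for (i in 1:10) {
    gs <- list(round(rnorm(8), 1), round(rnorm(9), 1), round(rnorm(7, 1), 1))
    kd <- kruskal_dunn(gs)
    expect_equal(kd$h, h_oracle(gs), tolerance = 1e-10)
    # Dunn adjusted p never below unadjusted
    expect_true(all(kd$pairwise$p_adj >= kd$pairwise$p - 1e-12))
  }
  expect_error(kruskal_dunn(list(1:5, 6:10)), "two-sample path")
})

test_that("Dunn comparisons flag a shifted group and stay calm under null", {
  set.seed(41)
  hits <- vapply(1:60, function(i) {
    kd <- kruskal_dunn(list(a = rnorm(10), b = rnorm(10), c = rnorm(10, 3)))
    pw <- kd$pairwise
    all(pw$p_adj[pw$group1 == "c" | pw$group2 == "c"] < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  set.seed(42)
  null_ok <- vapply(1:200, function(i)
    kruskal_dunn(list(rnorm(8), rnorm(8), rnorm(8)))$p_omnibus > 0.05,
    logical(1))
  expect_gte(mean(null_ok), 0.90)
})
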