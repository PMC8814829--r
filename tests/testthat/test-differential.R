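# brute-force oracle for the conditional exact test: enumerate every
# split of s as a product of NB densities at an arbitrary mean (the
# conditional law is mean-free), normalize, and sum the tail
exact_test_oracle <- function(sumA, sumB, nA, nB, phi, mu = 3.7) {
  s <- sumA + sumB
  a <- 0:s
  pr <- if (phi == 0) {
    dbinom(a, s, nA / (nA + nB))
  } else {
    vapply(a, function(ai) {
      dnbinom(ai, size = nA / phi, mu = nA * mu) *
        dnbinom(s - ai, size = nB / phi, mu = nB * mu)
    }, 0)
  }
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[sumA + 1] * (1 + 1e-10)])
}

test_that("CPM is exact arithmetic on counts over library size", {
  m <- matrix(c(75, 0, 1794033), nrow = 3,
              dimnames = list(c("a", "b", "c"), "s1"))
  got <- cpm(m, lib_sizes = c(s1 = 1794033))
  expect_equal(got["a", 1], 41.80, tolerance = 0.01)
  expect_equal(got["b", 1], 0)
  expect_equal(got["c", 1], 1e6)
  expect_error(cpm(m, lib_sizes = c(s1 = 0)), "positive")
  # equal libraries: CPM proportional to raw counts
  m2 <- matrix(1:6, 3, 2, dimnames = list(letters[1:3], c("x", "y")))
  got2 <- cpm(m2, lib_sizes = c(x = 100, y = 100))
  expect_equal(got2 / m2, matrix(1e4, 3, 2, dimnames = dimnames(m2)))
})

test_that("common dispersion recovers simulation truth", {
  sim0 <- simulate_count_matrix(rep(100, 2000), depth = 1e6, n_reps = 3,
                                dispersion = 0, seed = 8)
  est0 <- estimate_common_dispersion(sim0$counts, sim0$groups)
  expect_lt(est0$phi, 0.02)
  sim2 <- simulate_count_matrix(rep(100, 2000), depth = 1e6, n_reps = 3,
                                dispersion = 0.2, seed = 9)
  est2 <- estimate_common_dispersion(sim2$counts, sim2$groups)
  expect_gt(est2$phi, 0.1)
  expect_lt(est2$phi, 0.3)
  # identical counts across samples -> zero variance -> phi = 0
  flat <- matrix(50L, 10, 6,
                 dimnames = list(letters[1:10], paste0("s", 1:6)))
  expect_equal(estimate_common_dispersion(
    flat, rep(c("a", "b"), each = 3))$phi, 0)
})

test_that("exact test is symmetric, bounded, and exact at the binomial", {
  expect_equal(exact_count_test(25, 25, 3, 3, 0), 1)
  expect_equal(exact_count_test(25, 25, 3, 3, 0.4), 1)
  b <- dbinom(0:20, 20, 0.5)
  expect_equal(exact_count_test(0, 20, 3, 3, 0),
               sum(b[b <= b[1] * (1 + 1e-10)]))
  expect_error(exact_count_test(-1, 5, 3, 3, 0), "non-negative")
  expect_gt(exact_count_test(0, 0, 3, 3, 0.1), 0.999)
})

test_that("exact test equals brute-force enumeration over random splits", {
  set.seed(71)
  for (k in 1:150) {
    sa <- sample(0:100, 1); sb <- sample(0:100, 1)
    nA <- sample(2:4, 1); nB <- sample(2:4, 1)
    phi <- sample(c(0, 0.1, 0.5), 1)
    expect_equal(exact_count_test(sa, sb, nA, nB, phi),
                 exact_test_oracle(sa, sb, nA, nB, phi), tolerance = 1e-9)
  }
})

test_that("p-values decrease as a fixed total becomes more unbalanced", {
  s <- 60
  p <- vapply(30:60, function(b) exact_count_test(s - b, b, 3, 3, 0.1), 0)
  expect_true(all(diff(p) <= 1e-12))
})

test_that("fold ratio honors the pseudocount algebra", {
  fr <- fold_ratio(10, 10, pseudo = 0.5)
  expect_equal(fr$ratio, 1)
  expect_equal(fr$log2_ratio, 0)
  fr0 <- fold_ratio(0, 33, pseudo = 0.5)
  expect_true(is.finite(fr0$ratio) && fr0$ratio > 0)
  set.seed(3)
  a <- runif(1000, 0, 1000); b <- runif(1000, 0, 1000)
  fr2 <- fold_ratio(a, b, pseudo = 0.25)
  expect_equal(fr2$ratio * (a + 0.25), b + 0.25, tolerance = 1e-12)
})

test_that("two-tier classification follows the ratio and p thresholds", {
  got <- classify(c(5, 20, 20, 0.05, 1.5), c(0.01, 0.2, 0.001, 0.01, 0.001))
  expect_identical(got$mark2, c("UP", "NS", "UP", "DOWN", "NS"))
  expect_identical(got$mark10, c("NS", "NS", "UP", "DOWN", "NS"))
  # monotone in ratio at fixed p: increasing ratio never demotes a mark
  ratios <- sort(runif(50, 0, 30))
  marks <- classify(ratios, rep(0.01, 50))
  rank2 <- match(marks$mark2, c("DOWN", "NS", "UP"))
  expect_true(all(diff(rank2) >= 0))
})

test_that("identical condition groups give p = 1 everywhere", {
  set.seed(5)
  half <- matrix(rpois(30, 40), 10, 3)
  m <- cbind(half, half)
  rownames(m) <- sprintf("m%02d", 1:10)
  colnames(m) <- paste0("s", 1:6)
  de <- run_differential(m, rep(c("milk", "exo"), each = 3),
                         ref_group = "milk",
                         lib_sizes = setNames(rep(1000, 6), colnames(m)))
  expect_true(all(de$table$p_value == 1))
  expect_true(all(de$table$mark2 == "NS"))
})

test_that("all-zero miRNAs are excluded with a message", {
  m <- matrix(c(0, 0, 0, 0, 0, 0,
                5, 6, 7, 50, 60, 70), 2, 6, byrow = TRUE,
              dimnames = list(c("zero", "live"), paste0("s", 1:6)))
  expect_message(
    de <- run_differential(m, rep(c("milk", "exo"), each = 3),
                           ref_group = "milk",
                           lib_sizes = setNames(rep(1000, 6), paste0("s", 1:6))),
    "all-zero")
  expect_identical(de$table$miRNA, "live")
})

test_that("null p-values are calibrated and never anti-conservative", {
  set.seed(101)
  base_cpm <- rlnorm(2000, log(100), 1)
  sim <- simulate_count_matrix(base_cpm, fold = 1, depth = 1e6, n_reps = 3,
                               dispersion = 0.1, seed = 101)
  de <- run_differential(sim$counts, sim$groups, ref_group = "milk",
                         lib_sizes = sim$lib_sizes)
  frac <- mean(de$table$p_value < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
  # ECDF of p dominated by uniform up to 2 Monte-Carlo SE
  n <- nrow(de$table)
  for (t in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(de$table$p_value <= t),
               t + 2 * sqrt(t * (1 - t) / n))
  }
})

test_that("large planted folds at moderate abundance earn strong UP marks", {
  set.seed(9)
  folds <- sample(ENRICHMENT_FOLDS, 200, replace = TRUE)
  base <- exp(runif(200, log(50), log(1000)))
  sim <- simulate_count_matrix(base, fold = folds, depth = 1e6, n_reps = 3,
                               dispersion = 0.05, seed = 9)
  de <- run_differential(sim$counts, sim$groups, ref_group = "milk",
                         lib_sizes = sim$lib_sizes)
  expect_gte(mean(de$table$mark10 == "UP"), 0.9)
  # the extreme planted fold is recovered as strongly up
  big <- de$table[which.max(de$table$ratio), ]
  expect_identical(big$mark10, "UP")
  expect_gt(big$ratio, 100)
})
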