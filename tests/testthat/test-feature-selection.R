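test_that("pearson_r matches the definition-based oracle", {
  expect_equal(pearson_r(1:4, 1:4), 1.0)
  expect_equal(pearson_r(1:4, -(1:4)), -1.0)
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  expect_equal(pearson_r(x, y), oracle_pearson(x, y), tolerance = 1e-12)

  set.seed(2)
  for (i in 1:1000) {
    n <- sample(3:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(pearson_r(x, y), oracle_pearson(x, y), tolerance = 1e-12)
  }
  expect_error(pearson_r(rep(1, 5), rnorm(5)),
               class = "oastratify_degenerate_error")
  expect_error(pearson_r(c(1, NA, 2), c(1, 2, NA)),
               class = "oastratify_degenerate_error")
})

test_that("prune_vs_target drops target-correlated features only", {
  set.seed(3)
  n <- 500
  target <- rnorm(n)
  tab <- data.frame(dup = target,
                    strong = target + rnorm(n, 0, 0.3),
                    neg = -target + rnorm(n, 0, 0.3),
                    noise = rnorm(n))
  rep_ <- prune_vs_target(tab, target)
  expect_setequal(rep_$dropped$feature, c("dup", "strong", "neg"))
  expect_equal(rep_$kept, "noise")

  rep1 <- prune_vs_target(tab, target, cutoff = 1.0)
  expect_equal(rep1$dropped$feature, "dup")   # only the exact duplicate
  expect_setequal(union(rep1$kept, rep1$dropped$feature), names(tab))
})

test_that("prune_pairwise is greedy in column order", {
  set.seed(4)
  n <- 500
  a <- rnorm(n)
  c0 <- 0.5 * a + sqrt(1 - 0.25) * rnorm(n)
  b <- as.numeric(scale(0.75 * scale(a) + 0.66 * scale(c0)))  # r~0.9 with both
  tab <- data.frame(A = a, B = b, C = c0)
  stopifnot(abs(cor(a, b)) > 0.7, abs(cor(b, c0)) > 0.7, abs(cor(a, c0)) < 0.7)
  rep_ <- prune_pairwise(tab)
  expect_equal(rep_$kept, c("A", "C"))
  expect_equal(rep_$dropped$feature, "B")

  dup <- data.frame(x = a, y = a)
  expect_equal(prune_pairwise(dup)$kept, "x")

  ind <- data.frame(p = rnorm(n), q = rnorm(n), r = rnorm(n))
  expect_length(prune_pairwise(ind)$kept, 3)
})

test_that("kept set of prune_pairwise never contains a violating pair", {
  set.seed(5)
  for (i in 1:20) {
    n <- 200; k <- 8
    base <- matrix(rnorm(n * 3), n, 3)
    tab <- as.data.frame(sapply(1:k, function(j)
      base[, sample(3, 1)] * runif(1, 0.5, 1.5) + rnorm(n, 0, runif(1, 0.1, 2))))
    kept <- prune_pairwise(tab, cutoff = 0.7)$kept
    if (length(kept) > 1) {
      cm <- abs(cor(tab[, kept])); diag(cm) <- 0
      expect_true(all(cm <= 0.7))
    }
  }
})

test_that("information_gain matches hand-computed and oracle values", {
  y <- rep(c(0, 1), each = 50)
  expect_equal(information_gain(y, y), 1.0)
  # two pure bins from balanced labels: 1 bit
  feat <- rep(c(0, 1), each = 10)
  lab <- rep(c(1, 0), each = 10)
  expect_equal(information_gain(feat, lab), 1.0)

  set.seed(6)
  for (i in 1:200) {
    n <- sample(20:100, 1)
    f <- sample(0:3, n, replace = TRUE)      # used as-is (<= n_bins levels)
    l <- sample(0:1, n, replace = TRUE)
    if (length(unique(l)) < 2) next
    expect_equal(information_gain(f, l),
                 oracle_ig(as.character(f), l), tolerance = 1e-12)
  }
  expect_error(information_gain(rnorm(10), rep(1, 10)),
               class = "oastratify_degenerate_error")
})

test_that("information gain is bounded by the label entropy and near zero under the null", {
  set.seed(7)
  for (i in 1:50) {
    n <- 400
    f <- rnorm(n); l <- sample(0:1, n, replace = TRUE)
    H <- -sum(prop.table(table(l)) * log2(prop.table(table(l))))
    ig <- information_gain(f, l)
    expect_gte(ig, 0)
    expect_lte(ig, H + 1e-12)
  }
  # null IG has a small positive bias that shrinks with n
  igs <- sapply(1:30, function(s) {
    set.seed(s)
    information_gain(rnorm(2000), sample(0:1, 2000, replace = TRUE))
  })
  expect_lt(mean(igs), 0.02)
})

test_that("rank_by_information_gain surfaces the informative feature", {
  hits <- sapply(1:20, function(s) {
    set.seed(s)
    n <- 500
    l <- sample(0:1, n, replace = TRUE)
    tab <- as.data.frame(matrix(rnorm(n * 20), n, 20))
    tab$planted <- l + rnorm(n, 0, 0.5)
    rank_by_information_gain(tab, l, k = 1) == "planted"
  })
  expect_gte(mean(hits), 0.95)

  tab <- as.data.frame(matrix(rnorm(100 * 3), 100, 3))
  l <- rep(0:1, 50)
  expect_warning(sel <- rank_by_information_gain(tab, l, k = 10),
                 "only 3 features")
  expect_length(sel, 3)
})

test_that("completeness filter is inclusive at the boundary", {
  # 100 variables: 79, 80 and 100 percent complete rows
  mk_row <- function(n_missing) c(rep(NA_real_, n_missing),
                                  rnorm(100 - n_missing))
  tab <- as.data.frame(rbind(mk_row(21), mk_row(20), mk_row(0)))
  out <- completeness_filter(tab, 0.8)
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "n_removed"), 1)

  full <- as.data.frame(matrix(rnorm(50), 10, 5))
  expect_equal(nrow(completeness_filter(full, 0.8)), 10)
  allna <- as.data.frame(matrix(NA_real_, 3, 4))
  expect_error(completeness_filter(allna, 0.8),
               class = "oastratify_degenerate_error")
})
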