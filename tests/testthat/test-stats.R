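test_that("Spearman rho matches closed cases and the rank-Pearson oracle", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8, 9.7, 9.3)
  expect_equal(spearman_rho(x, x)$statistic, 1)
  expect_equal(spearman_rho(x, -x)$statistic, -1)

  set.seed(41)
  for (rep in 1:25) {
    n <- sample(9:40, 1)
    a <- sample(1:8, n, replace = TRUE)  # heavy ties
    b <- a + sample(-2:2, n, replace = TRUE)
    if (sd(rank(a)) == 0 || sd(rank(b)) == 0) next
    r <- spearman_rho(a, b)
    # independent oracle: average ranks computed by hand, then Pearson
    avg_rank <- function(v) {
      o <- order(v)
      rk <- numeric(length(v))
      i <- 1
      while (i <= length(v)) {
        j <- i
        while (j < length(v) && v[o[j + 1]] == v[o[i]]) j <- j + 1
        rk[o[i:j]] <- mean(i:j)
        i <- j + 1
      }
      rk
    }
    oracle <- cor(avg_rank(a), avg_rank(b))
    expect_equal(r$statistic, oracle, tolerance = 1e-12)
    expect_equal(r$statistic,
                 unname(suppressWarnings(
                   cor.test(a, b, method = "spearman")$estimate)),
                 tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(spearman_rho(exp(a), b)$statistic, r$statistic)
  }
})

test_that("Spearman exact permutation p agrees with cor.test for small n", {
  set.seed(42)
  for (rep in 1:5) {
    x <- sample(100, 7)  # distinct: tie-free exact regime
    y <- sample(100, 7)
    p_exact <- spearman_rho(x, y, p_method = "exact")$p_value
    p_ref <- cor.test(x, y, method = "spearman", exact = TRUE)$p.value
    expect_equal(p_exact, p_ref, tolerance = 1e-9)
  }
})

test_that("Bonferroni multiplies by family size and caps at one", {
  expect_equal(bonferroni(0.01), 0.01)
  expect_equal(bonferroni(c(0.01, 0.02, 0.03)), c(0.03, 0.06, 0.09))
  expect_equal(bonferroni(c(0.5, 0.9)), c(1, 1))
})

test_that("Mann-Whitney U matches enumeration and symmetry properties", {
  # identical groups: central U, zero Z
  r <- mann_whitney_u(c(2, 4, 6), c(2, 4, 6))
  expect_equal(r$statistic, 4.5)
  expect_equal(r$z, 0)
  # fully separated groups: U = 0, exact p = 2/20
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact")

  set.seed(43)
  for (rep in 1:60) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    g1 <- sample(1:6, n1, replace = TRUE)
    g2 <- sample(1:6, n2, replace = TRUE)
    res <- mann_whitney_u(g1, g2)
    # independent oracle: count-based U over all labelings
    u_of <- function(a, b) {
      sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    }
    pooled <- c(g1, g2)
    labelings <- combn(n1 + n2, n1)
    mu <- n1 * n2 / 2
    us <- apply(labelings, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
    u_obs <- u_of(g1, g2)
    p_oracle <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
    expect_equal(res$statistic, u_obs)
    expect_equal(res$p_value, p_oracle)
    # U1 + U2 = n1 n2 and swap invariance
    res_swap <- mann_whitney_u(g2, g1)
    expect_equal(res$statistic + res_swap$statistic, n1 * n2)
    expect_equal(res$p_value, res_swap$p_value)
  }
})

test_that("Mann-Whitney exact p equals wilcox.test in the tie-free regime", {
  set.seed(44)
  for (rep in 1:20) {
    g1 <- sample(1:1000, 4)
    g2 <- sample(1001:2000, 5) - sample(500, 5)
    if (any(g1 %in% g2)) next
    res <- mann_whitney_u(g1, g2)
    ref <- wilcox.test(g1, g2, exact = TRUE)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Fisher's exact test matches the hypergeometric closed form", {
  res <- fisher_exact(matrix(c(1, 11, 9, 3), 2))
  expect_equal(res$p_value, 0.002759456, tolerance = 1e-6)
  # degenerate margins
  expect_equal(fisher_exact(matrix(c(0, 5, 0, 7), 2))$p_value, 1)
  expect_equal(fisher_exact(matrix(c(3, 0, 4, 0), 2))$p_value, 1)
  expect_error(fisher_exact(matrix(c(400, 300, 200, 100), 2)),
               "enumeration bound")
  expect_error(fisher_exact(matrix(c(1.5, 2, 3, 4), 2)), "integer")

  set.seed(45)
  for (rep in 1:100) {
    m <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    # closed-form 2x2 oracle: sum of hypergeometric point masses at most
    # the observed mass
    k <- sum(m[1, ]); n1 <- sum(m[, 1]); n <- sum(m)
    supp <- max(0, k + n1 - n):min(k, n1)
    dens <- dhyper(supp, n1, n - n1, k)
    p_obs <- dhyper(m[1, 1], n1, n - n1, k)
    p_closed <- sum(dens[dens <= p_obs * (1 + 1e-7)])
    expect_equal(fisher_exact(m)$p_value, min(1, p_closed), tolerance = 1e-9)
  }
})

test_that("r x c enumeration agrees with stats::fisher.test", {
  set.seed(46)
  for (rep in 1:20) {
    m <- matrix(sample(0:8, 6, replace = TRUE), nrow = 3)
    if (sum(m) == 0) next
    expect_equal(fisher_exact(m)$p_value, fisher.test(m)$p.value,
                 tolerance = 1e-9)
  }
  # column swap leaves p unchanged
  m <- matrix(c(5, 5, 0, 4, 7, 18), nrow = 3)
  expect_equal(fisher_exact(m)$p_value, fisher_exact(m[, 2:1])$p_value)
})

test_that("hive concordance correlates abundance vectors over the taxon union", {
  a <- comp_from_counts(c(X = 60, Y = 30, Z = 10), hive = "A")
  b <- comp_from_counts(c(X = 600, Y = 300, Z = 100), hive = "B")
  res <- hive_concordance(list(a, b))
  expect_equal(nrow(res), 1)
  expect_equal(res$statistic, 1)

  c3 <- comp_from_counts(c(X = 10, W = 90), hive = "C")
  res3 <- hive_concordance(list(a, b, c3))
  expect_equal(nrow(res3), 3)  # three pairs in one month
  expect_equal(res3$n, rep(4, 3))  # union taxon list includes W and Z
  expect_true(all(res3$p_adjusted >= res3$p_value))
})

test_that("status association builds the expected contingency table", {
  checklist <- tibble::tibble(
    taxon = c("Alpha", "Beta", "Gamma", "Delta"),
    status = c("native", "both", "horticulture", "native"),
    habitat = "W", growth_form = "W", use = "N")
  comp <- comp_from_counts(c("Alpha one" = 60, "Beta" = 38,
                             "Gamma two" = 1, "Delta" = 1))
  comp$rank <- c("species", "genus", "species", "genus")
  cls <- classify_major_minor(comp)
  sa <- status_association(checklist, cls)
  expect_equal(sa$table["native", "major"], 1)
  expect_equal(sa$table["both", "major"], 1)
  expect_equal(sa$table["horticulture", "minor"], 1)
  expect_equal(sa$table["native", "minor"], 1)
  expect_true(sa$result$p_value > 0 && sa$result$p_value <= 1)
  # single status: no association detectable
  checklist$status <- "native"
  sa1 <- status_association(checklist, cls)
  expect_equal(sa1$result$p_value, 1)
})
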