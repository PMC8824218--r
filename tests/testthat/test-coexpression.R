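test_that("marginal probabilities count the threshold boundary as high", {
  expect_equal(marginalProbs(c(0.6, 0.7, 0.9), 0.5), c(PH = 1, PL = 0))
  expect_equal(marginalProbs(c(0.5, 0.4), 0.5), c(PH = 0.5, PL = 0.5))
  expect_equal(marginalProbs(runif(10), 0)[["PH"]], 1)
  expect_error(marginalProbs(numeric(0)), "empty")
})

test_that("quadrant probabilities are joint cell proportions", {
  # all cells double-positive
  qp <- quadrantProbs(rep(0.8, 5), rep(0.9, 5), 0.5)
  expect_equal(unname(qp$probs), c(1, 0, 0, 0))

  # 10 cells: 4 in Q1, 3 in Q2, 2 in Q3, 1 in Q4 (anticlockwise)
  v1 <- c(rep(0.9, 4), rep(0.1, 3), rep(0.2, 2), 0.7)
  v2 <- c(rep(0.8, 4), rep(0.9, 3), rep(0.3, 2), 0.1)
  qp <- quadrantProbs(v1, v2, 0.5)
  expect_equal(unname(qp$counts), c(4, 3, 2, 1))
  expect_equal(unname(qp$probs), c(0.4, 0.3, 0.2, 0.1))
  expect_equal(sum(qp$probs), 1)
  expect_equal(sum(qp$product), 1)  # (PH+PL)^2 = 1 algebraically

  # perfectly dependent pair: joint and product forms diverge
  v <- c(rep(0.9, 5), rep(0.1, 5))
  qp2 <- quadrantProbs(v, v, 0.5)
  expect_equal(qp2$probs[["q1"]], 0.5)
  expect_equal(qp2$product[["q1"]], 0.25)

  expect_error(quadrantProbs(c(0.1, 0.2), 0.3), "differ in length")
})

test_that("co-expression entropy matches its closed form", {
  # uniform quadrant occupancy: exactly 1 (epsilon inert, no zeros)
  expect_equal(coexpressionEntropy(rep(0.25, 4)), 1)
  # single-quadrant: 3 epsilon terms only, rounds to 0 at two decimals
  s <- coexpressionEntropy(c(1, 0, 0, 0), epsilon = 1e-6)
  expect_equal(s, 3e-6 * log(1e6) / log(4), tolerance = 1e-12)
  expect_equal(round(s, 2), 0)
  # two equal quadrants: 0.5 plus the epsilon excess
  s2 <- coexpressionEntropy(c(0.5, 0.5, 0, 0))
  expect_equal(s2, 0.5 + 2e-6 * log(1e6) / log(4), tolerance = 1e-12)
  expect_error(coexpressionEntropy(c(-0.1, 0.5, 0.3, 0.3)), "negative")
  expect_error(coexpressionEntropy(c(0.5, 0.5, 0.1, 0.1)), "sum to 1")
})

test_that("entropy is quadrant-permutation symmetric and maximal at uniform", {
  withr::with_seed(13, {
    for (i in 1:20) {
      p <- as.numeric(stats::rgamma(4, 1)); p <- p / sum(p)
      s <- coexpressionEntropy(p)
      for (j in 1:5) {
        perm <- sample(4)
        expect_equal(coexpressionEntropy(p[perm]), s, tolerance = 1e-12)
      }
    }
  })
  # dense grid over the simplex: no point beats the uniform distribution
  step <- 0.05
  grid <- expand.grid(p1 = seq(0, 1, step), p2 = seq(0, 1, step),
                      p3 = seq(0, 1, step))
  grid <- grid[grid$p1 + grid$p2 + grid$p3 <= 1 + 1e-12, ]
  s_max <- coexpressionEntropy(rep(0.25, 4))
  svals <- apply(grid, 1, function(r) {
    p <- c(r, 1 - sum(r))
    p[abs(p) < 1e-12] <- 0
    coexpressionEntropy(p)
  })
  expect_true(all(svals <= s_max + 1e-12))
  expect_equal(max(svals), s_max)
  # epsilon-inflated excess above 1 is bounded
  eps <- 1e-6
  expect_true(all(svals <= 1 + 4 * eps * log(1 / eps, 4)))
})

test_that("the pair screen enumerates cluster x pair combinations", {
  withr::with_seed(17, {
    K <- 5; C <- 3
    x <- matrix(runif(K * 60), K, 60,
                dimnames = list(paste0("ADT", 1:K), paste0("C", 1:60)))
    cl <- rep(0:(C - 1), each = 20)
    tab <- screenPairs(x, cl)
    expect_equal(nrow(tab), C * K * (K - 1) / 2)
    expect_true(all(diff(tab$entropy) >= 0))  # sorted ascending
    expect_true(all(tab$c1 + tab$c2 + tab$c3 + tab$c4 == tab$n))
    expect_true(all(tab$band %in% c("single-quadrant", "two-quadrant", "diffuse")))
  })
})

test_that("constant ADTs yield missing correlations but defined entropy", {
  x <- rbind(ADTa = c(0.8, 0.8, 0.8, 0.8), ADTb = c(0.1, 0.9, 0.2, 0.7))
  colnames(x) <- paste0("C", 1:4)
  tab <- screenPairs(x, rep(0, 4))
  expect_true(is.na(tab$pearson))
  expect_true(is.finite(tab$entropy))
  # clusters under 3 cells: correlations missing, entropy still computed
  tab2 <- screenPairs(x[, 1:2], c(0, 0))
  expect_true(all(is.na(c(tab2$pearson, tab2$spearman, tab2$kendall))))
  expect_true(is.finite(tab2$entropy))
})

test_that("an engineered double-positive population has minimal entropy", {
  ce <- simulateCiteSeq(citePreset("double_positive"))
  xa <- minMaxScale(clrTransform(adtCounts(ce), 1))
  truth <- ce$true_label
  # >= 95% of the cells of the DP cluster exceed the threshold in both ADTs
  dp <- truth == 0
  expect_gte(mean(xa["ADT01", dp] >= 0.5 & xa["ADT02", dp] >= 0.5), 0.95)
  tab <- screenPairs(xa, truth)
  hit <- tab$cluster == 0 & tab$adt1 == "ADT01" & tab$adt2 == "ADT02"
  expect_equal(tab$entropy[hit], min(tab$entropy))
  expect_equal(tab$p1[hit], max(tab[hit, c("p1", "p2", "p3", "p4")]))
  expect_identical(tab$band[hit], "single-quadrant")
})
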