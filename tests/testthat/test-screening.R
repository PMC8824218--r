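test_that("gene statistics match direct evaluation", {
  m <- named_matrix(c(0, 0, 7, 2, 0, 7, 3, 0, 7), 3, 3)
  st <- geneStats(m)
  expect_equal(st$total, c(5, 0, 21))
  expect_equal(st$sparsity, c(2L, 0L, 3L))
  # count conservation: totals sum to the grand total
  expect_equal(sum(st$total), sum(m))
})

test_that("sparsity equals a per-cell loop oracle on random matrices", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      m <- named_matrix(rpois(200, 0.7), 20, 10)
      st <- geneStats(m)
      oracle <- vapply(seq_len(nrow(m)), function(i) {
        s <- 0L
        for (j in seq_len(ncol(m))) if (m[i, j] != 0) s <- s + 1L
        s
      }, integer(1))
      expect_identical(st$sparsity, oracle)
      expect_equal(st$total, unname(rowSums(m)))
    }
  })
})

test_that("screening uses strict inequalities on both indexes", {
  # J = 100: T > 1 and SP > 5 required at thresholds (0.01, 0.05)
  J <- 100
  m <- matrix(0, 3, J, dimnames = list(c("kept", "low_sp", "low_t"),
                                       paste0("C", 1:J)))
  m["kept", 1:6] <- 1            # T=6 > 1, SP=6 > 5: kept
  m["low_sp", 1:5] <- c(2, 1, 1, 1, 1)  # T=6 > 1, SP=5 (not > 5): dropped
  m["low_t", 1] <- 1             # T=1 (not > 1): dropped
  out <- screenGenes(m, t_frac = 0.01, sp_frac = 0.05)
  expect_identical(rownames(out), "kept")
  expect_equal(ncol(out), J)

  # boundary: zero thresholds keep exactly the genes with T > 0
  m2 <- named_matrix(c(0, 1, 0, 2, 0, 0), 2, 3)
  out2 <- screenGenes(m2, 0, 0)
  expect_identical(rownames(out2), "G2")

  # screening is idempotent at fixed thresholds
  once <- screenGenes(m, 0.01, 0.05)
  expect_identical(screenGenes(once, 0.01, 0.05), once)

  # degenerate threshold removes everything -> advisory error
  expect_error(screenGenes(m2, 1, 0), "relax")
})

test_that("keep argument retains features past the thresholds", {
  m <- named_matrix(c(0, 9, 1, 9, 0, 9), 2, 3)  # G1: T=1,SP=1 fails sp 0.5
  out <- screenGenes(m, t_frac = 0, sp_frac = 0.5, keep = "G1")
  expect_identical(rownames(out), c("G1", "G2"))
})

test_that("top-CV selection ranks by coefficient of variation", {
  m <- rbind(flat = c(1, 1, 1), spiky = c(0, 0, 9), other = c(5, 5, 5))
  colnames(m) <- paste0("C", 1:3)
  expect_identical(topCVFeatures(m, "", 1), "spiky")
  # n larger than available clamps without error
  expect_identical(sort(topCVFeatures(m, "", 10)), c("flat", "other", "spiky"))
  # prefixes restrict the candidate set; no match warns and returns empty
  rownames(m) <- c("mm-a", "mm-b", "hs-a")
  expect_identical(topCVFeatures(m, "mm-", 1), "mm-b")
  expect_warning(res <- topCVFeatures(m, "zz-", 5), "no features match")
  expect_identical(res, character(0))
  # deterministic lexicographic tie-break
  m2 <- rbind(b = c(1, 3), a = c(2, 6), c = c(10, 10))
  colnames(m2) <- c("C1", "C2")
  expect_identical(topCVFeatures(m2, "", 2), c("a", "b"))
})

test_that("ADT removal handles unknown names per the strictness mode", {
  q <- named_matrix(rpois(12, 5), 4, 3, fprefix = "ADT")
  rownames(q) <- c("CD3", "CCR7", "CCR5", "CD10")
  out <- dropADTs(q, c("CCR7", "CCR5", "CD10"))
  expect_identical(rownames(out), "CD3")
  expect_identical(dropADTs(q, character(0)), q)
  expect_warning(same <- dropADTs(q, "CDxx"), "unknown ADT")
  expect_identical(same, q)
  expect_error(dropADTs(q, "CDxx", strict = TRUE), "unknown ADT")
  expect_error(suppressWarnings(dropADTs(q[1, , drop = FALSE], c("CD3"))),
               "every ADT")
})
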