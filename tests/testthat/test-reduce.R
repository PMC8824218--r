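test_that("PCA explains rank-1 data with a single component", {
  t_ <- seq(0, 1, length.out = 10)
  x <- rbind(a = 2 * t_, b = -1 * t_, c = 5 * t_)
  colnames(x) <- paste0("C", 1:10)
  rep <- pcaReduce(x, "all")
  ev <- explainedVariance(rep)
  expect_gt(ev[1] / sum(ev), 1 - 1e-10)
})

test_that("full PCA reconstructs the centred input", {
  withr::with_seed(2, {
    x <- named_matrix(rnorm(50 * 200), 50, 200)
    rep <- pcaReduce(x, "all")
    centred <- x - rowMeans(x)
    recon <- loadings(rep) %*% scores(rep)
    expect_lt(max(abs(recon - centred)), 1e-8)
  })
})

test_that("PC1 variance matches a covariance eigenvalue oracle", {
  pts <- rbind(f1 = c(0, 1, 2, 3), f2 = c(0, 1, 2, 3.1))
  colnames(pts) <- paste0("C", 1:4)
  rep <- pcaReduce(pts, "all")
  oracle <- eigen(stats::cov(t(pts)), symmetric = TRUE)$values
  expect_equal(explainedVariance(rep), oracle[seq_len(nComponents(rep))],
               tolerance = 1e-10)
})

test_that("PCA total variance is conserved and runs are bit-identical", {
  withr::with_seed(3, {
    x <- minMaxScale(named_matrix(rnorm(30 * 80), 30, 80))
    rep <- pcaReduce(x, "all")
    total_in <- sum(apply(x, 1, stats::var))
    expect_equal(sum(explainedVariance(rep)), total_in,
                 tolerance = 1e-8)
    expect_true(all(diff(explainedVariance(rep)) <= 1e-12))
    rep2 <- pcaReduce(x, "all")
    expect_identical(scores(rep), scores(rep2))
    # the sign convention puts the largest-|loading| entry positive
    l <- loadings(rep)
    picks <- vapply(seq_len(ncol(l)), function(j) l[which.max(abs(l[, j])), j],
                    numeric(1))
    expect_true(all(picks > 0))
  })
})

test_that("permuting cells permutes scores identically", {
  withr::with_seed(4, {
    x <- named_matrix(rnorm(20 * 40), 20, 40)
    perm <- sample(ncol(x))
    r1 <- pcaReduce(x, 5)
    r2 <- pcaReduce(x[, perm], 5)
    expect_equal(scores(r1)[, perm], scores(r2), tolerance = 1e-10)
  })
})

test_that("PCA rejects degenerate inputs", {
  x <- named_matrix(rep(1, 12), 3, 4)
  expect_error(pcaReduce(x), "zero-variance")
  expect_error(pcaReduce(named_matrix(rnorm(12), 3, 4), k = 10),
               "exceeds the number of features")
})

test_that("elbow selection keeps the components before the bend", {
  expect_equal(elbowSelect(c(50, 30, 2, 1.9, 1.8, 1.7)), 2)
  # a straight-line decay has no curvature: smallest k
  expect_equal(elbowSelect(seq(10, 1)), 1)
  expect_error(elbowSelect(c(3, 1)), "at least 3")
})

test_that("passthrough representation keeps the scaled ADTs, ordered by variance", {
  xa <- minMaxScale(clrTransform(adtCounts(toy_experiment()), 1))
  rep <- passthroughRep(xa)
  expect_equal(nComponents(rep), nrow(xa))
  expect_true(all(diff(explainedVariance(rep)) <= 0))
  expect_setequal(rownames(scores(rep)), rownames(xa))
  expect_equal(scores(rep)[rownames(xa)[1], ], xa[1, ])
})

test_that("integration stacks rescaled representations and re-reduces", {
  withr::with_seed(6, {
    xr <- minMaxScale(named_matrix(rnorm(40 * 60), 40, 60))
    xa <- minMaxScale(named_matrix(abs(rnorm(12 * 60)), 12, 60, fprefix = "ADT"))
    rr <- pcaReduce(xr, 10, modality = "rna")
    ra <- pcaReduce(xa, 10, modality = "adt")
    mm <- integrateModalities(rr, ra, k = "auto")
    expect_identical(modality(mm), "multimodal")
    expect_lte(nComponents(mm), 20)
    expect_identical(colnames(scores(mm)), colnames(xr))
    # explicit k mirrors the published configurations: a 10-component RNA
    # representation stacked with a 10-ADT passthrough gives a 20-row input
    stacked <- rbind(minMaxScale(scores(rr)), minMaxScale(scores(ra)))
    expect_equal(nrow(stacked), 20)
    mm15 <- integrateModalities(rr, ra, k = 15)
    expect_equal(nComponents(mm15), 15)
    # total variance of the stacked input is conserved by the second PCA
    full <- integrateModalities(rr, ra, k = 20)
    expect_equal(sum(explainedVariance(full)),
                 sum(apply(stacked, 1, stats::var)), tolerance = 1e-8)
  })
})

test_that("integration degenerates gracefully and rejects misaligned cells", {
  withr::with_seed(8, {
    xr <- minMaxScale(named_matrix(rnorm(20 * 30), 20, 30))
    rr <- pcaReduce(xr, 5, modality = "rna")
    empty <- methods::new("LowDimRep",
                          scores = matrix(0, 0, 30,
                                          dimnames = list(NULL, colnames(xr))),
                          explainedVariance = numeric(0),
                          loadings = matrix(0, 0, 0), modality = "adt")
    alone <- integrateModalities(rr, empty, k = 3)
    direct <- pcaReduce(minMaxScale(scores(rr)), 3, modality = "multimodal")
    expect_equal(abs(scores(alone)), abs(scores(direct)), tolerance = 1e-10,
                 ignore_attr = TRUE)

    shuffled <- pcaReduce(xr[, rev(seq_len(ncol(xr)))], 5, modality = "adt")
    expect_error(integrateModalities(rr, shuffled), "cell order mismatch")
  })
})

test_that("multimodal space separates pairs that single modalities cannot", {
  ce <- simulateCiteSeq(citePreset("mixed_five"))
  truth <- ce$true_label
  xr <- minMaxScale(logNormalize(screenGenes(rnaCounts(ce))))
  xa <- minMaxScale(clrTransform(adtCounts(ce), 1))
  rr <- pcaReduce(xr, 10, modality = "rna")
  ra <- passthroughRep(xa)
  mm <- integrateModalities(rr, ra, k = 15)

  sil <- function(rep, pair) {
    sel <- truth %in% pair
    d <- stats::dist(t(scores(rep)[, sel, drop = FALSE]))
    mean(cluster::silhouette(as.integer(truth[sel]), d)[, "sil_width"])
  }
  rna_pair <- c(0, 1)  # separable only in RNA
  adt_pair <- c(2, 3)  # separable only in ADT
  expect_gt(sil(mm, rna_pair), 0)
  expect_gt(sil(mm, adt_pair), 0)
  expect_gt(sil(rr, rna_pair), sil(rr, adt_pair))
  expect_gt(sil(ra, adt_pair), sil(ra, rna_pair))
  expect_lt(sil(rr, adt_pair), 0.1)
  expect_lt(sil(ra, rna_pair), 0.1)
})
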