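# small deterministic fixtures used across test files

named_matrix <- function(values, nrow, ncol, fprefix = "G", cprefix = "C") {
  matrix(values, nrow, ncol,
         dimnames = list(paste0(fprefix, seq_len(nrow)),
                         paste0(cprefix, seq_len(ncol))))
}

# paired toy experiment: 3 genes x 4 cells, 2 ADTs
toy_experiment <- function() {
  rna <- named_matrix(c(0, 2, 5, 2, 0, 5, 1, 1, 0, 3, 0, 2), 3, 4)
  adt <- named_matrix(c(10, 40, 20, 30, 15, 25, 50, 5), 2, 4, fprefix = "ADT")
  CiteExperiment(rna, adt)
}

# two well-separated Gaussian blobs in 2-D, n per blob
two_blobs <- function(n = 30, sep = 20, seed = 42) {
  withr::with_seed(seed, {
    x <- cbind(matrix(rnorm(2 * n), 2, n), matrix(rnorm(2 * n) + sep, 2, n))
    colnames(x) <- paste0("C", seq_len(2 * n))
    rownames(x) <- c("d1", "d2")
    x
  })
}

expect_ari_at_least <- function(labels, truth, min_ari) {
  ari <- mclust::adjustedRandIndex(labels, truth)
  expect_gte(ari, min_ari)
  invisible(ari)
}

# restricted ARI over the cells belonging to two ground-truth clusters
pair_ari <- function(labels, truth, pair) {
  sel <- truth %in% pair
  mclust::adjustedRandIndex(labels[sel], truth[sel])
}

# a clustering "resolves" a ground-truth pair when the two populations have
# distinct modal predicted clusters; returns the majority-mapping accuracy over
# the pair's cells, or 0 when the modal clusters coincide (pair not separated)
pair_resolution <- function(labels, truth, pair) {
  sel <- truth %in% pair
  tab <- table(truth[sel], labels[sel])
  modal <- colnames(tab)[apply(tab, 1, which.max)]
  if (modal[1] == modal[2]) return(0)
  sum(tab[1, modal[1]], tab[2, modal[2]]) / sum(tab)
}
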