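# shared fixture builders; everything is generated in code at test time

# strictly positive logistic-normal composition with an optional planted
# correlation matrix (identity by default)
makeComposition <- function(n, p, R = diag(p), seed = 1,
                            taxa = sprintf("g%02d", seq_len(p))) {
  withr::with_seed(seed, {
    Z <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = R)
    w <- exp(Z)
    comp <- w / rowSums(w)
    dimnames(comp) <- list(sprintf("s%04d", seq_len(n)), taxa)
    comp
  })
}

# correlation matrix with disjoint planted pairs
plantedCorr <- function(p, pairs, rhos) {
  R <- diag(p)
  for (k in seq_along(rhos)) {
    R[pairs[k, 1], pairs[k, 2]] <- R[pairs[k, 2], pairs[k, 1]] <- rhos[k]
  }
  R
}

# small two-group, three-region config with planted differential edges
smallStudyConfig <- function(p = 15, nPer = 200, nDiff = 5,
                             rhoA = 0.6, rhoB = 0, depth = 20000,
                             ...) {
  taxa <- sprintf("Genus%03d", seq_len(p))
  de <- data.frame(taxonA = taxa[seq_len(nDiff)],
                   taxonB = taxa[nDiff + seq_len(nDiff)],
                   rhoA = rep_len(rhoA, nDiff),
                   rhoB = rep_len(rhoB, nDiff))
  simConfig(taxa = taxa,
            nPerStratum = matrix(nPer, 2, 3),
            baseSparsity = 0.02, differentialEdges = de,
            depth = depth, ...)
}

# rank-based AUC of score for a logical label
scoreAUC <- function(score, label) {
  r <- rank(score)
  (sum(r[label]) - sum(label) * (sum(label) + 1) / 2) /
    (sum(label) * sum(!label))
}
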