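# shared fixtures built in code

yTree <- function(resistance = c(1, 2, 3)) {
  buildTree(cbind(c(1, 2, 2), c(2, 3, 4)),
            radius = c(2, 1.5, 1.5), length = c(12, 9, 9),
            resistance = resistance)
}

# 8-node reference topology: v1-e1-v2, v2 branching to v3/v4, each of
# which branches to two terminals (v5..v8)
twoLevelTree <- function(resistance = 1:7) {
  buildTree(cbind(c(1, 2, 2, 3, 3, 4, 4), c(2, 3, 4, 5, 6, 7, 8)),
            radius = c(4, 3, 3, 2, 2, 2, 2),
            length = c(24, 18, 18, 12, 12, 12, 12),
            resistance = resistance)
}

# random rooted tree: a trachea plus nodes attached uniformly at random,
# with lognormal resistances; returns a validated canonical AirwayTree
randomTree <- function(nBranchesTotal, seed) {
  stopifnot(nBranchesTotal >= 2)
  withr::with_seed(seed, {
    prox <- c(1L, 2L)
    for (b in 3:nBranchesTotal) {
      prox <- c(prox, sample(2:b, 1))   # attach below the trachea
    }
    rad <- exp(rnorm(nBranchesTotal, log(2), 0.3))
    res <- exp(rnorm(nBranchesTotal, 0, 1))
    buildTree(cbind(prox, seq_len(nBranchesTotal) + 1L),
              radius = rad, length = 6 * rad, resistance = res)
  })
}

relErr <- function(x, ref) {
  sqrt(sum((x - ref)^2)) / sqrt(sum(ref^2))
}
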