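test_that("subtree maps satisfy the incidence identity exactly", {
  tr <- yTree()
  sm <- subtreeMaps(tr)
  expect_equal(as.matrix(sm$S),
               rbind(c(1, 0, 0), c(1, 1, 0), c(1, 0, 1)),
               ignore_attr = TRUE)
  for (seed in 1:5) {
    rt <- randomTree(40, seed)
    sm <- subtreeMaps(rt)
    nv <- nNodes(rt)
    expect_equal(as.numeric(sm$S[, 1]), rep(1, nv - 1))  # root branch column
    N <- incidenceMatrix(rt)
    SNt <- as.matrix(sm$S %*% Matrix::t(N))
    expect_equal(SNt[, 1], rep(1, nv - 1))
    expect_equal(SNt[, -1], -diag(nv - 1), ignore_attr = TRUE)
    # terminal map row sums are root-to-terminal path lengths
    paths <- lapply(terminalNodes(rt), function(t) {
      n <- 0L; j <- t - 1L
      while (j >= 1L) { n <- n + 1L; j <- rt@prox[j] - 1L }
      n
    })
    expect_equal(as.numeric(Matrix::rowSums(sm$T)), unlist(paths))
  }
})

test_that("the three Maury constructions agree on hand examples", {
  tr <- yTree()
  expect_equal(mauryMatrix(tr), rbind(c(3, 1), c(1, 4)))
  expect_equal(mauryMatrix(tr, "lca"), rbind(c(3, 1), c(1, 4)))
  expect_equal(mauryMatrix(tr, "schur"), rbind(c(3, 1), c(1, 4)),
               tolerance = 1e-10)
  # symmetric single division: diagonal r1 + r2, off-diagonal r1
  w <- buildTree(cbind(c(1, 2, 2), c(2, 3, 4)), radius = c(2, 1.6, 1.6),
                 length = c(12, 9.6, 9.6), resistance = c(5, 3, 3))
  expect_equal(mauryMatrix(w), rbind(c(8, 5), c(5, 8)))
  # single-terminal path tree: scalar total resistance
  p <- buildTree(cbind(c(1, 2), c(2, 3)), radius = c(1, 1),
                 length = c(6, 6), resistance = c(2, 7))
  expect_equal(mauryMatrix(p), matrix(9, 1, 1))
  expect_equal(mauryMatrix(p, "schur"), matrix(9, 1, 1), tolerance = 1e-10)
  # 8-node reference tree with random resistances
  r <- withr::with_seed(21, exp(rnorm(7)))
  t8 <- twoLevelTree(resistance = r)
  expect_equal(mauryMatrix(t8, "schur"), mauryMatrix(t8), tolerance = 1e-10)
})

test_that("shared-path entries equal root-to-LCA resistance", {
  r <- 1:7
  tr <- twoLevelTree(resistance = r)
  R <- mauryMatrix(tr)
  # terminals v5, v6 share branches e1, e2; v5, v7 share only e1
  expect_equal(R[1, 2], r[1] + r[2])
  expect_equal(R[1, 3], r[1])
  expect_equal(diag(R), c(r[1] + r[2] + r[4], r[1] + r[2] + r[5],
                          r[1] + r[3] + r[6], r[1] + r[3] + r[7]))
})

test_that("construction equivalence holds across randomized trees", {
  for (seed in 1:25) {
    nb <- withr::with_seed(seed * 7, sample(10:80, 1))
    rt <- randomTree(nb, seed)
    Rf <- mauryMatrix(rt)
    scale <- max(abs(Rf))
    expect_lt(max(abs(Rf - mauryMatrix(rt, "lca"))) / scale, 1e-10)
    expect_lt(max(abs(Rf - mauryMatrix(rt, "schur"))) / scale, 1e-10)
    expect_equal(Rf, t(Rf))
    expect_true(all(Rf > 0))
  }
})

test_that("Maury spectrum matches the characteristic polynomial and trace identities", {
  tr <- yTree()
  dec <- maurySpectrum(tr)
  expect_equal(dec@values, c((7 + sqrt(5)) / 2, (7 - sqrt(5)) / 2))
  for (seed in 26:30) {
    rt <- randomTree(50, seed)
    dec <- maurySpectrum(rt)
    expect_true(all(dec@values > 0))
    R <- mauryMatrix(rt)
    expect_equal(sum(dec@values), sum(diag(R)), tolerance = 1e-10)
    # Perron mode: simple top eigenvalue with a sign-constant eigenvector
    expect_gt(dec@values[1], dec@values[2])
    v1 <- dec@vectors[, 1]
    expect_true(all(v1 > 0) || all(v1 < 0))
  }
})

test_that("matrix-free Lanczos modes agree with the dense decomposition", {
  rt <- randomTree(150, 31)
  dense <- maurySpectrum(rt, method = "dense")
  lan <- maurySpectrum(rt, nModes = 6, which = "largest", method = "lanczos")
  expect_equal(lan@values, dense@values[1:6], tolerance = 1e-8)
  for (k in 1:6) {
    expect_equal(abs(sum(lan@vectors[, k] * dense@vectors[, k])), 1,
                 tolerance = 1e-6)
  }
  small <- maurySpectrum(rt, nModes = 4, which = "smallest", method = "lanczos")
  nT <- nTerminals(rt)
  expect_equal(sort(small@values), sort(dense@values[(nT - 3):nT]),
               tolerance = 1e-8)
})

test_that("modal flux reconstruction equals the Laplacian-route solve", {
  tr <- yTree()
  dec <- maurySpectrum(tr)
  fl <- fluxFromModes(dec, c(1, 1))
  expect_equal(fl$QTerminal, -c(3 / 11, 2 / 11), tolerance = 1e-12)
  # a single mode contributes a flux parallel to its eigenvector
  one <- fluxFromModes(dec, c(1, 1), nModes = 1)
  v1 <- dec@vectors[, 1]
  expect_equal(abs(sum(one$QTerminal * v1)),
               sqrt(sum(one$QTerminal^2)), tolerance = 1e-12)
  for (seed in 32:36) {
    rt <- randomTree(70, seed)
    nT <- nTerminals(rt)
    dP <- withr::with_seed(seed, runif(nT))
    direct <- solveFixedPressure(rt, dP)
    fl <- fluxFromModes(maurySpectrum(rt), dP)
    expect_lt(relErr(fl$QTerminal, direct@QTerminal), 1e-8)
  }
})

test_that("symmetric trees drive only sign-constant modes under uniform pressure", {
  w <- weibelTree(4, 0)
  dec <- maurySpectrum(w)
  q <- fluxFromModes(dec, 1)$coefficients
  active <- abs(q) > 1e-10 * max(abs(q))
  for (k in which(active)) {
    v <- dec@vectors[, k]
    expect_true(all(v > -1e-10) || all(v < 1e-10))
  }
})

test_that("delta_R matches its closed form and the dense Frobenius oracle", {
  expect_equal(deltaR(c(4, 1), 1), 1 / sqrt(17))
  expect_equal(deltaR(c(4, 1), 2), 0)
  expect_equal(deltaR(c(4, 1), 0), 1)
  rt <- randomTree(60, 37)
  dec <- maurySpectrum(rt)
  R <- mauryMatrix(rt)
  Rinv <- solve(R)
  nT <- length(dec@values)
  V <- dec@vectors
  for (M in c(0, 1, 5, nT)) {
    keep <- if (M == 0) integer(0) else (nT - M + 1):nT
    partial <- if (M == 0) 0 * Rinv
               else V[, keep, drop = FALSE] %*%
                    ((1 / dec@values[keep]) * t(V[, keep, drop = FALSE]))
    oracle <- norm(Rinv - partial, "F") / norm(Rinv, "F")
    expect_equal(deltaR(dec@values, M), oracle, tolerance = 1e-10)
  }
  deltas <- vapply(0:nT, function(M) deltaR(dec@values, M), numeric(1))
  expect_true(all(diff(deltas) <= 1e-14))
})

test_that("Maury and Laplacian routes agree on identical boundary conditions", {
  for (seed in 38:42) {
    rt <- randomTree(120, seed)
    nT <- nTerminals(rt)
    dP <- withr::with_seed(seed + 100, runif(nT, 0.2, 2))
    lap <- solveFixedPressure(rt, dP)@QTerminal
    mau <- -solve(mauryMatrix(rt), dP)
    expect_lt(relErr(mau, lap), 1e-8)
  }
})

test_that("mode counting honours ranking, ties, and the accuracy limit", {
  tr <- yTree()
  # brute-force oracle over subset sizes using the explicit 2x2 spectrum
  dec <- maurySpectrum(tr)
  direct <- solveFixedPressure(tr, c(1, 1))@QTerminal
  q <- fluxFromModes(dec, c(1, 1))$coefficients
  o <- order(-abs(q))
  bruteM <- function(tol) {
    for (M in 0:2) {
      Q <- if (M == 0) c(0, 0)
           else -dec@vectors[, o[1:M], drop = FALSE] %*% q[o[1:M]]
      if (relErr(as.numeric(Q), direct) <= tol) return(M)
    }
  }
  res <- minModesForAccuracy(tr, c(1, 1), 0.75)
  expect_equal(res$M, bruteM(sqrt(1 - 0.75)))
  expect_equal(res$M, 1L)
  strict <- minModesForAccuracy(tr, c(1, 1), 0.75, metric = "l2")
  expect_equal(strict$M, bruteM(0.25))
  # accuracy -> 1 requires every mode carrying flux
  full <- minModesForAccuracy(tr, c(1, 1), 1 - 1e-12)
  expect_equal(full$M, 2L)
  # symmetric tree: only the Perron mode is needed, despite degeneracy
  w <- weibelTree(5, 0)
  expect_equal(minModesForAccuracy(w, 1, 0.75)$M, 1L)
  expect_equal(minModesForAccuracy(w, 1, 0.75, metric = "l2")$M, 1L)
})

test_that("the dominant flux mode migrates from Perron to low-resistance end with asymmetry", {
  idxDominant <- vapply(c(0, 0.5, 0.98), function(A) {
    tr <- weibelTree(6, A)
    dec <- maurySpectrum(tr)
    q <- fluxFromModes(dec, 1)$coefficients
    which.max(abs(q))
  }, numeric(1))
  expect_equal(idxDominant[1], 1)            # symmetric: Perron mode leads
  expect_true(all(diff(idxDominant) > 0))    # drifts toward the small-mu end
  expect_gt(idxDominant[3], 0.9 * nTerminals(weibelTree(6, 0.98)))
})
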