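test_that("Laplacian assembly matches hand computations", {
  tr <- yTree()
  sys <- buildLaplacian(tr)
  expect_equal(as.numeric(sys@Lint), 11 / 6)
  expect_equal(as.numeric(sys@L %*% rep(1, 4)), rep(0, 4))
  # two-branch path graph with unit resistances: textbook Laplacian
  path <- buildTree(cbind(c(1, 2), c(2, 3)), radius = c(1, 1),
                    length = c(6, 6), resistance = c(1, 1))
  expect_equal(as.matrix(buildLaplacian(path)@L),
               rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)),
               ignore_attr = TRUE)
})

test_that("the internal block equals its three-part block-form assembly", {
  for (seed in 1:5) {
    tr <- randomTree(35, seed)
    sys <- buildLaplacian(tr)
    part <- sys@partition
    r <- resistances(tr)
    N <- incidenceMatrix(tr)
    Nint <- N[part@internalNodes, part@internalBranches, drop = FALSE]
    # root-branch anchor: indicator of the root branch's distal node
    a <- as.numeric(N[part@internalNodes, part@rootBranch])
    direct <- (1 / r[part@rootBranch]) * tcrossprod(a) +
      as.matrix(Nint %*% diag(1 / r[part@internalBranches],
                              length(part@internalBranches)) %*% t(Nint)) +
      as.matrix(sys@B %*% diag(sys@gammaTerm,
                               length(sys@gammaTerm)) %*% t(sys@B))
    expect_equal(as.matrix(sys@Lint), direct, ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})

test_that("fixed-pressure solve reproduces the series-parallel hand solution", {
  sol <- solveFixedPressure(yTree(), c(1, 1))
  expect_equal(sol@QTerminal, -c(3 / 11, 2 / 11))
  expect_equal(sol@QRoot, 5 / 11)
  expect_equal(sol@dPInternal, 5 / 11)
  # zero boundary condition: no flow anywhere
  z <- solveFixedPressure(yTree(), c(0, 0))
  expect_equal(z@qBranch, rep(0, 3))
  # symmetric tree under uniform pressure: equal terminal fluxes
  w <- weibelTree(5, 0)
  sw <- solveFixedPressure(w, 1)
  expect_equal(sw@QTerminal, rep(sw@QTerminal[1], 32))
})

test_that("flux is conserved at internal nodes and matches the dense operator identity", {
  for (seed in 6:9) {
    tr <- randomTree(45, seed)
    sys <- buildLaplacian(tr)
    nT <- nTerminals(tr)
    dP <- withr::with_seed(seed, runif(nT, 0.5, 1.5))
    sol <- solveFixedPressure(sys, dP)
    N <- incidenceMatrix(tr)
    nodeFlux <- as.numeric(N %*% sol@qBranch)
    expect_equal(nodeFlux[sys@partition@internalNodes],
                 rep(0, length(sys@partition@internalNodes)),
                 tolerance = 1e-10)
    expect_equal(sol@QRoot, -sum(sol@QTerminal), tolerance = 1e-10)
    expect_equal(nodeFlux[sys@partition@terminalNodes], sol@QTerminal,
                 tolerance = 1e-10)
    # dense one-shot operator: Q_term = Gamma [B^T Lint^-1 B Gamma - I] dP
    G <- diag(sys@gammaTerm, nT)
    dense <- G %*% (t(as.matrix(sys@B)) %*%
                    solve(as.matrix(sys@Lint), as.matrix(sys@B) %*% G) -
                    diag(nT)) %*% dP
    expect_equal(sol@QTerminal, as.numeric(dense), tolerance = 1e-8)
  }
})

test_that("Laplacian spectrum is positive, orthonormal and reconstructs L_int", {
  tr <- yTree()
  dec <- laplacianSpectrum(buildLaplacian(tr))
  expect_equal(dec@values, 11 / 6)
  rt <- randomTree(40, 11)
  sys <- buildLaplacian(rt)
  dec <- laplacianSpectrum(sys)
  expect_true(all(dec@values > 0))
  expect_false(is.unsorted(dec@values))
  V <- dec@vectors
  expect_equal(crossprod(V), diag(ncol(V)), ignore_attr = TRUE,
               tolerance = 1e-10)
  recon <- V %*% (dec@values * t(V))
  expect_equal(recon, as.matrix(sys@Lint), ignore_attr = TRUE,
               tolerance = 1e-8)
  # iterative extremal modes agree with the dense decomposition
  part <- laplacianSpectrum(sys, nModes = 3, which = "smallest")
  expect_equal(part@values, dec@values[1:3], tolerance = 1e-8)
})

test_that("modal pressure solution converges to the direct solve", {
  tr <- yTree()
  sys <- buildLaplacian(tr)
  dec <- laplacianSpectrum(sys)
  m <- laplacianModalSolution(dec, sys, c(1, 1))
  expect_equal(m@QTerminal, -c(3 / 11, 2 / 11), tolerance = 1e-12)
  # zero modes: dP_int = 0 so Q_term = -Gamma dP_term
  m0 <- laplacianModalSolution(dec, sys, c(1, 1), nModes = 0)
  expect_equal(m0@QTerminal, -sys@gammaTerm)
  rt <- randomTree(60, 12)
  rsys <- buildLaplacian(rt)
  rdec <- laplacianSpectrum(rsys)
  dP <- rep(1, nTerminals(rt))
  direct <- solveFixedPressure(rsys, dP)
  full <- laplacianModalSolution(rdec, rsys, dP)
  expect_lt(relErr(full@QTerminal, direct@QTerminal), 1e-8)
  # adding modes in descending |p_k| order shrinks the internal-pressure
  # error monotonically (the modal increments are orthogonal in that space)
  ord <- order(-abs(full@coefficients))
  errs <- vapply(seq_along(ord), function(M) {
    relErr(laplacianModalSolution(rdec, rsys, dP, nModes = M,
                                  modeOrder = ord)@dPInternal,
           direct@dPInternal)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[length(errs)], 1e-10)
})

test_that("delta_L matches the dense Frobenius oracle and its closed form", {
  expect_equal(deltaL(c(1, 2), 1), 1 / sqrt(5))
  expect_equal(deltaL(c(1, 2), 2), 0)
  expect_equal(deltaL(c(3, 7, 9), 0), 1)
  for (seed in 13:15) {
    rt <- randomTree(20, seed)
    sys <- buildLaplacian(rt)
    dec <- laplacianSpectrum(sys)
    Linv <- solve(as.matrix(sys@Lint))
    nrmInv <- norm(Linv, "F")
    V <- dec@vectors
    for (M in c(0, 1, floor(length(dec@values) / 2), length(dec@values))) {
      partial <- if (M == 0) 0 * Linv
                 else V[, 1:M, drop = FALSE] %*%
                      ((1 / dec@values[1:M]) * t(V[, 1:M, drop = FALSE]))
      oracle <- norm(Linv - partial, "F") / nrmInv
      expect_equal(deltaL(dec@values, M), oracle, tolerance = 1e-10)
    }
    deltas <- vapply(0:length(dec@values),
                     function(M) deltaL(dec@values, M), numeric(1))
    expect_true(all(diff(deltas) <= 1e-14))
  }
})
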