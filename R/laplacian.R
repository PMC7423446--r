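#' Assemble the conductance Laplacian and its boundary blocks
#'
#' The full conductance Laplacian is \eqn{L = N\,diag(r)^{-1}N^T} with N the
#' signed incidence matrix, so branch conductances 1/r act as edge weights.
#' Imposing pressure boundary conditions at the root and terminal nodes
#' reduces the flow problem to the internal block \eqn{L_{int}}, which is
#' symmetric positive definite on connected trees, coupled to the terminal
#' pressure drops through \eqn{B\,\Gamma_{term}} where B is the incidence of
#' internal nodes onto terminal branches and \eqn{\Gamma_{term}} the
#' terminal conductances. The internal block is both extracted from L and
#' assembled directly from its three-part sum (root-branch anchor +
#' internal-branch Laplacian + terminal coupling); the two agree exactly.
#'
#' @param x an [AirwayTree-class] with resistances set
#' @return a [LaplacianSystem-class]
#' @rdname buildLaplacian
#' @export
setMethod("buildLaplacian", "AirwayTree", function(x) {
  r <- resistances(x)
  if (any(is.na(r))) stop("resistances must be set; see poiseuilleResistances()")
  N <- incidenceMatrix(x)
  L <- N %*% Matrix::Diagonal(x = 1 / r) %*% Matrix::t(N)
  part <- blockPartition(x)
  int <- part@internalNodes
  termB <- part@terminalBranches
  Lint <- L[int, int, drop = FALSE]
  # B: +1 where an internal node is proximal to a terminal branch
  proxTerm <- x@prox[termB]
  keep <- proxTerm %in% int
  B <- Matrix::sparseMatrix(
    i = match(proxTerm[keep], int),
    j = which(keep),
    x = 1,
    dims = c(length(int), length(termB)))
  new("LaplacianSystem",
      L = L, Lint = Lint, B = B,
      gammaTerm = 1 / r[termB],
      partition = part, tree = x)
})

setMethod("show", "LaplacianSystem", function(object) {
  cat("LaplacianSystem:", nrow(object@L), "nodes,",
      nrow(object@Lint), "internal;",
      length(object@gammaTerm), "terminal branches\n")
})

#' Solve the flow problem under fixed terminal pressure drops
#'
#' Solves \eqn{L_{int}\Delta P_{int} = B\Gamma_{term}\Delta P_{term}} by a
#' sparse Cholesky factorization (the internal Laplacian of a tree is SPD
#' and very sparse), then recovers the terminal fluxes
#' \eqn{Q_{term} = \Gamma_{term}(B^T\Delta P_{int} - \Delta P_{term})} and
#' back-computes per-branch fluxes from the linear resistance relation.
#' The relative residual of the internal solve is checked against the
#' configured tolerance.
#'
#' @param x a [LaplacianSystem-class] or an [AirwayTree-class]
#' @param dPTerminal numeric of length |T|: pressure drop root-to-terminal
#'   (cmH2O), or a single value recycled to all terminals.
#' @param ... passed through when x is a tree.
#' @param config configuration list, see [airwayConfig()].
#' @return a [FlowSolution-class]
#' @examples
#' tr <- buildTree(cbind(c(1, 2, 2), c(2, 3, 4)), radius = c(2, 1.5, 1.5),
#'                 length = c(12, 9, 9), resistance = c(1, 2, 3))
#' sol <- solveFixedPressure(tr, c(1, 1))
#' sol@QTerminal   # -(3/11, 2/11)
#' @rdname solveFixedPressure
#' @export
setMethod("solveFixedPressure", "LaplacianSystem",
          function(x, dPTerminal, ..., config = airwayConfig()) {
  nT <- length(x@gammaTerm)
  if (length(dPTerminal) == 1L) dPTerminal <- rep(dPTerminal, nT)
  if (length(dPTerminal) != nT) {
    stop("dPTerminal must have one entry per terminal node (", nT, ")")
  }
  nInt <- nrow(x@Lint)
  rhs <- x@B %*% (x@gammaTerm * dPTerminal)
  if (nInt > 0) {
    fac <- Matrix::Cholesky(forceSymmetricSparse(x@Lint), LDL = FALSE)
    dPint <- as.numeric(Matrix::solve(fac, rhs))
    res <- sqrt(sum((as.numeric(x@Lint %*% dPint) - as.numeric(rhs))^2))
    nrm <- sqrt(sum(as.numeric(rhs)^2))
    if (nrm > 0 && res > config$solveTol * max(1, nrm)) {
      stop(sprintf("internal solve residual %.3e exceeds tolerance", res / nrm))
    }
  } else {
    dPint <- numeric(0)
  }
  finishFlowSolution(x, dPint, dPTerminal, method = "direct")
})

#' @rdname solveFixedPressure
#' @export
setMethod("solveFixedPressure", "AirwayTree",
          function(x, dPTerminal, ..., config = airwayConfig()) {
  solveFixedPressure(buildLaplacian(x), dPTerminal, ..., config = config)
})

# Matrix's Cholesky wants a formally symmetric sparse matrix
forceSymmetricSparse <- function(M) {
  as(Matrix::forceSymmetric(M), "CsparseMatrix")
}

# assemble a FlowSolution from internal pressure drops
finishFlowSolution <- function(system, dPint, dPTerminal, method,
                               modesUsed = NA_integer_,
                               coefficients = numeric(0)) {
  tree <- system@tree
  QTerm <- system@gammaTerm *
    (as.numeric(Matrix::crossprod(system@B, dPint)) - dPTerminal)
  nv <- nNodes(tree)
  dP <- numeric(nv)
  dP[system@partition@internalNodes] <- dPint
  dP[system@partition@terminalNodes] <- dPTerminal
  # q_j = (dP_dist - dP_prox) / r_j : positive flux runs proximal -> distal
  nb <- nBranches(tree)
  q <- (dP[seq_len(nb) + 1L] - dP[tree@prox]) / resistances(tree)
  new("FlowSolution",
      dPInternal = dPint,
      dPTerminal = dPTerminal,
      QTerminal = as.numeric(QTerm),
      qBranch = q,
      QRoot = sum(q[tree@prox == 1L]),
      method = method,
      modesUsed = modesUsed,
      coefficients = coefficients)
}

setMethod("show", "FlowSolution", function(object) {
  cat("FlowSolution (", object@method,
      if (!is.na(object@modesUsed)) paste0(", ", object@modesUsed, " modes"),
      "): ", length(object@QTerminal), " terminals, Q_root = ",
      signif(object@QRoot, 6), " l/s\n", sep = "")
})

#' Eigendecomposition of the internal conductance Laplacian
#'
#' Full decompositions use a dense symmetric eigensolver (guarded by a size
#' cap, since the convergence metric delta_L needs every eigenvalue);
#' partial decompositions of large systems use the implicitly restarted
#' Lanczos method on the sparse operator. Eigenvalues are returned in
#' ascending order with orthonormal eigenvectors, and per-pair residuals
#' are checked against the configured tolerance.
#'
#' @param system a [LaplacianSystem-class]
#' @param nModes number of eigenpairs (default: all).
#' @param which "smallest" or "largest" eigenvalues when nModes is partial.
#' @param config configuration list, see [airwayConfig()].
#' @return a [SpectralDecomposition-class] with operator "laplacian"
#' @export
laplacianSpectrum <- function(system, nModes = NULL,
                              which = c("smallest", "largest"),
                              config = airwayConfig()) {
  which <- match.arg(which)
  n <- nrow(system@Lint)
  if (n == 0) stop("tree has no internal nodes")
  if (is.null(nModes)) nModes <- n
  if (nModes > n) stop("nModes exceeds the internal dimension ", n)
  if (nModes == n) {
    if (n > config$laplacianDenseCap) {
      stop("full decomposition of dimension ", n, " exceeds the dense cap; ",
           "request fewer modes")
    }
    eig <- eigen(as.matrix(system@Lint), symmetric = TRUE)
    ord <- order(eig$values)         # ascending
    vals <- eig$values[ord]
    vecs <- eig$vectors[, ord, drop = FALSE]
    whichOut <- "all"
  } else {
    op <- function(v, extra) as.numeric(system@Lint %*% v)
    ar <- igraph::arpack(op, sym = TRUE,
                         options = list(n = n, nev = nModes,
                                        ncv = min(n, max(2 * nModes + 1, 20)),
                                        which = if (which == "smallest") "SA" else "LA",
                                        maxiter = 5000))
    ord <- order(ar$values)
    vals <- ar$values[ord]
    vecs <- matrix(ar$vectors, nrow = n)[, ord, drop = FALSE]
    whichOut <- which
  }
  resid <- spectralResiduals(function(v) as.numeric(system@Lint %*% v),
                             vals, vecs)
  if (any(resid > config$eigTol)) {
    stop(sprintf(
      "laplacian eigensolve failed to converge: max relative residual %.3e",
      max(resid)))
  }
  new("SpectralDecomposition", operator = "laplacian", values = vals,
      vectors = vecs, which = whichOut, dim = as.integer(n),
      residuals = resid)
}

# relative residuals ||A v - lambda v|| / max(|lambda|)
spectralResiduals <- function(apply, vals, vecs) {
  scale <- max(abs(vals))
  vapply(seq_along(vals), function(k) {
    sqrt(sum((apply(vecs[, k]) - vals[k] * vecs[, k])^2)) / scale
  }, numeric(1))
}

#' @name SpectralDecomposition-accessors
#' @title Accessors for spectral decompositions
#' @param x a [SpectralDecomposition-class]
#' @return \code{eigenValues} returns the ordered eigenvalues;
#'   \code{eigenVectors} the matrix of eigenvectors (one column per mode).
NULL

#' @rdname SpectralDecomposition-accessors
#' @export
setMethod("eigenValues", "SpectralDecomposition", function(x) x@values)

#' @rdname SpectralDecomposition-accessors
#' @export
setMethod("eigenVectors", "SpectralDecomposition", function(x) x@vectors)

setMethod("show", "SpectralDecomposition", function(object) {
  cat("SpectralDecomposition (", object@operator, ", ", object@which, "): ",
      length(object@values), " of ", object@dim, " modes, range [",
      signif(min(object@values), 6), ", ", signif(max(object@values), 6),
      "]\n", sep = "")
})

#' Modal solution of the internal pressure problem
#'
#' Expands the internal pressure drop in the Laplacian eigenbasis,
#' \eqn{\Delta P_{int} = \sum_k (\hat u_k^T B \Gamma_{term} \Delta P_{term}
#' / \lambda_k)\,\hat u_k}, truncated to \code{nModes} terms, and recovers
#' terminal fluxes. Mode k's weight in the expansion is the coefficient
#' \eqn{p_k}. With all modes this reproduces the direct sparse solve.
#'
#' @param decomposition a laplacian [SpectralDecomposition-class] of the
#'   same system.
#' @param system the [LaplacianSystem-class].
#' @param dPTerminal numeric of length |T| (or scalar, recycled).
#' @param nModes number of modes to keep, in the decomposition's stored
#'   order (default: all available).
#' @param modeOrder optional explicit ordering (indices into the stored
#'   modes) from which the first nModes are taken, e.g. by descending
#'   |p_k|.
#' @return a [FlowSolution-class] with modal coefficients p_k attached
#' @export
laplacianModalSolution <- function(decomposition, system, dPTerminal,
                                   nModes = NULL, modeOrder = NULL) {
  stopifnot(decomposition@operator == "laplacian")
  nT <- length(system@gammaTerm)
  if (length(dPTerminal) == 1L) dPTerminal <- rep(dPTerminal, nT)
  nAvail <- length(decomposition@values)
  if (nrow(decomposition@vectors) != nrow(system@Lint)) {
    stop("decomposition does not match the system's internal dimension")
  }
  if (is.null(nModes)) nModes <- nAvail
  if (nModes > nAvail) stop("nModes exceeds the ", nAvail, " available modes")
  rhs <- as.numeric(system@B %*% (system@gammaTerm * dPTerminal))
  pAll <- as.numeric(crossprod(decomposition@vectors, rhs)) /
    decomposition@values
  keep <- if (is.null(modeOrder)) seq_len(nModes) else modeOrder[seq_len(nModes)]
  dPint <- if (nModes == 0) numeric(nrow(system@Lint))
           else as.numeric(decomposition@vectors[, keep, drop = FALSE] %*%
                           pAll[keep])
  finishFlowSolution(system, dPint, dPTerminal, method = "modal",
                     modesUsed = as.integer(nModes), coefficients = pAll)
}

#' Spectral truncation discrepancy of the internal Laplacian inverse
#'
#' Normalized Frobenius distance between the inverse operator and its
#' truncated spectral reconstruction keeping the M smallest-eigenvalue
#' modes. Because the eigenbasis is orthonormal this reduces to
#' \eqn{\sqrt{\sum_{k > M}\lambda_k^{-2} / \sum_k \lambda_k^{-2}}}: 1 at
#' M = 0, 0 at the full spectrum, nonincreasing in M, with the
#' smallest-eigenvalue modes contributing most.
#'
#' @param eigenvalues the complete nonzero spectrum, ascending.
#' @param M number of modes kept (counting from the smallest eigenvalue).
#' @return a value in [0, 1]
#' @export
deltaL <- function(eigenvalues, M) {
  n <- length(eigenvalues)
  if (M < 0 || M > n) stop("M must be between 0 and ", n)
  w <- eigenvalues^-2
  sqrt(sum(w[seq_len(n) > M]) / sum(w))
}
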