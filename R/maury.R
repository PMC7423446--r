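#' Subtree membership maps
#'
#' The matrix S maps each branch to the set of nodes descended from it
#' (including its own distal node): S has one row per non-root node
#' (row i is node i+1) and one column per branch, with a 1 where the node
#' lies in the branch's distal subtree. Its first column is all ones, every
#' branch's column is the sum of its children's columns plus its own
#' distal-node indicator, and S satisfies the exact identity
#' \eqn{S N^T = (e, -I)} with N the incidence matrix. The terminal map T
#' consists of the final |T| rows of S; its row sums are the root-to-
#' terminal path lengths.
#'
#' @param x an [AirwayTree-class]
#' @return list with sparse 0/1 matrices \code{S} ((|V|-1) x |E|) and
#'   \code{T} (|T| x |E|)
#' @rdname subtreeMaps
#' @export
setMethod("subtreeMaps", "AirwayTree", function(x) {
  nb <- nBranches(x)
  nv <- nb + 1L
  # node n's ancestor branches are n-1, then prox[n-1]-1, ... up to the root
  ii <- vector("list", nv - 1L)
  for (n in 2:nv) {
    path <- integer(0)
    j <- n - 1L
    while (j >= 1L) {
      path <- c(path, j)
      j <- x@prox[j] - 1L
    }
    ii[[n - 1L]] <- path
  }
  lens <- lengths(ii)
  S <- Matrix::sparseMatrix(
    i = rep(seq_len(nv - 1L), lens),
    j = unlist(ii, use.names = FALSE),
    x = 1,
    dims = c(nv - 1L, nb))
  nT <- nTerminals(x)
  list(S = S, T = S[(nv - nT):(nv - 1L), , drop = FALSE])
})

#' The Maury operator of a resistive tree
#'
#' A symmetric positive-definite |T| x |T| operator acting on the terminal
#' nodes: entry (i, i') is the total resistance of the branches shared by
#' the root-to-terminal paths of i and i', equivalently the resistance from
#' the root to the lowest common ancestor of the two terminals. It relates
#' terminal pressure drops to terminal fluxes via
#' \eqn{R\,Q_{term} = -\Delta P_{term}}, and can be read as the weighted
#' adjacency matrix of a complete graph (with self-loops) on the terminal
#' nodes. Its entries are strictly positive (every pair shares at least the
#' root branch), so by Perron-Frobenius its largest eigenvalue is simple
#' with a sign-constant eigenvector.
#'
#' Three independent constructions are provided and agree elementwise:
#' \describe{
#'   \item{factors}{\eqn{R = T\,diag(r)\,T^T} from the sparse terminal
#'     subtree map (the default).}
#'   \item{lca}{explicit shared-path resistance sums per terminal pair; an
#'     O(|T|^2 depth) oracle for cross-validation.}
#'   \item{schur}{\eqn{R = (\Gamma_{term} - \Gamma_{term} B^T L_{int}^{-1}
#'     B \Gamma_{term})^{-1}}, inverting the terminal flux response of the
#'     Laplacian system.}
#' }
#'
#' @param tree an [AirwayTree-class] with resistances set.
#' @param method construction to use.
#' @param config configuration list; \code{denseCap} bounds |T|.
#' @return dense symmetric matrix of shared-path resistances (cmH2O s/l)
#' @examples
#' tr <- buildTree(cbind(c(1, 2, 2), c(2, 3, 4)), radius = c(2, 1.5, 1.5),
#'                 length = c(12, 9, 9), resistance = c(1, 2, 3))
#' mauryMatrix(tr)   # rbind(c(3, 1), c(1, 4))
#' @export
mauryMatrix <- function(tree, method = c("factors", "lca", "schur"),
                        config = airwayConfig()) {
  method <- match.arg(method)
  r <- resistances(tree)
  if (any(is.na(r))) stop("resistances must be set; see poiseuilleResistances()")
  nT <- nTerminals(tree)
  if (nT > config$denseCap) {
    stop("|T| = ", nT, " exceeds the dense size cap ", config$denseCap,
         "; use maurySpectrum() for matrix-free eigenanalysis")
  }
  if (method == "factors") {
    Tm <- subtreeMaps(tree)$T
    R <- as.matrix(Tm %*% Matrix::Diagonal(x = r) %*% Matrix::t(Tm))
  } else if (method == "lca") {
    paths <- rootPaths(tree)[terminalNodes(tree)]
    R <- matrix(0, nT, nT)
    for (i in seq_len(nT)) {
      for (k in i:nT) {
        shared <- intersect(paths[[i]], paths[[k]])
        R[i, k] <- R[k, i] <- sum(r[shared])
      }
    }
  } else {
    sys <- buildLaplacian(tree)
    G <- sys@gammaTerm
    if (nrow(sys@Lint) > 0) {
      X <- Matrix::solve(forceSymmetricSparse(sys@Lint),
                         sys@B %*% Matrix::Diagonal(x = G))
      M <- diag(G, length(G)) -
        as.matrix(Matrix::Diagonal(x = G) %*% Matrix::crossprod(sys@B, X))
    } else {
      M <- diag(G, length(G))
    }
    kappaCond <- rcond(M)
    if (kappaCond < 1e-14) {
      warning(sprintf("terminal response matrix is ill-conditioned (rcond %.2e)",
                      kappaCond))
    }
    R <- solve(M)
    R <- (R + t(R)) / 2
  }
  unname(R)
}

# per-node root paths as branch index vectors
rootPaths <- function(tree) {
  nv <- nNodes(tree)
  paths <- vector("list", nv)
  paths[[1]] <- integer(0)
  for (n in 2:nv) {
    paths[[n]] <- c(paths[[tree@prox[n - 1L]]], n - 1L)
  }
  paths
}

#' Eigendecomposition of the Maury operator
#'
#' Partial decompositions never form the dense operator: the action
#' \eqn{v \mapsto T\,diag(r)\,T^T v} is applied through the sparse subtree
#' factors inside an implicitly restarted Lanczos iteration, which is how
#' the largest (high-resistance) modes of trees with many terminals are
#' obtained. Full decompositions use a dense symmetric eigensolver under
#' the size cap. Eigenvalues are returned in descending order (the Maury
#' convention, opposite to the Laplacian) and residuals are checked.
#'
#' @param tree an [AirwayTree-class] with resistances set.
#' @param nModes number of eigenpairs (default: all |T|).
#' @param which "largest" or "smallest" end of the spectrum for partial
#'   decompositions.
#' @param method "auto" (dense when full and under the cap, matrix-free
#'   otherwise), "dense", or "lanczos".
#' @param config configuration list, see [airwayConfig()].
#' @return a [SpectralDecomposition-class] with operator "maury"
#' @export
maurySpectrum <- function(tree, nModes = NULL,
                          which = c("largest", "smallest"),
                          method = c("auto", "dense", "lanczos"),
                          config = airwayConfig()) {
  which <- match.arg(which)
  method <- match.arg(method)
  nT <- nTerminals(tree)
  if (is.null(nModes)) nModes <- nT
  if (nModes > nT) stop("nModes exceeds |T| = ", nT)
  r <- resistances(tree)
  if (any(is.na(r))) stop("resistances must be set")
  if (method == "auto") {
    method <- if (nModes == nT && nT <= config$denseCap) "dense" else "lanczos"
  }
  Tm <- subtreeMaps(tree)$T
  applyR <- function(v) as.numeric(Tm %*% (r * as.numeric(Matrix::crossprod(Tm, v))))
  if (method == "dense") {
    eig <- eigen(mauryMatrix(tree, "factors", config), symmetric = TRUE)
    ord <- order(eig$values, decreasing = TRUE)
    vals <- eig$values[ord][seq_len(nModes)]
    vecs <- eig$vectors[, ord, drop = FALSE][, seq_len(nModes), drop = FALSE]
    whichOut <- if (nModes == nT) "all" else "largest"
  } else {
    if (nModes == nT) {
      # lanczos cannot return the complete spectrum reliably; cap nev below n
      stop("full spectra require the dense path (|T| within denseCap)")
    }
    ar <- igraph::arpack(function(v, extra) applyR(v), sym = TRUE,
                         options = list(n = nT, nev = nModes,
                                        ncv = min(nT, max(2 * nModes + 1, 20)),
                                        which = if (which == "largest") "LA" else "SA",
                                        maxiter = 5000))
    ord <- order(ar$values, decreasing = TRUE)
    vals <- ar$values[ord]
    vecs <- matrix(ar$vectors, nrow = nT)[, ord, drop = FALSE]
    whichOut <- which
  }
  resid <- spectralResiduals(applyR, vals, vecs)
  if (any(resid > config$eigTol)) {
    stop(sprintf("maury eigensolve failed to converge: max relative residual %.3e",
                 max(resid)))
  }
  new("SpectralDecomposition", operator = "maury", values = vals,
      vectors = vecs, which = whichOut, dim = as.integer(nT),
      residuals = resid)
}

#' Terminal fluxes from Maury modes
#'
#' Reconstructs the terminal flux solution from the modal expansion
#' \eqn{Q_{term} = -\sum_k (\Delta P_{term}^T \hat v_k / \mu_k)\,\hat v_k},
#' truncated to the first \code{nModes} modes of the decomposition (or of
#' an explicit ordering). Each mode acts as an independent resistor of
#' resistance \eqn{\mu_k} in parallel; the coefficient magnitude
#' \eqn{|q_k|} measures mode importance for the given boundary condition.
#' With the full spectrum this equals the direct sparse solve.
#'
#' @param decomposition a maury [SpectralDecomposition-class].
#' @param dPTerminal numeric of length |T| (or scalar, recycled).
#' @param nModes number of modes to keep (default: all available).
#' @param modeOrder optional explicit mode ordering (indices into the
#'   stored modes), e.g. by descending |q_k|.
#' @return list with \code{QTerminal} (numeric |T|) and \code{coefficients}
#'   q_k over all available modes (in stored order)
#' @export
fluxFromModes <- function(decomposition, dPTerminal, nModes = NULL,
                          modeOrder = NULL) {
  stopifnot(decomposition@operator == "maury")
  nT <- decomposition@dim
  if (length(dPTerminal) == 1L) dPTerminal <- rep(dPTerminal, nT)
  if (length(dPTerminal) != nT) stop("dPTerminal must have length ", nT)
  nAvail <- length(decomposition@values)
  if (is.null(nModes)) nModes <- nAvail
  if (nModes > nAvail) stop("nModes exceeds the ", nAvail, " available modes")
  qk <- as.numeric(crossprod(decomposition@vectors, dPTerminal)) /
    decomposition@values
  keep <- if (is.null(modeOrder)) seq_len(nModes) else modeOrder[seq_len(nModes)]
  Q <- if (nModes == 0) numeric(nT)
       else -as.numeric(decomposition@vectors[, keep, drop = FALSE] %*% qk[keep])
  list(QTerminal = Q, coefficients = qk)
}

#' Spectral truncation discrepancy of the Maury inverse
#'
#' Normalized Frobenius distance between \eqn{R^{-1}} and its truncated
#' spectral reconstruction keeping the M smallest-eigenvalue modes (which
#' carry the largest weights \eqn{\mu^{-1}} in the inverse):
#' \eqn{\sqrt{\sum_{excluded}\mu^{-2} / \sum_{all}\mu^{-2}}} where the
#' excluded modes are the |T| - M largest. 1 at M = 0, 0 at the full
#' spectrum, nonincreasing in M.
#'
#' @param eigenvalues the complete spectrum, descending.
#' @param M number of smallest-eigenvalue modes kept.
#' @return a value in [0, 1]
#' @export
deltaR <- function(eigenvalues, M) {
  n <- length(eigenvalues)
  if (M < 0 || M > n) stop("M must be between 0 and ", n)
  w <- eigenvalues^-2
  sqrt(sum(w[seq_len(n) <= n - M]) / sum(w))
}

#' Minimum number of modes for a target reconstruction accuracy
#'
#' For a given boundary condition, finds the smallest M such that the
#' terminal flux reconstructed from the top-M modes reaches the target
#' accuracy against the direct sparse solve. Modes are ranked by
#' descending coefficient magnitude (|q_k| for the Maury operator, |p_k|
#' for the Laplacian) with eigenvalue-descending order as a stable
#' tie-break, or by the operator's canonical eigenvalue order (largest-mu
#' first / smallest-lambda first).
#'
#' Accuracy \eqn{a} is translated to a bound on the relative L2 error
#' \eqn{\epsilon(M) = \|Q_M - Q\|_2/\|Q\|_2} according to \code{metric}:
#' \describe{
#'   \item{energy}{\eqn{\epsilon \le \sqrt{1-a}}: the reconstruction
#'     captures a fraction a of the squared solution norm. For the Maury
#'     route the modal increments are orthogonal, so this is exactly the
#'     cumulative fraction of the squared coefficients \eqn{q_k^2} — the
#'     standard captured-energy criterion of model-order reduction, and
#'     the default.}
#'   \item{l2}{\eqn{\epsilon \le 1-a}: accuracy read as one minus the
#'     relative error; a substantially stricter count.}
#'   \item{norm}{\eqn{\epsilon \le \sqrt{1-a^2}}: the reconstructed
#'     solution recovers a fraction a of the solution norm.}
#' }
#'
#' @param tree an [AirwayTree-class] with resistances set.
#' @param dPTerminal numeric of length |T| (or scalar, recycled).
#' @param accuracy target in (0, 1], e.g. 0.75 for 75\% accuracy.
#' @param operator "maury" or "laplacian".
#' @param rankBy "coefficient" (default) or "eigenvalue".
#' @param metric accuracy reading, see above.
#' @param decomposition optional precomputed full decomposition.
#' @param config configuration list, see [airwayConfig()].
#' @return list with \code{M} (integer), \code{errors} (relative L2 error
#'   after each added mode, starting at M = 0), \code{order} (the mode
#'   ranking used) and \code{errTol} (the error bound applied)
#' @export
minModesForAccuracy <- function(tree, dPTerminal, accuracy,
                                operator = c("maury", "laplacian"),
                                rankBy = c("coefficient", "eigenvalue"),
                                metric = c("energy", "l2", "norm"),
                                decomposition = NULL,
                                config = airwayConfig()) {
  operator <- match.arg(operator)
  rankBy <- match.arg(rankBy)
  metric <- match.arg(metric)
  if (accuracy <= 0 || accuracy > 1) stop("accuracy must be in (0, 1]")
  nT <- nTerminals(tree)
  if (length(dPTerminal) == 1L) dPTerminal <- rep(dPTerminal, nT)
  system <- buildLaplacian(tree)
  Qref <- solveFixedPressure(system, dPTerminal, config = config)@QTerminal
  nrmRef <- sqrt(sum(Qref^2))

  if (operator == "maury") {
    if (is.null(decomposition)) {
      decomposition <- maurySpectrum(tree, config = config)
    }
    fl <- fluxFromModes(decomposition, dPTerminal)
    coef <- fl$coefficients
    V <- decomposition@vectors
    increments <- -V * rep(coef, each = nrow(V))   # column k: -q_k v_k
    Q0 <- numeric(nT)
  } else {
    if (is.null(decomposition)) {
      decomposition <- laplacianSpectrum(system, config = config)
    }
    rhs <- as.numeric(system@B %*% (system@gammaTerm * dPTerminal))
    coef <- as.numeric(crossprod(decomposition@vectors, rhs)) /
      decomposition@values
    # adding mode k changes Q_term by Gamma B^T (p_k u_k)
    U <- decomposition@vectors
    increments <- system@gammaTerm *
      as.matrix(Matrix::crossprod(system@B, U)) * rep(coef, each = nT)
    Q0 <- -system@gammaTerm * dPTerminal
  }
  ord <- if (rankBy == "coefficient") {
    order(-abs(coef), -decomposition@values)
  } else if (operator == "maury") {
    order(-decomposition@values)
  } else {
    order(decomposition@values)
  }
  tol <- switch(metric,
                energy = sqrt(1 - accuracy),
                l2 = 1 - accuracy,
                norm = sqrt(1 - accuracy^2))
  Q <- Q0
  errors <- numeric(length(coef) + 1L)
  errors[1] <- sqrt(sum((Q - Qref)^2)) / nrmRef
  M <- NA_integer_
  if (errors[1] <= tol) M <- 0L
  for (m in seq_along(ord)) {
    Q <- Q + increments[, ord[m]]
    errors[m + 1L] <- sqrt(sum((Q - Qref)^2)) / nrmRef
    if (is.na(M) && errors[m + 1L] <= tol) M <- as.integer(m)
  }
  if (is.na(M)) M <- as.integer(length(ord))
  list(M = M, errors = errors, order = ord, errTol = tol)
}
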