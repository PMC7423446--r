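#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal crossprod t solve Cholesky rowSums colSums norm
NULL

#' AirwayTree: a rooted, oriented resistive tree network
#'
#' The single object every operator in the package is built from. An airway
#' tree is a connected acyclic network with one root node (the entrance from
#' the upper airway); every branch is oriented from its proximal to its
#' distal node. Nodes are stored in canonical order: root first, then
#' internal nodes, then terminal nodes last, and branch \code{j} is the
#' unique branch whose distal node is node \code{j + 1}. Under this
#' convention the tree structure is fully encoded by the proximal node of
#' each branch.
#'
#' @slot prox integer vector, proximal (parent-side) node of each branch.
#' @slot radius numeric, branch lumen radius in mm.
#' @slot length numeric, branch length in mm.
#' @slot resistance numeric, branch resistance in cmH2O s/l (may be all
#'   \code{NA} until resistances are assigned).
#' @slot coords numeric matrix with one row per node and columns x, y, z
#'   (mm), or a 0-row matrix when coordinates are absent.
#' @slot nodeLabels character, original input labels in canonical node order.
#' @slot horsfieldOrder integer per branch: Horsfield order counted upward
#'   from the terminal branches (terminals are order 1), or \code{NA}.
#' @slot metadata list of provenance: generator parameters, seeds, the
#'   Poiseuille constant used, input-label maps.
#'
#' @seealso [buildTree()], [weibelTree()], [horsfieldTree()]
#' @export
setClass("AirwayTree",
  representation(
    prox = "integer",
    radius = "numeric",
    length = "numeric",
    resistance = "numeric",
    coords = "matrix",
    nodeLabels = "character",
    horsfieldOrder = "integer",
    metadata = "list"
  ),
  prototype(
    coords = matrix(numeric(0), nrow = 0, ncol = 3),
    metadata = list()
  )
)

setValidity("AirwayTree", function(object) {
  nb <- length(object@prox)
  nv <- nb + 1L
  msgs <- character(0)
  if (length(object@radius) != nb || length(object@length) != nb ||
      length(object@resistance) != nb) {
    msgs <- c(msgs, "radius, length, resistance must have one entry per branch")
  }
  if (length(object@horsfieldOrder) != nb) {
    msgs <- c(msgs, "horsfieldOrder must have one entry per branch")
  }
  if (length(object@nodeLabels) != nv) {
    msgs <- c(msgs, "nodeLabels must have one entry per node")
  }
  if (nb > 0) {
    if (any(object@prox < 1L) || any(object@prox > nv)) {
      msgs <- c(msgs, "proximal node indices out of range")
    }
    # branch j points to distal node j + 1; orientation requires prox[j] < j + 1
    if (any(object@prox >= seq_len(nb) + 1L)) {
      msgs <- c(msgs, "branches must point away from the root (prox[j] < j + 1)")
    }
    if (any(!is.finite(object@radius)) || any(object@radius <= 0)) {
      msgs <- c(msgs, "all radii must be strictly positive")
    }
    if (any(!is.finite(object@length)) || any(object@length <= 0)) {
      msgs <- c(msgs, "all lengths must be strictly positive")
    }
    rs <- object@resistance
    if (any(!is.na(rs) & rs <= 0)) {
      msgs <- c(msgs, "all resistances must be strictly positive")
    }
    # canonical ordering: internal nodes precede terminal nodes
    isTermNode <- !(seq_len(nv) %in% object@prox)
    if (isTermNode[1L] && nb > 0) {
      msgs <- c(msgs, "root node must have at least one child branch")
    }
    ranks <- which(isTermNode[-1L])
    if (length(ranks) > 0 && length(ranks) < nb) {
      if (min(ranks) < max(which(!isTermNode[-1L]))) {
        msgs <- c(msgs, "terminal nodes must be listed last")
      }
    }
  }
  if (nrow(object@coords) > 0 &&
      (nrow(object@coords) != nv || ncol(object@coords) != 3)) {
    msgs <- c(msgs, "coords must be a |V| x 3 matrix (or empty)")
  }
  if (length(msgs)) msgs else TRUE
})

#' BlockPartition: node and branch index bookkeeping
#'
#' Separates the node set into root / internal / terminal nodes and the
#' branch set into the root branch, internal branches and terminal branches
#' (those whose distal node is terminal). Under the canonical ordering all
#' six index sets are contiguous.
#'
#' @slot rootNode integer scalar (always 1).
#' @slot internalNodes integer vector.
#' @slot terminalNodes integer vector.
#' @slot rootBranch integer vector of branches leaving the root (length 1
#'   for airway trees with a trachea).
#' @slot internalBranches integer vector.
#' @slot terminalBranches integer vector.
#' @export
setClass("BlockPartition",
  representation(
    rootNode = "integer",
    internalNodes = "integer",
    terminalNodes = "integer",
    rootBranch = "integer",
    internalBranches = "integer",
    terminalBranches = "integer"
  )
)

setValidity("BlockPartition", function(object) {
  nodes <- c(object@rootNode, object@internalNodes, object@terminalNodes)
  branches <- c(object@rootBranch, object@internalBranches, object@terminalBranches)
  msgs <- character(0)
  if (anyDuplicated(nodes)) msgs <- c(msgs, "node partitions overlap")
  if (anyDuplicated(branches)) msgs <- c(msgs, "branch partitions overlap")
  if (length(nodes) != length(branches) + 1L) {
    msgs <- c(msgs, "|V| must equal |E| + 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' LaplacianSystem: conductance Laplacian and its boundary blocks
#'
#' Holds the full conductance Laplacian \eqn{L = N \Gamma N^T} (branch
#' conductances \eqn{\Gamma = diag(r)^{-1}} as weights), the internal block
#' \eqn{L_{int}} over internal nodes (symmetric positive definite on
#' connected trees), the coupling matrix \eqn{B} between internal nodes and
#' terminal branches, and the terminal conductances.
#'
#' @slot L sparse symmetric |V| x |V| Laplacian; rows sum to zero.
#' @slot Lint sparse SPD block over internal nodes.
#' @slot B sparse 0/1 incidence of internal nodes onto terminal branches.
#' @slot gammaTerm numeric vector of terminal-branch conductances 1/r.
#' @slot partition the [BlockPartition-class] used for the blocks.
#' @slot tree the originating [AirwayTree-class].
#' @export
setClass("LaplacianSystem",
  representation(
    L = "Matrix",
    Lint = "Matrix",
    B = "Matrix",
    gammaTerm = "numeric",
    partition = "BlockPartition",
    tree = "AirwayTree"
  )
)

#' SpectralDecomposition: ordered eigenpairs of a tree operator
#'
#' Eigenvalues and orthonormal eigenvectors of either the internal
#' conductance Laplacian (ascending eigenvalues) or the Maury operator
#' (descending eigenvalues), with residual diagnostics.
#'
#' @slot operator "laplacian" or "maury".
#' @slot values numeric eigenvalues in the operator's canonical order.
#' @slot vectors matrix of eigenvectors, one column per eigenvalue.
#' @slot which "largest", "smallest" or "all".
#' @slot dim integer, dimension of the underlying operator.
#' @slot residuals numeric, per-pair relative residual norms.
#' @export
setClass("SpectralDecomposition",
  representation(
    operator = "character",
    values = "numeric",
    vectors = "matrix",
    which = "character",
    dim = "integer",
    residuals = "numeric"
  )
)

setValidity("SpectralDecomposition", function(object) {
  msgs <- character(0)
  if (!object@operator %in% c("laplacian", "maury")) {
    msgs <- c(msgs, "operator must be 'laplacian' or 'maury'")
  }
  if (ncol(object@vectors) != length(object@values)) {
    msgs <- c(msgs, "one eigenvector column per eigenvalue required")
  }
  if (length(object@values) > 1) {
    d <- diff(object@values)
    if (object@operator == "maury" && any(d > 1e-8 * max(abs(object@values)))) {
      msgs <- c(msgs, "maury eigenvalues must be in descending order")
    }
    if (object@operator == "laplacian" && any(d < -1e-8 * max(abs(object@values)))) {
      msgs <- c(msgs, "laplacian eigenvalues must be in ascending order")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' FlowSolution: pressures and fluxes on a resistive tree
#'
#' The solution of the linear resistance relations under fixed terminal
#' pressure-drop boundary conditions. Pressure drops are relative to the
#' root node, \eqn{\Delta P = P_1 e - P}; a positive branch flux flows from
#' proximal to distal.
#'
#' @slot dPInternal numeric, pressure drop at internal nodes (cmH2O).
#' @slot dPTerminal numeric, imposed terminal pressure drops (cmH2O).
#' @slot QTerminal numeric, net flux into the network at each terminal
#'   node (l/s); negative values are flow delivered out of the terminals.
#' @slot qBranch numeric, per-branch fluxes (l/s).
#' @slot QRoot numeric scalar, flux entering at the root (l/s).
#' @slot method "direct" (sparse factorization) or "modal".
#' @slot modesUsed integer, number of modes (NA for direct solves).
#' @slot coefficients numeric, modal coefficients when method = "modal".
#' @export
setClass("FlowSolution",
  representation(
    dPInternal = "numeric",
    dPTerminal = "numeric",
    QTerminal = "numeric",
    qBranch = "numeric",
    QRoot = "numeric",
    method = "character",
    modesUsed = "integer",
    coefficients = "numeric"
  ),
  prototype(method = "direct", modesUsed = NA_integer_, coefficients = numeric(0))
)

#' HorsfieldTable: per-order morphometry for recursive tree generation
#'
#' One record per Horsfield order g: the orders of its child branches
#' (strictly less than g) and mean radius and length in mm. Orders at or
#' below the termination order become terminal branches.
#'
#' @slot order integer vector of orders, descending coverage.
#' @slot childOrders list of integer vectors, one per order.
#' @slot meanRadius numeric, mm.
#' @slot meanLength numeric, mm.
#' @export
setClass("HorsfieldTable",
  representation(
    order = "integer",
    childOrders = "list",
    meanRadius = "numeric",
    meanLength = "numeric"
  )
)

setValidity("HorsfieldTable", function(object) {
  msgs <- character(0)
  n <- length(object@order)
  if (length(object@childOrders) != n || length(object@meanRadius) != n ||
      length(object@meanLength) != n) {
    msgs <- c(msgs, "all fields must have one entry per order")
  }
  if (anyDuplicated(object@order)) msgs <- c(msgs, "duplicate orders")
  for (i in seq_len(n)) {
    co <- object@childOrders[[i]]
    if (length(co) && any(co >= object@order[i])) {
      msgs <- c(msgs, sprintf("child orders of order %d must be strictly smaller",
                              object@order[i]))
    }
  }
  if (any(object@meanRadius <= 0) || any(object@meanLength <= 0)) {
    msgs <- c(msgs, "mean dimensions must be positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' VentilationParams: compliance-driven tidal breathing parameters
#'
#' Each terminal unit (acinus) is an elastic compartment of elastance
#' \eqn{\kappa} (cmH2O/l) driven by a shared sinusoidal pleural pressure
#' \eqn{P_{pl}(t) = P_{pl0} + P_s \sin(2\pi t/\tau)}. Elastance may be given
#' per unit (\code{kappaUnit}) or as the total lung elastance
#' \eqn{\kappa/|T|} (\code{kappaTotal}) of |T| identical units in parallel;
#' the per-unit value is resolved against the tree at simulation time.
#'
#' @slot kappaUnit numeric, per-unit elastance (cmH2O/l) or NA.
#' @slot kappaTotal numeric, total lung elastance kappa/|T| (cmH2O/l) or NA.
#' @slot tau numeric, breath period (s).
#' @slot Ps numeric, pleural pressure amplitude (cmH2O).
#' @slot Ppl0 numeric, pleural pressure offset (cmH2O).
#' @slot nCycles integer, breath cycles to integrate in direct simulation.
#' @export
setClass("VentilationParams",
  representation(
    kappaUnit = "numeric",
    kappaTotal = "numeric",
    tau = "numeric",
    Ps = "numeric",
    Ppl0 = "numeric",
    nCycles = "integer"
  )
)

setValidity("VentilationParams", function(object) {
  msgs <- character(0)
  if (is.na(object@kappaUnit) && is.na(object@kappaTotal)) {
    msgs <- c(msgs, "one of kappaUnit or kappaTotal must be given")
  }
  if (!is.na(object@kappaUnit) && object@kappaUnit <= 0) {
    msgs <- c(msgs, "kappaUnit must be positive")
  }
  if (!is.na(object@kappaTotal) && object@kappaTotal <= 0) {
    msgs <- c(msgs, "kappaTotal must be positive")
  }
  if (object@tau <= 0) msgs <- c(msgs, "tau must be positive")
  if (object@Ps <= 0) msgs <- c(msgs, "Ps must be positive")
  if (object@nCycles < 1) msgs <- c(msgs, "nCycles must be at least 1")
  if (length(msgs)) msgs else TRUE
})

#' VentilationResult: per-unit tidal volumes and their heterogeneity
#'
#' @slot deltaV numeric, tidal volume delivered to each terminal unit (l).
#' @slot meanDeltaV numeric scalar (l).
#' @slot sigmaV numeric scalar, coefficient of variation of deltaV
#'   (dimensionless) — the ventilation heterogeneity index.
#' @slot method "direct" (ODE integration) or "modal" (closed-form periodic
#'   solution from Maury modes).
#' @slot modesUsed integer, number of Maury modes in a modal solution
#'   (NA for direct).
#' @slot largeModeCount integer, number of modes with mu_k > 0.1 kappa tau
#'   among the modes available to the computation.
#' @slot diagnostics list: kappaUnit, tau, Ps, cycles integrated,
#'   periodicity error of the final cycle, seeds.
#' @export
setClass("VentilationResult",
  representation(
    deltaV = "numeric",
    meanDeltaV = "numeric",
    sigmaV = "numeric",
    method = "character",
    modesUsed = "integer",
    largeModeCount = "integer",
    diagnostics = "list"
  ),
  prototype(modesUsed = NA_integer_, largeModeCount = NA_integer_,
            diagnostics = list())
)
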