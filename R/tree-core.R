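#' Build an airway tree from an edge list
#'
#' Validates that the edge list describes a connected rooted tree, reorders
#' nodes to the canonical convention (root first, then internal nodes in
#' breadth-first order, then terminal nodes last) and reindexes branches so
#' that branch \code{j} is the branch whose distal node is node \code{j+1}.
#' Among siblings, input order is preserved, so the canonical form is
#' deterministic and idempotent.
#'
#' The root is detected as the unique node that never appears as a distal
#' node. Branch orientation in the input must already point proximal to
#' distal (parent to child).
#'
#' @param edges two-column matrix or data.frame of (proximal, distal) node
#'   labels, one row per branch. Labels may be integers or strings.
#' @param radius,length positive numerics, one per branch (mm).
#' @param resistance optional positive numerics, one per branch
#'   (cmH2O s/l). When omitted, assign later with
#'   [poiseuilleResistances()].
#' @param coords optional data.frame/matrix with one row per node giving
#'   label, x, y, z (mm); the first column is matched against node labels.
#' @param horsfieldOrder optional integer per branch.
#' @param metadata optional list stored on the tree.
#' @return an [AirwayTree-class]. \code{metadata(tree)$nodeMap} and
#'   \code{$branchMap} map input labels / input branch rows to canonical
#'   indices.
#' @examples
#' tr <- buildTree(cbind(c(1, 2, 2), c(2, 3, 4)),
#'                 radius = c(2, 1.5, 1.5), length = c(12, 9, 9),
#'                 resistance = c(1, 2, 3))
#' nTerminals(tr)
#' @export
buildTree <- function(edges, radius, length, resistance = NULL, coords = NULL,
                      horsfieldOrder = NULL, metadata = list()) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("edges must have two columns (proximal, distal)")
  branchLength <- length
  rm(length)   # unshadow base::length
  nb <- nrow(edges)
  if (nb < 1) stop("tree must have at least one branch")
  proxLab <- as.character(edges[, 1])
  distLab <- as.character(edges[, 2])
  labels <- unique(c(proxLab, distLab))
  nv <- length(labels)
  if (anyDuplicated(distLab)) {
    stop("cycle or multiple parents detected: node '",
         distLab[duplicated(distLab)][1], "' has more than one parent")
  }
  rootLab <- setdiff(labels, distLab)
  if (length(rootLab) == 0L) {
    stop("cycle detected: every node has a parent, so no root exists")
  }
  if (length(rootLab) > 1L) {
    stop("tree must have exactly one root (disconnected input?); candidates: ",
         paste(rootLab, collapse = ", "))
  }
  if (nv != nb + 1L) {
    stop("edge list is not a tree: |V| = ", nv, " but |E| + 1 = ", nb + 1L)
  }
  if (length(radius) != nb || length(branchLength) != nb) {
    stop("radius and length must have one entry per branch")
  }
  checkPositive(radius, "radius")
  checkPositive(branchLength, "length")
  if (!is.null(resistance)) {
    if (length(resistance) != nb) stop("resistance must have one entry per branch")
    checkPositive(resistance, "resistance")
  }

  # children of each node, in input branch order
  childBranches <- split(seq_len(nb), factor(proxLab, levels = labels))
  # BFS from root
  bfsNodes <- character(nv)
  bfsNodes[1] <- rootLab
  head <- 1L; tail <- 1L
  parentBranch <- integer(nb)   # input branch row feeding each BFS-visited node
  nodeOfBranch <- character(nb)
  while (head <= tail) {
    u <- bfsNodes[head]
    for (b in childBranches[[u]]) {
      tail <- tail + 1L
      if (tail > nv) stop("cycle detected while traversing the tree")
      bfsNodes[tail] <- distLab[b]
    }
    head <- head + 1L
  }
  if (tail != nv) {
    stop("disconnected input: ", nv - tail,
         " node(s) unreachable from root '", rootLab, "'")
  }
  isTerm <- vapply(bfsNodes, function(u) base::length(childBranches[[u]]) == 0L,
                   logical(1))
  if (isTerm[1]) stop("root has no child branch")
  # canonical labels: root 1, internal in BFS order, terminal in BFS order
  canon <- integer(nv)
  names(canon) <- bfsNodes
  internal <- bfsNodes[-1][!isTerm[-1]]
  terminal <- bfsNodes[-1][isTerm[-1]]
  canon[rootLab] <- 1L
  if (base::length(internal)) canon[internal] <- 1L + seq_along(internal)
  canon[terminal] <- 1L + base::length(internal) + seq_along(terminal)

  # branch j has distal node j + 1: permutation of input branch rows
  canonDist <- canon[distLab]            # canonical distal node of input row b
  branchOfRow <- canonDist - 1L          # canonical branch index of input row b
  rowOfBranch <- integer(nb)
  rowOfBranch[branchOfRow] <- seq_len(nb)
  prox <- canon[proxLab][rowOfBranch]

  cmat <- matrix(numeric(0), nrow = 0, ncol = 3,
                 dimnames = list(NULL, c("x", "y", "z")))
  if (!is.null(coords)) {
    coords <- as.data.frame(coords)
    cl <- as.character(coords[[1]])
    if (!all(labels %in% cl)) {
      stop("coords must cover every node label")
    }
    m <- as.matrix(coords[match(names(sort(canon)), cl), 2:4])
    storage.mode(m) <- "double"
    dimnames(m) <- list(NULL, c("x", "y", "z"))
    cmat <- m
  }

  ho <- rep(NA_integer_, nb)
  if (!is.null(horsfieldOrder)) ho <- as.integer(horsfieldOrder)[rowOfBranch]

  metadata$nodeMap <- canon
  metadata$branchMap <- branchOfRow

  new("AirwayTree",
      prox = as.integer(unname(prox)),
      radius = as.numeric(radius[rowOfBranch]),
      length = as.numeric(branchLength[rowOfBranch]),
      resistance = if (is.null(resistance)) rep(NA_real_, nb)
                   else as.numeric(resistance[rowOfBranch]),
      coords = cmat,
      nodeLabels = names(sort(canon)),
      horsfieldOrder = ho,
      metadata = metadata)
}

checkPositive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(what, " must be strictly positive and finite (offending entries: ",
         paste(utils::head(which(!is.finite(x) | x <= 0), 5), collapse = ", "),
         ")")
  }
  invisible(TRUE)
}

#' @name AirwayTree-accessors
#' @title Accessors for AirwayTree objects
#' @param x an [AirwayTree-class]
#' @return counts, index vectors, or per-branch attribute vectors.
NULL

#' @rdname AirwayTree-accessors
#' @export
setMethod("nNodes", "AirwayTree", function(x) length(x@prox) + 1L)

#' @rdname AirwayTree-accessors
#' @export
setMethod("nBranches", "AirwayTree", function(x) length(x@prox))

#' @rdname AirwayTree-accessors
#' @export
setMethod("nTerminals", "AirwayTree", function(x) {
  sum(!(seq_len(nNodes(x)) %in% x@prox))
})

#' @rdname AirwayTree-accessors
#' @export
setMethod("terminalNodes", "AirwayTree", function(x) {
  which(!(seq_len(nNodes(x)) %in% x@prox))
})

#' @rdname AirwayTree-accessors
#' @export
setMethod("internalNodes", "AirwayTree", function(x) {
  setdiff(which(seq_len(nNodes(x)) %in% x@prox), 1L)
})

#' @rdname AirwayTree-accessors
#' @export
setMethod("resistances", "AirwayTree", function(x) x@resistance)

#' @rdname AirwayTree-accessors
#' @export
setMethod("radii", "AirwayTree", function(x) x@radius)

#' @rdname AirwayTree-accessors
#' @export
setMethod("branchLengths", "AirwayTree", function(x) x@length)

#' @rdname AirwayTree-accessors
#' @export
setMethod("branchTable", "AirwayTree", function(x) {
  nb <- nBranches(x)
  data.frame(
    branch = seq_len(nb),
    prox = x@prox,
    dist = seq_len(nb) + 1L,
    radius_mm = x@radius,
    length_mm = x@length,
    resistance = x@resistance,
    horsfield_order = x@horsfieldOrder
  )
})

#' Tree metadata
#' @param x an [AirwayTree-class]
#' @return the metadata list (generator parameters, seeds, label maps).
#' @export
treeMetadata <- function(x) x@metadata

setMethod("show", "AirwayTree", function(object) {
  cat("AirwayTree with", nNodes(object), "nodes,", nBranches(object),
      "branches,", nTerminals(object), "terminal units\n")
  r <- object@resistance
  if (all(is.na(r))) {
    cat("  resistances: unset\n")
  } else {
    cat(sprintf("  resistance range: [%.4g, %.4g] cmH2O.s/l\n",
                min(r), max(r)))
  }
  if (!is.null(object@metadata$generator)) {
    cat("  generator:", object@metadata$generator, "\n")
  }
})

#' Partition nodes and branches into root / internal / terminal blocks
#'
#' Terminal branches are exactly the branches whose distal node is a
#' terminal node; under the canonical ordering all blocks are contiguous
#' index ranges.
#'
#' @param x an [AirwayTree-class]
#' @return a [BlockPartition-class]
#' @rdname blockPartition
#' @export
setMethod("blockPartition", "AirwayTree", function(x) {
  nv <- nNodes(x)
  term <- terminalNodes(x)
  int <- internalNodes(x)
  rootBranches <- which(x@prox == 1L)
  termBranches <- term - 1L
  new("BlockPartition",
      rootNode = 1L,
      internalNodes = as.integer(int),
      terminalNodes = as.integer(term),
      rootBranch = as.integer(rootBranches),
      internalBranches = as.integer(setdiff(seq_len(nv - 1L),
                                            c(rootBranches, termBranches))),
      terminalBranches = as.integer(termBranches))
})

setMethod("show", "BlockPartition", function(object) {
  cat("BlockPartition: 1 root /", length(object@internalNodes),
      "internal /", length(object@terminalNodes), "terminal nodes;",
      length(object@rootBranch), "root /", length(object@internalBranches),
      "internal /", length(object@terminalBranches), "terminal branches\n")
})

#' Signed node-branch incidence matrix
#'
#' Entry (i, j) is +1 when node i is the proximal node of branch j, -1 when
#' it is the distal node, 0 otherwise. Every column sums to zero, so the
#' all-ones vector spans the left null space on connected trees.
#'
#' @param x an [AirwayTree-class]
#' @return a sparse |V| x |E| matrix
#' @rdname incidenceMatrix
#' @export
setMethod("incidenceMatrix", "AirwayTree", function(x) {
  nb <- nBranches(x)
  Matrix::sparseMatrix(
    i = c(x@prox, seq_len(nb) + 1L),
    j = rep(seq_len(nb), 2),
    x = rep(c(1, -1), each = nb),
    dims = c(nb + 1L, nb))
})

#' Per-branch terminal descendant sets
#'
#' For each branch, the set of terminal nodes in its distal subtree. The
#' root branch maps to all terminals; a terminal branch maps to the
#' singleton of its own distal node. Each branch's set is the disjoint
#' union of its children's sets.
#'
#' @param x an [AirwayTree-class]
#' @return list of integer vectors, one per branch
#' @rdname subtreeTerminalSets
#' @export
setMethod("subtreeTerminalSets", "AirwayTree", function(x) {
  nb <- nBranches(x)
  childrenOf <- split(seq_len(nb), factor(x@prox, levels = seq_len(nb + 1L)))
  sets <- vector("list", nb)
  for (j in rev(seq_len(nb))) {
    kids <- childrenOf[[j + 1L]]   # branches whose prox is node j + 1
    if (length(kids) == 0L) {
      sets[[j]] <- j + 1L
    } else {
      sets[[j]] <- sort(unlist(sets[kids], use.names = FALSE))
    }
  }
  sets
})

#' Assign Poiseuille resistances from branch geometry
#'
#' Laminar fully developed flow in a cylindrical airway of radius a and
#' length l has resistance proportional to \eqn{\mu l / a^4}. The default
#' prefactor is the physical Poiseuille constant 8/pi, applied as
#' \eqn{r = (8/\pi)\,\mu\,l/a^4} with the dynamic viscosity of air, and
#' converted from SI to cmH2O s/l. The constant used is recorded in the
#' tree metadata; a uniform rescaling of all resistances leaves
#' eigenvectors, mode ranking and ventilation heterogeneity at fixed
#' kappa*tau scaling unchanged.
#'
#' @param tree an [AirwayTree-class] with radius and length set (mm)
#' @param viscosity dynamic viscosity of air, Pa s
#' @param prefactor dimensionless constant in r = prefactor * mu * l / a^4
#' @return the tree with resistances attached (cmH2O s/l)
#' @export
poiseuilleResistances <- function(tree, viscosity = airwayConfig()$viscosity,
                                  prefactor = airwayConfig()$poiseuillePrefactor) {
  stopifnot(is(tree, "AirwayTree"))
  if (viscosity <= 0) stop("viscosity must be positive")
  checkPositive(tree@radius, "radius")
  # geometry mm -> m gives l/a^4 in m^-3 scaled by 1e9; Pa s m^-3 -> cmH2O s/l
  rSI <- prefactor * viscosity * (tree@length / tree@radius^4) * 1e9
  tree@resistance <- rSI * siToCmH2OsPerL()
  tree@metadata$poiseuille <- list(viscosity = viscosity, prefactor = prefactor)
  validObject(tree)
  tree
}

#' Horsfield orders of all branches
#'
#' Terminal branches have order 1; a parent's order is 1 + max of its
#' children's orders (generations counted upward from the terminal nodes).
#' Returns the stored per-branch orders when the tree carries them (e.g.
#' from a table-driven generator), otherwise computes them topologically.
#'
#' @param tree an [AirwayTree-class]
#' @param recompute logical, force topological recomputation
#' @return integer vector, one order per branch
#' @export
horsfieldOrders <- function(tree, recompute = FALSE) {
  if (!recompute && !all(is.na(tree@horsfieldOrder))) {
    return(tree@horsfieldOrder)
  }
  nb <- nBranches(tree)
  childrenOf <- split(seq_len(nb), factor(tree@prox, levels = seq_len(nb + 1L)))
  ord <- integer(nb)
  for (j in rev(seq_len(nb))) {
    kids <- childrenOf[[j + 1L]]
    ord[j] <- if (length(kids) == 0L) 1L else 1L + max(ord[kids])
  }
  ord
}

# child branches of every node, as a list indexed by node
childBranchList <- function(tree) {
  nb <- nBranches(tree)
  split(seq_len(nb), factor(tree@prox, levels = seq_len(nb + 1L)))
}
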