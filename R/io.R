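#' Read an airway tree from CSV
#'
#' The tree CSV dialect has one row per branch with a header row and
#' columns \code{branch_id, prox_node, dist_node, radius_mm, length_mm},
#' optionally \code{resistance} and \code{x, y, z} (coordinates of the
#' distal node, mm). The root node is identified as the unique prox_node
#' never appearing as dist_node. An explicit resistance column takes
#' precedence; otherwise Poiseuille resistances are computed from the
#' geometry.
#'
#' @param path file path
#' @param config configuration list used for Poiseuille resistances when
#'   the file carries none.
#' @return an [AirwayTree-class]
#' @export
readTreeCsv <- function(path, config = airwayConfig()) {
  df <- utils::read.csv(path)
  need <- c("branch_id", "prox_node", "dist_node", "radius_mm", "length_mm")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("malformed header: missing column(s) ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$branch_id)) {
    stop("duplicate branch ids at rows ",
         paste(which(duplicated(df$branch_id)), collapse = ", "))
  }
  if (anyDuplicated(df$dist_node)) {
    rows <- which(df$dist_node %in% df$dist_node[duplicated(df$dist_node)])
    stop("cycle or multiple parents: dist_node repeated at rows ",
         paste(rows, collapse = ", "))
  }
  coords <- NULL
  if (all(c("x", "y", "z") %in% names(df)) && !all(is.na(df$x))) {
    # coordinates are given per distal node; the root has none recorded
    allNodes <- unique(c(df$prox_node, df$dist_node))
    cdf <- data.frame(label = df$dist_node, x = df$x, y = df$y, z = df$z)
    root <- setdiff(allNodes, df$dist_node)
    cdf <- rbind(data.frame(label = root, x = 0, y = 0, z = 0), cdf)
    coords <- cdf
  }
  res <- if ("resistance" %in% names(df) && !all(is.na(df$resistance))) {
    df$resistance
  } else {
    NULL
  }
  ho <- if ("horsfield_order" %in% names(df)) df$horsfield_order else NULL
  tr <- buildTree(cbind(df$prox_node, df$dist_node),
                  radius = df$radius_mm, length = df$length_mm,
                  resistance = res, coords = coords, horsfieldOrder = ho,
                  metadata = list(source = path))
  if (all(is.na(resistances(tr)))) {
    tr <- poiseuilleResistances(tr, viscosity = config$viscosity,
                                prefactor = config$poiseuillePrefactor)
  }
  tr
}

#' Write an airway tree to CSV
#'
#' Inverse of [readTreeCsv()]; canonical indices are used as node labels,
#' so a write-read round trip reproduces the tree exactly.
#'
#' @param tree an [AirwayTree-class]
#' @param path file path
#' @return the path, invisibly
#' @export
writeTreeCsv <- function(tree, path) {
  nb <- nBranches(tree)
  df <- data.frame(
    branch_id = seq_len(nb),
    prox_node = tree@prox,
    dist_node = seq_len(nb) + 1L,
    radius_mm = tree@radius,
    length_mm = tree@length,
    resistance = tree@resistance)
  if (!all(is.na(tree@horsfieldOrder))) {
    df$horsfield_order <- tree@horsfieldOrder
  }
  if (nrow(tree@coords) > 0) {
    df$x <- tree@coords[df$dist_node, "x"]
    df$y <- tree@coords[df$dist_node, "y"]
    df$z <- tree@coords[df$dist_node, "z"]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Convert an airway tree to an igraph object / GraphML
#'
#' Nodes carry their canonical index, original label and optional
#' coordinates; edges carry radius, length and resistance. GraphML export
#' makes the network readable by standard graph tools.
#'
#' @param tree an [AirwayTree-class]
#' @param path GraphML file path
#' @return \code{asIgraph} returns an igraph; \code{writeGraphML} the path.
#' @export
asIgraph <- function(tree) {
  nb <- nBranches(tree)
  g <- igraph::graph_from_edgelist(cbind(tree@prox, seq_len(nb) + 1L),
                                   directed = TRUE)
  igraph::V(g)$label <- tree@nodeLabels
  if (nrow(tree@coords) > 0) {
    igraph::V(g)$x <- tree@coords[, "x"]
    igraph::V(g)$y <- tree@coords[, "y"]
    igraph::V(g)$z <- tree@coords[, "z"]
  }
  igraph::E(g)$radius_mm <- tree@radius[igraph::as_edgelist(g)[, 2] - 1L]
  igraph::E(g)$length_mm <- tree@length[igraph::as_edgelist(g)[, 2] - 1L]
  igraph::E(g)$resistance <- tree@resistance[igraph::as_edgelist(g)[, 2] - 1L]
  g
}

#' @rdname asIgraph
#' @export
writeGraphML <- function(tree, path) {
  igraph::write_graph(asIgraph(tree), path, format = "graphml")
  invisible(path)
}

#' Built-in fixture trees
#'
#' A deterministic named collection used throughout the examples and
#' tests: the 4-node Y tree (resistances 1, 2, 3), the 8-node two-level
#' reference tree with terminals v5..v8, a trifurcating test tree,
#' Weibel trees for N in \{1, 5, 9\} crossed with A in \{0, 0.5, 0.98\},
#' and the demonstration-table recursive tree (noise-free).
#'
#' @return named list of [AirwayTree-class] objects
#' @export
fixtureTrees <- function() {
  out <- list()
  out$y <- buildTree(cbind(c(1, 2, 2), c(2, 3, 4)),
                     radius = c(2, 1.5, 1.5), length = c(12, 9, 9),
                     resistance = c(1, 2, 3),
                     metadata = list(generator = "fixture:y"))
  out$twoLevel <- buildTree(
    cbind(c(1, 2, 2, 3, 3, 4, 4), c(2, 3, 4, 5, 6, 7, 8)),
    radius = c(4, 3, 3, 2, 2, 2, 2),
    length = c(24, 18, 18, 12, 12, 12, 12),
    resistance = 1:7,
    metadata = list(generator = "fixture:twoLevel"))
  out$trifurcating <- buildTree(
    cbind(c(1, 2, 2, 2), c(2, 3, 4, 5)),
    radius = c(3, 2, 2, 2), length = c(18, 12, 12, 12),
    resistance = c(1, 2, 3, 4),
    metadata = list(generator = "fixture:trifurcating"))
  for (n in c(1L, 5L, 9L)) {
    for (a in c(0, 0.5, 0.98)) {
      out[[sprintf("weibel_N%d_A%g", n, a)]] <- weibelTree(n, a)
    }
  }
  out$horsfieldDemo <- horsfieldTree(demoHorsfieldTable(), rootOrder = 10,
                                     terminationOrder = 1, noiseFraction = 0)
  out
}

#' Export a spectral decomposition to CSV
#'
#' Writes an eigenvalue table and an eigenvector matrix (rows keyed by
#' terminal or internal node index, one column per mode). For Maury
#' decompositions of trees with coordinates, per-terminal eigenvector
#' magnitudes with coordinates are exported too, for external 3D viewers.
#'
#' @param decomposition a [SpectralDecomposition-class]
#' @param tree the originating [AirwayTree-class]
#' @param prefix output path prefix; files \code{<prefix>_values.csv},
#'   \code{<prefix>_vectors.csv} and optionally
#'   \code{<prefix>_magnitudes.csv} are written.
#' @return character vector of files written, invisibly
#' @export
writeSpectrumCsv <- function(decomposition, tree, prefix) {
  files <- character(0)
  vf <- paste0(prefix, "_values.csv")
  utils::write.csv(data.frame(mode = seq_along(decomposition@values),
                              eigenvalue = decomposition@values),
                   vf, row.names = FALSE)
  files <- c(files, vf)
  nodes <- if (decomposition@operator == "maury") terminalNodes(tree)
           else internalNodes(tree)
  vec <- as.data.frame(decomposition@vectors)
  names(vec) <- paste0("mode_", seq_along(decomposition@values))
  vec <- cbind(data.frame(node = nodes), vec)
  xf <- paste0(prefix, "_vectors.csv")
  utils::write.csv(vec, xf, row.names = FALSE)
  files <- c(files, xf)
  if (decomposition@operator == "maury" && nrow(tree@coords) > 0) {
    mag <- data.frame(node = nodes,
                      tree@coords[nodes, , drop = FALSE],
                      magnitude = sqrt(rowSums(decomposition@vectors^2)))
    mf <- paste0(prefix, "_magnitudes.csv")
    utils::write.csv(mag, mf, row.names = FALSE)
    files <- c(files, mf)
  }
  invisible(files)
}

#' Export a flow solution to CSV
#'
#' Writes a node table (pressure drops and net node fluxes) and a branch
#' table (per-branch fluxes).
#'
#' @param solution a [FlowSolution-class]
#' @param tree the originating [AirwayTree-class]
#' @param prefix output path prefix
#' @return character vector of files written, invisibly
#' @export
writeFlowCsv <- function(solution, tree, prefix) {
  part <- blockPartition(tree)
  nv <- nNodes(tree)
  dP <- numeric(nv)
  dP[part@internalNodes] <- solution@dPInternal
  dP[part@terminalNodes] <- solution@dPTerminal
  Q <- numeric(nv)
  Q[1] <- solution@QRoot
  Q[part@terminalNodes] <- solution@QTerminal
  nf <- paste0(prefix, "_nodes.csv")
  utils::write.csv(data.frame(node = seq_len(nv), dP_cmH2O = dP,
                              Q_l_per_s = Q), nf, row.names = FALSE)
  bf <- paste0(prefix, "_branches.csv")
  utils::write.csv(data.frame(branch = seq_len(nBranches(tree)),
                              q_l_per_s = solution@qBranch),
                   bf, row.names = FALSE)
  invisible(c(nf, bf))
}
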