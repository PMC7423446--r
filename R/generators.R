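#' Asymmetric Weibel airway tree
#'
#' Deterministic dyadic tree with \code{nDivisions} divisions below the
#' trachea (\code{nDivisions + 1} generations of airways). At each
#' bifurcation the major daughter scales radius and length by
#' \eqn{((1+A)/2)^{1/3}} and the minor daughter by \eqn{((1-A)/2)^{1/3}}
#' relative to the parent, where \eqn{0 \le A < 1} is the branching
#' asymmetry. The cube root makes the combined effective Poiseuille
#' resistance and volume of each daughter pair equal to that of the
#' symmetric case for every A. All airways have a fixed length-to-diameter
#' ratio.
#'
#' @param nDivisions integer N >= 1; the tree has 2^N terminal nodes.
#' @param asymmetry real A in [0, 1).
#' @param tracheaRadius trachea radius, mm.
#' @param lengthToDiameter dimensionless; l = lengthToDiameter * 2a.
#' @param resistance "poiseuille" to attach Poiseuille resistances (the
#'   default), or "none".
#' @param config configuration list, see [airwayConfig()].
#' @return an [AirwayTree-class]
#' @examples
#' tr <- weibelTree(3, asymmetry = 0.5)
#' nTerminals(tr)  # 8
#' @export
weibelTree <- function(nDivisions, asymmetry = 0, tracheaRadius = 9,
                       lengthToDiameter = 3,
                       resistance = c("poiseuille", "none"),
                       config = airwayConfig()) {
  resistance <- match.arg(resistance)
  if (nDivisions < 1) stop("nDivisions must be at least 1")
  if (asymmetry < 0 || asymmetry >= 1) stop("asymmetry must be in [0, 1)")
  fMaj <- ((1 + asymmetry) / 2)^(1 / 3)
  fMin <- ((1 - asymmetry) / 2)^(1 / 3)

  nb <- 2^(nDivisions + 1L) - 1L
  prox <- integer(nb)
  rad <- numeric(nb)
  # trachea: branch 1, v1 -> v2, generation 0
  prox[1] <- 1L
  rad[1] <- tracheaRadius
  # generation g branches occupy indices 2^g .. 2^(g+1) - 1 (heap layout);
  # branch j's distal node is j + 1, children of branch j are 2j and 2j + 1
  if (nDivisions >= 1) {
    for (j in seq_len(nb)) {
      k1 <- 2L * j
      if (k1 > nb) break
      prox[k1] <- j + 1L
      prox[k1 + 1L] <- j + 1L
      rad[k1] <- rad[j] * fMaj
      rad[k1 + 1L] <- rad[j] * fMin
    }
  }
  len <- lengthToDiameter * 2 * rad
  tr <- buildTree(cbind(prox, seq_len(nb) + 1L), radius = rad, length = len,
                  metadata = list(
                    generator = "weibel",
                    params = list(nDivisions = nDivisions,
                                  asymmetry = asymmetry,
                                  tracheaRadius = tracheaRadius,
                                  lengthToDiameter = lengthToDiameter)))
  if (resistance == "poiseuille") {
    tr <- poiseuilleResistances(tr, viscosity = config$viscosity,
                                prefactor = config$poiseuillePrefactor)
  }
  tr
}

#' Construct a Horsfield morphometry table
#'
#' @param order integer vector of Horsfield orders.
#' @param childOrders list of integer vectors (one per order); orders at the
#'   termination level may have no children.
#' @param meanRadius,meanLength numeric, mm.
#' @return a [HorsfieldTable-class]
#' @export
horsfieldTable <- function(order, childOrders, meanRadius, meanLength) {
  new("HorsfieldTable", order = as.integer(order), childOrders = childOrders,
      meanRadius = as.numeric(meanRadius), meanLength = as.numeric(meanLength))
}

#' Built-in demonstration Horsfield table
#'
#' A small synthetic table covering orders 1-10 with child orders
#' (g-1, g-2), giving a Fibonacci-like terminal count (89 terminals from
#' root order 10). Dimensions follow the classical symmetric taper — a
#' 9 mm trachea radius halving in cross-sectional volume per order
#' (radius factor 2^(-1/3)) with a length-to-diameter ratio of 3 — so the
#' resulting tree has realistic airway resistances and, unconstricted,
#' behaves as a healthy lung (every Maury eigenvalue well below 0.1 kappa
#' tau at adult elastance). This is a synthetic demonstration fixture,
#' not published human morphometry.
#'
#' @return a [HorsfieldTable-class]
#' @export
demoHorsfieldTable <- function() {
  ord <- 1:10
  rad <- 9 * 2^(-(10 - ord) / 3)
  horsfieldTable(
    order = ord,
    childOrders = c(list(integer(0)),
                    lapply(2:10, function(g) c(g - 1L, g - 2L))),
    meanRadius = rad,
    meanLength = 6 * rad)
}

#' Read / write a Horsfield table as CSV
#'
#' Columns: order, child_order_1, child_order_2, mean_radius_mm,
#' mean_length_mm. Empty child entries mark termination orders.
#'
#' @param path file path
#' @param table a [HorsfieldTable-class]
#' @return \code{readHorsfieldTable} returns a [HorsfieldTable-class].
#' @export
readHorsfieldTable <- function(path) {
  df <- utils::read.csv(path)
  need <- c("order", "child_order_1", "child_order_2",
            "mean_radius_mm", "mean_length_mm")
  if (!all(need %in% names(df))) {
    stop("Horsfield table CSV must have columns: ", paste(need, collapse = ", "))
  }
  co <- lapply(seq_len(nrow(df)), function(i) {
    v <- c(df$child_order_1[i], df$child_order_2[i])
    as.integer(v[!is.na(v)])
  })
  horsfieldTable(df$order, co, df$mean_radius_mm, df$mean_length_mm)
}

#' @rdname readHorsfieldTable
#' @export
writeHorsfieldTable <- function(table, path) {
  n <- length(table@order)
  c1 <- vapply(table@childOrders, function(x) if (length(x) >= 1) x[1] else NA_integer_, integer(1))
  c2 <- vapply(table@childOrders, function(x) if (length(x) >= 2) x[2] else NA_integer_, integer(1))
  utils::write.csv(data.frame(
    order = table@order, child_order_1 = c1, child_order_2 = c2,
    mean_radius_mm = table@meanRadius, mean_length_mm = table@meanLength),
    path, row.names = FALSE)
  invisible(path)
}

#' Horsfield-order recursive airway tree
#'
#' Expands a morphometry table recursively: a branch of order g spawns the
#' table's child orders for g; children whose order is at or below
#' \code{terminationOrder} become terminal branches. Radius and length are
#' drawn independently per branch as Gaussians with the table means and
#' standard deviation \code{noiseFraction} times the mean; draws at or
#' below 5\% of the mean (configurable) are resampled to avoid nonphysical
#' geometry. Orders below the table's coverage take the dimensions of the
#' lowest covered order.
#'
#' @param table a [HorsfieldTable-class] covering rootOrder down to
#'   terminationOrder.
#' @param rootOrder order of the root branch (trachea).
#' @param terminationOrder orders at or below this are terminal (default 1).
#' @param noiseFraction Gaussian sd as a fraction of the mean (default 0).
#' @param seed integer seed; the same seed reproduces the tree exactly.
#' @param resistance "poiseuille" or "none".
#' @param config configuration list, see [airwayConfig()].
#' @return an [AirwayTree-class] carrying per-branch Horsfield orders.
#' @export
horsfieldTree <- function(table, rootOrder, terminationOrder = 1L,
                          noiseFraction = 0, seed = 1L,
                          resistance = c("poiseuille", "none"),
                          config = airwayConfig()) {
  resistance <- match.arg(resistance)
  stopifnot(is(table, "HorsfieldTable"))
  if (noiseFraction < 0) stop("noiseFraction must be nonnegative")
  covered <- table@order
  if (!all(seq(terminationOrder, rootOrder) %in% covered)) {
    stop("table must cover all orders from ", rootOrder, " down to ",
         terminationOrder)
  }
  rowOf <- function(g) match(max(min(covered), g), covered)

  drawDim <- function(mean) {
    if (noiseFraction == 0) return(mean)
    repeat {
      x <- stats::rnorm(1, mean, noiseFraction * mean)
      if (x > config$resampleThreshold * mean) return(x)
    }
  }

  withSeed(seed, function() {
    prox <- integer(0); ord <- integer(0)
    rad <- numeric(0); len <- numeric(0)
    nextNode <- 2L
    # queue of (proximal node, order); grow breadth-first
    queue <- list(list(node = 1L, order = as.integer(rootOrder)))
    while (length(queue) > 0) {
      item <- queue[[1]]; queue <- queue[-1]
      g <- item$order
      i <- rowOf(g)
      prox <- c(prox, item$node)
      ord <- c(ord, g)
      rad <- c(rad, drawDim(table@meanRadius[i]))
      len <- c(len, drawDim(table@meanLength[i]))
      myNode <- nextNode
    nextNode <- nextNode + 1L
      if (g > terminationOrder) {
        for (cg in table@childOrders[[i]]) {
          queue <- c(queue, list(list(node = myNode, order = as.integer(cg))))
        }
      }
    }
    edges <- cbind(prox, seq_along(prox) + 1L)
    tr <- buildTree(edges, radius = rad, length = len, horsfieldOrder = ord,
                    metadata = list(
                      generator = "horsfield",
                      params = list(rootOrder = rootOrder,
                                    terminationOrder = terminationOrder,
                                    noiseFraction = noiseFraction),
                      seed = seed))
    if (resistance == "poiseuille") {
      tr <- poiseuilleResistances(tr, viscosity = config$viscosity,
                                  prefactor = config$poiseuillePrefactor)
    }
    tr
  })
}

#' Assign distal diameters from an exponential taper
#'
#' Branches below an anchored Horsfield order N take diameter
#' \eqn{D(g) = D_N R^{g-N}}, i.e. \eqn{\log D(g) = (g-N)\log R + \log D_N},
#' while branches at or above the anchor keep their measured diameters.
#' Resistances, when present, are rescaled by the fourth power of the
#' radius change.
#'
#' @param tree an [AirwayTree-class] with Horsfield orders available.
#' @param anchorOrder Horsfield order N of the most distal measured airway.
#' @param anchorDiameter measured diameter D_N at the anchor, mm.
#' @param ratio per-order diameter ratio (default 1.15).
#' @return the modified [AirwayTree-class]
#' @export
assignDistalDiameters <- function(tree, anchorOrder, anchorDiameter,
                                  ratio = 1.15) {
  if (anchorDiameter <= 0) stop("anchorDiameter must be positive")
  ord <- horsfieldOrders(tree)
  sel <- ord < anchorOrder
  newRad <- tree@radius
  newRad[sel] <- anchorDiameter * ratio^(ord[sel] - anchorOrder) / 2
  scale <- tree@radius / newRad
  tree@resistance <- tree@resistance * scale^4
  tree@radius <- newRad
  tree@metadata$distalDiameters <- list(anchorOrder = anchorOrder,
                                        anchorDiameter = anchorDiameter,
                                        ratio = ratio)
  validObject(tree)
  tree
}

#' Constriction specification
#'
#' Describes random airway narrowing applied to one Horsfield order: a
#' fraction f of the branches at order g is selected uniformly at random
#' and each selected radius is reduced by a factor drawn uniformly from
#' \code{reductionRange} (radius becomes radius*(1-u), so with the default
#' range constricted radii are 5-50\% of the original).
#'
#' @param order target Horsfield order g.
#' @param fraction f in [0, 1].
#' @param reductionRange interval of reduction factors (default c(0.5, 0.95)).
#' @param seed integer seed.
#' @return a list of class "ConstrictionSpec"
#' @export
constrictionSpec <- function(order, fraction, reductionRange = c(0.5, 0.95),
                             seed = 1L) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (any(reductionRange <= 0) || any(reductionRange >= 1)) {
    stop("reduction factors must be in (0, 1)")
  }
  structure(list(order = as.integer(order), fraction = fraction,
                 reductionRange = reductionRange, seed = as.integer(seed)),
            class = "ConstrictionSpec")
}

#' Apply random constrictions to one Horsfield order
#'
#' Selects \code{ceiling(f * n_g)} of the n_g branches at the target order
#' uniformly at random and narrows each selected radius. Selection uses a
#' seeded random permutation with reduction factors drawn in permutation
#' order, so at a fixed seed the constricted sets are nested as f grows.
#' Resistances are rescaled by the fourth power of the radius change;
#' topology, lengths and unselected radii are untouched.
#'
#' @param tree an [AirwayTree-class] with resistances set.
#' @param spec a [constrictionSpec()], or NULL to use the remaining
#'   arguments.
#' @param order,fraction,reductionRange,seed see [constrictionSpec()].
#' @param mode "reduce-by" (radius*(1-u), the default) or "multiply-by"
#'   (radius*u).
#' @return the constricted [AirwayTree-class]
#' @export
applyConstrictions <- function(tree, spec = NULL, order = NULL, fraction = NULL,
                               reductionRange = c(0.5, 0.95), seed = 1L,
                               mode = airwayConfig()$constrictionMode) {
  if (is.null(spec)) {
    spec <- constrictionSpec(order, fraction, reductionRange, seed)
  }
  ord <- horsfieldOrders(tree)
  idx <- which(ord == spec$order)
  if (length(idx) == 0) {
    stop("no branches of Horsfield order ", spec$order, " in the tree")
  }
  k <- as.integer(ceiling(spec$fraction * length(idx)))
  sel <- integer(0); u <- numeric(0)
  if (k > 0) {
    draws <- withSeed(spec$seed, function() {
      perm <- sample(idx)
      list(perm = perm,
           u = stats::runif(length(idx), spec$reductionRange[1],
                            spec$reductionRange[2]))
    })
    sel <- draws$perm[seq_len(k)]
    u <- draws$u[seq_len(k)]
    factor <- if (mode == "reduce-by") 1 - u else u
    oldRad <- tree@radius[sel]
    tree@radius[sel] <- oldRad * factor
    tree@resistance[sel] <- tree@resistance[sel] * (oldRad / tree@radius[sel])^4
  }
  tree@metadata$constrictions <- c(tree@metadata$constrictions, list(list(
    order = spec$order, fraction = spec$fraction,
    reductionRange = spec$reductionRange, seed = spec$seed, mode = mode,
    selected = sel)))
  validObject(tree)
  tree
}
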