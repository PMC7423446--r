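#' Construct ventilation parameters
#'
#' @param kappaUnit per-unit elastance, cmH2O/l (give this or kappaTotal).
#' @param kappaTotal total lung elastance kappa/|T|, cmH2O/l (default 5,
#'   representative of an adult at a 4 s breath period).
#' @param tau breath period, s (default 4).
#' @param Ps pleural pressure amplitude, cmH2O (default 1; tidal volumes
#'   scale linearly in Ps, so the heterogeneity index is invariant to it).
#' @param Ppl0 pleural pressure offset, cmH2O (default 0; shifts volumes
#'   only).
#' @param nCycles breath cycles for direct simulation (default 5).
#' @return a [VentilationParams-class]
#' @export
ventilationParams <- function(kappaUnit = NA_real_, kappaTotal = NA_real_,
                              tau = 4, Ps = 1, Ppl0 = 0, nCycles = 5L) {
  if (is.na(kappaUnit) && is.na(kappaTotal)) kappaTotal <- 5
  new("VentilationParams", kappaUnit = as.numeric(kappaUnit),
      kappaTotal = as.numeric(kappaTotal), tau = as.numeric(tau),
      Ps = as.numeric(Ps), Ppl0 = as.numeric(Ppl0),
      nCycles = as.integer(nCycles))
}

setMethod("show", "VentilationParams", function(object) {
  cat("VentilationParams: tau =", object@tau, "s, Ps =", object@Ps,
      "cmH2O,",
      if (!is.na(object@kappaUnit)) paste("kappa =", object@kappaUnit)
      else paste("kappa/|T| =", object@kappaTotal),
      "cmH2O/l\n")
})

# per-unit elastance for a tree with nTerm identical units in parallel
resolveKappa <- function(params, nTerm) {
  if (!is.na(params@kappaUnit)) return(params@kappaUnit)
  params@kappaTotal * nTerm
}

#' Coefficient of variation of per-unit ventilation
#'
#' The ventilation heterogeneity index: population standard deviation of
#' the per-unit tidal volumes divided by their mean. Zero for perfectly
#' homogeneous ventilation and invariant to rescaling all volumes.
#'
#' @param deltaV numeric vector of per-unit tidal volumes (l), mean > 0.
#' @param normalization "population" (divide by n, the default) or
#'   "sample" (divide by n - 1).
#' @return nonnegative scalar
#' @export
sigmaV <- function(deltaV, normalization = c("population", "sample")) {
  normalization <- match.arg(normalization)
  if (length(deltaV) == 0) stop("deltaV must be nonempty")
  m <- mean(deltaV)
  if (m <= 0) stop("mean ventilation must be positive")
  n <- length(deltaV)
  denom <- if (normalization == "population") n else n - 1L
  sqrt(sum((deltaV - m)^2) / denom) / m
}

#' Count the large (resistive) Maury eigenvalues
#'
#' Modes with \eqn{\mu_k > c\,\kappa\tau} (default c = 0.1) are slow enough
#' relative to the breath period that airway resistance, not unit
#' compliance, controls their dynamics; their count signals how many
#' independent high-resistance flow patterns shape ventilation
#' heterogeneity. A healthy tree typically has none.
#'
#' @param eigenvalues Maury eigenvalues, descending. Must either be the
#'   full spectrum or reach below the threshold.
#' @param params a [VentilationParams-class].
#' @param nTerm number of terminal units (needed to resolve kappa when
#'   given as a total; defaults to the number of eigenvalues).
#' @param threshold multiple c of kappa*tau (default 0.1).
#' @return integer count
#' @export
largeModeCount <- function(eigenvalues, params, nTerm = length(eigenvalues),
                           threshold = 0.1) {
  kappa <- resolveKappa(params, nTerm)
  cut <- threshold * kappa * params@tau
  cnt <- sum(eigenvalues > cut)
  if (cnt == length(eigenvalues) && length(eigenvalues) < nTerm) {
    warning("all supplied eigenvalues exceed the threshold; ",
            "the count is a lower bound - supply more modes")
  }
  as.integer(cnt)
}

#' Direct simulation of compliance-driven tidal ventilation
#'
#' Integrates \eqn{R\dot V + \kappa V = -P_{pl}(t)\,e} with sinusoidal
#' pleural pressure \eqn{P_{pl} = P_{pl0} + P_s\sin(2\pi t/\tau)} without
#' ever forming the dense Maury operator R: each right-hand-side
#' evaluation solves the sparse resistance network (via a prefactored
#' Cholesky of the internal Laplacian) for the terminal fluxes given the
#' instantaneous elastic recoil pressures. The per-unit tidal volume is
#' \eqn{\Delta V_i = \max V_i - \min V_i} over the final cycle, after the
#' transient has decayed; periodicity of the final cycle is checked
#' against the preceding one.
#'
#' @param tree an [AirwayTree-class] with resistances set.
#' @param params a [VentilationParams-class].
#' @param nCycles override the cycle count; NULL picks enough cycles for
#'   the slowest mode's transient \eqn{e^{-\kappa t/\mu_1}} to decay below
#'   1e-6 (estimating \eqn{\mu_1} by power iteration), never fewer than
#'   \code{params@nCycles}.
#' @param samplesPerCycle output resolution of the final two cycles
#'   (default 200).
#' @param rtol,atol integrator tolerances.
#' @param config configuration list, see [airwayConfig()].
#' @return a [VentilationResult-class] with method "direct"
#' @export
simulateDirect <- function(tree, params = ventilationParams(),
                           nCycles = NULL, samplesPerCycle = 200,
                           rtol = 1e-8, atol = 1e-10,
                           config = airwayConfig()) {
  nT <- nTerminals(tree)
  kappa <- resolveKappa(params, nT)
  tau <- params@tau
  sys <- buildLaplacian(tree)
  nInt <- nrow(sys@Lint)
  fac <- if (nInt > 0) Matrix::Cholesky(forceSymmetricSparse(sys@Lint),
                                        LDL = FALSE) else NULL
  qTerm <- function(dPterm) {
    if (nInt > 0) {
      dPint <- as.numeric(Matrix::solve(fac, sys@B %*% (sys@gammaTerm * dPterm)))
      sys@gammaTerm * (as.numeric(Matrix::crossprod(sys@B, dPint)) - dPterm)
    } else {
      -sys@gammaTerm * dPterm
    }
  }
  if (is.null(nCycles)) {
    mu1 <- powerIterationMu1(tree)
    needed <- ceiling(log(1e6) * mu1 / (kappa * tau)) + 1L
    nCycles <- max(params@nCycles, needed)
  }
  ppl <- function(t) params@Ppl0 + params@Ps * sin(2 * pi * t / tau)
  deriv <- function(t, V, p) {
    dPterm <- -(ppl(t) + kappa * V)
    list(-qTerm(dPterm))
  }
  # coarse sampling through the burn-in, fine over the last two cycles
  tBurn <- seq(0, (nCycles - 2) * tau, by = tau / 8)
  tFine <- seq((nCycles - 2) * tau, nCycles * tau, by = tau / samplesPerCycle)
  times <- unique(c(tBurn, tFine))
  V0 <- rep(-params@Ppl0 / kappa, nT)   # elastic equilibrium at t = 0
  out <- deSolve::lsoda(V0, times, deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) stop("ODE integration failed")
  tt <- out[, 1]
  lastIdx <- tt >= (nCycles - 1) * tau - 1e-12
  prevIdx <- tt >= (nCycles - 2) * tau - 1e-12 & tt <= (nCycles - 1) * tau + 1e-12
  Vlast <- out[lastIdx, -1, drop = FALSE]
  Vprev <- out[prevIdx, -1, drop = FALSE]
  deltaV <- apply(Vlast, 2, max) - apply(Vlast, 2, min)
  deltaVprev <- apply(Vprev, 2, max) - apply(Vprev, 2, min)
  periodErr <- max(abs(deltaV - deltaVprev)) / max(mean(deltaV), .Machine$double.eps)
  if (periodErr > config$periodicityTol) {
    warning(sprintf(
      "final cycle not periodic to tolerance (relative drift %.2e); increase nCycles",
      periodErr))
  }
  new("VentilationResult",
      deltaV = as.numeric(deltaV),
      meanDeltaV = mean(deltaV),
      sigmaV = sigmaV(deltaV),
      method = "direct",
      modesUsed = NA_integer_,
      largeModeCount = NA_integer_,
      diagnostics = list(kappaUnit = kappa, tau = tau, Ps = params@Ps,
                         Ppl0 = params@Ppl0, nCycles = nCycles,
                         periodicityError = periodErr))
}

# dominant Maury eigenvalue by power iteration on the sparse factors
powerIterationMu1 <- function(tree, iters = 30) {
  Tm <- subtreeMaps(tree)$T
  r <- resistances(tree)
  v <- rep(1, nrow(Tm))
  v <- v / sqrt(sum(v^2))
  mu <- 0
  for (i in seq_len(iters)) {
    w <- as.numeric(Tm %*% (r * as.numeric(Matrix::crossprod(Tm, v))))
    mu <- sum(v * w)
    v <- w / sqrt(sum(w^2))
  }
  mu
}

#' Closed-form modal solution of tidal ventilation
#'
#' Evaluates the periodic solution of the ventilation model in the Maury
#' eigenbasis. Each mode obeys an independent RC equation
#' \eqn{\mu_k\dot a_k + \kappa a_k = -P_{pl}(t)\,e^T\hat v_k}, and for
#' sinusoidal pleural pressure the per-unit tidal volume has the closed
#' form
#' \deqn{\Delta V_i = 2P_s\left[\left(\frac{1}{\kappa} - \sum_k
#'   \frac{e^T\hat v_k}{\kappa}\frac{x_k^2}{1+x_k^2}\hat v_{k,i}\right)^2 +
#'   \left(\sum_k \frac{e^T\hat v_k}{\kappa}\frac{x_k}{1+x_k^2}
#'   \hat v_{k,i}\right)^2\right]^{1/2}}
#' with \eqn{x_k = 2\pi\mu_k/(\kappa\tau)}. Truncating the sums to the
#' largest-eigenvalue modes retains the resistive corrections that matter
#' (modes with \eqn{\mu_k/(\kappa\tau)\ll 1} are compliance-dominated and
#' contribute only through the uniform elastic term); with all |T| modes
#' the result matches direct ODE integration. Zero modes give exactly
#' uniform ventilation \eqn{2P_s/\kappa}.
#'
#' @param tree an [AirwayTree-class] with resistances set.
#' @param decomposition a maury [SpectralDecomposition-class] holding the
#'   largest-eigenvalue modes (or the full spectrum); NULL computes the
#'   full spectrum.
#' @param params a [VentilationParams-class]. Unit elastance is uniform
#'   across units; heterogeneous elastance is not supported.
#' @param nModes number of largest-eigenvalue modes to use (default: all
#'   available in the decomposition).
#' @param config configuration list, see [airwayConfig()].
#' @return a [VentilationResult-class] with method "modal"
#' @export
simulateModal <- function(tree, decomposition = NULL,
                          params = ventilationParams(), nModes = NULL,
                          config = airwayConfig()) {
  nT <- nTerminals(tree)
  kappa <- resolveKappa(params, nT)
  tau <- params@tau
  if (is.null(decomposition)) {
    decomposition <- maurySpectrum(tree, config = config)
  }
  stopifnot(decomposition@operator == "maury")
  if (decomposition@dim != nT) {
    stop("decomposition is for a tree with ", decomposition@dim,
         " terminals, not ", nT)
  }
  nAvail <- length(decomposition@values)
  if (is.null(nModes)) nModes <- nAvail
  if (nModes > nAvail) stop("nModes exceeds the ", nAvail, " available modes")
  sel <- seq_len(nModes)
  sinCoef <- rep(1 / kappa, nT)
  cosCoef <- rep(0, nT)
  if (nModes > 0) {
    V <- decomposition@vectors[, sel, drop = FALSE]
    mu <- decomposition@values[sel]
    ck <- colSums(V)                       # e^T v_k
    x <- 2 * pi * mu / (kappa * tau)
    sinCoef <- sinCoef - as.numeric(V %*% (ck * x^2 / (1 + x^2))) / kappa
    cosCoef <- as.numeric(V %*% (ck * x / (1 + x^2))) / kappa
  }
  deltaV <- 2 * params@Ps * sqrt(sinCoef^2 + cosCoef^2)
  lmc <- largeModeCount(decomposition@values, params, nTerm = nT)
  new("VentilationResult",
      deltaV = deltaV,
      meanDeltaV = mean(deltaV),
      sigmaV = sigmaV(deltaV),
      method = "modal",
      modesUsed = as.integer(nModes),
      largeModeCount = lmc,
      diagnostics = list(kappaUnit = kappa, tau = tau, Ps = params@Ps,
                         Ppl0 = params@Ppl0))
}

setMethod("show", "VentilationResult", function(object) {
  cat("VentilationResult (", object@method,
      if (!is.na(object@modesUsed)) paste0(", ", object@modesUsed, " modes"),
      "): ", length(object@deltaV), " units, mean dV = ",
      signif(object@meanDeltaV, 5), " l, sigma_V = ",
      signif(object@sigmaV, 5), "\n", sep = "")
})

#' Quadrature evaluation of the modal convolution solution
#'
#' Integrates the per-mode convolution
#' \eqn{a_k(t) = -(e^T\hat v_k/\kappa)\,e^{-(\kappa/\mu_k)t}\int_0^t
#' \dot P_{pl}(t')e^{(\kappa/\mu_k)t'}dt' - (e^T\hat v_k/\kappa)P_{pl}(t)}
#' numerically for an arbitrary pleural pressure profile; for sinusoidal
#' driving it converges to the closed-form periodic solution once the
#' transient has decayed. Mainly a cross-check and a hook for non-
#' sinusoidal driving.
#'
#' @param tree an [AirwayTree-class].
#' @param decomposition a maury [SpectralDecomposition-class].
#' @param params a [VentilationParams-class].
#' @param pplFun pleural pressure function of time (default: the
#'   sinusoidal profile in params).
#' @param pplDotFun its time derivative.
#' @param nCycles cycles to integrate before reading off the final cycle.
#' @param samplesPerCycle quadrature/output resolution.
#' @return a [VentilationResult-class] with method "modal-quadrature"
#' @export
simulateModalQuadrature <- function(tree, decomposition = NULL,
                                    params = ventilationParams(),
                                    pplFun = NULL, pplDotFun = NULL,
                                    nCycles = NULL, samplesPerCycle = 400) {
  nT <- nTerminals(tree)
  kappa <- resolveKappa(params, nT)
  tau <- params@tau
  if (is.null(decomposition)) decomposition <- maurySpectrum(tree)
  if (is.null(pplFun)) {
    pplFun <- function(t) params@Ppl0 + params@Ps * sin(2 * pi * t / tau)
    pplDotFun <- function(t) params@Ps * (2 * pi / tau) * cos(2 * pi * t / tau)
  }
  if (is.null(nCycles)) {
    nCycles <- max(params@nCycles,
                   ceiling(log(1e6) * max(decomposition@values) /
                           (kappa * tau)) + 1L)
  }
  V <- decomposition@vectors
  mu <- decomposition@values
  ck <- colSums(V)
  tGrid <- seq(0, nCycles * tau, by = tau / samplesPerCycle)
  dt <- tau / samplesPerCycle
  # a_k(t) = -(ck/kappa) ppl(t) + (ck/kappa) exp(-t/tk) * I_k(t),
  # I_k(t) = int_0^t pplDot(s) exp(s/tk) ds, tk = mu_k/kappa, evaluated
  # stably as a running exponentially-discounted trapezoid sum
  tk <- mu / kappa
  nK <- length(mu)
  acc <- numeric(nK)
  A <- matrix(0, length(tGrid), nK)
  pd <- pplDotFun(tGrid)
  decay <- exp(-dt / tk)
  for (s in 2:length(tGrid)) {
    acc <- acc * decay + (pd[s - 1] * decay + pd[s]) * dt / 2
    A[s, ] <- acc
  }
  finalIdx <- tGrid >= (nCycles - 1) * tau - 1e-12
  Vt <- matrix(rep(-pplFun(tGrid[finalIdx]) / kappa, nT),
               ncol = nT)   # uniform elastic term on all units
  Ak <- A[finalIdx, , drop = FALSE] * rep(ck / kappa, each = sum(finalIdx))
  Vt <- Vt + Ak %*% t(V)
  deltaV <- apply(Vt, 2, max) - apply(Vt, 2, min)
  new("VentilationResult",
      deltaV = as.numeric(deltaV),
      meanDeltaV = mean(deltaV),
      sigmaV = sigmaV(deltaV),
      method = "modal-quadrature",
      modesUsed = as.integer(nK),
      largeModeCount = largeModeCount(mu, params, nTerm = nT),
      diagnostics = list(kappaUnit = kappa, tau = tau, nCycles = nCycles))
}

#' Constriction sweep with direct and reduced-order heterogeneity
#'
#' For each constriction specification: constrict the tree, compute the
#' ventilation heterogeneity by direct ODE simulation and by the modal
#' closed form using a budget of the largest-eigenvalue Maury modes
#' (default 1\% of |T|), and count the large (resistive) eigenvalues.
#'
#' @param tree the baseline [AirwayTree-class].
#' @param specs list of [constrictionSpec()] objects.
#' @param params a [VentilationParams-class].
#' @param modeBudget fraction of |T| used for the reduced model
#'   (default 0.01).
#' @param outFile optional CSV path for the results table.
#' @param config configuration list, see [airwayConfig()].
#' @return data.frame with one row per spec: order, fraction, seed,
#'   sigmaV_direct, sigmaV_modal, large_mode_count, modes_used,
#'   mean_deltaV_direct; the per-terminal tidal volume vectors are
#'   attached as attribute "deltaV".
#' @export
vhExperiment <- function(tree, specs, params = ventilationParams(),
                         modeBudget = 0.01, outFile = NULL,
                         config = airwayConfig()) {
  nT <- nTerminals(tree)
  nm <- max(1L, as.integer(ceiling(modeBudget * nT)))
  rows <- vector("list", length(specs))
  dVs <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    ctree <- if (sp$fraction > 0) applyConstrictions(tree, sp) else tree
    decomp <- if (nm < nT) {
      maurySpectrum(ctree, nModes = nm, which = "largest", config = config)
    } else {
      maurySpectrum(ctree, config = config)
    }
    direct <- simulateDirect(ctree, params, config = config)
    modal <- simulateModal(ctree, decomp, params, config = config)
    rows[[i]] <- data.frame(
      order = sp$order, fraction = sp$fraction, seed = sp$seed,
      sigmaV_direct = direct@sigmaV, sigmaV_modal = modal@sigmaV,
      large_mode_count = modal@largeModeCount, modes_used = modal@modesUsed,
      mean_deltaV_direct = direct@meanDeltaV)
    dVs[[i]] <- list(direct = direct@deltaV, modal = modal@deltaV)
  }
  res <- do.call(rbind, rows)
  attr(res, "deltaV") <- dVs
  if (!is.null(outFile)) utils::write.csv(res, outFile, row.names = FALSE)
  res
}
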