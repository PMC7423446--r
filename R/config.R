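#' Package configuration defaults
#'
#' Central record of physical constants, unit conventions, solver tolerances
#' and size caps. Geometry is in mm, pressure in cmH2O, volume in l, time in
#' s, resistance in cmH2O s/l. Override individual entries via \code{...}.
#'
#' @param ... named overrides of the defaults.
#' @return a named list:
#' \describe{
#'   \item{viscosity}{dynamic viscosity of air, Pa s (default 1.93e-5).}
#'   \item{poiseuillePrefactor}{constant in r = c mu l / a^4 (default 8/pi).}
#'   \item{denseCap}{largest |T| for which the dense Maury matrix is formed
#'     (default 4096).}
#'   \item{laplacianDenseCap}{largest internal dimension for a full dense
#'     Laplacian eigendecomposition (default 5000).}
#'   \item{solveTol}{relative residual tolerance for direct solves.}
#'   \item{eigTol}{relative residual tolerance for eigenpairs.}
#'   \item{resampleThreshold}{Gaussian geometry draws at or below this
#'     fraction of the mean are redrawn (default 0.05).}
#'   \item{constrictionMode}{"reduce-by" (radius -> radius*(1-u)) or
#'     "multiply-by" (radius -> radius*u).}
#'   \item{periodicityTol}{relative tolerance for the final-cycle
#'     periodicity check in direct ventilation simulation.}
#' }
#' @export
airwayConfig <- function(...) {
  cfg <- list(
    viscosity = 1.93e-5,
    poiseuillePrefactor = 8 / pi,
    denseCap = 4096L,
    laplacianDenseCap = 5000L,
    solveTol = 1e-10,
    eigTol = 1e-8,
    resampleThreshold = 0.05,
    constrictionMode = "reduce-by",
    periodicityTol = 1e-4
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  cfg
}

# Pa s m^-3 -> cmH2O s l^-1:  divide pressure by 98.0665 Pa/cmH2O and
# multiply flow by 1e3 l/m^3.
siToCmH2OsPerL <- function() 1 / (98.0665 * 1000)

#' Read or write a run configuration as YAML
#'
#' Configurations round-trip losslessly through YAML; unknown keys are
#' rejected so a config file always fully determines a run.
#'
#' @param path file path
#' @param cfg a config list from [airwayConfig()]
#' @return \code{readRunConfig} returns a config list.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(airwayConfig, raw)
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# evaluate fn with a temporary RNG seed, restoring global state
withSeed <- function(seed, fn) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fn()
}
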