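#' @include helix-geometry.R
NULL

## Stalk-filament elastic energy: quadratic in (kappa, tau) about the
## spontaneous values, with moduli derived from molecular dynamics of the
## stalk tetramer. Energies in kJ/mol; lengths in nm.

#' FilamentElasticParams: moduli and spontaneous shape of the stalk filament
#'
#' Parameters of the elastic energy per unit length
#' \eqn{E = \alpha_\kappa(\kappa-\kappa_0)^2 + \alpha_\tau(\tau-\tau_0)^2},
#' plus the dimer length used to report energies per dimer and an optional
#' GG-dimer interaction free energy per unit length \eqn{g_0} added when
#' the filament forms inter-rung GG dimers
#' (\eqn{E_{total} = E + g_0}). \eqn{g_0} is the same for one- and
#' two-start helices, so it shifts energies without moving any minimum;
#' its magnitude is unknown and defaults to 0.
#'
#' @slot alphaKappa bending modulus, nm kJ/mol (default 3000)
#' @slot alphaTau twist modulus, nm kJ/mol (default 2700)
#' @slot kappa0 spontaneous curvature, 1/nm (default 0.058)
#' @slot tau0 spontaneous twist density, 1/nm (default 0.041)
#' @slot dimerLength length of one dynamin dimer along the filament, nm
#'   (default 5.6)
#' @slot g0 GG-dimer free energy per unit length, kJ/mol/nm (default 0)
#' @exportClass FilamentElasticParams
setClass("FilamentElasticParams",
  representation(alphaKappa = "numeric", alphaTau = "numeric",
                 kappa0 = "numeric", tau0 = "numeric",
                 dimerLength = "numeric", g0 = "numeric"),
  prototype(alphaKappa = 3000, alphaTau = 2700, kappa0 = 0.058,
            tau0 = 0.041, dimerLength = 5.6, g0 = 0))

setValidity("FilamentElasticParams", function(object) {
  msg <- character()
  for (s in c("alphaKappa", "alphaTau", "kappa0", "tau0", "dimerLength",
              "g0")) {
    v <- slot(object, s)
    if (length(v) != 1 || !is.finite(v))
      msg <- c(msg, paste(s, "must be a single finite number"))
  }
  if (!length(msg)) {
    if (object@alphaKappa <= 0 || object@alphaTau <= 0)
      msg <- c(msg, "moduli must be > 0")
    if (object@dimerLength <= 0) msg <- c(msg, "dimerLength must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct FilamentElasticParams
#'
#' Defaults are the stalk-filament values: alphaKappa = 3000 nm kJ/mol,
#' alphaTau = 2700 nm kJ/mol, kappa0 = 0.058 1/nm, tau0 = 0.041 1/nm,
#' dimerLength = 5.6 nm, g0 = 0.
#'
#' @param alphaKappa bending modulus (nm kJ/mol)
#' @param alphaTau twist modulus (nm kJ/mol)
#' @param kappa0 spontaneous curvature (1/nm)
#' @param tau0 spontaneous twist density (1/nm)
#' @param dimerLength dimer length (nm)
#' @param g0 GG-dimer free energy per unit length (kJ/mol/nm)
#' @return a \linkS4class{FilamentElasticParams}
#' @export
FilamentElasticParams <- function(alphaKappa = 3000, alphaTau = 2700,
                                  kappa0 = 0.058, tau0 = 0.041,
                                  dimerLength = 5.6, g0 = 0) {
  new("FilamentElasticParams", alphaKappa = alphaKappa, alphaTau = alphaTau,
      kappa0 = kappa0, tau0 = tau0, dimerLength = dimerLength, g0 = g0)
}

setMethod("show", "FilamentElasticParams", function(object) {
  cat(sprintf(paste0(
    "FilamentElasticParams: alpha_kappa %.0f, alpha_tau %.0f nm kJ/mol; ",
    "kappa0 %.3f, tau0 %.3f 1/nm;\n  dimer %.1f nm, g0 %.3g kJ/mol/nm\n"),
    object@alphaKappa, object@alphaTau, object@kappa0, object@tau0,
    object@dimerLength, object@g0))
})

#' EnergyLandscape: per-dimer elastic energy over a (radius, pitch) grid
#'
#' @slot radius grid of radii, nm (rows of the energy matrix)
#' @slot pitch grid of pitches, nm (columns)
#' @slot energy matrix of per-dimer energies, kJ/mol
#' @slot params the \linkS4class{FilamentElasticParams} used
#' @exportClass EnergyLandscape
setClass("EnergyLandscape",
  representation(radius = "numeric", pitch = "numeric", energy = "matrix",
                 params = "FilamentElasticParams"))

setValidity("EnergyLandscape", function(object) {
  if (nrow(object@energy) != length(object@radius) ||
      ncol(object@energy) != length(object@pitch))
    return("energy matrix dimensions must match radius (rows) x pitch (cols)")
  if (any(!is.finite(object@energy)))
    return("energies must be finite")
  TRUE
})

setMethod("show", "EnergyLandscape", function(object) {
  i <- arrayInd(which.min(object@energy), dim(object@energy))
  cat(sprintf(paste0(
    "EnergyLandscape: %d x %d grid, r in [%.3g, %.3g] nm, ",
    "p in [%.3g, %.3g] nm\n  min %.4g kJ/mol per dimer at ",
    "(r %.3g, p %.3g)\n"),
    length(object@radius), length(object@pitch),
    min(object@radius), max(object@radius),
    min(object@pitch), max(object@pitch),
    min(object@energy), object@radius[i[1]], object@pitch[i[2]]))
})

#' Convert an EnergyLandscape to a long-format data.frame
#' @param x an \linkS4class{EnergyLandscape}
#' @param row.names,optional,... ignored (S3 compatibility)
#' @return data.frame with columns radius_nm, pitch_nm, energy_kjmol
#' @export
as.data.frame.EnergyLandscape <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(radius_nm = rep(x@radius, times = length(x@pitch)),
             pitch_nm = rep(x@pitch, each = length(x@radius)),
             energy_kjmol = as.vector(x@energy))
}

## ---- operations ----

#' Elastic energy per unit filament length
#'
#' \eqn{E = \alpha_\kappa(\kappa-\kappa_0)^2 +
#' \alpha_\tau(\tau-\tau_0)^2}, in kJ/mol/nm. Non-negative; zero exactly
#' at the spontaneous configuration. The GG term g0 is \emph{not} added
#' here (see \code{\link{energyPerDimer}}).
#'
#' @param ct a \linkS4class{CurvatureTwist}, or numeric vector of kappas
#' @param params a \linkS4class{FilamentElasticParams}
#' @param tau numeric vector of taus when \code{ct} is numeric
#' @return energy density in kJ/mol/nm (vectorised when given numerics)
#' @export
energyPerLength <- function(ct, params = FilamentElasticParams(),
                            tau = NULL) {
  validObject(params)
  if (is(ct, "CurvatureTwist")) {
    k <- ct@kappa; t <- ct@tau
  } else {
    k <- ct; t <- tau
    if (is.null(t)) stop("tau required when ct is numeric")
  }
  params@alphaKappa * (k - params@kappa0)^2 +
    params@alphaTau * (t - params@tau0)^2
}

#' Elastic energy per dynamin dimer
#'
#' Energy per unit length at the helix shape, times the dimer length
#' (default 5.6 nm). When \code{g0} is non-zero the GG free energy
#' \code{g0 x dimerLength} is added (total energy per unit length is
#' E + g0).
#'
#' @param shape a \linkS4class{HelixShape}, or numeric radius (nm)
#' @param params a \linkS4class{FilamentElasticParams}
#' @param pitch numeric pitch (nm) when \code{shape} is numeric
#' @return per-dimer energy in kJ/mol (vectorised over radius/pitch)
#' @examples
#' energyPerDimer(HelixShape(13.5, 10))  # ~19.7 kJ/mol
#' energyPerDimer(HelixShape(13.5, 20))  # ~11.5 kJ/mol
#' @export
energyPerDimer <- function(shape, params = FilamentElasticParams(),
                           pitch = NULL) {
  validObject(params)
  if (is(shape, "HelixShape")) {
    r <- shape@radius; p <- shape@pitch
  } else {
    r <- shape; p <- pitch
    if (is.null(p)) stop("pitch required when shape is numeric")
    if (any(r <= 0)) stop("radius must be > 0")
    if (any(p < 0)) stop("pitch must be >= 0")
  }
  h <- p / (2 * pi)
  d <- h^2 + r^2
  e <- energyPerLength(r / d, params, tau = h / d)
  (e + params@g0) * params@dimerLength
}

#' Per-dimer elastic energy landscape over (radius, pitch)
#'
#' Evaluates \code{\link{energyPerDimer}} on a regular grid. Radius varies
#' along rows, pitch along columns. Defaults cover r in [5, 25] nm,
#' p in [5, 80] nm on a 400 x 400 grid, which contains the physiological
#' range of dynamin helices and the global minimum.
#'
#' @param rMin,rMax radius range, nm
#' @param pMin,pMax pitch range, nm
#' @param nR,nP grid sizes (>= 2)
#' @param params a \linkS4class{FilamentElasticParams}
#' @return an \linkS4class{EnergyLandscape}
#' @export
energyLandscape <- function(rMin = 5, rMax = 25, pMin = 5, pMax = 80,
                            nR = 400, nP = 400,
                            params = FilamentElasticParams()) {
  if (rMin <= 0 || rMax <= rMin) stop("need 0 < rMin < rMax")
  if (pMin < 0 || pMax <= pMin) stop("need 0 <= pMin < pMax")
  if (nR < 2 || nP < 2) stop("grid sizes must be >= 2")
  r <- seq(rMin, rMax, length.out = nR)
  p <- seq(pMin, pMax, length.out = nP)
  e <- outer(r, p, function(ri, pi.) energyPerDimer(ri, params, pitch = pi.))
  new("EnergyLandscape", radius = r, pitch = p, energy = e, params = params)
}

#' Minimal per-dimer energy over radius at fixed pitch
#'
#' Bounded 1-D minimisation of \code{\link{energyPerDimer}} in the radius
#' at a fixed pitch; traces the black minimal-energy curve of the
#' landscape. If the minimum sits on a boundary of \code{rBounds} a
#' warning is issued and the boundary value returned.
#'
#' @param pitch pitch in nm
#' @param params a \linkS4class{FilamentElasticParams}
#' @param rBounds radius search interval, nm
#' @param tol convergence tolerance on the radius argument, nm
#' @return list with \code{radius} (argmin, nm) and \code{energy}
#'   (kJ/mol per dimer)
#' @export
minEnergyOverRadius <- function(pitch, params = FilamentElasticParams(),
                                rBounds = c(1, 50), tol = 1e-9) {
  if (length(rBounds) != 2 || rBounds[1] <= 0 || rBounds[2] <= rBounds[1])
    stop("rBounds must be a positive increasing interval")
  f <- function(r) energyPerDimer(r, params, pitch = pitch)
  opt <- optimize(f, interval = rBounds, tol = tol)
  r <- opt$minimum
  edge <- min(r - rBounds[1], rBounds[2] - r)
  if (edge < 1e-6 * diff(rBounds)) {
    warning("no interior minimum in rBounds; returning boundary value")
    bvals <- f(rBounds)
    i <- which.min(bvals)
    return(list(radius = rBounds[i], energy = bvals[i]))
  }
  list(radius = r, energy = opt$objective)
}

#' Global minimum of the per-dimer energy over (radius, pitch)
#'
#' The quadratic energy vanishes exactly at the spontaneous
#' curvature/twist, so the minimising shape follows in closed form:
#' \eqn{r^* = \kappa_0/(\kappa_0^2+\tau_0^2)},
#' \eqn{p^* = 2\pi\tau_0/(\kappa_0^2+\tau_0^2)}, with per-dimer energy
#' \eqn{g_0 \times} dimerLength. With the default parameters
#' r* = 11.50 nm and p* = 51.1 nm: the elastic energy is minimised at
#' large pitches (~50 nm).
#'
#' @param params a \linkS4class{FilamentElasticParams}
#' @return list with \code{radius} (nm), \code{pitch} (nm) and
#'   \code{energy} (kJ/mol per dimer)
#' @export
globalMinimum <- function(params = FilamentElasticParams()) {
  validObject(params)
  d <- params@kappa0^2 + params@tau0^2
  if (d == 0) stop("kappa0 and tau0 cannot both be zero")
  list(radius = params@kappa0 / d,
       pitch = 2 * pi * params@tau0 / d,
       energy = params@g0 * params@dimerLength)
}

#' One-start versus multi-start energies at fixed radius
#'
#' In a k-start helix with rung spacing d each strand advances
#' k x d per turn, so at fixed radius the strand pitch is k x d. A
#' two-start configuration therefore doubles the pitch of each strand
#' without changing the inter-rung spacing that supports the GG contacts.
#' Returns the per-dimer energy for each start number and the one- minus
#' two-start difference.
#'
#' @param radius filament radius, nm
#' @param rungSpacing axial spacing between adjacent rungs, nm (default
#'   10, the pitch of a one-start dynamin helix)
#' @param kStarts integer vector of start numbers to compare
#' @param params a \linkS4class{FilamentElasticParams}
#' @return list with \code{energies} (data.frame: k, pitch_nm,
#'   energy_kjmol) and \code{deltaOneTwo} (E(1-start) - E(2-start),
#'   kJ/mol per dimer; NA unless both 1 and 2 are in \code{kStarts})
#' @examples
#' multistartComparison(13.5)$deltaOneTwo  # ~8.1 kJ/mol
#' @export
multistartComparison <- function(radius, rungSpacing = 10,
                                 kStarts = c(1L, 2L),
                                 params = FilamentElasticParams()) {
  if (rungSpacing <= 0) stop("rungSpacing must be > 0")
  kStarts <- as.integer(kStarts)
  if (any(kStarts < 1L)) stop("start numbers must be >= 1")
  p <- kStarts * rungSpacing
  e <- energyPerDimer(radius, params, pitch = p)
  delta <- if (all(c(1L, 2L) %in% kStarts))
    e[match(1L, kStarts)] - e[match(2L, kStarts)] else NA_real_
  list(energies = data.frame(k = kStarts, pitch_nm = p, energy_kjmol = e),
       deltaOneTwo = delta)
}

#' Inner lumen diameter of the membrane tube under a filament
#'
#' Maps the filament radius (helical axis to Stalk interface 2) to the
#' inner diameter of the lipid lumen by subtracting a fixed radial offset
#' accounting for the PH domain and the bilayer:
#' diameter = 2 x (radius - offset). The default offset of 11.5 nm
#' calibrates the super-constricted two-start structure radius (13.5 nm)
#' to its ~4 nm lumen.
#'
#' @param filamentRadius filament radius, nm
#' @param offset radial offset, nm (>= 0)
#' @return list with \code{diameter} (nm) and \code{offset} (nm, echoed)
#' @export
lumenDiameter <- function(filamentRadius, offset = 11.5) {
  if (offset < 0) stop("offset must be >= 0")
  if (any(filamentRadius <= offset))
    stop("filamentRadius must exceed the offset: lumen would be closed")
  list(diameter = 2 * (filamentRadius - offset), offset = offset)
}
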