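## Axisymmetric Helfrich membrane tube. Bending energy density
## (chi/2)(2H)^2 with 2H = 1/r for a cylinder, plus tension gamma times
## area. Membrane energies are in kBT; the kBT <-> kJ/mol bridge (300 K)
## is applied only when combining with filament energies.

#' MembraneParams: Helfrich membrane constants
#'
#' @slot chi bending stiffness, kBT (default 24)
#' @slot gamma tension, kBT/nm^2 (default 0.03)
#' @slot kBT_kJmol conversion, kJ/mol per kBT (default 2.494, i.e. 300 K)
#' @exportClass MembraneParams
setClass("MembraneParams",
  representation(chi = "numeric", gamma = "numeric", kBT_kJmol = "numeric"),
  prototype(chi = 24, gamma = 0.03, kBT_kJmol = 2.494))

setValidity("MembraneParams", function(object) {
  msg <- character()
  if (length(object@chi) != 1 || !is.finite(object@chi) || object@chi <= 0)
    msg <- c(msg, "chi must be a single positive number (kBT)")
  if (length(object@gamma) != 1 || !is.finite(object@gamma) ||
      object@gamma <= 0)
    msg <- c(msg, "gamma must be a single positive number (kBT/nm^2)")
  if (length(object@kBT_kJmol) != 1 || object@kBT_kJmol <= 0)
    msg <- c(msg, "kBT_kJmol must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct MembraneParams
#' @param chi bending stiffness in kBT
#' @param gamma tension in kBT/nm^2
#' @param kBT_kJmol kJ/mol per kBT (2.494 at 300 K)
#' @return a \linkS4class{MembraneParams}
#' @export
MembraneParams <- function(chi = 24, gamma = 0.03, kBT_kJmol = 2.494) {
  new("MembraneParams", chi = chi, gamma = gamma, kBT_kJmol = kBT_kJmol)
}

setMethod("show", "MembraneParams", function(object) {
  cat(sprintf(paste0(
    "MembraneParams: chi %.3g kBT, gamma %.3g kBT/nm^2 ",
    "(equilibrium radius %.3g nm)\n"),
    object@chi, object@gamma, equilibriumRadius(object)))
})

#' MembraneTube: axisymmetric radius profile on a periodic grid
#'
#' @slot z uniform axial grid, nm; the profile is periodic with period
#'   \code{length(z) * dz} where dz is the grid spacing (z gives the left
#'   edge of each cell)
#' @slot r radius profile r(z), nm (> 0 everywhere)
#' @exportClass MembraneTube
setClass("MembraneTube",
  representation(z = "numeric", r = "numeric"))

setValidity("MembraneTube", function(object) {
  if (length(object@z) < 4) return("need at least 4 axial grid points")
  if (length(object@z) != length(object@r))
    return("z and r must have equal length")
  dz <- diff(object@z)
  if (any(dz <= 0) || diff(range(dz)) > 1e-9 * mean(dz))
    return("z must be a uniform increasing grid")
  if (any(!is.finite(object@r)) || any(object@r <= 0))
    return("r(z) must be positive everywhere")
  TRUE
})

#' Construct a MembraneTube
#'
#' @param length axial period of the tube, nm
#' @param n number of axial grid points
#' @param radius scalar or length-n vector of radii, nm
#' @return a \linkS4class{MembraneTube} on a uniform periodic grid
#' @export
MembraneTube <- function(length = 100, n = 64, radius = 20) {
  z <- seq(0, length, length.out = n + 1)[seq_len(n)]
  new("MembraneTube", z = z, r = rep_len(as.numeric(radius), n))
}

setMethod("show", "MembraneTube", function(object) {
  dz <- object@z[2] - object@z[1]
  cat(sprintf(
    "MembraneTube: period %.3g nm, %d grid points, mean radius %.4g nm\n",
    dz * length(object@z), length(object@z), mean(object@r)))
})

#' Mean radius of a tube profile
#' @param tube a \linkS4class{MembraneTube}
#' @return mean of r(z), nm
#' @export
meanTubeRadius <- function(tube) mean(tube@r)

## ---- operations ----

#' Helfrich energy per unit length of a cylindrical tube
#'
#' For a cylinder of radius r the mean-curvature term gives
#' \eqn{\pi\chi/r} and the tension term \eqn{2\pi\gamma r}, per unit
#' length, in kBT/nm. Strictly convex in r with a unique minimum at
#' \code{\link{equilibriumRadius}}.
#'
#' @param radius tube radius, nm (vectorised)
#' @param params a \linkS4class{MembraneParams}
#' @return energy per unit length, kBT/nm
#' @examples
#' tubeEnergyPerLength(20)  # 7.54 kBT/nm at the defaults
#' @export
tubeEnergyPerLength <- function(radius, params = MembraneParams()) {
  validObject(params)
  if (any(radius <= 0)) stop("radius must be > 0")
  pi * params@chi / radius + 2 * pi * params@gamma * radius
}

#' Equilibrium radius of a free membrane tube
#'
#' Minimiser of \code{\link{tubeEnergyPerLength}}:
#' \eqn{r_{eq} = \sqrt{\chi/(2\gamma)}}. With chi = 24 kBT and
#' gamma = 0.03 kBT/nm^2 this is 20 nm (equilibrium diameter 40 nm).
#'
#' @param params a \linkS4class{MembraneParams}
#' @return equilibrium radius in nm
#' @export
equilibriumRadius <- function(params = MembraneParams()) {
  validObject(params)
  sqrt(params@chi / (2 * params@gamma))
}

## Central differences on a periodic uniform grid.
periodicDiff <- function(r, dz) {
  n <- length(r)
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  list(d1 = (r[ip] - r[im]) / (2 * dz),
       d2 = (r[ip] - 2 * r + r[im]) / dz^2)
}

#' Helfrich energy of an axisymmetric tube profile
#'
#' Discretises
#' \deqn{E = \int 2\pi r \sqrt{1+r'^2}\left[\frac{\chi}{2}(2H)^2 +
#' \gamma\right] dz,\quad
#' 2H = \frac{1}{r\sqrt{1+r'^2}} - \frac{r''}{(1+r'^2)^{3/2}}}
#' over one axial period, with r' and r'' by central differences on the
#' periodic uniform grid. For a constant profile this reduces to
#' \code{\link{tubeEnergyPerLength}} times the period.
#'
#' @param tube a \linkS4class{MembraneTube}
#' @param params a \linkS4class{MembraneParams}
#' @return total energy over one period, kBT
#' @export
profileEnergy <- function(tube, params = MembraneParams()) {
  stopifnot(is(tube, "MembraneTube"))
  validObject(params)
  r <- tube@r
  if (any(r <= 0)) stop("r(z) must be positive everywhere")
  dz <- tube@z[2] - tube@z[1]
  d <- periodicDiff(r, dz)
  s2 <- 1 + d$d1^2
  twoH <- 1 / (r * sqrt(s2)) - d$d2 / s2^1.5
  dens <- 2 * pi * r * sqrt(s2) * (0.5 * params@chi * twoH^2 + params@gamma)
  sum(dens) * dz
}
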