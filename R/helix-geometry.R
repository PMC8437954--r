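## Helical geometry: discrete cryoEM symmetry <-> continuous helix shape
## <-> curvature/twist. Internal unit nm; rise is given in Angstrom as in
## cryoEM convention and converted on input.

#' HelicalSymmetry: discrete helical symmetry of a filament
#'
#' The cryoEM description of a helical assembly: axial rise and azimuthal
#' twist per subunit, the number of intertwined strands (start number) and
#' the cyclic point-group order relating the strands (e.g. 2 for C2).
#'
#' @slot rise per-subunit axial rise in Angstrom (> 0)
#' @slot twist per-subunit azimuthal twist in degrees (0 < twist <= 360)
#' @slot nStart number of strands (>= 1)
#' @slot cyclicOrder cyclic point-group order (>= 1; 2 means C2)
#' @slot handedness "right" or "left"
#' @exportClass HelicalSymmetry
setClass("HelicalSymmetry",
  representation(rise = "numeric", twist = "numeric", nStart = "integer",
                 cyclicOrder = "integer", handedness = "character"),
  prototype(rise = 13.58, twist = 24.43, nStart = 2L, cyclicOrder = 2L,
            handedness = "right"))

setValidity("HelicalSymmetry", function(object) {
  msg <- character()
  if (length(object@rise) != 1 || !is.finite(object@rise) || object@rise <= 0)
    msg <- c(msg, "rise must be a single positive number (Angstrom)")
  if (length(object@twist) != 1 || !is.finite(object@twist) ||
      object@twist <= 0 || object@twist > 360)
    msg <- c(msg, "twist must satisfy 0 < twist <= 360 (degrees)")
  if (object@nStart < 1L) msg <- c(msg, "nStart must be >= 1")
  if (object@cyclicOrder < 1L) msg <- c(msg, "cyclicOrder must be >= 1")
  if (!object@handedness %in% c("right", "left"))
    msg <- c(msg, "handedness must be 'right' or 'left'")
  if (length(msg)) msg else TRUE
})

#' Construct a HelicalSymmetry
#'
#' @param rise per-subunit rise in Angstrom
#' @param twist per-subunit twist in degrees (0 < twist <= 360)
#' @param nStart start number (number of strands)
#' @param cyclicOrder cyclic point-group order relating strands (2 = C2)
#' @param handedness "right" (default) or "left"
#' @return a \linkS4class{HelicalSymmetry} object
#' @examples
#' HelicalSymmetry(13.58, 24.43, nStart = 2, cyclicOrder = 2)
#' @export
HelicalSymmetry <- function(rise, twist, nStart = 1L, cyclicOrder = 1L,
                            handedness = c("right", "left")) {
  new("HelicalSymmetry", rise = as.numeric(rise), twist = as.numeric(twist),
      nStart = as.integer(nStart), cyclicOrder = as.integer(cyclicOrder),
      handedness = match.arg(handedness))
}

#' HelixShape: continuous shape of one filament strand
#'
#' A strand is an ideal circular helix of given radius (distance from the
#' helical axis to the filament centerline, defined at Stalk interface 2)
#' and pitch (axial advance per full turn). The reduced pitch
#' \eqn{h = p/2\pi} is derived.
#'
#' @slot radius helix radius in nm (> 0)
#' @slot pitch axial advance of one strand per turn, nm (>= 0; 0 is a ring)
#' @exportClass HelixShape
setClass("HelixShape",
  representation(radius = "numeric", pitch = "numeric"),
  prototype(radius = 13.5, pitch = 20))

setValidity("HelixShape", function(object) {
  msg <- character()
  if (length(object@radius) != 1 || !is.finite(object@radius) ||
      object@radius <= 0)
    msg <- c(msg, "radius must be a single positive number (nm)")
  if (length(object@pitch) != 1 || !is.finite(object@pitch) ||
      object@pitch < 0)
    msg <- c(msg, "pitch must be a single non-negative number (nm)")
  if (length(msg)) msg else TRUE
})

#' Construct a HelixShape
#' @param radius helix radius in nm
#' @param pitch pitch in nm (0 gives a planar ring)
#' @return a \linkS4class{HelixShape}
#' @export
HelixShape <- function(radius, pitch) {
  new("HelixShape", radius = as.numeric(radius), pitch = as.numeric(pitch))
}

#' CurvatureTwist: differential-geometric descriptors of a strand
#'
#' Curvature \eqn{\kappa} and twist density \eqn{\tau} of the filament
#' centerline helix, both in 1/nm.
#'
#' @slot kappa curvature, 1/nm (>= 0)
#' @slot tau twist density, 1/nm
#' @exportClass CurvatureTwist
setClass("CurvatureTwist",
  representation(kappa = "numeric", tau = "numeric"),
  prototype(kappa = 0.058, tau = 0.041))

setValidity("CurvatureTwist", function(object) {
  if (length(object@kappa) != 1 || !is.finite(object@kappa) ||
      object@kappa < 0)
    return("kappa must be a single non-negative number (1/nm)")
  if (length(object@tau) != 1 || !is.finite(object@tau))
    return("tau must be a single finite number (1/nm)")
  TRUE
})

#' Construct a CurvatureTwist
#' @param kappa curvature in 1/nm
#' @param tau twist density in 1/nm
#' @return a \linkS4class{CurvatureTwist}
#' @export
CurvatureTwist <- function(kappa, tau) {
  new("CurvatureTwist", kappa = as.numeric(kappa), tau = as.numeric(tau))
}

## ---- accessors ----

#' @describeIn HelicalSymmetry-accessors per-subunit rise (Angstrom)
#' @export
setGeneric("rise", function(x) standardGeneric("rise"))
#' @describeIn HelicalSymmetry-accessors per-subunit twist (degrees)
#' @export
setGeneric("twist", function(x) standardGeneric("twist"))
#' @describeIn HelicalSymmetry-accessors start number
#' @export
setGeneric("nStart", function(x) standardGeneric("nStart"))
#' @describeIn HelicalSymmetry-accessors helix radius (nm)
#' @export
setGeneric("helixRadius", function(x) standardGeneric("helixRadius"))
#' @describeIn HelicalSymmetry-accessors pitch (nm)
#' @export
setGeneric("helixPitch", function(x) standardGeneric("helixPitch"))
#' @describeIn HelicalSymmetry-accessors curvature (1/nm)
#' @export
setGeneric("kappa", function(x) standardGeneric("kappa"))
#' @describeIn HelicalSymmetry-accessors twist density (1/nm)
#' @export
setGeneric("tau", function(x) standardGeneric("tau"))

#' Accessors for helical geometry classes
#'
#' @param x a \linkS4class{HelicalSymmetry}, \linkS4class{HelixShape} or
#'   \linkS4class{CurvatureTwist}
#' @name HelicalSymmetry-accessors
NULL

#' @rdname HelicalSymmetry-accessors
#' @export
setMethod("rise", "HelicalSymmetry", function(x) x@rise)
#' @rdname HelicalSymmetry-accessors
#' @export
setMethod("twist", "HelicalSymmetry", function(x) x@twist)
#' @rdname HelicalSymmetry-accessors
#' @export
setMethod("nStart", "HelicalSymmetry", function(x) x@nStart)
#' @rdname HelicalSymmetry-accessors
#' @export
setMethod("helixRadius", "HelixShape", function(x) x@radius)
#' @rdname HelicalSymmetry-accessors
#' @export
setMethod("helixPitch", "HelixShape", function(x) x@pitch)
#' @rdname HelicalSymmetry-accessors
#' @export
setMethod("kappa", "CurvatureTwist", function(x) x@kappa)
#' @rdname HelicalSymmetry-accessors
#' @export
setMethod("tau", "CurvatureTwist", function(x) x@tau)

#' Reduced pitch h = p / (2 pi)
#' @param x a \linkS4class{HelixShape}
#' @return reduced pitch in nm
#' @export
reducedPitch <- function(x) {
  stopifnot(is(x, "HelixShape"))
  x@pitch / (2 * pi)
}

setMethod("show", "HelicalSymmetry", function(object) {
  cat(sprintf(
    "HelicalSymmetry: rise %.2f A, twist %.2f deg, %d-start, C%d, %s-handed\n",
    object@rise, object@twist, object@nStart, object@cyclicOrder,
    object@handedness))
  cat(sprintf("  %.2f subunits per turn, strand pitch %.2f nm\n",
              subunitsPerTurn(object@twist), strandPitch(object)))
})

setMethod("show", "HelixShape", function(object) {
  cat(sprintf("HelixShape: radius %.3f nm, pitch %.3f nm (h = %.4f nm)\n",
              object@radius, object@pitch, reducedPitch(object)))
})

setMethod("show", "CurvatureTwist", function(object) {
  cat(sprintf("CurvatureTwist: kappa %.5f 1/nm, tau %.5f 1/nm\n",
              object@kappa, object@tau))
})

## ---- operations ----

#' Number of subunits per helical turn
#'
#' For a per-subunit azimuthal twist of \code{twist} degrees a full turn
#' contains 360/\code{twist} subunits. The two-start dynamin helix
#' (twist 24.43 deg) has ~14.7 subunits per turn; the one-start helix
#' (twist 23.68 deg) has ~15.2.
#'
#' @param twist per-subunit twist in degrees (0 < twist <= 360)
#' @return subunits per turn (real, full precision; round at presentation)
#' @examples
#' subunitsPerTurn(24.43)  # ~14.7
#' @export
subunitsPerTurn <- function(twist) {
  if (!is.numeric(twist) || any(!is.finite(twist)) ||
      any(twist <= 0) || any(twist > 360))
    stop("twist must satisfy 0 < twist <= 360 degrees")
  360 / twist
}

#' Pitch of one strand from discrete helical symmetry
#'
#' The axial advance of one strand per full turn:
#' rise x (360/twist), converted from Angstrom to nm.
#'
#' @param sym a \linkS4class{HelicalSymmetry}
#' @return strand pitch in nm
#' @export
strandPitch <- function(sym) {
  stopifnot(is(sym, "HelicalSymmetry"))
  validObject(sym)
  (sym@rise / 10) * subunitsPerTurn(sym@twist)
}

#' Axial spacing between adjacent rungs
#'
#' The axial distance between successive filament turns counting all
#' strands: strand pitch divided by the start number. For the two-start
#' dynamin helix this is half the strand pitch.
#'
#' @param sym a \linkS4class{HelicalSymmetry}
#' @return rung spacing in nm
#' @export
rungSpacing <- function(sym) {
  strandPitch(sym) / nStart(sym)
}

#' Convert helix shape to curvature and twist density
#'
#' For a circular helix of radius \eqn{r} and reduced pitch
#' \eqn{h = p/2\pi}: \eqn{\kappa = r/(h^2+r^2)} and
#' \eqn{\tau = h/(h^2+r^2)}.
#'
#' @param shape a \linkS4class{HelixShape}
#' @return a \linkS4class{CurvatureTwist}
#' @examples
#' shapeToCurvature(HelixShape(radius = 13.5, pitch = 10))
#' @export
shapeToCurvature <- function(shape) {
  stopifnot(is(shape, "HelixShape"))
  validObject(shape)
  r <- shape@radius
  h <- reducedPitch(shape)
  d <- h^2 + r^2
  CurvatureTwist(kappa = r / d, tau = h / d)
}

#' Convert curvature and twist density to helix shape
#'
#' Analytic inverse of \code{\link{shapeToCurvature}}:
#' \eqn{r = \kappa/(\kappa^2+\tau^2)}, \eqn{h = \tau/(\kappa^2+\tau^2)},
#' \eqn{p = 2\pi h}. The straight-line degenerate case \eqn{\kappa = 0}
#' (infinite radius) is rejected.
#'
#' @param ct a \linkS4class{CurvatureTwist} with kappa > 0
#' @return a \linkS4class{HelixShape}
#' @export
curvatureToShape <- function(ct) {
  stopifnot(is(ct, "CurvatureTwist"))
  validObject(ct)
  if (ct@kappa <= 0)
    stop("kappa must be > 0: a straight filament has no finite radius")
  d <- ct@kappa^2 + ct@tau^2
  HelixShape(radius = ct@kappa / d, pitch = 2 * pi * ct@tau / d)
}

#' Generate the points of an n-start helical lattice
#'
#' Places one point per subunit on each strand. Subunit k of strand s sits
#' at z = k x rise and azimuth = sgn x k x twist + s x (360/cyclicOrder),
#' where sgn is +1 for a right-handed and -1 for a left-handed helix.
#' For a C2 two-start lattice the strand partner of a subunit at
#' (radius, phi, z) is at (radius, phi + 180, z).
#'
#' @param sym a \linkS4class{HelicalSymmetry}
#' @param radius lattice radius in nm
#' @param nSubunits subunits per strand (>= 1)
#' @return a data.frame with columns \code{subunit}, \code{strand},
#'   \code{radius_nm}, \code{azimuth_deg} (in [0, 360)), \code{z_nm},
#'   \code{x_nm}, \code{y_nm}
#' @examples
#' latticePoints(HelicalSymmetry(13.58, 24.43, 2, 2), radius = 13.5,
#'               nSubunits = 5)
#' @export
latticePoints <- function(sym, radius, nSubunits) {
  stopifnot(is(sym, "HelicalSymmetry"))
  validObject(sym)
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  nSubunits <- as.integer(nSubunits)
  if (nSubunits < 1L) stop("nSubunits must be >= 1")
  sgn <- if (sym@handedness == "right") 1 else -1
  k <- rep(seq_len(nSubunits) - 1L, times = sym@nStart)
  s <- rep(seq_len(sym@nStart) - 1L, each = nSubunits)
  az <- (sgn * k * sym@twist + s * (360 / sym@cyclicOrder)) %% 360
  z <- k * sym@rise / 10
  data.frame(subunit = k, strand = s, radius_nm = radius,
             azimuth_deg = az, z_nm = z,
             x_nm = radius * cos(az * pi / 180),
             y_nm = radius * sin(az * pi / 180))
}
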