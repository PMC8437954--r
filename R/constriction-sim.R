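#' @include helix-geometry.R elastic-model.R membrane-model.R
NULL

## Coarse-grained constriction simulator: n-start bead filaments (one
## bead per dynamin dimer) carrying the stalk elastic energy, optionally
## coupled to a deformable axisymmetric membrane tube. Passive relaxation
## only: the system descends its total energy; the GTP-driven motor that
## actively slides filament turns is out of scope (an optional constant
## axial force hook is provided, disabled by default).

#' BeadFilament: a discrete bead chain representing one strand
#'
#' @slot xyz n x 3 matrix of bead positions, nm; beads are dimer centres
#' @slot strand integer strand id (0-based)
#' @slot spacing target bead spacing, nm (the dimer length, default 5.6)
#' @exportClass BeadFilament
setClass("BeadFilament",
  representation(xyz = "matrix", strand = "integer", spacing = "numeric"))

setValidity("BeadFilament", function(object) {
  if (ncol(object@xyz) != 3) return("xyz must be an n x 3 matrix")
  if (nrow(object@xyz) < 4)
    return("need at least 4 beads (discrete torsion requires 4)")
  if (any(!is.finite(object@xyz))) return("bead positions must be finite")
  if (object@spacing <= 0) return("spacing must be > 0")
  L <- sqrt(rowSums(diff(object@xyz)^2))
  if (any(abs(L - object@spacing) > 0.2 * object@spacing))
    return("consecutive-bead distance deviates more than 20% from spacing")
  TRUE
})

#' Construct a BeadFilament
#' @param xyz n x 3 matrix of bead positions (nm)
#' @param strand integer strand id
#' @param spacing target bead spacing (nm)
#' @return a \linkS4class{BeadFilament}
#' @export
BeadFilament <- function(xyz, strand = 0L, spacing = 5.6) {
  new("BeadFilament", xyz = as.matrix(xyz), strand = as.integer(strand),
      spacing = spacing)
}

setMethod("show", "BeadFilament", function(object) {
  cat(sprintf("BeadFilament: strand %d, %d beads, spacing %.2f nm\n",
              object@strand, nrow(object@xyz), object@spacing))
})

#' Build bead helices for an n-start filament
#'
#' Beads are placed on each of \code{nStart} ideal helices of the given
#' shape, phase-offset by 360/nStart, with the angular step chosen so
#' that the consecutive-bead (chord) distance equals \code{spacing}
#' exactly. A pitch of zero gives a planar ring arc.
#'
#' @param shape a \linkS4class{HelixShape}
#' @param nStart number of strands
#' @param nBeads beads per strand (>= 4)
#' @param spacing bead spacing in nm (default 5.6, one dynamin dimer)
#' @return list of \linkS4class{BeadFilament}, one per strand
#' @examples
#' fil <- buildBeadHelix(HelixShape(20, 20), nStart = 2, nBeads = 12)
#' @export
buildBeadHelix <- function(shape, nStart = 1L, nBeads = 20L,
                           spacing = 5.6) {
  stopifnot(is(shape, "HelixShape"))
  if (spacing <= 0) stop("spacing must be > 0")
  nBeads <- as.integer(nBeads)
  if (nBeads < 4L) stop("nBeads must be >= 4")
  r <- shape@radius
  h <- reducedPitch(shape)
  chord <- function(dth) sqrt(2 * r^2 * (1 - cos(dth)) + h^2 * dth^2)
  if (chord(pi) < spacing)
    stop("spacing too large for this helix radius/pitch")
  dth <- stats::uniroot(function(x) chord(x) - spacing,
                        lower = 1e-12, upper = pi, tol = 1e-14)$root
  lapply(seq_len(nStart) - 1L, function(s) {
    phase <- s * 2 * pi / nStart
    th <- (seq_len(nBeads) - 1L) * dth
    xyz <- cbind(r * cos(th + phase), r * sin(th + phase), h * th)
    BeadFilament(xyz, strand = s, spacing = spacing)
  })
}

## Vectorised discrete differential geometry of a bead chain.
## Returns kappa at interior beads (2..n-1), signed twist density tau at
## each dihedral (1..n-3), bond lengths, and the arc weights used by the
## energy.
chainGeometry <- function(X) {
  n <- nrow(X)
  B <- X[-1, , drop = FALSE] - X[-n, , drop = FALSE]     # bonds, (n-1) x 3
  L <- sqrt(rowSums(B^2))
  crossRows <- function(U, V)
    cbind(U[, 2] * V[, 3] - U[, 3] * V[, 2],
          U[, 3] * V[, 1] - U[, 1] * V[, 3],
          U[, 1] * V[, 2] - U[, 2] * V[, 1])
  nb <- nrow(B)
  ## curvature: Menger curvature of (i-1, i, i+1) using bonds i-1, i
  U <- B[-nb, , drop = FALSE]; V <- B[-1, , drop = FALSE]
  CR <- crossRows(U, V)
  a2 <- sqrt(rowSums((U + V)^2))              # |x_{i+1} - x_{i-1}|
  kap <- 2 * sqrt(rowSums(CR^2)) / (L[-nb] * L[-1] * a2)
  kap[!is.finite(kap)] <- 0                   # collinear triples
  ## torsion: signed dihedral across bonds (j, j+1, j+2)
  tauD <- NULL; wTau <- NULL
  if (nb >= 3) {
    N1 <- CR[-nrow(CR), , drop = FALSE]       # cross(B_j, B_{j+1})
    N2 <- CR[-1, , drop = FALSE]              # cross(B_{j+1}, B_{j+2})
    Bm <- B[2:(nb - 1), , drop = FALSE]       # central bonds
    Lm <- L[2:(nb - 1)]
    x <- rowSums(N1 * N2)
    y <- rowSums(crossRows(N1, N2) * (Bm / Lm))
    phi <- atan2(y, x)
    wTau <- (L[1:(nb - 2)] + L[2:(nb - 1)] + L[3:nb]) / 3
    tauD <- phi / wTau
  }
  list(kappa = kap, tau = tauD, bonds = L,
       wKappa = (L[-nb] + L[-1]) / 2, wTau = wTau)
}

#' Discrete curvature and twist density along a bead chain
#'
#' Curvature at bead i is the Menger curvature of beads (i-1, i, i+1);
#' twist density at bond i is the signed dihedral angle between planes
#' (i-1, i, i+1) and (i, i+1, i+2) divided by the mean of the three bond
#' lengths. For beads sampled from an ideal helix these converge to the
#' continuous values \eqn{\kappa = r/(h^2+r^2)}, \eqn{\tau = h/(h^2+r^2)}
#' as the spacing shrinks. Collinear triples give curvature 0 and an
#' undefined (NA) twist.
#'
#' @param filament a \linkS4class{BeadFilament} or an n x 3 coordinate
#'   matrix
#' @return list with \code{kappa} (length n-2, 1/nm), \code{tau}
#'   (length n-3, 1/nm, signed; positive = right-handed) and
#'   \code{bonds} (length n-1, nm)
#' @export
discreteCurvatureTwist <- function(filament) {
  X <- if (is(filament, "BeadFilament")) filament@xyz else as.matrix(filament)
  if (nrow(X) < 4) stop("need at least 4 beads")
  g <- chainGeometry(X)
  tau <- g$tau
  if (!is.null(tau)) tau[g$kappa[seq_along(tau)] == 0 &
                         g$kappa[seq_along(tau) + 1] == 0] <- NA_real_
  list(kappa = g$kappa, tau = tau, bonds = g$bonds)
}

#' Mean helix shape of a bead filament
#'
#' Averages the discrete curvature and twist density over the chain and
#' maps them through \code{\link{curvatureToShape}}. This measures the
#' shape with the same discrete operators that define the bead energy,
#' so a chain whose every discrete (kappa, tau) equals the spontaneous
#' values maps exactly to the spontaneous helix.
#'
#' @param filament a \linkS4class{BeadFilament}
#' @return a \linkS4class{HelixShape}
#' @export
filamentShape <- function(filament) {
  ct <- discreteCurvatureTwist(filament)
  curvatureToShape(CurvatureTwist(mean(ct$kappa),
                                  mean(ct$tau, na.rm = TRUE)))
}

#' SimSystem: filaments, optional membrane tube, and their parameters
#'
#' Either component may be absent: a system with no tube relaxes a free
#' filament; a system with no filaments relaxes a bare membrane tube.
#' The filament-membrane coupling is a soft radial harmonic: each bead at
#' axial position z (wrapped into the tube period) and axial distance
#' rho from the axis contributes (couplingK/2)(rho - r(z))^2.
#'
#' @slot filaments list of \linkS4class{BeadFilament} (may be empty)
#' @slot tube a \linkS4class{MembraneTube}, or NULL
#' @slot fparams \linkS4class{FilamentElasticParams}
#' @slot mparams \linkS4class{MembraneParams}
#' @slot couplingK radial coupling stiffness, kJ/mol/nm^2 (default 100)
#' @slot kBond bond-length stiffness, kJ/mol/nm^2 (default 1000)
#' @slot slideForce optional constant inter-strand axial force, kJ/mol/nm
#'   (default 0 = disabled; hook for active-drive extensions)
#' @slot seed integer seed recorded in outputs (relaxation itself is
#'   deterministic)
#' @exportClass SimSystem
setClass("SimSystem",
  representation(filaments = "list", tube = "ANY",
                 fparams = "FilamentElasticParams",
                 mparams = "MembraneParams",
                 couplingK = "numeric", kBond = "numeric",
                 slideForce = "numeric", seed = "integer"))

setValidity("SimSystem", function(object) {
  if (!is.null(object@tube) && !is(object@tube, "MembraneTube"))
    return("tube must be a MembraneTube or NULL")
  if (!all(vapply(object@filaments, is, TRUE, "BeadFilament")))
    return("filaments must be a list of BeadFilament")
  if (!length(object@filaments) && is.null(object@tube))
    return("system must contain at least one filament or a tube")
  if (object@couplingK < 0 || object@kBond <= 0)
    return("couplingK must be >= 0 and kBond > 0")
  TRUE
})

#' Construct a SimSystem
#' @param filaments list of \linkS4class{BeadFilament} (or a single one)
#' @param tube a \linkS4class{MembraneTube} or NULL
#' @param fparams \linkS4class{FilamentElasticParams}
#' @param mparams \linkS4class{MembraneParams}
#' @param couplingK radial coupling stiffness, kJ/mol/nm^2
#' @param kBond bond stiffness, kJ/mol/nm^2
#' @param slideForce constant inter-strand axial force, kJ/mol/nm
#'   (0 disables the hook)
#' @param seed integer seed recorded in outputs
#' @return a \linkS4class{SimSystem}
#' @export
SimSystem <- function(filaments = list(), tube = NULL,
                      fparams = FilamentElasticParams(),
                      mparams = MembraneParams(),
                      couplingK = 100, kBond = 1000, slideForce = 0,
                      seed = 0L) {
  if (is(filaments, "BeadFilament")) filaments <- list(filaments)
  new("SimSystem", filaments = filaments, tube = tube, fparams = fparams,
      mparams = mparams, couplingK = couplingK, kBond = kBond,
      slideForce = slideForce, seed = as.integer(seed))
}

setMethod("show", "SimSystem", function(object) {
  cat(sprintf("SimSystem: %d filament strand(s)%s, coupling %.3g, seed %d\n",
              length(object@filaments),
              if (is.null(object@tube)) ", no tube" else
                sprintf(", tube mean r %.3g nm",
                        meanTubeRadius(object@tube)),
              object@couplingK, object@seed))
})

## ---- energy ----

## Periodic linear interpolation of the tube radius at axial positions z.
tubeRadiusAt <- function(tube, z) {
  n <- length(tube@r)
  dz <- tube@z[2] - tube@z[1]
  P <- n * dz
  u <- ((z %% P) / dz)
  i0 <- floor(u)
  f <- u - i0
  i0 <- (as.integer(i0) %% n) + 1L
  i1 <- (i0 %% n) + 1L
  tube@r[i0] * (1 - f) + tube@r[i1] * f
}

## Energy of one strand given its coordinate matrix.
strandEnergy <- function(X, fp, kBond, spacing) {
  g <- chainGeometry(X)
  eK <- sum(fp@alphaKappa * (g$kappa - fp@kappa0)^2 * g$wKappa)
  eT <- if (is.null(g$tau)) 0 else
    sum(fp@alphaTau * (g$tau - fp@tau0)^2 * g$wTau)
  eB <- sum(0.5 * kBond * (g$bonds - spacing)^2)
  c(elastic = eK + eT, bond = eB)
}

#' Total energy of a simulation system, with per-term breakdown
#'
#' Filament term: discrete stalk elastic energy (curvature and twist
#' deviations weighted by local arc length) in kJ/mol. Bond term: stiff
#' harmonics holding the bead spacing. Membrane term:
#' \code{\link{profileEnergy}} converted from kBT to kJ/mol. Coupling
#' term: radial harmonics tying beads to the local tube radius (bead
#' axial positions are wrapped into the tube period).
#'
#' @param sys a \linkS4class{SimSystem}
#' @return list with \code{total}, \code{filament}, \code{bond},
#'   \code{membrane}, \code{coupling} (all kJ/mol)
#' @export
systemEnergy <- function(sys) {
  stopifnot(is(sys, "SimSystem"))
  eF <- 0; eB <- 0; eC <- 0; eM <- 0
  for (fil in sys@filaments) {
    se <- strandEnergy(fil@xyz, sys@fparams, sys@kBond, fil@spacing)
    eF <- eF + se["elastic"]; eB <- eB + se["bond"]
  }
  if (!is.null(sys@tube)) {
    eM <- profileEnergy(sys@tube, sys@mparams) * sys@mparams@kBT_kJmol
    if (sys@couplingK > 0 && length(sys@filaments)) {
      for (fil in sys@filaments) {
        rho <- sqrt(fil@xyz[, 1]^2 + fil@xyz[, 2]^2)
        rt <- tubeRadiusAt(sys@tube, fil@xyz[, 3])
        eC <- eC + sum(0.5 * sys@couplingK * (rho - rt)^2)
      }
    }
  }
  if (sys@slideForce != 0 && length(sys@filaments) >= 2) {
    ## optional active hook: constant force pulling strand z-centroids
    ## together (disabled by default)
    zc <- vapply(sys@filaments, function(f) mean(f@xyz[, 3]), 0)
    eF <- eF + sys@slideForce * abs(diff(range(zc)))
  }
  list(total = unname(eF + eB + eM + eC), filament = unname(eF),
       bond = unname(eB), membrane = unname(eM), coupling = unname(eC))
}

## ---- relaxation ----

## Pack/unpack the degrees of freedom: all bead coordinates then tube
## radii (if the tube is free).
packState <- function(sys, freezeTube = FALSE) {
  par <- unlist(lapply(sys@filaments, function(f) as.vector(t(f@xyz))))
  if (!is.null(sys@tube) && !freezeTube) par <- c(par, sys@tube@r)
  par
}

unpackState <- function(sys, par, freezeTube = FALSE) {
  off <- 0L
  for (i in seq_along(sys@filaments)) {
    n <- nrow(sys@filaments[[i]]@xyz)
    sys@filaments[[i]]@xyz <-
      matrix(par[off + seq_len(3 * n)], ncol = 3, byrow = TRUE)
    off <- off + 3L * n
  }
  if (!is.null(sys@tube) && !freezeTube)
    sys@tube@r <- par[off + seq_along(sys@tube@r)]
  sys
}

## Objective without S4 validity overhead (called very often).
objectiveFactory <- function(sys, freezeTube = FALSE) {
  hasTube <- !is.null(sys@tube)
  nb <- vapply(sys@filaments, function(f) nrow(f@xyz), 0L)
  off <- c(0L, cumsum(3L * nb))
  nPar <- off[length(off)] + if (hasTube && !freezeTube)
    length(sys@tube@r) else 0L
  fp <- sys@fparams; mp <- sys@mparams
  spacing <- vapply(sys@filaments, function(f) f@spacing, 0)
  tube <- sys@tube
  kc <- sys@couplingK; kb <- sys@kBond
  function(par) {
    e <- 0
    if (hasTube) {
      if (!freezeTube)
        tube@r <- par[(off[length(off)] + 1L):nPar]
      if (any(tube@r <= 0)) return(1e12)
      e <- e + profileEnergy(tube, mp) * mp@kBT_kJmol
    }
    for (i in seq_along(nb)) {
      X <- matrix(par[(off[i] + 1L):(off[i] + 3L * nb[i])],
                  ncol = 3, byrow = TRUE)
      se <- strandEnergy(X, fp, kb, spacing[i])
      e <- e + sum(se)
      if (hasTube && kc > 0) {
        rho <- sqrt(X[, 1]^2 + X[, 2]^2)
        e <- e + sum(0.5 * kc * (rho - tubeRadiusAt(tube, X[, 3]))^2)
      }
    }
    e
  }
}

## Central-difference gradient, step 1e-5 nm.
numericGradient <- function(f, par, h = 1e-5) {
  g <- numeric(length(par))
  for (i in seq_along(par)) {
    pp <- par; pp[i] <- pp[i] + h
    pm <- par; pm[i] <- pm[i] - h
    g[i] <- (f(pp) - f(pm)) / (2 * h)
  }
  g
}

#' Trajectory: recorded frames of a relaxation
#'
#' @slot step integer vector of optimisation step counts (strictly
#'   increasing)
#' @slot energy total energy at each frame, kJ/mol (non-increasing over
#'   accepted frames)
#' @slot breakdown data.frame of per-term energies per frame
#' @slot meanRadius mean tube radius per frame, nm (NA without a tube)
#' @slot frames list of \linkS4class{SimSystem} snapshots
#' @slot converged logical
#' @slot finalGradInf max |numerical gradient| at the endpoint
#' @slot seed the seed recorded from the system
#' @exportClass Trajectory
setClass("Trajectory",
  representation(step = "integer", energy = "numeric",
                 breakdown = "data.frame", meanRadius = "numeric",
                 frames = "list", converged = "logical",
                 finalGradInf = "numeric", seed = "integer"))

setValidity("Trajectory", function(object) {
  if (any(!is.finite(object@energy))) return("energies must be finite")
  if (length(object@step) > 1 && any(diff(object@step) <= 0))
    return("step must be strictly increasing")
  TRUE
})

setMethod("show", "Trajectory", function(object) {
  n <- length(object@step)
  cat(sprintf(paste0("Trajectory: %d frames, E %.6g -> %.6g kJ/mol, ",
                     "%sconverged (|grad|_inf %.3g)\n"),
              n, object@energy[1], object@energy[n],
              if (object@converged) "" else "NOT ", object@finalGradInf))
})

#' Final system state of a trajectory
#' @param traj a \linkS4class{Trajectory}
#' @return the last \linkS4class{SimSystem} frame
#' @export
finalState <- function(traj) traj@frames[[length(traj@frames)]]

#' Relax a filament-membrane system by energy descent
#'
#' Jointly relaxes bead positions and the tube radius profile by
#' quasi-Newton descent (L-BFGS-B with finite-difference gradients) on
#' the total energy, run in chunks; a frame is recorded after each chunk
#' and only accepted if its energy does not exceed the previous frame's,
#' so accepted-frame energies are non-increasing by construction.
#' Terminates when the energy decrease over a chunk falls below
#' \code{tol} or after \code{maxSteps} optimiser iterations; the endpoint
#' stationarity (max absolute numerical gradient, step 1e-5 nm) is
#' recorded. Deterministic: no thermal noise.
#'
#' @param sys a \linkS4class{SimSystem}
#' @param maxSteps maximum optimiser iterations (default 2000)
#' @param tol termination threshold on the energy decrease per chunk,
#'   kJ/mol (default 1e-8)
#' @param chunk optimiser iterations per recorded frame (default 100)
#' @param freezeTube hold the tube profile fixed (beads still feel it)
#' @return a \linkS4class{Trajectory}
#' @export
relaxSystem <- function(sys, maxSteps = 2000, tol = 1e-8, chunk = 100,
                        freezeTube = FALSE) {
  stopifnot(is(sys, "SimSystem"))
  validObject(sys)
  f <- objectiveFactory(sys, freezeTube)
  par <- packState(sys, freezeTube)
  e0 <- f(par)
  if (!is.finite(e0)) stop("non-finite initial energy")
  nTube <- if (!is.null(sys@tube) && !freezeTube) length(sys@tube@r) else 0L
  lower <- c(rep(-Inf, length(par) - nTube), rep(0.5, nTube))
  steps <- 0L
  recSys <- list(unpackState(sys, par, freezeTube))
  recStep <- 0L; recE <- e0
  converged <- FALSE
  while (steps < maxSteps) {
    it <- min(chunk, maxSteps - steps)
    res <- tryCatch(
      optim(par, f, method = "L-BFGS-B", lower = lower,
            control = list(maxit = it, factr = 10, pgtol = 1e-7,
                           ndeps = rep(1e-5, length(par)))),
      error = function(e) NULL)
    steps <- steps + it
    if (is.null(res) || !is.finite(res$value)) {
      warning("optimiser failed; returning last accepted state")
      break
    }
    improve <- recE[length(recE)] - res$value
    if (improve >= 0) {           # accept (monotone by construction)
      par <- res$par
      recSys <- c(recSys, list(unpackState(sys, par, freezeTube)))
      recStep <- c(recStep, steps)
      recE <- c(recE, res$value)
    }
    if (res$convergence == 0 || improve < tol) {
      converged <- TRUE
      break
    }
  }
  g <- numericGradient(f, par)
  if (any(!is.finite(g))) stop("non-finite gradient at endpoint")
  bd <- do.call(rbind, lapply(recSys, function(s) {
    e <- systemEnergy(s)
    data.frame(total = e$total, filament = e$filament, bond = e$bond,
               membrane = e$membrane, coupling = e$coupling)
  }))
  mr <- vapply(recSys, function(s)
    if (is.null(s@tube)) NA_real_ else meanTubeRadius(s@tube), 0)
  new("Trajectory", step = as.integer(recStep), energy = recE,
      breakdown = bd, meanRadius = mr, frames = recSys,
      converged = converged, finalGradInf = max(abs(g)),
      seed = sys@seed)
}
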