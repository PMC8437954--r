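## Synthetic fixture generators: every analysis in the package can be
## exercised without downloading coordinates. Each fixture records its
## full generating spec (including the seed) in metadata, and
## regenerateFixture() rebuilds it bit-identically from that record.

#' Helical C-alpha trace fixture
#'
#' One CA pseudo-atom per subunit at the \code{\link{latticePoints}}
#' positions (converted nm to Angstrom), optionally perturbed by
#' isotropic Gaussian noise. Strands become chains A, B, ...; residue
#' numbers count subunits along each strand from 1.
#'
#' @param sym a \linkS4class{HelicalSymmetry}
#' @param radius lattice radius, nm
#' @param nSubunits subunits per strand
#' @param noiseSigma isotropic Gaussian noise sd, Angstrom (default 0)
#' @param seed integer seed (mandatory when noiseSigma > 0)
#' @return an \linkS4class{AtomicStructure} with the generating spec in
#'   \code{metadata}
#' @export
makeHelixTrace <- function(sym, radius, nSubunits, noiseSigma = 0,
                           seed = 1L) {
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  lp <- latticePoints(sym, radius, nSubunits)
  xyz <- 10 * cbind(lp$x_nm, lp$y_nm, lp$z_nm)   # nm -> Angstrom
  if (noiseSigma > 0) {
    set.seed(seed)
    xyz <- xyz + matrix(rnorm(length(xyz), sd = noiseSigma),
                        ncol = 3)
  }
  atoms <- data.frame(chain = LETTERS[lp$strand + 1L],
                      resno = lp$subunit + 1L, insert = "",
                      resid = "ALA", elety = "CA", elesy = "C",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  AtomicStructure(atoms, source = "synthetic helix trace",
                  metadata = list(kind = "helix_trace",
                                  rise = rise(sym), twist = twist(sym),
                                  nStart = nStart(sym),
                                  cyclicOrder = sym@cyclicOrder,
                                  handedness = sym@handedness,
                                  radius = radius, nSubunits = nSubunits,
                                  noiseSigma = noiseSigma, seed = seed))
}

## Rotation matrix about a unit axis by angle (degrees), Rodrigues.
rotationAboutAxis <- function(axis, angleDeg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Two-domain hinge fixture with a known applied rotation
#'
#' Builds a protein-like pair of structures: domain A (random points in a
#' 15 Angstrom sphere at the origin) is identical in both, domain B (a
#' second sphere 40 Angstrom away) is rotated in the second structure by
#' a known angle about a recorded axis through a recorded hinge point.
#' Ground truth for hinge-angle recovery. Independent Gaussian coordinate
#' noise can be added to both structures.
#'
#' @param angleDeg applied hinge rotation, degrees in [0, 180]
#' @param atomsPerDomain atoms per domain (default 100)
#' @param noiseSigma coordinate noise sd, Angstrom (default 0)
#' @param seed integer seed
#' @param axis rotation axis (default c(0, 0, 1); normalised internally)
#' @return list with \code{s1}, \code{s2}
#'   (\linkS4class{AtomicStructure}), \code{domains} (named list of
#'   \linkS4class{DomainDefinition} A and B) and \code{truth} (angle,
#'   axis, hinge point, seed)
#' @export
makeTwoDomainHinge <- function(angleDeg, atomsPerDomain = 100L,
                               noiseSigma = 0, seed = 1L,
                               axis = c(0, 0, 1)) {
  if (angleDeg < 0 || angleDeg > 180)
    stop("angleDeg must lie in [0, 180]")
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  n <- as.integer(atomsPerDomain)
  set.seed(seed)
  sphere <- function(center) {
    ## uniform in a ball of radius 15 A
    m <- matrix(rnorm(3 * n), ncol = 3)
    m <- m / sqrt(rowSums(m^2)) * 15 * runif(n)^(1 / 3)
    sweep(m, 2, center, "+")
  }
  A <- sphere(c(0, 0, 0))
  B <- sphere(c(40, 0, 0))
  hingePoint <- c(20, 0, 0)
  axis <- axis / sqrt(sum(axis^2))
  R <- rotationAboutAxis(axis, angleDeg)
  B2 <- sweep(sweep(B, 2, hingePoint) %*% t(R), 2, hingePoint, "+")
  mk <- function(Am, Bm, label) {
    xyz <- rbind(Am, Bm)
    if (noiseSigma > 0)
      xyz <- xyz + matrix(rnorm(length(xyz), sd = noiseSigma), ncol = 3)
    AtomicStructure(
      data.frame(chain = "A", resno = seq_len(2L * n), insert = "",
                 resid = "ALA", elety = "CA", elesy = "C",
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
      source = label,
      metadata = list(kind = "two_domain_hinge", angleDeg = angleDeg,
                      atomsPerDomain = n, noiseSigma = noiseSigma,
                      seed = seed, axis = axis))
  }
  list(s1 = mk(A, B, "synthetic hinge reference"),
       s2 = mk(A, B2, "synthetic hinge rotated"),
       domains = list(A = DomainDefinition("A", c(1, n)),
                      B = DomainDefinition("B", c(n + 1, 2 * n))),
       truth = list(angleDeg = angleDeg, axis = axis,
                    hingePoint = hingePoint, seed = seed))
}

#' Perturbed bead filament fixture
#'
#' \code{\link{buildBeadHelix}} output with isotropic Gaussian bead
#' displacements; a standard starting point for relaxation tests. Note
#' large displacements can violate the BeadFilament bond-length
#' invariant, so sigma should stay well below 10 percent of the spacing.
#'
#' @param shape a \linkS4class{HelixShape}
#' @param nStart strands
#' @param nBeads beads per strand
#' @param displacementSigma bead displacement sd, nm (default 0)
#' @param seed integer seed
#' @param spacing bead spacing, nm
#' @return list of \linkS4class{BeadFilament}
#' @export
makePerturbedFilament <- function(shape, nStart = 1L, nBeads = 20L,
                                  displacementSigma = 0, seed = 1L,
                                  spacing = 5.6) {
  if (displacementSigma < 0) stop("displacementSigma must be >= 0")
  fils <- buildBeadHelix(shape, nStart, nBeads, spacing)
  if (displacementSigma > 0) {
    set.seed(seed)
    fils <- lapply(fils, function(f) {
      f@xyz <- f@xyz + matrix(rnorm(length(f@xyz),
                                    sd = displacementSigma), ncol = 3)
      validObject(f)
      f
    })
  }
  fils
}

#' Regenerate a fixture from its embedded metadata
#'
#' Fixtures embed their generating spec (including the seed) in
#' \code{metadata}; this rebuilds the identical fixture from that
#' record.
#'
#' @param metadata the \code{metadata} list of a fixture structure
#' @return the regenerated fixture
#' @export
regenerateFixture <- function(metadata) {
  switch(metadata$kind,
    helix_trace = makeHelixTrace(
      HelicalSymmetry(metadata$rise, metadata$twist, metadata$nStart,
                      metadata$cyclicOrder, metadata$handedness),
      metadata$radius, metadata$nSubunits, metadata$noiseSigma,
      metadata$seed),
    two_domain_hinge = makeTwoDomainHinge(
      metadata$angleDeg, metadata$atomsPerDomain, metadata$noiseSigma,
      metadata$seed, metadata$axis),
    stop("unknown fixture kind: ", metadata$kind))
}
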