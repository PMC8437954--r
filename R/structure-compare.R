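## Rigid-body superposition, hinge-angle and interface-conservation
## operators on atomic coordinates. File parsing is delegated to bio3d;
## the Kabsch superposition and rotation-angle extraction are implemented
## here because the hinge measurement needs the full transform with a
## proper (det = +1) rotation.

#' AtomicStructure: atom records of a coordinate file
#'
#' A thin container around a data.frame of atom records with columns
#' \code{chain}, \code{resno}, \code{insert}, \code{resid}, \code{elety}
#' (atom name), \code{elesy} (element) and coordinates \code{x, y, z} in
#' Angstrom.
#'
#' @slot atoms data.frame of atom records (coordinates in Angstrom)
#' @slot source character label (file path or generator description)
#' @slot metadata list; fixture generators record their full generating
#'   spec (including the seed) here
#' @exportClass AtomicStructure
setClass("AtomicStructure",
  representation(atoms = "data.frame", source = "character",
                 metadata = "list"),
  prototype(source = "", metadata = list()))

setValidity("AtomicStructure", function(object) {
  need <- c("chain", "resno", "insert", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(object@atoms))
  if (length(miss))
    return(paste("atoms is missing columns:", paste(miss, collapse = ", ")))
  xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
  if (nrow(xyz) && any(!is.finite(xyz)))
    return("all coordinates must be finite")
  key <- paste(object@atoms$chain, object@atoms$resno, object@atoms$insert,
               object@atoms$elety)
  if (anyDuplicated(key))
    return("(chain, resno, insert, atom name) must be unique")
  TRUE
})

#' Construct an AtomicStructure from a data.frame of atom records
#'
#' @param atoms data.frame with at least chain, resno, elety, x, y, z;
#'   \code{insert}, \code{resid}, \code{elesy} filled with defaults when
#'   absent
#' @param source character label
#' @param metadata list of provenance metadata
#' @return an \linkS4class{AtomicStructure}
#' @export
AtomicStructure <- function(atoms, source = "", metadata = list()) {
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$resid)) atoms$resid <- "GLY"
  if (is.null(atoms$elesy)) atoms$elesy <- "C"
  new("AtomicStructure", atoms = atoms, source = source,
      metadata = metadata)
}

setMethod("show", "AtomicStructure", function(object) {
  a <- object@atoms
  cat(sprintf("AtomicStructure: %d atoms, %d chain(s) [%s]%s\n",
              nrow(a), length(unique(a$chain)),
              paste(sort(unique(a$chain)), collapse = ","),
              if (nzchar(object@source))
                paste0(" from ", object@source) else ""))
})

#' Number of atoms in an AtomicStructure
#' @param x an \linkS4class{AtomicStructure}
#' @return integer atom count
#' @export
nAtoms <- function(x) nrow(x@atoms)

#' Coordinate matrix of an AtomicStructure
#' @param x an \linkS4class{AtomicStructure}
#' @return n x 3 matrix of coordinates (Angstrom)
#' @export
coords <- function(x) as.matrix(x@atoms[, c("x", "y", "z")])

#' Read a structure from a PDB or mmCIF file
#'
#' ATOM records are loaded; HETATM records are ignored by default. When
#' alternate locations are present the highest-occupancy altloc of each
#' atom is kept. Insertion codes trigger a warning and are carried in the
#' \code{insert} column, which participates in all atom pairing.
#'
#' @param path file path
#' @param format "auto" (by extension), "pdb" or "cif"
#' @param keepHetatm keep HETATM records (default FALSE)
#' @return an \linkS4class{AtomicStructure}
#' @export
readStructure <- function(path, format = c("auto", "pdb", "cif"),
                          keepHetatm = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(cif|mmcif)(\\.gz)?$", path, ignore.case = TRUE))
      "cif" else "pdb"
  pdb <- if (format == "cif") bio3d::read.cif(path, rm.alt = FALSE)
         else bio3d::read.pdb(path, rm.alt = FALSE)
  a <- pdb$atom
  if (!keepHetatm) a <- a[a$type == "ATOM", , drop = FALSE]
  if (!nrow(a)) stop("no ATOM records in ", path)
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$chain[is.na(a$chain)] <- " "
  if (any(nzchar(a$insert)))
    warning("insertion codes present; they are kept and used in pairing")
  if (any(nzchar(a$alt))) {
    o <- a$o
    o[is.na(o)] <- 1
    key <- paste(a$chain, a$resno, a$insert, a$elety)
    keep <- unlist(lapply(split(seq_len(nrow(a)), key), function(i)
      i[which.max(o[i])]))
    a <- a[sort(keep), , drop = FALSE]
  }
  AtomicStructure(a[, c("chain", "resno", "insert", "resid", "elety",
                        "elesy", "x", "y", "z")],
                  source = path)
}

#' Write an AtomicStructure to a PDB file
#'
#' @param x an \linkS4class{AtomicStructure}
#' @param path output path
#' @return invisibly, the path
#' @export
writeStructure <- function(x, path) {
  a <- x@atoms
  bio3d::write.pdb(file = path, xyz = as.vector(t(coords(x))),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$elety, insert = ifelse(nzchar(a$insert),
                                                    a$insert, ""))
  invisible(path)
}

#' DomainDefinition: a named set of residue ranges
#'
#' @slot name domain name (e.g. "Gdomain")
#' @slot ranges integer matrix with columns start, end (inclusive,
#'   author numbering); rows must not overlap
#' @exportClass DomainDefinition
setClass("DomainDefinition",
  representation(name = "character", ranges = "matrix"))

setValidity("DomainDefinition", function(object) {
  r <- object@ranges
  if (ncol(r) != 2) return("ranges must have two columns (start, end)")
  if (any(r[, 2] < r[, 1])) return("range end before start")
  if (nrow(r) > 1) {
    o <- order(r[, 1])
    r <- r[o, , drop = FALSE]
    if (any(r[-1, 1] <= r[-nrow(r), 2]))
      return("ranges overlap within the domain")
  }
  TRUE
})

#' Construct a DomainDefinition
#' @param name domain name
#' @param ... residue ranges, each a length-2 numeric c(start, end), or a
#'   single 2-column matrix
#' @return a \linkS4class{DomainDefinition}
#' @examples
#' DomainDefinition("BSE", c(1, 32), c(294, 320), c(711, 746))
#' @export
DomainDefinition <- function(name, ...) {
  parts <- list(...)
  if (length(parts) == 1 && is.matrix(parts[[1]])) {
    r <- parts[[1]]
  } else {
    r <- do.call(rbind, parts)
  }
  storage.mode(r) <- "integer"
  colnames(r) <- c("start", "end")
  new("DomainDefinition", name = name, ranges = r)
}

setMethod("show", "DomainDefinition", function(object) {
  cat(sprintf("DomainDefinition %s: %s\n", object@name,
              paste(apply(object@ranges, 1, function(v)
                paste0(v[1], "-", v[2])), collapse = ", ")))
})

#' Default dynamin 1 domain boundaries
#'
#' Approximate domain ranges in dynamin 1 author numbering, shipped as a
#' JSON config (\code{inst/extdata/dynamin1_domains.json}) and editable
#' there: G domain 33-293, BSE 1-32 + 294-320 + 711-746, Stalk 321-499 +
#' 643-710, PH 500-642. Hinge 1 is the Stalk/BSE junction; Hinge 2 sits
#' at residues I289-P294 between the BSE and the G domain.
#'
#' @param file path to a JSON file mapping domain names to lists of
#'   [start, end] ranges; defaults to the shipped config
#' @return named list of \linkS4class{DomainDefinition}
#' @export
dynamin1Domains <- function(file = system.file("extdata",
                                               "dynamin1_domains.json",
                                               package = "dynhelix")) {
  raw <- jsonlite::read_json(file)
  out <- lapply(names(raw), function(nm) {
    r <- do.call(rbind, lapply(raw[[nm]], function(v)
      as.integer(unlist(v))))
    DomainDefinition(nm, r)
  })
  setNames(out, names(raw))
}

#' RigidTransform: a proper rotation plus translation
#'
#' @slot rotation 3 x 3 proper rotation matrix (det = +1), acting on
#'   column vectors: y = R x + t
#' @slot translation length-3 translation, Angstrom
#' @slot angle rotation angle in degrees, in [0, 180]
#' @slot axis unit rotation axis; sign chosen so the screw translation
#'   (component of the translation along the axis) is >= 0
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric",
                 angle = "numeric", axis = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3 x 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    return("rotation must be orthonormal")
  if (det(R) < 0) return("rotation must be proper (det = +1)")
  if (length(object@translation) != 3) return("translation must be length 3")
  if (object@angle < 0 || object@angle > 180)
    return("angle must lie in [0, 180] degrees")
  TRUE
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf(paste0("RigidTransform: %.3f deg about (%.3f, %.3f, %.3f), ",
                     "|t| = %.3f A (screw %.3f A)\n"),
              object@angle, object@axis[1], object@axis[2], object@axis[3],
              sqrt(sum(object@translation^2)), screwTranslation(object)))
})

## Angle (deg, [0,180]) and unit axis from a proper rotation matrix.
## Near 180 deg the antisymmetric part vanishes, so fall back to the
## eigenvector of eigenvalue +1.
rotationAngleAxis <- function(R) {
  tr <- sum(diag(R))
  angle <- acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (sqrt(sum(v^2)) > 1e-8) {
    axis <- v / sqrt(sum(v^2))
  } else if (angle < 1e-6) {
    axis <- c(0, 0, 1)
  } else {
    e <- eigen(R)
    i <- which.min(abs(e$values - 1))
    axis <- Re(e$vectors[, i])
    axis <- axis / sqrt(sum(axis^2))
  }
  list(angle = angle, axis = axis)
}

#' Build a RigidTransform from a rotation matrix and translation
#' @param rotation 3 x 3 proper rotation
#' @param translation length-3 numeric (default zero)
#' @return a \linkS4class{RigidTransform}
#' @export
RigidTransform <- function(rotation, translation = c(0, 0, 0)) {
  aa <- rotationAngleAxis(rotation)
  if (sum(translation * aa$axis) < 0) aa$axis <- -aa$axis
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation),
      angle = aa$angle, axis = aa$axis)
}

#' Rotation angle of a RigidTransform, degrees in [0, 180]
#' @param tf a \linkS4class{RigidTransform}
#' @return angle in degrees
#' @export
rotationAngle <- function(tf) tf@angle

#' Screw translation of a RigidTransform
#' @param tf a \linkS4class{RigidTransform}
#' @return translation component along the rotation axis, Angstrom (>= 0
#'   by axis sign convention)
#' @export
screwTranslation <- function(tf) abs(sum(tf@translation * tf@axis))

#' Apply a RigidTransform to a structure or coordinate matrix
#' @param x an \linkS4class{AtomicStructure} or n x 3 matrix
#' @param tf a \linkS4class{RigidTransform}
#' @return object of the same type with transformed coordinates
#' @export
applyTransform <- function(x, tf) {
  stopifnot(is(tf, "RigidTransform"))
  if (is(x, "AtomicStructure")) {
    xyz <- coords(x) %*% t(tf@rotation)
    xyz <- sweep(xyz, 2, tf@translation, "+")
    x@atoms$x <- xyz[, 1]; x@atoms$y <- xyz[, 2]; x@atoms$z <- xyz[, 3]
    return(x)
  }
  sweep(x %*% t(tf@rotation), 2, tf@translation, "+")
}

## Resolve a selection on a structure: rows of the atom table.
## selection: list(chains = NULL, domain = NULL (DomainDefinition),
##                 elety = "CA")
resolveSelection <- function(x, selection = list()) {
  a <- x@atoms
  keep <- rep(TRUE, nrow(a))
  elety <- if (is.null(selection$elety)) "CA" else selection$elety
  if (!identical(elety, "all")) keep <- keep & a$elety %in% elety
  if (!is.null(selection$chains)) keep <- keep & a$chain %in% selection$chains
  dom <- selection$domain
  if (!is.null(dom)) {
    stopifnot(is(dom, "DomainDefinition"))
    inDom <- rep(FALSE, nrow(a))
    for (i in seq_len(nrow(dom@ranges)))
      inDom <- inDom | (a$resno >= dom@ranges[i, 1] &
                        a$resno <= dom@ranges[i, 2])
    keep <- keep & inDom
  }
  which(keep)
}

## Pair selected atoms of two structures by (chain, resno, insert, elety).
## chainMap: named character vector mapping mobile chains to reference
## chains. Errors if no common atoms, or if selections disagree.
pairAtoms <- function(mobile, reference, selection = list(),
                      chainMap = NULL) {
  im <- resolveSelection(mobile, selection)
  selRef <- selection
  if (!is.null(chainMap) && !is.null(selection$chains))
    selRef$chains <- unname(chainMap[selection$chains])
  ir <- resolveSelection(reference, selRef)
  am <- mobile@atoms[im, ]; ar <- reference@atoms[ir, ]
  chm <- am$chain
  if (!is.null(chainMap)) {
    mapped <- chainMap[chm]
    if (any(is.na(mapped)))
      stop("chainMap does not cover mobile chain(s): ",
           paste(unique(chm[is.na(mapped)]), collapse = ","))
    chm <- unname(mapped)
  }
  keym <- paste(chm, am$resno, am$insert, am$elety)
  keyr <- paste(ar$chain, ar$resno, ar$insert, ar$elety)
  j <- match(keym, keyr)
  ok <- !is.na(j)
  if (sum(ok) < 3)
    stop("fewer than 3 paired atoms in the selection; check residue ",
         "numbering and chain mapping")
  list(mobile = im[ok], reference = ir[j[ok]], nPaired = sum(ok),
       nMobile = length(im), nReference = length(ir))
}

## Kabsch: least-squares proper rotation + translation taking X onto Y
## (both n x 3). Returns list(R, t, rmsd) with y ~ R x + t.
kabsch <- function(X, Y) {
  if (nrow(X) < 3) stop("need at least 3 paired atoms")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  s <- svd(crossprod(Xc, Yc))
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) stop("degenerate (collinear) atom selection")
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cy - as.vector(R %*% cx)
  fit <- sweep(Xc %*% t(R), 2, cy, "+")
  rmsd <- sqrt(mean(rowSums((fit - Y)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

#' Least-squares rigid superposition of two structures
#'
#' Computes the optimal proper rotation and translation (Kabsch, det = +1
#' enforced so a reflection is never returned) taking the selected atoms
#' of \code{mobile} onto the corresponding atoms of \code{reference}.
#' Atoms are paired by (chain, residue number, insertion code, atom
#' name); C-alpha atoms only by default.
#'
#' @param mobile,reference \linkS4class{AtomicStructure} objects
#' @param selection list with optional elements \code{chains} (character
#'   vector), \code{domain} (a \linkS4class{DomainDefinition}) and
#'   \code{elety} (atom names, default "CA"; "all" for every atom)
#' @param chainMap optional named character vector mapping mobile chain
#'   ids to reference chain ids
#' @return list with \code{transform} (a \linkS4class{RigidTransform}),
#'   \code{rmsd} (Angstrom over the paired selection) and \code{nPaired}
#' @export
superpose <- function(mobile, reference, selection = list(),
                      chainMap = NULL) {
  stopifnot(is(mobile, "AtomicStructure"), is(reference, "AtomicStructure"))
  pr <- pairAtoms(mobile, reference, selection, chainMap)
  X <- coords(mobile)[pr$mobile, , drop = FALSE]
  Y <- coords(reference)[pr$reference, , drop = FALSE]
  ## collinearity guard: rank of centred coordinates
  Xc <- sweep(X, 2, colMeans(X))
  if (sum(svd(Xc)$d > 1e-8 * max(svd(Xc)$d)) < 2)
    stop("selection is collinear; superposition is degenerate")
  k <- kabsch(X, Y)
  list(transform = RigidTransform(k$R, k$t), rmsd = k$rmsd,
       nPaired = pr$nPaired)
}

#' Hinge angle between two conformations
#'
#' Reproduces the domain-swing measurement used for dynamin hinges: the
#' two structures are first aligned on \code{alignDomain} (e.g. the BSE),
#' then the residual rigid rotation of \code{measureDomain} (e.g. the G
#' domain) of the aligned mobile structure onto the same domain of the
#' reference is reported. For dynamin, aligning on the BSE and measuring
#' the G domain gives the Hinge 2 swing; aligning on the Stalk and
#' measuring the BSE gives the Hinge 1 swing.
#'
#' @param s1 reference \linkS4class{AtomicStructure}
#' @param s2 mobile \linkS4class{AtomicStructure}
#' @param alignDomain a \linkS4class{DomainDefinition} used for the
#'   initial alignment
#' @param measureDomain a \linkS4class{DomainDefinition} whose residual
#'   rotation is reported
#' @param chains1,chains2 optional chain restriction for s1 / s2
#' @param chainMap optional named map from s2 chains to s1 chains
#' @param elety atom names used for pairing (default "CA")
#' @return list with \code{angle} (degrees, [0, 180]), \code{axis} (unit
#'   vector), \code{screwTranslation} (Angstrom), \code{alignRMSD} and
#'   \code{measureRMSD} (Angstrom)
#' @export
hingeAngle <- function(s1, s2, alignDomain, measureDomain,
                       chains1 = NULL, chains2 = NULL, chainMap = NULL,
                       elety = "CA") {
  if (!is.null(chains1) && !is.null(chains2) && is.null(chainMap))
    chainMap <- setNames(chains1, chains2)
  selAlign <- list(domain = alignDomain, chains = chains2, elety = elety)
  fitA <- tryCatch(
    superpose(s2, s1, selection = selAlign, chainMap = chainMap),
    error = function(e) stop("align domain '", alignDomain@name, "': ",
                             conditionMessage(e)))
  s2a <- applyTransform(s2, fitA$transform)
  selMeas <- list(domain = measureDomain, chains = chains2, elety = elety)
  fitM <- tryCatch(
    superpose(s2a, s1, selection = selMeas, chainMap = chainMap),
    error = function(e) stop("measure domain '", measureDomain@name,
                             "': ", conditionMessage(e)))
  tf <- fitM$transform
  list(angle = rotationAngle(tf), axis = tf@axis,
       screwTranslation = screwTranslation(tf),
       alignRMSD = fitA$rmsd, measureRMSD = fitM$rmsd)
}

## Contact set of one structure: residue pairs across a chain pair with
## any CA-CA distance <= cutoff. Returns character keys "resnoA|resnoB".
contactSet <- function(x, chainPair, cutoff) {
  a <- x@atoms
  ca <- a[a$elety == "CA", , drop = FALSE]
  A <- ca[ca$chain == chainPair[1], , drop = FALSE]
  B <- ca[ca$chain == chainPair[2], , drop = FALSE]
  if (!nrow(A) || !nrow(B))
    stop("chain(s) ", paste(chainPair, collapse = "/"),
         " not found or have no CA atoms")
  XA <- as.matrix(A[, c("x", "y", "z")])
  XB <- as.matrix(B[, c("x", "y", "z")])
  d2 <- outer(rowSums(XA^2), rowSums(XB^2), "+") - 2 * XA %*% t(XB)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (!nrow(hit))
    return(list(keys = character(0), resA = integer(0), resB = integer(0)))
  list(keys = unique(paste0(A$resno[hit[, 1]], "|", B$resno[hit[, 2]])),
       resA = unique(A$resno[hit[, 1]]), resB = unique(B$resno[hit[, 2]]))
}

#' Conservation of an inter-chain interface between two structures
#'
#' Contacts are residue pairs across the chain pair whose C-alpha atoms
#' lie within \code{cutoff} Angstrom. The contact sets of the two
#' structures are compared by Jaccard similarity (residue pairs matched
#' by residue number), and an interface RMSD is computed over the union
#' of contacting residues after superposing structure 2 on structure 1
#' using the first chain of the pair.
#'
#' @param s1,s2 \linkS4class{AtomicStructure} objects
#' @param chainPair1 length-2 character: the chain pair in s1
#' @param chainPair2 length-2 character: the corresponding pair in s2
#' @param cutoff contact cutoff in Angstrom (default 10, CA-CA)
#' @return list with \code{jaccard} (NA if both interfaces are empty),
#'   \code{interfaceRMSD} (Angstrom; NA if empty), \code{contacts1},
#'   \code{contacts2} (character vectors "resA|resB"), and counts
#' @export
interfaceConservation <- function(s1, s2, chainPair1, chainPair2 =
                                    chainPair1, cutoff = 10) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  c1 <- contactSet(s1, chainPair1, cutoff)
  c2 <- contactSet(s2, chainPair2, cutoff)
  u <- union(c1$keys, c2$keys)
  jac <- if (!length(u)) NA_real_ else
    length(intersect(c1$keys, c2$keys)) / length(u)
  irmsd <- NA_real_
  if (length(c1$keys) && length(c2$keys)) {
    chainMap <- setNames(chainPair1, chainPair2)
    fit <- superpose(s2, s1,
                     selection = list(chains = chainPair2[1], elety = "CA"),
                     chainMap = chainMap)
    s2a <- applyTransform(s2, fit$transform)
    resA <- union(c1$resA, c2$resA)
    resB <- union(c1$resB, c2$resB)
    pickCA <- function(x, pair) {
      a <- x@atoms
      keep <- a$elety == "CA" &
        ((a$chain == pair[1] & a$resno %in% resA) |
         (a$chain == pair[2] & a$resno %in% resB))
      a <- a[keep, , drop = FALSE]
      ch <- ifelse(a$chain == pair[1], "A", "B")
      key <- paste(ch, a$resno)
      list(key = key, xyz = as.matrix(a[, c("x", "y", "z")]))
    }
    p1 <- pickCA(s1, chainPair1)
    p2 <- pickCA(s2a, chainPair2)
    j <- match(p1$key, p2$key)
    if (any(is.na(j)))
      stop("interface residues of the two structures do not match by ",
           "residue number; cannot pair for interface RMSD")
    irmsd <- sqrt(mean(rowSums((p1$xyz - p2$xyz[j, , drop = FALSE])^2)))
  }
  list(jaccard = jac, interfaceRMSD = irmsd,
       contacts1 = c1$keys, contacts2 = c2$keys,
       nContacts1 = length(c1$keys), nContacts2 = length(c2$keys))
}
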