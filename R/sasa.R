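#' Deterministic unit-sphere point set
#'
#' Fibonacci-spiral sampling of the unit sphere; the same \code{n} always
#' yields the same point set, which makes the surface-area computation
#' fully deterministic.
#'
#' @param n number of points (>= 10).
#' @return n x 3 matrix of unit vectors.
#' @export
spherePoints <- function(n) {
  if (n < 10) stop("n_points must be at least 10")
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Accessible surface area by a rolling spherical probe
#'
#' Dot-sphere (Shrake-Rupley style) accessible surface area: for each
#' atom, points on the sphere of radius (vdw + probe) are tested against
#' the expanded spheres of neighbouring atoms; the accessible fraction
#' times the sphere area is the atom's ASA.  The default probe of 2.0
#' Angstrom mimics a -CH2 group of a lipid hydrocarbon chain (use 1.4
#' for a water probe).  Deterministic for fixed \code{n_points}.
#'
#' @param structure a \linkS4class{StructureModel} (HETATM atoms, if
#'   present, occlude surface but get no residue entry).
#' @param probe_radius probe radius in Angstrom (default 2.0).
#' @param n_points sphere sampling density (default 960).
#' @return an \linkS4class{AsaResult}.
#' @export
computeASA <- function(structure, probe_radius = 2.0, n_points = 960L) {
  a <- structure@atoms
  if (!nrow(a)) stop("empty structure")
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  if (n_points < 10) stop("n_points must be at least 10 (configuration error)")
  S <- spherePoints(n_points)
  X <- as.matrix(a[, c("x", "y", "z")])
  R <- a$vdw + probe_radius
  n <- nrow(X)
  area <- numeric(n)
  maxR <- max(R)
  for (i in seq_len(n)) {
    d2 <- (X[, 1] - X[i, 1])^2 + (X[, 2] - X[i, 2])^2 + (X[, 3] - X[i, 3])^2
    nb <- which(d2 < (R[i] + R)^2 & seq_len(n) != i)
    pts <- S * R[i]
    pts <- sweep(pts, 2, X[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (pts[acc, 1] - X[j, 1])^2 + (pts[acc, 2] - X[j, 2])^2 +
             (pts[acc, 3] - X[j, 3])^2
      acc[acc] <- dj2 >= R[j]^2
    }
    area[i] <- sum(acc) / n_points * 4 * pi * R[i]^2
  }
  prot <- !a$het
  key <- residue_key(a$chain, a$resno, a$insert)[prot]
  per_res <- rowsum(area[prot], group = factor(key, levels = unique(key)))
  first <- !duplicated(key)
  perResidue <- data.frame(
    chain = a$chain[prot][first], resno = a$resno[prot][first],
    insert = a$insert[prot][first], resid = a$resid[prot][first],
    asa = as.numeric(per_res[unique(key), ]),
    stringsAsFactors = FALSE)
  new("AsaResult", perAtom = area, perResidue = perResidue,
      probeRadius = probe_radius, nPoints = as.integer(n_points))
}

#' Relative accessible surface area
#'
#' Divides a residue's ASA by its reference ASA in an extended Gly-X-Gly
#' tripeptide.  Values can exceed 1 for distorted conformations; set
#' \code{clamp = TRUE} where a downstream profile requires [0, 1].
#'
#' @param asa accessible surface area, Angstrom^2.
#' @param residue_name 3-letter residue code(s).
#' @param reference named reference vector from
#'   \code{\link{loadReferenceTable}}.
#' @param clamp clamp the result into [0, 1] (default FALSE).
#' @return rASA fraction(s).
#' @export
relativeASA <- function(asa, residue_name, reference = loadReferenceTable(),
                        clamp = FALSE) {
  residue_name <- toupper(residue_name)
  unknown <- setdiff(unique(residue_name), names(reference))
  if (length(unknown))
    stop("no reference ASA for residue(s): ", paste(unknown, collapse = ", "))
  r <- unname(asa / reference[residue_name])
  if (clamp) r <- clamp01(r)
  r
}

#' Burial classification
#'
#' Buried ("B") iff rASA < threshold; exposed ("E") otherwise, so a
#' residue exactly at the 5 percent threshold is exposed.
#'
#' @param rasa rASA fraction(s), >= 0.
#' @param threshold burial threshold (default 0.05).
#' @return character vector of "B"/"E".
#' @export
classifyBurial <- function(rasa, threshold = 0.05) {
  if (any(rasa < -1e-9, na.rm = TRUE)) stop("negative rASA")
  ifelse(rasa < threshold, "B", "E")
}

#' Interface-residue exclusion mask
#'
#' Residues whose rASA differs between the single-subunit and the
#' complete-complex calculation sit on an interchain interface; they are
#' excluded from training and evaluation, as are residues with missing
#' atoms.  "Different" is judged against a small tolerance since the
#' two values come from floating-point area sums.
#'
#' @param rasa_subunit,rasa_complex rASA fractions over the same residues.
#' @param tolerance exclusion tolerance on the rASA fraction (default 1e-3).
#' @param missing_atoms optional logical: residues with missing atoms are
#'   excluded regardless of rASA.
#' @return logical exclusion mask.
#' @export
interfaceExclusion <- function(rasa_subunit, rasa_complex,
                               tolerance = 1e-3, missing_atoms = NULL) {
  if (length(rasa_subunit) != length(rasa_complex))
    stop("subunit and complex profiles cover different residue sets")
  excl <- abs(rasa_subunit - rasa_complex) > tolerance
  if (!is.null(missing_atoms)) {
    if (length(missing_atoms) != length(excl))
      stop("missing_atoms mask length mismatch")
    excl <- excl | missing_atoms
  }
  excl
}

#' Per-helix rASA profile from a surface-area result
#'
#' Joins a helix's residues to per-residue ASA, normalises by the
#' Gly-X-Gly reference (clamped into [0, 1] as the profile contract
#' requires), labels burial and masks residues with missing atoms.
#'
#' @param helix a \linkS4class{TMHelix}.
#' @param asa an \linkS4class{AsaResult} for the structure the helix came
#'   from.
#' @param reference reference table (see \code{\link{loadReferenceTable}}).
#' @param threshold burial threshold (default 0.05).
#' @return a \linkS4class{RasaProfile}.
#' @export
rasaProfile <- function(helix, asa, reference = loadReferenceTable(),
                        threshold = 0.05) {
  res <- helix@residues
  key <- residue_key(helix@chain, res$resno, res$insert)
  akey <- residue_key(asa@perResidue$chain, asa@perResidue$resno,
                      asa@perResidue$insert)
  idx <- match(key, akey)
  rasa <- rep(NA_real_, nrow(res))
  ok <- !is.na(idx) & !res$missing & res$resid %in% names(reference)
  rasa[ok] <- relativeASA(asa@perResidue$asa[idx[ok]], res$resid[ok],
                          reference, clamp = TRUE)
  labels <- rep(NA_character_, nrow(res))
  labels[ok] <- classifyBurial(rasa[ok], threshold)
  new("RasaProfile", helix = helix, rasa = rasa, labels = labels,
      excluded = !ok | !res$complete, threshold = threshold)
}

#' rASA values accessor
#' @param x a \linkS4class{RasaProfile}.
#' @return numeric rASA vector.
#' @export
rasaValues <- function(x) x@rasa

#' Burial labels accessor
#' @param x a \linkS4class{RasaProfile}.
#' @return character "B"/"E" vector.
#' @export
burialLabels <- function(x) x@labels

#' Exclusion mask accessor
#' @param x a \linkS4class{RasaProfile}.
#' @return logical mask.
#' @export
excludedMask <- function(x) x@excluded

#' @describeIn rasaProfile compact profile display.
#' @param object a RasaProfile.
#' @export
setMethod("show", "RasaProfile", function(object) {
  cat(sprintf("RasaProfile %s:%d  n=%d  buried=%d exposed=%d excluded=%d\n",
              object@helix@chain, object@helix@helixIndex,
              length(object@rasa),
              sum(object@labels == "B", na.rm = TRUE),
              sum(object@labels == "E", na.rm = TRUE),
              sum(object@excluded)))
})
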