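#' Principal axis of a helix
#'
#' Helical axis direction from an ordered set of C-alpha coordinates.
#' For a helix, the second differences of consecutive C-alpha positions
#' point radially toward the axis and are perpendicular to it, so the
#' axis is the null direction of their scatter (the smallest-eigenvalue
#' eigenvector of the second-difference covariance) -- exact for an
#' ideal helix of any length, where the raw largest-variance direction
#' of the coordinate cloud is measurably tilted for short helices.
#' Near-collinear traces (negligible curvature) fall back to the
#' dominant direction of the centered cloud.  The sign is chosen so the
#' axis points from the N-terminal half toward the C-terminal half.
#'
#' @param ca n x 3 matrix of ordered C-alpha coordinates (n >= 3).
#' @return unit 3-vector, N to C.
#' @export
principalAxis <- function(ca) {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  if (n < 3) stop("principal axis needs at least 3 C-alpha atoms")
  cc <- sweep(ca, 2, colMeans(ca))
  spread <- max(abs(cc))
  if (spread < 1e-9) stop("degenerate coordinates: all points coincide")
  v <- NULL
  if (n >= 4) {
    d2 <- ca[-c(1, 2), , drop = FALSE] - 2 * ca[-c(1, n), , drop = FALSE] +
      ca[-c(n - 1, n), , drop = FALSE]
    if (sum(d2^2) > (1e-4 * spread)^2) {
      ev <- eigen(crossprod(d2), symmetric = TRUE)
      # axis well defined only if the differences span a plane
      if (ev$values[2] > 1e-8 * ev$values[1]) v <- ev$vectors[, 3]
    }
  }
  if (is.null(v)) v <- svd(cc, nu = 0, nv = 1)$v[, 1]
  half <- n %/% 2
  nc <- colMeans(ca[(n - half + 1):n, , drop = FALSE]) -
        colMeans(ca[1:half, , drop = FALSE])
  if (sum(v * nc) < 0) v <- -v
  normalize_vec(v)
}

#' Construct a top-view frame for a helix axis
#'
#' Builds a right-handed orthonormal frame (basisU, basisV, axis).  With
#' the axis oriented N to C, in-plane angles atan2(v, u) increase in the
#' clockwise sense as seen from the N-terminal side, the sense in which
#' an ideal right-handed alpha helix advances +100 degrees per residue.
#'
#' @param axis unit 3-vector (N to C).
#' @return a \linkS4class{TopViewFrame}.
#' @export
topViewFrame <- function(axis) {
  axis <- normalize_vec(axis)
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- normalize_vec(crossprod3(ref, axis))
  v <- crossprod3(axis, u)
  new("TopViewFrame", axis = axis, basisU = u, basisV = v)
}

#' Project points into a top-view frame
#'
#' Maps 3-D points to (u, v) in-plane coordinates; axial components are
#' discarded.  In-plane displacements keep their lengths.
#'
#' @param points n x 3 matrix (or length-3 vector).
#' @param frame a \linkS4class{TopViewFrame}.
#' @return n x 2 matrix of (u, v) coordinates.
#' @export
topviewProject <- function(points, frame) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  cbind(u = p %*% frame@basisU, v = p %*% frame@basisV)
}

# In-plane angle of a 2-vector in the frame's positive (clockwise-from-N)
# sense, degrees in [0, 360).
frame_angle <- function(v2) mod360(rad2deg(atan2(v2[2], v2[1])))

#' Lipid-facing direction of a helix
#'
#' The outward unit vector from the molecular geometric center through
#' the helix geometric center, in top-view coordinates.
#'
#' @param helix_center,molecule_center 2-vectors in the same frame.
#' @return unit 2-vector.
#' @export
lipidFacingDirection <- function(helix_center, molecule_center) {
  d <- helix_center - molecule_center
  if (sqrt(sum(d^2)) < 1e-9)
    stop("helix center coincides with molecule center: lipid direction undefined")
  d / sqrt(sum(d^2))
}

#' Observed rotational angle of a transmembrane helix
#'
#' Computes the structure-derived rotational angle: fit the helix
#' principal axis from its transmembrane C-alpha atoms, project into the
#' top view, take the molecular center as the mean of all transmembrane
#' C-alpha atoms of the chain unit (atoms outside annotated segments
#' play no part), and measure the angle rotated from the first TM
#' residue's C-alpha vector to the lipid-facing direction, clockwise as
#' seen from the N-terminal side.  Result in [0, 360).
#'
#' @param helix a \linkS4class{TMHelix} with >= 3 C-alpha atoms.
#' @param chain_tm_ca m x 3 matrix of C-alpha coordinates of all TM
#'   residues of the chain unit (including this helix).
#' @return list with \code{angle} (degrees), \code{first_residue} (resno
#'   used as first residue), \code{fallback} (TRUE if the annotated first
#'   residue lacked a C-alpha).
#' @export
observedRotation <- function(helix, chain_tm_ca) {
  res <- helix@residues
  has <- which(res$hasCA)
  if (length(has) < 3) stop("helix has fewer than 3 C-alpha atoms")
  ca <- as.matrix(res[has, c("ca_x", "ca_y", "ca_z")])
  axis <- principalAxis(ca)
  frame <- topViewFrame(axis)
  P <- topviewProject(ca, frame)
  ch <- colMeans(P)
  Pm <- topviewProject(as.matrix(chain_tm_ca), frame)
  cm <- colMeans(Pm)
  L <- lipidFacingDirection(ch, cm)
  Fv <- P[1, ] - ch
  if (sqrt(sum(Fv^2)) < 1e-9)
    stop("first-residue C-alpha lies on the helix axis")
  ang <- mod360(frame_angle(L) - frame_angle(Fv))
  list(angle = ang,
       first_residue = res$resno[has[1]],
       fallback = has[1] != 1L)
}

#' Observed rotational angles for all helices of a structure
#'
#' Convenience wrapper: extracts helices, pools the TM C-alpha atoms per
#' chain as the molecule definition, and computes each helix's observed
#' rotational angle.
#'
#' @param structure a \linkS4class{StructureModel}.
#' @param annotations annotation data.frame
#'   (see \code{\link{readTMAnnotations}}).
#' @return data.frame: chain, helix_index, n_residues, observed_angle_deg,
#'   first_residue, fallback.
#' @export
observedRotationAngles <- function(structure, annotations) {
  helices <- extractHelices(structure, annotations)
  by_chain <- split(helices, vapply(helices, function(h) h@chain, ""))
  rows <- lapply(helices, function(h) {
    mates <- by_chain[[h@chain]]
    ca_all <- do.call(rbind, lapply(mates, function(m) {
      r <- m@residues
      as.matrix(r[r$hasCA, c("ca_x", "ca_y", "ca_z")])
    }))
    rot <- observedRotation(h, ca_all)
    data.frame(chain = h@chain, helix_index = h@helixIndex,
               n_residues = nrow(h@residues),
               observed_angle_deg = rot$angle,
               first_residue = rot$first_residue,
               fallback = rot$fallback, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
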