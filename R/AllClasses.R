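#' @import methods
NULL

#' StructureModel: atoms of one coordinate model
#'
#' Holds the ATOM records of a single model of a PDB-format file as a
#' data.frame of heavy atoms with assigned van der Waals radii, plus
#' provenance.  Columns of \code{atoms}: \code{name} (PDB atom name),
#' \code{element}, \code{x}, \code{y}, \code{z} (Angstrom), \code{vdw}
#' (Angstrom), \code{chain}, \code{resno}, \code{insert}, \code{resid}
#' (3-letter residue name).
#'
#' @slot atoms data.frame of atoms (see Description).
#' @slot chains character vector of chain identifiers present.
#' @slot provenance list with at least \code{source} and \code{model}.
#' @exportClass StructureModel
setClass("StructureModel",
         representation(atoms = "data.frame",
                        chains = "character",
                        provenance = "list"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("name", "element", "x", "y", "z", "vdw",
            "chain", "resno", "insert", "resid")
  if (!all(need %in% names(a)))
    return(paste("atoms lacks columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a)) {
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      return("non-finite atom coordinate")
    if (!all(a$vdw > 0))
      return("non-positive van der Waals radius")
    if (!all(a$chain %in% object@chains))
      return("atom chain id not listed in chains slot")
  }
  TRUE
})

#' TMHelix: one annotated transmembrane segment
#'
#' An annotated transmembrane helix with its ordered residue records.
#' \code{residues} columns: \code{resno}, \code{insert}, \code{resid},
#' \code{aa} (1-letter), \code{hasCA}, \code{complete} (all expected heavy
#' atoms present), \code{missing} (residue absent from the coordinates),
#' and \code{ca_x}, \code{ca_y}, \code{ca_z}.
#'
#' @slot chain chain identifier.
#' @slot helixIndex 1-based ordinal from the N-terminus.
#' @slot start,end first and last residue numbers (inclusive).
#' @slot residues data.frame ordered N to C.
#' @slot sequence 1-letter sequence, one character per residue.
#' @exportClass TMHelix
setClass("TMHelix",
         representation(chain = "character",
                        helixIndex = "integer",
                        start = "integer",
                        end = "integer",
                        residues = "data.frame",
                        sequence = "character"))

setValidity("TMHelix", function(object) {
  if (object@start > object@end) return("start > end")
  if (nchar(object@sequence) != nrow(object@residues))
    return("sequence length differs from residue count")
  TRUE
})

#' AsaResult: accessible surface areas of one structure
#'
#' @slot perAtom numeric vector, one area (Angstrom^2) per atom, in the
#'   atom order of the source StructureModel.
#' @slot perResidue data.frame with \code{chain}, \code{resno},
#'   \code{insert}, \code{resid}, \code{asa}.
#' @slot probeRadius probe radius in Angstrom.
#' @slot nPoints sphere sampling density.
#' @exportClass AsaResult
setClass("AsaResult",
         representation(perAtom = "numeric",
                        perResidue = "data.frame",
                        probeRadius = "numeric",
                        nPoints = "integer"))

setValidity("AsaResult", function(object) {
  if (any(object@perAtom < -1e-9)) return("negative per-atom area")
  if (any(object@perResidue$asa < -1e-9)) return("negative per-residue area")
  TRUE
})

#' RasaProfile: per-residue relative accessibility of one helix
#'
#' @slot helix the TMHelix the profile belongs to.
#' @slot rasa ordered relative accessible surface areas in [0, 1].
#' @slot labels burial labels, "B" (buried, rasa < threshold) or "E".
#' @slot excluded logical mask of residues removed from training/evaluation
#'   (interface residues or residues with missing atoms).
#' @slot threshold the burial threshold the labels were derived with.
#' @exportClass RasaProfile
setClass("RasaProfile",
         representation(helix = "TMHelix",
                        rasa = "numeric",
                        labels = "character",
                        excluded = "logical",
                        threshold = "numeric"))

setValidity("RasaProfile", function(object) {
  n <- nrow(object@helix@residues)
  if (length(object@rasa) != n) return("rasa length differs from helix length")
  if (length(object@labels) != n) return("labels length differs from helix length")
  ok <- !is.na(object@rasa)
  if (any(object@rasa[ok] < -1e-9 | object@rasa[ok] > 1 + 1e-9))
    return("rasa outside [0, 1]")
  lab <- ifelse(object@rasa[ok] < object@threshold, "B", "E")
  if (!all(object@labels[ok] == lab))
    return("label inconsistent with rasa and threshold")
  TRUE
})

#' MomentResult: the rASA moment of a helix
#'
#' Vector sum of per-residue scores placed at helical-wheel positions
#' (i - 1) * 100 degrees; its direction estimates the lipid-facing
#' direction, its length the exposure anisotropy.
#'
#' @slot x,y moment vector components (score units).
#' @slot length moment length |M| = sqrt(x^2 + y^2).
#' @slot theta direction in degrees, [0, 360); NA when |M| is below the
#'   undefined-direction epsilon.
#' @slot n number of residues summed.
#' @exportClass MomentResult
setClass("MomentResult",
         representation(x = "numeric", y = "numeric", length = "numeric",
                        theta = "numeric", n = "integer"))

setValidity("MomentResult", function(object) {
  if (object@length < 0) return("negative moment length")
  if (!is.na(object@theta) && (object@theta < 0 || object@theta >= 360))
    return("theta outside [0, 360)")
  TRUE
})

#' TopViewFrame: orthonormal helix frame for top-view projection
#'
#' Right-handed orthonormal frame (basisU, basisV, axis) with the axis
#' oriented N to C.  In-plane angles measured as atan2(v, u) increase in
#' the clockwise sense when viewed from the N-terminal side looking along
#' the axis, so consecutive residues of an ideal right-handed alpha helix
#' advance by +100 degrees per residue in this frame.
#'
#' @slot axis unit 3-vector, N to C.
#' @slot basisU,basisV orthonormal in-plane unit 3-vectors.
#' @exportClass TopViewFrame
setClass("TopViewFrame",
         representation(axis = "numeric", basisU = "numeric",
                        basisV = "numeric"))

setValidity("TopViewFrame", function(object) {
  v <- rbind(object@axis, object@basisU, object@basisV)
  if (ncol(v) != 3) return("frame vectors must be length 3")
  g <- v %*% t(v)
  if (max(abs(g - diag(3))) > 1e-6) return("frame not orthonormal")
  h <- crossprod3(object@basisU, object@basisV)
  if (sum(h * object@axis) < 0.99) return("frame not right-handed")
  TRUE
})

#' DatasetSplit: feature vectors with targets, grouped by chain
#'
#' @slot features numeric matrix, one row per residue.
#' @slot rasa numeric rASA targets in [0, 1].
#' @slot labels character burial labels ("B"/"E").
#' @slot chain character chain id per row (the LOOCV grouping unit).
#' @slot schemaVersion feature-layout version the rows were encoded with.
#' @exportClass DatasetSplit
setClass("DatasetSplit",
         representation(features = "matrix", rasa = "numeric",
                        labels = "character", chain = "character",
                        schemaVersion = "character"))

setValidity("DatasetSplit", function(object) {
  n <- nrow(object@features)
  if (length(object@rasa) != n || length(object@labels) != n ||
      length(object@chain) != n)
    return("targets/labels/chain must match feature rows")
  TRUE
})

#' TMexpoModel: trained burial classifier and rASA regressor
#'
#' @slot classifier RBF-kernel C-SVC for burial status.
#' @slot regressor RBF-kernel epsilon-SVR for rASA.
#' @slot hyperparams list of the training hyperparameters.
#' @slot schemaVersion feature-layout version of the training vectors;
#'   prediction refuses vectors encoded under a different version.
#' @slot meta training metadata (chains, date, seed).
#' @exportClass TMexpoModel
setClass("TMexpoModel",
         representation(classifier = "ANY", regressor = "ANY",
                        hyperparams = "list", schemaVersion = "character",
                        meta = "list"))

#' EvalReport: evaluation summary for angle and accessibility prediction
#'
#' @slot maae mean absolute angular error, degrees in [0, 180] (NA if no
#'   angle pairs were supplied).
#' @slot mae,rmse mean absolute / root-mean-squared rASA error (fractions).
#' @slot pcc Pearson correlation of predicted vs observed rASA.
#' @slot mcc Matthews correlation coefficient of the burial classification.
#' @slot accuracy,sensitivity,specificity,precision percentages (exposed =
#'   positive class).
#' @slot nHelices,nResidues sample sizes.
#' @exportClass EvalReport
setClass("EvalReport",
         representation(maae = "numeric", mae = "numeric", rmse = "numeric",
                        pcc = "numeric", mcc = "numeric",
                        accuracy = "numeric", sensitivity = "numeric",
                        specificity = "numeric", precision = "numeric",
                        nHelices = "integer", nResidues = "integer"))
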