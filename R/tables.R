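#' Load the van der Waals radii table
#'
#' Reads a radii table in the bundled two-column-override layout
#' (element defaults plus atom-name overrides, NACCESS/Chothia
#' convention).  The table is an editable data file so alternative radii
#' sets can be swapped in.
#'
#' @param path path to a radii TSV; default: the bundled table.
#' @return list with \code{element} (named numeric) and \code{atom}
#'   (named numeric overrides).
#' @export
loadRadiiTable <- function(path = extdata_path("vdw_radii.tsv")) {
  d <- read_tsv_commented(path)
  stopifnot(all(c("kind", "key", "radius") %in% names(d)))
  if (any(d$radius <= 0)) stop("radii table contains a non-positive radius")
  list(element = stats::setNames(d$radius[d$kind == "element"],
                                 toupper(d$key[d$kind == "element"])),
       atom = stats::setNames(d$radius[d$kind == "atom"],
                              toupper(d$key[d$kind == "atom"])))
}

#' Load the Gly-X-Gly reference ASA table
#'
#' Extended-conformation Gly-X-Gly reference accessible surface areas
#' (Miller et al. standard-state values) used to normalise per-residue
#' ASA to relative ASA.
#'
#' @param path path to a reference TSV; default: the bundled table.
#' @return named numeric vector, Angstrom^2, keyed by 3-letter residue code.
#' @export
loadReferenceTable <- function(path = extdata_path("gxg_reference.tsv")) {
  d <- read_tsv_commented(path)
  stopifnot(all(c("residue", "ref_asa") %in% names(d)))
  v <- stats::setNames(d$ref_asa, toupper(d$residue))
  if (!all(AA3 %in% names(v)))
    stop("reference table must cover the 20 standard residues")
  if (any(v <= 0)) stop("reference table contains a non-positive value")
  v
}

#' Load the per-residue property tables for the feature encoder
#'
#' Seven per-residue properties (volume, polarity, charge class,
#' interhelical contact propensity, helix insertion free energy,
#' amphiphilicity, turn propensity).  Three normalisation anchors are
#' asserted at load time: the volume maximum 237.2 (Tyr), the contact
#' propensity maximum 1.43 (Cys) and the turn propensity maximum 2.7
#' (Pro).  The bundled file is a constructed stand-in (see its header);
#' replace it with measured tables of the same layout if available.
#'
#' @param path path to a property TSV; default: the bundled table.
#' @return data.frame with rownames = 3-letter residue codes.
#' @export
loadPropertyTables <- function(path = extdata_path("property_tables_synthetic.tsv")) {
  d <- read_tsv_commented(path)
  need <- c("residue", "volume", "polarity", "charge", "contact",
            "energy", "amphiphilicity", "turn")
  stopifnot(all(need %in% names(d)))
  rownames(d) <- toupper(d$residue)
  if (!all(AA3 %in% rownames(d)))
    stop("property table must cover the 20 standard residues")
  d <- d[AA3, ]
  # normalisation anchors
  if (abs(max(d$volume) - 237.2) > 1e-9 || rownames(d)[which.max(d$volume)] != "TYR")
    stop("volume anchor violated: maximum must be 237.2 at TYR")
  if (abs(max(d$contact) - 1.43) > 1e-9 || rownames(d)[which.max(d$contact)] != "CYS")
    stop("contact propensity anchor violated: maximum must be 1.43 at CYS")
  if (abs(max(d$turn) - 2.7) > 1e-9 || rownames(d)[which.max(d$turn)] != "PRO")
    stop("turn propensity anchor violated: maximum must be 2.7 at PRO")
  if (!all(d$charge %in% c(0, 0.5, 1)))
    stop("charge classes must be 0, 0.5 or 1")
  d
}

#' Load a named per-residue score scale
#'
#' Ships the Eisenberg consensus hydrophobicity scale ("eisenberg") as a
#' baseline score profile for moment-based angle estimation; arbitrary
#' scales can be supplied as a two-column TSV (residue, value).
#'
#' @param name built-in scale name, currently \code{"eisenberg"}.
#' @param path optional path to a custom scale TSV (overrides \code{name}).
#' @return named numeric vector keyed by 3-letter residue code.
#' @export
loadScale <- function(name = "eisenberg", path = NULL) {
  if (is.null(path)) {
    path <- switch(name,
                   eisenberg = extdata_path("eisenberg_consensus.tsv"),
                   stop("unknown scale: ", name))
  }
  d <- read_tsv_commented(path)
  stopifnot(all(c("residue", "value") %in% names(d)))
  v <- stats::setNames(d$value, toupper(d$residue))
  if (!all(AA3 %in% names(v)))
    stop("scale must cover the 20 standard residues")
  v
}

#' The bundled rotational-angle benchmark
#'
#' A benchmark of 73 transmembrane helices from 14 polytopic membrane
#' protein chains (the Harrington & Ben-Tal helix-packing set) with
#' structure-derived observed rotational angles, rASA-moment predicted
#' angles, published per-helix angular errors and per-chain MAAE.
#'
#' @return data.frame with columns \code{chain}, \code{helix},
#'   \code{sequence}, \code{observed}, \code{predicted}, \code{error},
#'   \code{moment_length}, \code{chain_maae}.
#' @export
benchmarkAngles <- function() {
  read_tsv_commented(extdata_path("tmh_benchmark_angles.tsv"))
}
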