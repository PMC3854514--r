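# Expected heavy atoms per standard residue type (backbone N/CA/C/O plus
# side chain).  A residue is flagged incomplete if any of these is absent;
# terminal OXT is not required.
HEAVY_ATOMS <- list(
  ALA = c("CB"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2"))
BACKBONE <- c("N", "CA", "C", "O")

assign_vdw <- function(name, element, radii) {
  r <- radii$element[toupper(element)]
  ov <- radii$atom[toupper(name)]
  r[!is.na(ov)] <- ov[!is.na(ov)]
  if (anyNA(r)) {
    bad <- which(is.na(r))[1]
    stop("no van der Waals radius for atom '", name[bad],
         "' (element '", element[bad], "'); extend the radii table")
  }
  unname(r)
}

#' Read a PDB-format structure
#'
#' Parses ATOM records of one model of a PDB-format coordinate file
#' (via bio3d) into a \linkS4class{StructureModel}.  Hydrogens are
#' dropped (X-ray structures generally lack them), alternate locations
#' are resolved to the highest-occupancy conformer (tie: first
#' encountered) and van der Waals radii are assigned from an editable
#' radii table.  HETATM records are excluded by default.
#'
#' @param path PDB-format file.
#' @param model model number to load for multi-model files (default 1).
#' @param radii radii table from \code{\link{loadRadiiTable}}.
#' @param keep_hetatm include HETATM records in the atom set (they are
#'   never treated as protein residues but can occlude surface).
#' @return a \linkS4class{StructureModel}.
#' @export
readStructure <- function(path, model = 1L, radii = loadRadiiTable(),
                          keep_hetatm = FALSE) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = model > 1L, rm.alt = FALSE,
                    verbose = FALSE),
    error = function(e) stop("not parseable as PDB format: ", path,
                             " (", conditionMessage(e), ")"))
  at <- pdb$atom
  if (model > 1L) {
    nm <- nrow(pdb$xyz)
    if (is.null(nm) || model > nm)
      stop("model ", model, " not present in ", path)
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  if (!keep_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem) | elem == "")) {
    elem <- sub("^[0-9]*", "", at$elety)
    elem <- ifelse(substr(elem, 1, 2) %in% c("SE"), substr(elem, 1, 2),
                   substr(elem, 1, 1))
  }
  elem <- toupper(trimws(elem))
  keep <- elem != "H" & elem != "D"
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]

  # alternate locations: highest occupancy per (chain, resno, insert, name)
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(factor(key, levels = unique(key)), -occ,
               seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  elem <- elem[ord]
  dup <- duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                          sep = "\r"))
  at <- at[!dup, , drop = FALSE]
  elem <- elem[!dup]

  atoms <- data.frame(
    name = trimws(at$elety), element = elem,
    x = at$x, y = at$y, z = at$z,
    vdw = assign_vdw(trimws(at$elety), elem, radii),
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    resid = toupper(trimws(at$resid)),
    het = at$type != "ATOM",
    stringsAsFactors = FALSE)
  new("StructureModel", atoms = atoms, chains = unique(atoms$chain),
      provenance = list(source = path, model = as.integer(model)))
}

#' Write a StructureModel to PDB format
#'
#' Serialises the atom records back to a fixed-width PDB-format file via
#' bio3d, preserving coordinates to the format's 3-decimal precision.
#'
#' @param structure a \linkS4class{StructureModel}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeStructurePDB <- function(structure, path) {
  a <- structure@atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   insert = ifelse(a$insert == "", NA, a$insert),
                   elety = a$name, eleno = seq_len(nrow(a)),
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}

#' Read transmembrane-segment annotations
#'
#' Reads a tab-separated annotation file with columns \code{chain},
#' \code{helix_index}, \code{start}, \code{end} ('#' starts a comment).
#' Residue numbers are author numbers as printed in the coordinate file.
#' Annotations of one chain must be sorted and non-overlapping.
#'
#' @param path annotation TSV.
#' @return data.frame of validated annotations.
#' @export
readTMAnnotations <- function(path) {
  d <- read_tsv_commented(path)
  need <- c("chain", "helix_index", "start", "end")
  if (!all(need %in% names(d)))
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  d$chain <- as.character(d$chain)
  for (col in c("helix_index", "start", "end")) {
    v <- suppressWarnings(as.integer(d[[col]]))
    if (anyNA(v)) stop("non-integer value in annotation column '", col, "'")
    d[[col]] <- v
  }
  bad <- which(d$start > d$end)
  if (length(bad))
    stop("annotation row ", bad[1], ": start > end")
  for (ch in unique(d$chain)) {
    rows <- which(d$chain == ch)
    sub <- d[rows, ][order(d$start[rows]), ]
    if (nrow(sub) > 1 && any(sub$start[-1] <= sub$end[-nrow(sub)])) {
      i <- which(sub$start[-1] <= sub$end[-nrow(sub)])[1]
      stop("overlapping annotations for chain ", ch,
           " (rows with start ", sub$start[i], " and ", sub$start[i + 1], ")")
    }
    d[rows, ] <- sub
  }
  d[order(d$chain, d$start), , drop = FALSE]
}

#' Extract annotated transmembrane helices from a structure
#'
#' Builds one \linkS4class{TMHelix} per annotation, walking author residue
#' numbers from \code{start} to \code{end}.  Residues absent from the
#' coordinates are flagged \code{missing} (never silently dropped);
#' residues lacking any expected heavy atom are flagged incomplete;
#' residues without a C-alpha are flagged \code{hasCA = FALSE}.
#'
#' @param structure a \linkS4class{StructureModel}.
#' @param annotations data.frame from \code{\link{readTMAnnotations}}.
#' @return list of \linkS4class{TMHelix}.
#' @export
extractHelices <- function(structure, annotations) {
  a <- structure@atoms[!structure@atoms$het, , drop = FALSE]
  missing_chain <- setdiff(unique(annotations$chain), structure@chains)
  if (length(missing_chain))
    stop("annotation references absent chain(s): ",
         paste(missing_chain, collapse = ", "))
  lapply(seq_len(nrow(annotations)), function(i) {
    ann <- annotations[i, ]
    ca <- a[a$chain == ann$chain, , drop = FALSE]
    resnos <- ann$start:ann$end
    rec <- lapply(resnos, function(rn) {
      at <- ca[ca$resno == rn, , drop = FALSE]
      if (!nrow(at)) {
        return(data.frame(resno = rn, insert = "", resid = NA_character_,
                          aa = "X", hasCA = FALSE, complete = FALSE,
                          missing = TRUE, ca_x = NA_real_, ca_y = NA_real_,
                          ca_z = NA_real_, stringsAsFactors = FALSE))
      }
      # first insertion-code variant in file order
      at <- at[at$insert == at$insert[1], , drop = FALSE]
      resid <- at$resid[1]
      caat <- at[at$name == "CA", , drop = FALSE]
      has_ca <- nrow(caat) > 0
      expected <- c(BACKBONE, HEAVY_ATOMS[[resid]])
      complete <- if (is.null(HEAVY_ATOMS[[resid]])) FALSE else
        all(expected %in% at$name)
      data.frame(resno = rn, insert = at$insert[1], resid = resid,
                 aa = aa321(resid), hasCA = has_ca, complete = complete,
                 missing = FALSE,
                 ca_x = if (has_ca) caat$x[1] else NA_real_,
                 ca_y = if (has_ca) caat$y[1] else NA_real_,
                 ca_z = if (has_ca) caat$z[1] else NA_real_,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rec)
    new("TMHelix", chain = ann$chain,
        helixIndex = as.integer(ann$helix_index),
        start = as.integer(ann$start), end = as.integer(ann$end),
        residues = res, sequence = paste(res$aa, collapse = ""))
  })
}

#' @describeIn readStructure number of atoms and chains at a glance.
#' @param object a StructureModel.
#' @export
setMethod("show", "StructureModel", function(object) {
  cat("StructureModel:", nrow(object@atoms), "atoms,",
      length(object@chains), "chain(s) [",
      paste(object@chains, collapse = " "), "]\n")
  cat("  source:", object@provenance$source,
      " model:", object@provenance$model, "\n")
})

#' @describeIn extractHelices helix summary.
#' @param object a TMHelix.
#' @export
setMethod("show", "TMHelix", function(object) {
  r <- object@residues
  cat(sprintf("TMHelix %s:%d  residues %d-%d  (%d res, %d missing, %d incomplete)\n",
              object@chain, object@helixIndex, object@start, object@end,
              nrow(r), sum(r$missing), sum(!r$complete & !r$missing)))
  cat(" ", object@sequence, "\n")
})

#' Helix sequence accessor
#' @param x a \linkS4class{TMHelix}.
#' @return 1-letter sequence string.
#' @export
helixSequence <- function(x) x@sequence

#' Atom table accessor
#' @param x a \linkS4class{StructureModel}.
#' @return the atom data.frame.
#' @export
atomTable <- function(x) x@atoms

#' Helix residue table accessor
#' @param x a \linkS4class{TMHelix}.
#' @return the ordered residue data.frame.
#' @export
helixResidues <- function(x) x@residues
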