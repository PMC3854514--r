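# Synthetic fixtures with planted ground truth: ideal alpha-helix
# bundles, periodic exposure profiles and planted-signal training sets.
# These generators define testable conditions for every other module
# without any external structure downloads.

#' Ideal-helix specification
#'
#' Canonical alpha-helix C-alpha geometry: rise 1.5 Angstrom per residue,
#' twist 100 degrees per residue (the helical-wheel spacing), C-alpha
#' radius 2.3 Angstrom.
#'
#' @param n_residues number of residues (>= 3).
#' @param rise rise per residue, Angstrom.
#' @param twist twist per residue, degrees.
#' @param radius C-alpha radius, Angstrom.
#' @param position in-plane (x, y) position of the helix axis.
#' @param offset axial rotation offset of residue 1, degrees.
#' @param sequence 1-letter sequence (default poly-Ala).
#' @return list of class "helix_spec".
#' @export
helixSpec <- function(n_residues, rise = 1.5, twist = 100, radius = 2.3,
                      position = c(0, 0), offset = 0, sequence = NULL) {
  if (n_residues < 3) stop("a helix spec needs at least 3 residues")
  if (is.null(sequence)) sequence <- strrep("A", n_residues)
  if (nchar(sequence) != n_residues)
    stop("sequence length differs from n_residues")
  structure(list(n = as.integer(n_residues), rise = rise, twist = twist,
                 radius = radius, position = position, offset = offset,
                 sequence = toupper(sequence)),
            class = "helix_spec")
}

#' Build an ideal helix
#'
#' Places C-alpha i at helical-wheel angle (i - 1) * twist + offset on a
#' circle of the given radius, advancing by the rise along +z (N to C),
#' which matches the right-handed +100-degrees-per-residue contract of
#' the geometry module.  A minimal crude backbone (N, C, O, CB) is added
#' around each C-alpha so the structure can be written to PDB format and
#' passes heavy-atom completeness checks for poly-Ala/Gly sequences; CB
#' points radially outward.
#'
#' @param spec a \code{\link{helixSpec}}.
#' @param resno_start first residue number (default 1).
#' @return data.frame of atoms: name, element, x, y, z, resno, resid.
#' @export
idealHelix <- function(spec, resno_start = 1L) {
  i <- seq_len(spec$n)
  th <- deg2rad((i - 1) * spec$twist + spec$offset)
  u <- cbind(cos(th), sin(th), 0)          # radial
  tg <- cbind(-sin(th), cos(th), 0)        # tangential
  k <- c(0, 0, 1)
  ca <- cbind(spec$position[1] + spec$radius * cos(th),
              spec$position[2] + spec$radius * sin(th),
              (i - 1) * spec$rise)
  res3 <- aa123(strsplit(spec$sequence, "")[[1]])
  if (anyNA(res3)) stop("nonstandard residue in fixture sequence")
  mk <- function(name, elem, offs) {
    data.frame(name = name, element = elem,
               x = ca[, 1] + offs[, 1], y = ca[, 2] + offs[, 2],
               z = ca[, 3] + offs[, 3],
               resno = resno_start + i - 1L, resid = res3,
               stringsAsFactors = FALSE)
  }
  atoms <- rbind(
    mk("N", "N", -0.9 * tg - 0.9 * matrix(k, spec$n, 3, byrow = TRUE) +
         0.3 * u),
    mk("CA", "C", 0 * u),
    mk("C", "C", 0.9 * tg + 0.9 * matrix(k, spec$n, 3, byrow = TRUE) +
         0.3 * u),
    mk("O", "O", 0.9 * tg + 0.9 * matrix(k, spec$n, 3, byrow = TRUE) +
         1.4 * u),
    if (any(res3 != "GLY"))
      mk("CB", "C", 1.5 * u + 0.3 * matrix(k, spec$n, 3, byrow = TRUE))[
        res3 != "GLY", , drop = FALSE])
  atoms <- atoms[order(atoms$resno, match(atoms$name,
                                          c("N", "CA", "C", "O", "CB"))), ]
  rownames(atoms) <- NULL
  atoms
}

#' Build a helix bundle with known rotational angles
#'
#' Assembles ideal helices at distinct in-plane positions into one chain
#' and computes each helix's ground-truth observed rotational angle
#' analytically from the construction: the angle, in the clockwise-from-N
#' sense, from the first residue's C-alpha vector to the outward radial
#' direction (helix center minus bundle center).
#'
#' @param specs list of \code{\link{helixSpec}} (>= 2, distinct positions).
#' @param chain chain id (default "A").
#' @param gap unmodelled residues between consecutive helices in the
#'   numbering (default 5).
#' @param radii radii table for VDW assignment.
#' @return list with \code{structure} (\linkS4class{StructureModel}),
#'   \code{annotations} (data.frame), \code{truth} (data.frame with the
#'   analytic ground-truth angle per helix).
#' @export
helixBundle <- function(specs, chain = "A", gap = 5L,
                        radii = loadRadiiTable()) {
  if (length(specs) < 2) stop("a bundle needs at least 2 helices")
  pos <- t(vapply(specs, function(s) s$position, numeric(2)))
  if (anyDuplicated(round(pos, 6)))
    stop("helix positions must be distinct")
  start <- 1L
  parts <- list(); anns <- list()
  for (h in seq_along(specs)) {
    at <- idealHelix(specs[[h]], resno_start = start)
    parts[[h]] <- at
    anns[[h]] <- data.frame(chain = chain, helix_index = h,
                            start = start,
                            end = start + specs[[h]]$n - 1L,
                            stringsAsFactors = FALSE)
    start <- start + specs[[h]]$n + as.integer(gap)
  }
  atoms <- do.call(rbind, parts)
  atoms$chain <- chain
  atoms$insert <- ""
  atoms$het <- FALSE
  atoms$vdw <- assign_vdw(atoms$name, atoms$element, radii)
  atoms <- atoms[, c("name", "element", "x", "y", "z", "vdw",
                     "chain", "resno", "insert", "resid", "het")]
  structure_model <- new("StructureModel", atoms = atoms, chains = chain,
                         provenance = list(source = "synthetic bundle",
                                           model = 1L))
  # analytic truth from the construction (no axis fit, no file round trip)
  ca_centers <- t(vapply(seq_along(specs), function(h) {
    s <- specs[[h]]
    th <- deg2rad((seq_len(s$n) - 1) * s$twist + s$offset)
    c(s$position[1] + mean(s$radius * cos(th)),
      s$position[2] + mean(s$radius * sin(th)))
  }, numeric(2)))
  center <- colMeans(ca_centers[rep(seq_along(specs),
                                    vapply(specs, `[[`, 1L, "n")), ,
                                drop = FALSE])
  truth <- do.call(rbind, lapply(seq_along(specs), function(h) {
    s <- specs[[h]]
    first_ca <- c(s$position[1] + s$radius * cos(deg2rad(s$offset)),
                  s$position[2] + s$radius * sin(deg2rad(s$offset)))
    Fv <- first_ca - ca_centers[h, ]
    L <- ca_centers[h, ] - center
    ang <- mod360(rad2deg(atan2(L[2], L[1])) -
                  rad2deg(atan2(Fv[2], Fv[1])))
    data.frame(helix_index = h, truth_angle = ang)
  }))
  list(structure = structure_model,
       annotations = do.call(rbind, anns),
       truth = truth)
}

#' Periodic exposure profile with planted phase
#'
#' score_i = baseline + amplitude * cos((i - 1) * 100 - phase) + noise.
#' For a noiseless profile whose length is a multiple of 18 (a whole
#' number of helical-wheel turns), the moment direction equals the
#' planted phase exactly.  Values falling outside [0, 1] after noise are
#' clamped with a warning.
#'
#' @param n profile length.
#' @param phase planted phase, degrees.
#' @param baseline,amplitude profile shape; baseline +/- amplitude should
#'   stay within [0, 1].
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed RNG seed for the noise.
#' @return numeric scores in [0, 1].
#' @export
periodicRasa <- function(n, phase = 0, baseline = 0.25, amplitude = 0.25,
                         noise_sd = 0, seed = 1L) {
  if (n < 1) stop("profile length must be >= 1")
  if (baseline - amplitude < -1e-9 || baseline + amplitude > 1 + 1e-9)
    stop("baseline +/- amplitude must stay within [0, 1]")
  th <- (seq_len(n) - 1) * 100
  s <- baseline + amplitude * cos(deg2rad(th - phase))
  if (noise_sd > 0) {
    set.seed(seed)
    s <- s + stats::rnorm(n, 0, noise_sd)
  }
  if (any(s < 0 | s > 1)) {
    warning("profile values outside [0, 1] after noise; clamped")
    s <- clamp01(s)
  }
  s
}

#' Planted-signal training set for the support-vector models
#'
#' Builds a multi-chain dataset whose rASA targets follow a planted
#' helical wheel (periodic exposure with a per-chain phase) plus
#' optional Gaussian noise.  The first three feature columns are smooth
#' deterministic functions of the target (identity, square, square
#' root); the remaining columns are uniform noise, so the signal is
#' recoverable and leakage across chains is detectable.  Burial labels
#' follow the 5 percent threshold.
#'
#' @param n_chains number of chains (>= 2).
#' @param residues_per_chain residues per chain.
#' @param baseline,amplitude exposure wheel shape.
#' @param noise_sd Gaussian noise on the targets (default 0).
#' @param n_noise_features extra uninformative feature columns (default 7).
#' @param seed RNG seed.
#' @return a \linkS4class{DatasetSplit} (schema "synthetic-fv-1").
#' @export
synthTrainingSet <- function(n_chains, residues_per_chain = 36L,
                             baseline = 0.25, amplitude = 0.25,
                             noise_sd = 0, n_noise_features = 7L,
                             seed = 1L) {
  if (n_chains < 2) stop("need at least 2 chains")
  if (residues_per_chain < 18) stop("need at least 18 residues per chain")
  set.seed(seed)
  phases <- stats::runif(n_chains, 0, 360)
  rows <- lapply(seq_len(n_chains), function(c_i) {
    s <- suppressWarnings(
      periodicRasa(residues_per_chain, phase = phases[c_i],
                   baseline = baseline, amplitude = amplitude,
                   noise_sd = noise_sd, seed = seed + c_i))
    X <- cbind(f_id = s, f_sq = s^2, f_sqrt = sqrt(s),
               matrix(stats::runif(residues_per_chain * n_noise_features),
                      ncol = n_noise_features,
                      dimnames = list(NULL, paste0("noise", seq_len(n_noise_features)))))
    list(X = X, rasa = s, chain = rep(paste0("C", c_i), residues_per_chain))
  })
  X <- do.call(rbind, lapply(rows, `[[`, "X"))
  rasa <- unlist(lapply(rows, `[[`, "rasa"))
  chain <- unlist(lapply(rows, `[[`, "chain"))
  if (length(unique(classifyBurial(rasa))) < 2)
    stop("degenerate spec: planted wheel produces a single burial class")
  datasetSplit(X, rasa, chain = chain, schema_version = "synthetic-fv-1")
}
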