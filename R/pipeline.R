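#' Run configuration
#'
#' Collects the pipeline parameters; the defaults are the method's
#' published operating point (2.0 Angstrom probe, 5 percent burial
#' threshold, window 17, the cross-validation-optimal SVM/SVR
#' hyperparameters).
#'
#' @param probe_radius SASA probe radius, Angstrom.
#' @param n_points SASA sampling density.
#' @param burial_threshold rASA burial threshold.
#' @param window feature window length.
#' @param hyperparams model hyperparameters (\code{\link{tmHyperparams}}).
#' @param seed RNG seed.
#' @param radii,reference,properties optional pre-loaded tables
#'   (defaults: the bundled ones, loaded lazily).
#' @return list of class "tmexpo_config".
#' @export
tmConfig <- function(probe_radius = 2.0, n_points = 960L,
                     burial_threshold = 0.05, window = 17L,
                     hyperparams = tmHyperparams(), seed = 1L,
                     radii = NULL, reference = NULL, properties = NULL) {
  structure(list(probe_radius = probe_radius, n_points = as.integer(n_points),
                 burial_threshold = burial_threshold,
                 window = as.integer(window), hyperparams = hyperparams,
                 seed = as.integer(seed),
                 radii = radii %||% loadRadiiTable(),
                 reference = reference %||% loadReferenceTable(),
                 properties = properties %||% loadPropertyTables()),
            class = "tmexpo_config")
}

write_manifest <- function(outdir, config, inputs = character()) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    package = "tmexpo",
    version = as.character(utils::packageVersion("tmexpo")),
    config = list(probe_radius = config$probe_radius,
                  n_points = config$n_points,
                  burial_threshold = config$burial_threshold,
                  window = config$window,
                  hyperparams = config$hyperparams,
                  seed = config$seed),
    input_md5 = digests)
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Observe rASA and rotational angles from a structure
#'
#' The structure-side pipeline: compute accessible surface areas with
#' the lipid-mimicking probe, normalise to rASA and label burial per TM
#' residue, and derive each annotated helix's observed rotational angle
#' from the coordinates.
#'
#' @param structure a \linkS4class{StructureModel} or a PDB-format path.
#' @param annotations annotation data.frame or TSV path
#'   (\code{\link{readTMAnnotations}}).
#' @param config a \code{\link{tmConfig}}.
#' @param outdir optional output directory: writes residues.tsv,
#'   helices.tsv and a JSON run manifest.
#' @return list with \code{residues} (chain, resno, resname, asa, rasa,
#'   label, excluded) and \code{helices}
#'   (\code{\link{observedRotationAngles}} output).
#' @export
runObserve <- function(structure, annotations, config = tmConfig(),
                       outdir = NULL) {
  inputs <- character()
  if (is.character(structure)) {
    inputs <- c(inputs, structure)
    structure <- readStructure(structure, radii = config$radii)
  }
  if (is.character(annotations)) {
    inputs <- c(inputs, annotations)
    annotations <- readTMAnnotations(annotations)
  }
  asa <- computeASA(structure, probe_radius = config$probe_radius,
                    n_points = config$n_points)
  if (nrow(annotations)) {
    helices <- extractHelices(structure, annotations)
    profs <- lapply(helices, rasaProfile, asa = asa,
                    reference = config$reference,
                    threshold = config$burial_threshold)
    residues <- do.call(rbind, lapply(profs, function(p) {
      r <- p@helix@residues
      data.frame(chain = p@helix@chain, resno = r$resno, resname = r$resid,
                 asa = NA_real_,
                 rasa = p@rasa, label = p@labels, excluded = p@excluded,
                 stringsAsFactors = FALSE)
    }))
    akey <- residue_key(asa@perResidue$chain, asa@perResidue$resno,
                        asa@perResidue$insert)
    rkey <- residue_key(residues$chain, residues$resno, "")
    residues$asa <- asa@perResidue$asa[match(rkey, akey)]
    helix_table <- observedRotationAngles(structure, annotations)
  } else {
    residues <- data.frame(chain = asa@perResidue$chain,
                           resno = asa@perResidue$resno,
                           resname = asa@perResidue$resid,
                           asa = asa@perResidue$asa,
                           rasa = NA_real_, label = NA_character_,
                           excluded = NA, stringsAsFactors = FALSE)
    helix_table <- data.frame(chain = character(), helix_index = integer(),
                              n_residues = integer(),
                              observed_angle_deg = numeric(),
                              first_residue = integer(),
                              fallback = logical())
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(residues, file.path(outdir, "residues.tsv"))
    write_tsv(helix_table, file.path(outdir, "helices.tsv"))
    write_manifest(outdir, config, inputs)
  }
  list(residues = residues, helices = helix_table)
}

#' Predict rASA, burial and rotational angles from sequence
#'
#' The sequence-side workflow: encode each TM residue over a sliding
#' window, predict rASA with the regressor (clamped to [0, 1]) and
#' burial with the classifier, then per helix take the rASA moment
#' direction as the predicted rotational angle.  A helix whose moment
#' length is below the undefined-direction epsilon gets an NA angle and
#' a warning rather than an error.
#'
#' @param context chain context from \code{\link{chainContext}}.
#' @param model a trained \linkS4class{TMexpoModel}.
#' @param annotations data.frame with \code{helix_index}, \code{start},
#'   \code{end} giving helix spans as 1-based sequence positions.
#' @param config a \code{\link{tmConfig}}.
#' @param outdir optional output directory (TSVs + manifest).
#' @return list with \code{residues} (position, aa, rasa, label) and
#'   \code{helices} (helix_index, n, x, y, moment_length,
#'   predicted_angle_deg).
#' @export
runPredictPipeline <- function(context, model, annotations,
                               config = tmConfig(), outdir = NULL) {
  positions <- sort(unique(unlist(
    lapply(seq_len(nrow(annotations)),
           function(i) annotations$start[i]:annotations$end[i]))))
  X <- encodeChain(context, positions, window = config$window)
  rasa <- predictRasa(model, X)
  labels <- predictBurial(model, X)
  residues <- data.frame(position = positions,
                         aa = strsplit(context$sequence, "")[[1]][positions],
                         rasa = rasa, label = labels,
                         stringsAsFactors = FALSE)
  helices <- do.call(rbind, lapply(seq_len(nrow(annotations)), function(i) {
    span <- annotations$start[i]:annotations$end[i]
    s <- rasa[match(span, positions)]
    mom <- predictRotation(s)
    if (is.na(mom@theta))
      warning("helix ", annotations$helix_index[i],
              ": moment length ", format(mom@length),
              " below epsilon; direction undefined")
    data.frame(helix_index = annotations$helix_index[i], n = mom@n,
               x = mom@x, y = mom@y, moment_length = mom@length,
               predicted_angle_deg = mom@theta, stringsAsFactors = FALSE)
  }))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(residues, file.path(outdir, "predicted_residues.tsv"))
    write_tsv(helices, file.path(outdir, "predicted_helices.tsv"))
    write_manifest(outdir, config)
  }
  list(residues = residues, helices = helices)
}

#' Recompute the bundled rotational-angle benchmark
#'
#' Re-derives, from the bundled benchmark's observed/predicted angle
#' pairs, every per-helix angular error, the per-chain MAAE, the global
#' MAAE and the error-distribution counts (< 10 degrees, <= 43 degrees,
#' >= 100.29 degrees), and compares each recomputed value with the
#' published one.
#'
#' @param tolerance agreement tolerance against the published values,
#'   degrees (default 0.01, the table's printed precision).
#' @return list with \code{table} (per-helix, incl. recomputed error),
#'   \code{per_chain} (chain, maae, published, delta), \code{maae}
#'   (global), \code{summary} (threshold counts), \code{max_error_delta},
#'   \code{max_chain_delta}, \code{report} (an \linkS4class{EvalReport}).
#' @export
runAngleBenchmark <- function(tolerance = 0.01) {
  d <- benchmarkAngles()
  d$error_recomputed <- angularError(d$observed, d$predicted)
  d$error_delta <- d$error_recomputed - d$error
  per_chain <- do.call(rbind, lapply(split(d, d$chain), function(s) {
    data.frame(chain = s$chain[1],
               n_helices = nrow(s),
               maae = mean(s$error_recomputed),
               published = s$chain_maae[1], stringsAsFactors = FALSE)
  }))
  per_chain$delta <- per_chain$maae - per_chain$published
  rownames(per_chain) <- NULL
  summary <- errorPercentileSummary(d$observed, d$predicted,
                                    thresholds = c(10, 43, 100.29),
                                    comparator = c("lt", "le", "ge"))
  list(table = d, per_chain = per_chain,
       maae = mean(d$error_recomputed), summary = summary,
       max_error_delta = max(abs(d$error_delta)),
       max_chain_delta = max(abs(per_chain$delta)),
       within_tolerance = max(abs(d$error_delta)) <= tolerance + 1e-9 &&
         max(abs(per_chain$delta)) <= tolerance + 1e-9,
       report = evalReport(angles_obs = d$observed,
                           angles_pred = d$predicted))
}
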