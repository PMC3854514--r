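#' Model hyperparameters
#'
#' Defaults are the cross-validation optima of the method: the burial
#' classifier (C-SVC, RBF kernel) uses cost 2^1 and gamma 2^-4; the rASA
#' regressor (epsilon-SVR, RBF kernel) uses cost 2^-1, gamma 2^-5,
#' epsilon-insensitive loss width 1e-3 and termination tolerance 1e-2.
#'
#' @param class_cost,class_gamma classifier cost and kernel width.
#' @param reg_cost,reg_gamma regressor cost and kernel width.
#' @param reg_epsilon epsilon of the insensitive loss.
#' @param reg_tolerance termination tolerance.
#' @return list of hyperparameters.
#' @export
tmHyperparams <- function(class_cost = 2^1, class_gamma = 2^-4,
                          reg_cost = 2^-1, reg_gamma = 2^-5,
                          reg_epsilon = 1e-3, reg_tolerance = 1e-2) {
  list(class_cost = class_cost, class_gamma = class_gamma,
       reg_cost = reg_cost, reg_gamma = reg_gamma,
       reg_epsilon = reg_epsilon, reg_tolerance = reg_tolerance)
}

#' Assemble a DatasetSplit
#'
#' @param features numeric feature matrix (rows = residues).
#' @param rasa rASA targets in [0, 1].
#' @param labels burial labels "B"/"E" (default: derived from
#'   \code{rasa} at the 5 percent threshold).
#' @param chain chain id per row.
#' @param excluded optional logical mask; masked rows are dropped.
#' @param schema_version feature-layout version of the rows.
#' @return a \linkS4class{DatasetSplit}.
#' @export
datasetSplit <- function(features, rasa, labels = classifyBurial(rasa),
                         chain, excluded = NULL,
                         schema_version = attr(features, "schema_version") %||%
                           FEATURE_SCHEMA_VERSION) {
  features <- as.matrix(features)
  if (!is.null(excluded)) {
    keep <- !excluded
    features <- features[keep, , drop = FALSE]
    rasa <- rasa[keep]; labels <- labels[keep]; chain <- chain[keep]
  }
  new("DatasetSplit", features = features, rasa = as.numeric(rasa),
      labels = as.character(labels), chain = as.character(chain),
      schemaVersion = schema_version)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_schema <- function(model_version, data_version) {
  if (!identical(model_version, data_version))
    stop("feature schema mismatch: model '", model_version,
         "' vs vectors '", data_version, "'; re-encode with the matching ",
         "feature layout")
}

#' Train the burial classifier and rASA regressor
#'
#' Fits a C-SVC (burial status, exposed "E" vs buried "B") and an
#' epsilon-SVR (real-valued rASA) with RBF kernels via LIBSVM (e1071).
#' Features are expected pre-normalised to [0, 1] by the encoder, so no
#' internal rescaling is applied.  Training is deterministic for fixed
#' data order and seed.
#'
#' @param train a \linkS4class{DatasetSplit}.
#' @param hyperparams list from \code{\link{tmHyperparams}}.
#' @param seed RNG seed recorded in the bundle (default 1).
#' @return a \linkS4class{TMexpoModel}.
#' @export
trainModels <- function(train, hyperparams = tmHyperparams(), seed = 1L) {
  if (length(unique(train@labels)) < 2)
    stop("single-class training set: cannot fit the burial classifier")
  set.seed(seed)
  cls <- e1071::svm(x = train@features,
                    y = factor(train@labels, levels = c("B", "E")),
                    type = "C-classification", kernel = "radial",
                    cost = hyperparams$class_cost,
                    gamma = hyperparams$class_gamma, scale = FALSE)
  reg <- e1071::svm(x = train@features, y = train@rasa,
                    type = "eps-regression", kernel = "radial",
                    cost = hyperparams$reg_cost,
                    gamma = hyperparams$reg_gamma,
                    epsilon = hyperparams$reg_epsilon,
                    tolerance = hyperparams$reg_tolerance, scale = FALSE)
  new("TMexpoModel", classifier = cls, regressor = reg,
      hyperparams = hyperparams, schemaVersion = train@schemaVersion,
      meta = list(chains = unique(train@chain), n = nrow(train@features),
                  date = format(Sys.Date()), seed = seed))
}

#' Predict rASA
#'
#' Raw regressor outputs are clamped into [0, 1] (rASA lives in that
#' interval; the clamp is the documented post-processing of the method).
#'
#' @param bundle a \linkS4class{TMexpoModel}.
#' @param vectors feature matrix with matching schema.
#' @return rASA fractions in [0, 1].
#' @export
predictRasa <- function(bundle, vectors) {
  vectors <- as.matrix(vectors)
  if (!nrow(vectors)) return(numeric(0))
  check_schema(bundle@schemaVersion,
               attr(vectors, "schema_version") %||% bundle@schemaVersion)
  clamp01(as.numeric(stats::predict(bundle@regressor, vectors)))
}

#' Predict burial status
#'
#' @param bundle a \linkS4class{TMexpoModel}.
#' @param vectors feature matrix with matching schema.
#' @return character labels "B"/"E".
#' @export
predictBurial <- function(bundle, vectors) {
  vectors <- as.matrix(vectors)
  if (!nrow(vectors)) return(character(0))
  check_schema(bundle@schemaVersion,
               attr(vectors, "schema_version") %||% bundle@schemaVersion)
  as.character(stats::predict(bundle@classifier, vectors))
}

#' Denormalise rASA back to ASA
#'
#' Multiplies predicted rASA by the residue's Gly-X-Gly reference area.
#'
#' @param rasa rASA fraction(s).
#' @param residue_name 3-letter residue code(s).
#' @param reference reference table.
#' @return ASA in Angstrom^2.
#' @export
asaFromRasa <- function(rasa, residue_name, reference = loadReferenceTable()) {
  residue_name <- toupper(residue_name)
  unknown <- setdiff(unique(residue_name), names(reference))
  if (length(unknown))
    stop("no reference ASA for residue(s): ", paste(unknown, collapse = ", "))
  unname(rasa * reference[residue_name])
}

#' Chain-wise leave-one-out cross-validation
#'
#' One fold per chain: models trained on all other chains predict the
#' held-out chain; a leakage assertion verifies the held-out residues
#' never enter that fold's training set.  Concatenated predictions are
#' summarised by \code{\link{evalReport}}.
#'
#' @param dataset a \linkS4class{DatasetSplit} with >= 2 chains.
#' @param hyperparams list from \code{\link{tmHyperparams}}.
#' @param seed RNG seed (default 1).
#' @return list with \code{predictions} (data.frame: chain, observed
#'   rASA, predicted rASA, observed/predicted labels) and \code{report}
#'   (an \linkS4class{EvalReport}).
#' @export
chainwiseLOOCV <- function(dataset, hyperparams = tmHyperparams(), seed = 1L) {
  chains <- unique(dataset@chain)
  if (length(chains) < 2) stop("chain-wise LOOCV needs at least 2 chains")
  preds <- lapply(chains, function(ch) {
    test_idx <- which(dataset@chain == ch)
    train_idx <- which(dataset@chain != ch)
    stopifnot(length(intersect(test_idx, train_idx)) == 0)  # leakage check
    tr <- new("DatasetSplit",
              features = dataset@features[train_idx, , drop = FALSE],
              rasa = dataset@rasa[train_idx],
              labels = dataset@labels[train_idx],
              chain = dataset@chain[train_idx],
              schemaVersion = dataset@schemaVersion)
    fit <- trainModels(tr, hyperparams, seed = seed)
    X <- dataset@features[test_idx, , drop = FALSE]
    attr(X, "schema_version") <- dataset@schemaVersion
    data.frame(chain = ch,
               observed = dataset@rasa[test_idx],
               predicted = predictRasa(fit, X),
               observed_label = dataset@labels[test_idx],
               predicted_label = predictBurial(fit, X),
               stringsAsFactors = FALSE)
  })
  pred <- do.call(rbind, preds)
  report <- evalReport(rasa_obs = pred$observed, rasa_pred = pred$predicted,
                       labels_obs = pred$observed_label,
                       labels_pred = pred$predicted_label)
  list(predictions = pred, report = report)
}

#' @describeIn trainModels bundle display.
#' @param object a TMexpoModel.
#' @export
setMethod("show", "TMexpoModel", function(object) {
  h <- object@hyperparams
  cat("TMexpoModel  schema:", object@schemaVersion, "\n")
  cat(sprintf("  C-SVC: cost=%g gamma=%g   eps-SVR: cost=%g gamma=%g p=%g e=%g\n",
              h$class_cost, h$class_gamma, h$reg_cost, h$reg_gamma,
              h$reg_epsilon, h$reg_tolerance))
  cat("  trained on", object@meta$n, "residues /",
      length(object@meta$chains), "chains\n")
})
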