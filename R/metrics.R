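#' Absolute angular error between two rotational angles
#'
#' Circular difference in degrees: |x - y| if at most 180, otherwise
#' 360 - |x - y|.  Symmetric, in [0, 180]; inputs outside [0, 360) are
#' reduced modulo 360 first.
#'
#' @param x,y angles in degrees (vectorised).
#' @return error(s) in degrees, [0, 180].
#' @export
angularError <- function(x, y) {
  d <- abs(mod360(x) - mod360(y))
  ifelse(d > 180, 360 - d, d)
}

#' Mean absolute angular error
#'
#' @param observed,predicted paired angle vectors in degrees.
#' @return MAAE in degrees.
#' @export
maae <- function(observed, predicted) {
  if (!length(observed)) stop("MAAE of an empty pair list")
  if (length(observed) != length(predicted)) stop("length mismatch")
  mean(angularError(observed, predicted))
}

#' Mean absolute error of rASA prediction
#' @param predicted,observed paired rASA vectors.
#' @return MAE (fraction).
#' @export
maeRasa <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (!length(predicted)) stop("empty input")
  mean(abs(predicted - observed))
}

#' Root mean squared error of rASA prediction
#' @param predicted,observed paired rASA vectors.
#' @return RMSE (fraction).
#' @export
rmseRasa <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (!length(predicted)) stop("empty input")
  sqrt(mean((predicted - observed)^2))
}

#' Confusion counts for burial classification
#'
#' Exposed ("E") is the positive class.
#'
#' @param observed,predicted label vectors ("B"/"E").
#' @return list with TP, FP, TN, FN.
#' @export
confusionCounts <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  list(TP = sum(observed == "E" & predicted == "E"),
       FP = sum(observed == "B" & predicted == "E"),
       TN = sum(observed == "B" & predicted == "B"),
       FN = sum(observed == "E" & predicted == "B"))
}

#' Classification metrics from confusion counts
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FN)(TN+FP)), defined
#' as 0 when any denominator factor is zero (documented convention).
#' Accuracy, sensitivity, specificity and precision are reported as
#' percentages; a ratio with zero denominator is NA (never silently 0).
#'
#' @param counts list with TP, FP, TN, FN.
#' @return list with mcc, accuracy, sensitivity, specificity, precision.
#' @export
confusionMetrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  if (any(c(TP, FP, TN, FN) < 0)) stop("negative confusion count")
  total <- TP + FP + TN + FN
  if (total == 0) stop("empty confusion table")
  denom <- as.numeric(TP + FP) * (TP + FN) * (TN + FN) * (TN + FP)
  mcc <- if (denom == 0) 0 else
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(denom)
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  list(mcc = mcc,
       accuracy = rate(TP + TN, total),
       sensitivity = rate(TP, TP + FN),
       specificity = rate(TN, TN + FP),
       precision = rate(TP, TP + FP))
}

#' Pearson correlation coefficient
#'
#' @param a,b paired numeric vectors (length >= 2, non-constant).
#' @return correlation in [-1, 1], or NA for a constant vector.
#' @export
pearsonCC <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 2) stop("PCC needs at least 2 pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Angular-error distribution summary
#'
#' Counts and percentages of helix pairs whose angular error satisfies
#' each threshold bound.  Comparisons at printed thresholds use a tiny
#' numeric guard (1e-9 degrees) so a pair whose error equals a threshold
#' to within floating-point round-off is counted on the inclusive side.
#'
#' @param observed,predicted paired angle vectors in degrees.
#' @param thresholds numeric thresholds.
#' @param comparator one of "lt" (strict <), "le" (<=), "ge" (>=) per
#'   threshold (recycled).
#' @return data.frame: threshold, comparator, count, percent.
#' @export
errorPercentileSummary <- function(observed, predicted,
                                   thresholds = c(10, 43, 100.29),
                                   comparator = c("lt", "le", "ge")) {
  e <- angularError(observed, predicted)
  comparator <- rep(comparator, length.out = length(thresholds))
  eps <- 1e-9
  cnt <- mapply(function(t, cmp) {
    switch(cmp,
           lt = sum(e < t - eps),
           le = sum(e <= t + eps),
           ge = sum(e >= t - eps),
           stop("comparator must be lt, le or ge"))
  }, thresholds, comparator)
  data.frame(threshold = thresholds, comparator = comparator,
             count = as.integer(cnt),
             percent = 100 * cnt / length(e))
}

#' Build an evaluation report
#'
#' Aggregates whichever paired quantities are supplied: rotational
#' angles (degrees) give MAAE; rASA values give MAE, RMSE and PCC;
#' burial labels give MCC, accuracy, sensitivity, specificity and
#' precision.  Missing parts are reported as NA.
#'
#' @param angles_obs,angles_pred paired rotational angles, degrees.
#' @param rasa_obs,rasa_pred paired rASA fractions.
#' @param labels_obs,labels_pred paired burial labels.
#' @return an \linkS4class{EvalReport}.
#' @export
evalReport <- function(angles_obs = NULL, angles_pred = NULL,
                       rasa_obs = NULL, rasa_pred = NULL,
                       labels_obs = NULL, labels_pred = NULL) {
  m <- list(maae = NA_real_, mae = NA_real_, rmse = NA_real_,
            pcc = NA_real_, mcc = NA_real_, accuracy = NA_real_,
            sensitivity = NA_real_, specificity = NA_real_,
            precision = NA_real_)
  nh <- 0L; nr <- 0L
  if (!is.null(angles_obs)) {
    m$maae <- maae(angles_obs, angles_pred)
    nh <- length(angles_obs)
  }
  if (!is.null(rasa_obs)) {
    m$mae <- maeRasa(rasa_pred, rasa_obs)
    m$rmse <- rmseRasa(rasa_pred, rasa_obs)
    m$pcc <- pearsonCC(rasa_pred, rasa_obs)
    nr <- length(rasa_obs)
  }
  if (!is.null(labels_obs)) {
    cm <- confusionMetrics(confusionCounts(labels_obs, labels_pred))
    m[names(cm)] <- cm
    nr <- max(nr, length(labels_obs))
  }
  new("EvalReport", maae = m$maae, mae = m$mae, rmse = m$rmse,
      pcc = m$pcc, mcc = m$mcc, accuracy = m$accuracy,
      sensitivity = m$sensitivity, specificity = m$specificity,
      precision = m$precision, nHelices = nh, nResidues = as.integer(nr))
}

# Display rounding: 2 decimals, half-up (matching the field's reporting
# style); internal values keep full precision.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @describeIn evalReport report display (2-decimal, half-up).
#' @param object an EvalReport.
#' @export
setMethod("show", "EvalReport", function(object) {
  f <- function(x, unit = "") if (is.na(x)) "NA" else
    paste0(format(round_half_up(x), nsmall = 2), unit)
  cat("EvalReport  (", object@nHelices, "helices,", object@nResidues,
      "residues )\n")
  cat("  MAAE:", f(object@maae, " deg"),
      " MAE:", f(object@mae), " RMSE:", f(object@rmse),
      " PCC:", f(object@pcc), "\n")
  cat("  MCC:", f(object@mcc), " Acc:", f(object@accuracy, "%"),
      " Sens:", f(object@sensitivity, "%"),
      " Spec:", f(object@specificity, "%"),
      " Prec:", f(object@precision, "%"), "\n")
})
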