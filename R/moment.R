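#' rASA moment vector
#'
#' Places residue i of a helix at the helical-wheel angle
#' theta_i = (i - 1) * 100 degrees and sums the per-residue scores as a
#' 2-D vector: x = sum s_i cos(theta_i), y = sum s_i sin(theta_i).
#'
#' @param scores ordered per-residue scores (typically rASA fractions).
#' @param twist angular spacing per residue in degrees (default 100).
#' @return named numeric c(x, y).
#' @export
momentVector <- function(scores, twist = 100) {
  if (!length(scores)) stop("empty score profile")
  th <- deg2rad((seq_along(scores) - 1) * twist)
  c(x = sum(scores * cos(th)), y = sum(scores * sin(th)))
}

#' Moment direction
#'
#' Direction of the moment vector in degrees: gamma = arccos(x / |M|),
#' theta = gamma if y >= 0 else 360 - gamma (equivalently the
#' two-argument arctangent mapped to [0, 360)).  Undefined when |M| is
#' below \code{eps}, since the arccosine divides by |M|.
#'
#' @param x,y moment vector components.
#' @param eps undefined-direction threshold on |M| (default 1e-9).
#' @return theta in degrees, [0, 360).
#' @export
momentDirection <- function(x, y, eps = 1e-9) {
  m <- sqrt(x^2 + y^2)
  if (m <= eps)
    stop("moment direction undefined: |M| = ", format(m), " <= ", eps)
  gamma <- rad2deg(acos(max(-1, min(1, x / m))))
  mod360(if (y >= 0) gamma else 360 - gamma)
}

#' Predicted rotational angle from a score profile
#'
#' Composes the moment vector, its length and its direction; the
#' direction is taken as the predicted rotational angle (lipid-facing
#' direction) of the helix.  An optional post-processing hook over the
#' score profile is exposed (identity by default).
#'
#' @param scores ordered per-residue scores, or a
#'   \linkS4class{RasaProfile} (its rASA values are used; NA treated as 0).
#' @param eps undefined-direction threshold (default 1e-9).
#' @param post_process function applied to the score vector before the
#'   moment computation; default identity.
#' @return a \linkS4class{MomentResult}; \code{theta} is NA (not an
#'   error) when |M| <= eps so pipelines can mark the helix undefined.
#' @export
predictRotation <- function(scores, eps = 1e-9, post_process = identity) {
  if (is(scores, "RasaProfile")) {
    s <- scores@rasa
    s[is.na(s)] <- 0
  } else s <- as.numeric(scores)
  if (!length(s)) stop("empty score profile")
  s <- post_process(s)
  xy <- momentVector(s)
  m <- sqrt(sum(xy^2))
  theta <- if (m <= eps) NA_real_ else momentDirection(xy["x"], xy["y"], eps)
  new("MomentResult", x = unname(xy["x"]), y = unname(xy["y"]),
      length = m, theta = unname(theta), n = length(s))
}

#' Score a sequence with a named per-residue scale
#'
#' Maps a 1-letter sequence to per-residue values of a hydrophobicity or
#' propensity scale, for moment-based baseline predictions.
#'
#' @param sequence 1-letter amino-acid string.
#' @param scale named numeric vector keyed by 3-letter codes (see
#'   \code{\link{loadScale}}).
#' @return numeric score vector, one value per residue.
#' @export
scaleScores <- function(sequence, scale = loadScale("eisenberg")) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  res3 <- aa123(aa)
  if (anyNA(res3))
    stop("unknown residue(s) in sequence: ",
         paste(unique(aa[is.na(res3)]), collapse = ", "))
  missing <- setdiff(unique(res3), names(scale))
  if (length(missing))
    stop("scale lacks residue(s): ", paste(missing, collapse = ", "))
  unname(scale[res3])
}

#' Moment direction accessor
#' @param x a \linkS4class{MomentResult}.
#' @return theta in degrees (NA if undefined).
#' @export
momentTheta <- function(x) x@theta

#' Moment length accessor
#' @param x a \linkS4class{MomentResult}.
#' @return |M|.
#' @export
momentLength <- function(x) x@length

#' @describeIn predictRotation moment display.
#' @param object a MomentResult.
#' @export
setMethod("show", "MomentResult", function(object) {
  cat(sprintf("MomentResult: n=%d  M=(%.4f, %.4f)  |M|=%.4f  theta=%s\n",
              object@n, object@x, object@y, object@length,
              if (is.na(object@theta)) "undefined"
              else sprintf("%.2f deg", object@theta)))
})
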