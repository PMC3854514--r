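# Feature-vector layout version.  Models refuse vectors produced under a
# different schema, since the layout order is a package choice.
FEATURE_SCHEMA_VERSION <- "tmexpo-fv-1"

# Per-position feature names: 20 PSSM sigmoids (fixed amino-acid order),
# conservation, then the seven property encodings.  28 per position.
PSSM_AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
POSITION_FEATURES <- c(paste0("pssm_", PSSM_AA_ORDER), "conservation",
                       "volume", "polarity", "charge", "contact",
                       "energy", "amphiphilicity", "turn")

#' Sigmoid feature encoding
#'
#' The squashing used for PSSM entries, polarity and insertion free
#' energy is 1 - 1/(1 + exp(-v)); amphiphilicity uses the opposite sign
#' in the exponent, 1 - 1/(1 + exp(+v)).  Both map any finite value into
#' (0, 1) with 0 -> 0.5.
#'
#' @param value numeric value(s).
#' @param sign_convention "minus" (default; PSSM/polarity/energy) or
#'   "plus" (amphiphilicity).
#' @return fraction(s) in (0, 1).
#' @export
sigmoidEncode <- function(value, sign_convention = c("minus", "plus")) {
  sign_convention <- match.arg(sign_convention)
  e <- if (sign_convention == "minus") exp(-value) else exp(value)
  1 - 1 / (1 + e)
}

#' Linear max-anchored encoding
#'
#' Divides a property value by the scale's maximum (e.g. volume by
#' 237.2, contact propensity by 1.43, turn propensity by 2.7).  Results
#' outside [0, 1] are clamped with a warning.
#'
#' @param value numeric value(s).
#' @param anchor the scale maximum (> 0).
#' @return fraction(s) in [0, 1].
#' @export
linearEncode <- function(value, anchor) {
  if (anchor <= 0) stop("anchor must be positive")
  r <- value / anchor
  if (any(r < 0 | r > 1, na.rm = TRUE)) {
    warning("linear-encoded value outside [0, 1]; clamped")
    r <- clamp01(r)
  }
  r
}

#' Charge-class encoding
#'
#' Positively charged residues map to 1, neutral to 0.5, negatively
#' charged to 0, per the bundled charge-class column (Klein convention:
#' K/R/H positive, D/E negative).
#'
#' @param residue 3-letter residue code(s).
#' @param tables property tables from \code{\link{loadPropertyTables}}.
#' @return value(s) in \{0, 0.5, 1\}.
#' @export
chargeEncode <- function(residue, tables = loadPropertyTables()) {
  residue <- toupper(residue)
  out <- tables[residue, "charge"]
  if (anyNA(out)) {
    warning("nonstandard residue(s) encoded as neutral charge: ",
            paste(unique(residue[is.na(out)]), collapse = ", "))
    out[is.na(out)] <- 0.5
  }
  unname(out)
}

# BLOSUM62-style background amino-acid frequencies (normalised at use).
BG_FREQ <- c(A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025,
             Q = 0.034, E = 0.054, G = 0.074, H = 0.026, I = 0.068,
             L = 0.099, K = 0.058, M = 0.025, F = 0.047, P = 0.039,
             S = 0.057, T = 0.051, W = 0.013, Y = 0.032, V = 0.073)

#' Column conservation by Jensen-Shannon divergence
#'
#' Raw per-column conservation scores of an aligned set of sequences:
#' the Jensen-Shannon divergence (log base 2, so the score is already in
#' [0, 1]) between the column's amino-acid distribution and a background
#' distribution.  No window smoothing and no Z-score transformation are
#' applied.  Gaps are ignored within a column; an all-gap column scores
#' 0.
#'
#' @param msa aligned sequences: a character vector of equal-length
#'   strings or a Biostrings AAStringSet.
#' @param positions column indices to score (default: all columns).
#' @param background named background frequencies over the 20 standard
#'   residues (default: BLOSUM-style frequencies).
#' @return numeric scores in [0, 1], one per position.
#' @export
conservationScores <- function(msa, positions = NULL, background = BG_FREQ) {
  if (inherits(msa, "AAStringSet")) msa <- as.character(msa)
  msa <- toupper(msa)
  if (!length(msa)) stop("empty alignment")
  L <- unique(nchar(msa))
  if (length(L) != 1) stop("sequences are not aligned (unequal lengths)")
  if (is.null(positions)) positions <- seq_len(L)
  q <- background[AA1] / sum(background[AA1])
  mat <- do.call(rbind, strsplit(msa, ""))
  vapply(positions, function(j) {
    col <- mat[, j]
    col <- col[col %in% AA1]
    if (!length(col)) return(0)
    p <- tabulate(match(col, AA1), nbins = 20) / length(col)
    m <- (p + q) / 2
    kl <- function(a, b) {
      nz <- a > 0
      sum(a[nz] * log2(a[nz] / b[nz]))
    }
    0.5 * kl(p, m) + 0.5 * kl(q, m)
  }, numeric(1))
}

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the standard 20-column log-odds block of a PSI-BLAST ASCII
#' PSSM file (the first 20 numeric columns after the residue).
#'
#' @param path PSSM file.
#' @return list with \code{scores} (n x 20 matrix, columns in
#'   A R N D C Q E G H I L K M F P S T W Y V order) and \code{sequence}
#'   (query 1-letter string).
#' @export
readPSSM <- function(path) {
  lines <- readLines(path)
  toks <- lapply(strsplit(trimws(lines), "\\s+"), function(x) x[x != ""])
  is_data <- vapply(toks, function(x) {
    length(x) >= 22 && grepl("^[0-9]+$", x[1]) && x[2] %in% AA1
  }, logical(1))
  if (!any(is_data)) stop("no PSSM data rows found in ", path)
  rows <- toks[is_data]
  scores <- t(vapply(rows, function(x) as.numeric(x[3:22]), numeric(20)))
  colnames(scores) <- PSSM_AA_ORDER
  if (any(!is.finite(scores))) stop("non-numeric PSSM entry in ", path)
  list(scores = scores,
       sequence = paste(vapply(rows, `[`, "", 2), collapse = ""))
}

#' Chain context for the feature encoder
#'
#' Bundles everything the window encoder needs for one chain: sequence,
#' PSSM log-odds and (optionally) per-position conservation scores.
#' With \code{conservation = NULL} and an MSA supplied, conservation is
#' computed here; with neither, all positions get the neutral value 0.5.
#'
#' @param sequence 1-letter chain sequence.
#' @param pssm n x 20 PSSM log-odds matrix (rows = positions, columns in
#'   the standard A..V order); NULL means all-zero (sigmoid-neutral).
#' @param conservation numeric per-position scores in [0, 1], or NULL.
#' @param msa aligned sequences for conservation (used when
#'   \code{conservation} is NULL).
#' @param tables property tables.
#' @return list of class "tmexpo_context".
#' @export
chainContext <- function(sequence, pssm = NULL, conservation = NULL,
                         msa = NULL, tables = loadPropertyTables()) {
  n <- nchar(sequence)
  if (is.null(pssm)) pssm <- matrix(0, n, 20, dimnames = list(NULL, PSSM_AA_ORDER))
  pssm <- as.matrix(pssm)
  if (nrow(pssm) != n || ncol(pssm) != 20)
    stop("PSSM must have one 20-column row per residue (missing PSSM rows?)")
  if (is.null(conservation)) {
    conservation <- if (!is.null(msa)) conservationScores(msa) else rep(0.5, n)
  }
  if (length(conservation) != n)
    stop("conservation length differs from sequence length")
  structure(list(sequence = toupper(sequence), pssm = pssm,
                 conservation = clamp01(conservation), tables = tables),
            class = "tmexpo_context")
}

# Encode one existing position into its 28 per-position features.
encode_position <- function(context, pos) {
  aa <- substr(context$sequence, pos, pos)
  res3 <- aa123(aa)
  tb <- context$tables
  if (is.na(res3) || !(res3 %in% rownames(tb)))
    stop("cannot encode nonstandard residue '", aa, "' at position ", pos)
  p <- tb[res3, ]
  c(sigmoidEncode(context$pssm[pos, ]),
    context$conservation[pos],
    suppressWarnings(linearEncode(p$volume, 237.2)),
    sigmoidEncode(p$polarity),
    p$charge,
    suppressWarnings(linearEncode(p$contact, 1.43)),
    sigmoidEncode(p$energy),
    sigmoidEncode(p$amphiphilicity, "plus"),
    suppressWarnings(linearEncode(p$turn, 2.7)))
}

# Fill values for window positions outside the chain: 0.5 everywhere
# except charge, interhelical contact propensity and volume, which are 0.
padding_values <- function() {
  v <- rep(0.5, length(POSITION_FEATURES))
  names(v) <- POSITION_FEATURES
  v[c("volume", "charge", "contact")] <- 0
  v
}

#' Encode a 17-residue sliding window
#'
#' Builds the fixed-layout feature vector for the residue at
#' \code{center}: 28 features for each of the 17 window positions
#' (20 sigmoid-squashed PSSM entries, conservation, volume, polarity,
#' charge class, contact propensity, insertion-energy sigmoid,
#' amphiphilicity sigmoid, turn propensity), 476 values in total, each
#' in [0, 1].  Window positions beyond the chain ends are padded with
#' 0.5, except charge, contact propensity and volume which are padded
#' with 0.
#'
#' @param context a chain context from \code{\link{chainContext}}.
#' @param center 1-based residue position.
#' @param window window length (odd; default 17).
#' @return named numeric vector with attribute \code{schema_version}.
#' @export
encodeWindow <- function(context, center, window = 17L) {
  if (window %% 2 == 0) stop("window length must be odd")
  n <- nchar(context$sequence)
  if (center < 1 || center > n) stop("center outside the chain")
  half <- (window - 1L) %/% 2L
  pad <- padding_values()
  blocks <- lapply((center - half):(center + half), function(pos) {
    if (pos < 1 || pos > n) pad else
      stats::setNames(encode_position(context, pos), POSITION_FEATURES)
  })
  v <- unlist(lapply(seq_along(blocks), function(k)
    stats::setNames(blocks[[k]],
                    paste0("p", k, "_", POSITION_FEATURES))))
  stopifnot(length(v) == window * length(POSITION_FEATURES))
  attr(v, "schema_version") <- FEATURE_SCHEMA_VERSION
  v
}

#' Encode every position of a chain
#'
#' @param context a chain context.
#' @param positions positions to encode (default all).
#' @param window window length (default 17).
#' @return feature matrix (rows = positions) with attribute
#'   \code{schema_version}.
#' @export
encodeChain <- function(context, positions = NULL, window = 17L) {
  n <- nchar(context$sequence)
  if (is.null(positions)) positions <- seq_len(n)
  m <- t(vapply(positions, function(i) encodeWindow(context, i, window),
                numeric(window * length(POSITION_FEATURES))))
  attr(m, "schema_version") <- FEATURE_SCHEMA_VERSION
  m
}

#' Read a FASTA multiple sequence alignment
#'
#' Thin wrapper over Biostrings for aligned amino-acid FASTA input.
#'
#' @param path FASTA file of aligned sequences.
#' @return character vector of aligned sequences.
#' @export
readMSA <- function(path) {
  as.character(Biostrings::readAAStringSet(path))
}
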