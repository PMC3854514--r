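# Internal numeric helpers.  Degrees are the working unit everywhere;
# conversion to radians is confined to these two functions.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Reduce an angle to [0, 360).
mod360 <- function(x) {
  y <- x %% 360
  y[y == 360] <- 0
  y
}

clamp01 <- function(x) pmin(1, pmax(0, x))

normalize_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

# Cross product of two 3-vectors (used by frame validity and construction).
crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Residue key string used to index per-residue tables.
residue_key <- function(chain, resno, insert) {
  ins <- ifelse(is.na(insert) | insert == "", "", as.character(insert))
  paste(chain, resno, ins, sep = "|")
}

# Amino-acid code conversion (3-letter <-> 1-letter), standard residues only.
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
         "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

aa321 <- function(res3) {
  i <- match(toupper(res3), AA3)
  out <- AA1[i]
  out[is.na(i)] <- "X"
  out
}

aa123 <- function(res1) {
  i <- match(toupper(res1), AA1)
  out <- AA3[i]
  out[is.na(i)] <- NA_character_
  out
}

read_tsv_commented <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "tmexpo")
  if (!nzchar(p)) stop("bundled data file not found: ", file)
  p
}
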