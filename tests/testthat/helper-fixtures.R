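# Shared fixture builders; everything is generated in code at test time.

# Symmetric k-helix bundle with per-helix axial offsets.
make_bundle <- function(k = 4, n = 18, spacing = 10, offsets = NULL,
                        sequence = NULL) {
  if (is.null(offsets)) offsets <- 30 * (seq_len(k) - 1)
  specs <- lapply(seq_len(k), function(h) {
    ang <- 2 * pi * (h - 1) / k
    helixSpec(n, position = spacing * c(cos(ang), sin(ang)),
              offset = offsets[h], sequence = sequence)
  })
  helixBundle(specs)
}

write_annotations <- function(ann, path = tempfile(fileext = ".tsv")) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Minimal PSI-BLAST ASCII PSSM text for a given sequence with given
# log-odds rows (n x 20 matrix).
write_pssm <- function(sequence, scores, path = tempfile(fileext = ".pssm")) {
  aa_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  lines <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste(" ", paste(c(aa_order, aa_order), collapse = "  ")))
  aa <- strsplit(sequence, "")[[1]]
  for (i in seq_along(aa)) {
    lines <- c(lines, paste(c(i, aa[i], scores[i, ], rep(0, 20), "0.36", "0.08"),
                            collapse = " "))
  }
  writeLines(lines, path)
  path
}

# Independent brute-force moment oracle: plain loop, no shared code path.
oracle_moment <- function(scores) {
  x <- 0; y <- 0
  for (i in seq_along(scores)) {
    th <- (i - 1) * 100 * pi / 180
    x <- x + scores[i] * cos(th)
    y <- y + scores[i] * sin(th)
  }
  th <- atan2(y, x) * 180 / pi
  if (th < 0) th <- th + 360
  list(x = x, y = y, m = sqrt(x^2 + y^2), theta = th)
}

# Independent Jensen-Shannon divergence oracle (log2).
oracle_jsd <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) if (a[i] > 0) s <- s + a[i] * log2(a[i] / m[i])
    s
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

rotate_structure <- function(structure, angles = c(0.3, 1.1, 2.0),
                             shift = c(5, -3, 7)) {
  a <- angles
  Rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0,
                 0, 0, 1), 3)
  Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0,
                 sin(a[2]), 0, cos(a[2])), 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]),
                 0, -sin(a[1]), cos(a[1])), 3)
  M <- Rz %*% Ry %*% Rx
  at <- structure@atoms
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(M)
  at$x <- xyz[, 1] + shift[1]
  at$y <- xyz[, 2] + shift[2]
  at$z <- xyz[, 3] + shift[3]
  structure@atoms <- at
  structure
}
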