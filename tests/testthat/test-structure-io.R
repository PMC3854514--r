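test_that("a single ATOM record round-trips with its coordinate", {
  lines <- c(sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
                     "ATOM", 1, " CA ", "", "ALA", "A", 1, "",
                     1.234, -5.678, 9.012, 1.00, 0.00), "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  s <- readStructure(f)
  expect_equal(nrow(atomTable(s)), 1)
  expect_equal(unlist(atomTable(s)[1, c("x", "y", "z")]),
               c(x = 1.234, y = -5.678, z = 9.012))
  expect_equal(atomTable(s)$vdw, 1.87)  # tetrahedral carbon
})

test_that("write/read round-trip preserves C-alpha coordinates to PDB precision", {
  b <- make_bundle()
  f <- tempfile(fileext = ".pdb")
  writeStructurePDB(b$structure, f)
  s2 <- readStructure(f)
  ca1 <- subset(atomTable(b$structure), name == "CA")
  ca2 <- subset(atomTable(s2), name == "CA")
  expect_equal(nrow(ca1), nrow(ca2))
  expect_lt(max(abs(as.matrix(ca1[, c("x", "y", "z")]) -
                    as.matrix(ca2[, c("x", "y", "z")]))), 1e-3)
})

test_that("annotation reading validates spans and rejects overlaps", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("# comment", "chain\thelix_index\tstart\tend", "A\t1\t23\t48"), f)
  ann <- readTMAnnotations(f)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$end - ann$start + 1L, 26L)

  writeLines(c("chain\thelix_index\tstart\tend",
               "A\t1\t10\t30", "A\t2\t25\t40"), f)
  expect_error(readTMAnnotations(f), "overlap")

  writeLines(c("chain\thelix_index\tstart\tend", "A\t1\t30\t10"), f)
  expect_error(readTMAnnotations(f), "start > end")
})

test_that("a 12-helix annotation set yields 12 helices", {
  n <- 12
  starts <- seq(1, by = 30, length.out = n)
  f <- tempfile(fileext = ".tsv")
  writeLines(c("chain\thelix_index\tstart\tend",
               sprintf("A\t%d\t%d\t%d", 1:n, starts, starts + 20)), f)
  expect_equal(nrow(readTMAnnotations(f)), 12)
})

test_that("extractHelices flags missing and incomplete residues", {
  b <- make_bundle(k = 2, n = 12)
  h <- extractHelices(b$structure, b$annotations)
  expect_true(all(vapply(h, function(x) all(helixResidues(x)$complete), TRUE)))

  # delete one residue's side chain -> incomplete, not missing
  s <- b$structure
  at <- atomTable(s)
  drop <- at$resno == 3 & at$name == "CB"
  s@atoms <- at[!drop, ]
  h2 <- extractHelices(s, b$annotations)
  r <- helixResidues(h2[[1]])
  expect_false(r$complete[r$resno == 3])
  expect_false(r$missing[r$resno == 3])
  expect_true(r$hasCA[r$resno == 3])

  # annotation extending past the last modeled residue -> trailing missing
  ann <- b$annotations
  ann$end[2] <- ann$end[2] + 3L
  h3 <- extractHelices(s, ann)
  r3 <- helixResidues(h3[[2]])
  expect_equal(sum(r3$missing), 3)
  expect_equal(nchar(helixSequence(h3[[2]])), nrow(r3))

  # residue lacking a CA is flagged
  s4 <- b$structure
  at <- atomTable(s4)
  s4@atoms <- at[!(at$resno == 5 & at$name == "CA"), ]
  r4 <- helixResidues(extractHelices(s4, b$annotations)[[1]])
  expect_false(r4$hasCA[r4$resno == 5])
})

test_that("TM residue counts are conserved between chains and helices", {
  b <- make_bundle(k = 3, n = 15)
  h <- extractHelices(b$structure, b$annotations)
  n_by_helix <- sum(vapply(h, function(x) nrow(helixResidues(x)), 0L))
  n_by_ann <- sum(b$annotations$end - b$annotations$start + 1L)
  expect_equal(n_by_helix, n_by_ann)
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  f <- tempfile(fileext = ".pdb")
  fmt <- "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f"
  writeLines(c(sprintf(fmt, "ATOM", 1, " CA ", "A", "ALA", "A", 1, "",
                       0, 0, 0, 0.40, 0),
               sprintf(fmt, "ATOM", 2, " CA ", "B", "ALA", "A", 1, "",
                       9, 9, 9, 0.60, 0), "END"), f)
  s <- readStructure(f)
  expect_equal(nrow(atomTable(s)), 1)
  expect_equal(atomTable(s)$x, 9)
})

test_that("unknown elements fail loudly with the atom named", {
  b <- make_bundle(k = 2, n = 6)
  at <- atomTable(b$structure)
  at$element[1] <- "ZZ"
  expect_error(assign_vdw(at$name, at$element, loadRadiiTable()),
               "no van der Waals radius")
})
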