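test_that("sigmoid encodings match the printed formulas", {
  expect_equal(sigmoidEncode(0), 0.5)
  expect_equal(sigmoidEncode(0, "plus"), 0.5)
  expect_equal(sigmoidEncode(1), 1 - 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(sigmoidEncode(1), 0.2689414, tolerance = 1e-6)
  expect_equal(sigmoidEncode(1, "plus"), 1 - 1 / (1 + exp(1)), tolerance = 1e-12)
  expect_equal(sigmoidEncode(50), 0, tolerance = 1e-12)   # +inf limit
  expect_equal(sigmoidEncode(-50), 1, tolerance = 1e-12)  # -inf limit
})

test_that("linear encodings hit the published anchors at 1.0", {
  tb <- loadPropertyTables()
  expect_equal(linearEncode(tb["TYR", "volume"], 237.2), 1.0)
  expect_equal(linearEncode(tb["CYS", "contact"], 1.43), 1.0)
  expect_equal(linearEncode(tb["PRO", "turn"], 2.7), 1.0)
  expect_warning(out <- linearEncode(300, 237.2), "clamped")
  expect_equal(out, 1.0)
})

test_that("charge classes follow the positive/neutral/negative rule", {
  expect_equal(chargeEncode("LYS"), 1)
  expect_equal(chargeEncode("ASP"), 0)
  expect_equal(chargeEncode("ALA"), 0.5)
  expect_warning(z <- chargeEncode("XYZ"), "neutral")
  expect_equal(z, 0.5)
})

test_that("conservation scores agree with a brute-force JSD oracle", {
  bg <- tmexpo:::BG_FREQ
  q <- bg[tmexpo:::AA1] / sum(bg[tmexpo:::AA1])
  msa <- c("AAC", "AWC", "AYC")
  sc <- conservationScores(msa)
  for (j in 1:3) {
    col <- substring(msa, j, j)
    p <- tabulate(match(col, tmexpo:::AA1), nbins = 20) / length(col)
    expect_equal(sc[j], oracle_jsd(p, unname(q)), tolerance = 1e-12)
  }
  # identical column scores higher than a mixed one
  expect_gt(sc[1], sc[2])
  # column matching the background exactly has zero divergence
  uni <- stats::setNames(rep(1 / 20, 20), tmexpo:::AA1)
  msa20 <- tmexpo:::AA1
  expect_equal(conservationScores(msa20, background = uni)[1], 0,
               tolerance = 1e-12)
  # single-sequence alignment: every column equals its point-mass JSD
  one <- conservationScores("W")
  p <- tabulate(match("W", tmexpo:::AA1), nbins = 20)
  expect_equal(one, oracle_jsd(p, unname(q)), tolerance = 1e-12)
  # all-gap column is defined low
  expect_equal(conservationScores(c("-A", "-A"))[1], 0)
})

test_that("the PSI-BLAST PSSM reader recovers rows and sequence", {
  set.seed(3)
  scores <- matrix(sample(-5:8, 6 * 20, replace = TRUE), 6, 20)
  f <- write_pssm("MKTWYV", scores)
  p <- readPSSM(f)
  expect_equal(p$sequence, "MKTWYV")
  expect_equal(unname(p$scores), scores)
  expect_error(readPSSM(write_annotations(data.frame(chain = "A",
    helix_index = 1, start = 1, end = 3))), "no PSSM data rows")
})

test_that("window encoding has the fixed 476-dimension layout in [0,1]", {
  n <- 25
  ctx <- chainContext(strrep("A", n))
  v <- encodeWindow(ctx, 13)
  expect_length(v, 476)
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(attr(v, "schema_version"), tmexpo:::FEATURE_SCHEMA_VERSION)
  # all-zero PSSM -> sigmoid-neutral 0.5 PSSM block
  expect_true(all(v[grep("pssm", names(v))][1:20] == 0.5))
})

test_that("off-sequence window positions follow the padding rule", {
  ctx <- chainContext(strrep("A", 20))
  v <- encodeWindow(ctx, 1)   # 8 left positions padded
  for (k in 1:8) {
    zero_names <- paste0("p", k, "_", c("volume", "charge", "contact"))
    blk <- v[grep(paste0("^p", k, "_"), names(v))]
    expect_equal(unname(blk[zero_names]), rep(0, 3),
                 info = paste("pad position", k))
    expect_true(all(blk[setdiff(names(blk), zero_names)] == 0.5),
                info = paste("pad position", k))
  }
  # the center position itself is encoded, not padded
  blk9 <- v[grep("^p9_", names(v))]
  expect_false(all(blk9 == 0.5))
})

test_that("encoding is deterministic and errors on nonstandard residues", {
  ctx <- chainContext("ARNDCQEGHILKMFPSTWYV")
  m1 <- encodeChain(ctx)
  m2 <- encodeChain(ctx)
  expect_identical(m1, m2)
  expect_equal(dim(m1), c(20, 476))
  expect_true(all(m1 >= 0 & m1 <= 1))
  ctx2 <- chainContext("AXA")
  expect_error(encodeWindow(ctx2, 2), "nonstandard residue")
  expect_error(chainContext("AAA", pssm = matrix(0, 2, 20)), "PSSM")
})
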