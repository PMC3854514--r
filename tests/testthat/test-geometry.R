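test_that("principal axis recovers lines and ideal helices with orientation", {
  line <- cbind(0, 0, seq(0, 10, length.out = 8))
  expect_equal(principalAxis(line), c(0, 0, 1))
  expect_equal(principalAxis(line[nrow(line):1, ]), c(0, 0, -1))

  ca <- as.matrix(subset(idealHelix(helixSpec(26)),
                         name == "CA")[, c("x", "y", "z")])
  ax <- principalAxis(ca)
  expect_lt(acos(min(1, sum(ax * c(0, 0, 1)))) * 180 / pi, 0.5)

  expect_error(principalAxis(line[1:2, ]), "at least 3")
  expect_error(principalAxis(matrix(1, 5, 3)), "degenerate")
})

test_that("the top-view frame is right-handed with +100 deg/residue progression", {
  ca <- as.matrix(subset(idealHelix(helixSpec(18)),
                         name == "CA")[, c("x", "y", "z")])
  frame <- topViewFrame(principalAxis(ca))
  P <- topviewProject(ca, frame)
  ctr <- colMeans(P)
  ang <- atan2(P[, 2] - ctr[2], P[, 1] - ctr[1]) * 180 / pi
  step <- (diff(ang)) %% 360
  expect_true(all(abs(step - 100) < 1e-6))
})

test_that("projection drops the axial component and preserves in-plane distance", {
  frame <- topViewFrame(c(0, 0, 1))
  expect_equal(as.numeric(topviewProject(c(0, 0, 5), frame)), c(0, 0))
  p <- topviewProject(rbind(c(1, 2, 0), c(4, 6, 9)), frame)
  expect_equal(sqrt(sum((p[1, ] - p[2, ])^2)), 5)
})

test_that("lipid-facing direction points radially outward", {
  expect_equal(lipidFacingDirection(c(1, 0), c(0, 0)), c(1, 0))
  expect_equal(lipidFacingDirection(c(0, -2), c(0, 0)), c(0, -1))
  expect_error(lipidFacingDirection(c(1, 1), c(1, 1)), "undefined")
  b <- make_bundle(k = 4, n = 18, offsets = rep(0, 4))
  # all first residues at offset 0: observed angle equals the radial
  # direction angle minus 0, i.e. the helix placement angle
  obs <- observedRotationAngles(b$structure, b$annotations)
  expect_equal(angularError(obs$observed_angle_deg, b$truth$truth_angle),
               rep(0, 4), tolerance = 1e-6)
})

test_that("planted helix rotations are recovered", {
  offsets <- c(12.5, 222, 85, 301)
  b <- make_bundle(k = 4, n = 18, offsets = offsets)
  obs <- observedRotationAngles(b$structure, b$annotations)
  expect_lt(max(angularError(obs$observed_angle_deg, b$truth$truth_angle)), 1)

  # pre-rotating one helix by -delta increases its angle by delta
  b0 <- make_bundle(k = 2, n = 18, offsets = c(0, 0))
  b1 <- make_bundle(k = 2, n = 18, offsets = c(-37.5, 0))
  o0 <- observedRotationAngles(b0$structure, b0$annotations)
  o1 <- observedRotationAngles(b1$structure, b1$annotations)
  delta <- (o1$observed_angle_deg[1] - o0$observed_angle_deg[1]) %% 360
  expect_equal(delta, 37.5, tolerance = 1)
})

test_that("observed angles are invariant under global rigid motion", {
  b <- make_bundle(k = 3, n = 20, offsets = c(10, 150, 290))
  o1 <- observedRotationAngles(b$structure, b$annotations)
  o2 <- observedRotationAngles(rotate_structure(b$structure), b$annotations)
  expect_lt(max(angularError(o1$observed_angle_deg, o2$observed_angle_deg)),
            1e-6)
  expect_true(all(o1$observed_angle_deg >= 0 & o1$observed_angle_deg < 360))
})

test_that("a first residue without C-alpha falls back with a record", {
  b <- make_bundle(k = 2, n = 12)
  at <- atomTable(b$structure)
  s <- b$structure
  s@atoms <- at[!(at$resno == 1 & at$name == "CA"), ]
  obs <- observedRotationAngles(s, b$annotations)
  expect_true(obs$fallback[1])
  expect_equal(obs$first_residue[1], 2)
  expect_false(obs$fallback[2])
})

test_that("delta-exposure handedness pins the same sign convention as the moment", {
  # helix 1 placed on +x, rotated so residue i faces the lipid (outward +x)
  for (i in c(1, 4, 8)) {
    offset <- -(i - 1) * 100
    b <- helixBundle(list(
      helixSpec(18, position = c(10, 0), offset = offset),
      helixSpec(18, position = c(-10, 0), offset = 0)))
    obs <- observedRotationAngles(b$structure, b$annotations)
    geom_angle <- obs$observed_angle_deg[1]
    delta <- rep(0, 18); delta[i] <- 1
    mom_angle <- momentTheta(predictRotation(delta))
    expect_lt(angularError(geom_angle, ((i - 1) * 100) %% 360), 1)
    expect_lt(angularError(geom_angle, mom_angle), 1)
  }
})
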