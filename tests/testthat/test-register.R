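test_that("landmark transforms recover constructed displacements exactly", {
  g <- AcquisitionGeometry()
  ref <- referenceLandmarks(g)

  expect_equal(fitLandmarkTransform(ref, ref)@rotation, 0, tolerance = 1e-9)
  expect_equal(fitLandmarkTransform(ref, ref)@translation, c(0, 0),
               tolerance = 1e-9)

  # pure translation by (5, -3): moving frame displaced the opposite way
  shift <- matrix(c(5, -3), 2, 2, byrow = TRUE)
  mv <- LandmarkFrame(ref@mcaPoints - shift, ref@rfPoints - shift)
  tr <- fitLandmarkTransform(mv, ref)
  expect_equal(tr@rotation, 0, tolerance = 1e-9)
  expect_equal(tr@translation, c(5, -3), tolerance = 1e-9)

  # pure rotation about the line intersection
  piv <- vsdmap:::lineIntersection(ref@mcaPoints, ref@rfPoints)
  rot <- RigidTransform(10, c(0, 0), piv)
  mv2 <- LandmarkFrame(applyTransform(rot, ref@mcaPoints),
                       applyTransform(rot, ref@rfPoints))
  tr2 <- fitLandmarkTransform(mv2, ref)
  expect_equal(abs(tr2@rotation), 10, tolerance = 1e-6)
  # and the fitted transform undoes the displacement
  back <- applyTransform(tr2, applyTransform(rot, piv + c(20, 10)))
  expect_equal(back, piv + c(20, 10), tolerance = 1e-9)
})

test_that("transform composition with its inverse is the identity", {
  tr <- RigidTransform(23, c(4.5, -7.25), c(60, 90))
  pts <- cbind(runif(20, 1, 124), runif(20, 1, 184))
  round <- applyTransform(invertTransform(tr), applyTransform(tr, pts))
  expect_equal(round, pts, tolerance = 1e-9)
})

test_that("unresolvable landmarks lead to exclusion, not an error", {
  g <- AcquisitionGeometry()
  ref <- referenceLandmarks(g)
  bad <- LandmarkFrame(ref@mcaPoints, ref@rfPoints, resolvable = FALSE)
  expect_null(fitLandmarkTransform(bad, ref))
})

test_that("outline warping is exact for constructed rigid motions", {
  g <- AcquisitionGeometry()
  block <- as.matrix(expand.grid(row = 40:42, col = 60:62))

  ident <- warpOutline(block, RigidTransform(), g)
  expect_identical(pixKey(ident), pixKey(block))

  tr <- RigidTransform(0, c(7, -9), c(0, 0))
  round <- warpOutline(warpOutline(block, tr, g), invertTransform(tr), g)
  expect_identical(pixKey(round), pixKey(block))

  # 90 degree rotation about a pivot: direct coordinate arithmetic
  piv <- c(50, 50)
  r90 <- RigidTransform(90, c(0, 0), piv)
  got <- warpOutline(block, r90, g)
  th <- pi / 2
  expected <- cbind(
    round(piv[1] + cos(th) * (block[, 1] - piv[1]) + sin(th) * (block[, 2] - piv[2])),
    round(piv[2] - sin(th) * (block[, 1] - piv[1]) + cos(th) * (block[, 2] - piv[2]))
  )
  expect_identical(pixKey(got), pixKey(expected))

  # pixels leaving the field are dropped and counted
  far <- warpOutline(block, RigidTransform(0, c(200, 0), c(0, 0)), g)
  expect_identical(nrow(far), 0L)
  expect_identical(attr(far, "dropped"), 9L)
})

test_that("overlap maps count and threshold as specified", {
  g <- AcquisitionGeometry(nFrames = 2L, height = 20L, width = 20L,
                           stimOnsetFrame = 2L)
  r1 <- as.matrix(expand.grid(row = 5:8, col = 5:8))
  r2 <- as.matrix(expand.grid(row = 14:15, col = 14:15))

  # identical outlines: counts N inside, contour equals the outline
  ov <- buildOverlap(list(r1, r1, r1), g)
  expect_identical(max(overlapCounts(ov)), 3L)
  expect_identical(pixKey(which(majorityMask(ov), arr.ind = TRUE)), pixKey(r1))

  # 4 animals: R1 in all four, R2 in one -> threshold ceil(0.5*4) = 2 keeps R1 only
  ov4 <- buildOverlap(list(r1, r1, r1, rbind(r1, r2)), g)
  expect_identical(pixKey(which(majorityMask(ov4), arr.ind = TRUE)), pixKey(r1))
  expect_identical(overlapCounts(ov4)[14, 14], 1L)

  # fraction 1 is the intersection
  ovI <- buildOverlap(list(rbind(r1, r2), r1), g, fraction = 1)
  expect_identical(pixKey(which(majorityMask(ovI), arr.ind = TRUE)), pixKey(r1))

  expect_error(buildOverlap(list(), g), "no non-excluded")
})

test_that("overlap counts are permutation-invariant and monotone in fraction", {
  g <- AcquisitionGeometry(nFrames = 2L, height = 30L, width = 30L,
                           stimOnsetFrame = 2L)
  set.seed(4)
  outlines <- lapply(1:5, function(i) {
    ctr <- c(sample(8:22, 1), sample(8:22, 1))
    which(vsdmap:::discMask(30, 30, ctr, 6), arr.ind = TRUE)
  })
  a <- buildOverlap(outlines, g)
  b <- buildOverlap(rev(outlines), g)
  expect_identical(overlapCounts(a), overlapCounts(b))

  masks <- lapply(c(0.2, 0.5, 0.8, 1.0), function(fr)
    majorityMask(buildOverlap(outlines, g, fraction = fr)))
  for (i in 2:length(masks)) {
    expect_true(all(masks[[i - 1]] | !masks[[i]]))
  }
})

test_that("alignment round trip reproduces the overlap map (Jaccard >= 0.95)", {
  g <- AcquisitionGeometry()
  ref <- referenceLandmarks(g)
  outline <- which(vsdmap:::discMask(g@height, g@width, c(62, 92), 14), arr.ind = TRUE)
  jac <- vapply(1:20, function(s) {
    set.seed(s)
    piv <- c(runif(1, 40, 80), runif(1, 70, 120))
    pert <- RigidTransform(runif(1, -10, 10), c(runif(1, -10, 10), runif(1, -10, 10)), piv)
    mv <- LandmarkFrame(applyTransform(pert, ref@mcaPoints),
                        applyTransform(pert, ref@rfPoints))
    tr <- fitLandmarkTransform(mv, ref)
    aligned <- warpOutline(warpOutline(outline, pert, g), tr, g)
    a <- pixKey(aligned); b <- pixKey(outline)
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  expect_gte(mean(jac), 0.95)
})

test_that("mask boundaries outline the majority region", {
  mask <- matrix(FALSE, 10, 10)
  mask[3:7, 3:7] <- TRUE
  bd <- maskBoundary(mask)
  expect_identical(nrow(bd), 25L - 9L)
  expect_true(all(mask[bd]))
})
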