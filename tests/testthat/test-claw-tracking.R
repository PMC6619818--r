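test_that("Hungarian assignment equals the brute-force oracle, with and without gates", {
  withSeed(13, {
    for (i in 1:60) {
      nr <- sample(2:6, 1); nc <- sample(2:6, 1)
      cost <- matrix(runif(nr * nc, 0, 100), nr, nc)
      if (i %% 3 == 0) cost[runif(nr * nc) < 0.3] <- Inf
      a <- solveAssignment(cost)
      o <- bruteAssign(cost)
      expect_equal(sum(!is.na(a)), o$matched)
      got <- sum(cost[cbind(which(!is.na(a)), a[!is.na(a)])])
      expect_equal(got, o$cost, tolerance = 1e-9)
      expect_false(any(duplicated(a[!is.na(a)])))
    }
  })
})

test_that("body pose recovers orientation, centroid equivariance and extents", {
  # axis-aligned ellipse: theta = 0
  d <- 201
  xg <- matrix(rep(0:(d - 1), each = d), d) - 100
  yg <- matrix(rep(0:(d - 1), times = d), d) - 100
  ell <- (yg / 60)^2 + (xg / 20)^2 <= 1     # long along y (rows vary)
  ps <- bodyPose(ell)
  expect_equal(ps$theta, 0, tolerance = 0.5)
  expect_equal(c(ps$cx, ps$cy), c(100, 100), tolerance = 1e-6)
  expect_equal(ps$extentPx, 120, tolerance = 2)

  # rotated 30 degrees: theta = 30 (rasterized moments, +-0.5 deg)
  th <- 30 * pi / 180
  xr <- xg * cos(th) - yg * sin(th); yr <- xg * sin(th) + yg * cos(th)
  ell30 <- (((xr * sin(th) + yr * cos(th)) / 60)^2 +
            ((xr * cos(th) - yr * sin(th)) / 20)^2) <= 1
  # build by rotating the sampling grid instead
  u <- xg * sin(th) + yg * cos(th)     # along-axis coordinate
  v <- xg * cos(th) - yg * sin(th)
  ell30 <- (u / 60)^2 + (v / 20)^2 <= 1
  ps30 <- bodyPose(ell30)
  expect_equal(ps30$theta, 30, tolerance = 0.5)

  # translation equivariance
  shifted <- matrix(FALSE, d + 20, d + 20)
  shifted[(1:d) + 7, (1:d) + 5] <- ell
  ps2 <- bodyPose(shifted)
  expect_equal(c(ps2$cx - ps$cx, ps2$cy - ps$cy), c(5, 7), tolerance = 1e-9)
  expect_equal(ps2$theta, ps$theta, tolerance = 1e-6)
})

test_that("body-frame transform is the exact inverse pair and maps anterior to +y", {
  pose <- structure(list(cx = 50, cy = 80, theta = 25, flip = FALSE),
                    class = "BodyPose")
  expect_equal(drop(toBodyFrame(c(50, 80), pose)), c(x = 0, y = 0))
  pose0 <- structure(list(cx = 10, cy = 10, theta = 0, flip = FALSE),
                     class = "BodyPose")
  expect_equal(drop(toBodyFrame(c(13, 14), pose0)), c(x = 3, y = 4))
  withSeed(2, {
    pts <- matrix(runif(40, 0, 512), ncol = 2)
    for (flip in c(FALSE, TRUE)) {
      pose$flip <- flip
      rt <- fromBodyFrame(toBodyFrame(pts, pose), pose)
      expect_equal(unname(rt), unname(pts), tolerance = 1e-9)
    }
  })
  # a point one unit along the anterior direction maps to (0, 1)
  h <- 25 * pi / 180
  ant <- c(50 + sin(h), 80 + cos(h))
  expect_equal(drop(toBodyFrame(ant, `class<-`(list(cx = 50, cy = 80,
                                                    theta = 25,
                                                    flip = FALSE),
                                              "BodyPose"))),
               c(x = 0, y = 1), tolerance = 1e-9)
})

test_that("claw candidates are distal skeleton endpoints; loops are skipped", {
  lab <- matrix(0L, 60, 60)
  lab[30, 10:29] <- 1L                     # straight horizontal leg
  lab[40:49, 40] <- 2L; lab[49, 40:49] <- 2L   # L-shaped component
  seg <- structure(list(labels = lab, sizes = c(20L, 19L), thr = 0.65),
                   class = "LegSegmentation")
  pose <- structure(list(cx = 30, cy = 30, theta = 0, flip = FALSE),
                    class = "BodyPose")
  tips <- findClawCandidates(seg, pose)
  expect_equal(nrow(tips), 2L)
  # distal refinement averages the most distal pixels, so allow ~1 px
  t1 <- tips[tips$component == 1, ]
  expect_lt(sqrt((t1$x - 9)^2 + (t1$y - 29)^2), 1.2)   # far end (0-based)
  t2 <- tips[tips$component == 2, ]
  # L-shape: the distal endpoint is the farther arm end
  expect_lt(sqrt((t2$x - 48)^2 + (t2$y - 48)^2), 1.2)
  expect_gt(t2$dist, t1$dist)

  # ring artifact: no endpoint, no tip
  ring <- matrix(0L, 40, 40)
  ring[10:20, 10] <- 1L; ring[10:20, 20] <- 1L
  ring[10, 10:20] <- 1L; ring[20, 10:20] <- 1L
  segr <- structure(list(labels = ring, sizes = 40L, thr = 0.65),
                    class = "LegSegmentation")
  expect_equal(nrow(findClawCandidates(segr, pose)), 0L)
})

test_that("track initialization labels a clean stance geometrically and errors otherwise", {
  mkTips <- function(xb, yb) {
    n <- length(xb)
    structure(data.frame(x = xb + 250, y = yb + 250, xb = xb, yb = yb,
                         component = seq_len(n), dist = sqrt(xb^2 + yb^2)),
              class = c("TipSet", "data.frame"))
  }
  tips6 <- mkTips(c(-30, -40, -36, 30, 40, 36), c(48, 8, -40, 48, 8, -40))
  init <- initializeTracks(list(tips6), 6L)
  expect_equal(init$frame, 1L)
  expect_equal(names(init$labels), c("L1", "L2", "L3", "R1", "R2", "R3"))
  expect_equal(unname(init$labels), c(1L, 2L, 3L, 4L, 5L, 6L))

  # mirrored configuration swaps left and right labels
  tipsM <- mkTips(-c(-30, -40, -36, 30, 40, 36), c(48, 8, -40, 48, 8, -40))
  initM <- initializeTracks(list(tipsM), 6L)
  expect_equal(unname(initM$labels[c("R1", "R2", "R3")]), c(1L, 2L, 3L))
  expect_equal(unname(initM$labels[c("L1", "L2", "L3")]), c(4L, 5L, 6L))

  # five tips in every frame: initialization error
  tips5 <- mkTips(c(-30, -40, 30, 40, 36), c(48, 8, 48, 8, -40))
  expect_error(initializeTracks(list(tips5, tips5), 6L), "initialization")
})

test_that("tip assignment is gated at 20 px and recovers via last-seen positions", {
  mkTips <- function(xb, yb) {
    n <- length(xb)
    structure(data.frame(x = xb, y = yb, xb = xb, yb = yb,
                         component = seq_len(n), dist = 0),
              class = c("TipSet", "data.frame"))
  }
  cur <- cbind(c(-30, -40, -36, 30, 40, 36), c(48, 8, -40, 48, 8, -40))
  # identity: unmoved tips match with zero cost
  a <- assignTips(cur, cur, mkTips(cur[, 1], cur[, 2]), 20)
  expect_equal(a, 1:6)
  # one tip displaced 25 px: that leg goes missing
  moved <- cur; moved[2, 2] <- moved[2, 2] + 25
  a2 <- assignTips(cur, cur, mkTips(moved[, 1], moved[, 2]), 20)
  expect_true(is.na(a2[2]))
  expect_equal(a2[-2], c(1L, 3L, 4L, 5L, 6L))
  # recovery: leg 2 currently missing, a tip reappears near its last-seen
  cur2 <- cur; cur2[2, ] <- NA
  a3 <- assignTips(cur2, cur, mkTips(cur[, 1], cur[, 2] + 3), 20)
  expect_equal(a3[2], 2L)

  # random 6<->6 configurations within the gate match the brute-force oracle
  withSeed(41, {
    for (rep in 1:40) {
      prev <- matrix(runif(12, -60, 60), 6)
      tips <- prev + matrix(runif(12, -8, 8), 6)
      tips <- tips[sample(6), , drop = FALSE]
      cost <- outer(1:6, 1:6, Vectorize(function(i, j)
        sum((prev[i, ] - tips[j, ])^2)))
      cost[cost > 400] <- Inf
      o <- bruteAssign(cost)
      a <- assignTips(prev, prev, mkTips(tips[, 1], tips[, 2]), 20)
      expect_equal(sum(!is.na(a)), o$matched)
      ca <- sum(cost[cbind(which(!is.na(a)), a[!is.na(a)])])
      expect_equal(ca, o$cost, tolerance = 1e-9)
    }
  })
})
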