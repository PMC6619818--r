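test_that("frame stacks load from disk in name order with derived calibration", {
  dir <- file.path(tempdir(), "hexgait-frames")
  unlink(dir, recursive = TRUE)
  st0 <- smallWalker()$stack
  sub <- frameStack(st0@frames[1:5], st0@frameRate, 10)
  writeFrameStack(sub, dir)
  st <- loadFrameStack(dir, frameRate = 1000, fovMM = 10)
  expect_equal(nFrames(st), 5L)
  expect_equal(mmPerPx(st), 10 / 512)
  expect_equal(st@frames[[3]], sub@frames[[3]], tolerance = 1.01) # 8-bit
  # a single frame is not trackable
  dir1 <- file.path(tempdir(), "hexgait-one")
  unlink(dir1, recursive = TRUE); dir.create(dir1)
  file.copy(list.files(dir, full.names = TRUE)[1], dir1)
  expect_error(loadFrameStack(dir1, 1000, 10), "at least 2")
  # shape mismatch
  tiff::writeTIFF(matrix(0.5, 64, 64), file.path(dir, "zz_small.tif"))
  expect_error(loadFrameStack(dir, 1000, 10), "mismatch")
  expect_error(loadFrameStack(file.path(tempdir(), "no-such-dir"), 1000, 10),
               "no readable frames")
  unlink(c(dir, dir1), recursive = TRUE)
})

test_that("silhouette extraction follows the threshold formula and suppresses dust", {
  bgm <- matrix(200, 120, 120)
  bg <- new("BackgroundImage", image = bgm, mode = "loaded",
            flags = character(0))
  fr <- bgm
  fr[40:70, 40:70] <- 50                      # animal blob
  fr[100:101, 100:101] <- 50                  # distant dust
  fr[72:73, 55] <- 50                         # speck adjacent to the blob
  mask <- extractSilhouette(fr, bg, thr = 60)
  expect_true(all(mask[40:70, 40:70]))
  expect_false(any(mask[100:101, 100:101]))   # dust dropped
  expect_true(all(mask[72:73, 55]))           # nearby component kept
  # frame equal to background: empty mask with a warning
  expect_warning(m0 <- extractSilhouette(bgm, bg, thr = 60), "empty")
  expect_equal(sum(m0), 0)
  # re-thresholding the same frame is idempotent
  mask2 <- extractSilhouette(fr, bg, thr = 60)
  expect_identical(mask, mask2)
})

test_that("auto threshold matches an independent Otsu computation", {
  v <- smallWalker()
  fr <- v$stack@frames[[40]]
  d <- abs(fr - v$bg@image)
  mask <- extractSilhouette(fr, v$bg, thr = "auto")
  # brute-force Otsu on the 256-bin histogram of the difference image
  h <- tabulate(floor(pmin(pmax(d, 0), 255) / 255 * 256) + 1L, 257L)[1:256]
  p <- h / sum(h); lv <- (0:255) / 255
  bestSig <- -1; bestT <- 0
  for (t in 1:255) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 < 1e-12 || w1 < 1e-12) next
    m0 <- sum(p[1:t] * lv[1:t]) / w0
    m1 <- sum(p[(t + 1):256] * lv[(t + 1):256]) / w1
    sig <- w0 * w1 * (m0 - m1)^2
    if (sig > bestSig) { bestSig <- sig; bestT <- lv[t] }
  }
  expect_lt(abs(attr(mask, "threshold") / 256 - bestT), 2 / 256)
})

test_that("auto background recovers the clean background of a moving blob", {
  v <- smallWalker()
  st <- v$stack
  # fast-moving synthetic stack: constant background + blob visiting
  # disjoint places
  frames <- lapply(1:12, function(i) {
    f <- matrix(200, 100, 100)
    f[(i * 7):(i * 7 + 6), (i * 7):(i * 7 + 6)] <- 40
    f
  })
  stk <- frameStack(frames, 100, 10)
  bg <- estimateBackground(stk, mode = "auto", sampleStride = 1)
  # at pixels the blob never covers, the background equals the truth
  expect_equal(bg@image[90:100, 1:10], matrix(200, 11, 10))
  expect_true(all(bg@image >= 40))
  # auto background is at least the per-pixel minimum (dark-animal rule)
  mins <- Reduce(pmin, frames)
  expect_true(all(bg@image >= mins))

  # spliced mode removes a blob present in disjoint first/last regions
  fA <- matrix(200, 100, 100); fA[10:25, 10:25] <- 40
  fB <- matrix(200, 100, 100); fB[70:85, 70:85] <- 40
  stk2 <- frameStack(list(fA, fB), 100, 10)
  bg2 <- estimateBackground(stk2, mode = "spliced")
  expect_true(all(bg2@image == 200))

  # loaded mode passes through
  img <- matrix(123, 100, 100)
  bg3 <- estimateBackground(stk2, mode = "loaded", image = img)
  expect_identical(bg3@image, img)

  # stationary blob in auto mode gets flagged
  still <- frameStack(lapply(1:6, function(i) fA), 100, 10)
  bgS <- estimateBackground(still, mode = "auto", sampleStride = 1)
  expect_true("stationary" %in% bgS@flags)
})

test_that("track tables round-trip bit-exactly and encode missing claws as empty cells", {
  nf <- 100L
  legs <- c("L1", "L2", "L3", "R1", "R2", "R3")
  withSeed(3, {
    arena <- array(runif(nf * 6 * 2, 0, 512), c(nf, 6, 2))
    body <- array(rnorm(nf * 6 * 2), c(nf, 6, 2))
  })
  missing <- matrix(FALSE, nf, 6)
  missing[11:13, 2] <- TRUE                  # leg L2 missing frames 10-12
  arena[11:13, 2, ] <- NA; body[11:13, 2, ] <- NA
  ts <- new("TrackSet", legs = legs, arena = arena, body = body,
            missing = missing,
            poses = data.frame(frame = 0:(nf - 1), cx = runif(nf, 0, 512),
                               cy = runif(nf, 0, 512), theta = 0,
                               flip = FALSE, extent_px = 133),
            tipSets = list(), corrections = data.frame(),
            frameRate = 1000, mmPerPx = 10 / 512, gatePx = 20,
            startFrame = 1L)
  out <- file.path(tempdir(), "hexgait-tables")
  unlink(out, recursive = TRUE)
  files <- writeTrackTables(ts, NULL, out)
  traj <- read.csv(file.path(out, "trajectory.csv"))
  expect_equal(nrow(traj), nf)
  expect_equal(ncol(traj), 1L + 6L * 2L)
  norm <- read.csv(file.path(out, "norm_trajectory.csv"))
  expect_identical(norm$L1_x, body[, 1, 1])          # bit-exact round trip
  expect_identical(norm$R3_y, body[, 6, 2])
  expect_true(all(is.na(norm$L2_x[11:13])))
  raw <- readLines(file.path(out, "norm_trajectory.csv"))
  expect_true(grepl(",,", raw[12]))                  # empty cells, not "NA"
  unlink(out, recursive = TRUE)
})
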