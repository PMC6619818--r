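# Shake/tremor event detection on claw traces, tremor-frequency estimation
# via inter-event intervals, a permutation test for interval-histogram
# enrichment, and Cliff's delta effect sizes with bootstrap CIs.

# Deviation signal of one coordinate trace: the offset from a centred
# moving-average centreline (window in ms).
.deviationSignal <- function(x, fps, centreMs = 50) {
  k <- max(1L, round(centreMs / 1000 * fps))
  x - rollMeanCentered(x, k)
}

# Alternating-extrema reversal filter: local extrema of d are scanned in
# order; same-sense neighbours collapse to the more extreme one, and an
# opposite-sense extremum is committed only when the reversal from the
# pending extremum is at least minAmp.
.alternatingExtrema <- function(d, minAmp) {
  n <- length(d)
  if (n < 3L) return(NULL)
  # collapse plateaus, keeping the first index of each run of equal values
  r <- rle(d)
  firsts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  vals <- r$values
  if (length(vals) < 3L) return(NULL)
  s <- sign(diff(vals))
  turns <- which(s[-1L] != s[-length(s)]) + 1L   # interior turning points
  if (!length(turns)) return(NULL)
  cand <- data.frame(idx = firsts[turns], val = vals[turns],
                     pol = ifelse(s[turns - 1L] > 0, "peak", "valley"))
  out <- NULL
  pend <- cand[1L, ]
  if (nrow(cand) >= 2L) for (i in 2:nrow(cand)) {
    cc <- cand[i, ]
    if (cc$pol == pend$pol) {
      better <- if (cc$pol == "peak") cc$val > pend$val else cc$val < pend$val
      if (better) pend <- cc
    } else if (abs(cc$val - pend$val) >= minAmp) {
      pend$amplitude <- if (is.null(out)) abs(cc$val - pend$val)
                        else abs(pend$val - out$val[nrow(out)])
      out <- rbind(out, pend)
      pend <- cc
    } else if (is.null(out) && abs(cc$val) > abs(pend$val)) {
      # before anything is committed there is no anchor: a sub-threshold
      # wiggle must not pin the pending extremum to a spurious tiny one
      pend <- cc
    }
  }
  if (!is.null(out)) {
    pend$amplitude <- abs(pend$val - out$val[nrow(out)])
    out <- rbind(out, pend)
  }
  out
}

#' Detect shaking events in a claw trace
#'
#' The trace is reduced to its deviation from a 50-ms moving-average
#' centreline (per axis); local extrema alternating between peaks and
#' valleys qualify as shaking events when the reversal from the preceding
#' opposite extremum is at least \code{minAmp} pixels (default 3 px, about
#' the width of a leg tip, filtering out tracking jitter).
#'
#' @param trace numeric vector (one coordinate) or 2-column matrix (x, y) of
#'   body-frame claw positions in px; gaps up to 5 frames are interpolated.
#' @param fps frame rate.
#' @param minAmp minimum reversal amplitude, px.
#' @param centreMs centreline window, ms.
#' @return data.frame: \code{frame} (1-based), \code{axis}, \code{polarity}
#'   ("peak"/"valley"), \code{amplitude} (px), \code{value} (deviation px).
#' @export
detectShakeEvents <- function(trace, fps, minAmp = 3, centreMs = 50) {
  if (is.null(dim(trace))) trace <- matrix(trace, ncol = 1L,
                                           dimnames = list(NULL, "x"))
  if (is.null(colnames(trace)))
    colnames(trace) <- c("x", "y")[seq_len(ncol(trace))]
  empty <- data.frame(frame = integer(0), axis = character(0),
                      polarity = character(0), amplitude = numeric(0),
                      value = numeric(0))
  k <- max(1L, round(centreMs / 1000 * fps))
  if (nrow(trace) < k) return(empty)
  out <- empty
  for (ax in colnames(trace)) {
    x <- interpolateGaps(trace[, ax], 5L)
    if (anyNA(x)) {
      # analyse the longest complete run
      r <- rle(!is.na(x))
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      ok <- which(r$values)
      if (!length(ok)) next
      b <- ok[which.max(r$lengths[ok])]
      off <- starts[b] - 1L
      x <- x[starts[b]:ends[b]]
    } else off <- 0L
    d <- .deviationSignal(x, fps, centreMs)
    ex <- .alternatingExtrema(d, minAmp)
    if (is.null(ex)) next
    # the centreline is ill-defined inside one window of the trace ends
    ok <- ex$idx > k & ex$idx <= length(x) - k
    ex <- ex[ok, , drop = FALSE]
    if (!nrow(ex)) next
    out <- rbind(out, data.frame(frame = ex$idx + off, axis = ax,
                                 polarity = ex$pol,
                                 amplitude = ex$amplitude, value = ex$val))
  }
  out[order(out$frame), , drop = FALSE]
}

#' Group shaking events into tremor events
#'
#' A tremor episode is a maximal run of three or more shaking events whose
#' consecutive gaps are all below \code{maxGapMs} (default 100 ms,
#' conservatively below the ~10 Hz stride rhythm); every shake inside such a
#' run counts as one tremor event.
#'
#' @param shakes output of \code{\link{detectShakeEvents}} (time-ordered).
#' @param fps frame rate.
#' @param maxGapMs maximum within-run gap, ms.
#' @param minRun minimum run length.
#' @return the subset of \code{shakes} that are tremor events, with a
#'   \code{run} id column; attribute \code{ratePerSec} gives events per
#'   second of trace.
#' @export
detectTremorEvents <- function(shakes, fps, maxGapMs = 100, minRun = 3L) {
  out <- cbind(shakes[0, , drop = FALSE], run = integer(0))
  if (nrow(shakes) == 0L) return(out)
  sh <- shakes[order(shakes$frame), , drop = FALSE]
  gaps <- diff(sh$frame) / fps * 1000
  runId <- cumsum(c(1L, as.integer(gaps >= maxGapMs)))
  keepRuns <- as.integer(names(which(table(runId) >= minRun)))
  sel <- runId %in% keepRuns
  out <- cbind(sh[sel, , drop = FALSE],
               run = match(runId[sel], keepRuns))
  rownames(out) <- NULL
  out
}

#' Interval histogram of tremor events
#'
#' Intervals between consecutive same-polarity extrema (full oscillation
#' periods) within each tremor run, binned at \code{binMs}; the dominant bin
#' estimates the tremor period.
#'
#' @param tremors output of \code{\link{detectTremorEvents}}.
#' @param fps frame rate.
#' @param binMs histogram bin width, ms.
#' @return list: \code{intervals} (ms), \code{histogram} (data.frame with
#'   bin bounds and counts), \code{dominantBin} (c(lo, hi) ms, or NULL).
#' @export
intervalSpectrum <- function(tremors, fps, binMs = 10) {
  ivs <- numeric(0)
  if (nrow(tremors)) {
    for (rn in unique(tremors$run)) {
      tr <- tremors[tremors$run == rn, , drop = FALSE]
      for (pol in unique(tr$polarity)) {
        f <- sort(tr$frame[tr$polarity == pol])
        if (length(f) >= 2L) ivs <- c(ivs, diff(f) / fps * 1000)
      }
    }
  }
  if (!length(ivs))
    return(list(intervals = ivs,
                histogram = data.frame(lo = numeric(0), hi = numeric(0),
                                       count = integer(0)),
                dominantBin = NULL))
  hi <- ceiling(max(ivs) / binMs) * binMs
  breaks <- seq(0, hi, by = binMs)
  cnt <- tabulate(pmin(floor(ivs / binMs) + 1L, length(breaks) - 1L),
                  nbins = length(breaks) - 1L)
  histo <- data.frame(lo = breaks[-length(breaks)], hi = breaks[-1L],
                      count = cnt)
  b <- which.max(cnt)
  list(intervals = ivs, histogram = histo,
       dominantBin = c(histo$lo[b], histo$hi[b]))
}

#' Permutation test for interval-bin enrichment
#'
#' Tests whether the observed fraction of intervals falling in the queried
#' bin exceeds what uniform intervals over the observed range would give.
#' The null draws \code{nIter} resamples of equal size uniformly over
#' \code{[min(intervals), max(intervals)]}; the p-value uses the add-one
#' convention \code{(1 + #null >= observed) / (1 + nIter)}.
#'
#' @param intervals observed intervals, ms (at least 5).
#' @param bin c(lo, hi) queried bin, ms (lo inclusive, hi exclusive).
#' @param nIter permutation iterations (default 100000).
#' @return the p-value, with attribute \code{observed}.
#' @export
intervalPermutationTest <- function(intervals, bin, nIter = 100000L) {
  if (length(intervals) < 5L)
    stop("insufficient data: need at least 5 intervals")
  n <- length(intervals)
  obs <- mean(intervals >= bin[1L] & intervals < bin[2L])
  lo <- min(intervals); hi <- max(intervals)
  exceed <- 0L
  chunk <- max(1L, min(nIter, floor(1e6 / n)))
  done <- 0L
  while (done < nIter) {
    m <- min(chunk, nIter - done)
    u <- matrix(runif(m * n, lo, hi), m, n)
    stat <- rowMeans(u >= bin[1L] & u < bin[2L])
    exceed <- exceed + sum(stat >= obs)
    done <- done + m
  }
  p <- (1 + exceed) / (1 + nIter)
  attr(p, "observed") <- obs
  p
}

#' Convert an inter-event interval to a frequency
#'
#' @param intervalMs interval duration in ms (> 0).
#' @return frequency in Hz (\code{1000 / intervalMs}).
#' @export
intervalToFrequency <- function(intervalMs) {
  if (any(intervalMs <= 0)) stop("interval must be positive")
  1000 / intervalMs
}

#' Cliff's delta effect size
#'
#' The normalized difference between the number of pairs where a value of
#' \code{a} exceeds a value of \code{b} and the number where it is smaller:
#' \deqn{\delta = (\#\{a_i > b_j\} - \#\{a_i < b_j\}) / (n_a n_b).}
#' It is +1 when the groups are fully separated with \code{a} larger, -1 in
#' the opposite case, and 0 for identical distributions. Small samples use
#' the literal double loop; large samples an equivalent rank-based
#' formulation.
#'
#' @param a,b numeric samples (nonempty).
#' @return delta in [-1, 1].
#' @export
cliffsDelta <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample")
  na <- length(a); nb <- length(b)
  if (as.double(na) * nb <= 250000) {
    d <- outer(a, b, `-`)
    return((sum(d > 0) - sum(d < 0)) / (na * nb))
  }
  # rank path: U = #{a>b} + ties/2, so 2U - na*nb = #{a>b} - #{a<b}
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  (2 * U - na * nb) / (na * nb)
}

#' Bootstrap confidence interval for Cliff's delta
#'
#' Percentile bootstrap: both groups are resampled with replacement
#' \code{nBoot} times and the delta recomputed; the interval is clipped to
#' [-1, 1]. A group of size 1 yields a degenerate interval and a warning.
#'
#' @param a,b numeric samples.
#' @param nBoot bootstrap resamples (default 10000).
#' @param level confidence level in percent (default 95).
#' @return list of class \code{"EffectSize"}: \code{delta}, \code{ciLow},
#'   \code{ciHigh}, \code{nBoot}.
#' @export
bootstrapCI <- function(a, b, nBoot = 10000L, level = 95) {
  if (length(a) == 1L || length(b) == 1L)
    warning("degenerate CI: a group has a single observation")
  d0 <- cliffsDelta(a, b)
  ds <- vapply(seq_len(nBoot), function(i)
    cliffsDelta(a[sample.int(length(a), replace = TRUE)],
                b[sample.int(length(b), replace = TRUE)]),
    numeric(1L))
  alpha <- (1 - level / 100) / 2
  ci <- unname(quantile(ds, c(alpha, 1 - alpha), type = 7))
  structure(list(delta = d0,
                 ciLow = max(-1, min(ci[1L], d0)),
                 ciHigh = min(1, max(ci[2L], d0)),
                 nBoot = nBoot),
            class = "EffectSize")
}

#' @export
print.EffectSize <- function(x, ...) {
  cat(sprintf("Cliff's delta = %.3f [%.3f, %.3f] (%d bootstrap resamples)\n",
              x$delta, x$ciLow, x$ciHigh, x$nBoot))
  invisible(x)
}
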