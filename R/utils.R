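# Small internal helpers shared across modules.

# Centered moving average with shrinking windows at the edges, so the output
# has the same length as the input and no NA padding.
rollMeanCentered <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n == 0L) return(x)
  k <- min(k, n)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + (k - 1L - h), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Run a function with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards, so fixture generation is reproducible
# without clobbering the session stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

# Linear interpolation across NA runs of length <= maxGap in a numeric vector.
# Longer runs (and leading/trailing NAs) are left untouched.
interpolateGaps <- function(x, maxGap = 5L) {
  isna <- is.na(x)
  if (!any(isna) || all(isna)) return(x)
  r <- rle(isna)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    if (r$lengths[i] > maxGap) next
    s <- starts[i]; e <- ends[i]
    if (s == 1L || e == length(x)) next
    x[s:e] <- approx(c(s - 1L, e + 1L), c(x[s - 1L], x[e + 1L]),
                     xout = s:e)$y
  }
  x
}

# Row-wise median of a numeric matrix, vectorized through a single sort
# (fast enough for per-pixel medians over a full frame).
rowMedians <- function(m) {
  nr <- nrow(m); k <- ncol(m)
  s <- matrix(m[order(row(m), m)], nr, k, byrow = TRUE)
  if (k %% 2L == 1L) s[, (k + 1L) %/% 2L]
  else (s[, k %/% 2L] + s[, k %/% 2L + 1L]) / 2
}

# 0-based (x, y) of the TRUE pixels of a mask, as a 2-column matrix.
maskCoords <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(matrix(numeric(0), 0L, 2L,
                                  dimnames = list(NULL, c("x", "y"))))
  nr <- nrow(mask)
  cbind(x = (idx - 1L) %/% nr, y = (idx - 1L) %% nr)
}

# Shoelace area of a polygon given as a 2-column (x, y) matrix of vertices.
polygonArea <- function(v) {
  n <- nrow(v)
  if (is.null(n) || n < 3L) return(0)
  i2 <- c(2:n, 1L)
  abs(sum(v[, 1L] * v[i2, 2L] - v[i2, 1L] * v[, 2L])) / 2
}

# Sutherland-Hodgman clipping of convex polygon `subj` by convex polygon
# `clip` (both counter-clockwise 2-column matrices). Returns the (possibly
# empty) intersection polygon.
clipConvexPolygon <- function(subj, clip) {
  ccw <- function(v) {
    n <- nrow(v); i2 <- c(2:n, 1L)
    s <- sum(v[, 1L] * v[i2, 2L] - v[i2, 1L] * v[, 2L])
    if (s < 0) v[n:1L, , drop = FALSE] else v
  }
  subj <- ccw(subj); clip <- ccw(clip)
  out <- subj
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0L) return(out)
    a <- clip[i, ]; b <- clip[if (i == nc) 1L else i + 1L, ]
    inp <- out
    out <- matrix(numeric(0), 0L, 2L)
    n <- nrow(inp)
    side <- (b[1L] - a[1L]) * (inp[, 2L] - a[2L]) -
            (b[2L] - a[2L]) * (inp[, 1L] - a[1L])
    for (j in seq_len(n)) {
      k <- if (j == n) 1L else j + 1L
      p <- inp[j, ]; q <- inp[k, ]
      pin <- side[j] >= 0; qin <- side[k] >= 0
      if (pin) out <- rbind(out, p)
      if (xor(pin, qin)) {
        t <- side[j] / (side[j] - side[k])
        out <- rbind(out, p + t * (q - p))
      }
    }
  }
  out
}

# Douglas-Peucker polyline simplification; pts is an n x 2 matrix, tol the
# maximum allowed perpendicular deviation. Returns the indices kept.
douglasPeucker <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2L) return(seq_len(n))
  keep <- rep(FALSE, n)
  keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1L]; j <- seg[2L]
    if (j - i < 2L) next
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a
    len <- sqrt(sum(ab^2))
    mid <- (i + 1L):(j - 1L)
    d <- if (len < .Machine$double.eps) {
      sqrt((pts[mid, 1L] - a[1L])^2 + (pts[mid, 2L] - a[2L])^2)
    } else {
      abs(ab[1L] * (a[2L] - pts[mid, 2L]) - (a[1L] - pts[mid, 1L]) * ab[2L]) / len
    }
    w <- which.max(d)
    if (d[w] > tol) {
      k <- mid[w]
      keep[k] <- TRUE
      stack <- c(stack, list(c(i, k)), list(c(k, j)))
    }
  }
  which(keep)
}
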