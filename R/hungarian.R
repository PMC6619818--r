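# Linear sum assignment by the Hungarian method (shortest augmenting paths
# with dual potentials, O(n^3)). Written here because the tracker needs a
# gated, rectangular variant with unassignable (forbidden) pairs.

# Large finite cost standing in for a forbidden pairing; anything at or above
# half of it in the solution is treated as "unassigned".
.LAP_BIG <- 1e12

#' Solve a (gated) linear sum assignment problem
#'
#' Minimizes the total cost of an injective assignment of rows to columns.
#' Rectangular matrices are padded internally; entries that are \code{Inf}
#' (or \code{NA}) mark forbidden pairs. Rows that can only be matched through
#' a forbidden pair are left unassigned.
#'
#' @param cost numeric matrix (rows = agents, columns = tasks).
#' @return integer vector of length \code{nrow(cost)}: the column assigned to
#'   each row, \code{NA} for unassigned rows.
#' @export
solveAssignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0L || nc == 0L) return(rep(NA_integer_, nr))
  n <- max(nr, nc)
  C <- matrix(.LAP_BIG, n, n)
  C[seq_len(nr), seq_len(nc)] <- cost
  C[!is.finite(C)] <- .LAP_BIG
  # dummy pads cost 0 so real rows prefer real columns
  if (nc < n) C[seq_len(nr), (nc + 1L):n] <- .LAP_BIG / 2
  if (nr < n) C[(nr + 1L):n, ] <- 0

  INF <- Inf
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)          # p[j+1] = row matched to column j (1-based+1)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1L]) next
        cur <- C[i0, j] - u[i0 + 1L] - v[j + 1L]
        if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
        if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
      }
      for (j in 0L:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- rep(NA_integer_, nr)
  for (j in seq_len(n)) {
    i <- p[j + 1L]
    if (i >= 1L && i <= nr && j <= nc && C[i, j] < .LAP_BIG / 4)
      assign[i] <- j
  }
  assign
}
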