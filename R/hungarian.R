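## Optimal one-to-one assignment (Hungarian algorithm, Jonker-style
## shortest augmenting paths with potentials, O(n^2 m)). Costs are
## minimized; forbidden pairs are encoded by the caller as a large finite
## cost and filtered afterwards. Ties between equal-cost optima resolve to
## the lowest row/column indices because candidates are scanned in order.
solve_assignment <- function(cost) {
  if (!is.matrix(cost) || any(!is.finite(cost))) {
    stop("'cost' must be a finite numeric matrix", call. = FALSE)
  }
  n <- nrow(cost)
  m <- ncol(cost)
  if (n == 0L || m == 0L) return(integer(0))
  transposed <- FALSE
  if (n > m) { # algorithm requires rows <= columns
    cost <- t(cost)
    n <- nrow(cost); m <- ncol(cost)
    transposed <- TRUE
  }
  u <- numeric(n)
  v <- numeric(m + 1L)       # v[j + 1], column 0 is the virtual start
  p <- integer(m + 1L)       # p[j + 1] = row assigned to column j (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          if (p[j + 1L] > 0L) u[p[j + 1L]] <- u[p[j + 1L]] + delta
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
  assign_row <- integer(n)
  for (j in seq_len(m)) {
    if (p[j + 1L] > 0L) assign_row[p[j + 1L]] <- j
  }
  if (transposed) {
    out <- integer(m)     # original rows were columns here
    out[] <- 0L
    out[assign_row] <- seq_len(n)
    out
  } else {
    assign_row
  }
}
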