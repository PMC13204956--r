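#' Minimum-cost bipartite assignment (Hungarian algorithm)
#'
#' Solves the square linear assignment problem by the O(n^3) potential /
#' shortest-augmenting-path formulation of the Kuhn-Munkres algorithm. Used
#' to relabel narrowband microstate templates against broadband anchors and
#' to assign canonical class letters, where the cost is 1 minus the absolute
#' spatial correlation.
#'
#' @param cost square numeric cost matrix; entry (i, j) is the cost of
#'   assigning row i to column j.
#' @return integer vector \code{a} with \code{a[i]} the column assigned to
#'   row i; attribute \code{cost} carries the minimal total cost.
#' @examples
#' hungarianAssign(1 - diag(4))          # identity, total cost 0
#' @export
hungarianAssign <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  if (ncol(cost) != n) stop("cost matrix must be square")
  if (!all(is.finite(cost))) stop("cost matrix must be finite")
  ## columns are offset by 1: index 1 is the virtual start column
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)        # p[j]: row currently matched to column j-1
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  a <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) a[p[j]] <- j - 1L
  total <- sum(cost[cbind(seq_len(n), a)])
  attr(a, "cost") <- total
  a
}
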