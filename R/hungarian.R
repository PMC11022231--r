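#' Minimum-cost bipartite assignment (Hungarian algorithm)
#'
#' Solves \eqn{\min_h \sum_i C[i, h(i)]} over bijections `h` by the
#' Jonker--Volkgenant shortest-augmenting-path formulation in O(n^2 m).
#' Rows index ground-truth elements, columns index predictions; rectangular
#' problems with `nrow <= ncol` assign every row to a distinct column.
#'
#' @param cost numeric matrix, `nrow(cost) <= ncol(cost)`, all entries finite.
#' @return list with `assignment` (integer vector, `assignment[i]` = column
#'   matched to row `i`) and `total_cost` (the minimized sum).
#' @examples
#' hungarian_match(matrix(c(2, 1, 1, 2), 2, byrow = TRUE))
#' @export
hungarian_match <- function(cost) {
  if (!is.matrix(cost) || !is.numeric(cost))
    stop("cost must be a numeric matrix")
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) stop("cost matrix must have nrow <= ncol")
  if (any(!is.finite(cost))) stop("cost matrix entries must be finite")

  # dual variables and column -> row assignment; index 1 is the virtual
  # column 0 of the augmenting-path formulation, real columns live at 2..m+1
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)            # p[j+1] = row assigned to column j (0 = free)
  way <- integer(m + 1)

  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free_j <- which(!used[-1L])          # candidate real columns
      cur <- cost[i0, free_j] - u[i0 + 0L] - v[free_j + 1L]
      upd <- cur < minv[free_j]
      if (any(upd)) {
        minv[free_j[upd]] <- cur[upd]
        way[free_j[upd] + 1L] <- j0
      }
      delta_j <- free_j[which.min(minv[free_j])]
      delta <- minv[delta_j]
      used_cols <- which(used)             # 1-based, includes virtual col
      rows_touched <- p[used_cols]
      u[rows_touched] <- u[rows_touched] + delta
      v[used_cols] <- v[used_cols] - delta
      minv[free_j] <- minv[free_j] - delta
      j0 <- delta_j
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }

  assignment <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  list(assignment = assignment,
       total_cost = sum(cost[cbind(seq_len(n), assignment)]))
}
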