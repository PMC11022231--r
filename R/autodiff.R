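# Reverse-mode automatic differentiation on a tape.
#
# Every differentiable quantity is a node: an environment holding `val` (a
# numeric matrix), `grad` (accumulated during the backward sweep) and `bw`
# (a closure applying the chain rule into the parents' `grad`). Operations
# executed while a tape is active are recorded in order; `ad_backward()`
# replays them in reverse. Values are plain matrices so all heavy lifting
# stays in BLAS. With no active tape the same operations run as ordinary
# forward computation (inference mode) and nodes are garbage-collected as
# they fall out of scope.

the <- new.env(parent = emptyenv())
the$tape <- NULL
the$im2col_cache <- new.env(parent = emptyenv())

#' Start recording operations on a fresh gradient tape
#'
#' @return the tape object (an environment); pass it to [ad_backward()].
#' @export
ad_tape_begin <- function() {
  tape <- new.env(parent = emptyenv())
  tape$last <- NULL          # nodes form a linked chain via $prev
  the$tape <- tape
  tape
}

#' Stop recording on the active tape
#' @export
ad_tape_end <- function() {
  the$tape <- NULL
  invisible(NULL)
}

record <- function(node) {
  tape <- the$tape
  if (is.null(tape)) return(node)
  node$prev <- tape$last
  tape$last <- node
  node
}

new_node <- function(val, bw = NULL, ng = FALSE) {
  node <- new.env(parent = emptyenv())
  node$val <- val
  node$grad <- NULL
  node$bw <- bw
  node$ng <- ng
  if (!is.null(bw)) record(node)
  node
}

#' Wrap a value as a differentiable leaf (parameter) or a constant
#'
#' Leaves accumulate gradients during [ad_backward()]; constants do not.
#' @param x numeric matrix/array.
#' @export
ad_leaf <- function(x) new_node(as_mat(x))

#' @rdname ad_leaf
#' @export
ad_const <- function(x) new_node(as_mat(x), ng = TRUE)

as_mat <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1) else x
}

add_grad <- function(node, g) {
  if (node$ng) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Value and gradient accessors
#' @param x a node.
#' @export
ad_value <- function(x) x$val

#' @rdname ad_value
#' @export
ad_grad <- function(x) x$grad

#' Run the backward sweep from a scalar root
#'
#' @param tape tape returned by [ad_tape_begin()].
#' @param root node holding a 1x1 value (the loss).
#' @export
ad_backward <- function(tape, root) {
  if (length(root$val) != 1L) stop("backward root must be scalar")
  root$grad <- matrix(1, 1, 1)
  nd <- tape$last
  while (!is.null(nd)) {
    if (!is.null(nd$grad)) nd$bw(nd$grad)
    nd <- nd$prev
  }
  invisible(NULL)
}

# ---- arithmetic ------------------------------------------------------------

ad_matmul <- function(a, b, ta = FALSE, tb = FALSE) {
  val <- if (ta && !tb) crossprod(a$val, b$val)
    else if (!ta && tb) tcrossprod(a$val, b$val)
    else if (!ta && !tb) a$val %*% b$val
    else stop("ta && tb unsupported")
  new_node(val, bw = function(g) {
    if (!ta && !tb) { add_grad(a, tcrossprod(g, b$val)); add_grad(b, crossprod(a$val, g)) }
    else if (!ta && tb) { add_grad(a, g %*% b$val); add_grad(b, crossprod(g, a$val)) }
    else { add_grad(a, tcrossprod(b$val, g)); add_grad(b, a$val %*% g) }
  })
}

ad_add <- function(a, b) new_node(a$val + b$val, bw = function(g) { add_grad(a, g); add_grad(b, g) })

ad_sub <- function(a, b) new_node(a$val - b$val, bw = function(g) { add_grad(a, g); add_grad(b, -g) })

# bias broadcast over rows: x is n x d, b holds a 1 x d row vector
ad_add_bias <- function(x, b) {
  v <- x$val
  bv <- rep(as.vector(b$val), each = nrow(v))
  new_node(v + bv, bw = function(g) {
    add_grad(x, g)
    add_grad(b, matrix(colSums(g), 1))
  })
}

ad_mul <- function(a, b) new_node(a$val * b$val, bw = function(g) {
  add_grad(a, g * b$val); add_grad(b, g * a$val)
})

ad_scale <- function(a, s) new_node(a$val * s, bw = function(g) add_grad(a, g * s))

ad_add_const <- function(a, c) new_node(a$val + c, bw = function(g) add_grad(a, g))

# ---- nonlinearities --------------------------------------------------------

ad_relu <- function(x) {
  v <- x$val * (x$val > 0)
  new_node(v, bw = function(g) add_grad(x, g * (x$val > 0)))
}

ad_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$val))
  new_node(s, bw = function(g) add_grad(x, g * s * (1 - s)))
}

ad_log <- function(x) new_node(log(x$val), bw = function(g) add_grad(x, g / x$val))

ad_exp <- function(x) {
  v <- exp(x$val)
  new_node(v, bw = function(g) add_grad(x, g * v))
}

ad_sqrt <- function(x) {
  v <- sqrt(x$val)
  new_node(v, bw = function(g) add_grad(x, g * 0.5 / v))
}

ad_recip <- function(x) {
  v <- 1 / x$val
  new_node(v, bw = function(g) add_grad(x, -g * v * v))
}

ad_abs <- function(x) new_node(abs(x$val), bw = function(g) add_grad(x, g * sign(x$val)))

ad_pmax2 <- function(a, b) {
  sel <- a$val >= b$val
  new_node(pmax(a$val, b$val), bw = function(g) {
    add_grad(a, g * sel); add_grad(b, g * (!sel))
  })
}

ad_pmin2 <- function(a, b) {
  sel <- a$val <= b$val
  new_node(pmin(a$val, b$val), bw = function(g) {
    add_grad(a, g * sel); add_grad(b, g * (!sel))
  })
}

ad_pmax_const <- function(a, c) {
  sel <- a$val >= c
  new_node(pmax(a$val, c), bw = function(g) add_grad(a, g * sel))
}

ad_softmax_rows <- function(x) {
  v <- x$val
  n <- nrow(v); d <- ncol(v)
  rmax <- v[cbind(seq_len(n), max.col(v, ties.method = "first"))]
  e <- exp(v - rmax)
  p <- e / .rowSums(e, n, d)
  new_node(p, bw = function(g) add_grad(x, p * (g - .rowSums(g * p, n, d))))
}

# fused scaled-dot-product attention head: softmax(Q K^T * scale) V.
# One node instead of five keeps tape overhead and intermediate gradient
# allocations off the training hot path; backward is the hand-derived
# composite of the matmul and softmax rules.
ad_attention <- function(q, k, v, scale) {
  S <- tcrossprod(q$val, k$val) * scale
  n <- nrow(S); m <- ncol(S)
  rmax <- S[cbind(seq_len(n), max.col(S, ties.method = "first"))]
  E <- exp(S - rmax)
  P <- E / .rowSums(E, n, m)
  node <- new_node(P %*% v$val, bw = function(g) {
    dP <- tcrossprod(g, v$val)
    add_grad(v, crossprod(P, g))
    dS <- P * (dP - .rowSums(dP * P, n, m))
    add_grad(q, (dS %*% k$val) * scale)
    add_grad(k, crossprod(dS, q$val) * scale)
  })
  attr(node, "attn") <- P
  node
}

# ---- reductions and reshapes ----------------------------------------------

ad_sum <- function(x) new_node(matrix(sum(x$val), 1, 1), bw = function(g) {
  add_grad(x, array(as.numeric(g), dim(x$val)))
})

ad_rowsums <- function(x) {
  d <- ncol(x$val)
  new_node(matrix(rowSums(x$val), ncol = 1), bw = function(g) {
    add_grad(x, matrix(g, nrow(x$val), d))
  })
}

# multiply each row of x by the scalar in the matching row of column node v
ad_scale_rows <- function(x, v) {
  vv <- as.vector(v$val)
  new_node(x$val * vv, bw = function(g) {
    add_grad(x, g * vv)
    add_grad(v, matrix(rowSums(g * x$val), ncol = 1))
  })
}

ad_rows <- function(x, idx) {
  new_node(x$val[idx, , drop = FALSE], bw = function(g) {
    dx <- matrix(0, nrow(x$val), ncol(x$val))
    rs <- rowsum(g, group = idx)
    dx[as.integer(rownames(rs)), ] <- rs
    add_grad(x, dx)
  })
}

ad_cols <- function(x, idx) {
  new_node(x$val[, idx, drop = FALSE], bw = function(g) {
    dx <- matrix(0, nrow(x$val), ncol(x$val))
    if (anyDuplicated(idx) == 0L) dx[, idx] <- g
    else for (k in seq_along(idx)) dx[, idx[k]] <- dx[, idx[k]] + g[, k]
    add_grad(x, dx)
  })
}

# gather single elements; ij is an n x 2 matrix of (row, col) indices
ad_gather <- function(x, ij) {
  new_node(matrix(x$val[ij], ncol = 1), bw = function(g) {
    dx <- matrix(0, nrow(x$val), ncol(x$val))
    for (k in seq_len(nrow(ij))) dx[ij[k, 1], ij[k, 2]] <- dx[ij[k, 1], ij[k, 2]] + g[k]
    add_grad(x, dx)
  })
}

ad_rbind <- function(nodes) {
  sizes <- vapply(nodes, function(n) nrow(n$val), integer(1))
  new_node(do.call(rbind, lapply(nodes, function(n) n$val)), bw = function(g) {
    at <- 0L
    for (k in seq_along(nodes)) {
      add_grad(nodes[[k]], g[(at + 1L):(at + sizes[k]), , drop = FALSE])
      at <- at + sizes[k]
    }
  })
}

ad_cbind <- function(nodes) {
  sizes <- vapply(nodes, function(n) ncol(n$val), integer(1))
  new_node(do.call(cbind, lapply(nodes, function(n) n$val)), bw = function(g) {
    at <- 0L
    for (k in seq_along(nodes)) {
      add_grad(nodes[[k]], g[, (at + 1L):(at + sizes[k]), drop = FALSE])
      at <- at + sizes[k]
    }
  })
}

# ---- layer normalization ---------------------------------------------------

ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  d <- ncol(x$val)
  mu <- rowMeans(x$val)
  xc <- x$val - mu
  sd_ <- sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc / sd_
  gv <- as.vector(gamma$val)
  val <- xhat * matrix(gv, nrow(x$val), d, byrow = TRUE) +
    matrix(as.vector(beta$val), nrow(x$val), d, byrow = TRUE)
  new_node(val, bw = function(g) {
    add_grad(gamma, matrix(colSums(g * xhat), 1))
    add_grad(beta, matrix(colSums(g), 1))
    dxhat <- g * matrix(gv, nrow(g), d, byrow = TRUE)
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / sd_
    add_grad(x, dx)
  })
}

# ---- convolution via im2col ------------------------------------------------

# Feature maps are stored as (h*w) x C matrices in row-major spatial order
# (row y, column x -> matrix row (y-1)*w + x). im2col gathers the k x k
# neighbourhood of every (strided) output cell into one wide matrix so the
# convolution itself is a single GEMM against a (k^2*Cin) x Cout weight.
im2col_index <- function(h, w, k, stride, pad) {
  key <- paste(h, w, k, stride, pad, sep = "_")
  cached <- the$im2col_cache[[key]]
  if (!is.null(cached)) return(cached)
  h_out <- (h + 2L * pad - k) %/% stride + 1L
  w_out <- (w + 2L * pad - k) %/% stride + 1L
  yo <- rep(seq_len(h_out), each = w_out)
  xo <- rep(seq_len(w_out), times = h_out)
  n_out <- h_out * w_out
  idx <- matrix(0L, n_out, k * k)
  zero_row <- h * w + 1L
  o <- 0L
  for (dy in 0:(k - 1L)) for (dx in 0:(k - 1L)) {
    o <- o + 1L
    yi <- (yo - 1L) * stride + dy - pad + 1L
    xi <- (xo - 1L) * stride + dx - pad + 1L
    ok <- yi >= 1L & yi <= h & xi >= 1L & xi <= w
    idx[, o] <- ifelse(ok, (yi - 1L) * w + xi, zero_row)
  }
  out <- list(idx = as.vector(idx), n_out = n_out, h_out = h_out,
              w_out = w_out, k2 = k * k)
  the$im2col_cache[[key]] <- out
  out
}

ad_im2col <- function(x, h, w, k, stride, pad = k %/% 2L) {
  ix <- im2col_index(h, w, k, stride, pad)
  cin <- ncol(x$val)
  xa <- rbind(x$val, 0)
  G <- xa[ix$idx, , drop = FALSE]
  val <- G
  dim(val) <- c(ix$n_out, ix$k2 * cin)
  node <- new_node(val, bw = function(g) {
    dim(g) <- c(ix$n_out * ix$k2, cin)
    rs <- rowsum(g, group = ix$idx)
    keep <- as.integer(rownames(rs))
    dx <- matrix(0, h * w, cin)
    real <- keep <= h * w
    dx[keep[real], ] <- rs[real, , drop = FALSE]
    add_grad(x, dx)
  })
  attr(node, "h_out") <- ix$h_out
  attr(node, "w_out") <- ix$w_out
  node
}
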