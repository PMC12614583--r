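# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every intermediate value is a node: an environment holding the forward
# value (`val`, always a base matrix), an accumulated gradient (`grad`),
# and a backward closure (`bw`) that scatters the node's gradient into its
# parents. Nodes are recorded on a tape in creation order; the backward
# pass walks the tape in reverse. Constant nodes (`const = TRUE`) never
# receive gradients, which keeps the backward pass cheap for data inputs.
#
# The engine is deliberately small: only the operations the dual-branch
# model needs are implemented, and each op's gradient is exercised by
# finite-difference checks in the test suite.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

ad_tape_start <- function() {
  .ad$tape <- new.env(parent = emptyenv())
  .ad$tape$nodes <- vector("list", 512L)
  .ad$tape$n <- 0L
  invisible(.ad$tape)
}

ad_tape_stop <- function() {
  .ad$tape <- NULL
  invisible(NULL)
}

ad_record <- function(node) {
  tape <- .ad$tape
  if (is.null(tape)) return(node)
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- node
  tape$n <- n
  node
}

as_ad_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

ad_node <- function(val, bw = NULL, const = FALSE) {
  node <- new.env(parent = emptyenv())
  node$val <- val
  node$grad <- NULL
  node$bw <- bw
  node$const <- const
  ad_record(node)
}

#' @noRd
ad_const <- function(x) ad_node(as_ad_matrix(x), const = TRUE)

#' @noRd
ad_leaf <- function(x) ad_node(as_ad_matrix(x))

ad_is_node <- function(x) is.environment(x) && !is.null(x$val)

acc_grad <- function(node, g) {
  if (node$const) return(invisible(NULL))
  if (is.null(node$grad)) {
    node$grad <- g
  } else {
    node$grad <- node$grad + g
  }
  invisible(NULL)
}

#' Run the backward pass from a scalar loss node
#'
#' Walks the active tape in reverse creation order and accumulates
#' gradients into every non-constant node. The loss must be a 1 x 1 node
#' recorded on the active tape.
#' @noRd
ad_backward <- function(loss) {
  tape <- .ad$tape
  if (is.null(tape)) stop("ad_backward() requires an active tape", call. = FALSE)
  if (length(loss$val) != 1L) stop("loss must be scalar", call. = FALSE)
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq(tape$n, 1L)) {
    node <- tape$nodes[[i]]
    if (!is.null(node$bw) && !is.null(node$grad)) node$bw(node$grad)
  }
  invisible(NULL)
}

# ---- elementwise and linear ops ------------------------------------------

ad_add <- function(a, b) {
  node <- ad_node(a$val + b$val)
  node$bw <- function(g) { acc_grad(a, g); acc_grad(b, g) }
  node
}

ad_sub <- function(a, b) {
  node <- ad_node(a$val - b$val)
  node$bw <- function(g) { acc_grad(a, g); if (!b$const) acc_grad(b, -g) }
  node
}

ad_mul <- function(a, b) {
  node <- ad_node(a$val * b$val)
  node$bw <- function(g) {
    if (!a$const) acc_grad(a, g * b$val)
    if (!b$const) acc_grad(b, g * a$val)
  }
  node
}

ad_scale <- function(x, k) {
  node <- ad_node(x$val * k)
  node$bw <- function(g) acc_grad(x, g * k)
  node
}

# x scaled by a 1x1 scalar node s
ad_scale_node <- function(x, s) {
  node <- ad_node(x$val * s$val[1L])
  node$bw <- function(g) {
    acc_grad(x, g * s$val[1L])
    acc_grad(s, matrix(sum(g * x$val), 1L, 1L))
  }
  node
}

ad_matmul <- function(a, b) {
  node <- ad_node(a$val %*% b$val)
  node$bw <- function(g) {
    if (!a$const) acc_grad(a, tcrossprod(g, b$val))
    if (!b$const) acc_grad(b, crossprod(a$val, g))
  }
  node
}

# a %*% t(b)
ad_matmul_tb <- function(a, b) {
  node <- ad_node(tcrossprod(a$val, b$val))
  node$bw <- function(g) {
    if (!a$const) acc_grad(a, g %*% b$val)
    if (!b$const) acc_grad(b, crossprod(g, a$val))
  }
  node
}

# add a 1 x ncol(x) bias row to every row of x
ad_add_bias <- function(x, b) {
  node <- ad_node(sweep(x$val, 2L, as.vector(b$val), "+"))
  node$bw <- function(g) {
    acc_grad(x, g)
    acc_grad(b, matrix(colSums(g), 1L))
  }
  node
}

ad_relu <- function(x) {
  keep <- x$val > 0
  node <- ad_node(x$val * keep)
  node$bw <- function(g) acc_grad(x, g * keep)
  node
}

ad_softplus <- function(x) {
  v <- x$val
  node <- ad_node(pmax(v, 0) + log1p(exp(-abs(v))))
  node$bw <- function(g) acc_grad(x, g * stats::plogis(v))
  node
}

ad_log <- function(x) {
  node <- ad_node(log(x$val))
  node$bw <- function(g) acc_grad(x, g / x$val)
  node
}

# ---- normalizations -------------------------------------------------------

ad_softmax_rows <- function(x) {
  v <- x$val
  m <- v[cbind(seq_len(nrow(v)), max.col(v, ties.method = "first"))]
  e <- exp(v - m)          # recycles m down columns: e[i, j] = exp(v[i,j] - m[i])
  p <- e / rowSums(e)
  node <- ad_node(p)
  node$bw <- function(g) acc_grad(x, (g - rowSums(g * p)) * p)
  node
}

# rows divided by their sums (entries assumed positive)
ad_rownorm <- function(x) {
  s <- rowSums(x$val)
  p <- x$val / s
  node <- ad_node(p)
  node$bw <- function(g) acc_grad(x, g / s - (rowSums(g * x$val) / s^2))
  node
}

# row-wise layer normalization with learnable gain/offset (1 x d nodes)
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  v <- x$val
  mu <- rowMeans(v)
  cent <- v - mu
  var <- rowMeans(cent^2)
  sd <- sqrt(var + eps)
  xhat <- cent / sd
  gv <- as.vector(gamma$val)
  y <- sweep(xhat, 2L, gv, "*")
  y <- sweep(y, 2L, as.vector(beta$val), "+")
  node <- ad_node(y)
  node$bw <- function(g) {
    dxhat <- sweep(g, 2L, gv, "*")
    acc_grad(gamma, matrix(colSums(g * xhat), 1L))
    acc_grad(beta, matrix(colSums(g), 1L))
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / sd
    acc_grad(x, dx)
  }
  node
}

# ---- shape ops ------------------------------------------------------------

ad_mean_rows <- function(x) {
  tn <- nrow(x$val)
  node <- ad_node(matrix(colMeans(x$val), 1L))
  node$bw <- function(g) acc_grad(x, matrix(g / tn, tn, ncol(x$val), byrow = TRUE))
  node
}

ad_rows <- function(x, idx) {
  node <- ad_node(x$val[idx, , drop = FALSE])
  node$bw <- function(g) {
    dx <- matrix(0, nrow(x$val), ncol(x$val))
    dx[idx, ] <- g
    acc_grad(x, dx)
  }
  node
}

ad_cols <- function(x, idx) {
  node <- ad_node(x$val[, idx, drop = FALSE])
  node$bw <- function(g) {
    dx <- matrix(0, nrow(x$val), ncol(x$val))
    dx[, idx] <- g
    acc_grad(x, dx)
  }
  node
}

ad_cbind <- function(parts) {
  widths <- vapply(parts, function(p) ncol(p$val), integer(1))
  node <- ad_node(do.call(cbind, lapply(parts, function(p) p$val)))
  node$bw <- function(g) {
    at <- 0L
    for (k in seq_along(parts)) {
      acc_grad(parts[[k]], g[, at + seq_len(widths[k]), drop = FALSE])
      at <- at + widths[k]
    }
  }
  node
}

ad_rbind <- function(parts) {
  heights <- vapply(parts, function(p) nrow(p$val), integer(1))
  node <- ad_node(do.call(rbind, lapply(parts, function(p) p$val)))
  node$bw <- function(g) {
    at <- 0L
    for (k in seq_along(parts)) {
      acc_grad(parts[[k]], g[at + seq_len(heights[k]), , drop = FALSE])
      at <- at + heights[k]
    }
  }
  node
}

ad_add_list <- function(parts) {
  node <- ad_node(Reduce(`+`, lapply(parts, function(p) p$val)))
  node$bw <- function(g) for (p in parts) acc_grad(p, g)
  node
}

# kronecker(K, x) with K a constant matrix and x a node
ad_kron <- function(K, x) {
  m <- nrow(x$val); n <- ncol(x$val)
  rK <- rep(seq_len(nrow(K)), each = m); cK <- rep(seq_len(ncol(K)), each = n)
  rX <- rep(seq_len(m), nrow(K)); cX <- rep(seq_len(n), ncol(K))
  node <- ad_node(K[rK, cK, drop = FALSE] * x$val[rX, cX, drop = FALSE])
  node$bw <- function(g) {
    # dx[a, b] = sum_{i,j} K[i, j] * g[(i-1)m + a, (j-1)n + b]
    g4 <- aperm(array(g, c(m, nrow(K), n, ncol(K))), c(1L, 3L, 2L, 4L))
    dx <- matrix(g4, m * n, length(K)) %*% as.vector(K)
    acc_grad(x, matrix(dx, m, n))
  }
  node
}
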