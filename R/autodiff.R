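# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every differentiable quantity is an `adnode`: an environment holding a
# numeric matrix `val`, an accumulated gradient `grad`, and a backward
# closure `back` that routes the incoming gradient to the node's parents.
# Operations are mixed-mode: when no argument is an adnode they compute on
# plain matrices and return a plain matrix, so the same forward code serves
# both gradient-free evaluation and training.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL
.ad$n <- 0L

#' Start recording operations on a fresh tape
#'
#' Subsequent `ad_*` operations on adnodes register backward closures on the
#' tape until [ad_backward()] or another `ad_tape_start()` call.
#' @return invisibly, NULL
#' @keywords internal
ad_tape_start <- function() {
  .ad$tape <- vector("list", 512L)
  .ad$n <- 0L
  invisible(NULL)
}

ad_tape_stop <- function() {
  .ad$tape <- NULL
  .ad$n <- 0L
  invisible(NULL)
}

.ad_record <- function(e) {
  n <- .ad$n + 1L
  if (n > length(.ad$tape)) .ad$tape <- c(.ad$tape, vector("list", length(.ad$tape)))
  .ad$tape[[n]] <- e
  .ad$n <- n
  e
}

.ad_new <- function(val, back = NULL) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  e$back <- back
  class(e) <- "adnode"
  .ad_record(e)
}

#' Create a leaf parameter node
#'
#' Leaves live off-tape: their gradients survive [ad_backward()] and are
#' consumed/zeroed by the optimizer.
#' @param val numeric matrix or vector (vectors become column matrices)
#' @return an `adnode`
#' @keywords internal
ad_param <- function(val) {
  if (is.null(dim(val))) val <- matrix(val, ncol = 1L)
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  e$back <- NULL
  class(e) <- "adnode"
  e
}

# adnodes are the only environments flowing through the ops, so the cheap
# primitive check stands in for inherits()
is_adnode <- function(x) is.environment(x)

#' Value of a node or plain matrix
#' @keywords internal
ad_val <- function(x) if (is.environment(x)) x$val else x

.ad_acc <- function(x, g) {
  if (is.environment(x)) x$grad <- if (is.null(x$grad)) g else x$grad + g
  invisible(NULL)
}

#' Run backpropagation from a scalar loss node
#' @param loss adnode holding a 1x1 value
#' @keywords internal
ad_backward <- function(loss) {
  stopifnot(is_adnode(loss), length(loss$val) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  tape <- .ad$tape
  for (i in rev(seq_len(.ad$n))) {
    e <- tape[[i]]
    if (!is.null(e$grad) && !is.null(e$back)) e$back(e$grad)
  }
  invisible(NULL)
}

.any_node <- function(...) {
  for (x in list(...)) if (is_adnode(x)) return(TRUE)
  FALSE
}

# ---- arithmetic ----

ad_matmul <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  v <- av %*% bv
  if (!.any_node(a, b)) return(v)
  .ad_new(v, function(g) {
    if (is_adnode(a)) .ad_acc(a, g %*% t(bv))
    if (is_adnode(b)) .ad_acc(b, t(av) %*% g)
  })
}

ad_add <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  v <- av + bv
  if (!.any_node(a, b)) return(v)
  .ad_new(v, function(g) {
    .ad_acc(a, g)
    .ad_acc(b, g)
  })
}

ad_sub <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  v <- av - bv
  if (!.any_node(a, b)) return(v)
  .ad_new(v, function(g) {
    .ad_acc(a, g)
    .ad_acc(b, -g)
  })
}

# add a row vector (1 x d or length-d) to every row of a matrix (bias)
ad_add_rowvec <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  bvec <- as.numeric(bv)
  v <- av + matrix(bvec, nrow(av), ncol(av), byrow = TRUE)
  if (!.any_node(a, b)) return(v)
  .ad_new(v, function(g) {
    .ad_acc(a, g)
    if (is_adnode(b)) {
      gb <- colSums(g)
      .ad_acc(b, matrix(gb, nrow(b$val), ncol(b$val)))
    }
  })
}

ad_mul <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  v <- av * bv
  if (!.any_node(a, b)) return(v)
  .ad_new(v, function(g) {
    if (is_adnode(a)) .ad_acc(a, g * bv)
    if (is_adnode(b)) .ad_acc(b, g * av)
  })
}

# multiply every row of matrix a (n x d) by row vector q (length d)
ad_mul_rowvec <- function(a, q) {
  av <- ad_val(a); qv <- as.numeric(ad_val(q))
  qm <- matrix(qv, nrow(av), ncol(av), byrow = TRUE)
  v <- av * qm
  if (!.any_node(a, q)) return(v)
  .ad_new(v, function(g) {
    if (is_adnode(a)) .ad_acc(a, g * qm)
    if (is_adnode(q)) {
      gq <- colSums(g * av)
      .ad_acc(q, matrix(gq, nrow(q$val), ncol(q$val)))
    }
  })
}

ad_scale <- function(a, s) {
  av <- ad_val(a)
  v <- av * s
  if (!is_adnode(a)) return(v)
  .ad_new(v, function(g) .ad_acc(a, g * s))
}

ad_transpose <- function(a) {
  av <- ad_val(a)
  v <- t(av)
  if (!is_adnode(a)) return(v)
  .ad_new(v, function(g) .ad_acc(a, t(g)))
}

# ---- activations ----

ad_relu <- function(a) {
  av <- ad_val(a)
  v <- pmax(av, 0)
  if (!is_adnode(a)) return(v)
  .ad_new(v, function(g) .ad_acc(a, g * (av > 0)))
}

ad_leaky_relu <- function(a, alpha = 0.2) {
  av <- ad_val(a)
  pos <- av > 0
  v <- av * (pos + alpha * !pos)
  if (!is_adnode(a)) return(v)
  .ad_new(v, function(g) .ad_acc(a, g * (pos + alpha * !pos)))
}

ad_elu <- function(a, alpha = 1) {
  av <- ad_val(a)
  pos <- av > 0
  ex <- exp(pmin(av, 0))
  v <- av * pos + alpha * (ex - 1) * !pos
  if (!is_adnode(a)) return(v)
  .ad_new(v, function(g) .ad_acc(a, g * (pos + alpha * ex * !pos)))
}

ad_sigmoid <- function(a) {
  av <- ad_val(a)
  v <- 1 / (1 + exp(-av))
  if (!is_adnode(a)) return(v)
  .ad_new(v, function(g) .ad_acc(a, g * v * (1 - v)))
}

ad_tanh <- function(a) {
  av <- ad_val(a)
  v <- tanh(av)
  if (!is_adnode(a)) return(v)
  .ad_new(v, function(g) .ad_acc(a, g * (1 - v^2)))
}

ad_exp <- function(a) {
  av <- ad_val(a)
  v <- exp(av)
  if (!is_adnode(a)) return(v)
  .ad_new(v, function(g) .ad_acc(a, g * v))
}

ad_square <- function(a) {
  av <- ad_val(a)
  v <- av^2
  if (!is_adnode(a)) return(v)
  .ad_new(v, function(g) .ad_acc(a, 2 * g * av))
}

# ---- normalizations ----

#' Row-wise softmax with optional additive mask
#'
#' `mask` is a plain matrix of the same shape added to the logits (use large
#' negative entries to exclude positions); it never receives gradient.
#' @keywords internal
ad_softmax_rows <- function(a, mask = NULL) {
  av <- ad_val(a)
  if (!is.null(mask)) av <- av + mask
  m <- av[cbind(seq_len(nrow(av)), max.col(av, ties.method = "first"))]
  ex <- exp(av - m)
  v <- ex / rowSums(ex)
  if (!is_adnode(a)) return(v)
  .ad_new(v, function(g) {
    dot <- rowSums(g * v)
    .ad_acc(a, (g - dot) * v)
  })
}

# per-row layer normalization with learned gain/shift (length-d vectors)
ad_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  av <- ad_val(a)
  mu <- rowMeans(av)
  xc <- av - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  gv <- as.numeric(ad_val(gamma)); bv <- as.numeric(ad_val(beta))
  gm <- matrix(gv, nrow(av), ncol(av), byrow = TRUE)
  v <- xhat * gm + matrix(bv, nrow(av), ncol(av), byrow = TRUE)
  if (!.any_node(a, gamma, beta)) return(v)
  .ad_new(v, function(g) {
    if (is_adnode(gamma)) .ad_acc(gamma, matrix(colSums(g * xhat), ncol = 1L))
    if (is_adnode(beta)) .ad_acc(beta, matrix(colSums(g), ncol = 1L))
    if (is_adnode(a)) {
      d <- ncol(av)
      gx <- g * gm
      gs <- rowSums(gx)
      gxx <- rowSums(gx * xhat)
      .ad_acc(a, inv * (gx - gs / d - xhat * gxx / d))
    }
  })
}

# per-column (channel) normalization over a subset of rows; rows outside
# `rows` are zeroed.  Deterministic stand-in for 1-D batch norm.
ad_norm_cols <- function(a, gamma, beta, rows = NULL, eps = 1e-5) {
  av <- ad_val(a)
  n <- nrow(av)
  if (is.null(rows)) rows <- seq_len(n)
  x <- av[rows, , drop = FALSE]
  m <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, "-")
  va <- colMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2L, inv, "*")
  gv <- as.numeric(ad_val(gamma)); bv <- as.numeric(ad_val(beta))
  out <- matrix(0, n, ncol(av))
  out[rows, ] <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  if (!.any_node(a, gamma, beta)) return(out)
  .ad_new(out, function(g) {
    gr <- g[rows, , drop = FALSE]
    if (is_adnode(gamma)) .ad_acc(gamma, matrix(colSums(gr * xhat), ncol = 1L))
    if (is_adnode(beta)) .ad_acc(beta, matrix(colSums(gr), ncol = 1L))
    if (is_adnode(a)) {
      gx <- sweep(gr, 2L, gv, "*")
      gs <- colSums(gx)
      gxx <- colSums(gx * xhat)
      gin <- sweep(gx, 2L, gs / m, "-") - sweep(xhat, 2L, gxx / m, "*")
      gin <- sweep(gin, 2L, inv, "*")
      full <- matrix(0, n, ncol(av))
      full[rows, ] <- gin
      .ad_acc(a, full)
    }
  })
}

# ---- structural ops ----

ad_rbind <- function(...) {
  args <- list(...)
  vals <- lapply(args, ad_val)
  v <- do.call(rbind, vals)
  if (!any(vapply(args, is_adnode, logical(1)))) return(v)
  rows <- vapply(vals, nrow, integer(1))
  ends <- cumsum(rows)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  .ad_new(v, function(g) {
    for (i in seq_along(args)) {
      if (is_adnode(args[[i]])) .ad_acc(args[[i]], g[starts[i]:ends[i], , drop = FALSE])
    }
  })
}

ad_cbind <- function(...) {
  args <- list(...)
  vals <- lapply(args, ad_val)
  v <- do.call(cbind, vals)
  if (!any(vapply(args, is_adnode, logical(1)))) return(v)
  cols <- vapply(vals, ncol, integer(1))
  ends <- cumsum(cols)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  .ad_new(v, function(g) {
    for (i in seq_along(args)) {
      if (is_adnode(args[[i]])) .ad_acc(args[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

ad_rows <- function(a, idx) {
  av <- ad_val(a)
  v <- av[idx, , drop = FALSE]
  if (!is_adnode(a)) return(v)
  nr <- nrow(av); nc <- ncol(av)
  .ad_new(v, function(g) {
    z <- matrix(0, nr, nc)
    acc <- rowsum(g, group = idx)
    z[as.integer(rownames(acc)), ] <- acc
    .ad_acc(a, z)
  })
}

# select columns (forward slice, backward zero-scatter)
ad_cols <- function(a, idx) {
  av <- ad_val(a)
  v <- av[, idx, drop = FALSE]
  if (!is_adnode(a)) return(v)
  nr <- nrow(av); nc <- ncol(av)
  .ad_new(v, function(g) {
    z <- matrix(0, nr, nc)
    z[, idx] <- g
    .ad_acc(a, z)
  })
}

# zero-pad a matrix with extra columns on the right, to n_total columns
ad_pad_cols <- function(a, n_total) {
  av <- ad_val(a)
  nc <- ncol(av)
  stopifnot(n_total >= nc)
  v <- cbind(av, matrix(0, nrow(av), n_total - nc))
  if (!is_adnode(a)) return(v)
  .ad_new(v, function(g) .ad_acc(a, g[, seq_len(nc), drop = FALSE]))
}

# zero-pad a matrix with extra rows below, to n_total rows
ad_pad_rows <- function(a, n_total) {
  av <- ad_val(a)
  n <- nrow(av)
  stopifnot(n_total >= n)
  v <- rbind(av, matrix(0, n_total - n, ncol(av)))
  if (!is_adnode(a)) return(v)
  .ad_new(v, function(g) .ad_acc(a, g[seq_len(n), , drop = FALSE]))
}

ad_reshape <- function(a, nrow_new, ncol_new) {
  av <- ad_val(a)
  v <- matrix(as.numeric(av), nrow_new, ncol_new)
  if (!is_adnode(a)) return(v)
  nr <- nrow(av); nc <- ncol(av)
  .ad_new(v, function(g) .ad_acc(a, matrix(as.numeric(g), nr, nc)))
}

# insert (stride - 1) zero rows between consecutive rows (deconv upsampling)
ad_upsample_zeros <- function(a, stride) {
  av <- ad_val(a)
  n <- nrow(av)
  pos <- (seq_len(n) - 1L) * stride + 1L
  v <- matrix(0, n * stride, ncol(av))
  v[pos, ] <- av
  if (!is_adnode(a)) return(v)
  .ad_new(v, function(g) .ad_acc(a, g[pos, , drop = FALSE]))
}

# ---- convolution ----

#' 1-D convolution over rows (positions) with same-length zero padding
#'
#' `x` is positions x channels_in, `w` is (kernel*channels_in) x channels_out
#' laid out kernel-offset-major (offset 0 rows first), `b` length channels_out.
#' Stride 1; output has `nrow(x)` rows.
#' @keywords internal
ad_conv1d <- function(x, w, b = NULL, kernel = 3L) {
  xv <- ad_val(x); wv <- ad_val(w)
  n <- nrow(xv); dci <- ncol(xv)
  stopifnot(nrow(wv) == kernel * dci)
  p <- (kernel - 1L) %/% 2L
  pr <- kernel - 1L - p  # right pad (kernel may be even)
  xp <- rbind(matrix(0, p, dci), xv, matrix(0, pr, dci))
  cols <- vector("list", kernel)
  for (o in seq_len(kernel)) cols[[o]] <- xp[o:(n + o - 1L), , drop = FALSE]
  xcol <- do.call(cbind, cols)
  v <- xcol %*% wv
  if (!is.null(b)) v <- sweep(v, 2L, as.numeric(ad_val(b)), "+")
  if (!.any_node(x, w, b)) return(v)
  .ad_new(v, function(g) {
    if (is_adnode(w)) .ad_acc(w, t(xcol) %*% g)
    if (!is.null(b) && is_adnode(b)) .ad_acc(b, matrix(colSums(g), ncol = 1L))
    if (is_adnode(x)) {
      gw <- g %*% t(wv)  # n x (kernel*dci)
      gxp <- matrix(0, n + kernel - 1L, dci)
      for (o in seq_len(kernel)) {
        blk <- gw[, ((o - 1L) * dci + 1L):(o * dci), drop = FALSE]
        gxp[o:(n + o - 1L), ] <- gxp[o:(n + o - 1L), ] + blk
      }
      .ad_acc(x, gxp[(p + 1L):(p + n), , drop = FALSE])
    }
  })
}

# ---- pooling / reductions ----

# column-wise max over a subset of rows -> 1 x d row vector
ad_maxpool_cols <- function(a, rows = NULL) {
  av <- ad_val(a)
  if (is.null(rows)) rows <- seq_len(nrow(av))
  x <- av[rows, , drop = FALSE]
  idx <- max.col(t(x), ties.method = "first")
  d <- ncol(av)
  v <- matrix(x[cbind(idx, seq_len(d))], 1L, d)
  if (!is_adnode(a)) return(v)
  nr <- nrow(av)
  .ad_new(v, function(g) {
    z <- matrix(0, nr, d)
    z[cbind(rows[idx], seq_len(d))] <- as.numeric(g)
    .ad_acc(a, z)
  })
}

# non-overlapping temporal max pooling over rows (width w, floor division)
ad_maxpool1d <- function(a, width) {
  av <- ad_val(a)
  n <- nrow(av); d <- ncol(av)
  m <- n %/% width
  stopifnot(m >= 1L)
  base <- (seq_len(m) - 1L) * width
  slices <- lapply(seq_len(width), function(o) av[base + o, , drop = FALSE])
  v <- Reduce(pmax, slices)
  arg <- matrix(0L, m, d)           # winning absolute row per (group, channel)
  for (o in rev(seq_len(width))) {
    hit <- slices[[o]] == v
    arg[hit] <- (base + o)[row(arg)[hit]]
  }
  if (!is_adnode(a)) return(v)
  .ad_new(v, function(g) {
    z <- matrix(0, n, d)
    # winners are unique cells (groups cover disjoint row ranges)
    z[cbind(as.integer(arg), rep(seq_len(d), each = m))] <- as.numeric(g)
    .ad_acc(a, z)
  })
}

# column means over a subset of rows -> 1 x d
ad_meanpool_cols <- function(a, rows = NULL) {
  av <- ad_val(a)
  if (is.null(rows)) rows <- seq_len(nrow(av))
  m <- length(rows)
  v <- matrix(colMeans(av[rows, , drop = FALSE]), 1L)
  if (!is_adnode(a)) return(v)
  nr <- nrow(av); d <- ncol(av)
  .ad_new(v, function(g) {
    z <- matrix(0, nr, d)
    z[rows, ] <- matrix(as.numeric(g) / m, m, d, byrow = TRUE)
    .ad_acc(a, z)
  })
}

ad_sum <- function(a) {
  av <- ad_val(a)
  v <- matrix(sum(av), 1L, 1L)
  if (!is_adnode(a)) return(v)
  dims <- dim(av)
  .ad_new(v, function(g) .ad_acc(a, matrix(as.numeric(g), dims[1], dims[2])))
}

ad_mean <- function(a) {
  av <- ad_val(a)
  v <- matrix(mean(av), 1L, 1L)
  if (!is_adnode(a)) return(v)
  dims <- dim(av)
  .ad_new(v, function(g) .ad_acc(a, matrix(as.numeric(g) / prod(dims), dims[1], dims[2])))
}

# elementwise rectified-wing penalty (see rwing_loss for the scalar wrapper)
ad_rwing_elem <- function(a, r_thresh, w, eps) {
  av <- ad_val(a)
  C <- w - w * log(1 + (w - r_thresh) / eps)
  ax <- abs(av)
  v <- ifelse(ax < r_thresh, 0,
       ifelse(ax < w, w * log(1 + (ax - r_thresh) / eps), ax - C))
  if (!is_adnode(a)) return(v)
  .ad_new(v, function(g) {
    d <- ifelse(ax < r_thresh, 0,
         ifelse(ax < w, w / (eps + ax - r_thresh), 1)) * sign(av)
    .ad_acc(a, g * d)
  })
}

# ---- parameter utilities ----

#' Recursively convert a (nested list of) numeric arrays into ad_param leaves
#' @keywords internal
ad_params <- function(x) {
  if (is.list(x)) return(lapply(x, ad_params))
  if (is.integer(x) || is.character(x)) return(x)  # structural metadata
  ad_param(x)
}

#' Flatten a nested parameter list into a flat list of adnodes
#' @keywords internal
ad_param_list <- function(x) {
  out <- list()
  walk <- function(y) {
    if (is_adnode(y)) out[[length(out) + 1L]] <<- y
    else if (is.list(y)) for (e in y) walk(e)
  }
  walk(x)
  out
}

#' Recursively extract plain values from a parameter tree
#' @keywords internal
ad_values <- function(x) {
  if (is.list(x)) return(lapply(x, ad_values))
  if (is.integer(x) || is.character(x)) return(x)
  ad_val(x)
}

# ---- Adam optimizer ----

#' Create an Adam optimizer over a flat list of parameter nodes
#' @keywords internal
adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$b1 <- beta1; st$b2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(params, function(p) array(0, dim(p$val)))
  st$v <- lapply(params, function(p) array(0, dim(p$val)))
  st
}

#' One Adam step; consumes and zeroes accumulated gradients
#' @keywords internal
adam_step <- function(st, grad_scale = 1) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$b1^st$t
  bc2 <- 1 - st$b2^st$t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad * grad_scale
    st$m[[i]] <- st$b1 * st$m[[i]] + (1 - st$b1) * g
    st$v[[i]] <- st$b2 * st$v[[i]] + (1 - st$b2) * g^2
    mh <- st$m[[i]] / bc1
    vh <- st$v[[i]] / bc2
    p$val <- p$val - st$lr * mh / (sqrt(vh) + st$eps)
    p$grad <- NULL
  }
  invisible(NULL)
}

#' Glorot-uniform weight initialization
#' @keywords internal
glorot <- function(nr, nc, fan_in = nr, fan_out = nc) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}
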