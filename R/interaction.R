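# Pairwise representation learning: ligand kernel + response vector, binding
# region assembly BR = r U s, bilinear interaction maps, attention fusion,
# and the affinity head.

#' Interaction module configuration
#'
#' @param kernel_len L_s, length of the ligand kernel (odd recommended; used
#'   as a centred 1-D correlation filter over protein positions)
#' @param channels C, bilinear attention channels
#' @param out_dim L, fused interaction feature width
#' @param response_mode `"correlation"` (default; K_l slides over positions)
#'   or `"literal"` (r_i = sum(K_l) * proj(F_p)_i, the printed index-free
#'   reading)
#' @param br_mode `"max"` (union of evidence, default) or `"min"`
#'   (intersection) for combining r and s
#' @return list of class `interaction_config`
#' @export
interaction_config <- function(kernel_len = 9L, channels = 64L, out_dim = 256L,
                               response_mode = c("correlation", "literal"),
                               br_mode = c("max", "min")) {
  stopifnot(kernel_len >= 1, channels >= 1, out_dim >= 1)
  structure(list(kernel_len = as.integer(kernel_len),
                 channels = as.integer(channels), out_dim = as.integer(out_dim),
                 response_mode = match.arg(response_mode),
                 br_mode = match.arg(br_mode)),
            class = "interaction_config")
}

#' Initialize interaction weights
#'
#' @param cfg an [interaction_config()]
#' @param dims list with ligand/protein map widths `L_g`, `L_c`, `L_t`, `d_p`
#'   (protein feature-map channels) and fixed ligand-axis capacities
#'   `cap_g`, `cap_c`, `cap_t`
#' @return nested list of plain matrices
#' @export
init_interaction_weights <- function(cfg, dims) {
  C <- cfg$channels; L <- cfg$out_dim; Ls <- cfg$kernel_len
  Ktot <- dims$cap_g + dims$cap_c + dims$cap_t
  list(
    kernel_proj = list(W = glorot(dims$L_g + dims$L_c + dims$L_t, Ls),
                       b = matrix(0, Ls, 1L)),
    w_bs = glorot(dims$d_p, 1L),
    bil_g = list(U = glorot(dims$d_p, C), V = glorot(dims$L_g, C), q = matrix(stats::runif(C, -0.1, 0.1), C, 1L)),
    bil_c = list(U = glorot(dims$d_p, C), V = glorot(dims$L_c, C), q = matrix(stats::runif(C, -0.1, 0.1), C, 1L)),
    bil_t = list(U = glorot(dims$d_p, C), V = glorot(dims$L_t, C), q = matrix(stats::runif(C, -0.1, 0.1), C, 1L)),
    W_a = glorot(Ktot, Ktot), W_m = glorot(Ktot, Ktot),
    fuse_fc = list(W = glorot(Ktot, L), b = matrix(0, L, 1L)),
    head = list(fc1 = list(W = glorot(L, max(1L, L %/% 2L)), b = matrix(0, max(1L, L %/% 2L), 1L)),
                fc2 = list(W = glorot(max(1L, L %/% 2L), 1L), b = matrix(0, 1L, 1L)))
  )
}

#' Project concatenated multigranular ligand features to the ligand kernel
#'
#' K_l = W \[x_g || x_c || x_t\] + b.
#'
#' @param enc list with pooled vectors `x_g`, `x_c`, `x_t` (1 x L row
#'   matrices or adnodes)
#' @param kernel_proj list with `W` ((L_g+L_c+L_t) x L_s) and `b`
#' @return 1 x L_s kernel (matrix or adnode)
#' @export
make_ligand_kernel <- function(enc, kernel_proj) {
  fl <- ad_cbind(enc$x_g, enc$x_c, enc$x_t)
  ad_add_rowvec(ad_matmul(fl, kernel_proj$W), kernel_proj$b)
}

#' Target-ligand response vector
#'
#' Projects the protein feature map to a scalar per position via `w_bs` and
#' filters it with the ligand kernel: in `"correlation"` mode
#' r_i = sum_m K_l(m) * f(i + m - floor(L_s/2)) with zero padding; in
#' `"literal"` mode r_i = sum(K_l) * f(i). High values flag candidate
#' binding sites.
#'
#' @param K_l 1 x L_s ligand kernel
#' @param F_p n_p x d_p protein feature map
#' @param w_bs d_p x 1 projection
#' @param mode `"correlation"` or `"literal"`
#' @return n_p x 1 response (matrix or adnode)
#' @export
response_vector <- function(K_l, F_p, w_bs, mode = "correlation") {
  f <- ad_matmul(F_p, w_bs)                  # n_p x 1 scalar profile
  if (mode == "literal") {
    return(ad_scale_by_scalar(f, ad_sum(K_l)))
  }
  Ls <- ncol(ad_val(K_l))
  # correlation as conv1d with the kernel reshaped to (Ls*1) x 1
  Wk <- ad_reshape(K_l, Ls, 1L)
  ad_conv1d(f, Wk, b = NULL, kernel = Ls)
}

# scalar (1x1) times matrix, differentiable in both
ad_scale_by_scalar <- function(a, s) {
  av <- ad_val(a); sv <- as.numeric(ad_val(s))
  v <- av * sv
  if (!.any_node(a, s)) return(v)
  .ad_new(v, function(g) {
    if (is_adnode(a)) .ad_acc(a, g * sv)
    if (is_adnode(s)) .ad_acc(s, matrix(sum(g * av), 1L, 1L))
  })
}

.minmax <- function(x) {
  r <- range(x)
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else rep(0, length(x))
}

#' Assemble the binding-region profile BR and the predicted interval
#'
#' Combines the min-max-normalized response vector r with the original
#' binding area s (elementwise max by default, min for the intersection
#' reading), then places a width-R window whose midpoint is the argmax of
#' BR, clipped at the sequence ends with the width preserved.
#'
#' @param r numeric response vector
#' @param s numeric binding-area vector of the same length
#' @param R region width in positions, 1 <= R <= length(r)
#' @param mode `"max"` or `"min"`
#' @param n_real number of real (non-padding) protein positions; the argmax
#'   and the clipped window are restricted to them (default: all positions)
#' @return list with `br` (numeric vector) and `region` (0-based half-open
#'   `c(start, end)` with end - start = R)
#' @export
assemble_binding_region <- function(r, s, R, mode = "max", n_real = NULL) {
  r <- as.numeric(ad_val(r)); s <- as.numeric(ad_val(s))
  if (length(r) != length(s)) stop("r and s must have the same length")
  n <- length(r)
  if (is.null(n_real)) n_real <- n
  n_real <- min(as.integer(n_real), n)
  if (R < 1 || R > n_real) stop("R must be in [1, n_real]")
  R <- as.integer(R)
  rn <- .minmax(r)
  sn <- .minmax(s)
  br <- if (mode == "min") pmin(rn, sn) else pmax(rn, sn)
  # argmax over real positions; exact ties (common when both normalized
  # profiles peak at 1) are resolved by the response evidence r
  cand <- which(br[seq_len(n_real)] == max(br[seq_len(n_real)]))
  m <- cand[which.max(rn[cand])] - 1L          # 0-based argmax
  start <- m - R %/% 2L
  start <- max(0L, min(start, n_real - R))
  list(br = br, region = c(start, start + R))
}

#' Bilinear interaction map between protein and ligand position maps
#'
#' I\[i, j\] = sum_c q_c * sigma(P U)\[i, c\] * sigma(G V)\[j, c\] with sigma
#' a ReLU, the per-position resolution of the bilinear attention form.
#'
#' @param P n_p x d_p protein feature map
#' @param G n_g x d_g ligand feature map
#' @param U d_p x C, `V` d_g x C, `q` C x 1 weights
#' @param V,q see above
#' @return n_p x n_g interaction matrix (or adnode)
#' @export
bilinear_map <- function(P, G, U, V, q) {
  a <- ad_relu(ad_matmul(P, U))
  b <- ad_relu(ad_matmul(G, V))
  aq <- ad_mul_rowvec(a, if (is_adnode(q)) ad_transpose(q) else matrix(as.numeric(ad_val(q)), 1L))
  ad_matmul(aq, ad_transpose(b))
}

#' Fuse the three granular interaction maps with attention
#'
#' I = \[I_pg || I_pc || I_pt\] along the ligand axis (each block zero-padded
#' to its fixed capacity); f_a = row-wise softmax of I W_m restricted to real
#' ligand columns; X_out = (I W_a) * f_a; v_out = FC(global average pool of
#' X_out).
#'
#' @param I_pg,I_pc,I_pt interaction maps (n_p x n_g / n_c / n_t)
#' @param weights list with `W_a`, `W_m` (Ktot x Ktot) and `fuse_fc`
#' @param caps integer vector c(cap_g, cap_c, cap_t) fixed ligand capacities
#' @return list with `X_out` (n_p x Ktot) and `v_out` (1 x L)
#' @export
fuse_interactions <- function(I_pg, I_pc, I_pt, weights, caps) {
  pads <- list(I_pg, I_pc, I_pt)
  real <- integer(0)
  off <- 0L
  padded <- vector("list", 3L)
  for (k in 1:3) {
    m <- pads[[k]]
    ncol_k <- ncol(ad_val(m))
    if (ncol_k > caps[k]) stop("interaction map exceeds its ligand capacity")
    padded[[k]] <- if (ncol_k < caps[k]) ad_pad_cols(m, caps[k]) else m
    real <- c(real, off + seq_len(ncol_k))
    off <- off + caps[k]
  }
  I <- do.call(ad_cbind, padded)
  Ktot <- sum(caps)
  mask <- matrix(-1e30, nrow(ad_val(I)), Ktot)
  mask[, real] <- 0
  fa <- ad_softmax_rows(ad_matmul(I, weights$W_m), mask = mask)
  X_out <- ad_mul(ad_matmul(I, weights$W_a), fa)
  gap <- ad_meanpool_cols(X_out)
  v_out <- ad_add_rowvec(ad_matmul(gap, weights$fuse_fc$W), weights$fuse_fc$b)
  list(X_out = X_out, v_out = v_out)
}

#' Predict a scalar affinity from the fused interaction features
#'
#' Two fully connected layers with a ReLU between them.
#'
#' @param v_out 1 x L fused features
#' @param head list with `fc1`, `fc2` weight/bias pairs
#' @return 1 x 1 affinity on the label (pKd) scale
#' @export
predict_affinity <- function(v_out, head) {
  h <- ad_relu(ad_add_rowvec(ad_matmul(v_out, head$fc1$W), head$fc1$b))
  ad_add_rowvec(ad_matmul(h, head$fc2$W), head$fc2$b)
}
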