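# Three parallel ligand encoders producing pooled vectors x_g, x_c, x_t and
# the position-wise feature maps consumed by the interaction module.
#
# All forward code is written against the mixed-mode autodiff ops, so the
# same functions serve gradient-free evaluation (plain matrices in the
# weight lists) and training (ad_param leaves).

#' Graph attention encoder configuration
#'
#' @param embed_dim E_g, width of the per-atom linear transform
#' @param out_dim L_g, output feature width (pooled vector length)
#' @param n_heads attention heads in the first GAT layer (concatenated)
#' @param n_layers number of GAT layers (final layer is single-head)
#' @param zeta_alpha negative slope of the LeakyReLU scoring activation
#' @return list of class `gat_config`
#' @export
gat_config <- function(embed_dim = 128L, out_dim = 128L, n_heads = 4L,
                       n_layers = 2L, zeta_alpha = 0.2) {
  stopifnot(embed_dim >= 1, out_dim >= 1, n_heads >= 1, n_layers >= 1)
  structure(list(embed_dim = as.integer(embed_dim), out_dim = as.integer(out_dim),
                 n_heads = as.integer(n_heads), n_layers = as.integer(n_layers),
                 zeta_alpha = zeta_alpha), class = "gat_config")
}

#' Residual CNN encoder configuration
#' @param embed_dim E_c, character embedding width
#' @param n_filters W_cnn, hidden convolution channels
#' @param kernel_size K_f, odd convolution kernel width
#' @param out_dim L_c, output feature width
#' @return list of class `cnn_config`
#' @export
cnn_config <- function(embed_dim = 128L, n_filters = 128L, kernel_size = 7L,
                       out_dim = 128L) {
  stopifnot(embed_dim >= 1, n_filters >= 1, out_dim >= 1)
  if (kernel_size %% 2L != 1L) stop("kernel_size must be odd (same-length padding)")
  structure(list(embed_dim = as.integer(embed_dim), n_filters = as.integer(n_filters),
                 kernel_size = as.integer(kernel_size), out_dim = as.integer(out_dim)),
            class = "cnn_config")
}

#' Molecular transformer encoder configuration
#' @param embed_dim E_t, token embedding width (divisible by `n_heads`)
#' @param n_heads attention heads H
#' @param n_blocks number of transformer blocks (default 3)
#' @param out_dim L_t, output feature width
#' @param max_tokens positional-table capacity
#' @param vocab_size sub-structure vocabulary size
#' @return list of class `mt_config`
#' @export
mt_config <- function(embed_dim = 128L, n_heads = 4L, n_blocks = 3L,
                      out_dim = 128L, max_tokens = 50L, vocab_size = 256L) {
  stopifnot(embed_dim >= 1, n_heads >= 1, n_blocks >= 1, out_dim >= 1)
  if (embed_dim %% n_heads != 0L) stop("embed_dim must be divisible by n_heads")
  structure(list(embed_dim = as.integer(embed_dim), n_heads = as.integer(n_heads),
                 n_blocks = as.integer(n_blocks), out_dim = as.integer(out_dim),
                 max_tokens = as.integer(max_tokens), vocab_size = as.integer(vocab_size)),
            class = "mt_config")
}

# ---- weight initialization ----

#' Initialize GAT encoder weights
#' @param cfg a [gat_config()]
#' @param d_in input descriptor width (78 for molecular graphs)
#' @return nested list of plain matrices
#' @export
init_gat_weights <- function(cfg, d_in = 78L) {
  E <- cfg$embed_dim; H <- cfg$n_heads; L <- cfg$out_dim
  w <- list(W_go = glorot(d_in, E))
  w$heads <- lapply(seq_len(H), function(h) {
    list(W = glorot(E, E), a1 = glorot(E, 1L), a2 = glorot(E, 1L))
  })
  w$final <- list(W = glorot(H * E, L), a1 = glorot(L, 1L), a2 = glorot(L, 1L))
  w
}

#' Initialize residual CNN encoder weights
#' @param cfg a [cnn_config()]
#' @return nested list of plain matrices
#' @export
init_cnn_weights <- function(cfg) {
  E <- cfg$embed_dim; Wf <- cfg$n_filters; K <- cfg$kernel_size; L <- cfg$out_dim
  conv <- function(ci, co) list(W = glorot(K * ci, co, fan_in = K * ci),
                                b = matrix(0, co, 1L),
                                gamma = matrix(1, co, 1L), beta = matrix(0, co, 1L))
  list(M_c = glorot(64L, E),
       conv1 = conv(E, Wf), conv2 = conv(Wf, Wf), conv3 = conv(Wf, E),
       fc = list(W = glorot(E, L), b = matrix(0, L, 1L)))
}

#' Initialize molecular transformer encoder weights
#' @param cfg an [mt_config()]
#' @return nested list of plain matrices
#' @export
init_mt_weights <- function(cfg) {
  E <- cfg$embed_dim; L <- cfg$out_dim
  blk <- function() list(
    Wq = glorot(E, E), Wk = glorot(E, E), Wv = glorot(E, E), Wo = glorot(E, E),
    fc_att = list(W = glorot(E, E), b = matrix(0, E, 1L)),
    ln1 = list(gamma = matrix(1, E, 1L), beta = matrix(0, E, 1L)),
    fc_mlp = list(W = glorot(E, E), b = matrix(0, E, 1L)),
    ln2 = list(gamma = matrix(1, E, 1L), beta = matrix(0, E, 1L)))
  list(M_up = glorot(cfg$vocab_size + 1L, E),   # row 1 = padding id 0
       M_pos = glorot(cfg$max_tokens, E),
       blocks = lapply(seq_len(cfg$n_blocks), function(i) blk()),
       mlp = list(W = glorot(E, L), b = matrix(0, L, 1L)))
}

# ---- GAT ----

#' Attention score between two transformed atom features
#'
#' e_ij = zeta(a^T [h_i || h_j]) with zeta a LeakyReLU; not symmetric in
#' general.
#'
#' @param h_i,h_j numeric vectors of equal length E
#' @param a numeric vector of length 2E
#' @param zeta_alpha LeakyReLU negative slope
#' @return scalar attention coefficient
#' @export
gat_attention <- function(h_i, h_j, a, zeta_alpha = 0.2) {
  h_i <- as.numeric(h_i); h_j <- as.numeric(h_j); a <- as.numeric(a)
  if (length(a) != length(h_i) + length(h_j)) stop("length(a) must equal 2*length(h)")
  x <- sum(a * c(h_i, h_j))
  if (x > 0) x else zeta_alpha * x
}

# one attention head over n real atoms; h (n x E) node or matrix,
# returns n x E' aggregated (pre-sigma) or post-sigma per `activation`
.gat_head <- function(h, adj_mask, W, a1, a2, zeta_alpha, activation = ad_elu) {
  hp <- ad_matmul(h, W)
  f1 <- ad_matmul(hp, a1)            # n x 1
  f2 <- ad_matmul(hp, a2)            # n x 1
  n <- nrow(ad_val(hp))
  ones <- matrix(1, 1L, n)
  E <- ad_add(ad_matmul(f1, ones), ad_transpose(ad_matmul(f2, ones)))
  logits <- ad_leaky_relu(E, zeta_alpha)
  A <- ad_softmax_rows(logits, mask = adj_mask)
  activation(ad_matmul(A, hp))
}

# dense -Inf-style additive mask from a 0-based edge list; isolated nodes
# (no bonds) get a self-loop so their softmax neighborhood is non-empty
.adj_mask <- function(n, edges) {
  m <- matrix(-1e30, n, n)
  if (nrow(edges)) m[cbind(edges[, 1] + 1L, edges[, 2] + 1L)] <- 0
  iso <- which(rowSums(m == 0) == 0L)
  if (length(iso)) m[cbind(iso, iso)] <- 0
  m
}

#' One graph attention layer (single head)
#'
#' Normalizes attention scores over each node's chemical-bond neighborhood
#' (self-loops included, so isolated atoms are well defined) and aggregates
#' neighbor features.
#'
#' @param node_feats n x E matrix (or adnode) of transformed atom features
#' @param edges m x 2 integer matrix of 0-based directed edges
#' @param params list with `W` (E x E'), `a1`, `a2` (E' x 1 halves of the
#'   scoring vector a = \[a1; a2\])
#' @param zeta_alpha LeakyReLU slope for the scoring activation
#' @param activation output nonlinearity (default ELU); use `identity` to
#'   inspect the raw weighted sum
#' @return n x E' matrix (or adnode)
#' @export
gat_layer <- function(node_feats, edges, params, zeta_alpha = 0.2,
                      activation = ad_elu) {
  n <- nrow(ad_val(node_feats))
  if (nrow(edges) && max(edges) >= n) stop("edges reference nodes beyond the feature matrix")
  mask <- .adj_mask(n, edges)
  .gat_head(node_feats, mask, params$W, params$a1, params$a2, zeta_alpha,
            activation)
}

#' Encode a molecular graph with the multi-head GAT stack
#'
#' Linear transform of the 78-dim descriptors, a multi-head first GAT layer
#' (heads concatenated), a single-head output layer, then global max pooling
#' over real atoms.
#'
#' @param g a [smiles_to_graph()] result
#' @param cfg a [gat_config()]
#' @param weights from [init_gat_weights()] (plain or ad_param tree)
#' @return list with `x_g` (1 x L_g), `map_g` (n_real x L_g per-atom map)
#' @export
gat_encode <- function(g, cfg, weights) {
  stopifnot(inherits(g, "molecular_graph"))
  n <- g$n_real_atoms
  X <- g$node_features[seq_len(n), , drop = FALSE]
  mask <- .adj_mask(n, g$edges)
  h <- ad_matmul(X, weights$W_go)
  heads <- lapply(weights$heads, function(hd)
    .gat_head(h, mask, hd$W, hd$a1, hd$a2, cfg$zeta_alpha, ad_elu))
  hcat <- do.call(ad_cbind, heads)
  out <- .gat_head(hcat, mask, weights$final$W, weights$final$a1,
                   weights$final$a2, cfg$zeta_alpha, ad_elu)
  x_g <- ad_maxpool_cols(out)
  list(x_g = x_g, map_g = out)
}

# ---- residual CNN ----

#' Encode ligand character codes with the residual convolution stack
#'
#' Embeds the integer codes, applies three conv -> channel-norm -> ReLU
#' blocks, adds the embedding back (residual in embedding space), projects
#' position-wise to L_c, and max-pools over real positions.
#'
#' @param codes a [smiles_to_codes()] result
#' @param cfg a [cnn_config()]
#' @param weights from [init_cnn_weights()]
#' @return list with `x_c` (1 x L_c), `map_c` (n_real x L_c)
#' @export
cnn_encode <- function(codes, cfg, weights) {
  stopifnot(inherits(codes, "ligand_codes"))
  n <- codes$n_real
  if (n < 1) stop("empty code sequence")
  ids <- codes$codes[seq_len(n)]
  X_seq <- ad_rows(weights$M_c, ids)          # n x E (real positions only)
  K <- cfg$kernel_size
  block <- function(x, cw) {
    y <- ad_conv1d(x, cw$W, cw$b, kernel = K)
    y <- ad_norm_cols(y, cw$gamma, cw$beta)
    ad_relu(y)
  }
  y <- block(X_seq, weights$conv1)
  y <- block(y, weights$conv2)
  y <- block(y, weights$conv3)
  res <- ad_add(X_seq, y)
  map_c <- ad_add_rowvec(ad_matmul(res, weights$fc$W), weights$fc$b)
  x_c <- ad_maxpool_cols(map_c)
  list(x_c = x_c, map_c = map_c)
}

# ---- molecular transformer ----

.msa <- function(X, blk, H) {
  n <- nrow(ad_val(X))
  E <- ncol(ad_val(X))
  dk <- E %/% H
  Q <- ad_matmul(X, blk$Wq)
  K <- ad_matmul(X, blk$Wk)
  V <- ad_matmul(X, blk$Wv)
  outs <- vector("list", H)
  for (h in seq_len(H)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    Qh <- ad_cols(Q, cols)
    Kh <- ad_cols(K, cols)
    Vh <- ad_cols(V, cols)
    S <- ad_scale(ad_matmul(Qh, ad_transpose(Kh)), 1 / sqrt(dk))
    A <- ad_softmax_rows(S)
    outs[[h]] <- ad_matmul(A, Vh)
  }
  ad_matmul(do.call(ad_cbind, outs), blk$Wo)
}

#' Encode sub-structure tokens with the molecular transformer
#'
#' Token embeddings plus a learned positional signal, then `n_blocks`
#' transformer blocks (multi-head self-attention -> FC -> residual,
#' position-wise FC -> residual, two layer normalizations per block), a final
#' position-wise MLP to L_t, and max pooling over real tokens.
#'
#' @param tokens a [tokenize_substructures()] result
#' @param cfg an [mt_config()]
#' @param weights from [init_mt_weights()]
#' @return list with `x_t` (1 x L_t), `map_t` (n_real x L_t)
#' @export
mt_encode <- function(tokens, cfg, weights) {
  stopifnot(inherits(tokens, "substructure_tokens"))
  n <- tokens$n_real
  if (n < 1) stop("empty token sequence")
  ids <- tokens$token_ids[seq_len(n)]
  X <- ad_add(ad_rows(weights$M_up, ids + 1L),
              ad_rows(weights$M_pos, seq_len(n)))
  for (blk in weights$blocks) {
    att <- .msa(X, blk, cfg$n_heads)
    att <- ad_relu(ad_add_rowvec(ad_matmul(att, blk$fc_att$W), blk$fc_att$b))
    X <- ad_layernorm(ad_add(att, X), blk$ln1$gamma, blk$ln1$beta)
    mlp <- ad_add_rowvec(ad_matmul(X, blk$fc_mlp$W), blk$fc_mlp$b)
    X <- ad_layernorm(ad_add(mlp, X), blk$ln2$gamma, blk$ln2$beta)
  }
  map_t <- ad_add_rowvec(ad_matmul(X, weights$mlp$W), weights$mlp$b)
  x_t <- ad_maxpool_cols(map_t)
  list(x_t = x_t, map_t = map_t)
}
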