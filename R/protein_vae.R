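# Gated-convolution variational encoder for proteins, deconvolutional
# decoder, and the reconstruction-derived "original binding area" profile s.

#' Protein VAE configuration
#'
#' The first gated-conv layer has `n_filters` channels; the second and third
#' are doubled and tripled. The decoder upsamples by three stride-2
#' transposed convolutions from ceil(max_len / 8) positions and crops to
#' `max_len`.
#'
#' @param n_filters W_en, channels of the first encoder layer
#' @param kernel_en K_en, encoder kernel width
#' @param n_filters_de W_de, decoder channels
#' @param kernel_de K_de, decoder kernel width
#' @param latent_dim L_p, latent width
#' @param pool_width temporal max-pool width applied after the third layer on
#'   the path to the latent heads (the interaction feature map is pre-pool)
#' @return list of class `vae_config`
#' @export
vae_config <- function(n_filters = 32L, kernel_en = 5L, n_filters_de = 32L,
                       kernel_de = 5L, latent_dim = 64L, pool_width = 4L) {
  stopifnot(n_filters >= 1, kernel_en >= 1, n_filters_de >= 1, kernel_de >= 1,
            latent_dim >= 1, pool_width >= 1)
  structure(list(n_filters = as.integer(n_filters), kernel_en = as.integer(kernel_en),
                 n_filters_de = as.integer(n_filters_de), kernel_de = as.integer(kernel_de),
                 latent_dim = as.integer(latent_dim), pool_width = as.integer(pool_width)),
            class = "vae_config")
}

#' Initialize protein VAE weights
#' @param cfg a [vae_config()]
#' @param d_in input channel width D_p (3-mer embedding dimension)
#' @param max_len protein capacity, used to size the decoder
#' @return nested list of plain matrices
#' @export
init_vae_weights <- function(cfg, d_in = 64L, max_len = 1000L) {
  W1 <- cfg$n_filters; W2 <- 2L * W1; W3 <- 3L * W1
  Ke <- cfg$kernel_en; Kd <- cfg$kernel_de; Wd <- cfg$n_filters_de
  Lp <- cfg$latent_dim
  conv <- function(k, ci, co) list(W = glorot(k * ci, co, fan_in = k * ci),
                                   b = matrix(0, co, 1L))
  gated <- function(k, ci, co) list(A = conv(k, ci, co), B = conv(k, ci, co))
  n0 <- as.integer(ceiling(max_len / 8))
  list(
    g1 = gated(Ke, d_in, W1), g2 = gated(Ke, W1, W2), g3 = gated(Ke, W2, W3),
    fc_mu = list(W = glorot(W3, Lp), b = matrix(0, Lp, 1L)),
    fc_lv = list(W = glorot(W3, Lp), b = matrix(0, Lp, 1L)),
    de_fc1 = list(W = glorot(Lp, n0 * Wd), b = matrix(0, n0 * Wd, 1L)),
    d1 = conv(Kd, Wd, Wd), d2 = conv(Kd, Wd, Wd), d3 = conv(Kd, Wd, Wd),
    de_fc2 = list(W = glorot(Wd, 1L), b = matrix(0, 1L, 1L)),
    n0 = n0, max_len = as.integer(max_len)
  )
}

.gated_conv <- function(x, gw, kernel) {
  a <- ad_conv1d(x, gw$A$W, gw$A$b, kernel = kernel)
  b <- ad_conv1d(x, gw$B$W, gw$B$b, kernel = kernel)
  ad_mul(a, ad_sigmoid(b))
}

#' Variationally encode a protein 3-mer matrix
#'
#' Three 1-D gated convolution layers (output = conv_A(x) * sigmoid(conv_B(x)),
#' channels W_en, 2 W_en, 3 W_en) with ReLU after the first two; the third
#' layer's output is the position-wise `feature_map` kept for the interaction
#' module. The latent path applies temporal max pooling, a global average
#' pool, and FC heads for `mu` and `log_var`; `z` is sampled by
#' reparameterization (z = mu in deterministic mode).
#'
#' @param kmers a [protein_to_kmers()] result
#' @param cfg a [vae_config()]
#' @param weights from [init_vae_weights()]
#' @param rng_seed seed for the reparameterization draw (ignored when
#'   `deterministic`); when NULL the current RNG stream is used
#' @param deterministic if TRUE, z = mu and epsilon = 0
#' @return object of class `protein_encoding`: list with `mu`, `log_var`, `z`
#'   (1 x L_p), `epsilon` (recorded draw), `feature_map` (n_real x 3 W_en),
#'   `n_real`
#' @export
vae_encode <- function(kmers, cfg, weights, rng_seed = NULL, deterministic = FALSE) {
  stopifnot(inherits(kmers, "protein_kmer_matrix"))
  n <- kmers$n_real
  X <- kmers$kmer_features[seq_len(n), , drop = FALSE]
  Ke <- cfg$kernel_en
  h1 <- ad_relu(.gated_conv(X, weights$g1, Ke))
  h2 <- ad_relu(.gated_conv(h1, weights$g2, Ke))
  fm <- .gated_conv(h2, weights$g3, Ke)          # pre-pool feature map
  pw <- min(cfg$pool_width, n)
  pooled <- ad_maxpool1d(fm, pw)
  gap <- ad_meanpool_cols(pooled)
  mu <- ad_add_rowvec(ad_matmul(gap, weights$fc_mu$W), weights$fc_mu$b)
  lv <- ad_add_rowvec(ad_matmul(gap, weights$fc_lv$W), weights$fc_lv$b)
  Lp <- ncol(ad_val(mu))
  if (deterministic) {
    eps <- matrix(0, 1L, Lp)
    z <- mu
  } else {
    if (!is.null(rng_seed)) {
      old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
      set.seed(rng_seed)
    }
    eps <- matrix(stats::rnorm(Lp), 1L, Lp)
    z <- ad_add(mu, ad_mul(ad_exp(ad_scale(lv, 0.5)), eps))
  }
  structure(list(mu = mu, log_var = lv, z = z, epsilon = eps,
                 feature_map = fm, n_real = n),
            class = "protein_encoding")
}

#' Decode a latent vector to a reconstruction profile of length `max_len`
#'
#' A fully connected resize, three stride-2 transposed convolutions
#' (zero-interleave upsampling + convolution) each followed by ReLU, and a
#' final position-wise FC producing the scalar reconstruction profile,
#' cropped to exactly `max_len` positions.
#'
#' @param z 1 x L_p latent (matrix or adnode)
#' @param cfg a [vae_config()]
#' @param weights from [init_vae_weights()] (carries the target length)
#' @return length-`max_len` reconstruction (1-column matrix or adnode)
#' @export
vae_decode <- function(z, cfg, weights) {
  Wd <- cfg$n_filters_de; Kd <- cfg$kernel_de
  n0 <- weights$n0; out_len <- weights$max_len
  h <- ad_add_rowvec(ad_matmul(z, weights$de_fc1$W), weights$de_fc1$b)
  h <- ad_reshape(h, n0, Wd)
  for (dw in list(weights$d1, weights$d2, weights$d3)) {
    h <- ad_upsample_zeros(h, 2L)
    h <- ad_relu(ad_conv1d(h, dw$W, dw$b, kernel = Kd))
  }
  h <- if (is_adnode(h)) ad_rows(h, seq_len(out_len)) else h[seq_len(out_len), , drop = FALSE]
  ad_add_rowvec(ad_matmul(h, weights$de_fc2$W), weights$de_fc2$b)
}

#' Binding-area profile from a reconstruction
#'
#' Min-max normalizes the per-position reconstruction magnitude and marks the
#' top `ceiling(top_fraction * length)` positions as the original binding
#' area s (ties broken by position).
#'
#' @param reconstruction numeric vector (or 1-column matrix) X_de
#' @param top_fraction fraction of positions to mark, in (0, 1]
#' @return 0/1 numeric vector s of the same length
#' @export
reconstruction_binding_profile <- function(reconstruction, top_fraction = 0.1) {
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  x <- as.numeric(ad_val(reconstruction))
  n <- length(x)
  sal <- abs(x)
  rng <- range(sal)
  sal <- if (rng[2] > rng[1]) (sal - rng[1]) / (rng[2] - rng[1]) else rep(0, n)
  k <- as.integer(ceiling(top_fraction * n))
  s <- numeric(n)
  s[order(-sal, seq_len(n))[seq_len(k)]] <- 1
  s
}

#' KL divergence of a diagonal Gaussian against the standard normal
#' @param mu,log_var 1 x L matrices (or adnodes)
#' @return scalar (1 x 1) KL term, always >= 0
#' @export
vae_kl <- function(mu, log_var) {
  term <- ad_sub(ad_add(ad_square(mu), ad_exp(log_var)),
                 ad_add(1, log_var))
  ad_scale(ad_sum(term), 0.5)
}
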