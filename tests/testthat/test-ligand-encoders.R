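# The three ligand encoders against trivial cases and straight-line oracles.

test_that("gat_attention evaluates the concatenated scoring form", {
  expect_equal(gat_attention(c(1, 2), c(3, 4), rep(0, 4)), 0)
  # a = [u || u] with h_i = h_j gives zeta(2 * u . h)
  u <- c(0.3, -0.2)
  h <- c(1, 1)
  e <- gat_attention(h, h, c(u, u))
  z <- 2 * sum(u * h)
  expect_equal(e, if (z > 0) z else 0.2 * z)
  withr::with_seed(4, {
    h_i <- rnorm(4); h_j <- rnorm(4); a <- rnorm(8)
    raw <- sum(a * c(h_i, h_j))
    expect_equal(gat_attention(h_i, h_j, a),
                 if (raw > 0) raw else 0.2 * raw)
  })
  expect_error(gat_attention(1:2, 1:2, 1:3), "length")
})

test_that("gat_layer normalizes attention over bond neighborhoods", {
  withr::with_seed(7, {
    # star: node 0 bonded to 1, 2, 3; zero scoring vector -> uniform 1/3
    edges <- rbind(c(0, 1), c(0, 2), c(0, 3), c(1, 0), c(2, 0), c(3, 0))
    X <- matrix(rnorm(12), 4, 3)
    params <- list(W = diag(3), a1 = matrix(0, 3, 1), a2 = matrix(0, 3, 1))
    out <- gat_layer(X, edges, params, activation = function(x) x)
    expect_equal(as.numeric(out[1, ]), as.numeric(colMeans(X[2:4, ])),
                 tolerance = 1e-10)
    # single edge, identity activation: output is the neighbor feature
    out2 <- gat_layer(X[1:2, ], rbind(c(0, 1), c(1, 0)), params,
                      activation = function(x) x)
    expect_equal(as.numeric(out2[1, ]), as.numeric(X[2, ]), tolerance = 1e-12)
    expect_equal(as.numeric(out2[2, ]), as.numeric(X[1, ]), tolerance = 1e-12)
    # 3-node path graph with random weights matches the brute-force oracle
    edges3 <- rbind(c(0, 1), c(1, 0), c(1, 2), c(2, 1))
    p3 <- list(W = matrix(rnorm(9, sd = 0.5), 3, 3),
               a1 = matrix(rnorm(3, sd = 0.5), 3, 1),
               a2 = matrix(rnorm(3, sd = 0.5), 3, 1))
    got <- gat_layer(X[1:3, ], edges3, p3)
    want <- oracle_gat_layer(X[1:3, ], edges3, p3$W, as.numeric(p3$a1),
                             as.numeric(p3$a2))
    expect_equal(got, want, tolerance = 1e-10)
    expect_error(gat_layer(X[1:2, ], rbind(c(0, 5)), params), "beyond")
  })
})

test_that("gat_encode pools over real atoms and composes the layer oracle", {
  cfg <- gat_config(embed_dim = 6, out_dim = 4, n_heads = 2)
  w <- tiny_weights(21, init_gat_weights, cfg)
  g1 <- smiles_to_graph("C", max_atoms = 5)
  e1 <- gat_encode(g1, cfg, w)
  expect_equal(dim(e1$map_g), c(1L, 4L))
  expect_equal(as.numeric(e1$x_g), as.numeric(e1$map_g))
  # extra padding never changes the pooled output
  g <- smiles_to_graph("CCO", max_atoms = 4)
  gpad <- smiles_to_graph("CCO", max_atoms = 9)
  expect_equal(gat_encode(g, cfg, w)$x_g, gat_encode(gpad, cfg, w)$x_g)
  # composition against the dense oracle: transform, 2 heads, final layer, max
  X <- g$node_features[1:3, ]
  h <- X %*% w$W_go
  heads <- lapply(w$heads, function(hd)
    oracle_gat_layer(h, g$edges, hd$W, as.numeric(hd$a1), as.numeric(hd$a2)))
  hcat <- do.call(cbind, heads)
  out <- oracle_gat_layer(hcat, g$edges, w$final$W, as.numeric(w$final$a1),
                          as.numeric(w$final$a2))
  want <- apply(out, 2, max)
  expect_equal(as.numeric(gat_encode(g, cfg, w)$x_g), want, tolerance = 1e-8)
})

test_that("cnn_encode isolates the residual path and matches the hand oracle", {
  cfg <- cnn_config(embed_dim = 5, n_filters = 4, kernel_size = 3, out_dim = 6)
  w <- tiny_weights(31, init_cnn_weights, cfg)
  codes <- smiles_to_codes("CCOCN", max_len = 8)
  # zero conv path: output is exactly the position-wise FC of the embedding
  w0 <- w
  for (nm in c("conv1", "conv2", "conv3")) {
    w0[[nm]]$W[] <- 0; w0[[nm]]$b[] <- 0; w0[[nm]]$beta[] <- 0
  }
  got0 <- cnn_encode(codes, cfg, w0)
  X <- w$M_c[codes$codes[1:5], ]
  want0 <- X %*% w$fc$W + matrix(as.numeric(w$fc$b), 5, 6, byrow = TRUE)
  expect_equal(got0$map_c, want0, tolerance = 1e-12)
  # full stack vs straight-line oracle
  got <- cnn_encode(codes, cfg, w)
  want <- oracle_cnn_encode(codes$codes[1:5], w, cfg$kernel_size)
  expect_equal(got$map_c, want$map, tolerance = 1e-8)
  expect_equal(as.numeric(got$x_c), want$x, tolerance = 1e-8)
  # padding invariance through the public interface
  codes_wide <- smiles_to_codes("CCOCN", max_len = 20)
  expect_equal(cnn_encode(codes_wide, cfg, w)$x_c, got$x_c)
  expect_error(cnn_config(kernel_size = 4), "odd")
})

test_that("mt_encode matches the explicit QKV oracle", {
  cfg <- mt_config(embed_dim = 4, n_heads = 1, n_blocks = 2, out_dim = 3,
                   max_tokens = 6, vocab_size = 10)
  w <- tiny_weights(41, init_mt_weights, cfg)
  vocab <- structure(list(tokens = c("C", "O", "N", "CC"), max_token_len = 2L,
                          frequency_floor = 1L), class = "substructure_vocab")
  tk <- tokenize_substructures("CCO", vocab, max_tokens = 6)
  got <- mt_encode(tk, cfg, w)
  want <- oracle_mt_encode(tk$token_ids[1:tk$n_real], w, cfg$n_heads)
  expect_equal(got$map_t, want$map, tolerance = 1e-8)
  expect_equal(as.numeric(got$x_t), want$x, tolerance = 1e-8)
  # single token: self-attention weight is 1, output defined and finite
  tk1 <- tokenize_substructures("N", vocab, max_tokens = 6)
  out1 <- mt_encode(tk1, cfg, w)
  expect_true(all(is.finite(out1$x_t)))
  expect_equal(dim(out1$map_t), c(1L, 3L))
  # padding invariance
  tk_wide <- tokenize_substructures("CCO", vocab, max_tokens = 4)
  expect_equal(mt_encode(tk_wide, cfg, w)$x_t, got$x_t)
  expect_error(mt_config(embed_dim = 5, n_heads = 2), "divisible")
})

test_that("attention rows sum to one in both GAT and MSA", {
  withr::with_seed(9, {
    for (trial in 1:20) {
      n <- sample(2:6, 1)
      S <- matrix(rnorm(n * n), n, n)
      P <- ad("ad_softmax_rows")(S)
      expect_equal(rowSums(P), rep(1, n), tolerance = 1e-6)
    }
  })
})

test_that("pooled outputs are invariant to atom relabeling", {
  cfg <- gat_config(embed_dim = 5, out_dim = 4, n_heads = 2)
  w <- tiny_weights(51, init_gat_weights, cfg)
  g <- smiles_to_graph("CC(N)CO", max_atoms = 6)
  base <- gat_encode(g, cfg, w)$x_g
  withr::with_seed(52, {
    for (trial in 1:25) {
      perm <- sample(g$n_real_atoms)
      inv <- order(perm)
      g2 <- g
      g2$node_features[seq_len(g$n_real_atoms), ] <-
        g$node_features[perm, , drop = FALSE]
      g2$edges <- matrix(inv[g$edges + 1L] - 1L, ncol = 2)
      expect_equal(gat_encode(g2, cfg, w)$x_g, base, tolerance = 1e-9)
    }
  })
})
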