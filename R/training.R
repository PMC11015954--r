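# Labels, losses, splits, training regimes, and evaluation metrics.

#' Construct one (ligand, protein, affinity, optional region) training record
#'
#' @param ligand_smiles SMILES string
#' @param protein_seq amino-acid sequence
#' @param affinity finite numeric label on the pKd scale
#' @param region optional 0-based half-open interval `c(start, end)` on the
#'   protein sequence, or NULL
#' @return list of class `pair_record`
#' @export
pair_record <- function(ligand_smiles, protein_seq, affinity, region = NULL) {
  if (!is.finite(affinity)) stop("affinity must be finite")
  if (!is.null(region)) {
    region <- as.integer(region)
    if (length(region) != 2L || region[1] < 0L || region[2] <= region[1] ||
        region[2] > nchar(protein_seq))
      stop("region must be a half-open [start, end) within the protein sequence")
  }
  structure(list(ligand_smiles = ligand_smiles, protein_seq = protein_seq,
                 affinity = as.numeric(affinity), region = region),
            class = "pair_record")
}

#' Convert a dissociation constant in nM to pKd
#'
#' pKd = -log10(Kd / 1e9).
#'
#' @param kd positive dissociation constant in nM
#' @return pKd value
#' @examples kd_to_pkd(1)    # 9
#' @export
kd_to_pkd <- function(kd) {
  if (any(!is.finite(kd)) || any(kd <= 0)) stop("kd must be positive and finite")
  -log10(kd / 1e9)
}

#' Encode a record's region as a length-theta_p label vector
#'
#' Positions inside the (truncated) region carry the pair's affinity value;
#' all others are 0.
#'
#' @param rec a [pair_record()] with a non-NULL region
#' @param theta_p protein capacity
#' @return numeric vector of length `theta_p`
#' @export
encode_region_labels <- function(rec, theta_p) {
  if (is.null(rec$region)) stop("record has no region label; use the affinity-only regime")
  v <- numeric(theta_p)
  lo <- rec$region[1]; hi <- min(rec$region[2], theta_p)
  if (hi <= lo) {
    if (rec$region[2] <= rec$region[1]) stop("empty-width region")
    return(v)  # fully truncated beyond capacity
  }
  v[(lo + 1L):hi] <- rec$affinity
  v
}

#' Rectified wing loss
#'
#' Mean over elements of: 0 when |x| < r_thresh; w * ln(1 + (|x| -
#' r_thresh)/eps) when r_thresh <= |x| < w; |x| - C otherwise, with C = w -
#' w * ln(1 + (w - r_thresh)/eps) making the pieces continuous. Robust to
#' the many-zeros label vectors of region supervision.
#'
#' @param residuals numeric vector of prediction - label residuals
#' @param r_thresh dead-zone radius (default 0.1)
#' @param w wing width (default 2.0), must exceed `r_thresh`
#' @param eps curvature of the log branch (default 0.5), > 0
#' @return scalar mean penalty
#' @export
rwing_loss <- function(residuals, r_thresh = 0.1, w = 2.0, eps = 0.5) {
  if (!(w > r_thresh && r_thresh >= 0)) stop("need w > r_thresh >= 0")
  if (eps <= 0) stop("eps must be > 0")
  mean(ad_rwing_elem(matrix(as.numeric(residuals), ncol = 1L), r_thresh, w, eps))
}

#' Weighted combination of affinity and region losses
#'
#' Loss = psi * l_ba + (1 - psi) * l_br, default psi = 0.4.
#'
#' @param l_ba affinity (MSE) loss
#' @param l_br region (rectified wing) loss
#' @param psi weight in \[0, 1\]
#' @return combined scalar loss
#' @export
combined_loss <- function(l_ba, l_br, psi = 0.4) {
  if (!is.numeric(psi) || psi < 0 || psi > 1) stop("psi must be in [0, 1]")
  psi * l_ba + (1 - psi) * l_br
}

#' Split specification
#' @param mode one of `"random"`, `"cold_ligand"`, `"cold_target"`
#' @param fractions for random mode, (train, val, test) summing to 1; for
#'   cold modes the val/test entries are the entity fractions (defaults
#'   5% / 10%)
#' @param seed RNG seed
#' @return list of class `split_spec`
#' @export
split_spec <- function(mode = c("random", "cold_ligand", "cold_target"),
                       fractions = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(fractions)) {
    fractions <- if (mode == "random") c(4, 1, 1) / 6 else c(0.85, 0.05, 0.10)
  }
  if (length(fractions) != 3L || any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three non-negative numbers summing to 1")
  structure(list(mode = mode, fractions = fractions, seed = as.integer(seed)),
            class = "split_spec")
}

#' Split records into train / validation / test sets
#'
#' Random mode shuffles pairs 4:1:1 (or per `fractions`). Cold modes
#' allocate 5% of the ligands (targets) to validation and 10% to test and
#' remove every pair containing those entities from the training set, so
#' entity overlap between train and val/test is exactly zero.
#'
#' @param records list of [pair_record()]s
#' @param spec a [split_spec()]
#' @return list with `train`, `val`, `test` record lists and the index
#'   vectors `idx`
#' @export
split_dataset <- function(records, spec) {
  stopifnot(inherits(spec, "split_spec"))
  n <- length(records)
  if (n == 0L) stop("records must be non-empty")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  if (spec$mode == "random") {
    ord <- sample.int(n)
    n_val <- round(n * spec$fractions[2])
    n_test <- round(n * spec$fractions[3])
    n_train <- n - n_val - n_test
    idx <- list(train = ord[seq_len(n_train)],
                val = ord[n_train + seq_len(n_val)],
                test = ord[n_train + n_val + seq_len(n_test)])
  } else {
    key <- if (spec$mode == "cold_ligand") "ligand_smiles" else "protein_seq"
    ents <- vapply(records, `[[`, "", key)
    uents <- unique(ents)
    ne <- length(uents)
    n_val_e <- max(1L, round(ne * spec$fractions[2]))
    n_test_e <- max(1L, round(ne * spec$fractions[3]))
    if (n_val_e + n_test_e >= ne)
      stop("too few distinct entities for a cold split")
    perm <- sample(uents)
    val_e <- perm[seq_len(n_val_e)]
    test_e <- perm[n_val_e + seq_len(n_test_e)]
    idx <- list(train = which(!(ents %in% c(val_e, test_e))),
                val = which(ents %in% val_e),
                test = which(ents %in% test_e))
  }
  list(train = records[idx$train], val = records[idx$val],
       test = records[idx$test], idx = idx)
}

#' Remove duplicate and contradictory (ligand, protein) pairs
#'
#' Pairs whose key maps to more than one distinct affinity are dropped
#' entirely; exact duplicates are reduced to one record.
#'
#' @param records list of [pair_record()]s
#' @return cleaned list
#' @export
clean_pairs <- function(records) {
  keys <- vapply(records, function(r) paste(r$ligand_smiles, r$protein_seq, sep = "\r"), "")
  affs <- vapply(records, `[[`, 0, "affinity")
  drop_keys <- unique(keys[stats::ave(affs, keys, FUN = function(x) length(unique(x))) > 1])
  keep <- !(keys %in% drop_keys) & !duplicated(keys)
  records[keep]
}

# ---- metrics ----

#' Concordance index
#'
#' Over all pairs (i, j) with truth_i > truth_j, scores 1 when pred_i >
#' pred_j, 0.5 on ties, 0 otherwise, and averages.
#'
#' @param pred,truth equal-length numeric vectors, with at least one
#'   strictly ordered truth pair
#' @return CI in \[0, 1\]
#' @export
concordance_index <- function(pred, truth) {
  n <- length(pred)
  if (n != length(truth) || n < 2L) stop("pred and truth must be equal length >= 2")
  dt <- outer(truth, truth, ">")
  if (!any(dt)) stop("concordance index undefined: no strictly ordered truth pair")
  dp <- outer(pred, pred, "-")
  sum(ifelse(dp[dt] > 0, 1, ifelse(dp[dt] == 0, 0.5, 0))) / sum(dt)
}

#' Squared-correlation metric rm2
#'
#' rm2 = r2 * (1 - sqrt(|r2 - r0^2|)) with r2 the squared Pearson
#' correlation of pred and truth and r0^2 the squared correlation through
#' the origin.
#'
#' @param pred,truth equal-length numeric vectors (length >= 3, nonzero
#'   variance)
#' @return rm2 value (<= r2)
#' @export
rm2_score <- function(pred, truth) {
  n <- length(pred)
  if (n != length(truth) || n < 3L) stop("pred and truth must be equal length >= 3")
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0) stop("zero variance input")
  r2 <- stats::cor(pred, truth)^2
  k <- sum(truth * pred) / sum(pred^2)
  ss_res0 <- sum((truth - k * pred)^2)
  ss_tot <- sum((truth - mean(truth))^2)
  r02 <- 1 - ss_res0 / ss_tot
  r2 * (1 - sqrt(abs(r2 - r02)))
}

#' Area under the precision-recall curve
#'
#' Binarizes truth at `binarize_threshold` (positive when truth >=
#' threshold) and integrates precision over recall step-wise (average
#' precision; no trapezoids).
#'
#' @param pred numeric scores
#' @param truth numeric labels
#' @param binarize_threshold threshold defining the positive class
#' @return AUPR in \[0, 1\]
#' @export
aupr_score <- function(pred, truth, binarize_threshold = 7) {
  if (length(pred) != length(truth)) stop("pred and truth must be equal length")
  y <- as.integer(truth >= binarize_threshold)
  if (all(y == 1L) || all(y == 0L)) stop("both classes must be present after thresholding")
  # step integration over distinct score cut points (tied scores enter as one
  # block, so a constant predictor scores the positive-class prevalence)
  ord <- order(-pred)
  y <- y[ord]; p <- pred[ord]
  n_pos <- sum(y)
  cut <- which(c(p[-1] != p[-length(p)], TRUE))  # last index of each group
  tp <- cumsum(y)[cut]
  prec <- tp / cut
  d_tp <- diff(c(0L, tp))
  sum(prec * d_tp) / n_pos
}

#' Fraction of true sites falling inside predicted regions
#'
#' A pair scores a hit when its true site (a position or a half-open
#' interval) intersects the predicted half-open width-R window.
#'
#' @param predicted_regions list of `c(start, end)` 0-based half-open
#'   intervals
#' @param true_sites list of positions (length-1) or intervals (length-2),
#'   aligned with `predicted_regions`
#' @param R nominal region width (stored for reporting; widths come from
#'   the intervals themselves)
#' @return hit fraction in \[0, 1\]
#' @export
region_accuracy <- function(predicted_regions, true_sites, R = NULL) {
  if (length(predicted_regions) != length(true_sites))
    stop("predicted_regions and true_sites must be aligned")
  if (length(predicted_regions) == 0L) stop("empty input")
  hits <- mapply(function(reg, site) {
    if (length(site) == 1L) site <- c(site, site + 1L)
    (site[1] < reg[2]) && (reg[1] < site[2])
  }, predicted_regions, true_sites)
  mean(hits)
}

# ---- training ----

#' Training configuration
#' @param lr Adam learning rate
#' @param batch_size minibatch size
#' @param epochs maximum epochs
#' @param psi affinity weight of [combined_loss()] in the joint regime
#' @param beta_kl weight of the VAE KL term
#' @param gamma_recon weight of the VAE reconstruction MSE
#' @param rwing list of rectified-wing parameters
#' @param patience early-stopping patience on validation MSE (Inf disables)
#' @param region_scale R used when reporting regions during evaluation
#' @param verbose print per-epoch progress
#' @return list of class `train_config`
#' @export
train_config <- function(lr = 1e-3, batch_size = 32L, epochs = 20L, psi = 0.4,
                         beta_kl = 1e-3, gamma_recon = 0.1,
                         rwing = list(r_thresh = 0.1, w = 2.0, eps = 0.5),
                         patience = 10L, region_scale = 10L, verbose = FALSE) {
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), psi = psi, beta_kl = beta_kl,
                 gamma_recon = gamma_recon, rwing = rwing,
                 patience = patience, region_scale = as.integer(region_scale),
                 verbose = isTRUE(verbose)), class = "train_config")
}

# per-sample loss graph; returns the scalar loss node
.sample_loss <- function(params, feat, cfg, tc, regime, label, region_vec) {
  fw <- mg_forward(params, feat, cfg, deterministic = FALSE,
                   region_scale = tc$region_scale, want_region = FALSE)
  l_ba <- ad_square(ad_sub(fw$affinity, label))
  recon_target <- matrix(0, cfg$max_protein, 1L)
  kmv <- ad_val(fw$kmer_node)
  recon_target[seq_len(fw$protein_n), 1L] <- rowMeans(kmv)
  l_recon <- ad_mean(ad_square(ad_sub(fw$recon, recon_target)))
  l_kl <- vae_kl(fw$mu, fw$log_var)
  loss <- ad_add(l_ba, ad_add(ad_scale(l_recon, tc$gamma_recon),
                              ad_scale(l_kl, tc$beta_kl)))
  if (regime == "joint") {
    lab <- matrix(region_vec[seq_len(fw$protein_n)], ncol = 1L)
    l_br <- ad_mean(ad_rwing_elem(ad_sub(fw$r, lab), tc$rwing$r_thresh,
                                  tc$rwing$w, tc$rwing$eps))
    loss <- ad_add(ad_scale(loss, tc$psi), ad_scale(l_br, 1 - tc$psi))
  }
  loss
}

#' Train the model
#'
#' `regime = "affinity_only"` minimizes MSE plus the weighted VAE terms
#' (reconstruction MSE and KL); `regime = "joint"` optimizes
#' psi * L_BA + (1 - psi) * L_BR with the rectified-wing region loss over
#' the encoded label vectors. Records without a region contribute an
#' all-zero label vector (no binding region) in the joint regime, but at
#' least one labelled record is required. Fully seeded and reproducible.
#'
#' @param records training [pair_record()]s
#' @param cfg an [mg_config()]
#' @param regime `"affinity_only"` or `"joint"`
#' @param tc a [train_config()]
#' @param seed integer seed controlling initialization, shuffling and VAE
#'   sampling
#' @param val_records optional validation records for early stopping
#' @param init_weights optional plain weight tree to start from (fine-tuning)
#' @param subvocab optional sub-structure vocabulary (built from training
#'   SMILES when NULL)
#' @return list of class `mg_fit`: `weights` (plain), `cfg`, `subvocab`,
#'   `history` (data.frame per epoch), `regime`
#' @export
train_model <- function(records, cfg, regime = c("affinity_only", "joint"),
                        tc = train_config(), seed = 1L, val_records = NULL,
                        init_weights = NULL, subvocab = NULL) {
  regime <- match.arg(regime)
  if (length(records) == 0L) stop("no training records")
  has_region <- vapply(records, function(r) !is.null(r$region), FALSE)
  if (regime == "joint" && !any(has_region))
    stop("joint regime requires region labels on at least one record")
  fz <- featurize_pairs(records, cfg, subvocab)
  labels <- vapply(records, `[[`, 0, "affinity")
  region_vecs <- lapply(records, function(r) {
    if (is.null(r$region)) numeric(cfg$max_protein)
    else encode_region_labels(r, cfg$max_protein)
  })
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  weights <- if (is.null(init_weights)) mg_init(cfg, seed = seed) else init_weights
  params <- ad_params(weights)
  flat <- ad_param_list(params)
  opt <- adam_new(flat, lr = tc$lr)
  n <- length(records)
  history <- list()
  best_val <- Inf; best_weights <- NULL; stall <- 0L
  for (epoch in seq_len(tc$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (b0 in seq(1L, n, by = tc$batch_size)) {
      bidx <- ord[b0:min(b0 + tc$batch_size - 1L, n)]
      for (i in bidx) {
        ad_tape_start()
        loss <- .sample_loss(params, fz$feats[[i]], cfg, tc, regime,
                             labels[i], region_vecs[[i]])
        ep_loss <- ep_loss + as.numeric(ad_val(loss))
        ad_backward(loss)
        ad_tape_stop()
      }
      adam_step(opt, grad_scale = 1 / length(bidx))
    }
    ep_loss <- ep_loss / n
    val_mse <- NA_real_
    if (!is.null(val_records)) {
      cur <- ad_values(params)
      pv <- mg_predict(cur, val_records, cfg, fz$subvocab, tc$region_scale)
      vt <- vapply(val_records, `[[`, 0, "affinity")
      val_mse <- mean((pv$affinity - vt)^2)
      if (val_mse < best_val - 1e-9) {
        best_val <- val_mse; best_weights <- cur; stall <- 0L
      } else stall <- stall + 1L
    }
    history[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss,
                                   val_mse = val_mse)
    if (tc$verbose)
      message(sprintf("epoch %d  loss %.4f  val_mse %s", epoch, ep_loss,
                      ifelse(is.na(val_mse), "-", sprintf("%.4f", val_mse))))
    if (!is.null(val_records) && stall >= tc$patience) break
  }
  final <- if (!is.null(best_weights)) best_weights else ad_values(params)
  structure(list(weights = final, cfg = cfg, subvocab = fz$subvocab,
                 history = do.call(rbind, history), regime = regime),
            class = "mg_fit")
}

#' Repeated k-fold cross-validation
#'
#' Splits the records into `n_folds` folds, trains on all-but-one and
#' evaluates on the held-out fold, repeated `n_repeats` times with fresh
#' shuffles. Desk-scale tests use single splits; this runner exists for
#' protocol parity with repeated-CV evaluation (default 10 x 5-fold).
#'
#' @param records list of [pair_record()]s
#' @param cfg an [mg_config()]
#' @param regime,tc,seed forwarded to [train_model()]
#' @param n_repeats,n_folds repetition and fold counts
#' @return data.frame with one row per (repeat, fold): mse, ci, rm2
#' @export
cross_validate <- function(records, cfg, regime = "affinity_only",
                           tc = train_config(), seed = 1L,
                           n_repeats = 10L, n_folds = 5L) {
  n <- length(records)
  if (n < n_folds) stop("fewer records than folds")
  out <- list()
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  for (rep_i in seq_len(n_repeats)) {
    set.seed(seed + rep_i)
    ord <- sample.int(n)
    fold_of <- rep(seq_len(n_folds), length.out = n)[order(ord)]
    for (fold in seq_len(n_folds)) {
      tr <- records[fold_of != fold]
      te <- records[fold_of == fold]
      fit <- train_model(tr, cfg, regime = regime, tc = tc,
                         seed = seed + 1000L * rep_i + fold)
      pred <- mg_predict(fit$weights, te, cfg, fit$subvocab, tc$region_scale)
      truth <- vapply(te, `[[`, 0, "affinity")
      m <- evaluate_affinity(pred$affinity, truth)
      out[[length(out) + 1L]] <- data.frame(rep = rep_i, fold = fold,
                                            mse = m$mse, ci = m$ci, rm2 = m$rm2)
    }
  }
  do.call(rbind, out)
}

#' Evaluate affinity metrics of predictions against labels
#' @param pred,truth numeric vectors
#' @param aupr_threshold binarization threshold for AUPR (default pKd 7)
#' @return named list with mse, ci, rm2, aupr (aupr NA when one-class)
#' @export
evaluate_affinity <- function(pred, truth, aupr_threshold = 7) {
  aupr <- tryCatch(aupr_score(pred, truth, aupr_threshold), error = function(e) NA_real_)
  list(mse = mean((pred - truth)^2),
       ci = concordance_index(pred, truth),
       rm2 = rm2_score(pred, truth),
       aupr = aupr)
}
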