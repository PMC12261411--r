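#' Training configuration for the enhancer
#'
#' @param beta Non-negative weight of the restored-map prior (default 1e-3).
#' @param prior `"l1_sparsity"` or `"total_variation"`.
#' @param steps Number of optimization steps (default 400).
#' @param batch Patches per step (default 2).
#' @param learning_rate Initial Adam step size (default 0.01).
#' @param lr_decay Fraction of `learning_rate` reached at the final step
#'   under an exponential schedule (default 0.01); 1 disables decay.
#' @param patch_side Training patch side in bins (default 40, >= 8).
#' @param seed Integer master seed (weight init, batch shuffling).
#' @param loss_weights Length-2 numeric `c(w_restore, w_kernel)`: weights
#'   of the restoration data term and the degradation-kernel consistency
#'   term (default `c(1, 0.5)`).
#' @param consistency_weight Weight of the degradation-tail data term
#'   `mean((L - T(H_hat))^2)` under the estimated kernel (default 20;
#'   this term lives on a much smaller scale than the restoration error,
#'   so it needs a large weight to be binding). Together with
#'   `beta * P(H_hat)` this is the blind-SR objective evaluated at the
#'   network's own kernel estimate; it keeps the estimator honest about
#'   the degradation it reports.
#' @param n_alternations Estimator/restorer rounds per forward pass
#'   (default 5).
#' @param k_side Odd side of the estimated degradation kernel (default 3).
#' @param hidden Estimator MLP hidden width (default 8).
#' @param loss_type `"l1"` (robust to count outliers; default) or `"l2"`
#'   for the two data terms.
#' @return A `train_config` list.
#' @export
train_config <- function(beta = 1e-3, prior = c("l1_sparsity", "total_variation"),
                         steps = 400L, batch = 2L, learning_rate = 0.01,
                         lr_decay = 0.01, patch_side = 40L, seed = 1L,
                         loss_weights = c(1, 0.5), consistency_weight = 20,
                         n_alternations = 5L,
                         k_side = 3L, hidden = 8L,
                         loss_type = c("l1", "l2")) {
  prior <- match.arg(prior)
  loss_type <- match.arg(loss_type)
  if (beta < 0) stop("train_config: beta must be >= 0")
  if (steps < 1) stop("train_config: steps must be >= 1")
  if (patch_side < 8) stop("train_config: patch_side must be >= 8")
  if (length(loss_weights) != 2 || any(loss_weights < 0))
    stop("train_config: loss_weights must be two non-negative numbers")
  if (consistency_weight < 0)
    stop("train_config: consistency_weight must be >= 0")
  if (lr_decay <= 0 || lr_decay > 1)
    stop("train_config: lr_decay must be in (0, 1]")
  structure(list(beta = beta, prior = prior, steps = as.integer(steps),
                 batch = as.integer(batch), learning_rate = learning_rate,
                 lr_decay = lr_decay,
                 patch_side = as.integer(patch_side), seed = as.integer(seed),
                 loss_weights = loss_weights,
                 consistency_weight = consistency_weight,
                 n_alternations = as.integer(n_alternations),
                 k_side = as.integer(k_side), hidden = as.integer(hidden),
                 loss_type = loss_type),
            class = "train_config")
}

# loss + gradients for one (hr, lr) pair.
# Joint loss: w_restore * |H_hat - HR| + w_kernel * |T(HR) - LR| + beta * P(H_hat),
# all terms as means in normalized space.
pair_loss_grad <- function(params, dm, hr, lr, cfg) {
  s <- net_norm_scale(lr)
  ln <- lr / s
  hrn <- hr / s
  npix <- length(ln)
  fw <- net_forward_core(params, lr, cfg$n_alternations, cfg$k_side,
                         keep_tape = TRUE)
  diff <- fw$h_out - hrn
  w_r <- cfg$loss_weights[1]; w_k <- cfg$loss_weights[2]
  if (cfg$loss_type == "l1") {
    loss_restore <- w_r * mean(abs(diff))
    dh_out <- w_r * sign(diff) / npix
  } else {
    loss_restore <- w_r * mean(diff^2)
    dh_out <- w_r * 2 * diff / npix
  }
  loss_prior <- cfg$beta * prior_value(fw$h_out, cfg$prior)
  dh_out <- dh_out + prior_grad(fw$h_out, cfg$prior, cfg$beta)
  # degradation-tail consistency: the blind-SR data term ||L - T(H_hat)||^2
  # under the estimated kernel (always squared form)
  w_c <- cfg$consistency_weight
  loss_cons <- 0
  dk_last <- NULL; dscale_last <- 0
  if (w_c > 0) {
    ct <- conv2(fw$h_out, fw$est$kernel)
    e2 <- fw$est$scale * ct - ln
    loss_cons <- w_c * mean(e2^2)
    de2 <- w_c * 2 * e2 / npix
    dh_out <- dh_out + fw$est$scale * conv2_adj(de2, fw$est$kernel)
    dk_last <- fw$est$scale * conv2_kgrad(fw$h_out, de2, cfg$k_side)
    dscale_last <- sum(de2 * ct)
  }
  net_gr <- net_backward_core(params, fw, dh_out, cfg$k_side,
                              dk_last = dk_last, dscale_last = dscale_last)
  # degradation-kernel consistency term (standalone operator on HR)
  sc <- softplus(dm$scale_raw)
  th <- conv2(hrn, dm$kernel)
  e <- sc * th - ln
  if (cfg$loss_type == "l1") {
    loss_kern <- w_k * mean(abs(e))
    de <- w_k * sign(e) / npix
  } else {
    loss_kern <- w_k * mean(e^2)
    de <- w_k * 2 * e / npix
  }
  d_kernel <- sc * conv2_kgrad(hrn, de, nrow(dm$kernel))
  d_scale_raw <- sum(de * th) * sigmoid(dm$scale_raw)
  list(loss = loss_restore + loss_kern + loss_prior + loss_cons,
       net_grads = net_gr,
       dm_grads = list(kernel = d_kernel, scale_raw = d_scale_raw),
       h_out = fw$h_out)
}

adam_init <- function(template) {
  list(m = lapply(template, function(p) p * 0),
       v = lapply(template, function(p) p * 0), t = 0L)
}

adam_update <- function(values, grads, state, lr, b1 = 0.9, b2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(values)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    values[[nm]] <- values[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(values = values, state = state)
}

#' Train the enhancer on high/low-coverage pairs
#'
#' Jointly optimizes the alternating network and the standalone
#' degradation operator by Adam (with an exponential learning-rate
#' schedule) on the loss
#' `w_restore * |H_hat - H| + w_kernel * |T(H) - L|`
#' `+ w_consist * ||L - T_est(H_hat)||^2 + beta * P(H_hat)`
#' (means in normalized space; `"l2"` variants of the first two terms
#' available). The third term is the blind-SR objective's data term under
#' the network's own kernel estimate. Seeded and deterministic: identical
#' config and data give an identical loss trace.
#'
#' @param pairs List of `list(hr, lr, ...)` pairs, e.g. from
#'   [make_training_pairs()]; all patches must share one side length.
#' @param cfg A [train_config()].
#' @param val_pairs Optional held-out pairs: when given together with
#'   `checkpoint_every > 0`, the degradation-consistency data term
#'   `mean((L - T(H_hat))^2)` (normalized space, estimated kernel) is
#'   logged over them at every checkpoint.
#' @param checkpoint_every Checkpoint interval in steps (0 = off).
#' @return List with `net` (trained [alternating_network()]), `dm`
#'   (trained [degradation_model()]), `loss_trace` (one value per step),
#'   and `val_trace` (data frame of checkpointed validation data terms,
#'   or `NULL`).
#' @export
train_enhancer <- function(pairs, cfg = train_config(), val_pairs = NULL,
                           checkpoint_every = 0L) {
  if (length(pairs) < 1) stop("train_enhancer: need at least one pair")
  sides <- vapply(pairs, function(p) nrow(p$hr), 1L)
  if (length(unique(sides)) != 1)
    stop("train_enhancer: patches must share one side length")
  net <- alternating_network(cfg$n_alternations, cfg$k_side, cfg$hidden,
                             seed = cfg$seed)
  dm <- degradation_model(cfg$k_side)
  dm_vals <- list(kernel = dm$kernel, scale_raw = dm$scale_raw)
  st_net <- adam_init(net$params)
  st_dm <- adam_init(dm_vals)
  val_data_term <- function(params) {
    mean(vapply(val_pairs, function(p) {
      fw <- net_forward_core(params, p$lr, cfg$n_alternations, cfg$k_side)
      mean((fw$ln - fw$est$scale * conv2(fw$h_out, fw$est$kernel))^2)
    }, numeric(1)))
  }
  do_val <- !is.null(val_pairs) && checkpoint_every > 0
  val_steps <- integer(0); val_vals <- numeric(0)
  if (do_val) { val_steps <- 0L; val_vals <- val_data_term(net$params) }
  set.seed(cfg$seed + 3L)
  trace <- numeric(cfg$steps)
  for (step in seq_len(cfg$steps)) {
    lr_t <- cfg$learning_rate * cfg$lr_decay^((step - 1) / cfg$steps)
    idx <- sample.int(length(pairs), min(cfg$batch, length(pairs)))
    gsum_net <- zero_like(net$params)
    gsum_dm <- zero_like(dm_vals)
    lsum <- 0
    for (i in idx) {
      dm$kernel <- dm_vals$kernel; dm$scale_raw <- dm_vals$scale_raw
      pl <- pair_loss_grad(net$params, dm, pairs[[i]]$hr, pairs[[i]]$lr, cfg)
      lsum <- lsum + pl$loss
      for (nm in names(gsum_net))
        gsum_net[[nm]] <- gsum_net[[nm]] + pl$net_grads[[nm]] / length(idx)
      for (nm in names(gsum_dm))
        gsum_dm[[nm]] <- gsum_dm[[nm]] + pl$dm_grads[[nm]] / length(idx)
    }
    trace[step] <- lsum / length(idx)
    if (!is.finite(trace[step]))
      stop("train_enhancer: non-finite loss at step ", step,
           " (learning rate too high or degenerate input)")
    up <- adam_update(net$params, gsum_net, st_net, lr_t)
    net$params <- up$values; st_net <- up$state
    up <- adam_update(dm_vals, gsum_dm, st_dm, lr_t)
    dm_vals <- up$values; st_dm <- up$state
    if (do_val && (step %% checkpoint_every == 0 || step == cfg$steps)) {
      val_steps <- c(val_steps, step)
      val_vals <- c(val_vals, val_data_term(net$params))
    }
  }
  net$trained <- TRUE
  dm$kernel <- dm_vals$kernel; dm$scale_raw <- dm_vals$scale_raw
  list(net = net, dm = dm, loss_trace = trace,
       val_trace = if (do_val) data.frame(step = val_steps, data_term = val_vals)
                   else NULL)
}

#' Enhance a contact map with a trained network
#'
#' Tiles the map into overlapping patches, restores each with
#' [alternate_forward()], reassembles with overlap averaging, symmetrizes
#' and clamps at zero. Metadata is copied from the input.
#'
#' @param net A trained [alternating_network()].
#' @param cm A [contact_map()].
#' @param patch_side Patch side (default 40; capped at `n_bins`).
#' @param stride Patch anchor spacing (default `patch_side`).
#' @param force Allow an untrained network (default `FALSE`).
#' @return Enhanced [contact_map()].
#' @export
enhance_map <- function(net, cm, patch_side = 40L, stride = patch_side,
                        force = FALSE) {
  stopifnot(inherits(net, "alternating_network"), is_contact_map(cm))
  if (!net$trained && !force)
    stop("enhance_map: network is untrained (pass force = TRUE to override)")
  side <- min(patch_side, cm$n_bins)
  patches <- extract_patches(cm, side = side, stride = min(stride, side))
  out_patches <- lapply(patches, function(p) {
    list(values = alternate_forward(net, p$values)$h_hat, origin = p$origin)
  })
  m <- reassemble(out_patches, cm$n_bins)
  m <- pmax(symmetrize(m), 0)
  contact_map(m, cm$resolution_bp, cm$chrom, cm$start_bp)
}

#' Save / load an enhancer checkpoint
#'
#' Checkpoints are single JSON text files holding a format version, the
#' network hyper-parameters and weights, the degradation operator, and an
#' echo of the training configuration.
#'
#' @param net An [alternating_network()].
#' @param dm A [degradation_model()].
#' @param path Output path.
#' @param config Optional [train_config()] echoed into the file.
#' @export
save_checkpoint <- function(net, dm, path, config = NULL) {
  stopifnot(inherits(net, "alternating_network"),
            inherits(dm, "degradation_model"))
  obj <- list(
    format_version = 1L,
    n_alternations = net$n_alternations, k_side = net$k_side,
    hidden = net$hidden, trained = net$trained,
    params = lapply(net$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = NULL, data = as.numeric(p))
    }),
    degradation = list(kernel = list(dim = dim(dm$kernel),
                                     data = as.numeric(dm$kernel)),
                       scale_raw = dm$scale_raw),
    config = if (is.null(config)) NULL else unclass(config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns `list(net, dm, config)`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stop("load_checkpoint: unsupported checkpoint format")
  net <- alternating_network(obj$n_alternations, obj$k_side, obj$hidden)
  net$params <- lapply(obj$params, function(p) {
    if (!is.null(p$dim) && length(p$dim)) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  net$trained <- isTRUE(obj$trained)
  dm <- degradation_model(obj$k_side)
  dm$kernel <- matrix(obj$degradation$kernel$data,
                      obj$degradation$kernel$dim[1],
                      obj$degradation$kernel$dim[2])
  dm$scale_raw <- obj$degradation$scale_raw
  list(net = net, dm = dm, config = obj$config)
}
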