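#' Build a pipeline configuration
#'
#' Nested configuration for the end-to-end flow, with the training
#' defaults of the published setting (Adam optimizer, 150 epochs, batch
#' size 16) exposed and overridable. Unknown section or key names are
#' rejected.
#'
#' @param ... Named overrides per section, e.g.
#'   `train = list(epochs = 20)`, `zos_mamba = list(voxel_size = 0.3)`.
#' @return A `pipeline_config` list with sections `io`, `mde`,
#'   `zos_mamba`, `aloc`, `train`, `eval`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    io = list(normalize = "per_block"),
    mde = list(enabled = TRUE, d_s = 64, d_feat = 64, n_branch = 3, K = 16,
               d_out = 8, tau_g = 0.5, activation = "tanh",
               residual_input = "coords"),
    zos_mamba = list(enabled = TRUE, voxel_size = 0.2, state_dim = 8,
                     n_layers = 1, scan_mode = "sequential"),
    aloc = list(enabled = TRUE, size_threshold = 5000, budget = 50,
                downsample = 0.4, f_scale = 0.5, alpha = 0.7,
                replacement = "connectivity"),
    train = list(optimizer = "adam", epochs = 150, batch_size = 16,
                 lr = 0.01, weight_decay = 0.001, hidden = 16, seed = 1L),
    eval = list(tau = 0.5)
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) stop("unknown config section: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (sec in names(overrides)) {
    badkey <- setdiff(names(overrides[[sec]]), names(defaults[[sec]]))
    if (length(badkey)) stop(sprintf("unknown key in [%s]: %s", sec,
                                     paste(badkey, collapse = ", ")), call. = FALSE)
    defaults[[sec]][names(overrides[[sec]])] <- overrides[[sec]]
  }
  structure(defaults, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML file whose top-level keys are config
#'   sections (see [pipeline_config()]).
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

build_model <- function(config) {
  seed <- config$train$seed
  enc <- if (isTRUE(config$mde$enabled)) {
    encoder_params(d_s = config$mde$d_s, d_feat = config$mde$d_feat,
                   n_branch = config$mde$n_branch, K = config$mde$K,
                   d_out = config$mde$d_out, tau_g = config$mde$tau_g,
                   activation = config$mde$activation,
                   residual_input = config$mde$residual_input,
                   seed = seed)
  }
  d_struct <- if (isTRUE(config$mde$enabled)) config$mde$d_out else 3L
  ssm <- if (isTRUE(config$zos_mamba$enabled)) {
    ssm_block(d_struct, n_state = config$zos_mamba$state_dim, seed = seed + 1L)
  } else {
    # plain per-point MLP replacement for the serialized scan (ablation)
    rngl <- local_rng(seed + 1L)
    list(W1 = rngl(function() matrix(stats::rnorm(2 * d_struct * d_struct,
                                                  sd = 1 / sqrt(d_struct)),
                                     2 * d_struct, d_struct)),
         b1 = rep(0, 2 * d_struct),
         W2 = rngl(function() matrix(stats::rnorm(d_struct * 2 * d_struct,
                                                  sd = 1 / sqrt(2 * d_struct)),
                                     d_struct, 2 * d_struct)),
         b2 = rep(0, d_struct))
  }
  list(encoder = enc, ssm = ssm, d_struct = d_struct)
}

# Per-point features: geometric cues + encoder output + serialized-scan
# output, in the pipeline order encode -> structure.
featurize_block <- function(pc, ann, config, model) {
  norm <- normalize_coords(pc)
  col <- paste(floor(pc$x), floor(pc$y))          # 1 m XY columns
  colmax <- tapply(pc$z, col, max)
  # floor the column height at 1 m: a ground-only column otherwise
  # divides near-zero and a single noisy return explodes the feature
  relh <- pc$z / pmax(as.numeric(colmax[col]), 1)
  dens <- as.numeric(table(col)[col])
  dens <- dens / max(dens)
  # the saturating canopy-presence cue accompanies the relative-height one:
  # an all-ground block has relh ~ 1 everywhere and only the absolute column
  # height separates it from a canopy top, while tanh compresses the young
  # vs mature height difference so the cue transfers across growth stages
  # block-normalized z is deliberately absent: it confounds growth stages
  # (a young crown sits at the block height of a mature trunk)
  geom <- cbind(relh, dens, tanh(as.numeric(colmax[col]) / 5))
  f_struct <- if (isTRUE(config$mde$enabled)) {
    encode_points(pc, ann, model$encoder)$features
  } else {
    as.matrix(norm$pc[, c("x", "y", "z")])
  }
  f_seq <- if (isTRUE(config$zos_mamba$enabled)) {
    ssm_encode(pc, f_struct, voxel_size = config$zos_mamba$voxel_size,
               block = model$ssm, mode = config$zos_mamba$scan_mode)
  } else {
    mlp_forward(model$ssm, f_struct, "tanh")
  }
  # learned features are standardized within the block: they are functions
  # of block-normalized coordinates, so their location/scale is block
  # specific and would not transfer across blocks otherwise. The geometric
  # cues keep their physical scale.
  cbind(geom, scale_block(f_struct), scale_block(f_seq))
}

# Number of geometric cue columns produced by featurize_block; the
# remaining columns are learned-feature channels.
N_GEOM <- 3L

# Gain on the learned-feature channels relative to the geometric cues,
# applied after global standardization. The encoder stack is a fixed
# featurizer here, not trained end to end, so its channels act as
# positional refinements; a modest gain keeps the small semantic head from
# over-committing to them on tiny training sets.
FEATURE_GAIN <- 0.2

scale_block <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd < 1e-6 | !is.finite(sd)] <- 1   # near-constant channels stay centred
  out <- sweep(sweep(X, 2, mu), 2, sd, "/")
  pmin(pmax(out, -10), 10)              # winsorize numerical blow-ups
}

#' Train the semantic head on labelled blocks
#'
#' The encoder and serialized-scan stages are fixed, seeded featurizers;
#' training fits the small semantic head (binary cross-entropy on crown vs
#' background) with Adam. Deterministic given the config seed: every
#' epoch's minibatch order derives from `seed + epoch`, so an interrupted
#' run resumed from a checkpoint reproduces the uninterrupted run exactly.
#'
#' @param config A [pipeline_config()].
#' @param train_blocks,val_blocks Lists of blocks; each block is a list
#'   with `pc` (labelled [point_cloud()]) and optionally `annotations`.
#' @param epochs Override of `config$train$epochs`.
#' @param resume Optional checkpoint to continue from.
#' @param quiet Suppress per-epoch messages.
#' @return A `tp_checkpoint`: head weights, optimizer state, config,
#'   training log (`epoch`, `loss`, `val_miou`).
#' @export
train <- function(config, train_blocks, val_blocks = list(), epochs = NULL,
                  resume = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(train_blocks) == 0) stop("empty training set", call. = FALSE)
  epochs <- epochs %||% config$train$epochs
  model <- build_model(config)
  feats <- function(blocks, record = NULL) {
    X <- do.call(rbind, lapply(blocks, function(b) {
      featurize_block(b$pc, b$annotations, config, model)
    }))
    y <- unlist(lapply(blocks, function(b) b$pc[["semantic"]]))
    list(X = scale_features(X, record), y = y)
  }
  tr <- feats(train_blocks)
  va <- if (length(val_blocks)) feats(val_blocks, attr(tr$X, "scale_record"))
  seed <- config$train$seed
  if (is.null(resume)) {
    par <- head_init(ncol(tr$X), hidden = config$train$hidden, seed = seed)
    opt <- adam_init(par)
    log <- tibble::tibble(epoch = integer(), loss = double(), val_miou = double())
    start_epoch <- 1L
  } else {
    stopifnot(inherits(resume, "tp_checkpoint"))
    par <- resume$par; opt <- resume$opt
    log <- resume$log; start_epoch <- resume$epoch + 1L
  }
  n <- nrow(tr$X)
  bs <- config$train$batch_size
  # balanced class weights from the training label frequencies
  n1 <- sum(tr$y == 1); n0 <- n - n1
  cw <- if (n0 > 0 && n1 > 0) c(n / (2 * n0), n / (2 * n1)) else c(1, 1)
  if (epochs >= start_epoch) for (ep in start_epoch:epochs) {
    rng <- local_rng(seed + ep)
    ord <- rng(function() sample.int(n))
    losses <- c()
    for (b0 in seq(1, n, by = bs)) {
      idx <- ord[b0:min(b0 + bs - 1, n)]
      g <- head_grad(par, tr$X[idx, , drop = FALSE], tr$y[idx], w = cw)
      upd <- adam_step(par, g$grads, opt, lr = config$train$lr,
                       weight_decay = config$train$weight_decay)
      par <- upd$par; opt <- upd$state
      losses <- c(losses, g$loss)
    }
    vm <- if (is.null(va)) NA_real_ else {
      pr <- head_forward(par, va$X)$prob
      semantic_miou(as.integer(pr > 0.5), va$y)
    }
    log <- dplyr::bind_rows(log, tibble::tibble(epoch = ep, loss = mean(losses),
                                                val_miou = vm))
    if (!quiet) message(sprintf("epoch %d  loss %.4f  val mIoU %s", ep,
                                mean(losses),
                                if (is.na(vm)) "-" else sprintf("%.4f", vm)))
  }
  structure(list(par = par, opt = opt, epoch = max(epochs, start_epoch - 1L),
                 config = config, log = log,
                 feature_scale = attr(tr$X, "scale_record"),
                 d_in = ncol(tr$X)),
            class = "tp_checkpoint")
}

scale_features <- function(X, record = NULL) {
  if (is.null(record)) {
    mu <- colMeans(X)
    sd <- apply(X, 2, stats::sd)
    sd[sd == 0 | !is.finite(sd)] <- 1
    gain <- rep(1, ncol(X))
    if (ncol(X) > N_GEOM) gain[(N_GEOM + 1):ncol(X)] <- FEATURE_GAIN
    record <- list(mu = mu, sd = sd, gain = gain)
  }
  out <- sweep(sweep(X, 2, record$mu), 2, record$sd, "/")
  out <- pmin(pmax(out, -10), 10)
  out <- sweep(out, 2, record$gain %||% rep(1, ncol(X)), "*")
  attr(out, "scale_record") <- record
  out
}

#' Segment a point cloud with a trained checkpoint
#'
#' Runs the feature stack, thresholds the semantic head at probability
#' 0.5, and refines the crown (foreground) points into instances with the
#' adaptive clustering stage (or a drop-in replacement backend when
#' disabled). When `ann` is `NULL` the encoder runs in 3D-only mode.
#' Background points receive instance 0.
#'
#' @param config A [pipeline_config()] compatible with the checkpoint.
#' @param checkpoint A `tp_checkpoint` from [train()].
#' @param pc The [point_cloud()] to segment.
#' @param ann Optional [crown_annotation_set()].
#' @param val_fn Optional feedback scorer for the adaptive stage; a
#'   label-free proxy scorer is used by default.
#' @param seed Seed for the adaptive search.
#' @return A `segmentation_result`: the input cloud with `prob`,
#'   `pred_semantic` and `pred_instance` columns, plus provenance.
#' @export
segment <- function(config, checkpoint, pc, ann = NULL, val_fn = NULL,
                    seed = 1L) {
  stopifnot(inherits(checkpoint, "tp_checkpoint"))
  model <- build_model(config)
  X <- featurize_block(pc, ann, config, model)
  if (ncol(X) != checkpoint$d_in) stop("checkpoint incompatible with config", call. = FALSE)
  X <- scale_features(X, checkpoint$feature_scale)
  prob <- head_forward(checkpoint$par, X)$prob
  sem <- as.integer(prob > 0.5)
  work <- pc
  work[["semantic"]] <- sem
  inst <- if (!any(sem == 1L)) {
    rep(0L, nrow(pc))
  } else if (isTRUE(config$aloc$enabled)) {
    val_fn <- val_fn %||% make_proxy_scorer(work)
    fit <- optimize_clustering(work, val_fn,
                               max_iter = config$aloc$budget, seed = seed,
                               size_threshold = config$aloc$size_threshold,
                               downsample = config$aloc$downsample,
                               f_scale = config$aloc$f_scale,
                               alpha = config$aloc$alpha)
    fit$instance
  } else {
    fg <- which(sem == 1L)
    lab <- switch(config$aloc$replacement,
      connectivity = cluster_connectivity(work[fg, ], eps = 1, min_pts = 5),
      knn = cluster_knn(work[fg, ], k = 8, merge_dist = 1),
      meanshift = cluster_meanshift(work[fg, ], bandwidth = 1.5, min_size = 10),
      stop("unknown replacement backend", call. = FALSE))
    out <- rep(0L, nrow(pc)); out[fg] <- lab; out
  }
  res <- pc
  res$prob <- prob
  res$pred_semantic <- sem
  res$pred_instance <- as.integer(inst)
  structure(list(points = res,
                 provenance = list(config_hash = rlang::hash(unclass(config)),
                                   seed = seed,
                                   package_version = as.character(utils::packageVersion("treeparse3d")),
                                   mode = if (is.null(ann)) "3d_only" else "multimodal")),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  p <- x$points
  cat(sprintf("# Segmentation result: %d points, %d instances (%s mode)\n",
              nrow(p), length(unique(p$pred_instance[p$pred_instance > 0])),
              x$provenance$mode))
  invisible(x)
}

#' Report model complexity
#'
#' Exact trainable-parameter count of the full model (encoder +
#' serialized-scan block + head) and a dense FLOP estimate (2 x
#' multiply-accumulates of every linear map) for one forward pass at a
#' stated number of points.
#'
#' @param config A [pipeline_config()].
#' @param checkpoint Optional checkpoint (for the trained head size);
#'   a default-sized head is assumed otherwise.
#' @param n_points Input size for the FLOP estimate.
#' @return List with `param_count` and `flop_estimate`.
#' @export
report_complexity <- function(config, checkpoint = NULL, n_points = 10000) {
  model <- build_model(config)
  d_in <- 3L + model$d_struct + model$d_struct
  head <- if (!is.null(checkpoint)) checkpoint$par
          else head_init(d_in, hidden = config$train$hidden)
  parts <- list(encoder = model$encoder, ssm = model$ssm, head = head)
  param_count <- count_params(parts)
  flops_linear <- function(w) 2 * length(w)
  per_point <- sum(unlist(rapply(parts, function(x)
    if (is.matrix(x)) flops_linear(x) else 0, how = "unlist")), na.rm = TRUE)
  list(param_count = param_count,
       flop_estimate = per_point * n_points)
}

#' Split labelled blocks into train/validation/test sets
#'
#' Mirrors a 23/8/5 block split proportionally: blocks are assigned in
#' order with ratios 23:8:5 (at least one block per non-empty split when
#' the counts allow).
#'
#' @param blocks List of blocks.
#' @return List with `train`, `val`, `test` lists of blocks.
#' @export
split_blocks <- function(blocks) {
  n <- length(blocks)
  n_test <- max(1, round(n * 5 / 36))
  n_val <- max(1, round(n * 8 / 36))
  n_train <- n - n_val - n_test
  if (n_train < 1) stop("need at least 3 blocks to split", call. = FALSE)
  list(train = blocks[seq_len(n_train)],
       val = blocks[n_train + seq_len(n_val)],
       test = blocks[n_train + n_val + seq_len(n_test)])
}
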