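# The efficacy network: two independent Oligo encoders (siRNA 19 x D,
# mRNA 57 x D) each running 2D convolution -> max pooling -> average pooling
# -> bidirectional LSTM -> two-layer multi-head transformer encoder ->
# flatten, late-fused by plain concatenation with the pooled pretrained
# embeddings and the thermodynamic vector into an MLP head with sigmoid
# output.

#' Model configuration
#'
#' @param hidden_dim Master hidden size; the BiLSTM uses this many units per
#'   direction, so the transformer model width is `2 * hidden_dim`.
#' @param conv_out_channels Output channels of the 3x3 convolution.
#' @param lstm_hidden LSTM hidden units per direction (defaults to
#'   `hidden_dim`).
#' @param transformer_layers Number of transformer encoder layers (default 2).
#' @param attention_heads Attention heads (must divide `2 * lstm_hidden`).
#' @param transformer_ff Width of the transformer feed-forward layer.
#' @param dropout Dropout probability during training (0 disables).
#' @param mlp_hidden_sizes Integer vector of MLP head hidden widths.
#' @param use_sirna,use_mrna,use_pretrained,use_thermo Feature-group switches:
#'   siRNA sequence encoder, mRNA sequence encoder, pretrained embedding
#'   channel, thermodynamic features. At least one must be on.
#' @param sirna_len,mrna_len Sequence lengths (19 and 57 at defaults).
#' @param seq_dim Width of the encoder input embedding (5 = one-hot over
#'   A/C/G/U/X).
#' @param pretrained_dim Width of the pretrained per-position embeddings
#'   entering fusion as position means (640 for the language-model adapter
#'   and its fallback).
#' @param loss `"mse"` (default; the sigmoid score is trained as a regression
#'   on normalized efficacy) or `"bce"`.
#' @return A `sirna_config` list.
#' @export
sirna_config <- function(hidden_dim = 64L,
                         conv_out_channels = 16L,
                         lstm_hidden = hidden_dim,
                         transformer_layers = 2L,
                         attention_heads = 8L,
                         transformer_ff = 256L,
                         dropout = 0,
                         mlp_hidden_sizes = 64L,
                         use_sirna = TRUE, use_mrna = TRUE,
                         use_pretrained = TRUE, use_thermo = TRUE,
                         sirna_len = 19L, mrna_len = 57L,
                         seq_dim = 5L,
                         pretrained_dim = 640L,
                         loss = c("mse", "bce")) {
  cfg <- list(hidden_dim = as.integer(hidden_dim),
              conv_out_channels = as.integer(conv_out_channels),
              lstm_hidden = as.integer(lstm_hidden),
              transformer_layers = as.integer(transformer_layers),
              attention_heads = as.integer(attention_heads),
              transformer_ff = as.integer(transformer_ff),
              dropout = dropout,
              mlp_hidden_sizes = as.integer(mlp_hidden_sizes),
              use_sirna = use_sirna, use_mrna = use_mrna,
              use_pretrained = use_pretrained, use_thermo = use_thermo,
              sirna_len = as.integer(sirna_len), mrna_len = as.integer(mrna_len),
              seq_dim = as.integer(seq_dim),
              pretrained_dim = as.integer(pretrained_dim),
              loss = match.arg(loss))
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  dims <- c(cfg$hidden_dim, cfg$conv_out_channels, cfg$lstm_hidden,
            cfg$transformer_layers, cfg$attention_heads, cfg$transformer_ff,
            cfg$mlp_hidden_sizes, cfg$seq_dim, cfg$pretrained_dim)
  if (any(dims <= 0)) stop("config error: all dimensions must be positive")
  if (!any(unlist(cfg[c("use_sirna", "use_mrna", "use_pretrained", "use_thermo")])))
    stop("config error: at least one feature switch must be on")
  d_model <- 2L * cfg$lstm_hidden
  if (d_model %% cfg$attention_heads != 0L)
    stop("config error: attention_heads must divide 2 * lstm_hidden = ", d_model)
  if (cfg$seq_dim < 4L)
    stop("config error: seq_dim must be >= 4 to survive two width-2 poolings")
  invisible(cfg)
}

# width of the per-position feature after conv + max pool + avg pool
enc_lstm_input_dim <- function(cfg, D = cfg$seq_dim) {
  cfg$conv_out_channels * ((D %/% 2L) %/% 2L)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

.param_id_counter <- new.env(parent = emptyenv())
.param_id_counter$n <- 0L

tag_param <- function(m) {
  .param_id_counter$n <- .param_id_counter$n + 1L
  attr(m, "param_id") <- .param_id_counter$n
  m
}

init_encoder_params <- function(cfg, D = cfg$seq_dim) {
  C <- cfg$conv_out_channels
  H <- cfg$lstm_hidden
  Fdim <- enc_lstm_input_dim(cfg, D)
  d <- 2L * H
  lstm_dir <- function() list(Wx = tag_param(glorot(Fdim, 4L * H)),
                              Wh = tag_param(glorot(H, 4L * H)),
                              b = tag_param(matrix(0, 1L, 4L * H)))
  tlayer <- function() list(
    Wq = tag_param(glorot(d, d)), bq = tag_param(matrix(0, 1L, d)),
    Wk = tag_param(glorot(d, d)), bk = tag_param(matrix(0, 1L, d)),
    Wv = tag_param(glorot(d, d)), bv = tag_param(matrix(0, 1L, d)),
    Wo = tag_param(glorot(d, d)), bo = tag_param(matrix(0, 1L, d)),
    ln1g = tag_param(matrix(1, 1L, d)), ln1b = tag_param(matrix(0, 1L, d)),
    W1 = tag_param(glorot(d, cfg$transformer_ff)),
    b1 = tag_param(matrix(0, 1L, cfg$transformer_ff)),
    W2 = tag_param(glorot(cfg$transformer_ff, d)),
    b2 = tag_param(matrix(0, 1L, d)),
    ln2g = tag_param(matrix(1, 1L, d)), ln2b = tag_param(matrix(0, 1L, d)))
  list(conv_W = tag_param(glorot(C, 9L) * 3),  # fan-in 9 is tiny; widen a bit
       conv_b = tag_param(matrix(0, 1L, C)),
       lstm_f = lstm_dir(), lstm_b = lstm_dir(),
       transformer = replicate(cfg$transformer_layers, tlayer(), simplify = FALSE))
}

head_input_dim <- function(cfg) {
  d <- 2L * cfg$lstm_hidden
  n <- 0L
  if (cfg$use_sirna) n <- n + cfg$sirna_len * d
  if (cfg$use_mrna) n <- n + cfg$mrna_len * d
  if (cfg$use_pretrained) n <- n + 2L * cfg$pretrained_dim
  if (cfg$use_thermo) n <- n + length(thermo_feature_names())
  n
}

init_head_params <- function(cfg) {
  sizes <- c(head_input_dim(cfg), cfg$mlp_hidden_sizes, 1L)
  np <- length(sizes) - 1L
  lapply(seq_len(np), function(i)
    # zero-init the output layer: training starts at score 0.5 with
    # well-scaled first gradients regardless of the fused input width
    list(W = tag_param(if (i == np) matrix(0, sizes[i], sizes[i + 1L])
                       else glorot(sizes[i], sizes[i + 1L])),
         b = tag_param(matrix(0, 1L, sizes[i + 1L]))))
}

#' Initialize model parameters
#'
#' Glorot-uniform weights, zero biases, unit layer-norm gains; every
#' parameter matrix carries a unique `param_id` so encoder independence can
#' be audited.
#'
#' @param cfg A [sirna_config()].
#' @return Nested list of parameter matrices with components `enc_sirna`,
#'   `enc_mrna` (when the switches are on) and `head`.
#' @export
init_params <- function(cfg) {
  p <- list()
  if (cfg$use_sirna) p$enc_sirna <- init_encoder_params(cfg)
  if (cfg$use_mrna) p$enc_mrna <- init_encoder_params(cfg)
  p$head <- init_head_params(cfg)
  p
}

flatten_params <- function(p) {
  out <- list()
  rec <- function(x, path) {
    if (is.matrix(x)) {
      out[[path]] <<- x
    } else if (is.list(x)) {
      for (nm in names(x)) rec(x[[nm]], paste0(path, "$", nm))
      if (is.null(names(x)))
        for (i in seq_along(x)) rec(x[[i]], paste0(path, "[", i, "]"))
    }
  }
  for (nm in names(p)) rec(p[[nm]], nm)
  out
}

#' Total trainable parameter count
#'
#' Closed-form count as a pure function of the configuration; the test suite
#' asserts it equals the size of the instantiated parameter list.
#'
#' @param cfg A [sirna_config()].
#' @return Integer parameter count.
#' @export
parameter_count <- function(cfg) {
  C <- cfg$conv_out_channels; H <- cfg$lstm_hidden
  d <- 2L * H; ff <- cfg$transformer_ff
  Fdim <- enc_lstm_input_dim(cfg)
  enc <- (C * 9L + C) +
    2L * (Fdim * 4L * H + H * 4L * H + 4L * H) +
    cfg$transformer_layers * (4L * (d * d + d) + 2L * d +  # attention + ln1
                              d * ff + ff + ff * d + d + 2L * d)
  n_enc <- sum(cfg$use_sirna, cfg$use_mrna)
  sizes <- c(head_input_dim(cfg), cfg$mlp_hidden_sizes, 1L)
  head <- sum(sizes[-length(sizes)] * sizes[-1L] + sizes[-1L])
  n_enc * enc + head
}

ad_linear <- function(x, W, b) ad_add(ad_mm(x, W), b)

encoder_forward <- function(x, ep, cfg, B, T, D, train = FALSE,
                            shape_log = NULL) {
  C <- cfg$conv_out_channels
  H <- cfg$lstm_hidden
  d <- 2L * H
  log_shape <- function(layer, node) {
    if (!is.null(shape_log))
      shape_log$rows[[length(shape_log$rows) + 1L]] <-
        data.frame(layer = layer, rows = nrow(node$v), cols = ncol(node$v))
  }
  h <- ad_conv3x3(x, ep$conv_W, ep$conv_b, B, T, D)
  log_shape("conv2d_3x3", h)
  h <- ad_pool_pairs(h, C, D, "max")
  log_shape("max_pool_2x1", h)
  h <- ad_pool_pairs(h, C, D %/% 2L, "avg")
  log_shape("avg_pool_2x1", h)
  h <- ad_bilstm(h, ep$lstm_f$Wx, ep$lstm_f$Wh, ep$lstm_f$b,
                 ep$lstm_b$Wx, ep$lstm_b$Wh, ep$lstm_b$b,
                 B, T, H)
  log_shape("bilstm", h)
  for (tl in ep$transformer) {
    q <- ad_linear(h, tl$Wq, tl$bq)
    k <- ad_linear(h, tl$Wk, tl$bk)
    v <- ad_linear(h, tl$Wv, tl$bv)
    a <- ad_mhsa(q, k, v, B, T, cfg$attention_heads)
    a <- ad_linear(a, tl$Wo, tl$bo)
    if (train && cfg$dropout > 0) a <- ad_dropout(a, cfg$dropout)
    h <- ad_layernorm(ad_add(h, a), tl$ln1g, tl$ln1b)
    f <- ad_linear(ad_relu(ad_linear(h, tl$W1, tl$b1)), tl$W2, tl$b2)
    if (train && cfg$dropout > 0) f <- ad_dropout(f, cfg$dropout)
    h <- ad_layernorm(ad_add(h, f), tl$ln2g, tl$ln2b)
    log_shape("transformer_layer", h)
  }
  out <- ad_flatten_seq(h, B, T)
  log_shape("flatten", out)
  out
}

# Wrap a nested parameter list into autodiff leaf nodes (shared per batch so
# gradients accumulate on the same node objects).
wrap_params <- function(p) {
  if (is.matrix(p)) return(ad_leaf(p))
  lapply(p, wrap_params)
}

# Read gradients back in the same nested structure (zero where untouched).
param_grads <- function(pn) {
  if (inherits(pn, "ad_node"))
    return(if (is.null(pn$g)) matrix(0, nrow(pn$v), ncol(pn$v)) else pn$g)
  lapply(pn, param_grads)
}

# Forward pass over a prepared batch. `params_n` is a wrap_params() tree;
# `batch` holds plain matrices: sirna_oh (B*19 x seq_dim), mrna_oh
# (B*57 x seq_dim), pre (B x 2*Dp), thermo (B x thermo width). Returns the
# score node plus the input nodes (for gradient-based attribution).
model_forward <- function(params_n, cfg, batch, B, train = FALSE) {
  params <- params_n
  inputs <- list()
  parts <- list()
  if (cfg$use_sirna) {
    inputs$sirna <- ad_leaf(batch$sirna_oh)
    parts$sirna <- encoder_forward(inputs$sirna, params$enc_sirna, cfg, B,
                                   cfg$sirna_len, cfg$seq_dim, train)

  }
  if (cfg$use_mrna) {
    inputs$mrna <- ad_leaf(batch$mrna_oh)
    parts$mrna <- encoder_forward(inputs$mrna, params$enc_mrna, cfg, B,
                                  cfg$mrna_len, cfg$seq_dim, train)
  }
  if (cfg$use_pretrained) {
    inputs$pre <- ad_leaf(batch$pre)
    parts$pre <- inputs$pre
  }
  if (cfg$use_thermo) {
    inputs$thermo <- ad_leaf(batch$thermo)
    parts$thermo <- inputs$thermo
  }
  h <- if (length(parts) > 1L) ad_cbind(unname(parts)) else parts[[1L]]
  np <- length(params$head)
  for (i in seq_len(np)) {
    h <- ad_linear(h, params$head[[i]]$W, params$head[[i]]$b)
    if (i < np) h <- ad_relu(h)
  }
  # bounded logit keeps the sigmoid derivative away from exact zero, so a
  # mis-stepped optimizer can always recover from saturation
  list(score = ad_sigmoid(ad_softclamp(h)), inputs = inputs)
}

#' Run one sequence through a fresh Oligo encoder
#'
#' Instantiates encoder parameters for the given input width (unless
#' supplied) and runs the full layer stack on a single L x D matrix,
#' returning the flattened embedding with a per-layer shape table attached as
#' `attr(, "shapes")`. Layer order: 2D convolution, max pooling, average
#' pooling, bidirectional LSTM, two-layer multi-head transformer encoder,
#' flatten.
#'
#' @param m Numeric matrix, L x D (L positions, D embedding channels).
#' @param cfg A [sirna_config()].
#' @param params Optional encoder parameter list from an existing model.
#' @param seed Seed for fresh parameter initialization.
#' @return Numeric vector of length `L * 2 * lstm_hidden` with the shape log
#'   attached.
#' @export
oligo_encode <- function(m, cfg = sirna_config(), params = NULL, seed = 1L) {
  stopifnot(is.matrix(m))
  D <- ncol(m)
  if (D < 4L) stop("oligo_encode: input width ", D, " too small for pooling")
  if (is.null(params)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    params <- init_encoder_params(cfg, D)
  } else {
    exp_F <- enc_lstm_input_dim(cfg, D)
    if (ncol(params$conv_W) != 9L || nrow(params$lstm_f$Wx) != exp_F)
      stop("shape error at bilstm: encoder expects per-position width ",
           nrow(params$lstm_f$Wx), " but input of width ", D, " yields ", exp_F)
  }
  shape_log <- new.env(parent = emptyenv())
  shape_log$rows <- list(data.frame(layer = "input", rows = nrow(m), cols = D))
  out <- encoder_forward(ad_leaf(m), wrap_params(params), cfg, 1L, nrow(m), D,
                         shape_log = shape_log)
  v <- as.vector(out$v)
  attr(v, "shapes") <- do.call(rbind, shape_log$rows)
  v
}

collect_param_ids <- function(p) {
  unlist(lapply(flatten_params(p), attr, "param_id"), use.names = FALSE)
}

#' Check that the siRNA and mRNA encoders share no parameters
#'
#' Every parameter matrix carries a unique id from initialization; a tied
#' model (one encoder's matrices copied into the other) is detected by id
#' overlap.
#'
#' @param fit A `sirna_fit` object, or a raw parameter list from
#'   [init_params()].
#' @return `TRUE` when parameter sets are disjoint, else `FALSE`.
#' @export
encoder_independence_check <- function(fit) {
  p <- if (inherits(fit, "sirna_fit")) fit$params else fit
  if (is.null(p$enc_sirna) || is.null(p$enc_mrna)) return(TRUE)
  ids_s <- collect_param_ids(p$enc_sirna)
  ids_m <- collect_param_ids(p$enc_mrna)
  length(intersect(ids_s, ids_m)) == 0L
}
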