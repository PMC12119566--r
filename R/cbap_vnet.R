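# CBAP-VNet: a VNet-style 3D encoder-decoder with CBAM attention on the
# downsampling blocks, an optional parameter-free adaptive channel attention
# block at the input stage, and multi-scale prediction heads feeding the
# uncertainty-rectified consistency loss.

#' Network configuration for CBAP-VNet
#'
#' @param in_channels Number of input channels (1 for grayscale volumes).
#' @param num_classes Number of segmentation classes (>= 2; class 1 is
#'   background).
#' @param base_channels Channel width at full resolution; widths double at
#'   every level.
#' @param num_levels Number of downsampling stages (default 4).
#' @param cbam_positions Character vector, subset of `down1..downL` /
#'   `up1..upL`, naming the stages that carry a CBAM block.
#' @param input_attention Add the adaptive channel attention block (global
#'   average pool, sigmoid gate, elementwise multiply) after the input stem?
#' @param reduction_ratio Bottleneck ratio of the CBAM channel MLP; clamped
#'   per stage to at least 2 and at most the stage's channel count, and must
#'   then divide it.
#' @param spatial_kernel Odd kernel size of the CBAM spatial attention
#'   convolution (zero padding keeps any feature-map size valid).
#' @param pyramid_scales Number of prediction heads S (coarser heads are
#'   trilinearly upsampled to full resolution); at most `num_levels + 1`.
#' @return A `tpssan_netconfig` list.
#' @export
network_config <- function(in_channels = 1L, num_classes = 2L,
                           base_channels = 8L, num_levels = 4L,
                           cbam_positions = paste0("down", seq_len(num_levels)),
                           input_attention = TRUE, reduction_ratio = 16L,
                           spatial_kernel = 7L, pyramid_scales = 4L) {
  cfg <- list(in_channels = as.integer(in_channels),
              num_classes = as.integer(num_classes),
              base_channels = as.integer(base_channels),
              num_levels = as.integer(num_levels),
              cbam_positions = as.character(cbam_positions),
              input_attention = isTRUE(input_attention),
              reduction_ratio = as.integer(reduction_ratio),
              spatial_kernel = as.integer(spatial_kernel),
              pyramid_scales = as.integer(pyramid_scales))
  valid <- c(paste0("down", seq_len(cfg$num_levels)),
             paste0("up", seq_len(cfg$num_levels)))
  bad <- setdiff(cfg$cbam_positions, valid)
  if (length(bad) > 0)
    stop("unknown cbam position(s): ", paste(bad, collapse = ", "))
  if (cfg$num_classes < 2) stop("num_classes must be >= 2")
  if (cfg$pyramid_scales < 2 || cfg$pyramid_scales > cfg$num_levels + 1L)
    stop("pyramid_scales must be in [2, num_levels + 1]")
  if (cfg$spatial_kernel %% 2L == 0L) stop("spatial_kernel must be odd")
  # validate CBAM divisibility per stage now rather than at forward time
  for (pos in cfg$cbam_positions) {
    C <- stage_channels(cfg, pos)
    r <- cbam_ratio(cfg, C)
    if (C %% r != 0L)
      stop("CBAM at ", pos, ": ", C, " channels not divisible by ",
           "reduction ratio ", r, " (configuration error)")
  }
  structure(cfg, class = "tpssan_netconfig")
}

level_channels <- function(cfg) cfg$base_channels * 2L^(0:cfg$num_levels)

stage_channels <- function(cfg, pos) {
  l <- as.integer(sub("^(down|up)", "", pos))
  ch <- level_channels(cfg)
  if (startsWith(pos, "down")) ch[l + 1L] else ch[l]
}

cbam_ratio <- function(cfg, C) max(2L, min(cfg$reduction_ratio, C))

# convs per encoder stage (VNet-style: deeper stages get more)
n_stage_convs <- function(l) min(l, 2L)

#' Ablation placement variants of the attention modules
#'
#' Returns the five placement configurations studied for the attention
#' modules: 1 = CBAM on all four downsampling stages, no input attention;
#' 2 = input attention + CBAM on three downsampling stages; 3 = input
#' attention + CBAM on all four downsampling stages (the proposed CBAP-VNet);
#' 4 = input attention + CBAM on the four upsampling stages; 5 = plain VNet
#' with no attention modules.
#'
#' @param method_id Integer in 1..5.
#' @param ... Further arguments passed to [network_config()] (e.g.
#'   `base_channels`).
#' @return A `tpssan_netconfig`.
#' @export
make_variant <- function(method_id, ...) {
  if (!is.numeric(method_id) || length(method_id) != 1L ||
      !(method_id %in% 1:5))
    stop("method_id must be a single integer in 1..5")
  args <- list(...)
  if (is.null(args$num_levels)) args$num_levels <- 4L
  L <- args$num_levels
  sel <- switch(as.character(method_id),
    "1" = list(cbam = paste0("down", 1:L), input = FALSE),
    "2" = list(cbam = paste0("down", seq_len(max(1L, L - 1L))), input = TRUE),
    "3" = list(cbam = paste0("down", 1:L), input = TRUE),
    "4" = list(cbam = paste0("up", 1:L), input = TRUE),
    "5" = list(cbam = character(), input = FALSE))
  args$cbam_positions <- sel$cbam
  args$input_attention <- sel$input
  do.call(network_config, args)
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

conv_params <- function(p, prefix, k, cin, cout, norm = TRUE) {
  p[[paste0(prefix, ".w")]] <- he_init(c(k, k, k, cin, cout), k^3 * cin)
  p[[paste0(prefix, ".b")]] <- numeric(cout)
  if (norm) {
    p[[paste0(prefix, ".gamma")]] <- rep(1, cout)
    p[[paste0(prefix, ".beta")]] <- numeric(cout)
  }
  p
}

cbam_params <- function(p, prefix, C, cfg) {
  r <- cbam_ratio(cfg, C)
  h <- C %/% r
  p[[paste0(prefix, ".ca.w1")]] <- matrix(rnorm(h * C, sd = sqrt(2 / C)), h, C)
  p[[paste0(prefix, ".ca.b1")]] <- numeric(h)
  p[[paste0(prefix, ".ca.w2")]] <- matrix(rnorm(C * h, sd = sqrt(2 / h)), C, h)
  p[[paste0(prefix, ".ca.b2")]] <- numeric(C)
  k <- cfg$spatial_kernel
  p[[paste0(prefix, ".sa.w")]] <- he_init(c(k, k, k, 2, 1), k^3 * 2)
  p[[paste0(prefix, ".sa.b")]] <- numeric(1)
  p
}

#' Build a CBAP-VNet with freshly initialized parameters
#'
#' @param config A [network_config()] object.
#' @param seed Optional integer seed for the parameter initialization.
#' @return A `tpssan_network` list with elements `config` and `params`
#'   (a flat named list of numeric arrays).
#' @export
make_network <- function(config, seed = NULL) {
  stopifnot(inherits(config, "tpssan_netconfig"))
  if (!is.null(seed)) set.seed(seed)
  ch <- level_channels(config)
  L <- config$num_levels
  p <- list()
  p <- conv_params(p, "stem", 3L, config$in_channels, ch[1])
  for (l in seq_len(L)) {
    p <- conv_params(p, paste0("enc", l, ".down"), 2L, ch[l], ch[l + 1])
    for (j in seq_len(n_stage_convs(l)))
      p <- conv_params(p, paste0("enc", l, ".conv", j), 3L, ch[l + 1], ch[l + 1])
    if (paste0("down", l) %in% config$cbam_positions)
      p <- cbam_params(p, paste0("enc", l, ".cbam"), ch[l + 1], config)
  }
  for (l in rev(seq_len(L))) {
    # transposed conv halves the channel count while doubling resolution
    p[[paste0("dec", l, ".up.w")]] <- he_init(c(2, 2, 2, ch[l + 1], ch[l]),
                                              8 * ch[l + 1])
    p[[paste0("dec", l, ".up.b")]] <- numeric(ch[l])
    p[[paste0("dec", l, ".up.gamma")]] <- rep(1, ch[l])
    p[[paste0("dec", l, ".up.beta")]] <- numeric(ch[l])
    p <- conv_params(p, paste0("dec", l, ".conv1"), 3L, 2L * ch[l], ch[l])
    if (paste0("up", l) %in% config$cbam_positions)
      p <- cbam_params(p, paste0("dec", l, ".cbam"), ch[l], config)
  }
  for (s in seq_len(config$pyramid_scales)) {
    csrc <- if (s <= L) ch[s] else ch[L + 1]
    p <- conv_params(p, paste0("head", s), 1L, csrc, config$num_classes,
                     norm = FALSE)
  }
  structure(list(config = config, params = p), class = "tpssan_network")
}

#' Total number of trainable parameters
#' @param net A `tpssan_network`.
#' @return Integer count.
#' @export
network_num_params <- function(net) {
  sum(vapply(net$params, length, integer(1)))
}

wrap_params <- function(params, tape = NULL) {
  if (is.null(tape)) lapply(params, ag_const) else lapply(params, ag_param, tape = tape)
}

conv_in_act <- function(P, prefix, x, stride = 1L, pad = 1L) {
  y <- ag_conv3d(x, P[[paste0(prefix, ".w")]], P[[paste0(prefix, ".b")]],
                 stride = stride, pad = pad)
  y <- ag_instnorm(y, P[[paste0(prefix, ".gamma")]], P[[paste0(prefix, ".beta")]])
  ag_lrelu(y)
}

cbam_apply <- function(P, prefix, x, cfg) {
  # channel attention: shared MLP over average- and max-pooled descriptors
  # leaky activation in the bottleneck MLP: with very narrow hidden widths
  # (tiny test networks) a hard ReLU can permanently silence the branch
  h1 <- function(v) {
    ag_linear(ag_lrelu(ag_linear(v, P[[paste0(prefix, ".ca.w1")]],
                                 P[[paste0(prefix, ".ca.b1")]])),
              P[[paste0(prefix, ".ca.w2")]], P[[paste0(prefix, ".ca.b2")]])
  }
  gate <- ag_sigmoid(ag_add(h1(ag_gap(x)), h1(ag_gmp(x))))
  x <- ag_scale_channels(x, gate)
  # spatial attention: conv over channel-average + channel-max maps
  sm <- ag_concat_ch(ag_cmean(x), ag_cmax(x))
  k <- cfg$spatial_kernel
  sg <- ag_sigmoid(ag_conv3d(sm, P[[paste0(prefix, ".sa.w")]],
                             P[[paste0(prefix, ".sa.b")]],
                             stride = 1L, pad = (k - 1L) %/% 2L))
  ag_scale_spatial(x, sg)
}

# Adaptive channel attention: parameter-free sigmoid gate from the global
# average-pooled channel descriptor, multiplied elementwise into the input.
adaptive_channel_attention_t <- function(x) {
  ag_scale_channels(x, ag_sigmoid(ag_gap(x)))
}

#' Adaptive channel attention block
#'
#' Gates each channel by `sigmoid(global average pool)` of that channel and
#' multiplies the input elementwise, broadcasting the gate over space.
#'
#' @param x A numeric 4D array, dim (X, Y, Z, C).
#' @return Array of the same shape.
#' @export
adaptive_channel_attention <- function(x) {
  stopifnot(length(dim(x)) == 4L)
  adaptive_channel_attention_t(ag_const(x))$v
}

#' CBAM attention block applied with freshly initialized weights
#'
#' Convenience wrapper running channel attention (shared MLP over global
#' average- and max-pooled descriptors, summed, sigmoid) followed by spatial
#' attention (sigmoid of a convolution over the channel-wise average and max
#' maps). Mainly useful for inspecting the module in isolation; inside the
#' network the block's parameters are trained.
#'
#' @param x A numeric 4D array, dim (X, Y, Z, C).
#' @param config A [network_config()]; `reduction_ratio` and
#'   `spatial_kernel` are honored.
#' @param params Optional named list with elements `ca.w1, ca.b1, ca.w2,
#'   ca.b2, sa.w, sa.b`; freshly initialized when omitted.
#' @param seed Seed for the fresh initialization.
#' @return Array of the same shape as `x`.
#' @export
cbam_block <- function(x, config = network_config(base_channels = dim(x)[4],
                                                  num_levels = 2L,
                                                  pyramid_scales = 2L,
                                                  cbam_positions = character(),
                                                  input_attention = FALSE),
                       params = NULL, seed = NULL) {
  stopifnot(length(dim(x)) == 4L)
  C <- dim(x)[4]
  r <- cbam_ratio(config, C)
  if (C %% r != 0L)
    stop("cbam_block: ", C, " channels not divisible by reduction ratio ", r,
         " (configuration error)")
  if (is.null(params)) {
    if (!is.null(seed)) set.seed(seed)
    params <- cbam_params(list(), "blk", C, config)
  } else {
    names(params) <- paste0("blk.", names(params))
  }
  P <- wrap_params(params)
  cbam_apply(P, "blk", ag_const(x), config)$v
}

# Full forward pass. `P` is a named list of tensors (wrap_params); returns
# tensors so the trainer can backpropagate. With internals = TRUE the
# encoder stage outputs (pre-upsampling features) are attached.
net_forward_t <- function(P, cfg, x, internals = FALSE) {
  d <- dim(x$v)
  L <- cfg$num_levels
  div <- 2L^L
  for (ax in 1:3)
    if (d[ax] %% div != 0L)
      stop("patch axis ", c("x", "y", "z")[ax], " has extent ", d[ax],
           ", not divisible by 2^num_levels = ", div)
  f0 <- conv_in_act(P, "stem", x)
  if (cfg$input_attention) f0 <- adaptive_channel_attention_t(f0)
  enc <- vector("list", L)
  cur <- f0
  for (l in seq_len(L)) {
    cur <- conv_in_act(P, paste0("enc", l, ".down"), cur, stride = 2L, pad = 0L)
    res <- cur
    for (j in seq_len(n_stage_convs(l)))
      cur <- conv_in_act(P, paste0("enc", l, ".conv", j), cur)
    cur <- ag_add(cur, res)
    if (paste0("down", l) %in% cfg$cbam_positions)
      cur <- cbam_apply(P, paste0("enc", l, ".cbam"), cur, cfg)
    enc[[l]] <- cur
  }
  dec <- vector("list", L)
  cur <- enc[[L]]
  for (l in rev(seq_len(L))) {
    up <- ag_convt2(cur, P[[paste0("dec", l, ".up.w")]],
                    P[[paste0("dec", l, ".up.b")]])
    up <- ag_lrelu(ag_instnorm(up, P[[paste0("dec", l, ".up.gamma")]],
                               P[[paste0("dec", l, ".up.beta")]]))
    skip <- if (l == 1L) f0 else enc[[l - 1L]]
    cur <- conv_in_act(P, paste0("dec", l, ".conv1"), ag_concat_ch(up, skip))
    if (paste0("up", l) %in% cfg$cbam_positions)
      cur <- cbam_apply(P, paste0("dec", l, ".cbam"), cur, cfg)
    dec[[l]] <- cur
  }
  S <- cfg$pyramid_scales
  p_scales <- vector("list", S)
  for (s in seq_len(S)) {
    src <- if (s <= L) dec[[s]] else enc[[L]]
    logits <- ag_conv3d(src, P[[paste0("head", s, ".w")]],
                        P[[paste0("head", s, ".b")]], stride = 1L, pad = 0L)
    p_scales[[s]] <- ag_softmax_ch(ag_upsample(logits, 2L^(s - 1L)))
  }
  p_avg <- p_scales[[1]]
  for (s in 2:S) p_avg <- ag_add(p_avg, p_scales[[s]])
  p_avg <- ag_smul(p_avg, 1 / S)
  out <- list(p_scales = p_scales, p_avg = p_avg)
  if (internals) out$encoder_features <- enc
  out
}

#' Forward pass producing the prediction pyramid
#'
#' Runs the network on one input patch and returns S class-probability grids
#' (scale 1 is the full-resolution head; coarser heads are trilinearly
#' upsampled to full resolution) together with their voxelwise average.
#'
#' @param net A `tpssan_network`.
#' @param x Numeric 3D array (a patch) or 4D array with a channel axis.
#'   Each spatial extent must be divisible by `2^num_levels`.
#' @return A `tpssan_pyramid` list: `p_scales` (list of (X,Y,Z,C) arrays,
#'   each summing to 1 over the class axis) and `p_avg`.
#' @export
network_forward <- function(net, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  P <- wrap_params(net$params)
  out <- net_forward_t(P, net$config, ag_const(x))
  structure(list(p_scales = lapply(out$p_scales, function(t) t$v),
                 p_avg = out$p_avg$v),
            class = "tpssan_pyramid")
}

#' Save / load a network checkpoint
#'
#' The checkpoint is an RDS file holding student and teacher parameters plus
#' the training state; a JSON sidecar (`<path>.json`) records the network
#' configuration for inspection.
#'
#' @param state A checkpoint list (as produced by [train_semisup()] or
#'   assembled from a `tpssan_network`).
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(state, path) {
  saveRDS(state, path)
  cfg <- state$config
  jsonlite::write_json(unclass(cfg), paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  readRDS(path)
}
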