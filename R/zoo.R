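# Backbone zoo and compute-budget accountant. Architectures are declarative
# node graphs (ResNet-34, MobileNetV2, EfficientNet-B0 in their torchvision
# layouts); parameters and MACs are counted by shape propagation over the
# graph, and a small interpreter executes the graph on a (3, S, S) image.
#
# MAC convention ("standard", the default): one multiply-accumulate = one
# FLOP; convolution and linear MACs (squeeze-excitation 1x1 convolutions
# included), plus 4 ops per element for affine batch norm and one op per
# summed element (+1 per output, for the division) for average pooling;
# max pooling, activations and biases are free. This is the convention under
# which the published backbone figures at 256 x 256 are reproduced for all
# three architectures. "conv_only" counts convolution/linear MACs alone.

n_conv <- function(cin, cout, k, stride = 1L, pad = 0L, groups = 1L,
                   bias = FALSE)
  list(type = "conv", cin = cin, cout = cout, k = k, stride = stride,
       pad = pad, groups = groups, bias = bias)
n_bn <- function(c) list(type = "bn", c = c)
n_act <- function(fun) list(type = "act", fun = fun)
n_maxpool <- function(k, stride, pad = 0L)
  list(type = "maxpool", k = k, stride = stride, pad = pad)
n_gap <- function() list(type = "gap")
n_linear <- function(cin, cout) list(type = "linear", cin = cin, cout = cout)
n_seq <- function(...) list(type = "seq", nodes = list(...))
n_seql <- function(nodes) list(type = "seq", nodes = nodes)
n_res <- function(body, down = NULL, post_relu = FALSE, use_res = TRUE)
  list(type = "res", body = body, down = down, post_relu = post_relu,
       use_res = use_res)
n_se <- function(c, sq) list(type = "se", c = c, sq = sq)
n_attn <- function(kind, channels)
  list(type = "attn", kind = kind, cfg = diea_config(channels))

basic_block <- function(cin, cout, stride) {
  body <- n_seq(n_conv(cin, cout, 3L, stride, 1L), n_bn(cout), n_act("relu"),
                n_conv(cout, cout, 3L, 1L, 1L), n_bn(cout))
  down <- if (stride != 1L || cin != cout)
    n_seq(n_conv(cin, cout, 1L, stride, 0L), n_bn(cout))
  n_res(body, down, post_relu = TRUE)
}

inverted_residual <- function(cin, cout, stride, expand, k = 3L,
                              act = "relu6", se_ratio = 0) {
  hidden <- cin * expand
  nodes <- list()
  if (expand != 1L)
    nodes <- c(nodes, list(n_conv(cin, hidden, 1L), n_bn(hidden), n_act(act)))
  nodes <- c(nodes, list(
    n_conv(hidden, hidden, k, stride, k %/% 2L, groups = hidden),
    n_bn(hidden), n_act(act)))
  if (se_ratio > 0)
    nodes <- c(nodes, list(n_se(hidden, max(1L, as.integer(cin * se_ratio)))))
  nodes <- c(nodes, list(n_conv(hidden, cout, 1L), n_bn(cout)))
  n_res(n_seql(nodes), NULL, post_relu = FALSE,
        use_res = stride == 1L && cin == cout)
}

make_stage <- function(cin, cout, n, stride, block_fn) {
  blocks <- vector("list", n)
  for (i in seq_len(n))
    blocks[[i]] <- block_fn(if (i == 1L) cin else cout, cout,
                            if (i == 1L) stride else 1L)
  blocks
}

arch_parts <- function(architecture, num_classes) {
  switch(architecture,
    resnet34 = {
      cfgs <- list(c(64L, 3L, 1L), c(128L, 4L, 2L), c(256L, 6L, 2L),
                   c(512L, 3L, 2L))
      cin <- 64L
      stages <- lapply(cfgs, function(s) {
        st <- make_stage(cin, s[1L], s[2L], s[3L], basic_block)
        cin <<- s[1L]
        st
      })
      list(stem = list(n_conv(3L, 64L, 7L, 2L, 3L), n_bn(64L), n_act("relu"),
                       n_maxpool(3L, 2L, 1L)),
           stages = stages, stage_channels = c(64L, 128L, 256L, 512L),
           head = list(), feat_dim = 512L,
           classifier = list(n_gap(), n_linear(512L, num_classes)))
    },
    mobilenet_v2 = {
      tcns <- list(c(1L, 16L, 1L, 1L), c(6L, 24L, 2L, 2L), c(6L, 32L, 3L, 2L),
                   c(6L, 64L, 4L, 2L), c(6L, 96L, 3L, 1L), c(6L, 160L, 3L, 2L),
                   c(6L, 320L, 1L, 1L))
      cin <- 32L
      stages <- lapply(tcns, function(s) {
        st <- make_stage(cin, s[2L], s[3L], s[4L], function(ci, co, str)
          inverted_residual(ci, co, str, s[1L]))
        cin <<- s[2L]
        st
      })
      list(stem = list(n_conv(3L, 32L, 3L, 2L, 1L), n_bn(32L), n_act("relu6")),
           stages = stages,
           stage_channels = vapply(tcns, `[`, integer(1), 2L),
           head = list(n_conv(320L, 1280L, 1L), n_bn(1280L), n_act("relu6")),
           feat_dim = 1280L,
           classifier = list(n_gap(), n_linear(1280L, num_classes)))
    },
    efficientnet_b0 = {
      # (expand, cout, repeats, stride, kernel)
      tcns <- list(c(1L, 16L, 1L, 1L, 3L), c(6L, 24L, 2L, 2L, 3L),
                   c(6L, 40L, 2L, 2L, 5L), c(6L, 80L, 3L, 2L, 3L),
                   c(6L, 112L, 3L, 1L, 5L), c(6L, 192L, 4L, 2L, 5L),
                   c(6L, 320L, 1L, 1L, 3L))
      cin <- 32L
      stages <- lapply(tcns, function(s) {
        st <- make_stage(cin, s[2L], s[3L], s[4L], function(ci, co, str)
          inverted_residual(ci, co, str, s[1L], k = s[5L], act = "swish",
                            se_ratio = 0.25))
        cin <<- s[2L]
        st
      })
      list(stem = list(n_conv(3L, 32L, 3L, 2L, 1L), n_bn(32L), n_act("swish")),
           stages = stages,
           stage_channels = vapply(tcns, `[`, integer(1), 2L),
           head = list(n_conv(320L, 1280L, 1L), n_bn(1280L), n_act("swish")),
           feat_dim = 1280L,
           classifier = list(n_gap(), n_linear(1280L, num_classes)))
    },
    stop("unknown architecture: ", architecture)
  )
}

#' Backbone specification
#'
#' @param architecture one of `"resnet34"`, `"mobilenet_v2"`,
#'   `"efficientnet_b0"`.
#' @param num_classes size of the classification head (default 3 grades).
#' @export
backbone_spec <- function(architecture = c("resnet34", "mobilenet_v2",
                                           "efficientnet_b0"),
                          num_classes = 3L) {
  architecture <- match.arg(architecture)
  if (num_classes < 2L) stop("num_classes must be at least 2")
  structure(list(architecture = architecture,
                 num_classes = as.integer(num_classes)),
            class = "backbone_spec")
}

#' Attention injection policy
#'
#' @param module_kind `"none"`, `"diea"` or `"ca"`.
#' @param placement `"final_stage"` (one attention block after the last
#'   feature stage, the default budget-neutral choice), `"every_stage"`, or
#'   `"per_block"`.
#' @export
injection_policy <- function(module_kind = c("none", "diea", "ca"),
                             placement = c("final_stage", "every_stage",
                                           "per_block")) {
  structure(list(module_kind = match.arg(module_kind),
                 placement = match.arg(placement)),
            class = "injection_policy")
}

#' Build a classifier model from a backbone spec and injection policy
#'
#' Assembles the architecture graph, weaves attention blocks in at the
#' placement sites and initialises all weights (Kaiming-uniform
#' convolutions, unit-gamma BN).
#'
#' @param spec a [backbone_spec()].
#' @param policy an [injection_policy()].
#' @param seed integer seed for weight initialisation.
#' @return an object of class `zoo_model`.
#' @export
build_model <- function(spec, policy = injection_policy(), seed = 1L) {
  parts <- arch_parts(spec$architecture, spec$num_classes)
  kind <- policy$module_kind
  stages <- parts$stages
  if (kind != "none") {
    ns <- length(stages)
    for (i in seq_len(ns)) {
      ch <- parts$stage_channels[i]
      if (policy$placement == "per_block") {
        stages[[i]] <- unlist(lapply(stages[[i]], function(b)
          list(b, n_attn(kind, ch))), recursive = FALSE)
      } else if (policy$placement == "every_stage" ||
                 (policy$placement == "final_stage" && i == ns)) {
        stages[[i]] <- c(stages[[i]], list(n_attn(kind, ch)))
      }
    }
  }
  graph <- n_seql(c(parts$stem, unlist(stages, recursive = FALSE),
                    parts$head, parts$classifier))
  set.seed(seed)
  graph <- init_node(graph)
  structure(list(graph = graph, spec = spec, policy = policy,
                 feat_dim = parts$feat_dim, seed = seed),
            class = "zoo_model")
}

init_node <- function(node) {
  switch(node$type,
    conv = {
      fan_in <- (node$cin %/% node$groups) * node$k^2
      node$w <- kaiming_uniform(c(node$cout, node$cin %/% node$groups,
                                  node$k, node$k), fan_in)
      if (node$bias) node$b <- rep(0, node$cout)
      node
    },
    bn = { node$state <- bn_init(node$c); node },
    linear = {
      node$w <- kaiming_uniform(c(node$cout, node$cin), node$cin)
      node$b <- rep(0, node$cout)
      node
    },
    se = {
      node$w1 <- kaiming_uniform(c(node$sq, node$c), node$c)
      node$b1 <- rep(0, node$sq)
      node$w2 <- kaiming_uniform(c(node$c, node$sq), node$sq)
      node$b2 <- rep(0, node$c)
      node
    },
    attn = {
      node$weights <- if (node$kind == "diea") diea_init(node$cfg)
                      else ca_init(node$cfg)
      node
    },
    seq = { node$nodes <- lapply(node$nodes, init_node); node },
    res = {
      node$body <- init_node(node$body)
      if (!is.null(node$down)) node$down <- init_node(node$down)
      node
    },
    node
  )
}

act_fun <- function(fun) switch(fun,
  relu = function(x) pmax(x, 0),
  relu6 = function(x) pmin(pmax(x, 0), 6),
  swish = function(x) x * sigmoid_(x),
  hswish = h_swish,
  stop("unknown activation ", fun))

eval_node <- function(node, x) {
  switch(node$type,
    conv = conv2d(x, node$w, node$b, node$stride, node$pad, node$groups),
    bn = {
      s <- node$state
      (x - s$running_mean) / sqrt(s$running_var + 1e-5) * s$gamma + s$beta
    },
    act = act_fun(node$fun)(x),
    maxpool = {
      if (node$pad > 0L) {
        d <- dim(x)
        xp <- array(-Inf, c(d[1L], d[2L] + 2L * node$pad,
                            d[3L] + 2L * node$pad))
        xp[, (node$pad + 1L):(node$pad + d[2L]),
           (node$pad + 1L):(node$pad + d[3L])] <- x
        x <- xp
      }
      maxpool2d(x, node$k, node$stride)$y
    },
    gap = rowMeans(matrix(x, dim(x)[1L])),
    linear = drop(node$w %*% x + node$b),
    se = {
      s <- rowMeans(matrix(x, dim(x)[1L]))
      v <- sigmoid_(drop(node$w2 %*% (
        {u <- drop(node$w1 %*% s + node$b1); u * sigmoid_(u)}) + node$b2))
      x * v
    },
    attn = if (node$kind == "diea") diea_forward(x, node$cfg, node$weights)
           else ca_forward(x, node$cfg, node$weights),
    seq = { for (nd in node$nodes) x <- eval_node(nd, x); x },
    res = {
      skip <- if (!is.null(node$down)) eval_node(node$down, x)
              else if (node$use_res) x else NULL
      out <- eval_node(node$body, x)
      if (!is.null(skip)) out <- out + skip
      if (node$post_relu) out <- pmax(out, 0)
      out
    },
    stop("unsupported node type: ", node$type)
  )
}

#' Run a zoo model forward on one image
#'
#' @param model a `zoo_model` from [build_model()].
#' @param x numeric `(3, S, S)` array (values on any scale).
#' @return numeric vector of `num_classes` logits.
#' @export
zoo_forward <- function(model, x) {
  assert_feature_map(x)
  eval_node(model$graph, x)
}

count_node <- function(node, shape, acc) {
  switch(node$type,
    conv = {
      Ho <- conv_out_len(shape[2L], node$k, node$stride, node$pad)
      Wo <- conv_out_len(shape[3L], node$k, node$stride, node$pad)
      p <- node$cout * (node$cin %/% node$groups) * node$k^2 +
        if (node$bias) node$cout else 0L
      acc$params <- acc$params + p
      acc$macs <- acc$macs +
        as.numeric(node$cout) * (node$cin %/% node$groups) * node$k^2 * Ho * Wo
      acc$shape <- c(node$cout, Ho, Wo)
      acc
    },
    bn = {
      acc$params <- acc$params + 2L * node$c
      if (acc$elementwise) acc$macs <- acc$macs + 4 * prod(as.numeric(shape))
      acc
    },
    act = acc,
    maxpool = {
      acc$shape <- c(shape[1L],
                     conv_out_len(shape[2L], node$k, node$stride, node$pad),
                     conv_out_len(shape[3L], node$k, node$stride, node$pad))
      acc
    },
    gap = {
      if (acc$elementwise)
        acc$macs <- acc$macs + prod(as.numeric(shape)) + shape[1L]
      acc$shape <- c(shape[1L], 1L, 1L)
      acc
    },
    linear = {
      acc$params <- acc$params + node$cout * node$cin + node$cout
      acc$macs <- acc$macs + as.numeric(node$cout) * node$cin
      acc$shape <- c(node$cout, 1L, 1L)
      acc
    },
    se = {
      acc$params <- acc$params + node$sq * node$c + node$sq +
        node$c * node$sq + node$c
      acc$macs <- acc$macs + 2 * as.numeric(node$sq) * node$c
      if (acc$elementwise)
        acc$macs <- acc$macs + prod(as.numeric(shape)) + shape[1L]
      acc
    },
    attn = {
      acc$params <- acc$params +
        if (node$kind == "diea") diea_param_count(node$cfg)
        else ca_param_count(node$cfg)
      acc$macs <- acc$macs +
        if (node$kind == "diea") diea_mac_count(node$cfg, shape[2L], shape[3L])
        else ca_mac_count(node$cfg, shape[2L], shape[3L])
      acc
    },
    seq = {
      for (nd in node$nodes) { acc <- count_node(nd, acc$shape, acc) }
      acc
    },
    res = {
      inner <- count_node(node$body, shape,
                          list(params = 0, macs = 0, shape = shape,
                               elementwise = acc$elementwise))
      acc$params <- acc$params + inner$params
      acc$macs <- acc$macs + inner$macs
      if (!is.null(node$down)) {
        dn <- count_node(node$down, shape,
                         list(params = 0, macs = 0, shape = shape,
                              elementwise = acc$elementwise))
        acc$params <- acc$params + dn$params
        acc$macs <- acc$macs + dn$macs
      }
      acc$shape <- inner$shape
      acc
    },
    stop("unsupported node type: ", node$type)
  )
}

#' Count trainable parameters of a model (in millions)
#'
#' @param model a `zoo_model` (or a tiny training-framework model).
#' @return parameter count / 1e6.
#' @export
count_params <- function(model) UseMethod("count_params")

#' @export
count_params.zoo_model <- function(model) {
  acc <- count_node(model$graph, c(3L, 256L, 256L),
                    list(params = 0, macs = 0, shape = c(3L, 256L, 256L),
                         elementwise = FALSE))
  acc$params / 1e6
}

#' Count multiply-accumulate operations of a forward pass (in G)
#'
#' One MAC = one FLOP throughout. The default `"standard"` convention counts
#' convolution and linear MACs plus four ops per element for affine batch
#' norm and the summation/division ops of average pooling; max pooling,
#' activations and biases are free. This is the convention under which the
#' published backbone figures at 256 x 256 are reproduced for all three
#' architectures. `"conv_only"` restricts the count to convolution and
#' linear layers.
#'
#' @param model a `zoo_model`.
#' @param input_size spatial input size (default 256).
#' @param convention `"standard"` or `"conv_only"`.
#' @return MACs / 1e9.
#' @export
count_macs <- function(model, input_size = 256L,
                       convention = c("standard", "conv_only"))
  UseMethod("count_macs")

#' @export
count_macs.zoo_model <- function(model, input_size = 256L,
                                 convention = c("standard", "conv_only")) {
  convention <- match.arg(convention)
  shape <- c(3L, as.integer(input_size), as.integer(input_size))
  acc <- count_node(model$graph, shape,
                    list(params = 0, macs = 0, shape = shape,
                         elementwise = convention == "standard"))
  acc$macs / 1e9
}

#' Parameter/MACs budget report
#'
#' @param architecture backbone name.
#' @param attention `"none"`, `"diea"` or `"ca"`.
#' @param placement attention placement (see [injection_policy()]).
#' @param input_size spatial size used for the MACs figure.
#' @param num_classes classifier width.
#' @return list with `params_millions`, `macs_giga`, `input_size`.
#' @export
budget_report <- function(architecture, attention = "none",
                          placement = "final_stage", input_size = 256L,
                          num_classes = 3L) {
  m <- build_model(backbone_spec(architecture, num_classes),
                   injection_policy(attention, placement))
  list(params_millions = count_params(m),
       macs_giga = count_macs(m, input_size),
       input_size = c(as.integer(input_size), as.integer(input_size)))
}
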