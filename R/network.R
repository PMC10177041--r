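# Compact convolutional network engine. Tensors are R arrays (H, W, C, N);
# convolutions run through RcppArmadillo im2col + GEMM kernels with
# hand-derived backward passes. Two architecture families are provided:
# an encoder-decoder with skip connections (u-net) and a densely connected
# network adapted to dense prediction (dense-net).

new_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g
}

add_node <- function(g, node) {
  g$nodes[[length(g$nodes) + 1L]] <- node
  length(g$nodes)
}

g_input <- function(g) add_node(g, list(type = "input"))
g_conv <- function(g, input, k, cin, cout, relu = TRUE) {
  add_node(g, list(type = "conv", input = input, k = k,
                   cin = cin, cout = cout, relu = relu))
}
g_pool <- function(g, input) add_node(g, list(type = "pool", input = input))
g_up <- function(g, input, mode = "nearest") {
  add_node(g, list(type = "up", input = input, mode = mode))
}
g_concat <- function(g, a, b, ca, cb) {
  add_node(g, list(type = "concat", a = a, b = b, ca = ca, cb = cb))
}
g_bnrelu <- function(g, input, c) {
  add_node(g, list(type = "bnrelu", input = input, c = c))
}

init_params <- function(nodes) {
  params <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    if (nd$type == "conv") {
      fan_in <- nd$k * nd$k * nd$cin
      params[[i]] <- list(
        W = matrix(rnorm(fan_in * nd$cout, 0, sqrt(2 / fan_in)),
                   fan_in, nd$cout),
        b = rep(0, nd$cout)
      )
    } else if (nd$type == "bnrelu") {
      # batchnorm scale/shift stored as W/b so the optimizer treats them
      # like any other parameter pair
      params[[i]] <- list(W = rep(1, nd$c), b = rep(0, nd$c))
    }
  }
  params
}

init_bn_stats <- function(nodes) {
  stats <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    if (nodes[[i]]$type == "bnrelu") {
      stats[[i]] <- list(mean = rep(0, nodes[[i]]$c),
                         var = rep(1, nodes[[i]]$c))
    }
  }
  stats
}

# batchnorm + ReLU over the channel dimension of (H,W,C,N); training mode
# uses batch statistics (C++ kernels), inference the running statistics.
bn_eps <- 1e-5
bn_momentum <- 0.9

# 1D bilinear 2x upsampling operator (half-pixel centers), as a dense matrix
upmat <- function(n) {
  U <- matrix(0, 2 * n, n)
  for (d in seq_len(2 * n)) {
    s <- (d - 0.5) / 2 - 0.5
    s <- min(max(s, 0), n - 1)
    i0 <- floor(s)
    f <- s - i0
    i1 <- min(i0 + 1, n - 1)
    U[d, i0 + 1] <- U[d, i0 + 1] + (1 - f)
    U[d, i1 + 1] <- U[d, i1 + 1] + f
  }
  U
}

up_nearest_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

up_nearest_bwd <- function(dy) {
  d <- dim(dy)
  o1 <- seq(1, d[1], 2)
  o2 <- seq(2, d[1], 2)
  p1 <- seq(1, d[2], 2)
  p2 <- seq(2, d[2], 2)
  dy[o1, p1, , , drop = FALSE] + dy[o1, p2, , , drop = FALSE] +
    dy[o2, p1, , , drop = FALSE] + dy[o2, p2, , , drop = FALSE]
}

up_bilinear_fwd <- function(x) {
  d <- dim(x)
  Uh <- upmat(d[1])
  Uw <- upmat(d[2])
  out <- array(0, c(2 * d[1], 2 * d[2], d[3], d[4]))
  for (n in seq_len(d[4])) {
    for (c in seq_len(d[3])) {
      out[, , c, n] <- Uh %*% x[, , c, n] %*% t(Uw)
    }
  }
  out
}

up_bilinear_bwd <- function(dy) {
  d <- dim(dy)
  Uh <- upmat(d[1] / 2)
  Uw <- upmat(d[2] / 2)
  out <- array(0, c(d[1] / 2, d[2] / 2, d[3], d[4]))
  for (n in seq_len(d[4])) {
    for (c in seq_len(d[3])) {
      out[, , c, n] <- t(Uh) %*% dy[, , c, n] %*% Uw
    }
  }
  out
}

# keep = TRUE retains per-conv im2col matrices (and pool argmaxes) so
# backward_graph can run without recomputing them; use keep = FALSE for
# inference to save memory.
forward_graph <- function(model, x, keep = TRUE) {
  nodes <- model$nodes
  acts <- vector("list", length(nodes))
  aux <- vector("list", length(nodes))
  bn_stats <- model$bn_stats
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    acts[[i]] <- switch(nd$type,
      input = x,
      conv = {
        r <- cpp_conv_fwd(acts[[nd$input]], model$params[[i]]$W,
                          model$params[[i]]$b, nd$k, nd$relu, keep)
        if (keep) aux[[i]] <- r$M
        r$y
      },
      bnrelu = {
        if (keep) {
          r <- cpp_bn_fwd(acts[[nd$input]], model$params[[i]]$W,
                          model$params[[i]]$b, bn_eps)
          aux[[i]] <- list(mu = r$mu, var = r$var)
          m <- bn_momentum
          bn_stats[[i]] <- list(
            mean = m * bn_stats[[i]]$mean + (1 - m) * r$mu,
            var = m * bn_stats[[i]]$var + (1 - m) * r$var)
          r$y
        } else {
          cpp_bn_infer(acts[[nd$input]], model$params[[i]]$W,
                       model$params[[i]]$b, bn_stats[[i]]$mean,
                       bn_stats[[i]]$var, bn_eps)
        }
      },
      pool = {
        r <- cpp_pool_fwd(acts[[nd$input]])
        aux[[i]] <- r$idx
        r$y
      },
      up = if (nd$mode == "nearest") up_nearest_fwd(acts[[nd$input]])
           else up_bilinear_fwd(acts[[nd$input]]),
      concat = {
        a <- acts[[nd$a]]
        b <- acts[[nd$b]]
        da <- dim(a)
        out <- array(0, c(da[1], da[2], nd$ca + nd$cb, da[4]))
        out[, , seq_len(nd$ca), ] <- a
        out[, , nd$ca + seq_len(nd$cb), ] <- b
        out
      },
      stop("unknown node type ", nd$type)
    )
  }
  list(acts = acts, aux = aux, bn_stats = bn_stats)
}

backward_graph <- function(model, fwd, dlast) {
  nodes <- model$nodes
  acts <- fwd$acts
  dacts <- vector("list", length(nodes))
  grads <- vector("list", length(nodes))
  dacts[[length(nodes)]] <- dlast
  acc <- function(i, v) {
    if (is.null(dacts[[i]])) dacts[[i]] <<- v
    else dacts[[i]] <<- dacts[[i]] + v
  }
  for (i in rev(seq_along(nodes))) {
    nd <- nodes[[i]]
    if (nd$type == "input" || is.null(dacts[[i]])) next
    if (nd$type == "conv") {
      g <- cpp_conv_bwd(fwd$aux[[i]], acts[[i]], dacts[[i]],
                        model$params[[i]]$W, nd$k, nd$relu, nd$cin)
      grads[[i]] <- list(W = g$dW, b = g$db)
      acc(nd$input, g$dx)
    } else if (nd$type == "bnrelu") {
      g <- cpp_bn_bwd(acts[[nd$input]], acts[[i]], dacts[[i]],
                      model$params[[i]]$W, fwd$aux[[i]]$mu,
                      fwd$aux[[i]]$var, bn_eps)
      grads[[i]] <- list(W = g$dW, b = g$db)
      acc(nd$input, g$dx)
    } else if (nd$type == "pool") {
      din <- dim(acts[[nd$input]])
      acc(nd$input, cpp_pool_bwd(dacts[[i]], fwd$aux[[i]], din[1], din[2]))
    } else if (nd$type == "up") {
      acc(nd$input, if (nd$mode == "nearest") up_nearest_bwd(dacts[[i]])
                    else up_bilinear_bwd(dacts[[i]]))
    } else if (nd$type == "concat") {
      dy <- dacts[[i]]
      acc(nd$a, dy[, , seq_len(nd$ca), , drop = FALSE])
      acc(nd$b, dy[, , nd$ca + seq_len(nd$cb), , drop = FALSE])
    }
    dacts[i] <- list(NULL)  # free memory without shifting list indices
  }
  grads
}

#' Network specification
#'
#' @param family `"unet"` (encoder-decoder with skip connections,
#'   same-padding) or `"densenet"` (densely connected blocks adapted to
#'   dense prediction with a 1x1 classifier head; deeper presets downsample
#'   and restore resolution with bilinear upsampling).
#' @param input_shape length-2 patch shape the network trains on.
#' @param n_classes number of output classes (default 15).
#' @param preset `"reference"` (published-scale capacity: u-net 4 down/4 up with 64
#'   base filters; dense-net 4 blocks of growth 16) or `"tiny"` (2 levels /
#'   1 block, 8 filters, for desk-scale runs).
#' @return list of class `network_spec`.
#' @export
network_spec <- function(family = c("unet", "densenet"),
                         input_shape = c(128, 128), n_classes = 15,
                         preset = c("tiny", "reference")) {
  family <- match.arg(family)
  preset <- match.arg(preset)
  input_shape <- as.integer(input_shape)
  stopifnot(length(input_shape) == 2, all(input_shape > 0), n_classes >= 2)
  structure(list(family = family, input_shape = input_shape,
                 n_classes = as.integer(n_classes), preset = preset),
            class = "network_spec")
}

# 3x3 conv + batchnorm + ReLU block; normalization keeps the deep serial
# encoder-decoder path trainable at the small configured learning rate
conv_bn <- function(g, input, cin, cout) {
  c <- g_conv(g, input, 3L, cin, cout, relu = FALSE)
  g_bnrelu(g, c, cout)
}

build_unet <- function(g, input, levels, base, n_classes, dec_convs = 2L) {
  filters <- base * 2^(seq_len(levels) - 1)
  skips <- integer(0)
  cur <- input
  cin <- 3L
  for (l in seq_len(levels)) {
    cur <- conv_bn(g, cur, cin, filters[l])
    cur <- conv_bn(g, cur, filters[l], filters[l])
    cin <- filters[l]
    if (l < levels) {
      skips <- c(skips, cur)
      cur <- g_pool(g, cur)
    }
  }
  for (l in rev(seq_len(levels - 1))) {
    cur <- g_up(g, cur, "nearest")
    cur <- g_concat(g, skips[l], cur, filters[l], cin)
    cin <- filters[l] + cin
    # decoder width never drops below the class count, so the 1x1 head is
    # not starved of features
    width <- max(filters[l], n_classes + 1L)
    cur <- conv_bn(g, cur, cin, width)
    if (dec_convs > 1L) cur <- conv_bn(g, cur, width, width)
    cin <- width
  }
  g_conv(g, cur, 1L, cin, n_classes, relu = FALSE)
}

build_densenet <- function(g, input, blocks, layers_per_block, growth,
                           n_classes) {
  cur <- input
  cin <- 3L
  n_pool <- 0L
  for (b in seq_len(blocks)) {
    for (l in seq_len(layers_per_block)) {
      new <- g_conv(g, cur, 3L, cin, growth)
      cur <- g_concat(g, cur, new, cin, growth)
      cin <- cin + growth
    }
    if (b < blocks) {
      # transition: 1x1 compression + downsampling
      comp <- max(growth, as.integer(floor(cin / 2)))
      cur <- g_conv(g, cur, 1L, cin, comp)
      cin <- comp
      cur <- g_pool(g, cur)
      n_pool <- n_pool + 1L
    }
  }
  cur <- g_conv(g, cur, 1L, cin, n_classes, relu = FALSE)
  for (i in seq_len(n_pool)) cur <- g_up(g, cur, "bilinear")
  cur
}

#' Build a trainable segmentation network
#'
#' Both families map an H x W x 3 patch to per-pixel class logits of the
#' same spatial shape; probabilities come from a final per-pixel softmax
#' (see [predict.segnet()]). Weights are He-initialized from R's RNG stream.
#'
#' @param spec a [network_spec()].
#' @return a list of class `segnet` (nodes, params, pad multiple, spec).
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  g <- new_graph()
  input <- g_input(g)
  if (spec$family == "unet") {
    levels <- if (spec$preset == "tiny") 2L else 5L
    base <- if (spec$preset == "tiny") 12L else 64L
    # tiny preset trades the second decoder conv for throughput: full-res
    # decoder convolutions dominate its cost
    build_unet(g, input, levels, base, spec$n_classes,
               dec_convs = if (spec$preset == "tiny") 1L else 2L)
    pad_mult <- 2L^(levels - 1L)
  } else {
    if (spec$preset == "tiny") {
      build_densenet(g, input, blocks = 2L, layers_per_block = 2L,
                     growth = 8L, n_classes = spec$n_classes)
      pad_mult <- 2L
    } else {
      build_densenet(g, input, blocks = 4L, layers_per_block = 4L,
                     growth = 16L, n_classes = spec$n_classes)
      pad_mult <- 8L
    }
  }
  model <- list(spec = spec, nodes = g$nodes, params = NULL,
                bn_stats = init_bn_stats(g$nodes), pad_mult = pad_mult)
  model$params <- init_params(g$nodes)
  class(model) <- "segnet"
  model
}

#' @export
print.segnet <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) {
    if (is.null(p)) 0L else length(p$W) + length(p$b)
  }, 0L))
  cat("segnet:", x$spec$family, "(", x$spec$preset, "preset ),",
      length(x$nodes), "nodes,", np, "parameters\n")
  invisible(x)
}

# network input normalization: 0..255 RGB -> zero-centered, roughly unit
# scale (uncentered inputs noticeably slow early convergence of ReLU nets)
normalize_pixels <- function(pixels) {
  x <- pixels
  if (max(x) > 1.5) x <- x / 255
  (x - 0.5) * 2
}

# softmax over the class dimension (3rd) of (H,W,K[,N])
softmax_probs <- function(logits) {
  d <- dim(logits)
  if (length(d) == 3) {
    dim(logits) <- c(d, 1L)
    d <- dim(logits)
  }
  K <- d[3]
  X <- matrix(aperm(logits, c(1, 2, 4, 3)), ncol = K)
  X <- X - X[cbind(seq_len(nrow(X)), max.col(X, ties.method = "first"))]
  E <- exp(X)
  P <- E / rowSums(E)
  aperm(array(P, c(d[1], d[2], d[4], K)), c(1, 2, 4, 3))
}

net_logits <- function(model, x4d) {
  fwd <- forward_graph(model, x4d, keep = FALSE)
  fwd$acts[[length(model$nodes)]]
}

#' Per-pixel class probabilities for an image or patch
#'
#' The input is normalized to 0..1, mirror-padded to the network's
#' resolution multiple if needed, passed through the network, cropped back,
#' and mapped through the final softmax; each pixel's probability vector
#' sums to 1.
#'
#' @param object a `segnet`.
#' @param pixels H x W x 3 array (0..255 or 0..1).
#' @param ... unused.
#' @return H x W x n_classes probability array.
#' @export
predict.segnet <- function(object, pixels, ...) {
  x <- normalize_pixels(pixels)
  d <- dim(x)
  m <- object$pad_mult
  H2 <- as.integer(ceiling(d[1] / m) * m)
  W2 <- as.integer(ceiling(d[2] / m) * m)
  if (H2 != d[1] || W2 != d[2]) x <- crop_mirror(x, 1L, 1L, H2, W2)
  x4 <- array(x, c(H2, W2, 3, 1))
  logits <- net_logits(object, x4)
  probs <- softmax_probs(logits)[, , , 1]
  probs[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]
}
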