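# Minimal CPU conv-net engine. Tensors are (H, W, C) double arrays; the
# convolution runs through the im2col kernels in src/convnet.cpp with
# hand-derived backward passes. Parameter containers are plain nested
# lists of numeric leaves so the Adam update can walk them generically.

# weight array (kh, kw, cin, cout) -> im2col matrix layout
# (row index = c*kh*kw + a*kw + b, b fastest)
weight_to_mat <- function(W) {
  d <- dim(W)
  matrix(aperm(W, c(2, 1, 3, 4)), d[1] * d[2] * d[3], d[4])
}

mat_to_weight <- function(Wm, kh, kw, cin, cout) {
  aperm(array(Wm, c(kw, kh, cin, cout)), c(2, 1, 3, 4))
}

nn_conv_init <- function(cin, cout, k = 3, stride = 1, dilation = 1,
                         gain = 2) {
  fan_in <- k * k * cin
  list(W = matrix(rnorm(fan_in * cout, 0, sqrt(gain / fan_in)), fan_in, cout),
       b = numeric(cout),
       kh = k, kw = k, cin = cin, cout = cout,
       stride = as.integer(stride), dilation = as.integer(dilation))
}

conv_pad <- function(p) as.integer(p$dilation * (p$kh - 1) / 2)

conv_fwd <- function(p, x) {
  y <- cpp_conv_fwd(x, p$W, p$b, p$kh, p$kw, p$stride, p$dilation,
                    conv_pad(p))
  list(y = y, x = x)
}

conv_bwd <- function(p, cache, dy) {
  g <- cpp_conv_bwd(cache$x, p$W, dy, p$kh, p$kw, p$stride, p$dilation,
                    conv_pad(p))
  list(dx = g$dx, grads = list(W = g$dW, b = as.numeric(g$db)))
}

nn_selfonn_init <- function(cin, cout, k = 3, q = 3, stride = 1,
                            dilation = 1, squash = "tanh") {
  fan_in <- k * k * cin
  Ws <- lapply(seq_len(q), function(i)
    matrix(rnorm(fan_in * cout, 0, sqrt(2 / (fan_in * q))), fan_in, cout))
  names(Ws) <- paste0("W", seq_len(q))
  c(Ws, list(b = numeric(cout), kh = k, kw = k, cin = cin, cout = cout,
             q = as.integer(q), stride = as.integer(stride),
             dilation = as.integer(dilation), squash = squash))
}

selfonn_fwd <- function(p, x) {
  # tanh squash bounds the power series; at Q = 1 the series is linear and
  # the layer must reduce exactly to a plain convolution, so no squash.
  z <- if (p$q > 1 && identical(p$squash, "tanh")) tanh(x) else x
  pad <- conv_pad(p)
  zq <- z
  y <- cpp_conv_fwd(zq, p$W1, p$b, p$kh, p$kw, p$stride, p$dilation, pad)
  if (p$q > 1) {
    for (qi in 2:p$q) {
      zq <- zq * z
      y <- y + cpp_conv_fwd(zq, p[[paste0("W", qi)]], numeric(p$cout),
                            p$kh, p$kw, p$stride, p$dilation, pad)
    }
  }
  list(y = y, x = x, z = z)
}

selfonn_bwd <- function(p, cache, dy) {
  z <- cache$z
  pad <- conv_pad(p)
  dz <- array(0, dim(z))
  grads <- list()
  zq <- z
  for (qi in seq_len(p$q)) {
    if (qi > 1) zq <- zq * z
    g <- cpp_conv_bwd(zq, p[[paste0("W", qi)]], dy, p$kh, p$kw, p$stride,
                      p$dilation, pad)
    grads[[paste0("W", qi)]] <- g$dW
    if (qi == 1) grads$b <- as.numeric(g$db)
    # d(z^q)/dz = q * z^(q-1)
    dz <- dz + g$dx * (qi * zpow(z, qi - 1))
  }
  dx <- if (p$q > 1 && identical(p$squash, "tanh")) dz * (1 - z^2) else dz
  list(dx = dx, grads = grads)
}

zpow <- function(z, k) if (k == 0) 1 else z^k

#' Self-organized operational (Self-ONN) layer map
#'
#' The generative-neuron generalization of convolution: a learned
#' Taylor-series in element-wise powers of the input,
#' `y = sum_{q=1..Q} conv(x^q, W_q) + bias`. With `q_order = 1` the
#' operator reduces exactly to a standard convolution. An optional `tanh`
#' input squash (used by the network layers when Q > 1) bounds the power
#' series; the bare functional form here defaults to no squash.
#'
#' @param x input feature map, (H, W, Cin) array (a matrix is treated as a
#'   single-channel map).
#' @param weights list of `q_order` kernel arrays, each (kh, kw, Cin,
#'   Cout), all identically shaped.
#' @param q_order Taylor order Q >= 1; defaults to `length(weights)`.
#' @param bias length-Cout bias (default zeros).
#' @param squash `"none"` (default) or `"tanh"` input squashing, applied
#'   before the powers when Q > 1.
#' @param stride,dilation convolution geometry; `same` zero padding keeps
#'   the spatial size at stride 1.
#' @return (H', W', Cout) array.
#' @export
selfonn_map <- function(x, weights, q_order = length(weights), bias = NULL,
                        squash = c("none", "tanh"), stride = 1,
                        dilation = 1) {
  squash <- match.arg(squash)
  if (q_order < 1) stop("q_order must be >= 1")
  if (length(weights) < q_order)
    stop("need ", q_order, " kernel arrays, got ", length(weights))
  if (is.matrix(x)) x <- array(x, c(dim(x), 1))
  d1 <- dim(weights[[1]])
  if (length(d1) != 4) stop("each kernel must be a (kh, kw, Cin, Cout) array")
  for (w in weights[seq_len(q_order)])
    if (!identical(dim(w), d1)) stop("kernel shapes differ across orders")
  if (is.null(bias)) bias <- numeric(d1[4])
  p <- list(kh = d1[1], kw = d1[2], cin = d1[3], cout = d1[4],
            q = as.integer(q_order), stride = as.integer(stride),
            dilation = as.integer(dilation),
            squash = if (squash == "tanh") "tanh" else "none",
            b = bias)
  for (qi in seq_len(q_order))
    p[[paste0("W", qi)]] <- weight_to_mat(weights[[qi]])
  selfonn_fwd(p, x)$y
}

# ---- simple point-wise layers -------------------------------------------

relu_fwd <- function(x) list(y = pmax(x, 0), mask = x > 0)
relu_bwd <- function(cache, dy) dy * cache$mask

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_channels <- function(x) {
  # x: (H, W, K); softmax over the channel axis, numerically stable
  m <- apply(x, c(1, 2), max)
  e <- exp(x - array(m, dim(x)))
  s <- apply(e, c(1, 2), sum)
  e / array(s, dim(x))
}

up_nn <- function(x, f) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f), ,
    drop = FALSE]
}

up_nn_bwd <- function(dy, f) {
  d <- dim(dy)
  H <- d[1] / f; W <- d[2] / f
  dx <- array(0, c(H, W, d[3]))
  for (a in seq_len(f)) for (b in seq_len(f))
    dx <- dx + dy[seq(a, d[1], by = f), seq(b, d[2], by = f), ,
                  drop = FALSE]
  dx
}

concat_ch <- function(a, b) {
  out <- array(0, c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

split_ch <- function(d, n1) {
  list(a = d[, , seq_len(n1), drop = FALSE],
       b = d[, , -seq_len(n1), drop = FALSE])
}

# ---- losses --------------------------------------------------------------

# logits: (H, W, K) or length-K vector; target: integer classes in 1..K
# (matrix or scalar). Returns loss and dlogits (mean-reduced).
softmax_ce <- function(logits, target, class_weights = NULL) {
  if (is.null(dim(logits))) {
    K <- length(logits)
    p <- exp(logits - max(logits)); p <- p / sum(p)
    loss <- -log(max(p[target], 1e-12))
    d <- p; d[target] <- d[target] - 1
    return(list(loss = loss, dlogits = d))
  }
  K <- dim(logits)[3]
  p <- softmax_channels(logits)
  n <- length(target)
  idx <- cbind(c(row(target)), c(col(target)), c(target))
  w <- if (is.null(class_weights)) rep(1, n) else class_weights[c(target)]
  loss <- -sum(w * log(pmax(p[idx], 1e-12))) / sum(w)
  d <- p
  d[idx] <- d[idx] - 1
  d <- d * array(matrix(w, nrow(target), ncol(target)), dim(d)) / sum(w)
  list(loss = loss, dlogits = d)
}

# Soft Dice over the channel axis (squared-denominator variant).
# prob: (H, W, K) softmax output; target: integer matrix in 1..K.
# Returns loss = 1 - mean_c Dice_c over `classes` and the gradient wrt
# the *logits* (chained through the softmax Jacobian).
soft_dice <- function(prob, target, classes = seq_len(dim(prob)[3]),
                      eps = 1e-6) {
  K <- dim(prob)[3]
  dLdp <- array(0, dim(prob))
  dice <- numeric(0)
  for (k in classes) {
    t_k <- (target == k) * 1
    p_k <- prob[, , k]
    num <- 2 * sum(p_k * t_k)
    den <- sum(p_k^2) + sum(t_k) + eps
    dice <- c(dice, num / den)
    # d(1 - num/den)/dp = -(2*t*den - num*2*p) / den^2
    dLdp[, , k] <- dLdp[, , k] -
      (2 * t_k * den - num * 2 * p_k) / den^2 / length(classes)
  }
  # softmax jacobian: dz_k = p_k * (dp_k - sum_c dp_c p_c)
  s <- array(0, dim(prob)[1:2])
  for (k in seq_len(K)) s <- s + dLdp[, , k] * prob[, , k]
  dlogits <- array(0, dim(prob))
  for (k in seq_len(K))
    dlogits[, , k] <- prob[, , k] * (dLdp[, , k] - s)
  list(loss = 1 - mean(dice), dlogits = dlogits, dice = dice)
}

bce_loss <- function(prob, target, weight = NULL) {
  w <- if (is.null(weight)) 1 else weight
  n <- length(prob)
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  loss <- -sum(w * (target * log(p) + (1 - target) * log(1 - p))) / n
  dprob <- w * (p - target) / (p * (1 - p)) / n
  list(loss = loss, dprob = dprob)
}

# ---- generic parameter walking + Adam ------------------------------------

PARAM_KEYS <- function(p) {
  keys <- names(p)
  keys[vapply(keys, function(k)
    is.numeric(p[[k]]) && !k %in% c("kh", "kw", "cin", "cout", "q",
                                    "stride", "dilation"),
    logical(1))]
}

# params: nested named list whose leaves are layer lists (numeric fields
# plus optional character flags); gradient structures mirror them.
is_layer_node <- function(p) {
  is.list(p) && length(p) > 0 &&
    all(vapply(p, function(e) is.numeric(e) || is.character(e), logical(1)))
}

walk_layers <- function(params) {
  out <- list()
  rec <- function(p, path) {
    if (is_layer_node(p)) {
      out[[length(out) + 1]] <<- path
    } else if (is.list(p)) {
      for (nm in names(p)) rec(p[[nm]], c(path, nm))
    }
  }
  rec(params, character(0))
  out
}

get_path <- function(p, path) { for (k in path) p <- p[[k]]; p }
set_path <- function(p, path, value) {
  if (length(path) == 1) { p[[path]] <- value; return(p) }
  p[[path[1]]] <- set_path(p[[path[1]]], path[-1], value)
  p
}

adam_init <- function(params) {
  st <- list(t = 0, m = list(), v = list())
  for (path in walk_layers(params)) {
    layer <- get_path(params, path)
    key <- paste(path, collapse = "/")
    st$m[[key]] <- lapply(layer[PARAM_KEYS(layer)], function(x) x * 0)
    st$v[[key]] <- st$m[[key]]
  }
  st
}

adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (path in walk_layers(params)) {
    key <- paste(path, collapse = "/")
    layer <- get_path(params, path)
    g <- get_path(grads, path)
    for (nm in PARAM_KEYS(layer)) {
      gi <- g[[nm]]
      if (is.null(gi)) next
      state$m[[key]][[nm]] <- beta1 * state$m[[key]][[nm]] + (1 - beta1) * gi
      state$v[[key]][[nm]] <- beta2 * state$v[[key]][[nm]] +
        (1 - beta2) * gi^2
      layer[[nm]] <- layer[[nm]] - lr * (state$m[[key]][[nm]] / bc1) /
        (sqrt(state$v[[key]][[nm]] / bc2) + eps)
    }
    params <- set_path(params, path, layer)
  }
  list(params = params, state = state)
}

# accumulate grads (same structure) across a minibatch
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (path in walk_layers(b)) {
    la <- get_path(a, path); lb <- get_path(b, path)
    for (nm in names(lb)) la[[nm]] <- la[[nm]] + lb[[nm]]
    a <- set_path(a, path, la)
  }
  a
}

grads_scale <- function(g, s) {
  for (path in walk_layers(g)) {
    l <- get_path(g, path)
    for (nm in names(l)) l[[nm]] <- l[[nm]] * s
    g <- set_path(g, path, l)
  }
  g
}
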