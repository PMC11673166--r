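# Minimal dense-network machinery: forward pass with optional mid-network
# injection of a conditioning vector, manual backprop, Adam updates. Batches
# are row-major (m x d). This backs both the GAN networks and the MLP
# classifier used in utility evaluation.

act_fun <- function(z, kind) {
  switch(kind,
    lrelu = ifelse(z > 0, z, 0.2 * z),
    relu = pmax(z, 0),
    sigmoid = 1 / (1 + exp(-z)),
    identity = z,
    stop("unknown activation: ", kind))
}

act_grad <- function(z, kind) {
  switch(kind,
    lrelu = ifelse(z > 0, 1, 0.2),
    relu = (z > 0) * 1,
    identity = z * 0 + 1,
    stop("no gradient rule for: ", kind))
}

# layer i maps dims$in[i] -> dims$out[i]; if inject_after = k > 0, layer k+1's
# input is the layer-k activation concatenated with the injected vector.
dense_net <- function(input_dim, widths, output_dim,
                      inject_dim = 0L, inject_after = 0L,
                      hidden_act = "lrelu", out_act = "sigmoid", seed = 1L) {
  sizes_out <- c(widths, output_dim)
  n_layers <- length(sizes_out)
  if (inject_after >= n_layers)
    stop("injection layer must lie before the final layer", call. = FALSE)
  sizes_in <- c(input_dim, sizes_out[-n_layers])
  if (inject_after > 0L)
    sizes_in[inject_after + 1L] <- sizes_in[inject_after + 1L] + inject_dim
  params <- with_seed(seed, lapply(seq_len(n_layers), function(i) {
    list(W = matrix(stats::rnorm(sizes_in[i] * sizes_out[i],
                                 sd = sqrt(2 / sizes_in[i])),
                    sizes_in[i], sizes_out[i]),
         b = numeric(sizes_out[i]))
  }))
  list(params = params, n_layers = n_layers,
       input_dim = input_dim, output_dim = output_dim,
       inject_dim = as.integer(inject_dim),
       inject_after = as.integer(inject_after),
       hidden_act = hidden_act, out_act = out_act,
       widths = widths)
}

# X: m x input_dim; inject: m x inject_dim (required iff inject_dim > 0).
# Returns list(out, cache); cache holds per-layer inputs and pre-activations.
net_forward <- function(net, X, inject = NULL) {
  m <- nrow(X)
  if (net$inject_dim > 0L) {
    stopifnot(!is.null(inject), ncol(inject) == net$inject_dim)
  }
  inputs <- vector("list", net$n_layers)
  Z <- vector("list", net$n_layers)
  A <- X
  for (i in seq_len(net$n_layers)) {
    if (net$inject_after > 0L && i == net$inject_after + 1L)
      A <- cbind(A, inject)
    inputs[[i]] <- A
    p <- net$params[[i]]
    z <- A %*% p$W
    z <- sweep(z, 2L, p$b, "+")
    Z[[i]] <- z
    A <- act_fun(z, if (i == net$n_layers) net$out_act else net$hidden_act)
  }
  list(out = A, cache = list(inputs = inputs, Z = Z))
}

# dZ_out: gradient of the loss w.r.t. the final pre-activation (m x output_dim).
# Returns parameter grads and the gradient w.r.t. the original input X
# (injected columns are dropped).
net_backward <- function(net, cache, dZ_out) {
  grads <- vector("list", net$n_layers)
  dZ <- dZ_out
  for (i in rev(seq_len(net$n_layers))) {
    A <- cache$inputs[[i]]
    grads[[i]] <- list(W = crossprod(A, dZ), b = colSums(dZ))
    dA <- dZ %*% t(net$params[[i]]$W)
    if (net$inject_after > 0L && i == net$inject_after + 1L) {
      keep <- ncol(dA) - net$inject_dim
      dA <- dA[, seq_len(keep), drop = FALSE]
    }
    if (i > 1L) {
      dZ <- dA * act_grad(cache$Z[[i - 1L]], net$hidden_act)
    } else {
      dX <- dA
    }
  }
  list(grads = grads, dX = dX)
}

adam_init <- function(net) {
  lapply(net$params, function(p)
    list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(net, grads, state, lr, t,
                      beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(net$params)) {
    g <- grads[[i]]; s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    net$params[[i]]$W <- net$params[[i]]$W -
      lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    net$params[[i]]$b <- net$params[[i]]$b -
      lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[i]] <- s
  }
  list(net = net, state = state)
}
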