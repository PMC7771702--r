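# Minimal deterministic neural-network engine backing the heatmap FCN and
# the bounding-box regressor.  Static computation graphs over (H, W, C, N)
# tensors; convolution kernels live in src/conv_ops.cpp; batch-norm, ReLU,
# residual add, channel concat, flatten and linear layers are plain R.
# Gradients are verified against finite differences in the test suite.
#
# Internal API (not exported): nn_graph()/nn_add() build a graph,
# nn_init() draws seeded He weights, nn_forward()/nn_backward() run it,
# nn_adam_step() updates it, nn_fit() is the minibatch training loop.

nn_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g
}

nn_add <- function(g, op, inputs = integer(), ...) {
  inputs <- as.integer(inputs)   # force now: nested nn_add() calls mutate g
  cfg <- list(...)
  id <- length(g$nodes) + 1L
  g$nodes[[id]] <- list(id = id, op = op, inputs = inputs,
                        cfg = cfg, par = NULL)
  id
}

# Convenience: conv (+ optional BN + ReLU) chains used all over the FCN.
nn_conv_bn_relu <- function(g, inp, out_ch, k = 3L, stride = 1L,
                            bn = TRUE, act = TRUE) {
  id <- nn_add(g, "conv", inp, k = as.integer(k), stride = as.integer(stride),
               pad = as.integer((k - 1) / 2), out_ch = as.integer(out_ch))
  if (bn) id <- nn_add(g, "bn", id)
  if (act) id <- nn_add(g, "relu", id)
  id
}

nn_deconv_bn_relu <- function(g, inp, out_ch) {
  id <- nn_add(g, "deconv", inp, k = 3L, stride = 2L, pad = 1L,
               out_ch = as.integer(out_ch))
  id <- nn_add(g, "bn", id)
  nn_add(g, "relu", id)
}

# Shape inference + seeded He initialization.  `in_shape` is (H, W, C).
# Caller is responsible for seeding the RNG (everything runs inside
# with_seed() in the public training functions).
nn_init <- function(g, in_shape) {
  nodes <- g$nodes
  shapes <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    s_in <- if (length(nd$inputs)) shapes[[nd$inputs[1L]]] else NULL
    sh <- switch(nd$op,
      input = nd$cfg$shape,
      conv = {
        k <- nd$cfg$k; st <- nd$cfg$stride; p <- nd$cfg$pad
        cin <- s_in[3L]; cout <- nd$cfg$out_ch
        sd <- sqrt(2 / (k * k * cin)) * (nd$cfg$init_scale %||% 1)
        nodes[[i]]$par <- list(
          W = matrix(stats::rnorm(k * k * cin * cout, 0, sd),
                     k * k * cin, cout),
          b = numeric(cout))
        nodes[[i]]$cfg$in_ch <- cin
        c((s_in[1L] + 2 * p - k) %/% st + 1L,
          (s_in[2L] + 2 * p - k) %/% st + 1L, cout)
      },
      deconv = {
        k <- nd$cfg$k; cin <- s_in[3L]; cout <- nd$cfg$out_ch
        sd <- sqrt(2 / (k * k * cin))
        # weights of the reverse conv (large frame -> small frame):
        # (k*k*cout) rows, cin columns
        nodes[[i]]$par <- list(
          W = matrix(stats::rnorm(k * k * cout * cin, 0, sd),
                     k * k * cout, cin),
          b = numeric(cout))
        nodes[[i]]$cfg$in_ch <- cin
        c(2L * s_in[1L], 2L * s_in[2L], cout)
      },
      bn = {
        C <- s_in[3L]
        nodes[[i]]$par <- list(gamma = rep(1, C), beta = numeric(C),
                               rmean = numeric(C), rvar = rep(1, C))
        s_in
      },
      relu = s_in,
      add = s_in,
      concat = {
        cs <- vapply(nd$inputs, function(j) shapes[[j]][3L], numeric(1))
        nodes[[i]]$cfg$sizes <- as.integer(cs)
        c(s_in[1L], s_in[2L], sum(cs))
      },
      flatten = prod(s_in),
      gap = c(s_in[3L], 1L),
      soft_moments = c(4L, 1L),
      linear = {
        D <- s_in[1L]; out <- nd$cfg$out_dim
        W <- if (identical(nd$cfg$init, "identity") && D == out)
          diag(out) else matrix(stats::rnorm(out * D, 0, sqrt(2 / D)),
                                out, D)
        nodes[[i]]$par <- list(W = W, b = numeric(out))
        c(out, 1L)
      },
      stop_skullmark("invalid_config", paste("unknown op", nd$op)))
    shapes[[i]] <- sh
  }
  list(nodes = nodes, shapes = shapes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

bn_forward <- function(x, par, training, momentum = 0.1, eps = 1e-5) {
  r <- cpp_bn_fwd(x, par$gamma, par$beta, par$rmean, par$rvar,
                  training, momentum, eps)
  if (training) {
    par$rmean <- as.numeric(r$rmean)
    par$rvar <- as.numeric(r$rvar)
  }
  list(y = r$y, par = par,
       cache = if (training) list(xhat = r$xhat, invstd = r$invstd))
}

bn_backward <- function(dy, par, cache) {
  r <- cpp_bn_bwd(dy, cache$xhat, par$gamma, cache$invstd)
  list(dx = r$dx, dgamma = as.numeric(r$dgamma),
       dbeta = as.numeric(r$dbeta))
}

nn_forward <- function(net, x, training = FALSE) {
  nodes <- net$nodes
  n <- length(nodes)
  outs <- vector("list", n)
  caches <- vector("list", n)
  for (i in seq_len(n)) {
    nd <- nodes[[i]]
    outs[[i]] <- switch(nd$op,
      input = x,
      conv = cpp_conv_fwd(outs[[nd$inputs]], nd$par$W, nd$par$b,
                          nd$cfg$k, nd$cfg$k, nd$cfg$stride, nd$cfg$pad),
      deconv = {
        xin <- outs[[nd$inputs]]
        di <- dim(xin)
        y <- cpp_conv_bwd_data(xin, nd$par$W, nd$cfg$k, nd$cfg$k,
                               nd$cfg$stride, nd$cfg$pad,
                               2L * di[1L], 2L * di[2L])
        cpp_add_channel_bias(y, nd$par$b)
      },
      bn = {
        r <- bn_forward(outs[[nd$inputs]], nd$par, training)
        nodes[[i]]$par <- r$par
        caches[[i]] <- r$cache
        r$y
      },
      relu = cpp_relu_fwd(outs[[nd$inputs]]),
      add = outs[[nd$inputs[1L]]] + outs[[nd$inputs[2L]]],
      concat = concat_channels(outs[nd$inputs]),
      flatten = {
        xin <- outs[[nd$inputs]]
        d <- dim(xin)
        caches[[i]] <- d
        dim(xin) <- c(prod(d[1:3]), d[4L])
        xin
      },
      gap = {                      # global average pool -> (C, N) matrix
        xin <- outs[[nd$inputs]]
        d <- dim(xin)
        caches[[i]] <- d
        dim(xin) <- c(d[1L] * d[2L], d[3L] * d[4L])
        matrix(colMeans(xin), d[3L], d[4L])
      },
      soft_moments = {
        # spatial softmax of a 1-channel score map, reduced to first and
        # second moments: (E[r], E[c], log sd_r, log sd_c), coords in [0,1]
        xin <- outs[[nd$inputs]]
        d <- dim(xin)
        H <- d[1L]; W <- d[2L]; N <- d[4L]
        rc <- (seq_len(H) - 1) / max(1L, H - 1L)
        cc <- (seq_len(W) - 1) / max(1L, W - 1L)
        out <- matrix(0, 4L, N)
        P <- array(0, c(H, W, N))
        mm <- matrix(0, 4L, N)        # f1, f2, Vr, Vc per image
        for (n in seq_len(N)) {
          s <- xin[, , 1L, n]
          e <- exp(s - max(s))
          p <- e / sum(e)
          P[, , n] <- p
          pr <- rowSums(p); pc <- colSums(p)
          f1 <- sum(pr * rc); f2 <- sum(pc * cc)
          Vr <- sum(pr * (rc - f1)^2); Vc <- sum(pc * (cc - f2)^2)
          mm[, n] <- c(f1, f2, Vr, Vc)
          out[, n] <- c(f1, f2, 0.5 * log(Vr + 1e-8), 0.5 * log(Vc + 1e-8))
        }
        caches[[i]] <- list(P = P, mm = mm, rc = rc, cc = cc)
        out
      },
      linear = nd$par$W %*% outs[[nd$inputs]] + nd$par$b)
  }
  net$nodes <- nodes
  list(out = outs[[net$out]], outs = outs, caches = caches, net = net)
}

nn_backward <- function(net, fw, dout) {
  nodes <- net$nodes
  n <- length(nodes)
  douts <- vector("list", n)
  grads <- vector("list", n)
  douts[[net$out]] <- dout
  push <- function(id, g) {
    douts[[id]] <<- if (is.null(douts[[id]])) g else douts[[id]] + g
  }
  for (i in rev(seq_len(n))) {
    nd <- nodes[[i]]
    dy <- douts[[i]]
    if (is.null(dy) || nd$op == "input") next
    switch(nd$op,
      conv = {
        xin <- fw$outs[[nd$inputs]]
        wb <- cpp_conv_bwd_wb(xin, dy, nd$cfg$k, nd$cfg$k,
                              nd$cfg$stride, nd$cfg$pad)
        grads[[i]] <- list(W = wb$dW, b = as.numeric(wb$db))
        di <- dim(xin)
        push(nd$inputs, cpp_conv_bwd_data(dy, nd$par$W, nd$cfg$k, nd$cfg$k,
                                          nd$cfg$stride, nd$cfg$pad,
                                          di[1L], di[2L]))
      },
      deconv = {
        xin <- fw$outs[[nd$inputs]]
        wb <- cpp_conv_bwd_wb(dy, xin, nd$cfg$k, nd$cfg$k,
                              nd$cfg$stride, nd$cfg$pad)
        grads[[i]] <- list(W = wb$dW, b = as.numeric(cpp_channel_sums(dy)))
        push(nd$inputs, cpp_conv_fwd(dy, nd$par$W,
                                     numeric(ncol(nd$par$W)),
                                     nd$cfg$k, nd$cfg$k,
                                     nd$cfg$stride, nd$cfg$pad))
      },
      bn = {
        r <- bn_backward(dy, nd$par, fw$caches[[i]])
        grads[[i]] <- list(gamma = r$dgamma, beta = r$dbeta)
        push(nd$inputs, r$dx)
      },
      relu = push(nd$inputs, cpp_relu_bwd(dy, fw$outs[[i]])),
      add = {
        push(nd$inputs[1L], dy)
        push(nd$inputs[2L], dy)
      },
      concat = {
        parts <- split_channels(dy, nd$cfg$sizes)
        for (j in seq_along(nd$inputs)) push(nd$inputs[j], parts[[j]])
      },
      flatten = {
        d <- fw$caches[[i]]
        dim(dy) <- d
        push(nd$inputs, dy)
      },
      gap = {
        d <- fw$caches[[i]]
        hw <- d[1L] * d[2L]
        push(nd$inputs,
             array(rep(as.numeric(dy), each = hw) / hw, d))
      },
      soft_moments = {
        ca <- fw$caches[[i]]
        d <- dim(ca$P); H <- d[1L]; W <- d[2L]; N <- d[3L]
        dx <- array(0, c(H, W, 1L, N))
        for (n in seq_len(N)) {
          a <- dy[, n]
          f1 <- ca$mm[1L, n]; f2 <- ca$mm[2L, n]
          Vr <- ca$mm[3L, n]; Vc <- ca$mm[4L, n]
          # dL/dp at each pixel (second-moment terms use dV/dp = (x-f)^2
          # since sum p (x - f) = 0)
          g <- outer(a[1L] * ca$rc +
                       a[3L] * 0.5 / (Vr + 1e-8) * (ca$rc - f1)^2,
                     a[2L] * ca$cc +
                       a[4L] * 0.5 / (Vc + 1e-8) * (ca$cc - f2)^2, `+`)
          p <- ca$P[, , n]
          dx[, , 1L, n] <- p * (g - sum(p * g))
        }
        push(nd$inputs, dx)
      },
      linear = {
        xin <- fw$outs[[nd$inputs]]
        grads[[i]] <- list(W = dy %*% t(xin), b = rowSums(dy))
        push(nd$inputs, t(nd$par$W) %*% dy)
      })
  }
  grads
}

nn_adam_init <- function(net) {
  lapply(net$nodes, function(nd) {
    if (is.null(nd$par)) return(NULL)
    pn <- intersect(names(nd$par), c("W", "b", "gamma", "beta"))
    st <- lapply(nd$par[pn], function(p) list(m = p * 0, v = p * 0))
    st
  })
}

nn_adam_step <- function(net, grads, state, t, lr = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  b1t <- 1 - beta1^t
  b2t <- 1 - beta2^t
  for (i in seq_along(net$nodes)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (pn in names(g)) {
      st <- state[[i]][[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[pn]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[pn]]^2
      state[[i]][[pn]] <- st
      net$nodes[[i]]$par[[pn]] <- net$nodes[[i]]$par[[pn]] -
        lr * (st$m / b1t) / (sqrt(st$v / b2t) + eps)
    }
  }
  list(net = net, state = state)
}

nn_n_params <- function(net) {
  sum(vapply(net$nodes, function(nd) {
    if (is.null(nd$par)) return(0)
    sum(vapply(nd$par[intersect(names(nd$par),
                                c("W", "b", "gamma", "beta"))],
               length, numeric(1)))
  }, numeric(1)))
}

# Mean-squared error over every element, and its gradient.
mse_loss <- function(y, target) {
  r <- y - target
  list(loss = mean(r * r), grad = 2 * r / length(r))
}

take_batch <- function(x, idx) {
  if (length(dim(x)) == 4L) x[, , , idx, drop = FALSE]
  else x[, idx, drop = FALSE]
}

# Generic seeded minibatch trainer.  `x` is (H, W, C, N); `y` is either a
# (H, W, C, N) label array or an (out_dim x N) target matrix.  Records
# per-epoch mean training-batch loss and validation loss (inference-mode
# batch norm), and keeps a copy of the best-validation network.
nn_fit <- function(net, x, y, epochs, batch_size = 8L, lr = 1e-3,
                   val_x = NULL, val_y = NULL, verbose = FALSE) {
  N <- if (length(dim(x)) == 4L) dim(x)[4L] else ncol(x)
  state <- nn_adam_init(net)
  t <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  best <- list(net = net, val = Inf, epoch = 0L)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(N)
    bl <- numeric(0)
    for (start in seq(1L, N, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, N)]
      fw <- nn_forward(net, take_batch(x, idx), training = TRUE)
      net <- fw$net
      ls <- mse_loss(fw$out, take_batch(y, idx))
      grads <- nn_backward(net, fw, ls$grad)
      t <- t + 1L
      upd <- nn_adam_step(net, grads, state, t, lr = lr)
      net <- upd$net; state <- upd$state
      bl <- c(bl, ls$loss)
    }
    vl <- NA_real_
    if (!is.null(val_x)) {
      vfw <- nn_forward(net, val_x, training = FALSE)
      vl <- mse_loss(vfw$out, val_y)$loss
      if (vl < best$val) best <- list(net = net, val = vl, epoch = ep)
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(bl),
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %d  train %.6g  val %.6g", ep, mean(bl), vl))
  }
  if (is.infinite(best$val)) best <- list(net = net, val = NA_real_,
                                          epoch = epochs)
  list(net = net, best_net = best$net, best_epoch = best$epoch,
       history = hist)
}
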