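# Minimal static-graph neural network internals for the segmentation model.
# Tensors are numeric arrays dim (H, W, C, N). Parameters and batch-norm
# running statistics live in the model environment under "par." / "buf."
# prefixed names; gradients are accumulated into a parallel environment.

he_init <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

node_conv <- function(env, name, cin, cout, k = 3, stride = 1,
                      pad = k %/% 2, bias = FALSE) {
  env[[paste0("par.", name, ".W")]] <- he_init(k, k, cin, cout)
  if (bias) env[[paste0("par.", name, ".b")]] <- numeric(cout)
  list(kind = "conv", name = name, k = k, stride = stride, pad = pad,
       cin = cin, cout = cout, bias = bias)
}

node_bn <- function(env, name, c) {
  env[[paste0("par.", name, ".gamma")]] <- rep(1, c)
  env[[paste0("par.", name, ".beta")]]  <- rep(0, c)
  env[[paste0("buf.", name, ".mean")]]  <- rep(0, c)
  env[[paste0("buf.", name, ".var")]]   <- rep(1, c)
  list(kind = "bn", name = name, c = c)
}

node_relu    <- function() list(kind = "relu")
node_sigmoid <- function() list(kind = "sigmoid")
node_maxpool <- function(k = 3, stride = 2, pad = 1) {
  list(kind = "maxpool", k = k, stride = stride, pad = pad)
}
node_seq <- function(...) list(kind = "seq", nodes = list(...))

# residual block: relu(body(x) + shortcut(x)); shortcut NULL = identity
node_residual <- function(body, shortcut = NULL) {
  list(kind = "residual", body = body, shortcut = shortcut)
}

bn_forward <- function(x, gamma, beta, rmean, rvar, train, eps = 1e-5) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  x3 <- x; dim(x3) <- c(HW, C, N)
  if (train) {
    mu <- rowMeans(colMeans(x3, dims = 1))               # per-channel mean
    m2 <- rowMeans(colMeans(x3 * x3, dims = 1))
    v  <- pmax(m2 - mu^2, 0)
  } else {
    mu <- rmean; v <- rvar
  }
  inv_std <- 1 / sqrt(v + eps)
  xhat <- (as.vector(x) - rep(mu, each = HW)) * rep(inv_std, each = HW)
  y <- xhat * rep(gamma, each = HW) + rep(beta, each = HW)
  dim(y) <- d
  xh <- xhat; dim(xh) <- d
  list(y = y, xhat = xh, inv_std = inv_std, mu = mu, v = v)
}

bn_backward <- function(dy, xhat, inv_std, gamma) {
  d <- dim(dy); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]; Npc <- HW * N
  dy3 <- dy; dim(dy3) <- c(HW, C, N)
  xh3 <- xhat; dim(xh3) <- c(HW, C, N)
  dbeta  <- rowSums(colSums(dy3, dims = 1))
  dgamma <- rowSums(colSums(dy3 * xh3, dims = 1))
  g <- rep(gamma * inv_std, each = HW)
  dx <- g * (as.vector(dy) - rep(dbeta / Npc, each = HW) -
               as.vector(xhat) * rep(dgamma / Npc, each = HW))
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

upsample2_forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , drop = FALSE]
}

upsample2_backward <- function(dy) {
  d <- dim(dy)
  io <- seq(1, d[1], by = 2); ie <- seq(2, d[1], by = 2)
  jo <- seq(1, d[2], by = 2); je <- seq(2, d[2], by = 2)
  dy[io, jo, , , drop = FALSE] + dy[io, je, , , drop = FALSE] +
    dy[ie, jo, , , drop = FALSE] + dy[ie, je, , , drop = FALSE]
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

exec_forward <- function(node, x, env, train) {
  switch(node$kind,
    conv = {
      W <- env[[paste0("par.", node$name, ".W")]]
      b <- if (node$bias) env[[paste0("par.", node$name, ".b")]] else numeric(node$cout)
      y <- .conv2d_forward(x, W, b, node$stride, node$pad)
      list(y = y, cache = list(x = x))
    },
    bn = {
      g <- env[[paste0("par.", node$name, ".gamma")]]
      be <- env[[paste0("par.", node$name, ".beta")]]
      r <- bn_forward(x, g, be,
                      env[[paste0("buf.", node$name, ".mean")]],
                      env[[paste0("buf.", node$name, ".var")]], train)
      if (train) {   # momentum 0.1 running-statistics update
        env[[paste0("buf.", node$name, ".mean")]] <-
          0.9 * env[[paste0("buf.", node$name, ".mean")]] + 0.1 * r$mu
        env[[paste0("buf.", node$name, ".var")]] <-
          0.9 * env[[paste0("buf.", node$name, ".var")]] + 0.1 * r$v
      }
      list(y = r$y, cache = list(xhat = r$xhat, inv_std = r$inv_std))
    },
    relu = {
      y <- pmax(x, 0)
      list(y = y, cache = list(pos = x > 0))
    },
    sigmoid = {
      y <- 1 / (1 + exp(-x))
      list(y = y, cache = list(y = y))
    },
    maxpool = {
      r <- .maxpool_forward(x, node$k, node$stride, node$pad)
      list(y = r$y, cache = list(argmax = r$argmax, xdim = dim(x)))
    },
    seq = {
      caches <- vector("list", length(node$nodes))
      for (i in seq_along(node$nodes)) {
        r <- exec_forward(node$nodes[[i]], x, env, train)
        x <- r$y
        caches[[i]] <- r$cache
      }
      list(y = x, cache = caches)
    },
    residual = {
      rb <- exec_forward(node$body, x, env, train)
      if (is.null(node$shortcut)) {
        s <- x; cs <- NULL
      } else {
        rs <- exec_forward(node$shortcut, x, env, train)
        s <- rs$y; cs <- rs$cache
      }
      z <- rb$y + s
      list(y = pmax(z, 0),
           cache = list(body = rb$cache, shortcut = cs, pos = z > 0))
    },
    stopf("unknown node kind %s", node$kind)
  )
}

exec_backward <- function(node, cache, dy, env, grads) {
  switch(node$kind,
    conv = {
      W <- env[[paste0("par.", node$name, ".W")]]
      r <- .conv2d_backward(cache$x, W, dy, node$stride, node$pad)
      nm <- paste0("par.", node$name, ".W")
      grads[[nm]] <- if (is.null(grads[[nm]])) r$dw else grads[[nm]] + r$dw
      if (node$bias) {
        nb <- paste0("par.", node$name, ".b")
        grads[[nb]] <- if (is.null(grads[[nb]])) r$db else grads[[nb]] + r$db
      }
      r$dx
    },
    bn = {
      g <- env[[paste0("par.", node$name, ".gamma")]]
      r <- bn_backward(dy, cache$xhat, cache$inv_std, g)
      ng <- paste0("par.", node$name, ".gamma")
      nb <- paste0("par.", node$name, ".beta")
      grads[[ng]] <- if (is.null(grads[[ng]])) r$dgamma else grads[[ng]] + r$dgamma
      grads[[nb]] <- if (is.null(grads[[nb]])) r$dbeta else grads[[nb]] + r$dbeta
      r$dx
    },
    relu = dy * cache$pos,
    sigmoid = dy * cache$y * (1 - cache$y),
    maxpool = .maxpool_backward(dy, cache$argmax, cache$xdim),
    seq = {
      for (i in rev(seq_along(node$nodes))) {
        dy <- exec_backward(node$nodes[[i]], cache[[i]], dy, env, grads)
      }
      dy
    },
    residual = {
      dz <- dy * cache$pos
      dxb <- exec_backward(node$body, cache$body, dz, env, grads)
      dxs <- if (is.null(node$shortcut)) dz
             else exec_backward(node$shortcut, cache$shortcut, dz, env, grads)
      dxb + dxs
    },
    stopf("unknown node kind %s", node$kind)
  )
}

param_names <- function(model) ls(model$env, pattern = "^par\\.")

snapshot_params <- function(model) {
  nm <- ls(model$env)
  stats::setNames(lapply(nm, function(n) model$env[[n]]), nm)
}

restore_params <- function(model, snap) {
  for (n in names(snap)) model$env[[n]] <- snap[[n]]
  invisible(model)
}

clone_model <- function(model) {
  e <- new.env(parent = emptyenv())
  for (n in ls(model$env)) e[[n]] <- model$env[[n]]
  model$env <- e
  model
}

adam_init <- function(model) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st
}

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (n in param_names(model)) {
    g <- grads[[n]]
    if (is.null(g)) next
    mkey <- paste0("m.", n); vkey <- paste0("v.", n)
    m <- if (is.null(state[[mkey]])) g * 0 else state[[mkey]]
    v <- if (is.null(state[[vkey]])) g * 0 else state[[vkey]]
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    state[[mkey]] <- m; state[[vkey]] <- v
    mh <- m / (1 - beta1^t); vh <- v / (1 - beta2^t)
    model$env[[n]] <- model$env[[n]] - lr * mh / (sqrt(vh) + eps)
  }
  invisible(model)
}
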