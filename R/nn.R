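## Minimal CPU network engine backing the dual-branch classifier.
## Tensors are column-major R arrays [H, W, C, N]; vector features are
## matrices [d, N]. Convolution/pooling kernels live in src/nn_ops.cpp.

#' @useDynLib dbtdualnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---- layer constructors ----------------------------------------------------

#' Convolutional layer
#'
#' Creates a 2-D convolution layer with uniform fan-in initialization
#' (weights drawn from U(-sqrt(6/fan_in), +sqrt(6/fan_in)), zero bias).
#'
#' @param in_ch,out_ch channel counts (in_ch is the full input channel count;
#'   with `groups > 1` each group sees `in_ch/groups` channels).
#' @param k kernel side; @param stride,pad,groups usual convolution geometry.
#' @return a layer object consumed by [nn_forward()].
#' @keywords internal
layer_conv <- function(in_ch, out_ch, k, stride = 1L, pad = 0L, groups = 1L) {
  stopifnot(in_ch %% groups == 0, out_ch %% groups == 0)
  cg <- in_ch %/% groups
  fan_in <- k * k * cg
  bound <- sqrt(6 / fan_in)
  W <- array(stats::runif(k * k * cg * out_ch, -bound, bound),
             dim = c(k, k, cg, out_ch))
  structure(list(type = "conv", W = W, b = numeric(out_ch),
                 stride = as.integer(stride), pad = as.integer(pad),
                 groups = as.integer(groups)), class = "dn_layer")
}

#' @keywords internal
layer_bn <- function(ch, eps = 1e-5, momentum = 0.1) {
  structure(list(type = "bn", gamma = rep(1, ch), beta = numeric(ch),
                 rmean = numeric(ch), rvar = rep(1, ch),
                 eps = eps, momentum = momentum), class = "dn_layer")
}

#' @keywords internal
layer_relu <- function() structure(list(type = "relu"), class = "dn_layer")

#' @keywords internal
layer_relu6 <- function() structure(list(type = "relu6"), class = "dn_layer")

#' @keywords internal
layer_maxpool <- function(k, stride = k, pad = 0L) {
  structure(list(type = "maxpool", k = as.integer(k),
                 stride = as.integer(stride), pad = as.integer(pad)),
            class = "dn_layer")
}

#' @keywords internal
layer_avgpool <- function(k, stride = k) {
  structure(list(type = "avgpool", k = as.integer(k),
                 stride = as.integer(stride)), class = "dn_layer")
}

#' Adaptive average pooling to a fixed `out x out` spatial grid.
#' @keywords internal
layer_adaptive_avgpool <- function(out = 1L) {
  structure(list(type = "adaptive_avgpool", out = as.integer(out)),
            class = "dn_layer")
}

#' Fully connected layer on [d, N] matrices.
#' @keywords internal
layer_linear <- function(in_dim, out_dim) {
  bound <- sqrt(6 / in_dim)
  structure(list(type = "linear",
                 W = matrix(stats::runif(out_dim * in_dim, -bound, bound),
                            out_dim, in_dim),
                 b = numeric(out_dim)), class = "dn_layer")
}

#' @keywords internal
nn_sequential <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "dn_layer"))
    layers <- layers[[1]]
  structure(list(type = "sequential", layers = layers), class = "dn_layer")
}

#' Residual block: out = act(body(x) + shortcut(x)).
#' `shortcut = NULL` means identity; `post_relu = FALSE` gives the linear
#' residual used by inverted-bottleneck blocks.
#' @keywords internal
nn_residual <- function(body, shortcut = NULL, post_relu = TRUE) {
  structure(list(type = "residual", body = body, shortcut = shortcut,
                 post_relu = isTRUE(post_relu)), class = "dn_layer")
}

#' Densely connected block: each unit consumes the concatenation of the
#' block input and all previous unit outputs.
#' @keywords internal
nn_dense_block <- function(units) {
  structure(list(type = "dense_block", units = units), class = "dn_layer")
}

## ---- helpers ---------------------------------------------------------------

adaptive_bins <- function(n, s) {
  lo <- floor((0:(s - 1)) * n / s) + 1L
  hi <- ceiling((1:s) * n / s)
  cbind(lo, hi)
}

bn_stats_scale <- function(x, per_ch) {
  d <- dim(x)
  rep(rep(per_ch, each = d[1] * d[2]), times = d[4])
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

## ---- forward ---------------------------------------------------------------

#' Forward pass through a layer graph
#'
#' @param layer a layer object; @param x input tensor or matrix.
#' @param train logical; batch-norm uses batch statistics when `TRUE`.
#' @return `list(out, cache)`; `cache` feeds [nn_backward()].
#' @keywords internal
nn_forward <- function(layer, x, train = FALSE) {
  switch(layer$type,
    conv = {
      y <- cpp_conv2d_forward(x, layer$W, layer$b,
                              layer$stride, layer$pad, layer$groups)
      list(out = y, cache = list(x = x))
    },
    bn = {
      d <- dim(x)
      if (train) {
        xp <- matrix(aperm(array(x, c(d[1] * d[2], d[3], d[4])), c(1, 3, 2)),
                     ncol = d[3])
        mu <- colMeans(xp)
        va <- colMeans(xp^2) - mu^2
        layer$rmean <- (1 - layer$momentum) * layer$rmean + layer$momentum * mu
        layer$rvar  <- (1 - layer$momentum) * layer$rvar + layer$momentum * va
      } else {
        mu <- layer$rmean; va <- layer$rvar
      }
      inv <- 1 / sqrt(va + layer$eps)
      xc <- x - bn_stats_scale(x, mu)
      xhat <- xc * bn_stats_scale(x, inv)
      y <- xhat * bn_stats_scale(x, layer$gamma) +
        bn_stats_scale(x, layer$beta)
      list(out = y,
           cache = list(xhat = xhat, inv = inv, train = train),
           layer = if (train) layer else NULL)
    },
    relu = {
      y <- pmax(x, 0); if (!is.null(dim(x))) dim(y) <- dim(x)
      list(out = y, cache = list(mask = y > 0))
    },
    relu6 = {
      y <- pmin(pmax(x, 0), 6); dim(y) <- dim(x)
      list(out = y, cache = list(mask = x > 0 & x < 6))
    },
    maxpool = {
      r <- cpp_maxpool_forward(x, layer$k, layer$stride, layer$pad)
      list(out = r$y, cache = list(idx = r$idx, in_dim = dim(x)))
    },
    avgpool = {
      y <- cpp_avgpool_forward(x, layer$k, layer$stride)
      list(out = y, cache = list(in_dim = dim(x)))
    },
    adaptive_avgpool = {
      d <- dim(x); s <- layer$out
      if (s == 1L) {
        y <- array(colMeans(matrix(x, nrow = d[1] * d[2])), c(1, 1, d[3], d[4]))
      } else {
        hb <- adaptive_bins(d[1], s); wb <- adaptive_bins(d[2], s)
        y <- array(0, c(s, s, d[3], d[4]))
        for (i in seq_len(s)) for (j in seq_len(s)) {
          blk <- x[hb[i, 1]:hb[i, 2], wb[j, 1]:wb[j, 2], , , drop = FALSE]
          y[i, j, , ] <- colMeans(matrix(blk, nrow = prod(dim(blk)[1:2])))
        }
      }
      list(out = y, cache = list(in_dim = d))
    },
    linear = {
      list(out = layer$W %*% x + layer$b, cache = list(x = x))
    },
    sequential = {
      caches <- vector("list", length(layer$layers))
      bn_upd <- FALSE
      for (i in seq_along(layer$layers)) {
        r <- nn_forward(layer$layers[[i]], x, train)
        x <- r$out; caches[[i]] <- r$cache
        if (train && !is.null(r$layer)) { layer$layers[[i]] <- r$layer; bn_upd <- TRUE }
      }
      out <- list(out = x, cache = list(children = caches))
      if (bn_upd) out$layer <- layer
      out
    },
    residual = {
      rb <- nn_forward(layer$body, x, train)
      if (!is.null(rb$layer)) layer$body <- rb$layer
      if (is.null(layer$shortcut)) {
        sc <- x; cs <- NULL
      } else {
        rs <- nn_forward(layer$shortcut, x, train)
        if (!is.null(rs$layer)) layer$shortcut <- rs$layer
        sc <- rs$out; cs <- rs$cache
      }
      s <- rb$out + sc
      if (layer$post_relu) {
        y <- pmax(s, 0); dim(y) <- dim(s)
        mask <- y > 0
      } else {
        y <- s; mask <- NULL
      }
      list(out = y,
           cache = list(body = rb$cache, shortcut = cs, mask = mask),
           layer = if (train) layer else NULL)
    },
    dense_block = {
      caches <- vector("list", length(layer$units))
      widths <- integer(length(layer$units))
      for (i in seq_along(layer$units)) {
        r <- nn_forward(layer$units[[i]], x, train)
        if (!is.null(r$layer)) layer$units[[i]] <- r$layer
        caches[[i]] <- r$cache
        widths[i] <- dim(r$out)[3]
        x <- concat_channels(x, r$out)
      }
      list(out = x, cache = list(children = caches, widths = widths,
                                 in_ch = dim(x)[3] - sum(widths)),
           layer = if (train) layer else NULL)
    },
    stop("unknown layer type: ", layer$type)
  )
}

## ---- backward --------------------------------------------------------------

#' Backward pass; returns `list(dx, grads)` where `grads` mirrors the layer
#' structure (conv/linear: `W`,`b`; bn: `gamma`,`beta`; composites recurse).
#' @keywords internal
nn_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv = {
      r <- cpp_conv2d_backward(cache$x, layer$W, dout,
                               layer$stride, layer$pad, layer$groups)
      list(dx = r$dx, grads = list(W = r$dw, b = r$db))
    },
    bn = {
      xhat <- cache$xhat; inv <- cache$inv
      d <- dim(xhat); m <- d[1] * d[2] * d[4]
      per_ch_sum <- function(a) {
        colSums(matrix(aperm(array(a, c(d[1] * d[2], d[3], d[4])), c(1, 3, 2)),
                       ncol = d[3]))
      }
      dgamma <- per_ch_sum(dout * xhat)
      dbeta <- per_ch_sum(dout)
      dxhat <- dout * bn_stats_scale(dout, layer$gamma)
      if (cache$train) {
        dx <- bn_stats_scale(dxhat, inv / m) *
          (m * dxhat - bn_stats_scale(dxhat, per_ch_sum(dxhat)) -
             xhat * bn_stats_scale(dxhat, per_ch_sum(dxhat * xhat)))
      } else {
        dx <- dxhat * bn_stats_scale(dxhat, inv)
      }
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = ,
    relu6 = {
      dx <- dout * cache$mask; dim(dx) <- dim(dout)
      list(dx = dx, grads = NULL)
    },
    maxpool = {
      list(dx = cpp_maxpool_backward(cache$idx, as.integer(cache$in_dim), dout),
           grads = NULL)
    },
    avgpool = {
      list(dx = cpp_avgpool_backward(as.integer(cache$in_dim), dout,
                                     layer$k, layer$stride),
           grads = NULL)
    },
    adaptive_avgpool = {
      d <- cache$in_dim; s <- layer$out
      dx <- array(0, d)
      hb <- adaptive_bins(d[1], s); wb <- adaptive_bins(d[2], s)
      for (i in seq_len(s)) for (j in seq_len(s)) {
        nh <- hb[i, 2] - hb[i, 1] + 1L; nw <- wb[j, 2] - wb[j, 1] + 1L
        g <- dout[i, j, , , drop = FALSE] / (nh * nw)
        dx[hb[i, 1]:hb[i, 2], wb[j, 1]:wb[j, 2], , ] <-
          dx[hb[i, 1]:hb[i, 2], wb[j, 1]:wb[j, 2], , , drop = FALSE] +
          array(rep(g, each = nh * nw), c(nh, nw, d[3], d[4]))
      }
      list(dx = dx, grads = NULL)
    },
    linear = {
      list(dx = t(layer$W) %*% dout,
           grads = list(W = dout %*% t(cache$x), b = rowSums(dout)))
    },
    sequential = {
      n <- length(layer$layers)
      grads <- vector("list", n)
      for (i in rev(seq_len(n))) {
        r <- nn_backward(layer$layers[[i]], cache$children[[i]], dout)
        dout <- r$dx
        grads[i] <- list(r$grads) # keep NULL placeholders for param-free layers
      }
      list(dx = dout, grads = list(layers = grads))
    },
    residual = {
      ds <- if (is.null(cache$mask)) dout else {
        z <- dout * cache$mask; dim(z) <- dim(dout); z
      }
      rb <- nn_backward(layer$body, cache$body, ds)
      if (is.null(layer$shortcut)) {
        dx <- rb$dx + ds; gs <- NULL
      } else {
        rs <- nn_backward(layer$shortcut, cache$shortcut, ds)
        dx <- rb$dx + rs$dx; gs <- rs$grads
      }
      list(dx = dx, grads = list(body = rb$grads, shortcut = gs))
    },
    dense_block = {
      n <- length(layer$units)
      widths <- cache$widths; in_ch <- cache$in_ch
      grads <- vector("list", n)
      ## dout covers [input | u1 | ... | un]; walk units in reverse, folding
      ## each unit's gradient back onto its (concatenated) input slice.
      for (i in rev(seq_len(n))) {
        ch_in_i <- in_ch + sum(widths[seq_len(i - 1L)])
        d_ui <- dout[, , ch_in_i + seq_len(widths[i]), , drop = FALSE]
        dout <- dout[, , seq_len(ch_in_i), , drop = FALSE]
        r <- nn_backward(layer$units[[i]], cache$children[[i]], d_ui)
        dout <- dout + r$dx
        grads[i] <- list(r$grads)
      }
      list(dx = dout, grads = list(units = grads))
    },
    stop("unknown layer type: ", layer$type)
  )
}

## ---- parameter bookkeeping and Adam ----------------------------------------

leaf_param_names <- function(layer) {
  switch(layer$type,
         conv = c("W", "b"), linear = c("W", "b"),
         bn = c("gamma", "beta"), character(0))
}

child_fields <- function(layer) {
  switch(layer$type,
         sequential = "layers", dense_block = "units",
         residual = c("body", "shortcut"), character(0))
}

#' Total trainable parameter count of a layer graph.
#' @keywords internal
nn_param_count <- function(layer) {
  if (is.null(layer)) return(0)
  n <- sum(vapply(leaf_param_names(layer),
                  function(p) length(layer[[p]]), numeric(1)))
  for (f in child_fields(layer)) {
    ch <- layer[[f]]
    if (is.null(ch)) next
    if (inherits(ch, "dn_layer")) n <- n + nn_param_count(ch)
    else n <- n + sum(vapply(ch, nn_param_count, numeric(1)))
  }
  n
}

#' Flatten a gradient structure into one numeric vector (tests/diagnostics).
#' @keywords internal
nn_grads_flat <- function(grads) {
  if (is.null(grads)) return(numeric(0))
  if (is.numeric(grads)) return(as.numeric(grads))
  unlist(lapply(grads, nn_grads_flat), use.names = FALSE)
}

#' Adam state skeleton mirroring a layer graph.
#' @keywords internal
adam_init <- function(layer) {
  if (is.null(layer)) return(NULL)
  st <- list()
  for (p in leaf_param_names(layer)) {
    z <- layer[[p]]; z[] <- 0
    st[[p]] <- list(m = z, v = z)
  }
  for (f in child_fields(layer)) {
    ch <- layer[[f]]
    if (is.null(ch)) { st[[f]] <- NULL; next }
    st[[f]] <- if (inherits(ch, "dn_layer")) adam_init(ch)
               else lapply(ch, adam_init)
  }
  st
}

#' One Adam update; returns `list(layer, state)`.
#' @keywords internal
adam_step <- function(layer, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(layer) || is.null(grads)) return(list(layer = layer, state = state))
  for (p in leaf_param_names(layer)) {
    g <- grads[[p]]
    if (is.null(g)) next
    state[[p]]$m <- beta1 * state[[p]]$m + (1 - beta1) * g
    state[[p]]$v <- beta2 * state[[p]]$v + (1 - beta2) * g * g
    mhat <- state[[p]]$m / (1 - beta1^t)
    vhat <- state[[p]]$v / (1 - beta2^t)
    layer[[p]] <- layer[[p]] - lr * mhat / (sqrt(vhat) + eps)
  }
  for (f in child_fields(layer)) {
    ch <- layer[[f]]
    if (is.null(ch)) next
    gf <- switch(layer$type,
                 sequential = grads$layers, dense_block = grads$units,
                 residual = grads[[f]])
    if (inherits(ch, "dn_layer")) {
      r <- adam_step(ch, gf, state[[f]], lr, t, beta1, beta2, eps)
      layer[[f]] <- r$layer; state[[f]] <- r$state
    } else {
      for (i in seq_along(ch)) {
        r <- adam_step(ch[[i]], gf[[i]], state[[f]][[i]], lr, t,
                       beta1, beta2, eps)
        layer[[f]][[i]] <- r$layer; state[[f]][[i]] <- r$state
      }
    }
  }
  list(layer = layer, state = state)
}
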