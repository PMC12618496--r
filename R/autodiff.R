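# Minimal reverse-mode automatic differentiation over dense arrays.
#
# Values are numeric vectors, matrices, or 3D arrays (batch x tokens x dim).
# A node is an environment holding $value, $grad, $parents and $backfn; nodes
# are pushed onto a tape in creation order, so reverse traversal of the tape
# is a valid topological order for backpropagation. Parameters are leaf nodes
# that persist across tapes; their $grad accumulates until ad_zero_grad().

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

#' Open a fresh autodiff tape
#'
#' Required around manual calls to [forward()]; [predict_params()] and the
#' training loops manage tapes internally.
#' @return the tape (invisibly).
#' @export
ad_begin <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$k <- 0L
  .ad$tape <- tape
  invisible(tape)
}

#' Close the active autodiff tape
#' @export
ad_end <- function() {
  .ad$tape <- NULL
  invisible(NULL)
}

ad_push <- function(node) {
  tape <- .ad$tape
  if (is.null(tape)) stop("no active autodiff tape; call ad_begin() first")
  k <- tape$k + 1L
  if (k > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[k]] <- node
  tape$k <- k
  node
}

# leaf constructors ----------------------------------------------------------

ad_param <- function(value, name = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$leaf <- TRUE
  n$param <- TRUE
  n$name <- name
  n
}

ad_const <- function(value) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$leaf <- TRUE
  n$param <- FALSE
  n
}

ad_input <- function(value) {
  # a leaf whose gradient we want (e.g. for gradient-times-input relevance)
  n <- ad_const(value)
  n$param <- TRUE
  n
}

ad_new <- function(value, parents, backfn) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$leaf <- FALSE
  n$parents <- parents
  n$backfn <- backfn
  ad_push(n)
}

ad_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

#' @noRd
ad_backward <- function(root, seed_grad = NULL) {
  tape <- .ad$tape
  if (is.null(tape)) stop("no active tape")
  if (is.null(seed_grad)) {
    if (length(root$value) != 1L) stop("seed gradient required for non-scalar root")
    seed_grad <- 1
  }
  root$grad <- seed_grad
  for (i in seq.int(tape$k, 1L)) {
    n <- tape$nodes[[i]]
    if (is.null(n$grad) || n$leaf) next
    gs <- n$backfn(n$grad, n)
    ps <- n$parents
    for (j in seq_along(ps)) {
      if (!is.null(gs[[j]])) ad_accum(ps[[j]], gs[[j]])
    }
  }
  invisible(NULL)
}

# shape helpers ---------------------------------------------------------------

flat2 <- function(x) {
  # view a 3D array B x T x d as (B*T) x d; inverse is unflat2
  d <- dim(x)
  if (length(d) == 2L) return(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}

unflat2 <- function(x, d3) {
  dim(x) <- d3
  x
}

# elementwise / arithmetic ops ------------------------------------------------

ad_add <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  if (identical(da, db) || (is.null(da) && is.null(db) && length(a$value) == length(b$value))) {
    ad_new(a$value + b$value, list(a, b), function(g, n) list(g, g))
  } else if (length(da) == 2L && is.null(db) && length(b$value) == da[2]) {
    # matrix + row-vector bias
    ad_new(sweep(a$value, 2L, b$value, "+"), list(a, b),
           function(g, n) list(g, colSums(g)))
  } else if (length(da) == 3L && length(db) == 2L &&
             all(da[2:3] == db)) {
    # (B x T x d) + (T x d), broadcast over batch
    B <- da[1]
    out <- a$value + rep(b$value, each = B)
    ad_new(out, list(a, b), function(g, n) {
      gb <- apply(g, c(2, 3), sum)
      list(g, gb)
    })
  } else stop("ad_add: incompatible shapes")
}

ad_sub <- function(a, b) ad_new(a$value - b$value, list(a, b), function(g, n) list(g, -g))

ad_mul <- function(a, b) {
  stopifnot(identical(dim(a$value), dim(b$value)) || length(a$value) == length(b$value))
  ad_new(a$value * b$value, list(a, b),
         function(g, n) list(g * b$value, g * a$value))
}

ad_scale <- function(a, s) ad_new(a$value * s, list(a), function(g, n) list(g * s))

ad_matmul <- function(a, b) {
  ad_new(a$value %*% b$value, list(a, b),
         function(g, n) list(g %*% t(b$value), crossprod(a$value, g)))
}

ad_reshape <- function(a, dims) {
  old <- dim(a$value)
  v <- a$value
  dim(v) <- dims
  ad_new(v, list(a), function(g, n) { dim(g) <- old; list(g) })
}

# x: 2D (N x din) or 3D (B x T x din); W: din x dout; b: dout or NULL
ad_linear <- function(x, W, b = NULL) {
  d <- dim(x$value)
  if (length(d) == 3L) {
    x2 <- ad_reshape(x, c(d[1] * d[2], d[3]))
    out <- ad_matmul(x2, W)
    if (!is.null(b)) out <- ad_add(out, b)
    ad_reshape(out, c(d[1], d[2], ncol(W$value)))
  } else {
    out <- ad_matmul(x, W)
    if (!is.null(b)) out <- ad_add(out, b)
    out
  }
}

ad_relu <- function(a) {
  m <- a$value > 0
  ad_new(a$value * m, list(a), function(g, n) list(g * m))
}

ad_gelu <- function(a) {
  x <- a$value
  ph <- stats::pnorm(x)
  ad_new(x * ph, list(a), function(g, n) list(g * (ph + x * stats::dnorm(x))))
}

ad_tanh <- function(a) {
  y <- tanh(a$value)
  ad_new(y, list(a), function(g, n) list(g * (1 - y^2)))
}

ad_sigmoid <- function(a) {
  y <- stats::plogis(a$value)
  ad_new(y, list(a), function(g, n) list(g * y * (1 - y)))
}

ad_exp <- function(a) {
  y <- exp(a$value)
  ad_new(y, list(a), function(g, n) list(g * y))
}

ad_log <- function(a) ad_new(log(a$value), list(a), function(g, n) list(g / a$value))

# softplus_beta(x) = log(1 + exp(beta x)) / beta, numerically stable
ad_softplus <- function(a, beta = 1) {
  x <- a$value * beta
  y <- ifelse(x > 30, x, log1p(exp(pmin(x, 30)))) / beta
  if (!is.null(dim(a$value))) dim(y) <- dim(a$value)
  s <- stats::plogis(x)
  ad_new(y, list(a), function(g, n) list(g * s))
}

ad_sum <- function(a) {
  ad_new(sum(a$value), list(a), function(g, n) list(a$value * 0 + g))
}

ad_mean <- function(a) ad_scale(ad_sum(a), 1 / length(a$value))

ad_dot <- function(a, b) ad_sum(ad_mul(a, b))

# layer normalization over the last dimension --------------------------------

ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x$value)
  x2 <- if (length(d) == 3L) ad_reshape(x, c(d[1] * d[2], d[3])) else x
  v <- x2$value
  mu <- rowMeans(v)
  xc <- v - mu
  va <- rowMeans(xc^2)
  sdv <- sqrt(va + eps)
  xhat <- xc / sdv
  gam <- gamma$value
  out <- sweep(xhat, 2L, gam, "*")
  out <- sweep(out, 2L, beta$value, "+")
  node <- ad_new(out, list(x2, gamma, beta), function(g, n) {
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    gy <- sweep(g, 2L, gam, "*")
    m1 <- rowMeans(gy)
    m2 <- rowMeans(gy * xhat)
    dx <- (gy - m1 - xhat * m2) / sdv
    list(dx, dgamma, dbeta)
  })
  if (length(d) == 3L) ad_reshape(node, d) else node
}

# batched masked multi-head attention -----------------------------------------
# q: B x Tq x d, k/v: B x Tk x d, mask: B x Tk logical (TRUE = attendable).
# Composite op with hand-derived backward; stores attention weights in $attn
# (list over batch of Tq x Tk matrices, averaged over heads).

ad_mha <- function(q, k, v, mask, n_heads) {
  dq <- dim(q$value); dk <- dim(k$value)
  B <- dq[1]; Tq <- dq[2]; Tk <- dk[2]; d <- dq[3]
  stopifnot(d %% n_heads == 0L)
  dh <- d %/% n_heads
  sc <- 1 / sqrt(dh)
  qv <- q$value; kv <- k$value; vv <- v$value
  out <- array(0, dim = c(B, Tq, d))
  A <- vector("list", B)        # per subject: n_heads x Tq x Tk
  attn_mean <- vector("list", B)
  for (b in seq_len(B)) {
    mb <- mask[b, ]
    if (!any(mb)) stop("no observed modality: all tokens masked for subject ", b)
    Ab <- array(0, dim = c(n_heads, Tq, Tk))
    acc <- matrix(0, Tq, Tk)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      Qh <- matrix(qv[b, , cols], Tq, dh)
      Kh <- matrix(kv[b, , cols], Tk, dh)
      Vh <- matrix(vv[b, , cols], Tk, dh)
      S <- tcrossprod(Qh, Kh) * sc
      S[, !mb] <- -1e9
      S <- S - apply(S, 1L, max)
      E <- exp(S)
      W <- E / rowSums(E)
      W[, !mb] <- 0       # exact zero: outputs independent of masked values
      W <- W / rowSums(W)
      Ab[h, , ] <- W
      out[b, , cols] <- W %*% Vh
      acc <- acc + W
    }
    A[[b]] <- Ab
    attn_mean[[b]] <- acc / n_heads
  }
  node <- ad_new(out, list(q, k, v), function(g, n) {
    dqv <- array(0, dim = dq); dkv <- array(0, dim = dk); dvv <- array(0, dim = dk)
    for (b in seq_len(B)) {
      for (h in seq_len(n_heads)) {
        cols <- ((h - 1) * dh + 1):(h * dh)
        W <- matrix(A[[b]][h, , ], Tq, Tk)
        Gh <- matrix(g[b, , cols], Tq, dh)
        Vh <- matrix(vv[b, , cols], Tk, dh)
        Kh <- matrix(kv[b, , cols], Tk, dh)
        Qh <- matrix(qv[b, , cols], Tq, dh)
        dW <- tcrossprod(Gh, Vh)                    # Tq x Tk
        dvv[b, , cols] <- dvv[b, , cols] + crossprod(W, Gh)
        dS <- W * (dW - rowSums(dW * W))            # softmax backward
        dqv[b, , cols] <- dqv[b, , cols] + (dS %*% Kh) * sc
        dkv[b, , cols] <- dkv[b, , cols] + (crossprod(dS, Qh)) * sc
      }
    }
    list(dqv, dkv, dvv)
  })
  node$attn <- attn_mean
  node
}

# token-axis utilities ---------------------------------------------------------

ad_cat_tokens <- function(nodes) {
  dims <- lapply(nodes, function(n) dim(n$value))
  B <- dims[[1]][1]; d <- dims[[1]][3]
  Ts <- vapply(dims, function(x) x[2], 0)
  out <- array(0, dim = c(B, sum(Ts), d))
  at <- 0L
  for (i in seq_along(nodes)) {
    out[, (at + 1):(at + Ts[i]), ] <- nodes[[i]]$value
    at <- at + Ts[i]
  }
  ad_new(out, nodes, function(g, n) {
    gs <- vector("list", length(nodes)); at <- 0L
    for (i in seq_along(nodes)) {
      gi <- g[, (at + 1):(at + Ts[i]), , drop = FALSE]
      dim(gi) <- c(B, Ts[i], d)
      gs[[i]] <- gi
      at <- at + Ts[i]
    }
    gs
  })
}

ad_take_token <- function(x, t_idx) {
  d <- dim(x$value)
  out <- x$value[, t_idx, , drop = FALSE]
  dim(out) <- c(d[1], length(t_idx), d[3])
  ad_new(out, list(x), function(g, n) {
    gx <- array(0, dim = d)
    gx[, t_idx, ] <- g
    list(gx)
  })
}

ad_pool_tokens <- function(x) {
  # mean over the token axis: B x T x d -> B x d
  d <- dim(x$value)
  out <- apply(x$value, c(1, 3), mean)
  dim(out) <- c(d[1], d[3])
  ad_new(out, list(x), function(g, n) {
    gx <- aperm(array(g / d[2], dim = c(d[1], d[3], d[2])), c(1, 3, 2))
    list(gx)
  })
}

# Adam optimizer ---------------------------------------------------------------

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$b1 <- beta1; st$b2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(params, function(p) p$value * 0)
  st$v <- lapply(params, function(p) p$value * 0)
  st
}

adam_step <- function(st) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$b1^st$t
  bc2 <- 1 - st$b2^st$t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[i]] <- st$b1 * st$m[[i]] + (1 - st$b1) * g
    st$v[[i]] <- st$b2 * st$v[[i]] + (1 - st$b2) * g^2
    p$value <- p$value - st$lr * (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + st$eps)
  }
  invisible(NULL)
}
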