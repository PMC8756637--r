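# Reverse-mode automatic differentiation on dense R matrices.
#
# A "node" is an environment holding `value` (a matrix), an accumulated
# `grad`, and a `backward` closure that pushes the node's gradient into its
# parents. Operations executed while a tape is active append their node to
# the tape; ad_backward() then sweeps the tape in reverse. Values are plain
# double matrices so every matmul goes through BLAS.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

ad_tape_start <- function() {
  .ad$tape <- vector("list", 1024L)
  .ad$tape_n <- 0L
  invisible(NULL)
}

ad_tape_stop <- function() {
  .ad$tape <- NULL
  .ad$tape_n <- 0L
  invisible(NULL)
}

ad_record <- function(node) {
  if (is.null(.ad$tape)) return(invisible(node))
  n <- .ad$tape_n + 1L
  if (n > length(.ad$tape)) .ad$tape <- c(.ad$tape, vector("list", length(.ad$tape)))
  .ad$tape[[n]] <- node
  .ad$tape_n <- n
  invisible(node)
}

ad_node <- function(value, backward = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$backward <- backward
  class(e) <- "ad_node"
  if (!is.null(backward)) ad_record(e)
  e
}

#' @keywords internal
is_node <- function(x) is.environment(x)

val <- function(x) if (is.environment(x)) x$value else x

# Create a trainable parameter (never freed between tape sweeps).
ad_param <- function(value) {
  if (!is.matrix(value)) value <- matrix(value, nrow = 1L)
  ad_node(value, backward = NULL)
}

acc_grad <- function(x, g) {
  if (!is_node(x)) return(invisible(NULL))
  x$grad <- if (is.null(x$grad)) g else x$grad + g
  invisible(NULL)
}

ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Run the reverse sweep from a scalar loss node.
ad_backward <- function(loss) {
  stopifnot(is_node(loss), length(loss$value) == 1L)
  if (is.null(.ad$tape)) stop("no active tape: call ad_tape_start() before the forward pass")
  loss$grad <- matrix(1, 1L, 1L)
  n <- .ad$tape_n
  for (i in rev(seq_len(n))) {
    node <- .ad$tape[[i]]
    if (!is.null(node$grad) && !is.null(node$backward)) node$backward(node$grad)
  }
  invisible(NULL)
}

# --- shape helpers ----------------------------------------------------------

# Reduce a full-shape gradient `g` back to the shape of operand `x`
# (matrix, 1 x m row vector, n x 1 column vector, or scalar).
reduce_to_shape <- function(g, vx) {
  if (length(vx) == 1L) return(matrix(sum(g), 1L, 1L))
  if (nrow(vx) == 1L && nrow(g) > 1L) return(matrix(colSums(g), 1L))
  if (ncol(vx) == 1L && ncol(g) > 1L) return(matrix(rowSums(g), ncol = 1L))
  g
}

# Broadcast binary application: supports equal shapes, row vectors (1 x m),
# column vectors (n x 1) and scalars on either side.
bcast <- function(a, b, f) {
  if (length(a) == 1L && !identical(dim(a), dim(b))) return(f(as.vector(a), b))
  if (length(b) == 1L && !identical(dim(a), dim(b))) return(f(a, as.vector(b)))
  if (identical(dim(a), dim(b))) return(f(a, b))
  if (nrow(b) == 1L && ncol(b) == ncol(a)) return(f(a, rep(b, each = nrow(a))))
  if (nrow(a) == 1L && ncol(a) == ncol(b)) return(f(rep(a, each = nrow(b)), b))
  if (ncol(b) == 1L && nrow(b) == nrow(a)) return(f(a, as.vector(b)))
  if (ncol(a) == 1L && nrow(a) == nrow(b)) return(f(as.vector(a), b))
  stop("incompatible shapes: ", paste(dim(a), collapse = "x"), " vs ",
       paste(dim(b), collapse = "x"))
}

full_dim <- function(va, vb) {
  if (length(va) == 1L) return(vb)
  if (length(vb) == 1L) return(va)
  if (length(va) >= length(vb)) va else vb
}

# --- elementwise arithmetic -------------------------------------------------

ad_add <- function(a, b) {
  va <- val(a); vb <- val(b)
  out <- bcast(va, vb, `+`)
  if (is.null(dim(out))) out <- matrix(out, nrow(full_dim(va, vb)), ncol(full_dim(va, vb)))
  ad_node(out, backward = function(g) {
    acc_grad(a, reduce_to_shape(g, va))
    acc_grad(b, reduce_to_shape(g, vb))
  })
}

ad_sub <- function(a, b) {
  va <- val(a); vb <- val(b)
  out <- bcast(va, vb, `-`)
  if (is.null(dim(out))) out <- matrix(out, nrow(full_dim(va, vb)), ncol(full_dim(va, vb)))
  ad_node(out, backward = function(g) {
    acc_grad(a, reduce_to_shape(g, va))
    acc_grad(b, reduce_to_shape(-g, vb))
  })
}

ad_mul <- function(a, b) {
  va <- val(a); vb <- val(b)
  out <- bcast(va, vb, `*`)
  if (is.null(dim(out))) out <- matrix(out, nrow(full_dim(va, vb)), ncol(full_dim(va, vb)))
  ad_node(out, backward = function(g) {
    acc_grad(a, reduce_to_shape(bcast(g, vb, `*`), va))
    acc_grad(b, reduce_to_shape(bcast(g, va, `*`), vb))
  })
}

ad_div <- function(a, b) {
  va <- val(a); vb <- val(b)
  out <- bcast(va, vb, `/`)
  if (is.null(dim(out))) out <- matrix(out, nrow(full_dim(va, vb)), ncol(full_dim(va, vb)))
  ad_node(out, backward = function(g) {
    acc_grad(a, reduce_to_shape(bcast(g, vb, `/`), va))
    acc_grad(b, reduce_to_shape(bcast(bcast(-g, out, `*`), vb, `/`), vb))
  })
}

ad_scale <- function(a, k) { # k: plain scalar constant
  va <- val(a)
  ad_node(va * k, backward = function(g) acc_grad(a, g * k))
}

ad_neg <- function(a) ad_scale(a, -1)

# --- linear algebra ---------------------------------------------------------

ad_matmul <- function(a, b) {
  va <- val(a); vb <- val(b)
  ad_node(va %*% vb, backward = function(g) {
    acc_grad(a, g %*% t(vb))
    acc_grad(b, crossprod(va, g))
  })
}

# x %*% W + b with b a 1 x m bias row.
ad_linear <- function(x, W, b) {
  vx <- val(x); vW <- val(W); vb <- val(b)
  out <- vx %*% vW
  out <- out + rep(vb, each = nrow(out))
  ad_node(out, backward = function(g) {
    acc_grad(x, g %*% t(vW))
    acc_grad(W, crossprod(vx, g))
    acc_grad(b, matrix(colSums(g), 1L))
  })
}

ad_cbind <- function(a, b) {
  va <- val(a); vb <- val(b)
  na <- ncol(va)
  ad_node(cbind(va, vb), backward = function(g) {
    acc_grad(a, g[, seq_len(na), drop = FALSE])
    acc_grad(b, g[, -seq_len(na), drop = FALSE])
  })
}

# --- reductions -------------------------------------------------------------

ad_sum <- function(a) {
  va <- val(a)
  ad_node(matrix(sum(va), 1L, 1L), backward = function(g) {
    acc_grad(a, matrix(g[1L], nrow(va), ncol(va)))
  })
}

ad_rowsums <- function(a) {
  va <- val(a)
  ad_node(matrix(rowSums(va), ncol = 1L), backward = function(g) {
    acc_grad(a, matrix(as.vector(g), nrow(va), ncol(va)))
  })
}

ad_mean <- function(a) ad_scale(ad_sum(a), 1 / length(val(a)))

# --- nonlinearities ---------------------------------------------------------

ad_relu <- function(a) {
  va <- val(a)
  mask <- va > 0
  ad_node(va * mask, backward = function(g) acc_grad(a, g * mask))
}

# log(1 + exp(x)) computed stably; derivative is sigmoid(x).
softplus_mat <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
sigmoid_mat <- function(x) 1 / (1 + exp(-x))

ad_softplus <- function(a) {
  va <- val(a)
  ad_node(softplus_mat(va), backward = function(g) acc_grad(a, g * sigmoid_mat(va)))
}

ad_sigmoid <- function(a) {
  va <- val(a)
  s <- sigmoid_mat(va)
  ad_node(s, backward = function(g) acc_grad(a, g * s * (1 - s)))
}

# Hard clamp with straight-through gradient inside the interval.
ad_clamp <- function(a, lo, hi) {
  va <- val(a)
  inside <- va >= lo & va <= hi
  ad_node(pmin(pmax(va, lo), hi),
          backward = function(g) acc_grad(a, g * inside))
}

ad_exp <- function(a) {
  va <- val(a)
  ev <- exp(va)
  ad_node(ev, backward = function(g) acc_grad(a, g * ev))
}

ad_log <- function(a) {
  va <- val(a)
  ad_node(log(va), backward = function(g) acc_grad(a, g / va))
}

ad_square <- function(a) {
  va <- val(a)
  ad_node(va * va, backward = function(g) acc_grad(a, 2 * g * va))
}

row_max <- function(x) x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]

ad_logsumexp_rows <- function(a) {
  va <- val(a)
  m <- row_max(va)
  e <- exp(va - m)
  s <- rowSums(e)
  ad_node(matrix(m + log(s), ncol = 1L), backward = function(g) {
    acc_grad(a, as.vector(g) * (e / s))
  })
}

ad_softmax_rows <- function(a) {
  va <- val(a)
  m <- va - row_max(va)
  e <- exp(m)
  s <- e / rowSums(e)
  ad_node(s, backward = function(g) {
    dot <- rowSums(g * s)
    acc_grad(a, s * (g - dot))
  })
}

# --- normalisation layers ---------------------------------------------------

# Layer normalisation over features (per row), with learned gain/offset rows.
ad_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  va <- val(a); vg <- val(gamma); vb <- val(beta)
  m <- ncol(va)
  mu <- rowMeans(va)
  xc <- va - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- xhat * rep(vg, each = nrow(va)) + rep(vb, each = nrow(va))
  ad_node(out, backward = function(g) {
    dxhat <- g * rep(vg, each = nrow(va))
    acc_grad(gamma, matrix(colSums(g * xhat), 1L))
    acc_grad(beta, matrix(colSums(g), 1L))
    da <- (inv / m) * (m * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
    acc_grad(a, da)
  })
}

# Batch-norm state: environment holding running_mean / running_var rows.
bn_state <- function(m) {
  e <- new.env(parent = emptyenv())
  e$running_mean <- matrix(0, 1L, m)
  e$running_var <- matrix(1, 1L, m)
  e
}

# Batch normalisation over cells (per column). In training mode uses batch
# statistics and updates the running estimates; in eval mode each row is
# normalised independently of the rest of the batch.
ad_batchnorm <- function(a, gamma, beta, state, training = TRUE,
                         momentum = 0.1, eps = 1e-5) {
  va <- val(a); vg <- val(gamma); vb <- val(beta)
  n <- nrow(va)
  if (training && n > 1L) {
    mu <- colMeans(va)
    xc <- va - rep(mu, each = n)
    v <- colMeans(xc * xc)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * matrix(mu, 1L)
    state$running_var <- (1 - momentum) * state$running_var + momentum * matrix(v, 1L)
    inv <- 1 / sqrt(v + eps)
    xhat <- xc * rep(inv, each = n)
    out <- xhat * rep(vg, each = n) + rep(vb, each = n)
    ad_node(out, backward = function(g) {
      dxhat <- g * rep(vg, each = n)
      acc_grad(gamma, matrix(colSums(g * xhat), 1L))
      acc_grad(beta, matrix(colSums(g), 1L))
      cs <- colSums(dxhat)
      cx <- colSums(dxhat * xhat)
      da <- rep(inv / n, each = n) *
        (n * dxhat - rep(cs, each = n) - xhat * rep(cx, each = n))
      acc_grad(a, da)
    })
  } else {
    inv <- 1 / sqrt(state$running_var + eps)
    xhat <- (va - rep(state$running_mean, each = n)) * rep(inv, each = n)
    out <- xhat * rep(vg, each = n) + rep(vb, each = n)
    ad_node(out, backward = function(g) {
      acc_grad(gamma, matrix(colSums(g * xhat), 1L))
      acc_grad(beta, matrix(colSums(g), 1L))
      acc_grad(a, g * rep(vg * inv, each = n))
    })
  }
}

# --- multi-head self-attention ----------------------------------------------

# The width-wide activation of each cell is treated as a sequence of
# L = width / head_dim tokens of head_dim units. Q, K, V for every head are
# head_dim x head_dim maps of the tokens (stored column-blocked in Wq/Wk/Wv:
# head_dim x (head_dim * n_heads)); scaled dot-product attention runs over
# the tokens within each cell, heads are concatenated and projected by Wo
# ((head_dim * n_heads) x head_dim) back to token width.
#
# Implementation note: per-cell L x L attention is batched over cells with
# "wide" layouts — X_wide[i, (t-1)*hd + d] = token t, unit d of cell i — so
# the inner work is elementwise products and n x (L*hd) x L matmuls through
# 0/1 block-sum matrices, never a per-cell loop.
ad_mhsa <- function(a, Wq, Wk, Wv, Wo, n_heads, head_dim) {
  va <- val(a)
  n <- nrow(va); width <- ncol(va)
  hd <- head_dim
  L <- width %/% hd
  stopifnot(L * hd == width)
  vWq <- val(Wq); vWk <- val(Wk); vWv <- val(Wv); vWo <- val(Wo)
  sc <- 1 / sqrt(hd)
  # token rows: row (t-1)*n + i of Xr is cell i, token t
  Xr <- matrix(0, n * L, hd)
  for (t in seq_len(L)) Xr[(t - 1L) * n + seq_len(n), ] <- va[, (t - 1L) * hd + seq_len(hd)]
  Qall <- Xr %*% vWq; Kall <- Xr %*% vWk; Vall <- Xr %*% vWv
  tok <- function(m, t, cols) m[(t - 1L) * n + seq_len(n), cols, drop = FALSE]
  # block-sum matrices: Bsum collapses (s,d) -> s; Dsum collapses (s,d) -> d
  Bsum <- matrix(0, L * hd, L)
  Bsum[cbind(seq_len(L * hd), rep(seq_len(L), each = hd))] <- 1
  Dsum <- matrix(0, L * hd, hd)
  Dsum[cbind(seq_len(L * hd), rep(seq_len(hd), L))] <- 1
  rep_d <- rep(seq_len(hd), L)       # (s,d) column <- d
  rep_s <- rep(seq_len(L), each = hd) # (s,d) column <- s

  A_store <- vector("list", n_heads)
  Kw_store <- vector("list", n_heads)
  Vw_store <- vector("list", n_heads)
  Concat <- matrix(0, n * L, hd * n_heads)
  for (h in seq_len(n_heads)) {
    cols <- (h - 1L) * hd + seq_len(hd)
    # wide layouts: n x (L*hd)
    Kw <- matrix(0, n, L * hd); Vw <- Kw
    for (s in seq_len(L)) {
      Kw[, (s - 1L) * hd + seq_len(hd)] <- tok(Kall, s, cols)
      Vw[, (s - 1L) * hd + seq_len(hd)] <- tok(Vall, s, cols)
    }
    Kw_store[[h]] <- Kw; Vw_store[[h]] <- Vw
    A_h <- vector("list", L)
    for (t in seq_len(L)) {
      Qt <- tok(Qall, t, cols)
      St <- (Qt[, rep_d, drop = FALSE] * Kw) %*% Bsum * sc
      St <- exp(St - row_max(St))
      At <- St / rowSums(St)
      A_h[[t]] <- At
      Concat[(t - 1L) * n + seq_len(n), cols] <-
        (At[, rep_s, drop = FALSE] * Vw) %*% Dsum
    }
    A_store[[h]] <- A_h
  }
  Yr <- Concat %*% vWo
  out <- matrix(0, n, width)
  for (t in seq_len(L)) out[, (t - 1L) * hd + seq_len(hd)] <- Yr[(t - 1L) * n + seq_len(n), ]

  ad_node(out, backward = function(g) {
    dYr <- matrix(0, n * L, hd)
    for (t in seq_len(L)) dYr[(t - 1L) * n + seq_len(n), ] <- g[, (t - 1L) * hd + seq_len(hd)]
    acc_grad(Wo, crossprod(Concat, dYr))
    dConcat <- dYr %*% t(vWo)
    dQall <- matrix(0, n * L, hd * n_heads)
    dKall <- dQall; dVall <- dQall
    for (h in seq_len(n_heads)) {
      cols <- (h - 1L) * hd + seq_len(hd)
      Kw <- Kw_store[[h]]; Vw <- Vw_store[[h]]
      dKw <- Kw * 0; dVw <- Kw * 0
      for (t in seq_len(L)) {
        At <- A_store[[h]][[t]]
        dOt <- dConcat[(t - 1L) * n + seq_len(n), cols, drop = FALSE]
        dOt_rep <- dOt[, rep_d, drop = FALSE]
        dAt <- (dOt_rep * Vw) %*% Bsum
        dVw <- dVw + At[, rep_s, drop = FALSE] * dOt_rep
        dSt <- At * (dAt - rowSums(At * dAt)) * sc
        dSt_rep <- dSt[, rep_s, drop = FALSE]
        Qt <- tok(Qall, t, cols)
        dQall[(t - 1L) * n + seq_len(n), cols] <- (dSt_rep * Kw) %*% Dsum
        dKw <- dKw + dSt_rep * Qt[, rep_d, drop = FALSE]
      }
      for (s in seq_len(L)) {
        dKall[(s - 1L) * n + seq_len(n), cols] <- dKw[, (s - 1L) * hd + seq_len(hd)]
        dVall[(s - 1L) * n + seq_len(n), cols] <- dVw[, (s - 1L) * hd + seq_len(hd)]
      }
    }
    acc_grad(Wq, crossprod(Xr, dQall))
    acc_grad(Wk, crossprod(Xr, dKall))
    acc_grad(Wv, crossprod(Xr, dVall))
    dXr <- dQall %*% t(vWq) + dKall %*% t(vWk) + dVall %*% t(vWv)
    da <- matrix(0, n, width)
    for (t in seq_len(L)) da[, (t - 1L) * hd + seq_len(hd)] <- dXr[(t - 1L) * n + seq_len(n), ]
    acc_grad(a, da)
  })
}

# --- likelihood terms (fused, with analytic partials) -----------------------

# Elementwise negative log pmf of the Gamma(shape alpha, rate beta)-Poisson
# marginal (negative binomial) at integer counts x (a constant matrix).
ad_nb_nll <- function(x, alpha, beta, lgamma_x1 = NULL) {
  valpha <- val(alpha); vbeta <- val(beta)
  if (is.null(lgamma_x1)) lgamma_x1 <- lgamma(x + 1)
  lp <- lgamma(x + valpha) - lgamma_x1 - lgamma(valpha) +
    valpha * log(vbeta / (1 + vbeta)) - x * log1p(vbeta)
  ad_node(-lp, backward = function(g) {
    dal <- digamma(x + valpha) - digamma(valpha) + log(vbeta) - log1p(vbeta)
    dbe <- valpha / vbeta - (valpha + x) / (1 + vbeta)
    acc_grad(alpha, -g * dal)
    acc_grad(beta, -g * dbe)
  })
}

# Summed variant: returns the scalar total negative log-likelihood, so the
# backward pass never materialises a full-size upstream-gradient matrix.
ad_nb_nll_sum <- function(x, alpha, beta, lgamma_x1 = NULL) {
  valpha <- val(alpha); vbeta <- val(beta)
  if (is.null(lgamma_x1)) lgamma_x1 <- lgamma(x + 1)
  lp <- lgamma(x + valpha) - lgamma_x1 - lgamma(valpha) +
    valpha * log(vbeta / (1 + vbeta)) - x * log1p(vbeta)
  ad_node(matrix(-sum(lp), 1L, 1L), backward = function(g) {
    gs <- g[1L]
    acc_grad(alpha, -gs * (digamma(x + valpha) - digamma(valpha) +
                             log(vbeta) - log1p(vbeta)))
    acc_grad(beta, -gs * (valpha / vbeta - (valpha + x) / (1 + vbeta)))
  })
}

# Elementwise negative log pmf of the zero-inflated Poisson at counts y:
# tau is the probability of NOT being a structural zero.
ad_zip_nll <- function(y, mu, tau, lgamma_y1 = NULL, zero_idx = NULL) {
  vmu <- val(mu); vtau <- val(tau)
  if (is.null(zero_idx)) zero_idx <- which(y == 0)
  if (is.null(lgamma_y1)) lgamma_y1 <- lgamma(y + 1)
  emu0 <- exp(-vmu[zero_idx])
  tau0 <- vtau[zero_idx]
  p0 <- (1 - tau0) + tau0 * emu0
  lp <- log(vtau) + y * log(vmu) - vmu - lgamma_y1
  lp[zero_idx] <- log(p0)
  ad_node(-lp, backward = function(g) {
    dmu <- y / vmu - 1
    dmu[zero_idx] <- -tau0 * emu0 / p0
    dtau <- 1 / vtau
    dtau[zero_idx] <- (emu0 - 1) / p0
    acc_grad(mu, -g * dmu)
    acc_grad(tau, -g * dtau)
  })
}

# Summed variant of the ZIP negative log-likelihood (see ad_nb_nll_sum).
ad_zip_nll_sum <- function(y, mu, tau, lgamma_y1 = NULL, zero_idx = NULL) {
  vmu <- val(mu); vtau <- val(tau)
  if (is.null(zero_idx)) zero_idx <- which(y == 0)
  if (is.null(lgamma_y1)) lgamma_y1 <- lgamma(y + 1)
  emu0 <- exp(-vmu[zero_idx])
  tau0 <- vtau[zero_idx]
  p0 <- (1 - tau0) + tau0 * emu0
  lp <- log(vtau) + y * log(vmu) - vmu - lgamma_y1
  lp[zero_idx] <- log(p0)
  ad_node(matrix(-sum(lp), 1L, 1L), backward = function(g) {
    gs <- g[1L]
    dmu <- y / vmu - 1
    dmu[zero_idx] <- -tau0 * emu0 / p0
    dtau <- 1 / vtau
    dtau[zero_idx] <- (emu0 - 1) / p0
    acc_grad(mu, -gs * dmu)
    acc_grad(tau, -gs * dtau)
  })
}

ad_row <- function(a, i) {
  va <- val(a)
  ad_node(va[i, , drop = FALSE], backward = function(g) {
    z <- matrix(0, nrow(va), ncol(va))
    z[i, ] <- g
    acc_grad(a, z)
  })
}

# --- numeric gradient check helper (used by tests) --------------------------

# Central finite difference of f() (a scalar-valued closure over param values)
# with respect to entries of param p.
ad_numeric_grad <- function(f, p, idx = NULL, h = 1e-5) {
  v <- p$value
  if (is.null(idx)) idx <- seq_along(v)
  g <- numeric(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    orig <- v[i]
    p$value[i] <- orig + h; up <- f()
    p$value[i] <- orig - h; dn <- f()
    p$value[i] <- orig
    g[j] <- (up - dn) / (2 * h)
  }
  g
}
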