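# ---------------------------------------------------------------------------
# Minimal neural-network layer library.
#
# No deep-learning framework ships with the R stack this package targets, so
# the layers needed by the dual-stream classifier are implemented here
# directly: 2D/1D convolution via a cached sparse im2col operator, batch
# normalization, max/global pooling, dense layers, dropout, and a
# bidirectional LSTM with full backpropagation through time.  Every layer is
# an environment exposing forward(x, train) / backward(dout) and its
# parameter list; gradients are verified against finite differences in the
# test suite.
#
# Array layouts: 2D feature maps are (H, W, C, B); 1D maps reuse the same
# machinery with W = 1; feature vectors are (B, D); LSTM sequences are
# (T, B, D).
# ---------------------------------------------------------------------------

nn_param <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- array(0, dim = dim(value) %||% length(value))
  e
}

zero_grads <- function(params) {
  for (p in params) p$grad <- array(0, dim = dim(p$value) %||% length(p$value))
  invisible(NULL)
}

# He-uniform initialization
he_init <- function(rng, dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(rng$runif(prod(dims), -lim, lim), dim = dims)
}

# -- im2col machinery --------------------------------------------------------

# Gather index mapping a zero-padded (Hp*Wp*C)-vector to the stacked patch
# matrix entries (row r of the patch matrix reads padded element jj[r]);
# cached per (input-geometry, kernel) signature.  usj/jj_rank support the
# scatter-add needed by the backward pass.
make_im2col <- function(H, W, C, kh, kw, stride, pad_h, pad_w) {
  Hp <- H + 2 * pad_h; Wp <- W + 2 * pad_w
  Ho <- (Hp - kh) %/% stride + 1L
  Wo <- (Wp - kw) %/% stride + 1L
  kkC <- kh * kw * C
  # element offsets within one patch (ih fastest, then iw, then channel)
  eg <- expand.grid(ih = seq_len(kh), iw = seq_len(kw), c = seq_len(C))
  # patch positions, column-major over (Ho, Wo)
  pg <- expand.grid(oh = seq_len(Ho), ow = seq_len(Wo))
  n_e <- nrow(eg); n_p <- nrow(pg)
  src_h <- rep((pg$oh - 1L) * stride, each = n_e) + rep(eg$ih, n_p)
  src_w <- rep((pg$ow - 1L) * stride, each = n_e) + rep(eg$iw, n_p)
  src_c <- rep(eg$c, n_p)
  jj <- (src_c - 1L) * Hp * Wp + (src_w - 1L) * Hp + src_h
  ord <- order(jj)
  sj <- jj[ord]
  ends <- which(c(sj[-1L] != sj[-length(sj)], TRUE))
  list(jj = jj, ord = ord, ends = ends, usj = sj[ends],
       Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp, kkC = kkC)
}

# scatter-add of the patch-matrix gradient back onto the padded planes,
# using the precomputed sort order (runs of equal target summed via cumsum)
# dcols: (kkC * Ho*Wo, B); returns (Hp*Wp*C, B)
col2im_scatter <- function(dcols, op, C) {
  B <- ncol(dcols)
  ds <- dcols[op$ord, , drop = FALSE]
  acc <- matrix(0, length(op$ends), B)
  for (b in seq_len(B)) {
    cs <- cumsum(ds[, b])[op$ends]
    acc[, b] <- cs - c(0, cs[-length(cs)])
  }
  dxp <- matrix(0, op$Hp * op$Wp * C, B)
  dxp[op$usj, ] <- acc
  dxp
}

pad_maps <- function(x, pad_h, pad_w) {
  if (pad_h == 0 && pad_w == 0) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2 * pad_h, d[2] + 2 * pad_w, d[3], d[4]))
  out[pad_h + seq_len(d[1]), pad_w + seq_len(d[2]), , ] <- x
  out
}

unpad_maps <- function(x, pad_h, pad_w, H, W) {
  if (pad_h == 0 && pad_w == 0) return(x)
  x[pad_h + seq_len(H), pad_w + seq_len(W), , , drop = FALSE]
}

#' @noRd
layer_conv2d <- function(rng, in_ch, out_ch, kh, kw = kh, stride = 1L,
                         pad_h = (kh - 1L) %/% 2L, pad_w = (kw - 1L) %/% 2L,
                         bias = TRUE) {
  l <- new.env()
  fan_in <- kh * kw * in_ch
  l$W <- nn_param(matrix(he_init(rng, c(fan_in * out_ch), fan_in),
                         nrow = fan_in, ncol = out_ch))
  l$b <- if (bias) nn_param(numeric(out_ch)) else NULL
  l$cache_key <- NULL
  l$forward <- function(x, train = TRUE) {
    d <- dim(x)
    key <- paste(d, collapse = "x")
    if (!identical(l$cache_key, key)) {
      l$op <- make_im2col(d[1], d[2], d[3], kh, kw, stride, pad_h, pad_w)
      l$cache_key <- key
    }
    op <- l$op
    B <- d[4]
    xp <- pad_maps(x, pad_h, pad_w)
    dim(xp) <- c(op$Hp * op$Wp * d[3], B)
    cols <- xp[op$jj, , drop = FALSE]           # (kkC * Ho*Wo, B)
    dim(cols) <- c(op$kkC, op$Ho * op$Wo * B)
    out <- crossprod(l$W$value, cols)           # (out_ch, HoWo*B)
    if (!is.null(l$b)) out <- out + l$b$value
    l$x_cols <- cols; l$in_dim <- d
    dim(out) <- c(out_ch, op$Ho, op$Wo, B)
    aperm(out, c(2, 3, 1, 4))
  }
  l$backward <- function(dout) {
    op <- l$op; d <- l$in_dim; B <- d[4]
    dy <- aperm(dout, c(3, 1, 2, 4))
    dim(dy) <- c(out_ch, op$Ho * op$Wo * B)
    l$W$grad <- l$W$grad + tcrossprod(l$x_cols, dy)
    if (!is.null(l$b)) l$b$grad <- l$b$grad + rowSums(dy)
    dcols <- l$W$value %*% dy                   # (kkC, HoWo*B)
    dim(dcols) <- c(op$kkC * op$Ho * op$Wo, B)
    dxp <- col2im_scatter(dcols, op, d[3])
    dim(dxp) <- c(op$Hp, op$Wp, d[3], B)
    unpad_maps(dxp, pad_h, pad_w, d[1], d[2])
  }
  l$params <- function() c(list(l$W), if (!is.null(l$b)) list(l$b))
  l
}

#' @noRd
layer_bn2d <- function(channels, momentum = 0.1, eps = 1e-5) {
  l <- new.env()
  l$gamma <- nn_param(rep(1, channels))
  l$beta <- nn_param(numeric(channels))
  l$run_mean <- numeric(channels)
  l$run_var <- rep(1, channels)
  l$forward <- function(x, train = TRUE) {
    d <- dim(x); l$in_dim <- d
    xm <- aperm(x, c(1, 2, 4, 3)); dim(xm) <- c(prod(d[c(1, 2, 4)]), d[3])
    if (train) {
      mu <- colMeans(xm)
      var_ <- colMeans(xm^2) - mu^2
      l$run_mean <- (1 - momentum) * l$run_mean + momentum * mu
      l$run_var <- (1 - momentum) * l$run_var + momentum * var_
    } else {
      mu <- l$run_mean; var_ <- l$run_var
    }
    inv_sd <- 1 / sqrt(var_ + eps)
    xhat <- sweep(sweep(xm, 2, mu), 2, inv_sd, `*`)
    l$xhat <- xhat; l$inv_sd <- inv_sd; l$train <- train
    y <- sweep(sweep(xhat, 2, l$gamma$value, `*`), 2, l$beta$value, `+`)
    dim(y) <- d[c(1, 2, 4, 3)]
    aperm(y, c(1, 2, 4, 3))
  }
  l$backward <- function(dout) {
    d <- l$in_dim
    dym <- aperm(dout, c(1, 2, 4, 3)); dim(dym) <- c(prod(d[c(1, 2, 4)]), d[3])
    l$gamma$grad <- l$gamma$grad + colSums(dym * l$xhat)
    l$beta$grad <- l$beta$grad + colSums(dym)
    m <- nrow(dym)
    dxhat <- sweep(dym, 2, l$gamma$value, `*`)
    if (l$train) {
      t1 <- sweep(dxhat, 2, colMeans(dxhat))
      t2 <- sweep(l$xhat, 2, colMeans(dxhat * l$xhat), `*`)
      dxm <- sweep(t1 - t2, 2, l$inv_sd, `*`)
    } else {
      dxm <- sweep(dxhat, 2, l$inv_sd, `*`)
    }
    dim(dxm) <- d[c(1, 2, 4, 3)]
    aperm(dxm, c(1, 2, 4, 3))
  }
  l$params <- function() list(l$gamma, l$beta)
  l
}

#' @noRd
layer_relu <- function() {
  l <- new.env()
  l$forward <- function(x, train = TRUE) { l$mask <- x > 0; x * l$mask }
  l$backward <- function(dout) dout * l$mask
  l$params <- function() list()
  l
}

#' @noRd
layer_maxpool2d <- function(kh, kw = kh, stride = kh, pad_h = 0L, pad_w = 0L) {
  l <- new.env()
  l$cache_key <- NULL
  l$forward <- function(x, train = TRUE) {
    d <- dim(x); l$in_dim <- d
    key <- paste(d, collapse = "x")
    if (!identical(l$cache_key, key)) {
      l$op <- make_im2col(d[1], d[2], 1L, kh, kw, stride, pad_h, pad_w)
      l$cache_key <- key
    }
    op <- l$op
    CB <- d[3] * d[4]
    if (pad_h > 0 || pad_w > 0) {   # padded cells must never win a max
      xp <- array(-Inf, dim = c(op$Hp, op$Wp, d[3], d[4]))
      xp[pad_h + seq_len(d[1]), pad_w + seq_len(d[2]), , ] <- x
    } else xp <- x
    dim(xp) <- c(op$Hp * op$Wp, CB)
    n_win <- op$Ho * op$Wo
    gather <- xp[op$jj, , drop = FALSE]
    dim(gather) <- c(op$kkC, n_win * CB)
    amax <- max.col(t(gather), ties.method = "first")
    vmax <- gather[cbind(amax, seq_len(n_win * CB))]
    l$amax <- amax
    out <- vmax
    dim(out) <- c(op$Ho, op$Wo, d[3], d[4])
    out
  }
  l$backward <- function(dout) {
    d <- l$in_dim; op <- l$op
    CB <- d[3] * d[4]
    n_win <- op$Ho * op$Wo
    dv <- as.vector(dout)                      # length n_win * CB
    # row in the gather matrix that won each window
    win <- (seq_len(n_win * CB) - 1L) %% n_win
    cb <- (seq_len(n_win * CB) - 1L) %/% n_win
    rows_in_S <- win * op$kkC + l$amax         # 1-based via amax
    src <- op$jj[rows_in_S]                    # padded linear index
    dxp <- matrix(0, op$Hp * op$Wp, CB)
    lin <- src + cb * (op$Hp * op$Wp)
    acc <- rowsum(dv, group = lin)
    dxp[as.integer(rownames(acc))] <- acc
    dim(dxp) <- c(op$Hp, op$Wp, d[3], d[4])
    unpad_maps(dxp, pad_h, pad_w, d[1], d[2])
  }
  l$params <- function() list()
  l
}

#' @noRd
layer_global_avgpool <- function() {
  l <- new.env()
  l$forward <- function(x, train = TRUE) {
    d <- dim(x); l$in_dim <- d
    m <- x; dim(m) <- c(d[1] * d[2], d[3] * d[4])
    out <- colMeans(m)
    matrix(out, nrow = d[4], ncol = d[3], byrow = TRUE)   # (B, C)
  }
  l$backward <- function(dout) {
    d <- l$in_dim
    g <- t(dout) / (d[1] * d[2])                          # (C, B)
    array(rep(as.vector(g), each = d[1] * d[2]), dim = d)
  }
  l$params <- function() list()
  l
}

#' @noRd
layer_dense <- function(rng, in_dim, out_dim, zero_init = FALSE) {
  l <- new.env()
  l$W <- if (zero_init) nn_param(matrix(0, in_dim, out_dim))
  else nn_param(matrix(he_init(rng, c(in_dim * out_dim), in_dim),
                       in_dim, out_dim))
  l$b <- nn_param(numeric(out_dim))
  l$forward <- function(x, train = TRUE) {
    l$x <- x
    sweep(x %*% l$W$value, 2, l$b$value, `+`)
  }
  l$backward <- function(dout) {
    l$W$grad <- l$W$grad + crossprod(l$x, dout)
    l$b$grad <- l$b$grad + colSums(dout)
    tcrossprod(dout, l$W$value)
  }
  l$params <- function() list(l$W, l$b)
  l
}

#' @noRd
layer_bn1d <- function(dim_, momentum = 0.1, eps = 1e-5) {
  l <- new.env()
  l$gamma <- nn_param(rep(1, dim_))
  l$beta <- nn_param(numeric(dim_))
  l$run_mean <- numeric(dim_)
  l$run_var <- rep(1, dim_)
  l$forward <- function(x, train = TRUE) {
    if (train && nrow(x) > 1) {
      mu <- colMeans(x); var_ <- colMeans(x^2) - mu^2
      l$run_mean <- 0.9 * l$run_mean + 0.1 * mu
      l$run_var <- 0.9 * l$run_var + 0.1 * var_
      l$train <- TRUE
    } else {
      mu <- l$run_mean; var_ <- l$run_var; l$train <- FALSE
    }
    l$inv_sd <- 1 / sqrt(var_ + eps)
    l$xhat <- sweep(sweep(x, 2, mu), 2, l$inv_sd, `*`)
    sweep(sweep(l$xhat, 2, l$gamma$value, `*`), 2, l$beta$value, `+`)
  }
  l$backward <- function(dout) {
    l$gamma$grad <- l$gamma$grad + colSums(dout * l$xhat)
    l$beta$grad <- l$beta$grad + colSums(dout)
    dxhat <- sweep(dout, 2, l$gamma$value, `*`)
    if (l$train) {
      t1 <- sweep(dxhat, 2, colMeans(dxhat))
      t2 <- sweep(l$xhat, 2, colMeans(dxhat * l$xhat), `*`)
      sweep(t1 - t2, 2, l$inv_sd, `*`)
    } else sweep(dxhat, 2, l$inv_sd, `*`)
  }
  l$params <- function() list(l$gamma, l$beta)
  l
}

#' @noRd
layer_dropout <- function(p, rng) {
  l <- new.env()
  l$forward <- function(x, train = TRUE) {
    if (!train || p == 0) { l$mask <- NULL; return(x) }
    l$mask <- matrix(rng$runif(length(x)) >= p, nrow = nrow(x)) / (1 - p)
    x * l$mask
  }
  l$backward <- function(dout) if (is.null(l$mask)) dout else dout * l$mask
  l$params <- function() list()
  l
}

# -- LSTM --------------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

#' @noRd
lstm_cell <- function(rng, in_dim, hidden) {
  l <- new.env()
  l$W <- nn_param(matrix(he_init(rng, c(in_dim * 4 * hidden), in_dim),
                         in_dim, 4 * hidden))
  l$U <- nn_param(matrix(he_init(rng, c(hidden * 4 * hidden), hidden),
                         hidden, 4 * hidden))
  l$b <- nn_param(numeric(4 * hidden))
  l$hidden <- hidden
  # x: (T, B, D); returns (T, B, H) hidden states.  The input projection is
  # hoisted out of the time loop; gate activations are cached as (B*T, H)
  # blocks for the batched weight-gradient products in backward.
  l$forward <- function(x, train = TRUE) {
    d <- dim(x); T_ <- d[1]; B <- d[2]; H <- hidden
    xm <- matrix(aperm(x, c(2, 1, 3)), nrow = B * T_)   # row = b + (t-1) B
    xW <- xm %*% l$W$value
    bmat <- matrix(l$b$value, B, 4 * H, byrow = TRUE)
    h <- matrix(0, B, H); cc <- matrix(0, B, H)
    i_all <- matrix(0, B * T_, H); f_all <- i_all; g_all <- i_all
    o_all <- i_all; c_all <- i_all; cprev_all <- i_all; hprev_all <- i_all
    out <- array(0, dim = c(T_, B, H))
    i1 <- 1:H; i2 <- H + 1:H; i3 <- 2 * H + 1:H; i4 <- 3 * H + 1:H
    for (t in seq_len(T_)) {
      rows <- (t - 1L) * B + seq_len(B)
      z <- xW[rows, , drop = FALSE] + h %*% l$U$value + bmat
      i_g <- sigmoid(z[, i1, drop = FALSE])
      f_g <- sigmoid(z[, i2, drop = FALSE])
      g_g <- tanh(z[, i3, drop = FALSE])
      o_g <- sigmoid(z[, i4, drop = FALSE])
      hprev_all[rows, ] <- h
      cprev_all[rows, ] <- cc
      cc <- f_g * cc + i_g * g_g
      h <- o_g * tanh(cc)
      i_all[rows, ] <- i_g; f_all[rows, ] <- f_g
      g_all[rows, ] <- g_g; o_all[rows, ] <- o_g
      c_all[rows, ] <- cc
      out[t, , ] <- h
    }
    l$cache <- list(xm = xm, i = i_all, f = f_all, g = g_all, o = o_all,
                    c = c_all, c_prev = cprev_all, h_prev = hprev_all)
    l$in_dim_x <- d
    out
  }
  # dout: (T, B, H) gradient on every hidden state
  l$backward <- function(dout) {
    d <- l$in_dim_x; T_ <- d[1]; B <- d[2]; H <- hidden
    ca <- l$cache
    dz_all <- matrix(0, B * T_, 4 * H)
    i1 <- 1:H; i2 <- H + 1:H; i3 <- 2 * H + 1:H; i4 <- 3 * H + 1:H
    dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
    Ut <- t(l$U$value)
    for (t in rev(seq_len(T_))) {
      rows <- (t - 1L) * B + seq_len(B)
      i_g <- ca$i[rows, , drop = FALSE]; f_g <- ca$f[rows, , drop = FALSE]
      g_g <- ca$g[rows, , drop = FALSE]; o_g <- ca$o[rows, , drop = FALSE]
      tc <- tanh(ca$c[rows, , drop = FALSE])
      dh <- matrix(dout[t, , ], nrow = B) + dh_next
      dc <- dh * o_g * (1 - tc^2) + dc_next
      dz_all[rows, i1] <- dc * g_g * i_g * (1 - i_g)
      dz_all[rows, i2] <- dc * ca$c_prev[rows, , drop = FALSE] * f_g * (1 - f_g)
      dz_all[rows, i3] <- dc * i_g * (1 - g_g^2)
      dz_all[rows, i4] <- dh * tc * o_g * (1 - o_g)
      dh_next <- dz_all[rows, , drop = FALSE] %*% Ut
      dc_next <- dc * f_g
    }
    l$W$grad <- l$W$grad + crossprod(ca$xm, dz_all)
    l$U$grad <- l$U$grad + crossprod(ca$h_prev, dz_all)
    l$b$grad <- l$b$grad + colSums(dz_all)
    dxm <- tcrossprod(dz_all, l$W$value)                 # (B*T, D)
    aperm(array(dxm, dim = c(B, T_, d[3])), c(2, 1, 3))
  }
  l$params <- function() list(l$W, l$U, l$b)
  l
}

#' @noRd
layer_bilstm <- function(rng, in_dim, hidden) {
  l <- new.env()
  l$fwd <- lstm_cell(rng, in_dim, hidden)
  l$bwd <- lstm_cell(rng, in_dim, hidden)
  l$forward <- function(x, train = TRUE) {
    T_ <- dim(x)[1]
    hf <- l$fwd$forward(x, train)
    hb_rev <- l$bwd$forward(x[rev(seq_len(T_)), , , drop = FALSE], train)
    hb <- hb_rev[rev(seq_len(T_)), , , drop = FALSE]
    l$T_ <- T_
    out <- array(0, dim = c(T_, dim(x)[2], 2 * hidden))
    out[, , seq_len(hidden)] <- hf
    out[, , hidden + seq_len(hidden)] <- hb
    out
  }
  l$backward <- function(dout) {
    T_ <- l$T_
    H <- dim(dout)[3] / 2
    dhf <- dout[, , seq_len(H), drop = FALSE]
    dhb <- dout[, , H + seq_len(H), drop = FALSE]
    dx1 <- l$fwd$backward(dhf)
    dx2_rev <- l$bwd$backward(dhb[rev(seq_len(T_)), , , drop = FALSE])
    dx1 + dx2_rev[rev(seq_len(T_)), , , drop = FALSE]
  }
  l$params <- function() c(l$fwd$params(), l$bwd$params())
  l
}

# -- Adam --------------------------------------------------------------------

#' @noRd
adam_optimizer <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8) {
  st <- new.env()
  st$t <- 0L
  st$m <- lapply(params, function(p) array(0, dim = dim(p$value) %||% length(p$value)))
  st$v <- lapply(params, function(p) array(0, dim = dim(p$value) %||% length(p$value)))
  st$step <- function() {
    st$t <- st$t + 1L
    bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
    for (i in seq_along(params)) {
      g <- params[[i]]$grad
      st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * g
      st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * g^2
      newv <- params[[i]]$value -
        lr * (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + eps)
      dim(newv) <- dim(params[[i]]$value)    # keep vectors vectors
      params[[i]]$value <- newv
    }
  }
  st
}
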