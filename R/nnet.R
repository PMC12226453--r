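# Minimal CNN engine for the discrete-time survival network.
#
# Batches are 4D arrays (n, H, W, C), column-major, so a reshape to an
# (n*H*W) x C matrix keeps pixel identity across kernel offsets; 3x3
# convolutions are computed as nine shifted-window matrix products, which
# hands all heavy lifting to BLAS. Everything here is deterministic given
# the RNG state.

# ---- primitive layers ------------------------------------------------------

.as_mat <- function(x) { d <- dim(x); dim(x) <- c(prod(d[1:3]), d[4]); x }

conv3_fwd <- function(X, W, b) {
  d <- dim(X); n <- d[1]; H <- d[2]; Wd <- d[3]; Ci <- d[4]; Co <- dim(W)[4]
  Xp <- array(0, c(n, H + 2, Wd + 2, Ci))
  Xp[, 2:(H + 1), 2:(Wd + 1), ] <- X
  Y <- matrix(b, n * H * Wd, Co, byrow = TRUE)
  for (di in 1:3) for (dj in 1:3) {
    Xs <- Xp[, di:(di + H - 1), dj:(dj + Wd - 1), , drop = FALSE]
    Y <- Y + .as_mat(Xs) %*% matrix(W[di, dj, , ], Ci, Co)
  }
  list(out = array(Y, c(n, H, Wd, Co)), Xp = Xp)
}

conv3_bwd <- function(cache, W, dY) {
  Xp <- cache$Xp
  dp <- dim(Xp); n <- dp[1]; H <- dp[2] - 2L; Wd <- dp[3] - 2L; Ci <- dp[4]
  Co <- dim(W)[4]
  dYm <- .as_mat(dY)
  dW <- array(0, dim(W)); dXp <- array(0, dp)
  for (di in 1:3) for (dj in 1:3) {
    Xs <- Xp[, di:(di + H - 1), dj:(dj + Wd - 1), , drop = FALSE]
    dW[di, dj, , ] <- crossprod(.as_mat(Xs), dYm)
    dXs <- dYm %*% t(matrix(W[di, dj, , ], Ci, Co))
    dXp[, di:(di + H - 1), dj:(dj + Wd - 1), ] <-
      dXp[, di:(di + H - 1), dj:(dj + Wd - 1), , drop = FALSE] +
      array(dXs, c(n, H, Wd, Ci))
  }
  list(dX = dXp[, 2:(H + 1), 2:(Wd + 1), , drop = FALSE],
       dW = dW, db = colSums(dYm))
}

# depthwise 3x3 convolution: one 3x3 kernel per channel
dwconv3_fwd <- function(X, W, b) {
  d <- dim(X); n <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  Xp <- array(0, c(n, H + 2, Wd + 2, C))
  Xp[, 2:(H + 1), 2:(Wd + 1), ] <- X
  m <- n * H * Wd
  Y <- matrix(b, m, C, byrow = TRUE)
  for (di in 1:3) for (dj in 1:3) {
    Xs <- .as_mat(Xp[, di:(di + H - 1), dj:(dj + Wd - 1), , drop = FALSE])
    Y <- Y + Xs * rep(W[di, dj, ], each = m)
  }
  list(out = array(Y, d), Xp = Xp)
}

dwconv3_bwd <- function(cache, W, dY) {
  Xp <- cache$Xp
  dp <- dim(Xp); n <- dp[1]; H <- dp[2] - 2L; Wd <- dp[3] - 2L; C <- dp[4]
  m <- n * H * Wd
  dYm <- .as_mat(dY)
  dW <- array(0, dim(W)); dXp <- array(0, dp)
  for (di in 1:3) for (dj in 1:3) {
    Xs <- .as_mat(Xp[, di:(di + H - 1), dj:(dj + Wd - 1), , drop = FALSE])
    dW[di, dj, ] <- colSums(Xs * dYm)
    dXs <- dYm * rep(W[di, dj, ], each = m)
    dXp[, di:(di + H - 1), dj:(dj + Wd - 1), ] <-
      dXp[, di:(di + H - 1), dj:(dj + Wd - 1), , drop = FALSE] +
      array(dXs, c(n, H, Wd, C))
  }
  list(dX = dXp[, 2:(H + 1), 2:(Wd + 1), , drop = FALSE],
       dW = dW, db = colSums(dYm))
}

# pointwise (1x1) convolution
pwconv_fwd <- function(X, W, b) {
  d <- dim(X)
  Y <- .as_mat(X) %*% W + matrix(b, prod(d[1:3]), length(b), byrow = TRUE)
  list(out = array(Y, c(d[1:3], ncol(W))), Xm = .as_mat(X))
}

pwconv_bwd <- function(cache, W, dY) {
  d <- dim(dY)
  dYm <- .as_mat(dY)
  list(dX = array(dYm %*% t(W), c(d[1:3], nrow(W))),
       dW = crossprod(cache$Xm, dYm), db = colSums(dYm))
}

relu_fwd <- function(X) { m <- X > 0; list(out = X * m, mask = m) }
relu_bwd <- function(cache, dY) dY * cache$mask

swish <- function(x) x * plogis(x)
swish_grad <- function(x) { s <- plogis(x); s * (1 + x * (1 - s)) }
swish_fwd <- function(X) list(out = swish(X), X = X)
swish_bwd <- function(cache, dY) dY * swish_grad(cache$X)

pool2_fwd <- function(X) {
  d <- dim(X); H <- d[2]; W <- d[3]
  io <- seq(1, H, 2); ie <- seq(2, H, 2); jo <- seq(1, W, 2); je <- seq(2, W, 2)
  out <- (X[, io, jo, , drop = FALSE] + X[, ie, jo, , drop = FALSE] +
            X[, io, je, , drop = FALSE] + X[, ie, je, , drop = FALSE]) / 4
  list(out = out, dims = d)
}

pool2_bwd <- function(cache, dY) {
  d <- cache$dims
  dX <- array(0, d)
  io <- seq(1, d[2], 2); ie <- seq(2, d[2], 2)
  jo <- seq(1, d[3], 2); je <- seq(2, d[3], 2)
  q <- dY / 4
  dX[, io, jo, ] <- q; dX[, ie, jo, ] <- q
  dX[, io, je, ] <- q; dX[, ie, je, ] <- q
  dX
}

gap_fwd <- function(X) {
  d <- dim(X)
  M <- array(X, c(d[1], d[2] * d[3], d[4]))
  out <- matrix(0, d[1], d[4])
  for (c in seq_len(d[4])) out[, c] <- rowMeans(M[, , c, drop = FALSE])
  list(out = out, dims = d)
}

gap_bwd <- function(cache, dY) {
  d <- cache$dims
  npix <- d[2] * d[3]
  # dX[i, j, k, c] = dY[i, c] / npix
  dX <- array(0, d)
  M <- array(dX, c(d[1], npix, d[4]))
  for (c in seq_len(d[4])) M[, , c] <- dY[, c] / npix
  array(M, d)
}

fc_fwd <- function(X, W, b) {
  list(out = X %*% W + matrix(b, nrow(X), length(b), byrow = TRUE), X = X)
}
fc_bwd <- function(cache, W, dY) {
  list(dX = dY %*% t(W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

# squeeze-and-excitation block
se_fwd <- function(X, W1, b1, W2, b2) {
  g <- gap_fwd(X)
  a1 <- g$out %*% W1 + matrix(b1, nrow(g$out), length(b1), byrow = TRUE)
  z1 <- swish(a1)
  a2 <- z1 %*% W2 + matrix(b2, nrow(z1), length(b2), byrow = TRUE)
  gate <- plogis(a2) # (n, C)
  d <- dim(X); npix <- d[2] * d[3]
  Gb <- gate[, rep(seq_len(d[4]), each = npix), drop = FALSE]
  dim(Gb) <- d
  list(out = X * Gb, X = X, s = g$out, a1 = a1, z1 = z1, a2 = a2,
       gate = gate, gdims = g$dims, Gb = Gb)
}

se_bwd <- function(cache, W1, W2, dY) {
  d <- dim(cache$X); npix <- d[2] * d[3]
  dX_direct <- dY * cache$Gb
  # d gate: sum over spatial of dY * X, per (n, channel)
  P <- array(dY * cache$X, c(d[1], npix, d[4]))
  dgate <- matrix(0, d[1], d[4])
  for (c in seq_len(d[4])) dgate[, c] <- rowSums(P[, , c, drop = FALSE])
  da2 <- dgate * cache$gate * (1 - cache$gate)
  dW2 <- crossprod(cache$z1, da2); db2 <- colSums(da2)
  dz1 <- da2 %*% t(W2)
  da1 <- dz1 * swish_grad(cache$a1)
  dW1 <- crossprod(cache$s, da1); db1 <- colSums(da1)
  ds <- da1 %*% t(W1)
  dX_se <- gap_bwd(list(dims = cache$gdims), ds)
  list(dX = dX_direct + dX_se, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# ---- parameter initialisation ----------------------------------------------

.he_conv <- function(k, ci, co) {
  array(rnorm(k * k * ci * co, sd = sqrt(2 / (k * k * ci))), c(k, k, ci, co))
}
.he_mat <- function(ci, co) matrix(rnorm(ci * co, sd = sqrt(2 / ci)), ci, co)

net_init <- function(backbone = c("tiny", "mbconv-se"), in_channels = 2L,
                     n_out = 11L, seed = NULL) {
  backbone <- match.arg(backbone)
  if (!is.null(seed)) set.seed(seed)
  if (backbone == "tiny") {
    ch <- c(in_channels, 8L, 16L, 32L)
    params <- list(
      conv1_W = .he_conv(3, ch[1], ch[2]), conv1_b = numeric(ch[2]),
      conv2_W = .he_conv(3, ch[2], ch[3]), conv2_b = numeric(ch[3]),
      conv3_W = .he_conv(3, ch[3], ch[4]), conv3_b = numeric(ch[4]),
      fc_W = .he_mat(ch[4], n_out), fc_b = numeric(n_out))
  } else {
    cs <- 8L; ce <- 24L; cp <- 16L; ch <- 32L; cr <- 6L
    params <- list(
      stem_W = .he_conv(3, in_channels, cs), stem_b = numeric(cs),
      exp_W = .he_mat(cs, ce), exp_b = numeric(ce),
      dw_W = array(rnorm(9 * ce, sd = sqrt(2 / 9)), c(3, 3, ce)),
      dw_b = numeric(ce),
      se1_W = .he_mat(ce, cr), se1_b = numeric(cr),
      se2_W = .he_mat(cr, ce), se2_b = numeric(ce),
      proj_W = .he_mat(ce, cp), proj_b = numeric(cp),
      head_W = .he_conv(3, cp, ch), head_b = numeric(ch),
      fc_W = .he_mat(ch, n_out), fc_b = numeric(n_out))
  }
  list(backbone = backbone, params = params,
       in_channels = in_channels, n_out = n_out)
}

# ---- forward / backward over the whole graph -------------------------------

net_forward <- function(net, X, keep_cache = FALSE) {
  p <- net$params
  if (net$backbone == "tiny") {
    c1 <- conv3_fwd(X, p$conv1_W, p$conv1_b); r1 <- relu_fwd(c1$out)
    p1 <- pool2_fwd(r1$out)
    c2 <- conv3_fwd(p1$out, p$conv2_W, p$conv2_b); r2 <- relu_fwd(c2$out)
    p2 <- pool2_fwd(r2$out)
    c3 <- conv3_fwd(p2$out, p$conv3_W, p$conv3_b); r3 <- relu_fwd(c3$out)
    g <- gap_fwd(r3$out)
    f <- fc_fwd(g$out, p$fc_W, p$fc_b)
    cache <- if (keep_cache)
      list(c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2, p2 = p2,
           c3 = c3, r3 = r3, g = g, f = f)
  } else {
    st <- conv3_fwd(X, p$stem_W, p$stem_b); s1 <- swish_fwd(st$out)
    pl <- pool2_fwd(s1$out)
    ex <- pwconv_fwd(pl$out, p$exp_W, p$exp_b); s2 <- swish_fwd(ex$out)
    dw <- dwconv3_fwd(s2$out, p$dw_W, p$dw_b); s3 <- swish_fwd(dw$out)
    se <- se_fwd(s3$out, p$se1_W, p$se1_b, p$se2_W, p$se2_b)
    pr <- pwconv_fwd(se$out, p$proj_W, p$proj_b)
    p2 <- pool2_fwd(pr$out)
    hd <- conv3_fwd(p2$out, p$head_W, p$head_b); s4 <- swish_fwd(hd$out)
    g <- gap_fwd(s4$out)
    f <- fc_fwd(g$out, p$fc_W, p$fc_b)
    cache <- if (keep_cache)
      list(st = st, s1 = s1, pl = pl, ex = ex, s2 = s2, dw = dw, s3 = s3,
           se = se, pr = pr, p2 = p2, hd = hd, s4 = s4, g = g, f = f)
  }
  z <- f$out
  list(z = z, h = plogis(z), cache = cache)
}

# dz: gradient of the objective w.r.t. the pre-sigmoid outputs z
net_backward <- function(net, cache, dz) {
  p <- net$params
  if (net$backbone == "tiny") {
    fb <- fc_bwd(cache$f, p$fc_W, dz)
    dg <- gap_bwd(cache$g, fb$dX)
    d3 <- relu_bwd(cache$r3, dg)
    c3 <- conv3_bwd(cache$c3, p$conv3_W, d3)
    dp2 <- pool2_bwd(cache$p2, c3$dX)
    d2 <- relu_bwd(cache$r2, dp2)
    c2 <- conv3_bwd(cache$c2, p$conv2_W, d2)
    dp1 <- pool2_bwd(cache$p1, c2$dX)
    d1 <- relu_bwd(cache$r1, dp1)
    c1 <- conv3_bwd(cache$c1, p$conv1_W, d1)
    list(grads = list(conv1_W = c1$dW, conv1_b = c1$db,
                      conv2_W = c2$dW, conv2_b = c2$db,
                      conv3_W = c3$dW, conv3_b = c3$db,
                      fc_W = fb$dW, fc_b = fb$db),
         dX = c1$dX)
  } else {
    fb <- fc_bwd(cache$f, p$fc_W, dz)
    dg <- gap_bwd(cache$g, fb$dX)
    ds4 <- swish_bwd(cache$s4, dg)
    hd <- conv3_bwd(cache$hd, p$head_W, ds4)
    dp2 <- pool2_bwd(cache$p2, hd$dX)
    pr <- pwconv_bwd(cache$pr, p$proj_W, dp2)
    se <- se_bwd(cache$se, p$se1_W, p$se2_W, pr$dX)
    ds3 <- swish_bwd(cache$s3, se$dX)
    dw <- dwconv3_bwd(cache$dw, p$dw_W, ds3)
    ds2 <- swish_bwd(cache$s2, dw$dX)
    ex <- pwconv_bwd(cache$ex, p$exp_W, ds2)
    dpl <- pool2_bwd(cache$pl, ex$dX)
    ds1 <- swish_bwd(cache$s1, dpl)
    st <- conv3_bwd(cache$st, p$stem_W, ds1)
    list(grads = list(stem_W = st$dW, stem_b = st$db,
                      exp_W = ex$dW, exp_b = ex$db,
                      dw_W = dw$dW, dw_b = dw$db,
                      se1_W = se$dW1, se1_b = se$db1,
                      se2_W = se$dW2, se2_b = se$db2,
                      proj_W = pr$dW, proj_b = pr$db,
                      head_W = hd$dW, head_b = hd$db,
                      fc_W = fb$dW, fc_b = fb$db),
         dX = st$dX)
  }
}

# ---- survival loss gradient -------------------------------------------------

# gradient of the mean discrete NLL w.r.t. z, with hazards h = sigmoid(z):
# dL/dz_{ij} = (h_{ij} 1{j <= k_i} - 1{j = k_i, d_i = 1}) / n
nll_grad_z <- function(h, interval, event) {
  n <- nrow(h); K <- ncol(h)
  R <- outer(interval, seq_len(K), `>=`) # at-risk mask, j <= k_i
  D <- matrix(0, n, K)
  D[cbind(seq_len(n), interval)] <- event
  (h * R - D) / n
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

cosine_lr <- function(initial_lr, epoch, max_epochs) {
  initial_lr * 0.5 * (1 + cos(pi * (epoch - 1) / max_epochs))
}
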