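#' @include AllClasses.R
NULL

# Minimal deep-learning layer set used by the scar networks. Tensors are
# numeric arrays laid out (H, W, N, C); fully connected activations are
# (N, F) matrices. Each layer is an environment with $par (named arrays),
# $grad (same shapes, accumulated), $forward(x, train) and $backward(dy).
# Backward returns the input gradient. All gradients are checked against
# finite differences in the test suite.

.zeroGrads <- function(layers) {
  for (e in layers)
    if (!is.null(e$par)) e$grad <- lapply(e$par, function(p) p * 0)
  invisible(NULL)
}

.convLayer <- function(inC, outC, k = 3L, stride = 1L) {
  e <- new.env(parent = emptyenv())
  e$type <- "conv"; e$k <- as.integer(k); e$stride <- as.integer(stride)
  e$pad <- as.integer((k - 1) / 2)
  sdv <- sqrt(2 / (k * k * inC))                       # He initialisation
  e$par <- list(W = matrix(rnorm(outC * k * k * inC, 0, sdv), outC),
                b = numeric(outC))
  e$forward <- function(x, train = FALSE) {
    d <- dim(x)
    x2 <- cpp_im2col(x, d[1], d[2], d[3], d[4], e$k, e$stride, e$pad)
    oH <- (d[1] + 2 * e$pad - e$k) %/% e$stride + 1
    oW <- (d[2] + 2 * e$pad - e$k) %/% e$stride + 1
    y2 <- sweep(x2 %*% t(e$par$W), 2, e$par$b, "+")
    e$cache <- list(x2 = x2, d = d, oH = oH, oW = oW)
    array(y2, c(oH, oW, d[3], ncol(y2)))
  }
  e$backward <- function(dy) {
    cc <- e$cache
    dy2 <- matrix(dy, ncol = nrow(e$par$W))
    e$grad$W <- e$grad$W + t(dy2) %*% cc$x2
    e$grad$b <- e$grad$b + colSums(dy2)
    dx2 <- dy2 %*% e$par$W
    cpp_col2im(dx2, cc$d[1], cc$d[2], cc$d[3], cc$d[4], e$k, e$stride, e$pad)
  }
  e
}

# group normalisation over (H, W, channels-in-group) per sample
.gnLayer <- function(C, groups = 8L, eps = 1e-5) {
  g <- min(groups, C)
  while (C %% g != 0) g <- g - 1                       # groups must divide C
  e <- new.env(parent = emptyenv())
  e$type <- "gn"; e$G <- g; e$C <- C; e$eps <- eps
  e$par <- list(gamma = rep(1, C), beta = numeric(C))
  e$groupOf <- rep(seq_len(g), each = C / g)
  e$forward <- function(x, train = FALSE) {
    d <- dim(x); HW <- d[1] * d[2]; N <- d[3]; C <- d[4]
    m <- HW * (C / e$G)
    sums <- colSums(x, dims = 2)                        # (N, C), no copy
    sq <- colSums(x * x, dims = 2)
    gi <- e$groupOf
    mu <- t(rowsum(t(sums), gi)) / m                    # (N, G)
    v <- t(rowsum(t(sq), gi)) / m - mu^2
    istd <- 1 / sqrt(v + e$eps)
    muNC <- mu[, gi, drop = FALSE]; istdNC <- istd[, gi, drop = FALSE]
    xhat <- cpp_scale_shift(x, as.vector(istdNC),
                            as.vector(-muNC * istdNC), HW)
    gEx <- rep(e$par$gamma, each = N)                   # per-(n, c) expand
    bEx <- rep(e$par$beta, each = N)
    y <- cpp_scale_shift(xhat, gEx, bEx, HW)
    e$cache <- list(xhat = xhat, istdNC = istdNC, gEx = gEx,
                    d = d, m = m)
    y
  }
  e$backward <- function(dy) {
    cc <- e$cache; d <- cc$d; HW <- d[1] * d[2]; N <- d[3]; C <- d[4]
    gi <- e$groupOf
    xhat <- cc$xhat
    dyx <- dy * xhat
    e$grad$gamma <- e$grad$gamma + colSums(dyx, dims = 3)
    e$grad$beta <- e$grad$beta + colSums(dy, dims = 3)
    dxhat <- cpp_scale_shift(dy, cc$gEx, numeric(N * C), HW)
    s1 <- colSums(dxhat, dims = 2)
    s2 <- colSums(dxhat * xhat, dims = 2)
    S1 <- t(rowsum(t(s1), gi))[, gi, drop = FALSE]      # (N, C) expanded
    S2 <- t(rowsum(t(s2), gi))[, gi, drop = FALSE]
    cpp_gn_backward(dxhat, xhat, as.vector(cc$istdNC),
                    as.vector(S1), as.vector(S2), cc$m, HW)
  }
  e
}

.preluLayer <- function(C, init = 0.25) {
  e <- new.env(parent = emptyenv())
  e$type <- "prelu"; e$C <- C
  e$par <- list(a = rep(init, C))
  e$forward <- function(x, train = FALSE) {
    d <- dim(x)
    e$cache <- list(x = x, d = d)
    cpp_prelu_forward(x, e$par$a, d[1] * d[2] * d[3])
  }
  e$backward <- function(dy) {
    cc <- e$cache; d <- cc$d
    da <- numeric(d[4])
    dx <- cpp_prelu_backward(dy, cc$x, e$par$a, da, d[1] * d[2] * d[3])
    e$grad$a <- e$grad$a + da
    dx
  }
  e
}

.upsampleLayer <- function() {
  e <- new.env(parent = emptyenv())
  e$type <- "upsample"
  e$forward <- function(x, train = FALSE) {
    d <- dim(x); e$cache <- d
    cpp_upsample2(x, d[1], d[2], d[3], d[4])
  }
  e$backward <- function(dy) {
    d <- dim(dy)
    cpp_upsample2_backward(dy, d[1], d[2], d[3], d[4])
  }
  e
}

.linearLayer <- function(inF, outF) {
  e <- new.env(parent = emptyenv())
  e$type <- "linear"
  sdv <- sqrt(2 / inF)
  e$par <- list(W = matrix(rnorm(outF * inF, 0, sdv), outF), b = numeric(outF))
  e$forward <- function(x, train = FALSE) {
    e$cache <- x
    sweep(x %*% t(e$par$W), 2, e$par$b, "+")
  }
  e$backward <- function(dy) {
    e$grad$W <- e$grad$W + t(dy) %*% e$cache
    e$grad$b <- e$grad$b + colSums(dy)
    dy %*% e$par$W
  }
  e
}

# group norm over feature groups of an (N, F) activation
.gn1dLayer <- function(F_, groups = 8L, eps = 1e-5) {
  g <- min(groups, F_)
  while (F_ %% g != 0) g <- g - 1
  e <- new.env(parent = emptyenv())
  e$type <- "gn1d"; e$G <- g; e$eps <- eps
  e$par <- list(gamma = rep(1, F_), beta = numeric(F_))
  e$groupOf <- rep(seq_len(g), each = F_ / g)
  e$forward <- function(x, train = FALSE) {
    gi <- e$groupOf; m <- ncol(x) / e$G
    mu <- t(rowsum(t(x), gi)) / m
    v <- t(rowsum(t(x^2), gi)) / m - mu^2
    istd <- 1 / sqrt(v + e$eps)
    xhat <- (x - mu[, gi, drop = FALSE]) * istd[, gi, drop = FALSE]
    e$cache <- list(xhat = xhat, istd = istd, m = m)
    sweep(sweep(xhat, 2, e$par$gamma, "*"), 2, e$par$beta, "+")
  }
  e$backward <- function(dy) {
    cc <- e$cache; gi <- e$groupOf
    dxhat <- sweep(dy, 2, e$par$gamma, "*")
    e$grad$gamma <- e$grad$gamma + colSums(dy * cc$xhat)
    e$grad$beta <- e$grad$beta + colSums(dy)
    S1 <- t(rowsum(t(dxhat), gi))[, gi, drop = FALSE]
    S2 <- t(rowsum(t(dxhat * cc$xhat), gi))[, gi, drop = FALSE]
    cc$istd[, gi, drop = FALSE] *
      (dxhat - S1 / cc$m - cc$xhat * S2 / cc$m)
  }
  e
}

.prelu1dLayer <- function(F_, init = 0.25) {
  e <- new.env(parent = emptyenv())
  e$type <- "prelu1d"
  e$par <- list(a = rep(init, F_))
  e$forward <- function(x, train = FALSE) {
    neg <- (x < 0) * 1
    aF <- matrix(e$par$a, nrow(x), ncol(x), byrow = TRUE)
    e$cache <- list(x = x, neg = neg, aF = aF)
    x * (1 + (aF - 1) * neg)
  }
  e$backward <- function(dy) {
    cc <- e$cache
    e$grad$a <- e$grad$a + colSums(dy * cc$x * cc$neg)
    dy * (1 + (cc$aF - 1) * cc$neg)
  }
  e
}

# inverted dropout: active in train mode only
.dropoutLayer <- function(rate) {
  e <- new.env(parent = emptyenv())
  e$type <- "dropout"; e$rate <- rate
  e$forward <- function(x, train = FALSE) {
    if (!train || e$rate == 0) { e$cache <- NULL; return(x) }
    keep <- 1 - e$rate
    m <- matrix(rbinom(length(x), 1, keep) / keep, nrow(x), ncol(x))
    e$cache <- m
    x * m
  }
  e$backward <- function(dy) {
    if (is.null(e$cache)) dy else dy * e$cache
  }
  e
}

# flatten (H, W, N, C) -> (N, H*W*C); adjoint restores the layout
.flattenLayer <- function() {
  e <- new.env(parent = emptyenv())
  e$type <- "flatten"
  e$forward <- function(x, train = FALSE) {
    d <- dim(x); e$cache <- d
    matrix(aperm(x, c(3, 1, 2, 4)), d[3])
  }
  e$backward <- function(dy) {
    d <- e$cache
    aperm(array(dy, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
  }
  e
}

# global average pool (H, W, N, C) -> (N, C)
.gapLayer <- function() {
  e <- new.env(parent = emptyenv())
  e$type <- "gap"
  e$forward <- function(x, train = FALSE) {
    d <- dim(x); e$cache <- d
    matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
  }
  e$backward <- function(dy) {
    d <- e$cache; HW <- d[1] * d[2]
    array(rep(dy, each = HW) / HW, d)
  }
  e
}

# Adam over a list of layer environments
.adamInit <- function(layers) {
  st <- new.env(parent = emptyenv())
  st$t <- 0
  st$m <- lapply(layers, function(e)
    if (is.null(e$par)) NULL else lapply(e$par, function(p) p * 0))
  st$v <- st$m
  st
}

.adamStep <- function(layers, st, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (i in seq_along(layers)) {
    e <- layers[[i]]
    if (is.null(e$par)) next
    for (nm in names(e$par)) {
      g <- e$grad[[nm]]
      st$m[[i]][[nm]] <- beta1 * st$m[[i]][[nm]] + (1 - beta1) * g
      st$v[[i]][[nm]] <- beta2 * st$v[[i]][[nm]] + (1 - beta2) * g^2
      e$par[[nm]] <- e$par[[nm]] -
        lr * (st$m[[i]][[nm]] / bc1) / (sqrt(st$v[[i]][[nm]] / bc2) + eps)
    }
  }
  invisible(NULL)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.softmax2 <- function(logits) {
  m <- pmax(logits[, 1], logits[, 2])
  e1 <- exp(logits[, 1] - m); e2 <- exp(logits[, 2] - m)
  p <- cbind(e1, e2) / (e1 + e2)
  dimnames(p) <- NULL
  p
}
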