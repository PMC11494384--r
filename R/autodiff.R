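# Minimal reverse-mode automatic differentiation over R matrices.
#
# Nodes are environments holding a value (`v`), an accumulated gradient (`g`),
# parent nodes (`p`), and a backward closure (`bw`) that maps the node's
# output gradient to one gradient per parent. A fresh tape is built on every
# forward pass; `ad_backward()` walks nodes in reverse creation order.
# Heavy layers (convolution, BiLSTM, attention) are fused ops with
# hand-derived backward passes, verified against finite differences in the
# test suite.

.ad <- new.env(parent = emptyenv())
.ad$id <- 0L

ad_new <- function(v, parents = list(), bw = NULL) {
  n <- new.env(parent = emptyenv())
  n$v <- v
  n$g <- NULL
  n$p <- parents
  n$bw <- bw
  .ad$id <- .ad$id + 1L
  n$id <- .ad$id
  class(n) <- "ad_node"
  n
}

#' @export
print.ad_node <- function(x, ...) {
  cat("ad_node #", x$id, " [", paste(dim(x$v), collapse = " x "), "]\n", sep = "")
  invisible(x)
}

ad_leaf <- function(v) ad_new(as.matrix(v))

ad_value <- function(x) x$v
ad_grad <- function(x) x$g

# Accumulate gradient into a node.
ad_acc <- function(node, g) {
  node$g <- if (is.null(node$g)) g else node$g + g
  invisible()
}

#' Run backpropagation from a scalar (1 x 1) root node
#' @noRd
ad_backward <- function(root) {
  stopifnot(length(root$v) == 1L)
  # collect reachable nodes
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  nodes <- list()
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- n
    for (p in n$p) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  root$g <- matrix(1, 1, 1)
  for (n in nodes[ord]) {
    if (is.null(n$bw) || is.null(n$g)) next
    gs <- n$bw(n$g)
    for (i in seq_along(n$p))
      if (!is.null(gs[[i]])) ad_acc(n$p[[i]], gs[[i]])
  }
  invisible(root)
}

# ---- elementary ops --------------------------------------------------------

ad_mm <- function(a, b) {
  ad_new(a$v %*% b$v, list(a, b),
         function(g) list(tcrossprod(g, b$v), crossprod(a$v, g)))
}

# fast row-broadcast helpers: v recycled down columns
row_mul <- function(x, v) x * rep(v, rep.int(nrow(x), length(v)))
row_add <- function(x, v) x + rep(v, rep.int(nrow(x), length(v)))

# a + b; b may be a 1 x n bias broadcast over rows of a
ad_add <- function(a, b) {
  if (nrow(b$v) == 1L && nrow(a$v) > 1L) {
    ad_new(row_add(a$v, as.vector(b$v)), list(a, b),
           function(g) list(g, matrix(colSums(g), 1L)))
  } else {
    ad_new(a$v + b$v, list(a, b), function(g) list(g, g))
  }
}

ad_sub <- function(a, b) ad_new(a$v - b$v, list(a, b), function(g) list(g, -g))

ad_mul <- function(a, b) {
  ad_new(a$v * b$v, list(a, b), function(g) list(g * b$v, g * a$v))
}

ad_scale <- function(a, k) ad_new(a$v * k, list(a), function(g) list(g * k))

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$v))
  ad_new(s, list(a), function(g) list(g * s * (1 - s)))
}

ad_softclamp <- function(a, lim = 12) {
  u <- tanh(a$v / lim)
  ad_new(lim * u, list(a), function(g) list(g * (1 - u^2)))
}

ad_tanh <- function(a) {
  s <- tanh(a$v)
  ad_new(s, list(a), function(g) list(g * (1 - s^2)))
}

ad_relu <- function(a) {
  m <- a$v > 0
  ad_new(a$v * m, list(a), function(g) list(g * m))
}

ad_dropout <- function(a, p) {
  if (p <= 0) return(a)
  mask <- matrix(stats::rbinom(length(a$v), 1L, 1 - p), nrow(a$v)) / (1 - p)
  ad_new(a$v * mask, list(a), function(g) list(g * mask))
}

ad_cbind <- function(nodes) {
  widths <- vapply(nodes, function(n) ncol(n$v), integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ad_new(do.call(cbind, lapply(nodes, ad_value)), nodes,
         function(g) lapply(seq_along(nodes),
                            function(i) g[, starts[i]:ends[i], drop = FALSE]))
}

ad_rows <- function(a, idx) {
  ad_new(a$v[idx, , drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(a$v), ncol(a$v))
    out[idx, ] <- g
    list(out)
  })
}

ad_mean_sq_err <- function(pred, target) {
  # pred: (B x 1) node; target: numeric vector
  d <- as.vector(pred$v) - target
  ad_new(matrix(mean(d^2), 1L, 1L), list(pred),
         function(g) list(matrix(2 * d / length(d), ncol = 1L) * g[1]))
}

ad_bce <- function(pred, target, eps = 1e-7) {
  p <- pmin(pmax(as.vector(pred$v), eps), 1 - eps)
  ad_new(matrix(-mean(target * log(p) + (1 - target) * log(1 - p)), 1L, 1L),
         list(pred),
         function(g) list(matrix((p - target) / (p * (1 - p)) / length(p),
                                 ncol = 1L) * g[1]))
}

# row-wise layer normalization with learned gain/offset (1 x d each)
ad_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  x <- a$v
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- row_add(row_mul(xhat, as.vector(gamma$v)), as.vector(beta$v))
  ad_new(y, list(a, gamma, beta), function(g) {
    dgamma <- matrix(colSums(g * xhat), 1L)
    dbeta <- matrix(colSums(g), 1L)
    dxhat <- row_mul(g, as.vector(gamma$v))
    dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    list(dx, dgamma, dbeta)
  })
}

# (B*T x d), sample-major rows -> (B x T*d); per sample, features ordered
# position 1 first.
ad_flatten_seq <- function(a, B, T) {
  d <- ncol(a$v)
  # rows are sample-major, so vec(t(a)) concatenates each sample's rows
  out <- t(matrix(as.vector(t(a$v)), T * d, B))
  ad_new(out, list(a), function(g) {
    list(t(matrix(as.vector(t(g)), d, T * B)))
  })
}

# ---- fused layers ----------------------------------------------------------

# 3x3 'same' 2D convolution of a single-channel (T x D) image per sample,
# C output channels. x: (B*T x D); W: (C x 9) kernels in offset order
# (di, dj) for di, dj in -1:1 column-major; b: (1 x C).
# Output: (B*T x C*D), channel-major column blocks.
ad_conv3x3 <- function(x, W, b, B, T, D) {
  N <- B * T
  offs <- expand.grid(di = -1:1, dj = -1:1)
  K <- nrow(offs)
  t_in_sample <- rep(seq_len(T), times = B)
  shift_rows <- function(di) {
    tt <- t_in_sample + di
    ok <- tt >= 1L & tt <= T
    src <- ifelse(ok, seq_len(N) + di, NA_integer_)
    src
  }
  shift_mat <- function(M, di, dj) {
    src <- shift_rows(di)
    Y <- matrix(0, N, D)
    ok <- !is.na(src)
    if (dj == 0) {
      Y[ok, ] <- M[src[ok], , drop = FALSE]
    } else if (dj > 0) {
      Y[ok, 1:(D - dj)] <- M[src[ok], (1 + dj):D, drop = FALSE]
    } else {
      Y[ok, (1 - dj):D] <- M[src[ok], 1:(D + dj), drop = FALSE]
    }
    Y
  }
  Sm <- matrix(0, N * D, K)
  for (k in seq_len(K)) Sm[, k] <- as.vector(shift_mat(x$v, offs$di[k], offs$dj[k]))
  OUTv <- Sm %*% t(W$v)                       # (N*D x C)
  C <- ncol(OUTv)
  out <- matrix(0, N, C * D)
  for (c in seq_len(C))
    out[, ((c - 1L) * D + 1L):(c * D)] <- matrix(OUTv[, c], N, D) + b$v[1L, c]
  ad_new(out, list(x, W, b), function(g) {
    dOUTv <- matrix(0, N * D, C)
    db <- matrix(0, 1L, C)
    for (c in seq_len(C)) {
      blk <- g[, ((c - 1L) * D + 1L):(c * D), drop = FALSE]
      dOUTv[, c] <- as.vector(blk)
      db[1L, c] <- sum(blk)
    }
    dW <- crossprod(dOUTv, Sm)
    dSm <- dOUTv %*% W$v                       # (N*D x K)
    dx <- matrix(0, N, D)
    for (k in seq_len(K))
      dx <- dx + shift_mat(matrix(dSm[, k], N, D), -offs$di[k], -offs$dj[k])
    list(dx, dW, db)
  })
}

# Pairwise pooling along the embedding axis within each of C channel blocks.
# a: (N x C*Din) -> (N x C*Dout), Dout = floor(Din/2); an odd trailing column
# is dropped. type "max" keeps the larger of each pair (ties -> first),
# "avg" averages.
ad_pool_pairs <- function(a, C, Din, type = c("max", "avg")) {
  type <- match.arg(type)
  Dout <- Din %/% 2L
  if (Dout < 1L) stop("pooling: block width ", Din, " too small")
  base <- rep((seq_len(C) - 1L) * Din, each = Dout)
  j <- rep(seq(1L, 2L * Dout, by = 2L), times = C)
  i1 <- base + j
  i2 <- i1 + 1L
  A1 <- a$v[, i1, drop = FALSE]
  A2 <- a$v[, i2, drop = FALSE]
  if (type == "max") {
    m <- A1 >= A2
    ad_new(pmax(A1, A2), list(a), function(g) {
      da <- matrix(0, nrow(a$v), ncol(a$v))
      da[, i1] <- g * m
      da[, i2] <- g * !m
      list(da)
    })
  } else {
    ad_new(0.5 * (A1 + A2), list(a), function(g) {
      da <- matrix(0, nrow(a$v), ncol(a$v))
      da[, i1] <- 0.5 * g
      da[, i2] <- 0.5 * g
      list(da)
    })
  }
}

# Bidirectional LSTM over sample-major sequences. x: (B*T x F). Parameters
# per direction: Wx (F x 4H), Wh (H x 4H), b (1 x 4H); gate column order
# [input, forget, cell, output]. Output: (B*T x 2H), forward direction in
# columns 1..H, backward in H+1..2H.
ad_bilstm <- function(x, Wxf, Whf, bf, Wxb, Whb, bb, B, T, H) {
  N <- B * T
  sig <- function(z) 1 / (1 + exp(-z))
  run_dir <- function(Wx, Wh, b, ts) {
    XW <- x$v %*% Wx$v
    h <- matrix(0, B, H); cc <- matrix(0, B, H)
    cache <- vector("list", T)
    out <- matrix(0, N, H)
    for (s in seq_along(ts)) {
      t <- ts[s]
      idx <- (seq_len(B) - 1L) * T + t
      G <- row_add(XW[idx, , drop = FALSE] + h %*% Wh$v, as.vector(b$v))
      i_ <- sig(G[, 1:H, drop = FALSE])
      f_ <- sig(G[, (H + 1):(2 * H), drop = FALSE])
      g_ <- tanh(G[, (2 * H + 1):(3 * H), drop = FALSE])
      o_ <- sig(G[, (3 * H + 1):(4 * H), drop = FALSE])
      c_new <- f_ * cc + i_ * g_
      tc <- tanh(c_new)
      h_new <- o_ * tc
      cache[[s]] <- list(idx = idx, i = i_, f = f_, g = g_, o = o_,
                         c_prev = cc, tc = tc, h_prev = h)
      h <- h_new; cc <- c_new
      out[idx, ] <- h
    }
    list(out = out, cache = cache, XW = XW)
  }
  ts_f <- seq_len(T); ts_b <- rev(ts_f)
  Ff <- run_dir(Wxf, Whf, bf, ts_f)
  Fb <- run_dir(Wxb, Whb, bb, ts_b)
  out <- cbind(Ff$out, Fb$out)
  bw_dir <- function(dout_dir, Wx, Wh, fw) {
    dXW <- matrix(0, N, 4L * H)
    dWh <- matrix(0, H, 4L * H)
    db <- matrix(0, 1L, 4L * H)
    dh_carry <- matrix(0, B, H)
    dc <- matrix(0, B, H)
    for (s in rev(seq_len(T))) {
      ca <- fw$cache[[s]]
      dh <- dout_dir[ca$idx, , drop = FALSE] + dh_carry
      do_ <- dh * ca$tc
      dc <- dc + dh * ca$o * (1 - ca$tc^2)
      di <- dc * ca$g
      dg <- dc * ca$i
      df <- dc * ca$c_prev
      dG <- cbind(di * ca$i * (1 - ca$i),
                  df * ca$f * (1 - ca$f),
                  dg * (1 - ca$g^2),
                  do_ * ca$o * (1 - ca$o))
      dXW[ca$idx, ] <- dG
      dWh <- dWh + crossprod(ca$h_prev, dG)
      db <- db + colSums(dG)
      dh_carry <- tcrossprod(dG, Wh$v)
      dc <- dc * ca$f
    }
    list(dx = tcrossprod(dXW, Wx$v), dWx = crossprod(x$v, dXW),
         dWh = dWh, db = db)
  }
  ad_new(out, list(x, Wxf, Whf, bf, Wxb, Whb, bb), function(g) {
    gf <- bw_dir(g[, 1:H, drop = FALSE], Wxf, Whf, Ff)
    gb <- bw_dir(g[, (H + 1):(2 * H), drop = FALSE], Wxb, Whb, Fb)
    list(gf$dx + gb$dx, gf$dWx, gf$dWh, gf$db, gb$dWx, gb$dWh, gb$db)
  })
}

# Multi-head scaled-dot-product self-attention. q, k, v: (B*T x d) nodes
# (already projected); nh heads of width d/nh. Output (B*T x d).
ad_mhsa <- function(q, k, v, B, T, nh) {
  d <- ncol(q$v)
  stopifnot(d %% nh == 0L)
  dk <- d %/% nh
  sc <- 1 / sqrt(dk)
  hcols <- lapply(seq_len(nh), function(h) ((h - 1L) * dk + 1L):(h * dk))
  out <- matrix(0, B * T, d)
  Acache <- vector("list", B * nh)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T + 1L):(b * T)
    Qb <- q$v[rows, , drop = FALSE]
    Kb <- k$v[rows, , drop = FALSE]
    Vb <- v$v[rows, , drop = FALSE]
    Ob <- matrix(0, T, d)
    for (h in seq_len(nh)) {
      cols <- hcols[[h]]
      S <- tcrossprod(Qb[, cols, drop = FALSE], Kb[, cols, drop = FALSE]) * sc
      S <- S - max(S)   # global shift is enough for exp stability
      E <- exp(S)
      A <- E / rowSums(E)
      Acache[[(b - 1L) * nh + h]] <- A
      Ob[, cols] <- A %*% Vb[, cols, drop = FALSE]
    }
    out[rows, ] <- Ob
  }
  ad_new(out, list(q, k, v), function(g) {
    dq <- matrix(0, B * T, d); dkm <- matrix(0, B * T, d); dv <- matrix(0, B * T, d)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * T + 1L):(b * T)
      Qb <- q$v[rows, , drop = FALSE]
      Kb <- k$v[rows, , drop = FALSE]
      Vb <- v$v[rows, , drop = FALSE]
      Gb <- g[rows, , drop = FALSE]
      dQb <- matrix(0, T, d); dKb <- matrix(0, T, d); dVb <- matrix(0, T, d)
      for (h in seq_len(nh)) {
        cols <- hcols[[h]]
        A <- Acache[[(b - 1L) * nh + h]]
        gO <- Gb[, cols, drop = FALSE]
        Vh <- Vb[, cols, drop = FALSE]
        dVb[, cols] <- crossprod(A, gO)
        dA <- tcrossprod(gO, Vh)
        dS <- A * (dA - rowSums(dA * A))
        dQb[, cols] <- (dS %*% Kb[, cols, drop = FALSE]) * sc
        dKb[, cols] <- crossprod(dS, Qb[, cols, drop = FALSE]) * sc
      }
      dq[rows, ] <- dQb; dkm[rows, ] <- dKb; dv[rows, ] <- dVb
    }
    list(dq, dkm, dv)
  })
}

ad_sum_all <- function(a) {
  ad_new(matrix(sum(a$v), 1L, 1L), list(a),
         function(g) list(matrix(g[1], nrow(a$v), ncol(a$v))))
}
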