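# Minimal reverse-mode automatic differentiation over numeric arrays.
#
# The generator and discriminators are expressed as compositions of a small
# op set (dense products, batched per-window products, gathers/permutations,
# normalization, pointwise nonlinearities, reductions). Each forward call
# records nodes on a tape; ad_backward() replays the tape in reverse and
# accumulates vector-Jacobian products into the named leaf nodes (the model
# parameters). Values are plain base-R arrays/matrices throughout.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_node <- function(tape, value, parents = integer(0), vjp = NULL, leaf = NULL) {
  # force promises first: nested op calls must register their nodes before
  # this node takes its id, so parent ids are always below the child's
  force(parents); force(value); force(vjp)
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- list(id = tape$n, value = value, parents = parents,
                               vjp = vjp, leaf = leaf)
  list(id = tape$n, tape = tape)
}

ad_value <- function(h) h$tape$nodes[[h$id]]$value

# Leaf (parameter) node; `name` keys the gradient in ad_backward()'s result.
ad_leaf <- function(tape, value, name) ad_node(tape, value, leaf = name)

ad_const <- function(tape, value) ad_node(tape, value)

#' @keywords internal
ad_backward <- function(loss, seed = 1) {
  tape <- loss$tape
  grads <- vector("list", tape$n)
  lval <- tape$nodes[[loss$id]]$value
  g0 <- array(seed, dim = if (is.null(dim(lval))) length(lval) else dim(lval))
  grads[[loss$id]] <- g0
  out <- list()
  for (i in seq(loss$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- tape$nodes[[i]]
    if (!is.null(nd$leaf)) {
      if (is.null(out[[nd$leaf]])) out[[nd$leaf]] <- g else out[[nd$leaf]] <- out[[nd$leaf]] + g
      next
    }
    if (length(nd$parents) == 0L) { grads[[i]] <- NULL; next }
    pg <- nd$vjp(g)
    for (j in seq_along(nd$parents)) {
      if (is.null(pg[[j]])) next
      pid <- nd$parents[[j]]
      grads[[pid]] <- if (is.null(grads[[pid]])) pg[[j]] else grads[[pid]] + pg[[j]]
    }
    grads[[i]] <- NULL
  }
  out
}

## ---- dense linear algebra ----

ad_matmul <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  ad_node(a$tape, A %*% B, c(a$id, b$id), function(g) {
    list(g %*% t(B), crossprod(A, g))
  })
}

ad_add <- function(a, b) {
  ad_node(a$tape, ad_value(a) + ad_value(b), c(a$id, b$id),
          function(g) list(g, g))
}

ad_sub <- function(a, b) {
  ad_node(a$tape, ad_value(a) - ad_value(b), c(a$id, b$id),
          function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  ad_node(a$tape, A * B, c(a$id, b$id), function(g) list(g * B, g * A))
}

ad_scale <- function(a, s) {
  ad_node(a$tape, ad_value(a) * s, a$id, function(g) list(g * s))
}

# matrix (N x C) plus a length-C bias row
ad_add_bias <- function(a, b) {
  A <- ad_value(a); bias <- ad_value(b)
  V <- sweep(A, 2L, bias, "+")
  ad_node(a$tape, V, c(a$id, b$id), function(g) list(g, colSums(g)))
}

ad_cbind <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  ca <- ncol(A)
  ad_node(a$tape, cbind(A, B), c(a$id, b$id), function(g) {
    list(g[, seq_len(ca), drop = FALSE], g[, -seq_len(ca), drop = FALSE])
  })
}

## ---- shape ops ----

ad_reshape <- function(a, dims) {
  A <- ad_value(a)
  old <- if (is.null(dim(A))) length(A) else dim(A)
  V <- A; dim(V) <- dims
  ad_node(a$tape, V, a$id, function(g) { dim(g) <- old; list(g) })
}

ad_aperm <- function(a, perm) {
  inv <- order(perm)
  ad_node(a$tape, aperm(ad_value(a), perm), a$id,
          function(g) list(aperm(g, inv)))
}

# Row gather; idx of length M over rows of A, idx == 0L yields a zero row.
# Backward scatter-adds, so idx may repeat rows (im2col) or permute them;
# perm = TRUE marks a bijection (no zeros, no repeats) for a fast backward.
ad_gather_rows <- function(a, idx, perm = FALSE) {
  A <- ad_value(a)
  n <- nrow(A)
  if (perm) {
    V <- A[idx, , drop = FALSE]
    return(ad_node(a$tape, V, a$id, function(g) {
      gA <- g
      gA[idx, ] <- g
      list(gA)
    }))
  }
  V <- matrix(0, length(idx), ncol(A))
  nz <- idx > 0L
  V[nz, ] <- A[idx[nz], , drop = FALSE]
  ad_node(a$tape, V, a$id, function(g) {
    gA <- matrix(0, n, ncol(g))
    if (any(nz)) {
      r <- rowsum(g[nz, , drop = FALSE], idx[nz])
      gA[as.integer(rownames(r)), ] <- r
    }
    list(gA)
  })
}

# Fused windowed multi-head attention core on (w, d, slices) cubes.
ad_attention <- function(q, k, v, scale) {
  Q <- ad_value(q); K <- ad_value(k); V <- ad_value(v)
  fw <- attn_forward_cpp(Q, K, V, scale)
  ad_node(q$tape, fw$O, c(q$id, k$id, v$id), function(g) {
    bw <- attn_backward_cpp(g, fw$P, Q, K, V, scale)
    list(bw$gQ, bw$gK, bw$gV)
  })
}

## ---- batched (per-window) attention ops ----

cube_matmul <- function(A, B, ta = FALSE, tb = FALSE) cube_matmul_cpp(A, B, ta, tb)

ad_cube_matmul <- function(a, b, ta = FALSE, tb = FALSE) {
  A <- ad_value(a); B <- ad_value(b)
  V <- cube_matmul(A, B, ta, tb)
  vjp <- if (!ta && !tb) {
    function(g) list(cube_matmul(g, B, FALSE, TRUE), cube_matmul(A, g, TRUE, FALSE))
  } else if (!ta && tb) {
    function(g) list(cube_matmul(g, B, FALSE, FALSE), cube_matmul(g, A, TRUE, FALSE))
  } else if (ta && !tb) {
    function(g) list(cube_matmul(B, g, FALSE, TRUE), cube_matmul(A, g, FALSE, FALSE))
  } else {
    stop("ta && tb not needed")
  }
  ad_node(a$tape, V, c(a$id, b$id), vjp)
}

# Softmax along dim 2 of a (w1, w2, ns) cube (attention over keys).
ad_softmax2 <- function(a) {
  A <- ad_value(a)
  d <- dim(A)
  Af <- matrix(aperm(A, c(2L, 1L, 3L)), nrow = d[2L])  # keys x (query,slice)
  mx <- Af[1L, ]
  if (d[2L] > 1L) for (r in 2L:d[2L]) mx <- pmax(mx, Af[r, ])
  E <- exp(sweep(Af, 2L, mx, "-"))
  P <- sweep(E, 2L, colSums(E), "/")
  V <- aperm(array(P, c(d[2L], d[1L], d[3L])), c(2L, 1L, 3L))
  ad_node(a$tape, V, a$id, function(g) {
    Gf <- matrix(aperm(g, c(2L, 1L, 3L)), nrow = d[2L])
    dot <- colSums(P * Gf)
    dA <- P * sweep(Gf, 2L, dot, "-")
    list(aperm(array(dA, c(d[2L], d[1L], d[3L])), c(2L, 1L, 3L)))
  })
}

# (N, d*h) token matrix (window-major rows) -> (w, d, nb*h) head cube
ad_to_cube <- function(m, wt, nb, d, h) {
  M <- ad_value(m)
  V <- aperm(array(M, c(wt, nb, d, h)), c(1L, 3L, 2L, 4L))
  dim(V) <- c(wt, d, nb * h)
  ad_node(m$tape, V, m$id, function(g) {
    dim(g) <- c(wt, d, nb, h)
    g <- aperm(g, c(1L, 3L, 2L, 4L))
    dim(g) <- c(wt * nb, d * h)
    list(g)
  })
}

ad_from_cube <- function(a, wt, nb, d, h) {
  A <- ad_value(a)
  dim(A) <- c(wt, d, nb, h)
  V <- aperm(A, c(1L, 3L, 2L, 4L))
  dim(V) <- c(wt * nb, d * h)
  ad_node(a$tape, V, a$id, function(g) {
    dim(g) <- c(wt, nb, d, h)
    g <- aperm(g, c(1L, 3L, 2L, 4L))
    dim(g) <- c(wt, d, nb * h)
    list(g)
  })
}

## ---- normalization and nonlinearities ----

ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  X <- ad_value(x); gam <- ad_value(gamma); bet <- ad_value(beta)
  C <- ncol(X)
  mu <- rowMeans(X)
  xc <- X - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  V <- sweep(sweep(xhat, 2L, gam, "*"), 2L, bet, "+")
  ad_node(x$tape, V, c(x$id, gamma$id, beta$id), function(g) {
    gxhat <- sweep(g, 2L, gam, "*")
    m1 <- rowMeans(gxhat)
    m2 <- rowMeans(gxhat * xhat)
    gX <- istd * (gxhat - m1 - xhat * m2)
    list(gX, colSums(g * xhat), colSums(g))
  })
}

# tanh-form GELU; the tanh is cached so backward needs no transcendentals
ad_gelu <- function(a) {
  A <- ad_value(a)
  c0 <- sqrt(2 / pi)
  u <- c0 * (A + 0.044715 * A^3)
  t <- tanh(u)
  ad_node(a$tape, 0.5 * A * (1 + t), a$id, function(g) {
    du <- c0 * (1 + 3 * 0.044715 * A^2)
    list(g * (0.5 * (1 + t) + 0.5 * A * (1 - t * t) * du))
  })
}

ad_lrelu <- function(a, alpha = 0.2) {
  A <- ad_value(a)
  pos <- A > 0
  ad_node(a$tape, ifelse(pos, A, alpha * A), a$id,
          function(g) list(ifelse(pos, g, alpha * g)))
}

## ---- losses ----

# mean absolute difference (L1); target is a plain array, not a node
ad_l1_loss <- function(pred, target) {
  P <- ad_value(pred)
  D <- P - target
  n <- length(D)
  ad_node(pred$tape, mean(abs(D)), pred$id,
          function(g) list(array(as.numeric(g) * sign(D) / n, dim = dim(P))))
}

# numerically stable binary cross-entropy with logits against constant labels
ad_bce_logits <- function(logits, y) {
  Z <- ad_value(logits)
  n <- length(Z)
  val <- mean(pmax(Z, 0) - Z * y + log1p(exp(-abs(Z))))
  sig <- 1 / (1 + exp(-Z))
  ad_node(logits$tape, val, logits$id, function(g) {
    gg <- as.numeric(g) * (sig - y) / n
    dim(gg) <- dim(Z)
    list(gg)
  })
}

ad_mean <- function(a) {
  A <- ad_value(a)
  n <- length(A)
  ad_node(a$tape, mean(A), a$id, function(g) {
    gg <- array(as.numeric(g) / n, dim = if (is.null(dim(A))) length(A) else dim(A))
    list(gg)
  })
}

## ---- finite-difference gradient check (test helper) ----

#' @keywords internal
ad_grad_check <- function(fn, params, eps = 1e-5) {
  tape <- ad_tape()
  leaves <- lapply(names(params), function(nm) ad_leaf(tape, params[[nm]], nm))
  names(leaves) <- names(params)
  loss <- fn(tape, leaves)
  an <- ad_backward(loss)
  num <- lapply(names(params), function(nm) {
    p <- params[[nm]]
    gnum <- array(0, dim = if (is.null(dim(p))) length(p) else dim(p))
    for (i in seq_along(p)) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      tp <- ad_tape()
      lv <- lapply(names(pp), function(x) ad_leaf(tp, pp[[x]], x)); names(lv) <- names(pp)
      up <- ad_value(fn(tp, lv))
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      tm <- ad_tape()
      lm <- lapply(names(pm), function(x) ad_leaf(tm, pm[[x]], x)); names(lm) <- names(pm)
      dn <- ad_value(fn(tm, lm))
      gnum[i] <- (up - dn) / (2 * eps)
    }
    gnum
  })
  names(num) <- names(params)
  list(analytic = an, numeric = num)
}
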