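# Minimal reverse-mode automatic differentiation on dense arrays.
#
# A global tape records operations while `ag_record()` is active; `ag_backward()`
# walks the tape in reverse and accumulates gradients into every tensor with
# `requires_grad = TRUE` (the network parameters).  Values are plain numeric
# arrays; images and feature maps use dim (H, W, C), token matrices (N, C).

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL
.ag$n <- 0L
.ag$recording <- FALSE
.ag$cache <- new.env(parent = emptyenv()) # im2col index cache

#' Create an autodiff tensor
#'
#' Wraps a numeric array as a node usable with the `ag_*` operations.
#' Tensors with `requires_grad = TRUE` accumulate gradients in `$grad`
#' when [ag_backward()] runs.
#'
#' @param value numeric array/matrix/vector.
#' @param requires_grad logical; track gradients for this leaf.
#' @return an object of class `ag_tensor` (an environment with `$value`,
#'   `$grad`).
#' @keywords internal
#' @export
ag_tensor <- function(value, requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$rg <- requires_grad
  class(e) <- "ag_tensor"
  e
}

is_ag <- function(x) inherits(x, "ag_tensor")
ag_val <- function(x) if (is_ag(x)) x$value else x
ag_rg <- function(x) is_ag(x) && isTRUE(x$rg)

#' @export
print.ag_tensor <- function(x, ...) {
  d <- dim(x$value)
  cat("<ag_tensor", if (is.null(d)) paste0("len ", length(x$value)) else paste(d, collapse = "x"),
      if (x$rg) "grad" else "", ">\n")
  invisible(x)
}

#' Start/stop recording the autodiff tape
#' @keywords internal
#' @export
ag_record <- function() {
  .ag$tape <- vector("list", 1024L)
  .ag$n <- 0L
  .ag$recording <- TRUE
  invisible(NULL)
}

#' @rdname ag_record
#' @export
ag_stop <- function() {
  .ag$tape <- NULL
  .ag$n <- 0L
  .ag$recording <- FALSE
  invisible(NULL)
}

# Internal: create a result node, registering it on the tape when any parent
# requires a gradient.  `backward` maps the node's output gradient to a list
# of parent gradients (NULL entries allowed).
ag_node <- function(value, parents, backward) {
  rg <- .ag$recording && any(vapply(parents, ag_rg, logical(1)))
  t <- ag_tensor(value, rg)
  if (rg) {
    t$parents <- parents
    t$bw <- backward
    n <- .ag$n + 1L
    if (n > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
    .ag$tape[[n]] <- t
    .ag$n <- n
  }
  t
}

#' Backpropagate from a scalar loss
#'
#' Accumulates gradients into all recorded leaves with `requires_grad = TRUE`,
#' then clears the tape.
#'
#' @param loss an `ag_tensor` holding a length-1 value.
#' @keywords internal
#' @export
ag_backward <- function(loss) {
  stopifnot(is_ag(loss))
  if (!isTRUE(loss$rg)) {
    ag_stop()
    return(invisible(NULL))
  }
  loss$grad <- 1
  n <- .ag$n
  tape <- .ag$tape
  for (i in seq.int(n, 1L)) {
    node <- tape[[i]]
    g <- node$grad
    if (is.null(g)) next
    gs <- node$bw(g)
    ps <- node$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (ag_rg(p) && !is.null(gs[[j]])) {
        p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
      }
    }
    node$grad <- NULL
  }
  ag_stop()
  invisible(NULL)
}

# ---- elementwise arithmetic ------------------------------------------------

ag_add <- function(a, b) {
  av <- ag_val(a); bv <- ag_val(b)
  ag_node(av + bv, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  av <- ag_val(a); bv <- ag_val(b)
  ag_node(av - bv, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  av <- ag_val(a); bv <- ag_val(b)
  ag_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

# y = k * x for a fixed (non-learnable) scalar k
ag_scale <- function(x, k) {
  xv <- ag_val(x)
  ag_node(k * xv, list(x), function(g) list(k * g))
}

# y = a*x + b*y2 where a, b are learnable scalars (length-1 tensors).
# Used for the adaptive pooling-combination weights g1, g2 of the ACA module.
ag_axpby <- function(a, x, b, y) {
  av <- ag_val(a); xv <- ag_val(x); bv <- ag_val(b); yv <- ag_val(y)
  ag_node(av * xv + bv * yv, list(a, x, b, y), function(g) {
    list(sum(g * xv), av * g, sum(g * yv), bv * g)
  })
}

# ---- activations -----------------------------------------------------------

ag_relu <- function(x) {
  xv <- ag_val(x)
  m <- xv > 0
  y <- xv * m
  ag_node(y, list(x), function(g) list(g * m))
}

ag_sigmoid <- function(x) {
  xv <- ag_val(x)
  s <- 1 / (1 + exp(-xv))
  ag_node(s, list(x), function(g) list(g * s * (1 - s)))
}

# hard-swish: x * clamp(x + 3, 0, 6) / 6
ag_hardswish <- function(x) {
  xv <- ag_val(x)
  r6 <- pmin(pmax(xv + 3, 0), 6)
  y <- xv * r6 / 6
  ag_node(y, list(x), function(g) {
    d <- r6 / 6 + xv * ((xv > -3) & (xv < 3)) / 6
    list(g * d)
  })
}

ag_tanh <- function(x) {
  xv <- ag_val(x)
  y <- tanh(xv)
  ag_node(y, list(x), function(g) list(g * (1 - y^2)))
}

# ---- reductions and losses -------------------------------------------------

ag_sum <- function(x) {
  xv <- ag_val(x)
  ag_node(sum(xv), list(x), function(g) {
    gx <- array(g, dim = if (is.null(dim(xv))) length(xv) else dim(xv))
    list(gx)
  })
}

ag_mean <- function(x) {
  xv <- ag_val(x)
  n <- length(xv)
  ag_node(sum(xv) / n, list(x), function(g) {
    gx <- array(g / n, dim = if (is.null(dim(xv))) length(xv) else dim(xv))
    list(gx)
  })
}

# Binary cross-entropy of probabilities p against targets t in {0,1}; mean
# over elements.  Fused op with an analytic, clamped gradient.
ag_bce <- function(p, target, eps = 1e-7) {
  pv <- ag_val(p); tv <- ag_val(target)
  pc <- pmin(pmax(pv, eps), 1 - eps)
  n <- length(pv)
  v <- -sum(tv * log(pc) + (1 - tv) * log(1 - pc)) / n
  ag_node(v, list(p), function(g) {
    list(g * (pc - tv) / (pc * (1 - pc)) / n)
  })
}

# Soft Dice loss 1 - (2*sum(p*t) + s) / (sum(p) + sum(t) + s)
ag_dice_loss <- function(p, target, smooth = 1) {
  pv <- ag_val(p); tv <- ag_val(target)
  inter <- sum(pv * tv)
  denom <- sum(pv) + sum(tv) + smooth
  v <- 1 - (2 * inter + smooth) / denom
  ag_node(v, list(p), function(g) {
    dnum <- 2 * tv / denom
    dden <- -(2 * inter + smooth) / denom^2
    list(g * (-(dnum + dden)))
  })
}

# ---- linear algebra --------------------------------------------------------

ag_matmul <- function(a, b) {
  av <- ag_val(a); bv <- ag_val(b)
  ag_node(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), crossprod(av, g))
  })
}

# x: N x Cin, W: Cin x Cout, b: length Cout (or NULL)
ag_linear <- function(x, W, b = NULL) {
  xv <- ag_val(x); Wv <- ag_val(W)
  y <- xv %*% Wv
  if (!is.null(b)) y <- sweep(y, 2, ag_val(b), "+")
  parents <- if (is.null(b)) list(x, W) else list(x, W, b)
  ag_node(y, parents, function(g) {
    out <- list(g %*% t(Wv), crossprod(xv, g))
    if (!is.null(b)) out[[3]] <- colSums(g)
    out
  })
}

# Row-wise softmax of an N x K matrix.
ag_softmax_rows <- function(x) {
  xv <- ag_val(x)
  m <- xv - apply(xv, 1, max)
  e <- exp(m)
  p <- e / rowSums(e)
  ag_node(p, list(x), function(g) {
    dot <- rowSums(g * p)
    list(p * (g - dot))
  })
}

# LayerNorm across columns of an N x C matrix with learnable gamma/beta (C).
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- ag_val(x); gv <- ag_val(gamma); bv <- ag_val(beta)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc^2)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  y <- sweep(sweep(xhat, 2, gv, "*"), 2, bv, "+")
  C <- ncol(xv)
  ag_node(y, list(x, gamma, beta), function(g) {
    gg <- sweep(g, 2, gv, "*")
    s1 <- rowSums(gg)
    s2 <- rowSums(gg * xhat)
    dx <- istd * (gg - s1 / C - xhat * s2 / C)
    list(dx, colSums(g * xhat), colSums(g))
  })
}

# ---- shape ops -------------------------------------------------------------

ag_reshape <- function(x, new_dim) {
  xv <- ag_val(x)
  old <- if (is.null(dim(xv))) length(xv) else dim(xv)
  y <- xv
  dim(y) <- new_dim
  ag_node(y, list(x), function(g) {
    dim(g) <- old
    list(g)
  })
}

# Gather by integer index (indices need not be unique); out_dim optional.
ag_gather <- function(x, idx, out_dim = NULL, unique_idx = FALSE) {
  xv <- ag_val(x)
  y <- xv[idx]
  if (!is.null(out_dim)) dim(y) <- out_dim
  n <- length(xv)
  xd <- if (is.null(dim(xv))) length(xv) else dim(xv)
  ag_node(y, list(x), function(g) {
    gx <- numeric(n)
    if (unique_idx) {
      gx[idx] <- g
    } else {
      acc <- rowsum(as.vector(g), group = as.vector(idx), reorder = FALSE)
      gx[as.integer(rownames(acc))] <- acc[, 1]
    }
    dim(gx) <- xd
    list(gx)
  })
}
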