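# Parameter containers, initialisation and the Adam optimiser.
#
# A "module" is a plain list with class `vs_module`: `$params` holds named
# `ag_tensor` leaves with requires_grad = TRUE, `$modules` holds nested
# modules, and any forward logic lives in closures stored by the network
# constructors.  `collect_params()` walks the tree for the optimiser.

new_param <- function(value) {
  t <- ag_tensor(value, requires_grad = TRUE)
  t$is_param <- TRUE
  t
}

vs_module <- function(params = list(), modules = list(), ...) {
  structure(c(list(params = params, modules = modules), list(...)),
            class = "vs_module")
}

#' Collect all learnable parameters of a module tree
#'
#' @param mod a module as built by [build_mfnet()] or the attention block
#'   constructors.
#' @return named list of parameter tensors.
#' @keywords internal
#' @export
collect_params <- function(mod) {
  out <- list()
  walk <- function(m, prefix) {
    for (nm in names(m$params)) {
      out[[paste0(prefix, nm)]] <<- m$params[[nm]]
    }
    for (nm in names(m$modules)) {
      walk(m$modules[[nm]], paste0(prefix, nm, "."))
    }
  }
  walk(mod, "")
  out
}

n_params <- function(mod) {
  sum(vapply(collect_params(mod), function(p) length(p$value), numeric(1)))
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# He-normal initialisation for a (k, k, cin, cout) kernel.
init_conv_kernel <- function(k, cin, cout, gain = 2) {
  sd <- sqrt(gain / (k * k * cin))
  array(stats::rnorm(k * k * cin * cout, sd = sd), dim = c(k, k, cin, cout))
}

# A conv layer module; forward through conv_fwd(layer, x).
conv_layer <- function(cin, cout, k = 3) {
  vs_module(
    params = list(W = new_param(init_conv_kernel(k, cin, cout)),
                  b = new_param(numeric(cout))),
    k = k, cin = cin, cout = cout
  )
}

conv_fwd <- function(layer, x) ag_conv2d(x, layer$params$W, layer$params$b, layer$k)

linear_layer <- function(cin, cout, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / cin)
  vs_module(params = list(
    W = new_param(matrix(stats::rnorm(cin * cout, sd = sd), cin, cout)),
    b = new_param(numeric(cout))
  ), cin = cin, cout = cout)
}

linear_fwd <- function(layer, x) ag_linear(x, layer$params$W, layer$params$b)

layernorm_layer <- function(C) {
  vs_module(params = list(gamma = new_param(rep(1, C)), beta = new_param(numeric(C))))
}

layernorm_fwd <- function(layer, x) ag_layernorm(x, layer$params$gamma, layer$params$beta)

#' Adam optimiser state
#'
#' Classic Adam with L2 weight decay added to the gradient (the form used by
#' most deep-learning frameworks when `weight_decay` is set on the optimiser).
#'
#' @param params named list of parameter tensors (see [collect_params()]).
#' @param lr learning rate.
#' @param beta1,beta2 moment decay rates.
#' @param eps numerical floor.
#' @param weight_decay L2 coefficient added to every gradient.
#' @return an optimiser object; advance it with [adam_step()].
#' @keywords internal
#' @export
adam_optimizer <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8, weight_decay = 0) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$m <- lapply(params, function(p) p$value * 0)
  st$v <- lapply(params, function(p) p$value * 0)
  st$t <- 0L
  st$lr <- lr
  st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$weight_decay <- weight_decay
  class(st) <- "vs_adam"
  st
}

#' @rdname adam_optimizer
#' @param opt optimiser object.
#' @param lr optional learning-rate override for this step (the schedule).
#' @export
adam_step <- function(opt, lr = NULL) {
  if (is.null(lr)) lr <- opt$lr
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    if (opt$weight_decay > 0) g <- g + opt$weight_decay * p$value
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g * g
    mhat <- opt$m[[i]] / bc1
    vhat <- opt$v[[i]] / bc2
    p$value <- p$value - lr * mhat / (sqrt(vhat) + opt$eps)
  }
  invisible(opt)
}

# Serialise parameter values to a plain list of numeric vectors with dims
# (JSON-safe), and restore.  Used for text-format checkpoints.
params_to_list <- function(params) {
  lapply(params, function(p) {
    list(dim = if (is.null(dim(p$value))) length(p$value) else dim(p$value),
         data = as.vector(p$value))
  })
}

params_from_list <- function(params, saved) {
  for (nm in names(params)) {
    s <- saved[[nm]]
    if (is.null(s)) stop("checkpoint is missing parameter: ", nm)
    v <- as.numeric(s$data)
    d <- as.integer(unlist(s$dim))
    if (length(d) > 1) dim(v) <- d
    params[[nm]]$value <- v
  }
  invisible(params)
}
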