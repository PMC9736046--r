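# Attention modules against naive loop/stagewise oracles, plus the
# reductions to the SE/CA/SW baselines.

# Naive double-loop oracle for the directional pooling encodings.
loop_encode <- function(x) {
  d <- dim(x)
  kwa <- matrix(0, d[3], d[2]); kwm <- kwa
  kha <- matrix(0, d[3], d[1]); khm <- kha
  for (c in seq_len(d[3])) {
    for (w in seq_len(d[2])) {
      kwa[c, w] <- mean(x[, w, c]); kwm[c, w] <- max(x[, w, c])
    }
    for (h in seq_len(d[1])) {
      kha[c, h] <- mean(x[h, , c]); khm[c, h] <- max(x[h, , c])
    }
  }
  list(k_w_avg = kwa, k_w_max = kwm, k_h_avg = kha, k_h_max = khm)
}

test_that("directional encodings match hand values and the loop oracle", {
  # constant input: all encodings constant, avg == max
  cst <- array(3, c(4, 5, 2))
  e <- aca_encode(cst)
  for (nm in names(e)) expect_true(all(e[[nm]] == 3), info = nm)
  # hand-evaluated 2x2 single-channel case
  x <- array(c(1, 3, 2, 4), c(2, 2, 1))   # [[1,2],[3,4]] row-major
  e2 <- aca_encode(x)
  expect_equal(as.vector(e2$k_w_avg), c(2, 3))
  expect_equal(as.vector(e2$k_w_max), c(3, 4))
  expect_equal(as.vector(e2$k_h_avg), c(1.5, 3.5))
  expect_equal(as.vector(e2$k_h_max), c(2, 4))
  # random instances against the loop oracle
  set.seed(21)
  for (i in 1:25) {
    d <- c(sample(2:7, 1), sample(2:7, 1), sample(1:4, 1))
    x <- array(rnorm(prod(d)), d)
    got <- aca_encode(x)
    ref <- loop_encode(x)
    for (nm in names(ref)) {
      expect_equal(got[[nm]], ref[[nm]], tolerance = 1e-6, info = nm)
    }
    expect_true(all(got$k_w_max >= got$k_w_avg - 1e-12))
    expect_true(all(got$k_h_max >= got$k_h_avg - 1e-12))
  }
})

test_that("max encodings are invariant to non-dominant pixels", {
  set.seed(22)
  x <- array(runif(6 * 6, 0, 0.5), c(6, 6, 1))
  x[3, , 1] <- 5 + runif(6)             # one dominant row value per column
  e1 <- aca_encode(x)
  y <- x
  y[-3, , 1] <- runif(30, 0, 0.5)       # perturb all non-dominant pixels
  e2 <- aca_encode(y)
  expect_identical(e1$k_w_max, e2$k_w_max)
})

# Stagewise matrix-arithmetic oracle for the gate computation (hand-set
# single-reduction weights).
test_that("gate computation matches a naive matrix oracle and stays in (0,1)", {
  set.seed(23)
  C <- 2; H <- 3; W <- 4; Cr <- 2
  x <- array(rnorm(H * W * C), c(H, W, C))
  enc <- aca_encode(x)
  params <- list(F1 = matrix(rnorm(C * Cr), C, Cr), F1_b = rnorm(Cr),
                 Fh = matrix(rnorm(Cr * C), Cr, C), Fh_b = rnorm(C),
                 Fw = matrix(rnorm(Cr * C), Cr, C), Fw_b = rnorm(C),
                 g1 = 0.7, g2 = 0.4)
  got <- aca_weights(enc, params, delta = "relu")
  # oracle: concatenate (C x (H+W)) encodings, shared transform, recombine
  relu <- function(z) pmax(z, 0)
  sigm <- function(z) 1 / (1 + exp(-z))
  cat_a <- rbind(t(enc$k_h_avg), t(enc$k_w_avg))     # (H+W) x C
  cat_m <- rbind(t(enc$k_h_max), t(enc$k_w_max))
  za <- relu(sweep(cat_a %*% params$F1, 2, params$F1_b, "+"))
  zm <- relu(sweep(cat_m %*% params$F1, 2, params$F1_b, "+"))
  z <- params$g1 * za + params$g2 * zm
  fh <- sigm(sweep(z[1:H, , drop = FALSE] %*% params$Fh, 2, params$Fh_b, "+"))
  fw <- sigm(sweep(z[H + 1:W, , drop = FALSE] %*% params$Fw, 2, params$Fw_b, "+"))
  expect_equal(got$f_h, t(fh), tolerance = 1e-6)
  expect_equal(got$f_w, t(fw), tolerance = 1e-6)
  expect_true(all(got$f_h > 0 & got$f_h < 1))
  expect_true(all(got$f_w > 0 & got$f_w < 1))
})

test_that("gate application matches the triple-loop oracle and annihilates zero rows", {
  set.seed(24)
  x <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  fh <- matrix(runif(2 * 3), 2, 3)
  fw <- matrix(runif(2 * 4), 2, 4)
  y <- aca_apply(x, fh, fw)
  ref <- array(0, dim(x))
  for (c in 1:2) for (i in 1:3) for (j in 1:4) {
    ref[i, j, c] <- x[i, j, c] * fh[c, i] * fw[c, j]
  }
  expect_equal(y, ref, tolerance = 1e-6)
  # constant 0.5 gates scale by 1/4
  h5 <- matrix(0.5, 2, 3); w5 <- matrix(0.5, 2, 4)
  expect_equal(aca_apply(x, h5, w5), x / 4)
  # a zero f_h row annihilates that feature row
  fh0 <- fh; fh0[, 2] <- 0
  expect_true(all(aca_apply(x, fh0, fw)[2, , ] == 0))
})

test_that("ACA block output preserves shape and sign, and reduces to CA with g2 = 0", {
  set.seed(25)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  blk <- aca_block(4, r = 2)
  y <- aca_forward(blk, x)
  expect_equal(dim(y), dim(x))
  expect_true(all(sign(y) == sign(x) | x == 0))
  # reduction: with g1 = 1, g2 = 0 ACA equals the average-only CA baseline
  # given shared weights
  ca <- aca_block(4, r = 2, variant = "avg_only")
  for (nm in names(ca$params)) ca$params[[nm]]$value <- blk$params[[nm]]$value
  blk$params$g1$value <- 1
  blk$params$g2$value <- 0
  expect_identical(aca_forward(blk, x), aca_forward(ca, x))
})

test_that("SE baseline scales channels uniformly on constant input", {
  set.seed(26)
  blk <- se_block(3, r = 1)
  x <- array(rep(c(1, 2, 3), each = 16), c(4, 4, 3))
  y <- se_forward(blk, x)
  for (c in 1:3) {
    expect_equal(length(unique(round(as.vector(y[, , c] / x[, , c]), 10))), 1)
  }
})

test_that("window partition/merge is a bijection and shifting twice is the identity", {
  set.seed(27)
  x <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  for (sh in c(FALSE, TRUE)) {
    wp <- window_partition(x, 3, shifted = sh)
    expect_identical(wp$inverse(wp$windows), x)
  }
  # H = W = 4, M = 2: hand-checkable window indices
  m <- array(0, c(4, 4, 1)); m[, , 1] <- matrix(1:16, 4, 4)
  wp <- window_partition(m, 2)
  expect_equal(length(wp$windows), 4)
  expect_equal(as.vector(wp$windows[[1]]), c(1, 2, 5, 6))   # top-left window
  expect_equal(as.vector(wp$windows[[4]]), c(11, 12, 15, 16))
  # cyclic roll period: shifting an M x M map twice by floor(M/2) = identity
  z <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  r1 <- ag_val(ag_roll_hw(ag_tensor(z), -2, -2))
  r2 <- ag_val(ag_roll_hw(ag_tensor(r1), -2, -2))
  expect_identical(r2, z)
  expect_error(window_partition(x, 4), "divisible")
  expect_error(window_partition(x, 7), "exceeds")
})

test_that("relative position bias is shared across equal displacements", {
  M <- 4
  idx <- rel_pos_index(M)
  ii <- rep(1:M, times = M); jj <- rep(1:M, each = M)
  # same displacement -> same table entry, different -> different
  expect_equal(idx[1, 2], idx[5, 6])    # both displacement (+1 row, 0 col)?
  set.seed(28)
  for (k in 1:50) {
    p <- sample(M^2, 2); q <- sample(M^2, 2)
    dp <- c(ii[p[2]] - ii[p[1]], jj[p[2]] - jj[p[1]])
    dq <- c(ii[q[2]] - ii[q[1]], jj[q[2]] - jj[q[1]])
    if (all(dp == dq)) expect_equal(idx[p[1], p[2]], idx[q[1], q[2]])
    else expect_false(idx[p[1], p[2]] == idx[q[1], q[2]])
  }
})

test_that("patch self-attention matches a naive loop oracle and its limits", {
  set.seed(29)
  M <- 2; n <- 4; d <- 3
  for (i in 1:30) {
    Q <- matrix(rnorm(n * d), n); K <- matrix(rnorm(n * d), n)
    V <- matrix(rnorm(n * d), n)
    tab <- rnorm((2 * M - 1)^2)
    ga <- rnorm(1)
    got <- patch_self_attention(Q, K, V, tab, ga)
    # naive loop-softmax oracle
    B <- matrix(tab[rel_pos_index(M)], n, n)
    ref <- matrix(0, n, d)
    for (p in 1:n) {
      lg <- numeric(n)
      for (q in 1:n) lg[q] <- sum(Q[p, ] * K[q, ]) / sqrt(d) + ga * B[p, q]
      a <- exp(lg - max(lg)); a <- a / sum(a)
      for (q in 1:n) ref[p, ] <- ref[p, ] + a[q] * V[q, ]
    }
    expect_equal(got, ref, tolerance = 1e-6)
  }
  # ga = 0: standard scaled dot-product attention regardless of the table
  Q <- matrix(rnorm(n * d), n); K <- matrix(rnorm(n * d), n)
  V <- matrix(rnorm(n * d), n)
  expect_equal(patch_self_attention(Q, K, V, rnorm((2 * M - 1)^2), ga = 0),
               ref_softmax_rows(Q %*% t(K) / sqrt(d)) %*% V, tolerance = 1e-12)
  # zero Q, K with ga = 0: uniform attention -> column means of V
  expect_equal(patch_self_attention(matrix(0, n, d), matrix(0, n, d), V,
                                    rnorm((2 * M - 1)^2), ga = 0),
               matrix(rep(colMeans(V), each = n), n, d), tolerance = 1e-12)
})

test_that("softmax rows sum to one inside the GSA block", {
  z <- matrix(rnorm(36), 6, 6)
  p <- ag_val(ag_softmax_rows(ag_tensor(z)))
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)
})

test_that("GSA block has identity and shape contracts, and reduces to SW with the gate frozen", {
  set.seed(30)
  C <- 4
  x <- array(rnorm(6 * 6 * C), c(6, 6, C))
  blk <- gsa_block(C, M = 3, heads = 2)
  y <- gsa_forward(blk, x)
  expect_equal(dim(y), dim(x))
  # zeroed output projection + zeroed MLP second layer -> identity map
  idb <- gsa_block(C, M = 3, heads = 2)
  for (sub in idb$modules) {
    sub$params$Wproj$value[] <- 0; sub$params$bproj$value[] <- 0
    sub$params$Wm2$value[] <- 0; sub$params$bm2$value[] <- 0
  }
  expect_equal(gsa_forward(idb, x), x, tolerance = 1e-12)
  # reduction: ga frozen at 1 equals the SW baseline with shared weights
  sw <- gsa_block(C, M = 3, heads = 2, gate = "fixed1")
  for (nm in c("unshifted", "shifted")) {
    for (pn in names(sw$modules[[nm]]$params)) {
      sw$modules[[nm]]$params[[pn]]$value <- blk$modules[[nm]]$params[[pn]]$value
    }
  }
  blk$modules$unshifted$params$ga$value <- 1
  blk$modules$shifted$params$ga$value <- 1
  expect_equal(gsa_forward(blk, x), gsa_forward(sw, x), tolerance = 1e-12)
})

test_that("with zero Q/K the attention is position-only: permuting V permutes output", {
  set.seed(31)
  M <- 2; n <- 4; d <- 2
  V <- matrix(rnorm(n * d), n)
  tab <- rnorm((2 * M - 1)^2)
  base <- patch_self_attention(matrix(0, n, d), matrix(0, n, d), V, tab, ga = 1)
  # attention weights depend only on B; rows of the output are convex
  # combinations with position-determined weights
  B <- matrix(tab[rel_pos_index(M)], n, n)
  A <- ref_softmax_rows(B)
  expect_equal(base, A %*% V, tolerance = 1e-12)
})

test_that("single-window GSA equals the stagewise oracle", {
  set.seed(32)
  C <- 2; M <- 2
  x <- array(rnorm(M * M * C), c(M, M, C))
  blk <- gsa_block(C, M = M, heads = 1)
  got <- gsa_forward(blk, x)
  # stagewise reference using plain matrix arithmetic
  ln <- function(z, g, b) {
    mu <- rowMeans(z); v <- rowMeans((z - mu)^2)
    sweep(sweep((z - mu) / sqrt(v + 1e-5), 2, g, "*"), 2, b, "+")
  }
  stage <- function(tok, p, shifted) {
    # one window: the cyclic shift is a permutation of tokens; replicate it
    xm <- array(tok, c(M, M, C))
    if (shifted) xm <- ag_val(ag_roll_hw(ag_tensor(xm), -1, -1))
    tk <- matrix(xm, M * M, C)
    z <- ln(tk, p$ln1_g$value, p$ln1_b$value)
    qkv <- sweep(z %*% p$Wqkv$value, 2, p$bqkv$value, "+")
    Q <- qkv[, 1:C]; K <- qkv[, C + 1:C]; V <- qkv[, 2 * C + 1:C]
    B <- matrix(p$B1$value[rel_pos_index(M)], M^2, M^2)
    A <- ref_softmax_rows(Q %*% t(K) / sqrt(C) + p$ga$value * B)
    att <- sweep((A %*% V) %*% p$Wproj$value, 2, p$bproj$value, "+")
    am <- array(att, c(M, M, C))
    if (shifted) am <- ag_val(ag_roll_hw(ag_tensor(am), 1, 1))
    t1 <- matrix(am, M * M, C) + tok
    z2 <- ln(t1, p$ln2_g$value, p$ln2_b$value)
    h <- pmax(sweep(z2 %*% p$Wm1$value, 2, p$bm1$value, "+"), 0)
    t1 + sweep(h %*% p$Wm2$value, 2, p$bm2$value, "+")
  }
  tok <- matrix(x, M * M, C)
  tok <- stage(tok, blk$modules$unshifted$params, FALSE)
  tok <- stage(tok, blk$modules$shifted$params, TRUE)
  expect_equal(got, array(tok, c(M, M, C)), tolerance = 1e-6)
})

test_that("baseline block constructors share the gated interfaces", {
  set.seed(33)
  b <- baseline_blocks(4, r = 2, M = 2, heads = 1)
  x <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  for (nm in names(b)) {
    y <- b[[nm]]$forward(x)
    expect_equal(dim(y), dim(x), info = nm)
  }
})
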