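# Finite-difference checks of the tape's primitive operations on tiny
# shapes.  Central differences with small h; relative tolerance 1e-6 for
# smooth primitives.

fdCheck <- function(fwd, x0, gAnalytic, h = 1e-6, idx = NULL, tol = 1e-5) {
  if (is.null(idx)) idx <- seq_along(x0)
  for (i in idx) {
    xp <- x0; xp[i] <- xp[i] + h
    xm <- x0; xm[i] <- xm[i] - h
    fd <- (fwd(xp) - fwd(xm)) / (2 * h)
    expect_lt(abs(fd - gAnalytic[i]) / max(abs(fd), 1e-6), tol)
  }
}

test_that("convolution gradients match finite differences (2-D and 3-D)", {
  set.seed(50)
  for (nd in 2:3) {
    sdim <- if (nd == 2) c(5L, 6L) else c(4L, 4L, 3L)
    inch <- 2L; outch <- 3L; k <- 3L; pad <- 1L
    np <- prod(sdim)
    x0 <- matrix(rnorm(np * inch), np, inch)
    W0 <- matrix(rnorm(k^nd * inch * outch, sd = 0.3), k^nd * inch, outch)
    b0 <- rnorm(outch)
    wmat <- matrix(rnorm(np * outch), np, outch)
    run <- function(xv, Wv, bv) {
      tp <- synthreg:::.tape_new()
      xn <- synthreg:::.ad_leaf(tp, xv, req = TRUE, sdim = sdim)
      Wn <- synthreg:::.ad_leaf(tp, Wv, req = TRUE)
      bn <- synthreg:::.ad_leaf(tp, bv, req = TRUE)
      out <- synthreg:::.ad_conv(tp, xn, Wn, bn, k, 1L, pad)
      loss <- synthreg:::.ad_make(tp, sum(out$v * wmat), list(out),
        function(nd) synthreg:::.acc(out, nd$g * wmat))
      synthreg:::.ad_backward(tp, loss)
      list(v = loss$v, gx = xn$g, gW = Wn$g, gb = bn$g)
    }
    r <- run(x0, W0, b0)
    fdCheck(function(x) run(x, W0, b0)$v, x0, r$gx,
            idx = sample(length(x0), 4))
    fdCheck(function(W) run(x0, W, b0)$v, W0, r$gW,
            idx = sample(length(W0), 4))
    fdCheck(function(b) run(x0, W0, b)$v, b0, r$gb)
  }
})

test_that("strided (im2col) convolution gradients match finite differences", {
  set.seed(51)
  sdim <- c(8L, 8L); inch <- 2L; outch <- 3L; k <- 3L
  np <- prod(sdim)
  x0 <- matrix(rnorm(np * inch), np, inch)
  W0 <- matrix(rnorm(k^2 * inch * outch, sd = 0.3), k^2 * inch, outch)
  b0 <- rnorm(outch)
  wmat <- matrix(rnorm(16 * outch), 16, outch)
  run <- function(xv, Wv) {
    tp <- synthreg:::.tape_new()
    xn <- synthreg:::.ad_leaf(tp, xv, req = TRUE, sdim = sdim)
    Wn <- synthreg:::.ad_leaf(tp, Wv, req = TRUE)
    bn <- synthreg:::.ad_leaf(tp, b0, req = TRUE)
    out <- synthreg:::.ad_conv(tp, xn, Wn, bn, k, 2L, 1L)
    loss <- synthreg:::.ad_make(tp, sum(out$v * wmat), list(out),
      function(nd) synthreg:::.acc(out, nd$g * wmat))
    synthreg:::.ad_backward(tp, loss)
    list(v = loss$v, gx = xn$g, gW = Wn$g)
  }
  r <- run(x0, W0)
  fdCheck(function(x) run(x, W0)$v, x0, r$gx, idx = sample(length(x0), 4))
  fdCheck(function(W) run(x0, W)$v, W0, r$gW, idx = sample(length(W0), 4))
})

test_that("instance-norm, resize, grid-sample and bending gradients match
           finite differences", {
  set.seed(52)
  sdim <- c(5L, 5L)
  np <- prod(sdim)
  x0 <- matrix(rnorm(np * 3), np, 3)
  wmat <- matrix(rnorm(np * 3), np, 3)
  # instance norm
  run_in <- function(xv) {
    tp <- synthreg:::.tape_new()
    xn <- synthreg:::.ad_leaf(tp, xv, req = TRUE, sdim = sdim)
    out <- synthreg:::.ad_instnorm(tp, xn, 1e-5)
    loss <- synthreg:::.ad_make(tp, sum(out$v * wmat), list(out),
      function(nd) synthreg:::.acc(out, nd$g * wmat))
    synthreg:::.ad_backward(tp, loss)
    list(v = loss$v, gx = xn$g)
  }
  r <- run_in(x0)
  fdCheck(function(x) run_in(x)$v, x0, r$gx, idx = sample(length(x0), 5))
  # resize
  dst <- c(9L, 8L)
  wr <- matrix(rnorm(prod(dst) * 3), prod(dst), 3)
  run_rz <- function(xv) {
    tp <- synthreg:::.tape_new()
    xn <- synthreg:::.ad_leaf(tp, xv, req = TRUE, sdim = sdim)
    out <- synthreg:::.ad_resize(tp, xn, dst)
    loss <- synthreg:::.ad_make(tp, sum(out$v * wr), list(out),
      function(nd) synthreg:::.acc(out, nd$g * wr))
    synthreg:::.ad_backward(tp, loss)
    list(v = loss$v, gx = xn$g)
  }
  r <- run_rz(x0)
  fdCheck(function(x) run_rz(x)$v, x0, r$gx, idx = sample(length(x0), 5))
  # grid sample wrt data and grid (interior points, off-node coordinates)
  g0 <- gridCoords(makeIdentityGrid(c(4L, 4L))) * 0.63 +
    matrix(runif(32, -0.02, 0.02), 16, 2)
  wg <- matrix(rnorm(16 * 3), 16, 3)
  run_gs <- function(xv, gv) {
    tp <- synthreg:::.tape_new()
    xn <- synthreg:::.ad_leaf(tp, xv, req = TRUE, sdim = sdim)
    gn <- synthreg:::.ad_leaf(tp, gv, req = TRUE, sdim = c(4L, 4L))
    out <- synthreg:::.ad_gridsample(tp, xn, gn, c(4L, 4L))
    loss <- synthreg:::.ad_make(tp, sum(out$v * wg), list(out),
      function(nd) synthreg:::.acc(out, nd$g * wg))
    synthreg:::.ad_backward(tp, loss)
    list(v = loss$v, gx = xn$g, gg = gn$g)
  }
  r <- run_gs(x0, g0)
  fdCheck(function(x) run_gs(x, g0)$v, x0, r$gx, idx = sample(length(x0), 5))
  fdCheck(function(g) run_gs(x0, g)$v, g0, r$gg, idx = sample(length(g0), 5))
  # bending energy
  u0 <- matrix(rnorm(np * 2, sd = 0.1), np, 2)
  run_be <- function(uv) {
    tp <- synthreg:::.tape_new()
    un <- synthreg:::.ad_leaf(tp, uv, req = TRUE, sdim = sdim)
    out <- synthreg:::.ad_bending(tp, un)
    synthreg:::.ad_backward(tp, out)
    list(v = out$v, gu = un$g)
  }
  r <- run_be(u0)
  fdCheck(function(u) run_be(u)$v, u0, r$gu, idx = sample(length(u0), 5))
})

test_that("batched stack/part round-trips values and distributes gradients", {
  set.seed(53)
  sdim <- c(4L, 4L)
  xs <- lapply(1:3, function(i) matrix(rnorm(16 * 2), 16, 2))
  tp <- synthreg:::.tape_new()
  nodes <- lapply(xs, function(x)
    synthreg:::.ad_leaf(tp, x, req = TRUE, sdim = sdim))
  st <- synthreg:::.ad_stack(tp, nodes)
  expect_identical(st$B, 3L)
  p2 <- synthreg:::.ad_part(tp, st, 2L)
  expect_identical(p2$v, xs[[2]])
  loss <- synthreg:::.ad_make(tp, sum(p2$v^2), list(p2),
    function(nd) synthreg:::.acc(p2, nd$g * 2 * p2$v))
  synthreg:::.ad_backward(tp, loss)
  expect_equal(nodes[[2]]$g, 2 * xs[[2]], tolerance = 1e-12)
  # untouched items receive exactly zero gradient through the stack
  expect_identical(unique(as.vector(nodes[[1]]$g)), 0)
})
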