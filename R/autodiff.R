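# Reverse-mode automatic differentiation tape.
#
# The training objective couples every network through re-encodings and
# warps (a circular computing graph), so gradients are obtained by taping the
# forward pass and sweeping it once in reverse.  Nodes are environments with
# value `v`, accumulated gradient `g`, a `back` closure, a `req` flag
# (whether any ancestor is a trainable parameter) and the spatial metadata of
# the value: `sdim` (per-item spatial extents) and `B` (batch count; stages
# of the forward pass run several images through the same network at once,
# stacked as row blocks of one matrix).  Metadata lives on the node, never as
# attributes of the value, so no hidden copies of large matrices occur.
#
# Value layout matches the compiled kernels: feature maps are ((B*npos) x C)
# matrices; scalars are length-1 numerics.

.tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 1024L)
  tp$k <- 0L
  tp
}

.tape_push <- function(tape, nd) {
  k <- tape$k + 1L
  if (k > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[k]] <- nd
  tape$k <- k
  nd
}

.ad_leaf <- function(tape, v, req = FALSE, sdim = NULL, B = 1L) {
  if (is.null(sdim)) sdim <- attr(v, "sdim")
  nd <- new.env(parent = emptyenv())
  nd$v <- v; nd$g <- NULL; nd$back <- NULL; nd$req <- req
  nd$sdim <- sdim; nd$B <- B
  .tape_push(tape, nd)
}

.ad_make <- function(tape, v, parents, back, sdim = NULL, B = 1L) {
  req <- FALSE
  for (p in parents) if (p$req) { req <- TRUE; break }
  nd <- new.env(parent = emptyenv())
  nd$v <- v; nd$g <- NULL; nd$req <- req
  nd$sdim <- sdim; nd$B <- B
  nd$back <- if (req) back else NULL
  .tape_push(tape, nd)
}

# accumulate gradient `g` into node `p` (skipping constants)
.acc <- function(p, g) {
  if (p$req) p$g <- if (is.null(p$g)) g else p$g + g
  invisible(NULL)
}

# reverse sweep from a scalar root
.ad_backward <- function(tape, root) {
  root$g <- 1
  for (i in seq(tape$k, 1L)) {
    nd <- tape$nodes[[i]]
    if (nd$req && !is.null(nd$back) && !is.null(nd$g)) nd$back(nd)
  }
  invisible(NULL)
}

.sdim <- function(x) attr(x, "sdim")

.with_sdim <- function(v, sdim, B = 1L) {
  attr(v, "sdim") <- as.integer(sdim)
  attr(v, "B") <- as.integer(B)
  v
}

# ---- primitive operations -------------------------------------------------

.ad_conv <- function(tape, x, W, b, k, stride, pad, single = FALSE) {
  sdim <- x$sdim
  B <- x$B
  out_sdim <- (sdim + 2L * pad - k) %/% stride + 1L
  if (any(out_sdim < 1L)) stop("convolution output would be empty")
  inch <- ncol(x$v)
  if (stride == 1L) {
    # direct tap-wise convolution: no column matrix is materialised
    v <- .cpp_dconv_fw(x$v, sdim, W$v, b$v, k, pad, B, single)
    return(.ad_make(tape, v, list(x, W, b), function(nd) {
      r <- .cpp_dconv_bw(x$v, sdim, W$v, nd$g, k, pad, B, x$req, single)
      .acc(W, r$gW)
      .acc(b, r$gb)
      if (x$req) .acc(x, r$gx)
    }, sdim = out_sdim, B = B))
  }
  cols <- .cpp_im2col(x$v, sdim, k, stride, pad, B)  # cached for the backward
  v <- cols %*% W$v
  v <- v + rep(b$v, each = nrow(v))
  .ad_make(tape, v, list(x, W, b), function(nd) {
    .acc(W, crossprod(cols, nd$g))
    .acc(b, colSums(nd$g))
    if (x$req)
      .acc(x, .cpp_col2im(nd$g %*% t(W$v), sdim, inch, k, stride, pad, B))
  }, sdim = out_sdim, B = B)
}

# stack B same-shape items (each an unbatched node) into one batched node
.ad_stack <- function(tape, nodes) {
  B <- length(nodes)
  if (B == 1L) return(nodes[[1]])
  sdim <- nodes[[1]]$sdim
  m <- nrow(nodes[[1]]$v)
  v <- do.call(rbind, lapply(nodes, function(n) n$v))
  .ad_make(tape, v, nodes, function(nd) {
    for (i in seq_len(B)) {
      rows <- ((i - 1L) * m + 1L):(i * m)
      .acc(nodes[[i]], nd$g[rows, , drop = FALSE])
    }
  }, sdim = sdim, B = B)
}

# extract item i of a batched node
.ad_part <- function(tape, x, i) {
  B <- x$B
  if (B == 1L) return(x)
  m <- nrow(x$v) %/% B
  rows <- ((i - 1L) * m + 1L):(i * m)
  v <- x$v[rows, , drop = FALSE]
  .ad_make(tape, v, list(x), function(nd) {
    g <- matrix(0, nrow(x$v), ncol(x$v))
    g[rows, ] <- nd$g
    .acc(x, g)
  }, sdim = x$sdim, B = 1L)
}

.ad_dense <- function(tape, x, W, b) {
  v <- x$v %*% W$v + rep(b$v, each = nrow(x$v))
  .ad_make(tape, v, list(x, W, b), function(nd) {
    if (x$req) .acc(x, nd$g %*% t(W$v))
    .acc(W, t(x$v) %*% nd$g)
    .acc(b, colSums(nd$g))
  })
}

.ad_lrelu <- function(tape, x, slope = 0.2) {
  v <- .cpp_lrelu_fw(x$v, slope)
  .ad_make(tape, v, list(x), function(nd) {
    .acc(x, .cpp_lrelu_bw(x$v, nd$g, slope))
  }, sdim = x$sdim, B = x$B)
}

.ad_tanh <- function(tape, x) {
  v <- tanh(x$v)
  .ad_make(tape, v, list(x), function(nd) .acc(x, nd$g * (1 - v * v)),
           sdim = x$sdim, B = x$B)
}

.ad_scale <- function(tape, x, k) {
  .ad_make(tape, x$v * k, list(x), function(nd) .acc(x, nd$g * k),
           sdim = x$sdim, B = x$B)
}

.ad_add <- function(tape, a, b) {
  .ad_make(tape, a$v + b$v, list(a, b), function(nd) {
    .acc(a, nd$g); .acc(b, nd$g)
  }, sdim = a$sdim, B = a$B)
}

.ad_sub <- function(tape, a, b) {
  .ad_make(tape, a$v - b$v, list(a, b), function(nd) {
    .acc(a, nd$g); .acc(b, -nd$g)
  }, sdim = a$sdim, B = a$B)
}

.ad_concat <- function(tape, a, b) {
  ca <- ncol(a$v)
  .ad_make(tape, cbind(a$v, b$v), list(a, b), function(nd) {
    .acc(a, nd$g[, seq_len(ca), drop = FALSE])
    .acc(b, nd$g[, -seq_len(ca), drop = FALSE])
  }, sdim = a$sdim, B = a$B)
}

# instance normalisation: per-sample, per-channel statistics over spatial
# positions (population variance); batched inputs normalise each row block
# independently
.ad_instnorm <- function(tape, x, eps = 1e-5) {
  B <- x$B
  r <- .cpp_instnorm_fw(x$v, B, eps)
  y <- r$y
  s <- r$s
  .ad_make(tape, y, list(x), function(nd) {
    .acc(x, .cpp_instnorm_bw(y, s, nd$g, B))
  }, sdim = x$sdim, B = B)
}

.ad_gap <- function(tape, x) {
  m <- nrow(x$v)
  v <- matrix(colMeans(x$v), nrow = 1)
  .ad_make(tape, v, list(x), function(nd) {
    .acc(x, matrix(rep(nd$g / m, each = m), nrow = m))
  })
}

# pull-warp resampling; differentiable in both the data and the grid
.ad_gridsample <- function(tape, x, grid, out_sdim, nearest = FALSE) {
  in_sdim <- x$sdim
  v <- .cpp_grid_sample_fw(x$v, in_sdim, grid$v, nearest)
  .ad_make(tape, v, list(x, grid), function(nd) {
    r <- .cpp_grid_sample_bw(x$v, in_sdim, grid$v, nd$g, x$req, grid$req)
    if (x$req) .acc(x, r$gx)
    if (grid$req) .acc(grid, r$ggrid)
  }, sdim = as.integer(out_sdim), B = 1L)
}

# linear resize of each batch item onto a target grid (align-corners)
.ad_resize <- function(tape, x, target_shape) {
  src <- x$sdim
  B <- x$B
  dst <- as.integer(target_shape)
  v <- .cpp_resize_fw(x$v, src, dst, B)
  .ad_make(tape, v, list(x), function(nd) {
    .acc(x, .cpp_resize_bw(nd$g, src, dst, B))
  }, sdim = dst, B = B)
}

# affine grid: homogeneous coordinates (constant) times t(A)
.ad_affine_grid <- function(tape, A, shape) {
  P <- .homog_coords(shape)
  v <- P %*% t(A$v)
  .ad_make(tape, v, list(A), function(nd) .acc(A, t(nd$g) %*% P),
           sdim = as.integer(shape), B = 1L)
}

.ad_rms <- function(tape, a, b) {
  d <- a$v - b$v
  N <- length(d)
  v <- sqrt(sum(d * d) / N)
  .ad_make(tape, v, list(a, b), function(nd) {
    g <- (nd$g / (N * max(v, 1e-12))) * d
    .acc(a, g)
    .acc(b, -g)
  })
}

# bending energy of a displacement field via a cached second-difference
# stencil operator D: value = sum((D u)^2) / (n_interior * n_components)
.ad_bending <- function(tape, u, type = "bending") {
  sdim <- u$sdim
  # a grid with no interior points carries no curvature information
  if (any(sdim < 3L)) return(.ad_leaf(tape, 0))
  D <- .bending_operator(sdim, type)
  ncomp <- ncol(u$v)
  ninter <- attr(D, "ninterior")
  e <- as.matrix(D %*% u$v)
  denom <- ninter * ncomp
  v <- sum(e * e) / denom
  .ad_make(tape, v, list(u), function(nd) {
    .acc(u, as.matrix(Matrix::crossprod(D, e)) * (2 * nd$g / denom))
  })
}

.ad_sum <- function(tape, nodes) {
  v <- 0
  for (nd in nodes) v <- v + nd$v
  .ad_make(tape, v, nodes, function(nd) {
    for (p in nodes) .acc(p, nd$g)
  })
}

# ---- bending-energy stencil -----------------------------------------------

# Sparse operator of all second-order central differences (unmixed, and mixed
# partials counted for both axis orders via a sqrt(2) row scale), evaluated on
# interior points only.  The "laplacian" variant penalises the squared
# Laplacian (sum of unmixed second differences per point) instead.
.bending_operator <- function(sdim, type = c("bending", "laplacian")) {
  type <- match.arg(type)
  key <- paste0("bend:", type, ":", paste(sdim, collapse = ","))
  .cache_get(key, function() {
    n <- length(sdim)
    if (any(sdim < 3L)) stop("field extents must be >= 3 for bending energy")
    IDX <- array(seq_len(prod(sdim)), dim = sdim)
    interior <- lapply(sdim, function(S) 2:(S - 1L))
    sub <- function(off) {
      idx <- mapply(function(r, o) r + o, interior, as.list(off),
                    SIMPLIFY = FALSE)
      as.vector(do.call(`[`, c(list(IDX), idx)))
    }
    ninter <- prod(sdim - 2L)
    rows <- list(); cols <- list(); vals <- list()
    nrow_total <- 0L
    push <- function(terms) {
      # terms: list of (offset vector, coefficient)
      base <- nrow_total
      for (tm in terms) {
        rows[[length(rows) + 1L]] <<- base + seq_len(ninter)
        cols[[length(cols) + 1L]] <<- sub(tm[[1]])
        vals[[length(vals) + 1L]] <<- rep(tm[[2]], ninter)
      }
      nrow_total <<- nrow_total + ninter
    }
    ei <- function(a) { e <- integer(n); e[a] <- 1L; e }
    if (type == "bending") {
      for (a in seq_len(n))
        push(list(list(ei(a), 1), list(-ei(a), 1), list(integer(n), -2)))
      sq2 <- sqrt(2)  # mixed partials appear for both axis orders
      for (a in seq_len(n - 1)) for (b in (a + 1):n)
        push(list(list(ei(a) + ei(b), sq2 / 4), list(ei(a) - ei(b), -sq2 / 4),
                  list(-ei(a) + ei(b), -sq2 / 4),
                  list(-ei(a) - ei(b), sq2 / 4)))
    } else {
      # one row per interior point: the discrete Laplacian
      terms <- list()
      for (a in seq_len(n)) {
        terms[[length(terms) + 1L]] <- list(ei(a), 1)
        terms[[length(terms) + 1L]] <- list(-ei(a), 1)
      }
      terms[[length(terms) + 1L]] <- list(integer(n), -2 * n)
      push(terms)
    }
    D <- Matrix::sparseMatrix(i = unlist(rows), j = unlist(cols),
                              x = unlist(vals),
                              dims = c(nrow_total, prod(sdim)))
    attr(D, "ninterior") <- ninter
    D
  })
}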