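# Lightweight reverse-mode automatic differentiation on dense matrices.
#
# A tape records each primitive as a node holding its value, the ids of its
# adref parents, and a backward closure mapping the upstream gradient to
# per-parent gradients. Every op accepts a mix of tape references and plain
# matrices; when no argument is on a tape the op computes eagerly and
# returns a plain matrix, so the same network code runs in no-grad
# (inference) and grad (training) mode.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

is_ad <- function(x) inherits(x, "adref")

vof <- function(x) if (is_ad(x)) x$tape$nodes[[x$id]]$val else x

ad_new <- function(tape, val, parents = integer(0), bw = NULL) {
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- list(val = val, parents = parents, bw = bw)
  structure(list(id = tape$n, tape = tape), class = "adref")
}

# find the tape among op arguments (NULL if all plain)
tape_of <- function(...) {
  for (x in list(...)) if (is_ad(x)) return(x$tape)
  NULL
}

ad_leaf <- function(tape, val) ad_new(tape, val)

# parents/grads helper: build node from named arg list; bw receives upstream
# gradient G and must return a list of gradients for the adref args, in order
ad_record <- function(val, args, bw) {
  tp <- do.call(tape_of, args)
  if (is.null(tp)) return(val)
  which_ad <- vapply(args, is_ad, logical(1))
  parents <- vapply(args[which_ad], function(a) a$id, integer(1))
  ad_new(tp, val, parents, function(G) bw(G)[which_ad])
}

ad_matmul <- function(a, b) {
  A <- vof(a); B <- vof(b)
  ad_record(A %*% B, list(a, b),
            function(G) list(G %*% t(B), t(A) %*% G))
}

ad_add <- function(a, b) {
  A <- vof(a); B <- vof(b)
  ad_record(A + B, list(a, b), function(G) list(G, G))
}

# broadcast-add a length-d bias vector to every row
ad_add_bias <- function(a, bias) {
  A <- vof(a); bv <- vof(bias)
  val <- A + matrix(bv, nrow(A), length(bv), byrow = TRUE)
  ad_record(val, list(a, bias),
            function(G) list(G, colSums(G)))
}

ad_mul <- function(a, b) {
  A <- vof(a); B <- vof(b)
  ad_record(A * B, list(a, b), function(G) list(G * B, G * A))
}

ad_scale <- function(a, s) {
  A <- vof(a)
  ad_record(A * s, list(a), function(G) list(G * s))
}

ad_add_const <- function(a, m) {
  A <- vof(a)
  ad_record(A + m, list(a), function(G) list(G))
}

ad_mul_const <- function(a, m) {
  A <- vof(a)
  ad_record(A * m, list(a), function(G) list(G * m))
}

# fused affine map: x %*% W + bias (one tape node instead of two)
ad_linear <- function(x, W, bias) {
  X <- vof(x); Wv <- vof(W); bv <- vof(bias)
  val <- X %*% Wv
  val <- val + matrix(bv, nrow(val), length(bv), byrow = TRUE)
  ad_record(val, list(x, W, bias),
            function(G) list(G %*% t(Wv), crossprod(X, G), colSums(G)))
}

ad_relu <- function(a) {
  A <- vof(a)
  pos <- A > 0
  ad_record(A * pos, list(a), function(G) list(G * pos))
}

ad_gelu <- function(a) {
  A <- vof(a)
  Phi <- stats::pnorm(A)
  val <- A * Phi
  ad_record(val, list(a),
            function(G) list(G * (Phi + A * stats::dnorm(A))))
}

ad_concat_cols <- function(parts) {
  vals <- lapply(parts, vof)
  widths <- vapply(vals, ncol, integer(1))
  val <- do.call(cbind, vals)
  ends <- cumsum(widths); starts <- ends - widths + 1L
  ad_record(val, parts, function(G)
    lapply(seq_along(parts), function(p) G[, starts[p]:ends[p], drop = FALSE]))
}

ad_gather_rows <- function(a, idx) {
  A <- vof(a)
  ad_record(A[idx, , drop = FALSE], list(a), function(G) {
    M <- matrix(0, nrow(A), ncol(A))
    acc <- rowsum(G, group = idx, reorder = FALSE)
    rid <- as.integer(rownames(acc))
    M[rid, ] <- acc
    list(M)
  })
}

# out[i, ] = sum over rows r with idx[r] == i of a[r, ]
ad_scatter_rows <- function(a, idx, n_out) {
  A <- vof(a)
  out <- matrix(0, n_out, ncol(A))
  acc <- rowsum(A, group = idx, reorder = FALSE)
  out[as.integer(rownames(acc)), ] <- acc
  ad_record(out, list(a), function(G) list(G[idx, , drop = FALSE]))
}

# out[r, c] = a[r, cols[r, c]]; cols is an integer matrix with nrow(a) rows
ad_rowgather <- function(a, cols) {
  A <- vof(a)
  nr <- nrow(A); nc <- ncol(cols)
  val <- matrix(A[cbind(rep(seq_len(nr), nc), as.vector(cols))], nr, nc)
  ad_record(val, list(a), function(G) {
    M <- matrix(0, nr, ncol(A))
    for (cc in seq_len(nc)) {
      ii <- cbind(seq_len(nr), cols[, cc])
      M[ii] <- M[ii] + G[, cc]
    }
    list(M)
  })
}

# out = column vector of a[idx2]; idx2 an m x 2 (row, col) index matrix
ad_pick <- function(a, idx2) {
  A <- vof(a)
  val <- matrix(A[idx2], ncol = 1L)
  ad_record(val, list(a), function(G) {
    M <- matrix(0, nrow(A), ncol(A))
    # accumulate duplicates one at a time
    for (r in seq_len(nrow(idx2))) M[idx2[r, 1], idx2[r, 2]] <-
        M[idx2[r, 1], idx2[r, 2]] + G[r, 1]
    list(M)
  })
}

ad_concat_rows <- function(parts) {
  vals <- lapply(parts, vof)
  heights <- vapply(vals, nrow, integer(1))
  val <- do.call(rbind, vals)
  ends <- cumsum(heights); starts <- ends - heights + 1L
  ad_record(val, parts, function(G)
    lapply(seq_along(parts), function(p) G[starts[p]:ends[p], , drop = FALSE]))
}

# out[, c] = a[, perm[c]]
ad_permute_cols <- function(a, perm) {
  A <- vof(a)
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  ad_record(A[, perm, drop = FALSE], list(a),
            function(G) list(G[, inv, drop = FALSE]))
}

ad_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  A <- vof(a); g <- vof(gamma); b <- vof(beta)
  mu <- rowMeans(A)
  xc <- A - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gm <- matrix(g, nrow(A), ncol(A), byrow = TRUE)
  val <- xhat * gm + matrix(b, nrow(A), ncol(A), byrow = TRUE)
  ad_record(val, list(a, gamma, beta), function(G) {
    dgamma <- colSums(G * xhat)
    dbeta <- colSums(G)
    dxhat <- G * gm
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
    list(dx, dgamma, dbeta)
  })
}

ad_dropout <- function(a, rate, train = FALSE) {
  if (!train || rate <= 0) return(a)
  A <- vof(a)
  mask <- matrix((stats::runif(length(A)) >= rate) / (1 - rate),
                 nrow(A), ncol(A))
  ad_record(A * mask, list(a), function(G) list(G * mask))
}

ad_logsoftmax <- function(a) {
  A <- vof(a)
  mx <- A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]
  z <- A - mx
  lse <- log(rowSums(exp(z)))
  val <- z - lse
  ad_record(val, list(a),
            function(G) list(G - exp(val) * rowSums(G)))
}

ad_sum <- function(a) {
  A <- vof(a)
  ad_record(matrix(sum(A), 1L, 1L), list(a),
            function(G) list(matrix(G[1, 1], nrow(A), ncol(A))))
}

# run backward from a scalar node; returns accessor(ref) -> gradient matrix
ad_backward <- function(loss) {
  stopifnot(is_ad(loss))
  tp <- loss$tape
  val <- vof(loss)
  stopifnot(length(val) == 1L)
  grads <- vector("list", tp$n)
  grads[[loss$id]] <- matrix(1, 1L, 1L)
  for (id in seq(tp$n, 1L)) {
    g <- grads[[id]]
    node <- tp$nodes[[id]]
    if (is.null(g) || is.null(node$bw)) next
    pg <- node$bw(g)
    for (p in seq_along(node$parents)) {
      pid <- node$parents[p]
      grads[[pid]] <- if (is.null(grads[[pid]])) pg[[p]] else grads[[pid]] + pg[[p]]
    }
  }
  function(ref) {
    g <- grads[[ref$id]]
    if (is.null(g)) {
      v <- vof(ref)
      g <- if (is.matrix(v)) matrix(0, nrow(v), ncol(v)) else numeric(length(v))
    }
    g
  }
}

# apply f to the leaves of a nested list, where is_leaf() decides what
# counts as a leaf (adrefs are lists, so rapply() cannot be used here)
map_leaves <- function(x, f, is_leaf) {
  if (is_leaf(x)) return(f(x))
  if (is.list(x)) return(lapply(x, map_leaves, f = f, is_leaf = is_leaf))
  x
}

# register a (possibly nested) named list of parameter matrices on a tape;
# leaves that are already tape refs pass through untouched, so a single
# registration can be shared by several forward passes on one tape
ad_params <- function(tape, plist) {
  map_leaves(plist, function(m) if (is_ad(m)) m else ad_leaf(tape, m),
             is_leaf = function(x) is.numeric(x) || is_ad(x))
}

# collect gradients for a registered parameter list
ad_collect_grads <- function(gradfn, prefs) {
  map_leaves(prefs, gradfn, is_leaf = is_ad)
}
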