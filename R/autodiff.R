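# Tape-based reverse-mode automatic differentiation over dense matrices.
#
# The pre-installed R stack has no deep-learning framework, so the encoders in
# this package run on this minimal engine. Nodes are integer handles into a
# tape; each op records its parents and a backward closure. All values are
# base-R numeric matrices.

#' Create a fresh autodiff tape
#'
#' A tape records every intermediate value of a forward pass together with the
#' closures needed to backpropagate through it. One tape per forward pass.
#'
#' @return An environment holding the tape state.
#' @keywords internal
ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  # hashed environments mutate in place; a list held in an environment slot
  # would be fully copied on every `tp$val[[k]] <- v` complex assignment
  tp$v <- new.env(hash = TRUE, parent = emptyenv(), size = 1024L)
  tp$p <- new.env(hash = TRUE, parent = emptyenv(), size = 1024L)
  tp$b <- new.env(hash = TRUE, parent = emptyenv(), size = 1024L)
  tp$k <- 0L
  tp
}

# cached node keys (environment subscripts must be strings)
AD_KEYS <- as.character(seq_len(32768L))
adk <- function(i) if (i <= 32768L) AD_KEYS[[i]] else as.character(i)

# register a node; parents is an integer vector, bw a function(grad)->list of
# parent gradients (same order as parents, NULL entries allowed)
ad_node <- function(tp, val, parents = integer(0), bw = NULL) {
  k <- tp$k + 1L
  tp$k <- k
  ck <- adk(k)
  tp$v[[ck]] <- val
  if (!is.null(bw)) {
    tp$b[[ck]] <- bw
    tp$p[[ck]] <- parents
  }
  k
}

#' Fetch the value of a tape node
#' @keywords internal
ad_value <- function(tp, i) {
  force(i)
  tp$v[[adk(i)]]
}

# leaf holding a constant (no gradient tracked)
ad_const <- function(tp, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  ad_node(tp, x)
}

# leaf holding a parameter matrix; gradient retrievable after ad_backward
ad_leaf <- function(tp, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  ad_node(tp, x, bw = FALSE) # marker: wants gradient, has no parents
}

#' Reverse sweep from a scalar root node
#'
#' @param tp tape
#' @param root node index of a 1x1 scalar
#' @return invisibly, the list of gradients indexed by node id (also stored in
#'   `tp$grad`)
#' @keywords internal
ad_backward <- function(tp, root) {
  gr <- vector("list", tp$k)
  rv <- tp$v[[adk(root)]]
  stopifnot(length(rv) == 1L)
  gr[[root]] <- matrix(1, 1L, 1L)
  for (i in seq.int(tp$k, 1L)) {
    g <- gr[[i]]
    if (is.null(g)) next
    bwf <- tp$b[[adk(i)]]
    if (is.null(bwf) || identical(bwf, FALSE)) next
    pg <- bwf(g)
    ps <- tp$p[[adk(i)]]
    for (j in seq_along(ps)) {
      gj <- pg[[j]]
      if (is.null(gj)) next
      p <- ps[[j]]
      gr[[p]] <- if (is.null(gr[[p]])) gj else gr[[p]] + gj
    }
  }
  tp$grad <- gr
  invisible(gr)
}

# gradient of a leaf after ad_backward (zero matrix if unused)
ad_grad <- function(tp, i) {
  force(i)
  g <- tp$grad[[i]]
  if (is.null(g)) g <- array(0, dim(tp$v[[adk(i)]]))
  g
}

# ---- primitive ops ---------------------------------------------------------

ad_mm <- function(tp, a, b) {
  force(a); force(b)
  av <- tp$v[[adk(a)]]; bv <- tp$v[[adk(b)]]
  ad_node(tp, av %*% bv, c(a, b), function(g) {
    list(g %*% t(bv), crossprod(av, g))
  })
}

ad_add <- function(tp, a, b) {
  force(a); force(b)
  av <- tp$v[[adk(a)]]; bv <- tp$v[[adk(b)]]
  ad_node(tp, av + bv, c(a, b), function(g) list(g, g))
}

ad_sub <- function(tp, a, b) {
  force(a); force(b)
  ad_node(tp, tp$v[[adk(a)]] - tp$v[[adk(b)]], c(a, b), function(g) list(g, -g))
}

# row-broadcast bias: a is n x k, b is 1 x k
ad_bias <- function(tp, a, b) {
  force(a); force(b)
  av <- tp$v[[adk(a)]]; bv <- tp$v[[adk(b)]]
  # column-major recycling: element (i,j) gets bv[j]
  ad_node(tp, av + rep(as.numeric(bv), each = nrow(av)), c(a, b), function(g) {
    list(g, matrix(colSums(g), 1L))
  })
}

ad_mul <- function(tp, a, b) {
  force(a); force(b)
  av <- tp$v[[adk(a)]]; bv <- tp$v[[adk(b)]]
  ad_node(tp, av * bv, c(a, b), function(g) list(g * bv, g * av))
}

ad_div <- function(tp, a, b) {
  force(a); force(b)
  av <- tp$v[[adk(a)]]; bv <- tp$v[[adk(b)]]
  ad_node(tp, av / bv, c(a, b), function(g) {
    list(g / bv, -g * av / (bv * bv))
  })
}

# column-broadcast multiply: a is n x k, r is n x 1
ad_mul_rows <- function(tp, a, r) {
  force(a); force(r)
  av <- tp$v[[adk(a)]]; rv <- as.numeric(tp$v[[adk(r)]])
  ad_node(tp, av * rv, c(a, r), function(g) {
    list(g * rv, matrix(rowSums(g * av), ncol = 1L))
  })
}

# column-broadcast divide: a is n x k, r is n x 1 (nonzero)
ad_div_rows <- function(tp, a, r) {
  force(a); force(r)
  av <- tp$v[[adk(a)]]; rv <- as.numeric(tp$v[[adk(r)]])
  ad_node(tp, av / rv, c(a, r), function(g) {
    list(g / rv, matrix(-rowSums(g * av / rv^2), ncol = 1L))
  })
}

ad_scale <- function(tp, a, s) {
  force(a)
  ad_node(tp, tp$v[[adk(a)]] * s, a, function(g) list(g * s))
}

ad_addc <- function(tp, a, cst) {
  force(a)
  ad_node(tp, tp$v[[adk(a)]] + cst, a, function(g) list(g))
}

# elementwise multiply by a constant matrix/scalar (masking)
ad_mulc <- function(tp, a, cst) {
  force(a)
  ad_node(tp, tp$v[[adk(a)]] * cst, a, function(g) list(g * cst))
}

ad_relu <- function(tp, a) {
  force(a)
  av <- tp$v[[adk(a)]]
  pos <- av > 0
  ad_node(tp, av * pos, a, function(g) list(g * pos))
}

ad_lrelu <- function(tp, a, alpha = 0.1) {
  force(a)
  av <- tp$v[[adk(a)]]
  s <- ifelse(av > 0, 1, alpha)
  ad_node(tp, av * s, a, function(g) list(g * s))
}

ad_sigmoid <- function(tp, a) {
  force(a)
  y <- 1 / (1 + exp(-tp$v[[adk(a)]]))
  ad_node(tp, y, a, function(g) list(g * y * (1 - y)))
}

ad_tanh <- function(tp, a) {
  force(a)
  y <- tanh(tp$v[[adk(a)]])
  ad_node(tp, y, a, function(g) list(g * (1 - y * y)))
}

ad_exp <- function(tp, a) {
  force(a)
  y <- exp(tp$v[[adk(a)]])
  ad_node(tp, y, a, function(g) list(g * y))
}

ad_sum <- function(tp, a) {
  force(a)
  av <- tp$v[[adk(a)]]
  ad_node(tp, matrix(sum(av), 1L, 1L), a, function(g) {
    list(array(as.numeric(g), dim(av)))
  })
}

ad_rowsums <- function(tp, a) {
  force(a)
  av <- tp$v[[adk(a)]]
  ad_node(tp, matrix(rowSums(av), ncol = 1L), a, function(g) {
    list(matrix(as.numeric(g), nrow(av), ncol(av)))
  })
}

ad_colsums <- function(tp, a) {
  force(a)
  av <- tp$v[[adk(a)]]
  ad_node(tp, matrix(colSums(av), nrow = 1L), a, function(g) {
    list(matrix(as.numeric(g), nrow(av), ncol(av), byrow = TRUE))
  })
}

ad_t <- function(tp, a) {
  force(a)
  ad_node(tp, t(tp$v[[adk(a)]]), a, function(g) list(t(g)))
}

ad_cbind <- function(tp, ids) {
  ids <- vapply(ids, identity, 0L)
  vals <- lapply(ids, function(i) tp$v[[adk(i)]])
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  ad_node(tp, do.call(cbind, vals), as.integer(ids), function(g) {
    lapply(seq_along(ids), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

ad_rbind <- function(tp, ids) {
  ids <- vapply(ids, identity, 0L)
  vals <- lapply(ids, function(i) tp$v[[adk(i)]])
  hs <- vapply(vals, nrow, integer(1))
  ends <- cumsum(hs)
  starts <- c(1L, head(ends, -1L) + 1L)
  ad_node(tp, do.call(rbind, vals), as.integer(ids), function(g) {
    lapply(seq_along(ids), function(j) g[starts[j]:ends[j], , drop = FALSE])
  })
}

# gather rows by index; idx == 0L selects an implicit all-zero row
ad_gather <- function(tp, a, idx) {
  force(a)
  av <- tp$v[[adk(a)]]
  n <- nrow(av)
  if (any(idx == 0L)) {
    idx <- ifelse(idx == 0L, n + 1L, idx)
    av2 <- rbind(av, 0)
  } else {
    av2 <- av
  }
  ad_node(tp, av2[idx, , drop = FALSE], a, function(g) {
    acc <- matrix(0, n + 1L, ncol(av))
    sg <- rowsum(g, idx, reorder = FALSE)
    acc[as.integer(rownames(sg)), ] <- sg
    list(acc[seq_len(n), , drop = FALSE])
  })
}

# sum edge rows into `ng` groups given by seg (1-based, length nrow(a));
# empty groups yield zero rows
ad_segsum <- function(tp, a, seg, ng) {
  force(a)
  av <- tp$v[[adk(a)]]
  ad_node(tp, {
    out <- matrix(0, ng, ncol(av))
    sg <- rowsum(av, seg, reorder = FALSE)
    out[as.integer(rownames(sg)), ] <- sg
    out
  }, a, function(g) {
    list(g[seg, , drop = FALSE])
  })
}

# ---- composite helpers -----------------------------------------------------

# numerically-stable softmax across each row restricted to mask (logical,
# length ncol); masked-out columns get exactly zero weight
ad_softmax_rows <- function(tp, a, mask = NULL) {
  force(a)
  av <- tp$v[[adk(a)]]
  allk <- is.null(mask) || all(mask)
  mx <- if (allk) {
    if (ncol(av) == 1L) av[, 1L] else do.call(pmax, asplit(av, 2L))
  } else {
    apply(av[, mask, drop = FALSE], 1L, max)
  }
  sh <- ad_addc(tp, a, -as.numeric(mx)) # column-recycled detached shift
  e <- ad_exp(tp, sh)
  em <- if (allk) e else {
    ad_mulc(tp, e, matrix(as.numeric(mask), nrow(av), ncol(av), byrow = TRUE))
  }
  s <- ad_rowsums(tp, em)
  ad_div_rows(tp, em, s)
}

# softmax over segments of a column vector of logits (n x 1)
ad_segsoftmax <- function(tp, logits, seg, ng) {
  force(logits)
  lv <- as.numeric(tp$v[[adk(logits)]])
  mx <- tapply(lv, seg, max)
  shift <- as.numeric(mx[as.character(seg)])
  sh <- ad_addc(tp, logits, -matrix(shift, ncol = 1L))
  e <- ad_exp(tp, sh)
  s <- ad_segsum(tp, e, seg, ng)
  sgath <- ad_gather(tp, s, seg)
  ad_div(tp, e, sgath)
}

# masked mean over rows -> 1 x k (mask logical over rows)
ad_masked_mean <- function(tp, a, mask = NULL) {
  force(a)
  av <- tp$v[[adk(a)]]
  if (is.null(mask) || all(mask)) {
    return(ad_scale(tp, ad_colsums(tp, a), 1 / nrow(av)))
  }
  nv <- sum(mask)
  stopifnot(nv > 0)
  m <- ad_mulc(tp, a, matrix(as.numeric(mask), nrow(av), ncol(av)))
  ad_scale(tp, ad_colsums(tp, m), 1 / nv)
}
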