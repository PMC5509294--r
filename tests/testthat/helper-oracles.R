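# Independent oracles used across the suite. These deliberately use
# different algorithms from the package code paths they check.

# Scalar stack-based flood fill: the reference for connected-component
# labelling. Visits voxels one at a time with an explicit stack.
flood_fill_labels <- function(binary, connectivity) {
  d <- dim(binary)
  fg <- binary != 0
  off <- switch(as.character(connectivity),
                "6" = rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                            c(0,0,1), c(0,0,-1)),
                "18" = {
                  o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
                  o[rowSums(o != 0) %in% 1:2, , drop = FALSE]
                },
                "26" = {
                  o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
                  o[rowSums(o != 0) > 0, , drop = FALSE]
                })
  labels <- array(0L, dim = d)
  cur <- 0L
  for (lin in which(fg)) {
    if (labels[lin] != 0L) next
    cur <- cur + 1L
    stack <- list(as.integer(arrayInd(lin, d)))
    labels[lin] <- cur
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (r in seq_len(nrow(off))) {
        nb <- v + off[r, ]
        if (any(nb < 1L) || any(nb > d)) next
        nl <- nb[1] + d[1] * (nb[2] - 1) + d[1] * d[2] * (nb[3] - 1)
        if (fg[nl] && labels[nl] == 0L) {
          labels[nl] <- cur
          stack[[length(stack) + 1L]] <- nb
        }
      }
    }
  }
  labels
}

# Vectorized min-label propagation: a second, faster independent labelling
# algorithm (used where the scalar oracle would dominate run time). Each
# foreground voxel starts with its own linear index as label; labels are
# repeatedly replaced by the minimum over the neighborhood until stable.
minprop_labels <- function(binary, connectivity) {
  d <- dim(binary)
  fg <- binary != 0
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(off != 0)
  off <- off[switch(as.character(connectivity),
                    "6" = nz == 1, "18" = nz %in% 1:2, "26" = nz > 0), ,
             drop = FALSE]
  lab <- array(Inf, dim = d)
  lab[fg] <- which(fg)
  shift_arr <- function(a, o, fill) {
    idx <- lapply(1:3, function(ax) {
      s <- seq_len(d[ax]) - o[ax]
      s
    })
    ok <- lapply(1:3, function(ax) idx[[ax]] >= 1 & idx[[ax]] <= d[ax])
    out <- array(fill, dim = d)
    out[ok[[1]], ok[[2]], ok[[3]]] <-
      a[idx[[1]][ok[[1]]], idx[[2]][ok[[2]]], idx[[3]][ok[[3]]]]
    out
  }
  repeat {
    new <- lab
    for (r in seq_len(nrow(off))) {
      new <- pmin(new, shift_arr(lab, off[r, ], Inf))
    }
    new[!fg] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- array(0L, dim = d)
  out[fg] <- as.integer(lab[fg])
  out
}

# Canonical relabelling: component ids in order of first (raster) occurrence,
# so two labelings of the same partition compare equal.
canonical_labels <- function(labels) {
  fg <- labels != 0
  v <- labels[fg]
  labels[fg] <- match(v, unique(v))
  labels
}

# Soft-margin linear SVM solved through the dual QP with kernlab::ipop —
# the generic quadratic-programming oracle for max-margin toy problems.
svm_qp_oracle <- function(X, y, C = 1e6) {
  n <- nrow(X)
  K <- X %*% t(X)
  H <- (y %*% t(y)) * K
  sol <- kernlab::ipop(c = rep(-1, n), H = H + diag(1e-10, n),
                       A = matrix(y, nrow = 1), b = 0, r = 0,
                       l = rep(0, n), u = rep(C, n), sigf = 9)
  a <- kernlab::primal(sol)
  w <- as.numeric(t(X) %*% (a * y))
  sv <- a > 1e-6 * max(a)
  on_margin <- which(sv & a < C * (1 - 1e-6))
  if (!length(on_margin)) on_margin <- which(sv)
  b <- mean(y[on_margin] - X[on_margin, , drop = FALSE] %*% w)
  list(w = w, b = b, alpha = a,
       objective = 0.5 * sum(w^2) +
         C * sum(pmax(0, 1 - y * (X %*% w + b))))
}

# Closed-form pooled two-sample t (healthy minus disease), the textbook
# formula the intercept-only voxel-wise GLM must reproduce.
pooled_t <- function(healthy, disease) {
  n1 <- length(healthy); n2 <- length(disease)
  sp2 <- ((n1 - 1) * stats::var(healthy) + (n2 - 1) * stats::var(disease)) /
    (n1 + n2 - 2)
  (mean(healthy) - mean(disease)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}
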