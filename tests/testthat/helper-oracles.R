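# Independent reference implementations used as test oracles. These are
# deliberately written against the raw formulas (dense base-R linear algebra,
# brute-force enumeration) and never call the code paths they check.

# plain proximal-gradient (ISTA) reference solver with its own inline prox
ista_reference <- function(Yf, A, C, lambda1, lambda2, step, iters,
                           check_every = 0L) {
  A <- as.matrix(A)
  C <- as.matrix(C)
  X <- matrix(0, ncol(A), nrow(C))
  obj_prev <- Inf
  for (k in seq_len(iters)) {
    if (check_every > 0L && k %% check_every == 0L) {
      obj <- reference_objective(X, Yf, A, C, lambda1, lambda2)
      if (abs(obj_prev - obj) <= 1e-13 * max(obj, 1)) break
      obj_prev <- obj
    }
    G <- 2 * t(A) %*% (A %*% X %*% C - Yf) %*% t(C)
    V <- X - step * G
    # soft threshold
    U <- sign(V) * pmax(abs(V) - step * lambda1 * lambda2, 0)
    # row group shrinkage
    rn <- sqrt(rowSums(U^2))
    sc <- ifelse(rn > 0, pmax(0, 1 - step * lambda1 * (1 - lambda2) / rn), 0)
    X <- U * sc
  }
  X
}

reference_objective <- function(X, Yf, A, C, lambda1, lambda2) {
  A <- as.matrix(A)
  C <- as.matrix(C)
  r <- A %*% X %*% C - Yf
  sum(r^2) + lambda1 * (1 - lambda2) * sum(sqrt(rowSums(X^2))) +
    lambda1 * lambda2 * sum(abs(X))
}

# numeric minimizer of the row prox objective, as an oracle for the
# closed-form sparse-group prox
prox_row_numeric <- function(v, tau, lambda1, lambda2) {
  obj <- function(x) {
    0.5 * sum((x - v)^2) + tau * lambda1 * lambda2 * sum(abs(x)) +
      tau * lambda1 * (1 - lambda2) * sqrt(sum(x^2))
  }
  best <- stats::optim(v, obj, method = "BFGS",
                       control = list(maxit = 2000, reltol = 1e-14))
  # polish near zero: the optimum may be exactly 0 where BFGS stalls
  if (obj(numeric(length(v))) < best$value) return(numeric(length(v)))
  best$par
}

# row-wise subgradient optimality residual of the sparse-group prox problem:
# 0 must lie in x - v + tau*l1*l2*d||x||_1 + tau*l1*(1-l2)*d||x||_2
prox_subgradient_residual <- function(x, v, tau, lambda1, lambda2) {
  a <- tau * lambda1 * lambda2
  b <- tau * lambda1 * (1 - lambda2)
  nx <- sqrt(sum(x^2))
  if (nx > 0) {
    g <- x - v + a * sign(x) + b * x / nx
    # zero coordinates of a nonzero row: need |v_i| <= a
    zero <- x == 0
    g[zero] <- pmax(abs(v[zero]) - a, 0)
    max(abs(g))
  } else {
    # whole row zero: need || soft(v, a) ||_2 <= b
    u <- sign(v) * pmax(abs(v) - a, 0)
    max(0, sqrt(sum(u^2)) - b)
  }
}

# central finite differences of a scalar function at X along direction D
finite_diff_directional <- function(f, X, D, h = 1e-6) {
  (f(X + h * D) - f(X - h * D)) / (2 * h)
}

# exhaustive optimal one-to-one matching count on a tiny instance: maximum
# matching among admissible (pred, truth) pairs, by enumeration
brute_force_max_matching <- function(adj) {
  # adj: logical matrix preds x truths
  np <- nrow(adj)
  nt <- ncol(adj)
  best <- 0L
  assign_next <- function(p, used_t, count) {
    if (count + (np - p + 1L) <= best) return()
    if (p > np) {
      best <<- max(best, count)
      return()
    }
    assign_next(p + 1L, used_t, count) # leave pred p unmatched
    for (t in which(adj[p, ] & !used_t)) {
      used_t[t] <- TRUE
      assign_next(p + 1L, used_t, count + 1L)
      used_t[t] <- FALSE
    }
  }
  assign_next(1L, logical(nt), 0L)
  best
}

# independent homogeneity computation straight from entropy definitions,
# iterating over the long-format label pairs
homogeneity_reference <- function(tab) {
  N <- sum(tab)
  H <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  H_layer <- H(colSums(tab) / N)
  if (H_layer == 0) return(1)
  H_cond <- 0
  for (c in seq_len(nrow(tab))) {
    nc <- sum(tab[c, ])
    if (nc == 0) next
    H_cond <- H_cond + (nc / N) * H(tab[c, ] / nc)
  }
  1 - H_cond / H_layer
}

# direct 2-D convolution by definition (O(n^2 k^2) loops), reflect padding
conv2_reference <- function(img, kernel) {
  n1 <- nrow(img); n2 <- ncol(img)
  kr <- (nrow(kernel) - 1L) %/% 2L
  refl <- function(i, n) {
    # mirror with edge repetition onto 1..n
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > n, 2L * n + 1L - i, i)
  }
  out <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    acc <- 0
    for (a in -kr:kr) for (b in -kr:kr) {
      acc <- acc + kernel[a + kr + 1L, b + kr + 1L] *
        img[refl(i - a, n1), refl(j - b, n2)]
    }
    out[i, j] <- acc
  }
  out
}
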