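# Independent oracles, deliberately written as plain scalar loops so they
# share no code path with the package implementation.

# One-way ANOVA F-score by direct summation: within/between mean squared
# deviations over response groups, F = [S_B/(m-1)] / [S_W/(n-m)].
oracle_fscore <- function(x, g) {
  gl <- unique(g)
  m <- length(gl)
  n <- length(x)
  xbar <- 0
  for (v in x) xbar <- xbar + v / n
  SW <- 0; SB <- 0
  for (k in gl) {
    xs <- x[g == k]
    xk <- 0
    for (v in xs) xk <- xk + v / length(xs)
    for (v in xs) SW <- SW + (v - xk)^2 / n
    for (v in xs) SB <- SB + (xk - xbar)^2 / n
  }
  (SB / (m - 1)) / (SW / (n - m))
}

# Plug-in mutual information (nats) from two discrete label vectors.
oracle_mi <- function(a, b) {
  ua <- sort(unique(a)); ub <- sort(unique(b))
  n <- length(a)
  mi <- 0
  for (va in ua) for (vb in ub) {
    pj <- sum(a == va & b == vb) / n
    if (pj > 0) mi <- mi + pj * log(pj / (sum(a == va) / n * sum(b == vb) / n))
  }
  mi
}

# NCA regression objective by scalar-by-scalar evaluation.
oracle_nca_objective <- function(X, y, w, sigma = 1, lambda = 0,
                                 loss = c("mad", "robust")) {
  loss <- match.arg(loss)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  total <- 0
  for (i in seq_len(n)) {
    ker <- numeric(n)
    for (j in seq_len(n)) {
      if (j == i) next
      d <- 0
      for (m in seq_len(p)) d <- d + w[m]^2 * abs(X[i, m] - X[j, m])
      ker[j] <- exp(-d / sigma)
    }
    li <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      l <- if (loss == "mad") abs(y[i] - y[j]) else 1 - exp(-abs(y[i] - y[j]))
      li <- li + ker[j] / sum(ker) * l
    }
    total <- total + li / n
  }
  total + lambda * sum(w^2)
}

# Naive dense-inverse GP log marginal likelihood with explicit basis weights
# (w profiled out in closed form unless supplied).
oracle_gp_lml <- function(X, y, eta, amp, sigma2, w = NULL) {
  X <- rbind(X)
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- amp * exp(-sum((X[i, ] - X[j, ])^2) / (2 * eta^2))
  Ky <- K + diag(sigma2, n)
  Kinv <- solve(Ky)
  Om <- matrix(1, n, 1)
  if (is.null(w))
    w <- solve(t(Om) %*% Kinv %*% Om, t(Om) %*% Kinv %*% y)
  r <- y - Om %*% w
  as.numeric(-0.5 * determinant(Ky)$modulus - n / 2 * log(2 * pi) -
               0.5 * t(r) %*% Kinv %*% r)
}

# Naive GP posterior-mean prediction with constant basis.
oracle_gp_predict <- function(X, y, Xnew, eta, amp, sigma2) {
  X <- rbind(X); Xnew <- rbind(Xnew)
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- amp * exp(-sum((X[i, ] - X[j, ])^2) / (2 * eta^2))
  Ky <- K + diag(sigma2, n)
  Kinv <- solve(Ky)
  Om <- matrix(1, n, 1)
  w <- solve(t(Om) %*% Kinv %*% Om, t(Om) %*% Kinv %*% y)
  phi <- Kinv %*% (y - Om %*% w)
  out <- numeric(nrow(Xnew))
  for (s in seq_len(nrow(Xnew))) {
    ks <- numeric(n)
    for (i in seq_len(n))
      ks[i] <- amp * exp(-sum((Xnew[s, ] - X[i, ])^2) / (2 * eta^2))
    out[s] <- w + sum(ks * phi)
  }
  out
}

# Exhaustive per-step recomputation of the MRMR greedy trace from pre-binned
# discrete columns: relevance I(x,y), redundancy mean_z I(x,z) over S, MIQ.
oracle_mrmr_trace <- function(Xd, yd, zero_tol = 1e-12) {
  p <- ncol(Xd)
  rel <- vapply(seq_len(p), function(j) oracle_mi(Xd[, j], yd), numeric(1))
  S <- which.max(rel)
  Sc <- setdiff(seq_len(p), S)
  repeat {
    if (!length(Sc)) break
    red <- vapply(Sc, function(x)
      mean(vapply(S, function(z) oracle_mi(Xd[, x], Xd[, z]), numeric(1))),
      numeric(1))
    zr <- Sc[red <= zero_tol & rel[Sc] > zero_tol]
    if (length(zr)) {
      x <- zr[which.max(rel[zr])]
    } else {
      cand <- Sc[rel[Sc] > zero_tol]
      if (!length(cand)) break
      redc <- vapply(cand, function(x)
        mean(vapply(S, function(z) oracle_mi(Xd[, x], Xd[, z]), numeric(1))),
        numeric(1))
      x <- cand[which.max(rel[cand] / pmax(redc, zero_tol))]
    }
    S <- c(S, x); Sc <- setdiff(Sc, x)
  }
  S  # zero-relevance leftovers excluded (their order is random by contract)
}

# Small deterministic synthetic table shared across tests.
make_table <- function(n = 300, p = 8, support = c(1, 2),
                       effects = c(2, 1.5), noise = 0.3, seed = 5) {
  g <- generate_feature_table(synth_feature_config(
    n_segments = n, n_features = p, support = support,
    effect_sizes = effects, noise_sd = noise, seed = seed))
  list(X = as.matrix(g$table[, seq_len(p)]), y = g$table$SBP,
       truth = g$truth)
}
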