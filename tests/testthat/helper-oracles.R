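# Independent oracles used across the suite. These deliberately take
# different computational routes than the package implementations.

# CCA via the generalized eigenproblem: eigenvalues of
# S11^{-1} S12 S22^{-1} S21 are the squared canonical correlations. The
# package instead takes singular values of the whitened cross-covariance,
# so agreement is a genuine cross-check.
oracle_cca <- function(Z, Zp, C, rx = 1e-3, ry = 1e-3) {
  n <- nrow(Z)
  H1 <- scale(Z, center = TRUE, scale = FALSE)
  H2 <- scale(Zp, center = TRUE, scale = FALSE)
  S11 <- crossprod(H1) / (n - 1) + diag(rx, ncol(Z))
  S22 <- crossprod(H2) / (n - 1) + diag(ry, ncol(Zp))
  S12 <- crossprod(H1, H2) / (n - 1)
  M <- solve(S11, S12) %*% solve(S22, t(S12))
  ev <- sort(Re(eigen(M, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(pmax(ev[seq_len(C)], 0))
}

# Brute-force NT-Xent: explicit exp/log arithmetic over every ordered
# positive pair, no shared code with infonce_loss.
oracle_infonce <- function(Z, Zp, tau) {
  E <- rbind(Z, Zp)
  n <- nrow(Z)
  m <- 2 * n
  cossim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  total <- 0
  for (i in seq_len(m)) {
    j <- if (i <= n) i + n else i - n
    num <- exp(cossim(E[i, ], E[j, ]) / tau)
    den <- 0
    for (k in seq_len(m)) {
      if (k != i) den <- den + exp(cossim(E[i, ], E[k, ]) / tau)
    }
    total <- total - log(num / den)
  }
  total / m
}

# Brute-force Benjamini-Hochberg step-up from its definition: find the
# largest k with p_(k) <= k q / m; adjusted p by explicit minimization.
oracle_bh <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- numeric(m)
  for (k in seq_len(m)) {
    cand <- Inf
    for (j in k:m) cand <- min(cand, m / j * ps[j])
    adj_sorted[k] <- min(1, cand)
  }
  adj <- numeric(m)
  adj[o] <- adj_sorted
  kmax <- 0
  for (k in seq_len(m)) if (ps[k] <= k * q / m) kmax <- k
  reject <- logical(m)
  if (kmax > 0) reject[o[seq_len(kmax)]] <- TRUE
  list(p_adjusted = adj, reject = reject)
}

# Central finite differences of a scalar function of a matrix argument.
fd_grad <- function(f, X, h = 1e-5) {
  g <- matrix(0, nrow(X), ncol(X))
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(ncol(X))) {
      Xp <- X; Xp[i, j] <- Xp[i, j] + h
      Xm <- X; Xm[i, j] <- Xm[i, j] - h
      g[i, j] <- (f(Xp) - f(Xm)) / (2 * h)
    }
  }
  g
}

# Small random paired batch with controllable cross-view dependence.
random_pair <- function(n, d, rho = 0.5, seed = 1) {
  set.seed(seed)
  Z <- matrix(rnorm(n * d), n)
  Zp <- rho * Z + matrix(rnorm(n * d, sd = sqrt(1 - rho^2)), n)
  view_pair(Z, Zp)
}

# A desk-scale task + teacher-derived neural sets, cached per session so
# several test files can share one generation pass.
fixture_env <- new.env()

fixture_task <- function() {
  if (is.null(fixture_env$task)) {
    fixture_env$task <- generate_task(
      synthetic_task_spec(num_classes = 8, images_per_class = 40,
                          image_size = 16, seed = 42))
  }
  fixture_env$task
}

fixture_neural <- function(n_stim = 120) {
  if (is.null(fixture_env$neural)) {
    task <- fixture_task()
    stim <- task$train$images[, , , seq_len(n_stim), drop = FALSE]
    ts <- teacher_spec(variant = "tiny", input_size = 16,
                       site_counts = c(V1 = 30, V4 = 20, IT = 25),
                       response_noise_sd = 0, seed = 7)
    fixture_env$neural <- list(
      V1 = generate_responses(stim, ts, "V1"),
      V4 = generate_responses(stim, ts, "V4"),
      IT = generate_responses(stim, ts, "IT"))
  }
  fixture_env$neural
}

tiny_cfg <- function(seed = 11, epochs = 1, ...) {
  train_config(epochs = epochs, seed = seed, variant = "tiny",
               num_classes = 8, input_size = 16, class_batch = 64,
               neural_batch = 40, projector_width = 32, ...)
}
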