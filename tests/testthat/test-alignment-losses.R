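# Alignment losses: closed forms, oracle agreement, invariances, gradients.

test_that("canonical correlations saturate for invertibly related views", {
  set.seed(101)
  n <- 200; d <- 5
  Z <- matrix(rnorm(n * d), n)
  A <- matrix(rnorm(d * d), d) + diag(d)  # invertible w.h.p.; check below
  expect_gt(abs(det(A)), 1e-6)
  p <- dcca_params(C = d, rx = 1e-8, ry = 1e-8)
  r <- cca_correlations(view_pair(Z, Z %*% A), p)
  expect_equal(r$correlations, rep(1, d), tolerance = 1e-4)
  # column permutation is a special invertible map
  rp <- cca_correlations(view_pair(Z, Z[, c(3, 1, 2, 5, 4)]), p)
  expect_equal(rp$correlations, rep(1, d), tolerance = 1e-4)
  expect_true(all(diff(r$correlations) <= 1e-12))
})

test_that("cca_correlations matches the generalized-eigenvalue oracle", {
  set.seed(202)
  for (rep in 1:5) {
    n <- sample(50:300, 1)
    d <- sample(2:6, 1)
    vp <- random_pair(n, d, rho = runif(1, 0.2, 0.9), seed = 202 + rep)
    p <- dcca_params(C = d)
    got <- cca_correlations(vp, p)$correlations
    want <- oracle_cca(vp$Z, vp$Zp, C = d, rx = p$rx, ry = p$ry)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("cca rejects degenerate batches informatively", {
  Z <- matrix(rnorm(8), 2)
  expect_error(cca_correlations(view_pair(Z, Z), dcca_params(C = 2)),
               "more than 2 samples")
  Zc <- matrix(1, 20, 3)  # constant view
  set.seed(1)
  expect_error(
    cca_correlations(view_pair(matrix(rnorm(60), 20), Zc), dcca_params(C = 3)),
    "constant")
  expect_error(
    cca_correlations(random_pair(5, 8, seed = 1), dcca_params(C = 2)),
    "must exceed")
})

test_that("dcca_loss is bounded in [-C, 0] and equals the negated oracle sum", {
  set.seed(303)
  for (rep in 1:5) {
    vp <- random_pair(100, 4, rho = runif(1), seed = 303 + rep)
    p <- dcca_params(C = 4)
    val <- dcca_loss(vp, p)
    expect_lte(val, 0)
    expect_gte(val, -4)
    expect_equal(val, -sum(oracle_cca(vp$Z, vp$Zp, 4, p$rx, p$ry)),
                 tolerance = 1e-6)
  }
})

test_that("self-aligned views saturate the dcca loss at -C", {
  set.seed(404)
  Z <- matrix(rnorm(200 * 5), 200)
  val <- dcca_loss(view_pair(Z, Z), dcca_params(C = 5, rx = 1e-8, ry = 1e-8))
  expect_equal(val, -5, tolerance = 1e-3)
})

test_that("infonce matches brute-force NT-Xent and its closed forms", {
  # identical embeddings: uniform softmax over 2n-1 candidates
  E <- matrix(rep(c(1, 2, 3), each = 2), 2)
  expect_equal(infonce_loss(view_pair(E, E), infonce_params(0.5)), log(3),
               tolerance = 1e-12)
  # hand-sized instance vs independent summation
  Z <- matrix(c(1, 0, 0.3, 1), 2)
  Zp <- matrix(c(0.9, -0.2, 0.1, 1.2), 2)
  expect_equal(infonce_loss(view_pair(Z, Zp), infonce_params(0.5)),
               oracle_infonce(Z, Zp, 0.5), tolerance = 1e-12)
  vp <- random_pair(6, 3, seed = 5)
  expect_equal(infonce_loss(vp, infonce_params(0.7)),
               oracle_infonce(vp$Z, vp$Zp, 0.7), tolerance = 1e-10)
  # cosine similarity is scale-invariant
  expect_equal(infonce_loss(view_pair(7 * vp$Z, 7 * vp$Zp), infonce_params(0.7)),
               infonce_loss(vp, infonce_params(0.7)), tolerance = 1e-6)
})

test_that("infonce errors on zero-norm rows and n = 1", {
  Z <- matrix(c(0, 1, 0, 1), 2)
  Z[1, ] <- 0
  expect_error(infonce_loss(view_pair(Z, Z + 1), infonce_params()),
               "zero-norm")
  expect_error(view_pair(matrix(1, 1, 2), matrix(1, 1, 2)), "at least 2")
})

test_that("increasing a positive pair's similarity decreases infonce", {
  set.seed(6)
  vp <- random_pair(5, 3, rho = 0.3, seed = 6)
  base <- infonce_loss(vp, infonce_params(0.5))
  # rotate brain-view row 1 towards its model-view partner
  Zp2 <- vp$Zp
  Zp2[1, ] <- 0.5 * Zp2[1, ] + 0.5 * vp$Z[1, ] *
    sqrt(sum(Zp2[1, ]^2) / sum(vp$Z[1, ]^2))
  closer <- infonce_loss(view_pair(vp$Z, Zp2), infonce_params(0.5))
  expect_lt(closer, base)
})

test_that("vicreg reproduces the hand-computed example and closed forms", {
  Z <- matrix(c(0, 2, 0, 2), 2)
  br <- vicreg_loss(view_pair(Z, Z), vicreg_params(2, 2, 1, gamma = 1,
                                                   eps = 1e-4))
  expect_equal(br$invariance, 0)
  expect_equal(br$variance, 0)
  expect_equal(br$covariance, 8)   # c(Z) + c(Z') = 4 + 4
  expect_equal(br$total, 8)
  # identical views: invariance exactly zero
  vp <- random_pair(20, 4, seed = 7)
  expect_identical(vicreg_loss(view_pair(vp$Z, vp$Z))$invariance, 0)
  # uncorrelated unit-ish columns of std >= gamma: everything vanishes
  set.seed(8)
  X <- scale(matrix(rnorm(100 * 4), 100), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(X)) * sqrt(99) * 1.5  # centered, orthogonal, std 1.5 columns
  br0 <- vicreg_loss(view_pair(Q, Q), vicreg_params(gamma = 1))
  expect_lt(br0$total, 1e-6)
})

test_that("vicreg components are non-negative and total is the weighted sum", {
  set.seed(9)
  for (rep in 1:10) {
    vp <- random_pair(sample(5:40, 1), sample(2:6, 1), rho = runif(1),
                      seed = 900 + rep)
    pr <- vicreg_params(alpha = runif(1, 0, 3), mu = runif(1, 0, 3),
                        nu = runif(1, 0, 3))
    br <- vicreg_loss(vp, pr)
    expect_gte(br$invariance, 0)
    expect_gte(br$variance, 0)
    expect_gte(br$covariance, 0)
    expect_identical(br$total, pr$alpha * br$invariance +
                       pr$mu * br$variance + pr$nu * br$covariance)
  }
})

test_that("the variance hinge supports both std and var conventions", {
  vp <- random_pair(30, 3, seed = 10)
  b_std <- vicreg_loss(vp, vicreg_params(variance_hinge = "std"))
  b_var <- vicreg_loss(vp, vicreg_params(variance_hinge = "var"))
  expect_false(isTRUE(all.equal(b_std$variance, b_var$variance)))
  # shrink the batch so every column is far below the target spread:
  # hinge active under both conventions
  vps <- view_pair(vp$Z * 0.01, vp$Zp * 0.01)
  expect_gt(vicreg_loss(vps, vicreg_params(variance_hinge = "std"))$variance, 0)
  expect_gt(vicreg_loss(vps, vicreg_params(variance_hinge = "var"))$variance, 0)
})

test_that("all losses are invariant to a shared row permutation", {
  vp <- random_pair(40, 5, seed = 11)
  perm <- sample(40)
  vpp <- view_pair(vp$Z[perm, ], vp$Zp[perm, ])
  expect_equal(dcca_loss(vpp, dcca_params(C = 5)),
               dcca_loss(vp, dcca_params(C = 5)), tolerance = 1e-10)
  expect_equal(infonce_loss(vpp, infonce_params()),
               infonce_loss(vp, infonce_params()), tolerance = 1e-10)
  expect_equal(vicreg_loss(vpp)$total, vicreg_loss(vp)$total,
               tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences", {
  vp <- random_pair(15, 3, rho = 0.6, seed = 12)
  cases <- list(
    dcca = list(
      fn = function(Z, Zp) dcca_loss(view_pair(Z, Zp), dcca_params(C = 3)),
      gr = function(Z, Zp) dcca_loss(view_pair(Z, Zp), dcca_params(C = 3),
                                     grad = TRUE)),
    infonce = list(
      fn = function(Z, Zp) infonce_loss(view_pair(Z, Zp), infonce_params(0.5)),
      gr = function(Z, Zp) infonce_loss(view_pair(Z, Zp), infonce_params(0.5),
                                        grad = TRUE)),
    vicreg = list(
      fn = function(Z, Zp) vicreg_loss(view_pair(Z, Zp))$total,
      gr = function(Z, Zp) vicreg_loss(view_pair(Z, Zp), grad = TRUE))
  )
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    an <- cs$gr(vp$Z, vp$Zp)
    ref_Z <- fd_grad(function(X) cs$fn(X, vp$Zp), vp$Z)
    ref_Zp <- fd_grad(function(X) cs$fn(vp$Z, X), vp$Zp)
    scale <- max(abs(ref_Z), abs(ref_Zp), 1e-8)
    expect_lt(max(abs(an$dZ - ref_Z)) / scale, 1e-4)
    expect_lt(max(abs(an$dZp - ref_Zp)) / scale, 1e-4)
  }
})
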