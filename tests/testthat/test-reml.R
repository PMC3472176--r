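## balanced one-way random-effects data: q groups, r records per group
balanced_oneway <- function(q, r, mu, s2_b, s2_e, seed) {
  set.seed(seed)
  b <- rnorm(q, 0, sqrt(s2_b))
  g <- rep(paste0("grp", seq_len(q)), each = r)
  data.frame(id = g, y = mu + b[rep(seq_len(q), each = r)] +
               rnorm(q * r, 0, sqrt(s2_e)))
}

test_that("REML matches the closed-form ANOVA solution on balanced one-way data", {
  q <- 12; r <- 5
  dat <- balanced_oneway(q, r, mu = 10, s2_b = 4, s2_e = 2, seed = 301)
  K <- diag(q)
  dimnames(K) <- list(unique(dat$id), unique(dat$id))
  fit <- greml(y ~ 1, dat, random = list(b = K))
  # ANOVA oracle: sigma_e = MSE, sigma_b = (MSB - MSE) / r
  ybar_g <- tapply(dat$y, dat$id, mean)[unique(dat$id)]
  msb <- r * sum((ybar_g - mean(dat$y))^2) / (q - 1)
  mse <- sum((dat$y - ybar_g[dat$id])^2) / (q * (r - 1))
  expect_gt(msb, mse)  # interior optimum for this seed
  expect_equal(fit$sigma2[["b"]], (msb - mse) / r, tolerance = 1e-6)
  expect_equal(fit$sigma2[["residual"]], mse, tolerance = 1e-6)
  expect_true(fit$converged)
  # the profile of the restricted likelihood is maximal at the ANOVA solution
  l_opt <- reml_loglik(y ~ 1, dat, random = list(b = K),
                       sigma2 = c((msb - mse) / r, mse))
  for (f in c(0.8, 1.25)) {
    expect_lt(reml_loglik(y ~ 1, dat, random = list(b = K),
                          sigma2 = c(f * (msb - mse) / r, mse)), l_opt)
  }
})

test_that("restricted likelihood has the expected limits and invariances", {
  set.seed(302)
  n <- 10
  dat <- data.frame(id = as.character(1:n), y = rnorm(n, 5, 2),
                    w = runif(n, 0.5, 2))
  K <- tcrossprod(matrix(rnorm(n * 3), n, 3)) / 3 + diag(n) * 0.01
  dimnames(K) <- list(dat$id, dat$id)

  # zero genetic variance reduces to the weighted least-squares likelihood
  s2e <- 1.7
  l0 <- reml_loglik(y ~ 1, dat, random = list(g = K), sigma2 = c(0, s2e),
                    weights = "w")
  d <- 1 / dat$w
  Vinv <- diag(1 / (s2e * d))
  muhat <- sum(Vinv %*% dat$y) / sum(diag(Vinv))
  lwls <- -0.5 * (sum(log(s2e * d)) + log(sum(1 / (s2e * d))) +
                  sum((dat$y - muhat)^2 / (s2e * d)))
  expect_equal(l0, lwls, tolerance = 1e-10)

  # scaling y by c and variances by c^2 shifts logL by -(n - 1) log c
  s2 <- c(0.8, 1.3)
  l1 <- reml_loglik(y ~ 1, dat, random = list(g = K), sigma2 = s2)
  dat2 <- dat; dat2$y <- 3 * dat$y
  l2 <- reml_loglik(y ~ 1, dat2, random = list(g = K), sigma2 = 9 * s2)
  expect_equal(l2, l1 - (n - 1) * log(3), tolerance = 1e-8)

  # scaling K by c and its variance by 1/c leaves the likelihood unchanged
  l3 <- reml_loglik(y ~ 1, dat, random = list(g = 2.5 * K),
                    sigma2 = c(s2[1] / 2.5, s2[2]))
  expect_equal(l3, l1, tolerance = 1e-10)
})

test_that("the optimizer agrees with a dense grid search on a small instance", {
  set.seed(303)
  n <- 20
  M <- hwe_matrix(n, runif(400, 0.1, 0.5))
  G <- build_G(make_geno(M))
  rownames(G) <- colnames(G) <- as.character(1:n)
  u <- t(chol(unclass(G) + diag(1e-6, n))) %*% rnorm(n) * sqrt(3)
  dat <- data.frame(id = as.character(1:n), y = as.vector(2 + u + rnorm(n, 0, 1)))
  fit <- greml(y ~ 1, dat, random = list(g = G))
  vy <- var(dat$y)
  vg_grid <- seq(0.02 * vy, 2.5 * vy, length.out = 70)
  ve_grid <- seq(0.02 * vy, 2.5 * vy, length.out = 70)
  ll <- matrix(-Inf, 70, 70)
  for (i in seq_along(vg_grid))
    for (j in seq_along(ve_grid))
      ll[i, j] <- reml_loglik(y ~ 1, dat, random = list(g = G),
                              sigma2 = c(vg_grid[i], ve_grid[j]))
  best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  cell_g <- diff(vg_grid)[1]; cell_e <- diff(ve_grid)[1]
  expect_lt(abs(fit$sigma2[["g"]] - vg_grid[best[1]]), cell_g + 1e-9)
  expect_lt(abs(fit$sigma2[["residual"]] - ve_grid[best[2]]), cell_e + 1e-9)
  expect_gte(fit$logLik, max(ll) - 1e-6)
})

test_that("pure-noise data drive the genetic variance to the boundary", {
  set.seed(304)
  n <- 150
  G <- build_G(make_geno(hwe_matrix(n, runif(500, 0.1, 0.5))))
  rownames(G) <- colnames(G) <- as.character(1:n)
  dat <- data.frame(id = as.character(1:n), y = rnorm(n, 0, 3))
  fit <- suppressWarnings(greml(y ~ 1, dat, random = list(g = G)))
  expect_true(fit$boundary[["g"]] || fit$sigma2[["g"]] < 0.1 * var(dat$y))
  expect_lt(abs(fit$sigma2[["residual"]] - var(dat$y)), 0.25 * var(dat$y))
})

test_that("accepted iterations never decrease the restricted likelihood", {
  pop <- medium_pop()
  f2 <- fit_vc_model(pop$phenotypes, 2, G = pop$G)
  f3 <- suppressWarnings(fit_vc_model(pop$phenotypes, 3, A = pop$A, G = pop$G))
  for (f in list(f2, f3))
    expect_true(all(diff(f$fit$trace[, "logLik"]) >= -1e-7))
  # model nesting: adding the polygenic term cannot lower the optimum
  expect_gte(f3$fit$logLik, f2$fit$logLik - 1e-6)
})

test_that("scaling a covariance matrix rescales its variance component", {
  pop <- medium_pop()
  phen <- pop$phenotypes[1:120, ]
  G <- pop$G
  f1 <- fit_vc_model(phen, 2, G = G)
  G4 <- relmat(unclass(G) * 4, kind = "genomic")
  f4 <- fit_vc_model(phen, 2, G = G4)
  expect_equal(f4$fit$sigma2[["g"]], f1$fit$sigma2[["g"]] / 4,
               tolerance = 1e-3)
  expect_equal(f4$fit$logLik, f1$fit$logLik, tolerance = 1e-5)
})

test_that("variance ratio follows its defining arithmetic", {
  fake <- structure(list(sigma2 = c(g = 300, residual = 100), terms = "g",
                         dbar = 0.25), class = "greml")
  expect_equal(variance_ratio(fake), 300 / 325)
  fake2 <- structure(list(sigma2 = c(g = 2, residual = 2), terms = "g",
                          dbar = 1), class = "greml")
  expect_equal(variance_ratio(fake2), 0.5)
  fake3 <- structure(list(sigma2 = c(g = 5, residual = 0), terms = "g",
                          dbar = 1), class = "greml")
  expect_equal(variance_ratio(fake3), 1)
})

test_that("greml objects support the standard modelling methods", {
  pop <- medium_pop()
  phen <- pop$phenotypes[1:80, ]
  fit <- fit_vc_model(phen, 2, G = pop$G)$fit
  expect_named(coef(fit), "(Intercept)")
  expect_equal(length(residuals(fit)), 80)
  expect_equal(fitted(fit) + residuals(fit), fit$y)
  expect_s3_class(logLik(fit), "logLik")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(80L, 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1))
  expect_output(print(summary(fit)), "variance ratio")
})
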