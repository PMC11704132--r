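test_that("VP schedules conserve alpha^2 + sigma^2 = 1 with monotone laws", {
  for (T_ in c(10, 100, 1000)) {
    for (law in c("cosine", "linear")) {
      sch <- build_schedule("VP", T_, law = law)
      expect_lt(max(abs(sch$alpha^2 + sch$sigma^2 - 1)), 1e-6)
      expect_true(all(diff(sch$alpha) < 0))
      expect_true(all(diff(sch$sigma) > 0))
      expect_equal(sch$alpha[1], 1)
      expect_equal(sch$sigma[1], 0)
    }
  }
  expect_error(build_schedule("VP", 1), "T_steps")
  expect_error(build_schedule("OU"), "arg")
})

test_that("VP endpoint is close to a standard normal prior", {
  for (law in c("cosine", "linear")) {
    sch <- build_schedule("VP", 1000, law = law)
    expect_lt(sch$alpha[1001], 0.05)
  }
})

test_that("VE schedules have unit alpha and the configured terminal sigma", {
  sch <- build_schedule("VE", 100, sigma_min = 0.02, sigma_max = 10)
  expect_true(all(sch$alpha == 1))
  expect_equal(sch$sigma[101], 10)
  expect_equal(sch$sigma[1], 0)
  expect_true(all(diff(sch$sigma) > 0))
})

test_that("forward_noise is the exact affine map with exact endpoints", {
  sch <- build_schedule("VP", 100)
  x0 <- array(runif(32), c(4, 4, 2))
  z <- array(rnorm(32), c(4, 4, 2))
  expect_identical(forward_noise(x0, 0, z, sch), x0 * 1) # alpha=1, sigma=0
  xt <- forward_noise(x0, 57, z, sch)
  expect_equal(xt, sch$alpha[58] * x0 + sch$sigma[58] * z, tolerance = 1e-15)
  # terminal point is noise up to alpha(T)*max|x0|
  xT <- forward_noise(x0, 100, z, sch)
  expect_lte(max(abs(xT - sch$sigma[101] * z)), sch$alpha[101] * max(abs(x0)) + 1e-12)
  expect_error(forward_noise(x0, 101, z, sch), "out of")
  expect_error(forward_noise(x0, 5, array(0, c(2, 2, 2)), sch), "shapes differ")
})

test_that("forward-process moments match Monte-Carlo expectations", {
  sch <- build_schedule("VP", 100)
  set.seed(5)
  x0 <- matrix(runif(16, -1, 1), 4, 4)
  n <- 10000
  for (t in c(10, 50, 90)) {
    a <- sch$alpha[t + 1]; s <- sch$sigma[t + 1]
    draws <- vapply(1:n, function(i)
      forward_noise(x0, t, matrix(rnorm(16), 4, 4), sch), matrix(0, 4, 4))
    mean_err <- abs(apply(draws, c(1, 2), mean) - a * x0)
    expect_true(all(mean_err <= 4 * s / sqrt(n) + 1e-12))
    v <- apply(draws, c(1, 2), var)
    expect_true(all(abs(v / s^2 - 1) < 0.10))
  }
})

test_that("score conversion inverts the noising algebra exactly", {
  sch <- build_schedule("VP", 100)
  x0 <- matrix(runif(16), 4, 4)
  z <- matrix(rnorm(16), 4, 4)
  t <- 40
  a <- sch$alpha[t + 1]; s <- sch$sigma[t + 1]
  xt <- forward_noise(x0, t, z, sch)
  eps_true <- (xt - a * x0) / s
  analytic_score <- (a * x0 - xt) / s^2
  expect_equal(score_from_eps(eps_true, t, sch), analytic_score, tolerance = 1e-12)
  expect_equal(score_from_eps(matrix(0, 4, 4), t, sch), matrix(0, 4, 4))
  expect_equal(score_from_eps(3 * z, t, sch), 3 * score_from_eps(z, t, sch))
  expect_error(score_from_eps(z, 0, sch), "undefined")
})

test_that("em_step handles degenerate increments and rejects bad indices", {
  sch <- build_schedule("VE", 50, sigma_min = 0.1, sigma_max = 5)
  x <- matrix(rnorm(9), 3, 3)
  sc <- matrix(rnorm(9), 3, 3)
  z <- matrix(rnorm(9), 3, 3)
  # zero score and zero noise: pure drift-free step
  expect_equal(em_step(x, matrix(0, 3, 3), 9, 10, sch, 0), x)
  # flat segment (identical sigma) via skip on a custom flat schedule
  flat <- sch; flat$sigma[11] <- flat$sigma[12]
  expect_equal(em_step(x, sc, 10, 11, flat, z), x)
  expect_error(em_step(x, sc, 10, 10, sch, z), "t_index")
  expect_error(em_step(x, sc, 5, 10, sch, z), "allow_skip")
  vp <- build_schedule("VP", 50)
  expect_error(em_step(x, sc, 9, 10, vp, z), "VE")
})

test_that("reverse EM with the analytic Gaussian score recovers the moments", {
  sch <- build_schedule("VE", 500, sigma_min = 0.02, sigma_max = 5)
  m <- c(0.5, -0.3); s <- 0.2
  n <- 5000
  set.seed(123)
  X <- matrix(rnorm(2 * n, 0, sch$sigma[sch$T + 1]), n, 2)
  for (k in sch$T:1) {
    sig <- sch$sigma[k + 1]
    sc <- sweep(-X, 2, m, `+`) / (s^2 + sig^2)
    z <- if (k == 1) 0 else matrix(rnorm(2 * n), n, 2)
    X <- em_step(X, sc, k - 1, k, sch, z)
  }
  expect_lt(max(abs(colMeans(X) - m)), 0.05)
  expect_lt(max(abs(apply(X, 2, var) / s^2 - 1)), 0.10)
})

test_that("eps- and score-parameterized reverse sweeps coincide under shared noise", {
  sch <- build_schedule("VE", 200, sigma_min = 0.02, sigma_max = 5)
  m <- 0.4; s <- 0.3
  eps_model <- function(x, sig) -((m - x) / (s^2 + sig^2)) * sig # eps = -sigma*score
  set.seed(77)
  x_eps <- x_scr <- matrix(rnorm(100, 0, sch$sigma[sch$T + 1]), 50, 2)
  for (k in sch$T:1) {
    sig <- sch$sigma[k + 1]
    z <- if (k == 1) 0 else matrix(rnorm(100), 50, 2)
    sc_direct <- (m - x_scr) / (s^2 + sig^2)
    x_scr <- em_step(x_scr, sc_direct, k - 1, k, sch, z)
    sc_conv <- score_from_eps(eps_model(x_eps, sig), k, sch)
    x_eps <- em_step(x_eps, sc_conv, k - 1, k, sch, z)
  }
  expect_equal(x_eps, x_scr, tolerance = 1e-12)
})

test_that("denoising_loss has the right oracle values and reproducibility", {
  sch <- build_schedule("VP", 100)
  set.seed(2)
  x0s <- lapply(1:8, function(i) array(rnorm(32), c(4, 4, 2)))
  # oracle double: recovers the true eps from the noised latent
  mk_oracle <- function(x0) list(predict_eps = function(x_t, t, cond, schedule)
    (x_t - schedule$alpha[t + 1] * x0) / schedule$sigma[t + 1])
  loss0 <- mean(vapply(seq_along(x0s), function(i)
    denoising_loss(mk_oracle(x0s[[i]]), x0s[i], NULL, sch, seed = i), numeric(1)))
  expect_lt(loss0, 1e-20)
  # all-zero double: expected loss is E|eps|^2 per element = 1
  zero_model <- list(predict_eps = function(x_t, t, cond, schedule) x_t * 0)
  losses <- vapply(1:40, function(s)
    denoising_loss(zero_model, x0s, NULL, sch, seed = s), numeric(1))
  expect_equal(mean(losses), 1, tolerance = 0.05)
  # reproducible given the seed
  expect_identical(denoising_loss(zero_model, x0s, NULL, sch, seed = 3),
                   denoising_loss(zero_model, x0s, NULL, sch, seed = 3))
  # shape mismatch rejected
  bad <- list(predict_eps = function(x_t, t, cond, schedule) x_t[1:2])
  expect_error(denoising_loss(bad, x0s[1], NULL, sch, seed = 1), "shape")
})
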