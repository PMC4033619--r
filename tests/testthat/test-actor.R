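test_that("initialization gives the documented shapes, reproducibly", {
  a <- init_actor(60, seed = 4)
  expect_identical(dim(a$w_in), c(60L, 5L))
  expect_identical(dim(a$w_out), c(5L, 2L))
  expect_true(all(abs(a$w_in) <= 0.1) && all(abs(a$w_out) <= 0.1))
  b <- init_actor(60, seed = 4)
  expect_identical(a, b)
})

test_that("a zero-width init yields P = 0 everywhere and action 1", {
  a <- init_actor(4, w0 = 0, seed = 1)
  f <- actor_forward(a, c(0.2, 0.8, 0.5, 0))
  expect_identical(f$hidden$P, rep(0, 5))
  expect_identical(f$hidden$x, rep(1, 5))   # sgn(0) = +1
  expect_identical(f$output$P, rep(0, 2))
  expect_identical(f$action, 1L)            # tie toward the lowest index
})

test_that("running-max normalization matches the hand trace 2,4,3", {
  nz <- new_normalizer(1)
  out <- numeric(3)
  for (i in seq_along(c(2, 4, 3))) {
    r <- normalize_input(nz, c(2, 4, 3)[i])
    nz <- r$norm
    out[i] <- r$x
  }
  expect_identical(out, c(1, 1, 0.75))
})

test_that("normalizer guards zero history and rejects negative rates", {
  nz <- new_normalizer(3)
  r <- normalize_input(nz, c(0, 0, 0))
  expect_identical(r$x, c(0, 0, 0))
  expect_error(normalize_input(nz, c(1, -2, 0)), "non-negative")
  expect_error(normalize_input(nz, c(1, 2)), "length")
  # outputs stay in [0, 1] and the running max never decreases
  set.seed(8)
  prev_max <- rep(0, 3)
  for (i in 1:25) {
    r <- normalize_input(nz, stats::rpois(3, 5))
    nz <- r$norm
    expect_true(all(r$x >= 0 & r$x <= 1))
    expect_true(all(nz$running_max >= prev_max))
    prev_max <- nz$running_max
  }
})

test_that("forward pass reproduces the hand-computed tanh chain", {
  a <- init_actor(2, n_hidden = 1, seed = 1)
  a$w_in <- matrix(c(0.5, 0.3), 2, 1)
  a$w_out <- matrix(c(0.2, -0.1), 1, 2)
  f <- actor_forward(a, c(1, 0))
  expect_equal(f$hidden$P, tanh(0.5))
  expect_equal(f$hidden$P, 0.4621172, tolerance = 1e-6)
  expect_identical(f$hidden$x, 1)
  expect_equal(f$output$P, c(tanh(0.2), tanh(-0.1)))
  expect_equal(f$output$P, c(0.1973753, -0.0996680), tolerance = 1e-6)
  expect_identical(f$action, 1L)
  # negating the output weights swaps the ordering
  a$w_out <- -a$w_out
  expect_identical(actor_forward(a, c(1, 0))$action, 2L)
  expect_error(actor_forward(a, c(1, 0, 1)), "length 3")
})

test_that("reward-penalty increments match the worked substitutions", {
  # consolidation: r = 1 and P_j = x_j leave the weight untouched
  expect_identical(hrl_delta(1, 1, 1, r = 1, 0.1, 0.1), 0)
  expect_identical(hrl_delta(0.3, -1, -1, r = 1, 0.2, 0.4), 0)
  expect_equal(hrl_delta(1, 1, 0.5, r = 1, 0.1, 0.1), 0.05)
  # negative feedback engages both terms: the rule punishes harder
  expect_equal(hrl_delta(1, 1, 0.5, r = -1, 0.1, 0.1), -0.15)
  expect_error(hrl_delta(1, 1, 0.5, r = 0.5, 0.1, 0.1))
})

test_that("confidence rule reduces to the plain rule at rho = 1", {
  set.seed(2)
  for (i in 1:25) {
    x_i <- stats::runif(1); x_j <- sample(c(-1, 1), 1)
    P_j <- stats::runif(1, -0.99, 0.99); r <- sample(c(-1, 1), 1)
    base <- hrl_delta(x_i, x_j, P_j, r, 0.05, 0.05)
    expect_equal(hrl_delta_conf(x_i, x_j, P_j, r, rho = 1, 0.05, 0.05,
                                mode = "literal"), base)
    expect_equal(hrl_delta_conf(x_i, x_j, P_j, r, rho = 1, 0.05, 0.05,
                                mode = "gated"), base)
  }
})

test_that("rho = 0 freezes the gated rule but not the literal rule", {
  expect_identical(hrl_delta_conf(1, 1, 0.5, r = 1, rho = 0, 0.1, 0.1,
                                  mode = "gated"), 0)
  expect_identical(hrl_delta_conf(0.7, -1, -0.2, r = -1, rho = 0, 0.3, 0.2,
                                  mode = "gated"), 0)
  # literal rule: only the penalty-like term survives,
  # mu_minus * (1 - 0) * (1 - x_j - P_j) * x_i = 0.1 * (-0.5) = -0.05
  expect_equal(hrl_delta_conf(1, 1, 0.5, r = 1, rho = 0, 0.1, 0.1,
                              mode = "literal"), -0.05)
  expect_error(hrl_delta_conf(1, 1, 0.5, r = 1, rho = 1.5, 0.1, 0.1))
})

test_that("apply_update moves a single weight by the predicted amount", {
  a <- init_actor(1, n_hidden = 1, mu_plus = 0.1, mu_minus = 0.1, seed = 3)
  acts <- list(hidden = list(P = 0.5, x = 1),
               output = list(P = c(0, 0), x = c(1, 1)))
  before <- a$w_in[1, 1]
  upd <- apply_update(a, acts, x_in = 1, feedback = list(r = 1), "plain")
  expect_equal(upd$w_in[1, 1] - before, 0.05)
})

test_that("a saturated rewarded network does not change", {
  a <- init_actor(3, n_hidden = 2, seed = 6)
  acts <- list(hidden = list(P = c(1, -1), x = c(1, -1)),
               output = list(P = c(1, -1), x = c(1, -1)))
  upd <- apply_update(a, acts, x_in = c(0.5, 1, 0), list(r = 1), "plain")
  expect_identical(upd$w_in, a$w_in)
  expect_identical(upd$w_out, a$w_out)
})

test_that("gated confidence mode leaves the network bit-identical at rho=0", {
  a <- init_actor(3, n_hidden = 2, seed = 6)
  f <- actor_forward(a, c(0.2, 0.9, 0.4))
  upd <- apply_update(a, f, c(0.2, 0.9, 0.4),
                      list(r = -1, rho = 0), "confidence",
                      confidence_rule = "gated")
  expect_identical(upd$w_in, a$w_in)
  expect_identical(upd$w_out, a$w_out)
  expect_error(apply_update(a, f, c(0.2, 0.9, 0.4), list(r = -1),
                            "confidence"), "rho")
})

test_that("single-trial increments respect the loose magnitude bound", {
  set.seed(9)
  for (i in 1:30) {
    mu_p <- stats::runif(1, 0, 0.5); mu_m <- stats::runif(1, 0, 0.5)
    a <- init_actor(5, n_hidden = 3, mu_plus = mu_p, mu_minus = mu_m)
    x_in <- stats::runif(5)
    f <- actor_forward(a, x_in)
    fb <- list(r = sample(c(-1, 1), 1), rho = sample(0:1, 1))
    for (mode in c("plain", "confidence")) {
      upd <- apply_update(a, f, x_in, fb, mode)
      inc <- max(abs(upd$w_in - a$w_in), abs(upd$w_out - a$w_out))
      expect_lte(inc, mu_p * 2 + mu_m * 2 * 3 + 1e-12)
    }
  }
})

test_that("actor snapshots round-trip exactly through plain text", {
  a <- init_actor(7, n_hidden = 3, n_actions = 2, mu_plus = 0.013,
                  mu_minus = 0.07, seed = 12)
  path <- withr::local_tempfile()
  write_actor(a, path)
  b <- read_actor(path)
  expect_identical(b$w_in, a$w_in)
  expect_identical(b$w_out, a$w_out)
  expect_identical(c(b$mu_plus, b$mu_minus), c(a$mu_plus, a$mu_minus))
})
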