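# ADMM solver: configuration, state updates, and the full loop.

test_that("solver_config validates its parameter ranges", {
  expect_error(solver_config(rank = c(2, 2), rho = 1.2), "rho")
  expect_error(solver_config(rank = c(2, 2), rho = 1.0), "rho")
  expect_error(solver_config(rank = c(2, 2), alpha = c(0.4, 0.4)), "summing to 1")
  expect_error(solver_config(rank = c(2, 2), alpha = c(-0.2, 1.2)), "nonnegative|summing")
  expect_error(solver_config(rank = c(2, 2), mu0 = 0), "mu0")
  expect_error(solver_config(rank = c(0, 2)), "ranks")
  cfg <- solver_config(rank = c(3, 2, 4))
  expect_equal(cfg$alpha, rep(1 / 3, 3))
  expect_identical(cfg$factor_strategy, "qr")
})

test_that("init_state builds a feasible, orthonormal, zero-multiplier state", {
  p <- small_problem()
  st <- init_state(p$truth, p$mask, p$config)
  expect_identical(st$x[p$mask], p$truth[p$mask])
  expect_true(all(st$x[!p$mask] == 0))
  for (y in st$multipliers) expect_true(all(y == 0))
  for (u in st$factors)
    expect_equal(crossprod(u), diag(ncol(u)), tolerance = 1e-12)
  expect_equal(st$mu, p$config$mu0)
  # core is the projection of the zero-filled data
  expect_equal(st$core,
               multi_mode_product(st$x, st$factors, transpose = TRUE),
               tolerance = 1e-12)

  expect_error(init_state(p$truth, array(FALSE, dim(p$truth)), p$config),
               "no observed")
  expect_error(init_state(p$truth, p$mask, solver_config(rank = c(20, 2, 2))),
               "exceeds")
})

test_that("auxiliary update composes unfold, SVT, and fold per mode", {
  p <- small_problem()
  cfg <- p$config
  st <- init_state(p$truth, p$mask, cfg)
  st$multipliers <- lapply(st$multipliers, function(y) {
    array(rnorm(length(y), sd = 0.1), dim(y))
  })
  new <- update_auxiliary(st, cfg)
  for (i in 1:3) {
    target <- st$core + st$multipliers[[i]] / st$mu
    ref <- fold(svt(unfold(target, i), cfg$alpha[i] / st$mu)$matrix,
                i, dim(st$core))
    expect_equal(new$aux[[i]], ref, tolerance = 1e-12)
  }

  # zero weight: identity prox, bitwise
  cfg0 <- solver_config(rank = c(2, 2, 2), alpha = c(0, 0.5, 0.5))
  new0 <- update_auxiliary(st, cfg0)
  expect_identical(new0$aux[[1]], st$core + st$multipliers[[1]] / st$mu)

  # threshold above every singular value: full shrinkage to zero
  st2 <- st
  st2$mu <- 1e-12
  new2 <- update_auxiliary(st2, cfg)
  expect_true(all(new2$aux[[2]] == 0))
})

test_that("core update is the stationary point of its subproblem", {
  p <- small_problem(shape = c(4, 3, 3), rank = c(2, 2, 2))
  cfg <- p$config
  cfg$lam <- 0.8
  st <- init_state(p$truth, p$mask, cfg)
  set.seed(7)
  st$aux <- lapply(st$aux, function(v) array(rnorm(length(v)), dim(v)))
  st$multipliers <- lapply(st$multipliers,
                           function(y) array(rnorm(length(y)), dim(y)))
  st$mu <- 0.37
  new <- update_core(st, cfg)

  objective <- function(core_vec) {
    core <- array(core_vec, dim(st$core))
    fit <- st$x - tucker_reconstruct(core, st$factors)
    sum(vapply(1:3, function(i) {
      0.5 * st$mu * fnorm(core - st$aux[[i]] + st$multipliers[[i]] / st$mu)^2
    }, numeric(1))) + 0.5 * cfg$lam * fnorm(fit)^2
  }
  c0 <- as.vector(new$core)
  h <- 1e-5
  grad <- vapply(seq_along(c0), function(j) {
    e <- c0; e[j] <- e[j] + h
    f1 <- objective(e)
    e[j] <- c0[j] - h
    (f1 - objective(e)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(grad)), 1e-6)

  # lam = 0: the update collapses to the mean of (V_i - Y_i / mu)
  cfg0 <- cfg
  cfg0$lam <- 0
  new0 <- update_core(st, cfg0)
  ref <- Reduce(`+`, lapply(1:3, function(i) {
    st$aux[[i]] - st$multipliers[[i]] / st$mu
  })) / 3
  expect_equal(new0$core, ref, tolerance = 1e-12)
})

test_that("core update fixed point: consistent (V, Y, X) returns the core", {
  core_star <- rand_tensor(c(2, 2, 2), seed = 20)
  us <- lapply(1:3, function(i) rand_orthonormal(5, 2, seed = 20 + i))
  x <- tucker_reconstruct(core_star, us)
  cfg <- solver_config(rank = c(2, 2, 2))
  cfg$lam <- 1.3
  st <- init_state(x, array(TRUE, dim(x)), cfg)
  st$factors <- us
  st$aux <- rep(list(core_star), 3)
  st$multipliers <- rep(list(array(0, c(2, 2, 2))), 3)
  new <- update_core(st, cfg)
  expect_equal(new$core, core_star, tolerance = 1e-10)
})

test_that("factor update recovers the true subspace on noiseless data", {
  core_star <- rand_tensor(c(2, 2, 2), seed = 30)
  us <- lapply(1:3, function(i) rand_orthonormal(8, 2, seed = 30 + i))
  x <- tucker_reconstruct(core_star, us)
  cfg <- solver_config(rank = c(2, 2, 2))
  for (i in 1:3) {
    st <- init_state(x, array(TRUE, dim(x)), cfg)
    st$core <- core_star
    st$factors <- us
    st$factors[[i]] <- rand_orthonormal(8, 2, seed = 99)  # perturb mode i
    st$x <- x
    new <- update_factor(st, i, cfg)
    u <- new$factors[[i]]
    expect_equal(crossprod(u), diag(2), tolerance = 1e-12)
    p_new <- tcrossprod(u)
    p_true <- tcrossprod(us[[i]])
    expect_lt(max(abs(p_new - p_true)), 1e-8)
  }
})

test_that("factor update never increases the least-squares subproblem objective", {
  p <- small_problem(seed = 77)
  cfg <- p$config
  st <- init_state(p$truth, p$mask, cfg)
  for (k in 1:15) {
    st <- update_auxiliary(st, cfg)
    cfg_res <- cfg
    cfg_res$lam <- fnorm(p$truth[p$mask])
    st <- update_core(st, cfg_res)
    for (i in 1:3) {
      st <- update_factor(st, i, cfg)
      fo <- st$last_factor_objective
      expect_lte(fo[["ls"]], fo[["old"]] + 1e-8 * max(1, abs(fo[["old"]])))
    }
    st <- update_completion(st, p$truth, p$mask)
    st <- update_multipliers_and_penalty(st, cfg)
  }
})

test_that("completion update enforces the observed entries exactly", {
  p <- small_problem()
  st <- init_state(p$truth, p$mask, p$config)
  st <- update_completion(st, p$truth, p$mask)
  expect_identical(st$x[p$mask], p$truth[p$mask])
  recon <- tucker_reconstruct(st$core, st$factors)
  expect_equal(st$x[!p$mask], recon[!p$mask])

  # fully observed: X equals the data everywhere
  full <- array(TRUE, dim(p$truth))
  st2 <- init_state(p$truth, full, p$config)
  st2 <- update_completion(st2, p$truth, full)
  expect_identical(st2$x, p$truth)
})

test_that("multiplier and penalty updates follow the capped geometric schedule", {
  p <- small_problem()
  cfg <- p$config
  st <- init_state(p$truth, p$mask, cfg)
  st$aux <- rep(list(st$core), 3)          # C = V_i: multipliers unchanged
  new <- update_multipliers_and_penalty(st, cfg)
  for (y in new$multipliers) expect_true(all(y == 0))
  expect_equal(new$mu, cfg$rho * cfg$mu0)
  new2 <- update_multipliers_and_penalty(new, cfg)
  expect_equal(new2$mu, cfg$rho^2 * cfg$mu0)  # 1.05^2 * 1e-3 = 1.1025e-3
  expect_equal(new2$mu, 1.1025e-3)

  # cap at mu_max
  st$mu <- cfg$mu_max / 1.01
  expect_equal(update_multipliers_and_penalty(st, cfg)$mu, cfg$mu_max)

  # Y_i moves by mu * (C - V_i)
  st3 <- st
  st3$mu <- 2
  st3$aux <- lapply(st3$aux, function(v) v + 1)
  new3 <- update_multipliers_and_penalty(st3, cfg)
  expect_equal(new3$multipliers[[1]],
               st3$multipliers[[1]] + 2 * (st3$core - st3$aux[[1]]))
})

test_that("relative change matches the direct formula with an Inf sentinel", {
  x <- rand_tensor(c(3, 3, 2), seed = 1)
  expect_equal(relative_change(x, x), 0)
  expect_equal(relative_change(2 * x, x), 1)
  y <- rand_tensor(c(3, 3, 2), seed = 2)
  expect_equal(relative_change(y, x),
               sqrt(sum((y - x)^2)) / sqrt(sum(x^2)), tolerance = 1e-14)
  expect_identical(relative_change(x, array(0, dim(x))), Inf)
  expect_error(relative_change(x, rand_tensor(c(3, 3, 3))), "shapes")
})

test_that("fully observed input is returned unchanged after one iteration", {
  t <- random_tucker_tensor(c(8, 7, 6), c(2, 2, 2), seed = 4)
  mask <- array(TRUE, dim(t))
  fit <- ctnm_qr(t, mask, solver_config(rank = c(2, 2, 2)))
  expect_identical(fit$completed, t)
  expect_identical(fit$iterations, 1L)
  expect_equal(fit$rel_change_trace, 0)
  expect_identical(fit$stop_reason, "tolerance")
})

test_that("the full loop is deterministic, feasible, and self-consistent", {
  p <- small_problem()
  fit1 <- ctnm_qr(p$truth, p$mask, p$config, debug = TRUE)
  fit2 <- ctnm_qr(p$truth, p$mask, p$config)
  expect_identical(fit1$completed, fit2$completed)
  expect_identical(fit1$rel_change_trace, fit2$rel_change_trace)

  # observed entries preserved bitwise
  expect_identical(fit1$completed[p$mask], p$truth[p$mask])
  # trace bookkeeping
  expect_length(fit1$rel_change_trace, fit1$iterations)
  expect_identical(fit1$stop_reason, "tolerance")
  # capped geometric penalty
  expect_equal(fit1$mu_final,
               min(p$config$mu0 * p$config$rho^fit1$iterations,
                   p$config$mu_max))
  # returned model is a valid orthonormal Tucker model
  expect_s3_class(fit1$model, "tucker_model")

  # different seed changes the init but still recovers
  cfg2 <- p$config
  cfg2$seed <- 9L
  fit3 <- ctnm_qr(p$truth, p$mask, cfg2)
  expect_false(identical(fit1$rel_change_trace, fit3$rel_change_trace))
})

test_that("reconstruction and core share the weighted tensor nuclear norm", {
  p <- small_problem()
  fit <- ctnm_qr(p$truth, p$mask, p$config)
  recon <- tucker_reconstruct(fit$model)
  a <- p$config$alpha
  n_recon <- tensor_nuclear_norm(recon, a)
  n_core <- tensor_nuclear_norm(fit$model$core, a)
  expect_equal(n_recon, n_core, tolerance = 1e-6)
})

test_that("qr and hooi factor strategies agree at the fixed point", {
  p <- small_problem(shape = c(14, 12, 10), rank = c(3, 3, 3), seed = 5)
  fit_qr <- ctnm_qr(p$truth, p$mask, p$config)
  cfg_h <- p$config
  cfg_h$factor_strategy <- "hooi"
  fit_h <- ctnm_qr(p$truth, p$mask, cfg_h)
  r_qr <- rse(fit_qr$completed, p$truth)
  r_h <- rse(fit_h$completed, p$truth)
  expect_lt(max(r_qr, r_h) / min(r_qr, r_h), 2)
})

test_that("broom accessors and the convergence plot work on a fit", {
  p <- small_problem()
  fit <- ctnm_qr(p$truth, p$mask, p$config)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), fit$iterations)
  expect_named(td, c("iteration", "rel_change"))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$stop_reason, "tolerance")
  expect_s3_class(autoplot(fit), "ggplot")
})
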