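test_that("design matrix is C' with columns scaled by miRNA abundance", {
  Cp <- matrix(c(2, 0, 1, 3), 2, 2,
               dimnames = list(c("t1", "t2"), c("m1", "m2")))
  d <- build_design(Cp, c(m1 = 4, m2 = 1))
  expect_equal(unname(d$A["t1", "m1"]), 8)
  expect_equal(d$A[, "m2"], Cp[, "m2"])
  # all-ones expression leaves C' unchanged
  d1 <- build_design(Cp, c(m1 = 1, m2 = 1))
  expect_equal(d1$A, unclass(Cp), ignore_attr = TRUE)
  # entry-wise loop oracle on a random instance
  set.seed(2)
  C <- matrix(rpois(30, 2), 6, 5,
              dimnames = list(paste0("t", 1:6), paste0("m", 1:5)))
  ex <- setNames(runif(5, 2, 12), colnames(C))
  A <- build_design(C, ex)$A
  for (j in 1:6) for (i in 1:5) {
    expect_equal(A[j, i], C[j, i] * ex[[i]])
  }
})

test_that("miRNAs missing from the expression vector are dropped with warning", {
  Cp <- matrix(1, 2, 2, dimnames = list(c("t1", "t2"), c("m1", "m2")))
  expect_warning(d <- build_design(Cp, c(m1 = 3)), "dropping 1")
  expect_identical(d$mirna_ids, "m1")
  expect_error(build_design(Cp, c(zz = 1)), "no miRNA shared")
})

test_that("zero-noise fits recover the true parameters exactly", {
  sim <- small_sim(seed = 5)
  fit <- mirimpact(sim)
  expect_lt(max(abs(fit$dk - sim$true_dk)), 1e-8)
  expect_lt(abs(fit$b0 - sim$true_b0), 1e-8)
  expect_equal(fit$fitted + fit$residuals, sim$fc_observed)
})

test_that("least squares matches a pseudoinverse oracle, incl. rank deficiency", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 60; p <- 8
    A <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("t", 1:n), paste0("m", 1:p)))
    if (rep > 5) A[, p] <- A[, 1]  # duplicated column: rank deficient
    y <- rnorm(n)
    d <- structure(list(A = A, mirna_expr = setNames(rep(1, p), colnames(A)),
                        transcript_ids = rownames(A),
                        mirna_ids = colnames(A), C_prime = A),
                   class = "model_design")
    fit <- fit_least_squares(d, y)
    X <- cbind(A, 1)
    oracle <- as.numeric(MASS::ginv(X) %*% y)
    expect_lt(max(abs(c(fit$dk, fit$b0) - oracle)) / max(abs(oracle)), 1e-6)
    expect_lt(max(abs(fit$fitted - X %*% oracle)), 1e-8)
    if (rep > 5) {
      # minimum-norm solution splits a duplicated column equally
      expect_lt(abs(fit$dk[1] - fit$dk[p]), 1e-8)
      expect_lt(fit$rank, p + 1)
    }
  }
})

test_that("fitted residuals are orthogonal to the design on full-rank fits", {
  sim <- small_sim(seed = 13, noise_sd = 0.3)
  fit <- mirimpact(sim)
  X <- cbind(fit$design$A, 1)
  ip <- crossprod(X, fit$residuals)
  expect_lt(max(abs(ip)), 1e-8 * sqrt(sum(sim$fc_observed^2)))
})

test_that("shifting the response moves only the intercept", {
  sim <- small_sim(seed = 17, noise_sd = 0.2)
  f1 <- mirimpact(sim)
  f2 <- mirimpact(sim$C_prime, sim$mirna_expr, sim$fc_observed + 2.5)
  expect_lt(max(abs(f1$dk - f2$dk)), 1e-10)
  expect_lt(abs(f2$b0 - f1$b0 - 2.5), 1e-10)
})

test_that("prediction honours miRNA subsets", {
  sim <- small_sim(seed = 23, noise_sd = 0.1)
  fit <- mirimpact(sim)
  # full set equals A dk + b0
  expect_equal(predict(fit),
               drop(fit$design$A %*% fit$dk) + fit$b0,
               ignore_attr = TRUE)
  # intercept-only when nothing is included
  sub0 <- predict_fold_change(fit, subset = character(0))
  expect_true(all(sub0 == fit$b0))
  # random subset equals column-masked oracle product
  set.seed(1)
  sub <- sample(fit$design$mirna_ids, 5)
  mask <- fit$design$mirna_ids %in% sub
  oracle <- drop(fit$design$A[, mask, drop = FALSE] %*% fit$dk[mask]) + fit$b0
  expect_equal(unname(predict_fold_change(fit, subset = sub)), unname(oracle))
  expect_error(predict_fold_change(fit, subset = "not_a_mirna"), "unknown")
})

test_that("spearman matches the rank-then-Pearson oracle and edge cases", {
  expect_equal(spearman(1:10, (1:10)^3), 1)
  expect_equal(spearman(1:10, rev(1:10)), -1)
  set.seed(8)
  for (rep in 1:25) {
    x <- sample(1:5, 30, replace = TRUE)  # heavy ties
    y <- sample(1:5, 30, replace = TRUE) + x * (rep %% 3)
    expect_equal(spearman(x, y), oracle_spearman(x, y), tolerance = 1e-12)
  }
  expect_warning(r <- spearman(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
  expect_error(spearman(1:3, 1:4), "equal length")
})

test_that("split validation partitions transcripts and generalizes at zero noise", {
  sim <- simulate_dataset(n_mrna = 150, n_mirna = 10, n_active = 10,
                          noise_sd = 0, seed = 2)
  sv <- split_validate(sim$C_prime, sim$mirna_expr, sim$fc_observed,
                       n_splits = 20, seed = 4)
  expect_length(sv$rho_valid, 20)
  # exact fold-change ties between transcripts can break at ~1e-16 in the
  # prediction (weighted counts equal in value, not in bits), so allow a
  # hair below 1
  expect_true(all(sv$rho_valid > 0.999))
  expect_true(all(abs(sv$rho_train) <= 1, abs(sv$rho_valid) <= 1))
})

test_that("split validation at moderate noise brackets the full-data rho", {
  sim <- simulate_dataset(n_mrna = 600, n_mirna = 15, n_active = 15,
                          target_r2 = 0.5, seed = 9)
  full_rho <- mirimpact(sim)$rho_train
  sv <- split_validate(sim$C_prime, sim$mirna_expr, sim$fc_observed,
                       n_splits = 200, seed = 10)
  expect_lte(mean(sv$rho_valid), mean(sv$rho_train))
  expect_lt(abs(mean(sv$rho_train) - full_rho), 0.05)
  expect_lt(abs(mean(sv$rho_valid) - full_rho), 0.05)
  expect_error(split_validate(sim$C_prime, sim$mirna_expr, sim$fc_observed,
                              split_fraction = 0.999, n_splits = 2), "too few")
})

test_that("randomization controls keep their contracts", {
  sim <- simulate_dataset(n_mrna = 200, n_mirna = 10, n_active = 10,
                          target_r2 = 0.5, seed = 3)
  r0 <- randomization_control(sim$C_prime, sim$mirna_expr, sim$fc_observed,
                              "permute", n_reps = 0, seed = 1)
  expect_length(r0$rho, 0)
  r1 <- randomization_control(sim$C_prime, sim$mirna_expr, sim$fc_observed,
                              "permute_after_fit", n_reps = 25, seed = 6)
  r2 <- randomization_control(sim$C_prime, sim$mirna_expr, sim$fc_observed,
                              "permute_after_fit", n_reps = 25, seed = 6)
  expect_identical(r1$rho, r2$rho)
  expect_true(all(abs(r1$rho) <= 1))
})

test_that("model methods are coherent", {
  sim <- small_sim(seed = 29, noise_sd = 0.2)
  fit <- mirimpact(sim)
  expect_named(coef(fit)[length(coef(fit))], "b0")
  expect_equal(unname(coef(fit)[seq_along(fit$dk)]), unname(fit$dk))
  expect_equal(fitted(fit) + residuals(fit), sim$fc_observed)
  s <- summary(fit)
  expect_s3_class(s, "summary.mirimpact_fit")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(dim(sims), c(length(fit$fitted), 2L))
  expect_output(print(fit), "Spearman")
})
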