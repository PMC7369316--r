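test_that("additive model reproduces additively generated matrices", {
  e <- c(1, 3, 5, 2, 4, 6, 7); f <- c(2, 5, 3, 4)
  Tm <- 8 + outer(f, e, `+`)
  dimnames(Tm) <- list(OMA_FORMATS, OMA_EXEMPLARS)
  fit <- fit_additive(Tm)
  ## k1 = k2 = 1 and the prediction matches up to the (irrelevant) offset
  expect_equal(fit$k1, 1, tolerance = 1e-9)
  expect_equal(fit$k2, 1, tolerance = 1e-9)
  resid <- fit$A - Tm
  expect_lt(max(abs(resid - mean(resid))), 1e-9)
  expect_equal(model_r2(fit$A, Tm), 1, tolerance = 1e-12)
  ## constant matrix stays constant
  Tc <- matrix(3, 4, 7)
  expect_message(fitc <- fit_additive(Tc), "degenerate")
  expect_true(sd(fitc$A) < 1e-9)
})

test_that("additive model leaves residual on strongly multiplicative input", {
  g <- c(0.2, 1, 3, 6); e <- c(1, 2, 4, 8, 16, 32, 64)
  Tm <- outer(g, e)
  fit <- fit_additive(Tm)
  ## oracle: direct least squares on the intercept + two-regressor design
  X <- cbind(1, rep(colMeans(Tm), each = 4), rep(rowMeans(Tm), times = 7))
  beta <- solve(crossprod(X), crossprod(X, as.vector(Tm)))
  resid_oracle <- sum((as.vector(Tm) - X %*% beta)^2)
  expect_equal(sum((Tm - (fit$A + beta[1]))^2), resid_oracle, tolerance = 1e-6)
  expect_gt(resid_oracle, 1)
})

test_that("multiplicative model is the best rank-1 approximation", {
  ## exact rank-1 input is reproduced
  g <- c(1, 2, 0.5, 1.5); e <- 1:7
  Tm <- outer(g, e)
  expect_lt(max(abs(fit_multiplicative(Tm)$M - Tm)), 1e-9)

  ## Eckart-Young on random matrices: Frobenius error equals s2 (and more
  ## generally sqrt(sum of trailing squared singular values)), with the
  ## singular values from an independent eigendecomposition oracle
  set.seed(8)
  for (i in 1:25) {
    Tm <- matrix(rnorm(28, 5), 4, 7)
    M <- fit_multiplicative(Tm)$M
    ev <- sort(eigen(crossprod(Tm), symmetric = TRUE)$values, decreasing = TRUE)
    expect_equal(sqrt(sum((Tm - M)^2)), sqrt(sum(pmax(ev[-1], 0))),
                 tolerance = 1e-8)
    ## no random rank-1 probe does better
    probes <- replicate(20, {
      u <- rnorm(4); v <- rnorm(7)
      a <- sum(u * (Tm %*% v)) / (sum(u^2) * sum(v^2))
      sqrt(sum((Tm - a * outer(u, v))^2))
    })
    expect_true(all(probes >= sqrt(sum(pmax(ev[-1], 0))) - 1e-8))
  }
  expect_message(z <- fit_multiplicative(matrix(0, 4, 7)), "all-zero")
  expect_true(all(z$M == 0))
})

test_that("model r2 is the squared Pearson correlation over 28 entries", {
  set.seed(12)
  A <- matrix(rnorm(28), 4, 7); B <- matrix(rnorm(28), 4, 7)
  ## textbook-formula oracle
  a <- as.vector(A); b <- as.vector(B)
  r_oracle <- (sum((a - mean(a)) * (b - mean(b))) /
               sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)))^2
  expect_equal(model_r2(A, B), r_oracle, tolerance = 1e-12)
  expect_equal(model_r2(B, B), 1)
  expect_equal(model_r2(-B, B), 1)   # correlation is sign-blind
  expect_message(r <- model_r2(A, matrix(1, 4, 7)), "undefined")
  expect_true(is.na(r))
})

test_that("split-half matrices average the designated trial halves", {
  tr <- data.table::CJ(exemplar = OMA_EXEMPLARS, format = OMA_FORMATS,
                       rep = 1:2, sorted = TRUE)
  tr[, trial_id := seq_len(.N)]
  tr[, rate := 5 + match(exemplar, OMA_EXEMPLARS)]
  ## identical trials in each half -> O = O'
  sh <- split_half_matrices(tr)
  expect_equal(sh$O, sh$Oprime)
  ## 2 trials per cell: each half holds exactly one
  tr2 <- data.table::copy(tr)[, rate := rate + (trial_id %% 2L)]
  sh2 <- split_half_matrices(tr2)
  expect_equal(unname(sh2$O - sh2$Oprime),
               matrix(1, 4, 7) * (unique(tr2[trial_id %% 2 == 0, trial_id %% 2]) -
                                  1))
  ## random split: brute-force recomputation of cell means by assignment
  tr4 <- data.table::CJ(exemplar = OMA_EXEMPLARS, format = OMA_FORMATS,
                        rep = 1:4, sorted = TRUE)
  tr4[, trial_id := seq_len(.N)]
  set.seed(3); tr4[, rate := rnorm(.N, 10)]
  sh4 <- split_half_matrices(tr4, mode = "random", seed = 77)
  sh4b <- split_half_matrices(tr4, mode = "random", seed = 77)
  expect_identical(sh4, sh4b)
  for (cellmean in list(sh4$O, sh4$Oprime)) {
    ## every cell mean must be the average of exactly 2 of that cell's rates
    for (fidx in 1:4) for (eidx in 1:7) {
      cellrates <- tr4[format == OMA_FORMATS[fidx] &
                       exemplar == OMA_EXEMPLARS[eidx], rate]
      pairs <- combn(cellrates, 2, mean)
      expect_true(any(abs(pairs - cellmean[fidx, eidx]) < 1e-9))
    }
  }
  expect_error(split_half_matrices(tr[trial_id %% 2 == 0]), "empty")
})

test_that("observed split-half r2 is invariant to consistent exemplar relabeling", {
  rec <- generate_main_dataset(list(strong_mult_unit()), seed = 88)
  er <- epoch_rates(rec, list(e2 = c(0.3, 1.5)))
  er <- merge(er, rec$trials[, .(trial_id, exemplar, format)], by = "trial_id")
  sh <- split_half_matrices(er)
  r2 <- model_r2(sh$Oprime, sh$O)
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  expect_equal(model_r2(sh$Oprime[, perm], sh$O[, perm]), r2)
})

test_that("Mann-Whitney matches wilcox.test and exact enumeration", {
  set.seed(9)
  x <- rnorm(30); y <- rnorm(30, 0.5)
  mw <- mann_whitney(x, y)
  wt <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(mw$U, unname(wt$statistic))
  expect_equal(mw$p, wt$p.value, tolerance = 1e-10)
  ## identical distributions: Z near 0 over replications
  zs <- replicate(200, {
    a <- rnorm(20); b <- rnorm(20)
    mann_whitney(a, b)$Z
  })
  expect_lt(abs(mean(zs)), 3 / sqrt(200))
  ## exact U via enumeration for two 5-element samples
  x5 <- c(1.2, 3.4, 0.1, 5.6, 2.2); y5 <- c(2.1, 4.4, 6.0, 0.3, 3.9)
  mw5 <- mann_whitney(x5, y5)
  U_oracle <- sum(outer(x5, y5, `>`)) + 0.5 * sum(outer(x5, y5, `==`))
  expect_equal(mw5$U, U_oracle)
  ## exact p by full enumeration of rank assignments
  pool <- c(x5, y5)
  combos <- combn(10, 5)
  Us <- apply(combos, 2, function(idx)
    sum(outer(pool[idx], pool[-idx], `>`)))
  p_oracle <- mean(abs(Us - 12.5) >= abs(U_oracle - 12.5))
  expect_equal(mw5$p, p_oracle, tolerance = 1e-10)
})

test_that("multiplicative populations dissociate from additive ones", {
  pop_m <- sample_population(40, class_mix = c(multiplicative_stable = 1),
                             seed = 100)
  rec_m <- generate_main_dataset(pop_m, seed = 100)
  cmp_m <- compare_models_population(fit_mixing_population(rec_m))
  expect_gt(cmp_m$medians["r2_multiplicative"], cmp_m$medians["r2_additive"])

  pop_a <- sample_population(40, class_mix = c(additive = 1), seed = 101)
  rec_a <- generate_main_dataset(pop_a, seed = 101)
  cmp_a <- compare_models_population(fit_mixing_population(rec_a))
  expect_gt(cmp_a$medians["r2_additive"], cmp_a$medians["r2_multiplicative"])
})

test_that("time-resolved comparison tracks static rank-1 tuning", {
  pop <- lapply(1:8, function(i) strong_mult_unit(paste0("m", i)))
  rec <- generate_main_dataset(pop, seed = 55)
  tres <- time_resolved_comparison(rec, width = 0.3, step = 0.15,
                                   n_repeats = 5, seed = 9,
                                   window = c(0.3, 2.4))
  ## multiplicative prediction hugs the observed reliability everywhere
  gap <- abs(tres$mean_r2$multiplicative - tres$mean_r2$observed)
  expect_lt(max(gap), 0.12)
  expect_true(all(tres$mean_r2$multiplicative >= tres$mean_r2$additive - 0.05))
})

test_that("null populations produce no sustained significant runs", {
  hits <- vapply(1:5, function(s) {
    pop <- lapply(1:8, function(i) flat_unit(paste0("u", i)))
    rec <- generate_main_dataset(pop, seed = 300 + s)
    tres <- time_resolved_comparison(rec, width = 0.3, step = 0.15,
                                     n_repeats = 3, seed = s,
                                     window = c(0, 2.4))
    any(unlist(tres$masks))
  }, TRUE)
  expect_lte(mean(hits), 0.2)
})
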