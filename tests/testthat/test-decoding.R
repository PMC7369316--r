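## Shared small recording for decoding tests
dec_pop <- lapply(1:10, function(i) strong_mult_unit(paste0("m", i)))
dec_rec <- generate_main_dataset(dec_pop, seed = 901)
dec_bt2 <- bin_rates(dec_rec, 1.2, 1.2, c(0.3, 1.5))  # single epoch-2 bin

test_that("pseudopopulation split structure matches the factorial design", {
  bt <- dec_bt2
  pp_oma <- build_pseudopopulation(bt, "exemplar", seed = 1)
  expect_equal(pp_oma$n_splits, 48)
  expect_equal(pp_oma$n_data_points, 336)
  pp_vp <- build_pseudopopulation(bt, "viewpoint", seed = 1)
  expect_equal(pp_vp$n_splits, 24)
  expect_equal(pp_vp$n_data_points, 168)
  pp_po <- build_pseudopopulation(bt, "posture", seed = 1)
  expect_equal(pp_po$n_data_points, 168)
  pp_one <- build_pseudopopulation(bt, "exemplar", format = "sit_frontal",
                                   seed = 1)
  expect_equal(pp_one$n_splits, 12)
  expect_equal(pp_one$n_data_points, 84)
  ## every split holds exactly one data point per condition by construction
  expect_equal(dim(pp_oma$X)[2:3], c(7, 48))
})

test_that("insufficient trials are reported with the condition", {
  rec <- dec_rec
  drop <- rec$trials[exemplar == "roll", trial_id][-1]
  rec2 <- rec
  rec2$trials <- rec$trials[!trial_id %in% drop]
  rec2$spikes <- rec$spikes[!trial_id %in% drop]
  bt <- bin_rates(rec2, 1.2, 1.2, c(0.3, 1.5))
  expect_error(build_pseudopopulation(bt, "exemplar", seed = 1),
               "fewer than 2|zero trials")
})

test_that("PNB scores equal the closed-form Poisson log-likelihood", {
  ## one unit, observed count 3, lambda_A = 2, lambda_B = 5
  model <- structure(list(lambda = matrix(c(2, 5), 1, 2,
                                          dimnames = list(NULL, c("A", "B"))),
                          classes = c("A", "B")), class = "pnb_model")
  sc <- pnb_scores(model, matrix(3, 1, 1))
  expect_equal(unname(sc[1, "A"]), 3 * log(2) - 2, tolerance = 1e-12)
  expect_equal(unname(sc[1, "B"]), 3 * log(5) - 5, tolerance = 1e-12)
  expect_equal(unname(sc[1, "A"]), 0.0794, tolerance = 1e-3)
  expect_equal(unname(sc[1, "B"]), -0.1717, tolerance = 2e-3)
  expect_equal(pnb_predict(model, matrix(3, 1, 1)), "A")
  expect_error(pnb_scores(model, matrix(-1, 1, 1)), "negative")
})

test_that("PNB training floors lambda and predicts degenerate cases", {
  counts <- cbind(c(0, 4), c(0, 4), c(3, 0), c(3, 0))
  model <- pnb_train(counts, c("A", "A", "B", "B"))
  expect_true(all(model$lambda > 0))
  ## identical lambdas across classes -> first class by deterministic tie-break
  same <- pnb_train(cbind(c(2, 2), c(2, 2)), c("A", "B"))
  expect_equal(pnb_predict(same, matrix(c(2, 2), 2, 1)), "A")
  ## widely separated, noiseless counts -> perfect prediction
  expect_equal(pnb_predict(model, cbind(c(0, 4), c(3, 0))), c("A", "B"))
})

test_that("PNB predictions are invariant to exact unit duplication", {
  set.seed(2)
  counts <- matrix(rpois(5 * 20, 4), 5, 20)
  classes <- rep(c("A", "B"), each = 10)
  m1 <- pnb_train(counts, classes)
  test_pts <- matrix(rpois(5 * 8, 4), 5, 8)
  p1 <- pnb_predict(m1, test_pts)
  m2 <- pnb_train(rbind(counts, counts), classes)
  p2 <- pnb_predict(m2, rbind(test_pts, test_pts))
  expect_equal(p1, p2)
})

test_that("label-shuffled decoding sits at chance", {
  am <- decode_factor(dec_bt2, "exemplar", n_runs = 4, seed = 17,
                      shuffle_labels = TRUE)
  n_pts <- 336 * 4
  expect_lt(abs(am$diagonal - 1 / 7), 3 * sqrt((1 / 7) * (6 / 7) / n_pts) + 0.02)
})

test_that("real OMA decoding is far above chance for tuned units", {
  am <- decode_factor(dec_bt2, "exemplar", n_runs = 4, seed = 18)
  expect_gt(am$diagonal, 0.6)
})

test_that("temporal generalization is square for static format signals", {
  pop <- lapply(1:10, function(i)
    unit_spec(paste0("f", i), "format_only", baseline_rate = 10,
              format_gain = c(20, 18, 2, 3)))
  rec <- generate_main_dataset(pop, seed = 905)
  bt <- bin_rates(rec, 0.3, 0.3, c(-0.3, 2.4))   # 9 coarse bins
  am <- decode_factor(bt, "viewpoint", n_runs = 2, seed = 19)
  post <- which(bt$bin_starts >= 0)
  pre <- which(bt$bin_starts + 0.3 <= 0)
  ## block structure: all post-onset train/test combinations high
  expect_gt(min(am$accuracy[post, post]), 0.8)
  expect_lt(mean(am$accuracy[pre, post]), 0.7)
})

test_that("permutation null masks require sustained above-null accuracy", {
  bt <- bin_rates(dec_rec, 0.3, 0.15, c(-0.5, 2.45))
  real <- decode_factor(bt, "exemplar", n_runs = 2, seed = 23,
                        diagonal_only = TRUE)
  pn <- permutation_null(bt, real, "exemplar", n_shuffles = 10, seed = 29)
  ## strong exemplar signal: sustained significance during the video,
  ## onset no earlier than the first bin overlapping the dynamic period
  expect_true(any(pn$mask))
  expect_gte(pn$onset_s, -0.15)
  expect_false(any(pn$mask[bt$bin_starts + 0.3 <= 0]))
  expect_error(permutation_null(bt, real, "exemplar", n_shuffles = 0,
                                seed = 1), "n_shuffles")
  ## a null process yields no mask
  pop0 <- lapply(1:6, function(i) flat_unit(paste0("u", i)))
  rec0 <- generate_main_dataset(pop0, seed = 906)
  bt0 <- bin_rates(rec0, 0.3, 0.15, c(-0.5, 2.45))
  real0 <- decode_factor(bt0, "exemplar", n_runs = 2, seed = 31,
                         diagonal_only = TRUE)
  pn0 <- permutation_null(bt0, real0, "exemplar", n_shuffles = 10, seed = 37)
  expect_false(any(pn0$mask))
})

test_that("cross-format decoding generalizes only for format-invariant codes", {
  within <- decode_factor(dec_bt2, "exemplar", format = "stand_lateral",
                          n_runs = 4, seed = 41)
  cross <- cross_format_decode(dec_bt2, "stand_lateral", "sit_frontal",
                               n_runs = 4, seed = 41)
  expect_gt(cross$diagonal, 3 * (1 / 7))
  expect_lte(cross$diagonal, within$diagonal + 0.05)

  pop_x <- lapply(1:10, function(i) mixed_unit(paste0("x", i), seed = i))
  rec_x <- generate_main_dataset(pop_x, seed = 907)
  btx <- bin_rates(rec_x, 1.2, 1.2, c(0.3, 1.5))
  within_x <- decode_factor(btx, "exemplar", format = "stand_lateral",
                            n_runs = 4, seed = 43)
  cross_x <- cross_format_decode(btx, "stand_lateral", "sit_frontal",
                                 n_runs = 4, seed = 43)
  expect_gt(within_x$diagonal, 0.45)
  expect_lt(abs(cross_x$diagonal - 1 / 7), 0.12)

  expect_message(same <- cross_format_decode(dec_bt2, "sit_lateral",
                                             "sit_lateral", n_runs = 2,
                                             seed = 47), "coincide")
  expect_s3_class(same, "accuracy_matrix")
})

test_that("the correlation classifier is available behind a flag", {
  ## pattern correlation needs heterogeneous tuning across units
  pop <- lapply(1:10, function(i)
    strong_mult_unit(paste0("h", i),
                     tuning = seq(2, 44, by = 7)[with_seed(600 + i, sample(7))]))
  rec <- generate_main_dataset(pop, seed = 908)
  bt <- bin_rates(rec, 1.2, 1.2, c(0.3, 1.5))
  am <- decode_factor(bt, "exemplar", n_runs = 2, seed = 53,
                      method = "correlation")
  expect_gt(am$diagonal, 0.5)
})
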