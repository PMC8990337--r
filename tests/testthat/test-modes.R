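test_that("selectivity vector is the exact condition difference", {
  r <- matrix(10, 3, 5)
  p_same <- manual_psth(r, r)
  sv <- selectivity_vector(p_same)
  expect_true(all(sv$w == 0))
  p <- manual_psth(matrix(10, 1, 4), matrix(4, 1, 4))
  expect_true(all(selectivity_vector(p)$w == 6))
  # norm matches brute force over neurons
  set.seed(1)
  pr <- manual_psth(matrix(runif(40, 0, 20), 8), matrix(runif(40, 0, 20), 8))
  sv2 <- selectivity_vector(pr)
  brute <- sapply(seq_len(ncol(sv2$w)), function(j) {
    sqrt(sum((pr$rates[, j, "lick_right"] - pr$rates[, j, "lick_left"])^2))
  })
  expect_equal(sqrt(colSums(sv2$w^2)), brute, tolerance = 1e-12)
})

test_that("CD_delay: indicator for a single selective neuron, scale invariant", {
  right <- matrix(5, 4, 100)
  right[2, ] <- 15
  left <- matrix(5, 4, 100)
  p <- manual_psth(right, left, bin_width = 0.01, t0 = -1)
  cd <- compute_cd_delay(p)
  expect_equal(unname(cd$weights), c(0, 1, 0, 0))
  p2 <- manual_psth(2 * right, 2 * left, bin_width = 0.01, t0 = -1)
  expect_equal(compute_cd_delay(p2)$weights, cd$weights)
  expect_equal(sum(cd$weights^2), 1, tolerance = 1e-12)
  # no selectivity -> degenerate-mode error
  expect_error(compute_cd_delay(manual_psth(right, right, t0 = -1)),
               class = "popmodes_degenerate")
})

test_that("CD_response orthogonalization equals the least-squares residual (oracle)", {
  set.seed(42)
  # time-varying selectivity: delay pattern before the cue, a different
  # pattern after it (bins 1:60 pre-cue, 61:100 post-cue; t0 = -0.6)
  right <- matrix(8, 5, 100)
  left <- matrix(8, 5, 100)
  right[, 1:60] <- right[, 1:60] + runif(5, 0, 6)
  right[, 61:100] <- right[, 61:100] + runif(5, 0, 6)
  p <- manual_psth(right, left, bin_width = 0.01, t0 = -0.6)
  cd <- compute_cd_delay(p)
  cdr <- compute_cd_response(p, cd_delay = cd)
  expect_lt(abs(sum(cd$weights * cdr$weights)), 1e-10)
  # brute-force regression residual of the raw response mean on CD_delay
  raw <- rowMeans(selectivity_vector(p)$w[, popmodes:::window_bins(p$time, c(0, 0.4), 0.01)])
  fit <- lm(raw ~ 0 + unname(cd$weights))
  resid <- unname(residuals(fit))
  expect_equal(unname(cdr$weights), resid / sqrt(sum(resid^2)),
               tolerance = 1e-10)
  # raw response vector parallel to CD_delay -> degenerate
  right_c <- matrix(8 + runif(5, 0, 6), 5, 100)
  p_par <- manual_psth(right_c, matrix(8, 5, 100), bin_width = 0.01, t0 = -0.6)
  expect_error(compute_cd_response(p_par,
                                   cd_delay = compute_cd_delay(p_par)),
               class = "popmodes_degenerate")
  # a raw vector already orthogonal to CD_delay is returned unchanged
  right2 <- matrix(5, 2, 100)
  right2[1, 1:60] <- 10   # delay-selective unit 1
  right2[2, 61:100] <- 9  # response-selective unit 2
  p2 <- manual_psth(right2, matrix(5, 2, 100), bin_width = 0.01, t0 = -0.6)
  cd2 <- compute_cd_delay(p2)
  cdr2 <- compute_cd_response(p2, cd_delay = cd2)
  cdr2_raw <- compute_cd_response(p2, orthogonalize = FALSE)
  expect_equal(cdr2$weights, cdr2_raw$weights, tolerance = 1e-10)
})

test_that("D_go recovers planted response signs; no cue response errors", {
  right <- matrix(5, 3, 200)
  left <- matrix(5, 3, 200)
  # bins at 10 ms, t0 = -1: post-cue bins are 101:200
  right[1, 101:200] <- left[1, 101:200] <- 20   # go-up
  right[2, 101:200] <- left[2, 101:200] <- 1    # go-down
  p <- manual_psth(right, left, bin_width = 0.01, t0 = -1)
  dgo <- compute_d_go(p)
  expect_gt(dgo$weights[1], 0)
  expect_lt(dgo$weights[2], 0)
  expect_equal(unname(dgo$weights[3]), 0)
  flat <- manual_psth(matrix(5, 2, 200), matrix(5, 2, 200), bin_width = 0.01, t0 = -1)
  expect_error(compute_d_go(flat), class = "popmodes_degenerate")
})

test_that("D_ramp contrasts pre-trial and pre-cue windows", {
  r <- matrix(5, 2, 400)
  r[1, 201:400] <- 12  # ramps up by the cue
  p <- manual_psth(r, r, bin_width = 0.01, t0 = -4)
  dr <- compute_d_ramp(p, pre_trial_window = c(-3.2, -2.6))
  expect_equal(unname(dr$weights), c(1, 0))
})

test_that("D_stim concentrates on perturbation-scaled units and ignores common shifts", {
  omit <- manual_psth(matrix(5, 3, 100), matrix(5, 3, 100), bin_width = 0.01, t0 = -0.5)
  stim_r <- matrix(5, 3, 100)
  stim_r[2, 51:100] <- 25
  stim <- manual_psth(stim_r, stim_r, bin_width = 0.01, t0 = -0.5)
  ds <- compute_d_stim(omit, stim)
  expect_equal(unname(ds$weights), c(0, 1, 0))
  expect_error(compute_d_stim(omit, omit), class = "popmodes_degenerate")
  # common baseline shift leaves the direction unchanged
  omit2 <- omit; stim2 <- stim
  omit2$rates <- omit$rates + 3
  stim2$rates <- stim$rates + 3
  expect_equal(compute_d_stim(omit2, stim2)$weights, ds$weights)
})

test_that("Gram-Schmidt equals the QR Q-factor up to sign (oracle)", {
  set.seed(11)
  for (rep in 1:20) {
    n <- 8
    vs <- replicate(4, rnorm(n))
    modes <- lapply(seq_len(ncol(vs)), function(j) {
      popmodes:::new_mode_vector(vs[, j] / sqrt(sum(vs[, j]^2)),
                                 sprintf("u%02d", 1:n), paste0("m", j))
    })
    names(modes) <- paste0("m", 1:4)
    ortho <- orthogonalize_set(modes)
    M <- vapply(ortho, function(m) unname(m$weights), numeric(n))
    G <- crossprod(M)
    expect_equal(G, diag(4), tolerance = 1e-10, ignore_attr = TRUE)
    Q <- qr.Q(qr(vs))[, 1:4]
    for (j in 1:4) {
      expect_equal(abs(sum(Q[, j] * M[, j])), 1, tolerance = 1e-8)
    }
    # first mode never changes
    expect_equal(ortho[[1]]$weights, modes[[1]]$weights)
  }
  # linearly dependent input names the offending mode
  m1 <- popmodes:::new_mode_vector(c(1, 0) , c("a", "b"), "m1")
  m2 <- popmodes:::new_mode_vector(c(-1, 0), c("a", "b"), "m2")
  err <- tryCatch(orthogonalize_set(list(m1 = m1, m2 = m2)),
                  error = function(e) conditionMessage(e))
  expect_match(err, "m2")
})

test_that("reordering changes later modes but never the first", {
  set.seed(5)
  modes <- setNames(lapply(1:3, function(i) random_mode(6, paste0("m", i))),
                    paste0("m", 1:3))
  o1 <- orthogonalize_set(modes, order = c("m1", "m2", "m3"))
  o2 <- orthogonalize_set(modes, order = c("m2", "m1", "m3"))
  expect_equal(o1$m1$weights, modes$m1$weights)
  expect_equal(o2$m2$weights, modes$m2$weights)
  # m2 is altered when it no longer comes first
  expect_false(isTRUE(all.equal(o1$m2$weights, o2$m2$weights)))
  # the span is order-invariant, so the last residual direction agrees up to sign
  expect_equal(abs(sum(o1$m3$weights * o2$m3$weights)), 1, tolerance = 1e-8)
})

test_that("projection is an inner product, unit-normalized and linear", {
  set.seed(3)
  m <- random_mode(6)
  # projecting the mode's own weights (one 'time bin') gives 1
  rates1 <- matrix(m$weights, nrow = 1, dimnames = list(NULL, m$unit_ids))
  expect_equal(unname(project(rates1, m)), 1, tolerance = 1e-12)
  # orthogonal pattern projects to 0
  v_orth <- rnorm(6)
  v_orth <- v_orth - sum(v_orth * m$weights) * m$weights
  expect_equal(unname(project(matrix(v_orth, 1, dimnames = list(NULL, m$unit_ids)), m)),
               0, tolerance = 1e-12)
  # brute-force sum over neurons on a toy matrix, and linearity
  A <- matrix(runif(18), 3, 6, dimnames = list(NULL, m$unit_ids))
  B <- matrix(runif(18), 3, 6, dimnames = list(NULL, m$unit_ids))
  pa <- project(A, m)
  brute <- sapply(1:3, function(i) sum(A[i, ] * m$weights))
  expect_equal(unname(pa), brute, tolerance = 1e-12)
  expect_equal(project(2 * A + 3 * B, m), 2 * project(A, m) + 3 * project(B, m),
               tolerance = 1e-12)
})

test_that("normalization anchors hold exactly on training means and are affine-stable", {
  set.seed(8)
  right <- matrix(runif(300, 5, 15), 3, 100)
  left <- right - 2
  p <- manual_psth(right, left, bin_width = 0.01, t0 = -0.5)
  cd <- compute_cd_delay(p, window = c(-0.5, 0))
  tr <- project(p, cd)
  norm <- normalize_projection(tr, "CD_delay")
  idx <- popmodes:::window_bins(norm$time, c(-0.1, 0), 0.01)
  expect_equal(mean(norm$values[idx, "lick_left"]), 0, tolerance = 1e-10)
  expect_equal(mean(norm$values[idx, "lick_right"]), 1, tolerance = 1e-10)
  # adding a constant to all projections leaves the normalized trace unchanged
  tr_shift <- tr
  tr_shift$values <- tr$values + 7
  norm_shift <- normalize_projection(tr_shift, "CD_delay")
  expect_equal(norm_shift$values, norm$values, tolerance = 1e-10)
  # D_go anchors: pre-cue -> 0, pre-to-post change -> 1
  r_go <- matrix(5, 2, 100)
  r_go[, 51:100] <- 9
  p_go <- manual_psth(r_go, r_go, bin_width = 0.01, t0 = -0.5)
  dgo <- compute_d_go(p_go)
  ngo <- normalize_projection(project(p_go, dgo), "D_go")
  pre <- popmodes:::window_bins(ngo$time, c(-0.1, 0), 0.01)
  post <- popmodes:::window_bins(ngo$time, c(0, 0.1), 0.01)
  expect_equal(mean(rowMeans(ngo$values)[pre]), 0, tolerance = 1e-10)
  expect_equal(mean(rowMeans(ngo$values)[post]) - mean(rowMeans(ngo$values)[pre]),
               1, tolerance = 1e-10)
  # identical conditions: anchor denominator vanishes -> flagged
  p_flat <- manual_psth(right, right, bin_width = 0.01, t0 = -0.5)
  tr_flat <- project(p_flat, cd)
  expect_error(normalize_projection(tr_flat, "CD_delay"),
               class = "popmodes_ineligible")
})

test_that("train/test split is disjoint, type-balanced and seed-reproducible", {
  trials <- tibble::tibble(
    trial_index = 1:80,
    type = rep(c("lick_right", "lick_left"), each = 40),
    outcome = "correct", perturbation = "none",
    t_sample_on = 1:80, t_delay_on = 1:80 + 1, t_go = 1:80 + 2
  )
  sp <- split_train_test(trials, seed = 2)
  expect_equal(nrow(sp$train), 40)
  expect_equal(nrow(sp$test), 40)
  expect_equal(sum(sp$train$type == "lick_right"), 20)
  expect_length(intersect(sp$train$trial_index, sp$test$trial_index), 0)
  expect_identical(sp, split_train_test(trials, seed = 2))
  for (seed in 1:100) {
    spx <- split_train_test(trials, seed = seed)
    expect_length(intersect(spx$train$trial_index, spx$test$trial_index), 0)
  }
  expect_error(split_train_test(trials, fraction = 1), class = "popmodes_error")
  expect_error(split_train_test(trials[1:2, ], seed = 1),
               class = "popmodes_ineligible")
})

test_that("mode weights never depend on held-out trials (train/test discipline)", {
  sim <- small_sim()
  s <- sim$session
  sp <- split_train_test(s$trials, seed = 31)
  p_train <- compute_psth(s, sp$train, window = c(-1, 0.5), bin_width = 0.01)
  cd <- compute_cd_delay(p_train)
  # perturb the held-out trials by dropping spikes in their windows
  s2 <- s
  drop <- s$spikes$spike_time >= min(sp$test$t_go) - 1 &
    s$spikes$spike_time < min(sp$test$t_go) + 0.5
  s2$spikes <- s$spikes[!(drop & seq_len(nrow(s$spikes)) %% 2 == 0), ]
  p_train2 <- compute_psth(s2, sp$train, window = c(-1, 0.5), bin_width = 0.01)
  cd2 <- compute_cd_delay(p_train2)
  expect_equal(cd2$weights, cd$weights, tolerance = 1e-12)
})

test_that("explained fractions: single mode, orthogonal mode, complete basis", {
  set.seed(9)
  right <- matrix(runif(50, 5, 15), 5, 10)
  left <- matrix(runif(50, 5, 15), 5, 10)
  p <- manual_psth(right, left, bin_width = 0.1, t0 = -0.5)
  sv <- selectivity_vector(p)
  # mode equal to w_t at one bin explains everything at that bin
  w3 <- sv$w[, 3]
  m3 <- popmodes:::new_mode_vector(w3 / sqrt(sum(w3^2)), p$unit_ids, "custom")
  res <- selectivity_explained(p, list(m = m3))
  frac3 <- res$fraction[res$mode == "m"][3]
  expect_equal(frac3, 1, tolerance = 1e-10)
  # orthogonal mode explains nothing
  v <- rnorm(5)
  v <- v - sum(v * m3$weights) * m3$weights
  m_orth <- popmodes:::new_mode_vector(v / sqrt(sum(v^2)), p$unit_ids, "custom")
  res_o <- selectivity_explained(p, list(m = m_orth))
  expect_lt(res_o$fraction[res_o$mode == "m"][3], 1e-10)
})

test_that("mode_angle matches arccos of the dot product on random vectors", {
  set.seed(13)
  m <- random_mode(10)
  expect_equal(mode_angle(m, m), 0, tolerance = 1e-6)
  v <- rnorm(10)
  v <- v - sum(v * m$weights) * m$weights
  m_orth <- popmodes:::new_mode_vector(v / sqrt(sum(v^2)), m$unit_ids, "custom")
  expect_equal(mode_angle(m, m_orth), pi / 2, tolerance = 1e-10)
  for (i in 1:20) {
    a <- random_mode(10)
    b <- popmodes:::new_mode_vector(
      {x <- rnorm(10); x / sqrt(sum(x^2))}, a$unit_ids, "custom")
    expect_equal(mode_angle(a, b),
                 acos(pmin(1, pmax(-1, sum(a$weights * b$weights)))),
                 tolerance = 1e-12)
    expect_gte(mode_angle(a, b), 0)
    expect_lte(mode_angle(a, b), pi)
  }
})

test_that("pseudopopulation draws disjoint train/test trials per cell, reproducibly", {
  cfg <- sim_config(n_animals = 1, sessions_per_animal = 2,
                    neurons_per_session = 6, n_trials_per_type = 45,
                    p_no_response = 0, p_incorrect = 0.05, p_early_lick = 0,
                    seed = 61)
  ds <- simulate_dataset(cfg)
  pp <- build_pseudopopulation(ds$sessions, n_cells = 8, trials_per_type = 20,
                               seed = 4, window = c(-1, 0.5))
  expect_equal(length(pp$train$unit_ids), 8)
  expect_identical(dim(pp$train$rates), dim(pp$test$rates))
  pp2 <- build_pseudopopulation(ds$sessions, n_cells = 8, trials_per_type = 20,
                                seed = 4, window = c(-1, 0.5))
  expect_identical(pp$train$rates, pp2$train$rates)
  # ineligible units excluded with log
  cfg_small <- sim_config(n_animals = 1, sessions_per_animal = 1,
                          neurons_per_session = 3, n_trials_per_type = 10,
                          seed = 62)
  ds_small <- simulate_dataset(cfg_small)
  expect_error(build_pseudopopulation(ds_small$sessions, n_cells = 2,
                                      trials_per_type = 20),
               class = "popmodes_ineligible")
})
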