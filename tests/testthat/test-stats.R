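test_that("rank-sum test matches exact enumeration on a tiny sample", {
  x <- c(1.1, 2.3, 3.7)
  y <- c(0.4, 0.9, 5.2)
  got <- popmodes:::ranksum_test(x, y)
  # brute force: exact two-sided p over all 6-choose-3 label assignments
  pool <- c(x, y)
  combs <- utils::combn(6, 3)
  w_obs <- sum(rank(pool)[1:3])
  ws <- apply(combs, 2, function(ix) sum(rank(pool)[ix]))
  mu <- mean(ws)
  p_exact <- mean(abs(ws - mu) >= abs(w_obs - mu))
  expect_equal(got, p_exact, tolerance = 1e-12)
})

test_that("epoch selectivity test flags planted delay-selective units", {
  sim <- small_sim()
  s <- sim$session
  gt <- sim$ground_truth$units
  strong <- gt$unit_id[abs(gt$sel_amp) > 8]
  skip_if(length(strong) == 0)
  res <- epoch_selectivity_test(s, strong[1], n_sub = 15, seed = 2)
  expect_true(res$selective[res$epoch == "delay"])
  pref <- res$preferred[res$epoch == "delay"]
  expect_equal(pref,
               if (gt$sel_amp[gt$unit_id == strong[1]] > 0) "lick_right"
               else "lick_left")
})

test_that("AUC: perfect separation, brute-force oracle, monotone invariance", {
  proj <- c(1, 2, 3, 4, -1, -2, -3, -4)
  labels <- rep(c("lick_right", "lick_left"), each = 4)
  expect_equal(roc_decode(proj, labels)$auc, 1)
  withr::with_seed(1, {
    for (i in 1:20) {
      x <- rnorm(8)
      pos <- rep(c(TRUE, FALSE), 4)
      auc <- popmodes:::auc_rank(x, pos)
      # brute force: P(pos > neg) + 0.5 P(tie) over all pairs
      pairs <- expand.grid(p = x[pos], n = x[!pos])
      brute <- mean((pairs$p > pairs$n) + 0.5 * (pairs$p == pairs$n))
      expect_equal(auc, brute, tolerance = 1e-12)
      # strictly monotone transform leaves AUC unchanged
      expect_equal(popmodes:::auc_rank(exp(2 * x), pos), auc)
    }
  })
  expect_error(roc_decode(proj, rep("a", 8)), class = "popmodes_error")
})

test_that("shuffled labels give chance-level AUC", {
  withr::with_seed(2, {
    x <- rnorm(40)
    aucs <- replicate(500, {
      popmodes:::auc_rank(x, sample(rep(c(TRUE, FALSE), 20)))
    })
  })
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 4 * se + 0.01)
})

test_that("population vector correlation: constant vector, block structure, oracle", {
  # time-constant population vector -> all-ones matrix
  r <- matrix(c(3, 7, 1), 3, 40)
  p <- manual_psth(r + 1, r, bin_width = 0.01, t0 = -0.2)
  cc <- population_vector_correlation(p, bin = 0.01, mode = "mean")
  expect_true(all(abs(cc - 1) < 1e-12))
  # two orthogonal epoch patterns -> block structure
  r2 <- cbind(matrix(c(10, 0, 0), 3, 20), matrix(c(0, 10, 0), 3, 20))
  p2 <- manual_psth(r2 + 1e-3, r2 * 0 + 1e-3, bin_width = 0.01, t0 = -0.2)
  cc2 <- population_vector_correlation(p2, bin = 0.01)
  expect_gt(mean(cc2[1:20, 1:20]), 0.99)
  expect_lt(mean(cc2[1:20, 21:40]), 0)
  # matches brute-force Pearson on a 3-neuron toy
  withr::with_seed(3, {
    rr <- matrix(runif(30), 3, 10)
    ll <- matrix(runif(30), 3, 10)
  })
  p3 <- manual_psth(rr, ll, bin_width = 0.01, t0 = 0)
  cc3 <- population_vector_correlation(p3, bin = 0.01)
  w <- rr - ll
  expect_equal(unclass(cc3)[2, 7], cor(w[, 2], w[, 7]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(cc3, t(cc3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(abs(diag(cc3) - 1) < 1e-12))
})

test_that("trial-mode correlation: identical copies, shuffle null, shapes", {
  withr::with_seed(4, pre <- matrix(rnorm(200), 50, 4))
  tmc <- trial_mode_correlation(pre, pre, seed = 9)
  expect_true(all(abs(diag(tmc$r) - 1) < 1e-12))
  expect_lt(mean(abs(tmc$r_shuffled)), 2 / sqrt(50) + 0.15)
  withr::with_seed(5, post <- matrix(rnorm(150), 50, 3))
  tmc2 <- trial_mode_correlation(pre, post, seed = 9)
  expect_equal(dim(tmc2$r), c(4, 3))
  expect_error(trial_mode_correlation(pre, post[1:10, ]),
               class = "popmodes_error")
})

test_that("go response amplitude: flat unit zero, antisymmetric under time reversal", {
  r <- matrix(5, 2, 100)
  r[2, 51:100] <- 11
  p <- manual_psth(r, r, bin_width = 0.01, t0 = -0.5)
  g <- go_response_amplitude(p)
  expect_equal(g$delta[g$unit_id == "u01"], c(0, 0))
  expect_equal(g$delta[g$unit_id == "u02"], c(6, 6))
  p_rev <- p
  p_rev$rates <- p$rates[, 100:1, , drop = FALSE]
  g_rev <- go_response_amplitude(p_rev)
  expect_equal(g_rev$delta, -g$delta)
})

test_that("logit model matches closed-form log-odds and flags separation", {
  # deterministic 2x2 toy: covariate 0 -> lick prob 1/4, covariate 1 -> 3/4
  d <- tibble::tibble(
    x = rep(c(0, 1), each = 40),
    licked = c(rep(c(TRUE, FALSE, FALSE, FALSE), 10),
               rep(c(TRUE, TRUE, TRUE, FALSE), 10))
  )
  m <- logit_lick_model(d, "x", n_boot = 0)
  # covariates are standardized internally; the raw-scale slope is the
  # log-odds difference between the two x levels
  sd_x <- sd(d$x)
  slope_raw <- unname(m$coefficients["x"]) / sd_x
  expect_equal(slope_raw, log(3) - log(1 / 3), tolerance = 1e-6)
  expect_false(m$separated)
  # complete separation flagged
  d2 <- tibble::tibble(x = c(rnorm(20, -3), rnorm(20, 3)),
                       licked = rep(c(FALSE, TRUE), each = 20))
  m2 <- suppressWarnings(logit_lick_model(d2, "x", n_boot = 0))
  expect_true(m2$separated)
  expect_error(logit_lick_model(tibble::tibble(x = 1:4, licked = TRUE), "x"),
               class = "popmodes_error")
})

test_that("planted monotone dependence on the go-mode change is recovered", {
  withr::with_seed(11, {
    n <- 400
    dgo <- rnorm(n)
    p <- stats::plogis(-0.3 + 1.2 * dgo)
    d <- tibble::tibble(
      animal_id = rep(1:4, each = 100),
      session_id = rep(1:8, each = 50),
      d_go_change = dgo,
      licked = runif(n) < p
    )
  })
  m <- logit_lick_model(d, "d_go_change", n_boot = 200, seed = 3)
  td <- tidy(m)
  row <- td[td$term == "d_go_change", ]
  expect_gt(row$estimate, 0)
  expect_gt(row$conf.low, 0)
})

test_that("sinusoidal modulation recovers planted amplitude and phase", {
  fs <- 1000
  time <- seq(0, 0.5 - 1 / fs, by = 1 / fs)  # 20 cycles of 40 Hz
  r <- 30 + 6 * cos(2 * pi * 40 * time + 0.8)
  res <- sinusoidal_modulation(r, time, freq = 40)
  expect_equal(res$amplitude, 6, tolerance = 1e-6)
  expect_equal(res$phase, 0.8, tolerance = 1e-6)
  # constant rate -> zero amplitude
  res0 <- sinusoidal_modulation(rep(12, length(time)), time, 40)
  expect_lt(res0$amplitude, 1e-10)
  # negating the sinusoid shifts the phase by pi
  res_neg <- sinusoidal_modulation(30 - 6 * cos(2 * pi * 40 * time + 0.8),
                                   time, 40)
  expect_equal(abs(abs(res_neg$phase - res$phase) - pi), 0, tolerance = 1e-6)
  expect_error(sinusoidal_modulation(r[1:333], time[1:333], 40),
               class = "popmodes_error")
})

test_that("density map: zero map, regularizer ceiling, brute-force oracle", {
  d0 <- density_map(runif(10, 0, 100), runif(10, 0, 100),
                    flagged = rep(FALSE, 10), pixel_um = 50)
  expect_true(all(d0$density == 0))
  # all flagged, dense cluster: density approaches n/(n+0.05) < 1
  xs <- rep(50, 20)
  d1 <- density_map(xs, xs, flagged = rep(TRUE, 20), xlim = c(0, 100),
                    ylim = c(0, 100), pixel_um = 50)
  peak <- max(d1$density)
  expect_lt(peak, 1)
  expect_gt(peak, 20 / 20.1)
  # 5-point brute force
  withr::with_seed(7, {
    x <- runif(5, 0, 200); y <- runif(5, 0, 200)
  })
  fl <- c(TRUE, FALSE, TRUE, FALSE, FALSE)
  dm <- density_map(x, y, fl, xlim = c(0, 200), ylim = c(0, 200),
                    pixel_um = 100)
  sigma <- 250 / sqrt(2 * log(2))
  px <- dm$x[2]; py <- dm$y[1]
  k <- exp(-((px - x)^2 + (py - y)^2) / (2 * sigma^2))
  expect_equal(dm$density[1, 2], sum(k[fl]) / (sum(k) + 0.05),
               tolerance = 1e-12)
})

test_that("LDA boundary: axis-aligned case, orthogonality, oracle and MASS cross-check", {
  # classes separated along x only with equal spread -> vertical boundary
  pts <- rbind(cbind(rep(c(-2, -1), 3), rep(c(-1, 0, 1), 2)),
               cbind(rep(c(1, 2), 3), rep(c(-1, 0, 1), 2)))
  lab <- rep(c("L", "R"), each = 6)
  b <- lda_boundary(pts, lab)
  expect_true(b$vertical)
  expect_equal(b$x_vertical, 0, tolerance = 1e-10)
  # isotropic classes: boundary perpendicular to the mean difference
  withr::with_seed(8, {
    a <- matrix(rnorm(400), 200, 2)
    c2 <- sweep(matrix(rnorm(400), 200, 2), 2, c(3, 3), "+")
  })
  b2 <- lda_boundary(rbind(a, c2), rep(c("a", "b"), each = 200))
  dirn <- b2$direction / sqrt(sum(b2$direction^2))
  md <- (colMeans(a) - colMeans(c2))
  expect_gt(abs(sum(dirn * md / sqrt(sum(md^2)))), 0.98)
  # 6-point toy equals the scatter-matrix solution written out by hand
  toy <- rbind(c(0, 0), c(1, 0), c(0, 1), c(3, 3), c(4, 3), c(3, 4))
  lab6 <- rep(c("x", "y"), each = 3)
  b3 <- lda_boundary(toy, lab6)
  m1 <- colMeans(toy[1:3, ]); m2 <- colMeans(toy[4:6, ])
  sw <- crossprod(scale(toy[1:3, ], scale = FALSE)) +
    crossprod(scale(toy[4:6, ], scale = FALSE))
  w <- solve(sw, m1 - m2)
  expect_equal(b3$direction, unname(w), tolerance = 1e-12)
  # classification agrees with MASS::lda (equal priors)
  skip_if_not_installed("MASS")
  fit <- MASS::lda(toy, grouping = lab6, prior = c(0.5, 0.5))
  pred <- as.character(predict(fit, toy)$class)
  side <- ifelse(toy %*% b3$direction > b3$threshold, "x", "y")
  expect_equal(unname(side[, 1]), pred)
})

test_that("response rate: boundary semantics, exclusions, hand-counted fixture", {
  trials <- tibble::tibble(
    trial_index = 1:10,
    type = rep(c("lick_right", "lick_left"), 5),
    outcome = c("correct", "correct", "incorrect", "no_response", "correct",
                "early_lick", "correct", "incorrect", "no_response", "correct"),
    perturbation = "none",
    t_sample_on = 0, t_delay_on = 1, t_go = 2,
    first_lick_time = 2 + c(0.1, 0.3, 0.2, NA, 0.625, 0.5, 0.5, 0.625, NA, 0.0),
    first_lick_direction = c("right", "left", "right", NA, "right",
                             "right", "right", "right", NA, "right")
  )
  # early-lick (trial 6) excluded: 9 trials; licks in [0, 0.625): 1,2,3,7,10 -> 5/9
  expect_equal(response_rate(trials, c(0, 0.625)), 5 / 9)
  # lick exactly at the upper edge is excluded (half-open window)
  expect_equal(response_rate(trials, c(0, 0.5)), 4 / 9)
  # correct rate among trials licked in-window: 1 (R/R), 2 (L/L), 3 (R/R),
  # 7 (R/R), 10 (L instructed, licked right) -> 4/5
  expect_equal(response_rate(trials, c(0, 0.625), type = "correct"), 4 / 5)
  expect_true(is.na(response_rate(trials[0, ], c(0, 0.6))))
})
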