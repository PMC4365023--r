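test_that("time thinning keeps endpoints and validates subsets", {
  times <- grid_full()
  expect_identical(thin_timepoints(times, stride = 1), times)
  tstar <- thin_timepoints(times)  # default stride 16 on the 0.25 h grid
  expect_length(tstar, 13)
  expect_identical(tstar[1], times[1])
  expect_identical(tstar[length(tstar)], times[length(times)])
  expect_identical(thin_timepoints(times, subset = c(0, 24, 47.75)),
                   c(0, 24, 47.75))
  expect_error(thin_timepoints(times, subset = c(0, 24.1)), "not on the grid")
})

test_that("effect inputs are the per-array fitted values at T*", {
  times <- grid_coarse()
  tstar <- thin_timepoints(times, subset = c(0, 10, 24, 47.5))
  plates <- lapply(1:2, function(i) {
    sig <- rbind(W1 = rep(50, length(times)),
                 W2 = logistic_curve(times, 200, 10, 2))
    pm_plate(as.character(i), times, sig, "28", "s", i)
  })
  exp <- pm_experiment(plates, c("28", "s"))
  labels <- list(`1` = c(W1 = "non-active", W2 = "active"),
                 `2` = c(W1 = "non-active", W2 = "active"))
  inp <- build_effect_input(exp, labels, "W1", tstar)
  expect_equal(dim(inp$y), c(2, length(tstar)))
  expect_equal(unname(inp$y), matrix(50, 2, length(tstar)), tolerance = 1e-8)
  inp2 <- build_effect_input(exp, labels, "W2", tstar)
  # the fitted logistic passes through asym/2 at xmid = 10
  expect_equal(unname(inp2$y[, tstar == 10]), c(100, 100), tolerance = 1e-4)
})

test_that("control-only data give a tight conjugate posterior for zeta", {
  design <- structure(
    list(a = rep(1, 6), b = rep(1, 6), levels_a = "A1", levels_b = "B1",
         array_id = as.character(1:6)),
    class = "pm_design"
  )
  input <- list(substrate = "w", y = matrix(100, 6, 2),
                tstar = c(0, 24), array_id = design$array_id)
  ch <- sample_effects(input, design, sigma2 = 1, n_iter = 3000,
                       burn_in = 500, n_chains = 1, seed = 2)
  expect_equal(colMeans(ch$draws$zeta), c(100, 100), tolerance = 0.1)
  expect_true(all(ch$draws$zeta >= 0 & ch$draws$zeta <= 400))
})

test_that("Gibbs means match the closed-form Gaussian posterior", {
  design <- design_2x2(3)
  sim <- simulate_effect_dataset(design, zeta = 150, alpha = -40, beta = 60,
                                 gamma = -20, sigma2 = 25,
                                 tstar = c(0, 24, 47.75), seed = 42)
  ch <- sample_effects(sim$input, design, sigma2 = 25, n_iter = 6000,
                       burn_in = 1000, n_chains = 1, seed = 7,
                       zeta_support = c(-1e8, 1e8))
  nms <- c("zeta", "alpha2", "beta2", "gamma2_2")
  for (j in seq_along(sim$input$tstar)) {
    exact <- conjugate_posterior(sim$input$y[, j], design, sigma2 = 25)
    for (k in seq_along(nms)) {
      d <- ch$draws[[nms[k]]][, j]
      expect_lt(abs(mean(d) - exact$mean[k]), 3 * mc_se(d) + 1e-8)
      expect_equal(sd(d), exact$sd[k], tolerance = 0.1)
    }
  }
})

test_that("zeta samples never leave the prior support, with a bound warning", {
  design <- design_2x2(2)
  set.seed(1)
  input <- list(substrate = "w",
                y = matrix(rnorm(8 * 2, 450, 5), 8, 2),
                tstar = c(0, 24), array_id = design$array_id)
  expect_warning(
    ch <- sample_effects(input, design, sigma2 = 25, n_iter = 1000,
                         burn_in = 200, n_chains = 1, seed = 3),
    "prior support"
  )
  expect_true(all(ch$draws$zeta >= 0 & ch$draws$zeta <= 400))
})

test_that("summaries report equal-tailed intervals and significance", {
  # degenerate chain at zero: interval [0,0], not significant
  ch0 <- fake_chains(list(zeta = matrix(100, 500, 1),
                          alpha2 = matrix(0, 500, 1)),
                     tstar = 0, types = c("control", "A"))
  s <- summarize_effects(ch0)
  a <- s[s$effect_type == "A", ]
  expect_equal(c(a$mean, a$lower, a$upper), c(0, 0, 0))
  expect_false(a$significant)
  expect_true(is.na(s$significant[s$effect_type == "control"]))
  # standard normal draws: interval matches the empirical quantile oracle
  set.seed(6)
  z <- matrix(rnorm(20000), ncol = 1)
  ch1 <- fake_chains(list(alpha2 = z), tstar = 0, types = "A")
  s1 <- summarize_effects(ch1)
  expect_equal(s1$lower, unname(quantile(z, 0.025)), tolerance = 1e-10)
  expect_equal(s1$upper, unname(quantile(z, 0.975)), tolerance = 1e-10)
  expect_equal(s1$lower, -1.96, tolerance = 0.01)
  expect_equal(s1$upper, 1.96, tolerance = 0.01)
})

test_that("time averaging is a per-draw mean and cancels alternating effects", {
  # +5 at half the time points, -5 at the other half -> average 0
  d <- matrix(rep(c(5, -5), each = 10), nrow = 1)
  ch <- fake_chains(list(alpha2 = d[rep(1, 100), ]),
                    tstar = seq_len(20), types = "A")
  av <- average_over_time(ch)
  expect_equal(av$mean, 0)
  expect_false(av$significant)
  # time-linear effect 0..-10 over 11 points -> average -5
  d2 <- matrix(seq(0, -10, length.out = 11), nrow = 1)
  ch2 <- fake_chains(list(alpha2 = d2[rep(1, 100), ]),
                     tstar = seq_len(11), types = "A")
  expect_equal(average_over_time(ch2)$mean, -5)
  # identical effect at all t -> the common value
  d3 <- matrix(7, 100, 4)
  ch3 <- fake_chains(list(alpha2 = d3), tstar = 1:4, types = "A")
  expect_equal(average_over_time(ch3)$mean, 7)
})

test_that("relabeling the control leaves fitted cell means invariant", {
  design <- design_2x2(3)
  sim <- simulate_effect_dataset(design, zeta = 150, alpha = -40, beta = 60,
                                 gamma = -20, sigma2 = 25, tstar = c(0, 24),
                                 seed = 5)
  # posterior mean of mu for each design cell, keyed by the cell's
  # position in the sampler's own coordinates
  cell_means <- function(design) {
    ch <- sample_effects(sim$input, design, sigma2 = 25, n_iter = 3000,
                         burn_in = 500, n_chains = 1, seed = 9,
                         zeta_support = c(-1e6, 1e6))
    z <- colMeans(ch$draws$zeta)
    al <- colMeans(ch$draws$alpha2)
    be <- colMeans(ch$draws$beta2)
    ga <- colMeans(ch$draws$gamma2_2)
    list(`11` = z, `21` = z + al, `12` = z + be, `22` = z + al + be + ga)
  }
  mu1 <- cell_means(design)
  # swap the control to the opposite cell: sampler cell (1,1) is now the
  # original (2,2) and vice versa
  design2 <- design
  design2$a <- 3 - design$a
  design2$b <- 3 - design$b
  mu2 <- cell_means(design2)
  expect_equal(mu1$`11`, mu2$`22`, tolerance = 0.01)
  expect_equal(mu1$`22`, mu2$`11`, tolerance = 0.01)
  expect_equal(mu1$`21`, mu2$`12`, tolerance = 0.01)
  expect_equal(mu1$`12`, mu2$`21`, tolerance = 0.01)
})

test_that("run_effects produces one summary block per well", {
  fx <- scaled_replicates(c(1.1, 1.0, 0.9), n_each = 3)
  gs <- lapply(fx$experiment$plates, group_plate, threshold = 100)
  norm <- normalize_experiment(fx$experiment, gs)
  tstar <- thin_timepoints(fx$experiment$times, stride = 24)
  eff <- run_effects(norm, tstar = tstar, n_iter = 400, burn_in = 100,
                     n_chains = 1, seed = 3)
  wells <- fx$experiment$plates[[1]]$wells
  expect_setequal(unique(eff$substrate), wells)
  # single condition: only the control effect exists
  expect_setequal(unique(eff$effect_type), "control")
  expect_true(all(eff$lower <= eff$mean & eff$mean <= eff$upper))
})
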