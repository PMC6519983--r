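test_that("single-step first-branch oracle matches its closed form", {
  p <- sim_params()
  o <- first_branch_oracle_single_step(p)
  # sqrt(pi * 0.09 / (2 * 1.1e-3))
  expect_equal(o$mean_length, 11.33665, tolerance = 1e-5)
  expect_equal(o$survival(0), 1)
  expect_equal(o$survival(100), exp(-1.1e-3 * 0.09 * 100^2 / 2))
  # doubling k divides the mean length by sqrt(2)
  p2 <- p; p2$k <- 2 * p$k
  expect_equal(first_branch_oracle_single_step(p2)$mean_length,
               o$mean_length / sqrt(2), tolerance = 1e-12)
})

test_that("sequential first-branch oracle agrees with the cubic small-rate limit", {
  p <- sim_params()
  o <- first_branch_oracle_sequential(p)
  expect_equal(o$survival(0), 1)
  # survival monotone non-increasing
  ts <- seq(0, 400, by = 10)
  expect_true(all(diff(o$survival(ts)) <= 1e-12))
  # (6 / (k_bind v_pe k_branch))^(1/3) * Gamma(4/3) = 123.83 s; quadrature
  # within 3% of the limit at these parameters
  expect_equal(o$mean_time_smallkb, 123.8315, tolerance = 1e-5)
  expect_lt(abs(o$mean_time - o$mean_time_smallkb) / o$mean_time_smallkb, 0.03)
  expect_equal(o$mean_length, 0.09 * o$mean_time)
  # k_branch -> Inf: sequential survival approaches the single-step law with
  # k = k_bind
  pf <- p; pf$k_branch <- 50; pf$dt <- 1e-3
  of <- first_branch_oracle_sequential(pf)
  ss <- function(t) exp(-p$k_bind * p$v_pe * t^2 / 2)
  for (t in c(2, 5, 10)) expect_equal(of$survival(t), ss(t), tolerance = 0.02)
})

test_that("asymptotic growth rates solve the characteristic equations", {
  p <- sim_params()
  expect_equal(asymptotic_growth_rate("single_step", p), sqrt(1.1e-3 * 0.09))
  lam <- asymptotic_growth_rate("sequential", p)
  expect_equal(lam, 0.0130209, tolerance = 1e-5)
  # root property
  expect_equal(lam^2 * (lam + p$k_branch), p$k_bind * p$k_branch * p$v_pe,
               tolerance = 1e-10)
  # k_branch -> Inf limit
  pf <- p; pf$k_branch <- 1e5; pf$dt <- 1e-7
  expect_equal(asymptotic_growth_rate("sequential", pf),
               sqrt(p$k_bind * p$v_pe), tolerance = 1e-3)
})

test_that("dimensionless ratio is k_branch over sqrt(k_bind v_pe)", {
  p <- sim_params()
  expect_equal(dimensionless_ratio(p), 2.5e-4 / sqrt(0.1 * 0.09))
  p$k_branch <- sqrt(p$k_bind * p$v_pe)
  expect_equal(dimensionless_ratio(p), 1)
})

test_that("k = 0 yields a lone seed growing at v_pe", {
  net <- quiet_sim(sim_params(k = 0, seed = 3, t_max = 200, max_mts = 10),
                   "single_step")
  expect_equal(nrow(net$mts), 1)
  expect_equal(total_length(net, net$t_end), 0.09 * net$t_end)
  # k_branch = 0: sites accumulate but never fire
  net2 <- quiet_sim(sim_params(k_branch = 0, seed = 3, t_max = 200,
                               max_mts = 10), "sequential")
  expect_equal(nrow(net2$mts), 1)
  expect_gt(nrow(net2$sites), 0)
  expect_true(all(is.na(net2$sites$branch_time)))
})

test_that("site deposition on a lone mother matches k_bind v_pe t^2/2", {
  set.seed(31)
  t_max <- 150
  counts <- replicate(60, {
    net <- quiet_sim(sim_params(k_branch = 0, t_max = t_max, max_mts = 2),
                     "sequential")
    nrow(net$sites)
  })
  expected <- 0.1 * 0.09 * t_max^2 / 2   # 101.25
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 0.02 * expected)
  # deposited sites always lie on existing lattice and are never consumed
  net <- quiet_sim(sim_params(k_branch = 0, seed = 8, t_max = t_max,
                              max_mts = 2), "sequential")
  expect_true(all(net$sites$arc_pos <= 0.09 * net$sites$deposit_time + 1e-9))
})

test_that("simulated first-branch ensembles match the oracles", {
  set.seed(101)
  n <- 400
  ss <- simulate_first_branch_ensemble(sim_params(t_max = 1500), "single_step", n)
  len_ss <- ss$d_minus + ss$d_plus
  o_ss <- first_branch_oracle_single_step(sim_params())
  se <- sd(len_ss, na.rm = TRUE) / sqrt(n)
  expect_lt(abs(mean(len_ss, na.rm = TRUE) - o_ss$mean_length),
            3 * se + 0.015 * o_ss$mean_length)

  sq <- simulate_first_branch_ensemble(sim_params(t_max = 1500), "sequential", n)
  o_sq <- first_branch_oracle_sequential(sim_params())
  se_t <- sd(sq$t1, na.rm = TRUE) / sqrt(n)
  expect_lt(abs(mean(sq$t1, na.rm = TRUE) - o_sq$mean_time),
            3 * se_t + 0.015 * o_sq$mean_time)
  # single-step fractional position is uniform (KS not rejected at tiny alpha)
  ks <- suppressWarnings(stats::ks.test(ss$fraction, "punif"))
  expect_gt(ks$p.value, 1e-3)
  # sequential shows a positive minus-end bias
  expect_gt(bias_statistic(sq$fraction), 0.2)
  # no site is consumed twice and consumed fraction is at most 1
  net <- quiet_sim(sim_params(seed = 12, t_max = 500, max_mts = 30), "sequential")
  expect_lte(sum(!is.na(net$sites$branch_time)), nrow(net$sites))
  expect_equal(sum(!is.na(net$sites$branch_time)), nrow(net$mts) - 1)
})

test_that("halving the step size leaves ensemble means unchanged", {
  set.seed(55)
  n <- 600
  m1 <- simulate_first_branch_ensemble(sim_params(t_max = 1200, dt = 1),
                                       "sequential", n)
  m2 <- simulate_first_branch_ensemble(sim_params(t_max = 1200, dt = 0.5),
                                       "sequential", n)
  mu1 <- mean(m1$t1, na.rm = TRUE); mu2 <- mean(m2$t1, na.rm = TRUE)
  pooled_se <- sqrt(var(m1$t1, na.rm = TRUE) / n + var(m2$t1, na.rm = TRUE) / n)
  expect_lt(abs(mu1 - mu2), 3 * pooled_se + 0.01 * mu1)
})

test_that("long-time count growth matches the asymptotic rate", {
  set.seed(77)
  # single-path slope estimates carry branching-process noise of a few
  # percent; average over replicates
  for (model in c("single_step", "sequential")) {
    lam <- asymptotic_growth_rate(model, sim_params())
    slopes <- replicate(8, {
      net <- quiet_sim(sim_params(t_max = 1800, max_mts = 500), model)
      births <- sort(net$mts$birth_time)
      t_grid <- seq(births[100], net$t_end, by = 5)
      counts <- vapply(t_grid, function(t) sum(births <= t), 0)
      unname(coef(lm(log(counts) ~ t_grid))[2])
    })
    expect_lt(abs(mean(slopes) - lam) / lam, 0.05)
  }
})

test_that("parameter scan calibration holds the first-branch length fixed", {
  p <- sim_params()
  target <- first_branch_oracle_sequential(p)$mean_length
  sc <- suppressWarnings(parameter_scan(c(0.01, 1), p, n = 120))
  for (i in 1:2) {
    pi_ <- p; pi_$k_bind <- sc$k_bind[i]; pi_$k_branch <- sc$k_branch[i]
    expect_equal(first_branch_oracle_sequential(pi_)$mean_length, target,
                 tolerance = 1e-6)
    expect_equal(sc$k_branch[i] / sqrt(sc$k_bind[i] * p$v_pe), sc$ratio[i],
                 tolerance = 1e-9)
  }
  expect_true(all(is.finite(sc$bias_statistic)))
  expect_warning(parameter_scan(1, p, n = 50), "noisy")
})
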