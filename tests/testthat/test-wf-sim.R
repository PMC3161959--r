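test_that("multiplicative diploid fitness matches hand-computed examples", {
  expect_equal(diploid_fitness(-0.0025, FALSE, h = 0.5), 0.99875)
  expect_equal(diploid_fitness(c(0.025, -0.0025), c(TRUE, FALSE), h = 0.5),
               1.025 * 0.99875)
  expect_equal(diploid_fitness(numeric(0), logical(0)), 1)
})

test_that("parameter invariants are enforced", {
  expect_error(wf_params(N = 1), "N")
  expect_error(wf_params(gamma_d = 1), "gamma_d")
  expect_error(wf_params(gamma_a = -1), "gamma_a")
  expect_error(wf_params(h = 1.5))
  expect_error(wf_params(N = 10, sample_n = 21), "2N")
})

test_that("mutation influx matches the Poisson(2Nu) rate", {
  # from an empty population, one generation adds Poisson(theta/2) new
  # mutations per class; with theta_n = 70 the mean is 35
  p <- wf_params(N = 1000, theta_n = 70, theta_d = 0, theta_a = 0,
                 gamma_d = 0, rho = 0, burn_in = 1, sample_n = 10)
  set.seed(11)
  counts <- vapply(1:150, function(i) run_burn_in(p)$n_seg[["neutral"]], numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 35), 3 * se)
})

test_that("zero mutation rates give zero segregating sites", {
  p <- wf_params(N = 50, theta_n = 0, theta_d = 0, theta_a = 0, gamma_d = 0,
                 rho = 1, burn_in = 100, sample_n = 20)
  b <- run_burn_in(p, seed = 1, log_trajectory = TRUE)
  expect_true(all(b$n_seg == 0))
  expect_true(all(b$trajectory$n_seg == 0))
  expect_true(all(b$sfs$n_sites == 0))
})

test_that("sampled spectra satisfy the output contract", {
  p <- wf_params(N = 60, theta_n = 15, theta_d = 15, burn_in = 600,
                 sample_n = 30, rho = 2)
  b <- run_burn_in(p, seed = 3)
  expect_true(all(b$sfs$n_sites >= 0))
  expect_true(all(b$sfs$derived_count >= 1 & b$sfs$derived_count <= 29))
  expect_setequal(unique(b$sfs$mclass), c("neutral", "deleterious", "advantageous"))
})

test_that("identical seeds give identical results", {
  p <- wf_params(N = 40, theta_n = 10, theta_d = 10, rho = 1,
                 burn_in = 300, sample_n = 20)
  a <- run_single_sweep(p, seed = 99)
  b <- run_single_sweep(p, seed = 99)
  expect_identical(a$pre_sfs, b$pre_sfs)
  expect_identical(a$post_sfs, b$post_sfs)
  expect_identical(a$attempts, b$attempts)
})

test_that("negative selection suppresses deleterious diversity", {
  # paired comparison: same theta with and without selection
  set.seed(7)
  sel <- wf_params(N = 100, theta_n = 20, theta_d = 20, gamma_d = -10,
                   rho = 2, burn_in = 2000, sample_n = 50)
  neu <- wf_params(N = 100, theta_n = 20, theta_d = 20, gamma_d = 0,
                   rho = 2, burn_in = 2000, sample_n = 50)
  tw <- function(params) {
    mean(vapply(1:12, function(i) {
      class_thetas(run_burn_in(params)$sfs, 50) %>%
        dplyr::filter(mclass == "deleterious") %>%
        dplyr::pull(theta_w)
    }, numeric(1)))
  }
  expect_lt(tw(sel), tw(neu))
})

test_that("the sweep sample is conditioned on fixation", {
  p <- wf_params(N = 50, theta_n = 10, theta_d = 10, rho = 1,
                 burn_in = 300, sample_n = 20)
  s <- run_single_sweep(p, seed = 5)
  expect_true(s$sweep_fixed)
  expect_equal(s$sweep_final_count, 2 * 50)
  expect_gte(s$attempts, 1)
  expect_gt(s$sweep_generations, 0)
})

test_that("the re-injection attempt cap errors with the attempt count", {
  p <- wf_params(N = 40, theta_n = 5, theta_d = 0, rho = 0,
                 burn_in = 50, sample_n = 10)
  expect_error(run_single_sweep(p, seed = 2, max_attempts = 0), "0 attempts")
})

test_that("a sweep without recombination erases all standing variation", {
  p <- wf_params(N = 100, rho = 0, burn_in = 2000, sample_n = 50)
  for (seed in 1:3) {
    s <- run_single_sweep(p, seed = seed)
    standing <- class_thetas(s$post_standing_sfs, 50)
    expect_true(all(standing$theta_pi == 0))
    expect_true(all(standing$S == 0))
  }
})

test_that("recurrent mode with theta_a = 0 is a plain burn-in continuation", {
  p <- wf_params(N = 50, theta_n = 10, theta_d = 10, theta_a = 0,
                 rho = 1, burn_in = 300, sample_n = 20)
  r <- run_recurrent_sweeps(p, n_epochs = 3, seed = 4)
  expect_equal(unname(r$n_fixed["advantageous"]), 0)
  expect_true(all(r$sfs$n_sites[r$sfs$mclass == "advantageous"] == 0))
  expect_setequal(unique(r$sfs$epoch), 1:3)
})

test_that("sweep_study returns the long per-replicate layout", {
  p <- wf_params(N = 30, theta_n = 8, theta_d = 8, burn_in = 150, sample_n = 10)
  st <- sweep_study(p, rho = c(0, 1), n_reps = 2, mode = "single", seed = 8)
  expect_setequal(unique(st$phase), c("pre", "post", "post_standing"))
  expect_equal(nrow(st), 2 * 2 * 3 * 3)  # rho x rep x phase x class
  rat <- suppressWarnings(aggregate_class_ratio(st, "theta_w"))
  expect_setequal(names(rat), c("rho", "phase", "ratio"))
})
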