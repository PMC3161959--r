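#' Parameters for the Wright-Fisher hitchhiking simulator
#'
#' All selection and mutation parameters are population-scaled, so dynamics
#' depend on them (not on `N`) and a scaled-down `N` with the same
#' `theta`/`gamma` values reproduces the same standardized behaviour.
#' Defaults are the single-sweep study conditions: `4Nu_n = 70`,
#' `4Nu_d = 70`, `4Ns_d = -10`, `4Ns_a = 100`, `4Nu_a = 0.5`, `h = 0.5`,
#' `N = 1000` diploids, burn-in of `20 N` generations, and samples of 100
#' chromosomes.
#'
#' @param N Diploid population size (2N chromosomes).
#' @param theta_n,theta_d,theta_a Population-scaled mutation rates
#'   `4 N u` per chromosome for neutral, deleterious, and advantageous
#'   mutations (`theta_a` is used in recurrent mode only).
#' @param gamma_d Scaled selection coefficient `4 N s_d` of a deleterious
#'   homozygote (must be `<= 0`).
#' @param gamma_a Scaled selection coefficient `4 N s_a` of an advantageous
#'   homozygote (must be `>= 0`).
#' @param h Dominance coefficient in `[0, 1]` applied to all non-neutral
#'   mutations.
#' @param rho Population recombination parameter: expected crossover events
#'   per population per generation (`N r`, with `r` per individual meiosis
#'   across the unit-interval chromosome).
#' @param burn_in Burn-in generations before any sampling (default `20 N`).
#' @param sample_n Chromosomes sampled without replacement for spectra.
#' @return A validated `wf_params` list.
#' @export
wf_params <- function(N = 1000, theta_n = 70, theta_d = 70, theta_a = 0.5,
                      gamma_d = -10, gamma_a = 100, h = 0.5, rho = 0,
                      burn_in = 20 * N, sample_n = 100) {
  stopifnot(N >= 2, theta_n >= 0, theta_d >= 0, theta_a >= 0,
            gamma_d <= 0, gamma_a >= 0, h >= 0, h <= 1, rho >= 0,
            burn_in >= 0, sample_n >= 2)
  if (sample_n > 2 * N) abort("sample_n must be <= 2N")
  structure(
    list(N = as.integer(N), theta_n = theta_n, theta_d = theta_d,
         theta_a = theta_a, gamma_d = gamma_d, gamma_a = gamma_a,
         h = h, rho = rho, burn_in = as.integer(burn_in),
         sample_n = as.integer(sample_n)),
    class = "wf_params"
  )
}

#' @export
print.wf_params <- function(x, ...) {
  cat("Wright-Fisher simulation parameters\n")
  cat(sprintf("  N = %d diploids (2N = %d chromosomes), burn-in %d generations\n",
              x$N, 2 * x$N, x$burn_in))
  cat(sprintf("  4Nu: neutral %.3g, deleterious %.3g, advantageous %.3g\n",
              x$theta_n, x$theta_d, x$theta_a))
  cat(sprintf("  4Ns: deleterious %.3g, advantageous %.3g; h = %.2f; rho = %.3g\n",
              x$gamma_d, x$gamma_a, x$h, x$rho))
  cat(sprintf("  sample size %d chromosomes\n", x$sample_n))
  invisible(x)
}

sfs_matrix_to_tibble <- function(mat) {
  # Dense layout: a class with zero segregating sites must still contribute
  # zero-valued estimates to replicate means, so zero cells are kept.
  tibble(
    mclass = rep(MCLASS, times = ncol(mat)),
    derived_count = rep(seq_len(ncol(mat)), each = 3L),
    n_sites = as.integer(mat)
  )
}

#' Multiplicative diploid fitness over non-neutral sites
#'
#' Fitness is the product over sites of `1 + h s` for heterozygous and
#' `1 + s` for homozygous genotypes, exactly as used inside the simulator.
#'
#' @param s Homozygote selection coefficients, one per non-neutral site.
#' @param homozygous Logical vector: is the individual homozygous at the site?
#' @param h Dominance coefficient.
#' @return The fitness (a single number).
#' @examples
#' diploid_fitness(-0.0025, FALSE, h = 0.5)          # 0.99875
#' diploid_fitness(c(0.025, -0.0025), c(TRUE, FALSE)) # 1.025 * 0.99875
#' @export
diploid_fitness <- function(s, homozygous, h = 0.5) {
  wf_cpp_diploid_fitness(as.numeric(s), as.logical(homozygous), h)
}

#' Burn a population to mutation-selection-drift equilibrium
#'
#' Runs `burn_in` generations from an empty population and samples a
#' per-class site frequency spectrum. With selection off the sampled
#' spectra satisfy `E[theta_w] = E[theta_pi] = E[theta_h] = theta_n`.
#'
#' @param params A [wf_params()] object.
#' @param seed Optional RNG seed (`set.seed()` is called when supplied).
#' @param recurrent_mutation If `TRUE`, advantageous mutations also arise
#'   during the burn (recurrent-sweep regime); otherwise `theta_a` is
#'   ignored.
#' @param log_trajectory If `TRUE`, also return the per-generation count of
#'   segregating sites per class.
#' @return A `wf_burn` list: `sfs` (tibble `mclass`, `derived_count`,
#'   `n_sites`), `n_seg`, `n_fixed` (named per class), `trajectory`
#'   (tibble or `NULL`), and `params`.
#' @export
run_burn_in <- function(params, seed = NULL, recurrent_mutation = FALSE,
                        log_trajectory = FALSE) {
  stopifnot(inherits(params, "wf_params"))
  if (!is.null(seed)) set.seed(seed)
  res <- wf_cpp_burn(params$N, params$theta_n, params$theta_d, params$theta_a,
                     params$gamma_d, params$gamma_a, params$h, params$rho,
                     params$burn_in, params$sample_n, recurrent_mutation,
                     log_trajectory)
  traj <- NULL
  if (log_trajectory) {
    traj <- tibble(
      generation = rep(seq_len(nrow(res$trajectory)), times = 3L),
      mclass = rep(MCLASS, each = nrow(res$trajectory)),
      n_seg = as.integer(res$trajectory)
    )
  }
  structure(
    list(sfs = sfs_matrix_to_tibble(res$sfs),
         n_seg = setNames(res$n_seg, MCLASS),
         n_fixed = setNames(res$n_fixed, MCLASS),
         trajectory = traj, params = params),
    class = "wf_burn"
  )
}

#' Simulate a single selective sweep conditional on fixation
#'
#' After the burn-in, a matched pre-sweep sample is drawn, the state is
#' snapshotted, and one advantageous mutation (selection `gamma_a`) is
#' injected at the chromosome midpoint on a single random chromosome.
#' Generations are iterated until it fixes; on loss the snapshot is
#' restored and a fresh attempt is made, so the returned sample is always
#' conditioned on fixation. The post-sweep sample is taken at the fixation
#' generation and is also split into standing variation (mutations that
#' predate the sweep) versus all segregating sites.
#'
#' @inheritParams run_burn_in
#' @param max_attempts Cap on re-injection attempts before erroring.
#' @return A `wf_sweep` list: tibbles `pre_sfs`, `post_sfs`,
#'   `post_standing_sfs`; `attempts`, `sweep_generations` (injection to
#'   fixation), `sweep_final_count` (`2N` by construction), `sweep_fixed`
#'   flag, `n_fixed`, and `params`.
#' @export
run_single_sweep <- function(params, seed = NULL, max_attempts = 10000) {
  stopifnot(inherits(params, "wf_params"))
  if (params$gamma_a <= 0) abort("single-sweep mode requires gamma_a > 0")
  if (!is.null(seed)) set.seed(seed)
  res <- wf_cpp_single_sweep(params$N, params$theta_n, params$theta_d,
                             params$gamma_d, params$gamma_a, params$h,
                             params$rho, params$burn_in, params$sample_n,
                             as.integer(max_attempts))
  structure(
    list(pre_sfs = sfs_matrix_to_tibble(res$pre_sfs),
         post_sfs = sfs_matrix_to_tibble(res$post_sfs),
         post_standing_sfs = sfs_matrix_to_tibble(res$post_standing_sfs),
         attempts = res$attempts,
         sweep_generations = res$sweep_generations,
         sweep_final_count = res$sweep_final_count,
         sweep_fixed = TRUE,
         n_fixed = setNames(res$n_fixed, MCLASS),
         params = params),
    class = "wf_sweep"
  )
}

#' Simulate recurrent selective sweeps
#'
#' Advantageous mutations arise at rate `theta_a / 2` per generation
#' uniformly along the chromosome, during the burn-in and throughout the
#' sampled epochs. A per-class spectrum is sampled every `epoch_gens`
#' generations (default `N`).
#'
#' @inheritParams run_burn_in
#' @param n_epochs Number of sampling epochs after the burn-in.
#' @param epoch_gens Generations between samples (default `N`).
#' @return A `wf_recurrent` list with `sfs` (tibble with an `epoch`
#'   column), `adv_fixed_cum` (cumulative advantageous fixations at each
#'   epoch), `n_fixed`, and `params`.
#' @export
run_recurrent_sweeps <- function(params, n_epochs = 5, seed = NULL,
                                 epoch_gens = params$N) {
  stopifnot(inherits(params, "wf_params"), n_epochs >= 1)
  if (!is.null(seed)) set.seed(seed)
  res <- wf_cpp_recurrent(params$N, params$theta_n, params$theta_d,
                          params$theta_a, params$gamma_d, params$gamma_a,
                          params$h, params$rho, params$burn_in,
                          params$sample_n, as.integer(n_epochs),
                          as.integer(epoch_gens))
  sfs <- imap(res$sfs_by_epoch, function(m, e) {
    sfs_matrix_to_tibble(m) %>% mutate(epoch = e, .before = 1)
  }) %>% list_rbind()
  structure(
    list(sfs = sfs,
         adv_fixed_cum = res$adv_fixed_cum,
         n_fixed = setNames(res$n_fixed, MCLASS),
         params = params),
    class = "wf_recurrent"
  )
}

#' Replicated sweep study across recombination rates
#'
#' Runs replicate simulations across a grid of recombination parameters and
#' returns per-replicate diversity estimates by class, in the long layout
#' consumed by [aggregate_thetas()] and [aggregate_class_ratio()]. For
#' `mode = "single"` each replicate contributes a pre- and a post-sweep
#' phase; for `mode = "recurrent"` each sampling epoch is one phase, and a
#' matched control with `theta_a = 0` can be added with `paired_control`.
#'
#' @param params A [wf_params()] object (its `rho` is overridden by `rho`).
#' @param rho Recombination grid (population events per generation).
#' @param n_reps Replicates per grid point.
#' @param mode `"single"` or `"recurrent"`.
#' @param seed Optional seed for the whole study.
#' @param n_epochs,paired_control Recurrent mode: epochs per replicate, and
#'   whether to run a matched `theta_a = 0` control arm.
#' @return A tibble: `rho`, `rep`, `phase`, `mclass`, and the estimator
#'   columns of [theta_estimates()]. Class `wf_study`.
#' @export
sweep_study <- function(params, rho = c(0, 0.1, 1, 10, 100), n_reps = 50,
                        mode = c("single", "recurrent"), seed = NULL,
                        n_epochs = 5, paired_control = TRUE) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  grid <- crossing(rho = rho, rep = seq_len(n_reps))
  rows <- pmap(grid, function(rho, rep) {
    p <- params
    p$rho <- rho
    if (mode == "single") {
      r <- run_single_sweep(p)
      bind_rows(
        class_thetas(r$pre_sfs, p$sample_n) %>% mutate(phase = "pre"),
        class_thetas(r$post_sfs, p$sample_n) %>% mutate(phase = "post"),
        class_thetas(r$post_standing_sfs, p$sample_n) %>%
          mutate(phase = "post_standing")
      ) %>% mutate(rho = rho, rep = rep, .before = 1)
    } else {
      r <- run_recurrent_sweeps(p, n_epochs = n_epochs)
      out <- class_thetas(r$sfs, p$sample_n) %>%
        mutate(phase = "sweeps", rho = rho, rep = rep)
      if (paired_control) {
        p0 <- p
        p0$theta_a <- 0
        r0 <- run_recurrent_sweeps(p0, n_epochs = n_epochs)
        out <- bind_rows(
          out,
          class_thetas(r0$sfs, p$sample_n) %>%
            mutate(phase = "control", rho = rho, rep = rep)
        )
      }
      out
    }
  })
  structure(list_rbind(rows), class = c("wf_study", class(tibble())))
}

complete_sfs <- function(sfs, n) {
  # Fill mclass x derived_count grid with zeros (spectra tibbles are sparse).
  crossing(mclass = MCLASS, derived_count = seq_len(n - 1)) %>%
    left_join(sfs, by = c("mclass", "derived_count")) %>%
    mutate(n_sites = coalesce(.data$n_sites, 0L))
}
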