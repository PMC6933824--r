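#' Operating characteristics of the differential-abundance procedure
#'
#' Runs the full differential stage ([spectral_da()]) on repeated simulated
#' experiments and measures, against the known truth: the type-I error
#' (significant fraction among proteins without a planted effect), the
#' power (significant-with-correct-sign fraction among planted effects),
#' and the sign-error rate (wrong-sign fraction among significant planted
#' calls). Estimates are pooled over all simulations with binomial standard
#' errors. Each simulated dataset gets its own RNG stream derived from the
#' configuration seed and the simulation index, so runs are reproducible.
#'
#' Only proteins that survive the minimum-count filter enter the
#' denominators (the test is never applied to the others).
#'
#' @param config A [sim_config()] describing the simulated experiments.
#' @param control A [da_control()] for the differential stage.
#' @param n_sims Number of simulated experiments (>= 1).
#' @return An object of class `oc_evaluation`: list with `metrics` (data
#'   frame: metric, estimate, se, n_events, n), `per_sim` (per-simulation
#'   tallies) and the configurations. `print` method included.
#' @examples
#' oc <- evaluate_operating_characteristics(
#'   sim_config(n_proteins = 100, de_fraction = 0.2, seed = 42),
#'   da_control(), n_sims = 5)
#' oc
#' @export
evaluate_operating_characteristics <- function(config,
                                               control = da_control(),
                                               n_sims = 100) {
  if (!inherits(config, "sim_config"))
    stop_input("'config' must come from sim_config()")
  if (!is.numeric(n_sims) || length(n_sims) != 1L || n_sims < 1)
    stop_input("'n_sims' must be >= 1")
  n_sims <- as.integer(n_sims)
  # one independent stream per dataset, keyed by (seed, simulation index)
  sim_seeds <- with_seed(config$seed,
                         sample.int(.Machine$integer.max - 1L, n_sims))
  per_sim <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    cfg_i <- config
    cfg_i$seed <- sim_seeds[i]
    sim <- simulate_spectral_counts(cfg_i)
    fit <- suppressWarnings(spectral_da(sim$counts, control = control))
    res <- merge(fit$results, sim$truth, by = "protein_id", sort = FALSE)
    null_res <- res[!res$is_de, , drop = FALSE]
    de_res <- res[res$is_de, , drop = FALSE]
    sig_de <- de_res[de_res$significant, , drop = FALSE]
    correct <- sig_de$direction == sig_de$true_direction
    per_sim[[i]] <- data.frame(
      sim = i,
      n_tested = nrow(res),
      n_null = nrow(null_res),
      n_null_sig = sum(null_res$significant),
      n_de = nrow(de_res),
      n_de_sig_correct = sum(correct),
      n_de_sig_wrong = sum(!correct))
  }
  per_sim <- do.call(rbind, per_sim)
  pooled <- function(events, n) {
    est <- if (n > 0) events / n else NA_real_
    se <- if (n > 0) sqrt(est * (1 - est) / n) else NA_real_
    c(estimate = est, se = se, n_events = events, n = n)
  }
  n_sig_de <- sum(per_sim$n_de_sig_correct + per_sim$n_de_sig_wrong)
  metrics <- rbind(
    type_I_error = pooled(sum(per_sim$n_null_sig), sum(per_sim$n_null)),
    power = pooled(sum(per_sim$n_de_sig_correct), sum(per_sim$n_de)),
    sign_error_rate = pooled(sum(per_sim$n_de_sig_wrong), n_sig_de))
  metrics <- data.frame(metric = rownames(metrics), metrics,
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(metrics = metrics, per_sim = per_sim,
                 config = config, control = control, n_sims = n_sims),
            class = "oc_evaluation")
}

#' @export
print.oc_evaluation <- function(x, ...) {
  cat(sprintf("Operating characteristics over %d simulated experiment(s)\n",
              x$n_sims))
  cat(sprintf("  n_proteins = %d, de_fraction = %g, depth = %s, alpha = %g\n",
              x$config$n_proteins, x$config$de_fraction,
              paste(x$config$depth, collapse = "/"), x$control$alpha))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    if (is.na(m$estimate[i]))
      cat(sprintf("  %-16s (no events)\n", m$metric[i]))
    else
      cat(sprintf("  %-16s %.4f (se %.4f, %d/%d)\n", m$metric[i],
                  m$estimate[i], m$se[i], m$n_events[i], m$n[i]))
  }
  invisible(x)
}
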