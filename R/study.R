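#' Scaled-down peptide/lipid self-assembly study
#'
#' End-to-end demonstration workflow at desk scale: for each replica, pack a
#' random configuration at the requested composition and concentration,
#' minimize, run the ramped-timestep equilibration, then production Langevin
#' dynamics, and analyze the equilibrated window of the trajectory. The
#' default composition (20 lipids + 10 peptides, P/L = 1/2, 10 mM) sits in
#' the regime where mixed micelles form quickly and no discs are expected,
#' which makes it a stringent yet fast end-to-end check of the whole
#' pipeline. Production length defaults to 2e6 steps (20 ns at the 10 fs
#' production time step), an order of magnitude beyond the time at which
#' the first stable mixed micelles appear at this composition.
#'
#' @param n_lipids,n_peptides Composition.
#' @param lipid_concentration_mM Total lipid concentration (mmol/L).
#' @param replicas Number of independent replicas.
#' @param base_seed Integer; replica k runs with seed `base_seed + k - 1`.
#' @param n_steps Production steps per replica.
#' @param snapshot_every Steps between analyzed snapshots.
#' @param stage_steps Equilibration steps per time-step stage.
#' @param window Fraction range of the trajectory treated as equilibrated.
#' @param params `cooke_ff`.
#' @return A list with `replicas` (per-replica [analyze_trajectory()]
#'   results) and `summary`: a one-row data frame with the replica-averaged
#'   final aggregate count, mixed-micelle count, disc percentage, mean
#'   lipids per aggregate, mean P/L per aggregate, and free-lipid
#'   concentration (mM).
#' @examples
#' \donttest{
#' study <- assembly_study(n_lipids = 8, n_peptides = 4, replicas = 1,
#'                         n_steps = 2e5)
#' study$summary
#' }
#' @export
assembly_study <- function(n_lipids = 20, n_peptides = 10,
                           lipid_concentration_mM = 10,
                           replicas = 3, base_seed = 1,
                           n_steps = 2e6, snapshot_every = 2e5,
                           stage_steps = 1e4,
                           window = c(2/3, 1),
                           params = ff_params()) {
  spec <- system_spec(n_lipids, n_peptides, lipid_concentration_mM,
                      replicas = replicas, base_seed = base_seed)
  reps <- vector("list", replicas)
  for (r in seq_len(replicas)) {
    seed <- base_seed + r - 1L
    packed <- random_pack(spec, seed = seed, params = params)
    st <- minimize(packed$state, packed$topology, params)
    st <- equilibrate(st, packed$topology, params, seed = seed,
                      stage_steps = stage_steps)
    cfg <- engine_config(seed = seed, snapshot_every = snapshot_every)
    traj <- run_langevin(st, packed$topology, params, cfg, n_steps)
    reps[[r]] <- analyze_trajectory(traj, packed$topology, window = window)
  }
  finals <- lapply(reps, function(x) x$frames[[length(x$frames)]])
  final_aggs <- do.call(rbind, lapply(finals, function(f) f$aggregates))
  mixed <- final_aggs[final_aggs$n_lipids > 0 & final_aggs$n_peptides > 0, ]
  all_aggs <- do.call(rbind, lapply(reps, function(x) x$aggregates))
  summary <- data.frame(
    n_aggregates = mean(vapply(finals, function(f) nrow(f$aggregates),
                               numeric(1))),
    mixed_micelles = nrow(mixed) / replicas,
    pct_disc = if (nrow(all_aggs)) 100 * mean(all_aggs$label == "disc") else
      NA_real_,
    lipids_per_aggregate = if (nrow(final_aggs))
      mean(final_aggs$n_lipids) else NA_real_,
    p_over_l_per_aggregate = if (nrow(final_aggs))
      mean(final_aggs$n_peptides / final_aggs$n_lipids) else NA_real_,
    free_lipid_mM = mean(vapply(reps, function(x) x$free$plateau_mM,
                                numeric(1))))
  list(replicas = reps, summary = summary, spec = spec)
}
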