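# Simulation-study driver shared by the acceptance tests: dataset ->
# kinematics-level Delta traces -> exclusion filter -> per-lock epoching,
# averaging, analysis matrices and cluster test. The rendering-free
# observation path is used for runtime (pixel rendering at study scale is far
# beyond the suite's budget); rendering fidelity is established separately in
# test-delta.R.

run_cluster_study <- function(gen, locks, clip = NULL, n_perm = 1000L,
                              alpha_final = 0.017, seed = 1L,
                              exclusion = exclusion_config()) {
  gen$seed <- seed
  ds <- generate_dataset(gen, output = c("events", "kinematics"))
  traces <- lapply(ds$kinematics, delta_from_kinematics)
  flt <- filter_trials(ds$events, exclusion)
  out <- list()
  for (lock in locks) {
    avs <- average_dataset(traces, flt$kept, lock)
    m <- build_analysis_matrix(
      avs, clip_range = if (is.list(clip)) clip[[lock]] else clip)
    spec <- permutation_spec(n_permutations = n_perm, alpha_final = alpha_final,
                             seed = seed + 500000L)
    out[[lock]] <- cluster_test(m$early_planning, m$late_planning, m$times, spec)
  }
  out
}

# Generator config with the two conditions forced identical (exchangeable
# null): early-planning parameters are copied into late-planning.
null_generator_config <- function(...) {
  cfg <- generator_config(...)
  cfg$question_timing$late_planning <- cfg$question_timing$early_planning
  cfg$rt$late_planning <- cfg$rt$early_planning
  cfg$prep_lead$late_planning <- cfg$prep_lead$early_planning
  cfg
}
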