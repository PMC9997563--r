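# Cohort of simulated flies as a per-frame food-flag series shaped for
# windowed_tests: one fly per well, target stationary at-food occupancy.
sim_flag_cohort <- function(occupancy, n_flies, seed, duration_s = 55 * 60,
                            p_food_roam = 1 / 900) {
  p_roam_food <- occupancy / (1 - occupancy) * p_food_roam
  p <- sim_params(n_wells = n_flies, duration_s = duration_s,
                  p_roam_food = p_roam_food, p_food_roam = p_food_roam)
  gt <- simulate_behavior(p, seed = seed, positions = FALSE)
  tibble::tibble(fly = gt$truth$well,
                 time_min = gt$truth$frame / (30 * 60),
                 value = as.numeric(gt$truth$state == "at_food"))
}
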