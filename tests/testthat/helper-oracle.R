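# Independently coded plain-arithmetic oracles for the moment formulas.
# Deliberately duplicate the constants and formulas rather than calling the
# package, so agreement is a real cross-check.

oracle_constants <- function(sex) {
  if (sex == "male") {
    list(k1 = 0.1, K1 = 0.42, k2 = 0.0725, K2 = 0.51, g = 9.8)
  } else {
    list(k1 = 0.1115, K1 = 0.42, k2 = 0.0685, K2 = 0.51, g = 9.8)
  }
}

oracle_mf_hip <- function(m, L1, sex) {
  cc <- oracle_constants(sex)
  m * cc$g * L1 * (cc$k1 * cc$K1 + cc$k2)
}

oracle_mf_knee <- function(m, L2, sex) {
  cc <- oracle_constants(sex)
  m * cc$k2 * cc$g * cc$K2 * L2
}

oracle_mm_hip <- function(mf, F, l1) mf + F * l1

oracle_mm_knee <- function(F, l2) F * l2

# Build a minimal valid subjects tibble. `forces` is a named list
# task -> c(trial1, trial2); defaults give a distinct force per task.
make_subject <- function(id = "s1", sex = "male", age_group = "A",
                         mass_kg = 65, thigh_m = 0.35, lowerleg_m = 0.40,
                         lever_hip_m = 2 / 3 * thigh_m,
                         lever_knee_m = 2 / 3 * lowerleg_m,
                         forces = list(hip_flexion = c(160, 160),
                                       hip_extension = c(140, 140),
                                       knee_flexion = c(90, 90),
                                       knee_extension = c(240, 240))) {
  row <- list(id = id, sex = sex, age_group = age_group, mass_kg = mass_kg,
              thigh_m = thigh_m, lowerleg_m = lowerleg_m,
              lever_hip_m = lever_hip_m, lever_knee_m = lever_knee_m)
  for (task in mmt_tasks()) {
    row[[paste0(task, "_trial1_N")]] <- forces[[task]][1]
    row[[paste0(task, "_trial2_N")]] <- forces[[task]][2]
  }
  tibble::as_tibble(row)
}
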