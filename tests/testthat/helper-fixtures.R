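# shared small fixtures, built in code

# a sensor stream sampled on an irregular grid from closed-form axis signals
irregular_sine_stream <- function(duration = 10, seed = 42,
                                  placement = "probe") {
  set.seed(seed)
  ts <- sort(unique(c(0, cumsum(sample(c(1 / 29, 1 / 58), 400, TRUE,
                                       prob = c(0.7, 0.3))))))
  ts <- ts[ts <= duration]
  sensor_stream(ts, cbind(sin(ts), cos(ts), 0), placement = placement)
}

# uniform-grid joint channel from a function of time
channel_from_fun <- function(f, duration = 10, rate = 29, name = "probe") {
  t <- (0:(round(duration * rate))) / rate
  joint_channel(t, f(t), name, rate)
}

# a small adult reference cohort on the default path (kept small for speed)
make_reference <- function(n_adults = 6, seed = 5, target = "ankle_L") {
  adults <- simulate_cohort(n_adults, "NIA", target_joint = target,
                            seed = seed)
  build_reference(lapply(adults, process_session))
}

# one processed impaired session
make_patient_session <- function(seed = 99, mirror = 0.8, target = "ankle_L") {
  prof <- impairment_profile(tracking_noise_sd = 6, tracking_lag_s = 0.25,
                             mirror_gain = mirror,
                             synergy_gains = c(knee_L = 0.3),
                             trunk_sway_amp = 3)
  process_session(simulate_session(target, profile = prof, seed = seed,
                                   meta = list(id = "P_t", age = 9,
                                               group = "P")))
}
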