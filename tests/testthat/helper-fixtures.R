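# Shared fixtures: a 20 MHz laser, scanned-gate configurations, and small
# simulated acquisitions. All stacks are generated in code at test time.

laser20 <- laser_config(period_ns = 50)

# G gates of width W tiling the 50 ns period (offset 0)
tiling_gates <- function(num_gates, width_ns = 13.1) {
  gate_config(width_ns = width_ns, step_ns = 50 / num_gates,
              num_gates = num_gates)
}

# small simulated acquisition of a single-exponential dye
sim_dye_stack <- function(tau_ns, seed, num_gates = 140, side = 16,
                          brightness = 0.05, width_ns = 13.1,
                          frames_per_gate = 255, dcr_cps = 0, ...) {
  p <- sim_params(laser20, tiling_gates(num_gates, width_ns),
                  decay_model(tau_ns), height = side, width = side,
                  brightness = brightness, frames_per_gate = frames_per_gate,
                  dark_count_rate_cps = dcr_cps, ...)
  simulate_gate_stack(p, seed)
}

# per-ROI calibrated phase lifetimes of a simulated sample/calibration pair
pipeline_taus <- function(sample_stack, cal_stack, tau_cal_ns, roi_bin = 4) {
  res <- run_pipeline(sample_stack, cal_stack, tau_cal_ns = tau_cal_ns,
                      roi_bin = roi_bin)
  res$tau_ns[!is.na(res$tau_ns)]
}
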