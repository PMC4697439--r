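# Shared fixtures: the default mechanics model and a fully generated
# synthetic cytometry experiment (threshold control, cargo-free control and
# the measurement conditions), built once per test run.

default_model <- bundle_model()

# one synthetic cytometry experiment: thresholds from the unstained control,
# background from the cargo-free stained control
make_facs_experiment <- function(truth_co = 0.30, truth_dual = 0.04,
                                 background = 0.03, n_events = 50000,
                                 seed = 100) {
  uns <- gen_facs_events("unstained", 0, 0, 0.5, n_events = n_events,
                         seed = seed)
  ctl <- gen_facs_events("control", 0, background, 0.5, n_events = n_events,
                         seed = seed + 1)
  co <- gen_facs_events("co_culture", truth_co, background, 0.5,
                        n_events = n_events, seed = seed + 2)
  dual <- gen_facs_events("dual_culture", truth_dual, background, 0.5,
                          n_events = n_events, seed = seed + 3)
  gate <- derive_gate(uns)
  list(gate = gate,
       control_gated = gate_endothelial(ctl, gate),
       co = co, dual = dual,
       co_gated = gate_endothelial(co, gate),
       dual_gated = gate_endothelial(dual, gate))
}

# built once and shared by the transfer and acceptance test files
facs <- make_facs_experiment()
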