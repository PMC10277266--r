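# Shared fixtures: the reference parameter set used throughout (hourly SP/MP
# session figures: Ks=2.6, Kb=6.9, Q=0.23, Vb0=10, Cs=x0=2.9, y0=0) and
# patient-like random draws.

fig_sp <- function(Q = 0.23, Cd0 = 0, x0 = 2.9) {
  sp_params(Ks = 2.6, Kb = 6.9, Q = Q, Cs = 2.9, Cd0 = Cd0, Vb0 = 10, x0 = x0)
}

fig_mp <- function(Q = 0.23, Vd0 = 25, y0 = 0) {
  mp_params(Ks = 2.6, Kb = 6.9, Q = Q, Cs = 2.9, Vb0 = 10, Vd0 = Vd0,
            x0 = 2.9, y0 = y0)
}

# One random patient-like parameter set from the published per-patient ranges.
draw_mp <- function(Q = 0) {
  mp_params(Ks = runif(1, 2.4, 11), Kb = runif(1, 3.9, 17.4), Q = Q,
            Cs = runif(1, 1.0, 2.9), Vb0 = runif(1, 8, 23),
            Vd0 = runif(1, 14.24, 31.93), y0 = 0)
}

draw_sp <- function(Q = 0) {
  sp_params(Ks = runif(1, 2.4, 11), Kb = runif(1, 3.9, 17.4), Q = Q,
            Cs = runif(1, 1.0, 2.9), Cd0 = runif(1, 0.09, 0.21),
            Vb0 = runif(1, 8, 23))
}

# A small noiseless two-modality patient with known truth.
noiseless_patient <- function(Ks = 5, Kb = 8, Cs = 1.8, Vb0 = 15, Vd0 = 25,
                              Cd0 = 0.15, seed = 1) {
  truth <- mp_params(Ks = Ks, Kb = Kb, Q = 0, Cs = Cs, Vb0 = Vb0, Vd0 = Vd0)
  list(truth = truth,
       data = simulate_patient(truth, Cd0 = Cd0, noise_sd = 0, seed = seed))
}
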