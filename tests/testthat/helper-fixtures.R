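# small parameter sets shared across tests

const_params <- function(kp = 2, kn = 0, N = 10, kp1 = 1, kn1 = 0, S0 = 1) {
  kinetic_params(kp1 = kp1, kn1 = kn1,
                 kernel = kernel_spec("constant", kp_scale = kp,
                                      kn_scale = kn),
                 N = N, S0 = S0)
}

# a configuration whose vector field is exactly zero: all cell mass in C,
# no precursor, so neither silicification nor coagulation can fire
quiescent_state <- function(c0, N) system_state(C = c0, S = 0, A = rep(0, N))

random_state <- function(N) {
  system_state(C = runif(1), S = runif(1), A = runif(N))
}
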