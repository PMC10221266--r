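# Shared fixtures built in code.

# a clean 5-point pressure-like dataset with small residual scatter
make_linear_data <- function(a = 700, b = 250, sd_y = 0, k = 9, l = 1,
                             me_x = 0, x = seq(0.5, 2, length.out = k),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- a + b * x + rnorm(k, 0, sd_y)
  z <- rep(x, each = l) + rnorm(k * l, 0, me_x)
  calibration_data(point_id = rep(seq_len(k), each = l), signal_v = z,
                   measurand = rep(y, each = l))
}

# random but physically sensible exchange protocol
random_protocol <- function() {
  baps_protocol(
    initial = synthetic_air(),
    injected = co2_calibration_gas(),
    n_steps = sample(1:10, 1),
    dp_pa = runif(1, 100, 4000),
    p_pa = runif(1, 95000, 104000),
    t_k = runif(1, 283, 303),
    v_head_ml = runif(1, 600, 1500)
  )
}

# independent stepwise oracle for the idealized recursion: plain loop on
# the closed-form update, no shared code with the mole-balance engine
oracle_idealized <- function(n, q, init, inj) {
  conc <- c(o2 = init$frac_o2, co2 = init$frac_co2, n2 = init$frac_n2)
  injv <- c(o2 = inj$frac_o2, co2 = inj$frac_co2, n2 = inj$frac_n2)
  for (i in seq_len(n)) conc <- conc * (1 - q) + injv * q
  100 * conc
}
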