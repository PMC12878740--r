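# Shared fixtures for the test suite. Everything is built in code from the
# published healthy-adult defaults; no stored data.

default_params <- physiology_params()
default_implant <- scale_implants(params = default_params)

# Coarser grids than the shipping default keep the suite fast while staying
# fine enough for the conservation and comparison contracts being tested.
grid_3yr <- default_time_grid()
grid_short <- default_time_grid(n = 120)

# First interior local minimum of a series; NA if the series is monotone.
local_min <- function(x) {
  d <- diff(x)
  up <- which(d > 0)
  if (!length(up) || up[1] == 1 && all(d > 0)) return(NA_real_)
  i <- up[1]
  if (i == length(d) + 1L) return(NA_real_)
  min(x[seq_len(i + 1L)])
}

# Normalized serum concentration at time t from the closed-form solution,
# for crossing-time checks.
cs_star_at <- function(t, params, implant, rho = 1) {
  tr <- simulate_pbpk(params, implant, rho, t_grid = c(0, t),
                      method = "closed_form")
  tr$Cs_star[2L]
}
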