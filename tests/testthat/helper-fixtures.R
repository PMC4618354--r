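# Shared fixtures built in code.

# gaussian mass binned into segments of width bw over [0, stem_mm]
gaussian_profile <- function(mu, s2, bw = 2, stem_mm = 40, total = 1) {
  nb <- stem_mm / bw
  edges <- (0:nb) * bw
  mass <- diff(pnorm(edges, mu, sqrt(s2)))
  pulse_profile((edges[-1] + edges[-(nb + 1)]) / 2,
                total * mass / sum(mass), bin_width = bw)
}

# small single-channel model for fast simulator tests
small_single_channel <- function(p = 4e-4, q = 2.08e-5, D = 5e-6,
                                 n_cells = 200, N = 5) {
  tissue_model(list(channel_spec(linear_flux_params(p, q), D = D)),
               n_cells = n_cells, N = N)
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
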