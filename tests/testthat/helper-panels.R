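# Small synthetic fixtures shared across tests; all generated in code.

# two Gaussian populations separated by `delta` in arcsinh FL1/FL3 space
test_pair <- function(delta = 2, n_events = 600, ids = c("A", "B")) {
  base <- c("FL1-H" = 6.5, "FL2-H" = 5.5, "FL3-H" = 6.0, "FL4-H" = 5.0,
            "FSC-H" = 8.0, "SSC-H" = 7.5)
  shifted <- base
  shifted[c("FL1-H", "FL3-H")] <- shifted[c("FL1-H", "FL3-H")] + delta
  list(gaussian_population(ids[1], base, n_events = n_events),
       gaussian_population(ids[2], shifted, n_events = n_events))
}

# gated, pooled population samples for a quick panel
test_samples <- function(models, replicates = 1, seed = 101,
                         noise = noise_model(0)) {
  panel <- simulate_panel(models, noise = noise, replicates = replicates,
                          seed = seed)
  panel_samples(panel)
}

random_event_matrix <- function(n = 50, channels = c("FL1-H", "FL3-H")) {
  event_matrix(matrix(runif(n * length(channels), 0, 1e4), n), channels)
}
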