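# Tabulated clinical envelope used across tests.
grid_k <- 45:70
grid_trephine <- seq(6, 8, by = 0.25)

# Random valid (radius, chord) pairs with 0 < chord < 2 * radius.
random_radius_chord <- function(n, seed = 421) {
  set.seed(seed)
  radius <- runif(n, 0.5, 50)
  chord <- radius * 2 * runif(n, 1e-4, 1 - 1e-9)
  data.frame(radius = radius, chord = chord)
}
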