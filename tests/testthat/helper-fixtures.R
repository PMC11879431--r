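# Shared toy fixtures (small sizes keep the suite fast; acceptance-scale
# fixtures are built inside test-acceptance.R).

flat_fix <- function(seed = 1, n = 36, box = 5, d_hc = 2.8) {
  make_flat_membrane(n, c(POPC = 1), box_xy = box, d_hc = d_hc, seed = seed)
}

wire_fix <- function(seed = 2, ...) {
  make_water_wire(36, c(POPC = 1), box_xy = 5, d_hc = 2.8, seed = seed, ...)
}

pore_fix <- function(seed = 3, pore_radius = 0.8, box = 8, n = 100, ...) {
  make_pore_membrane(n, c(POPC = 1), box_xy = box, d_hc = 2.8,
                     pore_radius = pore_radius, seed = seed, ...)
}

frame_mid <- function(frame) frame_box(frame)[3] / 2

# independent Helfrich-only bending energy (plain loop, no shared code path)
helfrich_oracle <- function(surface, kappa, J_s) {
  e <- 0
  for (i in seq_len(nrow(surface))) {
    e <- e + surface$dA[i] * kappa / 2 * (surface$H[i] - J_s)^2
  }
  e
}
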