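# Shared fixtures: one registry per test run, plus small builders.
reg <- epcsaft_registry()
gly <- load_reactions()

mol_to_x <- function(molal) {
  nw <- 1000 / 18.015268
  tot <- nw + sum(molal)
  c(water = nw / tot, molal / tot)
}

# a minimal registry with a bare hard-sphere species (m = 1, no association,
# no charge) and a non-interacting ideal species, for closed-form checks
toy_registry <- function(u = 0, m_seg = 1, sigma = 3.0) {
  pure <- data.frame(
    species_id = c("ball", "water"), display_name = c("ball", "water"),
    m_seg = c(m_seg, 1.2047), sigma = c(sigma, NA), u_kB = c(u, 353.94),
    n_donor = c(0, 1), n_acceptor = c(0, 1),
    eps_AB_kB = c(0, 2425.7), kappa_AB = c(0, 0.04509),
    z = c(0, 0), sigma_T = c(FALSE, TRUE), source = "toy")
  binary <- data.frame(species_i = character(), species_j = character(),
                       kij_slope = numeric(), kij_T0 = numeric(),
                       source = character())
  epcsaft_registry(pure, binary,
                   data.frame(reaction_id = character()),
                   data.frame(metabolite_id = character(),
                              pka_values = character(),
                              charge_most_protonated = integer(),
                              provenance = character()))
}

hansen_medium <- function() {
  build_medium(T = 303.15, pH = 8, tris_hcl = 0.033,
               salts = c(mgcl2 = 0.00694, kcl = 0.050, ammonium_sulfate = 0.006),
               registry = reg, label = "hansen_pfk")
}

veech_medium <- function() {
  build_medium(T = 311.15, pH = 7, sodium_phosphate = 0.010,
               salts = c(kcl = 0.230), registry = reg, label = "veech_aldolase")
}
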