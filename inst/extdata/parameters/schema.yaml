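# Sidecar schema for the bundled parameter tables.
pure.csv:
  species_id: lowercase identifier, unique
  m_seg: segment number, dimensionless, > 0
  sigma: segment diameter, Angstrom (NA for water, which uses the temperature
    correlation sigma(T) = 2.7927 + 10.11*exp(-0.01775*T) - 1.417*exp(-0.01146*T))
  u_kB: dispersion energy / Boltzmann constant, Kelvin
  n_donor: number of electron-donor (proton-acceptor pairing) association sites
  n_acceptor: number of acceptor association sites; "X + Y" site counts of the
    source table are recorded as (n_donor, n_acceptor)
  eps_AB_kB: association energy / kB, Kelvin
  kappa_AB: association volume, dimensionless, in [0, 1]; absent when no sites
  z: integer valence (0 for neutral species)
  sigma_T: TRUE if sigma follows the water temperature correlation
binary.csv:
  species_i, species_j: unordered pair of species_id
  kij_slope: 1/K; kij_T0: dimensionless; kij(T) = kij_T0 + kij_slope * T
  missing pairs default to kij = 0
standard_data.csv:
  dRg0: standard Gibbs energy of reaction, kJ/mol at 298.15 K, pH 7 (molality scale,
    ideally diluted aqueous reference). All reactions are pH-7 apparent values with
    H+ absorbed, except gapdh which is on the chemical scale with H+ an explicit
    participant (a_H+ = 10^-pH enters its reaction quotient).
  dRh0: standard reaction enthalpy, kJ/mol, treated T-independent in 298.15-310.15 K
pka.csv:
  pka_values: ascending semicolon-separated pKa ladder at reference T (298.15 K)
  charge_most_protonated: integer charge of the fully protonated state
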