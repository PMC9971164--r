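# Published reference values (kcal/mol) used for round-trip parity:
# gating energies and perturbations for the hERG constructs.
ref_dg <- tibble::tribble(
  ~construct, ~kind, ~dg,
  "WT",    "activation", -1.6, "WT",    "inactivation", -1.2,
  "T425L", "activation", -0.3, "T425L", "inactivation", -0.6,
  "L524R", "activation", -1.9, "L524R", "inactivation", -1.5,
  "A527L", "activation", -2.1, "A527L", "inactivation", -1.6,
  "L529H", "activation", -3.7, "L529H", "inactivation", -1.4,
  "L532H", "activation", -2.4, "L532H", "inactivation", -1.2,
  "W563L", "activation", -4.0, "W563L", "inactivation", -1.2,
  "A614G", "activation", -1.6, "A614G", "inactivation", -1.8,
  "T618L", "activation", -1.2, "T618L", "inactivation", -1.3
)
ref_ddg <- tibble::tribble(
  ~construct, ~kind, ~ddg,
  "T425L", "activation",  1.3, "T425L", "inactivation",  0.7,
  "L524R", "activation", -0.4, "L524R", "inactivation", -0.3,
  "A527L", "activation", -0.5, "A527L", "inactivation", -0.3,
  "L529H", "activation", -2.1, "L529H", "inactivation", -0.2,
  "L532H", "activation", -0.8, "L532H", "inactivation",  0.1,
  "W563L", "activation", -2.4, "W563L", "inactivation",  0.0,
  "A614G", "activation",  0.0, "A614G", "inactivation", -0.6,
  "T618L", "activation",  0.4, "T618L", "inactivation",  0.0
)

# Indeterminacy of a printed-table comparison: the reference was computed
# from unrounded fits, so allow the propagation of +/- half a unit in the
# last printed digit of z (0.05) and V_half (0.05 mV) through z F V.
rounding_slack <- function(z, v_half, faraday = 23.061) {
  faraday * (0.05 * abs(v_half) / 1000 + 0.05 / 1000 * abs(z))
}
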