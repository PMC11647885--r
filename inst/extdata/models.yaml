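# Nonbonded parameter catalogue for the hydroxide models and TIP3P water.
#
# Conventions: charges in elementary charge units e; epsilon as the positive
# well depth in kcal/mol (tables in the force-field literature often print it
# with a minus sign); rmin_half in Å under the Rmin/2 convention, so the pair
# minimum for a like pair is twice this value; masses in amu; geometry in Å
# and degrees. Auxiliary particles (AP) are 1 amu charge sites.
#
# The 3AP hydrogen charge is +0.0740: the printed table value (+0.7400) is
# inconsistent with the model's stated net charge of -0.9 e and with the
# hydrogen charge pattern of the optimized 2p model (+0.0742); the transposed
# decimal reproduces the net charge exactly (0.4 + 0.074 - 3*0.458 = -0.9).

tip3p:
  kind: water
  net_charge: 0.0
  geometry: {r_oh: 0.9572, a_hoh: 104.52}
  o: {q: -0.834, eps: 0.1521, rmin_half: 1.7682, mass: 15.9994}
  h: {q: 0.417, eps: 0.046, rmin_half: 0.2245, mass: 1.008}

oh_full:
  kind: oh_2p
  net_charge: -1.0
  geometry: {r_oh: 0.97}
  o: {q: -1.30, eps: 0.12, rmin_half: 1.70, mass: 15.9994}
  h: {q: 0.30, eps: 0.046, rmin_half: 0.2245, mass: 1.008}

m07:
  kind: oh_2p
  net_charge: -0.7
  geometry: {r_oh: 0.97}
  o: {q: -1.00, eps: 0.12, rmin_half: 1.70, mass: 15.9994}
  h: {q: 0.30, eps: 0.046, rmin_half: 0.2245, mass: 1.008}

m09:
  kind: oh_2p
  net_charge: -0.9
  geometry: {r_oh: 0.97}
  o: {q: -1.20, eps: 0.12, rmin_half: 1.70, mass: 15.9994}
  h: {q: 0.30, eps: 0.046, rmin_half: 0.2245, mass: 1.008}

oh_2p_opt:
  kind: oh_2p
  net_charge: -1.0
  geometry: {r_oh: 0.97}
  o: {q: -1.0742, eps: 0.0699, rmin_half: 1.5990, mass: 15.9994}
  h: {q: 0.0742, eps: 0.0410, rmin_half: 2.1051, mass: 1.008}
  note: >
    Endpoint of the steepest-descent LJ optimization. Unsuitable for proton
    hopping: the large hydrogen Rmin causes severe clashes on identity swaps
    (mean hop energy ~354 kcal/mol), so the model is catalogued but not used
    by the hopping driver.

oh_3ap:
  kind: oh_3ap
  net_charge: -0.9
  geometry: {r_oh: 0.97, r_oap: 0.70, a_hoap: 110.0, ap_azimuth: 120.0}
  o: {q: 0.40, eps: 0.0240, rmin_half: 1.9825, mass: 15.9994}
  h: {q: 0.0740, eps: 0.046, rmin_half: 0.2245, mass: 1.008}
  ap: {q: -0.458, mass: 1.0}

oh_5ap:
  kind: oh_5ap
  net_charge: -0.9
  # Geometry is approximate (synthetic): the placement angles of the four
  # charged APs are not published in machine-readable form. Catalogued for
  # completeness; carries no validated observables and is not used by the
  # hopping driver.
  geometry: {r_oh: 0.97, r_oap: 0.50, r_oap_lj: 0.425, a_hoap: 109.47}
  o: {q: -1.23, mass: 15.9994}
  h: {eps: 0.046, rmin_half: 0.3927, mass: 1.008}
  h_chargesite: {q: 0.33, mass: 1.0}
  ap: {mass: 1.0}
  ap_lj: {eps: 0.0703, rmin_half: 1.5708, mass: 1.0}
  ap_lj_extra: {eps: 0.0703, rmin_half: 1.3464, mass: 1.0}

# Initial LJ/charge sets used by the parameter-space scan and the
# steepest-descent optimizer (all are 2p hydroxide parameter vectors).
starting_sets:
  charmm: {q_o: -1.30, q_h: 0.30, eps_o: 0.12, eps_h: 0.046, rmin_half_o: 1.70, rmin_half_h: 0.2245}
  ufimtsev: {q_o: -1.074, q_h: 0.074, eps_o: 0.024, eps_h: 0.046, rmin_half_o: 1.98, rmin_half_h: 0.2245}
  lee-meuwly: {q_o: -1.183, q_h: 0.183, eps_o: 0.06, eps_h: 0.044, rmin_half_o: 1.75, rmin_half_h: 1.443}
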