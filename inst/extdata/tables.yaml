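# Units and provenance for the packaged reference tables. All tables are
# verbatim transcriptions of the printed reference data for the 90Y YAS
# glass seed characterization study.
table1_nuclides:
  provenance: "Published comparison table of beta-emitting radionuclide properties"
  units:
    half_life_h: hours
    emax_mev: MeV (beta endpoint)
    beta_yield_pct: percent
    emean_mev: MeV (mean beta energy)
    parent_abundance_pct: percent (natural abundance of activatable parent)
    gamma_kev: keV
    gamma_yield_pct: percent
    sigma_parent_b: barns (thermal neutron capture cross-section of parent)
  notes: "90Sr half-life printed as 29.1 y (= 254938 h at 365.2425 d/y)."
table2_activation:
  provenance: "Published table of radionuclides produced by neutron activation of YAS glass"
  units:
    sigma_parent_b: barns
    half_life_h: hours
    beta_emax_mev: MeV
    beta_yield_pct: percent
    gamma_kev: keV
    gamma_yield_pct: percent
  notes: >
    90Y half-life printed as 64.1 h here but 64.0 h in the nuclide
    comparison table; both are kept with their own provenance. 28Al
    printed as 2.24 min, 19O as 26.9 s; converted to hours.
table3_composition:
  provenance: "Published composition of the YAS glass seed (total mass 8.618 mg)"
  units:
    weight_pct: percent by weight
    mass_mg: mg in one seed
    molar_mass_g_mol: g/mol (CODATA/IUPAC; 152Sm entry uses the isotopic mass)
    i_ev: eV (mean excitation energy, elemental ICRU values)
  notes: >
    parent_abundance is the isotopic fraction of the activatable parent
    used by the activation arithmetic: 152Sm treated as isotopically pure
    (98.7% enrichment rounded to 1), Si uses the 3.09% natural abundance
    of 30Si, Y and Al are mononuclidic. 18O listed for completeness only.
table4_radial_dose_rate:
  provenance: "Published Monte Carlo radial dose rates on the transverse axis (MCNP5/EGSnrc/FLUKA)"
  units:
    r_mm: mm from seed center
    MCNP5: cGy/h/uCi
    EGSnrc: cGy/h/uCi
    FLUKA: cGy/h/uCi
table5_reference_dose_rate:
  provenance: "Published absorbed dose rates at the reference point (2 mm, 90 deg) in water"
  units:
    dose_rate_cgy_h_uci: cGy/h/uCi
    uncertainty: cGy/h/uCi (1 sigma statistical)
table6_gL:
  provenance: "Published radial dose function gL(r) per code"
  units:
    r_mm: mm
    MCNP5: dimensionless
    EGSnrc: dimensionless
    FLUKA: dimensionless
table7_F:
  provenance: "Published 2D anisotropy function F(r,theta), MCNP5"
  units:
    theta_deg: degrees from the seed long axis
    r_columns: mm
  notes: >
    The second radius column header is misprinted as 7.5 in the source;
    the radius sequence implies 1.5 mm and it is stored as 1.5 mm here.
    Blank cells at small r and small theta (points inside or behind the
    seed) are kept as missing values.
table7_phi_an:
  provenance: "Published 1D anisotropy factor phi_an(r), MCNP5"
  units:
    r_mm: mm
    phi_an: dimensionless
eq1_coefficients:
  provenance: "Published fifth-order polynomial fit of the MCNP5 radial dose function"
  units:
    value: dimensionless (r in mm); R is the fit correlation coefficient
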