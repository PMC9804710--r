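{
  "meta": {
    "version": "1.0",
    "note": "Point nuclear constants for desk-scale BNCT beam evaluation. Capture cross sections are 2200 m/s (0.0253 eV) values; capture is extrapolated by the 1/v law. Scattering cross sections are free-atom values treated as energy-independent below the fast band. Sources: evaluated thermal-neutron data compilations (Mughabghab-style point constants); values rounded. The photon mu_en/rho table is an APPROXIMATE stand-in at NIST magnitudes (gamma dose is a secondary component of this model).",
    "E0_eV": 0.0253,
    "kT_eV": 0.0253,
    "avogadro": 6.02214076e23
  },
  "nuclides": {
    "H1":   {"atomic_mass": 1.008,  "sigma0_capture": 0.332,  "sigma_scatter": 20.5, "has_1v_capture": true,  "capture_reaction": "1H(n,g)2H, 2.223 MeV photon", "channel": "H_NG"},
    "C12":  {"atomic_mass": 12.011, "sigma0_capture": 0.0035, "sigma_scatter": 4.74, "has_1v_capture": true,  "capture_reaction": "12C(n,g)", "channel": ""},
    "N14":  {"atomic_mass": 14.003, "sigma0_capture": 1.83,   "sigma_scatter": 10.0, "has_1v_capture": true,  "capture_reaction": "14N(n,p)14C, 0.626 MeV charged", "channel": "N14_NP"},
    "O16":  {"atomic_mass": 15.995, "sigma0_capture": 0.00019,"sigma_scatter": 3.76, "has_1v_capture": true,  "capture_reaction": "16O(n,g)", "channel": ""},
    "Li6":  {"atomic_mass": 6.015,  "sigma0_capture": 940.0,  "sigma_scatter": 0.97, "has_1v_capture": true,  "capture_reaction": "6Li(n,a)t, Q=4.78 MeV charged", "channel": "LI6_NA"},
    "Li7":  {"atomic_mass": 7.016,  "sigma0_capture": 0.0454, "sigma_scatter": 1.40, "has_1v_capture": true,  "capture_reaction": "7Li(n,g)", "channel": ""},
    "B10":  {"atomic_mass": 10.013, "sigma0_capture": 3837.0, "sigma_scatter": 2.23, "has_1v_capture": true,  "capture_reaction": "10B(n,a)7Li, 2.31 MeV weighted charged branch", "channel": "B10_NA"},
    "F19":  {"atomic_mass": 18.998, "sigma0_capture": 0.0096, "sigma_scatter": 3.64, "has_1v_capture": true,  "capture_reaction": "19F(n,g)", "channel": ""},
    "Na23": {"atomic_mass": 22.990, "sigma0_capture": 0.530,  "sigma_scatter": 3.28, "has_1v_capture": true,  "capture_reaction": "23Na(n,g)", "channel": ""},
    "Mg":   {"atomic_mass": 24.305, "sigma0_capture": 0.063,  "sigma_scatter": 3.42, "has_1v_capture": true,  "capture_reaction": "Mg(n,g)", "channel": ""},
    "P31":  {"atomic_mass": 30.974, "sigma0_capture": 0.172,  "sigma_scatter": 3.31, "has_1v_capture": true,  "capture_reaction": "31P(n,g)", "channel": ""},
    "S":    {"atomic_mass": 32.06,  "sigma0_capture": 0.530,  "sigma_scatter": 1.02, "has_1v_capture": true,  "capture_reaction": "S(n,g)", "channel": ""},
    "Cl":   {"atomic_mass": 35.45,  "sigma0_capture": 33.5,   "sigma_scatter": 16.8, "has_1v_capture": true,  "capture_reaction": "Cl(n,g)", "channel": ""},
    "K":    {"atomic_mass": 39.098, "sigma0_capture": 2.10,   "sigma_scatter": 1.96, "has_1v_capture": true,  "capture_reaction": "K(n,g)", "channel": ""},
    "Ca":   {"atomic_mass": 40.078, "sigma0_capture": 0.43,   "sigma_scatter": 3.00, "has_1v_capture": true,  "capture_reaction": "Ca(n,g)", "channel": ""},
    "Au197":{"atomic_mass": 196.967,"sigma0_capture": 98.65,  "sigma_scatter": 7.75, "has_1v_capture": true,  "capture_reaction": "197Au(n,g)198Au", "channel": ""}
  },
  "kerma_constants_MeV": {
    "note": "Charged-particle energy deposited locally at the capture site (KERMA approximation). Boron value is the branch-weighted alpha+7Li kinetic energy; the 478 keV photon escape is folded into this constant.",
    "B10_NA": 2.31,
    "LI6_NA": 4.78,
    "N14_NP": 0.626,
    "H_NG_photon_MeV": 2.223
  },
  "li6_natural_atom_fraction": 0.0759,
  "elements": {
    "H":  {"molar_mass": 1.008,  "nuclides": {"H1": 1.0}},
    "C":  {"molar_mass": 12.011, "nuclides": {"C12": 1.0}},
    "N":  {"molar_mass": 14.007, "nuclides": {"N14": 1.0}},
    "O":  {"molar_mass": 15.999, "nuclides": {"O16": 1.0}},
    "F":  {"molar_mass": 18.998, "nuclides": {"F19": 1.0}},
    "Na": {"molar_mass": 22.990, "nuclides": {"Na23": 1.0}},
    "Mg": {"molar_mass": 24.305, "nuclides": {"Mg": 1.0}},
    "P":  {"molar_mass": 30.974, "nuclides": {"P31": 1.0}},
    "S":  {"molar_mass": 32.06,  "nuclides": {"S": 1.0}},
    "Cl": {"molar_mass": 35.45,  "nuclides": {"Cl": 1.0}},
    "K":  {"molar_mass": 39.098, "nuclides": {"K": 1.0}},
    "Ca": {"molar_mass": 40.078, "nuclides": {"Ca": 1.0}},
    "Au": {"molar_mass": 196.967,"nuclides": {"Au197": 1.0}}
  },
  "mu_en_over_rho": {
    "note": "Mass energy-absorption coefficients, cm^2/g, log-log interpolated; approximate stand-in values.",
    "energy_MeV": [0.1, 0.3, 0.5, 1.0, 2.0, 3.0, 6.0, 10.0],
    "H":  [0.0406, 0.0573, 0.0593, 0.0555, 0.0464, 0.0398, 0.0281, 0.0227],
    "C":  [0.0215, 0.0287, 0.0297, 0.0279, 0.0233, 0.0204, 0.0159, 0.0138],
    "N":  [0.0224, 0.0287, 0.0297, 0.0280, 0.0234, 0.0205, 0.0162, 0.0143],
    "O":  [0.0237, 0.0289, 0.0297, 0.0280, 0.0235, 0.0206, 0.0166, 0.0147],
    "Li": [0.0160, 0.0219, 0.0227, 0.0213, 0.0179, 0.0157, 0.0124, 0.0110],
    "F":  [0.0209, 0.0261, 0.0270, 0.0254, 0.0214, 0.0188, 0.0152, 0.0136],
    "Na": [0.0230, 0.0262, 0.0270, 0.0254, 0.0215, 0.0190, 0.0156, 0.0142],
    "Mg": [0.0255, 0.0275, 0.0282, 0.0266, 0.0226, 0.0200, 0.0166, 0.0152],
    "P":  [0.0290, 0.0280, 0.0287, 0.0270, 0.0230, 0.0205, 0.0172, 0.0160],
    "S":  [0.0330, 0.0292, 0.0297, 0.0280, 0.0239, 0.0213, 0.0180, 0.0168],
    "Cl": [0.0330, 0.0278, 0.0283, 0.0266, 0.0228, 0.0204, 0.0173, 0.0163],
    "K":  [0.0380, 0.0290, 0.0294, 0.0276, 0.0237, 0.0213, 0.0182, 0.0172],
    "Ca": [0.0409, 0.0299, 0.0300, 0.0283, 0.0241, 0.0215, 0.0177, 0.0163],
    "Au": [0.1500, 0.0350, 0.0290, 0.0260, 0.0235, 0.0225, 0.0215, 0.0210]
  },
  "materials": {
    "water":        {"density": 1.000, "mass_fractions": {"H": 0.1119, "O": 0.8881}},
    "pmma":         {"density": 1.190, "mass_fractions": {"H": 0.0805, "C": 0.5999, "O": 0.3196}},
    "brain_icrp":   {"density": 1.040, "mass_fractions": {"H": 0.107, "C": 0.145, "N": 0.022, "O": 0.712, "Na": 0.002, "P": 0.004, "S": 0.002, "Cl": 0.003, "K": 0.003}},
    "soft_tissue":  {"density": 1.000, "mass_fractions": {"H": 0.101, "C": 0.111, "N": 0.026, "O": 0.762}},
    "skin_icrp":    {"density": 1.090, "mass_fractions": {"H": 0.100, "C": 0.204, "N": 0.042, "O": 0.645, "Na": 0.002, "P": 0.001, "S": 0.002, "Cl": 0.003, "K": 0.001}},
    "adipose":      {"density": 0.950, "mass_fractions": {"H": 0.114, "C": 0.598, "N": 0.007, "O": 0.278, "Na": 0.001, "S": 0.001, "Cl": 0.001}},
    "lung":         {"density": 0.260, "mass_fractions": {"H": 0.101, "C": 0.111, "N": 0.026, "O": 0.762}},
    "bone_cortical":{"density": 1.850, "mass_fractions": {"H": 0.047, "C": 0.144, "N": 0.042, "O": 0.446, "Mg": 0.002, "P": 0.105, "S": 0.003, "Ca": 0.211}},
    "air":          {"density": 0.001205, "mass_fractions": {"N": 0.755, "O": 0.245}},
    "polyethylene": {"density": 0.940, "mass_fractions": {"H": 0.1437, "C": 0.8563}}
  },
  "lif_density": 2.635
}
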