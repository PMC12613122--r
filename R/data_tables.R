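# Bundled reference tables: free-atom ground-state configurations of the
# d-block metals, solvent dielectric constants, and atomic masses.
# Kept as in-source data frames so lookups are reproducible offline.

# Outer electron configuration of the FREE NEUTRAL atom (prior to
# coordination): number of electrons in the outermost s, d and f subshells.
# Anomalous ground states (Cr, Cu, Nb, Mo, Ru, Rh, Pd, Ag, Pt, Au, La, Ce,
# Gd) follow the accepted experimental configurations.
metal_config_table <- function() {
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
symbol period cs cd cf
Sc 4 2 1 0
Ti 4 2 2 0
V  4 2 3 0
Cr 4 1 5 0
Mn 4 2 5 0
Fe 4 2 6 0
Co 4 2 7 0
Ni 4 2 8 0
Cu 4 1 10 0
Zn 4 2 10 0
Y  5 2 1 0
Zr 5 2 2 0
Nb 5 1 4 0
Mo 5 1 5 0
Tc 5 2 5 0
Ru 5 1 7 0
Rh 5 1 8 0
Pd 5 0 10 0
Ag 5 1 10 0
Cd 5 2 10 0
La 6 2 1 0
Ce 6 2 1 1
Gd 6 2 1 7
Lu 6 2 1 14
Hf 6 2 2 14
Ta 6 2 3 14
W  6 2 4 14
Re 6 2 5 14
Os 6 2 6 14
Ir 6 2 7 14
Pt 6 1 9 14
Au 6 1 10 14
Hg 6 2 10 14
")
  tab
}

# Static (eps) and optical/infinite-frequency (epsinf = n^2) dielectric
# constants at 293-298 K, as tabulated by standard continuum-solvation
# parameter sets. Lowercase canonical names; common synonyms mapped below.
solvent_table <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
solvent eps epsinf
water 78.36 1.78
acetonitrile 35.69 1.81
dmso 46.83 2.18
methanol 32.61 1.77
ethanol 24.85 1.85
dichloromethane 8.93 2.03
chloroform 4.71 2.09
dmf 37.22 2.05
thf 7.43 1.97
acetone 20.49 1.85
toluene 2.37 2.24
benzene 2.27 2.25
hexane 1.88 1.89
dioxane 2.21 2.02
pyridine 12.98 2.28
ethyl_acetate 5.99 1.88
glycerol 42.69 2.16
")
}

SOLVENT_SYNONYMS <- c(
  "h2o" = "water", "pbs" = "water", "d2o" = "water",
  "mecn" = "acetonitrile", "ch3cn" = "acetonitrile", "acn" = "acetonitrile",
  "dimethylsulfoxide" = "dmso", "dimethyl_sulfoxide" = "dmso",
  "meoh" = "methanol", "etoh" = "ethanol",
  "dcm" = "dichloromethane", "ch2cl2" = "dichloromethane",
  "chcl3" = "chloroform", "dimethylformamide" = "dmf",
  "tetrahydrofuran" = "thf", "etoac" = "ethyl_acetate")

# standard atomic weights (abridged, g/mol), enough for typical TMC ligands
atomic_mass_table <- function() {
  c(H = 1.008, He = 4.0026, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
    F = 18.998, Na = 22.99, Mg = 24.305, Al = 26.982, Si = 28.085,
    P = 30.974, S = 32.06, Cl = 35.45, K = 39.098, Ca = 40.078,
    Sc = 44.956, Ti = 47.867, V = 50.942, Cr = 51.996, Mn = 54.938,
    Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38,
    Ga = 69.723, Ge = 72.63, As = 74.922, Se = 78.971, Br = 79.904,
    Y = 88.906, Zr = 91.224, Nb = 92.906, Mo = 95.95, Tc = 98,
    Ru = 101.07, Rh = 102.906, Pd = 106.42, Ag = 107.868, Cd = 112.414,
    In = 114.818, Sn = 118.71, Sb = 121.76, Te = 127.6, I = 126.904,
    La = 138.905, Ce = 140.116, Gd = 157.25, Lu = 174.967,
    Hf = 178.49, Ta = 180.948, W = 183.84, Re = 186.207, Os = 190.23,
    Ir = 192.217, Pt = 195.084, Au = 196.967, Hg = 200.592,
    Tl = 204.38, Pb = 207.2, Bi = 208.98)
}
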