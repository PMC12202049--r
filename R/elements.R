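# Element property tables shipped with the package.
#
# Van der Waals radii follow the Bondi compilation (with the common extensions
# for alkali/alkaline-earth metals); covalent radii follow the Cordero
# single-bond values. Unknown elements fall back to 1.50 A (vdW) and
# 0.76 A (covalent), i.e. carbon-like.

.VDW_FALLBACK <- 1.50
.COV_FALLBACK <- 0.76

.VDW_RADII <- c(
  H = 1.20, He = 1.40, Li = 1.82, Be = 1.53, B = 1.92, C = 1.70, N = 1.55,
  O = 1.52, F = 1.47, Ne = 1.54, Na = 2.27, Mg = 1.73, Al = 1.84, Si = 2.10,
  P = 1.80, S = 1.80, Cl = 1.75, Ar = 1.88, K = 2.75, Ca = 2.31, Mn = 2.05,
  Fe = 2.04, Co = 2.00, Ni = 1.97, Cu = 1.96, Zn = 2.01, Ga = 1.87,
  Ge = 2.11, As = 1.85, Se = 1.90, Br = 1.85, Kr = 2.02, Rb = 3.03,
  Sr = 2.49, Mo = 2.17, Ru = 2.07, Pd = 2.10, Ag = 2.11, Cd = 2.18,
  In = 1.93, Sn = 2.17, Sb = 2.06, Te = 2.06, I = 1.98, Xe = 2.16,
  Cs = 3.43, Ba = 2.68, Pt = 2.13, Au = 2.14, Hg = 2.23, Tl = 1.96,
  Pb = 2.02, Bi = 2.07, U = 2.40
)

.COVALENT_RADII <- c(
  H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71,
  O = 0.66, F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11,
  P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06, K = 2.03, Ca = 1.76, Mn = 1.39,
  Fe = 1.32, Co = 1.26, Ni = 1.24, Cu = 1.32, Zn = 1.22, Ga = 1.22,
  Ge = 1.20, As = 1.19, Se = 1.20, Br = 1.20, Kr = 1.16, Rb = 2.20,
  Sr = 1.95, Mo = 1.54, Ru = 1.46, Pd = 1.39, Ag = 1.45, Cd = 1.44,
  In = 1.42, Sn = 1.39, Sb = 1.39, Te = 1.38, I = 1.39, Xe = 1.40,
  Cs = 2.44, Ba = 2.15, Pt = 1.36, Au = 1.36, Hg = 1.32, Tl = 1.45,
  Pb = 1.46, Bi = 1.48, U = 1.96
)

# CPK-style element colors (RGB 0-255); fallback is pink.
.ELEMENT_COLORS <- list(
  H = c(255, 255, 255), C = c(144, 144, 144), N = c(48, 80, 248),
  O = c(255, 13, 13), S = c(255, 255, 48), P = c(255, 128, 0),
  F = c(144, 224, 80), Cl = c(31, 240, 31), Br = c(166, 41, 41),
  I = c(148, 0, 148), Fe = c(224, 102, 51), Mg = c(138, 255, 0),
  Na = c(171, 92, 242), K = c(143, 64, 212), Ca = c(61, 255, 0),
  Zn = c(125, 128, 176), He = c(217, 255, 255), Se = c(255, 161, 0),
  B = c(255, 181, 181), Cu = c(200, 128, 51), Mn = c(156, 122, 199)
)
.ELEMENT_COLOR_FALLBACK <- c(255, 105, 180)

# 10-color palette cycled over chains in order of first appearance.
.CHAIN_PALETTE <- matrix(c(
  102, 194, 165,
  252, 141,  98,
  141, 160, 203,
  231, 138, 195,
  166, 216,  84,
  255, 217,  47,
  229, 196, 148,
  179, 179, 179,
   27, 158, 119,
  217,  95,   2
), ncol = 3, byrow = TRUE)

# Two-letter element symbols recognized when inferring elements from atom
# names (uppercase keys).
.TWO_LETTER_ELEMENTS <- c(
  "HE", "LI", "BE", "NE", "NA", "MG", "AL", "SI", "CL", "AR", "CA", "MN",
  "FE", "CO", "NI", "CU", "ZN", "BR", "SE", "MO", "RU", "PD", "AG", "CD",
  "SN", "SB", "TE", "XE", "CS", "BA", "PT", "AU", "HG", "PB", "BI"
)

.normalize_element <- function(el) {
  el <- trimws(el)
  bad <- is.na(el) | el == ""
  el[bad] <- "Xx"
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2)))
}
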