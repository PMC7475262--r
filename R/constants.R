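## Controlled vocabularies and fixed numeric scales used across the package.

#' @keywords internal
AMINO_ACIDS <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")

## Ambiguity letters accepted on input; scored as background in the profile
## scan and excluded from consensus tallies.
AMBIGUOUS_AA <- c("X","B","Z")

MORPHOTYPES <- c("unicellular", "filamentous", "heterocytous")
HABITATS    <- c("freshwater", "marine", "terrestrial", "symbiotic", "other")
OCA_CLASSES <- c("wild_type", "mutated", "unresolved")

## Kyte-Doolittle hydropathy scale.
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
              Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
              L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
              S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

## Typical globular-proteome residue frequencies, used as the default
## background composition for synthetic proteins.
PROTEOME_COMPOSITION <- c(
  A = 0.083, R = 0.055, N = 0.041, D = 0.055, C = 0.014,
  Q = 0.039, E = 0.067, G = 0.071, H = 0.022, I = 0.059,
  L = 0.097, K = 0.058, M = 0.024, F = 0.039, P = 0.047,
  S = 0.066, T = 0.053, W = 0.011, Y = 0.029, V = 0.069)
PROTEOME_COMPOSITION <- PROTEOME_COMPOSITION / sum(PROTEOME_COMPOSITION)

## Strongly hydrophilic composition (no Kyte-Doolittle positive residues);
## backgrounds drawn from it can never reach the TM threshold.
HYDROPHILIC_COMPOSITION <- local({
  aa <- names(KD_SCALE)[KD_SCALE < 0]
  p <- PROTEOME_COMPOSITION[aa]
  p / sum(p)
})

## Synthetic 150-residue p20-like template (designed in-repo, not a real
## protein): catalytic H at 58 inside the FSGHG pocket frame, catalytic C at
## 112 inside DTCHS; hydrophilic elsewhere so it never triggers a TM call.
P20_TEMPLATE <- paste0(
  "HRGGAENYHNDDKYDEAHPGPTSNGQQQQKNDKYDAYGDEEPDKTDYYSRRTHE",
  "FSGHG",
  "HGPSTAENHHETHYYQNYEYTNSNKYDRYNAQYKERRHQQAAGGGDHPDT",
  "DTCHS",
  "ERQKNYGNDGANEYDGEHYGSEAYTHTPESTSGYTN")
P20_TEMPLATE_H_POS <- 58L
P20_TEMPLATE_C_POS <- 112L

## Distinctive hydrophilic 30-mers standing in for accessory-domain motifs in
## synthetic proteins (arbitrary, generated once; not real Pfam sequences).
ACCESSORY_MOTIFS <- c(
  WD40         = "NGQHGNPHNRQHYQEGYDYGNQPSPSNRQP",
  AAA_16       = "AGTDEKQTGPEADYGPRYGESAHRRNAQSS",
  NACHT        = "QTENNANPHKYQANSHSYPGSGNQDYQPDA",
  DUF4384      = "KERHNETYNRHPSADEPKYNKSDGGKAYHG",
  DUF2808      = "TASSEARKKKTPGRNNESQKKRSQQGSPEA",
  DUF2610      = "EQTHDHEATNDNPHKADNSDKNQNSYGTNT",
  Pentapeptide = "AHQKSPGAYPPTYEYATAHHAYQDKAPAQK")

## 21-residue hydrophobic stretch planted as a transmembrane segment.
TM_STRETCH <- "LLIVALLLIVALLLIVALLLI"

LINKER <- "GSGSG"
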