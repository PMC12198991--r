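# Shared fixtures: SMILES for the molecules used across the perception and
# estimation tests, and the diimidetricarboxylic acid (DITA) base
# decomposition used for atom-conservation checks.

smiles_benzene <- "c1ccccc1"
smiles_benzoic_acid <- "OC(=O)c1ccccc1"
smiles_succinimide <- "O=C1CCC(=O)N1"
smiles_phthalimide <- "O=C1N(C(=O)c2ccccc12)"
smiles_o_xylene <- "Cc1ccccc1C"
smiles_mesitylene <- "Cc1cc(C)cc(C)c1"

# two trimellitimide units on a central benzoic-acid ring
smiles_34dita <- paste0(
  "OC(=O)c1ccc(c(c1)N1C(=O)c2ccc(cc2C1=O)C(=O)O)",
  "N1C(=O)c2ccc(cc2C1=O)C(=O)O")
smiles_35dita <- paste0(
  "OC(=O)c1cc(cc(c1)N1C(=O)c2ccc(cc2C1=O)C(=O)O)",
  "N1C(=O)c2ccc(cc2C1=O)C(=O)O")

# proposed base decomposition of either DITA isomer (printed-table spellings)
dita_group_vector <- function() {
  group_vector(c("CO-(O)(C_B)" = 3, "O-(H)(CO)" = 3, "CO-(N)(C_B)" = 4,
                 "N-(CO)2(C_B)" = 2, "C_B-(CO)(C_B)2" = 7,
                 "C_B-(H)(C_B)2" = 9, "C_B-(N)(C_B)2" = 2),
               corrections = c(rsc = 2))
}

# hand-built benzene graph (aromatic flags set, no explicit H)
benzene_graph <- function() {
  molecular_graph(
    atoms = data.frame(element = rep("C", 6), hcount = rep(1L, 6),
                       aromatic = rep(TRUE, 6)),
    bonds = data.frame(i = 1:6, j = c(2:6, 1), order = "ar"))
}

expect_formula_equal <- function(f, text) {
  expected <- if (nzchar(text)) format(parse_formula(text)) else ""
  expect_equal(format(f), expected)
}
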