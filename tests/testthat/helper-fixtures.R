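# shared toy fixtures, all built in code

# three-reaction uptake chain: EX_a (lb -5) -> T_a -> demand drain
chain_gem <- function(uptake = 5) {
  gem(reactions = reaction_tbl(
    c("EX_a", "T_a", "BM"),
    c("a[e] <=> ", "a[e] <=> a[c]", "a[c] => "),
    lower_bound = c(-uptake, -1000, 0),
    kind = c(NA, NA, "biomass")),
    objective = "BM")
}

# sulfur-assimilation fixture: cysteine synthesis from sulfate plus a
# semi-essential import route; `repaired` includes the two reduction steps
sulfur_gem <- function(repaired = TRUE, cys_import = TRUE) {
  rxns <- bind_rows(
    reaction_tbl(
      c("EX_so4", "T_so4", "APS_FORM", "EX_ser", "T_ser", "CYS_SYNTH"),
      c("so4[e] <=> ", "so4[e] <=> so4[c]", "so4[c] => aps[c]",
        "ser[e] <=> ", "ser[e] <=> ser[c]",
        "h2s[c] + ser[c] => cys[c]"),
      lower_bound = c(-5, -1000, 0, -1000, -1000, 0),
      pathway = "sulfur metabolism"),
    if (repaired) reaction_tbl(
      c("APS_RED", "SULFITE_RED"),
      c("aps[c] => so3[c]", "so3[c] => h2s[c]"),
      pathway = "sulfur metabolism"),
    reaction_tbl(
      c("EX_cys", "T_cys"),
      c("cys[e] <=> ", "cys[e] <=> cys[c]"),
      lower_bound = if (cys_import) c(-3, -1000) else c(0, 0)))
  mets <- metabolite_tbl(
    c("so4[e]", "so4[c]", "aps[c]", "so3[c]", "h2s[c]",
      "ser[e]", "ser[c]", "cys[c]", "cys[e]"))
  gem(mets, rxns)
}

# composition table in the style of a whole-animal assay:
# 20 amino acids + 22 fatty acids + 9 trace elements + 2 saccharides
composition_53 <- function(water_fraction = 0.516) {
  aa <- molar_mass_table[molar_mass_table$class == "amino_acid", ]
  fa <- molar_mass_table[molar_mass_table$class == "fatty_acid", ]
  minerals <- molar_mass_table[molar_mass_table$class == "mineral", ]
  fa22 <- tibble::tibble(
    compound = c(fa$compound, paste0("fatty acid C", 12:21)),
    molar_mass = c(fa$molar_mass, seq(200, 290, 10)))
  comp <- tibble::tibble(
    component = paste0(gsub("[^a-z0-9]", "_",
                            tolower(c(aa$compound, fa22$compound,
                                      minerals$compound,
                                      "glucose", "glycogen unit"))), "[c]"),
    class = c(rep("amino_acid", 20), rep("fatty_acid", 22),
              rep("mineral", 9), rep("saccharide", 2)),
    content = c(rep(10.1 / 20, 20), rep(35 / 22, 22),
                rep(1.5 / 9, 9), rep(1 / 2, 2)),
    molar_mass = c(aa$molar_mass, fa22$molar_mass, minerals$molar_mass,
                   180.16, 162.14))
  biomass_composition(comp, water_fraction)
}
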