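# Builds the synthetic rice thiamin reference network tables shipped under
# inst/extdata/thiamin_rice_synthetic/. Topology: canonical plant de novo
# thiamin biosynthesis (THIC / THI1 branches, bifunctional TH1, TH2, TDPK,
# THiM salvage, inter-compartmental transport). Parameters are plausible
# placeholders on an nmol/L scale, not measured constants. Run from the
# repository root:  Rscript data-raw/make_reference_tables.R
pkgload::load_all(".", quiet = TRUE)

B <- TRUE  # clamped pools (cofactors, phosphate, external reservoirs)
mets <- list(
  # plastid (de novo synthesis)
  metabolite("AIR_p",    "5-aminoimidazole ribonucleotide",        "plastid", 17),
  metabolite("SAM_p",    "S-adenosylmethionine",                   "plastid", 17),
  metabolite("SAH_p",    "S-adenosylhomocysteine",                 "plastid", 1),
  metabolite("NAD_p",    "NAD",                                    "plastid", 100, B),
  metabolite("GLY_p",    "glycine",                                "plastid", 1000, B),
  metabolite("ATP_p",    "ATP",                                    "plastid", 1000, B),
  metabolite("ADP_p",    "ADP",                                    "plastid", 500, B),
  metabolite("HMP_P_p",  "hydroxymethylpyrimidine phosphate",      "plastid", 2),
  metabolite("HMP_PP_p", "hydroxymethylpyrimidine diphosphate",    "plastid", 5),
  metabolite("HET_P_p",  "hydroxyethylthiazole phosphate",         "plastid", 5),
  metabolite("HET_p",    "hydroxyethylthiazole",                   "plastid", 0.6),
  metabolite("TMP_p",    "thiamin monophosphate",                  "plastid", 1.5),
  metabolite("PI_p",     "inorganic phosphate",                    "plastid", 1000, B),
  # cytosol
  metabolite("TMP_c",    "thiamin monophosphate",                  "cytosol", 1.6),
  metabolite("THM_c",    "thiamin",                                "cytosol", 1),
  metabolite("TDP_c",    "thiamin diphosphate",                    "cytosol", 1),
  metabolite("HET_c",    "hydroxyethylthiazole",                   "cytosol", 0.5),
  metabolite("ATP_c",    "ATP",                                    "cytosol", 1000, B),
  metabolite("ADP_c",    "ADP",                                    "cytosol", 500, B),
  metabolite("AMP_c",    "AMP",                                    "cytosol", 100, B),
  metabolite("PI_c",     "inorganic phosphate",                    "cytosol", 1000, B),
  # mitochondrion
  metabolite("TMP_m",    "thiamin monophosphate",                  "mitochondrion", 0.9),
  metabolite("THM_m",    "thiamin",                                "mitochondrion", 0.5),
  metabolite("TDP_m",    "thiamin diphosphate",                    "mitochondrion", 0.5),
  metabolite("PI_m",     "inorganic phosphate",                    "mitochondrion", 1000, B),
  # external reservoirs
  metabolite("AIR_e",    "AIR (external)",                         "external", 100, B),
  metabolite("SAM_e",    "SAM (external)",                         "external", 100, B),
  metabolite("HET_e",    "hydroxyethylthiazole (external)",        "external", 100, B),
  metabolite("THM_e",    "thiamin (external)",                     "external", 100, B))

mm1 <- function(sub, vmax, km) kinetic_law("MM1", sub, vmax = vmax, km = km)
mm2 <- function(subs, vmax, ka, kb) kinetic_law("MM2", subs, vmax = vmax,
                                                km_a = ka, km_b = kb)
ma <- function(sub, k) kinetic_law("mass_action", sub, k = k)
cf <- function(k) kinetic_law("constant_flux", k = k)

rxns <- list(
  # core enzymatic steps
  reaction("R_THIC", "THIC", c(AIR_p = -1, SAM_p = -1, HMP_P_p = 1, SAH_p = 1),
           mm2(c("AIR_p", "SAM_p"), 0.05, 5, 5)),
  reaction("R_THI1", "THI1", c(NAD_p = -1, GLY_p = -1, HET_P_p = 1),
           mm1("NAD_p", 0.012, 20)),
  reaction("R_TH1_kinase", "TH1",
           c(HMP_P_p = -1, ATP_p = -1, HMP_PP_p = 1, ADP_p = 1),
           mm1("HMP_P_p", 0.08, 2)),
  reaction("R_TH1_synthase", "TH1",
           c(HMP_PP_p = -1, HET_P_p = -1, TMP_p = 1, PI_p = 1),
           mm2(c("HMP_PP_p", "HET_P_p"), 0.04, 2, 2)),
  reaction("R_TH2_c", "TH2", c(TMP_c = -1, THM_c = 1, PI_c = 1),
           mm1("TMP_c", 0.05, 5)),
  reaction("R_TH2_m", "TH2", c(TMP_m = -1, THM_m = 1, PI_m = 1),
           mm1("TMP_m", 0.02, 5)),
  reaction("R_TDPK", "TDPK", c(THM_c = -1, ATP_c = -1, TDP_c = 1, AMP_c = 1),
           mm1("THM_c", 0.03, 10)),
  reaction("R_THiM", "THiM", c(HET_p = -1, ATP_p = -1, HET_P_p = 1, ADP_p = 1),
           mm2(c("HET_p", "ATP_p"), 0.02, 1, 500)),
  # inter-compartmental and external transport
  reaction("T_AIR", "transport", c(AIR_e = -1, AIR_p = 1), ma("AIR_e", 2e-4)),
  reaction("T_SAM", "transport", c(SAM_e = -1, SAM_p = 1), ma("SAM_e", 2e-4)),
  reaction("T_HET", "transport", c(HET_e = -1, HET_c = 1), ma("HET_e", 5e-5)),
  reaction("T_HET_cp", "transport", c(HET_c = -1, HET_p = 1), ma("HET_c", 0.01)),
  reaction("T_TMP_pc", "transport", c(TMP_p = -1, TMP_c = 1), ma("TMP_p", 0.01)),
  reaction("T_TMP_cm", "transport", c(TMP_c = -1, TMP_m = 1), ma("TMP_c", 0.002)),
  reaction("T_TMP_mc", "transport", c(TMP_m = -1, TMP_c = 1), ma("TMP_m", 0.001)),
  reaction("T_THM_cm", "transport", c(THM_c = -1, THM_m = 1), ma("THM_c", 0.001)),
  reaction("T_THM_mc", "transport", c(THM_m = -1, THM_c = 1), ma("THM_m", 0.005)),
  reaction("T_THM_ec", "transport", c(THM_e = -1, THM_c = 1), ma("THM_e", 2e-5)),
  reaction("T_TDP_cm", "transport", c(TDP_c = -1, TDP_m = 1), ma("TDP_c", 0.001)),
  reaction("T_TDP_mc", "transport", c(TDP_m = -1, TDP_c = 1), ma("TDP_m", 1e-4)),
  # precursor supply within the plastid
  reaction("R_AIR_supply", "supply", c(AIR_p = 1), cf(0.01)),
  reaction("R_SAM_supply", "supply", c(SAM_p = 1), cf(0.01)),
  # turnover / recycling
  reaction("R_SAH_drain", "SAHH", c(SAH_p = -1), ma("SAH_p", 0.01)),
  reaction("R_HMP_P_deg", "degradation", c(HMP_P_p = -1), ma("HMP_P_p", 1e-4)),
  reaction("R_HMP_PP_deg", "degradation", c(HMP_PP_p = -1), ma("HMP_PP_p", 1e-4)),
  reaction("R_HET_P_deg", "degradation", c(HET_P_p = -1), ma("HET_P_p", 1e-4)),
  reaction("R_HET_deg_p", "degradation", c(HET_p = -1), ma("HET_p", 1e-4)),
  reaction("R_TMP_deg_c", "degradation", c(TMP_c = -1), ma("TMP_c", 2e-4)),
  reaction("R_THM_deg_c", "degradation", c(THM_c = -1), ma("THM_c", 2e-4)),
  reaction("R_TDP_TMP_c", "phosphatase", c(TDP_c = -1, TMP_c = 1, PI_c = 1),
           ma("TDP_c", 1e-4)),
  # steps without literature kinetics: flux-balance gap-fill
  reaction("T_THM_ce", "transport", c(THM_c = -1, THM_e = 1), needs_fba = TRUE),
  reaction("R_TDP_use_c", "utilization", c(TDP_c = -1), needs_fba = TRUE),
  reaction("R_TDP_use_m", "utilization", c(TDP_m = -1), needs_fba = TRUE),
  reaction("R_THM_use_m", "utilization", c(THM_m = -1), needs_fba = TRUE))

model <- pathway_model(mets, rxns,
                       metadata = list(kind = "thiamin_rice_synthetic"))
stopifnot(n_reactions(model) == 34L, n_metabolites(model) == 29L,
          nrow(validate_model(model)) == 0L)

out <- "inst/extdata/thiamin_rice_synthetic"
write_model_tables(model, out)

# flux-balance gap-fill configuration: finite uptake caps on the supply side,
# minimal cofactor-demand fluxes on the gap-filled utilisation steps, and
# maximisation of the TMP synthase flux
cfg <- data.frame(
  reaction_id = c("T_AIR", "R_AIR_supply", "T_SAM", "R_SAM_supply",
                  "T_HET", "T_THM_ec", "R_THIC", "R_TH1_synthase",
                  "R_TDP_use_c", "R_TDP_use_m", "R_THM_use_m", "T_THM_ce"),
  lower = c(NA, NA, NA, NA, NA, NA, NA, NA, 0.002, 0.001, 0.001, 0.001),
  upper = c(0.02, 0.01, 0.02, 0.01, 0.005, 0.002, 0.03, NA,
            NA, NA, NA, NA),
  objective = c(NA, NA, NA, NA, NA, NA, NA, 1, NA, NA, NA, NA))
write.table(cfg, file.path(out, "fba_config.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote", out, "\n")
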