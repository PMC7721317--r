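## Reduced synthetic plant core network.
##
## A ~100-reaction, five-compartment (plus extracellular) stand-in for a
## genome-scale plant core model. It contains the carbon, nitrogen and
## energy routes a diel leaf simulation exercises: light-driven ATP/NADPH
## supply, Rubisco carboxylase/oxygenase with photorespiration through Gly
## decarboxylase, the CBB cycle (lumped), starch and sucrose turnover, PEPC,
## the TCA cycle with cytosolic and mitochondrial aconitase/ICDH, malic
## enzymes, malate dehydrogenases (cytosol, mitochondrion, peroxisome),
## peroxisomal and mitochondrial citrate synthase, the Pro cycle
## (P5CS/P5CR/ProDH/P5CDH/GDH), nitrate assimilation, vacuolar transporters
## for every storable, phloem export and maintenance sinks.
##
## Cofactors are modelled as explicit pairs (ATP/ADP+Pi, NAD(P)H/NAD(P)) per
## compartment; reactions are balanced for carbon, nitrogen and phosphate
## groups (protons, water oxygen and full charge are not tracked - that
## level of curation is delegated to real SBML models).

toy_metabolite_table <- function() {
  ## base name -> carbons, nitrogens
  base <- c(
    CO2 = "1,0", HCO3 = "1,0", O2 = "0,0", H2O = "0,0", PHOTON = "0,0",
    NO3 = "0,1", NO2 = "0,1", NH4 = "0,1",
    ATP = "0,0", ADP = "0,0", Pi = "0,0",
    NADH = "0,0", NAD = "0,0", NADPH = "0,0", NADP = "0,0",
    RUBP = "5,0", PGA = "3,0", TP = "3,0", HP = "6,0",
    GCA = "2,0", GLX = "2,0", GCEA = "3,0", STARCH = "6,0",
    PEP = "3,0", PYR = "3,0", OAA = "4,0", MAL = "4,0",
    CIT = "6,0", ICIT = "6,0", AKG = "5,0", ACCOA = "2,0",
    GLU = "5,1", GLN = "5,2", ASP = "4,1", ASN = "4,2",
    PRO = "5,1", P5C = "5,1", GLY = "2,1", SER = "3,1",
    SUC = "12,0", GLC = "6,0", FRU = "6,0")
  ids <- c(
    e = "CO2 O2 NO3 PHOTON H2O",
    c = paste("CO2 HCO3 O2 H2O TP HP PEP PYR OAA MAL CIT ICIT AKG ACCOA",
              "GLU GLN ASP ASN PRO P5C SUC GLC FRU NO3 NO2 NH4",
              "ATP ADP Pi NADH NAD NADPH NADP"),
    p = paste("CO2 O2 RUBP PGA TP HP GCA GCEA STARCH NO2 NH4",
              "ATP ADP Pi NADPH NADP"),
    m = paste("CO2 O2 PYR ACCOA OAA MAL CIT ICIT AKG GLU PRO P5C GLY SER",
              "NH4 ATP ADP Pi NADH NAD"),
    x = "GCA GLX GLY SER GCEA OAA MAL ACCOA CIT GLU AKG NH4 O2 NADH NAD",
    v = "GLC FRU SUC MAL CIT ICIT PRO GLU ASP ASN NO3")
  out <- do.call(rbind, lapply(names(ids), function(cp) {
    bs <- strsplit(ids[[cp]], "\\s+")[[1]]
    cn <- do.call(rbind, strsplit(base[bs], ","))
    data.frame(id = paste0(bs, "_", cp), name = bs,
               compartment = unname(COMPARTMENTS[cp]),
               carbons = as.numeric(cn[, 1]), nitrogens = as.numeric(cn[, 2]))
  }))
  out$carries_carbon <- out$carbons > 0
  out$is_co2_species <- out$name %in% c("CO2", "HCO3")
  out
}

toy_reaction_table <- function(phloem_sucrose_fraction = 0.8) {
  fs <- phloem_sucrose_fraction
  fa <- (1 - fs) / 4
  ## id | equation | rev | tags | boundary
  rx <- list(
    ## --- exchanges and uptakes ---
    list("EX_CO2",   "CO2_e ->", TRUE,  "", TRUE),
    list("EX_O2",    "O2_e ->", TRUE,  "", TRUE),
    list("EX_H2O",   "H2O_e ->", TRUE,  "", TRUE),
    list("EX_NO3",   "-> NO3_e", FALSE, "", TRUE),
    list("EX_PHOTON", "-> PHOTON_e", FALSE, "LIGHT_UPTAKE", TRUE),
    list("CO2_UPTAKE", "CO2_e -> CO2_c", FALSE, "CO2_UPTAKE", FALSE),
    list("CO2_EFFLUX", "CO2_c -> CO2_e", FALSE, "CO2_EFFLUX", FALSE),
    list("O2_ET",    "O2_c <-> O2_e", TRUE,  "", FALSE),
    list("H2O_ET",   "H2O_c <-> H2O_e", TRUE, "", FALSE),
    list("NO3_UPTAKE", "NO3_e + ATP_c -> NO3_c + ADP_c + Pi_c",
         FALSE, "NITRATE_UPTAKE", FALSE),
    ## --- light reactions (lumped linear electron transport) ---
    list("LIGHT_RXN",
         "8 PHOTON_e + 3 ADP_p + 3 Pi_p + 2 NADP_p -> 3 ATP_p + 2 NADPH_p",
         FALSE, "", FALSE),
    ## --- plastid: CBB, photorespiration, starch ---
    list("RBC_CARB", "RUBP_p + CO2_p -> 2 PGA_p", FALSE, "RUBISCO_CARB", FALSE),
    list("RBC_OXY",  "RUBP_p + O2_p -> PGA_p + GCA_p + Pi_p", FALSE,
         "RUBISCO_OXY", FALSE),
    list("PGA_RED",
         "PGA_p + ATP_p + NADPH_p -> TP_p + ADP_p + Pi_p + NADP_p",
         FALSE, "", FALSE),
    list("RUBP_REGEN",
         "1.666667 TP_p + ATP_p -> RUBP_p + ADP_p + 0.666667 Pi_p",
         FALSE, "", FALSE),
    list("STARCH_SYN", "2 TP_p + ATP_p -> STARCH_p + ADP_p + 3 Pi_p",
         FALSE, "", FALSE),
    list("STARCH_DEG", "STARCH_p -> GLC_c", FALSE, "", FALSE),
    list("OPP_P", "HP_p + 6 NADP_p -> TP_p + 3 CO2_p + 6 NADPH_p",
         FALSE, "", FALSE),
    list("TPT",  "TP_p + Pi_c <-> TP_c + Pi_p", TRUE, "", FALSE),
    list("HPT",  "HP_c + Pi_p <-> HP_p + Pi_c", TRUE, "", FALSE),
    list("GCA_PT", "GCA_p -> GCA_x", FALSE, "", FALSE),
    list("GCEA_PT", "GCEA_x -> GCEA_p", FALSE, "", FALSE),
    list("GCEA_KIN", "GCEA_p + ATP_p -> PGA_p + ADP_p", FALSE, "", FALSE),
    list("NIR", "NO2_p + 3 NADPH_p -> NH4_p + 3 NADP_p", FALSE, "", FALSE),
    list("NO2_PT", "NO2_c -> NO2_p", FALSE, "", FALSE),
    list("NH4_PT", "NH4_p -> NH4_c", FALSE, "", FALSE),
    list("AAC_P", "ATP_p + ADP_c <-> ADP_p + ATP_c", TRUE, "", FALSE),
    list("PIT_P", "Pi_c <-> Pi_p", TRUE, "", FALSE),
    list("CO2_PT", "CO2_c <-> CO2_p", TRUE, "", FALSE),
    list("O2_PT",  "O2_c <-> O2_p", TRUE, "", FALSE),
    ## --- cytosol: sugars, glycolysis, anaplerosis, N assimilation ---
    list("CA", "CO2_c <-> HCO3_c", TRUE, "", FALSE),
    list("HXK", "GLC_c + ATP_c -> HP_c + ADP_c", FALSE, "", FALSE),
    list("FRK", "FRU_c + ATP_c -> HP_c + ADP_c", FALSE, "", FALSE),
    list("INV", "SUC_c -> GLC_c + FRU_c", FALSE, "", FALSE),
    list("SUC_SYN", "4 TP_c + 2 ATP_c -> SUC_c + 2 ADP_c + 6 Pi_c",
         FALSE, "", FALSE),
    list("PFK", "HP_c + ATP_c -> 2 TP_c + ADP_c", FALSE, "", FALSE),
    list("GAPDH_PGK",
         "TP_c + Pi_c + NAD_c + ADP_c <-> PEP_c + ATP_c + NADH_c",
         TRUE, "", FALSE),
    list("PYK", "PEP_c + ADP_c -> PYR_c + ATP_c", FALSE, "", FALSE),
    list("PPDK", "PYR_c + 2 ATP_c -> PEP_c + 2 ADP_c + Pi_c", FALSE, "", FALSE),
    list("PEPC", "PEP_c + HCO3_c -> OAA_c + Pi_c", FALSE, "PEPC", FALSE),
    list("MDH_C", "OAA_c + NADH_c <-> MAL_c + NAD_c", TRUE, "", FALSE),
    list("NADP_ME", "MAL_c + NADP_c -> PYR_c + CO2_c + NADPH_c",
         FALSE, "NADP_ME", FALSE),
    list("ACON_C", "CIT_c <-> ICIT_c", TRUE, "ACONITASE_C", FALSE),
    list("ICDH_C", "ICIT_c + NADP_c <-> AKG_c + CO2_c + NADPH_c",
         TRUE, "ICDH_C", FALSE),
    list("AAT_C", "OAA_c + GLU_c <-> ASP_c + AKG_c", TRUE, "ASP_AT", FALSE),
    list("ASN_SYN",
         "ASP_c + GLN_c + ATP_c -> ASN_c + GLU_c + ADP_c + Pi_c",
         FALSE, "ASN_SYN", FALSE),
    list("GS", "GLU_c + NH4_c + ATP_c -> GLN_c + ADP_c + Pi_c",
         FALSE, "", FALSE),
    list("GOGAT", "GLN_c + AKG_c + NADH_c -> 2 GLU_c + NAD_c",
         FALSE, "", FALSE),
    list("P5CS", "GLU_c + ATP_c + NADPH_c -> P5C_c + ADP_c + Pi_c + NADP_c",
         FALSE, "P5CS", FALSE),
    list("P5CR", "P5C_c + NADPH_c -> PRO_c + NADP_c", FALSE, "P5CR", FALSE),
    list("NR", "NO3_c + NADH_c -> NO2_c + NAD_c", FALSE, "", FALSE),
    list("OPP_C", "HP_c + 6 NADP_c -> TP_c + 3 CO2_c + 6 NADPH_c",
         FALSE, "", FALSE),
    list("ACCOA_SYN_C", "PYR_c + NAD_c -> ACCOA_c + CO2_c + NADH_c",
         FALSE, "", FALSE),
    list("NDH_EXT",
         "NADH_c + 0.5 O2_c + 1.5 ADP_c + 1.5 Pi_c -> NAD_c + 1.5 ATP_c",
         FALSE, "", FALSE),
    list("ATP_MAINT", "ATP_c -> ADP_c + Pi_c", FALSE, "ATP_MAINT", FALSE),
    list("NADPH_MAINT", "NADPH_c + 0.5 O2_c -> NADP_c", FALSE, "NADPH_MAINT", FALSE),
    ## --- mitochondrion: TCA, respiration, photorespiration, Pro cycle ---
    list("PYR_MT", "PYR_c -> PYR_m", FALSE, "", FALSE),
    list("PDH", "PYR_m + NAD_m -> ACCOA_m + CO2_m + NADH_m", FALSE, "", FALSE),
    list("CS_M", "ACCOA_m + OAA_m -> CIT_m", FALSE, "CS_M", FALSE),
    list("ACON_M", "CIT_m <-> ICIT_m", TRUE, "ACONITASE_M", FALSE),
    list("ICDH_M", "ICIT_m + NAD_m <-> AKG_m + CO2_m + NADH_m",
         TRUE, "ICDH_M", FALSE),
    list("TCA_LOWER",
         "AKG_m + 2 NAD_m + ADP_m + Pi_m -> MAL_m + CO2_m + 2 NADH_m + ATP_m",
         FALSE, "", FALSE),
    list("MDH_M", "OAA_m + NADH_m <-> MAL_m + NAD_m", TRUE, "", FALSE),
    list("NAD_ME", "MAL_m + NAD_m -> PYR_m + CO2_m + NADH_m",
         FALSE, "NAD_ME", FALSE),
    list("RESP",
         "NADH_m + 0.5 O2_m + 2.5 ADP_m + 2.5 Pi_m -> NAD_m + 2.5 ATP_m",
         FALSE, "", FALSE),
    list("GDC", "2 GLY_m + NAD_m -> SER_m + CO2_m + NH4_m + NADH_m",
         FALSE, "GDC", FALSE),
    list("PRODH", "PRO_m + NAD_m -> P5C_m + NADH_m", FALSE, "PRO_DH", FALSE),
    list("P5CDH", "P5C_m + NAD_m -> GLU_m + NADH_m", FALSE, "P5C_DH", FALSE),
    list("GDH", "GLU_m + NAD_m <-> AKG_m + NH4_m + NADH_m", TRUE, "GDH", FALSE),
    list("MAL_MT", "MAL_c <-> MAL_m", TRUE, "", FALSE),
    list("OAA_MT", "OAA_c <-> OAA_m", TRUE, "", FALSE),
    list("CIT_MT", "CIT_c <-> CIT_m", TRUE, "", FALSE),
    list("ICIT_MT", "ICIT_c <-> ICIT_m", TRUE, "", FALSE),
    list("AKG_MT", "AKG_c <-> AKG_m", TRUE, "", FALSE),
    list("GLU_MT", "GLU_c <-> GLU_m", TRUE, "", FALSE),
    list("PRO_MT", "PRO_c <-> PRO_m", TRUE, "", FALSE),
    list("NH4_MT", "NH4_m -> NH4_c", FALSE, "", FALSE),
    list("ANT_M", "ATP_m + ADP_c <-> ADP_m + ATP_c", TRUE, "", FALSE),
    list("PIT_M", "Pi_c <-> Pi_m", TRUE, "", FALSE),
    list("CO2_MT", "CO2_c <-> CO2_m", TRUE, "", FALSE),
    list("O2_MT", "O2_c <-> O2_m", TRUE, "", FALSE),
    list("GLY_MT", "GLY_x -> GLY_m", FALSE, "", FALSE),
    list("SER_MT", "SER_m -> SER_x", FALSE, "", FALSE),
    ## --- peroxisome: photorespiration, citrate synthase route ---
    list("GOX", "GCA_x + 0.75 O2_x -> GLX_x", FALSE, "", FALSE),
    list("AGT", "GLX_x + GLU_x -> GLY_x + AKG_x", FALSE, "", FALSE),
    list("SGAT_HPR", "SER_x + NADH_x -> GCEA_x + NAD_x + NH4_x",
         FALSE, "", FALSE),
    list("MDH_X", "MAL_x + NAD_x <-> OAA_x + NADH_x", TRUE, "MDH_X", FALSE),
    list("CS_X", "ACCOA_x + OAA_x -> CIT_x", FALSE, "CS_X", FALSE),
    list("MAL_XT", "MAL_c <-> MAL_x", TRUE, "", FALSE),
    list("CIT_XT", "CIT_x -> CIT_c", FALSE, "", FALSE),
    list("ACCOA_XT", "ACCOA_c -> ACCOA_x", FALSE, "", FALSE),
    list("GLU_XT", "GLU_c <-> GLU_x", TRUE, "", FALSE),
    list("AKG_XT", "AKG_x <-> AKG_c", TRUE, "", FALSE),
    list("NH4_XT", "NH4_x -> NH4_c", FALSE, "", FALSE),
    list("O2_XT", "O2_c <-> O2_x", TRUE, "", FALSE),
    ## --- vacuolar transporters (one per storable) ---
    list("VT_GLC", "GLC_c <-> GLC_v", TRUE, "VACUOLAR_TRANSPORT", FALSE),
    list("VT_FRU", "FRU_c <-> FRU_v", TRUE, "VACUOLAR_TRANSPORT", FALSE),
    list("VT_SUC", "SUC_c <-> SUC_v", TRUE, "VACUOLAR_TRANSPORT", FALSE),
    list("VT_MAL", "MAL_c <-> MAL_v", TRUE, "VACUOLAR_TRANSPORT", FALSE),
    list("VT_CIT", "CIT_c <-> CIT_v", TRUE, "VACUOLAR_TRANSPORT", FALSE),
    list("VT_ICIT", "ICIT_c <-> ICIT_v", TRUE, "VACUOLAR_TRANSPORT", FALSE),
    list("VT_PRO", "PRO_c <-> PRO_v", TRUE, "VACUOLAR_TRANSPORT", FALSE),
    list("VT_GLU", "GLU_c <-> GLU_v", TRUE, "VACUOLAR_TRANSPORT", FALSE),
    list("VT_ASP", "ASP_c <-> ASP_v", TRUE, "VACUOLAR_TRANSPORT", FALSE),
    list("VT_ASN", "ASN_c <-> ASN_v", TRUE, "VACUOLAR_TRANSPORT", FALSE),
    list("VT_NO3", "NO3_c <-> NO3_v", TRUE, "VACUOLAR_TRANSPORT", FALSE),
    ## --- phloem export sink ---
    list("PHLOEM",
         sprintf("%g SUC_c + %g GLU_c + %g ASP_c + %g ASN_c + %g PRO_c ->",
                 fs, fa, fa, fa, fa),
         FALSE, "PHLOEM_EXPORT", TRUE))
  rx
}

#' Build the reduced synthetic plant core network
#'
#' Constructs a compartmented (cytosol, plastid, mitochondrion, peroxisome,
#' vacuole, extracellular) core network of leaf metabolism, small enough to
#' solve quickly but complete enough that every diel flux route of interest
#' (C3 photosynthesis with photorespiration; nocturnal CO2 fixation by PEPC
#' into malate; the isocitrate-citrate-Pro-2OG cycle through reverse
#' mitochondrial ICDH; daytime decarboxylation and refixation) is feasible.
#'
#' @param icdh_reversible should mitochondrial ICDH be allowed to run in the
#'   carboxylating (reverse) direction? Default `TRUE`; `FALSE` sets its
#'   lower bound to 0 (conventional forward direction only).
#' @param mitochondria include the mitochondrial compartment. Disabling it
#'   while explicitly requesting an ICDH mode is a configuration error.
#' @param phloem_sucrose_fraction molar sucrose fraction of phloem export
#'   (remainder split equally over Glu, Asp, Asn, Pro). Default 0.8
#'   (80:20 sucrose:amino acids).
#' @param bound default absolute flux bound in umol m-2 s-1.
#' @return a [metabolic_network()].
#' @export
build_toy_core <- function(icdh_reversible = TRUE, mitochondria = TRUE,
                           phloem_sucrose_fraction = 0.8, bound = 1000) {
  if (!mitochondria && !missing(icdh_reversible))
    stop("configuration error: mitochondria disabled but an ICDH_M mode ",
         "was requested")
  stopifnot(phloem_sucrose_fraction > 0, phloem_sucrose_fraction < 1)
  mets <- toy_metabolite_table()
  rx <- toy_reaction_table(phloem_sucrose_fraction)
  if (!mitochondria) {
    drop_met <- grepl("_m$", mets$id)
    mets <- mets[!drop_met, ]
    keep <- vapply(rx, function(r) {
      st <- parse_rxn_eq(r[[1]], r[[2]])
      !any(grepl("_m$", st$metabolite))
    }, logical(1))
    rx <- rx[keep]
  }
  reactions <- data.frame(
    id = vapply(rx, `[[`, character(1), 1),
    name = vapply(rx, `[[`, character(1), 1),
    lb = ifelse(vapply(rx, `[[`, logical(1), 3), -bound, 0),
    ub = bound)
  reactions$tags <- lapply(rx, function(r)
    if (nzchar(r[[4]])) strsplit(r[[4]], ",")[[1]] else character(0))
  reactions$boundary <- vapply(rx, `[[`, logical(1), 5)
  stoi <- do.call(rbind, lapply(rx, function(r) parse_rxn_eq(r[[1]], r[[2]])))
  if (!icdh_reversible && mitochondria)
    reactions$lb[reactions$id == "ICDH_M"] <- 0
  metabolic_network(mets, reactions, stoi)
}
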