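## Hand-curated central-carbon toy network ("toy_core").
##
## A ~60-reaction E. coli central-carbon model covering glycolysis (with a
## PTS glucose uptake), the pentose phosphate pathway, a TCA cycle with
## anaplerosis and malic enzyme, overflow acetate and D-lactate
## fermentation, the GABA shunt (GLUDy -> GLUDC -> export, plus the
## ABTA/SSALy route closed in the production strain), and a lumped
## proton-pumping respiratory chain.  Every reaction except the lumped
## biomass is elementally balanced over CHNOPS (protons and water are
## explicit, as in the published E. coli core model).  The network is fixed
## by design -- worked-example fluxes must be stable across releases -- and
## is dimensioned so that the three measured rate vectors of the study are
## each feasible once AKGDH and ABTA are closed.

toy_metabolite_formulas <- c(
  glc__D = "C6H12O6", g6p = "C6H11O9P", f6p = "C6H11O9P",
  fdp = "C6H10O12P2", dhap = "C3H5O6P", g3p = "C3H5O6P",
  `13dpg` = "C3H4O10P2", `3pg` = "C3H4O7P", `2pg` = "C3H4O7P",
  pep = "C3H2O6P", pyr = "C3H3O3", lac__D = "C3H5O3",
  accoa = "C23H34N7O17P3S", coa = "C21H32N7O16P3S",
  cit = "C6H5O7", icit = "C6H5O7", akg = "C5H4O5",
  succoa = "C25H35N7O19P3S", succ = "C4H4O4", fum = "C4H2O4",
  mal__L = "C4H4O5", oaa = "C4H2O5",
  glu__L = "C5H8NO4", gaba = "C4H9NO2", sucsal = "C4H5O3",
  glx = "C2H1O3",
  ac = "C2H3O2", actp = "C2H3O5P",
  `6pgc` = "C6H10O10P", ru5p__D = "C5H9O8P", r5p = "C5H9O8P",
  xu5p__D = "C5H9O8P", s7p = "C7H13O10P", e4p = "C4H7O7P",
  atp = "C10H12N5O13P3", adp = "C10H12N5O10P2", pi = "HO4P",
  nad = "C21H26N7O14P2", nadh = "C21H27N7O14P2",
  nadp = "C21H25N7O17P3", nadph = "C21H26N7O17P3",
  nh4 = "H4N", co2 = "CO2", o2 = "O2", h2o = "H2O", h = "H",
  q8 = "C49H74O4", q8h2 = "C49H76O4")

toy_metabolite_names <- c(
  glc__D = "D-glucose", g6p = "glucose 6-phosphate",
  f6p = "fructose 6-phosphate", fdp = "fructose 1,6-bisphosphate",
  dhap = "dihydroxyacetone phosphate", g3p = "glyceraldehyde 3-phosphate",
  `13dpg` = "1,3-bisphosphoglycerate", `3pg` = "3-phosphoglycerate",
  `2pg` = "2-phosphoglycerate", pep = "phosphoenolpyruvate",
  pyr = "pyruvate", lac__D = "D-lactate", accoa = "acetyl-CoA",
  coa = "coenzyme A", cit = "citrate", icit = "isocitrate",
  akg = "2-oxoglutarate", succoa = "succinyl-CoA", succ = "succinate",
  fum = "fumarate", mal__L = "L-malate", oaa = "oxaloacetate",
  glu__L = "L-glutamate", gaba = "4-aminobutyrate",
  sucsal = "succinate semialdehyde", glx = "glyoxylate", ac = "acetate",
  actp = "acetyl phosphate", `6pgc` = "6-phosphogluconate",
  ru5p__D = "ribulose 5-phosphate", r5p = "ribose 5-phosphate",
  xu5p__D = "xylulose 5-phosphate", s7p = "sedoheptulose 7-phosphate",
  e4p = "erythrose 4-phosphate", atp = "ATP", adp = "ADP",
  pi = "phosphate", nad = "NAD+", nadh = "NADH", nadp = "NADP+",
  nadph = "NADPH", nh4 = "ammonium", co2 = "carbon dioxide",
  o2 = "oxygen", h2o = "water", h = "proton",
  q8 = "ubiquinone-8", q8h2 = "ubiquinol-8")

## id | name | equation | lb | ub | gpr | subsystem
## "<->" reversible (-1000..1000), "->" irreversible (0..1000) unless
## bounds are given explicitly.
toy_reaction_table <- function() {
  G <- "Glycolysis"; P <- "Pentose Phosphate Pathway"; T <- "TCA Cycle"
  A <- "Acetate Fermentation"; S <- "GABA Shunt"; O <- "Oxidative Phosphorylation"
  X <- "Transport"; E <- "Exchange"
  list(
    list("GLCpts", "D-glucose transport via PEP:Pyr PTS",
         "glc__D_e + pep_c -> g6p_c + pyr_c", "ptsG", G),
    list("PGI", "glucose-6-phosphate isomerase", "g6p_c <-> f6p_c",
         "pgi", G),
    list("PFK", "phosphofructokinase",
         "atp_c + f6p_c -> adp_c + fdp_c + h_c", "pfkA or pfkB", G),
    list("FBA", "fructose-bisphosphate aldolase",
         "fdp_c <-> dhap_c + g3p_c", "fbaA", G),
    list("TPI", "triose-phosphate isomerase", "dhap_c <-> g3p_c",
         "tpiA", G),
    list("GAPD", "glyceraldehyde-3-phosphate dehydrogenase",
         "g3p_c + nad_c + pi_c <-> 13dpg_c + h_c + nadh_c", "gapA", G),
    list("PGK", "phosphoglycerate kinase",
         "3pg_c + atp_c <-> 13dpg_c + adp_c", "pgk", G),
    list("PGM", "phosphoglycerate mutase", "2pg_c <-> 3pg_c", "gpmA or gpmM",
         G),
    list("ENO", "enolase", "2pg_c <-> h2o_c + pep_c", "eno", G),
    list("PYK", "pyruvate kinase", "adp_c + h_c + pep_c -> atp_c + pyr_c",
         "pykF or pykA", G),
    list("PDH", "pyruvate dehydrogenase",
         "coa_c + nad_c + pyr_c -> accoa_c + co2_c + nadh_c",
         "aceE and aceF and lpd", G),
    list("LDH_D", "D-lactate dehydrogenase",
         "lac__D_c + nad_c <-> h_c + nadh_c + pyr_c", "ldhA", G),

    list("G6PDHL",
         "glucose-6-phosphate dehydrogenase + lactonase (lumped)",
         "g6p_c + h2o_c + nadp_c -> 6pgc_c + nadph_c + 2 h_c",
         "zwf and pgl", P),
    list("GND", "6-phosphogluconate dehydrogenase",
         "6pgc_c + nadp_c -> co2_c + nadph_c + ru5p__D_c", "gnd", P),
    list("RPI", "ribose-5-phosphate isomerase", "r5p_c <-> ru5p__D_c",
         "rpiA or rpiB", P),
    list("RPE", "ribulose-5-phosphate 3-epimerase",
         "ru5p__D_c <-> xu5p__D_c", "rpe", P),
    list("TKT1", "transketolase 1", "r5p_c + xu5p__D_c <-> g3p_c + s7p_c",
         "tktA or tktB", P),
    list("TALA", "transaldolase", "g3p_c + s7p_c <-> e4p_c + f6p_c",
         "talA or talB", P),
    list("TKT2", "transketolase 2", "e4p_c + xu5p__D_c <-> f6p_c + g3p_c",
         "tktA or tktB", P),

    list("PPC", "phosphoenolpyruvate carboxylase",
         "co2_c + h2o_c + pep_c -> h_c + oaa_c + pi_c", "ppc", T),
    list("CS", "citrate synthase",
         "accoa_c + h2o_c + oaa_c -> cit_c + coa_c + h_c", "gltA", T),
    list("ACONT", "aconitase", "cit_c <-> icit_c", "acnA or acnB", T),
    list("ICDHyr", "isocitrate dehydrogenase (NADP)",
         "icit_c + nadp_c <-> akg_c + co2_c + nadph_c", "icd", T),
    list("AKGDH", "2-oxoglutarate dehydrogenase",
         "akg_c + coa_c + nad_c -> co2_c + nadh_c + succoa_c",
         "sucA and sucB and lpd", T),
    list("SUCOAS", "succinyl-CoA synthetase (ADP-forming)",
         "atp_c + coa_c + succ_c <-> adp_c + pi_c + succoa_c",
         "sucC and sucD", T),
    list("SUCDi", "succinate dehydrogenase (irreversible)",
         "q8_c + succ_c -> fum_c + q8h2_c",
         "sdhA and sdhB and sdhC and sdhD", T),
    list("FUM", "fumarase", "fum_c + h2o_c <-> mal__L_c",
         "fumA or fumB or fumC", T),
    list("MDH", "malate dehydrogenase",
         "mal__L_c + nad_c <-> h_c + nadh_c + oaa_c", "mdh", T),
    list("ME2", "malic enzyme (NADP)",
         "mal__L_c + nadp_c -> co2_c + nadph_c + pyr_c", "maeB", T),
    ## glyoxylate shunt: the strain's only succinate source when none is
    ## fed (2-oxoglutarate dehydrogenase being closed)
    list("ICL", "isocitrate lyase", "icit_c -> glx_c + succ_c", "aceA", T),
    list("MALS", "malate synthase",
         "accoa_c + glx_c + h2o_c -> coa_c + h_c + mal__L_c", "aceB", T),

    list("PTAr", "phosphotransacetylase",
         "accoa_c + pi_c <-> actp_c + coa_c", "pta", A),
    list("ACKr", "acetate kinase", "ac_c + atp_c <-> actp_c + adp_c",
         "ackA", A),

    list("GLUDy", "glutamate dehydrogenase (NADP)",
         "glu__L_c + h2o_c + nadp_c <-> akg_c + h_c + nadph_c + nh4_c",
         "gdhA", S),
    list("GLUDC", "glutamate decarboxylase",
         "glu__L_c + h_c -> co2_c + gaba_c", "gadA or gadB", S),
    list("ABTA", "4-aminobutyrate aminotransferase",
         "akg_c + gaba_c -> glu__L_c + sucsal_c", "gabT", S),
    list("SSALy", "succinate-semialdehyde dehydrogenase (NADP)",
         "h2o_c + nadp_c + sucsal_c -> 2 h_c + nadph_c + succ_c",
         "gabD", S),

    list("NADTRHD", "NAD(P) transhydrogenase (energy-independent)",
         "nad_c + nadph_c -> nadh_c + nadp_c", "sthA", O),
    list("NADH16", "NADH dehydrogenase (proton-pumping, lumped)",
         "4 h_c + nadh_c + q8_c -> 3 h_e + nad_c + q8h2_c", "nuo", O),
    list("CYTBD", "cytochrome oxidase bd (proton-pumping, lumped)",
         "2 h_c + 0.5 o2_c + q8h2_c -> h2o_c + 2 h_e + q8_c",
         "cydA and cydB", O),
    list("ATPS4r", "ATP synthase (four protons per ATP)",
         "adp_c + 4 h_e + pi_c <-> atp_c + h2o_c + 3 h_c", "atp", O),
    list("ATPM", "ATP maintenance requirement",
         "atp_c + h2o_c -> adp_c + h_c + pi_c", "", O),

    list("SUCCt2", "succinate transport via proton symport",
         "h_e + succ_e -> h_c + succ_c", "dctA", X),
    list("ACt2r", "acetate reversible transport via proton symport",
         "ac_e + h_e <-> ac_c + h_c", "actP", X),
    list("GLUt2r", "L-glutamate reversible transport via proton symport",
         "glu__L_e + h_e <-> glu__L_c + h_c", "gltP", X),
    list("GABAt", "4-aminobutyrate efflux", "gaba_c -> gaba_e", "gadC", X),
    list("D_LACt2", "D-lactate reversible transport via proton symport",
         "h_e + lac__D_e <-> h_c + lac__D_c", "lldP", X),
    list("O2t", "oxygen diffusion", "o2_e <-> o2_c", "", X),
    list("CO2t", "carbon dioxide diffusion", "co2_e <-> co2_c", "", X),
    list("H2Ot", "water diffusion", "h2o_e <-> h2o_c", "", X),
    list("NH4t", "ammonium uptake", "nh4_e <-> nh4_c", "", X),
    list("PIt2r", "phosphate reversible transport via proton symport",
         "h_e + pi_e <-> h_c + pi_c", "", X),

    list("EX_glc__D_e", "D-glucose exchange", "glc__D_e ->", "", E,
         -10, 1000),
    list("EX_succ_e", "succinate exchange", "succ_e ->", "", E, -10, 1000),
    list("EX_gaba_e", "4-aminobutyrate exchange", "gaba_e ->", "", E,
         0, 1000),
    list("EX_glu__L_e", "L-glutamate exchange", "glu__L_e ->", "", E,
         0, 1000),
    list("EX_ac_e", "acetate exchange", "ac_e ->", "", E, 0, 1000),
    list("EX_lac__D_e", "D-lactate exchange", "lac__D_e ->", "", E,
         0, 1000),
    list("EX_o2_e", "oxygen exchange", "o2_e ->", "", E, -1000, 1000),
    list("EX_co2_e", "carbon dioxide exchange", "co2_e ->", "", E,
         -1000, 1000),
    list("EX_h2o_e", "water exchange", "h2o_e ->", "", E, -1000, 1000),
    list("EX_h_e", "proton exchange", "h_e ->", "", E, -1000, 1000),
    list("EX_nh4_e", "ammonium exchange", "nh4_e ->", "", E, -1000, 1000),
    list("EX_pi_e", "phosphate exchange", "pi_e ->", "", E, -1000, 1000),

    ## Lumped biomass: carbon-light relative to a genome-scale biomass
    ## equation (the strain secretes most of its carbon as glutamate and
    ## overflow products); the succinyl-CoA term stands for the
    ## succinylated intermediates of lysine/diaminopimelate synthesis.
    list("BIOMASS",
         "biomass (lumped precursor drain, flux = growth rate h-1)",
         paste("0.5 g6p_c + 0.5 pyr_c + 0.3 accoa_c + 0.3 glu__L_c",
               "+ 0.2 oaa_c + 0.2 r5p_c + 0.1 e4p_c + 0.1 succoa_c",
               "+ 6 nadph_c + 15 atp_c + 15 h2o_c -> 0.4 coa_c + 6 nadp_c",
               "+ 15 adp_c + 15 pi_c + 15 h_c"),
         "", "Biomass", 0, 1000)
  )
}

## "a_c + 2 b_c -> c_c" -> named coefficient vector
parse_reaction_equation <- function(eq) {
  sides <- strsplit(eq, "<->|->")[[1]]
  rev <- grepl("<->", eq)
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric())
    terms <- trimws(strsplit(s, "\\+")[[1]])
    coef <- rep(1, length(terms))
    has_num <- grepl("^[0-9.]+[[:space:]]+", terms)
    coef[has_num] <- as.numeric(sub("^([0-9.]+)[[:space:]].*$", "\\1",
                                    terms[has_num]))
    ids <- sub("^[0-9.]+[[:space:]]+", "", terms)
    stats::setNames(sign * coef, ids)
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- if (length(sides) > 1) parse_side(sides[2], 1) else numeric()
  st <- c(lhs, rhs)
  st <- tapply(st, names(st), sum)
  list(stoich = stats::setNames(as.numeric(st), names(st)),
       reversible = rev)
}

## assemble the full toy model (internal; users go through build_toy_core)
toy_core_model <- function() {
  tab <- toy_reaction_table()
  rows <- list(); stoich <- list()
  for (r in tab) {
    id <- r[[1]]; name <- r[[2]]; eq <- r[[3]]; gpr <- r[[4]]
    sub <- r[[5]]
    pe <- parse_reaction_equation(eq)
    if (length(r) >= 7) { lb <- r[[6]]; ub <- r[[7]] }
    else if (pe$reversible) { lb <- -1000; ub <- 1000 }
    else { lb <- 0; ub <- 1000 }
    rows[[id]] <- data.frame(id = id, name = name, lower_bound = lb,
                             upper_bound = ub, gpr = gpr, subsystem = sub,
                             stringsAsFactors = FALSE)
    stoich[[id]] <- pe$stoich
  }
  rxns <- do.call(rbind, rows)
  met_ids <- sort(unique(unlist(lapply(stoich, names))))
  base <- sub("_[ce]$", "", met_ids)
  comp <- sub("^.*_([ce])$", "\\1", met_ids)
  mets <- data.frame(
    id = met_ids,
    name = unname(toy_metabolite_names[base]),
    compartment = comp,
    formula = unname(toy_metabolite_formulas[base]),
    stringsAsFactors = FALSE)
  metabolic_model(id = "toy_core", metabolites = mets, reactions = rxns,
                  stoichiometry = stoich, objective = "BIOMASS")
}
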