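# Controlled vocabularies: PK parameters, tissue transporters, probe drugs,
# and the bundled drug dictionary. All lookup is case-insensitive; canonical
# drug names are stored lowercase.

pk_param <- function(symbol, description, unit = NA_character_,
                     setting = "in_vivo", synonyms = character(),
                     priority_rank = NA_integer_) {
  tibble::tibble(
    symbol = symbol, description = description, unit = unit,
    setting = setting, synonyms = list(synonyms),
    priority_rank = as.integer(priority_rank)
  )
}

#' Pharmacokinetic parameter definitions
#'
#' The built-in ontology of in vitro and in vivo PK parameters: symbol,
#' description, unit, experimental setting, surface-form synonyms used by the
#' tagger, and the priority rank used when several parameters report on the
#' same drug pair. Ranked parameters are AUC > CL > t1/2 > Cmax (in vivo) and
#' Ki > IC50 (in vitro).
#'
#' @return A tibble with columns `symbol`, `description`, `unit`, `setting`
#'   (`"in_vitro"`, `"in_vivo"` or `"both"`), `synonyms` (list column) and
#'   `priority_rank` (integer, `NA` for unranked parameters).
#' @export
#' @examples
#' pk_parameters() %>% dplyr::filter(!is.na(priority_rank))
pk_parameters <- function() {
  dplyr::bind_rows(
    # in vitro: single drug metabolism
    pk_param("Km", "Michaelis-Menten constant.", "mg L^-1", "both",
             c("Michaelis-Menten constant", "K(m)")),
    pk_param("Vmax", "Maximum velocity of the enzyme activity.",
             "mg h^-1 mg^-1 protein", "both",
             c("maximum velocity", "V(max)")),
    pk_param("CLint", "Intrinsic metabolic clearance (Vmax/Km).",
             "ml h^-1 mg^-1 protein", "both",
             c("intrinsic clearance", "CL(int)")),
    pk_param("MR", "Parent drug/metabolite concentration ratio.", NA, "both",
             c("metabolic ratio", "urinary ratio", "metabolite ratio")),
    pk_param("fm_enzyme",
             "Fraction of available drug converted to a metabolite through a specific enzyme.",
             NA, "in_vitro", c("fraction of metabolism")),
    # in vitro: transporter
    pk_param("Papp", "The apparent permeability of compounds across the monolayer cells.",
             "cm/sec", "in_vitro", c("apparent permeability", "P(app)")),
    pk_param("Re", "Ratio of basolateral-to-apical over apical-to-basolateral permeability.",
             NA, "in_vitro", character()),
    pk_param("radioactivity", "Total radioactivity in plasma and bile samples.",
             "dpm/mg protein", "in_vitro", character()),
    pk_param("uptake volume",
             "Cell-associated radioactivity divided by its concentration in the incubation medium.",
             "ul/mg protein", "in_vitro", character()),
    # in vitro: drug interaction
    pk_param("IC50", "Inhibitor concentration that inhibits to 50% of enzyme activity.",
             "mg L^-1", "in_vitro", c("IC(50)", "IC 50"), 2L),
    pk_param("Ki", "Inhibition rate constant for competitive, noncompetitive and uncompetitive inhibition.",
             "mg L^-1", "in_vitro", c("K(i)", "inhibition constant"), 1L),
    pk_param("Kdeg", "The natural degradation rate constant for the enzyme.",
             "h^-1", "in_vitro", c("K(deg)")),
    pk_param("KI_mbi", "Inhibitor concentration at half-maximal inactivation (mechanism based inhibition).",
             "mg L^-1", "in_vitro", c("K(I)")),
    pk_param("Kinact", "Maximum degradation rate constant at saturating inhibitor (mechanism based inhibition).",
             "h^-1", "in_vitro", c("K(inact)")),
    pk_param("Emax", "Maximum induction rate.", NA, "in_vitro", c("E(max)")),
    pk_param("EC50", "Inducer concentration associated with half-maximal induction.",
             "mg L^-1", "in_vitro", c("EC(50)")),
    # in vivo
    pk_param("AUC", "Area under the drug concentration time curve.", "mg h L^-1",
             "in_vivo",
             c("area under the concentration curve",
               "area under the drug concentration time curve",
               "area under the plasma concentration-time curve",
               "area under the concentration-time curve"), 1L),
    pk_param("AUCinf", "Area under the concentration curve extrapolated to infinity.",
             "mg h L^-1", "in_vivo", c("AUC(inf)")),
    pk_param("AUCss", "Area under the concentration curve within a dosing interval at steady state.",
             "mg h L^-1", "in_vivo", c("AUC(ss)")),
    pk_param("AUCt", "Area under the concentration curve from time 0 to t.",
             "mg h L^-1", "in_vivo", c("AUC(t)")),
    pk_param("AUMC", "Area under the first moment of concentration versus time curve.",
             "mg^2 h L^-2", "in_vivo", character()),
    pk_param("AUCR", "AUC ratio (drug interaction parameter).", NA, "in_vivo",
             c("AUC ratio", "area under the concentration curve ratio")),
    pk_param("CL", "Total clearance.", "ml h^-1", "in_vivo",
             c("clearance", "total clearance", "oral clearance"), 2L),
    pk_param("CLb", "Blood clearance.", "ml h^-1", "in_vivo", c("blood clearance")),
    pk_param("CLu", "Unbound clearance.", "ml h^-1", "in_vivo", c("unbound clearance")),
    pk_param("CLH", "Hepatic portion of the total clearance.", "ml h^-1", "in_vivo",
             c("hepatic clearance", "CL(H)")),
    pk_param("CLR", "Renal portion of the total clearance.", "ml h^-1", "in_vivo",
             c("renal clearance", "CL(R)")),
    pk_param("CLpo", "Total clearance following an oral dose.", "ml h^-1", "in_vivo",
             c("CL(po)", "CLoral")),
    pk_param("CLIV", "Total clearance following an IV dose.", "ml h^-1", "in_vivo",
             c("CL(IV)")),
    pk_param("CL12", "Inter-compartment distribution clearance.", "ml h^-1", "in_vivo",
             c("CL(12)")),
    pk_param("CL ratio", "Ratio of the clearance (drug interaction parameter).",
             NA, "in_vivo", c("clearance ratio")),
    pk_param("Cmax", "Highest drug concentration observed in plasma.", "mg L^-1",
             "in_vivo", c("C(max)", "peak plasma concentration", "peak concentration"),
             4L),
    pk_param("Cmax ratio", "The ratio of Cmax (drug interaction parameter).", NA,
             "in_vivo", c("C(max) ratio")),
    pk_param("Css", "Plasma concentration at steady state.", "mg L^-1", "in_vivo",
             c("C(ss)", "steady state concentration", "steady-state concentration")),
    pk_param("Css ratio", "The ratio of Css (drug interaction parameter).", NA,
             "in_vivo", c("C(ss) ratio")),
    pk_param("E", "Extraction ratio.", NA, "in_vivo", c("extraction ratio")),
    pk_param("EH", "Hepatic extraction ratio.", NA, "in_vivo",
             c("hepatic extraction ratio", "E(H)")),
    pk_param("F", "Bioavailability.", NA, "in_vivo", c("bioavailability")),
    pk_param("FG", "Gut-wall bioavailability.", NA, "in_vivo", c("F(G)")),
    pk_param("FH", "Hepatic bioavailability.", NA, "in_vivo", c("F(H)")),
    pk_param("FR", "Renal bioavailability.", NA, "in_vivo", c("F(R)")),
    pk_param("fe", "Fraction of available drug excreted unchanged in urine.", NA,
             "in_vivo", character()),
    pk_param("fm", "Fraction of available drug converted to a metabolite.", NA,
             "in_vivo", character()),
    pk_param("fu", "Ratio of unbound and total drug concentrations in plasma.", NA,
             "in_vivo", character()),
    pk_param("k", "Elimination rate constant.", "h^-1", "in_vivo",
             c("elimination rate constant")),
    pk_param("k12", "Central-to-peripheral distribution rate constant.", "h^-1",
             "in_vivo", c("k(12)")),
    pk_param("k21", "Peripheral-to-central distribution rate constant.", "h^-1",
             "in_vivo", c("k(21)")),
    pk_param("ka", "Absorption rate constant.", "h^-1", "in_vivo",
             c("absorption rate constant", "k(a)")),
    pk_param("ke", "Urinary excretion rate constant.", "h^-1", "in_vivo",
             c("k(e)")),
    pk_param("km_met", "Rate constant for the elimination of a metabolite.", "h^-1",
             "in_vivo", character()),
    pk_param("MRT", "Mean time a molecule resides in the body.", "h", "in_vivo",
             c("mean residence time")),
    pk_param("Q", "Blood flow.", "L h^-1", "in_vivo", c("blood flow")),
    pk_param("QH", "Hepatic blood flow.", "L h^-1", "in_vivo",
             c("hepatic blood flow", "Q(H)")),
    pk_param("tmax", "Time of the highest observed plasma concentration.", "h",
             "in_vivo", c("t(max)", "T(max)")),
    pk_param("t1/2", "Half-life of the drug disposition.", "h", "in_vivo",
             c("half-life", "half life", "t(1/2)", "t1/2", "t ½",
               "t½", "elimination half-life", "terminal half-life"), 3L),
    pk_param("t1/2 ratio", "Half-life ratio (drug interaction parameter).", NA,
             "in_vivo", c("half-life ratio")),
    pk_param("t1/2,alpha", "Half-life of the fast disposition phase.", "h",
             "in_vivo", character()),
    pk_param("t1/2,beta", "Half-life of the slow disposition phase.", "h",
             "in_vivo", character()),
    pk_param("V", "Volume of distribution (plasma).", "L", "in_vivo",
             c("volume of distribution")),
    pk_param("Vb", "Volume of distribution (blood).", "L", "in_vivo", c("V(b)")),
    pk_param("V1", "Volume of distribution of the central compartment.", "L",
             "in_vivo", c("V(1)")),
    pk_param("V2", "Volume of distribution of the peripheral compartment.", "L",
             "in_vivo", c("V(2)")),
    pk_param("Vss", "Volume of distribution at steady state.", "L", "in_vivo",
             c("V(ss)")),
    pk_param("lambda1", "Fast disposition rate constant (two-compartment model).",
             "h^-1", "in_vivo", character()),
    pk_param("lambda2", "Slow disposition rate constant (two-compartment model).",
             "h^-1", "in_vivo", character())
  )
}

#' Tissue-specific transporter records
#'
#' @return A tibble with columns `gene`, `aliases` (list column), `tissues`
#'   (list column) and `function_` (`"uptake"` or `"efflux"`).
#' @export
pk_transporters <- function() {
  tibble::tibble(
    gene = c("ABCB1", "ABCG2", "SLCO1B1", "SLCO1B3", "SLC22A2", "SLC22A6",
             "SLC22A8"),
    aliases = list(
      c("P-gp", "MDR1"),
      c("BCRP"),
      c("OATP1B1", "OATP-C", "OATP2", "LST-1"),
      c("OATP1B3", "OATP-8"),
      c("OCT2"),
      c("OAT1"),
      c("OAT3")
    ),
    tissues = list(
      c("intestinal enterocyte", "kidney proximal tubule",
        "hepatocyte (canalicular)", "brain endothelia"),
      c("intestinal enterocyte", "hepatocyte (canalicular)",
        "kidney proximal tubule", "brain endothelia", "placenta", "stem cells",
        "mammary gland (lactating)"),
      c("hepatocyte (sinusoidal)"),
      c("hepatocyte (sinusoidal)"),
      c("kidney proximal tubule"),
      c("kidney proximal tubule", "placenta"),
      c("kidney proximal tubule", "choroid plexus", "brain endothelia")
    ),
    function_ = c("efflux", "efflux", "uptake", "uptake", "uptake", "uptake",
                  "uptake")
  )
}

probe_block <- function(enzyme, role, drugs) {
  tibble::tibble(enzyme = enzyme, role = role, drug = tolower(drugs))
}

#' Probe inhibitor/inducer/substrate assignments
#'
#' Probe-drug assignments for the major CYP450 enzymes and selected
#' transporters. A probe substrate is predominantly handled by one enzyme and
#' is used to isolate that enzyme's activity; probe inhibitors and inducers
#' act predominantly on one enzyme.
#'
#' @return A tibble with columns `enzyme`, `role` (`"inhibitor"`, `"inducer"`
#'   or `"substrate"`) and `drug` (lowercase canonical name).
#' @export
pk_probe_roles <- function() {
  dplyr::bind_rows(
    probe_block("CYP1A2", "inhibitor", c(
      "ciprofloxacin", "enoxacin", "fluvoxamine", "methoxsalen", "mexiletine",
      "oral contraceptives", "phenylpropanolamine", "thiabendazole",
      "vemurafenib", "zileuton", "acyclovir", "allopurinol", "caffeine",
      "cimetidine", "daidzein", "disulfiram", "echinacea", "famotidine",
      "norfloxacin", "propafenone", "propranolol", "terbinafine",
      "ticlopidine", "verapamil")),
    probe_block("CYP1A2", "inducer", c(
      "montelukast", "phenytoin", "smokers versus non-smokers", "moricizine",
      "omeprazole", "phenobarbital")),
    probe_block("CYP1A2", "substrate", c(
      "alosetron", "caffeine", "duloxetine", "melatonin", "ramelteon",
      "tacrine", "tizanidine", "theophylline")),
    probe_block("CYP2B6", "inhibitor", c(
      "clopidogrel", "ticlopidine", "prasugrel")),
    probe_block("CYP2B6", "inducer", c("efavirenz", "rifampin", "nevirapine")),
    probe_block("CYP2B6", "substrate", c("bupropion", "efavirenz")),
    probe_block("CYP2C8", "inhibitor", c(
      "gemfibrozil", "fluvoxamine", "ketoconazole", "trimethoprim")),
    probe_block("CYP2C8", "inducer", "rifampin"),
    probe_block("CYP2C8", "substrate", c("repaglinide", "paclitaxel")),
    probe_block("CYP2C9", "inhibitor", c(
      "amiodarone", "fluconazole", "miconazole", "oxandrolone", "capecitabine",
      "cotrimoxazole", "etravirine", "fluvastatin", "fluvoxamine",
      "metronidazole", "sulfinpyrazone", "tigecycline", "voriconazole",
      "zafirlukast")),
    probe_block("CYP2C9", "inducer", c(
      "carbamazepine", "rifampin", "aprepitant", "bosentan", "phenobarbital",
      "st john's wort")),
    probe_block("CYP2C9", "substrate", c("celecoxib", "warfarin", "phenytoin")),
    probe_block("CYP2C19", "inhibitor", c(
      "fluconazole", "fluvoxamine", "ticlopidine", "esomeprazole",
      "fluoxetine", "moclobemide", "omeprazole", "voriconazole", "allicin",
      "armodafinil", "carbamazepine", "cimetidine", "etravirine",
      "human growth hormone", "felbamate", "ketoconazole",
      "oral contraceptives")),
    probe_block("CYP2C19", "inducer", c("rifampin", "artemisinin")),
    probe_block("CYP2C19", "substrate", c(
      "clobazam", "lansoprazole", "omeprazole", "s-mephenytoin")),
    probe_block("CYP3A", "inhibitor", c(
      "boceprevir", "clarithromycin", "conivaptan", "grapefruit juice",
      "indinavir", "itraconazole", "ketoconazole", "lopinavir/ritonavir",
      "mibefradil", "nefazodone", "nelfinavir", "posaconazole", "ritonavir",
      "saquinavir", "telaprevir", "telithromycin", "voriconazole",
      "amprenavir", "aprepitant", "atazanavir", "ciprofloxacin", "crizotinib",
      "darunavir/ritonavir", "diltiazem", "erythromycin", "fluconazole",
      "fosamprenavir", "imatinib", "verapamil", "alprazolam", "amiodarone",
      "amlodipine", "atorvastatin", "bicalutamide", "cilostazol", "cimetidine",
      "cyclosporine", "fluoxetine", "fluvoxamine", "ginkgo", "goldenseal",
      "isoniazid", "lapatinib", "nilotinib", "oral contraceptives",
      "pazopanib", "ranitidine", "ranolazine", "tipranavir/ritonavir",
      "ticagrelor", "zileuton")),
    probe_block("CYP3A", "inducer", c(
      "avasimibe", "carbamazepine", "phenytoin", "rifampin", "st john's wort",
      "bosentan", "efavirenz", "etravirine", "modafinil", "nafcillin",
      "amprenavir", "aprepitant", "armodafinil", "clobazam", "echinacea",
      "pioglitazone", "prednisone", "rufinamide", "vemurafenib")),
    probe_block("CYP3A", "substrate", c(
      "alfentanil", "aprepitant", "budesonide", "buspirone", "conivaptan",
      "darifenacin", "darunavir", "dasatinib", "dronedarone", "eletriptan",
      "eplerenone", "everolimus", "felodipine", "indinavir", "fluticasone",
      "lopinavir", "lovastatin", "lurasidone", "maraviroc", "midazolam",
      "nisoldipine", "quetiapine", "saquinavir", "sildenafil", "simvastatin",
      "sirolimus", "tolvaptan", "tipranavir", "triazolam", "ticagrelor",
      "vardenafil", "astemizole", "cisapride", "cyclosporine",
      "dihydroergotamine", "ergotamine", "fentanyl", "pimozide", "quinidine",
      "tacrolimus", "terfenadine")),
    probe_block("CYP2D6", "inhibitor", c(
      "bupropion", "fluoxetine", "paroxetine", "quinidine", "cinacalcet",
      "duloxetine", "terbinafine", "amiodarone", "celecoxib", "clobazam",
      "cimetidine", "desvenlafaxine", "diltiazem", "diphenhydramine",
      "echinacea", "escitalopram", "febuxostat", "gefitinib", "hydralazine",
      "hydroxychloroquine", "imatinib", "methadone", "oral contraceptives",
      "pazopanib", "propafenone", "ranitidine", "ritonavir", "sertraline",
      "telithromycin", "verapamil", "vemurafenib")),
    probe_block("CYP2D6", "substrate", c(
      "atomoxetine", "desipramine", "dextromethorphan", "metoprolol",
      "nebivolol", "perphenazine", "tolterodine", "venlafaxine",
      "thioridazine", "pimozide")),
    # transporters (Table of probe drugs for selected transporters)
    probe_block("P-gp", "inhibitor", c(
      "amiodarone", "azithromycin", "captopril", "carvedilol",
      "clarithromycin", "conivaptan", "cyclosporine", "diltiazem",
      "dronedarone", "erythromycin", "felodipine", "itraconazole",
      "ketoconazole", "lopinavir", "ritonavir", "quercetin", "quinidine",
      "ranolazine", "ticagrelor", "verapamil")),
    probe_block("P-gp", "inducer", c(
      "avasimibe", "carbamazepine", "phenytoin", "rifampin", "st john's wort",
      "tipranavir/ritonavir")),
    probe_block("P-gp", "substrate", c(
      "aliskiren", "ambrisentan", "colchicine", "dabigatran etexilate",
      "digoxin", "everolimus", "fexofenadine", "imatinib", "lapatinib",
      "maraviroc", "nilotinib", "posaconazole", "ranolazine", "saxagliptin",
      "sirolimus", "sitagliptin", "talinolol", "tolvaptan", "topotecan")),
    probe_block("BCRP", "inhibitor", c(
      "cyclosporine", "elacridar", "eltrombopag", "gefitinib")),
    probe_block("BCRP", "substrate", c(
      "methotrexate", "mitoxantrone", "imatinib", "irinotecan", "lapatinib",
      "rosuvastatin", "sulfasalazine", "topotecan")),
    probe_block("OATP1B1", "inhibitor", c(
      "atazanavir", "cyclosporine", "eltrombopag", "gemfibrozil", "lopinavir",
      "rifampin", "ritonavir", "saquinavir", "tipranavir")),
    probe_block("OATP1B1", "substrate", c(
      "atrasentan", "atorvastatin", "bosentan", "ezetimibe", "fluvastatin",
      "glyburide", "sn-38", "rosuvastatin", "simvastatin acid", "pitavastatin",
      "pravastatin", "repaglinide", "rifampin", "valsartan", "olmesartan")),
    probe_block("OATP1B3", "inhibitor", c(
      "atazanavir", "cyclosporine", "lopinavir", "rifampin", "ritonavir",
      "saquinavir")),
    probe_block("OATP1B3", "substrate", c(
      "atorvastatin", "rosuvastatin", "pitavastatin", "telmisartan",
      "valsartan", "olmesartan")),
    probe_block("OCT2", "inhibitor", c("cimetidine", "quinidine")),
    probe_block("OCT2", "substrate", c(
      "amantadine", "amiloride", "cimetidine", "dopamine", "famotidine",
      "memantine", "metformin", "pindolol", "procainamide", "ranitidine",
      "varenicline", "oxaliplatin")),
    probe_block("OAT1", "inhibitor", "probenecid"),
    probe_block("OAT1", "substrate", c(
      "adefovir", "captopril", "furosemide", "lamivudine", "methotrexate",
      "oseltamivir", "tenofovir", "zalcitabine", "zidovudine")),
    probe_block("OAT3", "inhibitor", c("probenecid", "cimetidine", "diclofenac")),
    probe_block("OAT3", "substrate", c(
      "acyclovir", "bumetanide", "ciprofloxacin", "famotidine", "furosemide",
      "methotrexate", "zidovudine", "oseltamivir acid", "penicillin g",
      "pravastatin", "rosuvastatin", "sitagliptin"))
  ) %>% dplyr::distinct()
}

# Extra drugs that appear in the worked classification examples but not in the
# probe tables.
example_drugs <- function() {
  c("mitoxantrone", "etoposide", "valspodar", "st john's wort", "perazine",
    "ym758", "dpt", "norfloxacin", "tamoxifen", "placebo")
}

#' Built-in lexicon bundle
#'
#' Bundles the PK parameter ontology, transporter records, probe-role
#' assignments and a drug dictionary. The drug dictionary holds every probe
#' drug plus the drugs named in the worked classification examples; a full
#' dictionary (e.g. DrugBank) can be loaded with [load_drug_lexicon()] and
#' merged.
#'
#' @return An object of class `pk_lexicon`: a list with tibbles `parameters`,
#'   `transporters`, `probes` and `drugs`.
#' @export
#' @examples
#' lex <- pk_lexicon()
#' probe_roles("rifampin", lex)
pk_lexicon <- function() {
  probes <- pk_probe_roles()
  canon <- sort(unique(c(probes$drug, example_drugs())))
  drugs <- tibble::tibble(
    canonical = canon,
    surface_forms = purrr::map(canon, identity),
    is_metabolite = FALSE,
    parent = NA_character_
  )
  structure(
    list(parameters = pk_parameters(), transporters = pk_transporters(),
         probes = probes, drugs = drugs),
    class = "pk_lexicon"
  )
}

#' @export
print.pk_lexicon <- function(x, ...) {
  cat("<pk_lexicon>\n")
  cat("  parameters:   ", nrow(x$parameters), "\n")
  cat("  transporters: ", nrow(x$transporters), "\n")
  cat("  probe roles:  ", nrow(x$probes), "\n")
  cat("  drugs:        ", nrow(x$drugs), "\n")
  invisible(x)
}

#' Look up probe roles of a drug
#'
#' @param drug Drug name (any case).
#' @param lexicon A `pk_lexicon`, by default the built-in bundle.
#' @return A tibble of `enzyme`/`role`/`drug` rows; zero rows when the drug
#'   has no probe role.
#' @export
probe_roles <- function(drug, lexicon = pk_lexicon()) {
  dplyr::filter(lexicon$probes, .data$drug == tolower(.env$drug))
}

#' Read a drug lexicon from pipe-delimited text
#'
#' One entry per line, `canonical|form1|form2|...`; lines starting with `#`
#' are comments. Surface forms are lowercased and de-duplicated within an
#' entry; the canonical name is always a surface form.
#'
#' @param path Path to a UTF-8 text file.
#' @return A tibble with columns `canonical`, `surface_forms` (list column),
#'   `is_metabolite`, `parent`. Surface forms shared by several entries are
#'   recorded in the `"duplicate_forms"` attribute and raised as a warning.
#' @export
load_drug_lexicon <- function(path) {
  if (!file.exists(path)) abort(paste0("lexicon file not found: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  entries <- purrr::map(keep, function(i) {
    fields <- trimws(strsplit(lines[[i]], "|", fixed = TRUE)[[1]])
    fields <- fields[nzchar(fields)]
    if (length(fields) < 1) {
      abort(paste0("malformed lexicon row at line ", i, ": ", lines[[i]]))
    }
    tibble::tibble(
      canonical = tolower(fields[[1]]),
      surface_forms = list(unique(tolower(fields))),
      is_metabolite = FALSE,
      parent = NA_character_
    )
  })
  out <- if (length(entries)) dplyr::bind_rows(entries) else
    tibble::tibble(canonical = character(), surface_forms = list(),
                   is_metabolite = logical(), parent = character())
  all_forms <- unlist(out$surface_forms)
  dup <- sort(unique(all_forms[duplicated(all_forms)]))
  if (length(dup)) {
    warn(paste0("duplicate surface forms across entries: ",
                paste(dup, collapse = ", ")))
  }
  attr(out, "duplicate_forms") <- dup
  out
}

#' Write a drug lexicon to pipe-delimited text
#'
#' @param drugs A drug tibble as returned by [load_drug_lexicon()] or found in
#'   `pk_lexicon()$drugs`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_drug_lexicon <- function(drugs, path) {
  lines <- purrr::map2_chr(drugs$canonical, drugs$surface_forms, function(c, f) {
    paste(unique(c(c, f)), collapse = "|")
  })
  writeLines(c("# pkddi drug lexicon: canonical|form1|form2|...", lines),
             path, useBytes = TRUE)
  invisible(path)
}
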