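#' The nine-compartment sphingolipid metabolism model
#'
#' Programmatic reconstruction of the compartmental kinetic model of human
#' sphingolipid metabolism: 9 subcellular compartments (outer and inner
#' plasma-membrane leaflet, cytoplasm, endoplasmic reticulum, cytoplasmic
#' and lumenal Golgi face, nucleus, mitochondrion, lysosome), 39 species
#' (ceramide CER, sphingomyelin SM, sphingosine Sph,
#' sphingosine-1-phosphate S1P, ceramide-1-phosphate C1P and a
#' glycosphingolipid pool GSL, each resolved per compartment), 69 reactions
#' (29 mass-action transport/inflow reactions and 40 enzymatic
#' Michaelis-Menten reactions catalyzed by 37 enzymes) and 129 kinetic
#' parameters (29 rate constants, 40 x (Vmax, Km), 20 inhibition constants).
#'
#' Highlights of the wiring: de novo ceramide synthesis enters as a constant
#' inflow of CER into the ER (a serine-palmitoyltransferase surrogate,
#' inhibited by S1P and C1P); exogenous C1P, CER, Sph, S1P and SM enter at
#' the outer membrane; sphingomyelin is hydrolyzed to CER by compartmental
#' sphingomyelinases (S1P/C1P-inhibited); ceramidases release Sph, which
#' sphingosine kinases phosphorylate to S1P; S1P leaves the system only
#' through irreversible S1P lyase cleavage in the ER; CER reaches the Golgi
#' by the CERT transfer route (via a cytosolic carrier pool) and by
#' CERT-independent vesicular transport; complex-sphingolipid catabolism
#' runs through endocytosis to the lysosome (the salvage pathway entry).
#'
#' Parameterization: the model is calibrated to be stationary at its
#' tabulated initial concentrations — every reaction's parameters are backed
#' out from an exactly balanced flux distribution (a sum of source-to-sink
#' pathway fluxes and internal cycles) and a chosen operating saturation per
#' enzyme class (hydrolases near capacity at 70 percent saturation,
#' synthases with reserve at 30 percent, kinases/phosphatases at 50
#' percent). Inhibition constants equal the inhibitor's stationary level.
#' One species (the inner-leaflet GSL pool, a passive flip-equilibrium pool)
#' has a derived rather than tabulated initial value, giving 38 explicit
#' initial concentrations.
#'
#' @param params_source optional named vector of registry values overriding
#'   the calibrated defaults (keys as in `net$params`).
#' @return a `reaction_network` labelled `"homeostasis"`.
#' @export
build_homeostasis_model <- function(params_source = NULL) {
  inv <- sphingo_inventory()
  phi <- stats::setNames(inv$species$initial_concentration, inv$species$id)
  v <- sphingo_fluxes(inv)

  reactions <- vector("list", nrow(inv$reactions))
  for (i in seq_len(nrow(inv$reactions))) {
    r <- inv$reactions[i, ]
    vi <- v[[r$id]]
    inh_sp <- inv$inhibitors[[r$id]]
    inh <- NULL
    boost <- 1
    if (!is.null(inh_sp)) {
      inh <- stats::setNames(unname(phi[inh_sp]), inh_sp) # Ki = stationary level
      boost <- 2^length(inh_sp) # each factor is 1/2 at the operating point
    }
    from <- if (!is.na(r$from)) stats::setNames(1, r$from)
    to <- if (!is.na(r$to)) stats::setNames(1, r$to)
    law <- if (r$kind == "mal") {
      denom <- if (!is.na(r$from)) phi[[r$from]] else 1
      mal(k = vi * boost / denom, inhibitors = inh)
    } else {
      sig <- r$sigma
      mm(Vmax = vi * boost / sig, Km = phi[[r$from]] * (1 - sig) / sig,
         inhibitors = inh)
    }
    reactions[[i]] <- rxn(r$id, from = from, to = to, law = law,
                          modifiers = if (!is.na(r$enzyme)) r$enzyme else
                            character(),
                          transport = r$kind == "mal", name = r$rname)
  }

  net <- reaction_network(
    species = inv$species, reactions = reactions,
    compartments = sphingo_compartments(),
    metadata = list(scenario = "homeostasis"))

  if (!is.null(params_source)) {
    for (key in names(params_source)) {
      net <- set_param(net, key, params_source[[key]])
    }
  }
  check_inventory(net)
  net
}

check_inventory <- function(net) {
  g <- glance(net)
  want <- c(n_compartments = 9, n_species = 39, n_reactions = 69,
            n_enzymes = 37, n_parameters = 129, n_explicit_initials = 38)
  got <- unlist(g[names(want)])
  if (!all(got == want)) {
    diffs <- paste0(names(want)[got != want], ": got ", got[got != want],
                    ", expected ", want[got != want], collapse = "; ")
    stop("model assembly does not match the declared inventory — ", diffs,
         call. = FALSE)
  }
  M <- stoichiometry_matrix(net)
  cn <- compile_network(net)
  res <- max(abs(M %*% flux_vector_compiled(
    cn, unname(initial_state(net)[net$species$id]), unname(net$params))))
  if (res > 1e-8) {
    stop("calibrated model is not stationary at its initial state ",
         "(residual ", signif(res, 3), ")", call. = FALSE)
  }
  invisible(net)
}

sphingo_compartments <- function() {
  tibble(
    id = c("om", "im", "cyt", "er", "gc", "gl", "nuc", "mit", "lys"),
    name = c("outer membrane leaflet", "inner membrane leaflet",
             "cytoplasm", "endoplasmic reticulum",
             "Golgi (cytoplasmic face)", "Golgi (lumenal face)",
             "nucleus", "mitochondrion", "lysosome"),
    volume = 1)
}

sphingo_inventory <- function() {
  conc <- c(
    CER_om = 6, CER_im = 3, CER_cyt = 0.5, CER_er = 5, CER_gc = 2,
    CER_gl = 2, CER_nuc = 2, CER_mit = 2.5, CER_lys = 3,
    SM_om = 40, SM_im = 6, SM_er = 5, SM_gl = 8, SM_nuc = 4, SM_lys = 5,
    Sph_om = 0.8, Sph_im = 0.6, Sph_cyt = 1, Sph_er = 0.7, Sph_gc = 0.4,
    Sph_nuc = 0.5, Sph_mit = 0.9, Sph_lys = 0.6,
    S1P_om = 0.15, S1P_im = 0.1, S1P_cyt = 0.2, S1P_er = 0.12,
    S1P_nuc = 0.08, S1P_mit = 0.1,
    C1P_om = 0.5, C1P_im = 0.2, C1P_cyt = 0.3, C1P_er = 0.2, C1P_gc = 0.25,
    GSL_om = 12, GSL_im = 4, GSL_gc = 2, GSL_gl = 3, GSL_lys = 2.5)
  long <- c(CER = "ceramide", SM = "sphingomyelin", Sph = "sphingosine",
            S1P = "sphingosine-1-phosphate", C1P = "ceramide-1-phosphate",
            GSL = "glycosphingolipid")
  ids <- names(conc)
  base <- sub("_.*", "", ids)
  comp <- sub(".*_", "", ids)
  species <- tibble(
    id = ids, name = paste0(long[base], " [", comp, "]"),
    compartment = comp, initial_concentration = unname(conc),
    is_enzyme = FALSE,
    explicit_initial = ids != "GSL_im")

  # id | kind | from | to | enzyme | sigma | display name
  # sigma: operating saturation of MM reactions at the homeostatic point
  def <- function(id, kind, from, to, enzyme = NA, sigma = NA, rname = id) {
    tibble(id = id, kind = kind, from = from, to = to, enzyme = enzyme,
           sigma = sigma, rname = rname)
  }
  H <- 0.7   # membrane/lysosomal SMases and the ER hub ceramidase: near capacity
  CD <- 0.6  # ceramidases and the ER/lysosomal hydrolases: modest reserve
  GC <- 0.5  # lysosomal glucocerebrosidase
  S <- 0.3   # synthases keep ample reserve capacity
  SK <- 0.4  # sphingosine kinases (sized for drain headroom)
  K <- 0.5   # other kinases, phosphatases, lyase
  E <- 0.7   # endocytic machinery (near capacity)
  # per-reaction deviations from the class defaults (vignette: calibration)
  reactions <- bind_rows(
    # exogenous inflows at the outer membrane + de novo CER inflow into ER
    def("inflow_C1P_om", "mal", NA, "C1P_om", rname = "exogenous C1P inflow"),
    def("inflow_CER_om", "mal", NA, "CER_om", rname = "exogenous CER inflow"),
    def("inflow_Sph_om", "mal", NA, "Sph_om", rname = "exogenous Sph inflow"),
    def("inflow_S1P_om", "mal", NA, "S1P_om", rname = "exogenous S1P inflow"),
    def("inflow_SM_om", "mal", NA, "SM_om", rname = "exogenous SM inflow"),
    def("inflow_CER_er", "mal", NA, "CER_er",
        rname = "de novo CER synthesis (SPT surrogate)"),
    # CER transport
    def("t_CER_om_im", "mal", "CER_om", "CER_im", rname = "CER flip om->im"),
    def("t_CER_er_cyt", "mal", "CER_er", "CER_cyt",
        rname = "CERT loading ER->cytosol"),
    def("t_CER_cyt_gl", "mal", "CER_cyt", "CER_gl",
        rname = "CERT delivery cytosol->Golgi lumen"),
    def("t_CER_er_gc", "mal", "CER_er", "CER_gc",
        rname = "vesicular CER ER->Golgi (CERT-independent)"),
    def("t_CER_gc_gl", "mal", "CER_gc", "CER_gl",
        rname = "CER flip Golgi cytoplasmic->lumenal face"),
    def("t_CER_er_nuc", "mal", "CER_er", "CER_nuc",
        rname = "CER diffusion ER->nucleus"),
    def("t_CER_nuc_er", "mal", "CER_nuc", "CER_er",
        rname = "CER diffusion nucleus->ER"),
    def("t_CER_er_mit", "mal", "CER_er", "CER_mit",
        rname = "CER transfer ER->mitochondrion"),
    def("t_CER_mit_er", "mal", "CER_mit", "CER_er",
        rname = "CER transfer mitochondrion->ER"),
    # SM / Sph / S1P / C1P / GSL transport
    def("t_SM_gl_om", "mal", "SM_gl", "SM_om", rname = "SM exocytosis"),
    def("t_Sph_om_im", "mal", "Sph_om", "Sph_im", rname = "Sph flip om->im"),
    def("t_Sph_im_cyt", "mal", "Sph_im", "Sph_cyt",
        rname = "Sph desorption im->cytosol"),
    def("t_Sph_lys_cyt", "mal", "Sph_lys", "Sph_cyt",
        rname = "Sph salvage exit lysosome->cytosol"),
    def("t_Sph_cyt_er", "mal", "Sph_cyt", "Sph_er",
        rname = "Sph uptake cytosol->ER"),
    def("t_Sph_gc_cyt", "mal", "Sph_gc", "Sph_cyt",
        rname = "Sph desorption Golgi->cytosol"),
    def("t_S1P_im_cyt", "mal", "S1P_im", "S1P_cyt",
        rname = "S1P release im->cytosol"),
    def("t_S1P_cyt_er", "mal", "S1P_cyt", "S1P_er",
        rname = "S1P uptake cytosol->ER"),
    def("t_C1P_gc_om", "mal", "C1P_gc", "C1P_om",
        rname = "CPTP-mediated C1P Golgi->om"),
    def("t_C1P_im_cyt", "mal", "C1P_im", "C1P_cyt",
        rname = "C1P release im->cytosol"),
    def("t_C1P_cyt_er", "mal", "C1P_cyt", "C1P_er",
        rname = "C1P uptake cytosol->ER"),
    def("t_GSL_gl_om", "mal", "GSL_gl", "GSL_om", rname = "GSL exocytosis"),
    def("t_GSL_om_im", "mal", "GSL_om", "GSL_im",
        rname = "GSL flip om->im (FAPP2)"),
    def("t_GSL_im_om", "mal", "GSL_im", "GSL_om", rname = "GSL flip im->om"),
    # sphingomyelinases (SM -> CER)
    def("e_aSMase_om", "mm", "SM_om", "CER_om", "aSMase_om", H,
        "aSMase: SM->CER [om]"),
    def("e_nSMase_im", "mm", "SM_im", "CER_im", "nSMase_im", H,
        "nSMase: SM->CER [im]"),
    def("e_aSMase_lys", "mm", "SM_lys", "CER_lys", "aSMase_lys", H,
        "aSMase: SM->CER [lys]"),
    def("e_nSMase_er", "mm", "SM_er", "CER_er", "nSMase_er", CD,
        "nSMase: SM->CER [er]"),
    def("e_nSMase_nuc", "mm", "SM_nuc", "CER_nuc", "nSMase_nuc", H,
        "nSMase: SM->CER [nuc]"),
    # SM synthases (CER -> SM)
    def("e_SMS1_gl", "mm", "CER_gl", "SM_gl", "SMS1", 0.25,
        "SMS1: CER->SM [Golgi lumen]"),
    def("e_SMS2_im", "mm", "CER_im", "SM_im", "SMS2", K,
        "SMS2: CER->SM [im]"),
    def("e_SMS_nuc", "mm", "CER_nuc", "SM_nuc", "SMS_nuc", S,
        "SMS: CER->SM [nuc]"),
    def("e_SMSr_er", "mm", "CER_er", "SM_er", "SMSr", SK,
        "SMSr: CER->SM [er]"),
    # glycosphingolipid branch
    def("e_GCS_gc", "mm", "CER_gc", "GSL_gc", "GCS", 0.6,
        "GlcCer synthase: CER->GSL [Golgi cyt face]"),
    def("e_LacCS_gl", "mm", "GSL_gc", "GSL_gl", "LacCS", S,
        "GSL maturation [Golgi lumen]"),
    def("e_GCase_lys", "mm", "GSL_lys", "CER_lys", "GCase", GC,
        "GCase: GSL->CER [lys]"),
    # ceramidases (CER -> Sph)
    def("e_ACDase_lys", "mm", "CER_lys", "Sph_lys", "ACDase_lys", GC,
        "acid CDase: CER->Sph [lys]"),
    def("e_ACDase_mit", "mm", "CER_mit", "Sph_mit", "ACDase_mit", CD,
        "acid CDase: CER->Sph [mit]"),
    def("e_AlkCDase_gc", "mm", "CER_gc", "Sph_gc", "AlkCDase", CD,
        "alkaline CDase: CER->Sph [Golgi]"),
    def("e_NCDase_om", "mm", "CER_om", "Sph_om", "NCDase_om", CD,
        "neutral CDase: CER->Sph [om]"),
    def("e_NCDase_im", "mm", "CER_im", "Sph_im", "NCDase_im", SK,
        "neutral CDase: CER->Sph [im]"),
    def("e_CDase_er", "mm", "CER_er", "Sph_er", "CDase_er", H,
        "CDase: CER->Sph [er]"),
    def("e_CDase_nuc", "mm", "CER_nuc", "Sph_nuc", "CDase_nuc", CD,
        "CDase: CER->Sph [nuc]"),
    # ceramide synthases (Sph -> CER, salvage re-acylation)
    def("e_CerS_er", "mm", "Sph_er", "CER_er", "CerS_er", S,
        "CerS: Sph->CER [er]"),
    def("e_CerS_mit", "mm", "Sph_mit", "CER_mit", "CerS_mit", S,
        "CerS: Sph->CER [mit]"),
    def("e_CerS_nuc", "mm", "Sph_nuc", "CER_nuc", "CerS_nuc", S,
        "CerS: Sph->CER [nuc]"),
    # sphingosine kinases (Sph -> S1P)
    def("e_SK1_im", "mm", "Sph_im", "S1P_im", "SK1", SK,
        "SK1: Sph->S1P [im]"),
    def("e_SK2_cyt", "mm", "Sph_cyt", "S1P_cyt", "SK2", SK,
        "SK2: Sph->S1P [cyt]"),
    def("e_SK_er", "mm", "Sph_er", "S1P_er", "SK_er", SK,
        "SK: Sph->S1P [er]"),
    def("e_SK2_nuc", "mm", "Sph_nuc", "S1P_nuc", "SK2", SK,
        "SK2: Sph->S1P [nuc]"),
    def("e_SK_mit", "mm", "Sph_mit", "S1P_mit", "SK_mit", SK,
        "SK: Sph->S1P [mit]"),
    # S1P phosphatases and lyase
    def("e_SPP1_er", "mm", "S1P_er", "Sph_er", "SPP1", K,
        "SPP1: S1P->Sph [er]"),
    def("e_SPP2_nuc", "mm", "S1P_nuc", "Sph_nuc", "SPP2", K,
        "SPP2: S1P->Sph [nuc]"),
    def("e_SPP_mit", "mm", "S1P_mit", "Sph_mit", "SPP_mit", K,
        "SPP: S1P->Sph [mit]"),
    def("e_PAP2_om", "mm", "S1P_om", "Sph_om", "PAP2", K,
        "PAP2: S1P->Sph [om]"),
    def("e_SPL1_er", "mm", "S1P_er", NA, "SPL1", K,
        "SPL1: irreversible S1P degradation [er]"),
    # ceramide kinases (CER -> C1P) and C1P phosphatases
    def("e_CERK_gc", "mm", "CER_gc", "C1P_gc", "CERK_gc", E,
        "CERK: CER->C1P [Golgi]"),
    def("e_CERK_om", "mm", "CER_om", "C1P_om", "CERK_om", K,
        "CERK: CER->C1P [om]"),
    def("e_CERK_im", "mm", "CER_im", "C1P_im", "CERK_im", K,
        "CERK: CER->C1P [im]"),
    def("e_LPP_om", "mm", "C1P_om", "CER_om", "LPP_om", K,
        "LPP: C1P->CER [om]"),
    def("e_LPP_er", "mm", "C1P_er", "CER_er", "LPP_er", SK,
        "LPP: C1P->CER [er]"),
    # endocytosis to the lysosome (shared vesicular machinery, saturable)
    def("e_endo_SM", "mm", "SM_om", "SM_lys", "EndoV", E,
        "SM endocytosis om->lys"),
    def("e_endo_CER", "mm", "CER_om", "CER_lys", "EndoV", E,
        "CER endocytosis om->lys"),
    def("e_endo_GSL", "mm", "GSL_om", "GSL_lys", "EndoV", GC,
        "GSL endocytosis om->lys")
  )

  inhibitors <- list(
    inflow_CER_er = c("S1P_er", "C1P_er", "S1P_cyt", "C1P_cyt"),
    e_aSMase_om = c("S1P_om", "C1P_om"),
    e_nSMase_im = c("S1P_im", "C1P_im"),
    e_aSMase_lys = c("S1P_cyt", "C1P_cyt"),
    e_nSMase_er = c("S1P_er", "C1P_er"),
    e_nSMase_nuc = "S1P_nuc",
    e_CerS_er = c("S1P_er", "C1P_er"),
    e_CerS_mit = "S1P_mit",
    e_CerS_nuc = "S1P_nuc",
    e_GCase_lys = c("S1P_cyt", "C1P_cyt"),
    e_LPP_om = "S1P_om")

  list(species = species, reactions = reactions, inhibitors = inhibitors)
}

# Balanced stationary flux distribution: a weighted sum of source-to-sink
# pathway fluxes plus internal cycles. Every reaction lies on at least one
# route, so v > 0 and M v = 0 exactly.
sphingo_fluxes <- function(inv) {
  route <- function(w, ...) list(w = w, steps = c(...))
  routes <- list(
    route(1, "inflow_S1P_om", "e_PAP2_om", "t_Sph_om_im", "t_Sph_im_cyt",
          "t_Sph_cyt_er", "e_SK_er", "e_SPL1_er"),
    route(1, "inflow_Sph_om", "t_Sph_om_im", "e_SK1_im", "t_S1P_im_cyt",
          "t_S1P_cyt_er", "e_SPL1_er"),
    route(1, "inflow_CER_om", "e_NCDase_om", "t_Sph_om_im", "t_Sph_im_cyt",
          "e_SK2_cyt", "t_S1P_cyt_er", "e_SPL1_er"),
    route(1, "inflow_CER_om", "t_CER_om_im", "e_NCDase_im", "t_Sph_im_cyt",
          "t_Sph_cyt_er", "e_SK_er", "e_SPL1_er"),
    route(1, "inflow_CER_om", "e_endo_CER", "e_ACDase_lys", "t_Sph_lys_cyt",
          "e_SK2_cyt", "t_S1P_cyt_er", "e_SPL1_er"),
    route(1, "inflow_CER_om", "e_CERK_om", "e_LPP_om", "e_NCDase_om",
          "t_Sph_om_im", "t_Sph_im_cyt", "t_Sph_cyt_er", "e_SK_er",
          "e_SPL1_er"),
    route(2, "inflow_SM_om", "e_aSMase_om", "e_NCDase_om", "t_Sph_om_im",
          "t_Sph_im_cyt", "e_SK2_cyt", "t_S1P_cyt_er", "e_SPL1_er"),
    route(2, "inflow_SM_om", "e_endo_SM", "e_aSMase_lys", "e_ACDase_lys",
          "t_Sph_lys_cyt", "e_SK2_cyt", "t_S1P_cyt_er", "e_SPL1_er"),
    route(1, "inflow_C1P_om", "e_LPP_om", "t_CER_om_im", "e_SMS2_im",
          "e_nSMase_im", "e_NCDase_im", "t_Sph_im_cyt", "e_SK2_cyt",
          "t_S1P_cyt_er", "e_SPL1_er"),
    route(1, "inflow_CER_er", "e_CDase_er", "e_SK_er", "e_SPL1_er"),
    route(1, "inflow_CER_er", "e_SMSr_er", "e_nSMase_er", "e_CDase_er",
          "e_SK_er", "e_SPL1_er"),
    route(1, "inflow_CER_er", "t_CER_er_cyt", "t_CER_cyt_gl", "e_SMS1_gl",
          "t_SM_gl_om", "e_aSMase_om", "e_NCDase_om", "t_Sph_om_im",
          "t_Sph_im_cyt", "t_Sph_cyt_er", "e_SK_er", "e_SPL1_er"),
    route(1, "inflow_CER_er", "t_CER_er_gc", "t_CER_gc_gl", "e_SMS1_gl",
          "t_SM_gl_om", "e_endo_SM", "e_aSMase_lys", "e_ACDase_lys",
          "t_Sph_lys_cyt", "e_SK2_cyt", "t_S1P_cyt_er", "e_SPL1_er"),
    route(1, "inflow_CER_er", "t_CER_er_gc", "e_GCS_gc", "e_LacCS_gl",
          "t_GSL_gl_om", "e_endo_GSL", "e_GCase_lys", "e_ACDase_lys",
          "t_Sph_lys_cyt", "e_SK2_cyt", "t_S1P_cyt_er", "e_SPL1_er"),
    route(1, "inflow_CER_er", "t_CER_er_gc", "e_AlkCDase_gc", "t_Sph_gc_cyt",
          "e_SK2_cyt", "t_S1P_cyt_er", "e_SPL1_er"),
    route(1, "inflow_CER_er", "t_CER_er_gc", "e_CERK_gc", "t_C1P_gc_om",
          "e_LPP_om", "t_CER_om_im", "e_CERK_im", "t_C1P_im_cyt",
          "t_C1P_cyt_er", "e_LPP_er", "e_CDase_er", "e_SK_er", "e_SPL1_er"),
    route(1, "inflow_CER_er", "t_CER_er_nuc", "e_CDase_nuc", "e_CerS_nuc",
          "t_CER_nuc_er", "e_CDase_er", "e_SK_er", "e_SPL1_er"),
    route(1, "inflow_CER_er", "t_CER_er_mit", "e_ACDase_mit", "e_CerS_mit",
          "t_CER_mit_er", "e_CDase_er", "e_SK_er", "e_SPL1_er"),
    # internal cycles (futile phosphorylation/acylation turnover, GSL flip)
    route(0.5, "e_SK2_nuc", "e_SPP2_nuc"),
    route(0.5, "e_SMS_nuc", "e_nSMase_nuc"),
    route(0.5, "e_SK_mit", "e_SPP_mit"),
    route(2, "e_ACDase_mit", "e_CerS_mit"),
    route(0.5, "e_CerS_er", "e_CDase_er"),
    route(0.5, "e_SK_er", "e_SPP1_er"),
    route(0.5, "t_GSL_om_im", "t_GSL_im_om")
  )
  v <- stats::setNames(numeric(nrow(inv$reactions)), inv$reactions$id)
  for (r in routes) {
    for (s in r$steps) {
      if (!s %in% names(v)) stop("unknown reaction in route: ", s)
      v[[s]] <- v[[s]] + r$w
    }
  }
  if (any(v <= 0)) {
    stop("flux routes do not cover reactions: ",
         paste(names(v)[v <= 0], collapse = ", "), call. = FALSE)
  }
  v
}

#' Update one registry parameter consistently
#'
#' Writes the value both into the parameter registry and into the owning
#' reaction's kinetic-law record.
#'
#' @param net a `reaction_network`.
#' @param key registry key `"<reaction id>.<symbol>"`.
#' @param value new positive value.
#' @return the modified network.
#' @export
set_param <- function(net, key, value) {
  if (!key %in% names(net$params)) {
    stop("unknown parameter key '", key, "'", call. = FALSE)
  }
  stopifnot(value > 0)
  net$params[[key]] <- value
  rid <- sub("\\..*$", "", key)
  sym <- sub("^[^.]*\\.", "", key)
  if (startsWith(sym, "Ki_")) {
    net$reactions[[rid]]$law$inhibitors[[sub("^Ki_", "", sym)]] <- value
  } else {
    net$reactions[[rid]]$law$params[[sym]] <- value
  }
  net
}

#' Scenario patches
#'
#' A scenario patch is a table of parameter edits — multiplicative (`mul`)
#' or absolute (`set`) — with a free-text rationale per entry.
#' [apply_scenario()] returns a new network (the input is untouched) whose
#' metadata records the patch.
#'
#' @param label scenario label.
#' @param entries tibble with columns `key`, `op` (`"mul"` or `"set"`),
#'   `value` (> 0) and `note`.
#' @return a `scenario_patch`.
#' @export
scenario_patch <- function(label, entries) {
  entries <- as_tibble(entries)
  stopifnot(all(c("key", "op", "value", "note") %in% names(entries)),
            all(entries$op %in% c("mul", "set")), all(entries$value > 0))
  structure(list(label = label, entries = entries), class = "scenario_patch")
}

#' @export
print.scenario_patch <- function(x, ...) {
  cat("<scenario_patch> ", x$label, ": ", nrow(x$entries), " edits\n",
      sep = "")
  invisible(x)
}

#' @rdname scenario_patch
#' @param net target `reaction_network`; every patch key must exist in it.
#' @param patch a `scenario_patch`.
#' @export
apply_scenario <- function(net, patch) {
  stopifnot(inherits(patch, "scenario_patch"))
  out <- net
  for (i in seq_len(nrow(patch$entries))) {
    e <- patch$entries[i, ]
    if (!e$key %in% names(out$params)) {
      stop("patch key '", e$key, "' not present in the network",
           call. = FALSE)
    }
    new_val <- if (e$op == "mul") out$params[[e$key]] * e$value else e$value
    out <- set_param(out, e$key, new_val)
  }
  out$metadata$scenario <- patch$label
  out$metadata$patch <- patch$entries
  out
}

#' The Alzheimer's-disease perturbation scenario
#'
#' Parameter changes describing the sphingolipid fingerprint of Alzheimer's
#' disease: down-regulated ceramidase activity, altered sphingosine-kinase
#' and ceramide-kinase dynamics, reduced CERT-mediated ER-to-Golgi ceramide
#' transport, and up-regulated de novo ceramide synthesis. Applied alone,
#' these changes overload the saturable sphingomyelin-degradation capacity
#' and several SM pools grow without bound. The corrected scenario
#' (`corrected = TRUE`, default) therefore adds the compensating
#' modifications: reduced CERT-independent (vesicular) ER-to-Golgi CER
#' transport, increased sphingomyelinase activity, and minor adjustments of
#' SM transport between compartments — after which all species stay bounded
#' and the model reproduces the expected directions (CER accumulation in ER
#' and lysosome, an early Sph dip followed by accumulation, decreased S1P).
#'
#' Magnitudes are documented placeholders chosen to realize those reported
#' directions; individual entries can be overridden via `overrides`.
#'
#' @param corrected include the compensating modifications.
#' @param overrides optional tibble of entries replacing same-key defaults.
#' @return a `scenario_patch` labelled `"AD"` (or `"AD_uncorrected"`).
#' @export
ad_scenario <- function(corrected = TRUE, overrides = NULL) {
  e <- function(keys, op, value, note) {
    tibble(key = keys, op = op, value = value, note = note)
  }
  core <- bind_rows(
    e(paste0(c("e_ACDase_lys", "e_ACDase_mit", "e_AlkCDase_gc",
               "e_NCDase_om", "e_NCDase_im", "e_CDase_er", "e_CDase_nuc"),
             ".Vmax"), "mul", 0.8, "CDase activity down-regulated"),
    e(paste0(c("e_SK1_im", "e_SK2_cyt", "e_SK_er", "e_SK2_nuc", "e_SK_mit"),
             ".Vmax"), "mul", 0.7, "sphingosine kinase dynamics reduced"),
    e(paste0(c("e_CERK_gc", "e_CERK_om", "e_CERK_im"), ".Vmax"),
      "mul", 0.7, "ceramide kinase dynamics reduced"),
    e(c("t_CER_er_cyt.k", "t_CER_cyt_gl.k"), "mul", 0.2,
      "CERT down-regulation: CER transport to Golgi inhibited"),
    e("inflow_CER_er.k", "mul", 3,
      "de novo CER synthesis up-regulated")
  )
  corr <- bind_rows(
    e("t_CER_er_gc.k", "mul", 0.3,
      "reduced CERT-independent vesicular CER transport to Golgi"),
    e("e_aSMase_om.Vmax", "mul", 1.6,
      "increased sphingomyelinase activity"),
    e(paste0(c("e_nSMase_im", "e_aSMase_lys", "e_nSMase_nuc"), ".Vmax"),
      "mul", 2, "increased sphingomyelinase activity"),
    e("e_nSMase_er.Vmax", "mul", 2.5,
      "increased sphingomyelinase activity"),
    e("t_SM_gl_om.k", "mul", 0.8, "minor SM transport adjustment"),
    e("e_endo_SM.Vmax", "mul", 1.5, "minor SM transport adjustment")
  )
  entries <- if (corrected) bind_rows(core, corr) else core
  if (!is.null(overrides)) {
    overrides <- as_tibble(overrides)
    entries <- bind_rows(filter(entries, !.data$key %in% overrides$key),
                         overrides)
  }
  scenario_patch(if (corrected) "AD" else "AD_uncorrected", entries)
}

#' Convenience builder for the AD model
#'
#' @inheritParams ad_scenario
#' @param params_source forwarded to [build_homeostasis_model()].
#' @return the homeostasis network with the AD patch applied.
#' @export
build_ad_model <- function(corrected = TRUE, params_source = NULL,
                           overrides = NULL) {
  apply_scenario(build_homeostasis_model(params_source),
                 ad_scenario(corrected, overrides))
}
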