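# Heavier simulations shared by several blocks are computed once here.
home <- build_homeostasis_model()
x0_home <- initial_state(home)
ad_un <- build_ad_model(corrected = FALSE)
ad_co <- build_ad_model(corrected = TRUE)
traj_un <- simulate_network(ad_un, x0 = x0_home, t_end = 5000)
traj_co <- simulate_network(ad_co, x0 = x0_home,
                            grid = c(seq(0, 20, by = 0.5),
                                     seq(21, 5000, length.out = 250)))

test_that("the homeostasis model matches its declared inventory", {
  g <- glance(home)
  expect_equal(g$n_species, 39)
  expect_equal(g$n_reactions, 69)
  expect_equal(g$n_compartments, 9)
  expect_equal(g$n_enzymes, 37)
  expect_equal(g$n_parameters, 129)
  expect_equal(g$n_explicit_initials, 38)
  forms <- vapply(home$reactions, function(r) r$law$form, "")
  expect_equal(sum(forms == "MASS_ACTION"), 29)
  expect_equal(sum(forms %in% c("MICHAELIS_MENTEN", "MM_INHIBITED")), 40)
  transports <- vapply(home$reactions, `[[`, TRUE, "is_transport")
  expect_equal(sum(transports), 29)
})

test_that("the homeostasis model is stationary and stable at its initial state", {
  rhs <- build_rhs(home)
  expect_lt(max(abs(rhs(x0_home))), 1e-10)
  st <- find_stationary_state(home, horizon = 400)
  expect_lt(st$residual, 1e-8 * max(abs(st$state)))
  expect_equal(unname(st$state), unname(x0_home), tolerance = 1e-6)
  A <- lna_operators(home, st$state)$A
  expect_lt(max(Re(eigen(A, only.values = TRUE)$values)), 0)
})

test_that("scenario patches apply out of place with metadata", {
  bd <- make_birth_death(10, 1)
  empty <- scenario_patch("noop", tibble::tibble(
    key = character(), op = character(), value = numeric(),
    note = character()))
  same <- apply_scenario(bd, empty)
  expect_equal(same$params, bd$params)
  doubled <- apply_scenario(bd, scenario_patch("double", tibble::tibble(
    key = "birth.k", op = "mul", value = 2, note = "production up")))
  expect_equal(unname(doubled$params["birth.k"]), 20)
  expect_equal(unname(bd$params["birth.k"]), 10) # original untouched
  expect_equal(unname(find_stationary_state(doubled)$state), 20,
               tolerance = 1e-8)
  expect_equal(doubled$metadata$scenario, "double")
  expect_error(
    apply_scenario(bd, scenario_patch("bad", tibble::tibble(
      key = "nope.k", op = "mul", value = 2, note = ""))),
    "nope.k")
})

test_that("the AD patch encodes the reported directions of change", {
  p <- ad_scenario(corrected = TRUE)$entries
  mult <- function(key) p$value[p$key == key & p$op == "mul"]
  expect_lt(mult("t_CER_er_cyt.k"), 1)       # CERT transport inhibited
  expect_lt(mult("t_CER_cyt_gl.k"), 1)
  expect_gt(mult("inflow_CER_er.k"), 1)      # de novo synthesis up
  expect_lt(mult("t_CER_er_gc.k"), 1)        # vesicular route reduced
  expect_true(all(p$value[grepl("SMase", p$key)] > 1)) # SMases up
  expect_true(all(p$value[grepl("CDase", p$key)] < 1)) # CDases down
  expect_true(all(p$value[grepl("SK", p$key) & grepl("Vmax", p$key)] < 1))
  # the uncorrected patch is a strict subset
  pu <- ad_scenario(corrected = FALSE)$entries
  expect_true(all(pu$key %in% p$key))
  expect_lt(nrow(pu), nrow(p))
})

test_that("uncorrected AD changes drive unbounded sphingomyelin growth", {
  hits <- detect_divergence(traj_un, threshold = 25 * max(x0_home))
  expect_true(all(c("SM_lys", "SM_om", "SM_er") %in% hits$species))
  # the runaway is SM-specific: S1P pools stay near baseline
  fin <- traj_un$conc[nrow(traj_un$conc), ]
  expect_lt(max(fin[grep("^S1P", names(fin))]), 10)
})

test_that("corrected AD is bounded with the reported disease signature", {
  expect_equal(nrow(detect_divergence(traj_co,
                                      threshold = 25 * max(x0_home))), 0)
  fin <- traj_co$conc[nrow(traj_co$conc), ]
  late_growth <- (fin - traj_co$conc[round(0.8 * nrow(traj_co$conc)), ]) /
    pmax(fin, 1e-9)
  expect_lt(max(late_growth), 0.05) # plateaued, not slowly escaping
  ratio <- fin / x0_home
  # ceramide accumulates, prominently in the ER and lysosome
  expect_gt(ratio[["CER_er"]], 2)
  expect_gt(ratio[["CER_lys"]], 2)
  # S1P declines in the kinase-driven pools and in the median
  expect_lt(ratio[["S1P_im"]], 1)
  expect_lt(ratio[["S1P_nuc"]], 1)
  expect_lt(ratio[["S1P_mit"]], 1)
  expect_lt(median(ratio[grep("^S1P", names(ratio))]), 1)
})

test_that("sphingosine dips early and accumulates late in corrected AD", {
  sph <- traj_co$conc[, grep("^Sph", colnames(traj_co$conc))]
  early <- traj_co$time <= 5
  dipped <- vapply(colnames(sph), function(sp) {
    min(sph[early, sp]) < 0.97 * sph[1, sp]
  }, TRUE)
  expect_gte(sum(dipped), 5) # most pools show the immediate decline
  expect_gt(sum(sph[nrow(sph), ]) / sum(sph[1, ]), 1.2) # later accumulation
})

test_that("mitochondrial CER noise flags include its CerS and ACDase reactions", {
  st <- find_stationary_state(home, horizon = 400)
  dec <- decompose_variance(lna_operators(home, st$state))
  fl <- flag_components(dec)
  flagged <- fl[fl$species == "CER_mit" & fl$flag, ]
  expect_true(all(c("e_CerS_mit", "e_ACDase_mit") %in% flagged$reaction))
})
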