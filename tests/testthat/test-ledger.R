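# cofactor-ledger bioenergetics

eq1_spec <- function() spectrum_from_equation(fermentation_equation("eq1"))
eq2_spec <- function(per = "equation") {
  spectrum_from_equation(fermentation_equation("eq2"), per = per)
}

test_that("substrate oxidation bookkeeping matches the reconstructed pathways", {
  g <- oxidize_substrate("glucose", 1)
  expect_true(g$acetyl_coa == rational(2) && g$nadh == rational(2) &&
                g$fd == rational(2) && g$atp_slp == rational(2))
  l <- oxidize_substrate("lactate", 1)
  expect_true(l$acetyl_coa == rational(1) && l$nadh == rational(2) &&
                l$fd == rational(0) && l$atp_slp == rational(0))
  p <- oxidize_substrate("pyruvate", 1)
  expect_true(p$acetyl_coa == rational(1) && p$nadh == rational(0) &&
                p$fd == rational(1))
  expect_error(oxidize_substrate("ethanol"), "unknown reducing substrate")
})

test_that("reducing-equivalent ratios are exactly 1:4 and 1:2", {
  expect_true(reducing_equivalent_pairs("glucose") == rational(4))
  expect_true(reducing_equivalent_pairs("lactate") == rational(2))
  expect_true(reducing_equivalent_pairs("pyruvate") == rational(1))
  expect_true(reducing_equivalent_pairs("pyruvate") /
                reducing_equivalent_pairs("glucose") == rational(1, 4))
  expect_true(reducing_equivalent_pairs("pyruvate") /
                reducing_equivalent_pairs("lactate") == rational(1, 2))
})

test_that("equation-derived spectra carry the printed product ratios", {
  s1 <- eq1_spec()
  expect_true(s1$caproate == rational(2, 3))
  expect_true(s1$butyrate == rational(1, 6))
  expect_true(s1$acetate_consumed == rational(1, 3))
  s2 <- eq2_spec()
  expect_true(s2$substrate_moles == rational(21))
  expect_true(s2$caproate == rational(7))
  expect_true(s2$butyrate == rational(1))
  expect_true(s2$acetate_consumed == rational(2))
  # no products: everything becomes acetate
  noprod <- reaction(c(glucose = -1, acetate = 2, CO2 = 2, H2 = 2,
                       `H+` = 2))
  s0 <- spectrum_from_equation(noprod)
  expect_true(s0$caproate == rational(0) && s0$butyrate == rational(0))
  expect_error(spectrum_from_equation(reaction(c(H2O = -1, H2 = 1))),
               "exactly one")
})

test_that("elongation demand counts cycles, NADH and ferredoxin", {
  e1 <- elongation_demand(eq1_spec())
  expect_true(e1$steps == rational(3, 2))
  expect_true(e1$nadh_required == rational(9, 2))
  expect_true(e1$fd_generated == rational(3, 2))
  e2 <- elongation_demand(eq2_spec())
  expect_true(e2$steps == rational(15))
  expect_true(e2$nadh_required == rational(45))
  only_butyrate <- fermentation_spectrum("glucose", 1, butyrate = 1)
  eb <- elongation_demand(only_butyrate)
  expect_true(eb$steps == rational(1))
  expect_true(eb$nadh_required == rational(3))
  expect_true(eb$fd_generated == rational(1))
})

test_that("the glucose ledger closes at 3.75 ATP with the published internals", {
  led <- run_ledger(eq1_spec())
  expect_true(led$atp_slp == rational(2))
  expect_true(led$fd_reduced == rational(7, 2))
  expect_true(led$protons_translocated == rational(7))
  expect_true(led$atp_chemiosmotic == rational(7, 4))
  expect_true(led$h2 == rational(1))
  expect_true(led$atp_total == rational(15, 4))
  expect_true(led$nadh_produced == led$nadh_consumed)
})

test_that("the lactate ledger yields ~0.72 ATP per two moles and 12 H2 per equation", {
  led <- run_ledger(eq2_spec())
  expect_true(led$h2 == rational(12))
  expect_true(led$atp_total == rational(15, 2))
  led_ge <- run_ledger(eq2_spec("glucose_equivalent"))
  expect_true(led_ge$atp_total == rational(5, 7))
  expect_lt(abs(as.numeric(led_ge$atp_total) - 0.72), 0.02)
})

test_that("ledger H2 equals the balancer's solved H2 on both equations", {
  for (eq in c("eq1", "eq2")) {
    rxn <- fermentation_equation(eq)
    led <- run_ledger(spectrum_from_equation(rxn, per = "equation"))
    expect_true(led$h2 == reaction_coef(rxn, "H2"))
  }
})

test_that("a zero spectrum gives an all-zero ledger", {
  led <- run_ledger(fermentation_spectrum("glucose", 0))
  for (f in c("atp_slp", "nadh_produced", "nadh_consumed", "fd_reduced",
              "protons_translocated", "atp_chemiosmotic", "h2",
              "atp_total")) {
    expect_true(led[[f]] == rational(0))
  }
})

test_that("the ledger closes exactly on random feasible spectra", {
  set.seed(77)
  n_checked <- 0
  for (i in 1:200) {
    sub <- sample(c("glucose", "lactate", "pyruvate"), 1)
    s <- sample(1:10, 1)
    cap <- rational(sample(0:8, 1), sample(1:4, 1))
    but <- rational(sample(0:4, 1), sample(1:4, 1))
    spec <- fermentation_spectrum(sub, s, caproate = cap, butyrate = but)
    feas <- redox_feasibility(spec)
    if (!feas$feasible) next
    led <- run_ledger(spec)
    expect_true(led$nadh_produced == led$nadh_consumed)
    expect_true(led$atp_total ==
                  led$atp_slp + led$protons_translocated /
                    ledger_config()$atpase_protons_per_atp)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 50)
})

test_that("ATP total is monotone in the chemiosmotic constants", {
  spec <- eq1_spec()
  prev <- -Inf
  for (rnf in 1:4) {
    tot <- as.numeric(run_ledger(spec, ledger_config(rnf_protons_per_2e =
                                                       rnf))$atp_total)
    expect_gte(tot, prev)
    prev <- tot
  }
  prev <- Inf
  for (hatp in 2:6) {
    tot <- as.numeric(run_ledger(spec, ledger_config(atpase_protons_per_atp =
                                                       hatp))$atp_total)
    expect_lte(tot, prev)
    prev <- tot
  }
})

test_that("glucose yields about five times the ATP of two lactate", {
  atp_glu <- as.numeric(run_ledger(eq1_spec())$atp_total)
  atp_lac2 <- as.numeric(run_ledger(eq2_spec("glucose_equivalent"))$atp_total)
  ratio <- atp_glu / atp_lac2
  expect_gte(ratio, 5.0)
  expect_lte(ratio, 5.5)
  expect_gte(atp_lac2 / atp_glu, 0.18)
  expect_lte(atp_lac2 / atp_glu, 0.21)
})

test_that("free energy per ATP is ~68 kJ/mol from either substrate", {
  d1 <- delta_r_g_prime(fermentation_equation("eq1"))$drg_prime
  d2 <- delta_r_g_prime(fermentation_equation("eq2"))$drg_prime
  atp1 <- as.numeric(run_ledger(eq1_spec())$atp_total)
  atp2 <- as.numeric(run_ledger(eq2_spec("glucose_equivalent"))$atp_total)
  e1 <- free_energy_per_atp(d1, atp1)
  e2 <- free_energy_per_atp(2 * d2, atp2)   # two moles of lactate
  expect_equal(round(e1), 68)
  expect_lt(abs(e1 - e2), 2)
  expect_error(free_energy_per_atp(-100, 0), "positive")
})

test_that("redox feasibility flags pyruvate-to-caproate overdrafts", {
  ok <- redox_feasibility(eq1_spec())
  expect_true(ok$feasible)
  expect_true(ok$nadh_deficit == rational(0))
  forced <- fermentation_spectrum("pyruvate", 1, caproate = rational(1, 3))
  bad <- redox_feasibility(forced)
  expect_false(bad$feasible)
  expect_true(bad$nadh_deficit == rational(1, 3))
  # acetate, not caproate, dominates the achievable spectrum
  expect_gt(as.numeric(bad$acetate_produced),
            as.numeric(bad$max_spectrum$caproate))
  expect_error(run_ledger(forced), "redox-infeasible")
  trivial <- redox_feasibility(fermentation_spectrum("glucose", 1))
  expect_true(trivial$feasible)
})

test_that("spectra reject C2-inconsistent acetate bookkeeping", {
  expect_error(fermentation_spectrum("glucose", 1, caproate = 1,
                                     acetate_consumed = 5),
               "C2-unit conservation")
  expect_error(ledger_config(rnf_protons_per_2e = 0), "positive")
})
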