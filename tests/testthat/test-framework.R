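case_like_profile <- function() make_case_fixture(case_params())$original$profile

test_that("the case-study profile resolves to the documented data plan", {
  fw <- run_framework(case_like_profile())
  expect_equal(fw$mode, "prospective_lca")
  plan <- fw$plan
  get_tier <- function(nf, q) plan$tier[plan$nanoform %in% nf & plan$quantity == q]
  expect_equal(get_tier("p25_tio2", "cf"), "literature")
  expect_equal(get_tier("cu2o_p25_tio2", "cf"), "read_across")
  expect_equal(get_tier("p25_tio2", "exposure"), "default_precautionary")
  expect_equal(get_tier("cu2o_p25_tio2", "exposure"), "default_precautionary")
  expect_equal(plan$tier[is.na(plan$nanoform) & plan$quantity == "release"],
               "literature")
  # trace covers the preliminary steps, the cascade and the stubs
  expect_true(all(c(1, 4, 6, 7, 8, 9, 10, 11, 12, 13, 16) %in% fw$trace$step))
  expect_true(!is.unsorted(fw$trace$step))
})

test_that("an all-measured industrial profile needs no fallbacks", {
  prof <- availability_profile(
    reference_product_exists = TRUE,
    process_level_data_available = TRUE,
    process_data_tier = "measured_industrial",
    system_boundaries_known = TRUE,
    release_rate_known = TRUE,
    release_tier = "measured_industrial",
    nanoforms = list(nf = nanoform_availability(
      tox_data = TRUE, tox_tier = "measured_industrial",
      exposure_data = TRUE, exposure_tier = "measured_industrial",
      fate_data = TRUE, fate_tier = "measured_industrial")))
  fw <- run_framework(prof)
  expect_equal(fw$mode, "prospective_lca")
  expect_true(all(fw$plan$tier == "measured_industrial"))
  expect_true(all(is.na(fw$trace$fallback)))
})

test_that("missing process-level data drops to KPI-only mode at step 5", {
  prof <- availability_profile(
    reference_product_exists = TRUE,
    process_level_data_available = FALSE,
    system_boundaries_known = TRUE,
    release_rate_known = FALSE,
    nanoforms = list(nf = nanoform_availability()))
  fw <- run_framework(prof)
  expect_equal(fw$mode, "kpi_only")
  expect_equal(max(fw$trace$step), 5)
  # unknown boundaries trigger the same fallback at step 6
  prof2 <- availability_profile(
    reference_product_exists = TRUE,
    process_level_data_available = TRUE,
    system_boundaries_known = FALSE,
    release_rate_known = FALSE,
    nanoforms = list(nf = nanoform_availability()))
  expect_equal(run_framework(prof2)$mode, "kpi_only")
})

test_that("identical profiles yield identical traces and plans", {
  a <- run_framework(case_like_profile())
  b <- run_framework(case_like_profile())
  expect_identical(a$trace, b$trace)
  expect_identical(a$plan, b$plan)
})

test_that("the plan never claims lower uncertainty than the profile supports", {
  combos <- expand.grid(tox = c(TRUE, FALSE), db = c(TRUE, FALSE),
                        fate = c(TRUE, FALSE), ra = c(TRUE, FALSE))
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    prof <- availability_profile(
      reference_product_exists = TRUE,
      process_level_data_available = TRUE,
      system_boundaries_known = TRUE,
      release_rate_known = TRUE,
      nanoforms = list(nf = nanoform_availability(
        tox_data = cb$tox, tox_tier = if (cb$tox) "measured_lab" else NA,
        fate_data = cb$fate, fate_tier = if (cb$fate) "measured_lab" else NA,
        database_entry = cb$db, read_across_possible = cb$ra)))
    plan <- run_framework(prof)$plan
    nfp <- plan[plan$nanoform %in% "nf", ]
    # every per-nanoform quantity appears exactly once
    expect_setequal(nfp$quantity, c("effect", "exposure", "fate", "cf"))
    eff <- nfp$tier[nfp$quantity == "effect"]
    if (!cb$tox) expect_gt(tier_rank(eff), tier_rank("measured_lab"))
    if (!cb$tox && !cb$db && !cb$ra) expect_equal(eff, "bulk_proxy")
    fate <- nfp$tier[nfp$quantity == "fate"]
    if (!cb$fate && !cb$ra) expect_equal(fate, "default_precautionary")
    # composed cf is at least as uncertain as its components
    expect_gte(tier_rank(nfp$tier[nfp$quantity == "cf"]),
               max(tier_rank(eff), tier_rank(fate)))
  }
})

test_that("contradictory profiles are rejected", {
  expect_error(availability_profile(
    reference_product_exists = TRUE,
    process_level_data_available = TRUE,
    system_boundaries_known = TRUE,
    release_rate_known = TRUE,
    nanoforms = list()), "contradictory")
  expect_error(availability_profile(
    reference_product_exists = NA,
    process_level_data_available = TRUE,
    system_boundaries_known = TRUE,
    release_rate_known = FALSE), "no missing answers")
})

test_that("KPIs divide batch amounts by nanomaterial mass", {
  k <- compute_kpis(solvent_ml = 10, nm_mass_g = 2)
  expect_equal(k[["solvent_consumption"]], 5)
  expect_equal(k[["waste_production"]], 0)
  full <- compute_kpis(solvent_ml = 30, electricity_kwh = 1.2, heat_kj = 500,
                       pollutants_g = 4, waste_g = 12, nm_mass_g = 6)
  expect_equal(as.numeric(full), c(5, 0.2, 500 / 6, 4 / 6, 2))
  expect_error(compute_kpis(solvent_ml = 10, nm_mass_g = 0), "nm_mass_g")
  expect_error(compute_kpis(solvent_ml = -1, nm_mass_g = 1), ">= 0")
})

test_that("KPIs are scale-invariant in the batch size", {
  for (i in 1:40) {
    set.seed(i)
    batch <- stats::runif(5, 0, 100)
    mass <- stats::runif(1, 0.1, 50)
    alpha <- stats::runif(1, 0.01, 20)
    k1 <- compute_kpis(batch[1], batch[2], batch[3], batch[4], batch[5], mass)
    k2 <- compute_kpis(alpha * batch[1], alpha * batch[2], alpha * batch[3],
                       alpha * batch[4], alpha * batch[5], alpha * mass)
    expect_equal(as.numeric(k1), as.numeric(k2), tolerance = 1e-12)
  }
})

test_that("KPI comparison reports per-indicator verdicts without aggregation", {
  a <- compute_kpis(10, 2, 100, 5, 8, nm_mass_g = 2)
  expect_true(all(compare_kpis(a, a)$verdict == "equal"))
  b <- compute_kpis(10, 1, 100, 5, 8, nm_mass_g = 2)
  cmp <- compare_kpis(a, b)
  expect_equal(cmp$verdict[cmp$indicator == "electricity_consumption"],
               "improved")
  expect_equal(cmp$relative_change[cmp$indicator == "electricity_consumption"],
               -0.5)
  mixed <- compare_kpis(a, compute_kpis(20, 1, 100, 5, 8, nm_mass_g = 2))
  expect_setequal(unique(mixed$verdict), c("improved", "worsened", "equal"))
  expect_false("score" %in% names(mixed))
})
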