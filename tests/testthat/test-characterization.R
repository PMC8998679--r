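test_that("characterization factors compose as fate x exposure x effect", {
  expect_equal(compose_cf(FF = 18.7, XF = 0.25, effect = 1000), 4675)
  for (E in c(0, 1, 17700)) expect_equal(compose_cf(1, 1, E), E)
  expect_equal(compose_cf(0, 1, 1000), 0)
  expect_error(compose_cf(1, 1.2, 10), "XF")
  expect_error(compose_cf(-1, 1, 10), "FF")
})

test_that("precautionary defaults dominate any admissible FF/XF <= 1", {
  for (E in c(0.5, 100, 17700)) {
    precautionary <- compose_cf(1, 1, E)
    for (i in 1:20) {
      set.seed(i)
      expect_lte(compose_cf(stats::runif(1), stats::runif(1), E),
                 precautionary)
    }
  }
})

test_that("registry validates keys, ranges and surrogate acyclicity", {
  expect_error(
    cf_registry(data.frame(nanoform_id = c("a", "a"),
                           compartment = "freshwater", indicator = "FEP",
                           CF = 1, source_tier = "literature")),
    "duplicate")
  expect_error(
    cf_registry(data.frame(nanoform_id = "a", compartment = "freshwater",
                           indicator = "FEP", XF = 1.4, EF = 1,
                           source_tier = "literature")),
    "XF")
  expect_error(
    cf_registry(data.frame(nanoform_id = "a", compartment = "freshwater",
                           indicator = "FEP", source_tier = "literature")),
    "neither a CF nor an effect factor")
  expect_error(
    cf_registry(data.frame(nanoform_id = "a", compartment = "freshwater",
                           indicator = "FEP", CF = 1,
                           source_tier = "literature"),
                surrogates = data.frame(target_id = c("x", "y"),
                                        surrogate_id = c("y", "x"),
                                        rationale = "loop")),
    "cycle")
})

test_that("factor resolution follows the direct -> read-across -> default cascade", {
  fx <- make_case_fixture(case_params())
  reg <- fx$original$registry

  direct <- resolve_factors("p25_tio2", "freshwater", "FEP", reg)
  expect_equal(direct$cf, 3443)
  expect_equal(direct$tier, "literature")
  expect_length(direct$defaults, 0)
  expect_equal(resolve_factors("p25_tio2", "freshwater", "HTP", reg)$cf, 222)

  via_ra <- resolve_factors("cu2o_p25_tio2", "freshwater", "FEP", reg)
  expect_equal(via_ra$cf, 17700)
  expect_equal(via_ra$tier, "read_across")
  expect_true(any(grepl("read-across", via_ra$trace)))

  # coated form's human-toxicity factor is a direct literature value
  coated_htp <- resolve_factors("cu2o_p25_tio2", "freshwater", "HTP", reg)
  expect_equal(coated_htp$cf, 0.99)
  expect_equal(coated_htp$tier, "literature")

  expect_error(resolve_factors("unknown_form", "freshwater", "FEP", reg),
               "KPI-only", class = "ssbd_cannot_characterize")
})

test_that("EF-only entries compose with two flagged precautionary defaults", {
  reg <- cf_registry(data.frame(
    nanoform_id = "nf", compartment = "freshwater", indicator = "FEP",
    EF = 1000, source_tier = "literature", source_ref = "test",
    stringsAsFactors = FALSE))
  res <- resolve_factors("nf", "freshwater", "FEP", reg)
  expect_equal(res$cf, 1000)
  expect_equal(res$tier, "default_precautionary")
  expect_setequal(res$defaults, c("FF", "XF"))
  expect_equal(sum(grepl("defaulted to 1", res$trace)), 2)
})

test_that("resolution is deterministic for identical registry and query", {
  fx <- make_case_fixture(case_params())
  a <- resolve_factors("cu2o_p25_tio2", "freshwater", "FEP", fx$original$registry)
  b <- resolve_factors("cu2o_p25_tio2", "freshwater", "FEP", fx$original$registry)
  expect_identical(a, b)
})

test_that("characterization multiplies inventory by CF with conserved contributions", {
  flows <- rbind(
    flow_table("h2", "hydrogen", "product", unit = "g"),
    flow_table("nano_fw", "nano to freshwater", "elementary", phase = "nano",
               compartment = "freshwater", unit = "kg"))
  procs <- process_table("p1", "H2", "h2")
  ex <- rbind(exchange_table("p1", "h2", "output", 1, "g"),
              exchange_table("p1", "nano_fw", "output", 1e-3, "kg"))
  sys <- product_system(flows, procs, ex, c(h2 = 1))
  res <- characterize(solve_inventory(sys), tiny_registry(),
                      c(nano_fw = "nf"))
  expect_equal(res[["FEP.nano"]]$total, 3.443)
  expect_equal(res[["FEP.nano"]]$unit, "PAF.m3.d")
  expect_equal(sum(res[["FEP.nano"]]$contributions), res[["FEP.nano"]]$total)
  expect_equal(res[["HTP.bulk"]]$total, 0)
})

test_that("two emitting processes split contributions while totals add", {
  flows <- rbind(
    flow_table(c("a", "b"), c("a", "b"), "product", unit = "kg"),
    flow_table("nano_fw", "nano", "elementary", phase = "nano",
               compartment = "freshwater", unit = "kg"))
  procs <- rbind(process_table("pa", "pa", "a"), process_table("pb", "pb", "b"))
  ex <- rbind(
    exchange_table("pa", "a", "output", 1, "kg"),
    exchange_table("pa", "nano_fw", "output", 5e-4, "kg"),
    exchange_table("pb", "b", "output", 1, "kg"),
    exchange_table("pb", "a", "input", 1, "kg"),
    exchange_table("pb", "nano_fw", "output", 5e-4, "kg"))
  sys <- product_system(flows, procs, ex, c(b = 1))
  res <- characterize(solve_inventory(sys), tiny_registry(), c(nano_fw = "nf"))
  fep <- res[["FEP.nano"]]
  expect_equal(fep$total, 3.443)
  expect_equal(unname(fep$contributions / fep$total), c(0.5, 0.5))
})

test_that("characterization is additive and monotone in the inventory", {
  rs <- make_random_system(random_system_params(seed = 7, n_processes = 4))
  sys <- rs$system
  s1 <- sys; s1$f <- sys$f
  s2 <- sys; s2$f <- 2 * sys$f
  s3 <- sys; s3$f <- 3 * sys$f
  tot <- function(s) impact_totals(
    characterize(solve_inventory(s), rs$registry))
  t1 <- tot(s1); t2 <- tot(s2); t3 <- tot(s3)
  expect_equal(t3, t1 + t2, tolerance = 1e-12)
  expect_true(all(t2[c("GWP.bulk", "CED.bulk")] >=
                    t1[c("GWP.bulk", "CED.bulk")]))
})

test_that("empty inventory gives all-zero totals", {
  sys <- two_process_chain()
  sys$f[] <- 0
  res <- characterize(solve_inventory(sys), tiny_registry(),
                      c(nano_tio2_air = "nf"))
  expect_true(all(impact_totals(res) == 0))
})

test_that("unassigned nano flows error; uncharacterized bulk flows warn", {
  sys <- two_process_chain()
  expect_error(characterize(solve_inventory(sys), tiny_registry()),
               "nano_tio2_air")
  flows <- rbind(
    flow_table("h2", "hydrogen", "product", unit = "g"),
    flow_table("mystery", "mystery solvent", "elementary",
               compartment = "air", unit = "kg"))
  procs <- process_table("p1", "H2", "h2")
  ex <- rbind(exchange_table("p1", "h2", "output", 1, "g"),
              exchange_table("p1", "mystery", "output", 0.1, "kg"))
  sys2 <- product_system(flows, procs, ex, c(h2 = 1))
  expect_warning(res <- characterize(solve_inventory(sys2), tiny_registry()),
                 "mystery")
  expect_true("mystery" %in% res[["FEP.bulk"]]$uncharacterized)
})
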