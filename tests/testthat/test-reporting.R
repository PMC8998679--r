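test_that("small particle size raises the size hotspot with its design action", {
  fx <- make_case_fixture(case_params())
  sc <- screen_nanoform(fx$reference$nanoforms$p25_tio2)
  size <- sc[sc$parameter == "size", ]
  expect_equal(size$status, "hotspot")
  expect_equal(size$action, "Alter design to avoid NMs below this threshold")
})

test_that("a benign, fully characterized control raises no flags at all", {
  sc <- screen_nanoform(benign_nanoform(),
                        list(release_model("use", "control", c(air = 0))))
  expect_equal(sum(sc$status == "hotspot"), 0)
  expect_equal(sum(sc$status == "information_gap"), 0)
  # with no release model supplied, release behaviour is an open question
  sc2 <- screen_nanoform(benign_nanoform())
  expect_equal(sc2$status[sc2$parameter == "release_rate"], "information_gap")
  expect_equal(sum(sc2$status == "hotspot"), 0)
})

test_that("high aspect ratio triggers the HARN and fibrous-insoluble rules", {
  harn <- nanoform("fibre", "TiO2", particle_size = 80, surface_area = 30,
                   aspect_ratio = 6, solubility_class = "non_soluble",
                   coating_stability = "stable", persistence = "non_persistent",
                   reactivity = "low", agglomeration = "non_agglomerating",
                   ros = "no", exposure_route = "none")
  sc <- screen_nanoform(harn)
  expect_equal(sc$status[sc$parameter == "shape"], "hotspot")
  expect_equal(sc$action[sc$parameter == "shape"],
               "Alter design to avoid NMs with HARN")
  expect_equal(sc$status[sc$parameter == "solubility"], "hotspot")
})

test_that("unknown attributes surface as information gaps, not silent passes", {
  fx <- make_case_fixture(case_params())
  coated <- fx$original$nanoforms$cu2o_p25_tio2
  sc <- screen_nanoform(coated)
  expect_equal(sc$status[sc$parameter == "coating_stability"],
               "information_gap")
  expect_equal(sc$action[sc$parameter == "coating_stability"],
               "needs characterization")
})

test_that("shrinking particle size only adds the size flag", {
  base <- benign_nanoform()
  small <- base
  small$particle_size <- 20
  sc_base <- screen_nanoform(base)
  sc_small <- screen_nanoform(small)
  flagged <- function(sc) sc$parameter[sc$status == "hotspot"]
  expect_setequal(setdiff(flagged(sc_small), flagged(sc_base)), "size")
  expect_length(setdiff(flagged(sc_base), flagged(sc_small)), 0)
})

test_that("release-rate rule uses the summed stage fraction threshold", {
  nf <- benign_nanoform()
  high <- release_model("nm_manufacture", "control",
                        c(air = 0.004, sewer = 0.1))
  low <- release_model("nm_manufacture", "control", c(air = 0.001))
  rel_status <- function(sc) sc$status[sc$parameter == "release_rate"]
  expect_equal(rel_status(screen_nanoform(nf, list(high))), "hotspot")
  expect_equal(rel_status(screen_nanoform(nf, list(low))), "clear")
  expect_equal(rel_status(screen_nanoform(nf, list(low),
                                          release_threshold = 1e-4)),
               "hotspot")
  expect_equal(rel_status(screen_nanoform(nf)), "information_gap")
})

test_that("process hotspots rank contributions and flag dominance", {
  mk <- function(contrib) structure(list(
    indicator = "GWP", basis = "bulk", total = sum(contrib),
    unit = "kg CO2-eq", contributions = contrib), class = "impact_result")
  hot <- find_process_hotspots(mk(c(P1 = 0.9, P2 = 0.1)))[[1]]
  expect_equal(hot$ranking$process_id, c("P1", "P2"))
  expect_true(hot$dominant)
  expect_equal(hot$dominant_process, "P1")
  uniform <- find_process_hotspots(mk(c(a = 1, b = 1, c = 1, d = 1)))[[1]]
  expect_false(uniform$dominant)
  single <- find_process_hotspots(mk(c(only = 2)))[[1]]
  expect_true(single$dominant)
})

test_that("hotspot ranking is stable under input permutation with id tie-breaks", {
  contrib <- c(b = 0.2, a = 0.5, d = 0.2, c = 0.1)
  mk <- function(x) structure(list(indicator = "FEP", basis = "nano",
                                   total = sum(x), unit = "PAF.m3.d",
                                   contributions = x),
                              class = "impact_result")
  r1 <- find_process_hotspots(mk(contrib))[[1]]$ranking
  r2 <- find_process_hotspots(mk(contrib[c(3, 1, 4, 2)]))[[1]]$ranking
  expect_identical(r1, r2)
  expect_equal(r1$process_id, c("a", "b", "d", "c"))
})

test_that("methanol production dominates the bulk indicators of the case fixture", {
  fx <- make_case_fixture(case_params())
  res <- characterize(solve_inventory(fx$reference$system),
                      fx$reference$registry, fx$reference$assignment)
  hot <- find_process_hotspots(res)
  expect_true(hot[["GWP.bulk"]]$dominant)
  expect_equal(hot[["GWP.bulk"]]$dominant_process, "methanol_supply")
  expect_true(hot[["CED.bulk"]]$dominant)
})

test_that("system comparison detects trade-offs from Table-style totals", {
  rep <- compare_systems(c(GWP = 18.17, FEP = 15.08),
                         c(GWP = 9.28, FEP = 16.26))
  expect_equal(rep$table$verdict[rep$table$indicator == "GWP"], "better")
  expect_equal(rep$table$verdict[rep$table$indicator == "FEP"], "worse")
  expect_true(rep$trade_off_flag)
  expect_equal(rep$overall, "mixed")

  same <- compare_systems(c(GWP = 1, FEP = 2), c(GWP = 1, FEP = 2))
  expect_true(all(same$table$verdict == "equal"))
  expect_false(same$trade_off_flag)

  dom <- compare_systems(c(GWP = 2, CED = 3, HTP = 4, FEP = 5),
                         c(GWP = 1, CED = 2, HTP = 3, FEP = 4))
  expect_false(dom$trade_off_flag)
  expect_equal(dom$overall, "better")
})

test_that("swapping reference and original flips every verdict", {
  a <- c(GWP = 18.17, CED = 736.4, HTP = 1.04e-6, FEP = 2632.3)
  b <- c(GWP = 9.28, CED = 215.9, HTP = 5.34e-6, FEP = 9992.9)
  fwd <- compare_systems(a, b)
  rev <- compare_systems(b, a)
  flip <- c(better = "worse", worse = "better", equal = "equal")
  expect_equal(unname(flip[fwd$table$verdict]), rev$table$verdict)
  expect_equal(fwd$trade_off_flag, rev$trade_off_flag)
})

test_that("relative delta is reported as undefined when the reference is zero", {
  rep <- compare_systems(c(GWP = 0, FEP = 1), c(GWP = 2, FEP = 1))
  expect_true(is.na(rep$table$relative_delta[rep$table$indicator == "GWP"]))
  expect_error(compare_systems(c(GWP = 1), c(FEP = 1)), "different indicator")
})

test_that("heat maps are complete grids with resolution-derived CF tiers", {
  fx <- make_case_fixture(case_params())
  fw <- run_framework(fx$original$profile)
  maps <- build_heatmap(fw$trace, fw$plan,
                        list(fx$reference$system, fx$original$system),
                        fx$original$registry)
  lci <- maps$lci_map$cells
  cfm <- maps$cf_map$cells
  expect_equal(length(lci), nrow(lci) * ncol(lci))
  expect_false(anyNA(lci))
  expect_false(anyNA(cfm))
  expect_equal(cfm["cu2o_p25_tio2", "FEP"], "read_across")
  expect_equal(cfm["cu2o_p25_tio2", "HTP"], "literature")
  expect_equal(cfm["p25_tio2", "FEP"], "literature")
  expect_equal(lci["nano_coating", "HTP"], "measured_lab")
  expect_true(all(lci %in% data_tiers()))
})

test_that("a defaulted XF adds exactly one default_precautionary CF cell", {
  entries <- data.frame(
    nanoform_id = c("nf_full", "nf_full", "nf_noxf", "nf_noxf"),
    compartment = "freshwater", indicator = c("FEP", "HTP", "FEP", "HTP"),
    FF_days = 2, XF = c(0.5, 0.5, NA, 0.5), EF = 10, HEF = 1,
    source_tier = "literature", source_ref = "test", stringsAsFactors = FALSE)
  reg <- cf_registry(entries)
  plan <- data.frame(nanoform = rep(c("nf_full", "nf_noxf"), each = 1),
                     quantity = "cf", tier = "literature",
                     fallback = NA_character_, stringsAsFactors = FALSE)
  sys <- two_process_chain()
  maps <- build_heatmap(NULL, plan, sys, reg)
  expect_equal(sum(maps$cf_map$cells == "default_precautionary"), 1)
  expect_equal(maps$cf_map$cells["nf_noxf", "FEP"], "default_precautionary")
})

test_that("uncovered processes or unresolvable factors are reported as gaps", {
  fx <- make_case_fixture(case_params())
  fw <- run_framework(fx$original$profile)
  sys <- fx$reference$system
  sys$processes$data_tier[2] <- NA
  expect_error(build_heatmap(fw$trace, fw$plan, sys, fx$original$registry),
               "no data tier")
  plan_bad <- rbind(fw$plan,
                    data.frame(nanoform = "ghost", quantity = "cf",
                               tier = "literature", fallback = NA))
  expect_error(build_heatmap(fw$trace, plan_bad, fx$reference$system,
                             fx$original$registry), "ghost")
})
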