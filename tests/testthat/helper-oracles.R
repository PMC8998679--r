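# Independent linear-algebra oracle: cofactor-expansion determinant and
# adjugate-based solve, deliberately naive so it shares no code path with
# the package's LAPACK-backed solver. Only sane for n <= 6.

det_cofactor <- function(M) {
  n <- nrow(M)
  if (n == 1L) return(M[1, 1])
  total <- 0
  for (j in seq_len(n)) {
    minor <- M[-1, -j, drop = FALSE]
    total <- total + (-1)^(1 + j) * M[1, j] * det_cofactor(minor)
  }
  total
}

solve_adjugate <- function(A, f) {
  n <- nrow(A)
  d <- det_cofactor(A)
  x <- numeric(n)
  for (i in seq_len(n)) {
    Ai <- A
    Ai[, i] <- f
    x[i] <- det_cofactor(Ai) / d
  }
  stats::setNames(x, colnames(A))
}

# minimal two-process chain: catalyst production feeding hydrogen production
two_process_chain <- function() {
  flows <- rbind(
    flow_table("h2", "hydrogen", "product", unit = "g"),
    flow_table("catalyst", "catalyst", "product", unit = "kg"),
    flow_table("nano_tio2_air", "nano-TiO2 to air", "elementary",
               phase = "nano", compartment = "air", unit = "kg"))
  processes <- rbind(
    process_table("cat_prod", "catalyst production", "catalyst",
                  data_tier = "measured_lab"),
    process_table("h2_prod", "hydrogen production", "h2",
                  data_tier = "measured_lab"))
  exchanges <- rbind(
    exchange_table("cat_prod", "catalyst", "output", 1, "kg"),
    exchange_table("cat_prod", "nano_tio2_air", "output", 0.004, "kg"),
    exchange_table("h2_prod", "h2", "output", 1, "g"),
    exchange_table("h2_prod", "catalyst", "input", 0.002, "kg"))
  product_system(flows, processes, exchanges, demand = c(h2 = 1))
}

# registry with literature FEP (cf) and zero HTP entries for one nanoform
tiny_registry <- function(cf = 3443, compartment = "freshwater") {
  cf_registry(data.frame(
    nanoform_id = "nf", compartment = compartment,
    indicator = c("FEP", "HTP"), CF = c(cf, 0),
    CF_unit = c("PAF.d.m3/kg", "cases.d/kg"), source_tier = "literature",
    source_ref = "test", stringsAsFactors = FALSE))
}

# benign control nanoform: every screening attribute known and unproblematic
benign_nanoform <- function() {
  nanoform("control", "TiO2", particle_size = 100, surface_area = 10,
           aspect_ratio = 1, solubility_class = "soluble",
           coating_stability = "stable", persistence = "non_persistent",
           reactivity = "low", agglomeration = "non_agglomerating",
           ros = "no", exposure_route = "none")
}

# straight-line arithmetic recomputation of the case fixture's indicator
# totals from its parameters; shares no code with the matrix pipeline
hand_case_totals <- function(p, coated) {
  shrink <- if (coated) 1 - p$efficiency_gain else 1
  st <- p$sewer_transfer
  fr <- p$release_fractions
  meth <- p$methanol_per_g_h2 * shrink
  if (coated) {
    cat_coated <- p$catalyst_per_g_h2 * shrink
    cat_p25 <- cat_coated * p$p25_per_kg_coated
    elec <- cat_p25 * p$electricity_per_kg_catalyst +
      cat_coated * p$electricity_per_kg_coating
  } else {
    cat_p25 <- p$catalyst_per_g_h2
    elec <- cat_p25 * p$electricity_per_kg_catalyst
  }
  gwp <- elec * p$co2_per_kwh + meth * p$co2_per_kg_methanol
  ced <- elec * p$primary_energy_per_kwh + meth * p$primary_energy_per_kg_methanol

  released <- function(frac) sum(frac[names(frac) == "air"]) +
    st * sum(frac[names(frac) == "sewer"]) +
    sum(frac[names(frac) == "freshwater"])
  p25_mass <- cat_p25 * released(fr$nm_manufacture)
  if (coated) {
    coated_mass <- cat_coated * (released(fr$nano_coating) +
                                   released(fr$use) + released(fr$disposal))
  } else {
    p25_mass <- p25_mass + cat_p25 * (released(fr$use) + released(fr$disposal))
    coated_mass <- 0
  }
  fep <- 3443 * p25_mass + 17700 * coated_mass
  htp <- 222 * p25_mass + 0.99 * coated_mass
  c(GWP = gwp, CED = ced, HTP = htp, FEP = fep)
}
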