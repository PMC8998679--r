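#' Parameters of the photocatalytic-hydrogen case fixture
#'
#' Defines the synthetic scenario the package ships for testing and
#' demonstration: photocatalytic hydrogen production from water and
#' sunlight with methanol as sacrificial scavenger, comparing an uncoated
#' nano-TiO2 catalyst (reference system) against a Cu2O-coated variant
#' with better photocatalytic activity (original system). The registry
#' carries the published toxicity characterization factors of the two
#' nanoforms; all inventory magnitudes are synthetic, chosen to be
#' plausible for a lab-scale photoreactor, and are NOT measured values.
#'
#' Releases of the handled nanomaterial occur during catalyst manufacture
#' and nano-coating (to air and sewer) and at end-of-life catalyst
#' disposal (to freshwater; set `disposal` to zero fractions to model a
#' leak-free recycling filtration chain). Sewer loads are routed to
#' freshwater with `sewer_transfer` (default 1, precautionary).
#'
#' @param seed Integer seed for anything stochastic downstream.
#' @param functional_unit_g_h2 Functional unit: grams of hydrogen (1 g).
#' @param catalyst_per_g_h2 Catalyst demand of the reference photoreactor,
#'   kg per g H2.
#' @param methanol_per_g_h2 Methanol (scavenger) demand, kg per g H2;
#'   generous, as lab-scale runs over-dose the scavenger.
#' @param electricity_per_kg_catalyst Electricity demand of nano-TiO2
#'   manufacture, kWh per kg.
#' @param electricity_per_kg_coating Additional electricity demand of the
#'   gas-phase coating step, kWh per kg coated catalyst.
#' @param p25_per_kg_coated Uncoated catalyst consumed per kg of coated
#'   catalyst.
#' @param co2_per_kwh,primary_energy_per_kwh Background electricity:
#'   kg CO2 and MJ primary energy per kWh.
#' @param co2_per_kg_methanol,primary_energy_per_kg_methanol Background
#'   methanol production: kg CO2 and MJ primary energy per kg.
#' @param methanol_fugitive_fraction Fugitive bulk methanol emission to air
#'   per kg produced.
#' @param release_fractions Named list of per-stage compartment release
#'   fractions (`nm_manufacture`, `nano_coating`, `use`, `disposal`).
#' @param efficiency_gain Fractional reduction of the H2 process's
#'   catalyst, energy and methanol demand achieved by the coated catalyst
#'   (< 1).
#' @param sewer_transfer Sewer-to-freshwater transfer coefficient (0-1).
#' @return A `case_params` list.
#' @export
case_params <- function(seed = 1L,
                        functional_unit_g_h2 = 1,
                        catalyst_per_g_h2 = 0.002,
                        methanol_per_g_h2 = 0.1,
                        electricity_per_kg_catalyst = 50,
                        electricity_per_kg_coating = 30,
                        p25_per_kg_coated = 1,
                        co2_per_kwh = 0.5,
                        primary_energy_per_kwh = 10.8,
                        co2_per_kg_methanol = 0.7,
                        primary_energy_per_kg_methanol = 35,
                        methanol_fugitive_fraction = 0.001,
                        release_fractions = list(
                          nm_manufacture = c(air = 0.004, sewer = 0.1),
                          nano_coating = c(air = 0.004, sewer = 0.1),
                          use = c(air = 0, sewer = 0),
                          disposal = c(freshwater = 0.05)
                        ),
                        efficiency_gain = 0.45,
                        sewer_transfer = 1) {
  p <- list(seed = as.integer(seed),
            functional_unit_g_h2 = functional_unit_g_h2,
            catalyst_per_g_h2 = catalyst_per_g_h2,
            methanol_per_g_h2 = methanol_per_g_h2,
            electricity_per_kg_catalyst = electricity_per_kg_catalyst,
            electricity_per_kg_coating = electricity_per_kg_coating,
            p25_per_kg_coated = p25_per_kg_coated,
            co2_per_kwh = co2_per_kwh,
            primary_energy_per_kwh = primary_energy_per_kwh,
            co2_per_kg_methanol = co2_per_kg_methanol,
            primary_energy_per_kg_methanol = primary_energy_per_kg_methanol,
            methanol_fugitive_fraction = methanol_fugitive_fraction,
            release_fractions = release_fractions,
            efficiency_gain = efficiency_gain,
            sewer_transfer = sewer_transfer)
  for (nm in setdiff(names(p), c("seed", "release_fractions")))
    assert_scalar_number(p[[nm]], nm, min = 0)
  if (p$efficiency_gain >= 1) stopf("efficiency_gain must be < 1")
  assert_scalar_number(p$sewer_transfer, "sewer_transfer", min = 0, max = 1)
  for (st in names(release_fractions)) {
    fr <- release_fractions[[st]]
    if (length(fr) && (any(fr < 0 | fr > 1) || sum(fr) > 1))
      stopf("release fractions for stage '%s' out of range", st)
  }
  structure(p, class = "case_params")
}

# registry shared by both systems of the case fixture: published CFs for
# the two nanoforms plus the CuO surrogate used for read-across, synthetic
# bulk and GWP/CED multipliers. The same nano CF is applied to air and
# freshwater emissions (the source values are not compartment-resolved).
case_registry <- function(params) {
  comp <- c("air", "freshwater")
  entries <- rbind(
    data.frame(nanoform_id = "p25_tio2", compartment = comp, indicator = "FEP",
               CF = 3443, CF_unit = "PAF.d.m3/kg",
               source_tier = "literature",
               source_ref = "freshwater fate/ecotox literature for nano-TiO2",
               stringsAsFactors = FALSE),
    data.frame(nanoform_id = "p25_tio2", compartment = comp, indicator = "HTP",
               CF = 222, CF_unit = "cases.d/kg",
               source_tier = "literature",
               source_ref = "human toxicity literature for nano-TiO2",
               stringsAsFactors = FALSE),
    data.frame(nanoform_id = "cu2o_p25_tio2", compartment = comp,
               indicator = "HTP", CF = 0.99, CF_unit = "cases.d/kg",
               source_tier = "literature",
               source_ref = "human toxicity literature for the coated form",
               stringsAsFactors = FALSE),
    data.frame(nanoform_id = "cuo_nm", compartment = comp, indicator = "FEP",
               CF = 17700, CF_unit = "PAF.d.m3/kg",
               source_tier = "literature",
               source_ref = "copper oxide NM fate/effect literature",
               stringsAsFactors = FALSE)
  )
  surrogates <- data.frame(
    target_id = "cu2o_p25_tio2", surrogate_id = "cuo_nm",
    rationale = "no ecotoxicity data for the Cu2O-coated form; copper oxide NM data read across as nanoforms of the same substance class",
    stringsAsFactors = FALSE)
  bulk_factors <- data.frame(
    substance = c("methanol", "methanol"), compartment = c("air", "air"),
    indicator = c("FEP", "HTP"), cf = c(0.3, 1e-6),
    unit = c("PAF.d.m3/kg", "cases.d/kg"), stringsAsFactors = FALSE)
  gwp_ced <- data.frame(
    flow_id = c("co2_air", "primary_energy"),
    indicator = c("GWP", "CED"),
    factor = c(1, -1),  # draws are negative in B, so -1 yields positive MJ
    unit = c("kg CO2-eq/kg", "MJ/MJ"), stringsAsFactors = FALSE)
  nanoforms <- list(
    p25_tio2 = nanoform("p25_tio2", "TiO2", particle_size = 20,
                        surface_area = 50, aspect_ratio = 1,
                        solubility_class = "non_soluble",
                        persistence = "persistent",
                        agglomeration = "agglomerating",
                        exposure_route = "inhalation"),
    cu2o_p25_tio2 = nanoform("cu2o_p25_tio2", "TiO2", coating = "Cu2O",
                             particle_size = 20, surface_area = 50,
                             aspect_ratio = 1,
                             solubility_class = "non_soluble",
                             coating_stability = "unknown",
                             persistence = "persistent",
                             agglomeration = "agglomerating",
                             exposure_route = "inhalation",
                             ros = "yes"))
  cf_registry(entries, surrogates, bulk_factors, gwp_ced, nanoforms)
}

case_release_models <- function(params, coated) {
  fr <- params$release_fractions
  keep <- function(x) x[x > 0]
  mods <- list(
    nm_manufacture = release_model("nm_manufacture", "p25_tio2",
                                   keep(fr$nm_manufacture)),
    use = release_model("use",
                        if (coated) "cu2o_p25_tio2" else "p25_tio2",
                        keep(fr$use)),
    disposal = release_model("disposal",
                             if (coated) "cu2o_p25_tio2" else "p25_tio2",
                             keep(fr$disposal))
  )
  if (coated)
    mods$nano_coating <- release_model("nano_coating", "cu2o_p25_tio2",
                                       keep(fr$nano_coating))
  mods
}

# emissions of a stage per unit handled mass, as exchange rows
release_exchanges <- function(process_id, handled_mass, model, flow_prefix,
                              sewer_transfer) {
  em <- route_sewer(apply_release(handled_mass, model), sewer_transfer)
  em <- em[em > 0]
  if (!length(em)) return(NULL)
  exchange_table(process_id, paste0(flow_prefix, "_", names(em)),
                 "output", as.numeric(em), "kg")
}

case_system <- function(params, coated) {
  p <- params
  st <- p$sewer_transfer
  shrink <- if (coated) 1 - p$efficiency_gain else 1

  flows <- rbind(
    flow_table("h2", "hydrogen", "product", unit = "g"),
    flow_table("catalyst_p25", "nano-TiO2 catalyst", "product", unit = "kg"),
    flow_table("electricity", "electricity", "product", unit = "kWh"),
    flow_table("methanol", "methanol", "product", unit = "kg"),
    flow_table("co2_air", "carbon dioxide", "elementary",
               compartment = "air", unit = "kg", substance = "CO2"),
    flow_table("primary_energy", "primary energy carriers", "elementary",
               compartment = "soil", unit = "MJ", substance = "primary energy"),
    flow_table("methanol_air", "methanol (fugitive)", "elementary",
               compartment = "air", unit = "kg", substance = "methanol"),
    flow_table("nano_p25_air", "nano-TiO2 to air", "elementary",
               phase = "nano", compartment = "air", unit = "kg",
               substance = "TiO2"),
    flow_table("nano_p25_freshwater", "nano-TiO2 to freshwater", "elementary",
               phase = "nano", compartment = "freshwater", unit = "kg",
               substance = "TiO2")
  )
  if (coated) {
    flows <- rbind(flows,
      flow_table("catalyst_coated", "Cu2O-coated nano-TiO2 catalyst",
                 "product", unit = "kg"),
      flow_table("nano_coated_air", "coated nano-TiO2 to air", "elementary",
                 phase = "nano", compartment = "air", unit = "kg",
                 substance = "TiO2"),
      flow_table("nano_coated_freshwater", "coated nano-TiO2 to freshwater",
                 "elementary", phase = "nano", compartment = "freshwater",
                 unit = "kg", substance = "TiO2"))
  }

  rel <- case_release_models(p, coated)

  processes <- rbind(
    process_table("electricity_supply", "grid electricity supply",
                  "electricity", data_tier = "database"),
    process_table("methanol_supply", "methanol production",
                  "methanol", data_tier = "database"),
    process_table("p25_manufacture", "nano-TiO2 manufacture",
                  "catalyst_p25", data_tier = "measured_industrial"),
    process_table("h2_photocatalysis",
                  if (coated) "H2 photocatalysis (coated catalyst)"
                  else "H2 photocatalysis", "h2",
                  data_tier = "measured_lab")
  )
  if (coated)
    processes <- rbind(processes,
      process_table("nano_coating", "Cu2O nano-coating (gas phase)",
                    "catalyst_coated", data_tier = "measured_lab"))

  ex <- rbind(
    exchange_table("electricity_supply", "electricity", "output", 1, "kWh"),
    exchange_table("electricity_supply", "co2_air", "output",
                   p$co2_per_kwh, "kg"),
    exchange_table("electricity_supply", "primary_energy", "input",
                   p$primary_energy_per_kwh, "MJ"),
    exchange_table("methanol_supply", "methanol", "output", 1, "kg"),
    exchange_table("methanol_supply", "co2_air", "output",
                   p$co2_per_kg_methanol, "kg"),
    exchange_table("methanol_supply", "primary_energy", "input",
                   p$primary_energy_per_kg_methanol, "MJ"),
    exchange_table("methanol_supply", "methanol_air", "output",
                   p$methanol_fugitive_fraction, "kg"),
    exchange_table("p25_manufacture", "catalyst_p25", "output", 1, "kg"),
    exchange_table("p25_manufacture", "electricity", "input",
                   p$electricity_per_kg_catalyst, "kWh"),
    release_exchanges("p25_manufacture", 1, rel$nm_manufacture, "nano_p25", st)
  )
  cat_flow <- if (coated) "catalyst_coated" else "catalyst_p25"
  cat_amount <- p$catalyst_per_g_h2 * shrink
  ex <- rbind(ex,
    exchange_table("h2_photocatalysis", "h2", "output", 1, "g"),
    exchange_table("h2_photocatalysis", cat_flow, "input", cat_amount, "kg"),
    exchange_table("h2_photocatalysis", "methanol", "input",
                   p$methanol_per_g_h2 * shrink, "kg"),
    release_exchanges("h2_photocatalysis", cat_amount, rel$use,
                      if (coated) "nano_coated" else "nano_p25", st),
    release_exchanges("h2_photocatalysis", cat_amount, rel$disposal,
                      if (coated) "nano_coated" else "nano_p25", st))
  if (coated) {
    ex <- rbind(ex,
      exchange_table("nano_coating", "catalyst_coated", "output", 1, "kg"),
      exchange_table("nano_coating", "catalyst_p25", "input",
                     p$p25_per_kg_coated, "kg"),
      exchange_table("nano_coating", "electricity", "input",
                     p$electricity_per_kg_coating, "kWh"),
      release_exchanges("nano_coating", 1, rel$nano_coating, "nano_coated", st))
  }

  demand <- c(h2 = p$functional_unit_g_h2)
  list(system = product_system(flows, processes, ex, demand),
       release_models = rel)
}

case_profile <- function(coated) {
  nfs <- list(
    p25_tio2 = nanoform_availability(
      tox_data = TRUE, tox_tier = "literature",
      fate_data = TRUE, fate_tier = "literature")
  )
  if (coated)
    nfs$cu2o_p25_tio2 <- nanoform_availability(read_across_possible = TRUE)
  availability_profile(
    reference_product_exists = TRUE,
    process_level_data_available = TRUE,
    process_data_tier = "measured_lab",
    system_boundaries_known = TRUE,
    release_rate_known = TRUE,
    release_tier = "literature",
    nanoforms = nfs)
}

case_assignment <- function(coated) {
  a <- c(nano_p25_air = "p25_tio2", nano_p25_freshwater = "p25_tio2")
  if (coated)
    a <- c(a, nano_coated_air = "cu2o_p25_tio2",
           nano_coated_freshwater = "cu2o_p25_tio2")
  a
}

#' Generate the case-study-shaped fixture
#'
#' Builds the full paired scenario: the reference system (uncoated
#' nano-TiO2 photocatalyst) and the original system (Cu2O-coated catalyst
#' with improved photocatalytic activity), each with its product system,
#' shared characterization registry, data-availability profile, release
#' models and nano-flow assignment. Deterministic given the parameters.
#'
#' @param params A [case_params()] list.
#' @return A `case_fixture`: `reference` and `original` (each with
#'   `system`, `registry`, `profile`, `release_models`, `assignment`,
#'   `nanoforms`) plus `params`.
#' @examples
#' fx <- make_case_fixture(case_params())
#' lci <- solve_inventory(fx$reference$system)
#' characterize(lci, fx$reference$registry, fx$reference$assignment)
#' @export
make_case_fixture <- function(params = case_params()) {
  stopifnot(inherits(params, "case_params"))
  registry <- case_registry(params)
  side <- function(coated) {
    cs <- case_system(params, coated)
    list(system = cs$system, registry = registry,
         profile = case_profile(coated),
         release_models = cs$release_models,
         assignment = case_assignment(coated),
         nanoforms = registry$nanoforms)
  }
  structure(list(reference = side(FALSE), original = side(TRUE),
                 params = params),
            class = "case_fixture")
}

#' Random-system generation parameters
#'
#' @param seed Integer seed.
#' @param n_processes Number of processes (and product flows), <= 8.
#' @param n_elementary Number of elementary flows.
#' @param sparsity Probability that a process consumes another product.
#' @param magnitude Range of elementary-exchange magnitudes.
#' @return A `random_system_params` list.
#' @export
random_system_params <- function(seed = 1L, n_processes = 4L,
                                 n_elementary = 3L, sparsity = 0.5,
                                 magnitude = c(0.1, 2)) {
  if (n_processes < 1L || n_processes > 8L)
    stopf("n_processes must be between 1 and 8")
  assert_scalar_number(sparsity, "sparsity", min = 0, max = 1)
  structure(list(seed = as.integer(seed), n_processes = as.integer(n_processes),
                 n_elementary = as.integer(n_elementary), sparsity = sparsity,
                 magnitude = magnitude),
            class = "random_system_params")
}

#' Generate a random well-conditioned product system
#'
#' Draws a random linear production chain whose technology matrix is
#' column diagonally dominant (hence invertible) and a random emission
#' pattern, plus a small synthetic registry of GWP/CED multipliers. Used
#' for property-based testing of the solver and characterization
#' additivity; deterministic given the seed.
#'
#' @param params A [random_system_params()] list.
#' @return List with `system` (a [product_system()]) and `registry`
#'   (a [cf_registry()]).
#' @export
make_random_system <- function(params = random_system_params()) {
  stopifnot(inherits(params, "random_system_params"))
  n <- params$n_processes
  m <- params$n_elementary
  local_seed(params$seed, {
    prod_ids <- sprintf("prod_%d", seq_len(n))
    elem_ids <- sprintf("elem_%d", seq_len(m))
    flows <- rbind(
      flow_table(prod_ids, prod_ids, "product", unit = "kg"),
      flow_table(elem_ids, elem_ids, "elementary",
                 compartment = rep_len(c("air", "freshwater", "soil"), m),
                 unit = "kg"))
    processes <- process_table(sprintf("proc_%d", seq_len(n)),
                               sprintf("process %d", seq_len(n)),
                               prod_ids, data_tier = "database")
    ex <- exchange_table(processes$process_id, prod_ids, "output",
                         stats::runif(n, 1, 2), "kg")
    for (i in seq_len(n)) {
      others <- setdiff(seq_len(n), i)
      take <- others[stats::runif(length(others)) < params$sparsity]
      if (length(take)) {
        raw <- stats::runif(length(take))
        # scale inputs so each column stays strictly diagonally dominant
        amounts <- raw / sum(raw) * ex$amount[i] * stats::runif(1, 0.2, 0.8)
        ex <- rbind(ex, exchange_table(processes$process_id[i],
                                       prod_ids[take], "input", amounts, "kg"))
      }
      emit <- stats::runif(m) < 0.7
      if (any(emit)) {
        ex <- rbind(ex, exchange_table(
          processes$process_id[i], elem_ids[emit], "output",
          stats::runif(sum(emit), params$magnitude[1], params$magnitude[2]),
          "kg"))
      }
    }
    demand <- stats::setNames(stats::runif(1, 0.5, 2),
                              prod_ids[sample.int(n, 1)])
    gwp_ced <- rbind(
      data.frame(flow_id = elem_ids, indicator = "GWP",
                 factor = stats::runif(m, 0, 2), unit = "kg CO2-eq/kg",
                 stringsAsFactors = FALSE),
      data.frame(flow_id = elem_ids, indicator = "CED",
                 factor = stats::runif(m, 0, 5), unit = "MJ/kg",
                 stringsAsFactors = FALSE))
    registry <- cf_registry(
      entries = data.frame(nanoform_id = "synthetic_nf", compartment = "freshwater",
                           indicator = "FEP", EF = stats::runif(1, 1, 100),
                           source_tier = "assumption",
                           source_ref = "synthetic", stringsAsFactors = FALSE),
      gwp_ced_factors = gwp_ced)
    list(system = product_system(flows, processes, ex, demand),
         registry = registry)
  })
}
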