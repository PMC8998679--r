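#' Data availability for a single nanoform
#'
#' Answers to the per-nanoform questions of the stepwise framework: do
#' nano-toxicological data exist (effect factors), is there a usable
#' database entry, do fate data exist, and is read-across to another
#' nanoform of the same substance possible?
#'
#' @param tox_data Do nano-toxicological (effect) data exist?
#' @param tox_tier Provenance tier of those data (required when
#'   `tox_data` is `TRUE`).
#' @param exposure_data Do measured/modelled exposure factors exist?
#' @param exposure_tier Tier of the exposure data.
#' @param fate_data Do fate data (residence times) exist?
#' @param fate_tier Tier of the fate data.
#' @param database_entry Does a nano-database entry exist?
#' @param read_across_possible Is read-across to a characterized nanoform
#'   possible?
#' @return A `nanoform_availability` object.
#' @export
nanoform_availability <- function(tox_data = FALSE, tox_tier = NA_character_,
                                  exposure_data = FALSE,
                                  exposure_tier = NA_character_,
                                  fate_data = FALSE, fate_tier = NA_character_,
                                  database_entry = FALSE,
                                  read_across_possible = FALSE) {
  assert_flag(tox_data, "tox_data")
  assert_flag(exposure_data, "exposure_data")
  assert_flag(fate_data, "fate_data")
  assert_flag(database_entry, "database_entry")
  assert_flag(read_across_possible, "read_across_possible")
  if (tox_data && is.na(tox_tier))
    stopf("tox_tier required when tox_data is TRUE")
  if (exposure_data && is.na(exposure_tier))
    stopf("exposure_tier required when exposure_data is TRUE")
  if (fate_data && is.na(fate_tier))
    stopf("fate_tier required when fate_data is TRUE")
  for (t in c(tox_tier, exposure_tier, fate_tier))
    if (!is.na(t)) tier_rank(t)
  structure(list(tox_data = tox_data, tox_tier = tox_tier,
                 exposure_data = exposure_data, exposure_tier = exposure_tier,
                 fate_data = fate_data, fate_tier = fate_tier,
                 database_entry = database_entry,
                 read_across_possible = read_across_possible),
            class = "nanoform_availability")
}

#' Data-availability profile for the stepwise framework
#'
#' The complete, explicit set of answers the decision engine consumes. No
#' nulls are allowed: every question of the framework must be answered so
#' the resulting decision trace is deterministic.
#'
#' @param reference_product_exists Does a commercial reference product with
#'   the same function exist?
#' @param process_level_data_available Can process-level production data be
#'   collected? When `FALSE`, the assessment falls back to green-chemistry
#'   KPIs.
#' @param process_data_tier Tier of the process-level data.
#' @param system_boundaries_known Are the original system boundaries known?
#' @param release_rate_known Is the expected nanomaterial release rate
#'   known?
#' @param release_tier Tier of the release data.
#' @param nanoforms Named list of [nanoform_availability()] objects, one
#'   per nanoform in the system.
#' @return An `availability_profile` object.
#' @export
availability_profile <- function(reference_product_exists,
                                 process_level_data_available,
                                 process_data_tier = "measured_lab",
                                 system_boundaries_known,
                                 release_rate_known,
                                 release_tier = "literature",
                                 nanoforms = list()) {
  assert_flag(reference_product_exists, "reference_product_exists")
  assert_flag(process_level_data_available, "process_level_data_available")
  assert_flag(system_boundaries_known, "system_boundaries_known")
  assert_flag(release_rate_known, "release_rate_known")
  tier_rank(process_data_tier)
  tier_rank(release_tier)
  if (length(nanoforms)) {
    if (is.null(names(nanoforms)) || any(!nzchar(names(nanoforms))))
      stopf("nanoforms must be a named list")
    for (nf in nanoforms)
      if (!inherits(nf, "nanoform_availability"))
        stopf("each nanoform entry must be a nanoform_availability()")
  }
  if (!length(nanoforms) && release_rate_known)
    stopf("contradictory profile: release-rate data declared but no nanoform is")
  structure(list(reference_product_exists = reference_product_exists,
                 process_level_data_available = process_level_data_available,
                 process_data_tier = process_data_tier,
                 system_boundaries_known = system_boundaries_known,
                 release_rate_known = release_rate_known,
                 release_tier = release_tier,
                 nanoforms = nanoforms),
            class = "availability_profile")
}

#' Run the stepwise assessment framework
#'
#' Walks the two-part framework deterministically over a data-availability
#' profile: a preliminary assessment (concept design, steps 1-5) deciding
#' whether a prospective LCA is feasible at all, and — when it is — the
#' system-level cascade (steps 6-12 and 16) that assigns a provenance tier
#' to every required quantity, falling back tier by tier (database,
#' read-across, bulk proxy, precautionary default) when data are missing.
#' If process-level data cannot be collected or the system boundaries are
#' unknown, the assessment drops to green-chemistry KPIs instead.
#'
#' @param profile An [availability_profile()].
#' @return A `framework_result` with `mode` (`"kpi_only"` or
#'   `"prospective_lca"`), `plan` (a `data.frame` assigning a tier to every
#'   required quantity) and `trace` (the ordered decision trace).
#' @export
run_framework <- function(profile) {
  stopifnot(inherits(profile, "availability_profile"))
  rows <- list()
  add <- function(step, question, answer, action, fallback = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      step = step, question = question, answer = answer, action = action,
      fallback = fallback, stringsAsFactors = FALSE)
  }

  add(1L, "Define NM functionality; does a reference product exist?",
      if (profile$reference_product_exists) "yes" else "no",
      if (profile$reference_product_exists)
        "reference product identified; gather its data" else
        "no comparable product; proceed directly to process-data check")
  if (profile$reference_product_exists) {
    add(2L, "Gather reference-system data from databases/literature",
        "yes", "reference inventory collected")
    add(3L, "Perform LCA of the reference system", "yes",
        "reference system assessed")
  }
  add(4L, "Can process-level data be collected?",
      if (profile$process_level_data_available) "yes" else "no",
      if (profile$process_level_data_available)
        sprintf("process inventory at tier %s", profile$process_data_tier) else
        "compute green-chemistry KPIs instead",
      if (!profile$process_level_data_available) "kpi_estimation" else NA_character_)

  kpi_plan <- data.frame(nanoform = NA_character_, quantity = "kpis",
                         tier = "measured_lab",
                         fallback = "green-chemistry KPI estimation",
                         stringsAsFactors = FALSE)

  if (!profile$process_level_data_available) {
    add(5L, "Estimate green-chemistry KPIs for the manufacturing batch",
        "yes", "KPI-only assessment", "kpi_estimation")
    return(framework_result("kpi_only", kpi_plan, do.call(rbind, rows)))
  }

  add(6L, "Are the original system boundaries known?",
      if (profile$system_boundaries_known) "yes" else "no",
      if (profile$system_boundaries_known)
        "life-cycle stages identified" else "estimation of KPIs",
      if (!profile$system_boundaries_known) "kpi_estimation" else NA_character_)
  if (!profile$system_boundaries_known)
    return(framework_result("kpi_only", kpi_plan, do.call(rbind, rows)))

  plan <- list()
  addq <- function(nanoform, quantity, tier, fallback = NA_character_) {
    plan[[length(plan) + 1L]] <<- data.frame(
      nanoform = nanoform, quantity = quantity, tier = tier,
      fallback = fallback, stringsAsFactors = FALSE)
  }

  if (profile$release_rate_known) {
    add(7L, "What is the expected release rate of the NM?", "yes",
        sprintf("release fractions per stage/compartment at tier %s",
                profile$release_tier))
    addq(NA_character_, "release", profile$release_tier)
  } else {
    add(7L, "What is the expected release rate of the NM?", "no",
        "build an LCI based on bulk material flows", "bulk_proxy")
    addq(NA_character_, "release", "bulk_proxy",
         "Build an LCI based on bulk material flows")
  }

  nf_names <- names(profile$nanoforms)
  effect_tier <- stats::setNames(character(length(nf_names)), nf_names)
  fate_tier <- stats::setNames(character(length(nf_names)), nf_names)

  for (nm in nf_names) {
    nf <- profile$nanoforms[[nm]]
    add(8L, sprintf("Do nano-toxicological data exist for %s?", nm),
        if (nf$tox_data) "yes" else "no",
        if (nf$tox_data)
          sprintf("collect EF/HEF at tier %s", nf$tox_tier) else
          "try nano-databases (step 9)",
        if (!nf$tox_data) "database" else NA_character_)
  }
  for (nm in nf_names) {
    nf <- profile$nanoforms[[nm]]
    if (nf$tox_data) {
      effect_tier[nm] <- nf$tox_tier
      add(9L, sprintf("Can nano-databases be used for %s?", nm),
          "not needed", "effect data already collected")
    } else if (nf$database_entry) {
      effect_tier[nm] <- "database"
      add(9L, sprintf("Can nano-databases be used for %s?", nm), "yes",
          "collect EF/XF from a nano-database")
    } else if (nf$read_across_possible) {
      effect_tier[nm] <- "read_across"
      add(9L, sprintf("Can nano-databases be used for %s?", nm), "no",
          "use read-across method", "read_across")
    } else {
      effect_tier[nm] <- "bulk_proxy"
      add(9L, sprintf("Can nano-databases be used for %s?", nm), "no",
          "no effect data at any tier: build an LCI based on bulk material flows",
          "bulk_proxy")
    }
    # exposure factor: measured, database, else precautionary XF = 1
    if (nf$exposure_data) {
      addq(nm, "exposure", nf$exposure_tier)
    } else if (nf$database_entry) {
      addq(nm, "exposure", "database")
    } else {
      addq(nm, "exposure", "default_precautionary",
           "XF set to 1 (precautionary)")
    }
    addq(nm, "effect", effect_tier[nm],
         if (effect_tier[nm] %in% c("read_across", "bulk_proxy"))
           "per step-9 fallback" else NA_character_)
  }
  for (nm in nf_names) {
    nf <- profile$nanoforms[[nm]]
    if (nf$fate_data) {
      fate_tier[nm] <- nf$fate_tier
      add(10L, sprintf("Do fate data exist for %s?", nm), "yes",
          sprintf("fate factor at tier %s", nf$fate_tier))
      addq(nm, "fate", nf$fate_tier)
    } else if (nf$read_across_possible) {
      fate_tier[nm] <- "read_across"
      add(10L, sprintf("Do fate data exist for %s?", nm), "no",
          "read across fate data from a surrogate nanoform", "read_across")
      addq(nm, "fate", "read_across", "Use read-across method")
    } else {
      fate_tier[nm] <- "default_precautionary"
      add(10L, sprintf("Do fate data exist for %s?", nm), "no",
          "FF set to 1 (precautionary)", "default_precautionary")
      addq(nm, "fate", "default_precautionary", "FF set to 1 (precautionary)")
    }
    addq(nm, "cf", worse_tier(effect_tier[nm], fate_tier[nm]))
  }

  add(11L, "Build the life cycle inventory",
      "yes", sprintf("combine background (bulk) and foreground (bulk + nano) flows at tier %s",
                     profile$process_data_tier))
  addq(NA_character_, "lci_flows", profile$process_data_tier)
  add(12L, "Preliminary safety assessment", "yes",
      "record hazard notes for the pristine NM and bulk analogues")
  add(13L, "Steps 13-15", NA_character_,
      "not modelled: not enumerated in the framework description")
  add(16L, "Scaling up", NA_character_,
      "data need: good knowledge of thermodynamics and efficiencies for larger-scale equipment")

  framework_result("prospective_lca", do.call(rbind, plan), do.call(rbind, rows))
}

framework_result <- function(mode, plan, trace) {
  rownames(plan) <- NULL
  rownames(trace) <- NULL
  structure(list(mode = mode, plan = plan, trace = trace),
            class = "framework_result")
}

#' @export
print.framework_result <- function(x, ...) {
  cat(sprintf("<framework_result> mode: %s; %d plan row(s), %d trace row(s)\n",
              x$mode, nrow(x$plan), nrow(x$trace)))
  invisible(x)
}

#' Format a decision trace as readable text
#'
#' @param trace The `trace` data.frame of a [run_framework()] result.
#' @return Character vector, one line per decision step.
#' @export
format_trace <- function(trace) {
  vapply(seq_len(nrow(trace)), function(i) {
    r <- trace[i, ]
    fb <- if (!is.na(r$fallback)) sprintf(" [fallback: %s]", r$fallback) else ""
    sprintf("Step %d: %s -> %s (%s)%s", r$step, r$question,
            if (is.na(r$answer)) "-" else r$answer, r$action, fb)
  }, character(1))
}

#' Green-chemistry key performance indicators for a batch
#'
#' When a full prospective LCA is out of reach, the manufacturing batch is
#' scored on green-chemistry KPIs: consumption of solvent, electricity and
#' heat, and emission of pollutants and waste, each normalized per gram of
#' nanomaterial produced. Lower is better for all five.
#'
#' @param solvent_ml Solvent volume used (mL).
#' @param electricity_kwh Electricity used (kWh).
#' @param heat_kj Heat used (kJ).
#' @param pollutants_g Pollutant mass emitted (g).
#' @param waste_g Waste mass produced (g).
#' @param nm_mass_g Nanomaterial mass produced (g), > 0.
#' @return A `kpi_record`: named numeric vector of the five KPIs
#'   (mL/g, kWh/g, kJ/g, g/g, g/g).
#' @examples
#' compute_kpis(solvent_ml = 10, nm_mass_g = 2)
#' @export
compute_kpis <- function(solvent_ml = 0, electricity_kwh = 0, heat_kj = 0,
                         pollutants_g = 0, waste_g = 0, nm_mass_g) {
  assert_scalar_number(nm_mass_g, "nm_mass_g")
  if (nm_mass_g <= 0)
    stopf("nm_mass_g must be > 0 (got %s)", format(nm_mass_g))
  amounts <- c(solvent_ml, electricity_kwh, heat_kj, pollutants_g, waste_g)
  if (!is.numeric(amounts) || any(!is.finite(amounts)) || any(amounts < 0))
    stopf("batch amounts must be finite and >= 0")
  rec <- c(solvent_consumption = solvent_ml / nm_mass_g,
           electricity_consumption = electricity_kwh / nm_mass_g,
           heat_consumption = heat_kj / nm_mass_g,
           pollutant_emissions = pollutants_g / nm_mass_g,
           waste_production = waste_g / nm_mass_g)
  structure(rec, units = c("mL/g", "kWh/g", "kJ/g", "g/g", "g/g"),
            class = "kpi_record")
}

#' @export
print.kpi_record <- function(x, ...) {
  u <- attr(x, "units")
  cat("<kpi_record>\n")
  for (i in seq_along(x))
    cat(sprintf("  %-24s %12s %s\n", names(x)[i], fmt_num(x[[i]]), u[i]))
  invisible(x)
}

#' Compare two KPI records per indicator
#'
#' No aggregate score is produced: the five KPIs are compared one by one
#' (lower is better), since no weighting across them is defined.
#'
#' @param a,b [compute_kpis()] records (a = baseline, b = alternative).
#' @return `data.frame` with columns `indicator`, `a`, `b`, `unit`,
#'   `relative_change` ((b - a) / a, NA when a is 0 and b differs) and
#'   `verdict` (`"improved"`, `"worsened"`, `"equal"`).
#' @export
compare_kpis <- function(a, b) {
  stopifnot(inherits(a, "kpi_record"), inherits(b, "kpi_record"))
  if (!identical(attr(a, "units"), attr(b, "units")))
    stopf("KPI records have mismatched units")
  rel <- ifelse(a == 0, ifelse(b == 0, 0, NA_real_),
                (as.numeric(b) - as.numeric(a)) / as.numeric(a))
  verdict <- ifelse(b < a, "improved", ifelse(b > a, "worsened", "equal"))
  data.frame(indicator = names(a), a = as.numeric(a), b = as.numeric(b),
             unit = attr(a, "units"), relative_change = as.numeric(rel),
             verdict = verdict, stringsAsFactors = FALSE)
}
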