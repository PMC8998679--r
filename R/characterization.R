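#' Describe a nanoform
#'
#' A nanoform is a specific manufactured variant of a nanomaterial, defined
#' by the physicochemical attributes that drive toxicity screening: primary
#' particle size, specific surface area, aspect ratio, solubility, coating
#' stability, environmental persistence, surface reactivity, agglomeration
#' behaviour, reactive-oxygen-species (ROS) generation and the expected
#' exposure route. Attributes that have not been characterized are recorded
#' as `"unknown"` and surface as information-gap flags during screening
#' rather than passing silently.
#'
#' @param id Nanoform identifier token.
#' @param substance Parent substance (e.g. `"TiO2"`).
#' @param particle_size Primary particle size in nm (> 0).
#' @param surface_area Specific surface area in m2/g (> 0).
#' @param aspect_ratio Width:length ratio normalized to 1:x, as the scalar
#'   x >= 1 (so `6` means 1:6).
#' @param solubility_class `"soluble"` or `"non_soluble"`.
#' @param coating Optional coating substance.
#' @param coating_stability,persistence,reactivity,agglomeration,ros
#'   Categorical hazard attributes; `"unknown"` when uncharacterized.
#' @param exposure_route Dominant expected human exposure route.
#' @return A `nanoform` object.
#' @examples
#' nanoform("p25_tio2", "TiO2", particle_size = 20, surface_area = 50,
#'          solubility_class = "non_soluble")
#' @export
nanoform <- function(id, substance, particle_size, surface_area,
                     aspect_ratio = 1, solubility_class,
                     coating = NULL,
                     coating_stability = c("unknown", "stable", "unstable"),
                     persistence = c("unknown", "persistent", "non_persistent"),
                     reactivity = c("unknown", "high", "low"),
                     agglomeration = c("unknown", "agglomerating", "non_agglomerating"),
                     ros = c("unknown", "yes", "no"),
                     exposure_route = c("unknown", "inhalation", "dermal",
                                        "oral", "none")) {
  assert_scalar_number(particle_size, "particle_size")
  if (particle_size <= 0) stopf("particle_size must be > 0")
  assert_scalar_number(surface_area, "surface_area")
  if (surface_area <= 0) stopf("surface_area must be > 0")
  assert_scalar_number(aspect_ratio, "aspect_ratio", min = 1)
  assert_enum(solubility_class, "solubility_class", c("soluble", "non_soluble"))
  structure(list(
    id = as.character(id), substance = as.character(substance),
    coating = coating, particle_size = particle_size,
    surface_area = surface_area, aspect_ratio = aspect_ratio,
    solubility_class = solubility_class,
    coating_stability = match.arg(coating_stability),
    persistence = match.arg(persistence),
    reactivity = match.arg(reactivity),
    agglomeration = match.arg(agglomeration),
    ros = match.arg(ros),
    exposure_route = match.arg(exposure_route)
  ), class = "nanoform")
}

#' @export
print.nanoform <- function(x, ...) {
  cat(sprintf("<nanoform> %s (%s%s): %g nm, %g m2/g, aspect 1:%g, %s\n",
              x$id, x$substance,
              if (!is.null(x$coating)) paste0(", coated ", x$coating) else "",
              x$particle_size, x$surface_area, x$aspect_ratio,
              x$solubility_class))
  invisible(x)
}

#' Compose a characterization factor from fate, exposure and effect
#'
#' Nano toxicity characterization follows the fate x exposure x effect
#' chain: `CF = FF * XF * EF` (or HEF for human toxicity). The fate factor
#' FF (days) is the residence time in the receiving compartment, the
#' exposure factor XF (0-1) the bioavailable fraction, and the effect
#' factor the damage per kg of bioavailable substance. Setting FF or XF to
#' 1 when unknown is the precautionary default: the composed factor can
#' then never understate the impact.
#'
#' @param FF Fate factor in days (>= 0).
#' @param XF Exposure factor, dimensionless in \[0, 1\].
#' @param effect Effect factor (EF in PAF.m3/kg, or HEF in cases/kg).
#' @return The composed characterization factor (numeric scalar).
#' @examples
#' compose_cf(FF = 18.7, XF = 0.25, effect = 1000)
#' @export
compose_cf <- function(FF, XF, effect) {
  assert_scalar_number(FF, "FF", min = 0)
  assert_scalar_number(XF, "XF", min = 0)
  if (XF > 1) stopf("XF must not exceed 1 (got %s)", format(XF))
  assert_scalar_number(effect, "effect", min = 0)
  FF * XF * effect
}

#' Characterization-factor registry
#'
#' Holds everything needed to characterize an inventory: per-(nanoform,
#' compartment, indicator) factor entries, the read-across surrogate map,
#' bulk-substance toxicity factors, and per-flow GWP/CED multipliers.
#'
#' An entry either carries a literature/database CF directly, or the
#' components (`FF_days`, `XF`, and `EF` for FEP / `HEF` for HTP) from
#' which one is composed; missing FF or XF are defaulted to 1
#' (precautionary) at resolution time and flagged in the trace.
#'
#' @param entries `data.frame` with columns `nanoform_id`, `compartment`,
#'   `indicator` (`"FEP"`/`"HTP"`), `FF_days`, `XF`, `EF`, `HEF`, `CF`,
#'   `CF_unit`, `source_tier`, `source_ref` (NA where not applicable).
#' @param surrogates Read-across map: `data.frame` with columns
#'   `target_id`, `surrogate_id`, `rationale`. Chains are followed and must
#'   be acyclic.
#' @param bulk_factors `data.frame` with columns `substance`,
#'   `compartment`, `indicator`, `cf`, `unit` for bulk-phase flows.
#' @param gwp_ced_factors `data.frame` with columns `flow_id`, `indicator`
#'   (`"GWP"`/`"CED"`), `factor`, `unit`; applied to the signed inventory,
#'   so resource draws (negative) take a negative factor to yield a
#'   positive demand.
#' @param nanoforms Named list of [nanoform()] objects (optional metadata).
#' @return A `cf_registry` object.
#' @export
cf_registry <- function(entries, surrogates = NULL, bulk_factors = NULL,
                        gwp_ced_factors = NULL, nanoforms = list()) {
  tmpl <- c("nanoform_id", "compartment", "indicator", "FF_days", "XF",
            "EF", "HEF", "CF", "CF_unit", "source_tier", "source_ref")
  for (col in tmpl) if (is.null(entries[[col]])) entries[[col]] <- NA
  entries <- entries[, tmpl]
  if (!all(entries$indicator %in% c("FEP", "HTP")))
    stopf("registry entries: indicator must be 'FEP' or 'HTP'")
  if (!all(entries$compartment %in% setdiff(compartments(), "none")))
    stopf("registry entries: invalid compartment")
  tier_rank(entries$source_tier)
  key <- paste(entries$nanoform_id, entries$compartment, entries$indicator)
  if (anyDuplicated(key))
    stopf("registry entries: duplicate (nanoform, compartment, indicator) key: %s",
          key[duplicated(key)][1])
  num_ok <- function(x, lo, hi = Inf)
    all(is.na(x) | (is.finite(x) & x >= lo & x <= hi))
  if (!num_ok(entries$XF, 0, 1)) stopf("registry entries: XF must lie in [0, 1]")
  if (!num_ok(entries$FF_days, 0)) stopf("registry entries: FF_days must be >= 0")
  if (!num_ok(entries$EF, 0)) stopf("registry entries: EF must be >= 0")
  if (!num_ok(entries$HEF, 0)) stopf("registry entries: HEF must be >= 0")
  if (!num_ok(entries$CF, 0)) stopf("registry entries: CF must be >= 0")
  eff <- ifelse(entries$indicator == "HTP", entries$HEF, entries$EF)
  usable <- !is.na(entries$CF) | !is.na(eff)
  if (!all(usable))
    stopf("registry entries: row for %s/%s/%s has neither a CF nor an effect factor",
          entries$nanoform_id[!usable][1], entries$compartment[!usable][1],
          entries$indicator[!usable][1])

  if (!is.null(surrogates) && nrow(surrogates)) {
    if (anyDuplicated(surrogates$target_id))
      stopf("surrogate map: each target may have one surrogate")
    # cycle check by walking every chain
    for (t in surrogates$target_id) {
      seen <- character()
      cur <- t
      while (cur %in% surrogates$target_id) {
        if (cur %in% seen) stopf("surrogate map: cycle involving '%s'", cur)
        seen <- c(seen, cur)
        cur <- surrogates$surrogate_id[surrogates$target_id == cur]
      }
    }
  }
  structure(list(entries = entries, surrogates = surrogates,
                 bulk_factors = bulk_factors,
                 gwp_ced_factors = gwp_ced_factors,
                 nanoforms = nanoforms),
            class = "cf_registry")
}

#' @export
print.cf_registry <- function(x, ...) {
  cat(sprintf("<cf_registry> %d factor entries, %d surrogate mapping(s), %d bulk factor(s), %d GWP/CED factor(s)\n",
              nrow(x$entries),
              if (is.null(x$surrogates)) 0L else nrow(x$surrogates),
              if (is.null(x$bulk_factors)) 0L else nrow(x$bulk_factors),
              if (is.null(x$gwp_ced_factors)) 0L else nrow(x$gwp_ced_factors)))
  invisible(x)
}

#' Resolve a characterization factor through the fallback cascade
#'
#' Resolution order: (1) a direct registry entry for the nanoform;
#' (2) a surrogate entry through the read-across map; (3) composition from
#' whatever FF/XF/effect components the chosen entry carries, with missing
#' FF or XF defaulted to 1 (precautionary); (4) if no effect information
#' exists at any tier, an error instructing KPI-only assessment. Every
#' fallback is recorded in the resolution trace, and the resulting tier is
#' the highest-uncertainty tier touched on the way.
#'
#' @param nanoform_id Nanoform to characterize.
#' @param compartment Receiving compartment of the emission.
#' @param indicator `"FEP"` or `"HTP"`.
#' @param registry A [cf_registry()].
#' @return A list with `cf`, `unit`, `tier`, `defaults` (character vector
#'   of defaulted components) and `trace` (character vector of resolution
#'   steps).
#' @export
resolve_factors <- function(nanoform_id, compartment, indicator, registry) {
  stopifnot(inherits(registry, "cf_registry"))
  assert_enum(indicator, "indicator", c("FEP", "HTP"))
  assert_enum(compartment, "compartment", setdiff(compartments(), "none"))
  en <- registry$entries
  trace <- character()
  via_read_across <- FALSE

  pick <- function(id) {
    hit <- en[en$nanoform_id == id & en$compartment == compartment &
                en$indicator == indicator, , drop = FALSE]
    if (nrow(hit)) hit[1, , drop = FALSE] else NULL
  }

  cur <- nanoform_id
  entry <- pick(cur)
  if (!is.null(entry)) {
    trace <- c(trace, sprintf("direct entry for '%s' (%s, %s)",
                              cur, compartment, indicator))
  } else {
    sm <- registry$surrogates
    while (is.null(entry) && !is.null(sm) && cur %in% sm$target_id) {
      nxt <- sm$surrogate_id[sm$target_id == cur]
      trace <- c(trace, sprintf("read-across: '%s' -> surrogate '%s'", cur, nxt))
      via_read_across <- TRUE
      cur <- nxt
      entry <- pick(cur)
    }
    if (!is.null(entry))
      trace <- c(trace, sprintf("surrogate entry for '%s' (%s, %s)",
                                cur, compartment, indicator))
  }
  if (is.null(entry))
    stopf(paste0("cannot characterize nanoform '%s' for %s in %s: no factor, ",
                 "no surrogate and no effect data at any tier; ",
                 "fall back to KPI-only assessment"),
          nanoform_id, indicator, compartment,
          class = "ssbd_cannot_characterize")

  tier <- entry$source_tier
  defaults <- character()
  if (!is.na(entry$CF)) {
    cf <- entry$CF
    unit <- if (!is.na(entry$CF_unit)) entry$CF_unit else
      if (indicator == "FEP") "PAF.d.m3/kg" else "cases.d/kg"
    trace <- c(trace, sprintf("CF taken directly: %s %s (tier %s)",
                              fmt_num(cf), unit, tier))
  } else {
    effect <- if (indicator == "HTP") entry$HEF else entry$EF
    if (is.na(effect))
      stopf(paste0("cannot characterize nanoform '%s' for %s in %s: entry has ",
                   "no effect factor; fall back to KPI-only assessment"),
            nanoform_id, indicator, compartment,
            class = "ssbd_cannot_characterize")
    FF <- entry$FF_days
    XF <- entry$XF
    if (is.na(FF)) {
      FF <- 1
      defaults <- c(defaults, "FF")
      trace <- c(trace, "FF unknown: defaulted to 1 (precautionary)")
    }
    if (is.na(XF)) {
      XF <- 1
      defaults <- c(defaults, "XF")
      trace <- c(trace, "XF unknown: defaulted to 1 (precautionary)")
    }
    cf <- compose_cf(FF, XF, effect)
    unit <- if (indicator == "FEP") "PAF.d.m3/kg" else "cases.d/kg"
    trace <- c(trace, sprintf("CF composed = FF * XF * %s = %s %s",
                              if (indicator == "HTP") "HEF" else "EF",
                              fmt_num(cf), unit))
    if (length(defaults)) tier <- worse_tier(tier, "default_precautionary")
  }
  if (via_read_across) tier <- worse_tier(tier, "read_across")

  list(cf = as.numeric(cf), unit = unit, tier = tier, defaults = defaults,
       trace = trace, source_ref = entry$source_ref)
}

impact_result <- function(indicator, basis, total, unit, contributions,
                          uncharacterized = character()) {
  if (length(contributions)) {
    s <- sum(contributions)
    if (abs(s - total) > 1e-9 * max(abs(total), 1e-300))
      stopf("impact result %s (%s): contributions do not sum to total",
            indicator, basis, class = "ssbd_computation_error")
  }
  structure(list(indicator = indicator, basis = basis, total = total,
                 unit = unit, contributions = contributions,
                 uncharacterized = uncharacterized),
            class = "impact_result")
}

#' @export
print.impact_result <- function(x, ...) {
  cat(sprintf("%s (%s basis): %s %s\n", x$indicator, x$basis,
              fmt_num(x$total), x$unit))
  invisible(x)
}

#' @export
print.impact_results <- function(x, ...) {
  cat("<impact_results>\n")
  for (r in x)
    cat(sprintf("  %-4s %-5s %14s %s\n", r$indicator, paste0("(", r$basis, ")"),
                fmt_num(r$total), r$unit))
  invisible(x)
}

#' Characterize a solved inventory into impact results
#'
#' Applies characterization factors to the inventory: GWP and CED from the
#' registry's per-flow multipliers; human toxicity (HTP) and freshwater
#' ecotoxicity (FEP) separately on bulk-phase flows (via bulk substance
#' factors) and nano-phase flows (via the nanoform factor cascade of
#' [resolve_factors()]). Each impact total carries per-process
#' contributions attributed to the emitting process. Bulk flows with a
#' nonzero inventory but no factor anywhere are reported as
#' `uncharacterized` on the bulk-basis results rather than dropped
#' silently.
#'
#' @param lci An [solve_inventory()] result.
#' @param registry A [cf_registry()].
#' @param assignment Named character vector mapping nano elementary flow
#'   ids to nanoform ids.
#' @return An `impact_results` list (two results per indicator: bulk and
#'   nano basis), with factor resolutions attached as attribute
#'   `"resolutions"`.
#' @export
characterize <- function(lci, registry, assignment = character()) {
  stopifnot(inherits(lci, "lci_result"), inherits(registry, "cf_registry"))
  flows <- lci$system$flows
  g <- lci$inventory
  G <- lci$contributions
  procs <- colnames(G)
  elem <- flows[flows$kind == "elementary", , drop = FALSE]
  nano_ids <- elem$flow_id[elem$phase == "nano"]
  bulk_ids <- elem$flow_id[elem$phase == "bulk"]

  unresolved <- setdiff(nano_ids[abs(g[nano_ids]) > 0], names(assignment))
  if (length(unresolved))
    stopf("nano elementary flow(s) with no nanoform assignment: %s",
          paste(unresolved, collapse = ", "))

  zero_contrib <- stats::setNames(numeric(length(procs)), procs)
  results <- list()
  resolutions <- list()

  # GWP / CED from per-flow multipliers, split by flow phase
  gc <- registry$gwp_ced_factors
  for (ind in c("GWP", "CED")) {
    for (basis in c("bulk", "nano")) {
      ids <- if (basis == "bulk") bulk_ids else nano_ids
      contrib <- zero_contrib
      if (!is.null(gc) && nrow(gc)) {
        fac <- gc[gc$indicator == ind & gc$flow_id %in% ids, , drop = FALSE]
        for (i in seq_len(nrow(fac))) {
          fid <- fac$flow_id[i]
          contrib <- contrib + fac$factor[i] * G[fid, ]
        }
      }
      results[[paste(ind, basis, sep = ".")]] <- impact_result(
        ind, basis, sum(contrib), indicator_unit(ind), contrib)
    }
  }

  # flows with no factor under any indicator -> uncharacterized warning list
  bf <- registry$bulk_factors
  has_any_factor <- function(fid) {
    fl <- flows[flows$flow_id == fid, ]
    in_gc <- !is.null(gc) && nrow(gc) && fid %in% gc$flow_id
    in_bf <- !is.null(bf) && nrow(bf) &&
      any(bf$substance == fl$substance & bf$compartment == fl$compartment)
    in_gc || in_bf
  }
  uncharacterized <- bulk_ids[abs(g[bulk_ids]) > 0 &
                                !vapply(bulk_ids, has_any_factor, logical(1))]
  for (fid in uncharacterized)
    warnf("bulk flow '%s' has a nonzero inventory but no characterization factor",
          fid)

  # HTP / FEP: bulk basis via substance factors, nano basis via the cascade
  for (ind in c("HTP", "FEP")) {
    contrib <- zero_contrib
    if (!is.null(bf) && nrow(bf)) {
      for (fid in bulk_ids) {
        fl <- flows[flows$flow_id == fid, ]
        hit <- bf[bf$substance == fl$substance &
                    bf$compartment == fl$compartment &
                    bf$indicator == ind, , drop = FALSE]
        if (nrow(hit))
          contrib <- contrib + hit$cf[1] * G[fid, ]
      }
    }
    results[[paste(ind, "bulk", sep = ".")]] <- impact_result(
      ind, "bulk", sum(contrib), indicator_unit(ind), contrib,
      uncharacterized = uncharacterized)

    contrib <- zero_contrib
    for (fid in intersect(nano_ids, names(assignment))) {
      if (all(G[fid, ] == 0)) next  # nothing emitted: no factor needed
      fl <- flows[flows$flow_id == fid, ]
      res <- resolve_factors(assignment[[fid]], fl$compartment, ind, registry)
      resolutions[[paste(assignment[[fid]], fl$compartment, ind, sep = ".")]] <- res
      contrib <- contrib + res$cf * G[fid, ]
    }
    results[[paste(ind, "nano", sep = ".")]] <- impact_result(
      ind, "nano", sum(contrib), indicator_unit(ind), contrib)
  }

  structure(results, class = "impact_results", resolutions = resolutions)
}

#' Extract impact totals as a named vector
#'
#' @param results An `impact_results` list from [characterize()], or an
#'   already-named numeric vector (returned unchanged).
#' @return Named numeric vector keyed `"<indicator>.<basis>"`.
#' @export
impact_totals <- function(results) {
  if (is.numeric(results)) return(results)
  stopifnot(inherits(results, "impact_results"))
  vapply(results, function(r) r$total, numeric(1))
}
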