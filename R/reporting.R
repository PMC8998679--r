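#' Default safe-by-design hotspot rules
#'
#' The built-in screening rules map hazard-relevant nanoform attributes and
#' release behaviour to design actions. Numeric thresholds are encoded
#' where the underlying guidance states them (particle size below 50 nm;
#' aspect ratio beyond 1:5, the HARN fibre class); categorical rules
#' (coating stability, persistence, reactivity, ROS, agglomeration,
#' exposure route) evaluate enum attributes, and an `"unknown"` value
#' yields an information-gap flag — a prompt to characterize — rather than
#' a silent pass. The release-rate threshold (summed stage fraction
#' above `release_threshold`, default 0.01) is a tool default, configurable
#' in [screen_nanoform()].
#'
#' @return List of rule objects with fields `parameter`, `hotspot`
#'   (condition description), `action`, and `check(form, releases,
#'   release_threshold)`.
#' @export
default_hotspot_rules <- function() {
  rule <- function(parameter, hotspot, action, check)
    list(parameter = parameter, hotspot = hotspot, action = action,
         check = check)
  enum_check <- function(field, bad) {
    force(field); force(bad)
    function(form, releases, release_threshold) {
      v <- form[[field]]
      list(triggered = if (v == "unknown") NA else v %in% bad, value = v)
    }
  }
  list(
    rule("size", "Small NMs (<50 nm)",
         "Alter design to avoid NMs below this threshold",
         function(form, releases, release_threshold)
           list(triggered = form$particle_size < 50,
                value = paste0(form$particle_size, " nm"))),
    rule("shape", "High aspect ratio NMs (HARN, >1:5)",
         "Alter design to avoid NMs with HARN",
         function(form, releases, release_threshold)
           list(triggered = form$aspect_ratio > 5,
                value = paste0("1:", form$aspect_ratio))),
    rule("solubility", "Fibrous, non-soluble materials",
         "Alter design to avoid fibrous, non-soluble materials",
         function(form, releases, release_threshold)
           list(triggered = form$solubility_class == "non_soluble" &&
                  form$aspect_ratio > 5,
                value = paste0(form$solubility_class, ", aspect 1:",
                               form$aspect_ratio))),
    rule("coating_stability", "Unstable coatings which allow for NM release",
         "Alter design with stable coating",
         function(form, releases, release_threshold) {
           if (is.null(form$coating))
             return(list(triggered = FALSE, value = "no coating"))
           v <- form$coating_stability
           list(triggered = if (v == "unknown") NA else v == "unstable",
                value = v)
         }),
    rule("persistence", "Environmentally persistent",
         "Alter design to avoid environmentally persistent NMs",
         enum_check("persistence", "persistent")),
    rule("reactivity", "Highly reactive NMs",
         "Alter design to avoid reactive NMs",
         enum_check("reactivity", "high")),
    rule("ros", "Production of ROS and indirect genotoxicity",
         "Alter design to reduce/avoid ROS production",
         enum_check("ros", "yes")),
    rule("agglomeration", "Agglomeration as potent inducer of inflammatory lung injury",
         "Alter design to NMs that do not agglomerate if lung exposure is expected",
         enum_check("agglomeration", "agglomerating")),
    rule("exposure_route", "Inhalation exposure (powders)",
         "Avoid inhalation exposure",
         enum_check("exposure_route", "inhalation")),
    rule("release_rate", "High NM release rate",
         "Alter matrix design to avoid NM environmental release",
         function(form, releases, release_threshold) {
           if (is.null(releases) || !length(releases))
             return(list(triggered = NA, value = "no release model"))
           tot <- vapply(releases, function(m) sum(m$fractions), numeric(1))
           worst <- which.max(tot)
           list(triggered = max(tot) > release_threshold,
                value = sprintf("%s: %s released", releases[[worst]]$stage,
                                fmt_num(max(tot))))
         })
  )
}

#' Screen a nanoform against safe-by-design rules
#'
#' Evaluates each rule on the nanoform's attributes (and, for the release
#' rule, its stage release models). Each rule yields one of three
#' statuses: `"hotspot"` (condition met, design action recommended),
#' `"information_gap"` (attribute unknown — needs characterization before
#' it can pass), or `"clear"`.
#'
#' @param form A [nanoform()].
#' @param releases Optional list of [release_model()] objects for the
#'   nanoform's life-cycle stages.
#' @param rules Rule list, by default [default_hotspot_rules()].
#' @param release_threshold Summed stage release fraction above which the
#'   release-rate rule triggers (tool default 0.01).
#' @return A `hotspot_screen` data.frame with columns `parameter`,
#'   `value`, `status`, `condition`, `action`.
#' @examples
#' nf <- nanoform("p25_tio2", "TiO2", particle_size = 20, surface_area = 50,
#'                solubility_class = "non_soluble")
#' screen_nanoform(nf)
#' @export
screen_nanoform <- function(form, releases = NULL,
                            rules = default_hotspot_rules(),
                            release_threshold = 0.01) {
  stopifnot(inherits(form, "nanoform"))
  if (inherits(releases, "release_model")) releases <- list(releases)
  out <- lapply(rules, function(r) {
    res <- r$check(form, releases, release_threshold)
    status <- if (is.na(res$triggered)) "information_gap"
              else if (res$triggered) "hotspot" else "clear"
    data.frame(parameter = r$parameter, value = as.character(res$value),
               status = status, condition = r$hotspot,
               action = if (status == "hotspot") r$action
                        else if (status == "information_gap")
                          "needs characterization" else NA_character_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("hotspot_screen", "data.frame")
  res
}

#' Rank process contributions and flag dominant processes
#'
#' For every impact result, processes are ranked by contribution
#' (descending, ties broken by process id) and a dominance flag is raised
#' when a single process carries more than `dominance_share` of the total
#' — the "high impact from a single process" hotspot pattern.
#'
#' @param results An `impact_results` list from [characterize()], or a
#'   single `impact_result`.
#' @param dominance_share Share of the total above which the top process is
#'   flagged dominant (tool default 0.5).
#' @return A `process_hotspots` object: per impact result, a ranking
#'   data.frame (`process_id`, `contribution`, `share`) plus `dominant`
#'   and `dominant_process`.
#' @export
find_process_hotspots <- function(results, dominance_share = 0.5) {
  assert_scalar_number(dominance_share, "dominance_share", min = 0, max = 1)
  if (inherits(results, "impact_result")) {
    results <- structure(stats::setNames(
      list(results), paste(results$indicator, results$basis, sep = ".")),
      class = "impact_results")
  }
  out <- lapply(results, function(r) {
    contrib <- r$contributions
    ord <- order(-contrib, names(contrib))
    ranking <- data.frame(process_id = names(contrib)[ord],
                          contribution = as.numeric(contrib[ord]),
                          stringsAsFactors = FALSE)
    ranking$share <- if (r$total != 0) ranking$contribution / r$total else
      rep(0, nrow(ranking))
    dominant <- nrow(ranking) > 0 && ranking$share[1] > dominance_share
    list(indicator = r$indicator, basis = r$basis, ranking = ranking,
         dominant = dominant,
         dominant_process = if (dominant) ranking$process_id[1] else NA_character_)
  })
  structure(out, class = "process_hotspots")
}

#' @export
print.process_hotspots <- function(x, ...) {
  for (nm in names(x)) {
    h <- x[[nm]]
    cat(sprintf("%s (%s basis): top process %s%s\n", h$indicator, h$basis,
                if (nrow(h$ranking)) h$ranking$process_id[1] else "-",
                if (h$dominant) sprintf(" [DOMINANT, %.0f%% share]",
                                        100 * h$ranking$share[1]) else ""))
  }
  invisible(x)
}

#' Compare reference and original systems per indicator
#'
#' All impact indicators are lower-is-better potentials, so the original
#' (alternative) system is `"better"` on an indicator when its value is
#' lower than the reference's. The trade-off flag is raised when at least
#' one indicator improves while another worsens — the signature pattern of
#' an alternative that shifts burden instead of removing it.
#'
#' @param reference,original `impact_results` lists (see [characterize()])
#'   or named numeric vectors of totals with matching names.
#' @return A `comparison_report`: `table` (per-indicator values, deltas,
#'   verdicts), `trade_off_flag`, and `overall` (`"better"`, `"worse"`,
#'   `"mixed"` or `"equal"`).
#' @examples
#' compare_systems(c(GWP = 18.17, FEP = 15.08), c(GWP = 9.28, FEP = 16.26))
#' @export
compare_systems <- function(reference, original) {
  unit_of <- function(x) {
    if (is.numeric(x)) return(NULL)
    vapply(x, function(r) r$unit, character(1))
  }
  uref <- unit_of(reference); uorg <- unit_of(original)
  ref <- impact_totals(reference)
  org <- impact_totals(original)
  if (!setequal(names(ref), names(org)))
    stopf("systems report different indicator sets: %s vs %s",
          paste(names(ref), collapse = ","), paste(names(org), collapse = ","))
  org <- org[names(ref)]
  if (!is.null(uref) && !is.null(uorg) &&
      !identical(uref[names(ref)], uorg[names(ref)]))
    stopf("indicator unit mismatch between systems")
  delta <- org - ref
  relative <- ifelse(ref == 0, ifelse(delta == 0, 0, NA_real_), delta / ref)
  verdict <- ifelse(delta < 0, "better", ifelse(delta > 0, "worse", "equal"))
  tab <- data.frame(indicator = names(ref), reference = as.numeric(ref),
                    original = as.numeric(org), delta = as.numeric(delta),
                    relative_delta = as.numeric(relative), verdict = verdict,
                    stringsAsFactors = FALSE)
  if (!is.null(uref)) tab$unit <- unname(uref[names(ref)])
  trade_off <- any(verdict == "better") && any(verdict == "worse")
  overall <- if (trade_off) "mixed"
             else if (any(verdict == "better")) "better"
             else if (any(verdict == "worse")) "worse" else "equal"
  structure(list(table = tab, trade_off_flag = trade_off, overall = overall),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  print(transform(x$table,
                  reference = fmt_num(reference), original = fmt_num(original),
                  delta = fmt_num(delta),
                  relative_delta = ifelse(is.na(relative_delta), "undefined",
                                          fmt_num(relative_delta))),
        row.names = FALSE)
  cat(sprintf("trade-off flag: %s; overall: %s\n",
              x$trade_off_flag, x$overall))
  invisible(x)
}

new_heatmap <- function(cells) {
  structure(list(cells = cells, legend = data_tiers()),
            class = "uncertainty_heatmap")
}

#' Build uncertainty heat maps for inventory data and characterization factors
#'
#' Produces the two data-provenance maps of the assessment: the LCI map
#' (process x indicator, cell = provenance tier of the process inventory
#' data) and the CF map (nanoform x toxicity indicator, cell = tier at
#' which the characterization factor resolved, so read-across surrogates
#' and precautionary defaults surface at their high-uncertainty tier).
#'
#' @param trace Decision trace from [run_framework()] (recorded alongside
#'   the maps for audit).
#' @param plan Data plan from [run_framework()]; every nanoform to map must
#'   be covered by it.
#' @param systems A [product_system()] or list of them; rows of the LCI map
#'   are the union of their processes (sorted by id).
#' @param registry A [cf_registry()] used to resolve per-(nanoform,
#'   indicator) tiers for the CF map.
#' @return List with `lci_map` and `cf_map`, both `uncertainty_heatmap`
#'   objects (a character matrix of tiers plus the tier legend).
#' @export
build_heatmap <- function(trace, plan, systems, registry) {
  if (inherits(systems, "product_system")) systems <- list(systems)
  procs <- unique(do.call(rbind, lapply(systems, `[[`, "processes")))
  procs <- procs[!duplicated(procs$process_id), , drop = FALSE]
  procs <- procs[order(procs$process_id), , drop = FALSE]
  gaps <- procs$process_id[is.na(procs$data_tier) |
                             !(procs$data_tier %in% data_tiers())]
  if (length(gaps))
    stopf("no data tier recorded for process(es): %s",
          paste(gaps, collapse = ", "))
  lci <- matrix(rep(procs$data_tier, times = length(indicators())),
                nrow = nrow(procs),
                dimnames = list(procs$process_id, indicators()))

  nfs <- sort(unique(stats::na.omit(plan$nanoform)))
  if (!length(nfs))
    stopf("data plan covers no nanoform: nothing to map")
  missing_cf <- setdiff(nfs, plan$nanoform[plan$quantity == "cf"])
  if (length(missing_cf))
    stopf("data plan has no CF row for nanoform(s): %s",
          paste(missing_cf, collapse = ", "))
  cfm <- matrix(NA_character_, nrow = length(nfs), ncol = 2,
                dimnames = list(nfs, c("HTP", "FEP")))
  gaps <- character()
  for (nm in nfs) {
    for (ind in c("HTP", "FEP")) {
      res <- tryCatch(resolve_factors(nm, "freshwater", ind, registry),
                      ssbd_cannot_characterize = function(e) NULL)
      if (is.null(res)) gaps <- c(gaps, paste0(nm, "/", ind))
      else cfm[nm, ind] <- res$tier
    }
  }
  if (length(gaps))
    stopf("characterization factors unresolvable for: %s",
          paste(gaps, collapse = ", "))
  list(lci_map = new_heatmap(lci), cf_map = new_heatmap(cfm))
}

#' @export
print.uncertainty_heatmap <- function(x, ...) {
  cat(sprintf("<uncertainty_heatmap> %d x %d cells (tiers: %s)\n",
              nrow(x$cells), ncol(x$cells), paste(x$legend, collapse = " < ")))
  print(x$cells, quote = FALSE)
  invisible(x)
}

#' Render an uncertainty heat map
#'
#' Draws the tier matrix with a light-to-dark ramp over the tier ordering
#' (darker = more uncertain).
#'
#' @param x An `uncertainty_heatmap`.
#' @param main Plot title.
#' @param ... Unused.
#' @export
plot.uncertainty_heatmap <- function(x, main = "Data-provenance uncertainty",
                                     ...) {
  m <- matrix(tier_rank(x$cells), nrow = nrow(x$cells))
  pal <- grDevices::hcl.colors(length(x$legend), "YlOrRd", rev = TRUE)
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), ,
                                                          drop = FALSE]),
                  col = pal, zlim = c(1, length(x$legend)),
                  axes = FALSE, xlab = "", ylab = "",
                  main = main)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(x$cells),
                 las = 2, tick = FALSE)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(x$cells)),
                 las = 1, tick = FALSE)
  invisible(x)
}
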