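# CSV dialect is fixed: comma-separated, UTF-8, dot decimal, mandatory
# header row, numbers serialized with 12 significant digits.

read_table_checked <- function(path, columns) {
  if (!file.exists(path))
    stopf("input file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  miss <- setdiff(names(columns), names(df))
  if (length(miss))
    stopf("%s: missing column(s) %s", basename(path),
          paste(miss, collapse = ", "))
  for (col in names(columns)) {
    if (columns[[col]] == "numeric") {
      val <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(val) & !(is.na(df[[col]]) | df[[col]] %in% c("", "NA")))
      if (length(bad))
        stopf("%s, row %d, column %s: '%s' is not a number",
              basename(path), bad[1], col, df[[col]][bad[1]])
      df[[col]] <- val
    }
  }
  df
}

write_csv12 <- function(df, path) {
  out <- df
  for (col in names(out))
    if (is.numeric(out[[col]])) out[[col]] <- fmt_num(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Write a product system to CSV tables
#'
#' Emits `flows.csv`, `processes.csv`, `exchanges.csv` and `demand.csv`
#' into `dir` (created if needed), in the fixed CSV dialect. The matrices
#' `A` and `B` are also written (`matrix_A.csv`, `matrix_B.csv`) for
#' audit.
#'
#' @param system A [product_system()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_system_csv <- function(system, dir) {
  stopifnot(inherits(system, "product_system"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_csv12(system$flows, file.path(dir, "flows.csv"))
  write_csv12(system$processes, file.path(dir, "processes.csv"))
  write_csv12(system$exchanges, file.path(dir, "exchanges.csv"))
  dem <- data.frame(flow_id = names(system$f), amount = as.numeric(system$f),
                    stringsAsFactors = FALSE)
  write_csv12(dem[dem$amount != 0, , drop = FALSE],
              file.path(dir, "demand.csv"))
  amat <- data.frame(flow_id = rownames(system$A), system$A,
                     check.names = FALSE, stringsAsFactors = FALSE)
  write_csv12(amat, file.path(dir, "matrix_A.csv"))
  bmat <- data.frame(flow_id = rownames(system$B), system$B,
                     check.names = FALSE, stringsAsFactors = FALSE)
  write_csv12(bmat, file.path(dir, "matrix_B.csv"))
  invisible(dir)
}

#' Read a product system from CSV tables
#'
#' Counterpart of [write_system_csv()]: reads and validates `flows.csv`,
#' `processes.csv`, `exchanges.csv` and `demand.csv` from `dir`.
#'
#' @param dir Directory holding the tables.
#' @return A [product_system()].
#' @export
read_system_csv <- function(dir) {
  flows <- read_table_checked(file.path(dir, "flows.csv"),
                              c(flow_id = "character", name = "character",
                                kind = "character", phase = "character",
                                compartment = "character", unit = "character"))
  processes <- read_table_checked(file.path(dir, "processes.csv"),
                                  c(process_id = "character", name = "character",
                                    reference_product = "character",
                                    data_tier = "character"))
  exchanges <- read_table_checked(file.path(dir, "exchanges.csv"),
                                  c(process_id = "character",
                                    flow_id = "character",
                                    direction = "character",
                                    amount = "numeric", unit = "character"))
  demand <- read_table_checked(file.path(dir, "demand.csv"),
                               c(flow_id = "character", amount = "numeric"))
  product_system(flows, processes, exchanges,
                 stats::setNames(demand$amount, demand$flow_id))
}

#' Write a characterization registry to CSV tables
#'
#' Emits `registry.csv` (factor entries), `surrogates.csv`,
#' `bulk_factors.csv`, `gwp_ced_factors.csv` and `nanoforms.csv`.
#'
#' @param registry A [cf_registry()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_registry_csv <- function(registry, dir) {
  stopifnot(inherits(registry, "cf_registry"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_csv12(registry$entries, file.path(dir, "registry.csv"))
  if (!is.null(registry$surrogates))
    write_csv12(registry$surrogates, file.path(dir, "surrogates.csv"))
  if (!is.null(registry$bulk_factors))
    write_csv12(registry$bulk_factors, file.path(dir, "bulk_factors.csv"))
  if (!is.null(registry$gwp_ced_factors))
    write_csv12(registry$gwp_ced_factors, file.path(dir, "gwp_ced_factors.csv"))
  if (length(registry$nanoforms)) {
    nf <- do.call(rbind, lapply(registry$nanoforms, function(x)
      data.frame(id = x$id, substance = x$substance,
                 coating = x$coating %||% "", particle_size = x$particle_size,
                 surface_area = x$surface_area, aspect_ratio = x$aspect_ratio,
                 solubility_class = x$solubility_class,
                 coating_stability = x$coating_stability,
                 persistence = x$persistence, reactivity = x$reactivity,
                 agglomeration = x$agglomeration, ros = x$ros,
                 exposure_route = x$exposure_route, stringsAsFactors = FALSE)))
    write_csv12(nf, file.path(dir, "nanoforms.csv"))
  }
  invisible(dir)
}

#' Read a characterization registry from CSV tables
#'
#' @param dir Directory written by [write_registry_csv()].
#' @return A [cf_registry()].
#' @export
read_registry_csv <- function(dir) {
  entries <- read_table_checked(file.path(dir, "registry.csv"),
                                c(nanoform_id = "character",
                                  compartment = "character",
                                  indicator = "character", FF_days = "numeric",
                                  XF = "numeric", EF = "numeric",
                                  HEF = "numeric", CF = "numeric",
                                  CF_unit = "character",
                                  source_tier = "character",
                                  source_ref = "character"))
  opt <- function(fname, cols) {
    p <- file.path(dir, fname)
    if (file.exists(p)) read_table_checked(p, cols) else NULL
  }
  surrogates <- opt("surrogates.csv",
                    c(target_id = "character", surrogate_id = "character",
                      rationale = "character"))
  bulk <- opt("bulk_factors.csv",
              c(substance = "character", compartment = "character",
                indicator = "character", cf = "numeric", unit = "character"))
  gwp_ced <- opt("gwp_ced_factors.csv",
                 c(flow_id = "character", indicator = "character",
                   factor = "numeric", unit = "character"))
  nf_tab <- opt("nanoforms.csv", c(id = "character", substance = "character"))
  nanoforms <- list()
  if (!is.null(nf_tab)) {
    for (i in seq_len(nrow(nf_tab))) {
      r <- nf_tab[i, ]
      nanoforms[[r$id]] <- nanoform(
        r$id, r$substance,
        particle_size = as.numeric(r$particle_size),
        surface_area = as.numeric(r$surface_area),
        aspect_ratio = as.numeric(r$aspect_ratio),
        solubility_class = r$solubility_class,
        coating = if (nzchar(r$coating %||% "")) r$coating else NULL,
        coating_stability = r$coating_stability,
        persistence = r$persistence, reactivity = r$reactivity,
        agglomeration = r$agglomeration, ros = r$ros,
        exposure_route = r$exposure_route)
    }
  }
  cf_registry(entries, surrogates, bulk, gwp_ced, nanoforms)
}

#' Write release models and the nano-flow assignment to CSV
#'
#' @param release_models List of [release_model()] objects.
#' @param assignment Named character vector: nano flow id -> nanoform id.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_release_csv <- function(release_models, assignment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rel <- do.call(rbind, lapply(release_models, function(m) {
    if (!length(m$fractions))
      return(NULL)
    data.frame(stage = m$stage, nanoform_id = m$nanoform,
               compartment = names(m$fractions),
               fraction = as.numeric(m$fractions), stringsAsFactors = FALSE)
  }))
  if (is.null(rel))
    rel <- data.frame(stage = character(), nanoform_id = character(),
                      compartment = character(), fraction = numeric())
  write_csv12(rel, file.path(dir, "release.csv"))
  write_csv12(data.frame(flow_id = names(assignment),
                         nanoform_id = as.character(assignment),
                         stringsAsFactors = FALSE),
              file.path(dir, "assignment.csv"))
  invisible(dir)
}

#' Read release models and nano-flow assignment from CSV
#'
#' @param dir Directory written by [write_release_csv()].
#' @return List with `release_models` and `assignment`.
#' @export
read_release_csv <- function(dir) {
  rel <- read_table_checked(file.path(dir, "release.csv"),
                            c(stage = "character", nanoform_id = "character",
                              compartment = "character",
                              fraction = "numeric"))
  models <- list()
  if (nrow(rel)) {
    for (key in unique(paste(rel$stage, rel$nanoform_id, sep = "\r"))) {
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      sub <- rel[rel$stage == parts[1] & rel$nanoform_id == parts[2], ]
      models[[parts[1]]] <- release_model(
        parts[1], parts[2], stats::setNames(sub$fraction, sub$compartment))
    }
  }
  asg <- read_table_checked(file.path(dir, "assignment.csv"),
                            c(flow_id = "character", nanoform_id = "character"))
  list(release_models = models,
       assignment = stats::setNames(asg$nanoform_id, asg$flow_id))
}

profile_to_list <- function(profile) {
  p <- unclass(profile)
  p$nanoforms <- lapply(p$nanoforms, unclass)
  p
}

profile_from_list <- function(x) {
  nfs <- lapply(x$nanoforms, function(nf) {
    do.call(nanoform_availability, lapply(nf, function(v)
      if (is.null(v)) NA_character_ else v))
  })
  availability_profile(
    reference_product_exists = x$reference_product_exists,
    process_level_data_available = x$process_level_data_available,
    process_data_tier = x$process_data_tier %||% "measured_lab",
    system_boundaries_known = x$system_boundaries_known,
    release_rate_known = x$release_rate_known,
    release_tier = x$release_tier %||% "literature",
    nanoforms = nfs)
}

#' Write / read an availability profile as YAML
#'
#' @param profile An [availability_profile()].
#' @param path YAML file path.
#' @return `path` (write) or the profile (read).
#' @export
write_profile_yaml <- function(profile, path) {
  yaml::write_yaml(profile_to_list(profile), path)
  invisible(path)
}

#' @rdname write_profile_yaml
#' @export
read_profile_yaml <- function(path) {
  if (!file.exists(path)) stopf("profile file not found: %s", path)
  profile_from_list(yaml::read_yaml(path))
}

#' Read a run configuration (YAML or JSON)
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` run configuration.
#' @return The validated config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validate_config(cfg, dirname(path))
}

validate_config <- function(cfg, base = ".") {
  if (is.null(cfg$reference))
    stopf("config: a 'reference' system section is required")
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) file.path(base, p) else p
  }
  for (side in c("reference", "original")) {
    if (is.null(cfg[[side]])) next
    cfg[[side]]$dir <- resolve(cfg[[side]]$dir)
    if (is.null(cfg[[side]]$dir) || !dir.exists(cfg[[side]]$dir))
      stopf("config: %s system directory not found: %s", side,
            cfg[[side]]$dir %||% "<missing>")
  }
  cfg$thresholds <- cfg$thresholds %||% list()
  th <- cfg$thresholds
  assert_scalar_number(th$dominance_share %||% 0.5, "dominance_share",
                       min = 0, max = 1)
  assert_scalar_number(th$release_flag %||% 0.01, "release_flag", min = 0)
  assert_scalar_number(th$sewer_transfer %||% 1, "sewer_transfer",
                       min = 0, max = 1)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg
}

#' Write impact results as a tidy CSV
#'
#' One row per (indicator, basis, process) contribution, plus the totals.
#'
#' @param results An `impact_results` list.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  rows <- do.call(rbind, lapply(results, function(r) {
    rbind(
      data.frame(indicator = r$indicator, basis = r$basis,
                 process_id = "TOTAL", value = r$total, unit = r$unit,
                 stringsAsFactors = FALSE),
      data.frame(indicator = r$indicator, basis = r$basis,
                 process_id = names(r$contributions),
                 value = as.numeric(r$contributions), unit = r$unit,
                 stringsAsFactors = FALSE))
  }))
  rownames(rows) <- NULL
  write_csv12(rows, path)
}

#' Read impact totals back from a results CSV
#'
#' @param path CSV written by [write_results_csv()].
#' @return Named numeric vector of totals keyed `"<indicator>.<basis>"`.
#' @export
read_results_csv <- function(path) {
  df <- read_table_checked(path, c(indicator = "character",
                                   basis = "character",
                                   process_id = "character",
                                   value = "numeric"))
  tot <- df[df$process_id == "TOTAL", ]
  stats::setNames(tot$value, paste(tot$indicator, tot$basis, sep = "."))
}

#' Write an uncertainty heat map as a CSV grid
#'
#' @param heatmap An `uncertainty_heatmap`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_heatmap_csv <- function(heatmap, path) {
  df <- data.frame(row = rownames(heatmap$cells), heatmap$cells,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_csv12(df, path)
}
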