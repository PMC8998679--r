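#' Flow table constructor
#'
#' Builds and validates the flow table of a product system. Product flows
#' are the goods exchanged between processes (catalyst, electricity,
#' hydrogen, ...); elementary flows cross the system boundary into an
#' environmental compartment (emissions positive, resource draws negative
#' in the intervention matrix). A flow's `phase` separates bulk material
#' flows from nanomaterial flows, which are characterized separately.
#'
#' @param flow_id Unique flow identifiers.
#' @param name Human-readable names.
#' @param kind `"product"` or `"elementary"`.
#' @param phase `"bulk"` or `"nano"`.
#' @param compartment Environmental compartment; `"none"` for product flows,
#'   one of `"air"`, `"freshwater"`, `"sewer"`, `"soil"` for elementary flows.
#' @param unit Non-empty unit label (e.g. `"kg"`, `"g"`, `"MJ"`, `"kWh"`).
#' @param substance Substance name used to look up bulk characterization
#'   factors; defaults to `name`.
#' @return A validated `data.frame` of flows.
#' @export
flow_table <- function(flow_id, name, kind, phase = "bulk",
                       compartment = "none", unit, substance = name) {
  df <- data.frame(
    flow_id = as.character(flow_id), name = as.character(name),
    kind = as.character(kind), phase = as.character(phase),
    compartment = as.character(compartment), unit = as.character(unit),
    substance = as.character(substance), stringsAsFactors = FALSE
  )
  validate_flows(df)
}

validate_flows <- function(flows) {
  req <- c("flow_id", "name", "kind", "phase", "compartment", "unit")
  miss <- setdiff(req, names(flows))
  if (length(miss))
    stopf("flow table: missing column(s) %s", paste(miss, collapse = ", "))
  if (is.null(flows$substance)) flows$substance <- flows$name
  if (anyDuplicated(flows$flow_id))
    stopf("flow table: duplicate flow_id(s): %s",
          paste(unique(flows$flow_id[duplicated(flows$flow_id)]), collapse = ", "))
  for (i in seq_len(nrow(flows))) {
    r <- flows[i, ]
    assert_enum(r$kind, paste0("flow ", r$flow_id, ": kind"),
                c("product", "elementary"))
    assert_enum(r$phase, paste0("flow ", r$flow_id, ": phase"),
                c("bulk", "nano"))
    assert_enum(r$compartment, paste0("flow ", r$flow_id, ": compartment"),
                compartments())
    if (r$kind == "product" && r$compartment != "none")
      stopf("flow %s: product flows must have compartment 'none'", r$flow_id)
    if (r$kind == "elementary" && r$compartment == "none")
      stopf("flow %s: elementary flows must name a compartment", r$flow_id)
    if (!nzchar(r$unit) || is.na(r$unit))
      stopf("flow %s: unit must be non-empty", r$flow_id)
  }
  flows
}

#' Process table constructor
#'
#' @param process_id Unique process identifiers.
#' @param name Human-readable names.
#' @param reference_product Flow id of each process's reference product.
#' @param data_tier Provenance tier of the process inventory data
#'   (see [data_tiers()]).
#' @return A validated `data.frame` of processes.
#' @export
process_table <- function(process_id, name, reference_product,
                          data_tier = "measured_lab") {
  df <- data.frame(
    process_id = as.character(process_id), name = as.character(name),
    reference_product = as.character(reference_product),
    data_tier = as.character(data_tier), stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$process_id))
    stopf("process table: duplicate process_id(s)")
  tier_rank(df$data_tier)
  df
}

#' Exchange table constructor
#'
#' One row per (process, flow, direction): the amount of `flow_id` consumed
#' (`direction = "input"`) or produced/emitted (`direction = "output"`) per
#' unit of the process's reference product.
#'
#' @param process_id,flow_id,direction,amount,unit Columns of the table.
#' @return A `data.frame` of exchanges.
#' @export
exchange_table <- function(process_id, flow_id, direction, amount,
                           unit = NA_character_) {
  data.frame(
    process_id = as.character(process_id), flow_id = as.character(flow_id),
    direction = as.character(direction), amount = as.numeric(amount),
    unit = as.character(unit), stringsAsFactors = FALSE
  )
}

#' Assemble a product system
#'
#' Builds the technology matrix `A` (product flows x processes; outputs
#' positive, inputs negative) and the intervention matrix `B` (elementary
#' flows x processes; emissions positive, resource draws negative) from the
#' flow, process and exchange tables, together with the functional-unit
#' demand vector `f`. The system must be square — one reference product per
#' process and each product flow produced by exactly one process — so that
#' the inventory can be solved by `A s = f`.
#'
#' Exchange amounts stated in a unit other than the flow's unit are
#' converted only for the documented pairs g/kg and MJ/kWh; any other
#' mismatch is an error.
#'
#' @param flows Flow table (see [flow_table()]).
#' @param processes Process table (see [process_table()]).
#' @param exchanges Exchange table (see [exchange_table()]).
#' @param demand Functional-unit demand: a named numeric vector keyed by
#'   product flow id (in the flow's unit).
#' @return An object of class `product_system` with elements `A`, `B`, `f`,
#'   `flows`, `processes`, `exchanges`.
#' @examples
#' fl <- flow_table("h2", "hydrogen", "product", unit = "g")
#' pr <- process_table("photoreactor", "H2 photocatalysis", "h2")
#' ex <- exchange_table("photoreactor", "h2", "output", 1, "g")
#' sys <- product_system(fl, pr, ex, demand = c(h2 = 1))
#' solve_inventory(sys)$scaling
#' @export
product_system <- function(flows, processes, exchanges, demand) {
  flows <- validate_flows(flows)
  if (anyDuplicated(processes$process_id))
    stopf("duplicate process ids")
  tier_rank(processes$data_tier)

  ex <- exchanges
  req <- c("process_id", "flow_id", "direction", "amount")
  miss <- setdiff(req, names(ex))
  if (length(miss))
    stopf("exchange table: missing column(s) %s", paste(miss, collapse = ", "))
  if (is.null(ex$unit)) ex$unit <- NA_character_
  if (!all(ex$direction %in% c("input", "output")))
    stopf("exchange table: direction must be 'input' or 'output'")
  if (!all(is.finite(ex$amount)))
    stopf("exchange table: amounts must be finite numbers")
  bad <- setdiff(ex$flow_id, flows$flow_id)
  if (length(bad))
    stopf("exchange table: unknown flow id(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(ex$process_id, processes$process_id)
  if (length(bad))
    stopf("exchange table: unknown process id(s): %s", paste(bad, collapse = ", "))
  dup <- duplicated(ex[, c("process_id", "flow_id", "direction")])
  if (any(dup))
    stopf("exchange table: duplicate (process, flow, direction) pair(s), e.g. %s/%s",
          ex$process_id[dup][1], ex$flow_id[dup][1])

  # unit coercion to the flow's unit (documented pairs only)
  fu <- stats::setNames(flows$unit, flows$flow_id)
  for (i in seq_len(nrow(ex))) {
    exu <- ex$unit[i]
    if (!is.na(exu) && nzchar(exu) && !identical(exu, fu[[ex$flow_id[i]]])) {
      ex$amount[i] <- unit_convert(ex$amount[i], exu, fu[[ex$flow_id[i]]])
      ex$unit[i] <- fu[[ex$flow_id[i]]]
    }
  }

  # every process must output its reference product with amount > 0
  for (i in seq_len(nrow(processes))) {
    p <- processes[i, ]
    ref <- ex[ex$process_id == p$process_id & ex$flow_id == p$reference_product &
                ex$direction == "output", ]
    if (nrow(ref) != 1L || ref$amount <= 0)
      stopf("process %s: must produce its reference product %s with a single output amount > 0",
            p$process_id, p$reference_product)
    rf <- flows[flows$flow_id == p$reference_product, ]
    if (nrow(rf) != 1L || rf$kind != "product")
      stopf("process %s: reference product %s is not a product flow",
            p$process_id, p$reference_product)
  }

  prod_ids <- flows$flow_id[flows$kind == "product"]
  elem_ids <- flows$flow_id[flows$kind == "elementary"]
  n <- nrow(processes)
  if (length(prod_ids) != n)
    stopf("system is not square: %d product flows vs %d processes",
          length(prod_ids), n)
  produced_by <- table(processes$reference_product)
  multi <- names(produced_by)[produced_by > 1]
  if (length(multi))
    stopf("product flow(s) produced by more than one process: %s",
          paste(multi, collapse = ", "))
  orphan <- setdiff(prod_ids, processes$reference_product)
  if (length(orphan))
    stopf("product flow '%s' cannot be produced: no process has it as reference product",
          orphan[1])

  A <- matrix(0, length(prod_ids), n, dimnames = list(prod_ids, processes$process_id))
  B <- matrix(0, length(elem_ids), n, dimnames = list(elem_ids, processes$process_id))
  for (i in seq_len(nrow(ex))) {
    sgn <- if (ex$direction[i] == "output") 1 else -1
    fid <- ex$flow_id[i]
    pid <- ex$process_id[i]
    if (fid %in% prod_ids) {
      A[fid, pid] <- A[fid, pid] + sgn * ex$amount[i]
    } else {
      B[fid, pid] <- B[fid, pid] + sgn * ex$amount[i]
    }
  }

  f <- stats::setNames(numeric(length(prod_ids)), prod_ids)
  if (length(demand)) {
    if (is.data.frame(demand))
      demand <- stats::setNames(demand$amount, demand$flow_id)
    bad <- setdiff(names(demand), prod_ids)
    if (length(bad))
      stopf("demand names unknown product flow(s): %s", paste(bad, collapse = ", "))
    f[names(demand)] <- as.numeric(demand)
  }
  if (!all(is.finite(f))) stopf("demand must be finite")

  structure(list(A = A, B = B, f = f, flows = flows, processes = processes,
                 exchanges = ex),
            class = "product_system")
}

#' @export
print.product_system <- function(x, ...) {
  cat(sprintf("<product_system> %d processes, %d product flows, %d elementary flows\n",
              ncol(x$A), nrow(x$A), nrow(x$B)))
  nz <- names(x$f)[x$f != 0]
  if (length(nz))
    cat("  functional unit:",
        paste(sprintf("%s %s %s", fmt_num(x$f[nz]),
                      x$flows$unit[match(nz, x$flows$flow_id)], nz),
              collapse = ", "), "\n")
  invisible(x)
}

#' Solve the life cycle inventory for the functional unit
#'
#' Solves `A s = f` for the process scaling vector `s` and computes the
#' life cycle inventory `g = B s` of elementary flows, plus the per-process
#' contribution matrix `B diag(s)` used for contribution analysis.
#'
#' @param system A [product_system()].
#' @param rcond_tol Reciprocal-condition-number guard; a technology matrix
#'   estimated below this is rejected rather than solved into garbage.
#' @return An object of class `lci_result` with elements `scaling`
#'   (named process vector), `inventory` (named elementary-flow vector),
#'   `contributions` (elementary-flow x process matrix) and `system`.
#' @export
solve_inventory <- function(system, rcond_tol = 1e-12) {
  stopifnot(inherits(system, "product_system"))
  A <- system$A
  f <- system$f
  if (nrow(A) == 0L)
    stopf("empty system")
  rc <- rcond(A)
  if (!is.finite(rc) || rc < rcond_tol) {
    sv <- svd(A)
    culprit <- rownames(A)[which.max(abs(sv$u[, ncol(A)]))]
    stopf(paste0("technology matrix is singular or ill-conditioned ",
                 "(rcond = %.3g): product flow '%s' cannot be produced"),
          rc, culprit, class = "ssbd_computation_error")
  }
  s <- solve(A, f)
  resid <- sqrt(sum((A %*% s - f)^2))
  scale <- max(sqrt(sum(f^2)), .Machine$double.eps)
  if (resid / scale > 1e-9)
    stopf("inventory solve failed: relative residual %.3g", resid / scale,
          class = "ssbd_computation_error")
  s <- stats::setNames(as.numeric(s), colnames(A))
  G <- system$B %*% diag(s, nrow = length(s))
  colnames(G) <- colnames(A)
  g <- stats::setNames(as.numeric(system$B %*% s), rownames(system$B))
  structure(list(scaling = s, inventory = g, contributions = G,
                 system = system),
            class = "lci_result")
}

#' @export
print.lci_result <- function(x, ...) {
  cat("<lci_result>\n  scaling:\n")
  print(signif(x$scaling, 6))
  cat("  inventory (elementary flows):\n")
  print(signif(x$inventory, 6))
  invisible(x)
}

#' Nanomaterial release model for a life-cycle stage
#'
#' Fractions of the nanomaterial mass handled in a stage that are released
#' to each environmental compartment. Fractions must each lie in \[0, 1\]
#' and sum to at most 1 (mass balance).
#'
#' @param stage Stage token, e.g. `"nm_manufacture"`, `"nano_coating"`,
#'   `"use"`, `"disposal"`.
#' @param nanoform Nanoform id of the released material.
#' @param fractions Named numeric vector, names in
#'   `c("air","freshwater","sewer","soil")`.
#' @return A `release_model` object.
#' @examples
#' release_model("nm_manufacture", "p25_tio2", c(air = 0.004, sewer = 0.1))
#' @export
release_model <- function(stage, nanoform, fractions) {
  if (!is.numeric(fractions))
    stopf("release fractions must be numeric")
  fractions <- fractions[is.finite(fractions)]
  bad <- setdiff(names(fractions), setdiff(compartments(), "none"))
  if (length(bad))
    stopf("release model %s: unknown compartment(s): %s", stage,
          paste(bad, collapse = ", "))
  if (any(fractions < 0 | fractions > 1))
    stopf("release model %s: fractions must lie in [0, 1]", stage)
  if (sum(fractions) > 1 + 1e-12)
    stopf("release model %s: fractions sum to %.4g > 1 (mass balance violated)",
          stage, sum(fractions))
  structure(list(stage = as.character(stage), nanoform = as.character(nanoform),
                 fractions = fractions),
            class = "release_model")
}

#' Apply a release model to a handled nanomaterial mass
#'
#' @param handled_mass Mass of nanomaterial handled in the stage (kg).
#' @param model A [release_model()].
#' @return Named numeric vector: emitted nano mass (kg) per compartment.
#' @examples
#' m <- release_model("nm_manufacture", "p25_tio2", c(air = 0.004, sewer = 0.1))
#' apply_release(1, m)
#' @export
apply_release <- function(handled_mass, model) {
  assert_scalar_number(handled_mass, "handled_mass", min = 0)
  stopifnot(inherits(model, "release_model"))
  handled_mass * model$fractions
}

#' Route sewer emissions to freshwater
#'
#' Nanomaterial released to the sewer reaches freshwater through the
#' wastewater pathway; the transfer coefficient is the fraction passed
#' through (default 1: precautionary, no removal credited to treatment).
#'
#' @param emissions Named numeric vector of emitted masses per compartment.
#' @param transfer_coefficient Fraction of the sewer load reaching
#'   freshwater, in \[0, 1\].
#' @return Emissions with the sewer entry removed and its routed share
#'   added to freshwater.
#' @examples
#' route_sewer(c(air = 0.004, sewer = 0.1), transfer_coefficient = 0.5)
#' @export
route_sewer <- function(emissions, transfer_coefficient = 1) {
  assert_scalar_number(transfer_coefficient, "transfer_coefficient",
                       min = 0, max = 1)
  if (!("sewer" %in% names(emissions))) return(emissions)
  routed <- unname(emissions[["sewer"]]) * transfer_coefficient
  emissions <- emissions[names(emissions) != "sewer"]
  if (routed > 0) {
    cur <- if ("freshwater" %in% names(emissions)) emissions[["freshwater"]] else 0
    emissions[["freshwater"]] <- cur + routed
  }
  emissions
}
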