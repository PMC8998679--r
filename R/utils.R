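# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ..., class = "ssbd_validation_error") {
  stop(structure(
    class = c(class, "ssbd_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = NULL)
  ))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (x < min || x > max)
    stopf("'%s' must be in [%s, %s], got %s", name, min, max, format(x))
  invisible(x)
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be TRUE or FALSE (no missing answers allowed)", name)
  invisible(x)
}

assert_enum <- function(x, name, levels) {
  if (!is.character(x) || length(x) != 1L || !(x %in% levels))
    stopf("'%s' must be one of: %s (got '%s')", name,
          paste(levels, collapse = ", "), paste(x, collapse = ","))
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed without disturbing global RNG state.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Serialize numbers with 12 significant digits (fixed CSV dialect).
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    format(signif(v, 12), digits = 12, scientific = NA, trim = TRUE)
  }, character(1))
}

compartments <- function() c("none", "air", "freshwater", "sewer", "soil")

indicators <- function() c("GWP", "CED", "HTP", "FEP")

indicator_unit <- function(indicator) {
  switch(indicator,
    GWP = "kg CO2-eq",
    CED = "MJ",
    HTP = "cases.d",
    FEP = "PAF.m3.d",
    stopf("unknown indicator '%s'", indicator)
  )
}

# The two documented unit conversions; anything else is an error.
unit_convert <- function(amount, from, to) {
  if (identical(from, to)) return(amount)
  conv <- list(
    c("g", "kg", 1e-3), c("kg", "g", 1e3),
    c("MJ", "kWh", 1 / 3.6), c("kWh", "MJ", 3.6)
  )
  for (p in conv) {
    if (identical(from, p[[1]]) && identical(to, p[[2]]))
      return(amount * as.numeric(p[[3]]))
  }
  stopf("no unit conversion defined from '%s' to '%s'", from, to)
}
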