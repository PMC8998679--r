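#' Data-provenance tiers
#'
#' The toolkit annotates every quantity (inventory flow, release rate,
#' characterization factor) with the provenance of its value. Tiers are
#' ordered from lowest to highest uncertainty: industrial measurements are
#' the most reliable, while precautionary defaults and plain assumptions
#' carry the most uncertainty. The ordering drives the uncertainty heat
#' maps and the tier-soundness checks of the decision engine.
#'
#' @return Character vector of tier names, ordered from lowest to highest
#'   uncertainty.
#' @examples
#' data_tiers()
#' @export
data_tiers <- function() {
  c("measured_industrial", "measured_lab", "database", "literature",
    "read_across", "bulk_proxy", "default_precautionary", "assumption")
}

#' Rank of a data tier (1 = lowest uncertainty)
#'
#' @param tier Character vector of tier names.
#' @return Integer ranks into [data_tiers()].
#' @export
tier_rank <- function(tier) {
  r <- match(tier, data_tiers())
  if (anyNA(r))
    stopf("unknown data tier(s): %s",
          paste(unique(tier[is.na(r)]), collapse = ", "))
  r
}

# Highest-uncertainty tier among the arguments.
worse_tier <- function(...) {
  tiers <- c(...)
  tiers[which.max(tier_rank(tiers))]
}
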