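#' Published reference count tables
#'
#' Frequency tables released with a national estuary matchup database:
#' trophic-state class counts and observation/match counts per imagery
#' processing level (top-of-atmosphere "L1C" and atmospherically corrected
#' "L2A"). These are inputs for arithmetic cross-checks -- class shares,
#' method shares and totals are recomputed from the counts, never stored.
#'
#' @param which `"trophic"` or `"match"`.
#' @return data.frame of the requested table.
#' @export
reference_counts <- function(which = c("trophic", "match")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("reference_",
                          if (which == "trophic") "trophic" else "match",
                          "_counts.csv"),
                   package = "estuaryscope", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Method-category shares from match counts
#'
#' Given counts of matched chlorophyll records by method category and
#' processing level, computes each level's percentage share within a
#' category (e.g. the share of in vivo matches carried by each level).
#'
#' @param counts data.frame in the layout of
#'   `reference_counts("match")`.
#' @param category row to compute shares for.
#' @return Named numeric vector of percentages summing to 100.
#' @export
method_level_shares <- function(counts, category = "in_vivo_chlorophyll") {
  row <- counts[counts$category == category, , drop = FALSE]
  if (nrow(row) != 1) stop("category not found: ", category)
  tot <- row$level_1c + row$level_2a
  c(level_1c = 100 * row$level_1c / tot,
    level_2a = 100 * row$level_2a / tot)
}
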