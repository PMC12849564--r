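#' Built-in region archetype profiles
#'
#' Expected phenotype compositions and cell densities of the tissue-region
#' archetypes planted by the synthetic generator: nine archetypes for
#' early-stage (neoplasia) tumors and seven for late-stage (carcinoma)
#' tumors. Each stage carries three tumor-enriched archetypes (core, mid and
#' a myofibroblastic-CAF-rich margin that acts as a shield around the core),
#' one immune-exclusive archetype, one mCAF2-exclusive archetype, one mixed
#' immune + mCAF2 archetype, and endothelial-enriched archetypes (two early,
#' one late); the myofibroblast-exclusive archetype occurs early only.
#'
#' Fractions are qualitative encodings of the published enrichment patterns,
#' not measured values: the immune-rich archetypes carry more mCAF2 than
#' mCAF1, late-stage tumor-rich archetypes more mCAF1/vCAF1 than
#' mCAF2/vCAF2, early-stage tumor-rich archetypes more vCAF2 than vCAF1,
#' and so on.
#'
#' @param stage `"early"` or `"late"`.
#' @return A tibble with one row per archetype: `name`, `role`,
#'   `density` (expected cells per mm^2) and one fraction column per
#'   phenotype (rows sum to 1).
#' @export
#' @examples
#' builtin_archetypes("late")
builtin_archetypes <- function(stage = c("early", "late")) {
  if (!is.character(stage) || length(stage) != 1L || !stage %in% c("early", "late")) {
    abort('`stage` must be "early" or "late".')
  }
  # columns: tumor, immune, endothelial, mCAF1, mCAF2, vCAF1, vCAF2, intCAF, myofibroblast
  rows <- if (stage == "early") list(
    list("E1", "myofibroblast", 6000, c(.08, .05, .03, .11, .06, .04, .03, .04, .56)),
    list("E2", "mcaf2",         6000, c(.03, .02, .03, .04, .72, .06, .04, .03, .03)),
    list("E3", "immune",        7500, c(.02, .80, .03, .01, .03, .05, .02, .02, .02)),
    list("E4", "endothelial",   4500, c(.05, .07, .42, .05, .06, .20, .06, .04, .05)),
    list("E5", "tumor_core",    9000, c(.93, .002, .008, .01, .02, .005, .015, .005, .005)),
    list("E6", "mixed",         9000, c(.02, .36, .03, .02, .30, .14, .02, .07, .04)),
    list("E7", "endothelial2",  6000, c(.04, .09, .30, .03, .10, .04, .28, .04, .08)),
    list("E8", "tumor_margin",  5000, c(.14, .02, .02, .26, .16, .04, .08, .06, .22)),
    list("E9", "tumor_mid",     7500, c(.56, .01, .02, .05, .12, .02, .12, .07, .03))
  ) else list(
    list("L1", "tumor_core",    9000, c(.93, .002, .008, .02, .005, .015, .005, .005, .01)),
    list("L2", "mixed",         9000, c(.02, .36, .03, .02, .30, .02, .18, .05, .02)),
    list("L3", "immune",        7500, c(.02, .80, .03, .01, .03, .02, .05, .02, .02)),
    list("L4", "endothelial",   4500, c(.05, .07, .44, .04, .07, .16, .10, .04, .03)),
    list("L5", "mcaf2",         6000, c(.03, .02, .03, .04, .72, .02, .06, .04, .04)),
    list("L6", "tumor_margin",  5000, c(.14, .01, .02, .44, .02, .12, .02, .03, .20)),
    list("L7", "tumor_mid",     7500, c(.56, .01, .02, .14, .02, .12, .01, .09, .03))
  )
  comp <- do.call(rbind, lapply(rows, function(r) r[[4]]))
  colnames(comp) <- caf_phenotypes()
  out <- bind_cols(
    tibble(
      name    = vapply(rows, `[[`, character(1), 1),
      role    = vapply(rows, `[[`, character(1), 2),
      density = vapply(rows, function(r) as.numeric(r[[3]]), numeric(1))
    ),
    as_tibble(comp)
  )
  validate_archetypes(out)
  out
}

#' Validate an archetype profile table
#'
#' Checks that every phenotype fraction is non-negative, that each row sums
#' to one within `1e-9`, and that densities are positive.
#'
#' @param archetypes A tibble as returned by [builtin_archetypes()].
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_archetypes <- function(archetypes) {
  ph <- caf_phenotypes()
  miss <- setdiff(c("name", "density", ph), names(archetypes))
  if (length(miss)) {
    abort(paste0("Archetype table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  frac <- as.matrix(archetypes[ph])
  if (any(frac < 0)) abort("Archetype fractions must be non-negative.")
  s <- rowSums(frac)
  if (any(abs(s - 1) > 1e-9)) {
    bad <- archetypes$name[abs(s - 1) > 1e-9]
    abort(paste0("Archetype composition must sum to 1: ", paste(bad, collapse = ", ")))
  }
  if (any(archetypes$density <= 0)) abort("Archetype densities must be > 0.")
  if (anyDuplicated(archetypes$name)) abort("Archetype names must be unique.")
  invisible(archetypes)
}
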