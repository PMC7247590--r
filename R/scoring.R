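#' Scoring-method registry
#'
#' The six in-silico deleteriousness scoring methods supported by the
#' pipeline. Each entry records the orientation of the raw score (whether a
#' lower or a higher raw value means a more damaging variant) and, for
#' bounded methods, the native score range. SIFT is the reference scale:
#' raw SIFT scores already live in \[0,1\] with lower = more deleterious, so
#' they pass through normalization unchanged. MutationTaster and both
#' PolyPhen-2 models are bounded on \[0,1\] with the opposite orientation;
#' phyloP and GERP++ are conservation scores on an unbounded scale and are
#' min-max rescaled over the scores observed in the annotation table.
#'
#' @return A data.frame with one row per method and columns `method`,
#'   `orientation` (`"lower_is_deleterious"` or `"higher_is_deleterious"`),
#'   `lower`, `upper` (native range; `NA` for unbounded methods).
#' @export
#' @examples
#' scoring_methods()
scoring_methods <- function() {
  data.frame(
    method = c("SIFT", "MutationTaster", "PolyPhen2_HDIV", "PolyPhen2_HVAR",
               "phyloP", "GERPpp"),
    orientation = c("lower_is_deleterious", rep("higher_is_deleterious", 5L)),
    lower = c(0, 0, 0, 0, NA, NA),
    upper = c(1, 1, 1, 1, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' @rdname scoring_methods
#' @export
scoring_method_names <- function() scoring_methods()$method

method_info <- function(method) {
  reg <- scoring_methods()
  i <- match(method, reg$method)
  if (is.na(i)) {
    stop("unknown scoring method '", method, "'; known methods: ",
         paste(reg$method, collapse = ", "), call. = FALSE)
  }
  reg[i, ]
}

#' Normalize raw variant scores to a common deleteriousness scale
#'
#' Maps the raw scores of one method onto \[0,1\] so that, for every method,
#' a lower normalized score means a more severely deleterious variant.
#' SIFT is returned unchanged. Bounded higher-is-deleterious methods
#' (MutationTaster, PolyPhen-2 HDIV/HVAR) are affinely flipped over their
#' native range, `1 - (x - lower)/(upper - lower)`. Unbounded methods
#' (phyloP, GERP++) are min-max scaled over the raw scores observed in
#' `variants` and then flipped: `1 - (x - min)/(max - min)`. The observed
#' range is taken over the whole annotation table, never per individual, so
#' each variant has a single cohort-wide normalized score.
#'
#' @param variants Annotation data.frame as returned by [read_annotation()],
#'   with one raw-score column per method (`NA` = score absent).
#' @param method One of [scoring_method_names()].
#' @return Named numeric vector of normalized scores in \[0,1\], keyed by
#'   `variant_id`. Variants without a raw score for `method` are absent.
#' @export
#' @examples
#' ann <- data.frame(variant_id = c("v1", "v2", "v3"),
#'                   GERPpp = c(-2, 2, 6))
#' normalize_scores(ann, "GERPpp")  # c(v1 = 1, v2 = 0.5, v3 = 0)
normalize_scores <- function(variants, method) {
  info <- method_info(method)
  if (!method %in% names(variants)) {
    stop("annotation has no raw-score column for method '", method, "'",
         call. = FALSE)
  }
  raw <- variants[[method]]
  keep <- !is.na(raw)
  if (!any(keep)) {
    stop("no variant has a raw score for method '", method, "'",
         call. = FALSE)
  }
  x <- raw[keep]
  if (is.na(info$lower)) {
    lo <- min(x)
    hi <- max(x)
    if (hi == lo) {
      stop("degenerate scale for unbounded method '", method,
           "': all observed raw scores equal ", lo, call. = FALSE)
    }
  } else {
    lo <- info$lower
    hi <- info$upper
    bad <- x < lo | x > hi
    if (any(bad)) {
      stop(sum(bad), " raw ", method, " score(s) outside native range [",
           lo, ", ", hi, "]", call. = FALSE)
    }
  }
  s <- (x - lo) / (hi - lo)
  if (info$orientation == "higher_is_deleterious") s <- 1 - s
  stats::setNames(s, variants$variant_id[keep])
}

#' Retain deleterious nonsynonymous coding variants
#'
#' Applies the variant retention rule: a variant contributes to gene burdens
#' iff it is nonsynonymous coding and its normalized deleteriousness score is
#' at or below `cutoff` (default 0.7, the published SIFT threshold; here
#' applied on the common normalized scale of every method). Scores are passed
#' through unchanged.
#'
#' @param normalized Named numeric vector from [normalize_scores()].
#' @param variants Annotation data.frame (supplies `consequence`).
#' @param cutoff Retention threshold in \[0,1\]; variants with normalized
#'   score `<= cutoff` are kept.
#' @return Named numeric vector, the retained subset of `normalized`.
#' @export
retain_deleterious <- function(normalized, variants, cutoff = 0.7) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L)
  if (is.na(cutoff) || cutoff < 0 || cutoff > 1) {
    stop("cutoff must lie in [0, 1], got ", cutoff, call. = FALSE)
  }
  if (any(normalized < 0 | normalized > 1, na.rm = TRUE)) {
    stop("normalized scores must lie in [0, 1]", call. = FALSE)
  }
  nonsyn <- variants$variant_id[variants$consequence == "nonsynonymous_coding"]
  normalized[names(normalized) %in% nonsyn & normalized <= cutoff]
}
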