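# Classical Gensini banded severity points and segment multipliers
# (Gensini 1983). Stenosis bands are lower-closed: a stenosis exactly at a
# band edge takes the upper band's score; 100% (total occlusion) scores 32.
.gensini_severity_breaks <- c(0, 25, 50, 75, 90, 99, 100)
.gensini_severity_points <- c(0, 1, 2, 4, 8, 16, 32)

.gensini_location <- c(
  LM = 5, pLAD = 2.5, pLCx = 2.5, mLAD = 1.5,
  dLAD = 1, RCA = 1, OM = 1, PDA = 1, OTHER = 0.5
)

#' Gensini scoring configuration
#'
#' Bundles the banded severity table, the segment location multipliers, the
#' collateral dampening factor and the logarithm offset used to turn the raw
#' worst-case lesion product into the continuous modified Gensini training
#' target. The tables can be overridden so alternative Gensini dialects are
#' reproducible bit-exactly (see [read_gensini_config()]).
#'
#' @param dampening_factor Multiplier applied to the raw worst-case score
#'   when collaterals are present. Fixed at 0.25 in the reference pipeline.
#' @param log_offset Offset inside the logarithm so lesion-free subjects map
#'   to exactly zero: `modified = log(log_offset + raw)`.
#' @param severity_breaks Ascending lower edges of the stenosis bands (%).
#' @param severity_points Score for each band; strictly increasing.
#' @param location Named vector of positive segment multipliers.
#' @return An object of class `gensini_config`.
#' @examples
#' cfg <- gensini_config()
#' severity_score(90)                 # 8
#' location_multiplier("pLAD")        # 2.5
#' @export
gensini_config <- function(dampening_factor = 0.25, log_offset = 1,
                           severity_breaks = .gensini_severity_breaks,
                           severity_points = .gensini_severity_points,
                           location = .gensini_location) {
  if (!is.numeric(dampening_factor) || length(dampening_factor) != 1 ||
      dampening_factor <= 0 || dampening_factor > 1)
    stop("dampening_factor must lie in (0, 1]")
  if (log_offset < 0) stop("log_offset must be nonnegative")
  if (length(severity_breaks) != length(severity_points))
    stop("severity_breaks and severity_points must have equal length")
  if (is.unsorted(severity_breaks, strictly = TRUE))
    stop("severity_breaks must be strictly ascending")
  if (is.unsorted(severity_points, strictly = TRUE))
    stop("severity_points must be strictly increasing")
  if (is.null(names(location)) || any(location <= 0))
    stop("location must be a named vector of positive multipliers")
  structure(list(dampening_factor = dampening_factor, log_offset = log_offset,
                 severity_breaks = severity_breaks,
                 severity_points = severity_points,
                 location = location),
            class = "gensini_config")
}

#' Load a Gensini configuration from JSON
#'
#' @param path Path to a JSON file with any of the fields of
#'   [gensini_config()]; missing fields take the defaults.
#' @return A `gensini_config` object.
#' @export
read_gensini_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (f in c("dampening_factor", "log_offset", "severity_breaks",
              "severity_points"))
    if (!is.null(raw[[f]])) args[[f]] <- as.numeric(raw[[f]])
  if (!is.null(raw$location)) args$location <- unlist(raw$location)
  do.call(gensini_config, args)
}

#' Gensini severity score of a stenosis percentage
#'
#' Banded mapping: \[0,25) -> 0, \[25,50) -> 1, \[50,75) -> 2, \[75,90) -> 4,
#' \[90,99) -> 8, \[99,100) -> 16 and exactly 100 -> 32.
#'
#' @param stenosis Percent diameter reduction, in \[0, 100\]. Vectorised.
#' @param config A [gensini_config()].
#' @return Integer-valued severity score(s).
#' @export
severity_score <- function(stenosis, config = gensini_config()) {
  if (!is.numeric(stenosis)) stop("stenosis must be numeric")
  if (any(!is.finite(stenosis)) || any(stenosis < 0 | stenosis > 100))
    stop("stenosis must lie in [0, 100]")
  config$severity_points[findInterval(stenosis, config$severity_breaks)]
}

#' Gensini location multiplier of a coronary segment
#'
#' @param segment Character vector of segment codes (LM, pLAD, mLAD, dLAD,
#'   pLCx, OM, RCA, PDA, OTHER).
#' @param config A [gensini_config()].
#' @return Positive multiplier(s).
#' @export
location_multiplier <- function(segment, config = gensini_config()) {
  m <- config$location[as.character(segment)]
  if (anyNA(m))
    stop("unknown segment code(s): ",
         paste(unique(segment[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Construct an angiogram record
#'
#' @param stenosis,segment,ffr_measured,ffr Parallel per-lesion vectors; all
#'   may be length zero for a lesion-free subject. `ffr` must be present
#'   (in (0, 1\]) exactly where `ffr_measured` is TRUE and NA elsewhere.
#' @param collaterals_present Logical flag.
#' @return An object of class `angiogram`.
#' @export
angiogram_record <- function(stenosis = numeric(), segment = character(),
                             ffr_measured = logical(), ffr = numeric(),
                             collaterals_present = FALSE) {
  n <- length(stenosis)
  if (length(segment) != n || length(ffr_measured) != n || length(ffr) != n)
    stop("lesion fields must have equal length")
  if (any(ffr_measured & (is.na(ffr) | ffr <= 0 | ffr > 1)))
    stop("measured FFR values must lie in (0, 1]")
  if (any(!ffr_measured & !is.na(ffr)))
    stop("ffr must be NA where ffr_measured is FALSE")
  structure(list(
    lesions = data.frame(stenosis = as.numeric(stenosis),
                         segment = as.character(segment),
                         ffr_measured = as.logical(ffr_measured),
                         ffr = as.numeric(ffr)),
    collaterals_present = isTRUE(collaterals_present)),
    class = "angiogram")
}

#' Modified (continuous) Gensini score of an angiogram
#'
#' Only the worst-case lesion counts: the raw score is the maximum over
#' lesions of severity score times location multiplier (zero for a
#' lesion-free subject). When collaterals are present the raw score is
#' dampened by `dampening_factor` before the log transform
#' `modified = log(log_offset + raw)`.
#'
#' @param angiogram An [angiogram_record()].
#' @param config A [gensini_config()].
#' @return A list with `raw_worst_case`, `modified_score` and `cad_label`
#'   (`"positive"`/`"negative"`, per [cad_label()]).
#' @examples
#' a <- angiogram_record(90, "pLAD", FALSE, NA)
#' modified_gensini(a)$modified_score   # log(21)
#' @export
modified_gensini <- function(angiogram, config = gensini_config()) {
  les <- angiogram$lesions
  raw <- if (nrow(les) == 0) 0 else
    max(severity_score(les$stenosis, config) *
          location_multiplier(les$segment, config))
  if (angiogram$collaterals_present) raw <- raw * config$dampening_factor
  list(raw_worst_case = raw,
       modified_score = log(config$log_offset + raw),
       cad_label = cad_label(angiogram))
}

#' Binary CAD label of an angiogram (angiographic gold standard)
#'
#' A lesion is disease-positive iff its measured FFR is <= 0.80, or, when no
#' FFR was measured, its stenosis is >= 70%. A measured FFR overrides the
#' visual stenosis (a 75% lesion with FFR 0.85 is negative). The subject is
#' positive iff any lesion is positive; a lesion-free subject is negative.
#'
#' @param angiogram An [angiogram_record()].
#' @return `"positive"` or `"negative"`.
#' @export
cad_label <- function(angiogram) {
  if (.cad_positive(angiogram$lesions$stenosis,
                    angiogram$lesions$ffr_measured,
                    angiogram$lesions$ffr)) "positive" else "negative"
}

# vectorised lesion rule shared with the cohort generator
.lesion_positive <- function(stenosis, ffr_measured, ffr) {
  ifelse(ffr_measured, ffr <= 0.80, stenosis >= 70)
}

.cad_positive <- function(stenosis, ffr_measured, ffr) {
  length(stenosis) > 0 && any(.lesion_positive(stenosis, ffr_measured, ffr))
}
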