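#' Descriptive statistics for one functional area
#'
#' Per-element mean, sample SD (n - 1 denominator), coefficient of
#' variation (percent), adjusted Fisher–Pearson skewness and excess
#' kurtosis (the bias-corrected estimators reported by SPSS-style
#' software; `e1071` type 2), and range. Constant-valued elements get
#' `cv = 0` and undefined (`NA`) shape statistics.
#'
#' @param samples Samples data frame (see [read_samples()]).
#' @param area Area label to summarize; must have at least 3 samples.
#' @param type Estimator type for skewness/kurtosis as in
#'   [e1071::skewness()]; default 2 (adjusted).
#' @return Data frame with columns `area`, `element`, `n`, `mean`, `sd`,
#'   `cv`, `skewness`, `kurtosis`, `min`, `max`.
#' @export
summarize_area <- function(samples, area, type = 2) {
  .validate_samples(samples, require_coords = FALSE)
  s <- samples[samples$area == area, , drop = FALSE]
  if (nrow(s) < 3L) {
    stop("need at least 3 samples in area ", area, " (got ", nrow(s), ")",
         call. = FALSE)
  }
  rows <- lapply(hm_elements(), function(el) {
    x <- s[[el]]
    m <- mean(x)
    sdev <- stats::sd(x)
    degenerate <- sdev == 0
    data.frame(area = area, element = el, n = length(x), mean = m, sd = sdev,
               cv = if (m == 0) 0 else sdev / m * 100,
               skewness = if (degenerate) NA_real_ else
                 e1071::skewness(x, type = type),
               kurtosis = if (degenerate) NA_real_ else
                 e1071::kurtosis(x, type = type),
               min = min(x), max = max(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname summarize_area
#' @return `summarize_areas()` stacks one [summarize_area()] block per
#'   area present in `samples`.
#' @export
summarize_areas <- function(samples, type = 2) {
  do.call(rbind, lapply(sort(unique(samples$area)),
                        function(a) summarize_area(samples, a, type = type)))
}

#' Exceedance ratios against background and screening levels
#'
#' For each element of an area summary, the mean concentration divided
#' by the regional background value and by the GB 15618-2018 screening
#' level, with a flag for means above the screening level.
#'
#' @param summary Output of [summarize_area()] (one or more areas).
#' @param refs Reference table, see [element_references()].
#' @return Data frame with `area`, `element`, `mean`, `ratio_background`,
#'   `ratio_standard`, `exceeds_standard`.
#' @export
exceedance_ratios <- function(summary, refs = element_references()) {
  i <- match(summary$element, refs$element)
  data.frame(area = summary$area, element = summary$element,
             mean = summary$mean,
             ratio_background = summary$mean / refs$background[i],
             ratio_standard = summary$mean / refs$standard[i],
             exceeds_standard = summary$mean > refs$standard[i],
             stringsAsFactors = FALSE)
}

#' Cross-area mean background ratio for one element
#'
#' Arithmetic mean over the three functional areas of the unrounded
#' per-area ratios mean/background.
#'
#' @param summary Multi-area summary ([summarize_areas()] output) that
#'   covers areas A, B and C.
#' @param element Element symbol.
#' @param refs Reference table.
#' @return Single numeric ratio.
#' @export
cross_area_mean_ratio <- function(summary, element,
                                  refs = element_references()) {
  stopifnot(all(c("A", "B", "C") %in% summary$area))
  rows <- summary[summary$element == element, , drop = FALSE]
  bg <- get_reference(element, refs)$background
  mean(rows$mean / bg)
}

#' Composite area mean concentration
#'
#' Sum of the six per-element mean concentrations divided by
#' `denominator`. The arithmetic mean divides by 6 (default).
#' `denominator = 5` reproduces a composite convention seen in some
#' survey reports (sum of the six means over five) and warns, since it
#' is not a standard mean.
#'
#' @param summary Area summary (one or more areas).
#' @param denominator 6 (arithmetic mean, default) or 5.
#' @return Named numeric vector, one composite value (mg/kg) per area.
#' @export
composite_area_mean <- function(summary, denominator = 6) {
  stopifnot(denominator %in% c(5, 6))
  if (denominator == 5) {
    warning("denominator = 5 divides the sum of six element means by five; ",
            "this is a reporting convention, not an arithmetic mean",
            call. = FALSE)
  }
  totals <- tapply(summary$mean, summary$area, sum)
  if (any(tapply(summary$element, summary$area, length) != 6L)) {
    stop("each area needs all six element means", call. = FALSE)
  }
  stats::setNames(as.numeric(totals) / denominator, names(totals))
}

#' Flag strongly variable elements
#'
#' Elements whose coefficient of variation exceeds a threshold
#' (strictly greater), conventionally 36%: strong spatial variation,
#' read as a signature of uneven anthropogenic input.
#'
#' @param summary Area summary (one or more areas).
#' @param threshold CV threshold in percent; default 36.
#' @return For a single-area summary, a character vector of flagged
#'   elements; otherwise a named list of such vectors, one per area.
#' @export
flag_strong_variation <- function(summary, threshold = 36) {
  flagged <- lapply(split(summary, summary$area),
                    function(s) s$element[s$cv > threshold])
  if (length(flagged) == 1L) flagged[[1L]] else flagged
}
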