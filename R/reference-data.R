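#' Registered heavy-metal elements
#'
#' The six elements measured by the pipeline, in registry order. All
#' element-indexed tables in the package follow this order.
#'
#' @return Character vector `c("Zn", "Cu", "Cr", "Pb", "As", "Hg")`.
#' @export
hm_elements <- function() c("Zn", "Cu", "Cr", "Pb", "As", "Hg")

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "metalrisk")
  if (!nzchar(path)) stop("fixture not found: ", file, call. = FALSE)
  path
}

#' Element reference values
#'
#' Per-element reference constants: geochemical background value for
#' Xinjiang soils (mg/kg), the GB 15618-2018 screening ("standard") level
#' (mg/kg), and the Hakanson toxic-response coefficient (dimensionless).
#' Backgrounds and standards are shipped as fixtures; toxicity
#' coefficients are the standard Hakanson (1980) set
#' (Zn = 1, Cr = 2, Cu = Pb = 5, As = 10, Hg = 40).
#'
#' @param overrides Optional overrides for any constant: a data frame
#'   with an `element` column and any of `background`, `standard`,
#'   `toxicity`, or a path to a CSV file with those columns. Only the
#'   listed elements/columns are replaced.
#' @return Data frame with columns `element`, `background`, `standard`,
#'   `toxicity`, one row per element in registry order.
#' @export
element_references <- function(overrides = NULL) {
  refs <- utils::read.csv(.extdata("element_references.csv"),
                          stringsAsFactors = FALSE)
  if (!is.null(overrides)) {
    if (is.character(overrides)) {
      overrides <- utils::read.csv(overrides, stringsAsFactors = FALSE)
    }
    stopifnot(is.data.frame(overrides), "element" %in% names(overrides))
    bad <- setdiff(overrides$element, refs$element)
    if (length(bad)) {
      stop("unknown element in overrides: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (col in intersect(names(overrides), c("background", "standard", "toxicity"))) {
      i <- match(overrides$element, refs$element)
      keep <- !is.na(overrides[[col]])
      refs[[col]][i[keep]] <- overrides[[col]][keep]
    }
  }
  .validate_references(refs)
  refs
}

.validate_references <- function(refs) {
  stopifnot(identical(sort(refs$element), sort(hm_elements())),
            !anyDuplicated(refs$element))
  if (any(refs$background <= 0) || any(refs$standard <= 0)) {
    stop("background and standard levels must be positive", call. = FALSE)
  }
  if (any(refs$toxicity < 1)) {
    stop("toxicity coefficients must be >= 1", call. = FALSE)
  }
  invisible(refs)
}

#' Look up the reference record for one element
#'
#' @param element One of the six registered element symbols.
#' @param refs Reference table, see [element_references()].
#' @return List with `element`, `background`, `standard`, `toxicity`.
#' @export
#' @examples
#' get_reference("Pb")$background  # 19.4
get_reference <- function(element, refs = element_references()) {
  i <- match(element, refs$element)
  if (length(element) != 1L || is.na(i)) {
    stop("unknown element: ", paste(element, collapse = ", "),
         " (expected one of ", paste(refs$element, collapse = ", "), ")",
         call. = FALSE)
  }
  as.list(refs[i, , drop = FALSE])
}

#' Pollution / risk classification schemes
#'
#' Class schemes used throughout the pipeline:
#' \describe{
#'   \item{igeo}{Geo-accumulation index: clean (\eqn{\le 0}), then light /
#'     moderate / high pollution in unit steps, very high above 3.}
#'   \item{pi}{Single-factor pollution index: clean (\eqn{\le 1}),
#'     potential (1–2], mild (2–3], moderate (3–5], heavy (> 5).}
#'   \item{eri}{Per-element potential ecological risk coefficient:
#'     low (< 40), moderate [40, 80), considerable [80, 160),
#'     high [160, 320), very high (\eqn{\ge} 320).}
#'   \item{pri}{Summed potential ecological risk index: same labels with
#'     breaks 90 / 180 / 360 / 720.}
#' }
#' For `igeo` and `pi` a value exactly on a boundary joins the lower
#' (less severe) class, matching the "\eqn{\le}" convention of those
#' scales; for `eri`/`pri` the published dash ranges are half-open, so a
#' boundary value starts the upper class. `boundary_rule` makes either
#' convention explicit and overridable.
#'
#' @param name One of `"igeo"`, `"pi"`, `"eri"`, `"pri"`.
#' @param breakpoints,labels,boundary_rule Optional overrides to build a
#'   custom scheme: strictly increasing breakpoints, one more label than
#'   breakpoints, and `"lower"`/`"upper"` boundary assignment.
#' @return Object of class `classification_scheme`.
#' @export
classification_scheme <- function(name = c("igeo", "pi", "eri", "pri"),
                                  breakpoints = NULL, labels = NULL,
                                  boundary_rule = NULL) {
  name <- match.arg(name)
  risk_labels <- c("Low risk", "Moderate risk", "Considerable risk",
                   "High risk", "Very high risk")
  preset <- switch(name,
    igeo = list(breakpoints = c(0, 1, 2, 3),
                labels = c("Clean", "Light pollution", "Moderate pollution",
                           "High pollution", "Very high pollution"),
                boundary_rule = "lower"),
    pi   = list(breakpoints = c(1, 2, 3, 5),
                labels = c("Clean", "Potential pollution", "Mild pollution",
                           "Moderate pollution", "Heavy pollution"),
                boundary_rule = "lower"),
    eri  = list(breakpoints = c(40, 80, 160, 320), labels = risk_labels,
                boundary_rule = "upper"),
    pri  = list(breakpoints = c(90, 180, 360, 720), labels = risk_labels,
                boundary_rule = "upper"))
  if (!is.null(breakpoints)) preset$breakpoints <- breakpoints
  if (!is.null(labels)) preset$labels <- labels
  if (!is.null(boundary_rule)) {
    preset$boundary_rule <- match.arg(boundary_rule, c("lower", "upper"))
  }
  stopifnot(all(diff(preset$breakpoints) > 0),
            length(preset$labels) == length(preset$breakpoints) + 1L)
  structure(c(list(name = name), preset), class = "classification_scheme")
}

#' Classify index values
#'
#' Maps each finite value to exactly one class label of a scheme; the
#' interval a boundary value joins follows the scheme's `boundary_rule`
#' (see [classification_scheme()]).
#'
#' @param scheme A [classification_scheme()].
#' @param value Numeric vector of finite index values.
#' @return Ordered factor with the scheme's labels as levels (ascending
#'   severity).
#' @export
#' @examples
#' classify(classification_scheme("pi"), 5.56)   # Heavy pollution
#' classify(classification_scheme("igeo"), 0)    # Clean
classify <- function(scheme, value) {
  stopifnot(inherits(scheme, "classification_scheme"))
  if (!is.numeric(value) || any(!is.finite(value))) {
    stop("values to classify must be finite numbers", call. = FALSE)
  }
  idx <- findInterval(value, scheme$breakpoints,
                      left.open = scheme$boundary_rule == "lower") + 1L
  factor(scheme$labels[idx], levels = scheme$labels, ordered = TRUE)
}

#' Reference per-area marginal statistics
#'
#' Descriptive statistics (range, mean, SD, CV, skewness, excess
#' kurtosis; concentrations in mg/kg, CV in percent) for each element in
#' the three land-use functional areas of the reference survey —
#' commercial (A), industrial (B) and agricultural (C) zones of a
#' semi-arid region in NW China. These values calibrate the synthetic
#' generator and drive the desk-level reproduction of the survey's
#' exceedance ratios.
#'
#' @param area Optional area label (`"A"`, `"B"` or `"C"`) to filter on.
#' @return Data frame with columns `area`, `element`, `min`, `max`,
#'   `mean`, `sd`, `cv`, `skewness`, `kurtosis`.
#' @export
area_marginals <- function(area = NULL) {
  m <- utils::read.csv(.extdata("area_marginals.csv"), stringsAsFactors = FALSE)
  if (!is.null(area)) {
    stopifnot(area %in% m$area)
    m <- m[m$area == area, , drop = FALSE]
    rownames(m) <- NULL
  }
  m
}

#' Reference per-area correlation matrices
#'
#' Pearson correlation matrices between the six elements in each
#' functional area of the reference survey, used as copula targets by
#' the synthetic generator.
#'
#' @param area Area label (`"A"`, `"B"` or `"C"`).
#' @return Symmetric 6 x 6 matrix with unit diagonal, element symbols as
#'   dimnames.
#' @export
area_correlations <- function(area) {
  long <- utils::read.csv(.extdata("area_correlations.csv"),
                          stringsAsFactors = FALSE)
  stopifnot(length(area) == 1L, area %in% long$area)
  long <- long[long$area == area, , drop = FALSE]
  els <- hm_elements()
  r <- diag(length(els))
  dimnames(r) <- list(els, els)
  r[cbind(long$row, long$col)] <- long$r
  r[cbind(long$col, long$row)] <- long$r
  r
}
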