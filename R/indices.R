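#' Geo-accumulation index
#'
#' Muller's geo-accumulation index
#' \eqn{I_{geo} = \log_2\!\big(C_n / (1.5\, B_n)\big)}, where \eqn{C_n}
#' is the measured concentration and \eqn{B_n} the geochemical
#' background; the factor 1.5 absorbs natural lithogenic variation.
#'
#' @param concentration Measured concentration (mg/kg), > 0.
#' @param background Background value (mg/kg), > 0.
#' @return Dimensionless index; doubles in concentration add exactly 1.
#' @export
compute_igeo <- function(concentration, background) {
  if (any(concentration <= 0) || any(background <= 0)) {
    stop("igeo requires positive concentration and background (log domain)",
         call. = FALSE)
  }
  log2(concentration / (1.5 * background))
}

#' Single-factor pollution index
#'
#' \eqn{P_i = C_i / B_n}: measured concentration over the regional
#' background value.
#'
#' @param concentration Measured concentration (mg/kg), >= 0.
#' @param background Background value (mg/kg), > 0.
#' @return Dimensionless ratio.
#' @export
compute_pi <- function(concentration, background) {
  if (any(background <= 0)) stop("background must be positive", call. = FALSE)
  if (any(concentration < 0)) {
    stop("concentration must be non-negative", call. = FALSE)
  }
  concentration / background
}

#' Potential ecological risk coefficient
#'
#' Hakanson's per-element coefficient
#' \eqn{E_r^i = T_n^i \, C_i / C_n^i}: the toxic-response coefficient
#' times the pollution ratio against background.
#'
#' @param concentration Measured concentration (mg/kg), >= 0.
#' @param background Background value (mg/kg), > 0.
#' @param toxicity Toxic-response coefficient, >= 1.
#' @return Dimensionless coefficient; equals `toxicity * compute_pi(...)`.
#' @export
compute_eri <- function(concentration, background, toxicity) {
  if (any(toxicity < 1)) stop("toxicity coefficient must be >= 1", call. = FALSE)
  toxicity * compute_pi(concentration, background)
}

#' Potential ecological risk index of one sample
#'
#' Sums the per-element risk coefficients \eqn{E_r^i} over the six
#' elements and classifies the total on the summed-risk scheme
#' (low < 90, moderate, considerable, high, very high > 720).
#'
#' @param concentrations Named numeric vector of concentrations (mg/kg)
#'   containing all six registered elements.
#' @param refs Reference table, see [element_references()].
#' @return List with `pri` (numeric) and `class` (ordered factor level).
#' @export
#' @examples
#' x <- c(Zn = 68.8, Cu = 26.7, Cr = 49.3, Pb = 19.4, As = 11.2, Hg = 0.02)
#' compute_pri(x)$pri  # 63: sum of the toxicity coefficients
compute_pri <- function(concentrations, refs = element_references()) {
  missing <- setdiff(refs$element, names(concentrations))
  if (length(missing)) {
    stop("missing element concentrations: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  eri <- compute_eri(as.numeric(concentrations[refs$element]),
                     refs$background, refs$toxicity)
  total <- sum(eri)
  list(pri = total,
       class = classify(classification_scheme("pri"), total),
       eri = stats::setNames(eri, refs$element))
}

.validate_samples <- function(samples, require_coords = TRUE) {
  els <- hm_elements()
  needed <- c("sample_id", "area", if (require_coords) c("x", "y"), els)
  missing <- setdiff(needed, names(samples))
  if (length(missing)) {
    stop("samples table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(samples) == 0L) stop("empty sample collection", call. = FALSE)
  for (el in els) {
    bad <- !is.finite(samples[[el]]) | samples[[el]] <= 0
    if (any(bad)) {
      stop("non-positive or missing ", el, " concentration for sample(s): ",
           paste(samples$sample_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  if (require_coords && any(!is.finite(samples$x) | !is.finite(samples$y))) {
    stop("non-finite coordinates in samples table", call. = FALSE)
  }
  invisible(samples)
}

#' Index table for a sample collection
#'
#' Computes, for every (sample, element) pair, the geo-accumulation
#' index, the single-factor pollution index and the potential ecological
#' risk coefficient with their class labels, plus one summed risk index
#' (PRI) per sample. Rows are ordered by input sample order, then
#' element registry order.
#'
#' @param samples Data frame with columns `sample_id`, `area`, `x`, `y`
#'   and one concentration column (mg/kg) per element.
#' @param refs Reference table, see [element_references()].
#' @return Object of class `index_table`: list with data frames
#'   `elements` (per sample x element: `igeo`, `pi`, `eri` + classes)
#'   and `samples` (per sample: `pri` + class).
#' @export
build_index_table <- function(samples, refs = element_references()) {
  .validate_samples(samples, require_coords = FALSE)
  els <- refs$element
  n <- nrow(samples)
  sch <- list(igeo = classification_scheme("igeo"),
              pi = classification_scheme("pi"),
              eri = classification_scheme("eri"),
              pri = classification_scheme("pri"))

  long <- data.frame(
    sample_id = rep(samples$sample_id, each = length(els)),
    area = rep(samples$area, each = length(els)),
    element = rep(els, times = n),
    concentration = as.vector(t(as.matrix(samples[, els]))),
    stringsAsFactors = FALSE)
  i <- match(long$element, els)
  long$igeo <- compute_igeo(long$concentration, refs$background[i])
  long$igeo_class <- classify(sch$igeo, long$igeo)
  long$pi <- compute_pi(long$concentration, refs$background[i])
  long$pi_class <- classify(sch$pi, long$pi)
  long$eri <- compute_eri(long$concentration, refs$background[i],
                          refs$toxicity[i])
  long$eri_class <- classify(sch$eri, long$eri)

  pri <- tapply(long$eri, factor(long$sample_id, levels = samples$sample_id),
                sum)
  per_sample <- data.frame(sample_id = samples$sample_id, area = samples$area,
                           pri = as.numeric(pri), stringsAsFactors = FALSE)
  per_sample$pri_class <- classify(sch$pri, per_sample$pri)

  structure(list(elements = long, samples = per_sample),
            class = "index_table")
}

#' @export
print.index_table <- function(x, ...) {
  cat("Index table:", nrow(x$samples), "samples x",
      length(unique(x$elements$element)), "elements\n")
  cat("PRI classes:\n")
  print(table(x$samples$pri_class))
  invisible(x)
}

#' Read / write the canonical samples CSV
#'
#' The canonical exchange format is a CSV with header
#' `sample_id,area,x,y,Zn,Cu,Cr,Pb,As,Hg` (concentrations in mg/kg,
#' coordinates in projected meters).
#'
#' @param path File path.
#' @return `read_samples()` returns the validated samples data frame.
#' @export
read_samples <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  .validate_samples(s)
  s
}

#' @rdname read_samples
#' @param samples Samples data frame.
#' @export
write_samples <- function(samples, path) {
  .validate_samples(samples)
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

#' Write an index table as a long-format CSV
#'
#' One row per (sample, element) with all three indices and class
#' labels; the per-sample PRI and its class are repeated on each row of
#' the sample.
#'
#' @param tbl An `index_table` from [build_index_table()].
#' @param path Output file path.
#' @export
write_index_table <- function(tbl, path) {
  stopifnot(inherits(tbl, "index_table"))
  long <- tbl$elements
  i <- match(long$sample_id, tbl$samples$sample_id)
  long$pri <- tbl$samples$pri[i]
  long$pri_class <- tbl$samples$pri_class[i]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
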