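#' Calibration specification for volume-outcome quality functions
#'
#' Quality per patient is modeled as a piecewise-linear function of the number
#' of locations `NL` jointly treating a diagnosis group's national caseload:
#' fewer locations mean higher per-site volume and, for groups with a
#' volume-outcome relationship, better outcomes. Slopes are anchored on a
#' reference concentration scenario for the strongest ("high") category —
#' by default a gain of 0.5 QALY per patient when care is concentrated from
#' 94 to 15 locations — and the other categories are fixed fractions of that
#' slope (intermediate 50%, low 5%, none 0%).
#'
#' @param reference_gain_qaly QALY gained per patient in the reference
#'   concentration scenario (default 0.5).
#' @param reference_nl_from,reference_nl_to location counts bracketing the
#'   reference scenario (default 94 down to 15); `reference_nl_to` must be
#'   strictly smaller than `reference_nl_from`.
#' @param category_ratio named numeric, fraction of the high-category slope
#'   assigned to each volume-outcome category; all values in `[0, 1]`.
#' @param baseline_nl location count at which the quality gain is defined to
#'   be zero (default 94, the status-quo landscape), so evaluated quality is a
#'   gain relative to the current situation.
#' @param knots integer breakpoints used when a quality function is split into
#'   linear segments for the piecewise refinement loop.
#' @return an object of class `calibration_spec`.
#' @seealso [calibrate_slopes()], [build_quality_function()]
#' @export
calibration_spec <- function(reference_gain_qaly = 0.5,
                             reference_nl_from = 94L,
                             reference_nl_to = 15L,
                             category_ratio = c(high = 1, intermediate = 0.5,
                                                low = 0.05, none = 0),
                             baseline_nl = 94L,
                             knots = c(1L, 15L, 40L, 94L)) {
  stopifnot(reference_gain_qaly > 0, reference_nl_from >= 1,
            reference_nl_to >= 1, baseline_nl >= 1)
  if (reference_nl_to == reference_nl_from)
    stop("degenerate calibration anchor: reference_nl_from == reference_nl_to",
         call. = FALSE)
  if (reference_nl_to > reference_nl_from)
    stop("reference_nl_to must be smaller than reference_nl_from", call. = FALSE)
  miss <- setdiff(names(vo_categories()), names(category_ratio))
  if (length(miss))
    stop("category_ratio missing categories: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(category_ratio < 0 | category_ratio > 1))
    stop("category ratios must lie in [0, 1]", call. = FALSE)
  structure(list(reference_gain_qaly = reference_gain_qaly,
                 reference_nl_from = as.integer(reference_nl_from),
                 reference_nl_to = as.integer(reference_nl_to),
                 category_ratio = category_ratio,
                 baseline_nl = as.integer(baseline_nl),
                 knots = sort(unique(as.integer(knots)))),
            class = "calibration_spec")
}

#' Volume-outcome categories
#'
#' Named vector of the recognized volume-outcome categories with their default
#' slope ratios relative to the reference ("high") category.
#' @return named numeric vector.
#' @export
vo_categories <- function() {
  c(high = 1, intermediate = 0.5, low = 0.05, none = 0)
}

#' Calibrate per-category quality slopes
#'
#' The high-category slope is the reference QALY gain divided by the number of
#' locations removed in the reference scenario, with a negative sign (quality
#' per patient falls as locations are added):
#' `a_high = -gain / (nl_from - nl_to)`. Every other category's slope is its
#' configured fraction of `a_high`.
#'
#' @param spec a [calibration_spec()].
#' @return named numeric vector of slopes (QALY/patient per additional
#'   location), one per volume-outcome category.
#' @examples
#' calibrate_slopes(calibration_spec())  # high = -0.5/79
#' @export
calibrate_slopes <- function(spec = calibration_spec()) {
  stopifnot(inherits(spec, "calibration_spec"))
  a_high <- -spec$reference_gain_qaly /
    (spec$reference_nl_from - spec$reference_nl_to)
  slopes <- spec$category_ratio * a_high
  slopes[names(spec$category_ratio)]
}

#' Build a piecewise-linear quality function for a diagnosis group
#'
#' Returns the per-patient QALY gain (relative to the `baseline_nl` landscape)
#' as a piecewise-linear, continuous function of the number of locations
#' `NL` treating the group. The default `shape = "linear"` build uses the
#' category slope on every segment, so the function is globally linear and the
#' segments only matter to the refinement loop. `shape = "convex"` steepens
#' the slope (by `convex_factor`) on segments at or below the reference
#' concentration target, emulating diminishing returns of concentration while
#' preserving continuity at the knots.
#'
#' @param group a single-row data frame or list with at least `vo_category`
#'   (and `id`, used for labeling if present).
#' @param spec a [calibration_spec()].
#' @param max_sites number of candidate sites; the function's domain is
#'   `[1, max_sites]`.
#' @param shape `"linear"` (default) or `"convex"`.
#' @param convex_factor slope multiplier applied below the reference target in
#'   the convex build (default 2).
#' @return object of class `quality_function`: a data frame of segments with
#'   columns `nl_lo`, `nl_hi`, `slope`, `intercept`, carrying attributes
#'   `group_id` and `vo_category`.
#' @export
build_quality_function <- function(group, spec = calibration_spec(), max_sites,
                                   shape = c("linear", "convex"),
                                   convex_factor = 2) {
  shape <- match.arg(shape)
  stopifnot(max_sites >= 1)
  max_sites <- as.integer(max_sites)
  cat_ <- as.character(group$vo_category)
  if (!cat_ %in% names(spec$category_ratio))
    stop("unknown vo_category: ", cat_, call. = FALSE)
  a <- unname(calibrate_slopes(spec)[cat_])

  # segment bounds from knots clipped to [1, max_sites]
  ks <- sort(unique(c(spec$knots[spec$knots < max_sites & spec$knots > 1L],
                      max_sites)))
  nl_lo <- c(1L, head(ks, -1L) + 1L)
  nl_hi <- ks

  slopes <- rep(a, length(nl_lo))
  if (shape == "convex")
    slopes[nl_hi <= spec$reference_nl_to] <- a * convex_factor

  # anchor: zero gain at the baseline landscape (clipped into the domain),
  # then propagate intercepts so adjacent lines agree at each shared knot
  anchor <- min(spec$baseline_nl, max_sites)
  j <- findInterval(anchor, nl_lo)
  b <- numeric(length(nl_lo))
  b[j] <- -slopes[j] * anchor
  if (j < length(nl_lo))
    for (k in seq(j + 1L, length(nl_lo)))
      b[k] <- (slopes[k - 1L] - slopes[k]) * nl_hi[k - 1L] + b[k - 1L]
  if (j > 1L)
    for (k in seq(j - 1L, 1L))
      b[k] <- (slopes[k + 1L] - slopes[k]) * nl_hi[k] + b[k + 1L]

  qf <- data.frame(nl_lo = nl_lo, nl_hi = nl_hi,
                   slope = slopes, intercept = b)
  structure(qf, class = c("quality_function", "data.frame"),
            group_id = if (!is.null(group$id)) group$id else NA_integer_,
            vo_category = cat_)
}

# segment index of a quality function containing nl, or error
qf_segment_index <- function(qf, nl) {
  i <- which(qf$nl_lo <= nl & nl <= qf$nl_hi)
  if (!length(i))
    stop("location count ", nl, " outside quality-function domain [",
         min(qf$nl_lo), ", ", max(qf$nl_hi), "]", call. = FALSE)
  i[1L]
}

#' Evaluate per-patient quality (QALY) at a location count
#'
#' @param qf a [build_quality_function()] result.
#' @param nl integer location count within the function's domain.
#' @return QALY gain per patient relative to the baseline landscape.
#' @export
evaluate_quality_qaly <- function(qf, nl) {
  vapply(nl, function(x) {
    i <- qf_segment_index(qf, x)
    qf$slope[i] * x + qf$intercept[i]
  }, numeric(1))
}

#' Evaluate group-level quality in euros
#'
#' Monetizes the per-patient quality gain at `nl` locations:
#' `EQ * NP_d * (a_d * nl + b_d)` using the segment containing `nl`.
#'
#' @param group single-row data frame or list with `n_patients`.
#' @param qf the group's quality function.
#' @param nl location count.
#' @param eq euros per QALY.
#' @return euros (quality gain valued in money).
#' @examples
#' g <- list(id = 1L, vo_category = "high", n_patients = 100)
#' qf <- build_quality_function(g, calibration_spec(), max_sites = 150)
#' evaluate_quality_eur(g, qf, nl = 15, eq = 50000)
#' @export
evaluate_quality_eur <- function(group, qf, nl, eq) {
  stopifnot(eq > 0, group$n_patients > 0)
  as.numeric(eq) * as.numeric(group$n_patients) *
    evaluate_quality_qaly(qf, nl)
}

#' @export
print.quality_function <- function(x, ...) {
  cat(sprintf("Quality function (group %s, category %s): %d segment(s) on [1, %d]\n",
              attr(x, "group_id"), attr(x, "vo_category"),
              nrow(x), max(x$nl_hi)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
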