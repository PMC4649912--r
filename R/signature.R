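#' Extract a biomarker signature profile
#'
#' Pulls the mean CT of each panel miRNA for one (platform, sample) into an
#' ordered profile suitable for radar-plot style comparison. Replicates are
#' collapsed by the arithmetic mean of determined CTs (runs pooled).
#'
#' @param table A [ct_table].
#' @param panel Ordered character vector of at least 3 miRNA ids (the
#'   signature panel; axis order is the caller's).
#' @param platform,sample Identifiers selecting the profile's source.
#' @param invert If `TRUE`, values are flipped to `max_ct - ct` so that
#'   larger radii mean more abundant (lower CT); default plots raw CT.
#' @param max_ct Scale ceiling used when `invert = TRUE` (default 40).
#' @return A list of class `signature_profile`: `panel`, `values` (named,
#'   panel order), `platform`, `sample`.
#' @export
extract_signature <- function(table, panel, platform, sample,
                              invert = FALSE, max_ct = 40) {
  stopifnot(inherits(table, "ct_table"))
  if (length(panel) < 3L) {
    stop("extract_signature: panel needs at least 3 miRNAs", call. = FALSE)
  }
  sub <- table[table$platform == platform & table$sample == sample &
                 table$mirna %in% panel, , drop = FALSE]
  values <- vapply(panel, function(mir) {
    ct <- sub$ct[sub$mirna == mir]
    det <- ct[!is.na(ct)]
    if (length(det) == 0L) {
      stop("extract_signature: panel miRNA '", mir,
           "' has no determined measurement for (", platform, ", ", sample,
           ")", call. = FALSE)
    }
    mean(det)
  }, numeric(1))
  if (invert) values <- pmax(max_ct - values, 0)
  structure(list(panel = panel, values = values,
                 platform = platform, sample = sample),
            class = "signature_profile")
}

#' Polygon area of a radar profile
#'
#' The panel's axes are placed at equal angles around the origin; the
#' profile polygon connects the per-axis radii in order and its area is
#' `0.5 * sin(2*pi/n) * sum_i r_i * r_{i+1}` (indices cyclic). The area is
#' invariant under cyclic rotation or reversal of the axis order and scales
#' quadratically with the radii.
#'
#' @param profile A `signature_profile` or a numeric vector of radii
#'   (length >= 3, non-negative).
#' @return The polygon area in squared axis units.
#' @export
radar_area <- function(profile) {
  r <- if (inherits(profile, "signature_profile")) profile$values else profile
  if (length(r) < 3L) stop("radar_area: need at least 3 axes", call. = FALSE)
  if (any(r < 0)) stop("radar_area: radii must be non-negative", call. = FALSE)
  n <- length(r)
  0.5 * sin(2 * pi / n) * sum(r * r[c(2:n, 1L)])
}

#' Compare two signature profiles
#'
#' Computes both radar areas, their ratio, and the Pearson correlation of
#' the matched axis values ("shape correlation"). Profiles must share the
#' same panel in the same order.
#'
#' @param a,b `signature_profile` objects over identical panels.
#' @return A list of class `profile_comparison`: `area_a`, `area_b`,
#'   `area_ratio` (`area_a / area_b`; 1 if both areas are 0),
#'   `shape_correlation` (`NA` with `degenerate = TRUE` when either profile
#'   has zero variance across axes).
#' @export
compare_profiles <- function(a, b) {
  stopifnot(inherits(a, "signature_profile"),
            inherits(b, "signature_profile"))
  if (!identical(a$panel, b$panel)) {
    stop("compare_profiles: profiles have different panels or axis order",
         call. = FALSE)
  }
  area_a <- radar_area(a)
  area_b <- radar_area(b)
  if (area_b == 0 && area_a > 0) {
    stop("compare_profiles: area ratio undefined (second profile has zero ",
         "area)", call. = FALSE)
  }
  ratio <- if (area_a == 0 && area_b == 0) 1 else area_a / area_b
  degenerate <- stats::sd(a$values) == 0 || stats::sd(b$values) == 0
  shape_cor <- if (degenerate) NA_real_ else stats::cor(a$values, b$values)
  structure(list(area_a = area_a, area_b = area_b, area_ratio = ratio,
                 shape_correlation = shape_cor, degenerate = degenerate),
            class = "profile_comparison")
}
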