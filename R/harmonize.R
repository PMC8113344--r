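# Band-respective linear coefficients that place the three optical sensors
# on one reflectance scale. Values are the published image constants for the
# two sensor pairs, stored bit-exact.
.harmonization_table <- function() {
  list(
    tm_etm_to_oli = data.frame(
      band = REFLECTIVE_BANDS,
      slope = c(0.8474, 0.8483, 0.9047, 0.8462, 0.8937, 0.9071),
      intercept = c(0.0003, 0.0088, 0.0061, 0.0412, 0.0254, 0.0172)
    ),
    oli_msi = data.frame(
      band = REFLECTIVE_BANDS,
      slope = c(1.0946, 1.0043, 1.0524, 0.8954, 1.0049, 1.0002),
      intercept = c(-0.0107, 0.0026, -0.0015, 0.0033, 0.0065, 0.0046)
    )
  )
}

#' Harmonization coefficient sets
#'
#' Per-band slope/intercept constants of the affine transforms that place
#' TM/ETM+ reflectance on the OLI scale (`"tm_etm_to_oli"`) and relate OLI
#' and MSI reflectance (`"oli_msi"`). Which direction the OLI/MSI set maps is
#' not fixed by convention, so [harmonize_scene()] exposes both via
#' [invert_coefficients()]; the shipped constants are applied as printed.
#'
#' @param pair `"tm_etm_to_oli"` or `"oli_msi"`; or a data.frame with
#'   columns `band`, `slope`, `intercept` covering the six reflective bands
#'   (user override, same schema).
#' @return An object of class `coefficient_set`: data.frame of six rows with
#'   `band`, `slope`, `intercept`, and a `pair_id` attribute.
#' @export
harmonization_coefficients <- function(pair = c("tm_etm_to_oli", "oli_msi")) {
  if (is.data.frame(pair)) {
    cs <- pair
    pair_id <- attr(pair, "pair_id") %||% "custom"
  } else {
    pair_id <- match.arg(pair)
    cs <- .harmonization_table()[[pair_id]]
  }
  stopifnot(all(c("band", "slope", "intercept") %in% names(cs)))
  if (!setequal(cs$band, REFLECTIVE_BANDS) || nrow(cs) != 6L)
    stop("coefficient set must cover exactly the six reflective bands",
         call. = FALSE)
  if (any(!is.finite(cs$slope)) || any(cs$slope == 0))
    stop("slopes must be finite and nonzero", call. = FALSE)
  structure(cs[match(REFLECTIVE_BANDS, cs$band), , drop = FALSE],
            pair_id = pair_id, class = c("coefficient_set", "data.frame"))
}

#' Invert a coefficient set
#'
#' Returns the algebraic inverse `(1/slope, -intercept/slope)` per band, so
#' the pair can be applied in either direction;
#' `harmonize_scene(harmonize_scene(s, k), invert_coefficients(k))`
#' reproduces `s` to machine precision.
#'
#' @param coeffs a `coefficient_set`.
#' @return The inverted `coefficient_set`, `pair_id` suffixed `"_inverse"`.
#' @export
invert_coefficients <- function(coeffs) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  inv <- data.frame(band = coeffs$band,
                    slope = 1 / coeffs$slope,
                    intercept = -coeffs$intercept / coeffs$slope)
  structure(inv, pair_id = paste0(attr(coeffs, "pair_id"), "_inverse"),
            class = c("coefficient_set", "data.frame"))
}

#' Harmonize an optical scene
#'
#' Replaces each of the six reflective bands `x` by `slope * x + intercept`
#' at valid pixels; the thermal band, mask, date, and grid are untouched.
#' Harmonized values are deliberately not clamped to \[0, 1\]: the affine
#' transforms can push saturated pixels slightly past the nominal range, and
#' clamping would bias composites. A validity-range warning is emitted
#' instead (by [scene()]).
#'
#' @param x an `lulc_scene` carrying the six reflective bands.
#' @param coeffs a `coefficient_set` (see [harmonization_coefficients()]).
#' @param target_sensor sensor tag for the output scene; default keeps the
#'   input tag.
#' @return The harmonized `lulc_scene`.
#' @export
harmonize_scene <- function(x, coeffs, target_sensor = NULL) {
  stopifnot(inherits(x, "lulc_scene"))
  coeffs <- harmonization_coefficients(coeffs)
  missing_b <- setdiff(REFLECTIVE_BANDS, names(x$bands))
  if (length(missing_b))
    stop("scene lacks reflective band(s): ",
         paste(missing_b, collapse = ", "), call. = FALSE)
  bands <- x$bands
  for (i in seq_len(nrow(coeffs))) {
    b <- coeffs$band[i]
    bands[[b]] <- coeffs$slope[i] * bands[[b]] + coeffs$intercept[i]
  }
  scene(bands, date = x$date, grid = x$grid, mask = x$mask,
        sensor = target_sensor %||% x$sensor)
}
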