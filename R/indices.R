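# Each index is a function of the named reflective bands (plus thermal for
# NDBaI). The generic "swir" of several published formulas defaults to
# swir1 (1.6 um) except for NBR, which conventionally uses swir2 (2.2 um);
# both choices can be overridden per index.
.INDEX_SWIR_DEFAULT <- c(EBBI = "Bswir1", MVI = "Bswir1", NBR = "Bswir2",
                         NDBaI = "Bswir1", NDBI = "Bswir1", NDPI = "Bswir1",
                         UI = "Bswir1")

#' Supported spectral index names
#' @export
SPECTRAL_INDICES <- c("ARVI", "DVI", "EBBI", "EVI", "GCI", "MVI", "NBR",
                      "NDBaI", "NDBI", "NDPI", "NDTI", "NDVI", "NDWI",
                      "SAVI", "SIPI", "UI", "WRI")

#' Supported band-ratio names
#' @export
BAND_RATIOS <- c("ratio_blue_green", "ratio_red_blue", "ratio_red_green",
                 "ratio_red_nir", "ratio_nir_redswir1")

guard_div <- function(num, den, eps = 1e-9) {
  out <- num / den
  out[!is.na(den) & abs(den) < eps] <- NA_real_
  out
}

index_formula <- function(name, b, swir) {
  blue <- b$Bblue; green <- b$Bgreen; red <- b$Bred; nir <- b$Bnir
  s <- if (!is.null(swir)) b[[swir]] else NULL
  switch(name,
    ARVI = guard_div(nir - 2 * red + blue, nir + 2 * red + blue),
    DVI = nir - red,
    EBBI = {
      rad <- s + nir
      out <- guard_div(s - nir, 10 * sqrt(pmax(rad, 0)))
      out[!is.na(rad) & rad <= 0] <- NA_real_
      out
    },
    EVI = 2.5 * guard_div(nir - red, nir + 6 * red - 7.5 * blue + 1),
    GCI = guard_div(nir, green) - 1,
    MVI = guard_div(nir - green, s - green),
    NBR = guard_div(nir - s, nir + s),
    NDBaI = guard_div(s - b$Btir, s + b$Btir),
    NDBI = guard_div(s - nir, s + nir),
    NDPI = guard_div(green - s, green + s),
    NDTI = guard_div(red - green, red + green),
    NDVI = guard_div(nir - red, nir + red),
    NDWI = guard_div(green - nir, green + nir),
    SAVI = 1.5 * guard_div(nir - red, nir + red + 0.5),
    SIPI = guard_div(nir - blue, nir - red),
    UI = guard_div(s - nir, s + nir),
    WRI = guard_div(green + red + nir, blue),
    stop("unknown index: ", name, call. = FALSE)
  )
}

index_required_bands <- function(name, swir) {
  base <- switch(name,
    ARVI = c("Bblue", "Bred", "Bnir"),
    DVI = c("Bred", "Bnir"),
    EBBI = "Bnir", EVI = c("Bblue", "Bred", "Bnir"),
    GCI = c("Bgreen", "Bnir"), MVI = c("Bgreen", "Bnir"),
    NBR = "Bnir", NDBaI = "Btir", NDBI = "Bnir", NDPI = "Bgreen",
    NDTI = c("Bgreen", "Bred"), NDVI = c("Bred", "Bnir"),
    NDWI = c("Bgreen", "Bnir"), SAVI = c("Bred", "Bnir"),
    SIPI = c("Bblue", "Bred", "Bnir"), UI = "Bnir",
    WRI = c("Bblue", "Bgreen", "Bred", "Bnir"))
  c(base, swir)
}

# pull plain band matrices out of a composite: prefers bare band names, then
# "<prefix><band>" layers (medoid bands by default)
composite_bands <- function(x, prefix = "medoid_") {
  if (inherits(x, "lulc_composite")) {
    lay <- x$layers
    get1 <- function(b) lay[[b]] %||% lay[[paste0(prefix, b)]]
    b <- lapply(OPTICAL_BANDS, get1)
    names(b) <- OPTICAL_BANDS
    b[!vapply(b, is.null, TRUE)]
  } else if (is.list(x)) {
    x
  } else stop("expected a composite or a named list of band matrices",
              call. = FALSE)
}

#' Compute one spectral index
#'
#' Evaluates the published formula for `name` over the composite's band
#' layers. Pixels where a required band is nodata, or where the denominator
#' magnitude falls below `1e-9`, are nodata — never infinity. EBBI pixels
#' with a nonpositive `swir + nir` radicand are nodata.
#'
#' Formulas (band symbols are surface reflectance):
#' \describe{
#'   \item{ARVI}{`(nir - 2 red + blue) / (nir + 2 red + blue)`}
#'   \item{DVI}{`nir - red`}
#'   \item{EBBI}{`(swir - nir) / (10 sqrt(swir + nir))`}
#'   \item{EVI}{`2.5 (nir - red) / (nir + 6 red - 7.5 blue + 1)`}
#'   \item{GCI}{`nir / green - 1`}
#'   \item{MVI}{`(nir - green) / (swir - green)`}
#'   \item{NBR}{`(nir - swir2) / (nir + swir2)`}
#'   \item{NDBaI}{`(swir - tir) / (swir + tir)`}
#'   \item{NDBI, UI}{`(swir - nir) / (swir + nir)` (identical as printed)}
#'   \item{NDPI}{`(green - swir) / (green + swir)`}
#'   \item{NDTI}{`(red - green) / (red + green)`}
#'   \item{NDVI}{`(nir - red) / (nir + red)`}
#'   \item{NDWI}{`(green - nir) / (green + nir)`}
#'   \item{SAVI}{`1.5 (nir - red) / (nir + red + 0.5)`}
#'   \item{SIPI}{`(nir - blue) / (nir - red)`}
#'   \item{WRI}{`(green + red + nir) / blue`}
#' }
#'
#' @param x an `lulc_composite` (band layers found by bare name or under
#'   `prefix`) or a named list of band matrices.
#' @param name one of [SPECTRAL_INDICES].
#' @param swir band used where the formula says generic "swir"; default per
#'   index (see [SPECTRAL_INDICES]); ignored by formulas with fixed bands.
#' @param prefix composite layer prefix tried for band lookup.
#' @return A numeric matrix (the index layer).
#' @export
compute_index <- function(x, name, swir = NULL, prefix = "medoid_") {
  if (!name %in% SPECTRAL_INDICES) stop("unknown index: ", name, call. = FALSE)
  if (is.null(swir) && name %in% names(.INDEX_SWIR_DEFAULT))
    swir <- unname(.INDEX_SWIR_DEFAULT[[name]])
  b <- composite_bands(x, prefix)
  need <- index_required_bands(name, swir)
  missing_b <- setdiff(need, names(b))
  if (length(missing_b))
    stop(name, " needs band(s): ", paste(missing_b, collapse = ", "),
         call. = FALSE)
  index_formula(name, b, swir)
}

#' Compute the five band ratios
#'
#' `blue/green`, `red/blue`, `red/green`, `red/nir`, and
#' `nir/(red * swir1)`, with the same division guard as [compute_index()].
#'
#' @inheritParams compute_index
#' @return A named list of ratio matrices (names from [BAND_RATIOS]).
#' @export
compute_band_ratios <- function(x, prefix = "medoid_") {
  b <- composite_bands(x, prefix)
  need <- c("Bblue", "Bgreen", "Bred", "Bnir", "Bswir1")
  missing_b <- setdiff(need, names(b))
  if (length(missing_b))
    stop("band ratios need band(s): ", paste(missing_b, collapse = ", "),
         call. = FALSE)
  list(
    ratio_blue_green = guard_div(b$Bblue, b$Bgreen),
    ratio_red_blue = guard_div(b$Bred, b$Bblue),
    ratio_red_green = guard_div(b$Bred, b$Bgreen),
    ratio_red_nir = guard_div(b$Bred, b$Bnir),
    ratio_nir_redswir1 = guard_div(b$Bnir, b$Bred * b$Bswir1)
  )
}

#' Append spectral indices and ratios to a composite
#'
#' @param x an `lulc_composite`.
#' @param names indices to append, a subset of
#'   `c(SPECTRAL_INDICES, BAND_RATIOS)`; order is preserved.
#' @param swir_overrides optional named vector overriding the swir band per
#'   index.
#' @param prefix composite layer prefix for band lookup.
#' @return The composite with one appended layer per requested index.
#' @export
compute_all_indices <- function(x, names = c(SPECTRAL_INDICES, BAND_RATIOS),
                                swir_overrides = NULL, prefix = "medoid_") {
  stopifnot(inherits(x, "lulc_composite"))
  bad <- setdiff(names, c(SPECTRAL_INDICES, BAND_RATIOS))
  if (length(bad)) stop("unknown index name(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  dup <- intersect(names, names(x$layers))
  if (length(dup)) stop("duplicate layer name(s): ",
                        paste(dup, collapse = ", "), call. = FALSE)
  ratios <- NULL
  for (nm in names) {
    if (nm %in% BAND_RATIOS) {
      ratios <- ratios %||% compute_band_ratios(x, prefix)
      x$layers[[nm]] <- ratios[[nm]]
    } else {
      ov <- if (nm %in% names(swir_overrides)) swir_overrides[[nm]] else NULL
      x$layers[[nm]] <- compute_index(x, nm, swir = ov, prefix = prefix)
    }
  }
  x
}
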