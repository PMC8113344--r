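#' Land-cover class taxonomy
#'
#' A two-level land use/land cover classification system: detailed level-2
#' classes nest into broader level-1 classes through a total, surjective
#' mapping. Metrics, maps, and confusion matrices computed at level 2 can be
#' merged to level 1 with [merge_to_level1()].
#'
#' @param level2 data.frame with columns `id`, `name`, `parent_id` (level-1
#'   id of each level-2 class).
#' @param level1 data.frame with columns `id`, `name`.
#' @return An object of class `lulc_taxonomy` with elements `level1`,
#'   `level2`, and `n` (the number of level-2 classes, the `N` of the prior
#'   floor adjustment).
#' @seealso [default_taxonomy()]
#' @export
lulc_taxonomy <- function(level2, level1) {
  stopifnot(all(c("id", "name", "parent_id") %in% names(level2)),
            all(c("id", "name") %in% names(level1)))
  if (anyDuplicated(level2$id) || anyDuplicated(level1$id))
    stop("duplicate class ids", call. = FALSE)
  if (!all(level2$parent_id %in% level1$id))
    stop("level-2 parent_id values must all exist at level 1", call. = FALSE)
  if (!all(level1$id %in% level2$parent_id))
    stop("level-2 -> level-1 mapping must be surjective", call. = FALSE)
  structure(list(level1 = level1, level2 = level2, n = nrow(level2)),
            class = "lulc_taxonomy")
}

#' @export
print.lulc_taxonomy <- function(x, ...) {
  cat(sprintf("<lulc_taxonomy> %d level-1 classes, %d level-2 classes\n",
              nrow(x$level1), nrow(x$level2)))
  invisible(x)
}

#' Default two-level taxonomy
#'
#' The 10-class primary dominant land cover (level 1) and 18-class secondary
#' dominant land cover (level 2) system used for nationwide annual mapping of
#' Vietnam: residence, rice paddies, cropland, grassland, barren land,
#' scrubland, forest land, wetland, open water, and aquaculture at level 1;
#' level 2 splits residence in two, cropland into woody/other/in-house
#' crops, and forest into five forest types plus bamboo.
#'
#' @return An `lulc_taxonomy`.
#' @export
default_taxonomy <- function() {
  level1 <- data.frame(
    id = 1:10,
    name = c("Residence", "RicePaddies", "Cropland", "Grassland",
             "BarrenLand", "Scrubland", "ForestLand", "Wetland",
             "OpenWater", "Aquaculture")
  )
  level2 <- data.frame(
    id = 1:18,
    name = c("Residence1", "Residence2", "RicePaddies", "WoodyCrops",
             "OtherCrops", "InHouseCrops", "Grassland", "BarrenLand",
             "Scrubland", "DeciduousBroadleafForest",
             "EvergreenBroadleafForest", "EvergreenNeedleleafForest",
             "PlantationLand", "MangroveForest", "InlandWetland",
             "OpenWater", "Aquaculture", "BambooAreas"),
    parent_id = c(1, 1, 2, 3, 3, 3, 4, 5, 6, 7, 7, 7, 7, 7, 8, 9, 10, 7)
  )
  lulc_taxonomy(level2, level1)
}

#' Classes at a taxonomy level
#'
#' @param taxonomy an `lulc_taxonomy`.
#' @param level 1 or 2.
#' @return The class table (data.frame with `id`, `name`).
#' @export
taxonomy_classes <- function(taxonomy, level) {
  stopifnot(inherits(taxonomy, "lulc_taxonomy"), level %in% c(1L, 2L))
  if (level == 1L) taxonomy$level1 else taxonomy$level2[c("id", "name")]
}

#' Map level-2 class ids to their level-1 parents
#'
#' @param taxonomy an `lulc_taxonomy`.
#' @param ids level-2 class ids.
#' @return Level-1 class ids (same length; `NA` propagated).
#' @export
level1_parent <- function(taxonomy, ids) {
  m <- match(ids, taxonomy$level2$id)
  bad <- !is.na(ids) & is.na(m)
  if (any(bad))
    stop("unmapped level-2 class id(s): ",
         paste(unique(ids[bad]), collapse = ", "), call. = FALSE)
  taxonomy$level2$parent_id[m]
}

#' Resolve class labels to ids
#'
#' Accepts ids or names at the stated level; unknown labels raise an error
#' naming the offending values.
#'
#' @param taxonomy an `lulc_taxonomy`.
#' @param labels vector of class ids or names.
#' @param level 1 or 2.
#' @return Integer class ids.
#' @export
resolve_class <- function(taxonomy, labels, level) {
  tab <- taxonomy_classes(taxonomy, level)
  if (is.numeric(labels)) {
    ids <- as.integer(labels)
    bad <- !(ids %in% tab$id) & !is.na(ids)
  } else {
    ids <- tab$id[match(as.character(labels), tab$name)]
    bad <- is.na(ids) & !is.na(labels)
  }
  if (any(bad))
    stop("class label(s) not in the level-", level, " taxonomy: ",
         paste(unique(labels[bad]), collapse = ", "), call. = FALSE)
  ids
}
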