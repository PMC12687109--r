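#' Reclassify a 12-state LUH2 layer into the five habitat classes
#'
#' Collapses the twelve LUH2 fractional land-use states into the five classes
#' shared with the IUCN habitat scheme: primary + secondary forest to
#' `forest`; primary + secondary non-forest to `non_forest`; the five crop
#' functional types to `agriculture`; managed pasture + rangeland to
#' `managed`; `urban` unchanged. The per-cell total land fraction is
#' conserved exactly; any remainder below 1 (water/ice) is left untouched.
#'
#' @param layer Numeric matrix, cells x 12, with columns named as
#'   [luh2_states()]; each fraction in \[0,1\] and each row summing to at
#'   most 1 (plus numerical slack).
#' @return Numeric matrix, cells x 5, columns [habitat_classes()].
#' @export
#' @examples
#' m <- matrix(0, 1, 12, dimnames = list(NULL, luh2_states()))
#' m[, c("c3ann", "c4per")] <- c(0.2, 0.1)
#' reclassify_luh2(m)[, "agriculture"]  # 0.3
reclassify_luh2 <- function(layer) {
  layer <- as.matrix(layer)
  if (is.null(colnames(layer)) || !all(luh2_states() %in% colnames(layer)))
    stop("layer must have all 12 LUH2 state columns", call. = FALSE)
  layer <- layer[, luh2_states(), drop = FALSE]
  if (any(!is.finite(layer)) || any(layer < 0))
    stop("invalid land-use data: fractions must be finite and non-negative",
         call. = FALSE)
  if (any(rowSums(layer) > 1 + 1e-6))
    stop("invalid land-use data: per-cell fractions sum above 1", call. = FALSE)
  out <- matrix(0, nrow(layer), 5L,
                dimnames = list(rownames(layer), habitat_classes()))
  for (st in luh2_states())
    out[, luh2_class_map[[st]]] <- out[, luh2_class_map[[st]]] + layer[, st]
  out
}

#' Default IUCN habitat code to five-class mapping
#'
#' Maps level-1 and level-2 IUCN habitat classification scheme codes onto the
#' five shared classes, or to `"drop"`. Forest (1) maps to forest; savanna
#' (2), shrubland (3), grassland (4), terrestrial wetlands (5), rocky areas
#' (6) and desert (8) to non-forest; arable land (14.1) and plantations
#' (14.3) to agriculture; pastureland (14.2) to managed; rural gardens (14.4)
#' and urban areas (14.5) to urban. Caves (7), marine and aquatic habitats
#' (9-13, 15), introduced vegetation (16), other (17) and unknown (18) are
#' dropped. The mapping is an ordinary named character vector, so callers can
#' substitute their own (e.g. a published supplementary mapping table).
#'
#' @return Named character vector: names are code prefixes (`"1"`, `"14.4"`,
#'   ...), values a class name or `"drop"`.
#' @export
iucn_habitat_map <- function() {
  c("1" = "forest",
    "2" = "non_forest", "3" = "non_forest", "4" = "non_forest",
    "5" = "non_forest", "6" = "non_forest", "8" = "non_forest",
    "7" = "drop",
    "9" = "drop", "10" = "drop", "11" = "drop", "12" = "drop", "13" = "drop",
    "14.1" = "agriculture", "14.2" = "managed", "14.3" = "agriculture",
    "14.4" = "urban", "14.5" = "urban", "14.6" = "agriculture",
    "15" = "drop", "16" = "drop", "17" = "drop", "18" = "drop")
}

#' Reclassify IUCN habitat codes into the five-class scheme
#'
#' Level-2 codes (e.g. `"1.4"`) fall back to their level-1 prefix unless the
#' mapping lists the full code (the artificial habitats under 14 are mapped
#' at level 2). Codes mapped to `"drop"` are removed; a species whose entire
#' code list drops out is unclassifiable and raises an error, since it can
#' not be scored against land use.
#'
#' @param iucn_codes Character (or numeric) vector of IUCN habitat codes.
#' @param mapping Named mapping as from [iucn_habitat_map()].
#' @return Character vector: the sorted unique habitat classes.
#' @export
#' @examples
#' reclassify_iucn_habitats(c("2.1", "14.1"))  # non_forest, agriculture
reclassify_iucn_habitats <- function(iucn_codes, mapping = iucn_habitat_map()) {
  if (length(iucn_codes) == 0L)
    stop("species unclassifiable: no habitat codes given", call. = FALSE)
  codes <- trimws(as.character(iucn_codes))
  level1 <- sub("\\..*$", "", codes)
  cls <- character(length(codes))
  for (i in seq_along(codes)) {
    key <- if (codes[i] %in% names(mapping)) codes[i] else level1[i]
    if (!key %in% names(mapping))
      stop("unknown IUCN habitat code: '", codes[i], "'", call. = FALSE)
    cls[i] <- mapping[[key]]
  }
  cls <- setdiff(unique(cls), "drop")
  if (length(cls) == 0L)
    stop("species unclassifiable: all habitat codes drop out", call. = FALSE)
  sort(cls)
}

#' Preferred-habitat fraction of cells
#'
#' Sums a species' preferred habitat classes over a five-class layer. The
#' result is an absolute land fraction: cells with a water/ice remainder are
#' not renormalised.
#'
#' @param prefs Character vector of habitat classes (subset of
#'   [habitat_classes()]), or a species record with a `habitat_classes` field.
#' @param layer Five-class matrix as from [reclassify_luh2()].
#' @param cells Optional cell ids (row indices); default all rows.
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
habitat_fraction <- function(prefs, layer, cells = NULL) {
  if (is.list(prefs) && !is.null(prefs$habitat_classes))
    prefs <- prefs$habitat_classes
  prefs <- unlist(prefs)
  bad <- setdiff(prefs, habitat_classes())
  if (length(bad))
    stop("unknown habitat classes: ", paste(bad, collapse = ", "), call. = FALSE)
  m <- layer[, intersect(habitat_classes(), prefs), drop = FALSE]
  if (!is.null(cells)) m <- m[cells, , drop = FALSE]
  unname(rowSums(m))
}
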