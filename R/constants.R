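#' LUH2 land-use state names
#'
#' The twelve fractional land-use states of the Land-Use Harmonization 2
#' (LUH2) dataset, in the column order expected by [reclassify_luh2()]:
#' primary/secondary forest and non-forest, urban, the five crop functional
#' types, managed pasture and rangeland.
#'
#' @return Character vector of length 12.
#' @export
luh2_states <- function() {
  c("primf", "primn", "secdf", "secdn", "urban",
    "c3ann", "c4ann", "c3per", "c4per", "c3nfx",
    "pastr", "range")
}

#' The five shared habitat classes
#'
#' The five-class scheme onto which both LUH2 land-use states and IUCN
#' habitat codes are reclassified: forest, non-forest, agriculture, managed
#' (pasture/rangeland) and urban.
#'
#' @return Character vector of length 5.
#' @export
habitat_classes <- function() {
  c("forest", "non_forest", "agriculture", "managed", "urban")
}

# LUH2 state -> five-class mapping (fixed; the five crop types collapse to
# agriculture, pasture + rangeland to managed).
luh2_class_map <- c(
  primf = "forest",      secdf = "forest",
  primn = "non_forest",  secdn = "non_forest",
  c3ann = "agriculture", c4ann = "agriculture", c3per = "agriculture",
  c4per = "agriculture", c3nfx = "agriculture",
  pastr = "managed",     range = "managed",
  urban = "urban"
)

#' Scenario names
#'
#' The four SSP-RCP scenario combinations the pipeline projects:
#' a sustainability pathway (SSP1-RCP2.6), middle-of-the-road (SSP2-RCP4.5),
#' regional rivalry with heavy land conversion (SSP3-RCP7.0), and
#' fossil-fuelled development (SSP5-RCP8.5).
#'
#' @return Character vector of length 4.
#' @export
ssp_scenarios <- function() {
  c("SSP1-RCP2.6", "SSP2-RCP4.5", "SSP3-RCP7.0", "SSP5-RCP8.5")
}

#' Red List category levels
#'
#' IUCN Red List categories used for species metadata, ordered from Least
#' Concern to Critically Endangered, with Data Deficient last.
#'
#' @return Character vector.
#' @export
redlist_levels <- function() {
  c("LC", "NT", "VU", "EN", "CR", "DD")
}

#' Tetrapod species counts in the global range-map datasets
#'
#' Numbers of terrestrial vertebrate species with both range maps and
#' suitable-habitat data in the global datasets this pipeline is designed to
#' consume (IUCN for amphibians and mammals, BirdLife for birds, GARD for
#' reptiles). Useful for bookkeeping checks when running on the real data.
#'
#' @return Named integer vector over the four taxa, with a `total` attribute.
#' @export
#' @examples
#' sum(reference_species_counts())  # 29657
reference_species_counts <- function() {
  c(amphibian = 6407L, bird = 9472L, mammal = 5161L, reptile = 8617L)
}
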