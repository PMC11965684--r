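#' Build a clade registry
#'
#' A clade registry maps clade names to stem ages (million years ago, Myr)
#' and expected species counts, and names the reference clade used for
#' normalization (by convention the clade with the oldest stem age).
#'
#' @param clade character vector of unique clade names.
#' @param stem_age_mya positive numeric stem ages (ties permitted: Glires and
#'   Primates share 87 Myr in the vertebrate registry).
#' @param n_species expected species count per clade (optional, `NA` allowed).
#' @param reference name of the reference clade; defaults to the clade with
#'   the oldest stem age.
#' @return A tibble with columns `clade`, `stem_age_mya`, `n_species`,
#'   ordered by decreasing stem age, with attribute `reference`.
#' @seealso [default_registry()] for the bundled vertebrate and
#'   Actinopterygii fixtures.
#' @export
clade_registry <- function(clade, stem_age_mya, n_species = NA_integer_,
                           reference = NULL) {
  stopifnot(is.character(clade), length(clade) >= 1)
  if (anyDuplicated(clade)) {
    stop("clade names must be unique", call. = FALSE)
  }
  if (any(!is.finite(stem_age_mya)) || any(stem_age_mya <= 0)) {
    stop("stem ages must be positive and finite", call. = FALSE)
  }
  reg <- tibble::tibble(
    clade = clade,
    stem_age_mya = as.numeric(stem_age_mya),
    n_species = as.integer(n_species)
  )
  reg <- dplyr::arrange(reg, dplyr::desc(.data$stem_age_mya), .data$clade)
  if (is.null(reference)) reference <- reg$clade[1]
  if (!reference %in% reg$clade) {
    stop("reference clade '", reference, "' not in registry", call. = FALSE)
  }
  attr(reg, "reference") <- reference
  reg
}

#' Bundled clade registries
#'
#' Three fixtures cover the study designs the package targets:
#' \describe{
#'   \item{`"vertebrate"`}{Nine major gnathostome clades with TimeTree median
#'     stem ages: Chondrichthyes 462, Actinopterygii 429, Amphibia 352,
#'     Sauropsida 319, Marsupialia 160, Atlantogenata 99, Laurasiatheria 94,
#'     Glires 87, Primates 87 Myr. Reference: Chondrichthyes.}
#'   \item{`"vertebrate_alt"`}{The same nine clades with the alternative
#'     stem-age set found in some summaries of the vertebrate timescale
#'     (Amphibia 319, Sauropsida 180, Marsupialia 99, Atlantogenata 94).}
#'   \item{`"actinopterygii"`}{Twenty-one nested ray-finned-fish clades from
#'     Cladistia (396 Myr) down to Poeciliinae (18.9 Myr), for intraclade
#'     analyses.}
#' }
#'
#' @param set one of `"vertebrate"` (default), `"vertebrate_alt"`,
#'   `"actinopterygii"`.
#' @return A clade registry tibble (see [clade_registry()]).
#' @examples
#' default_registry()
#' @export
default_registry <- function(set = c("vertebrate", "vertebrate_alt",
                                     "actinopterygii")) {
  set <- match.arg(set)
  switch(set,
    vertebrate = clade_registry(
      clade = c("Cho", "Act", "Amp", "Sau", "Mar", "Atl", "Lau",
                "Gli", "Pri"),
      stem_age_mya = c(462, 429, 352, 319, 160, 99, 94, 87, 87),
      n_species = c(12L, 175L, 11L, 159L, 8L, 9L, 119L, 45L, 34L),
      reference = "Cho"
    ),
    vertebrate_alt = clade_registry(
      clade = c("Cho", "Act", "Amp", "Sau", "Mar", "Atl", "Lau",
                "Gli", "Pri"),
      stem_age_mya = c(462, 429, 319, 180, 99, 94, 94, 87, 87),
      n_species = c(11L, 175L, 11L, 159L, 8L, 9L, 119L, 45L, 34L),
      reference = "Cho"
    ),
    actinopterygii = clade_registry(
      clade = c("Cladistia", "Holostei", "Osteoglossocephala",
                "Elopocephala", "Otomorpha", "Protacanthopterygii",
                "Lampridacea", "Holocentrinomorphaceae", "Batrachoidaria",
                "Eupercaria", "Syngnathiaria", "Gobiaria", "Carangaria",
                "Cichlomorphae", "Beloniformes", "Pomacentridae",
                "Atheriniformes", "Aplocheiloidei", "Cyprinodontoidei",
                "Poecilinae", "Poeciliinae"),
      stem_age_mya = c(396, 321, 263, 250, 224, 219, 134, 127, 120,
                       113, 109, 108, 104, 91, 89, 87, 80, 74, 46,
                       18.9, 18.9),
      n_species = c(2L, 1L, 2L, 3L, 31L, 1L, 1L, 1L, 1L, 28L, 9L, 3L,
                    16L, 9L, 1L, 7L, 1L, 4L, 4L, 4L, 5L),
      reference = "Cladistia"
    )
  )
}

#' Registry reference clade
#'
#' @param registry a clade registry tibble.
#' @return The reference clade name.
#' @export
registry_reference <- function(registry) {
  ref <- attr(registry, "reference")
  if (is.null(ref)) registry$clade[which.max(registry$stem_age_mya)] else ref
}
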