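#' Species life-history registry
#'
#' Every age transformation in the package is parameterized per species by its
#' maximum lifespan and its average age at sexual maturity. The default
#' registry ships the constants used throughout: *Xenopus laevis* (maximum
#' lifespan 30.3 y, maturity 1 y), *Xenopus tropicalis* (16 y, 0.375 y), and
#' human (122.5 y, maturity configurable, default 13.5 y). Lifespans follow
#' the anAge database values used for relative-age normalization.
#'
#' @param human_maturity_years Age at sexual maturity assumed for humans, in
#'   years. Only the dual-species chronological clock is sensitive to it.
#' @return A tibble with columns `species`, `max_lifespan_years`,
#'   `maturity_years`; one row per species.
#' @examples
#' default_species_registry()
#' @export
default_species_registry <- function(human_maturity_years = 13.5) {
  reg <- tibble::tibble(
    species = c("laevis", "tropicalis", "human"),
    max_lifespan_years = c(30.3, 16, 122.5),
    maturity_years = c(1, 0.375, human_maturity_years)
  )
  validate_species_registry(reg)
}

#' Validate a species registry
#'
#' @param registry A data frame with columns `species`, `max_lifespan_years`,
#'   `maturity_years`.
#' @return The registry as a tibble, invisibly checked: for every species
#'   `max_lifespan_years > maturity_years > 0` and species labels are unique.
#' @export
validate_species_registry <- function(registry) {
  registry <- tibble::as_tibble(registry)
  need <- c("species", "max_lifespan_years", "maturity_years")
  miss <- setdiff(need, names(registry))
  if (length(miss)) {
    stop_validation(paste0("registry is missing columns: ", toString(miss)))
  }
  if (anyDuplicated(registry$species)) {
    stop_validation("registry species labels must be unique")
  }
  bad <- !(registry$max_lifespan_years > registry$maturity_years &
             registry$maturity_years > 0)
  if (any(bad)) {
    stop_validation(paste0(
      "registry requires max_lifespan_years > maturity_years > 0; violated for: ",
      toString(registry$species[bad])
    ))
  }
  registry
}

# look up one species row, erroring informatively
species_params <- function(registry, species) {
  row <- registry[registry$species == species, ]
  if (nrow(row) != 1L) {
    stop_validation(sprintf("species '%s' not found in registry", species))
  }
  row
}
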