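#' Parameter registry
#'
#' The registry bundles every biological parameter of the system: the
#' cassava metabolic-pool constants and, per species, the stage structure
#' (substage count `k` and mean duration `del` in degree-days), the
#' developmental-rate curve, the functional response, the reproduction
#' profile, mortality, scalars, preferences, dispersal responsiveness and
#' nominal initial densities.  The shipped default
#' (`inst/extdata/species_registry.yaml`) is a documented set of
#' assumptions chosen to reproduce the qualitative biology of the system;
#' it is not a transcription of published per-species fits.
#'
#' @name registry
NULL

species_set <- c("cm", "al", "ad", "p_cm", "cgm", "ta", "am", "p_cgm")

#' Load a parameter registry
#'
#' @param path YAML registry file; default the registry shipped with the
#'   package.
#' @return a `bc_registry` list with elements `plant` and `species`, all
#'   parameter blocks converted to validated parameter objects.
#' @examples
#' reg <- default_registry()
#' names(reg$species)
#' @export
load_registry <- function(path = system.file("extdata",
                                             "species_registry.yaml",
                                             package = "cassavabc")) {
  raw <- yaml::read_yaml(path)
  plant <- raw$plant
  plant$dev <- do.call(dev_rate_params, plant$dev)
  plant$temp_scalar <- do.call(scalar_params, plant$temp_scalar)
  plant$leaf_stage <- stage_config(plant$leaf_stage$k, plant$leaf_stage$del,
                                   "leaf")
  sp <- raw$species
  miss <- setdiff(species_set, names(sp))
  if (length(miss))
    stop("registry missing species: ", paste(miss, collapse = ", "))
  for (nm in names(sp)) {
    s <- sp[[nm]]
    if (identical(s$guild, "pathogen")) {
      s$incubation <- stage_config(s$incubation$k, s$incubation$del,
                                   paste0(nm, ".incubation"))
      if (s$transmissivity < 0) stop("registry: negative transmissivity")
    } else {
      s$dev <- do.call(dev_rate_params, s$dev)
      s$stages <- list(
        immature = stage_config(s$stages$immature$k, s$stages$immature$del,
                                paste0(nm, ".immature")),
        adult = stage_config(s$stages$adult$k, s$stages$adult$del,
                             paste0(nm, ".adult"))
      )
      s$temp_scalar <- do.call(scalar_params, s$temp_scalar)
      s$mort <- do.call(mortality_params, s$mort)
      if (!is.null(s$repro)) s$repro <- do.call(reproduction_profile, s$repro)
      if (!is.null(s$preference)) {
        w <- unlist(s$preference)
        if (any(w < 0)) stop("registry: negative preference weight for ", nm)
        s$preference <- w / sum(w)
      }
      if (s$fr$demand <= 0 || s$fr$alpha <= 0 || s$fr$alpha > 1)
        stop("registry: invalid functional response for ", nm)
    }
    sp[[nm]] <- s
  }
  structure(list(version = raw$version, sim = raw$sim, plant = plant,
                 species = sp),
            class = "bc_registry")
}

default_registry_cache <- new.env(parent = emptyenv())

#' @rdname load_registry
#' @export
default_registry <- function() {
  if (is.null(default_registry_cache$reg))
    default_registry_cache$reg <- load_registry()
  default_registry_cache$reg
}
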