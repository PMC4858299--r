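#' Read morphology and scenarios from a YAML config
#'
#' The config mirrors the constructor arguments: a `morphology` block with
#' [morphology_params()] field names, an optional `pressure` (kPa), and an
#' optional `scenarios` list whose entries have a `name` and a `crystals`
#' list of `{location, length_um, thickness_um, expansion_um}`.
#'
#' @param path Path to a YAML file.
#' @return List with `params` ([morphology_params()]) and `scenarios`
#'   (list of [scenario()]; the default roster if the file names none).
#' @examples
#' cfg <- read_config(system.file("extdata", "example-scenarios.yaml",
#'                                package = "capstress"))
#' names(cfg$scenarios)
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  m <- cfg$morphology %||% list()
  params <- morphology_params(
    cap_thickness = m$cap_thickness %||% 0.091,
    lumen_area = m$lumen_area %||% 5.77,
    core_arc = m$core_arc %||% 84.65,
    core_area = m$core_area %||% 2.22,
    stenosis_severity = m$stenosis_severity %||% 0.7053,
    wall_thickness = m$wall_thickness
  )
  pressure <- cfg$pressure %||% 14.6
  scenarios <- if (is.null(cfg$scenarios)) {
    default_scenarios(params = params, pressure = pressure)
  } else {
    out <- lapply(cfg$scenarios, function(sc) {
      crystals <- lapply(sc$crystals %||% list(), function(cr) {
        crystal_spec(
          location = cr$location,
          length = (cr$length_um %||% 269.1) / 1000,
          thickness = (cr$thickness_um %||% 3.0) / 1000,
          expansion_um = cr$expansion_um %||% 2
        )
      })
      scenario(sc$name, params = params, crystals = crystals,
               pressure = sc$pressure %||% pressure)
    })
    names(out) <- vapply(out, function(s) s$name, character(1))
    out
  }
  list(params = params, scenarios = scenarios)
}
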