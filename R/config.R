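#' Load a pipeline configuration file
#'
#' Reads a YAML configuration and merges it over the package defaults.
#' Recognized keys: `niche.n`, `niche.connectance`, `ranges.gamma`,
#' `ranges.mu`, `ranges.psi`, `ranges.phi`, `ranges.sigma`, `alpha.base`,
#' `alpha.exponent_scale`, `tolerances.eig`, `ensemble.size`,
#' `ensemble.max_tries`, `seed`.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A list of class `reactmotifs_config` with elements `niche`
#'   (`n`, `connectance`), `ranges` (a [param_ranges()]), `ensemble`
#'   (`size`, `max_tries`), `seed`.
#' @export
load_config <- function(path = NULL) {
  defaults <- list(
    niche = list(n = 15L, connectance = 0.15),
    ranges = list(),
    alpha = list(base = 10, exponent_scale = -2),
    tolerances = list(eig = 1e-9),
    ensemble = list(size = 10000L, max_tries = 1e5),
    seed = 1L
  )
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  merged <- utils::modifyList(defaults, user)
  ranges <- do.call(param_ranges, c(
    merged$ranges,
    list(
      alpha_base = merged$alpha$base,
      alpha_exponent_scale = merged$alpha$exponent_scale,
      tol = merged$tolerances$eig
    )
  ))
  structure(
    list(
      niche = merged$niche,
      ranges = ranges,
      ensemble = merged$ensemble,
      seed = merged$seed
    ),
    class = "reactmotifs_config"
  )
}
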