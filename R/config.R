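## YAML configuration: one file describing environment, gas exchange,
## diel constraints and scenario, mapped onto the package's constructors.

#' Read a YAML run configuration
#'
#' The file may contain any of the blocks `environment`, `gas`,
#' `constraints` and `scenario`; each block's entries are passed to the
#' corresponding constructor ([diel_environment()], [gas_exchange_params()],
#' [diel_constraints()], [scenario_config()]), so defaults apply to
#' anything omitted.
#'
#' @param path YAML file path.
#' @return list with elements `env`, `gas`, `constraints`, `scenario`
#'   (a [scenario_config()] built from the other three).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  env <- do.call(diel_environment, cfg$environment %||% list())
  gas <- do.call(gas_exchange_params, cfg$gas %||% list())
  cs <- do.call(diel_constraints, cfg$constraints %||% list())
  sc <- do.call(scenario_config,
                c(cfg$scenario %||% list(),
                  list(env = env, gas = gas, constraints = cs)))
  list(env = env, gas = gas, constraints = cs, scenario = sc)
}
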