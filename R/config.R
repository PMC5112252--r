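#' Default run configuration
#'
#' Full parameter set of the serial-reversal simulation, as nested lists:
#' `architecture`, `unit`, `learning`, `dcn`, `task` and `relax` sections.
#' The defaults reproduce the published simulation conditions; the `dcn`
#' switch selects the extended (three experts, dynamic control) or the
#' monolithic (single expert, no control network) variant.
#'
#' @param dcn Build the extended variant with a dynamic control network?
#' @return A nested configuration list.
#' @export
default_config <- function(dcn = TRUE) {
  list(
    architecture = list(n_input = 10, n_basis = c(100, 100), n_assoc = 48,
                        n_motor = 2, n_experts = if (dcn) 3 else 1,
                        max_weight = 4, init_general = c(0, 0.2),
                        init_motor = c(0, 0.3), init_mod = c(0, 0.1),
                        fan_in = 5, fan_input = 2),
    unit = list(alpha = 1, beta = 1, gamma = 4, zeta = 1, a = 0.1),
    learning = list(eta = 0.2, momentum = 0.9, tau = 0.15,
                    reward_correct = 0.4, reward_incorrect = 0,
                    accessory_gain = 20),
    dcn = c(list(enabled = dcn), unclass(dcn_params())),
    task = list(trials_per_phase = 160, n_phases = 3, target_category = 1),
    relax = list(dt = 0.1, tol = 1e-6, max_steps = 5000)
  )
}

#' Read a configuration file
#'
#' Reads a YAML (or JSON) configuration file and merges it recursively into
#' [default_config()], so partial files that override only a few fields are
#' valid.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param base Configuration to merge into.
#' @return The merged configuration list.
#' @export
read_config <- function(path, base = default_config()) {
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(user$dcn$enabled) &&
      !identical(user$dcn$enabled, base$dcn$enabled))
    base <- default_config(dcn = isTRUE(user$dcn$enabled))
  modifyList(base, user)
}

config_objects <- function(config) {
  list(spec = do.call(architecture_spec, config$architecture),
       up = do.call(unit_params, config$unit),
       lp = do.call(learning_params, config$learning),
       dp = do.call(dcn_params,
                    config$dcn[setdiff(names(config$dcn), "enabled")]),
       dcn_enabled = isTRUE(config$dcn$enabled))
}
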