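# Packaged simulation scenarios: named conformational-ensemble parameter
# sets (peak forces, fractions, step sizes, refolding kinetics) for the
# bulged-G4 sequence panel, read from a YAML config shipped with the package.

#' List packaged scenarios
#'
#' @param path Scenario YAML file. Defaults to the packaged one.
#' @return Character vector of scenario names.
#' @export
list_scenarios <- function(path = system.file("extdata", "scenarios.yaml",
                                              package = "g4tweezers")) {
  names(yaml::read_yaml(path)$scenarios)
}

#' Load a packaged simulation scenario
#'
#' Builds the full simulation condition for one sequence: the state mixture
#' (each component's `k_unfold` solved from its tabulated peak force at the
#' protocol loading rate with `dx` fixed at 1 nm), the ramp protocol, the
#' polymer and noise models, refolding kinetics where tabulated, and the
#' parsed sequence annotation. Step sizes of components labelled
#' `full`/`gvbq_5p`/`gvbq_3p` are checked against the sequence topology.
#'
#' @param name Scenario name (see [list_scenarios()]).
#' @param path Scenario YAML file. Defaults to the packaged one.
#' @param dx Transition distance assigned to every component, nm. Default 1.
#' @return List with `name`, `mixture`, `protocol`, `polymer`, `noise`,
#'   `kinetics` (or `NULL`), `annotation`, `truth` (data.frame of the
#'   generating peak forces, weights, and step sizes).
#' @export
load_scenario <- function(name,
                          path = system.file("extdata", "scenarios.yaml",
                                             package = "g4tweezers"),
                          dx = 1.0) {
  cfg <- yaml::read_yaml(path)
  if (!name %in% names(cfg$scenarios)) {
    stop("unknown scenario: ", name, " (see list_scenarios())")
  }
  sc <- cfg$scenarios[[name]]
  protocol <- ramp_protocol(
    f_start = cfg$protocol$f_start, f_end = cfg$protocol$f_end,
    loading_rate = cfg$protocol$loading_rate,
    hold_force = cfg$protocol$hold_force,
    hold_time = cfg$protocol$hold_time, kBT = cfg$protocol$kBT
  )
  polymer <- polymer_params(
    persistence_length = cfg$polymer$persistence_length_nm,
    contour_per_nt = cfg$polymer$contour_per_nt_nm,
    folded_extent = cfg$polymer$folded_extent_nm,
    kBT = cfg$polymer$kBT_pN_nm
  )
  noise <- noise_model(
    sigma_step = cfg$noise$sigma_step_nm,
    sigma_bead = cfg$noise$sigma_bead_nm,
    trace_rate = cfg$noise$trace_rate_hz
  )

  states <- lapply(sc$states, function(s) {
    bell_state(k_unfold_from_modal_force(s$peak_pN, dx, protocol),
               dx, step_nt = s$step_nt, label = s$label)
  })
  weights <- vapply(sc$states, function(s) s$weight, numeric(1))
  mixture <- state_mixture(states, weights, sc$w_unfolded)

  annotation <- NULL
  if (!is.null(sc$sequence)) {
    seqs <- load_g4_sequences()
    annotation <- seqs[[sc$sequence]]
    # topology-labelled components must carry the sequence-derived step size
    for (s in sc$states) {
      if (s$label %in% c("full", "gvbq_5p", "gvbq_3p")) {
        want <- expected_step_nt(annotation, s$label)
        if (s$step_nt != want) {
          stop("scenario ", name, ": component '", s$label, "' step_nt ",
               s$step_nt, " != sequence-derived ", want)
        }
      }
    }
  }

  truth <- data.frame(
    label = vapply(sc$states, function(s) s$label, character(1)),
    peak_pN = vapply(sc$states, function(s) s$peak_pN, numeric(1)),
    weight = weights / (sum(weights) + sc$w_unfolded),
    step_nt = vapply(sc$states, function(s) s$step_nt, numeric(1)),
    stringsAsFactors = FALSE
  )
  list(
    name = name, mixture = mixture, protocol = protocol, polymer = polymer,
    noise = noise, kinetics = sc$kinetics, annotation = annotation,
    truth = truth, w_unfolded = mixture$w_unfolded
  )
}

#' Load a packaged melting scenario
#'
#' @param name One of `"top_tetrad"`, `"bottom_tetrad"`, `"middle_tetrad"`
#'   (guanine-vacancy position groups).
#' @param path Scenario YAML file. Defaults to the packaged one.
#' @return List with `tm` (C) and `width` (C).
#' @export
load_melting_scenario <- function(name,
                                  path = system.file("extdata",
                                                     "scenarios.yaml",
                                                     package = "g4tweezers")) {
  cfg <- yaml::read_yaml(path)$melting_scenarios
  if (!name %in% names(cfg)) {
    stop("unknown melting scenario: ", name)
  }
  list(tm = cfg[[name]]$tm_C, width = cfg[[name]]$width_C)
}
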