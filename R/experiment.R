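#' Desk-scale experiment base configuration
#'
#' Bundles a synthetic dataset and the network / protocol settings used by
#' the package's scaled-down experiments: 100 excitatory neurons, 12x12
#' five-class stroke patterns, 600 training images at 100 per iteration,
#' and a homeostasis time constant short enough (1e4 ms, with a 2 mV
#' per-spike increment) that all neurons participate within a run — a
#' precondition for estimating the tail index from the final iteration's
#' increments, which requires every plastic synapse to carry updates.
#' The STDP fixed point \code{W0} and the learning rate are calibrated to
#' the plastic-weight scale of this small network (weights in [0, 1]);
#' the search-space learning rate \eqn{\eta} multiplies \code{eta_base}.
#'
#' @param n_classes,image_size,samples_per_class,noise_sd synthetic
#'   dataset parameters.
#' @param n_exc excitatory-layer size.
#' @param n_test held-out test images (generated from the same prototypes
#'   with fresh jitter).
#' @param data_seed seed for dataset generation.
#' @param images_per_iteration evaluation granularity.
#' @param eta desk-scale STDP learning rate.
#' @param eta_base base learning rate multiplied by a hyperparameter
#'   search's \code{eta} (the search domain is [0.05, 0.2], so the
#'   effective rate spans [0.01, 0.04] around the desk default).
#' @param tau_theta,theta_inc homeostasis settings.
#' @return list with all fields consumed by \code{\link{bg_objective}}
#'   and \code{\link{run_experiment}}.
#' @export
desk_experiment <- function(n_classes = 5, image_size = 12,
                            samples_per_class = 120, noise_sd = 0.12,
                            n_exc = 100, n_test = 150, data_seed = 99,
                            images_per_iteration = 100,
                            eta = 0.02, eta_base = 0.2,
                            tau_theta = 1e4, theta_inc = 2.0) {
  dataset <- generate_synthetic_patterns(
    n_classes = n_classes, image_size = image_size,
    samples_per_class = samples_per_class, noise_sd = noise_sd,
    seed = data_seed)
  test_set <- generate_synthetic_patterns(
    n_classes = n_classes, image_size = image_size,
    samples_per_class = ceiling(n_test / n_classes), noise_sd = noise_sd,
    seed = data_seed, sample_seed = data_seed + 5000L)
  list(dataset = dataset, test_set = test_set,
       n_input = image_size^2, n_exc = n_exc,
       w_min = 0, w_max = 1,
       exc_params = neuron_params("excitatory", theta_inc = theta_inc,
                                  tau_theta = tau_theta),
       inh_params = neuron_params("inhibitory"),
       stdp_args = list(rule = "log", eta = eta, sigma = 0.5,
                        c_plus = 1, c_minus = 0.5, W0 = 0.05,
                        w_min = 0, w_max = 1),
       eta_base = eta_base,
       images_per_iteration = images_per_iteration,
       gain_divisor = 4, duration = 350, dt = 0.5, relax_ms = 150)
}

#' Train and evaluate one experiment cell
#'
#' Trains a fresh network with the given STDP configuration on the base's
#' training stream, evaluates accuracies with frozen weights, and computes
#' the BG index of the final-iteration weight increments.
#'
#' @param base a \code{\link{desk_experiment}} base.
#' @param stdp an \code{\link{stdp_config}}.
#' @param seed run seed (weights, spike trains, noise).
#' @return one-row data.frame: rule, SFR, eta, BG index, accuracies,
#'   generalization error.
#' @export
run_cell <- function(base, stdp, seed = 1) {
  net <- build_network(base$n_input, base$n_exc, w_min = base$w_min,
                       w_max = base$w_max, seed = seed)
  run <- train_snn(base$dataset, net, base$exc_params, base$inh_params,
                   stdp, images_per_iteration = base$images_per_iteration,
                   gain_divisor = base$gain_divisor,
                   duration = base$duration, dt = base$dt,
                   relax_ms = base$relax_ms, seed = seed)
  ev <- evaluate_snn(run, base$dataset, base$test_set, base$exc_params,
                     base$inh_params, gain_divisor = base$gain_divisor,
                     duration = base$duration, dt = base$dt,
                     relax_ms = base$relax_ms)
  bg <- bg_index(run$trajectory)
  data.frame(rule = stdp$rule, sfr = stdp$c_plus / stdp$c_minus,
             eta = stdp$eta, seed = seed, bg_index = bg$bg_index,
             train_accuracy = ev$train_accuracy,
             test_accuracy = ev$test_accuracy,
             generalization_error = ev$generalization_error)
}

#' Run a (rule x SFR) or (rule x eta) experiment grid
#'
#' Reproduces the package's trend experiments at configurable scale: for
#' every combination of rule and swept value, trains and evaluates a
#' network and appends one result row. Partial failures are recorded
#' per cell (with \code{NA} metrics) and the grid continues.
#'
#' @param base a \code{\link{desk_experiment}} base.
#' @param rules character vector of STDP rules.
#' @param sweep \code{"sfr"} or \code{"eta"}.
#' @param values swept values: SFR = \code{c_plus/c_minus} with
#'   \code{c_minus} held at the rule default, or learning-rate
#'   multipliers on \code{eta_base}.
#' @param seeds one run per seed per cell.
#' @return data.frame of result rows (one per rule x value x seed).
#' @export
run_experiment <- function(base, rules = c("log", "add", "mult"),
                           sweep = c("sfr", "eta"),
                           values = c(0.9, 1.2, 1.7, 2.1),
                           seeds = 1) {
  sweep <- match.arg(sweep)
  rows <- list()
  for (rule in rules) {
    for (v in values) {
      for (sd in seeds) {
        args <- base$stdp_args
        args$rule <- rule
        if (rule != "log") { args$S <- NULL; args$gamma <- NULL }
        c_minus_def <- switch(rule, add = 0.6, mult = 2, log = 0.5)
        args$c_minus <- c_minus_def
        if (sweep == "sfr") {
          args$c_plus <- v * c_minus_def
        } else {
          args$c_plus <- 1
          args$eta <- v * base$eta_base
        }
        cfg <- do.call(stdp_config, args)
        row <- tryCatch(run_cell(base, cfg, seed = sd),
                        error = function(e)
                          data.frame(rule = rule, sfr = NA, eta = cfg$eta,
                                     seed = sd, bg_index = NA,
                                     train_accuracy = NA,
                                     test_accuracy = NA,
                                     generalization_error = NA))
        row$sweep <- sweep
        row$value <- v
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  do.call(rbind, rows)
}

#' Validate an experiment configuration document
#'
#' Schema-checks a configuration (an R list, or a JSON file path), fills
#' defaults, and reports all violations at once. Rule-specific STDP keys
#' are validated by the STDP module.
#'
#' @param document named list or path to a JSON file.
#' @return a validated configuration list of class \code{experiment_config}
#'   with a content hash in \code{$hash}.
#' @export
validate_config <- function(document = list()) {
  if (is.character(document))
    document <- jsonlite::read_json(document, simplifyVector = TRUE)
  defaults <- list(
    n_classes = 5, image_size = 12, samples_per_class = 120,
    noise_sd = 0.12, n_exc = 100, n_test = 150, data_seed = 99,
    images_per_iteration = 100, eta = 0.02, eta_base = 0.2,
    tau_theta = 1e4, theta_inc = 2.0,
    stdp = list(rule = "log"),
    seeds = 1)
  errors <- character(0)
  bad <- setdiff(names(document), names(defaults))
  if (length(bad) > 0)
    errors <- c(errors, paste("unknown keys:", paste(bad, collapse = ", ")))
  cfg <- utils::modifyList(defaults, document[setdiff(names(document), bad)])
  check_pos <- c("n_classes", "image_size", "samples_per_class", "n_exc",
                 "images_per_iteration", "eta", "eta_base", "tau_theta")
  for (key in check_pos) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] <= 0)
      errors <- c(errors, sprintf("%s must be a positive number", key))
  }
  if (cfg$noise_sd < 0) errors <- c(errors, "noise_sd must be >= 0")
  if (cfg$theta_inc < 0) errors <- c(errors, "theta_inc must be >= 0")
  stdp_ok <- tryCatch({
    stdp_config_from_list(cfg$stdp)
    TRUE
  }, error = function(e) {
    errors <<- c(errors, paste("stdp:", conditionMessage(e)))
    FALSE
  })
  if (length(errors) > 0)
    stop("invalid configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "experiment_config"
  cfg
}

#' Content hash of a configuration
#'
#' A stable short hash of the serialized configuration content, embedded
#' in every output artifact so reruns can be matched to their config.
#'
#' @param cfg a configuration list.
#' @return character scalar.
#' @export
config_hash <- function(cfg) {
  cfg$hash <- NULL
  raw <- as.integer(serialize(cfg, NULL, version = 2))
  # polynomial rolling hash over the serialized payload; exact in doubles
  h <- 5381
  for (b in raw) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Materialize a validated config into an experiment base
#'
#' @param cfg an \code{experiment_config}.
#' @return a base list as from \code{\link{desk_experiment}}.
#' @export
config_to_base <- function(cfg) {
  base <- desk_experiment(
    n_classes = cfg$n_classes, image_size = cfg$image_size,
    samples_per_class = cfg$samples_per_class, noise_sd = cfg$noise_sd,
    n_exc = cfg$n_exc, n_test = cfg$n_test, data_seed = cfg$data_seed,
    images_per_iteration = cfg$images_per_iteration,
    eta = cfg$eta, eta_base = cfg$eta_base, tau_theta = cfg$tau_theta,
    theta_inc = cfg$theta_inc)
  base$hash <- cfg$hash
  base
}
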