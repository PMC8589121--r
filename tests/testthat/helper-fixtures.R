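# Small shared fixtures, all built in code at test time.

# a fast miniature task: 8x8 images, 3 classes, small layers
mini_base <- function(n_exc = 36, samples_per_class = 20,
                      images_per_iteration = 30, seed = 7) {
  base <- desk_experiment(n_classes = 3, image_size = 8,
                          samples_per_class = samples_per_class,
                          noise_sd = 0.1, n_exc = n_exc, n_test = 30,
                          data_seed = seed,
                          images_per_iteration = images_per_iteration)
  base
}

mini_stdp <- function(rule = "log", ...) {
  args <- list(rule = rule, eta = 0.02, sigma = 0.5, c_plus = 1,
               c_minus = switch(rule, add = 0.6, mult = 2, log = 0.5),
               W0 = 0.05, w_min = 0, w_max = 1)
  if (rule != "log") args$S <- args$gamma <- NULL
  args <- utils::modifyList(args, list(...))
  do.call(stdp_config, args)
}

exc_pars <- function(...) {
  args <- utils::modifyList(list(tau_theta = 1e4, theta_inc = 2),
                            list(...))
  do.call(neuron_params, c(list("excitatory"), args))
}
inh_pars <- function(...) neuron_params("inhibitory", ...)
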