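#' Weight trajectory container
#'
#' Time-ordered record of the flattened plastic weight vector at iteration
#' boundaries; its final-iteration increments are the raw material for the
#' tail-index analysis.
#'
#' @param snapshots numeric matrix, one row per recorded iteration
#'   (row 1 = initialization), columns = flattened plastic synapses.
#' @return object of class \code{weight_trajectory}.
#' @export
weight_trajectory <- function(snapshots) {
  snapshots <- as.matrix(snapshots)
  obj <- list(snapshots = snapshots)
  class(obj) <- "weight_trajectory"
  obj
}

#' @rdname weight_trajectory
#' @param x a \code{weight_trajectory}.
#' @return \code{trajectory_increments}: matrix of consecutive snapshot
#'   differences.
#' @export
trajectory_increments <- function(x) {
  apply(x$snapshots, 2, diff)
}

#' @export
print.weight_trajectory <- function(x, ...) {
  cat(sprintf("<weight_trajectory> %d snapshots x %d synapses\n",
              nrow(x$snapshots), ncol(x$snapshots)))
  invisible(x)
}

#' Train a network with STDP on a labeled image stream
#'
#' Presents every image of the dataset in its presentation order through
#' \code{\link{run_presentation}} with plasticity on, with a silent
#' relaxation interval between presentations, and records a snapshot of
#' the plastic weights at every iteration boundary (an iteration =
#' \code{images_per_iteration} presentations). Labels are never used
#' during training (unsupervised learning).
#'
#' @param dataset a \code{labeled_image_set}.
#' @param net an \code{snn_topology}.
#' @param exc_params,inh_params \code{\link{neuron_params}}.
#' @param stdp an \code{\link{stdp_config}}.
#' @param images_per_iteration evaluation granularity.
#' @param gain_divisor intensity-to-rate divisor.
#' @param duration,dt,relax_ms presentation protocol (ms).
#' @param seed seed for all stochastic elements of the run.
#' @param state optional starting \code{\link{network_state}}.
#' @return object of class \code{train_run}: updated \code{net},
#'   \code{trajectory} (a \code{\link{weight_trajectory}}), final
#'   \code{state}, \code{schedule}, and per-presentation boost counts.
#' @export
train_snn <- function(dataset, net, exc_params, inh_params, stdp,
                      images_per_iteration = 60, gain_divisor = 4,
                      duration = 350, dt = 0.5, relax_ms = 150,
                      seed = 1, state = NULL) {
  n_img <- length(dataset$images)
  if (n_img == 0) stop("dataset is empty")
  schedule <- partition_iterations(n_img, images_per_iteration)
  set.seed(seed)
  if (is.null(state)) state <- network_state(net, exc_params, inh_params)
  rate_ceiling <- 255 / gain_divisor
  snapshots <- matrix(NA_real_, nrow(schedule) + 1L,
                      net$n_input * net$n_exc)
  snapshots[1, ] <- as.numeric(net$input_to_exc)
  boosts <- integer(n_img)
  row <- 2L
  for (it in seq_len(nrow(schedule))) {
    for (i in schedule$from[it]:schedule$to[it]) {
      state <- relax_state(state, exc_params, inh_params, stdp,
                           interval = relax_ms)
      rates <- encode_rates(dataset$images[[i]], gain_divisor)
      res <- tryCatch(
        run_presentation(net, exc_params, inh_params, stdp, rates,
                         state = state, duration = duration, dt = dt,
                         plastic = TRUE, rate_ceiling = rate_ceiling),
        error = function(e)
          stop(sprintf("presentation of sample %d failed: %s",
                       i, conditionMessage(e)), call. = FALSE))
      if (any(!is.finite(res$W)))
        stop(sprintf("divergent weights at iteration %d (sample %d)",
                     it, i))
      net$input_to_exc <- res$W
      state <- res$state
      boosts[i] <- res$n_boosts
    }
    snapshots[row, ] <- as.numeric(net$input_to_exc)
    row <- row + 1L
  }
  out <- list(net = net, trajectory = weight_trajectory(snapshots),
              state = state, schedule = schedule, boosts = boosts,
              stdp = stdp, seed = seed)
  class(out) <- "train_run"
  out
}

#' @export
print.train_run <- function(x, ...) {
  cat(sprintf("<train_run> %s rule, %d iterations, %d synapses\n",
              x$stdp$rule, nrow(x$schedule),
              ncol(x$trajectory$snapshots)))
  invisible(x)
}

#' Frozen-network response counts
#'
#' Presents every image with learning and homeostasis frozen and returns
#' the per-image, per-excitatory-neuron spike counts — the common input to
#' class assignment, prediction, and the training-loss curve.
#'
#' @inheritParams train_snn
#' @param state carried network state; homeostatic thresholds inside it
#'   stay fixed.
#' @return integer matrix, images in rows, excitatory neurons in columns.
#' @export
response_counts <- function(dataset, net, exc_params, inh_params, stdp,
                            gain_divisor = 4, duration = 350, dt = 0.5,
                            relax_ms = 150, state = NULL) {
  n_img <- length(dataset$images)
  if (is.null(state)) state <- network_state(net, exc_params, inh_params)
  rate_ceiling <- 255 / gain_divisor
  counts <- matrix(0L, n_img, net$n_exc)
  for (i in seq_len(n_img)) {
    state <- relax_state(state, exc_params, inh_params, stdp,
                         interval = relax_ms, frozen = TRUE)
    rates <- encode_rates(dataset$images[[i]], gain_divisor)
    res <- run_presentation(net, exc_params, inh_params, stdp, rates,
                            state = state, duration = duration, dt = dt,
                            plastic = FALSE, rate_ceiling = rate_ceiling)
    counts[i, ] <- res$spike_counts
    state <- res$state
  }
  counts
}

#' Assign a class to each excitatory neuron
#'
#' Each neuron is labeled with the class to which its mean response
#' (spike count per presentation) is maximal. Ties break to the lowest
#' class index; neurons that never spiked are marked unresponsive
#' (\code{NA}) and excluded from prediction.
#'
#' @param counts response matrix from \code{\link{response_counts}}
#'   (images x neurons).
#' @param labels 0-based class labels, one per image.
#' @return integer vector (one entry per neuron) of 0-based classes, with
#'   \code{NA} for unresponsive neurons.
#' @export
assign_classes <- function(counts, labels) {
  classes <- sort(unique(labels))
  mean_resp <- vapply(classes, function(cl)
    colMeans(counts[labels == cl, , drop = FALSE]), numeric(ncol(counts)))
  mean_resp <- matrix(mean_resp, nrow = ncol(counts))
  # rows of mean_resp are neurons, columns follow `classes`
  map <- classes[apply(mean_resp, 1, which.max)]
  map[colSums(counts) == 0] <- NA_integer_
  as.integer(map)
}

#' Predict classes from frozen responses
#'
#' For each image, the predicted class maximizes the mean spike count over
#' the neurons assigned to that class. Ties break to the lowest class
#' index.
#'
#' @param counts response matrix (images x neurons).
#' @param class_map assignment from \code{\link{assign_classes}}.
#' @return integer vector of 0-based predicted classes.
#' @export
predict_classes <- function(counts, class_map) {
  responsive <- which(!is.na(class_map))
  if (length(responsive) == 0)
    stop("no responsive neurons: prediction impossible")
  classes <- sort(unique(class_map[responsive]))
  per_class <- vapply(classes, function(cl) {
    idx <- responsive[class_map[responsive] == cl]
    rowMeans(counts[, idx, drop = FALSE])
  }, numeric(nrow(counts)))
  per_class <- matrix(per_class, nrow = nrow(counts))
  as.integer(classes[apply(per_class, 1, which.max)])
}

#' Classification accuracy in percent
#'
#' @param predicted,labels 0-based class vectors.
#' @return percentage of matches in [0, 100].
#' @export
accuracy_pct <- function(predicted, labels) {
  100 * mean(predicted == labels)
}

#' Generalization error
#'
#' The absolute difference between training and test accuracy, in
#' percentage points — the package's target metric of generalizability.
#'
#' @param train_acc,test_acc accuracies in [0, 100].
#' @return \eqn{|train - test|}.
#' @export
generalization_error <- function(train_acc, test_acc) {
  stopifnot(train_acc >= 0, train_acc <= 100,
            test_acc >= 0, test_acc <= 100)
  abs(train_acc - test_acc)
}

#' Cross-entropy training loss from response counts
#'
#' Per image, the per-class mean spike counts (over neurons assigned to
#' each class) are divided by their maximum, renormalized to a probability
#' vector with additive smoothing \code{eps}, and scored by cross-entropy
#' against the true label; the mean over images is returned. Images with
#' all-zero counts fall back to the uniform distribution (flagged via the
#' \code{n_zero} attribute).
#'
#' @param counts response matrix (images x neurons).
#' @param class_map assignment from \code{\link{assign_classes}}.
#' @param labels true 0-based labels.
#' @param n_classes total number of classes.
#' @param eps smoothing constant.
#' @return mean cross-entropy, with attribute \code{n_zero}.
#' @export
cross_entropy_loss <- function(counts, class_map, labels,
                               n_classes = length(unique(labels)),
                               eps = 1e-9) {
  classes <- seq_len(n_classes) - 1L
  resp <- vapply(classes, function(cl) {
    idx <- which(!is.na(class_map) & class_map == cl)
    if (length(idx) == 0) return(rep(0, nrow(counts)))
    rowMeans(counts[, idx, drop = FALSE])
  }, numeric(nrow(counts)))
  resp <- matrix(resp, nrow = nrow(counts))
  n_zero <- 0L
  losses <- vapply(seq_len(nrow(resp)), function(i) {
    v <- resp[i, ]
    if (max(v) == 0) {
      n_zero <<- n_zero + 1L
      v <- rep(1, n_classes)
    } else {
      v <- v / max(v)
    }
    p <- (v + eps) / sum(v + eps)
    -log(p[labels[i] + 1L])
  }, numeric(1))
  structure(mean(losses), n_zero = n_zero)
}

#' Training-loss curve point with repeat spread
#'
#' Evaluates the frozen network \code{repeats} times on the evaluation
#' subset, randomizing the presentation order each time, and reports the
#' mean loss and its spread.
#'
#' @inheritParams response_counts
#' @param class_map neuron-to-class assignment.
#' @param repeats number of shuffled evaluations.
#' @return list with \code{mean}, \code{sd}, and the individual
#'   \code{values}.
#' @export
training_loss <- function(dataset, net, exc_params, inh_params, stdp,
                          class_map, repeats = 5, gain_divisor = 4,
                          duration = 350, dt = 0.5, relax_ms = 150) {
  n_img <- length(dataset$images)
  vals <- vapply(seq_len(repeats), function(r) {
    ord <- sample.int(n_img)
    shuffled <- dataset
    shuffled$images <- dataset$images[ord]
    shuffled$labels <- dataset$labels[ord]
    cnt <- response_counts(shuffled, net, exc_params, inh_params, stdp,
                           gain_divisor = gain_divisor,
                           duration = duration, dt = dt,
                           relax_ms = relax_ms)
    as.numeric(cross_entropy_loss(cnt, class_map, shuffled$labels,
                                  n_classes = dataset$n_classes))
  }, numeric(1))
  list(mean = mean(vals), sd = stats::sd(vals), values = vals)
}

#' End-to-end frozen evaluation of a trained network
#'
#' One frozen pass over the training stream yields both the neuron class
#' assignment and the training accuracy; a second pass over the test set
#' yields the test accuracy and the generalization error.
#'
#' @param run a \code{train_run} (or a list with \code{net}).
#' @param train_set,test_set \code{labeled_image_set}s.
#' @inheritParams response_counts
#' @return list with \code{class_map}, \code{train_accuracy},
#'   \code{test_accuracy}, \code{generalization_error}.
#' @export
evaluate_snn <- function(run, train_set, test_set, exc_params, inh_params,
                         gain_divisor = 4, duration = 350, dt = 0.5,
                         relax_ms = 150) {
  net <- run$net
  stdp <- run$stdp
  train_counts <- response_counts(train_set, net, exc_params, inh_params,
                                  stdp, gain_divisor, duration, dt,
                                  relax_ms)
  class_map <- assign_classes(train_counts, train_set$labels)
  train_acc <- accuracy_pct(predict_classes(train_counts, class_map),
                            train_set$labels)
  test_counts <- response_counts(test_set, net, exc_params, inh_params,
                                 stdp, gain_divisor, duration, dt,
                                 relax_ms)
  test_acc <- accuracy_pct(predict_classes(test_counts, class_map),
                           test_set$labels)
  list(class_map = class_map, train_accuracy = train_acc,
       test_accuracy = test_acc,
       generalization_error = generalization_error(train_acc, test_acc))
}

#' Write / read a weight trajectory as portable CSV
#'
#' Snapshots go to a dense CSV (one row per iteration, no header) next to
#' a small JSON manifest recording the iteration indices, snapshot
#' dimensions, and the run seed, so archived trajectories can be re-read
#' and re-analyzed without the originating session.
#'
#' @param trajectory a \code{\link{weight_trajectory}}.
#' @param path output CSV path; the manifest is written alongside as
#'   \code{<path>.manifest.json}.
#' @param seed optional seed recorded in the manifest.
#' @return \code{read_trajectory} returns a \code{weight_trajectory}.
#' @export
write_trajectory <- function(trajectory, path, seed = NA) {
  utils::write.table(trajectory$snapshots, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  manifest <- list(iterations = seq_len(nrow(trajectory$snapshots)) - 1L,
                   n_snapshots = nrow(trajectory$snapshots),
                   n_synapses = ncol(trajectory$snapshots),
                   seed = seed)
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  snaps <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(snaps) <- NULL
  manifest_path <- paste0(path, ".manifest.json")
  if (file.exists(manifest_path)) {
    m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    if (m$n_snapshots != nrow(snaps) || m$n_synapses != ncol(snaps))
      stop("trajectory does not match its manifest")
  }
  weight_trajectory(snaps)
}
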