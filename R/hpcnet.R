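#' Encode an image as constant-rate spike trains
#'
#' Each normalised pixel p drives one input neuron with a homogeneous spike
#' train of constant interspike interval `tau_isi = 5 / (p + 0.01)` ms,
#' starting at `9 + tau_isi` ms and lasting to the end of the stimulus
#' (default 50 ms). Dark pixels (p near 0) yield intervals far longer than
#' the stimulus, i.e. empty trains.
#'
#' @param pixels Numeric vector or matrix of pixel values in \[0, 1\]
#'   (matrices are flattened column-major).
#' @param t_stop Stimulus duration, ms.
#' @return A list of spike-time vectors, one per pixel.
#' @examples
#' encode_image(c(0, 0.99))
#' @export
encode_image <- function(pixels, t_stop = 50) {
  p <- as.numeric(pixels)
  if (any(p < 0 | p > 1 | !is.finite(p))) {
    abort("pixel values must lie in [0, 1].")
  }
  lapply(p, function(px) {
    tau <- 5 / (px + 0.01)
    first <- 9 + tau
    if (first > t_stop) return(numeric(0))
    seq(first, t_stop, by = tau)
  })
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

relu <- function(x) pmax(x, 0)

#' Build a three-layer dendritic network
#'
#' A network of detailed passive neuron models for image classification:
#' input neurons (one per pixel) are passive single compartments driven by
#' spike trains through single-exponential synapses; hidden neurons are
#' copies of a passive dendritic tree (default: the 15-compartment
#' [example_tree()] with passive parameters cm 1.5 uF/cm^2, rm 48300 Ohm
#' cm^2, ra 261.97 Ohm cm, E_l 0 mV, a synthetic stand-in for a
#' reconstructed pyramidal morphology); output neurons are passive single
#' compartments. Inter-layer coupling is graded: the current of contact k
#' from neuron i onto neuron j is `g_ijk * W_ijk * relu(v_i)` with the
#' presynaptic somatic voltage taken from the previous step. Transfer
#' resistances from every synapse site to the postsynaptic soma are
#' precomputed at build time and drive the learning rule.
#'
#' @param n_in,n_hidden,n_out Layer sizes.
#' @param hidden_tree Compartment tree for hidden neurons (shared
#'   morphology), or NULL for the default.
#' @param contacts Synaptic contacts per input-hidden pair (default 1).
#' @param g_syn Synaptic conductance scale of input-to-hidden graded
#'   contacts, uS.
#' @param g_out Conductance scale of hidden-to-output contacts, uS. Output
#'   cells are high-impedance single compartments, so this is kept small by
#'   default to hold the readout voltages in a physiological range where the
#'   softmax is well conditioned.
#' @param w_scale Weights are initialised uniform(0, `w_scale`).
#' @param seed Integer seed for placement and initialisation.
#' @param dt,t_stop Integration step and stimulus duration, ms.
#' @param t_avg Readout-averaging window, ms (default c(20, 50)).
#' @param t_learn Learning window, ms (default c(30, 50)).
#' @param in_gmax,in_tau,in_esyn Input spike-synapse parameters
#'   (uS, ms, mV).
#' @param soma_size Length = diameter of single-compartment cells, um.
#' @return An object of class `hpcnet`.
#' @examples
#' net <- hpcnet(4, 2, 2, seed = 1)
#' @export
hpcnet <- function(n_in, n_hidden, n_out, hidden_tree = NULL, contacts = 1L,
                   g_syn = 0.05, g_out = 1e-4, w_scale = 0.1, seed = 1L,
                   dt = 0.025, t_stop = 50, t_avg = c(20, 50),
                   t_learn = c(30, 50), in_gmax = 0.05, in_tau = 0.5,
                   in_esyn = 1, soma_size = 10) {
  stopifnot(n_in >= 1, n_hidden >= 1, n_out >= 2, contacts >= 1)
  if (is.null(hidden_tree)) {
    hidden_tree <- example_tree(
      length = c(10, rep(20, 14)), diam = c(10, rep(1, 14)),
      cm = 1.5, rm = 48300, ra = 261.97, el = 0
    )
  }
  stopifnot(inherits(hidden_tree, "compartment_tree"))
  nh <- nrow(hidden_tree)
  dend_nodes <- which(hidden_tree$kind != "soma")

  withr_seed(seed, {
    ct <- tidyr::expand_grid(
      in_id = seq_len(n_in), hid_id = seq_len(n_hidden),
      contact = seq_len(contacts)
    )
    ct$node <- sample(dend_nodes, nrow(ct), replace = TRUE)
    ct$w <- runif(nrow(ct), 0, w_scale)
    w_out <- matrix(runif(n_hidden * n_out, 0, w_scale), n_hidden, n_out)
  })
  r_soma <- transfer_resistance_to(hidden_tree, 1L)
  ct$r <- r_soma[ct$node]

  cell <- function(cm, rm, ra) {
    new_compartment_tree(parent = NA_integer_, length = soma_size,
                         diam = soma_size, kind = "soma",
                         cm = cm, rm = rm, ra = ra, el = 0)
  }
  in_cell <- cell(1, 1e4, 100)
  out_cell <- cell(1, 1e4, 100)
  r_out <- input_resistance(out_cell, 1L)

  structure(
    list(
      n_in = n_in, n_hidden = n_hidden, n_out = n_out,
      hidden_tree = hidden_tree, contacts = ct, w_out = w_out,
      g_syn = g_syn, g_out = g_out, r_out = r_out,
      in_cell = in_cell, out_cell = out_cell,
      dt = dt, t_stop = t_stop, t_avg = t_avg, t_learn = t_learn,
      in_gmax = in_gmax, in_tau = in_tau, in_esyn = in_esyn,
      seed = seed
    ),
    class = "hpcnet"
  )
}

#' @export
print.hpcnet <- function(x, ...) {
  cat(sprintf(
    "hpcnet: %d-%d-%d, %d graded contacts, hidden tree of %d compartments\n",
    x$n_in, x$n_hidden, x$n_out, nrow(x$contacts), nrow(x$hidden_tree)
  ))
  invisible(x)
}

#' Forward pass of a dendritic network
#'
#' Encodes the image, integrates the three layers for the stimulus duration
#' and returns class probabilities (softmax of the output somatic voltages
#' averaged over the readout window) together with the per-neuron activation
#' sums over the learning window that the weight update needs.
#'
#' @param net An [hpcnet()].
#' @param pixels Image pixels in \[0, 1\] (length `n_in`).
#' @param record_traces Keep full somatic voltage traces.
#' @return A list of class `hpcnet_forward`: `p` (class probabilities),
#'   `vbar_out`, `vbar_hidden`, `sum_f_in`, `sum_f_hidden`,
#'   `n_learn_steps`, and optionally trace matrices.
#' @export
hpcnet_forward <- function(net, pixels, record_traces = FALSE) {
  if (length(as.numeric(pixels)) != net$n_in) {
    abort(sprintf("expected %d pixels, got %d.", net$n_in,
                  length(as.numeric(pixels))))
  }
  trains <- encode_image(pixels, net$t_stop)
  spike_times <- unlist(trains, use.names = FALSE)
  if (is.null(spike_times)) spike_times <- numeric(0)
  spike_off <- c(0L, cumsum(vapply(trains, length, 1L)))

  co_in <- tree_coefficients(net$in_cell)
  co_out <- tree_coefficients(net$out_cell)
  co_h <- tree_coefficients(net$hidden_tree)
  n_steps <- as.integer(round(net$t_stop / net$dt))

  res <- hpcnet_forward_cpp(
    in_cdt = rep(co_in$c_nf, net$n_in), in_gl = rep(co_in$g_leak, net$n_in),
    in_el = rep(0, net$n_in),
    in_gmax = rep(net$in_gmax, net$n_in), in_tau = net$in_tau,
    in_esyn = net$in_esyn,
    spike_times = as.numeric(spike_times), spike_off = as.integer(spike_off),
    h_parent = c(-1L, net$hidden_tree$parent[-1] - 1L),
    h_cnf = co_h$c_nf, h_gl = co_h$g_leak, h_gax = co_h$g_axial,
    h_el = co_h$el, n_hidden = net$n_hidden,
    ct_in = as.integer(net$contacts$in_id - 1L),
    ct_hid = as.integer(net$contacts$hid_id - 1L),
    ct_node = as.integer(net$contacts$node - 1L),
    ct_g = rep_len(net$g_syn, nrow(net$contacts)),
    ct_w = as.numeric(net$contacts$w),
    w_out = net$w_out, g_out = net$g_out,
    out_cdt = rep(co_out$c_nf, net$n_out),
    out_gl = rep(co_out$g_leak, net$n_out), out_el = rep(0, net$n_out),
    dt = net$dt, n_steps = n_steps,
    avg_lo = net$t_avg[1], avg_hi = net$t_avg[2],
    learn_lo = net$t_learn[1], learn_hi = net$t_learn[2],
    record_traces = record_traces
  )
  res$p <- softmax(res$vbar_out)
  class(res) <- "hpcnet_forward"
  res
}

#' Weight gradients from the transfer-resistance learning rule
#'
#' Implements the gradient-based plasticity rule: with the printed error
#' convention `e_c = y_c - p_c` for output neurons and
#' `e_j = sum_c e_c r_c g W_jc f'(vbar_j)` for hidden neurons, the
#' per-weight update accumulated over the learning window is
#' `dW = e * r * g * sum_t f(v_pre^t) * dt / (t_e - t_s)`, where `r` is the
#' transfer resistance from the synapse to the postsynaptic soma. Gradient
#' ascent on `e = y - p` is descent on the cross-entropy loss, so
#' [hpcnet_apply_update()] adds `eta * dW`.
#'
#' @param net An [hpcnet()].
#' @param fwd The matching [hpcnet_forward()] result.
#' @param label True class, 0-based (as in [toy_images()]).
#' @return A list of class `hpcnet_grad`: `dw_out` (n_hidden x n_out),
#'   `dw_contacts` (one per contact row), `loss`, `err_out`.
#' @export
hpcnet_backward <- function(net, fwd, label) {
  stopifnot(inherits(fwd, "hpcnet_forward"))
  if (is.null(fwd$sum_f_in)) abort("forward pass lacks recorded activations.")
  y <- as.numeric(seq_len(net$n_out) - 1L == label)
  if (sum(y) != 1) abort("`label` must be one of 0..n_out-1.")
  p <- fwd$p
  err_out <- y - p
  win <- net$t_learn[2] - net$t_learn[1]
  fac <- net$dt / win

  fbar_h <- fac * fwd$sum_f_hidden            # ~ mean f over the window
  dw_out <- outer(fbar_h, err_out * net$r_out * net$g_out)

  fprime <- as.numeric(fwd$vbar_hidden > 0)
  err_h <- as.numeric(net$w_out %*% (err_out * net$r_out * net$g_out)) * fprime

  fbar_in <- fac * fwd$sum_f_in
  ct <- net$contacts
  dw_ct <- err_h[ct$hid_id] * ct$r * net$g_syn * fbar_in[ct$in_id]

  structure(
    list(dw_out = dw_out, dw_contacts = dw_ct,
         loss = -sum(y * log(pmax(p, 1e-12))), err_out = err_out,
         pred = which.max(p) - 1L),
    class = "hpcnet_grad"
  )
}

#' @rdname hpcnet_backward
#' @param grad An `hpcnet_grad` (or the element-wise mean of several).
#' @param eta Learning rate.
#' @export
hpcnet_apply_update <- function(net, grad, eta = 0.01) {
  net$w_out <- net$w_out + eta * grad$dw_out
  net$contacts$w <- net$contacts$w + eta * grad$dw_contacts
  net
}

mean_grads <- function(grads) {
  list(
    dw_out = Reduce(`+`, lapply(grads, `[[`, "dw_out")) / length(grads),
    dw_contacts = Reduce(`+`, lapply(grads, `[[`, "dw_contacts")) /
      length(grads)
  )
}

#' Mini-batch update
#'
#' Runs independent forward/backward passes for every sample in the batch
#' (logical network copies sharing weights) and applies the mean weight
#' update once, so all copies stay identical.
#'
#' @param net An [hpcnet()].
#' @param pixel_list List of pixel vectors.
#' @param labels 0-based class labels, same length.
#' @param eta Learning rate.
#' @return The updated network, with attributes `loss` (mean) and
#'   `accuracy` over the batch.
#' @export
hpcnet_train_batch <- function(net, pixel_list, labels, eta = 0.01) {
  if (length(pixel_list) == 0) abort("batch must contain at least one sample.")
  stopifnot(length(pixel_list) == length(labels))
  grads <- purrr::map2(pixel_list, labels, function(px, lab) {
    hpcnet_backward(net, hpcnet_forward(net, px), lab)
  })
  out <- hpcnet_apply_update(net, mean_grads(grads), eta)
  attr(out, "loss") <- mean(vapply(grads, `[[`, 1, "loss"))
  attr(out, "accuracy") <- mean(vapply(grads, `[[`, 1L, "pred") == labels)
  out
}

#' Train a dendritic network on labelled images
#'
#' Shuffled mini-batch training with the transfer-resistance rule.
#'
#' @param net An [hpcnet()].
#' @param images A tibble as from [toy_images()] (`label`, `pixels`).
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param eta Learning rate (default 0.01).
#' @param seed Shuffling seed.
#' @return An object of class `hpcnet_fit`: list with the trained `net` and
#'   a `log` tibble (`epoch`, `loss`, `accuracy`). Methods: [tidy()],
#'   [glance()], [autoplot()].
#' @export
hpcnet_train <- function(net, images, epochs = 50, batch_size = 4,
                         eta = 0.01, seed = 1L) {
  n <- nrow(images)
  log <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- withr_seed(mix_seed(seed, ep), sample.int(n))
    losses <- numeric(0); accs <- numeric(0)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      net <- hpcnet_train_batch(net, images$pixels[idx], images$label[idx],
                                eta = eta)
      losses <- c(losses, attr(net, "loss"))
      accs <- c(accs, attr(net, "accuracy") * length(idx))
    }
    log[[ep]] <- tibble(epoch = ep, loss = mean(losses),
                        accuracy = sum(accs) / n)
  }
  structure(list(net = net, log = dplyr::bind_rows(log)),
            class = "hpcnet_fit")
}

#' Classify images with a trained network
#'
#' @param net An [hpcnet()] (e.g. `fit$net`).
#' @param images A tibble as from [toy_images()].
#' @return The tibble with `pred` and `correct` columns added.
#' @export
hpcnet_predict <- function(net, images) {
  preds <- vapply(images$pixels, function(px) {
    which.max(hpcnet_forward(net, px)$p) - 1L
  }, 1L)
  images$pred <- preds
  images$correct <- preds == images$label
  images
}

#' @describeIn hpcnet_train Per-epoch training log.
#' @param x An `hpcnet_fit`.
#' @param ... Unused.
#' @export
tidy.hpcnet_fit <- function(x, ...) x$log

#' @describeIn hpcnet_train Final-epoch summary.
#' @export
glance.hpcnet_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble(epochs = nrow(x$log), final_loss = last$loss,
         final_accuracy = last$accuracy)
}
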