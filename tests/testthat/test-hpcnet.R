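test_that("spike encoding follows the interspike-interval rule", {
  tr <- encode_image(c(0, 0.99))
  expect_length(tr[[1]], 0) # tau = 500 ms, first spike at 509 ms > 50 ms
  expect_equal(tr[[2]], seq(14, 49, by = 5)) # tau exactly 5 ms
  expect_true(all(lengths(encode_image(matrix(0, 4, 4))) == 0))
  expect_error(encode_image(c(0.5, 1.2)), "\\[0, 1\\]")
  # denser pixels spike more
  n_spk <- lengths(encode_image(c(0.1, 0.5, 0.9)))
  expect_true(all(diff(n_spk) >= 0))
})

test_that("forward pass yields normalised probabilities, uniform at zero weights", {
  net <- hpcnet(4, 3, 2, w_scale = 0, seed = 1)
  f <- hpcnet_forward(net, c(0.9, 0.1, 0.5, 0.7))
  expect_equal(sum(f$p), 1, tolerance = 1e-12)
  expect_equal(f$p, c(0.5, 0.5), tolerance = 1e-12)

  net2 <- hpcnet(4, 3, 2, seed = 2)
  f2 <- hpcnet_forward(net2, rep(0.8, 4))
  expect_equal(sum(f2$p), 1, tolerance = 1e-12)
  expect_true(all(f2$vbar_hidden >= 0))
  expect_error(hpcnet_forward(net2, rep(0.5, 7)), "expected 4 pixels")
})

test_that("steady-state readout matches the transfer-resistance circuit", {
  # fast hidden membrane so 50 ms reaches steady state; constant input
  fast_tree <- example_tree(length = c(10, rep(20, 14)),
                            diam = c(10, rep(1, 14)),
                            cm = 1, rm = 2000, ra = 261.97, el = 0)
  net <- hpcnet(1, 1, 2, hidden_tree = fast_tree, contacts = 1,
                in_gmax = 5, seed = 4) # strong drive pins v_in near E_syn
  f <- hpcnet_forward(net, 0.99, record_traces = TRUE)
  # at steady state: v_soma = sum_k g W f(v_in) r(node_k -> soma)
  f_in_ss <- tail(f$traces_in[, 1], 1)
  pred <- sum(net$g_syn * net$contacts$w * f_in_ss * net$contacts$r)
  obs <- tail(f$traces_hidden[, 1], 1)
  expect_equal(obs, pred, tolerance = 2e-2)
})

test_that("error terms follow the softmax identity and vanish at perfect prediction", {
  net <- hpcnet(4, 2, 2, seed = 1)
  fwd <- hpcnet_forward(net, rep(0.9, 4))
  g <- hpcnet_backward(net, fwd, label = 0)
  expect_equal(sum(g$err_out), 0, tolerance = 1e-12)

  # printed arithmetic: C = 2, p = (0.7, 0.3), y = (1, 0)
  mock <- structure(
    list(p = c(0.7, 0.3), vbar_hidden = fwd$vbar_hidden,
         sum_f_in = fwd$sum_f_in, sum_f_hidden = fwd$sum_f_hidden),
    class = "hpcnet_forward"
  )
  gm <- hpcnet_backward(net, mock, label = 0)
  expect_equal(gm$err_out, c(0.3, -0.3), tolerance = 1e-12)

  # p exactly the one-hot target: every update term is zero
  mock$p <- c(1, 0)
  g0 <- hpcnet_backward(net, mock, label = 0)
  expect_true(all(g0$dw_out == 0))
  expect_true(all(g0$dw_contacts == 0))
})

test_that("rule updates align with finite-difference gradients of the loss", {
  net <- hpcnet(4, 2, 2, seed = 3)
  px <- rep(0.99, 4) # constant suprathreshold drive
  loss_at <- function(n) {
    f <- hpcnet_forward(n, px)
    -log(max(f$p[1], 1e-12)) # label 0
  }
  g <- hpcnet_backward(net, hpcnet_forward(net, px), label = 0)
  analytic <- -as.vector(g$dw_out) # descent gradient
  eps <- 1e-4
  fd <- vapply(seq_along(net$w_out), function(i) {
    np <- net; np$w_out[i] <- np$w_out[i] + eps
    nm <- net; nm$w_out[i] <- nm$w_out[i] - eps
    (loss_at(np) - loss_at(nm)) / (2 * eps)
  }, 1)
  cosine <- sum(analytic * fd) / sqrt(sum(analytic^2) * sum(fd^2))
  expect_gte(cosine, 0.99)
})

test_that("mini-batch updates average per-sample gradients", {
  net <- hpcnet(4, 2, 2, seed = 5)
  imgs <- toy_images(2, size = 2, classes = 2, seed = 6)
  px <- imgs$pixels[[1]]
  lab <- imgs$label[1]

  one <- hpcnet_train_batch(net, list(px), lab, eta = 0.01)
  g <- hpcnet_backward(net, hpcnet_forward(net, px), lab)
  direct <- hpcnet_apply_update(net, g, eta = 0.01)
  expect_equal(one$w_out, direct$w_out)
  expect_equal(one$contacts$w, direct$contacts$w)

  # a batch of the same sample repeated equals the single-sample update
  rep3 <- hpcnet_train_batch(net, rep(list(px), 3), rep(lab, 3), eta = 0.01)
  expect_equal(rep3$w_out, one$w_out, tolerance = 1e-12)
  expect_equal(rep3$contacts$w, one$contacts$w, tolerance = 1e-12)

  expect_error(hpcnet_train_batch(net, list(), integer(0)), "at least one")
})

test_that("training on the separable toy task drives the loss down", {
  net <- hpcnet(16, 8, 2, seed = 1)
  imgs <- toy_images(8, size = 4, classes = 2, seed = 11)
  fit <- hpcnet_train(net, imgs, epochs = 10, batch_size = 4, seed = 1)
  log <- tidy(fit)
  # monotone decrease up to one plateau step over the first 10 epochs
  expect_lte(sum(diff(log$loss) > 1e-9), 1)
  expect_gte(max(log$accuracy), 0.9)
  expect_equal(glance(fit)$epochs, 10)
  pred <- hpcnet_predict(fit$net, imgs)
  expect_gte(mean(pred$correct), 0.9)
  expect_s3_class(autoplot(fit), "ggplot")
})
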