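# shared fixtures and oracles, all built in code

# a standing frame in ground-anchored coordinates (feet near y = 0)
make_standing_frame <- function(t = 0, height = 1.8, z = 2.5) {
  skel_frame(t, list(
    head = c(0, height, z),
    center_shoulder = c(0, 0.82 * height, z),
    left_shoulder = c(0.2, 0.82 * height, z),
    right_shoulder = c(-0.2, 0.82 * height, z),
    left_elbow = c(0.25, 0.6 * height, z),
    right_elbow = c(-0.25, 0.6 * height, z),
    left_hand = c(0.28, 0.42 * height, z),
    right_hand = c(-0.28, 0.42 * height, z),
    left_hip = c(0.15, 0.53 * height, z),
    right_hip = c(-0.15, 0.53 * height, z),
    left_knee = c(0.15, 0.285 * height, z),
    right_knee = c(-0.15, 0.285 * height, z),
    left_foot = c(0.15, 0, z),
    right_foot = c(-0.15, 0, z)
  ))
}

# hand-built 1-1-1 network for closed-form forward checks
tiny_net <- function(w1 = 1, b1 = 0, w2 = 1, b2 = 0, transfer = "sigmoid") {
  structure(list(W1 = matrix(w1, 1, 1), b1 = b1,
                 W2 = matrix(w2, 1, 1), b2 = b2,
                 transfer = transfer, levels = "a"),
            class = "mlp")
}

# independent brute-force objective: explicit loops, no linear algebra
brute_force_error <- function(net, x, d) {
  tf <- if (net$transfer == "sigmoid") function(v) 1 / (1 + exp(-v)) else tanh
  total <- 0
  for (p in seq_len(nrow(x))) {
    hid <- numeric(length(net$b1))
    for (j in seq_along(hid)) {
      v <- -net$b1[j]
      for (i in seq_len(ncol(x))) v <- v + net$W1[j, i] * x[p, i]
      hid[j] <- tf(v)
    }
    for (k in seq_along(net$b2)) {
      v <- -net$b2[k]
      for (j in seq_along(hid)) v <- v + net$W2[k, j] * hid[j]
      o <- if (net$transfer == "tanh") (tanh(v) + 1) / 2 else tf(v)
      total <- total + (d[p, k] - o)^2
    }
  }
  total / 2
}

# central finite differences of the objective with respect to every parameter
finite_diff_gradients <- function(net, x, d, h = 1e-5) {
  perturb <- function(getter, setter) {
    w <- getter(net)
    g <- w
    for (i in seq_along(w)) {
      wp <- w; wp[i] <- wp[i] + h
      wm <- w; wm[i] <- wm[i] - h
      g[i] <- (mlp_mse(setter(net, wp), x, d) - mlp_mse(setter(net, wm), x, d)) / (2 * h)
    }
    g
  }
  list(
    W1 = perturb(function(n) n$W1, function(n, w) { n$W1 <- w; n }),
    b1 = perturb(function(n) n$b1, function(n, w) { n$b1 <- w; n }),
    W2 = perturb(function(n) n$W2, function(n, w) { n$W2 <- w; n }),
    b2 = perturb(function(n) n$b2, function(n, w) { n$b2 <- w; n })
  )
}

random_net <- function(n_in, n_hidden, n_out, seed, transfer = "sigmoid") {
  net <- skelwatch:::mlp_init(n_in, n_hidden, n_out, transfer, seed, 0.5)
  net$levels <- paste0("c", seq_len(n_out))
  net
}

random_patterns <- function(n, n_in, n_out, seed) {
  set.seed(seed)
  x <- matrix(runif(n * n_in), n)
  d <- diag(n_out)[sample(n_out, n, replace = TRUE), , drop = FALSE]
  list(x = x, d = d)
}

# small trained upper-body bundle shared across detector/monitor tests,
# built once per test run
shared_cache <- new.env(parent = emptyenv())

small_upper_bundle <- function() {
  if (is.null(shared_cache$upper)) {
    tr <- generate_dataset(upper_postures(), 250, seed = 101)
    shared_cache$upper <- build_upper_classifier(tr, max_epochs = 12000, seed = 102)
  }
  shared_cache$upper
}

small_lower_bundle <- function() {
  if (is.null(shared_cache$lower)) {
    tr <- generate_dataset(lower_postures(), 160, seed = 103)
    shared_cache$lower <- build_lower_classifier(tr, max_epochs = 8000, seed = 104)
  }
  shared_cache$lower
}

small_fall_bundle <- function() {
  if (is.null(shared_cache$fall)) {
    ds <- generate_fall_dataset(200, 200, seed = 105)
    shared_cache$fall <- build_fall_classifier(ds, max_epochs = 8000, seed = 106)
  }
  shared_cache$fall
}
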