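## shared test fixtures: tiny grids, toy models, independent oracles, and
## a cache so expensive trained models are built once per test run

fine_grid <- function(n = 20001, lo = 2, hi = 4, freq = 400)
  nmr_grid(lo, hi, n, freq)

## hand-built linear "network": identity activation, one hidden layer
## whose composition is a known affine map
toy_linear_model <- function(W1, b1, W2, b2, norm_constant = 1) {
  spec <- model_spec(n_in = nrow(W1), hidden = ncol(W1),
                     n_out = ncol(W2), activation = "identity", seed = 1)
  m <- init_model(spec)
  m$W <- list(W1, W2)
  m$b <- list(b1, b2)
  m$norm_constant <- norm_constant
  m
}

## small random ReLU net with reproducible weights
toy_relu_model <- function(n_in = 20, h = 12, n_out = 3, seed = 42,
                           scale = 1) {
  m <- init_model(model_spec(n_in, h, n_out, "relu", seed = seed))
  m$W <- lapply(m$W, function(w) w * scale)
  m
}

## minimal baseline object for toy models on abstract grids
toy_baseline <- function(x, grid = nmr_grid(0, 1, length(x), 400)) {
  structure(list(x = x, grid = grid, description = "toy", ref_conc = 0,
                 seed = NULL),
            class = "ig_baseline")
}

## independent forward pass (plain loops, no package internals)
oracle_forward <- function(model, x) {
  a <- x
  L <- length(model$W)
  for (l in seq_len(L - 1)) {
    z <- as.numeric(t(model$W[[l]]) %*% a) + model$b[[l]]
    a <- if (model$spec$activation == "relu") pmax(z, 0) else z
  }
  as.numeric(t(model$W[[L]]) %*% a) + model$b[[L]]
}

## central finite-difference gradient of one output node
fd_gradient <- function(model, x, node, idx = seq_along(x), h = 1e-4) {
  vapply(idx, function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (oracle_forward(model, xp)[node] - oracle_forward(model, xm)[node]) /
      (2 * h)
  }, numeric(1))
}

## dense Riemann-sum integrated-gradients oracle: chunked loop over steps
## with an analytically computed single-hidden-layer ReLU gradient,
## written independently of the package's shared-path implementation
oracle_ig <- function(model, x, xp, node, m = 1e5) {
  stopifnot(length(model$W) == 2, model$spec$activation == "relu")
  W1 <- model$W[[1]]; b1 <- model$b[[1]]
  w2 <- model$W[[2]][, node]
  acc <- numeric(length(x))
  chunk <- 10000L
  for (i0 in seq(1L, m, by = chunk)) {
    ks <- i0:min(i0 + chunk - 1L, m)
    for (k in ks) {
      xi <- xp + (k / m) * (x - xp)
      z <- as.numeric(t(W1) %*% xi) + b1
      acc <- acc + as.numeric(W1 %*% ((z > 0) * w2))
    }
  }
  (x - xp) * acc / m
}

## expensive trained desk-scale models, built once and reused across
## test files (testthat keeps helper environments alive for the run)
.model_cache <- new.env(parent = emptyenv())

cached_study <- function(what = c("sim", "exp"), scale = "desk") {
  what <- match.arg(what)
  key <- paste(what, scale, sep = "_")
  if (!exists(key, envir = .model_cache)) {
    cfg <- experiment_config(scale, seed = 1)
    recipe <- if (what == "sim") "simulated" else "experimental_like"
    ds <- nmrxai:::.study_dataset(cfg, recipe)
    model <- nmrxai:::.study_model(cfg, ds, recipe)
    assign(key, list(config = cfg, dataset = ds, model = model),
           envir = .model_cache)
  }
  get(key, envir = .model_cache)
}
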