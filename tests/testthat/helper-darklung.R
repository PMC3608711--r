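# shared fixtures: built in code, cached per test run

# small, fast phantom configuration for unit tests
small_params <- function(...) {
  args <- utils::modifyList(
    list(image_height = 64, image_width = 64,
         n_projections = 2, n_per_group = 1),
    list(...))
  do.call(phantom_params, args)
}

# independent sinusoid-fit oracle: direct least squares via optim
ls_sine_fit <- function(y, fr) {
  obj <- function(par)
    sum((y - par[1] * (1 + par[2] * cos(2 * pi * fr + par[3])))^2)
  fit <- stats::optim(c(a0 = mean(y), v = 0.2, ph = 0.1), obj,
                      method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 2000))
  fit$par
}

# build an ideal single-harmonic stepping scan from per-pixel (a0, v, phi)
sine_scan <- function(a0, v, phi = 0, n_steps = 16, is_reference = FALSE) {
  a0 <- as.matrix(a0)
  if (length(v) == 1) v <- matrix(v, nrow(a0), ncol(a0))
  if (length(phi) == 1) phi <- matrix(phi, nrow(a0), ncol(a0))
  fr <- (seq_len(n_steps) - 1) / n_steps
  frames <- array(0, c(nrow(a0), ncol(a0), n_steps))
  for (k in seq_len(n_steps))
    frames[, , k] <- a0 * (1 + v * cos(2 * pi * fr[k] + phi))
  step_scan(frames, fr, is_reference = is_reference)
}

# default full-scale pipeline run, computed once and shared across tests
.run_cache <- new.env(parent = emptyenv())
default_run <- function(seed = 0) {
  key <- paste0("run", seed)
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- run_pipeline(default_config(seed = seed))
  .run_cache[[key]]
}
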