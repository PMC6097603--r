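# shared short-horizon scenarios used across test files

reference_pair <- function(t_end = 400, t_burn = 50, ...) {
  rotor_params(N = 2L, h = 4.2e-6, t_end = t_end, t_burn = t_burn, ...)
}

# a synthetic trajectory tibble with prescribed phase columns
make_traj <- function(time, phi, rho = NULL, params = NULL) {
  phi <- as.matrix(phi)
  N <- ncol(phi)
  if (is.null(rho)) rho <- matrix(1.59e-6, nrow(phi), N)
  df <- tibble::as_tibble(as.data.frame(cbind(time, phi, rho)))
  names(df) <- c("time", paste0("phi_", seq_len(N) - 1L),
                 paste0("rho_", seq_len(N) - 1L))
  if (!is.null(params)) attr(df, "params") <- params
  class(df) <- c("rotor_trajectory", class(df))
  df
}

# constant-frequency synthetic chain: phi_i(t) = w_i * t + offset_i
make_linear_traj <- function(t_end = 50, dt = 0.01, w = c(7, 7), offset = 0) {
  time <- seq(0, t_end, by = dt)
  offset <- rep_len(offset, length(w))
  make_traj(time, sweep(outer(time, w), 2, offset, `+`))
}
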