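#' Write a trajectory to CSV with a JSON parameter sidecar
#'
#' The trajectory table (`time`, `phi_*`, `rho_*`) is written as plain CSV
#' and the generating parameters as `<path>.json`, so a run is fully
#' reproducible from its files.
#'
#' @param traj A `rotor_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  readr::write_csv(tibble::as_tibble(traj), path)
  p <- attr(traj, "params")
  if (!is.null(p)) {
    jsonlite::write_json(unclass(p), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV path; `<path>.json` is read as parameters if present.
#' @return A `rotor_trajectory` tibble.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  res <- readr::read_csv(path, show_col_types = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    p <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    params <- rotor_params(
      a = p$a, R = p$R, ell = p$ell, h = p$h, mu = p$mu,
      lambda = p$lambda, F_dr = p$F_dr, D = p$D, N = p$N,
      truncation = p$truncation, t_end = p$t_end, t_burn = p$t_burn,
      seed = p$seed, experimental_lambda = p$experimental_lambda,
      gamma = p$gamma, samples_per_period = p$samples_per_period,
      rtol = p$rtol, atol = p$atol)
    attr(res, "params") <- params
  }
  class(res) <- c("rotor_trajectory", class(res))
  res
}

# read a YAML or JSON config file into a rotor_params object; entries not
# named are left at their defaults
read_params_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    y <- yaml::read_yaml(path)
    # YAML 1.1 reads a bare key `N` as the boolean FALSE; restore it
    names(y)[names(y) == "FALSE"] <- "N"
    y
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(rotor_params))
  extra <- setdiff(names(cfg), c(known, "sweep", "pair_scan"))
  if (length(extra))
    stop("unknown config entries: ", paste(extra, collapse = ", "),
         call. = FALSE)
  params <- do.call(rotor_params, cfg[intersect(names(cfg), known)])
  attr(params, "config") <- cfg
  params
}
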