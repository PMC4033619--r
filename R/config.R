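#' Resolved run configuration
#'
#' One flat bundle of every tunable setting: data generation (layout and
#' stimulus), actor (hidden size, init width, learning rates, confidence
#' rule), study grids and sizes, and the master seed. Unknown keys are
#' rejected, so config files cannot silently misspell a setting. The
#' resolved configuration (and its hash) is serialized beside every output
#' for provenance.
#'
#' @param ... Overrides of the defaults, by name.
#' @return An object of class `run_config`.
#' @export
#' @examples
#' run_config(n_sims = 50, accuracy_grid = c(0.5, 1.0))
run_config <- function(...) {
  defaults <- list(
    # data generation
    n_tuned_1 = 20, n_tuned_2 = 20, n_untuned = 20,
    dt = 0.5, trial_duration = 2000, base_stimulus = 1, current_gain = 10,
    background_current_sd = 1,
    noise_fraction = 0, noise_mean = 0.6, noise_sd = 0.2,
    # actor
    n_hidden = 5, n_actions = 2, w0 = 0.1,
    mu_plus = 0.005, mu_minus = 0.005,
    confidence_rule = "literal", gate = 0.5,
    # study
    accuracy_grid = seq(0.5, 1, by = 0.1),
    noise_grid = seq(0, 1, by = 0.1),
    modes = c("plain", "confidence"),
    n_sims = 200, n_trials = 100, pooled = TRUE, pool_size = 300,
    alpha = 0.001, stability_windows = c(50, 30),
    master_seed = 1
  )
  overrides <- list(...)
  if (length(overrides) > 0 && (is.null(names(overrides)) ||
                                any(names(overrides) == "")))
    stop("all configuration overrides must be named")
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  defaults[names(overrides)] <- overrides
  validate_run_config(structure(defaults, class = "run_config"))
}

validate_run_config <- function(config) {
  with(config, {
    if (noise_fraction < 0 || noise_fraction > 1)
      stop("'noise_fraction' must lie in [0, 1]")
    if (dt <= 0 || trial_duration <= 0)
      stop("'dt' and 'trial_duration' must be positive")
    if (any(accuracy_grid < 0 | accuracy_grid > 1))
      stop("'accuracy_grid' values must lie in [0, 1]")
    if (!all(modes %in% c("plain", "confidence")))
      stop("'modes' must be a subset of {plain, confidence}")
    if (!confidence_rule %in% c("literal", "gated"))
      stop("'confidence_rule' must be 'literal' or 'gated'")
    if (n_sims < 1 || n_trials < 1) stop("'n_sims'/'n_trials' must be >= 1")
  })
  config
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) cat(sprintf("  %s: %s\n", k,
                                  paste(x[[k]], collapse = " ")))
  invisible(x)
}

#' Read / write a run configuration as YAML
#'
#' The file is a flat key-value YAML document; keys missing from the file
#' keep their defaults, unknown keys are rejected.
#'
#' @param path File path.
#' @return `read_run_config` returns a validated [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# helpers mapping a run_config onto the module-level settings
config_layout <- function(config)
  ensemble_layout(config$n_tuned_1, config$n_tuned_2, config$n_untuned)

config_stimulus <- function(config)
  stimulus_config(dt = config$dt, trial_duration = config$trial_duration,
                  base_stimulus = config$base_stimulus,
                  current_gain = config$current_gain,
                  background_current_sd = config$background_current_sd,
                  noise_fraction = config$noise_fraction,
                  noise_mean = config$noise_mean,
                  noise_sd = config$noise_sd)

#' Deterministic configuration hash
#'
#' 64-bit FNV-1a hash of the deparsed configuration, as a fixed-length hex
#' string. Used to stamp outputs so that equal hashes imply equal resolved
#' settings.
#'
#' @param config Any R object (normally a [run_config()] or a study config
#'   list).
#' @return A 16-character hex string.
#' @export
config_hash <- function(config) {
  txt <- paste(deparse(config, control = c("keepNA", "keepInteger")),
               collapse = "")
  bytes <- utf8ToInt(txt)
  # FNV-1a over 64 bits, carried as two 32-bit halves to stay in doubles
  lo <- 0x84222325; hi <- 0xcbf29ce4
  p_lo <- 0x1b3; p_hi <- 0x100  # FNV prime 0x100000001b3
  for (b in bytes) {
    # xor into the low byte only (inputs are UTF-8 code points < 2^21;
    # fold larger ones into a byte first)
    b8 <- b %% 256
    low8 <- lo %% 256
    lo <- lo - low8 + bitwXor(as.integer(low8), as.integer(b8))
    # (hi,lo) * prime mod 2^64, in 16-bit limbs
    a0 <- lo %% 65536; a1 <- lo %/% 65536
    a2 <- hi %% 65536; a3 <- hi %/% 65536
    r0 <- a0 * p_lo
    r1 <- a1 * p_lo + a0 * p_hi
    r2 <- a2 * p_lo + a1 * p_hi
    r3 <- a3 * p_lo + a2 * p_hi
    c0 <- r0 %% 65536; carry <- r0 %/% 65536
    c1 <- (r1 + carry) %% 65536; carry <- (r1 + carry) %/% 65536
    c2 <- (r2 + carry) %% 65536; carry <- (r2 + carry) %/% 65536
    c3 <- (r3 + carry) %% 65536
    lo <- c0 + c1 * 65536
    hi <- c2 + c3 * 65536
  }
  sprintf("%04x%04x%04x%04x",
          as.integer(hi %/% 65536), as.integer(hi %% 65536),
          as.integer(lo %/% 65536), as.integer(lo %% 65536))
}
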