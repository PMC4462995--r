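# Plain-text interchange formats.  All files are tab-separated with one
# header line; times are milliseconds with 6 decimal places; neuron ids are
# 0-based on disk (1-based inside R).

fmt_ms <- function(x) sprintf("%.6f", x)

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an event log
#'
#' Tab-separated `time_ms` (6 decimals), `neuron_id` (0-based), `kind`.
#'
#' @param log An `event_log` from [simulate_network()].
#' @param path File path.
#' @return `write_event_log()` returns `path` invisibly;
#'   `read_event_log()` returns an `event_log` data frame.
#' @export
write_event_log <- function(log, path) {
  write_tsv(data.frame(time_ms = fmt_ms(log$time_ms),
                       neuron_id = log$neuron - 1L,
                       kind = as.character(log$kind)), path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  df <- read.delim(path, colClasses = c("numeric", "integer", "character"))
  kinds <- c("stimulus", "crossing", "spike", "failure")
  out <- data.frame(time_ms = df$time_ms, neuron = df$neuron_id + 1L,
                    kind = factor(df$kind, levels = kinds))
  class(out) <- c("event_log", "data.frame")
  out
}

#' Write / read a stimulus schedule
#'
#' Tab-separated `neuron_id` (0-based), `time_ms`, `strength`.
#'
#' @param schedule A `stimulus_schedule`.
#' @param path File path.
#' @export
write_schedule <- function(schedule, path) {
  write_tsv(data.frame(neuron_id = schedule$neuron - 1L,
                       time_ms = fmt_ms(schedule$time_ms),
                       strength = schedule$strength), path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- read.delim(path)
  as_schedule(data.frame(neuron = df$neuron_id + 1L, time_ms = df$time_ms,
                         strength = df$strength))
}

#' Write / read a network topology
#'
#' Two tab-separated files: an edge list (`pre_id`, `post_id`, `weight`,
#' `delay_ms`; 0-based ids) and a neuron table (`id`, `tau_c_ms`, `alpha`).
#' The membrane constant is not serialized and is restored at its default
#' on read.
#'
#' @param topology A [build_topology()] object.
#' @param edge_path,neuron_path File paths.
#' @param tau_m Membrane constant assigned on read, ms.
#' @export
write_topology <- function(topology, edge_path, neuron_path) {
  write_tsv(data.frame(pre_id = topology$edges$pre - 1L,
                       post_id = topology$edges$post - 1L,
                       weight = topology$edges$weight,
                       delay_ms = fmt_ms(topology$edges$delay_ms)),
            edge_path)
  write_tsv(data.frame(id = topology$neurons$id - 1L,
                       tau_c_ms = fmt_ms(topology$neurons$tau_c_ms),
                       alpha = topology$neurons$alpha), neuron_path)
  invisible(c(edge_path, neuron_path))
}

#' @rdname write_topology
#' @export
read_topology <- function(edge_path, neuron_path, tau_m = 20) {
  e <- read.delim(edge_path)
  nr <- read.delim(neuron_path)
  nr <- nr[order(nr$id), ]
  n <- nrow(nr)
  edges <- data.frame(pre = e$pre_id + 1L, post = e$post_id + 1L,
                      weight = e$weight, delay_ms = e$delay_ms)
  neurons <- data.frame(id = nr$id + 1L, tau_c_ms = nr$tau_c_ms,
                        fc_hz = 1000 / nr$tau_c_ms, alpha = nr$alpha,
                        tau_m = tau_m)
  structure(list(n = n, edges = edges, neurons = neurons,
                 params = list(fc_mode = "custom",
                               delay_range = range(edges$delay_ms))),
            class = "network_topology")
}

#' Write / read a latency trace
#'
#' Tab-separated `stim_index`, `time_ms`, `latency_ms` (`NA` marks a
#' response failure).
#'
#' @param trace Data frame with `stim_index`, `time_ms`, `latency_ms`.
#' @param path File path.
#' @export
write_latency_trace <- function(trace, path) {
  write_tsv(data.frame(stim_index = trace$stim_index,
                       time_ms = fmt_ms(trace$time_ms),
                       latency_ms = ifelse(is.na(trace$latency_ms), "NA",
                                           fmt_ms(trace$latency_ms))), path)
}

#' @rdname write_latency_trace
#' @export
read_latency_trace <- function(path) {
  df <- read.delim(path, na.strings = "NA")
  data.frame(stim_index = df$stim_index, time_ms = df$time_ms,
             latency_ms = as.numeric(df$latency_ms))
}

#' Write / read a stimulus train
#'
#' Tab-separated `stim_index`, `lag_ms`.
#'
#' @param train A [make_stimulus_train()] object.
#' @param path File path.
#' @export
write_stimulus_train <- function(train, path) {
  write_tsv(data.frame(stim_index = seq_along(train$lags),
                       lag_ms = fmt_ms(train$lags)), path)
}

#' @rdname write_stimulus_train
#' @export
read_stimulus_train <- function(path) {
  df <- read.delim(path)
  make_stimulus_train("custom", custom_lags = df$lag_ms[order(df$stim_index)])
}

#' Write a firing-rate histogram
#'
#' CSV with `bin_low_hz`, `count`.
#'
#' @param hist A [firing_rate_histogram()] object.
#' @param path File path.
#' @export
write_rate_histogram <- function(hist, path) {
  utils::write.csv(data.frame(bin_low_hz = hist$bin_low_hz,
                              count = hist$counts),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run-metadata sidecar
#'
#' Writes `key = value` lines recording the seed, a digest of the
#' configuration, and the package version, so a run can be re-identified
#' and reproduced.
#'
#' @param path File path.
#' @param seed Integer seed of the run.
#' @param config Configuration list.
#' @export
write_run_sidecar <- function(path, seed, config) {
  lines <- c(sprintf("seed = %d", as.integer(seed)),
             sprintf("config_hash = %s", config_digest(config)),
             sprintf("package_version = %s",
                     as.character(utils::packageVersion("impednet"))),
             sprintf("written = %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  writeLines(lines, path)
  invisible(path)
}

# FNV-1a over the deparsed configuration, reported as 8 hex digits; cheap
# and dependency-free, sufficient to flag config drift between runs.
# The xor touches only the low byte, so it is carried out on doubles
# without 32-bit integer overflow.
config_digest <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Default run configuration
#'
#' The nested configuration consumed by [read_run_config()] and the
#' command-line interface.  The network size is keyed `n_neurons` (a bare
#' `n` is a boolean in YAML 1.1 and would silently change its own key).
#' Defaults are the prototypical simulation
#' constants: 2000 neurons, supplemental-connection probability 0.1/N,
#' two-point critical frequencies 6.66/14.28 Hz, forgetting exponent 1.4,
#' delays uniform on 6-9.5 ms, connection strength 2, integration step
#' 0.05 ms, 60 s duration, and the 4-59 s rate window at 0.5 Hz bins.
#'
#' @return A nested list with sections `network`, `engine`, `init`,
#'   `spontaneous`, `histogram`, `output`.
#' @export
default_run_config <- function() {
  list(
    network = list(n_neurons = 2000, extra_per_n = 0.1, fc_mode = "two_point",
                   fc_values = c(6.66, 14.28), p_sub = 0, j_sub = 0,
                   alpha = 1.4, delay_min = 6, delay_max = 9.5, j = 2,
                   tau_m = 20),
    engine = list(dt = 0.05, duration_ms = 60000, extra_failure_c = 0,
                  seed = 1),
    init = list(rate_hz = 50, survival_tau_ms = 200, horizon_ms = 1000,
                strength = 2),
    spontaneous = list(per_step_probability = 0, strength = 2),
    histogram = list(window_ms = c(4000, 59000), bin_hz = 0.5),
    output = list(dir = ".", prefix = "run"))
}

#' Read and validate a run configuration
#'
#' Reads a hierarchical configuration from YAML (`.yml`/`.yaml`) or JSON
#' (`.json`), fills unspecified entries from [default_run_config()], and
#' rejects unknown keys with an error naming the offending dotted key.
#'
#' @param path Configuration file path, or `NULL` for pure defaults.
#' @return A validated configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  ext <- tolower(tools::file_ext(path))
  user <- switch(ext,
    yml = , yaml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported configuration format: .", ext))
  validate_config_keys(user, cfg, prefix = "")
  modifyList(cfg, user)
}

validate_config_keys <- function(user, template, prefix) {
  for (k in names(user)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", k) else k
    if (!k %in% names(template))
      stop("unknown configuration key: ", full, call. = FALSE)
    if (is.list(user[[k]]) && is.list(template[[k]]))
      validate_config_keys(user[[k]], template[[k]], full)
  }
  invisible(TRUE)
}

#' Named experiment presets
#'
#' Returns the configuration of the published network experiments as
#' arguments for [run_experiment()].  Presets: `"two_point"` (f_C of 6.66
#' or 14.28 Hz with equal probability), `"uniform"` (f_C uniform on that
#' range), `"extra_failure"` (two-point plus a baseline failure
#' probability C = 0.07 at all frequencies), `"spontaneous"` (two-point
#' plus ~1 Hz spontaneous stimulation per neuron),
#' `"subthreshold_sparse"` (uniform f_C plus on average 3 sub-threshold
#' out-connections of weight 0.4 per neuron) and `"subthreshold_dense"`
#' (uniform f_C plus 0.1 N sub-threshold out-connections of weight 12/N;
#' both preserve total sub-threshold out-strength 1.2).
#'
#' @param name Preset name.
#' @param n Network size.
#' @param ... Overrides passed through to [run_experiment()] (e.g.
#'   `alpha`, `p_extra`, `duration_ms`, `seed`).
#' @return A named list of [run_experiment()] arguments.
#' @examples
#' args <- experiment_preset("uniform", n = 200, alpha = 1.1,
#'                           duration_ms = 5000)
#' run <- do.call(run_experiment, c(args, list(seed = 1)))
#' @export
experiment_preset <- function(name = c("two_point", "uniform",
                                       "extra_failure", "spontaneous",
                                       "subthreshold_sparse",
                                       "subthreshold_dense"),
                              n = 2000, ...) {
  name <- match.arg(name)
  base <- list(n = n, p_extra = 0.1 / n)
  extra <- switch(name,
    two_point = list(fc_mode = "two_point"),
    uniform = list(fc_mode = "uniform"),
    extra_failure = list(fc_mode = "two_point", extra_failure_c = 0.07),
    spontaneous = list(fc_mode = "two_point", spontaneous_p = 5e-5),
    subthreshold_sparse = list(fc_mode = "uniform", p_sub = 3 / n,
                               j_sub = 0.4),
    subthreshold_dense = list(fc_mode = "uniform", p_sub = 0.1,
                              j_sub = 12 / n))
  modifyList(c(base, extra), list(...))
}
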