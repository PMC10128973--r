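# Configuration, serialization and the staged pipeline entry point. All
# physical quantities are in units of J (energies, rates) and 1/J
# (times). One master seed deterministically derives every
# per-trajectory seed, so re-running a config byte-reproduces all
# outputs.

#' Assemble a run configuration
#'
#' @param spec a [network_spec()]
#' @param numerosities template levels
#' @param n_traj trajectories per template
#' @param angle_mode stimulus angle mode (see [protocol_spec()])
#' @param total_angle constant-energy total (used by that mode only)
#' @param stim_window stimulus window
#' @param window recording window
#' @param dt recording step
#' @param refs reference numerosities for psychophysics
#' @param n_trials 2AFC trials per level
#' @param seed master seed
#' @return object of class `run_config` (fully JSON-serializable)
#' @export
run_config <- function(spec, numerosities = NULL, n_traj = 20,
                       angle_mode = "random_rotation",
                       total_angle = 3 * pi,
                       stim_window = c(0, 10), window = c(10, 20),
                       dt = 0.02, refs = NULL, n_trials = 40, seed = 1) {
  stopifnot(inherits(spec, "network_spec"))
  if (is.null(numerosities)) numerosities <- seq_len(spec$n_sites %/% 2)
  if (is.null(refs))
    refs <- intersect(2:4, numerosities)
  structure(list(spec = spec, numerosities = numerosities,
                 n_traj = n_traj, angle_mode = angle_mode,
                 total_angle = total_angle, stim_window = stim_window,
                 window = window, dt = dt, refs = refs,
                 n_trials = n_trials, seed = seed),
            class = "run_config")
}

#' Serialize / restore a run configuration
#' @param config a [run_config()]
#' @return JSON string / `run_config`
#' @export
config_to_json <- function(config) {
  x <- unclass(config)
  x$spec <- jsonlite::fromJSON(spec_to_json(config$spec))
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
}

#' @rdname config_to_json
#' @param json JSON produced by [config_to_json()]
#' @export
config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  sp <- x$spec
  spec <- network_spec(n_sites = sp$n_sites, connectivity = sp$connectivity,
                       J = sp$J, delta0 = sp$delta0,
                       sigma_int = sp$sigma_int,
                       gamma_loss = sp$gamma_loss,
                       gamma_dephase = sp$gamma_dephase,
                       adjacency = sp$adjacency)
  run_config(spec, numerosities = x$numerosities, n_traj = x$n_traj,
             angle_mode = x$angle_mode, total_angle = x$total_angle,
             stim_window = x$stim_window, window = x$window, dt = x$dt,
             refs = x$refs, n_trials = x$n_trials, seed = x$seed)
}

protocol_from_config <- function(config) {
  force(config)
  function(N) protocol_spec(N, window = config$stim_window,
                            angle_mode = config$angle_mode,
                            total_angle = config$total_angle)
}

#' Write / read a trajectory record as CSV + JSON sidecar
#'
#' CSV columns: time, site_1 .. site_M. The sidecar (same path with
#' extension `.json`) carries the network spec, events and seed.
#'
#' @param record a `trajectory_record`
#' @param path CSV path
#' @return `write_record`: the path, invisibly; `read_record`: a
#'   `trajectory_record`
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "trajectory_record"))
  df <- data.frame(time = record$times, t(record$mag))
  names(df) <- c("time", paste0("site_", seq_len(nrow(record$mag))))
  write.csv(df, path, row.names = FALSE)
  sidecar <- list(
    spec = if (!is.null(record$spec))
      jsonlite::fromJSON(spec_to_json(record$spec)),
    events = if (!is.null(record$events) && nrow(record$events))
      record$events,
    seed = record$seed, n_jumps = record$n_jumps)
  jsonlite::write_json(sidecar, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  df <- read.csv(path)
  mag <- t(as.matrix(df[, -1, drop = FALSE]))
  side_path <- sub("\\.csv$", ".json", path)
  events <- NULL; spec <- NULL; seed <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::fromJSON(side_path)
    if (!is.null(side$spec))
      spec <- spec_from_json(jsonlite::toJSON(side$spec,
                                              auto_unbox = TRUE,
                                              digits = NA))
    if (!is.null(side$events)) events <- as.data.frame(side$events)
    seed <- side$seed
  }
  new_trajectory_record(df$time, mag, events = events, spec = spec,
                        seed = seed)
}

#' Write / read a template library as JSON
#'
#' Stores the frequency grid, the per-numerosity amplitude arrays and a
#' provenance block (network spec, trajectory count, seed).
#'
#' @param library a `template_library`
#' @param path JSON path
#' @return path / `template_library`
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "template_library"))
  x <- list(freq = library$freq,
            numerosities = library$numerosities,
            templates = library$templates,
            provenance = list(
              n_traj = library$n_traj, seed = library$seed,
              window = library$window, dt = library$dt,
              spec = if (!is.null(library$spec))
                jsonlite::fromJSON(spec_to_json(library$spec))))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  x <- jsonlite::fromJSON(path)
  templates <- as.matrix(x$templates)
  colnames(templates) <- x$numerosities
  spec <- if (!is.null(x$provenance$spec))
    spec_from_json(jsonlite::toJSON(x$provenance$spec, auto_unbox = TRUE,
                                    digits = NA))
  structure(list(freq = x$freq, templates = templates,
                 numerosities = as.integer(x$numerosities),
                 n_traj = x$provenance$n_traj, spec = spec,
                 window = x$provenance$window, dt = x$provenance$dt,
                 seed = x$provenance$seed),
            class = "template_library")
}

#' Run a pipeline stage
#'
#' Stages: `"demo"` writes chain light-cone and all-to-all bounce
#' records for a single central flip; `"simulate"` one stimulus
#' realization per numerosity; `"templates"` the template library;
#' `"decode"` a decoded fresh probe per numerosity; `"psychometrics"`
#' 2AFC tables, Probit fits and Weber fractions; `"validate"` the
#' frequency-decoding control. Every stage writes CSV/JSON artifacts
#' with provenance into `out_dir`.
#'
#' @param config a [run_config()]
#' @param stage one of demo, simulate, templates, decode, psychometrics,
#'   validate
#' @param out_dir output directory (created if missing)
#' @return named list of the artifacts written (paths), invisibly
#' @export
run_pipeline <- function(config,
                         stage = c("demo", "simulate", "templates",
                                   "decode", "psychometrics", "validate"),
                         out_dir = ".") {
  stopifnot(inherits(config, "run_config"))
  stage <- match.arg(stage)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, paste0(...))
  proto <- protocol_from_config(config)
  out <- list()

  if (stage == "demo") {
    M <- config$spec$n_sites
    mid <- (M + 1) %/% 2
    times <- record_grid(c(0, config$window[2]), config$dt)
    ev <- stimulus_event(0, mid, pi)
    nn <- network_spec(M, "nearest_neighbour", J = config$spec$J)
    rec_nn <- evolve_trajectory(nn, ev, times)
    out$lightcone_csv <- write_record(rec_nn, p("demo_chain.csv"))
    lc <- lightcone_check(rec_nn, nn)
    write.csv(lc$arrival, p("demo_lightcone.csv"), row.names = FALSE)
    out$lightcone_table <- p("demo_lightcone.csv")
    aa <- network_spec(M, "all_to_all", J = config$spec$J)
    out$all_to_all_csv <- write_record(evolve_trajectory(aa, ev, times),
                                       p("demo_all_to_all.csv"))
    return(invisible(out))
  }

  if (stage == "simulate") {
    times <- record_grid(c(0, config$window[2]), config$dt)
    seeds <- with_seed(config$seed,
                       sample.int(.Machine$integer.max - 1,
                                  length(config$numerosities)))
    for (k in seq_along(config$numerosities)) {
      N <- config$numerosities[k]
      set.seed(seeds[k])
      ev <- sample_events(proto(N), config$spec)
      rec <- evolve_trajectory(config$spec, ev, times)
      rec$seed <- seeds[k]
      out[[paste0("record_N", N)]] <-
        write_record(rec, p("record_N", N, ".csv"))
    }
    return(invisible(out))
  }

  lib <- build_template_library(config$spec, config$numerosities,
                                n_traj = config$n_traj,
                                protocol_fun = proto,
                                window = config$window, dt = config$dt,
                                seed = config$seed)
  out$library <- write_library(lib, p("templates.json"))
  if (stage == "templates") return(invisible(out))

  if (stage == "decode") {
    pf <- quantum_probe_fun(config$spec, proto, config$window, config$dt)
    set.seed(config$seed + 1)
    res <- lapply(config$numerosities, function(N) {
      d <- decode_numerosity(pf(N), lib)
      list(true = N, decoded = d$decoded, tie = d$tie,
           correlations = as.list(d$correlations))
    })
    jsonlite::write_json(res, p("decode.json"), auto_unbox = TRUE,
                         digits = NA)
    out$decode <- p("decode.json")
    return(invisible(out))
  }

  if (stage == "psychometrics") {
    bank <- probe_bank(config$spec, config$numerosities,
                       n_draws = config$n_trials, protocol_fun = proto,
                       window = config$window, dt = config$dt,
                       seed = config$seed + 1)
    decoded <- decode_bank(bank, lib)
    fits <- list()
    for (r in config$refs) {
      pd <- bank_psychometrics(decoded, r, config$numerosities,
                               config$n_trials, seed = config$seed + r)
      write.csv(cbind(n_ref = r, as.data.frame(pd)),
                p("psychometric_N", r, ".csv"), row.names = FALSE)
      out[[paste0("table_N", r)]] <- p("psychometric_N", r, ".csv")
      fits[[as.character(r)]] <- fit_probit(pd)
    }
    wb <- if (length(config$refs) >= 2)
      suppressWarnings(weber_curve(fits, n_ref = config$refs))
    else data.frame(n_ref = config$refs,
                    sigma = fits[[1]]$sigma,
                    weber = fits[[1]]$sigma / config$refs)
    summary <- list(
      fits = lapply(fits, function(f)
        list(pse = f$pse, sigma = f$sigma, converged = f$converged)),
      weber = as.data.frame(wb),
      flatness = attr(wb, "flatness"))
    jsonlite::write_json(summary, p("psychometrics.json"),
                         auto_unbox = TRUE, digits = NA)
    out$summary <- p("psychometrics.json")
    return(invisible(out))
  }

  if (stage == "validate") {
    res <- frequency_decoding_experiment(noise = "one_over_f",
                                         n_probes = 10, Nt = 5,
                                         seed = config$seed)
    write.csv(as.data.frame(res), p("validate_one_over_f.csv"),
              row.names = FALSE)
    out$validate <- p("validate_one_over_f.csv")
    return(invisible(out))
  }
  invisible(out)
}
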