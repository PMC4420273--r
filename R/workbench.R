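# Configuration, seeding, serialization and the high-level run entry point
# tying the modules into reproducible experiments.

#' Default experiment configuration
#'
#' All tunable quantities of an experiment: connectivity scheme and sizes,
#' synaptic-strength table, protocol parameters and seeds.  Values default
#' to the reference physiological settings (e.g. ORN-to-mitral peak
#' conductance 6 nS).
#'
#' @return nested named list
#' @export
default_config <- function() {
  list(
    scheme = "default",
    n_lateral = 2L,
    seed = 1L,
    network = .default_net_opts(),
    synapses = as.data.frame(synapse_params()),
    protocol = list(trials = 8L, cycles = 2L, n_bins = 5L, conc = 1),
    scale = list(instances = 1L, trial_factor = 1)
  )
}

#' Load an experiment configuration
#'
#' Reads a YAML (or JSON) override file, validates every key against the
#' default configuration, and fills unset values with the defaults.
#'
#' @param path file path, or NULL for pure defaults
#' @return validated configuration list with attribute \code{hash}
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    ov <- if (grepl("[.]json$", path)) jsonlite::read_json(path,
                                                           simplifyVector = TRUE)
      else yaml::read_yaml(path)
    errs <- character()
    check <- function(ref, new, prefix = "") {
      for (k in names(new)) {
        if (!k %in% names(ref)) {
          errs <<- c(errs, paste0("unknown key: ", prefix, k))
        } else if (is.list(ref[[k]]) && !is.data.frame(ref[[k]]) &&
                   is.list(new[[k]])) {
          check(ref[[k]], new[[k]], paste0(prefix, k, "$"))
        }
      }
    }
    check(cfg, ov)
    if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)
    cfg <- utils::modifyList(cfg, ov)
  }
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

#' Serialize and hash a configuration
#' @param cfg configuration list
#' @export
config_hash <- function(cfg) {
  attr(cfg, "hash") <- NULL
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 12)
  # small polynomial rolling hash over the JSON text (no external digest
  # dependency); kept below 2^31 so integer arithmetic stays exact
  h <- 17
  for (b in utf8ToInt(js)) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Save a configuration to YAML
#' @param cfg configuration list
#' @param path output file
#' @export
save_config <- function(cfg, path) {
  attr(cfg, "hash") <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Expand a master seed into named streams
#'
#' One master seed deterministically yields separate structural,
#' dynamical and per-trial streams, all below 2^31.
#'
#' @param master master seed (integer)
#' @param stream \code{"structural"}, \code{"dynamical"} or \code{"trial"}
#' @param index trial index (for the trial stream)
#' @export
split_seed <- function(master, stream = c("structural", "dynamical",
                                          "trial"), index = 0L) {
  stream <- match.arg(stream)
  off <- switch(stream, structural = 1L, dynamical = 2L, trial = 3L)
  as.integer((as.double(master) * 2654435761 + off * 97561 + index * 1013) %%
               2147483629)
}

#' Save a protocol run to a directory
#'
#' Writes the network tables (cells, synapses), spike and binned-rate
#' tables as CSV, and a JSON metadata file carrying scheme, seeds, counts
#' and the configuration hash.
#'
#' @param run named list of data frames (e.g. \code{spikes},
#'   \code{binned}); non-data-frame entries are stored in the metadata
#' @param net the network instance
#' @param dir output directory (created)
#' @param config optional configuration (hash recorded)
#' @export
save_run <- function(run, net, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(scheme = net$scheme, seed = net$seed,
               n_lateral = net$n_lateral,
               n_granules = nrow(net$granules),
               aggregated = net$aggregated,
               schema_version = "1.0",
               config_hash = if (!is.null(config)) config_hash(config)
               else NA)
  tables <- character()
  for (nm in names(run)) {
    x <- run[[nm]]
    if (is.data.frame(x)) {
      write.csv(x, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
      tables <- c(tables, nm)
    } else {
      meta[[nm]] <- x
    }
  }
  meta$tables <- tables
  meta$checksums <- as.list(setNames(vapply(tables, function(nm) {
    f <- file.path(dir, paste0(nm, ".csv"))
    as.character(file.size(f))
  }, ""), tables))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write.csv(net$mitral, file.path(dir, "mitral.csv"), row.names = FALSE)
  invisible(dir)
}

#' Load a saved protocol run
#'
#' @param dir run directory written by [save_run()]
#' @return list of tables plus \code{meta}
#' @export
load_run <- function(dir) {
  mf <- file.path(dir, "meta.json")
  if (!file.exists(mf)) stop("not a run directory: ", dir, call. = FALSE)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  major <- strsplit(as.character(meta$schema_version), "[.]")[[1]][1]
  if (!identical(major, "1"))
    stop("incompatible run schema version: ", meta$schema_version,
         call. = FALSE)
  if (!identical(as.character(meta$schema_version), "1.0"))
    warning("run written by a newer minor schema (",
            meta$schema_version, "); loading anyway")
  out <- list(meta = meta)
  for (nm in meta$tables) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f) ||
        !identical(as.character(file.size(f)), meta$checksums[[nm]]))
      stop("run integrity check failed for table: ", nm, call. = FALSE)
    out[[nm]] <- as_tibble(read.csv(f))
  }
  out
}

#' High-level protocol runner
#'
#' Programmatic entry point composing the modules: builds (or reuses) an
#' instance, runs the requested protocol at the configured scale, and
#' optionally persists the outputs.
#'
#' @param protocol one of \code{"freely-breathing"}, \code{"linearity"},
#'   \code{"scaled-pulses"}, \code{"nerve-shock"}, \code{"adi-invitro"},
#'   \code{"adi-invivo"}, \code{"build-net"}
#' @param config configuration list from [load_config()]
#' @param out optional output directory for [save_run()]
#' @param ... protocol-specific overrides
#' @return the protocol result (invisibly if saved)
#' @export
bulbnet_run <- function(protocol, config = load_config(), out = NULL, ...) {
  seed <- config$seed
  res <- switch(protocol,
    "build-net" = {
      net <- build_network(config$scheme, config$n_lateral, seed = seed)
      aggregate_singles(net)
    },
    "freely-breathing" = {
      inst <- make_instance(seed, config$scheme, config$n_lateral)
      run_freely_breathing(inst, trials = config$protocol$trials,
                           conc = config$protocol$conc, ...)
    },
    "linearity" = {
      inst <- make_instance(seed, config$scheme, config$n_lateral)
      run_linearity_protocol(inst, conc = config$protocol$conc, ...)
    },
    "scaled-pulses" = {
      inst <- make_instance(seed, config$scheme, config$n_lateral)
      run_scaled_pulses(inst, ...)
    },
    "nerve-shock" = {
      inst <- make_instance(seed, config$scheme, 0)
      list(weak = run_nerve_shock(inst, "weak", seed = seed),
           strong = run_nerve_shock(inst, "strong", seed = seed))
    },
    "adi-invitro" = run_adi_invitro(base_seed = seed, ...),
    "adi-invivo" = run_adi_invivo(base_seed = seed, ...),
    stop("unknown protocol: ", protocol, call. = FALSE))
  if (!is.null(out) && protocol != "build-net") {
    run_tables <- Filter(is.data.frame, res)
    net <- if (exists("inst", inherits = FALSE)) inst$net else NULL
    if (!is.null(net)) save_run(run_tables, net, out, config)
  }
  res
}
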