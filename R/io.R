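# File formats and the pipeline driver. All tabular formats are plain CSV
# with a one-line header; capture histories are stored long-form
# (id, ring_year, year, code) with codes 0 = not seen, 1 = pre-breeder,
# 2 = breeder, 3 = skipper.

#' Write a study bundle to a directory
#'
#' Writes `counts.csv`, `histories.csv`, `reproduction.csv`, optionally
#' `patches.csv`, and a `meta.yaml` carrying the year range, the generating
#' seed (if known) and a hash of the generating configuration.
#'
#' @param study a `study` (or a list with the same stream elements).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(study$counts, file.path(dir, "counts.csv"), row.names = FALSE)
  write.csv(histories_to_long(study$histories),
            file.path(dir, "histories.csv"), row.names = FALSE)
  write.csv(study$reproduction, file.path(dir, "reproduction.csv"),
            row.names = FALSE)
  if (!is.null(study$patches)) {
    write.csv(study$patches, file.path(dir, "patches.csv"), row.names = FALSE)
  }
  cfg <- study$truth$config
  meta <- list(
    n_years = nrow(study$counts),
    years = c(1L, nrow(study$counts)),
    seed = if (!is.null(cfg)) cfg$seed else NA,
    config_hash = if (!is.null(cfg)) config_hash(unclass(cfg)) else NA
  )
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a study bundle from a directory
#'
#' Loads and validates the CSV streams written by [write_bundle] (or prepared
#' externally in the same schemas). Violations of the life-cycle invariants
#' -- non-positive counts, illegal status codes, breeder/skipper codes before
#' age 3, non-contiguous years -- raise typed validation errors.
#'
#' @param dir bundle directory.
#' @return list of class `study_bundle` with `counts`, `histories`,
#'   `reproduction`, `patches` (or `NULL`) and `meta`.
#' @export
read_bundle <- function(dir) {
  need <- file.path(dir, c("counts.csv", "histories.csv", "reproduction.csv"))
  for (f in need) {
    if (!file.exists(f)) bp_stop(sprintf("missing bundle file: %s", f))
  }
  counts <- read.csv(file.path(dir, "counts.csv"))
  if (!all(c("year", "count") %in% names(counts))) {
    bp_stop("counts.csv must have columns year, count")
  }
  if (any(counts$count <= 0)) bp_stop("non-positive count")
  if (!identical(sort(counts$year), seq(min(counts$year), max(counts$year)))) {
    bp_stop("count years must be contiguous")
  }
  # internal indexing is 1-based over the closed study window
  offset <- min(counts$year) - 1L
  counts$year <- counts$year - offset
  T <- max(counts$year)

  hl <- read.csv(file.path(dir, "histories.csv"))
  hl$year <- hl$year - offset
  hl$ring_year <- hl$ring_year - offset
  if (nrow(hl) > 0 && any(hl$year < 1L | hl$year > T)) {
    bp_stop("history year outside the study window")
  }
  histories <- histories_from_long(hl, T)

  repro <- read.csv(file.path(dir, "reproduction.csv"))
  if (!all(c("year", "category", "n_nests", "n_fledglings") %in% names(repro))) {
    bp_stop("reproduction.csv must have columns year, category, n_nests, n_fledglings")
  }
  repro$year <- repro$year - offset
  if (any(repro$n_fledglings > 0 & repro$n_nests == 0)) {
    bp_stop("fledglings recorded for a zero-nest cell")
  }

  patches <- NULL
  pfile <- file.path(dir, "patches.csv")
  if (file.exists(pfile)) {
    patches <- read.csv(pfile)
    patches$year <- patches$year - offset
  }
  meta <- if (file.exists(file.path(dir, "meta.yaml"))) {
    yaml::read_yaml(file.path(dir, "meta.yaml"))
  } else list(n_years = T)
  meta$year_offset <- offset

  structure(list(counts = counts, histories = histories,
                 reproduction = repro, patches = patches, meta = meta),
            class = "study_bundle")
}

#' Persist posterior draws as CSV
#'
#' One row per kept iteration with `chain` and `iteration` index columns;
#' a small `draws_meta.yaml` carries the layout needed to rebuild the
#' `posterior_draws` object.
#'
#' @param draws a `posterior_draws`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_draws <- function(draws, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- do.call(rbind, lapply(seq_along(draws$chains), function(ch) {
    m <- draws$chains[[ch]]
    cbind(chain = ch, iteration = seq_len(nrow(m)), m)
  }))
  write.csv(as.data.frame(tab), file.path(dir, "draws.csv"), row.names = FALSE)
  yaml::write_yaml(list(
    n_years = draws$n_years,
    time_varying = draws$time_varying,
    n_chains = length(draws$chains),
    seed = draws$config$seed,
    config_hash = config_hash(unclass(draws$config))
  ), file.path(dir, "draws_meta.yaml"))
  invisible(dir)
}

#' Read posterior draws written by [write_draws]
#'
#' @param dir directory holding `draws.csv` and `draws_meta.yaml`.
#' @return A `posterior_draws` object.
#' @export
read_draws <- function(dir) {
  tab <- read.csv(file.path(dir, "draws.csv"), check.names = FALSE)
  meta <- yaml::read_yaml(file.path(dir, "draws_meta.yaml"))
  chains <- lapply(sort(unique(tab$chain)), function(ch) {
    m <- as.matrix(tab[tab$chain == ch, setdiff(names(tab), c("chain", "iteration")),
                       drop = FALSE])
    rownames(m) <- NULL
    m
  })
  structure(list(chains = chains, accept = NULL,
                 n_years = meta$n_years, time_varying = meta$time_varying,
                 layout = NULL, prior = NULL,
                 config = list(seed = meta$seed)),
            class = "posterior_draws")
}

#' Run a pipeline step
#'
#' Dispatches the analysis stages over the package's functions:
#' \describe{
#'   \item{simulate}{generate a synthetic study and write it as a bundle;}
#'   \item{fit}{read a bundle, run the MCMC and write the draws;}
#'   \item{derive}{read draws and write the association tables;}
#'   \item{check-prereq}{run the heterogeneity prerequisite on a patch table;}
#'   \item{ppc}{posterior predictive checks of a fit against its bundle.}
#' }
#' Every stage writes a `log.yaml` with the seed, a configuration hash and
#' the runtime.
#'
#' @param command one of `simulate`, `fit`, `derive`, `check-prereq`, `ppc`.
#' @param config named list of stage options (see Details) or the path of a
#'   YAML file holding them.
#' @return The stage's main result, invisibly.
#' @details Options: `out` (output directory; all stages), `seed`,
#'   `n_years`, generator fields (simulate); `bundle`, `n_chains`,
#'   `n_iter`, `n_burnin`, `thin`, `time_varying` (fit); `draws` (derive,
#'   ppc); `patches` (check-prereq: CSV path or bundle directory).
#' @export
run_pipeline <- function(command, config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  t0 <- Sys.time()
  out <- config$out %||% "."
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)

  result <- switch(command,
    simulate = {
      keep <- intersect(names(config), names(formals(synthetic_config)))
      cfg <- do.call(synthetic_config, config[keep])
      study <- generate_study(cfg)
      write_bundle(study, out)
      study
    },
    fit = {
      if (is.null(config$bundle)) bp_stop("fit needs a 'bundle' directory")
      n_chains <- config$n_chains %||% 2L
      if (n_chains < 2L) {
        bp_stop("fit requires at least 2 chains (convergence diagnostics)")
      }
      bundle <- read_bundle(config$bundle)
      mc <- mcmc_config(n_chains = n_chains,
                        n_iter = config$n_iter %||% 3000L,
                        n_burnin = config$n_burnin %||% 1000L,
                        thin = config$thin %||% 2L,
                        seed = config$seed %||% 1L,
                        time_varying = config$time_varying %||% TRUE)
      draws <- run_mcmc(bundle, config = mc)
      write_draws(draws, out)
      write.csv(convergence_report(draws),
                file.path(out, "convergence.csv"), row.names = FALSE)
      draws
    },
    derive = {
      if (is.null(config$draws)) bp_stop("derive needs a 'draws' directory")
      draws <- read_draws(config$draws)
      tabs <- analysis_tables(draws)
      write.csv(tabs$growth, file.path(out, "growth_correlations.csv"),
                row.names = FALSE)
      write.csv(tabs$propensity, file.path(out, "propensity_correlations.csv"),
                row.names = FALSE)
      tabs
    },
    `check-prereq` = {
      if (is.null(config$patches)) bp_stop("check-prereq needs a 'patches' file")
      pf <- config$patches
      tab <- if (dir.exists(pf)) read.csv(file.path(pf, "patches.csv")) else read.csv(pf)
      chk <- prerequisite_check(tab)
      write.csv(chk$per_year, file.path(out, "heterogeneity_per_year.csv"),
                row.names = FALSE)
      yaml::write_yaml(list(correlation = chk$correlation,
                            n_years = chk$n_years),
                       file.path(out, "heterogeneity_summary.yaml"))
      chk
    },
    ppc = {
      if (is.null(config$draws) || is.null(config$bundle)) {
        bp_stop("ppc needs 'draws' and 'bundle' directories")
      }
      draws <- read_draws(config$draws)
      bundle <- read_bundle(config$bundle)
      ppc <- posterior_predictive_check(draws, bundle)
      yaml::write_yaml(list(p_counts = ppc$p_counts, p_repro = ppc$p_repro),
                       file.path(out, "ppc.yaml"))
      ppc
    },
    bp_stop(sprintf("unknown command '%s'", command), class = "bp_usage_error")
  )

  yaml::write_yaml(list(
    command = command,
    seed = config$seed %||% NA,
    config_hash = config_hash(config),
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    timestamp = format(t0, "%Y-%m-%d %H:%M:%S")
  ), file.path(out, "log.yaml"))
  invisible(result)
}
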