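# End-to-end orchestration: synthetic sampling or HILLS input -> FES ->
# partition statistic -> basins -> MFEP, with a machine-readable summary.

#' Assemble a pipeline configuration
#'
#' @param stages stages to run, in dependency order, from
#'   `c("simulate", "fes", "grnr", "minima", "mfep")`.  `fes` needs either
#'   `simulate` or a `hills_path`.
#' @param seed seed for the synthetic sampler.
#' @param hills_path optional HILLS file to analyse instead of sampling.
#' @param potential `"wildtype"` or `"d74e"` for the built-in two-basin
#'   landscapes, or a [potential_spec()].
#' @param sampler a [sampler_params()] (the seed is overridden by `seed`).
#' @param n_phi,n_theta FES grid size.
#' @param dialect,gamma hill-height dialect and bias factor for
#'   [reconstruct_fes()].
#' @param kT thermal energy for the partition statistic, kcal/mol.
#' @param grnr_mode `"boltzmann"` or `"minimum"`.
#' @param partition a [partition_spec()].
#' @param depth_threshold basin depth filter, kcal/mol.
#' @param outdir optional output directory for tables and the JSON summary.
#' @return a `run_config` list.
#' @export
run_config <- function(stages = c("simulate", "fes", "grnr", "minima", "mfep"),
                       seed = 1, hills_path = NULL, potential = "wildtype",
                       sampler = sampler_params(),
                       n_phi = 144, n_theta = 72,
                       dialect = "tempered", gamma = NULL,
                       kT = 0.596, grnr_mode = "boltzmann",
                       partition = partition_spec(),
                       depth_threshold = 0.5, outdir = NULL) {
  cfg <- mget(names(formals()))
  if (length(stages) == 0) abort("pipeline needs at least one stage")
  unknown <- setdiff(stages, c("simulate", "fes", "grnr", "minima", "mfep"))
  if (length(unknown) > 0) {
    abort(paste("unknown stage(s):", paste(unknown, collapse = ", ")))
  }
  if ("fes" %in% stages && !"simulate" %in% stages && is.null(hills_path)) {
    abort("the fes stage needs either the simulate stage or a hills_path")
  }
  structure(cfg, class = "run_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' The text form round-trips losslessly: built-in potentials by name,
#' custom [potential_spec()] objects by their term table and domain.
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `path` (writer) or a `run_config` (reader).
#' @export
write_run_config <- function(config, path) {
  if (!inherits(config, "run_config")) abort("config must come from run_config()")
  lst <- unclass(config)
  lst$partition <- unclass(config$partition)
  lst$sampler <- unclass(config$sampler)
  if (inherits(config$potential, "potential_spec")) {
    p <- config$potential
    lst$potential <- list(terms = as.list(p$terms), xlim = p$xlim,
                          ylim = p$ylim, cv_names = p$cv_names)
  }
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  partition <- do.call(partition_spec, lst$partition)
  sampler <- do.call(sampler_params, lst$sampler)
  potential <- lst$potential
  if (is.list(potential)) {
    potential <- potential_spec(as_tibble(potential$terms),
                                xlim = unlist(potential$xlim),
                                ylim = unlist(potential$ylim),
                                cv_names = unlist(potential$cv_names))
  }
  rest <- lst[setdiff(names(lst), c("partition", "sampler", "potential"))]
  do.call(run_config, c(rest, list(partition = partition, sampler = sampler,
                                   potential = potential)))
}

.resolve_potential <- function(potential) {
  if (inherits(potential, "potential_spec")) return(potential)
  switch(potential,
         wildtype = pucker_landscape(delta = -4),
         d74e = pucker_landscape(delta = 10),
         abort(sprintf("unknown built-in potential '%s'", potential)))
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order and returns all
#' stage outputs plus a compact summary (global-minimum conformer, the
#' reactive/nonreactive free-energy difference, activation and reaction
#' free energies).  When `config$outdir` is set, per-stage tables, the
#' JSON summary, and a MANIFEST of completed stages are written there;
#' partial outputs survive a failing stage.
#'
#' @param config a [run_config()].
#' @return invisible list with elements `hills`, `fes`, `minima`, `path`,
#'   and `summary`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) abort("config must come from run_config()")
  out <- list()
  summary <- list(seed = config$seed, dialect = config$dialect,
                  partition = list(phi = config$partition$phi,
                                   theta_b = config$partition$theta_b,
                                   inclusive_side = config$partition$inclusive_side))
  done <- character()
  emit <- function() {
    if (is.null(config$outdir)) return()
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    writeLines(done, file.path(config$outdir, "MANIFEST"))
    jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  if ("simulate" %in% config$stages) {
    pot <- .resolve_potential(config$potential)
    sp <- config$sampler
    sp$seed <- config$seed
    sim <- sample_wt_metad(pot, sp)
    out$hills <- sim$hills
    out$trajectory <- sim$trajectory
    summary$n_hills <- nrow(sim$hills)
    if (!is.null(config$outdir)) {
      dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
      write_hills(sim$hills, file.path(config$outdir, "HILLS"))
    }
    done <- c(done, "simulate"); emit()
  } else if (!is.null(config$hills_path)) {
    out$hills <- read_hills(config$hills_path)
    summary$n_hills <- nrow(out$hills)
  }

  if ("fes" %in% config$stages) {
    axes <- pucker_axes(config$n_phi, config$n_theta)
    out$fes <- reconstruct_fes(out$hills, axes, dialect = config$dialect,
                               gamma = config$gamma)
    summary$fes_range <- max(out$fes$values)
    summary$fes_range_exceeds_stop <- max(out$fes$values) > 14
    if (!is.null(config$outdir)) {
      write_fes(out$fes, file.path(config$outdir, "fes.dat"))
    }
    done <- c(done, "fes"); emit()
  }

  if ("grnr" %in% config$stages) {
    summary$delta_g_rnr <- delta_g_rnr(out$fes, config$partition,
                                       kT = config$kT, mode = config$grnr_mode)
    summary$delta_g_rnr_minimum <- delta_g_rnr(out$fes, config$partition,
                                               kT = config$kT, mode = "minimum")
    done <- c(done, "grnr"); emit()
  }

  if ("minima" %in% config$stages) {
    out$minima <- find_minima(out$fes, config$depth_threshold)
    if (nrow(out$minima) > 0) {
      cls <- classify_conformer(
        tibble(theta = rad2deg(out$minima$theta),
               phi = rad2deg(out$minima$phi)))
      out$minima$conformer <- cls$label
      out$minima$reactive <- is_reactive(
        tibble(theta = rad2deg(out$minima$theta),
               phi = rad2deg(out$minima$phi)), config$partition)
      summary$global_minimum_conformer <- out$minima$conformer[1]
      summary$global_minimum_reactive <- out$minima$reactive[1]
    }
    if (!is.null(config$outdir)) {
      readr::write_tsv(out$minima, file.path(config$outdir, "minima.tsv"))
    }
    done <- c(done, "minima"); emit()
  }

  if ("mfep" %in% config$stages) {
    if (is.null(out$minima) || nrow(out$minima) < 2) {
      abort("mfep stage needs at least two basins from the minima stage")
    }
    out$path <- find_mfep(out$fes, out$minima[1, ], out$minima[2, ])
    bar <- barrier_and_reaction_energy(out$path)
    summary$dg_activation <- bar$dg_activation
    summary$dg_reaction <- bar$dg_reaction
    if (!is.null(config$outdir)) {
      readr::write_tsv(as_tibble(out$path), file.path(config$outdir, "mfep.tsv"))
    }
    done <- c(done, "mfep"); emit()
  }

  out$summary <- summary
  emit()
  invisible(out)
}
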