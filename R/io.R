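# Configuration files, report writers and the high-level entry points used
# by the command-line wrapper (inst/cli/mamsdelay.R).

scenario_keys <- c("K", "J", "n", "shape", "alpha", "power", "delta", "sigma",
                   "spacing", "m0", "tmax", "model", "models", "spacings",
                   "shapes", "tau", "seed", "format", "n_max", "out_prefix",
                   "calibrate_n")

#' Read and validate a scenario configuration file
#'
#' Flat YAML key/value configuration. Unknown keys are rejected; values are
#' validated before any computation. Packaged presets live under
#' \code{system.file("extdata", package = "mamsdelay")}.
#'
#' @param path Path to a YAML file.
#' @return Named list of validated configuration values.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  # Keep the short key "n" a string: YAML 1.1 would otherwise read the bare
  # scalars y/n/yes/no as booleans (true/false/on/off still parse as such).
  keep_yn <- function(x) {
    lx <- tolower(x)
    if (lx %in% c("true", "on")) TRUE
    else if (lx %in% c("false", "off")) FALSE
    else x
  }
  cfg <- yaml::read_yaml(path, handlers = list("bool#yes" = keep_yn,
                                               "bool#no" = keep_yn))
  unknown <- setdiff(names(cfg), scenario_keys)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(cfg$spacing) && is.numeric(cfg$spacing) && is.null(cfg$J))
    cfg$J <- length(cfg$spacing)
  cfg
}

provenance_header <- function(cfg, seed = NA) {
  c(sprintf("# mamsdelay %s", as.character(utils::packageVersion("mamsdelay"))),
    sprintf("# config_hash=%s seed=%s abseps=%g maxpts=%d",
            config_hash(cfg), format(seed), mvn_abseps(), mvn_maxpts()))
}

write_tsv_report <- function(df, path, cfg, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(cfg, seed), con)
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

cfg_default <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else cfg[[key]]
}

#' Calibrate and report one design
#'
#' Reads (or takes) a scenario configuration, calibrates the boundaries and
#' the group size, and writes a stagewise boundary table (TSV with columns
#' stage, e, f, n_cum_per_arm) plus a plain-text summary.
#'
#' @param config Path to a YAML configuration file, or a config list.
#' @param out_dir Output directory; created if missing. \code{NULL} writes
#'   nothing and just returns the results.
#' @return Invisibly, a list with \code{design}, \code{boundaries},
#'   \code{n_MA}, \code{ess} and the boundary table.
#' @export
run_design <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_scenario_config(config) else config
  design <- mams_design(
    K = cfg_default(cfg, "K", 3), J = cfg_default(cfg, "J", 2),
    n = cfg_default(cfg, "n", NULL),
    spacing = cfg_default(cfg, "spacing", NULL),
    sigma = cfg_default(cfg, "sigma", 1),
    delta = cfg_default(cfg, "delta", 0.5),
    alpha = cfg_default(cfg, "alpha", 0.05),
    power = cfg_default(cfg, "power", 0.8))
  shape <- cfg_default(cfg, "shape", "fixed_futility_obf")
  if (isTRUE(cfg_default(cfg, "calibrate_n", is.null(cfg$n)))) {
    fit <- calibrate_group_size(design, shape = shape)
    design <- fit$design
    boundaries <- fit$boundaries
  } else {
    boundaries <- calibrate_boundaries(design, shape = shape)
  }
  tau <- resolve_tau(cfg_default(cfg, "tau", "alternative"),
                     design$K, design$delta)
  dist <- outcome_distribution(design, boundaries, tau)
  tab <- data.frame(stage = seq_len(design$J), e = boundaries$e,
                    f = boundaries$f,
                    n_cum_per_arm = cumsum(design$group_sizes[, 2]))
  res <- list(design = design, boundaries = boundaries,
              n_MA = single_stage_size(design),
              ess = ess(design, boundaries, tau, distribution = dist),
              table = tab)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_report(tab, file.path(out_dir, "design_boundaries.tsv"), cfg)
    writeLines(c(provenance_header(cfg),
                 utils::capture.output(print(design), print(boundaries)),
                 sprintf("n_MA=%.4f ESS=%.4f", res$n_MA, res$ess)),
               file.path(out_dir, "design_summary.txt"))
  }
  invisible(res)
}

#' Run a scenario grid from a configuration file
#'
#' @inheritParams run_design
#' @param format \code{"tsv"} (default), \code{"csv"} or \code{"json"}.
#' @return Invisibly, the grid data.frame (see \code{\link{scenario_grid}}).
#' @export
run_grid <- function(config, out_dir = NULL, format = NULL) {
  cfg <- if (is.character(config)) read_scenario_config(config) else config
  format <- if (is.null(format)) cfg_default(cfg, "format", "tsv") else format
  grid <- scenario_grid(
    J = cfg_default(cfg, "J", 2:4), K = cfg_default(cfg, "K", 2:4),
    m0 = cfg_default(cfg, "m0", seq(0, 36, 6)),
    tmax = cfg_default(cfg, "tmax", 36),
    models = cfg_default(cfg, "models", c("uniform", "linear")),
    spacings = cfg_default(cfg, "spacings", "I"),
    shapes = cfg_default(cfg, "shapes", "fixed_futility_obf"),
    tau = cfg_default(cfg, "tau", "alternative"),
    alpha = cfg_default(cfg, "alpha", 0.05),
    power = cfg_default(cfg, "power", 0.8),
    delta = cfg_default(cfg, "delta", 0.5),
    sigma = cfg_default(cfg, "sigma", 1))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (format == "json") {
      jsonlite::write_json(grid, file.path(out_dir, "scenario_grid.json"),
                           digits = NA, auto_unbox = TRUE)
    } else {
      sep <- if (format == "csv") "," else "\t"
      path <- file.path(out_dir, paste0("scenario_grid.", format))
      con <- file(path, "w"); on.exit(close(con))
      writeLines(provenance_header(cfg), con)
      utils::write.table(grid, con, sep = sep, quote = FALSE,
                         row.names = FALSE)
    }
  }
  invisible(grid)
}

#' Dose-ranging illustration report (TAILoR-style)
#'
#' Reproduces the computable columns of a delay-impact table for a 2-stage,
#' 3-experimental-arm trial with a 6-month outcome delay: per
#' recruitment-speed scenario, the pipeline participants at the first
#' interim, the excess over the stage-2 requirement for each number of arms
#' continuing, and (for boundary shapes calibrated in-package) ESS,
#' ESS_delay and EL under uniform and linear recruitment. The trial's own
#' unpublished ("original") boundaries cannot be recomputed, so that row
#' carries the pipeline columns only, computed from the published group
#' sizes.
#'
#' @inheritParams run_design
#' @return Invisibly, a list of two data.frames: \code{pipelines} (per
#'   shape, tmax and arms-continuing) and \code{efficiency} (per shape,
#'   tmax and recruitment model).
#' @export
run_tailor <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_scenario_config(config) else config
  n <- cfg_default(cfg, "n", 42)
  m0 <- cfg_default(cfg, "m0", 6)
  tmaxes <- cfg_default(cfg, "tmax", c(29, 24, 20))
  shapes <- cfg_default(cfg, "shapes", c("obf", "pocock", "triangular"))
  n_max_pipe <- cfg_default(cfg, "n_max", NULL)  # e.g. 379 actually recruited
  alpha <- cfg_default(cfg, "alpha", 0.05)
  power <- cfg_default(cfg, "power", 0.8)
  delta <- cfg_default(cfg, "delta", 0.5)
  K <- cfg_default(cfg, "K", 3); J <- cfg_default(cfg, "J", 2)

  base <- mams_design(K = K, J = J, n = n, alpha = alpha, power = power,
                      delta = delta)
  pipe_rows <- list(); eff_rows <- list()
  shape_designs <- list(original = list(design = base, boundaries = NULL))
  for (shp in shapes) {
    fit <- calibrate_group_size(base, shape = shp)
    shape_designs[[shp]] <- fit
  }
  n_MA <- single_stage_size(base)
  for (nm in names(shape_designs)) {
    des <- shape_designs[[nm]]$design
    bnd <- shape_designs[[nm]]$boundaries
    nmax_d <- if (nm == "original" && !is.null(n_max_pipe)) n_max_pipe
              else design_nmax(des)
    dist <- if (!is.null(bnd))
      outcome_distribution(des, bnd, rep(delta, K)) else NULL
    for (tm in tmaxes) {
      dl <- delay_spec(m0, tm)
      mods <- lapply(c(uniform = "uniform", linear = "linear"),
                     recruitment_model, n_max = nmax_d, tmax = tm)
      # pipelines at interim 1 and excess per number of continuing arms
      pipe1 <- vapply(mods, function(m)
        pipeline_count(des, rep(1L, K), 1L, m, dl), numeric(1))
      for (cont in 0:K) {
        omega2 <- c(rep(2L, cont), rep(1L, K - cont))
        n2 <- if (cont > 0) realized_sample_size(des, omega2) else NA_real_
        exc <- vapply(mods, function(m) {
          if (cont == 0) return(NA_real_)
          tl <- delay_timeline(des, omega2, m, dl)
          max(0, tl$n_cum[1] + tl$pipeline[1] - tl$n_cum[2])
        }, numeric(1))
        pipe_rows[[length(pipe_rows) + 1L]] <- data.frame(
          boundary = nm, tmax = tm, m0 = m0, arms_stage2 = cont + (cont > 0),
          n_stage2 = n2,
          pipeline_uniform = pipe1[["uniform"]],
          pipeline_linear = pipe1[["linear"]],
          excess_uniform = exc[["uniform"]], excess_linear = exc[["linear"]],
          stringsAsFactors = FALSE)
      }
      if (!is.null(bnd)) {
        ESS <- ess(des, bnd, rep(delta, K), distribution = dist)
        EG <- efficiency_gain(n_MA, ESS)
        for (mk in names(mods)) {
          ESSd <- ess_delay(des, bnd, rep(delta, K), mods[[mk]], dl,
                            distribution = dist)
          EGd <- efficiency_gain(n_MA, ESSd)
          eff_rows[[length(eff_rows) + 1L]] <- data.frame(
            boundary = nm, tmax = tm, m0 = m0, model = mk,
            n_max = design_nmax(des), n_MA = n_MA, ESS = ESS,
            ESS_delay = ESSd, EL = efficiency_loss(EG, EGd),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- list(pipelines = do.call(rbind, pipe_rows),
              efficiency = do.call(rbind, eff_rows))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_report(res$pipelines,
                     file.path(out_dir, "tailor_pipelines.tsv"), cfg)
    write_tsv_report(res$efficiency,
                     file.path(out_dir, "tailor_efficiency.tsv"), cfg)
  }
  invisible(res)
}
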