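#' Pipeline configuration
#'
#' All stage parameters with their standard defaults (SNR > 3 and 10
#' Angstrom low-resolution filters, 3-sigma contour, Savitzky-Golay
#' 21/3, 580-640 and 456-490 nm bands, 0.1 degree / 0.1 Angstrom dFoCC
#' convergence). Unknown keys are rejected; the object round-trips
#' through JSON identically.
#'
#' @param ... Overrides for the default keys, plus optionally `stages`
#'   (character vector) and `workdir`.
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    snr_min = 3, d_low = 10, contour_sigma = 3,
    sg_window = 21, sg_order = 3,
    band = c(580, 640), norm_band = c(456, 490),
    scatter_window = c(700, 800),
    dfocc_min_step_deg = 0.1, dfocc_min_step_ang = 0.1,
    d_min = 1.8, n_grid = list(n = 21, lo = 2, hi = 40),
    alpha = 0.2, noise_frac = 0.01, seed = 1,
    stages = character(0), workdir = ".")
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  structure(utils::modifyList(defaults, over), class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#' @param config A [pipeline_config()].
#' @param path JSON path.
#' @return `path` invisibly (write); a `pipeline_config` (read).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$stages <- as.character(x$stages)
  do.call(pipeline_config, x)
}

# stable hash of a config (canonical JSON -> md5); volatile paths excluded
.config_hash <- function(config) {
  x <- unclass(config)
  x$workdir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run a declared sequence of pipeline stages
#'
#' Executes the stages named in `config$stages` in order, writing
#' per-stage outputs under `config$workdir` and a JSON run manifest
#' capturing the package version, seed, parameter hash and per-stage
#' status. Deterministic stages re-run with an identical config produce
#' identical outputs (and the same manifest hash).
#'
#' Available stages: `"simulate"` (toy crystal + mixed dark/light
#' datasets), `"ded"` (observed DED map from the simulated pair),
#' `"integrate"` (signed density integrals around the perturbed
#' residue), `"extrapolate"` (residual-density scan + occupancy),
#' `"dfocc"` (reaction-coordinate refinement).
#'
#' @param config A [pipeline_config()].
#' @return The manifest (list), invisibly written to
#'   `workdir/manifest.json`. Stage failure records the error in the
#'   manifest and re-raises.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  wd <- config$workdir
  dir.create(wd, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "trsfx",
                   version = as.character(utils::packageVersion("trsfx")),
                   seed = config$seed,
                   config_hash = .config_hash(config),
                   stages = list())
  env <- new.env()
  for (st in config$stages) {
    res <- tryCatch({
      .run_stage(st, config, env)
      list(stage = st, status = "ok")
    }, error = function(e) list(stage = st, status = "error",
                                message = conditionMessage(e)))
    manifest$stages[[length(manifest$stages) + 1]] <- res
    if (res$status == "error") {
      jsonlite::write_json(manifest, file.path(wd, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      stop("stage '", st, "' failed: ", res$message)
    }
  }
  jsonlite::write_json(manifest, file.path(wd, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

.run_stage <- function(stage, cfg, env) {
  wd <- cfg$workdir
  switch(stage,
    simulate = {
      env$dark <- make_toy_crystal(cfg$seed)
      env$light <- apply_perturbation(env$dark, toy_chi2_perturbation())
      sim <- simulate_dataset(env$dark, env$light, alpha = cfg$alpha,
                              noise_frac = cfg$noise_frac, seed = cfg$seed,
                              d_min = cfg$d_min)
      env$sim <- sim
      write_pdb(env$dark, file.path(wd, "dark.pdb"))
      write_pdb(env$light, file.path(wd, "light.pdb"))
      write_reflections_csv(sim$dark_obs, file.path(wd, "dark_obs.csv"))
      write_reflections_csv(sim$light_obs, file.path(wd, "light_obs.csv"))
    },
    ded = {
      if (is.null(env$sim)) stop("stage 'ded' requires 'simulate' first")
      env$ded <- ded_map(env$sim$light_obs, env$sim$dark_obs, env$dark,
                         snr_min = cfg$snr_min, d_low = cfg$d_low)
      write_ccp4_map(env$ded, file.path(wd, "ded.ccp4"))
    },
    integrate = {
      if (is.null(env$ded)) stop("stage 'integrate' requires 'ded' first")
      mask <- region_mask(env$dark, "resi 2 and name CG,OD1,ND2",
                          grid = dim(env$ded$values), radius = 2.0)
      out <- list(
        positive = integrate_region(env$ded, mask, "positive",
                                    level_sigma = cfg$contour_sigma),
        negative = integrate_region(env$ded, mask, "negative",
                                    level_sigma = cfg$contour_sigma))
      out$total <- out$positive + out$negative
      jsonlite::write_json(out, file.path(wd, "integrate.json"),
                           auto_unbox = TRUE, digits = NA)
    },
    extrapolate = {
      if (is.null(env$sim)) stop("stage 'extrapolate' requires 'simulate' first")
      light_s <- scale_to_reference(env$sim$light_obs, env$sim$dark_obs)
      diff <- difference_amplitudes(light_s, env$sim$dark_obs,
                                    snr_min = cfg$snr_min, d_low = cfg$d_low)
      dark_calc <- calc_structure_factors(env$dark, min(diff$data$d))
      ng <- cfg$n_grid
      scan <- residual_density_scan(
        diff, dark_calc, env$dark, marker = "resi 2 and name CG,OD1,ND2",
        N_grid = exp(seq(log(ng$lo), log(ng$hi), length.out = ng$n)),
        level_sigma = cfg$contour_sigma)
      scan <- estimate_occupancy(scan)
      utils::write.csv(scan$scan, file.path(wd, "occupancy_scan.csv"),
                       row.names = FALSE)
      jsonlite::write_json(list(N_star = scan$N_star, alpha = scan$alpha,
                                se = scan$se),
                           file.path(wd, "occupancy.json"),
                           auto_unbox = TRUE, digits = NA)
    },
    dfocc = {
      if (is.null(env$ded)) stop("stage 'dfocc' requires 'ded' first")
      best <- dfocc_refine(env$dark, asn_chi_axes(2), env$ded,
                           config = list(min_step_deg = cfg$dfocc_min_step_deg))
      write_pdb(best$model, file.path(wd, "dfocc_refined.pdb"))
      jsonlite::write_json(list(offsets = best$offsets, cc = best$cc),
                           file.path(wd, "dfocc.json"),
                           auto_unbox = TRUE, digits = NA)
    },
    stop("unknown stage: '", stage, "'"))
  invisible(NULL)
}

#' Command-line entry point
#'
#' Implements the `trsfx` command (see `inst/cli/trsfx`):
#' `trsfx <subcommand> [--key value ...]`. Subcommands: `simulate`,
#' `ded`, `integrate`, `svd`, `extrapolate`, `dfocc`, `fit`, `spectra`,
#' `pipeline`.
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status (0 on success), invisibly.
#' @export
trsfx_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: trsfx <simulate|ded|integrate|svd|extrapolate|dfocc|fit|spectra|pipeline> [--key value ...]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- .parse_args(args[-1])
  getv <- function(key, default = NULL) {
    if (!is.null(opt[[key]])) opt[[key]] else default
  }
  status <- tryCatch({
    switch(cmd,
      simulate = {
        dark <- make_toy_crystal(as.integer(getv("seed", 1)))
        light <- apply_perturbation(dark, toy_chi2_perturbation(
          as.numeric(getv("angle", -86.4))))
        sim <- simulate_dataset(dark, light,
                                alpha = as.numeric(getv("alpha", 0.2)),
                                noise_frac = as.numeric(getv("noise", 0.01)),
                                seed = as.integer(getv("seed", 1)),
                                d_min = as.numeric(getv("dmin", 1.8)))
        out <- getv("out", ".")
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_pdb(dark, file.path(out, "dark.pdb"))
        write_pdb(light, file.path(out, "light.pdb"))
        write_reflections_csv(sim$dark_obs, file.path(out, "dark_obs.csv"))
        write_reflections_csv(sim$light_obs, file.path(out, "light_obs.csv"))
        jsonlite::write_json(list(seed = as.integer(getv("seed", 1)),
                                  alpha = as.numeric(getv("alpha", 0.2)),
                                  noise = as.numeric(getv("noise", 0.01))),
                             file.path(out, "simulate_manifest.json"),
                             auto_unbox = TRUE, digits = NA)
      },
      ded = {
        light <- read_reflections_csv(getv("light"))
        dark <- read_reflections_csv(getv("dark"))
        model <- read_pdb(getv("model"))
        m <- ded_map(light, dark, model,
                     snr_min = as.numeric(getv("snr", 3)),
                     d_low = as.numeric(getv("dlow", 10)))
        write_ccp4_map(m, getv("out", "ded.ccp4"))
      },
      integrate = {
        m <- read_ccp4_map(getv("map"))
        model <- read_pdb(getv("model"))
        mask <- region_mask(model, getv("select"), grid = dim(m$values),
                            radius = as.numeric(getv("radius", 2.0)))
        lv <- as.numeric(getv("sigma", 3))
        cat(sprintf("positive %.6g\nnegative %.6g\ntotal %.6g\n",
                    integrate_region(m, mask, "positive", lv),
                    integrate_region(m, mask, "negative", lv),
                    integrate_region(m, mask, "total", lv)))
      },
      svd = {
        paths <- Sys.glob(getv("maps"))
        if (length(paths) < 2) stop("need >= 2 maps")
        maps <- lapply(paths, read_ccp4_map)
        model <- read_pdb(getv("model"))
        mask <- region_mask(model, getv("select"),
                            grid = dim(maps[[1]]$values),
                            radius = as.numeric(getv("radius", 2.0)))
        res <- svd_decompose(maps, mask)
        utils::write.csv(data.frame(component = seq_along(res$sv),
                                    sv = res$sv),
                         getv("out", "svd_sv.csv"), row.names = FALSE)
      },
      extrapolate = {
        light <- read_reflections_csv(getv("light"))
        dark <- read_reflections_csv(getv("dark"))
        model <- read_pdb(getv("model"))
        light_s <- scale_to_reference(light, dark)
        diff <- difference_amplitudes(light_s, dark,
                                      snr_min = as.numeric(getv("snr", 3)),
                                      d_low = as.numeric(getv("dlow", 10)))
        dark_calc <- calc_structure_factors(model, min(diff$data$d))
        ng <- exp(seq(log(as.numeric(getv("nmin", 2))),
                      log(as.numeric(getv("nmax", 40))), length.out = 21))
        scan <- estimate_occupancy(residual_density_scan(
          diff, dark_calc, model, marker = getv("marker"), N_grid = ng))
        utils::write.csv(scan$scan, getv("out", "occupancy_scan.csv"),
                         row.names = FALSE)
        cat(sprintf("N* %.4g alpha %.4g se %.4g\n",
                    scan$N_star, scan$alpha, scan$se))
      },
      dfocc = {
        model <- read_pdb(getv("model"))
        ded_o <- read_ccp4_map(getv("dedo"))
        resi <- as.integer(getv("resi", 2))
        best <- dfocc_refine(model, asn_chi_axes(resi), ded_o)
        write_pdb(best$model, getv("out", "dfocc_refined.pdb"))
        cat(sprintf("offsets %s  CC %.4f\n",
                    paste(signif(best$offsets, 5), collapse = " "), best$cc))
      },
      fit = {
        trace <- read_trace_csv(getv("trace"))
        fit <- fit_trace(trace, getv("model", "first_order"))
        write_fit_json(fit, getv("out", "fit.json"))
        print(fit)
      },
      spectra = {
        manifest <- utils::read.csv(getv("manifest"))
        series <- lapply(seq_len(nrow(manifest)), function(i) {
          list(delay = manifest$delay_s[i],
               transient = read_spectrum_csv(manifest$transient[i]),
               dark = read_spectrum_csv(manifest$dark[i]))
        })
        trace <- build_difference_trace(series)
        write_trace_csv(trace, getv("out", "trace.csv"))
        if (!is.null(opt$fit)) print(fit_trace(trace, opt$fit))
      },
      pipeline = {
        cfg <- if (!is.null(opt$config)) read_config(opt$config)
               else pipeline_config()
        if (!is.null(opt$stages))
          cfg$stages <- strsplit(opt$stages, ",")[[1]]
        if (!is.null(opt$workdir)) cfg$workdir <- opt$workdir
        run_pipeline(cfg)
      },
      stop("unknown subcommand: ", cmd))
    0L
  }, error = function(e) {
    message("trsfx ", cmd, ": ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.parse_args <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i + 1 <= length(args) && !startsWith(args[i + 1], "--")) {
        out[[key]] <- args[i + 1]; i <- i + 2
      } else { out[[key]] <- TRUE; i <- i + 1 }
    } else i <- i + 1
  }
  out
}
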