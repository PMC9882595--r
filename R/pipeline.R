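#' Run a configured multi-stage analysis
#'
#' Executes the requested stages in dependency order and writes their
#' tables to `outDir` as CSV, plus a JSON provenance record of the
#' parameters and seed. Available stages and their dependencies:
#'
#' * `simulate_hbond`: synthetic occupancy tables ([simulateHbondOccupancy()];
#'   parameters under `hbond`, defaulting to [exampleHbondScenario()]).
#' * `hbond_dafs` (needs `simulate_hbond`): occupancy profile,
#'   force-response labels and DAFS calls.
#' * `simulate_umbrella`: biased window samples from a double-well
#'   potential (`umbrella` parameters: `depth`, `centers`, `k`,
#'   `nSamples`).
#' * `wham` (needs `simulate_umbrella`): PMF and binding free energy.
#' * `simulate_fret`: a three-channel FRET scene (`fret` parameters).
#' * `fret_efficiency` (needs `simulate_fret`): pixelwise efficiency and
#'   the recovery error against the planted truth.
#'
#' Rerunning with the same config and seed reproduces the CSV outputs
#' byte for byte.
#'
#' @param config list (or path to a YAML file) with `stages` (character
#'   vector), optional per-stage parameter blocks, and `seed`.
#' @param outDir output directory, created if missing.
#' @return named list of per-stage results (invisibly written to disk).
#' @export
runPipeline <- function(config, outDir = tempfile("catchlink")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages
  if (is.null(stages)) stop("config$stages is missing")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  need <- function(dep, stage)
    if (is.null(res[[dep]]))
      stop(sprintf("stage '%s' requires output of stage '%s'", stage, dep))
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(outDir, paste0(name, ".csv")),
                     row.names = FALSE)

  for (stage in stages) {
    res[[stage]] <- switch(stage,
      simulate_hbond = {
        p <- config$hbond
        bonds <- if (is.null(p$bonds)) exampleHbondScenario()
                 else as.data.frame(p$bonds)
        sim <- simulateHbondOccupancy(
          bonds, noise = isTRUE(p$noise), seed = seed,
          nReplicates = if (is.null(p$nReplicates)) 10 else p$nReplicates)
        wcsv(sim$occupancy, "hbond_occupancy")
        sim
      },
      hbond_dafs = {
        need("simulate_hbond", stage)
        occ <- res$simulate_hbond$occupancy
        occ$present <- NULL
        prof <- occupancyProfile(occ)
        dafs <- callDafs(prof)
        wcsv(prof, "hbond_profile")
        wcsv(dafs$calls, "dafs_calls")
        wcsv(dafs$counts, "dafs_counts")
        dafs
      },
      simulate_umbrella = {
        p <- config$umbrella
        depth <- if (is.null(p$depth)) 3 else p$depth
        centers <- if (is.null(p$centers)) seq(1, 14, length.out = 10)
                   else p$centers
        windows <- simulateUmbrellaWindows(
          doubleWellPotential(depth), centers,
          springConstant = if (is.null(p$k)) 3 else p$k,
          nSamples = if (is.null(p$nSamples)) 5000 else p$nSamples,
          seed = seed)
        writeUmbrellaCsv(windows, file.path(outDir, "windows.csv"),
                         file.path(outDir, "samples.csv"))
        windows
      },
      wham = {
        need("simulate_umbrella", stage)
        pmf <- whamSolve(res$simulate_umbrella)
        dg <- deltaG(pmf)
        wcsv(data.frame(xi = pmfGrid(pmf), pmf = pmfValues(pmf),
                        reliable = validityMask(pmf)), "pmf")
        wcsv(data.frame(deltaG = dg$deltaG, unit = dg$unit), "delta_g")
        list(pmf = pmf, deltaG = dg)
      },
      simulate_fret = {
        p <- config$fret
        fa <- if (is.null(p$faEllipses))
          data.frame(cx = c(40, 90), cy = c(40, 90), a = c(12, 10),
                     b = c(6, 5), theta_deg = c(20, 110),
                     donor_level = 800, acceptor_level = 700,
                     E_true = if (is.null(p$E_true)) 0.3 else p$E_true)
          else as.data.frame(p$faEllipses)
        simulateFretScene(faEllipses = fa, seed = seed,
                          noise = if (isTRUE(p$noise))
                            list(poisson = TRUE, readSd = 2) else NULL)
      },
      fret_efficiency = {
        need("simulate_fret", stage)
        sc <- res$simulate_fret
        pre <- preprocessChannels(sc$channels,
                                  dark = sc$truth$darkLevel,
                                  backgroundMask = !sc$faMask,
                                  register = FALSE)
        ch <- pre$channels
        Fc <- correctedFretImage(ch$fret, ch$donor, ch$acceptor,
                                 sc$truth$dbt, sc$truth$abt)
        eff <- efficiencyImage(Fc, ch$donor, sc$truth$G)
        stats_df <- data.frame(
          region = "fa",
          mean_E = mean(efficiencyMap(eff)[sc$faMask], na.rm = TRUE),
          mean_E_true = mean(sc$truth$faEllipses$E_true))
        wcsv(stats_df, "fret_recovery")
        list(efficiency = eff, recovery = stats_df)
      },
      stop(sprintf("unknown stage '%s'", stage)))
  }
  prov <- list(package = "catchlink",
               version = as.character(utils::packageVersion("catchlink")),
               seed = seed, stages = stages)
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
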