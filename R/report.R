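#' Deterministic production grid: cows bred, weaning weight, calf revenue
#'
#' Evaluates the deterministic reproduction and calf-crop layers over a grid
#' of breeding-season lengths and bull fertilities, averaging each quantity
#' over the planning horizon. These are the quantities that explain most of
#' the Monte Carlo comparison: lower fertility and longer seasons mean fewer,
#' later, lighter calves.
#'
#' @param config A [herd_config()] object.
#' @param cycles Breeding-season lengths (estrus cycles).
#' @param fertility Bull fertility values (per-cycle conception probability).
#' @return A list of class `"deterministic_grid"` with matrices `cows_bred`
#'   (head/yr), `weaning_weight` (lb, calf-weighted), and `calf_revenue`
#'   (thousand $/yr); rows are season lengths, columns fertilities. Values
#'   are unrounded; [format_deterministic_grid()] applies the display
#'   convention.
#' @export
deterministic_grid <- function(config = herd_config(),
                               cycles = 2:6,
                               fertility = seq(0.66, 0.54, by = -0.01)) {
  sim <- config$simulation
  dn <- list(cycles = as.character(cycles),
             fertility = sprintf("%.0f%%", 100 * fertility))
  bred <- wt <- rev <- matrix(NA_real_, length(cycles), length(fertility),
                              dimnames = dn)
  for (i in seq_along(cycles)) {
    ages <- weaning_age(seq_len(cycles[i]))
    wts <- weaning_weight(ages, config$budget$calf_birth_weight,
                          config$budget$calf_adg)
    for (j in seq_along(fertility)) {
      conc <- simulate_reproduction(sim$herd_size, cycles[i], fertility[j],
                                    sim$horizon)
      bred[i, j] <- average_cows_bred(conc)
      wt[i, j] <- sum(unclass(conc) %*% wts) / sum(conc)
      rev[i, j] <- mean(calf_revenue_by_year(conc, config$budget,
                                             config$prices,
                                             sim$abortion_rate,
                                             sim$calf_death_loss)) / 1000
    }
  }
  structure(list(cows_bred = bred, weaning_weight = wt, calf_revenue = rev,
                 cycles = cycles, fertility = fertility),
            class = "deterministic_grid")
}

# Round up to a whole unit, guarding against floating-point residue
# (e.g. 0.6 * 400 = 240.0000000000000284 must display as 240, not 241).
display_round_up <- function(x) ceiling(round(x, 6))

#' Display-rounded deterministic grid
#'
#' Applies the reporting convention of the deterministic tables: cows bred
#' and calf revenue (in thousands of dollars) round up to the next whole
#' unit — a fractional expected cow or sale is booked whole — while weaning
#' weights round to the nearest pound.
#'
#' @param grid A [deterministic_grid()] object.
#' @return A list of integer matrices `cows_bred`, `weaning_weight`,
#'   `calf_revenue`.
#' @export
format_deterministic_grid <- function(grid) {
  stopifnot(inherits(grid, "deterministic_grid"))
  list(cows_bred = display_round_up(grid$cows_bred),
       weaning_weight = round(grid$weaning_weight),
       calf_revenue = display_round_up(grid$calf_revenue))
}

#' @export
print.deterministic_grid <- function(x, ...) {
  disp <- format_deterministic_grid(x)
  cat("<deterministic_grid> horizon averages by season length x fertility\n")
  cat("\nAverage numbers of cows bred:\n")
  print(disp$cows_bred)
  cat("\nAverage weaning weights of calves (lb):\n")
  print(disp$weaning_weight)
  cat("\nAverage revenues from calves (thousand $):\n")
  print(disp$calf_revenue)
  invisible(x)
}

write_grid_csv <- function(mat, path, row_label = "cycles") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE)
  names(df)[1] <- row_label
  utils::write.csv(df, path, row.names = FALSE)
  path
}

run_manifest <- function(config, seed, outputs, n = NULL) {
  list(package = "herdsim",
       version = as.character(utils::packageVersion("herdsim")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = seed,
       iterations = n,
       config = list(
         budget = unclass(config$budget),
         prices = list(class_weight = config$prices$class_weight,
                       price = config$prices$price),
         bse = unclass(config$bse),
         nbse = unclass(config$nbse),
         simulation = unclass(config$simulation)),
       outputs = outputs)
}

#' Write the deterministic production grids to CSV
#'
#' Emits `cows_bred.csv`, `weaning_weights.csv`, and `calf_revenues.csv`
#' (display-rounded, rows = season length, columns = fertility), the
#' unrounded grids (`*_raw.csv`), and a `manifest.json` describing the run.
#'
#' @param config A [herd_config()] object.
#' @param dir Output directory (created if missing).
#' @param cycles,fertility Grid axes, as in [deterministic_grid()].
#' @return Invisibly, the list of files written.
#' @export
deterministic_report <- function(config = herd_config(), dir = ".",
                                 cycles = 2:6,
                                 fertility = seq(0.66, 0.54, by = -0.01)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- deterministic_grid(config, cycles, fertility)
  disp <- format_deterministic_grid(grid)
  files <- c(
    write_grid_csv(disp$cows_bred, file.path(dir, "cows_bred.csv")),
    write_grid_csv(disp$weaning_weight, file.path(dir, "weaning_weights.csv")),
    write_grid_csv(disp$calf_revenue, file.path(dir, "calf_revenues.csv")),
    write_grid_csv(grid$cows_bred, file.path(dir, "cows_bred_raw.csv")),
    write_grid_csv(grid$weaning_weight,
                   file.path(dir, "weaning_weights_raw.csv")),
    write_grid_csv(grid$calf_revenue, file.path(dir, "calf_revenues_raw.csv"))
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(run_manifest(config, config$simulation$seed,
                                    basename(files)),
                       manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(files, manifest_path))
}

#' Run the Monte Carlo sweep and write its outputs
#'
#' Writes the long-format sweep (`sweep.csv`: one row per scenario with
#' `P(dNPV > 0)`), a JSON summary with the per-curve indifference points
#' (`summary.json`), optionally a per-period culling audit of the first
#' iteration of the first scenario (`culling_audit.csv`), and a
#' `manifest.json` sufficient to reproduce the run.
#'
#' @param config A [herd_config()] object.
#' @param dir Output directory (created if missing).
#' @param grid A [scenario_grid()] data frame.
#' @param n Iterations per scenario.
#' @param seed Base seed.
#' @param common_random_numbers Share event substreams between strategies.
#' @param audit Also write the per-period culling audit.
#' @param verbose Print progress.
#' @return Invisibly, the sweep result (with the file list as attribute
#'   `"files"`).
#' @export
montecarlo_report <- function(config = herd_config(), dir = ".",
                              grid = scenario_grid(),
                              n = config$simulation$iterations,
                              seed = config$simulation$seed,
                              common_random_numbers = FALSE,
                              audit = FALSE, verbose = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sweep <- sweep_scenarios(config, grid, n = n, seed = seed,
                           common_random_numbers = common_random_numbers,
                           verbose = verbose)
  sweep_path <- file.path(dir, "sweep.csv")
  utils::write.csv(as.data.frame(sweep), sweep_path, row.names = FALSE)
  files <- sweep_path

  indiff <- indifference_table(sweep)
  summary_path <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(n_scenarios = nrow(sweep), iterations = n, seed = seed,
         common_random_numbers = common_random_numbers,
         indifference_points = indiff),
    summary_path, auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
  files <- c(files, summary_path)

  if (audit) {
    audit_path <- file.path(dir, "culling_audit.csv")
    utils::write.csv(audit_culls(grid[1, , drop = FALSE], config, seed),
                     audit_path, row.names = FALSE)
    files <- c(files, audit_path)
  }

  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(run_manifest(config, seed, basename(files), n),
                       manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  attr(sweep, "files") <- c(files, manifest_path)
  invisible(sweep)
}
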