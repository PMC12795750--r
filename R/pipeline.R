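#' Configuration of a full pipeline run
#'
#' Bundles every stage's settings. The master `seed` overrides the
#' seeds of the stage configs so a single integer reproduces the whole
#' run.
#'
#' @param generator A [generator_config()].
#' @param transport A [transport_config()].
#' @param workplace_iterations Monte Carlo iterations for the workplace
#'   stage.
#' @param workplace_threshold Workplace hazard threshold in dBA.
#' @param bootstrap_n Bootstrap samples for the ERR CIs (default 100).
#' @param quintile_mode `"per_metro"` or `"pooled"` (see
#'   [tract_quintiles()]).
#' @param models Character vector of model stages to run.
#' @param seed Master seed.
#' @return A list of class `noisequity_run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       transport = transport_config(),
                       workplace_iterations = 1000,
                       workplace_threshold = 85,
                       bootstrap_n = 100,
                       quintile_mode = c("per_metro", "pooled"),
                       models = c("logistic", "poisson_workplace",
                                  "poisson_transport", "redlining"),
                       seed = 1L) {
  quintile_mode <- match.arg(quintile_mode)
  generator$seed <- as.integer(seed)
  transport$seed <- as.integer(seed)
  structure(list(generator = generator, transport = transport,
                 workplace_iterations = as.integer(workplace_iterations),
                 workplace_threshold = workplace_threshold,
                 bootstrap_n = as.integer(bootstrap_n),
                 quintile_mode = quintile_mode, models = models,
                 seed = as.integer(seed)),
            class = "noisequity_run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file with any subset of the [run_config()] fields
#'   (including nested `generator` and `transport` blocks).
#' @param seed Optional master-seed override.
#' @return A `noisequity_run_config`.
#' @export
run_config_from_json <- function(path, seed = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  gen <- do.call(generator_config, as.list(raw$generator %||% list()))
  tra <- do.call(transport_config, as.list(raw$transport %||% list()))
  args <- raw[setdiff(names(raw), c("generator", "transport"))]
  args$generator <- gen
  args$transport <- tra
  if (!is.null(seed)) args$seed <- as.integer(seed)
  do.call(run_config, args)
}

run_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  attr(res, "elapsed") <- proc.time()[["elapsed"]] - t0
  res
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate -> prevalence -> inequity metrics ->
#' structural indices -> regression models into a run directory. Every
#' stage output is a header-row CSV; a `manifest.json` records the
#' config hash, master seed, per-file md5 checksums, row counts and
#' stage timings, and `report.md` summarizes nationwide exposure, the
#' ERR table and the model effect tables. Identical config and seed
#' reproduce identical outputs (and therefore identical manifests).
#'
#' @param config A [run_config()].
#' @param out_dir Run directory (created if missing).
#' @param verbose Log stage progress to the console and to `run.log`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "noisequity_run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_file <- file.path(out_dir, "run.log")
  cat("", file = log_file)
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(msg, "\n", file = log_file, append = TRUE)
    if (verbose) message(msg)
  }
  timings <- list()

  say("stage generate: synthetic geography, JEM, structural tables")
  geo <- run_stage("generate", {
    g <- generate_geography(config$generator)
    s <- generate_structural(g$tracts, config$generator)
    j <- generate_jem()
    write_synthetic_tables(g, s, j, out_dir)
    list(tracts = g$tracts, blocks = g$blocks, gt = g$ground_truth,
         holc = s$holc, mortgage = s$mortgage, jem = j)
  })
  timings$generate <- attr(geo, "elapsed")

  say("stage prevalence: workplace and transportation Monte Carlo")
  prev <- run_stage("prevalence", {
    wp <- estimate_workplace_prevalence_all(
      geo$tracts, geo$jem, threshold = config$workplace_threshold,
      n_iterations = config$workplace_iterations, seed = config$seed,
      return_draws = TRUE)
    tp <- estimate_transport_prevalence_all(geo$blocks, config$transport,
                                            return_draws = TRUE)
    ord <- match(geo$tracts$tract_id, tp$tract_id)
    dr <- attr(tp, "draws")[ord, , drop = FALSE]
    tp <- tp[ord, ]
    rownames(tp) <- NULL
    attr(tp, "draws") <- dr
    utils::write.csv(wp[, 1:8], file.path(out_dir, "workplace_prevalence.csv"),
                     row.names = FALSE)
    utils::write.csv(tp[, 1:8], file.path(out_dir, "transport_prevalence.csv"),
                     row.names = FALSE)
    list(wp = wp, tp = tp)
  })
  timings$prevalence <- attr(prev, "elapsed")

  say("stage metrics: ERRs, cumulative flags, quintiles")
  met <- run_stage("metrics", {
    tr <- geo$tracts
    wp <- prev$wp; tp <- prev$tp
    ow <- ifelse(wp$excluded, NA_real_, wp$omega)
    ot <- ifelse(tp$excluded, NA_real_, tp$omega)
    groups <- c(minority = "minority",
                stats::setNames(minority_columns(), minority_columns()))
    err_rows <- list()
    for (gname in names(groups)) {
      p <- if (gname == "minority") tr$population - tr$pop_nh_white
           else tr[[gname]]
      base <- data.frame(p = p, t = tr$population)
      err_rows[[paste0(gname, ":w")]] <- bootstrap_err(
        cbind(base, omega = ow), gname, "workplace",
        n_boot = config$bootstrap_n, seed = config$seed)
      err_rows[[paste0(gname, ":t")]] <- bootstrap_err(
        cbind(base, omega = ot), gname, "transportation",
        n_boot = config$bootstrap_n, seed = config$seed)
      err_rows[[paste0(gname, ":c")]] <- bootstrap_err(
        cbind(base, omega_work = ow, omega_transport = ot), gname,
        "cumulative", n_boot = config$bootstrap_n, seed = config$seed)
    }
    errs <- do.call(rbind, err_rows)
    rownames(errs) <- NULL
    flags <- classify_cumulative_high(wp, tp)
    quin <- tract_quintiles(tr, "minority", mode = config$quintile_mode,
                            quiet = TRUE)
    utils::write.csv(errs, file.path(out_dir, "err_results.csv"),
                     row.names = FALSE)
    utils::write.csv(flags, file.path(out_dir, "cumulative_flags.csv"),
                     row.names = FALSE)
    utils::write.csv(quin, file.path(out_dir, "quintiles.csv"),
                     row.names = FALSE)
    list(errs = errs, flags = flags, quin = quin)
  })
  timings$metrics <- attr(met, "elapsed")

  say("stage indices: redlining score and mortgage discrimination")
  idx <- run_stage("indices", {
    si <- structural_indices(geo$holc, geo$mortgage)
    utils::write.csv(si, file.path(out_dir, "structural_indices.csv"),
                     row.names = FALSE)
    si
  })
  timings$indices <- attr(idx, "elapsed")

  say("stage models: regression fits")
  mod <- run_stage("models", {
    fit_model_stages(config, geo$tracts, prev$wp, prev$tp, met$flags,
                     met$quin, idx, out_dir)
  })
  timings$models <- attr(mod, "elapsed")

  say("stage report")
  nat <- run_stage("report", {
    write_run_report(out_dir, geo, prev, met, mod)
  })
  timings$report <- attr(nat, "elapsed")

  manifest <- build_manifest(config, out_dir, timings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: %d files in %s", length(manifest$files), out_dir)
  invisible(manifest)
}

fit_model_stages <- function(config, tracts, wp, tp, flags, quin, indices,
                             out_dir) {
  results <- list()
  eff_rows <- list()
  add <- function(name, model) {
    results[[name]] <<- model
    e <- model$effects
    e$model <- name
    e$separation <- model$separation
    eff_rows[[name]] <<- e
  }
  if ("logistic" %in% config$models) {
    sp <- model_spec("logistic", "minority")
    de <- build_design(tracts, quin, sp, flags = flags)
    add("logistic_cumulative", fit_cumulative_logistic(de))
  }
  if ("poisson_workplace" %in% config$models) {
    sp <- model_spec("poisson", "minority", offset = "workers")
    de <- build_design(tracts, quin, sp, prevalence = wp)
    add("poisson_workplace", fit_prevalence_poisson(de))
  }
  if ("poisson_transport" %in% config$models) {
    sp <- model_spec("poisson", "minority", offset = "residents")
    de <- build_design(tracts, quin, sp, prevalence = tp)
    add("poisson_transport", fit_prevalence_poisson(de))
  }
  if ("redlining" %in% config$models) {
    for (st in c("sustained", "not_sustained")) {
      nm <- paste0("redlining_", st)
      m <- tryCatch(suppressWarnings(
        fit_redlining_linear(tracts, indices, wp, tp, stratum = st)),
        error = function(e) NULL)
      if (!is.null(m)) add(nm, m)
    }
  }
  eff <- do.call(rbind, eff_rows)
  if (!is.null(eff)) {
    rownames(eff) <- NULL
    utils::write.csv(eff, file.path(out_dir, "model_results.csv"),
                     row.names = FALSE)
  }
  results
}

write_run_report <- function(out_dir, geo, prev, met, mod) {
  tr <- geo$tracts
  nat_t <- aggregate_exposed(prev$tp, tr$population,
                             draws = attr(prev$tp, "draws"))
  nat_w <- aggregate_exposed(prev$wp, tr$workers, draws = attr(prev$wp, "draws"))
  lines <- c(
    "# noisequity run report", "",
    sprintf("Tracts: %d; blocks: %d.", nrow(tr), nrow(geo$blocks)), "",
    "## Nationwide exposure", "",
    sprintf("- Transportation noise (>55 dBA, 24-h): %.0f of %.0f residents exposed, %.1f%% (95%% CI %.1f-%.1f).",
            nat_t$exposed, nat_t$population, nat_t$percent,
            nat_t$percent_low, nat_t$percent_high),
    sprintf("- Workplace noise (>85 dBA, 8-h TWA): %.0f of %.0f workers exposed, %.1f%% (95%% CI %.1f-%.1f).",
            nat_w$exposed, nat_w$population, nat_w$percent,
            nat_w$percent_low, nat_w$percent_high),
    "", "## Exposure-risk ratios", "",
    "| group | source | ERR | 95% CI |", "|---|---|---|---|",
    sprintf("| %s | %s | %.3f | %.3f-%.3f |", met$errs$group,
            met$errs$source, met$errs$err, met$errs$ci_low,
            met$errs$ci_high),
    "", "## Model effects (vs Q1 / per 1-to-4 HRS)", "")
  for (nm in names(mod)) {
    e <- mod[[nm]]$effects
    lines <- c(lines, sprintf("### %s (n = %d)", nm, mod[[nm]]$n), "",
               "| exposure | quintile | estimate | 95% CI |",
               "|---|---|---|---|",
               sprintf("| %s | %s | %.3f | %.3f-%.3f |", e$exposure,
                       ifelse(is.na(e$quintile), "-", e$quintile),
                       e$estimate, e$ci_low, e$ci_high), "")
  }
  writeLines(lines, file.path(out_dir, "report.md"))
  list(transport = nat_t, workplace = nat_w)
}

build_manifest <- function(config, out_dir, timings) {
  files <- sort(setdiff(list.files(out_dir),
                        c("manifest.json", "run.log")))
  info <- lapply(files, function(f) {
    p <- file.path(out_dir, f)
    rows <- if (grepl("\\.csv$", f)) length(readLines(p)) - 1L else NA_integer_
    list(md5 = unname(tools::md5sum(p)), rows = rows)
  })
  names(info) <- files
  list(package = "noisequity",
       config_hash = config_hash(config),
       seed = config$seed,
       files = info,
       timings = lapply(timings, function(x) round(x, 3)))
}

#' @rdname run_pipeline
#' @export
config_hash <- function(config) hash_object(unclass_recursive(config))

unclass_recursive <- function(x) {
  x <- unclass(x)
  if (is.list(x)) x[] <- lapply(x, unclass_recursive)
  x
}

#' Validate pipeline input tables
#'
#' Schema, range and partition checks on the tract/block (and
#' optionally HOLC/mortgage) tables: non-negative populations, workers
#' not exceeding population, proportions within `[0, 1]`, racial/ethnic
#' group counts summing to the tract population, and block populations
#' partitioning tract populations exactly. Each failure is reported as
#' one row naming the table and offending row.
#'
#' @param tables Named list with `tracts` and `blocks` (data.frames),
#'   optionally `holc` and `mortgage`.
#' @return A data.frame of violations (`table`, `row`, `message`);
#'   zero rows when everything checks out.
#' @export
validate_inputs <- function(tables) {
  v <- list()
  bad <- function(tab, row, msg)
    v[[length(v) + 1L]] <<- data.frame(table = tab, row = row, message = msg,
                                       stringsAsFactors = FALSE)
  tr <- tables$tracts
  if (!is.null(tr)) {
    for (i in which(tr$population < 0))
      bad("tracts", i, "negative population")
    for (i in which(tr$workers > tr$population))
      bad("tracts", i, "workers exceed population")
    for (col in c("pct_unemployed", "pct_low_income", "pct_no_diploma")) {
      for (i in which(tr[[col]] < 0 | tr[[col]] > 1))
        bad("tracts", i, sprintf("%s outside [0, 1]", col))
    }
    rc <- intersect(race_columns(), names(tr))
    if (length(rc) == length(race_columns())) {
      rs <- rowSums(tr[, rc])
      for (i in which(rs != tr$population))
        bad("tracts", i, "racial/ethnic group counts do not sum to population")
    }
  }
  bl <- tables$blocks
  if (!is.null(bl)) {
    for (i in which(bl$population < 0))
      bad("blocks", i, "negative population")
    if (!is.null(tr)) {
      sums <- tapply(bl$population, bl$tract_id, sum)
      for (tid in names(sums)) {
        j <- match(tid, tr$tract_id)
        if (!is.na(j) && sums[[tid]] != tr$population[j])
          bad("blocks", j,
              sprintf("block populations for tract %s sum to %d, expected %d",
                      tid, sums[[tid]], tr$population[j]))
      }
    }
  }
  ho <- tables$holc
  if (!is.null(ho) && nrow(ho)) {
    tot <- ho$overlap_a + ho$overlap_b + ho$overlap_c + ho$overlap_d
    for (i in which(tot > 1 + 1e-9))
      bad("holc", i, "overlap proportions sum to more than 1")
  }
  mo <- tables$mortgage
  if (!is.null(mo) && nrow(mo)) {
    for (i in which(mo$loans_minority > mo$loans_total))
      bad("mortgage", i, "minority loans exceed total loans")
  }
  if (length(v) == 0L)
    return(data.frame(table = character(), row = integer(),
                      message = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}
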