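#' Configuration of a full analysis run
#'
#' Bundles the input (a path to a participant-level trial CSV or a
#' [trial_config()] to generate one), the endpoints, the number of
#' imputations, all seeds, the composite-endpoint hierarchy and the output
#' directory. All seeds are recorded in the output manifest; a rerun with
#' the same configuration is bit-identical.
#'
#' @param input Path to a trial CSV, or a [trial_config()].
#' @param endpoints Endpoints analyzed (default all four).
#' @param m Number of imputations for the bundled pipeline (default 20;
#'   [impute_endpoint()] itself defaults to 100 and supports up to 1000).
#' @param seed_imputation,seed_bootstrap Integer seeds for the imputation
#'   draws and the win-ratio bootstrap.
#' @param boot_B Win-ratio bootstrap resamples per imputation (default 500).
#' @param hierarchy A [hierarchy_spec()].
#' @param alpha Two-sided significance level (default 0.05; no multiplicity
#'   adjustment).
#' @param outdir Output directory for the report bundle.
#' @return An `analysis_config` object.
#' @export
analysis_config <- function(input = trial_config(),
                            endpoints = ENDPOINTS,
                            m = 20,
                            seed_imputation = 2,
                            seed_bootstrap = 3,
                            boot_B = 500,
                            hierarchy = hierarchy_spec(),
                            alpha = 0.05,
                            outdir = "hfpef-report") {
  stopifnot(all(endpoints %in% ENDPOINTS))
  if (m < 2) stop("m must be >= 2", call. = FALSE)
  if (m < 10) warning("m below recommended (>= 10) for stable pooling")
  structure(list(input = input, endpoints = endpoints, m = m,
                 seed_imputation = seed_imputation,
                 seed_bootstrap = seed_bootstrap, boot_B = boot_B,
                 hierarchy = hierarchy, alpha = alpha, outdir = outdir),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Recognized top-level keys: `input` (path), `generator` (arguments of
#' [trial_config()]), `endpoints`, `m`, `seed_imputation`, `seed_bootstrap`,
#' `boot_B`, `hierarchy` (arguments of [hierarchy_spec()]), `alpha`,
#' `outdir`. `input` and `generator` are mutually exclusive.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (!is.null(y$input) && !is.null(y$generator)) {
    stop("config must give either 'input' or 'generator', not both",
         call. = FALSE)
  }
  input <- if (!is.null(y$input)) y$input else
    do.call(trial_config, if (is.null(y$generator)) list() else y$generator)
  hier <- if (is.null(y$hierarchy)) hierarchy_spec() else {
    h <- y$hierarchy
    if (!is.null(h$kccq_thresholds)) h$kccq_thresholds <-
        as.numeric(unlist(h$kccq_thresholds))
    do.call(hierarchy_spec, h)
  }
  args <- list(input = input, hierarchy = hier)
  for (k in c("endpoints", "m", "seed_imputation", "seed_bootstrap",
              "boot_B", "alpha", "outdir")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(analysis_config, args)
}

stage_msg <- function(...) message("[hfpeftrial] ", sprintf(...))

#' Run the full analysis pipeline and write a report bundle
#'
#' Orchestrates generation/loading, baseline trend table, intention-to-treat
#' (multiply imputed) and on-treatment subgroup ETD tables, the per-class
#' win ratios with Cochran's Q, the dose-response tables (continuous Models
#' 1 and 2, ordinal categories, observed category counts), baseline
#' BMI-association regressions and death/HF-event rates per 100
#' patient-years, and writes everything as plain CSV plus a JSON manifest
#' (configuration hash, seeds, version, record counts).
#'
#' @param config An [analysis_config()].
#' @return Invisibly, a list with all result objects and output paths.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  cfg <- config
  if (is.character(cfg$input) && !file.exists(cfg$input)) {
    stop("input file not found: ", cfg$input, call. = FALSE)
  }
  if (is.character(cfg$input)) {
    df <- read_trial_csv(cfg$input)
    provenance <- list(source = cfg$input)
    stage_msg("loaded %d records from %s", nrow(df), cfg$input)
  } else {
    df <- generate_trial(cfg$input)
    provenance <- list(generator_seed = cfg$input$seed,
                       n_per_arm = cfg$input$n_per_arm)
    stage_msg("generated %d records (seed %d)", nrow(df),
              as.integer(cfg$input$seed))
  }
  issues <- validate_trial(df)
  if (nrow(issues)) {
    stop("input fails validation: ", issues$message[1], " (",
         issues$participant_id[1], ")", call. = FALSE)
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$outdir, f)
  results <- list()

  bt <- baseline_trend_table(df)
  utils::write.csv(bt, out("baseline_table.csv"), row.names = FALSE)
  stage_msg("baseline trend table: %d variables", nrow(bt))
  results$baseline <- bt

  itt_rows <- list()
  ot_rows <- list()
  for (ep in cfg$endpoints) {
    imp <- impute_endpoint(df, ep, m = cfg$m, seed = cfg$seed_imputation)
    eff <- subgroup_etds_mi(imp, ep)
    tab <- eff$table
    tab <- cbind(endpoint = ep, tab,
                 interaction_p = eff$interaction$p, scale = eff$scale)
    itt_rows[[ep]] <- tab
    ot <- subgroup_etds_on_treatment(df, ep)
    ot_rows[[ep]] <- cbind(endpoint = ep, ot$table,
                           interaction_p = ot$interaction$p, scale = ot$scale)
    stage_msg("subgroup ETDs for %s: ITT (m = %d) and on-treatment", ep,
              cfg$m)
  }
  itt <- do.call(rbind, itt_rows)
  ot <- do.call(rbind, ot_rows)
  utils::write.csv(itt, out("subgroup_effects_itt.csv"), row.names = FALSE)
  utils::write.csv(ot, out("subgroup_effects_on_treatment.csv"),
                   row.names = FALSE)
  results$subgroup_itt <- itt
  results$subgroup_on_treatment <- ot

  imp_wr <- impute_endpoint(df, c("kccq", "sixmwd"), m = cfg$m,
                            seed = cfg$seed_imputation + 1)
  wrs <- lapply(BMI_CLASS_LEVELS, function(k) {
    win_ratio_mi(imp_wr, cfg$hierarchy, stratum = k, B = cfg$boot_B,
                 seed = cfg$seed_bootstrap)
  })
  q <- cochran_q_winratio(wrs)
  wr_tab <- do.call(rbind, lapply(wrs, function(w) {
    data.frame(stratum = w$stratum, n_treated = w$n_treated,
               n_control = w$n_control, wins = w$wins, losses = w$losses,
               ties = w$ties, wr = w$wr, ci_low = w$ci_low,
               ci_high = w$ci_high)
  }))
  wr_tab <- rbind(wr_tab,
                  data.frame(stratum = "Q-test", n_treated = NA,
                             n_control = NA, wins = NA, losses = NA,
                             ties = NA, wr = q$Q, ci_low = NA,
                             ci_high = q$p))
  utils::write.csv(wr_tab, out("win_ratio.csv"), row.names = FALSE)
  stage_msg("win ratio by class: Q = %.3g, p = %.3g", q$Q, q$p)
  results$win_ratio <- wrs
  results$win_ratio_q <- q

  dr_rows <- list()
  for (ep in intersect(cfg$endpoints, c("kccq", "sixmwd", "crp"))) {
    for (mod in c("model1", "model2")) {
      f <- fit_dose_response(df, ep, mod)
      dr_rows[[paste(ep, mod)]] <- data.frame(
        endpoint = ep, model = mod, slope_per_10pct = f$slope_per_10pct,
        ci_low = f$ci_low, ci_high = f$ci_high, p = f$p, n = f$n_used,
        scale = f$scale)
    }
  }
  dr <- do.call(rbind, dr_rows)
  utils::write.csv(dr, out("dose_response.csv"), row.names = FALSE)
  results$dose_response <- dr
  stage_msg("dose-response regressions: %d fits", nrow(dr))

  wcc <- weight_category_counts(df)
  utils::write.csv(wcc, out("weight_categories.csv"), row.names = FALSE)
  results$weight_categories <- wcc

  ord <- fit_ordinal_categories(df, "kccq")
  ord_tab <- cbind(ord$table, linearity_p = ord$linearity_p)
  utils::write.csv(ord_tab, out("ordinal_categories_kccq.csv"),
                   row.names = FALSE)
  results$ordinal_kccq <- ord

  ba_rows <- lapply(c("kccq", "sixmwd", "crp"), function(ep) {
    f <- fit_baseline_association(df, ep)
    data.frame(endpoint = ep, slope_per_unit_bmi = f$slope_per_10pct,
               ci_low = f$ci_low, ci_high = f$ci_high, p = f$p,
               scale = f$scale)
  })
  ba <- do.call(rbind, ba_rows)
  utils::write.csv(ba, out("baseline_associations.csv"), row.names = FALSE)
  results$baseline_associations <- ba

  ae <- ae_rate_table(df)
  utils::write.csv(ae, out("event_rates.csv"), row.names = FALSE)
  results$event_rates <- ae

  cfg_json <- jsonlite::toJSON(list(
    endpoints = cfg$endpoints, m = cfg$m,
    seed_imputation = cfg$seed_imputation,
    seed_bootstrap = cfg$seed_bootstrap, boot_B = cfg$boot_B,
    alpha = cfg$alpha, provenance = provenance,
    hierarchy = vapply(cfg$hierarchy, level_label, character(1))),
    auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "hfpeftrial",
    version = as.character(utils::packageVersion("hfpeftrial")),
    config = jsonlite::fromJSON(cfg_json),
    config_hash = unname(tools::md5sum(textConnection_md5(cfg_json))),
    n_records = nrow(df),
    n_per_arm = as.list(table(df$arm)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  stage_msg("report bundle written to %s", cfg$outdir)
  results$manifest <- manifest
  results$outdir <- cfg$outdir
  invisible(results)
}

# md5 of an in-memory string via a temp file (tools::md5sum wants a path)
textConnection_md5 <- function(txt) {
  tf <- tempfile()
  writeLines(as.character(txt), tf)
  tf
}

# death and HF-event rates per 100 patient-years by class and arm
ae_rate_table <- function(df) {
  cls <- assign_bmi_class(df$bmi)
  ev <- parse_event_days(df$hf_event_days)
  rows <- list()
  for (k in levels(cls)) {
    for (a in levels(df$arm)) {
      idx <- cls == k & df$arm == a
      py <- sum(df$observation_days[idx]) / 365.25
      rows[[paste(k, a)]] <- data.frame(
        bmi_class = k, arm = a, n = sum(idx),
        patient_years = py,
        death_rate = adverse_event_rate(sum(!is.na(df$death_day[idx])), py),
        hf_event_rate = adverse_event_rate(sum(lengths(ev[idx])), py))
    }
  }
  do.call(rbind, rows)
}
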