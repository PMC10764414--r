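#' Pipeline configuration
#'
#' One declarative configuration for the whole analysis: either a CSV
#' panel path (`input`) or `synthetic = TRUE` (with optional
#' [synthetic_config()] arguments in `synthetic_args`), frontier
#' options, DID options, placebo options, an optional output
#' directory and a seed.  `pipeline_config()` normalises a plain list
#' or a YAML file into validated form.
#'
#' @param x a named list of options, or the path of a YAML file
#'   holding one.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x) && length(x) == 1L) {
    x <- yaml::read_yaml(x)
  }
  stopifnot(is.list(x))
  cfg <- list(
    input = x$input %||% NULL,
    synthetic = isTRUE(x$synthetic) || is.null(x$input),
    synthetic_args = x$synthetic_args %||% list(),
    batches = x$batches %||% NULL,
    rts = x$rts %||% "CRS",
    pooling = x$pooling %||% "pooled_years",
    controls = x$controls %||% control_cols(),
    se_type = x$se_type %||% "conventional",
    n_perm = x$n_perm %||% 1000L,
    out_dir = x$out_dir %||% NULL,
    seed = x$seed %||% 1L,
    quiet = isTRUE(x$quiet)
  )
  if (!is.null(cfg$input) && cfg$synthetic) {
    stop_mraedid("exactly one of input path or synthetic mode must be active",
                 "config_error")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full two-stage pipeline
#'
#' Executes panel load/generation, treatment assignment, group and
#' meta-frontier scoring, technology-gap-ratio decomposition, regional
#' summaries, the benchmark DID regression, the event study, the
#' permutation placebo (skipped when `n_perm = 0`), heterogeneity
#' subgroup fits and VIF diagnostics, logging each stage.  When
#' `out_dir` is set, the standard artifacts are written there
#' (`efficiency.csv`, `table2_summary.csv`, `did_results.json`,
#' `event_study.csv`, `placebo_coefs.csv`, `vif.json`,
#' `density_summary.json`).
#'
#' @param config a [pipeline_config()] (or a list / YAML path coerced
#'   through it).
#' @return a `report_bundle` list with all stage outputs.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  say <- function(...) if (!config$quiet) message("[mraedid] ", ...)
  set.seed(config$seed)
  t0 <- Sys.time()

  if (config$synthetic) {
    say("generating synthetic panel (seed ", config$seed, ")")
    sargs <- config$synthetic_args
    sargs$seed <- sargs$seed %||% config$seed
    panel <- generate_panel(do.call(synthetic_config, sargs))
  } else {
    say("reading panel from ", config$input)
    panel <- read_panel(config$input)
    batches <- config$batches %||% batches_from_column(panel)
    panel <- attach_treatment(panel, batches)
  }
  grouping <- region_grouping(panel)

  say("scoring meta-frontier (", nrow(panel), " unit-periods)")
  meta <- meta_efficiencies(panel, pooling = config$pooling, rts = config$rts)
  say("scoring group frontiers")
  group <- group_efficiencies(panel, grouping, pooling = config$pooling,
                              rts = config$rts)
  tgr <- technology_gap_ratio(meta, group)
  summary2 <- render_table2(list(tgr = tgr, grouping = grouping))

  dens <- lapply(sort(unique(meta$year)), function(y)
    density_summary(meta, y))

  df <- as.data.frame(panel)
  df$mrae <- meta$efficiency[match(paste(df$province, df$year),
                                   paste(meta$province, meta$year))]
  spec <- did_spec(outcome = "mrae", controls = config$controls,
                   se_type = config$se_type)
  say("fitting two-way FE DID")
  did <- fit_twfe_did(df, spec)
  say("fitting event study")
  # widest window the panel supports, capped at the 6 + 6 benchmark
  by <- df$batch_year[!is.na(df$batch_year)]
  leads <- max(1L, min(6L, max(by) - min(df$year) - 1L))
  lags <- max(1L, min(6L, max(df$year) - min(by) + 1L))
  event <- fit_event_study(df, spec, leads = leads, lags = lags)
  placebo <- NULL
  if (config$n_perm > 0) {
    say("placebo test (", config$n_perm, " permutations)")
    placebo <- placebo_test(df, spec, n_perm = config$n_perm,
                            seed = config$seed + 1L)
  }
  say("heterogeneity subgroups")
  subgroups <- list(
    region = try_subgroup(df, spec, split_by_region),
    mrae_median = try_subgroup(df, spec,
                               function(d) split_by_median(d, "mrae")),
    population_median = try_subgroup(df, spec,
                                     function(d) split_by_median(d, "lnPOP"))
  )
  vif <- compute_vif(df, c("du_dt", config$controls))

  bundle <- structure(list(
    panel = panel, meta = meta, group = group, tgr = tgr,
    table2 = summary2, density = dens, did = did, event_study = event,
    placebo = placebo, subgroups = subgroups, vif = vif,
    grouping = grouping, config = config), class = "report_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  say(sprintf("done in %.1f s", as.numeric(Sys.time() - t0, units = "secs")))
  bundle
}

# subgroup fits may be legitimately inestimable (e.g. no treated
# province in a region of a user panel); record the reason instead of
# aborting the whole run
try_subgroup <- function(df, spec, splitter) {
  tryCatch(subgroup_did(df, spec, splitter),
           mraedid_error = function(e) conditionMessage(e))
}

batches_from_column <- function(panel) {
  df <- as.data.frame(panel)
  first <- !duplicated(df$province)
  tb <- df$treat_batch[first]
  prov <- df$province[first]
  out <- split(prov[tb != "never"], tb[tb != "never"])
  lapply(out, identity)
}

#' Provincial summary table (meta / group / TGR)
#'
#' Renders the per-province time means of meta-frontier efficiency,
#' group-frontier efficiency and TGR, with unweighted regional and
#' overall averages, all displayed to 3 decimals (rounded half away
#' from zero; averages computed from unrounded province means).
#'
#' @param bundle a `report_bundle`, or any list with elements `tgr`
#'   (a TGR table) and `grouping` (province -> region).
#' @return data frame with columns `province`, `region`, `meta`,
#'   `group`, `tgr`; regional rows carry `province = "Average"`.
#' @export
render_table2 <- function(bundle) {
  tgr <- bundle$tgr
  grouping <- bundle$grouping
  if (is.null(tgr) || is.null(grouping)) {
    stop_mraedid("bundle lacks tgr table or grouping", "reporting_error")
  }
  pm <- function(col) tapply(tgr[[col]], tgr$province, mean)
  prov <- sort(unique(tgr$province))
  tab <- data.frame(province = prov,
                    region = unname(grouping[prov]),
                    meta = as.numeric(pm("e_meta")[prov]),
                    group = as.numeric(pm("e_group")[prov]),
                    tgr = as.numeric(pm("tgr")[prov]),
                    stringsAsFactors = FALSE)
  rows <- list()
  for (rg in unique(tab$region)) {
    sub <- tab[tab$region == rg, ]
    rows[[rg]] <- data.frame(province = "Average", region = rg,
                             meta = mean(sub$meta), group = mean(sub$group),
                             tgr = mean(sub$tgr), stringsAsFactors = FALSE)
  }
  rows$Overall <- data.frame(province = "Average", region = "Overall",
                             meta = mean(tab$meta), group = mean(tab$group),
                             tgr = mean(tab$tgr), stringsAsFactors = FALSE)
  out <- rbind(tab, do.call(rbind, rows))
  for (cl in c("meta", "group", "tgr")) {
    out[[cl]] <- round_half_away(out[[cl]], 3)
  }
  rownames(out) <- NULL
  out
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                        row.names = FALSE)
  w(bundle$tgr, "efficiency.csv")
  w(bundle$table2, "table2_summary.csv")
  w(bundle$event_study$coefficients, "event_study.csv")
  did <- bundle$did
  jsonlite::write_json(list(
    alpha1 = did$alpha1, se_alpha1 = did$se_alpha1,
    t_alpha1 = did$t_alpha1, p_alpha1 = did$p_alpha1,
    alpha0 = did$alpha0, beta = as.list(did$beta),
    r_squared = did$r_squared, n_obs = did$n_obs,
    unit_fe = did$spec$unit_fe, time_fe = did$spec$time_fe,
    se_type = did$spec$se_type),
    file.path(out_dir, "did_results.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$placebo)) {
    w(data.frame(coef = bundle$placebo$perm_coefs,
                 p = bundle$placebo$perm_pvalues), "placebo_coefs.csv")
  }
  jsonlite::write_json(as.list(bundle$vif), file.path(out_dir, "vif.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$density,
                       file.path(out_dir, "density_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
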