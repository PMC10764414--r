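#' @title Province-year panel schema
#' @description
#' The pipeline operates on a balanced province-by-year panel with four
#' inputs (HE health expenditure, HP health personnel, MIB medical
#' institution beds, MI medical institutions), three desirable outputs
#' (OV outpatient visits, DR discharge rate, BU bed utilization), two
#' undesirable outputs (MOR observation-room mortality, EM emergency
#' mortality), five controls (lnPGDP, lnPOP, Gov, Idu, lnPat), a region
#' label and a treatment-batch label (`"2015"`, `"2016"` or `"never"`).
#'
#' Helper constants name the column groups so that downstream modules
#' never hard-code positions.
#' @name panel-schema
NULL

input_cols <- function() c("HE", "HP", "MIB", "MI")
desirable_cols <- function() c("OV", "DR", "BU")
undesirable_cols <- function() c("MOR", "EM")
control_cols <- function() c("lnPGDP", "lnPOP", "Gov", "Idu", "lnPat")

panel_cols <- function() {
  c("province", "year", "region",
    input_cols(), desirable_cols(), undesirable_cols(), control_cols(),
    "treat_batch")
}

#' Construct a validated province panel
#'
#' Coerces a data frame with the canonical columns (see
#' [panel-schema]) into a `province_panel`, normalising column order
#' and sorting rows by province then year.  Fails if the panel breaks
#' a structural invariant: any strictly-positive quantity at or below
#' zero, a percentage outside `(0, 100]`, `Gov` outside `(0, 1)`,
#' duplicate `(province, year)` keys, or an unbalanced design.
#'
#' @param df data frame holding the canonical columns.
#' @return a `province_panel` (a data frame with attributes
#'   `provinces` and `years`).
#' @export
province_panel <- function(df) {
  miss <- setdiff(panel_cols(), names(df))
  if (length(miss)) {
    stop_mraedid(paste0("missing panel column(s): ",
                        paste(miss, collapse = ", ")),
                 "panel_schema_error", list(columns = miss))
  }
  df <- as.data.frame(df)[, panel_cols()]
  df$province <- as.character(df$province)
  df$region <- as.character(df$region)
  df$treat_batch <- as.character(df$treat_batch)
  num_cols <- setdiff(panel_cols(), c("province", "region", "treat_batch"))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad)) {
      stop_mraedid(sprintf("non-numeric or missing value in '%s' (row %d)",
                           cl, bad[1]),
                   "panel_validation_error")
    }
    df[[cl]] <- v
  }
  df$year <- as.integer(df$year)
  df <- df[order(df$province, df$year), , drop = FALSE]
  rownames(df) <- NULL

  rep <- validate_panel_df(df)
  if (nrow(rep)) {
    stop_mraedid(paste0("invalid panel: ", rep$message[1],
                        " (", rep$province[1], ", ", rep$year[1], ")",
                        if (nrow(rep) > 1)
                          sprintf(" and %d more violation(s)", nrow(rep) - 1)
                        else ""),
                 "panel_validation_error", list(report = rep))
  }
  check_balance(df)
  structure(df,
            provinces = unique(df$province),
            years = sort(unique(df$year)),
            class = c("province_panel", "data.frame"))
}

check_balance <- function(df) {
  provs <- unique(df$province)
  yrs <- sort(unique(df$year))
  full <- expand.grid(province = provs, year = yrs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(df$province, df$year)
  fkey <- paste(full$province, full$year)
  missing <- full[!(fkey %in% key), , drop = FALSE]
  if (nrow(missing)) {
    stop_mraedid(
      paste0("unbalanced panel; missing (province, year) pairs: ",
             paste(sprintf("(%s, %d)", missing$province, missing$year),
                   collapse = ", ")),
      "panel_balance_error", list(missing = missing))
  }
  invisible(TRUE)
}

# invariant scan shared by province_panel() and validate_panel()
validate_panel_df <- function(df) {
  out <- list()
  note <- function(rows, field, msg) {
    if (length(rows)) {
      out[[length(out) + 1L]] <<- data.frame(
        province = df$province[rows], year = df$year[rows],
        field = field, message = msg, stringsAsFactors = FALSE)
    }
  }
  for (cl in input_cols()) {
    note(which(df[[cl]] <= 0), cl, "input must be > 0")
  }
  for (cl in desirable_cols()) {
    note(which(df[[cl]] <= 0), cl, "desirable output must be > 0")
  }
  for (cl in undesirable_cols()) {
    note(which(df[[cl]] <= 0), cl, "undesirable output must be > 0")
  }
  for (cl in c("DR", "BU")) {
    note(which(df[[cl]] > 100), cl, "percent out of range")
  }
  note(which(df$Gov <= 0 | df$Gov >= 1), "Gov", "ratio out of (0, 1)")
  note(which(!df$treat_batch %in% c("2015", "2016", "never")),
       "treat_batch", "must be one of 2015, 2016, never")
  dup <- which(duplicated(df[, c("province", "year")]))
  note(dup, "province", "duplicate (province, year) key")
  reg <- tapply(df$region, df$province,
                function(r) length(unique(r)) > 1)
  bad_reg <- which(df$province %in% names(reg)[reg])
  note(bad_reg[!duplicated(df$province[bad_reg])], "region",
       "region must be constant within province")
  if (!length(out)) {
    return(data.frame(province = character(), year = integer(),
                      field = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Validate a panel without raising
#'
#' Scans a data frame in the panel schema and reports every violated
#' invariant with its record coordinates.  An empty report means the
#' panel is valid.
#'
#' @param panel a `province_panel` or plain data frame with the
#'   canonical columns.
#' @return data frame with columns `province`, `year`, `field`,
#'   `message`; zero rows iff valid.
#' @export
validate_panel <- function(panel) {
  df <- as.data.frame(panel)
  validate_panel_df(df)
}

#' Read / write a panel CSV
#'
#' `read_panel()` loads a comma-separated, UTF-8, header-first file in
#' the canonical schema (optionally renaming columns through `schema`,
#' a named character vector `canonical = file_column`) and returns a
#' validated balanced [province_panel()].  `write_panel()` writes one
#' back; the two are inverse on valid panels.
#'
#' @param path CSV file path.
#' @param schema optional named character vector mapping canonical
#'   column names to the names used in the file.
#' @return `read_panel()`: a `province_panel`; `write_panel()`: the
#'   path, invisibly.
#' @export
read_panel <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    stop_mraedid(paste0("no such file: ", path), "panel_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df)) {
        stop_mraedid(sprintf("schema column '%s' (for '%s') not in file",
                             src, canon), "panel_schema_error")
      }
      names(df)[names(df) == src] <- canon
    }
  }
  province_panel(df)
}

#' @rdname read_panel
#' @param panel a `province_panel`.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel)[, panel_cols()], path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Staggered treatment indicators
#'
#' Builds the ever-treated flag `du`, the post-adoption flag `dt` and
#' their product `du_dt` for a staggered design with batch-year
#' adoption.  `dt` switches on in the adoption calendar year itself
#' (annual data cannot resolve months) and stays on.
#'
#' @param panel a `province_panel`.
#' @param batches named list mapping a batch year (as name) to a
#'   character vector of province labels, e.g.
#'   `list("2015" = c("P01"), "2016" = c("P02", "P03"))`.  An empty
#'   list yields an all-zero `du_dt`.
#' @return data frame (class `treatment_indicators`) with one row per
#'   province-year: `province`, `year`, `batch_year` (`NA` for never
#'   treated), `du`, `dt`, `du_dt`.
#' @export
assign_treatment <- function(panel, batches = cmrp_batches()) {
  stopifnot(inherits(panel, "province_panel"))
  provs <- attr(panel, "provinces")
  yrs <- attr(panel, "years")
  batch_year <- stats::setNames(rep(NA_integer_, length(provs)), provs)
  for (by in names(batches)) {
    y <- as.integer(by)
    listed <- batches[[by]]
    unknown <- setdiff(listed, provs)
    if (length(unknown)) {
      stop_mraedid(paste0("unknown province(s) in batch ", by, ": ",
                          paste(unknown, collapse = ", ")),
                   "treatment_lookup_error")
    }
    if (y < min(yrs) || y > max(yrs)) {
      stop_mraedid(sprintf("batch year %d outside panel range %d-%d",
                           y, min(yrs), max(yrs)),
                   "treatment_range_error")
    }
    dup <- listed[!is.na(batch_year[listed])]
    if (length(dup)) {
      stop_mraedid(paste0("province listed in two batches: ",
                          paste(dup, collapse = ", ")),
                   "treatment_lookup_error")
    }
    batch_year[listed] <- y
  }
  ind <- data.frame(
    province = rep(provs, each = length(yrs)),
    year = rep(yrs, times = length(provs)),
    stringsAsFactors = FALSE)
  ind$batch_year <- batch_year[ind$province]
  ind$du <- as.integer(!is.na(ind$batch_year))
  ind$dt <- as.integer(!is.na(ind$batch_year) & ind$year >= ind$batch_year)
  ind$du_dt <- ind$du * ind$dt
  class(ind) <- c("treatment_indicators", "data.frame")
  ind
}

#' Attach treatment indicator columns to a panel
#'
#' Convenience wrapper around [assign_treatment()] that merges `du`,
#' `dt`, `du_dt` (and `batch_year`) into the panel and rewrites
#' `treat_batch` accordingly.
#'
#' @inheritParams assign_treatment
#' @return the panel with indicator columns appended.
#' @export
attach_treatment <- function(panel, batches = cmrp_batches()) {
  ind <- assign_treatment(panel, batches)
  df <- as.data.frame(panel)
  df$du <- NULL; df$dt <- NULL; df$du_dt <- NULL; df$batch_year <- NULL
  df <- merge(df, ind, by = c("province", "year"), sort = FALSE)
  df$treat_batch <- ifelse(is.na(df$batch_year), "never",
                           as.character(df$batch_year))
  df <- df[order(df$province, df$year), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            provinces = attr(panel, "provinces"),
            years = attr(panel, "years"),
            class = c("province_panel", "data.frame"))
}

#' Pilot batches of China's comprehensive medical reform
#'
#' The two staggered batches of pilot provinces: four provinces from
#' January 2015 (Jiangsu, Anhui, Fujian, Qinghai) and seven more from
#' May 2016 (Shanghai, Zhejiang, Hunan, Chongqing, Sichuan, Shaanxi,
#' Ningxia) — eleven pilot provinces in all.
#'
#' @return named list mapping batch year to province names.
#' @export
cmrp_batches <- function() {
  list(
    "2015" = c("Jiangsu", "Anhui", "Fujian", "Qinghai"),
    "2016" = c("Shanghai", "Zhejiang", "Hunan", "Chongqing",
               "Sichuan", "Shaanxi", "Ningxia")
  )
}

#' Published provincial mean efficiency scores
#'
#' Bundled reference table of mean medical-resource-allocation
#' efficiency scores for 30 Chinese provinces over 2009-2021 under the
#' meta-frontier and the regional group frontier, with the
#' East/Central/West region partition (11/8/11 provinces).  Used by
#' worked examples and by regression tests of the aggregation
#' utilities (the technology gap ratio and regional means are pure
#' arithmetic on these columns).
#'
#' @return data frame with columns `province`, `region`, `meta`,
#'   `group`.
#' @export
china_mrae_table <- function() {
  path <- system.file("extdata", "china_mrae_2009_2021.csv",
                      package = "mraedid", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
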