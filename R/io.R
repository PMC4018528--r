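# CSV/JSON exchange. Time-course CSV dialect: replicate_id, time_min,
# value_pct. Configuration JSON is flat with units tagged in the key names
# (the source literature mixes M, uM, nM, s and min; unit-tagged keys
# prevent silent conversion errors).

#' Read and write time-course CSV files
#'
#' Schema-validated round-trippable CSV with columns `replicate_id`,
#' `time_min`, `value_pct`. Validation errors name the offending data row.
#'
#' @param path file path.
#' @return `read_timecourse()`: a [timecourse()].
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty input file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("no observations in ", path)
  validate_timecourse(df, paste0("'", path, "'"))
}

#' @rdname read_timecourse
#' @param tc a [timecourse()].
#' @export
write_timecourse <- function(tc, path) {
  tc <- validate_timecourse(tc)
  write.csv(tc, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a trajectory as long-format CSV
#'
#' Columns `time_min`, `species`, `value_uM` (protein reported in AU).
#'
#' @param trajectory a `model_trajectory` from [simulate_model()].
#' @param path file path.
#' @export
write_trajectory <- function(trajectory, path) {
  long <- do.call(rbind, lapply(.species_names, function(sp)
    data.frame(time_min = trajectory$time_min, species = sp,
               value_uM = trajectory[[sp]])))
  write.csv(format(long, digits = 8, trim = TRUE, scientific = NA),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default model configuration
#'
#' Flat configuration list with unit-tagged keys mirroring
#' [rate_parameters()] and [totals()].
#'
#' @return named list.
#' @export
default_config <- function() {
  p <- rate_parameters(); tt <- totals()
  list(k_on1_per_uM_s = p[["k_on1"]], k_off1_per_s = p[["k_off1"]],
       k_on2_per_uM_s = p[["k_on2"]], k_off2_per_s = p[["k_off2"]],
       k_cat_4ebp_per_s = p[["k_cat_4ebp"]],
       k_lys_4ebp_per_s = p[["k_lys_4ebp"]],
       k_cat_protein_per_s = p[["k_cat_protein"]],
       total_4ebp_uM = tt[["total_4ebp"]],
       total_eif4e_uM = tt[["total_eif4e"]],
       total_eif4g_uM = tt[["total_eif4g"]])
}

#' Read a configuration JSON
#'
#' Missing keys fall back to the defaults of [default_config()]; unknown
#' keys are rejected.
#'
#' @param path JSON file path (`NULL` returns the defaults).
#' @return list with elements `params` ([rate_parameters()]) and `tot`
#'   ([totals()]).
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  list(params = rate_parameters(
         k_on1 = cfg$k_on1_per_uM_s, k_off1 = cfg$k_off1_per_s,
         k_on2 = cfg$k_on2_per_uM_s, k_off2 = cfg$k_off2_per_s,
         k_cat_4ebp = cfg$k_cat_4ebp_per_s,
         k_lys_4ebp = cfg$k_lys_4ebp_per_s,
         k_cat_protein = cfg$k_cat_protein_per_s),
       tot = totals(cfg$total_4ebp_uM, cfg$total_eif4e_uM,
                    cfg$total_eif4g_uM),
       raw = cfg)
}

# Machine-readable provenance record written next to every CLI output.
write_provenance <- function(path, config, seed = NULL, extra = list()) {
  rec <- c(list(package = "capinit",
                version = as.character(packageVersion("capinit")),
                seed = seed, config = config), extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
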