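# CSV schemas used across the pipeline. Column names carry units where a
# unit bug would be silent (concentrations mg/L, volumes uL, time h).
mixtk_schemas <- list(
  dose_response = list(
    columns = c(compound = "character", conc = "numeric",
                viability = "numeric", bio_rep = "character",
                tech_rep = "character"),
    checks = list(
      list(test = function(d) d$conc >= 0,
           msg = "negative concentration")),
    key = c("compound", "conc", "bio_rep", "tech_rep")),
  transport = list(
    columns = c(analyte = "character", direction = "character",
                replicate = "character", t_h = "numeric",
                c_receiver_mg_l = "numeric", donor_c0_mg_l = "numeric",
                v_donor_ul = "numeric", v_receiver_ul = "numeric",
                v_sample_ul = "numeric"),
    checks = list(
      list(test = function(d)
        d$direction %in% c("AP_to_BL", "BL_to_AP"),
        msg = "direction must be AP_to_BL or BL_to_AP"),
      list(test = function(d) d$donor_c0_mg_l > 0,
           msg = "donor_c0_mg_l must be > 0"),
      list(test = function(d) d$v_sample_ul < d$v_receiver_ul,
           msg = "sample volume not smaller than receiver volume")),
    key = c("analyte", "direction", "replicate", "t_h")),
  anisotropy = list(
    columns = c(condition = "character", replicate = "character",
                I_VV = "numeric", I_VH = "numeric", I_HV = "numeric",
                I_HH = "numeric"),
    checks = list(
      list(test = function(d)
        d$I_VV >= 0 & d$I_VH >= 0 & d$I_HV >= 0 & d$I_HH >= 0,
        msg = "negative intensity")),
    key = c("condition", "replicate")),
  atpase = list(
    columns = c(condition = "character", conc = "numeric",
                rlu = "numeric"),
    checks = list(
      list(test = function(d) d$rlu >= 0, msg = "negative RLU")),
    key = NULL))

#' Read and validate a pipeline CSV
#'
#' Reads a UTF-8, comma-separated, header-row CSV and validates it against
#' one of the pipeline schemas (\code{"dose_response"}, \code{"transport"},
#' \code{"anisotropy"}, \code{"atpase"}): required columns and types,
#' value constraints (e.g. non-negative concentrations), and duplicate
#' replicate keys. All violations are collected and reported together, with
#' offending row numbers.
#'
#' @param path CSV file path.
#' @param schema_id schema name.
#' @return the validated data.frame (for \code{"dose_response"}, a
#'   \code{\link{dr_data}}).
#' @export
read_validate <- function(path, schema_id = names(mixtk_schemas)) {
  schema_id <- match.arg(schema_id)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8")
  validate_table(d, schema_id, where = path)
}

#' Validate an in-memory table against a pipeline schema
#'
#' @param d data.frame.
#' @param schema_id schema name, see \code{\link{read_validate}}.
#' @param where label used in error messages.
#' @return the validated table.
#' @export
validate_table <- function(d, schema_id = names(mixtk_schemas),
                           where = "table") {
  schema_id <- match.arg(schema_id)
  sc <- mixtk_schemas[[schema_id]]
  problems <- character()
  miss <- setdiff(names(sc$columns), names(d))
  if (length(miss))
    problems <- c(problems,
                  paste("missing column(s):", paste(miss, collapse = ", ")))
  extra <- setdiff(names(d), names(sc$columns))
  if (length(extra))
    problems <- c(problems,
                  paste("unknown column(s):", paste(extra, collapse = ", ")))
  if (!length(miss)) {
    for (col in names(sc$columns)) {
      want <- sc$columns[[col]]
      if (want == "numeric" && !is.numeric(d[[col]]))
        problems <- c(problems, paste0("column '", col, "' must be numeric"))
    }
    for (chk in sc$checks) {
      ok <- tryCatch(chk$test(d), error = function(e) FALSE)
      if (!all(ok))
        problems <- c(problems, paste0(chk$msg, " (rows ",
          paste(utils::head(which(!ok), 5), collapse = ", "),
          if (sum(!ok) > 5) ", ..." else "", ")"))
    }
    if (!is.null(sc$key) && all(sc$key %in% names(d))) {
      dup <- duplicated(d[, sc$key])
      if (any(dup))
        problems <- c(problems, paste0("duplicate replicate key(s) (rows ",
          paste(utils::head(which(dup), 5), collapse = ", "), ")"))
    }
  }
  if (length(problems))
    stop("validation of ", where, " against schema '", schema_id,
         "' failed:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  if (schema_id == "dose_response") dr_data(d) else d
}

#' Write a pipeline CSV
#'
#' UTF-8, comma-separated, header row, period decimal separator; numeric
#' columns are written at 12 significant digits so round-trips are stable.
#'
#' @param d data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_csv12 <- function(d, path) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(x) signif(x, 12))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert raw assay signals to percent of control
#'
#' Viability normalisation: raw absorbance/fluorescence divided by the mean
#' of the (solvent) control wells, times 100.
#'
#' @param raw raw signals.
#' @param control_mean mean control signal (> 0).
#' @return percent of control.
#' @export
percent_of_control <- function(raw, control_mean) {
  check_scalar(control_mean, "control_mean", lower = 0,
               strict_lower = TRUE)
  100 * raw / control_mean
}

#' Serialise a transport series set to the transport CSV schema
#'
#' @param series_list list of \code{\link{transport_series}}.
#' @return data.frame in the \code{"transport"} schema (one row per sample
#'   event).
#' @export
transport_to_table <- function(series_list) {
  do.call(rbind, lapply(series_list, function(s)
    data.frame(analyte = s$analyte_id, direction = s$direction,
               replicate = s$replicate, t_h = s$samples$t,
               c_receiver_mg_l = s$samples$c_receiver,
               donor_c0_mg_l = s$donor_c0, v_donor_ul = s$V_donor,
               v_receiver_ul = s$V_receiver, v_sample_ul = s$v_sample)))
}

#' Build transport series from a transport-schema table
#'
#' @param d a validated table in the \code{"transport"} schema.
#' @return list of \code{\link{transport_series}}, one per analyte x
#'   direction x replicate.
#' @export
table_to_transport <- function(d) {
  d <- validate_table(d, "transport")
  sp <- split(d, list(d$analyte, d$direction, d$replicate), drop = TRUE)
  lapply(unname(sp), function(g) {
    g <- g[order(g$t_h), ]
    transport_series(analyte_id = g$analyte[1], direction = g$direction[1],
                     donor_c0 = g$donor_c0_mg_l[1],
                     V_donor = g$v_donor_ul[1],
                     V_receiver = g$v_receiver_ul[1],
                     v_sample = g$v_sample_ul[1], t = g$t_h,
                     c_receiver = g$c_receiver_mg_l,
                     replicate = g$replicate[1])
  })
}
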