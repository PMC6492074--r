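#' @include AllClasses.R pharmacology.R
NULL

.schemaError <- function(msg) {
  stop(structure(class = c("torsadeSchemaError", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

.hergCols <- c("Kmax", "Ku", "n", "halfmax", "Vhalf")

## permitted columns of the drug-table dialect; IC50 columns may be given
## in nM or uM, Cmax likewise
.drugTableCols <- function() {
  cur <- .blockableCurrents
  c("drug", "cmax_nM", "cmax_uM", .hergCols, "risk_label",
    paste0(rep(cur, each = 2), c("_IC50_nM", "_hill")),
    paste0(cur, "_IC50_uM"))
}

#' Read a drug block-parameter table
#'
#' Parses the drug-table CSV dialect: one row per drug with columns
#' `drug`, `cmax_nM` (or `cmax_uM`), the five dynamic hERG parameters
#' `Kmax, Ku, n, halfmax, Vhalf`, optional per-current Hill columns
#' `<current>_IC50_nM` (or `_uM`) and `<current>_hill`, and an optional
#' `risk_label`. Empty IC50 cells become the "no measurable block"
#' sentinel (IC50 = Inf); micromolar columns are converted to nM.
#'
#' @param path CSV file
#' @return list of [DrugRecord-class]
#' @export
readDrugTable <- function(path) {
  if (!file.exists(path)) .schemaError(paste("no such file:", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  unknown <- setdiff(names(tab), .drugTableCols())
  if (length(unknown))
    .schemaError(paste("unknown drug-table column(s):",
                       paste(unknown, collapse = ", ")))
  req <- c("drug", .hergCols)
  miss <- setdiff(req, names(tab))
  if (length(miss))
    .schemaError(paste("missing drug-table column(s):",
                       paste(miss, collapse = ", ")))
  if (!any(c("cmax_nM", "cmax_uM") %in% names(tab)))
    .schemaError("missing column cmax_nM (or cmax_uM)")
  if (anyDuplicated(tab$drug))
    .schemaError(paste("duplicated drug name(s):",
                       paste(unique(tab$drug[duplicated(tab$drug)]),
                             collapse = ", ")))
  cmax <- if ("cmax_nM" %in% names(tab)) tab$cmax_nM else tab$cmax_uM * 1000
  if (any(!is.finite(cmax) | cmax <= 0))
    stop("cmax must be positive for every drug", call. = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    herg <- hergDynamicParams(tab$Kmax[i], tab$Ku[i], tab$n[i],
                              tab$halfmax[i], tab$Vhalf[i])
    blocks <- list()
    for (cur in .blockableCurrents) {
      nmN <- paste0(cur, "_IC50_nM"); nmU <- paste0(cur, "_IC50_uM")
      ic <- if (nmN %in% names(tab)) tab[[nmN]][i]
            else if (nmU %in% names(tab)) tab[[nmU]][i] * 1000 else NA
      if (is.na(ic)) ic <- Inf   # empty cell: no measurable block
      hl <- tab[[paste0(cur, "_hill")]][i] %||% 1
      if (is.na(hl)) hl <- 1
      if (nmN %in% names(tab) || nmU %in% names(tab))
        blocks <- c(blocks, channelBlock(cur, ic, hl))
    }
    lab <- tab$risk_label[i] %||% NA_character_
    drugRecord(tab$drug[i], cmax[i], herg, blocks,
               if (is.na(lab) || !nzchar(lab)) NA_character_ else lab)
  })
}

#' Write a drug table in the CSV dialect read by [readDrugTable()]
#'
#' @param drugs list of [DrugRecord-class]
#' @param path output CSV
#' @return `path`, invisibly
#' @export
writeDrugTable <- function(drugs, path) {
  row1 <- function(d) {
    out <- data.frame(drug = d@name, cmax_nM = d@cmax, Kmax = d@herg@kmax,
                      Ku = d@herg@ku, n = d@herg@n, halfmax = d@herg@halfmax,
                      Vhalf = d@herg@vhalf, risk_label = d@riskLabel)
    for (b in d@blocks) {
      out[[paste0(b@current, "_IC50_nM")]] <-
        if (is.finite(b@ic50)) b@ic50 else NA
      out[[paste0(b@current, "_hill")]] <- b@hill
    }
    out
  }
  rows <- lapply(drugs, row1)
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) { r[setdiff(cols, names(r))] <- NA; r[cols] })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write per-cell concentration-response tables
#'
#' The per-cell dialect has columns `drug, current, cell_id, conc_nM,
#' frac_block`.
#'
#' @param path CSV file
#' @return data.frame of responses
#' @export
readCellResponses <- function(path) {
  if (!file.exists(path)) .schemaError(paste("no such file:", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("drug", "current", "cell_id", "conc_nM", "frac_block")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    .schemaError(paste("missing response column(s):",
                       paste(miss, collapse = ", ")))
  if (any(tab$conc_nM <= 0))
    stop("concentrations must be > 0", call. = FALSE)
  tab
}

#' @rdname readCellResponses
#' @param responses data.frame as returned by
#'   [generatePatchClampPanel()]
#' @export
writeCellResponses <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE)
  invisible(path)
}

#' Read / write per-drug parameter-sample files
#'
#' One CSV per drug, one row per bootstrap replicate: metadata columns
#' `drug, cmax_nM, risk_label` plus the joint parameter columns
#' (`kmax, ku, n, halfmax, vhalf` and `<current>_ic50` /
#' `<current>_hill`). Values round-trip exactly (written with full
#' precision), so precomputed sample files can be re-emitted unchanged.
#'
#' @param path CSV file
#' @return a [DrugSampleSet-class]
#' @export
readSampleSet <- function(path) {
  if (!file.exists(path)) .schemaError(paste("no such file:", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("drug", "cmax_nM", "kmax", "ku", "n", "halfmax", "vhalf")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    .schemaError(paste("missing sample-set column(s):",
                       paste(miss, collapse = ", ")))
  meta <- c("drug", "cmax_nM", "risk_label")
  lab <- if ("risk_label" %in% names(tab)) tab$risk_label[1] else NA_character_
  drugSampleSet(tab$drug[1], tab$cmax_nM[1],
                tab[setdiff(names(tab), meta)],
                if (is.na(lab) || !nzchar(lab)) NA_character_ else lab)
}

#' @rdname readSampleSet
#' @param set a [DrugSampleSet-class]
#' @export
writeSampleSet <- function(set, path) {
  df <- cbind(data.frame(drug = set@drug, cmax_nM = set@cmax,
                         risk_label = set@riskLabel), set@samples)
  ## full precision so that read -> write is value-identical
  old <- options(digits = 17); on.exit(options(old))
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write thresholds as JSON
#'
#' @param th a [Thresholds-class]
#' @param path JSON file
#' @param datasetId dataset label stored alongside the values
#' @return `path` invisibly / a [Thresholds-class]
#' @export
writeThresholds <- function(th, path, datasetId = NA) {
  jsonlite::write_json(
    list(dataset_id = datasetId, t1 = th@t1, t2 = th@t2,
         fit = th@fit[setdiff(names(th@fit), "zeta")],
         zeta = th@fit$zeta),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeThresholds
#' @export
readThresholds <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  thresholds(x$t1, x$t2, fit = c(x$fit, list(zeta = x$zeta)))
}

#' Write a performance report (CSV + JSON)
#'
#' One row per measure with median, 95% CI bounds and resample count;
#' the JSON variant embeds the report metadata (dataset id, seeds,
#' config hash) for reproducibility.
#'
#' @param report a [PerformanceReport-class]
#' @param path output path; `.csv` and `.json` variants are written
#' @return invisible character vector of the files written
#' @export
writeReport <- function(report, path) {
  base <- sub("\\.(csv|json)$", "", path)
  csv <- paste0(base, ".csv"); js <- paste0(base, ".json")
  utils::write.csv(report@measures, csv, row.names = FALSE)
  meta <- report@meta
  meta$foldThresholds <- NULL   # S4 objects do not belong in JSON
  meta$thresholds <- if (!is.null(report@meta$thresholds))
    list(t1 = report@meta$thresholds@t1, t2 = report@meta$thresholds@t2)
  jsonlite::write_json(list(measures = report@measures, meta = meta),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
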