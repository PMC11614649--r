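#' Column dialect for longitudinal PK event tables
#'
#' Maps the column names of an input CSV onto the NONMEM-style names used
#' internally (`ID`, `TIME`, `AMT`, `DV`, `EVID`, `WT`, `FLU`, `DUL`).
#' The defaults are the NONMEM conventions themselves, so files written in
#' that dialect need no mapping.
#'
#' @param id,time,amt,dv,evid,wt,flu,dul Column names in the source file.
#' @return A named character vector usable as the `dialect` argument of
#'   [read_tdm()].
#' @export
tdm_dialect <- function(id = "ID", time = "TIME", amt = "AMT", dv = "DV",
                        evid = "EVID", wt = "WT", flu = "FLU", dul = "DUL") {
  c(ID = id, TIME = time, AMT = amt, DV = dv, EVID = evid,
    WT = wt, FLU = flu, DUL = dul)
}

#' Construct a TDM dataset from a data frame
#'
#' A `tdm_dataset` is a data frame of dose and observation events, one row per
#' event, time-sorted within subject. Dose rows have `EVID = 1` and an `AMT`
#' in mg; observation rows have `EVID = 0` and a `DV` in ng/mL. `WT` (kg) and
#' the binary comedication flags `FLU` (fluvoxamine) and `DUL` (duloxetine)
#' are subject-level covariates repeated on every row. Additional numeric
#' columns (e.g. `AGE`) are retained and available as covariates.
#'
#' @param data A data frame with at least the standard columns.
#' @param validate If `TRUE` (default), stop when [validate_tdm()] reports
#'   issues. Set to `FALSE` to build intentionally invalid datasets, e.g. to
#'   exercise the validator.
#' @return An object of class `tdm_dataset` (a data frame).
#' @export
tdm_dataset <- function(data, validate = TRUE) {
  required <- c("ID", "TIME", "AMT", "DV", "EVID", "WT", "FLU", "DUL")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  for (col in c("TIME", "AMT", "DV", "EVID", "WT", "FLU", "DUL")) {
    if (!is.numeric(data[[col]]) && !is.logical(data[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(data[[col]]))) &
                     !is.na(data[[col]]))
      if (length(bad) > 0) {
        stop("non-numeric value in column ", col, " at row ", bad[1])
      }
      data[[col]] <- as.numeric(data[[col]])
    }
  }
  data$ID <- as.character(data$ID)
  ord <- order(match(data$ID, unique(data$ID)), data$TIME, -data$EVID)
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL
  class(data) <- c("tdm_dataset", "data.frame")
  if (validate) {
    issues <- validate_tdm(data)
    if (nrow(issues) > 0) {
      stop("invalid dataset:\n", paste0("  subject ", issues$subject_id, ": ",
                                        issues$reason, collapse = "\n"))
    }
  }
  data
}

#' Read a NONMEM-style event CSV
#'
#' Rows with `EVID = 1` become dose records (the `DV` cell, if any, is
#' ignored); rows with `EVID = 0` become observation records. The file must
#' be comma-separated with a header row, UTF-8, `.` decimal separator.
#'
#' @param path Path to the CSV file.
#' @param dialect Column-name mapping from [tdm_dialect()].
#' @return A validated [tdm_dataset()].
#' @export
read_tdm <- function(path, dialect = tdm_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing <- dialect[!(dialect %in% names(raw))]
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  out <- raw
  # rename mapped columns to internal names; keep extras as-is
  for (i in seq_along(dialect)) {
    names(out)[names(out) == dialect[[i]]] <- names(dialect)[i]
  }
  for (col in setdiff(names(out), "ID")) {
    val <- out[[col]]
    val[val == ""] <- NA
    num <- suppressWarnings(as.numeric(val))
    bad <- which(is.na(num) & !is.na(val))
    if (length(bad) > 0) {
      stop("non-numeric value '", val[bad[1]], "' in column ", col,
           " at row ", bad[1])
    }
    out[[col]] <- num
  }
  out$DV[out$EVID == 1] <- NA_real_
  tdm_dataset(out, validate = TRUE)
}

#' Write a TDM dataset to CSV
#'
#' Numeric cells are written with 15 significant digits so a
#' [read_tdm()] round trip reproduces the dataset to well beyond the required
#' 10 significant digits, and write-read-write is byte-identical.
#'
#' @param ds A [tdm_dataset()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tdm <- function(ds, path) {
  stopifnot(inherits(ds, "tdm_dataset"))
  out <- as.data.frame(ds)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      txt <- vapply(out[[col]], function(x) {
        if (is.na(x)) "" else format(x, digits = 15, scientific = FALSE)
      }, character(1))
      out[[col]] <- txt
    }
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a TDM dataset
#'
#' Checks the dataset invariants: nonnegative times, positive weights, binary
#' comedication flags, exactly one of `AMT`/`DV` per record, covariates
#' constant within subject, and at least one dose preceding each subject's
#' first observation. Issues are returned, never raised.
#'
#' @param ds A `tdm_dataset` (or plain data frame with the standard columns).
#' @return A data frame with columns `subject_id` and `reason`; zero rows iff
#'   all invariants hold.
#' @export
validate_tdm <- function(ds) {
  issues <- list()
  add <- function(id, reason) {
    issues[[length(issues) + 1]] <<- data.frame(
      subject_id = as.character(id), reason = reason,
      stringsAsFactors = FALSE)
  }
  for (id in unique(ds$ID)) {
    sub <- ds[ds$ID == id, , drop = FALSE]
    if (any(is.na(sub$TIME)) || any(sub$TIME < 0)) {
      add(id, "negative or missing time")
    }
    if (any(is.na(sub$WT)) || any(sub$WT <= 0)) add(id, "weight not positive")
    for (flag in c("FLU", "DUL")) {
      if (!all(sub[[flag]] %in% c(0, 1))) {
        add(id, paste0(flag, " flag not in {0,1}"))
      }
    }
    for (cov in c("WT", "FLU", "DUL")) {
      if (length(unique(sub[[cov]])) > 1) {
        add(id, paste0("covariate ", cov, " not constant within subject"))
      }
    }
    if (!all(sub$EVID %in% c(0, 1))) add(id, "EVID not in {0,1}")
    dose <- sub$EVID == 1
    if (any(dose & (is.na(sub$AMT) | sub$AMT < 0))) {
      add(id, "dose record without nonnegative AMT")
    }
    if (any(!dose & is.na(sub$DV))) add(id, "observation record without DV")
    if (any(!dose & !is.na(sub$AMT) & sub$AMT != 0)) {
      add(id, "observation record carries AMT")
    }
    obs_t <- sub$TIME[!dose]
    if (length(obs_t) > 0) {
      if (!any(dose) || min(sub$TIME[dose]) > min(obs_t)) {
        add(id, "observation before first dose")
      }
    }
  }
  if (length(issues) == 0) {
    return(data.frame(subject_id = character(0), reason = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' Number of subjects in a dataset
#' @param ds A `tdm_dataset`.
#' @return Integer count of distinct subject IDs.
#' @export
n_subjects <- function(ds) length(unique(ds$ID))

#' Number of observation records in a dataset
#' @param ds A `tdm_dataset`.
#' @return Integer count of `EVID = 0` rows.
#' @export
n_observations <- function(ds) sum(ds$EVID == 0)

#' @export
print.tdm_dataset <- function(x, ...) {
  cat("<tdm_dataset> ", n_subjects(x), " subjects, ",
      n_observations(x), " observations, ", sum(x$EVID == 1),
      " dose records\n", sep = "")
  NextMethod()
}
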