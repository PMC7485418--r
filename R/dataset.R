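#' Input/output configuration
#'
#' Options controlling how study tables are read and written: delimiter,
#' external time and concentration units, and the lower limit of
#' quantification in external concentration units. The internal scheme is
#' fixed (time in minutes, amounts in mg, concentrations in mg/L); the
#' conversion happens once, at the I/O boundary.
#'
#' @param delimiter field separator of the delimited text files
#' @param time_unit external time unit, \code{"min"} or \code{"h"}
#' @param conc_unit external concentration unit, \code{"ug/L"} (= ng/mL) or
#'   \code{"mg/L"}
#' @param lloq lower limit of quantification in \code{conc_unit}
#' @return a list of class \code{pk_config}
#' @export
pk_config <- function(delimiter = ",", time_unit = "min", conc_unit = "ug/L",
                      lloq = 2) {
  if (!time_unit %in% c("min", "h")) stop("time_unit must be 'min' or 'h'")
  if (!conc_unit %in% c("ug/L", "mg/L")) stop("conc_unit must be 'ug/L' or 'mg/L'")
  if (!is.numeric(lloq) || lloq <= 0) stop("lloq must be positive")
  structure(list(delimiter = delimiter, time_unit = time_unit,
                 conc_unit = conc_unit, lloq = lloq), class = "pk_config")
}

#' Read an I/O configuration from a key = value text file
#'
#' Lines of the form \code{key = value}; blank lines and lines starting
#' with \code{#} are ignored. Recognised keys are the arguments of
#' \code{\link{pk_config}}.
#'
#' @param path path to the configuration file
#' @return a \code{pk_config}
#' @export
read_pk_config <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  kv <- strsplit(ln, "=", fixed = TRUE)
  args <- list()
  for (p in kv) {
    if (length(p) != 2L) stop("malformed config line: ", paste(p, collapse = "="))
    key <- trimws(p[1]); val <- trimws(p[2])
    args[[key]] <- if (key == "lloq") as.numeric(val) else val
  }
  do.call(pk_config, args)
}

## unit conversions (self-inverse pairs)
.time_to_min  <- function(x, unit) if (unit == "h") x * 60 else x
.time_from_min <- function(x, unit) if (unit == "h") x / 60 else x
.conc_to_mgL  <- function(x, unit) if (unit == "ug/L") x / 1000 else x
.conc_from_mgL <- function(x, unit) if (unit == "ug/L") x * 1000 else x

#' Construct a validated PK study dataset
#'
#' The single exchange format between all pipeline stages. Internal units:
#' minutes, mg, mg/L. Censored observations carry the LLOQ in the
#' concentration field (never zero) plus \code{censored = TRUE}; rows
#' flagged \code{excluded} are retained but skipped by every downstream
#' stage.
#'
#' @param doses data frame: \code{subject_id}, \code{time} (min),
#'   \code{amount} (mg), \code{route} (IV/IM/PO/TD), \code{phase} (1 or 2),
#'   \code{period} (1 or 2; crossover period, phase 2 only, else NA)
#' @param observations data frame: \code{subject_id}, \code{time} (min),
#'   \code{conc} (mg/L), \code{censored} (logical), \code{excluded}
#'   (logical)
#' @param covariates data frame: \code{subject_id}, \code{sex} (M/F),
#'   \code{bodyweight} (kg), \code{MET} (0 fast / 1 slow, may be NA before
#'   classification)
#' @param lloq lower limit of quantification (mg/L)
#' @return object of class \code{pk_dataset}
#' @export
pk_dataset <- function(doses, observations, covariates, lloq) {
  stopifnot(is.data.frame(doses), is.data.frame(observations),
            is.data.frame(covariates))
  if (!is.numeric(lloq) || length(lloq) != 1L || lloq <= 0)
    stop("lloq must be a single positive number")
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(what, " table missing column(s): ",
                           paste(miss, collapse = ", "))
  }
  need(doses, c("subject_id", "time", "amount", "route", "phase", "period"), "dose")
  need(observations, c("subject_id", "time", "conc", "censored", "excluded"),
       "observation")
  need(covariates, c("subject_id", "sex", "bodyweight", "MET"), "covariate")
  bad <- which(doses$amount <= 0)
  if (length(bad)) stop("non-positive dose amount at dose row ", bad[1])
  bad <- which(doses$time < 0)
  if (length(bad)) stop("negative dose time at dose row ", bad[1])
  bad <- which(!doses$route %in% .known_routes)
  if (length(bad)) stop("unknown route code '", doses$route[bad[1]],
                        "' at dose row ", bad[1])
  bad <- which(observations$time < 0)
  if (length(bad)) stop("negative observation time at observation row ", bad[1])
  bad <- which(observations$conc < 0)
  if (length(bad)) stop("negative concentration at observation row ", bad[1])
  if (any(!observations$subject_id %in% covariates$subject_id))
    stop("observation subject(s) without covariate record: ",
         paste(setdiff(unique(observations$subject_id),
                       covariates$subject_id), collapse = ", "))
  if (any(!doses$subject_id %in% covariates$subject_id))
    stop("dose subject(s) without covariate record")
  nodose <- setdiff(unique(observations$subject_id), unique(doses$subject_id))
  if (length(nodose)) stop("subject(s) with observations but no dose event: ",
                           paste(nodose, collapse = ", "))
  cens <- observations$censored
  if (any(cens & abs(observations$conc - lloq) > 1e-9 * lloq))
    stop("censored observations must carry the LLOQ in the concentration field")
  if (any(!covariates$bodyweight > 0)) stop("bodyweights must be positive")
  structure(list(doses = doses, observations = observations,
                 covariates = covariates, lloq = lloq),
            class = "pk_dataset")
}

#' @export
print.pk_dataset <- function(x, ...) {
  cat("PK study dataset:", n_subjects(x), "subjects,",
      nrow(x$doses), "dose events,", nrow(x$observations), "observations (",
      sum(x$observations$censored), "BLQ,", sum(x$observations$excluded),
      "excluded ), LLOQ", x$lloq * 1000, "ug/L\n")
  print(route_counts(x))
  invisible(x)
}

#' Number of distinct subjects in a dataset
#' @param dataset a \code{pk_dataset}
#' @return integer count
#' @export
n_subjects <- function(dataset) length(unique(dataset$covariates$subject_id))

#' Per-route subject counts
#'
#' Number of distinct subjects that received at least one dose by each
#' route (crossover subjects count once per route).
#'
#' @param dataset a \code{pk_dataset}
#' @return named integer vector over IV, IM, PO, TD
#' @export
route_counts <- function(dataset) {
  vapply(.known_routes, function(r)
    length(unique(dataset$doses$subject_id[dataset$doses$route == r])),
    integer(1))
}

#' Read a long-format study table
#'
#' Reads a delimited text file with one row per event: columns \code{ID},
#' \code{TIME}, \code{EVID} (1 = dose, 0 = observation), \code{AMT},
#' \code{ROUTE}, \code{DV}, \code{BLQ}, \code{EXCL}, \code{SEX}, \code{BW},
#' \code{MET}, \code{PHASE}, \code{PERIOD}. A DV field equal to
#' \code{"BLQ"} (or a set BLQ flag) marks a censored observation, stored
#' with the dataset LLOQ as its value. Units are converted to the internal
#' scheme on the way in.
#'
#' @param path file to read
#' @param config a \code{\link{pk_config}}
#' @return a validated \code{\link{pk_dataset}}
#' @export
read_dataset <- function(path, config = pk_config()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = config$delimiter,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  req <- c("ID", "TIME", "EVID", "AMT", "ROUTE", "DV", "BLQ")
  miss <- setdiff(req, names(raw))
  if (length(miss)) stop("input file missing required column(s): ",
                         paste(miss, collapse = ", "))
  opt <- c("EXCL", "SEX", "BW", "MET", "PHASE", "PERIOD")
  for (cc in setdiff(opt, names(raw))) raw[[cc]] <- NA
  num <- function(x) suppressWarnings(as.numeric(x))
  tm <- .time_to_min(num(raw$TIME), config$time_unit)
  bad <- which(is.na(tm) | tm < 0)
  if (length(bad)) stop("missing or negative TIME at file row ", bad[1])
  evid <- num(raw$EVID)
  lloq_int <- .conc_to_mgL(config$lloq, config$conc_unit)

  isd <- evid == 1
  amt <- num(raw$AMT[isd])
  bad <- which(is.na(amt) | amt <= 0)
  if (length(bad)) stop("missing or non-positive AMT at dose record ", bad[1])
  doses <- data.frame(subject_id = raw$ID[isd], time = tm[isd], amount = amt,
                      route = toupper(raw$ROUTE[isd]),
                      phase = num(raw$PHASE[isd]),
                      period = num(raw$PERIOD[isd]),
                      stringsAsFactors = FALSE)
  bad <- which(!doses$route %in% .known_routes)
  if (length(bad)) stop("unknown route code '", doses$route[bad[1]], "'")

  iso <- evid == 0
  blq <- raw$BLQ[iso] %in% c("1", "TRUE", "true", "T")
  dvs <- raw$DV[iso]
  blq <- blq | toupper(trimws(dvs)) == "BLQ"
  dv <- num(dvs)
  dv_int <- .conc_to_mgL(dv, config$conc_unit)
  dv_int[blq] <- lloq_int
  bad <- which(is.na(dv_int))
  if (length(bad)) stop("unparseable DV at observation record ", bad[1])
  excl <- raw$EXCL[iso] %in% c("1", "TRUE", "true", "T")
  observations <- data.frame(subject_id = raw$ID[iso], time = tm[iso],
                             conc = dv_int, censored = blq, excluded = excl,
                             stringsAsFactors = FALSE)

  first <- !duplicated(raw$ID)
  covariates <- data.frame(subject_id = raw$ID[first],
                           sex = raw$SEX[first],
                           bodyweight = num(raw$BW[first]),
                           MET = num(raw$MET[first]),
                           stringsAsFactors = FALSE)
  pk_dataset(doses, observations, covariates, lloq_int)
}

#' Write a dataset as a long-format study table
#'
#' Inverse of \code{\link{read_dataset}}: one row per dose event or
#' observation, units converted back to the external scheme. Reading the
#' written file restores the dataset field for field.
#'
#' @param dataset a \code{\link{pk_dataset}}
#' @param path file to write
#' @param config a \code{\link{pk_config}}
#' @return \code{path}, invisibly
#' @export
write_dataset <- function(dataset, path, config = pk_config()) {
  d <- dataset$doses; o <- dataset$observations; cv <- dataset$covariates
  cov_of <- function(id, col) cv[[col]][match(id, cv$subject_id)]
  drow <- data.frame(ID = d$subject_id,
                     TIME = .time_from_min(d$time, config$time_unit),
                     EVID = 1, AMT = d$amount, ROUTE = d$route, DV = ".",
                     BLQ = 0, EXCL = 0,
                     SEX = cov_of(d$subject_id, "sex"),
                     BW = cov_of(d$subject_id, "bodyweight"),
                     MET = cov_of(d$subject_id, "MET"),
                     PHASE = d$phase, PERIOD = d$period,
                     stringsAsFactors = FALSE)
  orow <- data.frame(ID = o$subject_id,
                     TIME = .time_from_min(o$time, config$time_unit),
                     EVID = 0, AMT = ".", ROUTE = ".",
                     DV = format(.conc_from_mgL(o$conc, config$conc_unit),
                                 digits = 15, scientific = FALSE, trim = TRUE),
                     BLQ = as.integer(o$censored),
                     EXCL = as.integer(o$excluded),
                     SEX = cov_of(o$subject_id, "sex"),
                     BW = cov_of(o$subject_id, "bodyweight"),
                     MET = cov_of(o$subject_id, "MET"),
                     PHASE = NA, PERIOD = NA,
                     stringsAsFactors = FALSE)
  all <- rbind(drow, orow)
  all <- all[order(match(all$ID, unique(c(d$subject_id, o$subject_id))),
                   all$TIME, -all$EVID), ]
  utils::write.table(all, path, sep = config$delimiter, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Write named result tables as delimited text
#'
#' Each element of \code{tables} is written to
#' \code{file.path(path, paste0(name, ".csv"))} with stable column order.
#'
#' @param tables non-empty named list of data frames
#' @param path output directory (created if absent)
#' @return character vector of written file paths
#' @export
write_results <- function(tables, path) {
  if (!is.list(tables) || length(tables) == 0L || is.null(names(tables)) ||
      any(!nzchar(names(tables))))
    stop("'tables' must be a non-empty named list of data frames")
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", path)
  }
  out <- character(0)
  for (nm in names(tables)) {
    fp <- file.path(path, paste0(nm, ".csv"))
    utils::write.table(tables[[nm]], fp, sep = ",", row.names = FALSE,
                       quote = FALSE, na = "NA")
    out <- c(out, fp)
  }
  out
}

## Non-excluded observations of one subject, ordered by time.
.subject_obs <- function(dataset, id) {
  o <- dataset$observations
  o <- o[o$subject_id == id & !o$excluded, , drop = FALSE]
  o[order(o$time), , drop = FALSE]
}

## Dose events of one subject, ordered by time.
.subject_doses <- function(dataset, id) {
  d <- dataset$doses
  d <- d[d$subject_id == id, , drop = FALSE]
  d[order(d$time), , drop = FALSE]
}
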