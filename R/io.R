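#' Write / read a behavioral trial table
#'
#' Plain-CSV persistence with a JSON sidecar (`<path>.meta.json`) holding
#' the time unit and generating seed, so that analyses cannot silently mix
#' tables recorded on different time scales.
#'
#' @param trials Trial table (e.g. from [simulate_dataset()] or
#'   [generate_behavior()]).
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  need <- c("instruction", "difficulty", "choice", "rt")
  if (!all(need %in% names(trials)))
    stop("missing columns: ", paste(setdiff(need, names(trials)), collapse = ", "))
  write.csv(as.data.frame(trials), path, row.names = FALSE)
  meta <- list(unit = attr(trials, "unit") %||% "s",
               seed = attr(trials, "seed"),
               package_version = as.character(packageVersion("raceSAT")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_trial_table
#' @param unit Expected time unit; reading refuses a table whose sidecar
#'   declares a different unit. `NULL` accepts whatever is on disk.
#' @export
read_trial_table <- function(path, unit = NULL) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("instruction", "difficulty", "choice", "rt")
  if (!all(need %in% names(x)))
    stop("file lacks required columns: ", paste(setdiff(need, names(x)), collapse = ", "))
  bad_instr <- which(!x$instruction %in% .instructions)
  if (length(bad_instr))
    stop("row ", bad_instr[1], ": unknown instruction '", x$instruction[bad_instr[1]], "'")
  bad_diff <- which(!x$difficulty %in% .difficulties)
  if (length(bad_diff))
    stop("row ", bad_diff[1], ": unknown difficulty '", x$difficulty[bad_diff[1]], "'")
  bad_choice <- which(!x$choice %in% .choice_labels)
  if (length(bad_choice))
    stop("row ", bad_choice[1], ": unknown choice '", x$choice[bad_choice[1]], "'")
  if (!is.numeric(x$rt)) {
    suppressWarnings(rt_num <- as.numeric(x$rt))
    bad <- which(is.na(rt_num) & !is.na(x$rt) & x$rt != "NA" & x$rt != "")
    if (length(bad))
      stop("row ", bad[1], ": non-numeric reaction time '", x$rt[bad[1]], "'")
    x$rt <- rt_num
  }
  neg <- which(!is.na(x$rt) & x$rt < 0)
  if (length(neg)) stop("row ", neg[1], ": negative reaction time")
  none_rt <- which(x$choice == "none" & !is.na(x$rt))
  if (length(none_rt)) stop("row ", none_rt[1], ": non-response trial with a reaction time")
  meta_path <- paste0(path, ".meta.json")
  file_unit <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path)$unit else NULL
  if (!is.null(unit) && !is.null(file_unit) && !identical(unit, file_unit))
    stop("table is recorded in unit '", file_unit, "', expected '", unit, "'")
  attr(x, "unit") <- file_unit %||% unit %||% "s"
  x
}

#' Write / read an MEP record table
#'
#' @param records MEP records (see [generate_mep_records()]).
#' @param path CSV file path.
#' @return `path` invisibly; reading returns the validated table.
#' @export
write_mep_table <- function(records, path) {
  need <- c("trial_id", "muscle_role", "tms_latency", "amplitude")
  if (!all(need %in% names(records)))
    stop("missing columns: ", paste(setdiff(need, names(records)), collapse = ", "))
  write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mep_table
#' @export
read_mep_table <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "muscle_role", "tms_latency", "amplitude")
  if (!all(need %in% names(x)))
    stop("file lacks required columns: ", paste(setdiff(need, names(x)), collapse = ", "))
  bad <- which(!x$muscle_role %in% c("responding", "nonresponding"))
  if (length(bad))
    stop("row ", bad[1], ": unknown muscle_role '", x$muscle_role[bad[1]], "'")
  if (!is.numeric(x$amplitude)) stop("`amplitude` must be numeric")
  if (!is.numeric(x$tms_latency) || any(x$tms_latency < 0, na.rm = TRUE))
    stop("`tms_latency` must be numeric and non-negative")
  x
}

#' Write / read an epoch set as long-format CSV
#'
#' Epochs are stored as (`trial`, `time`, `amplitude`) triples (masked
#' samples omitted) next to the per-trial table, keeping everything in
#' plain text at the cost of size.
#'
#' @param epochs An [epoch_set()].
#' @param path CSV path for the samples; the trial table goes to
#'   `<path>.trials.csv`.
#' @return `path` invisibly; reading returns the reconstructed
#'   [epoch_set()].
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  amp <- epochs$amplitude
  idx <- which(!is.na(amp), arr.ind = TRUE)
  long <- data.frame(trial = idx[, 1], time = epochs$times[idx[, 2]],
                     amplitude = amp[idx])
  long <- long[order(long$trial, long$time), ]
  write.csv(long, path, row.names = FALSE)
  tr <- epochs$trials
  tr$.row <- seq_len(nrow(tr))
  write.csv(tr, paste0(path, ".trials.csv"), row.names = FALSE)
  jsonlite::write_json(list(unit = epochs$unit, t0 = epochs$times[1],
                            step = if (length(epochs$times) > 1)
                              diff(epochs$times[1:2]) else 1,
                            n_times = length(epochs$times)),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  long <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  tr <- read.csv(paste0(path, ".trials.csv"), stringsAsFactors = FALSE)
  tr <- tr[order(tr$.row), ]; tr$.row <- NULL
  times <- meta$t0 + meta$step * (seq_len(meta$n_times) - 1)
  amp <- matrix(NA_real_, nrow(tr), meta$n_times)
  col <- round((long$time - meta$t0) / meta$step) + 1L
  amp[cbind(long$trial, col)] <- long$amplitude
  epoch_set(times, amp, tr, unit = meta$unit)
}

#' Write a signal (or signal list) to CSV
#'
#' @param signal A [race_signal()] or a named list of them (bound into one
#'   long table with a `signal` column).
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  if (inherits(signal, "race_signal")) signal <- list(signal = signal)
  rows <- lapply(names(signal), function(k) {
    s <- signal[[k]]
    cbind(data.frame(signal = k, alignment = attr(s, "alignment"),
                     stringsAsFactors = FALSE), as.data.frame(s))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' Serializes a named list of results together with reproducibility
#' metadata (seed, package version, timestamp).
#'
#' @param results Named list of scalars, vectors or data frames.
#' @param path Output `.json` path.
#' @param seed The seed that produced the results (recorded verbatim).
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, seed = NULL) {
  payload <- list(package = "raceSAT",
                  version = as.character(packageVersion("raceSAT")),
                  seed = seed,
                  created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  results = results)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  invisible(path)
}
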