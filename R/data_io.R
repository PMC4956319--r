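#' Read a polyp-count experiment table from CSV
#'
#' Reads the replicated count tables produced by thermal-osmotic or
#' feeding-frequency experiments: one row per well per census week, with
#' the well's treatment covariates and its total polyp count. Columns are
#' matched by header name (case-insensitive, tolerant of whitespace,
#' punctuation and unit suffixes such as "Temperature (°C)"), never by
#' position, because the two experiment layouts order their columns
#' differently.
#'
#' Recognised headers (after normalisation): sample identification number,
#' well number, treatment number (optional), temperature, salinity, time
#' (weeks), total (polyp count) and proportion (optional). The proportion
#' column, where present, is cross-checked against count / week-0 count and
#' mismatches beyond 0.005 are reported; counts are always the primary
#' data.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema `"thermal_osmotic"` (has a treatment column; wells are
#'   identified by treatment x well number) or `"feeding"` (well numbers
#'   are globally unique).
#' @return An `experiment_table`: a data frame with columns `sample_id`,
#'   `well_id`, `treatment_id`, `temperature`, `salinity`, `time`, `count`,
#'   `proportion`, validated so that counts are non-negative integers,
#'   every well has exactly one week-0 row, no (well, time) pair repeats,
#'   and covariates are constant within a well.
#' @seealso [pair_initial_final()], [summarize_initial()],
#'   [design_summary()]
#' @export
read_count_table <- function(path, schema = c("thermal_osmotic", "feeding")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  cols <- .match_columns(names(raw), schema)
  df <- data.frame(
    sample_id    = .col_chr(raw, cols["sample_id"]),
    well         = .col_chr(raw, cols["well"]),
    treatment_id = .col_chr(raw, cols["treatment_id"]),
    temperature  = .col_num(raw, cols["temperature"], "temperature"),
    salinity     = .col_num(raw, cols["salinity"], "salinity"),
    time         = .col_num(raw, cols["time"], "time"),
    count        = .col_num(raw, cols["count"], "count"),
    proportion   = .col_num(raw, cols["proportion"], "proportion"),
    stringsAsFactors = FALSE)
  # well numbers are only unique within a treatment in the crossed layout;
  # prefix with the treatment only when bare numbers collide, so that
  # writing and re-reading a table leaves well ids unchanged
  collide <- anyDuplicated(paste(df$well, df$time)) > 0L
  df$well_id <- if (collide && !all(is.na(df$treatment_id)))
    paste(df$treatment_id, df$well, sep = ":") else df$well
  df$well <- NULL
  as_experiment_table(df, schema = schema)
}

# canonical header key: lowercase alphanumerics only, so "Temperature (°C)",
# "temperature" and "Temperature C" all collapse to the same key
.norm_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

.HEADER_ALIASES <- list(
  sample_id    = c("sampleidentificationnumber", "sampleid", "sample", "id"),
  well         = c("wellnumber", "well"),
  treatment_id = c("treatmentnumber", "treatment"),
  temperature  = c("temperaturec", "temperature", "tempc", "temp"),
  salinity     = c("salinity", "salinityppt", "salinitypsu"),
  time         = c("timeweeks", "time", "week", "weeks"),
  count        = c("total", "totalpolyps", "count", "polyps"),
  proportion   = c("proportion", "proportionalchange"))

.REQUIRED <- c("well", "temperature", "salinity", "time", "count")

.match_columns <- function(headers, schema) {
  keys <- .norm_header(headers)
  out <- vapply(names(.HEADER_ALIASES), function(field) {
    hit <- which(keys %in% .HEADER_ALIASES[[field]])
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1))
  missing <- .REQUIRED[is.na(out[.REQUIRED])]
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out
}

.col_chr <- function(raw, i) {
  if (is.na(i)) rep(NA_character_, nrow(raw)) else as.character(raw[[i]])
}
.col_num <- function(raw, i, what) {
  if (is.na(i)) return(rep(NA_real_, nrow(raw)))
  v <- suppressWarnings(as.numeric(raw[[i]]))
  bad <- which(!is.na(raw[[i]]) & raw[[i]] != "" & is.na(v))
  if (length(bad))
    stop("non-numeric ", what, " in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  v
}

#' Construct and validate an experiment table
#'
#' Validates a data frame of per-well, per-week polyp counts and stamps it
#' with the `experiment_table` class. Used by [read_count_table()] and by
#' the synthetic generator; call it directly on programmatically assembled
#' data.
#'
#' @param df Data frame with columns `well_id`, `temperature`, `salinity`,
#'   `time`, `count` (plus optional `sample_id`, `treatment_id`,
#'   `proportion`).
#' @param schema Experiment layout label, stored as an attribute.
#' @return The validated `experiment_table`.
#' @export
as_experiment_table <- function(df, schema = "thermal_osmotic") {
  for (nm in c("sample_id", "treatment_id"))
    if (is.null(df[[nm]])) df[[nm]] <- rep(NA_character_, nrow(df))
  if (is.null(df$proportion)) df$proportion <- rep(NA_real_, nrow(df))
  need <- c("well_id", "temperature", "salinity", "time", "count")
  if (!all(need %in% names(df)))
    stop("missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  df <- df[, c("sample_id", "well_id", "treatment_id", "temperature",
               "salinity", "time", "count", "proportion")]
  if (nrow(df)) .validate_observations(df)
  structure(df, class = c("experiment_table", "data.frame"), schema = schema)
}

.validate_observations <- function(df) {
  bad <- which(is.na(df$count) | df$count < 0 |
                 abs(df$count - round(df$count)) > 1e-8)
  if (length(bad))
    stop("count must be a non-negative integer; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  bad <- which(is.na(df$time) | df$time < 0 |
                 abs(df$time - round(df$time)) > 1e-8)
  if (length(bad))
    stop("time must be a non-negative whole number of weeks; row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  key <- paste(df$well_id, df$time)
  if (anyDuplicated(key))
    stop("duplicate (well, time) pair(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "),
         call. = FALSE)
  n0 <- tapply(df$time == 0, df$well_id, sum)
  if (any(n0 != 1L))
    stop("every well needs exactly one week-0 observation; offending well(s): ",
         paste(utils::head(names(n0)[n0 != 1L], 5), collapse = ", "),
         call. = FALSE)
  for (v in c("temperature", "salinity")) {
    spread <- tapply(df[[v]], df$well_id,
                     function(x) diff(range(x, na.rm = TRUE)))
    vary <- names(spread)[!is.na(spread) & spread > 1e-8]
    if (length(vary))
      stop(v, " varies within well(s): ",
           paste(utils::head(vary, 5), collapse = ", "), call. = FALSE)
  }
  # recompute proportion from counts; the stored column is advisory only
  c0 <- df$count[df$time == 0][match(df$well_id, df$well_id[df$time == 0])]
  chk <- which(!is.na(df$proportion) & df$time > 0 & c0 > 0 &
                 abs(df$proportion - df$count / c0) > 0.005)
  if (length(chk))
    warning("proportion column disagrees with count/count0 in row(s): ",
            paste(utils::head(chk, 10), collapse = ", "),
            "; counts are used as primary data", call. = FALSE)
  invisible(df)
}

#' Write an experiment table to CSV
#'
#' Inverse of [read_count_table()]: emits the canonical header names so a
#' written table re-reads to identical observations.
#'
#' @param table An `experiment_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "experiment_table"))
  out <- data.frame(
    `Sample identification number` = table$sample_id,
    `Treatment number` = table$treatment_id,
    `Well number` = table$well_id,
    `Temperature` = table$temperature,
    `Salinity` = table$salinity,
    `Time` = table$time,
    `Total` = table$count,
    `Proportion` = table$proportion,
    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Summarize the experimental design of a count table
#'
#' @param table An `experiment_table`.
#' @return List with the distinct temperatures and salinities and a table
#'   of replicate wells per (temperature, salinity) cell at week 0.
#' @export
design_summary <- function(table) {
  stopifnot(inherits(table, "experiment_table"))
  t0 <- table[table$time == 0, , drop = FALSE]
  if (nrow(t0) == 0L)
    return(list(temperatures = numeric(0), salinities = numeric(0),
                replicates = data.frame(temperature = numeric(0),
                                        salinity = numeric(0),
                                        n_wells = integer(0))))
  reps <- stats::aggregate(list(n_wells = t0$well_id),
                           by = list(temperature = t0$temperature,
                                     salinity = t0$salinity),
                           FUN = length)
  list(temperatures = sort(unique(t0$temperature)),
       salinities = sort(unique(t0$salinity)),
       replicates = reps[order(reps$temperature, reps$salinity), ])
}

#' @export
print.experiment_table <- function(x, ...) {
  ds <- design_summary(x)
  cat(sprintf("Experiment table (%s schema): %d observations, %d wells\n",
              attr(x, "schema"), nrow(x), length(unique(x$well_id))))
  cat(sprintf("  %d temperatures x %d salinities, weeks %s\n",
              length(ds$temperatures), length(ds$salinities),
              paste(range(x$time), collapse = "-")))
  NextMethod()
}

#' Pair week-0 and final-week counts per well
#'
#' Builds the fitting table: one record per well that was censused both at
#' week 0 and at `final_week`. Wells with a week-0 count of zero carry no
#' information about the proportional-change model (the predicted mean is
#' zero for any parameter values), so they are dropped with a message.
#'
#' @param table An `experiment_table`.
#' @param final_week Integer week of the final census (default 6).
#' @return A `paired_counts` data frame with columns `well_id`,
#'   `temperature`, `salinity`, `initial_count`, `final_count` and
#'   attributes `final_week` and `n_dropped_zero_initial`.
#' @export
pair_initial_final <- function(table, final_week = 6) {
  stopifnot(inherits(table, "experiment_table"))
  t0 <- table[table$time == 0, c("well_id", "temperature", "salinity", "count")]
  tf <- table[table$time == final_week, c("well_id", "count")]
  if (nrow(tf) == 0L)
    stop("no well has an observation at week ", final_week, call. = FALSE)
  names(t0)[names(t0) == "count"] <- "initial_count"
  names(tf)[names(tf) == "count"] <- "final_count"
  paired <- merge(t0, tf, by = "well_id", sort = TRUE)
  zero <- paired$initial_count == 0
  if (any(zero)) {
    message("dropping ", sum(zero), " well(s) with zero initial count: ",
            paste(utils::head(paired$well_id[zero], 5), collapse = ", "))
    paired <- paired[!zero, , drop = FALSE]
  }
  rownames(paired) <- NULL
  structure(paired, class = c("paired_counts", "data.frame"),
            final_week = final_week, n_dropped_zero_initial = sum(zero))
}

#' Summarize week-0 polyp counts across wells
#'
#' @param table An `experiment_table`.
#' @return List with `mean`, `sd` (sample SD, n-1 denominator; `NA` for a
#'   single well) and `n_wells` of the week-0 counts.
#' @export
summarize_initial <- function(table) {
  stopifnot(inherits(table, "experiment_table"))
  x <- table$count[table$time == 0]
  if (length(x) == 0L) stop("table has no week-0 observations", call. = FALSE)
  list(mean = mean(x),
       sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
       n_wells = length(x))
}
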