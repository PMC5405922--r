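# Ingestion, severity coding and quality control of bleaching reports
# (ReefBase-style schema).

# Canonical column names of the report schema. Matching is case-insensitive
# and order-free; files may carry extra columns, which are preserved.
.report_columns <- c(
  "country", "location", "site_name", "latitude", "longitude", "date",
  "month", "year", "depth", "severity_code", "percent_bleached",
  "mortality_code", "percent_mortality", "survey_type", "source", "name",
  "citation", "comments", "entry_code", "database_code"
)

#' Severity code from percent bleached
#'
#' Converts percent of coral bleached into the ordinal severity code used
#' throughout the pipeline: -1 unknown, 0 none, 1 mild (0-10%], 2 moderate
#' (10-50%], 3 severe (50-100%]. Band edges are closed on the right so the
#' printed labels "1-10%", "11-50%", ">50%" are mutually exclusive and
#' exhaustive for integer percents; fractional values between bands fall in
#' the higher band.
#'
#' @param percent_bleached numeric vector of percent bleached in [0, 100];
#'   `NA` means the extent of bleaching is unknown.
#' @return integer vector of severity codes in {-1, 0, 1, 2, 3}.
#' @examples
#' assign_severity(c(NA, 0, 5, 10, 11, 55))
#' @export
assign_severity <- function(percent_bleached) {
  p <- as.numeric(percent_bleached)
  bad <- !is.na(p) & (p < 0 | p > 100)
  if (any(bad)) {
    stop("percent_bleached outside [0, 100]: ", paste(p[bad], collapse = ", "))
  }
  out <- rep.int(-1L, length(p))
  ok <- !is.na(p)
  out[ok & p == 0] <- 0L
  out[ok & p > 0 & p <= 10] <- 1L
  out[ok & p > 10 & p <= 50] <- 2L
  out[ok & p > 50] <- 3L
  out
}

#' Read bleaching reports from a delimited text file
#'
#' Reads a report table in the ReefBase-style schema (one row per
#' observation; missing values as empty strings). Header names are matched
#' case-insensitively and may be in any order. Rows that fail validation
#' (unparseable or out-of-range coordinates or year, percent bleached outside
#' [0, 100], a stored severity code inconsistent with the percent-bleached
#' band, an invalid database code) are collected in a rejects log rather than
#' silently dropped.
#'
#' @param path path to the delimited text file.
#' @param sep field separator (default comma).
#' @return list with elements `reports` (data frame of valid rows, canonical
#'   lower-case column names, severity codes filled from percent bleached
#'   where absent) and `rejects` (data frame with columns `row`, `reason`,
#'   `detail`).
#' @export
read_reports <- function(path, sep = ",") {
  if (!file.exists(path)) stop("report file not found: ", path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", fill = TRUE,
                           na.strings = NULL, strip.white = TRUE)
  names(raw) <- tolower(trimws(names(raw)))

  mandatory <- c("latitude", "longitude", "year")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols)) {
    stop("report schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!any(c("percent_bleached", "severity_code") %in% names(raw))) {
    stop("report schema error: need at least one of percent_bleached, severity_code")
  }
  for (col in setdiff(.report_columns, names(raw))) raw[[col]] <- ""

  n <- nrow(raw)
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  lat  <- num(raw$latitude)
  lon  <- num(raw$longitude)
  year <- num(raw$year)
  pct  <- num(raw$percent_bleached)
  sev  <- num(raw$severity_code)
  dbc  <- num(raw$database_code)

  reason <- character(n)
  flag <- function(cond, why) {
    hit <- cond & reason == ""
    reason[hit] <<- why
  }
  flag(is.na(lat), "latitude missing or unparseable")
  flag(!is.na(lat) & abs(lat) > 90, "latitude out of range")
  flag(is.na(lon), "longitude missing or unparseable")
  flag(!is.na(lon) & (lon < -180 | lon > 360), "longitude out of range")
  flag(is.na(year) | year != round(year), "year missing or not an integer")
  flag(!is.na(pct) & (pct < 0 | pct > 100), "percent_bleached out of range")
  flag(!is.na(sev) & !(sev %in% c(-1, 0, 1, 2, 3)), "invalid severity code")
  flag(is.na(pct) & is.na(sev), "no severity information")
  # stored severity must agree with the percent-bleached band when both exist
  both <- !is.na(pct) & !is.na(sev) & reason == ""
  if (any(both)) {
    derived <- assign_severity(pct[both])
    mism <- both
    mism[both] <- derived != sev[both]
    flag(mism, "severity code inconsistent with percent bleached")
  }
  flag(!is.na(dbc) & !(dbc %in% c(1, 2)), "invalid database code")

  ok <- reason == ""
  rejects <- data.frame(row = which(!ok), reason = reason[!ok],
                        detail = apply(raw[!ok, mandatory, drop = FALSE], 1,
                                       paste, collapse = "/"),
                        stringsAsFactors = FALSE)
  rownames(rejects) <- NULL

  rep_df <- raw[ok, , drop = FALSE]
  rep_df$latitude <- lat[ok]
  rep_df$longitude <- lon[ok]
  rep_df$year <- as.integer(year[ok])
  rep_df$percent_bleached <- pct[ok]
  sev_ok <- sev[ok]
  fill <- is.na(sev_ok)
  sev_ok[fill] <- assign_severity(rep_df$percent_bleached[fill])
  rep_df$severity_code <- as.integer(sev_ok)
  rep_df$database_code <- as.integer(dbc[ok])
  rep_df$month <- suppressWarnings(as.integer(ifelse(rep_df$month == "", NA,
                                                     rep_df$month)))
  rownames(rep_df) <- NULL
  list(reports = rep_df, rejects = rejects)
}

#' Write bleaching reports to a delimited text file
#'
#' Inverse of [read_reports()]: canonical headers, missing values as empty
#' strings. Well-formed rows round-trip through read/write unchanged.
#'
#' @param reports data frame of reports.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path, sep = ",") {
  cols <- union(intersect(.report_columns, names(reports)),
                names(reports))
  out <- reports[, cols, drop = FALSE]
  for (j in seq_along(out)) {
    x <- out[[j]]
    if (is.numeric(x)) x <- format(x, trim = TRUE, scientific = FALSE, digits = 15)
    x[is.na(out[[j]]) | x == "NA"] <- ""
    out[[j]] <- x
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default keyword list flagging non-thermal bleaching causes
#' @return character vector of lower-case keywords.
#' @export
nonthermal_keywords <- function() {
  c("freshwater", "runoff", "tidal", "exposure", "effluent", "cold")
}

#' Quality-filter bleaching reports
#'
#' Removes reports attributed to non-thermal causes (keyword match in the
#' comments field) and reports whose coordinates fall outside every reef cell
#' of the mask (erroneous coordinates, e.g. bleaching reported on land). The
#' kept and removed sets partition the input; every removal carries a
#' machine-readable reason.
#'
#' @param reports data frame of validated reports (from [read_reports()]).
#' @param grid a [reef_grid()] acting as the reef mask.
#' @param keywords lower-case keywords marking non-thermal causes; matched
#'   case-insensitively against the comments field.
#' @return list with `kept` and `removed` data frames; `removed` carries
#'   `qc_reason` ("non-thermal" or "off-reef") and `qc_detail` columns.
#' @export
qc_filter <- function(reports, grid, keywords = nonthermal_keywords()) {
  n <- nrow(reports)
  reason <- character(n)
  detail <- character(n)

  if (n > 0 && length(keywords) && "comments" %in% names(reports)) {
    pat <- paste(keywords, collapse = "|")
    txt <- tolower(ifelse(is.na(reports$comments), "", reports$comments))
    hit <- grepl(pat, txt)
    reason[hit] <- "non-thermal"
    detail[hit] <- txt[hit]
  }
  if (n > 0) {
    ids <- cell_index(reports$latitude, reports$longitude, grid)
    off <- !(ids %in% grid$cells$cell_id) & reason == ""
    reason[off] <- "off-reef"
    detail[off] <- sprintf("cell %d not in reef mask", ids[off])
  }

  keep <- reason == ""
  removed <- reports[!keep, , drop = FALSE]
  removed$qc_reason <- reason[!keep]
  removed$qc_detail <- detail[!keep]
  rownames(removed) <- NULL
  kept <- reports[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed = removed)
}

#' Collapse duplicate reports into independent records
#'
#' An independent record is a unique (latitude, longitude, year, severity)
#' tuple; exact duplicates are collapsed and the number collapsed is attached
#' as attribute `n_collapsed`.
#'
#' @param reports data frame of reports.
#' @return data frame of unique records.
#' @export
independent_records <- function(reports) {
  key <- paste(reports$latitude, reports$longitude, reports$year,
               reports$severity_code, sep = "|")
  keep <- !duplicated(key)
  out <- reports[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_collapsed") <- sum(!keep)
  out
}
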