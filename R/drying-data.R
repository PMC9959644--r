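#' Assemble a drying dataset
#'
#' A drying dataset is the tabular record of one drying run: for each sample
#' index `k` (1-based, contiguous), the measured area shrinkage `S(k)` (ratio
#' of current to initial slice area, in (0, 1]) and the moisture ratio
#' `MR(k)` (moisture content normalised by its initial value). Time is
#' optional metadata: the estimators treat the records as an unordered
#' regression sample of MR on S.
#'
#' @param shrinkage Numeric vector of shrinkage values in (0, 1].
#' @param moisture_ratio Numeric vector of moisture ratios, same length.
#'   Measurement noise may push values slightly outside [0, 1]; they need
#'   only be finite.
#' @param time_min Optional numeric vector of sampling times in minutes.
#' @param delta Sampling period in minutes, kept as metadata (default 0.5).
#'
#' @return A tibble with columns `k`, `time_min`, `shrinkage`,
#'   `moisture_ratio` and attribute `delta`, validated by
#'   [validate_drying_data()].
#' @export
#' @examples
#' drying_data(shrinkage = c(1, 0.8, 0.6), moisture_ratio = c(1, 0.5, 0.2))
drying_data <- function(shrinkage, moisture_ratio, time_min = NULL,
                        delta = 0.5) {
  kmax <- length(shrinkage)
  if (is.null(time_min)) time_min <- rep(NA_real_, kmax)
  out <- tibble::tibble(
    k = seq_len(kmax),
    time_min = as.numeric(time_min),
    shrinkage = as.numeric(shrinkage),
    moisture_ratio = as.numeric(moisture_ratio)
  )
  attr(out, "delta") <- delta
  validate_drying_data(out)
}

#' Validate a drying dataset
#'
#' Checks the invariants every estimator in the package relies on: `k` runs
#' 1..kmax without gaps or duplicates, every shrinkage lies in (0, 1], every
#' moisture ratio is finite, and there are at least two records.
#'
#' @param data A data frame with columns `k`, `shrinkage`, `moisture_ratio`
#'   (and optionally `time_min`).
#' @return The data, invisibly unchanged, as a tibble (rows ordered by `k`).
#' @export
validate_drying_data <- function(data) {
  required <- c("k", "shrinkage", "moisture_ratio")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("drying data is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  kmax <- nrow(data)
  if (kmax < 2) stop("a drying dataset needs at least 2 records", call. = FALSE)
  k <- data$k
  if (anyNA(k) || !all(is.finite(k))) {
    stop("column 'k' must be finite", call. = FALSE)
  }
  dup <- which(duplicated(k))
  if (length(dup) > 0) {
    stop("duplicated sample index k = ", k[dup[1]], " at row ", dup[1],
         call. = FALSE)
  }
  if (!setequal(k, seq_len(kmax))) {
    stop("sample index k must run 1..", kmax, " without gaps", call. = FALSE)
  }
  data <- data[order(data$k), , drop = FALSE]
  s <- data$shrinkage
  bad <- which(!is.finite(s) | s <= 0 | s > 1)
  if (length(bad) > 0) {
    stop("shrinkage must lie in (0, 1]; offending value ", s[bad[1]],
         " at row ", bad[1], call. = FALSE)
  }
  mr <- data$moisture_ratio
  bad <- which(!is.finite(mr))
  if (length(bad) > 0) {
    stop("moisture_ratio must be finite; offending row ", bad[1],
         call. = FALSE)
  }
  if (is.null(attr(data, "delta"))) attr(data, "delta") <- 0.5
  data
}

#' Dry-basis moisture content
#'
#' MC = (m - m_d) / m_d: grams of water per gram of dry matter.
#'
#' @param mass Sample mass in grams.
#' @param dry_mass Dry-matter mass in grams (positive, at most `mass`).
#' @return Moisture content in g/g (dimensionless ratio). Vectorised.
#' @export
#' @examples
#' moisture_content(10.87, 1.00) # 9.87 g/g, a typical fresh-slice value
moisture_content <- function(mass, dry_mass) {
  if (any(!is.finite(dry_mass)) || any(dry_mass <= 0)) {
    stop("dry_mass must be positive", call. = FALSE)
  }
  if (any(!is.finite(mass)) || any(mass < dry_mass)) {
    stop("mass must be at least dry_mass", call. = FALSE)
  }
  (mass - dry_mass) / dry_mass
}

#' Moisture ratio
#'
#' MR(t) = MC(t) / MC(0): current moisture content relative to the initial
#' one. Near 1 at the start of drying, approaches 0 when dry.
#'
#' @param mc_t Moisture content at time t (non-negative).
#' @param mc_0 Initial moisture content (positive).
#' @return Dimensionless moisture ratio. Vectorised.
#' @export
moisture_ratio <- function(mc_t, mc_0) {
  if (any(!is.finite(mc_0)) || any(mc_0 <= 0)) {
    stop("initial moisture content mc_0 must be positive", call. = FALSE)
  }
  if (any(!is.finite(mc_t)) || any(mc_t < 0)) {
    stop("moisture content mc_t must be non-negative", call. = FALSE)
  }
  mc_t / mc_0
}

#' Read a drying dataset from CSV
#'
#' Expects a header with at least `k,shrinkage,moisture_ratio`; a `time_min`
#' column is optional and may be empty. Decimal separator is '.'. All
#' dataset invariants are enforced; violations name the offending row.
#'
#' @param path Path to the CSV file.
#' @return A validated drying-data tibble.
#' @export
read_drying_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("k", "shrinkage", "moisture_ratio")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("CSV ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in required) {
    v <- raw[[col]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad) > 0) {
        stop("non-numeric value '", v[bad[1]], "' in column '", col,
             "' at row ", bad[1], call. = FALSE)
      }
      raw[[col]] <- num
    }
  }
  if (is.null(raw$time_min)) {
    raw$time_min <- NA_real_
  } else {
    raw$time_min <- suppressWarnings(as.numeric(raw$time_min))
  }
  validate_drying_data(raw[, c("k", "time_min", "shrinkage", "moisture_ratio")])
}

#' Write a drying dataset to CSV
#'
#' Numeric cells are written with 9 significant digits so that a write/read
#' round trip reproduces the dataset to 1e-9 and repeated runs diff cleanly.
#'
#' @param data A drying-data tibble (validated on the way out).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_drying_csv <- function(data, path) {
  data <- validate_drying_data(data)
  fmt <- function(x) ifelse(is.na(x), "", formatC(x, format = "g", digits = 9))
  lines <- c(
    "k,time_min,shrinkage,moisture_ratio",
    paste(data$k, fmt(data$time_min), fmt(data$shrinkage),
          fmt(data$moisture_ratio), sep = ",")
  )
  writeLines(lines, path)
  invisible(path)
}
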