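#' Validate an annual area-level constituent panel
#'
#' A constituent panel records, for every area (5-digit zip code) and
#' calendar year, the annual mean concentration of each particulate
#' constituent.  It is the exposure source of record that gets linked to
#' individual recipients.  Zip codes are kept as character strings so
#' that leading zeros survive.
#'
#' @param panel data frame with columns \code{zip} (character),
#'   \code{year} (integer) and one numeric column per constituent.
#' @param constituents character vector naming the constituent columns;
#'   defaults to all columns other than \code{zip} and \code{year}.
#' @return the validated panel, with \code{zip} coerced to character and
#'   a \code{"constituents"} attribute, classed \code{constituent_panel}.
#' @examples
#' p <- data.frame(zip = c("01002", "01002"), year = c(2005, 2006),
#'                 SO4 = c(2.0, 2.4), Ni = c(0.5, 0.7))
#' panel <- as_constituent_panel(p)
#' attr(panel, "constituents")
#' @export
as_constituent_panel <- function(panel, constituents = NULL) {
  stopifnot(is.data.frame(panel))
  if (!all(c("zip", "year") %in% names(panel)))
    stop("panel must have 'zip' and 'year' columns")
  panel$zip <- as.character(panel$zip)
  panel$year <- as.integer(panel$year)
  if (is.null(constituents))
    constituents <- setdiff(names(panel), c("zip", "year"))
  if (length(constituents) < 1L) stop("panel has no constituent columns")
  missing_cols <- setdiff(constituents, names(panel))
  if (length(missing_cols))
    stop("panel schema error: missing constituent columns: ",
         paste(missing_cols, collapse = ", "))
  for (cc in constituents) {
    v <- panel[[cc]]
    if (!is.numeric(v)) stop("constituent column not numeric: ", cc)
    if (any(v < 0, na.rm = TRUE))
      stop("negative concentration in constituent: ", cc)
  }
  key <- paste(panel$zip, panel$year)
  if (anyDuplicated(key))
    stop("duplicate (zip, year) rows in panel: ",
         paste(unique(key[duplicated(key)])[1:3], collapse = "; "))
  attr(panel, "constituents") <- constituents
  class(panel) <- c("constituent_panel", "data.frame")
  panel
}

#' Read a constituent panel from CSV
#'
#' Expects columns \code{zip}, \code{year}, then one column per
#' constituent.  Zip codes are read as character.
#'
#' @param file path to a CSV file.
#' @inheritParams as_constituent_panel
#' @return a \code{constituent_panel}.
#' @export
read_constituent_panel <- function(file, constituents = NULL) {
  df <- utils::read.csv(file, colClasses = c(zip = "character"),
                        check.names = FALSE)
  as_constituent_panel(df, constituents = constituents)
}

panel_row <- function(panel, zip, year) {
  i <- which(panel$zip == zip & panel$year == year)
  if (length(i) == 0L)
    stop(sprintf("missing exposure data for zip %s, year %d", zip,
                 as.integer(year)), call. = FALSE)
  i[1L]
}

#' Calendar-weighted one-year pre-transplant moving average
#'
#' The exposure assigned to a recipient is a moving average of the
#' annual constituent levels over the 12 months preceding transplant.
#' A transplant in month \eqn{m} of year \eqn{y} receives weight
#' \eqn{m/12} on year \eqn{y} and \eqn{(12-m)/12} on year \eqn{y-1}: a
#' July transplant weights the transplant year by 7/12 and the prior
#' year by 5/12.
#'
#' @param panel a \code{\link{as_constituent_panel}} object.
#' @param zip area identifier (character).
#' @param tx_year transplant calendar year.
#' @param tx_month transplant month, integer in 1..12.
#' @return named numeric vector of moving-average concentrations, one
#'   per constituent, in the panel's units.
#' @examples
#' p <- as_constituent_panel(data.frame(
#'   zip = "10001", year = c(2005, 2006), SO4 = c(0, 12)))
#' compute_moving_average(p, "10001", 2006, 7)  # 7/12 * 12 = 7
#' @export
compute_moving_average <- function(panel, zip, tx_year, tx_month) {
  stopifnot(inherits(panel, "constituent_panel"))
  tx_month <- as.integer(tx_month)
  if (is.na(tx_month) || tx_month < 1L || tx_month > 12L)
    stop("tx_month must be an integer in 1..12")
  cons <- attr(panel, "constituents")
  i1 <- panel_row(panel, zip, tx_year)
  i0 <- panel_row(panel, zip, tx_year - 1L)
  cur <- as.numeric(panel[i1, cons])
  prev <- as.numeric(panel[i0, cons])
  out <- (tx_month / 12) * cur + ((12 - tx_month) / 12) * prev
  names(out) <- cons
  out
}

#' Link an exposure panel to a transplant cohort
#'
#' Computes the one-year pre-transplant moving-average exposure for each
#' recipient from their residential zip code and transplant year/month.
#' Recipients whose zip or either of the two required panel years is
#' absent are handled per \code{policy}: dropped with a logged count
#' (default) or a hard error.
#'
#' @param panel a \code{constituent_panel}.
#' @param cohort data frame with columns \code{id}, \code{zip},
#'   \code{tx_year}, \code{tx_month} (one row per recipient).
#' @param policy \code{"drop"} (exclude unlinkable recipients, message
#'   the count) or \code{"strict"} (abort on the first failure).
#' @return data frame with \code{id} and one column per constituent;
#'   attribute \code{"n_dropped"} records exclusions.
#' @export
link_exposures <- function(panel, cohort, policy = c("drop", "strict")) {
  policy <- match.arg(policy)
  stopifnot(inherits(panel, "constituent_panel"), is.data.frame(cohort))
  need <- c("id", "zip", "tx_year", "tx_month")
  if (!all(need %in% names(cohort)))
    stop("cohort must have columns: ", paste(need, collapse = ", "))
  cons <- attr(panel, "constituents")
  n <- nrow(cohort)
  out <- matrix(NA_real_, n, length(cons), dimnames = list(NULL, cons))
  ok <- logical(n)
  # index panel rows once; avoids O(n * panel) scans on large cohorts
  key <- paste(panel$zip, panel$year)
  lut <- setNames(seq_len(nrow(panel)), key)
  zipc <- as.character(cohort$zip)
  m <- as.integer(cohort$tx_month)
  y <- as.integer(cohort$tx_year)
  i1 <- lut[paste(zipc, y)]
  i0 <- lut[paste(zipc, y - 1L)]
  ok <- !is.na(i1) & !is.na(i0) & !is.na(m) & m >= 1L & m <= 12L
  if (any(!ok) && policy == "strict") {
    j <- which(!ok)[1L]
    stop(sprintf("missing exposure data for zip %s, year %d (recipient %s)",
                 zipc[j], if (is.na(i1[j])) y[j] else y[j] - 1L,
                 as.character(cohort$id[j])), call. = FALSE)
  }
  if (any(ok)) {
    P <- as.matrix(panel[, cons, drop = FALSE])
    wk <- m[ok] / 12
    out[ok, ] <- wk * P[i1[ok], , drop = FALSE] +
      (1 - wk) * P[i0[ok], , drop = FALSE]
  }
  if (any(!ok))
    message(sum(!ok), " recipient(s) dropped: no linkable exposure")
  res <- data.frame(id = cohort$id[ok], out[ok, , drop = FALSE],
                    check.names = FALSE)
  attr(res, "n_dropped") <- sum(!ok)
  attr(res, "constituents") <- cons
  res
}
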