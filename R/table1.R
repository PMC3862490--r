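## Published BCR-level trend comparison (1999-2009) between the spatial
## CAR model and the nonspatial hierarchical model, shipped as a
## plain-text fixture, plus the precision-comparison statistics computed
## from it. All statistics operate on the printed (rounded) values — the
## only ones available.

#' Load the shipped BCR trend comparison table
#'
#' 45 BCR x species combinations, each with a trend estimate (% per
#' year) and 95% CI for both methods (`"CAR"`, `"nonspatial"`). Validated
#' on load: both methods cover exactly the same combinations, and every
#' estimate lies inside its interval.
#'
#' @param path optional path to a CSV in the same dialect
#'   (`bcr,species,method,estimate,lo,hi`); default: the shipped fixture.
#' @return data.frame of class `trend_table`.
#' @export
load_trend_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1_trends.csv", package = "cartrend",
                        mustWork = TRUE)
  tt <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("bcr", "species", "method", "estimate", "lo", "hi")
  miss <- setdiff(need, names(tt))
  if (length(miss)) stop("trend table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(tt$method %in% c("CAR", "nonspatial")))
    stop("method must be 'CAR' or 'nonspatial'")
  bad <- which(tt$lo > tt$estimate | tt$estimate > tt$hi)
  if (length(bad)) stop("estimate outside its CI at row(s): ",
                        paste(bad, collapse = ", "))
  key <- function(m) sort(paste(tt$bcr, tt$species)[tt$method == m])
  if (!identical(key("CAR"), key("nonspatial")))
    stop("CAR and nonspatial rows cover different BCR x species combinations")
  class(tt) <- c("trend_table", "data.frame")
  tt
}

check_method <- function(table, method) {
  if (!method %in% c("CAR", "nonspatial"))
    stop("unknown method: ", method, " (use 'CAR' or 'nonspatial')")
  table[table$method == method, , drop = FALSE]
}

#' Count significant trends for one method
#'
#' A trend is significant when its 95% CI excludes 0. By default a
#' printed bound exactly equal to 0 counts as excluding 0
#' (`zero_bound_excludes = TRUE`): printed bounds are rounded, so a
#' displayed 0 stands for a bound on the open side of zero.
#'
#' @param table a `trend_table`.
#' @param method `"CAR"` or `"nonspatial"`.
#' @param zero_bound_excludes see above.
#' @return integer count.
#' @export
count_significant <- function(table, method, zero_bound_excludes = TRUE) {
  tt <- check_method(table, method)
  if (nrow(tt) == 0L) return(0L)
  sig <- if (zero_bound_excludes) tt$lo >= 0 | tt$hi <= 0 else tt$lo > 0 | tt$hi < 0
  sum(sig)
}

#' Spread of CI lengths for one method
#'
#' Sample standard deviation (n-1 denominator) of the 95% CI lengths
#' (`hi - lo`) across the table's rows for one method, rounded to 2
#' decimals for reporting. A method whose CI lengths vary less delivers
#' more consistent precision across regions.
#'
#' @param table a `trend_table`.
#' @param method `"CAR"` or `"nonspatial"`.
#' @return standard deviation of CI lengths, 2 decimals.
#' @export
ci_length_sd <- function(table, method) {
  tt <- check_method(table, method)
  if (nrow(tt) < 2L) stop("need at least 2 rows for method ", method)
  round(sd(tt$hi - tt$lo), 2)
}

#' Average precision gain of the spatial method
#'
#' `100 * (1 - mean CAR CI length / mean nonspatial CI length)` over the
#' selected rows, rounded to the nearest integer percent. Positive
#' values mean the spatial CIs are shorter on average.
#'
#' @param table a `trend_table`.
#' @param species a species name present in the table, or `"all"`.
#' @return integer percent.
#' @export
precision_gain <- function(table, species = "all") {
  tt <- table
  if (!identical(species, "all")) {
    if (!species %in% tt$species) stop("species not in table: ", species)
    tt <- tt[tt$species == species, , drop = FALSE]
  }
  len <- function(m) { s <- tt[tt$method == m, ]; mean(s$hi - s$lo) }
  round(100 * (1 - len("CAR") / len("nonspatial")))
}

#' Row-wise CI length comparison between methods
#'
#' For every BCR x species combination, compares the CI lengths of the
#' two methods at the table's printed precision. Returns how often the
#' nonspatial interval is strictly shorter, and the number of ties.
#'
#' @param table a `trend_table`.
#' @return named integer vector `c(nonspatial_smaller, ties)`.
#' @export
compare_ci_lengths <- function(table) {
  a <- table[table$method == "CAR", ]
  b <- table[table$method == "nonspatial", ]
  key <- function(x) paste(x$bcr, x$species)
  b <- b[match(key(a), key(b)), ]
  if (anyNA(b$estimate)) stop("mismatched row sets between methods")
  ## printed bounds carry <= 2 decimals; kill float noise before comparing
  la <- round(a$hi - a$lo, 8)
  lb <- round(b$hi - b$lo, 8)
  c(nonspatial_smaller = sum(lb < la), ties = sum(lb == la))
}
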