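# Method-agreement statistics: Pearson correlation, OLS regression and
# Bland-Altman limits of agreement, applied to paired measurements such as
# automatic- vs manual-ROI ERPF or CT right-to-left ratios vs scintigraphy
# uptake ratios. Differences are taken second-minus-first (y - x), so a
# positive bias means the second method reads higher.

checkPairs <- function(x, y, minN = 3L) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < minN)
    stop("at least ", minN, " pairs are required", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in the pairs", call. = FALSE)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y paired measurements (length >= 3, nonzero variance).
#' @return list with \code{r} and \code{pValue} (t distribution, n - 2 df).
#' @export
pearsonAgreement <- function(x, y) {
  checkPairs(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), pValue = ct$p.value)
}

#' OLS regression of y on x
#'
#' @param x,y paired measurements.
#' @return list with \code{slope} and \code{intercept}.
#' @export
regressAgreement <- function(x, y) {
  checkPairs(x, y)
  if (stats::sd(x) == 0) stop("zero x variance: regression undefined",
                              call. = FALSE)
  co <- stats::coef(stats::lm(y ~ x))
  list(slope = unname(co["x"]), intercept = unname(co["(Intercept)"]))
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences d = y - x; bias = mean(d); limits of agreement are
#' bias -/+ 1.96 times the sample (n - 1 denominator) SD of d.
#'
#' @param x,y paired measurements (length >= 2).
#' @return list with \code{bias}, \code{loaLow}, \code{loaHigh}, \code{sd}.
#' @examples
#' blandAltman(c(10, 20, 30), c(12, 18, 31))
#' @export
blandAltman <- function(x, y) {
  checkPairs(x, y, minN = 2L)
  d <- y - x
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loaLow = bias - 1.96 * s, loaHigh = bias + 1.96 * s,
       sd = s)
}

#' Full agreement summary for a method pair
#'
#' @param x reference-method values (e.g. manual-ROI ERPF).
#' @param y comparison-method values (e.g. automatic-ROI ERPF).
#' @return an \linkS4class{AgreementStats}.
#' @export
agreementStats <- function(x, y) {
  checkPairs(x, y, minN = 2L)
  ba <- blandAltman(x, y)
  if (length(x) >= 3L && stats::sd(x) > 0 && stats::sd(y) > 0) {
    pe <- pearsonAgreement(x, y)
    re <- regressAgreement(x, y)
  } else {
    pe <- list(r = NA_real_, pValue = NA_real_)
    re <- list(slope = NA_real_, intercept = NA_real_)
  }
  new("AgreementStats", n = length(x), r = pe$r, pValue = pe$pValue,
      slope = re$slope, intercept = re$intercept,
      bias = ba$bias, loaLow = ba$loaLow, loaHigh = ba$loaHigh)
}

#' Right-to-left ratio comparison between modalities
#'
#' Matches cases by id between a CT-ERPF table and an uptake table (each a
#' data.frame with columns \code{case_id}, \code{right}, \code{left}),
#' computes per-case right/left ratios for both, and summarizes their
#' agreement. With fewer than 3 shared cases the correlation is NA and a
#' warning flags it.
#'
#' @param erpfTable data.frame with case_id, right, left (ml/min).
#' @param uptakeTable data.frame with case_id, right, left (uptake units).
#' @return list with \code{ratios} (data.frame: case_id, ratio_x from the
#'   uptake table, ratio_y from the ERPF table) and \code{stats}
#'   (\linkS4class{AgreementStats}; differences are CT minus uptake).
#' @export
ratioComparison <- function(erpfTable, uptakeTable) {
  need <- c("case_id", "right", "left")
  for (tb in list(erpfTable, uptakeTable))
    if (!all(need %in% names(tb)))
      stop("tables need columns: ", paste(need, collapse = ", "),
           call. = FALSE)
  un1 <- setdiff(erpfTable$case_id, uptakeTable$case_id)
  un2 <- setdiff(uptakeTable$case_id, erpfTable$case_id)
  if (length(un1) || length(un2))
    stop("unmatched case ids: ",
         paste(unique(c(un1, un2)), collapse = ", "), call. = FALSE)
  m <- merge(erpfTable, uptakeTable, by = "case_id",
             suffixes = c("_erpf", "_uptake"))
  ratios <- data.frame(case_id = m$case_id,
                       ratio_x = m$right_uptake / m$left_uptake,
                       ratio_y = m$right_erpf / m$left_erpf)
  if (nrow(ratios) < 3L)
    warning("fewer than 3 shared cases: correlation and p-value unavailable")
  stats <- if (nrow(ratios) >= 2L)
    agreementStats(ratios$ratio_x, ratios$ratio_y)
  else
    new("AgreementStats", n = nrow(ratios), r = NA_real_, pValue = NA_real_,
        slope = NA_real_, intercept = NA_real_, bias = NA_real_,
        loaLow = NA_real_, loaHigh = NA_real_)
  list(ratios = ratios, stats = stats)
}
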