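# SG-like-condensate (SG-ls) enrichment scoring: stress-independent
# vs stress-dependent recruitment to G3BP1 condensates.

#' SG-ls enrichment scores
#'
#' Per protein (G3BP1 pull-down only): ratio = mean intensity across
#' the unstressed-condensate (SGls) replicates divided by the maximum
#' replicate-mean intensity across HS10..Re10; the log2 ratio is then
#' standardized (mean 0, sd 1) across the scoring cohort. Positive z
#' means enrichment in the stress-independent condensate, negative z
#' means heat-shock-SG enrichment.
#'
#' @param m quant_matrix containing SGls samples (bait G3BP1).
#' @param cohort accessions over which to standardize (default: all
#'   proteins in `m` with usable SGls and window measurements;
#'   typically the classified dynamic + invariable set).
#' @param denominator "window_max" (default) or "hs0" (re-runs the
#'   same score against the unstressed control instead of the window
#'   maximum).
#' @return data.frame: accession, ratio, log_ratio, z; attribute
#'   `excluded` (accessions with reasons), attribute `degenerate`
#'   (TRUE when the cohort has zero log-ratio variance, in which case
#'   z is all 0).
#' @export
sgls_scores <- function(m, cohort = NULL,
                        denominator = c("window_max", "hs0")) {
  stopifnot(inherits(m, "quant_matrix"))
  denominator <- match.arg(denominator)
  sg_cols <- which(m$samples$time_label == "SGls" &
                     m$samples$bait == "G3BP1")
  if (!length(sg_cols)) stop("no SGls samples present")
  sg_mean <- rowMeans(m$values[, sg_cols, drop = FALSE], na.rm = TRUE)

  if (denominator == "window_max") {
    win <- label_means(m, "G3BP1", labels = WINDOW_LABELS)
    denom <- apply(win, 1, function(x)
      if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
    denom_reason <- "window means missing/non-positive"
  } else {
    denom <- label_means(m, "G3BP1", labels = "HS0")[, 1]
    denom_reason <- "HS0 mean missing/non-positive"
  }

  acc <- m$records$accession
  if (is.null(cohort)) cohort <- acc
  idx <- match(cohort, acc)
  if (anyNA(idx)) stop("cohort accession(s) absent from matrix")

  sgm <- sg_mean[idx]; den <- denom[idx]
  bad_sg <- !is.finite(sgm) | sgm <= 0
  bad_den <- !is.finite(den) | den <= 0
  usable <- !(bad_sg | bad_den)
  excl <- data.frame(
    accession = cohort[!usable],
    reason = ifelse(bad_sg[!usable], "missing SGls measurement",
                    denom_reason),
    stringsAsFactors = FALSE)

  ratio <- sgm[usable] / den[usable]
  log_ratio <- log2(ratio)
  s <- sd(log_ratio)
  degenerate <- !is.finite(s) || s < 1e-12
  z <- if (degenerate) rep(0, length(log_ratio)) else
    (log_ratio - mean(log_ratio)) / s

  out <- data.frame(accession = cohort[usable], ratio = ratio,
                    log_ratio = log_ratio, z = z,
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excl
  attr(out, "degenerate") <- degenerate
  out
}
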