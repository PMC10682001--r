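# Fold-change rule separating dynamic from invariable proteins across
# the HS10 -> Re10 window.

#' Per-protein replicate-mean intensity at each condition label
#'
#' @param m quant_matrix.
#' @param bait "G3BP1" or "CAPRIN1".
#' @param labels condition labels to average (default: the nine
#'   time-course labels).
#' @return proteins x labels matrix of replicate means (NA-aware).
#' @export
label_means <- function(m, bait, labels = TIME_LABELS) {
  stopifnot(inherits(m, "quant_matrix"))
  sel <- m$samples$bait == bait
  if (!any(sel)) stop("no samples for bait ", bait)
  out <- vapply(labels, function(lab) {
    cols <- which(sel & m$samples$time_label == lab)
    if (!length(cols)) return(rep(NA_real_, nrow(m$values)))
    rowMeans(m$values[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(m$values)))
  matrix(out, nrow = nrow(m$values),
         dimnames = list(m$records$accession, labels))
}

#' Fold changes of each protein against the unstressed control
#'
#' Intensities are averaged over replicates at each time label; then,
#' per protein, fc_up = (maximum mean across HS10..Re10)/(mean at HS0)
#' and fc_down = (mean at HS0)/(minimum mean across HS10..Re10). The
#' unstressed condensate (SGls) column is never part of the window.
#'
#' @param m quant_matrix (normalized).
#' @param bait "G3BP1" or "CAPRIN1".
#' @return data.frame: accession, gene_name, hs0_mean, fc_up, fc_down,
#'   computable, reason. Proteins whose HS0 mean is non-positive or
#'   whose window is entirely missing are flagged uncomputable.
#' @export
fold_changes <- function(m, bait) {
  means <- label_means(m, bait, labels = c("HS0", WINDOW_LABELS))
  hs0 <- means[, "HS0"]
  win <- means[, WINDOW_LABELS, drop = FALSE]
  win_max <- apply(win, 1, function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  win_min <- apply(win, 1, function(x)
    if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
  bad_hs0 <- !is.finite(hs0) | hs0 <= 0
  bad_win <- !is.finite(win_max) | win_min <= 0
  computable <- !(bad_hs0 | bad_win)
  data.frame(
    accession = m$records$accession,
    gene_name = m$records$gene_name,
    hs0_mean = hs0,
    fc_up = ifelse(computable, win_max / hs0, NA_real_),
    fc_down = ifelse(computable, hs0 / win_min, NA_real_),
    computable = computable,
    reason = ifelse(bad_hs0, "non-positive or missing HS0 mean",
                    ifelse(bad_win, "window means missing/non-positive",
                           "")),
    stringsAsFactors = FALSE
  )
}

#' Classify proteins as dynamic or invariable
#'
#' A protein is dynamic when it shows a strictly greater than
#' `threshold` fold change -- either max/control (fc_up) or
#' control/min (fc_down) -- in BOTH pull-down datasets; everything
#' else quantified in both is invariable.
#'
#' @param fc_g3bp1,fc_caprin1 [fold_changes()] tables for the two baits.
#' @param threshold fold-change cutoff (default 1.2, strict >).
#' @param on_single_bait what to do with accessions computable in only
#'   one bait: "drop" (default; recorded in attribute `excluded`) or
#'   "error".
#' @return data.frame: accession, gene_name, per-bait fc columns,
#'   passing rule per bait (up/down/both/none), label
#'   (dynamic/invariable). Attribute `excluded` lists dropped
#'   accessions with reasons.
#' @export
classify_dynamic <- function(fc_g3bp1, fc_caprin1, threshold = 1.2,
                             on_single_bait = c("drop", "error")) {
  on_single_bait <- match.arg(on_single_bait)
  g <- fc_g3bp1[fc_g3bp1$computable, ]
  c_ <- fc_caprin1[fc_caprin1$computable, ]
  common <- intersect(g$accession, c_$accession)
  only <- setdiff(union(fc_g3bp1$accession, fc_caprin1$accession), common)
  if (length(only) && on_single_bait == "error")
    stop("accession(s) not computable in both baits: ",
         paste(head(only, 5), collapse = ", "),
         if (length(only) > 5) " ...")
  gi <- g[match(common, g$accession), ]
  ci <- c_[match(common, c_$accession), ]

  rule <- function(up, down) {
    ifelse(up > threshold & down > threshold, "both",
           ifelse(up > threshold, "up",
                  ifelse(down > threshold, "down", "none")))
  }
  rule_g <- rule(gi$fc_up, gi$fc_down)
  rule_c <- rule(ci$fc_up, ci$fc_down)
  dynamic <- rule_g != "none" & rule_c != "none"

  out <- data.frame(
    accession = common,
    gene_name = gi$gene_name,
    fc_up_g3bp1 = gi$fc_up, fc_down_g3bp1 = gi$fc_down,
    fc_up_caprin1 = ci$fc_up, fc_down_caprin1 = ci$fc_down,
    rule_g3bp1 = rule_g, rule_caprin1 = rule_c,
    label = ifelse(dynamic, "dynamic", "invariable"),
    stringsAsFactors = FALSE
  )
  excl <- data.frame(
    accession = only,
    reason = rep("not computable in both pull-down datasets",
                 length(only)),
    stringsAsFactors = FALSE
  )
  attr(out, "excluded") <- excl
  attr(out, "threshold") <- threshold
  out
}
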