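# Per-protein biochemical properties (pI, IDR coverage, PrLD/RBP
# flags) and the three-group statistical comparisons.

#' Built-in side-chain/terminus pKa sets for pI calculation
#'
#' EMBOSS (default) and Bjellqvist values. A custom named vector with
#' entries Nterm, Cterm, C, D, E, H, K, R, Y may be supplied instead.
#' @export
PKA_SETS <- list(
  EMBOSS = c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
             H = 6.5, K = 10.8, R = 12.5, Y = 10.1),
  Bjellqvist = c(Nterm = 7.5, Cterm = 3.55, C = 9.0, D = 4.05,
                 E = 4.45, H = 5.98, K = 10.0, R = 12.0, Y = 10.0)
)

POSITIVE_GROUPS <- c("Nterm", "K", "R", "H")
NEGATIVE_GROUPS <- c("Cterm", "D", "E", "C", "Y")
STANDARD_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# ionizable-group composition of a sequence (warns once about
# non-standard residues)
ionizable_counts <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  nonstd <- setdiff(unique(aa), STANDARD_AA)
  if (length(nonstd)) {
    warning("ignoring non-standard residue(s): ",
            paste(nonstd, collapse = ", "))
    aa <- aa[aa %in% STANDARD_AA]
  }
  if (!length(aa)) stop("empty sequence")
  counts <- c(Nterm = 1, Cterm = 1, table(aa)[c("C", "D", "E", "H",
                                                "K", "R", "Y")])
  names(counts) <- c("Nterm", "Cterm", "C", "D", "E", "H", "K", "R", "Y")
  counts[is.na(counts)] <- 0
  counts
}

charge_from_counts <- function(counts, pH, pka) {
  active <- names(counts)[counts > 0]
  missing_pka <- setdiff(active, names(pka))
  if (length(missing_pka))
    stop("pKa set lacks value(s) for: ",
         paste(missing_pka, collapse = ", "))
  pos_g <- intersect(active, POSITIVE_GROUPS)
  neg_g <- intersect(active, NEGATIVE_GROUPS)
  vapply(pH, function(p) {
    pos <- sum(counts[pos_g] / (1 + 10^(p - pka[pos_g])))
    neg <- sum(counts[neg_g] / (1 + 10^(pka[neg_g] - p)))
    pos - neg
  }, numeric(1))
}

resolve_pka <- function(pka_set) {
  if (is.character(pka_set) && length(pka_set) == 1)
    PKA_SETS[[match.arg(pka_set, names(PKA_SETS))]] else pka_set
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum: positive groups (N-terminus, K, R, H)
#' contribute n/(1 + 10^(pH - pKa)); negative groups (C-terminus, D,
#' E, C, Y) contribute -n/(1 + 10^(pKa - pH)).
#'
#' @param sequence amino-acid string (one-letter codes).
#' @param pH numeric pH (vectorized).
#' @param pka_set name in [PKA_SETS] or a named pKa vector.
#' @return net charge (same length as pH).
#' @export
net_charge <- function(sequence, pH, pka_set = "EMBOSS") {
  charge_from_counts(ionizable_counts(sequence), pH,
                     resolve_pka(pka_set))
}

#' Predicted isoelectric point of a protein sequence
#'
#' Bisection on pH in (0, 14) for the root of the net-charge curve;
#' composition-only, so the result is invariant to residue order.
#'
#' @inheritParams net_charge
#' @param tol pH tolerance (default 1e-4).
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence, pka_set = "EMBOSS",
                              tol = 1e-4) {
  counts <- ionizable_counts(sequence)  # composition-only, warns once
  pka <- resolve_pka(pka_set)
  lo <- 0; hi <- 14
  f <- function(p) charge_from_counts(counts, p, pka)
  flo <- f(lo); fhi <- f(hi)
  if (flo < 0) return(lo)
  if (fhi > 0) return(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Read a per-residue disorder score track
#'
#' Plain-text predictor output: "#"-prefixed header lines skipped,
#' whitespace-separated columns position, residue, score.
#'
#' @param path track file.
#' @return numeric score vector (one per residue).
#' @export
read_idr_track <- function(path) {
  tab <- read.table(path, comment.char = "#", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("expected columns: position, residue, score")
  as.numeric(tab[[3]])
}

#' Intrinsically-disordered-region coverage of a protein
#'
#' Fraction of residues whose disorder score is strictly greater than
#' the threshold: (length of regions with score > 0.5)/(total length).
#'
#' @param scores per-residue scores in [0, 1].
#' @param threshold disorder cutoff (default 0.5, strict >).
#' @return coverage fraction in [0, 1].
#' @export
idr_coverage <- function(scores, threshold = 0.5) {
  if (!length(scores)) stop("empty score track")
  if (anyNA(scores) || any(scores < 0 | scores > 1))
    stop("scores must lie in [0, 1]")
  mean(scores > threshold)
}

#' Parse a prion-like-domain prediction summary table
#'
#' Accepts a PLAAC-style TSV with a per-sequence core-length column
#' (matched case-insensitively against "CORELEN"/"core length"); a
#' protein has a PrLD when its core length is positive.
#'
#' @param path summary TSV (first column = sequence id).
#' @return data.frame: id, core_length, has_prld.
#' @export
parse_prld <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#")
  if (!ncol(tab)) stop("malformed PrLD table: ", path)
  core_col <- grep("core.?len", names(tab), ignore.case = TRUE)
  if (!length(core_col))
    stop("no core-length column found in ", path)
  core <- suppressWarnings(as.numeric(tab[[core_col[1]]]))
  if (anyNA(core)) stop("non-numeric core length in ", path)
  data.frame(id = as.character(tab[[1]]), core_length = core,
             has_prld = core > 0, stringsAsFactors = FALSE)
}

#' Compare a continuous property across protein groups
#'
#' Two groups: Welch's t-test. Three or more: one-way ANOVA with
#' Tukey HSD pairwise comparisons (Tukey-Kramer for unequal sizes).
#'
#' @param values numeric vector.
#' @param group factor/character of group labels (same length).
#' @param variable name carried in the result.
#' @param pairwise compute pairwise p-values (default TRUE).
#' @return object of class `group_comparison`: per-group summary
#'   (n, mean, median), method, statistic, df, p_value, pairwise
#'   table.
#' @export
compare_groups_continuous <- function(values, group,
                                      variable = "value",
                                      pairwise = TRUE) {
  group <- factor(group)
  ok <- is.finite(values) & !is.na(group)
  values <- values[ok]; group <- droplevels(group[ok])
  if (nlevels(group) < 2) stop("need >= 2 groups")
  if (any(table(group) < 2)) stop("every group needs >= 2 values")
  if (all(tapply(values, group, sd) < 1e-12))
    stop("degenerate variance in all groups")
  summ <- data.frame(
    group = levels(group),
    n = as.integer(table(group)),
    mean = as.numeric(tapply(values, group, mean)),
    median = as.numeric(tapply(values, group, median)),
    stringsAsFactors = FALSE)
  if (nlevels(group) == 2) {
    tt <- t.test(values ~ group)  # Welch by default
    pw <- data.frame(contrast = paste(levels(group), collapse = " - "),
                     p = tt$p.value, stringsAsFactors = FALSE)
    res <- list(variable = variable, method = "Welch t-test",
                summary = summ, statistic = unname(tt$statistic),
                df = unname(tt$parameter), p_value = tt$p.value,
                pairwise = if (pairwise) pw else NULL)
  } else {
    fit <- aov(values ~ group)
    a <- summary(fit)[[1]]
    pw <- NULL
    if (pairwise) {
      th <- TukeyHSD(fit)$group
      pw <- data.frame(contrast = rownames(th), diff = th[, "diff"],
                       p = th[, "p adj"], stringsAsFactors = FALSE,
                       row.names = NULL)
    }
    res <- list(variable = variable,
                method = "one-way ANOVA + Tukey HSD",
                summary = summ, statistic = a[["F value"]][1],
                df = a[["Df"]], p_value = a[["Pr(>F)"]][1],
                pairwise = pw)
  }
  structure(res, class = "group_comparison")
}

#' Compare group proportions with a Pearson chi-square test
#'
#' Two-sided chi-square without continuity correction on a 2 x k
#' count table (e.g. fused vs not-fused regions per treatment, RBP
#' vs non-RBP per protein group).
#'
#' @param contingency non-negative integer matrix/table with positive
#'   row and column margins.
#' @param variable name carried in the result.
#' @return `group_comparison` with statistic, df, p_value and the
#'   per-column proportions.
#' @export
compare_groups_categorical <- function(contingency,
                                       variable = "proportion") {
  tab <- as.matrix(contingency)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("contingency table must hold non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has a zero margin")
  if (is.null(colnames(tab)))
    colnames(tab) <- paste0("group", seq_len(ncol(tab)))
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  summ <- data.frame(group = colnames(tab),
                     n = colSums(tab),
                     proportion = tab[1, ] / colSums(tab),
                     row.names = NULL, stringsAsFactors = FALSE)
  structure(list(variable = variable,
                 method = "Pearson chi-square (no continuity correction)",
                 summary = summ, statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 pairwise = NULL),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("group_comparison [", x$variable, "]: ", x$method, "\n", sep = "")
  print(x$summary, row.names = FALSE)
  cat(sprintf("statistic = %.4g, p = %.4g\n", x$statistic, x$p_value))
  if (!is.null(x$pairwise)) {
    cat("pairwise:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Read protein sequences from a FASTA file
#' @param path FASTA file.
#' @return named character vector of sequences (names = first token
#'   of each header).
#' @export
read_protein_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers in ", path)
  id <- sub("^>", "", lines[hdr])
  id <- vapply(strsplit(id, "\\s+"), `[`, "", 1)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, "",
                 collapse = "")
  setNames(toupper(gsub("\\s", "", seqs)), id)
}
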