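# z-scoring, hierarchical clustering and PCA over dynamic-protein
# temporal profiles; early/late assignment; sigmoid inflection fitting.

#' Unit-variance (z-score) temporal profiles
#'
#' Per protein: replicate-mean intensity at each of the nine
#' time-course labels, then centered and divided by the sample
#' (n-1) standard deviation across labels. Zero-variance rows get
#' all-zero z and are flagged.
#'
#' @param m quant_matrix (normalized).
#' @param bait dataset to profile; the time-course clustering uses the
#'   CAPRIN1 pull-down by default.
#' @param proteins optional accession subset (e.g. the dynamic set).
#' @return proteins x 9 matrix of z-scores (rows ordered by
#'   accession); attribute `degenerate` flags zero-variance rows,
#'   attribute `dropped` lists proteins with incomplete label means.
#' @export
zscore_profiles <- function(m, bait = "CAPRIN1", proteins = NULL) {
  means <- label_means(m, bait, labels = TIME_LABELS)
  rownames(means) <- m$records$accession
  if (!is.null(proteins)) {
    idx <- match(proteins, rownames(means))
    if (anyNA(idx)) stop("unknown accession: ",
                         paste(proteins[is.na(idx)], collapse = ", "))
    means <- means[idx, , drop = FALSE]
  }
  complete <- apply(means, 1, function(x) all(is.finite(x)))
  dropped <- rownames(means)[!complete]
  if (length(dropped))
    warning(length(dropped), " protein(s) lack means at all 9 labels",
            " and were dropped")
  means <- means[complete, , drop = FALSE]
  means <- means[order(rownames(means)), , drop = FALSE]
  mu <- rowMeans(means)
  s <- apply(means, 1, sd)
  degenerate <- s < 1e-12
  z <- (means - mu) / ifelse(degenerate, 1, s)
  z[degenerate, ] <- 0
  attr(z, "degenerate") <- setNames(degenerate, rownames(means))
  attr(z, "dropped") <- dropped
  z
}

#' Agglomerative clustering of temporal profiles
#'
#' Chebyshev (maximum coordinate difference) distance with average
#' linkage, cut to k clusters. Rows are sorted by accession before
#' the distance computation so the result is invariant to input
#' order.
#'
#' @param profiles proteins x labels z-matrix.
#' @param k number of clusters (default 2: early/late).
#' @return list: `tree` (hclust), `labels` (named integer cluster ids).
#' @export
hierarchical_cluster <- function(profiles, k = 2) {
  if (k > nrow(profiles))
    stop("k = ", k, " exceeds number of profiles (", nrow(profiles), ")")
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  d <- dist(profiles, method = "maximum")
  tree <- hclust(d, method = "average")
  labels <- cutree(tree, k = k)
  list(tree = tree, labels = labels)
}

#' Principal-component loadings of temporal profiles
#'
#' PCA of the protein x label z-matrix with proteins as observations;
#' returns each protein's coordinates on the first two components
#' ("component loadings" in the clustering-heatmap sense) and the
#' variance explained. Sign convention: PC1 is flipped so its label
#' weights correlate negatively with sampling order (early, decreasing
#' proteins then load negative); PC2 is flipped so its first label
#' weight is non-negative.
#'
#' @param profiles proteins x labels z-matrix.
#' @return list: `loadings` (proteins x 2), `explained_variance`
#'   (fractions), `rotation` (labels x 2).
#' @export
pca_loadings <- function(profiles) {
  if (nrow(profiles) < 3) stop("need >= 3 profiles")
  p <- prcomp(profiles, center = TRUE, scale. = FALSE)
  k <- min(2, ncol(p$x))
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  x <- p$x[, seq_len(k), drop = FALSE]
  ord <- seq_len(nrow(rot))
  if (sum(p$sdev^2) > 0) {
    if (isTRUE(cor(rot[, 1], ord) > 0)) {
      rot[, 1] <- -rot[, 1]; x[, 1] <- -x[, 1]
    }
    if (k >= 2 && rot[1, 2] < 0) {
      rot[, 2] <- -rot[, 2]; x[, 2] <- -x[, 2]
    }
  }
  ev <- p$sdev^2 / max(sum(p$sdev^2), .Machine$double.eps)
  list(loadings = x, explained_variance = ev[seq_len(k)],
       rotation = rot)
}

#' Assign early/late identities to two temporal clusters
#'
#' The cluster whose mean z-score at HS10 exceeds its mean z-score at
#' HS180 is "early" (SG abundance decreasing over prolonged stress);
#' the other is "late". If both clusters trend the same way the
#' steeper-declining one is early and a warning is emitted; an exact
#' tie is an error.
#'
#' @param labels named cluster ids from [hierarchical_cluster()].
#' @param profiles the z-matrix the clustering was computed on.
#' @return data.frame: accession, cluster ("early"/"late"), original
#'   cluster id.
#' @export
assign_early_late <- function(labels, profiles) {
  ids <- sort(unique(labels))
  if (length(ids) != 2) stop("expected exactly two clusters")
  drop_ <- function(cl)
    colMeans(profiles[names(labels)[labels == cl], , drop = FALSE])
  d <- vapply(ids, function(cl) {
    mz <- drop_(cl); mz[["HS10"]] - mz[["HS180"]]
  }, numeric(1))
  if (d[1] == d[2]) stop("clusters tie on the HS10 vs HS180 contrast")
  if (all(d > 0) || all(d < 0))
    warning("both clusters trend the same way; assigning the ",
            "steeper-declining cluster as early")
  early_id <- ids[which.max(d)]
  data.frame(
    accession = names(labels),
    cluster = ifelse(labels == early_id, "early", "late"),
    cluster_id = unname(labels),
    stringsAsFactors = FALSE
  )
}

#' Fit a four-parameter logistic to a temporal profile
#'
#' Least squares on v(t) = lower + (upper - lower)/(1 + exp(-slope *
#' (t - t0))), multi-started on t0 over the observed time grid (and on
#' slope sign/magnitude); t0 is bounded to the observed time range.
#' The inflection time is t0.
#'
#' @param times minutes, strictly increasing.
#' @param values profile values (same length).
#' @return object of class `sigmoid_fit`: lower, upper, t0, slope,
#'   direction ("decreasing"/"increasing"), rss, converged, fitted.
#' @export
fit_sigmoid <- function(times, values) {
  if (length(times) < 4) stop("need >= 4 points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (length(values) != length(times))
    stop("times and values differ in length")
  degenerate <- sd(values) < 1e-10
  best <- NULL
  if (!degenerate) {
    df <- data.frame(t = times, v = values)
    trend <- suppressWarnings(cor(times, values))
    slope_starts <- c(0.02, 0.1, 0.3)
    slope_starts <- c(slope_starts * sign(ifelse(is.na(trend) ||
                                                   trend == 0, 1, trend)),
                      -0.1 * sign(ifelse(is.na(trend) || trend == 0,
                                         1, trend)))
    t0_starts <- unique(c(times[-c(1, length(times))],
                          mean(range(times))))
    for (t0s in t0_starts) for (ss in slope_starts) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          v ~ lower + (upper - lower) / (1 + exp(-slope * (t - t0))),
          data = df,
          start = list(lower = min(values), upper = max(values),
                       slope = ss, t0 = t0s),
          lower = c(lower = -Inf, upper = -Inf, slope = -10,
                    t0 = min(times)),
          upper = c(lower = Inf, upper = Inf, slope = 10,
                    t0 = max(times)),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(lower = min(values), upper = max(values),
                          t0 = NA_real_, slope = NA_real_,
                          direction = NA_character_, rss = NA_real_,
                          converged = FALSE,
                          fitted = rep(mean(values), length(values))),
                     class = "sigmoid_fit"))
  }
  cf <- coef(best$fit)
  fv <- fitted(best$fit)
  flat <- abs(cf[["upper"]] - cf[["lower"]]) < 1e-6
  structure(list(
    lower = cf[["lower"]], upper = cf[["upper"]], t0 = cf[["t0"]],
    slope = cf[["slope"]],
    direction = if (fv[length(fv)] < fv[1]) "decreasing" else
      "increasing",
    rss = best$rss,
    converged = !flat,
    fitted = as.numeric(fv)),
    class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf(
      "sigmoid_fit: %s, inflection t0 = %.2f min (slope %.4f, rss %.4g)\n",
      x$direction, x$t0, x$slope, x$rss))
  else cat("sigmoid_fit: not converged / degenerate\n")
  invisible(x)
}

#' Fit group-average sigmoid kinetics for early and late clusters
#'
#' Averages z-profiles within each cluster and fits the logistic over
#' the heat-shock portion of the course (0--180 min); recovery points
#' reverse the trend and are excluded by default.
#'
#' @param profiles z-matrix (proteins x 9 labels).
#' @param assignment data.frame from [assign_early_late()].
#' @param include_recovery also use Re5/Re10 (on the recovery clock
#'   appended after 180 min)? Default FALSE.
#' @return named list of `sigmoid_fit` objects (early, late) with the
#'   group-average profiles attached.
#' @export
fit_group_sigmoids <- function(profiles, assignment,
                               include_recovery = FALSE) {
  labs <- if (include_recovery) TIME_LABELS else names(HS_MINUTES)
  tt <- if (include_recovery)
    c(HS_MINUTES, Re5 = 185, Re10 = 190) else HS_MINUTES
  out <- lapply(c(early = "early", late = "late"), function(cl) {
    acc <- assignment$accession[assignment$cluster == cl]
    avg <- colMeans(profiles[acc, labs, drop = FALSE])
    fit <- fit_sigmoid(unname(tt[labs]), unname(avg))
    fit$mean_profile <- avg
    fit$n_proteins <- length(acc)
    fit
  })
  out
}

#' Export a clustering dendrogram as Newick text
#' @param tree an hclust object.
#' @param path output file.
#' @return invisibly, the Newick string.
#' @export
write_dendrogram_newick <- function(tree, path) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the 'ape' package is required for Newick export")
  txt <- ape::write.tree(ape::as.phylo(tree))
  writeLines(txt, path)
  invisible(txt)
}
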