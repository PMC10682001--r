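# Column scaling, empirical-Bayes batch correction across replicates,
# and TMM normalization of intensity matrices.

#' Scale every sample column to the mean column total
#'
#' Each column is multiplied by (mean of all column sums)/(its sum) so
#' that every sample carries an equal total amount. Missing values are
#' treated as 0 for the sums and stay missing afterwards.
#'
#' @param m quant_matrix.
#' @return quant_matrix with equal column sums.
#' @export
scale_columns_to_mean <- function(m) {
  stopifnot(inherits(m, "quant_matrix"))
  cs <- colSums(m$values, na.rm = TRUE)
  if (any(cs == 0))
    stop("column sum is zero for sample(s): ",
         paste(m$samples$sample_id[cs == 0], collapse = ", "))
  target <- mean(cs)
  out <- m
  out$values <- sweep(m$values, 2, target / cs, `*`)
  out
}

# half the smallest positive finite value; floor used before logging
intensity_floor <- function(values) {
  pos <- values[is.finite(values) & values > 0]
  if (!length(pos)) stop("matrix contains no positive intensities")
  min(pos) / 2
}

#' Empirical-Bayes location/scale batch correction
#'
#' Adjusts log2 intensities for additive and multiplicative batch
#' effects with parametric empirical-Bayes shrinkage: per protein,
#' values are standardized against a pooled model with the condition
#' group (early/middle/late over the time course) as covariate;
#' per-batch location (gamma) and scale (delta) effects are estimated,
#' shrunk towards normal / inverse-gamma priors fitted across
#' proteins, removed, and the data back-transformed. Batches are the
#' TMT replicates. Samples without a condition group (the unstressed
#' condensate column) are given their own covariate level so they are
#' corrected on the same scale.
#'
#' Zeros and missing values are replaced by half the smallest positive
#' intensity before logging; originally-missing cells are restored to
#' NA afterwards. Proteins with (near-)zero pooled variance are passed
#' through unadjusted, so data carrying no batch signal are returned
#' unchanged.
#'
#' @param m quant_matrix (strictly positive after flooring).
#' @param parametric only parametric priors are implemented; kept as
#'   an argument for interface clarity.
#' @param max_iter,tol iteration control for the empirical-Bayes
#'   fixed-point solver.
#' @return list with `matrix` (adjusted quant_matrix) and `model`
#'   (per-batch gamma_hat/gamma_star, delta_hat/delta_star and prior
#'   hyperparameters).
#' @export
combat_adjust <- function(m, parametric = TRUE, max_iter = 200,
                          tol = 1e-6) {
  stopifnot(inherits(m, "quant_matrix"))
  if (!parametric) stop("non-parametric priors are not implemented")
  batch <- factor(m$samples$replicate)
  if (nlevels(batch) < 2) stop("need >= 2 batches (replicates)")
  if (any(table(batch) < 2)) stop("every batch needs >= 2 samples")
  group <- m$samples$combat_group
  group[is.na(group)] <- "condensate"
  group <- factor(group)

  # design: one indicator per batch + condition-group covariates
  batch_design <- stats::model.matrix(~ 0 + batch)
  mod <- if (nlevels(group) > 1)
    stats::model.matrix(~ group)[, -1, drop = FALSE]
  else NULL
  design <- cbind(batch_design, mod)
  if (qr(design)$rank < ncol(design)) {
    confounded <- vapply(levels(batch), function(b)
      length(unique(group[batch == b])) == 1, logical(1))
    stop("batch/group design is singular",
         if (any(confounded)) paste0(
           " (batch ", paste(levels(batch)[confounded], collapse = ", "),
           " contains a single condition group)") else "")
  }

  na_mask <- is.na(m$values)
  floor_val <- intensity_floor(m$values)
  v <- m$values
  v[na_mask | v <= 0] <- floor_val
  dat <- log2(v)  # proteins x samples

  n <- ncol(dat)
  n_batch <- nlevels(batch)
  batches <- lapply(levels(batch), function(b) which(batch == b))
  n_per <- lengths(batches)

  B_hat <- solve(crossprod(design), t(design) %*% t(dat))
  grand_mean <- crossprod(n_per / n, B_hat[seq_len(n_batch), ,
                                           drop = FALSE])
  var_pooled <- ((dat - t(design %*% B_hat))^2) %*% rep(1 / n, n)
  var_pooled <- as.numeric(var_pooled)
  degenerate <- var_pooled < 1e-12

  stand_mean <- matrix(grand_mean, nrow(dat), n)
  if (!is.null(mod)) {
    tmp <- design
    tmp[, seq_len(n_batch)] <- 0
    stand_mean <- stand_mean + t(tmp %*% B_hat)
  }
  sdv <- sqrt(pmax(var_pooled, 1e-12))
  s_data <- (dat - stand_mean) / sdv

  gamma_hat <- solve(crossprod(batch_design),
                     t(batch_design) %*% t(s_data))
  delta_hat <- t(vapply(batches, function(idx)
    apply(s_data[, idx, drop = FALSE], 1, var), numeric(nrow(dat))))

  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1, var)
  apriors <- apply(delta_hat, 1, function(d) {
    mdel <- mean(d); s2 <- var(d); (2 * s2 + mdel^2) / s2
  })
  bpriors <- apply(delta_hat, 1, function(d) {
    mdel <- mean(d); s2 <- var(d); (mdel * s2 + mdel^3) / s2
  })

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (i in seq_len(n_batch)) {
    idx <- batches[[i]]
    ni <- n_per[i]
    g_hat <- gamma_hat[i, ]
    g_old <- g_hat
    d_old <- pmax(delta_hat[i, ], 1e-12)
    sub <- s_data[, idx, drop = FALSE]
    for (it in seq_len(max_iter)) {
      g_new <- (t2[i] * ni * g_hat + d_old * gamma_bar[i]) /
        (t2[i] * ni + d_old)
      sum2 <- rowSums((sub - g_new)^2)
      d_new <- (0.5 * sum2 + bpriors[i]) / (ni / 2 + apriors[i] - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                    abs(d_new - d_old) / d_old)
      g_old <- g_new
      d_old <- d_new
      if (change < tol) break
    }
    gamma_star[i, ] <- g_old
    delta_star[i, ] <- d_old
  }

  adjusted <- s_data
  for (i in seq_len(n_batch)) {
    idx <- batches[[i]]
    adjusted[, idx] <- (s_data[, idx, drop = FALSE] -
                          gamma_star[i, ]) / sqrt(delta_star[i, ])
  }
  adjusted <- adjusted * sdv + stand_mean
  adjusted[degenerate, ] <- dat[degenerate, ]

  out_vals <- 2^adjusted
  out_vals[na_mask] <- NA_real_
  out <- m
  out$values <- out_vals

  model <- list(
    batch_of_sample = setNames(as.character(batch), m$samples$sample_id),
    group_of_sample = setNames(as.character(group), m$samples$sample_id),
    gamma_hat = gamma_hat, gamma_star = gamma_star,
    delta_hat = delta_hat, delta_star = delta_star,
    var_pooled = var_pooled,
    # batch location effects back on the log2 scale
    gamma_star_log2 = sweep(gamma_star, 2, sqrt(pmax(var_pooled,
                                                     1e-12)), `*`),
    prior_params = data.frame(batch = levels(batch),
                              gamma_bar = gamma_bar, t2 = t2,
                              a_prior = apriors, b_prior = bpriors),
    degenerate_proteins = m$records$accession[degenerate]
  )
  list(matrix = out, model = model)
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' For each sample against a reference: M = log2(sample/reference) and
#' A = 0.5*log2(sample*reference) over proteins positive in both;
#' proteins outside the central (1 - 2*trim_M) quantile band of M or
#' the central (1 - 2*trim_A) band of A are trimmed; the factor is
#' 2^(precision-weighted mean of the retained M), with weights the
#' inverse delta-method variances 1/(1/sample + 1/reference). Column
#' totals are assumed already equalized upstream, so M carries no
#' library-size term. The "auto" reference is the sample whose upper
#' quartile is closest to the mean upper quartile.
#'
#' @param m quant_matrix or numeric matrix.
#' @param reference sample id, column index, or "auto".
#' @param trim_M,trim_A two-sided trim fractions (defaults 0.30, 0.05).
#' @param min_pairs minimum usable protein pairs per sample (default 10).
#' @return list of class `tmm_factors`: reference_sample,
#'   factor_of_sample (named, reference = 1), trim fractions.
#' @export
tmm_factors <- function(m, reference = "auto", trim_M = 0.30,
                        trim_A = 0.05, min_pairs = 10) {
  vals <- if (inherits(m, "quant_matrix")) m$values else as.matrix(m)
  ids <- colnames(vals)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(vals)))
  if (identical(reference, "auto")) {
    uq <- apply(vals, 2, function(x)
      quantile(x[is.finite(x) & x > 0], 0.75, names = FALSE))
    ref_idx <- which.min(abs(uq - mean(uq)))
  } else {
    ref_idx <- if (is.character(reference)) match(reference, ids)
    else as.integer(reference)
    if (is.na(ref_idx) || ref_idx < 1 || ref_idx > ncol(vals))
      stop("unknown reference sample: ", reference)
  }
  ref <- vals[, ref_idx]
  factors <- vapply(seq_len(ncol(vals)), function(k) {
    x <- vals[, k]
    ok <- is.finite(x) & is.finite(ref) & x > 0 & ref > 0
    if (sum(ok) < min_pairs)
      stop("fewer than ", min_pairs, " usable pairs for sample ",
           ids[k])
    M <- log2(x[ok] / ref[ok])
    A <- 0.5 * log2(x[ok] * ref[ok])
    np <- length(M)
    # rank-based double trim (keeps exactly the central band even
    # under ties)
    rM <- rank(M, ties.method = "average")
    rA <- rank(A, ties.method = "average")
    keep <- rM > floor(np * trim_M) & rM <= np - floor(np * trim_M) &
      rA > floor(np * trim_A) & rA <= np - floor(np * trim_A)
    w <- 1 / (1 / x[ok] + 1 / ref[ok])
    2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }, numeric(1))
  names(factors) <- ids
  structure(list(reference_sample = ids[ref_idx],
                 factor_of_sample = factors,
                 trim_M = trim_M, trim_A = trim_A),
            class = "tmm_factors")
}

#' Apply TMM factors to a quant_matrix
#'
#' Factors are re-centered to geometric mean 1 across samples and each
#' column is divided by its factor.
#'
#' @param m quant_matrix.
#' @param factors a [tmm_factors()] object.
#' @return quant_matrix.
#' @export
apply_tmm <- function(m, factors) {
  stopifnot(inherits(m, "quant_matrix"), inherits(factors, "tmm_factors"))
  f <- factors$factor_of_sample[m$samples$sample_id]
  if (anyNA(f)) stop("factors do not cover all samples")
  f <- f / exp(mean(log(f)))
  out <- m
  out$values <- sweep(m$values, 2, f, `/`)
  out
}

#' Full normalization chain for one pull-down dataset
#'
#' Runs, in order: column scaling to the mean total -> empirical-Bayes
#' batch correction (batches = replicates, covariate = condition
#' group) -> TMM. The chain is deterministic given its input.
#'
#' @param m quant_matrix.
#' @param reference TMM reference ("auto" by default).
#' @return list: `matrix` (normalized quant_matrix), `batch_model`,
#'   `tmm` factors.
#' @export
normalize_intensities <- function(m, reference = "auto") {
  scaled <- scale_columns_to_mean(m)
  cb <- combat_adjust(scaled)
  f <- tmm_factors(cb$matrix, reference = reference)
  list(matrix = apply_tmm(cb$matrix, f),
       batch_model = cb$model, tmm = f)
}
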