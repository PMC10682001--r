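# Shared fixture builders: small quant matrices and oracles used
# across test files.

# minimal protein-record table
make_records <- function(acc, gene = acc, mito = FALSE, ker = FALSE,
                         fdr = "high", peptides = list(c(1L, 1L, 1L))) {
  n <- length(acc)
  rec <- data.frame(accession = acc, gene_name = rep_len(gene, n),
                    is_mitochondrial = rep_len(mito, n),
                    is_keratin = rep_len(ker, n),
                    fdr_confidence = rep_len(fdr, n),
                    stringsAsFactors = FALSE)
  rec$unique_peptides <- rep_len(peptides, n)
  rec
}

# full 9-label x 3-replicate design for one bait (+ optional SGls)
make_design <- function(bait = "CAPRIN1", with_sgls = FALSE,
                        n_rep = 3) {
  labels <- if (with_sgls) c(sgdynamics:::TIME_LABELS, "SGls") else
    sgdynamics:::TIME_LABELS
  grid <- expand.grid(r = seq_len(n_rep), lab = labels,
                      stringsAsFactors = FALSE)
  sample_design(paste0(bait, "_", grid$lab, "_R", grid$r),
                grid$lab, grid$r, bait)
}

# quant_matrix whose per-label replicate means equal `label_means`
# (proteins x 9), exactly (no noise)
make_quant_from_means <- function(label_means, bait = "CAPRIN1",
                                  n_rep = 3) {
  des <- make_design(bait, n_rep = n_rep)
  vals <- label_means[, des$time_label, drop = FALSE]
  rec <- make_records(rownames(label_means))
  quant_matrix(vals, rec, des)
}

# random positive quant matrix for property tests
make_random_quant <- function(n = 50, bait = "CAPRIN1", seed = 1,
                              with_sgls = FALSE) {
  set.seed(seed)
  des <- make_design(bait, with_sgls = with_sgls)
  vals <- matrix(2^rnorm(n * nrow(des), 15, 1), n)
  rec <- make_records(sprintf("P%03d", seq_len(n)))
  quant_matrix(vals, rec, des)
}

# independent 8-connected labelling oracle: BFS flood fill
flood_fill_label <- function(mask) {
  mask <- mask > 0
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  nbr <- expand.grid(dr = -1:1, dc = -1:1)
  nbr <- nbr[!(nbr$dr == 0 & nbr$dc == 0), ]
  for (start in which(mask & lab == 0)) {
    if (lab[start] != 0) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      r <- (p - 1) %% nrow(mask) + 1
      cc <- (p - 1) %/% nrow(mask) + 1
      for (k in seq_len(nrow(nbr))) {
        r2 <- r + nbr$dr[k]; c2 <- cc + nbr$dc[k]
        if (r2 < 1 || r2 > nrow(mask) || c2 < 1 || c2 > ncol(mask))
          next
        q <- (c2 - 1) * nrow(mask) + r2
        if (mask[q] && lab[q] == 0) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# brute-force optimal bipartite matching (minimum total distance)
# for small point sets; oracle for the greedy tracker
brute_force_match <- function(a, b, max_disp) {
  n <- nrow(a); m <- nrow(b)
  k <- min(n, m)
  best <- NULL; best_cost <- Inf
  idx <- seq_len(m)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  for (sub in utils::combn(idx, k, simplify = FALSE))
    for (p in perms(sub)) {
      d <- sqrt((a$x[seq_len(k)] - b$x[p])^2 +
                  (a$y[seq_len(k)] - b$y[p])^2)
      ok <- d <= max_disp
      cost <- sum(d[ok]) + sum(!ok) * 1e6
      if (cost < best_cost) {
        best_cost <- cost
        best <- cbind(seq_len(k)[ok], p[ok])
      }
    }
  best
}

# Newman-Girvan Q by direct edge-by-edge summation (oracle)
brute_force_modularity <- function(g, membership) {
  el <- igraph::as_edgelist(g, names = FALSE)
  m <- nrow(el)
  deg <- igraph::degree(g)
  q <- 0
  for (c_ in unique(membership)) {
    nodes <- which(membership == c_)
    e_c <- sum(el[, 1] %in% nodes & el[, 2] %in% nodes)
    d_c <- sum(deg[nodes])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}
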