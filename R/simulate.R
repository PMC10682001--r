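# Seeded generators producing time-course matrices, property tables,
# PPI graphs and granule movies with known ground truth.

#' Simulation configuration for the synthetic SG time course
#'
#' Defaults emulate the study conditions: three protein classes with
#' sigmoidal log2 kinetics (early, decreasing, inflection 21 min;
#' late, increasing, inflection 30 min; invariable, flat), three TMT
#' replicates with additive log2 batch shifts, log-normal measurement
#' noise, recovery points reverting partway towards the unstressed
#' control, and an unstressed-condensate (SGls) column in the G3BP1
#' pull-down whose early-protein behaviour is bipolar (a
#' ribosomal-like early subset is depleted from the condensate).
#'
#' @param n_early,n_late,n_invariable class sizes (defaults
#'   150/100/80).
#' @param inflection_early,inflection_late minutes (21, 30).
#' @param slope logistic rate (1/min, default 0.15).
#' @param amplitude kinetic swing in log2 units (default 1.5, i.e.
#'   ~2.8-fold, comfortably beyond the 1.2-fold call threshold).
#' @param noise_sd total per-measurement log2 noise sd (default 0.3).
#'   Measurement error is decomposed TMT-style into a per-(protein,
#'   replicate) shared component -- pull-down/labelling efficiency,
#'   the per-protein batch effect the empirical-Bayes correction
#'   estimates -- of sd sqrt(noise_sd^2 - channel_noise_sd^2), plus
#'   an i.i.d. per-channel residual of sd `channel_noise_sd`.
#' @param channel_noise_sd i.i.d. per-channel residual log2 sd
#'   (default 0.1, within-run TMT channel precision; must not exceed
#'   `noise_sd`).
#' @param batch_shifts per-replicate mean additive log2 offsets
#'   (default c(0, 0.4, -0.3)); each protein's per-replicate batch
#'   effect scatters around these.
#' @param sgls_effect named per-class mean log2 SGls/window-max ratio
#'   (early 0.6, late -0.8, invariable 0, ribosomal -0.8).
#' @param ribo_fraction fraction of early proteins given the
#'   ribosomal-like negative SGls effect (default 0.2).
#' @param recovery_return fractional reversion towards HS0 at 10 min
#'   recovery (default 0.3; Re5 reverts half as far).
#' @param baseline_mean,baseline_sd per-protein log2 abundance prior.
#' @param core_abundance_log2 extra log2 abundance given to the
#'   invariable class (default 2.5): the stable core (bait and
#'   scaffold proteins) dominates pull-down mass, which keeps column
#'   totals stable and anchors the abundance-weighted TMM step.
#' @param n_replicates TMT replicates per condition (default 3).
#' @param n_missing_sgls,n_single_bait,n_zero_variance degenerate-case
#'   toggles: proteins with the SGls measurement removed, proteins
#'   present only in the G3BP1 dataset, and exactly-constant proteins
#'   (all drawn from the invariable class where possible).
#' @param seed integer; fixes all randomness.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_early = 150, n_late = 100, n_invariable = 80,
                       inflection_early = 21, inflection_late = 30,
                       slope = 0.15, amplitude = 1.5, noise_sd = 0.3,
                       channel_noise_sd = min(0.1, noise_sd),
                       batch_shifts = c(0, 0.4, -0.3),
                       sgls_effect = c(early = 0.6, late = -0.8,
                                       invariable = 0,
                                       ribosomal = -0.8),
                       ribo_fraction = 0.2, recovery_return = 0.3,
                       baseline_mean = 17, baseline_sd = 1.2,
                       core_abundance_log2 = 2.5,
                       n_replicates = 3, n_missing_sgls = 0,
                       n_single_bait = 0, n_zero_variance = 0,
                       seed = 7) {
  stopifnot(n_early >= 0, n_late >= 0, n_invariable >= 0,
            noise_sd >= 0, channel_noise_sd >= 0,
            channel_noise_sd <= noise_sd,
            length(batch_shifts) == n_replicates)
  structure(as.list(environment()), class = "sim_config")
}

# class mean log2 deviation from baseline at HS minutes t; kinetic
# templates are centred on the baseline (half-amplitude up/down) so
# planted dynamics leave column totals stable -- the scale on which
# the equal-amount + TMM normalization (and hence the fold-change
# rule) operates
sim_template <- function(class, t, cfg) {
  a <- cfg$amplitude
  switch(class,
         early = a * (1 - plogis(cfg$slope * (t - cfg$inflection_early))) -
           a / 2,
         late = a * plogis(cfg$slope * (t - cfg$inflection_late)) - a / 2,
         invariable = rep(0, length(t)))
}

# template over the nine labels, with recovery reverting towards HS0
sim_profile <- function(class, cfg) {
  hs <- sim_template(class, unname(HS_MINUTES), cfg)
  names(hs) <- names(HS_MINUTES)
  rev_frac <- cfg$recovery_return * c(Re5 = 0.5, Re10 = 1)
  re <- hs[["HS180"]] + rev_frac * (hs[["HS0"]] - hs[["HS180"]])
  c(hs, re)
}

#' Simulate the two-bait SG time-course experiment
#'
#' Generates matched G3BP1 (with SGls columns) and CAPRIN1 intensity
#' matrices plus the planted truth. Per protein: mean log2 profile =
#' baseline + class template; per sample: + replicate batch shift +
#' N(0, noise_sd); intensities are 2^log2. SGls replicates are drawn
#' around the protein's window maximum times 2^(class effect).
#'
#' @param cfg a [sim_config()].
#' @return list: g3bp1 (quant_matrix), caprin1 (quant_matrix), truth
#'   (accession, gene_name, class, is_ribosomal_like, inflection),
#'   config.
#' @export
simulate_timecourse <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_early + cfg$n_late + cfg$n_invariable
  classes <- rep(c("early", "late", "invariable"),
                 c(cfg$n_early, cfg$n_late, cfg$n_invariable))
  acc <- sprintf("SIM%04d", seq_len(n))
  gene <- sprintf("GENE%d", seq_len(n))
  n_ribo <- floor(cfg$ribo_fraction * cfg$n_early)
  is_ribo <- rep(FALSE, n)
  if (n_ribo > 0) is_ribo[sample(which(classes == "early"), n_ribo)] <- TRUE
  baseline <- rnorm(n, cfg$baseline_mean, cfg$baseline_sd) +
    ifelse(classes == "invariable", cfg$core_abundance_log2, 0)

  # degenerate-case toggles, preferentially on invariable proteins
  pick_tail <- function(k) {
    pool <- which(classes == "invariable")
    if (length(pool) < k) pool <- seq_len(n)
    utils::tail(pool, k)
  }
  zero_var <- if (cfg$n_zero_variance > 0)
    pick_tail(cfg$n_zero_variance) else integer(0)
  miss_sgls <- if (cfg$n_missing_sgls > 0)
    utils::head(which(classes == "invariable"), cfg$n_missing_sgls)
  else integer(0)
  single_bait <- if (cfg$n_single_bait > 0)
    utils::head(seq_len(n), cfg$n_single_bait) else integer(0)

  profiles <- t(vapply(classes, sim_profile, numeric(9), cfg = cfg))
  colnames(profiles) <- TIME_LABELS
  mean_log2 <- baseline + profiles  # n x 9

  batch_sd <- sqrt(max(0, cfg$noise_sd^2 - cfg$channel_noise_sd^2))
  make_bait <- function(bait, with_sgls) {
    labels <- if (with_sgls) ALL_LABELS else TIME_LABELS
    grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                        time_label = labels,
                        KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    samples <- sample_design(
      sample_id = paste0(bait, "_", grid$time_label, "_R",
                         grid$replicate),
      time_label = grid$time_label, replicate = grid$replicate,
      bait = bait)
    # per-(protein, replicate) batch effect around the replicate shift
    batch_eff <- vapply(seq_len(cfg$n_replicates), function(r)
      rnorm(n, cfg$batch_shifts[r], batch_sd), numeric(n))
    vals <- matrix(NA_real_, n, nrow(samples))
    for (j in seq_len(nrow(samples))) {
      lab <- samples$time_label[j]
      if (lab == "SGls") {
        win_max <- apply(mean_log2[, WINDOW_LABELS, drop = FALSE], 1,
                         max)
        eff <- ifelse(is_ribo, cfg$sgls_effect[["ribosomal"]],
                      cfg$sgls_effect[classes])
        mu <- win_max + eff
      } else {
        mu <- mean_log2[, lab]
      }
      lv <- mu + batch_eff[, samples$replicate[j]] +
        rnorm(n, 0, cfg$channel_noise_sd)
      lv[zero_var] <- baseline[zero_var]  # exactly constant rows
      vals[, j] <- 2^lv
    }
    if (with_sgls && length(miss_sgls))
      vals[miss_sgls, samples$time_label == "SGls"] <- NA_real_
    records <- data.frame(accession = acc, gene_name = gene,
                          is_mitochondrial = FALSE, is_keratin = FALSE,
                          fdr_confidence = "high",
                          stringsAsFactors = FALSE)
    records$unique_peptides <-
      rep(list(rep(2L, cfg$n_replicates)), n)
    quant_matrix(vals, records, samples)
  }

  g3 <- make_bait("G3BP1", with_sgls = TRUE)
  cp <- make_bait("CAPRIN1", with_sgls = FALSE)
  if (length(single_bait)) {
    keep <- setdiff(seq_len(n), single_bait)
    cp <- subset_quant(cp, proteins = acc[keep])
  }
  truth <- data.frame(
    accession = acc, gene_name = gene, class = classes,
    is_ribosomal_like = is_ribo,
    inflection = ifelse(classes == "early", cfg$inflection_early,
                        ifelse(classes == "late", cfg$inflection_late,
                               NA_real_)),
    stringsAsFactors = FALSE)
  truth$class[zero_var] <- "invariable"
  list(g3bp1 = g3, caprin1 = cp, truth = truth, config = cfg)
}

#' Simulate a planted-structure PPI network
#'
#' Early nodes form a dense Erdos-Renyi core; late nodes are split
#' into near-clique modules with sparse inter-module wiring;
#' invariable nodes attach sparsely. Emulates a scaffold-like early
#' subnetwork (high density, low modularity) against a modular late
#' subnetwork.
#'
#' @param n_early,n_late,n_invariable group sizes (40/30/20).
#' @param p_core early-core edge probability (default 0.25).
#' @param module_sizes late module sizes (default: split into
#'   modules of ~6).
#' @param p_in within-module edge probability (default 0.9).
#' @param p_out edge probability between late modules and across
#'   groups (default 0.02).
#' @param invariable_edges edges attached per invariable node
#'   (default 2).
#' @param seed integer seed.
#' @return list: graph (igraph, vertex attrs group and module),
#'   nodes (data.frame id, group, module), truth = nodes.
#' @export
simulate_network <- function(n_early = 40, n_late = 30,
                             n_invariable = 20, p_core = 0.25,
                             module_sizes = NULL, p_in = 0.9,
                             p_out = 0.02, invariable_edges = 2,
                             seed = 1) {
  set.seed(seed)
  if (is.null(module_sizes)) {
    k <- max(1, round(n_late / 6))
    module_sizes <- rep(n_late %/% k, k)
    extra <- n_late - sum(module_sizes)
    if (extra > 0)
      module_sizes[seq_len(extra)] <- module_sizes[seq_len(extra)] + 1
  }
  if (sum(module_sizes) != n_late)
    stop("module_sizes must sum to n_late")
  group <- rep(c("early", "late", "invariable"),
               c(n_early, n_late, n_invariable))
  id <- sprintf("NODE%03d", seq_along(group))
  module <- rep(NA_integer_, length(group))
  module[group == "late"] <- rep(seq_along(module_sizes), module_sizes)

  edges <- list()
  add_pairs <- function(i, j, p) {
    if (!length(i) || !length(j)) return(NULL)
    pr <- expand.grid(a = i, b = j, KEEP.OUT.ATTRS = FALSE)
    pr <- pr[pr$a < pr$b, , drop = FALSE]
    pr[runif(nrow(pr)) < p, , drop = FALSE]
  }
  early_idx <- which(group == "early")
  edges[[1]] <- add_pairs(early_idx, early_idx, p_core)
  for (mzi in seq_along(module_sizes)) {
    mi <- which(!is.na(module) & module == mzi)
    edges[[length(edges) + 1]] <- add_pairs(mi, mi, p_in)
  }
  late_idx <- which(group == "late")
  cross_late <- add_pairs(late_idx, late_idx, p_out)
  if (!is.null(cross_late) && nrow(cross_late))
    cross_late <- cross_late[module[cross_late$a] !=
                               module[cross_late$b], , drop = FALSE]
  edges[[length(edges) + 1]] <- cross_late
  edges[[length(edges) + 1]] <- add_pairs(early_idx, late_idx, p_out)
  inv_idx <- which(group == "invariable")
  if (length(inv_idx) && invariable_edges > 0) {
    others <- c(early_idx, late_idx)
    anchor <- do.call(rbind, lapply(inv_idx, function(i) {
      tgt <- sample(others, min(invariable_edges, length(others)))
      data.frame(a = pmin(i, tgt), b = pmax(i, tgt))
    }))
    edges[[length(edges) + 1]] <- anchor
  }
  ed <- unique(do.call(rbind, edges))
  nodes <- data.frame(id = id, group = group, module = module,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = id[ed$a], to = id[ed$b]),
    directed = FALSE, vertices = nodes)
  g <- igraph::simplify(g)
  list(graph = g, nodes = nodes, truth = nodes)
}

# render Gaussian spots onto a background image
render_spots <- function(dim_img, spots, background, noise_sd) {
  img <- matrix(background, dim_img[1], dim_img[2])
  for (i in seq_len(nrow(spots))) {
    s <- spots[i, ]
    r0 <- max(1, floor(s$y - 4 * s$sigma))
    r1 <- min(dim_img[1], ceiling(s$y + 4 * s$sigma))
    c0 <- max(1, floor(s$x - 4 * s$sigma))
    c1 <- min(dim_img[2], ceiling(s$x + 4 * s$sigma))
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - s$y)^2, (cc - s$x)^2, `+`)
    img[rr, cc] <- img[rr, cc] + s$amp * exp(-d2 / (2 * s$sigma^2))
  }
  if (noise_sd > 0)
    img <- img + matrix(rnorm(length(img), 0, noise_sd),
                        dim_img[1], dim_img[2])
  pmin(pmax(img, 0), 1)
}

#' Simulate a granule movie with known fusion events
#'
#' Cells are disk masks on a tile grid; granules are Gaussian spots
#' undergoing Brownian motion. In fusion cells a dedicated spot pair
#' approaches deterministically and is replaced, at the scripted
#' frame, by a single spot at the midpoint with the parents' summed
#' area (sigma added in quadrature). Spots are placed with a minimum
#' separation so segmentation recovers planted counts exactly.
#'
#' @param n_cells number of cells (default 4).
#' @param granules_per_cell spots per cell (default 5).
#' @param motion_sd Brownian step sd in pixels/frame (default 0.5).
#' @param planted_fusions number of fusion events, at most one per
#'   cell (default 2).
#' @param frames movie length (default 8).
#' @param seed integer seed.
#' @param tile tile edge in pixels per cell (default 64).
#' @param cell_radius disk radius (default 26).
#' @param spot_sigma Gaussian spot sd in pixels (default 1.5).
#' @param spot_amp spot peak amplitude over background (default 0.8).
#' @param background background level (default 0.05).
#' @param noise_sd additive pixel noise (default 0.005).
#' @param min_sep minimum spot separation at placement (default 12).
#' @return list: frames (list of matrices in [0,1]), cell_masks
#'   (label matrix), truth (counts per cell, fusion events data.frame
#'   (cell, frame), spot positions per frame), params.
#' @export
simulate_movie <- function(n_cells = 4, granules_per_cell = 5,
                           motion_sd = 0.5, planted_fusions = 2,
                           frames = 8, seed = 1, tile = 64,
                           cell_radius = 26, spot_sigma = 1.5,
                           spot_amp = 0.8, background = 0.05,
                           noise_sd = 0.005, min_sep = 10) {
  if (planted_fusions > n_cells)
    stop("at most one planted fusion per cell")
  set.seed(seed)
  ncol_grid <- ceiling(sqrt(n_cells))
  nrow_grid <- ceiling(n_cells / ncol_grid)
  dim_img <- c(nrow_grid * tile, ncol_grid * tile)
  centers <- data.frame(
    cell = seq_len(n_cells),
    y = (((seq_len(n_cells) - 1) %/% ncol_grid) + 0.5) * tile,
    x = (((seq_len(n_cells) - 1) %% ncol_grid) + 0.5) * tile)
  masks <- matrix(0L, dim_img[1], dim_img[2])
  for (i in seq_len(n_cells)) {
    rr <- matrix(seq_len(dim_img[1]), dim_img[1], dim_img[2])
    cc <- matrix(seq_len(dim_img[2]), dim_img[1], dim_img[2],
                 byrow = TRUE)
    inside <- (rr - centers$y[i])^2 + (cc - centers$x[i])^2 <=
      cell_radius^2
    masks[inside] <- i
  }
  fusion_cells <- if (planted_fusions > 0)
    seq_len(planted_fusions) else integer(0)
  t_merge <- max(3, ceiling(frames / 2))

  place_spots <- function(cy, cx, k, exclusion = NULL) {
    pts <- data.frame(y = numeric(0), x = numeric(0))
    guard <- 0
    while (nrow(pts) < k && guard < 5000) {
      guard <- guard + 1
      ang <- runif(1, 0, 2 * pi)
      rad <- sqrt(runif(1)) * (cell_radius - 8)
      cand <- c(cy + rad * sin(ang), cx + rad * cos(ang))
      all_pts <- rbind(pts, exclusion)
      if (nrow(all_pts) == 0 ||
          all(sqrt((all_pts$y - cand[1])^2 +
                     (all_pts$x - cand[2])^2) >= min_sep))
        pts <- rbind(pts, data.frame(y = cand[1], x = cand[2]))
    }
    if (nrow(pts) < k) stop("could not place spots with min_sep")
    pts
  }

  # per-cell spot state for frame 1
  spot_list <- list()
  fusion_pair <- list()
  for (i in seq_len(n_cells)) {
    if (i %in% fusion_cells) {
      # fusing pair straddles the cell centre, 14 px apart
      ang <- runif(1, 0, 2 * pi)
      off <- 7 * c(sin(ang), cos(ang))
      pair <- data.frame(y = centers$y[i] + c(off[1], -off[1]),
                         x = centers$x[i] + c(off[2], -off[2]))
      rest <- if (granules_per_cell > 2)
        place_spots(centers$y[i], centers$x[i],
                    granules_per_cell - 2, exclusion = pair)
      else data.frame(y = numeric(0), x = numeric(0))
      pts <- rbind(pair, rest)
      fusion_pair[[i]] <- c(1L, 2L)
    } else {
      pts <- place_spots(centers$y[i], centers$x[i],
                         granules_per_cell)
      fusion_pair[[i]] <- integer(0)
    }
    spot_list[[i]] <- data.frame(
      cell = i, spot = seq_len(nrow(pts)), y = pts$y, x = pts$x,
      sigma = spot_sigma, amp = spot_amp, alive = TRUE)
  }

  frames_out <- vector("list", frames)
  positions <- list()
  fusion_truth <- list()
  for (t in seq_len(frames)) {
    if (t > 1) {
      for (i in seq_len(n_cells)) {
        sp <- spot_list[[i]]
        live <- which(sp$alive)
        pair <- fusion_pair[[i]]
        pair_live <- intersect(pair, live)
        for (s in live) {
          if (s %in% pair_live && t <= t_merge) next  # scripted
          y_new <- sp$y[s] + rnorm(1, 0, motion_sd)
          x_new <- sp$x[s] + rnorm(1, 0, motion_sd)
          # keep inside the cell
          dy <- y_new - centers$y[i]; dx <- x_new - centers$x[i]
          dd <- sqrt(dy^2 + dx^2)
          if (dd > cell_radius - 6) {
            y_new <- centers$y[i] + dy / dd * (cell_radius - 6)
            x_new <- centers$x[i] + dx / dd * (cell_radius - 6)
          }
          # merge-separated scenario: reject moves that approach
          # another spot (only scripted pairs ever fuse)
          others <- setdiff(live, s)
          if (!length(others) ||
              all(sqrt((sp$y[others] - y_new)^2 +
                         (sp$x[others] - x_new)^2) >= 8)) {
            sp$y[s] <- y_new; sp$x[s] <- x_new
          }
        }
        if (length(pair_live) == 2) {
          if (t < t_merge) {
            # approach: shrink separation towards 7 px at t_merge - 1
            # (two sigma-1.5 spots 7 px apart still segment separately)
            mid <- c(mean(sp$y[pair]), mean(sp$x[pair]))
            sep0 <- 14
            sep_t <- sep0 - (sep0 - 7) * (t - 1) / max(1, t_merge - 2)
            dirv <- c(sp$y[pair[1]] - mid[1], sp$x[pair[1]] - mid[2])
            dirv <- dirv / sqrt(sum(dirv^2))
            sp$y[pair] <- mid[1] + c(1, -1) * dirv[1] * sep_t / 2
            sp$x[pair] <- mid[2] + c(1, -1) * dirv[2] * sep_t / 2
          } else if (t == t_merge) {
            mid <- c(mean(sp$y[pair]), mean(sp$x[pair]))
            sp$y[pair[1]] <- mid[1]; sp$x[pair[1]] <- mid[2]
            sp$sigma[pair[1]] <- sqrt(sum(sp$sigma[pair]^2))
            sp$alive[pair[2]] <- FALSE
            fusion_truth[[length(fusion_truth) + 1]] <-
              data.frame(cell = i, frame = t)
          }
        }
        spot_list[[i]] <- sp
      }
    }
    all_sp <- do.call(rbind, spot_list)
    all_sp <- all_sp[all_sp$alive, , drop = FALSE]
    frames_out[[t]] <- render_spots(dim_img, all_sp, background,
                                    noise_sd)
    positions[[t]] <- cbind(frame = t,
                            all_sp[, c("cell", "spot", "y", "x",
                                       "sigma")])
  }
  list(
    frames = frames_out,
    cell_masks = masks,
    truth = list(
      counts = setNames(rep(granules_per_cell, n_cells),
                        seq_len(n_cells)),
      fusions = if (length(fusion_truth))
        do.call(rbind, fusion_truth) else
          data.frame(cell = integer(), frame = integer()),
      positions = do.call(rbind, positions)),
    params = list(n_cells = n_cells,
                  granules_per_cell = granules_per_cell,
                  motion_sd = motion_sd,
                  planted_fusions = planted_fusions,
                  frames = frames, seed = seed, dim = dim_img,
                  t_merge = t_merge))
}

#' Write movie frames and cell masks as TIFF files
#' @param movie result of [simulate_movie()].
#' @param dir output directory (created if needed).
#' @return invisibly, the frame file paths.
#' @export
write_movie_tiff <- function(movie, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(movie$frames), function(t) {
    p <- file.path(dir, sprintf("frame_%03d.tif", t))
    tiff::writeTIFF(movie$frames[[t]], p)
    p
  }, "")
  tiff::writeTIFF(movie$cell_masks / max(1, max(movie$cell_masks)),
                  file.path(dir, "cell_masks.tif"), bits.per.sample = 16)
  invisible(paths)
}

#' Simulate protein property tables with planted group differences
#'
#' Produces, for a classified truth table, synthetic sequences (early
#' proteins basic/arginine-rich, late proteins acidic), per-residue
#' disorder tracks whose coverage differs by class (early highest),
#' a PLAAC-style PrLD summary and an RBP annotation list, mirroring
#' the property contrasts expected between early, late and invariable
#' SG proteins. All draws are seeded.
#'
#' @param truth data.frame with accession and class columns.
#' @param seed integer seed.
#' @return list: sequences (named character), idr_tracks (named list
#'   of score vectors), prld (data.frame id/core_length/has_prld),
#'   rbp_genes (character vector of accessions annotated as RBPs).
#' @export
simulate_property_tables <- function(truth, seed = 1) {
  set.seed(seed)
  n <- nrow(truth)
  base_aa <- c("A", "G", "S", "T", "P", "Q", "N", "L", "V", "F")
  make_seq <- function(class) {
    len <- sample(250:500, 1)
    frac_pos <- switch(class, early = 0.16, late = 0.07,
                       invariable = 0.11)
    frac_neg <- switch(class, early = 0.08, late = 0.15,
                       invariable = 0.11)
    aa <- sample(c(sample(c("K", "R"), len, replace = TRUE),
                   sample(c("D", "E"), len, replace = TRUE),
                   sample(base_aa, len, replace = TRUE)),
                 len, replace = FALSE,
                 prob = c(rep(frac_pos / len, len),
                          rep(frac_neg / len, len),
                          rep((1 - frac_pos - frac_neg) / len, len)))
    paste(aa, collapse = "")
  }
  make_track <- function(class, len) {
    target <- switch(class, early = 0.30, late = 0.17,
                     invariable = 0.23)
    cov <- min(0.95, max(0.02, rnorm(1, target, 0.08)))
    k <- round(cov * len)
    sc <- runif(len, 0.05, 0.45)
    if (k > 0) {
      start <- sample(seq_len(len - k + 1), 1)
      sc[start:(start + k - 1)] <- runif(k, 0.55, 0.95)
    }
    sc
  }
  p_prld <- c(early = 0.11, late = 0.026, invariable = 0.094)
  p_rbp <- c(early = 0.65, late = 0.38, invariable = 0.33)
  seqs <- character(n); tracks <- vector("list", n)
  core <- integer(n); rbp <- logical(n)
  for (i in seq_len(n)) {
    cl <- truth$class[i]
    seqs[i] <- make_seq(cl)
    tracks[[i]] <- make_track(cl, nchar(seqs[i]))
    core[i] <- if (runif(1) < p_prld[[cl]]) sample(30:80, 1) else 0L
    rbp[i] <- runif(1) < p_rbp[[cl]]
  }
  names(seqs) <- truth$accession
  names(tracks) <- truth$accession
  list(
    sequences = seqs,
    idr_tracks = tracks,
    prld = data.frame(id = truth$accession, core_length = core,
                      has_prld = core > 0, stringsAsFactors = FALSE),
    rbp_genes = truth$accession[rbp])
}
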