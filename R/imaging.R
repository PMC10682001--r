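# Granule image quantification: segmentation within cell masks,
# per-cell enrichment, particle tracking and fusion-event counting.

#' Otsu threshold of an intensity sample
#'
#' Maximizes between-class variance over a binned histogram; used to
#' threshold pixels within an arbitrary cell mask.
#'
#' @param values numeric intensities.
#' @param levels number of histogram bins (default 256).
#' @return threshold value (pixels strictly above are foreground).
#' @export
otsu_threshold <- function(values, levels = 256) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values")
  r <- range(values)
  if (r[1] == r[2]) return(r[1])
  breaks <- seq(r[1], r[2], length.out = levels + 1)
  h <- tabulate(findInterval(values, breaks, all.inside = TRUE),
                nbins = levels)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(levels + 1)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[levels]
  sigma_b <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

#' 8-connected component labelling of a binary mask
#'
#' Components are found over the 8-neighbour pixel graph (so
#' diagonally touching pixels join), the connectivity convention used
#' throughout the imaging module.
#'
#' @param mask logical/0-1 matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  mask <- mask > 0
  lab <- matrix(0L, nrow(mask), ncol(mask))
  fg <- which(mask)
  if (!length(fg)) return(lab)
  nr <- nrow(mask)
  rc <- arrayInd(fg, dim(mask))
  rank_of <- integer(length(mask))
  rank_of[fg] <- seq_along(fg)
  edges <- list()
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rc[, 1] + off[1]; c2 <- rc[, 2] + off[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncol(mask)
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    src <- fg[ok]
    both <- mask[nb]
    edges[[length(edges) + 1]] <-
      cbind(rank_of[src[both]], rank_of[nb[both]])
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(em) && nrow(em))
    g <- igraph::add_edges(g, t(em))
  lab[fg] <- igraph::components(g)$membership
  lab
}

#' Segment granules within cell masks and measure them
#'
#' Per cell: threshold the in-mask intensities (Otsu by default, or a
#' fixed value), label 8-connected components, discard components
#' smaller than `min_area`, and report count and mean area.
#'
#' @param image 2D intensity matrix.
#' @param cell_masks integer label matrix (0 = background, one id per
#'   cell), same shape as `image`.
#' @param min_area minimum component size in pixels (default 4).
#' @param threshold "otsu" or "fixed".
#' @param fixed_value threshold when `threshold = "fixed"`.
#' @param pixel_size optional micrometres per pixel; areas are then
#'   also reported in square micrometres.
#' @return list: `cells` (cell, n_granules, mean_area[, mean_area_um2]),
#'   `granules` (cell, granule, area, x, y), `labels` (global granule
#'   label matrix).
#' @export
segment_granules <- function(image, cell_masks, min_area = 4,
                             threshold = c("otsu", "fixed"),
                             fixed_value = NULL, pixel_size = NULL) {
  threshold <- match.arg(threshold)
  if (!all(dim(image) == dim(cell_masks)))
    stop("image and cell_masks differ in shape")
  ids <- sort(setdiff(unique(as.integer(cell_masks)), 0L))
  if (!length(ids)) stop("cell mask is empty")
  glab <- matrix(0L, nrow(image), ncol(image))
  cells <- list(); gran <- list(); next_lab <- 0L
  for (cid in ids) {
    inside <- cell_masks == cid
    if (!any(inside)) stop("empty cell mask for cell ", cid)
    thr <- if (threshold == "otsu") otsu_threshold(image[inside])
    else fixed_value
    if (is.null(thr)) stop("fixed threshold requires fixed_value")
    bin <- inside & image > thr
    lab <- label_components(bin)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_area)
    areas <- numeric(0); xs <- numeric(0); ys <- numeric(0)
    for (k in keep) {
      px <- which(lab == k)
      next_lab <- next_lab + 1L
      glab[px] <- next_lab
      rc <- arrayInd(px, dim(image))
      areas <- c(areas, length(px))
      ys <- c(ys, mean(rc[, 1])); xs <- c(xs, mean(rc[, 2]))
    }
    cells[[length(cells) + 1]] <- data.frame(
      cell = cid, n_granules = length(keep),
      mean_area = if (length(keep)) mean(areas) else NA_real_)
    if (length(keep))
      gran[[length(gran) + 1]] <- data.frame(
        cell = cid, granule = seq_along(keep), area = areas,
        x = xs, y = ys)
  }
  cells <- do.call(rbind, cells)
  if (!is.null(pixel_size))
    cells$mean_area_um2 <- cells$mean_area * pixel_size^2
  granules <- if (length(gran)) do.call(rbind, gran) else
    data.frame(cell = integer(), granule = integer(),
               area = numeric(), x = numeric(), y = numeric())
  list(cells = cells, granules = granules, labels = glab)
}

#' Per-cell granule enrichment of a target channel
#'
#' Mean intensity over the union of granule pixels in a cell divided
#' by the mean intensity over all pixels of that cell; invariant to
#' multiplicative intensity rescaling. Cells without granules get NA.
#'
#' @param target_channel 2D intensity matrix.
#' @param granule_labels granule label matrix (e.g. from
#'   [segment_granules()]; > 0 marks granule pixels).
#' @param cell_masks cell label matrix.
#' @return data.frame: cell, enrichment.
#' @export
enrichment_score <- function(target_channel, granule_labels,
                             cell_masks) {
  if (!all(dim(target_channel) == dim(cell_masks)) ||
      !all(dim(granule_labels) == dim(cell_masks)))
    stop("channel, granule and cell masks must share one shape")
  ids <- sort(setdiff(unique(as.integer(cell_masks)), 0L))
  res <- lapply(ids, function(cid) {
    inside <- cell_masks == cid
    gp <- inside & granule_labels > 0
    data.frame(cell = cid,
               enrichment = if (!any(gp)) NA_real_ else
                 mean(target_channel[gp]) / mean(target_channel[inside]))
  })
  do.call(rbind, res)
}

#' Link particle detections across frames
#'
#' Greedy nearest-neighbour frame-to-frame assignment with a distance
#' cap: at each step the globally closest (track head, detection)
#' pair within `max_disp` is linked; unmatched detections start new
#' tracks and unmatched heads end theirs.
#'
#' @param frames list of data.frames with columns x, y and optionally
#'   area (one per movie frame).
#' @param max_disp maximum per-step displacement in pixels.
#' @return list of class `particle_tracks`: `tracks` (track, frame,
#'   x, y, area), `mean_step` (pooled mean per-step displacement),
#'   `per_track` (track, n_steps, mean_step).
#' @export
track_particles <- function(frames, max_disp) {
  if (length(frames) < 2) stop("need >= 2 frames")
  frames <- lapply(frames, function(f) {
    if (!all(c("x", "y") %in% names(f))) stop("frames need x, y")
    if (is.null(f$area)) f$area <- NA_real_
    f
  })
  rows <- list()
  f1 <- frames[[1]]
  active <- if (nrow(f1)) seq_len(nrow(f1)) else integer(0)
  n_tracks <- length(active)
  for (i in active)
    rows[[length(rows) + 1]] <- data.frame(
      track = i, frame = 1L, x = f1$x[i], y = f1$y[i],
      area = f1$area[i])
  heads <- f1; head_track <- active
  for (t in seq_along(frames)[-1]) {
    det <- frames[[t]]
    assigned_head <- integer(0); assigned_det <- integer(0)
    if (nrow(heads) && nrow(det)) {
      dm <- outer(seq_len(nrow(heads)), seq_len(nrow(det)),
                  Vectorize(function(i, j)
                    sqrt((heads$x[i] - det$x[j])^2 +
                           (heads$y[i] - det$y[j])^2)))
      repeat {
        mi <- which(dm == min(dm), arr.ind = TRUE)[1, , drop = TRUE]
        if (!is.finite(dm[mi[1], mi[2]]) ||
            dm[mi[1], mi[2]] > max_disp) break
        assigned_head <- c(assigned_head, mi[1])
        assigned_det <- c(assigned_det, mi[2])
        dm[mi[1], ] <- Inf; dm[, mi[2]] <- Inf
        if (all(!is.finite(dm))) break
      }
    }
    new_heads <- det
    new_track <- integer(nrow(det))
    if (length(assigned_det))
      new_track[assigned_det] <- head_track[assigned_head]
    for (j in seq_len(nrow(det))) {
      if (new_track[j] == 0L) {
        n_tracks <- n_tracks + 1L
        new_track[j] <- n_tracks
      }
      rows[[length(rows) + 1]] <- data.frame(
        track = new_track[j], frame = t, x = det$x[j], y = det$y[j],
        area = det$area[j])
    }
    heads <- new_heads; head_track <- new_track
  }
  tracks <- do.call(rbind, rows)
  tracks <- tracks[order(tracks$track, tracks$frame), ]
  steps <- do.call(rbind, lapply(split(tracks, tracks$track),
                                 function(tr) {
    if (nrow(tr) < 2) return(NULL)
    data.frame(track = tr$track[1],
               disp = sqrt(diff(tr$x)^2 + diff(tr$y)^2))
  }))
  per_track <- if (is.null(steps))
    data.frame(track = integer(), n_steps = integer(),
               mean_step = numeric())
  else do.call(rbind, lapply(split(steps, steps$track), function(s)
    data.frame(track = s$track[1], n_steps = nrow(s),
               mean_step = mean(s$disp))))
  structure(list(
    tracks = tracks,
    mean_step = if (is.null(steps)) NA_real_ else mean(steps$disp),
    per_track = per_track),
    class = "particle_tracks")
}

#' Count granule fusion events in a set of tracks
#'
#' A fusion is scored when a track ends at frame t and its last
#' position lies within `merge_radius` of a surviving track's
#' position at frame t+1 whose area is at least `area_ratio` times
#' the two parents' summed areas. Tracks ending within
#' `border_margin` of the image edge are excluded (particles leaving
#' the field are not fusions).
#'
#' @param tracks a `particle_tracks` object or its `tracks`
#'   data.frame (track, frame, x, y, area).
#' @param merge_radius association radius in pixels (default 5).
#' @param area_ratio minimum child/parent-sum area fraction
#'   (default 0.8; set 0 to disable the area check when areas are
#'   unavailable).
#' @param dims optional c(rows, cols) of the image, required for the
#'   border exclusion.
#' @param border_margin pixels from the edge within which an ending
#'   track is never a fusion parent (default 0 = no exclusion).
#' @return list: n_events, events (frame, ended_track,
#'   surviving_track), has_event (>= 1 event in this region).
#' @export
count_fusion_events <- function(tracks, merge_radius = 5,
                                area_ratio = 0.8, dims = NULL,
                                border_margin = 0) {
  tr <- if (inherits(tracks, "particle_tracks")) tracks$tracks else
    tracks
  if (!nrow(tr))
    return(list(n_events = 0L, events = NULL, has_event = FALSE))
  last_frame <- max(tr$frame)
  ends <- do.call(rbind, lapply(split(tr, tr$track), function(x)
    x[which.max(x$frame), ]))
  ends <- ends[ends$frame < last_frame, , drop = FALSE]
  events <- list()
  for (i in seq_len(nrow(ends))) {
    e <- ends[i, ]
    if (border_margin > 0 && !is.null(dims)) {
      if (e$y <= border_margin || e$x <= border_margin ||
          e$y > dims[1] - border_margin ||
          e$x > dims[2] - border_margin) next
    }
    t1 <- e$frame + 1
    cand <- tr[tr$frame == t1 & tr$track != e$track, , drop = FALSE]
    if (!nrow(cand)) next
    d <- sqrt((cand$x - e$x)^2 + (cand$y - e$y)^2)
    ord <- order(d)
    for (j in ord) {
      if (d[j] > merge_radius) break
      surv <- cand$track[j]
      prev <- tr[tr$track == surv & tr$frame == e$frame, , drop = FALSE]
      if (!nrow(prev)) next
      parent_sum <- e$area + prev$area[1]
      if (is.finite(parent_sum) && area_ratio > 0 &&
          !is.na(cand$area[j]) &&
          cand$area[j] < area_ratio * parent_sum) next
      events[[length(events) + 1]] <- data.frame(
        frame = t1, ended_track = e$track, surviving_track = surv)
      break
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else NULL
  list(n_events = length(events), events = ev,
       has_event = length(events) >= 1)
}

#' Read a movie of single-channel TIFF frames from a directory
#' @param dir directory of per-frame TIFF files (lexicographic order).
#' @return list of intensity matrices.
#' @export
read_movie_tiff <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tiff?$",
                           full.names = TRUE))
  if (!length(files)) stop("no TIFF frames in ", dir)
  lapply(files, function(f) {
    x <- tiff::readTIFF(f)
    if (length(dim(x)) == 3) x <- x[, , 1]
    x
  })
}
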