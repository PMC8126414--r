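#' Track branches across a skeletonized time series
#'
#' Builds branch lineages over time. Each branch at frame k+1 is assigned
#' to the frame-k branch with which its skeleton overlaps maximally after
#' dilating the frame-k branch by its local half-width (ties broken by
#' larger overlap, then smaller centroid distance). The best-overlapping
#' successor continues the lineage; additional matches and unmatched new
#' branches start child lineages. Per lineage, length and width series are
#' normalized to the branch's first appearance.
#'
#' @param analyses List of [analyze_frame()] results (>= 2 frames, constant
#'   pixel size).
#' @return Object of class `branch_tracks`: `table` (data frame: lineage,
#'   parent, frame, branch, length_um, width_um, rel_length, rel_width).
#' @export
track_branches <- function(analyses) {
  stopifnot(length(analyses) >= 2)
  ps <- vapply(analyses, function(a) a$graph$pixel_size, numeric(1))
  if (diff(range(ps)) > 1e-12) stop("pixel size must be constant over frames")

  rows <- list()
  # lineage bookkeeping: per active lineage, last frame branch pixels/width
  lineage_parent <- integer(0)
  active <- list()   # per current-frame branch index: lineage id
  n_lin <- 0L

  for (f in seq_along(analyses)) {
    g <- analyses[[f]]$graph
    w <- analyses[[f]]$widths_um
    len <- vapply(g$branches, `[[`, numeric(1), "length_um")
    nb <- length(g$branches)
    assign_lin <- rep(NA_integer_, nb)

    if (f == 1) {
      for (i in seq_len(nb)) {
        n_lin <- n_lin + 1L
        assign_lin[i] <- n_lin
        lineage_parent[n_lin] <- NA_integer_
      }
    } else {
      prev <- analyses[[f - 1]]$graph
      prev_w <- analyses[[f - 1]]$widths_um
      prev_lin <- active$lin
      # overlap of each new branch with each dilated old branch
      ov <- matrix(0, nb, length(prev$branches))
      cdist <- matrix(Inf, nb, length(prev$branches))
      for (i in seq_len(nb)) {
        pnew <- g$branches[[i]]$path
        cn <- colMeans(pnew)
        for (j in seq_along(prev$branches)) {
          pold <- prev$branches[[j]]$path
          r <- max(1, prev_w[j] / ps[1] / 2)
          d2 <- outer(pnew[, 1], pold[, 1], "-")^2 +
            outer(pnew[, 2], pold[, 2], "-")^2
          ov[i, j] <- sum(apply(d2, 1, min) <= r^2)
          co <- colMeans(pold)
          cdist[i, j] <- sqrt(sum((cn - co)^2))
        }
      }
      # greedy global one-to-one matching by overlap (ties: centroid
      # distance); matched pairs continue lineages
      pairs <- which(ov > 0, arr.ind = TRUE)
      if (nrow(pairs)) {
        o <- order(-ov[pairs], cdist[pairs])
        used_new <- logical(nb)
        used_old <- logical(length(prev$branches))
        for (p in o) {
          i <- pairs[p, 1]; j <- pairs[p, 2]
          if (used_new[i] || used_old[j]) next
          assign_lin[i] <- prev_lin[j]
          used_new[i] <- TRUE
          used_old[j] <- TRUE
        }
      }
      for (i in which(is.na(assign_lin))) {
        # unmatched: child lineage of the best-overlapping (else nearest)
        # previous branch
        n_lin <- n_lin + 1L
        jm <- if (any(ov[i, ] > 0)) which.max(ov[i, ])
        else if (any(is.finite(cdist[i, ]))) which.min(cdist[i, ]) else NA
        lineage_parent[n_lin] <- if (!is.na(jm)) prev_lin[jm] else NA_integer_
        assign_lin[i] <- n_lin
      }
    }
    active <- list(lin = assign_lin)
    for (i in seq_len(nb)) {
      rows[[length(rows) + 1L]] <- data.frame(
        lineage = assign_lin[i], frame = f, branch = i,
        length_um = len[i], width_um = w[i])
    }
  }

  tab <- do.call(rbind, rows)
  tab$parent <- lineage_parent[tab$lineage]
  tab <- tab[order(tab$lineage, tab$frame), ]
  first <- !duplicated(tab$lineage)
  l0 <- tab$length_um[first][match(tab$lineage, tab$lineage[first])]
  w0 <- tab$width_um[first][match(tab$lineage, tab$lineage[first])]
  tab$rel_length <- tab$length_um / l0
  tab$rel_width <- tab$width_um / w0
  rownames(tab) <- NULL
  structure(list(table = tab, n_lineages = n_lin), class = "branch_tracks")
}

#' @export
print.branch_tracks <- function(x, ...) {
  cat(sprintf("Branch tracks: %d lineages over %d frames\n",
              x$n_lineages, max(x$table$frame)))
  invisible(x)
}

#' 2D elongation bias of a tracked branch
#'
#' Relative length growth divided by relative width growth at the final
#' frame of a lineage. Values above 1 indicate biased (anisotropic) tube
#' elongation; isotropic growth gives 1.
#'
#' @param tracks A [track_branches()] result, or a data frame with
#'   `rel_length` and `rel_width` ordered in time.
#' @param lineage Lineage id (default: the first lineage).
#' @return Bias (dimensionless).
#' @export
elongation_bias_2d <- function(tracks, lineage = NULL) {
  tab <- if (inherits(tracks, "branch_tracks")) tracks$table else tracks
  if (!is.null(lineage)) tab <- tab[tab$lineage == lineage, , drop = FALSE]
  else if ("lineage" %in% names(tab)) {
    tab <- tab[tab$lineage == tab$lineage[1], , drop = FALSE]
  }
  if (nrow(tab) < 2) stop("need >= 2 frames in the track")
  last <- tab[nrow(tab), ]
  if (last$rel_width == 0) stop("zero relative width")
  last$rel_length / last$rel_width
}
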