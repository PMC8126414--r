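# --- skeleton -> branch graph ---------------------------------------------

OFFS <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
              dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

# 8-connected component labelling (union-find over foreground pixels);
# skeleton pixels are diagonal-connected, so 4-connected labelling would
# shatter them
label8 <- function(mask) {
  out <- matrix(0L, nrow(mask), ncol(mask))
  lin <- which(mask)
  n <- length(lin)
  if (!n) return(out)
  nr <- nrow(mask)
  id <- integer(length(mask))
  id[lin] <- seq_len(n)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  r <- ((lin - 1L) %% nr) + 1L
  c0 <- ((lin - 1L) %/% nr) + 1L
  for (k in seq_len(4)) {              # forward offsets: E, SE, S, SW
    dr <- c(0L, 1L, 1L, 1L)[k]; dc <- c(1L, 1L, 0L, -1L)[k]
    rr <- r + dr; cc <- c0 + dc
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= ncol(mask)
    nb <- (cc[ok] - 1L) * nr + rr[ok]
    a <- id[lin[ok]]; b <- id[nb]
    live <- b > 0L
    for (e in which(live)) {
      ra <- find(a[e]); rb <- find(b[e])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out[lin] <- match(roots, unique(roots))
  out
}

# Path length in pixel units. Raw 8-connected step sums overestimate the
# length of digitized curves by several percent (staircase effect), so long
# paths are measured on a stride-3 simplification of the pixel chain; for
# straight axial or diagonal paths this is identical to the step sum.
branch_pixel_length <- function(path) {
  n <- nrow(path)
  if (n < 2) return(0)
  if (n <= 6) {
    d <- abs(diff(path))
    return(sum(ifelse(d[, 1] & d[, 2], sqrt(2), 1)))
  }
  keep <- unique(c(seq(1L, n, by = 3L), n))
  sum(sqrt(rowSums(diff(path[keep, , drop = FALSE])^2)))
}

# internal tracer in 1-based pixel coordinates
trace_skeleton <- function(sk) {
  if (!any(sk)) return(NULL)
  cnt <- neighbour_count(sk)
  jmask <- sk & cnt >= 3
  emask <- sk & cnt <= 1           # endpoints and isolated pixels

  nodes <- data.frame(row = numeric(0), col = numeric(0),
                      type = character(0))
  jlab <- matrix(0L, nrow(sk), ncol(sk))
  if (any(jmask)) {
    jlab <- label8(jmask)
    for (k in seq_len(max(jlab))) {
      px <- which(jlab == k, arr.ind = TRUE)
      nodes <- rbind(nodes, data.frame(row = mean(px[, 1]),
                                       col = mean(px[, 2]),
                                       type = "junction"))
    }
  }
  n_j <- nrow(nodes)
  ep <- which(emask, arr.ind = TRUE)
  if (nrow(ep)) {
    nodes <- rbind(nodes, data.frame(row = as.numeric(ep[, 1]),
                                     col = as.numeric(ep[, 2]),
                                     type = "endpoint"))
  }
  epid <- matrix(0L, nrow(sk), ncol(sk))
  if (nrow(ep)) epid[ep] <- n_j + seq_len(nrow(ep))

  bmask <- sk & !jmask
  if (!any(bmask)) {
    # skeleton is junction pixels only (tiny blob): one degenerate branch
    px <- which(sk, arr.ind = TRUE)
    return(list(nodes = nodes,
                branches = list(list(path = px, node1 = NA_integer_,
                                     node2 = NA_integer_, conn = 0))))
  }
  bl <- label8(bmask)
  branches <- list()
  for (k in seq_len(max(bl))) {
    px <- which(bl == k, arr.ind = TRUE)
    path <- order_path(px, bl, k)
    ends <- rbind(path[1, ], path[nrow(path), ])
    node_id <- c(NA_integer_, NA_integer_)
    conn <- 0
    for (e in 1:2) {
      r <- ends[e, 1]; cc <- ends[e, 2]
      if (epid[r, cc] > 0) { node_id[e] <- epid[r, cc]; next }
      # adjacent junction cluster?
      best <- NULL
      for (o in seq_len(8)) {
        rr <- r + OFFS[o, 1]; c2 <- cc + OFFS[o, 2]
        if (rr < 1 || c2 < 1 || rr > nrow(sk) || c2 > ncol(sk)) next
        if (jlab[rr, c2] > 0) {
          step <- if (OFFS[o, 1] != 0 && OFFS[o, 2] != 0) sqrt(2) else 1
          if (is.null(best) || step < best$step) {
            best <- list(id = jlab[rr, c2], step = step)
          }
        }
      }
      if (!is.null(best)) {
        node_id[e] <- best$id
        conn <- conn + best$step
      }
    }
    branches[[length(branches) + 1L]] <-
      list(path = path, node1 = node_id[1], node2 = node_id[2], conn = conn)
  }
  list(nodes = nodes, branches = branches)
}

# order the pixels of a ~1-px-wide component into a path
order_path <- function(px, lab, k) {
  if (nrow(px) <= 2) return(px)
  key <- paste(px[, 1], px[, 2])
  nb_in <- integer(nrow(px))
  idx <- stats::setNames(seq_len(nrow(px)), key)
  for (i in seq_len(nrow(px))) {
    nb <- sweep(OFFS, 2, c(px[i, 1], px[i, 2]), `+`)
    nb_in[i] <- sum(paste(nb[, 1], nb[, 2]) %in% key)
  }
  start <- which(nb_in <= 1)[1]
  if (is.na(start)) start <- 1L  # closed loop
  visited <- logical(nrow(px))
  ord <- integer(nrow(px))
  cur <- start
  for (step in seq_len(nrow(px))) {
    ord[step] <- cur
    visited[cur] <- TRUE
    nb <- sweep(OFFS, 2, c(px[cur, 1], px[cur, 2]), `+`)
    cand <- idx[paste(nb[, 1], nb[, 2])]
    cand <- cand[!is.na(cand)]
    cand <- cand[!visited[cand]]
    if (!length(cand)) break
    if (length(cand) > 1) {
      # prefer axial moves to keep staircase paths in order
      ax <- cand[rowSums(abs(px[cand, , drop = FALSE] -
                               matrix(px[cur, ], length(cand), 2,
                                      byrow = TRUE))) == 1]
      cur <- if (length(ax)) ax[1] else cand[1]
    } else cur <- cand
  }
  px[ord[ord > 0], , drop = FALSE]
}

#' Extract the branch graph of a skeleton
#'
#' Junction nodes are clusters of adjacent skeleton pixels with three or
#' more skeleton neighbours (merged at their centroid); endpoints have one.
#' Branch length is the sum of pixel steps along the path (1 for axial,
#' sqrt(2) for diagonal, including the connecting step into each junction
#' cluster) times the pixel size.
#'
#' @param skeleton Logical skeleton matrix (from [skeletonize_mask()]).
#' @param pixel_size µm/px.
#' @return Object of class `branch_graph`: `nodes` (data frame, 0-based
#'   row/col, type), `branches` (list: `path` 0-based pixel matrix,
#'   `node1`, `node2`, `length_um`), `pixel_size`.
#' @export
extract_branch_graph <- function(skeleton, pixel_size = 1) {
  g <- trace_skeleton(skeleton)
  if (is.null(g)) stop("empty skeleton")
  branches <- lapply(g$branches, function(br) {
    list(path = br$path - 1L,           # 0-based public coordinates
         node1 = br$node1, node2 = br$node2,
         length_um = (branch_pixel_length(br$path) + br$conn) * pixel_size)
  })
  nodes <- g$nodes
  nodes$row <- nodes$row - 1
  nodes$col <- nodes$col - 1
  nodes$id <- seq_len(nrow(nodes))
  structure(list(nodes = nodes, branches = branches,
                 pixel_size = pixel_size, dim = dim(skeleton)),
            class = "branch_graph")
}

#' @export
print.branch_graph <- function(x, ...) {
  cat(sprintf("Branch graph: %d branches, %d junctions, %d endpoints\n",
              length(x$branches), sum(x$nodes$type == "junction"),
              sum(x$nodes$type == "endpoint")))
  len <- vapply(x$branches, `[[`, numeric(1), "length_um")
  cat(sprintf("  lengths (um): %s\n",
              paste(signif(sort(len, decreasing = TRUE), 4), collapse = ", ")))
  invisible(x)
}

#' Per-branch mean width from the distance transform
#'
#' Local width at a skeleton pixel is twice the Euclidean distance
#' transform of the mask (the local-thickness read-out). Branch width is
#' the mean over the branch path, excluding pixels that lie within one
#' local radius of a junction node (where the EDT reflects the junction
#' blob, not the branch). A branch whose pixels are all excluded gets the
#' width at its midpoint pixel and is flagged.
#'
#' @param frame The [binary_frame()] the graph was derived from.
#' @param graph A `branch_graph` (from [extract_branch_graph()]).
#' @return Numeric vector of mean widths (µm) with attribute `flagged`
#'   (logical: width from midpoint only).
#' @export
measure_branch_widths <- function(frame, graph) {
  stopifnot(inherits(frame, "binary_frame"), inherits(graph, "branch_graph"))
  edt <- as.matrix(EBImage::distmap(EBImage::Image(frame$mask * 1)))
  px <- graph$pixel_size
  jn <- graph$nodes[graph$nodes$type == "junction", , drop = FALSE]
  jrad <- if (nrow(jn)) {
    edt[cbind(pmin(nrow(edt), pmax(1, round(jn$row + 1))),
              pmin(ncol(edt), pmax(1, round(jn$col + 1))))]
  } else numeric(0)
  flagged <- logical(length(graph$branches))
  w <- vapply(seq_along(graph$branches), function(i) {
    path1 <- graph$branches[[i]]$path + 1L   # back to 1-based
    vals <- 2 * edt[path1] * px
    keep <- rep(TRUE, nrow(path1))
    if (nrow(jn)) {
      for (j in seq_len(nrow(jn))) {
        d <- sqrt((path1[, 1] - (jn$row[j] + 1))^2 +
                    (path1[, 2] - (jn$col[j] + 1))^2)
        keep <- keep & d > jrad[j]
      }
    }
    if (!any(keep)) {
      flagged[i] <<- TRUE
      vals[ceiling(length(vals) / 2)]
    } else {
      mean(vals[keep])
    }
  }, numeric(1))
  attr(w, "flagged") <- flagged
  w
}

#' Full morphometric analysis of one frame
#'
#' Convenience wrapper: skeletonize, extract the branch graph, measure
#' widths.
#'
#' @param frame A [binary_frame()].
#' @return List of class `frame_morphometrics`: `graph`, `widths_um`,
#'   `frame`.
#' @export
analyze_frame <- function(frame) {
  sk <- skeletonize_mask(frame)
  g <- extract_branch_graph(sk, frame$pixel_size)
  w <- measure_branch_widths(frame, g)
  structure(list(graph = g, widths_um = w, frame = frame),
            class = "frame_morphometrics")
}
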