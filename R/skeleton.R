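#' Skeletonize a binary image
#'
#' Topology-preserving two-subiteration (Guo-Hall) thinning to a one-pixel
#' wide, 8-connected skeleton. Idempotent: skeletonizing a skeleton returns
#' it unchanged.
#'
#' @param binary logical/0-1 matrix.
#' @return logical matrix.
#' @export
skeletonize <- function(binary) {
  if (!is.matrix(binary)) stop("binary must be a 2D matrix")
  cpp_thin_guo_hall(matrix(as.integer(binary != 0), nrow = nrow(binary))) == 1L
}

#' Build the skeleton graph
#'
#' Decomposes a one-pixel-wide skeleton into nodes and branches. Junction
#' pixels (>= 3 skeleton neighbours) that are 8-adjacent are merged into a
#' single node; endpoint pixels (<= 1 neighbour) are nodes of their own.
#' Branches are the pixel paths running between nodes through degree-2
#' pixels; an isolated closed loop with no node pixels counts as one branch.
#' Branch length sums per-step pixel-centre distances: `pixel_size` for
#' 4-neighbour steps and `sqrt(2) * pixel_size` for diagonal steps. A
#' branch ending at a multi-pixel junction node is anchored at that node's
#' pixel centroid (the junction-centroid convention of standard skeleton
#' analyzers): the Euclidean distance from the junction pixel where the
#' trace ends to the component centroid is added, so e.g. each arm of a
#' plus-shaped skeleton measures from the cross centre. No endpoint pruning
#' is performed: branches terminating at endpoints are kept.
#'
#' @param skeleton logical/0-1 matrix (one-pixel-wide skeleton).
#' @param pixel_size um/pixel; default 1.
#' @return list with `edges` (data.frame: `edge`, `from`, `to`, `n_steps`,
#'   `length_um`, `kind` in `branch`/`cycle`), `n_nodes`, `n_junctions`,
#'   `n_endpoints`.
#' @export
skeleton_graph <- function(skeleton, pixel_size = 1) {
  sk <- matrix(as.integer(skeleton != 0), nrow = nrow(skeleton))
  nr <- nrow(sk); nc <- ncol(sk)
  empty <- data.frame(edge = integer(), from = integer(), to = integer(),
                      n_steps = integer(), length_um = numeric(),
                      kind = character())
  if (sum(sk) == 0)
    return(list(edges = empty, n_nodes = 0L, n_junctions = 0L,
                n_endpoints = 0L))

  deg <- cpp_neighbor_count(sk)
  junction <- sk == 1L & deg >= 3L
  endpoint <- sk == 1L & deg <= 1L
  # merged junction nodes: 8-connected components of junction pixels
  jlab <- cpp_label8(matrix(as.integer(junction), nrow = nr))
  n_jnodes <- max(jlab)
  node_id <- matrix(0L, nr, nc)
  node_id[junction] <- jlab[junction]
  ep_idx <- which(endpoint)
  node_id[ep_idx] <- n_jnodes + seq_along(ep_idx)
  n_nodes <- n_jnodes + length(ep_idx)
  # centroid anchor of each merged junction component
  jcent <- NULL
  if (n_jnodes > 0) {
    jp <- which(junction, arr.ind = TRUE)
    jcent <- cbind(tapply(jp[, 1], jlab[junction], mean),
                   tapply(jp[, 2], jlab[junction], mean))
  }
  anchor_extra <- function(node, pix) {
    if (is.na(node) || node > n_jnodes) return(0)
    sqrt(sum((pix - jcent[node, ])^2))
  }

  off_r <- c(-1, -1, -1, 0, 0, 1, 1, 1)
  off_c <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  lin <- function(i, j) (j - 1L) * nr + i
  neighbors <- function(i, j) {
    ii <- i + off_r; jj <- j + off_c
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    ii <- ii[ok]; jj <- jj[ok]
    on <- sk[cbind(ii, jj)] == 1L
    cbind(ii[on], jj[on])
  }
  step_len <- function(a, b) if (sum(abs(a - b)) == 2) sqrt(2) else 1

  visited <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- function(p, q) {
    a <- lin(p[1], p[2]); b <- lin(q[1], q[2])
    paste0(min(a, b), "-", max(a, b))
  }
  edges <- list()
  add_edge <- function(from, to, n_steps, len, kind,
                       startpix = NULL, endpix = NULL) {
    if (!is.null(startpix)) len <- len + anchor_extra(from, startpix)
    if (!is.null(endpix)) len <- len + anchor_extra(to, endpix)
    edges[[length(edges) + 1L]] <<- data.frame(
      edge = length(edges) + 1L, from = from, to = to,
      n_steps = n_steps, length_um = len * pixel_size, kind = kind)
  }

  node_pix <- which(node_id > 0L, arr.ind = TRUE)
  for (r in seq_len(nrow(node_pix))) {
    p <- node_pix[r, ]
    pid <- node_id[p[1], p[2]]
    nb <- neighbors(p[1], p[2])
    for (s in seq_len(nrow(nb))) {
      q <- nb[s, ]
      k <- ekey(p, q)
      if (!is.null(visited[[k]])) next
      qid <- node_id[q[1], q[2]]
      if (qid > 0L) {
        visited[[k]] <- TRUE
        same_junction <- qid == pid && junction[p[1], p[2]] && junction[q[1], q[2]]
        if (!same_junction)
          add_edge(pid, qid, 1L, step_len(p, q), "branch",
                   startpix = p, endpix = q)
        next
      }
      # walk through degree-2 slab pixels
      visited[[k]] <- TRUE
      len <- step_len(p, q); steps <- 1L
      prev <- p; cur <- q
      repeat {
        nb2 <- neighbors(cur[1], cur[2])
        keep <- !(nb2[, 1] == prev[1] & nb2[, 2] == prev[2])
        nxt <- nb2[keep, , drop = FALSE]
        if (nrow(nxt) == 0L) break  # cannot happen for degree-2 slabs
        nxt <- nxt[1, ]
        visited[[ekey(cur, nxt)]] <- TRUE
        len <- len + step_len(cur, nxt); steps <- steps + 1L
        if (node_id[nxt[1], nxt[2]] > 0L) {
          add_edge(pid, node_id[nxt[1], nxt[2]], steps, len, "branch",
                   startpix = p, endpix = nxt)
          break
        }
        prev <- cur; cur <- nxt
      }
    }
  }

  # isolated cycles: remaining slab pixels none of whose edges were visited
  slab <- which(sk == 1L & node_id == 0L, arr.ind = TRUE)
  if (nrow(slab) > 0) {
    done <- new.env(hash = TRUE, parent = emptyenv())
    for (r in seq_len(nrow(slab))) {
      p <- slab[r, ]
      pk <- as.character(lin(p[1], p[2]))
      if (!is.null(done[[pk]])) next
      nb <- neighbors(p[1], p[2])
      if (nrow(nb) == 0L) { done[[pk]] <- TRUE; next }
      if (!is.null(visited[[ekey(p, nb[1, ])]])) { done[[pk]] <- TRUE; next }
      # trace the closed loop
      len <- 0; steps <- 0L
      prev <- p; cur <- nb[1, ]
      visited[[ekey(p, cur)]] <- TRUE
      len <- len + step_len(p, cur); steps <- steps + 1L
      done[[pk]] <- TRUE
      while (!(cur[1] == p[1] && cur[2] == p[2])) {
        done[[as.character(lin(cur[1], cur[2]))]] <- TRUE
        nb2 <- neighbors(cur[1], cur[2])
        keep <- !(nb2[, 1] == prev[1] & nb2[, 2] == prev[2])
        nxt <- nb2[keep, , drop = FALSE][1, ]
        visited[[ekey(cur, nxt)]] <- TRUE
        len <- len + step_len(cur, nxt); steps <- steps + 1L
        prev <- cur; cur <- nxt
      }
      add_edge(NA_integer_, NA_integer_, steps, len, "cycle")
    }
  }

  edges <- if (length(edges)) do.call(rbind, edges) else empty
  list(edges = edges, n_nodes = n_nodes, n_junctions = n_jnodes,
       n_endpoints = length(ep_idx))
}

#' Skeleton branch metrics
#'
#' Counts branches, measures the longest branch and the network density of a
#' one-pixel-wide skeleton. A branch is a skeleton path between two nodes
#' (junctions or endpoints); endpoint-terminated branches are not pruned;
#' an isolated cycle counts as one branch. Network density is the total
#' skeleton path length per unit ROI area (um of skeleton per um^2).
#'
#' @param skeleton logical/0-1 matrix.
#' @param pixel_size um/pixel.
#' @param roi_area_um2 ROI area in um^2; defaults to the full image area.
#' @return data.frame with `n_branches`, `longest_branch_um`,
#'   `total_length_um`, `network_density`.
#' @export
analyze_skeleton <- function(skeleton, pixel_size = 1, roi_area_um2 = NULL) {
  if (is.null(roi_area_um2))
    roi_area_um2 <- prod(dim(skeleton)) * pixel_size^2
  g <- skeleton_graph(skeleton, pixel_size)
  n <- nrow(g$edges)
  data.frame(
    n_branches = n,
    longest_branch_um = if (n) max(g$edges$length_um) else 0,
    total_length_um = if (n) sum(g$edges$length_um) else 0,
    network_density = if (n) sum(g$edges$length_um) / roi_area_um2 else 0
  )
}
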