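# Skeletonization and branch decomposition of binary tubule masks.

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 8-neighborhood in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW),
# as (dr, dc) offsets of the neighbor relative to the center.
zs_offsets <- list(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                   c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' Iterative two-subpass thinning to a unit-width, 8-connected medial
#' skeleton. The skeleton is a subset of the mask and preserves
#' connectivity of its components.
#'
#' @param mask a `tubule_mask` from [global_threshold()] or a logical
#'   matrix.
#' @return logical matrix of the same shape.
#' @export
skeletonize_mask <- function(mask) {
  if (inherits(mask, "tubule_mask")) mask <- mask$mask
  m <- matrix(as.integer(as.logical(mask)), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- lapply(zs_offsets, function(o) shift_mat(m, -o[1L], -o[2L]))
      # p[[k]] holds the value of neighbor P(k+1) at each center pixel
      b <- Reduce(`+`, p)
      ring <- c(p, p[1L])
      a <- Reduce(`+`, lapply(1:8, function(k) (ring[[k]] == 0L) * (ring[[k + 1L]] == 1L)))
      if (step == 1L) {
        c1 <- p[[1L]] * p[[3L]] * p[[5L]] == 0L   # P2*P4*P6
        c2 <- p[[3L]] * p[[5L]] * p[[7L]] == 0L   # P4*P6*P8
      } else {
        c1 <- p[[1L]] * p[[3L]] * p[[7L]] == 0L   # P2*P4*P8
        c2 <- p[[1L]] * p[[5L]] * p[[7L]] == 0L   # P2*P6*P8
      }
      del <- m == 1L & b >= 2L & b <= 6L & a == 1L & c1 & c2
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

#' Decompose a skeleton into branches
#'
#' Junction pixels are skeleton pixels with more than two 8-connected
#' skeleton neighbors. Branches are the maximal junction-free paths between
#' endpoints and/or junctions; a junction-free connected component with no
#' endpoint is returned as a simple cycle.
#'
#' @param skeleton logical matrix (unit-width, from [skeletonize_mask()]).
#' @return A `branch_set`: list with `branches` (each a `branch`: ordered
#'   `path` matrix of (row, col), `endpoints`, `is_cycle`, `length_px`
#'   counting diagonal steps as sqrt(2)) and `junctions` (matrix of
#'   junction pixel coordinates).
#' @export
split_branches <- function(skeleton) {
  skeleton <- as.matrix(skeleton)
  nr <- nrow(skeleton)
  sk <- matrix(as.integer(as.logical(skeleton)), nr, ncol(skeleton))
  nb_count <- Reduce(`+`, lapply(zs_offsets, function(o) shift_mat(sk, -o[1L], -o[2L])))
  junction <- sk == 1L & nb_count > 2L
  body <- sk == 1L & !junction
  ids <- which(body)                       # column-major linear indices
  branches <- list()
  if (length(ids)) {
    rowv <- (ids - 1L) %% nr + 1L
    colv <- (ids - 1L) %/% nr + 1L
    index_of <- rep(0L, length(sk))
    index_of[ids] <- seq_along(ids)
    neighbors_of <- function(i) {
      r <- rowv[i]; cc <- colv[i]
      out <- integer(0)
      for (o in zs_offsets) {
        rr <- r + o[1L]; cn <- cc + o[2L]
        if (rr >= 1L && rr <= nr && cn >= 1L && cn <= ncol(sk)) {
          j <- index_of[(cn - 1L) * nr + rr]
          if (j > 0L) out <- c(out, j)
        }
      }
      out
    }
    adj <- lapply(seq_along(ids), neighbors_of)
    deg <- lengths(adj)
    visited <- rep(FALSE, length(ids))
    trace_from <- function(start) {
      path <- start
      visited[start] <<- TRUE
      cur <- start; prev <- 0L
      repeat {
        nxt <- setdiff(adj[[cur]], c(prev, path))
        nxt <- nxt[!visited[nxt]]
        if (length(nxt) == 0L) break
        prev <- cur; cur <- nxt[1L]
        visited[cur] <<- TRUE
        path <- c(path, cur)
      }
      path
    }
    step_len <- function(path, close = FALSE) {
      if (length(path) < 2L && !close) return(0)
      r <- rowv[path]; cc <- colv[path]
      if (close) { r <- c(r, r[1L]); cc <- c(cc, cc[1L]) }
      sum(sqrt(diff(r)^2 + diff(cc)^2))
    }
    # open paths first: start from pixels of degree <= 1
    for (s in which(deg <= 1L)) {
      if (visited[s]) next
      path <- trace_from(s)
      branches[[length(branches) + 1L]] <- list(path = path, is_cycle = FALSE)
    }
    # remaining unvisited components are cycles
    for (s in seq_along(ids)) {
      if (visited[s]) next
      path <- trace_from(s)
      branches[[length(branches) + 1L]] <- list(path = path, is_cycle = TRUE)
    }
    branches <- lapply(branches, function(b) {
      pm <- cbind(row = rowv[b$path], col = colv[b$path])
      structure(list(path = pm,
                     endpoints = pm[c(1L, nrow(pm)), , drop = FALSE],
                     is_cycle = b$is_cycle,
                     length_px = step_len(b$path, close = b$is_cycle)),
                class = "branch")
    })
  }
  structure(list(branches = branches,
                 junctions = which(junction, arr.ind = TRUE)),
            class = "branch_set")
}

#' @export
print.branch_set <- function(x, ...) {
  cat(sprintf("branch_set: %d branches (%d cycles), %d junction px\n",
              length(x$branches),
              sum(vapply(x$branches, `[[`, logical(1L), "is_cycle")),
              nrow(x$junctions)))
  invisible(x)
}

#' Straightness of a branch
#'
#' Euclidean distance between the branch endpoints divided by the
#' diagonal-aware path length; 1 for a perfectly straight segment.
#'
#' @param branch a `branch` from [split_branches()].
#' @return ratio in (0, 1].
#' @export
branch_straightness <- function(branch) {
  if (branch$is_cycle) stop("straightness is undefined for cycles", call. = FALSE)
  if (nrow(branch$path) < 2L) stop("branch must have >= 2 pixels", call. = FALSE)
  chord <- sqrt(sum((branch$endpoints[2L, ] - branch$endpoints[1L, ])^2))
  chord / branch$length_px
}

#' Principal-axis orientation of a branch
#'
#' Angle of the largest-variance direction of the branch pixel coordinates
#' (x = column, y = row), mapped to `(-pi/2, pi/2]`; a horizontal branch
#' has orientation 0, a vertical one pi/2.
#'
#' @param branch a `branch`.
#' @return angle in radians.
#' @export
branch_orientation <- function(branch) {
  p <- branch$path
  if (nrow(p) < 2L) return(0)
  x <- p[, "col"]; y <- p[, "row"]
  cv <- stats::cov(cbind(x, y))
  if (all(abs(cv) < .Machine$double.eps)) return(0)
  e <- eigen(cv, symmetric = TRUE)
  v <- e$vectors[, 1L]
  ang <- atan2(v[2L], v[1L])
  if (ang <= -pi / 2) ang <- ang + pi
  if (ang > pi / 2) ang <- ang - pi
  if (ang == -pi / 2) ang <- pi / 2
  ang
}
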