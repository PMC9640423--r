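# Pure-R reference implementation of the region-merging criterion, used as
# the brute-force oracle on tiny images. Unlike the compiled core, every
# quantity is recomputed from scratch from the current label matrix at each
# evaluation, so the two paths share no code or incremental state.

oracle_seg_stats <- function(labels, values, id) {
  px <- which(labels == id)
  rr <- (px - 1L) %% nrow(labels) + 1L
  cc <- (px - 1L) %/% nrow(labels) + 1L
  v <- matrix(values, length(labels), dim(values)[3])[px, , drop = FALSE]
  # exposed edges: neighbours outside the segment or outside the image
  perim <- 0
  for (i in seq_along(px)) {
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      r2 <- rr[i] + d[1]; c2 <- cc[i] + d[2]
      if (r2 < 1 || r2 > nrow(labels) || c2 < 1 || c2 > ncol(labels)) {
        perim <- perim + 1
      } else if (is.na(labels[r2, c2]) || labels[r2, c2] != id) {
        perim <- perim + 1
      }
    }
  }
  list(n = length(px),
       sd = apply(v, 2, function(x) sqrt(mean((x - mean(x))^2))),
       perim = perim,
       bbox = c(min(rr), max(rr), min(cc), max(cc)))
}

oracle_shared_edges <- function(labels, a, b) {
  H <- nrow(labels); W <- ncol(labels)
  s <- 0
  for (px in which(labels == a)) {
    r <- (px - 1L) %% H + 1L; c <- (px - 1L) %/% H + 1L
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W &&
          !is.na(labels[r2, c2]) && labels[r2, c2] == b) s <- s + 1
    }
  }
  s
}

oracle_cost <- function(labels, values, a, b, shape_w, cmpct_w) {
  A <- oracle_seg_stats(labels, values, a)
  B <- oracle_seg_stats(labels, values, b)
  lm <- labels
  lm[lm == b] <- a
  M <- oracle_seg_stats(lm, values, a)
  h_colour <- sum(M$n * M$sd - A$n * A$sd - B$n * B$sd)
  h_compact <- M$perim * sqrt(M$n) -
    (A$perim * sqrt(A$n) + B$perim * sqrt(B$n))
  bb <- function(s) 2 * ((s$bbox[2] - s$bbox[1] + 1) + (s$bbox[4] - s$bbox[3] + 1))
  h_smooth <- M$n * M$perim / bb(M) -
    (A$n * A$perim / bb(A) + B$n * B$perim / bb(B))
  h_shape <- cmpct_w * h_compact + (1 - cmpct_w) * h_smooth
  shape_w * h_shape + (1 - shape_w) * h_colour
}

oracle_neighbours <- function(labels, id) {
  H <- nrow(labels); W <- ncol(labels)
  nb <- integer()
  for (px in which(labels == id)) {
    r <- (px - 1L) %% H + 1L; c <- (px - 1L) %/% H + 1L
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W &&
          !is.na(labels[r2, c2]) && labels[r2, c2] != id) {
        nb <- c(nb, labels[r2, c2])
      }
    }
  }
  sort(unique(nb))
}

# best neighbour: minimal cost, near-ties (1e-12) broken towards lowest id
oracle_best <- function(labels, values, id, shape_w, cmpct_w) {
  nbs <- oracle_neighbours(labels, id)
  if (!length(nbs)) return(list(id = NA_integer_, cost = Inf))
  costs <- vapply(nbs, function(b)
    oracle_cost(labels, values, id, b, shape_w, cmpct_w), 0)
  m <- min(costs)
  pick <- nbs[costs <= m + 1e-12][1]
  list(id = pick, cost = costs[match(pick, nbs)])
}

# full reference segmentation: sweeps in ascending id over the segments
# alive at sweep start, local mutual-best-fitting, merged segment keeps the
# lower id, repeat to fixed point; relabel 1..n in column-major first-pixel
# order
oracle_mrs <- function(values, scale, shape_w = 0.1, cmpct_w = 0.1) {
  if (length(dim(values)) == 2L) values <- array(values, c(dim(values), 1L))
  H <- dim(values)[1]; W <- dim(values)[2]
  labels <- matrix(seq_len(H * W), H, W)
  thr <- scale^2
  repeat {
    merged <- FALSE
    for (id in sort(unique(as.vector(labels)))) {
      if (!any(labels == id)) next
      ba <- oracle_best(labels, values, id, shape_w, cmpct_w)
      if (!is.finite(ba$cost) || !(ba$cost < thr)) next
      bb <- oracle_best(labels, values, ba$id, shape_w, cmpct_w)
      if (bb$id != id) next
      keep <- min(id, ba$id); drop <- max(id, ba$id)
      labels[labels == drop] <- keep
      merged <- TRUE
    }
    if (!merged) break
  }
  out <- matrix(match(labels, unique(as.vector(labels))), H, W)
  out
}
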