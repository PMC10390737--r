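# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

# Per-pixel ring assignment by an explicit double loop.
brute_ring_assignment <- function(image_shape, center, pixel_size, spacing,
                                  n_rings) {
  out <- matrix(NA_integer_, image_shape[1], image_shape[2])
  for (i in seq_len(image_shape[1])) {
    for (j in seq_len(image_shape[2])) {
      d <- pixel_size * sqrt((i - 1 - center[1])^2 + (j - 1 - center[2])^2)
      k <- as.integer(floor(d / spacing))
      if (k < n_rings) out[i, j] <- k
    }
  }
  out
}

# Naive double-loop integrated density.
brute_integrated_density <- function(image, mask) {
  tot <- 0; n <- 0
  for (i in seq_len(nrow(image))) for (j in seq_len(ncol(image)))
    if (mask[i, j]) { tot <- tot + image[i, j]; n <- n + 1 }
  list(integrated = tot, normalized = tot / n)
}

# Composite trapezoid rule written independently.
brute_trapezoid <- function(x, y) {
  s <- 0
  for (k in seq_len(length(x) - 1))
    s <- s + (x[k + 1] - x[k]) * (y[k] + y[k + 1]) / 2
  s
}

# Sliding-window disk median away from borders.
brute_median_disk <- function(img, radius) {
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  offs <- expand.grid(a = -radius:radius, b = -radius:radius)
  offs <- offs[offs$a^2 + offs$b^2 <= radius^2, ]
  for (i in (radius + 1):(nr - radius)) {
    for (j in (radius + 1):(nc - radius)) {
      out[i, j] <- median(img[cbind(i + offs$a, j + offs$b)])
    }
  }
  out
}

# Li/minimum-cross-entropy criterion of a candidate threshold.
li_criterion <- function(v, t) {
  b <- v[v <= t]; f <- v[v > t]
  if (!length(b) || !length(f)) return(Inf)
  sum(b * log(b / mean(b))) + sum(f * log(f / mean(f)))
}

# Recursive-free flood fill labeling (8-connectivity) with an explicit stack.
brute_flood_fill <- function(binary) {
  nr <- nrow(binary); nc <- ncol(binary)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!binary[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j)); lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (a in -1:1) for (b in -1:1) {
        ii <- p[1] + a; jj <- p[2] + b
        if (ii < 1 || jj < 1 || ii > nr || jj > nc) next
        if (binary[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# Branch count from the raw pixel adjacency graph, by counting:
#   edges not internal to a junction component  -  degree-2 slab pixels
#   + number of pure-cycle components (no junction/endpoint pixels).
# Derivation: a branch through k slab pixels contributes k+1 edges; a pure
# cycle of n slabs contributes n edges and n slabs.
brute_branch_count <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  pix <- which(skel, arr.ind = TRUE)
  if (nrow(pix) == 0) return(0L)
  id <- matrix(0L, nr, nc)
  id[pix] <- seq_len(nrow(pix))
  deg <- integer(nrow(pix))
  edges <- list()
  for (p in seq_len(nrow(pix))) {
    i <- pix[p, 1]; j <- pix[p, 2]
    for (a in -1:1) for (b in -1:1) {
      if (a == 0 && b == 0) next
      ii <- i + a; jj <- j + b
      if (ii < 1 || jj < 1 || ii > nr || jj > nc) next
      q <- id[ii, jj]
      if (q > 0) {
        deg[p] <- deg[p] + 1L
        if (q > p) edges[[length(edges) + 1L]] <- c(p, q)
      }
    }
  }
  junction <- deg >= 3
  slab <- deg == 2 & !junction
  e_mat <- do.call(rbind, edges)
  n_edges_ext <- if (is.null(e_mat)) 0L else
    sum(!(junction[e_mat[, 1]] & junction[e_mat[, 2]]))
  # pure cycles: connected components with every pixel of degree exactly 2
  labs <- brute_flood_fill(skel)
  n_cycles <- 0L
  for (lb in seq_len(max(labs))) {
    members <- id[labs == lb & skel]
    if (all(deg[members] == 2)) n_cycles <- n_cycles + 1L
  }
  n_edges_ext - sum(slab) + n_cycles
}

# Hand-computed one-way ANOVA F and Tukey HSD adjusted p-values via the
# studentized range distribution.
brute_oneway_tukey <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); N <- length(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  grand <- mean(values)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((values - means[groups])^2)
  df1 <- k - 1; df2 <- N - k
  mse <- ss_within / df2
  f_stat <- (ss_between / df1) / mse
  p_f <- pf(f_stat, df1, df2, lower.tail = FALSE)
  combs <- combn(levels(groups), 2)
  tukey <- apply(combs, 2, function(pr) {
    n1 <- ns[pr[1]]; n2 <- ns[pr[2]]
    se <- sqrt(mse / 2 * (1 / n1 + 1 / n2))
    q <- abs(means[pr[1]] - means[pr[2]]) / se
    ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
  })
  list(f = f_stat, p = p_f,
       tukey = data.frame(contrast = apply(combs, 2, paste, collapse = " - "),
                          p_adjusted = as.numeric(tukey)))
}

# Filled digitized disk mask of radius r px centred in a square image.
disk_mask <- function(r, pad = 5) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad
  d <- sqrt(outer(((0:(n - 1)) - c0)^2, ((0:(n - 1)) - c0)^2, `+`))
  d <= r
}

# Plus-sign skeleton: two perpendicular arm_len*2+1 pixel lines crossing at
# their centres.
plus_skeleton <- function(arm_len = 20, pad = 2) {
  n <- 2 * (arm_len + pad) + 1
  c0 <- arm_len + pad + 1
  m <- matrix(FALSE, n, n)
  m[c0, (c0 - arm_len):(c0 + arm_len)] <- TRUE
  m[(c0 - arm_len):(c0 + arm_len), c0] <- TRUE
  m
}
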