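# Independent oracles and fixture builders shared across the suite.

# dense-subdivision clip oracle: cut every polyline into ~`step` km pieces
# and sum the lengths of pieces whose midpoints fall inside the polygon
oracle_clip_length <- function(network, poly, step = 0.001) {
  pieces <- if (is.list(poly)) poly else list(poly)
  bb <- c(min(sapply(pieces, function(p) min(p[, 1]))),
          max(sapply(pieces, function(p) max(p[, 1]))),
          min(sapply(pieces, function(p) min(p[, 2]))),
          max(sapply(pieces, function(p) max(p[, 2]))))
  total <- 0
  for (s in network$segments) {
    cc <- s$coords
    for (i in seq_len(nrow(cc) - 1)) {
      if (max(cc[i:(i + 1), 1]) < bb[1] || min(cc[i:(i + 1), 1]) > bb[2] ||
          max(cc[i:(i + 1), 2]) < bb[3] || min(cc[i:(i + 1), 2]) > bb[4]) next
      L <- sqrt(sum((cc[i + 1, ] - cc[i, ])^2))
      n <- max(2L, ceiling(L / step))
      t <- (seq_len(n) - 0.5) / n
      px <- cc[i, 1] + t * (cc[i + 1, 1] - cc[i, 1])
      py <- cc[i, 2] + t * (cc[i + 1, 2] - cc[i, 2])
      inside <- rep(FALSE, n)
      for (p in pieces) inside <- inside | point_in_polygon(px, py, p)
      total <- total + L * mean(inside)
    }
  }
  total
}

# recursive Strahler oracle over a parent-pointer forest
oracle_strahler <- function(topology) {
  ids <- as.character(topology$segment_id)
  parents <- as.character(topology$parent_id)
  kids <- lapply(ids, function(id) ids[!is.na(parents) & parents == id])
  names(kids) <- ids
  rec <- function(id) {
    ch <- kids[[id]]
    if (!length(ch)) return(1L)
    sub <- vapply(ch, rec, integer(1))
    m <- max(sub)
    if (sum(sub == m) >= 2L) m + 1L else m
  }
  roots <- ids[is.na(parents)]
  out <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  fill <- function(id) {
    out[id] <<- rec(id)
    for (ch in kids[[id]]) fill(ch)
  }
  for (r in roots) fill(r)
  out
}

# pairwise-median slope oracle (explicit double loop)
oracle_pairwise_median_slope <- function(x, y) {
  s <- c()
  n <- length(x)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (x[j] != x[i]) s <- c(s, (y[j] - y[i]) / (x[j] - x[i]))
  }
  stats::median(s)
}

# random parent-pointer tree with shuffled ids
random_tree <- function(n, seed) {
  set.seed(seed)
  parent_idx <- c(NA, vapply(2:n, function(i) sample.int(i - 1, 1), integer(1)))
  ids <- sample(sprintf("n%03d", 1:n))
  data.frame(segment_id = ids,
             parent_id = ifelse(is.na(parent_idx), NA_character_, ids[parent_idx]),
             stringsAsFactors = FALSE)
}

# one-segment network from a coordinate matrix
line_network <- function(coords, region) {
  stream_network(list(list(segment_id = "L1", parent_id = NA_character_,
                           strahler_order = 1L,
                           coords = cbind(x = coords[, 1], y = coords[, 2]))),
                 region)
}

# uniform horizontal-grid network: `n_lines` lines across a square region
grid_network <- function(region, n_lines) {
  ys <- seq(region[3], region[4], length.out = n_lines + 2)[2:(n_lines + 1)]
  segs <- lapply(seq_along(ys), function(i)
    list(segment_id = sprintf("g%02d", i), parent_id = NA_character_,
         strahler_order = 1L,
         coords = cbind(x = c(region[1], region[2]), y = c(ys[i], ys[i]))))
  stream_network(segs, region)
}

# burn scar over the unit square split into left/right half patches
half_half_scar <- function(left_class, right_class, year = 2000) {
  patches <- stats::setNames(vector("list", 6), severity_classes())
  patches[[left_class]] <- rect_polygon(0, 0.5, 0, 1)
  patches[[right_class]] <- rect_polygon(0.5, 1, 0, 1)
  burn_scar("fireHH", year, rect_polygon(0, 1, 0, 1), patches)
}

# scar whose every patch is one class covering the whole perimeter
single_class_scar <- function(class, perimeter, fire_id = "fireSC", year = 2000) {
  patches <- stats::setNames(vector("list", 6), severity_classes())
  patches[[class]] <- perimeter
  burn_scar(fire_id, year, perimeter, patches)
}

# decay_fit stand-in with known parameters (for solve_extent oracles)
known_fit <- function(a1, k1, a2 = 0, k2 = 0) {
  structure(list(a1 = a1, k1 = k1, a2 = a2, k2 = k2,
                 degenerate = (k1 == 0 && k2 == 0)),
            class = "decay_fit")
}
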