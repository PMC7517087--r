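# Independent brute-force oracles. Everything here is written with naive
# explicit loops and its own small helpers, deliberately sharing no code
# path with the package implementation.

random_raster <- function(h, w, n_levels) {
  matrix(sample.int(n_levels, h * w, replace = TRUE) - 1L, h, w)
}

# Naive co-occurrence matrix: loop over every pixel, count both pair
# orders, normalize at the end.
oracle_glcm <- function(img, d, angle, n_levels) {
  off <- switch(as.character(angle),
                "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0),
                "135" = c(-d, -d))
  P <- matrix(0, n_levels, n_levels)
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= nrow(img) && c2 >= 1 && c2 <= ncol(img)) {
        a <- img[r, c] + 1; b <- img[r2, c2] + 1
        P[a, b] <- P[a, b] + 1
        P[b, a] <- P[b, a] + 1
      }
    }
  }
  P / sum(P)
}

oracle_log2 <- function(p) if (p > 0) log2(p) else 0

# The 11 second-order statistics, as plain nested loops.
oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  lev <- 0:(ng - 1)
  mu_h <- sum(lev * px); mu_v <- sum(lev * py)
  sd_h <- sqrt(sum((lev - mu_h)^2 * px)); sd_v <- sqrt(sum((lev - mu_v)^2 * py))
  energy <- 0; entropy <- 0; idm <- 0; variance <- 0; corr_num <- 0
  for (a in 1:ng) for (b in 1:ng) {
    p <- P[a, b]
    energy <- energy + p^2
    entropy <- entropy - p * oracle_log2(p)
    idm <- idm + p / (1 + (a - b)^2)
    variance <- variance + ((a - 1) - mu_h)^2 * p
    corr_num <- corr_num + (a - 1) * (b - 1) * p
  }
  p_sum <- numeric(2 * ng - 1)
  p_dif <- numeric(ng)
  for (a in 1:ng) for (b in 1:ng) {
    p_sum[(a - 1) + (b - 1) + 1] <- p_sum[(a - 1) + (b - 1) + 1] + P[a, b]
    p_dif[abs(a - b) + 1] <- p_dif[abs(a - b) + 1] + P[a, b]
  }
  contrast <- 0; sum_avg <- 0; sum_ent <- 0; dif_ent <- 0
  for (k in seq_along(p_dif)) {
    contrast <- contrast + (k - 1)^2 * p_dif[k]
    dif_ent <- dif_ent - p_dif[k] * oracle_log2(p_dif[k])
  }
  for (k in seq_along(p_sum)) {
    sum_avg <- sum_avg + (k - 1) * p_sum[k]
    sum_ent <- sum_ent - p_sum[k] * oracle_log2(p_sum[k])
  }
  mu_dif <- 0
  for (k in seq_along(p_dif)) mu_dif <- mu_dif + (k - 1) * p_dif[k]
  dif_var <- 0
  for (k in seq_along(p_dif)) dif_var <- dif_var + ((k - 1) - mu_dif)^2 * p_dif[k]
  sum_var <- 0
  for (k in seq_along(p_sum)) sum_var <- sum_var + ((k - 1) - sum_avg)^2 * p_sum[k]
  correlation <- if (sd_h == 0 || sd_v == 0) 0 else
    (corr_num - mu_h * mu_v) / (sd_h * sd_v)
  c(Energy = energy, Contrast = contrast, Correlation = correlation,
    Variance = variance, InvDfMom = idm, DifVarnc = dif_var,
    SumAverg = sum_avg, SumVarnc = sum_var, Entropy = entropy,
    SumEntrp = sum_ent, DifEntrp = dif_ent)
}

# Naive run-length matrix: walk each line pixel by pixel.
oracle_glrlm <- function(img, direction, n_levels) {
  h <- nrow(img); w <- ncol(img)
  starts <- switch(as.character(direction),
    "0"   = lapply(seq_len(h), function(r) cbind(r, seq_len(w))),
    "90"  = lapply(seq_len(w), function(c) cbind(seq_len(h), c)),
    "45"  = {  # anti-diagonals, stepping (-1, +1)
      out <- list()
      for (s in 2:(h + w)) {
        rs <- seq(min(h, s - 1), max(1, s - w))
        out[[length(out) + 1]] <- cbind(rs, s - rs)
      }
      out
    },
    "135" = {  # main diagonals, stepping (+1, +1)
      out <- list()
      for (k in (-(h - 1)):(w - 1)) {
        rs <- seq(max(1, 1 - k), min(h, w - k))
        out[[length(out) + 1]] <- cbind(rs, rs + k)
      }
      out
    })
  P <- matrix(0, n_levels, max(h, w))
  for (line in starts) {
    vals <- img[line]
    i <- 1
    while (i <= length(vals)) {
      j <- i
      while (j < length(vals) && vals[j + 1] == vals[i]) j <- j + 1
      P[vals[i] + 1, j - i + 1] <- P[vals[i] + 1, j - i + 1] + 1
      i <- j + 1
    }
  }
  P
}

oracle_glrlm_features <- function(P, n_pixels) {
  N <- sum(P)
  ng <- nrow(P); nr <- ncol(P)
  out <- c(ShrtREmph = 0, LngREmph = 0, GLevNonU = 0, GLevNonUNorm = 0,
           RLNonUni = 0, RLNonUniNorm = 0, Fraction = N / n_pixels,
           LowGREmph = 0, HighGREmph = 0, ShrtRLowGREmph = 0,
           ShrtRHighGREmph = 0, LngRLowGREmph = 0, LngRHighGREmph = 0,
           GLevVar = 0, RLenVar = 0)
  for (l in 1:ng) for (m in 1:nr) {
    p <- P[l, m]
    out["ShrtREmph"] <- out["ShrtREmph"] + p / m^2
    out["LngREmph"] <- out["LngREmph"] + p * m^2
    out["LowGREmph"] <- out["LowGREmph"] + p / l^2
    out["HighGREmph"] <- out["HighGREmph"] + p * l^2
    out["ShrtRLowGREmph"] <- out["ShrtRLowGREmph"] + p / (l^2 * m^2)
    out["ShrtRHighGREmph"] <- out["ShrtRHighGREmph"] + p * l^2 / m^2
    out["LngRLowGREmph"] <- out["LngRLowGREmph"] + p * m^2 / l^2
    out["LngRHighGREmph"] <- out["LngRHighGREmph"] + p * l^2 * m^2
  }
  for (l in 1:ng) out["GLevNonU"] <- out["GLevNonU"] + sum(P[l, ])^2
  for (m in 1:nr) out["RLNonUni"] <- out["RLNonUni"] + sum(P[, m])^2
  out["GLevNonUNorm"] <- out["GLevNonU"] / N^2
  out["RLNonUniNorm"] <- out["RLNonUni"] / N^2
  for (nm in c("ShrtREmph", "LngREmph", "GLevNonU", "RLNonUni", "LowGREmph",
               "HighGREmph", "ShrtRLowGREmph", "ShrtRHighGREmph",
               "LngRLowGREmph", "LngRHighGREmph")) {
    out[nm] <- out[nm] / N
  }
  mu_l <- 0; mu_m <- 0
  for (l in 1:ng) for (m in 1:nr) {
    mu_l <- mu_l + l * P[l, m] / N
    mu_m <- mu_m + m * P[l, m] / N
  }
  for (l in 1:ng) for (m in 1:nr) {
    out["GLevVar"] <- out["GLevVar"] + (l - mu_l)^2 * P[l, m] / N
    out["RLenVar"] <- out["RLenVar"] + (m - mu_m)^2 * P[l, m] / N
  }
  out
}

# Independent entropy / symmetric uncertainty, and exhaustive CFS over all
# non-empty subsets (for small feature counts).
oracle_entropy <- function(v) {
  p <- table(v) / length(v)
  -sum(ifelse(p > 0, p * log2(p), 0))
}

oracle_su <- function(a, b) {
  ha <- oracle_entropy(a); hb <- oracle_entropy(b)
  if (ha + hb == 0) return(0)
  hab <- oracle_entropy(paste(a, b, sep = "\r"))
  2 * (ha + hb - hab) / (ha + hb)
}

oracle_cfs_exhaustive <- function(disc, y) {
  p <- ncol(disc)
  su_c <- vapply(seq_len(p), function(i) oracle_su(disc[, i], y), numeric(1))
  su_ff <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i < j) su_ff[i, j] <- su_ff[j, i] <- oracle_su(disc[, i], disc[, j])
  }
  best <- NULL; best_merit <- -Inf
  for (k in seq_len(p)) {
    for (subset in utils::combn(p, k, simplify = FALSE)) {
      rcf <- mean(su_c[subset])
      rff <- if (k > 1) mean(su_ff[subset, subset][upper.tri(diag(k))]) else 0
      merit <- k * rcf / sqrt(k + k * (k - 1) * rff)
      if (merit > best_merit + 1e-12) {
        best_merit <- merit; best <- subset
      }
    }
  }
  sort(best)
}

# 8-connected components of a predicate via igraph (independent of the
# package's own labelling).
igraph_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  edges <- integer(0)
  for (p in idx) {
    r <- (p - 1) %% h + 1; c <- (p - 1) %/% h + 1
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
        q <- (c2 - 1) * h + r2
        if (mask[q] && q > p) edges <- c(edges, p, q)
      }
    }
  }
  g <- igraph::graph_from_edgelist(matrix(match(edges, idx), ncol = 2,
                                          byrow = TRUE), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  out <- matrix(0L, h, w)
  out[idx] <- comp
  out
}

# clip+round a numeric matrix into a valid gray image
requant <- function(m) {
  matrix(as.integer(pmin(255, pmax(0, round(m)))), nrow(m))
}
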