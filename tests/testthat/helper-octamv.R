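# Independent 8-connectivity component counter (BFS), used as an oracle for
# topology checks on skeletons.
count_components8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc); nxt <- 0L
  for (s in which(m)) {
    if (lab[s] > 0L) next
    nxt <- nxt + 1L; stack <- s; lab[s] <- nxt
    while (length(stack)) {
      u <- stack[1L]; stack <- stack[-1L]
      i <- (u - 1L) %% nr + 1L; j <- (u - 1L) %/% nr + 1L
      for (a in -1:1) for (b in -1:1) {
        ii <- i + a; jj <- j + b
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            m[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- nxt
          stack <- c(stack, (jj - 1L) * nr + ii)
        }
      }
    }
  }
  nxt
}

# All 2x2 all-on blocks of a logical matrix (top-left corners, arr.ind).
blocks_2x2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  which(m[-nr, -nc] & m[-1, -nc] & m[-nr, -1] & m[-1, -1], arr.ind = TRUE)
}

# Construct raw data that realize (n, mean, sd) exactly: affine transform of
# a fixed base vector standardized to zero mean / unit sample SD.
exact_sample <- function(n, mean, sd) {
  v <- seq_len(n)
  v <- (v - base::mean(v)) / stats::sd(v)
  mean + sd * v
}

# Raw cohort (long data frame) realizing a summary table exactly.
exact_cohort <- function(summaries) {
  do.call(rbind, lapply(seq_len(nrow(summaries)), function(i)
    data.frame(group = summaries$group[i],
               y = exact_sample(summaries$n[i], summaries$mean[i],
                                summaries$sd[i]),
               stringsAsFactors = FALSE)))
}

# O(n^2) Mann-Whitney pair-count oracle: P(pos > neg) + 0.5 P(tie).
pair_count_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Dilate a logical mask by k 4-neighbour steps.
dilate4 <- function(m, k) {
  for (s in seq_len(k)) {
    nr <- nrow(m); nc <- ncol(m)
    P <- matrix(FALSE, nr + 2L, nc + 2L)
    P[2:(nr + 1L), 2:(nc + 1L)] <- m
    m <- P[1:nr, 2:(nc + 1L)] | P[3:(nr + 2L), 2:(nc + 1L)] |
      P[2:(nr + 1L), 1:nc] | P[2:(nr + 1L), 3:(nc + 2L)] |
      P[2:(nr + 1L), 2:(nc + 1L)]
  }
  m
}

# Hand-built single-segment tree for rasterization tests.
toy_tree <- function(segments, field_mm, faz_radius = 0,
                     capillary_width = 0.025) {
  structure(
    list(segments = segments,
         total_centerline_length = sum(sqrt((segments$x1 - segments$x0)^2 +
                                              (segments$y1 - segments$y0)^2)),
         field_mm = field_mm, faz_centre = c(0, 0), faz_radius = faz_radius,
         capillary_width = capillary_width, dropout_fraction = 0, seed = 0L),
    class = "vessel_tree_truth")
}

noiseless <- list(background = 0, background_sd = 0, speckle_sd = 0)
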