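# Independent brute-force oracles used across test files.

# per-read pattern validator: explicit position loop (weak at odd positions,
# strong at even), independent of the vectorized implementation
oracle_pattern_ok <- function(read, len = 30) {
  if (nchar(read) < len) return(FALSE)
  for (i in seq_len(len)) {
    ch <- substr(read, i, i)
    ok <- if (i %% 2 == 1) ch %in% c("A", "T") else ch %in% c("G", "C")
    if (!ok) return(FALSE)
  }
  TRUE
}

oracle_hamming <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  sum(va != vb)
}

# O(n^2) all-pairs iterated Hamming merge implementing the stated contract
oracle_collapse <- function(barcodes, counts, max_hamming = 2, min_ratio = 8) {
  repeat {
    changed <- FALSE
    o <- order(counts)
    for (idx in o) {
      if (counts[idx] == -1) next
      cand <- c(); dist <- c()
      for (j in seq_along(barcodes)) {
        if (j == idx || counts[j] == -1) next
        if (counts[j] >= min_ratio * counts[idx]) {
          d <- oracle_hamming(barcodes[idx], barcodes[j])
          if (d <= max_hamming) { cand <- c(cand, j); dist <- c(dist, d) }
        }
      }
      if (!length(cand)) next
      best <- cand[dist == min(dist)]
      if (length(best) > 1) next  # ambiguous parent: leave unmerged
      counts[best] <- counts[best] + counts[idx]
      counts[idx] <- -1
      changed <- TRUE
    }
    if (!changed) break
  }
  keep <- counts != -1
  data.frame(barcode = barcodes[keep], counts = counts[keep],
             stringsAsFactors = FALSE)
}

# literal nine-neighbour windowed median
oracle_median_filter <- function(m) {
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    vals <- c()
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m))
        vals <- c(vals, m[ii, jj])
    }
    out[i, j] <- median(vals)
  }
  out
}

# random weak/strong-alternating barcodes of length len
random_ws_barcodes <- function(n, len = 30) {
  vapply(seq_len(n), function(i) {
    paste0(ifelse(seq_len(len) %% 2 == 1,
                  sample(c("A", "T"), len, replace = TRUE),
                  sample(c("G", "C"), len, replace = TRUE)),
           collapse = "")
  }, character(1))
}

# mutate one random position of a weak/strong barcode so the pattern breaks
break_pattern <- function(bc) {
  len <- nchar(bc)
  i <- sample(len, 1)
  wrong <- if (i %% 2 == 1) sample(c("G", "C"), 1) else sample(c("A", "T"), 1)
  paste0(substr(bc, 1, i - 1), wrong, substr(bc, i + 1, len))
}

make_barcode_counts <- function(barcodes, ...) {
  df <- data.frame(barcode = barcodes, ..., stringsAsFactors = FALSE)
  class(df) <- c("barcode_counts", "data.frame")
  df
}
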