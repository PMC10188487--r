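# Shared fixture builders; everything is generated in code at test time.

# Rasterized disk mask of radius r_px with a margin.
disk_mask <- function(r_px, margin = 10) {
  n <- 2 * (r_px + margin) + 1
  ctr <- r_px + margin + 1
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  d <= r_px
}

square_mask <- function(side_px, margin = 10) {
  n <- side_px + 2 * margin
  m <- matrix(FALSE, n, n)
  m[margin + seq_len(side_px), margin + seq_len(side_px)] <- TRUE
  m
}

# Brute-force all-pairs closest gene oracle on BED-style intervals.
closest_gene_bruteforce <- function(peak, genes) {
  # peak: c(chrom, start, end); genes: data.frame
  g <- genes[genes$chrom == peak$chrom, ]
  if (!nrow(g)) return(list(gene_id = NA_character_, distance = NA_integer_))
  gap <- function(s1, e1, s2, e2) {
    if (e1 > s2 && e2 > s1) 0L else if (e1 <= s2) s2 - e1 else s1 - e2
  }
  d <- vapply(seq_len(nrow(g)),
              function(i) gap(peak$start, peak$end, g$start[i], g$end[i]),
              numeric(1))
  best <- which(d == min(d))
  best <- best[which.min(g$start[best])]
  list(gene_id = g$gene_id[best], distance = as.integer(min(d)))
}

# Closed-form two-sided pooled t test on two samples (independent oracle).
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

welch_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x) / n1; v2 <- var(y) / n2
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

two_prop_z_oracle <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2; ph <- (x1 + x2) / (n1 + n2)
  (p1 - p2) / sqrt(ph * (1 - ph) * (1 / n1 + 1 / n2))
}
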