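# Independent oracles used to cross-check the implementation. Each is a
# deliberately naive, separately coded route to the same quantity.

# Digest oracle: naive character scan for the recognition site, cutting at
# the 5' start of every occurrence; zero-length fragments dropped.
naive_digest <- function(seq_string, site = "GATC") {
  chars <- strsplit(seq_string, "")[[1]]
  n <- length(chars)
  w <- nchar(site)
  cuts <- integer(0)
  for (i in seq_len(n - w + 1)) {
    if (paste(chars[i:(i + w - 1)], collapse = "") == site) {
      cuts <- c(cuts, i - 1L)  # 0-based cut
    }
  }
  bounds <- sort(unique(c(0L, cuts, n)))
  out <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
  out[out$end > out$start, , drop = FALSE]
}

# Interval-assignment oracle: O(n*m) scan of every (region, fragment) pair.
brute_overlaps <- function(regions, fragments) {
  hits <- list()
  for (r in seq_len(nrow(regions))) {
    for (f in seq_len(nrow(fragments))) {
      if (regions$chrom[r] == fragments$chrom[f] &&
          regions$start[r] < fragments$end[f] &&
          regions$end[r] > fragments$start[f]) {
        hits[[length(hits) + 1L]] <- data.frame(
          gene_id = regions$gene_id[r], chrom = regions$chrom[r],
          fragment = fragments$index[f]
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(gene_id = character(), chrom = character(),
                      fragment = integer()))
  }
  do.call(rbind, hits)
}

# Step-up FDR oracle: adjusted p_(k) = min over r >= k of m * p_(r) / r.
stepup_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  running <- Inf
  for (k in rev(seq_len(m))) {
    running <- min(running, m * p[ord[k]] / k)
    adj_sorted[k] <- min(1, running)
  }
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# Pooled two-proportion Z closed form.
two_prop_z <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  (p1 - p2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
}

# Supporting-interaction conservation oracle: enumerate every
# (record, SNP-end, overlapping gene) triple.
brute_support_total <- function(interactions, snp_map, gene_map) {
  total <- 0L
  for (r in seq_len(nrow(interactions))) {
    rec <- interactions[r, ]
    for (snp_end in 1:2) {
      sc <- rec[[paste0("chrom", snp_end)]]
      sf <- rec[[paste0("frag", snp_end)]]
      gc <- rec[[paste0("chrom", 3 - snp_end)]]
      gf <- rec[[paste0("frag", 3 - snp_end)]]
      n_snps <- sum(snp_map$chrom == sc & snp_map$fragment == sf)
      n_genes <- sum(gene_map$chrom == gc & gene_map$fragment == gf)
      total <- total + n_snps * n_genes
    }
  }
  total
}
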