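# Independent brute-force oracles used to check the package's own
# implementations. Each oracle takes the slow-but-obvious route and shares
# no code with the path it checks.

# Single-linkage components by all-pairs union-find: elements i, j are
# connected when |pos_i - pos_j| <= max_gap. Returns component id per input
# element (in input order).
oracle_single_linkage <- function(positions, max_gap) {
  n <- length(positions)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && abs(positions[i] - positions[j]) <= max_gap) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Canonical form of a clustering: sorted vector of comma-joined sorted
# member positions, for comparison independent of labels and order.
cluster_signature <- function(positions, comp) {
  parts <- split(positions, comp)
  sig <- vapply(parts, function(p) paste(sort(p), collapse = ","),
                character(1))
  sort(unname(sig))
}

# Per-position brute-force invariable-interval scan: walk the genome, start
# a new interval at each variable base or after each insertion gap.
oracle_invariable <- function(variable_set, gap_set, genome_len) {
  out <- list()
  cur_start <- NA_integer_
  for (p in seq_len(genome_len)) {
    if (p %in% variable_set) {
      if (!is.na(cur_start)) {
        out[[length(out) + 1L]] <- c(cur_start, p - 1L)
        cur_start <- NA_integer_
      }
    } else {
      if (is.na(cur_start)) cur_start <- p
      if (p %in% gap_set || p == genome_len) {
        out[[length(out) + 1L]] <- c(cur_start, p)
        cur_start <- NA_integer_
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          length = integer(0)))
  }
  m <- do.call(rbind, out)
  tibble::tibble(start = m[, 1], end = m[, 2], length = m[, 2] - m[, 1] + 1L)
}

# Exact HWE p-value by enumeration over all genotype vectors of n diploid
# individuals (feasible for n <= 7): each vector g in {0,1,2}^n with the
# observed rare-allele total has probability proportional to the number of
# allele arrangements prod_i choose(2, g_i).
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  stopifnot(n <= 7)
  total_alt <- 2 * n_aa + n_Aa
  grid <- as.matrix(expand.grid(rep(list(0:2), n)))
  keep <- rowSums(grid) == total_alt
  grid <- grid[keep, , drop = FALSE]
  w <- apply(grid, 1, function(g) prod(choose(2, g)))
  het <- rowSums(grid == 1)
  probs <- tapply(w, het, sum)
  probs <- probs / sum(probs)
  obs <- probs[as.character(n_Aa)]
  sum(probs[probs <= obs + 1e-12])
}

# Brute-force window-overlap count: double loop over windows x intervals.
# Intervals are 1-based closed.
oracle_overlap_count <- function(win_chrom, win_start, win_end, intervals) {
  hits <- 0L
  for (i in seq_along(win_chrom)) {
    for (j in seq_len(nrow(intervals))) {
      if (win_chrom[i] == intervals$chrom[j] &&
          win_start[i] <= intervals$end[j] &&
          win_end[i] >= intervals$start[j]) {
        hits <- hits + 1L
        break
      }
    }
  }
  hits
}

# One-tailed (greater) rank-sum p-value by full enumeration of group-label
# assignments; requires tie-free pooled values and small n.
oracle_ranksum_greater <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(length(pooled) <= 10, !anyDuplicated(pooled))
  r <- rank(pooled)
  obs <- sum(r[seq_along(x)])
  combos <- utils::combn(length(pooled), length(x))
  stats <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(stats >= obs)
}

# Minimal VCF writer independent of the package's own writer, used to craft
# malformed or multi-allelic fixtures.
write_raw_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=chrM,length=16569>",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", "S1"), collapse = "\t"))
  writeLines(c(header, lines), path)
  path
}
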