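# Independent oracles and small fixture builders used across the suite.

# Exhaustive-search global alignment score under the package's declared
# scheme (match +1, mismatch -1, gap of length L costs 3 + L). Pure
# recursion over every alignment path; no dynamic programming shared with
# the implementation under test. Feasible for sequences up to ~8 nt.
bf_align_score <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B))
      best <- max(best, (if (A[i] == B[j]) 1 else -1) + rec(i + 1, j + 1, "M"))
    if (i <= length(A))
      best <- max(best, (if (identical(prev, "GB")) -1 else -4) +
                    rec(i + 1, j, "GB"))
    if (j <= length(B))
      best <- max(best, (if (identical(prev, "GA")) -1 else -4) +
                    rec(i, j + 1, "GA"))
    best
  }
  rec(1, 1, "M")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# plant substitutions at given 1-based positions, returning the mutant
plant_subs <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

# fabricate a pileup object directly from a count matrix
fab_pileup <- function(ref, counts,
                       insertions = data.frame(position = integer(0),
                                               sequence = character(0),
                                               count = integer(0),
                                               stringsAsFactors = FALSE)) {
  stopifnot(nrow(counts) == 5)
  rownames(counts) <- c("A", "C", "G", "T", "del")
  structure(list(ref = ref, counts = counts, insertions = insertions,
                 depth = colSums(counts)),
            class = "pileup")
}

# direct-counting variant caller: the threshold rule applied naively,
# independent of detect_variants' implementation
naive_variants <- function(p, min_depth = 10, min_count = 2,
                           min_freq = 0.05) {
  ref <- strsplit(p$ref, "")[[1]]
  rows <- list()
  for (pos in seq_along(p$depth)) {
    d <- p$depth[pos]
    if (d < min_depth) next
    for (allele in c("A", "C", "G", "T", "-")) {
      row <- if (allele == "-") "del" else allele
      cnt <- p$counts[row, pos]
      if (allele != ref[pos] && cnt >= min_count && cnt / d >= min_freq &&
          cnt > 0)
        rows[[length(rows) + 1]] <- data.frame(position = pos - 1L,
                                               alt = allele, count = cnt,
                                               stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(position = integer(0), alt = character(0),
                  count = integer(0), stringsAsFactors = FALSE)
}

# a small default panel shared by slower tests (built once per run)
shared_panel <- local({
  panel <- NULL
  function() {
    if (is.null(panel)) panel <<- make_reference_panel(panel_config(seed = 42))
    panel
  }
})
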