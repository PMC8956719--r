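# Shared fixtures and independent brute-force oracles.

tbl <- default_fertility_table()

# Brute-force oracle for clutch-size allocations: enumerate every function
# hosts -> {0..max_clutch}, filter by offspring total, canonicalise each
# assignment as a non-increasing multiset of positive clutch sizes.
oracle_size_allocations <- function(n_hosts, n_offspring, max_clutch = 4L) {
  if (n_hosts == 0L) {
    return(if (n_offspring == 0L) list(integer(0)) else list())
  }
  grid <- as.matrix(expand.grid(rep(list(0:max_clutch), n_hosts)))
  keep <- rowSums(grid) == n_offspring
  canon <- unique(apply(grid[keep, , drop = FALSE], 1L, function(row) {
    row <- sort(row[row > 0], decreasing = TRUE)
    paste(row, collapse = "+")
  }))
  lapply(canon, function(s) {
    if (s == "") integer(0) else as.integer(strsplit(s, "\\+")[[1]])
  })
}

canon_strings <- function(allocs) {
  sort(vapply(allocs, paste, character(1), collapse = "+"))
}

# Brute-force oracle for the composition menu: all sex vectors of length k,
# collapsed to multiset equivalence classes.
oracle_composition_count <- function(max_clutch) {
  total <- 0L
  for (k in seq_len(max_clutch)) {
    vecs <- expand.grid(rep(list(c("F", "M")), k))
    classes <- unique(apply(as.matrix(vecs), 1L,
                            function(v) paste(sort(v), collapse = "")))
    total <- total + length(classes)
  }
  total
}

# All-female F2 of a size multiset, written independently of sizes_f2().
oracle_f2 <- function(table, sizes) {
  f <- table$f
  sum(sizes * f[sizes])
}
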