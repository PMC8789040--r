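# shared fixtures, built in code at test time

# a tiny two-species RNA pool: one binder, one non-binder
tiny_mixture <- function(binder_frac = 0.01, total = 1e8) {
  rna <- rna_pool(c(strrep("A", 20), strrep("C", 20)),
                  c(binder_frac, 1 - binder_frac) * total,
                  ids = c("bind", "nonbind"))
  phage <- protein_pool(c("ARNDCEQG", "WYVLKIHF"), c(1, 99) * 1e8,
                        ids = c("Pbind", "Pnon"), seed = 11L)
  landscape <- kd_landscape("bind", "Pbind", k_on = 1e7, k_off = 1e-4)
  list(rna = rna, phage = phage, landscape = landscape)
}

# random count table over two rounds with identical species sets
random_two_round_table <- function(n_species = 50L, seed = 1L,
                                   pool = "RNA") {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n_species), function(i)
      paste(sample(c("A", "C", "G", "U"), 12L, replace = TRUE),
            collapse = ""), character(1L))
    seqs <- unique(seqs)
    t1 <- build_count_table(rep(seqs, sample(1:50, length(seqs), TRUE)),
                            pool, 1L)
    t2 <- build_count_table(rep(seqs, sample(1:50, length(seqs), TRUE)),
                            pool, 2L)
    count_table_bind(t1, t2)
  })
}

# independent sort-based quantile oracle (linear interpolation)
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  unname(x[lo] + (h - lo) * (x[hi] - x[lo]))
}
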