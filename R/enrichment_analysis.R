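# NGS analysis of selection pools: demultiplexing, variable-region
# extraction, abundance and enrichment-factor (EF) tables, monotonic-EF
# filtering, top-N ranking, diversity binning, consensus-motif fractions and
# positional residue preferences.
#
# EFs are ratios of relative abundances (not raw counts): robust to unequal
# sequencing depth per round, and the natural reading of "abundance after
# round N divided by that of round N-1".

.hamming <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

#' Demultiplex reads by 5' barcode
#'
#' Each read is assigned to the unique barcode within `max_mismatch` of its
#' prefix, or to the unassigned bin. The barcode set must have pairwise
#' Hamming distance > 2 * max_mismatch so assignment is unambiguous; a set
#' violating this is rejected. Assigned reads have the barcode stripped.
#'
#' @param reads data.frame with a `sequence` column (and optionally `id`,
#'   `quality`), as returned by [generate_reads()] or [read_fastq()].
#' @param barcodes named character vector of equal-length DNA barcodes.
#' @param max_mismatch tolerated mismatches (default 1).
#' @return list with `assigned` (named list of data.frames, barcode
#'   stripped) and `unassigned` (data.frame).
#' @export
demultiplex <- function(reads, barcodes, max_mismatch = 1L) {
  stopifnot(is.character(barcodes), length(barcodes) >= 1L,
            !is.null(names(barcodes)))
  bl <- unique(nchar(barcodes))
  if (length(bl) != 1L) stop("barcodes must be equal length", call. = FALSE)
  if (length(barcodes) > 1L) {
    pairs <- utils::combn(length(barcodes), 2L)
    dmin <- min(apply(pairs, 2L, function(ij)
      .hamming(barcodes[ij[1L]], barcodes[ij[2L]])))
    if (dmin <= 2L * max_mismatch)
      stop(sprintf(paste0("barcode set rejected: minimum pairwise Hamming ",
                          "distance %d is not > 2 * max_mismatch = %d"),
                   dmin, 2L * max_mismatch), call. = FALSE)
  }
  prefix <- substr(reads$sequence, 1L, bl)
  pm <- matrix(unlist(strsplit(prefix, ""), use.names = FALSE),
               ncol = bl, byrow = TRUE)
  mm <- vapply(barcodes, function(b) {
    bc <- strsplit(b, "")[[1L]]
    rowSums(pm != matrix(bc, nrow(pm), bl, byrow = TRUE))
  }, numeric(nrow(reads)))
  if (nrow(reads) == 1L) mm <- matrix(mm, nrow = 1L)
  best <- apply(mm, 1L, which.min)
  ok <- mm[cbind(seq_len(nrow(mm)), best)] <= max_mismatch
  assigned <- lapply(seq_along(barcodes), function(k) {
    sub <- reads[ok & best == k, , drop = FALSE]
    sub$sequence <- substr(sub$sequence, bl + 1L, nchar(sub$sequence))
    rownames(sub) <- NULL
    sub
  })
  names(assigned) <- names(barcodes)
  unassigned <- reads[!ok, , drop = FALSE]
  rownames(unassigned) <- NULL
  list(assigned = assigned, unassigned = unassigned)
}

# best fuzzy occurrence of `anchor` in `x` at or after `from`; returns the
# leftmost start with <= mm mismatches, or -1
.fuzzy_find <- function(x, anchor, mm, from = 1L) {
  la <- nchar(anchor)
  lx <- nchar(x)
  if (lx - from + 1L < la) return(-1L)
  a <- strsplit(anchor, "")[[1L]]
  for (s in from:(lx - la + 1L)) {
    w <- strsplit(substr(x, s, s + la - 1L), "")[[1L]]
    if (sum(w != a) <= mm) return(s)
  }
  -1L
}

#' Extract variable regions from RNA-library reads
#'
#' Anchors on the 3' end of the 5' fixed flank and the 5' start of the 3'
#' fixed flank (each within `max_flank_mismatch` substitutions; exact match
#' is tried first for speed) and returns the enclosed subsequence,
#' canonicalized to the RNA alphabet. Reads whose anchors cannot be located
#' are rejected with reason "flank_not_found".
#'
#' @param reads character vector of read sequences, or a data.frame with a
#'   `sequence` column.
#' @param design an [rna_library_design()].
#' @param flank_anchor_len anchor length taken from each flank (default 12).
#' @param max_flank_mismatch tolerated substitutions per anchor (default 1).
#' @return character vector of variable regions (RNA alphabet), `NA` where
#'   rejected, with `attr(, "reject_reason")`.
#' @export
extract_variable_region <- function(reads, design = hairpin_n20_design(),
                                    flank_anchor_len = 12L,
                                    max_flank_mismatch = 1L) {
  if (is.data.frame(reads)) reads <- reads$sequence
  seqs <- chartr("U", "T", toupper(reads))
  f5 <- chartr("U", "T", design$fixed_5p)
  f3 <- chartr("U", "T", design$fixed_3p)
  al <- min(flank_anchor_len, nchar(f5), nchar(f3))
  a5 <- substr(f5, nchar(f5) - al + 1L, nchar(f5))
  a3 <- substr(f3, 1L, al)
  stopifnot(all(nchar(seqs) >= 2L * al + 1L | TRUE))
  n <- length(seqs)
  out <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  p5 <- regexpr(a5, seqs, fixed = TRUE)
  p3 <- regexpr(a3, seqs, fixed = TRUE)
  exact <- p5 > 0L & p3 > 0L & p3 > p5 + al - 1L
  need_fuzzy <- which(!exact)
  if (max_flank_mismatch > 0L) {
    for (i in need_fuzzy) {
      s5 <- if (p5[i] > 0L) p5[i] else .fuzzy_find(seqs[i], a5, max_flank_mismatch)
      if (s5 < 0L) { reason[i] <- "flank_not_found"; next }
      s3 <- .fuzzy_find(seqs[i], a3, max_flank_mismatch, from = s5 + al)
      if (s3 < 0L) { reason[i] <- "flank_not_found"; next }
      p5[i] <- s5
      p3[i] <- s3
      exact[i] <- TRUE
    }
  } else reason[need_fuzzy] <- "flank_not_found"
  hit <- which(exact)
  var <- substr(seqs[hit], p5[hit] + al, p3[hit] - 1L)
  empty <- nchar(var) == 0L
  reason[hit[empty]] <- "empty_insert"
  out[hit[!empty]] <- canonicalize_rna(var[!empty])
  attr(out, "reject_reason") <- reason
  out
}

# ---- count tables -----------------------------------------------------------

#' Build an abundance table from extracted sequences
#'
#' Exact multiset counting; rejected (NA) sequences are dropped first. Rows
#' are ordered deterministically by count descending, then sequence
#' lexicographically — the ordering used by every ranked output. An empty
#' input for a declared (pool, round) is an error, not a silent empty table.
#'
#' @param sequences character vector (NAs dropped).
#' @param pool pool label (e.g. "RNA", "PD").
#' @param round round number.
#' @param drop_stops drop sequences containing "*" (nonfunctional displayed
#'   variants); default FALSE.
#' @return data.frame of class `count_table` with columns pool, round,
#'   sequence, count, abundance.
#' @export
build_count_table <- function(sequences, pool, round, drop_stops = FALSE) {
  seqs <- sequences[!is.na(sequences)]
  if (drop_stops) seqs <- seqs[!grepl("*", seqs, fixed = TRUE)]
  if (length(seqs) == 0L)
    stop(sprintf("no sequences for pool '%s' round %s", pool, round),
         call. = FALSE)
  tab <- table(seqs)
  df <- data.frame(pool = pool, round = as.integer(round),
                   sequence = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$sequence), , drop = FALSE]
  df$abundance <- df$count / sum(df$count)
  rownames(df) <- NULL
  class(df) <- c("count_table", "data.frame")
  df
}

#' Count table directly from a simulated pool
#'
#' Uses the pool's exact counts (no sequencing), for expectation-mode and
#' truth-table analyses. Real-valued counts are allowed.
#'
#' @param pool a `selex_pool`.
#' @param label pool label.
#' @param round round number.
#' @param drop_stops drop "*"-containing sequences.
#' @return a `count_table` (count column may be real-valued).
#' @export
pool_count_table <- function(pool, label, round, drop_stops = FALSE) {
  keep <- pool$count > 0
  if (drop_stops) keep <- keep & !grepl("*", pool$sequence, fixed = TRUE)
  df <- data.frame(pool = label, round = as.integer(round),
                   sequence = pool$sequence[keep],
                   count = pool$count[keep], stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    stop(sprintf("no sequences for pool '%s' round %s", label, round),
         call. = FALSE)
  df <- df[order(-df$count, df$sequence), , drop = FALSE]
  df$abundance <- df$count / sum(df$count)
  rownames(df) <- NULL
  class(df) <- c("count_table", "data.frame")
  df
}

#' Bind count tables across pools/rounds
#' @param ... `count_table`s.
#' @return a single `count_table`.
#' @export
count_table_bind <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  class(df) <- c("count_table", "data.frame")
  df
}

.ct_slice <- function(table, pool, round) {
  df <- table[table$pool == pool & table$round == round, , drop = FALSE]
  if (nrow(df) == 0L)
    stop(sprintf("count table has no rows for pool '%s' round %s",
                 pool, round), call. = FALSE)
  df
}

# ---- enrichment factors -----------------------------------------------------

#' Round-to-round enrichment factors
#'
#' EF = abundance in `round_to` / abundance in `round_to - 1`, per species.
#' Species absent from the earlier round have an undefined EF (status
#' "undefined", distinct from EF 0); species absent from the later round get
#' EF 0 (status "ok").
#'
#' @param table a `count_table` covering both rounds for `pool`.
#' @param pool pool label.
#' @param round_to later round; the earlier round is `round_to - 1` unless
#'   `round_from` is given.
#' @param round_from optional explicit earlier round.
#' @return data.frame with columns sequence, abundance_from, abundance_to,
#'   ef, status ("ok" or "undefined").
#' @export
enrichment_factors <- function(table, pool, round_to,
                               round_from = round_to - 1L) {
  from <- .ct_slice(table, pool, round_from)
  to <- .ct_slice(table, pool, round_to)
  species <- union(from$sequence, to$sequence)
  ab_f <- setNames(rep(0, length(species)), species)
  ab_t <- ab_f
  ab_f[from$sequence] <- from$abundance
  ab_t[to$sequence] <- to$abundance
  undef <- ab_f == 0
  ef <- ifelse(undef, NA_real_, ab_t / ab_f)
  out <- data.frame(sequence = species, abundance_from = unname(ab_f),
                    abundance_to = unname(ab_t), ef = unname(ef),
                    status = ifelse(undef, "undefined", "ok"),
                    stringsAsFactors = FALSE)
  out[order(-out$abundance_to, out$sequence), , drop = FALSE]
}

#' Enrichment factor of a single species
#'
#' @inheritParams enrichment_factors
#' @param species sequence string.
#' @return one-row data.frame (see [enrichment_factors()]); requesting a
#'   species absent from the earlier round yields status "undefined" with a
#'   warning.
#' @export
enrichment_factor <- function(table, species, pool, round_to,
                              round_from = round_to - 1L) {
  efs <- enrichment_factors(table, pool, round_to, round_from)
  row <- efs[efs$sequence == species, , drop = FALSE]
  if (nrow(row) == 0L)
    row <- data.frame(sequence = species, abundance_from = 0,
                      abundance_to = 0, ef = NA_real_, status = "undefined",
                      stringsAsFactors = FALSE)
  if (row$status == "undefined")
    warning(sprintf("species absent from round %s: EF undefined", round_from))
  rownames(row) <- NULL
  row
}

#' Keep species enriched across consecutive rounds
#'
#' Applies the monotonic-EF filter: over three consecutive rounds r1 < r2 <
#' r3, a species survives iff both EFs (r1 to r2, r2 to r3) are defined and
#' >= threshold. The boundary is inclusive (EF = 1.0 passes at the default
#' threshold); species unseen in an earlier round have undefined EF and are
#' dropped.
#'
#' @param table a `count_table`.
#' @param pool pool label.
#' @param rounds three consecutive round numbers.
#' @param threshold minimum EF (default 1.0).
#' @return character vector of surviving sequences.
#' @export
filter_monotonic_enrichment <- function(table, pool, rounds, threshold = 1.0) {
  stopifnot(length(rounds) == 3L, all(diff(rounds) == 1L))
  ef1 <- enrichment_factors(table, pool, rounds[2L], rounds[1L])
  ef2 <- enrichment_factors(table, pool, rounds[3L], rounds[2L])
  ok1 <- ef1$sequence[ef1$status == "ok" & !is.na(ef1$ef) & ef1$ef >= threshold]
  ok2 <- ef2$sequence[ef2$status == "ok" & !is.na(ef2$ef) & ef2$ef >= threshold]
  intersect(ok1, ok2)
}

#' Top-N species by abundance
#'
#' First `n` species in the deterministic ordering (count descending, ties
#' broken lexicographically by sequence). If the pool has fewer than `n`
#' species, all are returned with a warning and `attr(, "truncated")` set.
#'
#' @param table a `count_table`.
#' @param pool pool label.
#' @param round round number.
#' @param n number of species (default 20).
#' @return data.frame slice of the count table, ranked.
#' @export
top_species <- function(table, pool, round, n = 20L) {
  stopifnot(n >= 1L)
  df <- .ct_slice(table, pool, round)
  df <- df[order(-df$count, df$sequence), , drop = FALSE]
  truncated <- nrow(df) < n
  if (truncated)
    warning(sprintf("only %d species available (n = %d requested)",
                    nrow(df), n))
  out <- utils::head(df, n)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "truncated") <- truncated
  out
}

# ---- diversity profile ------------------------------------------------------

#' Copy-number diversity profile of a pool
#'
#' Splits a sequenced population into a singleton bin (species observed
#' exactly once) and copy-count bins; each bin reports its proportion of the
#' population (read-weighted) and its number of unique sequences. The
#' default edges give six multi-copy bins: \[2,10), \[10,1e2), ...,
#' \[1e5,Inf).
#'
#' @param table a `count_table`.
#' @param pool pool label.
#' @param round round number.
#' @param bin_edges strictly increasing edges; first edge must be 2.
#' @return data.frame with columns bin, lower, upper, proportion, n_unique.
#' @export
diversity_profile <- function(table, pool, round,
                              bin_edges = c(2, 10, 1e2, 1e3, 1e4, 1e5, Inf)) {
  stopifnot(bin_edges[1L] == 2, all(diff(bin_edges) > 0))
  df <- .ct_slice(table, pool, round)
  total <- sum(df$count)
  single <- df$count == 1
  lower <- bin_edges[-length(bin_edges)]
  upper <- bin_edges[-1L]
  bins <- data.frame(
    bin = c("singleton", sprintf("[%g,%g)", lower, upper)),
    lower = c(1, lower), upper = c(2, upper),
    stringsAsFactors = FALSE)
  idx <- findInterval(df$count, bin_edges)  # 0 = singleton
  prop <- c(sum(df$count[single]),
            vapply(seq_along(lower), function(k)
              sum(df$count[idx == k & !single]), numeric(1L))) / total
  uniq <- c(sum(single),
            vapply(seq_along(lower), function(k)
              sum(idx == k & !single), numeric(1L)))
  bins$proportion <- prop
  bins$n_unique <- as.integer(uniq)
  bins
}

# ---- motif and residue statistics -------------------------------------------

#' Abundance-weighted fraction of a pool matching a motif
#'
#' Sum of relative abundances over species that contain the motif
#' ([motif_match()] contains-semantics).
#'
#' @param table a `count_table`.
#' @param pattern a [motif_pattern()] or IUPAC string.
#' @param pool,round optional slice selectors; if omitted the table must
#'   already be a single (pool, round).
#' @return proportion in \[0, 1\].
#' @export
motif_fraction <- function(table, pattern, pool = NULL, round = NULL) {
  df <- if (is.null(pool)) table else .ct_slice(table, pool, round)
  sum(df$abundance[motif_match(df$sequence, pattern)])
}

#' Positional residue frequencies among top-ranked variants
#'
#' For protein 8-mers: per randomized position, the frequency of each
#' residue among the `top_k` most abundant variants, unweighted (each
#' variant counts once) or abundance-weighted.
#'
#' @param table a `count_table` of equal-length sequences.
#' @param pool,round slice selectors.
#' @param top_k number of top variants to examine (e.g. 20 or 1000).
#' @param weighted abundance-weighted if TRUE.
#' @return matrix \[residue, position\]; each column sums to 1.
#' @export
positional_residue_frequency <- function(table, pool, round, top_k = 20L,
                                         weighted = FALSE) {
  top <- top_species(table, pool, round, n = top_k)
  seqs <- top$sequence
  stopifnot(length(unique(nchar(seqs))) == 1L)
  L <- nchar(seqs[1L])
  m <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
              ncol = L, byrow = TRUE)
  w <- if (weighted) top$abundance / sum(top$abundance)
       else rep(1 / nrow(m), nrow(m))
  res <- sort(unique(as.vector(m)))
  freq <- vapply(seq_len(L), function(j)
    vapply(res, function(a) sum(w[m[, j] == a]), numeric(1L)),
    numeric(length(res)))
  dimnames(freq) <- list(res, paste0("pos", seq_len(L)))
  freq
}

#' Exhaustive k-mer consensus scan (extension)
#'
#' A helper for consensus discovery: abundance-weighted frequency of every
#' k-mer window across a pool, with single-position variant pairs collapsed
#' into IUPAC codes. This is a convenience extension of the package, not a
#' procedure taken from any particular published pipeline.
#'
#' @param table a `count_table` slice (single pool/round, or use selectors).
#' @param pool,round optional slice selectors.
#' @param k k-mer length(s), default 8:10.
#' @param top number of top k-mers to report per k.
#' @return data.frame with columns k, kmer, weight, collapsed IUPAC pattern.
#' @export
scan_kmer_consensus <- function(table, pool = NULL, round = NULL, k = 8:10,
                                top = 5L) {
  df <- if (is.null(pool)) table else .ct_slice(table, pool, round)
  out <- list()
  for (kk in k) {
    acc <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_len(nrow(df))) {
      s <- df$sequence[i]
      L <- nchar(s)
      if (L < kk) next
      wins <- unique(substring(s, 1:(L - kk + 1L), kk:L))
      for (w in wins) {
        prev <- acc[[w]]
        acc[[w]] <- if (is.null(prev)) df$abundance[i] else prev + df$abundance[i]
      }
    }
    kmers <- ls(acc)
    if (length(kmers) == 0L) next
    wts <- vapply(kmers, function(w) acc[[w]], numeric(1L))
    ord <- order(-wts, kmers)
    sel <- utils::head(ord, top)
    out[[as.character(kk)]] <- data.frame(
      k = kk, kmer = kmers[sel], weight = wts[sel],
      pattern = vapply(seq_along(sel), function(j)
        .collapse_iupac(kmers[sel[j]], kmers, wts), character(1L)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# merge a k-mer with any comparably weighted single-mismatch partner into an
# IUPAC degenerate pattern
.collapse_iupac <- function(kmer, kmers, wts, min_ratio = 0.25) {
  to_code <- c(AC = "M", AG = "R", AU = "W", CG = "S", CU = "Y", GU = "K")
  chars <- strsplit(kmer, "")[[1L]]
  w0 <- wts[kmer]
  for (j in seq_along(chars)) {
    for (b in setdiff(c("A", "C", "G", "U"), chars[j])) {
      alt <- chars
      alt[j] <- b
      alt <- paste(alt, collapse = "")
      if (!is.na(wts[alt]) && wts[alt] >= min_ratio * w0) {
        pair <- paste(sort(c(chars[j], b)), collapse = "")
        chars[j] <- to_code[pair]
      }
    }
  }
  paste(chars, collapse = "")
}
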