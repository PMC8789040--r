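# Re-selection deconvolution: a focused RNA library (the most abundant
# post-selection species plus labeled controls) is selected against each
# candidate protein individually; per-RNA enrichment factors are summarized
# over consensus-motif subsets and cognate / depleted / neutral calls are
# made from the subset medians.

#' Re-selection experiment container
#'
#' @param pre_table `count_table` of the focused library before selection.
#' @param post_tables named list of `count_table`s, one per protein arm.
#' @param control_ids sequences of labeled control RNAs (subset of the pre
#'   table); controls are excluded from motif subsets unless they match the
#'   motif themselves.
#' @return object of class `reselection_experiment`. Post-table species not
#'   present in the pre table are dropped with a warning (EF undefined).
#' @export
reselection_experiment <- function(pre_table, post_tables,
                                   control_ids = character()) {
  stopifnot(is.list(post_tables), !is.null(names(post_tables)),
            all(nzchar(names(post_tables))))
  if (any(pre_table$abundance <= 0))
    stop("pre-selection abundances must be > 0 for EF computation",
         call. = FALSE)
  pre_species <- pre_table$sequence
  arms <- names(post_tables)
  post_tables <- lapply(arms, function(p) {
    tab <- post_tables[[p]]
    extra <- setdiff(tab$sequence, pre_species)
    if (length(extra) > 0L) {
      warning(sprintf(
        "%d species in post table '%s' absent from pre table: excluded (EF undefined)",
        length(extra), p))
      tab <- tab[!tab$sequence %in% extra, , drop = FALSE]
      tab$abundance <- tab$count / sum(tab$count)
    }
    tab
  })
  names(post_tables) <- arms
  structure(list(pre_table = pre_table, post_tables = post_tables,
                 control_ids = control_ids),
            class = "reselection_experiment")
}

#' Per-RNA enrichment factors for one protein arm
#'
#' EF = abundance after selection against the named protein / abundance in
#' the pre-selection library. Species absent from the post table get EF 0.
#'
#' @param experiment a [reselection_experiment()].
#' @param protein_id name of a post-table arm.
#' @return named numeric vector of EFs over all pre-table species.
#' @export
reselection_ef <- function(experiment, protein_id) {
  stopifnot(inherits(experiment, "reselection_experiment"))
  if (!protein_id %in% names(experiment$post_tables))
    stop(sprintf("no post-selection table for protein '%s'", protein_id),
         call. = FALSE)
  pre <- experiment$pre_table
  post <- experiment$post_tables[[protein_id]]
  ab_post <- setNames(rep(0, nrow(pre)), pre$sequence)
  ab_post[post$sequence] <- post$abundance
  ab_post / setNames(pre$abundance, pre$sequence)
}

#' Box-plot statistics of an EF subset
#'
#' Median and quartiles by linear interpolation (`stats::quantile` type 7);
#' whiskers at 1.5 x IQR, clamped to the data range. An empty subset yields
#' an explicit empty-stats row (n = 0, all NA) rather than an error.
#'
#' @param efs named numeric vector (e.g. from [reselection_ef()]).
#' @param subset logical or character index selecting the subset; NULL = all.
#' @param label subset label carried into the output.
#' @param protein_id protein label carried into the output.
#' @return one-row data.frame: protein_id, subset, n, median, q1, q3,
#'   whisker_low, whisker_high.
#' @export
subset_box_stats <- function(efs, subset = NULL, label = "all",
                             protein_id = NA_character_) {
  x <- if (is.null(subset)) efs else efs[subset]
  x <- x[!is.na(x)]
  if (length(x) == 0L)
    return(data.frame(protein_id = protein_id, subset = label, n = 0L,
                      median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                      whisker_low = NA_real_, whisker_high = NA_real_,
                      stringsAsFactors = FALSE))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3L] - q[1L]
  data.frame(protein_id = protein_id, subset = label, n = length(x),
             median = q[2L], q1 = q[1L], q3 = q[3L],
             whisker_low = max(min(x), q[1L] - 1.5 * iqr),
             whisker_high = min(max(x), q[3L] + 1.5 * iqr),
             stringsAsFactors = FALSE)
}

#' Bootstrap confidence interval for a median
#'
#' Seeded percentile bootstrap; reported alongside subset medians because
#' box-plot "significance" judgments need an uncertainty measure, and no
#' named test is implied by the box plots themselves.
#'
#' @param x numeric vector.
#' @param n_boot resamples (default 10000).
#' @param conf confidence level.
#' @param seed integer seed.
#' @return named numeric: median, lower, upper.
#' @export
boot_median_ci <- function(x, n_boot = 10000L, conf = 0.95, seed = 1L) {
  x <- x[!is.na(x)]
  stopifnot(length(x) >= 1L)
  meds <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i)
      stats::median(x[sample.int(length(x), replace = TRUE)]), numeric(1L))
  })
  a <- (1 - conf) / 2
  ci <- stats::quantile(meds, c(a, 1 - a), names = FALSE)
  c(median = stats::median(x), lower = ci[1L], upper = ci[2L])
}

#' EF box statistics for motif subsets across all protein arms
#'
#' Convenience wrapper: for each protein arm and each named motif, computes
#' [subset_box_stats()] over the RNAs containing the motif. Control RNAs are
#' excluded from motif subsets unless they match the motif.
#'
#' @param experiment a [reselection_experiment()].
#' @param motifs named list of [motif_pattern()]s (or IUPAC strings).
#' @return data.frame of box statistics, one row per (protein, motif).
#' @export
reselection_box_stats <- function(experiment, motifs) {
  stopifnot(length(motifs) >= 1L, !is.null(names(motifs)))
  pre <- experiment$pre_table
  is_control <- pre$sequence %in% experiment$control_ids
  rows <- list()
  for (p in names(experiment$post_tables)) {
    efs <- reselection_ef(experiment, p)
    for (m in names(motifs)) {
      in_subset <- motif_match(pre$sequence, motifs[[m]]) & !is_control
      rows[[paste(p, m)]] <- subset_box_stats(efs, in_subset, label = m,
                                              protein_id = p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call cognate / depleted / neutral pairs from subset medians
#'
#' A (protein, subset) pair is called cognate when the subset median EF is
#' >= `enriched_median_min` (boundary inclusive), depleted when it is <
#' `depleted_ef_max`, and neutral otherwise. Two pairs (subset A, protein A)
#' and (subset B, protein B) are proposed as mutually orthogonal when each
#' protein is cognate for its own subset and depleted for the other's.
#'
#' @param stats data.frame from [reselection_box_stats()] (needs columns
#'   protein_id, subset, median).
#' @param enriched_median_min cognate threshold (default 1.0).
#' @param depleted_ef_max depletion threshold (default 0.5).
#' @return list with `calls` (stats plus a `call` column, thresholds in
#'   attributes) and `orthogonal_pairs` (data.frame of proposed pairs).
#' @export
call_pairs <- function(stats, enriched_median_min = 1.0,
                       depleted_ef_max = 0.5) {
  stopifnot(all(c("protein_id", "subset", "median") %in% names(stats)))
  call <- ifelse(is.na(stats$median), "neutral",
          ifelse(stats$median >= enriched_median_min, "cognate",
          ifelse(stats$median < depleted_ef_max, "depleted", "neutral")))
  calls <- cbind(stats, call = call, stringsAsFactors = FALSE)
  attr(calls, "enriched_median_min") <- enriched_median_min
  attr(calls, "depleted_ef_max") <- depleted_ef_max
  subsets <- unique(calls$subset)
  pairs <- list()
  if (length(subsets) >= 2L) {
    get_call <- function(p, s)
      calls$call[calls$protein_id == p & calls$subset == s][1L]
    combs <- utils::combn(subsets, 2L)
    for (k in seq_len(ncol(combs))) {
      sA <- combs[1L, k]; sB <- combs[2L, k]
      pA <- unique(calls$protein_id[calls$subset == sA & calls$call == "cognate"])
      pB <- unique(calls$protein_id[calls$subset == sB & calls$call == "cognate"])
      for (a in pA) for (b in pB) {
        if (a == b) next
        if (identical(get_call(a, sB), "depleted") &&
            identical(get_call(b, sA), "depleted"))
          pairs[[length(pairs) + 1L]] <- data.frame(
            subset_a = sA, protein_a = a, subset_b = sB, protein_b = b,
            stringsAsFactors = FALSE)
      }
    }
  }
  orth <- if (length(pairs) > 0L) do.call(rbind, pairs)
          else data.frame(subset_a = character(), protein_a = character(),
                          subset_b = character(), protein_b = character(),
                          stringsAsFactors = FALSE)
  list(calls = calls, orthogonal_pairs = orth)
}

#' Simulate a single-protein re-selection arm
#'
#' One selection round of a focused RNA pool against a single recombinant
#' protein immobilized on beads (monovalent: no avidity), using the same
#' capture model as [simulate_round()] step 1.
#'
#' @param pre_pool `selex_pool` of the focused RNA library.
#' @param protein_id the immobilized protein's species id.
#' @param landscape a [kd_landscape()].
#' @param cfg a [round_config()] (use `avidity_copies = 1` for recombinant
#'   protein).
#' @param mode "stochastic" or "expectation".
#' @param seed optional seed.
#' @return post-selection `selex_pool`.
#' @export
simulate_reselection <- function(pre_pool, protein_id, landscape, cfg,
                                 mode = c("stochastic", "expectation"),
                                 seed = NULL) {
  mode <- match.arg(mode)
  bead_pool <- new_pool(protein_id, "protein", "", 1)
  run <- function() {
    p <- capture_probability(pre_pool$species_id, bead_pool, landscape, cfg)
    post <- .thin_pool(pre_pool, p, mode)
    .bottleneck_pool(post, cfg$bottleneck_rna, mode)
  }
  if (mode == "stochastic" && !is.null(seed)) withr::with_seed(seed, run())
  else run()
}
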