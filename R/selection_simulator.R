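# Stochastic simulator of library-vs-library selection campaigns.
#
# The physical model: phage-displayed proteins are immobilized on beads and
# incubated with the RNA pool (step 1); RNA-phage complexes are then captured
# on docking-oligo beads (step 2); both pools are eluted, amplified and
# re-used. Capture probabilities are driven by single-site equilibrium
# occupancy against the abundance-weighted partner mixture at one effective
# concentration, with avidity and urea acting as phenomenological multipliers
# on the apparent K_D. Everything is seeded and has an expectation mode that
# replaces every random draw with its mean, so closed-form checks are exact.

#' Equilibrium bound fraction of a 1:1 interaction
#'
#' @param kd dissociation constant (M), > 0 (Inf = no binding).
#' @param conc free partner concentration (M), >= 0.
#' @return `conc / (conc + kd)` in \[0, 1\].
#' @export
equilibrium_bound_fraction <- function(kd, conc) {
  stopifnot(all(kd > 0), all(conc >= 0))
  n <- max(length(kd), length(conc))
  kd <- rep_len(kd, n)
  conc <- rep_len(conc, n)
  out <- numeric(n)
  pos <- conc > 0 & is.finite(kd)
  out[pos] <- conc[pos] / (conc[pos] + kd[pos])
  out
}

#' Apparent K_D under multivalent display and denaturant
#'
#' Roughly ten protein copies are displayed per virion, which increases
#' apparent affinity to immobilized partners; urea in the binding/washing
#' buffer weakens it. Both are modeled as multiplicative factors on K_D:
#' `kd / copies^avidity_exponent`, times `urea_penalty` when urea is on.
#' Monotone decreasing in copies, increasing with urea.
#'
#' @param kd intrinsic K_D (M).
#' @param copies displayed copies per particle (>= 1).
#' @param urea logical; denaturant present.
#' @param avidity_exponent,urea_penalty phenomenological factors.
#' @return apparent K_D (M).
#' @export
avidity_adjusted_kd <- function(kd, copies = 10, urea = FALSE,
                                avidity_exponent = 1, urea_penalty = 5) {
  stopifnot(all(kd > 0), copies >= 1)
  kd / copies^avidity_exponent * ifelse(urea, urea_penalty, 1)
}

#' Per-round selection configuration
#'
#' Stringency knobs for one selection round. Probabilities are in \[0,1\];
#' `wash_loss` applies per wash to the nonspecific background term only
#' (specifically bound complexes persist according to their bound fraction).
#' `rnaseh_specificity` scales step-2 nonspecific phage retention down,
#' modeling RNase H elution which releases only genuine RNA-DNA hybrids.
#'
#' @param rna_input,phage_input input molecules / PFU.
#' @param binding_time incubation time (s); recorded metadata (occupancy is
#'   modeled at equilibrium).
#' @param n_washes integer wash count.
#' @param urea logical; 0.5 M urea stringency.
#' @param negative_selection logical; pre-deplete flagged bead/phage binders.
#' @param effective_protein_conc,effective_rna_conc effective binding-partner
#'   concentrations (M) seen in steps 1 and 2.
#' @param avidity_copies displayed copies per virion.
#' @param capture_eff_step1,capture_eff_step2 capture efficiencies.
#' @param background_step1,background_step2 nonspecific retention
#'   probabilities before washes.
#' @param wash_loss per-wash background survival complement.
#' @param rnaseh_specificity background-reduction factor for step 2.
#' @param neg_selection_depletion fraction of flagged binders removed when
#'   negative selection is on.
#' @param bottleneck_rna,bottleneck_phage maximum molecules carried forward.
#' @param avidity_exponent,urea_penalty see [avidity_adjusted_kd()].
#' @param seed optional per-round seed.
#' @return object of class `round_config`.
#' @export
round_config <- function(rna_input = 1e12, phage_input = 1e10,
                         binding_time = 600, n_washes = 3L, urea = FALSE,
                         negative_selection = FALSE,
                         effective_protein_conc = 1e-9,
                         effective_rna_conc = 1e-9,
                         avidity_copies = 10L,
                         capture_eff_step1 = 0.5, capture_eff_step2 = 0.5,
                         background_step1 = 1e-4, background_step2 = 1e-4,
                         wash_loss = 0.5, rnaseh_specificity = 0.1,
                         neg_selection_depletion = 0.99,
                         bottleneck_rna = 1e6, bottleneck_phage = 1e6,
                         avidity_exponent = 1, urea_penalty = 5,
                         seed = NULL) {
  cfg <- list(rna_input = rna_input, phage_input = phage_input,
              binding_time = binding_time, n_washes = as.integer(n_washes),
              urea = isTRUE(urea), negative_selection = isTRUE(negative_selection),
              effective_protein_conc = effective_protein_conc,
              effective_rna_conc = effective_rna_conc,
              avidity_copies = as.integer(avidity_copies),
              capture_eff_step1 = capture_eff_step1,
              capture_eff_step2 = capture_eff_step2,
              background_step1 = background_step1,
              background_step2 = background_step2,
              wash_loss = wash_loss, rnaseh_specificity = rnaseh_specificity,
              neg_selection_depletion = neg_selection_depletion,
              bottleneck_rna = bottleneck_rna,
              bottleneck_phage = bottleneck_phage,
              avidity_exponent = avidity_exponent, urea_penalty = urea_penalty,
              seed = seed)
  probs <- c(cfg$capture_eff_step1, cfg$capture_eff_step2,
             cfg$background_step1, cfg$background_step2, cfg$wash_loss,
             cfg$rnaseh_specificity, cfg$neg_selection_depletion)
  stopifnot(all(probs >= 0 & probs <= 1), cfg$n_washes >= 0L,
            cfg$avidity_copies >= 1L, cfg$rna_input >= 0, cfg$phage_input >= 0,
            cfg$bottleneck_rna >= 0, cfg$bottleneck_phage >= 0)
  class(cfg) <- "round_config"
  cfg
}

#' Default six-round stringency schedule
#'
#' Encodes what the campaign design states: negative selection in rounds 1-2
#' (to remove bead/phage binders), 0.5 M urea in rounds 5-6, monotonically
#' decreasing input amounts and increasing wash counts. Per-round numeric
#' values in between are package defaults, overridable via `...`.
#'
#' @param n_rounds number of rounds (default 6).
#' @param ... overrides applied to every round's [round_config()] call.
#' @return list of `round_config` objects.
#' @export
default_campaign_schedule <- function(n_rounds = 6L, ...) {
  n_rounds <- as.integer(n_rounds)
  stopifnot(n_rounds >= 1L)
  washes <- pmin(3L + 1L * (seq_len(n_rounds) - 1L), 8L)
  rna_in <- 1e12 / 2^(seq_len(n_rounds) - 1L)
  phage_in <- 1e10 / 2^(seq_len(n_rounds) - 1L)
  lapply(seq_len(n_rounds), function(r)
    round_config(rna_input = rna_in[r], phage_input = phage_in[r],
                 n_washes = washes[r],
                 negative_selection = r <= 2L,
                 urea = r >= n_rounds - 1L && n_rounds >= 5L, ...))
}

# ---- pools and K_D landscapes ----------------------------------------------

#' Construct a species pool
#'
#' @param species_id unique species identifiers.
#' @param kind "RNA" or "protein".
#' @param sequence variable region (RNA alphabet) or randomized 8-mer (aa).
#' @param count nonnegative counts (molecules / PFU); real-valued counts are
#'   permitted in expectation mode.
#' @param read_template DNA template emitted by [generate_reads()].
#' @param bead_binder logical; species depleted by negative selection.
#' @return data.frame of class `selex_pool`.
#' @export
new_pool <- function(species_id, kind, sequence, count,
                     read_template = NA_character_, bead_binder = FALSE) {
  stopifnot(!anyDuplicated(species_id), all(count >= 0),
            kind %in% c("RNA", "protein"))
  df <- data.frame(species_id = as.character(species_id), kind = kind,
                   sequence = as.character(sequence), count = as.numeric(count),
                   read_template = read_template, bead_binder = bead_binder,
                   stringsAsFactors = FALSE)
  class(df) <- c("selex_pool", "data.frame")
  df
}

#' RNA pool from variable-region sequences
#'
#' Read templates are the DNA of 5' flank + variable region + 3' flank.
#'
#' @param sequences variable regions (RNA alphabet; T read as U).
#' @param counts per-species counts (recycled).
#' @param design an [rna_library_design()].
#' @param ids optional species ids (default R1, R2, ...).
#' @param bead_binder logical vector flagging negative-selection targets.
#' @return a `selex_pool`.
#' @export
rna_pool <- function(sequences, counts, design = hairpin_n20_design(),
                     ids = NULL, bead_binder = FALSE) {
  seqs <- canonicalize_rna(sequences)
  .validate_rna(seqs)
  stopifnot(all(nchar(seqs) == design$variable_length))
  if (is.null(ids)) ids <- paste0("R", seq_along(seqs))
  rna <- paste0(design$fixed_5p, seqs, design$fixed_3p)
  tmpl <- chartr("U", "T", rna)
  new_pool(ids, "RNA", seqs, rep_len(counts, length(seqs)), tmpl,
           rep_len(bead_binder, length(seqs)))
}

#' Protein pool from randomized 8-mers
#'
#' Read templates are in-frame DNA covering the mutated scaffold region,
#' with one NNK-consistent codon choice per species drawn at `seed`.
#'
#' @param aa_seqs 8-mers over the randomized positions.
#' @param counts per-species counts (recycled).
#' @param design a [protein_library_design()].
#' @param ids optional species ids (default P1, P2, ...).
#' @param seed seed for the codon choice.
#' @param bead_binder logical vector flagging negative-selection targets.
#' @return a `selex_pool`.
#' @export
protein_pool <- function(aa_seqs, counts, design = l7ae_scaffold_design(),
                         ids = NULL, seed = 1L, bead_binder = FALSE) {
  if (is.null(ids)) ids <- paste0("P", seq_along(aa_seqs))
  tmpl <- encode_variable_region(aa_seqs, design, seed = seed)
  new_pool(ids, "protein", aa_seqs, rep_len(counts, length(aa_seqs)), tmpl,
           rep_len(bead_binder, length(aa_seqs)))
}

#' Sparse kinetic landscape of specific RNA-protein interactions
#'
#' Pairs absent from the landscape have no specific binding (K_D = Inf);
#' present pairs carry strictly positive rates with K_D = k_off / k_on.
#'
#' @param rna_id,protein_id species ids of interacting pairs.
#' @param k_on association rate constants (1/(M s)).
#' @param k_off dissociation rate constants (1/s).
#' @return data.frame of class `kd_landscape` with a derived `kd` column.
#' @export
kd_landscape <- function(rna_id, protein_id, k_on, k_off) {
  stopifnot(all(k_on > 0), all(k_off > 0))
  df <- data.frame(rna_id = as.character(rna_id),
                   protein_id = as.character(protein_id),
                   k_on = k_on, k_off = k_off, kd = k_off / k_on,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("rna_id", "protein_id")]))
    stop("duplicate (rna_id, protein_id) pair in landscape", call. = FALSE)
  class(df) <- c("kd_landscape", "data.frame")
  df
}

# ---- capture probabilities --------------------------------------------------

# abundance-weighted specific bound fraction of each `ids` member against the
# partner pool, at effective concentration `conc`, with avidity/urea applied
.mixture_bound_fraction <- function(ids, id_col, partner_col, partner_pool,
                                    landscape, conc, cfg) {
  b <- setNames(numeric(length(ids)), ids)
  tot <- sum(partner_pool$count)
  if (tot <= 0 || nrow(landscape) == 0L) return(b)
  w <- setNames(partner_pool$count / tot, partner_pool$species_id)
  l <- landscape[landscape[[id_col]] %in% ids &
                   landscape[[partner_col]] %in% names(w), , drop = FALSE]
  if (nrow(l) == 0L) return(b)
  kd_app <- avidity_adjusted_kd(l$kd, copies = cfg$avidity_copies,
                                urea = cfg$urea,
                                avidity_exponent = cfg$avidity_exponent,
                                urea_penalty = cfg$urea_penalty)
  contrib <- w[l[[partner_col]]] * equilibrium_bound_fraction(kd_app, conc)
  agg <- tapply(contrib, l[[id_col]], sum)
  b[names(agg)] <- agg
  pmin(b, 1)
}

#' Probability that an RNA survives step-1 capture
#'
#' `p = capture_eff_step1 * (abundance-weighted bound fraction against the
#' bead-immobilized protein mixture) + background_step1 * (1 - wash_loss)^n_washes`.
#' The specific term uses avidity/urea-adjusted K_Ds at the round's effective
#' protein concentration; washes erode only the nonspecific background.
#' Urea penalizes the background by the same factor as the specific K_D
#' (denaturant suppresses nonspecific sticking at least as strongly as
#' specific binding), which makes raising stringency never decrease the
#' cognate pair's expected enrichment.
#'
#' @param rna_ids RNA species ids to evaluate (must exist if a landscape
#'   entry references them).
#' @param phage_pool the protein `selex_pool` on the beads.
#' @param landscape a [kd_landscape()].
#' @param cfg a [round_config()].
#' @return named vector of capture probabilities.
#' @export
capture_probability <- function(rna_ids, phage_pool, landscape, cfg) {
  stopifnot(inherits(cfg, "round_config"))
  if (anyNA(rna_ids) || any(!nzchar(rna_ids)))
    stop("unknown RNA species id (NA or empty)", call. = FALSE)
  spec <- .mixture_bound_fraction(rna_ids, "rna_id", "protein_id", phage_pool,
                                  landscape, cfg$effective_protein_conc, cfg)
  bg <- cfg$background_step1 * (1 - cfg$wash_loss)^cfg$n_washes
  if (cfg$urea) bg <- bg / cfg$urea_penalty
  pmin(cfg$capture_eff_step1 * spec + bg, 1)
}

# step-2 retention probability for phage, given the captured RNA mixture
.phage_capture_probability <- function(protein_ids, captured_rna_pool,
                                       landscape, cfg) {
  b <- .mixture_bound_fraction(protein_ids, "protein_id", "rna_id",
                               captured_rna_pool, landscape,
                               cfg$effective_rna_conc, cfg)
  bg <- cfg$background_step2 * cfg$rnaseh_specificity
  if (cfg$urea) bg <- bg / cfg$urea_penalty
  pmin(cfg$capture_eff_step2 * b + bg * (1 - b), 1)
}

# rbinom that stays exact for small sizes and switches to a normal
# approximation when size exceeds the integer range rbinom can return
.rbinom_safe <- function(size, prob) {
  out <- numeric(length(size))
  big <- size * prob > 1e8 | size > 2e9
  if (any(!big))
    out[!big] <- stats::rbinom(sum(!big), size[!big], prob[!big])
  if (any(big)) {
    m <- size[big] * prob[big]
    s <- sqrt(size[big] * prob[big] * (1 - prob[big]))
    out[big] <- pmax(0, round(stats::rnorm(sum(big), m, s)))
  }
  out
}

.thin_pool <- function(pool, p, mode) {
  if (mode == "expectation") pool$count <- pool$count * p
  else pool$count <- .rbinom_safe(pool$count, p)
  pool
}

.bottleneck_pool <- function(pool, limit, mode) {
  tot <- sum(pool$count)
  if (tot <= limit || limit <= 0) return(pool)
  if (mode == "expectation") {
    pool$count <- pool$count * limit / tot
  } else {
    keep <- pool$count > 0
    draw <- stats::rmultinom(1L, size = limit, prob = pool$count[keep])[, 1L]
    pool$count[keep] <- draw
  }
  pool
}

#' Simulate one two-step selection round
#'
#' Step 1 retains each RNA molecule independently with its
#' [capture_probability()]; step 2 retains each phage with probability
#' `capture_eff_step2 * b + background_step2 * rnaseh_specificity * (1 - b)`,
#' where `b` is its bound fraction against the captured RNA mixture. Rounds
#' with negative selection first deplete species flagged `bead_binder`.
#' Counts are binomially thinned, then multinomially bottlenecked to the
#' configured carrying capacities. Expectation mode replaces every draw by
#' its mean (real-valued counts), which makes mixture-enrichment arithmetic
#' exact. A fully empty post-selection pool is reported as a selection crash
#' (`crashed = TRUE`), not as an error.
#'
#' @param rna_pool,phage_pool nonempty `selex_pool`s.
#' @param landscape a [kd_landscape()].
#' @param cfg a [round_config()].
#' @param mode "stochastic" or "expectation".
#' @param seed seed for stochastic mode (default `cfg$seed`).
#' @return list with elements `rna`, `phage` (captured pools), `crashed`,
#'   `crashed_pool`, and a `log` of totals and mean capture probabilities.
#' @export
simulate_round <- function(rna_pool, phage_pool, landscape, cfg,
                           mode = c("stochastic", "expectation"),
                           seed = cfg$seed) {
  mode <- match.arg(mode)
  stopifnot(nrow(rna_pool) > 0L, nrow(phage_pool) > 0L,
            sum(rna_pool$count) > 0, sum(phage_pool$count) > 0)
  run <- function() {
    rp <- rna_pool; pp <- phage_pool
    if (cfg$negative_selection) {
      rp <- .thin_pool(rp, ifelse(rp$bead_binder,
                                  1 - cfg$neg_selection_depletion, 1), mode)
      pp <- .thin_pool(pp, ifelse(pp$bead_binder,
                                  1 - cfg$neg_selection_depletion, 1), mode)
    }
    p_rna <- capture_probability(rp$species_id, pp, landscape, cfg)
    rp <- .thin_pool(rp, p_rna, mode)
    rp <- .bottleneck_pool(rp, cfg$bottleneck_rna, mode)
    p_phage <- .phage_capture_probability(pp$species_id, rp, landscape, cfg)
    pp <- .thin_pool(pp, p_phage, mode)
    pp <- .bottleneck_pool(pp, cfg$bottleneck_phage, mode)
    crashed_pool <- c("RNA", "phage")[c(sum(rp$count) == 0, sum(pp$count) == 0)]
    list(rna = rp, phage = pp,
         crashed = length(crashed_pool) > 0L,
         crashed_pool = crashed_pool,
         log = list(rna_captured = sum(rp$count),
                    phage_captured = sum(pp$count),
                    mean_p_rna = mean(p_rna), mean_p_phage = mean(p_phage)))
  }
  if (mode == "stochastic" && !is.null(seed)) withr::with_seed(seed, run())
  else run()
}

#' Amplify a pool to a target total with lognormal amplification bias
#'
#' Each surviving species is scaled to the target total; per-species
#' amplification bias is lognormal with the given sd on the log scale
#' (mean-one, so relative abundances are preserved in expectation; sd 0 gives
#' exact proportional scaling). Non-integer stochastic counts are rounded
#' stochastically (floor + Bernoulli on the fraction).
#'
#' @param pool nonempty `selex_pool`.
#' @param target_total total molecules after amplification.
#' @param amplification_noise_sd lognormal sd (log scale).
#' @param seed optional seed.
#' @param mode "stochastic" or "expectation".
#' @return amplified `selex_pool`.
#' @export
amplify <- function(pool, target_total, amplification_noise_sd = 0,
                    seed = NULL, mode = c("stochastic", "expectation")) {
  mode <- match.arg(mode)
  stopifnot(sum(pool$count) > 0, target_total > 0)
  run <- function() {
    w <- pool$count
    if (mode == "stochastic" && amplification_noise_sd > 0) {
      keep <- w > 0
      bias <- exp(stats::rnorm(sum(keep), -amplification_noise_sd^2 / 2,
                               amplification_noise_sd))
      w[keep] <- w[keep] * bias
    }
    scaled <- w / sum(w) * target_total
    if (mode == "stochastic") {
      fl <- floor(scaled)
      frac <- scaled - fl
      scaled <- fl + stats::rbinom(length(scaled), 1L, frac)
    }
    pool$count <- scaled
    pool
  }
  if (mode == "stochastic" && !is.null(seed)) withr::with_seed(seed, run())
  else run()
}

# ---- sequencing-read generation ---------------------------------------------

#' Generate FASTQ-style reads from a pool
#'
#' Templates are drawn multinomially by abundance; independent per-base
#' substitution errors are applied; the barcode is prepended; qualities are a
#' constant "I" string. Deterministic given the seed.
#'
#' @param pool a `selex_pool` with read templates.
#' @param n_reads number of reads (>= 0).
#' @param per_base_error_rate substitution probability per base.
#' @param barcode DNA barcode prepended to every read ("" for none).
#' @param seed optional seed.
#' @return data.frame with columns id, sequence, quality (0 rows if
#'   `n_reads` is 0).
#' @export
generate_reads <- function(pool, n_reads, per_base_error_rate = 0,
                           barcode = "", seed = NULL) {
  stopifnot(n_reads >= 0, per_base_error_rate >= 0, per_base_error_rate < 1)
  if (n_reads == 0)
    return(data.frame(id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  stopifnot(sum(pool$count) > 0, !anyNA(pool$read_template))
  run <- function() {
    idx <- sample.int(nrow(pool), n_reads, replace = TRUE, prob = pool$count)
    reads <- pool$read_template[idx]
    if (per_base_error_rate > 0) {
      len <- nchar(reads)
      n_err <- stats::rbinom(n_reads, len, per_base_error_rate)
      hit <- which(n_err > 0L)
      bases <- c("A", "C", "G", "T")
      for (i in hit) {
        pos <- sample.int(len[i], n_err[i])
        for (p in pos) {
          old <- substr(reads[i], p, p)
          substr(reads[i], p, p) <- sample(setdiff(bases, old), 1L)
        }
      }
    }
    data.frame(id = sprintf("read_%07d", seq_len(n_reads)),
               sequence = paste0(barcode, reads),
               quality = strrep("I", nchar(barcode) + nchar(reads)),
               stringsAsFactors = FALSE)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# ---- campaigns --------------------------------------------------------------

#' Campaign configuration
#'
#' @param rna_pool,phage_pool initial pools.
#' @param landscape a [kd_landscape()].
#' @param schedule list of [round_config()]s, one per round.
#' @param n_reads reads generated per pool per round (0 = none).
#' @param per_base_error_rate sequencing substitution rate.
#' @param amplification_noise_sd lognormal amplification bias sd.
#' @param seed master seed; per-round, per-stage seeds are derived from it
#'   deterministically (see [stage_seed()]).
#' @return object of class `campaign_config`.
#' @export
campaign_config <- function(rna_pool, phage_pool, landscape, schedule,
                            n_reads = 0L, per_base_error_rate = 1e-3,
                            amplification_noise_sd = 0.1, seed = 1L) {
  stopifnot(length(schedule) >= 1L,
            all(vapply(schedule, inherits, logical(1L), "round_config")))
  structure(list(rna_pool = rna_pool, phage_pool = phage_pool,
                 landscape = landscape, schedule = schedule,
                 n_reads = as.integer(n_reads),
                 per_base_error_rate = per_base_error_rate,
                 amplification_noise_sd = amplification_noise_sd,
                 seed = as.integer(seed)),
            class = "campaign_config")
}

#' Derive a per-stage seed from a master seed
#'
#' One master seed fans out to independent per-round, per-stage streams via
#' `(seed + 7919 * round + offset) mod (2^31 - 1)`, so any stage can be
#' re-run in isolation.
#'
#' @param seed master integer seed.
#' @param round round index (0 = initial pools).
#' @param stage offset distinguishing stages within a round.
#' @return integer seed below 2^31.
#' @export
stage_seed <- function(seed, round, stage = 0L) {
  as.integer((as.numeric(seed) + 7919 * round + 131 * stage) %% 2147483647)
}

#' Simulate a multi-round selection campaign
#'
#' Chains [simulate_round()] and [amplify()] over the schedule. Reads are
#' generated for the initial pools (round 0) and after each round's
#' amplification. The landscape (the planted truth) is returned alongside
#' the outputs so parameter-recovery analyses can compare against it. A
#' selection crash stops the campaign and records the crashing round.
#'
#' @param campaign a [campaign_config()].
#' @param mode "stochastic" or "expectation".
#' @return list with `pools` (per-round list of `list(rna, phage)`, entry
#'   "0" = initial), `reads` (per-round `list(rna, phage)` read
#'   data.frames if `n_reads > 0`), `truth` (the landscape), `crashed_round`
#'   (NA if none) and per-round `logs`.
#' @export
simulate_campaign <- function(campaign, mode = c("stochastic", "expectation")) {
  mode <- match.arg(mode)
  stopifnot(inherits(campaign, "campaign_config"))
  rp <- campaign$rna_pool
  pp <- campaign$phage_pool
  pools <- list("0" = list(rna = rp, phage = pp))
  reads <- list()
  logs <- list()
  if (campaign$n_reads > 0L)
    reads[["0"]] <- list(
      rna = generate_reads(rp, campaign$n_reads, campaign$per_base_error_rate,
                           seed = stage_seed(campaign$seed, 0L, 3L)),
      phage = generate_reads(pp, campaign$n_reads, campaign$per_base_error_rate,
                             seed = stage_seed(campaign$seed, 0L, 4L)))
  crashed_round <- NA_integer_
  for (r in seq_along(campaign$schedule)) {
    cfg <- campaign$schedule[[r]]
    res <- simulate_round(rp, pp, campaign$landscape, cfg, mode = mode,
                          seed = stage_seed(campaign$seed, r, 0L))
    logs[[as.character(r)]] <- res$log
    if (res$crashed) {
      crashed_round <- r
      pools[[as.character(r)]] <- list(rna = res$rna, phage = res$phage)
      break
    }
    rp <- amplify(res$rna, cfg$rna_input, campaign$amplification_noise_sd,
                  seed = stage_seed(campaign$seed, r, 1L), mode = mode)
    pp <- amplify(res$phage, cfg$phage_input, campaign$amplification_noise_sd,
                  seed = stage_seed(campaign$seed, r, 2L), mode = mode)
    pools[[as.character(r)]] <- list(rna = rp, phage = pp)
    if (campaign$n_reads > 0L)
      reads[[as.character(r)]] <- list(
        rna = generate_reads(rp, campaign$n_reads,
                             campaign$per_base_error_rate,
                             seed = stage_seed(campaign$seed, r, 3L)),
        phage = generate_reads(pp, campaign$n_reads,
                               campaign$per_base_error_rate,
                               seed = stage_seed(campaign$seed, r, 4L)))
  }
  list(pools = pools, reads = reads, truth = campaign$landscape,
       crashed_round = crashed_round, logs = logs)
}
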