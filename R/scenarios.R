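# Synthetic study scenarios: reproducible generators for the simulated
# datasets the analysis modules are validated on. These are first-class,
# tested code — the scenario parameters ARE the study conditions (pool
# sizes, affinities, backgrounds), chosen to emulate a gradual multi-round
# co-enrichment rather than single-round fixation, and documented in the
# methods vignette.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

.random_loops <- function(n, len = 20L, avoid_motif = NULL) {
  bases <- c("A", "C", "G", "U")
  loops <- vapply(seq_len(n), function(i)
    paste(sample(bases, len, replace = TRUE), collapse = ""), character(1L))
  if (!is.null(avoid_motif)) {
    bad <- which(motif_match(loops, avoid_motif))
    while (length(bad) > 0L) {
      loops[bad] <- vapply(bad, function(i)
        paste(sample(bases, len, replace = TRUE), collapse = ""), character(1L))
      bad <- bad[motif_match(loops[bad], avoid_motif)]
    }
  }
  loops
}

.random_aa8 <- function(n) {
  p <- nnk_amino_acid_distribution()
  p <- p[names(p) != "*"]        # displayed (functional) variants only
  p <- p / sum(p)
  vapply(seq_len(n), function(i)
    paste(sample(names(p), 8L, replace = TRUE, prob = p), collapse = ""),
    character(1L))
}

#' Planted-pair library-vs-library campaign scenario
#'
#' Builds a complete seeded campaign with one planted cognate RNA-protein
#' pair: the planted RNA loop carries a consensus motif, the planted protein
#' binds every motif-bearing RNA at the planted (picomolar) affinity, and
#' every other protein is given one weak "decoy" RNA binder at the off-target
#' affinity floor (every phage-display hit binds something weakly). All other
#' combinations have no specific binding. Default affinities: planted pair
#' K_D = 10 pM (k_on 1e7, k_off 1e-4), decoys K_D = 1 uM (k_on 1e5, k_off
#' 0.1). The stringency schedule uses moderate backgrounds so enrichment is
#' gradual over the rounds instead of fixating in one.
#'
#' @param seed master seed.
#' @param n_rna,n_protein library sizes (default 1e4 RNA x 100 proteins).
#' @param n_rounds selection rounds (default 3).
#' @param n_reads sequencing reads per pool per round (default 1e5).
#' @param motif planted consensus motif (IUPAC string).
#' @param per_base_error_rate sequencing substitution rate.
#' @return list: `campaign` (a [campaign_config()]), `motif`,
#'   `planted` (list with rna_id, loop, protein_id, aa8), `decoys` (named
#'   character: protein_id -> decoy loop), `designs`.
#' @export
planted_pair_scenario <- function(seed = 1L, n_rna = 1e4, n_protein = 100L,
                                  n_rounds = 3L, n_reads = 1e5,
                                  motif = "UUGUGACGC",
                                  per_base_error_rate = 1e-3) {
  design_r <- hairpin_n20_design()
  design_p <- l7ae_scaffold_design()
  withr::with_seed(stage_seed(seed, 0L, 9L), {
    loops <- .random_loops(n_rna, design_r$variable_length,
                           avoid_motif = motif)
    planted_loop <- paste0("AUCGA", canonicalize_rna(motif), "GCAAUC")
    stopifnot(nchar(planted_loop) == design_r$variable_length)
    loops[1L] <- planted_loop
    aa8 <- .random_aa8(n_protein)
    aa8[1L] <- "SKEGWRIA"   # planted variant; W89/R90-type loop residues
    rna0 <- rna_pool(loops, 1e8, design_r)
    prot0 <- protein_pool(aa8, 1e8, design_p, seed = stage_seed(seed, 0L, 10L))
    # motif-determined cognate binding + one weak decoy per other protein
    motif_rna <- rna0$species_id[motif_match(rna0$sequence, motif)]
    decoy_rna <- paste0("R", 1L + seq_len(n_protein - 1L))
    decoy_prot <- paste0("P", 1L + seq_len(n_protein - 1L))
    landscape <- kd_landscape(
      rna_id = c(motif_rna, decoy_rna),
      protein_id = c(rep("P1", length(motif_rna)), decoy_prot),
      k_on = c(rep(1e7, length(motif_rna)), rep(1e5, n_protein - 1L)),
      k_off = c(rep(1e-4, length(motif_rna)), rep(0.1, n_protein - 1L)))
    schedule <- default_campaign_schedule(
      n_rounds, background_step1 = 3e-3, background_step2 = 1e-3,
      rnaseh_specificity = 0.3)
    campaign <- campaign_config(rna0, prot0, landscape, schedule,
                                n_reads = n_reads,
                                per_base_error_rate = per_base_error_rate,
                                amplification_noise_sd = 0.1, seed = seed)
    list(campaign = campaign, motif = motif,
         planted = list(rna_id = "R1", loop = planted_loop,
                        protein_id = "P1", aa8 = aa8[1L]),
         decoys = stats::setNames(rna0$sequence[match(decoy_rna,
                                                      rna0$species_id)],
                                  decoy_prot),
         designs = list(rna = design_r, protein = design_p))
  })
}

#' Focused re-selection experiment from a campaign's final RNA table
#'
#' Mirrors the deconvolution stage: the most abundant post-selection RNA
#' loops (plus the decoy loops of the tested proteins, spiked in as labeled
#' controls) are synthesized at uniform abundance and selected against each
#' tested protein individually on monovalent beads. Binding in the focused
#' round is motif-determined — every library member containing the scenario
#' motif binds the planted protein at the planted affinity; each decoy binds
#' only its own protein at the off-target affinity.
#'
#' @param rna_table `count_table` of RNA rounds from the analyzed campaign.
#' @param scenario the [planted_pair_scenario()] that produced the campaign.
#' @param arms protein ids to test (must include the planted protein to
#'   reproduce the cognate call).
#' @param round round whose abundances define the focused library.
#' @param n_top focused library size before spiking controls (default 2000).
#' @param copies_per_species synthesis scale per library member.
#' @param cfg re-selection [round_config()]; the default uses monovalent
#'   protein (no avidity) at 1 uM effective concentration with stringent
#'   washing.
#' @param seed seed for the stochastic arms.
#' @return list: `experiment` (a [reselection_experiment()]), `subset_motif`,
#'   `landscape`, `pre_pool`.
#' @export
reselection_from_campaign <- function(rna_table, scenario, arms,
                                      round, n_top = 2000L,
                                      copies_per_species = 1e6,
                                      cfg = NULL, seed = 1L) {
  stopifnot(scenario$planted$protein_id %in% arms)
  if (is.null(cfg))
    cfg <- round_config(n_washes = 5L, avidity_copies = 1L,
                        capture_eff_step1 = 0.8, background_step1 = 1e-3,
                        effective_protein_conc = 1e-6,
                        bottleneck_rna = 1e9)
  slice <- rna_table[rna_table$pool == unique(rna_table$pool)[1L] &
                       rna_table$round == round, , drop = FALSE]
  slice <- slice[order(-slice$count, slice$sequence), , drop = FALSE]
  top_loops <- utils::head(slice$sequence, n_top)
  controls <- scenario$decoys[names(scenario$decoys) %in% arms]
  library_loops <- union(top_loops, unname(controls))
  pre_pool <- rna_pool(library_loops, copies_per_species,
                       scenario$designs$rna,
                       ids = paste0("F", seq_along(library_loops)))
  # motif-determined cognate binding; decoys bind their own protein only
  motif_ids <- pre_pool$species_id[motif_match(pre_pool$sequence,
                                               scenario$motif)]
  decoy_ids <- pre_pool$species_id[match(unname(controls), pre_pool$sequence)]
  landscape <- kd_landscape(
    rna_id = c(motif_ids, decoy_ids),
    protein_id = c(rep(scenario$planted$protein_id, length(motif_ids)),
                   names(controls)),
    k_on = c(rep(1e7, length(motif_ids)), rep(1e5, length(decoy_ids))),
    k_off = c(rep(1e-4, length(motif_ids)), rep(0.1, length(decoy_ids))))
  pre_table <- pool_count_table(pre_pool, "pre", 0L)
  post <- lapply(seq_along(arms), function(i) {
    pool_i <- simulate_reselection(pre_pool, arms[i], landscape, cfg,
                                   seed = stage_seed(seed, i, 20L))
    pool_count_table(pool_i, arms[i], 1L)
  })
  names(post) <- arms
  # tables are keyed by sequence; EFs line up on the loop sequences
  experiment <- reselection_experiment(pre_table, post,
                                       control_ids = unname(controls))
  list(experiment = experiment, subset_motif = scenario$motif,
       landscape = landscape, pre_pool = pre_pool)
}

#' Mock-selection mixture scenario
#'
#' The protocol-validation experiment: a known cognate pair spiked at low
#' frequency into a background of non-binders on both sides (e.g. 1:99
#' binder:non-binder RNA against 1:99 binder:non-binder phage), selected for
#' a single round. The cognate pair uses the kink-turn/L7Ae-range kinetics
#' (k_on 1.41e7 1/(M s), k_off 2.77e-4 1/s, K_D 21 pM).
#'
#' @param binder_frac_rna,binder_frac_phage spiked binder fractions.
#' @param total_rna,total_phage pool totals.
#' @return list: `rna_pool`, `phage_pool`, `landscape`, `cfg` (single
#'   mock round).
#' @export
mock_mixture_scenario <- function(binder_frac_rna = 0.01,
                                  binder_frac_phage = 0.01,
                                  total_rna = 1e10, total_phage = 1e9) {
  design_r <- hairpin_n20_design()
  design_p <- l7ae_scaffold_design()
  kt_loop <- "GGAUGAUGAAAGCAAUCCGC"     # stand-in kink-turn-bearing loop
  dkt_loop <- "CCUACUACUUUCGUUAGGCG"    # defective (non-binding) loop
  rna <- rna_pool(c(kt_loop, dkt_loop),
                  c(binder_frac_rna, 1 - binder_frac_rna) * total_rna,
                  design_r, ids = c("Kt", "dKt"))
  phage <- protein_pool(c("IEVPCKER", "GGGGSGGS"),
                        c(binder_frac_phage, 1 - binder_frac_phage) *
                          total_phage,
                        design_p, ids = c("L7Ae", "dL7Ae"), seed = 42L)
  landscape <- kd_landscape("Kt", "L7Ae", k_on = 1.41e7, k_off = 2.77e-4)
  cfg <- round_config(n_washes = 3L, background_step1 = 1e-3,
                      background_step2 = 1e-3, rnaseh_specificity = 0.3,
                      bottleneck_rna = Inf, bottleneck_phage = Inf)
  list(rna_pool = rna, phage_pool = phage, landscape = landscape, cfg = cfg)
}
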