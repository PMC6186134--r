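# Multi-species synthetic dataset assembly and the per-species analysis
# pipeline that turns a species_dataset into one row of the trait table.

#' Simulation configuration
#'
#' Defaults describe a moderately diverse bacterial species: core nucleotide
#' diversity theta = 0.02/site, strong purifying selection on universal genes
#' (omega = 0.15), transition bias kappa = 2, a 1500-family root genome with
#' gain-dominated accessory turnover (gains accumulate at 4e4 per unit branch
#' length, i.e. hundreds of family differences per percent core divergence,
#' as observed in enterobacteria), and 5\% paralog contamination of hit
#' tables.  Per-species fields (theta_per_site, omega, lifestyle,
#' mutation_rate, gain_rate, loss_rate, root_gene_count,
#' recombination_events) may be vectors recycled across species.
#'
#' @param n_species number of species.
#' @param strains_per_species strains per species (>= 15).
#' @param theta_per_site population-scaled mutation rate per site.
#' @param omega true dN/dS of the codon process, in (0, 1].
#' @param kappa transition/transversion rate ratio.
#' @param n_universal_genes universal gene count (default 44).
#' @param n_codons_per_gene codons per universal gene.
#' @param n_core_codons codons in the core concatenate.
#' @param root_gene_count families present at the species root.
#' @param gain_rate,loss_rate gene-content rates per unit branch length.
#' @param recombination_events tract-copy events injected into the core
#'   alignment.
#' @param tract_length recombination tract length (nt).
#' @param paralog_fraction probability a rank-1 hit is a paralog.
#' @param lifestyle per-species lifestyle labels.
#' @param mutation_rate per-species mutation rate (NA when unknown).
#' @param min_doubling_time per-species minimal doubling time (hours).
#' @param seed master seed; all species substreams derive from it.
#' @return list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_species = 3, strains_per_species = 15,
                              theta_per_site = 0.02, omega = 0.15, kappa = 2,
                              n_universal_genes = 44, n_codons_per_gene = 100,
                              n_core_codons = 2000, root_gene_count = 1500,
                              gain_rate = 40000, loss_rate = 1,
                              recombination_events = 0, tract_length = 300,
                              paralog_fraction = 0.05,
                              lifestyle = "unknown", mutation_rate = NA,
                              min_doubling_time = NA, seed = 1) {
  if (strains_per_species < 15)
    abort_category("argument_error", "strains_per_species must be >= 15")
  if (any(omega <= 0) || any(omega > 1))
    abort_category("argument_error", "omega must be in (0, 1]")
  if (any(theta_per_site <= 0))
    abort_category("argument_error", "theta_per_site must be > 0")
  if (any(paralog_fraction < 0) || any(paralog_fraction >= 1))
    abort_category("argument_error", "paralog_fraction must be in [0, 1)")
  structure(as.list(environment()), class = "simulation_config")
}

recycle <- function(x, n) rep(x, length.out = n)

#' Generate a full multi-species synthetic dataset
#'
#' Per species: a coalescent strain genealogy, codon alignments for the
#' universal and core concatenates evolved at the species' omega,
#' recombination tracts injected into the core alignment, gene-content
#' evolution with a complete event log, and a paralog-contaminated hit
#' table.  A cross-species tree is generated for comparative analyses.  When
#' \code{out_dir} is given the full on-disk layout (one directory per
#' species plus \code{ground_truth/}) is written and is loadable with
#' \code{\link{load_species_dataset}}.
#'
#' @param config a \code{simulation_config}.
#' @param out_dir optional output directory.
#' @return list with \code{species} (list of \code{species_dataset}),
#'   \code{ground_truth} (true trees, omega, theta, event and recombination
#'   logs, hit-table truth maps, species tree) and \code{dir}.
#' @export
generate_dataset <- function(config, out_dir = NULL) {
  n_sp <- config$n_species
  ids <- sprintf("sp%02d", seq_len(n_sp))
  theta <- recycle(config$theta_per_site, n_sp)
  omega <- recycle(config$omega, n_sp)
  lifestyle <- recycle(config$lifestyle, n_sp)
  mu <- recycle(config$mutation_rate, n_sp)
  dtime <- recycle(config$min_doubling_time, n_sp)
  root_n <- recycle(config$root_gene_count, n_sp)
  g_rate <- recycle(config$gain_rate, n_sp)
  l_rate <- recycle(config$loss_rate, n_sp)
  rec_n <- recycle(config$recombination_events, n_sp)
  para <- recycle(config$paralog_fraction, n_sp)
  n_uni_codons <- config$n_universal_genes * config$n_codons_per_gene
  species <- vector("list", n_sp)
  names(species) <- ids
  gt <- list(true_trees = list(), true_omega = stats::setNames(omega, ids),
             true_theta = stats::setNames(theta, ids),
             gene_event_log = list(), recombination_log = list(),
             hit_truth = list())
  for (i in seq_len(n_sp)) {
    sd0 <- function(k) derive_seed(config$seed, i * 100 + k)
    labels <- sprintf("%s_s%02d", ids[i], seq_len(config$strains_per_species))
    tree <- simulate_strain_genealogy(config$strains_per_species, theta[i],
                                      sd0(1), labels = labels)
    uni <- evolve_codon_alignment(tree, omega[i], config$kappa,
                                  n_uni_codons, sd0(2))
    core <- evolve_codon_alignment(tree, omega[i], config$kappa,
                                   config$n_core_codons, sd0(3))
    rec <- inject_recombination(core, tree, rec_n[i],
                                min(config$tract_length, aln_length(core)),
                                sd0(4))
    core <- rec$alignment
    gc_sim <- simulate_gene_content(tree, root_n[i], g_rate[i], l_rate[i],
                                    sd0(5))
    ht <- make_hit_table(config$strains_per_species,
                         config$n_universal_genes, para[i], sd0(6),
                         strain_ids = labels)
    meta <- species_metadata(lifestyle = lifestyle[i],
                             min_doubling_time = dtime[i],
                             mutation_rate = mu[i])
    species[[i]] <- structure(
      list(species_id = ids[i], strain_ids = sort(labels),
           universal_alignment = uni, core_alignment = core,
           strain_tree = tree, family_matrix = gc_sim$matrix,
           metadata = meta, hits = ht$hits),
      class = "species_dataset")
    gt$true_trees[[ids[i]]] <- tree
    gt$gene_event_log[[ids[i]]] <- gc_sim$events
    gt$recombination_log[[ids[i]]] <- rec$log
    gt$hit_truth[[ids[i]]] <- ht$truth
  }
  gt$species_tree <- simulate_strain_genealogy(max(n_sp, 2), 0.5,
                                               derive_seed(config$seed, 7),
                                               labels = if (n_sp >= 2) ids
                                               else c(ids, "outgroup"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_sp)) {
      sp_dir <- file.path(out_dir, ids[i])
      dir.create(sp_dir, showWarnings = FALSE)
      ds <- species[[i]]
      write_fasta(ds$universal_alignment, file.path(sp_dir, "universal.fasta"))
      write_fasta(ds$core_alignment, file.path(sp_dir, "core.fasta"))
      write_newick(ds$strain_tree, file.path(sp_dir, "tree.nwk"))
      write_presence_tsv(ds$family_matrix, file.path(sp_dir, "families.tsv"))
      write_metadata(ds$metadata, file.path(sp_dir, "metadata.txt"))
      write_hit_table(ds$hits, file.path(sp_dir, "hits.tsv"))
    }
    gt_dir <- file.path(out_dir, "ground_truth")
    dir.create(gt_dir, showWarnings = FALSE)
    write_newick(gt$species_tree, file.path(gt_dir, "species_tree.nwk"))
    for (sp in ids) {
      utils::write.table(gt$gene_event_log[[sp]],
                         file.path(gt_dir, paste0(sp, "_events.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(gt$recombination_log[[sp]],
                         file.path(gt_dir, paste0(sp, "_recombination.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    params <- data.frame(species_id = ids, theta = theta, omega = omega,
                         lifestyle = lifestyle)
    utils::write.table(params, file.path(gt_dir, "params.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(species = species, ground_truth = gt, dir = out_dir)
}

#' Analyze one species into a trait-table row
#'
#' Runs the single-species pipeline: pairwise NG86 dN/dS on the universal
#' concatenate averaged inside the dS window, Watterson's theta on the
#' four-fold degenerate sites of the core concatenate (absolute Ne when a
#' mutation rate is available), harmonic-normalized pan-genome size, h/m
#' homoplasy ratios on both concatenates, and bookkeeping traits (mean gene
#' count, GC content).
#'
#' @param ds a \code{species_dataset}.
#' @param ds_window inclusive dS window (default c(0.1, 0.3)).
#' @return one-row data.frame.
#' @export
analyze_species <- function(ds, ds_window = c(0.1, 0.3)) {
  pairs <- alignment_pairwise_dnds(ds$universal_alignment)
  sp_ds <- species_dsdn(pairs, window = ds_window)
  ff <- fourfold_sites(ds$core_alignment)
  theta <- if (length(ff) > 0)
    watterson_theta(aln_matrix(ds$core_alignment)[, ff, drop = FALSE])
  else NA_real_
  ne_abs <- if (!is.na(theta) && !is.na(ds$metadata$mutation_rate))
    ne_from_theta(theta, ds$metadata$mutation_rate) else NA_real_
  pan <- pan_genome_stats(ds$family_matrix)
  hm_core <- classify_homoplasy(ds$strain_tree, ds$core_alignment)
  hm_uni <- classify_homoplasy(ds$strain_tree, ds$universal_alignment)
  seq_all <- paste(unclass(ds$core_alignment), collapse = "")
  bases <- table(strsplit(seq_all, "")[[1]])
  gc <- sum(bases[c("G", "C")], na.rm = TRUE) / sum(bases[NUC], na.rm = TRUE)
  data.frame(
    species_id = ds$species_id,
    n_strains = length(ds$strain_ids),
    mean_dnds = sp_ds$mean_dnds,
    ne_relative = sp_ds$mean_dsdn,
    n_pairs_in_window = sp_ds$n_pairs_in_window,
    dsdn_excluded = sp_ds$excluded,
    theta_per_site = theta,
    ne_absolute = ne_abs,
    n_pan = pan$n_pan,
    p_normalized = pan$p_normalized,
    genome_size = mean(rowSums(ds$family_matrix$presence)),
    h_over_m = hm_core$ratio,
    h_over_m_universal = hm_uni$ratio,
    gc_content = gc,
    min_doubling_time = ds$metadata$min_doubling_time,
    lifestyle = ds$metadata$lifestyle,
    stringsAsFactors = FALSE)
}

#' Build the cross-species trait table
#'
#' @param species list of \code{species_dataset}.
#' @param ... passed to \code{\link{analyze_species}}.
#' @return data.frame, one row per species.
#' @export
species_trait_table <- function(species, ...) {
  do.call(rbind, lapply(species, analyze_species, ...))
}
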