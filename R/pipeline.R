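#' End-to-end run configuration
#'
#' Bundles the parameter blocks of all pipeline stages. Validation is
#' exhaustive at construction time, before any work starts.
#'
#' @param picking an `icm_picking_params` (used when inputs are profile
#'   spectra).
#' @param consensus an `icm_consensus_params`.
#' @param score_tol_da matching tolerance for the similarity score, Da.
#' @param linkage tree linkage method.
#' @param sim an `icm_sim_config`, or NULL when reading real peak lists.
#' @param input_dir directory of per-replicate peak-list CSVs named
#'   `<sample>__<replicate>.csv`, or NULL to simulate from `sim`.
#' @param proteins_fasta optional FASTA of candidate proteins to assign.
#' @param assign_tol_da assignment tolerance, Da.
#' @param seed integer seed governing all randomness in the run.
#' @return a list of class `icm_run_config`.
#' @export
run_config <- function(picking = picking_params(),
                       consensus = consensus_params(),
                       score_tol_da = 2, linkage = "upgma",
                       sim = sim_config(), input_dir = NULL,
                       proteins_fasta = NULL, assign_tol_da = 6, seed = 1) {
  stopifnot(inherits(picking, "icm_picking_params"),
            inherits(consensus, "icm_consensus_params"),
            score_tol_da > 0, assign_tol_da > 0,
            linkage %in% c("upgma", "complete", "single"))
  if (is.null(input_dir) && is.null(sim))
    stop("either input_dir or sim must be given")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir)
  if (!is.null(proteins_fasta) && !file.exists(proteins_fasta))
    stop("proteins_fasta does not exist: ", proteins_fasta)
  if (!is.null(sim)) stopifnot(inherits(sim, "icm_sim_config"))
  structure(list(picking = picking, consensus = consensus,
                 score_tol_da = score_tol_da, linkage = linkage,
                 sim = sim, input_dir = input_dir,
                 proteins_fasta = proteins_fasta,
                 assign_tol_da = assign_tol_da, seed = as.integer(seed)),
            class = "icm_run_config")
}

#' Run the full typing pipeline
#'
#' Simulates (or loads) replicate peak lists, builds the consensus library,
#' computes the all-pairs similarity matrix, renders the heat map, builds
#' the UPGMA similarity tree and, when a protein FASTA is configured,
#' assigns proteins to the first sample's consensus peaks. All non-image
#' outputs are byte-identical across reruns with the same configuration.
#'
#' @param cfg an `icm_run_config`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly. Writes `library.json`,
#'   `similarity_matrix.csv`, `tree.nwk`, `heatmap.png`,
#'   `assignments.csv` (optional) and `run_log.json`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "icm_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(cfg$input_dir)) {
    files <- list.files(cfg$input_dir, pattern = "\\.csv$", full.names = TRUE)
    if (length(files) == 0L) stop("no peak-list CSVs in ", cfg$input_dir)
    parts <- strsplit(sub("\\.csv$", "", basename(files)), "__")
    by_sample <- split(seq_along(files),
                       vapply(parts, `[`, character(1), 1))
    peaklists <- lapply(by_sample, function(ii)
      lapply(ii, function(i)
        read_peaklist_csv(files[i], sample_id = parts[[i]][1],
                          replicate_id = parts[[i]][2])))
  } else {
    sim <- cfg$sim
    sim$seed <- cfg$seed
    fps <- generate_fingerprints(sim)
    peaklists <- lapply(fps, simulate_replicates, cfg = sim)
    names(peaklists) <- vapply(fps, function(f) f$sample_id, character(1))
  }

  library_ <- lapply(peaklists, build_virtual_spectrum, p = cfg$consensus)
  write_library(library_, file.path(out_dir, "library.json"))

  m <- similarity_matrix(library_, tol_da = cfg$score_tol_da)
  write_similarity_csv(m, file.path(out_dir, "similarity_matrix.csv"))
  render_heatmap(m, file.path(out_dir, "heatmap.png"))
  tree <- build_tree(m, linkage = cfg$linkage)
  write_tree_newick(tree, file.path(out_dir, "tree.nwk"))

  if (!is.null(cfg$proteins_fasta)) {
    prot <- protein_records(cfg$proteins_fasta)
    asn <- match_masses_to_peaks(prot, library_[[1]]$mz,
                                 tol = cfg$assign_tol_da)
    utils::write.csv(asn$assignments,
                     file.path(out_dir, "assignments.csv"),
                     row.names = FALSE)
  }

  log <- list(
    package = "icmaldi",
    version = as.character(utils::packageVersion("icmaldi")),
    seed = cfg$seed,
    n_samples = length(library_),
    params = list(
      picking = unclass(cfg$picking), consensus = unclass(cfg$consensus),
      score_tol_da = cfg$score_tol_da, linkage = cfg$linkage,
      assign_tol_da = cfg$assign_tol_da,
      sim = if (is.null(cfg$sim)) NULL else unclass(cfg$sim),
      input_dir = cfg$input_dir, proteins_fasta = cfg$proteins_fasta),
    outputs = list.files(out_dir))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
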