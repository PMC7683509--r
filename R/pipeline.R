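# End-to-end run: catalog + mutations -> partitions -> tests -> FDR -> reports.

#' Run the full enrichment pipeline on files
#'
#' Orchestrates one analysis run for one PTM type: loads the site catalog,
#' proteome and cohort mutations; applies the missense-only consequence
#' filter; drops mutations that cannot be mapped onto the proteome; builds
#' the per-protein modification/background partitions; tests every protein
#' with both regions non-empty; applies Benjamini-Hochberg correction across
#' the run and flags drivers. Writes four artifacts to `out_dir`:
#' `results.tsv` (one row per tested protein), `annotated_mutations.tsv`,
#' `skipped_proteins.tsv` (with reasons), and `manifest.json` (config echo
#' and counts at each filter stage). Partial outputs are removed on failure.
#'
#' @param mutations,ptm_sites,proteome Input file paths (see
#'   [load_mutations()], [load_ptm_sites()], [load_protein_lengths()]).
#' @param ptm_type Modification type analysed in this run.
#' @param out_dir Output directory (created if needed).
#' @param window Motif half-width in residues (default 7).
#' @param prior_mod,prior_bg Gamma priors on the two rates.
#' @param method `"exact"` (incomplete-beta, default) or `"mc"` (posterior
#'   sampling honoring `iterations`/`burn_in`).
#' @param iterations,burn_in Monte-Carlo settings.
#' @param seed Integer seed (drives `method = "mc"`; recorded in the manifest).
#' @param q_threshold Driver-call threshold on the BH q-value.
#' @param predictor_table Optional path to a predictor-call TSV for the
#'   0-7 pathogenicity tally.
#' @param info_key INFO field for VCF input.
#' @param genome_assembly Free-text assembly tag; recorded in the manifest
#'   only (no coordinate conversion is performed).
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list: `results`, `annotated`, `skipped`, `manifest`,
#'   and the output `paths`.
#' @export
run_pipeline <- function(mutations, ptm_sites, proteome, ptm_type,
                         out_dir,
                         window = 7L,
                         prior_mod = gamma_prior(), prior_bg = gamma_prior(),
                         method = c("exact", "mc"),
                         iterations = 10000L, burn_in = 1000L,
                         seed = 1L, q_threshold = 0.05,
                         predictor_table = NULL,
                         info_key = "PROTANN",
                         genome_assembly = NULL,
                         quiet = FALSE) {
  method <- match.arg(method)
  if (iterations <= burn_in) stop("iterations must exceed burn_in")
  if (q_threshold <= 0 || q_threshold > 1) stop("q_threshold must be in (0, 1]")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(results = file.path(out_dir, "results.tsv"),
                annotated = file.path(out_dir, "annotated_mutations.tsv"),
                skipped = file.path(out_dir, "skipped_proteins.tsv"),
                manifest = file.path(out_dir, "manifest.json"))
  say <- function(...) if (!quiet) message(sprintf(...))

  run <- function() {
    say("stage load: reading inputs")
    sites <- load_ptm_sites(ptm_sites, ptm_type_filter = ptm_type)
    if (nrow(sites) == 0) stop("stage load: no PTM sites of type ", ptm_type)
    proteins <- load_protein_lengths(proteome)
    muts <- load_mutations(mutations, info_key = info_key)
    n_input <- nrow(muts)

    say("stage filter: consequence filter (%d input mutations)", n_input)
    retained <- filter_nonsynonymous(muts)
    n_dropped_consequence <- n_input - nrow(retained)

    # unmapped = accession absent from proteome, or position beyond its length
    plen <- proteins$length[match(retained$accession, proteins$accession)]
    unmapped <- is.na(plen) | retained$position > plen
    if (any(unmapped)) {
      tally <- table(retained$accession[unmapped])
      say("stage map: dropping %d unmappable mutation(s) on %d protein(s)",
          sum(unmapped), length(tally))
    }
    n_dropped_unmapped <- sum(unmapped)
    retained <- retained[!unmapped, , drop = FALSE]
    n_retained <- nrow(retained)

    say("stage partition: %d catalogued protein(s), window %d",
        length(unique(sites$accession)), window)
    built <- build_all_partitions(proteins, sites, window = window)
    partitions <- built$partitions

    say("stage test: %d testable protein(s)", length(partitions))
    if (method == "mc") set.seed(seed)
    res_rows <- lapply(partitions, function(part) {
      cv <- suppressWarnings(count_by_position(part, retained))
      test_protein(part, cv, prior_mod = prior_mod, prior_bg = prior_bg,
                   method = method, iterations = iterations, burn_in = burn_in)
    })
    results <- if (length(res_rows)) do.call(rbind, res_rows) else NULL
    results <- call_drivers(results, q_threshold = q_threshold)
    rownames(results) <- NULL

    say("stage annotate: %d retained mutation(s)", n_retained)
    pred <- if (!is.null(predictor_table)) {
      utils::read.delim(predictor_table, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE, quote = "")
    } else NULL
    annotated <- annotate_mutations(retained, partitions, sites,
                                    predictor_table = pred)

    manifest <- list(
      config = list(mutations = mutations, ptm_sites = ptm_sites,
                    proteome = proteome, ptm_type = ptm_type,
                    window = window, method = method,
                    prior_mod = unclass(prior_mod), prior_bg = unclass(prior_bg),
                    iterations = iterations, burn_in = burn_in, seed = seed,
                    q_threshold = q_threshold,
                    genome_assembly = genome_assembly),
      counts = list(input_mutations = n_input,
                    retained = n_retained,
                    dropped_by_consequence = n_dropped_consequence,
                    dropped_unmapped = n_dropped_unmapped,
                    proteins_tested = nrow(results),
                    proteins_skipped = nrow(built$skipped),
                    drivers_called = sum(results$is_driver))
    )
    write_tsv <- function(df, path) {
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = TRUE)
    }
    write_tsv(results, paths$results)
    write_tsv(annotated, paths$annotated)
    write_tsv(built$skipped, paths$skipped)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    say("done: %d tested, %d driver call(s), %d skipped",
        nrow(results), sum(results$is_driver), nrow(built$skipped))
    list(results = results, annotated = annotated, skipped = built$skipped,
         manifest = manifest, paths = paths)
  }

  tryCatch(invisible(run()), error = function(e) {
    unlink(unlist(paths))
    stop(e)
  })
}
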