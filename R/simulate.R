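# Truth-labelled synthetic cohorts with the generative structure of the
# inference model: per-position counts Poisson(lambda2) in the background and
# Poisson(R_true * lambda2) in the merged modification region.

#' Configuration for the synthetic-cohort generator
#'
#' Defaults describe the reference simulation used for calibration and power
#' studies: 500 proteins of 400 residues, three modification sites each
#' (window 7, so the merged modification region holds up to 45 residues), a
#' cohort-summed background rate of 0.1 mutations per position, and a 10%
#' driver fraction at a five-fold regional rate increase.
#'
#' @param n_proteins Number of proteins.
#' @param protein_length Residues per protein: a single fixed length or a
#'   `c(min, max)` range sampled uniformly.
#' @param sites_per_protein Modification sites placed uniformly (distinct
#'   positions) per protein.
#' @param window Motif half-width in residues.
#' @param cohort_size Number of cohort samples mutation rows are attributed
#'   to (inference ignores sample identity; this only shapes the files).
#' @param bg_rate Background rate lambda2: expected cohort-summed mutation
#'   count per background position.
#' @param enrichment_ratio True relative rate R for driver proteins
#'   (modification-region rate = `enrichment_ratio * bg_rate`); must be >= 1.
#' @param fraction_drivers Fraction of proteins simulated as drivers; the
#'   rest are nulls with R = 1.
#' @param ptm_type Modification type written to the catalog.
#' @param seed Integer seed; fixes every random choice.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_proteins = 500L, protein_length = 400L,
                       sites_per_protein = 3L, window = 7L,
                       cohort_size = 100L, bg_rate = 0.1,
                       enrichment_ratio = 5, fraction_drivers = 0.1,
                       ptm_type = "Phosphorylation", seed = 1L) {
  stopifnot(n_proteins >= 1, all(protein_length >= 1),
            length(protein_length) %in% c(1L, 2L),
            sites_per_protein >= 1, window >= 0, cohort_size >= 1,
            bg_rate > 0, enrichment_ratio >= 1,
            fraction_drivers >= 0, fraction_drivers <= 1)
  structure(list(n_proteins = as.integer(n_proteins),
                 protein_length = as.integer(protein_length),
                 sites_per_protein = as.integer(sites_per_protein),
                 window = as.integer(window),
                 cohort_size = as.integer(cohort_size),
                 bg_rate = bg_rate, enrichment_ratio = enrichment_ratio,
                 fraction_drivers = fraction_drivers,
                 ptm_type = ptm_type, seed = as.integer(seed)),
            class = "sim_config")
}

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulate a truth-labelled mutation cohort
#'
#' Draws per-position mutation counts from the generative model, expands them
#' into per-sample mutation rows (uniform sample attribution, uniform distinct
#' ref/alt amino acids, all missense), and optionally writes the exact file
#' dialects the readers consume. Fully reproducible: a fixed seed gives
#' byte-identical files.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `ptm_sites.tsv`,
#'   `protein_lengths.tsv`, `mutations.tsv` and `truth.tsv` there.
#' @return List with data.frames `sites`, `proteins`, `mutations`, `truth`
#'   (per-protein `r_true`, `is_driver`, realized regional totals and sizes)
#'   and, when `out_dir` was given, the file `paths`.
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nP <- config$n_proteins
  acc <- sprintf("SIM%04d", seq_len(nP))
  lens <- if (length(config$protein_length) == 2L) {
    sample(config$protein_length[1]:config$protein_length[2], nP, replace = TRUE)
  } else rep(config$protein_length, nP)
  n_drivers <- round(config$fraction_drivers * nP)
  is_driver <- rep(FALSE, nP)
  if (n_drivers > 0) is_driver[sample.int(nP, n_drivers)] <- TRUE
  r_true <- ifelse(is_driver, config$enrichment_ratio, 1)

  samples <- sprintf("SAMPLE%03d", seq_len(config$cohort_size))
  site_rows <- vector("list", nP)
  mut_rows <- vector("list", nP)
  truth <- data.frame(accession = acc, r_true = r_true, is_driver = is_driver,
                      n = lens, k = NA_integer_,
                      mod_total = NA_integer_, bg_total = NA_integer_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nP)) {
    n <- lens[i]
    spos <- sort(sample.int(n, min(config$sites_per_protein, n)))
    site_rows[[i]] <- data.frame(
      accession = acc[i], position = spos,
      residue = sample(AA_LETTERS, length(spos), replace = TRUE),
      ptm_type = config$ptm_type, evidence = "simulated",
      stringsAsFactors = FALSE)
    part <- build_partition(list(accession = acc[i], length = n),
                            site_rows[[i]], window = config$window)
    mod_counts <- stats::rpois(part$k, r_true[i] * config$bg_rate)
    bg_counts <- stats::rpois(part$n - part$k, config$bg_rate)
    truth$k[i] <- part$k
    truth$mod_total[i] <- sum(mod_counts)
    truth$bg_total[i] <- sum(bg_counts)
    pos <- c(rep(part$mod_positions, mod_counts),
             rep(part$bg_positions, bg_counts))
    if (length(pos) > 0) {
      ref <- sample(AA_LETTERS, length(pos), replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(AA_LETTERS, r), 1L),
                    character(1), USE.NAMES = FALSE)
      mut_rows[[i]] <- data.frame(
        sample_id = sample(samples, length(pos), replace = TRUE),
        accession = acc[i], position = pos, ref_aa = ref, alt_aa = alt,
        consequence = "missense", stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, site_rows)
  mutations <- do.call(rbind, mut_rows[!vapply(mut_rows, is.null, logical(1))])
  if (is.null(mutations)) {
    mutations <- data.frame(sample_id = character(), accession = character(),
                            position = integer(), ref_aa = character(),
                            alt_aa = character(), consequence = character(),
                            stringsAsFactors = FALSE)
  }
  rownames(sites) <- rownames(mutations) <- NULL
  proteins <- data.frame(accession = acc, length = lens, stringsAsFactors = FALSE)
  out <- list(sites = sites, proteins = proteins, mutations = mutations,
              truth = truth, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(sites = file.path(out_dir, "ptm_sites.tsv"),
                  proteins = file.path(out_dir, "protein_lengths.tsv"),
                  mutations = file.path(out_dir, "mutations.tsv"),
                  truth = file.path(out_dir, "truth.tsv"))
    write_tsv <- function(df, path) {
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = TRUE)
    }
    write_tsv(sites, paths$sites)
    write_tsv(proteins, paths$proteins)
    write_tsv(mutations, paths$mutations)
    write_tsv(truth, paths$truth)
    out$paths <- paths
  }
  out
}

#' Compare pipeline results against simulation truth
#'
#' @param truth Truth data.frame from [simulate_cohort()] (or its TSV).
#' @param results Results data.frame with `accession`, `p_value`, `q_value`
#'   (from [call_drivers()]); every result accession must exist in the truth.
#' @param alpha Nominal level for the raw-p type-I tally (default 0.05).
#' @param q_threshold Driver-call threshold on the q-value (default 0.05).
#' @return List of metrics: `type_i_error` (fraction of tested nulls with
#'   p < alpha), `power` (fraction of tested drivers with q < q_threshold),
#'   `realized_fdr` (nulls among called drivers), plus the underlying counts.
#' @export
evaluate_run <- function(truth, results, alpha = 0.05, q_threshold = 0.05) {
  if (is.null(results) || nrow(results) == 0) stop("empty results")
  idx <- match(results$accession, truth$accession)
  if (any(is.na(idx))) {
    stop("result accession(s) absent from truth: ",
         paste(utils::head(results$accession[is.na(idx)], 5), collapse = ", "))
  }
  is_driver <- truth$is_driver[idx]
  called <- results$q_value < q_threshold
  n_null <- sum(!is_driver)
  n_driver <- sum(is_driver)
  list(
    n_tested = nrow(results), n_null = n_null, n_driver = n_driver,
    type_i_error = if (n_null > 0) mean(results$p_value[!is_driver] < alpha) else NA_real_,
    power = if (n_driver > 0) mean(called[is_driver]) else NA_real_,
    n_called = sum(called),
    realized_fdr = if (sum(called) > 0) mean(!is_driver[called]) else 0
  )
}
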