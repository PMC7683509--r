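# PTM-site catalogs, protein lengths, and motif-region partitions.

#' Load a PTM-site catalog from TSV
#'
#' Reads a tab-separated catalog of experimentally known post-translational
#' modification sites. Required columns: `accession`, `position`, `ptm_type`;
#' optional columns `residue` and `evidence` are carried through when present.
#' Rows are deduplicated on (accession, position, ptm_type); rows with a
#' non-integer or sub-1 position are rejected with a warning.
#'
#' @param path Path to the catalog TSV (UTF-8, header row).
#' @param ptm_type_filter Optional modification type (e.g. `"Phosphorylation"`);
#'   when given, only sites of that type are returned.
#' @return A data.frame of PTM sites with columns `accession` (character),
#'   `position` (integer), `residue`, `ptm_type`, `evidence`. The number of
#'   rejected malformed rows is attached as attribute `n_rejected`.
#' @export
load_ptm_sites <- function(path, ptm_type_filter = NULL) {
  if (!file.exists(path)) stop("PTM catalog not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE, quote = "",
                           check.names = FALSE)
  required <- c("accession", "position", "ptm_type")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("PTM catalog is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(raw$position))
  bad <- is.na(pos) | pos < 1 | raw$accession == "" | raw$ptm_type == ""
  n_rejected <- sum(bad)
  if (n_rejected > 0) {
    warning(sprintf("rejected %d malformed PTM-site row(s) (bad position or empty key field)",
                    n_rejected))
  }
  sites <- data.frame(
    accession = raw$accession[!bad],
    position  = pos[!bad],
    residue   = if ("residue" %in% names(raw)) raw$residue[!bad] else NA_character_,
    ptm_type  = raw$ptm_type[!bad],
    evidence  = if ("evidence" %in% names(raw)) raw$evidence[!bad] else NA_character_,
    stringsAsFactors = FALSE
  )
  sites <- sites[!duplicated(sites[c("accession", "position", "ptm_type")]), , drop = FALSE]
  if (!is.null(ptm_type_filter)) {
    sites <- sites[sites$ptm_type == ptm_type_filter, , drop = FALSE]
  }
  rownames(sites) <- NULL
  attr(sites, "n_rejected") <- n_rejected
  sites
}

#' Load protein lengths from a proteome FASTA or a lengths TSV
#'
#' For FASTA input the accession is the first whitespace-delimited token of
#' each header and the length is the residue count; for TSV input two columns
#' `accession` and `length` are expected (header optional when exactly two
#' columns). Duplicate accessions resolve to the first occurrence with a
#' warning; empty-sequence FASTA records are rejected.
#'
#' @param path Path to the proteome file.
#' @param format `"fasta"`, `"tsv"`, or `"auto"` (default: sniff from content).
#' @return A data.frame with columns `accession`, `length` (integer) and, for
#'   FASTA input, `sequence`; one row per distinct accession.
#' @export
load_protein_lengths <- function(path, format = c("auto", "fasta", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("proteome file not found: ", path)
  if (file.size(path) == 0) stop("proteome file is empty: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, ">")) "fasta" else "tsv"
  }
  if (format == "fasta") {
    seqs <- Biostrings::readAAStringSet(path)
    acc <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
    len <- Biostrings::width(seqs)
    keep <- len > 0
    if (any(!keep)) warning(sprintf("rejected %d empty FASTA record(s)", sum(!keep)))
    info <- data.frame(accession = acc[keep], length = as.integer(len[keep]),
                       sequence = as.character(seqs)[keep],
                       stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                             colClasses = "character",
                             stringsAsFactors = FALSE, quote = "")
    if (nrow(raw) > 0 && identical(tolower(raw[1, 1]), "accession")) {
      raw <- raw[-1, , drop = FALSE]
    }
    if (ncol(raw) < 2) stop("lengths TSV must have columns accession, length")
    len <- suppressWarnings(as.integer(raw[[2]]))
    bad <- is.na(len) | len < 1
    if (any(bad)) warning(sprintf("rejected %d row(s) with non-positive length", sum(bad)))
    info <- data.frame(accession = raw[[1]][!bad], length = len[!bad],
                       stringsAsFactors = FALSE)
  }
  dup <- duplicated(info$accession)
  if (any(dup)) {
    warning(sprintf("%d duplicate accession(s); first occurrence kept", sum(dup)))
    info <- info[!dup, , drop = FALSE]
  }
  rownames(info) <- NULL
  info
}

#' Partition a protein into modification region and background
#'
#' Expands each known modification site into a symmetric motif window of
#' `window` residues on either side of the central site (so up to
#' `2 * window + 1` residues per site), truncated at the protein termini.
#' Same-type windows on the same protein are merged into a single
#' modification region of size k; the remaining `n - k` residues form the
#' background region.
#'
#' @param protein A one-row data.frame or list with fields `accession` and
#'   `length` (and optionally `sequence`).
#' @param sites Data.frame of PTM sites for this protein, all of one
#'   `ptm_type` (as returned by [load_ptm_sites()]).
#' @param window Half-width of the motif window in residues (default 7).
#' @return An object of class `region_partition`: a list with `accession`,
#'   `ptm_type`, `n`, `k`, `window`, `mod_positions` (sorted 1-based positions,
#'   length k), `bg_positions` (the complement in 1..n), and `site_positions`.
#' @examples
#' prot <- data.frame(accession = "P1", length = 100)
#' site <- data.frame(accession = "P1", position = 10,
#'                    ptm_type = "Phosphorylation")
#' build_partition(prot, site)$k  # 15 = 2*7 + 1
#' @export
build_partition <- function(protein, sites, window = 7L) {
  n <- as.integer(protein$length)
  stopifnot(length(n) == 1L, !is.na(n), n >= 1L)
  if (window < 0) stop("window must be >= 0")
  if (is.null(sites) || nrow(sites) == 0) {
    stop("no PTM sites supplied for ", protein$accession, "; protein not testable")
  }
  if (length(unique(sites$ptm_type)) > 1L) {
    stop("build_partition expects sites of a single ptm_type; got: ",
         paste(unique(sites$ptm_type), collapse = ", "))
  }
  pos <- as.integer(sites$position)
  over <- pos > n
  if (any(over)) {
    stop(sprintf("PTM site(s) beyond protein length for %s: position %s > length %d",
                 protein$accession, paste(pos[over], collapse = ","), n))
  }
  covered <- rep(FALSE, n)
  for (p in unique(pos)) {
    covered[max(1L, p - window):min(n, p + window)] <- TRUE
  }
  structure(list(
    accession = as.character(protein$accession),
    ptm_type = as.character(sites$ptm_type[1]),
    n = n,
    k = sum(covered),
    window = as.integer(window),
    mod_positions = which(covered),
    bg_positions = which(!covered),
    site_positions = sort(unique(pos))
  ), class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("region_partition: %s [%s]\n", x$accession, x$ptm_type))
  cat(sprintf("  n = %d residues; modification region k = %d; background %d\n",
              x$n, x$k, x$n - x$k))
  cat(sprintf("  %d site(s), window +/-%d\n", length(x$site_positions), x$window))
  invisible(x)
}

#' Build partitions for every protein with catalogued sites
#'
#' Convenience wrapper over [build_partition()] for a whole cohort run. Sites
#' on accessions absent from the proteome are skipped (tallied); proteins whose
#' modification region swallows the whole sequence (k = n, empty background)
#' are returned in the `skipped` table rather than the partition list, since
#' the rate comparison needs both regions.
#'
#' @param proteins Data.frame from [load_protein_lengths()].
#' @param sites Data.frame of PTM sites of a single `ptm_type`.
#' @param window Motif half-width in residues.
#' @return List with `partitions` (named list of `region_partition`, keyed by
#'   accession) and `skipped` (data.frame accession/reason).
#' @export
build_all_partitions <- function(proteins, sites, window = 7L) {
  skipped <- list()
  parts <- list()
  for (acc in unique(sites$accession)) {
    prow <- proteins[match(acc, proteins$accession), , drop = FALSE]
    if (is.na(prow$length[1])) {
      skipped[[acc]] <- "accession not in proteome"
      next
    }
    ssub <- sites[sites$accession == acc, , drop = FALSE]
    if (any(ssub$position > prow$length[1])) {
      skipped[[acc]] <- "site position beyond protein length"
      next
    }
    part <- build_partition(prow, ssub, window = window)
    if (part$k == part$n) {
      skipped[[acc]] <- "no background (modification region covers whole protein)"
      next
    }
    parts[[acc]] <- part
  }
  skipped_df <- data.frame(accession = names(skipped),
                           reason = unlist(skipped, use.names = FALSE),
                           stringsAsFactors = FALSE)
  if (nrow(skipped_df) == 0) {
    skipped_df <- data.frame(accession = character(), reason = character(),
                             stringsAsFactors = FALSE)
  }
  list(partitions = parts, skipped = skipped_df)
}
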