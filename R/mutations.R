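# Cohort mutation ingestion, consequence filtering, per-position counting.

CONSEQUENCE_LEVELS <- c("missense", "synonymous", "stopgain", "stoploss", "other")

#' Load protein-level mutations from TSV or pre-annotated VCF
#'
#' TSV input needs columns `sample_id`, `accession`, `position`, `ref_aa`,
#' `alt_aa`, `consequence`. VCF input must carry one pipe-delimited protein
#' annotation per ALT allele in an INFO field
#' (`accession|protein_position|ref_aa|alt_aa|consequence`); genomic-to-protein
#' mapping itself is out of scope and assumed done upstream. Records whose
#' annotation cannot be parsed are skipped and tallied.
#'
#' @param path Input file.
#' @param format `"tsv"`, `"vcf"`, or `"auto"` (sniffed from content).
#' @param info_key INFO field holding the protein annotation (VCF only).
#' @return Data.frame of mutation records with attribute `n_skipped`.
#' @export
load_mutations <- function(path, format = c("auto", "tsv", "vcf"),
                           info_key = "PROTANN") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("mutation file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, "##fileformat=VCF")) "vcf" else "tsv"
  }
  if (format == "tsv") {
    load_mutations_tsv(path)
  } else {
    load_mutations_vcf(path, info_key)
  }
}

load_mutations_tsv <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE, quote = "")
  required <- c("sample_id", "accession", "position", "ref_aa", "alt_aa", "consequence")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("mutation TSV missing column(s): ", paste(missing, collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(raw$position))
  bad <- is.na(pos) | pos < 1
  n_skipped <- sum(bad)
  if (n_skipped > 0) warning(sprintf("skipped %d unparsable mutation row(s)", n_skipped))
  rec <- data.frame(
    sample_id = raw$sample_id[!bad], accession = raw$accession[!bad],
    position = pos[!bad], ref_aa = raw$ref_aa[!bad], alt_aa = raw$alt_aa[!bad],
    consequence = normalize_consequence(raw$consequence[!bad]),
    stringsAsFactors = FALSE
  )
  rownames(rec) <- NULL
  attr(rec, "n_skipped") <- n_skipped
  rec
}

# Maps common annotation spellings onto the controlled consequence vocabulary.
normalize_consequence <- function(x) {
  x <- tolower(trimws(x))
  out <- rep("other", length(x))
  out[x %in% c("missense", "missense_variant", "nonsynonymous", "nonsynonymous_snv")] <- "missense"
  out[x %in% c("synonymous", "synonymous_variant", "silent", "synonymous_snv")] <- "synonymous"
  out[x %in% c("stopgain", "stop_gained", "nonsense")] <- "stopgain"
  out[x %in% c("stoploss", "stop_lost")] <- "stoploss"
  out
}

load_mutations_vcf <- function(path, info_key) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("VCF input requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  info <- VariantAnnotation::info(vcf)
  if (!info_key %in% colnames(info)) {
    stop(sprintf(paste0("VCF lacks the '%s' INFO annotation; pre-annotate protein ",
                        "consequences (accession|position|ref_aa|alt_aa|consequence) ",
                        "or point info_key at the right field"), info_key))
  }
  ann <- info[[info_key]]            # CharacterList, one entry per ALT allele
  ann_flat <- unlist(as.list(ann), use.names = FALSE)
  # sample id: first genotyped sample name if present, else the VCF basename
  samples <- VariantAnnotation::samples(VariantAnnotation::header(vcf))
  n_skipped <- 0L
  rows <- list()
  for (i in seq_along(ann_flat)) {
    fields <- strsplit(ann_flat[i], "|", fixed = TRUE)[[1]]
    pos <- suppressWarnings(as.integer(fields[2]))
    if (length(fields) < 5 || is.na(pos) || pos < 1 || fields[1] == "") {
      n_skipped <- n_skipped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = if (length(samples)) samples[1] else basename(path),
      accession = fields[1], position = pos,
      ref_aa = fields[3], alt_aa = fields[4],
      consequence = normalize_consequence(fields[5]),
      stringsAsFactors = FALSE
    )
  }
  n_missing <- sum(lengths(as.list(ann)) == 0)
  n_skipped <- n_skipped + n_missing
  rec <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), accession = character(),
               position = integer(), ref_aa = character(),
               alt_aa = character(), consequence = character(),
               stringsAsFactors = FALSE)
  if (n_skipped > 0) warning(sprintf("skipped %d VCF record(s) without parsable annotation", n_skipped))
  rownames(rec) <- NULL
  attr(rec, "n_skipped") <- n_skipped
  rec
}

#' Retain only missense mutations
#'
#' Applies the consequence filter used throughout: only non-synonymous single
#' amino-acid substitutions that neither create a premature stop codon nor
#' remove the existing one are kept, i.e. `consequence == "missense"`.
#'
#' @param records Mutation data.frame from [load_mutations()].
#' @return Filtered data.frame; counts of dropped records per consequence
#'   class attached as attribute `dropped_by_class` (named integer vector).
#' @export
filter_nonsynonymous <- function(records) {
  keep <- records$consequence == "missense"
  dropped <- table(factor(records$consequence[!keep],
                          levels = setdiff(CONSEQUENCE_LEVELS, "missense")))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_by_class") <- stats::setNames(as.integer(dropped), names(dropped))
  out
}

#' Per-position mutation counts over a region partition
#'
#' Counts retained mutations at each residue of the modification and
#' background regions, summed over samples (recurrent hits in multiple
#' samples, and distinct amino-acid changes at one position, all accumulate).
#' Positions with no mutation are kept as zeros; records beyond the protein
#' length are dropped with a warning.
#'
#' @param partition A `region_partition`.
#' @param records Mutations for this protein (any sample), already filtered.
#' @return Object of class `count_vector`: list with `partition`,
#'   `mod_counts` (integer vector aligned to `partition$mod_positions`),
#'   `bg_counts` (aligned to `bg_positions`), and totals `mod_total`,
#'   `bg_total`.
#' @export
count_by_position <- function(partition, records) {
  stopifnot(inherits(partition, "region_partition"))
  records <- records[records$accession == partition$accession, , drop = FALSE]
  over <- records$position > partition$n
  if (any(over)) {
    warning(sprintf("dropped %d mutation(s) beyond length of %s",
                    sum(over), partition$accession))
    records <- records[!over, , drop = FALSE]
  }
  tab <- tabulate(records$position, nbins = partition$n)
  structure(list(
    partition = partition,
    mod_counts = tab[partition$mod_positions],
    bg_counts = tab[partition$bg_positions],
    mod_total = sum(tab[partition$mod_positions]),
    bg_total = sum(tab[partition$bg_positions])
  ), class = "count_vector")
}

#' @export
print.count_vector <- function(x, ...) {
  cat(sprintf("count_vector: %s [%s] mod %d over k=%d | bg %d over %d\n",
              x$partition$accession, x$partition$ptm_type,
              x$mod_total, x$partition$k, x$bg_total,
              x$partition$n - x$partition$k))
  invisible(x)
}
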