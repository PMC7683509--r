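# In-code fixtures: tiny catalogs, proteomes, mutation tables and a minimal
# pre-annotated VCF, written to tempfiles.

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

fixture_sites <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(accession = r[[1]], position = as.integer(r[[2]]),
               residue = if (length(r) >= 4) r[[4]] else "S",
               ptm_type = r[[3]], evidence = "PMID:1",
               stringsAsFactors = FALSE)
  }))
}

fixture_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  lines <- unlist(lapply(names(seqs), function(a) c(paste0(">", a), seqs[[a]])))
  writeLines(lines, path)
  path
}

fixture_mutations <- function(df, path = tempfile(fileext = ".tsv")) {
  write_tsv_fixture(df, path)
}

mut_row <- function(sample, acc, pos, ref = "A", alt = "V",
                    consequence = "missense") {
  data.frame(sample_id = sample, accession = acc, position = as.integer(pos),
             ref_aa = ref, alt_aa = alt, consequence = consequence,
             stringsAsFactors = FALSE)
}

# Minimal pre-annotated VCF: body rows are lists of (chrom, pos, ref, alt, info)
fixture_vcf <- function(body, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=PROTANN,Number=.,Type=String,Description=\"accession|protein_position|ref_aa|alt_aa|consequence, one per ALT\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- vapply(body, function(r) {
    paste(r[[1]], r[[2]], ".", r[[3]], r[[4]], ".", "PASS", r[[5]], sep = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  path
}

# partition for a single protein/length with given site positions
make_partition <- function(n, site_pos, window = 7, acc = "P1",
                           ptm = "Phosphorylation") {
  sites <- do.call(rbind, lapply(site_pos, function(p) {
    data.frame(accession = acc, position = as.integer(p), residue = "S",
               ptm_type = ptm, evidence = NA_character_,
               stringsAsFactors = FALSE)
  }))
  build_partition(list(accession = acc, length = n), sites, window = window)
}

# independent textbook step-up BH, used as oracle against bh_adjust()
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- pmin(rev(cummin(rev(ranked))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
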