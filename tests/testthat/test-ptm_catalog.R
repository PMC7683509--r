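test_that("catalog loading deduplicates, filters by type, rejects bad positions", {
  df <- rbind(fixture_sites(list("P1", 10, "Phosphorylation"),
                            list("P1", 10, "Phosphorylation"),   # exact duplicate
                            list("P1", 20, "Ubiquitination"),
                            list("P2", 5, "Phosphorylation"),
                            list("P2", 9, "Phosphorylation")))
  path <- write_tsv_fixture(df)
  sites <- load_ptm_sites(path)
  expect_equal(nrow(sites), 4)

  phos <- load_ptm_sites(path, ptm_type_filter = "Phosphorylation")
  expect_equal(nrow(phos), 3)
  expect_true(all(phos$ptm_type == "Phosphorylation"))

  df_bad <- df
  df_bad$position[1] <- 0L
  path_bad <- write_tsv_fixture(df_bad)
  expect_warning(bad <- load_ptm_sites(path_bad), "malformed")
  expect_equal(attr(bad, "n_rejected"), 1)

  expect_error(load_ptm_sites(write_tsv_fixture(df[, -1, drop = FALSE])),
               "missing required column")
})

test_that("protein lengths load from FASTA and TSV with first-wins duplicates", {
  fa <- fixture_fasta(list(P1 = strrep("M", 100)))
  info <- load_protein_lengths(fa)
  expect_equal(info$length[info$accession == "P1"], 100L)

  tsv <- write_tsv_fixture(data.frame(accession = "P2", length = 42L))
  info2 <- load_protein_lengths(tsv)
  expect_equal(info2$length, 42L)

  dup <- fixture_fasta(list(P3 = strrep("A", 10), P3 = strrep("A", 20)))
  expect_warning(info3 <- load_protein_lengths(dup), "duplicate")
  expect_equal(info3$length[info3$accession == "P3"], 10L)

  empty <- tempfile(); file.create(empty)
  expect_error(load_protein_lengths(empty), "empty")
})

test_that("motif windows expand, merge and truncate correctly", {
  p <- make_partition(100, 10)
  expect_equal(p$mod_positions, 3:17)
  expect_equal(p$k, 15L)

  p2 <- make_partition(100, c(10, 20))
  expect_equal(p2$mod_positions, 3:27)   # overlapping windows merged
  expect_equal(p2$k, 25L)

  p3 <- make_partition(10, 2)            # truncation at the N-terminus
  expect_equal(p3$mod_positions, 1:9)
  expect_equal(p3$bg_positions, 10L)

  p4 <- make_partition(15, 8)            # whole protein covered
  expect_equal(p4$k, 15L)
  expect_length(p4$bg_positions, 0)
})

test_that("partition construction validates its inputs", {
  expect_error(make_partition(50, 60), "beyond protein length")
  expect_error(build_partition(list(accession = "P1", length = 50),
                               fixture_sites()[0, ]), "not testable")
  two_types <- rbind(fixture_sites(list("P1", 5, "Phosphorylation")),
                     fixture_sites(list("P1", 9, "Acetylation")))
  expect_error(build_partition(list(accession = "P1", length = 50), two_types),
               "single ptm_type")
})

test_that("partition algebra holds over random site sets", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(20:500, 1)
    w <- sample(0:10, 1)
    npos <- sample(1:5, 1)
    pos <- sample.int(n, npos)
    p <- make_partition(n, pos, window = w)
    expect_length(intersect(p$mod_positions, p$bg_positions), 0)
    expect_equal(length(p$mod_positions) + length(p$bg_positions), n)
    expect_true(all(pos %in% p$mod_positions))
    # order invariance and idempotence under duplicated sites
    p_rev <- make_partition(n, c(rev(pos), pos[1]), window = w)
    expect_equal(p_rev$mod_positions, p$mod_positions)
    # monotonicity: one more site never shrinks the region
    extra <- make_partition(n, c(pos, sample.int(n, 1)), window = w)
    expect_gte(extra$k, p$k)
  }
})

test_that("cohort partition builder skips unmapped and fully covered proteins", {
  proteins <- data.frame(accession = c("P1", "P2"), length = c(100L, 15L))
  sites <- rbind(fixture_sites(list("P1", 10, "Phosphorylation"),
                               list("P2", 8, "Phosphorylation"),
                               list("P9", 3, "Phosphorylation")))
  built <- build_all_partitions(proteins, sites)
  expect_named(built$partitions, "P1")
  expect_setequal(built$skipped$accession, c("P2", "P9"))
  expect_match(built$skipped$reason[built$skipped$accession == "P2"],
               "no background")
})
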