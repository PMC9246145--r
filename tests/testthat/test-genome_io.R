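test_that("FASTA reading takes the first header token and upper-cases", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1 some description", "atggcctaa", ">g2", "ATGAAATAA"), path)
  rec <- read_cds_fasta(path)
  expect_identical(rec$gene_id, c("g1", "g2"))
  expect_identical(rec$sequence[1], "ATGGCCTAA")

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_cds_fasta(empty))
})

test_that("gene filters enforce start, frame, internal stops and alphabet", {
  rec <- data.frame(
    gene_id = paste0("g", 1:6),
    sequence = c(
      "ATGGCCTAA",     # canonical
      "ATGTAAGCCTAA",  # internal stop
      "TTGGCCTAA",     # non-canonical start
      "ATGGCCTA",      # length not multiple of 3
      "ATGGNCTAA",     # ambiguity code
      "ATGGCCGCC"      # no terminal stop: still fine
    ),
    stringsAsFactors = FALSE
  )
  flt <- filter_genes(rec, exclusion_ids = "g6")
  expect_identical(flt$retained$gene_id, "g1")
  got <- setNames(flt$rejected$reason, flt$rejected$gene_id)
  expect_identical(got[["g2"]], "internal_stop")
  expect_identical(got[["g3"]], "non_canonical_start")
  expect_identical(got[["g4"]], "length_not_multiple_of_3")
  expect_identical(got[["g5"]], "ambiguous_bases")
  expect_identical(got[["g6"]], "excluded")
})

test_that("codon counting drops the initiator and terminal stop", {
  gc <- genetic_code()
  counts <- count_codons("ATGGCCGCCTAA", gc)
  expect_identical(unname(counts["GCC"]), 2L)
  expect_identical(sum(counts), 2L)

  # a second ATG is an ordinary methionine codon
  counts2 <- count_codons("ATGATGTAA", gc)
  expect_identical(unname(counts2["ATG"]), 1L)

  # start codon can be kept for compatibility checks
  counts3 <- count_codons("ATGGCCTAA", gc, count_start_codon = TRUE)
  expect_identical(unname(counts3["ATG"]), 1L)
  expect_identical(sum(counts3), 2L)
})

test_that("count totals follow the length arithmetic", {
  gc <- genetic_code()
  set.seed(42)
  for (with_stop in c(TRUE, FALSE)) {
    body <- paste(sample(gc$codons, 300, replace = TRUE), collapse = "")
    seq <- paste0("ATG", body, if (with_stop) "TAA" else "")
    counts <- count_codons(seq, gc)
    expect_identical(sum(counts), 300L)
  }
})

test_that("GC3 equals a brute-force scan of third positions", {
  gc <- genetic_code()
  expect_equal(gc3_percent(count_codons("ATGGCCGCCTAA", gc)), 1.0)
  v <- setNames(rep(0L, 61), gc$codons)
  v["AAA"] <- 1L; v["AAG"] <- 1L
  expect_equal(gc3_percent(v), 0.5)
  expect_error(gc3_percent(v * 0L), "zero")

  set.seed(7)
  cods <- sample(gc$codons, 1000, replace = TRUE)
  seq <- paste0("ATG", paste(cods, collapse = ""), "TAA")
  counts <- count_codons(seq, gc)
  brute <- mean(substr(cods, 3, 3) %in% c("G", "C"))
  expect_equal(gc3_percent(counts), brute)
  # invariant under permutation of codon order
  seq2 <- paste0("ATG", paste(sample(cods), collapse = ""), "TAA")
  expect_equal(gc3_percent(count_codons(seq2, gc)), brute)
})

test_that("count tables align genes, GC3 and coordinates", {
  meta <- data.frame(gene_id = c("gA", "gB", "gC"),
                     chromosome = c("chr1", "chr1", "chr2"),
                     position = c(1L, 2L, 1L))
  tab <- toy_table(metadata = meta)
  expect_identical(tab$gene_ids, c("gA", "gB", "gC"))
  expect_identical(dim(tab$counts), c(3L, 61L))
  expect_equal(unname(tab$gc3), unname(gc3_percent(tab$counts)))
  expect_identical(tab$coords$chromosome, c("chr1", "chr1", "chr2"))

  # partial metadata warns and leaves NA coordinates
  expect_warning(
    tab2 <- build_count_table(toy_records(), metadata = meta[1:2, ]),
    "missing"
  )
  expect_true(is.na(tab2$coords$chromosome[3]))

  # duplicated ids are an integrity error
  dup <- rbind(toy_records(), toy_records()[1, ])
  expect_error(build_count_table(dup), "duplicate")
})

test_that("FASTA round trip reproduces the count table", {
  rec <- toy_records()
  path <- withr::local_tempfile(fileext = ".fasta")
  write_cds_fasta(rec, path)
  rec2 <- read_cds_fasta(path)
  expect_identical(build_count_table(rec2)$counts, toy_table()$counts)
})
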