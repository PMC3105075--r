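# File readers/writers: validation, positional diagnostics, round trips.

test_that("read_fasta parses minimal files and validates records", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1 a contig", "ACGT"), f)
  x <- read_fasta(f)
  expect_equal(names(x), "c1")
  expect_equal(as.character(x[["c1"]]), "ACGT")

  writeLines(c(">c1", "ACGT", ">c1", "GGCC"), f)
  expect_error(read_fasta(f), "duplicate FASTA id 'c1'")

  writeLines(c(">c1", "ACGT", ">c2"), f)
  expect_error(read_fasta(f), "empty sequence")

  writeLines(c(">c1", "ACGT", ">c2", "ACXT"), f)
  expect_error(read_fasta(f), "line 4")
})

test_that("read_fasta normalises case and admits N", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1", "acgtN"), f)
  expect_equal(as.character(read_fasta(f)[[1]]), "ACGTN")
})

test_that("write_fasta / read_fasta round-trips sequences", {
  set.seed(42)
  seqs <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), sample(50:300, 1),
                 replace = TRUE), collapse = ""), character(1))
  names(seqs) <- sprintf("s%02d", 1:20)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_equal(names(back), names(seqs))
  expect_equal(as.character(back), seqs, ignore_attr = TRUE)
})

test_that("alignment hit tables parse, validate and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(
    "contig21506", "nr_cel1c", "88.6", "300", "34", "0", "1", "300",
    "1", "300", "1e-110", "400", "Piromyces", "beta-glucosidase Cel1C",
    sep = "\t"), f)
  h <- read_hit_table(f, "alignment")
  expect_equal(h$percent_identity, 88.6)
  expect_equal(h$e_value, 1e-110)
  expect_equal(h$subject_taxon, "Piromyces")

  # empty (comments only) file -> empty typed table
  writeLines("# no hits", f)
  expect_equal(nrow(read_hit_table(f, "alignment")), 0)

  # coordinate violation and unparsable numerics carry positions
  writeLines(paste("r1", "s1", "90", "100", "0", "0", "200", "100",
                   "1", "100", "1e-20", "80", sep = "\t"), f)
  expect_error(read_hit_table(f, "alignment"), "q_start > q_end")
  writeLines(paste("r1", "s1", "ninety", "100", "0", "0", "1", "100",
                   "1", "100", "1e-20", "80", sep = "\t"), f)
  expect_error(read_hit_table(f, "alignment"), "row 1")

  hits <- rbind(make_hit("r1", e_value = 1.5e-33, taxon = "Piromyces",
                         annotation = "cellulase Cel48A precursor"),
                make_hit("r2", bit_score = 52))
  write_hit_table(hits, f)
  back <- read_hit_table(f, "alignment")
  expect_equal(back, validate_alignment_hits(hits), ignore_attr = TRUE)
})

test_that("domain hit tables parse, validate and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  dh <- rbind(make_domain_hit("c1", "PF_GH48", 101.5, 2e-31, 10, 900),
              make_domain_hit("c1", "PF_CBM10", 53, 1e-8, 950, 1050))
  write_hit_table(dh, f, comments = "config=abc")
  back <- read_hit_table(f, "domain")
  expect_equal(back, validate_domain_hits(dh), ignore_attr = TRUE)
  expect_error(
    validate_domain_hits(make_domain_hit("c1", "m", q_start = 5, q_end = 2)),
    "q_start > q_end")
})

test_that("coordinates are 1-based inclusive: span a..b has length b-a+1", {
  h <- make_hit("r1", q_start = 17, q_end = 66)
  expect_equal(h$q_end - h$q_start + 1, 50)
  # the ncRNA overlap rule sees exactly this length
  res <- classify_ncrna("r1", h, max_evalue = 1e-5, min_overlap = 50)
  expect_true(res$calls$is_ncrna)
})

test_that("taxonomy reader validates tree structure", {
  f <- withr::local_tempfile(fileext = ".tsv")
  nodes <- data.frame(
    taxon_id = c("root", "Eukaryota", "Neocallimastigomycota"),
    parent_id = c("", "root", "Eukaryota"),
    rank = c("root", "kingdom", "phylum"),
    name = c("r", "e", "n"), stringsAsFactors = FALSE)
  write_taxonomy(taxonomy(nodes), f)
  tax <- read_taxonomy(f)
  expect_equal(length(tax_lineage(tax, "Neocallimastigomycota")), 3)

  bad <- nodes; bad$parent_id[3] <- "missing"
  expect_error(taxonomy(bad), "not present as a node")
  bad <- nodes; bad$parent_id[1] <- "root"; bad$parent_id[2] <- ""
  expect_error(taxonomy(bad), "exactly one root")
  bad <- rbind(nodes, data.frame(taxon_id = c("a", "b"),
                                 parent_id = c("b", "a"),
                                 rank = "genus", name = c("a", "b")))
  expect_error(taxonomy(bad), "cycle|not present")
})

test_that("taxonomy from the generator round-trips through TSV", {
  tax <- generate_taxonomy()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_taxonomy(tax, f, comments = "config=xyz")
  back <- read_taxonomy(f)
  expect_equal(back$nodes, tax$nodes)
  expect_equal(back$root, tax$root)
})
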