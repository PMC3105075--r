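# Association-table construction (member coverage rules), module calling,
# architecture resolution and identity binning.

test_that("single-family models are accepted at >= 80% member coverage", {
  fd <- small_family_defs()
  # 17 of 20 GH6 members (85%) -> accepted
  tab <- build_association_table(fd, member_hits_for(fd, "GH6", 17))
  expect_true(tab$accepted)
  expect_equal(tab$label, "GH6")
  expect_equal(tab$step, "B")
  expect_equal(tab$rejection_reason, "none")
  # 15 of 20 (75%) -> rejected, low coverage
  tab <- build_association_table(fd, member_hits_for(fd, "GH6", 15))
  expect_false(tab$accepted)
  expect_equal(tab$rejection_reason, "low_coverage")
  # exactly 16 of 20 (80%) sits on the boundary and is accepted
  tab <- build_association_table(fd, member_hits_for(fd, "GH6", 16))
  expect_true(tab$accepted)
})

test_that("combined classes need every implicated family to pass coverage", {
  fd <- small_family_defs()
  both <- rbind(member_hits_for(fd, "CE2", 9),   # 90%
                member_hits_for(fd, "CE3", 8))   # 80%
  tab <- build_association_table(fd, both)
  expect_true(tab$accepted)
  expect_equal(tab$label, "CE2/CE3")   # parts sorted, joined by /

  mixed <- rbind(member_hits_for(fd, "CE2", 9),  # 90%
                 member_hits_for(fd, "CE3", 2))  # 20%
  tab <- build_association_table(fd, mixed)
  expect_false(tab$accepted)
  expect_equal(tab$rejection_reason, "impure")
})

test_that("association building is order-independent and strict on members", {
  fd <- small_family_defs()
  h <- rbind(member_hits_for(fd, "GH6", 18, model_id = "PF_A"),
             member_hits_for(fd, "CE2", 9, model_id = "PF_B"),
             member_hits_for(fd, "CE3", 9, model_id = "PF_B"))
  set.seed(1)
  shuffled <- h[sample(nrow(h)), ]
  expect_equal(build_association_table(fd, h),
               build_association_table(fd, shuffled))
  expect_error(
    build_association_table(fd, data.frame(member_id = "nobody",
                                           model_id = "PF_A",
                                           significant = TRUE)),
    "nobody")
})

test_that("the score cutoff is inclusive and routes label hits", {
  assoc <- data.frame(model_id = c("PF_GH6", "PF_GH48"),
                      label = c("GH6", "GH48"), step = "B",
                      accepted = TRUE, rejection_reason = "none",
                      stringsAsFactors = FALSE)
  dh <- rbind(make_domain_hit("c1", "PF_GH6", bit_score = 52),
              make_domain_hit("c2", "PF_GH48", bit_score = 51.9))
  calls <- call_modules(dh, assoc = assoc)
  expect_equal(calls$contig_id, "c1")   # exactly 52 retained, 51.9 dropped
  expect_equal(calls$label, "GH6")
})

test_that("stacked distinct modules are kept in coordinate order", {
  direct <- c(PF_GH48 = "GH48", PF_CBM10 = "CBM10")
  dh <- rbind(make_domain_hit("c1", "PF_CBM10", q_start = 950, q_end = 1050),
              make_domain_hit("c1", "PF_GH48", q_start = 10, q_end = 900))
  calls <- call_modules(dh, direct_models = direct)
  expect_equal(calls$label, c("GH48", "CBM10"))
  expect_equal(calls$q_start, c(10, 950))
})

test_that("overlapping same-label hits merge to the union with max score", {
  direct <- c(PF_GH6 = "GH6")
  dh <- rbind(make_domain_hit("c1", "PF_GH6", 60, q_start = 10, q_end = 200),
              make_domain_hit("c1", "PF_GH6", 75, q_start = 150, q_end = 400))
  calls <- call_modules(dh, direct_models = direct)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$q_start, 10)
  expect_equal(calls$q_end, 400)
  expect_equal(calls$score, 75)

  # non-overlapping same-label hits stay separate
  dh2 <- rbind(make_domain_hit("c1", "PF_GH6", 60, q_start = 10, q_end = 100),
               make_domain_hit("c1", "PF_GH6", 70, q_start = 300, q_end = 400))
  expect_equal(nrow(call_modules(dh2, direct_models = direct)), 2)
})

test_that("module calling is idempotent under re-merging", {
  direct <- c(PF_GH6 = "GH6", PF_CBM10 = "CBM10")
  set.seed(7)
  dh <- do.call(rbind, lapply(1:40, function(i) {
    st <- sample(1000, 1)
    make_domain_hit(paste0("c", sample(5, 1)),
                    sample(names(direct), 1),
                    bit_score = runif(1, 40, 120),
                    q_start = st, q_end = st + sample(50:300, 1))
  }))
  calls <- call_modules(dh, direct_models = direct)
  as_hits <- data.frame(query_id = calls$contig_id, model_id =
                          paste0("PF_", calls$label),
                        bit_score = calls$score, e_value = 1e-20,
                        q_start = calls$q_start, q_end = calls$q_end,
                        source = calls$source, stringsAsFactors = FALSE)
  again <- call_modules(as_hits, direct_models = direct)
  expect_equal(again, calls)
})

test_that("unroutable models warn and are counted as unclassified", {
  dh <- make_domain_hit("c1", "PF_MYSTERY", bit_score = 90)
  expect_warning(calls <- call_modules(dh, direct_models = c(PF_GH6 = "GH6")),
                 "PF_MYSTERY")
  expect_equal(calls$label, "unclassified")
})

test_that("the representative-sequence (blast) route labels calls", {
  bh <- rbind(make_hit("c1", subject_id = "rep_GH61", bit_score = 52,
                       q_start = 1, q_end = 200),
              make_hit("c2", subject_id = "rep_GH61", bit_score = 40,
                       q_start = 1, q_end = 200))
  calls <- call_modules(empty_hits("domain"), blast_hits = bh,
                        rep_labels = c(rep_GH61 = "GH61"))
  expect_equal(calls$contig_id, "c1")
  expect_equal(calls$source, "blast")
})

test_that("multi-domain architectures and label shares resolve correctly", {
  calls <- rbind(
    data.frame(contig_id = "c1", label = c("GH48", "CBM10"),
               q_start = c(10, 950), q_end = c(900, 1050),
               score = 80, source = "hmm"),
    data.frame(contig_id = "c2", label = c("GH6", "GH6"),
               q_start = c(10, 400), q_end = c(200, 600),
               score = 70, source = "hmm"),
    data.frame(contig_id = "c3", label = c("GH6", "CBM10"),
               q_start = c(10, 400), q_end = c(200, 600),
               score = 70, source = "hmm"),
    data.frame(contig_id = "c4", label = "GH11",
               q_start = 10, q_end = 200, score = 70, source = "hmm"))
  info <- data.frame(contig_id = paste0("c", 1:4),
                     length = c(1200, 800, 700, 300))
  ann <- annotate_contigs(info, calls)
  arch <- resolve_architectures(ann, min_len = 500)
  # c2 has two calls of ONE label -> not multi-domain; c4 is short
  expect_equal(arch$multi_domain_contigs, c("c1", "c3"))
  expect_equal(arch$n_multi, 2)
  share <- setNames(arch$label_share$percent, arch$label_share$label)
  expect_equal(share[["CBM10"]], 100)
  expect_equal(share[["GH48"]], 50)
  cooc <- arch$cooccurrence
  expect_equal(cooc$count[cooc$label_a == "CBM10" & cooc$label_b == "GH48"], 1)
  expect_equal(cooc$count[cooc$label_a == "CBM10" & cooc$label_b == "GH6"], 1)
})

test_that("identity bins use the stated edges and balance their total", {
  info <- data.frame(contig_id = paste0("c", 1:5), length = 1000)
  calls <- data.frame(contig_id = paste0("c", 1:5), label = "GH6",
                      q_start = 1, q_end = 200, score = 80, source = "hmm")
  top <- rbind(make_hit("c1", pident = 88.6), make_hit("c2", pident = 37.8),
               make_hit("c3", pident = 50.0), make_hit("c4", pident = 70.0))
  ann <- annotate_contigs(info, calls, top_hits = top)
  b <- bin_identity(ann)
  expect_equal(unname(b$counts),
               c(1L, 2L, 1L, 1L))  # <50: 37.8; 50-70: 50 and 70; >70: 88.6
  expect_equal(sum(b$counts), nrow(ann$contigs))
  expect_equal(unname(b$percent["50-70"]), 50)
  expect_error(bin_identity(local({
    a <- ann; a$contigs$top_identity[1] <- 120; a
  })), "outside")
})

test_that("zero-noise module calls equal the planted architecture truth", {
  sim <- simulate_dataset(n_contigs = 150, n_reads = 1000, seed = 23)
  assoc <- build_association_table(sim$family_defs, sim$member_hits)
  expect_true(all(assoc$accepted))
  calls <- call_modules(sim$hits$domain, assoc = assoc)
  truth <- sim$truth$modules
  got <- calls[order(calls$contig_id, calls$q_start),
               c("contig_id", "label", "q_start", "q_end")]
  want <- truth[order(truth$contig_id, truth$q_start),
                c("contig_id", "label", "q_start", "q_end")]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, transform(want, q_start = as.numeric(q_start),
                              q_end = as.numeric(q_end)))

  # contig-level co-occurrence tallies equal the truth's architectures
  info <- data.frame(contig_id = names(sim$contigs),
                     length = Biostrings::width(sim$contigs))
  ann <- annotate_contigs(info, calls)
  arch <- resolve_architectures(ann, min_len = 0)
  truth_sets <- lapply(split(truth$label, truth$contig_id), unique)
  expect_setequal(arch$multi_domain_contigs,
                  names(truth_sets)[lengths(truth_sets) >= 2])
})
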