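# Shared fixtures and independent oracles for the test suite.

# A minimal 6-node taxonomy: root -> Eukaryota -> one fungal phylum with
# two genera, plus a bacterial outgroup.
tiny_taxonomy <- function() {
  taxonomy(data.frame(
    taxon_id = c("root", "Eukaryota", "Neocallimastigomycota",
                 "Piromyces", "Orpinomyces", "Bacteria"),
    parent_id = c("", "root", "Eukaryota",
                  "Neocallimastigomycota", "Neocallimastigomycota", "root"),
    rank = c("root", "kingdom", "phylum", "genus", "genus", "kingdom"),
    name = c("cellular organisms", "Eukaryota", "Neocallimastigomycota",
             "Piromyces", "Orpinomyces", "Bacteria"),
    stringsAsFactors = FALSE
  ))
}

# Random tree over n nodes: node i's parent drawn uniformly among 1..i-1.
# Ranks are unused by the LCA machinery, so every internal node gets a
# generic rank.
random_taxonomy <- function(n) {
  parent <- c("", paste0("t", vapply(seq_len(n - 1) + 1, function(i)
    sample.int(i - 1, 1), integer(1))))
  taxonomy(data.frame(
    taxon_id = paste0("t", seq_len(n)),
    parent_id = parent,
    rank = c("root", rep("species", n - 1)),
    name = paste0("taxon ", seq_len(n)),
    stringsAsFactors = FALSE
  ))
}

# Brute-force LCA oracle: intersect full ancestor sets, pick the deepest.
oracle_lca <- function(tax, ids) {
  lineages <- lapply(ids, function(id) tax_lineage(tax, id))
  common <- Reduce(intersect, lineages)
  depths <- vapply(common, function(id) length(tax_lineage(tax, id)),
                   integer(1))
  common[which.max(depths)]
}

# Minimal alignment-hit row builder with sensible defaults.
make_hit <- function(query_id, subject_id = "s1", pident = 90,
                     alen = 100, q_start = 1, q_end = 100,
                     e_value = 1e-20, bit_score = 100,
                     taxon = "", annotation = "") {
  data.frame(query_id = query_id, subject_id = subject_id,
             percent_identity = pident, align_length = alen,
             mismatches = 0, gap_open = 0,
             q_start = q_start, q_end = q_end, s_start = 1, s_end = alen,
             e_value = e_value, bit_score = bit_score,
             subject_taxon = taxon, subject_annotation = annotation,
             stringsAsFactors = FALSE)
}

make_domain_hit <- function(query_id, model_id, bit_score = 80,
                            e_value = 1e-20, q_start = 1, q_end = 120,
                            source = "hmm") {
  data.frame(query_id = query_id, model_id = model_id,
             bit_score = bit_score, e_value = e_value,
             q_start = q_start, q_end = q_end, source = source,
             stringsAsFactors = FALSE)
}

# Family universe with controllable member counts for association tests.
small_family_defs <- function(sizes = c(GH6 = 20L, CE2 = 10L, CE3 = 10L)) {
  df <- data.frame(
    family_id = names(sizes),
    class_code = sub("[0-9].*$", "", names(sizes)),
    stringsAsFactors = FALSE
  )
  df$member_ids <- lapply(seq_along(sizes), function(i)
    sprintf("%s_m%02d", names(sizes)[i], seq_len(sizes[i])))
  df$pfam_model_ids <- lapply(names(sizes), function(f) paste0("PF_", f))
  class(df) <- c("cazy_family_defs", "data.frame")
  df
}

member_hits_for <- function(family_defs, family_id, n_members,
                            model_id = "PF_X") {
  members <- family_defs$member_ids[[
    which(family_defs$family_id == family_id)]][seq_len(n_members)]
  data.frame(member_id = members, model_id = model_id, significant = TRUE,
             stringsAsFactors = FALSE)
}
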