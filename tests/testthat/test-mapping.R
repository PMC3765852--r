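# small handcrafted reference: two genes with distinct unique tags
tag_g1 <- paste0("CATG", strrep("A", 17))
tag_g2 <- paste0("CATG", strrep("C", 17))
handcrafted_ref <- build_virtual_library(c(
  g1 = paste0("TT", tag_g1),
  g2 = paste0("GG", tag_g2)
))

lib_of <- function(tags, counts = rep(1L, length(tags))) {
  clean_tags(data.frame(tag = tags, count = counts))
}

test_that("exact unique hit maps unambiguously to its gene", {
  res <- map_tags(lib_of(tag_g1), handcrafted_ref)
  expect_equal(res$assignments$status, "unambiguous")
  expect_equal(res$assignments$gene_id, "g1")
  expect_equal(res$gene_counts$copies, 1L)
})

test_that("distance-1 hits to two genes with no exact hit are ambiguous", {
  # one substitution from tag_g1 AND from a tag of a second gene
  tag_mid <- paste0("CATG", "T", strrep("A", 16))
  ref <- build_virtual_library(c(
    g1 = paste0("TT", tag_g1),
    g2 = paste0("GG", "CATG", "T", strrep("A", 15), "C")
  ))
  res <- map_tags(lib_of(tag_mid), ref)
  expect_equal(res$assignments$status, "ambiguous")
  expect_true(is.na(res$assignments$gene_id))
  expect_setequal(res$genes_all_mapped, c("g1", "g2"))
})

test_that("exact hits take priority over 1-mismatch co-hits", {
  # query equals g1's tag exactly and is one mismatch from g2's second tag
  near <- paste0("CATG", strrep("A", 16), "C")
  ref <- build_virtual_library(c(
    g1 = paste0("TT", tag_g1),
    g2 = paste0("GG", near)
  ))
  res <- map_tags(lib_of(tag_g1), ref)
  expect_equal(res$assignments$status, "unambiguous")
  expect_equal(res$assignments$gene_id, "g1")
})

test_that("a tag hitting two sites of the same gene is unambiguous", {
  ref <- build_virtual_library(c(
    g1 = paste0(tag_g1, "GG", tag_g1)
  ))
  res <- map_tags(lib_of(tag_g1), ref)
  expect_equal(res$assignments$status, "unambiguous")
  expect_equal(res$assignments$gene_id, "g1")
})

test_that("unmatched tags are unknown and parameters are validated", {
  res <- map_tags(lib_of(paste0("CATG", strrep("G", 17))), handcrafted_ref)
  expect_equal(res$assignments$status, "unknown")
  expect_error(map_tags(lib_of(tag_g1), handcrafted_ref, max_mismatch = 2),
               "max_mismatch")
  short <- clean_tags(data.frame(tag = "CATGAA", count = 1), tag_length = 6)
  expect_error(map_tags(short, handcrafted_ref), "length")
})

test_that("anchor-exact mode rejects mismatches inside CATG", {
  anchor_hit <- paste0("CTTG", strrep("A", 17))  # 1 mismatch, in the anchor
  res_any <- map_tags(lib_of(anchor_hit), handcrafted_ref)
  res_strict <- map_tags(lib_of(anchor_hit), handcrafted_ref,
                         anchor_exact = TRUE)
  expect_equal(res_any$assignments$status, "unambiguous")
  expect_equal(res_strict$assignments$status, "unknown")
  # brute method agrees with the index method in strict mode too
  res_brute <- map_tags(lib_of(anchor_hit), handcrafted_ref,
                        anchor_exact = TRUE, method = "brute")
  expect_identical(res_strict$assignments, res_brute$assignments)
})

test_that("raising max_mismatch from 0 to 1 never grows the unknown class", {
  for (seed in 1:5) {
    cfg <- synthetic_config(n_genes = 60, length_min = 60, length_max = 200,
                            seed = seed)
    ref <- build_virtual_library(generate_transcriptome(cfg))
    set.seed(seed + 100)
    tags <- unique(c(sample(ref$tags$tag, 30, replace = TRUE),
                     mutate_tag(sample(ref$tags$tag, 30, replace = TRUE)),
                     random_tag(30)))
    lib <- lib_of(tags)
    u0 <- sum(map_tags(lib, ref, max_mismatch = 0)$assignments$status ==
              "unknown")
    u1 <- sum(map_tags(lib, ref, max_mismatch = 1)$assignments$status ==
              "unknown")
    expect_lte(u1, u0)
  }
})

test_that("index and brute-force methods agree on random instances", {
  for (seed in 1:10) {
    cfg <- synthetic_config(n_genes = 50, length_min = 60, length_max = 200,
                            seed = seed)
    ref <- build_virtual_library(generate_transcriptome(cfg))
    set.seed(seed)
    tags <- unique(c(sample(ref$tags$tag, 40, replace = TRUE),
                     mutate_tag(sample(ref$tags$tag, 40, replace = TRUE)),
                     random_tag(40)))
    lib <- lib_of(tags)
    for (mm in c(0L, 1L)) {
      a <- map_tags(lib, ref, max_mismatch = mm)
      b <- map_tags(lib, ref, max_mismatch = mm, method = "brute")
      expect_identical(a$assignments, b$assignments)
      expect_identical(a$gene_counts, b$gene_counts)
      expect_identical(a$genes_all_mapped, b$genes_all_mapped)
    }
  }
})

test_that("error-free unique-tag reads all map back to their source gene", {
  cfg <- synthetic_config(n_genes = 40, depth = 5000, error_rate = 0,
                          junk_fraction = 0, length_min = 80,
                          length_max = 200, seed = 31)
  exp <- make_de_experiment(cfg)
  ref <- build_virtual_library(exp$reference)
  lib <- clean_tags(exp$library_a)
  res <- map_tags(lib, ref)
  # tags from single-gene-unique canonical sites must be unambiguous
  genes_per_tag <- tapply(ref$tags$gene_id, ref$tags$tag,
                          function(g) length(unique(g)))
  unique_tags <- names(genes_per_tag)[genes_per_tag == 1]
  sel <- res$assignments$tag %in% unique_tags
  expect_true(all(res$assignments$status[sel] == "unambiguous"))
  expect_equal(sum(res$assignments$count), lib$total_clean)
})

test_that("mapping statistics partition clean tags and reproduce percentages", {
  cfg <- synthetic_config(n_genes = 60, depth = 2e4, length_min = 80,
                          length_max = 200, seed = 37)
  exp <- make_de_experiment(cfg)
  ref <- build_virtual_library(exp$reference)
  lib <- clean_tags(exp$library_a)
  st <- mapping_stats(map_tags(lib, ref), ref)
  val <- function(sec, met) st$value[st$section == sec & st$metric == met]
  expect_equal(val("All Tag Mapping to Gene", "Total number") +
               val("Unknown Tag", "Total number"),
               val("Clean Tag", "Total number"))
  expect_equal(val("All Tag Mapping to Gene", "Total % of clean tag") +
               val("Unknown Tag", "Total % of clean tag"),
               100, tolerance = 0.011)
  expect_lte(val("Unambiguous Tag Mapping to Gene", "Total number"),
             val("All Tag Mapping to Gene", "Total number"))
  expect_lte(val("Unambiguous Tag-mapped Genes", "number"),
             val("All Tag-mapped Genes", "number"))
})

test_that("percentages round half away from zero to two decimals", {
  expect_equal(mapping_percent(1215015, 3366354), 36.09)
  expect_equal(mapping_percent(20411, 52040), 39.22)
  expect_equal(mapping_percent(5, 1000), 0.5)
  expect_equal(mapping_percent(125, 100000), 0.13)  # 0.125 rounds up
  expect_warning(z <- mapping_percent(1, 0), "denominator")
  expect_equal(z, 0)
})

test_that("stats tables combine by sample column", {
  cfg <- synthetic_config(n_genes = 30, depth = 5000, length_min = 80,
                          length_max = 150, seed = 41)
  exp <- make_de_experiment(cfg)
  ref <- build_virtual_library(exp$reference)
  sa <- mapping_stats(map_tags(clean_tags(exp$library_a, "A"), ref), ref)
  sb <- mapping_stats(map_tags(clean_tags(exp$library_b, "B"), ref), ref)
  tab <- mapping_stats_table(CK = sa, JA = sb)
  expect_named(tab, c("section", "metric", "CK", "JA"))
  expect_equal(nrow(tab), 18)
})
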